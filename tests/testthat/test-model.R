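# SE block, architecture census, forward/backward, prediction contracts.

desk_cfg <- function(seed = 1L)
  model_config(input_size = 32L, width_mult = 1 / 32, fc_width = 16L,
               seed = seed)

test_that("se_block implements squeeze, two-layer gate and rescale", {
  set.seed(14)
  H <- 4; W <- 5; C <- 6
  u <- array(rnorm(H * W * C), c(H, W, C))
  params <- se_init(C, reduction = 2, seed = 3)
  got <- se_block(u, params)
  # explicit loop transcription of squeeze/excite/scale
  z <- vapply(1:C, function(c) mean(u[, , c]), 0)
  h <- pmax(params$W1 %*% z + params$b1, 0)
  s <- 1 / (1 + exp(-(params$W2 %*% h + params$b2)))
  want <- array(0, c(H, W, C))
  for (c in 1:C) want[, , c] <- u[, , c] * s[c]
  expect_equal(got, want, tolerance = 1e-6)
  # constant channel squeezes to its value
  u2 <- u; u2[, , 3] <- 7
  u4 <- u2; dim(u4) <- c(H, W, C, 1L)
  expect_equal(strokeEEG:::.se_forward(u4, params)$z[3, 1], 7)
  # all-zero gate parameters -> every s_c = 0.5 -> output = u / 2
  zero <- list(W1 = matrix(0, 3, C), b1 = rep(0, 3),
               W2 = matrix(0, C, 3), b2 = rep(0, C))
  expect_equal(se_block(u, zero), u * 0.5)
  # gate output in (0,1) bounds the block by its input
  expect_true(all(abs(got) <= abs(u) + 1e-12))
  expect_error(se_block(u, se_init(4L)), "channel count")
})

test_that("architecture census matches the 13/3/5/5 layout at full scale", {
  cen <- model_census(model_config(input_size = 224L, width_mult = 1))
  expect_identical(cen[["conv"]], 13L)
  expect_identical(cen[["fc"]], 3L)
  expect_identical(cen[["pool"]], 5L)
  expect_identical(cen[["se"]], 5L)
  expect_identical(cen[["conv_3x3"]], 13L)
  # census of an instantiated desk-scale model agrees
  m <- build_model(desk_cfg())
  expect_identical(model_census(m), cen)
  expect_error(model_config(input_size = 48L), "multiple of 32")
})

test_that("forward pass is finite, shaped, deterministic and row-normalised", {
  m <- build_model(desk_cfg(seed = 7))
  set.seed(2)
  x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  p <- predict_proba(m, x)
  expect_identical(dim(p), c(4L, 2L))
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  # duplicated input row -> identical output rows
  x2 <- x; x2[, , , 2] <- x[, , , 1]
  p2 <- predict_proba(m, x2)
  expect_identical(p2[1, ], p2[2, ])
  # batch invariance: same image alone or in a batch
  p1 <- predict_proba(m, x[, , , 1])
  expect_equal(unname(p1[1, ]), unname(p[1, ]), tolerance = 1e-12)
  expect_identical(predict_label(m, x), as.integer(max.col(p) - 1L))
})

test_that("forcing SE gates to one reproduces the plain VGG twin", {
  cfg <- desk_cfg(seed = 11)
  mse <- build_model(cfg, with_se = TRUE)
  plain <- build_model(cfg, with_se = FALSE)
  set.seed(5)
  x <- array(rnorm(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  expect_equal(predict_proba(mse, x, se_scale = 1),
               predict_proba(plain, x), tolerance = 1e-12)
  # and the SE parameters are exactly the parameter-count surplus
  surplus <- count_params(mse) - count_params(plain)
  expect_identical(surplus, count_params(mse, type = "se"))
  widths <- cfg$widths
  hid <- pmax(1L, widths %/% cfg$se_reduction)
  expect_identical(as.numeric(surplus),
                   sum(2 * widths * hid + widths + hid))
})

test_that("backward gradients match finite differences on a tiny model", {
  cfg <- desk_cfg(seed = 3)
  m <- build_model(cfg)
  set.seed(7)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  y <- c(0L, 1L)
  fw <- strokeEEG:::model_forward(m, x, keep_cache = TRUE)
  ls <- strokeEEG:::softmax_xent(fw$logits, y)
  gr <- strokeEEG:::model_backward(m, fw$caches, ls$dlogits)
  lossfn <- function(mm)
    strokeEEG:::softmax_xent(strokeEEG:::model_forward(mm, x)$logits, y)$loss
  types <- vapply(m$layers, function(l) l$type, "")
  probes <- list(c(which(types == "conv")[1], "W", 5),
                 c(which(types == "conv")[13], "b", 1),
                 c(which(types == "se")[2], "W2", 3),
                 c(which(types == "se")[5], "b2", 1),
                 c(which(types == "fc")[3], "W", 4))
  eps <- 1e-5
  for (pr in probes) {
    li <- as.integer(pr[1]); nm <- pr[2]; k <- as.integer(pr[3])
    mp <- m; mp$layers[[li]][[nm]][k] <- mp$layers[[li]][[nm]][k] + eps
    mm <- m; mm$layers[[li]][[nm]][k] <- mm$layers[[li]][[nm]][k] - eps
    num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
    expect_equal(gr[[li]][[nm]][k], num, tolerance = 1e-5)
  }
})

test_that("convolution and pooling kernels agree with direct loops", {
  set.seed(9)
  H <- 6; W <- 5; Ci <- 2; Co <- 3; N <- 2
  x <- array(rnorm(H * W * Ci * N), c(H, W, Ci, N))
  w <- array(rnorm(9 * Ci * Co), c(3, 3, Ci, Co))
  b <- rnorm(Co)
  y <- strokeEEG:::.conv3x3_forward(x, w, b)
  want <- array(0, c(H, W, Co, N))
  for (n in 1:N) for (o in 1:Co) for (i in 1:H) for (j in 1:W) {
    acc <- b[o]
    for (c in 1:Ci) for (dh in -1:1) for (dw in -1:1) {
      ii <- i + dh; jj <- j + dw
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + w[dh + 2, dw + 2, c, o] * x[ii, jj, c, n]
    }
    want[i, j, o, n] <- acc
  }
  expect_equal(y, want, tolerance = 1e-12)
  xp <- array(rnorm(4 * 4 * 2 * 1), c(4, 4, 2, 1))
  pl <- strokeEEG:::.maxpool2_forward(xp)
  for (c in 1:2) for (i in 1:2) for (j in 1:2)
    expect_identical(pl$y[i, j, c, 1],
                     max(xp[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, 1]))
})
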