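# Independent brute-force oracles used across tests. Each is a direct
# transcription of the defining formula, kept free of the package's own
# code paths.

# PLI oracle: wrap, sign (with zero tolerance), mean, abs -- operating on
# externally supplied phases so it shares no code with pli()
oracle_pli_from_phases <- function(ph_x, ph_y, tol = 1e-9) {
  d <- ph_x - ph_y
  d <- d - 2 * pi * floor((d + pi) / (2 * pi))  # wrap to [-pi, pi)
  s <- sign(d)
  s[abs(d) < tol] <- 0
  abs(mean(s))
}

# analytic-signal phase by explicit frequency-domain construction
oracle_phase <- function(x) {
  K <- length(x)
  X <- fft(x)
  h <- rep(0, K)
  if (K %% 2 == 0) {
    h[1] <- 1; h[K / 2 + 1] <- 1; h[2:(K / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((K + 1) / 2)] <- 2
  }
  Arg(fft(X * h, inverse = TRUE) / K)
}

# O(K^2) Sample Entropy by the textbook double loop (absolute radius)
oracle_sampen <- function(x, m, r_abs) {
  K <- length(x)
  count <- function(len) {
    n <- K - m              # template count shared by both lengths
    hits <- 0L
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)]))
        if (d < r_abs) hits <- hits + 1L
      }
    }
    hits
  }
  B <- count(m); A <- count(m + 1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# O(n^2) AUC: pairwise concordance with ties counted half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# small coupled-cohort helper used by several connectivity tests
tiny_cohort_features <- function(seed, n_per_class = 4, duration_s = 20,
                                 ...) {
  sc <- synth_config(duration_s = duration_s,
                     n_subjects_per_class = n_per_class, seed = seed, ...)
  extract_features(generate_cohort(sc), reject_uv = Inf)
}
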