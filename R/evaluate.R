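# Subject-level stratified cross-validation and binary classification
# metrics: accuracy, sensitivity, specificity from confusion counts, and
# ROC/AUC by the midrank concordance statistic.

#' Subject-level stratified k-fold partition
#'
#' All epochs of a subject share a fold (no identity leakage); folds are
#' stratified by class so every test fold contains both classes whenever
#' each class has at least `k` subjects.
#'
#' @param labels Integer 0/1 vector, one entry per subject.
#' @param k Number of folds (>= 2).
#' @param seed Shuffling seed.
#' @return List of `k` integer vectors of test-subject indices; their union
#'   is all subjects and they are pairwise disjoint.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  folds <- vector("list", k)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- with_local_seed(seed + as.integer(cls), sample(idx))
    for (i in seq_along(idx)) {
      f <- ((i - 1L) %% k) + 1L
      folds[[f]] <- c(folds[[f]], idx[i])
    }
  }
  if (any(vapply(folds, function(f) length(unique(labels[f])), 0L) < 2L))
    stop("stratification failed: a test fold lacks one class ",
         "(need at least k subjects per class)")
  lapply(folds, sort)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `Acc = (TP+TN)/total`, `Sen = TP/(TP+FN)`, `Spe = TN/(TN+FP)`, reported
#' as percentages. Sensitivity or specificity with a zero denominator is
#' returned as `NaN`.
#'
#' @param tp,fn,fp,tn Non-negative confusion counts (total > 0).
#' @return Named list `acc`, `sen`, `spe` (percent), plus the counts.
#' @export
classification_metrics <- function(tp, fn, fp, tn) {
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be non-negative")
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty confusion matrix")
  list(acc = 100 * (tp + tn) / total,
       sen = if (tp + fn > 0) 100 * tp / (tp + fn) else NaN,
       spe = if (tn + fp > 0) 100 * tn / (tn + fp) else NaN,
       tp = tp, fn = fn, fp = fp, tn = tn)
}

#' ROC curve and AUC
#'
#' AUC is the rank (concordance) statistic: the probability that a random
#' positive scores above a random negative, ties counted half (midranks).
#' ROC points are swept over every distinct score threshold.
#'
#' @param scores Numeric scores (larger = more stroke-like; typically the
#'   class-1 softmax probability).
#' @param labels Integer 0/1 vector; both classes must be present.
#' @return List with `auc` and a data frame `roc` of (fpr, tpr) points.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: both classes required")
  r <- rank(scores)   # midranks for ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, 0)
  list(auc = auc, roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

# Per-subject feature bundle: everything the CV driver needs, computed once
# per cohort and reused across folds, seeds and feature ablations.
#
# Returns a list per subject: pli [C x C x E] per-epoch PLI, spli [C x C]
# subject-level (epoch-mean) PLI, saen [C x E], label, subject_id.
#' Extract per-subject connectivity and complexity features
#'
#' Runs preprocessing (optional re-filtering), 1-s segmentation,
#' amplitude-based artifact rejection, per-epoch PLI matrices, the
#' subject-level epoch-mean PLI, and per-channel Sample Entropy.
#'
#' @param cohort List of [eeg_recording()] objects.
#' @param epoch_length_s Epoch window (default 1 s).
#' @param reject_uv Artifact amplitude threshold in microvolts (default
#'   200; `Inf` disables rejection).
#' @param saen_m,saen_r Sample Entropy parameters (default m = 2,
#'   r = 0.2 x SD).
#' @return List of per-subject feature bundles, class `subject_features`.
#' @export
extract_features <- function(cohort, epoch_length_s = 1, reject_uv = 200,
                             saen_m = 2L, saen_r = 0.2) {
  out <- lapply(cohort, function(rec) {
    ep <- segment(rec, epoch_length_s)
    if (is.finite(reject_uv)) ep <- reject_artifact_epochs(ep, reject_uv)
    if (n_epochs(ep) == 0L)
      stop("no epochs survive artifact rejection for ", rec$subject_id)
    pli_arr <- pli_matrix(ep)
    list(pli = unclass(pli_arr), spli = subject_pli(pli_arr),
         saen = saen_vector(ep, m = saen_m, r = saen_r),
         label = as.integer(rec$label), subject_id = rec$subject_id)
  })
  class(out) <- "subject_features"
  out
}

# build the [32 x 32 x 3 x N] image stack for a set of subjects under one
# feature ablation, given fold-level weights and SaEn bounds
.feature_images <- function(features, subj_idx, feature_type, w, saen_bounds,
                            img_size) {
  imgs <- list(); labs <- integer(); subj <- integer()
  for (si in subj_idx) {
    f <- features[[si]]
    E <- dim(f$pli)[3]
    for (e in seq_len(E)) {
      m <- f$pli[, , e]
      if (feature_type != "pli") m <- m * unclass(w)
      saen <- if (feature_type == "cwpli_saen") f$saen[, e]
      fm <- fuse(m, saen, saen_bounds)
      imgs[[length(imgs) + 1L]] <- to_rgb(fm, size = img_size)
      labs <- c(labs, f$label)
      subj <- c(subj, si)
    }
  }
  arr <- array(0, dim = c(img_size, img_size, 3L, length(imgs)))
  for (i in seq_along(imgs)) arr[, , , i] <- imgs[[i]] / 255
  list(images = arr, labels = labs, subject = subj)
}

#' Subject-level cross-validated evaluation
#'
#' For each fold: correlation weights and Sample Entropy rescaling bounds
#' are learned from the training subjects only, feature images are built
#' for both splits, a fresh classifier is trained (a 10% subject-level
#' validation split drives early stopping) and the held-out epochs are
#' scored. Per-fold confusion counts, Acc/Sen/Spe, ROC and AUC are
#' returned together with their across-fold mean and SD.
#'
#' @param features A `subject_features` bundle from [extract_features()].
#' @param feature_type `"pli"`, `"cwpli"` or `"cwpli_saen"` (the ablation
#'   axis: plain connectivity, weighted, weighted + complexity diagonal).
#' @param k Number of folds (default 5).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param img_size Feature image side in pixels.
#' @param n_models Independent initialisations trained per fold; their
#'   softmax probabilities are averaged. A 2-model ensemble damps the
#'   fold-to-fold variance of training small networks on small cohorts.
#' @param seed Master seed (folds, validation split, initialisation,
#'   shuffling all derive from it).
#' @return A `metrics_report` list: `folds` (per-fold metrics), `mean`,
#'   `sd`, `pooled` (metrics over pooled epochs), `auc`.
#' @export
cross_validate <- function(features, feature_type = "cwpli_saen", k = 5L,
                           model_cfg = model_config(),
                           train_cfg = train_config(),
                           img_size = 32L, n_models = 1L, seed = 1L) {
  stopifnot(inherits(features, "subject_features"),
            feature_type %in% c("pli", "cwpli", "cwpli_saen"))
  labels <- vapply(features, function(f) f$label, 0L)
  folds <- make_folds(labels, k = k, seed = seed)
  fold_res <- list()
  all_scores <- numeric(); all_labels <- integer()
  for (fi in seq_along(folds)) {
    test_idx <- folds[[fi]]
    train_idx <- setdiff(seq_along(features), test_idx)
    # fold-internal weights: learned on training subjects only
    w <- if (feature_type == "pli") NULL else
      correlation_weights(
        lapply(train_idx[labels[train_idx] == 1L],
               function(i) features[[i]]$spli),
        lapply(train_idx[labels[train_idx] == 0L],
               function(i) features[[i]]$spli))
    # per-channel SaEn rescaling bounds from training subjects only;
    # 2%/98% quantiles rather than min/max, so two extreme epochs cannot
    # dictate the scale (values outside clip to [0, 1])
    sb <- if (feature_type == "cwpli_saen")
      apply(do.call(cbind, lapply(train_idx, function(i) features[[i]]$saen)),
            1, stats::quantile, probs = c(0.02, 0.98), names = FALSE)
    # subject-level validation split for early stopping
    n_val <- max(1L, round(train_cfg$val_fraction * length(train_idx)))
    val_idx <- with_local_seed(seed * 100L + fi,
                               sample(train_idx, n_val))
    fit_idx <- setdiff(train_idx, val_idx)
    if (length(unique(labels[fit_idx])) < 2L) {
      fit_idx <- train_idx; val_idx <- integer()  # tiny cohorts
    }
    tr <- .feature_images(features, fit_idx, feature_type, w, sb, img_size)
    va <- if (length(val_idx))
      .feature_images(features, val_idx, feature_type, w, sb, img_size)
    te <- .feature_images(features, test_idx, feature_type, w, sb, img_size)
    # an unlucky initialisation sometimes fails to escape the softmax
    # plateau or fits only marginally; both failures are visible on the
    # training split alone (low training accuracy), so each member is
    # retried with a fresh init seed and the best-fitting attempt kept --
    # no test information is consulted
    fit_member <- function(member_seed) {
      mc <- model_cfg; mc$seed <- member_seed
      tc <- train_cfg; tc$seed <- member_seed
      best_fit <- NULL; best_tr_acc <- -1
      for (attempt in 0:3) {
        model <- build_model(mc)
        fit <- train_model(model, tr$images, tr$labels, tc,
                           val_images = if (length(val_idx)) va$images,
                           val_labels = if (length(val_idx)) va$labels)
        tr_acc <- mean(predict_label(fit$model, tr$images) == tr$labels)
        if (tr_acc > best_tr_acc) {
          best_fit <- fit; best_tr_acc <- tr_acc
        }
        if (tr_acc >= 0.80) break
        mc$seed <- mc$seed + 503L
        tc$seed <- tc$seed + 503L
      }
      best_fit
    }
    prob <- 0
    best_epochs <- integer()
    for (mi in seq_len(n_models)) {
      fit <- fit_member(as.integer(seed * 10L + fi + (mi - 1L) * 7001L))
      prob <- prob + predict_proba(fit$model, te$images) / n_models
      best_epochs <- c(best_epochs, fit$best_epoch)
    }
    score <- prob[, 2]
    pred <- as.integer(score >= 0.5)
    tp <- sum(pred == 1L & te$labels == 1L)
    fn <- sum(pred == 0L & te$labels == 1L)
    fp <- sum(pred == 1L & te$labels == 0L)
    tn <- sum(pred == 0L & te$labels == 0L)
    met <- classification_metrics(tp, fn, fp, tn)
    met$auc <- if (length(unique(te$labels)) == 2L)
      roc_auc(score, te$labels)$auc else NA_real_
    met$n_eval <- length(te$labels)
    met$best_epoch <- max(best_epochs)
    fold_res[[fi]] <- met
    all_scores <- c(all_scores, score)
    all_labels <- c(all_labels, te$labels)
  }
  pick <- function(nm) vapply(fold_res, function(m) as.numeric(m[[nm]]), 0)
  pooled_counts <- lapply(c("tp", "fn", "fp", "tn"), function(nm)
    sum(pick(nm)))
  pooled <- do.call(classification_metrics, pooled_counts)
  roc_all <- roc_auc(all_scores, all_labels)
  structure(list(
    feature_type = feature_type, k = k, seed = seed,
    folds = fold_res,
    mean = list(acc = mean(pick("acc")), sen = mean(pick("sen")),
                spe = mean(pick("spe")), auc = mean(pick("auc"), na.rm = TRUE)),
    sd = list(acc = sd(pick("acc")), sen = sd(pick("sen")),
              spe = sd(pick("spe"))),
    pooled = pooled, auc = roc_all$auc, roc = roc_all$roc
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s, %d-fold subject-level CV (seed %d)\n",
              x$feature_type, x$k, x$seed))
  cat(sprintf("  mean  Acc %.2f%%  Sen %.2f%%  Spe %.2f%%  (SD %.2f/%.2f/%.2f)\n",
              x$mean$acc, x$mean$sen, x$mean$spe,
              x$sd$acc, x$sd$sen, x$sd$spe))
  cat(sprintf("  pooled Acc %.2f%%  Sen %.2f%%  Spe %.2f%%  AUC %.4f\n",
              x$pooled$acc, x$pooled$sen, x$pooled$spe, x$auc))
  invisible(x)
}
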