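# One-command orchestration: synthetic cohort (or EDF directory) ->
# preprocessing -> features -> fold-internal weighting -> training ->
# cross-validated metrics report, with per-stage RDS caching and a
# deterministic JSON report.

#' Pipeline configuration
#'
#' Bundles every stage's parameters. The desk-scale training protocol
#' (Adam, batch 64, learning rate 1e-3, weight decay 1e-4, gradient-norm
#' clip 5, up to 12 epochs, patience 4, a 2-model ensemble per fold)
#' trains the 1/16-width network on small synthetic cohorts;
#' pass a custom `train_cfg` for the full-scale reference protocol
#' (batch 512, lr 1e-4, 100 epochs).
#'
#' @param synth A [synth_config()] describing the cohort to generate, or
#'   `NULL` when `input_dir` is given.
#' @param input_dir Optional directory of EDF files + `labels.csv`
#'   (see [write_cohort_edf()]); overrides `synth`.
#' @param features Character vector of feature ablations to evaluate
#'   (subset of `"pli"`, `"cwpli"`, `"cwpli_saen"`).
#' @param low_hz,high_hz Bandpass edges.
#' @param reject_uv Artifact rejection threshold (microvolts).
#' @param epoch_length_s Epoch window in seconds.
#' @param saen_m,saen_r Sample Entropy parameters.
#' @param k Cross-validation folds.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param img_size Feature image side in pixels.
#' @param n_models Per-fold ensemble size (see [cross_validate()]).
#' @param out_dir Report directory, or `NULL` for no files.
#' @param cache_dir Optional stage-cache directory.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            input_dir = NULL,
                            features = "cwpli_saen",
                            low_hz = 1, high_hz = 35,
                            reject_uv = 200, epoch_length_s = 1,
                            saen_m = 2L, saen_r = 0.2,
                            k = 5L,
                            model_cfg = model_config(),
                            train_cfg = train_config(
                              optimizer = "adam", batch_size = 64L,
                              learning_rate = 1e-3, weight_decay = 1e-4,
                              clip_norm = 5, max_epochs = 12L,
                              patience = 4L),
                            img_size = 32L, n_models = 2L,
                            out_dir = NULL, cache_dir = NULL,
                            seed = 1L) {
  stopifnot(all(features %in% c("pli", "cwpli", "cwpli_saen")))
  structure(list(synth = synth, input_dir = input_dir, features = features,
                 low_hz = low_hz, high_hz = high_hz, reject_uv = reject_uv,
                 epoch_length_s = epoch_length_s, saen_m = saen_m,
                 saen_r = saen_r, k = k, model_cfg = model_cfg,
                 train_cfg = train_cfg, img_size = img_size,
                 n_models = as.integer(n_models),
                 out_dir = out_dir, cache_dir = cache_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.cached <- function(cache_dir, key, expr) {
  if (is.null(cache_dir)) return(force(expr))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- force(expr)
  saveRDS(val, path)
  val
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full detection pipeline
#'
#' Generates (or loads) the cohort, preprocesses and segments it, extracts
#' PLI/Sample Entropy features, and runs subject-level cross-validation for
#' each requested feature ablation. Deterministic given `cfg$seed`:
#' repeated runs produce byte-identical metrics JSON. Stages are cached in
#' `cfg$cache_dir` (keyed by a hash of the relevant sub-config), so an
#' interrupted run resumes without recomputation.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Log stage progress.
#' @return Named list of `metrics_report` objects, one per feature
#'   ablation, with attribute `provenance`. If `cfg$out_dir` is set,
#'   writes `metrics.json` and `provenance.json` there.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_ <- if (verbose) .stage_log else function(...) invisible()

  cohort_key <- .config_hash(list("cohort", cfg$synth, cfg$input_dir,
                                  cfg$seed))
  cohort <- .cached(cfg$cache_dir, cohort_key, {
    if (!is.null(cfg$input_dir)) {
      log_("input", "reading EDF cohort from %s", cfg$input_dir)
      recs <- read_cohort_edf(cfg$input_dir)
      lapply(recs, bandpass_filter, low_hz = cfg$low_hz,
             high_hz = cfg$high_hz)
    } else {
      sc <- cfg$synth
      sc$seed <- as.integer((sc$seed + cfg$seed * 9973) %% 2147483629)
      log_("synth", "generating %d + %d subjects",
           sc$n_subjects_per_class[["stroke"]],
           sc$n_subjects_per_class[["control"]])
      generate_cohort(sc)
    }
  })

  feat_key <- .config_hash(list("features", cohort_key, cfg$epoch_length_s,
                                cfg$reject_uv, cfg$saen_m, cfg$saen_r))
  features <- .cached(cfg$cache_dir, feat_key, {
    log_("features", "PLI + SaEn for %d subjects", length(cohort))
    extract_features(cohort, epoch_length_s = cfg$epoch_length_s,
                     reject_uv = cfg$reject_uv,
                     saen_m = cfg$saen_m, saen_r = cfg$saen_r)
  })

  reports <- lapply(cfg$features, function(ft) {
    log_("evaluate", "%d-fold CV with feature %s", cfg$k, ft)
    cross_validate(features, feature_type = ft, k = cfg$k,
                   model_cfg = cfg$model_cfg, train_cfg = cfg$train_cfg,
                   img_size = cfg$img_size,
                   n_models = if (is.null(cfg$n_models)) 1L else cfg$n_models,
                   seed = cfg$seed)
  })
  names(reports) <- cfg$features

  prov <- list(seed = cfg$seed, features = cfg$features,
               synth = unclass(cfg$synth),
               preprocess = cfg[c("low_hz", "high_hz", "reject_uv",
                                  "epoch_length_s")],
               saen = cfg[c("saen_m", "saen_r")],
               model = unclass(cfg$model_cfg),
               train = unclass(cfg$train_cfg),
               k = cfg$k, img_size = cfg$img_size,
               n_models = cfg$n_models)
  attr(reports, "provenance") <- prov

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(metrics_json(reports),
                         file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (ft in names(reports))
      write.csv(reports[[ft]]$roc,
                file.path(cfg$out_dir, paste0("roc_", ft, ".csv")),
                row.names = FALSE)
  }
  reports
}

#' Plain-list summary of pipeline reports (JSON-ready)
#'
#' @param reports Return value of [run_pipeline()].
#' @return Nested list of per-feature fold metrics and summaries.
#' @export
metrics_json <- function(reports) {
  lapply(reports, function(r) list(
    feature = r$feature_type, k = r$k, seed = r$seed,
    folds = lapply(r$folds, function(m)
      m[c("tp", "fn", "fp", "tn", "acc", "sen", "spe", "auc", "n_eval")]),
    mean = r$mean, sd = r$sd,
    pooled = r$pooled[c("acc", "sen", "spe")], auc = r$auc))
}
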