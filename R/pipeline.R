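# End-to-end pipeline: simulate/load -> preprocess -> VCG -> segment ->
# features -> cross-validated SVM, with a config whose unknown keys are
# rejected and a manifest for reproducibility.

.PIPELINE_SECTIONS <- list(
  simulate = c("n_ischemic", "n_healthy", "noise"),
  input = c("paths", "fs", "lead_names", "format"),
  preprocess = c("highpass_cutoff", "butter_order", "wavelet_name",
                 "dwt_levels", "threshold_rule", "gain", "paper_speed"),
  segmentation = c("detection_lead", "slope_frac"),
  features = c("m", "r", "step", "neighbor_exclusion", "decay_scale"),
  model = c("C", "gamma", "screen_threshold", "cv_folds", "feature_set",
            "selection", "features"),
  seed = NULL, out_dir = NULL, log_level = NULL)

#' Build and validate a pipeline configuration
#'
#' Nested sections mirror the stage configurations; unknown keys anywhere are
#' rejected before any computation. Either a `simulate` section or an `input`
#' section must be present.
#'
#' @param config named list (e.g. parsed from JSON).
#' @return The validated config with defaults filled in.
#' @export
pipeline_config <- function(config) {
  unknown <- setdiff(names(config), names(.PIPELINE_SECTIONS))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (sec in intersect(names(config), names(.PIPELINE_SECTIONS))) {
    allowed <- .PIPELINE_SECTIONS[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad)) {
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(config$simulate) && is.null(config$input)) {
    stop("config needs a 'simulate' or 'input' section", call. = FALSE)
  }
  defaults <- list(seed = 1L, out_dir = NULL, log_level = "info",
                   segmentation = list(detection_lead = "II", slope_frac = 0.05),
                   model = list(selection = "fixed",
                                features = c("S_I", "THI", "SHI")))
  cfg <- modifyList(defaults, config)
  cfg
}

.log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

# stable hash of an R object (polynomial rolling hash over serialized bytes)
.manifest_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full detection pipeline
#'
#' Executes preprocess -> derive-VCG -> segment -> features -> cross-validated
#' SVM in order, logging record counts in and out of every stage. Records
#' whose delineation or feature extraction fails are flagged and excluded
#' from modelling (counts are reported). If `out_dir` is set, the feature
#' table (CSV), the evaluation report (JSON) and a run manifest (config hash,
#' seed, package version) are written there.
#'
#' @param config a list accepted by [pipeline_config()].
#' @return List with `report` (an `evaluation_report`), `features`
#'   (data.frame), `manifest`, and `flagged` (ids of excluded records).
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  seed <- as.integer(cfg$seed)
  pre_cfg <- do.call(preprocess_config, cfg$preprocess %||% list())
  f <- cfg$features %||% list()
  se_p <- sampen_params(m = f$m %||% 2L, r = f$r %||% 0.1)
  shi_p <- shi_params(step = f$step %||% 10L,
                      neighbor_exclusion = f$neighbor_exclusion %||% 1L)
  thi_p <- thi_params(decay_scale = f$decay_scale %||% 0.001)

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    noise <- if (is.null(sim$noise)) noise_params() else do.call(noise_params, sim$noise)
    .log("info", "simulate: %d ischemic + %d healthy records (seed %d)",
         sim$n_ischemic, sim$n_healthy, seed)
    cohort <- generate_cohort(sim$n_ischemic, sim$n_healthy, seed = seed,
                              noise = noise)
    records <- lapply(cohort, `[[`, "record")
  } else {
    inp <- cfg$input
    records <- lapply(inp$paths, function(p) {
      if (identical(inp$format, "wfdb")) read_wfdb_record(p)
      else read_delimited_record(p, fs = inp$fs, lead_names = inp$lead_names)
    })
  }

  rows <- list()
  flagged <- character(0)
  for (rec in records) {
    res <- tryCatch({
      rec20 <- truncate_record(rec)
      pre <- preprocess_record(rec20, pre_cfg)
      vcg <- ecg_to_vcg(pre)
      rp <- detect_r_peaks(get_lead(pre, cfg$segmentation$detection_lead), pre$fs)
      segs <- delineate_stt(pre, rp, slope_frac = cfg$segmentation$slope_frac)
      fv <- suppressWarnings(extract_features(pre, vcg, segs, se_p, shi_p, thi_p))
      if (isTRUE(attr(fv, "flagged"))) stop(paste(attr(fv, "flag_messages"), collapse = "; "))
      list(record_id = rec$record_id, label = rec$label, features = fv)
    }, error = function(e) {
      .log("warn", "record '%s' flagged: %s", rec$record_id, conditionMessage(e))
      NULL
    })
    if (is.null(res)) flagged <- c(flagged, rec$record_id) else rows[[length(rows) + 1L]] <- res
  }
  .log("info", "features: %d records in, %d usable, %d flagged",
       length(records), length(rows), length(flagged))
  if (length(rows) < 2L) stop("pipeline aborted at stage 'features': too few usable records", call. = FALSE)

  ftab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(record_id = r$record_id, label = r$label,
               as.list(setNames(as.numeric(r$features[FEATURE_COLUMNS]),
                                FEATURE_COLUMNS)), check.names = FALSE)
  }))

  mc <- cfg$model %||% list()
  model_cfg <- model_config(C = mc$C %||% 1.0, gamma = mc$gamma,
                            screen_threshold = mc$screen_threshold %||% 0.6,
                            cv_folds = mc$cv_folds %||% 5L, seed = seed,
                            feature_set = mc$feature_set %||% "ecg_plus_vcg")
  X <- as.matrix(ftab[, FEATURE_COLUMNS])
  rownames(X) <- ftab$record_id
  y <- ftab$label
  selection <- mc$selection %||% "fixed"
  if (selection == "fixed") {
    sel <- mc$features %||% c("S_I", "THI", "SHI")
    report <- cross_validate(X[, sel, drop = FALSE], y, model_cfg)
  } else if (selection == "grid") {
    pool <- feature_pool(model_cfg$feature_set)
    screened <- screen_single_features(X[, pool, drop = FALSE], y, model_cfg)
    cand <- if (nrow(screened)) head(screened$feature, 12L) else pool[1]
    gs <- grid_search_subsets(X, y, cand, model_cfg)
    report <- gs$report
  } else if (selection == "pca") {
    pool <- feature_pool(model_cfg$feature_set)
    report <- pca_baseline(X[, pool, drop = FALSE], y, model_cfg)$report
  } else {
    stop(sprintf("unknown model selection mode '%s'", selection), call. = FALSE)
  }
  .log("info", "model: mean accuracy %.3f, mean AUC %.3f",
       report$mean[["accuracy"]], report$mean[["auc"]])

  manifest <- list(config_hash = .manifest_hash(cfg), seed = seed,
                   package_version = as.character(utils::packageVersion("vcgischemia")),
                   n_records = length(records), n_flagged = length(flagged))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(ftab, file.path(cfg$out_dir, "features.csv"))
    jsonlite::write_json(
      list(per_fold = report$per_fold, mean = as.list(report$mean),
           sd = as.list(report$sd), selected_features = report$selected_features),
      file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(report = report, features = ftab, manifest = manifest, flagged = flagged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom utils head
NULL
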