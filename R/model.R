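#' Model configuration
#'
#' @param C SVM regularization (> 0).
#' @param gamma RBF kernel width; `NULL` uses the reciprocal of
#'   (feature count x overall feature variance), computed on the
#'   standardized training matrix.
#' @param screen_threshold single-feature screening accuracy cutoff, in (0,1).
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param seed integer seed controlling fold assignment.
#' @param feature_set which candidate pool a pipeline run uses:
#'   `"ecg_only"` (12 ECG sample entropies), `"vcg_only"` (3 VCG sample
#'   entropies + SHI + THI) or `"ecg_plus_vcg"` (union of the features the
#'   first two pools selected).
#' @return A `model_config` list.
#' @export
model_config <- function(C = 1.0, gamma = NULL, screen_threshold = 0.6,
                         cv_folds = 5L, seed = 1L,
                         feature_set = c("ecg_plus_vcg", "ecg_only", "vcg_only")) {
  feature_set <- match.arg(feature_set)
  stopifnot(C > 0, cv_folds >= 2, screen_threshold >= 0, screen_threshold < 1)
  structure(list(kernel = "rbf", C = C, gamma = gamma,
                 screen_threshold = screen_threshold,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 feature_set = feature_set),
            class = "model_config")
}

#' Candidate feature pools per model family
#' @param feature_set one of `"ecg_only"`, `"vcg_only"`, `"ecg_plus_vcg"`.
#' @return Character vector of feature names.
#' @export
feature_pool <- function(feature_set) {
  switch(feature_set,
         ecg_only = FEATURE_COLUMNS[1:12],
         vcg_only = FEATURE_COLUMNS[13:17],
         ecg_plus_vcg = FEATURE_COLUMNS,
         stop("unknown feature set", call. = FALSE))
}

#' Classification metrics from labels and scores
#'
#' Accuracy, specificity, sensitivity and F1 from the confusion counts, and
#' AUC by the rank (Mann-Whitney) formulation on the continuous scores.
#'
#' @param y_true true labels (two classes).
#' @param y_pred predicted labels.
#' @param scores continuous decision values (higher favours the positive
#'   class); required for AUC.
#' @param positive the positive-class label.
#' @return Named list: `accuracy`, `specificity`, `sensitivity`, `f1`, `auc`,
#'   and confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL, positive = "ischemic") {
  stopifnot(length(y_true) == length(y_pred))
  is_pos <- y_true == positive
  if (all(is_pos) || !any(is_pos)) {
    stop("AUC undefined: y_true contains a single class", call. = FALSE)
  }
  pred_pos <- y_pred == positive
  tp <- sum(is_pos & pred_pos); fn <- sum(is_pos & !pred_pos)
  tn <- sum(!is_pos & !pred_pos); fp <- sum(!is_pos & pred_pos)
  auc <- NA_real_
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(y_true))
    r <- rank(scores, ties.method = "average")
    n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
    auc <- (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       specificity = tn / (tn + fp),
       sensitivity = tp / (tp + fn),
       f1 = 2 * tp / (2 * tp + fp + fn),
       auc = auc, tp = tp, tn = tn, fp = fp, fn = fn)
}

# stratified fold assignment; every fold gets members of every class present
# (requires each class count >= k); re-drawn up to 100 times otherwise
.stratified_folds <- function(y, k, seed) {
  n <- length(y)
  .with_seed(seed, {
    for (attempt in seq_len(100L)) {
      fold <- integer(n)
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
      ok <- all(vapply(seq_len(k), function(f) {
        length(unique(y[fold == f])) == length(unique(y))
      }, logical(1)))
      if (ok) return(fold)
    }
    stop("could not build folds with both classes in every fold", call. = FALSE)
  })
}

#' Stratified k-fold cross-validation of the RBF-SVM
#'
#' Each sample is tested exactly once. Per-fold metrics and their mean and SD
#' are reported together with fold confusion counts.
#'
#' @param X numeric feature matrix with named columns.
#' @param y class labels (both classes present).
#' @param cfg a [model_config()]; `cfg$seed` fixes the partition.
#' @return An `evaluation_report`: list with `per_fold` (data.frame), `mean`,
#'   `sd`, `selected_features`, `folds`.
#' @export
cross_validate <- function(X, y, cfg = model_config()) {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  stopifnot(n == length(y), n >= cfg$cv_folds)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  fold <- .stratified_folds(y, cfg$cv_folds, cfg$seed)
  rows <- lapply(seq_len(cfg$cv_folds), function(f) {
    tr <- fold != f; te <- fold == f
    fit <- suppressWarnings(train_svm(X[tr, , drop = FALSE], y[tr], cfg))
    sc <- predict(fit, X[te, , drop = FALSE], type = "score")
    lab <- predict(fit, X[te, , drop = FALSE], type = "label")
    m <- compute_metrics(y[te], lab, sc, positive = fit$positive)
    data.frame(fold = f, accuracy = m$accuracy, specificity = m$specificity,
               sensitivity = m$sensitivity, f1 = m$f1, auc = m$auc,
               tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn)
  })
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "specificity", "sensitivity", "f1", "auc")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 sd = apply(per_fold[metric_cols], 2L, sd),
                 selected_features = colnames(X),
                 folds = fold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d folds on features: %s\n",
              nrow(x$per_fold), paste(x$selected_features, collapse = ", ")))
  for (m in names(x$mean)) {
    cat(sprintf("  %-11s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Screen features by single-feature SVM accuracy
#'
#' Each feature alone is cross-validated (same folds/seed); features whose
#' mean accuracy exceeds `cfg$screen_threshold` are kept. An empty result is
#' returned as an empty data.frame, not an error.
#'
#' @param X numeric feature matrix with named columns.
#' @param y class labels.
#' @param cfg a [model_config()].
#' @return data.frame with columns `feature`, `accuracy` (kept rows only),
#'   sorted by decreasing accuracy.
#' @export
screen_single_features <- function(X, y, cfg = model_config()) {
  X <- as.matrix(X)
  acc <- vapply(colnames(X), function(fname) {
    rep <- cross_validate(X[, fname, drop = FALSE], y, cfg)
    rep$mean[["accuracy"]]
  }, numeric(1))
  keep <- acc > cfg$screen_threshold
  out <- data.frame(feature = colnames(X)[keep], accuracy = unname(acc[keep]))
  out[order(-out$accuracy), , drop = FALSE]
}

#' Exhaustive subset search over screened candidates
#'
#' Every non-empty subset of the candidates (at most 12, i.e. 4095 subsets)
#' is cross-validated; subsets are ranked by mean accuracy, ties broken by
#' fewer features, then by higher mean AUC.
#'
#' @param X numeric feature matrix with named columns.
#' @param y class labels.
#' @param candidates character vector of candidate feature names (1..12).
#' @param cfg a [model_config()].
#' @return List with `best` (winning feature names), `report` (its
#'   `evaluation_report`) and `table` (all subsets with mean accuracy/AUC).
#' @export
grid_search_subsets <- function(X, y, candidates, cfg = model_config()) {
  if (length(candidates) == 0L) stop("no candidate features", call. = FALSE)
  if (length(candidates) > 12L) stop("more than 12 candidates (2^12 cap)", call. = FALSE)
  X <- as.matrix(X)
  stopifnot(all(candidates %in% colnames(X)))
  p <- length(candidates)
  n_sub <- 2L^p - 1L
  tab <- vector("list", n_sub)
  reports <- vector("list", n_sub)
  for (mask in seq_len(n_sub)) {
    sel <- candidates[bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L]
    rep <- cross_validate(X[, sel, drop = FALSE], y, cfg)
    reports[[mask]] <- rep
    tab[[mask]] <- data.frame(subset = paste(sel, collapse = "+"),
                              size = length(sel),
                              accuracy = rep$mean[["accuracy"]],
                              auc = rep$mean[["auc"]])
  }
  tab <- do.call(rbind, tab)
  ord <- order(-tab$accuracy, tab$size, -tab$auc)
  win <- ord[1]
  best <- strsplit(tab$subset[win], "+", fixed = TRUE)[[1]]
  list(best = best, report = reports[[win]], table = tab[ord, , drop = FALSE])
}

# Minka's Bayesian model-selection log-likelihood for PCA rank k
# (spectrum = covariance eigenvalues, descending; n = sample count)
.assess_dimension <- function(spectrum, rank, n) {
  d <- length(spectrum)
  if (rank >= d || rank < 1) return(-Inf)
  eps <- 1e-15
  if (spectrum[rank] < eps) return(-Inf)
  pu <- -rank * log(2)
  for (i in seq_len(rank)) {
    pu <- pu + lgamma((d - i + 1) / 2) - log(pi) * (d - i + 1) / 2
  }
  pl <- -sum(log(spectrum[seq_len(rank)])) * n / 2
  v <- sum(spectrum[seq(rank + 1, d)]) / (d - rank)
  if (v < eps) return(-Inf)
  pv <- -log(v) * n * (d - rank) / 2
  m <- d * rank - rank * (rank + 1) / 2
  pp <- log(2 * pi) * (m + rank) / 2
  sp <- spectrum
  sp[seq(rank + 1, d)] <- v
  pa <- 0
  for (i in seq_len(rank)) {
    for (j in seq(i + 1, d)) {
      pa <- pa + log((spectrum[i] - spectrum[j]) * (1 / sp[j] - 1 / sp[i])) + log(n)
    }
  }
  pu + pl + pv + pp - pa / 2 - rank * log(n) / 2
}

#' Minka maximum-likelihood PCA dimension
#'
#' @param spectrum covariance eigenvalues, descending.
#' @param n number of samples.
#' @return The rank (1..d-1) maximizing Minka's evidence approximation.
#' @export
minka_dimension <- function(spectrum, n) {
  d <- length(spectrum)
  ll <- vapply(seq_len(d - 1L), .assess_dimension, numeric(1),
               spectrum = spectrum, n = n)
  which.max(ll)
}

#' PCA baseline with Minka dimension selection
#'
#' Centres the features, projects onto the leading principal components with
#' the dimension chosen by Minka's maximum-likelihood rule, and
#' cross-validates the SVM on the projection. Used as the comparison point
#' for the grid-search feature selection.
#'
#' @param X numeric feature matrix (`n > d` required for the MLE rule).
#' @param y class labels.
#' @param cfg a [model_config()].
#' @return List with `projected` (n x k matrix), `dimension`, `rotation`, and
#'   `report` (an `evaluation_report`).
#' @export
pca_baseline <- function(X, y, cfg = model_config()) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n <= d) stop("Minka's MLE rule needs more samples than features", call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- tryCatch(minka_dimension(ev, n), error = function(e) NA_integer_)
  if (is.na(k) || !is.finite(k) || k < 1) {
    warning("degenerate covariance; keeping full rank", call. = FALSE)
    k <- min(n - 1L, d)
  }
  proj <- pc$x[, seq_len(k), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(k))
  rep <- cross_validate(proj, y, cfg)
  list(projected = proj, dimension = k,
       rotation = pc$rotation[, seq_len(k), drop = FALSE], report = rep)
}

#' @importFrom stats prcomp setNames
NULL
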