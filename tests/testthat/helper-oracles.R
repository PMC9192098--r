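# Independent brute-force oracles, written before (and kept independent of)
# the package implementations they check.

# Sample entropy by direct template counting over the standardized series:
# templates j = 1..N-m, Chebyshev distance strictly < r, self-matches
# excluded. Returns -log(A/B).
oracle_sampen <- function(series, m = 2L, r = 0.1) {
  x <- (series - mean(series)) / sd(series)
  n <- length(x)
  nt <- n - m
  # pairwise |x_i - x_j| matrices for each offset, vectorised
  match_upto <- function(len) {
    ok <- matrix(TRUE, nt, nt)
    for (k in 0:(len - 1)) {
      v <- x[seq_len(nt) + k]
      ok <- ok & abs(outer(v, v, "-")) < r
    }
    diag(ok) <- FALSE
    sum(ok) / 2
  }
  B <- match_upto(m)
  A <- match_upto(m + 1L)
  -log(A / B)
}

# SHI by explicit nearest-neighbour search (squared-distance scan per point).
oracle_shi <- function(pts, step = 10L, theiler = 1L) {
  n <- nrow(pts)
  terms <- c()
  valid <- seq_len(n - step)
  for (i in valid) {
    d2 <- rowSums((pts - matrix(pts[i, ], n, 3, byrow = TRUE))^2)
    d2[abs(seq_len(n) - i) <= theiler] <- Inf
    d2[seq_len(n) > n - step] <- Inf
    j <- which.min(d2)
    d1 <- sqrt(d2[j])
    d2adv <- sqrt(sum((pts[i + step, ] - pts[j + step, ])^2))
    if (d1 == 0 || d2adv == 0) next
    terms <- c(terms, log(d2adv / d1))
  }
  mean(terms)
}

# quick preprocessed synthetic record with segments and VCG
make_segmented_record <- function(label = "healthy", seed = 1,
                                  noise = no_noise(), params = NULL) {
  g <- generate_record(label, params = params, noise = noise, seed = seed)
  rec <- preprocess_record(g$record)
  vcg <- ecg_to_vcg(rec)
  rp <- detect_r_peaks(get_lead(rec, "II"), rec$fs)
  segs <- delineate_stt(rec, rp)
  list(rec = rec, vcg = vcg, segs = segs, truth = g$truth)
}

# cached feature matrix for a small cohort (built once per test run)
cohort_features <- local({
  cache <- NULL
  function(n_each = 15L, seed = 11L) {
    key <- paste(n_each, seed)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$val)
    cohort <- generate_cohort(n_each, n_each, seed = seed)
    F <- t(vapply(cohort, function(entry) {
      rec <- preprocess_record(entry$record)
      vcg <- ecg_to_vcg(rec)
      segs <- delineate_stt(rec, detect_r_peaks(get_lead(rec, "II"), rec$fs))
      as.numeric(extract_features(rec, vcg, segs))
    }, numeric(17)))
    colnames(F) <- vcgischemia:::FEATURE_COLUMNS
    val <- list(X = F, y = vapply(cohort, function(e) e$record$label, ""))
    cache <<- list(key = key, val = val)
    val
  }
})
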