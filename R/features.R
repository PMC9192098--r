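#' Sample entropy parameters
#' @param m embedding dimension (>= 1).
#' @param r match tolerance, as a fraction of the series SD (the series is
#'   standardized first, so `r` is applied on the unit-SD scale).
#' @return A `sampen_params` list.
#' @export
sampen_params <- function(m = 2L, r = 0.1) {
  stopifnot(m >= 1, r > 0)
  structure(list(m = as.integer(m), r = r), class = "sampen_params")
}

#' Spatial heterogeneity index parameters
#' @param step lag (samples) at which trajectory divergence is measured.
#' @param neighbor_exclusion Theiler window: neighbours with
#'   `|j - n| <= neighbor_exclusion` are excluded from the search.
#' @return A `shi_params` list.
#' @export
shi_params <- function(step = 10L, neighbor_exclusion = 1L) {
  stopifnot(step >= 1, neighbor_exclusion >= 0)
  structure(list(step = as.integer(step),
                 neighbor_exclusion = as.integer(neighbor_exclusion)),
            class = "shi_params")
}

#' Temporal heterogeneity index parameters
#' @param decay_scale fixed decay constant of the spectral model.
#' @return A `thi_params` list.
#' @export
thi_params <- function(decay_scale = 0.001) {
  stopifnot(decay_scale > 0)
  structure(list(decay_scale = decay_scale), class = "thi_params")
}

#' Sample entropy of a series
#'
#' The series is standardized to zero mean and unit SD, then SampEn(N, m, r)
#' is the negative log of the conditional probability that templates matching
#' at length `m` (Chebyshev distance strictly below `r`, self-matches
#' excluded) still match at length `m + 1`. Because standardization precedes
#' matching, the value is exactly invariant to positive rescaling of the
#' input.
#'
#' @param series numeric vector, `length > m + 1`, nonzero SD.
#' @param p a [sampen_params()].
#' @return SampEn value (dimensionless).
#' @export
sample_entropy <- function(series, p = sampen_params()) {
  n <- length(series)
  if (n <= p$m + 1L) stop("series too short for the embedding dimension", call. = FALSE)
  s <- sd(series)
  if (s == 0) stop("degenerate series: zero standard deviation", call. = FALSE)
  x <- (series - mean(series)) / s
  cnt <- sampen_counts(x, p$m, p$r)
  if (cnt[["B"]] == 0) stop("undefined entropy: no template matches at length m", call. = FALSE)
  if (cnt[["A"]] == 0) stop("undefined entropy: no template matches at length m+1", call. = FALSE)
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Spatial heterogeneity index of a 3D trajectory
#'
#' A Lyapunov-style divergence measure: for each point the nearest neighbour
#' (Euclidean, excluding temporally adjacent indices) is found, and the mean
#' of `log(d2/d1)` is returned, where `d1` is the initial neighbour distance
#' and `d2` the distance between the two points advanced by `step` samples.
#' Pairs with a zero distance are skipped (and counted in the
#' `"n_skipped"` attribute).
#'
#' @param trajectory numeric matrix, `n_points x 3`.
#' @param p a [shi_params()].
#' @return SHI value with attributes `n_terms`, `n_skipped`.
#' @export
shi <- function(trajectory, p = shi_params()) {
  trajectory <- as.matrix(trajectory)
  stopifnot(ncol(trajectory) == 3L)
  n <- nrow(trajectory)
  if (n <= p$step + p$neighbor_exclusion + 1L) {
    stop("trajectory too short for the step and Theiler window", call. = FALSE)
  }
  res <- shi_terms(trajectory, p$step, p$neighbor_exclusion)
  terms <- res$terms
  if (length(terms) == 0L) stop("SHI undefined: no valid neighbour pairs", call. = FALSE)
  structure(mean(terms), n_terms = length(terms), n_skipped = res$skipped)
}

# gamma for one lead: integer decay exponent minimizing the L1 distance
# between the magnitude spectrum and f[1] * exp(-scale * lambda * k), k = 0..
.thi_gamma <- function(spectrum, decay_scale = 0.001) {
  L <- length(spectrum)
  if (all(spectrum == 0)) stop("THI undefined: all-zero lead", call. = FALSE)
  k <- seq_len(L) - 1
  f1 <- spectrum[1]
  best_l <- 1L
  best_r <- Inf
  for (lam in seq_len(L)) {
    r <- sum(abs(spectrum - f1 * exp(-decay_scale * lam * k)))
    if (r < best_r) { best_r <- r; best_l <- lam }
  }
  best_l
}

# one-sided magnitude spectrum, DC bin excluded
.magnitude_spectrum <- function(x) {
  n <- length(x)
  f <- Mod(fft(x))
  f[seq(2L, floor(n / 2) + 1L)]
}

#' Temporal heterogeneity index of the VCG ST-T series
#'
#' Per VCG lead, the one-sided magnitude spectrum of the spliced ST-T series
#' (DC excluded) is fitted by an exponential decay anchored at the first
#' frequency bin, `f1 * exp(-0.001 * lambda * k)`; the integer `lambda`
#' in `1..L` minimizing the L1 residual is the lead's decay exponent
#' `gamma`. THI is the root mean square of the three exponents.
#'
#' @param vx,vy,vz spliced ST-T sample series of the three VCG leads
#'   (each of length >= 8).
#' @param p a [thi_params()].
#' @return THI value with attribute `gamma` (the three per-lead exponents).
#' @export
thi <- function(vx, vy, vz, p = thi_params()) {
  series <- list(vx, vy, vz)
  if (any(vapply(series, length, 1L) < 8L)) {
    stop("each VCG lead series must have length >= 8", call. = FALSE)
  }
  gam <- vapply(series, function(s) {
    .thi_gamma(.magnitude_spectrum(s), p$decay_scale)
  }, integer(1))
  structure(sqrt(sum(gam^2) / 3), gamma = gam)
}

#' Extract the 17-feature vector of one record
#'
#' Computes sample entropy of the spliced ST-T series of the 12 ECG leads and
#' the 3 VCG leads, SHI of the 3D VCG ST-T trajectory, and THI of the three
#' VCG ST-T series. A per-feature failure (e.g. a constant lead) is isolated:
#' the feature becomes `NA`, the others are still computed, and the record is
#' flagged via the `"flagged"`/`"flag_messages"` attributes (flagged records
#' are excluded from modelling).
#'
#' @param ecg a preprocessed `multi_lead_record` with the 12 canonical leads.
#' @param vcg the matching `vcg_record` from [ecg_to_vcg()].
#' @param segs the record's `stt_segment_set` (shared by ECG and VCG).
#' @param sampen a [sampen_params()].
#' @param shi_p a [shi_params()].
#' @param thi_p a [thi_params()].
#' @return Named numeric vector of the 17 features in canonical order
#'   (`S_I ... S_V6, S_Vx, S_Vy, S_Vz, SHI, THI`), with attributes `flagged`
#'   and `flag_messages`.
#' @export
extract_features <- function(ecg, vcg, segs, sampen = sampen_params(),
                             shi_p = shi_params(), thi_p = thi_params()) {
  stopifnot(inherits(ecg, "multi_lead_record"), inherits(vcg, "vcg_record"),
            inherits(segs, "stt_segment_set"))
  out <- setNames(rep(NA_real_, length(FEATURE_COLUMNS)), FEATURE_COLUMNS)
  msgs <- character(0)
  grab <- function(name, expr) {
    v <- tryCatch(as.numeric(expr), error = function(e) {
      msgs <<- c(msgs, sprintf("%s: %s", name, conditionMessage(e)))
      NA_real_
    })
    out[[name]] <<- v
  }
  for (ld in CANONICAL_LEADS) {
    grab(paste0("S_", ld),
         sample_entropy(splice_stt(get_lead(ecg, ld), segs)$series, sampen))
  }
  spl <- lapply(c("Vx", "Vy", "Vz"), function(ld) {
    splice_stt(vcg$samples[, ld], segs)$series
  })
  names(spl) <- c("Vx", "Vy", "Vz")
  for (ld in names(spl)) grab(paste0("S_", ld), sample_entropy(spl[[ld]], sampen))
  grab("SHI", shi(cbind(spl$Vx, spl$Vy, spl$Vz), shi_p))
  grab("THI", thi(spl$Vx, spl$Vy, spl$Vz, thi_p))
  if (length(msgs)) {
    warning(sprintf("record '%s' flagged: %s", ecg$record_id,
                    paste(msgs, collapse = "; ")), call. = FALSE)
  }
  structure(out, flagged = length(msgs) > 0, flag_messages = msgs)
}
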