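#' Per-beat ST-T segment set
#'
#' Ordered beat annotations shared by all leads of one record. Intervals are
#' half-open `[stt_start, stt_end)` in 1-based sample indices, so the window
#' contains samples `stt_start .. stt_end - 1`.
#'
#' @param r_peak,stt_start,stt_end integer vectors, one entry per beat.
#' @param fs sampling frequency, Hz.
#' @param record_id identifier of the source record.
#' @param n_dropped count of beats discarded during delineation.
#' @return An `stt_segment_set`.
#' @export
stt_segment_set <- function(r_peak, stt_start, stt_end, fs, record_id = "",
                            n_dropped = 0L) {
  beats <- data.frame(r_peak = as.integer(r_peak),
                      stt_start = as.integer(stt_start),
                      stt_end = as.integer(stt_end))
  if (nrow(beats)) {
    stopifnot(all(beats$r_peak < beats$stt_start),
              all(beats$stt_start < beats$stt_end),
              !is.unsorted(beats$r_peak, strictly = TRUE))
    len_s <- (beats$stt_end - beats$stt_start) / fs
    if (any(len_s < 0.08 - 1e-9 | len_s > 0.6 + 1e-9)) {
      stop("ST-T window outside the physiological 80-600 ms range", call. = FALSE)
    }
  }
  structure(list(beats = beats, fs = fs, record_id = record_id,
                 n_dropped = as.integer(n_dropped)),
            class = "stt_segment_set")
}

#' @export
print.stt_segment_set <- function(x, ...) {
  cat(sprintf("<stt_segment_set '%s'> %d beats (%d dropped) @ %g Hz\n",
              x$record_id, nrow(x$beats), x$n_dropped, x$fs))
  invisible(x)
}

#' Detect R peaks on a single lead
#'
#' Pan-Tompkins-style detector: zero-phase 5--15 Hz band-pass, derivative,
#' squaring, 150 ms moving-window integration, adaptive signal/noise
#' thresholds with a 200 ms refractory period. Detected peaks are refined to
#' the local extremum of the original lead within +/- 50 ms.
#'
#' @param lead numeric sample vector (typically lead II), >= 2 s long.
#' @param fs sampling frequency, Hz.
#' @return Integer vector of 1-based R-peak sample indices.
#' @export
detect_r_peaks <- function(lead, fs) {
  n <- length(lead)
  if (n < 2 * fs) stop("need at least 2 s of signal", call. = FALSE)
  bp <- .bandpass_zero_phase(lead, fs, 5, 15, order = 2L)
  der <- c(diff(bp), 0)
  sq <- der^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  refractory <- round(0.200 * fs)
  # adaptive thresholding over local maxima of the integrated signal
  is_peak <- c(FALSE, diff(sign(diff(mwi))) < 0, FALSE)
  cand <- which(is_peak)
  spki <- max(mwi[seq_len(min(n, 2 * fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(n, 2 * fs))]) * 0.5
  thr <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) && (i - peaks[length(peaks)]) < refractory) {
      # within refractory: keep the larger
      if (mwi[i] > mwi[peaks[length(peaks)]]) peaks[length(peaks)] <- i
      next
    }
    if (mwi[i] >= thr) {
      peaks <- c(peaks, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(peaks) < 3L) stop("insufficient beats: fewer than 3 R peaks", call. = FALSE)
  # refine to the extremum of the raw lead within +/- 50 ms
  half <- round(0.050 * fs)
  ctr <- median(lead)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(abs(lead[lo:hi] - ctr)) - 1L)
  }, integer(1))
  sort(unique(refined))
}

#' Delineate per-beat ST-T segments
#'
#' Works on the RMS across all leads (robust to per-lead polarity). Per beat:
#' the J point is the first sample after the R peak where the 40 ms slope
#' magnitude of the RMS signal falls below a fraction of the peak QRS slope,
#' bounded to `[R + 30 ms, R + 120 ms]`; ST onset is `J + 40 ms`; the T
#' offset is found by the tangent method (maximal descending-slope tangent
#' after the T apex intersected with the local baseline), bounded to
#' `[R + 200 ms, R + min(600 ms, 0.7 RR)]`. Beats violating the bounds (or
#' truncated by the record end) are dropped and counted.
#'
#' @param rec a preprocessed `multi_lead_record`.
#' @param r_peaks integer R-peak indices (>= 3), e.g. from [detect_r_peaks()].
#' @param slope_frac J-point threshold as a fraction of the peak QRS slope.
#' @return An `stt_segment_set` shared by all leads (and the derived VCG).
#' @export
delineate_stt <- function(rec, r_peaks, slope_frac = 0.05) {
  stopifnot(inherits(rec, "multi_lead_record"))
  if (length(r_peaks) < 3L) stop("need at least 3 R peaks", call. = FALSE)
  fs <- rec$fs
  n <- nrow(rec$samples)
  rms <- sqrt(rowMeans(rec$samples^2))
  # centred 40 ms slope of the RMS signal
  hw <- round(0.020 * fs)
  slope <- rep(0, n)
  rng <- seq(hw + 1L, n - hw)
  slope[rng] <- (rms[rng + hw] - rms[rng - hw]) / (2 * hw / fs)
  rr_all <- diff(r_peaks)
  beats <- list()
  dropped <- 0L
  for (b in seq_along(r_peaks)) {
    r <- r_peaks[b]
    rr <- if (b < length(r_peaks)) rr_all[b] else median(rr_all)
    # --- J point ---
    j_lo <- r + round(0.030 * fs); j_hi <- r + round(0.120 * fs)
    if (j_hi > n) { dropped <- dropped + 1L; next }
    qrs_win <- seq(max(1L, r - round(0.050 * fs)), min(n, r + round(0.050 * fs)))
    peak_slope <- max(abs(slope[qrs_win]))
    idx <- seq(j_lo, j_hi)
    below <- idx[abs(slope[idx]) < slope_frac * peak_slope]
    j <- if (length(below)) below[1] else j_hi
    stt_start <- j + round(0.040 * fs)
    # --- T offset (tangent method) ---
    t_hi <- r + round(min(0.600, 0.7 * rr / fs) * fs)
    t_lo <- r + round(0.200 * fs)
    if (t_hi > n || stt_start >= t_hi) { dropped <- dropped + 1L; next }
    apex_win <- seq(stt_start + round(0.020 * fs), t_hi)
    apex <- apex_win[which.max(rms[apex_win])]
    desc_win <- seq(apex, min(n - hw, t_hi))
    if (length(desc_win) < 3L) { dropped <- dropped + 1L; next }
    i_m <- desc_win[which.min(slope[desc_win])]   # steepest descent
    s_m <- slope[i_m]
    baseline <- min(rms[seq(apex, min(n, t_hi + round(0.050 * fs)))])
    if (s_m >= 0) { dropped <- dropped + 1L; next }
    t_off <- i_m + (rms[i_m] - baseline) / (-s_m) * fs
    t_off <- round(t_off)
    if (t_off < t_lo || t_off > t_hi) { dropped <- dropped + 1L; next }
    stt_end <- t_off
    len_s <- (stt_end - stt_start) / fs
    if (len_s < 0.08 || len_s > 0.6) { dropped <- dropped + 1L; next }
    beats[[length(beats) + 1L]] <- c(r, stt_start, stt_end)
  }
  if (length(beats) < 3L) {
    stop("delineation failed: fewer than 3 valid beats", call. = FALSE)
  }
  m <- do.call(rbind, beats)
  stt_segment_set(m[, 1], m[, 2], m[, 3], fs = fs, record_id = rec$record_id,
                  n_dropped = dropped)
}

#' Splice per-beat ST-T windows into one series
#'
#' Concatenates the half-open windows `[stt_start, stt_end)` in beat order.
#'
#' @param lead numeric sample vector of one lead.
#' @param segs an `stt_segment_set` whose indices lie within the series.
#' @return List with `series` (the spliced samples) and `boundaries`
#'   (cumulative 0-based beat boundaries, starting at 0).
#' @export
splice_stt <- function(lead, segs) {
  stopifnot(inherits(segs, "stt_segment_set"))
  if (nrow(segs$beats) == 0L) stop("empty segment set", call. = FALSE)
  if (max(segs$beats$stt_end) - 1L > length(lead)) {
    stop("segment indices outside the series", call. = FALSE)
  }
  pieces <- lapply(seq_len(nrow(segs$beats)), function(i) {
    lead[seq(segs$beats$stt_start[i], segs$beats$stt_end[i] - 1L)]
  })
  lens <- vapply(pieces, length, integer(1))
  list(series = unlist(pieces, use.names = FALSE),
       boundaries = c(0L, cumsum(lens)))
}
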