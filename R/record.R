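#' Canonical 12-lead order
#'
#' All downstream indexing (the lead transform, feature naming) relies on this
#' fixed order: limb leads first, then augmented, then precordial.
#'
#' @format Character vector of length 12.
#' @export
CANONICAL_LEADS <- c("I", "II", "III", "AVR", "AVL", "AVF",
                     "V1", "V2", "V3", "V4", "V5", "V6")

#' Normalize ECG lead names to the canonical labels
#'
#' Matching is case-insensitive ("avf" -> "AVF", "aVR" -> "AVR"); names already
#' canonical pass through unchanged, so normalization is idempotent. VCG lead
#' names Vx/Vy/Vz are also recognised.
#'
#' @param lead_names character vector of lead labels.
#' @return Character vector of normalized labels.
#' @export
normalize_lead_names <- function(lead_names) {
  up <- toupper(trimws(lead_names))
  vcg <- c(VX = "Vx", VY = "Vy", VZ = "Vz")
  hit <- up %in% names(vcg)
  up[hit] <- vcg[up[hit]]
  up
}

#' Construct a multi-lead ECG record
#'
#' A uniformly sampled multi-lead signal in mV with lead labels and sampling
#' frequency. The canonical analysis duration is 20 s; records of other
#' lengths are accepted (and flagged via [is_canonical_length()]) but the
#' feature pipeline truncates/rejects them.
#'
#' @param samples numeric matrix, `n_samples x n_leads`, amplitudes in mV.
#' @param fs sampling frequency in Hz (> 0).
#' @param lead_names character vector, one label per column.
#' @param record_id opaque identifier string.
#' @param label class tag: `"ischemic"`, `"healthy"` or `"unknown"`.
#' @param meta optional named list of metadata (e.g. display calibration).
#' @return An object of class `multi_lead_record`.
#' @export
multi_lead_record <- function(samples, fs, lead_names, record_id = "",
                              label = c("unknown", "ischemic", "healthy"),
                              meta = list()) {
  label <- match.arg(label)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  lead_names <- normalize_lead_names(lead_names)
  if (ncol(samples) != length(lead_names)) {
    stop(sprintf("samples has %d columns but %d lead names given",
                 ncol(samples), length(lead_names)), call. = FALSE)
  }
  if (anyNA(samples)) stop("samples contain NA/NaN; record rejected", call. = FALSE)
  if (anyDuplicated(lead_names)) stop("duplicate lead names", call. = FALSE)
  colnames(samples) <- lead_names
  structure(list(samples = samples, fs = fs, lead_names = lead_names,
                 record_id = record_id, label = label, meta = meta),
            class = "multi_lead_record")
}

#' @export
print.multi_lead_record <- function(x, ...) {
  cat(sprintf("<multi_lead_record '%s'> %d samples x %d leads @ %g Hz (%.2f s), label=%s\n",
              x$record_id, nrow(x$samples), ncol(x$samples), x$fs,
              nrow(x$samples) / x$fs, x$label))
  invisible(x)
}

#' Number of samples in a record
#' @param rec a `multi_lead_record` or `vcg_record`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' Does a record have the canonical 20 s duration?
#' @param rec a `multi_lead_record`.
#' @param duration_s canonical duration, seconds.
#' @return Logical.
#' @export
is_canonical_length <- function(rec, duration_s = 20) {
  nrow(rec$samples) == round(duration_s * rec$fs)
}

#' Truncate a record to the canonical analysis window
#'
#' The feature pipeline operates on fixed 20 s windows: longer records are
#' truncated to the first 20 s, shorter ones are an error.
#'
#' @param rec a `multi_lead_record`.
#' @param duration_s window length in seconds.
#' @return A `multi_lead_record` of exactly `duration_s * fs` samples.
#' @export
truncate_record <- function(rec, duration_s = 20) {
  n_want <- round(duration_s * rec$fs)
  n <- nrow(rec$samples)
  if (n < n_want) {
    stop(sprintf("record '%s' is %.2f s, shorter than the %g s analysis window",
                 rec$record_id, n / rec$fs, duration_s), call. = FALSE)
  }
  if (n == n_want) return(rec)
  rec$samples <- rec$samples[seq_len(n_want), , drop = FALSE]
  rec
}

#' Extract one lead as a numeric vector
#' @param rec a `multi_lead_record` or `vcg_record`.
#' @param lead lead name (normalized automatically).
#' @return Numeric vector of samples.
#' @export
get_lead <- function(rec, lead) {
  lead <- normalize_lead_names(lead)
  if (!lead %in% rec$lead_names) {
    stop(sprintf("lead not found: '%s'", lead), call. = FALSE)
  }
  rec$samples[, lead]
}

#' Construct a 3-lead VCG record
#'
#' @param samples numeric matrix `n_samples x 3` (columns Vx, Vy, Vz), mV.
#' @param fs sampling frequency, Hz.
#' @param source_record_id id of the ECG record the VCG was derived from.
#' @return An object of class `vcg_record`.
#' @export
vcg_record <- function(samples, fs, source_record_id = "") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (ncol(samples) != 3L) stop("a VCG record has exactly 3 leads", call. = FALSE)
  if (anyNA(samples)) stop("samples contain NA/NaN", call. = FALSE)
  colnames(samples) <- c("Vx", "Vy", "Vz")
  structure(list(samples = samples, fs = fs, lead_names = c("Vx", "Vy", "Vz"),
                 record_id = source_record_id,
                 source_record_id = source_record_id),
            class = "vcg_record")
}

#' @export
print.vcg_record <- function(x, ...) {
  cat(sprintf("<vcg_record from '%s'> %d samples x 3 leads @ %g Hz\n",
              x$source_record_id, nrow(x$samples), x$fs))
  invisible(x)
}
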