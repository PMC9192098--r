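# Record and feature-table I/O.
#
# WFDB support is a minimal reader/writer for header (.hea) plus format-16
# signal (.dat) pairs -- the layout used by the public diagnostic ECG
# databases -- with per-channel gain/baseline applied so samples are in mV.

FEATURE_COLUMNS <- c("S_I", "S_II", "S_III", "S_AVR", "S_AVL", "S_AVF",
                     "S_V1", "S_V2", "S_V3", "S_V4", "S_V5", "S_V6",
                     "S_Vx", "S_Vy", "S_Vz", "SHI", "THI")

#' Read a WFDB record (format 16)
#'
#' Parses the `.hea` header and the interleaved 16-bit little-endian signal
#' file, converts ADC units to mV with each channel's gain and baseline, and
#' normalizes lead names.
#'
#' @param path record path with or without the `.hea` extension.
#' @param channels optional character vector of lead names to keep (order
#'   preserved); an absent lead is an error naming it.
#' @return A `multi_lead_record`.
#' @export
read_wfdb_record <- function(path, channels = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop(sprintf("WFDB header not found: %s", hea), call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- head_tok[1]
  n_sig <- as.integer(head_tok[2])
  fs <- if (length(head_tok) >= 3) as.numeric(head_tok[3]) else 250
  n_samp <- if (length(head_tok) >= 4) as.integer(head_tok[4]) else NA_integer_
  sig_lines <- lines[seq(2L, 1L + n_sig)]
  parse_sig <- function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- sub("x.*$", "", tok[2])
    gain_spec <- tok[3]
    baseline <- 0
    m <- regmatches(gain_spec, regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?", gain_spec))[[1]]
    gain <- as.numeric(m[2])
    if (nzchar(m[4])) baseline <- as.numeric(m[4])
    if (is.na(gain) || gain == 0) gain <- 200  # WFDB default gain
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ") else tok[length(tok)]
    list(file = tok[1], fmt = fmt, gain = gain, baseline = baseline, desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  fmts <- unique(vapply(sigs, `[[`, "", "fmt"))
  if (!identical(fmts, "16")) {
    stop(sprintf("unsupported WFDB signal format: %s (only 16)", paste(fmts, collapse = ",")),
         call. = FALSE)
  }
  dat_file <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(dat_file)) stop(sprintf("WFDB signal file not found: %s", dat_file), call. = FALSE)
  raw_n <- file.size(dat_file) / 2L
  adc <- readBin(dat_file, "integer", n = raw_n, size = 2L, signed = TRUE,
                 endian = "little")
  mat <- matrix(adc, ncol = n_sig, byrow = TRUE)
  if (!is.na(n_samp) && nrow(mat) > n_samp) mat <- mat[seq_len(n_samp), , drop = FALSE]
  mv <- sapply(seq_len(n_sig), function(j) (mat[, j] - sigs[[j]]$baseline) / sigs[[j]]$gain)
  lead_names <- normalize_lead_names(vapply(sigs, `[[`, "", "desc"))
  rec <- multi_lead_record(mv, fs = fs, lead_names = lead_names,
                           record_id = record_name)
  if (!is.null(channels)) {
    channels <- normalize_lead_names(channels)
    missing <- setdiff(channels, rec$lead_names)
    if (length(missing)) {
      stop(sprintf("lead not found: %s", paste(missing, collapse = ", ")), call. = FALSE)
    }
    rec$samples <- rec$samples[, channels, drop = FALSE]
    rec$lead_names <- channels
  }
  rec
}

#' Write a record as a WFDB (format 16) header/signal pair
#'
#' @param rec a `multi_lead_record`.
#' @param path output path without extension; `.hea` and `.dat` are created.
#' @param gain ADC units per mV (all channels).
#' @return Invisibly, the header path.
#' @export
write_wfdb_record <- function(rec, path, gain = 1000) {
  stopifnot(inherits(rec, "multi_lead_record"))
  base <- sub("\\.hea$", "", path)
  name <- basename(base)
  adc <- round(rec$samples * gain)
  if (any(abs(adc) > 32767)) stop("sample out of int16 range at this gain", call. = FALSE)
  storage.mode(adc) <- "integer"
  hea <- c(sprintf("%s %d %g %d", name, ncol(adc), rec$fs, nrow(adc)),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
                   name, gain, adc[1, ], rec$lead_names))
  writeLines(hea, paste0(base, ".hea"))
  writeBin(as.integer(t(adc)), paste0(base, ".dat"), size = 2L, endian = "little")
  invisible(paste0(base, ".hea"))
}

#' Read a delimited (CSV/TSV) sample matrix as a record
#'
#' One column per lead; an optional header row matching `lead_names` is
#' consumed. Ragged rows or non-numeric cells raise a parse error with the
#' offending line number.
#'
#' @param path file path.
#' @param fs sampling frequency of the stored samples, Hz.
#' @param lead_names labels for the columns, in order.
#' @param sep field separator; guessed from the extension by default.
#' @param record_id identifier; defaults to the file name.
#' @return A `multi_lead_record`.
#' @export
read_delimited_record <- function(path, fs, lead_names, sep = NULL,
                                  record_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  nf <- count.fields(path, sep = sep)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("parse error: ragged row at line %d (%d fields, expected %d)",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- read.table(path, sep = sep, header = has_header,
                   colClasses = "character", check.names = FALSE)
  mat <- suppressWarnings(apply(as.matrix(df), 2L, as.numeric))
  if (anyNA(mat)) {
    bad_row <- which(rowSums(is.na(mat)) > 0)[1] + has_header
    stop(sprintf("parse error: non-numeric cell at line %d", bad_row), call. = FALSE)
  }
  if (ncol(mat) != length(lead_names)) {
    stop(sprintf("file has %d columns but %d lead names given",
                 ncol(mat), length(lead_names)), call. = FALSE)
  }
  multi_lead_record(mat, fs = fs, lead_names = lead_names, record_id = record_id)
}

#' Write a record as a delimited matrix with a lead-name header
#'
#' @param rec a `multi_lead_record` or `vcg_record`.
#' @param path output path (`.tsv` for tab-separated, CSV otherwise).
#' @return Invisibly, `path`.
#' @export
write_delimited_record <- function(rec, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- as.data.frame(rec$samples)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a record to a new sampling frequency
#'
#' Fourier-domain resampling per lead (band-limited interpolation), keeping
#' the duration fixed to within one output sample. `target_fs == fs` returns
#' the input unchanged.
#'
#' @param rec a `multi_lead_record`.
#' @param target_fs new sampling frequency, Hz.
#' @return A resampled `multi_lead_record`.
#' @export
resample_record <- function(rec, target_fs) {
  stopifnot(inherits(rec, "multi_lead_record"), target_fs > 0)
  if (target_fs == rec$fs) return(rec)
  n <- nrow(rec$samples)
  m <- round(n * target_fs / rec$fs)
  rec$samples <- apply(rec$samples, 2L, .fft_resample, m = m)
  colnames(rec$samples) <- rec$lead_names
  rec$fs <- target_fs
  rec
}

#' Write a feature table
#'
#' One row per record: `record_id`, `label`, then the 17 named feature
#' columns (12 ECG sample entropies, 3 VCG sample entropies, SHI, THI).
#'
#' @param rows a data.frame with those columns, or a list of rows from
#'   [extract_features()] results (each a list with `record_id`, `label`,
#'   `features`).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(rows, path) {
  cols <- c("record_id", "label", FEATURE_COLUMNS)
  if (is.data.frame(rows)) {
    df <- rows
  } else if (length(rows) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    df <- do.call(rbind, lapply(rows, function(r) {
      fv <- r$features[FEATURE_COLUMNS]
      data.frame(record_id = r$record_id, label = r$label,
                 as.list(setNames(as.numeric(fv), FEATURE_COLUMNS)),
                 check.names = FALSE)
    }))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("schema error: missing column(s) %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  write.table(df[, cols], path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A data.frame with `record_id`, `label` and the 17 feature columns.
#' @export
read_feature_table <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   colClasses = c(record_id = "character", label = "character"))
  cols <- c("record_id", "label", FEATURE_COLUMNS)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("schema error: missing column(s) %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  extra <- setdiff(names(df), cols)
  if (length(extra)) {
    stop(sprintf("schema error: unknown column(s) %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  df[, cols]
}
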