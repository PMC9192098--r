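# Digital Butterworth design and zero-phase filtering.
#
# No signal-processing package is assumed; the design is the textbook route:
# analog prototype poles -> frequency transform with prewarped cutoff ->
# bilinear transform -> polynomial coefficients. Verified against
# scipy.signal.butter in the test suite (frozen coefficients).

# polynomial coefficients (descending powers, leading 1) from complex roots
.poly_from_roots <- function(roots) {
  p <- complex(real = 1)
  for (r in roots) p <- c(p, 0) - c(0, r * p)
  p
}

#' Design a digital Butterworth filter
#'
#' Returns transfer-function coefficients `b`, `a` (normalized so `a[1] = 1`)
#' for a low-pass or high-pass Butterworth filter of the given order,
#' discretized with the bilinear transform and cutoff prewarping.
#'
#' @param order filter order (poles).
#' @param cutoff cutoff frequency, Hz (-3 dB point).
#' @param fs sampling frequency, Hz; requires `fs > 2 * cutoff`.
#' @param type `"high"` or `"low"`.
#' @return List with numeric vectors `b` and `a` of length `order + 1`.
#' @export
butter_design <- function(order, cutoff, fs, type = c("high", "low")) {
  type <- match.arg(type)
  stopifnot(order >= 1, cutoff > 0, fs > 2 * cutoff)
  k <- seq_len(order)
  # analog prototype: poles on the unit left-half circle
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warped <- 2 * fs * tan(pi * cutoff / fs)
  if (type == "low") {
    poles_s <- warped * proto
    zeros_s <- complex(0)
    gain_s  <- warped^order
  } else {
    poles_s <- warped / proto
    zeros_s <- rep(complex(real = 0), order)
    gain_s  <- 1
  }
  # bilinear transform s -> z
  fs2 <- 2 * fs
  poles_z <- (fs2 + poles_s) / (fs2 - poles_s)
  zeros_z <- (fs2 + zeros_s) / (fs2 - zeros_s)
  # zeros at infinity map to z = -1
  zeros_z <- c(zeros_z, rep(-1 + 0i, length(poles_s) - length(zeros_s)))
  gain_z <- gain_s * Re(prod(fs2 - zeros_s) / prod(fs2 - poles_s))
  b <- Re(.poly_from_roots(zeros_z)) * gain_z
  a <- Re(.poly_from_roots(poles_z))
  list(b = b / a[1], a = a / a[1])
}

# odd (anti-symmetric) end extension, as used before zero-phase filtering
.odd_ext <- function(x, n_pad) {
  n <- length(x)
  n_pad <- min(n_pad, n - 1L)
  front <- 2 * x[1] - x[seq(n_pad + 1L, 2L)]
  back  <- 2 * x[n] - x[seq(n - 1L, n - n_pad)]
  c(front, x, back)
}

#' Zero-phase forward-backward IIR filtering
#'
#' Applies the filter forwards and backwards so the net phase response is
#' zero (squared magnitude response). Signal ends are extended by odd
#' reflection before filtering and trimmed afterwards, which suppresses the
#' start-up transient.
#'
#' @param b,a transfer-function coefficients (e.g. from [butter_design()]).
#' @param x numeric signal.
#' @param pad_len extension length per end in samples; defaults to a multiple
#'   of the filter's slowest time constant, capped at `length(x) - 1`.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_zero_phase <- function(b, a, x, pad_len = NULL) {
  n <- length(x)
  if (is.null(pad_len)) {
    # time constant of the slowest pole, with a safety factor
    p <- polyroot(rev(a))
    rho <- max(Mod(p))
    tau <- if (rho >= 1) n - 1L else ceiling(-8 / log(rho))
    pad_len <- min(n - 1L, max(3L * (length(a) - 1L), tau))
  }
  if (n <= 2L * (length(a) - 1L)) {
    stop("signal too short for the filter order", call. = FALSE)
  }
  xe <- .odd_ext(x, pad_len)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[seq(pad_len + 1L, pad_len + n)]
}

# zero-phase band-pass via cascaded high- and low-pass Butterworth sections
.bandpass_zero_phase <- function(x, fs, low, high, order = 2L) {
  hp <- butter_design(order, low, fs, "high")
  lp <- butter_design(order, high, fs, "low")
  y <- filtfilt_zero_phase(hp$b, hp$a, x)
  filtfilt_zero_phase(lp$b, lp$a, y)
}

# Fourier-domain resampling of one channel to m samples (scipy-style)
.fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- fft(x)
  Y <- complex(length.out = m)
  nh <- min(n, m)
  half <- floor(nh / 2)
  idx_pos <- seq_len(half + 1L)                 # DC .. positive freqs
  Y[idx_pos] <- X[idx_pos]
  if (half > 0) {
    Y[m - seq_len(half) + 1L] <- X[n - seq_len(half) + 1L]
  }
  if (nh %% 2 == 0) {
    # split or fold the Nyquist bin to keep the result real
    if (m > n) {
      Y[half + 1L] <- X[half + 1L] / 2
      Y[m - half + 1L] <- X[half + 1L] / 2
    } else {
      if (m < n) Y[half + 1L] <- X[half + 1L] + X[n - half + 1L]
    }
  }
  Re(fft(Y, inverse = TRUE)) * (1 / n)
}
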