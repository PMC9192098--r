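# Orthogonal DWT with the Coiflet-4 filter bank, used for ECG denoising.
#
# The 24-tap coif4 scaling filter below is the standard published filter bank
# (sum h = sqrt(2); shifts of 2 are orthonormal). The highpass filter is the
# quadrature mirror g[k] = (-1)^k h[K-1-k]. The transform is periodized, which
# makes the inverse exact; signals are symmetrically padded to a multiple of
# 2^levels first so the circular wrap never lands inside the analysis window.

COIF4_LO <- c(
  -1.784990914493346854e-06, -3.259647940030751042e-06,
   3.122986159919526473e-05,  6.233885431278719162e-05,
  -2.599743371222568156e-04, -5.890202246332165367e-04,
   1.266561078925660310e-03,  3.751434697146086624e-03,
  -5.658283800130883487e-03, -1.521172818769721095e-02,
   2.508225333794961154e-02,  3.933442260558914910e-02,
  -9.622042453595264222e-02, -6.662747236681716700e-02,
   4.343860331143565290e-01,  7.822389344242826059e-01,
   4.153084270006822676e-01, -5.607731960356925754e-02,
  -8.126671024919372710e-02,  2.668230466960483035e-02,
   1.606894713157502874e-02, -7.346167936268050737e-03,
  -1.629492425226786037e-03,  8.923139025370029715e-04)

COIF4_HI <- (-1)^(seq_along(COIF4_LO) - 1L) * rev(COIF4_LO)

# one level of periodized analysis: x (length even) -> list(a, d)
.dwt_step <- function(x, lo = COIF4_LO, hi = COIF4_HI) {
  n <- length(x)
  half <- n %/% 2L
  i0 <- 2L * (seq_len(half) - 1L)          # 0-based base index per output
  a <- numeric(half)
  d <- numeric(half)
  for (k in seq_along(lo)) {
    idx <- (i0 + k - 1L) %% n + 1L
    a <- a + lo[k] * x[idx]
    d <- d + hi[k] * x[idx]
  }
  list(a = a, d = d)
}

# exact inverse of .dwt_step
.idwt_step <- function(a, d, lo = COIF4_LO, hi = COIF4_HI) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  i0 <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(lo)) {
    idx <- (i0 + k - 1L) %% n + 1L
    contrib <- lo[k] * a + hi[k] * d
    # scatter-add; idx values are distinct within one k
    x[idx] <- x[idx] + contrib
  }
  x
}

# multi-level periodized DWT: returns list(a, d = list(d1, d2, ...))
.dwt <- function(x, levels) {
  d <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- .dwt_step(a)
    a <- s$a
    d[[l]] <- s$d
  }
  list(a = a, d = d)
}

.idwt <- function(a, d) {
  for (l in rev(seq_along(d))) a <- .idwt_step(a, d[[l]])
  a
}

.soft_threshold <- function(w, thr) sign(w) * pmax(abs(w) - thr, 0)

# Denoise one channel: universal soft threshold on all detail levels.
# Noise SD is estimated from the level-1 details (median absolute deviation).
.wavelet_denoise_channel <- function(x, levels = 4L) {
  n <- length(x)
  block <- 2L^levels
  n_pad <- (block - n %% block) %% block
  # symmetric (reflect) padding at the end up to a multiple of 2^levels
  xp <- if (n_pad > 0) c(x, x[seq(n, n - n_pad + 1L)]) else x
  dec <- .dwt(xp, levels)
  sigma <- median(abs(dec$d[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(xp)))
  dec$d <- lapply(dec$d, .soft_threshold, thr = thr)
  y <- .idwt(dec$a, dec$d)
  y[seq_len(n)]
}
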