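# Synthetic 20 s, 12-lead, 1000 Hz ECG generator.
#
# Beats are sums of Gaussians (P, Q, R, S, T) on a per-lead amplitude profile,
# with an optional ST-level plateau, T-wave inversion, and smooth random
# beat-to-beat perturbation confined to the ST-T window (modelling
# repolarization dispersion, not measurement noise). Small fixed per-lead
# timing offsets of the T wave keep the derived VCG trajectory genuinely
# three-dimensional.

# amplitude scaling per canonical lead (lead II is the unit reference)
LEAD_AMP_PROFILE <- c(I = 0.6, II = 1.0, III = 0.5, AVR = -0.5, AVL = 0.35,
                      AVF = 0.75, V1 = -0.35, V2 = 0.5, V3 = 0.8, V4 = 1.1,
                      V5 = 1.0, V6 = 0.85)
# fixed per-lead shift of the T-wave centre (s) and width factor
LEAD_T_SHIFT <- c(I = 0.000, II = 0.002, III = -0.002, AVR = 0.001,
                  AVL = -0.001, AVF = 0.003, V1 = -0.004, V2 = -0.002,
                  V3 = 0.000, V4 = 0.002, V5 = 0.004, V6 = 0.003)
LEAD_T_WIDTH <- c(I = 1.00, II = 1.00, III = 0.95, AVR = 1.05, AVL = 0.97,
                  AVF = 1.03, V1 = 0.92, V2 = 0.96, V3 = 1.00, V4 = 1.04,
                  V5 = 1.06, V6 = 1.02)

#' Beat template parameters
#'
#' @param heart_rate beats per minute, in `[40, 180]`.
#' @param p_amp,q_amp,r_amp,s_amp,t_amp wave amplitudes in mV for the
#'   reference lead (lead II); other leads scale by a fixed profile.
#' @param st_deviation ST-level offset in mV (positive = elevation).
#' @param t_inversion flip the T wave?
#' @param stt_jitter_sd SD (mV) of the smooth, beat-independent perturbation
#'   applied only inside the ST-T window.
#' @param stt_drift_sd SD (mV) of the slow across-beat ST-T modulation
#'   (AR(1) amplitude on a fixed smooth window shape), modelling transient
#'   repolarization trends over consecutive cycles.
#' @param rr_jitter_sd SD (s) of beat-to-beat RR-interval variation.
#' @return A `beat_template_params` list.
#' @export
beat_template_params <- function(heart_rate = 70, p_amp = 0.10, q_amp = -0.08,
                                 r_amp = 1.10, s_amp = -0.20, t_amp = 0.30,
                                 st_deviation = 0, t_inversion = FALSE,
                                 stt_jitter_sd = 0.01, stt_drift_sd = 0,
                                 rr_jitter_sd = 0.02) {
  stopifnot(heart_rate >= 40, heart_rate <= 180,
            stt_jitter_sd >= 0, stt_drift_sd >= 0, rr_jitter_sd >= 0)
  structure(list(heart_rate = heart_rate, p_amp = p_amp, q_amp = q_amp,
                 r_amp = r_amp, s_amp = s_amp, t_amp = t_amp,
                 st_deviation = st_deviation, t_inversion = isTRUE(t_inversion),
                 stt_jitter_sd = stt_jitter_sd, stt_drift_sd = stt_drift_sd,
                 rr_jitter_sd = rr_jitter_sd),
            class = "beat_template_params")
}

#' Noise parameters for synthetic records
#'
#' @param baseline_amp baseline-drift amplitude, mV.
#' @param baseline_freq drift frequency, Hz; must stay below the 0.67 Hz
#'   diagnostic high-pass cutoff.
#' @param powerline_amp 50 Hz interference amplitude, mV.
#' @param broadband_sd white-noise SD, mV.
#' @return A `noise_params` list.
#' @export
noise_params <- function(baseline_amp = 0.05, baseline_freq = 0.30,
                         powerline_amp = 0.02, broadband_sd = 0.01) {
  stopifnot(baseline_amp >= 0, powerline_amp >= 0, broadband_sd >= 0,
            baseline_freq < 0.67, baseline_freq > 0)
  structure(list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 powerline_amp = powerline_amp, broadband_sd = broadband_sd),
            class = "noise_params")
}

#' Zero-noise parameter set
#' @return A `noise_params` list with all amplitudes zero.
#' @export
no_noise <- function() noise_params(0, 0.30, 0, 0)

# Beat geometry for a given RR interval: wave centres/widths relative to the
# R peak, with sqrt-RR (Bazett-style) scaling of repolarization timing.
.beat_geometry <- function(params) {
  rr <- 60 / params$heart_rate
  scale <- sqrt(rr / (60 / 70))
  list(rr = rr,
       r_lead_time = 0.40,                    # first R peak offset in record
       j_offset = 0.045,                      # J point, s after R
       t_center = 0.25 * scale,               # T apex, s after R
       t_sigma = 0.035 * scale,
       p_center = -0.16 * scale, p_sigma = 0.020,
       q_center = -0.030, q_sigma = 0.008,
       r_sigma = 0.012,
       s_center = 0.030, s_sigma = 0.008)
}

# Evaluate one beat template (reference lead, unit profile) at times t (s,
# relative to the R peak).
.beat_waveform <- function(t, params, geom) {
  g <- function(c0, s0) exp(-((t - c0)^2) / (2 * s0^2))
  t_sign <- if (params$t_inversion) -1 else 1
  w <- params$p_amp * g(geom$p_center, geom$p_sigma) +
       params$q_amp * g(geom$q_center, geom$q_sigma) +
       params$r_amp * g(0, geom$r_sigma) +
       params$s_amp * g(geom$s_center, geom$s_sigma) +
       t_sign * params$t_amp * g(geom$t_center, geom$t_sigma)
  # smooth ST-level plateau from J into the T wave
  if (params$st_deviation != 0) {
    plateau <- pnorm((t - geom$j_offset) / 0.008) *
      (1 - pnorm((t - geom$t_center) / 0.03))
    w <- w + params$st_deviation * plateau
  }
  w
}

#' Generate a single PQRST beat
#'
#' Returns the 12-lead waveform of one beat plus the ground-truth sample
#' indices (1-based, relative to the beat start) of the R peak, the ST onset
#' (J point + 40 ms) and the T offset (where the tangent through the T-wave
#' inflection meets the baseline, i.e. T centre + 2 sigma).
#'
#' @param params a [beat_template_params()].
#' @param fs sampling frequency, Hz (>= 250).
#' @return List with `leads` (n x 12 matrix, mV), `r_peak`, `stt_start`,
#'   `stt_end`, `fs`.
#' @export
generate_beat <- function(params, fs) {
  stopifnot(inherits(params, "beat_template_params"), fs >= 250)
  geom <- .beat_geometry(params)
  n <- round(geom$rr * fs)
  r_at <- round(0.35 * geom$rr * fs)          # R peak inside the beat window
  t_rel <- (seq_len(n) - 1 - r_at) / fs
  leads <- sapply(CANONICAL_LEADS, function(ld) {
    p2 <- params
    geom2 <- geom
    geom2$t_center <- geom$t_center + LEAD_T_SHIFT[[ld]]
    geom2$t_sigma <- geom$t_sigma * LEAD_T_WIDTH[[ld]]
    LEAD_AMP_PROFILE[[ld]] * .beat_waveform(t_rel, p2, geom2)
  })
  list(leads = leads,
       r_peak = r_at + 1L,
       stt_start = r_at + 1L + round((geom$j_offset + 0.040) * fs),
       stt_end = r_at + 1L + round((geom$t_center + 2 * geom$t_sigma) * fs),
       fs = fs)
}

# band-limited random perturbation: white noise smoothed with a Gaussian
# kernel (sigma ~10 ms at 1 kHz), edge-tapered, normalised to the requested
# SD. Its energy sits below the denoiser's detail bands, so it survives
# preprocessing, yet it is fast enough to register as waveform irregularity.
.bandlimited_jitter <- function(nw, sd_target, sigma = 10) {
  kern_x <- seq(-3 * sigma, 3 * sigma)
  kern <- exp(-kern_x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  pad <- length(kern_x)
  w <- rnorm(nw + 2L * pad)
  w <- as.numeric(stats::filter(w, kern, sides = 2))
  w <- w[seq(pad + 1L, pad + nw)]
  taper_n <- max(2L, round(0.1 * nw))
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = taper_n)))
  taper <- rep(1, nw)
  taper[seq_len(taper_n)] <- ramp
  taper[seq(nw, nw - taper_n + 1L)] <- ramp
  w <- (w - mean(w)) * taper
  s <- sd(w)
  if (s == 0) return(numeric(nw))
  w / s * sd_target
}

# smooth random perturbation over nw samples: random cubic, edge-tapered,
# normalised to the requested SD
.smooth_jitter <- function(nw, sd_target) {
  u <- seq(-1, 1, length.out = nw)
  coef <- rnorm(4L)
  w <- coef[1] + coef[2] * u + coef[3] * (u^2 - 1 / 3) + coef[4] * (u^3 - 3 * u / 5)
  taper_n <- max(2L, round(0.1 * nw))
  taper <- rep(1, nw)
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = taper_n)))
  taper[seq_len(taper_n)] <- ramp
  taper[seq(nw, nw - taper_n + 1L)] <- ramp
  w <- w * taper
  s <- sd(w)
  if (s == 0) return(numeric(nw))
  w / s * sd_target
}

# run expr with a private RNG stream; global .Random.seed is restored
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

#' Generate a labelled synthetic 20 s, 12-lead record
#'
#' All randomness (RR jitter, ST-T perturbation, noise) is a pure function of
#' `seed`. The ischemic preset differs from the healthy one by a nonzero ST
#' deviation and/or T inversion and a strictly larger `stt_jitter_sd`.
#'
#' @param class_label `"healthy"` or `"ischemic"`.
#' @param params a [beat_template_params()]; defaults to the class preset.
#' @param noise a [noise_params()].
#' @param seed integer seed.
#' @param fs sampling frequency, Hz.
#' @param duration_s record length, s.
#' @param record_id identifier; autogenerated by default.
#' @return List with `record` (a `multi_lead_record`) and `truth`
#'   (an `stt_segment_set` of ground-truth beat annotations).
#' @export
generate_record <- function(class_label = c("healthy", "ischemic"),
                            params = NULL, noise = noise_params(), seed = 1L,
                            fs = 1000, duration_s = 20, record_id = NULL) {
  class_label <- match.arg(class_label)
  if (is.null(params)) {
    params <- if (class_label == "healthy") healthy_beat_params()
              else ischemic_beat_params()
  }
  if (is.null(record_id)) record_id <- sprintf("%s_seed%d", class_label, seed)
  .with_seed(seed, {
    n <- round(duration_s * fs)
    x <- matrix(0, n, 12L, dimnames = list(NULL, CANONICAL_LEADS))
    geom <- .beat_geometry(params)
    truth <- list()
    # Repolarization dispersion model, confined to the ST-T window:
    #  - drift: a fixed smooth window shape per lead whose amplitude follows
    #    a single slow wave across the record (a transient ST-T trend that
    #    waxes and wanes over the 20 s, about one cycle);
    #  - jitter: an independent smooth perturbation drawn per beat per lead.
    beat0 <- generate_beat(params, fs)
    win <- seq(beat0$stt_start, min(beat0$stt_end + round(0.02 * fs),
                                    nrow(beat0$leads)))
    nw <- length(win)
    shape0 <- sapply(CANONICAL_LEADS, function(ld) .smooth_jitter(nw, 1))
    k_beats <- ceiling(duration_s / geom$rr) + 1L
    drift_phase <- runif(12L, 0, 2 * pi)
    drift_cycles <- runif(12L, 0.35, 0.8)
    beat_no <- 0L
    # R-peak position is accumulated in whole samples so that with zero RR
    # jitter the record is exactly periodic (beats tile without off-by-one
    # rounding drift)
    r_s <- round(geom$r_lead_time * fs)      # current R peak, 0-based sample
    while (r_s < (duration_s + geom$rr) * fs) {
      beat <- generate_beat(params, fs)
      start0 <- r_s - (beat$r_peak - 1L)               # beat start, 0-based
      idx <- start0 + seq_len(nrow(beat$leads))        # 1-based target rows
      keep <- idx >= 1L & idx <= n
      bl <- beat$leads
      beat_no <- beat_no + 1L
      if (params$stt_jitter_sd > 0 || params$stt_drift_sd > 0) {
        a_k <- sqrt(2) * sin(2 * pi * drift_cycles * beat_no / k_beats + drift_phase)
        for (j in seq_len(12L)) {
          ld <- CANONICAL_LEADS[j]
          pert <- params$stt_drift_sd * a_k[j] * shape0[, j] +
            params$stt_jitter_sd * .bandlimited_jitter(nw, 1)
          bl[win, ld] <- bl[win, ld] + abs(LEAD_AMP_PROFILE[[ld]]) * pert
        }
      }
      x[idx[keep], ] <- x[idx[keep], ] + bl[keep, ]
      ann <- c(r_peak = start0 + beat$r_peak,
               stt_start = start0 + beat$stt_start,
               stt_end = start0 + beat$stt_end)
      if (ann["r_peak"] >= 1 && ann["stt_end"] <= n) {
        truth[[length(truth) + 1L]] <- ann
      }
      rr_k <- geom$rr + if (params$rr_jitter_sd > 0) rnorm(1, 0, params$rr_jitter_sd) else 0
      r_s <- r_s + round(max(0.3, rr_k) * fs)
    }
    tt <- (seq_len(n) - 1) / fs
    if (noise$baseline_amp > 0 || noise$powerline_amp > 0 || noise$broadband_sd > 0) {
      for (j in seq_len(12L)) {
        ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
        x[, j] <- x[, j] +
          noise$baseline_amp * sin(2 * pi * noise$baseline_freq * tt + ph1) +
          noise$powerline_amp * sin(2 * pi * 50 * tt + ph2) +
          (if (noise$broadband_sd > 0) rnorm(n, 0, noise$broadband_sd) else 0)
      }
    }
    rec <- multi_lead_record(x, fs = fs, lead_names = CANONICAL_LEADS,
                             record_id = record_id, label = class_label)
    truth_mat <- do.call(rbind, truth)
    list(record = rec,
         truth = stt_segment_set(truth_mat[, "r_peak"], truth_mat[, "stt_start"],
                                 truth_mat[, "stt_end"], fs = fs,
                                 record_id = record_id))
  })
}

#' Healthy beat preset
#' @param ... overrides passed to [beat_template_params()].
#' @return A `beat_template_params` list.
#' @export
healthy_beat_params <- function(...) {
  args <- modifyList(list(st_deviation = 0, t_inversion = FALSE,
                          stt_jitter_sd = 0.010, stt_drift_sd = 0.005),
                     list(...))
  do.call(beat_template_params, args)
}

#' Ischemic beat preset
#'
#' ST depression with elevated beat-to-beat repolarization variability.
#' @param ... overrides passed to [beat_template_params()].
#' @return A `beat_template_params` list.
#' @export
ischemic_beat_params <- function(...) {
  args <- modifyList(list(st_deviation = -0.15, t_inversion = FALSE,
                          stt_jitter_sd = 0.050, stt_drift_sd = 0.080),
                     list(...))
  do.call(beat_template_params, args)
}

#' Generate a labelled synthetic cohort
#'
#' Per-record seeds are derived deterministically from the master seed, and
#' within-class template parameters are mildly perturbed (heart rate, wave
#' amplitudes, ST deviation, jitter level) so records are not identical.
#' Ischemic records draw an ST elevation or depression of 0.10--0.25 mV
#' (occasionally with T inversion) and a repolarization jitter SD of
#' 0.03--0.07 mV; healthy records stay near the isoelectric line with jitter
#' SD 0.005--0.015 mV.
#'
#' @param n_ischemic,n_healthy record counts (>= 0).
#' @param seed master seed.
#' @param noise a [noise_params()] shared by all records.
#' @param fs sampling frequency, Hz.
#' @return List of `list(record, truth)` entries (ischemic first).
#' @export
generate_cohort <- function(n_ischemic, n_healthy, seed = 1L,
                            noise = noise_params(), fs = 1000) {
  stopifnot(n_ischemic >= 0, n_healthy >= 0)
  out <- vector("list", n_ischemic + n_healthy)
  k <- 0L
  for (i in seq_len(n_ischemic)) {
    rec_seed <- (seed + 7919 * i) %% 2147483647
    params <- .with_seed(rec_seed * 2 + 1, {
      ischemic_beat_params(
        heart_rate = min(110, max(50, rnorm(1, 72, 8))),
        r_amp = runif(1, 0.9, 1.3), t_amp = runif(1, 0.2, 0.4),
        st_deviation = sample(c(-1, 1), 1, prob = c(0.6, 0.4)) * runif(1, 0.10, 0.25),
        t_inversion = runif(1) < 0.3,
        stt_jitter_sd = runif(1, 0.03, 0.07),
        stt_drift_sd = runif(1, 0.06, 0.12))
    })
    k <- k + 1L
    out[[k]] <- generate_record("ischemic", params, noise, seed = rec_seed,
                                fs = fs, record_id = sprintf("isch_%03d", i))
  }
  for (i in seq_len(n_healthy)) {
    rec_seed <- (seed + 7919 * (n_ischemic + i) + 13) %% 2147483647
    params <- .with_seed(rec_seed * 2 + 1, {
      healthy_beat_params(
        heart_rate = min(110, max(50, rnorm(1, 70, 7))),
        r_amp = runif(1, 0.9, 1.3), t_amp = runif(1, 0.25, 0.40),
        st_deviation = rnorm(1, 0, 0.01),
        stt_jitter_sd = runif(1, 0.005, 0.015),
        stt_drift_sd = runif(1, 0.002, 0.008))
    })
    k <- k + 1L
    out[[k]] <- generate_record("healthy", params, noise, seed = rec_seed,
                                fs = fs, record_id = sprintf("ctrl_%03d", i))
  }
  out
}
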