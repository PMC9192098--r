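test_that("R-peak detection recovers synthetic ground truth", {
  s <- make_segmented_record("healthy", seed = 6)
  g <- generate_record("healthy", seed = 6, noise = no_noise())
  rec <- preprocess_record(g$record)
  rp <- detect_r_peaks(get_lead(rec, "II"), rec$fs)
  truth <- g$truth$beats$r_peak
  # ~70 bpm over 20 s: 23 +/- 1 beats
  expect_lte(abs(length(rp) - 23L), 1L)
  err <- vapply(truth, function(r) min(abs(rp - r)), numeric(1))
  expect_lte(max(err), 10)      # within 10 ms at 1 kHz
  # all-zero input
  expect_error(detect_r_peaks(rep(0, 5000), 1000), "insufficient beats")
  expect_error(detect_r_peaks(rep(0, 500), 1000), "2 s")
})

test_that("R-peak detection is robust to broadband noise", {
  g <- generate_record("healthy", seed = 8,
                       noise = noise_params(baseline_amp = 0.05,
                                            powerline_amp = 0.02,
                                            broadband_sd = 0.05))
  rec <- preprocess_record(g$record)
  rp <- detect_r_peaks(get_lead(rec, "II"), rec$fs)
  truth <- g$truth$beats$r_peak
  hit <- vapply(truth, function(r) min(abs(rp - r)) <= 20, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("ST-T delineation recovers ground-truth windows on clean records", {
  g <- generate_record("healthy", seed = 6, noise = no_noise())
  rec <- preprocess_record(g$record)
  segs <- delineate_stt(rec, detect_r_peaks(get_lead(rec, "II"), rec$fs))
  tb <- g$truth$beats
  db <- segs$beats
  idx <- vapply(db$r_peak, function(r) which.min(abs(tb$r_peak - r)), 1L)
  expect_lte(mean(abs(db$stt_start - tb$stt_start[idx])), 15)
  expect_lte(mean(abs(db$stt_end - tb$stt_end[idx])), 25)
  # invariants: ordered, non-overlapping, physiological lengths
  expect_true(all(db$r_peak < db$stt_start))
  expect_true(all(db$stt_start < db$stt_end))
  expect_true(all(diff(db$r_peak) > 0))
  expect_true(all(db$stt_end[-nrow(db)] <= db$r_peak[-1]))
  len_ms <- (db$stt_end - db$stt_start)
  expect_true(all(len_ms >= 80 & len_ms <= 600))
})

test_that("beats truncated by the record end are dropped, others kept", {
  g <- generate_record("healthy", seed = 6, noise = no_noise())
  rec <- preprocess_record(g$record)
  rp <- detect_r_peaks(get_lead(rec, "II"), rec$fs)
  full <- delineate_stt(rec, rp)
  # cut the record just after the last R peak so its T wave is lost
  cut <- multi_lead_record(rec$samples[seq_len(max(rp) + 100), ], rec$fs,
                           rec$lead_names, "cut")
  part <- delineate_stt(cut, rp)
  expect_equal(nrow(part$beats), nrow(full$beats) - 1L)
  expect_equal(part$beats, full$beats[seq_len(nrow(part$beats)), ],
               ignore_attr = TRUE)
  expect_gte(part$n_dropped, 1L)
})

test_that("fast heart rates respect the 0.7 RR upper bound", {
  p <- healthy_beat_params(heart_rate = 120)
  g <- generate_record("healthy", params = p, noise = no_noise(), seed = 3)
  rec <- preprocess_record(g$record)
  rp <- detect_r_peaks(get_lead(rec, "II"), rec$fs)
  segs <- delineate_stt(rec, rp)
  rr <- median(diff(rp))
  expect_true(all(segs$beats$stt_end - segs$beats$r_peak <= 0.7 * rr + 1))
})

test_that("delineation is deterministic and refuses hopeless input", {
  g <- generate_record("ischemic", seed = 9)
  rec <- preprocess_record(g$record)
  rp <- detect_r_peaks(get_lead(rec, "II"), rec$fs)
  expect_identical(delineate_stt(rec, rp)$beats, delineate_stt(rec, rp)$beats)
  expect_error(delineate_stt(rec, rp[1:2]), "3 R peaks")
})

test_that("splicing concatenates half-open windows with exact bookkeeping", {
  segs <- stt_segment_set(r_peak = c(100, 600), stt_start = c(200, 700),
                          stt_end = c(400, 900), fs = 1000, record_id = "t")
  x <- seq_len(1000)
  sp <- splice_stt(x, segs)
  expect_length(sp$series, 400L)
  expect_identical(sp$boundaries, c(0L, 200L, 400L))
  expect_identical(sp$series, c(x[200:399], x[700:899]))
  # one beat: the window itself
  one <- stt_segment_set(100, 200, 400, fs = 1000)
  expect_identical(splice_stt(x, one)$series, x[200:399])
  # full record: length equals the sum of window lengths
  g <- make_segmented_record("healthy", seed = 6)
  sp <- splice_stt(get_lead(g$rec, "V2"), g$segs)
  expect_length(sp$series, sum(g$segs$beats$stt_end - g$segs$beats$stt_start))
  # errors
  empty <- stt_segment_set(integer(0), integer(0), integer(0), fs = 1000)
  expect_error(splice_stt(x, empty), "empty")
  far <- stt_segment_set(100, 200, 400, fs = 1000)
  expect_error(splice_stt(seq_len(300), far), "outside")
})

test_that("segment sets validate ordering and physiological bounds", {
  expect_error(stt_segment_set(100, 90, 200, fs = 1000))       # start <= r
  expect_error(stt_segment_set(100, 200, 190, fs = 1000))      # end <= start
  expect_error(stt_segment_set(100, 200, 210, fs = 1000), "80")  # too short
  expect_error(stt_segment_set(100, 200, 900, fs = 1000), "range")  # too long
})
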