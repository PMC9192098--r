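test_that("WFDB round-trip preserves samples and normalizes lead names", {
  dir <- withr::local_tempdir()
  fs <- 500
  # calibration pulse of 1 mV on channel 1
  x <- cbind(c(rep(0, 100), rep(1, 100), rep(0, 300)), rep(0.25, 500))
  rec <- multi_lead_record(x, fs = fs, lead_names = c("avf", "v6"),
                           record_id = "cal")
  expect_identical(rec$lead_names, c("AVF", "V6"))
  write_wfdb_record(rec, file.path(dir, "cal"), gain = 1000)
  back <- read_wfdb_record(file.path(dir, "cal"))
  expect_identical(back$lead_names, c("AVF", "V6"))
  expect_equal(max(back$samples[, "AVF"]), 1.0)
  expect_equal(back$fs, fs)

  # 12 x 20,000 synthetic record: round-trip within format quantization
  g <- generate_record("healthy", seed = 5)
  write_wfdb_record(g$record, file.path(dir, "r12"), gain = 1000)
  b <- read_wfdb_record(file.path(dir, "r12"))
  expect_equal(dim(b$samples), c(20000L, 12L))
  expect_lt(max(abs(b$samples - g$record$samples)), 0.5 / 1000 + 1e-12)

  # channel selection and lead-not-found error
  sel <- read_wfdb_record(file.path(dir, "r12"), channels = c("V6", "I"))
  expect_identical(sel$lead_names, c("V6", "I"))
  expect_error(read_wfdb_record(file.path(dir, "r12"), channels = "VX"),
               "lead not found")
  expect_error(read_wfdb_record(file.path(dir, "absent")), "not found")
})

test_that("delimited record reading validates shape and numeric content", {
  dir <- withr::local_tempdir()
  p0 <- file.path(dir, "zeros.csv")
  write.table(matrix(0, 10, 3), p0, sep = ",", row.names = FALSE,
              col.names = FALSE)
  rec <- read_delimited_record(p0, fs = 1000, lead_names = c("I", "II", "V1"))
  expect_true(all(rec$samples == 0))

  # header row consumed
  ph <- file.path(dir, "hdr.csv")
  writeLines(c("I,II,V1", "0.1,0.2,0.3", "0.4,0.5,0.6"), ph)
  rec <- read_delimited_record(ph, fs = 1000, lead_names = c("I", "II", "V1"))
  expect_equal(nrow(rec$samples), 2L)
  expect_equal(unname(rec$samples[1, "I"]), 0.1)

  # ragged row -> parse error with line number
  pr <- file.path(dir, "ragged.csv")
  writeLines(c("1,2,3", "1,2", "1,2,3"), pr)
  expect_error(read_delimited_record(pr, 1000, c("I", "II", "V1")), "line 2")

  # non-numeric cell -> parse error with line number
  pn <- file.path(dir, "bad.csv")
  writeLines(c("1,2,3", "1,x,3"), pn)
  expect_error(read_delimited_record(pn, 1000, c("I", "II", "V1")), "line 2")

  # full-size write/read passes the 20 s check
  g <- generate_record("ischemic", seed = 2)
  pf <- file.path(dir, "full.csv")
  write_delimited_record(g$record, pf)
  rec <- read_delimited_record(pf, fs = 1000, lead_names = CANONICAL_LEADS)
  expect_equal(nrow(rec$samples), 20000L)
  expect_true(is_canonical_length(rec))
  expect_equal(rec$samples, g$record$samples, tolerance = 1e-6)
})

test_that("resampling preserves duration and band-limited content", {
  fs0 <- 500
  t0 <- seq(0, 10 - 1 / fs0, by = 1 / fs0)
  rec <- multi_lead_record(cbind(sin(2 * pi * 5 * t0)), fs0, "I", "sin5")
  up <- resample_record(rec, 1000)
  expect_equal(nrow(up$samples), 10000L)
  expect_equal(up$fs, 1000)
  t1 <- seq(0, 10 - 1 / 1000, by = 1 / 1000)
  expect_gt(cor(up$samples[, 1], sin(2 * pi * 5 * t1)), 0.999)
  # identity: same fs returns bitwise-equal input
  expect_identical(resample_record(rec, fs0)$samples, rec$samples)
  # 10,000 samples at 500 Hz -> 20,000 at 1,000 Hz
  expect_equal(nrow(resample_record(rec, 1000)$samples), 2L * nrow(rec$samples))
})

test_that("feature table round-trips and enforces its schema", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "feat.csv")
  cols <- vcgischemia:::FEATURE_COLUMNS
  # empty -> header-only file
  write_feature_table(list(), p)
  expect_equal(length(readLines(p)), 1L)
  expect_equal(nrow(read_feature_table(p)), 0L)
  # round-trip of 5 random vectors
  set.seed(1)
  rows <- lapply(1:5, function(i) {
    list(record_id = sprintf("r%d", i), label = "healthy",
         features = setNames(rnorm(17), cols))
  })
  write_feature_table(rows, p)
  back <- read_feature_table(p)
  for (i in 1:5) {
    expect_equal(as.numeric(back[i, cols]),
                 as.numeric(rows[[i]]$features), tolerance = 1e-12)
  }
  # missing SHI column -> schema error naming it
  df <- read.csv(p, check.names = FALSE)
  df$SHI <- NULL
  write.csv(df, p, row.names = FALSE)
  expect_error(read_feature_table(p), "SHI")
  # unknown column -> schema error
  df$SHI <- 0; df$extra <- 1
  write.csv(df, p, row.names = FALSE)
  expect_error(read_feature_table(p), "extra")
})

test_that("lead-name normalization is idempotent over arbitrary case", {
  set.seed(3)
  for (i in 1:20) {
    nm <- sample(c(CANONICAL_LEADS, "Vx", "Vy", "Vz"), 5)
    scrambled <- vapply(nm, function(s) {
      flip <- runif(nchar(s)) < 0.5
      ch <- strsplit(s, "")[[1]]
      paste(ifelse(flip, tolower(ch), ch), collapse = "")
    }, "")
    once <- unname(normalize_lead_names(scrambled))
    expect_identical(once, nm)
    expect_identical(normalize_lead_names(once), once)
  }
})

test_that("record validation rejects NaN and mismatched leads", {
  expect_error(multi_lead_record(matrix(c(1, NA), 2, 1), 100, "I"), "NA")
  expect_error(multi_lead_record(matrix(0, 5, 2), 100, "I"), "lead names")
  expect_error(multi_lead_record(matrix(0, 5, 1), -1, "I"), "positive")
  # truncation: longer records cut, shorter rejected
  rec <- multi_lead_record(matrix(0, 2500, 1), 100, "I")
  expect_equal(nrow(truncate_record(rec, 20)$samples), 2000L)
  short <- multi_lead_record(matrix(0, 900, 1), 100, "I")
  expect_error(truncate_record(short, 20), "shorter")
})
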