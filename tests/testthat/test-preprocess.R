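# Preprocessing chain: decimation, saturation zeroing, zero-phase band-pass,
# artifact interpolation, channel quality control, and the full pipeline.

fake_rec <- function(data, fs = 200) {
  structure(list(subject_id = "T", condition = "baseline",
                 sample_rate_hz = fs, channels = paste0("ch", seq_len(ncol(data))),
                 data = data, duration_s = nrow(data) / fs),
            class = "raw_recording")
}

cfg <- preprocess_config()

test_that("decimation: length rule, rate update, non-integer factor rejected", {
  rec <- fake_rec(matrix(rnorm(240000 * 2), ncol = 2), fs = 2000)
  out <- decimate_to_target(rec, cfg)
  expect_equal(nrow(out$data), 24000)
  expect_equal(out$sample_rate_hz, 200)
  bad <- fake_rec(matrix(0, 1999, 1), fs = 1999)
  expect_error(decimate_to_target(bad, cfg), "integer multiple")
})

test_that("saturation zeroing matches a brute-force recount and is idempotent", {
  x <- matrix(200, 1000, 1)
  out <- zero_saturated(fake_rec(x), cfg)
  expect_true(all(out$rec$data == 0))
  expect_equal(unname(out$dropped_fraction), 1)

  x2 <- matrix(sin(1:1000) * 1, 1000, 1)
  out2 <- zero_saturated(fake_rec(x2), cfg)
  expect_identical(out2$rec$data, x2)
  expect_equal(unname(out2$dropped_fraction), 0)

  x3 <- matrix(0.5, 120000, 1)
  x3[sample.int(120000, 12000), 1] <- 190
  out3 <- zero_saturated(fake_rec(x3), cfg)
  expect_equal(unname(out3$dropped_fraction), 0.10)
  # brute-force recount of replaced samples
  expect_equal(sum(out3$rec$data != x3), sum(abs(x3) >= 187.5))
  # idempotence
  again <- zero_saturated(out3$rec, cfg)
  expect_identical(again$rec$data, out3$rec$data)
  expect_equal(unname(again$dropped_fraction), 0)
})

test_that("band-pass is zero-phase, passes the band and rejects DC and 5 Hz", {
  fs <- 200
  t <- seq(0, 900, by = 1 / fs)[-1]
  trim <- (60 * fs):(length(t) - 60 * fs)

  dc <- fake_rec(matrix(5, length(t), 1))
  out <- bandpass_zero_phase(dc, cfg)
  expect_lt(max(abs(out$data[trim, 1])), 1e-3 * 5)

  for (f in c(0.1, 0.2, 0.4)) {
    x <- sin(2 * pi * f * t)
    y <- bandpass_zero_phase(fake_rec(matrix(x, ncol = 1)), cfg)$data[, 1]
    cc <- stats::ccf(y[trim], x[trim], lag.max = fs, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
    if (f == 0.2) {
      expect_gt(stats::sd(y[trim]) / stats::sd(x[trim]), 0.9)
      expect_lte(stats::sd(y[trim]) / stats::sd(x[trim]), 1.0)
    }
  }

  hi <- sin(2 * pi * 5 * t)
  yh <- bandpass_zero_phase(fake_rec(matrix(hi, ncol = 1)), cfg)$data[, 1]
  expect_lt(stats::sd(yh[trim]) / stats::sd(hi), 0.01)

  expect_error(bandpass_zero_phase(fake_rec(matrix(0, 100, 1), fs = 1),
                                   cfg), "inside")
})

test_that("artifact interpolation replaces out-of-range runs with straight lines", {
  ok <- matrix(1.9 * sin(1:500 / 10), ncol = 1)
  out <- interpolate_artifacts(fake_rec(ok), cfg)
  expect_identical(out$rec$data, ok)
  expect_equal(unname(out$interp_fraction), 0)

  flat <- matrix(0, 1000, 1)
  flat[300:304, 1] <- 10
  out2 <- interpolate_artifacts(fake_rec(flat), cfg)
  expect_true(all(out2$rec$data == 0))
  expect_equal(unname(out2$interp_fraction), 5 / 1000)

  n <- 1000
  ramp <- seq(0, 1, length.out = n)
  spiked <- ramp
  spiked[500:502] <- 10
  out3 <- interpolate_artifacts(fake_rec(matrix(spiked, ncol = 1)), cfg)
  line <- ramp[499] + (ramp[503] - ramp[499]) * (1:3) / 4
  expect_lt(max(abs(out3$rec$data[500:502, 1] - line)), 1e-9)

  # boundary runs take the nearest in-range value
  edge <- c(rep(10, 5), rep(1, 10), rep(-10, 5))
  out4 <- interpolate_artifacts(fake_rec(matrix(edge, ncol = 1)), cfg)
  expect_equal(out4$rec$data[1:5, 1], rep(1, 5))
  expect_equal(out4$rec$data[16:20, 1], rep(1, 5))

  allout <- matrix(10, 100, 1)
  expect_warning(out5 <- interpolate_artifacts(fake_rec(allout), cfg),
                 "entirely")
  expect_equal(unname(out5$interp_fraction), 1)
})

test_that("fraction bookkeeping: dropped and interpolated counts are disjoint and exact", {
  x <- numeric(2000) + 0.5
  x[100:199] <- 190   # saturated: later zeroed, zeros are in-range
  x[900:949] <- 5     # movement artifact
  s <- zero_saturated(fake_rec(matrix(x, ncol = 1)), cfg)
  i <- interpolate_artifacts(s$rec, cfg)
  expect_equal(unname(s$dropped_fraction), 100 / 2000)
  expect_equal(unname(i$interp_fraction), 50 / 2000)
})

test_that("quality gate reproduces the printed channel-quality table exactly", {
  t1 <- read.csv(table1_path())
  expect_equal(nrow(t1), 32L)
  passed <- qc_pass(t1$pct_dropped, t1$pct_artifact, t1$power, cfg)
  flagged <- t1[!passed, c("animal", "condition", "channel")]
  expect_equal(nrow(flagged), 3L)
  expect_true(all(flagged$channel == 3))
  expect_setequal(unique(flagged$animal), c("60-21", "87-21"))
  expect_setequal(paste(flagged$animal, flagged$condition),
                  c("60-21 baseline", "60-21 feeding", "87-21 feeding"))
  # worked examples
  expect_false(qc_pass(1.3, 51.2, 8.7e8, cfg))   # 60-21 baseline ch3
  expect_true(qc_pass(18.3, 6.5, 2.0e8, cfg))    # 58-21 feeding ch1
  expect_false(qc_pass(0, 0, 0, cfg))            # dead channel: power criterion
})

test_that("full pipeline retains clean channels and drops an artifact-heavy one", {
  sp <- signal_params()
  clean <- generate_recording("F1", "baseline", sp,
                              artifact_params(saturation_rate_per_hour = 0,
                                              movement_rate_per_hour = 0),
                              duration_s = 180, sample_rate_hz = 2000, seed = 1)
  out <- run_preprocess(clean, cfg)
  expect_equal(out$sample_rate_hz, 200)
  expect_equal(nrow(out$data), 180 * 200)
  expect_setequal(out$retained_channels, paste0("ch", 1:4))
  expect_equal(out$qc$pct_dropped, rep(0, 4))
  expect_equal(out$qc$pct_interpolated, rep(0, 4))
  expect_equal(out$fingerprint$stages,
               c("decimate", "zero_saturated", "bandpass",
                 "interpolate_artifacts", "channel_qc"))

  dirty <- generate_recording("F1", "baseline", sp,
                              artifact_params(saturation_rate_per_hour = 400,
                                              saturation_dur_s = c(5, 10),
                                              channels = 3L),
                              duration_s = 180, sample_rate_hz = 2000, seed = 2)
  out2 <- run_preprocess(dirty, cfg)
  expect_setequal(out2$retained_channels, c("ch1", "ch2", "ch4"))

  bad <- generate_recording("F1", "baseline", sp,
                            artifact_params(saturation_rate_per_hour = 0,
                                            movement_rate_per_hour = 0),
                            duration_s = 2, sample_rate_hz = 1999, seed = 1)
  expect_error(run_preprocess(bad, cfg), "decimate")
})
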