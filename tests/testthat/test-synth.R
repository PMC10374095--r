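# Synthetic recording generator: shapes, determinism, spectral structure,
# artifact statistics, CSV round trips.

quiet_signal <- signal_params(noise_sd_mv = 0, drift_amp_mv = 0,
                              tachy_power_fraction = 0)
no_artifacts <- artifact_params(saturation_rate_per_hour = 0,
                                movement_rate_per_hour = 0)

test_that("recording dimensions follow duration x rate and inputs are validated", {
  rec <- generate_recording("F1", "baseline", quiet_signal, no_artifacts,
                            duration_s = 3600, sample_rate_hz = 2000, seed = 1)
  expect_equal(nrow(rec$data), 3600 * 2000)
  expect_equal(ncol(rec$data), 4L)
  expect_true(all(abs(rec$data) <= 187.5))
  expect_error(generate_recording("F1", "baseline", duration_s = 0), "positive")
  expect_error(generate_recording("F1", "baseline", quiet_signal, no_artifacts,
                                  duration_s = 1, sample_rate_hz = 0.2),
               "Nyquist")
  expect_error(signal_params(slow_wave_freq_hz = 1.5))
  expect_error(artifact_params(movement_amp_mv = c(1, 5)))
})

test_that("identical seed and parameters give bit-identical recordings", {
  r1 <- generate_recording("F2", "feeding", duration_s = 30,
                           sample_rate_hz = 200, seed = 42)
  r2 <- generate_recording("F2", "feeding", duration_s = 30,
                           sample_rate_hz = 200, seed = 42)
  expect_identical(r1$data, r2$data)
  r3 <- generate_recording("F2", "feeding", duration_s = 30,
                           sample_rate_hz = 200, seed = 43)
  expect_false(identical(r1$data, r3$data))
})

test_that("pure-tone generation puts the periodogram peak at the slow-wave frequency", {
  rec <- generate_recording("F1", "baseline",
                            signal_params(noise_sd_mv = 0, drift_amp_mv = 0,
                                          tachy_power_fraction = 0,
                                          amp_mod_depth = 0),
                            no_artifacts, duration_s = 600,
                            sample_rate_hz = 200, seed = 5)
  for (c in 1:4) {
    expect_lt(abs(periodogram_peak(rec$data[, c], 200) - 0.15), 1 / 600 + 1e-9)
  }
})

test_that("spectral placement: signal variance concentrates at the two rhythm lines", {
  sp <- signal_params(noise_sd_mv = 0, drift_amp_mv = 0)
  for (cond in c("baseline", "feeding")) {
    rec <- generate_recording("F3", cond, sp, no_artifacts,
                              duration_s = 600, sample_rate_hz = 200, seed = 9)
    for (c in 1:4) {
      expect_gt(variance_fraction_near(rec$data[, c], 200, c(0.15, 0.45)),
                0.99)
    }
  }
})

test_that("feeding shifts power toward the tachygastric range on every seeded pair", {
  frac_above <- function(rec) {
    mean(vapply(1:4, function(c) {
      p <- periodogram(rec$data[, c] - mean(rec$data[, c]), 200)
      sum(p$power[p$freqs_hz > 0.3]) / sum(p$power[-1])
    }, 0))
  }
  for (seed in 1:10) {
    b <- generate_recording("F1", "baseline", signal_params(), no_artifacts,
                            duration_s = 120, sample_rate_hz = 200, seed = seed)
    f <- generate_recording("F1", "feeding", signal_params(), no_artifacts,
                            duration_s = 120, sample_rate_hz = 200, seed = seed)
    expect_gt(frac_above(f), frac_above(b))
  }
})

test_that("injected artifact counts follow the configured Poisson rates", {
  ap <- artifact_params(saturation_rate_per_hour = 2,
                        movement_rate_per_hour = 6)
  n_sat <- n_mov <- 0
  n_rec <- 60
  for (seed in seq_len(n_rec)) {
    rec <- generate_recording("F1", "baseline", quiet_signal, ap,
                              duration_s = 3600, sample_rate_hz = 20,
                              seed = seed)
    n_sat <- n_sat + sum(attr(rec, "n_saturation"))
    n_mov <- n_mov + sum(attr(rec, "n_movement"))
  }
  exp_sat <- 2 * 4 * n_rec   # rate x channels x recordings, 1 h each
  exp_mov <- 6 * 4 * n_rec
  expect_lt(abs(n_sat - exp_sat), 3 * sqrt(exp_sat))
  expect_lt(abs(n_mov - exp_mov), 3 * sqrt(exp_mov))
})

test_that("artifact injection produces rail-valued and >2 mV samples", {
  ap <- artifact_params(saturation_rate_per_hour = 40,
                        movement_rate_per_hour = 40, channels = 3L)
  rec <- generate_recording("F1", "baseline", quiet_signal, ap,
                            duration_s = 600, sample_rate_hz = 200, seed = 2)
  expect_true(any(abs(rec$data[, 3]) == 187.5))
  expect_true(any(abs(rec$data[, 3]) > 2 & abs(rec$data[, 3]) < 187.5))
  # untouched channels stay clean
  expect_true(all(abs(rec$data[, c(1, 2, 4)]) < 2))
})

test_that("CSV round trip is lossless to 1e-6 mV and rejects empty recordings", {
  rec <- generate_recording("F1", "feeding", duration_s = 3,
                            sample_rate_hz = 200, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path, subject_id = "F1", condition = "feeding")
  expect_lt(max(abs(back$data - rec$data)), 1e-6)
  expect_equal(back$sample_rate_hz, 200)

  toy <- rec
  toy$data <- toy$data[1:3, , drop = FALSE]
  write_recording_csv(toy, path)
  expect_length(readLines(path), 4L)  # header + 3 samples

  empty <- rec
  empty$data <- rec$data[0, , drop = FALSE]
  expect_error(write_recording_csv(empty, path), "empty")
})
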