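# Synthetic multichannel gastric myoelectric recordings.
#
# The generator emulates serosal recordings from a freely moving ferret: a
# quasi-sinusoidal gastric slow wave (0.05-0.3 Hz) shared across channels with
# per-channel phase lag and gain, a tachygastric component whose power
# fraction rises with feeding, slow baseline drift, broadband instrument
# noise, amplifier-saturation episodes clipped at the input rail
# (+/- 187.5 mV) and >2 mV raised-cosine movement transients at
# Poisson-distributed times.

AMP_RAIL_MV <- 187.5

#' Signal-model parameters for the synthetic slow-wave generator
#'
#' Defaults place the baseline slow wave at 0.15 Hz (9 cpm, mid-band of the
#' ferret normogastric range) with a 0.45 Hz tachygastric component carrying
#' 5% of rhythm power at baseline and 35% during feeding.
#'
#' @param slow_wave_freq_hz dominant slow-wave frequency in Hz.
#' @param slow_wave_amp_mv slow-wave amplitude in mV (well below the 2 mV
#'   artifact threshold).
#' @param tachy_freq_hz tachygastric component frequency in Hz.
#' @param tachy_power_fraction fraction of rhythm power in the tachygastric
#'   component; either a scalar or a named vector with elements `baseline`
#'   and `feeding`.
#' @param noise_sd_mv SD of additive white instrument noise, mV.
#' @param drift_amp_mv amplitude of the <0.05 Hz baseline drift, mV.
#' @param amp_mod_depth amplitude-modulation depth of the slow wave in [0,1).
#' @param amp_mod_freq_hz modulation frequency, Hz (sidebands stay within
#'   0.01 Hz of the carrier).
#' @param second_harmonic_frac amplitude of an optional second harmonic
#'   relative to the fundamental (default 0).
#' @return object of class `signal_params`.
#' @export
signal_params <- function(slow_wave_freq_hz = 0.15,
                          slow_wave_amp_mv = 0.5,
                          tachy_freq_hz = 0.45,
                          tachy_power_fraction = c(baseline = 0.05, feeding = 0.35),
                          noise_sd_mv = 0.05,
                          drift_amp_mv = 0.1,
                          amp_mod_depth = 0.2,
                          amp_mod_freq_hz = 0.01,
                          second_harmonic_frac = 0) {
  stopifnot(slow_wave_freq_hz > 0, slow_wave_freq_hz < 1,
            tachy_freq_hz > 0, tachy_freq_hz < 1,
            slow_wave_amp_mv >= 0, noise_sd_mv >= 0, drift_amp_mv >= 0,
            amp_mod_depth >= 0, amp_mod_depth < 1,
            all(tachy_power_fraction >= 0), all(tachy_power_fraction <= 1))
  structure(list(slow_wave_freq_hz = slow_wave_freq_hz,
                 slow_wave_amp_mv = slow_wave_amp_mv,
                 tachy_freq_hz = tachy_freq_hz,
                 tachy_power_fraction = tachy_power_fraction,
                 noise_sd_mv = noise_sd_mv,
                 drift_amp_mv = drift_amp_mv,
                 amp_mod_depth = amp_mod_depth,
                 amp_mod_freq_hz = amp_mod_freq_hz,
                 second_harmonic_frac = second_harmonic_frac),
            class = "signal_params")
}

#' Artifact-injection parameters
#'
#' @param saturation_rate_per_hour expected number of amplifier-saturation
#'   episodes per hour per affected channel.
#' @param saturation_dur_s length-2 range of episode durations, seconds.
#' @param movement_rate_per_hour expected number of movement transients per
#'   hour per affected channel.
#' @param movement_amp_mv length-2 range of transient peak amplitudes, mV
#'   (minimum must exceed the 2 mV physiological threshold).
#' @param movement_dur_s length-2 range of transient durations, seconds.
#' @param channels channel indices artifacts are injected into (default all).
#' @return object of class `artifact_params`.
#' @export
artifact_params <- function(saturation_rate_per_hour = 2,
                            saturation_dur_s = c(2, 10),
                            movement_rate_per_hour = 6,
                            movement_amp_mv = c(5, 50),
                            movement_dur_s = c(1, 3),
                            channels = NULL) {
  stopifnot(saturation_rate_per_hour >= 0, movement_rate_per_hour >= 0,
            length(saturation_dur_s) == 2, all(saturation_dur_s > 0),
            length(movement_amp_mv) == 2, movement_amp_mv[1] > 2,
            length(movement_dur_s) == 2, all(movement_dur_s > 0))
  structure(list(saturation_rate_per_hour = saturation_rate_per_hour,
                 saturation_dur_s = sort(saturation_dur_s),
                 movement_rate_per_hour = movement_rate_per_hour,
                 movement_amp_mv = sort(movement_amp_mv),
                 movement_dur_s = sort(movement_dur_s),
                 channels = channels),
            class = "artifact_params")
}

# Stable string hash -> RNG stream seed, so each (subject, condition) pair
# gets an independent but reproducible stream from one master seed.
stable_seed <- function(seed, key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate one synthetic multichannel recording
#'
#' @param subject_id subject label (e.g. `"F1"`).
#' @param condition `"baseline"` or `"feeding"`; feeding selects the higher
#'   tachygastric power fraction from `signal`.
#' @param signal [signal_params()].
#' @param artifacts [artifact_params()].
#' @param duration_s recording length in seconds (default one hour).
#' @param sample_rate_hz acquisition rate (native default 2000 Hz).
#' @param n_channels number of gastric channels (default 4).
#' @param seed master RNG seed; identical `(seed, params)` give bit-identical
#'   output.
#' @return object of class `raw_recording` with fields `subject_id`,
#'   `condition`, `sample_rate_hz`, `channels`, `data` (samples x channels,
#'   mV) and `duration_s`.  Injected artifact episode counts are attached as
#'   attributes `n_saturation` and `n_movement`.
#' @export
generate_recording <- function(subject_id, condition = c("baseline", "feeding"),
                               signal = signal_params(),
                               artifacts = artifact_params(),
                               duration_s = 3600, sample_rate_hz = 2000,
                               n_channels = 4L, seed = 1L) {
  condition <- match.arg(condition)
  if (duration_s <= 0) stop("duration_s must be positive, got ", duration_s)
  fs <- sample_rate_hz
  if (signal$slow_wave_freq_hz >= fs / 2 || signal$tachy_freq_hz >= fs / 2) {
    stop("signal frequencies must lie below the Nyquist rate ", fs / 2, " Hz")
  }
  tpf <- signal$tachy_power_fraction
  if (length(tpf) > 1) {
    if (is.null(names(tpf))) stop("multi-element tachy_power_fraction must be named")
    tpf <- unname(tpf[[condition]])
  }
  n <- round(duration_s * fs)
  t <- seq(0, length.out = n, by = 1 / fs)
  A <- signal$slow_wave_amp_mv
  A_t <- if (tpf >= 1) Inf else A * sqrt(tpf / (1 - tpf))
  with_seed(stable_seed(seed, paste(subject_id, condition, sep = "/")), {
    phi0 <- stats::runif(1, 0, 2 * pi)
    psi0 <- stats::runif(1, 0, 2 * pi)
    theta <- stats::runif(1, 0, 2 * pi)
    lag <- stats::runif(n_channels, 0, pi / 2)
    lag_t <- stats::runif(n_channels, 0, pi / 2)
    gain <- stats::runif(n_channels, 0.7, 1.3)
    xi <- stats::runif(n_channels, 0, 2 * pi)
    data <- matrix(0, nrow = n, ncol = n_channels)
    n_sat <- integer(n_channels)
    n_mov <- integer(n_channels)
    art_ch <- if (is.null(artifacts$channels)) seq_len(n_channels) else artifacts$channels
    for (c in seq_len(n_channels)) {
      env <- 1 + signal$amp_mod_depth * sin(2 * pi * signal$amp_mod_freq_hz * t + theta)
      x <- gain[c] * A * env * sin(2 * pi * signal$slow_wave_freq_hz * t + phi0 - lag[c])
      if (signal$second_harmonic_frac > 0) {
        x <- x + gain[c] * A * signal$second_harmonic_frac *
          sin(4 * pi * signal$slow_wave_freq_hz * t + 2 * (phi0 - lag[c]))
      }
      if (A_t > 0) {
        x <- x + gain[c] * A_t * sin(2 * pi * signal$tachy_freq_hz * t + psi0 - lag_t[c])
      }
      if (signal$drift_amp_mv > 0) {
        x <- x + signal$drift_amp_mv * sin(2 * pi * 0.01 * t + xi[c])
      }
      if (signal$noise_sd_mv > 0) {
        x <- x + stats::rnorm(n, 0, signal$noise_sd_mv)
      }
      if (c %in% art_ch) {
        hours <- duration_s / 3600
        # movement transients: raised-cosine bumps added to the signal
        n_mov[c] <- stats::rpois(1, artifacts$movement_rate_per_hour * hours)
        for (i in seq_len(n_mov[c])) {
          dur <- stats::runif(1, artifacts$movement_dur_s[1], artifacts$movement_dur_s[2])
          amp <- stats::runif(1, artifacts$movement_amp_mv[1], artifacts$movement_amp_mv[2]) *
            sample(c(-1, 1), 1)
          len <- max(3L, round(dur * fs))
          start <- sample.int(max(1L, n - len), 1)
          idx <- start:(start + len - 1L)
          x[idx] <- x[idx] + amp * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = len)))
        }
        # saturation: amplifier clips to exactly the rail for the episode
        n_sat[c] <- stats::rpois(1, artifacts$saturation_rate_per_hour * hours)
        for (i in seq_len(n_sat[c])) {
          dur <- stats::runif(1, artifacts$saturation_dur_s[1], artifacts$saturation_dur_s[2])
          len <- max(1L, round(dur * fs))
          start <- sample.int(max(1L, n - len), 1)
          x[start:(start + len - 1L)] <- AMP_RAIL_MV * sample(c(-1, 1), 1)
        }
      }
      data[, c] <- pmin(pmax(x, -AMP_RAIL_MV), AMP_RAIL_MV)
    }
    structure(list(subject_id = subject_id, condition = condition,
                   sample_rate_hz = fs,
                   channels = paste0("ch", seq_len(n_channels)),
                   data = data, duration_s = duration_s),
              class = "raw_recording",
              n_saturation = n_sat, n_movement = n_mov)
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s, %s: %d channels x %d samples @ %g Hz (%.0f s)\n",
              x$subject_id, x$condition, ncol(x$data), nrow(x$data),
              x$sample_rate_hz, x$duration_s))
  invisible(x)
}

#' Generate a full synthetic study
#'
#' One recording per subject x condition, each drawn from an independent
#' seeded stream of the master seed.
#'
#' @inheritParams generate_recording
#' @param subjects character vector of subject labels.
#' @param conditions character vector of conditions.
#' @return list of `raw_recording` objects.
#' @export
simulate_study <- function(subjects = paste0("F", 1:4),
                           conditions = c("baseline", "feeding"),
                           signal = signal_params(), artifacts = artifact_params(),
                           duration_s = 3600, sample_rate_hz = 2000, seed = 1L) {
  recs <- list()
  for (s in subjects) {
    for (cond in conditions) {
      recs[[paste(s, cond, sep = "_")]] <-
        generate_recording(s, cond, signal, artifacts, duration_s,
                           sample_rate_hz, seed = seed)
    }
  }
  recs
}

#' Write a recording to CSV (`time_s,ch1,...`)
#'
#' @param rec a `raw_recording` (or preprocessed recording).
#' @param path output file path.
#' @export
write_recording_csv <- function(rec, path) {
  if (is.null(rec$data) || nrow(rec$data) == 0L) {
    stop("refusing to write empty recording to ", path)
  }
  df <- data.table::as.data.table(rec$data)
  data.table::setnames(df, rec$channels)
  time_s <- seq(0, length.out = nrow(rec$data), by = 1 / rec$sample_rate_hz)
  df <- cbind(data.table::data.table(time_s = time_s), df)
  tryCatch(data.table::fwrite(df, path),
           error = function(e) stop("failed writing recording to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a recording CSV written by [write_recording_csv()]
#'
#' @param path CSV file with a `time_s` column and one column per channel.
#' @param subject_id,condition optional metadata to attach.
#' @return a `raw_recording`.
#' @export
read_recording_csv <- function(path, subject_id = NA_character_,
                               condition = c("baseline", "feeding")) {
  condition <- match.arg(condition)
  df <- tryCatch(data.table::fread(path),
                 error = function(e) stop("failed reading recording from ", path,
                                          ": ", conditionMessage(e)))
  if (!"time_s" %in% names(df) || nrow(df) < 2L) {
    stop("not a recording CSV (need a time_s column and >= 2 rows): ", path)
  }
  fs <- 1 / stats::median(diff(df$time_s))
  chans <- setdiff(names(df), "time_s")
  structure(list(subject_id = subject_id, condition = condition,
                 sample_rate_hz = round(fs, 6),
                 channels = chans,
                 data = as.matrix(df[, chans, with = FALSE]),
                 duration_s = nrow(df) / fs),
            class = "raw_recording")
}
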