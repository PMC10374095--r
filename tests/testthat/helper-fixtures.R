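# Shared fixture builders and independent oracles.  Everything is generated
# in code; no binary fixtures.

# Construct a labeled_window directly from a channels x samples matrix.
make_window <- function(data, label = 0L, subject = "S1", fs = 200,
                        index = 1L) {
  structure(list(subject_id = subject, label = as.integer(label),
                 channels = paste0("ch", seq_len(nrow(data))),
                 data = data, sample_rate_hz = fs, window_index = index),
            class = "labeled_window")
}

sine_window <- function(freq_hz, n = 12000L, fs = 200, n_channels = 1L,
                        amp = 1, label = 0L) {
  t <- seq(0, length.out = n, by = 1 / fs)
  make_window(matrix(rep(amp * sin(2 * pi * freq_hz * t), n_channels),
                     nrow = n_channels, byrow = TRUE), label = label, fs = fs)
}

# Promote a raw_recording (already at 200 Hz, artifact-free) to a
# clean_recording without running the preprocessing chain.
as_clean <- function(rec, retained = c("ch1", "ch2", "ch4")) {
  rec$retained_channels <- intersect(retained, rec$channels)
  rec$qc <- NULL
  class(rec) <- "clean_recording"
  rec
}

# Windows of a default synthetic study generated directly at 200 Hz with
# artifacts off; 3 retained channels, mirroring the study-wide exclusion of
# channel 3.
study_windows <- function(duration_s = 720, seed = 11,
                          signal = signal_params(),
                          retained = c("ch1", "ch2", "ch4")) {
  recs <- simulate_study(signal = signal,
                         artifacts = artifact_params(saturation_rate_per_hour = 0,
                                                     movement_rate_per_hour = 0),
                         duration_s = duration_s, sample_rate_hz = 200,
                         seed = seed)
  do.call(c, lapply(recs, function(r) segment(as_clean(r, retained))))
}

# O(n^2) pair-count AUC oracle: P(score_pos > score_neg) + 0.5 P(tie).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Plain rectangular periodogram oracle (independent of the Welch path).
periodogram <- function(x, fs) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2 / n
  nb <- n %/% 2 + 1
  list(freqs_hz = seq(0, nb - 1) * fs / n, power = sp[1:nb])
}

periodogram_peak <- function(x, fs) {
  p <- periodogram(x, fs)
  p$freqs_hz[which.max(p$power[-1]) + 1]  # skip DC
}

# Fraction of total variance within freq +/- half_width, by periodogram.
variance_fraction_near <- function(x, fs, freqs, half_width = 0.02) {
  p <- periodogram(x - mean(x), fs)
  keep <- Reduce(`|`, lapply(freqs, function(f)
    abs(p$freqs_hz - f) <= half_width))
  sum(p$power[-1][keep[-1]]) / sum(p$power[-1])
}

# Two well-separated Gaussian blobs in feature space.
blob_features <- function(n_per_class = 20, p = 2, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p, mean = sep), n_per_class))
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

# Feature matrix with exactly one informative column (class shift in SD
# units); the rest is pure noise.
one_informative_fm <- function(n_per_class = 30, p = 8, informative = 4,
                               shift = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  values <- matrix(rnorm(n * p), n)
  y <- rep(c(0L, 1L), each = n_per_class)
  values[y == 1L, informative] <- values[y == 1L, informative] + shift
  colnames(values) <- paste0("f", seq_len(p))
  structure(list(values = values, feature_names = colnames(values),
                 labels = y, subjects = rep("S1", n),
                 window_index = seq_len(n)),
            class = "feature_matrix")
}

random_feature_matrix <- function(n = 60, p = 6, seed = 1) {
  set.seed(seed)
  values <- matrix(rnorm(n * p), n)
  colnames(values) <- paste0("f", seq_len(p))
  structure(list(values = values, feature_names = colnames(values),
                 labels = rep_len(c(0L, 1L), n),
                 subjects = rep(paste0("S", 1:4), length.out = n,
                                each = ceiling(n / 4)),
                 window_index = seq_len(n)),
            class = "feature_matrix")
}

# Small CNN configuration and tone-vs-noise toy windows used across the
# network tests.
tiny_cfg <- function(dropout = 0, seed = 2) {
  cnn_config(in_channels = 2, block_channels = c(2L, 3L, 3L, 4L, 4L),
             block_kernel = 9L, dropout_rate = dropout, seed = seed)
}

tiny_windows <- function(n, len = 128L, seed = 1, fs = 200) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    label <- (i - 1L) %% 2L
    t <- seq_len(len) / fs
    base <- matrix(rnorm(2 * len, sd = 0.5), 2)
    if (label == 1L) base <- base + rbind(sin(2 * pi * 20 * t),
                                          sin(2 * pi * 20 * t))
    make_window(base, label = label, fs = fs, index = i)
  })
}

table1_path <- function() {
  system.file("extdata", "table1_channel_quality.csv", package = "slowwave")
}
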