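# Welch band-power featurization and sequential feature selection.
#
# Each 1-minute window yields one Welch PSD per retained channel
# (16384-point FFT), normalized per channel by its total power, then summed
# into 10 equal-width bands over 0.05-0.7 Hz: 3 channels x 10 bands = 30
# features per window.

#' Welch PSD of a labeled window
#'
#' @param window a `labeled_window` (channels x samples).
#' @param nfft FFT length (default 16384).
#' @param n_segments Welch segmentation (default 8 Hamming-tapered segments
#'   at 50% overlap, zero-padded to `nfft`); use 1 for a single segment.
#' @return object of class `psd_estimate`: `freqs_hz`, `power` (bins x
#'   channels), `nfft`, `normalized = FALSE`.
#' @export
welch_psd <- function(window, nfft = 16384L, n_segments = 8L) {
  X <- window$data
  pw <- vapply(seq_len(nrow(X)), function(c) {
    welch_psd_vector(X[c, ], window$sample_rate_hz, nfft = nfft,
                     n_segments = n_segments)$power
  }, numeric(nfft %/% 2L + 1L))
  structure(list(freqs_hz = seq(0, nfft %/% 2L) * window$sample_rate_hz / nfft,
                 power = pw, channels = window$channels, nfft = nfft,
                 normalized = FALSE),
            class = "psd_estimate")
}

#' Frequency-band specification
#'
#' @param low_hz,high_hz band-of-interest limits (defaults 0.05 and 0.7 Hz).
#' @param n_bands number of equal-width bands (default 10, width 0.065 Hz).
#' @return object of class `band_spec` with 11 monotone `edges`.
#' @export
band_spec <- function(low_hz = 0.05, high_hz = 0.7, n_bands = 10L) {
  stopifnot(low_hz > 0, low_hz < high_hz, n_bands >= 1L)
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 n_bands = as.integer(n_bands),
                 edges = seq(low_hz, high_hz, length.out = n_bands + 1L)),
            class = "band_spec")
}

#' Sum PSD bins into frequency bands
#'
#' Band `b` collects bins whose center lies in `[edge_b, edge_{b+1})` (last
#' band closed).  With `normalize = TRUE` each channel's PSD is first divided
#' by its total power, so the banded values are dimensionless power
#' fractions.
#'
#' @param psd a [welch_psd()] estimate.
#' @param bands a [band_spec()].
#' @param normalize divide each channel by its total power first.
#' @return matrix `channels x n_bands`.
#' @export
band_features <- function(psd, bands = band_spec(), normalize = TRUE) {
  P <- psd$power
  if (normalize) {
    tot <- colSums(P)
    tot[tot == 0] <- 1
    P <- sweep(P, 2, tot, "/")
  }
  e <- bands$edges
  out <- matrix(0, nrow = ncol(P), ncol = bands$n_bands,
                dimnames = list(psd$channels, paste0("band", seq_len(bands$n_bands))))
  for (b in seq_len(bands$n_bands)) {
    inb <- if (b < bands$n_bands) {
      psd$freqs_hz >= e[b] & psd$freqs_hz < e[b + 1]
    } else {
      psd$freqs_hz >= e[b] & psd$freqs_hz <= e[b + 1]
    }
    if (!any(inb)) stop("band ", b, " [", e[b], ", ", e[b + 1],
                        "] contains no PSD bins")
    out[, b] <- colSums(P[inb, , drop = FALSE])
  }
  out
}

#' Band-power feature matrix for a set of windows
#'
#' @param windows list of `labeled_window`s (all with the same channels).
#' @inheritParams welch_psd
#' @inheritParams band_features
#' @return object of class `feature_matrix`: `values` (n x p), unique
#'   `feature_names` (`ch<i>_band<j>`), `labels`, `subjects`,
#'   `window_index`, and `standardization` (NULL until standardized).
#' @export
featurize_windows <- function(windows, bands = band_spec(), nfft = 16384L,
                              n_segments = 8L, normalize = TRUE) {
  stopifnot(length(windows) > 0)
  feats <- lapply(windows, function(w) {
    f <- band_features(welch_psd(w, nfft = nfft, n_segments = n_segments),
                       bands, normalize = normalize)
    as.vector(t(f))
  })
  chans <- windows[[1]]$channels
  nm <- as.vector(vapply(chans, function(ch)
    paste0(ch, "_band", seq_len(bands$n_bands)), character(bands$n_bands)))
  values <- do.call(rbind, feats)
  colnames(values) <- nm
  structure(list(values = values, feature_names = nm,
                 labels = window_labels(windows),
                 subjects = window_subjects(windows),
                 window_index = vapply(windows, `[[`, integer(1), "window_index"),
                 bands = bands, standardization = NULL),
            class = "feature_matrix")
}

#' Fit a per-feature z-score standardizer on a training set
#'
#' Uses the n-1 (sample) SD convention.  Zero-variance features get SD 1
#' with a warning, so they standardize to all zeros.
#'
#' @param values numeric matrix (samples x features) or a `feature_matrix`.
#' @return list with `mean` and `sd` vectors.
#' @export
fit_standardizer <- function(values) {
  if (inherits(values, "feature_matrix")) values <- values$values
  mu <- colMeans(values)
  sd <- apply(values, 2, stats::sd)
  if (any(sd == 0 | !is.finite(sd))) {
    warning("zero-variance feature(s): ",
            paste(colnames(values)[sd == 0 | !is.finite(sd)], collapse = ", "),
            "; SD replaced by 1")
    sd[sd == 0 | !is.finite(sd)] <- 1
  }
  list(mean = mu, sd = sd)
}

#' Apply (or invert) a fitted standardizer
#'
#' @param stats_fit output of [fit_standardizer()] (training-fold statistics
#'   only; validation data must never contribute).
#' @param values matrix or `feature_matrix` to transform.
#' @param invert undo the transformation.
#' @return object of the same type as `values`.
#' @export
apply_standardizer <- function(stats_fit, values, invert = FALSE) {
  fm <- NULL
  if (inherits(values, "feature_matrix")) {
    fm <- values
    values <- values$values
  }
  out <- if (invert) {
    sweep(sweep(values, 2, stats_fit$sd, "*"), 2, stats_fit$mean, "+")
  } else {
    sweep(sweep(values, 2, stats_fit$mean, "-"), 2, stats_fit$sd, "/")
  }
  if (is.null(fm)) return(out)
  fm$values <- out
  fm$standardization <- if (invert) NULL else stats_fit
  fm
}

# Monte-Carlo-averaged k-fold misclassification rate of a feature subset.
# Also returns the cross-validated log-loss, used only to break exact ties
# in the misclassification objective (common on well-separated data, where
# many single features reach zero validation error).
subset_misclassification <- function(values, labels, subset, spec,
                                     k = 3L, n_mc = 100L, seed = 1L) {
  if (length(subset) == 0L) {
    return(list(err = 1 - max(table(labels)) / length(labels), logloss = Inf))
  }
  errs <- ll <- numeric(n_mc)
  eps <- 1e-12
  for (r in seq_len(n_mc)) {
    plan <- make_folds(labels, n_folds = k, seed = stable_seed(seed, paste0("mc", r)))
    wrong <- 0L
    nll <- 0
    for (f in seq_len(k)) {
      tr <- plan$assignments != f
      Xtr <- values[tr, subset, drop = FALSE]
      Xva <- values[!tr, subset, drop = FALSE]
      st <- suppressWarnings(fit_standardizer(Xtr))
      model <- tryCatch(
        train_classifier(spec, apply_standardizer(st, Xtr), labels[tr]),
        error = function(e) NULL)
      if (is.null(model)) {
        wrong <- wrong + sum(!tr)  # failed fit counts as all-wrong
        nll <- nll + sum(!tr) * -log(eps)
        next
      }
      sc <- predict_scores(model, apply_standardizer(st, Xva))
      yv <- labels[!tr] == 1L
      wrong <- wrong + sum((sc >= 0.5) != yv)
      nll <- nll - sum(log(pmax(ifelse(yv, sc, 1 - sc), eps)))
    }
    errs[r] <- wrong / length(labels)
    ll[r] <- nll / length(labels)
  }
  list(err = mean(errs), logloss = mean(ll))
}

#' Sequential (forward or backward) feature selection
#'
#' Greedy search minimizing the Monte-Carlo-averaged k-fold
#' misclassification rate: forward starts from the empty set and adds the
#' best feature; backward starts from the full set and removes the most
#' dispensable one.  The search stops at the first step that fails to
#' strictly improve the objective (tolerance 1e-6).
#'
#' @param features a `feature_matrix`.
#' @param spec a [classifier_spec()] trained inside the objective.
#' @param direction `"forward"` or `"backward"`.
#' @param k folds of the inner cross-validation (default 3).
#' @param n_mc Monte-Carlo repetitions of the inner CV (default 100).
#' @param seed RNG seed; the whole search is deterministic under it.
#' @param max_steps optional cap on the number of greedy moves.
#' @return object of class `selection_result` with the logical `selected`
#'   mask, `selection_frequency` (0/1 for a single run), and
#'   `objective_history`.
#' @export
sequential_select <- function(features, spec, direction = c("forward", "backward"),
                              k = 3L, n_mc = 100L, seed = 1L, max_steps = Inf) {
  direction <- match.arg(direction)
  if (n_mc < 1L) stop("n_mc must be >= 1")
  values <- features$values
  labels <- features$labels
  if (length(unique(labels)) < 2L) stop("need both classes for selection")
  p <- ncol(values)
  selected <- if (direction == "forward") logical(p) else rep(TRUE, p)
  obj <- subset_misclassification(values, labels, which(selected), spec,
                                  k, n_mc, seed)
  history <- obj$err
  step <- 0L
  tol <- 1e-6
  repeat {
    step <- step + 1L
    if (step > max_steps) break
    cand <- if (direction == "forward") which(!selected) else which(selected)
    if (length(cand) == 0L) break
    if (direction == "backward" && length(cand) == 1L) break
    res <- lapply(cand, function(j) {
      s <- selected
      s[j] <- !s[j]
      subset_misclassification(values, labels, which(s), spec, k, n_mc,
                               stable_seed(seed, paste0("step", step)))
    })
    errs <- vapply(res, `[[`, 0, "err")
    # candidates within tol of the best error tie; lowest log-loss wins
    tied <- which(errs <= min(errs) + tol)
    best <- tied[which.min(vapply(res[tied], `[[`, 0, "logloss"))]
    if (errs[best] < obj$err - tol) {
      selected[cand[best]] <- !selected[cand[best]]
      obj <- res[[best]]
      history <- c(history, obj$err)
    } else break
  }
  structure(list(direction = direction, selected = selected,
                 selection_frequency = as.numeric(selected),
                 objective_history = history,
                 feature_names = features$feature_names),
            class = "selection_result")
}

#' Selection-frequency map over repeated selection runs
#'
#' Repeats [sequential_select()] with derived seeds and reports, per feature,
#' the fraction of runs in which it was selected (the analogue of a
#' per-classifier feature-contribution map).
#'
#' @inheritParams sequential_select
#' @param n_repeats number of repeated runs.
#' @return `selection_result` whose `selection_frequency` is a fraction in
#'   [0, 1] per feature.
#' @export
selection_frequency_map <- function(features, spec, direction = "forward",
                                    k = 3L, n_mc = 10L, seed = 1L,
                                    n_repeats = 10L, max_steps = Inf) {
  masks <- vapply(seq_len(n_repeats), function(r) {
    sequential_select(features, spec, direction, k, n_mc,
                      seed = stable_seed(seed, paste0("rep", r)),
                      max_steps = max_steps)$selected
  }, logical(ncol(features$values)))
  structure(list(direction = direction,
                 selected = rowMeans(masks) >= 0.5,
                 selection_frequency = rowMeans(masks),
                 objective_history = numeric(0),
                 feature_names = features$feature_names),
            class = "selection_result")
}
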