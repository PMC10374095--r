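# Segmentation of cleaned recordings into labeled 1-minute windows and
# construction of stratified cross-validation fold plans.

#' Segment a cleaned recording into non-overlapping labeled windows
#'
#' The trailing remainder shorter than one window is discarded.  Only
#' channels that passed quality control are kept, and the label is inherited
#' from the recording condition (0 = baseline, 1 = feeding).
#'
#' @param rec a `clean_recording`.
#' @param window_s window length in seconds (default 60).
#' @param channels channel labels to keep; defaults to
#'   `rec$retained_channels`.
#' @return list of `labeled_window` objects, each with a `channels x samples`
#'   `data` matrix.
#' @export
segment <- function(rec, window_s = 60, channels = NULL) {
  if (is.null(channels)) channels <- rec$retained_channels
  stopifnot(all(channels %in% rec$channels))
  wlen <- round(window_s * rec$sample_rate_hz)
  n <- nrow(rec$data)
  k <- n %/% wlen
  if (k == 0L) {
    warning("recording shorter than one window (", n, " < ", wlen,
            " samples); returning no windows")
    return(list())
  }
  ci <- match(channels, rec$channels)
  label <- if (identical(rec$condition, "feeding")) 1L else 0L
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * wlen + 1L):(i * wlen)
    structure(list(subject_id = rec$subject_id, label = label,
                   channels = channels,
                   data = t(rec$data[idx, ci, drop = FALSE]),
                   sample_rate_hz = rec$sample_rate_hz,
                   window_index = i),
              class = "labeled_window")
  })
}

#' Segment every recording of a study
#'
#' @param cleans list of `clean_recording` objects.
#' @inheritParams segment
#' @param channels channel labels kept for every recording; defaults to the
#'   intersection of all recordings' retained channels, mirroring study-wide
#'   exclusion of any channel that fails QC in any recording.
#' @return single flat list of `labeled_window` objects.
#' @export
segment_study <- function(cleans, window_s = 60, channels = NULL) {
  if (is.null(channels)) {
    channels <- Reduce(intersect, lapply(cleans, `[[`, "retained_channels"))
  }
  if (length(channels) == 0L) stop("no channel passed QC in every recording")
  do.call(c, lapply(cleans, segment, window_s = window_s, channels = channels))
}

window_labels <- function(windows) {
  vapply(windows, `[[`, integer(1), "label")
}

window_subjects <- function(windows) {
  vapply(windows, `[[`, character(1), "subject_id")
}

#' Build a (stratified) cross-validation fold plan
#'
#' Stratified assignment shuffles each class independently and deals windows
#' round-robin, so per-fold class counts differ by at most one.  With
#' `group_by_subject = TRUE`, whole subjects are assigned to folds instead
#' (a leakage-controlled alternative; off by default to reproduce the
#' window-level protocol).
#'
#' @param windows list of `labeled_window`s, or an integer label vector.
#' @param n_folds number of folds (default 3).
#' @param seed RNG seed; identical seeds give identical plans.
#' @param stratified balance class counts across folds.
#' @param group_by_subject assign whole subjects to folds.
#' @param subjects subject labels (needed for grouping when `windows` is a
#'   label vector).
#' @return object of class `fold_plan` with integer `assignments`.
#' @export
make_folds <- function(windows, n_folds = 3L, seed = 1L, stratified = TRUE,
                       group_by_subject = FALSE, subjects = NULL) {
  labels <- if (is.list(windows)) window_labels(windows) else as.integer(windows)
  n <- length(labels)
  stopifnot(n_folds >= 2L)
  assignments <- integer(n)
  if (group_by_subject) {
    if (is.null(subjects) && is.list(windows)) subjects <- window_subjects(windows)
    if (is.null(subjects)) stop("subject labels required for group_by_subject")
    us <- unique(subjects)
    if (n_folds > length(us)) stop("more folds than subjects")
    with_seed(seed, {
      us <- sample(us)
      fold_of <- rep_len(seq_len(n_folds), length(us))
      assignments <- fold_of[match(subjects, us)]
    })
  } else if (stratified) {
    counts <- table(labels)
    if (n_folds > min(counts)) {
      stop("n_folds (", n_folds, ") exceeds the smallest class count (",
           min(counts), ")")
    }
    with_seed(seed, {
      for (cl in names(counts)) {
        ids <- sample(which(labels == as.integer(cl)))
        assignments[ids] <- rep_len(seq_len(n_folds), length(ids))
      }
    })
  } else {
    if (n_folds > n) stop("more folds than windows")
    with_seed(seed, {
      assignments <- rep_len(seq_len(n_folds), n)[sample.int(n)]
    })
  }
  structure(list(n_folds = as.integer(n_folds), assignments = assignments,
                 seed = seed, stratified = stratified,
                 group_by_subject = group_by_subject),
            class = "fold_plan")
}
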