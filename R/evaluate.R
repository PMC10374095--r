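# ROC/AUC computation, thresholded metrics and repeated stratified k-fold
# cross-validation over the shallow classifiers or the CNN.

#' ROC curve and trapezoidal AUC
#'
#' The curve is swept over all distinct score thresholds; tied scores
#' contribute with the midpoint convention, so the trapezoidal AUC equals
#' the pair statistic `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores numeric scores (higher = more feeding-like).
#' @param labels 0/1 labels.
#' @return object of class `roc_curve` with `thresholds`, `fpr`, `tpr`,
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes; got ", n_pos, " positives and ",
         n_neg, " negatives")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # collapse tied scores into single thresholds
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  last <- which(c(diff(grp) != 0, TRUE))
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[last]), fpr = fpr, tpr = tpr,
                 auc = auc),
            class = "roc_curve")
}

#' Accuracy, sensitivity and specificity at a fixed threshold
#'
#' Predicted feeding iff `score >= threshold` (boundary inclusive).
#' Sensitivity is the true-positive rate on the feeding class (label 1),
#' specificity the true-negative rate on baseline (label 0).  All metrics
#' are returned in percent.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold (default 0.5).
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent) and
#'   the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("metrics require both classes")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(accuracy = 100 * (tp + tn) / length(labels),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Pipeline specification for cross-validated evaluation
#'
#' @param kind a shallow classifier kind (see [classifier_spec()]), `"cnn"`,
#'   or `"stub_oracle"` (scores equal to the labels; for testing the
#'   evaluation machinery).
#' @param classifier a [classifier_spec()] for shallow kinds (defaults to
#'   `classifier_spec(kind)`).
#' @param selection optional [sequential_select()] arguments (list with
#'   `direction`, `n_mc`, `k`, `max_steps`) applied per training fold.
#' @param cnn a [cnn_config()] for `kind = "cnn"`.
#' @param train a [train_config()] for `kind = "cnn"`.
#' @return object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(kind, classifier = NULL, selection = NULL,
                          cnn = cnn_config(), train = train_config()) {
  stopifnot(kind %in% c(SHALLOW_KINDS, "cnn", "stub_oracle"))
  if (is.null(classifier) && kind %in% SHALLOW_KINDS) {
    classifier <- classifier_spec(kind)
  }
  structure(list(kind = kind, classifier = classifier, selection = selection,
                 cnn = cnn, train = train),
            class = "pipeline_spec")
}

# Train on the training folds and score the validation fold; returns scores
# plus an audit record of which sample ids each training-fold statistic was
# fitted on.
run_fold <- function(spec, data, tr_idx, va_idx) {
  audit <- list(train_ids = tr_idx, val_ids = va_idx)
  if (spec$kind == "stub_oracle") {
    labels <- if (inherits(data, "feature_matrix")) data$labels else window_labels(data)
    return(list(scores = as.numeric(labels[va_idx]), audit = audit))
  }
  if (spec$kind == "cnn") {
    res <- train_model(build_model(spec$cnn, ncol(data[[1]]$data)),
                       data[tr_idx], data[va_idx], spec$train)
    audit$fit_ids <- tr_idx
    audit$early_stop_ids <- va_idx  # held-out fold doubles as the early-stopping set
    return(list(scores = score_windows(res$model, data[va_idx]),
                audit = audit, history = res$history))
  }
  values <- data$values
  labels <- data$labels
  Xtr <- values[tr_idx, , drop = FALSE]
  st <- suppressWarnings(fit_standardizer(Xtr))
  audit$standardizer_ids <- tr_idx
  Xtr <- apply_standardizer(st, Xtr)
  Xva <- apply_standardizer(st, values[va_idx, , drop = FALSE])
  keep <- seq_len(ncol(values))
  if (!is.null(spec$selection)) {
    sub_fm <- structure(list(values = Xtr, labels = labels[tr_idx],
                             feature_names = colnames(values)),
                        class = "feature_matrix")
    sel <- do.call(sequential_select,
                   c(list(features = sub_fm, spec = spec$classifier),
                     spec$selection))
    keep <- which(sel$selected)
    if (length(keep) == 0L) keep <- seq_len(ncol(values))
    audit$selection_ids <- tr_idx
  }
  model <- train_classifier(spec$classifier, Xtr[, keep, drop = FALSE],
                            labels[tr_idx])
  audit$classifier_ids <- tr_idx
  list(scores = predict_scores(model, Xva[, keep, drop = FALSE]),
       audit = audit, selected = keep)
}

#' Repeated stratified k-fold cross-validation
#'
#' Each repeat draws a fresh seeded fold plan, runs a full train/score cycle
#' per fold, pools the validation scores of the repeat and computes
#' accuracy, sensitivity and specificity at the threshold.  Reported as
#' means and SDs across repeats, with a per-subject breakdown from all
#' pooled validation scores.  Failed repeats are recorded and excluded.
#'
#' @param data a `feature_matrix` (shallow kinds) or list of
#'   `labeled_window`s (`"cnn"`, `"stub_oracle"`).
#' @param spec a [pipeline_spec()].
#' @param n_repeats repeats of the k-fold cycle (default 10).
#' @param k folds (default 3).
#' @param seed master seed; repeat r uses a derived stream.
#' @param threshold decision threshold (default 0.5).
#' @return object of class `metric_report`.
#' @export
repeated_cv <- function(data, spec, n_repeats = 10L, k = 3L, seed = 1L,
                        threshold = 0.5) {
  labels <- if (inherits(data, "feature_matrix")) data$labels else window_labels(data)
  subjects <- if (inherits(data, "feature_matrix")) data$subjects else window_subjects(data)
  n <- length(labels)
  per_repeat <- list()
  pooled <- list()
  audits <- list()
  rocs <- list()
  failed <- 0L
  for (r in seq_len(n_repeats)) {
    res <- tryCatch({
      plan <- make_folds(labels, n_folds = k,
                         seed = stable_seed(seed, paste0("repeat", r)))
      scores <- numeric(n)
      for (f in seq_len(k)) {
        va <- which(plan$assignments == f)
        tr <- which(plan$assignments != f)
        fold <- run_fold(spec, data, tr, va)
        scores[va] <- fold$scores
        audits[[length(audits) + 1L]] <- fold$audit
      }
      scores
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      warning("repeat ", r, " failed and was excluded: ",
              conditionMessage(res))
      next
    }
    m <- threshold_metrics(res, labels, threshold)
    per_repeat[[length(per_repeat) + 1L]] <-
      data.frame(repeat_id = r, accuracy = m$accuracy,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 auc = roc_auc(res, labels)$auc)
    rocs[[length(rocs) + 1L]] <- roc_auc(res, labels)
    pooled[[length(pooled) + 1L]] <- data.frame(repeat_id = r,
                                                sample_id = seq_len(n),
                                                subject = subjects,
                                                label = labels, score = res)
  }
  if (length(per_repeat) == 0L) stop("all repeats failed")
  rep_df <- do.call(rbind, per_repeat)
  pooled_df <- do.call(rbind, pooled)
  per_subject <- do.call(rbind, lapply(split(pooled_df, pooled_df$subject),
    function(d) {
      # a subject may carry a single class (e.g. grouped folds); report NA
      # for the rate whose class is absent rather than failing
      pred <- as.integer(d$score >= threshold)
      pos <- d$label == 1L
      data.frame(subject = d$subject[1],
                 accuracy = 100 * mean(pred == d$label),
                 sensitivity = if (any(pos)) 100 * mean(pred[pos] == 1L) else NA_real_,
                 specificity = if (any(!pos)) 100 * mean(pred[!pos] == 0L) else NA_real_)
    }))
  structure(list(
    kind = spec$kind,
    n_repeats = n_repeats, n_completed = nrow(rep_df), n_failed = failed,
    threshold = threshold,
    per_repeat = rep_df,
    mean = colMeans(rep_df[, c("accuracy", "sensitivity", "specificity", "auc")]),
    sd = vapply(rep_df[, c("accuracy", "sensitivity", "specificity", "auc")],
                stats::sd, 0),
    per_subject = per_subject,
    scores = pooled_df,
    roc = rocs,
    audit = audits), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s: %d/%d repeats, threshold %.2f\n",
              x$kind, x$n_completed, x$n_repeats, x$threshold))
  cat(sprintf("  accuracy    %5.1f%% (SD %.1f)\n", x$mean["accuracy"], x$sd["accuracy"]))
  cat(sprintf("  sensitivity %5.1f%% (SD %.1f)\n", x$mean["sensitivity"], x$sd["sensitivity"]))
  cat(sprintf("  specificity %5.1f%% (SD %.1f)\n", x$mean["specificity"], x$sd["specificity"]))
  cat(sprintf("  AUC         %5.3f\n", x$mean["auc"]))
  invisible(x)
}

#' Write evaluation reports to CSV
#'
#' Emits one ROC-point CSV per classifier, a combined metric table
#' (classifier x metric, mean and SD), and optionally a selection-frequency
#' matrix.
#'
#' @param reports named list of `metric_report`s (name = classifier label).
#' @param out_dir output directory (created if missing).
#' @param selection optional named list of `selection_result`s.
#' @return invisibly, the paths written.
#' @export
render_reports <- function(reports, out_dir, selection = NULL) {
  if (length(reports) == 0L) stop("no evaluated pipeline to report")
  if (is.null(names(reports)) || any(names(reports) == "")) {
    stop("reports must be a named list")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  metrics <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(classifier = nm,
               metric = c("accuracy", "sensitivity", "specificity", "auc"),
               mean = unname(r$mean), sd = unname(r$sd))
  }))
  p <- file.path(out_dir, "metrics.csv")
  data.table::fwrite(metrics, p)
  paths <- c(paths, p)
  for (nm in names(reports)) {
    r <- reports[[nm]]
    roc <- r$roc[[1]]
    p <- file.path(out_dir, paste0("roc_", nm, ".csv"))
    data.table::fwrite(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                                  tpr = roc$tpr), p)
    paths <- c(paths, p)
    p <- file.path(out_dir, paste0("per_subject_", nm, ".csv"))
    data.table::fwrite(r$per_subject, p)
    paths <- c(paths, p)
  }
  if (!is.null(selection)) {
    freq <- do.call(rbind, lapply(names(selection), function(nm) {
      s <- selection[[nm]]
      d <- as.data.frame(t(s$selection_frequency))
      names(d) <- s$feature_names
      cbind(data.frame(classifier = nm, direction = s$direction), d)
    }))
    p <- file.path(out_dir, "selection_frequency.csv")
    data.table::fwrite(freq, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
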