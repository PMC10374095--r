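# ROC/AUC, thresholded metrics, repeated cross-validation and reports.

test_that("ROC handles perfect separation, nulls and matches the pair-count oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)

  set.seed(13)
  null_scores <- runif(2000)
  null_labels <- rep_len(c(0L, 1L), 2000)
  a <- roc_auc(null_scores, null_labels)$auc
  expect_gt(a, 0.45); expect_lt(a, 0.55)

  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(20:80, 1)
    scores <- round(runif(n), 2)  # coarse scores force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc,
                 pair_count_auc(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("threshold metrics use the inclusive boundary and exact confusion counts", {
  m <- threshold_metrics(c(0.9, 0.6, 0.4, 0.1), c(1, 1, 0, 0))
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(100, 100, 100))

  m2 <- threshold_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(c(m2$accuracy, m2$sensitivity, m2$specificity), c(50, 50, 50))

  m3 <- threshold_metrics(rep(0.5, 6), rep_len(c(1L, 0L), 6))
  expect_equal(m3$sensitivity, 100)  # score >= threshold predicts feeding
  expect_equal(m3$specificity, 0)

  # accuracy identity on pooled counts
  set.seed(2)
  sc <- runif(300); y <- rbinom(300, 1, 0.4)
  m4 <- threshold_metrics(sc, y)
  n_pos <- sum(y); n_neg <- sum(1 - y)
  expect_equal(m4$accuracy,
               (m4$sensitivity * n_pos + m4$specificity * n_neg) /
                 (n_pos + n_neg))
})

test_that("repeated CV with a stub oracle is perfect and runs k x repeats cycles", {
  fm <- random_feature_matrix(n = 48, seed = 5)
  rep <- repeated_cv(fm, pipeline_spec("stub_oracle"), n_repeats = 10, k = 3,
                     seed = 1)
  expect_equal(unname(rep$mean[c("accuracy", "sensitivity", "specificity")]),
               c(100, 100, 100))
  expect_equal(unname(rep$sd[c("accuracy", "sensitivity", "specificity")]),
               c(0, 0, 0))
  expect_length(rep$audit, 30L)  # 10 repeats x 3 folds
  expect_equal(nrow(rep$per_subject), 4L)
})

test_that("fold hygiene: no training-fold statistic ever sees validation samples", {
  fm <- random_feature_matrix(n = 48, seed = 6)
  rep <- repeated_cv(fm, pipeline_spec("lda"), n_repeats = 2, k = 3, seed = 2)
  for (a in rep$audit) {
    expect_length(intersect(a$train_ids, a$val_ids), 0L)
    for (nm in c("standardizer_ids", "classifier_ids", "selection_ids")) {
      if (!is.null(a[[nm]])) {
        expect_length(intersect(a[[nm]], a$val_ids), 0L)
      }
    }
  }
})

test_that("reports are reproducible and rendered to the expected CSVs", {
  fm <- random_feature_matrix(n = 36, seed = 7)
  r1 <- repeated_cv(fm, pipeline_spec("lda"), n_repeats = 2, k = 3, seed = 3)
  r2 <- repeated_cv(fm, pipeline_spec("lda"), n_repeats = 2, k = 3, seed = 3)
  expect_identical(r1$per_repeat, r2$per_repeat)

  d1 <- withr::local_tempdir()
  stub <- repeated_cv(fm, pipeline_spec("stub_oracle"), n_repeats = 2, seed = 1)
  paths <- render_reports(list(lda = r1, stub = stub), d1,
                          selection = list(lda = sequential_select(
                            one_informative_fm(seed = 1),
                            classifier_spec("lda"), "forward",
                            n_mc = 2, max_steps = 1)))
  expect_true(file.exists(file.path(d1, "metrics.csv")))
  expect_true(file.exists(file.path(d1, "roc_lda.csv")))
  expect_true(file.exists(file.path(d1, "roc_stub.csv")))
  expect_true(file.exists(file.path(d1, "selection_frequency.csv")))
  met <- read.csv(file.path(d1, "metrics.csv"))
  expect_setequal(unique(met$classifier), c("lda", "stub"))

  # byte-identical reports under the same master seed
  d2 <- withr::local_tempdir()
  render_reports(list(lda = r2), d2)
  expect_identical(readLines(file.path(d2, "roc_lda.csv")),
                   readLines(file.path(d1, "roc_lda.csv")))

  expect_error(render_reports(list(), d1), "no evaluated pipeline")
})

test_that("repeated CV integrates the CNN end to end at reduced scale", {
  ws <- tiny_windows(24, len = 128L, seed = 9)
  spec <- pipeline_spec("cnn",
                        cnn = cnn_config(in_channels = 2,
                                         block_channels = c(2L, 3L, 3L, 4L, 4L),
                                         block_kernel = 9L, dropout_rate = 0,
                                         seed = 1),
                        train = train_config(max_epochs = 5L, batch_size = 8L,
                                             patience = 4L, seed = 1))
  rep <- repeated_cv(ws, spec, n_repeats = 1, k = 3, seed = 4)
  expect_equal(rep$n_completed, 1L)
  expect_true(all(rep$scores$score > 0 & rep$scores$score < 1))
})
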