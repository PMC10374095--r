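# Residual CNN: architecture shapes, parameter count, training mechanics,
# early stopping and inference determinism.

test_that("shape theorem: feature length is ceil(input_len / 32), 375 at 12000", {
  m <- build_model(cnn_config(), 12000L)
  expect_equal(m$lens, c(12000L, 6000L, 3000L, 1500L, 750L, 375L))
  expect_equal(m$feature_len, 375L)
  for (L in c(32L, 33L, 100L, 1001L, 4096L)) {
    expect_equal(build_model(tiny_cfg(), L)$feature_len,
                 as.integer(ceiling(L / 32)))
  }
  expect_error(build_model(cnn_config(), 31L), ">= 32")
})

test_that("parameter count of the default architecture is frozen", {
  expect_equal(count_parameters(build_model(cnn_config(), 12000L)), 750054L)
})

test_that("untrained forward pass yields sigmoid-range scores, deterministically", {
  m <- build_model(tiny_cfg(), 256L)
  set.seed(5)
  w <- make_window(matrix(rnorm(2 * 256), 2))
  s1 <- score_windows(m, list(w, w))
  expect_true(all(s1 > 0 & s1 < 1))
  expect_equal(s1[1], s1[2])  # duplicate window, identical score
  # batch vs one-at-a-time scoring
  ws <- tiny_windows(7, len = 256L, seed = 6)
  batch <- score_windows(m, ws)
  single <- vapply(ws, function(x) score_windows(m, list(x)), 0)
  expect_lt(max(abs(batch - single)), 1e-5)
})

test_that("shape and channel mismatches are rejected by name", {
  m <- build_model(tiny_cfg(), 128L)
  w3 <- make_window(matrix(0, 3, 128))
  expect_error(score_windows(m, list(w3)), "expects 2 channels")
  wlong <- make_window(matrix(0, 2, 130))
  expect_error(score_windows(m, list(wlong)), "length mismatch")
})

test_that("one AdamW step decreases the loss on a toy batch (5 seeds)", {
  for (seed in 1:5) {
    m <- build_model(tiny_cfg(seed = seed), 128L)
    ws <- tiny_windows(6, len = 128L, seed = seed)
    X <- slowwave:::windows_to_batch(ws)
    y <- vapply(ws, `[[`, 0L, "label")
    fwd <- slowwave:::cnn_forward(m, X, 6L, training = TRUE)
    m <- fwd$model
    l0 <- slowwave:::bce_loss(fwd$scores, y)
    gr <- slowwave:::cnn_backward(m, fwd, (fwd$scores - y) / 6, 6L)
    st <- slowwave:::adamw_init(m$params)
    up <- slowwave:::adamw_step(m$params, gr, st, 1e-3, 0.01)
    m$params <- up$params
    l1 <- slowwave:::bce_loss(
      slowwave:::cnn_forward(m, X, 6L, training = TRUE)$scores, y)
    expect_lt(l1, l0)
  }
})

test_that("a 4-window toy set is memorized within 200 epochs", {
  ws <- tiny_windows(4, len = 250L, seed = 3)
  m <- build_model(cnn_config(in_channels = 2, dropout_rate = 0, seed = 3),
                   250L)
  res <- train_model(m, ws, ws,
                     train_config(max_epochs = 200L, batch_size = 4L,
                                  patience = 199L, seed = 3))
  expect_lt(min(res$history$train_loss), 0.1)
})

test_that("early stopping schedule arithmetic matches the contract", {
  improving <- seq(1, 0.01, length.out = 250)
  r <- early_stop_schedule(improving, patience = 50, max_epochs = 200)
  expect_equal(r$n_epochs, 200L)
  expect_false(r$stopped_early)
  expect_equal(r$best_epoch, 200L)

  flat <- rep(1, 300)
  r2 <- early_stop_schedule(flat, patience = 50, max_epochs = 200)
  expect_equal(r2$best_epoch, 1L)
  expect_equal(r2$n_epochs, 51L)  # halts at best_epoch + patience
  expect_true(r2$stopped_early)

  set.seed(8)
  trace <- cumsum(rnorm(180))
  r3 <- early_stop_schedule(trace, patience = 20, max_epochs = 200)
  expect_lte(r3$n_epochs, min(200L, r3$best_epoch + 20L))
  expect_equal(trace[r3$best_epoch], min(trace[seq_len(r3$n_epochs)]))
})

test_that("training returns the minimum-validation-loss checkpoint", {
  ws <- tiny_windows(12, len = 128L, seed = 4)
  m <- build_model(tiny_cfg(seed = 4), 128L)
  tc <- train_config(max_epochs = 12L, batch_size = 4L, patience = 5L,
                     seed = 4)
  res <- train_model(m, ws[1:8], ws[9:12], tc)
  h <- res$history
  expect_lte(length(h$val_loss), 12L)
  expect_lte(length(h$val_loss), h$best_epoch + 5L)
  expect_equal(h$val_loss[h$best_epoch], min(h$val_loss))
  # returned model reproduces the best validation loss
  sc <- score_windows(res$model, ws[9:12])
  y <- vapply(ws[9:12], `[[`, 0L, "label")
  expect_equal(slowwave:::bce_loss(sc, y), min(h$val_loss), tolerance = 1e-10)
})

test_that("non-finite loss aborts with history attached", {
  ws <- tiny_windows(4, len = 128L, seed = 5)
  ws[[1]]$data[1, 1] <- NaN
  m <- build_model(tiny_cfg(seed = 5), 128L)
  err <- tryCatch(
    train_model(m, ws, ws, train_config(max_epochs = 5L, batch_size = 4L,
                                        patience = 2L, seed = 5)),
    slowwave_nan_loss = function(e) e)
  expect_s3_class(err, "slowwave_nan_loss")
  expect_true(is.list(err$history))
})

test_that("training rejects single-class or empty validation inputs", {
  ws <- tiny_windows(4, len = 128L, seed = 6)
  ones <- Filter(function(w) w$label == 1L, ws)
  m <- build_model(tiny_cfg(), 128L)
  expect_error(train_model(m, ones, ws, train_config(max_epochs = 2L,
                                                     patience = 1L)),
               "single class")
  expect_error(train_model(m, ws, list(), train_config(max_epochs = 2L,
                                                       patience = 1L)),
               "empty")
})
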