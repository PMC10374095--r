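# Shallow classifiers over hand-crafted band-power features.  All models
# expose posterior-style scores in [0, 1] with 1 = feeding.
#
# The environment provides no SVM or random-forest binding, so the C-SVM is
# solved exactly as its dual quadratic program (quadprog) with Platt scaling
# of the margins, and the random forest is bagged CART (gini impurity,
# sqrt-p feature subsampling) implemented here.

SHALLOW_KINDS <- c("svm_linear", "svm_rbf", "lda", "qda", "logistic",
                   "random_forest")

#' Specification of a shallow classifier
#'
#' @param kind one of `"svm_linear"`, `"svm_rbf"`, `"lda"`, `"qda"`,
#'   `"logistic"`, `"random_forest"`.
#' @param cost soft-margin cost C of the SVM (default 1).
#' @param gamma RBF kernel coefficient `exp(-gamma * d^2)`; `NULL` uses the
#'   median-distance heuristic on the training set.
#' @param n_trees,mtry,min_node random-forest size, features tried per split
#'   (default `floor(sqrt(p))`), and minimum splittable node size.
#' @param seed RNG seed (used by the random forest).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = SHALLOW_KINDS, cost = 1, gamma = NULL,
                            n_trees = 100L, mtry = NULL, min_node = 2L,
                            seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(cost > 0, n_trees >= 1L, min_node >= 1L)
  structure(list(kind = kind, cost = cost, gamma = gamma, n_trees = n_trees,
                 mtry = mtry, min_node = min_node, seed = seed),
            class = "classifier_spec")
}

# ---- SVM (dual QP) ---------------------------------------------------------

kernel_matrix <- function(X, Y, kind, gamma) {
  if (kind == "svm_linear") return(X %*% t(Y))
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  exp(-gamma * pmax(d2, 0))
}

svm_fit <- function(X, y01, spec) {
  y <- ifelse(y01 == 1L, 1, -1)
  n <- nrow(X)
  gamma <- spec$gamma
  if (spec$kind == "svm_rbf" && is.null(gamma)) {
    d <- stats::dist(X)
    med <- stats::median(d[d > 0])
    if (!is.finite(med) || med == 0) med <- 1
    gamma <- 1 / (2 * med^2)
  }
  K <- kernel_matrix(X, X, spec$kind, gamma)
  Dmat <- (y %*% t(y)) * K
  Dmat <- Dmat + diag(1e-8 * max(diag(Dmat), 1), n)
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-spec$cost, n))
  sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), spec$cost)
  sv <- alpha > 1e-6 * spec$cost
  coef <- alpha * y
  f0 <- as.vector(K %*% coef)
  margin_sv <- sv & alpha < spec$cost * (1 - 1e-6)
  b <- if (any(margin_sv)) mean(y[margin_sv] - f0[margin_sv]) else {
    -(max(f0[y == -1]) + min(f0[y == 1])) / 2
  }
  list(sv_x = X[sv, , drop = FALSE], sv_coef = coef[sv], b = b, gamma = gamma)
}

svm_margin <- function(fit, X, kind) {
  as.vector(kernel_matrix(X, fit$sv_x, kind, fit$gamma) %*% fit$sv_coef) + fit$b
}

# ---- CART / random forest --------------------------------------------------

best_split <- function(X, y, feat_idx, min_node) {
  n <- length(y)
  best <- list(gain = 0)
  pos <- sum(y)
  gini_parent <- 1 - (pos / n)^2 - ((n - pos) / n)^2
  for (j in feat_idx) {
    o <- order(X[, j])
    xs <- X[o, j]
    ys <- y[o]
    cum_pos <- cumsum(ys)
    i <- seq_len(n - 1)
    valid <- xs[i] < xs[i + 1]
    if (!any(valid)) next
    nl <- i
    nr <- n - i
    pl <- cum_pos[i] / nl
    pr <- (pos - cum_pos[i]) / nr
    gini <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / n
    gain <- gini_parent - gini
    gain[!valid] <- -Inf
    bi <- which.max(gain)
    if (gain[bi] > best$gain + 1e-12) {
      best <- list(gain = gain[bi], feature = j,
                   value = (xs[bi] + xs[bi + 1]) / 2)
    }
  }
  if (is.null(best$feature)) NULL else best
}

grow_tree <- function(X, y, mtry, min_node) {
  n <- length(y)
  prob <- mean(y)
  if (n < min_node || prob == 0 || prob == 1) {
    return(list(leaf = TRUE, prob = prob))
  }
  feat_idx <- sample.int(ncol(X), min(mtry, ncol(X)))
  sp <- best_split(X, y, feat_idx, min_node)
  if (is.null(sp)) return(list(leaf = TRUE, prob = prob))
  left <- X[, sp$feature] <= sp$value
  if (!any(left) || all(left)) return(list(leaf = TRUE, prob = prob))
  list(leaf = FALSE, feature = sp$feature, value = sp$value,
       left = grow_tree(X[left, , drop = FALSE], y[left], mtry, min_node),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], mtry, min_node))
}

predict_tree <- function(tree, x) {
  while (!tree$leaf) {
    tree <- if (x[tree$feature] <= tree$value) tree$left else tree$right
  }
  tree$prob
}

rf_fit <- function(X, y01, spec) {
  mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(ncol(X)))) else spec$mtry
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_trees), function(i) {
      idx <- sample.int(nrow(X), replace = TRUE)
      grow_tree(X[idx, , drop = FALSE], y01[idx], mtry, spec$min_node)
    })
  })
}

rf_score <- function(trees, X) {
  sapply(seq_len(nrow(X)), function(i) {
    mean(vapply(trees, predict_tree, 0, X[i, ]))
  })
}

# ---- Posterior calibration -------------------------------------------------

#' Fit a monotone posterior map (Platt scaling) on raw margin scores
#'
#' Fits a logistic sigmoid of the margin on the training fold only; applied
#' unchanged to validation margins.  Because the map is strictly monotone,
#' score ranks -- and therefore ROC curves and AUC -- are preserved.
#'
#' @param margins real-valued training scores.
#' @param labels 0/1 training labels.
#' @return object of class `posterior_map`; use [apply_posterior()].
#' @export
score_to_posterior <- function(margins, labels) {
  if (stats::sd(margins) == 0 || !is.finite(stats::sd(margins))) {
    warning("degenerate (all-equal) margins; using a constant 0.5 map")
    return(structure(list(a = 0, b = 0), class = "posterior_map"))
  }
  # Platt's regularized targets keep the slope finite under perfect
  # separation, so outputs stay strictly inside (0, 1)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  targets <- ifelse(labels == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, margins), targets, family = stats::binomial()))
  a <- fit$coefficients[2]
  b <- fit$coefficients[1]
  if (!is.finite(a) || a <= 0) {
    # fall back to a unit-slope sigmoid centered on the margin midpoint;
    # keeps monotonicity when glm degenerates under perfect separation
    a <- 1
    b <- -mean(range(margins))
  }
  structure(list(a = unname(a), b = unname(b)), class = "posterior_map")
}

#' @rdname score_to_posterior
#' @param map a `posterior_map`.
#' @export
apply_posterior <- function(map, margins) {
  stats::plogis(map$a * margins + map$b)
}

# ---- Unified training interface -------------------------------------------

#' Train a shallow classifier
#'
#' @param spec a [classifier_spec()].
#' @param X numeric feature matrix (samples x features), already
#'   standardized with training-fold statistics.
#' @param y integer 0/1 labels (1 = feeding).
#' @return object of class `shallow_model`; score with [predict_scores()].
#' @export
train_classifier <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class; need both 0 and 1")
  }
  fit <- switch(spec$kind,
    svm_linear = ,
    svm_rbf = {
      f <- svm_fit(X, y, spec)
      f$posterior <- score_to_posterior(svm_margin(f, X, spec$kind), y)
      f
    },
    lda = MASS::lda(X, grouping = factor(y, levels = c(0, 1))),
    qda = tryCatch(MASS::qda(X, grouping = factor(y, levels = c(0, 1))),
                   error = function(e) {
                     stop("QDA failed (likely singular within-class covariance): ",
                          conditionMessage(e), call. = FALSE)
                   }),
    logistic = suppressWarnings(
      stats::glm.fit(cbind(1, X), y, family = stats::binomial())$coefficients),
    random_forest = rf_fit(X, y, spec))
  structure(list(kind = spec$kind, fit = fit, p = ncol(X)),
            class = "shallow_model")
}

#' Posterior scores of a trained shallow model
#'
#' @param model a `shallow_model`.
#' @param X feature matrix standardized with the same training-fold
#'   statistics used at fit time.
#' @return numeric scores in [0, 1] (1 = feeding).
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$p) {
    stop("feature count mismatch: model expects ", model$p, ", got ", ncol(X))
  }
  switch(model$kind,
    svm_linear = ,
    svm_rbf = apply_posterior(model$fit$posterior,
                              svm_margin(model$fit, X, model$kind)),
    lda = unname(stats::predict(model$fit, X)$posterior[, "1"]),
    qda = unname(stats::predict(model$fit, X)$posterior[, "1"]),
    logistic = as.vector(stats::plogis(cbind(1, X) %*% model$fit)),
    random_forest = rf_score(model$fit, X))
}
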