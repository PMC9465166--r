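# The seven base learners and the voting meta-learner. The classic
# workbench algorithm line-up is implemented through functional analogues
# built on standard R fits: a Gaussian naive Bayes (e1071), a CART-style pruned tree
# (rpart) standing in for a C4.5 tree, plain k-nearest-neighbour (class),
# an entropic distance-weighted nearest-neighbour analogue of K-star,
# a random forest (randomForest), bagging over knn, and AdaBoost (SAMME)
# over pruned trees. Every learner exposes a class-probability output so
# the voting ensemble can average probabilities.

HS_LEARNERS <- c("naive_bayes", "decision_tree", "knn_entropic", "knn",
                 "random_forest", "bagging_knn", "adaboost_tree", "voting")

#' Specify a learner
#'
#' @param name One of `"naive_bayes"`, `"decision_tree"` (pruned CART;
#'   params `cp`, `minsplit`, `maxdepth`, or `confidence` which maps
#'   monotonically to `cp`), `"knn"` (param `k`), `"knn_entropic"`
#'   (distance-weighted nearest neighbour with an exponential kernel whose
#'   bandwidth is the `blend`-th percentile of training distances; param
#'   `blend` in (0, 100\]), `"random_forest"` (params `ntree`, `mtry`),
#'   `"bagging_knn"` (params `k`, `n_bags`), `"adaboost_tree"` (params
#'   `n_rounds`, `maxdepth`, `cp`) or `"voting"` (param `base`: list of
#'   base learner specs, default all seven).
#' @param params Named list of parameters, validated against the learner's
#'   schema.
#' @return A list of class `learner_spec`.
#' @export
learner_spec <- function(name, params = list()) {
  name <- match.arg(name, HS_LEARNERS)
  defaults <- switch(name,
    naive_bayes = list(laplace = 0),
    decision_tree = list(cp = 0.01, minsplit = 10, maxdepth = 30,
                         confidence = NULL),
    knn = list(k = 5),
    knn_entropic = list(blend = 20),
    random_forest = list(ntree = 500, mtry = NULL),
    bagging_knn = list(k = 1, n_bags = 10),
    adaboost_tree = list(n_rounds = 20, maxdepth = 3, cp = 0.01,
                         confidence = NULL),
    voting = list(base = NULL)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    hs_config_error("unknown parameter(s) for %s: %s", name,
                    paste(unknown, collapse = ", "))
  }
  params <- utils::modifyList(defaults, params)
  if (!is.null(params$confidence)) {
    # pruning-confidence analogue: lower confidence = heavier pruning
    if (params$confidence <= 0 || params$confidence > 0.5) {
      hs_config_error("confidence must be in (0, 0.5]")
    }
    params$cp <- (0.5 - params$confidence) * 0.1 + 1e-4
  }
  if (name %in% c("knn", "bagging_knn") &&
      (params$k < 1 || params$k != round(params$k))) {
    hs_config_error("k must be a positive integer")
  }
  if (name == "knn_entropic" && (params$blend <= 0 || params$blend > 100)) {
    hs_config_error("blend must be in (0, 100]")
  }
  structure(list(name = name, params = params), class = "learner_spec")
}

#' Fit a learner
#'
#' @param spec A [learner_spec()].
#' @param x Numeric feature matrix (or descriptor matrix; the `id` column is
#'   dropped).
#' @param y Binary labels (`active`/`inactive`, logical, or 0/1).
#' @return A fitted model of class `hs_model`.
#' @export
fit_learner <- function(spec, x, y) {
  stopifnot(inherits(spec, "learner_spec"))
  x <- as_feature_matrix(x)
  y <- factor(ifelse(as_active(y), "active", "inactive"),
              levels = c("active", "inactive"))
  if (nlevels(droplevels(y)) < 2) hs_data_error("y must contain both classes")
  p <- spec$params
  fit <- switch(spec$name,
    naive_bayes = e1071::naiveBayes(as.data.frame(x), y, laplace = p$laplace),
    decision_tree = fit_tree(x, y, cp = p$cp, minsplit = p$minsplit,
                             maxdepth = p$maxdepth),
    knn = list(x = x, y = y, k = p$k),
    knn_entropic = fit_kstar(x, y, blend = p$blend),
    random_forest = randomForest::randomForest(
      x, y, ntree = p$ntree,
      mtry = if (is.null(p$mtry)) max(1, floor(sqrt(ncol(x)))) else p$mtry),
    bagging_knn = fit_bagging_knn(x, y, k = p$k, n_bags = p$n_bags),
    adaboost_tree = fit_adaboost(x, y, n_rounds = p$n_rounds,
                                 maxdepth = p$maxdepth, cp = p$cp),
    voting = {
      base <- p$base %||% lapply(setdiff(HS_LEARNERS, "voting"), learner_spec)
      if (length(base) < 2) hs_config_error("voting needs >= 2 base learners")
      lapply(base, fit_learner, x = x, y = y)
    }
  )
  structure(list(spec = spec, fit = fit, features = colnames(x)),
            class = "hs_model")
}

as_feature_matrix <- function(x) {
  if (inherits(x, "descriptor_matrix") ||
      (is.data.frame(x) && "id" %in% names(x))) {
    x <- tibble::as_tibble(x)[setdiff(names(x), "id")]
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

#' Predict active-class probabilities
#'
#' @param model An `hs_model` from [fit_learner()].
#' @param x Feature matrix with the training columns.
#' @return Numeric vector of active-class probabilities in \[0, 1\].
#' @export
predict_active_prob <- function(model, x) {
  stopifnot(inherits(model, "hs_model"))
  x <- as_feature_matrix(x)[, model$features, drop = FALSE]
  f <- model$fit
  switch(model$spec$name,
    naive_bayes = as.numeric(predict(f, as.data.frame(x), type = "raw")[, "active"]),
    decision_tree = as.numeric(predict(f, as.data.frame(x), type = "prob")[, "active"]),
    knn = predict_knn(f, x),
    knn_entropic = predict_kstar(f, x),
    random_forest = as.numeric(predict(f, x, type = "prob")[, "active"]),
    bagging_knn = predict_bagging_knn(f, x),
    adaboost_tree = predict_adaboost(f, x),
    voting = voting_predict(f, x)
  )
}

#' Voting: average the base models' probabilities
#'
#' The voting score of a sample is the unweighted mean of the base models'
#' active-class probabilities; the predicted label is active when the score
#' is at least 0.5 (the boundary counts as active).
#'
#' @param base_models List of at least two fitted `hs_model` objects (a
#'   plain function `x -> probability vector` is also accepted, e.g. for a
#'   calibrated external scorer).
#' @param x Feature matrix.
#' @return Numeric vector of voting scores.
#' @export
voting_predict <- function(base_models, x) {
  if (length(base_models) < 2) {
    hs_config_error("voting requires at least 2 fitted base models")
  }
  probs <- vapply(base_models, function(m) {
    if (is.function(m)) m(as_feature_matrix(x)) else predict_active_prob(m, x)
  }, numeric(nrow(as_feature_matrix(x))))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

# --- learner internals -----------------------------------------------------

fit_tree <- function(x, y, cp, minsplit, maxdepth) {
  df <- data.frame(.y = y, as.data.frame(x))
  rpart::rpart(.y ~ ., data = df, method = "class",
               control = rpart::rpart.control(cp = cp, minsplit = minsplit,
                                              maxdepth = maxdepth, xval = 0))
}

predict_knn <- function(f, x) {
  pred <- class::knn(f$x, x, f$y, k = f$k, prob = TRUE)
  pwin <- attr(pred, "prob")
  ifelse(pred == "active", pwin, 1 - pwin)
}

# Entropic distance-weighted nearest neighbour (K-star analogue): every
# training point votes with weight exp(-d / d0), where the bandwidth d0 is
# the blend-th percentile of the training pairwise distances. Documented as
# an analogue of the entropic-distance learner, not a clone.
fit_kstar <- function(x, y, blend) {
  d0 <- quantile(dist(x), probs = blend / 100, names = FALSE)
  list(x = x, y = y, d0 = max(d0, 1e-8))
}

predict_kstar <- function(f, x) {
  apply(x, 1, function(q) {
    d <- sqrt(colSums((t(f$x) - q)^2))
    w <- exp(-d / f$d0)
    sum(w[f$y == "active"]) / sum(w)
  })
}

fit_bagging_knn <- function(x, y, k, n_bags) {
  bags <- lapply(seq_len(n_bags), function(b) sample(nrow(x), replace = TRUE))
  list(x = x, y = y, k = k, bags = bags)
}

predict_bagging_knn <- function(f, x) {
  probs <- vapply(f$bags, function(idx) {
    predict_knn(list(x = f$x[idx, , drop = FALSE], y = f$y[idx], k = f$k), x)
  }, numeric(nrow(x)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

# AdaBoost (discrete SAMME, K = 2) over pruned CART trees.
fit_adaboost <- function(x, y, n_rounds, maxdepth, cp) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(.y = y, as.data.frame(x))
  stages <- list()
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          cp = cp, maxdepth = maxdepth, minsplit = 5, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y))
    if (err <= 1e-10) {
      stages[[t]] <- list(fit = fit, alpha = 10)
      break
    }
    if (err >= 0.5) break
    alpha <- log((1 - err) / err)
    stages[[t]] <- list(fit = fit, alpha = alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  if (length(stages) == 0) {
    stages <- list(list(fit = rpart::rpart(
      .y ~ ., data = df, method = "class",
      control = rpart::rpart.control(cp = cp, maxdepth = 1, xval = 0)),
      alpha = 1))
  }
  list(stages = stages)
}

predict_adaboost <- function(f, x) {
  df <- as.data.frame(x)
  num <- rep(0, nrow(df))
  den <- 0
  for (s in f$stages) {
    pred <- predict(s$fit, df, type = "class")
    num <- num + s$alpha * (pred == "active")
    den <- den + s$alpha
  }
  num / den
}

#' Stratified k-fold cross-validation of a learner
#'
#' Folds are stratified by class and drawn deterministically from `seed`.
#' Metrics are pooled across folds: one confusion matrix is accumulated
#' over all out-of-fold predictions (decision threshold 0.5, boundary
#' active), and the AUC is computed from the pooled out-of-fold scores.
#'
#' @param x Feature matrix or descriptor matrix.
#' @param y Binary labels.
#' @param spec A [learner_spec()].
#' @param k Number of folds (default 5); every class must have at least `k`
#'   members.
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   learner internals.
#' @return An object of class `hs_cv`: list with `metrics` (a
#'   [confusion_metrics()] row including AUC), `scores` (tibble of
#'   out-of-fold scores), `spec`, `k`, `seed`, `folds`.
#' @export
crossvalidate <- function(x, y, spec, k = 5, seed = 1) {
  x <- as_feature_matrix(x)
  pos <- as_active(y)
  if (k < 2) hs_config_error("k must be >= 2")
  if (all(pos) || !any(pos)) hs_data_error("y is constant; need both classes")
  if (min(sum(pos), sum(!pos)) < k) {
    hs_data_error("smallest class (%d) has fewer members than k = %d",
                  min(sum(pos), sum(!pos)), k)
  }
  set.seed(seed)
  folds <- integer(length(pos))
  for (cl in c(TRUE, FALSE)) {
    idx <- which(pos == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  scores <- rep(NA_real_, length(pos))
  for (f in seq_len(k)) {
    hold <- folds == f
    model <- fit_learner(spec, x[!hold, , drop = FALSE], pos[!hold])
    scores[hold] <- predict_active_prob(model, x[hold, , drop = FALSE])
  }
  pred_active <- scores >= 0.5
  metrics <- confusion_metrics(
    tp = sum(pred_active & pos), fn = sum(!pred_active & pos),
    tn = sum(!pred_active & !pos), fp = sum(pred_active & !pos),
    auc = auc_score(scores, pos)
  )
  structure(list(metrics = metrics,
                 scores = tibble::tibble(fold = folds, score = scores,
                                         active = pos),
                 spec = spec, k = k, seed = seed, folds = folds),
            class = "hs_cv")
}

#' @export
print.hs_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV of %s (seed %d)\n", x$k, x$spec$name, x$seed))
  print(x$metrics)
  invisible(x)
}

#' Grid search over learner parameters by cross-validated accuracy
#'
#' Evaluates every grid point with [crossvalidate()] and returns the spec
#' at the accuracy-maximizing point. Ties are broken toward simpler models
#' (fewer neighbours, fewer boosting rounds, shallower trees, heavier
#' pruning), then by grid order.
#'
#' @inheritParams crossvalidate
#' @param grid Named list of parameter vectors (crossed).
#' @return The winning [learner_spec()]; the full results table is attached
#'   as attribute `"search"`.
#' @export
parameter_search <- function(x, y, spec, grid, k = 5, seed = 1) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    hs_config_error("parameter grid is empty")
  }
  pts <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    sp <- learner_spec(spec$name, utils::modifyList(spec$params,
                                                    as.list(pts[i, , drop = FALSE])))
    acc[i] <- crossvalidate(x, y, sp, k = k, seed = seed)$metrics$acc
  }
  simplicity <- rep(0, nrow(pts))
  for (key in intersect(c("k", "n_rounds", "maxdepth"), names(pts))) {
    simplicity <- simplicity + rank(pts[[key]], ties.method = "min")
  }
  for (key in intersect(c("cp"), names(pts))) {
    simplicity <- simplicity + rank(-pts[[key]], ties.method = "min")
  }
  for (key in intersect(c("confidence"), names(pts))) {
    simplicity <- simplicity + rank(pts[[key]], ties.method = "min")
  }
  ord <- order(-acc, simplicity, seq_len(nrow(pts)))
  best <- ord[1]
  out <- learner_spec(spec$name, utils::modifyList(spec$params,
                                                   as.list(pts[best, , drop = FALSE])))
  attr(out, "search") <- dplyr::bind_cols(tibble::as_tibble(pts),
                                          tibble::tibble(acc = acc))
  out
}

#' Evaluate a fitted model on a held-out set
#'
#' @param model A fitted `hs_model`.
#' @param x Held-out features.
#' @param y Held-out labels.
#' @return A [confusion_metrics()] row including AUC.
#' @export
evaluate_model <- function(model, x, y) {
  pos <- as_active(y)
  scores <- predict_active_prob(model, x)
  pred <- scores >= 0.5
  confusion_metrics(sum(pred & pos), sum(!pred & pos),
                    sum(!pred & !pos), sum(pred & !pos),
                    auc = auc_score(scores, pos))
}
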