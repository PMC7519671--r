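# Base-learner contract for the ensemble: each learner is a list with
# `name`, `fit(X, y) -> model` and `predict(model, X) -> numeric`. X is the
# one-hot design matrix. All default learners are deterministic given the
# learner seed (tree ensembles fix their RNG internally).

new_learner <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "trp_learner")
}

lm_learner <- function() {
  new_learner(
    "linear",
    fit = function(X, y) {
      f <- stats::lm.fit(cbind(1, X), y)
      cf <- f$coefficients
      cf[is.na(cf)] <- 0            # one-hot blocks are collinear; pivoted QR
      cf
    },
    predict = function(m, X) drop(cbind(1, X) %*% m))
}

glmnet_learner <- function(name, alpha) {
  new_learner(
    name,
    fit = function(X, y) {
      foldid <- rep_len(1:5, length(y))   # deterministic fold assignment
      suppressWarnings(                   # small folds warn about grouped CV
        glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid))
    },
    predict = function(m, X) drop(stats::predict(m, X, s = "lambda.min")))
}

loglm_learner <- function() {
  new_learner(
    "log_linear",
    fit = function(X, y) {
      f <- stats::lm.fit(cbind(1, X), log(pmax(y, 1e-6)))
      cf <- f$coefficients
      cf[is.na(cf)] <- 0
      cf
    },
    predict = function(m, X) exp(drop(cbind(1, X) %*% m)))
}

rpart_learner <- function() {
  new_learner(
    "tree",
    fit = function(X, y) {
      d <- as.data.frame(X)
      names(d) <- make.names(colnames(X))
      d$.y <- y
      rpart::rpart(.y ~ ., d, method = "anova",
                   control = rpart::rpart.control(minsplit = 5, cp = 0.003,
                                                  xval = 0))
    },
    predict = function(m, X) {
      d <- as.data.frame(X)
      names(d) <- make.names(colnames(X))
      unname(stats::predict(m, d))
    })
}

rf_learner <- function(seed = 101, ntree = 300) {
  new_learner(
    "random_forest",
    fit = function(X, y) local_seed(seed,
      randomForest::randomForest(X, y, ntree = ntree)),
    predict = function(m, X) unname(stats::predict(m, X)))
}

ranger_learner <- function(seed = 103, num_trees = 300) {
  new_learner(
    "extra_trees",
    fit = function(X, y)
      ranger::ranger(x = X, y = y, num.trees = num_trees,
                     splitrule = "extratrees", seed = seed,
                     num.threads = 1),
    predict = function(m, X)
      stats::predict(m, data = X, num.threads = 1)$predictions)
}

xgb_learner <- function(seed = 102, nrounds = 150) {
  new_learner(
    "gradient_boosting",
    fit = function(X, y)
      xgboost::xgboost(X, y, nrounds = nrounds, max_depth = 4,
                       learning_rate = 0.1, nthreads = 1, seed = seed,
                       verbosity = 0),
    predict = function(m, X) stats::predict(m, X))
}

svm_learner <- function() {
  new_learner(
    "svm_rbf",
    fit = function(X, y) e1071::svm(X, y, kernel = "radial", cost = 10,
                                    scale = FALSE),
    predict = function(m, X) unname(stats::predict(m, X)))
}

knn_learner <- function(k = 5) {
  new_learner(
    "knn",
    fit = function(X, y) caret::knnreg(X, y, k = min(k, nrow(X))),
    predict = function(m, X) unname(stats::predict(m, as.data.frame(X))))
}

#' Default base-learner set for the ensemble
#'
#' Eight regressors spanning linear (on the rate and on the log-rate scale
#' -- promoter effects act multiplicatively on synthesis rates, so a
#' log-linear model is a natural member), regularized-linear, kernel,
#' tree-ensemble and nearest-neighbor families, each exposing the
#' `fit(X, y)` / `predict(model, X)` contract. All are deterministic given
#' `seed`.
#'
#' @param seed integer; fixes the internal RNG of the stochastic learners.
#' @return list of learner objects.
#' @export
default_learners <- function(seed = 100) {
  list(lm_learner(),
       loglm_learner(),
       glmnet_learner("ridge", alpha = 0),
       glmnet_learner("lasso", alpha = 1),
       rf_learner(seed = seed + 1),
       ranger_learner(seed = seed + 2),
       svm_learner(),
       knn_learner())
}

#' A learner that interpolates a known response function
#'
#' Ignores the training data and predicts `fun(X)`; used to plant a perfect
#' learner in simulation studies of the weight posterior.
#'
#' @param fun function of the one-hot matrix returning a numeric vector.
#' @param name learner name.
#' @return a learner object.
#' @export
oracle_learner <- function(fun, name = "oracle") {
  new_learner(name, fit = function(X, y) fun,
              predict = function(m, X) m(X))
}

#' A learner that predicts seeded pure noise
#' @param seed integer seed for the noise stream.
#' @param scale noise scale.
#' @return a learner object.
#' @export
noise_learner <- function(seed = 999, scale = 100) {
  new_learner("noise",
              fit = function(X, y) list(seed = seed, scale = scale, m = mean(y)),
              predict = function(m, X)
                m$m + local_seed(m$seed + nrow(X), stats::rnorm(nrow(X), 0, m$scale)))
}
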