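#' Bayesian stacked ensemble of genotype-to-rate regressors
#'
#' Fits the study's learn step: GFP synthesis rate (the tryptophan
#' productivity proxy, MFI/h) as a function of one-hot-encoded promoter
#' genotype, through a probabilistic ensemble of base regression learners.
#' Each base learner is fitted to the training data; the ensemble weights
#' are treated as a random variable on the simplex and inferred by MCMC
#' from the likelihood
#' \deqn{y_i ~ Normal(\sum_m w_m g_m(x_i), \sigma^2)}
#' where the \eqn{g_m(x_i)} are out-of-fold (stacked) base-learner
#' predictions, under a flat Dirichlet prior on \eqn{w} and a
#' weakly-informative half-normal prior on \eqn{\sigma}. Sampling is
#' random-walk Metropolis on stick-breaking-transformed weights.
#'
#' @param x genotypes: a data.frame with one promoter column per catalog
#'   gene, a character vector of genotype keys, or a model formula (see
#'   Details).
#' @param ... further arguments passed on between methods.
#' @return An object of class `trp_ensemble` with components including
#'   `learner_names`, fitted base `models`, posterior `weights` (draws x
#'   learners matrix), `sigma` draws, `accept` rates per chain, the stacked
#'   out-of-fold prediction matrix `oof`, training data and per-learner
#'   mean absolute errors. Methods: `print`, `summary`, `coef` (posterior
#'   mean weights), `predict` (predictive mean and sd per genotype),
#'   `fitted`, `residuals`, `simulate`, `plot`.
#' @seealso [predict.trp_ensemble], [cross_validate], [learning_curve],
#'   [recommend_designs]
#' @export
trp_ensemble <- function(x, ...) UseMethod("trp_ensemble")

#' @rdname trp_ensemble
#' @param formula a formula whose LHS names the rate column of `data`; the
#'   genotype columns are taken from the catalog's gene names.
#' @param data data.frame holding the rate column and one promoter column
#'   per gene.
#' @param catalog a [promoter_catalog].
#' @export
#' @method trp_ensemble formula
trp_ensemble.formula <- function(formula, data, catalog = default_catalog(),
                                 ...) {
  # LHS names the rate; the genotype block is identified by catalog gene names
  mf <- stats::model.frame(stats::update.formula(formula, . ~ 1), data)
  y <- stats::model.response(mf)
  genes <- catalog_genes(catalog)
  missing <- setdiff(genes, names(data))
  if (length(missing))
    stop("data lacks promoter columns: ", paste(missing, collapse = ", "))
  fit <- trp_ensemble.default(data[genes], y, catalog = catalog, ...)
  fit$call <- match.call()
  fit
}

#' @rdname trp_ensemble
#' @param y numeric response: per-genotype rate (MFI/h).
#' @param learners list of base learners (see [default_learners]).
#' @param mcmc an [mcmc_control] list.
#' @param oof_folds internal folds for the stacked out-of-fold predictions.
#' @param seed integer seed governing fold assignment and the MCMC chains.
#' @export
#' @method trp_ensemble default
trp_ensemble.default <- function(x, y, catalog = default_catalog(),
                                 learners = default_learners(),
                                 mcmc = mcmc_control(), oof_folds = 5,
                                 seed = 1, ...) {
  X <- if (is.matrix(x)) x else one_hot_encode(x, catalog)
  keys <- if (is.character(x)) x
          else if (is.data.frame(x)) genotype_key(x, catalog)
          else NULL
  n <- nrow(X)
  M0 <- length(learners)
  stopifnot(n == length(y), M0 >= 1)
  K <- min(oof_folds, n)
  folds <- local_seed(substream_seed(seed, "oof"),
                      sample(rep_len(seq_len(K), n)))
  fit_one <- function(lrn) {
    oof <- numeric(n)
    for (k in seq_len(K)) {
      tr <- folds != k
      m <- lrn$fit(X[tr, , drop = FALSE], y[tr])
      oof[!tr] <- lrn$predict(m, X[!tr, , drop = FALSE])
    }
    list(model = lrn$fit(X, y), oof = oof)
  }
  fits <- vector("list", M0)
  ok <- logical(M0)
  for (m in seq_len(M0)) {
    fits[[m]] <- tryCatch(fit_one(learners[[m]]), error = function(e) e)
    ok[m] <- !inherits(fits[[m]], "error")
    if (!ok[m]) warning("learner '", learners[[m]]$name, "' failed to fit (",
                        conditionMessage(fits[[m]]), "); excluded")
  }
  if (!any(ok)) stop("all base learners failed to fit")
  learners <- learners[ok]
  fits <- fits[ok]
  M <- length(learners)
  G <- vapply(fits, `[[`, numeric(n), "oof")
  G <- matrix(G, nrow = n)
  post <- sample_weight_posterior(G, y, mcmc, seed)
  models <- lapply(fits, `[[`, "model")
  P_train <- predict_learners(learners, models, X)
  obj <- structure(list(
    learners = learners, models = models,
    learner_names = vapply(learners, `[[`, character(1), "name"),
    weights = post$weights, sigma = post$sigma, accept = post$accept,
    oof = G, X = X, y = y, keys = keys, catalog = catalog,
    folds = folds, mcmc = mcmc, seed = seed,
    learner_mae = data.frame(
      learner = vapply(learners, `[[`, character(1), "name"),
      train_mae = colMeans(abs(P_train - y)),
      oof_mae = colMeans(abs(G - y))),
    call = match.call()), class = "trp_ensemble")
  obj$fitted <- predict_core(obj, P_train)
  obj
}

#' MCMC settings for the weight posterior
#'
#' @param chains number of independent chains.
#' @param draws iterations per chain (including burn-in).
#' @param burn burn-in iterations discarded per chain.
#' @param step_z random-walk step for the stick-breaking coordinates.
#' @param step_logsigma random-walk step for log sigma.
#' @return list of settings.
#' @export
mcmc_control <- function(chains = 4, draws = 5000, burn = 1000,
                         step_z = 0.25, step_logsigma = 0.15) {
  stopifnot(draws > burn, chains >= 1)
  list(chains = chains, draws = draws, burn = burn, step_z = step_z,
       step_logsigma = step_logsigma)
}

stick_break <- function(z) {
  v <- stats::plogis(z)
  M <- length(z) + 1
  w <- numeric(M)
  rem <- 1
  for (m in seq_len(M - 1)) { w[m] <- v[m] * rem; rem <- rem * (1 - v[m]) }
  w[M] <- rem
  w
}

# log |d(w_1..w_{M-1}) / d(z_1..z_{M-1})| for the logistic stick-breaking map
stick_jacobian <- function(z) {
  v <- stats::plogis(z)
  M1 <- length(z)
  sum(log(v) + log(1 - v)) + sum((M1 - seq_len(M1)) * log(1 - v))
}

sample_weight_posterior <- function(G, y, mcmc, seed) {
  n <- nrow(G); M <- ncol(G)
  sdy <- max(stats::sd(y), 1e-8)
  logpost <- function(z, ls) {
    w <- if (M == 1) 1 else stick_break(z)
    sig <- exp(ls)
    mu <- drop(G %*% w)
    sum(stats::dnorm(y, mu, sig, log = TRUE)) +
      (if (M == 1) 0 else stick_jacobian(z)) +
      stats::dnorm(sig, 0, 2 * sdy, log = TRUE) + ls   # half-normal prior, log-scale Jacobian
  }
  keep <- mcmc$draws - mcmc$burn
  W <- matrix(NA_real_, mcmc$chains * keep, M)
  S <- numeric(mcmc$chains * keep)
  accept <- numeric(mcmc$chains)
  nz <- M - 1
  for (ch in seq_len(mcmc$chains)) {
    local_seed(substream_seed(seed, paste0("mcmc_chain_", ch)), {
      z <- rep(0, nz)
      ls <- log(max(stats::sd(y - rowMeans(G)), 1e-6))
      lp <- logpost(z, ls)
      acc <- 0L
      row0 <- (ch - 1) * keep
      for (it in seq_len(mcmc$draws)) {
        z2 <- z + if (nz) stats::rnorm(nz, 0, mcmc$step_z) else numeric(0)
        ls2 <- ls + stats::rnorm(1, 0, mcmc$step_logsigma)
        lp2 <- logpost(z2, ls2)
        if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
          z <- z2; ls <- ls2; lp <- lp2; acc <- acc + 1L
        }
        if (it > mcmc$burn) {
          W[row0 + it - mcmc$burn, ] <- if (M == 1) 1 else stick_break(z)
          S[row0 + it - mcmc$burn] <- exp(ls)
        }
      }
      accept[ch] <- acc / mcmc$draws
    })
  }
  list(weights = W, sigma = S, accept = accept)
}

predict_learners <- function(learners, models, X) {
  P <- vapply(seq_along(learners),
              function(m) as.numeric(learners[[m]]$predict(models[[m]], X)),
              numeric(nrow(X)))
  matrix(P, nrow = nrow(X))
}

predict_core <- function(object, P) {
  wbar <- colMeans(object$weights)
  mu <- drop(P %*% wbar)
  Wc <- stats::cov(object$weights)
  var_model <- rowSums((P %*% Wc) * P)      # Var over weight draws of P w
  sig <- sqrt(pmax(var_model, 0) + mean(object$sigma^2))
  data.frame(mu = mu, sigma = sig)
}

#' Predictive mean and sd for genotypes
#'
#' The predictive mean is the posterior average of the weighted base-learner
#' prediction; the predictive variance adds the posterior variance of that
#' weighted prediction (model disagreement) to the posterior mean noise
#' variance.
#'
#' @param object a fitted [trp_ensemble].
#' @param newdata genotypes (data.frame, keys, or one-hot matrix); defaults
#'   to the training genotypes.
#' @param ... unused.
#' @return data.frame with columns `mu` and `sigma` (MFI/h); genotype keys
#'   as a `key` column when derivable.
#' @export
predict.trp_ensemble <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- if (is.matrix(newdata)) newdata else one_hot_encode(newdata, object$catalog)
  P <- predict_learners(object$learners, object$models, X)
  out <- predict_core(object, P)
  if (is.character(newdata)) out <- cbind(data.frame(key = newdata), out)
  else if (is.data.frame(newdata))
    out <- cbind(data.frame(key = genotype_key(newdata, object$catalog)), out)
  out
}

#' @export
print.trp_ensemble <- function(x, ...) {
  cat("Bayesian stacked ensemble:", length(x$learners), "base learners,",
      length(x$y), "training genotypes\n")
  w <- round(colMeans(x$weights), 3)
  names(w) <- x$learner_names
  cat("Posterior mean weights:\n")
  print(w)
  cat(sprintf("Posterior noise sd: %.2f MFI/h; mean MH acceptance %.2f\n",
              mean(x$sigma), mean(x$accept)))
  invisible(x)
}

#' @export
coef.trp_ensemble <- function(object, ...)
  stats::setNames(colMeans(object$weights), object$learner_names)

#' @export
fitted.trp_ensemble <- function(object, ...) object$fitted$mu

#' @export
residuals.trp_ensemble <- function(object, ...) object$y - object$fitted$mu

#' @export
summary.trp_ensemble <- function(object, ...) {
  w <- object$weights
  s <- data.frame(learner = object$learner_names,
                  weight_mean = colMeans(w),
                  weight_sd = apply(w, 2, stats::sd),
                  train_mae = object$learner_mae$train_mae,
                  oof_mae = object$learner_mae$oof_mae)
  structure(list(weights = s,
                 sigma_mean = mean(object$sigma),
                 sigma_sd = stats::sd(object$sigma),
                 accept = object$accept,
                 train_mae = mean(abs(residuals(object))),
                 n = length(object$y)),
            class = "summary.trp_ensemble")
}

#' @export
print.summary.trp_ensemble <- function(x, ...) {
  cat("Bayesian stacked ensemble (", x$n, " genotypes)\n", sep = "")
  print(x$weights, digits = 3, row.names = FALSE)
  cat(sprintf("noise sd: %.2f +/- %.2f MFI/h\n", x$sigma_mean, x$sigma_sd))
  cat(sprintf("ensemble train MAE: %.2f MFI/h\n", x$train_mae))
  cat("MH acceptance per chain:", paste(round(x$accept, 2), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.trp_ensemble <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::boxplot(x$weights, names = x$learner_names, las = 2,
                    ylab = "posterior weight", main = "Ensemble weights", ...)
  graphics::plot(x$y, fitted(x), xlab = "measured rate (MFI/h)",
                 ylab = "posterior predictive mean (MFI/h)",
                 main = "Training fit")
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.trp_ensemble <- function(object, nsim = 1, seed = NULL,
                                  newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X
       else if (is.matrix(newdata)) newdata
       else one_hot_encode(newdata, object$catalog)
  P <- predict_learners(object$learners, object$models, X)
  ndraw <- nrow(object$weights)
  sim_fun <- function() {
    s <- sample.int(ndraw, 1)
    drop(P %*% object$weights[s, ]) + stats::rnorm(nrow(P), 0, object$sigma[s])
  }
  run <- function() as.data.frame(replicate(nsim, sim_fun()))
  if (is.null(seed)) run() else local_seed(seed, run())
}

#' k-fold cross-validated prediction error
#'
#' Random (stratification-free) fold assignment from `seed`; the reported
#' MAE pools the held-out absolute errors of all folds.
#'
#' @param genotypes genotype data.frame or key vector.
#' @param rates numeric response (MFI/h).
#' @param catalog a [promoter_catalog].
#' @param k number of folds (k = n gives leave-one-out).
#' @param seed integer seed.
#' @param ... passed to [trp_ensemble] (learners, mcmc, ...).
#' @return list: `mae` (pooled test MAE, MFI/h), `fold_mae`, `predictions`
#'   (data.frame y, mu, sigma, fold).
#' @export
cross_validate <- function(genotypes, rates, catalog = default_catalog(),
                           k = 10, seed = 1, ...) {
  X <- if (is.matrix(genotypes)) genotypes else one_hot_encode(genotypes, catalog)
  n <- nrow(X)
  stopifnot(k >= 2, n >= k)
  folds <- local_seed(substream_seed(seed, "cv_folds"),
                      sample(rep_len(seq_len(k), n)))
  mu <- numeric(n); sg <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- trp_ensemble(X[tr, , drop = FALSE], rates[tr], catalog = catalog,
                        seed = substream_seed(seed, paste0("cv_fit_", f)), ...)
    pr <- predict(fit, X[!tr, , drop = FALSE])
    mu[!tr] <- pr$mu; sg[!tr] <- pr$sigma
  }
  err <- abs(mu - rates)
  list(mae = mean(err),
       fold_mae = as.numeric(tapply(err, folds, mean)),
       predictions = data.frame(y = rates, mu = mu, sigma = sg, fold = folds))
}

#' Learning curves: MAE as a function of training-set size
#'
#' For each size, `n_reps` random subsamples are drawn. The train MAE of a
#' subsample's fit is computed on the whole dataset; the test MAE is the
#' cross-validated MAE within the subsample. Confidence half-widths are
#' 1.96 sd / sqrt(n_reps).
#'
#' @inheritParams cross_validate
#' @param sizes integer vector of training-set sizes (each <= n).
#' @param n_reps random subsamples per size.
#' @param cv_folds folds for the within-subsample cross-validation.
#' @return data.frame: size, train_mae, train_ci, test_mae, test_ci.
#' @export
learning_curve <- function(genotypes, rates, catalog = default_catalog(),
                           sizes, n_reps = 10, cv_folds = 10, seed = 1, ...) {
  X <- if (is.matrix(genotypes)) genotypes else one_hot_encode(genotypes, catalog)
  n <- nrow(X)
  stopifnot(all(sizes <= n), all(sizes >= 2))
  rows <- lapply(sizes, function(s) {
    tr_mae <- te_mae <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      sub_seed <- substream_seed(seed, sprintf("lc_%d_%d", s, r))
      idx <- local_seed(sub_seed, sample.int(n, s))
      fit <- trp_ensemble(X[idx, , drop = FALSE], rates[idx],
                          catalog = catalog, seed = sub_seed, ...)
      tr_mae[r] <- mean(abs(predict(fit, X)$mu - rates))
      te_mae[r] <- cross_validate(X[idx, , drop = FALSE], rates[idx],
                                  catalog = catalog,
                                  k = min(cv_folds, s), seed = sub_seed,
                                  ...)$mae
    }
    data.frame(size = s,
               train_mae = mean(tr_mae),
               train_ci = 1.96 * stats::sd(tr_mae) / sqrt(n_reps),
               test_mae = mean(te_mae),
               test_ci = 1.96 * stats::sd(te_mae) / sqrt(n_reps))
  })
  do.call(rbind, rows)
}
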