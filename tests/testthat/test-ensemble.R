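# Shared small fixture: additive-ish ground truth over the default catalog.
fixture_data <- function(n = 80, cv = 0, seed = 42, interactions = 0) {
  cat0 <- default_catalog()
  tr <- make_ground_truth(cat0, seed = seed, interaction_sd = interactions)
  lib <- sample_training_set(tr, n_strains = n, n_reps = 3, cv = cv,
                             seed = seed + 1)
  y <- as.numeric(tapply(lib$replicates$rate, lib$replicates$strain,
                         mean)[lib$strains$strain])
  list(catalog = cat0, truth = tr, keys = lib$strains$key, y = y,
       strains = lib$strains)
}

fast_mcmc <- mcmc_control(chains = 2, draws = 1500, burn = 500)

test_that("weight posterior is a point mass with a single learner", {
  fx <- fixture_data(n = 40)
  fit <- trp_ensemble(fx$keys, fx$y, catalog = fx$catalog,
                      learners = list(default_learners()[[1]]),
                      mcmc = fast_mcmc, seed = 3)
  expect_true(all(fit$weights == 1))
  expect_true(all(fit$sigma > 0))
})

test_that("posterior weights live on the simplex and chains behave", {
  fx <- fixture_data(n = 60, cv = 0.043)
  fit <- trp_ensemble(fx$keys, fx$y, catalog = fx$catalog, mcmc = fast_mcmc,
                      seed = 4)
  expect_true(all(abs(rowSums(fit$weights) - 1) < 1e-9))
  expect_true(all(fit$weights >= 0))
  expect_true(all(fit$accept > 0.05) && all(fit$accept < 0.9))
  # ensemble training MAE no worse than the worst single learner
  expect_lte(mean(abs(residuals(fit))), max(fit$learner_mae$train_mae) + 1e-8)
})

test_that("the posterior concentrates on a planted perfect learner", {
  fx <- fixture_data(n = 120, cv = 0.043, interactions = 0.08)
  truth_fun <- function(X) true_rate(fx$truth, one_hot_decode(X, fx$catalog)$key)
  fit <- trp_ensemble(fx$keys, fx$y, catalog = fx$catalog,
                      learners = list(oracle_learner(truth_fun),
                                      noise_learner(seed = 11, scale = 80)),
                      mcmc = fast_mcmc, seed = 5)
  w <- coef(fit)
  expect_gt(w["oracle"], 0.9)
})

test_that("predictive mean matches a brute-force average over posterior draws", {
  fx <- fixture_data(n = 50, cv = 0.043)
  fit <- trp_ensemble(fx$keys, fx$y, catalog = fx$catalog, mcmc = fast_mcmc,
                      seed = 6)
  newk <- enumerate_design_space(fx$catalog)$key[c(1, 500, 7000)]
  pr <- predict(fit, newk)
  X <- one_hot_encode(newk, fx$catalog)
  P <- vapply(seq_along(fit$learners),
              function(m) as.numeric(fit$learners[[m]]$predict(fit$models[[m]], X)),
              numeric(3))
  mu_brute <- rowMeans(P %*% t(fit$weights))       # average over raw draws
  expect_equal(pr$mu, mu_brute, tolerance = 1e-10)
  var_brute <- apply(P %*% t(fit$weights), 1, stats::var) + mean(fit$sigma^2)
  expect_equal(pr$sigma^2, var_brute, tolerance = 1e-6)
})

test_that("with one learner the predictive sd reduces to the noise sd", {
  fx <- fixture_data(n = 40)
  fit <- trp_ensemble(fx$keys, fx$y, catalog = fx$catalog,
                      learners = list(default_learners()[[1]]),
                      mcmc = fast_mcmc, seed = 7)
  pr <- predict(fit, fx$keys[1:5])
  expect_equal(pr$sigma, rep(sqrt(mean(fit$sigma^2)), 5), tolerance = 1e-10)
})

test_that("predictions are invariant to training-row permutation and reproducible", {
  fx <- fixture_data(n = 40, cv = 0.043)
  lr <- list(default_learners()[[1]], default_learners()[[2]])
  fit1 <- trp_ensemble(fx$keys, fx$y, catalog = fx$catalog, learners = lr,
                       mcmc = fast_mcmc, seed = 8)
  perm <- rev(seq_along(fx$keys))
  fit2 <- trp_ensemble(fx$keys[perm], fx$y[perm], catalog = fx$catalog,
                       learners = lr, mcmc = fast_mcmc, seed = 8)
  newk <- enumerate_design_space(fx$catalog)$key[1:20]
  expect_equal(predict(fit1, newk)$mu, predict(fit2, newk)$mu,
               tolerance = 0.05)
  # bit-identical reruns at fixed seed
  fit3 <- trp_ensemble(fx$keys, fx$y, catalog = fx$catalog, learners = lr,
                       mcmc = fast_mcmc, seed = 8)
  expect_identical(fit1$weights, fit3$weights)
  expect_identical(predict(fit1, newk)$mu, predict(fit3, newk)$mu)
})

test_that("failing learners are excluded with a warning", {
  fx <- fixture_data(n = 30)
  broken <- structure(list(name = "broken",
                           fit = function(X, y) stop("boom"),
                           predict = function(m, X) 0),
                      class = "trp_learner")
  expect_warning(
    fit <- trp_ensemble(fx$keys, fx$y, catalog = fx$catalog,
                        learners = list(default_learners()[[1]], broken),
                        mcmc = fast_mcmc, seed = 9),
    "broken")
  expect_equal(fit$learner_names, "linear")
  expect_error(
    suppressWarnings(
      trp_ensemble(fx$keys, fx$y, catalog = fx$catalog,
                   learners = list(broken), mcmc = fast_mcmc, seed = 9)),
    "all base learners failed")
})

test_that("formula interface matches the default interface", {
  fx <- fixture_data(n = 30)
  df <- fx$strains
  df$rate <- fx$y
  lr <- list(default_learners()[[1]])
  f1 <- trp_ensemble(rate ~ ., data = df, catalog = fx$catalog,
                     learners = lr, mcmc = fast_mcmc, seed = 10)
  f2 <- trp_ensemble(fx$keys, fx$y, catalog = fx$catalog, learners = lr,
                     mcmc = fast_mcmc, seed = 10)
  expect_equal(fitted(f1), fitted(f2))
  expect_s3_class(summary(f1), "summary.trp_ensemble")
  expect_length(coef(f1), 1)
  expect_equal(length(residuals(f1)), 30)
  sims <- simulate(f1, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(30L, 2L))
  expect_identical(simulate(f1, nsim = 2, seed = 1), sims)
})

test_that("cross-validation: interpolating learner, fold counts, leave-one-out", {
  fx <- fixture_data(n = 40)
  truth_fun <- function(X) true_rate(fx$truth, one_hot_decode(X, fx$catalog)$key)
  # noiseless data generated exactly by the planted learner -> test MAE ~ 0
  cv <- cross_validate(fx$keys, fx$strains$true_rate, catalog = fx$catalog,
                       k = 5, seed = 2,
                       learners = list(oracle_learner(truth_fun)),
                       mcmc = fast_mcmc)
  expect_lt(cv$mae, 1e-6)
  expect_length(cv$fold_mae, 5)
  # leave-one-out returns n fold errors
  cv2 <- cross_validate(fx$keys[1:12], fx$strains$true_rate[1:12],
                        catalog = fx$catalog, k = 12, seed = 3,
                        learners = list(oracle_learner(truth_fun)),
                        mcmc = fast_mcmc)
  expect_length(cv2$fold_mae, 12)
})

test_that("pure-noise response: test MAE approaches the no-signal baseline", {
  cat0 <- default_catalog()
  keys <- enumerate_design_space(cat0)$key
  set.seed(31)
  idx <- sample(7776, 60)
  y <- rnorm(60, 150, 30)
  lr <- list(default_learners()[[1]], default_learners()[[2]])
  cv <- cross_validate(keys[idx], y, catalog = cat0, k = 5, seed = 4,
                       learners = lr, mcmc = fast_mcmc)
  baseline <- mean(abs(y - mean(y)))
  expect_lt(abs(cv$mae - baseline) / baseline, 0.35)
})

test_that("learning curves: more data helps and train MAE <= test MAE", {
  fx <- fixture_data(n = 90, cv = 0.043, interactions = 0.08)
  lr <- default_learners()[c(1, 2, 6)]
  lc <- learning_curve(fx$keys, fx$y, catalog = fx$catalog,
                       sizes = c(25, 90), n_reps = 3, cv_folds = 3,
                       seed = 5, learners = lr, mcmc = fast_mcmc)
  expect_equal(lc$size, c(25, 90))
  expect_lt(lc$test_mae[2], lc$test_mae[1])
  expect_true(all(lc$train_mae <= lc$test_mae))
  expect_true(all(lc$train_ci >= 0 & lc$test_ci >= 0))
})
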