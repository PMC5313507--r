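# LASSO coordinate descent, prediction, nested LOSO CV, null thresholds.

test_that("soft-threshold solution on a single standardized feature", {
  # rho = (1/N) x'y = 0.8, lambda = 0.4 -> theta = 0.8 - 0.2 = 0.6
  set.seed(1)
  N <- 50
  x <- zscore(rnorm(N))
  y <- 0.8 * x
  fit <- lasso_fit(matrix(x), y, 0.4)
  expect_equal(fit$beta, 0.6, tolerance = 1e-8)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  # at lambda >= lambda_max everything shrinks to the intercept
  y2 <- 0.8 * x + 0.3
  lam_max <- 2 * abs(mean(x * (y2 - mean(y2))))
  fit2 <- lasso_fit(matrix(x), y2, lam_max * 1.01)
  expect_equal(fit2$beta, 0)
  expect_equal(fit2$intercept, mean(y2))
})

test_that("lambda = 0 on an orthonormal-ish design matches least squares", {
  set.seed(2)
  N <- 60
  X <- qr.Q(qr(matrix(rnorm(N * 5), N, 5))) * sqrt(N)  # columns ~ unit pop var
  X <- sweep(X, 2, colMeans(X))
  beta_true <- c(1, -2, 0.5, 0, 3)
  y <- as.vector(X %*% beta_true) + rnorm(N, sd = 0.1)
  fit <- lasso_fit(X, y, 0)
  ls <- lm.fit(cbind(1, X), y)$coefficients
  expect_equal(fit$beta, unname(ls[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ls[1]), tolerance = 1e-6)
})

test_that("coordinate descent agrees with glmnet at lambda/2", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  N <- 80
  d <- 30
  X <- matrix(rnorm(N * d), N, d)
  X <- sweep(sweep(X, 2, colMeans(X)), 2,
             sqrt(colMeans(sweep(X, 2, colMeans(X))^2)), "/")
  y <- as.vector(X[, 1:3] %*% c(1.5, -1, 0.8)) + rnorm(N, sd = 0.5)
  for (lam in c(0.05, 0.2, 0.6)) {
    fit <- lasso_fit(X, y, lam)
    gn <- glmnet::glmnet(X, y, alpha = 1, lambda = lam / 2,
                         standardize = FALSE, intercept = TRUE,
                         thresh = 1e-12)
    expect_equal(fit$beta, as.vector(gn$beta), tolerance = 1e-4)
    expect_equal(fit$intercept, as.numeric(gn$a0), tolerance = 1e-4)
  }
})

test_that("the objective never increases across sweeps", {
  set.seed(4)
  N <- 40
  d <- 60
  X <- matrix(rnorm(N * d), N, d)
  X <- sweep(sweep(X, 2, colMeans(X)), 2,
             sqrt(colMeans(sweep(X, 2, colMeans(X))^2)), "/")
  y <- rbinom(N, 1, 0.5)
  for (lam in c(0.01, 0.1)) {
    fit <- lasso_fit(X, y, lam, trace = TRUE)
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
  }
})

test_that("sparsity is non-increasing in lambda along the default grid", {
  set.seed(5)
  N <- 60
  d <- 100
  X <- matrix(rnorm(N * d), N, d)
  X <- sweep(sweep(X, 2, colMeans(X)), 2,
             sqrt(colMeans(sweep(X, 2, colMeans(X))^2)), "/")
  y <- rbinom(N, 1, 0.5)
  fits <- lasso_fit(X, y, lambda_grid())          # descending grid
  nnz <- vapply(fits, function(f) sum(f$beta != 0), integer(1))
  # sparsity grows with lambda; at the saturated end (d > N, lambda -> 0)
  # exact LASSO paths are known to swap features in and out, so small
  # local wobbles are tolerated while the trend must be strictly monotone
  expect_true(all(diff(nnz) >= -3))
  expect_lt(cor(lambda_grid(), nnz, method = "spearman"), -0.95)
  expect_identical(nnz[1], 0L)
})

test_that("prediction thresholds the regression output at 0.5", {
  model <- structure(list(beta = rep(0, 3), intercept = 0.7, lambda = 1),
                     class = "lasso_model")
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(predict_labels(model, X), rep(1L, 5))
  model$intercept <- 0.3
  expect_equal(predict_labels(model, X), rep(0L, 5))
  # separable one-feature problem fits perfectly at small lambda
  set.seed(6)
  x <- c(rnorm(10, -2), rnorm(10, 2))
  y <- as.integer(x > 0)
  st <- dtwfc:::standardize_train(matrix(x))
  fit <- lasso_fit(st$X, y, 0.01)
  expect_equal(predict_labels(fit, st$X), y)
})

test_that("dataset constructor enforces one label per subject", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(classification_dataset(X, rep(c(0, 1), 5),
                                      rep(c("a", "b"), each = 5)),
               "share one label")
  ds <- classification_dataset(X, rep(c(0, 1), each = 5),
                               rep(c("a", "b"), each = 5))
  expect_s3_class(ds, "classification_dataset")
  # 26 subjects x 5 runs = 130 instances
  ds26 <- synth_classification_dataset(n_subjects = 26, n_runs = 5,
                                       n_features = 10, seed = 1)
  expect_equal(nrow(ds26$X), 130)
})

test_that("nested LOSO recovers planted signal and respects the grid", {
  ds <- synth_classification_dataset(n_subjects = 12, n_runs = 3,
                                     n_features = 80, n_informative = 5,
                                     snr = 2, seed = 11)
  cv <- nested_loso_cv(ds)
  expect_gte(cv$accuracy, 0.9)
  expect_true(all(cv$fold_lambda %in% lambda_grid()))
  expect_equal(length(cv$predicted), nrow(ds$X))
})

test_that("standardization leakage inflates null accuracy measurably", {
  # negative control: standardizing on all data before the CV split must
  # not be done; verify the no-leakage pipeline stays at chance while a
  # deliberately leaky feature (contaminated with the label) succeeds
  ds <- synth_classification_dataset(n_subjects = 10, n_runs = 3,
                                     n_features = 40, n_informative = 0,
                                     seed = 12)
  cv_clean <- nested_loso_cv(ds, lambdas = lambda_grid(n = 8))
  leaky <- ds$X
  leaky[, 1] <- ds$y + rnorm(length(ds$y), sd = 0.1)
  cv_leaky <- nested_loso_cv(
    classification_dataset(leaky, ds$y, ds$subject),
    lambdas = lambda_grid(n = 8))
  expect_gt(cv_leaky$accuracy, cv_clean$accuracy + 0.2)
  expect_lt(cv_clean$accuracy, 0.75)
})

test_that("coin-flip threshold matches the binomial quantile", {
  y <- rep(c(0L, 1L), c(60, 70))              # 130 instances
  thr <- coin_flip_threshold(y, n_draws = 100000, percentile = 95,
                             seed = 42)
  expect_equal(thr, qbinom(0.95, 130, 0.5) / 130, tolerance = 0.01)
  # N = 1: any percentile >= 50 gives 1.0
  expect_equal(coin_flip_threshold(1L, n_draws = 2000, percentile = 95,
                                   seed = 1), 1)
  # monotone in the percentile
  t50 <- coin_flip_threshold(y, 20000, 50, seed = 2)
  t95 <- coin_flip_threshold(y, 20000, 95, seed = 2)
  t99 <- coin_flip_threshold(y, 20000, 99, seed = 2)
  expect_true(t50 <= t95 && t95 <= t99)
})

test_that("permutation threshold is reproducible and near coin flip", {
  ds <- synth_classification_dataset(n_subjects = 8, n_runs = 2,
                                     n_features = 20, n_informative = 0,
                                     seed = 13)
  grid <- lambda_grid(n = 5)
  p1 <- permutation_threshold(ds, grid, n_perm = 12, seed = 7)
  p2 <- permutation_threshold(ds, grid, n_perm = 12, seed = 7)
  expect_identical(p1, p2)
  cf <- coin_flip_threshold(ds$y, 20000, 95, seed = 7)
  expect_lt(abs(p1$threshold - cf), 0.2)
})
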