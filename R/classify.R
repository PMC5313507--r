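# Connectome-pattern classification: LASSO regression on pairwise
# connectivity features, nested leave-subject-out cross-validation, and
# the two significance-null procedures (coin-flip labels and subject-level
# label permutation).

#' Assemble a classification dataset
#'
#' Bundles the instance-by-feature table, binary labels and subject
#' grouping, checking that every subject's instances (runs) carry one
#' label.
#'
#' @param X Numeric instance-by-feature matrix.
#' @param y Binary labels (0/1), one per instance.
#' @param subject Subject identifier per instance; all runs of a subject
#'   leave the training set together under leave-subject-out CV.
#' @return An object of class `classification_dataset`.
#' @export
classification_dataset <- function(X, y, subject) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), length(subject) == length(y),
            all(y %in% c(0L, 1L)), all(is.finite(X)))
  per_subj <- tapply(y, subject, function(v) length(unique(v)))
  if (any(per_subj != 1L))
    stop("every subject's instances must share one label")
  structure(list(X = X, y = y, subject = as.character(subject)),
            class = "classification_dataset")
}

# Standardize columns with training-set statistics (population sd);
# near-constant columns are left centered but unscaled.
standardize_train <- function(X) {
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  s[s < 1e-12] <- 1
  list(mu = mu, sd = s, X = sweep(sweep(X, 2L, mu), 2L, s, "/"))
}
standardize_apply <- function(X, st) {
  sweep(sweep(X, 2L, st$mu), 2L, st$sd, "/")
}

#' Fit a LASSO regression model
#'
#' Minimizes `(1/N) * ||y - b0 - X theta||^2 + lambda * ||theta||_1` with
#' an unpenalized intercept, by cyclic coordinate descent (convergence
#' when the largest coefficient change in a sweep drops below `tol`, or
#' after `max_sweeps` sweeps). Features are expected to be standardized
#' (mean 0, sd 1 over the training rows); under that scaling the
#' single-coordinate update is the soft threshold
#' `theta_j = sign(rho_j) * max(|rho_j| - lambda/2, 0)`. At
#' `lambda >= lambda_max = 2 * max_j |(1/N) x_j'(y - mean(y))|` all
#' coefficients are zero and the intercept is `mean(y)`.
#'
#' @param X Standardized instance-by-feature matrix.
#' @param y Numeric response (binary labels for classification).
#' @param lambda Regularization weight(s); a vector is processed with warm
#'   starts in the given order.
#' @param tol Convergence tolerance on the largest coefficient change.
#'   Default 1e-6.
#' @param max_sweeps Sweep cap. Default 10000.
#' @param trace Record the objective after every sweep (for diagnostics).
#' @return For scalar `lambda`, an object of class `lasso_model` (list
#'   with `beta`, `intercept`, `lambda`, `sweeps`, and `objective_trace`
#'   when requested). For a vector, a list of `lasso_model`s.
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-6, max_sweeps = 10000L,
                      trace = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in X or y")
  stopifnot(nrow(X) == length(y), all(lambda >= 0))
  fit <- .lasso_cd_cpp(X, y, as.numeric(lambda), tol, as.integer(max_sweeps),
                       isTRUE(trace))
  models <- lapply(seq_along(lambda), function(k) {
    m <- list(beta = fit$beta[, k], intercept = fit$intercept[k],
              lambda = lambda[k], sweeps = fit$sweeps[k])
    if (isTRUE(trace)) m$objective_trace <- fit$objective_trace[[k]]
    class(m) <- "lasso_model"
    m
  })
  if (length(lambda) == 1L) models[[1L]] else models
}

#' Predict binary labels from a LASSO model
#'
#' Continuous regression output `X theta + b0` thresholded at 0.5. Feature
#' standardization parameters from the training set must already have been
#' applied to `X`.
#'
#' @param model A `lasso_model`.
#' @param X Standardized feature matrix.
#' @return Integer vector of 0/1 labels.
#' @export
predict_labels <- function(model, X) {
  stopifnot(inherits(model, "lasso_model"))
  X <- as.matrix(X)
  as.integer(as.vector(X %*% model$beta) + model$intercept >= 0.5)
}

#' Default regularization grid
#'
#' 25 log-spaced values spanning the search interval 0.0005 to 0.5,
#' descending (so warm starts follow the regularization path).
#'
#' @param n Number of grid points. Default 25.
#' @param min,max Interval endpoints.
#' @return Numeric vector, descending.
#' @export
lambda_grid <- function(n = 25L, min = 5e-4, max = 0.5) {
  exp(seq(log(max), log(min), length.out = n))
}

#' Nested leave-subject-out cross-validation
#'
#' Outer loop: all runs of one subject are held out. Inner loop: a second
#' leave-one-subject-out pass over the remaining subjects selects the
#' regularization weight maximizing inner held-out accuracy (ties broken
#' toward the larger, i.e. sparser, lambda). The model is then refit on
#' the full outer-training set at the chosen lambda and the held-out runs
#' are predicted. Feature standardization always uses the respective
#' training rows only (no leakage).
#'
#' @param dataset A [classification_dataset()].
#' @param lambdas Regularization grid (descending recommended); defaults
#'   to [lambda_grid()].
#' @return An object of class `cv_result`: list with `accuracy`,
#'   `predicted` / `truth` (per instance, outer), `fold_lambda` (chosen
#'   lambda per outer fold), `subjects` (fold order).
#' @export
nested_loso_cv <- function(dataset, lambdas = lambda_grid()) {
  stopifnot(inherits(dataset, "classification_dataset"))
  X <- dataset$X
  y <- dataset$y
  subj <- dataset$subject
  subjects <- unique(subj)
  if (length(subjects) < 3L) stop("need at least 3 subjects")
  lambdas <- as.numeric(lambdas)

  predicted <- rep(NA_integer_, length(y))
  fold_lambda <- rep(NA_real_, length(subjects))
  names(fold_lambda) <- subjects

  for (si in seq_along(subjects)) {
    s_out <- subjects[si]
    test_idx <- which(subj == s_out)
    train_idx <- which(subj != s_out)
    y_tr <- y[train_idx]
    if (length(unique(y_tr)) < 2L) {
      warning(sprintf("fold '%s' skipped: single-class training set", s_out))
      next
    }
    inner_subjects <- unique(subj[train_idx])
    n_correct <- numeric(length(lambdas))
    n_total <- 0L
    for (s_in in inner_subjects) {
      val_idx <- train_idx[subj[train_idx] == s_in]
      fit_idx <- train_idx[subj[train_idx] != s_in]
      if (length(unique(y[fit_idx])) < 2L) next
      st <- standardize_train(X[fit_idx, , drop = FALSE])
      models <- lasso_fit(st$X, y[fit_idx], lambdas)
      Xv <- standardize_apply(X[val_idx, , drop = FALSE], st)
      for (k in seq_along(lambdas)) {
        pred <- predict_labels(models[[k]], Xv)
        n_correct[k] <- n_correct[k] + sum(pred == y[val_idx])
      }
      n_total <- n_total + length(val_idx)
    }
    if (n_total == 0L) {
      warning(sprintf("fold '%s' skipped: no usable inner folds", s_out))
      next
    }
    best <- which(n_correct == max(n_correct))
    # grid is descending: the first index among the ties is the largest
    # lambda, i.e. the sparser model
    k_star <- best[which.max(lambdas[best])]
    fold_lambda[si] <- lambdas[k_star]
    st <- standardize_train(X[train_idx, , drop = FALSE])
    model <- lasso_fit(st$X, y_tr, lambdas)[[k_star]]
    Xt <- standardize_apply(X[test_idx, , drop = FALSE], st)
    predicted[test_idx] <- predict_labels(model, Xt)
  }

  scored <- !is.na(predicted)
  structure(list(accuracy = mean(predicted[scored] == y[scored]),
                 predicted = predicted, truth = y,
                 fold_lambda = fold_lambda, subjects = subjects,
                 lambdas = lambdas),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("nested LOSO CV: accuracy %.3f over %d instances (%d subjects)\n",
              x$accuracy, length(x$truth), length(x$subjects)))
  invisible(x)
}

#' Coin-flip accuracy threshold
#'
#' Null accuracy of random guessing: for each draw, iid Bernoulli(1/2)
#' labels are predicted for all instances and scored against the true
#' labels; the requested percentile of the resulting accuracy distribution
#' is returned. Since each guess is correct with probability 1/2 whatever
#' the labels, the distribution is Binomial(N, 1/2)/N.
#'
#' @param y True binary labels.
#' @param n_draws Number of random labelings. Default 100000.
#' @param percentile Percentile of the accuracy distribution (e.g. 95).
#' @param seed Optional integer seed.
#' @return Accuracy threshold in `[0, 1]`.
#' @export
coin_flip_threshold <- function(y, n_draws = 100000L, percentile = 95,
                                seed = NULL) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), length(y) >= 1L)
  n <- length(y)
  with_seed(seed, {
    acc <- numeric(n_draws)
    chunk <- max(1L, min(n_draws, floor(2e6 / n)))
    done <- 0L
    while (done < n_draws) {
      k <- min(chunk, n_draws - done)
      G <- matrix(runif(k * n) < 0.5, k, n)
      acc[done + seq_len(k)] <-
        rowMeans(G == matrix(y, k, n, byrow = TRUE))
      done <- done + k
    }
    unname(quantile(acc, percentile / 100, type = 1L))
  })
}

#' Permutation-test accuracy threshold
#'
#' Reruns the full nested leave-subject-out pipeline on label-permuted
#' copies of the dataset and returns the requested percentile of the
#' permuted accuracies. Labels are permuted at the subject level (all runs
#' of a subject keep a common label), respecting the exchangeability
#' structure under leave-subject-out CV.
#'
#' @param dataset A [classification_dataset()].
#' @param lambdas Regularization grid. Defaults to [lambda_grid()].
#' @param n_perm Number of permutations.
#' @param percentile Percentile of the permuted accuracy distribution.
#' @param seed Optional integer seed.
#' @return List with `threshold` and the vector of permuted `accuracies`.
#' @export
permutation_threshold <- function(dataset, lambdas = lambda_grid(),
                                  n_perm = 100L, percentile = 95,
                                  seed = NULL) {
  stopifnot(inherits(dataset, "classification_dataset"))
  subjects <- unique(dataset$subject)
  subj_label <- vapply(subjects, function(s)
    dataset$y[match(s, dataset$subject)], integer(1L))
  acc <- vapply(seq_len(n_perm), function(p) {
    perm <- with_seed(child_seed(seed, p), sample(subj_label))
    y_perm <- perm[match(dataset$subject, subjects)]
    ds <- classification_dataset(dataset$X, y_perm, dataset$subject)
    nested_loso_cv(ds, lambdas)$accuracy
  }, numeric(1L))
  list(threshold = unname(quantile(acc, percentile / 100, type = 1L)),
       accuracies = acc)
}
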