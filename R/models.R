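#' Stratified 7:3 calibration/validation split
#'
#' Splits the sample table into calibration and validation sets at the
#' given fraction, stratified on the year x variety x density cells. Each
#' stratum contributes `floor(f * n)` calibration samples plus possibly one
#' extra; the extras needed to reach `round(f * N)` in total are placed by a
#' deterministic balanced largest-remainder rule that keeps every year,
#' variety and density margin at `round(f * margin total)`. Membership
#' within a stratum is randomized by `seed`; the per-stratum counts depend
#' only on the design.
#'
#' @param table a `sample_table`.
#' @param calibration_fraction fraction in (0, 1), default 0.7.
#' @param strata character vector of stratification columns.
#' @param seed integer seed.
#' @return list with `calibration` and `validation` data frames.
#' @export
split_dataset <- function(table, calibration_fraction = 0.7,
                          strata = c("year", "variety", "density"), seed = 1) {
  f <- calibration_fraction
  if (f <= 0 || f >= 1) stopf("calibration_fraction must be in (0, 1)")
  miss <- setdiff(strata, names(table))
  if (length(miss)) stopf("missing stratification columns: %s", paste(miss, collapse = ", "))
  key <- interaction(table[, strata, drop = FALSE], drop = TRUE, sep = "|")
  n_s <- table(key)
  if (any(n_s < 2)) stopf("every stratum needs at least 2 samples")
  target_total <- round(f * nrow(table))
  base <- floor(f * as.numeric(n_s))
  names(base) <- names(n_s)
  n_extra <- target_total - sum(base)

  if (n_extra > 0) {
    # margin targets: round(f * margin total) for each level of each key
    margins <- lapply(strata, function(s) {
      tot <- table(table[[s]])
      round(f * as.numeric(tot)) - vapply(names(tot), function(lv) {
        sum(base[vapply(strsplit(names(base), "|", fixed = TRUE),
                        function(kk) kk[match(s, strata)] == lv, TRUE)])
      }, numeric(1)) |> stats::setNames(names(tot))
    })
    names(margins) <- strata
    rem <- f * as.numeric(n_s) - base
    names(rem) <- names(n_s)
    boosted <- character(0)
    lev <- strsplit(names(n_s), "|", fixed = TRUE)
    for (e in seq_len(n_extra)) {
      cand <- setdiff(names(n_s), boosted)
      cand <- cand[base[cand] + 1 <= as.numeric(n_s[cand])]
      defsum <- vapply(cand, function(k) {
        kk <- lev[[match(k, names(n_s))]]
        sum(vapply(seq_along(strata), function(si) margins[[si]][[kk[si]]], numeric(1)))
      }, numeric(1))
      allpos <- vapply(cand, function(k) {
        kk <- lev[[match(k, names(n_s))]]
        all(vapply(seq_along(strata), function(si) margins[[si]][[kk[si]]], numeric(1)) > 0)
      }, logical(1))
      pool <- if (any(allpos)) cand[allpos] else cand
      score <- rem[pool] + defsum[pool]
      pick <- pool[order(-score, pool)][1]
      base[pick] <- base[pick] + 1
      boosted <- c(boosted, pick)
      kk <- lev[[match(pick, names(n_s))]]
      for (si in seq_along(strata))
        margins[[si]][[kk[si]]] <- margins[[si]][[kk[si]]] - 1
    }
  } else if (n_extra < 0) {
    stopf("internal allocation error") # floor() can never exceed round(f*N)
  }

  set.seed(seed)
  cal_idx <- unlist(lapply(names(n_s), function(k) {
    rows <- which(key == k)
    sample(rows, base[[k]])
  }), use.names = FALSE)
  list(calibration = table[sort(cal_idx), , drop = FALSE],
       validation = table[setdiff(seq_len(nrow(table)), cal_idx), , drop = FALSE])
}

#' Hyperparameter grids for the SBW regression models
#'
#' The full grids searched for each family: ridge penalty
#' `alpha in {0.001, 0.01, 0.1, 1, 10, 100}`; random forest
#' `n_estimators in {100, 200, 300}`, `max_depth in {3, 5, 10}`,
#' `max_features in {sqrt, log2}`, `min_samples_split in {2, 4, 6}`,
#' `min_samples_leaf in {1, 2, 4}`; neural network
#' `hidden_size in {32, 64, 128}`, `learning_rate in {0.01, 0.001, 0.0001}`,
#' `epochs in {500, 1000}`, `batch_size in {8, 16, 32}`. The `"fast"`
#' profile is a reduced search for test-scale runs (documented in the
#' methods vignette): ridge unchanged; random forest 100 trees, depth
#' {3, 5, 10}, sqrt features, split 2, leaf {1, 4}; neural network hidden
#' {32, 64}, learning rate 0.01, 200 epochs, batch 16.
#'
#' @param family one of `"ridge"`, `"random_forest"`, `"neural_net"`.
#' @param profile `"full"` or `"fast"`.
#' @return data frame with one row per hyperparameter combination.
#' @export
model_grid <- function(family = c("ridge", "random_forest", "neural_net"),
                       profile = c("full", "fast")) {
  family <- match.arg(family); profile <- match.arg(profile)
  switch(family,
    ridge = data.frame(alpha = c(0.001, 0.01, 0.1, 1, 10, 100)),
    random_forest = if (profile == "full") {
      expand.grid(n_estimators = c(100, 200, 300), max_depth = c(3, 5, 10),
                  max_features = c("sqrt", "log2"), min_samples_split = c(2, 4, 6),
                  min_samples_leaf = c(1, 2, 4), stringsAsFactors = FALSE)
    } else {
      expand.grid(n_estimators = 100, max_depth = c(3, 5, 10),
                  max_features = "sqrt", min_samples_split = 2,
                  min_samples_leaf = c(1, 4), stringsAsFactors = FALSE)
    },
    neural_net = if (profile == "full") {
      expand.grid(hidden_size = c(32, 64, 128), learning_rate = c(0.01, 0.001, 1e-4),
                  epochs = c(500, 1000), batch_size = c(8, 16, 32))
    } else {
      expand.grid(hidden_size = c(32, 64), learning_rate = 0.01,
                  epochs = 200, batch_size = 16)
    })
}

ridge_fit <- function(X, y, alpha) {
  # closed form with unpenalized intercept: beta = (X'X + alpha I)^-1 X' (y - ybar)
  ybar <- mean(y)
  XtX <- crossprod(X)
  beta <- solve(XtX + diag(alpha, ncol(X)), crossprod(X, y - ybar))
  list(beta = drop(beta), intercept = ybar)
}

ridge_predict <- function(fit, X) drop(X %*% fit$beta) + fit$intercept

make_folds <- function(strata, k, seed) {
  set.seed(seed)
  fold <- integer(length(strata))
  for (lv in unique(strata)) {
    rows <- which(strata == lv)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

fit_one <- function(family, X, y, hp, seed) {
  switch(family,
    ridge = ridge_fit(X, y, hp$alpha),
    random_forest = {
      p <- ncol(X)
      mtry <- if (hp$max_features == "sqrt") max(1L, floor(sqrt(p))) else
        max(1L, floor(log2(p)))
      ranger::ranger(x = as.data.frame(X), y = y, num.trees = hp$n_estimators,
                     max.depth = hp$max_depth, mtry = mtry,
                     min.node.size = hp$min_samples_split,
                     min.bucket = hp$min_samples_leaf,
                     seed = seed, num.threads = 1)
    },
    neural_net = mlp_fit(X, y, hidden = hp$hidden_size, lr = hp$learning_rate,
                         epochs = hp$epochs, batch_size = hp$batch_size,
                         seed = seed))
}

predict_one <- function(family, fit, X) {
  switch(family,
    ridge = ridge_predict(fit, X),
    random_forest = predict(fit, data = as.data.frame(X), num.threads = 1)$predictions,
    neural_net = mlp_predict(fit, X))
}

#' Train one SBW regression family by grid search with five-fold CV
#'
#' Exhaustively searches the family's hyperparameter grid (see
#' [model_grid()]); each candidate is scored by its mean cross-validated
#' R-squared over folds stratified by planting density, and the winner is
#' refit on the full calibration set. Ridge and the neural network operate
#' on z-scored features (statistics taken from the calibration set); the
#' neural network is a one-hidden-layer feed-forward net with
#' rectified-linear activation trained by minibatch Adam on a z-scored
#' target.
#'
#' @param calibration calibration `sample_table`.
#' @param family `"ridge"`, `"random_forest"` or `"neural_net"`.
#' @param features feature column names (typically [selected_features()]).
#' @param profile grid profile, `"full"` or `"fast"`.
#' @param cv_folds number of cross-validation folds (default 5).
#' @param seed integer seed for folds and stochastic fits.
#' @return object of class `sbw_model`: fitted handle, `best` (winning
#'   hyperparameters), `cv` (per-candidate mean CV R-squared),
#'   `calibration_r2`, `calibration_rmse`, scaling statistics and feature
#'   list. Supports `predict(model, newdata)`.
#' @export
train_sbw_model <- function(calibration, family = c("ridge", "random_forest", "neural_net"),
                            features, profile = c("full", "fast"),
                            cv_folds = 5, seed = 1) {
  family <- match.arg(family); profile <- match.arg(profile)
  if (cv_folds < 2) stopf("cv_folds must be >= 2")
  X <- as.matrix(calibration[, features, drop = FALSE])
  y <- calibration$sbw_g
  if (any(!is.finite(X))) stopf("non-finite feature values in calibration set")
  if (stats::sd(y) == 0) stopf("calibration SBW has zero variance")
  if (nrow(X) < cv_folds * 2) stopf("need at least %d calibration samples", cv_folds * 2)

  standardize <- family %in% c("ridge", "neural_net")
  center <- colMeans(X); scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- if (standardize) sweep(sweep(X, 2, center), 2, scale, "/") else X

  dens <- if ("density" %in% names(calibration)) calibration$density else rep("all", nrow(X))
  fold <- make_folds(dens, cv_folds, seed)
  grid <- model_grid(family, profile)
  cv_r2 <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    hp <- grid[gi, , drop = FALSE]
    r2s <- vapply(seq_len(cv_folds), function(kf) {
      tr <- fold != kf
      fit <- fit_one(family, Xs[tr, , drop = FALSE], y[tr], hp, seed + kf)
      pred <- predict_one(family, fit, Xs[!tr, , drop = FALSE])
      evaluate_predictions(y[!tr], pred)$r2
    }, numeric(1))
    cv_r2[gi] <- mean(r2s)
  }
  best_i <- which.max(cv_r2)
  best <- grid[best_i, , drop = FALSE]
  fit <- fit_one(family, Xs, y, best, seed)
  cal_pred <- predict_one(family, fit, Xs)
  cal <- evaluate_predictions(y, cal_pred)
  structure(list(family = family, fit = fit, best = best,
                 cv = cbind(grid, cv_r2 = cv_r2),
                 features = features, standardize = standardize,
                 center = center, scale = scale, seed = seed,
                 calibration_r2 = cal$r2, calibration_rmse = cal$rmse,
                 n_calibration = nrow(X)),
            class = "sbw_model")
}

#' @export
predict.sbw_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  if (object$standardize)
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  predict_one(object$family, object$fit, X)
}

#' @export
print.sbw_model <- function(x, ...) {
  cat(sprintf("<sbw_model> %s | features: %s\n", x$family,
              paste(x$features, collapse = ", ")))
  cat("best:", paste(names(x$best), unlist(x$best), sep = "=", collapse = ", "), "\n")
  cat(sprintf("calibration R2 %.3f, RMSE %.3f g (n = %d)\n",
              x$calibration_r2, x$calibration_rmse, x$n_calibration))
  invisible(x)
}

#' Coefficient of determination and RMSE of predictions
#'
#' `R2 = 1 - sum((y_i - x_i)^2) / sum((x_i - xbar)^2)` with `x_i` observed,
#' `y_i` predicted, and `xbar` the mean of the observed values (default);
#' `RMSE = sqrt(mean((y_i - x_i)^2))` in grams. `center = "predicted"`
#' reproduces the variant that normalizes by deviations from the mean of
#' the predictions instead.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 2).
#' @param center `"observed"` (default) or `"predicted"`.
#' @return list with `r2`, `rmse`, `n`.
#' @export
evaluate_predictions <- function(observed, predicted,
                                 center = c("observed", "predicted")) {
  center <- match.arg(center)
  if (length(observed) != length(predicted)) stopf("length mismatch")
  n <- length(observed)
  if (n < 2) stopf("need at least 2 samples")
  ss_res <- sum((predicted - observed)^2)
  mu <- if (center == "observed") mean(observed) else mean(predicted)
  ss_tot <- sum((observed - mu)^2)
  if (ss_tot == 0) stopf("observed values have zero variance")
  list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(ss_res / n), n = n)
}
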