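test_that("the stratified split reproduces the trial design margins", {
  tab <- paper_design_table(seed = 61)
  sp <- split_dataset(tab, seed = 7)
  cal <- sp$calibration
  expect_equal(nrow(cal), 202)
  expect_equal(nrow(sp$validation), 86)
  expect_equal(as.vector(table(cal$density)), c(38, 38, 38, 38, 50))
  expect_equal(as.vector(table(factor(cal$variety, c("V1", "V2", "V3", "CK")))),
               c(63, 63, 63, 13))
  expect_equal(as.vector(table(cal$year)), c(101, 101))
  # validation is the complement
  expect_equal(sort(c(cal$sample_id, sp$validation$sample_id)),
               sort(tab$sample_id))
})

test_that("split membership is deterministic given the seed", {
  tab <- paper_design_table(seed = 62)
  s1 <- split_dataset(tab, seed = 3)
  s2 <- split_dataset(tab, seed = 3)
  expect_identical(s1$calibration$sample_id, s2$calibration$sample_id)
  s3 <- split_dataset(tab, seed = 4)
  expect_false(identical(s1$calibration$sample_id, s3$calibration$sample_id))
})

test_that("single-stratum and degenerate splits behave as specified", {
  one <- data.frame(year = 1, variety = "V", density = "D",
                    sample_id = sprintf("s%02d", 1:54), sbw_g = rnorm(54))
  s <- split_dataset(one, seed = 1)
  expect_equal(nrow(s$calibration), 38)
  expect_equal(nrow(s$validation), 16)
  tiny <- one[1, ]
  expect_error(split_dataset(tiny, seed = 1), "at least 2")
})

test_that("per-stratum counts stay within one sample of exact 7:3", {
  tab <- paper_design_table(seed = 63)
  sp <- split_dataset(tab, seed = 11)
  key <- interaction(tab[, c("year", "variety", "density")], drop = TRUE)
  calkey <- interaction(sp$calibration[, c("year", "variety", "density")], drop = TRUE)
  for (k in levels(key)) {
    n <- sum(key == k); ncal <- sum(calkey == k)
    expect_lt(abs(ncal - 0.7 * n), 1)
  }
})

test_that("ridge matches its closed form and recovers noiseless coefficients", {
  set.seed(64)
  # one centered feature, no standardization: slope = Sxy / (Sxx + alpha)
  x <- rnorm(50); x <- x - mean(x)
  y <- 2 + 3 * x + rnorm(50, 0, 0.1)
  fit <- cottonsbw:::ridge_fit(matrix(x, ncol = 1), y, alpha = 2.5)
  expect_equal(unname(fit$beta), sum(x * (y - mean(y))) / (sum(x^2) + 2.5),
               tolerance = 1e-10)
  expect_equal(fit$intercept, mean(y))
  # noiseless linear data at alpha = 0.001: near-exact recovery
  X <- matrix(rnorm(200 * 3), 200, 3)
  beta <- c(1.5, -2, 0.5)
  yy <- drop(X %*% beta) + 4
  f2 <- cottonsbw:::ridge_fit(scale(X, scale = FALSE), yy, alpha = 0.001)
  expect_equal(unname(f2$beta), beta, tolerance = 1e-3)
  pred <- cottonsbw:::ridge_predict(f2, scale(X, scale = FALSE))
  expect_gt(evaluate_predictions(yy, pred)$r2, 0.999)
})

test_that("ridge converges to least squares as alpha -> 0", {
  set.seed(65)
  X <- scale(matrix(rnorm(100 * 4), 100, 4), scale = FALSE)
  y <- drop(X %*% c(1, 2, -1, 0.5)) + rnorm(100, 0, 0.3)
  ols <- lm.fit(cbind(1, X), y)$coefficients
  fr <- cottonsbw:::ridge_fit(X, y, alpha = 1e-8)
  pred_ridge <- cottonsbw:::ridge_predict(fr, X)
  pred_ols <- drop(cbind(1, X) %*% ols)
  expect_lt(max(abs(pred_ridge - pred_ols)), 1e-6)
})

test_that("evaluation metrics match hand arithmetic and degenerate cases", {
  obs <- c(1, 2, 3); pred <- c(2, 2, 2)
  ev <- evaluate_predictions(obs, pred)
  expect_equal(ev$r2, 0)
  expect_equal(ev$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(ev$rmse, 4), 0.8165)
  perfect <- evaluate_predictions(obs, obs)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  # constant prediction at the observed mean has R2 = 0
  expect_equal(evaluate_predictions(obs, rep(2, 3))$r2, 0)
  # printed variant centers on predictions
  # SSres = 0.75; centering on mean(pred) = 2.5 gives SStot = 2.75
  ev2 <- evaluate_predictions(obs, c(1.5, 2.5, 3.5), center = "predicted")
  expect_equal(ev2$r2, 1 - 0.75 / 2.75, tolerance = 1e-12)
  expect_error(evaluate_predictions(rep(1, 3), rep(1, 3)), "zero variance")
  expect_error(evaluate_predictions(1, 1), "at least 2")
})

test_that("model grids hold exactly the specified candidate values", {
  g <- model_grid("ridge")
  expect_equal(g$alpha, c(0.001, 0.01, 0.1, 1, 10, 100))
  rf <- model_grid("random_forest", "full")
  expect_equal(nrow(rf), 3 * 3 * 2 * 3 * 3)
  expect_setequal(unique(rf$n_estimators), c(100, 200, 300))
  expect_setequal(unique(rf$max_depth), c(3, 5, 10))
  expect_setequal(unique(rf$max_features), c("sqrt", "log2"))
  expect_setequal(unique(rf$min_samples_split), c(2, 4, 6))
  expect_setequal(unique(rf$min_samples_leaf), c(1, 2, 4))
  nn <- model_grid("neural_net", "full")
  expect_equal(nrow(nn), 3 * 3 * 2 * 3)
  expect_setequal(unique(nn$hidden_size), c(32, 64, 128))
  expect_setequal(unique(nn$learning_rate), c(0.01, 0.001, 0.0001))
  expect_setequal(unique(nn$epochs), c(500, 1000))
  expect_setequal(unique(nn$batch_size), c(8, 16, 32))
})

make_model_table <- function(n = 120, seed = 66, f = identity) {
  set.seed(seed)
  tab <- data.frame(A = runif(n), B = runif(n),
                    density = sample(paste0("D", 1:5), n, replace = TRUE))
  tab$sbw_g <- 5 + f(tab$A) - 0.5 * tab$B + rnorm(n, 0, 0.02)
  tab
}

test_that("grid-search training selects, refits and predicts", {
  tab <- make_model_table()
  mdl <- train_sbw_model(tab, "ridge", c("A", "B"), profile = "fast", seed = 1)
  expect_s3_class(mdl, "sbw_model")
  expect_true(mdl$best$alpha %in% model_grid("ridge")$alpha)
  expect_gt(mdl$calibration_r2, 0.99)
  pred <- predict(mdl, tab)
  expect_equal(length(pred), nrow(tab))
  expect_gt(evaluate_predictions(tab$sbw_g, pred)$r2, 0.99)
})

test_that("random forest beats ridge on a step-function target", {
  tab <- make_model_table(n = 150, seed = 67,
                          f = function(a) 2 * (a > 0.5))
  r <- train_sbw_model(tab, "ridge", c("A", "B"), profile = "fast", seed = 2)
  rf <- train_sbw_model(tab, "random_forest", c("A", "B"), profile = "fast", seed = 2)
  expect_gt(rf$calibration_r2, r$calibration_r2)
})

test_that("the neural network fits a smooth relation and is seed-stable", {
  tab <- make_model_table(n = 150, seed = 68)
  nn <- train_sbw_model(tab, "neural_net", c("A", "B"), profile = "fast", seed = 3)
  expect_gt(nn$calibration_r2, 0.9)
  p1 <- predict(nn, tab)
  nn2 <- train_sbw_model(tab, "neural_net", c("A", "B"), profile = "fast", seed = 3)
  expect_identical(p1, predict(nn2, tab))
})

test_that("training guards reject degenerate inputs", {
  tab <- make_model_table(n = 30)
  tab$sbw_g <- 1
  expect_error(train_sbw_model(tab, "ridge", c("A", "B")), "zero variance")
  tab2 <- make_model_table(n = 8)
  expect_error(train_sbw_model(tab2, "ridge", c("A", "B")), "at least")
  tab3 <- make_model_table(n = 30)
  tab3$A[3] <- Inf
  expect_error(train_sbw_model(tab3, "ridge", c("A", "B")), "non-finite")
})
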