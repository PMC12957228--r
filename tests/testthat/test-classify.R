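test_that("class statistics match textbook formulas and handle priors", {
  gen <- generate_scene(small_scene_config(seed = 21))
  rois <- generate_rois(gen$truth, 10, 3, seed = 2)
  st <- fit_class_statistics(gen$scene, rois)
  # independent recomputation for one class
  idx <- roi_pixel_index(rois, dim(gen$scene$reflectance)[1:2])
  px <- unlist(idx[rois$class == "lint"], use.names = FALSE)
  X <- apply(gen$scene$reflectance, 3, function(m) m[px])
  mu <- colSums(X) / nrow(X)
  S <- matrix(0, 5, 5)
  for (i in seq_len(nrow(X))) S <- S + tcrossprod(X[i, ] - mu)
  S <- S / (nrow(X) - 1)
  expect_equal(unname(st$stats$lint$mean), unname(mu), tolerance = 1e-10)
  expect_equal(unname(st$stats$lint$cov), unname(S), tolerance = 1e-10)
  # count priors proportional to ROI pixels; uniform mode
  expect_equal(sum(st$priors), 1)
  stu <- fit_class_statistics(gen$scene, rois, priors = "uniform")
  expect_equal(unname(stu$priors), rep(1 / 3, 3))
})

test_that("constant ROI pixels give mean = value and a regularized covariance", {
  refl <- array(0.4, dim = c(10, 10, 5))
  scene <- structure(list(reflectance = refl,
                          band_names = c("blue", "green", "red", "red_edge", "nir"),
                          year = NA), class = "ms_scene")
  rois <- data.frame(roi_id = c("a", "b", "c"),
                     class = c("soil", "stems_leaves", "lint"),
                     row = c(1, 4, 7), col = c(1, 1, 1), size = 3)
  class(rois) <- c("roi_set", "data.frame")
  st <- fit_class_statistics(scene, rois)
  expect_equal(unname(st$stats$soil$mean), rep(0.4, 5))
  expect_gt(rcond(st$stats$soil$cov), 0)       # invertible after regularization
  expect_lt(max(abs(st$stats$soil$cov)), 1e-10) # but still near-zero
})

test_that("classes with fewer than 6 ROI pixels are rejected", {
  gen <- generate_scene(small_scene_config(seed = 22))
  rois <- generate_rois(gen$truth, 1, 2, seed = 3) # 4 px per class
  expect_error(fit_class_statistics(gen$scene, rois), "at least 6")
})

test_that("all three classifiers match their brute-force definitions", {
  for (s in 1:10) {
    st <- random_class_stats(3, seed = s)
    set.seed(1000 + s)
    X <- matrix(runif(200 * 5), 200, 5)
    scene <- as_scene(X)
    expect_equal(as.vector(classify_maximum_likelihood(scene, st)$labels),
                 unname(oracle_ml(X, st)))
    expect_equal(as.vector(classify_mahalanobis(scene, st)$labels),
                 unname(oracle_mahalanobis(X, st)))
    k <- sample(c(1, 2, 3), 1)
    expect_equal(as.vector(classify_parallelepiped(scene, st, k)$labels),
                 unname(oracle_parallelepiped(X, st, k)))
  }
})

test_that("maximum likelihood at a class mean and with identity covariances", {
  st <- random_class_stats(3, seed = 5)
  # equal priors, shared identity-scaled covariance -> nearest mean
  for (cls in st$classes) st$stats[[cls]]$cov <- diag(1e-4, 5)
  st$priors[] <- 1 / 3
  mus <- t(vapply(st$classes, function(c) st$stats[[c]]$mean, numeric(5)))
  set.seed(9)
  X <- matrix(runif(100 * 5), 100, 5)
  lab <- as.vector(classify_maximum_likelihood(as_scene(X), st)$labels)
  nearest <- apply(X, 1, function(x) which.min(colSums((t(mus) - x)^2)))
  expect_equal(lab, unname(nearest))
  # pixel exactly at a class mean -> that class
  labmu <- as.vector(classify_maximum_likelihood(as_scene(mus), st)$labels)
  expect_equal(labmu, 1:3)
})

test_that("maximum likelihood equals Mahalanobis under equal priors and shared covariance", {
  st <- random_class_stats(3, seed = 6)
  shared <- st$pooled_cov
  for (cls in st$classes) st$stats[[cls]]$cov <- shared
  st$priors[] <- 1 / 3
  set.seed(10)
  X <- matrix(runif(300 * 5), 300, 5)
  expect_equal(classify_maximum_likelihood(as_scene(X), st)$labels,
               classify_mahalanobis(as_scene(X), st)$labels)
})

test_that("parallelepiped box membership and the documented tie rule", {
  st <- random_class_stats(2, seed = 7)
  # hand-built overlapping 2-class toy: means 0.4 and 0.5, sd 0.1 everywhere
  st$stats[[1]]$mean <- rep(0.4, 5); st$stats[[1]]$cov <- diag(0.01, 5)
  st$stats[[2]]$mean <- rep(0.5, 5); st$stats[[2]]$cov <- diag(0.01, 5)
  k <- 2
  X <- rbind(rep(0.45, 5),              # inside both; nearer (std) to either equally -> class 1 (first)
             rep(0.33, 5),              # inside box 1 only (dev2 = 1.7 sd? no: |0.33-0.5|=0.17 > 0.2? no, 1.7 sd <= 2 -> inside both, closer to 1)
             rep(0.25, 5),              # 1.5 sd from class1, 2.5 sd from class2 -> class 1 only
             rep(0.75, 5),              # outside both -> unclassified
             c(0.4, 0.4, 0.4, 0.4, 0.72)) # one band breaks both boxes -> unclassified
  lab <- as.vector(classify_parallelepiped(as_scene(X), st, k)$labels)
  expect_equal(lab, c(1L, 1L, 1L, 0L, 0L))
  # multi-match resolved by smallest maximum standardized deviation
  x <- rep(0.48, 5) # 0.8 sd from class 2, 0.8 sd from... |0.48-0.4|=0.8sd, tie -> first? no: 0.08/0.1=0.8 vs 0.02/0.1=0.2 -> class 2
  lab2 <- as.vector(classify_parallelepiped(as_scene(rbind(x)), st, k)$labels)
  expect_equal(lab2, 2L)
})

test_that("boll mask extraction handles full, empty and checkerboard maps", {
  refl <- array(runif(8 * 8 * 5), dim = c(8, 8, 5))
  scene <- structure(list(reflectance = refl,
                          band_names = c("blue", "green", "red", "red_edge", "nir"),
                          year = NA), class = "ms_scene")
  mk_map <- function(labels) structure(
    list(labels = labels, classifier = "test", params = list(),
         codes = c(unclassified = 0L, soil = 1L, stems_leaves = 2L, lint = 3L)),
    class = "class_map")
  all_lint <- mk_map(matrix(3L, 8, 8))
  res <- extract_boll_mask(all_lint, scene)
  expect_true(all(res$mask))
  expect_equal(res$masked_fraction_pct, 0)
  expect_identical(res$masked_scene$reflectance, refl)

  none <- mk_map(matrix(1L, 8, 8))
  expect_warning(res0 <- extract_boll_mask(none, scene), "no lint")
  expect_false(any(res0$mask))
  expect_equal(res0$masked_fraction_pct, 100)
  expect_true(all(is.nan(res0$masked_scene$reflectance)))

  cb <- matrix(rep(c(3L, 1L), length.out = 64), 8, 8)
  resc <- extract_boll_mask(mk_map(cb), scene)
  expect_equal(sum(resc$mask), 32)
  expect_equal(sum(is.finite(resc$masked_scene$reflectance[, , 1])), 32)
})
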