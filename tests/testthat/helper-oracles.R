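# Independent brute-force oracles used to check the vectorized classifiers,
# zonal statistics and SHAP attributions. These deliberately use naive
# per-element loops and textbook formulas, not the package's code paths.

# small synthetic class statistics for classifier tests
random_class_stats <- function(n_classes = 3, seed = 1) {
  set.seed(seed)
  classes <- c("soil", "stems_leaves", "lint")[seq_len(n_classes)]
  stats <- lapply(classes, function(cls) {
    A <- matrix(rnorm(25, 0, 0.05), 5, 5)
    list(mean = runif(5, 0.1, 0.9), cov = crossprod(A) + diag(1e-3, 5),
         n = sample(20:60, 1))
  })
  names(stats) <- classes
  n <- vapply(stats, `[[`, 1, "n")
  pooled <- Reduce(`+`, Map(function(s, w) w * s$cov, stats, n / sum(n)))
  structure(list(classes = classes, stats = stats, priors = n / sum(n),
                 pooled_cov = pooled, priors_mode = "counts"),
            class = "class_statistics")
}

# wrap a pixel matrix as an ms_scene (one row of pixels)
as_scene <- function(X) {
  n <- nrow(X)
  refl <- aperm(array(X, dim = c(n, 1, 5)), c(2, 1, 3))
  structure(list(reflectance = refl,
                 band_names = c("blue", "green", "red", "red_edge", "nir"),
                 year = NA), class = "ms_scene")
}

oracle_ml <- function(X, st) {
  apply(X, 1, function(x) {
    lp <- vapply(st$classes, function(cls) {
      s <- st$stats[[cls]]
      d <- x - s$mean
      log(st$priors[[cls]]) - 0.5 * log(det(s$cov)) -
        0.5 * drop(t(d) %*% solve(s$cov) %*% d)
    }, numeric(1))
    which(lp == max(lp))[1]
  })
}

oracle_mahalanobis <- function(X, st) {
  Sinv <- solve(st$pooled_cov)
  apply(X, 1, function(x) {
    d2 <- vapply(st$classes, function(cls) {
      d <- x - st$stats[[cls]]$mean
      drop(t(d) %*% Sinv %*% d)
    }, numeric(1))
    which(d2 == min(d2))[1]
  })
}

oracle_parallelepiped <- function(X, st, k) {
  apply(X, 1, function(x) {
    devs <- vapply(st$classes, function(cls) {
      s <- st$stats[[cls]]
      sd_b <- sqrt(diag(s$cov))
      max(abs(x - s$mean) / sd_b)
    }, numeric(1))
    inside <- which(devs <= k)
    if (!length(inside)) 0L else inside[which.min(devs[inside])]
  })
}

# independent vegetation-index formulas (plain transliteration, scalar)
oracle_indices <- function(b, g, r, re, nir, L = 0.5, Y = 0.16) {
  c(DVI = nir - r,
    REDVI = nir - re,
    NDVI = (nir - r) / (nir + r),
    RTVI = 100 * (nir - re) - 10 * (nir - g),
    EVI = 2.5 * (nir - r) / (nir + 6 * r - 7.5 * b + 1),
    SAVI = (1 + L) * (nir - r) / (nir + r + L),
    RESAVI = (1 + L) * (nir - re) / (nir + re + L),
    OSAVI = (1 + Y) * (nir - r) / (nir + r + Y),
    REOSAVI = (1 + Y) * (nir - re) / (nir + re + Y),
    RDVI = (nir - r) / sqrt(nir + r),
    RERDVI = (nir - re) / sqrt(nir + re),
    NLI = (nir^2 - r) / (nir^2 + r),
    NLVI = (re^2 - r) / (re^2 + r),
    TVI = 60 * (nir - g) - 100 * (r - g),
    MSR = (nir / r - 1) / (sqrt(nir / r) + 1))
}

# ---- exact Shapley values for an xgboost model (path-dependent value fn) ----

# expected tree output when only features in S are known, marginalizing the
# rest with the training-cover weights recorded in the dump
tree_expectation <- function(tr, x, S) {
  walk <- function(id) {
    row <- tr[tr$ID == id, ]
    if (row$Feature == "Leaf") return(row$Gain)
    f <- row$Feature
    if (f %in% S) {
      nxt <- if (x[[f]] < row$Split) row$Yes else row$No
      return(walk(nxt))
    }
    cy <- tr$Cover[tr$ID == row$Yes]; cn <- tr$Cover[tr$ID == row$No]
    (cy * walk(row$Yes) + cn * walk(row$No)) / (cy + cn)
  }
  walk(tr$ID[tr$Node == 0][1])
}

exact_shapley <- function(bst, x, features) {
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = bst))
  trees <- split(dump, dump$Tree)
  v <- function(S) sum(vapply(trees, tree_expectation, numeric(1), x = x, S = S))
  p <- length(features)
  phi <- setNames(numeric(p), features)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (j in seq_len(p)) {
    for (si in seq_len(nrow(subsets))) {
      inc <- as.logical(subsets[si, ])
      if (inc[j]) next
      S <- features[inc]
      wt <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[j] <- phi[j] + wt * (v(c(S, features[j])) - v(S))
    }
  }
  phi
}
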