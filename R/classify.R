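#' Fit per-class training statistics from ROI pixels
#'
#' Computes, for each of the three classes, the unbiased sample mean vector
#' and covariance matrix of its ROI pixels in the five bands, the pixel
#' count, and a prior (proportional to ROI pixel counts, or uniform), plus
#' the count-weighted pooled covariance. Near-singular covariances are
#' regularized by adding `lambda * I` with
#' `lambda = 1e-6 * trace(Sigma) / 5` (plus a tiny absolute floor so a
#' constant-valued class still yields an invertible matrix).
#'
#' @param scene an `ms_scene`.
#' @param rois an `roi_set` of training regions.
#' @param priors `"counts"` (default) or `"uniform"`.
#' @return object of class `class_statistics`: per class `mean` (5), `cov`
#'   (5 x 5), `n`, `prior`; and `pooled_cov`.
#' @export
fit_class_statistics <- function(scene, rois, priors = c("counts", "uniform")) {
  priors <- match.arg(priors)
  stopifnot(inherits(scene, "ms_scene"))
  X <- pixel_matrix(scene$reflectance)
  if (any(!is.finite(X))) stopf("scene contains non-finite reflectance")
  idx <- roi_pixel_index(rois, dim(scene$reflectance)[1:2])
  classes <- CLASS_NAMES[CLASS_NAMES %in% unique(rois$class)]
  stats_list <- lapply(classes, function(cls) {
    px <- unlist(idx[rois$class == cls], use.names = FALSE)
    if (length(px) < 6)
      stopf("class '%s' has %d ROI pixels; at least 6 (more than the 5 bands) required",
            cls, length(px))
    Xc <- X[px, , drop = FALSE]
    S <- stats::cov(Xc)
    S <- regularize_cov(S)
    list(mean = colMeans(Xc), cov = S, n = length(px))
  })
  names(stats_list) <- classes
  n <- vapply(stats_list, `[[`, 1, "n")
  pr <- if (priors == "counts") n / sum(n) else rep(1 / length(n), length(n))
  names(pr) <- classes
  pooled <- Reduce(`+`, Map(function(s, w) w * s$cov, stats_list, n / sum(n)))
  pooled <- regularize_cov(pooled)
  structure(list(classes = classes, stats = stats_list, priors = pr,
                 pooled_cov = pooled, priors_mode = priors),
            class = "class_statistics")
}

regularize_cov <- function(S) {
  if (rcond(S) < 1e-10) {
    lambda <- 1e-6 * sum(diag(S)) / ncol(S) + 1e-12
    S <- S + diag(lambda, ncol(S))
  }
  S
}

new_class_map <- function(codes, dim, classifier, params = list()) {
  m <- matrix(as.integer(codes), dim[1], dim[2])
  structure(list(labels = m, classifier = classifier, params = params,
                 codes = c(unclassified = UNCLASSIFIED_CODE, CLASS_CODES)),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(0:3),
                      labels = c("unclassified", CLASS_NAMES)))
  cat(sprintf("<class_map> %s, %d x %d px\n", x$classifier,
              nrow(x$labels), ncol(x$labels)))
  print(tab)
  invisible(x)
}

#' Maximum likelihood classification
#'
#' Gaussian maximum likelihood: each pixel `x` is assigned to the class
#' maximizing the log-posterior
#' `ln pi_c - 0.5 ln|Sigma_c| - 0.5 (x - mu_c)' Sigma_c^-1 (x - mu_c)`.
#' Every pixel receives a label; ties are broken in favour of the smallest
#' class index (soil < stems_leaves < lint).
#'
#' @param scene an `ms_scene`.
#' @param stats a `class_statistics`.
#' @return a `class_map`.
#' @export
classify_maximum_likelihood <- function(scene, stats) {
  X <- pixel_matrix(scene$reflectance)
  sc <- vapply(stats$classes, function(cls) {
    s <- stats$stats[[cls]]
    Sinv <- solve(s$cov)
    delta <- sweep(X, 2, s$mean)
    quad <- rowSums((delta %*% Sinv) * delta)
    log(stats$priors[[cls]]) - 0.5 * determinant(s$cov)$modulus[1] - 0.5 * quad
  }, numeric(nrow(X)))
  if (!is.matrix(sc)) sc <- matrix(sc, nrow = 1)
  lab <- CLASS_CODES[stats$classes][max.col(sc, ties.method = "first")]
  new_class_map(lab, dim(scene$reflectance)[1:2], "maximum_likelihood",
                list(priors = stats$priors_mode))
}

#' Mahalanobis distance classification
#'
#' Assigns each pixel to the class whose mean is nearest in Mahalanobis
#' distance under the pooled covariance,
#' `argmin_c (x - mu_c)' Sigma_pooled^-1 (x - mu_c)`. Ties are broken in
#' favour of the smallest class index.
#'
#' @inheritParams classify_maximum_likelihood
#' @return a `class_map`.
#' @export
classify_mahalanobis <- function(scene, stats) {
  X <- pixel_matrix(scene$reflectance)
  Sinv <- solve(stats$pooled_cov)
  d2 <- vapply(stats$classes, function(cls) {
    delta <- sweep(X, 2, stats$stats[[cls]]$mean)
    rowSums((delta %*% Sinv) * delta)
  }, numeric(nrow(X)))
  if (!is.matrix(d2)) d2 <- matrix(d2, nrow = 1)
  lab <- CLASS_CODES[stats$classes][max.col(-d2, ties.method = "first")]
  new_class_map(lab, dim(scene$reflectance)[1:2], "mahalanobis")
}

#' Parallelepiped classification
#'
#' A pixel matches class `c` when its value in every band lies within
#' `mu_cb +/- k * sigma_cb` (per-band standard deviation). Pixels matching
#' no class remain unclassified; a pixel matching several classes is given
#' the class with the smallest maximum standardized deviation
#' `max_b |x_b - mu_cb| / sigma_cb`.
#'
#' @inheritParams classify_maximum_likelihood
#' @param k box half-width in per-band standard deviations (default 2).
#' @return a `class_map`, possibly containing unclassified pixels (code 0).
#' @export
classify_parallelepiped <- function(scene, stats, k = 2) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stopf("k must be a positive scalar")
  X <- pixel_matrix(scene$reflectance)
  maxdev <- vapply(stats$classes, function(cls) {
    s <- stats$stats[[cls]]
    sd_b <- sqrt(diag(s$cov))
    if (any(sd_b == 0)) {
      warnf("class '%s' has a zero per-band standard deviation; floored to machine epsilon", cls)
      sd_b[sd_b == 0] <- .Machine$double.eps
    }
    Z <- sweep(abs(sweep(X, 2, s$mean)), 2, sd_b, "/") # |x_b - mu_cb| / sigma_cb
    do.call(pmax, lapply(seq_len(ncol(Z)), function(b) Z[, b]))
  }, numeric(nrow(X)))
  if (!is.matrix(maxdev)) maxdev <- matrix(maxdev, nrow = 1)
  inside <- maxdev <= k
  maxdev[!inside] <- Inf
  lab <- CLASS_CODES[stats$classes][max.col(-maxdev, ties.method = "first")]
  lab[!rowSums(inside)] <- UNCLASSIFIED_CODE
  new_class_map(lab, dim(scene$reflectance)[1:2], "parallelepiped", list(k = k))
}

#' Extract the lint (boll) mask and masked reflectance
#'
#' Converts the lint class of a classification into a boolean mask and
#' applies it to the scene: reflectance is kept where the mask is TRUE and
#' set to NaN elsewhere.
#'
#' @param classmap a `class_map`.
#' @param scene the `ms_scene` the map was derived from.
#' @return list with `mask` (logical matrix), `masked_scene` (an `ms_scene`
#'   whose non-lint pixels are NaN), and `masked_fraction_pct` (share of
#'   pixels removed, %).
#' @export
extract_boll_mask <- function(classmap, scene) {
  stopifnot(inherits(classmap, "class_map"), inherits(scene, "ms_scene"))
  mask <- classmap$labels == CLASS_CODES[["lint"]]
  if (!any(mask)) warnf("classification contains no lint pixels; mask is empty")
  refl <- scene$reflectance
  nanv <- array(rep(as.vector(!mask), dim(refl)[3]), dim = dim(refl))
  refl[nanv] <- NaN
  masked <- structure(list(reflectance = refl, band_names = scene$band_names,
                           year = scene$year), class = "ms_scene")
  list(mask = mask, masked_scene = masked,
       masked_fraction_pct = 100 * mean(!mask))
}
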