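#' Pixel-level SBW prediction inside the boll mask
#'
#' For every lint pixel of the masked scene, computes the model's selected
#' vegetation indices from that single pixel's reflectance (same formulas
#' as the sampling-point features) and applies the trained model, including
#' its feature standardization. Non-mask pixels stay NaN. Note the scale
#' discrepancy documented in the methods vignette: the model is trained on
#' sampling-point mean reflectance but applied here to single-pixel
#' reflectance.
#'
#' @param masked_scene `ms_scene` from [extract_boll_mask()].
#' @param model an `sbw_model`.
#' @param L,Y,resavi_form index constants, as used for training features.
#' @return object of class `sbw_map`: `values` (matrix of per-pixel SBW in
#'   grams, NaN off-mask), `n_pixels`, and the model family.
#' @export
predict_pixel_sbw <- function(masked_scene, model, L = 0.5, Y = 0.16,
                              resavi_form = "canonical") {
  stopifnot(inherits(masked_scene, "ms_scene"), inherits(model, "sbw_model"))
  refl <- masked_scene$reflectance
  d <- dim(refl)
  Xb <- matrix(refl, d[1] * d[2], d[3])
  colnames(Xb) <- c("b", "g", "r", "re", "nir")
  mask_idx <- which(is.finite(Xb[, 1]))
  if (!length(mask_idx)) stopf("mask is empty; no lint pixels to predict")
  vi <- compute_vegetation_indices(as.data.frame(Xb[mask_idx, , drop = FALSE]),
                                   L = L, Y = Y, resavi_form = resavi_form)
  missing_feat <- setdiff(model$features, colnames(vi))
  if (length(missing_feat))
    stopf("model features not computable from bands: %s",
          paste(missing_feat, collapse = ", "))
  pred <- predict(model, vi)
  vals <- matrix(NaN, d[1], d[2])
  vals[mask_idx] <- pred
  structure(list(values = vals, n_pixels = length(mask_idx),
                 family = model$family, features = model$features),
            class = "sbw_map")
}

#' @export
print.sbw_map <- function(x, ...) {
  cat(sprintf("<sbw_map> %d x %d px, %d boll pixels, %s model, range %.2f-%.2f g\n",
              nrow(x$values), ncol(x$values), x$n_pixels, x$family,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Aggregate a pixel SBW map to plot means
#'
#' Averages the masked per-pixel predictions over the pixels inside each
#' plot polygon. Plots whose mask is empty are flagged rather than dropped.
#'
#' @param map an `sbw_map`.
#' @param plots polygon data frame (e.g. `truth$plots`).
#' @return data frame: plot identifiers, `n_boll_pixels`,
#'   `predicted_sbw_g` (NA when flagged), `flagged`.
#' @export
aggregate_to_plot <- function(map, plots) {
  stopifnot(inherits(map, "sbw_map"))
  d <- dim(map$values)
  keep <- setdiff(names(plots), c("coords", "row0", "row1", "col0", "col1"))
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    idx <- polygon_pixel_index(plots$coords[[i]], d)
    if (!length(idx)) stopf("plot polygon %d lies outside the raster extent", i)
    v <- map$values[idx]
    v <- v[is.finite(v)]
    out <- plots[i, keep, drop = FALSE]
    out$n_boll_pixels <- length(v)
    out$predicted_sbw_g <- if (length(v)) mean(v) else NA_real_
    out$flagged <- length(v) == 0
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Relative error in percent
#'
#' `100 * |predicted - observed| / observed`; the observation must be
#' strictly positive.
#'
#' @param predicted,observed numeric vectors (recycled as usual).
#' @return percent relative error per element.
#' @export
relative_error <- function(predicted, observed) {
  if (any(observed <= 0, na.rm = TRUE)) stopf("observed values must be > 0")
  100 * abs(predicted - observed) / observed
}

#' Share of pixels removed by boll masking
#'
#' `100 * (non-lint pixels) / (total pixels)` over a region (the full
#' raster by default, or a polygon).
#'
#' @param classmap a `class_map`.
#' @param region optional polygon coordinate matrix restricting the
#'   computation.
#' @return percent of background (non-lint) pixels.
#' @export
masked_fraction <- function(classmap, region = NULL) {
  stopifnot(inherits(classmap, "class_map"))
  lab <- classmap$labels
  if (is.null(region)) {
    vals <- lab
  } else {
    idx <- polygon_pixel_index(region, dim(lab))
    if (!length(idx)) stopf("region is empty or outside the raster extent")
    vals <- lab[idx]
  }
  100 * mean(vals != CLASS_CODES[["lint"]])
}
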