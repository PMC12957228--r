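VI_NAMES <- c("DVI", "REDVI", "NDVI", "RTVI", "EVI", "SAVI", "RESAVI", "OSAVI",
              "REOSAVI", "RDVI", "RERDVI", "NLI", "NLVI", "TVI", "MSR")

#' Compute the fifteen vegetation indices
#'
#' Evaluates, from band reflectance, the fifteen-index spectral feature pool
#' spanning difference, normalized-difference, soil-adjusted, triangular,
#' non-linear and ratio families:
#' \deqn{DVI = nir - r,\quad REDVI = nir - re,\quad NDVI = (nir-r)/(nir+r)}
#' \deqn{RTVI = 100(nir-re) - 10(nir-g),\quad EVI = 2.5(nir-r)/(nir+6r-7.5b+1)}
#' \deqn{SAVI = (1+L)(nir-r)/(nir+r+L),\quad RESAVI = (1+L)(nir-re)/(nir+re+L)}
#' \deqn{OSAVI = (1+Y)(nir-r)/(nir+r+Y),\quad REOSAVI = (1+Y)(nir-re)/(nir+re+Y)}
#' \deqn{RDVI = (nir-r)/\sqrt{nir+r},\quad RERDVI = (nir-re)/\sqrt{nir+re}}
#' \deqn{NLI = (nir^2-r)/(nir^2+r),\quad NLVI = (re^2-r)/(re^2+r)}
#' \deqn{TVI = 60(nir-g) - 100(r-g),\quad MSR = (nir/r-1)/(\sqrt{nir/r}+1)}
#' with soil-adjustment constants `L = 0.5` and `Y = 0.16`.
#'
#' The red-edge soil-adjusted index also has a product form
#' `(1+L) * (nir-r)/(nir+r+L) * (nir-re)/(nir+re)` selectable with
#' `resavi_form = "product"`; the canonical red-edge substitution is the
#' default.
#'
#' @param bands data frame or matrix with columns `b`, `g`, `r`, `re`,
#'   `nir` (reflectance in [0, 1]); a single named vector is also accepted.
#' @param L,Y soil-adjustment constants (defaults 0.5 and 0.16).
#' @param resavi_form `"canonical"` (default) or `"product"`.
#' @return matrix with one row per input row and the 15 index columns.
#'   Rows with a zero denominator yield NA in the affected index, with a
#'   warning (never a silent infinity).
#' @export
compute_vegetation_indices <- function(bands, L = 0.5, Y = 0.16,
                                       resavi_form = c("canonical", "product")) {
  resavi_form <- match.arg(resavi_form)
  if (is.null(dim(bands))) bands <- as.data.frame(as.list(bands))
  bands <- as.data.frame(bands)
  need <- c("b", "g", "r", "re", "nir")
  if (!all(need %in% names(bands))) stopf("bands must contain columns %s",
                                          paste(need, collapse = ", "))
  b <- bands$b; g <- bands$g; r <- bands$r; re <- bands$re; nir <- bands$nir

  safe_div <- function(num, den, nm) {
    bad <- is.finite(den) & den == 0
    if (any(bad, na.rm = TRUE)) {
      warnf("%s: zero denominator in %d record(s); flagged NA", nm, sum(bad))
      den[bad] <- NA_real_
    }
    num / den
  }

  out <- cbind(
    DVI = nir - r,
    REDVI = nir - re,
    NDVI = safe_div(nir - r, nir + r, "NDVI"),
    RTVI = 100 * (nir - re) - 10 * (nir - g),
    EVI = safe_div(2.5 * (nir - r), nir + 6 * r - 7.5 * b + 1, "EVI"),
    SAVI = safe_div((1 + L) * (nir - r), nir + r + L, "SAVI"),
    RESAVI = if (resavi_form == "canonical") {
      safe_div((1 + L) * (nir - re), nir + re + L, "RESAVI")
    } else {
      safe_div((1 + L) * (nir - r), nir + r + L, "RESAVI") *
        safe_div(nir - re, nir + re, "RESAVI")
    },
    OSAVI = safe_div((1 + Y) * (nir - r), nir + r + Y, "OSAVI"),
    REOSAVI = safe_div((1 + Y) * (nir - re), nir + re + Y, "REOSAVI"),
    RDVI = safe_div(nir - r, sqrt(pmax(nir + r, 0)), "RDVI"),
    RERDVI = safe_div(nir - re, sqrt(pmax(nir + re, 0)), "RERDVI"),
    NLI = safe_div(nir^2 - r, nir^2 + r, "NLI"),
    NLVI = safe_div(re^2 - r, re^2 + r, "NLVI"),
    TVI = 60 * (nir - g) - 100 * (r - g),
    MSR = safe_div(nir / pmax(r, .Machine$double.xmin) - 1,
                   sqrt(pmax(nir / pmax(r, .Machine$double.xmin), 0)) + 1, "MSR")
  )
  rr <- r
  if (any(is.finite(rr) & rr == 0)) {
    warnf("MSR: zero red reflectance in %d record(s); flagged NA", sum(rr == 0))
    out[which(rr == 0), "MSR"] <- NA_real_
  }
  out
}

#' Mean boll-pixel reflectance per sampling-point polygon
#'
#' For each polygon, averages the masked (lint-only) reflectance of the
#' pixels whose centers fall inside it, per band. Polygons containing no
#' lint pixel yield a record flagged invalid rather than an error, so a
#' plot with a failed extraction does not abort the pipeline.
#'
#' @param masked_scene `ms_scene` with non-lint pixels set to NaN, from
#'   [extract_boll_mask()].
#' @param polygons polygon data frame (e.g. `truth$sampling_points`): one
#'   row per polygon with a `coords` list-column and identifier columns.
#' @return data frame: identifier columns, band means `b`, `g`, `r`, `re`,
#'   `nir`, `n_pixels` (lint pixels contributing) and `valid`.
#' @export
zonal_mean_reflectance <- function(masked_scene, polygons) {
  stopifnot(inherits(masked_scene, "ms_scene"))
  refl <- masked_scene$reflectance
  d <- dim(refl)
  npx <- d[1] * d[2]
  Xb <- matrix(refl, npx, d[3])
  keep <- setdiff(names(polygons), c("coords", "row0", "row1", "col0", "col1"))
  rows <- lapply(seq_len(nrow(polygons)), function(i) {
    idx <- polygon_pixel_index(polygons$coords[[i]], d[1:2])
    if (length(idx) == 0 || any(idx < 1 | idx > npx))
      stopf("polygon %d lies outside the raster extent", i)
    vals <- Xb[idx, , drop = FALSE]
    ok <- is.finite(vals[, 1])
    out <- polygons[i, keep, drop = FALSE]
    if (!any(ok)) {
      out[, c("b", "g", "r", "re", "nir")] <- NA_real_
      out$n_pixels <- 0L; out$valid <- FALSE
    } else {
      m <- colMeans(vals[ok, , drop = FALSE])
      out[, c("b", "g", "r", "re", "nir")] <- as.list(m)
      out$n_pixels <- sum(ok); out$valid <- TRUE
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Assemble the per-sampling-point modeling table
#'
#' Joins zonal band means with the measured-SBW table on `sample_id`,
#' computes the 15 vegetation indices from each record's band means (not
#' per-pixel), and drops records that are invalid (no lint pixels) or lack
#' an SBW measurement, with a logged count.
#'
#' @param band_means output of [zonal_mean_reflectance()].
#' @param sbw_table data frame with `sample_id` and `sbw_g` (plus any
#'   treatment tags not already carried by `band_means`).
#' @param L,Y,resavi_form passed to [compute_vegetation_indices()].
#' @return data frame of class `sample_table`: identifiers, treatment tags,
#'   band means, 15 indices, `sbw_g`.
#' @export
build_sample_table <- function(band_means, sbw_table, L = 0.5, Y = 0.16,
                               resavi_form = "canonical") {
  if (anyDuplicated(band_means$sample_id)) stopf("duplicate sample_id in band means")
  if (anyDuplicated(sbw_table$sample_id)) stopf("duplicate sample_id in SBW table")
  extra <- setdiff(names(sbw_table), c(names(band_means), "q_latent"))
  tab <- merge(band_means, sbw_table[, c("sample_id", extra)],
               by = "sample_id", sort = FALSE)
  n_in <- nrow(band_means)
  drop_invalid <- !tab$valid
  drop_missing <- is.na(tab$sbw_g)
  n_drop <- sum(drop_invalid | drop_missing) + (n_in - nrow(tab))
  if (n_drop > 0)
    warnf("build_sample_table: dropped %d of %d sampling points (no lint pixels or missing SBW)",
          n_drop, n_in)
  tab <- tab[!(drop_invalid | drop_missing), , drop = FALSE]
  if (!nrow(tab)) stopf("no valid sampling-point records remain")
  vi <- compute_vegetation_indices(tab[, c("b", "g", "r", "re", "nir")],
                                   L = L, Y = Y, resavi_form = resavi_form)
  tab <- cbind(tab, vi)
  rownames(tab) <- NULL
  class(tab) <- c("sample_table", "data.frame")
  tab
}
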