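#' Default class-conditional band spectra
#'
#' Per-class mean and standard deviation of reflectance in the five bands
#' (blue, green, red, red-edge, NIR). Soil is bright and spectrally flat;
#' senescent stems/leaves are dark in the red with moderate NIR; opened-boll
#' lint is the brightest class in the visible bands and near-flat across the
#' spectrum, which is what makes the lint/soil separation non-trivial for
#' box classifiers.
#'
#' @return list with `mean` and `sd`, each a 3 x 5 matrix
#'   (classes x bands, reflectance units).
#' @export
default_class_spectra <- function() {
  mean <- rbind(
    soil         = c(0.18, 0.22, 0.26, 0.28, 0.30),
    stems_leaves = c(0.05, 0.09, 0.07, 0.18, 0.35),
    lint         = c(0.45, 0.47, 0.48, 0.50, 0.52)
  )
  sd <- matrix(0.02, 3, 5, dimnames = dimnames(mean))
  colnames(mean) <- colnames(sd) <- BAND_NAMES
  list(mean = mean, sd = sd)
}

#' Configuration for the synthetic cotton-trial scene generator
#'
#' Describes a single-year multispectral scene of a density x variety cotton
#' trial: a rectangular plot grid (default 6 x 8 = 48 plots; five planting
#' densities D1-D5; varieties V1-V3 plus a check variety CK grown only at
#' D5; three replicates), class-conditional band distributions for soil,
#' stems/leaves and lint, a density-dependent lint pixel fraction, and a
#' linear latent link from per-plot boll quality to single-boll weight (SBW).
#'
#' Each plot carries a latent boll quality `q` drawn uniformly from a
#' density-specific window (higher density -> lower window), so SBW declines
#' with planting density while remaining recoverable from lint spectra:
#' the lint-class red-edge and NIR means are shifted upward by
#' `q * nir_rededge_offset` and sampling-point SBW is
#' `sbw_intercept_g + sbw_slope_g * q * nir_rededge_offset + N(0, sbw_noise_sd_g^2)`
#' truncated to positive values.
#'
#' @param height,width raster size in pixels.
#' @param plot_rows,plot_cols plot grid shape; `plot_rows * plot_cols` plots.
#' @param class_spectra list with 3 x 5 `mean` and `sd` matrices, see
#'   [default_class_spectra()].
#' @param sigma_scale multiplier on all class standard deviations; values
#'   around 4 produce heavily overlapping classes.
#' @param lint_fraction_by_density named fraction of in-plot pixels that are
#'   lint, per density D1-D5, each in (0, 1).
#' @param q_window_by_density 5 x 2 matrix (rows D1-D5) of lower/upper bounds
#'   of the uniform latent-quality window.
#' @param sbw_intercept_g,sbw_slope_g,sbw_noise_sd_g SBW link: intercept (g),
#'   slope (g per reflectance unit), residual standard deviation (g).
#' @param nir_rededge_offset maximum reflectance offset added to the lint
#'   red-edge/NIR means at `q = 1` (reflectance units).
#' @param plot_margin pixels of soil border inside each grid cell.
#' @param stripe_width,stripe_gap width/spacing (pixels) of the vertical
#'   stems/leaves row stripes mimicking the mulch-row planting pattern.
#' @param year year label attached to plots and samples.
#' @param seed integer seed; the whole scene is deterministic given the seed.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(height = 384, width = 512,
                         plot_rows = 6, plot_cols = 8,
                         class_spectra = default_class_spectra(),
                         sigma_scale = 1,
                         lint_fraction_by_density = c(D1 = 0.06, D2 = 0.08, D3 = 0.10,
                                                      D4 = 0.12, D5 = 0.14),
                         q_window_by_density = cbind(lo = c(0.5, 0.4, 0.3, 0.2, 0.1),
                                                     hi = c(1.0, 0.9, 0.8, 0.7, 0.6)),
                         sbw_intercept_g = 4.5, sbw_slope_g = 25,
                         sbw_noise_sd_g = 0.215,
                         nir_rededge_offset = 0.10,
                         plot_margin = 4, stripe_width = 4, stripe_gap = 6,
                         year = 2023, seed = 1) {
  if (!is_count(height) || !is_count(width)) stopf("height/width must be positive integers")
  if (!is_count(plot_rows) || !is_count(plot_cols)) stopf("plot grid must be positive integers")
  sp <- class_spectra
  if (!all(dim(sp$mean) == c(3, 5)) || !all(dim(sp$sd) == c(3, 5)))
    stopf("class_spectra must hold 3 x 5 mean and sd matrices")
  if (any(sp$sd < 0)) stopf("class spectral standard deviations must be >= 0")
  if (any(sp$mean < 0 | sp$mean > 1)) stopf("class band means must lie in [0, 1]")
  lf <- lint_fraction_by_density
  if (length(lf) != 5 || any(!is.finite(lf)) || any(lf < 0) || any(lf >= 1))
    stopf("lint_fraction_by_density must give five fractions in [0, 1)")
  if (is.null(names(lf))) names(lf) <- paste0("D", 1:5)
  qw <- q_window_by_density
  if (!all(dim(qw) == c(5, 2)) || any(qw < 0) || any(qw > 1) || any(qw[, 1] >= qw[, 2]))
    stopf("q_window_by_density must be a 5 x 2 matrix of [0,1] windows with lo < hi")
  if (sbw_noise_sd_g < 0) stopf("sbw_noise_sd_g must be >= 0")
  if (sigma_scale <= 0) stopf("sigma_scale must be > 0")
  if (nir_rededge_offset < 0) stopf("nir_rededge_offset must be >= 0")
  cell_h <- height %/% plot_rows; cell_w <- width %/% plot_cols
  if (cell_h - 2 * plot_margin < 9 || cell_w - 2 * plot_margin < 9)
    stopf("plots are degenerate: grid cells of %d x %d pixels leave no usable plot interior",
          cell_h, cell_w)
  structure(list(
    height = as.integer(height), width = as.integer(width),
    plot_rows = as.integer(plot_rows), plot_cols = as.integer(plot_cols),
    band_names = BAND_NAMES, class_spectra = sp, sigma_scale = sigma_scale,
    lint_fraction_by_density = lf, q_window_by_density = qw,
    sbw_intercept_g = sbw_intercept_g, sbw_slope_g = sbw_slope_g,
    sbw_noise_sd_g = sbw_noise_sd_g, nir_rededge_offset = nir_rededge_offset,
    plot_margin = as.integer(plot_margin), stripe_width = as.integer(stripe_width),
    stripe_gap = as.integer(stripe_gap), year = year, seed = as.integer(seed)
  ), class = "scene_config")
}

# treatment table of the emulated trial: V1-V3 x D1-D5 plus CK at D5 only,
# three replicates -> 48 plots
trial_treatments <- function() {
  tr <- expand.grid(variety = c("V1", "V2", "V3"), density = paste0("D", 1:5),
                    stringsAsFactors = FALSE)
  tr <- rbind(tr, data.frame(variety = "CK", density = "D5"))
  tr[rep(seq_len(nrow(tr)), each = 3), ]
}

#' Generate a synthetic multispectral cotton scene with ground truth
#'
#' Builds a five-band reflectance raster plus per-pixel class labels, plot
#' and sampling-point polygons, and a per-sampling-point SBW table, with the
#' statistical structure described in [scene_config()]. Soil fills the
#' background; stems/leaves form vertical row stripes inside each plot; lint
#' appears as small blobs (2-4 px across, emulating opened bolls at ~2 cm
#' ground sampling distance) centred on the stripes, at the density's lint
#' fraction of in-plot pixels. Pixel band values are drawn from the
#' class-conditional normals, clipped to [0, 1].
#'
#' @param config a [scene_config()].
#' @return list with `scene` (class `ms_scene`: `reflectance` array height x
#'   width x 5, `band_names`, `year`) and `truth` (class `ground_truth`:
#'   `label_raster` integer matrix with codes 1 = soil, 2 = stems_leaves,
#'   3 = lint; `plots` and `sampling_points` polygon data frames; `sbw` table
#'   with one row per sampling point).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  cf <- config
  set.seed(cf$seed)
  h <- cf$height; w <- cf$width
  n_plots <- cf$plot_rows * cf$plot_cols
  treatments <- trial_treatments()
  if (nrow(treatments) != n_plots)
    stopf("plot grid (%d plots) must match the 48-plot trial design", n_plots)
  treatments <- treatments[sample.int(n_plots), ]
  plot_subseeds <- sample.int(.Machine$integer.max, n_plots)

  cell_h <- h %/% cf$plot_rows; cell_w <- w %/% cf$plot_cols
  m <- cf$plot_margin
  label <- matrix(CLASS_CODES[["soil"]], h, w)
  qmap <- matrix(0, h, w)

  plots <- vector("list", n_plots)
  spoints <- vector("list", n_plots * 3L)
  sbw_rows <- vector("list", n_plots * 3L)
  plot_q <- numeric(n_plots)

  for (p in seq_len(n_plots)) {
    set.seed(plot_subseeds[p])
    gi <- (p - 1L) %/% cf$plot_cols; gj <- (p - 1L) %% cf$plot_cols
    r0 <- gi * cell_h + m + 1L; r1 <- (gi + 1L) * cell_h - m
    c0 <- gj * cell_w + m + 1L; c1 <- (gj + 1L) * cell_w - m
    density <- treatments$density[p]; variety <- treatments$variety[p]
    d_idx <- match(density, paste0("D", 1:5))
    q <- stats::runif(1, cf$q_window_by_density[d_idx, 1], cf$q_window_by_density[d_idx, 2])
    plot_q[p] <- q

    # stems/leaves row stripes
    period <- cf$stripe_width + cf$stripe_gap
    stripe_cols <- c0:c1
    stripe_cols <- stripe_cols[((stripe_cols - c0) %% period) < cf$stripe_width]
    label[r0:r1, stripe_cols] <- CLASS_CODES[["stems_leaves"]]

    # lint blobs on the stripes until the density's pixel budget is met
    inner_area <- (r1 - r0 + 1L) * (c1 - c0 + 1L)
    target <- round(cf$lint_fraction_by_density[[density]] * inner_area)
    lint_px <- integer(0)
    guard <- 0L
    while (length(lint_px) < target && guard < 50000L) {
      guard <- guard + 1L
      s <- sample(2:4, 1L)
      cc <- sample(stripe_cols, 1L); rr <- sample(r0:r1, 1L)
      rs <- rr:min(rr + s - 1L, r1); cs <- cc:min(cc + s - 1L, c1)
      blob <- as.integer(outer(rs, (cs - 1L) * h, "+"))
      blob <- setdiff(blob, lint_px)
      need <- target - length(lint_px)
      if (length(blob) > need) blob <- blob[seq_len(need)]
      lint_px <- c(lint_px, blob)
    }
    label[lint_px] <- CLASS_CODES[["lint"]]
    qmap[r0:r1, c0:c1] <- q

    plot_id <- sprintf("P%02d", p)
    plots[[p]] <- list(
      plot_id = plot_id, density = density, variety = variety, year = cf$year,
      row0 = r0, row1 = r1, col0 = c0, col1 = c1,
      coords = rect_coords(r0, r1, c0, c1)
    )

    # three sampling points: vertical thirds of the plot interior
    sp_w <- (c1 - c0 + 1L) %/% 3L
    for (s3 in 1:3) {
      sc0 <- c0 + (s3 - 1L) * sp_w
      sc1 <- if (s3 == 3L) c1 else sc0 + sp_w - 1L
      sid <- sprintf("%s_%s_S%d", cf$year, plot_id, s3)
      spoints[[(p - 1L) * 3L + s3]] <- list(
        sample_id = sid, plot_id = plot_id, density = density, variety = variety,
        year = cf$year, row0 = r0, row1 = r1, col0 = sc0, col1 = sc1,
        coords = rect_coords(r0, r1, sc0, sc1)
      )
      repeat {
        sbw <- cf$sbw_intercept_g + cf$sbw_slope_g * q * cf$nir_rededge_offset +
          stats::rnorm(1, 0, cf$sbw_noise_sd_g)
        if (sbw > 0) break
      }
      sbw_rows[[(p - 1L) * 3L + s3]] <- data.frame(
        sample_id = sid, plot_id = plot_id, density = density, variety = variety,
        year = cf$year, sbw_g = sbw, q_latent = q, stringsAsFactors = FALSE
      )
    }
  }

  # draw reflectance for every pixel from its class distribution
  set.seed(plot_subseeds[1L] %% 1000003L + 7L)
  mu <- cf$class_spectra$mean; sig <- cf$class_spectra$sd * cf$sigma_scale
  reflectance <- array(0, dim = c(h, w, 5L), dimnames = list(NULL, NULL, BAND_NAMES))
  lab_vec <- as.vector(label)
  for (b in 1:5) {
    mean_b <- mu[lab_vec, b]
    if (b >= 4L) { # red-edge and NIR of lint carry the boll-quality signal
      shift <- as.vector(qmap) * cf$nir_rededge_offset * (lab_vec == CLASS_CODES[["lint"]])
      mean_b <- mean_b + shift
    }
    vals <- stats::rnorm(h * w, mean_b, sig[lab_vec, b])
    reflectance[, , b] <- pmin(pmax(vals, 0), 1)
  }

  scene <- structure(list(reflectance = reflectance, band_names = BAND_NAMES,
                          year = cf$year), class = "ms_scene")
  truth <- structure(list(
    label_raster = label,
    plots = polygon_frame(plots),
    sampling_points = polygon_frame(spoints),
    sbw = do.call(rbind, sbw_rows),
    plot_q = stats::setNames(plot_q, vapply(plots, `[[`, "", "plot_id")),
    config = cf
  ), class = "ground_truth")
  list(scene = scene, truth = truth)
}

# store rectangles as a data frame with a list-column of polygon coords
polygon_frame <- function(lst) {
  df <- do.call(rbind, lapply(lst, function(x) {
    as.data.frame(x[setdiff(names(x), "coords")], stringsAsFactors = FALSE)
  }))
  df$coords <- lapply(lst, `[[`, "coords")
  df
}

#' @export
print.ms_scene <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<ms_scene> %d x %d pixels, %d bands (%s), year %s\n",
              d[1], d[2], d[3], paste(x$band_names, collapse = "/"),
              as.character(x$year %||% "?")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample label-pure square training ROIs from ground truth
#'
#' Emulates manual delineation of training regions of interest: for each of
#' the three classes, `n_per_class` square ROIs of side `roi_size` whose
#' pixels all carry the ROI's class label, spread across the plot grid
#' (round-robin over grid cells) and non-overlapping.
#'
#' @param truth `ground_truth` from [generate_scene()].
#' @param n_per_class ROIs per class (default 20).
#' @param roi_size ROI side length in pixels (default 3).
#' @param seed integer seed.
#' @return data frame of class `roi_set`: `roi_id`, `class`, `row`, `col`
#'   (top-left pixel), `size`.
#' @export
generate_rois <- function(truth, n_per_class = 20, roi_size = 3, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(seed)
  lab <- truth$label_raster
  h <- nrow(lab); w <- ncol(lab)
  cell_h <- h %/% truth$config$plot_rows; cell_w <- w %/% truth$config$plot_cols
  out <- list()
  for (cls in CLASS_NAMES) {
    pos <- pure_window_positions(lab == CLASS_CODES[[cls]], roi_size)
    if (nrow(pos) < n_per_class)
      stopf("class '%s' has only %d pure %dx%d windows; %d ROIs requested",
            cls, nrow(pos), roi_size, roi_size, n_per_class)
    pos <- pos[sample.int(nrow(pos)), , drop = FALSE]
    cell <- (pos[, "row"] - 1L) %/% cell_h * truth$config$plot_cols +
      (pos[, "col"] - 1L) %/% cell_w
    picked <- matrix(NA_integer_, 0, 2)
    taken <- matrix(FALSE, h, w)
    queue <- split(seq_len(nrow(pos)), cell)
    ptr <- 1L
    while (nrow(picked) < n_per_class && length(queue)) {
      qi <- ((ptr - 1L) %% length(queue)) + 1L
      ptr <- ptr + 1L
      while (length(queue[[qi]])) {
        i <- queue[[qi]][1L]; queue[[qi]] <- queue[[qi]][-1L]
        r <- pos[i, "row"]; c <- pos[i, "col"]
        block <- taken[r:(r + roi_size - 1L), c:(c + roi_size - 1L)]
        if (!any(block)) {
          taken[r:(r + roi_size - 1L), c:(c + roi_size - 1L)] <- TRUE
          picked <- rbind(picked, c(r, c))
          break
        }
      }
      queue <- queue[vapply(queue, length, 1L) > 0]
      if (!length(queue)) break
    }
    if (nrow(picked) < n_per_class)
      stopf("could not place %d non-overlapping ROIs for class '%s'", n_per_class, cls)
    out[[cls]] <- data.frame(
      class = cls, row = picked[, 1], col = picked[, 2], size = roi_size,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- cbind(roi_id = sprintf("ROI_%03d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  class(res) <- c("roi_set", "data.frame")
  res
}

#' Linear pixel indices covered by each ROI
#'
#' @param rois an `roi_set`.
#' @param dim raster dimensions c(height, width).
#' @return named list (by `roi_id`) of integer index vectors.
#' @export
roi_pixel_index <- function(rois, dim) {
  h <- dim[1]
  idx <- lapply(seq_len(nrow(rois)), function(i) {
    r <- rois$row[i]:(rois$row[i] + rois$size[i] - 1L)
    c <- rois$col[i]:(rois$col[i] + rois$size[i] - 1L)
    as.integer(outer(r, (c - 1L) * h, "+"))
  })
  stats::setNames(idx, rois$roi_id)
}

#' Stratified held-out evaluation pixels, disjoint from training ROIs
#'
#' Samples `n_per_class` labeled pixels per class from the ground-truth label
#' raster, excluding every pixel covered by a training ROI, for unbiased
#' accuracy assessment.
#'
#' @param truth `ground_truth`.
#' @param rois `roi_set` whose pixels are excluded.
#' @param n_per_class pixels per class.
#' @param seed integer seed.
#' @return data frame with `index` (linear pixel index) and `class`.
#' @export
sample_eval_pixels <- function(truth, rois, n_per_class = 1000, seed = 1) {
  set.seed(seed)
  lab <- truth$label_raster
  excl <- unlist(roi_pixel_index(rois, dim(lab)), use.names = FALSE)
  out <- lapply(CLASS_NAMES, function(cls) {
    cand <- setdiff(which(lab == CLASS_CODES[[cls]]), excl)
    if (length(cand) < n_per_class)
      stopf("class '%s' has only %d non-ROI pixels (%d requested)",
            cls, length(cand), n_per_class)
    data.frame(index = sample(cand, n_per_class), class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
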