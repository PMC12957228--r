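test_that("all 15 indices match independent formulas on random band vectors", {
  set.seed(31)
  for (i in 1:100) {
    v <- runif(5, 0.02, 0.98)
    bands <- data.frame(b = v[1], g = v[2], r = v[3], re = v[4], nir = v[5])
    got <- compute_vegetation_indices(bands)[1, ]
    want <- oracle_indices(v[1], v[2], v[3], v[4], v[5])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("hand-computed index values are reproduced", {
  bm <- data.frame(b = 0.1, g = 0.3, r = 0.2, re = 0.5, nir = 0.6)
  vi <- compute_vegetation_indices(bm)[1, ]
  expect_equal(unname(vi["NDVI"]), 0.5)
  expect_equal(unname(vi["DVI"]), 0.4)
  expect_equal(unname(vi["SAVI"]), 1.5 * 0.4 / 1.3, tolerance = 1e-12)
  expect_equal(round(unname(vi["SAVI"]), 6), 0.461538)
  msr <- compute_vegetation_indices(
    data.frame(b = 0.1, g = 0.3, r = 0.04, re = 0.5, nir = 0.64))[1, "MSR"]
  expect_equal(unname(msr), 3.0, tolerance = 1e-12) # (16-1)/(4+1)
})

test_that("red-edge indices reduce to their red counterparts as re -> r", {
  set.seed(32)
  for (i in 1:20) {
    v <- runif(5, 0.05, 0.95)
    bands <- data.frame(b = v[1], g = v[2], r = v[3], re = v[3], nir = v[5])
    vi <- compute_vegetation_indices(bands)[1, ]
    expect_equal(unname(vi["RESAVI"]), unname(vi["SAVI"]), tolerance = 1e-12)
    expect_equal(unname(vi["REOSAVI"]), unname(vi["OSAVI"]), tolerance = 1e-12)
    expect_equal(unname(vi["RERDVI"]), unname(vi["RDVI"]), tolerance = 1e-12)
    expect_equal(unname(vi["REDVI"]), unname(vi["DVI"]), tolerance = 1e-12)
  }
})

test_that("normalized indices are bounded and scale behavior differs from DVI", {
  set.seed(33)
  X <- data.frame(b = runif(200, .01, 1), g = runif(200, .01, 1),
                  r = runif(200, .01, 1), re = runif(200, .01, 1),
                  nir = runif(200, .01, 1))
  vi <- compute_vegetation_indices(X)
  expect_true(all(abs(vi[, "NDVI"]) <= 1))
  expect_true(all(abs(vi[, "NLI"]) <= 1))
  expect_true(all(abs(vi[, "NLVI"]) <= 1))
  # NDVI invariant to common positive rescaling of nir and r; DVI is not
  X2 <- X; X2$nir <- 0.5 * X$nir; X2$r <- 0.5 * X$r
  vi2 <- compute_vegetation_indices(X2)
  expect_equal(vi2[, "NDVI"], vi[, "NDVI"], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(vi2[, "DVI"], vi[, "DVI"])))
})

test_that("zero denominators are flagged NA with a warning, never infinite", {
  bands <- data.frame(b = 0.1, g = 0.2, r = 0, re = 0.3, nir = 0)
  expect_warning(vi <- compute_vegetation_indices(bands), "zero")
  expect_true(is.na(vi[1, "NDVI"]))
  expect_true(is.na(vi[1, "MSR"]))
  expect_false(any(is.infinite(vi)))
})

test_that("the product-form red-edge SAVI alternative is selectable", {
  bm <- data.frame(b = 0.1, g = 0.3, r = 0.2, re = 0.5, nir = 0.6)
  vp <- compute_vegetation_indices(bm, resavi_form = "product")[1, "RESAVI"]
  expect_equal(unname(vp), (1.5 * 0.4 / 1.3) * (0.1 / 1.1), tolerance = 1e-12)
})

test_that("zonal band means equal a brute-force loop over contained pixels", {
  gen <- generate_scene(small_scene_config(seed = 41))
  cm <- structure(list(labels = gen$truth$label_raster, classifier = "truth",
                       params = list(),
                       codes = c(unclassified = 0L, soil = 1L,
                                 stems_leaves = 2L, lint = 3L)),
                  class = "class_map")
  boll <- extract_boll_mask(cm, gen$scene)
  sp <- gen$truth$sampling_points
  bm <- zonal_mean_reflectance(boll$masked_scene, sp)
  refl <- gen$scene$reflectance
  lab <- gen$truth$label_raster
  for (i in sample(nrow(sp), 10)) {
    r <- sp[i, ]
    vals <- matrix(NA_real_, 0, 5)
    for (rr in r$row0:r$row1) for (cc in r$col0:r$col1)
      if (lab[rr, cc] == 3L) vals <- rbind(vals, refl[rr, cc, ])
    expect_equal(unname(unlist(bm[i, c("b", "g", "r", "re", "nir")])),
                 unname(colMeans(vals)), tolerance = 1e-12)
    expect_equal(bm$n_pixels[i], nrow(vals))
  }
})

test_that("polygons without lint pixels yield flagged records, not errors", {
  gen <- generate_scene(small_scene_config(seed = 42))
  lab0 <- matrix(1L, nrow(gen$truth$label_raster), ncol(gen$truth$label_raster))
  cm <- structure(list(labels = lab0, classifier = "truth", params = list(),
                       codes = c(unclassified = 0L, soil = 1L,
                                 stems_leaves = 2L, lint = 3L)),
                  class = "class_map")
  suppressWarnings(boll <- extract_boll_mask(cm, gen$scene))
  bm <- zonal_mean_reflectance(boll$masked_scene, gen$truth$sampling_points)
  expect_true(all(!bm$valid))
  expect_true(all(bm$n_pixels == 0))
})

test_that("simple two-pixel zonal mean is exact", {
  refl <- array(NaN, dim = c(2, 2, 5))
  refl[1, 1, ] <- c(0.1, 0.2, 0.3, 0.35, 0.4)
  refl[2, 2, ] <- c(0.1, 0.2, 0.3, 0.45, 0.6)
  scene <- structure(list(reflectance = refl,
                          band_names = c("blue", "green", "red", "red_edge", "nir"),
                          year = NA), class = "ms_scene")
  poly <- data.frame(id = "p")
  poly$coords <- list(cbind(x = c(0, 2, 2, 0, 0), y = c(0, 0, 2, 2, 0)))
  bm <- zonal_mean_reflectance(scene, poly)
  expect_equal(bm$nir, 0.5)
  expect_equal(bm$n_pixels, 2L)
})

test_that("sample table assembly joins, drops and recomputes correctly", {
  gen <- generate_scene(scene_config(seed = 43))
  tab <- truth_sample_table(gen)
  expect_equal(nrow(tab), 144)
  expect_s3_class(tab, "sample_table")
  # indices recompute from stored band means
  vi <- compute_vegetation_indices(tab[, c("b", "g", "r", "re", "nir")])
  expect_equal(unname(as.matrix(tab[, colnames(vi)])), unname(vi), tolerance = 1e-12)
  # a missing SBW drops one record with a warning
  cm <- structure(list(labels = gen$truth$label_raster, classifier = "truth",
                       params = list(),
                       codes = c(unclassified = 0L, soil = 1L,
                                 stems_leaves = 2L, lint = 3L)),
                  class = "class_map")
  boll <- extract_boll_mask(cm, gen$scene)
  bmeans <- zonal_mean_reflectance(boll$masked_scene, gen$truth$sampling_points)
  sbw <- gen$truth$sbw
  sbw$sbw_g[5] <- NA
  expect_warning(tab2 <- build_sample_table(bmeans, sbw), "dropped 1")
  expect_equal(nrow(tab2), 143)
  expect_error(build_sample_table(bmeans, rbind(sbw, sbw[1, ])), "duplicate")
})
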