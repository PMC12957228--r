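# shared small-scene configuration: full 48-plot trial on a compact raster
small_scene_config <- function(seed = 1, ...) {
  scene_config(height = 192, width = 256, seed = seed, ...)
}

# sample table straight from ground truth (perfect lint mask), skipping the
# classification stage — used where only the downstream statistics matter
truth_sample_table <- function(gen) {
  cm <- structure(list(labels = gen$truth$label_raster, classifier = "truth",
                       params = list(),
                       codes = c(unclassified = 0L, soil = 1L,
                                 stems_leaves = 2L, lint = 3L)),
                  class = "class_map")
  boll <- extract_boll_mask(cm, gen$scene)
  bm <- zonal_mean_reflectance(boll$masked_scene, gen$truth$sampling_points)
  build_sample_table(bm, gen$truth$sbw)
}

# the paper-design sample table (288 rows) without imagery, for split tests
paper_design_table <- function(seed = 1) {
  set.seed(seed)
  main <- expand.grid(year = c(2023, 2024), variety = c("V1", "V2", "V3"),
                      density = paste0("D", 1:5), rep = 1:3, sp = 1:3,
                      stringsAsFactors = FALSE)
  ck <- expand.grid(year = c(2023, 2024), variety = "CK", density = "D5",
                    rep = 1:3, sp = 1:3, stringsAsFactors = FALSE)
  tab <- rbind(main, ck)
  tab$sample_id <- sprintf("S%03d", seq_len(nrow(tab)))
  tab$sbw_g <- rnorm(nrow(tab), 5.8, 0.5)
  tab
}
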