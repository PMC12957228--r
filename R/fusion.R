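#' Absolute Pearson correlation of each vegetation index with SBW
#'
#' @param table a `sample_table` (or any data frame with the index columns
#'   and `sbw_g`).
#' @param features character vector of feature columns (default the 15
#'   vegetation indices).
#' @return named vector of |r| per feature. Zero-variance features score 0
#'   with a warning.
#' @export
pearson_scores <- function(table, features = VI_NAMES) {
  tab <- stats::na.omit(table[, c(features, "sbw_g")])
  if (nrow(tab) < 3) stopf("need at least 3 complete records for Pearson scores")
  if (stats::sd(tab$sbw_g) == 0) stopf("SBW has zero variance")
  out <- vapply(features, function(f) {
    if (stats::sd(tab[[f]]) == 0) {
      warnf("feature '%s' has zero variance; Pearson score set to 0", f)
      return(0)
    }
    abs(stats::cor(tab[[f]], tab$sbw_g))
  }, numeric(1))
  out
}

#' Global SHAP importance of each index from a gradient-boosted tree model
#'
#' Fits an XGBoost regression of SBW on the feature columns (squared-error
#' objective; defaults: 300 trees, depth 4, learning rate 0.05, subsample
#' 0.8) and computes per-sample, per-feature SHAP values with the
#' tree-path-dependent TreeSHAP attribution. Global importance is the mean
#' absolute SHAP value over samples. Per-sample attributions satisfy the
#' efficiency axiom: the attributions plus the base value reproduce the
#' model prediction.
#'
#' @inheritParams pearson_scores
#' @param params list overriding the model hyperparameters `nrounds`,
#'   `max_depth`, `eta`, `subsample`.
#' @param seed integer seed for the (subsampled) tree fitting.
#' @return named vector of mean |SHAP| per feature, with attributes
#'   `model` (the fitted booster), `shap` (n x p attribution matrix),
#'   `base_value`, and `prediction`.
#' @export
shap_scores <- function(table, features = VI_NAMES, params = list(), seed = 42) {
  tab <- stats::na.omit(table[, c(features, "sbw_g")])
  if (nrow(tab) < 20) stopf("need at least 20 complete records for SHAP scores")
  p <- utils::modifyList(list(nrounds = 300, max_depth = 4, eta = 0.05,
                              subsample = 0.8), params)
  X <- as.matrix(tab[, features, drop = FALSE])
  if (any(!is.finite(X))) stopf("non-finite feature values")
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = tab$sbw_g)
  bst <- xgboost::xgb.train(
    params = list(max_depth = p$max_depth, eta = p$eta, subsample = p$subsample,
                  objective = "reg:squarederror", nthread = 1, seed = seed),
    data = dtrain, nrounds = p$nrounds, verbose = 0)
  contrib <- predict(bst, dtrain, predcontrib = TRUE)
  base <- contrib[, ncol(contrib)]
  shap <- contrib[, seq_along(features), drop = FALSE]
  colnames(shap) <- features
  imp <- colMeans(abs(shap))
  structure(imp, model = bst, shap = shap, base_value = base,
            prediction = predict(bst, dtrain))
}

#' Fuse Pearson and SHAP scores and select features
#'
#' Normalizes each score vector to sum to one, averages them with equal
#' weights, ranks features by the fused score (ties broken alphabetically
#' by feature name), and selects the shortest prefix of the ranking whose
#' cumulative fused score reaches `cum_threshold` (default 60%). A
#' rank-averaging alternative is available: features are ranked by mean
#' rank and selection uses normalized inverse-rank weights.
#'
#' @param pearson,shap named score vectors over the same feature set.
#' @param cum_threshold cumulative-contribution cutoff in (0, 1].
#' @param method `"score"` (default, score averaging after sum-to-one
#'   normalization) or `"rank"`.
#' @return data frame of class `feature_ranking`: per feature the raw and
#'   normalized scores, `fused_score`, `rank`, `cumulative`, `selected`.
#' @export
fuse_and_select <- function(pearson, shap, cum_threshold = 0.60,
                            method = c("score", "rank")) {
  method <- match.arg(method)
  if (is.null(names(pearson)) || is.null(names(shap)))
    stopf("score vectors must be named")
  if (!setequal(names(pearson), names(shap)))
    stopf("Pearson and SHAP scores must cover the same feature set")
  shap <- shap[names(pearson)]
  if (cum_threshold <= 0 || cum_threshold > 1) stopf("cum_threshold must be in (0, 1]")
  if (sum(pearson) <= 0 || sum(shap) <= 0)
    stopf("score vectors must have positive sums")
  if (method == "score") {
    p_norm <- pearson / sum(pearson)
    s_norm <- as.numeric(shap) / sum(shap)
    fused <- 0.5 * p_norm + 0.5 * s_norm
  } else {
    # rank averaging: best feature = rank 1; weight = inverse mean rank
    rp <- rank(-pearson, ties.method = "average")
    rs <- rank(-as.numeric(shap), ties.method = "average")
    w <- 1 / ((rp + rs) / 2)
    p_norm <- pearson / sum(pearson)
    s_norm <- as.numeric(shap) / sum(shap)
    fused <- w / sum(w)
  }
  ord <- order(-fused, names(pearson))
  res <- data.frame(
    feature = names(pearson)[ord],
    pearson_abs = as.numeric(pearson)[ord],
    shap_importance = as.numeric(shap)[ord],
    pearson_norm = p_norm[ord],
    shap_norm = s_norm[ord],
    fused_score = fused[ord],
    stringsAsFactors = FALSE
  )
  res$rank <- seq_len(nrow(res))
  res$cumulative <- cumsum(res$fused_score)
  n_sel <- which(res$cumulative >= cum_threshold - 1e-12)[1]
  res$selected <- res$rank <= n_sel
  attr(res, "cum_threshold") <- cum_threshold
  attr(res, "method") <- method
  rownames(res) <- NULL
  class(res) <- c("feature_ranking", "data.frame")
  res
}

#' Selected feature names from a ranking
#' @param ranking a `feature_ranking`.
#' @return character vector in rank order.
#' @export
selected_features <- function(ranking) ranking$feature[ranking$selected]
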