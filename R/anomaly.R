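# Screen-mode anomaly scoring: an ensemble of robust-distance detectors on
# random feature subsets, fitted on control (uninduced) cells. A cell's
# anomaly score is the number of detectors placing it in the top 5% / 10%
# of all scored cells.

#' Fit an anomaly-detector ensemble on control cells
#'
#' Each detector draws a random feature subset and estimates a robust
#' center (median) and scale (MAD) per feature on the control cells. The
#' detector's raw score of a cell is the Euclidean norm of its robustly
#' standardized subset features.
#'
#' @param controls control cell table (normalized feature space).
#' @param n_detectors ensemble size (default 100).
#' @param subset_size features per detector (default 8; must be >= 2).
#' @param seed RNG seed fixing the subsets.
#' @return an [AnomalyEnsemble-class].
#' @export
fitAnomalyEnsemble <- function(controls, n_detectors = 100L, subset_size = 8L,
                               seed = 1L) {
  feats <- featureColumns(controls)
  if (subset_size < 2L) stop("subset_size must be >= 2")
  if (subset_size > length(feats))
    stop("subset_size exceeds available features")
  X <- as.matrix(controls[, feats, drop = FALSE])
  withSeed(seed, {
    det <- lapply(seq_len(n_detectors), function(i) {
      fs <- sort(sample(feats, subset_size))
      ctr <- apply(X[, fs, drop = FALSE], 2, median)
      scl <- apply(X[, fs, drop = FALSE], 2, mad)
      scl[scl == 0] <- 1  # constant control feature: unit scale
      list(features = fs, center = ctr, scale = scl)
    })
    new("AnomalyEnsemble", detectors = det, feature_space = feats,
        seed = as.integer(seed))
  })
}

# Raw detector scores: cells x detectors matrix of robust distances.
rawAnomalyScores <- function(ensemble, cells) {
  X <- as.matrix(cells[, ensemble@feature_space, drop = FALSE])
  vapply(ensemble@detectors, function(d) {
    Z <- sweep(sweep(X[, d$features, drop = FALSE], 2, d$center), 2,
               d$scale, "/")
    sqrt(rowSums(Z^2))
  }, numeric(nrow(X)))
}

#' Score cells with an anomaly ensemble
#'
#' Per detector, the top-5% and top-10% thresholds are the 95th and 90th
#' percentiles of the raw scores over all scored cells; a cell is flagged by
#' a detector if its raw score strictly exceeds the threshold (ties fall
#' below). `n_top5` / `n_top10` count flagging detectors per cell.
#'
#' @param ensemble an [AnomalyEnsemble-class].
#' @param cells cell table sharing the control feature space (>= 20 cells;
#'   percentile thresholds are unreliable below that and the call refuses).
#' @return data.frame (cell_id, n_top5, n_top10, n_detectors).
#' @export
anomalyScores <- function(ensemble, cells) {
  if (nrow(cells) < 20L)
    stop("fewer than 20 cells: percentile thresholds unreliable")
  R <- rawAnomalyScores(ensemble, cells)
  q95 <- apply(R, 2, quantile, probs = 0.95)
  q90 <- apply(R, 2, quantile, probs = 0.90)
  data.frame(cell_id = cells$cell_id,
             n_top5 = as.integer(rowSums(sweep(R, 2, q95, ">"))),
             n_top10 = as.integer(rowSums(sweep(R, 2, q90, ">"))),
             n_detectors = length(ensemble@detectors),
             stringsAsFactors = FALSE)
}
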