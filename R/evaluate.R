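# Evaluation battery: join predictions to genotypes, ROC with shuffled-label
# noise, confidence-threshold metrics, confusion summaries, Kruskal-Wallis
# feature ranking, feature-subset analyses, gRNA significance,
# reproducibility and the frameshift-vs-anomaly comparison.

#' Join pick predictions to genotype calls
#'
#' Inner join on raft key; ambiguous and no-data genotype calls are
#' excluded, as are prediction scores inside \[0.4, 0.6\] (the model could
#' not classify those cells).
#'
#' @param picks pick list (see [buildPickList()]).
#' @param calls genotype calls (see [genotypeWells()]).
#' @param class_map named character vector mapping each genotype to
#'   WT/benign/pathogenic.
#' @param exclusion_band closed score band to exclude (default
#'   c(0.4, 0.6)).
#' @return data.frame (raft_key, score, predicted_class, band, genotype,
#'   genotype_class, truth_mutant).
#' @export
joinPredictionsGenotypes <- function(picks, calls, class_map,
                                     exclusion_band = c(0.4, 0.6)) {
  if (anyDuplicated(calls$raft_key[!is.na(calls$raft_key)]))
    stop("join key collision: duplicated raft_key in genotype calls")
  j <- merge(picks, calls[, c("raft_key", "call")], by = "raft_key")
  j <- j[!(j$call %in% c("ambiguous", "no-data")), , drop = FALSE]
  j <- j[j$score < exclusion_band[1] | j$score > exclusion_band[2], ,
         drop = FALSE]
  unknown <- setdiff(unique(j$call), names(class_map))
  if (length(unknown))
    stop("genotype(s) missing from class map: ",
         paste(unknown, collapse = ", "))
  j$genotype <- j$call
  j$genotype_class <- unname(class_map[j$call])
  j$truth_mutant <- j$genotype_class == "pathogenic"
  rownames(j) <- NULL
  j[, c("raft_key", "score", "predicted_class", "band", "genotype",
        "genotype_class", "truth_mutant")]
}

#' Class map for a genotype panel
#' @param genotypes data.frame (genotype, class), e.g.
#'   [defaultGenotypes()].
#' @return named character vector genotype -> class.
#' @export
classMap <- function(genotypes = defaultGenotypes()) {
  setNames(genotypes$class, genotypes$genotype)
}

#' Empirical ROC with shuffled-label noise curves
#'
#' ROC points over all score thresholds, AUC by the rank/trapezoid method,
#' and a null AUC distribution from label permutations.
#'
#' @param join output of [joinPredictionsGenotypes()] (or any data.frame
#'   with `score` and logical `truth_mutant`).
#' @param n_shuffles number of label permutations (default 50).
#' @param seed RNG seed.
#' @return list(roc = data.frame(fpr, tpr), auc, noise_auc = numeric
#'   vector).
#' @export
rocWithNoise <- function(join, n_shuffles = 50L, seed = 1L) {
  y <- as.logical(join$truth_mutant); s <- join$score
  if (length(unique(y)) < 2L) stop("single class: ROC undefined")
  th <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  roc <- t(vapply(th, function(t0)
    c(fpr = mean(s[!y] >= t0), tpr = mean(s[y] >= t0)), numeric(2)))
  noise <- withSeed(seed, vapply(seq_len(n_shuffles), function(i)
    aucScore(s, sample(y)), numeric(1)))
  list(roc = as.data.frame(roc), auc = aucScore(s, y), noise_auc = noise)
}

#' Per-confidence-band accuracy and AUC
#'
#' For each band b, restrict the join to scores >= b or <= 1 - b and report
#' accuracy (predicted class equals true class), AUC and n.
#'
#' @param join output of [joinPredictionsGenotypes()].
#' @param bands confidence bands (default 0.7, 0.8, 0.9).
#' @return data.frame (band, n, accuracy, auc).
#' @export
thresholdMetrics <- function(join, bands = c(0.7, 0.8, 0.9)) {
  stopifnot(nrow(join) > 0L)
  do.call(rbind, lapply(bands, function(b) {
    sub <- join[join$score >= b | join$score <= 1 - b, , drop = FALSE]
    pred_mut <- sub$score > 0.5
    data.frame(band = b, n = nrow(sub),
               accuracy = if (nrow(sub)) mean(pred_mut == sub$truth_mutant)
                          else NA_real_,
               auc = suppressWarnings(aucScore(sub$score, sub$truth_mutant)))
  }))
}

#' Stacked confusion counts per group
#'
#' Counts of predicted class by true genotype, per grouping key (for
#' example the source well role or mixture), with conserved marginals.
#'
#' @param join output of [joinPredictionsGenotypes()].
#' @param group optional vector of group labels aligned with `join`.
#' @return data.frame (group, predicted_class, genotype, n).
#' @export
confusionSummary <- function(join, group = NULL) {
  g <- if (is.null(group)) rep("all", nrow(join)) else as.character(group)
  tab <- as.data.frame(table(group = g, predicted_class = join$predicted_class,
                             genotype = join$genotype),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  tab[tab$n > 0 | TRUE, , drop = FALSE]
}

#' Kruskal-Wallis feature ranking
#'
#' Per feature, the tie-corrected Kruskal-Wallis H (chi-squared) statistic
#' between classes, ranked descending.
#'
#' @param cells labeled cell table.
#' @param classes class label per cell (>= 2 classes, >= 2 cells each).
#' @param features feature names (default: all F columns).
#' @return data.frame (feature, statistic, rank) sorted by rank.
#' @export
kwFeatureRanking <- function(cells, classes, features = NULL) {
  if (is.null(features)) features <- featureColumns(cells)
  cl <- factor(classes)
  stopifnot(nlevels(cl) >= 2L, all(table(cl) >= 2L))
  stat <- vapply(features, function(f)
    unname(suppressWarnings(kruskal.test(cells[[f]], cl)$statistic)),
    numeric(1))
  out <- data.frame(feature = features, statistic = stat)
  out <- out[order(-out$statistic), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Feature-subset AUC analyses
#'
#' mode "subsets": models for every subset of each size 1..k of the base
#' set (sampled when a size has more than `max_per_size` combinations);
#' mode "single": one model per feature; mode "loo": one model per excluded
#' feature. Each model is a logistic fit on the training wells, evaluated
#' by AUC on the held-out labeled wells.
#'
#' @param cells QC'd labeled cell table.
#' @param layout plate layout.
#' @param base_features base feature set (>= 2).
#' @param mode "subsets", "single" or "loo".
#' @param max_size largest subset size for mode "subsets" (default
#'   `length(base_features)`).
#' @param max_per_size sampling cap per size (default 50).
#' @param seed RNG seed.
#' @return data.frame (mode, size, features, auc).
#' @export
featureSubsetAnalysis <- function(cells, layout, base_features,
                                  mode = c("subsets", "single", "loo"),
                                  max_size = NULL, max_per_size = 50L,
                                  seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(base_features) >= 2L)
  labels <- labelFromLayout(cells, layout)
  split <- splitWells(layout, "well", seed = seed)
  tr <- cells$well_key %in% split$train_wells & !is.na(labels)
  te <- cells$well_key %in% split$test_wells & !is.na(labels)
  X <- as.matrix(cells[, base_features, drop = FALSE])
  one_auc <- function(fs) {
    pr <- tryCatch(fitClassifier(X[tr, fs, drop = FALSE], labels[tr],
                                 "logistic", 0.1),
                   error = function(e) NULL)
    if (is.null(pr)) return(NA_real_)
    suppressWarnings(aucScore(pr(X[te, fs, drop = FALSE]), labels[te]))
  }
  subsets <- switch(mode,
    single = as.list(base_features),
    loo = lapply(base_features, function(f) setdiff(base_features, f)),
    subsets = {
      if (is.null(max_size)) max_size <- length(base_features)
      out <- list()
      withSeed(seed, for (sz in seq_len(max_size)) {
        all_c <- combn(base_features, sz, simplify = FALSE)
        if (length(all_c) > max_per_size)
          all_c <- all_c[sample.int(length(all_c), max_per_size)]
        out <- c(out, all_c)
      })
      out
    })
  data.frame(mode = mode,
             size = lengths(subsets),
             features = vapply(subsets, paste, "", collapse = "+"),
             auc = vapply(subsets, one_auc, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Per-gRNA significance by one-sample t test with BH correction
#'
#' Each gRNA's member-cell prediction scores are tested against
#' `null_value` (default: the median score of control cells) by a
#' one-sample t test; decisions are Benjamini-Hochberg step-up at
#' `fdr`. gRNAs with fewer than 3 cells are excluded and logged.
#'
#' @param scores per-cell scores.
#' @param grna gRNA id per cell (NA = untested).
#' @param control logical: control cells defining the default null value.
#' @param null_value explicit null; overrides the control median.
#' @param fdr false discovery rate (default 0.2).
#' @return data.frame (grna, n, mean_score, t, p, p_adj, significant),
#'   excluded gRNAs in attribute "excluded".
#' @export
grnaSignificance <- function(scores, grna, control = NULL, null_value = NULL,
                             fdr = 0.2) {
  if (is.null(null_value)) {
    stopifnot(!is.null(control))
    null_value <- median(scores[control])
  }
  sp <- split(scores, grna)
  small <- names(sp)[lengths(sp) < 3L]
  sp <- sp[lengths(sp) >= 3L]
  rows <- lapply(names(sp), function(g) {
    v <- sp[[g]]
    tt <- tryCatch(t.test(v, mu = null_value),
                   error = function(e) list(statistic = 0, p.value = 1))
    data.frame(grna = g, n = length(v), mean_score = mean(v),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, "BH")
  out$significant <- bhDecisions(out$p, fdr)
  attr(out, "excluded") <- small
  attr(out, "null_value") <- null_value
  out
}

#' Benjamini-Hochberg step-up decisions
#'
#' Rejects hypotheses i with BH-adjusted p at most `fdr` (equivalently, all
#' ordered p(i) with i <= max j such that p(j) <= j * fdr / m).
#'
#' @param p raw p-values.
#' @param fdr false discovery rate.
#' @return logical rejection vector aligned with `p`.
#' @export
bhDecisions <- function(p, fdr) {
  p.adjust(p, "BH") <= fdr
}

#' Reproducibility of gRNA effects across replicates
#'
#' A gRNA is measurable iff it has at least `min_cells` cells in at least
#' two replicates; it is reproducible iff the sign of (replicate mean score
#' minus the replicate-wide median of per-gRNA means) agrees across all its
#' replicates. Reports the reproducible fraction over measurable gRNAs.
#'
#' @param scores per-cell scores.
#' @param grna gRNA id per cell.
#' @param replicate replicate label per cell.
#' @param min_cells per-replicate cell floor (default 3).
#' @return list(fraction, per_grna = data.frame(grna, measurable,
#'   reproducible)).
#' @export
reproducibility <- function(scores, grna, replicate, min_cells = 3L) {
  df <- data.frame(s = scores, g = grna, r = replicate)
  agg <- aggregate(s ~ g + r, df, mean)
  cnt <- aggregate(s ~ g + r, df, length)
  agg <- agg[cnt$s >= min_cells, , drop = FALSE]
  med <- tapply(agg$s, agg$r, median)  # replicate-wide median of gRNA means
  agg$dir <- sign(agg$s - med[as.character(agg$r)])
  nrep <- table(agg$g)
  per <- data.frame(grna = names(nrep),
                    measurable = as.integer(nrep) >= 2L)
  per$reproducible <- vapply(per$grna, function(g) {
    d <- agg$dir[agg$g == g]
    length(d) >= 2L && (all(d >= 0) || all(d <= 0))
  }, logical(1))
  per$reproducible[!per$measurable] <- NA
  frac <- mean(per$reproducible[per$measurable])
  list(fraction = frac, per_grna = per)
}

#' Anomaly score vs predicted frameshift probability
#'
#' At each frameshift threshold t, a two-sided rank-sum test compares the
#' per-gRNA anomaly scores of gRNAs with frameshift probability >= t
#' against those below t.
#'
#' @param anomaly per-gRNA anomaly scores.
#' @param frameshift per-gRNA predicted frameshift probabilities.
#' @param thresholds frameshift thresholds (default 0.9, 0.8, 0.7).
#' @return data.frame (threshold, n_high, n_low, statistic, p); a threshold
#'   with an empty group reports NA (not computable).
#' @export
frameshiftVsAnomaly <- function(anomaly, frameshift,
                                thresholds = c(0.9, 0.8, 0.7)) {
  do.call(rbind, lapply(thresholds, function(t0) {
    hi <- anomaly[frameshift >= t0]; lo <- anomaly[frameshift < t0]
    if (!length(hi) || !length(lo))
      return(data.frame(threshold = t0, n_high = length(hi),
                        n_low = length(lo), statistic = NA_real_,
                        p = NA_real_))
    w <- suppressWarnings(wilcox.test(hi, lo))
    data.frame(threshold = t0, n_high = length(hi), n_low = length(lo),
               statistic = unname(w$statistic), p = w$p.value)
  }))
}
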