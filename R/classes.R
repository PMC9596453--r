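# Central S4 containers with validity checks.

#' SimConfig: study conditions for the synthetic screen
#'
#' Holds every parameter of the simulated microraft experiment: plate/well
#' geometry, genotype panel, feature model (effect size, correlation, batch
#' effects, leaky features), raft occupancy, fiduciary and debris rates.
#' Defaults reproduce the mixed-variant study design: three labeled wells
#' per class spread over two plates plus unlabeled admixture wells at
#' wild-type:pathogenic ratios of 50:50 and 90:10.
#'
#' @slot n_plates,wells_per_plate,cells_per_well experiment geometry counts.
#' @slot genotypes data.frame with columns `genotype` and `class`
#'   (WT/benign/pathogenic).
#' @slot effect_size standardized mean shift on informative features for
#'   pathogenic genotypes.
#' @slot n_features,n_informative feature counts (informative features are
#'   the leading ones).
#' @slot feature_correlation pairwise correlation within feature blocks.
#' @slot block_size size of equicorrelated feature blocks.
#' @slot batch_sd per-plate additive offset scale.
#' @slot leaky_feature_count trailing features replaced by well-position
#'   proxies (leak-detector positive controls).
#' @slot unlabeled_fractions expected pathogenic fraction of each unlabeled
#'   well.
#' @slot n_labeled_wells labeled wells per class.
#' @slot raft_grid rows, cols of the per-well raft grid.
#' @slot mean_cells_per_raft truncated-Poisson occupancy mean.
#' @slot fiduciary_fraction fraction of rafts carrying fiduciary marks.
#' @slot debris_fraction fraction of records rendered as out-of-gate debris.
#' @slot seed master seed; fully determines all outputs.
#' @export
setClass("SimConfig", representation(
  n_plates = "integer", wells_per_plate = "integer", cells_per_well = "integer",
  genotypes = "data.frame", effect_size = "numeric",
  n_features = "integer", n_informative = "integer",
  feature_correlation = "numeric", block_size = "integer",
  batch_sd = "numeric", leaky_feature_count = "integer",
  unlabeled_fractions = "numeric", n_labeled_wells = "integer",
  raft_grid = "integer", mean_cells_per_raft = "numeric",
  fiduciary_fraction = "numeric", debris_fraction = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@n_informative > object@n_features)
    msg <- c(msg, "n_informative must be <= n_features")
  for (s in c("n_plates", "wells_per_plate", "cells_per_well", "n_features",
              "n_informative"))
    if (slot(object, s) <= 0L) msg <- c(msg, paste(s, "must be positive"))
  if (!all(c("genotype", "class") %in% colnames(object@genotypes)))
    msg <- c(msg, "genotypes needs columns genotype, class")
  if (!all(object@genotypes$class %in% c("WT", "benign", "pathogenic")))
    msg <- c(msg, "genotype class must be WT, benign or pathogenic")
  if (object@feature_correlation < 0 || object@feature_correlation >= 1)
    msg <- c(msg, "feature_correlation must be in [0,1)")
  if (any(object@unlabeled_fractions < 0 | object@unlabeled_fractions > 1))
    msg <- c(msg, "unlabeled_fractions must lie in [0,1]")
  if (length(object@raft_grid) != 2L || any(object@raft_grid < 1L))
    msg <- c(msg, "raft_grid must be two positive integers")
  if (object@effect_size < 0) msg <- c(msg, "effect_size must be nonnegative")
  if (object@batch_sd < 0) msg <- c(msg, "batch_sd must be nonnegative")
  if (object@fiduciary_fraction < 0 || object@fiduciary_fraction > 1)
    msg <- c(msg, "fiduciary_fraction must be in [0,1]")
  if (object@debris_fraction < 0 || object@debris_fraction > 1)
    msg <- c(msg, "debris_fraction must be in [0,1]")
  if (object@mean_cells_per_raft <= 0)
    msg <- c(msg, "mean_cells_per_raft must be positive")
  n_wells <- object@n_plates * object@wells_per_plate
  if (2L * object@n_labeled_wells + length(object@unlabeled_fractions) > n_wells)
    msg <- c(msg, "not enough wells for the requested layout")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param n_plates,wells_per_plate,cells_per_well experiment geometry.
#' @param genotypes data.frame (genotype, class); default: wild type plus the
#'   four pathogenic mitofusin-2 point mutants used in the mixed pool.
#' @param effect_size standardized shift on informative features
#'   (pathogenic vs WT).
#' @param n_features,n_informative total and informative feature counts.
#' @param feature_correlation,block_size equicorrelated block noise model.
#' @param batch_sd per-plate offset scale.
#' @param leaky_feature_count number of well-position proxy features.
#' @param unlabeled_fractions expected pathogenic fraction per unlabeled well.
#' @param n_labeled_wells labeled wells per class.
#' @param raft_grid c(rows, cols) of the raft grid per well.
#' @param mean_cells_per_raft occupancy mean (Poisson truncated to 1..10).
#' @param fiduciary_fraction,debris_fraction contamination rates.
#' @param seed master seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(cells_per_well = 50, seed = 7)
#' cfg
#' @export
simConfig <- function(n_plates = 2L, wells_per_plate = 4L, cells_per_well = 400L,
                      genotypes = defaultGenotypes(), effect_size = 1,
                      n_features = 170L, n_informative = 16L,
                      feature_correlation = 0.3, block_size = 8L,
                      batch_sd = 0.5, leaky_feature_count = 2L,
                      unlabeled_fractions = c(0.5, 0.1), n_labeled_wells = 3L,
                      raft_grid = c(30L, 30L), mean_cells_per_raft = 1.5,
                      fiduciary_fraction = 0.02, debris_fraction = 0.05,
                      seed = 1L) {
  new("SimConfig",
      n_plates = as.integer(n_plates), wells_per_plate = as.integer(wells_per_plate),
      cells_per_well = as.integer(cells_per_well), genotypes = genotypes,
      effect_size = as.numeric(effect_size), n_features = as.integer(n_features),
      n_informative = as.integer(n_informative),
      feature_correlation = as.numeric(feature_correlation),
      block_size = as.integer(block_size), batch_sd = as.numeric(batch_sd),
      leaky_feature_count = as.integer(leaky_feature_count),
      unlabeled_fractions = as.numeric(unlabeled_fractions),
      n_labeled_wells = as.integer(n_labeled_wells),
      raft_grid = as.integer(raft_grid),
      mean_cells_per_raft = as.numeric(mean_cells_per_raft),
      fiduciary_fraction = as.numeric(fiduciary_fraction),
      debris_fraction = as.numeric(debris_fraction), seed = as.integer(seed))
}

#' Default genotype panel: WT plus four pathogenic MFN2 point mutants
#'
#' The mixed-variant condition: wild type against L76P, R94Q, P251A and
#' R280H, all annotated pathogenic.
#' @return data.frame with columns genotype and class.
#' @export
defaultGenotypes <- function() {
  data.frame(
    genotype = c("WT", "L76P", "R94Q", "P251A", "R280H"),
    class = c("WT", "pathogenic", "pathogenic", "pathogenic", "pathogenic"),
    stringsAsFactors = FALSE)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_plates, "plate(s) x", object@wells_per_plate,
      "wells x", object@cells_per_well, "cells/well\n")
  cat("  genotypes:", paste(object@genotypes$genotype, collapse = ", "), "\n")
  cat("  effect_size:", object@effect_size, " features:", object@n_features,
      "(", object@n_informative, "informative )\n")
  cat("  raft grid:", paste(object@raft_grid, collapse = " x "),
      " mean cells/raft:", object@mean_cells_per_raft, "\n")
  cat("  seed:", object@seed, "\n")
})

#' LocusPanel: genotyping loci with WT/mutant 20-mer search fragments
#'
#' One row per locus: the wild-type and mutant 20-base search fragments, the
#' mutant name they diagnose, flanking context and the primer pair used to
#' build the amplicon, plus the universal forward/reverse adapter tags.
#'
#' @slot loci data.frame with columns locus, wt_fragment, mut_fragment,
#'   mutant_name, context_left, context_right, primer_f, primer_r.
#' @slot fwd_tag,rev_tag universal Illumina-compatible adapter tags.
#' @export
setClass("LocusPanel", representation(
  loci = "data.frame", fwd_tag = "character", rev_tag = "character"))

setValidity("LocusPanel", function(object) {
  msg <- character()
  need <- c("locus", "wt_fragment", "mut_fragment", "mutant_name",
            "context_left", "context_right", "primer_f", "primer_r")
  if (!all(need %in% colnames(object@loci)))
    return(paste("loci must have columns:", paste(need, collapse = ", ")))
  frs <- c(object@loci$wt_fragment, object@loci$mut_fragment)
  if (!all(nchar(frs) == 20L))
    msg <- c(msg, "all search fragments must be exactly 20 bases")
  if (!all(grepl("^[ACGT]+$", frs)))
    msg <- c(msg, "fragments must be over {A,C,G,T}")
  same <- object@loci$wt_fragment == object@loci$mut_fragment
  if (any(same))
    msg <- c(msg, "WT and mutant fragments must differ at >= 1 position")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LocusPanel", function(object) {
  cat("LocusPanel with", nrow(object@loci), "loci:",
      paste(object@loci$locus, collapse = ", "), "\n")
})

#' Accessor: loci table of a LocusPanel
#' @param panel a [LocusPanel-class].
#' @return the loci data.frame.
#' @export
panelLoci <- function(panel) panel@loci

#' QcGates: record-level quality gates
#'
#' Interval gates on nuclear geometry and intensities, a raft-edge margin,
#' a raft occupancy ceiling and fiduciary exclusion. Numeric defaults sit at
#' the 1%/99% quantiles of the generator's live-cell distributions (the
#' gating variables come from the screening protocol; the values are a
#' documented package choice, fully config-exposed).
#'
#' @slot nuclear_area,form_factor,nuclear_intensity,cell_intensity numeric
#'   length-2 \[min, max\] intervals.
#' @slot raft_edge_margin minimum distance (um) from the raft edge.
#' @slot max_cells_per_raft occupancy ceiling (rafts holding more are
#'   excluded whole).
#' @slot exclude_fiduciary drop cells on fiduciary-marked rafts.
#' @export
setClass("QcGates", representation(
  nuclear_area = "numeric", form_factor = "numeric",
  nuclear_intensity = "numeric", cell_intensity = "numeric",
  raft_edge_margin = "numeric", max_cells_per_raft = "integer",
  exclude_fiduciary = "logical"))

setValidity("QcGates", function(object) {
  msg <- character()
  for (s in c("nuclear_area", "form_factor", "nuclear_intensity",
              "cell_intensity")) {
    v <- slot(object, s)
    if (length(v) != 2L || v[1] > v[2])
      msg <- c(msg, paste(s, "must be a nonempty [min,max] interval"))
  }
  if (object@raft_edge_margin < 0) msg <- c(msg, "margin must be nonnegative")
  if (object@max_cells_per_raft < 1L) msg <- c(msg, "max_cells_per_raft >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct QcGates
#'
#' @param nuclear_area,form_factor,nuclear_intensity,cell_intensity
#'   \[min,max\] intervals; defaults at the generator's 1%/99% live-cell
#'   quantiles.
#' @param raft_edge_margin um margin from the raft edge (default 2).
#' @param max_cells_per_raft occupancy ceiling (default 6).
#' @param exclude_fiduciary drop fiduciary rafts (default TRUE).
#' @return a validated [QcGates-class].
#' @export
qcGates <- function(nuclear_area = qnorm(c(0.01, 0.99), 120, 15),
                    form_factor = c(qbeta(0.01, 14, 2), 1),
                    nuclear_intensity = qlnorm(c(0.01, 0.99), log(500), 0.25),
                    cell_intensity = qlnorm(c(0.01, 0.99), log(2000), 0.3),
                    raft_edge_margin = 2, max_cells_per_raft = 6L,
                    exclude_fiduciary = TRUE) {
  new("QcGates", nuclear_area = as.numeric(nuclear_area),
      form_factor = as.numeric(form_factor),
      nuclear_intensity = as.numeric(nuclear_intensity),
      cell_intensity = as.numeric(cell_intensity),
      raft_edge_margin = as.numeric(raft_edge_margin),
      max_cells_per_raft = as.integer(max_cells_per_raft),
      exclude_fiduciary = as.logical(exclude_fiduciary))
}

setMethod("show", "QcGates", function(object) {
  fmt <- function(v) sprintf("[%.3g, %.3g]", v[1], v[2])
  cat("QcGates: nuclear_area", fmt(object@nuclear_area),
      " form_factor", fmt(object@form_factor), "\n",
      " nuclear_intensity", fmt(object@nuclear_intensity),
      " cell_intensity", fmt(object@cell_intensity), "\n",
      " raft_edge_margin", object@raft_edge_margin,
      " max_cells_per_raft", object@max_cells_per_raft,
      " exclude_fiduciary", object@exclude_fiduciary, "\n")
})

#' ScreenModelSet: a trained classifier grid with its evaluation
#'
#' Bundle of fitted binary classifiers (one per grid spec), their per-cell
#' prediction scores and per-model metrics (train/test AUC, MCC,
#' mixture-proportion meta deviation).
#'
#' @slot results data.frame, one row per model (model_id, algorithm, lambda,
#'   n_features, feature method, auc_train, auc_test, mcc_test,
#'   meta_deviation, failed).
#' @slot models list of fitted model objects, named by model_id.
#' @slot scores numeric matrix, cells x models, scores in \[0,1\].
#' @slot features list of feature subsets per model.
#' @export
setClass("ScreenModelSet", representation(
  results = "data.frame", models = "list", scores = "matrix",
  features = "list"))

setMethod("show", "ScreenModelSet", function(object) {
  ok <- !object@results$failed
  cat("ScreenModelSet:", nrow(object@results), "models (",
      sum(!ok), "failed )\n")
  if (any(ok))
    cat("  test AUC: median", round(median(object@results$auc_test[ok]), 3),
        " best", round(max(object@results$auc_test[ok]), 3), "\n")
})

#' Accessor: per-model results table
#' @param x a [ScreenModelSet-class].
#' @return data.frame of per-model metrics.
#' @export
modelResults <- function(x) x@results

#' Accessor: per-cell score matrix
#' @param x a [ScreenModelSet-class].
#' @return matrix (cells x models) of scores in \[0,1\].
#' @export
modelScores <- function(x) x@scores

#' AnomalyEnsemble: robust-distance detectors on random feature subsets
#'
#' Each detector holds a random feature subset with robust per-feature
#' center (median) and scale (MAD) estimated on control cells; a cell's raw
#' detector score is the Euclidean norm of its robustly standardized subset.
#'
#' @slot detectors list of lists (features, center, scale).
#' @slot feature_space character vector of feature names.
#' @slot seed integer seed used to draw the subsets.
#' @export
setClass("AnomalyEnsemble", representation(
  detectors = "list", feature_space = "character", seed = "integer"))

setMethod("show", "AnomalyEnsemble", function(object) {
  cat("AnomalyEnsemble:", length(object@detectors), "detectors over",
      length(object@feature_space), "features (subset size",
      length(object@detectors[[1]]$features), ")\n")
})

#' Accessor: number of detectors
#' @param x an [AnomalyEnsemble-class].
#' @return integer detector count.
#' @export
nDetectors <- function(x) length(x@detectors)
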