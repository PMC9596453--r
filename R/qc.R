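# Record-level quality gates, per-plate robust normalization and
# leaky-feature exclusion. Fixed pipeline order: gates -> leak exclusion ->
# normalization.

#' Apply record-level quality gates
#'
#' A record is kept iff it passes every interval gate, lies at least the
#' margin from its raft edge, its raft holds no more than
#' `max_cells_per_raft` cells and (when enabled) the raft carries no
#' fiduciary mark. Dropped records get exactly one reason code: the first
#' failing gate in a fixed alphabetical order of gate names
#' (cell_intensity, fiduciary, form_factor, nuclear_area, nuclear_intensity,
#' raft_edge, raft_overcrowded).
#'
#' @param cells cell table (needs the gated columns and raft assignments).
#' @param gates a [QcGates-class].
#' @return list(kept = passing rows, log = data.frame(cell_id, reason)).
#' @export
applyQcGates <- function(cells, gates = qcGates()) {
  stopifnot(is(gates, "QcGates"))
  need <- c("cell_intensity", "fiduciary", "form_factor", "nuclear_area",
            "nuclear_intensity", "dist_to_raft_edge", "raft_key", "cell_id")
  miss <- setdiff(need, colnames(cells))
  if (length(miss))
    stop("configuration error: missing gated column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(cells) == 0L)
    return(list(kept = cells,
                log = data.frame(cell_id = character(0), reason = character(0))))
  inside <- function(v, iv) v >= iv[1] & v <= iv[2]
  occupancy <- table(cells$raft_key)
  fails <- list(  # alphabetical gate order fixes the reported reason
    cell_intensity = !inside(cells$cell_intensity, gates@cell_intensity),
    fiduciary = if (gates@exclude_fiduciary) cells$fiduciary
                else rep(FALSE, nrow(cells)),
    form_factor = !inside(cells$form_factor, gates@form_factor),
    nuclear_area = !inside(cells$nuclear_area, gates@nuclear_area),
    nuclear_intensity = !inside(cells$nuclear_intensity,
                                gates@nuclear_intensity),
    raft_edge = cells$dist_to_raft_edge < gates@raft_edge_margin,
    raft_overcrowded =
      as.integer(occupancy[cells$raft_key]) > gates@max_cells_per_raft)
  fail_any <- Reduce("|", fails)
  reason <- rep(NA_character_, nrow(cells))
  for (g in rev(names(fails))) reason[fails[[g]]] <- g
  list(kept = cells[!fail_any, , drop = FALSE],
       log = data.frame(cell_id = cells$cell_id[fail_any],
                        reason = reason[fail_any],
                        stringsAsFactors = FALSE))
}

#' Robust per-plate feature normalization
#'
#' Per plate and feature column: subtract the median and divide by the MAD
#' (scaled for normal consistency), so every plate's features end with
#' median 0 and scaled MAD 1. A feature with zero MAD on any plate is
#' flagged constant, dropped from the table and logged - not an error.
#'
#' @param cells cell table with a `plate` column and F### feature columns.
#' @return list(cells = normalized table, constant_features = character
#'   vector of dropped features).
#' @export
normalizeByPlate <- function(cells) {
  feats <- featureColumns(cells)
  constant <- character(0)
  for (f in feats) {
    for (p in unique(cells$plate)) {
      i <- cells$plate == p
      v <- cells[[f]][i]
      m <- mad(v)
      if (!is.finite(m) || m == 0) { constant <- c(constant, f); break }
      cells[[f]][i] <- (v - median(v)) / m
    }
  }
  constant <- unique(constant)
  if (length(constant)) cells <- cells[, setdiff(colnames(cells), constant)]
  list(cells = cells, constant_features = constant)
}

#' Flag leaky features (well-position proxies)
#'
#' Because labeled wells sit at fixed plate positions, any feature that
#' proxies well identity leaks the training label. The blacklist is the
#' union of: features whose rank-based eta-squared across wells (from the
#' Kruskal-Wallis H statistic) exceeds `eta2_cutoff`; features constant
#' within every well but varying across wells; and user-listed global
#' features.
#'
#' @param cells cell table with `well_key` and feature columns.
#' @param eta2_cutoff association cutoff (default 0.5).
#' @param user_blacklist feature names always excluded.
#' @return character vector of blacklisted feature names.
#' @export
flagLeakyFeatures <- function(cells, eta2_cutoff = 0.5,
                              user_blacklist = character(0)) {
  feats <- featureColumns(cells)
  wells <- factor(cells$well_key)
  k <- nlevels(wells)
  if (k < 2L) {
    warning("single well: leak detection impossible, empty blacklist")
    return(intersect(user_blacklist, feats))
  }
  n <- nrow(cells)
  black <- character(0)
  for (f in feats) {
    v <- cells[[f]]
    within_const <- all(tapply(v, wells, function(z) diff(range(z)) == 0))
    across_vary <- diff(range(tapply(v, wells, median))) > 0
    if (within_const && across_vary) { black <- c(black, f); next }
    H <- tryCatch(suppressWarnings(kruskal.test(v, wells)$statistic),
                  error = function(e) NA_real_)
    if (is.finite(H)) {
      eta2 <- (H - k + 1) / (n - k)  # rank-based eta-squared from H
      if (eta2 > eta2_cutoff) black <- c(black, f)
    }
  }
  union(black, intersect(user_blacklist, feats))
}

#' Run the full QC stage in its fixed order
#'
#' Gates, then leaky-feature exclusion, then per-plate normalization.
#' Re-running on the same input is bit-stable (no randomness).
#'
#' @param cells raw cell table.
#' @param gates a [QcGates-class].
#' @param eta2_cutoff,user_blacklist passed to [flagLeakyFeatures()].
#' @return list(cells, rejection_log, blacklist, constant_features).
#' @export
runQc <- function(cells, gates = qcGates(), eta2_cutoff = 0.5,
                  user_blacklist = character(0)) {
  gated <- applyQcGates(cells, gates)
  black <- flagLeakyFeatures(gated$kept, eta2_cutoff, user_blacklist)
  kept <- gated$kept[, setdiff(colnames(gated$kept), black), drop = FALSE]
  norm <- normalizeByPlate(kept)
  list(cells = norm$cells, rejection_log = gated$log, blacklist = black,
       constant_features = norm$constant_features)
}
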