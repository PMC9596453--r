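# Shared fixtures: small configs and independent brute-force oracles.

tinyConfig <- function(cells_per_well = 60L, effect_size = 1, seed = 1L, ...) {
  simConfig(cells_per_well = cells_per_well, effect_size = effect_size,
            seed = seed, ...)
}

# Independent AUC oracle: pairwise concordance with half credit for ties.
aucByConcordance <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Independent BH step-up oracle by explicit enumeration of the rule.
bhByEnumeration <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  jmax <- 0L
  for (j in seq_len(m)) if (ps[j] <= j * q / m) jmax <- j
  rej <- logical(m)
  if (jmax > 0L) rej[o[seq_len(jmax)]] <- TRUE
  rej
}

# Independent brute-force QC filter: re-evaluates every gate per record.
bruteForceQc <- function(cells, gates) {
  occ <- table(cells$raft_key)
  keep <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, ]
    keep[i] <-
      r$nuclear_area >= gates@nuclear_area[1] &&
      r$nuclear_area <= gates@nuclear_area[2] &&
      r$form_factor >= gates@form_factor[1] &&
      r$form_factor <= gates@form_factor[2] &&
      r$nuclear_intensity >= gates@nuclear_intensity[1] &&
      r$nuclear_intensity <= gates@nuclear_intensity[2] &&
      r$cell_intensity >= gates@cell_intensity[1] &&
      r$cell_intensity <= gates@cell_intensity[2] &&
      r$dist_to_raft_edge >= gates@raft_edge_margin &&
      occ[[r$raft_key]] <= gates@max_cells_per_raft &&
      !(gates@exclude_fiduciary && r$fiduciary)
  }
  keep
}

# Independent fragment counter: enumerate every k-length window of each
# read and its reverse complement (naive quadratic scan over windows).
naiveFragmentCounts <- function(seqs, panel) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  loci <- panelLoci(panel)
  frags <- c(setNames(loci$wt_fragment, paste0(loci$locus, ":wt")),
             setNames(loci$mut_fragment, paste0(loci$locus, ":mut")))
  k <- 20L
  counts <- setNames(integer(length(frags)), names(frags))
  for (s in seqs) {
    # all k-windows of the read and of its reverse complement
    wins <- unlist(lapply(c(s, rc(s)), function(v) {
      n <- nchar(v)
      if (n < k) character(0)
      else substring(v, seq_len(n - k + 1L), k:n)
    }))
    hit <- vapply(frags, function(f) f %in% wins, logical(1))
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# Picks table over rafts with exactly one member cell (clean truth).
singleCellPicks <- function(truth, n) {
  occ <- table(truth$raft_key)
  singles <- names(occ)[occ == 1L]
  keys <- head(singles, n)
  data.frame(raft_key = keys,
             dest_plate = ((seq_along(keys) - 1L) %/% 96L) + 1L,
             dest_well = sprintf("SC%03d", seq_along(keys)),
             stringsAsFactors = FALSE)
}
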