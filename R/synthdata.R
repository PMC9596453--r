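# Synthetic screen generator: feature tables, plate layouts, ground truth
# and amplicon reads. The generator defines the study conditions every
# downstream stage is tested against.

#' Build the plate layout for a SimConfig
#'
#' Assigns a role to every well: labeled wild-type and labeled mutant wells
#' are interleaved across plates (so a well-wise split can place training
#' wells on distinct plates), then one unlabeled admixture well per entry of
#' `unlabeled_fractions`; any remaining wells cycle through those fractions.
#'
#' @param config a [SimConfig-class].
#' @return data.frame (plate, well, well_key, role, expected_mut_fraction).
#' @export
makePlateLayout <- function(config) {
  n_wells <- config@n_plates * config@wells_per_plate
  # wells enumerated plate-alternating: P1W1, P2W1, P1W2, P2W2, ...
  plate <- rep(seq_len(config@n_plates), config@wells_per_plate)
  well <- paste0("W", rep(seq_len(config@wells_per_plate), each = config@n_plates))
  k <- config@n_labeled_wells
  nu <- n_wells - 2L * k
  fr <- rep(config@unlabeled_fractions, length.out = max(nu, 0L))
  # labeled roles flip order every consecutive well pair so each class's
  # wells land on both plates (required for cross-plate training splits)
  lab <- unlist(lapply(seq_len(k), function(j)
    if (j %% 2L == 1L) c("labeled-WT", "labeled-mutant")
    else c("labeled-mutant", "labeled-WT")))
  role <- c(lab, rep("unlabeled-mix", nu))
  frac <- c(ifelse(lab == "labeled-WT", 0, 1), fr)
  data.frame(plate = plate, well = well,
             well_key = wellKey(plate, well),
             role = role, expected_mut_fraction = frac,
             stringsAsFactors = FALSE)
}

# Truncated-Poisson raft occupancy: i.i.d. draws from Poisson(lambda)
# truncated to 1..10, accumulated until n cells are placed (last raft
# trimmed), over a random subset of the grid.
assignRafts <- function(n_cells, grid, lambda) {
  n_rafts <- grid[1] * grid[2]
  raft_order <- sample.int(n_rafts)
  occ <- integer(0)
  while (sum(occ) < n_cells) {
    draw <- rpois(max(16L, ceiling(n_cells / max(lambda, 0.5))), lambda)
    draw <- pmin(draw[draw >= 1L], 10L)
    occ <- c(occ, draw)
  }
  cum <- cumsum(occ)
  last <- which(cum >= n_cells)[1]
  occ <- occ[seq_len(last)]
  occ[last] <- occ[last] - (cum[last] - n_cells)
  if (last > n_rafts) stop("raft grid too small for cells_per_well")
  rep(raft_order[seq_len(last)], occ)
}

#' Simulate a full microraft screening plate set
#'
#' Draws one record per cell: genotype (per the well's role and mixture
#' proportion), informative features shifted by `effect_size` for pathogenic
#' genotypes under a block-equicorrelated Gaussian noise model, per-plate
#' additive batch offsets, leaky features that deterministically encode well
#' position, QC variables (nuclear area/intensity, cell intensity, form
#' factor, raft-edge distance) with a `debris_fraction` of records rendered
#' out of gate, truncated-Poisson raft occupancy and fiduciary-flagged
#' rafts. Identical config + seed gives identical output.
#'
#' @param config a [SimConfig-class].
#' @return list with `cells` (one row per record; features F001..Fnnn),
#'   `layout` (see [makePlateLayout()]) and `truth` (cell_id, genotype,
#'   class, is_debris, raft_key).
#' @examples
#' sim <- simulatePlate(simConfig(cells_per_well = 40, seed = 3))
#' head(sim$truth)
#' @export
simulatePlate <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  layout <- makePlateLayout(config)
  withSeed(childSeed(config@seed, 1), {
    p <- config@n_features
    classes <- setNames(config@genotypes$class, config@genotypes$genotype)
    path_geno <- config@genotypes$genotype[config@genotypes$class == "pathogenic"]
    if (length(path_geno) == 0L)
      path_geno <- config@genotypes$genotype[config@genotypes$class != "WT"]
    wt_geno <- config@genotypes$genotype[config@genotypes$class == "WT"][1]

    # per-plate batch offsets, one per feature
    batch <- matrix(rnorm(config@n_plates * p, 0, config@batch_sd),
                    nrow = config@n_plates)

    rows <- vector("list", nrow(layout))
    for (w in seq_len(nrow(layout))) {
      n <- config@cells_per_well
      lw <- layout[w, ]
      genotype <- switch(lw$role,
        "labeled-WT" = rep(wt_geno, n),
        "labeled-mutant" = sample(path_geno, n, replace = TRUE),
        "unlabeled-mix" = ifelse(runif(n) < lw$expected_mut_fraction,
                                 sample(path_geno, n, replace = TRUE), wt_geno))
      cls <- unname(classes[genotype])

      # block-equicorrelated noise: sqrt(rho) shared + sqrt(1-rho) own
      rho <- config@feature_correlation
      n_blocks <- ceiling(p / config@block_size)
      block_of <- rep(seq_len(n_blocks), each = config@block_size)[seq_len(p)]
      shared <- matrix(rnorm(n * n_blocks), n, n_blocks)
      X <- sqrt(rho) * shared[, block_of, drop = FALSE] +
        sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
      # effect on informative features for pathogenic cells
      inf <- seq_len(config@n_informative)
      X[, inf] <- X[, inf] + outer(as.numeric(cls == "pathogenic"),
                                   rep(config@effect_size, length(inf)))
      # plate batch offset
      X <- X + matrix(batch[lw$plate, ], n, p, byrow = TRUE)
      # leaky features: exact well column index plus tiny noise
      if (config@leaky_feature_count > 0L) {
        leak_cols <- (p - config@leaky_feature_count + 1L):p
        wi <- as.integer(sub("^W", "", lw$well))
        X[, leak_cols] <- wi + matrix(rnorm(n * length(leak_cols), 0, 0.01),
                                      n, length(leak_cols))
      }
      colnames(X) <- sprintf("F%03d", seq_len(p))

      # QC variables: live-cell distributions with a debris subpopulation
      is_debris <- runif(n) < config@debris_fraction
      nd <- sum(is_debris)
      nuclear_area <- rnorm(n, 120, 15)
      nuclear_intensity <- rlnorm(n, log(500), 0.25)
      cell_intensity <- rlnorm(n, log(2000), 0.3)
      form_factor <- pmin(rbeta(n, 14, 2), 1)
      if (nd > 0L) {
        nuclear_area[is_debris] <- runif(nd, 5, 40)
        nuclear_intensity[is_debris] <- rlnorm(nd, log(80), 0.5)
        cell_intensity[is_debris] <- rlnorm(nd, log(300), 0.5)
        form_factor[is_debris] <- rbeta(nd, 2, 2)
      }

      raft_idx <- assignRafts(n, config@raft_grid, config@mean_cells_per_raft)
      rr <- (raft_idx - 1L) %/% config@raft_grid[2]
      cc <- (raft_idx - 1L) %% config@raft_grid[2]
      raft_id <- encodeRaftId(rr, cc)
      # fiduciary rafts: fixed fraction of the grid per well
      n_rafts <- config@raft_grid[1] * config@raft_grid[2]
      fid_rafts <- sample.int(n_rafts,
                              size = round(config@fiduciary_fraction * n_rafts))
      fiduciary <- raft_idx %in% fid_rafts
      # position in the 100x100 um raft
      x <- runif(n, 0, 100); y <- runif(n, 0, 100)
      dist_to_raft_edge <- pmin(x, 100 - x, y, 100 - y)
      field <- 1L + (rr %/% max(1L, config@raft_grid[1] %/% 2L)) * 2L +
        (cc %/% max(1L, config@raft_grid[2] %/% 2L))

      cell_id <- sprintf("P%d_%s_C%05d", lw$plate, lw$well, seq_len(n))
      rows[[w]] <- data.frame(
        cell_id = cell_id, plate = lw$plate, well = lw$well,
        well_key = lw$well_key, field = field, raft_id = raft_id,
        raft_key = raftKey(lw$plate, lw$well, raft_id),
        x = x, y = y, dist_to_raft_edge = dist_to_raft_edge,
        nuclear_area = nuclear_area, nuclear_intensity = nuclear_intensity,
        cell_intensity = cell_intensity, form_factor = form_factor,
        fiduciary = fiduciary, genotype = genotype, class = cls,
        is_debris = is_debris, stringsAsFactors = FALSE)
      rows[[w]] <- cbind(rows[[w]], as.data.frame(X))
    }
    cells <- do.call(rbind, rows)
    rownames(cells) <- NULL
    truth <- cells[, c("cell_id", "raft_key", "genotype", "class", "is_debris")]
    cells$genotype <- NULL; cells$class <- NULL; cells$is_debris <- NULL
    list(cells = cells, layout = layout, truth = truth)
  })
}

#' The built-in genotyping locus panel
#'
#' Seven mitofusin-2 mutation loci plus the RFP/GFP reporter loci and the
#' PRIMPOL deletion locus, each with its wild-type and mutant 20-mer search
#' fragment and the genotyping primer pair; universal Illumina-compatible
#' forward/reverse adapter tags. Flanking context sequences are synthetic
#' (generated once under a fixed seed); the fragments and primers are the
#' published panel. Shipped as a plain-text table in
#' `inst/extdata/locus_panel_synthetic.tsv`.
#'
#' @return a [LocusPanel-class].
#' @export
defaultLocusPanel <- function() {
  path <- system.file("extdata", "locus_panel_synthetic.tsv",
                      package = "raftscreen")
  loci <- read.delim(path, stringsAsFactors = FALSE)
  new("LocusPanel", loci = loci,
      fwd_tag = "CACTCTTTCCCTACACGACGCTCTTCCGATCT",
      rev_tag = "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT")
}

# One simulated read pair from an amplicon: R1 = 5' read, R2 = reverse
# complement of the 3' end. Substitution errors at error_rate.
applySubstitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1, n, error_rate)
    if (k == 0) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired amplicon reads for picked rafts
#'
#' For every picked raft, each member cell (if the raft is captured) emits
#' `reads_per_cell` read pairs per panel locus. A mutant cell's own locus
#' carries the mutant fragment with probability drawn once per cell from
#' `mutant_allele_fraction`; every other locus (and every locus of WT cells)
#' carries the wild-type fragment. Per-base substitution errors are applied
#' at `error_rate`, and a fraction (1 - `capture_rate`) of rafts emit zero
#' reads, emulating isolation/amplification dropout.
#'
#' @param picks data.frame with columns `raft_key`, `dest_plate`,
#'   `dest_well` (a pick list, see [buildPickList()]).
#' @param truth ground-truth table from [simulatePlate()].
#' @param panel a [LocusPanel-class].
#' @param reads_per_cell read pairs per locus per captured cell (default 30).
#' @param error_rate per-base substitution probability (default 0.002; must
#'   be < 0.25).
#' @param capture_rate probability a raft yields reads (default 0.8).
#' @param mutant_allele_fraction function(n) returning n allele fractions.
#'   The default, 0.6 + 0.4 * Beta(8, 2), reflects mutant cDNA expressed
#'   above the endogenous wild-type copies: always mutant-majority, yet
#'   variable enough that the >50% call rule is nontrivially exercised.
#' @param read_length read length in bases (default 150).
#' @param seed RNG seed.
#' @return list of per-destination-well read sets; each element has `r1`,
#'   `r2` (character vectors), `q1`, `q2` (quality strings), plus attributes
#'   `captured` (logical per raft) recorded in the `capture` element.
#' @export
simulateAmpliconReads <- function(picks, truth, panel = defaultLocusPanel(),
                                  reads_per_cell = 30L, error_rate = 0.002,
                                  capture_rate = 0.8,
                                  mutant_allele_fraction = function(n)
                                    0.6 + 0.4 * rbeta(n, 8, 2),
                                  read_length = 150L, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 0.25, capture_rate >= 0,
            capture_rate <= 1)
  loci <- panel@loci
  if (any(nchar(loci$context_left) < 25L | nchar(loci$context_right) < 25L))
    stop("panel context must be >= 25 bases per side")
  unknown <- setdiff(picks$raft_key, truth$raft_key)
  if (length(unknown))
    stop("unknown raft id(s): ", paste(head(unknown, 3), collapse = ", "))
  withSeed(seed, {
    out <- list()
    capture <- setNames(runif(nrow(picks)) < capture_rate, picks$raft_key)
    for (i in seq_len(nrow(picks))) {
      rk <- picks$raft_key[i]
      wellname <- paste0(picks$dest_plate[i], "_", picks$dest_well[i])
      if (!capture[[rk]]) {
        out[[wellname]] <- list(r1 = character(0), r2 = character(0),
                                q1 = character(0), q2 = character(0),
                                raft_key = rk)
        next
      }
      members <- truth$genotype[truth$raft_key == rk]
      r1 <- character(0); r2 <- character(0)
      for (g in members) {
        maf <- mutant_allele_fraction(1)
        for (j in seq_len(nrow(loci))) {
          is_mut_locus <- identical(loci$mutant_name[j], g)
          n_mut <- if (is_mut_locus) rbinom(1, reads_per_cell, maf) else 0L
          frs <- c(rep(loci$mut_fragment[j], n_mut),
                   rep(loci$wt_fragment[j], reads_per_cell - n_mut))
          amplicon <- paste0(panel@fwd_tag, loci$primer_f[j],
                             loci$context_left[j], frs, loci$context_right[j],
                             revComp(loci$primer_r[j]), revComp(panel@rev_tag))
          amplicon <- applySubstitutions(amplicon, error_rate)
          r1 <- c(r1, substr(amplicon, 1L, read_length))
          r2 <- c(r2, revComp(substr(amplicon,
                                     pmax(1L, nchar(amplicon) - read_length + 1L),
                                     nchar(amplicon))))
        }
      }
      q1 <- strrep("F", nchar(r1)); q2 <- strrep("F", nchar(r2))
      out[[wellname]] <- list(r1 = r1, r2 = r2, q1 = q1, q2 = q2,
                              raft_key = rk)
    }
    attr(out, "capture") <- capture
    out
  })
}

#' Write simulated read sets as gzipped paired FASTQ files
#'
#' One `<well>_R1.fastq.gz` / `<well>_R2.fastq.gz` pair per destination
#' well.
#'
#' @param reads output of [simulateAmpliconReads()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
writeAmpliconFastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (wellname in names(reads)) {
    rd <- reads[[wellname]]
    for (mate in c("r1", "r2")) {
      p <- file.path(dir, paste0(wellname, "_", toupper(mate), ".fastq.gz"))
      seqs <- rd[[mate]]
      if (length(seqs)) {
        qs <- Biostrings::PhredQuality(rd[[sub("r", "q", mate)]])
        dss <- Biostrings::QualityScaledDNAStringSet(seqs, qs)
        names(dss) <- sprintf("%s_read%06d", wellname, seq_along(seqs))
        Biostrings::writeQualityScaledXStringSet(dss, p, compress = TRUE)
      } else {
        con <- gzfile(p, "w"); close(con)  # empty well: zero reads
      }
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Write the cell table / layout / truth of a simulation as TSV
#'
#' @param sim output of [simulatePlate()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cells.tsv", "layout.tsv", "truth.tsv"))
  write.table(sim$cells, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$layout, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
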