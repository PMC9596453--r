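# Sequencing analysis: merging, fragment counting, genotype calls and gRNA
# identification.

rcStr <- function(s) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))

test_that("read pairs merge at the constructed overlap", {
  set.seed(61)
  left <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  ov <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  r1 <- paste0(left, ov)            # 80 bases ending in the overlap
  r2 <- rcStr(paste0(ov, right))    # mate covering overlap + extension
  m <- mergeReadPair(r1, r2, min_overlap = 20)
  expect_true(m$merged)
  expect_equal(m$seq, paste0(left, ov, right))
  expect_equal(nchar(m$seq), 120L)
})

test_that("non-overlapping or noisy pairs stay unmerged", {
  a <- strrep("ACGT", 20)
  b <- strrep("GGCCATAT", 10)
  m <- mergeReadPair(a, b, min_overlap = 20)
  expect_false(m$merged)
  expect_length(m$mates, 2L)
  # 50% mismatches in the only candidate overlap: above the rate cap
  set.seed(5)
  ov <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  bad <- strsplit(ov, "")[[1]]
  bad[seq(1, 40, 2)] <- c(A = "C", C = "A", G = "T", T = "G")[
    bad[seq(1, 40, 2)]]
  m2 <- mergeReadPair(paste0(strrep("A", 30), ov),
                      rcStr(paste0(paste(bad, collapse = ""),
                                   strrep("C", 30))),
                      min_overlap = 20, max_mismatch_rate = 0.1)
  expect_false(m2$merged)
  expect_warning(mergeReadPair("", "ACGT"), "empty read")
})

test_that("overlap disagreements resolve by base quality", {
  ov <- strrep("ACGTG", 8)                    # 40-base true overlap
  ov_err <- sub("^A", "T", ov)                # one disagreeing base
  r1 <- paste0(strrep("C", 20), ov_err)
  r2 <- rcStr(paste0(ov, strrep("G", 20)))
  # r2 higher quality at the disagreement -> its base wins
  m <- mergeReadPair(r1, r2, q1 = strrep("#", 60), q2 = strrep("I", 60),
                     min_overlap = 20, min_q = 0)
  expect_true(m$merged)
  expect_equal(substr(m$seq, 21, 21), "A")
})

test_that("fragment counting is exact, strand-aware and mismatch-free", {
  panel <- defaultLocusPanel()
  gfp <- "TGCCCGAAGGCTACGTCCAG"  # GFP guide-site fragment
  read <- paste0(strrep("A", 30), gfp, strrep("C", 30))
  counts <- countFragments(read, panel)
  expect_equal(unname(counts["GFP:wt"]), 1L)
  # reverse-complemented read still counts
  expect_equal(unname(countFragments(rcStr(read), panel)["GFP:wt"]), 1L)
  # a single substitution kills the exact match
  mm <- sub("TGCCCG", "TGACCG", read)
  expect_equal(unname(countFragments(mm, panel)["GFP:wt"]), 0L)
  expect_equal(sum(countFragments(character(0), panel)), 0L)
})

test_that("fragment counts equal the naive quadratic scan", {
  panel <- defaultLocusPanel()
  loci <- panelLoci(panel)
  set.seed(71)
  reads <- vapply(1:300, function(i) {
    base <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    if (i %% 3 == 0) {  # implant a random panel fragment
      j <- sample(nrow(loci), 1)
      fr <- if (runif(1) < 0.5) loci$wt_fragment[j] else loci$mut_fragment[j]
      if (runif(1) < 0.5) fr <- rcStr(fr)
      base <- paste0(substr(base, 1, 20), fr, substr(base, 41, 60))
    }
    base
  }, "")
  fast <- countFragments(reads, panel)
  slow <- naiveFragmentCounts(reads, panel)
  expect_equal(as.integer(fast[names(slow)]), unname(slow))
})

test_that("genotype calls follow the >50% / argmax / tie / floor rules", {
  panel <- defaultLocusPanel()
  loci <- panelLoci(panel)
  blank <- setNames(integer(2 * nrow(loci)),
                    c(paste0(loci$locus, ":wt"), paste0(loci$locus, ":mut")))
  # L76 locus 90/10 mutant, everything else WT-only
  c1 <- blank; c1[paste0(loci$locus, ":wt")] <- 50L
  c1["MFN2_L76:mut"] <- 90L; c1["MFN2_L76:wt"] <- 10L
  call1 <- callGenotype(c1, panel)
  expect_equal(call1$call, "L76P")
  expect_equal(call1$loci$pct_mutant[call1$loci$locus == "MFN2_L76"], 0.9)
  # no locus above 50% -> WT
  c2 <- blank; c2[paste0(loci$locus, ":wt")] <- 40L
  c2[paste0(loci$locus, ":mut")] <- 10L
  expect_equal(callGenotype(c2, panel)$call, "WT")
  # two loci tied at 0.8 -> ambiguous
  c3 <- blank; c3[paste0(loci$locus, ":wt")] <- 20L
  c3["MFN2_L76:mut"] <- 80L; c3["MFN2_R94:mut"] <- 80L
  expect_equal(callGenotype(c3, panel)$call, "ambiguous")
  # depth floor: a high-% locus under min_reads is ignored
  c4 <- blank; c4["MFN2_L76:mut"] <- 4L
  expect_equal(callGenotype(c4, panel, min_reads = 10)$call, "no-data")
})

test_that("small-scale end-to-end genotyping recovers simulated truth", {
  sim <- simulatePlate(tinyConfig(cells_per_well = 150L, seed = 81L))
  picks <- singleCellPicks(sim$truth, 25L)
  rd <- simulateAmpliconReads(picks, sim$truth, reads_per_cell = 15L,
                              error_rate = 0, capture_rate = 1, seed = 4L)
  calls <- genotypeWells(rd, min_reads = 10L)
  truth <- sim$truth$genotype[match(vapply(rd, `[[`, "", "raft_key"),
                                    sim$truth$raft_key)]
  expect_equal(calls$call, unname(truth))
})

test_that("gRNA identification applies the majority and 20% rules", {
  lib <- c(g1 = "AAACCCGGGTTTAAACCCGG", g2 = "TTTGGGCCCAAATTTGGGCC")
  mk <- function(sp) paste0("ACGT", "GACGAAACACCG", sp, "GTTTTAGAGCTAGAA",
                            "TTTT")
  res <- identifyGrna(rep(mk(lib[["g1"]]), 10), lib)
  expect_equal(res$call, lib[["g1"]])
  expect_false(res$multi_infected)
  # 70/30 split -> multi-infected, both listed
  res2 <- identifyGrna(c(rep(mk(lib[["g1"]]), 7), rep(mk(lib[["g2"]]), 3)),
                       lib)
  expect_true(res2$multi_infected)
  expect_setequal(names(res2$spacers), unname(lib))
  # unknown spacer is tallied as such; no spacer reads -> no-data
  res3 <- identifyGrna(mk("GGGGGGGGGGGGGGGGGGGG"), lib)
  expect_equal(res3$call, "unknown")
  expect_equal(identifyGrna("ACGTACGT", lib)$call, "no-data")
})

test_that("FASTQ round-trip preserves reads and empty wells", {
  sim <- simulatePlate(tinyConfig(cells_per_well = 100L, seed = 91L))
  picks <- singleCellPicks(sim$truth, 6L)
  rd <- simulateAmpliconReads(picks, sim$truth, reads_per_cell = 5L,
                              error_rate = 0, capture_rate = 0.5, seed = 6L)
  dir <- tempfile("fq")
  writeAmpliconFastq(rd, dir)
  back <- readFastqPairs(dir)
  expect_setequal(names(back), names(rd))
  for (w in names(rd)) {
    expect_equal(back[[w]]$r1, unname(rd[[w]]$r1))
    expect_equal(back[[w]]$q2, unname(rd[[w]]$q2))
  }
})
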