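# Sequencing analysis: paired-read merging, exact 20-mer fragment counting
# (both strands), %mutant scoring, genotype calls and gRNA identification.

# Trim 3' bases with quality below min_q (Phred+33).
qualityTrim <- function(seq, qual, min_q = 10L) {
  if (!nchar(seq)) return(list(seq = seq, qual = qual))
  q <- utf8ToInt(qual) - 33L
  last <- length(q)
  while (last > 0L && q[last] < min_q) last <- last - 1L
  list(seq = substr(seq, 1L, last), qual = substr(qual, 1L, last))
}

#' Merge a read pair by overlap
#'
#' Reverse-complements the second mate, trims low-quality 3' tails, then
#' scans all overlap lengths from the longest down to `min_overlap` and
#' merges at the first (longest) overlap whose mismatch rate is at most
#' `max_mismatch_rate`. Disagreeing bases are resolved by the higher base
#' quality. Adapter tags are trimmed by exact prefix match when supplied.
#' If no acceptable overlap exists both mates are returned unmerged (they
#' are searched independently downstream).
#'
#' @param r1,r2 read sequences (r2 in sequencing orientation).
#' @param q1,q2 quality strings (Phred+33); NULL for uniform quality.
#' @param min_overlap minimum overlap length (default 20).
#' @param max_mismatch_rate maximum mismatch rate in the overlap
#'   (default 0.1).
#' @param trim_tags character vector of adapter/tag prefixes to strip from
#'   the merged sequence start.
#' @param min_q 3' quality-trim threshold (default Q10).
#' @return list(merged = logical, seq = merged sequence or NULL,
#'   mates = c(r1, rc(r2)) when unmerged).
#' @export
mergeReadPair <- function(r1, r2, q1 = NULL, q2 = NULL, min_overlap = 20L,
                          max_mismatch_rate = 0.1, trim_tags = character(0),
                          min_q = 10L) {
  if (!nchar(r1) || !nchar(r2)) {
    warning("empty read: skipped")
    return(list(merged = FALSE, seq = NULL, mates = character(0)))
  }
  if (is.null(q1)) q1 <- strrep("I", nchar(r1))
  if (is.null(q2)) q2 <- strrep("I", nchar(r2))
  t1 <- qualityTrim(r1, q1, min_q)
  t2 <- qualityTrim(r2, q2, min_q)
  s1 <- t1$seq
  s2 <- revComp(t2$seq)
  qq1 <- utf8ToInt(t1$qual) - 33L
  qq2 <- rev(utf8ToInt(t2$qual) - 33L)
  n1 <- nchar(s1); n2 <- nchar(s2)
  a1 <- charToRaw(s1); a2 <- charToRaw(s2)
  best <- NULL
  if (n1 >= min_overlap && n2 >= min_overlap) {
    # seed shortcut: locate the start of s2 inside s1 by exact 20-mer match,
    # implying a candidate overlap; verify it, then confirm no longer
    # overlap also passes (longest acceptable overlap wins).
    sd_len <- min(20L, n2)
    hit <- gregexpr(substr(s2, 1L, sd_len), s1, fixed = TRUE)[[1]]
    cand <- sort(unique(c(n1 - hit[hit > 0L] + 1L)), decreasing = TRUE)
    cand <- cand[cand >= min_overlap & cand <= min(n1, n2)]
    scan <- function(ovs) {
      for (ov in ovs) {
        mm <- sum(a1[(n1 - ov + 1L):n1] != a2[seq_len(ov)])
        if (mm / ov <= max_mismatch_rate) return(ov)
      }
      NULL
    }
    for (ov in cand) {
      mm <- sum(a1[(n1 - ov + 1L):n1] != a2[seq_len(ov)])
      if (mm / ov <= max_mismatch_rate) {
        longer <- if (ov < min(n1, n2)) scan(seq(min(n1, n2), ov + 1L))
                  else NULL
        best <- if (is.null(longer)) ov else longer
        break
      }
    }
    if (is.null(best)) best <- scan(seq(min(n1, n2), min_overlap))
  }
  if (is.null(best)) {
    out <- list(merged = FALSE, seq = NULL, mates = c(s1, s2))
  } else {
    ov <- best
    x <- a1[(n1 - ov + 1L):n1]; y <- a2[seq_len(ov)]
    use_y <- x != y & qq2[seq_len(ov)] > qq1[(n1 - ov + 1L):n1]
    cons <- x; cons[use_y] <- y[use_y]
    merged <- paste0(substr(s1, 1L, n1 - ov), rawToChar(cons),
                     substr(s2, ov + 1L, n2))
    out <- list(merged = TRUE, seq = merged, mates = character(0))
  }
  if (length(trim_tags)) {
    strip <- function(s) {
      for (tg in trim_tags)
        if (startsWith(s, tg)) s <- substr(s, nchar(tg) + 1L, nchar(s))
      s
    }
    if (!is.null(out$seq)) out$seq <- strip(out$seq)
    out$mates <- vapply(out$mates, strip, "", USE.NAMES = FALSE)
  }
  out
}

# Merge all pairs of a well's read set; returns character vector of
# sequences to search (merged reads, plus both mates of unmerged pairs).
mergeWellReads <- function(rd, min_overlap = 20L, max_mismatch_rate = 0.1) {
  out <- character(0)
  for (i in seq_along(rd$r1)) {
    m <- mergeReadPair(rd$r1[i], rd$r2[i], rd$q1[i], rd$q2[i],
                       min_overlap = min_overlap,
                       max_mismatch_rate = max_mismatch_rate)
    out <- c(out, if (m$merged) m$seq else m$mates)
  }
  out
}

#' Count panel fragments in a set of reads
#'
#' Each panel fragment (WT and mutant 20-mer per locus) found as an exact
#' substring of a read or of its reverse complement increments that
#' fragment's count once per read. No mismatches are tolerated.
#'
#' @param seqs character vector of (merged) read sequences.
#' @param panel a [LocusPanel-class].
#' @return named integer vector: `<locus>:wt` and `<locus>:mut` counts,
#'   plus attribute "total_reads".
#' @export
countFragments <- function(seqs, panel = defaultLocusPanel()) {
  loci <- panel@loci
  frag_names <- c(paste0(loci$locus, ":wt"), paste0(loci$locus, ":mut"))
  counts <- setNames(integer(length(frag_names)), frag_names)
  if (length(seqs)) {
    ss <- Biostrings::DNAStringSet(seqs)
    rc <- Biostrings::reverseComplement(ss)
    hit <- function(frag)
      sum((Biostrings::vcountPattern(frag, ss, fixed = TRUE) +
           Biostrings::vcountPattern(frag, rc, fixed = TRUE)) > 0L)
    for (j in seq_len(nrow(loci))) {
      counts[paste0(loci$locus[j], ":wt")] <- hit(loci$wt_fragment[j])
      counts[paste0(loci$locus[j], ":mut")] <- hit(loci$mut_fragment[j])
    }
  }
  attr(counts, "total_reads") <- length(seqs)
  counts
}

#' Call a genotype from fragment counts
#'
#' Per locus, the %mutant score is mutant reads over total reads at the
#' locus; loci with fewer than `min_reads` total reads are excluded from
#' the decision. The call is `no-data` if no locus has data, `WT` if no
#' locus has a %mutant score above 0.5, otherwise the mutant name of the
#' unique highest-scoring locus; `ambiguous` if the top scores tie within
#' 1e-9.
#'
#' @param counts output of [countFragments()] for one well.
#' @param panel a [LocusPanel-class].
#' @param min_reads per-locus read-depth floor (default 10).
#' @return list(call, loci = data.frame(locus, mutant_name, wt, mut, total,
#'   pct_mutant, used)).
#' @export
callGenotype <- function(counts, panel = defaultLocusPanel(),
                         min_reads = 10L) {
  loci <- panel@loci
  wt <- as.integer(counts[paste0(loci$locus, ":wt")])
  mut <- as.integer(counts[paste0(loci$locus, ":mut")])
  total <- wt + mut
  pct <- ifelse(total > 0, mut / total, NA_real_)
  used <- total >= min_reads
  tab <- data.frame(locus = loci$locus, mutant_name = loci$mutant_name,
                    wt = wt, mut = mut, total = total, pct_mutant = pct,
                    used = used, stringsAsFactors = FALSE)
  if (!any(used)) return(list(call = "no-data", loci = tab))
  p <- pct[used]
  if (all(p <= 0.5)) return(list(call = "WT", loci = tab))
  top <- max(p)
  hits <- which(used)[p >= top - 1e-9]
  if (length(hits) > 1L) return(list(call = "ambiguous", loci = tab))
  list(call = loci$mutant_name[hits], loci = tab)
}

#' Genotype a set of wells from simulated or file-based reads
#'
#' Merges each well's read pairs, counts panel fragments and calls the
#' genotype.
#'
#' @param reads list of per-well read sets (see [simulateAmpliconReads()])
#'   or a directory of `<well>_R1/R2.fastq.gz` pairs.
#' @param panel a [LocusPanel-class].
#' @param min_reads read-depth floor per locus.
#' @return data.frame (well, raft_key if known, call, plus one
#'   `pct_<locus>` column per locus); fragment counts in attribute
#'   "counts" (wells x fragments matrix).
#' @export
genotypeWells <- function(reads, panel = defaultLocusPanel(),
                          min_reads = 10L) {
  if (is.character(reads)) reads <- readFastqPairs(reads)
  loci <- panel@loci
  rows <- vector("list", length(reads))
  cmat <- matrix(0L, length(reads), 2L * nrow(loci),
                 dimnames = list(names(reads),
                                 c(paste0(loci$locus, ":wt"),
                                   paste0(loci$locus, ":mut"))))
  for (i in seq_along(reads)) {
    seqs <- mergeWellReads(reads[[i]])
    counts <- countFragments(seqs, panel)
    cmat[i, names(counts)] <- counts
    call <- callGenotype(counts, panel, min_reads)
    pcts <- setNames(as.list(call$loci$pct_mutant),
                     paste0("pct_", call$loci$locus))
    rows[[i]] <- cbind(data.frame(well = names(reads)[i],
                                  raft_key = reads[[i]]$raft_key %||% NA,
                                  call = call$call,
                                  stringsAsFactors = FALSE),
                       as.data.frame(pcts))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- cmat
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read per-well gzipped FASTQ pairs from a directory
#'
#' Expects files named `<well>_R1.fastq.gz` / `<well>_R2.fastq.gz`.
#'
#' @param dir directory path.
#' @return list of per-well read sets (r1, r2, q1, q2).
#' @export
readFastqPairs <- function(dir) {
  f1 <- sort(list.files(dir, "_R1\\.fastq\\.gz$", full.names = TRUE))
  out <- list()
  for (p1 in f1) {
    well <- sub("_R1\\.fastq\\.gz$", "", basename(p1))
    p2 <- file.path(dir, paste0(well, "_R2.fastq.gz"))
    # suppress the benign "metadata columns dropped" notice on read
    rd1 <- tryCatch(suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(p1)),
      error = function(e) NULL)
    rd2 <- tryCatch(suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(p2)),
      error = function(e) NULL)
    if (is.null(rd1) || length(rd1) == 0L) {
      out[[well]] <- list(r1 = character(0), r2 = character(0),
                          q1 = character(0), q2 = character(0))
    } else {
      out[[well]] <- list(r1 = unname(as.character(rd1)),
                          r2 = unname(as.character(rd2)),
                          q1 = unname(as.character(Biostrings::quality(rd1))),
                          q2 = unname(as.character(Biostrings::quality(rd2))))
    }
  }
  out
}

#' Identify the gRNA present in a well from spacer-bearing reads
#'
#' The spacer is the subsequence between the known vector flanks; exact
#' matches against the library are tallied. The well is assigned the
#' majority spacer; if two spacers each hold at least 20% of spacer reads
#' the well is reported multi-infected. Spacers absent from the library
#' count as "unknown".
#'
#' @param seqs character vector of (merged) read sequences for one well.
#' @param library character vector of spacer sequences (named or not).
#' @param flank5,flank3 vector sequences bounding the spacer.
#' @return list(call, multi_infected, spacers = sorted tally,
#'   n_spacer_reads).
#' @export
identifyGrna <- function(seqs, library,
                         flank5 = "GACGAAACACCG", flank3 = "GTTTTAGAGCTAGAA") {
  spacers <- character(0)
  if (length(seqs)) {
    pat <- paste0(flank5, "([ACGT]+?)", flank3)
    for (s in c(seqs, revComp(seqs))) {
      m <- regmatches(s, regexec(pat, s))[[1]]
      if (length(m) == 2L) spacers <- c(spacers, m[2])
    }
  }
  if (!length(spacers))
    return(list(call = "no-data", multi_infected = FALSE,
                spacers = integer(0), n_spacer_reads = 0L))
  known <- spacers %in% library
  spacers[!known] <- "unknown"
  tab <- sort(table(spacers), decreasing = TRUE)
  frac <- tab / sum(tab)
  multi <- sum(frac >= 0.2) >= 2L
  list(call = names(tab)[1], multi_infected = multi,
       spacers = tab, n_spacer_reads = length(spacers))
}
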