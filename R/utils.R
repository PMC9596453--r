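# Internal helpers shared across stages.

#' Derive a stage-specific child seed from a master seed
#'
#' All stochastic stages draw their RNG state from one master seed through
#' fixed per-stage offsets, so a single integer reproduces a whole run while
#' stages stay independently re-runnable.
#'
#' @param seed master seed (integer-valued scalar).
#' @param offset fixed, stage-specific nonnegative integer offset.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
childSeed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(offset), length(offset) == 1L, offset >= 0)
  as.integer((abs(as.numeric(seed)) + as.numeric(offset) * 1000003) %% 2147483629)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Rank-based area under the ROC curve
#'
#' AUC computed from the rank statistic (Mann-Whitney form), which equals the
#' trapezoidal area under the empirical ROC curve; tied scores receive half
#' credit.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical or 0/1 vector, TRUE/1 = positive class.
#' @return AUC in [0, 1]; NA (with a warning) if a class is absent.
#' @examples
#' aucScore(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))  # 1
#' @export
aucScore <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: one class absent")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient at a score threshold
#'
#' @param scores numeric scores in [0, 1].
#' @param labels logical or 0/1 truth.
#' @param threshold decision threshold (default 0.5; predicted positive if
#'   score > threshold).
#' @return MCC in [-1, 1]; 0 when a marginal is degenerate.
#' @export
mccScore <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  pred <- scores > threshold
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  if (den == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
}

# Reverse complement of plain character DNA (byte-level; fast for the
# per-read paths).
revComp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(x, function(s) rawToChar(rev(charToRaw(s))), "",
                USE.NAMES = FALSE))
}

#' Names of the feature columns of a cell table (F001..Fnnn)
#' @param cells a cell table.
#' @return character vector of feature column names.
#' @export
featureColumns <- function(cells) {
  grep("^F[0-9]+$", colnames(cells), value = TRUE)
}

# Canonical per-plate-well key.
wellKey <- function(plate, well) paste0("P", plate, "_", well)

# Canonical raft key unique across the experiment.
raftKey <- function(plate, well, raft_id) paste0("P", plate, "_", well, "_", raft_id)
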