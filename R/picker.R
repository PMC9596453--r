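# Pick-list generation: per-raft score aggregation with a conflict veto,
# confidence bands, deterministic ranking and destination-plate assignment.

# 96-well destinations in row-major order A1..H12.
destWells <- function(n) {
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  k <- ((seq_len(n) - 1L) %% 96L) + 1L
  data.frame(dest_plate = ((seq_len(n) - 1L) %/% 96L) + 1L,
             dest_well = wells[k])
}

#' Build a deterministic raft pick list from per-cell scores
#'
#' Per raft, the score is the mean of its member cells' scores. A raft is
#' dropped if any two members conflict confidently (one scoring at or below
#' 1 - `confidence_threshold`, another at or above it) or if its score
#' falls in the open exclusion band (0.4, 0.6). Remaining rafts are ranked
#' by |score - 0.5| descending (ties by raft id) and the top `n_max` per
#' predicted class are selected. Destinations are assigned row-major
#' A1..H12 across 96-well plates; an optional quota of labeled-well control
#' rafts is interleaved at every `control_every`-th destination.
#'
#' @param cells cell table (needs raft_key, well_key, cell_id).
#' @param scores per-cell scores aligned with `cells`.
#' @param layout plate layout (identifies labeled wells for controls).
#' @param confidence_threshold conflict-veto threshold in (0.5, 1\]
#'   (default 0.8).
#' @param exclusion_band open interval of unclassifiable scores
#'   (default c(0.4, 0.6); boundary scores stay eligible).
#' @param n_max maximum picks per predicted class (default 96).
#' @param n_controls labeled-well control rafts to interleave (default 0).
#' @param control_every interleave period for controls (default 8).
#' @return data.frame (raft_id, raft_key, score, predicted_class, band,
#'   n_cells, is_control, dest_plate, dest_well); deterministic for equal
#'   inputs. If fewer confident rafts exist than requested, the shortfall
#'   is reported in attribute "shortfall".
#' @export
buildPickList <- function(cells, scores, layout,
                          confidence_threshold = 0.8,
                          exclusion_band = c(0.4, 0.6), n_max = 96L,
                          n_controls = 0L, control_every = 8L) {
  stopifnot(confidence_threshold > 0.5, confidence_threshold <= 1)
  roles <- layout$role[match(cells$well_key, layout$well_key)]
  unl <- roles == "unlabeled-mix"
  agg <- function(idx) {
    df <- data.frame(raft_key = cells$raft_key[idx], s = scores[idx])
    sp <- split(df$s, df$raft_key)
    data.frame(raft_key = names(sp),
               score = vapply(sp, mean, 0),
               n_cells = lengths(sp),
               conflict = vapply(sp, function(v)
                 any(v <= 1 - confidence_threshold) &&
                 any(v >= confidence_threshold), TRUE),
               stringsAsFactors = FALSE)
  }
  rafts <- agg(which(unl))
  ok <- !rafts$conflict &
    !(rafts$score > exclusion_band[1] & rafts$score < exclusion_band[2])
  rafts <- rafts[ok, , drop = FALSE]
  rafts$predicted_class <- ifelse(rafts$score > 0.5, "mutant", "WT")
  band <- function(s) {
    conf <- pmax(s, 1 - s)
    ifelse(conf >= 0.9, "0.9", ifelse(conf >= 0.8, "0.8",
           ifelse(conf >= 0.7, "0.7", "<0.7")))
  }
  rafts$band <- band(rafts$score)
  rafts <- rafts[order(-abs(rafts$score - 0.5), rafts$raft_key), ,
                 drop = FALSE]
  picked <- do.call(rbind, lapply(split(rafts, rafts$predicted_class),
                                  head, n_max))
  shortfall <- max(0L, 2L * n_max - nrow(picked)) # informative, not fatal
  picked <- picked[order(-abs(picked$score - 0.5), picked$raft_key), ,
                   drop = FALSE]
  picked$is_control <- FALSE
  if (n_controls > 0L) {
    ctl <- agg(which(!unl & !is.na(roles)))
    ctl <- ctl[!ctl$conflict, , drop = FALSE]
    ctl <- ctl[order(ctl$raft_key), , drop = FALSE]
    ctl <- head(ctl, n_controls)
    ctl$predicted_class <- ifelse(ctl$score > 0.5, "mutant", "WT")
    ctl$band <- band(ctl$score)
    ctl$is_control <- TRUE
    # interleave: every control_every-th slot holds a control while any last
    out <- list(); ci <- 1L; pi <- 1L; slot <- 1L
    while (pi <= nrow(picked) || ci <= nrow(ctl)) {
      take_ctl <- (slot %% control_every == 0L && ci <= nrow(ctl)) ||
        pi > nrow(picked)
      if (take_ctl && ci <= nrow(ctl)) {
        out[[slot]] <- ctl[ci, , drop = FALSE]; ci <- ci + 1L
      } else {
        out[[slot]] <- picked[pi, , drop = FALSE]; pi <- pi + 1L
      }
      slot <- slot + 1L
    }
    picked <- do.call(rbind, out)
  }
  dest <- destWells(nrow(picked))
  picked <- cbind(picked, dest)
  picked$raft_id <- sub("^P[0-9]+_[^_]+_", "", picked$raft_key)
  rownames(picked) <- NULL
  out <- picked[, c("raft_id", "raft_key", "score", "predicted_class",
                    "band", "n_cells", "is_control", "dest_plate",
                    "dest_well")]
  attr(out, "shortfall") <- shortfall
  out
}

#' Write a pick list as the CSV contract consumed downstream
#'
#' @param picks output of [buildPickList()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writePickList <- function(picks, path) {
  write.table(picks[, c("raft_id", "score", "predicted_class", "band",
                        "dest_plate", "dest_well")],
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
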