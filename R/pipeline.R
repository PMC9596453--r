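# Stage runner tying the pipeline together over plain-file contracts
# (TSV/CSV/FASTQ), with a manifest of output digests for reproducibility.

manifestAppend <- function(outdir, stage, files) {
  mf <- file.path(outdir, "manifest.tsv")
  rows <- data.frame(stage = stage, file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     stringsAsFactors = FALSE)
  write.table(rows, mf, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !file.exists(mf), append = file.exists(mf))
  invisible(rows)
}

#' Read a flat key-value (YAML) config file into a SimConfig
#'
#' Keys mirror [simConfig()] argument names; missing keys keep defaults.
#'
#' @param path YAML file path.
#' @return a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  kv <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  do.call(simConfig, kv[intersect(names(kv), known)])
}

#' Run one pipeline stage on the file contracts in an output directory
#'
#' Stages: `simulate`, `qc`, `train`, `pick`, `reads`, `genotype`,
#' `evaluate`. Each stage reads the files earlier stages wrote under
#' `outdir`, writes its own outputs there, and appends their digests to
#' `manifest.tsv`. Any stage is independently re-runnable on files produced
#' by an earlier run.
#'
#' @param stage stage name.
#' @param outdir working directory for the run.
#' @param config a [SimConfig-class] (used by `simulate`).
#' @param seed master seed; stage seeds derive from it by fixed offsets.
#' @param n_random random-subset count for the model grid (default 20,
#'   giving a few hundred models).
#' @param n_max,n_controls pick-list sizing (see [buildPickList()]).
#' @param reads_per_cell,error_rate,capture_rate amplicon simulation
#'   parameters.
#' @return invisibly, a list of the stage's in-memory outputs.
#' @export
runStage <- function(stage, outdir, config = simConfig(), seed = 1L,
                     n_random = 20L, n_max = 96L, n_controls = 0L,
                     reads_per_cell = 30L, error_rate = 0.002,
                     capture_rate = 0.8) {
  stages <- c("simulate", "qc", "train", "pick", "reads", "genotype",
              "evaluate")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; stages: ",
         paste(stages, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(name) file.path(outdir, name)
  rd <- function(name, ...) read.delim(tsv(name), stringsAsFactors = FALSE, ...)
  wr <- function(x, name) {
    write.table(x, tsv(name), sep = "\t", quote = FALSE, row.names = FALSE)
    tsv(name)
  }
  need <- function(name) {
    if (!file.exists(tsv(name))) stop("missing input: ", tsv(name))
    name
  }
  out <- switch(stage,
    simulate = {
      sim <- simulatePlate(config)
      files <- writeSimulation(sim, outdir)
      manifestAppend(outdir, stage, files)
      message(sprintf("simulate: %d cells, %d wells", nrow(sim$cells),
                      nrow(sim$layout)))
      sim
    },
    qc = {
      cells <- rd(need("cells.tsv"))
      qc <- runQc(cells)
      files <- c(wr(qc$cells, "qc_cells.tsv"),
                 wr(qc$rejection_log, "rejection_log.tsv"))
      writeLines(qc$blacklist, tsv("blacklist.txt"))
      manifestAppend(outdir, stage, c(files, tsv("blacklist.txt")))
      message(sprintf("qc: %d/%d cells kept, %d leaky features excluded",
                      nrow(qc$cells), nrow(cells), length(qc$blacklist)))
      qc
    },
    train = {
      cells <- rd(need("qc_cells.tsv"))
      layout <- rd(need("layout.tsv"))
      labels <- labelFromLayout(cells, layout)
      split <- splitWells(layout, "well", seed = childSeed(seed, 10))
      tr <- cells$well_key %in% split$train_wells & !is.na(labels)
      X <- as.matrix(cells[, featureColumns(cells)])
      specs <- makeModelGrid(X[tr, ], labels[tr], n_random = n_random,
                             seed = childSeed(seed, 3))
      mset <- trainModelGrid(cells, layout, specs = specs, split = split,
                             seed = childSeed(seed, 10))
      chosen <- selectPickModel(mset)
      files <- c(wr(modelResults(mset), "models.tsv"),
                 wr(data.frame(cell_id = rownames(modelScores(mset)),
                               score = modelScores(mset)[, chosen]),
                    "cell_scores.tsv"))
      writeLines(chosen, tsv("selected_model.txt"))
      manifestAppend(outdir, stage, c(files, tsv("selected_model.txt")))
      message(sprintf("train: %d models, selected %s",
                      nrow(modelResults(mset)), chosen))
      list(mset = mset, chosen = chosen)
    },
    pick = {
      cells <- rd(need("qc_cells.tsv"))
      layout <- rd(need("layout.tsv"))
      sc <- rd(need("cell_scores.tsv"))
      scores <- sc$score[match(cells$cell_id, sc$cell_id)]
      picks <- buildPickList(cells, scores, layout, n_max = n_max,
                             n_controls = n_controls)
      f <- wr(picks, "picks.tsv")
      writePickList(picks, tsv("picks.csv"))
      manifestAppend(outdir, stage, c(f, tsv("picks.csv")))
      message(sprintf("pick: %d rafts", nrow(picks)))
      picks
    },
    reads = {
      picks <- rd(need("picks.tsv"))
      truth <- rd(need("truth.tsv"))
      reads <- simulateAmpliconReads(picks, truth,
                                     reads_per_cell = reads_per_cell,
                                     error_rate = error_rate,
                                     capture_rate = capture_rate,
                                     seed = childSeed(seed, 20))
      files <- writeAmpliconFastq(reads, file.path(outdir, "fastq"))
      manifestAppend(outdir, stage, files)
      message(sprintf("reads: %d wells written", length(reads)))
      reads
    },
    genotype = {
      calls <- genotypeWells(file.path(outdir, "fastq"))
      picks <- rd(need("picks.tsv"))
      key <- paste0(picks$dest_plate, "_", picks$dest_well)
      calls$raft_key <- picks$raft_key[match(calls$well, key)]
      f <- wr(calls, "genotype_calls.tsv")
      manifestAppend(outdir, stage, f)
      message(sprintf("genotype: %d wells, %d called",
                      nrow(calls), sum(!calls$call %in% "no-data")))
      calls
    },
    evaluate = {
      picks <- rd(need("picks.tsv"))
      calls <- rd(need("genotype_calls.tsv"))
      join <- joinPredictionsGenotypes(picks[!picks$is_control, ], calls,
                                       classMap())
      res <- list(n = nrow(join))
      if (nrow(join) && length(unique(join$truth_mutant)) == 2L) {
        roc <- rocWithNoise(join, seed = childSeed(seed, 30))
        res$auc <- roc$auc
        res$noise_auc_mean <- mean(roc$noise_auc)
        res$accuracy <- mean((join$score > 0.5) == join$truth_mutant)
        tm <- thresholdMetrics(join)
        res$band_accuracy <- setNames(tm$accuracy, tm$band)
      }
      writeLines(as.character(utils::capture.output(str(res))),
                 tsv("metrics.txt"))
      f <- wr(join, "eval_join.tsv")
      manifestAppend(outdir, stage, c(f, tsv("metrics.txt")))
      message(sprintf("evaluate: %d joined rafts", res$n))
      res
    })
  invisible(out)
}

#' Run the full pipeline end to end
#'
#' simulate -> qc -> train -> pick -> reads -> genotype -> evaluate, all
#' seeded from one master seed.
#'
#' @param outdir working directory.
#' @param config a [SimConfig-class].
#' @param seed master seed.
#' @param ... passed to [runStage()].
#' @return invisibly, the evaluate stage's metric list.
#' @export
runPipeline <- function(outdir, config = simConfig(), seed = 1L, ...) {
  for (s in c("simulate", "qc", "train", "pick", "reads", "genotype",
              "evaluate"))
    out <- runStage(s, outdir, config = config, seed = seed, ...)
  invisible(out)
}

#' @importFrom utils str capture.output
#' @importFrom stats aggregate
NULL
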