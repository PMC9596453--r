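# Supervised ensemble: splits, oversampling, feature selection, training,
# evaluation, the meta-feature check and pick-model selection.

test_that("well-wise splits never split a well and span plates", {
  layout <- makePlateLayout(tinyConfig())
  sp <- splitWells(layout, "well", seed = 4L)
  expect_length(intersect(sp$train_wells, sp$test_wells), 0L)
  for (r in c("labeled-WT", "labeled-mutant")) {
    wk <- layout$well_key[layout$role == r]
    tr <- intersect(sp$train_wells, wk)
    expect_length(tr, 2L)
    expect_equal(length(unique(layout$plate[layout$well_key %in% tr])), 2L)
  }
  expect_identical(sp, splitWells(layout, "well", seed = 4L))
  # degenerate: one labeled well per class
  lay1 <- layout[c(1, 2), ]
  expect_error(splitWells(lay1, "well"), ">= 2 labeled wells")
})

test_that("random 80-20 split partitions cells reproducibly", {
  cells <- data.frame(cell_id = sprintf("c%03d", 1:100))
  sp <- splitWells(makePlateLayout(tinyConfig()), "random", seed = 2L,
                   cells = cells)
  expect_length(sp$train_ids, 80L)
  expect_length(sp$test_ids, 20L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_identical(sp, splitWells(makePlateLayout(tinyConfig()), "random",
                                  seed = 2L, cells = cells))
})

test_that("minority oversampling balances classes by convex interpolation", {
  # balanced input unchanged
  X <- matrix(rnorm(40), 20)
  y <- rep(0:1, each = 10)
  os <- oversampleMinority(X, y, seed = 1L)
  expect_identical(os$X, X)
  # hand case: minority {(0,0),(1,1)}, k = 1 -> synthetic on the diagonal
  X2 <- rbind(matrix(rnorm(20, 10), 10), c(0, 0), c(1, 1))
  y2 <- c(rep(0, 10), 1, 1)
  os2 <- oversampleMinority(X2, y2, k_neighbors = 1L, seed = 3L)
  expect_equal(as.vector(table(os2$y)), c(10L, 10L))
  syn <- os2$X[os2$synthetic, , drop = FALSE]
  expect_equal(syn[, 1], syn[, 2], tolerance = 1e-12)  # on the segment
  expect_true(all(syn >= 0 & syn <= 1))
  # 10/90 -> 90/90, and every synthetic point between its parent pair
  X3 <- matrix(rnorm(200), 100)
  y3 <- c(rep(1, 10), rep(0, 90))
  os3 <- oversampleMinority(X3, y3, seed = 5L)
  expect_equal(as.vector(table(os3$y)), c(90L, 90L))
  syn3 <- os3$X[os3$synthetic, , drop = FALSE]
  for (i in seq_len(nrow(syn3))) {
    p <- X3[os3$parents[i, 1], ]; q <- X3[os3$parents[i, 2], ]
    lo <- pmin(p, q) - 1e-9; hi <- pmax(p, q) + 1e-9
    expect_true(all(syn3[i, ] >= lo & syn3[i, ] <= hi))
    # collinear: s - p parallel to q - p
    if (sum((q - p)^2) > 0) {
      u <- (syn3[i, ] - p) / (q - p)
      u <- u[is.finite(u)]
      expect_lt(diff(range(u)), 1e-9)
    }
  }
})

test_that("feature selection methods behave on constructed cases", {
  set.seed(11)
  n <- 200
  informative <- rnorm(n) + rep(c(0, 3), each = n / 2)
  X <- cbind(info = informative,
             matrix(rnorm(n * 9), n, 9,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  y <- rep(0:1, each = n / 2)
  # duplicated feature: correlation filter keeps exactly one
  Xdup <- cbind(X, info2 = X[, "info"])
  kept <- selectFeatures(Xdup, method = "correlation", max_cor = 0.95)
  expect_equal(sum(kept %in% c("info", "info2")), 1L)
  # anova_f finds the informative feature
  expect_equal(selectFeatures(X, y, "anova_f", k = 1), "info")
  # random subsets are reproducible and size-checked
  r1 <- selectFeatures(X, method = "random", size = 4, seed = 9)
  expect_identical(r1, selectFeatures(X, method = "random", size = 4,
                                      seed = 9))
  expect_error(selectFeatures(X, method = "random", size = 99), "exceeds")
  # l1svm keeps a sparse informative set
  expect_true("info" %in% selectFeatures(X, y, "l1svm", lambda = 0.05))
  # variance filter drops near-constants
  Xc <- cbind(X, flat = rep(1, n) + rnorm(n, 0, 1e-6))
  expect_false("flat" %in%
    selectFeatures(Xc, method = "variance", min_variance = 1e-3))
})

test_that("AUC equals the pairwise-concordance oracle and MCC checks out", {
  expect_equal(aucScore(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(aucScore(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(21)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    s <- round(runif(n), 2)  # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(aucScore(s, y), aucByConcordance(s, y), tolerance = 1e-12)
  }
  expect_equal(mccScore(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  # TP = TN = FP = FN = 1 -> 0 by the MCC formula
  expect_equal(mccScore(c(0.9, 0.1, 0.9, 0.1), c(1, 1, 0, 0)), 0.0)
  ev <- evaluateModel(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unname(ev), c(1, 1))
  expect_warning(aucScore(1:3, c(1, 1, 1)), "one class")
})

test_that("monotone score transforms leave AUC unchanged", {
  set.seed(33)
  s <- runif(100); y <- rbinom(100, 1, 0.5)
  a <- aucScore(s, y)
  expect_equal(aucScore(plogis(5 * s - 2), y), a, tolerance = 1e-12)
  expect_equal(aucScore(s^3, y), a, tolerance = 1e-12)
})

test_that("training on a separable toy gives AUC 1 and the grid contract", {
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:40),
    well_key = rep(c("P1_W1", "P2_W1", "P1_W2", "P2_W2"), each = 10),
    F001 = c(rnorm(10, -3), rnorm(10, 3), rnorm(10, -3), rnorm(10, 3)),
    F002 = rnorm(40))
  layout <- data.frame(plate = c(1, 2, 1, 2), well = "W",
                       well_key = c("P1_W1", "P2_W1", "P1_W2", "P2_W2"),
                       role = c("labeled-WT", "labeled-mutant",
                                "labeled-WT", "labeled-mutant"),
                       expected_mut_fraction = c(0, 1, 0, 1))
  split <- list(mode = "well", train_wells = c("P1_W1", "P2_W1"),
                test_wells = c("P1_W2", "P2_W2"))
  specs <- list(m1 = list(algorithm = "logistic", lambda = 0.01,
                          features = c("F001", "F002"), method = "manual",
                          model_id = "m1"))
  mset <- suppressWarnings(
    trainModelGrid(cells, layout, specs = specs, split = split, seed = 1L))
  expect_equal(modelResults(mset)$auc_test, 1.0)
  expect_equal(dim(modelScores(mset)), c(40L, 1L))
  expect_true(all(modelScores(mset) >= 0 & modelScores(mset) <= 1))
})

test_that("shuffled-label training is null-calibrated", {
  set.seed(44)
  aucs <- numeric(30)
  n <- 120
  for (i in seq_len(30)) {
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("F00", 1:4)))
    y <- sample(rep(0:1, each = n / 2))  # labels carry no signal
    tr <- seq_len(n * 0.8); te <- setdiff(seq_len(n), tr)
    pr <- raftscreen:::fitClassifier(X[tr, ], y[tr], "logistic", 0.1)
    aucs[i] <- aucScore(pr(X[te, ]), y[te])
  }
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("meta-feature deviation follows the exclusion-band definition", {
  cells <- data.frame(cell_id = as.character(1:40),
                      well_key = rep(c("P1_W4", "P2_W4"), each = 20))
  layout <- data.frame(plate = 1:2, well = "W4",
                       well_key = c("P1_W4", "P2_W4"),
                       role = "unlabeled-mix",
                       expected_mut_fraction = c(0.5, 0.1))
  # 50:50 well scoring half 0.05, half 0.95 -> deviation 0 there;
  # 90:10-WT well scoring all 0.95 -> deviation 0.9
  scores <- c(rep(c(0.05, 0.95), 10), rep(0.95, 20))
  mf <- metaFeatureCheck(scores, cells, layout)
  expect_equal(mf$per_well$deviation, c(0, 0.9))
  expect_equal(mf$meta_deviation, 0.45)
  # all scores excluded -> worst-case deviation 1
  mf2 <- metaFeatureCheck(rep(0.5, 40), cells, layout)
  expect_equal(mf2$per_well$deviation, c(1, 1))
  # no unlabeled wells -> NA with warning
  expect_warning(
    mf3 <- metaFeatureCheck(scores, cells,
                            transform(layout, role = "labeled-WT")),
    "no unlabeled")
  expect_true(is.na(mf3$meta_deviation))
})

test_that("pick-model selection applies the lexicographic tolerance rule", {
  mk <- function(df) new("ScreenModelSet", results = df, models = list(),
                         scores = matrix(0, 1, 1), features = list())
  df <- data.frame(model_id = c("a", "b"), algorithm = "logistic",
                   lambda = 0.1, method = "x", n_features = c(5L, 5L),
                   auc_train = c(0.99, 0.90), auc_test = c(0.90, 0.89),
                   mcc_test = 0.5, meta_deviation = c(0.1, 0.1),
                   failed = FALSE)
  expect_equal(selectPickModel(mk(df)), "b")  # smaller overfit gap wins
  df2 <- df; df2$auc_train <- c(0.95, 0.95); df2$auc_test <- c(0.9, 0.9)
  expect_equal(selectPickModel(mk(df2)), "a")  # tie -> lowest id
  expect_equal(selectPickModel(mk(df[1, ])), "a")
  df3 <- df; df3$failed <- TRUE
  expect_error(selectPickModel(mk(df3)), "all models failed")
})

test_that("ensembles average member scores and behave sensibly", {
  sc <- matrix(c(0.2, 0.6, 0.8, 0.4), 2,
               dimnames = list(c("c1", "c2"), c("m1", "m2")))
  mset <- new("ScreenModelSet", results = data.frame(), models = list(),
              scores = sc, features = list())
  expect_equal(unname(ensemblePredict(mset, c("m1", "m2"))), c(0.5, 0.5))
  sc2 <- cbind(m1 = c(0.3, 0.7), m2 = c(0.3, 0.7))
  rownames(sc2) <- c("c1", "c2")
  mset2 <- new("ScreenModelSet", results = data.frame(), models = list(),
               scores = sc2, features = list())
  expect_equal(unname(ensemblePredict(mset2, c("m1", "m2"))), c(0.3, 0.7))
  expect_error(ensemblePredict(mset, "m1"))
})

test_that("selected-model unlabeled AUC tracks the generator effect size", {
  auc_at <- function(es) {
    cfg <- simConfig(cells_per_well = 200L, effect_size = es, seed = 61L)
    sim <- simulatePlate(cfg)
    qc <- runQc(sim$cells)
    labels <- labelFromLayout(qc$cells, sim$layout)
    split <- splitWells(sim$layout, "well", seed = 61L)
    tr <- qc$cells$well_key %in% split$train_wells & !is.na(labels)
    X <- as.matrix(qc$cells[, featureColumns(qc$cells)])
    specs <- makeModelGrid(X[tr, ], labels[tr], n_random = 2L,
                           lambdas = 0.1, seed = 61L)
    mset <- trainModelGrid(qc$cells, sim$layout, specs = specs,
                           split = split, seed = 61L)
    sc <- modelScores(mset)[, selectPickModel(mset)]
    un <- qc$cells$well_key %in%
      sim$layout$well_key[sim$layout$role == "unlabeled-mix"]
    truthc <- sim$truth$class[match(qc$cells$cell_id, sim$truth$cell_id)]
    aucScore(sc[un], truthc[un] == "pathogenic")
  }
  aucs <- vapply(c(0.5, 1, 2), auc_at, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})
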