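# Evaluation battery: joins, ROC with noise, threshold metrics, confusion
# bookkeeping, feature ranking, gRNA statistics and reproducibility.

joinFixture <- function() {
  picks <- data.frame(raft_key = sprintf("r%02d", 1:10),
                      raft_id = sprintf("r%02d", 1:10),
                      score = c(0.9, 0.8, 0.2, 0.1, 0.95, 0.5, 0.85, 0.15,
                                0.7, 0.3),
                      predicted_class = ifelse(c(0.9, 0.8, 0.2, 0.1, 0.95,
                                                 0.5, 0.85, 0.15, 0.7, 0.3)
                                               > 0.5, "mutant", "WT"),
                      band = "0.7", n_cells = 1L, is_control = FALSE,
                      dest_plate = 1L, dest_well = sprintf("A%d", 1:10))
  calls <- data.frame(well = sprintf("1_A%d", 1:10),
                      raft_key = sprintf("r%02d", 1:10),
                      call = c("L76P", "R94Q", "WT", "WT", "L76P",
                               "R280H", "ambiguous", "no-data", "P251A",
                               "WT"))
  list(picks = picks, calls = calls)
}

test_that("prediction-genotype joins drop ambiguous, no-data and mid-band", {
  fx <- joinFixture()
  j <- joinPredictionsGenotypes(fx$picks, fx$calls, classMap())
  # r06 excluded (score 0.5 in band), r07 ambiguous, r08 no-data
  expect_equal(nrow(j), 7L)
  expect_false(any(j$raft_key %in% c("r06", "r07", "r08")))
  expect_true(all(j$genotype_class %in% c("WT", "pathogenic")))
  # unmapped genotype -> named error
  calls2 <- fx$calls; calls2$call[1] <- "X999Y"
  expect_error(joinPredictionsGenotypes(fx$picks, calls2, classMap()),
               "X999Y")
  calls3 <- rbind(fx$calls, fx$calls[1, ])
  expect_error(joinPredictionsGenotypes(fx$picks, calls3, classMap()),
               "collision")
})

test_that("ROC, its oracle, label inversion and shuffle null agree", {
  fx <- joinFixture()
  j <- joinPredictionsGenotypes(fx$picks, fx$calls, classMap())
  r <- rocWithNoise(j, n_shuffles = 200, seed = 3)
  expect_equal(r$auc, aucByConcordance(j$score, j$truth_mutant),
               tolerance = 1e-12)
  expect_gt(mean(r$noise_auc), 0.45)
  expect_lt(mean(r$noise_auc), 0.55)
  # perfectly separated scores -> AUC 1
  j2 <- data.frame(score = c(0.9, 0.8, 0.1, 0.2),
                   truth_mutant = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rocWithNoise(j2, n_shuffles = 5, seed = 1)$auc, 1)
  # label inversion mirrors the AUC
  j3 <- j; j3$truth_mutant <- !j3$truth_mutant
  expect_equal(rocWithNoise(j3, n_shuffles = 5, seed = 1)$auc, 1 - r$auc,
               tolerance = 1e-12)
  expect_error(rocWithNoise(transform(j, truth_mutant = TRUE)),
               "single class")
})

test_that("threshold metrics restrict to confident scores per band", {
  j <- data.frame(score = c(0.95, 0.85, 0.15, 0.75),
                  truth_mutant = c(TRUE, FALSE, FALSE, TRUE))
  tm <- thresholdMetrics(j)
  expect_equal(tm$n, c(4L, 3L, 1L))
  expect_equal(tm$accuracy[tm$band == 0.9], 1.0)
  expect_equal(tm$accuracy[tm$band == 0.7], 0.75)
  jall <- data.frame(score = rep(0.95, 5), truth_mutant = rep(TRUE, 5))
  expect_equal(thresholdMetrics(jall)$accuracy, rep(1, 3))
})

test_that("confusion counts conserve marginals and recompute accuracy", {
  fx <- joinFixture()
  j <- joinPredictionsGenotypes(fx$picks, fx$calls, classMap())
  cs <- confusionSummary(j)
  expect_equal(sum(cs$n), nrow(j))
  acc_direct <- mean((j$score > 0.5) == j$truth_mutant)
  # accuracy from confusion counts: predicted mutant x pathogenic plus
  # predicted WT x WT-class
  cs$truth_path <- classMap()[cs$genotype] == "pathogenic"
  acc_conf <- sum(cs$n[(cs$predicted_class == "mutant") == cs$truth_path]) /
    sum(cs$n)
  expect_equal(acc_conf, acc_direct)
  # grouping keeps totals
  cs2 <- confusionSummary(j, group = rep(c("g1", "g2"), length.out = nrow(j)))
  expect_equal(sum(cs2$n), nrow(j))
})

test_that("Kruskal-Wallis ranking matches the hand-computed statistic", {
  cells <- data.frame(F001 = c(1, 2, 3, 4, 5, 6))
  cls <- rep(c("a", "b"), each = 3)
  kw <- kwFeatureRanking(cells, cls, features = "F001")
  expect_equal(kw$statistic, 3.857, tolerance = 1e-3)
  # the generator's informative feature ranks first at a strong effect
  sim <- simulatePlate(tinyConfig(cells_per_well = 120L, effect_size = 2,
                                  seed = 15L))
  lab <- sim$cells$well_key %in%
    sim$layout$well_key[sim$layout$role != "unlabeled-mix"]
  kw2 <- kwFeatureRanking(sim$cells[lab, ], sim$truth$class[lab],
                          features = c("F001", paste0("F", 100:110)))
  expect_equal(kw2$feature[1], "F001")
  expect_true(all(diff(kw2$statistic) <= 0))
})

test_that("feature-subset analyses emit the promised model counts", {
  sim <- simulatePlate(tinyConfig(cells_per_well = 60L, effect_size = 1.5,
                                  seed = 25L))
  qc <- runQc(sim$cells)
  base <- sprintf("F%03d", 1:6)
  single <- featureSubsetAnalysis(qc$cells, sim$layout, base, "single")
  expect_equal(nrow(single), 6L)
  loo <- featureSubsetAnalysis(qc$cells, sim$layout, base, "loo")
  expect_equal(nrow(loo), 6L)
  expect_true(all(loo$size == 5L))
  sub <- featureSubsetAnalysis(qc$cells, sim$layout, base, "subsets",
                               max_size = 3, max_per_size = 10)
  expect_true(all(sub$size %in% 1:3))
  # more informative features help, on average (qualitative trend)
  m <- tapply(sub$auc, sub$size, mean, na.rm = TRUE)
  expect_gt(m[["3"]], m[["1"]] - 0.02)
})

test_that("BH decisions match enumeration and the step-up hand case", {
  expect_equal(bhDecisions(c(0.01, 0.02, 0.03, 0.5), 0.2),
               c(TRUE, TRUE, TRUE, FALSE))
  set.seed(90)
  for (i in 1:100) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(c(1, 2, 3), 1)
    q <- sample(c(0.05, 0.1, 0.2), 1)
    expect_identical(bhDecisions(p, q), bhByEnumeration(p, q))
  }
})

test_that("gRNA significance tests against the control median", {
  set.seed(95)
  scores <- c(rnorm(60, 0.5, 0.05),          # controls
              rnorm(30, 0.9, 0.05),          # shifted gRNA g1
              rnorm(30, 0.5, 0.05),          # null gRNA g2
              rnorm(2, 0.9, 0.05))           # too-small gRNA g3
  grna <- c(rep(NA, 60), rep("g1", 30), rep("g2", 30), rep("g3", 2))
  ctl <- c(rep(TRUE, 60), rep(FALSE, 62))
  gs <- grnaSignificance(scores, grna, control = ctl)
  expect_true(gs$significant[gs$grna == "g1"])
  expect_false(gs$significant[gs$grna == "g2"])
  expect_equal(attr(gs, "excluded"), "g3")
  # scores exactly at the null value -> t = 0, nothing rejected
  gs0 <- grnaSignificance(rep(0.5, 9), rep(c("a", "b", "c"), 3),
                          null_value = 0.5)
  expect_true(all(!gs0$significant))
})

test_that("reproducibility counts direction-consistent measurable gRNAs", {
  mkcells <- function(g, r, mu) data.frame(
    s = rnorm(5, mu, 0.01), g = g, r = r)
  df <- rbind(mkcells("hi", "rep1", 0.9), mkcells("hi", "rep2", 0.9),
              mkcells("lo", "rep1", 0.1), mkcells("lo", "rep2", 0.1),
              mkcells("flip", "rep1", 0.9), mkcells("flip", "rep2", 0.1),
              mkcells("solo", "rep1", 0.5),
              mkcells("mid1", "rep1", 0.5), mkcells("mid1", "rep2", 0.52),
              mkcells("mid2", "rep1", 0.55), mkcells("mid2", "rep2", 0.5))
  rp <- reproducibility(df$s, df$g, df$r)
  per <- rp$per_grna
  expect_true(per$reproducible[per$grna == "hi"])
  expect_true(per$reproducible[per$grna == "lo"])
  expect_false(per$reproducible[per$grna == "flip"])
  expect_false(per$measurable[per$grna == "solo"])
  expect_equal(rp$fraction,
               mean(per$reproducible[per$measurable]))
})

test_that("frameshift-anomaly association is detected when constructed", {
  set.seed(99)
  n <- 300
  fs <- runif(n)
  anom <- fs + rnorm(n, 0, 0.02)  # tight association
  fa <- frameshiftVsAnomaly(anom, fs)
  expect_true(all(fa$p < 0.01))
  expect_equal(fa$n_high + fa$n_low, rep(n, 3))
  # null association: p roughly uniform on average
  ps <- vapply(1:40, function(i) {
    frameshiftVsAnomaly(rnorm(120), runif(120), thresholds = 0.5)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.35); expect_lt(mean(ps), 0.65)
  # empty group -> not computable
  fa0 <- frameshiftVsAnomaly(rnorm(10), rep(0.2, 10), thresholds = 0.9)
  expect_true(is.na(fa0$p))
})
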