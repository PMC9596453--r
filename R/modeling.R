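# Supervised ensemble: well-wise splits, minority oversampling, feature
# selection, a grid of linear classifiers scored in [0,1] (0 = confident
# WT, 1 = confident mutant), the mixture-proportion meta-feature check and
# deterministic pick-model selection.

#' Label cells from the plate layout
#'
#' Cells in labeled wild-type wells get 0, labeled mutant wells 1, unlabeled
#' wells NA. Labels come from well roles only (never from ground truth),
#' exactly as at screen time.
#'
#' @param cells cell table with `well_key`.
#' @param layout plate layout (see [makePlateLayout()]).
#' @return integer vector (0 / 1 / NA) aligned with `cells`.
#' @export
labelFromLayout <- function(cells, layout) {
  role <- layout$role[match(cells$well_key, layout$well_key)]
  ifelse(role == "labeled-WT", 0L, ifelse(role == "labeled-mutant", 1L, NA))
}

#' Split labeled wells into train and test sets
#'
#' Well-wise mode assigns, per class, two labeled wells to training -
#' preferring wells on distinct plates - and the remainder to testing; a
#' well is never split. Randomized 80-20 mode shuffles cells by seed.
#'
#' @param layout plate layout.
#' @param mode "well" (default) or "random".
#' @param seed RNG seed.
#' @param cells cell table (required for mode "random").
#' @param train_fraction fraction for mode "random" (default 0.8).
#' @return list with `mode`, and either `train_wells` / `test_wells`
#'   (well_key vectors) or `train_ids` / `test_ids` (cell_id vectors).
#' @export
splitWells <- function(layout, mode = c("well", "random"), seed = 1L,
                       cells = NULL, train_fraction = 0.8) {
  mode <- match.arg(mode)
  if (mode == "random") {
    stopifnot(!is.null(cells))
    withSeed(seed, {
      n <- nrow(cells)
      tr <- sample.int(n, floor(train_fraction * n))
      list(mode = mode, train_ids = cells$cell_id[tr],
           test_ids = cells$cell_id[-tr])
    })
  } else {
    withSeed(seed, {
      train <- character(0); test <- character(0)
      for (r in c("labeled-WT", "labeled-mutant")) {
        w <- layout[layout$role == r, , drop = FALSE]
        if (nrow(w) < 2L)
          stop("well-wise split needs >= 2 labeled wells per class")
        w <- w[sample.int(nrow(w)), , drop = FALSE]
        # prefer two training wells on distinct plates
        first <- 1L
        second <- which(w$plate != w$plate[first])[1]
        if (is.na(second)) second <- 2L
        tr <- w$well_key[c(first, second)]
        train <- c(train, tr)
        test <- c(test, setdiff(w$well_key, tr))
      }
      list(mode = mode, train_wells = train, test_wells = test)
    })
  }
}

#' Synthetic minority oversampling
#'
#' Balances a two-class training set by convex interpolation: each synthetic
#' point lies on the segment between a minority point and one of its
#' `k_neighbors` nearest minority neighbors, at a uniform interpolation
#' factor. Applied only when the classes are imbalanced. A minority class of
#' size 1 is duplicated unchanged (degenerate fallback, logged as a
#' message).
#'
#' @param X numeric matrix of features (rows = cells).
#' @param y 0/1 labels.
#' @param k_neighbors neighbor count (default 5).
#' @param seed RNG seed.
#' @return list(X, y, synthetic = logical marking generated rows,
#'   parents = 2-column matrix of parent row indices for synthetic rows).
#' @export
oversampleMinority <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  stopifnot(length(unique(y)) == 2L)
  tab <- table(y)
  if (tab[1] == tab[2])
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X)),
                parents = matrix(integer(0), 0, 2)))
  min_class <- as.integer(names(tab)[which.min(tab)])
  mi <- which(y == min_class)
  n_new <- abs(diff(as.integer(tab)))
  withSeed(seed, {
    if (length(mi) == 1L) {
      message("minority class of size 1: duplicating without interpolation")
      newX <- X[rep(mi, n_new), , drop = FALSE]
      parents <- cbind(rep(mi, n_new), rep(mi, n_new))
    } else {
      k <- min(k_neighbors, length(mi) - 1L)
      D <- as.matrix(dist(X[mi, , drop = FALSE]))
      diag(D) <- Inf
      nn <- apply(D, 1, function(d) order(d)[seq_len(k)])
      nn <- matrix(nn, nrow = k)
      base <- sample(seq_along(mi), n_new, replace = TRUE)
      pick <- vapply(base, function(b) nn[sample.int(k, 1L), b], integer(1))
      u <- runif(n_new)
      newX <- X[mi[base], , drop = FALSE] +
        u * (X[mi[pick], , drop = FALSE] - X[mi[base], , drop = FALSE])
      parents <- cbind(mi[base], mi[pick])
    }
    list(X = rbind(X, newX), y = c(y, rep(min_class, n_new)),
         synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_new)),
         parents = parents)
  })
}

#' Select a feature subset
#'
#' Methods: `variance` drops features below a minimum variance;
#' `correlation` greedily drops one member of each pair with |r| above the
#' maximum (keeping the higher-variance member); `random` draws a uniform
#' subset of the requested size; `anova_f` keeps the top-k features by
#' one-way F statistic between classes; `l1svm` keeps features with nonzero
#' coefficients in an L1-penalized sparse linear fit at the given penalty.
#'
#' @param X feature matrix (columns named).
#' @param y 0/1 labels (needed for anova_f and l1svm).
#' @param method one of variance, correlation, random, anova_f, l1svm.
#' @param min_variance,max_cor,size,k,lambda method parameters.
#' @param seed RNG seed (random method).
#' @return character vector of selected feature names.
#' @export
selectFeatures <- function(X, y = NULL,
                           method = c("variance", "correlation", "random",
                                      "anova_f", "l1svm"),
                           min_variance = 1e-8, max_cor = 0.95, size = 8L,
                           k = 8L, lambda = 0.1, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  feats <- colnames(X)
  switch(method,
    variance = {
      v <- apply(X, 2, var)
      feats[v >= min_variance]
    },
    correlation = {
      v <- apply(X, 2, var)
      ord <- order(v, decreasing = TRUE)  # visit high-variance first
      keep <- character(0)
      C <- abs(cor(X))
      for (f in feats[ord])
        if (!length(keep) || all(C[f, keep] <= max_cor)) keep <- c(keep, f)
      feats[feats %in% keep]
    },
    random = {
      if (size > length(feats))
        stop("requested size exceeds available features")
      withSeed(seed, sort(sample(feats, size)))
    },
    anova_f = {
      stopifnot(!is.null(y))
      if (k > length(feats))
        stop("requested size exceeds available features")
      fstat <- apply(X, 2, function(col) {
        m <- tapply(col, y, mean); n <- tapply(col, y, length)
        ssb <- sum(n * (m - mean(col))^2)
        ssw <- sum((col - m[as.character(y)])^2)
        (ssb / 1) / (ssw / (length(col) - 2))
      })
      feats[order(fstat, decreasing = TRUE)[seq_len(k)]]
    },
    l1svm = {
      stopifnot(!is.null(y))
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                            lambda = lambda)
      b <- as.matrix(coef(fit))[-1, 1]
      out <- feats[b != 0]
      if (!length(out)) feats[which.max(abs(as.matrix(coef(
        glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                       lambda = lambda / 10)))[-1, 1]))]
      else out
    })
}

# Fit one linear classifier; returns list(predict = function(X) -> [0,1]).
# Margin classifiers are squashed through a logistic map so every model
# honors the 0 = WT, 1 = mutant score contract.
fitClassifier <- function(X, y, algorithm, lambda) {
  pad <- ncol(X) < 2L
  prep <- function(M) if (pad) cbind(M, .pad = 0) else M
  X <- prep(as.matrix(X))
  if (algorithm == "logistic") {
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = lambda)
    function(M) as.numeric(predict(fit, prep(as.matrix(M)),
                                   type = "response"))
  } else if (algorithm == "ridge") {
    fit <- glmnet::glmnet(X, as.numeric(y), family = "gaussian", alpha = 0,
                          lambda = lambda)
    function(M) plogis(4 * (as.numeric(predict(fit, prep(as.matrix(M)))) - 0.5))
  } else if (algorithm == "svm_linear") {
    fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                      cost = 1 / lambda, scale = FALSE)
    dv_tr <- attr(predict(fit, X, decision.values = TRUE),
                  "decision.values")[, 1]
    flip <- if (aucScore(dv_tr, y) < 0.5) -1 else 1
    function(M)
      plogis(flip * attr(predict(fit, prep(as.matrix(M)),
                                 decision.values = TRUE),
                         "decision.values")[, 1])
  } else stop("unknown algorithm: ", algorithm)
}

#' Build the default model grid
#'
#' Feature subsets from the five selection methods (random subsets sized
#' 2-20, top-k ANOVA F, sparse L1 fits, variance- and correlation-filtered
#' random subsets) crossed with three algorithms (logistic regression, ridge
#' classifier, linear SVM) and three regularization strengths - a few
#' hundred models, mirroring the scale of the screening runs.
#'
#' @param X training feature matrix.
#' @param y 0/1 training labels.
#' @param n_random number of random subsets (default 20).
#' @param lambdas regularization strengths (default 0.01, 0.1, 1).
#' @param seed RNG seed fixing subset draws and iteration order.
#' @return list of model specs (algorithm, lambda, features, method,
#'   model_id).
#' @export
makeModelGrid <- function(X, y, n_random = 20L, lambdas = c(0.01, 0.1, 1),
                          seed = 1L) {
  feats <- colnames(X)
  subsets <- list()
  withSeed(seed, {
    for (i in seq_len(n_random)) {
      sz <- min(sample(2:20, 1), length(feats))
      subsets[[paste0("random", i)]] <- sort(sample(feats, sz))
    }
    for (k in c(2L, 4L, 8L, 16L)) if (k <= length(feats))
      subsets[[paste0("anova_f", k)]] <-
        selectFeatures(X, y, "anova_f", k = k)
    for (l in c(0.05, 0.1, 0.2))
      subsets[[paste0("l1svm", l)]] <-
        selectFeatures(X, y, "l1svm", lambda = l)
    vpool <- selectFeatures(X, y, "variance", min_variance = 0.1)
    for (i in 1:3) if (length(vpool) >= 2L)
      subsets[[paste0("variance", i)]] <-
        sort(sample(vpool, min(10L, length(vpool))))
    cpool <- selectFeatures(X, y, "correlation", max_cor = 0.9)
    for (i in 1:2) if (length(cpool) >= 2L)
      subsets[[paste0("correlation", i)]] <-
        sort(sample(cpool, min(10L, length(cpool))))
  })
  specs <- list()
  for (alg in c("logistic", "ridge", "svm_linear"))
    for (lam in lambdas)
      for (s in names(subsets)) {
        id <- sprintf("%s_lam%g_%s", alg, lam, s)
        specs[[id]] <- list(algorithm = alg, lambda = lam,
                            features = subsets[[s]],
                            method = sub("[0-9.]+$", "", s), model_id = id)
      }
  specs
}

#' Train a grid of classifiers and score every cell
#'
#' Each spec is fitted on the (optionally oversampled) training cells and
#' produces a score in \[0,1\] for every cell in the table - train, test and
#' unlabeled alike. Singular or failed fits are flagged and excluded from
#' selection, not fatal. Metrics: train/test AUC, test MCC and the
#' mixture-proportion meta deviation.
#'
#' @param cells QC'd, normalized cell table.
#' @param layout plate layout.
#' @param specs model grid (see [makeModelGrid()]); NULL builds the default.
#' @param split output of [splitWells()] (NULL: well-wise split with
#'   `seed`).
#' @param oversample balance training classes by [oversampleMinority()].
#' @param seed RNG seed.
#' @return a [ScreenModelSet-class].
#' @export
trainModelGrid <- function(cells, layout, specs = NULL, split = NULL,
                           oversample = TRUE, seed = 1L) {
  labels <- labelFromLayout(cells, layout)
  if (is.null(split)) split <- splitWells(layout, "well", seed = seed)
  if (split$mode == "well") {
    tr <- cells$well_key %in% split$train_wells & !is.na(labels)
    te <- cells$well_key %in% split$test_wells & !is.na(labels)
  } else {
    tr <- cells$cell_id %in% split$train_ids & !is.na(labels)
    te <- cells$cell_id %in% split$test_ids & !is.na(labels)
  }
  feats <- featureColumns(cells)
  Xall <- as.matrix(cells[, feats, drop = FALSE])
  Xtr <- Xall[tr, , drop = FALSE]; ytr <- labels[tr]
  if (oversample && length(unique(ytr)) == 2L) {
    os <- oversampleMinority(Xtr, ytr, seed = childSeed(seed, 2))
    Xtr <- os$X; ytr <- os$y
  }
  if (is.null(specs))
    specs <- makeModelGrid(Xtr, ytr, seed = childSeed(seed, 3))
  n <- nrow(cells)
  scores <- matrix(NA_real_, n, length(specs),
                   dimnames = list(cells$cell_id, names(specs)))
  res <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    fs <- intersect(sp$features, feats)
    row <- data.frame(model_id = sp$model_id, algorithm = sp$algorithm,
                      lambda = sp$lambda, method = sp$method,
                      n_features = length(fs), auc_train = NA_real_,
                      auc_test = NA_real_, mcc_test = NA_real_,
                      meta_deviation = NA_real_, failed = TRUE,
                      stringsAsFactors = FALSE)
    if (length(fs) >= 1L) {
      fitted <- tryCatch({
        pr <- fitClassifier(Xtr[, fs, drop = FALSE], ytr, sp$algorithm,
                            sp$lambda)
        s <- pr(Xall[, fs, drop = FALSE])
        if (any(!is.finite(s))) stop("non-finite scores")
        s
      }, error = function(e) NULL)
      if (!is.null(fitted)) {
        scores[, i] <- fitted
        row$auc_train <- aucScore(fitted[tr], labels[tr])
        row$auc_test <- suppressWarnings(aucScore(fitted[te], labels[te]))
        row$mcc_test <- mccScore(fitted[te], labels[te])
        row$meta_deviation <-
          metaFeatureCheck(fitted, cells, layout)$meta_deviation
        row$failed <- FALSE
      }
    }
    res[[i]] <- row
  }
  new("ScreenModelSet", results = do.call(rbind, res),
      models = list(), scores = scores,
      features = lapply(specs, `[[`, "features"))
}

#' Mixture-proportion meta-feature check
#'
#' For every unlabeled well, the predicted positive fraction is the fraction
#' of cells scoring above 0.5 after excluding scores in \[0.4, 0.6\] (the
#' pick-time exclusion band). The meta deviation is the mean absolute
#' difference from the well's expected mutant fraction. A well whose scores
#' are all excluded contributes the worst-case deviation 1 (logged in the
#' per-well table).
#'
#' @param scores per-cell scores aligned with `cells`.
#' @param cells cell table.
#' @param layout plate layout with expected fractions.
#' @return list(meta_deviation, per_well data.frame, curves = ranked scores
#'   per unlabeled well).
#' @export
metaFeatureCheck <- function(scores, cells, layout) {
  un <- layout[layout$role == "unlabeled-mix", , drop = FALSE]
  if (nrow(un) == 0L) {
    warning("no unlabeled wells: meta deviation undefined")
    return(list(meta_deviation = NA_real_, per_well = NULL, curves = NULL))
  }
  rows <- lapply(seq_len(nrow(un)), function(i) {
    s <- scores[cells$well_key == un$well_key[i]]
    keep <- s <= 0.4 | s >= 0.6
    frac <- if (any(keep)) mean(s[keep] > 0.5) else NA_real_
    dev <- if (is.na(frac)) 1 else abs(frac - un$expected_mut_fraction[i])
    data.frame(well_key = un$well_key[i],
               expected = un$expected_mut_fraction[i],
               predicted = frac, deviation = dev, n_used = sum(keep))
  })
  per_well <- do.call(rbind, rows)
  curves <- lapply(seq_len(nrow(un)), function(i)
    sort(scores[cells$well_key == un$well_key[i]]))
  names(curves) <- un$well_key
  list(meta_deviation = mean(per_well$deviation), per_well = per_well,
       curves = curves)
}

#' Evaluate one model's scores on a labeled test set
#'
#' AUC by the rank method (ties at half credit) and MCC at threshold 0.5.
#' A single-class test set yields NA AUC with a warning.
#'
#' @param scores numeric scores in \[0,1\].
#' @param labels 0/1 truth.
#' @return named numeric: auc_test, mcc_test.
#' @export
evaluateModel <- function(scores, labels) {
  c(auc_test = aucScore(scores, labels),
    mcc_test = mccScore(scores, labels))
}

#' Select the pick model
#'
#' Deterministic lexicographic rule: among non-failed models within
#' `delta_auc` of the best test AUC, prefer the smallest train-test AUC gap
#' (least overfitting), then the smallest meta deviation, then the fewest
#' features, then the lexicographically smallest model id.
#'
#' @param mset a [ScreenModelSet-class].
#' @param delta_auc AUC tolerance band (default 0.02).
#' @return the chosen model_id (character).
#' @export
selectPickModel <- function(mset, delta_auc = 0.02) {
  r <- mset@results[!mset@results$failed & !is.na(mset@results$auc_test), ,
                    drop = FALSE]
  if (nrow(r) == 0L) stop("all models failed")
  best <- max(r$auc_test)
  cand <- r[r$auc_test >= best - delta_auc, , drop = FALSE]
  gap <- cand$auc_train - cand$auc_test
  md <- ifelse(is.na(cand$meta_deviation), Inf, cand$meta_deviation)
  cand$model_id[order(gap, md, cand$n_features, cand$model_id)][1]
}

#' Ensemble prediction: per-cell mean of member scores
#'
#' @param mset a [ScreenModelSet-class].
#' @param model_ids at least two member model ids.
#' @return numeric vector of ensemble scores, named by cell_id.
#' @export
ensemblePredict <- function(mset, model_ids) {
  stopifnot(length(model_ids) >= 2L)
  rowMeans(mset@scores[, model_ids, drop = FALSE])
}
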