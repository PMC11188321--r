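test_that("the internal rank AUC agrees with an independent ROC implementation", {
  set.seed(30)
  for (rep in 1:5) {
    sc <- round(rnorm(80), 1)  # ties included
    y <- rbinom(80, 1, plogis(sc))
    if (length(unique(y)) < 2) next
    expect_equal(petrad:::.aucRank(sc, y),
                 as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                                direction = "<",
                                                levels = c(0, 1)))),
                 tolerance = 1e-12)
  }
})

test_that("a feature duplicating the outcome dominates the LASSO weights", {
  set.seed(31)
  X <- matrix(rnorm(150 * 5), 150)
  colnames(X) <- paste0("f", 1:5)
  y <- rbinom(150, 1, 0.5)
  X[, 3] <- y  # perfect predictor
  Xs <- scale(X)
  w <- rankFeatures("LASSO", Xs, y, seed = 1)
  expect_length(w, 5)
  expect_equal(names(which.max(w)), "f3")
  expect_gt(w["f3"], max(w[-3]))
  expect_true(all(w >= 0))
})

test_that("every method returns one non-negative weight per feature", {
  sim <- simFeatures(120, 4, beta = c(1.5, 0), seed = 32)
  for (m in crossComboMethods()) {
    w <- rankFeatures(m, scale(sim$X), sim$y, seed = 1, params = fastParams)
    expect_length(w, 4)
    expect_true(all(w >= 0), info = m)
    expect_identical(names(w), colnames(sim$X))
  }
  expect_error(rankFeatures("LR", sim$X, rep(1, 120)), "both classes")
  expect_error(rankFeatures("PCA", sim$X, sim$y), "unknown method")
})

test_that("pure-noise features show no systematically dominant linear weight", {
  hits <- 0
  for (s in 1:8) {
    sim <- simFeatures(500, 10, beta = NULL, seed = 100 + s)
    w <- rankFeatures("LR", scale(sim$X), sim$y, seed = s)
    if (max(w) > 3 * median(w)) hits <- hits + 1
  }
  expect_lte(hits, 4)  # not in more than half the seeds
})

test_that("recursive elimination returns sane paths and trivial cases", {
  sim <- simFeatures(100, 5, beta = c(2, 2), seed = 33)
  sel <- selectFeatures("LR", sim$X, sim$y, k = 3, seed = 1)
  expect_equal(nrow(sel$path), 5)  # full trace, one drop per step
  expect_true(all(sel$features %in% colnames(sim$X)))
  # single feature input returns that feature
  s1 <- selectFeatures("LR", sim$X[, 1, drop = FALSE], sim$y, k = 3, seed = 1)
  expect_equal(s1$features, "f1")
})

test_that("planted informative features are recovered across seeds", {
  recovered <- 0
  nseeds <- 10
  for (s in seq_len(nseeds)) {
    sim <- simFeatures(600, 20, beta = c(1.5, 1.5), seed = 200 + s)
    sel <- selectFeatures("LR", sim$X, sim$y, k = 3, seed = s)
    if (all(c("f1", "f2") %in% sel$features)) recovered <- recovered + 1
  }
  expect_gte(recovered, 9)  # >= 90% of seeds
})

test_that("stratified folds for n = 123 and k = 5 have the printed sizes", {
  y <- c(rep(1, 40), rep(0, 83))
  f <- petrad:::.stratifiedFolds(y, 5, seed = 3)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(25L, 25L, 25L, 24L, 24L))
  # stratification: each fold carries both classes
  expect_true(all(tapply(y, f, function(v) length(unique(v))) == 2))
})

test_that("evaluatePair is unbiased under the null and perfect when separable", {
  sim <- simFeatures(500, 4, beta = NULL, seed = 34)
  ev <- evaluatePair("LR", "LR", sim$X, sim$y, k = 5, seed = 1)
  expect_gt(ev$meanAUC, 0.4)
  expect_lt(ev$meanAUC, 0.6)
  # separable data
  sim2 <- simFeatures(100, 3, beta = NULL, seed = 35)
  X2 <- sim2$X; y2 <- sim2$y
  X2[, 1] <- ifelse(y2 == 1, X2[, 1] + 10, X2[, 1] - 10)
  ev2 <- evaluatePair("LR", "LR", X2, y2, k = 5, seed = 1)
  expect_equal(ev2$meanAUC, 1.0)
})

test_that("label shuffling breaks cross-validated AUC to chance (no leakage)", {
  sim <- simFeatures(300, 8, beta = c(2, 1.5), seed = 36)
  yshuf <- withr::with_seed(1, sample(sim$y))
  aucs <- vapply(list(c("LR", "LR"), c("LASSO", "RF"), c("RF", "LASSO")),
                 function(pr) evaluatePair(pr[1], pr[2], sim$X, yshuf,
                                           k = 5, seed = 2,
                                           params = fastParams)$meanAUC,
                 numeric(1))
  expect_true(all(aucs > 0.35 & aucs < 0.65))
})

test_that("the 49-cell grid elects the matrix maximum deterministically", {
  sim <- simFeatures(60, 3, beta = c(1.5), seed = 37)
  g1 <- runGrid(sim$X, sim$y, k = 3, seed = 5, innerK = 2,
                params = fastParams)
  expect_equal(dim(aucMatrix(g1)), c(7, 7))
  expect_equal(sum(!is.na(aucMatrix(g1))), 49)
  ep <- electedPair(g1)
  expect_equal(unname(aucMatrix(g1)[ep["selector"], ep["classifier"]]),
               max(aucMatrix(g1)))
  g2 <- runGrid(sim$X, sim$y, k = 3, seed = 5, innerK = 2,
                params = fastParams)
  expect_identical(aucMatrix(g1), aucMatrix(g2))
  expect_identical(electedPair(g1), electedPair(g2))
})

test_that("RadScore is the weighted sum of standardized selected features", {
  m <- new("RadScoreModel", features = c("a", "b"), weights = c(0.5, -0.2),
           center = c(a = 0, b = 0), scale = c(a = 1, b = 1),
           cutoffs = c(outcome = NA_real_, pfs = NA_real_, os = NA_real_),
           selector = "LR", classifier = "LR")
  expect_equal(radScore(m, data.frame(a = 2, b = 1)), 0.8)
  expect_error(radScore(m, data.frame(a = 2)), "\\bb\\b")
})

test_that("fitRadScore recovers the ranking of a known linear score", {
  sim <- simFeatures(600, 8, beta = c(1.2, -1, 0.8), seed = 38)
  truth <- sim$X[, 1:3] %*% c(1.2, -1, 0.8)
  model <- fitRadScore(sim$X, sim$y, selector = "LR", classifier = "LR",
                       seed = 1)
  expect_s4_class(model, "RadScoreModel")
  sc <- radScore(model, sim$X)
  expect_gt(abs(cor(sc, truth, method = "spearman")), 0.8)
  expect_false(any(is.na(model@cutoffs["outcome"])))
})
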