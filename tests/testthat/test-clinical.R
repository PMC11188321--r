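test_that("Youden cutoff on perfectly separated scores is the midpoint", {
  r <- youdenCutoff(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(r$threshold, 5)
  expect_equal(r$youdenJ, 1)
  expect_equal(r$auc, 1)
})

test_that("Youden cutoff equals exhaustive threshold search", {
  set.seed(41)
  for (rep in 1:5) {
    sc <- round(rnorm(120), 1)  # force ties
    lb <- rbinom(120, 1, plogis(sc))
    if (length(unique(lb)) < 2 || length(unique(sc)) < 2) next
    r <- youdenCutoff(sc, lb)
    # oracle: J over every candidate threshold (all midpoints + extremes)
    u <- sort(unique(sc))
    cand <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
    J <- sapply(cand, function(t)
      mean(sc[lb == 1] >= t) + mean(sc[lb == 0] < t) - 1)
    expect_equal(r$youdenJ, max(J), tolerance = 1e-12)
    expect_equal(r$sensitivity + r$specificity - 1, r$youdenJ)
  }
  expect_error(youdenCutoff(rep(1, 10), rep(0:1, 5)), "constant")
})

test_that("null scores give near-zero J and chance AUC", {
  set.seed(42)
  sc <- rnorm(4000); lb <- rbinom(4000, 1, 0.5)
  r <- youdenCutoff(sc, lb)
  expect_lt(abs(r$auc - 0.5), 0.03)
  expect_lt(r$youdenJ, 0.1)
})

test_that("logistic OR on a binary predictor equals the cross-product ratio", {
  d <- data.frame(x = c(rep(1, 20), rep(0, 30), rep(1, 10), rep(0, 40)),
                  outcome = c(rep(1, 50), rep(0, 50)))
  u <- univariateLogistic(d, "x")
  expect_lt(abs(u$table$or - (20 * 40) / (30 * 10)), 1e-6)
  expect_true(u$table$or_low < u$table$or & u$table$or < u$table$or_high)
})

test_that("null-coefficient CIs cover 1 at the nominal rate", {
  cover <- 0
  for (s in 1:40) {
    d <- withr::with_seed(300 + s, data.frame(x = rnorm(2000),
                                              z = rbinom(2000, 1, 0.5)))
    d$outcome <- withr::with_seed(600 + s, rbinom(2000, 1, plogis(0.7 * d$x)))
    tab <- multivariateLogistic(d, c("x", "z"))$table
    zr <- tab[tab$variable == "z", ]
    if (zr$or_low <= 1 && 1 <= zr$or_high) cover <- cover + 1
  }
  expect_gte(cover, 33)  # ~95% coverage, binomial slack
})

test_that("perfect separation raises an explicit error", {
  d <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                  outcome = c(rep(0, 20), rep(1, 20)))
  expect_error(univariateLogistic(d, "x"), "separation")
})

test_that("only univariate p < 0.05 predictors enter the multivariate model", {
  set.seed(43)
  n <- 400
  d <- data.frame(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5),
                  c = rbinom(n, 1, 0.5))
  d$outcome <- rbinom(n, 1, plogis(-1 + 2 * d$a))
  scr <- screenPredictors(d, c("a", "b", "c"))
  expect_true("a" %in% scr$selected)
  expect_equal(scr$selected,
               scr$univariate$variable[scr$univariate$p < 0.05])
})

test_that("the five prediction models use the reference predictor sets", {
  tab <- simulateCohort(cohortSpec(n = 600, seed = 44))
  model <- fitRadScore(as.matrix(tab[keyFeatureNames()]), tab$outcome,
                       "LR", "LR", seed = 1)
  tab$radscore <- radScore(model, tab)
  tab$radscore_high <- as.integer(tab$radscore >= model@cutoffs["outcome"])
  sp <- splitCohort(tab, 0.3, seed = 2)
  models <- buildModels(sp$train, sp$validation)
  expect_equal(models$model,
               c("combined", "clinical", "pet", "nccn_ipi", "ipi"))
  expect_equal(models$predictors[models$model == "combined"],
               "sex+b_symptoms+suvmax_high+radscore_high")
  expect_equal(length(strsplit(models$predictors[1], "\\+")[[1]]), 4)
  expect_true(all(models$auc_train >= 0 & models$auc_train <= 1))
  # planted structure: the combined model dominates the clinical model
  expect_gte(models$auc_train[models$model == "combined"],
             models$auc_train[models$model == "clinical"])
  # refitting on identical data reproduces coefficients
  m2 <- buildModels(sp$train, sp$validation)
  expect_identical(coef(attr(models, "fits")$combined),
                   coef(attr(m2, "fits")$combined))
})

test_that("calibration is near-ideal for data generated by the fitted model", {
  set.seed(45)
  n <- 2000
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  d$outcome <- rbinom(n, 1, plogis(-0.5 + 1.2 * d$x1 + 0.7 * d$x2))
  fit <- glm(outcome ~ x1 + x2, data = d, family = binomial())
  cal <- calibrationBootstrap(fit, d, reps = 50, seed = 1)
  expect_gt(cal$slope, 0.9); expect_lt(cal$slope, 1.1)
  expect_lt(abs(cal$intercept), 0.15)
  expect_true(all(cal$curve$mean_predicted >= 0 &
                  cal$curve$mean_predicted <= 1))
  # reps = 1 degenerates to the apparent calibration
  cal1 <- calibrationBootstrap(fit, d, reps = 1, seed = 1)
  p <- predict(fit, type = "response")
  expect_equal(sum(cal1$curve$mean_predicted * table(cut(p,
    breaks = unique(quantile(p, seq(0, 1, 0.1))), include.lowest = TRUE))),
    sum(p), tolerance = 1e-6)
})

test_that("decision-curve identities hold exactly", {
  ob <- c(rep(1, 40), rep(0, 60))
  # perfect predictor: NB = prevalence at every threshold
  d <- dca(ifelse(ob == 1, 1, 0), ob)  # FP = 0 on the whole grid
  expect_true(all(abs(d$net_benefit - 0.4) < 1e-12))
  expect_true(all(d$treat_none == 0))
  # treat-all curve crosses 0 exactly at the prevalence
  expect_equal(d$treat_all[abs(d$threshold - 0.4) < 1e-9], 0)
  expect_true(all(d$net_benefit <= 0.4 + 1e-12))
  # random predictor stays at or below max(treat-all, 0) + noise
  set.seed(46)
  ob2 <- rbinom(2000, 1, 0.3)
  d2 <- dca(runif(2000), ob2)
  se <- 2 * sqrt(0.3 * 0.7 / 2000)
  expect_true(all(d2$net_benefit <= pmax(d2$treat_all, 0) + 3 * se))
})

test_that("nomogram points are exact and scale-free", {
  set.seed(47)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  d$outcome <- rbinom(n, 1, plogis(0.8 * d$x1 - 1.1 * d$x2))
  fit <- glm(outcome ~ x1 + x2, data = d, family = binomial())
  nm <- nomogramPoints(fit, d)
  expect_equal(max(nm$points$max_points), 100)
  # risk read from the map equals the direct model probability
  idx <- sample(n, 20)
  risks <- nm$riskAt(nm$pointsFor(d[idx, ])$total)
  expect_equal(unname(risks),
               unname(predict(fit, d[idx, ], type = "response")),
               tolerance = 1e-6)
  # doubling coefficients leaves point allocations unchanged
  fit2 <- fit; fit2$coefficients <- 2 * coef(fit)
  nm2 <- nomogramPoints(fit2, d)
  expect_equal(nm$points$max_points, nm2$points$max_points)
  # single-predictor model spans 0-100
  f1 <- glm(outcome ~ x1, data = d, family = binomial())
  expect_equal(nomogramPoints(f1, d)$points$max_points, 100)
})

test_that("uncorrected chi-square reproduces the printed two-cohort p-values", {
  # counts from the reference demographics table (train vs validation)
  expect_equal(round(chisqTestCounts(rbind(c(29, 94), c(19, 35)))$p, 3),
               0.110)
  expect_equal(round(chisqTestCounts(rbind(c(102, 21), c(40, 14)))$p, 3),
               0.173)
  expect_equal(round(chisqTestCounts(rbind(c(86, 37), c(33, 21)))$p, 3),
               0.250)
  expect_equal(round(chisqTestCounts(rbind(c(77, 46), c(33, 21)))$p, 3),
               0.851)
  expect_equal(round(chisqTestCounts(rbind(c(54, 69), c(24, 30)))$p, 3),
               0.947)
  # identical proportions give chi-square 0, p 1
  r <- chisqTestCounts(rbind(c(30, 60), c(10, 20)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(chisqTestCounts(rbind(c(0, 0), c(1, 2))), "zero expected")
  # cohortChisq wraps the same test over data frames
  tr <- data.frame(sex = rep(c(0, 1), c(29, 94)))
  va <- data.frame(sex = rep(c(0, 1), c(19, 35)))
  expect_equal(round(cohortChisq(tr, va, "sex")$p, 3), 0.110)
})
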