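#' Optimal dichotomization cutoff by the Youden index
#'
#' Scans every midpoint between consecutive distinct score values, computes
#' sensitivity and specificity of the rule `score >= threshold`, and returns
#' the threshold maximizing the Youden index J = sensitivity + specificity
#' - 1 (ties resolved towards the lower threshold). The AUC and its DeLong
#' 95% confidence interval accompany the cutoff.
#'
#' @param scores numeric predictor values.
#' @param labels binary outcome (0/1).
#' @return list: `threshold`, `sensitivity`, `specificity`, `youdenJ`,
#'   `auc`, `auc_ci` (length-2).
#' @examples
#' youdenCutoff(c(1, 2, 8, 9), c(0, 0, 1, 1))$threshold
#' @export
youdenCutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("constant scores: no cutoff exists")
  thr <- (u[-length(u)] + u[-1]) / 2
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  J <- vapply(thr, function(t) {
    sum(scores >= t & labels == 1L) / n1 +
      sum(scores < t & labels == 0L) / n0 - 1
  }, numeric(1))
  k <- which.max(J)  # which.max returns the first (lowest) maximizer
  best <- thr[k]
  sens <- sum(scores >= best & labels == 1L) / n1
  spec <- sum(scores < best & labels == 0L) / n0
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<",
                 levels = c(0, 1))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  list(threshold = best, sensitivity = sens, specificity = spec,
       youdenJ = sens + spec - 1, auc = as.numeric(pROC::auc(r)),
       auc_ci = ci[c(1, 3)])
}

# shared logistic fit with explicit separation detection
.logisticFit <- function(formula, data) {
  fit <- suppressWarnings(stats::glm(formula, data = data,
                                     family = stats::binomial()))
  p <- stats::fitted(fit)
  if (any(p < 1e-8 | p > 1 - 1e-8) && max(abs(stats::coef(fit))) > 10)
    stop("perfect separation detected for ", deparse(formula))
  fit
}

.orTable <- function(fit) {
  cf <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  z <- cf / se
  data.frame(variable = names(cf), or = exp(cf),
             or_low = exp(cf - 1.96 * se), or_high = exp(cf + 1.96 * se),
             p = 2 * stats::pnorm(-abs(z)), coefficient = cf,
             row.names = NULL)
}

#' Univariate and multivariate logistic regression
#'
#' Maximum-likelihood logistic fits with Wald odds ratios, 95% confidence
#' intervals and p-values. Perfect separation raises an explicit error
#' rather than returning a silently divergent fit; fewer than ~10
#' observations per variable triggers a warning.
#'
#' @param cohort data.frame of patient records.
#' @param variable,variables predictor column name(s).
#' @param outcome binary outcome column (default `"outcome"`).
#' @return list: `table` (odds ratios), `fit` (the glm object).
#' @export
univariateLogistic <- function(cohort, variable, outcome = "outcome") {
  multivariateLogistic(cohort, variable, outcome = outcome)
}

#' @rdname univariateLogistic
#' @export
multivariateLogistic <- function(cohort, variables, outcome = "outcome") {
  stopifnot(all(c(variables, outcome) %in% names(cohort)))
  if (nrow(cohort) <= 10 * length(variables))
    warning("fewer than ~10 observations per variable")
  f <- stats::reformulate(variables, response = outcome)
  fit <- .logisticFit(f, cohort)
  list(table = .orTable(fit), fit = fit)
}

#' Screen univariate predictors for the multivariate model
#'
#' Applies the entry rule used throughout: only variables with univariate
#' p < `alpha` enter the multivariate model.
#'
#' @param cohort data.frame.
#' @param variables candidate column names.
#' @param outcome outcome column.
#' @param alpha entry threshold (default 0.05).
#' @return list: `univariate` (stacked OR table), `selected` (names with
#'   p < alpha).
#' @export
screenPredictors <- function(cohort, variables, outcome = "outcome",
                             alpha = 0.05) {
  tabs <- lapply(variables, function(v)
    univariateLogistic(cohort, v, outcome = outcome)$table)
  tab <- do.call(rbind, tabs)
  list(univariate = tab, selected = variables[tab$p < alpha])
}

#' Build the five mid-term outcome prediction models
#'
#' The combined model (sex, B symptoms, SUVmax group, RadScore group), the
#' clinical model (sex, B symptoms), the PET model (SUVmax group), and the
#' single-index NCCN-IPI and IPI models, each fit on the training cohort by
#' logistic regression and evaluated by AUC on both cohorts.
#'
#' @param train,validation cohort data.frames.
#' @param outcome outcome column (default `"outcome"`).
#' @param columns named list overriding the predictor column names
#'   (`sex`, `bsym`, `suv`, `rad`, `nccn`, `ipi`).
#' @return data.frame of model name, predictors, train/validation AUC, plus
#'   attribute `"fits"` with the glm objects.
#' @export
buildModels <- function(train, validation, outcome = "outcome",
                        columns = list()) {
  cols <- utils::modifyList(list(sex = "sex", bsym = "b_symptoms",
                                 suv = "suvmax_high", rad = "radscore_high",
                                 nccn = "nccn_ipi_high", ipi = "ipi3"),
                            columns)
  spec <- list(
    combined = c(cols$sex, cols$bsym, cols$suv, cols$rad),
    clinical = c(cols$sex, cols$bsym),
    pet = cols$suv,
    nccn_ipi = cols$nccn,
    ipi = cols$ipi)
  fits <- lapply(spec, function(v)
    .logisticFit(stats::reformulate(v, response = outcome), train))
  aucOf <- function(fit, dat)
    .aucRank(stats::predict(fit, newdata = dat, type = "response"),
             dat[[outcome]])
  out <- data.frame(
    model = names(spec),
    predictors = vapply(spec, paste, "", collapse = "+"),
    auc_train = vapply(fits, aucOf, numeric(1), dat = train),
    auc_validation = vapply(fits, aucOf, numeric(1), dat = validation),
    row.names = NULL)
  attr(out, "fits") <- fits
  out
}

#' Bootstrap calibration curve of a logistic model
#'
#' Decile-binned observed-vs-predicted calibration with bootstrap
#' resampling: in each replicate the model is refit on a resample and its
#' predictions on the original cohort are binned; curves are averaged over
#' replicates. The calibration slope is the coefficient of the linear
#' predictor in a logistic recalibration fit, the intercept comes from the
#' offset model. `reps = 1` degenerates to the apparent calibration.
#'
#' @param fit a fitted glm (binomial).
#' @param data the evaluation cohort.
#' @param reps bootstrap replicates (default 1000).
#' @param bins number of risk bins (default 10).
#' @param seed integer seed.
#' @return list: `curve` (data.frame bin/mean predicted/mean observed),
#'   `slope`, `intercept`.
#' @export
calibrationBootstrap <- function(fit, data, reps = 1000, bins = 10,
                                 seed = 1L) {
  stopifnot(reps >= 1)
  y <- stats::model.response(stats::model.frame(fit$formula, data))
  p <- stats::predict(fit, newdata = data, type = "response")
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE))
  cutbin <- function(pp) cut(pp, breaks = br, include.lowest = TRUE)
  curves <- .withSeed(seed, {
    lapply(seq_len(reps), function(r) {
      idx <- if (reps == 1) seq_len(nrow(data))
             else sample.int(nrow(data), replace = TRUE)
      bfit <- suppressWarnings(stats::glm(fit$formula, data = data[idx, ],
                                          family = stats::binomial()))
      pb <- stats::predict(bfit, newdata = data, type = "response")
      stopifnot(all(pb >= 0 & pb <= 1))
      tapply(pb, cutbin(p), mean)
    })
  })
  predMean <- Reduce(`+`, curves) / length(curves)
  obs <- tapply(y, cutbin(p), mean)
  lp <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  slope <- unname(stats::coef(suppressWarnings(
    stats::glm(y ~ lp, family = stats::binomial())))[2])
  intercept <- unname(stats::coef(suppressWarnings(
    stats::glm(y ~ 1 + offset(lp), family = stats::binomial())))[1])
  list(curve = data.frame(bin = names(obs), mean_predicted = as.numeric(predMean),
                          mean_observed = as.numeric(obs)),
       slope = slope, intercept = intercept)
}

#' Decision curve analysis
#'
#' Net benefit of acting on `predicted risk >= p_t` over a grid of threshold
#' probabilities: NB(p_t) = TP/n - FP/n * p_t / (1 - p_t), together with the
#' treat-all and treat-none reference curves (treat-none is identically 0;
#' treat-all crosses 0 at p_t = prevalence).
#'
#' @param predicted predicted probabilities.
#' @param observed binary outcomes (0/1).
#' @param grid threshold probabilities in (0, 1)
#'   (default 0.01 ... 0.99 step 0.01).
#' @return data.frame: `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
dca <- function(predicted, observed, grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(all(grid > 0 & grid < 1))
  observed <- as.integer(observed)
  n <- length(observed)
  prev <- mean(observed)
  nb <- vapply(grid, function(pt) {
    pos <- predicted >= pt
    tp <- sum(pos & observed == 1L) / n
    fp <- sum(pos & observed == 0L) / n
    tp - fp * pt / (1 - pt)
  }, numeric(1))
  data.frame(threshold = grid, net_benefit = nb,
             treat_all = prev - (1 - prev) * grid / (1 - grid),
             treat_none = 0)
}

#' Nomogram point scales for a logistic model
#'
#' Converts a fitted logistic model into nomogram points: each variable's
#' points are proportional to |coefficient| x its observed range, scaled so
#' the largest effect spans 0-100, and total points map to predicted risk
#' through the inverse logit. The mapping is exact: risk read from the
#' point-to-risk map equals the model's predicted probability.
#'
#' @param fit a fitted binomial glm.
#' @param data data.frame used for the variable ranges (default: the model
#'   frame).
#' @return list: `points` (data.frame variable/range/points span),
#'   `pointsFor(newdata)` (per-variable and total points), `riskAt(total)`
#'   (total points to predicted risk).
#' @export
nomogramPoints <- function(fit, data = NULL) {
  mf <- if (is.null(data)) stats::model.frame(fit) else
    stats::model.frame(stats::delete.response(stats::terms(fit)), data)
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), mf)
  cf <- stats::coef(fit)
  vars <- setdiff(colnames(X), "(Intercept)")
  rng <- vapply(vars, function(v) range(X[, v]), numeric(2))
  eff <- abs(cf[vars]) * (rng[2, ] - rng[1, ])
  maxEff <- max(eff)
  if (maxEff == 0) stop("all effects are zero")
  scale <- 100 / maxEff
  # per-variable reference = the value at which the variable contributes
  # 0 points (minimum of beta * x)
  ref <- ifelse(cf[vars] > 0, rng[1, ], rng[2, ])
  lp0 <- unname(cf["(Intercept)"] + sum(cf[vars] * ref))
  pointsFor <- function(newdata) {
    mfn <- stats::model.frame(stats::delete.response(stats::terms(fit)),
                              newdata)
    Xn <- stats::model.matrix(stats::delete.response(stats::terms(fit)), mfn)
    pts <- sweep(Xn[, vars, drop = FALSE], 2, ref, "-") %*%
      diag(cf[vars] * scale, length(vars))
    colnames(pts) <- vars
    list(points = pts, total = rowSums(pts))
  }
  riskAt <- function(total) stats::plogis(lp0 + total / scale)
  list(points = data.frame(variable = vars, low = rng[1, ], high = rng[2, ],
                           max_points = eff * scale, row.names = NULL),
       pointsFor = pointsFor, riskAt = riskAt)
}

#' Pearson chi-square comparison of two cohorts
#'
#' Compares the distribution of a categorical variable between the training
#' and validation cohorts with Pearson's chi-square test *without* Yates
#' continuity correction (the convention that reproduces the reference
#' demographic-table p-values; the corrected test is available via
#' `correct = TRUE`).
#'
#' @param train,validation cohort data.frames.
#' @param variable column name.
#' @param correct apply the continuity correction (default FALSE).
#' @return list: `statistic`, `df`, `p`, `table`.
#' @export
cohortChisq <- function(train, validation, variable, correct = FALSE) {
  x <- factor(c(train[[variable]], validation[[variable]]))
  g <- rep(c("train", "validation"), c(nrow(train), nrow(validation)))
  chisqTestCounts(table(g, x), correct = correct)
}

#' @rdname cohortChisq
#' @param counts a 2 x k contingency matrix of counts.
#' @export
chisqTestCounts <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  exp_ <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(exp_ <= 0)) stop("zero expected cell count")
  ct <- stats::chisq.test(counts, correct = correct)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = counts)
}
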