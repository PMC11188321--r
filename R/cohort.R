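#' Clinical covariate margins of the reference high-risk DLBCL population
#'
#' Marginal frequencies of the twelve binary clinical covariates used by the
#' cohort simulator, taken from the pooled demographics of a 177-patient
#' two-centre high-risk DLBCL population (NCCN-IPI >= 4, R-CHOP-like
#' first-line therapy).
#'
#' @return named numeric vector of P(covariate = 1).
#' @export
cohortMargins <- function() {
  c(sex          = 129 / 177,  # male
    age60        = 96 / 177,
    ldh_high     = 35 / 177,
    b_symptoms   = 58 / 177,
    ecog2        = 145 / 177,
    ipi3         = 37 / 177,
    nccn_ipi_high = 25 / 177,  # NCCN-IPI 6-8
    stage34      = 158 / 177,
    extranodal2  = 47 / 177,
    bone_marrow  = 128 / 177,
    bulky        = 67 / 177,
    non_gcb      = 77 / 177)
}

#' Specify a synthetic patient cohort
#'
#' Describes the statistical structure of a simulated high-risk DLBCL cohort:
#' sample size, prevalence of the non-CR mid-term outcome, covariate margins,
#' the radiomic feature columns, planted log-odds coefficients for the
#' outcome, and an exponential survival model whose hazard depends on the
#' latent radiomic score group.
#'
#' @param n number of patients (default 177).
#' @param prevalence marginal probability of the non-CR outcome, in (0, 1).
#' @param margins named vector of binary covariate frequencies
#'   (default [cohortMargins()]).
#' @param features character vector of radiomic feature column names to
#'   simulate as independent standard normals (default: the 11 key catalogue
#'   features plus 5 pure-noise columns).
#' @param coefficients named numeric vector of true log-odds coefficients on
#'   feature or covariate columns. Names must refer to generated columns.
#' @param survival list with elements `base_hazard_pfs`, `base_hazard_os`
#'   (events/month), `log_hr_pfs`, `log_hr_os` (planted log hazard ratios of
#'   the high latent-score group), `high_fraction` (fraction of patients in
#'   the high group), `censor_min`, `censor_max` (administrative censoring
#'   window, months), `dropout` (extra early-dropout censoring rate in
#'   [0, 1)).
#' @param seed integer RNG seed.
#' @return A `CohortSpec` list.
#' @export
cohortSpec <- function(n = 177, prevalence = 0.40, margins = cohortMargins(),
                       features = defaultCohortFeatures(),
                       coefficients = defaultCohortCoefficients(),
                       survival = list(), seed = 1L) {
  if (n < 10) stop("n must be >= 10")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  sv <- utils::modifyList(list(
    base_hazard_pfs = log(2) / 50, base_hazard_os = log(2) / 85,
    log_hr_pfs = log(2.1737), log_hr_os = log(2.1356),
    high_fraction = 49 / 177, censor_min = 6, censor_max = 54,
    dropout = 0.10), survival)
  if (sv$dropout < 0 || sv$dropout >= 1)
    stop("survival$dropout (censoring rate) must be in [0, 1)")
  structure(list(n = as.integer(n), prevalence = prevalence,
                 margins = margins, features = features,
                 coefficients = coefficients, survival = sv,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' @rdname cohortSpec
#' @export
defaultCohortFeatures <- function() {
  c(keyFeatureNames(), paste0("noise", 1:5))
}

#' @rdname cohortSpec
#' @export
defaultCohortCoefficients <- function() {
  c(sex = log(2.76), b_symptoms = log(4.065), suvmax_high = log(2.619),
    "glcm.GYBY.joint_maximum" = 0.8,
    "firstorder.0F91.global_intensity_peak" = 0.7,
    "shape.C0JK.surface_area" = 0.6)
}

#' Simulate a synthetic patient cohort feature table
#'
#' Draws binary clinical covariates at the specified margins, independent
#' standard-normal radiomic feature columns, lognormal PET metabolic metrics
#' (SUVmax/MTV/TLG, with dichotomized companions at the reference cutoffs
#' 19.2 / 25.6 cm^3 / 222), a Bernoulli non-CR outcome whose log-odds are
#' `intercept + sum(coefficients * columns)` (the intercept is calibrated so
#' the marginal outcome rate matches `prevalence`), and exponential PFS/OS
#' times whose hazard is multiplied by the planted hazard ratio in the high
#' latent-radiomic-score group. Censoring is administrative (uniform window)
#' plus optional early dropout.
#'
#' @param spec a [cohortSpec()].
#' @return data.frame with one row per patient: `patient_id`, binary
#'   covariates, feature columns, `suvmax`/`mtv`/`tlg` (+ `_high` versions),
#'   `latent_score`, `latent_high`, `outcome` (1 = non-CR), `pfs_months`,
#'   `pfs_event`, `os_months`, `os_event`.
#' @examples
#' tab <- simulateCohort(cohortSpec(n = 177, seed = 7))
#' nrow(tab)
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$n
  .withSeed(spec$seed, {
    tab <- data.frame(patient_id = sprintf("P%04d", seq_len(n)))
    for (nm in names(spec$margins))
      tab[[nm]] <- stats::rbinom(n, 1L, spec$margins[[nm]])
    for (nm in spec$features)
      tab[[nm]] <- stats::rnorm(n)
    tab$suvmax <- stats::rlnorm(n, log(18), 0.5)
    tab$mtv <- stats::rlnorm(n, log(40), 0.8)
    tab$tlg <- tab$mtv * tab$suvmax * 0.4 * stats::rlnorm(n, 0, 0.3)
    tab$suvmax_high <- as.integer(tab$suvmax >= 19.2)
    tab$mtv_high <- as.integer(tab$mtv >= 25.6)
    tab$tlg_high <- as.integer(tab$tlg >= 222)

    cf <- spec$coefficients
    unknown <- setdiff(names(cf), names(tab))
    if (length(unknown))
      stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "))
    lp <- if (length(cf))
      as.numeric(as.matrix(tab[names(cf)]) %*% cf) else rep(0, n)

    # calibrate the intercept to the requested marginal prevalence
    b0 <- if (stats::sd(lp) == 0) stats::qlogis(spec$prevalence) - mean(lp)
      else stats::uniroot(function(b) mean(stats::plogis(b + lp)) -
                            spec$prevalence, c(-30, 30))$root
    tab$outcome <- stats::rbinom(n, 1L, stats::plogis(b0 + lp))

    # latent prognostic score: the radiomic part of the linear predictor
    fcf <- cf[names(cf) %in% spec$features]
    latent <- if (length(fcf))
      as.numeric(as.matrix(tab[names(fcf)]) %*% fcf) else rep(0, n)
    tab$latent_score <- latent
    hi_cut <- stats::quantile(latent, 1 - spec$survival$high_fraction,
                              names = FALSE)
    tab$latent_high <- as.integer(latent > hi_cut)
    if (all(tab$latent_high == 0L) && spec$survival$high_fraction > 0)
      tab$latent_high[latent >= hi_cut] <- 1L  # degenerate constant latent

    sv <- spec$survival
    for (ep in c("pfs", "os")) {
      lam <- sv[[paste0("base_hazard_", ep)]] *
        exp(sv[[paste0("log_hr_", ep)]] * tab$latent_high)
      tt <- stats::rexp(n, lam)
      cc <- stats::runif(n, sv$censor_min, sv$censor_max)
      drop <- stats::runif(n) < sv$dropout
      cc[drop] <- stats::runif(sum(drop), 0, cc[drop])
      tab[[paste0(ep, "_months")]] <- pmin(tt, cc)
      tab[[paste0(ep, "_event")]] <- as.integer(tt <= cc)
    }
    tab
  })
}

#' Randomly split a cohort into training and validation sets
#'
#' The validation set has `ceiling(n * testFraction)` patients (ceiling
#' convention: 177 patients at 0.3 give 123 training / 54 validation); the
#' two parts are disjoint and exhaustive, and the split is reproducible for
#' a fixed seed.
#'
#' @param table cohort data.frame (e.g. from [simulateCohort()]).
#' @param testFraction fraction held out for validation, in (0, 1).
#' @param seed integer RNG seed.
#' @param outcome name of the binary outcome column used for the
#'   degenerate-split warning (default `"outcome"`; ignored when absent).
#' @return list with data.frames `train` and `validation`.
#' @examples
#' sp <- splitCohort(simulateCohort(cohortSpec(seed = 1)), 0.3, seed = 2)
#' c(nrow(sp$train), nrow(sp$validation))
#' @export
splitCohort <- function(table, testFraction = 0.3, seed = 1L,
                        outcome = "outcome") {
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0, 1)")
  n <- nrow(table)
  nVal <- as.integer(ceiling(n * testFraction))
  idx <- .withSeed(seed, sample.int(n, nVal))
  train <- table[-idx, , drop = FALSE]
  validation <- table[idx, , drop = FALSE]
  if (outcome %in% names(table) &&
      length(unique(train[[outcome]])) < 2L)
    warning("training split contains fewer than 2 outcome classes")
  list(train = train, validation = validation)
}
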