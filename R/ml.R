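#' The seven cross-combination methods
#'
#' Canonical order of the machine-learning methods used both as feature
#' selectors and as classifiers: gradient boosted decision trees, extremely
#' randomized trees, random forest, adaptive boosting, L1-penalized logistic
#' regression (LASSO), support vector machine and logistic regression.
#' Grid tie-breaks follow this order.
#'
#' @return character vector of 7 method ids.
#' @export
crossComboMethods <- function() {
  c("GBDT", "ET", "RF", "AdaBoost", "LASSO", "SVM", "LR")
}

# ---- weighted decision stumps + discrete AdaBoost --------------------------

# exhaustive weighted decision stump: best (feature, threshold, polarity)
.stumpFit <- function(X, y, w) {
  n <- nrow(X)
  best <- list(err = Inf)
  for (f in seq_len(ncol(X))) {
    o <- order(X[, f])
    xs <- X[o, f]; ys <- y[o]; ws <- w[o]
    # err(t after position k) for rule "x > t => 1":
    #   sum w over positives at or below k plus negatives above k
    cpos <- cumsum(ws * (ys == 1L))
    cneg <- cumsum(ws * (ys == 0L))
    totneg <- cneg[n]
    errs <- cpos + (totneg - cneg)          # cut after k = 1..n-1 (and n)
    valid <- c(xs[-n] != xs[-1], FALSE)     # only between distinct values
    if (!any(valid)) next
    errs[!valid] <- NA
    kmin <- which.min(errs)            # best for rule "x > t => 1"
    kmax <- which.max(errs)            # best for the flipped rule
    for (cand in list(list(errs[kmin], 1, kmin),
                      list(1 - errs[kmax], -1, kmax))) {
      # polarity -1 flips the rule to "x <= t => 1"
      if (cand[[1]] < best$err) {
        k <- cand[[3]]
        best <- list(err = cand[[1]], feature = f,
                     threshold = (xs[k] + xs[k + 1]) / 2,
                     polarity = cand[[2]])
      }
    }
  }
  if (!is.finite(best$err)) {  # all features constant: trivial stump
    best <- list(err = min(sum(w[y == 1L]), 1 - sum(w[y == 1L])),
                 feature = 1L, threshold = Inf,
                 polarity = if (sum(w[y == 1L]) > 0.5) -1 else 1)
  }
  best
}

.stumpPredict <- function(stump, X) {
  g <- X[, stump$feature] > stump$threshold
  if (stump$polarity < 0) g <- !g
  as.integer(g)
}

# discrete AdaBoost (two-class SAMME) over exhaustive stumps
.adaboostFit <- function(X, y, M = 30L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(M)) {
    st <- .stumpFit(X, y, w)
    pred <- .stumpPredict(st, X)
    err <- sum(w[pred != y])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5 && m > 1L) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-9) break
  }
  structure(list(stumps = stumps, alphas = alphas, p = ncol(X),
                 features = colnames(X)), class = "petradAdaBoost")
}

.adaboostScore <- function(fit, X) {
  s <- rep(0, nrow(X))
  for (m in seq_along(fit$stumps))
    s <- s + fit$alphas[m] * (2 * .stumpPredict(fit$stumps[[m]], X) - 1)
  s
}

.adaboostImportance <- function(fit) {
  imp <- stats::setNames(rep(0, fit$p), fit$features)
  for (m in seq_along(fit$stumps)) {
    f <- fit$stumps[[m]]$feature
    imp[f] <- imp[f] + abs(fit$alphas[m])
  }
  imp
}

# ---- unified method interface ----------------------------------------------

# Fit `method` on standardized X (matrix with colnames) and binary y.
# role = "selector" forces variants that expose coefficients (linear SVM).
# Returns list(method, fit, type) used by .methodPredict / .methodWeights.
.fitMethod <- function(method, X, y, seed = 1L, role = "classifier",
                       params = list()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  pr <- utils::modifyList(list(
    gbdt_nrounds = 60L, gbdt_eta = 0.3, gbdt_depth = 3L,
    trees = 150L, adaboost_m = 30L, glmnet_nfolds = 3L), params)
  fit <- switch(method,
    GBDT = .withSeed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = pr$gbdt_depth,
                    eta = pr$gbdt_eta, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = pr$gbdt_nrounds, verbose = 0)),
    ET = ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
      probability = TRUE, num.trees = pr$trees, importance = "impurity",
      seed = seed, num.threads = 1, splitrule = "extratrees",
      replace = FALSE, sample.fraction = 1),
    RF = ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
      probability = TRUE, num.trees = pr$trees, importance = "impurity",
      seed = seed, num.threads = 1),
    AdaBoost = .adaboostFit(X, y, M = pr$adaboost_m),
    LASSO = if (ncol(X) >= 2L) .withSeed(seed, suppressWarnings(
        glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          standardize = FALSE, nfolds = pr$glmnet_nfolds)))
      else stats::glm.fit(cbind(1, X), y,
                          family = stats::binomial())$coefficients,
    SVM = e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
      kernel = if (role == "selector") "linear" else "radial",
      scale = FALSE),
    LR = suppressWarnings(
      stats::glm.fit(cbind(1, X), y,
                     family = stats::binomial())$coefficients),
    stop("unknown method '", method, "'; methods: ",
         paste(crossComboMethods(), collapse = ", ")))
  list(method = method, fit = fit, features = colnames(X),
       single = (method == "LASSO" && ncol(X) < 2L))
}

# continuous score (higher = class 1) on new data
.methodPredict <- function(mf, X) {
  X <- as.matrix(X)
  switch(mf$method,
    GBDT = stats::predict(mf$fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    ET = ,
    RF = stats::predict(mf$fit, data = X,
                        num.threads = 1)$predictions[, "1"],
    AdaBoost = stats::plogis(2 * .adaboostScore(mf$fit, X)),
    LASSO = if (mf$single)
        as.numeric(stats::plogis(cbind(1, X) %*% mf$fit))
      else as.numeric(stats::predict(mf$fit, X, s = "lambda.min",
                                     type = "response")),
    SVM = {
      dv <- attr(stats::predict(mf$fit, X, decision.values = TRUE),
                 "decision.values")
      # orientation: the column name "A/B" means positive values favour A
      if (startsWith(colnames(dv)[1], "1")) as.numeric(dv)
      else -as.numeric(dv)
    },
    LR = as.numeric(stats::plogis(cbind(1, X) %*% mf$fit)))
}

# per-feature weights; signed coefficients for linear methods when
# signed = TRUE, otherwise magnitudes (used for ranking)
.methodWeights <- function(mf, signed = FALSE) {
  w <- switch(mf$method,
    GBDT = {
      imp <- xgboost::xgb.importance(model = mf$fit)
      out <- stats::setNames(rep(0, length(mf$features)), mf$features)
      out[imp$Feature] <- imp$Gain
      out
    },
    ET = ,
    RF = {
      imp <- mf$fit$variable.importance
      pmax(imp, 0)
    },
    AdaBoost = .adaboostImportance(mf$fit),
    LASSO = {
      cf <- if (mf$single) mf$fit[-1]
        else as.numeric(stats::coef(mf$fit, s = "lambda.min"))[-1]
      stats::setNames(cf, mf$features)
    },
    SVM = {
      if (mf$fit$kernel != 0)
        stop("SVM feature weights require a linear kernel")
      w <- as.numeric(t(mf$fit$coefs) %*% mf$fit$SV)
      # coefs are oriented towards the first factor level ("0")
      stats::setNames(-w, mf$features)
    },
    LR = stats::setNames(mf$fit[-1], mf$features))
  if (signed) w else abs(w)
}

#' Rank features by a method's weights
#'
#' Fits the method on the (already standardized) feature matrix and returns
#' non-negative per-feature weights: impurity/gain importances for the tree
#' ensembles (GBDT, ET, RF), accumulated stump weights for AdaBoost, and
#' absolute coefficients for the linear methods (LASSO, linear-kernel SVM,
#' LR).
#'
#' @param method one of [crossComboMethods()].
#' @param X numeric matrix or data.frame of standardized features.
#' @param y binary outcome vector (0/1), both classes present.
#' @param seed integer seed.
#' @param params optional hyperparameter overrides (see the methods
#'   vignette).
#' @return named non-negative numeric vector, one weight per column of `X`.
#' @export
rankFeatures <- function(method, X, y, seed = 1L, params = list()) {
  mf <- .fitMethod(method, X, y, seed = seed, role = "selector",
                   params = params)
  .methodWeights(mf, signed = FALSE)
}
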