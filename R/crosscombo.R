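# mean stratified k-fold CV AUC of `method` on X, y
.cvMethodAUC <- function(method, X, y, k = 3L, seed = 1L, params = list()) {
  X <- as.matrix(X)
  fold <- .stratifiedFolds(y, k, seed = seed)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    mf <- .fitMethod(method, X[tr, , drop = FALSE], y[tr],
                     seed = .subSeed(seed, f), params = params)
    .aucRank(.methodPredict(mf, X[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Recursive feature elimination with a cross-combination method
#'
#' Backwards elimination driven by the method's own weights: starting from
#' all features, the method's cross-validated AUC is recorded for the
#' current subset, the lowest-weight feature(s) are dropped, and the
#' procedure repeats down to a single feature. The returned subset maximizes
#' CV AUC (ties go to the smaller subset). Features are standardized
#' internally (training statistics of `X`).
#'
#' @param method one of [crossComboMethods()].
#' @param X feature matrix or data.frame (training cohort).
#' @param y binary outcome (0/1).
#' @param k folds for the per-subset CV AUC (default 3).
#' @param seed integer seed.
#' @param dropPerStep features removed per elimination step (default 1, so
#'   the elimination path has exactly `ncol(X)` entries).
#' @param params hyperparameter overrides passed to the method.
#' @return list: `features` (selected names), `auc` (their CV AUC), `path`
#'   (data.frame of subset size, AUC and dropped feature per step).
#' @export
selectFeatures <- function(method, X, y, k = 3L, seed = 1L, dropPerStep = 1L,
                           params = list()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(y)
  std <- .standardize(X)
  Xs <- std$x
  feats <- colnames(Xs)
  path <- list()
  bestFeats <- feats
  bestAUC <- -Inf
  stepn <- 0L
  while (length(feats) >= 1L) {
    stepn <- stepn + 1L
    auc <- .cvMethodAUC(method, Xs[, feats, drop = FALSE], y, k = k,
                        seed = .subSeed(seed, stepn), params = params)
    # ties go to the smaller (later-recorded) subset
    if (auc >= bestAUC - 1e-12) {
      if (auc > bestAUC + 1e-12 || length(feats) < length(bestFeats)) {
        bestAUC <- max(auc, bestAUC)
        bestFeats <- feats
      }
    }
    if (length(feats) == 1L) {
      path[[stepn]] <- data.frame(n_features = 1L, auc = auc,
                                  dropped = NA_character_)
      break
    }
    w <- rankFeatures(method, Xs[, feats, drop = FALSE], y,
                      seed = .subSeed(seed, 1000L + stepn), params = params)
    nd <- min(max(1L, as.integer(dropPerStep)), length(feats) - 1L)
    drop <- names(sort(w))[seq_len(nd)]
    path[[stepn]] <- data.frame(n_features = length(feats), auc = auc,
                                dropped = paste(drop, collapse = ";"))
    feats <- setdiff(feats, drop)
  }
  list(features = bestFeats, auc = bestAUC, path = do.call(rbind, path))
}

#' Cross-validated AUC of one selector/classifier pair
#'
#' Stratified k-fold cross-validation of the full selection + classification
#' pipeline. By default selection is re-run inside each training fold
#' (leakage-safe): features are standardized on the training fold, the
#' selector's recursive elimination picks a subset, the classifier is fit on
#' it, and the AUC is measured on the held-out fold. With
#' `paperProtocol = TRUE` the selection step instead runs once on the full
#' training data before cross-validating the classifier — the literal
#' step order of the original protocol, which is leak-prone and therefore
#' not the default.
#'
#' @param selector,classifier method ids from [crossComboMethods()].
#' @param X feature matrix or data.frame.
#' @param y binary outcome (0/1).
#' @param k outer folds (default 5).
#' @param seed integer seed.
#' @param innerK folds of the selector's internal CV (default 3).
#' @param dropPerStep elimination step size (default 1).
#' @param paperProtocol run selection once before the CV (default FALSE).
#' @param params hyperparameter overrides.
#' @return list: `meanAUC`, `foldAUC` (length k), `selected` (list of
#'   per-fold feature subsets).
#' @export
evaluatePair <- function(selector, classifier, X, y, k = 5L, seed = 1L,
                         innerK = 3L, dropPerStep = 1L,
                         paperProtocol = FALSE, params = list()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(y)
  fold <- .stratifiedFolds(y, k, seed = seed)
  presel <- NULL
  if (paperProtocol)
    presel <- selectFeatures(selector, X, y, k = innerK, seed = seed,
                             dropPerStep = dropPerStep,
                             params = params)$features
  sel_list <- vector("list", k)
  foldAUC <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    std <- .standardize(X[tr, , drop = FALSE])
    Xtr <- std$x
    Xte <- .standardize(X[!tr, , drop = FALSE], std$center, std$scale)$x
    feats <- if (paperProtocol) presel
      else selectFeatures(selector, X[tr, , drop = FALSE], y[tr],
                          k = innerK, seed = .subSeed(seed, f),
                          dropPerStep = dropPerStep,
                          params = params)$features
    sel_list[[f]] <<- feats
    mf <- .fitMethod(classifier, Xtr[, feats, drop = FALSE], y[tr],
                     seed = .subSeed(seed, 100L + f), params = params)
    .aucRank(.methodPredict(mf, Xte[, feats, drop = FALSE]), y[!tr])
  }, numeric(1))
  list(meanAUC = mean(foldAUC, na.rm = TRUE), foldAUC = foldAUC,
       selected = sel_list)
}

#' Run the full 7 x 7 cross-combination grid
#'
#' Evaluates all 49 selector/classifier pairs with [evaluatePair()] under a
#' common fold assignment and elects the pair with the largest mean CV AUC
#' (ties broken lexicographically in the canonical method order).
#'
#' @inheritParams evaluatePair
#' @param methods method ids to cross (default all seven).
#' @return A [CrossComboResult-class].
#' @export
runGrid <- function(X, y, k = 5L, seed = 1L, innerK = 3L, dropPerStep = 1L,
                    paperProtocol = FALSE, params = list(),
                    methods = crossComboMethods()) {
  m <- length(methods)
  auc <- matrix(NA_real_, m, m, dimnames = list(selector = methods,
                                                classifier = methods))
  foldA <- array(NA_real_, c(m, m, k),
                 dimnames = list(methods, methods, NULL))
  for (s in methods) for (cl in methods) {
    ev <- evaluatePair(s, cl, X, y, k = k, seed = seed, innerK = innerK,
                       dropPerStep = dropPerStep,
                       paperProtocol = paperProtocol, params = params)
    auc[s, cl] <- ev$meanAUC
    foldA[s, cl, ] <- ev$foldAUC
  }
  best <- which(auc == max(auc, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  new("CrossComboResult", aucMatrix = auc, foldAUC = foldA,
      selector = methods[best[1]], classifier = methods[best[2]],
      k = as.integer(k), seed = as.integer(seed))
}

#' Fit the weighted radiomic score (RadScore)
#'
#' Runs the elected selector's recursive elimination on the full training
#' cohort, refits the elected classifier on the selected features, and takes
#' its per-feature weights (signed coefficients for linear classifiers,
#' importances for tree ensembles) as the RadScore weights:
#' RadScore(x) = sum_i w_i x_i on standardized features. If outcome /
#' survival-event labels are supplied, maximum-Youden-index cutoffs for
#' dichotomizing the score are stored in the model.
#'
#' @param X training feature matrix or data.frame.
#' @param y binary training outcome (0/1).
#' @param selector,classifier the elected pair (e.g. from [runGrid()]).
#' @param seed integer seed.
#' @param weightSource `"classifier"` (default) or `"selector"`: which
#'   refit's weights define the score.
#' @param pfsEvent,osEvent optional binary event indicators used to compute
#'   the PFS/OS cutoffs.
#' @param innerK,dropPerStep,params as in [selectFeatures()].
#' @return A [RadScoreModel-class].
#' @export
fitRadScore <- function(X, y, selector, classifier, seed = 1L,
                        weightSource = c("classifier", "selector"),
                        pfsEvent = NULL, osEvent = NULL, innerK = 3L,
                        dropPerStep = 1L, params = list()) {
  weightSource <- match.arg(weightSource)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(y)
  sel <- selectFeatures(selector, X, y, k = innerK, seed = seed,
                        dropPerStep = dropPerStep, params = params)
  feats <- sel$features
  std <- .standardize(X[, feats, drop = FALSE])
  wmethod <- if (weightSource == "classifier") classifier else selector
  mf <- .fitMethod(wmethod, std$x, y, seed = .subSeed(seed, 7L),
                   role = if (weightSource == "selector") "selector"
                          else "classifier", params = params)
  w <- tryCatch(.methodWeights(mf, signed = TRUE), error = function(e) NULL)
  if (is.null(w) || all(w == 0)) {
    # RBF-SVM classifiers expose no coefficients; LASSO may zero out all
    # weights at lambda.min -- fall back to the selector's ranking weights
    w <- rankFeatures(selector, std$x, y, seed = .subSeed(seed, 8L),
                      params = params)
  }
  model <- new("RadScoreModel", features = feats, weights = unname(w[feats]),
               center = std$center, scale = std$scale,
               cutoffs = c(outcome = NA_real_, pfs = NA_real_,
                           os = NA_real_),
               selector = selector, classifier = classifier)
  scores <- radScore(model, X)
  cut <- model@cutoffs
  cut["outcome"] <- youdenCutoff(scores, y)$threshold
  if (!is.null(pfsEvent)) cut["pfs"] <- youdenCutoff(scores, pfsEvent)$threshold
  if (!is.null(osEvent)) cut["os"] <- youdenCutoff(scores, osEvent)$threshold
  model@cutoffs <- cut
  model
}

#' Compute RadScore values for new records
#'
#' @param model a [RadScoreModel-class].
#' @param newdata data.frame or matrix containing the model's feature
#'   columns; a missing column is an error naming it.
#' @return numeric score per row.
#' @export
radScore <- function(model, newdata) {
  stopifnot(is(model, "RadScoreModel"))
  newdata <- as.data.frame(newdata, check.names = FALSE)
  missing <- setdiff(model@features, names(newdata))
  if (length(missing))
    stop("record is missing selected feature(s): ",
         paste(missing, collapse = ", "))
  Xs <- .standardize(as.matrix(newdata[model@features]),
                     model@center, model@scale)$x
  as.numeric(Xs %*% model@weights)
}
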