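#' Grey-level co-occurrence matrices
#'
#' One symmetric, normalized GLCM per direction: 13 unique 3D directions at
#' Chebyshev distance `distance`. A pair is counted when both voxels are in
#' the mask; the matrix is symmetrized (both orderings) and normalized to
#' sum to 1.
#'
#' @param discretized a [DiscretizedVOI-class].
#' @param distance integer offset multiplier (default 1).
#' @return list of 13 Ng x Ng matrices (may contain NULL for directions with
#'   no in-mask pairs).
#' @export
glcmMatrices <- function(discretized, distance = 1L) {
  lev <- discretized@levels
  ng <- discretized@nBins
  dirs <- .directions13() * as.integer(distance)
  lapply(seq_len(nrow(dirs)), function(r) {
    nb <- .shift3(lev, dirs[r, ], fill = NA_integer_)
    ok <- !is.na(lev) & !is.na(nb)
    if (!any(ok)) return(NULL)
    m <- table(factor(lev[ok], levels = seq_len(ng)),
               factor(nb[ok], levels = seq_len(ng)))
    m <- unclass(m) + t(unclass(m))
    m / sum(m)
  })
}

# the 23 features of one normalized symmetric GLCM
.glcmFeaturesOne <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  pxy <- P
  mu <- sum(i * pxy)             # symmetric: row mean = col mean
  sig2 <- sum((i - mu)^2 * pxy)  # marginal variance

  # diagonal (difference) and cross-diagonal (sum) distributions
  dk <- 0:(ng - 1)
  pdiff <- vapply(dk, function(k) sum(pxy[abs(i - j) == k]), numeric(1))
  sk <- 2:(2 * ng)
  psum <- vapply(sk, function(k) sum(pxy[(i + j) == k]), numeric(1))

  davg <- sum(dk * pdiff)
  dvar <- sum((dk - davg)^2 * pdiff)
  dent <- -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0]))
  savg <- sum(sk * psum)
  svar <- sum((sk - savg)^2 * psum)
  sent <- -sum(psum[psum > 0] * log2(psum[psum > 0]))

  corr <- if (sig2 > 0) (sum(i * j * pxy) - mu^2) / sig2 else 0

  c(joint_maximum = max(pxy),
    joint_average = mu,
    joint_variance = sum((i - mu)^2 * pxy),
    joint_entropy = -sum(pxy[pxy > 0] * log2(pxy[pxy > 0])),
    difference_average = davg,
    difference_variance = dvar,
    difference_entropy = dent,
    sum_average = savg,
    sum_variance = svar,
    sum_entropy = sent,
    angular_second_moment = sum(pxy^2),
    contrast = sum((i - j)^2 * pxy),
    dissimilarity = sum(abs(i - j) * pxy),
    inverse_difference = sum(pxy / (1 + abs(i - j))),
    norm_inverse_difference = sum(pxy / (1 + abs(i - j) / ng)),
    inverse_difference_moment = sum(pxy / (1 + (i - j)^2)),
    norm_inverse_difference_moment = sum(pxy / (1 + ((i - j) / ng)^2)),
    inverse_variance = sum(pxy[i != j] / (i - j)[i != j]^2),
    correlation = corr,
    autocorrelation = sum(i * j * pxy),
    cluster_tendency = sum((i + j - 2 * mu)^2 * pxy),
    cluster_shade = sum((i + j - 2 * mu)^3 * pxy),
    cluster_prominence = sum((i + j - 2 * mu)^4 * pxy))
}

#' GLCM texture features
#'
#' The 23 grey-level co-occurrence features of the catalogue, computed per
#' direction on the symmetric normalized matrices and averaged over the 13
#' unique 3D directions ("averaged" aggregation). Degenerate conventions:
#' correlation of a constant VOI is 0.
#'
#' @inheritParams glcmMatrices
#' @return named numeric vector of 23 catalogue features.
#' @export
glcmFeatures <- function(discretized, distance = 1L) {
  mats <- glcmMatrices(discretized, distance)
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (!length(mats)) stop("no voxel pairs available for the GLCM")
  f <- rowMeans(vapply(mats, .glcmFeaturesOne,
                       numeric(23)))
  cat <- featureCatalogue()
  stats::setNames(f, cat$name[cat$family == "glcm"])
}
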