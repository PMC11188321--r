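#' Grey-level size-zone matrix
#'
#' Zones are 26-connected components of in-mask voxels sharing the same grey
#' level, over the whole VOI (orientation-free; no direction averaging).
#' Element (i, j) counts zones of level i and size j voxels.
#'
#' @param discretized a [DiscretizedVOI-class].
#' @return Ng x maxZoneSize count matrix.
#' @export
glszmMatrix <- function(discretized) {
  lev <- discretized@levels
  ng <- discretized@nBins
  nVox <- sum(!is.na(lev))
  M <- matrix(0, ng, nVox)
  for (g in seq_len(ng)) {
    mk <- !is.na(lev) & lev == g
    if (!any(mk)) next
    lab <- .labelComponents(mk)
    sizes <- tabulate(lab[lab > 0L])
    for (sz in sizes) M[g, sz] <- M[g, sz] + 1
  }
  M[, seq_len(max(1L, max(which(colSums(M) > 0)))), drop = FALSE]
}

#' GLSZM texture features
#'
#' The 16 size-zone features of the catalogue, computed from the single
#' orientation-free zone matrix.
#'
#' @inheritParams glszmMatrix
#' @return named numeric vector of 16 catalogue features.
#' @export
glszmFeatures <- function(discretized) {
  M <- glszmMatrix(discretized)
  nVox <- sum(!is.na(discretized@levels))
  Ns <- sum(M)
  i <- row(M); j <- col(M)
  ri <- rowSums(M); rj <- colSums(M)
  p <- M / Ns
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  pz <- rj / Ns
  ent <- -sum(p[p > 0] * log2(p[p > 0]))
  f <- c(sum(M / j^2) / Ns,
         sum(M * j^2) / Ns,
         sum(M / i^2) / Ns,
         sum(M * i^2) / Ns,
         sum(M / (i^2 * j^2)) / Ns,
         sum(M * i^2 / j^2) / Ns,
         sum(M * j^2 / i^2) / Ns,
         sum(M * i^2 * j^2) / Ns,
         sum(ri^2) / Ns,
         sum(ri^2) / Ns^2,
         sum(rj^2) / Ns,
         sum(rj^2) / Ns^2,
         Ns / nVox,
         sum((i - mu_i)^2 * p),
         sum((j - mu_j)^2 * p),
         ent)
  cat <- featureCatalogue()
  stats::setNames(f, cat$name[cat$family == "glszm"])
}
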