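#' Discretize a VOI into grey levels
#'
#' Equal-width intensity binning of the in-mask SUVs into `nBins` grey
#' levels: the in-mask minimum maps to level 1, the maximum to level Ng.
#' Fixed bin *number* (rather than fixed bin width) is the package default
#' for PET radiomics; texture and intensity-histogram features are computed
#' on the resulting levels.
#'
#' @param volume a [PETVolume-class].
#' @param mask a non-empty [LesionMask-class].
#' @param nBins number of grey levels Ng >= 2 (default 64).
#' @return A [DiscretizedVOI-class].
#' @examples
#' v <- petVolume(array(1:64, c(4, 4, 4)), spacing = 4)
#' m <- lesionMask(array(TRUE, c(4, 4, 4)), spacing = 4)
#' dv <- discretizeVOI(v, m, nBins = 8)
#' @export
discretizeVOI <- function(volume, mask, nBins = 64) {
  stopifnot(is(volume, "PETVolume"), is(mask, "LesionMask"),
            all(dim(mask@mask) == dim(volume@voxels)))
  if (!any(mask@mask)) stop("empty lesion mask")
  if (nBins < 2) stop("nBins must be >= 2")
  nBins <- as.integer(nBins)
  vals <- volume@voxels[mask@mask]
  lo <- min(vals); hi <- max(vals)
  lev <- array(NA_integer_, dim(volume@voxels))
  if (hi == lo) {
    warning("constant VOI: all voxels assigned level 1; ",
            "texture features are degenerate")
    lev[mask@mask] <- 1L
    edges <- seq(lo, lo + 1, length.out = nBins + 1)
  } else {
    w <- (hi - lo) / nBins
    l <- pmin(nBins, floor((vals - lo) / w) + 1L)
    lev[mask@mask] <- as.integer(l)
    edges <- seq(lo, hi, length.out = nBins + 1)
  }
  new("DiscretizedVOI", levels = lev, nBins = nBins, binEdges = edges,
      spacing = mask@spacing)
}
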