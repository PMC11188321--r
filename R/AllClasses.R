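#' @import methods
NULL

#' PETVolume: a 3D PET image in SUV units
#'
#' Container for a 3D voxel grid of standardized uptake values (SUV,
#' dimensionless) together with its physical voxel spacing in millimetres.
#' SUV grids are the substrate for lesion segmentation, metabolic metrics
#' and radiomic feature extraction.
#'
#' @slot voxels numeric 3D array of SUV values.
#' @slot spacing numeric length-3 vector, voxel edge length per axis (mm).
#' @slot origin numeric length-3 vector, physical position of the centre of
#'   voxel (1,1,1) in mm.
#'
#' @seealso [petVolume()], [readVolume()], [makePhantom()]
#' @export
setClass("PETVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(4, 4, 4), origin = c(0, 0, 0))
)

setValidity("PETVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' LesionMask: a boolean lesion mask congruent with a PETVolume
#'
#' @slot mask logical 3D array, TRUE inside the lesion.
#' @slot spacing numeric length-3 voxel spacing (mm), copied from the volume.
#' @slot lesionId character scalar identifier.
#'
#' @seealso [segmentLesion()], [filterLesions()]
#' @export
setClass("LesionMask",
  representation(mask = "array", spacing = "numeric", lesionId = "character"),
  prototype(spacing = c(4, 4, 4), lesionId = "lesion")
)

setValidity("LesionMask", function(object) {
  msg <- character(0)
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a logical 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(object@lesionId) != 1L)
    msg <- c(msg, "lesionId must be a single string")
  if (length(msg)) msg else TRUE
})

#' FilteredVolume: a filtered PET image with provenance
#'
#' Output of image preprocessing ([logFilter()], [waveletDecompose()]).
#' Carries a provenance tag (filter name, parameters, sub-band) that
#' propagates into feature names when filtered-image features are enabled.
#'
#' @slot voxels numeric 3D array.
#' @slot spacing numeric length-3 voxel spacing (mm).
#' @slot tag character scalar provenance tag, e.g. `"log_sigma2"` or
#'   `"wavelet_coif1_HHL"`.
#' @export
setClass("FilteredVolume",
  representation(voxels = "array", spacing = "numeric", tag = "character")
)

#' DiscretizedVOI: integer grey levels over a VOI
#'
#' Result of equal-width intensity discretization of the in-mask SUVs into
#' `nBins` grey levels (1..Ng). Texture matrices and intensity-histogram
#' features are computed from this object.
#'
#' @slot levels integer 3D array; grey level for in-mask voxels, NA outside.
#' @slot nBins integer number of grey levels Ng.
#' @slot binEdges numeric vector of length Ng + 1, bin edges in SUV.
#' @slot spacing numeric length-3 voxel spacing (mm).
#' @export
setClass("DiscretizedVOI",
  representation(levels = "array", nBins = "integer", binEdges = "numeric",
                 spacing = "numeric")
)

setValidity("DiscretizedVOI", function(object) {
  lv <- object@levels[!is.na(object@levels)]
  if (!length(lv)) return("no in-mask voxels")
  if (min(lv) < 1L || max(lv) > object@nBins)
    return("levels must lie in 1..nBins")
  TRUE
})

#' CrossComboResult: the 7x7 selector-by-classifier grid
#'
#' Result of [runGrid()]: mean cross-validated AUC for each of the 49
#' selector/classifier pairs, the per-fold AUCs, and the elected pair
#' (the matrix argmax; lexicographic tie-break in the canonical method
#' order GBDT, ET, RF, AdaBoost, LASSO, SVM, LR).
#'
#' @slot aucMatrix 7x7 numeric matrix, rows = selectors, cols = classifiers.
#' @slot foldAUC numeric array selectors x classifiers x folds.
#' @slot selector character, elected selector.
#' @slot classifier character, elected classifier.
#' @slot k integer, number of CV folds.
#' @slot seed integer seed the grid was run under.
#' @export
setClass("CrossComboResult",
  representation(aucMatrix = "matrix", foldAUC = "array",
                 selector = "character", classifier = "character",
                 k = "integer", seed = "integer")
)

setValidity("CrossComboResult", function(object) {
  m <- object@aucMatrix
  if (!all(dim(m) == c(7L, 7L))) return("aucMatrix must be 7x7")
  if (any(m < 0 | m > 1, na.rm = TRUE)) return("AUCs must lie in [0, 1]")
  best <- m[object@selector, object@classifier]
  if (best < max(m, na.rm = TRUE) - 1e-12)
    return("elected pair must attain the matrix maximum")
  TRUE
})

#' RadScoreModel: weighted radiomic score
#'
#' RadScore(x) = sum_i w_i x_i over the selected (standardized) features.
#' Weights are the elected classifier's coefficients (linear methods, signed)
#' or impurity importances (tree ensembles) refit on the full training
#' cohort. Dichotomization cutoffs (maximum Youden index) are stored for the
#' mid-term outcome and for PFS/OS events.
#'
#' @slot features character, selected feature names.
#' @slot weights numeric, one weight per selected feature.
#' @slot center,scale numeric, training standardization statistics.
#' @slot cutoffs numeric named vector (outcome/pfs/os), NA until computed.
#' @slot selector,classifier character, the elected pair.
#' @export
setClass("RadScoreModel",
  representation(features = "character", weights = "numeric",
                 center = "numeric", scale = "numeric", cutoffs = "numeric",
                 selector = "character", classifier = "character"),
  prototype(cutoffs = c(outcome = NA_real_, pfs = NA_real_, os = NA_real_))
)

setValidity("RadScoreModel", function(object) {
  if (length(object@weights) != length(object@features))
    return("one weight per feature required")
  if (any(!is.finite(object@weights))) return("weights must be finite")
  if (all(object@weights == 0)) return("at least one nonzero weight required")
  TRUE
})

# ---- constructors ----------------------------------------------------------

#' Create a PETVolume
#'
#' @param voxels numeric 3D array of SUV values.
#' @param spacing voxel spacing in mm (length 3 or scalar).
#' @param origin physical position of voxel (1,1,1) centre, mm.
#' @return A [PETVolume-class] object.
#' @examples
#' v <- petVolume(array(1, c(4, 4, 4)), spacing = 4)
#' @export
petVolume <- function(voxels, spacing = c(4, 4, 4), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PETVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a LesionMask
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing in mm.
#' @param lesionId identifier string.
#' @return A [LesionMask-class] object.
#' @export
lesionMask <- function(mask, spacing = c(4, 4, 4), lesionId = "lesion") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("LesionMask", mask = mask, spacing = as.numeric(spacing),
      lesionId = as.character(lesionId))
}

# ---- accessors -------------------------------------------------------------

#' @rdname petrad-accessors
#' @param object a petrad S4 object.
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname petrad-accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' Accessors for petrad imaging objects
#'
#' `voxelData()` returns the raw 3D array, `voxelSpacing()` the per-axis
#' voxel edge length in mm.
#'
#' @name petrad-accessors
#' @aliases voxelData,PETVolume-method
#' @export
setMethod("voxelData", "PETVolume", function(object) object@voxels)

#' @rdname petrad-accessors
#' @export
setMethod("voxelData", "FilteredVolume", function(object) object@voxels)

#' @rdname petrad-accessors
#' @export
setMethod("voxelData", "LesionMask", function(object) object@mask)

#' @rdname petrad-accessors
#' @export
setMethod("voxelSpacing", "PETVolume", function(object) object@spacing)

#' @rdname petrad-accessors
#' @export
setMethod("voxelSpacing", "FilteredVolume", function(object) object@spacing)

#' @rdname petrad-accessors
#' @export
setMethod("voxelSpacing", "LesionMask", function(object) object@spacing)

#' @rdname petrad-accessors
#' @export
setMethod("voxelSpacing", "DiscretizedVOI", function(object) object@spacing)

#' Number of grey levels of a discretized VOI
#' @param object a [DiscretizedVOI-class].
#' @export
setGeneric("nGreyLevels", function(object) standardGeneric("nGreyLevels"))

#' @rdname nGreyLevels
#' @export
setMethod("nGreyLevels", "DiscretizedVOI", function(object) object@nBins)

#' @rdname petrad-accessors
#' @export
setGeneric("lesionId", function(object) standardGeneric("lesionId"))

#' @rdname petrad-accessors
#' @export
setMethod("lesionId", "LesionMask", function(object) object@lesionId)

#' AUC matrix of a cross-combination grid
#' @param object a [CrossComboResult-class].
#' @export
setGeneric("aucMatrix", function(object) standardGeneric("aucMatrix"))

#' @rdname aucMatrix
#' @export
setMethod("aucMatrix", "CrossComboResult", function(object) object@aucMatrix)

#' Elected selector/classifier pair of a grid
#' @param object a [CrossComboResult-class].
#' @return character vector `c(selector, classifier)`.
#' @export
setGeneric("electedPair", function(object) standardGeneric("electedPair"))

#' @rdname electedPair
#' @export
setMethod("electedPair", "CrossComboResult", function(object)
  c(selector = object@selector, classifier = object@classifier))

#' Selected features / weights of a RadScore model
#' @param object a [RadScoreModel-class].
#' @export
setGeneric("scoreFeatures", function(object) standardGeneric("scoreFeatures"))

#' @rdname scoreFeatures
#' @export
setMethod("scoreFeatures", "RadScoreModel", function(object) object@features)

#' @rdname scoreFeatures
#' @export
setGeneric("scoreWeights", function(object) standardGeneric("scoreWeights"))

#' @rdname scoreFeatures
#' @export
setMethod("scoreWeights", "RadScoreModel", function(object)
  stats::setNames(object@weights, object@features))

#' @rdname scoreFeatures
#' @export
setGeneric("scoreCutoffs", function(object) standardGeneric("scoreCutoffs"))

#' @rdname scoreFeatures
#' @export
setMethod("scoreCutoffs", "RadScoreModel", function(object) object@cutoffs)

# ---- show ------------------------------------------------------------------

setMethod("show", "PETVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("PETVolume: %d x %d x %d voxels @ %s mm\n", d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  v <- object@voxels
  cat(sprintf("  SUV range [%.3g, %.3g], mean %.3g\n",
              min(v), max(v), mean(v)))
})

setMethod("show", "LesionMask", function(object) {
  d <- dim(object@mask)
  nv <- sum(object@mask)
  cat(sprintf("LesionMask '%s': %d voxels (%.2f cm^3) in %d x %d x %d grid\n",
              object@lesionId, nv, nv * prod(object@spacing) / 1000,
              d[1], d[2], d[3]))
})

setMethod("show", "FilteredVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("FilteredVolume [%s]: %d x %d x %d voxels\n",
              object@tag, d[1], d[2], d[3]))
})

setMethod("show", "DiscretizedVOI", function(object) {
  cat(sprintf("DiscretizedVOI: %d in-mask voxels, Ng = %d\n",
              sum(!is.na(object@levels)), object@nBins))
})

setMethod("show", "CrossComboResult", function(object) {
  cat("CrossComboResult (7 x 7 selector x classifier grid)\n")
  cat(sprintf("  elected pair: %s-%s, mean CV AUC = %.3f (k = %d)\n",
              object@selector, object@classifier,
              object@aucMatrix[object@selector, object@classifier], object@k))
})

setMethod("show", "RadScoreModel", function(object) {
  cat(sprintf("RadScoreModel (%s-%s): %d features\n", object@selector,
              object@classifier, length(object@features)))
  w <- sort(abs(object@weights), decreasing = TRUE)
  cat("  top |weights|:", paste(sprintf("%.3g", utils::head(w, 5)),
                                collapse = ", "), "\n")
  if (!all(is.na(object@cutoffs)))
    cat("  cutoffs:", paste(names(object@cutoffs),
        sprintf("%.3g", object@cutoffs), sep = "=", collapse = ", "), "\n")
})
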