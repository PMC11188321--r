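#' Extract the full 110-feature radiomic vector for a VOI
#'
#' Runs the six feature families ([shapeFeatures()], [intensityFeatures()],
#' [glcmFeatures()], [glrlmFeatures()], [ngtdmFeatures()],
#' [glszmFeatures()]) on one VOI and returns the complete catalogue in
#' catalogue order. The default computes features on the original image
#' only, which keeps the catalogue at exactly 110 values; preprocessed
#' (wavelet / Laplacian-of-Gaussian) images can additionally be supplied,
#' in which case intensity and texture families are recomputed on each
#' filtered image and appended with the provenance tag as a name prefix.
#'
#' @param volume a [PETVolume-class].
#' @param mask a non-empty [LesionMask-class] (normally the merged
#'   patient-level VOI surviving the MTV filter).
#' @param nBins grey levels for discretization (default 64).
#' @param glcmDistance GLCM offset distance (default 1).
#' @param filtered optional named list of [FilteredVolume-class] images on
#'   the same grid; off by default.
#' @return named numeric vector (110 features; more when `filtered` images
#'   are given). Any non-finite feature raises an error naming it.
#' @examples
#' p <- makePhantom(phantomSpec(noiseSD = 0, seed = 2, lesions = list(
#'   lesionSpec(center = c(128, 128, 128), radii = 24, peak = 10,
#'              texture = "gaussian-noise"))))
#' fv <- extractFeatures(p$volume, p$masks[[1]])
#' length(fv)
#' @export
extractFeatures <- function(volume, mask, nBins = 64, glcmDistance = 1L,
                            filtered = NULL) {
  dv <- discretizeVOI(volume, mask, nBins = nBins)
  out <- c(shapeFeatures(mask, volume = volume),
           intensityFeatures(volume, mask, dv),
           glcmFeatures(dv, distance = glcmDistance),
           glrlmFeatures(dv),
           ngtdmFeatures(dv),
           glszmFeatures(dv))
  if (!is.null(filtered)) {
    for (fv in filtered) {
      stopifnot(is(fv, "FilteredVolume"))
      if (!all(dim(fv@voxels) == dim(volume@voxels)))
        stop("filtered image grid does not match the volume (sub-band ",
             "images must be upsampled or extracted separately): ", fv@tag)
      pv <- petVolume(fv@voxels, spacing = fv@spacing)
      dvf <- discretizeVOI(pv, mask, nBins = nBins)
      ff <- c(intensityFeatures(pv, mask, dvf),
              glcmFeatures(dvf, distance = glcmDistance),
              glrlmFeatures(dvf), ngtdmFeatures(dvf), glszmFeatures(dvf))
      names(ff) <- paste(fv@tag, names(ff), sep = ".")
      out <- c(out, ff)
    }
  }
  bad <- names(out)[!is.finite(out)]
  if (length(bad))
    stop("non-finite feature value(s): ", paste(bad, collapse = ", "))
  out
}

#' Extract features for a set of patients
#'
#' Convenience wrapper: for each patient, merges the retained lesion masks
#' into the patient-level VOI, computes metabolic metrics and the full
#' feature vector, and binds everything into a feature table.
#'
#' @param patients named list; each element is a list with `volume` and
#'   `masks` (as returned by [makePhantom()]).
#' @param minMTV minimum lesion MTV in cm^3 (default 10).
#' @param ... passed to [extractFeatures()].
#' @return data.frame with `patient_id`, `suvmax`, `mtv`, `tlg` and the 110
#'   feature columns.
#' @export
extractCohortFeatures <- function(patients, minMTV = 10, ...) {
  rows <- lapply(names(patients), function(pid) {
    p <- patients[[pid]]
    keep <- filterLesions(p$masks, p$volume, minMTV = minMTV)
    if (!length(keep)) return(NULL)
    pm <- patientMetrics(p$volume, keep)
    fv <- extractFeatures(p$volume, pm$voi, ...)
    cbind(data.frame(patient_id = pid, suvmax = pm$suvmax,
                     mtv = pm$mtv_cm3, tlg = pm$tlg),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  do.call(rbind, rows)
}
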