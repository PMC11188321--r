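#' Read a PET volume from a NIfTI file
#'
#' Reads a 3D NIfTI image (.nii or .nii.gz) of SUV values; voxel spacing is
#' taken from the header pixdim. Volumes with non-finite voxels are rejected
#' so that NaN propagation cannot silently corrupt downstream features.
#'
#' @param path file path.
#' @return A [PETVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  if (length(dim(a)) != 3L) stop("expected a 3D volume: ", path)
  nbad <- sum(!is.finite(a))
  if (nbad > 0)
    stop(sprintf("volume contains %d non-finite voxel(s): %s", nbad, path))
  sp <- RNifti::pixdim(img)[1:3]
  petVolume(a, spacing = sp)
}

#' Write a PET volume to NIfTI
#'
#' @param volume a [PETVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "PETVolume"))
  img <- RNifti::asNifti(volume@voxels)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a lesion mask as NIfTI
#'
#' Masks are stored as 0/1 integer volumes with the same geometry as their
#' parent PET volume; `readMask()` treats any voxel > 0.5 as in-mask.
#'
#' @param mask a [LesionMask-class].
#' @param path file path.
#' @return `path` (write) or a [LesionMask-class] (read).
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "LesionMask"))
  img <- RNifti::asNifti(array(as.integer(mask@mask), dim(mask@mask)))
  RNifti::pixdim(img) <- mask@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeMask
#' @param lesionId identifier for the mask read back.
#' @export
readMask <- function(path, lesionId = "lesion") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) != 3L) stop("expected a 3D mask: ", path)
  lesionMask(a > 0.5, spacing = RNifti::pixdim(img)[1:3], lesionId = lesionId)
}
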