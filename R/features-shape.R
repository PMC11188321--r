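#' Shape features of a lesion mask
#'
#' Twelve morphological features computed from a triangulated iso-surface of
#' the mask (marching tetrahedra + Taubin smoothing; see the methods
#' vignette): mesh volume V and approximate (voxel-count) volume, surface
#' area A, surface-to-volume ratio, compactness 1 = V / (sqrt(pi) A^{3/2}),
#' compactness 2 = 36 pi V^2 / A^3, spherical disproportion
#' = A / (36 pi V^2)^{1/3}, sphericity = its reciprocal, asphericity
#' = (A^3 / (36 pi V^2))^{1/3} - 1, centre-of-mass shift (distance in mm
#' between the unweighted and the SUV-weighted mask centroid), maximum 3D
#' diameter (largest pairwise distance between surface-mesh vertices), and
#' integrated intensity = SUVmean x V.
#'
#' @param mask a non-empty [LesionMask-class].
#' @param volume the parent [PETVolume-class]; required for the two
#'   intensity-weighted features (centre-of-mass shift, integrated
#'   intensity), which are NA when it is missing.
#' @param smoothIters Taubin smoothing iterations for the surface mesh.
#' @return named numeric vector of 12 catalogue features.
#' @export
shapeFeatures <- function(mask, volume = NULL, smoothIters = 100L) {
  stopifnot(is(mask, "LesionMask"))
  if (!any(mask@mask)) stop("empty lesion mask")
  sp <- mask@spacing
  msh <- .maskMesh(mask@mask, sp, smoothIters = smoothIters)
  A <- msh$area
  V <- msh$volume
  if (V <= 0 || A <= 0) {  # degenerate single-voxel fallback: voxel box
    V <- prod(sp)
    A <- 2 * (sp[1] * sp[2] + sp[1] * sp[3] + sp[2] * sp[3])
  }
  nv <- sum(mask@mask)
  approxV <- nv * prod(sp)
  sph <- (36 * pi * V^2)^(1 / 3) / A

  # maximum pairwise distance between mesh vertices (mm), blocked for memory
  vx <- sweep(msh$vertices, 2, sp, "*")
  maxd <- 0
  if (nrow(vx) >= 2) {
    nb <- nrow(vx)
    step <- 2000L
    for (i0 in seq(1L, nb, by = step)) {
      ii <- i0:min(nb, i0 + step - 1L)
      d2 <- outer(rowSums(vx[ii, , drop = FALSE]^2), rowSums(vx^2), "+") -
        2 * vx[ii, , drop = FALSE] %*% t(vx)
      maxd <- max(maxd, sqrt(max(0, max(d2))))
    }
  }

  com <- NA_real_
  integ <- NA_real_
  if (!is.null(volume)) {
    stopifnot(is(volume, "PETVolume"),
              all(dim(volume@voxels) == dim(mask@mask)))
    co <- arrayInd(which(mask@mask), dim(mask@mask))
    cmm <- sweep(co - 0.5, 2, sp, "*")
    w <- volume@voxels[mask@mask]
    geo <- colMeans(cmm)
    wgt <- colSums(cmm * w) / sum(w)
    com <- sqrt(sum((geo - wgt)^2))
    integ <- mean(w) * V / 1000  # SUVmean x mesh volume, cm^3 x SUV
  }

  cat <- featureCatalogue()
  nm <- cat$name[cat$family == "shape"]
  stats::setNames(c(
    V / 1000,               # volume, cm^3
    approxV / 1000,         # approximate volume, cm^3
    A / 100,                # surface area, cm^2
    A / V,                  # surface-to-volume ratio, 1/mm
    V / (sqrt(pi) * A^1.5), # compactness1
    36 * pi * V^2 / A^3,    # compactness2
    1 / sph,                # spherical disproportion
    sph,                    # sphericity
    (A^3 / (36 * pi * V^2))^(1 / 3) - 1,  # asphericity
    com,                    # centre-of-mass shift, mm
    maxd,                   # maximum 3D diameter, mm
    integ                   # integrated intensity, SUV x cm^3
  ), nm)
}
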