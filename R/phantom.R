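#' Specify a synthetic lesion
#'
#' Defines one ellipsoidal lesion to be painted into a synthetic PET phantom:
#' its physical centre and radii (mm), peak SUV, and a texture generator that
#' controls the intensity pattern inside the ellipsoid. Textures exist to make
#' texture features discriminative on phantoms:
#' \describe{
#'   \item{uniform}{constant `peak` everywhere inside.}
#'   \item{gaussian-noise}{`peak` plus i.i.d. Gaussian noise with SD
#'     `peak * params$sd_rel` (default 0.15).}
#'   \item{checker}{3D checkerboard alternating `peak` and
#'     `peak * params$contrast` (default 0.5) with period `params$period`
#'     voxels (default 2).}
#'   \item{radial-gradient}{`peak * (1 - params$gradient * r/rmax)` declining
#'     from centre to boundary (default gradient 0.5).}
#' }
#'
#' @param center numeric length-3, lesion centre in mm.
#' @param radii numeric length-3 (or scalar), ellipsoid radii in mm.
#' @param peak peak SUV inside the lesion.
#' @param texture one of `"uniform"`, `"gaussian-noise"`, `"checker"`,
#'   `"radial-gradient"`.
#' @param params named list of texture parameters (see Details).
#' @return A `LesionSpec` list.
#' @examples
#' lesionSpec(center = c(100, 100, 100), radii = 20, peak = 10)
#' @export
lesionSpec <- function(center, radii, peak, texture = "uniform",
                       params = list()) {
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  stopifnot(length(center) == 3L, length(radii) == 3L)
  if (any(radii <= 0)) stop("all lesion radii must be > 0")
  if (!is.numeric(peak) || peak <= 0) stop("peak SUV must be > 0")
  texture <- match.arg(texture,
    c("uniform", "gaussian-noise", "checker", "radial-gradient"))
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 peak = peak, texture = texture, params = params),
            class = "LesionSpec")
}

#' Specify a synthetic PET phantom
#'
#' A phantom is a low-uptake background volume with added Gaussian noise and
#' a list of textured ellipsoidal lesions. The default geometry mirrors
#' whole-body PET reconstructions with 4 x 4 x 4 mm voxels.
#'
#' @param dim integer length-3, grid size in voxels.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param background background SUV level (must be below every lesion peak).
#' @param noiseSD SD of additive Gaussian background noise (SUV).
#' @param lesions list of [lesionSpec()] objects.
#' @param seed integer RNG seed; all phantom randomness derives from it.
#' @return A `PhantomSpec` list.
#' @examples
#' spec <- phantomSpec(lesions = list(
#'   lesionSpec(center = c(128, 128, 128), radii = 20, peak = 10)))
#' @export
phantomSpec <- function(dim = c(64, 64, 64), spacing = c(4, 4, 4),
                        background = 1, noiseSD = 0.05, lesions = list(),
                        seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(dim) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0 per axis")
  if (noiseSD < 0) stop("noiseSD must be >= 0")
  for (i in seq_along(lesions)) {
    if (!inherits(lesions[[i]], "LesionSpec"))
      stop("lesions must be a list of lesionSpec() objects")
    if (lesions[[i]]$peak <= background)
      stop(sprintf("lesion %d: peak SUV must exceed the background level", i))
  }
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 background = background, noiseSD = noiseSD,
                 lesions = lesions, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Generate a synthetic PET phantom with ground-truth lesion masks
#'
#' Renders the phantom described by a [phantomSpec()]: a background volume at
#' `background` SUV with optional Gaussian noise, plus each lesion painted
#' into its exact ellipsoidal ground-truth mask using the requested texture.
#' The result is deterministic for a fixed spec (including its seed).
#'
#' @param spec a [phantomSpec()].
#' @return list with elements `volume` (a [PETVolume-class]) and `masks`
#'   (list of ground-truth [LesionMask-class], one per lesion; empty if no
#'   lesions).
#' @examples
#' p <- makePhantom(phantomSpec(noiseSD = 0, lesions = list(
#'   lesionSpec(center = c(128, 128, 128), radii = 20, peak = 10))))
#' max(voxelData(p$volume))
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$dim
  sp <- spec$spacing
  extent <- d * sp
  # voxel centres in mm
  cx <- (seq_len(d[1]) - 0.5) * sp[1]
  cy <- (seq_len(d[2]) - 0.5) * sp[2]
  cz <- (seq_len(d[3]) - 0.5) * sp[3]
  vol <- .withSeed(spec$seed, {
    v <- array(spec$background, d)
    if (spec$noiseSD > 0)
      v <- v + array(stats::rnorm(prod(d), 0, spec$noiseSD), d)
    masks <- vector("list", length(spec$lesions))
    for (li in seq_along(spec$lesions)) {
      ls <- spec$lesions[[li]]
      if (any(ls$center - ls$radii < 0) || any(ls$center + ls$radii > extent))
        stop(sprintf("lesion %d extends beyond the phantom grid", li))
      # ellipsoid membership on voxel centres
      ux <- (cx - ls$center[1]) / ls$radii[1]
      uy <- (cy - ls$center[2]) / ls$radii[2]
      uz <- (cz - ls$center[3]) / ls$radii[3]
      r2 <- outer(outer(ux^2, uy^2, "+"), uz^2, "+")
      m <- r2 <= 1
      idx <- which(m)
      val <- switch(ls$texture,
        "uniform" = rep(ls$peak, length(idx)),
        "gaussian-noise" = {
          sd_rel <- if (is.null(ls$params$sd_rel)) 0.15 else ls$params$sd_rel
          ls$peak + stats::rnorm(length(idx), 0, ls$peak * sd_rel)
        },
        "checker" = {
          period <- if (is.null(ls$params$period)) 2L else as.integer(ls$params$period)
          contrast <- if (is.null(ls$params$contrast)) 0.5 else ls$params$contrast
          co <- arrayInd(idx, d)
          par <- (co[, 1] %/% period + co[, 2] %/% period +
                  co[, 3] %/% period) %% 2L
          ifelse(par == 0L, ls$peak, ls$peak * contrast)
        },
        "radial-gradient" = {
          g <- if (is.null(ls$params$gradient)) 0.5 else ls$params$gradient
          ls$peak * (1 - g * sqrt(r2[idx]))
        })
      v[idx] <- val
      masks[[li]] <- lesionMask(m, spacing = sp,
                                lesionId = sprintf("lesion%02d", li))
    }
    list(v = v, masks = masks)
  })
  list(volume = petVolume(vol$v, spacing = sp), masks = vol$masks)
}
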