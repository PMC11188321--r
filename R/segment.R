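#' Segment a lesion at 41% of SUVmax
#'
#' Semi-automatic threshold segmentation: SUVmax is located inside the
#' user-supplied search region (a seed voxel or a bounding box), the
#' inclusion threshold is `fraction * SUVmax` (default 41%, the EANM
#' recommendation for lymphoma), and the lesion mask is the 26-connected
#' component of above-threshold voxels that contains that maximum.
#'
#' @param volume a [PETVolume-class].
#' @param seed either an integer length-3 voxel coordinate, or a list
#'   `list(lo = c(i,j,k), hi = c(i,j,k))` bounding box defining the search
#'   region.
#' @param fraction threshold fraction of SUVmax (default 0.41).
#' @param global if TRUE the threshold uses the global volume maximum rather
#'   than the search-region maximum.
#' @param connectivity 26 (default) or 6 neighbour connectivity.
#' @param lesionId identifier for the returned mask.
#' @return A [LesionMask-class].
#' @examples
#' p <- makePhantom(phantomSpec(noiseSD = 0, lesions = list(
#'   lesionSpec(center = c(128, 128, 128), radii = 20, peak = 10))))
#' m <- segmentLesion(p$volume, seed = c(32, 32, 32))
#' @export
segmentLesion <- function(volume, seed, fraction = 0.41, global = FALSE,
                          connectivity = 26, lesionId = "lesion") {
  stopifnot(is(volume, "PETVolume"))
  v <- volume@voxels
  d <- dim(v)
  if (is.list(seed)) {
    lo <- pmax(as.integer(seed$lo), 1L)
    hi <- pmin(as.integer(seed$hi), d)
    if (any(lo > hi)) stop("empty search region")
  } else {
    seed <- as.integer(seed)
    if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
      stop("seed voxel outside the grid")
    lo <- hi <- seed
  }
  region <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  suvmax <- if (global) max(v) else max(region)
  thr <- fraction * suvmax
  above <- v >= thr
  if (!any(above[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]))
    stop("no voxel in the search region reaches the threshold; empty mask")
  # start from the region's hottest voxel
  ridx <- which(region == max(region), arr.ind = TRUE)[1, ]
  start <- lo + as.integer(ridx) - 1L
  lab <- if (connectivity == 26) .labelComponents(above)
         else .labelComponents6(above)
  comp <- lab[start[1], start[2], start[3]]
  mask <- lab == comp & comp > 0L
  lesionMask(mask, spacing = volume@spacing, lesionId = lesionId)
}

# 6-connectivity variant used when connectivity = 6
.labelComponents6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  idx_all <- which(mask)
  if (!length(idx_all)) return(lab)
  comp <- 0L
  for (s in idx_all) {
    if (lab[s] > 0L) next
    comp <- comp + 1L
    frontier <- s
    lab[s] <- comp
    while (length(frontier)) {
      fc <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (r in seq_len(nrow(offs))) {
        nc <- sweep(fc, 2, offs[r, ], "+")
        ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] & nc[, 2] >= 1 &
              nc[, 2] <= d[2] & nc[, 3] >= 1 & nc[, 3] <= d[3]
        if (!any(ok)) next
        li <- nc[ok, 1] + (nc[ok, 2] - 1L) * d[1] + (nc[ok, 3] - 1L) * d[1] * d[2]
        li <- li[mask[li] & lab[li] == 0L]
        if (length(li)) { lab[li] <- comp; nxt <- c(nxt, li) }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Filter lesions by minimum metabolic tumor volume
#'
#' Retains exactly the lesion masks whose MTV is at least `minMTV` cm^3
#' (default 10 cm^3; lesions strictly smaller are excluded), preserving
#' order. May return an empty list (with a message).
#'
#' @param masks list of [LesionMask-class].
#' @param volume the parent [PETVolume-class] (geometry check only).
#' @param minMTV minimum MTV in cm^3.
#' @return filtered list of masks.
#' @export
filterLesions <- function(masks, volume, minMTV = 10) {
  stopifnot(is(volume, "PETVolume"))
  keep <- vapply(masks, function(m) {
    stopifnot(is(m, "LesionMask"),
              all(dim(m@mask) == dim(volume@voxels)))
    mtv <- sum(m@mask) * prod(m@spacing) / 1000
    mtv >= minMTV
  }, logical(1))
  if (!any(keep)) message("no lesion survives the ", minMTV, " cm^3 filter")
  masks[keep]
}

#' Metabolic metrics of a lesion
#'
#' SUVmax and SUVmean over the mask, MTV (metabolic tumor volume,
#' voxel count x voxel volume, cm^3) and TLG (total lesion glycolysis,
#' SUVmean x MTV).
#'
#' @param volume a [PETVolume-class].
#' @param mask a non-empty [LesionMask-class] congruent with `volume`.
#' @return named list: `suvmax`, `suvmean`, `mtv_cm3`, `tlg`.
#' @examples
#' v <- petVolume(array(5, c(10, 10, 10)), spacing = 4)
#' m <- lesionMask(array(TRUE, c(10, 10, 10)), spacing = 4)
#' metabolicMetrics(v, m)$tlg
#' @export
metabolicMetrics <- function(volume, mask) {
  stopifnot(is(volume, "PETVolume"), is(mask, "LesionMask"),
            all(dim(mask@mask) == dim(volume@voxels)))
  if (!any(mask@mask)) stop("empty lesion mask")
  vals <- volume@voxels[mask@mask]
  mtv <- sum(mask@mask) * prod(mask@spacing) / 1000
  suvmean <- mean(vals)
  list(suvmax = max(vals), suvmean = suvmean, mtv_cm3 = mtv,
       tlg = suvmean * mtv)
}

#' Patient-level VOI and metabolic metrics
#'
#' Merges all retained lesion masks into one patient-level VOI (their union).
#' Patient SUVmax is the maximum over lesions; MTV and TLG are summed over
#' lesions.
#'
#' @param volume a [PETVolume-class].
#' @param masks non-empty list of [LesionMask-class].
#' @return list: `voi` (merged [LesionMask-class]), `suvmax`, `mtv_cm3`,
#'   `tlg`.
#' @export
patientMetrics <- function(volume, masks) {
  if (!length(masks)) stop("no lesions supplied")
  per <- lapply(masks, metabolicMetrics, volume = volume)
  u <- Reduce(`|`, lapply(masks, function(m) m@mask))
  list(voi = lesionMask(u, spacing = masks[[1]]@spacing, lesionId = "patient"),
       suvmax = max(vapply(per, `[[`, 1, "suvmax")),
       mtv_cm3 = sum(vapply(per, `[[`, 1, "mtv_cm3")),
       tlg = sum(vapply(per, `[[`, 1, "tlg")))
}
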