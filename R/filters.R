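# ---- Laplacian of Gaussian -------------------------------------------------

# separable Gaussian smoothing with replicate (nearest-edge) padding;
# sigma is given per-axis in voxel units
.gaussSmooth <- function(a, sigmaVox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, dp[1], dp[2] * dp[3])
    n <- dp[1]
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    a <- aperm(array(out, dp), order(perm))
  }
  a
}

# discrete Laplacian with physical spacing (replicate padding)
.laplacian3 <- function(a, spacing) {
  d <- dim(a)
  out <- array(0, d)
  for (ax in 1:3) {
    up <- .shift3(a, replace(c(0L, 0L, 0L), ax, 1L), fill = NA)
    dn <- .shift3(a, replace(c(0L, 0L, 0L), ax, -1L), fill = NA)
    up[is.na(up)] <- a[is.na(up)]
    dn[is.na(dn)] <- a[is.na(dn)]
    out <- out + (up - 2 * a + dn) / spacing[ax]^2
  }
  out
}

#' Laplacian-of-Gaussian filtered image
#'
#' Gaussian smoothing at physical scale `sigma` (mm) followed by the discrete
#' Laplacian (second differences scaled by the squared voxel spacing). The
#' operator is linear in the input and returns zero for a constant volume.
#' Edges are handled by replicate padding.
#'
#' @param volume a [PETVolume-class].
#' @param sigma Gaussian scale in mm (> 0; a warning is issued when sigma is
#'   smaller than half the smallest voxel edge, where the discretized kernel
#'   is badly resolved). Default 2 mm.
#' @return A [FilteredVolume-class] tagged `log_sigma<sigma>`.
#' @export
logFilter <- function(volume, sigma = 2) {
  stopifnot(is(volume, "PETVolume"))
  if (sigma <= 0) stop("sigma must be > 0")
  sp <- volume@spacing
  if (sigma < min(sp) / 2)
    warning("sigma is below half the smallest voxel edge; ",
            "the LoG kernel is poorly resolved at this scale")
  sm <- .gaussSmooth(volume@voxels, sigma / sp)
  lg <- .laplacian3(sm, sp)
  new("FilteredVolume", voxels = lg, spacing = sp,
      tag = sprintf("log_sigma%g", sigma))
}

# ---- orthogonal separable 3D wavelet ---------------------------------------

# orthonormal decomposition low-pass filters
.waveletFilters <- function(family) {
  lo <- switch(family,
    haar = c(0.70710678118654757, 0.70710678118654757),
    db2 = c(-0.12940952255126037, 0.22414386804201339,
            0.83651630373780794, 0.48296291314453416),
    coif1 = c(-0.015655728135791993, -0.07273261951252645,
              0.38486484686485778, 0.85257202021160039,
              0.33789766245748182, -0.07273261951252645),
    stop("unknown wavelet family '", family,
         "'; supported families: haar, db2, coif1"))
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)  # quadrature mirror filter
  list(lo = lo, hi = hi)
}

# periodized single-level analysis along one axis; returns list(L =, H =)
.dwtAxis <- function(a, ax, flt) {
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  n <- dp[1]
  if (n %% 2L != 0L) stop("axis length must be even for periodized DWT")
  if (n < length(flt$lo)) stop("axis length shorter than the wavelet filter")
  m <- matrix(ap, n, dp[2] * dp[3])
  half <- n / 2L
  lo <- matrix(0, half, ncol(m))
  hi <- matrix(0, half, ncol(m))
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_along(flt$lo)) {
    row <- (base + (j - 1L)) %% n + 1L
    lo <- lo + flt$lo[j] * m[row, , drop = FALSE]
    hi <- hi + flt$hi[j] * m[row, , drop = FALSE]
  }
  reord <- order(perm)
  list(L = aperm(array(lo, c(half, dp[2], dp[3])), reord),
       H = aperm(array(hi, c(half, dp[2], dp[3])), reord))
}

# adjoint (synthesis) along one axis given the L and H halves
.idwtAxis <- function(loA, hiA, ax, flt) {
  perm <- c(ax, setdiff(1:3, ax))
  lp <- aperm(loA, perm); hp <- aperm(hiA, perm)
  dp <- dim(lp)
  half <- dp[1]; n <- 2L * half
  lo <- matrix(lp, half, dp[2] * dp[3])
  hi <- matrix(hp, half, dp[2] * dp[3])
  out <- matrix(0, n, ncol(lo))
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_along(flt$lo)) {
    # the shifted rows are pairwise distinct for fixed j (even strides mod n)
    row <- (base + (j - 1L)) %% n + 1L
    out[row, ] <- out[row, ] + flt$lo[j] * lo + flt$hi[j] * hi
  }
  aperm(array(out, c(n, dp[2], dp[3])), order(perm))
}

#' Single-level 3D wavelet decomposition
#'
#' Separable periodized orthogonal discrete wavelet transform, one level,
#' producing the 8 sub-bands LLL ... HHH (letter i = low/high-pass along axis
#' i). The transform is orthonormal: sub-band energies sum to the input
#' energy and [waveletReconstruct()] restores the input to numerical
#' precision. All axes must have even length.
#'
#' @param volume a [PETVolume-class].
#' @param family `"coif1"` (default), `"haar"` or `"db2"`.
#' @param level decomposition level; only 1 is supported.
#' @return named list of 8 [FilteredVolume-class] sub-bands; each has half
#'   the grid size and doubled voxel spacing.
#' @export
waveletDecompose <- function(volume, family = "coif1", level = 1) {
  stopifnot(is(volume, "PETVolume"))
  if (level != 1) stop("only single-level decomposition is supported")
  flt <- .waveletFilters(family)
  b1 <- .dwtAxis(volume@voxels, 1L, flt)
  out <- list()
  for (n1 in c("L", "H")) {
    b2 <- .dwtAxis(b1[[n1]], 2L, flt)
    for (n2 in c("L", "H")) {
      b3 <- .dwtAxis(b2[[n2]], 3L, flt)
      for (n3 in c("L", "H")) {
        tag <- paste0(n1, n2, n3)
        out[[tag]] <- new("FilteredVolume", voxels = b3[[n3]],
                          spacing = volume@spacing * 2,
                          tag = sprintf("wavelet_%s_%s", family, tag))
      }
    }
  }
  out
}

#' @rdname waveletDecompose
#' @param bands the list returned by [waveletDecompose()].
#' @return `waveletReconstruct()`: the reconstructed numeric 3D array.
#' @export
waveletReconstruct <- function(bands, family = "coif1") {
  flt <- .waveletFilters(family)
  arr <- lapply(bands, voxelData)
  for (n1 in c("L", "H")) for (n2 in c("L", "H")) {
    arr[[paste0(n1, n2)]] <- .idwtAxis(arr[[paste0(n1, n2, "L")]],
                                       arr[[paste0(n1, n2, "H")]], 3L, flt)
  }
  for (n1 in c("L", "H")) {
    arr[[n1]] <- .idwtAxis(arr[[paste0(n1, "L")]], arr[[paste0(n1, "H")]],
                           2L, flt)
  }
  .idwtAxis(arr[["L"]], arr[["H"]], 1L, flt)
}
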