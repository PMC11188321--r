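# linear-interpolation percentile (same formula as the classical
# 'type 7' definition, written out so tests can check it against an
# independent routine)
.pctl <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# mean SUV inside the ~1 cm^3 sphere neighbourhood maximizing it over
# in-mask centres (global intensity peak)
.globalIntensityPeak <- function(vol, mask, spacing) {
  r <- (3 / (4 * pi) * 1000)^(1 / 3)  # radius of a 1 cm^3 sphere in mm
  rv <- floor(r / spacing)
  offs <- as.matrix(expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2],
                                dz = -rv[3]:rv[3]))
  dist <- sqrt(colSums((t(offs) * spacing)^2))
  offs <- offs[dist <= r, , drop = FALSE]
  s <- array(0, dim(vol))
  cnt <- array(0, dim(vol))
  for (i in seq_len(nrow(offs))) {
    sh <- .shift3(vol, offs[i, ], fill = NA)
    ok <- !is.na(sh)
    s[ok] <- s[ok] + sh[ok]
    cnt <- cnt + ok
  }
  peak <- s / cnt
  max(peak[mask])
}

#' First-order intensity features
#'
#' The 43 first-order catalogue features: 20 statistics of the continuous
#' in-mask SUVs (moments, order statistics, dispersion measures, energy,
#' and the global intensity peak — the mean SUV in the 1 cm^3 sphere
#' maximizing it) and 23 statistics of the discretized intensity histogram
#' (analogous statistics on grey levels, plus entropy, uniformity, and the
#' histogram-gradient features). Degenerate conventions for a constant VOI:
#' skewness, excess kurtosis and coefficient of variation are 0.
#'
#' @param volume a [PETVolume-class].
#' @param mask a non-empty [LesionMask-class].
#' @param discretized the matching [DiscretizedVOI-class].
#' @return named numeric vector of 43 catalogue features.
#' @export
intensityFeatures <- function(volume, mask, discretized) {
  stopifnot(is(volume, "PETVolume"), is(mask, "LesionMask"),
            is(discretized, "DiscretizedVOI"))
  if (!any(mask@mask)) stop("empty lesion mask")
  x <- volume@voxels[mask@mask]
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  s <- sqrt(v)
  skew <- if (s > 0) mean((x - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - mu)^4) / s^4 - 3 else 0
  p10 <- .pctl(x, 0.10); p25 <- .pctl(x, 0.25); p50 <- .pctl(x, 0.50)
  p75 <- .pctl(x, 0.75); p90 <- .pctl(x, 0.90)
  xr <- x[x >= p10 & x <= p90]
  cont <- c(
    mu, v, skew, kurt, p50, min(x), p10, p50, p90, max(x),
    p75 - p25, max(x) - min(x), mean(abs(x - mu)),
    mean(abs(xr - mean(xr))), mean(abs(x - p50)),
    if (mu != 0) s / mu else 0,
    if (p75 + p25 != 0) (p75 - p25) / (p75 + p25) else 0,
    sum(x^2), sqrt(mean(x^2)),
    .globalIntensityPeak(volume@voxels, mask@mask, volume@spacing))

  # intensity-histogram statistics on grey levels
  lev <- discretized@levels[!is.na(discretized@levels)]
  ng <- discretized@nBins
  cnts <- tabulate(lev, nbins = ng)
  p <- cnts / sum(cnts)
  i <- seq_len(ng)
  hmu <- sum(i * p)
  hv <- sum((i - hmu)^2 * p)
  hs <- sqrt(hv)
  hskew <- if (hs > 0) sum((i - hmu)^3 * p) / hs^3 else 0
  hkurt <- if (hs > 0) sum((i - hmu)^4 * p) / hs^4 - 3 else 0
  hp10 <- .pctl(lev, 0.10); hp25 <- .pctl(lev, 0.25)
  hp50 <- .pctl(lev, 0.50); hp75 <- .pctl(lev, 0.75); hp90 <- .pctl(lev, 0.90)
  lr <- lev[lev >= hp10 & lev <= hp90]
  # mode: highest count; ties resolved towards the level nearest the mean,
  # then the lower level
  mx <- which(cnts == max(cnts))
  mode <- mx[order(abs(mx - hmu), mx)][1]
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  unif <- sum(p^2)
  # histogram gradient over counts
  if (ng >= 2) {
    g <- c(cnts[2] - cnts[1],
           if (ng > 2) (cnts[3:ng] - cnts[1:(ng - 2)]) / 2,
           cnts[ng] - cnts[ng - 1])
  } else g <- 0
  ih <- c(
    hmu, hv, hskew, hkurt, hp50, min(lev), hp10, hp90, max(lev), mode,
    hp75 - hp25, max(lev) - min(lev), sum(p * abs(i - hmu)),
    mean(abs(lr - mean(lr))), sum(p * abs(i - hp50)),
    if (hmu != 0) hs / hmu else 0,
    if (hp75 + hp25 != 0) (hp75 - hp25) / (hp75 + hp25) else 0,
    entropy, unif,
    max(g), which.max(g), min(g), which.min(g))

  cat <- featureCatalogue()
  stats::setNames(c(cont, ih), cat$name[cat$family == "firstorder"])
}
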