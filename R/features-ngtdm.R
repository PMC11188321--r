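#' Neighbourhood grey-tone difference table
#'
#' For every in-mask voxel with at least one in-mask 26-neighbour, the
#' absolute difference between its grey level and the mean level of those
#' neighbours is accumulated per grey level: `s_i` (summed differences) and
#' `n_i` (voxel counts).
#'
#' @param discretized a [DiscretizedVOI-class].
#' @return list with vectors `s`, `n` (length Ng).
#' @export
ngtdmTable <- function(discretized) {
  lev <- discretized@levels
  ng <- discretized@nBins
  offs <- .neighbourOffsets26()
  sum_nb <- array(0, dim(lev))
  cnt_nb <- array(0, dim(lev))
  for (r in seq_len(nrow(offs))) {
    sh <- .shift3(lev, offs[r, ], fill = NA_integer_)
    ok <- !is.na(sh)
    sum_nb[ok] <- sum_nb[ok] + sh[ok]
    cnt_nb <- cnt_nb + ok
  }
  valid <- !is.na(lev) & cnt_nb > 0
  a <- abs(lev[valid] - sum_nb[valid] / cnt_nb[valid])
  g <- lev[valid]
  s <- vapply(seq_len(ng), function(i) sum(a[g == i]), numeric(1))
  n <- tabulate(g, nbins = ng)
  list(s = s, n = n)
}

#' NGTDM texture features
#'
#' Coarseness, contrast, busyness, complexity and strength from the
#' neighbourhood grey-tone difference table. Division-by-zero conventions:
#' coarseness is capped at 1e6 (constant VOI); contrast, busyness,
#' complexity and strength fall back to 0 when their denominators vanish.
#'
#' @inheritParams ngtdmTable
#' @return named numeric vector of 5 catalogue features.
#' @export
ngtdmFeatures <- function(discretized) {
  tb <- ngtdmTable(discretized)
  s <- tb$s; n <- tb$n
  N <- sum(n)
  ng <- length(n)
  p <- if (N > 0) n / N else rep(0, ng)
  pres <- which(n > 0)
  npres <- length(pres)
  i <- seq_len(ng)

  den <- sum(p * s)
  coarseness <- if (den > 0) min(1 / den, 1e6) else 1e6

  contrast <- 0
  if (npres > 1 && N > 0) {
    pij <- outer(p[pres], p[pres])
    dij2 <- outer(pres, pres, "-")^2
    contrast <- sum(pij * dij2) / (npres * (npres - 1)) * sum(s) / N
  }

  busy_den <- 0
  for (ii in pres) for (jj in pres)
    busy_den <- busy_den + abs(ii * p[ii] - jj * p[jj])
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0

  complexity <- 0
  strength <- 0
  if (npres >= 1 && N > 0) {
    for (ii in pres) for (jj in pres) {
      if (ii == jj) next
      complexity <- complexity + abs(ii - jj) *
        (p[ii] * s[ii] + p[jj] * s[jj]) / (p[ii] + p[jj])
      strength <- strength + (p[ii] + p[jj]) * (ii - jj)^2
    }
    complexity <- complexity / N
    strength <- if (sum(s) > 0) strength / sum(s) else 0
  }

  cat <- featureCatalogue()
  stats::setNames(c(coarseness, contrast, busyness, complexity, strength),
                  cat$name[cat$family == "ngtdm"])
}
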