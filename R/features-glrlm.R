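#' Grey-level run-length matrices
#'
#' One GLRLM per direction (13 unique 3D directions): element (i, j) counts
#' maximal collinear runs of j consecutive in-mask voxels sharing grey level
#' i. Out-of-mask voxels break runs.
#'
#' @param discretized a [DiscretizedVOI-class].
#' @return list of 13 Ng x maxRun count matrices.
#' @export
glrlmMatrices <- function(discretized) {
  lev <- discretized@levels
  ng <- discretized@nBins
  d <- dim(lev)
  maxRun <- max(d)
  dirs <- .directions13()
  lapply(seq_len(nrow(dirs)), function(r) {
    dd <- dirs[r, ]
    # a voxel starts a run if its predecessor along -dd is absent or differs
    prev <- .shift3(lev, -dd, fill = NA_integer_)
    isStart <- !is.na(lev) & (is.na(prev) | prev != lev)
    starts <- which(isStart)
    M <- matrix(0, ng, maxRun)
    if (!length(starts)) return(M)
    co <- arrayInd(starts, d)
    g <- lev[starts]
    len <- rep(1L, length(starts))
    cur <- co
    repeat {
      nxt <- sweep(cur, 2, dd, "+")
      ok <- nxt[, 1] >= 1 & nxt[, 1] <= d[1] & nxt[, 2] >= 1 &
            nxt[, 2] <= d[2] & nxt[, 3] >= 1 & nxt[, 3] <= d[3]
      li <- rep(NA_integer_, nrow(nxt))
      li[ok] <- nxt[ok, 1] + (nxt[ok, 2] - 1L) * d[1] +
                (nxt[ok, 3] - 1L) * d[1] * d[2]
      cont <- ok & !is.na(lev[ifelse(is.na(li), 1L, li)]) &
              lev[ifelse(is.na(li), 1L, li)] == g
      cont[is.na(cont)] <- FALSE
      if (!any(cont)) break
      len[cont] <- len[cont] + 1L
      # finished runs get recorded; continue only the active ones
      done <- !cont
      if (any(done)) {
        t2 <- table(factor(g[done], levels = seq_len(ng)),
                    factor(len[done], levels = seq_len(maxRun)))
        M <- M + unclass(t2)
      }
      cur <- nxt[cont, , drop = FALSE]
      g <- g[cont]
      len <- len[cont]
    }
    if (length(g)) {
      t2 <- table(factor(g, levels = seq_len(ng)),
                  factor(len, levels = seq_len(maxRun)))
      M <- M + unclass(t2)
    }
    M
  })
}

# 11 features of one run-length count matrix
.glrlmFeaturesOne <- function(M, nVox) {
  Nr <- sum(M)
  if (Nr == 0) return(rep(0, 11))
  i <- row(M); j <- col(M)
  ri <- rowSums(M); rj <- colSums(M)
  c(short_runs_emphasis = sum(M / j^2) / Nr,
    long_runs_emphasis = sum(M * j^2) / Nr,
    low_grey_level_run_emphasis = sum(M / i^2) / Nr,
    high_grey_level_run_emphasis = sum(M * i^2) / Nr,
    short_run_low_grey_level_emphasis = sum(M / (i^2 * j^2)) / Nr,
    short_run_high_grey_level_emphasis = sum(M * i^2 / j^2) / Nr,
    long_run_low_grey_level_emphasis = sum(M * j^2 / i^2) / Nr,
    long_run_high_grey_level_emphasis = sum(M * i^2 * j^2) / Nr,
    grey_level_non_uniformity = sum(ri^2) / Nr,
    run_length_non_uniformity = sum(rj^2) / Nr,
    run_percentage = Nr / nVox)
}

#' GLRLM texture features
#'
#' The 11 run-length features of the catalogue, computed per direction and
#' averaged over the 13 unique 3D directions.
#'
#' @inheritParams glrlmMatrices
#' @return named numeric vector of 11 catalogue features.
#' @export
glrlmFeatures <- function(discretized) {
  nVox <- sum(!is.na(discretized@levels))
  mats <- glrlmMatrices(discretized)
  f <- rowMeans(vapply(mats, .glrlmFeaturesOne, numeric(11), nVox = nVox))
  cat <- featureCatalogue()
  stats::setNames(f, cat$name[cat$family == "glrlm"])
}
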