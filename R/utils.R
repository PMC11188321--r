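# internal helpers shared across modules

# Evaluate expr under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

# Deterministic sub-seed derivation: one master seed per run, stage offsets.
.subSeed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}

# Rank (Wilcoxon) AUC of scores against binary labels; ties handled by
# midranks. Positive class = 1, higher scores predict positives.
.aucRank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment. Returns integer fold id per observation.
# Extras of the positive class go to the first folds, extras of the negative
# class to the last folds, so overall fold sizes differ by at most one
# whenever the total number of extras does not exceed k.
.stratifiedFolds <- function(y, k, seed = NULL) {
  y <- as.integer(y)
  n <- length(y)
  fold <- integer(n)
  .withSeed(seed, {
    classes <- sort(unique(y))
    for (ci in seq_along(classes)) {
      idx <- which(y == classes[ci])
      idx <- sample(idx)
      nc <- length(idx)
      base <- nc %/% k
      extra <- nc %% k
      sizes <- rep(base, k)
      if (extra > 0) {
        target <- if (ci %% 2L == 1L) seq_len(extra) else (k + 1L) - seq_len(extra)
        sizes[target] <- sizes[target] + 1L
      }
      fold[idx] <- rep(seq_len(k), times = sizes)
    }
  })
  fold
}

# Column standardization; returns list(x, center, scale). Zero-variance
# columns get scale 1 so they map to constant zero.
.standardize <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, center, "-"), 2, scale, "/"),
       center = center, scale = scale)
}

# array index <-> linear index helpers for 3D neighbourhood walks
.neighbourOffsets26 <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
}

# The 13 unique 3D directions (lexicographically positive half of the 26).
.directions13 <- function() {
  o <- .neighbourOffsets26()
  keep <- (o[, 1] > 0) |
    (o[, 1] == 0 & o[, 2] > 0) |
    (o[, 1] == 0 & o[, 2] == 0 & o[, 3] > 0)
  o[keep, , drop = FALSE]
}

# Shift a 3D logical/numeric array by integer offset, padding with `fill`.
.shift3 <- function(a, off, fill = NA) {
  d <- dim(a)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) + off[ax]
    i[i < 1 | i > d[ax]] <- NA
    i
  })
  out <- array(fill, d)
  ok <- lapply(src, function(i) !is.na(i))
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

# Connected components of a logical 3D array (26-connectivity); returns an
# integer array of component labels (0 = background).
.labelComponents <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- .neighbourOffsets26()
  idx_all <- which(mask)
  if (!length(idx_all)) return(lab)
  comp <- 0L
  coords <- arrayInd(idx_all, d)
  rownames(coords) <- NULL
  pos <- stats::setNames(seq_along(idx_all), idx_all)
  visited <- logical(length(idx_all))
  for (s in seq_along(idx_all)) {
    if (visited[s]) next
    comp <- comp + 1L
    frontier <- idx_all[s]
    visited[s] <- TRUE
    lab[frontier] <- comp
    while (length(frontier)) {
      fc <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (r in seq_len(nrow(offs))) {
        nc <- sweep(fc, 2, offs[r, ], "+")
        ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] &
              nc[, 2] >= 1 & nc[, 2] <= d[2] &
              nc[, 3] >= 1 & nc[, 3] <= d[3]
        if (!any(ok)) next
        li <- nc[ok, 1] + (nc[ok, 2] - 1L) * d[1] +
              (nc[ok, 3] - 1L) * d[1] * d[2]
        li <- li[mask[li] & lab[li] == 0L]
        if (length(li)) {
          lab[li] <- comp
          p <- pos[as.character(li)]
          visited[p] <- TRUE
          nxt <- c(nxt, li)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}
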