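# Brute-force oracles for the texture families, written as explicit loops so
# they stay independent of the vectorized implementations they check.

# all 26 neighbour offsets / the 13 unique directions
oracleDirs <- function() {
  out <- list()
  # same enumeration order as the implementation (first axis varies fastest)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dx > 0 || (dx == 0 && dy > 0) || (dx == 0 && dy == 0 && dz > 0))
      out[[length(out) + 1]] <- c(dx, dy, dz)
  }
  out
}

inGrid <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric normalized GLCMs by explicit pair enumeration
oracleGLCM <- function(lev, ng, distance = 1) {
  d <- dim(lev)
  lapply(oracleDirs(), function(dir) {
    M <- matrix(0, ng, ng)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (is.na(lev[i, j, k])) next
      q <- c(i, j, k) + dir * distance
      if (!inGrid(q, d)) next
      lq <- lev[q[1], q[2], q[3]]
      if (is.na(lq)) next
      M[lev[i, j, k], lq] <- M[lev[i, j, k], lq] + 1
      M[lq, lev[i, j, k]] <- M[lq, lev[i, j, k]] + 1
    }
    if (sum(M) == 0) NULL else M / sum(M)
  })
}

# 23 GLCM features from one normalized matrix, plain loops
oracleGLCMFeatures <- function(P) {
  ng <- nrow(P)
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * P[i, j]
  sig2 <- 0
  for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu)^2 * P[i, j]
  pd <- numeric(ng); ps <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j] <- ps[i + j] + P[i, j]
  }
  davg <- sum((0:(ng - 1)) * pd)
  savg <- sum((1:(2 * ng)) * ps)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  acc <- c(jmax = max(P), javg = mu, jvar = 0, jent = ent(P),
           davg = davg, dvar = sum((0:(ng - 1) - davg)^2 * pd),
           dent = ent(pd), savg = savg,
           svar = sum(((1:(2 * ng)) - savg)^2 * ps), sent = ent(ps),
           asm = sum(P^2), contrast = 0, dissim = 0, id = 0, idn = 0,
           idm = 0, idmn = 0, invvar = 0, corr = 0, autoc = 0,
           ctend = 0, cshade = 0, cprom = 0)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acc["jvar"] <- acc["jvar"] + (i - mu)^2 * p
    acc["contrast"] <- acc["contrast"] + (i - j)^2 * p
    acc["dissim"] <- acc["dissim"] + abs(i - j) * p
    acc["id"] <- acc["id"] + p / (1 + abs(i - j))
    acc["idn"] <- acc["idn"] + p / (1 + abs(i - j) / ng)
    acc["idm"] <- acc["idm"] + p / (1 + (i - j)^2)
    acc["idmn"] <- acc["idmn"] + p / (1 + ((i - j) / ng)^2)
    if (i != j) acc["invvar"] <- acc["invvar"] + p / (i - j)^2
    acc["autoc"] <- acc["autoc"] + i * j * p
    acc["ctend"] <- acc["ctend"] + (i + j - 2 * mu)^2 * p
    acc["cshade"] <- acc["cshade"] + (i + j - 2 * mu)^3 * p
    acc["cprom"] <- acc["cprom"] + (i + j - 2 * mu)^4 * p
  }
  acc["corr"] <- if (sig2 > 0) (acc[["autoc"]] - mu^2) / sig2 else 0
  acc
}

# run-length matrices by walking each line voxel by voxel
oracleGLRLM <- function(lev, ng) {
  d <- dim(lev)
  maxRun <- max(d)
  lapply(oracleDirs(), function(dir) {
    M <- matrix(0, ng, maxRun)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      p <- c(i, j, k)
      if (is.na(lev[i, j, k])) next
      prev <- p - dir
      if (inGrid(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
          lev[prev[1], prev[2], prev[3]] == lev[i, j, k]) next  # not a start
      g <- lev[i, j, k]
      len <- 1
      q <- p + dir
      while (inGrid(q, d) && !is.na(lev[q[1], q[2], q[3]]) &&
             lev[q[1], q[2], q[3]] == g) {
        len <- len + 1
        q <- q + dir
      }
      M[g, len] <- M[g, len] + 1
    }
    M
  })
}

# size-zone matrix by stack-based flood fill over 26-neighbourhoods
oracleGLSZM <- function(lev, ng) {
  d <- dim(lev)
  nVox <- sum(!is.na(lev))
  M <- matrix(0, ng, nVox)
  seen <- array(FALSE, d)
  offs <- c(oracleDirs(), lapply(oracleDirs(), function(x) -x))
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lev[i, j, k]) || seen[i, j, k]) next
    g <- lev[i, j, k]
    stack <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (o in offs) {
        q <- p + o
        if (!inGrid(q, d)) next
        if (seen[q[1], q[2], q[3]]) next
        lq <- lev[q[1], q[2], q[3]]
        if (is.na(lq) || lq != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    M[g, size] <- M[g, size] + 1
  }
  M
}

# NGTDM s/n by explicit neighbour loops
oracleNGTDM <- function(lev, ng) {
  d <- dim(lev)
  s <- numeric(ng); n <- numeric(ng)
  offs <- c(oracleDirs(), lapply(oracleDirs(), function(x) -x))
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lev[i, j, k])) next
    nb <- c()
    for (o in offs) {
      q <- c(i, j, k) + o
      if (inGrid(q, d) && !is.na(lev[q[1], q[2], q[3]]))
        nb <- c(nb, lev[q[1], q[2], q[3]])
    }
    if (!length(nb)) next
    g <- lev[i, j, k]
    s[g] <- s[g] + abs(g - mean(nb))
    n[g] <- n[g] + 1
  }
  list(s = s, n = n)
}

# random small discretized VOI for property sweeps
randomDVOI <- function(dim = c(5, 5, 5), ng = 3, maskFrac = 0.8,
                       spacing = c(4, 4, 4)) {
  lev <- array(sample.int(ng, prod(dim), replace = TRUE), dim)
  drop <- runif(prod(dim)) > maskFrac
  lev[drop] <- NA_integer_
  if (all(is.na(lev))) lev[1] <- 1L
  new("DiscretizedVOI", levels = lev, nBins = as.integer(ng),
      binEdges = seq(0, ng, by = 1), spacing = spacing)
}

# wrap an explicit level array (NA outside mask) as a DiscretizedVOI
asDVOI <- function(lev, ng, spacing = c(4, 4, 4)) {
  new("DiscretizedVOI", levels = lev, nBins = as.integer(ng),
      binEdges = seq(0, ng, by = 1), spacing = spacing)
}
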