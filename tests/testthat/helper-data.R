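# shared fixture builders (all generated in code)

# digital sphere mask: radius in voxels, centred on a voxel centre
digitalSphere <- function(radiusVox, spacing = c(1, 1, 1), pad = 3L) {
  n <- 2L * ceiling(radiusVox) + 1L + 2L * pad
  ctr <- (n + 1) / 2
  x <- seq_len(n)
  r2 <- outer(outer((x - ctr)^2, (x - ctr)^2, "+"), (x - ctr)^2, "+")
  lesionMask(r2 <= radiusVox^2, spacing = spacing, lesionId = "sphere")
}

# one-lesion phantom with the lesion centre on a voxel centre
spherePhantom <- function(radiusMM = 20, peak = 10, background = 1,
                          noiseSD = 0, texture = "uniform", seed = 1L,
                          dim = c(64, 64, 64), spacing = 4) {
  ctr <- ((dim / 2) - 0.5) * spacing  # voxel-centre aligned
  makePhantom(phantomSpec(dim = dim, spacing = spacing,
                          background = background, noiseSD = noiseSD,
                          seed = seed,
                          lesions = list(lesionSpec(center = ctr,
                                                    radii = radiusMM,
                                                    peak = peak,
                                                    texture = texture))))
}

# standard-normal feature matrix + logistic outcome on the first columns
simFeatures <- function(n, p, beta = NULL, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- paste0("f", seq_len(p))
    lp <- if (is.null(beta)) rep(0, n)
      else X[, seq_along(beta), drop = FALSE] %*% beta
    y <- rbinom(n, 1, plogis(lp))
    list(X = X, y = y)
  })
}

fastParams <- list(trees = 50L, gbdt_nrounds = 20L, adaboost_m = 10L,
                   glmnet_nfolds = 3L)
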