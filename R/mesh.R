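# Iso-surface meshing of binary masks.
#
# Marching tetrahedra on the zero-padded binary field (iso level 0.5, Kuhn
# 6-tetrahedron cube decomposition) followed by Taubin lambda/mu smoothing.
# Raw binary iso-surfaces carry the well-known staircase area bias; Taubin
# smoothing is a shrink-free low-pass filter on the vertex positions that
# removes it while leaving flat faces (fixed points of the neighbour
# averaging) in place.

# Returns list(vertices = n x 3 matrix in voxel-index units, faces = m x 3
# integer matrix, consistently outward-oriented).
.mtMesh <- function(mask) {
  d <- dim(mask)
  f <- array(0, d + 2L)
  f[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask * 1.0
  dd <- dim(f)
  corners <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                   c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  tets <- rbind(c(1,2,3,7), c(1,3,4,7), c(1,4,8,7),
                c(1,8,5,7), c(1,5,6,7), c(1,6,2,7))
  iso <- 0.5
  nx <- dd[1] - 1L; ny <- dd[2] - 1L; nz <- dd[3] - 1L
  V <- matrix(0, nx * ny * nz, 8)
  for (k in 1:8) {
    o <- corners[k, ]
    V[, k] <- as.numeric(f[(1 + o[1]):(nx + o[1]),
                           (1 + o[2]):(ny + o[2]),
                           (1 + o[3]):(nz + o[3])])
  }
  mixed <- which(rowSums(V > iso) %in% 1:7)
  if (!length(mixed)) return(list(vertices = matrix(0, 0, 3),
                                  faces = matrix(0L, 0, 3)))
  ij <- arrayInd(mixed, c(nx, ny, nz)) - 1L
  tris <- vector("list", length(mixed))
  interp <- function(p1, p2, v1, v2) p1 + (iso - v1) / (v2 - v1) * (p2 - p1)
  orient <- function(a, b, cc, outpt) {
    u <- b - a; v <- cc - a
    n <- c(u[2]*v[3] - u[3]*v[2], u[3]*v[1] - u[1]*v[3], u[1]*v[2] - u[2]*v[1])
    if (sum(n * (outpt - (a + b + cc) / 3)) < 0) rbind(a, cc, b)
    else rbind(a, b, cc)
  }
  for (ci in seq_along(mixed)) {
    base <- ij[ci, ]
    vals <- V[mixed[ci], ]
    pts <- sweep(corners, 2, base, "+")
    acc <- list()
    for (t in 1:6) {
      id <- tets[t, ]
      tv <- vals[id]; tp <- pts[id, , drop = FALSE]
      inside <- tv > iso; ni <- sum(inside)
      if (ni == 0L || ni == 4L) next
      if (ni == 1L || ni == 3L) {
        s <- if (ni == 1L) which(inside) else which(!inside)
        o <- setdiff(1:4, s)
        p1 <- interp(tp[s, ], tp[o[1], ], tv[s], tv[o[1]])
        p2 <- interp(tp[s, ], tp[o[2], ], tv[s], tv[o[2]])
        p3 <- interp(tp[s, ], tp[o[3], ], tv[s], tv[o[3]])
        outpt <- if (ni == 1L) 2 * (p1 + p2 + p3) / 3 - tp[s, ] else tp[s, ]
        acc[[length(acc) + 1L]] <- orient(p1, p2, p3, outpt)
      } else {
        ins <- which(inside); outs <- which(!inside)
        q1 <- interp(tp[ins[1], ], tp[outs[1], ], tv[ins[1]], tv[outs[1]])
        q2 <- interp(tp[ins[1], ], tp[outs[2], ], tv[ins[1]], tv[outs[2]])
        q3 <- interp(tp[ins[2], ], tp[outs[2], ], tv[ins[2]], tv[outs[2]])
        q4 <- interp(tp[ins[2], ], tp[outs[1], ], tv[ins[2]], tv[outs[1]])
        outpt <- (tp[outs[1], ] + tp[outs[2], ]) / 2
        acc[[length(acc) + 1L]] <- orient(q1, q2, q3, outpt)
        acc[[length(acc) + 1L]] <- orient(q1, q3, q4, outpt)
      }
    }
    tris[[ci]] <- do.call(rbind, acc)
  }
  P <- do.call(rbind, tris)
  key <- paste(round(P[, 1], 6), round(P[, 2], 6), round(P[, 3], 6))
  uid <- match(key, unique(key))
  list(vertices = P[!duplicated(key), , drop = FALSE],
       faces = matrix(uid, ncol = 3, byrow = TRUE))
}

.taubinSmooth <- function(mesh, iters = 100L, lambda = 0.5, mu = -0.53) {
  if (nrow(mesh$vertices) < 4L || nrow(mesh$faces) < 4L) return(mesh)
  Fm <- mesh$faces
  Vx <- mesh$vertices
  e <- rbind(Fm[, 1:2], Fm[, 2:3], Fm[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(nrow(Vx), nrow(Vx)))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  W <- Matrix::Diagonal(x = 1 / deg) %*% A
  for (it in seq_len(iters)) {
    Vx <- Vx + lambda * (as.matrix(W %*% Vx) - Vx)
    Vx <- Vx + mu * (as.matrix(W %*% Vx) - Vx)
  }
  mesh$vertices <- Vx
  mesh
}

# area (mm^2) and enclosed volume (mm^3) of an oriented triangle mesh whose
# vertices are in voxel-index units; spacing converts to mm
.meshMeasure <- function(mesh, spacing) {
  if (!nrow(mesh$faces)) return(list(area = 0, volume = 0))
  Vx <- sweep(mesh$vertices, 2, spacing, "*")
  a <- Vx[mesh$faces[, 1], , drop = FALSE]
  b <- Vx[mesh$faces[, 2], , drop = FALSE]
  cc <- Vx[mesh$faces[, 3], , drop = FALSE]
  cr <- cbind((b[,2]-a[,2])*(cc[,3]-a[,3]) - (b[,3]-a[,3])*(cc[,2]-a[,2]),
              (b[,3]-a[,3])*(cc[,1]-a[,1]) - (b[,1]-a[,1])*(cc[,3]-a[,3]),
              (b[,1]-a[,1])*(cc[,2]-a[,2]) - (b[,2]-a[,2])*(cc[,1]-a[,1]))
  area <- sum(sqrt(rowSums(cr^2))) / 2
  vol <- abs(sum(a[,1]*(b[,2]*cc[,3] - b[,3]*cc[,2]) -
                 a[,2]*(b[,1]*cc[,3] - b[,3]*cc[,1]) +
                 a[,3]*(b[,1]*cc[,2] - b[,2]*cc[,1])) / 6)
  list(area = area, volume = vol)
}

# full mask -> smoothed mesh + measurements; exposed internally to shape
# features and tests
.maskMesh <- function(mask, spacing, smoothIters = 100L) {
  mesh <- .mtMesh(mask)
  mesh <- .taubinSmooth(mesh, iters = smoothIters)
  c(mesh, .meshMeasure(mesh, spacing))
}
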