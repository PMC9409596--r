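# Exact convex hull volume in arbitrary (small) dimension.
#
# 2-D uses grDevices::chull + the shoelace formula. For d >= 3 the hull is
# integrated as a fan of pyramids from the centroid over the supporting
# facets, found by enumerating d-point subsets whose hyperplane has all
# remaining points on one side; coplanar point groups sharing a hyperplane
# are merged and their facet measure computed recursively in d-1
# dimensions. Exact for the point counts used here (tens of species,
# dimensions up to ~6); cost grows as C(n, d).

.shoelace <- function(x, y) {
  nx <- length(x)
  j <- c(2:nx, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

.affineRank <- function(P, relTol = 1e-9) {
  C <- sweep(P, 2, colMeans(P))
  sv <- svd(C, nu = 0, nv = 0)$d
  sum(sv > max(sv[1], 1e-300) * relTol)
}

.hullVolume <- function(P) {
  P <- as.matrix(P)
  storage.mode(P) <- "double"
  n <- nrow(P)
  d <- ncol(P)
  if (n < d + 1) return(NA_real_)
  if (.affineRank(P) < d) return(NA_real_)   # affinely degenerate
  if (d == 1) return(max(P) - min(P))
  if (d == 2) {
    h <- grDevices::chull(P)
    return(.shoelace(P[h, 1], P[h, 2]))
  }
  scl <- max(abs(P), 1)
  tol <- scl * 1e-9
  centroid <- colMeans(P)
  combs <- utils::combn(n, d)
  normals <- NULL
  offsets <- numeric(0)
  for (ci in seq_len(ncol(combs))) {
    idx <- combs[, ci]
    p0 <- P[idx[1], ]
    M <- P[idx[-1], , drop = FALSE] - rep(p0, each = d - 1)
    qrM <- qr(t(M))
    if (qrM$rank < d - 1) next
    normal <- qr.Q(qrM, complete = TRUE)[, d]
    s <- as.vector(P %*% normal) - sum(normal * p0)
    if (all(s <= tol) || all(s >= -tol)) {
      if (sum((centroid - p0) * normal) > 0) normal <- -normal
      off <- sum(normal * p0)
      dup <- FALSE
      if (!is.null(normals)) {
        cand <- which(abs(offsets - off) < tol * 100)
        for (k in cand)
          if (max(abs(normals[, k] - normal)) < 1e-6) { dup <- TRUE; break }
      }
      if (!dup) {
        normals <- cbind(normals, normal)
        offsets <- c(offsets, off)
      }
    }
  }
  if (is.null(normals)) return(NA_real_)
  vol <- 0
  for (k in seq_along(offsets)) {
    normal <- normals[, k]
    s <- as.vector(P %*% normal) - offsets[k]
    onPlane <- which(abs(s) <= tol * 100)
    if (length(onPlane) < d) next
    basis <- qr.Q(qr(matrix(normal, d, 1)), complete = TRUE)[, -1, drop = FALSE]
    Fp <- (P[onPlane, , drop = FALSE] -
             rep(P[onPlane[1], ], each = length(onPlane))) %*% basis
    facetMeasure <- .hullVolume(Fp)
    if (is.na(facetMeasure)) next
    height <- abs(sum((centroid - P[onPlane[1], ]) * normal))
    vol <- vol + facetMeasure * height / d
  }
  vol
}
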