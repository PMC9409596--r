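# The five distance-based functional diversity metrics.
#
# Working space: FEve, FDis, FDiv and Rao's Q operate on the species
# dissimilarity matrix directly; the centroid-based metrics (FDis, FDiv)
# obtain coordinates internally from all positive PCoA axes, which is
# mathematically equivalent for Euclidean-embeddable distances. Only
# functional richness requires an explicit ordination, conventionally
# truncated to 2 axes. Undefined values propagate as NA, never as zero
# (zeros would bias downstream trait-number regressions).

.checkAbund <- function(abund, n, tol = 1e-6) {
  if (length(abund) != n)
    stop("abundance vector length does not match species count")
  if (any(abund < 0)) stop("abundances must be non-negative")
  if (abs(sum(abund) - 1) > tol)
    stop("relative abundances must sum to 1")
  abund / sum(abund)
}

#' Functional richness: convex hull volume in ordination space
#'
#' Convex hull volume (area when `dims = 2`) of the present species'
#' coordinates truncated to the first `dims` ordination axes. Undefined
#' (returned as `NA`, never 0) when fewer than `dims + 1` species are
#' present or the points are affinely degenerate.
#'
#' @param ord an [OrdinationResult-class] over the species pool
#' @param present species ids (or indices) present in the community
#' @param dims number of ordination axes to use (>= 2; conventionally 2)
#' @return hull volume, or `NA` if undefined
#' @export
functionalRichness <- function(ord, present = rownames(ord@coordinates),
                               dims = 2) {
  stopifnot(is(ord, "OrdinationResult"), dims >= 1)
  coords <- ord@coordinates
  if (dims > ncol(coords)) {
    # the configuration is degenerate in the requested dimensionality
    message(sprintf(
      "functionalRichness undefined: only %d positive axes (requested %d)",
      ncol(coords), dims))
    return(NA_real_)
  }
  X <- coords[present, seq_len(dims), drop = FALSE]
  if (nrow(X) < dims + 1) {
    message("functionalRichness undefined: fewer species than dims + 1")
    return(NA_real_)
  }
  v <- .hullVolume(X)
  if (is.na(v))
    message("functionalRichness undefined: degenerate point configuration")
  v
}

#' Functional evenness from the minimum spanning tree
#'
#' For each branch l of the MST the weighted evenness is
#' `EW_l = dist(i, j) / (w_i + w_j)`; the partial weighted evenness is
#' `PEW_l = EW_l / sum(EW)`; and
#' `FEve = (sum_l min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`.
#' Requires at least 3 species with positive abundance (otherwise `NA`).
#'
#' @param d a [DistanceMatrix-class] (or [SpanningTree-class]) over the
#'   present species
#' @param abund relative abundances of the present species, summing to 1
#' @return FEve in `[0, 1]`, or `NA` if undefined
#' @export
functionalEvenness <- function(d, abund) {
  if (is(d, "SpanningTree")) {
    tree <- d
    abund <- .checkAbund(abund, length(tree@species))
  } else {
    stopifnot(is(d, "DistanceMatrix"))
    abund <- .checkAbund(abund, nrow(d@d))
    keep <- abund > 0
    if (!all(keep)) {
      abund <- abund[keep] / sum(abund[keep])
      d <- newDistanceMatrix(d@d[keep, keep, drop = FALSE], d@method)
    }
    if (nrow(d@d) < 3) {
      message("functionalEvenness undefined for fewer than 3 species")
      return(NA_real_)
    }
    tree <- minimumSpanningTree(d)
  }
  S <- length(tree@species)
  if (S < 3) {
    message("functionalEvenness undefined for fewer than 3 species")
    return(NA_real_)
  }
  br <- tree@branches
  ew <- br[, "length"] / (abund[br[, "i"]] + abund[br[, "j"]])
  if (sum(ew) == 0) return(NA_real_)   # all species coincident
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

.coordsFromDistance <- function(d) {
  ordn <- suppressMessages(pcoa(d))
  ordn@coordinates
}

#' Functional dispersion
#'
#' Abundance-weighted mean distance of species to the abundance-weighted
#' community centroid: `FDis = sum(a_j z_j) / sum(a_j)`. Coordinates may be
#' supplied directly or derived internally from all positive PCoA axes of a
#' distance matrix.
#'
#' @param x species coordinates (matrix) or a [DistanceMatrix-class]
#' @param abund relative abundances summing to 1
#' @return FDis `>= 0` (0 for a single species)
#' @export
functionalDispersion <- function(x, abund) {
  coords <- if (is(x, "DistanceMatrix")) .coordsFromDistance(x) else as.matrix(x)
  abund <- .checkAbund(abund, nrow(coords))
  if (nrow(coords) == 1) return(0)
  centroid <- as.vector(abund %*% coords)
  z <- sqrt(rowSums(sweep(coords, 2, centroid)^2))
  sum(abund * z)
}

#' Functional divergence from distances to the centroid
#'
#' Computes `FDiv = (Delta d + dG) / (Delta|d| + dG)` where `dG` is the
#' unweighted mean distance of species to the centroid,
#' `Delta d = sum a_j (z_j - dG)` and `Delta|d| = sum a_j |z_j - dG|`.
#' This is the deviation kernel shared by all [functionalDivergence()]
#' entry points; exposed so closed-form distance profiles can be evaluated
#' directly.
#'
#' @param z non-negative distances of species to the community centroid
#' @param abund relative abundances summing to 1
#' @return FDiv in `[0, 1]`, or `NA` when all species are coincident
#' @export
divergenceIndex <- function(z, abund) {
  abund <- .checkAbund(abund, length(z))
  dG <- mean(z)
  dev <- z - dG
  deltaD <- sum(abund * dev)
  deltaAbs <- sum(abund * abs(dev))
  if (dG == 0 && deltaAbs == 0) {
    message("functionalDivergence undefined: all species coincident")
    return(NA_real_)
  }
  (deltaD + dG) / (deltaAbs + dG)
}

.hullVertices <- function(coords) {
  dd <- ncol(coords)
  n <- nrow(coords)
  if (dd == 1) return(unique(c(which.min(coords), which.max(coords))))
  if (dd == 2) return(grDevices::chull(coords))
  if (dd == 3 && n <= 25) {
    # union of supporting-facet points
    verts <- logical(n)
    combs <- utils::combn(n, 3)
    tol <- max(abs(coords), 1) * 1e-9
    for (ci in seq_len(ncol(combs))) {
      idx <- combs[, ci]
      M <- coords[idx[-1], , drop = FALSE] -
        rep(coords[idx[1], ], each = 2)
      qrM <- qr(t(M))
      if (qrM$rank < 2) next
      nv <- qr.Q(qrM, complete = TRUE)[, 3]
      s <- as.vector(coords %*% nv) - sum(nv * coords[idx[1], ])
      if (all(s <= tol) || all(s >= -tol)) verts[abs(s) <= tol * 100] <- TRUE
    }
    if (any(verts)) return(which(verts))
  }
  seq_len(n)   # fallback: all species
}

#' Functional divergence
#'
#' Abundance-weighted spread of species toward the extremes of the
#' occupied trait space, independent of functional richness. With explicit
#' coordinates the reference centroid is the unweighted mean of the convex
#' hull vertex species; in distance-only mode (coordinates reconstructed
#' from all positive PCoA axes) it falls back to the unweighted mean of all
#' species. Requires at least 3 species.
#'
#' @inheritParams functionalDispersion
#' @param vertexCentroid use the hull-vertex centroid when coordinates are
#'   supplied (default TRUE; distance input always uses the all-species mean)
#' @return FDiv in `[0, 1]`, or `NA` if undefined
#' @export
functionalDivergence <- function(x, abund, vertexCentroid = TRUE) {
  distanceMode <- is(x, "DistanceMatrix")
  coords <- if (distanceMode) .coordsFromDistance(x) else as.matrix(x)
  abund <- .checkAbund(abund, nrow(coords))
  if (nrow(coords) < 3) {
    message("functionalDivergence undefined for fewer than 3 species")
    return(NA_real_)
  }
  ref <- if (!distanceMode && vertexCentroid)
    .hullVertices(coords) else seq_len(nrow(coords))
  centroid <- colMeans(coords[ref, , drop = FALSE])
  z <- sqrt(rowSums(sweep(coords, 2, centroid)^2))
  divergenceIndex(z, abund)
}

#' Rao's quadratic entropy
#'
#' Expected trait distance between two individuals drawn at random:
#' `Q = sum_{i<j} d_ij p_i p_j`.
#'
#' @param d a [DistanceMatrix-class] (or symmetric matrix)
#' @param abund relative abundances summing to 1
#' @return Rao's Q `>= 0`
#' @examples
#' d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' raosQ(d, c(0.5, 0.5))   # 0.25
#' @export
raosQ <- function(d, abund) {
  dm <- if (is(d, "DistanceMatrix")) d@d else as.matrix(d)
  abund <- .checkAbund(abund, nrow(dm))
  as.numeric(abund %*% dm %*% abund) / 2
}
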