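# Gaussian kernel-density hypervolumes and the three KDE metrics.

.kdeDensity <- function(centers, weights, bandwidth, X) {
  d <- ncol(centers)
  Ys <- centers * rep(1 / bandwidth, each = nrow(centers))
  Xs <- X * rep(1 / bandwidth, each = nrow(X))
  D2 <- matrix(rowSums(Xs^2), nrow(Xs), nrow(Ys)) +
    rep(rowSums(Ys^2), each = nrow(Xs)) - 2 * tcrossprod(Xs, Ys)
  D2[D2 < 0] <- 0
  as.vector(exp(-D2 / 2) %*% weights) /
    ((2 * pi)^(d / 2) * prod(bandwidth))
}

# Lean hypervolume kernel: everything buildHypervolume() computes, as a
# plain list (the sweep builds hypervolumes per plot x subset, where S4
# construction costs would dominate).
.hvBuild <- function(coords, w, bandwidth = NULL, mass = 0.95,
                     nSamples = 2000, seed = 1) {
  S <- nrow(coords)
  d <- ncol(coords)
  if (is.null(bandwidth)) {
    sds <- apply(coords, 2, weightedSd, w = w)
    if (any(sds == 0))
      stop("zero-variance dimension(s): ",
           paste(which(sds == 0), collapse = ", "),
           "; remove constant trait(s) before building a hypervolume")
    nEff <- nrow(unique(coords))
    bandwidth <- sds * (4 / (d + 2))^(1 / (d + 4)) * nEff^(-1 / (d + 4))
  }
  sm <- withLocalSeed(seed, {
    list(u = stats::runif(nSamples),
         noise = matrix(stats::rnorm(nSamples * d), nSamples, d))
  })
  idx <- pmin(findInterval(sm$u, cumsum(w)) + 1L, S)
  X <- coords[idx, , drop = FALSE] +
    sm$noise * rep(bandwidth, each = nSamples)
  f <- .kdeDensity(coords, w, bandwidth, X)
  threshold <- unname(stats::quantile(f, 1 - mass, type = 7))
  retain <- f >= threshold
  list(centers = coords, weights = w, bandwidth = bandwidth,
       threshold = threshold, mass = mass,
       support = X[retain, , drop = FALSE], density = f[retain],
       volume = sum(1 / f[retain]) / nSamples, nSamples = nSamples,
       seed = seed)
}

.hvOverlap <- function(a, b) {
  fracIn <- function(p, hv) {
    if (!nrow(p)) return(0)
    mean(.kdeDensity(hv$centers, hv$weights, hv$bandwidth, p) >=
           hv$threshold)
  }
  inter <- (fracIn(a$support, b) * a$volume +
              fracIn(b$support, a) * b$volume) / 2
  uni <- a$volume + b$volume - inter
  if (uni <= 0) return(NA_real_)
  max(0, min(1, inter / uni))
}

.hvDispersion <- function(hv) {
  pts <- hv$support
  if (!nrow(pts)) return(NA_real_)
  centroid <- colMeans(pts)
  mean(sqrt(rowSums((pts - rep(centroid, each = nrow(pts)))^2)))
}

#' Build a Gaussian kernel-density hypervolume
#'
#' Places a Gaussian kernel (diagonal, per-dimension Silverman bandwidth)
#' at every species coordinate, optionally abundance-weighted; bounds the
#' occupancy region at the density quantile enclosing `mass` of the
#' probability; and estimates the bounded volume by importance-weighted
#' Monte-Carlo integration over the mixture itself
#' (`Vol = E_f[ 1{f >= t} / f ]`). Deterministic given `seed`: component
#' choice uses inverse-CDF sampling on the cumulative weights, so splitting
#' a species into duplicates with divided weights reproduces the identical
#' point stream and hence a bit-identical hypervolume.
#'
#' Continuous traits only; coordinates are expected z-scored. The Silverman
#' sample size is the number of distinct species coordinates.
#'
#' @param coords species-by-dimension numeric matrix (>= 2 species)
#' @param weights relative abundances (default uniform)
#' @param bandwidth optional per-dimension bandwidth override
#' @param mass probability mass the boundary encloses (default 0.95)
#' @param nSamples Monte-Carlo sample size (default 10000)
#' @param seed RNG seed (default 1)
#' @return a [Hypervolume-class]
#' @export
buildHypervolume <- function(coords, weights = NULL, bandwidth = NULL,
                             mass = 0.95, nSamples = 10000, seed = 1) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  S <- nrow(coords)
  d <- ncol(coords)
  if (S < 2) stop("a hypervolume needs at least 2 species")
  weighted <- !is.null(weights) &&
    max(abs(weights / sum(weights) - 1 / S)) > 1e-12
  w <- if (is.null(weights)) rep(1 / S, S) else weights / sum(weights)
  if (any(w < 0)) stop("weights must be non-negative")
  if (!is.null(bandwidth) && length(bandwidth) == 1)
    bandwidth <- rep(bandwidth, d)
  hv <- .hvBuild(coords, w, bandwidth = bandwidth, mass = mass,
                 nSamples = nSamples, seed = seed)
  new("Hypervolume", dims = as.integer(d), centers = hv$centers,
      weights = hv$weights, bandwidth = hv$bandwidth,
      threshold = hv$threshold, mass = hv$mass,
      supportPoints = hv$support, supportDensity = hv$density,
      volume = hv$volume, nSamples = as.integer(nSamples),
      seed = as.integer(seed), weighted = weighted)
}

#' KDE richness: total volume of the unweighted hypervolume
#'
#' @param hv a [Hypervolume-class] built with uniform weights
#' @return the hypervolume volume
#' @export
kdeRichness <- function(hv) {
  stopifnot(is(hv, "Hypervolume"))
  if (hv@weighted)
    stop("KDE richness is defined on the unweighted hypervolume; ",
         "rebuild with uniform weights")
  hv@volume
}

#' KDE evenness: overlap between two hypervolumes
#'
#' Jaccard-type overlap (intersection volume / union volume) between the
#' abundance-weighted hypervolume and the reference hypervolume with
#' uniform weights on the same trait space. The intersection is estimated
#' by cross-inclusion: the fraction of each hypervolume's support points
#' falling inside the other (density at or above the other's threshold),
#' scaled by its volume, averaged over both directions.
#'
#' @param hv1,hv2 [Hypervolume-class] objects on the same trait space
#' @return overlap in `[0, 1]`; symmetric in its arguments
#' @export
kdeEvenness <- function(hv1, hv2) {
  stopifnot(is(hv1, "Hypervolume"), is(hv2, "Hypervolume"))
  if (hv1@dims != hv2@dims)
    stop("hypervolumes have different dimensionality")
  fracIn <- function(a, b) {
    if (!nrow(a@supportPoints)) return(0)
    mean(.kdeDensity(b@centers, b@weights, b@bandwidth,
                     a@supportPoints) >= b@threshold)
  }
  inter <- (fracIn(hv1, hv2) * hv1@volume + fracIn(hv2, hv1) * hv2@volume) / 2
  uni <- hv1@volume + hv2@volume - inter
  if (uni <= 0) return(NA_real_)
  max(0, min(1, inter / uni))
}

#' KDE dispersion: mean distance of random points to the centroid
#'
#' Average Euclidean distance between the hypervolume's retained random
#' points and their centroid.
#'
#' @param hv a [Hypervolume-class]
#' @return dispersion `>= 0`
#' @export
kdeDispersion <- function(hv) {
  stopifnot(is(hv, "Hypervolume"))
  pts <- hv@supportPoints
  if (!nrow(pts)) return(NA_real_)
  centroid <- colMeans(pts)
  mean(sqrt(rowSums(sweep(pts, 2, centroid)^2)))
}

#' All three KDE metrics for one community
#'
#' Builds the unweighted and the abundance-weighted hypervolume on the
#' given (z-scored, continuous) coordinates and returns KDE richness
#' (volume of the unweighted hypervolume), KDE evenness (overlap of the
#' weighted and unweighted hypervolumes) and KDE dispersion (of the
#' weighted hypervolume). Returns `NA`s with a message when the community
#' has fewer than 2 species or a zero-variance dimension.
#'
#' @inheritParams buildHypervolume
#' @param abund relative abundances of the species rows
#' @return named numeric: `KDErich`, `KDEeven`, `KDEdisp`
#' @export
communityKDE <- function(coords, abund, mass = 0.95, nSamples = 10000,
                         seed = 1) {
  out <- c(KDErich = NA_real_, KDEeven = NA_real_, KDEdisp = NA_real_)
  coords <- as.matrix(coords)
  tryCatch({
    S <- nrow(coords)
    hvU <- .hvBuild(coords, rep(1 / S, S), mass = mass,
                    nSamples = nSamples, seed = seed)
    hvW <- .hvBuild(coords, abund / sum(abund), mass = mass,
                    nSamples = nSamples, seed = seed)
    c(KDErich = hvU$volume, KDEeven = .hvOverlap(hvW, hvU),
      KDEdisp = .hvDispersion(hvW))
  }, error = function(e) {
    message("KDE metrics undefined: ", conditionMessage(e))
    out
  })
}

#' Serialize a hypervolume summary to a data.frame / CSV
#' @param hv a [Hypervolume-class]
#' @param path optional CSV path
#' @export
hypervolumeSummary <- function(hv, path = NULL) {
  df <- data.frame(dims = hv@dims,
                   bandwidth = paste(signif(hv@bandwidth, 6), collapse = ";"),
                   threshold = hv@threshold, mass = hv@mass,
                   volume = hv@volume, nSamples = hv@nSamples,
                   seed = hv@seed, weighted = hv@weighted)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
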