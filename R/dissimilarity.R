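# Gower and Euclidean species dissimilarities and principal coordinates.

newDistanceMatrix <- function(d, method) {
  d <- (d + t(d)) / 2          # kill rounding asymmetry
  diag(d) <- 0
  if (method == "gower") d[d > 1] <- 1
  new("DistanceMatrix", d = d, method = method)
}

#' Gower dissimilarity on a trait subset
#'
#' Per-trait contribution is `|x_i - x_j| / range` for continuous traits
#' (range taken globally over all species in the table, so distances are
#' comparable across plots) and 0/1 match/mismatch for categorical traits;
#' the distance is the unweighted mean over the subset. A continuous trait
#' with zero range contributes 0 with a warning. All species must be
#' complete on the subset (apply [filterTraitCoverage()] first).
#'
#' @param traits species-mean [TraitTable-class]
#' @param subset character vector of trait ids (defaults to all traits)
#' @return a [DistanceMatrix-class] with entries in `[0, 1]`
#' @export
gowerDistance <- function(traits, subset = traitIds(traits)) {
  stopifnot(is(traits, "TraitTable"))
  v <- traits@values[, subset, drop = FALSE]
  if (any(!stats::complete.cases(v)))
    stop("species with missing trait values in subset; filter coverage first: ",
         paste(utils::head(rownames(v)[!stats::complete.cases(v)], 5),
               collapse = ", "))
  kind <- traits@traitKind[subset]
  n <- nrow(v)
  acc <- matrix(0, n, n)
  for (tr in subset) {
    if (kind[[tr]] == "continuous") {
      x <- v[[tr]]
      rng <- max(x) - min(x)
      if (rng == 0) {
        warning(sprintf("trait '%s' has zero range; contributes 0 to Gower", tr))
        next
      }
      acc <- acc + abs(outer(x, x, "-")) / rng
    } else {
      x <- v[[tr]]
      acc <- acc + (outer(x, x, "!=") * 1)
    }
  }
  d <- acc / length(subset)
  dimnames(d) <- list(rownames(v), rownames(v))
  newDistanceMatrix(d, "gower")
}

#' Euclidean dissimilarity on continuous traits
#'
#' Standard Euclidean distance on the trait columns, by default z-scored
#' per trait first (traits carry incommensurate units). Errors on
#' categorical traits, which should go through [gowerDistance()].
#'
#' @param traits species-mean [TraitTable-class]
#' @param subset character vector of continuous trait ids
#' @param standardize z-score each trait column first (default TRUE)
#' @return a [DistanceMatrix-class]
#' @export
euclideanDistance <- function(traits, subset = traitIds(traits),
                              standardize = TRUE) {
  stopifnot(is(traits, "TraitTable"))
  kind <- traits@traitKind[subset]
  if (any(kind == "categorical"))
    stop("subset contains categorical trait(s): ",
         paste(subset[kind == "categorical"], collapse = ", "),
         "; use gowerDistance() for mixed traits")
  v <- as.matrix(traits@values[, subset, drop = FALSE])
  if (any(!stats::complete.cases(v)))
    stop("species with missing trait values in subset; filter coverage first")
  if (standardize) {
    sds <- apply(v, 2, stats::sd)
    zero <- sds == 0 | is.na(sds)
    if (any(zero)) {
      warning("zero-variance trait(s) left unscaled: ",
              paste(subset[zero], collapse = ", "))
      sds[zero] <- 1
    }
    v <- scale(v, center = TRUE, scale = sds)
  }
  d <- as.matrix(stats::dist(v))
  dimnames(d) <- list(rownames(traits@values), rownames(traits@values))
  newDistanceMatrix(d, "euclidean")
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Eigendecomposition of the double-centred Gram matrix
#' `-1/2 J D^2 J`; coordinates are eigenvectors scaled by the square root
#' of their eigenvalues. Axes with eigenvalues at or below numerical zero
#' are dropped before truncation to `nAxes`; negative eigenvalues (possible
#' under Gower) are dropped without a Cailliez/Lingoes correction and their
#' total magnitude is recorded in the result so distortion can be judged.
#'
#' @param d a [DistanceMatrix-class]
#' @param nAxes number of axes to keep (default: all positive axes)
#' @return an [OrdinationResult-class]
#' @export
pcoa <- function(d, nAxes = NULL) {
  stopifnot(is(d, "DistanceMatrix"))
  dm <- d@d
  n <- nrow(dm)
  sp <- rownames(dm)
  if (n == 1) {
    return(new("OrdinationResult",
               coordinates = matrix(0, 1, 1, dimnames = list(sp, "Axis1")),
               eigenvalues = numeric(0), axesRetained = 1L,
               negativeInertia = 0))
  }
  A <- -0.5 * dm^2
  G <- A - rowMeans(A) - rep(colMeans(A), each = n) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values), 1e-300) * 1e-9
  pos <- which(e$values > tol)
  negInertia <- sum(abs(e$values[e$values < -tol]))
  if (negInertia > tol)
    message(sprintf("pcoa: dropped %d negative eigenvalue(s), total inertia %.4g",
                    sum(e$values < -tol), negInertia))
  if (!length(pos)) {
    # fully degenerate (all species coincident): one all-zero axis
    return(new("OrdinationResult",
               coordinates = matrix(0, n, 1, dimnames = list(sp, "Axis1")),
               eigenvalues = e$values, axesRetained = 1L,
               negativeInertia = negInertia))
  }
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  if (!is.null(nAxes)) {
    if (nAxes > length(pos))
      warning(sprintf("only %d positive axes available (requested %d)",
                      length(pos), nAxes))
    coords <- coords[, seq_len(min(nAxes, length(pos))), drop = FALSE]
  }
  dimnames(coords) <- list(sp, paste0("Axis", seq_len(ncol(coords))))
  new("OrdinationResult", coordinates = coords, eigenvalues = e$values,
      axesRetained = ncol(coords), negativeInertia = negInertia)
}

#' Write / read a DistanceMatrix as a square CSV
#'
#' Species ids form both the header row and the first column.
#' @param d a [DistanceMatrix-class]
#' @param path CSV path
#' @export
writeDistanceMatrix <- function(d, path) {
  utils::write.csv(as.data.frame(d@d), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @param method distance method label to stamp on the read matrix
#' @export
readDistanceMatrix <- function(path, method = "gower") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  newDistanceMatrix(as.matrix(df), method)
}
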