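# Exhaustive trait-subset sweep: every metric on every plot for every
# subset and distance type, plus trait-correlation summaries.

#' Enumerate trait subsets
#'
#' All unordered subsets of sizes `kMin` to `kMax`, in deterministic
#' lexicographic order (trait ids sorted within and across subsets). For a
#' 10-trait site this yields 45 two-trait, 120 three-trait, 210 four-trait,
#' ... subsets.
#'
#' @param traitIds character vector of trait ids
#' @param kMin,kMax subset size range, `2 <= kMin <= kMax <= length(traitIds)`
#' @return list of sorted character vectors
#' @examples
#' length(enumerateSubsets(letters[1:10], 2, 2))   # 45 trait pairs
#' enumerateSubsets(c("SLA", "height", "leafN"), 2, 3)
#' @export
enumerateSubsets <- function(traitIds, kMin = 2, kMax = length(traitIds)) {
  n <- length(traitIds)
  if (kMax > n) stop("kMax exceeds the number of traits")
  if (kMin < 2 || kMin > kMax) stop("need 2 <= kMin <= kMax")
  ids <- sort(traitIds)
  out <- list()
  for (k in kMin:kMax)
    out <- c(out, utils::combn(ids, k, simplify = FALSE))
  out
}

#' Sweep configuration
#'
#' Collects the knobs a sweep run fixes: distance types, ordination
#' dimensions for functional richness, KDE settings, the trait-coverage
#' threshold and the correlation convention.
#'
#' @param distances distance types to run (`"gower"`, `"euclidean"`)
#' @param frichDims integer vector of ordination dimensionalities for
#'   functional richness (default 2; use e.g. `c(2, 3, 4)` plus the subset
#'   size for a dimensionality sensitivity analysis)
#' @param kdeSamples Monte-Carlo sample size per hypervolume (default 2000)
#' @param kdeMass hypervolume boundary mass (default 0.95)
#' @param kdeSeed seed for every hypervolume build (default 1)
#' @param minRetained abundance-representation threshold (default 0.80)
#' @param standardizeEuclidean z-score traits before Euclidean distances
#' @param absoluteCorrelation summarise absolute Pearson correlations
#' @return a list of class `fdsweep_config`
#' @export
sweepConfig <- function(distances = c("gower", "euclidean"), frichDims = 2,
                        kdeSamples = 2000, kdeMass = 0.95, kdeSeed = 1,
                        minRetained = 0.80, standardizeEuclidean = TRUE,
                        absoluteCorrelation = TRUE) {
  distances <- match.arg(distances, c("gower", "euclidean"),
                         several.ok = TRUE)
  structure(list(distances = distances, frichDims = as.integer(frichDims),
                 kdeSamples = as.integer(kdeSamples), kdeMass = kdeMass,
                 kdeSeed = as.integer(kdeSeed), minRetained = minRetained,
                 standardizeEuclidean = standardizeEuclidean,
                 absoluteCorrelation = absoluteCorrelation),
            class = "fdsweep_config")
}

#' Read a sweep configuration from a YAML key-value file
#' @param path YAML file path
#' @export
readSweepConfig <- function(path) {
  do.call(sweepConfig, yaml::read_yaml(path))
}

.subsetKey <- function(subset) paste(sort(subset), collapse = ";")

# Vectorised per-plot metrics for one subset x distance. W is the filtered
# plot-by-species relative abundance matrix; D the species distances;
# coords the positive PCoA axes.
.classicBlock <- function(W, D, coords, frichDims) {
  P <- nrow(W)
  S <- ncol(W)
  pres <- W > 0
  nPres <- rowSums(pres)
  # Rao's Q: p' D p / 2 per plot
  rao <- rowSums((W %*% D) * W) / 2
  # FDis: abundance-weighted centroid distances
  G <- rowSums(coords^2)
  Cw <- W %*% coords
  Z2 <- outer(rowSums(Cw^2), rep(1, S)) + outer(rep(1, P), G) -
    2 * tcrossprod(Cw, coords)
  Z2[Z2 < 0] <- 0
  Zw <- sqrt(Z2)
  fdis <- rowSums(W * Zw)
  fdis[nPres == 1] <- 0
  # FDiv: unweighted present-species centroid (distance-only mode)
  Cm <- (pres %*% coords) / nPres
  Z2m <- outer(rowSums(Cm^2), rep(1, S)) + outer(rep(1, P), G) -
    2 * tcrossprod(Cm, coords)
  Z2m[Z2m < 0] <- 0
  Zm <- sqrt(Z2m)
  dG <- rowSums(Zm * pres) / nPres
  dev <- Zm - dG
  deltaD <- rowSums(W * dev * pres)
  deltaAbs <- rowSums(W * abs(dev) * pres)
  fdiv <- (deltaD + dG) / (deltaAbs + dG)
  fdiv[nPres < 3 | (dG == 0 & deltaAbs == 0)] <- NA_real_
  # FEve: per-plot MST over present species (lean kernel, no S4)
  feve <- rep(NA_real_, P)
  for (p in seq_len(P)) {
    S_p <- nPres[p]
    if (S_p < 3) next
    idx <- which(pres[p, ])
    br <- .kruskal(D[idx, idx, drop = FALSE])
    w <- W[p, idx] / sum(W[p, idx])
    ew <- br[, 3] / (w[br[, 1]] + w[br[, 2]])
    if (sum(ew) == 0) next
    pew <- ew / sum(ew)
    thr <- 1 / (S_p - 1)
    feve[p] <- (sum(pmin(pew, thr)) - thr) / (1 - thr)
  }
  # FRich per requested dimensionality (undefined when the ordination has
  # fewer positive axes than requested)
  frich <- matrix(NA_real_, P, length(frichDims))
  for (di in seq_along(frichDims)) {
    dd <- frichDims[di]
    if (dd > ncol(coords)) next
    for (p in seq_len(P)) {
      if (nPres[p] < dd + 1) next
      X <- coords[pres[p, ], seq_len(dd), drop = FALSE]
      frich[p, di] <- .hullVolume(X)
    }
  }
  list(rao = rao, fdis = fdis, fdiv = fdiv, feve = feve, frich = frich,
       frichDims = frichDims)
}

#' Run the full metric sweep
#'
#' For every trait subset: applies the trait-coverage and
#' abundance-representation filter, computes Gower (and, for all-continuous
#' subsets, Euclidean) species distances and their principal coordinates,
#' and evaluates all eight metrics for every plot. Plots failing the
#' abundance rule for a subset carry explicit missing values for that
#' subset, as do per-cell computation failures; the sweep itself never
#' aborts. KDE metrics work in z-scored Euclidean trait space on the
#' continuous traits of the subset and are emitted once per subset under
#' the `"euclidean"` distance label. Deterministic given the config.
#'
#' @param comm a [CommunityMatrix-class] of raw abundances
#' @param traits a species-mean [TraitTable-class]
#' @param subsets list of trait-id vectors (see [enumerateSubsets()])
#' @param config a [sweepConfig()] list
#' @return long-format data.frame: `study`, `plot`, `metric`, `distance`,
#'   `subset` (";"-joined sorted trait ids), `k`, `dims`, `value`
#' @export
runSweep <- function(comm, traits, subsets, config = sweepConfig()) {
  stopifnot(is(comm, "CommunityMatrix"), is(traits, "TraitTable"))
  allPlots <- plotIds(comm)
  studies <- studyIds(comm)
  kinds <- traitKind(traits)
  blocks <- vector("list", length(subsets))
  for (si in seq_along(subsets)) {
    subset <- sort(subsets[[si]])
    key <- .subsetKey(subset)
    k <- length(subset)
    rows <- list()
    addRows <- function(metric, distance, plots, values, dims = NA_integer_) {
      rows[[length(rows) + 1]] <<- data.frame(
        study = unname(studies[plots]), plot = plots, metric = metric,
        distance = distance, subset = key, k = k,
        dims = rep(dims, length.out = length(plots)), value = values,
        stringsAsFactors = FALSE)
    }
    filt <- tryCatch(
      suppressMessages(filterTraitCoverage(comm, traits, subset,
                                           config$minRetained)),
      error = function(e) NULL)
    keptPlots <- if (is.null(filt)) character(0) else plotIds(filt$community)
    lostPlots <- setdiff(allPlots, keptPlots)
    hasCat <- any(kinds[subset] == "categorical")
    contSub <- subset[kinds[subset] == "continuous"]
    W <- if (length(keptPlots)) filt$community@abundance else NULL
    keptSpecies <- if (is.null(W)) character(0) else colnames(W)
    subTraits <- if (length(keptSpecies))
      traitTable(traits@values[keptSpecies, subset, drop = FALSE],
                 kinds[subset]) else NULL
    for (distance in config$distances) {
      classic <- NULL
      if (!is.null(W) && nrow(W) && ncol(W) >= 2 &&
          !(distance == "euclidean" && hasCat)) {
        classic <- tryCatch({
          D <- if (distance == "gower")
            suppressWarnings(gowerDistance(subTraits, subset))
          else suppressWarnings(
            euclideanDistance(subTraits, subset,
                              standardize = config$standardizeEuclidean))
          ordn <- suppressMessages(pcoa(D))
          .classicBlock(W, D@d, ordn@coordinates, config$frichDims)
        }, error = function(e) {
          message(sprintf("subset %s (%s): %s", key, distance,
                          conditionMessage(e)))
          NULL
        })
      }
      if (is.null(classic)) {
        for (m in c("FEve", "FDis", "FDiv", "RaoQ"))
          addRows(m, distance, allPlots, NA_real_)
        for (dd in config$frichDims)
          addRows("FRich", distance, allPlots, NA_real_, dd)
      } else {
        pad <- function(v) {
          out <- stats::setNames(rep(NA_real_, length(allPlots)), allPlots)
          out[keptPlots] <- v
          unname(out)
        }
        addRows("FEve", distance, allPlots, pad(classic$feve))
        addRows("FDis", distance, allPlots, pad(classic$fdis))
        addRows("FDiv", distance, allPlots, pad(classic$fdiv))
        addRows("RaoQ", distance, allPlots, pad(classic$rao))
        for (di in seq_along(config$frichDims))
          addRows("FRich", distance, allPlots, pad(classic$frich[, di]),
                  classic$frichDims[di])
      }
    }
    # KDE metrics: continuous traits only, z-scored over the retained pool
    kde <- matrix(NA_real_, length(allPlots), 3,
                  dimnames = list(allPlots, c("KDErich", "KDEeven", "KDEdisp")))
    if (!is.null(W) && length(contSub) >= 1 && ncol(W) >= 2) {
      V <- as.matrix(traits@values[keptSpecies, contSub, drop = FALSE])
      sds <- apply(V, 2, stats::sd)
      ok <- sds > 0
      if (any(ok)) {
        V <- scale(V[, ok, drop = FALSE])
        for (p in keptPlots) {
          w <- W[p, ]
          idx <- which(w > 0)
          if (length(idx) < 2) next
          kde[p, ] <- suppressMessages(
            communityKDE(V[idx, , drop = FALSE], w[idx] / sum(w[idx]),
                         mass = config$kdeMass,
                         nSamples = config$kdeSamples,
                         seed = config$kdeSeed))
        }
      }
    }
    for (m in colnames(kde))
      addRows(m, "euclidean", allPlots, unname(kde[, m]))
    blocks[[si]] <- data.table::rbindlist(rows)
  }
  out <- as.data.frame(data.table::rbindlist(blocks))
  out$dims <- as.integer(out$dims)
  out
}

#' Pearson correlation summary of a trait subset
#'
#' Pairwise Pearson correlations over species-mean values of the subset's
#' (continuous) traits, summarised as the minimum, maximum and mean. By
#' default correlations enter as absolute values (correlation strength).
#'
#' @param traits a species-mean [TraitTable-class]
#' @param subset continuous trait ids (the 4-trait analysis uses `k = 4`)
#' @param absolute summarise `|r|` rather than signed `r` (default TRUE)
#' @return one-row data.frame: `subset`, `k`, `min_corr`, `max_corr`,
#'   `mean_corr`
#' @export
correlationSummary <- function(traits, subset, absolute = TRUE) {
  stopifnot(is(traits, "TraitTable"))
  kinds <- traitKind(traits)[subset]
  if (any(kinds == "categorical"))
    stop("correlation summary requires continuous traits only")
  v <- as.matrix(traits@values[, subset, drop = FALSE])
  v <- v[stats::complete.cases(v), , drop = FALSE]
  if (nrow(v) < 3) stop("need at least 3 complete species")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait(s): correlation undefined: ",
         paste(subset[sds == 0], collapse = ", "))
  cm <- stats::cor(v)
  r <- cm[upper.tri(cm)]
  if (absolute) r <- abs(r)
  data.frame(subset = .subsetKey(subset), k = length(subset),
             min_corr = min(r), max_corr = max(r), mean_corr = mean(r),
             stringsAsFactors = FALSE)
}

#' Correlation summaries for all qualifying subsets
#'
#' Applies [correlationSummary()] to every subset of size `k` composed of
#' continuous traits only (subsets containing categorical traits are
#' excluded, Pearson correlation being undefined on unordered categories).
#'
#' @inheritParams correlationSummary
#' @param subsets list of trait-id vectors
#' @param k subset size to keep (default 4, the between-site standard)
#' @return data.frame, one row per qualifying subset
#' @export
correlationTable <- function(traits, subsets, k = 4, absolute = TRUE) {
  kinds <- traitKind(traits)
  keep <- Filter(function(s) length(s) == k &&
                   all(kinds[s] == "continuous"), subsets)
  if (!length(keep)) stop("no all-continuous subsets of size ", k)
  do.call(rbind, lapply(keep, function(s)
    correlationSummary(traits, s, absolute = absolute)))
}

#' Write / read a sweep table as CSV
#' @param sweep data.frame from [runSweep()]
#' @param path CSV path
#' @export
writeSweepTable <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSweepTable
#' @export
readSweepTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
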