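#' @import methods
NULL

TRAIT_KINDS <- c("continuous", "categorical")

METRIC_NAMES <- c("FRich", "FEve", "FDis", "FDiv", "RaoQ",
                  "KDErich", "KDEeven", "KDEdisp")

#' Species-mean trait table
#'
#' Holds one value per (species, trait): the species-mean for continuous
#' traits and the single level for categorical traits. Rows are species,
#' columns are traits; missing combinations are `NA`. The central trait
#' container consumed by the dissimilarity, metric and sweep machinery.
#'
#' @slot values data.frame of trait values, species ids as rownames;
#'   continuous traits are numeric columns, categorical traits character.
#' @slot traitKind named character vector, one of `"continuous"` or
#'   `"categorical"` per trait column.
#'
#' @seealso [speciesMeanTraits()], [traitTable()]
#' @export
setClass("TraitTable",
  slots = c(values = "data.frame", traitKind = "character"))

setValidity("TraitTable", function(object) {
  v <- object@values
  kind <- object@traitKind
  if (!identical(sort(names(kind)), sort(colnames(v))))
    return("traitKind must name exactly the trait columns")
  if (!all(kind %in% TRAIT_KINDS))
    return(sprintf("trait kinds must be one of: %s",
                   paste(TRAIT_KINDS, collapse = ", ")))
  for (tr in names(kind)) {
    col <- v[[tr]]
    if (kind[[tr]] == "continuous") {
      if (!is.numeric(col))
        return(sprintf("continuous trait '%s' must be numeric", tr))
      if (any(!is.finite(col) & !is.na(col)))
        return(sprintf("continuous trait '%s' has non-finite values", tr))
    }
  }
  if (anyDuplicated(rownames(v)))
    return("duplicated species ids")
  TRUE
})

#' Plot-by-species community matrix
#'
#' Abundances (percent cover or relative abundance) for each plot and
#' species, with a study label per plot. Raw (unnormalised) abundances are
#' retained on read; normalisation to relative abundance happens after
#' trait-coverage filtering, per trait subset.
#'
#' @slot abundance numeric matrix, plots in rows, species in columns,
#'   entries `>= 0`.
#' @slot study named character vector mapping plot id to study id.
#'
#' @seealso [readCommunity()], [filterTraitCoverage()]
#' @export
setClass("CommunityMatrix",
  slots = c(abundance = "matrix", study = "character"))

setValidity("CommunityMatrix", function(object) {
  a <- object@abundance
  if (!is.numeric(a)) return("abundance matrix must be numeric")
  if (length(a) && any(a < 0)) return("abundances must be non-negative")
  if (nrow(a) > 0 && is.null(rownames(a)))
    return("abundance matrix needs plot rownames")
  if (ncol(a) > 0 && is.null(colnames(a)))
    return("abundance matrix needs species colnames")
  if (length(object@study) != nrow(a) ||
      !setequal(names(object@study), rownames(a)))
    return("study labels must name exactly the plots")
  TRUE
})

#' Report of trait-coverage filtering
#'
#' Records which species were dropped for lacking complete coverage of a
#' trait subset, the fraction of raw abundance each plot retains after the
#' drop, and the plots flagged (and excluded) for retaining less than the
#' required fraction of community abundance.
#'
#' @slot subset character vector of trait ids the filter was applied for.
#' @slot speciesDropped character vector of dropped species ids.
#' @slot retainedFraction named numeric in `[0, 1]`, per original plot.
#' @slot plotsFlagged plots whose retained fraction fell below the threshold.
#' @slot plotsDropped plots excluded from analysis (flagged plots plus plots
#'   left with no species).
#' @slot threshold the minimum retained-abundance fraction applied.
#' @export
setClass("FilterReport",
  slots = c(subset = "character", speciesDropped = "character",
            retainedFraction = "numeric", plotsFlagged = "character",
            plotsDropped = "character", threshold = "numeric"))

setValidity("FilterReport", function(object) {
  f <- object@retainedFraction
  if (length(f) && (any(f < -1e-12) || any(f > 1 + 1e-12)))
    return("retained fractions must lie in [0, 1]")
  TRUE
})

#' Pairwise species dissimilarity matrix
#'
#' Symmetric matrix of non-negative species-species dissimilarities with a
#' zero diagonal. Gower entries are bounded in `[0, 1]`.
#'
#' @slot d symmetric numeric matrix with species ids as dimnames.
#' @slot method `"gower"` or `"euclidean"`.
#' @seealso [gowerDistance()], [euclideanDistance()], [pcoa()]
#' @export
setClass("DistanceMatrix", slots = c(d = "matrix", method = "character"))

setValidity("DistanceMatrix", function(object) {
  d <- object@d
  if (nrow(d) != ncol(d)) return("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-12) return("distance matrix must be symmetric")
  if (any(diag(d) != 0)) return("diagonal must be exactly zero")
  if (any(d < 0)) return("distances must be non-negative")
  if (object@method == "gower" && any(d > 1 + 1e-12))
    return("Gower distances must lie in [0, 1]")
  if (is.null(rownames(d))) return("species ids required as dimnames")
  TRUE
})

#' Principal coordinates of a dissimilarity matrix
#'
#' Coordinates from the eigendecomposition of the double-centred Gram
#' matrix, scaled by the square root of their eigenvalues. Axes with
#' non-positive eigenvalues are dropped; the magnitude of dropped negative
#' inertia (possible under Gower) is recorded so distortion can be judged.
#'
#' @slot coordinates species-by-axis numeric matrix.
#' @slot eigenvalues all eigenvalues, descending.
#' @slot axesRetained number of positive axes kept.
#' @slot negativeInertia sum of absolute negative eigenvalues dropped.
#' @seealso [pcoa()]
#' @export
setClass("OrdinationResult",
  slots = c(coordinates = "matrix", eigenvalues = "numeric",
            axesRetained = "integer", negativeInertia = "numeric"))

setValidity("OrdinationResult", function(object) {
  if (object@axesRetained > max(1L, nrow(object@coordinates) - 1L))
    return("axis count must not exceed species - 1")
  TRUE
})

#' Minimum spanning tree over species in trait space
#'
#' @slot branches numeric matrix with columns `i`, `j`, `length`; `S - 1`
#'   rows connecting all `S` species, acyclic, total length minimal.
#' @slot species character vector of species ids indexed by `i`, `j`.
#' @seealso [minimumSpanningTree()], [functionalEvenness()]
#' @export
setClass("SpanningTree", slots = c(branches = "matrix", species = "character"))

setValidity("SpanningTree", function(object) {
  s <- length(object@species)
  if (s >= 2 && nrow(object@branches) != s - 1)
    return("a spanning tree over S species has S - 1 branches")
  TRUE
})

#' Gaussian kernel-density hypervolume
#'
#' A kernel-density occupancy model of trait space: Gaussian kernels with a
#' per-dimension bandwidth placed at species coordinates (optionally
#' abundance-weighted), a boundary at the density quantile enclosing a
#' configured probability mass, and a Monte-Carlo volume estimate.
#'
#' @slot dims number of trait dimensions.
#' @slot centers species coordinates the kernels sit on.
#' @slot weights kernel mixture weights (sum to 1).
#' @slot bandwidth per-dimension positive bandwidths (Silverman rule).
#' @slot threshold density value bounding the hypervolume.
#' @slot mass probability mass the boundary encloses.
#' @slot supportPoints retained random points (density `>=` threshold).
#' @slot supportDensity kernel density at the support points.
#' @slot volume Monte-Carlo volume of the bounded region.
#' @slot nSamples Monte-Carlo sample size used.
#' @slot seed RNG seed the build used (deterministic contract).
#' @slot weighted whether non-uniform weights were supplied.
#' @seealso [buildHypervolume()], [kdeRichness()], [kdeEvenness()],
#'   [kdeDispersion()]
#' @export
setClass("Hypervolume",
  slots = c(dims = "integer", centers = "matrix", weights = "numeric",
            bandwidth = "numeric", threshold = "numeric", mass = "numeric",
            supportPoints = "matrix", supportDensity = "numeric",
            volume = "numeric", nSamples = "integer", seed = "integer",
            weighted = "logical"))

setValidity("Hypervolume", function(object) {
  if (any(object@bandwidth <= 0)) return("bandwidths must be positive")
  if (object@volume < 0) return("volume must be non-negative")
  if (length(object@supportDensity) &&
      any(object@supportDensity < object@threshold * (1 - 1e-9)))
    return("support points must have density >= threshold")
  TRUE
})

#' Parameters of a synthetic grassland study
#'
#' Generator knobs for one study-like dataset: species pool size, plot
#' count, numbers of continuous and categorical traits, the target trait
#' correlation matrix, the within-plot abundance model, richness range,
#' missingness pressure on rare species, and the seed.
#'
#' @slot studyId study label stamped on generated plots.
#' @slot nSpecies species pool size.
#' @slot nPlots number of plots.
#' @slot nTraitsContinuous number of continuous traits.
#' @slot nTraitsCategorical number of categorical traits.
#' @slot categoricalLevels list of level vectors, one per categorical trait.
#' @slot correlation positive semi-definite target correlation matrix for
#'   the latent Gaussian behind the continuous traits (unit diagonal).
#' @slot abundanceModel list: `type` `"lognormal"` (fields `meanlog`,
#'   `sdlog`) or `"geometric"` (field `ratio`).
#' @slot richnessRange integer pair: min and max species per plot.
#' @slot missingness probability scale for trait missingness; applied
#'   preferentially to rare species.
#' @slot seed integer RNG seed.
#' @seealso [syntheticStudySpec()], [generateTraits()],
#'   [generateCommunities()], [makeBenchmarkSuite()]
#' @export
setClass("SyntheticStudySpec",
  slots = c(studyId = "character", nSpecies = "integer", nPlots = "integer",
            nTraitsContinuous = "integer", nTraitsCategorical = "integer",
            categoricalLevels = "list", correlation = "matrix",
            abundanceModel = "list", richnessRange = "integer",
            missingness = "numeric", seed = "integer"))

setValidity("SyntheticStudySpec", function(object) {
  cm <- object@correlation
  p <- object@nTraitsContinuous
  if (nrow(cm) != p || ncol(cm) != p)
    return("correlation matrix must be nTraitsContinuous x nTraitsContinuous")
  if (max(abs(cm - t(cm))) > 1e-10 || max(abs(diag(cm) - 1)) > 1e-10)
    return("correlation matrix must be symmetric with unit diagonal")
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    return(paste("correlation target is not positive semi-definite;",
                 "consider projecting with Matrix::nearPD()"))
  if (object@missingness < 0 || object@missingness > 1)
    return("missingness must be a probability")
  if (length(object@categoricalLevels) != object@nTraitsCategorical)
    return("one level set per categorical trait required")
  rr <- object@richnessRange
  if (length(rr) != 2 || rr[1] < 1 || rr[2] > object@nSpecies || rr[1] > rr[2])
    return("richnessRange must be within [1, nSpecies]")
  TRUE
})

#' Polynomial mixed-model fits for one metric-predictor test
#'
#' All candidate polynomial fits (degrees 1-4) of a functional diversity
#' metric against a predictor, with a per-plot random intercept where the
#' data contain more than one plot, plus the AIC-selected fit and a
#' likelihood-ratio p-value against the intercept-only model.
#'
#' @slot response metric name.
#' @slot predictor `"k"`, `"min_corr"`, `"max_corr"` or `"mean_corr"`.
#' @slot fits list of fitted model objects, named by degree.
#' @slot table data.frame: degree, nPar, logLik, AIC, converged.
#' @slot selectedDegree degree of the minimum-AIC fit (ties to lower degree).
#' @slot coefficients coefficient table of the selected fit (estimate,
#'   std. error, p value).
#' @slot randomInterceptVariance plot random-intercept variance (NA for the
#'   ordinary-least-squares fallback).
#' @slot pValue likelihood-ratio p-value of the selected fit vs intercept-only.
#' @slot nObs number of observations used.
#' @export
setClass("ModelFitSet",
  slots = c(response = "character", predictor = "character", fits = "list",
            table = "data.frame", selectedDegree = "integer",
            coefficients = "data.frame", randomInterceptVariance = "numeric",
            pValue = "numeric", nObs = "integer"))
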