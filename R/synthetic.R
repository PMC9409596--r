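# Synthetic grassland data generator: community and trait tables with the
# statistical structure the analysis assumes (correlated trait blocks,
# skewed abundances, missingness concentrated on rare species), standing in
# for site data that are described but not packaged.

#' Block-structured trait correlation target
#'
#' A unit-diagonal correlation matrix with one strongly correlated block of
#' leading traits (a "leaf-economics-like" suite) over a weak background
#' correlation. Positive semi-definiteness is checked at construction of
#' the study spec.
#'
#' @param nTraits number of continuous traits
#' @param blockSize size of the correlated leading block (default 4)
#' @param rho within-block correlation (default 0.7)
#' @param background correlation outside the block (default 0.05)
#' @return correlation matrix
#' @export
traitCorrelationTarget <- function(nTraits, blockSize = 4, rho = 0.7,
                                   background = 0.05) {
  cm <- matrix(background, nTraits, nTraits)
  b <- min(blockSize, nTraits)
  cm[seq_len(b), seq_len(b)] <- rho
  diag(cm) <- 1
  cm
}

#' Construct a synthetic study specification
#'
#' @param studyId study label
#' @param nSpecies species pool size
#' @param nPlots number of plots
#' @param nTraitsContinuous number of continuous traits
#' @param nTraitsCategorical number of categorical traits (default 0)
#' @param categoricalLevels list of level vectors, one per categorical
#'   trait (defaults to a C3/C4 photosynthetic pathway and a growth form)
#' @param correlation target correlation matrix for the latent Gaussian
#'   (default: [traitCorrelationTarget()])
#' @param abundanceModel `list(type = "lognormal", meanlog, sdlog)` or
#'   `list(type = "geometric", ratio)`
#' @param richnessRange min and max species per plot
#' @param missingness missingness pressure on rare species (mean per-cell
#'   missingness probability; the rarest species get about twice this)
#' @param seed RNG seed
#' @return a [SyntheticStudySpec-class]
#' @export
syntheticStudySpec <- function(studyId, nSpecies, nPlots, nTraitsContinuous,
                               nTraitsCategorical = 0,
                               categoricalLevels = NULL,
                               correlation = traitCorrelationTarget(nTraitsContinuous),
                               abundanceModel = list(type = "lognormal",
                                                     meanlog = 0, sdlog = 1),
                               richnessRange = c(2, nSpecies),
                               missingness = 0.1, seed = 1) {
  if (is.null(categoricalLevels))
    categoricalLevels <- list(c("C3", "C4"),
                              c("grass", "forb", "shrub"))[
                                seq_len(nTraitsCategorical)]
  ev <- eigen((correlation + t(correlation)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation target is not positive semi-definite; project it ",
         "first, e.g. as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)")
  new("SyntheticStudySpec", studyId = studyId,
      nSpecies = as.integer(nSpecies), nPlots = as.integer(nPlots),
      nTraitsContinuous = as.integer(nTraitsContinuous),
      nTraitsCategorical = as.integer(nTraitsCategorical),
      categoricalLevels = categoricalLevels, correlation = correlation,
      abundanceModel = abundanceModel,
      richnessRange = as.integer(richnessRange),
      missingness = missingness, seed = as.integer(seed))
}

.speciesNames <- function(n) sprintf("sp%03d", seq_len(n))

# Latent species commonness scores, shared by the trait and community
# generators so missingness can concentrate on the species that are rare
# in the plots.
.commonness <- function(spec) {
  withLocalSeed(spec@seed, stats::rlnorm(spec@nSpecies, 0, 1))
}

#' Generate a species-mean trait table
#'
#' Continuous traits arise from a Gaussian copula: a multivariate normal
#' with the target correlation, pushed through mild monotone marginal
#' transforms (lognormal for size-like traits, logit-normal in (0, 1) for
#' every third trait, emulating fraction-type traits). The transforms are
#' kept mild so Pearson correlations of the emitted values track the latent
#' targets. Categorical traits are multinomial, independent of the
#' continuous block. Missing values are assigned preferentially to rare
#' species (rarest about twice the nominal rate, commonest near zero).
#' Deterministic given the spec seed.
#'
#' @param spec a [SyntheticStudySpec-class]
#' @return a [TraitTable-class]
#' @export
generateTraits <- function(spec) {
  stopifnot(is(spec, "SyntheticStudySpec"))
  n <- spec@nSpecies
  p <- spec@nTraitsContinuous
  commonness <- .commonness(spec)
  withLocalSeed(spec@seed + 1L, {
    Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = spec@correlation)
    if (n == 1) Z <- matrix(Z, 1, p)
    vals <- as.data.frame(matrix(NA_real_, n, p))
    names(vals) <- sprintf("trait%02d", seq_len(p))
    for (j in seq_len(p)) {
      vals[[j]] <- if (j %% 3 == 0) stats::plogis(0.6 * Z[, j])
      else exp(log(5 * j) + 0.25 * Z[, j])
    }
    kind <- stats::setNames(rep("continuous", p), names(vals))
    if (spec@nTraitsCategorical > 0) {
      for (cj in seq_len(spec@nTraitsCategorical)) {
        lv <- spec@categoricalLevels[[cj]]
        nm <- sprintf("cat%02d", cj)
        vals[[nm]] <- sample(lv, n, replace = TRUE)
        kind[nm] <- "categorical"
      }
    }
    # missingness concentrated on rare species: linear in rarity rank
    rarity <- rank(-commonness, ties.method = "first")  # 1 = most common
    pMiss <- if (n > 1)
      2 * spec@missingness * (rarity - 1) / (n - 1) else 0
    for (nm in names(vals)) {
      drop <- stats::runif(n) < pMiss
      vals[[nm]][drop] <- NA
    }
    rownames(vals) <- .speciesNames(n)
    traitTable(vals, kind)
  })
}

#' Generate a plot-by-species community matrix
#'
#' Each plot draws its richness uniformly from the configured range,
#' samples that many species from the pool with probability proportional to
#' the latent commonness scores, and assigns abundances from the abundance
#' model: `geometric(ratio)` gives relative abundances proportional to
#' `ratio^(0:(r-1))`, ranked so the most common sampled species dominates;
#' `lognormal(meanlog, sdlog)` draws independent lognormal covers.
#' Abundances are normalised to sum to one per plot. Deterministic given
#' the spec seed.
#'
#' @param spec a [SyntheticStudySpec-class]
#' @return a [CommunityMatrix-class]
#' @export
generateCommunities <- function(spec) {
  stopifnot(is(spec, "SyntheticStudySpec"))
  n <- spec@nSpecies
  commonness <- .commonness(spec)
  rr <- spec@richnessRange
  am <- spec@abundanceModel
  withLocalSeed(spec@seed + 2L, {
    m <- matrix(0, spec@nPlots, n,
                dimnames = list(sprintf("%s_plot%03d", spec@studyId,
                                        seq_len(spec@nPlots)),
                                .speciesNames(n)))
    for (pl in seq_len(spec@nPlots)) {
      r <- rr[1] + sample.int(rr[2] - rr[1] + 1L, 1) - 1L
      sel <- sample.int(n, r, prob = commonness)
      ab <- switch(am$type,
        geometric = {
          a <- am$ratio^(seq_len(r) - 1)
          # most common sampled species gets the largest share
          a[order(order(-commonness[sel]))]
        },
        lognormal = stats::rlnorm(r, am$meanlog, am$sdlog),
        stop("unknown abundance model type: ", am$type))
      m[pl, sel] <- ab / sum(ab)
    }
    communityMatrix(m, spec@studyId)
  })
}

#' Three study-like synthetic datasets for an end-to-end run
#'
#' A bundle emulating the shapes of three grassland studies: a planted
#' 16-species biodiversity experiment (48 plots, 10 continuous traits), a
#' tallgrass watershed survey (60 species, 4 transects, 12 traits of which
#' 2 categorical), and a desert grassland (40 species, 60 quadrats, 10
#' traits of which 1 categorical, strongly dominance-skewed abundances).
#'
#' @param seed integer seed; each study derives its own sub-seed
#' @return named list of studies, each `list(spec, traits, community)`
#' @export
makeBenchmarkSuite <- function(seed = 1) {
  base <- as.integer(seed) * 1000L
  specs <- list(
    biocon = syntheticStudySpec(
      "biocon", nSpecies = 16, nPlots = 48, nTraitsContinuous = 10,
      correlation = traitCorrelationTarget(10),
      abundanceModel = list(type = "lognormal", meanlog = 0, sdlog = 1),
      richnessRange = c(8, 16), missingness = 0.08, seed = base + 1L),
    konza = syntheticStudySpec(
      "konza", nSpecies = 60, nPlots = 4, nTraitsContinuous = 10,
      nTraitsCategorical = 2,
      correlation = traitCorrelationTarget(10),
      abundanceModel = list(type = "lognormal", meanlog = 0, sdlog = 1.2),
      richnessRange = c(25, 40), missingness = 0.12, seed = base + 2L),
    sevilleta = syntheticStudySpec(
      "sevilleta", nSpecies = 40, nPlots = 60, nTraitsContinuous = 9,
      nTraitsCategorical = 1,
      correlation = traitCorrelationTarget(9),
      abundanceModel = list(type = "geometric", ratio = 0.2),
      richnessRange = c(4, 12), missingness = 0.12, seed = base + 3L))
  lapply(specs, function(sp)
    list(spec = sp, traits = generateTraits(sp),
         community = generateCommunities(sp)))
}
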