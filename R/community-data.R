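# Reading, validating and filtering community and trait tables.

#' Construct a species-mean TraitTable
#'
#' @param values data.frame of trait values with species ids as rownames
#'   (continuous traits numeric, categorical character).
#' @param traitKind named character vector, `"continuous"` or
#'   `"categorical"` per column of `values`.
#' @return a [TraitTable-class]
#' @export
traitTable <- function(values, traitKind) {
  values <- as.data.frame(values)
  for (tr in names(traitKind))
    if (traitKind[[tr]] == "categorical")
      values[[tr]] <- as.character(values[[tr]])
  new("TraitTable", values = values, traitKind = traitKind)
}

#' Construct a CommunityMatrix
#'
#' @param abundance plots x species numeric matrix with dimnames.
#' @param study named character vector (plot -> study id), or a single
#'   study id recycled over plots.
#' @return a [CommunityMatrix-class]
#' @export
communityMatrix <- function(abundance, study) {
  if (length(study) == 1 && is.null(names(study)))
    study <- stats::setNames(rep(study, nrow(abundance)), rownames(abundance))
  new("CommunityMatrix", abundance = abundance, study = study)
}

#' Read a community composition table
#'
#' Reads a CSV with header columns `plot`, `study`, `species`, `abundance`
#' (percent cover or any non-negative abundance). Duplicate
#' `(plot, species)` rows are summed; zero-abundance rows are dropped (they
#' carry no weight in any metric); negative abundances are a hard error
#' naming the offending row.
#'
#' @param path path to a CSV file, or a data.frame already in that layout.
#' @return a [CommunityMatrix-class] of raw abundances
#' @export
readCommunity <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot", "study", "species", "abundance")
  if (!all(need %in% names(df)))
    stop("community CSV must have columns: ", paste(need, collapse = ", "))
  ab <- suppressWarnings(as.numeric(df$abundance))
  bad <- which(is.na(ab) & !is.na(df$abundance) |
                 is.na(df$abundance) | ab < 0)
  if (length(bad))
    stop(sprintf("invalid abundance at row %d (plot %s, species %s): '%s'",
                 bad[1], df$plot[bad[1]], df$species[bad[1]],
                 df$abundance[bad[1]]))
  df$abundance <- ab
  # one study per plot
  ps <- unique(df[, c("plot", "study")])
  if (anyDuplicated(ps$plot))
    stop("a plot is assigned to more than one study")
  df <- df[df$abundance > 0, , drop = FALSE]
  agg <- stats::aggregate(abundance ~ plot + species, data = df, FUN = sum)
  plots <- sort(unique(ps$plot))
  species <- sort(unique(agg$species))
  m <- matrix(0, length(plots), length(species),
              dimnames = list(plots, species))
  m[cbind(match(agg$plot, plots), match(agg$species, species))] <- agg$abundance
  communityMatrix(m, stats::setNames(ps$study, ps$plot)[plots])
}

#' Read a long-format trait measurement table
#'
#' CSV layout: `species,trait,value,kind` with one row per
#' (species, trait, replicate measurement); `kind` is `"continuous"` or
#' `"categorical"` and must be consistent within a trait.
#'
#' @param path CSV path or equivalent data.frame.
#' @return data.frame of measurements (not yet averaged)
#' @seealso [speciesMeanTraits()]
#' @export
readTraitMeasurements <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "trait", "value", "kind")
  if (!all(need %in% names(df)))
    stop("trait CSV must have columns: ", paste(need, collapse = ", "))
  if (!all(df$kind %in% TRAIT_KINDS))
    stop("trait kind must be 'continuous' or 'categorical'")
  kinds <- tapply(df$kind, df$trait, function(k) length(unique(k)))
  if (any(kinds > 1))
    stop("trait declared with conflicting kinds: ",
         paste(names(kinds)[kinds > 1], collapse = ", "))
  df
}

#' Average replicate trait measurements into species means
#'
#' One value per (species, trait): the arithmetic mean of all measurements
#' for continuous traits and the single declared level for categorical
#' traits. A categorical trait recorded with conflicting levels within a
#' species is an error; (species, trait) combinations with no measurement
#' remain missing.
#'
#' @param measurements data.frame from [readTraitMeasurements()]
#' @return a [TraitTable-class] of species means
#' @export
speciesMeanTraits <- function(measurements) {
  df <- readTraitMeasurements(measurements)  # revalidates
  species <- sort(unique(df$species))
  traits <- sort(unique(df$trait))
  kind <- stats::setNames(
    vapply(traits, function(tr) df$kind[df$trait == tr][1], ""), traits)
  out <- as.data.frame(
    stats::setNames(lapply(traits, function(tr) {
      if (kind[[tr]] == "continuous") rep(NA_real_, length(species))
      else rep(NA_character_, length(species))
    }), traits), row.names = species, optional = TRUE)
  for (tr in traits) {
    sub <- df[df$trait == tr & !is.na(df$value), , drop = FALSE]
    if (kind[[tr]] == "continuous") {
      val <- suppressWarnings(as.numeric(sub$value))
      if (any(is.na(val)))
        stop(sprintf("non-numeric value for continuous trait '%s'", tr))
      m <- tapply(val, sub$species, mean)
    } else {
      m <- tapply(sub$value, sub$species, function(v) {
        u <- unique(v)
        if (length(u) > 1)
          stop(sprintf("categorical trait '%s' has conflicting levels within a species: %s",
                       tr, paste(u, collapse = ", ")))
        u
      })
    }
    out[names(m), tr] <- unname(m)
  }
  traitTable(out, kind)
}

#' Apply the trait-coverage and abundance-representation rules
#'
#' Species missing any trait of `subset` are removed from all plots (the
#' 100%-trait-coverage rule). Per plot, the fraction of raw abundance
#' retained is recorded; plots retaining less than `minRetained` of their
#' original abundance are flagged and excluded, as are plots left with no
#' species. Remaining plots are renormalised to relative abundances summing
#' to one.
#'
#' @param comm a [CommunityMatrix-class] of raw abundances.
#' @param traits a species-mean [TraitTable-class].
#' @param subset non-empty character vector of trait ids.
#' @param minRetained minimum fraction of community abundance that must be
#'   represented by trait-complete species (default 0.80).
#' @return list with elements `community` (filtered, renormalised
#'   [CommunityMatrix-class]) and `report` ([FilterReport-class])
#' @export
filterTraitCoverage <- function(comm, traits, subset, minRetained = 0.80) {
  stopifnot(is(comm, "CommunityMatrix"), is(traits, "TraitTable"))
  if (!length(subset)) stop("trait subset must be non-empty")
  missingTr <- setdiff(subset, traitIds(traits))
  if (length(missingTr))
    stop("unknown trait(s): ", paste(missingTr, collapse = ", "))
  a <- comm@abundance
  tv <- traits@values[, subset, drop = FALSE]
  complete <- rownames(tv)[stats::complete.cases(tv)]
  # species absent from the trait table have zero coverage by definition
  keep <- intersect(colnames(a), complete)
  dropped <- setdiff(colnames(a), keep)
  total <- rowSums(a)
  kept <- rowSums(a[, keep, drop = FALSE])
  retained <- ifelse(total > 0, kept / total, 0)
  names(retained) <- rownames(a)
  flagged <- rownames(a)[retained < minRetained]
  empty <- rownames(a)[kept <= 0]
  exclude <- union(flagged, empty)
  if (length(empty))
    message("plot(s) left with zero species excluded: ",
            paste(empty, collapse = ", "))
  keepPlots <- setdiff(rownames(a), exclude)
  m <- a[keepPlots, keep, drop = FALSE]
  if (nrow(m)) m <- m / rowSums(m)
  rep <- new("FilterReport", subset = as.character(subset),
             speciesDropped = dropped, retainedFraction = retained,
             plotsFlagged = flagged, plotsDropped = exclude,
             threshold = minRetained)
  list(community = communityMatrix(m, comm@study[keepPlots]), report = rep)
}

#' Serialize a FilterReport to a data.frame / CSV
#' @param report a [FilterReport-class]
#' @param path optional CSV path to write to
#' @return data.frame with one row per original plot
#' @export
filterReportTable <- function(report, path = NULL) {
  df <- data.frame(plot = names(report@retainedFraction),
                   retained_fraction = unname(report@retainedFraction),
                   flagged = names(report@retainedFraction) %in%
                     report@plotsFlagged,
                   excluded = names(report@retainedFraction) %in%
                     report@plotsDropped,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Write a community table to the CSV dialect readCommunity() reads
#' @param comm a [CommunityMatrix-class]
#' @param path output CSV path
#' @export
writeCommunity <- function(comm, path) {
  utils::write.csv(as.data.frame(comm), path, row.names = FALSE)
  invisible(path)
}

#' Write species-mean traits to the long CSV dialect
#' @param traits a [TraitTable-class]
#' @param path output CSV path
#' @export
writeTraits <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE)
  invisible(path)
}
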