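# Accessors and show methods for the core classes.

#' @describeIn TraitTable-class trait ids
#' @param object,x a \code{TraitTable}
#' @export
setGeneric("traitIds", function(object) standardGeneric("traitIds"))

#' @export
setMethod("traitIds", "TraitTable", function(object) colnames(object@values))

#' Species identifiers
#' @param object a TraitTable or CommunityMatrix
#' @export
setGeneric("speciesIds", function(object) standardGeneric("speciesIds"))

#' @export
setMethod("speciesIds", "TraitTable", function(object) rownames(object@values))

#' @export
setMethod("speciesIds", "CommunityMatrix",
          function(object) colnames(object@abundance))

#' Trait kind lookup
#' @param object a TraitTable
#' @return named character vector: "continuous" or "categorical" per trait
#' @export
setGeneric("traitKind", function(object) standardGeneric("traitKind"))

#' @export
setMethod("traitKind", "TraitTable",
          function(object) object@traitKind[colnames(object@values)])

#' Trait values as a data.frame (species as rownames)
#' @param object a TraitTable
#' @export
setGeneric("traitValues", function(object) standardGeneric("traitValues"))

#' @export
setMethod("traitValues", "TraitTable", function(object) object@values)

#' Plot identifiers
#' @param object a CommunityMatrix
#' @export
setGeneric("plotIds", function(object) standardGeneric("plotIds"))

#' @export
setMethod("plotIds", "CommunityMatrix",
          function(object) rownames(object@abundance))

#' Study labels, one per plot
#' @param object a CommunityMatrix
#' @export
setGeneric("studyIds", function(object) standardGeneric("studyIds"))

#' @export
setMethod("studyIds", "CommunityMatrix",
          function(object) object@study[rownames(object@abundance)])

#' Abundance matrix (plots x species)
#' @param object a CommunityMatrix
#' @export
setGeneric("abundanceMatrix", function(object) standardGeneric("abundanceMatrix"))

#' @export
setMethod("abundanceMatrix", "CommunityMatrix",
          function(object) object@abundance)

#' Hypervolume volume
#' @param object a Hypervolume
#' @export
setGeneric("hvVolume", function(object) standardGeneric("hvVolume"))

#' @export
setMethod("hvVolume", "Hypervolume", function(object) object@volume)

#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@d)

#' Coerce a DistanceMatrix to stats::dist
#' @param m a DistanceMatrix
#' @export
asDist <- function(m) {
  stopifnot(is(m, "DistanceMatrix"))
  stats::as.dist(m@d)
}

#' @export
setMethod("as.data.frame", "CommunityMatrix", function(x, ...) {
  a <- x@abundance
  idx <- which(a > 0, arr.ind = TRUE)
  df <- data.frame(plot = rownames(a)[idx[, 1]],
                   study = unname(x@study[rownames(a)[idx[, 1]]]),
                   species = colnames(a)[idx[, 2]],
                   abundance = a[idx],
                   stringsAsFactors = FALSE)
  df[order(df$plot, df$species), , drop = FALSE]
})

#' @export
setMethod("as.data.frame", "TraitTable", function(x, ...) {
  v <- x@values
  out <- do.call(rbind, lapply(colnames(v), function(tr) {
    val <- v[[tr]]
    keep <- !is.na(val)
    if (!any(keep)) return(NULL)
    data.frame(species = rownames(v)[keep], trait = tr,
               value = as.character(val[keep]),
               kind = unname(x@traitKind[[tr]]), stringsAsFactors = FALSE)
  }))
  out[order(out$species, out$trait), , drop = FALSE]
})

setMethod("show", "TraitTable", function(object) {
  kind <- traitKind(object)
  cat(sprintf("TraitTable: %d species x %d traits (%d continuous, %d categorical)\n",
              nrow(object@values), ncol(object@values),
              sum(kind == "continuous"), sum(kind == "categorical")))
  miss <- sum(is.na(as.matrix(object@values)))
  cat(sprintf("  missing values: %d (%.1f%%)\n", miss,
              100 * miss / max(1, prod(dim(object@values)))))
})

setMethod("show", "CommunityMatrix", function(object) {
  cat(sprintf("CommunityMatrix: %d plots x %d species, %d stud%s\n",
              nrow(object@abundance), ncol(object@abundance),
              length(unique(object@study)),
              if (length(unique(object@study)) == 1) "y" else "ies"))
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport for subset {%s}\n",
              paste(object@subset, collapse = ", ")))
  cat(sprintf("  species dropped: %d; plots flagged (< %.0f%% abundance retained): %d; plots excluded: %d\n",
              length(object@speciesDropped), 100 * object@threshold,
              length(object@plotsFlagged), length(object@plotsDropped)))
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (%s): %d species\n",
              object@method, nrow(object@d)))
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult: %d species, %d axes retained",
              nrow(object@coordinates), object@axesRetained))
  if (object@negativeInertia > 0)
    cat(sprintf(" (negative inertia dropped: %.4g)", object@negativeInertia))
  cat("\n")
})

setMethod("show", "Hypervolume", function(object) {
  cat(sprintf("Hypervolume: %d-D, %s weights, volume %.4g (mass %.2f, %d MC samples, seed %d)\n",
              object@dims, if (object@weighted) "abundance" else "uniform",
              object@volume, object@mass, object@nSamples, object@seed))
})

setMethod("show", "SyntheticStudySpec", function(object) {
  cat(sprintf("SyntheticStudySpec '%s': %d species, %d plots, %d+%d traits, seed %d\n",
              object@studyId, object@nSpecies, object@nPlots,
              object@nTraitsContinuous, object@nTraitsCategorical,
              object@seed))
})

setMethod("show", "ModelFitSet", function(object) {
  cat(sprintf("ModelFitSet: %s ~ poly(%s), selected degree %d (AIC), LRT p = %.3g, n = %d\n",
              object@response, object@predictor, object@selectedDegree,
              object@pValue, object@nObs))
  print(object@table, row.names = FALSE)
})
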