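# Shared fixtures and independent oracles.

# --- builders -----------------------------------------------------------

toyCommunityDf <- function() {
  data.frame(plot = "plotA", study = "s1",
             species = c("sp1", "sp2", "sp3"),
             abundance = c(50, 30, 20), stringsAsFactors = FALSE)
}

# continuous-only trait table with species ids sp1..spN
randomTraitTable <- function(nSpecies, nTraits, seed = 1) {
  set.seed(seed)
  v <- as.data.frame(matrix(rnorm(nSpecies * nTraits), nSpecies, nTraits))
  names(v) <- sprintf("t%02d", seq_len(nTraits))
  rownames(v) <- sprintf("sp%d", seq_len(nSpecies))
  traitTable(v, setNames(rep("continuous", nTraits), names(v)))
}

distFromCoords <- function(X, ids = sprintf("s%d", seq_len(nrow(X)))) {
  d <- as.matrix(dist(X))
  dimnames(d) <- list(ids, ids)
  fdsweep:::newDistanceMatrix(d, "euclidean")
}

# synthetic sweep tables with known polynomial structure for recovery tests
simulateTraitNumberSweep <- function(nPlots = 40, ks = 2:10,
                                     subsetsPerK = 3, intercept = 2,
                                     slope = -0.1, quad = 0, plotSd = 0.05,
                                     noiseSd = 0.1, seed = 1) {
  set.seed(seed)
  plots <- sprintf("p%02d", seq_len(nPlots))
  plotEff <- rnorm(nPlots, 0, plotSd)
  rows <- expand.grid(plot = plots, k = ks,
                      rep = seq_len(subsetsPerK),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$study <- "s"
  rows$metric <- "FRich"
  rows$distance <- "gower"
  rows$subset <- paste0("sub", rows$k, "_", rows$rep)
  rows$dims <- 2L
  rows$value <- intercept + slope * rows$k + quad * rows$k^2 +
    plotEff[match(rows$plot, plots)] + rnorm(nrow(rows), 0, noiseSd)
  rows
}

# --- independent oracles ------------------------------------------------

# polygon area by the shoelace formula on an explicitly ordered polygon
shoelaceArea <- function(x, y) {
  j <- c(seq_along(x)[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Rao's Q by exhaustive double loop
bruteRaoQ <- function(D, p) {
  q <- 0
  S <- nrow(D)
  for (i in seq_len(S - 1))
    for (j in (i + 1):S)
      q <- q + D[i, j] * p[i] * p[j]
  q
}

# minimum spanning tree length by exhaustive enumeration of spanning trees
# (all (S-1)-edge subsets that connect the graph); feasible for S <= 7
bruteMSTLength <- function(D) {
  S <- nrow(D)
  edges <- which(upper.tri(D), arr.ind = TRUE)
  best <- Inf
  for (comb in utils::combn(nrow(edges), S - 1, simplify = FALSE)) {
    e <- edges[comb, , drop = FALSE]
    # connectivity check by label propagation
    lab <- seq_len(S)
    repeat {
      changed <- FALSE
      for (r in seq_len(nrow(e))) {
        m <- min(lab[e[r, 1]], lab[e[r, 2]])
        if (lab[e[r, 1]] != m || lab[e[r, 2]] != m) {
          lab[c(e[r, 1], e[r, 2])] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (length(unique(lab)) == 1)
      best <- min(best, sum(D[e]))
  }
  best
}
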