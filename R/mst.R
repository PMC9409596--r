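# Minimum spanning tree over species in trait space (Kruskal).

#' Minimum spanning tree of a species dissimilarity matrix
#'
#' Kruskal's algorithm with a deterministic tie-break: edges are processed
#' in (length, i, j) lexicographic order, so equal-length configurations
#' always yield the same tree.
#'
#' @param d a [DistanceMatrix-class] or plain symmetric matrix
#' @return a [SpanningTree-class] with `S - 1` branches
#' @export
minimumSpanningTree <- function(d) {
  dm <- if (is(d, "DistanceMatrix")) d@d else as.matrix(d)
  sp <- rownames(dm)
  if (is.null(sp)) sp <- as.character(seq_len(nrow(dm)))
  new("SpanningTree", branches = .kruskal(dm), species = sp)
}

# Plain-matrix Kruskal kernel (no S4 overhead; used per plot in the sweep).
.kruskal <- function(dm) {
  S <- nrow(dm)
  if (S < 2)
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("i", "j", "length"))))
  ij <- which(upper.tri(dm), arr.ind = TRUE)
  len <- dm[ij]
  ord <- order(len, ij[, 1], ij[, 2])
  parent <- seq_len(S)
  branches <- matrix(0, S - 1, 3,
                     dimnames = list(NULL, c("i", "j", "length")))
  cnt <- 0L
  for (e in ord) {
    a <- ij[e, 1]
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    b <- ij[e, 2]
    while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
    if (a != b) {
      parent[a] <- b
      cnt <- cnt + 1L
      branches[cnt, ] <- c(ij[e, 1], ij[e, 2], len[e])
      if (cnt == S - 1L) break
    }
  }
  branches
}

#' Total branch length of a spanning tree
#' @param tree a [SpanningTree-class]
#' @export
treeLength <- function(tree) {
  stopifnot(is(tree, "SpanningTree"))
  sum(tree@branches[, "length"])
}
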