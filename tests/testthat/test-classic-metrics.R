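ordFromCoords <- function(X) pcoa(distFromCoords(X))

test_that("functional richness equals the convex hull area/volume", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  o <- ordFromCoords(sq)
  expect_equal(functionalRichness(o, dims = 2), 1)

  # collinear species: undefined, NA (never 0)
  coll <- ordFromCoords(cbind(0:2, 0:2))
  expect_true(is.na(suppressMessages(functionalRichness(coll, dims = 2))))

  # too few species for dims + 1
  expect_true(is.na(suppressMessages(
    functionalRichness(ordFromCoords(rbind(c(0, 0), c(1, 1))), dims = 2))))

  # random 2-D points: hull area equals the shoelace formula on the hull
  set.seed(21)
  P <- matrix(runif(12), 6, 2)
  hull <- grDevices::chull(P)
  expect_equal(fdsweep:::.hullVolume(P),
               shoelaceArea(P[hull, 1], P[hull, 2]), tolerance = 1e-9)

  # 3-D sanity: unit cube (coplanar facets merged correctly)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(fdsweep:::.hullVolume(cube), 1, tolerance = 1e-9)
  # 4-D unit simplex has volume 1/4!
  expect_equal(fdsweep:::.hullVolume(rbind(rep(0, 4), diag(4))), 1 / 24,
               tolerance = 1e-9)
})

test_that("functional richness is monotone under species addition", {
  set.seed(31)
  P <- matrix(rnorm(40), 20, 2)
  o <- pcoa(distFromCoords(P))
  ids <- rownames(o@coordinates)
  prev <- 0
  for (n in c(5, 8, 12, 16, 20)) {
    v <- functionalRichness(o, present = ids[seq_len(n)], dims = 2)
    expect_gte(v, prev - 1e-12)
    prev <- v
  }
})

test_that("functional evenness follows the partial-weighted-evenness formula", {
  # equally spaced, equally abundant species on a line: perfectly even
  d1 <- distFromCoords(matrix(c(0, 1, 2), ncol = 1))
  expect_equal(functionalEvenness(d1, rep(1/3, 3)), 1)

  # positions 0, 1, 10: EW ratios 0.1/0.9 -> FEve = 0.2
  d2 <- distFromCoords(matrix(c(0, 1, 10), ncol = 1))
  expect_equal(functionalEvenness(d2, rep(1/3, 3)), 0.2)

  # one branch hogging all partial weight drives FEve toward 0 (S = 3 limit)
  d3 <- distFromCoords(matrix(c(0, 1e-9, 10), ncol = 1))
  expect_lt(functionalEvenness(d3, rep(1/3, 3)), 0.01)

  # fewer than 3 species: undefined
  expect_true(is.na(suppressMessages(
    functionalEvenness(distFromCoords(matrix(c(0, 1), ncol = 1)),
                       c(0.5, 0.5)))))
})

test_that("functional dispersion is the abundance-weighted centroid distance", {
  expect_equal(functionalDispersion(matrix(0, 1, 1), 1), 0)
  two <- matrix(c(0, 1), ncol = 1)
  expect_equal(functionalDispersion(two, c(0.5, 0.5)), 0.5)
  # skewed abundances pull the centroid: 0.9*0.1 + 0.1*0.9 = 0.18
  expect_equal(functionalDispersion(two, c(0.9, 0.1)), 0.18)
  # distance-matrix input is equivalent for Euclidean-embeddable distances
  set.seed(13)
  X <- matrix(rnorm(12), 6, 2)
  p <- runif(6); p <- p / sum(p)
  expect_equal(functionalDispersion(distFromCoords(X), p),
               functionalDispersion(X, p), tolerance = 1e-9)
})

test_that("functional divergence matches the adopted deviation formula", {
  # all species equidistant from the centroid: FDiv = 1
  expect_equal(divergenceIndex(c(2, 2, 2), rep(1/3, 3)), 1)
  # hand case z = (1, 1, 4), equal abundance -> 0.6
  expect_equal(divergenceIndex(c(1, 1, 4), rep(1/3, 3)), 0.6)
  # abundance concentrated on the farthest species -> 1 in the limit
  eps <- 1e-6
  expect_equal(divergenceIndex(c(1, 1, 4), c(eps / 2, eps / 2, 1 - eps)), 1,
               tolerance = 1e-4)
  # coincident species: undefined
  expect_true(is.na(suppressMessages(
    divergenceIndex(c(0, 0, 0), rep(1/3, 3)))))
  # geometric route stays in [0, 1]
  set.seed(17)
  X <- matrix(rnorm(14), 7, 2)
  p <- runif(7); p <- p / sum(p)
  fd <- functionalDivergence(X, p)
  expect_gte(fd, 0); expect_lte(fd, 1)
  fdm <- functionalDivergence(distFromCoords(X), p)
  expect_gte(fdm, 0); expect_lte(fdm, 1)
})

test_that("Rao's Q equals brute force and is permutation invariant", {
  expect_equal(raosQ(matrix(0, 1, 1, dimnames = list("a", "a")), 1), 0)
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(raosQ(d2, c(0.5, 0.5)), 0.25)

  set.seed(19)
  X <- matrix(rnorm(8), 4, 2)
  D <- as.matrix(dist(X))
  p <- runif(4); p <- p / sum(p)
  expect_equal(raosQ(D, p), bruteRaoQ(D, p), tolerance = 1e-12)

  perm <- sample(4)
  expect_equal(raosQ(D[perm, perm], p[perm]), raosQ(D, p), tolerance = 1e-12)
})

test_that("FDis and Rao's Q are invariant to splitting a species' abundance", {
  set.seed(23)
  X <- matrix(rnorm(10), 5, 2)
  p <- runif(5); p <- p / sum(p)
  # duplicate species 1, split its abundance in half
  X2 <- rbind(X[1, ], X)
  p2 <- c(p[1] / 2, p[1] / 2, p[-1])
  expect_equal(functionalDispersion(X2, p2), functionalDispersion(X, p),
               tolerance = 1e-12)
  D <- as.matrix(dist(X)); D2 <- as.matrix(dist(X2))
  expect_equal(raosQ(D2, p2), raosQ(D, p), tolerance = 1e-12)
})

test_that("the MST builder is exactly minimal and matches vegan", {
  set.seed(29)
  for (S in c(5, 6, 7)) {
    D <- as.matrix(dist(matrix(rnorm(S * 2), S, 2)))
    dimnames(D) <- list(sprintf("s%d", 1:S), sprintf("s%d", 1:S))
    tree <- minimumSpanningTree(D)
    expect_equal(nrow(tree@branches), S - 1)
    expect_equal(treeLength(tree), bruteMSTLength(D), tolerance = 1e-12)
  }
  skip_if_not_installed("vegan")
  D <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  dimnames(D) <- list(sprintf("s%d", 1:10), sprintf("s%d", 1:10))
  expect_equal(treeLength(minimumSpanningTree(D)),
               sum(vegan::spantree(as.dist(D))$dist), tolerance = 1e-12)
})

test_that("metric ranges hold on random communities whenever defined", {
  set.seed(37)
  for (rep in 1:10) {
    S <- sample(3:9, 1)
    X <- matrix(rnorm(S * 3), S, 3)
    p <- rexp(S); p <- p / sum(p)
    d <- distFromCoords(X)
    fe <- functionalEvenness(d, p)
    expect_gte(fe, 0); expect_lte(fe, 1)
    fd <- suppressMessages(functionalDivergence(d, p))
    if (!is.na(fd)) { expect_gte(fd, 0); expect_lte(fd, 1) }
    expect_gte(functionalDispersion(d, p), 0)
    expect_gte(raosQ(d, p), 0)
  }
})
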