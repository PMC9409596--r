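test_that("Gower distance matches the range-normalised mixed-trait definition", {
  # global height range 0-10 fixed by two extreme species
  tt <- traitTable(
    data.frame(height = c(2, 7, 0, 10),
               pathway = c("C3", "C4", "C3", "C3"),
               row.names = c("sp1", "sp2", "sp3", "sp4")),
    c(height = "continuous", pathway = "categorical"))
  g <- as.matrix(gowerDistance(tt))
  expect_equal(g["sp1", "sp2"], (0.5 + 1) / 2)   # (|2-7|/10 + mismatch)/2
  expect_equal(g["sp1", "sp1"], 0)
  expect_equal(g["sp3", "sp4"], 0.5)             # extremes on height, same pathway

  # identical species -> 0; full-range opposites on every trait -> 1
  tt2 <- traitTable(
    data.frame(a = c(0, 1), b = c(5, 9), p = c("x", "y"),
               row.names = c("s1", "s2")),
    c(a = "continuous", b = "continuous", p = "categorical"))
  expect_equal(as.matrix(gowerDistance(tt2))["s1", "s2"], 1)

  # zero-range trait contributes 0 with a warning
  tt3 <- traitTable(
    data.frame(a = c(1, 1, 1), b = c(0, 1, 2),
               row.names = c("s1", "s2", "s3")),
    c(a = "continuous", b = "continuous"))
  expect_warning(g3 <- as.matrix(gowerDistance(tt3)), "zero range")
  expect_equal(g3["s1", "s3"], 0.5)   # (0 + 1)/2
})

test_that("Gower agrees with cluster::daisy on random mixed traits", {
  skip_if_not_installed("cluster")
  set.seed(7)
  v <- data.frame(a = rnorm(8), b = runif(8),
                  p = sample(c("C3", "C4"), 8, replace = TRUE),
                  row.names = sprintf("sp%d", 1:8))
  tt <- traitTable(v, c(a = "continuous", b = "continuous",
                        p = "categorical"))
  ours <- as.matrix(gowerDistance(tt))
  v$p <- factor(v$p)
  ref <- as.matrix(cluster::daisy(v, metric = "gower"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("Euclidean distance honours standardisation and rejects categoricals", {
  tt <- traitTable(data.frame(x = c(0, 3), y = c(0, 4),
                              row.names = c("s1", "s2")),
                   c(x = "continuous", y = "continuous"))
  expect_equal(as.matrix(euclideanDistance(tt, standardize = FALSE))["s1", "s2"], 5)

  # z-scoring removes the unit dependence
  tt2 <- traitTable(data.frame(x = c(0, 3, 1), y = c(0, 4, 2),
                               row.names = c("s1", "s2", "s3")),
                    c(x = "continuous", y = "continuous"))
  ttScaled <- traitTable(data.frame(x = c(0, 300, 100), y = c(0, 0.4, 0.2),
                                    row.names = c("s1", "s2", "s3")),
                         c(x = "continuous", y = "continuous"))
  expect_equal(as.matrix(euclideanDistance(tt2)),
               as.matrix(euclideanDistance(ttScaled)), tolerance = 1e-12)

  ttc <- traitTable(data.frame(x = c(0, 1), p = c("a", "b"),
                               row.names = c("s1", "s2")),
                    c(x = "continuous", p = "categorical"))
  expect_error(euclideanDistance(ttc), "gowerDistance")
})

test_that("distance matrices satisfy symmetry, zero diagonal and triangle inequality", {
  set.seed(11)
  tt <- randomTraitTable(9, 4, seed = 11)
  for (d in list(gowerDistance(tt), euclideanDistance(tt))) {
    m <- as.matrix(d)
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_true(all(diag(m) == 0))
    if (d@method == "gower") expect_true(all(m >= 0 & m <= 1))
    # triangle inequality on random triples
    for (rep in 1:25) {
      ijk <- sample(nrow(m), 3)
      expect_lte(m[ijk[1], ijk[2]],
                 m[ijk[1], ijk[3]] + m[ijk[3], ijk[2]] + 1e-12)
    }
  }
})

test_that("PCoA reconstructs Euclidean configurations and conserves inertia", {
  # unit square: 2 positive axes, distances reproduced
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  d <- distFromCoords(sq)
  o <- pcoa(d)
  expect_equal(o@axesRetained, 2L)
  expect_lt(max(abs(as.matrix(dist(o@coordinates)) - as.matrix(d))), 1e-8)

  # random k-dimensional configuration recovered up to rotation/reflection
  set.seed(5)
  X <- matrix(rnorm(6 * 3), 6, 3)
  d2 <- distFromCoords(X)
  o2 <- pcoa(d2)
  expect_lt(max(abs(as.matrix(dist(o2@coordinates)) - as.matrix(d2))), 1e-8)

  # positive eigenvalues equal the trace of the centred Gram matrix
  A <- -0.5 * as.matrix(d2)^2
  G <- scale(scale(A, scale = FALSE, center = TRUE), scale = FALSE,
             center = TRUE)
  G <- t(scale(t(G), scale = FALSE, center = TRUE))
  ev <- o2@eigenvalues
  expect_equal(sum(ev[ev > 0]), sum(diag((A - rowMeans(A) -
    rep(colMeans(A), each = nrow(A)) + mean(A)))), tolerance = 1e-8)
})

test_that("PCoA handles degeneracy, axis truncation and Gower inputs", {
  # two identical species: all-zero coordinates
  dz <- fdsweep:::newDistanceMatrix(
    matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))), "euclidean")
  oz <- pcoa(dz)
  expect_true(all(oz@coordinates == 0))

  # requesting more axes than available positive ones warns
  sq <- distFromCoords(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_warning(ot <- pcoa(sq, nAxes = 3), "positive axes")
  expect_equal(ot@axesRetained, 2L)

  # Gower on mixed traits: reconstruction from positive axes when no
  # negative eigenvalues; otherwise negative inertia is recorded
  set.seed(9)
  v <- data.frame(a = rnorm(5), b = runif(5),
                  p = sample(c("x", "y"), 5, replace = TRUE),
                  row.names = sprintf("sp%d", 1:5))
  tt <- traitTable(v, c(a = "continuous", b = "continuous",
                        p = "categorical"))
  g <- gowerDistance(tt)
  o <- suppressMessages(pcoa(g))
  if (o@negativeInertia == 0)
    expect_lt(max(abs(as.matrix(dist(o@coordinates)) - as.matrix(g))), 1e-6)
  else
    expect_gt(o@negativeInertia, 0)
})

test_that("distance matrices round-trip through square CSV", {
  tt <- randomTraitTable(5, 3, seed = 2)
  d <- gowerDistance(tt)
  path <- withr::local_tempfile(fileext = ".csv")
  writeDistanceMatrix(d, path)
  d2 <- readDistanceMatrix(path, method = "gower")
  expect_equal(as.matrix(d2), as.matrix(d), tolerance = 1e-12)
})
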