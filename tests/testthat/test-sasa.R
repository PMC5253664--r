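test_that("an isolated atom exposes its full expanded sphere", {
  s <- sphereStructure(matrix(c(0, 0, 0), 1))
  expect_equal(shrakeRupley(s), 4 * pi * 3.1^2, tolerance = 1e-9)
  # two atoms far apart do not interact
  s2 <- sphereStructure(matrix(c(0, 0, 0, 100, 0, 0), 2, byrow = TRUE))
  expect_equal(shrakeRupley(s2), rep(4 * pi * 3.1^2, 2), tolerance = 1e-9)
})

test_that("two-sphere occlusion matches the analytic spherical cap", {
  R <- 1.7 + 1.4
  for (d in c(2.0, 3.1, 4.5, 5.5)) {
    s <- sphereStructure(matrix(c(0, 0, 0, d, 0, 0), 2, byrow = TRUE))
    analytic <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
    got <- shrakeRupley(s, nPoints = 10000)
    expect_equal(got[1], analytic, tolerance = 5e-3)
    expect_equal(got[2], analytic, tolerance = 5e-3)
  }
})

test_that("random sphere clusters agree with a Monte-Carlo surface oracle", {
  set.seed(31)
  for (n in c(3, 5)) {
    centers <- matrix(runif(3 * n, 0, 4.5), n, 3)
    s <- sphereStructure(centers)
    got <- shrakeRupley(s, nPoints = 10000)
    oracle <- mcSphereSasa(centers, 1.7, 1.4, nPer = 2e5)
    expect_equal(sum(got), sum(oracle), tolerance = 0.01)
  }
})

test_that("total SASA is invariant under rigid motion", {
  s <- makeFixtureStructure("bundle", 30, seed = 5)
  base <- sum(shrakeRupley(s))
  set.seed(9)
  for (i in 1:3) {
    ang <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                   0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
    Rz <- matrix(c(cos(ang[2]), -sin(ang[2]), 0,
                   sin(ang[2]), cos(ang[2]), 0, 0, 0, 1), 3, byrow = TRUE)
    a <- atoms(s)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% (Rx %*% Rz)
    a$x <- xyz[, 1] + runif(1, -50, 50)
    a$y <- xyz[, 2] + runif(1, -50, 50)
    a$z <- xyz[, 3] + runif(1, -50, 50)
    moved <- new("ProteinStructure", atoms = a)
    expect_equal(sum(shrakeRupley(moved)), base, tolerance = 1e-9)
  }
})

test_that("adding a neighbouring atom never increases existing SASA", {
  set.seed(13)
  centers <- matrix(runif(12, 0, 5), 4, 3)
  for (i in 1:5) {
    base <- shrakeRupley(sphereStructure(centers), frame = "input")
    extra <- rbind(centers, runif(3, 0, 5))
    grown <- shrakeRupley(sphereStructure(extra), frame = "input")
    expect_true(all(grown[seq_len(nrow(centers))] <= base + 1e-12))
    centers <- extra
  }
})

test_that("the point lattice is converged at the default density", {
  s <- makeFixtureStructure("helix", 20, seed = 3)
  a960 <- sum(shrakeRupley(s, nPoints = 960))
  a3840 <- sum(shrakeRupley(s, nPoints = 3840))
  expect_lt(abs(a960 - a3840) / a3840, 0.01)
})

test_that("unknown elements are rejected by name", {
  s <- sphereStructure(matrix(0, 1, 3), element = "ZZ")
  expect_error(shrakeRupley(s), "ZZ")
})

test_that("weighted peptide SASA uses normalized reactivity weights", {
  expect_equal(weightedPeptideSasa(42, "W", c(W = 10)), 42)
  expect_equal(weightedPeptideSasa(c(100, 50), c("W", "Y"),
                                   c(W = 10, Y = 10)), 75)
  expect_equal(weightedPeptideSasa(c(100, 50), c("W", "Y"),
                                   c(W = 30, Y = 10)), 87.5)
  # non-oxidizable residues carry zero weight
  expect_equal(weightedPeptideSasa(c(100, 7), c("W", "G"), c(W = 10)), 100)
  expect_error(weightedPeptideSasa(50, "G", c(W = 10)), "no oxidizable")
  # uniform-weight alternative
  expect_equal(weightedPeptideSasa(c(100, 50), c("W", "Y"),
                                   c(W = 30, Y = 10), uniform = TRUE), 75)
})

test_that("fractional SASA shares weights between numerator and reference", {
  expect_equal(fractionalSasa(50, "W", c(W = 200), c(W = 10))$fsasa, 0.25)
  expect_equal(fractionalSasa(0, "W", c(W = 200), c(W = 10))$fsasa, 0)
  got <- fractionalSasa(c(50, 100), c("W", "Y"), c(W = 200, Y = 200),
                        c(W = 10, Y = 10))
  expect_equal(got$fsasa, 0.375)
  # above-reference values are flagged, not rejected
  over <- fractionalSasa(300, "W", c(W = 200), c(W = 10))
  expect_true(over$flagged)
  expect_error(fractionalSasa(50, "W", c(Y = 100), c(W = 10)),
               "reference")
})

test_that("fixture fSASA stays within [0, 1] against the bundled reference", {
  ref <- loadSasaRefTable()
  for (kind in c("helix", "bundle", "sheet_pair")) {
    s <- makeFixtureStructure(kind, 24, seed = 4)
    prs <- perResidueSasa(s)
    f <- prs$sasa / unname(ref[prs$code])
    f <- f[!is.na(f)]
    expect_true(all(f >= 0))
    expect_true(all(f <= 1))
  }
})

test_that("side-chain mode zeroes backbone-only residues", {
  s <- readStructure(writeGagPdb())
  prs <- perResidueSasa(s, sideChainOnly = TRUE)
  expect_equal(prs$sasa[prs$code == "G"], c(0, 0))
  expect_gt(prs$sasa[prs$code == "A"], 0)
  prsAll <- perResidueSasa(s, sideChainOnly = FALSE)
  expect_true(all(prsAll$sasa > prs$sasa - 1e-9))
})
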