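test_that("the helix fixture has ideal rise and stub side chains", {
  s <- makeFixtureStructure("helix", 30, seed = 1)
  ca <- atoms(s)[atoms(s)$name == "CA", ]
  expect_equal(nrow(ca), 30)
  expect_equal(diff(ca$z), rep(1.5, 29), tolerance = 1e-9)
  expect_true(all(atoms(s)$name %in% c("N", "CA", "C", "O", "CB")))
})

test_that("generators are seed-deterministic", {
  s1 <- makeFixtureStructure("bundle", 24, seed = 9)
  s2 <- makeFixtureStructure("bundle", 24, seed = 9)
  expect_identical(atoms(s1), atoms(s2))
  expect_false(identical(atoms(s1),
                         atoms(makeFixtureStructure("bundle", 24, seed = 10))))
  sim1 <- simulateFootprinting(s1, nSites = 8, seed = 3)
  sim2 <- simulateFootprinting(s1, nSites = 8, seed = 3)
  expect_identical(sim1$rates, sim2$rates)
  b1 <- simulateBret(1e-8, sigma = 0.1, seed = 5)
  expect_identical(b1, simulateBret(1e-8, sigma = 0.1, seed = 5))
})

test_that("complex interface residues lose SASA upon complexation", {
  s <- makeFixtureStructure("two_domain_complex", 30, seed = 2)
  iface <- complexInterface(s)
  expect_gt(nrow(iface), 2)
  a <- atoms(s)
  sepA <- new("ProteinStructure", atoms = a[a$chain == "A", ])
  prsSep <- perResidueSasa(sepA)
  prsCplx <- perResidueSasa(s)
  ifA <- iface[iface$chain == "A", ]
  for (i in seq_len(nrow(ifA))) {
    inCplx <- prsCplx$sasa[prsCplx$chain == "A" &
                             prsCplx$resno == ifA$resno[i]]
    inSep <- prsSep$sasa[prsSep$resno == ifA$resno[i]]
    expect_lte(inCplx, inSep + 1e-9)
  }
  expect_lt(sum(prsCplx$sasa[prsCplx$chain == "A"]), sum(prsSep$sasa))
})

test_that("noiseless simulation round-trips the generating line exactly", {
  s <- makeFixtureStructure("bundle", 45, seed = 6)
  sim <- simulateFootprinting(s, a = 4, b = -3.5, nSites = 12,
                              rateNoise = 0, fractionNoise = 0, seed = 2)
  res <- runFreeState(sim$rates, s)
  expect_equal(calIntercept(res$model), 4, tolerance = 1e-6)
  expect_equal(calSlope(res$model), -3.5, tolerance = 1e-6)
  expect_equal(pearsonR(res$model), -1, tolerance = 1e-9)
  # fitted rates equal the generator's observed rates
  idx <- match(res$rates$site, sim$truth$sites$site)
  expect_equal(res$rates$k_per_s, sim$truth$sites$k_obs[idx],
               tolerance = 1e-6)
})

test_that("the measurability guard keeps rates inside the dose window", {
  s <- makeFixtureStructure("bundle", 60, seed = 7)
  sim <- simulateFootprinting(s, nSites = NULL, rateNoise = 0,
                              fractionNoise = 0, seed = 1)
  kt <- sim$truth$sites$k_true * max(sim$truth$timesMs) / 1000
  expect_true(all(kt >= 0.2))
  ktFirst <- sim$truth$sites$k_true *
    min(sim$truth$timesMs[sim$truth$timesMs > 0]) / 1000
  expect_true(all(ktFirst <= 3))
})

test_that("simulation sidecar files land in the structio schema", {
  s <- makeFixtureStructure("bundle", 45, seed = 6)
  dir <- tempfile()
  sim <- simulateFootprinting(s, nSites = 6, seed = 2, dir = dir)
  expect_true(file.exists(file.path(dir, "rates.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  reread <- readTable(file.path(dir, "rates.csv"), ratesTableSchema())
  expect_equal(nrow(reread), nrow(sim$rates))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$b, -3.5)
  expect_equal(nrow(truth$sites), 6)
})

test_that("BRET simulation at zero noise reproduces its parameters", {
  d <- simulateBret(33e-9, emax = 0.52, hill = 1, sigma = 0, seed = 1)
  pe <- fitDoseResponse(d$conc_M, d$response)
  expect_equal(pEC50(pe), -log10(33e-9), tolerance = 1e-5)
  expect_equal(eMax(pe), 0.52, tolerance = 1e-5)
  fp <- foldPotency(
    fitDoseResponse(d$conc_M, d$response),
    local({
      d2 <- simulateBret(8.5e-9, emax = 1, sigma = 0, seed = 2)
      fitDoseResponse(d2$conc_M, d2$response)
    }))
  expect_equal(fp$fold_rounded, 4)
})
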