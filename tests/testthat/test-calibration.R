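test_that("an exact line is recovered with R = -1", {
  f <- c(0.1, 0.4, 0.9)
  m <- calibrate(f, 5 - 4 * f)
  expect_equal(calIntercept(m), 5, tolerance = 1e-12)
  expect_equal(calSlope(m), -4, tolerance = 1e-12)
  expect_equal(pearsonR(m), -1, tolerance = 1e-12)
  expect_error(calibrate(c(0.5, 0.5, 0.5), c(1, 2, 3)), "rank")
  expect_error(calibrate(c(0.1, 0.9), c(1, 2)), "3 pairs")
})

test_that("pure-noise correlations behave like the Pearson null at n = 200", {
  set.seed(21)
  rs <- replicate(200, {
    pearsonR(calibrate(runif(200), rnorm(200)))
  })
  # 95% null quantile of |R| at n = 200 is ~0.139
  expect_gte(mean(abs(rs) < 0.139), 0.9)
  expect_lt(abs(median(rs)), 0.05)
})

test_that("R and slope share sign and R is affine-invariant", {
  set.seed(3)
  f <- runif(40)
  y <- 2 - 3 * f + rnorm(40, 0, 0.3)
  m <- calibrate(f, y)
  expect_equal(sign(calSlope(m)), sign(pearsonR(m)))
  m2 <- calibrate(10 * f + 4, 0.5 * y - 7)
  expect_equal(pearsonR(m2), pearsonR(m), tolerance = 1e-12)
})

test_that("inversion predicts fSASA and clips out-of-range values", {
  f <- c(0.1, 0.4, 0.9)
  m <- calibrate(f, 5 - 4 * f)
  p <- predictBoundFsasa(3, m)
  expect_equal(p$fsasa, 0.5)
  # deep protection: raw negative, clipped to 0, flagged
  deep <- predictBoundFsasa(6, m)
  expect_lt(deep$fsasa_raw, 0)
  expect_equal(deep$fsasa, 0)
  expect_true(deep$clipped)
  noclip <- predictBoundFsasa(6, m, clip = FALSE)
  expect_equal(noclip$fsasa, noclip$fsasa_raw)
  # round trip on training points
  p2 <- predictBoundFsasa(5 - 4 * f, m)
  expect_equal(p2$fsasa, f, tolerance = 1e-12)
  # absolute SASA from reference area
  pa <- predictBoundFsasa(3, m, sasaRefW = 200)
  expect_equal(pa$sasa_pred, 100)
})

test_that("slope and intercept are recovered within 2 SE on noisy data", {
  set.seed(11)
  hit <- replicate(200, {
    f <- runif(25)
    y <- 4 - 3.5 * f + rnorm(25, 0, 0.5)
    fit <- lm(y ~ f)
    se <- coef(summary(fit))[, "Std. Error"]
    m <- calibrate(f, y)
    abs(calSlope(m) + 3.5) <= 2 * se[2] &&
      abs(calIntercept(m) - 4) <= 2 * se[1]
  })
  expect_gte(mean(hit), 0.9)
})

test_that("rescaling reactivities shifts only the calibration intercept", {
  r <- loadReactivityTable()
  rates <- data.frame(site = paste0("A:", 1:6),
                      residues = c("W", "Y", "F", "M", "L", "H"),
                      peptide_id = paste0("p", 1:6), mod_mass = 16,
                      k_per_s = c(2, 30, 11, 5, 0.7, 60),
                      stringsAsFactors = FALSE)
  f <- c(0.05, 0.5, 0.3, 0.15, 0.02, 0.8)
  pt1 <- protectionTable(rates, r)
  m1 <- calibrate(f, pt1$ln_pf)
  pt2 <- protectionTable(rates, r * 7)
  m2 <- calibrate(f, pt2$ln_pf)
  expect_equal(calSlope(m2), calSlope(m1), tolerance = 1e-12)
  expect_equal(pearsonR(m2), pearsonR(m1), tolerance = 1e-12)
  expect_equal(calIntercept(m2) - calIntercept(m1), log(7),
               tolerance = 1e-12)
})

test_that("burial changes join by site and rank interfaces first", {
  free <- data.frame(site = paste0("A:", 1:6),
                     fsasa = c(0.8, 0.7, 0.6, 0.5, 0.4, 0.3))
  bound <- data.frame(site = paste0("A:", 1:6),
                      fsasa = c(0.1, 0.1, 0.1, 0.5, 0.4, 0.3))
  d <- deltaAccessibility(free, bound)
  expect_equal(d$delta[d$site == "A:1"], 0.7)
  expect_equal(d$delta[d$site == "A:4"], 0)
  expect_equal(d$site[1:3], paste0("A:", 1:3))
  bad <- bound[-2, ]
  expect_error(deltaAccessibility(free, bad), "A:2")
})

test_that("the inverse-regression alternative inverts consistently", {
  set.seed(5)
  f <- runif(30)
  y <- 4 - 3.5 * f + rnorm(30, 0, 0.2)
  m <- calibrate(f, y, inverse = TRUE)
  expect_lt(calSlope(m), 0)
  # on exact data both directions coincide
  mExact <- calibrate(f, 4 - 3.5 * f, inverse = TRUE)
  expect_equal(calSlope(mExact), -3.5, tolerance = 1e-9)
  expect_equal(calIntercept(mExact), 4, tolerance = 1e-9)
})
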