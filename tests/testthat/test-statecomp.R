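mkRates <- function(sites, k, residues = "W", peptide = "p1", mod = 16) {
  data.frame(site = sites, residues = residues, peptide_id = peptide,
             mod_mass = mod, k_per_s = k, sd_k = 0.05 * k,
             stringsAsFactors = FALSE)
}

test_that("log10 rate ratios join on shared species keys", {
  a <- mkRates(c("A:1", "A:2"), c(2, 5))
  b <- mkRates(c("A:1", "A:2"), c(1, 5))
  rr <- rateRatios(a, b)
  expect_equal(rr$log10_ratio, c(log10(2), 0), tolerance = 1e-12)
  expect_equal(nrow(attr(rr, "orphans")), 0)
})

test_that("unmatched species are reported, never silently dropped", {
  a <- mkRates(c("A:1", "A:2"), c(2, 5))
  b <- mkRates(c("A:2", "A:3"), c(5, 7))
  rr <- rateRatios(a, b)
  expect_equal(rr$site, "A:2")
  orph <- attr(rr, "orphans")
  expect_setequal(orph$site, c("A:1", "A:3"))
  expect_setequal(orph$state, c("A", "B"))
  # fully disjoint tables: empty result, complete orphan report
  rr2 <- rateRatios(mkRates("A:1", 2), mkRates("A:9", 3))
  expect_equal(nrow(rr2), 0)
  expect_equal(nrow(attr(rr2, "orphans")), 2)
})

test_that("non-positive rates are excluded with a message", {
  a <- mkRates(c("A:1", "A:2"), c(2, 0))
  b <- mkRates(c("A:1", "A:2"), c(1, 3))
  expect_message(rr <- rateRatios(a, b), "non-positive")
  expect_equal(rr$site, "A:1")
})

test_that("swapping states negates ratios and swaps labels", {
  a <- mkRates(paste0("A:", 1:4), c(2, 5, 0.5, 9))
  b <- mkRates(paste0("A:", 1:4), c(1, 5, 2.5, 3))
  ab <- classifyActivationSites(aggregatePerResidue(rateRatios(a, b)))
  ba <- classifyActivationSites(aggregatePerResidue(rateRatios(b, a)))
  expect_equal(ba$mean_log10_ratio, -ab$mean_log10_ratio, tolerance = 1e-12)
  swap <- c(increased_in_B = "decreased_in_B",
            decreased_in_B = "increased_in_B", unchanged = "unchanged")
  expect_equal(unname(swap[ab$label]), ba$label)
})

test_that("multiple oxidation events on one residue average their ratios", {
  a <- rbind(mkRates("A:7", 10^0.2, peptide = "p1"),
             mkRates("A:7", 10^0.4, peptide = "p2"))
  b <- rbind(mkRates("A:7", 1, peptide = "p1"),
             mkRates("A:7", 1, peptide = "p2"))
  agg <- aggregatePerResidue(rateRatios(a, b))
  expect_equal(nrow(agg), 1)
  expect_equal(agg$mean_log10_ratio, 0.3, tolerance = 1e-9)
  expect_equal(agg$n_species, 2)
})

test_that("aggregation is invariant to input order", {
  a <- mkRates(paste0("A:", c(3, 1, 2)), c(2, 4, 8))
  b <- mkRates(paste0("A:", c(3, 1, 2)), c(1, 1, 1))
  agg1 <- aggregatePerResidue(rateRatios(a, b))
  perm <- c(2, 3, 1)
  agg2 <- aggregatePerResidue(rateRatios(a[perm, ], b[perm, ]))
  expect_equal(agg1, agg2)
})

test_that("ambiguous two-residue sites propagate to both residues", {
  a <- mkRates("A:10-11", 10^0.5, residues = "WF")
  b <- mkRates("A:10-11", 1, residues = "WF")
  agg <- aggregatePerResidue(rateRatios(a, b))
  expect_equal(agg$resno, c(10L, 11L))
  expect_equal(agg$mean_log10_ratio, c(0.5, 0.5), tolerance = 1e-9)
  expect_true(all(agg$ambiguous))
})

test_that("the fold-change classification uses strict inequalities", {
  mk <- function(fold) {
    a <- mkRates("A:1", 1)
    b <- mkRates("A:1", fold)
    classifyActivationSites(aggregatePerResidue(rateRatios(a, b)),
                            thresholdFold = 1.4)$label
  }
  expect_equal(mk(1.5), "increased_in_B")
  expect_equal(mk(1.39), "unchanged")
  expect_equal(mk(1.4), "unchanged")     # exactly at threshold: unchanged
  expect_equal(mk(1 / 1.5), "decreased_in_B")
  expect_error(classifyActivationSites(data.frame(mean_log10_ratio = 0),
                                       thresholdFold = 1), "> 1")
})

test_that("a 3-fold protected subset is recovered exactly without noise", {
  s <- makeFixtureStructure("two_domain_complex", 30, seed = 2)
  sim <- simulateStateComparison(s, rateNoise = 0, seed = 1)
  cmp <- runStateCompare(sim$ratesA, sim$ratesB)
  called <- with(cmp$perResidue,
                 paste0(chain, ":", resno)[label == "decreased_in_B"])
  expect_setequal(called, sim$truth$protected)
})
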