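test_that("pair scenarios validate their parameters", {
  expect_error(pairScenario(1, 10), "n_anadromous")
  expect_error(pairScenario(10, 10, fst_target = 1))
  expect_error(pairScenario(10, 10, n_outlier_loci = 5, outlier_fst = 0),
               "outlier_fst must exceed")
  sc <- divergentPairScenario()
  expect_equal(sc$n_anadromous, 103L)
  expect_equal(sc$n_resident, 45L)
  expect_equal(sc$fst_target, 0.09)
  sc2 <- panmicticPairScenario()
  expect_equal(sc2$n_anadromous, 14L)
  expect_equal(sc2$n_resident, 49L)
  expect_equal(sc2$fst_target, 0)
})

test_that("simulatePair is deterministic and labels truth consistently", {
  sc <- pairScenario(4, 4, n_loci = 10, fst_target = 0.1,
                     n_outlier_loci = 2, outlier_fst = 0.3,
                     missing_rate = 0.1)
  a <- simulatePair(sc, seed = 3)
  b <- simulatePair(sc, seed = 3)
  expect_identical(genoCodes(a$geno), genoCodes(b$geno))
  expect_identical(a$truth$outlier_locus_ids, b$truth$outlier_locus_ids)
  expect_true(all(a$truth$outlier_locus_ids %in% lociIds(a$geno)))
  # divergent scenario: phenotype coincides with collection
  expect_equal(lifeHistory(a$geno),
               as.integer(grepl("anadromous", populations(a$geno))))
  # panmictic scenario: class sizes exactly match the scenario
  p <- simulatePair(pairScenario(14, 49, n_loci = 50, fst_target = 0,
                                 n_causal_loci = 3, missing_rate = 0),
                    seed = 1)
  expect_equal(sum(lifeHistory(p$geno) == 1L), 14L)
  expect_equal(sum(lifeHistory(p$geno) == 0L), 49L)
  expect_length(p$truth$causal_locus_ids, 3L)
})

test_that("realized differentiation tracks fst_target monotonically", {
  grid <- c(0.01, 0.05, 0.15)
  th <- vapply(grid, function(cc) {
    mean(vapply(1:3, function(s) {
      sim <- simulatePair(pairScenario(40, 40, n_loci = 600,
                                       fst_target = cc,
                                       missing_rate = 0), seed = s)
      wcTheta(sim$geno)
    }, 0))
  }, 0)
  expect_true(all(diff(th) > 0))
  expect_lt(abs(th[3] - 0.15), 0.02)
})

test_that("within-population genotypes are HWE-consistent", {
  # moderate frequencies: at MAF below ~0.1 the exact test has almost no
  # rejection region at this n, which would mask the calibration signal
  sim <- simulatePair(pairScenario(200, 50, n_loci = 2000,
                                   fst_target = 0.08, missing_rate = 0,
                                   maf_range = c(0.1, 0.9)),
                      seed = 21)
  codes <- genoCodes(sim$geno)[lifeHistory(sim$geno) == 1L, ]
  pv <- vapply(seq_len(ncol(codes)), function(j) {
    g <- codes[, j]
    hweExactTest(sum(g == 2), sum(g == 1), sum(g == 0))
  }, 0)
  rate <- mean(pv < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("planted outliers carry elevated differentiation on average", {
  sim <- simulatePair(pairScenario(60, 60, n_loci = 1200,
                                   fst_target = 0.09,
                                   n_outlier_loci = 60, outlier_fst = 0.4,
                                   missing_rate = 0), seed = 13)
  comp <- wcComponents(sim$geno)
  planted <- comp$locus %in% sim$truth$outlier_locus_ids
  tt <- t.test(comp$theta[planted], comp$theta[!planted],
               alternative = "greater")
  expect_lt(tt$p.value, 1e-3)
})

test_that("injectMissingness masks at the requested rate, reproducibly", {
  sim <- simulatePair(pairScenario(25, 25, n_loci = 200, fst_target = 0,
                                   missing_rate = 0), seed = 2)
  expect_identical(genoCodes(injectMissingness(sim$geno, 0)),
                   genoCodes(sim$geno))
  m1 <- injectMissingness(sim$geno, 0.3, seed = 5)
  m2 <- injectMissingness(sim$geno, 0.3, seed = 5)
  expect_identical(genoCodes(m1), genoCodes(m2))
  frac <- mean(is.na(genoCodes(m1)))   # 10,000 cells
  expect_gt(frac, 0.28)
  expect_lt(frac, 0.32)
  expect_error(injectMissingness(sim$geno, 1), "rate")
})

test_that("combinePairs stacks two scenarios on one shared locus panel", {
  d <- simulatePair(pairScenario(6, 6, n_loci = 40, fst_target = 0.2,
                                 n_outlier_loci = 4, outlier_fst = 0.5,
                                 missing_rate = 0, pair = "divergent"),
                    seed = 1)
  p <- simulatePair(pairScenario(5, 7, n_loci = 40, fst_target = 0,
                                 n_causal_loci = 2, missing_rate = 0,
                                 pair = "panmictic"), seed = 2)
  both <- combinePairs(d, p)
  expect_equal(nSamples(both$geno), 24L)
  expect_equal(nLoci(both$geno), 40L)
  expect_length(unique(populations(both$geno)), 4L)
  expect_true(all(both$truth$divergent$outlier_locus_ids %in%
                    lociIds(both$geno)))
  expect_true(all(both$truth$panmictic$causal_locus_ids %in%
                    lociIds(both$geno)))
})

test_that("Wright-Fisher drift raises LD while huge populations do not", {
  wf <- simulateWrightFisher(60, n_loci = 150, n_generations = 15,
                             sample_size = 40, seed = 4)
  expect_equal(dim(genoCodes(wf)), c(40L, 150L))
  expect_identical(
    genoCodes(simulateWrightFisher(60, 50, 5, 20, seed = 9)),
    genoCodes(simulateWrightFisher(60, 50, 5, 20, seed = 9)))
  expect_error(simulateWrightFisher(50, 10, 0, 10), "n_generations")
  big <- simulateWrightFisher(1e6, n_loci = 200, n_generations = 3,
                              sample_size = 50, seed = 11)
  expect_equal(neLdEstimate(big)$ne, Inf)
})
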