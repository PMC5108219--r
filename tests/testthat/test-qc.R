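test_that("global MAF matches hand counts, including missing data", {
  # genotypes {AA, AA, AA, Aa}: counted-allele copies {0,0,0,1}
  ge <- makeGeno(cbind(c(0L, 0L, 0L, 1L)))
  expect_equal(unname(computeMaf(ge)), 1 / 8)
  expect_equal(unname(computeMaf(makeGeno(cbind(rep(1L, 6))))), 0.5)
  # {2, 2, NA, 1}: p = 5/6, MAF = 1/6
  expect_equal(unname(computeMaf(makeGeno(cbind(c(2L, 2L, NA, 1L))))),
               1 / 6)
  expect_true(is.na(computeMaf(makeGeno(cbind(rep(NA_integer_, 3))))))
})

test_that("individual call-rate filter removes strictly below threshold", {
  codes <- matrix(0L, 10, 100)
  codes[1, 1:26] <- NA    # 74% called -> removed
  codes[2, 1:25] <- NA    # 75% called -> kept (boundary)
  codes[3, 1:40] <- NA
  codes[4, 1:30] <- NA
  out <- filterIndividuals(makeGeno(codes), callrate_min = 0.75)
  expect_equal(sum(out$report$removed), 3L)
  expect_equal(nSamples(out$geno), 7L)
  expect_false("s02" %in% out$report$sample_id[out$report$removed])
  clean <- filterIndividuals(makeGeno(matrix(1L, 4, 5)))
  expect_equal(sum(clean$report$removed), 0L)
})

test_that("locus filters apply strict MAF/heterozygosity/missingness rules", {
  n <- 100
  codes <- cbind(
    maf04  = c(rep(1L, 8), rep(0L, 92)),          # MAF 0.04 -> removed
    maf05  = c(rep(1L, 10), rep(0L, 90)),         # MAF 0.05 -> kept
    het85  = c(rep(1L, 85), rep(0L, 10), rep(2L, 5)),  # 85% het -> removed
    miss31 = c(rep(NA_integer_, 31), rep(c(0L, 1L), c(35, 34))),
    ok     = rep(c(0L, 1L, 2L), c(40, 40, 20)))
  out <- filterLoci(makeGeno(codes))
  expect_setequal(out$report$locus[out$report$reason != ""],
                  c("maf04", "het85", "miss31"))
  expect_equal(out$report$reason[out$report$locus == "het85"],
               "heterozygosity")
  expect_setequal(lociIds(out$geno), c("maf05", "ok"))
})

test_that("HWE exact test reproduces enumerated Levene probabilities", {
  expect_equal(hweExactTest(2, 0, 2), 0.0857142857, tolerance = 1e-9)
  expect_equal(hweExactTest(1, 2, 1), 1)
  # monomorphic: single feasible configuration
  expect_equal(hweExactTest(5, 0, 0), 1)
  expect_equal(hweExactTest(0, 0, 7), 1)
  expect_error(hweExactTest(-1, 2, 0), "negative")
  expect_error(hweExactTest(0, 0, 0), "empty")
  # oracle agreement on a grid of small configurations
  for (n in c(4, 7, 12)) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hweExactTest(nAA, nAa, naa), hweOracle(nAA, nAa, naa),
                   tolerance = 1e-12)
    }
  }
})

test_that("BY-FDR threshold equals q over the harmonic sum", {
  expect_equal(byFdrThreshold(1, 0.05), 0.05)
  expect_equal(byFdrThreshold(4, 0.05), 0.05 / (1 + 1/2 + 1/3 + 1/4))
  expect_equal(byFdrThreshold(4, 0.05), 0.024, tolerance = 1e-3)
  expect_error(byFdrThreshold(0, 0.05))
})

test_that("cross-population HWE filter needs three violating collections", {
  set.seed(31)
  n <- 30
  hweLocus <- function() rbinom(n, 2, 0.5)
  allHet <- rep(1L, n)
  codes3 <- rbind(
    cbind(bad3 = allHet, bad2 = allHet, good = hweLocus()),
    cbind(bad3 = allHet, bad2 = allHet, good = hweLocus()),
    cbind(bad3 = allHet, bad2 = hweLocus(), good = hweLocus()),
    cbind(bad3 = hweLocus(), bad2 = hweLocus(), good = hweLocus()))
  rownames(codes3) <- sprintf("s%03d", seq_len(4 * n))
  ge <- makeGeno(codes3, population = rep(paste0("pop", 1:4), each = n))
  out <- hweCrossPopFilter(ge, q = 0.05)
  expect_true(out$report$removed[out$report$locus == "bad3"])   # 3 of 4
  expect_false(out$report$removed[out$report$locus == "bad2"])  # only 2
  expect_false(out$report$removed[out$report$locus == "good"])
  expect_equal(dim(out$hwe_p), c(3L, 4L))
  # fewer than 3 collections: warned no-op
  ge2 <- makeGeno(codes3[1:(2 * n), ],
                  population = rep(c("a", "b"), each = n))
  expect_warning(out2 <- hweCrossPopFilter(ge2), "skipped")
  expect_equal(nLoci(out2$geno), 3L)
})

test_that("the full QC chain is idempotent and logs ordered counts", {
  sim <- simulatePair(pairScenario(25, 25, n_loci = 120, fst_target = 0.05,
                                   missing_rate = 0.08,
                                   maf_range = c(0.02, 0.98)), seed = 5)
  cfg <- pipelineConfig()
  q1 <- suppressWarnings(qcFilter(sim$geno, cfg))
  q2 <- suppressWarnings(qcFilter(q1$geno, cfg))
  expect_identical(genoCodes(q2$geno), genoCodes(q1$geno))
  expect_equal(q1$summary$step,
               c("individual_callrate", "locus_maf_het_missing",
                 "locus_hwe"))
  expect_equal(nLoci(q1$geno) + sum(q1$summary$loci_removed),
               nLoci(sim$geno))
})

test_that("HWE-true simulation rejects at close to the nominal rate", {
  set.seed(77)
  L <- 2000; n <- 60
  p <- runif(L, 0.1, 0.9)
  codes <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  pv <- vapply(seq_len(L), function(j) {
    g <- codes[, j]
    hweExactTest(sum(g == 2), sum(g == 1), sum(g == 0))
  }, 0)
  # exact tests are conservative; rejection rate at alpha = .05 in [.03,.07]
  expect_gt(mean(pv < 0.05), 0.03)
  expect_lt(mean(pv < 0.05), 0.07)
})
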