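test_that("heterozygosity statistics match plug-in values", {
  # all heterozygotes, n = 10: Ho = 1, He = 0.5 * 20/19, F = -0.9
  ge <- makeGeno(cbind(rep(1L, 10)))
  st <- heterozygosityStats(ge, groups = rep("g", 10))
  expect_equal(st$per_locus$Ho, 1)
  expect_equal(st$per_locus$He, 0.5 * 20 / 19)
  expect_equal(st$per_locus$F, 1 - 1 / (0.5 * 20 / 19))
  expect_equal(st$per_locus$F, -0.9, tolerance = 1e-12)
  # identical homozygotes: Ho = He = 0, F undefined
  st0 <- heterozygosityStats(makeGeno(cbind(rep(2L, 6))),
                             groups = rep("g", 6))
  expect_equal(st0$per_locus$Ho, 0)
  expect_equal(st0$per_locus$He, 0)
  expect_true(is.na(st0$per_locus$F))
  expect_error(heterozygosityStats(makeGeno(cbind(1L)), groups = "g"),
               "fewer than 2")
})

test_that("mean fixation index is near zero under HWE simulation", {
  set.seed(8)
  L <- 2000; n <- 50
  p <- runif(L, 0.1, 0.9)
  codes <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  st <- heterozygosityStats(makeGeno(codes), groups = rep("g", n))
  expect_lt(abs(st$summary$F), 0.02)
})

test_that("Weir-Cockerham components match an independent oracle", {
  # alternate fixation: theta = 1
  ge <- makeGeno(rbind(matrix(0L, 30, 1), matrix(2L, 30, 1)),
                 population = rep(c("a", "b"), each = 30))
  expect_equal(wcComponents(ge)$theta, 1)
  # identical genotype counts in both groups (12 AA, 26 Aa, 12 aa)
  g <- rep(c(2L, 1L, 0L), c(12, 26, 12))
  comp <- wcComponents(makeGeno(cbind(c(g, g)),
                                population = rep(c("a", "b"), each = 50)))
  orc <- wcOracle(g, g)
  expect_equal(comp$a, unname(orc["a"]), tolerance = 1e-12)
  expect_equal(comp$b, unname(orc["b"]), tolerance = 1e-12)
  expect_equal(comp$c, unname(orc["c"]), tolerance = 1e-12)
  expect_equal(comp$theta, unname(orc["theta"]), tolerance = 1e-12)
  # random unbalanced configurations with missing data
  set.seed(99)
  for (k in 1:25) {
    g1 <- rbinom(17, 2, runif(1, .1, .9))
    g2 <- rbinom(41, 2, runif(1, .1, .9))
    ge2 <- makeGeno(cbind(c(g1, g2)),
                    population = rep(c("a", "b"), c(17, 41)))
    expect_equal(wcComponents(ge2)$theta,
                 unname(wcOracle(g1, g2)["theta"]), tolerance = 1e-10)
  }
  # monomorphic across groups is uninformative
  expect_true(is.na(wcComponents(
    makeGeno(cbind(rep(0L, 20)),
             population = rep(c("a", "b"), each = 10)))$theta))
})

test_that("multilocus theta is order/duplication invariant (ratio of sums)", {
  ge <- bnPair(150, 20, 25, 0.1, seed = 17)
  comp <- wcComponents(ge)
  t1 <- wcTheta(comp)
  t2 <- wcTheta(comp[sample.int(nrow(comp)), ])
  expect_equal(t1, t2)
  codes2 <- genoCodes(ge)[rep(seq_len(45), 2), ]
  rownames(codes2) <- NULL
  dup <- makeGeno(codes2, population = rep(populations(ge), 2))
  expect_lt(abs(wcTheta(dup) - t1), 0.02)
})

test_that("bootstrap F_ST intervals behave sensibly", {
  ge <- bnPair(400, 30, 30, 0.1, seed = 23)
  fr <- fstWithCI(ge, reps = 300, seed = 1)
  expect_s3_class(fr, "FstResult")
  expect_true(fr$ci[1] < fr$theta && fr$theta < fr$ci[2])
  expect_lt(fr$p_value, 0.05)
  expect_output(print(fr), "multilocus theta")
  # identical resampling seed -> identical CI
  fr2 <- fstWithCI(ge, reps = 300, seed = 1)
  expect_identical(fr$ci, fr2$ci)
  # point estimate only
  fr0 <- fstWithCI(ge, reps = 0)
  expect_null(fr0$ci)
  expect_true(is.na(fr0$p_value))
  # panmictic data: CI straddles zero in most replicate worlds
  hits <- vapply(1:8, function(s) {
    g0 <- bnPair(400, 30, 30, 0, seed = 100 + s)
    ci <- fstWithCI(g0, reps = 200, seed = s)$ci
    ci[1] <= 0 && 0 <= ci[2]
  }, NA)
  expect_gte(mean(hits), 0.9)
  expect_error(fstWithCI(makeGeno(cbind(rep(0L, 10)),
                                  population = rep(c("a", "b"), 5))),
               "informative")
})

test_that("genotype PCA separates structured pairs and not panmictic ones", {
  ge <- bnPair(800, 40, 40, 0.09, seed = 3)
  pc <- pcaGenotypes(ge)
  grp <- populations(ge)
  s1 <- pc$scores[grp == "anad", 1]
  s2 <- pc$scores[grp == "res", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))  # zero overlap
  expect_true(all(pc$explained > 0))
  expect_lte(sum(pc$explained), 1 + 1e-8)
  # panmictic: no axis aligns with the labels
  g0 <- bnPair(800, 40, 40, 0, seed = 4)
  pc0 <- pcaGenotypes(g0)
  lab <- as.integer(populations(g0) == "anad")
  rmax <- max(abs(cor(pc0$scores[, 1:5], lab)))
  expect_lt(rmax, 0.3)
  # duplicated samples score identically
  dupc <- genoCodes(ge)[rep(seq_len(80), 2), ]
  rownames(dupc) <- NULL
  dup <- makeGeno(dupc, population = rep(populations(ge), 2))
  pcd <- pcaGenotypes(dup)
  expect_equal(pcd$scores[1:80, 1], pcd$scores[81:160, 1],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pcaGenotypes(makeGeno(matrix(1L, 5, 3))), "constant")
})

test_that("composite LD r2 matches its definition and sampling theory", {
  codes <- genoCodes(bnPair(2, 60, 60, 0, seed = 5))
  expect_equal(ldR2(codes, 1, 1), 1)
  dup <- cbind(codes, dup = codes[, 1])
  expect_equal(ldR2(dup, 1, 3), 1)
  # independent loci: mean r2 ~ 1/n within +-50%
  big <- genoCodes(bnPair(80, 200, 0, 0, seed = 6))
  R <- cor(big)^2
  mean_r2 <- mean(R[upper.tri(R)], na.rm = TRUE)
  expect_gt(mean_r2, 0.5 / 200)
  expect_lt(mean_r2, 1.5 / 200)
  # constant locus undefined
  cc <- cbind(codes[, 1], rep(1L, nrow(codes)))
  expect_true(is.na(ldR2(cc, 1, 2)))
})

test_that("LD-based Ne uses the documented small-sample branch", {
  wf <- simulateWrightFisher(50, n_loci = 120, n_generations = 12,
                             sample_size = 25, seed = 31)
  est <- neLdEstimate(wf)
  expect_equal(est$branch, "small-S")
  expect_true(est$ne > 0)
  expect_output(print(est), "small-S")
  wf2 <- simulateWrightFisher(50, n_loci = 120, n_generations = 12,
                              sample_size = 45, seed = 31)
  expect_equal(neLdEstimate(wf2)$branch, "large-S")
  expect_error(neLdEstimate(makeGeno(cbind(rep(1L, 10)))), "qualifying")
})
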