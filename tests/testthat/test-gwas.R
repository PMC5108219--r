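test_that("imputation fills missing codes from subpopulation frequencies", {
  sim <- simulatePair(pairScenario(30, 30, n_loci = 300, fst_target = 0.2,
                                   missing_rate = 0), seed = 61)
  # complete data: identity
  expect_identical(genoCodes(imputeGenotypes(sim$geno)),
                   genoCodes(sim$geno))
  # locus fixed in a subpopulation imputes the fixed code
  codes <- cbind(c(2L, 2L, 2L, NA, 0L, 0L, 0L, 0L))
  ge <- makeGeno(codes, population = rep(c("a", "b"), each = 4))
  imp <- imputeGenotypes(ge, seed = 1)
  expect_equal(unname(genoCodes(imp)[4, 1]), 2L)
  # masked-entry benchmark: beats global random guessing
  masked <- injectMissingness(sim$geno, 0.3, seed = 3)
  imp2 <- imputeGenotypes(masked, seed = 4)
  truth <- genoCodes(sim$geno)
  holes <- is.na(genoCodes(masked))
  err <- mean(genoCodes(imp2)[holes] != truth[holes])
  set.seed(5)
  guess <- sample(0:2, sum(holes), replace = TRUE)
  err_guess <- mean(guess != truth[holes])
  expect_lt(err, err_guess)
  # all-missing within a subpopulation falls back to global frequency
  codes2 <- cbind(c(NA, NA, 1L, 1L))
  ge2 <- makeGeno(codes2, population = rep(c("a", "b"), each = 2))
  expect_warning(imputeGenotypes(ge2, seed = 2), "global frequency")
})

test_that("VanRaden kinship matches hand computations", {
  # all heterozygous at p = 0.5 loci: Z = 0 so K = 0
  ge <- makeGeno(matrix(1L, 6, 40))
  expect_true(all(vanRadenKinship(ge) == 0))
  # individuals homozygous at every p-hat = 0.5 locus: diagonal 2
  codes <- rbind(matrix(1L, 10, 40),
                 rep(c(0L, 2L), 20), rep(c(2L, 0L), 20))
  K <- vanRadenKinship(makeGeno(codes))
  expect_equal(unname(diag(K)[11]), 2)
  expect_equal(unname(diag(K)[12]), 2)
  expect_equal(unname(K[11, 12]), -2)
  # clone: off-diagonal equals both diagonals
  set.seed(62)
  base <- matrix(rbinom(20 * 60, 2, 0.4), 20, 60)
  codes2 <- rbind(base, base[1, ])
  rownames(codes2) <- NULL
  K2 <- vanRadenKinship(makeGeno(codes2))
  expect_equal(K2[1, 21], K2[1, 1])
  expect_equal(K2[21, 21], K2[1, 1])
  expect_error(vanRadenKinship(makeGeno(matrix(2L, 5, 8))),
               "monomorphic")
  expect_error(vanRadenKinship(makeGeno(cbind(c(1L, NA, 0L)))),
               "complete")
})

test_that("covariate selection keeps only informative fixed effects", {
  set.seed(63)
  # phenotype identical to a candidate: that candidate always enters
  n <- 60
  K <- diag(n)
  y <- rbinom(n, 1, 0.5)
  sel <- selectCovariates(y, list(sex = rep(c("M", "F"), n / 2),
                                  PC1 = as.numeric(y)), K)
  expect_true("PC1" %in% sel)
  expect_false("sex" %in% sel)
  # structured pair: PC1 selected; pure noise candidates are not
  ge <- bnPair(600, 40, 40, 0.15, seed = 64)
  Ks <- vanRadenKinship(ge)
  pc <- pcaGenotypes(ge)$scores
  lh <- lifeHistory(ge)
  sel2 <- selectCovariates(lh, list(sex = sample(c("M", "F"), 80, TRUE),
                                    PC1 = pc[, 1], PC2 = pc[, 2],
                                    PC3 = pc[, 3]), Ks)
  expect_true("PC1" %in% sel2)
  expect_s3_class(attr(sel2, "bic_trace"), "data.frame")
})

test_that("marker mixed-model tests are calibrated and find true signals", {
  # perfect association ranks first and passes BY-FDR
  set.seed(65)
  n <- 60; L <- 150
  codes <- matrix(rbinom(n * L, 2, 0.4), n, L,
                  dimnames = list(sprintf("s%02d", 1:n),
                                  sprintf("L%03d", 1:L)))
  y <- as.integer(codes[, 7] >= 1)
  K <- vanRadenKinship(codes)
  fit <- fitMlmMarkerTests(y, codes, NULL, K)
  expect_equal(which.min(fit$tests$p), 7L)
  expect_true(fit$tests$significant[7])
  expect_output(print(fit), "MLM marker scan")
  # permuted phenotype on exchangeable (panmictic) genotypes: uniform p
  set.seed(66)
  ge <- bnPair(2000, 50, 50, 0, seed = 67)
  yperm <- sample(lifeHistory(ge))
  K2 <- vanRadenKinship(ge)
  fit2 <- fitMlmMarkerTests(yperm, ge, NULL, K2)
  ks <- suppressWarnings(
    ks.test(fit2$tests$p[is.finite(fit2$tests$p)], "punif")$statistic)
  expect_lt(unname(ks), 0.05)
  expect_true(all(fit2$tests$p > 0 & fit2$tests$p <= 1, na.rm = TRUE))
  expect_gte(fit2$sigma_g, 0)
  expect_gte(fit2$sigma_e, 0)
})

test_that("REML profile optimum is reproducible to tight tolerance", {
  ge <- bnPair(400, 30, 30, 0.1, seed = 68)
  K <- vanRadenKinship(ge)
  y <- lifeHistory(ge)
  f1 <- fitMlmMarkerTests(y, genoCodes(ge)[, 1:5], NULL, K)
  f2 <- fitMlmMarkerTests(y, genoCodes(ge)[, 1:5], NULL, K)
  expect_equal(f1$delta, f2$delta, tolerance = 1e-6)
  expect_equal(f1$sigma_g, f2$sigma_g, tolerance = 1e-6)
})

test_that("residualization removes fixed effects and kinship structure", {
  ge <- bnPair(500, 35, 35, 0.12, seed = 69)
  K <- vanRadenKinship(ge)
  pc <- pcaGenotypes(ge)$scores
  y <- lifeHistory(ge)
  Xf <- cbind(PC1 = pc[, 1])
  rd <- residualize(y, ge[1:40, ], Xf, K)
  expect_length(rd$phenotype, 70)
  expect_equal(dim(rd$genotypes), c(70L, 40L))
  # orthogonality to the selected fixed effect
  expect_lt(abs(cor(rd$phenotype, pc[, 1])), 0.05)
  # identical duplicate individuals with equal y get equal residuals
  codes <- genoCodes(ge)[c(1:10, 1:10), 1:50]
  rownames(codes) <- NULL
  yy <- rep(y[1:10], 2)
  Kd <- vanRadenKinship(codes)
  rd2 <- residualize(yy, codes, NULL, Kd)
  expect_equal(rd2$phenotype[1:10], rd2$phenotype[11:20],
               tolerance = 1e-6)
  # with negligible genetic variance the residual is ~ centered response
  set.seed(70)
  noise <- rnorm(70)
  rd3 <- residualize(noise, genoCodes(ge)[, 1:30], NULL, diag(70))
  expect_gt(cor(rd3$phenotype, noise - mean(noise)), 0.99)
})
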