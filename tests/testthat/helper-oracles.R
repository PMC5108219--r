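# Shared fixtures and independent oracles for the test suite.

# Build a GenotypeExperiment from a plain samples x loci matrix.
makeGeno <- function(codes, population = rep("p1", nrow(codes)),
                     lifeHistory = rep(NA_integer_, nrow(codes)),
                     sex = rep("U", nrow(codes))) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("s%02d", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- sprintf("L%03d", seq_len(ncol(codes)))
  GenotypeExperiment(codes, population = population,
                     lifeHistory = lifeHistory, sex = sex)
}

# Independent HWE exact-test oracle: enumerate every feasible heterozygote
# count via binomial coefficients (choose()), sum the Levene probabilities
# not exceeding the observed one. Distinct code path from the package's
# log-factorial implementation.
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  nB <- 2 * n - nA
  hs <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  pr <- vapply(hs, function(h) {
    choose(n, (nA - h) / 2) * choose(n - (nA - h) / 2, h) * 2^h /
      choose(2 * n, nA)
  }, 0)
  pr <- pr / sum(pr)
  obs <- pr[hs == nAa]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Independent Weir-Cockerham (1984) per-locus oracle, written directly
# from the published component formulas for complete two-group data.
wcOracle <- function(g1, g2) {
  cnt <- function(g) {
    n <- sum(!is.na(g))
    list(n = n, p = sum(g, na.rm = TRUE) / (2 * n),
         h = sum(g == 1, na.rm = TRUE) / n)
  }
  x <- cnt(g1); y <- cnt(g2)
  r <- 2
  nbar <- (x$n + y$n) / 2
  nc <- (r * nbar - (x$n^2 + y$n^2) / (r * nbar)) / (r - 1)
  pbar <- (x$n * x$p + y$n * y$p) / (r * nbar)
  s2 <- (x$n * (x$p - pbar)^2 + y$n * (y$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (x$n * x$h + y$n * y$h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Quick Balding-Nichols two-population genotype simulation used where a
# test needs raw matrices rather than the package generator.
bnPair <- function(L, n1, n2, c_par, seed, p_range = c(0.05, 0.95)) {
  set.seed(seed)
  p <- runif(L, p_range[1], p_range[2])
  draw <- function(p) if (c_par < 1e-9) p else
    rbeta(length(p), p * (1 - c_par) / c_par, (1 - p) * (1 - c_par) / c_par)
  p1 <- draw(p); p2 <- draw(p)
  codes <- rbind(
    matrix(rbinom(n1 * L, 2, rep(p1, each = n1)), n1, L),
    matrix(rbinom(n2 * L, 2, rep(p2, each = n2)), n2, L))
  dimnames(codes) <- list(sprintf("s%03d", seq_len(n1 + n2)),
                          sprintf("L%04d", seq_len(L)))
  makeGeno(codes, population = rep(c("anad", "res"), c(n1, n2)),
           lifeHistory = rep(c(1L, 0L), c(n1, n2)))
}
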