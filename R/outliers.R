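#' Calibrate the heterozygosity-conditioned neutral null for F_ST outliers
#'
#' Emulates the FDIST2/LOSITAN strategy with a Balding-Nichols F-model in
#' place of the coalescent island model: (1) the neutral mean theta is the
#' ratio-of-sums multilocus theta after excluding the 5% most extreme
#' per-locus theta values at each tail; (2) \code{n_sim} neutral loci are
#' simulated at that mean (ancestral frequency Uniform(0.05, 0.95),
#' group frequencies Beta-distributed, binomial genotypes at the observed
#' group sizes); (3) the divergence parameter is rescaled once if the
#' simulated mean theta misses the target by more than 0.005, and the
#' simulation repeated; (4) simulated loci are cut into 20 equal-count
#' bins of total expected heterozygosity. A non-positive target mean
#' degenerates to near-panmixia (c = 1e-6).
#'
#' @param ge a [GenotypeExperiment-class] of the observed data.
#' @param groups group assignment per sample (default: populations).
#' @param n_sim simulated loci (>= 10,000 recommended).
#' @param seed integer seed.
#' @param n_bins heterozygosity bins, default 20.
#' @return list of class \code{"NullDistribution"}: sim (data.frame He,
#'   theta, bin), bin_edges, target_theta, c_par, group_sizes, n_sim,
#'   seed.
#' @export
calibrateNull <- function(ge, groups = NULL, n_sim = 10000L, seed = 1L,
                          n_bins = 20L) {
  if (is.null(groups)) groups <- populations(ge)
  comp <- wcComponents(ge, groups)
  ok <- is.finite(comp$theta)
  if (sum(ok) < 50L) stop("need at least 50 informative loci")
  th <- comp$theta[ok]
  qs <- quantile(th, c(0.05, 0.95))
  trim <- ok
  trim[ok] <- th > qs[1] & th < qs[2]
  target <- wcTheta(comp[trim, , drop = FALSE])
  degenerate <- !is.finite(target) || target <= 0
  c_par <- if (degenerate) 1e-6 else min(target, 0.99)
  if (degenerate)
    message("neutral mean theta <= 0: null degenerates to panmixia")
  sizes <- vapply(split(seq_along(groups), groups), length, 0L)
  simOnce <- function(c_use, sd) withSeed(sd, {
    p_anc <- runif(n_sim, 0.05, 0.95)
    pmat <- hmat <- matrix(0, n_sim, length(sizes))
    for (k in seq_along(sizes)) {
      pk <- .bnFreq(p_anc, c_use)
      nk <- sizes[k]
      # multinomial HWE genotype counts, sequentially decomposed
      nAa <- rbinom(n_sim, nk, 2 * pk * (1 - pk))
      w <- pk^2 / (pk^2 + (1 - pk)^2)
      nAA <- rbinom(n_sim, nk - nAa, w)
      pmat[, k] <- (2 * nAA + nAa) / (2 * nk)
      hmat[, k] <- nAa / nk
    }
    .wcFromCounts(sizes, pmat, hmat)
  })
  # the target is a tail-trimmed mean, so the simulated cloud must be
  # summarised the same way or the rescaling inherits the trim's
  # downward bias (theta is right-skewed)
  trimmedMean <- function(s) {
    ok <- is.finite(s$theta)
    qs2 <- quantile(s$theta[ok], c(0.05, 0.95))
    use <- ok & s$theta > qs2[1] & s$theta < qs2[2]
    sum(s$a[use]) / sum(s$a[use] + s$b[use] + s$c[use])
  }
  sim <- simOnce(c_par, stageSeed(seed, "null-sim-1"))
  if (!degenerate) {
    m1 <- trimmedMean(sim)
    if (is.finite(m1) && abs(m1 - target) > 0.005 && m1 > 0) {
      c_par <- min(max(c_par * target / m1, 1e-6), 0.99)
      sim <- simOnce(c_par, stageSeed(seed, "null-sim-2"))
    }
  }
  keep <- is.finite(sim$theta) & is.finite(sim$He)
  sim <- sim[keep, , drop = FALSE]
  probs <- seq(0, 1, length.out = n_bins + 1L)
  edges <- unique(quantile(sim$He, probs))
  sim$bin <- findInterval(sim$He, edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
  structure(list(sim = sim, bin_edges = edges,
                 target_theta = if (degenerate) 0 else target,
                 c_par = c_par, group_sizes = sizes,
                 n_sim = as.integer(n_sim), seed = seed),
            class = "NullDistribution")
}

# Weir-Cockerham components from per-group sample allele frequencies and
# observed-het fractions (no genotype matrix needed; complete data, fixed
# group sizes). pmat/hmat are n_loci x n_groups.
.wcFromCounts <- function(sizes, pmat, hmat) {
  r <- length(sizes)
  ni <- as.numeric(sizes)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- as.vector(pmat %*% ni) / (r * nbar)
  s2 <- as.vector(((pmat - pbar)^2) %*% ni) / ((r - 1) * nbar)
  hbar <- as.vector(hmat %*% ni) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  theta <- ifelse(a + b + cc != 0, a / (a + b + cc), NA_real_)
  theta[pbar <= 0 | pbar >= 1] <- NA_real_
  He <- 2 * pbar * (1 - pbar)
  data.frame(He = He, theta = theta, a = a, b = b, c = cc)
}

#' Empirical p-values against the calibrated null
#'
#' Each observed locus is assigned to the heterozygosity bin of the null
#' its total He falls into; the empirical p-value is
#' p = (1 + #\{sim theta < obs\} + 0.5 #\{sim theta = obs\}) /
#' (1 + bin count) (add-one smoothing, mid-rank ties). Small p flags
#' unusually low differentiation (balancing), large p unusually high
#' differentiation (divergent).
#'
#' @param null a \code{"NullDistribution"} from [calibrateNull()].
#' @param ge the observed [GenotypeExperiment-class].
#' @param groups group assignment (must match the calibration).
#' @return data.frame of class \code{"OutlierResult"}: locus, theta, He,
#'   bin, p.
#' @export
empiricalPvalues <- function(null, ge, groups = NULL) {
  if (is.null(groups)) groups <- populations(ge)
  comp <- wcComponents(ge, groups)
  bin <- findInterval(comp$He_total, null$bin_edges,
                      rightmost.closed = TRUE, all.inside = TRUE)
  simsplit <- split(null$sim$theta, null$sim$bin)
  bins_present <- as.integer(names(simsplit))
  p <- rep(NA_real_, nrow(comp))
  for (i in seq_len(nrow(comp))) {
    if (!is.finite(comp$theta[i]) || !is.finite(comp$He_total[i])) next
    b <- bin[i]
    if (!b %in% bins_present) {       # empty bin: nearest populated one
      b <- bins_present[which.min(abs(bins_present - b))]
      warning("empty He bin for locus ", comp$locus[i],
              "; nearest bin used")
    }
    sims <- simsplit[[as.character(b)]]
    nle <- sum(sims < comp$theta[i]) + 0.5 * sum(sims == comp$theta[i])
    p[i] <- (1 + nle) / (1 + length(sims))
  }
  structure(data.frame(locus = comp$locus, theta = comp$theta,
                       He = comp$He_total, bin = bin, p = p,
                       row.names = NULL),
            class = c("OutlierResult", "data.frame"))
}

#' Classify loci as divergent, balancing or unclassified
#'
#' Divergent iff (1 - p) is below the BY-FDR threshold for m = number of
#' loci with a p-value; balancing iff p is below the same threshold.
#'
#' @param result an \code{"OutlierResult"} from [empiricalPvalues()].
#' @param q FDR level, default 0.05.
#' @return the result with added columns \code{class} (factor: divergent,
#'   balancing, unclassified) and attribute \code{"by_threshold"}.
#' @export
classifyOutliers <- function(result, q = 0.05) {
  m <- sum(is.finite(result$p))
  thr <- if (m >= 1) byFdrThreshold(m, q) else NA_real_
  cls <- rep("unclassified", nrow(result))
  cls[is.finite(result$p) & (1 - result$p) < thr] <- "divergent"
  cls[is.finite(result$p) & result$p < thr] <- "balancing"
  result$class <- factor(cls,
                         levels = c("divergent", "balancing", "unclassified"))
  attr(result, "by_threshold") <- thr
  result
}

#' Putatively neutral locus set across the three outlier analyses
#'
#' A locus is putatively neutral when its empirical p-value lies within
#' the closed band in \emph{all} supplied analyses (the two pairwise
#' scans and the combined four-collection scan). Loci missing a finite
#' p in any analysis are excluded and counted.
#'
#' @param results list of \code{"OutlierResult"} data.frames covering the
#'   same loci.
#' @param band closed p-value interval, default c(0.1, 0.9).
#' @return character vector of neutral locus ids, with attribute
#'   \code{"n_excluded_missing"}.
#' @export
neutralSet <- function(results, band = c(0.1, 0.9)) {
  stopifnot(length(results) >= 1L)
  loci <- results[[1]]$locus
  for (r in results) stopifnot(identical(sort(r$locus), sort(loci)))
  inband <- rep(TRUE, length(loci)); missing <- rep(FALSE, length(loci))
  for (r in results) {
    p <- r$p[match(loci, r$locus)]
    missing <- missing | !is.finite(p)
    inband <- inband & is.finite(p) & p >= band[1] & p <= band[2]
  }
  out <- loci[inband & !missing]
  attr(out, "n_excluded_missing") <- sum(missing)
  out
}
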