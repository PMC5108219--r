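#' Observed/expected heterozygosity and the fixation index
#'
#' Per locus and per group: Ho is the heterozygote fraction among
#' non-missing calls; He is Nei's unbiased expected heterozygosity
#' 2*p*q * 2n/(2n-1); F = 1 - Ho/He, defined only where He > 0
#' (monomorphic loci are excluded from the F mean). Group means carry
#' standard errors across loci.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param groups character vector assigning each sample to a group
#'   (default: collection labels).
#' @return list with \code{per_locus} (data.frame: group, locus, n, Ho,
#'   He, F) and \code{summary} (data.frame: group, mean and SE of Ho, He,
#'   F).
#' @export
heterozygosityStats <- function(ge, groups = populations(ge)) {
  codes <- genoCodes(ge)
  res <- lapply(unique(groups), function(g) {
    sub <- codes[groups == g, , drop = FALSE]
    if (nrow(sub) < 2L) stop("group '", g, "' has fewer than 2 individuals")
    ncall <- colSums(!is.na(sub))
    p <- colSums(sub, na.rm = TRUE) / pmax(2L * ncall, 1L)
    Ho <- colSums(sub == 1L, na.rm = TRUE) / pmax(ncall, 1L)
    He <- 2 * p * (1 - p) * ifelse(ncall > 0, 2 * ncall / (2 * ncall - 1), NA)
    Fi <- ifelse(He > 0, 1 - Ho / He, NA)
    data.frame(group = g, locus = colnames(sub), n = ncall, Ho = Ho,
               He = He, F = Fi, row.names = NULL)
  })
  per_locus <- do.call(rbind, res)
  se <- function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  summary <- do.call(rbind, lapply(split(per_locus, per_locus$group),
    function(d) data.frame(group = d$group[1],
      Ho = mean(d$Ho, na.rm = TRUE), Ho_se = se(d$Ho),
      He = mean(d$He, na.rm = TRUE), He_se = se(d$He),
      F = mean(d$F, na.rm = TRUE), F_se = se(d$F), row.names = NULL)))
  rownames(summary) <- NULL
  list(per_locus = per_locus, summary = summary)
}

#' Weir-Cockerham variance components per locus
#'
#' The 1984 two-level estimator for haploid-count data on diploids: for
#' each locus, components a (among populations), b (among individuals
#' within populations) and c (within individuals) are computed from the
#' per-group sample sizes, counted-allele frequencies and observed
#' heterozygote fractions; theta = a / (a + b + c). Negative estimates
#' are retained. Loci monomorphic across all groups (or with fewer than
#' two groups called) are uninformative and returned as NA.
#'
#' @param ge a [GenotypeExperiment-class] (or samples x loci codes
#'   matrix).
#' @param groups group assignment per sample (default: populations).
#' @return data.frame with one row per locus: locus, a, b, c, theta, and
#'   He_total (total expected heterozygosity 2*pbar*(1-pbar), used by the
#'   outlier scan's conditioning).
#' @export
wcComponents <- function(ge, groups = NULL) {
  codes <- if (is(ge, "GenotypeExperiment")) genoCodes(ge) else ge
  if (is.null(groups)) {
    stopifnot(is(ge, "GenotypeExperiment"))
    groups <- populations(ge)
  }
  gl <- unique(groups)
  r_all <- length(gl)
  if (r_all < 2L) stop("need at least two groups")
  L <- ncol(codes)
  nMat <- hMat <- pMat <- matrix(0, r_all, L)
  for (k in seq_len(r_all)) {
    sub <- codes[groups == gl[k], , drop = FALSE]
    ncall <- colSums(!is.na(sub))
    nMat[k, ] <- ncall
    pMat[k, ] <- ifelse(ncall > 0, colSums(sub, na.rm = TRUE) / (2 * ncall), NA)
    hMat[k, ] <- ifelse(ncall > 0, colSums(sub == 1L, na.rm = TRUE) / ncall, NA)
  }
  a <- b <- cc <- theta <- rep(NA_real_, L)
  He_total <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    use <- nMat[, j] > 0
    r <- sum(use)
    if (r < 2L) next
    ni <- nMat[use, j]; pi <- pMat[use, j]; hi <- hMat[use, j]
    nbar <- mean(ni)
    pbar <- sum(ni * pi) / (r * nbar)
    He_total[j] <- 2 * pbar * (1 - pbar)
    if (pbar <= 0 || pbar >= 1) next               # monomorphic overall
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    if (nbar <= 1 || nc <= 0) next
    a[j] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b[j] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar))
    cc[j] <- hbar / 2
    denom <- a[j] + b[j] + cc[j]
    theta[j] <- if (denom != 0) a[j] / denom else NA_real_
  }
  data.frame(locus = colnames(codes), a = a, b = b, c = cc, theta = theta,
             He_total = He_total, row.names = NULL)
}

#' Multilocus Weir-Cockerham theta (ratio of sums)
#'
#' @param comp data.frame from [wcComponents()] (or a
#'   [GenotypeExperiment-class], in which case components are computed
#'   with the given groups).
#' @param groups optional group assignment when \code{comp} is a genotype
#'   object.
#' @return scalar multilocus theta = sum(a) / sum(a + b + c) over
#'   informative loci.
#' @export
wcTheta <- function(comp, groups = NULL) {
  if (is(comp, "GenotypeExperiment")) comp <- wcComponents(comp, groups)
  ok <- is.finite(comp$a) & is.finite(comp$b) & is.finite(comp$c)
  if (!any(ok)) return(NA_real_)
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}

#' Pairwise F_ST with bootstrap confidence interval
#'
#' Multilocus Weir-Cockerham theta between two (or more) groups, with a
#' percentile 95% CI and a one-sided bootstrap p-value (fraction of
#' replicates with theta <= 0) obtained by resampling loci with
#' replacement.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param groups group assignment per sample (default: populations).
#' @param reps bootstrap replicates (0 for a point estimate only).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level, default 0.95.
#' @return list of class \code{"FstResult"}: theta, ci (or NULL),
#'   p_value (or NA), reps, n_loci (informative loci), per_locus
#'   components.
#' @export
fstWithCI <- function(ge, groups = NULL, reps = 1000L, seed = 1L,
                      conf = 0.95) {
  comp <- wcComponents(ge, groups)
  ok <- is.finite(comp$a) & is.finite(comp$b) & is.finite(comp$c)
  if (sum(ok) < 2L) stop("fewer than 2 informative loci")
  a <- comp$a[ok]; tot <- comp$a[ok] + comp$b[ok] + comp$c[ok]
  theta <- sum(a) / sum(tot)
  ci <- NULL; pval <- NA_real_
  if (reps > 0L) {
    boot <- withSeed(seed, {
      vapply(seq_len(reps), function(i) {
        idx <- sample.int(length(a), replace = TRUE)
        sum(a[idx]) / sum(tot[idx])
      }, 0)
    })
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
    pval <- mean(boot <= 0)
  }
  structure(list(theta = theta, ci = ci, p_value = pval,
                 reps = as.integer(reps), n_loci = sum(ok),
                 per_locus = comp), class = "FstResult")
}

#' @export
print.FstResult <- function(x, ...) {
  cat(sprintf("Weir-Cockerham multilocus theta = %.4f (%d loci)\n",
              x$theta, x$n_loci))
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap 95%% CI [%.4f, %.4f], p(theta<=0) = %.3f (%d reps)\n",
                x$ci[1], x$ci[2], x$p_value, x$reps))
  invisible(x)
}

#' Principal components of the genotype matrix
#'
#' Missing codes are mean-imputed per locus, columns centered by twice
#' the allele frequency, no scaling; scores come from the eigenvectors of
#' the sample covariance and are returned for every component with a
#' positive eigenvalue.
#'
#' @param ge a [GenotypeExperiment-class].
#' @return list with \code{scores} (samples x components, PC1...),
#'   \code{explained} (variance fractions) and \code{center}.
#' @export
pcaGenotypes <- function(ge) {
  codes <- genoCodes(ge)
  if (nrow(codes) < 2L || ncol(codes) < 2L)
    stop("need at least 2 samples and 2 loci")
  ctr <- 2 * .alleleFreq(codes)
  X <- sweep(codes, 2, ctr)
  X[is.na(X)] <- 0                       # mean imputation after centering
  pr <- prcomp(X, center = FALSE, scale. = FALSE)
  pos <- pr$sdev^2 > max(pr$sdev^2) * 1e-12
  if (!any(pos) || max(pr$sdev) == 0)
    stop("constant genotype matrix: no positive eigenvalues")
  scores <- pr$x[, pos, drop = FALSE]
  list(scores = scores, explained = (pr$sdev^2 / sum(pr$sdev^2))[pos],
       center = ctr)
}

#' Composite pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of 0/1/2 genotype codes over
#' pairwise-complete samples (composite LD; gametic phase unknown).
#' Returns NA when either locus is constant on the complete subset or
#' fewer than 2 complete samples exist.
#'
#' @param ge a [GenotypeExperiment-class] (or codes matrix).
#' @param locus_i,locus_j locus identifiers or column indices.
#' @return scalar r-squared.
#' @export
ldR2 <- function(ge, locus_i, locus_j) {
  codes <- if (is(ge, "GenotypeExperiment")) genoCodes(ge) else ge
  x <- codes[, locus_i]; y <- codes[, locus_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' LD-based effective population size (Waples random-mating method)
#'
#' Mean squared genotype correlation over all pairs of loci passing the
#' MAF cutoff, corrected for the sampling expectation at the harmonic
#' mean pairwise sample size S: for S >= 30, E(r^2 | drift = 0) =
#' 1/S + 3.19/S^2 and Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2'); for
#' S < 30 the small-sample forms 0.0018 + 0.907/S + 4.44/S^2 and
#' Ne = (0.308 + sqrt(0.308^2 - 2.08 r2')) / (2 r2') are used. A
#' non-positive corrected r2' reports an infinite estimate. The
#' parametric CI treats n_pairs * r2 / E(r2) as chi-square with df =
#' n_pairs (all pairs used; without a map, physically linked pairs cannot
#' be excluded, which biases estimates downward).
#'
#' @param ge a [GenotypeExperiment-class] (single population assumed).
#' @param maf_min MAF cutoff for qualifying loci, default 0.05.
#' @param conf confidence level for the parametric CI.
#' @return list of class \code{"NeEstimate"}: r2_mean, r2_drift, S,
#'   n_pairs, ne, ci, branch ("large-S" or "small-S").
#' @export
neLdEstimate <- function(ge, maf_min = 0.05, conf = 0.95) {
  codes <- if (is(ge, "GenotypeExperiment")) genoCodes(ge) else ge
  maf <- computeMaf(codes)
  keep <- !is.na(maf) & maf >= maf_min
  if (sum(keep) < 2L) stop("fewer than 2 qualifying loci")
  X <- codes[, keep, drop = FALSE]
  R <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))^2
  ut <- upper.tri(R)
  r2 <- R[ut]
  # pairwise complete sample sizes for the harmonic mean S
  M <- !is.na(X)
  Npair <- crossprod(M)[ut]
  ok <- is.finite(r2) & Npair >= 2
  r2 <- r2[ok]; Npair <- Npair[ok]
  n_pairs <- length(r2)
  if (n_pairs < 1L) stop("no informative locus pairs")
  S <- 1 / mean(1 / Npair)
  r2_mean <- mean(r2)
  neFrom <- function(r2m) {
    if (S >= 30) {
      rd <- r2m - (1 / S + 3.19 / S^2)
      if (rd <= 0) return(Inf)
      disc <- max(0, 1 / 9 - 2.76 * rd)
      (1 / 3 + sqrt(disc)) / (2 * rd)
    } else {
      rd <- r2m - (0.0018 + 0.907 / S + 4.44 / S^2)
      if (rd <= 0) return(Inf)
      disc <- max(0, 0.308^2 - 2.08 * rd)
      (0.308 + sqrt(disc)) / (2 * rd)
    }
  }
  branch <- if (S >= 30) "large-S" else "small-S"
  r2_drift <- r2_mean - if (S >= 30) 1 / S + 3.19 / S^2 else
    0.0018 + 0.907 / S + 4.44 / S^2
  alpha <- (1 - conf) / 2
  r2_ci <- n_pairs * r2_mean / qchisq(c(1 - alpha, alpha), df = n_pairs)
  ne_ci <- sort(vapply(r2_ci, neFrom, 0))
  structure(list(r2_mean = r2_mean, r2_drift = r2_drift, S = S,
                 n_pairs = n_pairs, ne = neFrom(r2_mean), ci = ne_ci,
                 branch = branch), class = "NeEstimate")
}

#' @export
print.NeEstimate <- function(x, ...) {
  cat(sprintf("LD Ne estimate: %s (95%% CI %s - %s)\n",
              format(round(x$ne, 1)), format(round(x$ci[1], 1)),
              format(round(x$ci[2], 1))))
  cat(sprintf("  mean r2 = %.5f, drift r2 = %.5f, S = %.1f, %d pairs (%s)\n",
              x$r2_mean, x$r2_drift, x$S, x$n_pairs, x$branch))
  invisible(x)
}
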