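#' Global minor allele frequency per locus
#'
#' MAF is computed globally across all samples: with p the frequency of
#' the counted allele among non-missing calls, MAF = min(p, 1 - p).
#' All-missing loci get NA and are flagged for removal downstream.
#'
#' @param ge a [GenotypeExperiment-class] (or a samples x loci codes
#'   matrix).
#' @return named numeric vector of per-locus MAF.
#' @export
computeMaf <- function(ge) {
  codes <- if (is(ge, "GenotypeExperiment")) genoCodes(ge) else ge
  p <- .alleleFreq(codes)
  pmin(p, 1 - p)
}

# observed heterozygosity per locus, global over non-missing calls
.obsHet <- function(codes)
  colSums(codes == 1L, na.rm = TRUE) / pmax(colSums(!is.na(codes)), 1L)

#' Remove individuals with low genotyping call rate
#'
#' Individuals with strictly fewer than \code{callrate_min} of loci
#' genotyped are removed (the boundary value is kept). This filter runs
#' before any locus filter.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param callrate_min minimum fraction of genotyped loci, default 0.75.
#' @return list with \code{geno} (filtered) and \code{report}
#'   (data.frame: sample_id, call_rate, removed).
#' @export
filterIndividuals <- function(ge, callrate_min = 0.75) {
  codes <- genoCodes(ge)
  cr <- rowSums(!is.na(codes)) / ncol(codes)
  removed <- cr < callrate_min
  list(geno = ge[, !removed],
       report = data.frame(sample_id = rownames(codes), call_rate = cr,
                           removed = removed, row.names = NULL))
}

#' Locus filters: MAF, excess heterozygosity, missingness
#'
#' Removes loci with (i) global MAF strictly below \code{maf_min}, (ii)
#' global observed heterozygosity strictly above \code{het_max} (putative
#' paralogous sequence variants), or (iii) a missing fraction strictly
#' above \code{missing_max}. All-missing loci are removed. Apply after
#' [filterIndividuals()].
#'
#' @param ge a [GenotypeExperiment-class].
#' @param maf_min,het_max,missing_max thresholds (strict inequalities for
#'   removal).
#' @return list with \code{geno} (filtered) and \code{report}
#'   (data.frame: locus, maf, het_obs, missing_frac, reason; reason ""
#'   when kept).
#' @export
filterLoci <- function(ge, maf_min = 0.05, het_max = 0.80,
                       missing_max = 0.30) {
  codes <- genoCodes(ge)
  maf <- computeMaf(codes)
  het <- .obsHet(codes)
  missf <- colMeans(is.na(codes))
  reason <- character(ncol(codes))
  reason[missf > missing_max] <- "missingness"
  reason[het > het_max] <- "heterozygosity"
  reason[is.na(maf) | maf < maf_min] <- "maf"   # earliest-listed filter wins
  keep <- reason == ""
  list(geno = ge[keep, ],
       report = data.frame(locus = colnames(codes), maf = maf,
                           het_obs = het, missing_frac = missf,
                           reason = reason, row.names = NULL))
}

#' Hardy-Weinberg exact test (Levene conditional distribution)
#'
#' Two-sided exact test for one biallelic locus in one population: the
#' number of heterozygotes h, conditional on the sample size and allele
#' counts, follows the Levene distribution; the p-value sums the
#' probabilities of every feasible h (same parity as the minor-allele
#' count) whose probability does not exceed that of the observed h
#' (probability method, with a 1e-9 relative tie tolerance).
#'
#' @param nAA,nAa,naa genotype counts (non-negative; n >= 1).
#' @return the exact two-sided p-value.
#' @examples
#' hweExactTest(2, 0, 2)   # 0.0857...
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("negative genotype counts")
  n <- nAA + nAa + naa
  if (n < 1) stop("empty sample")
  nA <- 2L * nAA + nAa
  nB <- 2L * n - nA
  nMin <- min(nA, nB)
  h <- seq(nMin %% 2L, nMin, by = 2L)          # feasible heterozygote counts
  logp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((nB - h) / 2) + h * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(nAa, h)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

#' Benjamini-Yekutieli per-test p-value threshold
#'
#' The simplified BY correction used throughout the pipeline: the
#' empirical significance threshold for m tests at FDR level q is
#' q / sum_{i=1..m}(1/i).
#'
#' @param m number of tests (>= 1).
#' @param q FDR level in (0, 1).
#' @return scalar p-value threshold.
#' @examples
#' byFdrThreshold(2593, 0.05)   # 0.005926
#' @export
byFdrThreshold <- function(m, q = 0.05) {
  stopifnot(m >= 1, q > 0, q < 1)
  q / sum(1 / seq_len(m))
}

#' Cross-population Hardy-Weinberg filter
#'
#' Computes the HWE exact p-value per locus within each collection and
#' removes loci significant (below the per-collection BY-FDR threshold,
#' m = loci tested in that collection) in three or more collections.
#' With fewer than three collections the filter is a warned no-op.
#'
#' @param ge a [GenotypeExperiment-class] with populations assigned.
#' @param q FDR level, default 0.05.
#' @param min_pops collections a locus must violate HWE in, default 3.
#' @return list with \code{geno}, \code{report} (data.frame: locus,
#'   n_significant, removed) and \code{hwe_p} (loci x populations matrix
#'   of exact p-values).
#' @export
hweCrossPopFilter <- function(ge, q = 0.05, min_pops = 3L) {
  codes <- genoCodes(ge)
  pops <- populations(ge)
  upops <- unique(pops)
  P <- matrix(NA_real_, ncol(codes), length(upops),
              dimnames = list(colnames(codes), upops))
  for (k in seq_along(upops)) {
    sub <- codes[pops == upops[k], , drop = FALSE]
    nAA <- colSums(sub == 2L, na.rm = TRUE)
    nAa <- colSums(sub == 1L, na.rm = TRUE)
    naa <- colSums(sub == 0L, na.rm = TRUE)
    ok <- (nAA + nAa + naa) >= 1L
    P[ok, k] <- vapply(which(ok),
                       function(j) hweExactTest(nAA[j], nAa[j], naa[j]), 0)
  }
  if (length(upops) < min_pops) {
    warning("fewer than ", min_pops,
            " collections: HWE cross-population filter skipped")
    nsig <- integer(ncol(codes)); removed <- rep(FALSE, ncol(codes))
  } else {
    thr <- vapply(seq_along(upops),
                  function(k) byFdrThreshold(sum(!is.na(P[, k])), q), 0)
    sig <- sweep(P, 2, thr, "<")
    nsig <- rowSums(sig, na.rm = TRUE)
    removed <- nsig >= min_pops
  }
  list(geno = ge[!removed, ],
       report = data.frame(locus = colnames(codes), n_significant = nsig,
                           removed = removed, row.names = NULL),
       hwe_p = P)
}

#' Full genotype QC chain
#'
#' Applies, in the fixed and logged order, the individual call-rate
#' filter, then the locus MAF / excess-heterozygosity / missingness
#' filters, then the cross-population HWE filter. The chain is idempotent.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param config a \code{"RunConfig"} from [pipelineConfig()].
#' @return list with \code{geno} (surviving genotypes), \code{summary}
#'   (data.frame of per-step removal counts) and the three per-step
#'   reports.
#' @export
qcFilter <- function(ge, config = pipelineConfig()) {
  st1 <- filterIndividuals(ge, config$indiv_callrate_min)
  st2 <- filterLoci(st1$geno, config$maf_min, config$het_max,
                    config$locus_missing_max)
  st3 <- suppressWarnings(hweCrossPopFilter(st2$geno, config$fdr_q))
  summary <- data.frame(
    step = c("individual_callrate", "locus_maf_het_missing", "locus_hwe"),
    samples_removed = c(sum(st1$report$removed), 0L, 0L),
    loci_removed = c(0L, sum(st2$report$reason != ""),
                     sum(st3$report$removed)))
  list(geno = st3$geno, summary = summary, individuals = st1$report,
       loci = st2$report, hwe = st3$report, hwe_p = st3$hwe_p)
}
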