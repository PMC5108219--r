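# Internal helpers: seed substreams and small numerics.

#' Derive a reproducible per-stage seed from a master seed
#'
#' All stochastic stages draw their RNG state from one master seed through
#' named substreams, so that re-running a single stage reproduces the full
#' pipeline's behaviour for that stage. The derived seed is a deterministic
#' hash of (master seed, stage name), kept below 2^31.
#'
#' @param seed master integer seed.
#' @param stage character stage name, e.g. "simulate", "null", "rf1".
#' @return an integer seed.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 12345) %%
               2147483587)
}

# with_seed: evaluate expr under a fixed RNG state, restoring the caller's.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# column allele frequency of the counted allele, ignoring NA
.alleleFreq <- function(codes) {
  colSums(codes, na.rm = TRUE) / (2 * colSums(!is.na(codes)))
}

#' Genomic inflation factor
#'
#' Median chi-square test statistic implied by a vector of p-values,
#' divided by the null median (0.4549); values near 1 indicate a
#' well-calibrated association scan.
#'
#' @param p vector of p-values.
#' @return the inflation factor lambda.
#' @export
genomicInflation <- function(p) {
  p <- p[is.finite(p) & p > 0 & p <= 1]
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}
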