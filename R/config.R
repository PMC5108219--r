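#' Pipeline run configuration
#'
#' Bundles every threshold and tuning constant of the analysis chain, with
#' defaults matching the published filter and testing choices: MAF < 0.05
#' removal, observed heterozygosity > 0.80 removal (paralog guard), locus
#' missingness > 0.30 removal, individual call rate < 0.75 removal, 5%
#' Benjamini-Yekutieli FDR, neutral-set empirical-p band [0.1, 0.9], 1,000
#' bootstrap replicates for F_ST confidence intervals, 10,000 simulated
#' loci for the outlier null, and random-forest settings of 10,000 initial
#' / 100,000 escalated trees, 0.90 convergence correlation and a 2% top
#' fraction.
#'
#' @param seed master integer seed; every stochastic stage derives its own
#'   substream from it via [stageSeed()].
#' @param maf_min,het_max,locus_missing_max,indiv_callrate_min QC
#'   thresholds (strict inequalities for removal, as phrased in the field:
#'   "less than", "greater than").
#' @param fdr_q FDR level for every multiple-testing correction.
#' @param neutral_band closed empirical-p interval defining putatively
#'   neutral loci across the three outlier analyses.
#' @param bootstrap_reps bootstrap replicates for F_ST CIs.
#' @param null_sim_loci simulated loci in the outlier null distribution.
#' @param rf_trees_initial,rf_trees_escalated,rf_convergence_r,rf_top_fraction
#'   random-forest stage settings.
#' @return a validated list of class \code{"RunConfig"}.
#' @export
pipelineConfig <- function(seed = 1L,
                           maf_min = 0.05, het_max = 0.80,
                           locus_missing_max = 0.30,
                           indiv_callrate_min = 0.75,
                           fdr_q = 0.05, neutral_band = c(0.1, 0.9),
                           bootstrap_reps = 1000L,
                           null_sim_loci = 10000L,
                           rf_trees_initial = 10000L,
                           rf_trees_escalated = 100000L,
                           rf_convergence_r = 0.90,
                           rf_top_fraction = 0.02) {
  cfg <- list(seed = as.integer(seed), maf_min = maf_min, het_max = het_max,
              locus_missing_max = locus_missing_max,
              indiv_callrate_min = indiv_callrate_min, fdr_q = fdr_q,
              neutral_band = as.numeric(neutral_band),
              bootstrap_reps = as.integer(bootstrap_reps),
              null_sim_loci = as.integer(null_sim_loci),
              rf_trees_initial = as.integer(rf_trees_initial),
              rf_trees_escalated = as.integer(rf_trees_escalated),
              rf_convergence_r = rf_convergence_r,
              rf_top_fraction = rf_top_fraction)
  inRange <- function(x, lo, hi) is.numeric(x) && length(x) == 1L &&
    is.finite(x) && x >= lo && x <= hi
  stopifnot(inRange(cfg$maf_min, 0, 0.5), inRange(cfg$het_max, 0, 1),
            inRange(cfg$locus_missing_max, 0, 1),
            inRange(cfg$indiv_callrate_min, 0, 1),
            inRange(cfg$fdr_q, 1e-6, 1 - 1e-6),
            length(cfg$neutral_band) == 2L,
            cfg$neutral_band[1] < cfg$neutral_band[2],
            inRange(cfg$neutral_band[1], 0, 1),
            inRange(cfg$neutral_band[2], 0, 1),
            cfg$bootstrap_reps >= 0L, cfg$null_sim_loci >= 100L,
            cfg$rf_trees_initial >= 1L,
            cfg$rf_trees_escalated >= cfg$rf_trees_initial,
            inRange(cfg$rf_convergence_r, 0, 1),
            inRange(cfg$rf_top_fraction, 1e-6, 1))
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [pipelineConfig()]; absent keys keep their
#' defaults. YAML is used when the \pkg{yaml} package is available (it is
#' part of the standard toolchain), JSON always works.
#'
#' @param path config file (.yaml/.yml/.json).
#' @return a \code{"RunConfig"} list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package unavailable; supply a JSON config")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig:\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k,
                                  paste(x[[k]], collapse = ", ")))
  invisible(x)
}
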