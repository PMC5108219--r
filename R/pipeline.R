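#' Run the full resident/anadromous analysis chain
#'
#' Executes, in order: genotype QC ([qcFilter()]); diversity statistics
#' and pairwise F_ST with bootstrap CIs; the heterozygosity-conditioned
#' outlier scan for each lake-system pair and for all collections
#' combined, with BY-FDR classification and the neutral-set rule; the
#' kinship-corrected mixed-model GWAS (imputation, VanRaden kinship,
#' covariate selection, P3D marker tests) for the same analyses; and the
#' random-forest backward purge on residualized data. Per-stage tables,
#' a log recording the seed and every threshold, and a machine-readable
#' JSON summary are written to \code{out_dir}. All randomness derives
#' from \code{config$seed} via named substreams, so identical inputs and
#' config give byte-identical outputs.
#'
#' @param genotypes a [GenotypeExperiment-class], or the path of a
#'   genotype TSV ([readGenotypeTsv()]) or genepop file.
#' @param samples optional sample-table path (required when
#'   \code{genotypes} is a TSV path); ignored for an in-memory object.
#' @param config a \code{"RunConfig"}; see [pipelineConfig()].
#' @param out_dir output directory, created if needed.
#' @return (invisibly) a list with the per-stage results and the summary.
#' @export
runPipeline <- function(genotypes, samples = NULL,
                        config = pipelineConfig(), out_dir = "ecoscan_out") {
  stopifnot(inherits(config, "RunConfig"))
  stage <- "input"
  result <- tryCatch(
    .runPipelineImpl(genotypes, samples, config, out_dir,
                     function(s) stage <<- s),
    error = function(e)
      stop("pipeline failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE))
  invisible(result)
}

.runPipelineImpl <- function(genotypes, samples, config, out_dir,
                             setStage) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
    message(line)
  }
  cat("", file = logfile)
  logmsg("pipeline start; seed = %d", config$seed)
  for (k in setdiff(names(config), "seed"))
    logmsg("config %s = %s", k, paste(config[[k]], collapse = ", "))

  setStage("input")
  if (is.character(genotypes)) {
    if (is.null(samples)) {
      ge <- readGenepop(genotypes)
    } else {
      if (!file.exists(samples)) stop("sample table not found: ", samples)
      ge <- readGenotypeTsv(genotypes, readSampleTable(samples))
    }
  } else ge <- genotypes
  stopifnot(is(ge, "GenotypeExperiment"))
  writeTab <- function(d, f)
    write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)

  setStage("qc")
  qc <- qcFilter(ge, config)
  writeTab(qc$summary, "qc_summary.tsv")
  writeTab(qc$loci, "qc_loci.tsv")
  writeTab(qc$individuals, "qc_individuals.tsv")
  geq <- qc$geno
  logmsg("QC: %d/%d samples, %d/%d loci retained", nSamples(geq),
         nSamples(ge), nLoci(geq), nLoci(ge))

  # analysis plan: one per pair + combined (when >1 pair)
  cd <- SummarizedExperiment::colData(geq)
  pair <- if ("pair" %in% colnames(cd)) as.character(cd$pair) else {
    if (length(unique(populations(geq))) > 2L)
      stop("more than two populations but no 'pair' column in the sample table")
    rep("pair1", nSamples(geq))
  }
  analyses <- lapply(unique(pair), function(p) which(pair == p))
  names(analyses) <- unique(pair)
  if (length(analyses) > 1L)
    analyses$combined <- seq_len(nSamples(geq))

  setStage("popgen")
  div <- heterozygosityStats(geq)
  writeTab(div$summary, "diversity_summary.tsv")
  writeTab(div$per_locus, "diversity_per_locus.tsv")
  pops <- populations(geq)
  upop <- unique(pops)
  fst_rows <- list()
  for (i in seq_along(upop)) for (j in seq_len(i - 1L)) {
    sel <- pops %in% c(upop[i], upop[j])
    fr <- fstWithCI(geq[, sel], reps = config$bootstrap_reps,
                    seed = stageSeed(config$seed,
                                     paste0("fst-", upop[j], "-", upop[i])))
    fst_rows[[length(fst_rows) + 1L]] <- data.frame(
      pop1 = upop[j], pop2 = upop[i], theta = fr$theta,
      ci_lo = if (is.null(fr$ci)) NA else fr$ci[1],
      ci_hi = if (is.null(fr$ci)) NA else fr$ci[2],
      p_value = fr$p_value, n_loci = fr$n_loci)
  }
  fst_table <- do.call(rbind, fst_rows)
  writeTab(fst_table, "fst_pairwise.tsv")
  pca <- pcaGenotypes(geq)
  writeTab(data.frame(sample_id = rownames(pca$scores),
                      pca$scores[, seq_len(min(5, ncol(pca$scores))),
                                 drop = FALSE]), "pca_scores.tsv")

  setStage("outliers")
  scans <- list()
  for (an in names(analyses)) {
    sel <- analyses[[an]]
    sub <- geq[, sel]
    null <- calibrateNull(sub, n_sim = config$null_sim_loci,
                          seed = stageSeed(config$seed,
                                           paste0("null-", an)))
    res <- suppressWarnings(empiricalPvalues(null, sub))
    res <- classifyOutliers(res, config$fdr_q)
    scans[[an]] <- res
    writeTab(res, sprintf("outliers_%s.tsv", an))
    logmsg("outliers[%s]: %d divergent, %d balancing of %d loci", an,
           sum(res$class == "divergent"), sum(res$class == "balancing"),
           nrow(res))
  }
  neutral <- neutralSet(scans, config$neutral_band)
  writeLines(neutral, file.path(out_dir, "neutral_loci.txt"))
  logmsg("neutral set: %d loci (%.0f%%)", length(neutral),
         100 * length(neutral) / nLoci(geq))

  setStage("ne")
  ne_rows <- lapply(upop, function(p) {
    est <- tryCatch(
      neLdEstimate(geq[neutral, pops == p], maf_min = config$maf_min),
      error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(population = p, ne = est$ne, ci_lo = est$ci[1],
               ci_hi = est$ci[2], r2_mean = est$r2_mean, S = est$S,
               n_pairs = est$n_pairs)
  })
  ne_table <- do.call(rbind, ne_rows)
  if (!is.null(ne_table)) writeTab(ne_table, "ne_ld.tsv")

  setStage("gwas")
  gwas <- list(); resid <- list()
  for (an in names(analyses)) {
    sel <- analyses[[an]]
    sub <- geq[, sel]
    lh <- lifeHistory(sub)
    use <- !is.na(lh)
    sub <- sub[, use]; lh <- lh[use]
    if (length(unique(lh)) < 2L) {
      logmsg("gwas[%s]: phenotype constant, skipped", an); next
    }
    imp <- suppressWarnings(imputeGenotypes(
      sub, seed = stageSeed(config$seed, paste0("impute-", an))))
    K <- vanRadenKinship(imp)
    pc <- pcaGenotypes(imp)$scores
    cand <- list(sex = sexes(imp))
    for (k in seq_len(min(3, ncol(pc)))) cand[[paste0("PC", k)]] <- pc[, k]
    selcov <- selectCovariates(lh, cand, K)
    Xf <- if (length(selcov)) {
      do.call(cbind, lapply(selcov, function(nm) {
        v <- cand[[nm]]
        if (is.character(v)) as.integer(factor(v)) else v
      }))
    } else NULL
    if (!is.null(Xf)) colnames(Xf) <- selcov
    fit <- fitMlmMarkerTests(lh, imp, Xf, K, q = config$fdr_q)
    gwas[[an]] <- list(fit = fit, covariates = selcov)
    writeTab(fit$tests, sprintf("gwas_%s.tsv", an))
    logmsg("gwas[%s]: covariates {%s}; %d significant; lambda = %.3f", an,
           paste(selcov, collapse = ","),
           sum(fit$tests$significant, na.rm = TRUE), fit$lambda)
    resid[[an]] <- list(data = residualize(lh, imp, Xf, K),
                        geno = imp)
  }

  setStage("rf")
  rf <- list()
  for (an in names(resid)) {
    rd <- resid[[an]]$data
    run <- suppressWarnings(rfImportanceConverged(
      rd$genotypes, rd$phenotype, config$rf_trees_initial,
      config$rf_trees_escalated, config$rf_convergence_r,
      seed = stageSeed(config$seed, paste0("rf-full-", an))))
    subset <- selectTopUnion(run, config$rf_top_fraction)
    if (length(subset) < 3L)
      subset <- names(sort(run$mean_importance, decreasing = TRUE))[1:3]
    purge <- suppressWarnings(backwardPurge(
      rd$genotypes[, subset, drop = FALSE], rd$phenotype,
      config$rf_trees_initial, config$rf_trees_escalated,
      config$rf_convergence_r,
      seed = stageSeed(config$seed, paste0("rf-purge-", an))))
    rf[[an]] <- list(full_run = run, subset = subset, purge = purge)
    writeTab(purge$steps, sprintf("rf_purge_%s.tsv", an))
    writeLines(purge$best_markers,
               file.path(out_dir, sprintf("rf_best_markers_%s.txt", an)))
    logmsg("rf[%s]: union %d markers; best subset %d markers, pseudo-R2 = %.3f",
           an, length(subset), length(purge$best_markers),
           purge$best_pseudo_r2)
  }

  setStage("summary")
  summary <- list(
    seed = config$seed,
    n_samples_input = nSamples(ge), n_loci_input = nLoci(ge),
    n_samples_qc = nSamples(geq), n_loci_qc = nLoci(geq),
    analyses = names(analyses),
    n_outlier_analyses = length(scans),
    n_gwas_analyses = length(gwas),
    n_rf_analyses = length(rf),
    n_neutral = length(neutral),
    fst = fst_table,
    outlier_counts = lapply(scans, function(s) table(s$class)),
    gwas_significant = lapply(gwas, function(g)
      sum(g$fit$tests$significant, na.rm = TRUE)),
    rf_best = lapply(rf, function(r)
      list(n_markers = length(r$purge$best_markers),
           pseudo_r2 = r$purge$best_pseudo_r2)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  logmsg("pipeline done")
  invisible(list(geno = geq, qc = qc, diversity = div, fst = fst_table,
                 pca = pca, scans = scans, neutral = neutral,
                 ne = ne_table, gwas = gwas, residuals = resid, rf = rf,
                 summary = summary))
}
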