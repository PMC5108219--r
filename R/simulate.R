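#' Describe a resident/anadromous pair scenario
#'
#' A scenario captures the statistical structure of one lake system: two
#' collections (anadromous and resident) genotyped at unlinked biallelic
#' loci, with divergence controlled by a Balding-Nichols F-model
#' (per-population allele frequencies Beta-distributed around a shared
#' ancestral frequency, with variance parameter equal to the target
#' F_ST). Two presets mirror the emulated study system:
#' \code{divergentPairScenario()} is the strongly differentiated pair
#' (103 anadromous / 45 resident, F_ST 0.09) and
#' \code{panmicticPairScenario()} the undifferentiated pair
#' (14 anadromous / 49 resident, F_ST 0) whose phenotype is instead driven
#' by planted causal loci through a liability threshold.
#'
#' @param n_anadromous,n_resident sample sizes of the two collections.
#' @param n_loci number of unlinked biallelic loci.
#' @param fst_target background divergence parameter in [0, 1).
#' @param n_outlier_loci number of planted divergent-selection loci.
#' @param outlier_fst elevated divergence at planted outliers (must exceed
#'   \code{fst_target} when outliers are planted).
#' @param n_causal_loci number of planted causal loci for the binary
#'   life-history phenotype (used by the liability model in panmictic
#'   scenarios).
#' @param effect_size per-allele liability shift of causal loci, in
#'   residual-SD units.
#' @param causal_maf_min causal loci are planted only at loci whose
#'   ancestral frequency lies in [causal_maf_min, 1 - causal_maf_min]
#'   (default 0.2): a rare causal variant carries almost no association
#'   information at these sample sizes.
#' @param missing_rate independent per-cell missingness probability.
#' @param maf_range ancestral-frequency range (uniform draw).
#' @param pair label used for the pair grouping column.
#' @return a validated list of class \code{"PairScenario"}.
#' @export
pairScenario <- function(n_anadromous, n_resident, n_loci = 2600L,
                         fst_target = 0, n_outlier_loci = 0L,
                         outlier_fst = 0, n_causal_loci = 0L,
                         effect_size = 0.8, missing_rate = 0.02,
                         maf_range = c(0.05, 0.95), causal_maf_min = 0.2,
                         pair = "pair1") {
  sc <- list(n_anadromous = as.integer(n_anadromous),
             n_resident = as.integer(n_resident),
             n_loci = as.integer(n_loci), fst_target = fst_target,
             n_outlier_loci = as.integer(n_outlier_loci),
             outlier_fst = outlier_fst,
             n_causal_loci = as.integer(n_causal_loci),
             effect_size = effect_size, missing_rate = missing_rate,
             maf_range = maf_range, causal_maf_min = causal_maf_min,
             pair = pair)
  stopifnot(sc$n_anadromous >= 2L, sc$n_resident >= 2L, sc$n_loci >= 1L,
            sc$fst_target >= 0, sc$fst_target < 1,
            sc$missing_rate >= 0, sc$missing_rate < 1,
            sc$n_outlier_loci >= 0L, sc$n_causal_loci >= 0L,
            sc$n_outlier_loci + sc$n_causal_loci <= sc$n_loci)
  if (sc$n_outlier_loci > 0L && sc$outlier_fst <= sc$fst_target)
    stop("outlier_fst must exceed fst_target when outliers are planted")
  structure(sc, class = "PairScenario")
}

#' @rdname pairScenario
#' @export
divergentPairScenario <- function(n_anadromous = 103L, n_resident = 45L,
                                  n_loci = 2600L, fst_target = 0.09, ...)
  pairScenario(n_anadromous, n_resident, n_loci, fst_target,
               pair = "divergent", ...)

#' @rdname pairScenario
#' @export
panmicticPairScenario <- function(n_anadromous = 14L, n_resident = 49L,
                                  n_loci = 2600L, ...)
  pairScenario(n_anadromous, n_resident, n_loci, fst_target = 0,
               pair = "panmictic", ...)

# Balding-Nichols subpopulation frequencies around ancestral p with
# divergence c; c -> 0 collapses to the shared frequency.
.bnFreq <- function(p, c_par) {
  if (c_par < 1e-9) return(p)
  rbeta(length(p), p * (1 - c_par) / c_par, (1 - p) * (1 - c_par) / c_par)
}

#' Simulate a resident/anadromous genotype dataset
#'
#' Draws ancestral allele frequencies uniformly on the scenario's
#' \code{maf_range}, per-population frequencies from the Balding-Nichols
#' F-model at \code{fst_target} (or \code{outlier_fst} at planted outlier
#' loci), and genotypes as Binomial(2, p) within each population (HWE
#' within populations). For a divergent scenario (\code{fst_target > 0})
#' the binary life-history phenotype equals the collection label, as in a
#' system where ecotype and population coincide. For a panmictic scenario
#' the phenotype comes from a liability model: standard-normal noise plus
#' \code{effect_size} per causal allele (centered), thresholded so that
#' exactly \code{n_anadromous} individuals are anadromous; collection
#' labels then follow the phenotype. Sex is Bernoulli(0.5); missingness is
#' injected independently per cell at \code{missing_rate}.
#'
#' @param scenario a \code{"PairScenario"} from [pairScenario()].
#' @param seed integer seed (all randomness of this call).
#' @param prefix prefix for population/sample/locus identifiers.
#' @return a list with elements \code{geno} (a
#'   [GenotypeExperiment-class]) and \code{truth} (list: outlier and
#'   causal locus ids, ancestral frequencies \code{p_anc}, realized
#'   per-population frequencies \code{p_pop}, scenario).
#' @export
simulatePair <- function(scenario, seed = 1L, prefix = scenario$pair) {
  stopifnot(inherits(scenario, "PairScenario"))
  withSeed(seed, {
    L <- scenario$n_loci
    nA <- scenario$n_anadromous; nR <- scenario$n_resident
    n <- nA + nR
    p_anc <- runif(L, scenario$maf_range[1], scenario$maf_range[2])
    cvec <- rep(scenario$fst_target, L)
    outlier_idx <- integer(0)
    if (scenario$n_outlier_loci > 0L) {
      outlier_idx <- sample.int(L, scenario$n_outlier_loci)
      cvec[outlier_idx] <- scenario$outlier_fst
    }
    causal_idx <- integer(0)
    if (scenario$n_causal_loci > 0L) {
      mm <- scenario$causal_maf_min
      eligible <- setdiff(which(p_anc >= mm & p_anc <= 1 - mm),
                          outlier_idx)
      if (length(eligible) < scenario$n_causal_loci)
        stop("too few common loci available to plant causal effects")
      causal_idx <- sample(eligible, scenario$n_causal_loci)
    }
    p1 <- vapply(seq_len(L), function(j) .bnFreq(p_anc[j], cvec[j]), 0)
    p2 <- vapply(seq_len(L), function(j) .bnFreq(p_anc[j], cvec[j]), 0)

    divergent <- scenario$fst_target > 0
    if (divergent) {
      g1 <- matrix(rbinom(nA * L, 2L, rep(p1, each = nA)), nA, L)
      g2 <- matrix(rbinom(nR * L, 2L, rep(p2, each = nR)), nR, L)
      codes <- rbind(g1, g2)
      lh <- c(rep(1L, nA), rep(0L, nR))
    } else {
      # one gene pool; phenotype via liability over planted causal loci
      codes <- matrix(rbinom(n * L, 2L, rep(p1, each = n)), n, L)
      liab <- rnorm(n)
      if (length(causal_idx)) {
        gC <- codes[, causal_idx, drop = FALSE]
        gC <- sweep(gC, 2, colMeans(gC))
        liab <- liab + scenario$effect_size * rowSums(gC)
      }
      lh <- integer(n)
      lh[order(liab, decreasing = TRUE)[seq_len(nA)]] <- 1L
      ord <- order(-lh)               # anadromous first, stable grouping
      codes <- codes[ord, , drop = FALSE]
      lh <- lh[ord]
    }
    locus_ids <- sprintf("%s_L%04d", prefix, seq_len(L))
    dimnames(codes) <- list(sprintf("%s_S%03d", prefix, seq_len(n)),
                            locus_ids)
    pop <- ifelse(lh == 1L, paste0(prefix, "_anadromous"),
                  paste0(prefix, "_resident"))
    sex <- sample(c("M", "F"), n, replace = TRUE)
    ge <- GenotypeExperiment(codes, population = pop, lifeHistory = lh,
                             sex = sex)
    SummarizedExperiment::colData(ge)$pair <- scenario$pair
    if (scenario$missing_rate > 0)
      ge <- injectMissingness(ge, scenario$missing_rate,
                              seed = stageSeed(seed, "missingness"))
    list(geno = ge,
         truth = list(outlier_locus_ids = locus_ids[sort(outlier_idx)],
                      causal_locus_ids = locus_ids[sort(causal_idx)],
                      p_anc = setNames(p_anc, locus_ids),
                      p_pop = rbind(anadromous = p1, resident = p2),
                      scenario = scenario))
  })
}

#' Combine two simulated pairs into one four-collection dataset
#'
#' The emulated study genotypes all four collections at one shared locus
#' panel, so the two simulated pairs are stacked on a common panel by
#' identifying their loci positionally (equal \code{n_loci} required) and
#' renaming them \code{L0001, L0002, ...}; truth sets are relabelled
#' accordingly.
#'
#' @param divergent,panmictic results of [simulatePair()] with equal locus
#'   counts.
#' @return a list with \code{geno} (combined [GenotypeExperiment-class])
#'   and \code{truth} (per-pair truth lists).
#' @export
combinePairs <- function(divergent, panmictic) {
  gd <- divergent$geno; gp <- panmictic$geno
  if (nLoci(gd) != nLoci(gp))
    stop("pairs must be simulated at the same number of loci")
  shared <- sprintf("L%04d", seq_len(nLoci(gd)))
  cd <- genoCodes(gd); colnames(cd) <- shared
  cp <- genoCodes(gp); colnames(cp) <- shared
  codes <- rbind(cd, cp)
  ge <- GenotypeExperiment(codes,
    population = c(populations(gd), populations(gp)),
    lifeHistory = c(lifeHistory(gd), lifeHistory(gp)),
    sex = c(sexes(gd), sexes(gp)))
  SummarizedExperiment::colData(ge)$pair <-
    c(SummarizedExperiment::colData(gd)$pair,
      SummarizedExperiment::colData(gp)$pair)
  relabel <- function(tr) {
    tr$outlier_locus_ids <- shared[match(tr$outlier_locus_ids,
                                         names(tr$p_anc))]
    tr$causal_locus_ids <- shared[match(tr$causal_locus_ids,
                                        names(tr$p_anc))]
    names(tr$p_anc) <- shared
    tr
  }
  list(geno = ge, truth = list(divergent = relabel(divergent$truth),
                               panmictic = relabel(panmictic$truth)))
}

#' Inject missing genotypes completely at random
#'
#' @param ge a [GenotypeExperiment-class].
#' @param rate per-cell missingness probability in [0, 1).
#' @param seed integer seed; the same seed reproduces the same mask.
#' @return the genotype object with additional NA cells.
#' @export
injectMissingness <- function(ge, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(ge)
  codes <- genoCodes(ge)
  mask <- withSeed(seed,
    matrix(runif(length(codes)) < rate, nrow(codes), ncol(codes)))
  codes[mask] <- NA_integer_
  out <- ge
  SummarizedExperiment::assay(out, "codes") <- t(codes)
  out
}

#' Forward Wright-Fisher simulation of unlinked diploid genotypes
#'
#' Propagates \code{ne} diploid individuals for \code{n_generations} of
#' random mating (parents drawn with replacement; free recombination, one
#' binomially sampled gamete per parent per locus), then draws
#' \code{sample_size} offspring of the final generation. Finite parent
#' numbers generate the drift linkage disequilibrium that the LD method
#' for effective population size measures. Initial allele frequencies are
#' Uniform(0.2, 0.8). For \code{ne > 1e5} the explicit parent population
#' is replaced by its infinite-parent limit (independent HWE draws from
#' drifting frequencies), which carries no drift LD -- the regime in which
#' the LD estimate is expected to be effectively infinite.
#'
#' @param ne effective (= census, here) number of diploid parents, >= 2.
#' @param n_loci number of unlinked loci.
#' @param n_generations generations of drift, >= 1. A short burn-in
#'   (default 20) is enough for the unlinked-locus LD to approach its
#'   drift equilibrium, which recombination resets by half each
#'   generation.
#' @param sample_size diploids sampled from the final generation (may
#'   exceed \code{ne}).
#' @param seed integer seed.
#' @return a [GenotypeExperiment-class] with one population.
#' @export
simulateWrightFisher <- function(ne, n_loci = 500L, n_generations = 20L,
                                 sample_size = 50L, seed = 1L) {
  stopifnot(ne >= 2, n_loci >= 1, sample_size >= 2)
  if (n_generations < 1L) stop("n_generations must be >= 1")
  withSeed(seed, {
    L <- as.integer(n_loci)
    p <- runif(L, 0.2, 0.8)
    offspringOf <- function(G, n_off) {
      # one gamete from each of two random parents, per offspring
      p1 <- sample.int(nrow(G), n_off, replace = TRUE)
      p2 <- sample.int(nrow(G), n_off, replace = TRUE)
      gam <- function(idx) {
        pg <- G[idx, , drop = FALSE] / 2
        matrix(rbinom(length(pg), 1L, pg), nrow = n_off)
      }
      gam(p1) + gam(p2)
    }
    if (ne > 1e5) {
      for (g in seq_len(n_generations))
        p <- rbinom(L, 2L * 1e5, p) / (2 * 1e5)   # negligible drift
      codes <- matrix(rbinom(sample_size * L, 2L, rep(p, each = sample_size)),
                      sample_size, L)
    } else {
      G <- matrix(rbinom(ne * L, 2L, rep(p, each = ne)), ne, L)
      for (g in seq_len(n_generations)) G <- offspringOf(G, ne)
      codes <- offspringOf(G, sample_size)
    }
    dimnames(codes) <- list(sprintf("wf_S%04d", seq_len(nrow(codes))),
                            sprintf("wf_L%04d", seq_len(L)))
    GenotypeExperiment(codes, population = rep("wf", nrow(codes)))
  })
}
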