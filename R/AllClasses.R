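#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData colData<-
#' @importFrom S4Vectors DataFrame
#' @importFrom stats var cor sd median quantile rbinom rnorm runif rbeta
#'   optimize qchisq pchisq qnorm pt prcomp setNames complete.cases ks.test
#'   pnorm
#' @importFrom utils read.table write.table head
#' @importFrom Rcpp sourceCpp
#' @useDynLib EcotypeScan, .registration = TRUE
NULL

#' GenotypeExperiment: biallelic SNP genotypes with sample metadata
#'
#' An S4 container for a biallelic SNP genotype matrix together with the
#' per-sample metadata the ecotype-pair analyses need (population label,
#' binary life history, sex). It extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: the single assay
#' \code{"codes"} is a loci x samples integer matrix whose non-missing
#' entries count copies (0, 1 or 2) of the counted allele at each locus
#' (by package convention the globally minor allele; missing genotypes are
#' \code{NA}). \code{colData} carries \code{population},
#' \code{life_history} (1 = anadromous/migratory, 0 = resident, \code{NA}
#' unknown) and \code{sex} (\code{"M"}, \code{"F"} or \code{"U"}).
#'
#' @slot .dummy unused; the class adds validity constraints, not slots.
#'
#' @seealso [GenotypeExperiment()] for construction, [genoCodes()],
#'   [populations()], [lifeHistory()], [sexes()] for access.
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

.validGenotypeExperiment <- function(object) {
  msg <- NULL
  if (!"codes" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'codes' is required")
  else {
    a <- SummarizedExperiment::assay(object, "codes")
    bad <- a[!is.na(a)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
      msg <- c(msg, "non-missing genotype codes must be 0, 1 or 2")
  }
  if (nrow(object) > 0 &&
      (is.null(rownames(object)) || anyDuplicated(rownames(object))))
    msg <- c(msg, "locus identifiers must be present and unique")
  if (ncol(object) > 0 &&
      (is.null(colnames(object)) || anyDuplicated(colnames(object))))
    msg <- c(msg, "sample identifiers must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  for (f in c("population", "life_history", "sex"))
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", f))
  if ("life_history" %in% colnames(cd)) {
    lh <- cd$life_history
    if (length(lh) && !all(is.na(lh) | lh %in% c(0L, 1L)))
      msg <- c(msg, "life_history must be 0, 1 or NA")
  }
  if ("population" %in% colnames(cd)) {
    p <- cd$population
    if (length(p) && any(is.na(p) | !nzchar(p)))
      msg <- c(msg, "population labels must be non-empty")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeExperiment", .validGenotypeExperiment)

#' Construct a GenotypeExperiment
#'
#' @param codes integer matrix of genotype codes, \emph{samples x loci}
#'   (the orientation genotype tables are usually exchanged in); values in
#'   \{0, 1, 2, NA\}. Row names are sample ids, column names locus ids;
#'   defaults are generated when absent.
#' @param population character vector of collection labels, one per sample.
#' @param lifeHistory integer vector (1 anadromous, 0 resident, NA), one
#'   per sample.
#' @param sex character vector in \code{c("M","F","U")}, one per sample.
#'
#' @return A [GenotypeExperiment-class] object.
#' @examples
#' gm <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'              dimnames = list(c("s1", "s2"), c("L1", "L2")))
#' ge <- GenotypeExperiment(gm, population = c("A", "B"))
#' nLoci(ge)
#' @export
GenotypeExperiment <- function(codes, population = rep("pop1", nrow(codes)),
                               lifeHistory = rep(NA_integer_, nrow(codes)),
                               sex = rep("U", nrow(codes))) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("sample_%d", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- sprintf("locus_%d", seq_len(ncol(codes)))
  storage.mode(codes) <- "integer"
  cd <- S4Vectors::DataFrame(
    population = as.character(population),
    life_history = as.integer(lifeHistory),
    sex = as.character(sex),
    row.names = rownames(codes))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(codes = t(codes)), colData = cd)
  new("GenotypeExperiment", se)
}

setMethod("show", "GenotypeExperiment", function(object) {
  cat("GenotypeExperiment:", ncol(object), "samples x", nrow(object),
      "loci\n")
  tab <- table(populations(object))
  cat("populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  a <- SummarizedExperiment::assay(object, "codes")
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * mean(is.na(a))))
})
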