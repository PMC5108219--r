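#' Accessors for GenotypeExperiment
#'
#' @param x a [GenotypeExperiment-class].
#' @return \code{genoCodes} returns the genotype codes as a
#'   \emph{samples x loci} integer matrix (the orientation every estimator
#'   in the package works in); \code{sampleIds} / \code{lociIds} the
#'   identifier vectors; \code{populations}, \code{lifeHistory} and
#'   \code{sexes} the per-sample metadata columns; \code{nSamples} /
#'   \code{nLoci} the dimensions; \code{sampleTable} the whole colData as
#'   a data.frame.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("genoCodes", function(x) standardGeneric("genoCodes"))

#' @rdname genotype-accessors
#' @export
setMethod("genoCodes", "GenotypeExperiment", function(x)
  t(SummarizedExperiment::assay(x, "codes")))

#' @rdname genotype-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname genotype-accessors
#' @export
setMethod("sampleIds", "GenotypeExperiment", function(x) colnames(x))

#' @rdname genotype-accessors
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))

#' @rdname genotype-accessors
#' @export
setMethod("lociIds", "GenotypeExperiment", function(x) rownames(x))

#' @rdname genotype-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname genotype-accessors
#' @export
setMethod("populations", "GenotypeExperiment", function(x)
  SummarizedExperiment::colData(x)$population)

#' @rdname genotype-accessors
#' @export
setGeneric("lifeHistory", function(x) standardGeneric("lifeHistory"))

#' @rdname genotype-accessors
#' @export
setMethod("lifeHistory", "GenotypeExperiment", function(x)
  SummarizedExperiment::colData(x)$life_history)

#' @rdname genotype-accessors
#' @export
setGeneric("sexes", function(x) standardGeneric("sexes"))

#' @rdname genotype-accessors
#' @export
setMethod("sexes", "GenotypeExperiment", function(x)
  SummarizedExperiment::colData(x)$sex)

#' @rdname genotype-accessors
#' @export
nSamples <- function(x) ncol(x)

#' @rdname genotype-accessors
#' @export
nLoci <- function(x) nrow(x)

#' @rdname genotype-accessors
#' @export
sampleTable <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' Subset a GenotypeExperiment by sample and/or locus identifiers
#'
#' Convenience wrapper around `[` keeping the samples-first argument order
#' used throughout the package.
#'
#' @param x a [GenotypeExperiment-class].
#' @param samples sample ids (or logical/integer index over samples);
#'   NULL keeps all.
#' @param loci locus ids (or index); NULL keeps all.
#' @export
subsetGeno <- function(x, samples = NULL, loci = NULL) {
  if (!is.null(loci)) x <- x[loci, ]
  if (!is.null(samples)) x <- x[, samples]
  x
}
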