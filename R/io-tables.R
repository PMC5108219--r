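#' Read/write the tabular genotype dialect and the sample table
#'
#' The tabular genotype dialect is a TSV with samples as rows and loci as
#' columns; the first column (\code{sample_id}) holds sample identifiers
#' and cells are 0/1/2 counts of the counted allele or \code{NA}. The
#' sample table is a TSV with columns \code{sample_id}, \code{population},
#' \code{life_history} (0/1/NA) and \code{sex} (M/F/U); an optional
#' \code{pair} column groups collections into lake-system pairs for the
#' pairwise analyses.
#'
#' @param path file path.
#' @param ge a [GenotypeExperiment-class].
#' @param sampleInfo data.frame as returned by [readSampleTable()]; used
#'   to attach phenotype metadata when reading a genotype TSV.
#' @return \code{readGenotypeTsv} returns a [GenotypeExperiment-class];
#'   \code{readSampleTable} a data.frame; the writers return their path
#'   invisibly.
#' @name tabular-io
NULL

#' @rdname tabular-io
#' @export
readGenotypeTsv <- function(path, sampleInfo = NULL) {
  if (!file.exists(path)) stop("genotype TSV not found: ", path)
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (colnames(d)[1] != "sample_id")
    stop("genotype TSV must have 'sample_id' as its first column")
  codes <- as.matrix(d[, -1, drop = FALSE])
  rownames(codes) <- d$sample_id
  storage.mode(codes) <- "integer"
  if (is.null(sampleInfo))
    return(GenotypeExperiment(codes))
  m <- match(rownames(codes), sampleInfo$sample_id)
  if (anyNA(m))
    stop("samples absent from sample table: ",
         paste(head(rownames(codes)[is.na(m)]), collapse = ", "))
  ge <- GenotypeExperiment(codes,
                           population = sampleInfo$population[m],
                           lifeHistory = sampleInfo$life_history[m],
                           sex = sampleInfo$sex[m])
  if ("pair" %in% colnames(sampleInfo))
    SummarizedExperiment::colData(ge)$pair <- sampleInfo$pair[m]
  ge
}

#' @rdname tabular-io
#' @export
writeGenotypeTsv <- function(ge, path) {
  codes <- genoCodes(ge)
  d <- data.frame(sample_id = rownames(codes), codes, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tabular-io
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "life_history", "sex")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in sample table")
  d$life_history <- as.integer(d$life_history)
  d
}

#' @rdname tabular-io
#' @export
writeSampleTable <- function(ge, path) {
  d <- data.frame(sample_id = sampleIds(ge),
                  population = populations(ge),
                  life_history = lifeHistory(ge),
                  sex = sexes(ge))
  cd <- SummarizedExperiment::colData(ge)
  if ("pair" %in% colnames(cd)) d$pair <- cd$pair
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
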