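#' Read a genepop file into a GenotypeExperiment
#'
#' Parses the classical genepop dialect: a title line, locus names (one
#' per line and/or comma-separated), \code{POP} separator lines, and per
#' individual lines of the form \code{"id , 0101 0202 ..."} with 2- or
#' 3-digit allele codes. A genotype with any \code{00}/\code{000} allele
#' is missing. Populations are labelled \code{pop1}, \code{pop2}, ... in
#' block order (genepop does not name them). Each locus must show at most
#' two distinct alleles; the counted allele of the returned codes is the
#' globally minor one (ties broken by smaller allele code).
#'
#' @param path path to a genepop text file.
#' @return a [GenotypeExperiment-class] with populations assigned from the
#'   POP blocks (life history and sex are NA/unknown; genepop carries
#'   neither).
#' @seealso [writeGenepop()]
#' @export
readGenepop <- function(path) {
  if (!file.exists(path)) stop("genepop file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("genepop parse error: file too short")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop("genepop parse error: no POP separator after locus names")
  loci <- unlist(strsplit(lines[2:(first_pop - 1L)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("genepop parse error: duplicate locus names")
  nl <- length(loci)

  ids <- character(); popv <- character()
  allele1 <- list(); allele2 <- list()
  pop_idx <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (toupper(ln) == "POP") { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L)
      stop("genepop parse error at line ", i, ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    gg <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    gg <- gg[nzchar(gg)]
    if (length(gg) != nl)
      stop("genepop parse error at line ", i, ": ", length(gg),
           " genotypes for ", nl, " loci")
    w <- nchar(gg)
    if (!all(w %in% c(4L, 6L)) || length(unique(w)) != 1L)
      stop("genepop parse error at line ", i,
           ": allele codes must be uniformly 2- or 3-digit")
    half <- w[1] / 2L
    a1 <- as.integer(substr(gg, 1L, half))
    a2 <- as.integer(substr(gg, half + 1L, w[1]))
    if (anyNA(a1) || anyNA(a2))
      stop("genepop parse error at line ", i, ": non-numeric allele code")
    ids <- c(ids, id); popv <- c(popv, sprintf("pop%d", pop_idx))
    allele1[[length(allele1) + 1L]] <- a1
    allele2[[length(allele2) + 1L]] <- a2
  }
  if (!length(ids)) stop("genepop parse error: no individuals")
  A1 <- do.call(rbind, allele1)
  A2 <- do.call(rbind, allele2)
  A1[A1 == 0L] <- NA; A2[A2 == 0L] <- NA
  miss <- is.na(A1) | is.na(A2)
  A1[miss] <- NA; A2[miss] <- NA

  codes <- matrix(NA_integer_, nrow(A1), nl)
  for (j in seq_len(nl)) {
    obs <- c(A1[, j], A2[, j])
    alleles <- sort(unique(obs[!is.na(obs)]))
    if (length(alleles) > 2L)
      stop("biallelic violation: locus '", loci[j], "' shows ",
           length(alleles), " alleles")
    if (length(alleles) == 0L) next        # all missing, codes stay NA
    counts <- vapply(alleles, function(a) sum(obs == a, na.rm = TRUE), 0L)
    # counted allele: globally minor; tie -> smaller allele code
    counted <- alleles[order(counts, alleles)][1]
    codes[, j] <- (A1[, j] == counted) + (A2[, j] == counted)
    if (length(alleles) == 1L) codes[!miss[, j], j] <- 0L
  }
  dimnames(codes) <- list(make.unique(ids), loci)
  GenotypeExperiment(codes, population = popv)
}

#' Write a GenotypeExperiment as a genepop file
#'
#' Emits 3-digit allele codes with the counted (minor) allele written as
#' \code{001} and the other allele as \code{002}; missing genotypes are
#' \code{000000}. Samples are grouped into POP blocks by population label
#' (first-appearance order), preserving input order within a block, so
#' write-then-read reproduces codes and population blocks exactly for
#' minor-allele-oriented matrices.
#'
#' @param ge a [GenotypeExperiment-class] with populations assigned.
#' @param path output file path.
#' @param title first (comment) line of the file.
#' @return \code{path}, invisibly.
#' @export
writeGenepop <- function(ge, path, title = "EcotypeScan genotypes") {
  codes <- genoCodes(ge)
  if (nrow(codes) == 0L || ncol(codes) == 0L)
    stop("refusing to write an empty genotype matrix")
  pops <- populations(ge)
  if (any(is.na(pops) | !nzchar(pops)))
    stop("all samples must have a population assigned")
  gg <- matrix("000000", nrow(codes), ncol(codes))
  gg[!is.na(codes) & codes == 0L] <- "002002"
  gg[!is.na(codes) & codes == 1L] <- "001002"
  gg[!is.na(codes) & codes == 2L] <- "001001"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(colnames(codes), con)
  for (p in unique(pops)) {
    writeLines("POP", con)
    for (i in which(pops == p))
      writeLines(paste0(rownames(codes)[i], " ,  ",
                        paste(gg[i, ], collapse = " ")), con)
  }
  invisible(path)
}

#' Re-orient genotype codes to count the globally minor allele
#'
#' Flips codes (0 <-> 2) at loci where the counted allele's global
#' frequency exceeds 0.5, so every locus counts its minor allele (the
#' package's orientation convention, under which genepop round trips are
#' exact). Ties are left as-is.
#'
#' @param ge a [GenotypeExperiment-class].
#' @return the re-oriented object.
#' @export
orientMinor <- function(ge) {
  codes <- genoCodes(ge)
  p <- .alleleFreq(codes)
  flip <- which(is.finite(p) & p > 0.5)
  if (length(flip))
    codes[, flip] <- 2L - codes[, flip]
  out <- ge
  SummarizedExperiment::assay(out, "codes") <- t(codes)
  out
}
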