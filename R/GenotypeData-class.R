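#' GenotypeData: samples-by-markers allele-count calls
#'
#' The central container of the package. A \code{GenotypeData} object extends
#' \linkS4class{RangedSummarizedExperiment}: the single assay \code{"calls"}
#' holds biallelic genotype calls coded as copies of allele 1 (0, 1, 2, or
#' \code{NA} for missing), with markers as rows and samples as columns.
#' Marker metadata (chromosome, base-pair position, genetic position in cM,
#' allele codes) lives in \code{rowRanges}; the sample sheet (family, parents,
#' sex, case/control phenotype) lives in \code{colData}.
#'
#' Markers are always stored sorted by (chromosome, bp), with chromosome
#' \code{"X"} ordered after \code{"18"}. Coordinates are 1-based and all
#' intervals in the package are closed on both ends. After quality control
#' allele 1 is the minor allele, so downstream counts are minor-allele counts.
#'
#' @param calls integer matrix, markers x samples, values in {0, 1, 2, NA}.
#' @param markers data.frame with columns \code{marker_id}, \code{chrom},
#'   \code{cm}, \code{bp}, \code{allele1}, \code{allele2}.
#' @param samples data.frame with columns \code{family_id}, \code{sample_id},
#'   \code{sire_id}, \code{dam_id} (\code{"0"} = unknown), \code{sex}
#'   (\code{"male"}, \code{"female"} or \code{"unknown"}) and
#'   \code{phenotype} (\code{"control"}, \code{"case"} or \code{NA}).
#'
#' @return A \code{GenotypeData} object with markers sorted by (chrom, bp).
#' @export
#' @examples
#' gd <- GenotypeData(
#'   calls = matrix(c(0L, 1L, 2L, 1L), nrow = 2,
#'                  dimnames = list(c("m1", "m2"), c("s1", "s2"))),
#'   markers = data.frame(marker_id = c("m1", "m2"), chrom = "1",
#'                        cm = 0, bp = c(100L, 200L),
#'                        allele1 = "A", allele2 = "G"),
#'   samples = data.frame(family_id = "F", sample_id = c("s1", "s2"),
#'                        sire_id = "0", dam_id = "0", sex = "male",
#'                        phenotype = c("case", "control"))
#' )
#' nMarkers(gd)
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

.validGenotypeData <- function(object) {
  msg <- NULL
  if (!("calls" %in% SummarizedExperiment::assayNames(object))) {
    msg <- c(msg, "assay 'calls' is required")
  } else {
    calls <- SummarizedExperiment::assay(object, "calls")
    bad <- !(is.na(calls) | calls == 0L | calls == 1L | calls == 2L)
    if (any(bad)) {
      msg <- c(msg, "calls must be 0, 1, 2 or NA")
    }
  }
  rr <- SummarizedExperiment::rowRanges(object)
  if (anyDuplicated(names(rr))) {
    msg <- c(msg, "marker ids must be unique")
  }
  need <- c("cm", "allele1", "allele2")
  if (!all(need %in% colnames(S4Vectors::mcols(rr)))) {
    msg <- c(msg, "rowRanges must carry cm, allele1, allele2")
  }
  chrom <- as.character(GenomicRanges::seqnames(rr))
  bp <- GenomicRanges::start(rr)
  if (any(bp <= 0)) {
    msg <- c(msg, "bp positions must be positive")
  }
  ord <- order(match(chrom, .chromLevels(chrom)), bp)
  if (!identical(ord, seq_along(rr))) {
    msg <- c(msg, "markers must be sorted by (chrom, bp)")
  }
  if (is.null(msg)) TRUE else msg
}

setValidity("GenotypeData", .validGenotypeData)

#' @rdname GenotypeData-class
#' @export
GenotypeData <- function(calls, markers, samples) {
  stopifnot(
    is.matrix(calls),
    nrow(calls) == nrow(markers),
    ncol(calls) == nrow(samples)
  )
  markers$chrom <- as.character(markers$chrom)
  lev <- .chromLevels(markers$chrom)
  ord <- order(match(markers$chrom, lev), markers$bp)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  storage.mode(calls) <- "integer"
  rr <- GenomicRanges::GRanges(
    seqnames = factor(markers$chrom, levels = lev),
    ranges = IRanges::IRanges(start = markers$bp, width = 1L),
    cm = markers$cm,
    allele1 = as.character(markers$allele1),
    allele2 = as.character(markers$allele2)
  )
  names(rr) <- markers$marker_id
  cd <- S4Vectors::DataFrame(
    family_id = as.character(samples$family_id),
    sire_id = as.character(samples$sire_id),
    dam_id = as.character(samples$dam_id),
    sex = as.character(samples$sex),
    phenotype = as.character(samples$phenotype),
    row.names = as.character(samples$sample_id)
  )
  dimnames(calls) <- list(names(rr), rownames(cd))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowRanges = rr, colData = cd
  )
  methods::new("GenotypeData", se)
}

#' @describeIn GenotypeData-class genotype call matrix (markers x samples)
#' @param x,object a \code{GenotypeData} object
#' @export
genotypeCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @describeIn GenotypeData-class marker table (marker_id, chrom, cm, bp,
#'   allele1, allele2), in storage order
#' @export
markerInfo <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(
    marker_id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    cm = S4Vectors::mcols(rr)$cm,
    bp = GenomicRanges::start(rr),
    allele1 = S4Vectors::mcols(rr)$allele1,
    allele2 = S4Vectors::mcols(rr)$allele2,
    row.names = NULL
  )
}

#' @describeIn GenotypeData-class sample sheet with sample_id column
#' @export
sampleInfo <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(
    family_id = cd$family_id,
    sample_id = rownames(cd),
    sire_id = cd$sire_id,
    dam_id = cd$dam_id,
    sex = cd$sex,
    phenotype = cd$phenotype,
    row.names = NULL
  )
}

#' @describeIn GenotypeData-class named phenotype vector ("case"/"control"/NA)
#' @export
phenotypes <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(cd$phenotype, rownames(cd))
}

#' @describeIn GenotypeData-class number of markers
#' @export
nMarkers <- function(x) nrow(x)

#' @describeIn GenotypeData-class number of samples
#' @export
nSamples <- function(x) ncol(x)

#' @describeIn GenotypeData-class allele-1 frequency per marker
#'   (non-missing calls only)
#' @export
alleleFreq <- function(x) {
  calls <- genotypeCalls(x)
  rowMeans(calls, na.rm = TRUE) / 2
}

#' @describeIn GenotypeData-class subset to autosomal markers
#' @export
autosomes <- function(x) {
  x[.isAutosome(markerInfo(x)$chrom), ]
}

#' Recode calls so that allele 1 is the minor allele
#'
#' Flips the allele-count coding (and swaps the allele labels) at markers
#' where allele 1 has frequency above one half; at exactly 0.5 the
#' lexicographically smaller allele code becomes allele 1. Run after sample
#' removal so downstream statistics count minor alleles.
#'
#' @param x a \code{GenotypeData} object
#' @return a \code{GenotypeData} object with minor-allele coding
#' @export
recodeMinor <- function(x) {
  calls <- genotypeCalls(x)
  mk <- markerInfo(x)
  p <- rowMeans(calls, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  flip <- p > 0.5 | (p == 0.5 & mk$allele1 > mk$allele2)
  if (any(flip)) {
    calls[flip, ] <- 2L - calls[flip, , drop = FALSE]
    tmp <- mk$allele1[flip]
    mk$allele1[flip] <- mk$allele2[flip]
    mk$allele2[flip] <- tmp
  }
  GenotypeData(calls, mk, sampleInfo(x))
}

setMethod("show", "GenotypeData", function(object) {
  ph <- phenotypes(object)
  cat(
    "GenotypeData:", nMarkers(object), "markers x",
    nSamples(object), "samples\n"
  )
  cat(
    " chromosomes:",
    paste(GenomeInfoDb::seqlevels(SummarizedExperiment::rowRanges(object)),
      collapse = " "
    ), "\n"
  )
  cat(
    " phenotype: ", sum(ph == "case", na.rm = TRUE), " case / ",
    sum(ph == "control", na.rm = TRUE), " control / ",
    sum(is.na(ph)), " missing\n",
    sep = ""
  )
  miss <- mean(is.na(genotypeCalls(object)))
  cat(sprintf(" missing call rate: %.4f\n", miss))
})
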