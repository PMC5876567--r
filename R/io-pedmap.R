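#' Read PLINK text PED/MAP files
#'
#' Parses a whitespace-delimited PLINK pedigree file (six leading columns:
#' family, individual, sire, dam, sex, phenotype; then one allele pair per
#' marker) together with its 4-column MAP file (chrom, marker id, cM, bp).
#' Any allele coded \code{"0"} renders the call missing. Per marker the two
#' observed alleles are identified and allele 1 is set to the minor allele
#' (ties broken lexicographically), so calls count minor-allele copies.
#' Markers are returned sorted by (chromosome, bp) regardless of MAP order;
#' sample order follows the PED file.
#'
#' Phenotypes use PLINK affection coding: 1 = control, 2 = case, 0/-9 =
#' missing. Sex: 1 = male, 2 = female, anything else unknown.
#'
#' @param pedPath path to the PED file.
#' @param mapPath path to the MAP file.
#' @return a \link{GenotypeData} object.
#' @export
readPedMap <- function(pedPath, mapPath) {
  map <- utils::read.table(mapPath,
    header = FALSE, colClasses = "character",
    col.names = c("chrom", "marker_id", "cm", "bp")
  )
  if (anyDuplicated(map$marker_id)) {
    stop("duplicate marker ids in MAP file")
  }
  m <- nrow(map)
  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * m
  nf <- lengths(toks)
  if (any(nf != expected)) {
    bad <- which(nf != expected)[1]
    stop(sprintf(
      "PED row %d has %d fields, expected %d (6 + 2 x %d markers)",
      bad, nf[bad], expected, m
    ))
  }
  tok <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  samples <- data.frame(
    family_id = tok[, 1], sample_id = tok[, 2],
    sire_id = tok[, 3], dam_id = tok[, 4],
    sex = c("male", "female")[match(tok[, 5], c("1", "2"))],
    phenotype = c("control", "case")[match(tok[, 6], c("1", "2"))]
  )
  samples$sex[is.na(samples$sex)] <- "unknown"
  if (anyDuplicated(paste(samples$family_id, samples$sample_id))) {
    stop("sample ids must be unique within family")
  }
  n <- nrow(tok)
  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  ok <- a1 %in% c("A", "C", "G", "T", "0", "1", "2") &
    a2 %in% c("A", "C", "G", "T", "0", "1", "2")
  if (!all(ok)) {
    stop("PED contains allele codes outside {A,C,G,T,0,1,2}")
  }
  calls <- matrix(NA_integer_, nrow = m, ncol = n)
  allele1 <- allele2 <- character(m)
  for (j in seq_len(m)) {
    x <- a1[, j]
    y <- a2[, j]
    miss <- x == "0" | y == "0"
    obs <- sort(unique(c(x[!miss], y[!miss])))
    if (length(obs) > 2) {
      stop(sprintf(
        "marker %s has more than two alleles: %s",
        map$marker_id[j], paste(obs, collapse = ",")
      ))
    }
    if (length(obs) == 0) {
      allele1[j] <- "0"
      allele2[j] <- "0"
      next
    }
    if (length(obs) == 1) {
      obs <- c(obs, "0")
    }
    cnt1 <- sum(x[!miss] == obs[1]) + sum(y[!miss] == obs[1])
    cnt2 <- sum(x[!miss] == obs[2]) + sum(y[!miss] == obs[2])
    # minor allele first; lexicographic tie-break (obs already sorted)
    if (cnt2 < cnt1) {
      obs <- obs[c(2, 1)]
    }
    allele1[j] <- obs[1]
    allele2[j] <- obs[2]
    cj <- (x == obs[1]) + (y == obs[1])
    cj[miss] <- NA_integer_
    calls[j, ] <- cj
  }
  markers <- data.frame(
    marker_id = map$marker_id, chrom = map$chrom,
    cm = as.numeric(map$cm), bp = as.integer(map$bp),
    allele1 = allele1, allele2 = allele2
  )
  GenotypeData(calls, markers, samples)
}

#' Write PLINK text PED/MAP files
#'
#' Emits files that re-parse (via \code{\link{readPedMap}}) to an equal
#' dataset. Missing calls are written as \code{"0 0"}; phenotypes use PLINK
#' coding (1 = control, 2 = case, -9 = missing).
#'
#' @param gd a \link{GenotypeData} object.
#' @param pedPath,mapPath output paths.
#' @return invisibly, a character vector with the two paths written.
#' @export
writePedMap <- function(gd, pedPath, mapPath) {
  mk <- markerInfo(gd)
  sm <- sampleInfo(gd)
  calls <- genotypeCalls(gd)
  utils::write.table(
    mk[, c("chrom", "marker_id", "cm", "bp")],
    mapPath,
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  m <- nrow(mk)
  n <- nrow(sm)
  sexCode <- c(male = "1", female = "2", unknown = "0")[sm$sex]
  sexCode[is.na(sexCode)] <- "0"
  pheCode <- ifelse(is.na(sm$phenotype), "-9",
    ifelse(sm$phenotype == "case", "2", "1")
  )
  geno <- matrix("0", nrow = n, ncol = 2L * m)
  if (m > 0) {
    for (j in seq_len(m)) {
      cj <- calls[j, ]
      g1 <- ifelse(is.na(cj), "0", ifelse(cj >= 1, mk$allele1[j], mk$allele2[j]))
      g2 <- ifelse(is.na(cj), "0", ifelse(cj == 2, mk$allele1[j], mk$allele2[j]))
      geno[, 2L * j - 1L] <- g1
      geno[, 2L * j] <- g2
    }
  }
  rows <- cbind(
    sm$family_id, sm$sample_id, sm$sire_id, sm$dam_id,
    sexCode, pheCode, geno
  )
  writeLines(apply(rows, 1, paste, collapse = " "), pedPath)
  invisible(c(ped = pedPath, map = mapPath))
}
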