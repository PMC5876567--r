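#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Expectation-maximisation over the 2^m haplotypes of m = 2 or 3 biallelic
#' markers: the E-step distributes each individual's multilocus genotype
#' over its compatible (unordered) haplotype pairs in proportion to the
#' current frequency products, the M-step re-estimates frequencies from the
#' expected haplotype counts. Initialisation is the deterministic uniform
#' distribution; convergence when the largest frequency change drops below
#' \code{tol} (default 1e-8) or after \code{maxIter} (default 1000)
#' iterations, in which case the last iterate is returned flagged as
#' non-converged. The log-likelihood is non-decreasing across iterations.
#' Individuals missing a call at any of the markers are excluded.
#'
#' Haplotypes are labelled with the marker allele codes (allele 1 / allele
#' 2 per marker) so a label like \code{"GC"} reads as the allele sequence
#' along the span.
#'
#' @param gd a \link{GenotypeData} object.
#' @param markerIds 2 or 3 marker ids defining the span.
#' @param group optional subset of sample ids to fit (default all samples).
#' @param tol,maxIter EM convergence controls.
#' @return list of class \code{"EmHaplotypes"}: \code{freq} (named
#'   haplotype frequency vector summing to 1), \code{n} (individuals
#'   fitted), \code{logLik}, \code{logLikTrace}, \code{converged},
#'   \code{carrierProb} (per-individual posterior probability of carrying
#'   at least one copy of each haplotype, individuals x haplotypes).
#' @export
emHaplotypeFreqs <- function(gd, markerIds, group = NULL, tol = 1e-8,
                             maxIter = 1000) {
  m <- length(markerIds)
  if (!(m %in% c(2L, 3L))) {
    stop("haplotype spans of 2 or 3 markers are supported")
  }
  mk <- markerInfo(gd)
  sel <- match(markerIds, mk$marker_id)
  if (anyNA(sel)) {
    stop("unknown marker id(s): ",
      paste(markerIds[is.na(sel)], collapse = ", "))
  }
  calls <- genotypeCalls(gd)[sel, , drop = FALSE]
  if (!is.null(group)) {
    calls <- calls[, group, drop = FALSE]
  }
  complete <- colSums(is.na(calls)) == 0
  calls <- calls[, complete, drop = FALSE]
  n <- ncol(calls)
  if (n == 0) {
    stop("no individuals with complete genotypes at the span")
  }
  # haplotypes as rows of 0/1 allele-1 copies per marker
  hapMat <- as.matrix(expand.grid(rep(list(1:0), m)))[, m:1, drop = FALSE]
  nh <- nrow(hapMat)
  hapLab <- apply(hapMat, 1, function(h) {
    paste(ifelse(h == 1, mk$allele1[sel], mk$allele2[sel]), collapse = "")
  })
  # unordered compatible pairs per genotype signature
  pairs <- which(upper.tri(matrix(0, nh, nh), diag = TRUE), arr.ind = TRUE)
  pairGeno <- hapMat[pairs[, 1], , drop = FALSE] +
    hapMat[pairs[, 2], , drop = FALSE]
  genoKey <- apply(t(calls), 1, paste, collapse = "/")
  pairKey <- apply(pairGeno, 1, paste, collapse = "/")
  tab <- table(genoKey)
  keys <- names(tab)
  counts <- as.numeric(tab)
  compat <- lapply(keys, function(k) which(pairKey == k))
  if (any(lengths(compat) == 0)) {
    stop("genotype incompatible with biallelic haplotypes at the span")
  }
  het <- (pairs[, 1] != pairs[, 2]) + 1 # 2 for heterozygous pairs

  freq <- rep(1 / nh, nh)
  llTrace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    pairP <- het * freq[pairs[, 1]] * freq[pairs[, 2]]
    expCount <- numeric(nh)
    ll <- 0
    postByKey <- vector("list", length(keys))
    for (g in seq_along(keys)) {
      idx <- compat[[g]]
      w <- pairP[idx]
      tw <- sum(w)
      ll <- ll + counts[g] * log(tw)
      w <- w / tw
      postByKey[[g]] <- w
      contrib <- counts[g] * w
      for (z in seq_along(idx)) {
        expCount[pairs[idx[z], 1]] <- expCount[pairs[idx[z], 1]] + contrib[z]
        expCount[pairs[idx[z], 2]] <- expCount[pairs[idx[z], 2]] + contrib[z]
      }
    }
    newFreq <- expCount / (2 * n)
    delta <- max(abs(newFreq - freq))
    freq <- newFreq
    llTrace <- c(llTrace, ll)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # posterior carrier probabilities per individual
  pairP <- het * freq[pairs[, 1]] * freq[pairs[, 2]]
  carrier <- matrix(0, n, nh, dimnames = list(colnames(calls), hapLab))
  keyOfInd <- match(genoKey, keys)
  for (g in seq_along(keys)) {
    idx <- compat[[g]]
    w <- pairP[idx]
    w <- w / sum(w)
    hasHap <- vapply(seq_len(nh), function(h) {
      as.numeric(pairs[idx, 1] == h | pairs[idx, 2] == h)
    }, numeric(length(idx)))
    if (length(idx) == 1) hasHap <- matrix(hasHap, nrow = 1)
    probCarrier <- as.numeric(w %*% hasHap)
    carrier[keyOfInd == g, ] <- matrix(probCarrier, sum(keyOfInd == g), nh,
      byrow = TRUE
    )
  }
  structure(
    list(
      freq = stats::setNames(freq, hapLab), n = n,
      logLik = llTrace[length(llTrace)], logLikTrace = llTrace,
      converged = converged, carrierProb = carrier
    ),
    class = "EmHaplotypes"
  )
}

#' Haplotype case/control association
#'
#' Fits haplotype frequencies separately in cases and controls with
#' \code{\link{emHaplotypeFreqs}}, forms expected haplotype counts
#' (2n x frequency per group) and tests each haplotype against all others
#' in a 2x2 chi-square (1 df), plus an omnibus chi-square over all
#' haplotypes (h - 1 df). Haplotypes with an expected count below 1 in both
#' groups are excluded from per-haplotype testing and reported
#' descriptively. Odds ratios use the +0.5 correction when a cell is zero,
#' so a haplotype absent from one group still reports a direction.
#' Estimated carrier frequencies (posterior probability of carrying at
#' least one copy) are reported alongside the chromosome frequencies.
#'
#' @param gd a \link{GenotypeData} object with phenotypes.
#' @param markerIds 2 or 3 marker ids defining the span.
#' @return list of class \code{"HaplotypeAssoc"}: \code{table} (haplotype,
#'   freq_cases, freq_controls, carrier_freq_cases, carrier_freq_controls,
#'   tested, chi2, p, odds_ratio), \code{omnibus_chi2}, \code{omnibus_df},
#'   \code{omnibus_p}, \code{n_cases}, \code{n_controls}.
#' @export
haplotypeAssoc <- function(gd, markerIds) {
  ph <- phenotypes(gd)
  caseIds <- names(ph)[which(ph == "case")]
  ctrlIds <- names(ph)[which(ph == "control")]
  if (length(caseIds) == 0 || length(ctrlIds) == 0) {
    stop("both cases and controls are required")
  }
  emCase <- emHaplotypeFreqs(gd, markerIds, group = caseIds)
  emCtrl <- emHaplotypeFreqs(gd, markerIds, group = ctrlIds)
  fCa <- emCase$freq
  fCo <- emCtrl$freq
  nCa <- 2 * emCase$n
  nCo <- 2 * emCtrl$n
  expCa <- nCa * fCa
  expCo <- nCo * fCo
  tested <- expCa >= 1 | expCo >= 1
  h <- length(fCa)
  chi2 <- p <- or <- rep(NA_real_, h)
  for (k in which(tested)) {
    tst <- .chisq2x2(expCa[k], nCa - expCa[k], expCo[k], nCo - expCo[k])
    chi2[k] <- tst["chi2"]
    p[k] <- tst["p"]
    or[k] <- .oddsRatio(expCa[k], nCa - expCa[k], expCo[k], nCo - expCo[k])
  }
  # omnibus over all haplotypes, h-1 df, pooled expectation
  pool <- (expCa + expCo) / (nCa + nCo)
  eCa <- nCa * pool
  eCo <- nCo * pool
  nz <- pool > 0
  omni <- sum((expCa[nz] - eCa[nz])^2 / eCa[nz]) +
    sum((expCo[nz] - eCo[nz])^2 / eCo[nz])
  df <- sum(nz) - 1
  structure(
    list(
      table = data.frame(
        haplotype = names(fCa), freq_cases = unname(fCa),
        freq_controls = unname(fCo),
        carrier_freq_cases = colMeans(emCase$carrierProb),
        carrier_freq_controls = colMeans(emCtrl$carrierProb),
        tested = tested, chi2 = chi2, p = p, odds_ratio = or,
        row.names = NULL
      ),
      omnibus_chi2 = omni, omnibus_df = df,
      omnibus_p = stats::pchisq(omni, df = df, lower.tail = FALSE),
      n_cases = emCase$n, n_controls = emCtrl$n
    ),
    class = "HaplotypeAssoc"
  )
}
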