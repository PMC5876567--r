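#' Quality-control thresholds
#'
#' Bundles the marker/sample filters applied by \code{\link{filterMarkers}}.
#' Defaults follow common SNP-array practice for small case/control cohorts:
#' minor allele frequency at least 1\%, at most 10\% missingness per marker
#' and per sample, an exact Hardy-Weinberg test at p < 9.5e-7, and LD
#' pruning at r^2 < 0.2.
#'
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param markerMissingMax maximum per-marker missing proportion (0.10).
#' @param sampleMissingMax maximum per-sample missing proportion (0.10).
#' @param hwePMin Hardy-Weinberg exact p-value threshold (9.5e-7).
#' @param ldR2Max r^2 ceiling used by \code{\link{ldPrune}} (0.2).
#' @return a named list of class \code{"QcThresholds"}.
#' @export
qcThresholds <- function(mafMin = 0.01, markerMissingMax = 0.10,
                         sampleMissingMax = 0.10, hwePMin = 9.5e-7,
                         ldR2Max = 0.2) {
  th <- list(
    mafMin = mafMin, markerMissingMax = markerMissingMax,
    sampleMissingMax = sampleMissingMax, hwePMin = hwePMin,
    ldR2Max = ldR2Max
  )
  if (any(unlist(th) < 0 | unlist(th) > 1)) {
    stop("all QC thresholds must lie in [0, 1]")
  }
  structure(th, class = "QcThresholds")
}

#' QcReport: auditable marker/sample QC bookkeeping
#'
#' Call-rate and MAF failures are tabulated jointly (failed call rate only,
#' failed MAF only, failed both), the Hardy-Weinberg filter is applied to
#' the markers surviving those two, and the validity method enforces the
#' partition identity
#' \code{nMarkersOut = nMarkersIn - nFailCallrateOnly - nFailMafOnly -
#' nFailBoth - nFailHwe}. \code{nMarkersPreHwe} carries the intermediate
#' count (input minus call-rate/MAF removals) since published summaries
#' sometimes quote it instead of the post-HWE panel size.
#'
#' @slot nMarkersIn,nFailCallrateOnly,nFailMafOnly,nFailBoth,nFailHwe
#'   integer marker bookkeeping.
#' @slot nMarkersPreHwe,nMarkersOut integer panel sizes before/after HWE.
#' @slot nSamplesIn,nSamplesRemoved integer sample bookkeeping.
#' @slot markerReasons data.frame (marker_id, reason) for removed markers.
#' @slot sampleReasons data.frame (sample_id, reason) for removed samples.
#' @export
setClass("QcReport", representation(
  nMarkersIn = "integer", nFailCallrateOnly = "integer",
  nFailMafOnly = "integer", nFailBoth = "integer", nFailHwe = "integer",
  nMarkersPreHwe = "integer", nMarkersOut = "integer",
  nSamplesIn = "integer", nSamplesRemoved = "integer",
  markerReasons = "data.frame", sampleReasons = "data.frame"
))

setValidity("QcReport", function(object) {
  msg <- NULL
  out <- object@nMarkersIn - object@nFailCallrateOnly -
    object@nFailMafOnly - object@nFailBoth - object@nFailHwe
  if (out != object@nMarkersOut) {
    msg <- c(msg, "marker counts violate the partition identity")
  }
  pre <- object@nMarkersIn - object@nFailCallrateOnly -
    object@nFailMafOnly - object@nFailBoth
  if (pre != object@nMarkersPreHwe) {
    msg <- c(msg, "pre-HWE count inconsistent with removal categories")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname QcReport-class
#' @param nMarkersIn,nFailCallrateOnly,nFailMafOnly,nFailBoth,nFailHwe,nSamplesIn,nSamplesRemoved
#'   integer bookkeeping counts.
#' @param markerReasons,sampleReasons removal tables (marker_id/sample_id,
#'   reason); default empty.
#' @export
QcReport <- function(nMarkersIn, nFailCallrateOnly, nFailMafOnly, nFailBoth,
                     nFailHwe = 0L, nSamplesIn = 0L, nSamplesRemoved = 0L,
                     markerReasons = data.frame(
                       marker_id = character(), reason = character()
                     ),
                     sampleReasons = data.frame(
                       sample_id = character(), reason = character()
                     )) {
  pre <- nMarkersIn - nFailCallrateOnly - nFailMafOnly - nFailBoth
  methods::new("QcReport",
    nMarkersIn = as.integer(nMarkersIn),
    nFailCallrateOnly = as.integer(nFailCallrateOnly),
    nFailMafOnly = as.integer(nFailMafOnly),
    nFailBoth = as.integer(nFailBoth),
    nFailHwe = as.integer(nFailHwe),
    nMarkersPreHwe = as.integer(pre),
    nMarkersOut = as.integer(pre - nFailHwe),
    nSamplesIn = as.integer(nSamplesIn),
    nSamplesRemoved = as.integer(nSamplesRemoved),
    markerReasons = markerReasons, sampleReasons = sampleReasons
  )
}

#' @describeIn QcReport-class marker counts as a named integer vector
#' @param object a \code{QcReport}
#' @export
qcCounts <- function(object) {
  c(
    markers_in = object@nMarkersIn,
    fail_callrate_only = object@nFailCallrateOnly,
    fail_maf_only = object@nFailMafOnly,
    fail_both = object@nFailBoth,
    markers_pre_hwe = object@nMarkersPreHwe,
    fail_hwe = object@nFailHwe,
    markers_out = object@nMarkersOut,
    samples_in = object@nSamplesIn,
    samples_removed = object@nSamplesRemoved
  )
}

setMethod("show", "QcReport", function(object) {
  cat("Marker/sample QC report\n")
  cat(sprintf(
    " samples: %d in, %d removed (missingness)\n",
    object@nSamplesIn, object@nSamplesRemoved
  ))
  cat(sprintf(" markers in:            %7d\n", object@nMarkersIn))
  cat(sprintf(" fail call rate only:   %7d\n", object@nFailCallrateOnly))
  cat(sprintf(" fail MAF only:         %7d\n", object@nFailMafOnly))
  cat(sprintf(" fail both:             %7d\n", object@nFailBoth))
  cat(sprintf(" pre-HWE panel:         %7d\n", object@nMarkersPreHwe))
  cat(sprintf(" fail HWE:              %7d\n", object@nFailHwe))
  cat(sprintf(" markers out:           %7d\n", object@nMarkersOut))
})

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts
#' (Levene-Haldane distribution over heterozygote counts, no mid-p): the
#' p-value is the total probability of all heterozygote configurations no
#' more probable than the observed one. Monomorphic input returns 1.
#'
#' Probabilities are evaluated by the usual two-directional recurrence from
#' the observed configuration, which stays stable for array-scale counts.
#'
#' @param nAA,nAa,naa genotype counts (either homozygote may be the minor
#'   one; the test is symmetric).
#' @return the exact two-sided p-value in (0, 1].
#' @export
#' @examples
#' hweExactTest(1, 0, 1) # 1/3
hweExactTest <- function(nAA, nAa, naa) {
  if (nAA < 0 || nAa < 0 || naa < 0) {
    stop("genotype counts must be non-negative")
  }
  n <- nAA + nAa + naa
  if (n < 1) {
    stop("at least one individual is required")
  }
  r <- min(2 * nAA + nAa, 2 * naa + nAa) # rare allele count
  if (r == 0) {
    return(1)
  }
  hs <- seq(r %% 2, r, by = 2) # attainable heterozygote counts
  logp <- numeric(length(hs))
  iObs <- match(nAa, hs)
  # recurrence: P(h+2)/P(h) = 4 * nhomRare(h) * nhomCommon(h) / ((h+2)(h+1))
  ratioUp <- function(h) {
    hr <- (r - h) / 2
    hc <- n - h - hr
    log(4 * hr * hc) - log((h + 2) * (h + 1))
  }
  if (iObs < length(hs)) {
    for (k in iObs:(length(hs) - 1)) {
      logp[k + 1] <- logp[k] + ratioUp(hs[k])
    }
  }
  if (iObs > 1) {
    for (k in iObs:2) {
      logp[k - 1] <- logp[k] - ratioUp(hs[k - 1])
    }
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  min(1, sum(p[p <= p[iObs] * (1 + 1e-9)]))
}

#' Apply marker and sample quality filters
#'
#' Removal order follows PLINK convention: samples exceeding the missingness
#' ceiling are dropped first, then markers are screened on the remaining
#' samples. Call-rate and MAF failures are tabulated jointly (only/only/
#' both); the exact HWE test is then applied to the surviving markers using
#' all remaining samples. MAF is computed on non-missing calls only. The
#' returned panel is recoded so allele 1 is the minor allele.
#'
#' @param gd a \link{GenotypeData} object.
#' @param thresholds a \code{\link{qcThresholds}} list.
#' @return list with elements \code{genotypes} (filtered
#'   \code{GenotypeData}) and \code{report} (a \linkS4class{QcReport}).
#' @export
filterMarkers <- function(gd, thresholds = qcThresholds()) {
  if (nMarkers(gd) == 0 || nSamples(gd) == 0) {
    stop("empty genotype matrix")
  }
  calls <- genotypeCalls(gd)
  nIn <- nMarkers(gd)
  nSampIn <- nSamples(gd)

  sampMiss <- colMeans(is.na(calls))
  dropSamp <- sampMiss > thresholds$sampleMissingMax
  sampleReasons <- data.frame(
    sample_id = colnames(calls)[dropSamp],
    reason = rep("missingness", sum(dropSamp))
  )
  if (any(dropSamp)) {
    gd <- gd[, !dropSamp]
    calls <- genotypeCalls(gd)
  }
  if (ncol(calls) == 0) {
    stop("all samples removed by missingness filter")
  }

  mkMiss <- rowMeans(is.na(calls))
  p <- rowMeans(calls, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  failCall <- mkMiss > thresholds$markerMissingMax
  failMaf <- maf < thresholds$mafMin
  crOnly <- failCall & !failMaf
  mafOnly <- failMaf & !failCall
  both <- failCall & failMaf
  keep1 <- !(failCall | failMaf)

  hweP <- rep(NA_real_, nIn)
  failHwe <- rep(FALSE, nIn)
  for (j in which(keep1)) {
    cj <- calls[j, ]
    hweP[j] <- hweExactTest(
      sum(cj == 2, na.rm = TRUE), sum(cj == 1, na.rm = TRUE),
      sum(cj == 0, na.rm = TRUE)
    )
    failHwe[j] <- hweP[j] < thresholds$hwePMin
  }
  keep <- keep1 & !failHwe
  if (!any(keep)) {
    stop("empty panel: all markers removed by QC")
  }

  ids <- markerInfo(gd)$marker_id
  markerReasons <- rbind(
    data.frame(marker_id = ids[crOnly], reason = rep("callrate", sum(crOnly))),
    data.frame(marker_id = ids[mafOnly], reason = rep("maf", sum(mafOnly))),
    data.frame(
      marker_id = ids[both],
      reason = rep("callrate+maf", sum(both))
    ),
    data.frame(marker_id = ids[failHwe], reason = rep("hwe", sum(failHwe)))
  )
  report <- QcReport(
    nMarkersIn = nIn,
    nFailCallrateOnly = sum(crOnly), nFailMafOnly = sum(mafOnly),
    nFailBoth = sum(both), nFailHwe = sum(failHwe),
    nSamplesIn = nSampIn, nSamplesRemoved = sum(dropSamp),
    markerReasons = markerReasons, sampleReasons = sampleReasons
  )
  list(genotypes = recodeMinor(gd[keep, ]), report = report)
}

#' Pairwise linkage disequilibrium r^2
#'
#' Squared Pearson correlation of two allele-count vectors over their
#' pairwise-complete samples.
#'
#' @param callsI,callsJ numeric vectors of 0/1/2 calls (NA = missing).
#' @return r^2 in [0, 1]; \code{NA} when either marker has zero variance
#'   among the complete pairs (treated upstream as "prune one of the pair").
#' @export
ldR2 <- function(callsI, callsJ) {
  if (length(callsI) != length(callsJ)) {
    stop("call vectors must have equal length")
  }
  ok <- !is.na(callsI) & !is.na(callsJ)
  x <- callsI[ok]
  y <- callsJ[ok]
  if (length(x) < 2 || stats::var(x) == 0 || stats::var(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Greedy windowed LD pruning
#'
#' Slides a window of \code{windowSnps} markers (step \code{stepSnps}) along
#' each autosome; within a window, while any retained pair has r^2 at or
#' above \code{r2Max}, the member of the offending pair with the lower MAF
#' is dropped (tie: the marker at the later bp). Sex-chromosome markers
#' never enter the pruned panel. Pruning is idempotent.
#'
#' @param gd a \link{GenotypeData} object (markers sorted by chrom, bp).
#' @param windowSnps window size in SNPs (default 50).
#' @param stepSnps step between window starts (default 5).
#' @param r2Max r^2 ceiling (default 0.2); pairs at or above it conflict.
#' @return character vector of retained (autosomal) marker ids.
#' @export
ldPrune <- function(gd, windowSnps = 50, stepSnps = 5, r2Max = 0.2) {
  if (windowSnps < 2) {
    stop("windowSnps must be at least 2")
  }
  mk <- markerInfo(gd)
  calls <- genotypeCalls(gd)
  p <- alleleFreq(gd)
  maf <- pmin(p, 1 - p)
  keep <- .isAutosome(mk$chrom)
  for (chr in unique(mk$chrom[keep])) {
    idx <- which(mk$chrom == chr & keep)
    L <- length(idx)
    starts <- unique(c(seq(1L, max(1L, L - windowSnps + 1L), by = stepSnps)))
    for (s in starts) {
      win <- idx[s:min(L, s + windowSnps - 1L)]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        r2 <- suppressWarnings(
          stats::cor(t(calls[act, , drop = FALSE]),
            use = "pairwise.complete.obs"
          )^2
        )
        # zero-variance pairs yield NA: treat as offending (prune one)
        r2[is.na(r2)] <- 1
        diag(r2) <- 0
        if (max(r2) < r2Max) break
        off <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        a <- act[off[1]]
        b <- act[off[2]]
        drop <- if (maf[a] < maf[b]) {
          a
        } else if (maf[b] < maf[a]) {
          b
        } else {
          c(a, b)[which.max(mk$bp[c(a, b)])]
        }
        keep[drop] <- FALSE
      }
    }
  }
  mk$marker_id[keep]
}

#' Per-sample heterozygosity check
#'
#' Computes the inbreeding-style statistic F = 1 - observed/expected
#' heterozygosity per sample (expectation from panel allele frequencies over
#' the sample's non-missing markers) and flags samples whose F falls more
#' than \code{sdMultiplier} standard deviations below the cohort mean -
#' heterozygosity excess suggesting cross-contamination.
#'
#' @param gd a \link{GenotypeData} object with at least 5 samples.
#' @param sdMultiplier flagging threshold in SD units (default 3).
#' @return data.frame (sample_id, obs_het, exp_het, f, flagged).
#' @export
sampleHetCheck <- function(gd, sdMultiplier = 3) {
  if (nSamples(gd) < 5) {
    stop("at least 5 samples are required")
  }
  calls <- genotypeCalls(gd)
  p <- alleleFreq(gd)
  expPer <- 2 * p * (1 - p)
  obsHet <- colSums(calls == 1, na.rm = TRUE)
  expHet <- colSums(expPer * !is.na(calls))
  f <- 1 - obsHet / expHet
  sdF <- stats::sd(f)
  flagged <- if (is.na(sdF) || sdF == 0) {
    rep(FALSE, length(f))
  } else {
    f < mean(f) - sdMultiplier * sdF
  }
  data.frame(
    sample_id = colnames(calls), obs_het = obsHet, exp_het = expHet,
    f = f, flagged = flagged, row.names = NULL
  )
}
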