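#' Run-of-homozygosity detection parameters
#'
#' Sliding-window settings used by \code{\link{detectRoh}}: a window of
#' \code{windowSnps} consecutive SNPs counts as homozygous when it contains
#' at most \code{windowHetMax} heterozygous and \code{windowMissMax} missing
#' calls; a SNP is ROH-eligible when at least \code{hitFraction} of the
#' windows overlapping it are homozygous; maximal eligible runs are reported
#' when they contain at least \code{minSnps} SNPs and span at least
#' \code{minLengthKb} kb. The defaults (50-SNP window, one heterozygote and
#' one missing call allowed, 100 SNPs and 1000 kb minimum) follow standard
#' array-scale ROH scanning practice; \code{hitFraction} = 0.05 is the
#' conventional scanning-tool default.
#'
#' @param windowSnps,windowHetMax,windowMissMax window settings.
#' @param minSnps,minLengthKb segment filters.
#' @param hitFraction per-SNP window hit-rate threshold.
#' @return a named list of class \code{"RohParams"}.
#' @export
rohParams <- function(windowSnps = 50, windowHetMax = 1, windowMissMax = 1,
                      minSnps = 100, minLengthKb = 1000, hitFraction = 0.05) {
  if (minSnps < windowSnps) {
    stop("minSnps must be at least windowSnps")
  }
  if (any(c(windowSnps, minSnps, minLengthKb) <= 0) || hitFraction <= 0) {
    stop("ROH parameters must be positive")
  }
  structure(
    list(
      windowSnps = windowSnps, windowHetMax = windowHetMax,
      windowMissMax = windowMissMax, minSnps = minSnps,
      minLengthKb = minLengthKb, hitFraction = hitFraction
    ),
    class = "RohParams"
  )
}

# Shared run-emitter for ROH / shared-segment scans: apply window
# eligibility per chromosome, collect maximal eligible runs passing the
# SNP-count and kb-length filters. Segment length is (end_bp - start_bp)/1000.
.scanSegments <- function(bad1, bad2, chrom, bp, params) {
  out <- vector("list", 0)
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    elig <- .windowEligible(
      bad1[sel], bad2[sel], params$windowSnps,
      params$windowHetMax, params$windowMissMax, params$hitFraction
    )
    if (is.null(elig)) {
      message(sprintf(
        "chromosome %s has fewer than %d SNPs; skipped", chr,
        params$windowSnps
      ))
      next
    }
    runs <- .trueRuns(elig)
    if (nrow(runs) == 0) next
    startBp <- bp[sel][runs$start]
    endBp <- bp[sel][runs$end]
    nSnps <- runs$end - runs$start + 1L
    lenKb <- (endBp - startBp) / 1000
    keep <- nSnps >= params$minSnps & lenKb >= params$minLengthKb
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      chrom = chr, start_bp = startBp[keep], end_bp = endBp[keep],
      n_snps = nSnps[keep], length_kb = lenKb[keep]
    )
  }
  if (length(out) == 0) {
    return(data.frame(
      chrom = character(), start_bp = integer(), end_bp = integer(),
      n_snps = integer(), length_kb = numeric()
    ))
  }
  do.call(rbind, out)
}

#' Detect runs of homozygosity
#'
#' Sliding-window scan per sample over the autosomes (the X chromosome is
#' excluded): windows with at most the allowed heterozygous/missing calls
#' are homozygous, SNPs overlapped by a sufficient fraction of homozygous
#' windows are eligible, and maximal eligible runs passing the SNP-count
#' and length filters are reported. Chromosomes shorter than one window are
#' skipped with a message. Tolerated heterozygous/missing calls apply at
#' the window level only, not as a per-segment allowance.
#'
#' @param gd a \link{GenotypeData} object.
#' @param params a \code{\link{rohParams}} list.
#' @param samples optional character vector of sample ids (default all).
#' @return data.frame (sample_id, chrom, start_bp, end_bp, n_snps,
#'   length_kb); segments of one sample on one chromosome never overlap.
#' @export
detectRoh <- function(gd, params = rohParams(), samples = NULL) {
  gd <- autosomes(gd)
  calls <- genotypeCalls(gd)
  mk <- markerInfo(gd)
  if (is.null(samples)) samples <- colnames(calls)
  out <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    x <- calls[, samples[s]]
    seg <- .scanSegments(
      bad1 = !is.na(x) & x == 1L, bad2 = is.na(x),
      chrom = mk$chrom, bp = mk$bp, params = params
    )
    if (nrow(seg) > 0) {
      out[[s]] <- cbind(sample_id = samples[s], seg)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(
      sample_id = character(), chrom = character(), start_bp = integer(),
      end_bp = integer(), n_snps = integer(), length_kb = numeric()
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genomic inbreeding coefficient FROH
#'
#' FROH = sum of ROH segment lengths (kb) divided by the genome length L
#' (kb). The default L = 2,808,525 kb is the total autosomal swine genome
#' length of the Sscrofa10.2 assembly; for simulated maps pass the summed
#' map span instead.
#'
#' @param segments ROH table from \code{\link{detectRoh}}.
#' @param genomeLengthKb genome length L in kb (> 0).
#' @param samples optional sample ids to report (defaults to those present
#'   in \code{segments}); samples without segments get FROH 0.
#' @return data.frame (sample_id, n_segments, total_roh_kb, froh).
#' @export
computeFroh <- function(segments, genomeLengthKb = 2808525,
                        samples = unique(segments$sample_id)) {
  if (genomeLengthKb <= 0) {
    stop("genome length must be positive")
  }
  tot <- tapply(segments$length_kb, segments$sample_id, sum)
  cnt <- table(segments$sample_id)
  res <- data.frame(
    sample_id = as.character(samples),
    n_segments = as.integer(cnt[samples]),
    total_roh_kb = as.numeric(tot[samples])
  )
  res$n_segments[is.na(res$n_segments)] <- 0L
  res$total_roh_kb[is.na(res$total_roh_kb)] <- 0
  res$froh <- res$total_roh_kb / genomeLengthKb
  res
}

#' Compare FROH between cases and controls
#'
#' Two-sample Welch t-test (two-sided) on per-animal FROH values; Welch is
#' used because group sizes and variances typically differ in matched
#' case/control designs. When a group has (numerically) zero variance the
#' pooled statistic is computed with a small variance floor and the result
#' is flagged.
#'
#' @param frohCases,frohControls numeric FROH vectors (length >= 2 each).
#' @return list (mean_case, mean_control, t, p, flagged).
#' @export
frohGroupTest <- function(frohCases, frohControls) {
  if (length(frohCases) < 2 || length(frohControls) < 2) {
    stop("at least two samples per group are required")
  }
  flagged <- FALSE
  if (stats::var(frohCases) == 0 && stats::var(frohControls) == 0 &&
    mean(frohCases) == mean(frohControls)) {
    return(list(
      mean_case = mean(frohCases), mean_control = mean(frohControls),
      t = 0, p = 1, flagged = FALSE
    ))
  }
  if (stats::var(frohCases) == 0 || stats::var(frohControls) == 0) {
    flagged <- TRUE
    eps <- max(1e-12, 1e-6 * abs(mean(c(frohCases, frohControls))))^2
    v1 <- max(stats::var(frohCases), eps)
    v2 <- max(stats::var(frohControls), eps)
    n1 <- length(frohCases)
    n2 <- length(frohControls)
    se <- sqrt(v1 / n1 + v2 / n2)
    t <- (mean(frohCases) - mean(frohControls)) / se
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t), df)
    return(list(
      mean_case = mean(frohCases), mean_control = mean(frohControls),
      t = t, p = p, flagged = flagged
    ))
  }
  tt <- stats::t.test(frohCases, frohControls)
  list(
    mean_case = mean(frohCases), mean_control = mean(frohControls),
    t = unname(tt$statistic), p = tt$p.value, flagged = flagged
  )
}
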