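#' Shared-segment detection parameters
#'
#' Same sliding-window machinery as \code{\link{rohParams}}, applied to a
#' sample pair: a window is IBS-compatible when it contains at most
#' \code{windowIbs0Max} markers at IBS 0 (opposite homozygotes) and at most
#' \code{windowMissMax} markers missing in either sample. The tolerance of
#' one opposite-homozygote per 50-SNP window mirrors the ROH genotyping
#' error allowance. Defaults: segments of at least 100 SNPs and 1000 kb.
#'
#' @param windowSnps,windowIbs0Max,windowMissMax window settings.
#' @param minSnps,minLengthKb segment filters.
#' @param hitFraction per-SNP window hit-rate threshold.
#' @return a named list of class \code{"SharingParams"}.
#' @export
sharingParams <- function(windowSnps = 50, windowIbs0Max = 1,
                          windowMissMax = 1, minSnps = 100,
                          minLengthKb = 1000, hitFraction = 0.05) {
  if (any(c(windowSnps, minSnps, minLengthKb) <= 0) || hitFraction <= 0) {
    stop("sharing parameters must be positive")
  }
  structure(
    list(
      windowSnps = windowSnps, windowHetMax = windowIbs0Max,
      windowMissMax = windowMissMax, minSnps = minSnps,
      minLengthKb = minLengthKb, hitFraction = hitFraction
    ),
    class = "SharingParams"
  )
}

#' Detect IBS-compatible shared segments for one sample pair
#'
#' Windowed scan over the autosomes of an (ideally LD-pruned) panel:
#' windows with at most the allowed opposite-homozygote and missing
#' markers are compatible; SNPs overlapped by enough compatible windows
#' are eligible; maximal eligible runs passing the SNP-count and length
#' filters are emitted. Chromosomes shorter than one window are skipped
#' with a message.
#'
#' @param gd a \link{GenotypeData} object (autosomal, LD-pruned panel).
#' @param sampleA,sampleB sample ids.
#' @param params a \code{\link{sharingParams}} list.
#' @return data.frame (id1, id2, chrom, start_bp, end_bp, n_snps,
#'   length_kb); per pair per chromosome segments never overlap.
#' @export
detectSharedSegments <- function(gd, sampleA, sampleB,
                                 params = sharingParams()) {
  gd <- autosomes(gd)
  mk <- markerInfo(gd)
  calls <- genotypeCalls(gd)
  .pairSegments(
    calls[, sampleA], calls[, sampleB], sampleA, sampleB,
    mk$chrom, mk$bp, params
  )
}

# Raw-matrix pair scan shared by the single-pair and all-pairs entry points.
.pairSegments <- function(x, y, idA, idB, chrom, bp, params) {
  miss <- is.na(x) | is.na(y)
  ibs0 <- !miss & abs(x - y) == 2L
  seg <- .scanSegments(
    bad1 = ibs0, bad2 = miss, chrom = chrom, bp = bp, params = params
  )
  if (nrow(seg) == 0) {
    return(data.frame(
      id1 = character(), id2 = character(), chrom = character(),
      start_bp = integer(), end_bp = integer(), n_snps = integer(),
      length_kb = numeric()
    ))
  }
  cbind(id1 = idA, id2 = idB, seg)
}

#' Detect shared segments for all sample pairs
#'
#' @param gd a \link{GenotypeData} object (autosomal, LD-pruned panel).
#' @param params a \code{\link{sharingParams}} list.
#' @return row-bound segment table over all unordered sample pairs.
#' @export
detectAllSharedSegments <- function(gd, params = sharingParams()) {
  gd <- autosomes(gd)
  mk <- markerInfo(gd)
  calls <- genotypeCalls(gd)
  ids <- colnames(calls)
  pr <- .pairIndices(length(ids))
  out <- vector("list", nrow(pr))
  for (k in seq_len(nrow(pr))) {
    out[[k]] <- suppressMessages(
      .pairSegments(
        calls[, pr$i[k]], calls[, pr$j[k]], ids[pr$i[k]], ids[pr$j[k]],
        mk$chrom, mk$bp, params
      )
    )
  }
  res <- do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
  if (is.null(res)) {
    res <- data.frame(
      id1 = character(), id2 = character(), chrom = character(),
      start_bp = integer(), end_bp = integer(), n_snps = integer(),
      length_kb = numeric()
    )
  }
  rownames(res) <- NULL
  res
}

# Map segments onto the marker grid: per segment the covered grid index
# range on its chromosome, in the grid's storage order.
.segmentGridRange <- function(segments, grid) {
  startIdx <- endIdx <- integer(nrow(segments))
  for (chr in unique(segments$chrom)) {
    gsel <- which(grid$chrom == chr)
    ssel <- which(segments$chrom == chr)
    pos <- grid$bp[gsel]
    s <- findInterval(segments$start_bp[ssel] - 1L, pos) + 1L
    e <- findInterval(segments$end_bp[ssel], pos)
    startIdx[ssel] <- gsel[1] - 1L + s
    endIdx[ssel] <- gsel[1] - 1L + e
  }
  data.frame(start_idx = startIdx, end_idx = endIdx)
}

# Per-position pair-sharing counts for one label assignment via difference
# arrays; pairClass selects which segments count.
.positionCounts <- function(startIdx, endIdx, use, nPos) {
  d <- numeric(nPos + 1L)
  s <- startIdx[use]
  e <- endIdx[use]
  if (length(s) > 0) {
    ds <- tabulate(s, nbins = nPos)
    de <- tabulate(e + 1L, nbins = nPos + 1L)
    d[seq_len(nPos)] <- ds
    d <- d - de
  }
  cumsum(d[seq_len(nPos)])
}

#' Per-position case/case segment-sharing counts
#'
#' At every marker-grid position, counts the sample pairs of each phenotype
#' class (case/case, case/control, control/control) whose shared segment
#' overlaps the position. Segments per pair per chromosome are
#' non-overlapping, so a pair contributes at most one to each position.
#'
#' @param segments all-pairs segment table from
#'   \code{\link{detectAllSharedSegments}}.
#' @param labels named character vector, \code{"case"}/\code{"control"} per
#'   sample id; every sample appearing in \code{segments} must be labelled.
#' @param grid data.frame (chrom, bp) of evaluation positions, sorted by
#'   (chrom, bp) - typically \code{markerInfo()} of the pruned panel.
#' @return list with \code{grid} (chrom, bp, case_case, case_control,
#'   control_control) and the segment/grid bookkeeping reused by
#'   \code{\link{sharingPermutationTest}}.
#' @export
sharingStatistic <- function(segments, labels, grid) {
  ids <- unique(c(segments$id1, segments$id2))
  if (!all(ids %in% names(labels)) ||
    anyNA(labels[ids])) {
    stop("every sample in the segment table must be labelled case/control")
  }
  nPos <- nrow(grid)
  gr <- .segmentGridRange(segments, grid)
  inGrid <- gr$start_idx <= gr$end_idx
  isCase1 <- labels[segments$id1] == "case"
  isCase2 <- labels[segments$id2] == "case"
  cc <- .positionCounts(gr$start_idx, gr$end_idx,
    inGrid & isCase1 & isCase2, nPos
  )
  uu <- .positionCounts(gr$start_idx, gr$end_idx,
    inGrid & !isCase1 & !isCase2, nPos
  )
  cu <- .positionCounts(gr$start_idx, gr$end_idx,
    inGrid & (isCase1 != isCase2), nPos
  )
  list(
    grid = data.frame(
      chrom = grid$chrom, bp = grid$bp, case_case = cc,
      case_control = cu, control_control = uu
    ),
    segment_start = gr$start_idx, segment_end = gr$end_idx,
    segment_in_grid = inGrid,
    segment_id1 = segments$id1, segment_id2 = segments$id2
  )
}

#' Case/case sharing permutation test
#'
#' Permutes case/control labels uniformly over samples (group sizes held
#' fixed); segments are label-free and are not recomputed. Per grid
#' position the empirical p-value is (1 + number of permutations with a
#' case/case count at least the observed) / (1 + nPerm), so the smallest
#' attainable p is 1/(nPerm + 1). Within each chromosome a max-statistic
#' correction is applied: the chromosome-level p compares the observed
#' maximum count against the permutation distribution of per-chromosome
#' maxima. Results are reproducible for a fixed seed.
#'
#' @param segments all-pairs segment table.
#' @param labels named case/control vector over all analysis samples
#'   (including samples without segments - they take part in the shuffle).
#' @param grid evaluation positions (chrom, bp), sorted.
#' @param nPerm number of permutations (>= 1; the reference analysis
#'   setting is 100,000, desk-scale runs use 10,000 or fewer).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of class \code{"PermutationResult"}: \code{positions}
#'   (chrom, bp, observed, null_mean, null_q95, p), \code{chromosomes}
#'   (chrom, observed_max, p), \code{n_perm}, \code{seed}.
#' @export
sharingPermutationTest <- function(segments, labels, grid, nPerm = 10000,
                                   seed) {
  if (nPerm < 1) {
    stop("nPerm must be at least 1")
  }
  if (missing(seed)) {
    stop("a seed is required")
  }
  obsStat <- sharingStatistic(segments, labels, grid)
  obs <- obsStat$grid$case_case
  nPos <- length(obs)
  chromF <- factor(grid$chrom, levels = unique(grid$chrom))
  obsMax <- tapply(obs, chromF, max)

  idAll <- names(labels)
  nCase <- sum(labels == "case")
  i1 <- match(obsStat$segment_id1, idAll)
  i2 <- match(obsStat$segment_id2, idAll)
  sIdx <- obsStat$segment_start
  eIdx <- obsStat$segment_end
  inG <- obsStat$segment_in_grid

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  chromSplit <- split(seq_len(nPos), chromF)
  exceed <- numeric(nPos)
  nullSum <- numeric(nPos)
  chromExceed <- numeric(nlevels(chromF))
  obsMaxV <- as.numeric(obsMax)
  # subsample of null count vectors for the q95 summary
  q95Sample <- matrix(NA_real_, nPos, min(nPerm, 200))
  q95Cols <- unique(round(seq(1, nPerm, length.out = ncol(q95Sample))))
  q95k <- 0L
  nSamp <- length(idAll)
  for (b in seq_len(nPerm)) {
    caseFlag <- logical(nSamp)
    caseFlag[sample.int(nSamp, nCase)] <- TRUE
    use <- inG & caseFlag[i1] & caseFlag[i2]
    cnt <- .positionCounts(sIdx, eIdx, use, nPos)
    exceed <- exceed + (cnt >= obs)
    nullSum <- nullSum + cnt
    permMax <- vapply(chromSplit, function(ix) max(cnt[ix]), numeric(1))
    chromExceed <- chromExceed + (permMax >= obsMaxV)
    if (b %in% q95Cols) {
      q95k <- q95k + 1L
      q95Sample[, q95k] <- cnt
    }
  }
  q95 <- apply(q95Sample[, seq_len(q95k), drop = FALSE], 1,
    stats::quantile,
    probs = 0.95, names = FALSE
  )
  structure(
    list(
      positions = data.frame(
        chrom = grid$chrom, bp = grid$bp, observed = obs,
        null_mean = nullSum / nPerm, null_q95 = q95,
        p = (1 + exceed) / (1 + nPerm)
      ),
      chromosomes = data.frame(
        chrom = levels(chromF), observed_max = as.numeric(obsMax),
        p = as.numeric((1 + chromExceed) / (1 + nPerm))
      ),
      n_perm = nPerm, seed = seed
    ),
    class = "PermutationResult"
  )
}
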