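#' IBS distance matrix
#'
#' Allele-sharing distance between every sample pair: 1 - (mean IBS)/2,
#' where IBS in {0, 1, 2} per marker is evaluated over the pair's
#' non-missing markers. Identical samples sit at distance 0, opposite
#' homozygotes at every marker at distance 1.
#'
#' @param gd a \link{GenotypeData} object with at least two samples.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
ibsDistanceMatrix <- function(gd) {
  calls <- genotypeCalls(gd)
  n <- ncol(calls)
  pr <- .pairIndices(n)
  d <- matrix(0, n, n, dimnames = list(colnames(calls), colnames(calls)))
  for (k in seq_len(nrow(pr))) {
    xi <- calls[, pr$i[k]]
    xj <- calls[, pr$j[k]]
    ok <- !is.na(xi) & !is.na(xj)
    if (!any(ok)) {
      stop(sprintf(
        "samples %s and %s have no overlapping non-missing markers",
        colnames(calls)[pr$i[k]], colnames(calls)[pr$j[k]]
      ))
    }
    ibs <- 2 - abs(xi[ok] - xj[ok])
    d[pr$i[k], pr$j[k]] <- d[pr$j[k], pr$i[k]] <- 1 - mean(ibs) / 2
  }
  d
}

#' Method-of-moments IBD estimation (PI_HAT)
#'
#' PLINK-style moments estimator of the IBD-state proportions (Z0, Z1, Z2)
#' for every sample pair. Expected IBS-state probabilities under IBD 0/1/2
#' are derived from panel allele frequencies and averaged over each pair's
#' non-missing polymorphic markers; Z estimates are solved sequentially,
#' bounded to [0, 1] and renormalized. PI_HAT = Z1/2 + Z2. Estimated on an
#' LD-pruned panel; per-panel allele frequencies make the estimator mildly
#' biased in small cohorts, which is accepted and documented.
#'
#' @param gd a \link{GenotypeData} object (ideally the LD-pruned autosomal
#'   panel).
#' @param alleleFreqs optional per-marker allele-1 frequencies; defaults to
#'   frequencies estimated from \code{gd}.
#' @return data.frame (id1, id2, z0, z1, z2, pi_hat, n_markers).
#' @export
ibdPiHat <- function(gd, alleleFreqs = alleleFreq(gd)) {
  calls <- genotypeCalls(gd)
  p <- alleleFreqs
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) {
    stop("no polymorphic markers available for IBD estimation")
  }
  calls <- calls[poly, , drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  # per-marker expected IBS-state probabilities given IBD state
  e0i0 <- 2 * p^2 * q^2 # P(IBS0 | IBD0)
  e1i0 <- 4 * p^3 * q + 4 * p * q^3 # P(IBS1 | IBD0)
  e2i0 <- 1 - e0i0 - e1i0 # P(IBS2 | IBD0)
  e1i1 <- 2 * p * q # P(IBS1 | IBD1)
  e2i1 <- 1 - e1i1 # P(IBS2 | IBD1)
  n <- ncol(calls)
  pr <- .pairIndices(n)
  res <- data.frame(
    id1 = colnames(calls)[pr$i], id2 = colnames(calls)[pr$j],
    z0 = NA_real_, z1 = NA_real_, z2 = NA_real_, pi_hat = NA_real_,
    n_markers = NA_integer_
  )
  for (k in seq_len(nrow(pr))) {
    xi <- calls[, pr$i[k]]
    xj <- calls[, pr$j[k]]
    ok <- !is.na(xi) & !is.na(xj)
    if (!any(ok)) {
      stop(sprintf(
        "samples %s and %s have no overlapping non-missing markers",
        res$id1[k], res$id2[k]
      ))
    }
    ibs <- 2 - abs(xi[ok] - xj[ok])
    m <- sum(ok)
    o0 <- mean(ibs == 0)
    o1 <- mean(ibs == 1)
    o2 <- mean(ibs == 2)
    E00 <- mean(e0i0[ok])
    E10 <- mean(e1i0[ok])
    E20 <- mean(e2i0[ok])
    E11 <- mean(e1i1[ok])
    E21 <- mean(e2i1[ok])
    z0 <- o0 / E00
    z1 <- (o1 - z0 * E10) / E11
    z2 <- o2 - z0 * E20 - z1 * E21
    z <- pmin(pmax(c(z0, z1, z2), 0), 1)
    if (sum(z) == 0) z <- c(1, 0, 0)
    z <- z / sum(z)
    res$z0[k] <- z[1]
    res$z1[k] <- z[2]
    res$z2[k] <- z[3]
    res$pi_hat[k] <- z[2] / 2 + z[3]
    res$n_markers[k] <- m
  }
  res
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared-distance matrix, eigendecomposes and returns
#' the top-k coordinates scaled by the square root of the eigenvalues
#' (via \code{stats::cmdscale}). For reproducibility each dimension's sign
#' is fixed so that its largest-magnitude loading is positive. If fewer
#' than k positive eigenvalues exist, k is reduced with a warning.
#'
#' @param d symmetric zero-diagonal distance matrix.
#' @param k number of dimensions (default 2).
#' @return list with \code{points} (n x k matrix) and \code{eig}
#'   (non-increasing eigenvalues).
#' @export
classicalMds <- function(d, k = 2) {
  stopifnot(k >= 1)
  n <- nrow(d)
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, n - 1), eig = TRUE)
  pts <- fit$points
  nPos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1))
  if (nPos == 0) {
    pts <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
    return(list(points = pts, eig = fit$eig))
  }
  if (ncol(pts) < k) {
    warning(sprintf(
      "only %d positive dimensions available; k reduced from %d",
      ncol(pts), k
    ))
  }
  for (j in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, j])), j] < 0) {
      pts[, j] <- -pts[, j]
    }
  }
  list(points = pts, eig = fit$eig)
}

#' Flag genetic-background outliers on an MDS projection
#'
#' Deterministic replacement for by-eye outlier removal: a sample is
#' flagged when its Euclidean distance from the per-dimension median centre
#' of MDS dimensions 1-2 exceeds the median distance by more than
#' \code{sdMultiplier} times the MAD of the distances. An explicit
#' \code{override} list short-circuits the rule entirely.
#'
#' @param mds result of \code{\link{classicalMds}} with at least 2 dims.
#' @param sdMultiplier robust-spread multiplier (default 3).
#' @param override optional character vector of sample ids to flag instead
#'   of applying the rule.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flagBackgroundOutliers <- function(mds, sdMultiplier = 3, override = NULL) {
  if (!is.null(override)) {
    return(as.character(override))
  }
  pts <- mds$points
  if (ncol(pts) < 2) {
    stop("projection must have at least 2 dimensions")
  }
  xy <- pts[, 1:2, drop = FALSE]
  ctr <- apply(xy, 2, stats::median)
  dist <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  spread <- stats::mad(dist)
  if (is.na(spread) || spread == 0) {
    return(character())
  }
  rownames(pts)[dist > stats::median(dist) + sdMultiplier * spread]
}
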