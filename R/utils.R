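# Internal helpers shared across modules.

# Chromosome label ordering: numeric labels numerically, then X, Y, XY, MT,
# then anything else alphabetically. X must sort after "18" so that the sex
# chromosome sits at the end of autosome-ordered tables.
.chromLevels <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(u))
  c(
    u[!is.na(num)][order(num[!is.na(num)])],
    intersect(c("X", "Y", "XY", "MT"), u),
    sort(setdiff(u[is.na(num)], c("X", "Y", "XY", "MT")))
  )
}

.isAutosome <- function(chrom) {
  !is.na(suppressWarnings(as.numeric(as.character(chrom))))
}

# Rolling window sums of a 0/1 vector; returns one value per window start.
.rollSum <- function(x, width) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  cs[(width + 1):(n + 1)] - cs[1:(n - width + 1)]
}

# Sliding-window eligibility shared by ROH and shared-segment detection.
# bad1/bad2 are logical per-SNP violation flags (e.g. heterozygous, missing);
# a window of `windowSnps` consecutive SNPs passes when it holds at most
# max1/max2 violations; a SNP is eligible when the fraction of windows
# overlapping it that pass is at least hitFraction. Returns NULL when the
# chromosome is shorter than one window.
.windowEligible <- function(bad1, bad2, windowSnps, max1, max2, hitFraction) {
  L <- length(bad1)
  if (L < windowSnps) {
    return(NULL)
  }
  nw <- L - windowSnps + 1L
  winOk <- (.rollSum(as.integer(bad1), windowSnps) <= max1) &
    (.rollSum(as.integer(bad2), windowSnps) <= max2)
  cw <- cumsum(c(0, winOk))
  s <- seq_len(L)
  lo <- pmax(1L, s - windowSnps + 1L)
  hi <- pmin(s, nw)
  hits <- cw[hi + 1L] - cw[lo]
  hits / (hi - lo + 1L) >= hitFraction
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end) indices.
.trueRuns <- function(eligible) {
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Unordered sample pair index table for n samples.
.pairIndices <- function(n) {
  if (n < 2) {
    stop("at least two samples are required")
  }
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  data.frame(i = i, j = j)
}

# Pearson chi-square for a 2x2 table of counts, 1 df, no continuity
# correction; returns c(chi2, p). Zero margins give chi2 = 0, p = 1.
.chisq2x2 <- function(a, b, c, d) {
  a <- unname(a)
  b <- unname(b)
  c <- unname(c)
  d <- unname(d)
  n <- a + b + c + d
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) {
    return(c(chi2 = 0, p = 1))
  }
  chi2 <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Odds ratio with the Haldane-Anscombe +0.5 correction applied to every cell
# iff any cell is zero, so degenerate tables still report a direction.
.oddsRatio <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5
    b <- b + 0.5
    c <- c + 0.5
    d <- d + 0.5
  }
  (a * d) / (b * c)
}
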