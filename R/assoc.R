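#' Per-marker allelic case/control association
#'
#' For every marker, builds the 2x2 allele-count table (minor/major x
#' case/control) from non-missing calls and computes the Pearson 1-df
#' chi-square without continuity correction, its p-value, and the odds
#' ratio (with the Haldane-Anscombe +0.5 correction applied to all cells
#' iff any cell is zero). The conventional genome-wide screen for panels of
#' this size declares significance at p < 5e-5 downstream.
#'
#' @param gd a \link{GenotypeData} object with case/control phenotypes.
#' @return data.frame (marker_id, chrom, bp, case_minor, case_major,
#'   control_minor, control_major, chi2, p, odds_ratio).
#' @export
allelicTest <- function(gd) {
  ph <- phenotypes(gd)
  if (!any(ph == "case", na.rm = TRUE) ||
    !any(ph == "control", na.rm = TRUE)) {
    stop("both cases and controls are required")
  }
  calls <- genotypeCalls(gd)
  mk <- markerInfo(gd)
  caseCalls <- calls[, which(ph == "case"), drop = FALSE]
  ctrlCalls <- calls[, which(ph == "control"), drop = FALSE]
  aMiss <- rowSums(!is.na(caseCalls))
  bMiss <- rowSums(!is.na(ctrlCalls))
  if (any(aMiss == 0) || any(bMiss == 0)) {
    bad <- which(aMiss == 0 | bMiss == 0)[1]
    grp <- if (aMiss[bad] == 0) "cases" else "controls"
    stop(sprintf(
      "marker %s has no non-missing calls among %s", mk$marker_id[bad], grp
    ))
  }
  a <- rowSums(caseCalls, na.rm = TRUE) # case minor-allele count
  b <- 2 * aMiss - a
  c <- rowSums(ctrlCalls, na.rm = TRUE)
  d <- 2 * bMiss - c
  n <- a + b + c + d
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  c2 <- b + d
  chi2 <- ifelse(
    c1 == 0 | c2 == 0, 0,
    n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  )
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  or <- mapply(.oddsRatio, a, b, c, d)
  data.frame(
    marker_id = mk$marker_id, chrom = mk$chrom, bp = mk$bp,
    case_minor = a, case_major = b, control_minor = c, control_major = d,
    chi2 = chi2, p = p, odds_ratio = or, row.names = NULL
  )
}

#' Genomic inflation factor
#'
#' lambda_GC = median(chi-square) / 0.4549, the null median of a 1-df
#' chi-square. Values near 1 indicate no population stratification.
#'
#' @param chi2 vector of 1-df association statistics.
#' @return list (lambda_gc, n_markers).
#' @export
genomicInflation <- function(chi2) {
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) == 0) {
    stop("at least one finite statistic is required")
  }
  list(
    lambda_gc = stats::median(chi2) / stats::qchisq(0.5, df = 1),
    n_markers = length(chi2)
  )
}

#' Quantile-quantile plot coordinates
#'
#' Sorted observed p-values against uniform expectations (rank - 0.5)/n,
#' both on the -log10 scale; p = 0 is clamped to 1/(2n) with a warning.
#'
#' @param p vector of p-values in (0, 1].
#' @return data.frame (expected, observed) of -log10 pairs, plot-ready.
#' @export
qqPoints <- function(p) {
  n <- length(p)
  if (any(p == 0)) {
    warning("p = 0 clamped to 1/(2n)")
    p[p == 0] <- 1 / (2 * n)
  }
  obs <- sort(p)
  expd <- (seq_len(n) - 0.5) / n
  data.frame(expected = -log10(expd), observed = -log10(obs))
}

#' Per-marker logistic effect estimate
#'
#' Single-predictor logistic regression of case status on the
#' additive-coded genotype (intercept included), fitted by iteratively
#' reweighted least squares (tolerance 1e-10, at most 50 iterations), with
#' the Wald test on the genotype coefficient. Complete or quasi-complete
#' separation is detected (diverging coefficient / degenerate fitted
#' probabilities) and flagged; no Wald p is then reported.
#'
#' @param callsVec additive-coded calls (0/1/2, NA dropped with its label).
#' @param labels case/control vector aligned with \code{callsVec}.
#' @return list (beta, se, p, separated).
#' @export
logisticEffect <- function(callsVec, labels) {
  ok <- !is.na(callsVec) & !is.na(labels)
  x <- callsVec[ok]
  y <- as.integer(labels[ok] == "case")
  if (length(unique(x)) < 2) {
    stop("marker is monomorphic among the analysed samples")
  }
  if (length(unique(y)) < 2) {
    stop("both outcome classes are required")
  }
  fit <- suppressWarnings(stats::glm(
    y ~ x,
    family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 50)
  ))
  beta <- unname(stats::coef(fit)["x"])
  se <- unname(summary(fit)$coefficients["x", "Std. Error"])
  mu <- stats::fitted(fit)
  separated <- !fit$converged || abs(beta) > 15 ||
    all(mu > 1 - 1e-8 | mu < 1e-8)
  if (separated) {
    return(list(beta = beta, se = NA_real_, p = NA_real_, separated = TRUE))
  }
  z <- beta / se
  list(
    beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)),
    separated = FALSE
  )
}
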