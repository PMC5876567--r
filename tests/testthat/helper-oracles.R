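# Shared fixtures and independent brute-force oracles used across tests.

# Minimal GenotypeData builder: calls is markers x samples.
makeGd <- function(calls, chrom = "1", bp = NULL, phenotype = NULL,
                   allele1 = "A", allele2 = "G") {
  m <- nrow(calls)
  n <- ncol(calls)
  if (is.null(bp)) bp <- seq_len(m) * 100000L
  if (is.null(phenotype)) phenotype <- rep(NA_character_, n)
  chrom <- rep_len(chrom, m)
  mk <- data.frame(
    marker_id = sprintf("m%04d", seq_len(m)), chrom = chrom,
    cm = bp / 1e6, bp = bp,
    allele1 = rep_len(allele1, m), allele2 = rep_len(allele2, m)
  )
  sm <- data.frame(
    family_id = "F", sample_id = sprintf("s%03d", seq_len(n)),
    sire_id = "0", dam_id = "0", sex = "male",
    phenotype = phenotype
  )
  GenotypeData(calls, mk, sm)
}

# Exact HWE p by direct enumeration of every heterozygote configuration,
# with probabilities from the log-factorial formula (independent of the
# package's recurrence).
oracleHweP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  r <- min(nA, na)
  if (r == 0) {
    return(1)
  }
  hs <- seq(r %% 2, r, by = 2)
  logp <- vapply(hs, function(h) {
    hr <- (r - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(nAa, hs)]
  sum(p[p <= obs * (1 + 1e-9)])
}

# Brute-force sliding-window segment scan for one violation-flag pair on a
# single chromosome: explicit loops over windows, SNPs and runs.
oracleScanOneChrom <- function(bad1, bad2, bp, params) {
  L <- length(bad1)
  w <- params$windowSnps
  if (L < w) {
    return(data.frame(start = integer(), end = integer()))
  }
  winOk <- logical(L - w + 1)
  for (i in seq_len(L - w + 1)) {
    winOk[i] <- sum(bad1[i:(i + w - 1)]) <= params$windowHetMax &&
      sum(bad2[i:(i + w - 1)]) <= params$windowMissMax
  }
  elig <- logical(L)
  for (s in seq_len(L)) {
    wins <- max(1, s - w + 1):min(s, L - w + 1)
    elig[s] <- mean(winOk[wins]) >= params$hitFraction
  }
  runs <- data.frame(start = integer(), end = integer())
  s <- 1
  while (s <= L) {
    if (elig[s]) {
      e <- s
      while (e < L && elig[e + 1]) e <- e + 1
      nSnps <- e - s + 1
      lenKb <- (bp[e] - bp[s]) / 1000
      if (nSnps >= params$minSnps && lenKb >= params$minLengthKb) {
        runs <- rbind(runs, data.frame(start = s, end = e))
      }
      s <- e + 1
    } else {
      s <- s + 1
    }
  }
  runs
}

oracleRohOneSample <- function(x, chrom, bp, params) {
  out <- NULL
  for (chr in unique(chrom[.isAuto(chrom)])) {
    sel <- chrom == chr
    runs <- oracleScanOneChrom(
      !is.na(x[sel]) & x[sel] == 1, is.na(x[sel]), bp[sel], params
    )
    if (nrow(runs) > 0) {
      out <- rbind(out, data.frame(
        chrom = chr, start_bp = bp[sel][runs$start],
        end_bp = bp[sel][runs$end], n_snps = runs$end - runs$start + 1
      ))
    }
  }
  out
}

oracleSharingOnePair <- function(x, y, chrom, bp, params) {
  miss <- is.na(x) | is.na(y)
  ibs0 <- !miss & abs(x - y) == 2
  out <- NULL
  for (chr in unique(chrom[.isAuto(chrom)])) {
    sel <- chrom == chr
    runs <- oracleScanOneChrom(ibs0[sel], miss[sel], bp[sel], params)
    if (nrow(runs) > 0) {
      out <- rbind(out, data.frame(
        chrom = chr, start_bp = bp[sel][runs$start],
        end_bp = bp[sel][runs$end], n_snps = runs$end - runs$start + 1
      ))
    }
  }
  out
}

.isAuto <- function(chrom) !is.na(suppressWarnings(as.numeric(chrom)))

# Naive per-pair IBS distance loop.
oracleIbsMatrix <- function(calls) {
  n <- ncol(calls)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      m <- 0
      for (k in seq_len(nrow(calls))) {
        if (!is.na(calls[k, i]) && !is.na(calls[k, j])) {
          s <- s + 2 - abs(calls[k, i] - calls[k, j])
          m <- m + 1
        }
      }
      d[i, j] <- 1 - (s / m) / 2
    }
  }
  d
}

# 2x2 chi-square by the observed-vs-expected cell route (the package uses
# the closed form), and odds ratio by direct division.
oracleChi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - e)^2 / e)
}

# Grid-search maximum-likelihood haplotype frequencies for a 2-marker span
# whose haplotype space is restricted to AB/ab mixtures (plus the double
# heterozygote ambiguity). freqs searched on a 3-decimal grid.
oracleEmGrid <- function(genoCounts) {
  # genoCounts: named counts of genotype signatures "g1/g2" for 2 markers
  haps <- list(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  grid <- seq(0, 1, by = 0.001)
  bestLL <- -Inf
  bestF <- NULL
  # restrict to 2 free haplotypes AB and ab (others 0) as constructed
  for (f in grid) {
    fr <- c(f, 0, 0, 1 - f)
    ll <- 0
    for (g in names(genoCounts)) {
      gv <- as.numeric(strsplit(g, "/")[[1]])
      pg <- 0
      for (i in 1:4) {
        for (j in i:4) {
          if (all(haps[[i]] + haps[[j]] == gv)) {
            pg <- pg + (2 - (i == j)) * fr[i] * fr[j]
          }
        }
      }
      ll <- ll + genoCounts[[g]] * log(pg)
    }
    if (ll > bestLL) {
      bestLL <- ll
      bestF <- fr
    }
  }
  list(freq = bestF, logLik = bestLL)
}
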