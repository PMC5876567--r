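#' Configuration for the pedigree gene-drop simulator
#'
#' Describes the synthetic population emulating a commercial swine
#' case/control cohort: a marker map over 18 autosomes plus X, founder
#' allele frequencies, a three-generation partially inbred pedigree, a
#' Haldane (no-interference) recombination model at 1 cM per Mb, and a
#' risk haplotype implanted on founder chromosomes whose carriers have
#' elevated penetrance. An optional protective pattern at the same focal
#' marker pair (default penetrance 0) reproduces the two-sided structure
#' of real risk-locus reports, where the alternative haplotype is absent
#' from affected animals.
#'
#' Default penetrances and implant frequency were chosen analytically so
#' that the expected carrier pattern in a 35-case / 18-control draw is
#' about 83\% vs 40\% for the risk haplotype and 0\% vs about 39\% for the
#' protective one.
#'
#' @param nAutosomes number of autosomes (default 18).
#' @param markersPerAutosome,xMarkers markers per autosome / on X.
#' @param autosomeLengthBp,xLengthBp chromosome lengths in bp.
#' @param mafRange founder allele-1 frequency range (uniform draw).
#' @param cmPerMb genetic map scale (0 disables recombination).
#' @param pedigree \code{"herd"} (default) or \code{"first_cousin"}.
#' @param nFounderSires,nFounderDams,nOffspringPerDam,nMatings herd
#'   pedigree shape.
#' @param nFinal size of the final genotyped generation pool.
#' @param risk list describing the implanted locus: \code{chrom},
#'   \code{centerBp}, \code{spanBp}, \code{implantFreq} (probability a
#'   founder chromosome carries the implant), \code{focalAllele1Freq}
#'   (founder allele-1 frequency at the two focal markers),
#'   \code{fRisk}, \code{fBase}, \code{fProtective} (penetrances for risk
#'   carriers, non-carriers, protective carriers). \code{NULL} disables
#'   the implant and gives every animal penetrance \code{fBase}.
#' @param missingRate per-call missingness probability.
#' @param caseN,controlN target study cohort sizes.
#' @param seed mandatory RNG seed.
#' @return a named list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nAutosomes = 18, markersPerAutosome = 300,
                      xMarkers = 150, autosomeLengthBp = 140e6,
                      xLengthBp = 125e6, mafRange = c(0.05, 0.5),
                      cmPerMb = 1, pedigree = "herd",
                      nFounderSires = 5, nFounderDams = 20,
                      nOffspringPerDam = 2, nMatings = 40, nFinal = 220,
                      risk = list(
                        chrom = "2", centerBp = 70e6, spanBp = 5e6,
                        implantFreq = 0.285, focalAllele1Freq = 0.75,
                        fRisk = 0.64, fBase = 0.21, fProtective = 0
                      ),
                      missingRate = 0.002, caseN = 35, controlN = 18,
                      seed) {
  if (missing(seed)) {
    stop("a seed is mandatory")
  }
  if (!is.null(risk)) {
    pen <- c(risk$fRisk, risk$fBase, risk$fProtective)
    if (any(pen < 0 | pen > 1)) {
      stop("penetrances must lie in [0, 1]")
    }
    if (!(risk$chrom %in% as.character(seq_len(nAutosomes)))) {
      stop("risk chromosome outside the autosomal map")
    }
    if (risk$centerBp > autosomeLengthBp) {
      stop("risk span outside the map")
    }
  }
  structure(
    list(
      nAutosomes = nAutosomes, markersPerAutosome = markersPerAutosome,
      xMarkers = xMarkers, autosomeLengthBp = autosomeLengthBp,
      xLengthBp = xLengthBp, mafRange = mafRange, cmPerMb = cmPerMb,
      pedigree = pedigree, nFounderSires = nFounderSires,
      nFounderDams = nFounderDams, nOffspringPerDam = nOffspringPerDam,
      nMatings = nMatings, nFinal = nFinal, risk = risk,
      missingRate = missingRate, caseN = caseN, controlN = controlN,
      seed = seed
    ),
    class = "SimConfig"
  )
}

# Pedigree builders: data.frame(id, sire, dam, sex, generation), founders
# have sire = dam = "0", rows in drop order (parents before offspring).
.pedigreeHerd <- function(cfg) {
  sires <- sprintf("S%02d", seq_len(cfg$nFounderSires))
  dams <- sprintf("D%02d", seq_len(cfg$nFounderDams))
  ped <- data.frame(
    id = c(sires, dams), sire = "0", dam = "0",
    sex = c(
      rep("male", length(sires)),
      rep("female", length(dams))
    ),
    generation = 0L
  )
  g1 <- NULL
  k <- 0L
  for (d in seq_along(dams)) {
    s <- sires[(d - 1L) %% length(sires) + 1L]
    for (o in seq_len(cfg$nOffspringPerDam)) {
      k <- k + 1L
      g1 <- rbind(g1, data.frame(
        id = sprintf("G1_%03d", k), sire = s, dam = dams[d],
        sex = if (k %% 2 == 0) "female" else "male", generation = 1L
      ))
    }
  }
  males <- g1$id[g1$sex == "male"]
  females <- g1$id[g1$sex == "female"]
  matings <- data.frame(
    sire = sample(males, cfg$nMatings, replace = TRUE),
    dam = sample(females, cfg$nMatings, replace = TRUE)
  )
  g2 <- data.frame(
    id = sprintf("G2_%03d", seq_len(cfg$nFinal)),
    sire = matings$sire[(seq_len(cfg$nFinal) - 1L) %% cfg$nMatings + 1L],
    dam = matings$dam[(seq_len(cfg$nFinal) - 1L) %% cfg$nMatings + 1L],
    sex = "male", generation = 2L
  )
  rbind(ped, g1, g2)
}

.pedigreeFirstCousin <- function(cfg) {
  founders <- data.frame(
    id = c("GA", "GB", "W", "X"), sire = "0", dam = "0",
    sex = c("male", "female", "female", "male"), generation = 0L
  )
  g1 <- data.frame(
    id = c("U", "V", "P1", "P2"),
    sire = c("GA", "GA", "U", "X"),
    dam = c("GB", "GB", "W", "V"),
    sex = c("male", "female", "male", "female"),
    generation = c(1L, 1L, 2L, 2L)
  )
  finals <- data.frame(
    id = sprintf("FC_%03d", seq_len(cfg$nFinal)),
    sire = "P1", dam = "P2", sex = "male", generation = 3L
  )
  rbind(founders, g1, finals)
}

# Pedigree inbreeding coefficients via the kinship recursion.
.pedigreeF <- function(ped) {
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  Fcoef <- stats::setNames(numeric(n), ped$id)
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    if (s == "0" || d == "0") {
      K[i, i] <- 0.5
    } else {
      Fcoef[i] <- K[s, d]
      K[i, i] <- 0.5 * (1 + Fcoef[i])
    }
    if (i > 1) {
      for (j in seq_len(i - 1L)) {
        K[i, j] <- K[j, i] <- if (s == "0" || d == "0") {
          0
        } else {
          0.5 * (K[s, ped$id[j]] + K[d, ped$id[j]])
        }
      }
    }
  }
  Fcoef
}

# One gamete from a parent: Haldane crossovers on the cM map, per
# chromosome; returns index vector selecting haplotype 1 or 2 per marker.
.gameteChoice <- function(cmByChrom) {
  unlist(lapply(cmByChrom, function(cm) {
    lenM <- (max(cm) - min(cm)) / 100
    nx <- stats::rpois(1, lenM)
    start <- sample(1:2, 1)
    if (nx == 0 || lenM == 0) {
      return(rep(start, length(cm)))
    }
    xpos <- sort(stats::runif(nx, min(cm), max(cm)))
    seg <- findInterval(cm, xpos, left.open = TRUE)
    (start - 1L + seg) %% 2L + 1L
  }), use.names = FALSE)
}

#' Simulate a pedigree population by gene-dropping
#'
#' Draws founder haplotypes from the configured allele frequencies,
#' implants the risk haplotype on founder chromosomes, drops haplotypes
#' through the pedigree with Haldane-model crossovers on the cM map, and
#' returns the final-generation pool as a \link{GenotypeData} object (with
#' missing calls injected at the configured rate) together with the full
#' transmission record.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return list with \code{genotypes} (finals, phenotype unset) and
#'   \code{truth}: map, pedigree with inbreeding coefficients, per-final
#'   haplotype and founder-origin matrices (markers x individuals),
#'   realized autozygosity per final, risk/protective carrier status, and
#'   the identity of the final pool.
#' @export
simulatePopulation <- function(config) {
  set.seed(config$seed)
  nA <- config$nAutosomes
  mA <- config$markersPerAutosome
  chroms <- c(as.character(seq_len(nA)), "X")
  nPer <- c(rep(mA, nA), config$xMarkers)
  lens <- c(rep(config$autosomeLengthBp, nA), config$xLengthBp)
  mk <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    bp <- round(seq(1e5, lens[ci], length.out = nPer[ci]))
    data.frame(
      marker_id = sprintf("snp_%s_%04d", chroms[ci], seq_len(nPer[ci])),
      chrom = chroms[ci], cm = bp / 1e6 * config$cmPerMb, bp = bp
    )
  }))
  letterPairs <- rbind(
    c("A", "G"), c("A", "C"), c("A", "T"),
    c("C", "G"), c("C", "T"), c("G", "T")
  )
  lp <- letterPairs[sample.int(6, nrow(mk), replace = TRUE), , drop = FALSE]
  mk$allele1 <- lp[, 1]
  mk$allele2 <- lp[, 2]
  M <- nrow(mk)
  p1 <- stats::runif(M, config$mafRange[1], config$mafRange[2])

  risk <- config$risk
  spanIdx <- integer(0)
  focalIdx <- integer(0)
  if (!is.null(risk)) {
    onChr <- which(mk$chrom == risk$chrom)
    spanIdx <- onChr[abs(mk$bp[onChr] - risk$centerBp) <= risk$spanBp / 2]
    if (length(spanIdx) < 2) {
      stop("risk span covers fewer than two markers")
    }
    focalIdx <- spanIdx[order(abs(mk$bp[spanIdx] - risk$centerBp))][1:2]
    focalIdx <- sort(focalIdx)
    p1[focalIdx] <- risk$focalAllele1Freq
  }

  ped <- switch(config$pedigree,
    herd = .pedigreeHerd(config),
    first_cousin = .pedigreeFirstCousin(config),
    stop("unknown pedigree type: ", config$pedigree)
  )
  Fcoef <- .pedigreeF(ped)
  n <- nrow(ped)
  hap1 <- matrix(0L, M, n, dimnames = list(mk$marker_id, ped$id))
  hap2 <- hap1 # 1 = carries allele 1
  org1 <- matrix(0L, M, n, dimnames = list(mk$marker_id, ped$id))
  org2 <- org1 # founder haplotype id
  cmByChrom <- split(mk$cm, factor(mk$chrom, levels = chroms))
  founderHapId <- 0L
  for (i in seq_len(n)) {
    if (ped$sire[i] == "0") {
      for (h in 1:2) {
        hap <- as.integer(stats::runif(M) < p1)
        founderHapId <- founderHapId + 1L
        if (!is.null(risk) &&
          stats::runif(1) < risk$implantFreq) {
          hap[spanIdx] <- 0L # implant carries allele 2 along the span
        }
        if (h == 1) {
          hap1[, i] <- hap
          org1[, i] <- founderHapId
        } else {
          hap2[, i] <- hap
          org2[, i] <- founderHapId
        }
      }
    } else {
      si <- match(ped$sire[i], ped$id)
      di <- match(ped$dam[i], ped$id)
      ch <- .gameteChoice(cmByChrom)
      hap1[, i] <- ifelse(ch == 1L, hap1[, si], hap2[, si])
      org1[, i] <- ifelse(ch == 1L, org1[, si], org2[, si])
      ch <- .gameteChoice(cmByChrom)
      hap2[, i] <- ifelse(ch == 1L, hap1[, di], hap2[, di])
      org2[, i] <- ifelse(ch == 1L, org1[, di], org2[, di])
    }
  }
  finals <- ped$id[ped$generation == max(ped$generation)]
  fi <- match(finals, ped$id)
  calls <- hap1[, fi, drop = FALSE] + hap2[, fi, drop = FALSE]
  if (config$missingRate > 0) {
    miss <- matrix(
      stats::runif(length(calls)) < config$missingRate,
      nrow(calls), ncol(calls)
    )
    calls[miss] <- NA_integer_
  }
  samples <- data.frame(
    family_id = "SIM", sample_id = finals,
    sire_id = ped$sire[fi], dam_id = ped$dam[fi],
    sex = ped$sex[fi], phenotype = NA_character_
  )
  gd <- GenotypeData(calls, mk, samples)

  riskCarrier <- protCarrier <- stats::setNames(
    rep(FALSE, length(finals)), finals
  )
  if (!is.null(risk)) {
    f1 <- focalIdx[1]
    f2 <- focalIdx[2]
    isR <- function(hp, i) hp[f1, i] == 0L && hp[f2, i] == 0L
    isP <- function(hp, i) hp[f1, i] == 1L && hp[f2, i] == 0L
    for (k in seq_along(fi)) {
      i <- fi[k]
      riskCarrier[k] <- isR(hap1, i) || isR(hap2, i)
      protCarrier[k] <- isP(hap1, i) || isP(hap2, i)
    }
  }
  autoz <- colMeans((org1[, fi, drop = FALSE] ==
    org2[, fi, drop = FALSE])[.isAutosome(mk$chrom), , drop = FALSE])
  truth <- list(
    map = mk, pedigree = cbind(ped, f_pedigree = Fcoef),
    hap1 = hap1, hap2 = hap2, origin1 = org1, origin2 = org2,
    finals = finals, autozygosity = stats::setNames(autoz, finals),
    risk_carrier = riskCarrier, protective_carrier = protCarrier,
    focal_markers = mk$marker_id[focalIdx],
    span_markers = mk$marker_id[spanIdx]
  )
  list(genotypes = gd, truth = truth)
}

#' Assign case/control phenotypes by penetrance
#'
#' Each final-generation animal becomes affected with the penetrance of
#' its carrier class (protective carriers, risk carriers, non-carriers);
#' exactly \code{caseN} cases and \code{controlN} controls are then drawn
#' from the affected/unaffected pools.
#'
#' @param truth the \code{truth} element of \code{\link{simulatePopulation}}.
#' @param risk the risk list of the \code{\link{simConfig}} used (or
#'   \code{NULL} with \code{fBase} for a null generator).
#' @param caseN,controlN required group sizes.
#' @param seed RNG seed.
#' @param fBase penetrance used when \code{risk} is \code{NULL}.
#' @return data.frame (sample_id, affected, phenotype) where phenotype is
#'   \code{"case"}, \code{"control"} or \code{NA} for unsampled animals.
#' @export
assignPhenotypes <- function(truth, risk, caseN, controlN, seed,
                             fBase = 0.5) {
  set.seed(seed)
  ids <- truth$finals
  if (is.null(risk)) {
    pAff <- rep(fBase, length(ids))
  } else {
    pAff <- ifelse(
      truth$protective_carrier[ids], risk$fProtective,
      ifelse(truth$risk_carrier[ids], risk$fRisk, risk$fBase)
    )
  }
  affected <- stats::runif(length(ids)) < pAff
  if (sum(affected) < caseN || sum(!affected) < controlN) {
    stop(sprintf(
      "infeasible sampling: %d affected (need %d), %d unaffected (need %d)",
      sum(affected), caseN, sum(!affected), controlN
    ))
  }
  phen <- rep(NA_character_, length(ids))
  aff <- which(affected)
  una <- which(!affected)
  phen[aff[sample.int(length(aff), caseN)]] <- "case"
  phen[una[sample.int(length(una), controlN)]] <- "control"
  data.frame(sample_id = ids, affected = affected, phenotype = phen)
}

#' Simulate a ready-to-analyse case/control study cohort
#'
#' Convenience wrapper: gene-drop the population, assign phenotypes, and
#' subset to the sampled study animals (cases + controls) with phenotypes
#' filled in.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return list (genotypes, truth, phenotypes) where \code{genotypes} is
#'   the study cohort of \code{caseN + controlN} animals.
#' @export
simulateCaseControlCohort <- function(config) {
  pop <- simulatePopulation(config)
  phen <- assignPhenotypes(
    pop$truth, config$risk, config$caseN, config$controlN,
    seed = config$seed + 1L
  )
  keep <- !is.na(phen$phenotype)
  gd <- pop$genotypes[, phen$sample_id[keep]]
  SummarizedExperiment::colData(gd)$phenotype <-
    phen$phenotype[keep][match(colnames(gd), phen$sample_id[keep])]
  list(genotypes = gd, truth = pop$truth, phenotypes = phen)
}

#' Simulate an unstructured null case/control panel
#'
#' Unrelated samples at independent Hardy-Weinberg markers (allele-1
#' frequencies uniform on \code{mafRange}), with case/control labels
#' assigned at random - a null generator with no association or
#' stratification, used for calibration checks such as the genomic
#' inflation factor.
#'
#' @param nSamples,nMarkers panel size.
#' @param nCase number of samples labelled case (rest are controls).
#' @param mafRange allele-frequency range.
#' @param missingRate per-call missingness.
#' @param seed RNG seed.
#' @return a \link{GenotypeData} object.
#' @export
simulateNullPanel <- function(nSamples = 53, nMarkers = 2000, nCase = 35,
                              mafRange = c(0.05, 0.5), missingRate = 0,
                              seed) {
  set.seed(seed)
  p <- stats::runif(nMarkers, mafRange[1], mafRange[2])
  calls <- matrix(
    stats::rbinom(nMarkers * nSamples, 2, rep(p, nSamples)),
    nMarkers, nSamples
  )
  if (missingRate > 0) {
    calls[matrix(
      stats::runif(length(calls)) < missingRate,
      nMarkers, nSamples
    )] <- NA_integer_
  }
  phen <- rep("control", nSamples)
  phen[sample.int(nSamples, nCase)] <- "case"
  mk <- data.frame(
    marker_id = sprintf("null_%05d", seq_len(nMarkers)), chrom = "1",
    cm = seq_len(nMarkers) * 0.1, bp = seq_len(nMarkers) * 100000L,
    allele1 = "A", allele2 = "G"
  )
  sm <- data.frame(
    family_id = "NULL", sample_id = sprintf("ind_%03d", seq_len(nSamples)),
    sire_id = "0", dam_id = "0", sex = "male", phenotype = phen
  )
  GenotypeData(calls, mk, sm)
}

#' Force a shared haplotype segment into selected samples
#'
#' Overwrites the calls of \code{sampleIds} over [startBp, endBp] on one
#' chromosome with a common homozygous haplotype (drawn once from the
#' panel allele frequencies), so every pair of those samples shares the
#' segment at IBS 2. Used to build positive controls for the segment
#' sharing permutation test.
#'
#' @param gd a \link{GenotypeData} object.
#' @param chrom,startBp,endBp segment coordinates (1-based, closed).
#' @param sampleIds samples to receive the shared segment.
#' @param seed RNG seed for the haplotype draw.
#' @return the modified \code{GenotypeData}.
#' @export
implantSharedSegment <- function(gd, chrom, startBp, endBp, sampleIds,
                                 seed) {
  set.seed(seed)
  mk <- markerInfo(gd)
  sel <- which(mk$chrom == chrom & mk$bp >= startBp & mk$bp <= endBp)
  if (length(sel) == 0) {
    stop("no markers in the requested span")
  }
  p <- alleleFreq(gd)[sel]
  hap <- as.integer(stats::runif(length(sel)) < p)
  calls <- genotypeCalls(gd)
  calls[sel, sampleIds] <- 2L * hap
  GenotypeData(calls, mk, sampleInfo(gd))
}

#' Write a simulated dataset as a PED/MAP fixture with truth tables
#'
#' @param cohort list from \code{\link{simulateCaseControlCohort}} (or a
#'   bare \code{GenotypeData} in \code{$genotypes}).
#' @param outDir output directory (created if needed).
#' @param prefix file name prefix (default "fixture").
#' @return named character vector of the written paths.
#' @export
writeFixture <- function(cohort, outDir, prefix = "fixture") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pedPath <- file.path(outDir, paste0(prefix, ".ped"))
  mapPath <- file.path(outDir, paste0(prefix, ".map"))
  writePedMap(cohort$genotypes, pedPath, mapPath)
  paths <- c(ped = pedPath, map = mapPath)
  if (!is.null(cohort$truth)) {
    truthPath <- file.path(outDir, paste0(prefix, "_truth.tsv"))
    tr <- cohort$truth
    utils::write.table(
      data.frame(
        sample_id = tr$finals,
        risk_carrier = tr$risk_carrier[tr$finals],
        protective_carrier = tr$protective_carrier[tr$finals],
        autozygosity = tr$autozygosity[tr$finals],
        f_pedigree = tr$pedigree$f_pedigree[
          match(tr$finals, tr$pedigree$id)
        ]
      ),
      truthPath,
      quote = FALSE, sep = "\t", row.names = FALSE
    )
    paths <- c(paths, truth = truthPath)
  }
  paths
}
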