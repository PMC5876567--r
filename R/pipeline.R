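#' Pipeline configuration
#'
#' Collects every stage parameter with its conventional default so a run
#' is fully described by one object: QC thresholds, LD-pruning window, MDS
#' outlier rule, ROH and segment-sharing parameters, permutation count,
#' association threshold and the RNG seed (mandatory, used by the
#' permutation stage).
#'
#' @param pedPath,mapPath PLINK text input paths (or supply
#'   \code{genotypes}).
#' @param genotypes optional \link{GenotypeData} object, overrides paths.
#' @param outDir optional output directory for per-stage TSV artifacts.
#' @param qc a \code{\link{qcThresholds}} list.
#' @param roh a \code{\link{rohParams}} list.
#' @param sharing a \code{\link{sharingParams}} list.
#' @param pruneWindow,pruneStep LD-pruning window/step in SNPs.
#' @param nPerm permutations for the sharing test (default 10,000; the
#'   reference analysis setting is 100,000).
#' @param assocThreshold genome-wide significance threshold (5e-5).
#' @param mdsDims,outlierSd,outlierOverride MDS outlier-screen settings.
#' @param genomeLengthKb FROH denominator; \code{NULL} (default) uses the
#'   summed autosomal map span of the analysed panel.
#' @param hetSd heterozygosity-excess flagging threshold in SD units.
#' @param seed RNG seed (mandatory).
#' @return a named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(pedPath = NULL, mapPath = NULL, genotypes = NULL,
                           outDir = NULL, qc = qcThresholds(),
                           roh = rohParams(), sharing = sharingParams(),
                           pruneWindow = 50, pruneStep = 5, nPerm = 10000,
                           assocThreshold = 5e-5, mdsDims = 2,
                           outlierSd = 3, outlierOverride = NULL,
                           genomeLengthKb = NULL, hetSd = 3, seed) {
  if (missing(seed)) {
    stop("a seed is mandatory")
  }
  if (is.null(genotypes) && (is.null(pedPath) || is.null(mapPath))) {
    stop("either genotypes or pedPath+mapPath must be supplied")
  }
  structure(
    list(
      pedPath = pedPath, mapPath = mapPath, genotypes = genotypes,
      outDir = outDir, qc = qc, roh = roh, sharing = sharing,
      pruneWindow = pruneWindow, pruneStep = pruneStep, nPerm = nPerm,
      assocThreshold = assocThreshold, mdsDims = mdsDims,
      outlierSd = outlierSd, outlierOverride = outlierOverride,
      genomeLengthKb = genomeLengthKb, hetSd = hetSd, seed = seed
    ),
    class = "PipelineConfig"
  )
}

.writeTsv <- function(x, outDir, name) {
  if (!is.null(outDir)) {
    utils::write.table(x, file.path(outDir, name),
      quote = FALSE, sep = "\t", row.names = FALSE
    )
  }
}

#' Run the full analysis pipeline
#'
#' Executes the stages in the standard order: sample screens
#' (heterozygosity excess, missingness) and marker QC; LD pruning;
#' IBS/MDS genetic-background outlier removal; IBD estimation; ROH
#' detection and FROH with the case/control t-test; pairwise shared
#' segments with the case/case permutation test; and the per-marker
#' allelic GWAS with inflation factor, QQ table, logistic effects and
#' per-chromosome haplotype tests on the associated markers. A failure in
#' any stage aborts with the stage name; identical seed and input give
#' identical results.
#'
#' @param config a \code{\link{pipelineConfig}} object.
#' @return a list of class \code{"RunReport"}: per-stage attrition table
#'   (\code{stages}), headline statistics (\code{headline}), and the
#'   per-stage result objects (\code{qc_report}, \code{mds},
#'   \code{outliers}, \code{ibd}, \code{roh}, \code{froh},
#'   \code{froh_test}, \code{segments}, \code{sharing}, \code{assoc},
#'   \code{inflation}, \code{qq}, \code{haplotypes}, \code{logistic}).
#' @export
runPipeline <- function(config) {
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  }
  stages <- data.frame(
    stage = character(), n_samples = integer(), n_markers = integer(),
    seconds = numeric()
  )
  mark <- function(stage, gd, t0) {
    stages <<- rbind(stages, data.frame(
      stage = stage, n_samples = nSamples(gd), n_markers = nMarkers(gd),
      seconds = round(as.numeric(Sys.time()) - t0, 2)
    ))
  }
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  t0 <- as.numeric(Sys.time())
  gd <- run("input", {
    if (!is.null(config$genotypes)) {
      config$genotypes
    } else {
      readPedMap(config$pedPath, config$mapPath)
    }
  })
  mark("input", gd, t0)

  t0 <- as.numeric(Sys.time())
  het <- run("sample_het", sampleHetCheck(gd, sdMultiplier = config$hetSd))
  if (any(het$flagged)) {
    gd <- gd[, !colnames(gd) %in% het$sample_id[het$flagged]]
  }
  qcRes <- run("marker_qc", filterMarkers(gd, config$qc))
  gd <- qcRes$genotypes
  mark("marker_qc", gd, t0)

  t0 <- as.numeric(Sys.time())
  prunedIds <- run("ld_prune", ldPrune(
    gd, config$pruneWindow, config$pruneStep, config$qc$ldR2Max
  ))
  pruned <- gd[markerInfo(gd)$marker_id %in% prunedIds, ]
  mark("ld_prune", pruned, t0)

  t0 <- as.numeric(Sys.time())
  mds <- run("relatedness", classicalMds(
    ibsDistanceMatrix(pruned), config$mdsDims
  ))
  outliers <- run("relatedness", flagBackgroundOutliers(
    mds, config$outlierSd, config$outlierOverride
  ))
  if (length(outliers) > 0) {
    keep <- !colnames(gd) %in% outliers
    gd <- recodeMinor(gd[, keep])
    pruned <- recodeMinor(pruned[, keep])
  }
  ph <- phenotypes(gd)
  if (!any(ph == "case", na.rm = TRUE) ||
    !any(ph == "control", na.rm = TRUE)) {
    stop("pipeline stage 'relatedness' failed: a phenotype class is empty")
  }
  ibd <- run("relatedness", ibdPiHat(pruned))
  mark("relatedness", gd, t0)

  t0 <- as.numeric(Sys.time())
  rohSeg <- run("roh", detectRoh(gd, config$roh))
  mkAuto <- markerInfo(autosomes(gd))
  L <- config$genomeLengthKb
  if (is.null(L)) {
    L <- sum(tapply(mkAuto$bp, mkAuto$chrom, max) / 1000)
  }
  froh <- run("roh", computeFroh(rohSeg, L, samples = colnames(gd)))
  frohTest <- run("roh", frohGroupTest(
    froh$froh[ph[froh$sample_id] == "case"],
    froh$froh[ph[froh$sample_id] == "control"]
  ))
  mark("roh", gd, t0)

  t0 <- as.numeric(Sys.time())
  segments <- run("sharing", detectAllSharedSegments(pruned, config$sharing))
  grid <- markerInfo(autosomes(pruned))[, c("chrom", "bp")]
  sharing <- run("sharing", sharingPermutationTest(
    segments, ph, grid,
    nPerm = config$nPerm, seed = config$seed
  ))
  mark("sharing", pruned, t0)

  t0 <- as.numeric(Sys.time())
  assoc <- run("gwas", allelicTest(gd))
  infl <- run("gwas", genomicInflation(assoc$chi2))
  qq <- run("gwas", qqPoints(assoc$p))
  hits <- assoc[assoc$p < config$assocThreshold, , drop = FALSE]
  logistic <- NULL
  if (nrow(hits) > 0) {
    calls <- genotypeCalls(gd)
    logistic <- do.call(rbind, lapply(hits$marker_id, function(id) {
      eff <- logisticEffect(calls[id, ], ph)
      data.frame(
        marker_id = id, beta = eff$beta, se = eff$se, p = eff$p,
        separated = eff$separated
      )
    }))
  }
  haps <- list()
  for (chr in unique(hits$chrom)) {
    ids <- hits$marker_id[hits$chrom == chr]
    ids <- ids[order(hits$p[hits$chrom == chr])]
    if (length(ids) >= 2) {
      haps[[chr]] <- run(
        "gwas",
        haplotypeAssoc(gd, utils::head(ids, 3))
      )
    }
  }
  mark("gwas", gd, t0)

  headline <- list(
    n_samples_analysed = nSamples(gd),
    n_markers_analysed = nMarkers(gd),
    n_markers_pruned_panel = nMarkers(pruned),
    n_outliers_removed = length(outliers),
    lambda_gc = infl$lambda_gc,
    froh_mean_case = frohTest$mean_case,
    froh_mean_control = frohTest$mean_control,
    froh_p = frohTest$p,
    min_sharing_chrom_p = min(sharing$chromosomes$p),
    best_sharing_chrom = sharing$chromosomes$chrom[
      which.min(sharing$chromosomes$p)
    ],
    n_assoc_hits = nrow(hits),
    min_assoc_p = min(assoc$p),
    best_assoc_marker = assoc$marker_id[which.min(assoc$p)],
    best_assoc_chrom = assoc$chrom[which.min(assoc$p)]
  )

  .writeTsv(qcRes$report@markerReasons, config$outDir, "qc_marker_removals.tsv")
  .writeTsv(ibd, config$outDir, "ibd_pihat.tsv")
  .writeTsv(
    data.frame(
      sample_id = rownames(mds$points), mds$points,
      check.names = FALSE
    ),
    config$outDir, "mds_coordinates.tsv"
  )
  .writeTsv(rohSeg, config$outDir, "roh_segments.tsv")
  .writeTsv(froh, config$outDir, "froh.tsv")
  .writeTsv(segments, config$outDir, "shared_segments.tsv")
  .writeTsv(sharing$positions, config$outDir, "sharing_positions.tsv")
  .writeTsv(sharing$chromosomes, config$outDir, "sharing_chromosomes.tsv")
  .writeTsv(assoc, config$outDir, "assoc.tsv")
  .writeTsv(qq, config$outDir, "qq_points.tsv")

  structure(
    list(
      stages = stages, headline = headline, qc_report = qcRes$report,
      het = het, mds = mds, outliers = outliers, ibd = ibd,
      roh = rohSeg, froh = froh, froh_test = frohTest,
      segments = segments, sharing = sharing, assoc = assoc,
      inflation = infl, qq = qq, haplotypes = haps, logistic = logistic,
      config = config
    ),
    class = "RunReport"
  )
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Pipeline run report\n")
  cat("-------------------\n")
  print(x$stages, row.names = FALSE)
  h <- x$headline
  cat(sprintf(
    "\nanalysed: %d samples, %d markers (%d in pruned panel)\n",
    h$n_samples_analysed, h$n_markers_analysed, h$n_markers_pruned_panel
  ))
  cat(sprintf("background outliers removed: %d\n", h$n_outliers_removed))
  cat(sprintf("lambda_GC = %.3f\n", h$lambda_gc))
  cat(sprintf(
    "FROH case %.4f vs control %.4f (p = %.3g)\n",
    h$froh_mean_case, h$froh_mean_control, h$froh_p
  ))
  cat(sprintf(
    "best sharing chromosome: %s (p = %.3g)\n",
    h$best_sharing_chrom, h$min_sharing_chrom_p
  ))
  cat(sprintf(
    "GWAS: %d markers below threshold; best %s on chrom %s (p = %.3g)\n",
    h$n_assoc_hits, h$best_assoc_marker, h$best_assoc_chrom, h$min_assoc_p
  ))
  invisible(x)
}
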