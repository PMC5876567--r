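shareTestParams <- sharingParams(
  windowSnps = 10, windowIbs0Max = 1, windowMissMax = 1,
  minSnps = 20, minLengthKb = 200, hitFraction = 0.05
)

test_that("shared-segment detection handles the textbook cases", {
  bp <- round(seq(1e5, 2.1e6, length.out = 150))
  # identical fully homozygous samples -> one segment per chromosome
  hom <- sample(c(0L, 2L), 150, replace = TRUE)
  gd <- makeGd(cbind(hom, hom), bp = bp)
  seg <- detectSharedSegments(gd, "s001", "s002")
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 150L)
  # opposite homozygotes everywhere -> nothing
  gd2 <- makeGd(cbind(rep(0L, 150), rep(2L, 150)), bp = bp)
  expect_equal(nrow(detectSharedSegments(gd2, "s001", "s002")), 0L)
  # a compatible run spanning only 990 kb is rejected by the length filter
  bp3 <- round(seq(5e5, 1.49e6, length.out = 120))
  gd3 <- makeGd(cbind(rep(1L, 120), rep(1L, 120)), bp = bp3)
  expect_equal(nrow(detectSharedSegments(gd3, "s001", "s002")), 0L)
})

test_that("pair scan equals the brute-force oracle on random panels", {
  set.seed(444)
  for (rep in 1:4) {
    m <- 400
    chrom <- rep(c("3", "7"), each = m / 2)
    bp <- c(sort(sample(6e6, m / 2)), sort(sample(6e6, m / 2)))
    p <- runif(m, 0.1, 0.5)
    x <- rbinom(m, 2, p)
    y <- rbinom(m, 2, p)
    share <- 150:260 # force a long compatible stretch
    y[share] <- x[share]
    y[200] <- 2L - x[200] # one opposite homozygote inside
    x[sample(m, 6)] <- NA
    gd <- makeGd(cbind(as.integer(x), as.integer(y)),
      chrom = chrom, bp = bp
    )
    seg <- detectSharedSegments(gd, "s001", "s002", shareTestParams)
    ora <- oracleSharingOnePair(x, y, chrom, bp, shareTestParams)
    if (is.null(ora)) {
      expect_equal(nrow(seg), 0L)
    } else {
      expect_equal(nrow(seg), nrow(ora))
      expect_equal(seg$start_bp, ora$start_bp)
      expect_equal(seg$end_bp, ora$end_bp)
    }
  }
})

test_that("sharing statistic counts pairs by phenotype class per position", {
  grid <- data.frame(chrom = rep("1", 10), bp = seq_len(10) * 1e5)
  labels <- c(a = "case", b = "case", c = "control", d = "control")
  segs <- data.frame(
    id1 = c("a", "a", "c"), id2 = c("b", "c", "d"),
    chrom = "1", start_bp = c(2e5, 5e5, 9e5), end_bp = c(4e5, 7e5, 1e6),
    n_snps = 3L, length_kb = 200
  )
  st <- sharingStatistic(segs, labels, grid)
  expect_equal(st$grid$case_case, c(0, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(st$grid$case_control, c(0, 0, 0, 0, 1, 1, 1, 0, 0, 0))
  expect_equal(st$grid$control_control, c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1))
  # empty segment table -> all zero
  st0 <- sharingStatistic(segs[0, ], labels, grid)
  expect_true(all(st0$grid$case_case == 0))
  # unlabelled sample -> error
  expect_error(sharingStatistic(segs, labels[-1], grid), "labelled")
})

test_that("statistic equals a brute-force per-position pair scan", {
  set.seed(555)
  ids <- sprintf("i%02d", 1:12)
  labels <- setNames(sample(rep(c("case", "control"), c(7, 5))), ids)
  grid <- data.frame(
    chrom = rep(c("1", "2"), each = 30),
    bp = rep(seq_len(30) * 1e5, 2)
  )
  pr <- t(combn(12, 2))
  segs <- NULL
  for (k in seq_len(nrow(pr))) {
    for (chr in c("1", "2")) {
      if (runif(1) < 0.6) {
        s <- sample(30, 1)
        e <- min(30, s + sample(12, 1))
        segs <- rbind(segs, data.frame(
          id1 = ids[pr[k, 1]], id2 = ids[pr[k, 2]], chrom = chr,
          start_bp = s * 1e5, end_bp = e * 1e5, n_snps = e - s + 1L,
          length_kb = (e - s) * 100
        ))
      }
    }
  }
  st <- sharingStatistic(segs, labels, grid)
  for (g in seq_len(nrow(grid))) {
    ov <- segs$chrom == grid$chrom[g] & segs$start_bp <= grid$bp[g] &
      segs$end_bp >= grid$bp[g]
    cc <- sum(ov & labels[segs$id1] == "case" & labels[segs$id2] == "case")
    expect_equal(st$grid$case_case[g], cc)
  }
})

test_that("permutation p-values respect their contracts", {
  grid <- data.frame(chrom = rep("1", 5), bp = seq_len(5) * 1e5)
  labels <- c(a = "case", b = "case", c = "control", d = "control")
  # every pair shares everywhere -> statistic invariant -> p = 1
  pr <- t(combn(c("a", "b", "c", "d"), 2))
  segs <- data.frame(
    id1 = pr[, 1], id2 = pr[, 2], chrom = "1",
    start_bp = 1e5, end_bp = 5e5, n_snps = 5L, length_kb = 400
  )
  res <- sharingPermutationTest(segs, labels, grid, nPerm = 200, seed = 1)
  expect_true(all(res$positions$p == 1))
  expect_true(all(res$chromosomes$p == 1))
  # add-one floor: minimum attainable p is 1/(nPerm + 1)
  expect_true(all(res$positions$p >= 1 / 201))
  # determinism under seed, invariance to segment order and sample renaming
  segs2 <- data.frame(
    id1 = c("a", "c"), id2 = c("b", "d"), chrom = "1",
    start_bp = c(1e5, 3e5), end_bp = c(3e5, 5e5), n_snps = 3L,
    length_kb = 200
  )
  r1 <- sharingPermutationTest(segs2, labels, grid, nPerm = 500, seed = 7)
  r2 <- sharingPermutationTest(segs2, labels, grid, nPerm = 500, seed = 7)
  expect_identical(r1$positions$p, r2$positions$p)
  r3 <- sharingPermutationTest(
    segs2[2:1, ], labels, grid,
    nPerm = 500, seed = 7
  )
  expect_identical(r1$positions$p, r3$positions$p)
  ren <- c(a = "x1", b = "x2", c = "x3", d = "x4")
  segs4 <- transform(segs2, id1 = ren[id1], id2 = ren[id2])
  labels4 <- setNames(labels, ren[names(labels)])
  r4 <- sharingPermutationTest(segs4, labels4, grid, nPerm = 500, seed = 7)
  expect_identical(r1$positions$p, r4$positions$p)
  expect_error(
    sharingPermutationTest(segs2, labels, grid, nPerm = 0, seed = 1),
    "nPerm"
  )
})

test_that("a forced case-shared segment is localized by the permutation test", {
  # power check: implant a segment shared by all cases on one chromosome
  set.seed(666)
  hits <- 0
  nRep <- 12
  for (r in seq_len(nRep)) {
    gd <- simulateNullPanel(
      nSamples = 30, nMarkers = 600, nCase = 18,
      seed = 1000 + r
    )
    mk <- markerInfo(gd)
    mk$chrom <- rep(c("1", "2", "3"), each = 200)
    mk$bp <- rep(round(seq(1e5, 6e6, length.out = 200)), 3)
    gd <- GenotypeData(genotypeCalls(gd), mk, sampleInfo(gd))
    cases <- names(phenotypes(gd))[phenotypes(gd) == "case"]
    gd <- implantSharedSegment(gd, "2", 2e6, 4.5e6, cases, seed = 2000 + r)
    segs <- detectAllSharedSegments(gd, sharingParams(
      windowSnps = 20, minSnps = 40, minLengthKb = 800
    ))
    grid <- markerInfo(gd)[, c("chrom", "bp")]
    res <- sharingPermutationTest(
      segs, phenotypes(gd), grid,
      nPerm = 999, seed = 3000 + r
    )
    best <- res$chromosomes$chrom[which.min(res$chromosomes$p)]
    if (best == "2" && min(res$chromosomes$p) <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / nRep, 0.8)
})
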