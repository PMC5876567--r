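test_that("exact HWE test matches enumeration and known values", {
  expect_equal(hweExactTest(10, 0, 0), 1)
  expect_equal(hweExactTest(1, 0, 1), 1 / 3)
  expect_lt(hweExactTest(0, 100, 0), 9.5e-7)
  expect_error(hweExactTest(-1, 0, 1), "non-negative")
  # symmetric in the homozygote classes
  expect_equal(hweExactTest(7, 3, 1), hweExactTest(1, 3, 7))
  # oracle equivalence over random genotype counts, n <= 50
  set.seed(202)
  for (k in 1:60) {
    n <- sample(1:50, 1)
    cnt <- as.vector(stats::rmultinom(1, n, prob = runif(3, 0.05, 1)))
    expect_equal(
      hweExactTest(cnt[1], cnt[2], cnt[3]),
      oracleHweP(cnt[1], cnt[2], cnt[3]),
      tolerance = 1e-10
    )
  }
})

test_that("marker filters tabulate call-rate/MAF jointly and apply HWE after", {
  set.seed(303)
  n <- 20
  # 6 markers: clean, callrate-only, maf-only, both, hwe-fail, clean
  clean <- function() sample(0:2, n, replace = TRUE, prob = c(.36, .48, .16))
  m1 <- clean()
  m2 <- clean()
  m2[1:3] <- NA # 15% missing -> callrate
  m3 <- rep(0L, n) # monomorphic -> MAF 0
  m4 <- c(rep(NA, 3), rep(0L, n - 3)) # both
  m5 <- rep(1L, n) # all het -> HWE fail at n=20? p ~ 1e-5 > 9.5e-7
  m6 <- clean()
  calls <- rbind(m1, m2, m3, m4, m5, m6)
  gd <- makeGd(matrix(as.integer(calls), 6, n))
  # with default 9.5e-7 the all-het marker survives at n=20; use 1e-4.
  # sampleMissingMax is relaxed so the 6-marker toy panel keeps all samples
  res <- filterMarkers(gd, qcThresholds(hwePMin = 1e-4, sampleMissingMax = 0.9))
  rep <- res$report
  expect_equal(rep@nMarkersIn, 6L)
  expect_equal(rep@nFailCallrateOnly, 1L)
  expect_equal(rep@nFailMafOnly, 1L)
  expect_equal(rep@nFailBoth, 1L)
  expect_equal(rep@nFailHwe, 1L)
  expect_equal(rep@nMarkersOut, 2L)
  expect_equal(nMarkers(res$genotypes), 2L)
  # partition identity is enforced by the class validity
  expect_true(methods::validObject(rep))
  # removal reasons partition the removed markers
  expect_equal(nrow(rep@markerReasons), 4L)
  expect_equal(anyDuplicated(rep@markerReasons$marker_id), 0L)
})

test_that("QC report counts equal a brute-force per-marker recount", {
  set.seed(304)
  n <- 30
  m <- 80
  p <- runif(m, 0, 0.5)
  calls <- matrix(rbinom(m * n, 2, rep(p, n)), m, n)
  calls[matrix(runif(m * n) < 0.06, m, n)] <- NA
  gd <- makeGd(calls)
  th <- qcThresholds(mafMin = 0.05, markerMissingMax = 0.08)
  res <- filterMarkers(gd, th)
  # independent tally loop, removing high-missingness samples first as the
  # filter contract specifies
  keepSamp <- colMeans(is.na(calls)) <= th$sampleMissingMax
  expect_equal(res$report@nSamplesRemoved, sum(!keepSamp))
  cr <- maf <- hwe <- logical(m)
  for (j in seq_len(m)) {
    cj <- calls[j, keepSamp]
    cr[j] <- mean(is.na(cj)) > 0.08
    pj <- mean(cj, na.rm = TRUE) / 2
    maf[j] <- min(pj, 1 - pj) < 0.05
    if (!cr[j] && !maf[j]) {
      hwe[j] <- oracleHweP(
        sum(cj == 2, na.rm = TRUE), sum(cj == 1, na.rm = TRUE),
        sum(cj == 0, na.rm = TRUE)
      ) < th$hwePMin
    }
  }
  expect_equal(res$report@nFailCallrateOnly, sum(cr & !maf))
  expect_equal(res$report@nFailMafOnly, sum(maf & !cr))
  expect_equal(res$report@nFailBoth, sum(cr & maf))
  expect_equal(res$report@nFailHwe, sum(hwe))
  expect_equal(nMarkers(res$genotypes), sum(!cr & !maf & !hwe))
  # survivors are recoded to minor-allele counts
  expect_true(all(alleleFreq(res$genotypes) <= 0.5 + 1e-12))
})

test_that("all markers failing QC is an explicit error", {
  gd <- makeGd(matrix(0L, 3, 10)) # all monomorphic
  expect_error(filterMarkers(gd), "empty panel")
})

test_that("ldR2 matches hand computation and detects independence", {
  x <- c(0, 1, 2, 2)
  y <- c(0, 1, 1, 2)
  expect_equal(ldR2(x, y), 4 / 5.5, tolerance = 1e-12)
  expect_equal(ldR2(x, x), 1)
  expect_true(is.na(ldR2(c(1, 1, 1, 1), y)))
  set.seed(404)
  a <- rbinom(10000, 2, 0.3)
  b <- rbinom(10000, 2, 0.4)
  expect_lt(ldR2(a, b), 0.01)
})

test_that("LD pruning removes duplicates, keeps independents, is idempotent", {
  set.seed(505)
  n <- 40
  base <- matrix(rbinom(20 * n, 2, 0.4), 20, n)
  calls <- rbind(base[1, ], base[1, ], base[2:20, ]) # duplicated first marker
  gd <- makeGd(matrix(as.integer(calls), 21, n))
  kept <- ldPrune(gd, windowSnps = 10, stepSnps = 3)
  ids <- markerInfo(gd)$marker_id
  expect_equal(sum(ids[1:2] %in% kept), 1L)
  # brute-force recheck: no surviving within-window pair at r2 >= 0.2
  calls2 <- genotypeCalls(gd)[kept, ]
  for (i in seq_len(nrow(calls2) - 1)) {
    for (j in (i + 1):min(nrow(calls2), i + 9)) {
      r2 <- ldR2(calls2[i, ], calls2[j, ])
      expect_lt(ifelse(is.na(r2), 0, r2), 0.2)
    }
  }
  # idempotent
  gd2 <- gd[markerInfo(gd)$marker_id %in% kept, ]
  expect_setequal(ldPrune(gd2, windowSnps = 10, stepSnps = 3), kept)
  # X chromosome markers never enter
  gdx <- makeGd(matrix(rbinom(20, 2, 0.5), 10, 2),
    chrom = c(rep("1", 5), rep("X", 5))
  )
  keptx <- ldPrune(gdx, windowSnps = 5, stepSnps = 2)
  expect_false(any(keptx %in% markerInfo(gdx)$marker_id[
    markerInfo(gdx)$chrom == "X"
  ]))
  expect_error(ldPrune(gd, windowSnps = 1), "at least 2")
})

test_that("heterozygosity screen flags the constructed excess-het sample", {
  set.seed(606)
  n <- 30
  m <- 400
  p <- runif(m, 0.2, 0.5)
  calls <- matrix(rbinom(m * n, 2, rep(p, n)), m, n)
  hc <- sampleHetCheck(makeGd(calls))
  expect_lt(abs(mean(hc$f)), 0.05) # HWE panel: mean F near 0
  expect_false(any(hc$flagged))
  calls[, 1] <- 1L # all-heterozygous contaminated sample
  hc2 <- sampleHetCheck(makeGd(calls))
  expect_true(hc2$flagged[1])
  expect_equal(sum(hc2$flagged), 1L)
  # clones: zero dispersion, no flags
  clone <- matrix(rep(rbinom(m, 2, p), 5), m, 5)
  expect_false(any(sampleHetCheck(makeGd(clone))$flagged))
})
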