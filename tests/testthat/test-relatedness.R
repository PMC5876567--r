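test_that("IBS distances hit their extremes and match the naive loop", {
  # identical samples -> 0; opposite homozygotes everywhere -> 1
  calls <- cbind(c(0L, 2L, 0L), c(0L, 2L, 0L), c(2L, 0L, 2L))
  d <- ibsDistanceMatrix(makeGd(calls))
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 1)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  set.seed(707)
  calls2 <- matrix(sample(c(0:2, NA), 50 * 6,
    replace = TRUE,
    prob = c(.3, .3, .3, .1)
  ), 50, 6)
  gd <- makeGd(calls2)
  expect_equal(unname(ibsDistanceMatrix(gd)), oracleIbsMatrix(calls2),
    tolerance = 1e-12
  )
  expect_true(isSymmetric(ibsDistanceMatrix(gd)))
  # zero-overlap pair errors with the pair named
  calls3 <- cbind(c(1L, NA), c(NA, 1L))
  expect_error(ibsDistanceMatrix(makeGd(calls3)), "s001.*s002")
})

test_that("PI_HAT is 1 for duplicates, ~0 for unrelated, ~0.5 parent-offspring", {
  set.seed(808)
  m <- 5000
  p <- runif(m, 0.1, 0.5)
  founders <- matrix(rbinom(m * 60, 2, rep(p, 60)), m, 60)
  gd <- makeGd(cbind(founders[, 1], founders)) # first sample duplicated
  est <- ibdPiHat(gd)
  dup <- est[est$id1 == "s001" & est$id2 == "s002", ]
  expect_equal(dup$pi_hat, 1)
  unrel <- est[!(est$id1 %in% c("s001", "s002")) &
    !(est$id2 %in% c("s001", "s002")), ]
  expect_lt(abs(mean(unrel$pi_hat)), 0.02)
  # parent-offspring by direct gamete draw: child inherits one allele
  # from the parent and one from the population at every marker
  parent <- rbinom(m, 2, p)
  fromParent <- rbinom(m, 1, parent / 2)
  child <- fromParent + rbinom(m, 1, p)
  gd2 <- makeGd(cbind(parent, child, founders[, 1:20]))
  est2 <- ibdPiHat(gd2)
  po <- est2[est2$id1 == "s001" & est2$id2 == "s002", ]
  expect_lt(abs(po$pi_hat - 0.5), 0.05)
  # symmetry of the pair statistic: Z sums to 1, pi_hat in [0,1]
  expect_true(all(abs(est2$z0 + est2$z1 + est2$z2 - 1) < 1e-12))
  expect_true(all(est2$pi_hat >= 0 & est2$pi_hat <= 1))
})

test_that("classical MDS reproduces an exactly embeddable configuration", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 4
  d["b", "c"] <- d["c", "b"] <- 5
  mds <- classicalMds(d, k = 2)
  emb <- as.matrix(dist(mds$points))
  expect_equal(unname(emb), unname(d), tolerance = 1e-9)
  expect_true(all(diff(mds$eig) <= 1e-9))
  # all-identical samples project to the origin
  z <- suppressWarnings(classicalMds(matrix(0, 4, 4), k = 2))
  expect_true(all(z$points == 0))
  # sign convention: the largest-magnitude loading per dimension is positive
  expect_true(all(apply(mds$points, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("MDS dimension 1 separates two simulated populations", {
  set.seed(909)
  m <- 600
  p1 <- runif(m, 0.05, 0.95)
  flip <- runif(m) < 0.3
  p2 <- ifelse(flip, 1 - p1, p1) # strongly diverged at 30% of markers
  g1 <- matrix(rbinom(m * 12, 2, rep(p1, 12)), m, 12)
  g2 <- matrix(rbinom(m * 12, 2, rep(p2, 12)), m, 12)
  gd <- makeGd(cbind(g1, g2))
  mds <- classicalMds(ibsDistanceMatrix(gd), k = 2)
  x <- mds$points[, 1]
  lab <- rep(c(1, 2), each = 12)
  # silhouette on dimension 1
  sil <- vapply(seq_along(x), function(i) {
    own <- mean(abs(x[i] - x[lab == lab[i]][-match(i, which(lab == lab[i]))]))
    oth <- mean(abs(x[i] - x[lab != lab[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("background outlier rule flags implanted divergent samples only", {
  set.seed(1010)
  m <- 500
  p <- runif(m, 0.2, 0.8)
  g <- matrix(rbinom(m * 20, 2, rep(p, 20)), m, 20)
  gd <- makeGd(g)
  mds <- classicalMds(ibsDistanceMatrix(gd), k = 2)
  expect_length(flagBackgroundOutliers(mds), 0)
  # implant one sample from a diverged population
  pd <- ifelse(runif(m) < 0.5, 1 - p, p)
  g[, 20] <- rbinom(m, 2, pd)
  mds2 <- classicalMds(ibsDistanceMatrix(makeGd(g)), k = 2)
  out <- flagBackgroundOutliers(mds2)
  expect_true("s020" %in% out)
  expect_lt(length(out), 3)
  # override short-circuits the rule
  expect_equal(
    flagBackgroundOutliers(mds2, override = c("s001", "s002")),
    c("s001", "s002")
  )
})
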