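test_that("Welch t matches the hand-evaluated example and degenerate paths", {
  w <- welchTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(unname(w$statistic), -1.224745, tolerance = 1e-6)
  expect_equal(unname(w$parameter), 4)
  expect_equal(w$p.value, 0.2878641, tolerance = 1e-6)
  same <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_warning(deg <- welchTTest(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(deg$p.value, 0)
  flat <- welchTTest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(flat$p.value, 1)
  expect_error(welchTTest(1, c(1, 2)), "n >= 2")
})

test_that("Welch t agrees with independent oracles on random samples", {
  set.seed(801)
  for (i in 1:500) {
    a <- rnorm(sample(3:12, 1L), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1L), mean = runif(1, -1, 1))
    w <- welchTTest(a, b)
    cf <- closedFormWelch(a, b)
    expect_equal(unname(w$statistic), cf$t, tolerance = 1e-10)
    expect_equal(unname(w$parameter), cf$df, tolerance = 1e-10)
    expect_equal(w$p.value, cf$p, tolerance = 1e-10)
    # and with the reference implementation
    tt <- t.test(a, b)
    expect_equal(w$p.value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney matches enumeration exactly for small tie-free samples", {
  m <- mannWhitneyTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(m$statistic), 0)
  expect_equal(m$p.value, 0.1)
  expect_match(m$method, "exact")
  set.seed(802)
  for (i in 1:500) {
    a <- round(rnorm(sample(2:6, 1L)), 6)
    b <- round(rnorm(sample(2:6, 1L), mean = runif(1, -1, 1)), 6)
    if (anyDuplicated(c(a, b))) next  # keep to the tie-free exact path
    m <- mannWhitneyTest(a, b)
    expect_equal(m$p.value, enumMannWhitneyP(a, b), tolerance = 1e-8)
  }
})

test_that("Mann-Whitney handles ties and identical groups", {
  m <- mannWhitneyTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$p.value, 1)
  expect_match(m$method, "tie-corrected")
  m1 <- mannWhitneyTest(2, c(1, 3, 5))
  expect_true(m1$p.value > 0 && m1$p.value <= 1)
  expect_error(mannWhitneyTest(numeric(0), 1), "empty")
})

test_that("SMM tail is monotone in k with nested draws and bounded by Sidak", {
  for (q in c(1, 2, 3)) {
    ps <- vapply(1:5, function(k) pSMM(q, k, df = 10, mcReps = 20000L,
                                       seed = 42L), numeric(1L))
    expect_true(all(diff(ps) >= 0))
    # never exceeds the independence (Sidak) bound by more than MC noise
    p1 <- 2 * pt(-q, 10)
    sidak <- 1 - (1 - p1)^(1:5)
    expect_true(all(ps <= sidak + 0.02))
  }
  # k = 1 reduces exactly to the two-tailed t tail
  expect_equal(pSMM(2.1, 1L, df = 7.3), 2 * pt(-2.1, 7.3))
})

test_that("Dunnett T3 honours its invariants on random group sets", {
  set.seed(803)
  for (i in 1:20) {
    g <- list(a = rnorm(sample(4:10, 1L)),
              b = rnorm(sample(4:10, 1L), 1),
              c = rnorm(sample(4:10, 1L), 0, 3))
    t3 <- dunnettT3(g, mcReps = 5000L, seed = i)
    cmp <- t3$comparisons
    expect_true(all(cmp$pAdjusted >= cmp$pRaw - 1e-12))
    expect_true(all(cmp$pAdjusted >= 0 & cmp$pAdjusted <= 1))
    expect_true(all(cmp$pAdjusted <= cmp$pSidak + 0.05))
  }
})

test_that("Dunnett T3 with two groups reduces to the Welch comparison", {
  set.seed(804)
  g <- list(a = rnorm(8), b = rnorm(8, 1))
  t3 <- dunnettT3(g, mcReps = 1000L, seed = 1)
  w <- welchTTest(g$a, g$b)
  expect_equal(t3$comparisons$pAdjusted, w$p.value, tolerance = 1e-12)
  expect_identical(t3$k, 1L)
})

test_that("Dunnett T3 separated groups give near-zero adjusted p", {
  set.seed(805)
  g <- list(a = rnorm(15), b = rnorm(15, 10), c = rnorm(15, 20))
  t3 <- dunnettT3(g, mcReps = 20000L, seed = 2)
  expect_true(all(t3$comparisons$pAdjusted < 0.001))
  expect_error(dunnettT3(list(a = 1, b = c(1, 2)), 100, 1), "n >= 2")
})

test_that("group label permutation does not change the comparison p-values", {
  set.seed(806)
  g <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2))
  t3 <- dunnettT3(g, mcReps = 10000L, seed = 3)
  t3p <- dunnettT3(g[c("c", "a", "b")], mcReps = 10000L, seed = 3)
  key <- function(x) {
    k <- apply(cbind(x$groupA, x$groupB), 1L, function(r) paste(sort(r),
                                                                collapse = "-"))
    x$pAdjusted[order(k)]
  }
  expect_equal(key(t3$comparisons), key(t3p$comparisons), tolerance = 1e-12)
})

test_that("ROUT flags a gross contaminant but leaves constant data alone", {
  expect_identical(length(routOutliers(c(5, 5, 5, 5), Q = 1)$flagged), 0L)
  set.seed(807)
  r <- routOutliers(c(rnorm(14), 100), Q = 1)
  expect_equal(r$flagged, 100)
  expect_identical(length(r$kept), 14L)
  expect_error(routOutliers(c(1, 2), Q = 1), "n >= 3")
  expect_error(routOutliers(rnorm(5), Q = 0), "Q must be")
  # kept + flagged partition the input multiset
  set.seed(808)
  x <- c(rnorm(12), 50, 50)
  r2 <- routOutliers(x, Q = 1)
  expect_equal(sort(c(r2$kept, r2$flagged)), sort(x))
})

test_that("Tukey box summary follows type-7 quartiles and 1.5 IQR fences", {
  s <- tukeyBoxSummary(c(1, 2, 3, 4, 100))
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$median, 3)
  expect_equal(s$whiskerHigh, 4)  # most extreme point within fence 7
  expect_equal(s$outliers, 100)
  flat <- tukeyBoxSummary(rep(7, 4))
  expect_equal(flat$iqr, 0)
  expect_identical(length(flat$outliers), 0L)
  one <- tukeyBoxSummary(5)
  expect_equal(one$median, 5)
  expect_identical(length(one$outliers), 0L)
})
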