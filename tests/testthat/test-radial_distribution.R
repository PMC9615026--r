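test_that("scaled shell boundaries nest and end at the outline", {
  g <- circleGeometry(radius = 10)
  sh <- shapeScaledShells(g, 2L)
  expect_identical(nShells(sh), 2L)
  b <- shellBoundaries(sh)
  r1 <- sqrt(rowSums(b[[1L]]^2)); r2 <- sqrt(rowSums(b[[2L]]^2))
  expect_equal(r1, rep(5, length(r1)), tolerance = 1e-12)
  expect_equal(r2, rep(10, length(r2)), tolerance = 1e-12)
  expect_equal(b[[2L]], cellOutline(g))
  # a square outline scales to similar squares about its center
  gs <- squareGeometry(10)
  shs <- shapeScaledShells(gs, 5L)
  expect_equal(shellBoundaries(shs)[[2L]],
               cbind(c(3, 7, 7, 3), c(3, 3, 7, 7)))
  # n = 1 gives a single shell equal to the outline
  sh1 <- shapeScaledShells(gs, 1L)
  expect_equal(shellBoundaries(sh1)[[1L]], cellOutline(gs))
})

test_that("non-star-convex outlines are rejected with guidance", {
  # a deep wedge cut toward the center breaks single-valuedness
  th <- seq(0, 2 * pi, length.out = 13L)[-13L]
  r <- rep(10, 12L)
  out <- cbind(10 + r * cos(th), 10 + r * sin(th))
  out[3L, ] <- c(10 + 0.5 * cos(th[3L] - 1.0), 10 + 0.5 * sin(th[3L] - 1.0))
  g <- CellGeometry(out, c(10, 10))
  expect_error(shapeScaledShells(g, 5L), "star-convex")
})

test_that("objects at radii 3 and 8 of a radius-10 circle split shells 50/50", {
  g <- circleGeometry(radius = 10, n = 360L)
  sh <- shapeScaledShells(g, 2L)
  pts <- data.frame(x = c(3, -8), y = c(0, 0))
  d <- radialDistribution(pts, sh)
  expect_equal(shellFrequencies(d), c(50, 50))
  expect_identical(nIncluded(d), 2L)
})

test_that("all objects at the center land in the first shell", {
  g <- circleGeometry(radius = 10)
  sh <- shapeScaledShells(g, 4L)
  pts <- data.frame(x = rep(0, 5), y = rep(0, 5))
  d <- radialDistribution(pts, sh)
  expect_equal(shellFrequencies(d), c(100, 0, 0, 0))
})

test_that("boundary ties resolve inward and outside objects are excluded", {
  g <- squareGeometry(10)
  sh <- shapeScaledShells(g, 2L)
  # (7.5, 5) sits exactly on the inner boundary (r = 0.5): inner shell
  d <- radialDistribution(data.frame(x = 7.5, y = 5), sh)
  expect_equal(shellFrequencies(d), c(100, 0))
  # outside object excluded with warning; frequencies sum over the rest
  pts <- data.frame(x = c(5, 5.5, 4.5, 6, 20), y = c(5, 5, 5, 9.5, 20))
  expect_warning(d2 <- radialDistribution(pts, sh), "excluded")
  expect_identical(nExcluded(d2), 1L)
  expect_identical(nIncluded(d2), 4L)
  expect_equal(sum(shellFrequencies(d2)), 100)
})

test_that("distributions are invariant under uniform rescaling of coordinates", {
  set.seed(611)
  cell <- simulateCos7Cell(simulationParams(imageShape = c(4L, 64L, 64L),
                                            nPeroxisomes = 20L, seed = 41))
  tr <- cell$truth$organelleCentroids
  g <- cell$geometry
  sh <- shapeScaledShells(g, 10L)
  d1 <- radialDistribution(tr, sh)
  s <- 3.7
  g2 <- CellGeometry(cellOutline(g) * s, cellCenter(g) * s)
  d2 <- radialDistribution(tr[, c("x", "y")] * s, shapeScaledShells(g2, 10L))
  expect_equal(shellFrequencies(d1), shellFrequencies(d2), tolerance = 1e-9)
})

test_that("uniformly placed objects match shell area fractions (chi-square)", {
  cell <- simulateCos7Cell(simulationParams(imageShape = c(4L, 64L, 64L),
                                            nPeroxisomes = 4L, seed = 43))
  g <- cell$geometry
  sh <- shapeScaledShells(g, 10L)
  set.seed(617)
  pts <- samplePointsInPolygon(1000L, cellOutline(g))
  d <- radialDistribution(pts, sh)
  counts <- round(shellFrequencies(d) * nIncluded(d) / 100)
  areaFrac <- diff((0:10 / 10)^2)  # scaled-polygon shell areas go as k^2
  p <- suppressWarnings(chisq.test(counts, p = areaFrac)$p.value)
  expect_gt(p, 0.01)
})

test_that("aggregation gives per-shell means and n-1 SDs, NA for one cell", {
  d1 <- new("ShellDistribution", frequencies = c(100, 0), nIncluded = 5L,
            nExcluded = 0L)
  d2 <- new("ShellDistribution", frequencies = c(0, 100), nIncluded = 5L,
            nExcluded = 0L)
  a <- aggregateDistributions(list(d1, d2))
  expect_equal(a$mean, c(50, 50))
  expect_equal(a$sd, c(100 / sqrt(2), 100 / sqrt(2)), tolerance = 1e-9)
  one <- aggregateDistributions(list(d1))
  expect_equal(one$mean, c(100, 0))
  expect_true(all(is.na(one$sd)))
  same <- aggregateDistributions(list(d1, d1, d1))
  expect_equal(same$sd, c(0, 0))
  expect_error(aggregateDistributions(list()), "empty")
  expect_error(aggregateDistributions(list(d1,
    new("ShellDistribution", frequencies = c(100, 0, 0), nIncluded = 1L,
        nExcluded = 0L))), "mismatched")
})
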