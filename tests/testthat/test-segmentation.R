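test_that("fixed threshold separates two bright squares into 18 px, 2 objects", {
  m <- array(0, c(1L, 12L, 12L))
  m[1, 2:4, 2:4] <- 100   # 3x3 square
  m[1, 8:10, 8:10] <- 200 # 3x3 square, brighter
  stack <- ChannelStack(array(m, c(1L, 12L, 12L, 1L)), "marker")
  seg <- segmentMarker(stack, method = "fixed:50", minSizePx = 1L)
  expect_identical(sum(masks(seg$mask)), 18L)
  expect_identical(nrow(objectTable(seg$objects)), 2L)
  expect_equal(sort(objectTable(seg$objects)$area), c(9L, 9L))
})

test_that("blank stacks segment to empty masks without error", {
  stack <- ChannelStack(array(0, c(2L, 8L, 8L, 1L)), "marker")
  seg <- segmentMarker(stack, method = "otsu")
  expect_false(any(masks(seg$mask)))
  expect_identical(nrow(objectTable(seg$objects)), 0L)
})

test_that("minimum size filter removes single-pixel specks", {
  m <- array(0, c(1L, 8L, 8L))
  m[1, 2, 2] <- 100          # 1-px speck
  m[1, 5:6, 5] <- 100        # 2-px object
  stack <- ChannelStack(array(m, c(1L, 8L, 8L, 1L)), "marker")
  seg <- segmentMarker(stack, method = "fixed:50", minSizePx = 2L)
  expect_identical(nrow(objectTable(seg$objects)), 1L)
  expect_identical(sum(masks(seg$mask)), 2L)
})

test_that("objects are 8-connected components of the max projection", {
  m <- array(0, c(2L, 8L, 8L))
  m[1, 2, 2] <- 100; m[1, 3, 3] <- 100  # diagonal pair: one object
  m[2, 3, 3] <- 100                     # same punctum, next slice
  stack <- ChannelStack(array(m, c(2L, 8L, 8L, 1L)), "marker")
  seg <- segmentMarker(stack, method = "fixed:50", minSizePx = 1L)
  tab <- objectTable(seg$objects)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$sliceMin, 1L)
  expect_identical(tab$sliceMax, 2L)
})

test_that("re-running from a method record reproduces the mask bit-exactly", {
  cell <- simulateCos7Cell(simulationParams(imageShape = c(4L, 48L, 48L),
                                            nPeroxisomes = 8L, seed = 21))
  seg <- segmentMarker(cell$stack)
  seg2 <- segmentMarker(cell$stack, method = methodRecord(seg$mask))
  expect_identical(masks(seg$mask), masks(seg2$mask))
})

test_that("double-positive mask is a subset, monotone in the threshold", {
  cell <- simulateCos7Cell(simulationParams(imageShape = c(4L, 48L, 48L),
                                            nPeroxisomes = 8L, seed = 22))
  seg <- segmentMarker(cell$stack)
  dp <- doublePositiveMask(seg$mask, cell$stack)
  expect_true(all(masks(seg$mask) | !masks(dp)))  # dp subset of marker
  thresholds <- c(0, 20, 60, 120, 1e6)
  sizes <- vapply(thresholds, function(t)
    sum(masks(doublePositiveMask(seg$mask, cell$stack,
                                 constructThreshold = t))), integer(1L))
  expect_true(all(diff(sizes) <= 0L))
  # threshold 0 is the identity; huge threshold annihilates
  expect_identical(sizes[1L], sum(masks(seg$mask)))
  expect_identical(sizes[length(sizes)], 0L)
})

test_that("hand-built double-positive example keeps only construct-positive half", {
  m <- array(0, c(1L, 4L, 4L))
  m[1, 1, 1:4] <- 100                      # 4 marker px in a row
  cons <- array(0, c(1L, 4L, 4L))
  cons[1, 1, 1:2] <- 50                    # construct on half of them
  stack <- makeStack(m, cons, constArray(0, c(1L, 4L, 4L)))
  seg <- segmentMarker(stack, method = "fixed:50", minSizePx = 1L)
  dp <- doublePositiveMask(seg$mask, stack, constructThreshold = 10)
  expect_identical(sum(masks(dp)), 2L)
  expect_true(all(which(masks(dp)) %in% which(masks(seg$mask))))
})

test_that("cell region rasterizes the outline boundary-inclusively", {
  stack <- ChannelStack(array(0, c(2L, 20L, 20L, 1L)), "marker")
  rg <- cellRegion(stack, CellGeometry(cbind(c(0, 9, 9, 0), c(0, 0, 9, 9)),
                                       c(4.5, 4.5)))
  expect_identical(sum(masks(rg)[1, , ]), 100L)  # 10 x 10 pixel centers
  expect_identical(masks(rg)[1, , ], masks(rg)[2, , ])
})

test_that("geometry-free cell region covers bright blobs (union threshold oracle)", {
  cell <- simulateCos7Cell(simulationParams(imageShape = c(4L, 48L, 48L),
                                            nPeroxisomes = 6L, seed = 23))
  rg <- cellRegion(cell$stack)
  # brute-force oracle: global per-channel Otsu union
  v <- voxels(cell$stack)
  expected <- array(FALSE, dim(v)[1:3])
  for (ch in 1:3) {
    vc <- v[, , , ch]
    thr <- EBImage::otsu(matrix(vc), range = range(vc), levels = 256L)
    expected <- expected | (vc > thr)
  }
  expect_identical(masks(rg), expected)
  expect_identical(methodRecord(rg)$method, "union-otsu")
})
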