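test_that("the worked 4x4 example gives raw 90, background 10, normalized 1.8", {
  marker <- array(0, c(1L, 4L, 4L))
  marker[1, 1, 1:2] <- 100
  cons <- array(0, c(1L, 4L, 4L)); cons[1, 1, 1:2] <- 50
  cargo <- array(10, c(1L, 4L, 4L)); cargo[1, 1, 1:2] <- 100
  stack <- makeStack(marker, cons, cargo)
  mk <- MaskStack(array(marker > 0, c(1L, 4L, 4L)))
  rg <- MaskStack(array(TRUE, c(1L, 4L, 4L)))
  er <- peroxisomalEnrichment(stack, mk, mk, rg)
  expect_equal(er@rawEnrichment, 90)
  expect_equal(er@background, 10)
  expect_equal(er@constructIntensity, 50)
  expect_equal(er@normalizedEnrichment, 1.8)
  expect_identical(er@nSlicesUsed, 1L)
  expect_identical(er@analysisMaskPx, 2L)
})

test_that("uniform cargo gives zero raw and normalized enrichment", {
  marker <- array(0, c(2L, 4L, 4L)); marker[, 2, 2:3] <- 80
  stack <- makeStack(marker, constArray(40, c(2L, 4L, 4L)),
                     constArray(25, c(2L, 4L, 4L)))
  mk <- MaskStack(marker > 0)
  rg <- MaskStack(array(TRUE, c(2L, 4L, 4L)))
  er <- peroxisomalEnrichment(stack, mk, mk, rg)
  expect_equal(er@rawEnrichment, 0)
  expect_equal(er@normalizedEnrichment, 0)
})

test_that("slices with empty analysis mask are skipped, not averaged in", {
  marker <- array(0, c(2L, 4L, 4L))
  marker[1, 1, 1:2] <- 100  # slice 2 has no mask
  cons <- array(0, c(2L, 4L, 4L)); cons[1, 1, 1:2] <- 50
  cargo <- array(10, c(2L, 4L, 4L)); cargo[1, 1, 1:2] <- 100
  stack <- makeStack(marker, cons, cargo)
  mk <- MaskStack(marker > 0)
  rg <- MaskStack(array(TRUE, c(2L, 4L, 4L)))
  er <- peroxisomalEnrichment(stack, mk, mk, rg)
  expect_identical(er@nSlicesUsed, 1L)
  expect_equal(er@rawEnrichment, 90)
})

test_that("error paths: empty analysis mask, no cytosol, zero construct", {
  marker <- array(0, c(1L, 4L, 4L)); marker[1, 1, 1:2] <- 100
  stack <- makeStack(marker, constArray(0, c(1L, 4L, 4L)),
                     constArray(10, c(1L, 4L, 4L)))
  mk <- MaskStack(marker > 0)
  rg <- MaskStack(array(TRUE, c(1L, 4L, 4L)))
  empty <- MaskStack(array(FALSE, c(1L, 4L, 4L)))
  expect_error(peroxisomalEnrichment(stack, mk, empty, rg),
               "no construct-positive organelles")
  expect_error(peroxisomalEnrichment(stack, MaskStack(array(TRUE, c(1L, 4L, 4L))),
                                     mk, rg),
               "no cytosol")
  expect_error(peroxisomalEnrichment(stack, mk, mk, rg),
               "normalization undefined")
  # analysis mask must be nested in the marker mask
  outsider <- array(FALSE, c(1L, 4L, 4L)); outsider[1, 4, 4] <- TRUE
  expect_error(peroxisomalEnrichment(stack, mk, MaskStack(outsider), rg),
               "subset")
})

test_that("enrichment equals the brute-force per-pixel oracle on random stacks", {
  set.seed(501)
  for (i in 1:60) {
    d <- c(sample(1:2, 1L), sample(4:8, 1L), sample(4:8, 1L))
    marker <- array(0, d)
    nMask <- sample(2:5, 1L)
    idx <- sample(prod(d[2:3]), nMask)
    for (z in seq_len(d[1L])) {
      sl <- matrix(0, d[2L], d[3L]); sl[idx] <- 100
      marker[z, , ] <- sl
    }
    cons <- array(runif(prod(d), 10, 60), d)
    cargo <- array(runif(prod(d), 0, 120), d)
    stack <- makeStack(marker, cons, cargo)
    mk <- MaskStack(marker > 0)
    # analysis mask: random subset of the marker mask
    am <- marker > 0
    drop <- which(am)
    if (length(drop) > 2L) am[sample(drop, 1L)] <- FALSE
    rg <- MaskStack(array(TRUE, d))
    er <- peroxisomalEnrichment(stack, mk, MaskStack(am), rg)
    bf <- bruteForceEnrichment(stack, mk, MaskStack(am), rg)
    expect_equal(er@rawEnrichment, bf$raw, tolerance = 1e-12)
    expect_equal(er@background, bf$background, tolerance = 1e-12)
    expect_equal(er@normalizedEnrichment, bf$normalized, tolerance = 1e-12)
    expect_identical(er@nSlicesUsed, bf$nSlices)
    expect_identical(er@analysisMaskPx, bf$px)
  }
})

test_that("gain and offset act on raw enrichment exactly as linearity demands", {
  cell <- simulateCos7Cell(simulationParams(imageShape = c(4L, 48L, 48L),
                                            nPeroxisomes = 8L, seed = 31))
  seg <- segmentMarker(cell$stack)
  dp <- doublePositiveMask(seg$mask, cell$stack)
  rg <- cellRegion(cell$stack, cell$geometry)
  base <- peroxisomalEnrichment(cell$stack, seg$mask, dp, rg)
  v <- voxels(cell$stack)
  # scale cargo by 3
  v3 <- v; v3[, , , 3] <- 3 * v3[, , , 3]
  er3 <- peroxisomalEnrichment(ChannelStack(v3, channelRoles(cell$stack)),
                               seg$mask, dp, rg)
  expect_equal(er3@rawEnrichment, 3 * base@rawEnrichment, tolerance = 1e-12)
  # add a constant 17 to cargo everywhere
  vc <- v; vc[, , , 3] <- vc[, , , 3] + 17
  erc <- peroxisomalEnrichment(ChannelStack(vc, channelRoles(cell$stack)),
                               seg$mask, dp, rg)
  expect_equal(erc@rawEnrichment, base@rawEnrichment, tolerance = 1e-9)
  # scale construct by 4: normalized divides by 4 (masks held fixed)
  v4 <- v; v4[, , , 2] <- 4 * v4[, , , 2]
  er4 <- peroxisomalEnrichment(ChannelStack(v4, channelRoles(cell$stack)),
                               seg$mask, dp, rg)
  expect_equal(er4@normalizedEnrichment, base@normalizedEnrichment / 4,
               tolerance = 1e-12)
})

test_that("mitochondrial enrichment matches direct ratios and orderings", {
  mito <- array(0, c(1L, 4L, 4L)); mito[1, 1, 1:2] <- 1
  cargo <- array(20, c(1L, 4L, 4L)); cargo[1, 1, 1:2] <- 80
  stack <- makeStack(constArray(0, c(1L, 4L, 4L)),
                     constArray(10, c(1L, 4L, 4L)), cargo)
  mm <- MaskStack(mito > 0)
  rg <- MaskStack(array(TRUE, c(1L, 4L, 4L)))
  expect_equal(mitochondrialEnrichment(stack, mm, rg), 4)
  # uniform cargo: ratio 1
  ustack <- makeStack(constArray(0, c(1L, 4L, 4L)),
                      constArray(10, c(1L, 4L, 4L)),
                      constArray(20, c(1L, 4L, 4L)))
  expect_equal(mitochondrialEnrichment(ustack, mm, rg), 1)
  # difference mode
  expect_equal(mitochondrialEnrichment(stack, mm, rg, mode = "difference"), 60)
  # cytosol-shifted condition scores lower than its control
  shifted <- cargo; shifted[1, 1, 1:2] <- 30; shifted[shifted == 20] <- 40
  sstack <- makeStack(constArray(0, c(1L, 4L, 4L)),
                      constArray(10, c(1L, 4L, 4L)), shifted)
  expect_lt(mitochondrialEnrichment(sstack, mm, rg),
            mitochondrialEnrichment(stack, mm, rg))
})

test_that("pixel weighting and ratio flags change only what they should", {
  marker <- array(0, c(2L, 4L, 4L))
  marker[1, 1, 1:3] <- 100; marker[2, 2, 1] <- 100
  cons <- array(0, c(2L, 4L, 4L)); cons[marker > 0] <- 50
  cargo <- array(5, c(2L, 4L, 4L))
  cargo[1, 1, 1:3] <- 65; cargo[2, 2, 1] <- 20
  stack <- makeStack(marker, cons, cargo)
  mk <- MaskStack(marker > 0)
  rg <- MaskStack(array(TRUE, c(2L, 4L, 4L)))
  un <- peroxisomalEnrichment(stack, mk, mk, rg)
  pw <- peroxisomalEnrichment(stack, mk, mk, rg, sliceWeighting = "pixel")
  expect_equal(un@rawEnrichment, mean(c(60, 15)))
  expect_equal(pw@rawEnrichment, (3 * 60 + 1 * 15) / 4)
  aor <- peroxisomalEnrichment(stack, mk, mk, rg,
                               normalization = "average-of-ratios")
  expect_equal(aor@normalizedEnrichment, mean(c(60 / 50, 15 / 50)))
})
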