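# Synthetic fluorescence microscopy generator with analytic ground truth.
#
# COS-7-like cells: a random star-convex outline, perinuclear punctate
# peroxisomes rendered as Gaussian spots spanning 1-3 z-slices, tubular
# mitochondria (construct "spillover" only), diffuse cytosolic cargo
# background, additive Gaussian noise clipped at zero. Neuron-like cells:
# soma + neurite + growth-cone geometry with requested per-ROI counts.
#
# Closed-form truth: the cargo spot profile is recruitmentFraction times the
# construct spot profile and the cytosolic background is uniform, so the
# expected normalized enrichment of a cell equals recruitmentFraction, and
# the radial placement CDF is F(r) = r^(1 + radialBias) (r the normalized
# radial coordinate), giving expected shell frequencies
# 100 * [ (k/n)^(1+b) - ((k-1)/n)^(1+b) ].

.SPOT_SIGMA <- 2          # px; Gaussian spot width
.SPOT_Z_WEIGHTS <- c(0.5, 1, 0.5)  # amplitude on (zc-1, zc, zc+1)
.MARKER_LEVEL <- 150
# COS-7 cells tolerate occasional touching puncta (enrichment and radial
# scores are robust to merges); neuron counts must recover every punctum
# exactly, so neuron placements enforce a separation larger than twice the
# segmented spot radius.
.COS7_SPOT_SEP <- 3
.NEURON_SPOT_SEP <- 11

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameters of the synthetic microscopy generator
#'
#' @param imageShape Integer \code{(z, y, x)} stack extents (all >= 4).
#' @param nPeroxisomes Number of peroxisome puncta.
#' @param nMitochondria Number of mitochondrial tubules (construct spillover
#'   targets; they carry no marker signal).
#' @param recruitmentFraction Fraction in [0, 1] of peroxisomal cargo capacity
#'   occupied: the generative analog of the construct's nucleotide state
#'   (wild-type/GTP-like high, GDP-like 0).
#' @param constructLevel Peak construct intensity on a peroxisome.
#' @param cargoBackground Uniform cytosolic cargo intensity inside the
#'   outline.
#' @param mitoSpilloverFraction Fraction in [0, 1] of \code{constructLevel}
#'   painted onto mitochondrial tubules (overexpression spillover).
#' @param radialBias >= 0; 0 places peroxisomes perinuclearly, larger values
#'   disperse them toward the cell periphery. Placement CDF is
#'   \code{F(r) = r^(1 + radialBias)}.
#' @param noiseSd SD of additive Gaussian noise (clipped at zero).
#' @param markerLevel Peak marker intensity on a peroxisome.
#' @param seed Integer RNG seed.
#' @return A validated list of class \code{"SimulationParams"}.
#' @export
simulationParams <- function(imageShape = c(6L, 128L, 128L),
                             nPeroxisomes = 40L,
                             nMitochondria = 6L,
                             recruitmentFraction = 0.8,
                             constructLevel = 120,
                             cargoBackground = 20,
                             mitoSpilloverFraction = 0.3,
                             radialBias = 0,
                             noiseSd = 2,
                             markerLevel = .MARKER_LEVEL,
                             seed = 1L) {
  stopifnot(length(imageShape) == 3L, all(imageShape >= 4L),
            nPeroxisomes >= 0L, nMitochondria >= 0L,
            recruitmentFraction >= 0, recruitmentFraction <= 1,
            constructLevel > 0, cargoBackground >= 0,
            mitoSpilloverFraction >= 0, mitoSpilloverFraction <= 1,
            radialBias >= 0, noiseSd >= 0, markerLevel > 0)
  structure(list(imageShape = as.integer(imageShape),
                 nPeroxisomes = as.integer(nPeroxisomes),
                 nMitochondria = as.integer(nMitochondria),
                 recruitmentFraction = recruitmentFraction,
                 constructLevel = constructLevel,
                 cargoBackground = cargoBackground,
                 mitoSpilloverFraction = mitoSpilloverFraction,
                 radialBias = radialBias,
                 noiseSd = noiseSd,
                 markerLevel = markerLevel,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

# Random star-convex outline: radius function 1 + sum of low-order harmonics.
.randomOutline <- function(center, baseRadius, nVertices = 24L) {
  amp <- stats::runif(3L, 0, 0.06)
  phase <- stats::runif(3L, 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  s <- 1 + amp[1L] * cos(th + phase[1L]) + amp[2L] * cos(2 * th + phase[2L]) +
    amp[3L] * cos(3 * th + phase[3L])
  cbind(center[1L] + baseRadius * s * cos(th),
        center[2L] + baseRadius * s * sin(th))
}

# Add a Gaussian spot to one (ny, nx) slice matrix, windowed at 4 sigma.
.addSpot <- function(img, x0, y0, amp, sigma = .SPOT_SIGMA) {
  ny <- nrow(img); nx <- ncol(img)
  w <- ceiling(4 * sigma)
  xs <- max(0L, floor(x0 - w)):min(nx - 1L, ceiling(x0 + w))
  ys <- max(0L, floor(y0 - w)):min(ny - 1L, ceiling(y0 + w))
  if (!length(xs) || !length(ys)) return(img)
  gx <- exp(-(xs - x0)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y0)^2 / (2 * sigma^2))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amp * outer(gy, gx)
  img
}

# Paint a thickened segment (width ~2*halfWidth) into a slice matrix.
.addTube <- function(img, p1, p2, amp, halfWidth = 1.5) {
  ny <- nrow(img); nx <- ncol(img)
  xr <- floor(min(p1[1L], p2[1L]) - halfWidth):ceiling(max(p1[1L], p2[1L]) + halfWidth)
  yr <- floor(min(p1[2L], p2[2L]) - halfWidth):ceiling(max(p1[2L], p2[2L]) + halfWidth)
  xr <- xr[xr >= 0L & xr < nx]; yr <- yr[yr >= 0L & yr < ny]
  if (!length(xr) || !length(yr)) return(img)
  px <- rep(xr, each = length(yr)); py <- rep(yr, times = length(xr))
  dx <- p2[1L] - p1[1L]; dy <- p2[2L] - p1[2L]
  len2 <- dx * dx + dy * dy
  t <- if (len2 > 0) pmin(1, pmax(0, ((px - p1[1L]) * dx + (py - p1[2L]) * dy) / len2)) else 0
  d2 <- (px - (p1[1L] + t * dx))^2 + (py - (p1[2L] + t * dy))^2
  hit <- d2 <= halfWidth^2
  idx <- cbind(py[hit] + 1L, px[hit] + 1L)
  img[idx] <- pmax(img[idx], amp)
  img
}

.placePeroxisomes <- function(n, outline, center, radialBias, minSep,
                              maxTries = 20000L) {
  pts <- matrix(NA_real_, n, 2L)
  got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("could not place ", n, " peroxisomes with separation ", minSep)
    th <- stats::runif(1L, 0, 2 * pi)
    rf <- stats::runif(1L)^(1 / (1 + radialBias))
    # probe point along the ray to find the boundary distance
    probe <- center + 0.1 * c(cos(th), sin(th))
    B <- .rayBoundaryDistance(probe[1L], probe[2L], center, outline)$boundaryDist
    if (is.na(B)) next
    p <- center + rf * B * c(cos(th), sin(th))
    if (!.pointInPolygon(p[1L], p[2L], outline, boundary = FALSE)) next
    if (got > 0L) {
      d2 <- (pts[seq_len(got), 1L] - p[1L])^2 + (pts[seq_len(got), 2L] - p[2L])^2
      if (min(d2) < minSep^2) next
    }
    got <- got + 1L
    pts[got, ] <- p
  }
  pts
}

.renderCell <- function(params, outline, center, spotXY, nShellsTruth = 10L) {
  z <- params$imageShape[1L]; ny <- params$imageShape[2L]; nx <- params$imageShape[3L]
  n <- nrow(spotXY)
  marker <- construct <- cargo <- array(0, c(z, ny, nx))
  zc <- if (n) sample(seq_len(z), n, replace = TRUE) else integer(0)
  bMark <- stats::runif(n, 0.8, 1.2)
  bCons <- stats::runif(n, 0.8, 1.2)
  for (i in seq_len(n)) {
    for (dz in -1:1) {
      zi <- zc[i] + dz
      if (zi < 1L || zi > z) next
      w <- .SPOT_Z_WEIGHTS[dz + 2L]
      marker[zi, , ] <- .addSpot(matrix(marker[zi, , ], ny, nx),
                                 spotXY[i, 1L], spotXY[i, 2L],
                                 params$markerLevel * bMark[i] * w)
      construct[zi, , ] <- .addSpot(matrix(construct[zi, , ], ny, nx),
                                    spotXY[i, 1L], spotXY[i, 2L],
                                    params$constructLevel * bCons[i] * w)
      cargo[zi, , ] <- .addSpot(matrix(cargo[zi, , ], ny, nx),
                                spotXY[i, 1L], spotXY[i, 2L],
                                params$recruitmentFraction *
                                  params$constructLevel * bCons[i] * w)
    }
  }
  # mitochondrial tubules: construct spillover only
  if (params$nMitochondria > 0L && params$mitoSpilloverFraction > 0) {
    starts <- samplePointsInPolygon(params$nMitochondria, outline)
    for (i in seq_len(params$nMitochondria)) {
      p <- starts[i, ]
      th <- stats::runif(1L, 0, 2 * pi)
      zi <- sample(seq_len(z), 1L)
      for (seg in 1:3) {
        q <- p + 13 * c(cos(th), sin(th))
        construct[zi, , ] <- .addTube(matrix(construct[zi, , ], ny, nx), p, q,
                                      params$mitoSpilloverFraction *
                                        params$constructLevel)
        p <- q
        th <- th + stats::runif(1L, -0.5, 0.5)
      }
    }
  }
  # uniform cytosolic cargo background inside the outline plus a small halo:
  # the outline stands for a user-drawn boundary just inside the cell's
  # cargo-filled margin, so puncta hugging the boundary remain surrounded by
  # background (their mask pixels never sample empty space)
  halo <- .scalePolygon(outline, center, 1.12)
  inCell <- .rasterizePolygon(outline, ny, nx) | .rasterizePolygon(halo, ny, nx)
  for (zi in seq_len(z))
    cargo[zi, , ] <- cargo[zi, , ] + params$cargoBackground * inCell
  v <- array(0, c(z, ny, nx, 3L))
  v[, , , 1L] <- marker; v[, , , 2L] <- construct; v[, , , 3L] <- cargo
  if (params$noiseSd > 0)
    v <- v + stats::rnorm(length(v), 0, params$noiseSd)
  v <- round(pmax(v, 0))
  truthShell <- 100 * diff((seq(0, nShellsTruth) / nShellsTruth)^(1 + params$radialBias))
  truth <- structure(list(
    organelleCentroids = if (n) data.frame(x = spotXY[, 1L], y = spotXY[, 2L],
                                           z = zc - 1L)
                         else data.frame(x = numeric(0), y = numeric(0),
                                         z = numeric(0)),
    perOrganelleEnrichment = params$recruitmentFraction *
      params$constructLevel * bCons,
    normalizedEnrichment = params$recruitmentFraction,
    shellTruth = truthShell,
    roiCounts = integer(0)), class = "SimulationTruth")
  list(voxels = v, truth = truth)
}

#' Simulate a COS-7-like cell
#'
#' Generates a 3-channel z-stack (marker, construct, cargo), its geometry and
#' the ground truth. Peroxisomes are Gaussian puncta spanning up to three
#' adjacent slices; the construct is present on every peroxisome and, per
#' \code{mitoSpilloverFraction}, on mitochondrial tubules; the cargo channel
#' carries \code{recruitmentFraction} times the construct's spot signal plus a
#' uniform cytosolic background. The expected normalized enrichment of the
#' cell is exactly \code{recruitmentFraction}.
#'
#' @param params A \code{\link{simulationParams}} object.
#' @return List with elements \code{stack} (\linkS4class{ChannelStack}),
#'   \code{geometry} (\linkS4class{CellGeometry}) and \code{truth}
#'   (\code{SimulationTruth} list: \code{organelleCentroids},
#'   \code{perOrganelleEnrichment}, \code{normalizedEnrichment},
#'   \code{shellTruth}, \code{roiCounts}).
#' @examples
#' cell <- simulateCos7Cell(simulationParams(nPeroxisomes = 10, seed = 7))
#' cell$stack
#' @export
simulateCos7Cell <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  .withSeed(params$seed, {
    ny <- params$imageShape[2L]; nx <- params$imageShape[3L]
    center <- c((nx - 1) / 2, (ny - 1) / 2)
    outline <- .randomOutline(center, 0.4 * min(nx, ny))
    spotXY <- .placePeroxisomes(params$nPeroxisomes, outline, center,
                                params$radialBias, .COS7_SPOT_SEP)
    r <- .renderCell(params, outline, center, spotXY)
    list(stack = ChannelStack(r$voxels, c("marker", "construct", "cargo"),
                              zStepUm = 0.3),
         geometry = CellGeometry(outline, center),
         truth = r$truth)
  })
}

.neuronGeometry <- function(ny, nx) {
  cy <- (ny - 1) / 2
  Rs <- 0.3 * ny + 2
  S <- c(max(Rs + 5, 0.16 * nx), cy)
  h <- 3
  coneX <- 0.74 * nx
  coneL <- 0.2 * nx; coneH <- 0.27 * ny
  a0 <- asin(h / Rs)
  arc <- seq(a0, 2 * pi - a0, length.out = 28L)
  somaArc <- cbind(S[1L] + Rs * cos(arc), cy + Rs * sin(arc))
  cone <- cbind(coneX + coneL * c(0, 0.3, 0.73, 1, 0.73, 0.3, 0),
                cy + coneH * c(0, -1, -0.53, 0, 0.53, 1, 0))
  cone[c(1L, 7L), 2L] <- cy + c(-h, h)
  # walk: soma arc from the bottom attachment around the left side to the top
  # attachment, then the neurite top edge into the cone (top to bottom), then
  # back along the neurite bottom edge (implicit closing edge)
  outline <- rbind(somaArc, cone)
  thSoma <- seq(0, 2 * pi, length.out = 25L)[-25L]
  somaRoi <- cbind(S[1L] + (Rs - 1) * cos(thSoma), cy + (Rs - 1) * sin(thSoma))
  coneRoi <- cone
  list(outline = outline, center = S, Rs = Rs, h = h, coneX = coneX,
       rois = list(soma = somaRoi, growth_cone = coneRoi))
}

#' Simulate a neuron-like cell with soma and growth-cone ROIs
#'
#' The geometry is a soma disc joined by a thin neurite to a growth-cone fan;
#' \code{somaCount} peroxisomes are placed inside the soma ROI,
#' \code{growthConeCount} inside the growth-cone ROI, and any remainder along
#' the neurite. Slice spacing is 0.2 um.
#'
#' @param params A \code{\link{simulationParams}} object; the default neuron
#'   stack shape is \code{c(4, 160, 320)} with 30 peroxisomes.
#' @param somaCount,growthConeCount Requested per-ROI peroxisome counts;
#'   their sum must not exceed \code{params$nPeroxisomes}.
#' @return As \code{\link{simulateCos7Cell}}; \code{truth$roiCounts} records
#'   the requested placements.
#' @export
simulateNeuron <- function(params = simulationParams(imageShape = c(4L, 160L, 320L),
                                                     nPeroxisomes = 30L),
                           somaCount = 20L, growthConeCount = 5L) {
  stopifnot(inherits(params, "SimulationParams"))
  if (somaCount + growthConeCount > params$nPeroxisomes)
    stop("somaCount + growthConeCount exceeds nPeroxisomes")
  .withSeed(params$seed, {
    ny <- params$imageShape[2L]; nx <- params$imageShape[3L]
    geo <- .neuronGeometry(ny, nx)
    somaDisc <- .scalePolygon(geo$rois$soma, geo$center, (geo$Rs - 4) / (geo$Rs - 1))
    somaPts <- samplePointsInPolygon(somaCount, somaDisc,
                                     minSep = .NEURON_SPOT_SEP)
    coneInner <- .scalePolygon(geo$rois$growth_cone,
                               .polygonCentroid(geo$rois$growth_cone), 0.88)
    conePts <- samplePointsInPolygon(growthConeCount, coneInner,
                                     minSep = .NEURON_SPOT_SEP)
    nRest <- params$nPeroxisomes - somaCount - growthConeCount
    restPts <- if (nRest > 0L) {
      # evenly spaced slots with jitter keep the separation guarantee
      x0 <- geo$center[1L] + geo$Rs + 6; x1 <- geo$coneX - 6
      spacing <- (x1 - x0) / nRest
      if (spacing < .NEURON_SPOT_SEP + 1)
        stop("too many peroxisomes for the neurite length")
      jit <- (spacing - .NEURON_SPOT_SEP) / 2
      xs <- x0 + (seq_len(nRest) - 0.5) * spacing +
        stats::runif(nRest, -jit, jit)
      cbind(xs, (ny - 1) / 2 + stats::runif(nRest, -1, 1))
    } else matrix(numeric(0), 0L, 2L)
    spotXY <- rbind(somaPts, conePts, restPts)
    r <- .renderCell(params, geo$outline, geo$center, spotXY)
    r$truth$roiCounts <- c(soma = somaCount, growth_cone = growthConeCount)
    list(stack = ChannelStack(r$voxels, c("marker", "construct", "cargo"),
                              zStepUm = 0.2),
         geometry = CellGeometry(geo$outline, geo$center, geo$rois),
         truth = r$truth)
  })
}

# Deterministic per-cell seed from the master seed, condition label and index.
.cellSeed <- function(masterSeed, label, index) {
  h <- as.numeric(masterSeed) %% 2147483647
  for (ch in utf8ToInt(label))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((h * 131 + index * 7919) %% 2147483647)
}

#' Simulate a labeled panel of cells across conditions
#'
#' Emulates a per-condition experimental design (e.g. 15 cells per construct
#' over replicates) with deterministic per-cell seeds derived from the master
#' seed, the condition label and the cell index.
#'
#' @param conditions Named list mapping condition label to a
#'   \code{\link{simulationParams}} object (its \code{seed} is overridden
#'   per cell).
#' @param nCellsPerCondition Cells per condition (>= 1).
#' @param seed Master seed.
#' @param mode \code{"cos7"} or \code{"neuron"}.
#' @param ... For \code{mode = "neuron"}: per-condition \code{somaCount} /
#'   \code{growthConeCount} named lists.
#' @return List of class \code{"simulationPanel"}: one element per cell with
#'   \code{label}, \code{cellId}, \code{stack}, \code{geometry}, \code{truth}.
#' @export
simulateConditionPanel <- function(conditions, nCellsPerCondition = 15L,
                                   seed = 1L, mode = c("cos7", "neuron"),
                                   somaCount = NULL, growthConeCount = NULL) {
  mode <- match.arg(mode)
  if (!length(conditions)) stop("empty condition map")
  if (nCellsPerCondition < 1L) stop("nCellsPerCondition must be >= 1")
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("conditions must be a named list")
  cells <- list()
  for (label in names(conditions)) {
    base <- conditions[[label]]
    stopifnot(inherits(base, "SimulationParams"))
    for (i in seq_len(nCellsPerCondition)) {
      p <- base
      p$seed <- .cellSeed(seed, label, i)
      cell <- if (mode == "cos7") simulateCos7Cell(p)
              else simulateNeuron(p,
                     somaCount = somaCount[[label]] %||% 20L,
                     growthConeCount = growthConeCount[[label]] %||% 5L)
      cell$label <- label
      cell$cellId <- sprintf("%s_%02d", label, i)
      cells[[cell$cellId]] <- cell
    }
  }
  structure(cells, class = "simulationPanel")
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat("SimulationTruth:", nrow(x$organelleCentroids), "organelles;",
      "expected normalized enrichment", x$normalizedEnrichment, "\n")
  if (length(x$roiCounts))
    cat("  ROI counts:", paste(names(x$roiCounts), x$roiCounts,
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}
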