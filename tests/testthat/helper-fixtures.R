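# Shared fixture builders. Everything is generated in code; no binary files.

# A tiny hand-specified stack: values per channel given as (z, y, x) arrays.
makeStack <- function(marker, construct, cargo, zStepUm = 0.3) {
  d <- dim(marker)
  v <- array(0, c(d, 3L))
  v[, , , 1L] <- marker; v[, , , 2L] <- construct; v[, , , 3L] <- cargo
  ChannelStack(v, c("marker", "construct", "cargo"), zStepUm = zStepUm)
}

constArray <- function(value, d) array(value, d)

squareGeometry <- function(side = 10, center = NULL) {
  out <- cbind(c(0, side, side, 0), c(0, 0, side, side))
  if (is.null(center)) center <- c(side / 2, side / 2)
  CellGeometry(out, center)
}

# Regular polygon approximating a circle.
circleGeometry <- function(radius = 10, center = c(0, 0), n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  CellGeometry(cbind(center[1L] + radius * cos(th),
                     center[2L] + radius * sin(th)), center)
}

# Independent brute-force implementation of the peroxisomal enrichment
# contract: literal per-pixel loops, no shared code with the package path.
bruteForceEnrichment <- function(stack, markerMask, analysisMask, region,
                                 cargoChannel = 3L, constructChannel = 2L) {
  v <- voxels(stack)
  d <- dim(v)
  rawZ <- c(); outZ <- c(); consZ <- c(); px <- 0L
  for (z in seq_len(d[1L])) {
    inVals <- c(); outVals <- c(); consVals <- c()
    for (y in seq_len(d[2L])) for (x in seq_len(d[3L])) {
      if (masks(analysisMask)[z, y, x]) {
        inVals <- c(inVals, v[z, y, x, cargoChannel])
        consVals <- c(consVals, v[z, y, x, constructChannel])
      }
      if (masks(region)[z, y, x] && !masks(markerMask)[z, y, x])
        outVals <- c(outVals, v[z, y, x, cargoChannel])
    }
    if (length(inVals) == 0L) next
    rawZ <- c(rawZ, mean(inVals) - mean(outVals))
    outZ <- c(outZ, mean(outVals))
    consZ <- c(consZ, mean(consVals))
    px <- px + length(inVals)
  }
  raw <- mean(rawZ)
  list(raw = raw, background = mean(outZ), construct = mean(consZ),
       normalized = raw / mean(consZ), nSlices = length(rawZ), px = px)
}

# Exact two-tailed Mann-Whitney p by enumeration of all rank assignments.
enumMannWhitneyP <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-12)
}

# Closed-form Welch test evaluated independently of the package path.
closedFormWelch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
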