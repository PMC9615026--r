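# Cargo-enrichment scoring on construct-positive organelles.
#
# Per z-slice with a non-empty analysis mask:
#   in_z   = mean cargo over the analysis mask
#   out_z  = mean cargo over (cell region \ marker mask)   [cytosol]
#   raw_z  = in_z - out_z
#   cons_z = mean construct over the analysis mask
# Cell-level values are unweighted means over used slices (a pixel-weighted
# variant is available); normalized = mean(raw_z) / mean(cons_z)
# (ratio of averages; the average-of-ratios variant is available).

.sliceMatrix <- function(a, z) matrix(a[z, , ], dim(a)[2L], dim(a)[3L])

#' Peroxisomal cargo enrichment of one cell
#'
#' Computes the background-subtracted mean cargo intensity on the
#' construct-positive organelle pixels, averaged across z-slices, normalized
#' to construct expression. Raw enrichment may be negative (cargo depleted on
#' the organelles); it is reported, not clipped.
#'
#' @param stack A \linkS4class{ChannelStack} with declared construct and
#'   cargo channels.
#' @param markerMask Marker \linkS4class{MaskStack} (defines the cytosol as
#'   everything in the cell region outside it).
#' @param analysisMask Analysis \linkS4class{MaskStack} (the double-positive
#'   mask); must be a subset of \code{markerMask}.
#' @param region Whole-cell \linkS4class{MaskStack} from
#'   \code{\link{cellRegion}}.
#' @param cargoChannel Channel role or index of the cargo; default
#'   \code{"cargo"}.
#' @param cellId Identifier recorded in the result.
#' @param sliceWeighting \code{"unweighted"} (default): plain mean over used
#'   slices; \code{"pixel"}: slice terms weighted by analysis-mask pixel
#'   count.
#' @param normalization \code{"ratio-of-averages"} (default) or
#'   \code{"average-of-ratios"}.
#' @return An \linkS4class{EnrichmentResult}.
#' @examples
#' v <- array(10, c(1, 4, 4, 3))
#' v[1, 1, 1:2, 3] <- 100; v[1, 1, 1:2, 2] <- 50
#' cs <- ChannelStack(v, c("marker", "construct", "cargo"))
#' m <- array(FALSE, c(1, 4, 4)); m[1, 1, 1:2] <- TRUE
#' mk <- MaskStack(m); rg <- MaskStack(array(TRUE, c(1, 4, 4)))
#' peroxisomalEnrichment(cs, mk, mk, rg)  # raw 90, normalized 1.8
#' @export
peroxisomalEnrichment <- function(stack, markerMask, analysisMask, region,
                                  cargoChannel = "cargo",
                                  cellId = "cell",
                                  sliceWeighting = c("unweighted", "pixel"),
                                  normalization = c("ratio-of-averages",
                                                    "average-of-ratios")) {
  sliceWeighting <- match.arg(sliceWeighting)
  normalization <- match.arg(normalization)
  d <- dim(stack@voxels)
  for (mk in list(markerMask, analysisMask, region))
    if (!identical(dim(mk@masks), d[1:3]))
      stop("mask shape does not match the stack")
  if (any(analysisMask@masks & !markerMask@masks))
    stop("analysisMask must be a subset of markerMask")
  cargo <- channelData(stack, cargoChannel)
  cons <- channelData(stack, "construct")
  rawZ <- outZ <- consZ <- wZ <- numeric(0)
  for (z in seq_len(d[1L])) {
    am <- .sliceMatrix(analysisMask@masks, z)
    if (!any(am)) next
    cyto <- .sliceMatrix(region@masks, z) & !.sliceMatrix(markerMask@masks, z)
    if (!any(cyto)) stop("no cytosol for background on slice ", z)
    cg <- .sliceMatrix(cargo, z)
    inZ <- mean(cg[am])
    oZ <- mean(cg[cyto])
    rawZ <- c(rawZ, inZ - oZ)
    outZ <- c(outZ, oZ)
    consZ <- c(consZ, mean(.sliceMatrix(cons, z)[am]))
    wZ <- c(wZ, sum(am))
  }
  if (!length(rawZ))
    stop("no construct-positive organelles: analysis mask empty on every slice")
  w <- if (sliceWeighting == "pixel") wZ / sum(wZ) else rep(1 / length(rawZ), length(rawZ))
  raw <- sum(w * rawZ)
  background <- sum(w * outZ)
  consMean <- sum(w * consZ)
  normalized <- if (normalization == "ratio-of-averages") {
    if (consMean == 0) stop("normalization undefined: construct intensity is zero")
    raw / consMean
  } else {
    if (any(consZ == 0)) stop("normalization undefined: construct intensity is zero")
    sum(w * (rawZ / consZ))
  }
  new("EnrichmentResult", cellId = cellId, rawEnrichment = raw,
      constructIntensity = consMean, normalizedEnrichment = normalized,
      background = background, nSlicesUsed = length(rawZ),
      analysisMaskPx = as.integer(sum(wZ)))
}

#' Mitochondrial cargo enrichment relative to the cytosol
#'
#' The mitochondrial variant of the co-localization score: per used slice the
#' ratio of the mean cargo intensity on the mitochondrial mask to the mean
#' over the cytosol (cell region minus mask), averaged over slices. Uniform
#' cargo gives 1; a cytosol-shifted condition gives a smaller value than its
#' control.
#'
#' @param stack A \linkS4class{ChannelStack}.
#' @param mitoMask Mitochondrial \linkS4class{MaskStack} (non-empty on at
#'   least one slice).
#' @param region Whole-cell \linkS4class{MaskStack}.
#' @param cargoChannel Channel role or index of the cargo; default
#'   \code{"cargo"}.
#' @param mode \code{"ratio"} (default) or \code{"difference"}
#'   (mito mean minus cytosol mean).
#' @return Per-cell fold enrichment (dimensionless scalar).
#' @export
mitochondrialEnrichment <- function(stack, mitoMask, region,
                                    cargoChannel = "cargo",
                                    mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  d <- dim(stack@voxels)
  cargo <- channelData(stack, cargoChannel)
  vals <- numeric(0)
  for (z in seq_len(d[1L])) {
    mm <- .sliceMatrix(mitoMask@masks, z)
    if (!any(mm)) next
    cyto <- .sliceMatrix(region@masks, z) & !mm
    if (!any(cyto)) next
    cg <- .sliceMatrix(cargo, z)
    inZ <- mean(cg[mm]); outZ <- mean(cg[cyto])
    if (mode == "ratio") {
      if (outZ == 0) {
        warning("zero cytosolic mean on slice ", z, "; slice dropped")
        next
      }
      vals <- c(vals, inZ / outZ)
    } else {
      vals <- c(vals, inZ - outZ)
    }
  }
  if (!length(vals)) stop("no usable slices for mitochondrial enrichment")
  mean(vals)
}
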