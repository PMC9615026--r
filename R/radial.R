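# Cell-shape-scaled concentric-shell analysis: the percentage frequency of
# objects per shell, radiating from the user-chosen center. Shell boundaries
# are scaled copies of the outline, so the shells follow the shape of the
# cell rather than being circles.

#' Build shape-scaled concentric shells
#'
#' Boundary k has vertices \code{center + (k/nShells) * (v - center)} for each
#' outline vertex v; boundary \code{nShells} is the outline itself. The
#' outline must be star-convex about the center, otherwise scaled boundaries
#' would cross.
#'
#' @param geometry A \linkS4class{CellGeometry}.
#' @param nShells Number of shells (>= 1); default 10.
#' @return A \linkS4class{ShellSet}.
#' @examples
#' g <- CellGeometry(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), c(5, 5))
#' shapeScaledShells(g, 2)
#' @export
shapeScaledShells <- function(geometry, nShells = 10L) {
  stopifnot(nShells >= 1L)
  if (!.isStarConvex(geometry@outline, geometry@center))
    stop("outline is not star-convex about the center; scaled shell ",
         "boundaries would cross. Re-draw the outline or move the center.")
  bounds <- lapply(seq_len(nShells), function(k)
    .scalePolygon(geometry@outline, geometry@center, k / nShells))
  new("ShellSet", nShells = as.integer(nShells), boundaries = bounds,
      center = geometry@center, outline = geometry@outline)
}

#' Radial shell distribution of objects
#'
#' Each object centroid gets the normalized radial coordinate
#' \code{r = |p - c| / B(theta)}, where \code{B(theta)} is the distance from
#' the center to the outline along the centroid's ray (computed by ray
#' casting). The shell index is \code{ceiling(r * nShells)} with half-open
#' intervals \code{(lo, hi]}, so a centroid exactly on a boundary falls in
#' the inner shell. Centroids outside the outline are excluded with a
#' warning and counted in \code{nExcluded}.
#'
#' @param objects An \linkS4class{ObjectSet}, or a matrix/data.frame with
#'   \code{x} and \code{y} centroid columns.
#' @param shells A \linkS4class{ShellSet}.
#' @return A \linkS4class{ShellDistribution}; frequencies are percentages
#'   summing to 100 over included objects.
#' @export
radialDistribution <- function(objects, shells) {
  xy <- .objectXY(objects)
  n <- nrow(xy)
  if (n == 0L) stop("no objects inside outline")
  rb <- .rayBoundaryDistance(xy[, 1L], xy[, 2L], shells@center, shells@outline)
  r <- rb$pointDist / rb$boundaryDist
  r[rb$pointDist == 0] <- 0  # an object exactly at the center
  outside <- is.na(r) | r > 1 + 1e-9
  nExcl <- sum(outside)
  if (nExcl > 0L)
    warning(nExcl, " object(s) outside the outline were excluded")
  r <- pmin(r[!outside], 1)
  if (!length(r)) stop("no objects inside outline")
  k <- pmin(pmax(ceiling(r * shells@nShells), 1L), shells@nShells)
  counts <- tabulate(k, shells@nShells)
  new("ShellDistribution", frequencies = 100 * counts / length(r),
      nIncluded = length(r), nExcluded = as.integer(nExcl))
}

.objectXY <- function(objects) {
  if (is(objects, "ObjectSet")) {
    tab <- objects@objects
    return(cbind(tab$x, tab$y))
  }
  if (is.data.frame(objects)) return(cbind(objects$x, objects$y))
  as.matrix(objects)[, 1:2, drop = FALSE]
}

#' Aggregate shell distributions across cells
#'
#' @param dists List of \linkS4class{ShellDistribution} objects sharing the
#'   same shell count.
#' @return \code{data.frame} with columns \code{shell}, \code{mean},
#'   \code{sd} (sample SD, n - 1 denominator; \code{NA} for a single cell
#'   rather than fabricating zero spread).
#' @export
aggregateDistributions <- function(dists) {
  if (!length(dists)) stop("empty distribution list")
  ns <- vapply(dists, function(d) length(d@frequencies), integer(1L))
  if (length(unique(ns)) != 1L) stop("mismatched shell counts")
  m <- do.call(rbind, lapply(dists, function(d) d@frequencies))
  data.frame(shell = seq_len(ncol(m)),
             mean = colMeans(m),
             sd = if (nrow(m) > 1L) apply(m, 2L, stats::sd) else NA_real_)
}
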