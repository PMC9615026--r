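# Polygon primitives used throughout the package.
#
# Conventions: pixel coordinates are 0-based (x, y) with y increasing downward,
# so pixel (x, y) corresponds to voxel array element [, y + 1, x + 1, ].
# Polygons are n x 2 matrices of (x, y) vertices, implicitly closed.

.polygonArea <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

.polygonCentroid <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Vectorized even-odd point-in-polygon; boundary points count as inside.
.pointInPolygon <- function(px, py, poly, boundary = TRUE, eps = 1e-9) {
  n <- length(px)
  inside <- logical(n)
  onb <- logical(n)
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- poly[j, 1L]; y1 <- poly[j, 2L]
    x2 <- poly[i, 1L]; y2 <- poly[i, 2L]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xi[crosses])
    }
    # distance from point to segment for boundary detection
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    } else {
      d2 <- (px - x1)^2 + (py - y1)^2
    }
    onb <- onb | d2 <= eps * eps
    j <- i
  }
  if (boundary) inside | onb else inside & !onb
}

# Proper segment-intersection test between non-adjacent edges.
.segmentsIntersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
  d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
  d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
  ((d1 > eps & d2 < -eps) | (d1 < -eps & d2 > eps)) &&
    ((d3 > eps & d4 < -eps) | (d3 < -eps & d4 > eps))
}

.isSimplePolygon <- function(poly) {
  nv <- nrow(poly)
  if (nv < 3L) return(FALSE)
  for (i in seq_len(nv)) {
    a1 <- poly[i, ]; a2 <- poly[if (i == nv) 1L else i + 1L, ]
    for (k in seq_len(nv)) {
      # skip the same and adjacent edges (they share a vertex)
      if (abs(i - k) <= 1L || abs(i - k) == nv - 1L) next
      b1 <- poly[k, ]; b2 <- poly[if (k == nv) 1L else k + 1L, ]
      if (.segmentsIntersect(a1, a2, b1, b2)) return(FALSE)
    }
  }
  TRUE
}

# A polygon is star-convex about `center` when the boundary is a single-valued
# function of the angle around the center: vertex angles must wind exactly once
# around the center without reversing direction.
.isStarConvex <- function(poly, center, tol = 1e-9) {
  th <- atan2(poly[, 2L] - center[2L], poly[, 1L] - center[1L])
  d <- diff(c(th, th[1L]))
  d <- ((d + pi) %% (2 * pi)) - pi  # wrap to (-pi, pi]
  if (any(abs(d) >= pi - tol)) return(FALSE)
  s <- sum(d)
  if (abs(abs(s) - 2 * pi) > 1e-6) return(FALSE)
  all(sign(d) == sign(s) | abs(d) < tol)
}

# Distance from `center` to the polygon boundary along the ray through each
# point, returned together with the point's own distance.  Used for the
# normalized radial coordinate r = |p - c| / B(theta).
.rayBoundaryDistance <- function(px, py, center, poly) {
  n <- length(px)
  cx <- center[1L]; cy <- center[2L]
  dx <- px - cx; dy <- py - cy
  r <- sqrt(dx * dx + dy * dy)
  out <- numeric(n)
  nv <- nrow(poly)
  ax <- poly[, 1L]; ay <- poly[, 2L]
  bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
  ex <- bx - ax; ey <- by - ay
  for (i in seq_len(n)) {
    if (r[i] == 0) { out[i] <- NA_real_; next }
    ux <- dx[i] / r[i]; uy <- dy[i] / r[i]
    # solve c + t*u = a + s*e for each edge (Cramer on [u, -e])
    den <- ux * ey - uy * ex
    ok <- abs(den) > 1e-12
    s <- (uy * (ax - cx) - ux * (ay - cy)) / den
    t <- ((ax - cx) * ey - (ay - cy) * ex) / den
    hit <- ok & s >= -1e-9 & s <= 1 + 1e-9 & t > 1e-9
    out[i] <- if (any(hit)) min(t[hit]) else NA_real_
  }
  list(pointDist = r, boundaryDist = out)
}

# Rasterize a polygon onto an ny x nx pixel grid (pixel centers at integer
# 0-based coordinates); boundary-inclusive.
.rasterizePolygon <- function(poly, ny, nx) {
  px <- rep(seq_len(nx) - 1L, each = ny)
  py <- rep(seq_len(ny) - 1L, times = nx)
  matrix(.pointInPolygon(px, py, poly), nrow = ny, ncol = nx)
}

.scalePolygon <- function(poly, center, factor) {
  cbind(center[1L] + factor * (poly[, 1L] - center[1L]),
        center[2L] + factor * (poly[, 2L] - center[2L]))
}

#' Sample points uniformly inside a polygon
#'
#' Rejection sampling from the polygon's bounding box. Used by the synthetic
#' data generator and by calibration checks that need spatially uniform
#' object placements.
#'
#' @param n Number of points.
#' @param poly An \code{n x 2} matrix of polygon vertices \code{(x, y)}.
#' @param minSep Optional minimum pairwise distance between accepted points
#'   (rejection is applied incrementally); \code{0} disables the constraint.
#' @param maxTries Give up (with an error) after this many candidate draws.
#' @return An \code{n x 2} matrix of points strictly inside \code{poly}.
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' set.seed(1)
#' pts <- samplePointsInPolygon(50, sq)
#' @export
samplePointsInPolygon <- function(n, poly, minSep = 0, maxTries = 100000L) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  pts <- matrix(NA_real_, n, 2L)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("could not place ", n, " points with minSep = ", minSep,
           " inside the polygon")
    x <- stats::runif(1L, xr[1L], xr[2L])
    y <- stats::runif(1L, yr[1L], yr[2L])
    if (!.pointInPolygon(x, y, poly, boundary = FALSE)) next
    if (minSep > 0 && got > 0L) {
      d2 <- (pts[seq_len(got), 1L] - x)^2 + (pts[seq_len(got), 2L] - y)^2
      if (min(d2) < minSep^2) next
    }
    got <- got + 1L
    pts[got, ] <- c(x, y)
  }
  pts
}

# 8-connected component labeling of a logical matrix by iterative minimum-label
# propagation. EBImage::bwlabel is 4-connected, whereas object identity here is
# defined on the 8-neighborhood, so this is implemented directly.
.labelComponents <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  if (!any(mask)) return(lab)
  lab[mask] <- seq_len(sum(mask))
  full <- matrix(NA_integer_, ny, nx)
  repeat {
    full[] <- NA_integer_
    full[mask] <- lab[mask]
    m <- full
    # 8 neighbor shifts
    sh <- list(
      rbind(NA_integer_, m[-ny, , drop = FALSE]),              # down
      rbind(m[-1L, , drop = FALSE], NA_integer_),              # up
      cbind(NA_integer_, m[, -nx, drop = FALSE]),              # right
      cbind(m[, -1L, drop = FALSE], NA_integer_)               # left
    )
    dm <- rbind(NA_integer_, m[-ny, , drop = FALSE])
    um <- rbind(m[-1L, , drop = FALSE], NA_integer_)
    sh[[5L]] <- cbind(NA_integer_, dm[, -nx, drop = FALSE])
    sh[[6L]] <- cbind(dm[, -1L, drop = FALSE], NA_integer_)
    sh[[7L]] <- cbind(NA_integer_, um[, -nx, drop = FALSE])
    sh[[8L]] <- cbind(um[, -1L, drop = FALSE], NA_integer_)
    best <- m
    for (s in sh) best <- pmin(best, s, na.rm = TRUE)
    best[!mask] <- NA_integer_
    changed <- !identical(best[mask], lab[mask])
    lab[mask] <- best[mask]
    if (!changed) break
  }
  # consecutive labels
  u <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], u)
  lab
}
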