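# File formats: TIFF for stacks and masks, GeoJSON for geometries, CSV for
# result tables. Stacks are stored one z-slice per TIFF page with the channels
# as samples-per-pixel; intensities are kept in their native integer range
# (16-bit on write).

#' Read a multi-channel z-stack from a TIFF file
#'
#' Accepts single- or multi-page 8/16-bit integer or 32-bit float TIFFs with
#' consistent page dimensions. Integer data are returned in their native range
#' (not rescaled to [0, 1]); float data are returned as stored.
#'
#' @param path Path to a TIFF/OME-TIFF file.
#' @param channelRoles Either a character vector with one role per channel
#'   (\code{"marker"}, \code{"construct"}, \code{"cargo"}, \code{"other"}) or
#'   a named vector/list mapping 1-based channel index to role, e.g.
#'   \code{c("1" = "marker")}; unnamed channels default to \code{"other"}.
#' @param zStepUm,pixelSizeUm Voxel spacing in micrometers.
#' @return A \linkS4class{ChannelStack} with dimension order \code{(z, y, x,
#'   channel)}.
#' @export
readStack <- function(path, channelRoles = NULL,
                      zStepUm = 0.3, pixelSizeUm = 0.25) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # integer TIFFs come back scaled to [0, 1]; restore native integer values.
  # Float TIFFs (sample.format "float") are returned as stored.
  pages <- lapply(pages, function(p) {
    fmt <- attr(p, "sample.format") %||% "uint"
    if (identical(fmt, "float")) return(p)
    bits <- attr(p, "bits.per.sample") %||% 16L
    round(p * (2^bits - 1))
  })
  dims <- lapply(pages, function(p) {
    d <- dim(p)
    if (length(d) == 2L) c(d, 1L) else d
  })
  if (length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L)
    stop("inconsistent page shapes in ", path)
  d <- dims[[1L]]
  nz <- length(pages)
  v <- array(0, c(nz, d[1L], d[2L], d[3L]))
  for (z in seq_len(nz)) {
    p <- pages[[z]]
    if (length(dim(p)) == 2L) dim(p) <- c(dim(p), 1L)
    v[z, , , ] <- p
  }
  roles <- .normalizeRoles(channelRoles, d[3L])
  ChannelStack(v, roles, zStepUm = zStepUm, pixelSizeUm = pixelSizeUm)
}

.normalizeRoles <- function(channelRoles, nChannels) {
  if (is.null(channelRoles)) return(rep("other", nChannels))
  channelRoles <- unlist(channelRoles)
  if (!is.null(names(channelRoles)) && any(names(channelRoles) != "")) {
    idx <- as.integer(names(channelRoles))
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > nChannels))
      stop("channel index out of range in role map")
    roles <- rep("other", nChannels)
    roles[idx] <- unname(channelRoles)
    return(roles)
  }
  if (length(channelRoles) != nChannels)
    stop("channel index out of range: role vector has ",
         length(channelRoles), " entries for ", nChannels, " channels")
  unname(channelRoles)
}

#' Write a ChannelStack to a 16-bit TIFF file
#'
#' One page per z-slice with channels stored as samples per pixel. Values are
#' rounded to the nearest integer; integer-valued stacks (such as the
#' simulator's output) therefore round-trip bit-exactly through
#' \code{\link{readStack}}.
#'
#' @param stack A \linkS4class{ChannelStack} with at most 4 channels and all
#'   intensities < 65536.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  v <- stack@voxels
  d <- dim(v)
  if (d[4L] > 4L) stop("writeStack supports at most 4 channels per page")
  if (max(v) > 65535) stop("intensities exceed the 16-bit range")
  v <- round(v)
  pages <- lapply(seq_len(d[1L]), function(z) {
    p <- array(v[z, , , ], d[2:4])
    if (d[4L] == 1L) dim(p) <- d[2:3]
    p / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  invisible(path)
}

#' Write a MaskStack as an 8-bit TIFF (0/255)
#'
#' @param mask A \linkS4class{MaskStack}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  m <- mask@masks
  d <- dim(m)
  pages <- lapply(seq_len(d[1L]), function(z) matrix(m[z, , ], d[2L], d[3L]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "LZW")
  invisible(path)
}

#' Read cell geometry from GeoJSON
#'
#' The file must be a FeatureCollection with one polygon feature named
#' \code{"outline"}, one point feature named \code{"center"}, and optionally
#' further named polygon features which become ROIs. Coordinates are pixel
#' coordinates (0-based, y downward).
#'
#' @param path Path to a GeoJSON file.
#' @return A validated \linkS4class{CellGeometry}.
#' @export
readGeometry <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  outline <- NULL; center <- NULL; rois <- list()
  for (f in gj$features) {
    nm <- f$properties$name
    geom <- f$geometry
    if (identical(geom$type, "Point")) {
      if (identical(nm, "center")) center <- as.numeric(unlist(geom$coordinates))
    } else if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1L]]
      m <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
      # GeoJSON rings repeat the first vertex at the end
      if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      if (identical(nm, "outline")) outline <- m
      else if (!is.null(nm)) rois[[nm]] <- m
    }
  }
  if (is.null(outline)) stop("missing required feature 'outline'")
  if (is.null(center)) stop("missing required feature 'center'")
  CellGeometry(outline, center, rois)
}

.polygonFeature <- function(name, poly) {
  ring <- lapply(seq_len(nrow(poly) + 1L), function(i) {
    j <- if (i > nrow(poly)) 1L else i
    c(poly[j, 1L], poly[j, 2L])
  })
  list(type = "Feature", properties = list(name = name),
       geometry = list(type = "Polygon", coordinates = list(ring)))
}

#' Write cell geometry to GeoJSON
#'
#' @param geometry A \linkS4class{CellGeometry}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGeometry <- function(geometry, path) {
  feats <- list(
    .polygonFeature("outline", geometry@outline),
    list(type = "Feature", properties = list(name = "center"),
         geometry = list(type = "Point",
                         coordinates = as.list(geometry@center))))
  for (nm in names(geometry@rois))
    feats <- c(feats, list(.polygonFeature(nm, geometry@rois[[nm]])))
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a results table to CSV
#'
#' Numeric columns are written with 17 significant digits so that reading the
#' file back reproduces the values exactly.
#'
#' @param results A \code{data.frame} of per-cell records.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(results, path) {
  out <- results
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a results table written by \code{\link{writeResults}}
#'
#' @param path Path to a CSV file.
#' @return \code{data.frame}.
#' @export
readResults <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
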