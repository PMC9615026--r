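# Batch orchestration: config-driven runs over a manifest of per-cell stack +
# geometry files with condition labels; filename blinding; per-cell
# quantification; statistics; CSV tables and a JSON provenance log.

#' Blind a manifest of filenames
#'
#' Assigns opaque codes carrying no condition information to each path, in a
#' random but seed-deterministic order. The returned map is the only way to
#' unblind.
#'
#' @param paths Character vector of unique file paths.
#' @param seed Integer seed.
#' @return \code{data.frame} of class \code{"blindingMap"} with columns
#'   \code{original} and \code{code}.
#' @export
blindFilenames <- function(paths, seed = 1L) {
  if (anyDuplicated(paths)) stop("duplicate paths in manifest")
  n <- length(paths)
  perm <- .withSeed(seed, sample.int(n))
  codes <- sprintf("blind_%04d", perm)
  structure(data.frame(original = paths, code = codes,
                       stringsAsFactors = FALSE),
            class = c("blindingMap", "data.frame"), seed = as.integer(seed))
}

#' Unblind codes using a blinding map
#'
#' @param map A \code{\link{blindFilenames}} result.
#' @param codes Codes to map back.
#' @return Original paths.
#' @export
unblind <- function(map, codes) {
  idx <- match(codes, map$code)
  if (anyNA(idx)) stop("unknown blind code(s)")
  map$original[idx]
}

#' Read and validate a pipeline configuration
#'
#' The configuration is a single JSON or YAML file with fields:
#' \describe{
#'   \item{manifest}{List of per-cell records: \code{stack} (TIFF path),
#'     \code{geometry} (GeoJSON path), \code{condition}, optional
#'     \code{cellId}.}
#'   \item{channels}{Role map, e.g. \code{{"1": "marker", "2": "construct",
#'     "3": "cargo"}}.}
#'   \item{segmentation}{\code{method} and \code{minSizePx}.}
#'   \item{enrichment}{\code{sliceWeighting}, \code{normalization},
#'     optional \code{constructThreshold}.}
#'   \item{nShells}{Shell count for radial analysis.}
#'   \item{stats}{\code{test} (\code{"dunnettT3"}, \code{"welch"} or
#'     \code{"mannwhitney"}), \code{mcReps}, \code{seed}, \code{outlierRule}
#'     (\code{"none"}, \code{"rout"} or \code{"tukey"}), \code{Q}.}
#'   \item{outputDir}{Directory for result tables and provenance.}
#' }
#'
#' @param path Path to a \code{.json} or \code{.yaml}/\code{.yml} file.
#' @return Validated config list of class \code{"pipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  validatePipelineConfig(cfg, baseDir = dirname(path))
}

#' Validate an in-memory pipeline configuration
#'
#' @param cfg Config list (see \code{\link{readPipelineConfig}}).
#' @param baseDir Directory against which relative manifest paths resolve.
#' @return The normalized config, invisibly classed \code{"pipelineConfig"}.
#' @export
validatePipelineConfig <- function(cfg, baseDir = ".") {
  if (is.null(cfg$manifest) || !length(cfg$manifest))
    stop("config must list at least one manifest entry")
  if (is.null(cfg$channels)) stop("config must declare a channel role map")
  for (i in seq_along(cfg$manifest)) {
    e <- cfg$manifest[[i]]
    for (fld in c("stack", "geometry", "condition")) {
      if (is.null(e[[fld]]) || !nzchar(e[[fld]]))
        stop("manifest entry ", i, " is missing '", fld, "'")
    }
    for (fld in c("stack", "geometry")) {
      p <- e[[fld]]
      if (!file.exists(p) && !file.exists(file.path(baseDir, p)))
        stop("manifest entry ", i, ": file not found: ", p)
      if (!file.exists(p)) cfg$manifest[[i]][[fld]] <- file.path(baseDir, p)
    }
    if (is.null(e$cellId)) cfg$manifest[[i]]$cellId <- sprintf("cell_%03d", i)
  }
  roles <- unlist(cfg$channels)
  if (!"marker" %in% roles) stop("channel role map must declare a marker channel")
  bad <- setdiff(roles, .CHANNEL_ROLES)
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  cfg$segmentation <- utils::modifyList(list(method = "otsu", minSizePx = 2L),
                                        cfg$segmentation %||% list())
  cfg$enrichment <- utils::modifyList(
    list(sliceWeighting = "unweighted", normalization = "ratio-of-averages",
         constructThreshold = NULL), cfg$enrichment %||% list())
  cfg$nShells <- cfg$nShells %||% 10L
  cfg$stats <- utils::modifyList(
    list(test = "dunnettT3", mcReps = 100000L, seed = 1L,
         outlierRule = "none", Q = 1), cfg$stats %||% list())
  if (!cfg$stats$test %in% c("dunnettT3", "welch", "mannwhitney"))
    stop("stats$test must be one of dunnettT3, welch, mannwhitney")
  cfg$outputDir <- cfg$outputDir %||% "."
  structure(cfg, class = "pipelineConfig")
}

#' Quantify cargo enrichment for a single cell
#'
#' Segments the marker channel, restricts to construct-positive pixels, and
#' scores the enrichment; the per-cell building block of
#' \code{\link{runColocalization}}.
#'
#' @param stack A \linkS4class{ChannelStack}.
#' @param geometry Optional \linkS4class{CellGeometry}.
#' @param cellId Identifier.
#' @param segMethod,minSizePx Passed to \code{\link{segmentMarker}}.
#' @param constructThreshold Passed to \code{\link{doublePositiveMask}}.
#' @param sliceWeighting,normalization Passed to
#'   \code{\link{peroxisomalEnrichment}}.
#' @return An \linkS4class{EnrichmentResult}, or \code{NULL} (with an
#'   attribute-free warning) when the cell fails the inclusion criterion
#'   (empty double-positive mask).
#' @export
colocalizeCell <- function(stack, geometry = NULL, cellId = "cell",
                           segMethod = "otsu", minSizePx = 2L,
                           constructThreshold = NULL,
                           sliceWeighting = "unweighted",
                           normalization = "ratio-of-averages") {
  seg <- segmentMarker(stack, method = segMethod, minSizePx = minSizePx)
  dp <- doublePositiveMask(seg$mask, stack,
                           constructThreshold = constructThreshold)
  if (!any(dp@masks)) {
    warning("cell ", cellId,
            " excluded: no construct-positive organelle pixels")
    return(NULL)
  }
  region <- cellRegion(stack, geometry)
  peroxisomalEnrichment(stack, seg$mask, dp, region,
                        cellId = cellId, sliceWeighting = sliceWeighting,
                        normalization = normalization)
}

.applyOutlierRule <- function(values, rule, Q) {
  switch(rule,
    none = values,
    rout = routOutliers(values, Q = Q)$kept,
    tukey = {
      s <- tukeyBoxSummary(values)
      values[!values %in% s$outliers]
    },
    stop("unknown outlier rule: ", rule))
}

.runGroupStats <- function(valuesByCondition, statsCfg) {
  labs <- names(valuesByCondition)
  if (statsCfg$outlierRule != "none")
    valuesByCondition <- lapply(valuesByCondition, .applyOutlierRule,
                                rule = statsCfg$outlierRule, Q = statsCfg$Q)
  if (statsCfg$test == "dunnettT3" || length(labs) > 2L) {
    t3 <- dunnettT3(valuesByCondition, mcReps = statsCfg$mcReps,
                    seed = statsCfg$seed)
    return(t3$comparisons)
  }
  res <- if (statsCfg$test == "welch")
    welchTTest(valuesByCondition[[1L]], valuesByCondition[[2L]])
  else mannWhitneyTest(valuesByCondition[[1L]], valuesByCondition[[2L]])
  data.frame(groupA = labs[1L], groupB = labs[2L],
             t = unname(res$statistic), df = unname(res$parameter),
             pRaw = res$p.value, pAdjusted = res$p.value,
             pSidak = res$p.value, stringsAsFactors = FALSE)
}

#' Run the co-localization pipeline over a config
#'
#' Blinds the manifest, quantifies every cell (cells with an empty
#' double-positive mask are excluded and listed with reasons, never silently
#' dropped), writes the per-cell results CSV, a comparisons CSV per the
#' configured test, and a JSON provenance log.
#'
#' @param config A \code{\link{readPipelineConfig}} /
#'   \code{\link{validatePipelineConfig}} result.
#' @return Invisible list: \code{results} (per-cell \code{data.frame}),
#'   \code{comparisons}, \code{excluded}, \code{blinding}, \code{paths}.
#' @export
runColocalization <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(config$manifest, `[[`, character(1L), "stack")
  blinding <- blindFilenames(paths, seed = config$stats$seed)
  rows <- list(); excluded <- list()
  for (i in seq_along(config$manifest)) {
    e <- config$manifest[[i]]
    code <- blinding$code[match(e$stack, blinding$original)]
    res <- tryCatch({
      stack <- readStack(e$stack, channelRoles = config$channels)
      geometry <- readGeometry(e$geometry)
      withCallingHandlers(
        colocalizeCell(stack, geometry, cellId = code,
                       segMethod = config$segmentation$method,
                       minSizePx = config$segmentation$minSizePx,
                       constructThreshold = config$enrichment$constructThreshold,
                       sliceWeighting = config$enrichment$sliceWeighting,
                       normalization = config$enrichment$normalization),
        warning = function(w) invokeRestart("muffleWarning"))
    }, error = function(err) err)
    if (is.null(res) || inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        cellId = e$cellId, condition = e$condition,
        reason = if (is.null(res)) "no construct-positive organelles"
                 else conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    tab <- enrichmentTable(res, condition = e$condition)
    tab$cellId <- e$cellId   # unblind for the output table
    rows[[length(rows) + 1L]] <- tab
  }
  if (!length(rows)) stop("zero included cells")
  results <- do.call(rbind, rows)
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(cellId = character(0), condition = character(0),
               reason = character(0))
  byCond <- split(results$normalizedEnrichment, results$condition)
  comparisons <- if (length(byCond) >= 2L)
    .runGroupStats(byCond, config$stats) else NULL
  outResults <- file.path(config$outputDir, "enrichment_results.csv")
  writeResults(results, outResults)
  outComp <- NULL
  if (!is.null(comparisons)) {
    outComp <- file.path(config$outputDir, "comparisons.csv")
    writeResults(comparisons, outComp)
  }
  prov <- list(pipeline = "colocalization",
               package = as.character(utils::packageVersion("pexquant")),
               channels = config$channels,
               segmentation = config$segmentation,
               enrichment = config$enrichment,
               stats = config$stats,
               nCellsIncluded = nrow(results),
               excluded = excluded,
               blinding = blinding)
  outProv <- file.path(config$outputDir, "provenance.json")
  jsonlite::write_json(prov, outProv, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(results = results, comparisons = comparisons,
                 excluded = excluded, blinding = blinding,
                 paths = c(results = outResults, comparisons = outComp,
                           provenance = outProv)))
}

#' Run the radial-distribution pipeline over a config
#'
#' Segments each cell's marker channel, computes its shape-scaled shell
#' distribution, and writes a wide per-cell CSV (one column per shell) plus
#' a per-condition mean/SD table.
#'
#' @param config A validated \code{"pipelineConfig"}.
#' @return Invisible list: \code{perCell} (wide \code{data.frame}),
#'   \code{aggregated} (per condition), \code{paths}.
#' @export
runRadial <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  perCell <- list(); dists <- list(); conds <- character(0)
  for (e in config$manifest) {
    stack <- readStack(e$stack, channelRoles = config$channels)
    geometry <- readGeometry(e$geometry)
    seg <- segmentMarker(stack, method = config$segmentation$method,
                         minSizePx = config$segmentation$minSizePx)
    shells <- shapeScaledShells(geometry, nShells = config$nShells)
    d <- withCallingHandlers(radialDistribution(seg$objects, shells),
                             warning = function(w) invokeRestart("muffleWarning"))
    row <- data.frame(cellId = e$cellId, condition = e$condition,
                      stringsAsFactors = FALSE)
    freq <- as.list(d@frequencies)
    names(freq) <- sprintf("shell%02d", seq_along(freq))
    perCell[[length(perCell) + 1L]] <- cbind(row, as.data.frame(freq))
    dists[[length(dists) + 1L]] <- d
    conds <- c(conds, e$condition)
  }
  perCell <- do.call(rbind, perCell)
  agg <- do.call(rbind, lapply(unique(conds), function(cc) {
    a <- aggregateDistributions(dists[conds == cc])
    a$condition <- cc
    a
  }))
  outCell <- file.path(config$outputDir, "radial_per_cell.csv")
  outAgg <- file.path(config$outputDir, "radial_aggregated.csv")
  writeResults(perCell, outCell)
  writeResults(agg, outAgg)
  invisible(list(perCell = perCell, aggregated = agg,
                 paths = c(perCell = outCell, aggregated = outAgg)))
}

#' Run ROI counting over a config (neuron mode)
#'
#' @param config A validated \code{"pipelineConfig"}; geometries must carry
#'   \code{soma} and \code{growth_cone} ROIs.
#' @return Invisible list: \code{counts} (\code{data.frame} with per-ROI
#'   counts and the growth-cone/soma ratio), \code{paths}.
#' @export
runCounts <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (e in config$manifest) {
    stack <- readStack(e$stack, channelRoles = config$channels)
    geometry <- readGeometry(e$geometry)
    seg <- segmentMarker(stack, method = config$segmentation$method,
                         minSizePx = config$segmentation$minSizePx)
    rc <- suppressWarnings(roiObjectCounts(seg$objects, geometry,
                                           cellId = e$cellId))
    rows[[length(rows) + 1L]] <- data.frame(
      cellId = e$cellId, condition = e$condition,
      soma = rc$counts[["soma"]], growthCone = rc$counts[["growth_cone"]],
      gcSomaRatio = rc$gcSomaRatio, stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  out <- file.path(config$outputDir, "roi_counts.csv")
  writeResults(counts, out)
  invisible(list(counts = counts, paths = c(counts = out)))
}
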