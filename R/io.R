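# File formats: Esri ASCII grid (+ JSON legend sidecar) and fix CSV.

#' Write a landscape as an Esri ASCII grid
#'
#' Writes the standard `.asc` header (ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value -9999) followed by rows from the top (northern)
#' row, and the legend/level as a JSON sidecar `<file>.legend.json`.
#'
#' @param landscape a \linkS4class{GridLandscape}
#' @param path output path (conventionally ending in `.asc`)
#' @return `path`, invisibly
#' @export
writeAsciiGrid <- function(landscape, path) {
  stopifnot(is(landscape, "GridLandscape"))
  g <- classGrid(landscape)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(g)),
    paste("nrows", nrow(g)),
    paste("xllcorner", gridOrigin(landscape)[1]),
    paste("yllcorner", gridOrigin(landscape)[2]),
    paste("cellsize", cellSize(landscape)),
    "NODATA_value -9999"), con)
  # row 1 of the matrix is the southernmost: write from the top
  for (i in rev(seq_len(nrow(g))))
    writeLines(paste(g[i, ], collapse = " "), con)
  jsonlite::write_json(
    list(level = landscapeLevel(landscape),
         legend = as.list(habitatLegend(landscape))),
    paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a landscape from an Esri ASCII grid
#'
#' @param path path to an `.asc` file written by \code{\link{writeAsciiGrid}}
#'   (or any Esri ASCII grid; without a legend sidecar the landscape is read
#'   as functional if its codes are within 0..3)
#' @return a \linkS4class{GridLandscape}
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)],
                 function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  g <- do.call(rbind, vals)
  stopifnot(nrow(g) == hdr$nrows, ncol(g) == hdr$ncols)
  g <- g[rev(seq_len(nrow(g))), , drop = FALSE]  # back to south-first rows
  sidecar <- paste0(path, ".legend.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    legend <- vapply(meta$legend, as.character, character(1))
    GridLandscape(g, cellSize = hdr$cellsize,
                  origin = c(hdr$xllcorner, hdr$yllcorner),
                  legend = legend, level = meta$level)
  } else {
    GridLandscape(g, cellSize = hdr$cellsize,
                  origin = c(hdr$xllcorner, hdr$yllcorner))
  }
}

#' Write a distance surface as an Esri ASCII grid
#' @param dgrid a \linkS4class{DistanceGrid}
#' @param path output path
#' @return `path`, invisibly
#' @export
writeDistanceGrid <- function(dgrid, path) {
  v <- distanceValues(dgrid)
  v[!is.finite(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", gridOrigin(dgrid)[1]),
    paste("yllcorner", gridOrigin(dgrid)[2]),
    paste("cellsize", cellSize(dgrid)),
    "NODATA_value -9999"), con)
  for (i in rev(seq_len(nrow(v))))
    writeLines(paste(format(v[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' Write fixes as CSV
#' @param fixset a \linkS4class{FixSet}
#' @param path output path
#' @return `path`, invisibly
#' @export
writeFixSet <- function(fixset, path) {
  write.csv(fixes(fixset), path, row.names = FALSE)
  invisible(path)
}

#' Read fixes from CSV
#' @param path CSV with columns `individual_id, x_m, y_m, phase, behavior,
#'   true_x_m, true_y_m`
#' @return a \linkS4class{FixSet}
#' @export
readFixSet <- function(path) FixSet(read.csv(path))
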