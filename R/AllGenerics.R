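# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for landcomp classes
#' @description Small accessor generics so user code never touches slots.
#' @param x an object
#' @return the requested component
NULL

#' @rdname accessors
#' @export
setGeneric("classGrid", function(x) standardGeneric("classGrid"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("habitatLegend", function(x) standardGeneric("habitatLegend"))
#' @rdname accessors
#' @export
setGeneric("landscapeLevel", function(x) standardGeneric("landscapeLevel"))
#' @rdname accessors
#' @export
setGeneric("areaHa", function(x) standardGeneric("areaHa"))
#' @rdname accessors
#' @export
setGeneric("fixes", function(x) standardGeneric("fixes"))
#' @rdname accessors
#' @export
setGeneric("udDensity", function(x) standardGeneric("udDensity"))
#' @rdname accessors
#' @export
setGeneric("hrMask", function(x) standardGeneric("hrMask"))
#' @rdname accessors
#' @export
setGeneric("selectionCalls", function(x) standardGeneric("selectionCalls"))
#' @rdname accessors
#' @export
setGeneric("assignmentMapping", function(x) standardGeneric("assignmentMapping"))
#' @rdname accessors
#' @export
setGeneric("nestPoints", function(x) standardGeneric("nestPoints"))
#' @rdname accessors
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))

#' @rdname accessors
setMethod("classGrid", "GridLandscape", function(x) x@classGrid)
#' @rdname accessors
setMethod("cellSize", "GridLandscape", function(x) x@cellSize)
#' @rdname accessors
setMethod("cellSize", "UtilizationDistribution", function(x) x@cellSize)
#' @rdname accessors
setMethod("cellSize", "HomeRange", function(x) x@cellSize)
#' @rdname accessors
setMethod("cellSize", "DistanceGrid", function(x) x@cellSize)
#' @rdname accessors
setMethod("gridOrigin", "GridLandscape", function(x) x@origin)
#' @rdname accessors
setMethod("gridOrigin", "UtilizationDistribution", function(x) x@origin)
#' @rdname accessors
setMethod("gridOrigin", "HomeRange", function(x) x@origin)
#' @rdname accessors
setMethod("gridOrigin", "DistanceGrid", function(x) x@origin)
#' @rdname accessors
setMethod("habitatLegend", "GridLandscape", function(x) x@legend)
#' @rdname accessors
setMethod("landscapeLevel", "GridLandscape", function(x) x@level)
#' @rdname accessors
setMethod("areaHa", "GridLandscape",
          function(x) length(x@classGrid) * x@cellSize^2 / 1e4)
#' @rdname accessors
setMethod("areaHa", "HomeRange", function(x) x@areaHa)
#' @rdname accessors
setMethod("fixes", "FixSet", function(x) x@fixes)
#' @rdname accessors
setMethod("udDensity", "UtilizationDistribution", function(x) x@density)
#' @rdname accessors
setMethod("hrMask", "HomeRange", function(x) x@mask)
#' @rdname accessors
setMethod("selectionCalls", "SelectionTable",
          function(x) setNames(x@table$call, x@table$cover_type))
#' @rdname accessors
setMethod("assignmentMapping", "FunctionalAssignment", function(x) x@mapping)
#' @rdname accessors
setMethod("nestPoints", "NestSet", function(x) x@points)
#' @rdname accessors
setMethod("distanceValues", "DistanceGrid", function(x) x@values)

setMethod("show", "GridLandscape", function(object) {
  d <- dim(object@classGrid)
  cat(sprintf("GridLandscape (%s): %d x %d cells of %g m (%.1f ha)\n",
              object@level, d[1], d[2], object@cellSize, areaHa(object)))
  tab <- table(factor(as.vector(object@classGrid),
                      levels = names(object@legend)))
  frac <- round(100 * tab / sum(tab), 1)
  for (k in names(object@legend))
    cat(sprintf("  %-18s (%s): %5.1f%%\n", object@legend[[k]], k, frac[[k]]))
})

setMethod("show", "FixSet", function(object) {
  f <- object@fixes
  cat(sprintf("FixSet: %d fixes, %d individual(s)\n",
              nrow(f), length(unique(f$individual_id))))
  if (nrow(f)) print(table(f$individual_id, f$behavior))
})

setMethod("show", "UtilizationDistribution", function(object) {
  d <- dim(object@density)
  cat(sprintf(
    "UtilizationDistribution: %d x %d grid at %g m, h = %g m, %d fixes\n",
    d[1], d[2], object@cellSize, object@h, object@nFixes))
})

setMethod("show", "HomeRange", function(object) {
  cat(sprintf("HomeRange: %.0f%% isopleth, %.1f ha\n",
              100 * object@isopleth, object@areaHa))
})

setMethod("show", "SelectionTable", function(object) {
  cat(sprintf("SelectionTable (%s, individual %s): chi^2 = %.3f, df = %d, p = %.4g\n",
              object@behavior, object@individual, object@chiSquare,
              object@df, object@pValue))
  print(object@table, digits = 3, row.names = FALSE)
})

setMethod("show", "FunctionalAssignment", function(object) {
  cat("FunctionalAssignment:\n")
  cls <- FUNCTIONAL_LEGEND[as.character(object@mapping)]
  for (k in names(object@mapping))
    cat(sprintf("  typology %s -> %s\n", k, cls[[match(k, names(object@mapping))]]))
})

setMethod("show", "MoranResult", function(object) {
  cat(sprintf(
    "Global Moran's I = %.4f (E = %.4f), Z = %.3f, p = %.4g, n = %d\n  [%s]\n",
    object@I, object@expectedI, object@zScore, object@pValue, object@nUnits,
    object@weightsSpec))
})

setMethod("show", "NestSet", function(object) {
  cat(sprintf("NestSet: %d nests, minimum spacing %g m (seed %d)\n",
              nrow(object@points), object@minDist, object@seed))
})

setMethod("show", "DistanceGrid", function(object) {
  v <- object@values[is.finite(object@values)]
  cat(sprintf("DistanceGrid: %d x %d at %g m; range %.1f-%.1f m\n",
              nrow(object@values), ncol(object@values), object@cellSize,
              min(v), max(v)))
})

setMethod("show", "LandscapeSpec", function(object) {
  cat(sprintf("LandscapeSpec: %d x %d cells of %g m, %s\n",
              object@dims[1], object@dims[2], object@cellSize, object@config))
  cat("  composition:",
      paste(sprintf("%s %.3f", names(object@composition), object@composition),
            collapse = ", "), "\n")
})

setMethod("show", "ExperimentConfig", function(object) {
  cat("ExperimentConfig\n  natural: "); show(object@natural)
  cat("  managed: "); show(object@managed)
  cat(sprintf("  %s individuals, %d fixes each; %d nests (>= %g m apart)\n",
              paste(object@nIndividuals, collapse = "+"),
              object@fixesPerIndividual, object@nNests, object@minDistM))
  cat(sprintf("  h = %g m, isopleth %.2f, B = %d, blocks %g m, seed %d\n",
              object@hM, object@isopleth, object@bootstrapB,
              object@blockSizeM, object@seed))
})
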