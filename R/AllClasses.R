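# S4 containers for the spatial objects of the analysis.
#
# Grid convention, stated once and used everywhere: coordinates are metres,
# the origin is the lower-left corner of the grid, y increases northward.
# Matrices are indexed [row, col] with row 1 the southernmost row, so the
# centre of cell [i, j] is origin + ((j - 0.5), (i - 0.5)) * cellSize.

FUNCTIONAL_LEGEND <- c(`0` = "non-usable", `1` = "breeding",
                       `2` = "roosting", `3` = "foraging")

#' GridLandscape: a categorical landscape raster
#'
#' Holds a rectangular grid of integer cover-class codes at either the
#' \emph{functional} level (codes 0 = non-usable, 1 = breeding, 2 = roosting,
#' 3 = foraging) or the \emph{structural} level (cover typologies, arbitrary
#' positive codes named in the legend).
#'
#' @slot classGrid integer matrix of class codes (row 1 = southernmost row)
#' @slot cellSize cell edge length in metres
#' @slot origin x, y of the grid's lower-left corner (metres)
#' @slot legend named character vector mapping code (as name) to class name
#' @slot level `"functional"` or `"structural"`
#' @exportClass GridLandscape
setClass("GridLandscape",
  representation(classGrid = "matrix", cellSize = "numeric",
                 origin = "numeric", legend = "character", level = "character"))

setValidity("GridLandscape", function(object) {
  msgs <- character()
  g <- object@classGrid
  if (!is.numeric(g) && !is.integer(g)) msgs <- c(msgs, "classGrid must be numeric")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(object@origin) != 2L) msgs <- c(msgs, "origin must be length 2")
  if (!object@level %in% c("functional", "structural"))
    msgs <- c(msgs, "level must be 'functional' or 'structural'")
  codes <- unique(as.vector(g))
  if (!all(as.character(codes) %in% names(object@legend)))
    msgs <- c(msgs, "every code in classGrid must be present in the legend")
  if (object@level == "functional" &&
      !identical(object@legend[as.character(0:3)], FUNCTIONAL_LEGEND))
    msgs <- c(msgs, "functional legend must be exactly {0: non-usable, 1: breeding, 2: roosting, 3: foraging}")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GridLandscape
#'
#' @param classGrid integer matrix of class codes
#' @param cellSize cell edge length in metres
#' @param origin lower-left corner coordinates in metres
#' @param legend named character vector (names = codes); defaults to the
#'   functional legend when `level = "functional"`
#' @param level `"functional"` or `"structural"`
#' @return a \linkS4class{GridLandscape}
#' @examples
#' g <- GridLandscape(matrix(0L, 4, 4), cellSize = 10)
#' areaHa(g)
#' @export
GridLandscape <- function(classGrid, cellSize = 10, origin = c(0, 0),
                          legend = NULL, level = "functional") {
  storage.mode(classGrid) <- "integer"
  if (is.null(legend)) {
    if (level != "functional")
      stop("a legend is required for structural landscapes")
    legend <- FUNCTIONAL_LEGEND
  }
  new("GridLandscape", classGrid = classGrid, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin), legend = legend, level = level)
}

#' LandscapeSpec: recipe for a synthetic functional landscape
#'
#' @slot dims rows, cols of the grid
#' @slot cellSize cell edge length in metres
#' @slot composition named target areal fractions over the four functional
#'   classes; must sum to 1
#' @slot config `"clumped"` (few contiguous blobs per class) or
#'   `"interspersed"` (regular parcel mosaic)
#' @slot patchScale named characteristic patch diameters in metres (clumped:
#'   blob scale per class; interspersed: the single parcel pitch is
#'   `min(patchScale)`)
#' @slot clusterParcels interspersed only: parcels per roosting block
#' @slot roadDepthCells interspersed only: road strip width in cells
#' @slot roadShare interspersed only: share of the foraging budget laid down
#'   as road strips along block rims (the rest becomes crop-block parcels)
#' @slot seed integer seed
#' @exportClass LandscapeSpec
setClass("LandscapeSpec",
  representation(dims = "integer", cellSize = "numeric",
                 composition = "numeric", config = "character",
                 patchScale = "numeric", clusterParcels = "integer",
                 roadDepthCells = "integer", roadShare = "numeric",
                 seed = "integer"))

setValidity("LandscapeSpec", function(object) {
  msgs <- character()
  if (length(object@dims) != 2L || any(object@dims < 1L))
    msgs <- c(msgs, "dims must be two positive integers")
  comp <- object@composition
  if (is.null(names(comp)) || !all(names(comp) %in% FUNCTIONAL_LEGEND))
    msgs <- c(msgs, "composition names must be functional class names")
  if (any(comp < 0) || any(comp > 1)) msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (abs(sum(comp) - 1) > 1e-9) msgs <- c(msgs, "composition must sum to 1")
  if (!object@config %in% c("clumped", "interspersed"))
    msgs <- c(msgs, "config must be 'clumped' or 'interspersed'")
  if (any(object@patchScale < object@cellSize))
    msgs <- c(msgs, "patchScale must be >= cellSize")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LandscapeSpec
#'
#' @param dims grid dimensions (rows, cols)
#' @param cellSize cell size in metres (default 10)
#' @param composition named fractions over
#'   `c("non-usable", "breeding", "roosting", "foraging")`, summing to 1
#' @param config `"clumped"` or `"interspersed"`
#' @param patchScale characteristic patch diameter(s) in metres; a scalar or a
#'   vector named by class
#' @param clusterParcels parcels per roosting block (interspersed)
#' @param roadDepthCells road strip depth in cells (interspersed)
#' @param roadShare share of foraging area laid as road strips (interspersed)
#' @param seed integer seed
#' @return a \linkS4class{LandscapeSpec}
#' @export
LandscapeSpec <- function(dims, composition, config,
                          cellSize = 10, patchScale = 1000,
                          clusterParcels = 14L, roadDepthCells = 1L,
                          roadShare = 0.15, seed = 1L) {
  new("LandscapeSpec", dims = as.integer(dims), cellSize = as.numeric(cellSize),
      composition = composition, config = config,
      patchScale = as.numeric(patchScale),
      clusterParcels = as.integer(clusterParcels),
      roadDepthCells = as.integer(roadDepthCells),
      roadShare = as.numeric(roadShare), seed = as.integer(seed))
}

#' FixSet: radio-telemetry fixes
#'
#' One row per fix: reported coordinates (with positional error), phase,
#' behaviour, and for synthetic data the error-free ground-truth coordinates.
#'
#' @slot fixes data.frame with columns `individual_id`, `x_m`, `y_m`,
#'   `phase` (day/night), `behavior` (nest/roost/forage/unknown),
#'   `true_x_m`, `true_y_m` (NA for field data)
#' @exportClass FixSet
setClass("FixSet", representation(fixes = "data.frame"))

setValidity("FixSet", function(object) {
  f <- object@fixes
  need <- c("individual_id", "x_m", "y_m", "phase", "behavior",
            "true_x_m", "true_y_m")
  msgs <- character()
  if (!all(need %in% names(f)))
    msgs <- c(msgs, paste("fixes must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(f) && !all(is.finite(f$x_m) & is.finite(f$y_m)))
      msgs <- c(msgs, "reported coordinates must be finite")
    if (nrow(f) && !all(f$phase %in% c("day", "night")))
      msgs <- c(msgs, "phase must be 'day' or 'night'")
    if (nrow(f) && !all(f$behavior %in% c("nest", "roost", "forage", "unknown")))
      msgs <- c(msgs, "behavior must be nest/roost/forage/unknown")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a FixSet
#' @param fixes data.frame of fixes (see \linkS4class{FixSet})
#' @return a \linkS4class{FixSet}
#' @export
FixSet <- function(fixes) {
  fixes <- as.data.frame(fixes)
  rownames(fixes) <- NULL
  new("FixSet", fixes = fixes)
}

#' UtilizationDistribution: a kernel density surface
#'
#' The equal-weight mixture of isotropic bivariate normal kernels (per-axis
#' standard deviation `h`) centred on an individual's fixes, evaluated on a
#' regular grid. Densities are in m^-2 and integrate to 1 over the padded grid.
#'
#' @slot density numeric matrix of densities (m^-2), row 1 southernmost
#' @slot cellSize grid resolution in metres
#' @slot origin lower-left corner of the grid
#' @slot h smoothing bandwidth in metres
#' @slot nFixes number of fixes used
#' @exportClass UtilizationDistribution
setClass("UtilizationDistribution",
  representation(density = "matrix", cellSize = "numeric", origin = "numeric",
                 h = "numeric", nFixes = "integer"))

setValidity("UtilizationDistribution", function(object) {
  msgs <- character()
  if (any(object@density < 0)) msgs <- c(msgs, "density must be non-negative")
  mass <- sum(object@density) * object@cellSize^2
  if (abs(mass - 1) > 1e-3)
    msgs <- c(msgs, sprintf("density must integrate to 1 (got %.6f)", mass))
  if (length(msgs)) msgs else TRUE
})

#' HomeRange: a volume-contour home range
#'
#' The smallest set of highest-density cells of a utilization distribution
#' whose enclosed probability mass reaches the isopleth level.
#'
#' @slot mask logical matrix (same geometry as the source UD)
#' @slot cellSize grid resolution in metres
#' @slot origin lower-left corner
#' @slot isopleth contour level in (0, 1)
#' @slot areaHa home-range area in hectares
#' @exportClass HomeRange
setClass("HomeRange",
  representation(mask = "matrix", cellSize = "numeric", origin = "numeric",
                 isopleth = "numeric", areaHa = "numeric"))

#' SelectionTable: habitat selection against availability
#'
#' Per cover type: used counts and proportions, availability, simultaneous
#' Agresti-Coull confidence limits for the used proportion, and the
#' selected / avoided / neutral call; plus the overall goodness-of-fit
#' chi-square against random habitat use.
#'
#' @slot table data.frame with columns `cover_type`, `used_count`,
#'   `used_prop`, `avail_prop`, `ci_low`, `ci_high`, `call`
#' @slot chiSquare Pearson statistic
#' @slot df degrees of freedom (types with availability > 0, minus 1)
#' @slot pValue upper-tail chi-square p
#' @slot behavior `"nesting"`, `"roosting"` or `"foraging"`
#' @slot individual individual identifier
#' @slot conf family confidence level before Bonferroni adjustment
#' @exportClass SelectionTable
setClass("SelectionTable",
  representation(table = "data.frame", chiSquare = "numeric", df = "integer",
                 pValue = "numeric", behavior = "character",
                 individual = "character", conf = "numeric"))

#' FunctionalAssignment: typology-to-functional-class mapping
#'
#' @slot mapping named integer vector: structural typology code (name) to
#'   functional class code; typologies without detected selection map to 0
#' @slot votes data.frame of per-typology, per-behaviour vote counts
#' @exportClass FunctionalAssignment
setClass("FunctionalAssignment",
  representation(mapping = "integer", votes = "data.frame"))

#' MoranResult: global Moran's I with analytical inference
#'
#' @slot I observed Moran's I
#' @slot expectedI -1/(n - 1)
#' @slot varianceI variance under the selected null
#' @slot zScore (I - E[I]) / sqrt(Var)
#' @slot pValue two-sided normal p
#' @slot nUnits number of spatial units
#' @slot weightsSpec description of the weight scheme and null
#' @exportClass MoranResult
setClass("MoranResult",
  representation(I = "numeric", expectedI = "numeric", varianceI = "numeric",
                 zScore = "numeric", pValue = "numeric", nUnits = "integer",
                 weightsSpec = "character"))

setValidity("MoranResult", function(object) {
  msgs <- character()
  if (abs(object@expectedI - (-1 / (object@nUnits - 1))) > 1e-12)
    msgs <- c(msgs, "expectedI must equal -1/(n - 1)")
  if (object@pValue <= 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' NestSet: simulated nest locations
#'
#' @slot points matrix of nest coordinates (x_m, y_m)
#' @slot nRequested number of nests requested
#' @slot minDist minimum pairwise spacing in metres
#' @slot seed seed used for placement
#' @exportClass NestSet
setClass("NestSet",
  representation(points = "matrix", nRequested = "integer",
                 minDist = "numeric", seed = "integer"))

setValidity("NestSet", function(object) {
  msgs <- character()
  if (nrow(object@points) != object@nRequested)
    msgs <- c(msgs, "number of points must equal nRequested")
  if (nrow(object@points) > 1L) {
    d <- stats::dist(object@points)
    if (min(d) < object@minDist - 1e-9)
      msgs <- c(msgs, "pairwise nest distances must all be >= minDist")
  }
  if (length(msgs)) msgs else TRUE
})

#' DistanceGrid: a distance surface over the landscape grid
#'
#' @slot values numeric matrix of distances in metres (Inf = unreachable)
#' @slot cellSize cell size in metres
#' @slot origin lower-left corner
#' @exportClass DistanceGrid
setClass("DistanceGrid",
  representation(values = "matrix", cellSize = "numeric", origin = "numeric"))

#' ExperimentConfig: full two-landscape experiment settings
#'
#' @slot natural \linkS4class{LandscapeSpec} for the clumped plot
#' @slot managed \linkS4class{LandscapeSpec} for the interspersed plot
#' @slot nIndividuals named integer: tracked individuals per plot
#' @slot fixesPerIndividual fixes simulated per individual
#' @slot nNests simulated nests per plot
#' @slot minDistM minimum nest spacing (m)
#' @slot hM kernel smoothing bandwidth (m)
#' @slot isopleth home-range contour level
#' @slot bootstrapB bootstrap replicates for correlations
#' @slot blockSizeM aggregation block size for Moran's I (m)
#' @slot abundanceWeeks paired weekly transect counts to simulate
#' @slot abundanceRates named mean rates (birds/km) for natural and managed
#' @slot seed root seed
#' @exportClass ExperimentConfig
setClass("ExperimentConfig",
  representation(natural = "LandscapeSpec", managed = "LandscapeSpec",
                 nIndividuals = "integer", fixesPerIndividual = "integer",
                 nNests = "integer", minDistM = "numeric", hM = "numeric",
                 isopleth = "numeric", bootstrapB = "integer",
                 blockSizeM = "numeric", abundanceWeeks = "integer",
                 abundanceRates = "numeric", seed = "integer"))
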