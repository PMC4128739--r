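# Nest placement and nest-to-nearest-habitat movement needs.

#' Simulate nest locations with a minimum-spacing constraint
#'
#' Places points uniformly at random within breeding-class cells and accepts
#' them by rejection against the minimum pairwise distance (territorial
#' spacing of nesting birds). If a pass exhausts its attempt budget the
#' placement restarts from scratch; after three failed passes the function
#' fails, reporting how many nests it could place.
#'
#' @param functional a functional-level \linkS4class{GridLandscape}
#' @param n number of nests (default 60)
#' @param min_dist_m minimum pairwise nest distance in metres (default 50)
#' @param seed integer seed
#' @param max_attempts candidate draws per pass (default 10000)
#' @return a \linkS4class{NestSet}
#' @export
simulateNests <- function(functional, n = 60, min_dist_m = 50, seed = 1L,
                          max_attempts = 10000L) {
  stopifnot(is(functional, "GridLandscape"))
  g <- classGrid(functional)
  breeding <- which(g == CLASS_CODES[["breeding"]])
  if (!length(breeding)) stop("landscape has no cells of class 'breeding'")
  nr <- nrow(g)
  cellsz <- cellSize(functional); orig <- gridOrigin(functional)
  withSeed(seed, {
    placed <- NULL
    for (pass in 1:3) {
      pts <- matrix(numeric(0), 0, 2)
      attempts <- 0L
      while (nrow(pts) < n && attempts < max_attempts) {
        attempts <- attempts + 1L
        k <- breeding[sample.int(length(breeding), 1L)]
        xy <- cellCenters(k, nr, cellsz, orig) + (runif(2) - 0.5) * cellsz
        if (nrow(pts) == 0L ||
            min((pts[, 1] - xy[1])^2 + (pts[, 2] - xy[2])^2) >= min_dist_m^2)
          pts <- rbind(pts, xy)
      }
      placed <- pts
      if (nrow(pts) == n) break
    }
    if (nrow(placed) < n)
      stop("could only place ", nrow(placed), " of ", n,
           " nests at spacing >= ", min_dist_m, " m")
    dimnames(placed) <- list(NULL, c("x_m", "y_m"))
    new("NestSet", points = placed, nRequested = as.integer(n),
        minDist = as.numeric(min_dist_m), seed = as.integer(seed))
  })
}

#' Distance to the nearest cell of a habitat class
#'
#' Exact Euclidean distance transform: each cell's value is the distance from
#' its centre to the centre of the nearest cell of the target class (zero on
#' target cells). Under the study's assumption of straight minimum-length
#' flights between habitats, this is the movement distance surface.
#'
#' @param functional a functional-level \linkS4class{GridLandscape}
#' @param target_class class name (`"breeding"`, `"roosting"`, `"foraging"`)
#'   or code
#' @return a \linkS4class{DistanceGrid} in metres
#' @export
nearestHabitatDistance <- function(functional, target_class) {
  stopifnot(is(functional, "GridLandscape"))
  code <- if (is.character(target_class)) CLASS_CODES[[target_class]]
          else as.integer(target_class)
  g <- classGrid(functional)
  if (!any(g == code))
    stop("landscape has no cells of target class '", target_class, "'")
  ind <- matrix(1, nrow(g), ncol(g))
  ind[g == code] <- 0
  d <- EBImage::distmap(ind, metric = "euclidean")
  new("DistanceGrid", values = as.matrix(d) * cellSize(functional),
      cellSize = cellSize(functional), origin = gridOrigin(functional))
}

#' Daily movement needs of simulated nests
#'
#' For each nest, the distance to the nearest roosting habitat, the distance
#' to the nearest foraging habitat, and their sum: the minimum daily travel a
#' breeding pair must cover to link nest, roost and foraging site.
#'
#' @param nests a \linkS4class{NestSet}
#' @param d_roost \linkS4class{DistanceGrid} to roosting habitat
#' @param d_forage \linkS4class{DistanceGrid} to foraging habitat
#' @param group landscape label stored alongside (e.g. `"natural"`)
#' @return data.frame with columns `nest_id`, `x_m`, `y_m`, `d_roost_m`,
#'   `d_forage_m`, `d_total_m`, `group`
#' @export
movementNeeds <- function(nests, d_roost, d_forage, group = "landscape") {
  stopifnot(is(nests, "NestSet"), is(d_roost, "DistanceGrid"),
            is(d_forage, "DistanceGrid"))
  if (!isTRUE(all.equal(dim(distanceValues(d_roost)),
                        dim(distanceValues(d_forage)))) ||
      cellSize(d_roost) != cellSize(d_forage) ||
      !isTRUE(all.equal(gridOrigin(d_roost), gridOrigin(d_forage))))
    stop("distance grids must share geometry")
  pts <- nestPoints(nests)
  v <- distanceValues(d_roost)
  idx <- cellAt(pts, nrow(v), ncol(v), cellSize(d_roost), gridOrigin(d_roost))
  if (anyNA(idx)) stop("nest outside the distance-grid extent")
  dr <- distanceValues(d_roost)[idx]
  df <- distanceValues(d_forage)[idx]
  data.frame(nest_id = seq_len(nrow(pts)), x_m = pts[, 1], y_m = pts[, 2],
             d_roost_m = dr, d_forage_m = df, d_total_m = dr + df,
             group = group)
}

#' Summarize movement needs per landscape
#'
#' Mean and standard error of nest-to-roost, nest-to-forage and summed
#' distances, per group.
#'
#' @param needs data.frame from \code{\link{movementNeeds}} (possibly several
#'   groups row-bound)
#' @return data.frame with one row per group
#' @export
summarizeMovementNeeds <- function(needs) {
  out <- do.call(rbind, lapply(split(needs, needs$group), function(d) {
    se <- function(x) sd(x) / sqrt(length(x))
    data.frame(group = d$group[1], n = nrow(d),
               mean_d_roost_m = mean(d$d_roost_m), se_d_roost_m = se(d$d_roost_m),
               mean_d_forage_m = mean(d$d_forage_m), se_d_forage_m = se(d$d_forage_m),
               mean_d_total_m = mean(d$d_total_m), se_d_total_m = se(d$d_total_m))
  }))
  row.names(out) <- NULL
  out
}

#' Least-cost distance over a cost surface
#'
#' Shortest-path (geodesic) distance from a set of source points over the
#' landscape grid, moving between 8-connected cells; a step costs its length
#' (cell size orthogonally, cell size times sqrt(2) diagonally) weighted by
#' the mean unit cost of the two cells. Infinite-cost classes are barriers;
#' unreachable cells keep distance Inf. With uniform unit cost this reduces
#' to the grid-constrained Euclidean distance (within the 8-connectivity
#' metric bound of ~8.24\%).
#'
#' @param functional a functional-level \linkS4class{GridLandscape}
#' @param cost named numeric vector of per-class unit costs (> 0 or Inf),
#'   named by class name or code
#' @param sources two-column matrix of source coordinates (metres)
#' @return a \linkS4class{DistanceGrid} of geodesic distances in metres
#' @export
costDistance <- function(functional, cost, sources) {
  stopifnot(is(functional, "GridLandscape"))
  g <- classGrid(functional)
  nr <- nrow(g); nc <- ncol(g); n <- nr * nc
  cellsz <- cellSize(functional); orig <- gridOrigin(functional)
  nm <- names(cost)
  if (!is.null(nm) && any(nm %in% names(CLASS_CODES)))
    names(cost) <- as.character(CLASS_CODES[nm])
  cc <- cost[as.character(as.vector(g))]
  if (anyNA(cc)) stop("cost must be given for every class present")
  if (any(cc <= 0, na.rm = TRUE)) stop("costs must be positive (or Inf)")
  sources <- matrix(sources, ncol = 2)
  src <- cellAt(sources, nr, nc, cellsz, orig)
  if (anyNA(src)) stop("source point outside the landscape")

  open <- which(is.finite(cc))
  vid <- integer(n); vid[open] <- seq_along(open)  # grid index -> vertex id
  edges <- list(); wts <- list()
  addEdges <- function(from, to, step) {
    ok <- vid[from] > 0L & vid[to] > 0L
    from <- from[ok]; to <- to[ok]
    w <- step * (cc[from] + cc[to]) / 2
    edges[[length(edges) + 1L]] <<- rbind(vid[from], vid[to])
    wts[[length(wts) + 1L]] <<- w
  }
  idx <- seq_len(n)
  r <- cellRow(idx, nr); cl <- cellCol(idx, nr)
  up <- idx[r < nr]
  addEdges(up, up + 1L, cellsz)
  right <- idx[cl < nc]
  addEdges(right, right + nr, cellsz)
  dur <- idx[r < nr & cl < nc]
  addEdges(dur, dur + nr + 1L, cellsz * sqrt(2))
  ddr <- idx[r > 1L & cl < nc]
  addEdges(ddr, ddr + nr - 1L, cellsz * sqrt(2))
  gr <- igraph::make_graph(as.vector(do.call(cbind, edges)),
                           n = length(open), directed = FALSE)
  src_v <- vid[src]
  if (any(src_v == 0L)) stop("source point lies on a barrier cell")
  dmat <- igraph::distances(gr, v = unique(src_v),
                            weights = unlist(wts), algorithm = "dijkstra")
  dmin <- if (nrow(dmat) > 1L) apply(dmat, 2, min) else as.numeric(dmat)
  out <- matrix(Inf, nr, nc)
  out[open] <- dmin
  new("DistanceGrid", values = out, cellSize = cellsz, origin = orig)
}
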