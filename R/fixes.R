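# Synthetic radio-telemetry: behaviour-dependent fixes with positional error.

#' Simulate radio-telemetry fixes for one individual
#'
#' Emulates a breeding bird tracked over a season. The individual gets one
#' nest point inside a breeding cell; day-phase fixes split between the nest
#' (incubation) and a small set of day roosts inside roosting cells near the
#' nest; night-phase foraging fixes fall on foraging cells, with a fixed
#' share on the road typology (road-sitting birds). Reported coordinates are
#' the true coordinates plus isotropic Gaussian error: per-axis standard
#' deviation `accuracy_sd_m` for triangulated fixes, and `road_gps_sd_m` for
#' road fixes, which in the field are GPS-recorded sightings with metre-level
#' accuracy.
#'
#' @param structural a structural-level \linkS4class{GridLandscape}
#' @param truth named integer mapping typology code to functional class code
#'   (as returned by \code{\link{attachStructuralLayer}})
#' @param n_fixes total fixes to simulate (>= 10)
#' @param road_forage_share expected share of foraging fixes on the road
#'   typology (default 0.31)
#' @param accuracy_sd_m per-axis positional error of triangulated fixes
#'   (default 35 m)
#' @param seed integer seed
#' @param individual_id identifier stored in the output
#' @param road_gps_sd_m per-axis error of GPS-sighted road fixes (default 3 m)
#' @param behavior_mix named fractions of fixes that are nest / roost / forage
#' @param n_roost_points number of distinct day roosts used (default 2;
#'   nightjars reuse a small number of favoured roosts)
#' @param forage_decay_m spatial scale of the exponential distance decay used
#'   when sampling foraging cells around the nest
#' @return a \linkS4class{FixSet} with ground-truth coordinates retained
#' @export
simulateIndividualFixes <- function(structural, truth, n_fixes,
                                    road_forage_share = 0.31,
                                    accuracy_sd_m = 35, seed = 1L,
                                    individual_id = "ind1",
                                    road_gps_sd_m = 3,
                                    behavior_mix = c(nest = 0.2, roost = 0.3,
                                                     forage = 0.5),
                                    n_roost_points = 2L,
                                    forage_decay_m = 800) {
  stopifnot(is(structural, "GridLandscape"), n_fixes >= 10)
  if (landscapeLevel(structural) != "structural")
    stop("simulateIndividualFixes() expects a structural-level landscape")
  g <- classGrid(structural)
  nr <- nrow(g); nc <- ncol(g)
  cellsz <- cellSize(structural); orig <- gridOrigin(structural)
  fun_of <- function(code) truth[as.character(code)]
  cls <- matrix(truth[as.character(g)], nr, nc)
  for (need in c("breeding", "roosting", "foraging")) {
    if (!any(cls == CLASS_CODES[[need]]))
      stop("landscape has no cells of required class '", need, "'")
  }
  legend <- habitatLegend(structural)
  road_codes <- as.integer(names(legend)[grepl("road", legend, fixed = TRUE)])
  road_cells <- which(g %in% road_codes & cls == CLASS_CODES[["foraging"]])
  offroad_cells <- which(cls == CLASS_CODES[["foraging"]] & !(g %in% road_codes))

  n_nest <- round(behavior_mix[["nest"]] * n_fixes)
  n_roost <- round(behavior_mix[["roost"]] * n_fixes)
  n_forage <- n_fixes - n_nest - n_roost

  # nests and day roosts sit on patch-interior cells (concealment); roosts
  # lie deeper into the woodland (~50 m) than nests in low shrub (~20 m).
  # The mask is eroded to the requested depth, falling back to shallower
  # interiors when a patch is too small.
  erode1 <- function(m) {
    inner <- m
    inner[-1, ] <- inner[-1, , drop = FALSE] & m[-nr, , drop = FALSE]
    inner[-nr, ] <- inner[-nr, , drop = FALSE] & m[-1, , drop = FALSE]
    inner[, -1] <- inner[, -1, drop = FALSE] & m[, -nc, drop = FALSE]
    inner[, -nc] <- inner[, -nc, drop = FALSE] & m[, -1, drop = FALSE]
    inner
  }
  interiorCells <- function(code, depth_m) {
    m <- cls == code
    masks <- list(m)
    for (k in seq_len(max(0L, as.integer(round(depth_m / cellsz)))))
      masks[[k + 1L]] <- erode1(masks[[k]])
    for (candidate in rev(masks)) {
      out <- which(candidate)
      if (length(out)) return(out)
    }
    integer(0)
  }
  withSeed(seed, {
    # one nest, uniform over interior breeding cells, uniform within the cell
    br_cells <- interiorCells(CLASS_CODES[["breeding"]], 20)
    nest_cell <- br_cells[sample.int(length(br_cells), 1L)]
    nest_xy <- cellCenters(nest_cell, nr, cellsz, orig) +
      (runif(2) - 0.5) * cellsz
    # day roosts: a couple of points among the woodland-interior cells
    # nearest the nest (the pool spans a few stands)
    ro_cells <- interiorCells(CLASS_CODES[["roosting"]], 50)
    ro_xy <- cellCenters(ro_cells, nr, cellsz, orig)
    d_nest <- sqrt((ro_xy[, 1] - nest_xy[1])^2 + (ro_xy[, 2] - nest_xy[2])^2)
    pool <- ro_cells[order(d_nest)[seq_len(min(500L, length(ro_cells)))]]
    roost_cells <- pool[sample.int(length(pool),
                                   min(n_roost_points, length(pool)))]
    roost_pts <- cellCenters(roost_cells, nr, cellsz, orig) +
      matrix(runif(2 * length(roost_cells)) - 0.5, ncol = 2) * cellsz

    rows <- list()
    addFix <- function(xy, phase, behavior, sd_m) {
      rep_xy <- xy + rnorm(2, sd = sd_m)
      rows[[length(rows) + 1L]] <<- data.frame(
        individual_id = individual_id, x_m = rep_xy[1], y_m = rep_xy[2],
        phase = phase, behavior = behavior,
        true_x_m = xy[1], true_y_m = xy[2])
    }
    for (i in seq_len(n_nest))
      addFix(nest_xy, "day", "nest", accuracy_sd_m)
    for (i in seq_len(n_roost)) {
      k <- sample.int(nrow(roost_pts), 1L)
      addFix(roost_pts[k, ], "day", "roost", accuracy_sd_m)
    }
    if (n_forage > 0L) {
      n_road <- rbinom(1L, n_forage, road_forage_share)
      pickForage <- function(cells, n) {
        if (!length(cells)) stop("landscape has no cells of required class 'foraging'")
        xy <- cellCenters(cells, nr, cellsz, orig)
        d <- sqrt((xy[, 1] - nest_xy[1])^2 + (xy[, 2] - nest_xy[2])^2)
        w <- exp(-d / forage_decay_m)
        cells[sample.int(length(cells), n, replace = TRUE, prob = w)]
      }
      if (n_road > 0L) {
        if (!length(road_cells))
          stop("road_forage_share > 0 but the landscape has no road cells")
        for (cellk in pickForage(road_cells, n_road)) {
          xy <- cellCenters(cellk, nr, cellsz, orig) + (runif(2) - 0.5) * cellsz
          addFix(xy, "night", "forage", road_gps_sd_m)
        }
      }
      n_off <- n_forage - n_road
      if (n_off > 0L) {
        pool2 <- if (length(offroad_cells)) offroad_cells else road_cells
        for (cellk in pickForage(pool2, n_off)) {
          xy <- cellCenters(cellk, nr, cellsz, orig) + (runif(2) - 0.5) * cellsz
          addFix(xy, "night", "forage", accuracy_sd_m)
        }
      }
    }
    FixSet(do.call(rbind, rows))
  })
}

#' Simulate paired weekly abundance counts
#'
#' Generates paired weekly transect counts (standardized to birds/km) for two
#' plots surveyed simultaneously, as a fixture for the signed-rank comparison
#' of abundances. Weekly counts share a lognormal seasonal effect (the same
#' week is good or bad in both plots) and are negative-binomially dispersed
#' around `rate * transect_km * season`.
#'
#' @param n_weeks number of paired weeks
#' @param mean_rate_a,mean_rate_b mean abundance (birds/km) in each plot
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson); default 8
#' @param seed integer seed
#' @param transect_km transect length driven each week (default 10 km)
#' @param season_sd standard deviation of the shared log-seasonal effect
#' @return data.frame with columns `week`, `rate_a`, `rate_b` (birds/km)
#' @export
generateAbundanceSeries <- function(n_weeks, mean_rate_a, mean_rate_b,
                                    dispersion = 8, seed = 1L,
                                    transect_km = 10, season_sd = 0.5) {
  stopifnot(n_weeks >= 1, mean_rate_a >= 0, mean_rate_b >= 0)
  withSeed(seed, {
    season <- rlnorm(n_weeks, meanlog = -season_sd^2 / 2, sdlog = season_sd)
    draw <- function(rate) {
      mu <- rate * transect_km * season
      counts <- ifelse(mu > 0, rnbinom(n_weeks, size = dispersion, mu = mu), 0)
      counts / transect_km
    }
    data.frame(week = seq_len(n_weeks), rate_a = draw(mean_rate_a),
               rate_b = draw(mean_rate_b))
  })
}
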