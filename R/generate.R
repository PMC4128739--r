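# Synthetic functional landscapes: clumped blob growth versus an
# interspersed parcel mosaic, at identical composition.

CLASS_CODES <- c("non-usable" = 0L, "breeding" = 1L,
                 "roosting" = 2L, "foraging" = 3L)

#' Generate a synthetic functional landscape
#'
#' Produces a categorical raster of the four functional habitat classes with
#' a prescribed composition (areal fractions) in one of two configurations:
#'
#' \describe{
#'   \item{clumped}{each non-dominant class occupies at most five contiguous
#'     blobs, grown by multi-seed frontier accretion on the dominant-class
#'     background; emulates a natural landscape of large habitat blocks.}
#'   \item{interspersed}{a regular parcel mosaic. Non-usable parcels are
#'     assigned by uniform sampling without replacement, so at the parcel
#'     scale the usable/non-usable field is exchangeable (no spatial
#'     autocorrelation beyond chance). Within the usable mosaic, roosting
#'     habitat forms compact multi-parcel blocks (plantation stands) and
#'     foraging habitat is carved as narrow corridors along two sides of each
#'     block (the road network that serves the blocks); remaining usable
#'     parcels are breeding remnants. Emulates an intensively managed
#'     landscape of regularly shaped blocks with closely juxtaposed
#'     functional habitats.}
#' }
#'
#' Realized class fractions are exact up to parcel/blob rounding (well within
#' 2 percentage points of the target at default sizes).
#'
#' @param spec a \linkS4class{LandscapeSpec}
#' @return a functional-level \linkS4class{GridLandscape}
#' @examples
#' sp <- LandscapeSpec(c(120, 120), config = "interspersed",
#'   composition = c("non-usable" = 0.259, "breeding" = 0.14,
#'                   "roosting" = 0.543, "foraging" = 0.058),
#'   patchScale = 100, seed = 7)
#' usableFraction(generateFunctionalLandscape(sp))
#' @export
generateFunctionalLandscape <- function(spec) {
  validObject(spec)
  comp <- fullComposition(spec@composition)
  withSeed(spec@seed, {
    g <- if (spec@config == "clumped") {
      growClumped(spec@dims[1], spec@dims[2], comp, spec@cellSize,
                  patchScale(spec))
    } else {
      mosaicInterspersed(spec@dims[1], spec@dims[2], comp, spec@cellSize,
                         min(patchScale(spec)), spec@clusterParcels,
                         spec@roadDepthCells, spec@roadShare)
    }
    GridLandscape(g, cellSize = spec@cellSize, level = "functional")
  })
}

# composition vector over all four classes, zeros filled in
fullComposition <- function(comp) {
  out <- setNames(numeric(4), names(CLASS_CODES))
  out[names(comp)] <- comp
  out
}

# per-class patch scale, recycling a scalar
patchScale <- function(spec) {
  ps <- spec@patchScale
  if (is.null(names(ps)))
    ps <- setNames(rep(ps, length.out = 4), names(CLASS_CODES))
  out <- setNames(rep(min(ps), 4), names(CLASS_CODES))
  out[names(ps)] <- ps
  out
}

## ---- clumped: multi-seed frontier growth -----------------------------------

# Grow one class as <= 5 contiguous blobs on unclaimed cells. Every added
# cell is 4-adjacent to the already-grown set, so each seed's component stays
# contiguous (blobs may merge, which only reduces the count).
growBlobs <- function(claimed, n_target, n_seeds, nr, nc, class_name) {
  if (sum(!claimed) < n_target)
    stop("cannot fit requested area for class '", class_name, "'")
  claimed0 <- claimed
  for (attempt in 1:3) {
    claimed <- claimed0
    free <- which(!claimed)
    seeds <- free[sample.int(length(free), min(n_seeds, n_target))]
    grown <- seeds
    claimed[seeds] <- TRUE
    n_blobs <- length(seeds)
    ok <- TRUE
    while (length(grown) < n_target) {
      frontier <- unique(neighbors4(grown, nr, nc))
      frontier <- frontier[!claimed[frontier]]
      if (!length(frontier)) {
        # blobs boxed in by earlier classes: start another blob if the cap
        # allows, otherwise retry the whole class with fresh seeds
        free <- which(!claimed)
        if (n_blobs < 5L && length(free)) {
          seed <- free[sample.int(length(free), 1L)]
          claimed[seed] <- TRUE
          grown <- c(grown, seed)
          n_blobs <- n_blobs + 1L
          next
        }
        ok <- FALSE
        break
      }
      need <- n_target - length(grown)
      take <- if (length(frontier) > need)
        frontier[sample.int(length(frontier), need)] else frontier
      claimed[take] <- TRUE
      grown <- c(grown, take)
    }
    if (ok) return(list(cells = grown, claimed = claimed))
  }
  stop("frontier exhausted while growing class '", class_name,
       "' (infeasible composition/patch-scale combination)")
}

growClumped <- function(nr, nc, comp, cell_size, patch_scale) {
  total <- nr * nc
  dominant <- names(comp)[which.max(comp)]
  others <- setdiff(names(comp)[comp > 0], dominant)
  # grow larger classes first so small ones are not boxed in
  others <- others[order(comp[others], decreasing = TRUE)]
  g <- matrix(NA_integer_, nr, nc)
  claimed <- matrix(FALSE, nr, nc)
  for (cl in others) {
    n_target <- round(comp[[cl]] * total)
    if (n_target < 1L) next
    blob_cells <- pi / 4 * (patch_scale[[cl]] / cell_size)^2
    n_blobs <- max(1L, min(5L, as.integer(round(n_target / blob_cells))))
    res <- growBlobs(claimed, n_target, n_blobs, nr, nc, cl)
    claimed <- res$claimed
    g[res$cells] <- CLASS_CODES[[cl]]
  }
  g[!claimed] <- CLASS_CODES[[dominant]]
  g
}

## ---- interspersed: aligned parcel mosaic -----------------------------------

mosaicInterspersed <- function(nr, nc, comp, cell_size, parcel_m,
                               cluster_parcels, road_depth, road_share) {
  parcel <- max(1L, as.integer(round(parcel_m / cell_size)))
  pr <- nr %/% parcel; pc <- nc %/% parcel
  if (pr < 2L || pc < 2L)
    stop("grid too small for parcels of ", parcel_m,
         " m (infeasible for every class)")
  np <- pr * pc
  n_fo_cells <- round(comp[["foraging"]] * nr * nc)
  n_nu <- round(comp[["non-usable"]] * np)
  # roosting parcels are inflated by the road budget: road strips are carved
  # back out of the block rims below; the crop-parcel share of foraging comes
  # out of the breeding remainder
  n_ro <- round((comp[["roosting"]] + road_share * comp[["foraging"]]) * np)
  if (n_nu + n_ro > np)
    stop("cannot fit requested area for class 'breeding'")

  pg <- matrix(NA_integer_, pr, pc)
  nu <- sample.int(np, n_nu)
  pg[nu] <- CLASS_CODES[["non-usable"]]
  usable <- setdiff(seq_len(np), nu)
  memb <- integer(np)  # roost block membership per parcel

  if (n_ro > 0L) {
    n_seed <- max(1L, round(n_ro / cluster_parcels))
    claimed <- rep(FALSE, np); claimed[nu] <- TRUE
    seeds <- usable[sample.int(length(usable), min(n_seed, n_ro))]
    claimed[seeds] <- TRUE
    roost <- seeds
    memb[seeds] <- seq_along(seeds)
    while (length(roost) < n_ro) {
      frontier <- unique(neighbors4(roost, pr, pc))
      frontier <- frontier[!claimed[frontier]]
      if (!length(frontier)) {  # blocks boxed in: scatter the remainder
        extra <- setdiff(usable, roost)
        extra <- extra[sample.int(length(extra), n_ro - length(roost))]
        memb[extra] <- 1L
        claimed[extra] <- TRUE
        roost <- c(roost, extra)
        break
      }
      need <- n_ro - length(roost)
      take <- if (length(frontier) > need)
        frontier[sample.int(length(frontier), need)] else frontier
      for (t in take) {
        nb <- neighbors4(t, pr, pc)
        nb <- nb[memb[nb] > 0L]
        memb[t] <- memb[nb[1L]]
      }
      claimed[take] <- TRUE
      roost <- c(roost, take)
    }
    pg[roost] <- CLASS_CODES[["roosting"]]
  }
  pg[is.na(pg)] <- CLASS_CODES[["breeding"]]

  # expand parcels to cells; remainder rows/cols at the north/east edges
  # extend their edge parcels so no artificial band is created
  ri <- pmin(ceiling(seq_len(nr) / parcel), pr)
  ci <- pmin(ceiling(seq_len(nc) / parcel), pc)
  g <- pg[ri, ci, drop = FALSE]
  mm <- matrix(0L, pr, pc); mm[seq_len(np)] <- memb
  mcell <- mm[ri, ci, drop = FALSE]

  breeding_parcels <- which(pg == CLASS_CODES[["breeding"]])
  if (n_fo_cells > 0L)
    g <- carveForaging(g, mcell, memb, breeding_parcels, n_fo_cells,
                       road_depth, road_share, pr, pc, parcel)
  g
}

# Foraging habitat of the managed mosaic, in two geometric forms served
# round-robin over the roosting blocks so every block has foraging nearby:
# (1) road strips along the south/east rims of the blocks (share road_share
# of the areal budget), and (2) whole crop parcels converted from the
# breeding remainder adjacent to the blocks (the rest of the budget).
carveForaging <- function(g, mcell, memb, breeding_parcels, n_fo_cells,
                          road_depth, road_share, pr, pc, parcel) {
  nr <- nrow(g); nc <- ncol(g)
  code_fo <- CLASS_CODES[["foraging"]]
  isro <- g == CLASS_CODES[["roosting"]]
  n_blocks <- max(max(mcell), 1L)

  # (1) road strips from the block rims
  road_budget <- round(road_share * n_fo_cells)
  rim <- matrix(FALSE, nr, nc)
  cur <- isro
  for (k in seq_len(road_depth)) {
    inner <- cur
    inner[-1, ] <- inner[-1, , drop = FALSE] & cur[-nr, , drop = FALSE]
    inner[-nr, ] <- inner[-nr, , drop = FALSE] & cur[-1, , drop = FALSE]
    inner[, -1] <- inner[, -1, drop = FALSE] & cur[, -nc, drop = FALSE]
    inner[, -nc] <- inner[, -nc, drop = FALSE] & cur[, -1, drop = FALSE]
    rim <- rim | (cur & !inner)
    cur <- inner
  }
  rowi <- row(g); coli <- col(g)
  forage <- integer(0)
  if (road_budget > 0L) {
    for (ci in sample.int(n_blocks)) {
      cells <- which(mcell == ci & isro)
      if (!length(cells)) next
      ring <- which(rim & mcell == ci &
                    (rowi > mean(rowi[cells]) | coli > mean(coli[cells])))
      if (!length(ring)) next
      if (length(forage) + length(ring) > road_budget) {
        short <- road_budget - length(forage)
        forage <- c(forage, ring[sample.int(length(ring), short)])
        break
      }
      forage <- c(forage, ring)
      if (length(forage) >= road_budget) break
    }
    g[forage] <- code_fo
  }

  # (2) crop parcels from the breeding remainder next to the blocks
  n_left <- n_fo_cells - length(forage)
  taken <- integer(0)
  while (n_left > 0L) {
    progressed <- FALSE
    for (ci in sample.int(n_blocks)) {
      if (n_left <= 0L) break
      cc <- which(memb == ci)
      if (!length(cc)) next
      adj <- setdiff(intersect(unique(neighbors4(cc, pr, pc)),
                               breeding_parcels), taken)
      if (!length(adj)) next
      p <- adj[sample.int(length(adj), 1L)]
      taken <- c(taken, p)
      prow <- (p - 1L) %% pr + 1L; pcol <- (p - 1L) %/% pr + 1L
      rr <- ((prow - 1L) * parcel + 1L):min(prow * parcel, nr)
      cc2 <- ((pcol - 1L) * parcel + 1L):min(pcol * parcel, nc)
      sub <- as.matrix(expand.grid(rr, cc2))
      sub <- sub[g[sub] == CLASS_CODES[["breeding"]], , drop = FALSE]
      k <- min(nrow(sub), n_left)
      if (k > 0L) {
        g[sub[seq_len(k), , drop = FALSE]] <- code_fo
        n_left <- n_left - k
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  if (n_left > 0L) {  # fallback: thicken the road rims
    rest <- setdiff(which(rim), which(g == code_fo))
    take <- min(length(rest), n_left)
    if (take > 0L) g[rest[sample.int(length(rest), take)]] <- code_fo
  }
  g
}

## ---- structural layer ------------------------------------------------------

#' Refine a functional landscape into structural cover typologies
#'
#' Splits each functional class into one or more structural cover typologies
#' and returns the ground-truth typology-to-functional mapping used (the
#' target of the selection-recovery pipeline). Typologies are assigned
#' tile-coherently: the class's cells are partitioned by a square tiling
#' (default 100 m) and each occupied tile draws one typology with the given
#' weights, so typologies form stands and segments rather than single-cell
#' salt-and-pepper, as real cover maps do. Realized typology fractions match
#' the weights in expectation over tiles.
#'
#' @param functional a functional-level \linkS4class{GridLandscape}
#' @param typology_split named list: functional class name to a named numeric
#'   vector of typology weights (weights must sum to 1 per class);
#'   see \code{\link{defaultTypologySplit}}
#' @param seed integer seed
#' @param tile_size_m tile edge for typology coherence (default 100 m)
#' @param linear_typologies typology names assigned to the \emph{thinnest}
#'   cells of their class (fewest same-class neighbours) instead of by tile:
#'   linear features such as roads and paths run along patch margins and
#'   block rims. Default `"road"`.
#' @return list with elements \code{landscape} (structural
#'   \linkS4class{GridLandscape}; typology codes 1, 2, ... in list order) and
#'   \code{truth} (named integer: typology code to functional class code)
#' @examples
#' sp <- LandscapeSpec(c(60, 60), config = "interspersed",
#'   composition = c("breeding" = 0.5, "roosting" = 0.5),
#'   patchScale = 100, seed = 1)
#' fun <- generateFunctionalLandscape(sp)
#' st <- attachStructuralLayer(fun, defaultTypologySplit("natural"), seed = 2)
#' st$truth
#' @export
attachStructuralLayer <- function(functional, typology_split, seed = 1L,
                                  tile_size_m = 100,
                                  linear_typologies = "road") {
  stopifnot(is(functional, "GridLandscape"))
  if (landscapeLevel(functional) != "functional")
    stop("attachStructuralLayer() expects a functional-level landscape")
  present <- names(CLASS_CODES)[CLASS_CODES %in% unique(as.vector(classGrid(functional)))]
  missing_split <- setdiff(present, names(typology_split))
  if (length(missing_split))
    stop("typology_split must cover every functional class present; missing: ",
         paste(missing_split, collapse = ", "))
  for (cl in names(typology_split)) {
    w <- typology_split[[cl]]
    if (abs(sum(w) - 1) > 1e-9)
      stop("typology weights for class '", cl, "' must sum to 1")
  }
  # assign typology codes in list order
  all_types <- unlist(lapply(typology_split, names), use.names = FALSE)
  if (anyDuplicated(all_types)) stop("typology names must be unique")
  codes <- setNames(seq_along(all_types), all_types)
  truth <- integer(0)
  for (cl in names(typology_split))
    truth[as.character(codes[names(typology_split[[cl]])])] <- CLASS_CODES[[cl]]
  truth <- truth[order(as.integer(names(truth)))]

  g <- classGrid(functional)
  nr <- nrow(g); nc <- ncol(g)
  tile <- max(1L, as.integer(round(tile_size_m / cellSize(functional))))
  tile_id <- (ceiling(row(g) / tile) - 1L) * ceiling(nc / tile) +
    ceiling(col(g) / tile)
  # same-class neighbour count (8-neighbourhood) for linear-feature placement
  neighborCount <- function(mask) {
    cnt <- matrix(0L, nr, nc)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      sh <- matrix(FALSE, nr, nc)
      rs <- max(1, 1 + d[1]):min(nr, nr + d[1])
      cs <- max(1, 1 + d[2]):min(nc, nc + d[2])
      sh[rs, cs] <- mask[rs - d[1], cs - d[2]]
      cnt <- cnt + sh
    }
    cnt
  }
  out <- matrix(0L, nr, nc)
  withSeed(seed, {
    for (cl in names(typology_split)) {
      idx <- which(g == CLASS_CODES[[cl]])
      if (!length(idx)) next
      w <- typology_split[[cl]]
      lin <- names(w)[names(w) %in% linear_typologies]
      if (length(lin)) {
        # thinnest cells of the class carry the linear typologies
        cnt <- neighborCount(g == CLASS_CODES[[cl]])
        ord <- idx[order(cnt[idx], idx)]
        n_lin <- round(sum(w[lin]) * length(idx))
        take <- head(ord, n_lin)
        splits <- round(cumsum(w[lin]) / sum(w[lin]) * n_lin)
        from <- 1L
        for (j in seq_along(lin)) {
          if (splits[j] >= from)
            out[take[from:splits[j]]] <- codes[[lin[j]]]
          from <- splits[j] + 1L
        }
        idx <- setdiff(idx, take)
        w <- w[setdiff(names(w), lin)]
        if (!length(w) && length(idx)) w <- setNames(1, lin[1])  # degenerate
      }
      if (length(idx) && length(w)) {
        tiles <- unique(tile_id[idx])
        pick <- setNames(
          names(w)[sample.int(length(w), length(tiles), replace = TRUE,
                              prob = w)], tiles)
        out[idx] <- codes[pick[as.character(tile_id[idx])]]
      }
    }
  })
  legend <- setNames(all_types, as.character(codes))
  list(landscape = GridLandscape(out, cellSize = cellSize(functional),
                                 origin = gridOrigin(functional),
                                 legend = legend, level = "structural"),
       truth = truth)
}

#' Default cover-typology splits
#'
#' Ten cover typologies grouped under the four functional classes, with
#' weights chosen so that roads cover just under 1\% of the total surface
#' at the default plot compositions. The road typology carries the foraging
#' fixes of road-sitting birds.
#'
#' @param plot `"natural"` (shrubland-dominated reserve: mature pinewood,
#'   sandy paths) or `"managed"` (plantation mosaic: planted pinewood, orange
#'   groves)
#' @return named list of named weight vectors, one per functional class
#' @export
defaultTypologySplit <- function(plot = c("natural", "managed")) {
  plot <- match.arg(plot)
  if (plot == "natural")
    list(
      "breeding"   = c("open shrubland" = 1),
      "roosting"   = c("mature pinewood" = 0.8, "planted pinewood" = 0.2),
      "foraging"   = c("road" = 0.3, "sandy path" = 0.7),
      "non-usable" = c("marshland" = 0.5, "bare dune" = 0.3, "pasture" = 0.2))
  else
    list(
      "breeding"   = c("open shrubland" = 1),
      "roosting"   = c("planted pinewood" = 0.85, "mature pinewood" = 0.15),
      "foraging"   = c("road" = 0.15, "orange grove" = 0.85),
      "non-usable" = c("pasture" = 0.6, "built-up" = 0.2, "marshland" = 0.2))
}
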