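# Shared builders for the study's two plot types at reduced extent.

naturalComposition <- c("non-usable" = 0.391, "breeding" = 0.475,
                        "roosting" = 0.104, "foraging" = 0.030)
managedComposition <- c("non-usable" = 0.259, "breeding" = 0.140,
                        "roosting" = 0.543, "foraging" = 0.058)

# clumped plot at reduced extent; patch scales shrink with the grid so the
# blob counts stay comparable to the full-size plot
naturalSpec <- function(seed, dims = c(250L, 250L)) {
  LandscapeSpec(dims, config = "clumped", composition = naturalComposition,
                patchScale = c("non-usable" = 800, "roosting" = 500,
                               "foraging" = 500),
                seed = seed)
}

managedSpec <- function(seed, dims = c(250L, 250L)) {
  LandscapeSpec(dims, config = "interspersed",
                composition = managedComposition, patchScale = 100,
                seed = seed)
}

# one tracked individual's tables for the recovery pipeline
individualTables <- function(structural, truth, n_fixes, seed, id) {
  fx <- simulateIndividualFixes(structural, truth, n_fixes, seed = seed,
                                individual_id = id)
  ud <- estimateUD(fx)
  hr <- volumeContour(ud)
  avail <- availabilityWithinRange(structural, hr)
  out <- list()
  for (beh in c("nest", "roost", "forage")) {
    used <- tabulateUse(fx, structural, beh)
    if (sum(used) < 5) next
    ctx <- c(nest = "nesting", roost = "roosting", forage = "foraging")[[beh]]
    out[[length(out) + 1L]] <- selectionTest(used, avail, behavior = ctx,
                                             individual = id)
  }
  out
}

# full selection-recovery run on one landscape; returns the recovered
# mapping keyed by typology name
recoverMapping <- function(plot, seed, n_ind = 6, n_fixes = 50,
                           dims = c(250L, 250L)) {
  spec <- if (plot == "natural") naturalSpec(seed, dims)
          else managedSpec(seed, dims)
  fun <- generateFunctionalLandscape(spec)
  st <- attachStructuralLayer(fun, defaultTypologySplit(plot),
                              seed = seed + 1L)
  tables <- list()
  for (i in seq_len(n_ind))
    tables <- c(tables, individualTables(st$landscape, st$truth, n_fixes,
                                         seed = seed * 100L + i,
                                         id = sprintf("b%02d", i)))
  fm <- buildFunctionalMap(tables, st$landscape)
  m <- assignmentMapping(fm$assignment)
  list(byname = setNames(m, habitatLegend(st$landscape)[names(m)]),
       mapping = m, truth = st$truth, landscape = fm$landscape)
}

# brute-force nearest-target distance (independent oracle for the EDT)
bruteForceDistance <- function(grid, code, cell_size) {
  nr <- nrow(grid); nc <- ncol(grid)
  targets <- which(grid == code)
  tr <- (targets - 1) %% nr + 1
  tc <- (targets - 1) %/% nr + 1
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      out[i, j] <- sqrt(min((tr - i)^2 + (tc - j)^2)) * cell_size
  out
}

# tiny structural landscape carrying the full 10-typology legend
makeStructural10 <- function() {
  legend <- setNames(
    c("open shrubland", "mature pinewood", "planted pinewood", "road",
      "sandy path", "orange grove", "pasture", "built-up", "marshland",
      "bare dune"), as.character(1:10))
  grid <- matrix(rep(1:10, length.out = 100), 10, 10)
  storage.mode(grid) <- "integer"
  GridLandscape(grid, cellSize = 10, legend = legend, level = "structural")
}
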