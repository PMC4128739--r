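# Use-versus-availability selection and functional reclassification.

fullMask <- function(landscape) {
  g <- classGrid(landscape)
  new("HomeRange", mask = matrix(TRUE, nrow(g), ncol(g)),
      cellSize = cellSize(landscape), origin = gridOrigin(landscape),
      isopleth = 0.95,
      areaHa = length(g) * cellSize(landscape)^2 / 1e4)
}

test_that("availability on a uniform landscape is a point mass", {
  g <- GridLandscape(matrix(2L, 10, 10), cellSize = 10)
  av <- availabilityWithinRange(g, fullMask(g))
  expect_equal(unname(av["roosting"]), 1)
  expect_equal(sum(av), 1)
})

test_that("a half-and-half mask yields 0.5/0.5 availability", {
  grid <- cbind(matrix(1L, 10, 5), matrix(2L, 10, 5))
  g <- GridLandscape(grid, cellSize = 10)
  av <- availabilityWithinRange(g, fullMask(g))
  expect_equal(unname(av["breeding"]), 0.5)
  expect_equal(unname(av["roosting"]), 0.5)
})

test_that("whole-plot shrubland availability matches the natural plot", {
  g <- generateFunctionalLandscape(naturalSpec(seed = 12))
  av <- availabilityWithinRange(g, fullMask(g))
  expect_equal(unname(av["breeding"]), 0.475, tolerance = 0.02 / 0.475)
})

test_that("a disjoint home range is an error", {
  g <- GridLandscape(matrix(0L, 10, 10), cellSize = 10)
  hr <- new("HomeRange", mask = matrix(TRUE, 5, 5), cellSize = 10,
            origin = c(1e6, 1e6), isopleth = 0.95, areaHa = 0.25)
  expect_error(availabilityWithinRange(g, hr), "overlap")
})

test_that("use proportional to availability is neutral with zero chi-square", {
  st <- selectionTest(c(a = 30, b = 60, c = 10),
                      c(a = 0.3, b = 0.6, c = 0.1))
  expect_equal(st@chiSquare, 0)
  expect_equal(st@pValue, 1)
  expect_true(all(st@table$call == "neutral"))
  expect_equal(sum(st@table$used_prop), 1)
  expect_equal(sum(st@table$avail_prop), 1)
  expect_identical(st@df, 2L)
})

test_that("road use at 31/100 against 1% availability is selected", {
  st <- selectionTest(c(road = 31, other = 69), c(road = 0.01, other = 0.99))
  expect_identical(unname(selectionCalls(st)["road"]), "selected")
  expect_lt(st@pValue, 0.001)
  # independent multinomial oracle for the chi-square p-value
  set.seed(1)
  draws <- rmultinom(20000, 100, c(0.01, 0.99))
  stats <- colSums((draws - c(1, 99))^2 / c(1, 99))
  expect_lt(mean(stats >= st@chiSquare), 0.001)
})

test_that("the Agresti-Coull interval matches the direct formula", {
  st <- selectionTest(c(road = 31, other = 69), c(road = 0.5, other = 0.5),
                      conf = 0.9)  # 1 - (1-0.9)/2 per-type level = 0.95
  row <- st@table[st@table$cover_type == "road", ]
  expect_equal(row$ci_low, 0.2275, tolerance = 1e-3)
  expect_equal(row$ci_high, 0.4066, tolerance = 1e-3)
})

test_that("categories used despite zero availability are flagged selected", {
  st <- selectionTest(c(a = 5, b = 45, c = 50),
                      c(a = 0, b = 0.5, c = 0.5))
  expect_identical(unname(selectionCalls(st)["a"]), "selected")
  expect_identical(st@df, 1L)  # only b and c enter the chi-square
})

test_that("use in a category entirely absent is an error", {
  expect_error(selectionTest(c(a = 5), c(b = 1)), "absent")
})

test_that("widening the confidence level never un-neutralizes a call", {
  set.seed(13)
  for (k in 1:20) {
    n <- sample(20:80, 1)
    used <- as.vector(rmultinom(1, n, c(0.5, 0.3, 0.2)))
    names(used) <- c("a", "b", "c")
    avail <- c(a = 0.4, b = 0.35, c = 0.25)
    lo <- selectionCalls(selectionTest(used, avail, conf = 0.9))
    hi <- selectionCalls(selectionTest(used, avail, conf = 0.99))
    flipped <- lo == "neutral" & hi != "neutral"
    expect_false(any(flipped))
  }
})

test_that("unanimous nesting selection assigns shrubland to breeding", {
  st <- makeStructural10()
  tables <- lapply(sprintf("b%02d", 1:10), function(id)
    selectionTest(c("open shrubland" = 9, "pasture" = 1),
                  c("open shrubland" = 0.4, "pasture" = 0.6),
                  behavior = "nesting", individual = id))
  fm <- buildFunctionalMap(tables, st)
  m <- setNames(assignmentMapping(fm$assignment),
                habitatLegend(st)[names(assignmentMapping(fm$assignment))])
  expect_identical(unname(m["open shrubland"]), 1L)
  expect_identical(unname(m["pasture"]), 0L)
})

test_that("no detected selection leaves every typology non-usable", {
  st <- makeStructural10()
  tables <- lapply(sprintf("b%02d", 1:4), function(id)
    selectionTest(c("open shrubland" = 4, "pasture" = 6),
                  c("open shrubland" = 0.4, "pasture" = 0.6),
                  behavior = "foraging", individual = id))
  fm <- buildFunctionalMap(tables, st)
  expect_true(all(assignmentMapping(fm$assignment) == 0L))
  expect_true(all(classGrid(fm$landscape) == 0L))
})

test_that("a 6-of-10 foraging majority assigns roads to foraging", {
  st <- makeStructural10()
  sel <- selectionTest(c(road = 31, "open shrubland" = 69),
                       c(road = 0.01, "open shrubland" = 0.99),
                       behavior = "foraging", individual = "x")
  neu <- selectionTest(c(road = 1, "open shrubland" = 99),
                       c(road = 0.01, "open shrubland" = 0.99),
                       behavior = "foraging", individual = "x")
  tables <- c(
    lapply(sprintf("s%02d", 1:6), function(id) { sel@individual <- id; sel }),
    lapply(sprintf("n%02d", 1:4), function(id) { neu@individual <- id; neu }))
  fm <- buildFunctionalMap(tables, st)
  m <- setNames(assignmentMapping(fm$assignment),
                habitatLegend(st)[names(assignmentMapping(fm$assignment))])
  expect_identical(unname(m["road"]), 3L)
})

test_that("usable fraction counts non-zero cells", {
  grid <- matrix(0L, 4, 4)
  grid[c(1, 3, 6, 9, 16)] <- c(1L, 2L, 3L, 1L, 2L)
  g <- GridLandscape(grid, cellSize = 10)
  expect_equal(usableFraction(g), 5 / 16)
  expect_equal(usableFraction(GridLandscape(matrix(0L, 3, 3))), 0)
})

test_that("usable fractions of the two synthetic plots match the study", {
  expect_equal(usableFraction(generateFunctionalLandscape(naturalSpec(14))),
               0.609, tolerance = 0.02 / 0.609)
  expect_equal(usableFraction(generateFunctionalLandscape(managedSpec(15))),
               0.741, tolerance = 0.02 / 0.741)
})

test_that("usableFraction refuses structural landscapes", {
  fun <- generateFunctionalLandscape(managedSpec(16, dims = c(120L, 120L)))
  st <- attachStructuralLayer(fun, defaultTypologySplit("managed"), seed = 1)
  expect_error(usableFraction(st$landscape), "functional")
})
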