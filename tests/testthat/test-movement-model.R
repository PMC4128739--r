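# Nest placement, distance transforms, movement needs, cost distances.

test_that("nests respect count, habitat and spacing on the managed mosaic", {
  g <- generateFunctionalLandscape(managedSpec(seed = 22))
  nests <- simulateNests(g, n = 60, min_dist_m = 50, seed = 23)
  pts <- nestPoints(nests)
  expect_identical(nrow(pts), 60L)
  expect_gte(min(dist(pts)), 50)
  # every nest on a breeding cell
  grid <- classGrid(g)
  idx <- floor(pts[, 1] / 10) * nrow(grid) + floor(pts[, 2] / 10) + 1
  expect_true(all(grid[idx] == 1L))
})

test_that("nest placement is deterministic under the seed", {
  g <- generateFunctionalLandscape(managedSpec(seed = 24, dims = c(150L, 150L)))
  a <- simulateNests(g, 30, 50, seed = 7)
  b <- simulateNests(g, 30, 50, seed = 7)
  expect_identical(nestPoints(a), nestPoints(b))
})

test_that("infeasible spacing fails reporting the placed count", {
  grid <- matrix(0L, 5, 5); grid[13] <- 1L   # one 10-m breeding cell
  g <- GridLandscape(grid, cellSize = 10)
  expect_error(simulateNests(g, 2, 50, seed = 1, max_attempts = 200),
               "place 1 of 2")
})

test_that("distance is zero on target cells and exact off them", {
  grid <- matrix(0L, 8, 8)
  grid[2, 2] <- 3L                 # row 2, col 2
  grid[1, 1] <- 1L
  g <- GridLandscape(grid, cellSize = 10)
  d <- distanceValues(nearestHabitatDistance(g, "foraging"))
  expect_equal(d[2, 2], 0)
  # 3 cells east, 4 cells north: the 3-4-5 triangle at 10-m cells
  expect_equal(d[6, 5], 50)
})

test_that("the transform equals brute force exactly on random grids", {
  set.seed(25)
  for (k in 1:20) {
    grid <- matrix(0L, 50, 50)
    grid[sample.int(2500, 25)] <- 3L
    g <- GridLandscape(grid, cellSize = 10)
    d <- distanceValues(nearestHabitatDistance(g, 3L))
    expect_equal(d, bruteForceDistance(grid, 3L, 10), tolerance = 1e-12)
  }
})

test_that("an empty target class is an error", {
  g <- GridLandscape(matrix(1L, 5, 5), cellSize = 10)
  expect_error(nearestHabitatDistance(g, "foraging"), "foraging")
})

test_that("movement needs add exactly and fail outside the grid", {
  grid <- matrix(0L, 9, 9)
  grid[5, 5] <- 1L; grid[1, 1] <- 2L; grid[9, 9] <- 3L
  g <- GridLandscape(grid, cellSize = 10)
  dro <- nearestHabitatDistance(g, "roosting")
  dfo <- nearestHabitatDistance(g, "foraging")
  nests <- simulateNests(g, 1, 0, seed = 2)
  needs <- movementNeeds(nests, dro, dfo, "toy")
  # nest sits in the centre cell: both distances enumerable by hand
  expect_equal(needs$d_roost_m, sqrt(32) * 10)
  expect_equal(needs$d_forage_m, sqrt(32) * 10)
  expect_equal(needs$d_total_m, needs$d_roost_m + needs$d_forage_m)
  bad <- new("NestSet", points = cbind(x_m = 1e5, y_m = 1e5),
             nRequested = 1L, minDist = 0, seed = 1L)
  expect_error(movementNeeds(bad, dro, dfo), "outside")
})

test_that("distances scale linearly with cell size", {
  set.seed(26)
  grid <- matrix(0L, 30, 30)
  grid[sample.int(900, 12)] <- 2L
  d10 <- distanceValues(nearestHabitatDistance(GridLandscape(grid, cellSize = 10), 2L))
  d20 <- distanceValues(nearestHabitatDistance(GridLandscape(grid, cellSize = 20), 2L))
  expect_equal(d20, 2 * d10)
})

test_that("uniform-cost geodesics reduce to Euclidean on the axis", {
  grid <- matrix(1L, 5, 20)
  g <- GridLandscape(grid, cellSize = 10)
  d <- costDistance(g, c(breeding = 1), sources = cbind(5, 25))
  v <- distanceValues(d)
  # along the row through the source the path is axis-aligned
  expect_equal(v[3, 15], 140)
})

test_that("uniform-cost geodesics stay within the 8-connectivity bound", {
  set.seed(27)
  grid <- matrix(1L, 25, 25)
  g <- GridLandscape(grid, cellSize = 10)
  src <- cbind(125, 125)
  geo <- distanceValues(costDistance(g, c(breeding = 1), src))
  centers_x <- (col(grid) - 0.5) * 10
  centers_y <- (row(grid) - 0.5) * 10
  eucl <- sqrt((centers_x - 125)^2 + (centers_y - 125)^2)
  ratio <- geo[eucl > 0] / eucl[eucl > 0]
  expect_gte(min(ratio), 1 - 1e-9)
  expect_lte(max(ratio), 1 / cos(pi / 8) + 1e-9)
})

test_that("barriers make enclosed cells unreachable", {
  grid <- matrix(1L, 9, 9)
  grid[4:6, 4:6] <- 2L
  grid[5, 5] <- 3L
  g <- GridLandscape(grid, cellSize = 10)
  d <- costDistance(g, c(breeding = 1, roosting = Inf, foraging = 1),
                    sources = cbind(5, 5))
  v <- distanceValues(d)
  expect_true(is.infinite(v[5, 5]))   # target ringed by barrier
  expect_true(all(is.finite(v[1, ])))
})

test_that("uniform-cost geodesics dominate the Euclidean transform", {
  set.seed(28)
  grid <- matrix(0L, 40, 40)
  grid[sample.int(1600, 20)] <- 3L
  g <- GridLandscape(grid, cellSize = 10)
  edt <- distanceValues(nearestHabitatDistance(g, 3L))
  targets <- which(grid == 3L)
  nr <- nrow(grid)
  src <- cbind(((targets - 1) %/% nr + 0.5) * 10,
               ((targets - 1) %% nr + 0.5) * 10)
  cost <- c("non-usable" = 1, "foraging" = 1)
  geo <- distanceValues(costDistance(g, cost, src))
  expect_true(all(geo >= edt - 1e-9))
  expect_true(all(geo <= edt / cos(pi / 8) + 1e-9))
})
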