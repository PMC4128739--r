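# Landscape and telemetry generators: composition, configuration, noise.

test_that("realized composition matches the target within 2 points", {
  for (mk in list(naturalSpec, managedSpec)) {
    g <- generateFunctionalLandscape(mk(seed = 11))
    tab <- table(factor(classGrid(g), levels = 0:3)) / length(classGrid(g))
    target <- if (identical(mk, naturalSpec)) naturalComposition
              else managedComposition
    expect_equal(unname(as.numeric(tab)), unname(target), tolerance = 0.02)
    # composition conservation is exact by cell counting
    expect_equal(sum(tab), 1)
  }
})

test_that("managed-spec mosaic realizes the usable fraction of the study", {
  g <- generateFunctionalLandscape(managedSpec(seed = 3))
  expect_equal(usableFraction(g), 0.741, tolerance = 0.02)
})

test_that("degenerate composition gives an all-non-usable map", {
  for (config in c("clumped", "interspersed")) {
    sp <- LandscapeSpec(c(40L, 40L), composition = c("non-usable" = 1),
                        config = config, patchScale = 100, seed = 1)
    expect_true(all(classGrid(generateFunctionalLandscape(sp)) == 0L))
  }
})

test_that("generation is deterministic under the spec seed", {
  for (mk in list(naturalSpec, managedSpec)) {
    a <- generateFunctionalLandscape(mk(seed = 5, dims = c(120L, 120L)))
    b <- generateFunctionalLandscape(mk(seed = 5, dims = c(120L, 120L)))
    expect_identical(classGrid(a), classGrid(b))
  }
})

test_that("clumped landscapes place each non-dominant class in few blobs", {
  g <- generateFunctionalLandscape(naturalSpec(seed = 9))
  for (code in c(0L, 2L, 3L)) {
    comps <- EBImage::bwlabel(classGrid(g) == code)
    expect_lte(max(comps), 5L)
  }
})

test_that("infeasible compositions fail naming the class", {
  sp <- LandscapeSpec(c(6L, 6L), cellSize = 10,
                      composition = c("breeding" = 0.5, "roosting" = 0.5),
                      config = "interspersed", patchScale = 1000, seed = 1)
  expect_error(generateFunctionalLandscape(sp), "class")
})

test_that("structural layer refines the functional map and returns truth", {
  fun <- generateFunctionalLandscape(managedSpec(seed = 21))
  st <- attachStructuralLayer(fun, defaultTypologySplit("managed"), seed = 2)
  g <- classGrid(st$landscape)
  # every structural code maps back to exactly the underlying functional class
  remapped <- matrix(st$truth[as.character(g)], nrow(g), ncol(g))
  expect_identical(remapped, matrix(as.integer(classGrid(fun)),
                                    nrow(g), ncol(g)))
  expect_identical(landscapeLevel(st$landscape), "structural")
})

test_that("a half-and-half typology split covers about half the class each", {
  fun <- generateFunctionalLandscape(naturalSpec(seed = 31))
  split <- defaultTypologySplit("natural")
  split[["roosting"]] <- c("mature pinewood" = 0.5, "planted pinewood" = 0.5)
  st <- attachStructuralLayer(fun, split, seed = 4)
  g <- classGrid(st$landscape)
  codes <- names(habitatLegend(st$landscape))[
    habitatLegend(st$landscape) %in% c("mature pinewood", "planted pinewood")]
  counts <- table(factor(g[g %in% as.integer(codes)], levels = codes))
  expect_equal(unname(counts[1] / sum(counts)), 0.5, tolerance = 0.15)
})

test_that("an identity split reproduces the functional map up to relabeling", {
  fun <- generateFunctionalLandscape(managedSpec(seed = 41, dims = c(120L, 120L)))
  split <- list("non-usable" = c(other = 1), "breeding" = c(shrub = 1),
                "roosting" = c(pine = 1), "foraging" = c(road = 1))
  st <- attachStructuralLayer(fun, split, seed = 5)
  remapped <- matrix(st$truth[as.character(classGrid(st$landscape))],
                     120L, 120L)
  expect_identical(remapped, matrix(as.integer(classGrid(fun)), 120L, 120L))
})

test_that("typology weights must sum to one per class", {
  fun <- generateFunctionalLandscape(managedSpec(seed = 1, dims = c(120L, 120L)))
  split <- defaultTypologySplit("managed")
  split[["foraging"]] <- c("road" = 0.6, "orange grove" = 0.6)
  expect_error(attachStructuralLayer(fun, split), "sum to 1")
})

test_that("road share of foraging fixes follows the requested probability", {
  fun <- generateFunctionalLandscape(managedSpec(seed = 51))
  st <- attachStructuralLayer(fun, defaultTypologySplit("managed"), seed = 6)
  fx <- simulateIndividualFixes(st$landscape, st$truth, n_fixes = 1000,
                                road_forage_share = 0.31, seed = 7,
                                behavior_mix = c(nest = 0.05, roost = 0.05,
                                                 forage = 0.9))
  f <- fixes(fx)
  forage <- f[f$behavior == "forage", ]
  road_codes <- names(habitatLegend(st$landscape))[
    habitatLegend(st$landscape) == "road"]
  g <- classGrid(st$landscape)
  idx <- floor((forage$true_x_m - gridOrigin(st$landscape)[1]) /
                 cellSize(st$landscape)) * nrow(g) +
    floor((forage$true_y_m - gridOrigin(st$landscape)[2]) /
            cellSize(st$landscape)) + 1
  on_road <- g[idx] %in% as.integer(road_codes)
  n <- nrow(forage)
  ci <- 0.31 + c(-1, 1) * qnorm(0.995) * sqrt(0.31 * 0.69 / n)
  expect_gte(mean(on_road), ci[1])
  expect_lte(mean(on_road), ci[2])
})

test_that("zero accuracy reproduces true coordinates exactly", {
  fun <- generateFunctionalLandscape(managedSpec(seed = 61, dims = c(150L, 150L)))
  st <- attachStructuralLayer(fun, defaultTypologySplit("managed"), seed = 8)
  fx <- simulateIndividualFixes(st$landscape, st$truth, n_fixes = 40,
                                accuracy_sd_m = 0, road_gps_sd_m = 0, seed = 9)
  f <- fixes(fx)
  expect_equal(f$x_m, f$true_x_m)
  expect_equal(f$y_m, f$true_y_m)
})

test_that("35-m noise gives the Rayleigh mean radial displacement", {
  # closed form: E[radius] = sd * sqrt(pi / 2) ~ 43.87 m at sd = 35
  fun <- generateFunctionalLandscape(managedSpec(seed = 71))
  st <- attachStructuralLayer(fun, defaultTypologySplit("managed"), seed = 10)
  fx <- simulateIndividualFixes(st$landscape, st$truth, n_fixes = 10000,
                                accuracy_sd_m = 35, road_gps_sd_m = 35,
                                seed = 11)
  f <- fixes(fx)
  disp <- sqrt((f$x_m - f$true_x_m)^2 + (f$y_m - f$true_y_m)^2)
  expect_equal(mean(disp), 35 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("fix simulation fails when a required class is missing", {
  sp <- LandscapeSpec(c(60L, 60L), config = "interspersed",
                      composition = c("breeding" = 0.5, "roosting" = 0.5),
                      patchScale = 100, seed = 1)
  fun <- generateFunctionalLandscape(sp)
  st <- attachStructuralLayer(fun, list("breeding" = c(shrub = 1),
                                        "roosting" = c(pine = 1)), seed = 2)
  expect_error(simulateIndividualFixes(st$landscape, st$truth, 20, seed = 3),
               "foraging")
})

test_that("abundance series: equal rates give a well-behaved null", {
  nonsig <- vapply(1:100, function(s) {
    ab <- generateAbundanceSeries(74, 1.5, 1.5, seed = s)
    wilcoxonSignedRank(ab$rate_a, ab$rate_b)$p.value > 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.9)
})

test_that("abundance series: a doubled rate is detected at n = 74", {
  sig <- vapply(1:50, function(s) {
    ab <- generateAbundanceSeries(74, 1, 2, seed = 1000 + s)
    wilcoxonSignedRank(ab$rate_b, ab$rate_a)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})

test_that("abundance series handles the degenerate single zero week", {
  ab <- generateAbundanceSeries(1, 0, 0, seed = 1)
  expect_identical(nrow(ab), 1L)
  expect_equal(ab$rate_a, 0)
  expect_equal(ab$rate_b, 0)
})
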