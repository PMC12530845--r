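fixture_drivers <- function(g, seed = 1) {
  withr::with_seed(seed, {
    elev <- matrix(runif(g$n_rows * g$n_cols, 0, 200), g$n_rows)
    driver_stack(list(
      elevation = raster_layer(elev, g, "elevation"),
      noise = raster_layer(matrix(runif(g$n_rows * g$n_cols), g$n_rows), g, "noise"),
      flat = raster_layer(matrix(1, g$n_rows, g$n_cols), g, "flat")))
  })
}

test_that("expansion sampling counts positives by construction", {
  g <- grid_spec(10, 10, 30)
  m1 <- lulc_map(matrix(2L, 10, 10), g)
  drv <- fixture_drivers(g)
  # no change -> zero positives, warning
  expect_warning(s0 <- extract_expansion_samples(m1, m1, drv, 1L), "no expansion")
  expect_equal(length(s0$label), 0L)
  # exactly 3 new farmland cells -> 3 positive rows
  m2 <- m1; m2$codes[c(5, 17, 60)] <- 1L
  m2 <- lulc_map(m2$codes, g)
  s <- extract_expansion_samples(m1, m2, drv, 1L, seed = 4)
  expect_equal(sum(s$label == 1L), 3L)
  expect_equal(sum(s$label == 0L), 3L)  # 1:1 background ratio
  # fixed seed -> identical samples
  s2 <- extract_expansion_samples(m1, m2, drv, 1L, seed = 4)
  expect_identical(s$cells, s2$cells)
  expect_equal(s$features, s2$features)
})

test_that("development probability learns a separable expansion rule", {
  g <- grid_spec(30, 30, 30)
  drv <- fixture_drivers(g, seed = 8)
  elev <- drv$layers$elevation$values
  m1 <- lulc_map(matrix(2L, 30, 30), g)
  codes2 <- m1$codes
  codes2[elev < 100] <- 1L  # expansion iff low elevation, noise-free
  m2 <- lulc_map(codes2, g)
  s <- extract_expansion_samples(m1, m2, drv, 1L, seed = 3)
  fit <- fit_development_probability(s, drv, seed = 3, num_trees = 100)
  p <- fit$probability$values
  expect_gt(mean(p[elev < 80]), 0.9)
  expect_lt(mean(p[elev > 120]), 0.1)
  imp <- fit$importance
  expect_equal(imp$driver[1], "elevation")
  expect_lt(imp$importance[imp$driver == "flat"], 0.01)  # constant driver useless
  expect_equal(sum(imp$importance), 1)
  # same seed -> identical surface
  fit2 <- fit_development_probability(s, drv, seed = 3, num_trees = 100)
  expect_identical(fit$probability$values, fit2$probability$values)
})

test_that("neighbourhood density matches hand counts", {
  g <- grid_spec(5, 5, 30)
  uni <- lulc_map(matrix(1L, 5, 5), g)
  expect_equal(neighborhood_effect(uni, 1L, 1)$values, matrix(1, 5, 5))
  one <- matrix(2L, 5, 5); one[3, 3] <- 1L
  ne <- neighborhood_effect(lulc_map(one, g), 1L, 1)
  expect_equal(ne$values[2, 2], 1 / 9)   # interior neighbour
  expect_equal(ne$values[3, 3], 1 / 9)
  expect_equal(ne$values[1, 1], 0)
  # corner window is truncated to 4 cells
  crn <- matrix(2L, 5, 5); crn[1, 1] <- 1L
  expect_equal(neighborhood_effect(lulc_map(crn, g), 1L, 1)$values[1, 1], 1 / 4)
  rnd <- random_lulc(12, 12, seed = 3)
  v <- neighborhood_effect(rnd, 2L, 2)$values
  expect_true(all(v >= 0 & v <= 1))
})

flat_probs <- function(g, classes, p = 0.8) {
  out <- lapply(classes, function(k)
    raster_layer(matrix(p, g$n_rows, g$n_cols), g, sprintf("p%d", k)))
  names(out) <- as.character(classes)
  out
}

test_that("allocation meets demand exactly on feasible toys and is inert at equilibrium", {
  m <- random_lulc(20, 20, seed = 14, cell_size = 1000)
  # demand = current areas -> nothing converts
  dem0 <- class_areas(m)[, c("code", "area_km2")]
  out0 <- allocate(m, dem0, flat_probs(m$grid, 1:7),
                   allocation_config(rng_seed = 5))
  expect_identical(out0$codes, m$codes)
  expect_true(attr(out0, "converged"))
  expect_equal(attr(out0, "iterations"), 0L)
  # move 10 cells forest -> farmland, tolerance 0
  dem <- dem0
  ca <- cell_area_km2(m$grid)
  dem$area_km2[dem$code == 1] <- dem$area_km2[dem$code == 1] + 10 * ca
  dem$area_km2[dem$code == 2] <- dem$area_km2[dem$code == 2] - 10 * ca
  out <- allocate(m, dem, flat_probs(m$grid, 1:7),
                  allocation_config(rng_seed = 5, demand_tolerance = 0))
  expect_true(attr(out, "converged"))
  expect_equal(sum(out$codes == 1L) - sum(m$codes == 1L), 10L)
  expect_equal(sum(out$codes == 2L) - sum(m$codes == 2L), -10L)
  expect_equal(attr(out, "residual")$residual_km2, rep(0, 7))
  # conservation: same multiset of valid cells
  expect_equal(sum(out$codes != out$grid$nodata_code),
               sum(m$codes != m$grid$nodata_code))
  # only forest cells changed
  changed <- which(out$codes != m$codes)
  expect_true(all(m$codes[changed] == 2L))
})

test_that("allocation is deterministic under a fixed seed and respects the mask", {
  m <- random_lulc(20, 20, seed = 23, cell_size = 1000)
  ca <- cell_area_km2(m$grid)
  dem <- class_areas(m)[, c("code", "area_km2")]
  dem$area_km2[dem$code == 1] <- dem$area_km2[dem$code == 1] + 8 * ca
  dem$area_km2[dem$code == 2] <- dem$area_km2[dem$code == 2] - 8 * ca
  cfg <- allocation_config(rng_seed = 77)
  a <- allocate(m, dem, flat_probs(m$grid, 1:7), cfg)
  b <- allocate(m, dem, flat_probs(m$grid, 1:7), cfg)
  expect_identical(a$codes, b$codes)
  # full mask over forest: infeasible, zero conversions, residual flagged
  mask <- matrix(m$codes == 2L, 20, 20)
  cfg_m <- allocation_config(rng_seed = 77, restricted_mask = mask,
                             max_iterations = 30)
  expect_warning(blocked <- allocate(m, dem, flat_probs(m$grid, 1:7), cfg_m),
                 "did not meet demand")
  expect_identical(blocked$codes[mask], m$codes[mask])
  expect_false(attr(blocked, "converged"))
  expect_true(any(attr(blocked, "residual")$residual_km2 != 0))
})

test_that("allocation prefers high development-probability cells", {
  g <- grid_spec(30, 30, 1000)
  m <- lulc_map(matrix(2L, 30, 30), g)
  pv <- withr::with_seed(3, matrix(runif(900), 30))
  probs <- list(`1` = raster_layer(pv, g, "p1"))
  ca <- cell_area_km2(g)
  dem <- class_areas(m)[, c("code", "area_km2")]
  dem$area_km2[dem$code == 1] <- 60 * ca
  dem$area_km2[dem$code == 2] <- dem$area_km2[dem$code == 2] - 60 * ca
  out <- allocate(m, dem, probs, allocation_config(rng_seed = 2))
  converted <- which(out$codes == 1L)
  expect_gt(mean(pv[converted]), mean(pv))
})

test_that("conversion-cost gating forbids disallowed transitions", {
  m <- random_lulc(15, 15, seed = 31, cell_size = 1000)
  ca <- cell_area_km2(m$grid)
  dem <- class_areas(m)[, c("code", "area_km2")]
  dem$area_km2[dem$code == 6] <- dem$area_km2[dem$code == 6] + 5 * ca
  dem$area_km2[dem$code == 2] <- dem$area_km2[dem$code == 2] - 5 * ca
  cost <- matrix(1, 7, 7)
  cost[5, 6] <- 0  # water may never become construction
  out <- suppressWarnings(
    allocate(m, dem, flat_probs(m$grid, 1:7),
             allocation_config(rng_seed = 3, conversion_cost = cost,
                               max_iterations = 40)))
  became_constr <- which(out$codes == 6L & m$codes != 6L)
  expect_true(all(m$codes[became_constr] != 5L))
})
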