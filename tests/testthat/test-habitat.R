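test_that("decay weights match their closed forms", {
  th <- default_threats()
  expect_equal(decay_weight(0, th$farmland), 1)
  expect_equal(decay_weight(0, th$construction), 1)
  expect_equal(decay_weight(1, th$farmland), 0)          # linear at d_max
  expect_equal(decay_weight(0.25, th$farmland), 0.75)
  expect_equal(decay_weight(10, th$construction), exp(-2.99))
  expect_equal(decay_weight(5, th$construction), exp(-2.99 / 2))
  expect_equal(decay_weight(10.001, th$construction), 0)  # cut beyond d_max
  expect_equal(decay_weight(1.5, th$farmland), 0)
  expect_error(decay_weight(-1, th$farmland), "non-negative")
})

test_that("threat presence counts equal the class histogram", {
  m <- random_lulc(12, 12, seed = 21)
  for (th in default_threats()) {
    pres <- threat_presence(m, th)
    expect_equal(sum(pres$values), sum(lulc_values(m) == th$source_class))
  }
  forest <- toy_map(matrix(2L, 4, 4))
  expect_equal(sum(threat_presence(forest, default_threats()$farmland)$values), 0)
})

test_that("degradation is zero without sources and weight-scale invariant", {
  forest <- toy_map(matrix(2L, 6, 6))
  D <- compute_degradation(forest)
  expect_true(all(D$values == 0))
  # doubling all weights changes nothing (normalised)
  m <- random_lulc(10, 10, seed = 31)
  th2 <- default_threats()
  th2$farmland$weight <- th2$farmland$weight * 2
  th2$construction$weight <- th2$construction$weight * 2
  expect_equal(compute_degradation(m, th2)$values,
               compute_degradation(m)$values, tolerance = 1e-12)
})

test_that("degradation reproduces the hand-evaluated formula chain", {
  # one construction cell; forest 5 km away on a 1 km grid
  codes <- matrix(2L, 1, 11); codes[1, 1] <- 6L
  m <- toy_map(codes, cell_size = 1000)
  D <- compute_degradation(m)
  # w_constr/(w_farm+w_constr) * exp(-2.99*5/10) * beta * S_forest,constr
  expect_equal(D$values[1, 6], (1 / 1.4) * exp(-2.99 * 5 / 10) * 1 * 0.5,
               tolerance = 1e-12)
})

test_that("degradation matches the brute-force all-pairs oracle to 1e-9", {
  for (seed in c(2, 13, 44)) {
    m <- random_lulc(sample(8:20, 1), sample(8:20, 1), seed = seed,
                     cell_size = 800)
    D <- compute_degradation(m)
    expect_equal(D$values, bf_degradation(m), tolerance = 1e-9)
  }
})

test_that("mirroring the landscape mirrors degradation and quality exactly", {
  m <- random_lulc(9, 14, seed = 55)
  mir <- lulc_map(m$codes[, ncol(m$codes):1], m$grid, m$class_labels)
  hq <- habitat_quality(m)
  hq_m <- habitat_quality(mir)
  expect_equal(hq_m$degradation$values,
               hq$degradation$values[, ncol(m$codes):1], tolerance = 1e-12)
  expect_equal(hq_m$quality$values,
               hq$quality$values[, ncol(m$codes):1], tolerance = 1e-12)
})

test_that("adding a threat source never raises quality anywhere", {
  for (seed in c(5, 17)) {
    m <- withr::with_seed(seed,
      toy_map(matrix(sample(c(2L, 4L, 5L), 144, replace = TRUE), 12)))
    q0 <- habitat_quality(m)$quality$values
    m2 <- m
    free <- which(m$codes != 6L)
    m2$codes[withr::with_seed(seed, sample(free, 1))] <- 6L
    q1 <- habitat_quality(m2)$quality$values
    keep <- m2$codes == m$codes
    expect_true(all(q1[keep] <= q0[keep] + 1e-12))
  }
})

test_that("quality follows the half-saturation transform", {
  sens <- default_sensitivity()
  cfg <- habitat_config(k = 0.5)
  m <- toy_map(matrix(2L, 2, 2))
  # D = 0 -> Q = H
  expect_equal(compute_quality(m, raster_layer(matrix(0, 2, 2), m$grid), sens, cfg)$values,
               matrix(1, 2, 2))
  # D = k -> Q = H/2
  expect_equal(compute_quality(m, raster_layer(matrix(0.5, 2, 2), m$grid), sens, cfg)$values,
               matrix(0.5, 2, 2))
  # construction has H = 0 -> Q = 0 at any degradation
  mc <- toy_map(matrix(6L, 2, 2))
  expect_equal(compute_quality(mc, raster_layer(matrix(0.9, 2, 2), m$grid), sens, cfg)$values,
               matrix(0, 2, 2))
  # bounds: 0 <= Q <= H_j, 0 <= D <= 1 on a random mosaic
  mm <- random_lulc(15, 15, seed = 61)
  hq <- habitat_quality(mm)
  H <- matrix(sens$suitability[match(mm$codes, sens$code)], 15, 15)
  expect_true(all(hq$quality$values <= H + 1e-12))
  expect_true(all(hq$quality$values >= 0))
  expect_true(all(hq$degradation$values >= 0 & hq$degradation$values <= 1))
})

test_that("grade classification uses left-closed intervals with 1 in the top grade", {
  g <- grid_spec(1, 6, 30)
  q <- raster_layer(matrix(c(0, 0.297, 0.298, 0.698, 0.984, 1), 1), g)
  grades <- classify_quality(q)
  expect_equal(as.vector(grades$values), c(1, 1, 2, 3, 4, 4))
  q2 <- raster_layer(matrix(0.99, 1, 1), grid_spec(1, 1, 30))
  expect_equal(classify_quality(q2)$values[1, 1], 4)  # excellent
})

test_that("jenks breaks match the exhaustive-partition oracle", {
  expect_equal(jenks_breaks(c(0.1, 0.11, 0.9, 0.91), 2), 0.9)
  for (seed in c(1, 2, 3)) {
    x <- withr::with_seed(seed, round(runif(sample(6:12, 1)), 3))
    for (k in 2:3) {
      got <- jenks_breaks(x, k)
      oracle <- bf_jenks(x, k)
      expect_equal(goodness_of_variance_fit(x, got),
                   goodness_of_variance_fit(x, oracle$breaks), tolerance = 1e-12)
      # no random partition beats the returned breaks
      gvf <- goodness_of_variance_fit(x, got)
      for (r in 1:20) {
        cand <- sort(withr::with_seed(seed * 100 + r, sample(x, k - 1)))
        expect_true(gvf >= goodness_of_variance_fit(x, cand) - 1e-12)
      }
    }
  }
  # each distinct value its own class
  expect_equal(jenks_breaks(c(1, 2, 3), 3), c(2, 3))
  expect_warning(b <- jenks_breaks(rep(0.5, 5), 2), "degenerate")
  expect_equal(b, 0.5)
})

test_that("grade summary reports areas, proportions and landscape means", {
  g <- grid_spec(2, 2, 1000)
  q <- raster_layer(matrix(c(1, 0.99, 0.5, 0.1), 2), g)
  d <- raster_layer(matrix(c(0, 0.01, 0.4, 0.9), 2), g)
  grades <- classify_quality(q)
  gs <- grade_summary(grades, q, d)
  expect_equal(sum(gs$area_km2), 4)
  expect_equal(sum(gs$proportion), 1)
  expect_equal(attr(gs, "mean_quality"), mean(c(1, 0.99, 0.5, 0.1)))
  expect_equal(attr(gs, "mean_degradation"), mean(c(0, 0.01, 0.4, 0.9)))
  # uniform Q = 1 -> all area excellent
  q1 <- raster_layer(matrix(1, 2, 2), g)
  gs1 <- grade_summary(classify_quality(q1), q1, raster_layer(matrix(0, 2, 2), g))
  expect_equal(gs1$proportion[gs1$grade == "Excellent"], 1)
  expect_equal(attr(gs1, "mean_quality"), 1)
})

test_that("mean-over-sources aggregation stays within [0,1] and below-or-equal nearest at the source-free far field", {
  m <- random_lulc(10, 10, seed = 77, cell_size = 500)
  near <- compute_degradation(m, config = habitat_config(aggregation = "nearest"))
  avg <- compute_degradation(m, config = habitat_config(aggregation = "mean"))
  expect_true(all(avg$values >= -1e-12 & avg$values <= 1 + 1e-12))
  expect_true(all(avg$values <= near$values + 1e-9))
})
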