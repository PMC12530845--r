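toy_tm <- function(S, labels = NULL) {
  n <- nrow(S)
  labels <- labels %||% lulc_classes()[seq_len(n), ]
  dimnames(S) <- list(labels$name, labels$name)
  structure(list(areas = S, counts = S, labels = labels,
                 period = c("t1", "t2"), cell_area = 1),
            class = "transition_matrix")
}

test_that("row-normalisation yields a stochastic matrix", {
  S <- diag(c(3, 5, 2))
  P <- estimate_transition_probabilities(toy_tm(S))
  expect_equal(unname(P$probs), diag(3))
  S2 <- rbind(c(1, 1, 2), c(0, 4, 0), c(1, 0, 1))
  P2 <- estimate_transition_probabilities(toy_tm(S2))
  expect_equal(unname(P2$probs[1, ]), c(0.25, 0.25, 0.5))
  for (seed in 1:3) {
    S3 <- withr::with_seed(seed, matrix(runif(49), 7))
    P3 <- estimate_transition_probabilities(toy_tm(S3, lulc_classes()))
    expect_equal(unname(rowSums(P3$probs)), rep(1, 7), tolerance = 1e-9)
  }
})

test_that("empty first-epoch classes get identity rows with a warning", {
  S <- rbind(c(2, 1, 0), c(0, 0, 0), c(0, 0, 3))
  expect_warning(P <- estimate_transition_probabilities(toy_tm(S)), "identity rows")
  expect_equal(unname(P$probs[2, ]), c(0, 1, 0))
  expect_equal(unname(rowSums(P$probs)), rep(1, 3))
})

test_that("scenario multipliers adjust off-diagonals and renormalise via the diagonal", {
  S <- rbind(c(0.8, 0.1, 0.1), c(0, 1, 0), c(0, 0, 1)) * 10
  P <- estimate_transition_probabilities(toy_tm(S))
  adj <- scenario_adjustment(
    tibble::tibble(from = c(1L, 1L), to = c(2L, 3L), multiplier = 1.5))
  P2 <- apply_scenario(P, adj)
  expect_equal(unname(P2$probs[1, ]), c(0.70, 0.15, 0.15))
  expect_equal(unname(rowSums(P2$probs)), rep(1, 3))
  # empty rule set leaves P untouched
  expect_equal(apply_scenario(P, scenario_nd())$probs, P$probs)
  # degenerate residual: off-diagonals rescaled proportionally, diagonal 0
  S3 <- rbind(c(0.1, 0.5, 0.4), c(0, 1, 0), c(0, 0, 1)) * 10
  P3 <- estimate_transition_probabilities(toy_tm(S3))
  big <- scenario_adjustment(
    tibble::tibble(from = c(1L, 1L), to = c(2L, 3L), multiplier = 3))
  P4 <- apply_scenario(P3, big)
  expect_equal(P4$probs[1, 1], 0)
  expect_equal(unname(P4$probs[1, 2:3]), c(1.5, 1.2) / 2.7)
  expect_equal(unname(rowSums(P4$probs)), rep(1, 3))
})

test_that("EP preset moves probabilities in the protective direction", {
  for (seed in 1:3) {
    S <- withr::with_seed(seed, matrix(runif(49, 0.01, 1), 7))
    diag(S) <- diag(S) + 5
    P <- estimate_transition_probabilities(toy_tm(S, lulc_classes()))
    Pe <- apply_scenario(P, scenario_ep())
    expect_equal(unname(rowSums(Pe$probs)), rep(1, 7), tolerance = 1e-9)
    expect_true(Pe$probs[2, 1] <= P$probs[2, 1])       # forest -> farmland never up
    expect_true(Pe$probs[1, 2] >= P$probs[1, 2])       # farmland -> forest never down
    expect_equal(Pe$probs[2, 5], P$probs[2, 5])        # forest -> water untouched
  }
})

test_that("demand projection is a conserved matrix power", {
  labs <- lulc_classes()[1:2, ]
  P <- structure(list(probs = matrix(c(0.5, 0, 0.5, 1), 2,
                                     dimnames = list(labs$name, labs$name)),
                      labels = labs, period_years = 14L),
                 class = "transition_probability_matrix")
  d <- project_demand(P, c(100, 0), steps = 1)
  expect_equal(d$area_km2, c(50, 50))
  d2 <- project_demand(P, c(100, 0), steps = 2)
  expect_equal(d2$area_km2, c(25, 75))
  # identity P: demand = areas for any steps
  I <- P; I$probs <- diag(2); dimnames(I$probs) <- dimnames(P$probs)
  expect_equal(project_demand(I, c(30, 70), steps = 5)$area_km2, c(30, 70))
  # conservation for random stochastic P
  for (seed in 1:3) {
    M <- withr::with_seed(seed, matrix(runif(49), 7))
    M <- M / rowSums(M)
    labs7 <- lulc_classes()
    dimnames(M) <- list(labs7$name, labs7$name)
    P7 <- structure(list(probs = M, labels = labs7, period_years = 14L),
                    class = "transition_probability_matrix")
    a <- withr::with_seed(seed, runif(7, 0, 100))
    expect_equal(sum(project_demand(P7, a)$area_km2), sum(a), tolerance = 1e-6)
  }
})

test_that("transition probabilities are recovered from sampled transitions", {
  # 10^5-cell parameter recovery: sample per-cell transitions from known P
  labs <- lulc_classes()[1:4, ]
  P_true <- rbind(c(0.85, 0.10, 0.03, 0.02),
                  c(0.05, 0.90, 0.02, 0.03),
                  c(0.10, 0.10, 0.75, 0.05),
                  c(0.02, 0.08, 0.10, 0.80))
  nr <- 320; nc <- 320  # 102,400 cells
  codes1 <- withr::with_seed(91, matrix(sample(1:4, nr * nc, replace = TRUE,
                                               prob = c(0.3, 0.4, 0.15, 0.15)), nr))
  codes2 <- withr::with_seed(92, {
    out <- codes1
    for (i in 1:4) {
      idx <- which(codes1 == i)
      out[idx] <- sample(1:4, length(idx), replace = TRUE, prob = P_true[i, ])
    }
    out
  })
  g <- grid_spec(nr, nc, 30)
  m1 <- lulc_map(codes1, g, labs); m2 <- lulc_map(codes2, g, labs)
  P_hat <- estimate_transition_probabilities(compute_transition_matrix(m1, m2))
  n_min <- min(table(codes1))
  # multinomial sampling error bound: 4 sigma at the smallest class count
  tol <- 4 * sqrt(0.25 / n_min)
  expect_true(max(abs(P_hat$probs - P_true)) < tol)
  expect_equal(unname(rowSums(P_hat$probs)), rep(1, 4), tolerance = 1e-9)
})
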