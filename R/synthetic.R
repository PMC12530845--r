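# Seed-reproducible synthetic landscapes with the statistical structure the
# pipeline assumes: a patchy mosaic dominated by forest, farmland at its
# edges, smooth correlated driver fields and a core-area conservation mask.

# smooth Gaussian random field via FFT convolution with a Gaussian kernel
# (periodic boundary), standardised to mean 0 / sd 1
smooth_field <- function(n_rows, n_cols, scale) {
  noise <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (scale <= 0) return(noise)
  di <- pmin(0:(n_rows - 1), n_rows - (0:(n_rows - 1)))
  dj <- pmin(0:(n_cols - 1), n_cols - (0:(n_cols - 1)))
  kern <- exp(-outer(di^2, dj^2, `+`) / (2 * scale^2))
  kern <- kern / sum(kern)
  sm <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / (n_rows * n_cols)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Specify a synthetic landscape
#'
#' @param grid A [grid_spec()].
#' @param class_fractions Named (by code) target fractions summing to 1.
#'   Default mimics a forest-dominated mountainous mosaic: forest 0.90,
#'   farmland 0.06, water 0.02, the remaining classes 0.02 together.
#' @param patch_scale Correlation length of the underlying random fields, in
#'   cells.
#' @param redline_fraction Fraction of the dominant natural class's area
#'   covered by the restricted-conversion (conservation redline) mask.
#' @param rng_seed Integer seed; identical specs generate identical output.
#' @return Object of class `landscape_spec`.
#' @export
landscape_spec <- function(grid,
                           class_fractions = c(`1` = 0.06, `2` = 0.90,
                                               `3` = 0.007, `4` = 0.007,
                                               `5` = 0.02, `6` = 0.005,
                                               `7` = 0.001),
                           patch_scale = 8,
                           redline_fraction = 0.5,
                           rng_seed = 1L) {
  if (abs(sum(class_fractions) - 1) > 1e-6)
    abort("class fractions must sum to 1")
  if (redline_fraction < 0 || redline_fraction > 1)
    abort("redline_fraction must lie in [0, 1]")
  structure(list(grid = grid, class_fractions = class_fractions,
                 patch_scale = patch_scale,
                 redline_fraction = redline_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "landscape_spec")
}

#' Generate a synthetic landscape, driver stack and redline mask
#'
#' The land-cover mosaic is built by cutting a smoothed seeded random field
#' at the quantiles of the target class fractions, ordered so that farmland
#' bands sit at the forest edge (water in valleys, construction near
#' farmland, forest on the high end). Drivers comprise a correlated elevation
#' field with derived slope and aspect, Euclidean distances to seeded random
#' linear features (roads) and to water cells, population/GDP fields
#' negatively correlated with elevation, temperature (lapse-rate linked to
#' elevation), precipitation, and a categorical soil class from elevation
#' bands. The mask covers `redline_fraction` of the dominant natural class,
#' preferring core (interior) cells.
#'
#' @param spec A [landscape_spec()].
#' @return List with `lulc` ([lulc_map()]), `drivers` ([driver_stack()]) and
#'   `mask` (0/1 [raster_layer()]).
#' @export
generate_landscape <- function(spec) {
  g <- spec$grid
  nr <- g$n_rows; nc <- g$n_cols
  withr::with_seed(spec$rng_seed, {
    base <- smooth_field(nr, nc, spec$patch_scale)
    # low field -> water/construction/farmland, high -> forest
    order_codes <- c(5L, 6L, 7L, 4L, 3L, 1L, 2L)
    fr <- spec$class_fractions[as.character(order_codes)]
    if (any(is.na(fr))) abort("class_fractions must be named by codes 1..7")
    cuts <- quantile(base, probs = cumsum(fr)[-length(fr)], names = FALSE)
    codes <- matrix(order_codes[findInterval(base, cuts) + 1L], nr, nc)
    lulc <- lulc_map(codes, g, epoch_label = "t1")

    elev_field <- 0.7 * base + 0.3 * smooth_field(nr, nc, spec$patch_scale)
    elev <- pmax(600 + 450 * elev_field, 0)
    cs <- g$cell_size
    gx <- (elev[, c(2:nc, nc)] - elev[, c(1, 1:(nc - 1))]) / (2 * cs)
    gy <- (elev[c(2:nr, nr), ] - elev[c(1, 1:(nr - 1)), ]) / (2 * cs)
    slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
    aspect <- (atan2(gy, gx) * 180 / pi) %% 360

    road <- matrix(FALSE, nr, nc)
    for (k in 1:3) {
      r <- sample.int(nr, 1); c0 <- 1
      while (c0 <= nc) {
        road[r, c0] <- TRUE
        r <- min(max(r + sample(-1:1, 1), 1), nr)
        c0 <- c0 + 1
      }
    }
    dist_road <- distance_to_cells(road, g)
    dist_water <- distance_to_cells(codes == 5L, g)

    pop <- exp(-(elev - min(elev)) / 400) *
      exp(0.5 * smooth_field(nr, nc, spec$patch_scale / 2)) * 100
    gdp <- pop * exp(0.3 * smooth_field(nr, nc, spec$patch_scale / 2)) * 10
    temperature <- 24.5 - 0.006 * elev + 0.3 * smooth_field(nr, nc, spec$patch_scale)
    precipitation <- 1300 + 500 * stats::plogis(smooth_field(nr, nc, spec$patch_scale))
    soil <- findInterval(elev, quantile(elev, c(0.4, 0.7, 0.9), names = FALSE)) + 1L

    drivers <- driver_stack(list(
      elevation = raster_layer(elev, g, "elevation"),
      slope = raster_layer(slope, g, "slope"),
      aspect = raster_layer(aspect, g, "aspect"),
      dist_road = raster_layer(dist_road, g, "dist_road"),
      dist_water = raster_layer(dist_water, g, "dist_water"),
      pop_density = raster_layer(pop, g, "pop_density"),
      gdp = raster_layer(gdp, g, "gdp"),
      temperature = raster_layer(temperature, g, "temperature"),
      precipitation = raster_layer(precipitation, g, "precipitation"),
      soil = raster_layer(matrix(soil, nr, nc), g, "soil", categorical = TRUE)))

    dominant <- as.integer(names(which.max(spec$class_fractions)))
    inner <- neighborhood_effect(lulc, dominant, 1)$values
    is_dom <- codes == dominant
    n_mask <- round(spec$redline_fraction * sum(is_dom))
    cand <- which(is_dom)
    # core first: rank by neighbourhood density, ties broken reproducibly
    ord <- order(inner[cand], runif(length(cand)), decreasing = TRUE)
    mask <- matrix(0, nr, nc)
    mask[cand[ord[seq_len(n_mask)]]] <- 1
    list(lulc = lulc, drivers = drivers,
         mask = raster_layer(mask, g, "redline"))
  })
}

#' A land-change rule
#'
#' @param from,to Class codes.
#' @param n_cells Exact number of cells to convert.
#' @param adjacency `"edge"` (conversion biased to cells bordering the
#'   destination class and to low elevation) or `"random"`.
#' @return One-row tibble.
#' @export
change_rule <- function(from, to, n_cells, adjacency = c("edge", "random")) {
  adjacency <- match.arg(adjacency)
  tibble(from = as.integer(from), to = as.integer(to),
         n_cells = as.integer(n_cells), adjacency = adjacency)
}

#' Apply land-change rules to generate a second epoch
#'
#' Converts exactly `n_cells` cells per rule (rules applied in order).
#' Edge-biased rules draw source cells with probability elevated for cells
#' 8-adjacent to the destination class and for low-elevation cells; random
#' rules draw uniformly. Errors if a rule exceeds the available source cells.
#'
#' @param t1 Base [lulc_map()].
#' @param rules Tibble of [change_rule()]s.
#' @param drivers Optional [driver_stack()] providing `elevation` for the
#'   low-elevation bias.
#' @param seed Integer RNG seed.
#' @return The second-epoch [lulc_map()] (`epoch_label = "t2"`).
#' @export
generate_change <- function(t1, rules, drivers = NULL, seed = 1L) {
  codes <- t1$codes
  g <- t1$grid
  elev <- if (!is.null(drivers) && !is.null(drivers$layers$elevation))
    drivers$layers$elevation$values else NULL
  withr::with_seed(seed, {
    for (r in seq_len(nrow(rules))) {
      from <- rules$from[r]; to <- rules$to[r]; n <- rules$n_cells[r]
      src <- which(codes == from)
      if (length(src) < n)
        abort(sprintf("rule %d->%d infeasible: %d source cells < %d requested",
                      from, to, length(src), n))
      if (n == 0) next
      w <- rep(1, length(src))
      if (rules$adjacency[r] == "edge") {
        dest_dens <- box_sum((codes == to) * 1, 1)
        w <- w + 20 * (dest_dens[src] > 0)
        if (!is.null(elev)) {
          e <- elev[src]
          w <- w * exp(-2 * (e - min(e)) / max(diff(range(e)), 1e-9))
        }
      }
      pick <- if (length(src) == 1) src else sample(src, n, prob = w)
      codes[pick] <- to
    }
  })
  lulc_map(codes, g, t1$class_labels, epoch_label = "t2")
}
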