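# Simplified patch-generating land-use simulation: expansion-sample mining,
# tree-ensemble development probabilities and a multi-seed CA allocator.
# Parity with the released PLUS desktop software is not a goal; the mechanism
# (development probability x neighbourhood x random seeds under conversion
# constraints and a restricted mask) is.

#' Bundle co-registered driver rasters
#'
#' @param layers Named list of [raster_layer()]s sharing one grid;
#'   categorical layers (e.g. soil class) must be flagged on the layer.
#' @return Object of class `driver_stack`.
#' @export
driver_stack <- function(layers) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    abort("driver layers must be named")
  g <- layers[[1]]$grid
  for (l in layers) stop_if_grid_mismatch(g, l$grid, "driver layers")
  structure(list(layers = layers, grid = g), class = "driver_stack")
}

#' @export
print.driver_stack <- function(x, ...) {
  cat(sprintf("<driver_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

# feature matrix (data.frame) for linear cell indices; categorical layers are
# one-hot encoded against their full-layer level set
driver_features <- function(drivers, idx) {
  cols <- list()
  for (nm in names(drivers$layers)) {
    l <- drivers$layers[[nm]]
    v <- l$values[idx]
    if (l$categorical) {
      lev <- sort(unique(as.vector(l$values[!is.na(l$values)])))
      for (k in lev) cols[[paste0(nm, "_", k)]] <- as.numeric(v == k)
    } else {
      cols[[nm]] <- v
    }
  }
  as.data.frame(cols)
}

#' Mine land-expansion samples for one class
#'
#' Positives are all cells that newly converted to `target_class` between the
#' two epochs (`m1 != target`, `m2 == target`); negatives are a seeded random
#' background sample of the remaining jointly valid cells, of size
#' `background_ratio` times the positive count. Features are the driver
#' values at the sampled cells (categorical drivers one-hot encoded).
#'
#' @param m1,m2 [lulc_map()]s at the two epochs.
#' @param drivers A [driver_stack()] on the same grid.
#' @param target_class Class code whose expansion is mined.
#' @param background_ratio Negatives per positive (default 1).
#' @param seed Integer RNG seed for the background sample.
#' @return Object of class `expansion_samples` (`features` data frame,
#'   binary `label`, linear cell `cells`, `target_class`, `seed`). Empty with
#'   a warning when the class did not expand.
#' @export
extract_expansion_samples <- function(m1, m2, drivers, target_class,
                                      background_ratio = 1, seed = 1L) {
  stop_if_grid_mismatch(m1$grid, m2$grid, "the two epochs")
  stop_if_grid_mismatch(m1$grid, drivers$grid, "maps and drivers")
  ok <- valid_mask(m1) & valid_mask(m2)
  pos <- which(ok & m1$codes != target_class & m2$codes == target_class)
  if (length(pos) == 0) {
    warn(sprintf("class %d has no expansion cells", target_class))
    return(structure(list(features = data.frame(), label = integer(),
                          cells = integer(), target_class = target_class,
                          seed = seed),
                     class = "expansion_samples"))
  }
  bg_pool <- setdiff(which(ok), pos)
  n_neg <- min(length(bg_pool), round(background_ratio * length(pos)))
  neg <- withr::with_seed(seed, sample(bg_pool, n_neg))
  cells <- c(pos, neg)
  structure(list(features = driver_features(drivers, cells),
                 label = rep(c(1L, 0L), c(length(pos), n_neg)),
                 cells = cells, target_class = target_class, seed = seed),
            class = "expansion_samples")
}

#' Fit a development-probability surface from expansion samples
#'
#' Trains a seeded random forest (probability forest) on the expansion
#' samples and evaluates the positive-class probability at every cell where
#' all drivers are defined. Impurity importances are normalised to sum 1.
#'
#' @param samples An [extract_expansion_samples()] result with both labels.
#' @param drivers The [driver_stack()] used for sampling.
#' @param seed Integer seed for the forest.
#' @param num_trees Number of trees (default 200).
#' @param mtry Candidate features per split; defaults to half the features
#'   (rounded up), which keeps the probability surface sharp when only a few
#'   drivers are informative.
#' @param ... Further arguments passed to [ranger::ranger()].
#' @return Object of class `development_probability`: `probability` (a
#'   [raster_layer()] in \[0, 1\]), `importance` (tibble `driver`,
#'   `importance`), `target_class`, `fit` (the ranger object).
#' @export
fit_development_probability <- function(samples, drivers, seed = 1L,
                                        num_trees = 200, mtry = NULL, ...) {
  if (length(samples$label) == 0 || length(unique(samples$label)) < 2)
    abort("need samples of both labels to fit a development probability")
  df <- samples$features
  df$.label <- factor(samples$label, levels = c(0L, 1L))
  mtry <- mtry %||% max(1L, ceiling(ncol(samples$features) / 2))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    probability = TRUE, num.trees = num_trees, seed = seed,
    importance = "impurity", mtry = mtry, ...)
  g <- drivers$grid
  all_feat <- driver_features(drivers, seq_len(g$n_rows * g$n_cols))
  complete <- stats::complete.cases(all_feat)
  p <- rep(NA_real_, nrow(all_feat))
  if (any(complete))
    p[complete] <- stats::predict(fit, all_feat[complete, , drop = FALSE],
                                  seed = seed)$predictions[, "1"]
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  structure(
    list(probability = raster_layer(matrix(p, g$n_rows, g$n_cols), g,
                                    name = sprintf("p_dev_%d", samples$target_class)),
         importance = tibble(driver = names(imp), importance = as.numeric(imp)) |>
           dplyr::arrange(dplyr::desc(.data$importance)),
         target_class = samples$target_class, fit = fit),
    class = "development_probability")
}

#' @export
print.development_probability <- function(x, ...) {
  cat(sprintf("<development_probability> class %d; top drivers: %s\n",
              x$target_class,
              paste(head(x$importance$driver, 3), collapse = ", ")))
  invisible(x)
}

#' Tidy factor importances of a development-probability fit
#' @param x A `development_probability`.
#' @param ... Unused.
#' @return Tibble `driver`, `importance` (sums to 1).
#' @export
#' @exportS3Method generics::tidy
tidy.development_probability <- function(x, ...) x$importance

#' @export
#' @exportS3Method generics::glance
glance.development_probability <- function(x, ...) {
  tibble(target_class = x$target_class,
         num_trees = x$fit$num.trees,
         oob_brier = x$fit$prediction.error)
}

# box sums over (2r+1)^2 windows, truncated at edges, via integral image
box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- matrix(0, nr + 1, nc + 1)
  ii[-1, -1] <- m
  ii <- apply(ii, 2, cumsum)
  ii <- t(apply(ii, 1, cumsum))
  r1 <- pmax(outer(seq_len(nr), rep(1L, nc)) - r, 1)
  r2 <- pmin(outer(seq_len(nr), rep(1L, nc)) + r, nr)
  c1 <- pmax(outer(rep(1L, nr), seq_len(nc)) - r, 1)
  c2 <- pmin(outer(rep(1L, nr), seq_len(nc)) + r, nc)
  s <- ii[cbind(as.vector(r2 + 1), as.vector(c2 + 1))] -
    ii[cbind(as.vector(r1), as.vector(c2 + 1))] -
    ii[cbind(as.vector(r2 + 1), as.vector(c1))] +
    ii[cbind(as.vector(r1), as.vector(c1))]
  matrix(s, nr, nc)
}

#' Neighbourhood density of a class
#'
#' Fraction of cells of `class` within the `(2r+1)^2` window centred on each
#' cell, nodata excluded from both numerator and denominator; edge windows
#' are truncated.
#'
#' @param lulc An [lulc_map()].
#' @param class Class code.
#' @param radius Window radius in cells (>= 1).
#' @return A [raster_layer()] with values in \[0, 1\].
#' @export
neighborhood_effect <- function(lulc, class, radius = 1) {
  if (radius < 1) abort("radius must be >= 1")
  ok <- valid_mask(lulc)
  ind <- matrix(0, nrow(ok), ncol(ok))
  ind[ok & lulc$codes == class] <- 1
  num <- box_sum(ind, radius)
  den <- box_sum(ok * 1, radius)
  v <- matrix(0, nrow(ok), ncol(ok))
  v[den > 0] <- num[den > 0] / den[den > 0]
  v[!ok] <- NA_real_
  raster_layer(v, lulc$grid, name = sprintf("neigh_%d", class))
}

#' Cellular-automata allocation configuration
#'
#' @param neighborhood_radius Window radius in cells for the density term.
#' @param neighborhood_weight Named numeric, per-class weight on the density
#'   term (default 1 for every class).
#' @param conversion_cost n x n 0/1 matrix, `[i, j] = 1` when conversion
#'   i -> j is allowed (default all allowed).
#' @param patch_seed_fraction Scale of the spontaneous-seeding term added to
#'   the neighbourhood density (uniform draw in \[0, patch_seed_fraction\]),
#'   which lets new patches nucleate away from existing ones.
#' @param initial_threshold Starting conversion threshold on the candidate
#'   score.
#' @param threshold_decay Multiplier in (0, 1) applied when an iteration
#'   converts nothing.
#' @param demand_tolerance Convergence tolerance on per-class areas (km^2).
#' @param max_iterations Iteration cap.
#' @param rng_seed Integer seed controlling all stochastic terms.
#' @param restricted_mask Optional boolean matrix / 0-1 [raster_layer()];
#'   masked cells holding a protected class never convert.
#' @param protected_classes Codes protected under the mask (default forest,
#'   shrub, grass, water).
#' @return Object of class `allocation_config`.
#' @export
allocation_config <- function(neighborhood_radius = 2,
                              neighborhood_weight = NULL,
                              conversion_cost = NULL,
                              patch_seed_fraction = 0.1,
                              initial_threshold = 0.5,
                              threshold_decay = 0.5,
                              demand_tolerance = 0,
                              max_iterations = 200,
                              rng_seed = 1L,
                              restricted_mask = NULL,
                              protected_classes = c(2L, 3L, 4L, 5L)) {
  if (neighborhood_radius < 1) abort("neighborhood_radius must be >= 1")
  if (threshold_decay <= 0 || threshold_decay >= 1)
    abort("threshold_decay must lie in (0, 1)")
  if (demand_tolerance < 0) abort("demand_tolerance must be >= 0")
  structure(list(neighborhood_radius = neighborhood_radius,
                 neighborhood_weight = neighborhood_weight,
                 conversion_cost = conversion_cost,
                 patch_seed_fraction = patch_seed_fraction,
                 initial_threshold = initial_threshold,
                 threshold_decay = threshold_decay,
                 demand_tolerance = demand_tolerance,
                 max_iterations = max_iterations,
                 rng_seed = as.integer(rng_seed),
                 restricted_mask = restricted_mask,
                 protected_classes = as.integer(protected_classes)),
            class = "allocation_config")
}

# normalise demand to integer cell targets conserving the total cell count
demand_to_cells <- function(demand, codes, total_cells, cell_area) {
  if (inherits(demand, "data.frame")) {
    d <- demand$area_km2[match(codes, demand$code)]
  } else {
    d <- as.numeric(demand)[match(codes, as.integer(names(demand) %||% codes))]
  }
  if (any(is.na(d))) abort("demand does not cover every class")
  frac <- d / cell_area
  n <- floor(frac)
  rem <- total_cells - sum(n)
  if (rem > 0) {
    ord <- order(frac - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(frac - n)
    take <- ord[seq_len(-rem)]
    n[take] <- n[take] - 1
  }
  as.integer(n)
}

#' Allocate projected land demand with a multi-seed cellular automaton
#'
#' Iterative allocation: for each class short of demand, candidate cells are
#' scored `development probability x (neighbourhood density + seeded random
#' patch term)`, gated by the conversion-cost matrix and the restricted mask;
#' cells scoring above a global threshold convert in score order, drawing
#' only from classes above their demand. When an iteration converts nothing
#' the threshold decays. Terminates when every class area is within
#' `demand_tolerance` of demand or at `max_iterations`.
#'
#' @param lulc_t Base-epoch [lulc_map()].
#' @param demand Demand tibble from [project_demand()] (or named km^2
#'   vector); its total must match the map's valid area.
#' @param probs Named list (by class code) of [fit_development_probability()]
#'   results or probability [raster_layer()]s for every class that must grow.
#' @param config An [allocation_config()].
#' @return The simulated [lulc_map()], with attributes `converged`
#'   (logical), `iterations`, and `residual` (tibble of per-class leftover
#'   demand in km^2, non-zero when demand is infeasible under the mask and
#'   cost constraints — flagged with a warning).
#' @export
allocate <- function(lulc_t, demand, probs, config = allocation_config()) {
  g <- lulc_t$grid
  codes <- lulc_t$class_labels$code
  n_class <- length(codes)
  ca <- cell_area_km2(g)
  ok <- valid_mask(lulc_t)
  total_cells <- sum(ok)
  target_n <- demand_to_cells(demand, codes, total_cells, ca)
  cost <- config$conversion_cost %||% matrix(1, n_class, n_class)
  mask <- config$restricted_mask
  if (inherits(mask, "raster_layer")) mask <- !is.na(mask$values) & mask$values > 0
  if (is.null(mask)) mask <- matrix(FALSE, g$n_rows, g$n_cols)
  prob_mat <- function(code) {
    p <- probs[[as.character(code)]]
    if (is.null(p)) abort(sprintf("no development probability for class %d", code))
    if (inherits(p, "development_probability")) p <- p$probability
    stop_if_grid_mismatch(g, p$grid, "map and development probability")
    p$values
  }
  nw <- function(code) {
    w <- config$neighborhood_weight
    if (is.null(w)) 1 else (w[[as.character(code)]] %||% 1)
  }

  cur <- lulc_t$codes
  cnt <- vapply(codes, function(k) sum(cur[ok] == k), integer(1))
  protected_cell <- mask & matrix(cur %in% config$protected_classes,
                                  g$n_rows, g$n_cols)
  threshold <- config$initial_threshold
  iterations <- 0L
  converged <- all(abs(target_n - cnt) * ca <= config$demand_tolerance)

  withr::with_seed(config$rng_seed, {
    while (!converged && iterations < config$max_iterations) {
      iterations <- iterations + 1L
      converted_any <- FALSE
      need <- target_n - cnt
      cur_map <- lulc_map(cur, g, lulc_t$class_labels, lulc_t$epoch_label)
      for (ci in order(need, decreasing = TRUE)) {
        if (need[ci] <= 0) next
        code <- codes[ci]
        pv <- prob_mat(code)
        neigh <- neighborhood_effect(cur_map, code,
                                     config$neighborhood_radius)$values
        seed_term <- matrix(runif(length(cur), 0, config$patch_seed_fraction),
                            g$n_rows, g$n_cols)
        score <- pv * (nw(code) * neigh + seed_term)
        donor <- matrix(need[match(cur, codes)] < 0, g$n_rows, g$n_cols)
        allowed <- matrix(cost[cbind(match(cur, codes),
                                     rep(ci, length(cur)))] > 0,
                          g$n_rows, g$n_cols)
        cand <- which(ok & cur != code & donor & allowed & !protected_cell &
                        !is.na(score) & score > threshold)
        if (length(cand) == 0) next
        cand <- cand[order(score[cand], decreasing = TRUE)]
        surplus <- pmax(-need, 0L)
        n_take <- 0L
        for (cell in cand) {
          if (n_take >= need[ci]) break
          si <- match(cur[cell], codes)
          if (surplus[si] <= 0L) next
          cur[cell] <- code
          surplus[si] <- surplus[si] - 1L
          cnt[si] <- cnt[si] - 1L
          cnt[ci] <- cnt[ci] + 1L
          n_take <- n_take + 1L
        }
        if (n_take > 0L) {
          converted_any <- TRUE
          need <- target_n - cnt
        }
      }
      converged <- all(abs(target_n - cnt) * ca <= config$demand_tolerance)
      if (!converged && !converted_any) {
        threshold <- threshold * config$threshold_decay
        if (threshold < 1e-12) break
      }
    }
  })

  residual <- tibble(code = codes, class = lulc_t$class_labels$name,
                     residual_km2 = (target_n - cnt) * ca)
  if (!converged)
    warn(paste0("allocation did not meet demand; max residual ",
                sprintf("%.4f km2", max(abs(residual$residual_km2)))))
  out <- lulc_map(cur, g, lulc_t$class_labels,
                  epoch_label = paste0(lulc_t$epoch_label, "_sim"))
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iterations
  attr(out, "residual") <- residual
  out
}
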