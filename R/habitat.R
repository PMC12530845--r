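# Habitat quality after the InVEST habitat-quality model: threat sources on
# the land-cover map degrade surrounding habitat with distance-decay kernels;
# quality is class suitability discounted through a half-saturation transform.

#' Specify a habitat threat factor
#'
#' @param name Threat name; must match a sensitivity column.
#' @param source_class Land-cover code whose cells emit the threat.
#' @param d_max_km Maximum effective distance in kilometres (> 0).
#' @param weight Threat weight `w_r >= 0` (normalised across threats).
#' @param decay `"linear"` (`1 - d/d_max`) or `"exponential"`
#'   (`exp(-2.99 d / d_max)`); both are cut to 0 beyond `d_max`.
#' @return Object of class `threat_spec`.
#' @export
threat_spec <- function(name, source_class, d_max_km, weight,
                        decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  if (d_max_km <= 0) abort("d_max_km must be > 0")
  if (weight < 0) abort("weight must be >= 0")
  structure(list(name = name, source_class = as.integer(source_class),
                 d_max_km = d_max_km, weight = weight, decay = decay),
            class = "threat_spec")
}

#' Default threat factors
#'
#' Farmland: 1 km maximum distance, weight 0.4, linear decay. Construction
#' land: 10 km, weight 1, exponential decay.
#' @return List of [threat_spec()]s.
#' @export
default_threats <- function() {
  list(farmland = threat_spec("farmland", 1L, 1, 0.4, "linear"),
       construction = threat_spec("construction", 6L, 10, 1, "exponential"))
}

#' Default habitat suitability and threat sensitivity table
#'
#' Per class: habitat suitability `H_j` in \[0, 1\] and relative sensitivity
#' `S_jr` to each threat. Construction land has suitability 0; farmland is
#' insensitive to the farmland threat.
#' @return Tibble with columns `code`, `name`, `suitability`, then one
#'   sensitivity column per threat name.
#' @export
default_sensitivity <- function() {
  dplyr::mutate(lulc_classes(),
                suitability = c(0.3, 1, 0.9, 0.7, 0.7, 0, 0.2),
                farmland = c(0, 0.6, 0.7, 0.8, 0.2, 0, 0.1),
                construction = c(0.6, 0.5, 0.8, 0.6, 0.3, 0, 0.9))
}

#' Habitat model configuration
#'
#' @param k Half-saturation constant (> 0): the degradation level at which
#'   quality falls to half the class suitability. Default 0.5.
#' @param beta Habitat accessibility/anti-interference `beta_x` in \[0, 1\]:
#'   a scalar or a [raster_layer()]. Default 1.
#' @param thresholds Increasing grade cut points (low/medium, medium/good,
#'   good/excellent), defaults `c(0.298, 0.698, 0.984)`.
#' @param aggregation How multiple source cells of one threat combine:
#'   `"nearest"` (decay weight of the nearest source; default) or `"mean"`
#'   (mean decay weight over all sources within `d_max`).
#' @return Object of class `habitat_config`.
#' @export
habitat_config <- function(k = 0.5, beta = 1,
                           thresholds = c(0.298, 0.698, 0.984),
                           aggregation = c("nearest", "mean")) {
  aggregation <- match.arg(aggregation)
  if (k <= 0) abort("k must be > 0")
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0) || any(thresholds >= 1))
    abort("thresholds must be strictly increasing within (0, 1)")
  structure(list(k = k, beta = beta, thresholds = thresholds,
                 aggregation = aggregation),
            class = "habitat_config")
}

#' Binary presence raster of a threat's source cells
#'
#' @param lulc An [lulc_map()].
#' @param threat A [threat_spec()].
#' @return A [raster_layer()] with 1 on source cells, 0 elsewhere, `NA` on
#'   nodata.
#' @export
threat_presence <- function(lulc, threat) {
  v <- matrix(NA_real_, lulc$grid$n_rows, lulc$grid$n_cols)
  ok <- valid_mask(lulc)
  v[ok] <- as.numeric(lulc$codes[ok] == threat$source_class)
  raster_layer(v, lulc$grid, name = paste0("presence_", threat$name))
}

#' Distance-decay weight of a threat
#'
#' Linear: `max(0, 1 - d/d_max)`; exponential: `exp(-2.99 d / d_max)`. Both
#' forms are exactly 0 beyond the maximum effective distance.
#'
#' @param d Distance(s) in km, >= 0.
#' @param threat A [threat_spec()].
#' @return Weight(s) in \[0, 1\].
#' @export
#' @examples
#' decay_weight(5, default_threats()$construction)  # exp(-2.99/2)
decay_weight <- function(d, threat) {
  if (any(d < 0, na.rm = TRUE)) abort("distances must be non-negative")
  w <- switch(threat$decay,
              linear = pmax(0, 1 - d / threat$d_max_km),
              exponential = exp(-2.99 * d / threat$d_max_km))
  w[d > threat$d_max_km] <- 0
  w
}

# Euclidean distance (km, centre-to-centre) from every cell to the nearest
# TRUE cell of `src`; Inf where no source exists.
distance_to_cells <- function(src, grid) {
  if (!any(src)) return(matrix(Inf, grid$n_rows, grid$n_cols))
  bg <- matrix(1, grid$n_rows, grid$n_cols)
  bg[src] <- 0
  d <- EBImage::distmap(bg, metric = "euclidean")
  as.matrix(d) * grid$cell_size / 1000
}

# per-threat influence field i_r(x) in [0,1]
threat_influence <- function(lulc, threat, aggregation = "nearest") {
  ok <- valid_mask(lulc)
  src <- ok & lulc$codes == threat$source_class
  if (aggregation == "nearest") {
    d <- distance_to_cells(src, lulc$grid)
    infl <- matrix(0, nrow(d), ncol(d))
    fin <- is.finite(d)
    infl[fin] <- decay_weight(d[fin], threat)
  } else {
    infl <- mean_influence(src, lulc$grid, threat)
  }
  infl[!ok] <- NA_real_
  infl
}

# mean-over-sources aggregation (sensitivity analysis variant): average decay
# weight over all sources within d_max of each cell
mean_influence <- function(src, grid, threat) {
  nr <- grid$n_rows; nc <- grid$n_cols
  out <- matrix(0, nr, nc)
  idx <- which(src, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  cnt <- matrix(0, nr, nc)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (s in seq_len(nrow(idx))) {
    d <- sqrt((rows - idx[s, 1])^2 + (cols - idx[s, 2])^2) * grid$cell_size / 1000
    within <- d <= threat$d_max_km
    out[within] <- out[within] + decay_weight(d[within], threat)
    cnt[within] <- cnt[within] + 1
  }
  has <- cnt > 0
  out[has] <- out[has] / cnt[has]
  out
}

check_sensitivity <- function(sens, threats, codes) {
  missing_cols <- setdiff(vapply(threats, `[[`, "", "name"), names(sens))
  if (length(missing_cols))
    abort(paste0("sensitivity table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  if (!all(codes %in% sens$code))
    abort("sensitivity table lacks rows for some class codes")
  rng <- unlist(sens[c("suitability", vapply(threats, `[[`, "", "name"))])
  if (any(rng < 0 | rng > 1)) abort("suitability/sensitivity values must lie in [0, 1]")
  invisible(TRUE)
}

#' Habitat degradation surface
#'
#' For each cell `x` of class `j`, degradation is the threat-weight-normalised
#' sum over threats `r` of `i_r(x) * beta_x * S_jr`, where `i_r(x)` is the
#' distance-decay influence of the threat's source cells (nearest-source decay
#' weight by default) and `S_jr` the class's sensitivity to the threat. Values
#' are clamped to \[0, 1\].
#'
#' @param lulc An [lulc_map()].
#' @param threats List of [threat_spec()]s (default [default_threats()]).
#' @param sens Sensitivity table (default [default_sensitivity()]).
#' @param config A [habitat_config()].
#' @return A [raster_layer()] `"degradation"` with values in \[0, 1\].
#' @export
compute_degradation <- function(lulc, threats = default_threats(),
                                sens = default_sensitivity(),
                                config = habitat_config()) {
  if (length(threats) == 0) abort("at least one threat is required")
  w <- vapply(threats, `[[`, numeric(1), "weight")
  if (sum(w) <= 0) abort("threat weights must sum to > 0")
  check_sensitivity(sens, threats, sort(unique(lulc_values(lulc))))
  w <- w / sum(w)
  ok <- valid_mask(lulc)
  beta <- config$beta
  if (inherits(beta, "raster_layer")) {
    stop_if_grid_mismatch(lulc$grid, beta$grid, "lulc and beta")
    beta <- beta$values
  }
  D <- matrix(0, lulc$grid$n_rows, lulc$grid$n_cols)
  for (i in seq_along(threats)) {
    th <- threats[[i]]
    infl <- threat_influence(lulc, th, config$aggregation)
    s_col <- sens[[th$name]][match(lulc$codes, sens$code)]
    s_mat <- matrix(s_col, lulc$grid$n_rows, lulc$grid$n_cols)
    contrib <- w[i] * infl * s_mat
    D[ok] <- D[ok] + contrib[ok]
  }
  D <- D * beta
  D <- pmin(pmax(D, 0), 1)
  D[!ok] <- NA_real_
  raster_layer(D, lulc$grid, name = "degradation")
}

#' Habitat quality surface
#'
#' `Q = H_j * (1 - D^2 / (D^2 + k^2))`: the class suitability discounted by
#' degradation through a half-saturation transform — at `D = k` quality is
#' half the suitability.
#'
#' @param lulc An [lulc_map()].
#' @param deg Degradation [raster_layer()] from [compute_degradation()].
#' @param sens Sensitivity table supplying the suitabilities `H_j`.
#' @param config A [habitat_config()] supplying `k`.
#' @return A [raster_layer()] `"quality"` with values in \[0, H_j\].
#' @export
compute_quality <- function(lulc, deg, sens = default_sensitivity(),
                            config = habitat_config()) {
  stop_if_grid_mismatch(lulc$grid, deg$grid, "lulc and degradation")
  H <- matrix(sens$suitability[match(lulc$codes, sens$code)],
              lulc$grid$n_rows, lulc$grid$n_cols)
  D <- deg$values
  Q <- H * (1 - D^2 / (D^2 + config$k^2))
  Q[!valid_mask(lulc)] <- NA_real_
  raster_layer(Q, lulc$grid, name = "quality")
}

#' One-call habitat quality
#'
#' Convenience wrapper running [compute_degradation()] then
#' [compute_quality()].
#' @inheritParams compute_degradation
#' @return List with elements `degradation` and `quality`.
#' @export
habitat_quality <- function(lulc, threats = default_threats(),
                            sens = default_sensitivity(),
                            config = habitat_config()) {
  deg <- compute_degradation(lulc, threats, sens, config)
  list(degradation = deg,
       quality = compute_quality(lulc, deg, sens, config))
}

#' Classify a quality surface into four grades
#'
#' Intervals are closed on the left: Low `[0, t1)`, Medium `[t1, t2)`, Good
#' `[t2, t3)`, Excellent `[t3, 1]` — the top grade includes `Q = 1`.
#'
#' @param q Quality [raster_layer()].
#' @param thresholds Increasing cut points, default the [habitat_config()]
#'   defaults.
#' @return Categorical [raster_layer()] with codes 1 (Low) .. 4 (Excellent).
#' @export
classify_quality <- function(q, thresholds = habitat_config()$thresholds) {
  v <- q$values
  g <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  g[ok] <- 1 + findInterval(v[ok], thresholds)
  raster_layer(g, q$grid, name = "quality_grade", categorical = TRUE)
}

#' Grade labels in code order
#' @return Character vector `c("Low", "Medium", "Good", "Excellent")`.
#' @export
grade_labels <- function() c("Low", "Medium", "Good", "Excellent")

#' Jenks natural-breaks classification
#'
#' Fisher--Jenks dynamic programme minimising the within-class sum of squared
#' deviations; deterministic for a fixed sample. For `n_classes` classes the
#' `n_classes - 1` interior breaks are reported as the smallest value of each
#' upper class, so they can be used directly as left-closed grade cut points.
#'
#' @param values Numeric sample (raster values are typically subsampled by
#'   the caller).
#' @param n_classes Number of classes (>= 2).
#' @return Numeric vector of `n_classes - 1` increasing cut points. With a
#'   degenerate all-equal sample, the common value is returned once with a
#'   warning.
#' @export
#' @examples
#' jenks_breaks(c(0.1, 0.11, 0.9, 0.91), 2)
jenks_breaks <- function(values, n_classes) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (n_classes < 2) abort("n_classes must be >= 2")
  if (n < n_classes) abort("need at least n_classes values")
  if (diff(range(x)) == 0) {
    warn("degenerate sample: all values equal; single break returned")
    return(x[1])
  }
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # sse of x[a..b], vectorised over a for fixed b
  seg_sse <- function(a, b) {
    s <- cs[b] - c(0, cs)[a]
    s2 <- cs2[b] - c(0, cs2)[a]
    len <- b - a + 1
    pmax(s2 - s^2 / len, 0)
  }
  cost <- matrix(Inf, n, n_classes)   # cost[b, k]: best SSE of x[1..b] in k classes
  split <- matrix(NA_integer_, n, n_classes)
  cost[, 1] <- vapply(seq_len(n), function(b) seg_sse(1L, b)[1], numeric(1))
  for (k in 2:n_classes) {
    for (b in k:n) {
      a <- k:b                       # start index of the last class
      tot <- cost[a - 1L, k - 1L] + seg_sse(a, b)
      j <- which.min(tot)
      cost[b, k] <- tot[j]
      split[b, k] <- a[j]
    }
  }
  starts <- integer(n_classes)
  b <- n
  for (k in n_classes:2) {
    starts[k] <- split[b, k]
    b <- starts[k] - 1L
  }
  x[starts[2:n_classes]]
}

#' Goodness of variance fit of a set of breaks
#'
#' `1 - SSE_within / SSE_total` for the classification induced by left-closed
#' `breaks`; used to compare break sets.
#' @param values Numeric sample.
#' @param breaks Increasing cut points.
#' @return Scalar in \[0, 1\].
#' @export
goodness_of_variance_fit <- function(values, breaks) {
  x <- values[!is.na(values)]
  cls <- findInterval(x, breaks)
  sse <- sum(tapply(x, cls, function(v) sum((v - mean(v))^2)))
  tot <- sum((x - mean(x))^2)
  if (tot == 0) return(1)
  1 - sse / tot
}

#' Area summary of habitat-quality grades
#'
#' @param grades Grade [raster_layer()] from [classify_quality()].
#' @param q Quality [raster_layer()].
#' @param deg Degradation [raster_layer()].
#' @return Tibble with one row per grade (`grade`, `code`, `n_cells`,
#'   `area_km2`, `proportion`) carrying the landscape-wide unweighted cell
#'   means as attributes `mean_quality` and `mean_degradation` (also surfaced
#'   by [quality_means()]).
#' @export
grade_summary <- function(grades, q, deg) {
  stop_if_grid_mismatch(grades$grid, q$grid, "grades and quality")
  stop_if_grid_mismatch(grades$grid, deg$grid, "grades and degradation")
  ca <- cell_area_km2(grades$grid)
  g <- grades$values[!is.na(grades$values)]
  cnt <- vapply(1:4, function(k) sum(g == k), numeric(1))
  out <- tibble(code = 1:4, grade = grade_labels(), n_cells = as.integer(cnt),
                area_km2 = cnt * ca, proportion = cnt / sum(cnt))
  attr(out, "mean_quality") <- mean(q$values, na.rm = TRUE)
  attr(out, "mean_degradation") <- mean(deg$values, na.rm = TRUE)
  out
}

#' Landscape-wide mean quality and degradation
#' @param q,deg Quality and degradation [raster_layer()]s.
#' @return One-row tibble with `mean_quality`, `mean_degradation` (unweighted
#'   means over valid cells).
#' @export
quality_means <- function(q, deg) {
  tibble(mean_quality = mean(q$values, na.rm = TRUE),
         mean_degradation = mean(deg$values, na.rm = TRUE))
}
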