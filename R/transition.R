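#' Class-by-class transition matrix between two epochs
#'
#' Cross-tabulates two co-registered land-cover maps and scales counts to
#' areas. `S[i, j]` is the area (km^2) that moved from class `i` at the first
#' epoch to class `j` at the second. Cells that are nodata in *either* map are
#' excluded from both marginals, so row sums equal first-epoch class areas,
#' column sums equal second-epoch class areas and the grand total equals the
#' jointly valid area.
#'
#' @param m1,m2 [lulc_map()]s on the same grid.
#' @return An object of class `transition_matrix` with fields `areas` (n x n
#'   km^2 matrix), `counts`, `labels`, `period`, `cell_area`.
#' @export
#' @examples
#' m1 <- lulc_map(matrix(c(1, 1, 2, 2), 2), epoch_label = "t1")
#' m2 <- lulc_map(matrix(c(1, 2, 2, 2), 2), epoch_label = "t2")
#' compute_transition_matrix(m1, m2)$areas[1:2, 1:2]
compute_transition_matrix <- function(m1, m2) {
  stop_if_grid_mismatch(m1$grid, m2$grid, "the two epochs")
  ok <- valid_mask(m1) & valid_mask(m2)
  codes <- m1$class_labels$code
  f1 <- factor(m1$codes[ok], levels = codes)
  f2 <- factor(m2$codes[ok], levels = codes)
  counts <- table(f1, f2)
  ca <- cell_area_km2(m1$grid)
  counts <- unclass(counts)
  dimnames(counts) <- list(m1$class_labels$name, m1$class_labels$name)
  areas <- counts * ca
  structure(
    list(areas = areas, counts = counts, labels = m1$class_labels,
         period = c(m1$epoch_label, m2$epoch_label), cell_area = ca),
    class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %s -> %s, total %.4f km2\n",
              x$period[1], x$period[2], sum(x$areas)))
  print(round(x$areas, 4))
  invisible(x)
}

#' Tidy a transition matrix to long form
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `area_km2`, `share` (fraction of the
#'   total valid area) — one row per ordered class pair, Sankey-ready.
#' @export
#' @exportS3Method generics::tidy
tidy.transition_matrix <- function(x, ...) {
  total <- sum(x$areas)
  tidyr::expand_grid(from = x$labels$name, to = x$labels$name) |>
    dplyr::mutate(area_km2 = as.vector(t(x$areas)),
                  share = if (total > 0) .data$area_km2 / total else NA_real_)
}

#' Per-class change summary from two epochs' areas
#'
#' The change rate is expressed as a percentage of the first-epoch area,
#' `100 * (area_t2 - area_t1) / area_t1`, reported `NA` where `area_t1 = 0`.
#'
#' @param area_t1,area_t2 Non-negative area vectors (km^2), same length.
#' @param labels Class names (defaults to names of `area_t1` or the seven
#'   canonical classes).
#' @return Tibble with `class`, `area_t1`, `prop_t1`, `area_t2`, `prop_t2`,
#'   `delta_area`, `delta_rate_pct`.
#' @export
#' @examples
#' area_change_table(c(Farmland = 607.64), c(Farmland = 1017.08))
area_change_table <- function(area_t1, area_t2, labels = NULL) {
  if (length(area_t1) != length(area_t2)) abort("area vectors differ in length")
  labels <- labels %||% names(area_t1) %||%
    lulc_classes()$name[seq_along(area_t1)]
  tibble(class = labels,
         area_t1 = as.numeric(area_t1),
         prop_t1 = area_t1 / sum(area_t1),
         area_t2 = as.numeric(area_t2),
         prop_t2 = area_t2 / sum(area_t2),
         delta_area = as.numeric(area_t2 - area_t1),
         delta_rate_pct = ifelse(area_t1 > 0,
                                 100 * (area_t2 - area_t1) / area_t1, NA_real_))
}

#' Change summary of a transition matrix
#'
#' Row/column marginals of the transition matrix give the two epochs' class
#' areas; see [area_change_table()] for the derived columns.
#'
#' @param tm A `transition_matrix`.
#' @return Tibble as in [area_change_table()].
#' @export
change_summary <- function(tm) {
  area_change_table(rowSums(tm$areas), colSums(tm$areas), labels = tm$labels$name)
}

#' Trajectory map of class transitions
#'
#' Encodes each cell's pair of classes as `10 * i + j` (e.g. 12 = farmland at
#' the first epoch converted to forest; 22 = persistent forest). Nodata in
#' either epoch propagates.
#'
#' @param m1,m2 [lulc_map()]s on the same grid.
#' @return A [raster_layer()] (categorical) of trajectory codes.
#' @export
trajectory_map <- function(m1, m2) {
  stop_if_grid_mismatch(m1$grid, m2$grid, "the two epochs")
  ok <- valid_mask(m1) & valid_mask(m2)
  v <- matrix(NA_real_, m1$grid$n_rows, m1$grid$n_cols)
  v[ok] <- 10 * m1$codes[ok] + m2$codes[ok]
  raster_layer(v, m1$grid, name = "trajectory", categorical = TRUE)
}

#' Decode trajectory codes back to class pairs
#' @param code Integer vector of `10 * i + j` codes.
#' @return Tibble with `from`, `to`.
#' @export
decode_trajectory <- function(code) {
  tibble(from = code %/% 10L, to = code %% 10L)
}

#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.transition_matrix <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$area_km2 > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$to, .data$from, fill = .data$area_km2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = object$period[2], y = object$period[1], fill = "km²") +
    ggplot2::theme_minimal()
}
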