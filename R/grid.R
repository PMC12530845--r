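#' Grid geometry of a raster
#'
#' A `grid_spec` describes the geometry shared by every raster in an analysis:
#' dimensions, square cell size in metres, the projected coordinate of the
#' top-left corner, a free-text CRS label and the integer nodata code. Cells
#' are row-major with the origin at the top-left cell *corner*; the centre of
#' cell (r, c) is at `origin + ((c - 0.5) * cell_size, -(r - 0.5) * cell_size)`.
#'
#' @param n_rows,n_cols Positive integers.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Numeric length-2, projected (x, y) of the top-left corner.
#' @param crs_label Free-text label for the coordinate reference system.
#' @param nodata_code Integer code marking missing cells; must not collide
#'   with the land-cover class codes 1--7.
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec(10, 10, cell_size = 30)
grid_spec <- function(n_rows, n_cols, cell_size, origin = c(0, 0),
                      crs_label = "local", nodata_code = -9999L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) abort("n_rows and n_cols must be >= 1")
  if (!is.numeric(cell_size) || cell_size <= 0) abort("cell_size must be > 0")
  nodata_code <- as.integer(nodata_code)
  if (nodata_code %in% 1:7) abort("nodata_code collides with class codes 1..7")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs_label = as.character(crs_label),
         nodata_code = nodata_code),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g m, origin (%.6g, %.6g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2], x$crs_label))
  invisible(x)
}

#' Area of one grid cell in square kilometres
#' @param grid A [grid_spec()].
#' @return A scalar, `cell_size^2 / 1e6`.
#' @export
cell_area_km2 <- function(grid) grid$cell_size^2 / 1e6

# grids equal up to a tolerance of 1e-6 of a cell on origin/cell_size
grids_equal <- function(a, b) {
  tol <- 1e-6 * a$cell_size
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!grids_equal(a, b)) abort(paste0("grid mismatch between ", what))
  invisible(TRUE)
}

#' The seven land-cover classes
#'
#' Canonical coding used throughout: 1 Farmland, 2 Forests, 3 Shrubs,
#' 4 Grasslands, 5 Water bodies, 6 Construction land, 7 Barren.
#' @return A tibble with columns `code` and `name`.
#' @export
lulc_classes <- function() {
  tibble(code = 1:7,
         name = c("Farmland", "Forests", "Shrubs", "Grasslands",
                  "Water bodies", "Construction land", "Barren"))
}

#' Categorical land-use/land-cover map
#'
#' @param codes Integer matrix of class codes; cells equal to the grid's
#'   nodata code (or `NA`) are treated as missing.
#' @param grid A [grid_spec()] matching `dim(codes)`; if omitted, a local
#'   grid with 30 m cells is created.
#' @param class_labels Tibble with columns `code`, `name` (default
#'   [lulc_classes()]).
#' @param epoch_label Free-text epoch tag (e.g. `"2007"`).
#' @return An object of class `lulc_map`.
#' @export
#' @examples
#' m <- lulc_map(matrix(2L, 3, 3), epoch_label = "t1")
#' table(lulc_values(m))
lulc_map <- function(codes, grid = NULL, class_labels = lulc_classes(),
                     epoch_label = "") {
  codes <- matrix(as.integer(codes), nrow = nrow(codes), ncol = ncol(codes))
  if (is.null(grid)) grid <- grid_spec(nrow(codes), ncol(codes), 30)
  if (!identical(dim(codes), c(grid$n_rows, grid$n_cols)))
    abort("codes matrix shape does not match grid")
  codes[is.na(codes)] <- grid$nodata_code
  valid <- codes != grid$nodata_code
  bad <- valid & !(codes %in% class_labels$code)
  if (any(bad)) abort(sprintf("%d cells carry codes outside the class set", sum(bad)))
  structure(list(grid = grid, codes = codes, class_labels = class_labels,
                 epoch_label = as.character(epoch_label)),
            class = "lulc_map")
}

#' @export
print.lulc_map <- function(x, ...) {
  n_valid <- sum(x$codes != x$grid$nodata_code)
  cat(sprintf("<lulc_map> '%s', %d x %d (%d valid cells)\n",
              x$epoch_label, x$grid$n_rows, x$grid$n_cols, n_valid))
  print(class_areas(x), n = Inf)
  invisible(x)
}

#' Class code vector of a map's valid cells
#' @param map An [lulc_map()].
#' @return Integer vector of codes over valid cells (column-major order).
#' @export
lulc_values <- function(map) {
  v <- as.vector(map$codes)
  v[v != map$grid$nodata_code]
}

# logical matrix of valid cells
valid_mask <- function(map) map$codes != map$grid$nodata_code

#' Per-class areas of a map
#' @param map An [lulc_map()].
#' @return Tibble with `code`, `name`, `n_cells`, `area_km2` for every class
#'   in the map's class table (zero rows included).
#' @export
class_areas <- function(map) {
  ca <- cell_area_km2(map$grid)
  v <- lulc_values(map)
  cnt <- vapply(map$class_labels$code, function(k) sum(v == k), integer(1))
  tibble(code = map$class_labels$code, name = map$class_labels$name,
         n_cells = cnt, area_km2 = cnt * ca)
}

#' Continuous raster layer
#'
#' Thin container pairing a numeric matrix with a [grid_spec()]; used for
#' habitat quality/degradation surfaces, driver fields and probabilities.
#' `NA` marks nodata.
#'
#' @param values Numeric matrix.
#' @param grid A [grid_spec()]; defaults to a local 30 m grid.
#' @param name Layer name.
#' @param categorical Flag for integer-coded categorical layers.
#' @return Object of class `raster_layer`.
#' @export
raster_layer <- function(values, grid = NULL, name = "layer", categorical = FALSE) {
  values <- as.matrix(values)
  if (is.null(grid)) grid <- grid_spec(nrow(values), ncol(values), 30)
  if (!identical(dim(values), c(grid$n_rows, grid$n_cols)))
    abort("values matrix shape does not match grid")
  structure(list(grid = grid, values = values, name = as.character(name),
                 categorical = isTRUE(categorical)),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer> '%s'%s, %d x %d, range [%.4g, %.4g]\n",
              x$name, if (x$categorical) " (categorical)" else "",
              x$grid$n_rows, x$grid$n_cols,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Tidy a raster to cell records
#'
#' @param x An [lulc_map()] or [raster_layer()].
#' @param ... Unused.
#' @return Tibble with `row`, `col`, centre coordinates `x`, `y` and the cell
#'   value (`code` plus `name` for maps, `value` for layers); nodata cells
#'   are dropped.
#' @export
#' @exportS3Method generics::tidy
tidy.lulc_map <- function(x, ...) {
  g <- x$grid
  idx <- which(valid_mask(x), arr.ind = TRUE)
  tibble(row = idx[, 1], col = idx[, 2],
         x = g$origin[1] + (idx[, 2] - 0.5) * g$cell_size,
         y = g$origin[2] - (idx[, 1] - 0.5) * g$cell_size,
         code = x$codes[idx]) |>
    dplyr::left_join(x$class_labels, by = "code")
}

#' @rdname tidy.lulc_map
#' @export
#' @exportS3Method generics::tidy
tidy.raster_layer <- function(x, ...) {
  g <- x$grid
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  tibble(row = idx[, 1], col = idx[, 2],
         x = g$origin[1] + (idx[, 2] - 0.5) * g$cell_size,
         y = g$origin[2] - (idx[, 1] - 0.5) * g$cell_size,
         value = x$values[idx])
}

#' Plot a land-cover map or raster layer
#' @param object An [lulc_map()] or [raster_layer()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.lulc_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$name)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "Class", title = object$epoch_label) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lulc_map
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.raster_layer <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = object$name) +
    ggplot2::theme_minimal()
}
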