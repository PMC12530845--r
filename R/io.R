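# Esri ASCII grid (.asc) I/O. The header carries ncols/nrows/xllcorner/
# yllcorner/cellsize/NODATA_value; data rows run north to south, matching the
# row-major top-left grid convention used throughout.

parse_asc <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read raster: ", path))
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1)
    if (length(line) == 0) abort("empty or truncated .asc file")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) abort("malformed .asc header")
  vals <- scan(con, what = numeric(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) abort("data block does not match header dimensions")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  list(header = hdr, values = m)
}

write_asc <- function(values, grid, path, nodata, fmt = "%.10g") {
  con <- file(path, "w"); on.exit(close(con))
  yll <- grid$origin[2] - grid$n_rows * grid$cell_size
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %s", format(nodata, scientific = FALSE))), con)
  for (r in seq_len(grid$n_rows))
    writeLines(paste(sprintf(fmt, values[r, ]), collapse = " "), con)
  invisible(path)
}

grid_from_header <- function(hdr, nodata_code = -9999L, crs_label = "local") {
  nr <- as.integer(hdr$nrows)
  grid_spec(nr, as.integer(hdr$ncols), hdr$cellsize,
            origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
            crs_label = crs_label, nodata_code = nodata_code)
}

#' Read a categorical land-cover raster from an Esri ASCII grid
#'
#' Cells carrying codes outside `class_codes` are remapped to nodata with a
#' warning reporting the count.
#'
#' @param path Path to a `.asc` file with integer class codes.
#' @param class_codes Integer vector of admissible codes (default `1:7`).
#' @param class_labels Class table as in [lulc_classes()].
#' @param epoch_label Epoch tag attached to the map.
#' @param crs_label CRS label for the grid.
#' @return An [lulc_map()].
#' @export
read_lulc_asc <- function(path, class_codes = 1:7, class_labels = lulc_classes(),
                          epoch_label = "", crs_label = "local") {
  p <- parse_asc(path)
  m <- p$values
  if (any(abs(m - round(m)) > 1e-9, na.rm = TRUE))
    abort("non-integer band: land-cover rasters must carry integer codes")
  m <- matrix(as.integer(round(m)), nrow(m), ncol(m))
  nodata <- as.integer(p$header$nodata_value %||% -9999)
  grid <- grid_from_header(p$header, nodata_code = nodata, crs_label = crs_label)
  stray <- m != nodata & !(m %in% class_codes)
  if (any(stray)) {
    warn(sprintf("%d cells with codes outside the class set mapped to nodata",
                 sum(stray)))
    m[stray] <- nodata
  }
  if (!any(m != nodata)) abort("raster has no valid cells")
  lulc_map(m, grid, class_labels = class_labels[class_labels$code %in% class_codes, ],
           epoch_label = epoch_label)
}

#' Write a categorical land-cover raster as an Esri ASCII grid
#'
#' Inverse of [read_lulc_asc()]: the written file reads back bit-exactly
#' (codes, nodata pattern and grid geometry).
#'
#' @param map An [lulc_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lulc_asc <- function(map, path) {
  write_asc(map$codes, map$grid, path, nodata = map$grid$nodata_code, fmt = "%d")
  invisible(path)
}

#' Read/write continuous rasters as Esri ASCII grids
#'
#' @param path File path.
#' @param name,categorical Passed to [raster_layer()].
#' @param crs_label CRS label.
#' @return `read_raster_asc()` returns a [raster_layer()] (nodata as `NA`);
#'   `write_raster_asc()` returns `path` invisibly.
#' @export
read_raster_asc <- function(path, name = NULL, categorical = FALSE,
                            crs_label = "local") {
  p <- parse_asc(path)
  nodata <- p$header$nodata_value %||% -9999
  m <- p$values
  m[m == nodata] <- NA_real_
  grid <- grid_from_header(p$header, crs_label = crs_label)
  raster_layer(m, grid, name = name %||% sub("\\.asc$", "", basename(path)),
               categorical = categorical)
}

#' @rdname read_raster_asc
#' @param layer A [raster_layer()].
#' @export
write_raster_asc <- function(layer, path) {
  v <- layer$values
  v[is.na(v)] <- -9999
  if (layer$categorical) v <- matrix(as.integer(round(v)), nrow(v), ncol(v))
  write_asc(v, layer$grid, path, nodata = -9999,
            fmt = if (layer$categorical) "%d" else "%.10g")
  invisible(path)
}
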