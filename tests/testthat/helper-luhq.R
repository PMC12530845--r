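# shared fixtures and independent oracles

`%||%` <- function(a, b) if (is.null(a)) b else a

# small map from a vector/matrix of codes (column-major when a vector)
toy_map <- function(codes, nrow = NULL, cell_size = 1000, epoch = "t",
                    nodata = -9999L) {
  if (is.null(dim(codes))) {
    nrow <- nrow %||% floor(sqrt(length(codes)))
    codes <- matrix(codes, nrow = nrow)
  }
  g <- grid_spec(nrow(codes), ncol(codes), cell_size, nodata_code = nodata)
  lulc_map(codes, g, epoch_label = epoch)
}

random_lulc <- function(nr, nc, codes = 1:7, cell_size = 1000, seed = 1) {
  withr::with_seed(seed,
    toy_map(matrix(sample(codes, nr * nc, replace = TRUE), nr), cell_size = cell_size))
}

# brute-force degradation oracle: all-pairs nearest-source rule, evaluated
# independently of the package's distance-transform path
bf_degradation <- function(lulc, threats = default_threats(),
                           sens = default_sensitivity(), k_beta = 1) {
  g <- lulc$grid
  w <- vapply(threats, function(t) t$weight, numeric(1))
  w <- w / sum(w)
  D <- matrix(NA_real_, g$n_rows, g$n_cols)
  for (i in seq_len(g$n_rows)) for (j in seq_len(g$n_cols)) {
    if (lulc$codes[i, j] == g$nodata_code) next
    d_tot <- 0
    for (ti in seq_along(threats)) {
      th <- threats[[ti]]
      src <- which(lulc$codes == th$source_class, arr.ind = TRUE)
      infl <- 0
      if (nrow(src) > 0) {
        d <- sqrt((src[, 1] - i)^2 + (src[, 2] - j)^2) * g$cell_size / 1000
        infl <- max(decay_weight(d, th))
      }
      s <- sens[[th$name]][match(lulc$codes[i, j], sens$code)]
      d_tot <- d_tot + w[ti] * infl * k_beta * s
    }
    D[i, j] <- min(max(d_tot, 0), 1)
  }
  D
}

# exhaustive Jenks oracle: best split of a sorted sample into contiguous
# classes by total within-class SSE, via enumeration of all partitions
bf_jenks <- function(values, n_classes) {
  x <- sort(values)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  splits <- utils::combn(n - 1, n_classes - 1)
  best <- NULL; best_sse <- Inf
  for (s in seq_len(ncol(splits))) {
    bounds <- c(0, splits[, s], n)
    tot <- sum(vapply(seq_len(n_classes), function(k)
      sse(x[(bounds[k] + 1):bounds[k + 1]]), numeric(1)))
    if (tot < best_sse - 1e-12) { best_sse <- tot; best <- splits[, s] }
  }
  list(breaks = x[best + 1], sse = best_sse)
}
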