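#' Estimate a Markov transition-probability matrix from a transition matrix
#'
#' Row-normalises the area transition matrix: `P[i, j] = S[i, j] / sum_j
#' S[i, j]`. Classes absent at the first epoch receive an identity row (they
#' persist) with a warning.
#'
#' @param tm A `transition_matrix` from [compute_transition_matrix()].
#' @param period_years Length of the calibration period in years (metadata).
#' @return Object of class `transition_probability_matrix` with fields
#'   `probs`, `labels`, `period_years`.
#' @export
estimate_transition_probabilities <- function(tm, period_years = NA_integer_) {
  S <- tm$areas
  if (length(S) == 0 || sum(S) == 0) abort("empty transition matrix")
  rs <- rowSums(S)
  P <- S / ifelse(rs > 0, rs, 1)
  empty <- rs == 0
  if (any(empty)) {
    warn(sprintf("classes with zero initial area get identity rows: %s",
                 paste(rownames(S)[empty], collapse = ", ")))
    P[empty, ] <- 0
    diag(P)[empty] <- 1
  }
  structure(list(probs = P, labels = tm$labels,
                 period_years = as.integer(period_years)),
            class = "transition_probability_matrix")
}

#' @export
print.transition_probability_matrix <- function(x, ...) {
  cat("<transition_probability_matrix>\n")
  print(round(x$probs, 4))
  invisible(x)
}

#' Tidy a transition-probability matrix
#' @param x A `transition_probability_matrix`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `prob`.
#' @export
#' @exportS3Method generics::tidy
tidy.transition_probability_matrix <- function(x, ...) {
  tidyr::expand_grid(from = rownames(x$probs), to = colnames(x$probs)) |>
    dplyr::mutate(prob = as.vector(t(x$probs)))
}

#' Scenario adjustment of transition probabilities
#'
#' A rule multiplies the probabilities of the named off-diagonal transitions
#' by a positive factor; the ecological-priority preset encodes: farmland to
#' forest/shrub/grass/water up 50% (x1.5); forest to everything except water
#' down 60% (x0.4); shrub to everything except water and forest down 40%
#' (x0.6); grass to everything except water, shrub and forest down 40%
#' (x0.6); water to everything except shrub, forest and grass down 40%
#' (x0.6).
#'
#' @param rules Tibble with columns `from`, `to` (class codes) and
#'   `multiplier` (> 0); `to` must differ from `from`.
#' @param label Scenario label.
#' @return Object of class `scenario_adjustment`.
#' @export
scenario_adjustment <- function(rules, label = "custom") {
  rules <- as_tibble(rules)
  if (nrow(rules)) {
    if (any(rules$multiplier <= 0)) abort("multipliers must be > 0")
    if (any(rules$from == rules$to)) abort("rules must target off-diagonal transitions")
  }
  structure(list(rules = rules, label = label), class = "scenario_adjustment")
}

#' @rdname scenario_adjustment
#' @export
scenario_nd <- function() {
  scenario_adjustment(tibble(from = integer(), to = integer(),
                             multiplier = numeric()), label = "ND")
}

#' @rdname scenario_adjustment
#' @export
scenario_ep <- function() {
  rule <- function(from, to, m) tibble(from = from, to = to, multiplier = m)
  scenario_adjustment(dplyr::bind_rows(
    rule(1L, c(2L, 3L, 4L, 5L), 1.5),
    rule(2L, setdiff(1:7, c(2L, 5L)), 0.4),
    rule(3L, setdiff(1:7, c(3L, 5L, 2L)), 0.6),
    rule(4L, setdiff(1:7, c(4L, 5L, 3L, 2L)), 0.6),
    rule(5L, setdiff(1:7, c(5L, 3L, 2L, 4L)), 0.6)), label = "EP")
}

#' Apply a scenario adjustment to a transition-probability matrix
#'
#' Targeted off-diagonal entries are multiplied by their factors, then each
#' row is renormalised by resetting the diagonal to `1 - sum(off-diagonal)`
#' (persistence absorbs the adjustment). If that residual is negative the
#' row's off-diagonals are rescaled proportionally to sum to 1 and the
#' diagonal set to 0.
#'
#' @param P A `transition_probability_matrix`.
#' @param adj A [scenario_adjustment()].
#' @return An adjusted, row-stochastic `transition_probability_matrix`.
#' @export
apply_scenario <- function(P, adj) {
  M <- P$probs
  codes <- P$labels$code
  if (nrow(adj$rules)) {
    if (!all(c(adj$rules$from, adj$rules$to) %in% codes))
      abort("scenario rule names a class absent from the matrix")
    for (r in seq_len(nrow(adj$rules))) {
      i <- match(adj$rules$from[r], codes)
      j <- match(adj$rules$to[r], codes)
      M[i, j] <- M[i, j] * adj$rules$multiplier[r]
    }
    for (i in seq_len(nrow(M))) {
      off <- sum(M[i, -i])
      if (off <= 1) {
        M[i, i] <- 1 - off
      } else {
        M[i, -i] <- M[i, -i] / off
        M[i, i] <- 0
      }
    }
  }
  structure(list(probs = M, labels = P$labels, period_years = P$period_years,
                 scenario = adj$label),
            class = "transition_probability_matrix")
}

#' Project class-area demand with a Markov chain
#'
#' `demand = areas %*% P^steps`. One step spans the calibration period, so a
#' projection horizon equal in length to the calibration period is
#' `steps = 1`.
#'
#' @param P A `transition_probability_matrix`.
#' @param areas Named (or label-ordered) non-negative class-area vector
#'   (km^2) at the base epoch.
#' @param steps Number of Markov steps (>= 1).
#' @return Tibble with `code`, `class`, `area_km2` — total area conserved.
#' @export
project_demand <- function(P, areas, steps = 1) {
  if (steps < 1) abort("steps must be >= 1")
  if (any(areas < 0)) abort("areas must be non-negative")
  if (length(areas) != nrow(P$probs)) abort("label mismatch between P and areas")
  if (!is.null(names(areas)) &&
      !all(names(areas) == rownames(P$probs)))
    abort("label mismatch between P and areas")
  v <- as.numeric(areas)
  for (s in seq_len(steps)) v <- as.numeric(v %*% P$probs)
  tibble(code = P$labels$code, class = P$labels$name, area_km2 = v)
}
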