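#' Confusion matrix between reference and simulated maps
#'
#' Cross-tabulation over jointly valid cells; reference classes in rows,
#' simulated in columns.
#'
#' @param reference,simulated [lulc_map()]s on the same grid.
#' @return Object of class `confusion_matrix` (`counts`, `labels`).
#' @export
confusion_matrix <- function(reference, simulated) {
  stop_if_grid_mismatch(reference$grid, simulated$grid,
                        "reference and simulated maps")
  ok <- valid_mask(reference) & valid_mask(simulated)
  codes <- reference$class_labels$code
  counts <- table(factor(reference$codes[ok], levels = codes),
                  factor(simulated$codes[ok], levels = codes))
  counts <- unclass(counts)
  dimnames(counts) <- list(reference$class_labels$name,
                           reference$class_labels$name)
  structure(list(counts = counts, labels = reference$class_labels),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> reference rows x simulated columns\n")
  print(x$counts)
  invisible(x)
}

#' Overall accuracy and Cohen's kappa
#'
#' `OA = trace / total`; `kappa = (OA - p_e) / (1 - p_e)` with `p_e` the
#' marginal chance agreement. Kappa is reported `NA` when `p_e = 1`.
#'
#' @param cm A [confusion_matrix()].
#' @return One-row tibble with `overall_accuracy`, `kappa`, `n`.
#' @export
oa_kappa <- function(cm) {
  n <- sum(cm$counts)
  if (n == 0) abort("empty confusion matrix")
  oa <- sum(diag(cm$counts)) / n
  pe <- sum(rowSums(cm$counts) * colSums(cm$counts)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) NA_real_
           else (oa - pe) / (1 - pe)
  tibble(overall_accuracy = oa, kappa = kappa, n = as.integer(n))
}

#' Figure of merit of a change simulation
#'
#' Pontius' change-focused agreement ratio `B / (A + B + C + D)` with, over
#' jointly valid cells: A observed change simulated as persistence; B observed
#' change simulated as the correct new class; C observed change simulated as
#' change to the wrong class; D observed persistence simulated as change.
#'
#' @param ref_t1,ref_t2 Observed maps at the two epochs.
#' @param simulated_t2 Simulated map at the second epoch.
#' @return One-row tibble with `fom` (`NA` with a warning when no observed
#'   change exists) and the four components `a`, `b`, `c`, `d` (cell counts).
#' @export
figure_of_merit <- function(ref_t1, ref_t2, simulated_t2) {
  stop_if_grid_mismatch(ref_t1$grid, ref_t2$grid, "reference epochs")
  stop_if_grid_mismatch(ref_t1$grid, simulated_t2$grid,
                        "reference and simulated maps")
  ok <- valid_mask(ref_t1) & valid_mask(ref_t2) & valid_mask(simulated_t2)
  o1 <- ref_t1$codes[ok]; o2 <- ref_t2$codes[ok]; s2 <- simulated_t2$codes[ok]
  obs_change <- o1 != o2
  sim_change <- o1 != s2
  a <- sum(obs_change & !sim_change)
  b <- sum(obs_change & sim_change & s2 == o2)
  cc <- sum(obs_change & sim_change & s2 != o2)
  d <- sum(!obs_change & sim_change)
  if (!any(obs_change)) {
    warn("no observed-change cells: figure of merit undefined")
    fom <- NA_real_
  } else {
    fom <- b / (a + b + cc + d)
  }
  tibble(fom = fom, a = a, b = b, c = cc, d = d)
}

#' All agreement metrics in one call
#'
#' @inheritParams figure_of_merit
#' @return One-row tibble with `overall_accuracy`, `kappa`, `fom`.
#' @export
validate_simulation <- function(ref_t1, ref_t2, simulated_t2) {
  ok <- oa_kappa(confusion_matrix(ref_t2, simulated_t2))
  fm <- figure_of_merit(ref_t1, ref_t2, simulated_t2)
  tibble(overall_accuracy = ok$overall_accuracy, kappa = ok$kappa,
         fom = fm$fom)
}
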