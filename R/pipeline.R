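# Config-driven orchestration: historical analysis (transition accounting +
# habitat quality), agreement validation and scenario projection
# (Markov demand -> expansion mining -> forest fit -> CA allocation -> habitat
# quality), with per-stage logging and CSV/raster/JSON outputs.

#' Assemble a pipeline run configuration
#'
#' Maps and drivers may be given as in-memory objects or as `.asc` paths;
#' paths are loaded lazily when the run starts.
#'
#' @param t1,t2 [lulc_map()]s or paths to land-cover `.asc` files.
#' @param drivers A [driver_stack()], or a named character vector of `.asc`
#'   paths (names ending in `_cat` flag categorical layers).
#' @param mask Optional 0/1 [raster_layer()] or `.asc` path (restricted-
#'   conversion zone).
#' @param scenario `"ND"`, `"EP"` or a custom [scenario_adjustment()].
#' @param steps Markov steps to the horizon (default 1: a horizon as long as
#'   the calibration period).
#' @param threats,sens,habitat Habitat model parameters (defaults as in
#'   [default_threats()], [default_sensitivity()], [habitat_config()]).
#' @param allocation An [allocation_config()].
#' @param background_ratio,num_trees LEAS background ratio and forest size.
#' @param rng_seed Integer seed for every stochastic stage.
#' @param output_dir Optional run directory; when set, tables (CSV), rasters
#'   (`.asc`), `summary.json` and `log.txt` are written under it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(t1, t2, drivers = NULL, mask = NULL,
                       scenario = "ND", steps = 1,
                       threats = default_threats(),
                       sens = default_sensitivity(),
                       habitat = habitat_config(),
                       allocation = allocation_config(),
                       background_ratio = 1, num_trees = 200,
                       rng_seed = 1L, output_dir = NULL) {
  if (is.character(scenario) && !scenario %in% c("ND", "EP"))
    abort("scenario must be 'ND', 'EP' or a scenario_adjustment")
  structure(list(t1 = t1, t2 = t2, drivers = drivers, mask = mask,
                 scenario = scenario, steps = steps, threats = threats,
                 sens = sens, habitat = habitat, allocation = allocation,
                 background_ratio = background_ratio, num_trees = num_trees,
                 rng_seed = as.integer(rng_seed), output_dir = output_dir),
            class = "run_config")
}

load_map <- function(x, epoch) {
  if (inherits(x, "lulc_map")) return(x)
  read_lulc_asc(x, epoch_label = epoch)
}

load_drivers <- function(x) {
  if (is.null(x) || inherits(x, "driver_stack")) return(x)
  layers <- lapply(seq_along(x), function(i) {
    read_raster_asc(x[[i]], name = names(x)[i],
                    categorical = grepl("_cat$", names(x)[i]))
  })
  names(layers) <- sub("_cat$", "", names(x))
  driver_stack(layers)
}

load_mask <- function(x) {
  if (is.null(x) || inherits(x, "raster_layer")) return(x)
  read_raster_asc(x, name = "redline")
}

pipeline_log <- function(state, ...) {
  msg <- sprintf(...)
  inform(paste0("[luhq] ", msg))
  if (!is.null(state$log_path))
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", sep = "",
        file = state$log_path, append = TRUE)
  invisible(NULL)
}

out_state <- function(config) {
  dir <- config$output_dir
  if (is.null(dir)) return(list(log_path = NULL, dir = NULL))
  for (d in c(dir, file.path(dir, "tables"), file.path(dir, "rasters")))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  list(log_path = file.path(dir, "log.txt"), dir = dir)
}

write_table <- function(state, df, name) {
  if (!is.null(state$dir))
    write.csv(df, file.path(state$dir, "tables", paste0(name, ".csv")),
              row.names = FALSE)
}

write_raster_out <- function(state, layer, name) {
  if (!is.null(state$dir))
    write_raster_asc(layer, file.path(state$dir, "rasters", paste0(name, ".asc")))
}

epoch_hq <- function(map, config, state, tag) {
  hq <- habitat_quality(map, config$threats, config$sens, config$habitat)
  grades <- classify_quality(hq$quality, config$habitat$thresholds)
  gs <- grade_summary(grades, hq$quality, hq$degradation)
  pipeline_log(state, "habitat quality %s: mean Q %.4f, mean D %.4f over %d cells",
               tag, attr(gs, "mean_quality"), attr(gs, "mean_degradation"),
               sum(gs$n_cells))
  write_raster_out(state, hq$quality, paste0("quality_", tag))
  write_raster_out(state, hq$degradation, paste0("degradation_", tag))
  write_raster_out(state, grades, paste0("grades_", tag))
  write_table(state, gs, paste0("grade_summary_", tag))
  list(quality = hq$quality, degradation = hq$degradation, grades = grades,
       grade_summary = gs,
       means = quality_means(hq$quality, hq$degradation))
}

#' Run the historical analysis
#'
#' Transition accounting between the two epochs (matrix, change summary,
#' trajectory map) plus habitat quality, degradation and grade summaries for
#' both epochs; a machine-readable summary is returned (and written as JSON
#' when an output directory is configured).
#'
#' @param config A [run_config()].
#' @return List of class `historical_report`: `transition`, `change_summary`,
#'   `trajectory`, per-epoch habitat results `t1`/`t2`, and `summary` (a
#'   plain list mirrored to `summary.json`).
#' @export
run_historical <- function(config) {
  state <- out_state(config)
  m1 <- load_map(config$t1, "t1"); m2 <- load_map(config$t2, "t2")
  pipeline_log(state, "loaded epochs '%s' (%d cells) and '%s' (%d cells)",
               m1$epoch_label, sum(valid_mask(m1)),
               m2$epoch_label, sum(valid_mask(m2)))
  tm <- compute_transition_matrix(m1, m2)
  cs <- change_summary(tm)
  traj <- trajectory_map(m1, m2)
  pipeline_log(state, "transition matrix: %.4f km2 total, %.4f km2 changed",
               sum(tm$areas), sum(tm$areas) - sum(diag(tm$areas)))
  write_table(state, tidy(tm), "transition_matrix")
  write_table(state, cs, "change_summary")
  write_raster_out(state, traj, "trajectory")
  h1 <- epoch_hq(m1, config, state, m1$epoch_label)
  h2 <- epoch_hq(m2, config, state, m2$epoch_label)
  summary <- list(
    total_area_km2 = sum(tm$areas),
    changed_area_km2 = sum(tm$areas) - sum(diag(tm$areas)),
    change_summary = cs,
    means = dplyr::bind_rows(t1 = h1$means, t2 = h2$means, .id = "epoch"),
    grade_areas = dplyr::bind_rows(t1 = h1$grade_summary,
                                   t2 = h2$grade_summary, .id = "epoch"))
  if (!is.null(state$dir))
    jsonlite::write_json(summary, file.path(state$dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  structure(list(transition = tm, change_summary = cs, trajectory = traj,
                 t1 = h1, t2 = h2, summary = summary),
            class = "historical_report")
}

#' Run a scenario projection
#'
#' Chains Markov estimation from the two calibration epochs, the scenario's
#' transition-probability adjustment (EP preset when `scenario = "EP"`),
#' demand projection, expansion-sample mining and development-probability
#' fitting for growing classes, CA allocation (with the restricted mask under
#' EP) and habitat quality on the simulated map.
#'
#' @param config A [run_config()]; `drivers` is required.
#' @return List of class `scenario_report`: `tpm` (adjusted matrix),
#'   `demand`, `probs`, `simulated` ([lulc_map()] with allocation
#'   attributes), `habitat`, `deltas` (per-class area change base -> horizon)
#'   and `summary`.
#' @export
run_scenario <- function(config) {
  state <- out_state(config)
  m1 <- load_map(config$t1, "t1"); m2 <- load_map(config$t2, "t2")
  drivers <- load_drivers(config$drivers)
  if (is.null(drivers)) abort("run_scenario requires a driver stack")
  mask <- load_mask(config$mask)
  label <- if (is.character(config$scenario)) config$scenario else
    config$scenario$label

  tm <- compute_transition_matrix(m1, m2)
  P <- estimate_transition_probabilities(tm)
  adj <- if (inherits(config$scenario, "scenario_adjustment")) config$scenario
         else if (identical(config$scenario, "EP")) scenario_ep()
         else scenario_nd()
  P_adj <- apply_scenario(P, adj)
  areas_t2 <- colSums(tm$areas)
  demand <- project_demand(P_adj, areas_t2, steps = config$steps)
  pipeline_log(state, "scenario %s demand: %s", label,
               paste(sprintf("%s %.2f", demand$class, demand$area_km2),
                     collapse = "; "))
  write_table(state, demand, paste0("demand_", label))

  cur_areas <- class_areas(m2)
  growing <- demand$code[demand$area_km2 >
                           cur_areas$area_km2[match(demand$code, cur_areas$code)]]
  probs <- list()
  importances <- list()
  for (code in growing) {
    samples <- extract_expansion_samples(m1, m2, drivers, code,
                                         config$background_ratio,
                                         seed = config$rng_seed + code)
    if (length(samples$label) == 0 || length(unique(samples$label)) < 2) {
      # no history of expansion: fall back to a flat surface
      g <- m2$grid
      probs[[as.character(code)]] <-
        raster_layer(matrix(0.5, g$n_rows, g$n_cols), g,
                     name = sprintf("p_dev_%d", code))
      next
    }
    fit <- fit_development_probability(samples, drivers,
                                       seed = config$rng_seed + code,
                                       num_trees = config$num_trees)
    probs[[as.character(code)]] <- fit
    importances[[as.character(code)]] <- fit$importance
    write_table(state, fit$importance, sprintf("importance_class%d_%s", code, label))
  }
  pipeline_log(state, "fitted development probabilities for classes: %s",
               paste(growing, collapse = ", "))

  alloc_cfg <- config$allocation
  alloc_cfg$rng_seed <- config$rng_seed
  if (identical(label, "EP")) alloc_cfg$restricted_mask <- mask
  sim <- allocate(m2, demand, probs, alloc_cfg)
  pipeline_log(state, "allocation %s: converged %s after %d iterations",
               label, attr(sim, "converged"), attr(sim, "iterations"))
  write_raster_out(state, raster_layer(sim$codes, sim$grid, "lulc_sim",
                                       categorical = TRUE),
                   paste0("lulc_2035_", label))

  hq <- epoch_hq(sim, config, state, paste0("sim_", label))
  deltas <- area_change_table(cur_areas$area_km2,
                              class_areas(sim)$area_km2,
                              labels = cur_areas$name)
  write_table(state, deltas, paste0("area_deltas_", label))
  summary <- list(scenario = label, demand = demand,
                  residual = attr(sim, "residual"),
                  converged = attr(sim, "converged"),
                  deltas = deltas, means = hq$means,
                  grade_areas = hq$grade_summary)
  if (!is.null(state$dir))
    jsonlite::write_json(summary, file.path(state$dir,
                                            paste0("summary_", label, ".json")),
                         auto_unbox = TRUE, digits = NA)
  structure(list(tpm = P_adj, demand = demand, probs = probs,
                 importances = importances, simulated = sim, habitat = hq,
                 deltas = deltas, summary = summary),
            class = "scenario_report")
}

#' @export
print.historical_report <- function(x, ...) {
  cat("<historical_report>\n")
  print(x$change_summary, n = Inf)
  print(x$summary$means)
  invisible(x)
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %s (converged: %s)\n", x$summary$scenario,
              x$summary$converged))
  print(x$deltas, n = Inf)
  invisible(x)
}

#' @export
#' @exportS3Method generics::glance
glance.historical_report <- function(x, ...) {
  m <- x$summary$means
  tibble(total_area_km2 = x$summary$total_area_km2,
         changed_area_km2 = x$summary$changed_area_km2,
         mean_quality_t1 = m$mean_quality[1],
         mean_quality_t2 = m$mean_quality[2],
         mean_degradation_t1 = m$mean_degradation[1],
         mean_degradation_t2 = m$mean_degradation[2])
}

#' @export
#' @exportS3Method generics::glance
glance.scenario_report <- function(x, ...) {
  tibble(scenario = x$summary$scenario,
         converged = x$summary$converged,
         mean_quality = x$summary$means$mean_quality,
         mean_degradation = x$summary$means$mean_degradation,
         max_residual_km2 = max(abs(x$summary$residual$residual_km2)))
}
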