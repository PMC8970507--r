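# End-to-end driver wiring the two phases in order: observations -> EA ->
# GLM -> selection -> disaggregation -> consistency check. Configuration is
# a single structured list (optionally read from YAML); all randomness flows
# from one seed.

#' Build a run configuration
#'
#' @param paths named list of input CSV paths (`trips`, `costs`,
#'   `segment_costs`, `transversal`); ignored when `scenario` is given.
#' @param scenario optional [fleet_scenario()]: generate the inputs instead
#'   of reading them.
#' @param out_dir output directory for the report tree.
#' @param activity_metric metric defining the prevalent metier.
#' @param coverage_threshold global coverage threshold in (0, 1].
#' @param coverage_overrides optional named per-segment thresholds.
#' @param min_n minimum observations per regression (default 30).
#' @param alpha significance level (default 0.05).
#' @param relationships EA catalogue (see [default_relationships()]).
#' @param candidates selection candidates (see [default_candidates()]).
#' @param fallback fallback policy for unmodelled metiers (`"skip"` or
#'   `"pooled"`).
#' @param scale_intercepts_by_vessel_count see [disaggregate()].
#' @param variable_composition see [run_ea()].
#' @param col_maps optional column maps per table (see
#'   [read_fishery_data()]).
#' @param plots write diagnostic plots (PNG) under `out_dir/plots`.
#' @param seed integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(paths = NULL, scenario = NULL, out_dir = "metiercost_out",
                       activity_metric = "hours_at_sea",
                       coverage_threshold = 0.8, coverage_overrides = NULL,
                       min_n = 30, alpha = 0.05,
                       relationships = default_relationships(),
                       candidates = default_candidates(),
                       fallback = "skip",
                       scale_intercepts_by_vessel_count = FALSE,
                       variable_composition = c("fuel_cost_adj",
                                                "labour_cost_adj",
                                                "other_variable_adj"),
                       col_maps = NULL, plots = FALSE, seed = 1L) {
  cfg <- list(paths = paths, scenario = scenario, out_dir = out_dir,
              activity_metric = activity_metric,
              coverage_threshold = coverage_threshold,
              coverage_overrides = coverage_overrides,
              min_n = min_n, alpha = alpha, relationships = relationships,
              candidates = candidates, fallback = fallback,
              scale_intercepts_by_vessel_count =
                scale_intercepts_by_vessel_count,
              variable_composition = variable_composition,
              col_maps = col_maps, plots = plots, seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Rejects out-of-range thresholds and missing inputs before any
#' computation starts.
#'
#' @param config a `run_config` (or plain list with the same fields).
#' @return the config, invisibly, or an error.
#' @export
validate_run_config <- function(config) {
  thr <- config$coverage_threshold
  if (!is.numeric(thr) || length(thr) != 1L || thr <= 0 || thr > 1) {
    stop("validation error: coverage_threshold must be in (0, 1]",
         call. = FALSE)
  }
  if (!is.null(config$coverage_overrides) &&
      (any(config$coverage_overrides <= 0) ||
       any(config$coverage_overrides > 1))) {
    stop("validation error: coverage_overrides must be in (0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    stop("validation error: alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(config$min_n) || config$min_n < 2) {
    stop("validation error: min_n must be >= 2", call. = FALSE)
  }
  if (!config$activity_metric %in%
      c("hours_at_sea", "fishing_days", "trip_count")) {
    stop("validation error: unknown activity_metric", call. = FALSE)
  }
  if (!config$fallback %in% c("skip", "pooled")) {
    stop("validation error: fallback must be 'skip' or 'pooled'",
         call. = FALSE)
  }
  if (is.null(config$scenario)) {
    need <- c("trips", "costs", "segment_costs", "transversal")
    if (is.null(config$paths) || !all(need %in% names(config$paths))) {
      stop("validation error: paths must name trips, costs, segment_costs ",
           "and transversal files (or provide a scenario)", call. = FALSE)
    }
  }
  invisible(config)
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the [run_config()] arguments; `scenario` may be a
#' mapping of [fleet_scenario()] arguments (with `segments` a list of
#' segment mappings).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenario <- NULL
  if (!is.null(y$scenario)) {
    sargs <- y$scenario
    if (!is.null(sargs$true_fuel_intercepts)) {
      sargs$true_fuel_intercepts <- unlist(sargs$true_fuel_intercepts)
    }
    if (!is.null(sargs$revenue_rates)) {
      sargs$revenue_rates <- unlist(sargs$revenue_rates)
    }
    if (!is.null(sargs$true_slope_offsets)) {
      sargs$true_slope_offsets <- unlist(sargs$true_slope_offsets)
    }
    if (!is.null(sargs$years)) sargs$years <- as.integer(sargs$years)
    scenario <- do.call(fleet_scenario, sargs)
  }
  args <- y[setdiff(names(y), "scenario")]
  if (!is.null(args$coverage_overrides)) {
    args$coverage_overrides <- unlist(args$coverage_overrides)
  }
  if (!is.null(args$relationships)) {
    args$relationships <- as.data.frame(
      do.call(rbind, lapply(args$relationships, as.data.frame)),
      stringsAsFactors = FALSE)
  }
  do.call(run_config, c(args, list(scenario = scenario)))
}

log_line <- function(con, ...) {
  msg <- sprintf(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full two-phase pipeline
#'
#' Executes, in order: input generation or reading, observation building,
#' coverage filtering, exploratory regressions, GLM fitting and model
#' selection, disaggregation, and the consistency check. Every stage's row
#' counts and dropped rows are logged to stderr and to `out_dir/run.log`;
#' result tables are written as CSVs under `out_dir` and GLM summaries
#' under `out_dir/glm/<cost_variable>/`.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with `data`, `observations`, `coverage`, `ea`,
#'   `selections`, `disaggregated`, `consistency`.
#' @export
run_all <- function(config) {
  validate_run_config(config)
  set.seed(config$seed)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logcon <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logcon))

  if (!is.null(config$scenario)) {
    sim <- simulate_fleet(config$scenario, seed = config$seed)
    data <- list(trips = sim$trips, costs = sim$costs,
                 segment_costs = sim$segment_costs,
                 transversal = sim$transversal,
                 rejections = empty_rejection_log())
    # round-trip the generated tables through the CSV layer so a simulated
    # run exercises the same input path as a real one
    in_dir <- file.path(out_dir, "inputs")
    dir.create(in_dir, showWarnings = FALSE)
    for (nm in c("trips", "costs", "segment_costs", "transversal")) {
      write_csv_exact(data[[nm]], file.path(in_dir, paste0(nm, ".csv")))
    }
    log_line(logcon, "simulate: %d trips, %d cost records (seed %d)",
             nrow(data$trips), nrow(data$costs), config$seed)
  } else {
    data <- read_fishery_data(config$paths$trips, config$paths$costs,
                              config$paths$segment_costs,
                              config$paths$transversal, config$col_maps)
    log_line(logcon, "read: %d trips, %d cost records, %d rejected rows",
             nrow(data$trips), nrow(data$costs), nrow(data$rejections))
  }

  obs <- build_observations(data$trips, data$costs, config$activity_metric)
  log_line(logcon,
           "observations: %d vessel-years (activity metric %s); %d prevalence tie(s); share applied to costs and transversal totals",
           nrow(obs), config$activity_metric, length(attr(obs, "ties")))

  flt <- filter_by_coverage(obs, config$coverage_threshold,
                            config$coverage_overrides)
  log_line(logcon, "coverage filter (threshold %.2f): %d -> %d observations",
           config$coverage_threshold, nrow(obs), nrow(flt$observations))

  ea <- run_ea(flt$observations, config$relationships, config$min_n,
               config$alpha, config$variable_composition)
  log_line(logcon, "exploratory regressions: %d rows", nrow(ea))

  sels <- run_glm(flt$observations, config$candidates, config$alpha,
                  config$min_n,
                  variable_composition = config$variable_composition)
  glm_tab <- glm_summary_table(sels)
  for (sel in sels$selections) {
    if (is.null(sel$fit)) next
    sub <- file.path(out_dir, "glm", sel$cost_variable)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    txt <- utils::capture.output(print(summary(sel$fit)))
    writeLines(txt, file.path(sub, paste0(sel$fleet_segment, ".txt")))
  }
  log_line(logcon, "model selection: %s",
           paste(sprintf("%s/%s=%s", sels$summary$fleet_segment,
                         sels$summary$cost_variable,
                         sels$summary$chosen_equation), collapse = ", "))

  disagg <- disaggregate(sels, data$transversal, fallback = config$fallback,
                         pooled_slopes = ea,
                         scale_intercepts_by_vessel_count =
                           config$scale_intercepts_by_vessel_count)
  skipped <- attr(disagg, "skipped")
  log_line(logcon, "disaggregation: %d metier-level estimates, %d skipped (fallback %s)",
           nrow(disagg), if (is.null(skipped)) 0L else nrow(skipped),
           config$fallback)

  consistency <- NULL
  if (nrow(disagg) > 0L) {
    consistency <- consistency_check(disagg, data$segment_costs)
    log_line(logcon, "consistency: overall mean |relative difference| = %.2f%%",
             consistency$overall_abs_relative_difference)
  } else {
    log_line(logcon, "consistency: skipped (no disaggregated rows)")
  }

  results <- list(
    regressions = as.data.frame(ea),
    glm_summaries = glm_tab,
    coverage = flt$coverage,
    disaggregated_costs = as.data.frame(disagg),
    consistency_check = if (is.null(consistency))
      data.frame(year = numeric(), fleet_segment = character(),
                 variable_name = character(), sum_costs_by_metier = numeric(),
                 costs_by_fleet_segment = numeric(),
                 relative_difference = numeric(), flagged = logical())
      else consistency$table,
    rejections = data$rejections
  )
  write_results(results, out_dir)

  if (isTRUE(config$plots)) {
    pdir <- file.path(out_dir, "plots")
    dir.create(pdir, showWarnings = FALSE)
    for (k in seq_len(nrow(config$relationships))) {
      cv <- config$relationships$cost_variable[k]
      tv <- config$relationships$transversal[k]
      grDevices::png(file.path(pdir, sprintf("ea_%s_vs_%s.png", cv, tv)),
                     width = 1200, height = 900)
      try(plot_ea(flt$observations, cv, tv, min_n = config$min_n),
          silent = TRUE)
      grDevices::dev.off()
    }
    if (!is.null(consistency)) {
      for (vn in unique(consistency$table$variable_name)) {
        grDevices::png(file.path(pdir, sprintf("consistency_%s.png", vn)),
                       width = 1000, height = 700)
        try(plot_consistency(consistency, vn), silent = TRUE)
        grDevices::dev.off()
      }
    }
  }

  invisible(list(data = data, observations = obs,
                 coverage = flt$coverage,
                 filtered_observations = flt$observations, ea = ea,
                 selections = sels, disaggregated = disagg,
                 consistency = consistency))
}
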