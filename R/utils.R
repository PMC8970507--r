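# Internal helpers shared across the package.

# Canonical cost variables and the observation columns that carry their
# activity-adjusted values.
COST_VARIABLES <- c(
  fuel_cost        = "fuel_cost_adj",
  fuel_consumption = "fuel_consumption_adj",
  labour_cost      = "labour_cost_adj",
  other_variable   = "other_variable_adj"
)

# Canonical transversal variables. revenue_minus_* are derived on demand.
TRANSVERSALS <- c(
  "effort_hours", "effort_dayskw", "revenue",
  "revenue_minus_variable", "revenue_minus_fuel"
)

# cost variable -> variable_name used in segment-level official cost tables
VARIABLE_NAME_MAP <- c(
  fuel_cost        = "fuel_costs",
  fuel_consumption = "fuel_consumption",
  labour_cost      = "labour_costs",
  other_variable   = "other"
)

# transversal -> column of the metier-level transversal table usable in phase 2
TRANSVERSAL_DISAGG_COLUMN <- c(
  effort_hours  = "effort_hours",
  effort_dayskw = "effort_dayskw",
  revenue       = "landings_value"
)

#' Extract a transversal variable from an observation table
#'
#' Observations carry `hours_at_sea`, `effort_dayskw` and `revenue` directly;
#' the derived regressors `revenue_minus_variable` and `revenue_minus_fuel`
#' are computed here. The composition of "total variable costs" subtracted in
#' `revenue_minus_variable` is configurable through `variable_composition`.
#'
#' @param observations a metier observation data frame
#'   (see [build_observations()]).
#' @param transversal one of `"effort_hours"`, `"effort_dayskw"`, `"revenue"`,
#'   `"revenue_minus_variable"`, `"revenue_minus_fuel"`.
#' @param variable_composition character vector of adjusted cost columns
#'   summed as "total variable costs".
#' @return numeric vector aligned with `observations` rows.
#' @keywords internal
transversal_values <- function(observations, transversal,
                               variable_composition = c("fuel_cost_adj",
                                                        "labour_cost_adj",
                                                        "other_variable_adj")) {
  switch(transversal,
    effort_hours  = observations$hours_at_sea,
    effort_dayskw = observations$effort_dayskw,
    revenue       = observations$revenue,
    revenue_minus_fuel = observations$revenue - observations$fuel_cost_adj,
    revenue_minus_variable = {
      vc <- rep(0, nrow(observations))
      for (col in variable_composition) {
        v <- observations[[col]]
        v[is.na(v)] <- 0
        vc <- vc + v
      }
      observations$revenue - vc
    },
    stop("unknown transversal variable: ", transversal, call. = FALSE)
  )
}

cost_values <- function(observations, cost_variable) {
  col <- COST_VARIABLES[[cost_variable]]
  if (is.null(col) || !col %in% names(observations)) {
    stop("unknown or absent cost variable: ", cost_variable, call. = FALSE)
  }
  observations[[col]]
}

# Deterministic ordering of a data frame by all of its columns, left to right.
order_rows <- function(df) {
  if (nrow(df) == 0L) return(df)
  df[do.call(order, unname(as.list(df))), , drop = FALSE]
}

# sprintf("%.17g") formatting keeps doubles exact through a CSV round-trip.
format_exact <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
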