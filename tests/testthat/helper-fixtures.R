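# Small in-code fixtures shared across tests.

make_trips <- function(vessel_id, year, fleet_segment, metier, hours,
                       days = pmax(1, round(hours / 14)), kw = 200,
                       value = hours * 100, weight = value / 5) {
  data.frame(vessel_id = vessel_id, year = year,
             fleet_segment = fleet_segment, metier = metier,
             hours_at_sea = hours, fishing_days = days, kw = kw,
             landings_weight = weight, landings_value = value,
             stringsAsFactors = FALSE)
}

make_costs <- function(vessel_id, year, fuel = 1000, cons = 2000,
                       labour = 3000, other = 100) {
  data.frame(vessel_id = vessel_id, year = year, fuel_cost = fuel,
             fuel_consumption = cons, labour_cost = labour,
             other_variable_costs = other, stringsAsFactors = FALSE)
}

# observations table built directly (bypassing trips) for regression/GLM
# tests: one segment, given metier labels, x = effort hours
make_obs <- function(metier, hours, fuel, labour = NA_real_,
                     revenue = NA_real_, segment = "SEG", year = 2015) {
  n <- length(hours)
  data.frame(
    vessel_id = sprintf("V%03d", seq_len(n)), year = year,
    fleet_segment = segment, prevalent_metier = metier,
    activity_share = 1, hours_at_sea = hours,
    effort_dayskw = hours * 10,
    revenue = if (length(revenue) == 1L && is.na(revenue[1L]))
      hours * 120 else revenue,
    fuel_cost_adj = fuel,
    fuel_consumption_adj = fuel * 1.8,
    labour_cost_adj = if (length(labour) == 1L && is.na(labour[1L]))
      hours * 40 else labour,
    other_variable_adj = hours * 5,
    stringsAsFactors = FALSE)
}

# write a data frame to a temp CSV and return the path
tmp_csv <- function(df, name = "t") {
  path <- tempfile(paste0(name, "_"), fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# independent normal-equation oracle for least squares on a design matrix
ls_oracle <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))[, 1L]
}
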