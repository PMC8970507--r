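# Readers, validation and writers for the four flat-CSV input layouts:
# trip-level activity, annual vessel costs, official segment costs and
# metier-level transversal data. Layouts mirror the DCF/FDI concepts with
# named headers; a column-mapping config lets users rename columns.

TRIP_COLUMNS <- c("vessel_id", "year", "fleet_segment", "metier",
                  "hours_at_sea", "fishing_days", "kw",
                  "landings_weight", "landings_value")
COST_COLUMNS <- c("vessel_id", "year", "fuel_cost", "fuel_consumption",
                  "labour_cost")
COST_OPTIONAL <- "other_variable_costs"
SEGMENT_COST_COLUMNS <- c("year", "fleet_segment", "variable_name", "value")
TRANSVERSAL_COLUMNS <- c("year", "fleet_segment", "metier",
                         "effort_hours", "landings_value")
TRANSVERSAL_OPTIONAL <- "effort_dayskw"

# Read a CSV with case-insensitive header matching and optional renaming.
# col_map: named character vector, names = canonical column, values = header
# used in the file.
read_mapped_csv <- function(path, required, optional = character(),
                            col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(df)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      hit <- match(tolower(col_map[[canon]]), tolower(nm))
      if (!is.na(hit)) nm[hit] <- canon
    }
  }
  nm <- tolower(nm)
  names(df) <- nm
  missing <- setdiff(required, nm)
  if (length(missing) > 0L) {
    stop("schema error in ", basename(path), ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[, c(required, intersect(optional, nm)), drop = FALSE]
}

reject <- function(log, table, rows, reason) {
  if (length(rows) == 0L) return(log)
  rbind(log, data.frame(table = table, row = rows, reason = reason,
                        stringsAsFactors = FALSE))
}

empty_rejection_log <- function() {
  data.frame(table = character(), row = integer(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Read and validate trip-level activity records
#'
#' Each row is one fishing trip: vessel, year, fleet segment, metier, effort
#' (hours at sea, fishing days), engine power and landings. Rows violating
#' hard invariants (negative effort or landings, non-positive kW, missing
#' metier) are rejected and logged. A missing `landings_value` does not
#' reject the row: the trip still contributes to effort-based (fuel)
#' analyses and is only excluded from revenue-based (labour) analyses.
#' Vessel-years whose trips disagree on the fleet segment are rejected
#' entirely, since the segment must be constant within a vessel-year.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping canonical column
#'   names to the headers used in the file, e.g.
#'   `c(vessel_id = "VESSEL", hours_at_sea = "HRS")`.
#' @return a `data.frame` of validated trips with attribute `"rejections"`
#'   (a data frame of table, row, reason).
#' @export
read_trips <- function(path, col_map = NULL) {
  df <- read_mapped_csv(path, TRIP_COLUMNS, col_map = col_map)
  log <- empty_rejection_log()
  num <- c("year", "hours_at_sea", "fishing_days", "kw",
           "landings_weight", "landings_value")
  for (col in num) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  bad <- which(is.na(df$vessel_id) | df$vessel_id == "" |
               is.na(df$metier) | df$metier == "" |
               is.na(df$fleet_segment) | df$fleet_segment == "" |
               is.na(df$year))
  log <- reject(log, "trips", bad, "missing identifier (vessel, year, segment or metier)")
  ok <- setdiff(seq_len(nrow(df)), bad)

  neg <- ok[with(df[ok, , drop = FALSE],
                 is.na(hours_at_sea) | hours_at_sea < 0 |
                 is.na(fishing_days) | fishing_days < 0 |
                 is.na(kw) | kw <= 0 |
                 (!is.na(landings_weight) & landings_weight < 0) |
                 (!is.na(landings_value) & landings_value < 0))]
  log <- reject(log, "trips", neg, "negative or invalid effort/power/landings")
  ok <- setdiff(ok, neg)

  # fleet_segment must be constant within a vessel-year
  key <- paste(df$vessel_id, df$year, sep = "\r")
  nseg <- tapply(df$fleet_segment[ok], key[ok], function(s) length(unique(s)))
  badkeys <- names(nseg)[nseg > 1L]
  inc <- ok[key[ok] %in% badkeys]
  log <- reject(log, "trips", inc, "fleet_segment not constant within vessel-year")
  ok <- setdiff(ok, inc)

  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- log
  out
}

#' Read and validate annual per-vessel variable costs
#'
#' One row per vessel-year with fuel cost, fuel consumption, labour cost and
#' (optionally) other variable costs. Negative values reject the row;
#' duplicated (vessel_id, year) keys are a validation error because the
#' proportional attribution step requires a unique annual record.
#'
#' @inheritParams read_trips
#' @return validated `data.frame` with attribute `"rejections"`.
#' @export
read_vessel_costs <- function(path, col_map = NULL) {
  df <- read_mapped_csv(path, COST_COLUMNS, COST_OPTIONAL, col_map = col_map)
  if (!"other_variable_costs" %in% names(df)) df$other_variable_costs <- NA_real_
  log <- empty_rejection_log()
  num <- c("year", "fuel_cost", "fuel_consumption", "labour_cost",
           "other_variable_costs")
  for (col in num) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  key <- paste(df$vessel_id, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("validation error: duplicate (vessel_id, year) in cost file: ",
         paste(gsub("\r", "/", dup), collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(df$vessel_id) | df$vessel_id == "" | is.na(df$year))
  log <- reject(log, "costs", bad, "missing vessel_id or year")
  ok <- setdiff(seq_len(nrow(df)), bad)

  neg <- ok[with(df[ok, , drop = FALSE],
                 (!is.na(fuel_cost) & fuel_cost < 0) |
                 (!is.na(fuel_consumption) & fuel_consumption < 0) |
                 (!is.na(labour_cost) & labour_cost < 0) |
                 (!is.na(other_variable_costs) & other_variable_costs < 0))]
  log <- reject(log, "costs", neg, "negative cost value")
  ok <- setdiff(ok, neg)

  allna <- ok[with(df[ok, , drop = FALSE],
                   is.na(fuel_cost) & is.na(fuel_consumption) &
                   is.na(labour_cost) & is.na(other_variable_costs))]
  log <- reject(log, "costs", allna, "all cost values missing")
  ok <- setdiff(ok, allna)

  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- log
  out
}

#' Read official variable costs by fleet segment and year
#'
#' Long layout: one row per (year, fleet_segment, variable_name) with
#' `variable_name` one of `fuel_costs`, `labour_costs`, `fuel_consumption`,
#' `other`. Rows with a missing or negative value are dropped and logged.
#'
#' @inheritParams read_trips
#' @return validated `data.frame` with attribute `"rejections"`.
#' @export
read_segment_costs <- function(path, col_map = NULL) {
  df <- read_mapped_csv(path, SEGMENT_COST_COLUMNS, col_map = col_map)
  log <- empty_rejection_log()
  df$year <- suppressWarnings(as.numeric(df$year))
  df$value <- suppressWarnings(as.numeric(df$value))

  bad <- which(is.na(df$year) | is.na(df$fleet_segment) | df$fleet_segment == "" |
               !(df$variable_name %in% VARIABLE_NAME_MAP))
  log <- reject(log, "segment_costs", bad, "missing key or unknown variable_name")
  ok <- setdiff(seq_len(nrow(df)), bad)

  mis <- ok[is.na(df$value[ok]) | df$value[ok] < 0]
  log <- reject(log, "segment_costs", mis, "missing or negative value")
  ok <- setdiff(ok, mis)

  key <- paste(df$year, df$fleet_segment, df$variable_name, sep = "\r")
  if (anyDuplicated(key[ok])) {
    stop("validation error: duplicate (year, fleet_segment, variable_name) ",
         "in segment cost file", call. = FALSE)
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- log
  out
}

#' Read metier-level transversal data (effort and landings value)
#'
#' FDI-style layout: one row per (year, fleet_segment, metier) with effort in
#' hours at sea, optionally fishing days x kW, and landings value. Rows with
#' a missing effort-hours or landings value are dropped and logged.
#'
#' @inheritParams read_trips
#' @return validated `data.frame` with attribute `"rejections"`.
#' @export
read_transversal <- function(path, col_map = NULL) {
  df <- read_mapped_csv(path, TRANSVERSAL_COLUMNS, TRANSVERSAL_OPTIONAL,
                        col_map = col_map)
  if (!"effort_dayskw" %in% names(df)) df$effort_dayskw <- NA_real_
  log <- empty_rejection_log()
  for (col in c("year", "effort_hours", "effort_dayskw", "landings_value")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  bad <- which(is.na(df$year) | is.na(df$fleet_segment) | df$fleet_segment == "" |
               is.na(df$metier) | df$metier == "")
  log <- reject(log, "transversal", bad, "missing key")
  ok <- setdiff(seq_len(nrow(df)), bad)

  mis <- ok[with(df[ok, , drop = FALSE],
                 is.na(effort_hours) | effort_hours < 0 |
                 is.na(landings_value) | landings_value < 0 |
                 (!is.na(effort_dayskw) & effort_dayskw < 0))]
  log <- reject(log, "transversal", mis, "missing or negative effort/landings value")
  ok <- setdiff(ok, mis)

  key <- paste(df$year, df$fleet_segment, df$metier, sep = "\r")
  if (anyDuplicated(key[ok])) {
    stop("validation error: duplicate (year, fleet_segment, metier) ",
         "in transversal file", call. = FALSE)
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- log
  out
}

#' Read the four input tables at once
#'
#' @param trips,costs,segment_costs,transversal CSV file paths.
#' @param col_maps optional named list of column maps, with elements
#'   `trips`, `costs`, `segment_costs`, `transversal`.
#' @return a list of class `fishery_data` with the four validated tables and
#'   a combined `$rejections` log. Validation is total: every input row is
#'   either in a table or in the log with a reason.
#' @export
read_fishery_data <- function(trips, costs, segment_costs, transversal,
                              col_maps = NULL) {
  tr <- read_trips(trips, col_maps$trips)
  co <- read_vessel_costs(costs, col_maps$costs)
  sc <- read_segment_costs(segment_costs, col_maps$segment_costs)
  tv <- read_transversal(transversal, col_maps$transversal)
  out <- list(
    trips = tr, costs = co, segment_costs = sc, transversal = tv,
    rejections = rbind(attr(tr, "rejections"), attr(co, "rejections"),
                       attr(sc, "rejections"), attr(tv, "rejections"))
  )
  class(out) <- "fishery_data"
  out
}

#' @export
print.fishery_data <- function(x, ...) {
  cat("Fishery input data\n")
  cat(sprintf("  trips:         %6d rows\n", nrow(x$trips)))
  cat(sprintf("  vessel costs:  %6d rows\n", nrow(x$costs)))
  cat(sprintf("  segment costs: %6d rows\n", nrow(x$segment_costs)))
  cat(sprintf("  transversal:   %6d rows\n", nrow(x$transversal)))
  nrej <- nrow(x$rejections)
  if (nrej > 0L) {
    cat(sprintf("  rejected:      %6d rows\n", nrej))
    tab <- table(paste(x$rejections$table, x$rejections$reason, sep = ": "))
    for (i in seq_along(tab)) {
      cat(sprintf("    %s (%d)\n", names(tab)[i], tab[[i]]))
    }
  } else {
    cat("  no rows rejected\n")
  }
  invisible(x)
}

# Write a data frame as CSV with doubles formatted to 17 significant digits,
# so that write -> read reproduces numeric values exactly.
write_csv_exact <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- format_exact(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write result tables to a directory
#'
#' One CSV per result table with deterministic column order and row sort, so
#' repeated runs on identical inputs produce byte-identical files. Doubles
#' are written to full precision (17 significant digits).
#'
#' @param results named list of data frames (e.g. `regressions`,
#'   `glm_summaries`, `disaggregated_costs`, `consistency_check`).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the vector of file paths written.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (name in sort(names(results))) {
    df <- results[[name]]
    if (!is.data.frame(df)) next
    path <- file.path(out_dir, paste0(name, ".csv"))
    write_csv_exact(order_rows(df), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
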