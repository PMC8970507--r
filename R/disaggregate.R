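# Phase 2: apply the selected coefficients to metier-level transversal data
# and reconcile the resulting metier costs against the official segment
# totals.

#' Disaggregate segment costs to metier level
#'
#' For each (year, metier) row of the transversal table belonging to the
#' selection's fleet segment, estimates the metier's cost from the selected
#' model: `alpha_m + beta * X_m` (EQ1), `alpha_m + (beta + gamma_m) * X_m`
#' (EQ2), or `alpha * X_m` (EQ3, same slope for all metiers). `X_m` is the
#' metier's transversal total for the year, taken from the column matching
#' the fitted regressor (`effort_hours`, `effort_dayskw`, or
#' `landings_value` for revenue).
#'
#' Metiers present in the transversal data but absent from an EQ1/EQ2 fit
#' (they fell below the coverage threshold in phase 1) are handled by the
#' fallback policy: `"skip"` leaves them unallocated, which reproduces the
#' coverage-loss share of the reconciliation gap; `"pooled"` applies the
#' segment's pooled zero-intercept slope as an EQ3-style estimate.
#'
#' @param selection a `cost_model_selection` (or a
#'   `cost_model_selection_set`, in which case all selections are applied
#'   and the results stacked).
#' @param transversal metier-level transversal table (see
#'   [read_transversal()]).
#' @param fallback `"skip"` (default) or `"pooled"`.
#' @param pooled_slopes exploratory regression table from [run_ea()]; its
#'   `"ALL"` rows supply the pooled slope when `fallback = "pooled"`.
#' @param scale_intercepts_by_vessel_count if `TRUE`, multiply each metier
#'   intercept `alpha_m` by the number of active vessels before adding it to
#'   the fleet-level product `beta * X_m`. Off by default: the baseline
#'   method adds the vessel-year-scale intercept once per metier, and the
#'   flag exists for users who want scale consistency between the two terms.
#' @param vessel_counts data frame (year, fleet_segment, metier, n_vessels),
#'   required when `scale_intercepts_by_vessel_count = TRUE`.
#' @return data frame of class `disaggregated_costs`: one row per (year,
#'   fleet_segment, metier, cost_variable) with `transversal_value`,
#'   `equation_used` and `estimated_value`. Skipped metiers are recorded in
#'   attribute `"skipped"`.
#' @export
disaggregate <- function(selection, transversal,
                         fallback = c("skip", "pooled"),
                         pooled_slopes = NULL,
                         scale_intercepts_by_vessel_count = FALSE,
                         vessel_counts = NULL) {
  fallback <- match.arg(fallback)
  if (inherits(selection, "cost_model_selection_set")) {
    parts <- lapply(selection$selections, disaggregate, transversal,
                    fallback = fallback, pooled_slopes = pooled_slopes,
                    scale_intercepts_by_vessel_count =
                      scale_intercepts_by_vessel_count,
                    vessel_counts = vessel_counts)
    out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
    attr(out, "skipped") <- do.call(rbind, c(
      lapply(parts, attr, "skipped"), list(make.row.names = FALSE)))
    class(out) <- c("disaggregated_costs", "data.frame")
    return(out)
  }
  stopifnot(inherits(selection, "cost_model_selection"))
  empty <- data.frame(
    year = numeric(), fleet_segment = character(), metier = character(),
    cost_variable = character(), transversal_value = numeric(),
    equation_used = character(), estimated_value = numeric(),
    stringsAsFactors = FALSE)
  skipped <- empty[, c("year", "fleet_segment", "metier", "cost_variable")]
  if (selection$chosen_equation == "none") {
    out <- empty
    attr(out, "skipped") <- skipped
    class(out) <- c("disaggregated_costs", "data.frame")
    return(out)
  }
  xcol <- TRANSVERSAL_DISAGG_COLUMN[selection$chosen_transversal]
  if (is.na(xcol)) {
    stop("transversal '", selection$chosen_transversal,
         "' is not observable at metier level; cannot disaggregate",
         call. = FALSE)
  }
  tv <- transversal[transversal$fleet_segment == selection$fleet_segment, ,
                    drop = FALSE]
  if (nrow(tv) == 0L) {
    warning("no transversal rows for segment ", selection$fleet_segment,
            call. = FALSE)
    out <- empty
    attr(out, "skipped") <- skipped
    class(out) <- c("disaggregated_costs", "data.frame")
    return(out)
  }
  X <- tv[[xcol]]
  if (anyNA(X)) {
    stop("transversal column '", xcol, "' has missing values for segment ",
         selection$fleet_segment, call. = FALSE)
  }
  fit <- selection$fit
  cf <- coef(fit)
  eq <- selection$chosen_equation
  est <- rep(NA_real_, nrow(tv))
  used <- rep(eq, nrow(tv))

  if (eq == "EQ3") {
    est <- cf$beta * X
  } else {
    modelled <- tv$metier %in% names(cf$alpha)
    if (any(modelled)) {
      m <- tv$metier[modelled]
      a <- cf$alpha[m]
      if (scale_intercepts_by_vessel_count) {
        if (is.null(vessel_counts)) {
          stop("vessel_counts required when scale_intercepts_by_vessel_count",
               call. = FALSE)
        }
        key <- paste(tv$year[modelled], selection$fleet_segment, m, sep = "\r")
        vckey <- paste(vessel_counts$year, vessel_counts$fleet_segment,
                       vessel_counts$metier, sep = "\r")
        nv <- vessel_counts$n_vessels[match(key, vckey)]
        if (anyNA(nv)) {
          stop("vessel_counts missing for some (year, segment, metier)",
               call. = FALSE)
        }
        a <- a * nv
      }
      b <- cf$beta + if (eq == "EQ2") cf$gamma[m] else 0
      est[modelled] <- a + b * X[modelled]
    }
    if (any(!modelled)) {
      if (fallback == "pooled") {
        slope <- pooled_slope_for(pooled_slopes, selection)
        if (is.na(slope)) {
          stop("fallback = 'pooled' but no pooled slope available for ",
               selection$fleet_segment, " / ", selection$cost_variable,
               call. = FALSE)
        }
        est[!modelled] <- slope * X[!modelled]
        used[!modelled] <- "pooled"
      } else {
        skipped <- data.frame(
          year = tv$year[!modelled],
          fleet_segment = selection$fleet_segment,
          metier = tv$metier[!modelled],
          cost_variable = selection$cost_variable,
          stringsAsFactors = FALSE)
      }
    }
  }
  keep <- !is.na(est)
  out <- data.frame(
    year = tv$year[keep], fleet_segment = selection$fleet_segment,
    metier = tv$metier[keep], cost_variable = selection$cost_variable,
    transversal_value = X[keep], equation_used = used[keep],
    estimated_value = est[keep], stringsAsFactors = FALSE)
  out <- order_rows(out)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("disaggregated_costs", "data.frame")
  out
}

# pooled ("ALL") zero-intercept slope matching the selection's segment, cost
# variable and transversal
pooled_slope_for <- function(pooled_slopes, selection) {
  if (is.null(pooled_slopes)) return(NA_real_)
  hit <- pooled_slopes$fleet_segment == selection$fleet_segment &
    pooled_slopes$metier == "ALL" &
    pooled_slopes$cost_variable == selection$cost_variable &
    pooled_slopes$transversal == selection$chosen_transversal
  if (!any(hit)) return(NA_real_)
  pooled_slopes$slope[which(hit)[1L]]
}

#' Consistency check between disaggregated and official segment costs
#'
#' Sums the disaggregated metier costs per (year, fleet_segment, cost
#' variable), joins the official segment totals, and reports the signed
#' relative difference per row plus the overall mean absolute relative
#' difference in percent. Rows with an official value of zero are flagged
#' and excluded from the overall statistic.
#'
#' @param disaggregated either metier-level rows from [disaggregate()] (with
#'   `estimated_value`) or pre-summed rows with a `sum_costs_by_metier`
#'   column.
#' @param segment_costs official totals: columns `year`, `fleet_segment`,
#'   `variable_name`, `value` (see [read_segment_costs()]), or the same with
#'   a `costs_by_fleet_segment` column in place of `value`.
#' @return object of class `consistency_report`: list with `table` (year,
#'   fleet_segment, variable_name, sum_costs_by_metier,
#'   costs_by_fleet_segment, relative_difference, flagged) and
#'   `overall_abs_relative_difference` (percent).
#' @export
consistency_check <- function(disaggregated, segment_costs) {
  if ("sum_costs_by_metier" %in% names(disaggregated)) {
    sums <- disaggregated[, c("year", "fleet_segment", "variable_name",
                              "sum_costs_by_metier")]
  } else {
    vn <- VARIABLE_NAME_MAP[disaggregated$cost_variable]
    agg <- stats::aggregate(
      list(sum_costs_by_metier = disaggregated$estimated_value),
      by = list(year = disaggregated$year,
                fleet_segment = disaggregated$fleet_segment,
                variable_name = unname(vn)),
      FUN = sum)
    sums <- agg
  }
  sc <- segment_costs
  if (!"value" %in% names(sc) && "costs_by_fleet_segment" %in% names(sc)) {
    sc$value <- sc$costs_by_fleet_segment
  }
  key_s <- paste(sums$year, sums$fleet_segment, sums$variable_name, sep = "\r")
  key_o <- paste(sc$year, sc$fleet_segment, sc$variable_name, sep = "\r")
  idx <- match(key_s, key_o)
  if (anyNA(idx)) {
    miss <- key_s[is.na(idx)]
    stop("no official segment cost for: ",
         paste(gsub("\r", "/", miss), collapse = "; "), call. = FALSE)
  }
  official <- sc$value[idx]
  flagged <- official == 0
  rel <- ifelse(flagged, NA_real_,
                (sums$sum_costs_by_metier - official) / official)
  if (any(flagged)) {
    warning(sum(flagged), " row(s) with official value 0 flagged and ",
            "excluded from the overall difference", call. = FALSE)
  }
  tab <- data.frame(
    year = sums$year, fleet_segment = sums$fleet_segment,
    variable_name = sums$variable_name,
    sum_costs_by_metier = sums$sum_costs_by_metier,
    costs_by_fleet_segment = official,
    relative_difference = rel, flagged = flagged,
    stringsAsFactors = FALSE)
  tab <- order_rows(tab)
  rownames(tab) <- NULL
  out <- list(
    table = tab,
    overall_abs_relative_difference =
      100 * mean(abs(rel[!flagged]), na.rm = TRUE))
  class(out) <- "consistency_report"
  out
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("Consistency check: disaggregated metier costs vs official segment totals\n")
  df <- x$table
  df$sum_costs_by_metier <- round(df$sum_costs_by_metier, 0)
  df$costs_by_fleet_segment <- round(df$costs_by_fleet_segment, 0)
  df$relative_difference <- round(100 * df$relative_difference, 1)
  names(df)[names(df) == "relative_difference"] <- "rel_diff_pct"
  print(df[, setdiff(names(df), "flagged")], row.names = FALSE)
  cat(sprintf("\nOverall mean absolute relative difference: %.1f%%\n",
              x$overall_abs_relative_difference))
  if (any(x$table$flagged)) {
    cat(sprintf("(%d row(s) with official value 0 excluded)\n",
                sum(x$table$flagged)))
  }
  invisible(x)
}

#' Bar chart of disaggregated vs official costs
#'
#' @param report a `consistency_report`.
#' @param variable_name which cost variable to plot (default all).
#' @return invisibly, `NULL`.
#' @export
plot_consistency <- function(report, variable_name = NULL) {
  df <- report$table
  if (!is.null(variable_name)) df <- df[df$variable_name %in% variable_name, ]
  lab <- paste(df$fleet_segment, df$year, sep = "\n")
  m <- rbind(df$costs_by_fleet_segment, df$sum_costs_by_metier)
  graphics::barplot(m, beside = TRUE, names.arg = lab, las = 2,
                    cex.names = 0.7,
                    col = c("grey40", "steelblue"),
                    legend.text = c("official (segment)",
                                    "sum of metier estimates"),
                    main = paste(unique(df$variable_name), collapse = ", "))
  invisible(NULL)
}
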