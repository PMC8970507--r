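# Phase-1 exploratory analysis ("EA"): Pearson correlations and
# zero-intercept linear regressions of each variable cost on its candidate
# transversal variables, per fleet segment x metier and pooled.

#' Default catalogue of cost ~ transversal relationships
#'
#' Fuel cost and fuel consumption against effort; labour cost against
#' revenue (landings value), revenue minus total variable costs, revenue
#' minus fuel costs, and effort. Effort may be expressed as hours at sea
#' (default) or fishing days x kW.
#'
#' @param effort `"effort_hours"` or `"effort_dayskw"`.
#' @return data frame with columns `cost_variable`, `transversal`.
#' @export
default_relationships <- function(effort = c("effort_hours", "effort_dayskw")) {
  effort <- match.arg(effort)
  data.frame(
    cost_variable = c("fuel_cost", "fuel_consumption",
                      "labour_cost", "labour_cost", "labour_cost",
                      "labour_cost"),
    transversal = c(effort, effort,
                    "revenue", "revenue_minus_variable", "revenue_minus_fuel",
                    effort),
    stringsAsFactors = FALSE
  )
}

#' Zero-intercept linear regression
#'
#' Fits `y = slope * x` by least squares through the origin. The null
#' intercept simplifies the later disaggregation step, where the fitted
#' slope multiplies a metier-level transversal total directly. The slope is
#' `sum(x*y) / sum(x^2)`, its standard error
#' `sqrt(RSS / (n - 1) / sum(x^2))`, and the p-value comes from the t
#' distribution with `n - 1` degrees of freedom. The Pearson correlation of
#' the (centred) pair is reported alongside.
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @param min_n minimum number of complete pairs (default 30); below it the
#'   fit is suppressed with status `"insufficient observations"`.
#' @param alpha significance level for the slope t-test (default 0.05,
#'   strict inequality).
#' @return list with `status` (`"ok"` or a suppression reason), `n`,
#'   `slope`, `slope_se`, `p_value`, `significant`, `pearson_r`,
#'   `pearson_p`.
#' @export
fit_zero_intercept <- function(x, y, min_n = 30, alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < min_n) {
    return(list(status = "insufficient observations", n = n,
                slope = NA_real_, slope_se = NA_real_, p_value = NA_real_,
                significant = FALSE, pearson_r = NA_real_,
                pearson_p = NA_real_))
  }
  sxx <- sum(x^2)
  if (sxx <= 0) {
    return(list(status = "degenerate regressor (sum of squares zero)", n = n,
                slope = NA_real_, slope_se = NA_real_, p_value = NA_real_,
                significant = FALSE, pearson_r = NA_real_,
                pearson_p = NA_real_))
  }
  fit <- stats::lm(y ~ 0 + x)
  # summary.lm warns on noiseless fixtures ("essentially perfect fit");
  # that case is legitimate here and handled explicitly below
  cf <- suppressWarnings(summary(fit)$coefficients)
  slope <- unname(cf[1L, 1L])
  se <- unname(cf[1L, 2L])
  p <- unname(cf[1L, 4L])
  if (!is.finite(p)) p <- if (abs(slope) < .Machine$double.eps^0.5) 1 else 0

  if (stats::var(x) > 0 && stats::var(y) > 0) {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate)
    rp <- ct$p.value
    if (!is.finite(rp)) rp <- 0
  } else {
    r <- NA_real_
    rp <- NA_real_
  }
  list(status = "ok", n = n, slope = slope, slope_se = se, p_value = p,
       significant = is.finite(p) && p < alpha,
       pearson_r = r, pearson_p = rp)
}

#' Exploratory analysis: correlations and zero-intercept regressions
#'
#' For every fleet segment, every retained metier with at least `min_n`
#' observations, and every relationship in the catalogue, computes the
#' Pearson correlation and the zero-intercept regression of the adjusted
#' cost on the transversal variable. A pooled `"ALL"` row per segment and
#' relationship combines the segment's retained metiers.
#'
#' @param observations coverage-filtered observation table.
#' @param relationships catalogue data frame (see [default_relationships()]).
#' @param min_n minimum observations per emitted row (default 30).
#' @param alpha significance level (default 0.05).
#' @param variable_composition columns summed as "total variable costs" in
#'   the `revenue_minus_variable` regressor.
#' @return data frame of class `metier_ea`: one row per (fleet_segment,
#'   metier-or-ALL, cost_variable, transversal) with `n`, `pearson_r`,
#'   `pearson_p`, `slope`, `slope_se`, `p_value`, `significant`.
#'   Suppressed fits (n below `min_n`) are omitted from the table.
#' @export
run_ea <- function(observations, relationships = default_relationships(),
                   min_n = 30, alpha = 0.05,
                   variable_composition = c("fuel_cost_adj", "labour_cost_adj",
                                            "other_variable_adj")) {
  rows <- list()
  if (nrow(relationships) > 0L && nrow(observations) > 0L) {
    for (seg in sort(unique(observations$fleet_segment))) {
      obs_s <- observations[observations$fleet_segment == seg, , drop = FALSE]
      groups <- c(as.list(sort(unique(obs_s$prevalent_metier))), list("ALL"))
      for (k in seq_len(nrow(relationships))) {
        cv <- relationships$cost_variable[k]
        tv <- relationships$transversal[k]
        for (g in groups) {
          obs_g <- if (identical(g, "ALL")) obs_s else
            obs_s[obs_s$prevalent_metier == g, , drop = FALSE]
          y <- cost_values(obs_g, cv)
          x <- transversal_values(obs_g, tv, variable_composition)
          f <- fit_zero_intercept(x, y, min_n = min_n, alpha = alpha)
          if (f$status != "ok") next
          rows[[length(rows) + 1L]] <- data.frame(
            fleet_segment = seg, metier = g, cost_variable = cv,
            transversal = tv, n = f$n, pearson_r = f$pearson_r,
            pearson_p = f$pearson_p, slope = f$slope, slope_se = f$slope_se,
            p_value = f$p_value, significant = f$significant,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fleet_segment = character(), metier = character(),
               cost_variable = character(), transversal = character(),
               n = integer(), pearson_r = numeric(), pearson_p = numeric(),
               slope = numeric(), slope_se = numeric(), p_value = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("metier_ea", "data.frame")
  out
}

#' @export
print.metier_ea <- function(x, digits = 3, ...) {
  cat("Exploratory cost ~ transversal regressions (zero intercept)\n")
  if (nrow(x) == 0L) {
    cat("  (no rows: no group reached the minimum observation count)\n")
    return(invisible(x))
  }
  df <- as.data.frame(x)
  df$pearson_r <- round(df$pearson_r, digits)
  df$slope <- signif(df$slope, digits + 1)
  df$p_value <- signif(df$p_value, digits)
  print(df[, c("fleet_segment", "metier", "cost_variable", "transversal",
               "n", "pearson_r", "slope", "p_value", "significant")],
        row.names = FALSE)
  invisible(x)
}

#' Scatter plot of a cost ~ transversal relationship with fitted lines
#'
#' One panel per fleet segment: adjusted cost against the transversal
#' variable, points coloured by prevalent metier, with the zero-intercept
#' fitted line per metier and the pooled line.
#'
#' @param observations observation table.
#' @param cost_variable,transversal the relationship to plot.
#' @param min_n minimum observations for a per-metier line.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_ea <- function(observations, cost_variable = "fuel_cost",
                    transversal = "effort_hours", min_n = 30, ...) {
  segs <- sort(unique(observations$fleet_segment))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(segs)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (seg in segs) {
    obs_s <- observations[observations$fleet_segment == seg, , drop = FALSE]
    x <- transversal_values(obs_s, transversal)
    y <- cost_values(obs_s, cost_variable)
    mets <- sort(unique(obs_s$prevalent_metier))
    cols <- grDevices::hcl.colors(max(3L, length(mets)), "Dark 3")[
      seq_along(mets)]
    graphics::plot(x, y, col = cols[match(obs_s$prevalent_metier, mets)],
                   pch = 19, cex = 0.6, xlab = transversal,
                   ylab = cost_variable, main = seg, ...)
    for (i in seq_along(mets)) {
      sel <- obs_s$prevalent_metier == mets[i]
      f <- fit_zero_intercept(x[sel], y[sel], min_n = min_n)
      if (f$status == "ok") graphics::abline(0, f$slope, col = cols[i])
    }
    fa <- fit_zero_intercept(x, y, min_n = min_n)
    if (fa$status == "ok") graphics::abline(0, fa$slope, lty = 2)
    graphics::legend("topleft", legend = mets, col = cols, pch = 19,
                     cex = 0.7, bty = "n")
  }
  invisible(NULL)
}
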