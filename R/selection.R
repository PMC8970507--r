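# Decision flow selecting the disaggregation equation for one fleet segment
# and cost variable:
#   (i)   no significant cost ~ transversal relationship in the exploratory
#         stage -> "none" (no disaggregation is meaningful);
#   (ii)  EQ2 if metier, transversal and interaction terms are significant;
#   (iii) else EQ1 if metier and transversal terms are significant;
#   (iv)  else EQ3 if the through-origin slope is significant;
#   (v)   else "none".
# When several candidate transversals qualify, the lowest AIC wins.

#' Default candidate transversals per cost variable
#'
#' Fuel cost and fuel consumption are modelled against effort; labour cost
#' against revenue or effort (the crew-share system makes revenue the usual
#' winner). Only transversals observable at metier level in the FDI layout
#' are candidates, because phase 2 must evaluate the chosen regressor on the
#' metier-level transversal table.
#'
#' @param effort `"effort_hours"` or `"effort_dayskw"`.
#' @return named list: cost variable -> character vector of transversals.
#' @export
default_candidates <- function(effort = c("effort_hours", "effort_dayskw")) {
  effort <- match.arg(effort)
  list(
    fuel_cost        = effort,
    fuel_consumption = effort,
    labour_cost      = c("revenue", effort)
  )
}

#' Select the disaggregation model for one segment and cost variable
#'
#' Runs the decision flow above on the observations of a single fleet
#' segment. The exploratory gate (step i) uses the Pearson correlation test
#' between the adjusted cost and each candidate transversal: absence of a
#' significant correlation means no disaggregation approach makes sense. A
#' through-origin slope test would not serve here, since strictly positive
#' costs regressed through the origin on positive effort are nearly always
#' "significant" regardless of any real association.
#'
#' @param observations observation table for one fleet segment.
#' @param cost_variable one of the cost variables.
#' @param transversals character vector of candidate transversals.
#' @param alpha significance level (default 0.05, strict).
#' @param min_n minimum complete observations (default 30).
#' @param joint use the joint F-test for metier significance.
#' @param variable_composition see [run_ea()].
#' @return object of class `cost_model_selection`: list with
#'   `fleet_segment`, `cost_variable`, `chosen_equation` (`"EQ1"`, `"EQ2"`,
#'   `"EQ3"` or `"none"`), `chosen_transversal`, `fit` (a `metier_glm` or
#'   `NULL`), and `rationale` (text trail of the decision flow).
#' @export
select_cost_model <- function(observations, cost_variable,
                              transversals = default_candidates()[[cost_variable]],
                              alpha = 0.05, min_n = 30, joint = FALSE,
                              variable_composition = c("fuel_cost_adj",
                                                       "labour_cost_adj",
                                                       "other_variable_adj")) {
  seg <- unique(observations$fleet_segment)
  if (length(seg) != 1L) {
    stop("select_cost_model expects observations from a single fleet segment",
         call. = FALSE)
  }
  rationale <- character(0)
  note <- function(...) rationale <<- c(rationale, sprintf(...))
  y <- cost_values(observations, cost_variable)

  candidates <- list()
  for (tv in transversals) {
    x <- transversal_values(observations, tv, variable_composition)
    keep <- is.finite(x) & is.finite(y)
    n <- sum(keep)
    if (n < min_n) {
      note("%s: only %d complete observations (< %d), skipped", tv, n, min_n)
      next
    }
    if (stats::var(x[keep]) <= 0 || stats::var(y[keep]) <= 0) {
      note("%s: zero variance, correlation undefined, skipped", tv)
      next
    }
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
    if (!(is.finite(ct$p.value) && ct$p.value < alpha)) {
      note("%s: no significant correlation with %s (r = %.2f, p = %.3f)",
           tv, cost_variable, unname(ct$estimate), ct$p.value)
      next
    }
    note("%s: significant correlation (r = %.2f, p = %.3g)",
         tv, unname(ct$estimate), ct$p.value)

    k <- length(unique(observations$prevalent_metier[keep]))
    fit <- NULL
    if (k >= 2L) {
      eq2 <- tryCatch(
        fit_cost_glm(observations, cost_variable, tv, "EQ2",
                     variable_composition),
        error = function(e) NULL)
      if (!is.null(eq2) &&
          metier_significant(eq2, alpha, joint) &&
          slope_significant(eq2, alpha) &&
          interaction_significant(eq2, alpha)) {
        note("%s: EQ2 accepted (metier, transversal and interaction all significant)", tv)
        fit <- eq2
      } else {
        note("%s: EQ2 rejected", tv)
        eq1 <- tryCatch(
          fit_cost_glm(observations, cost_variable, tv, "EQ1",
                       variable_composition),
          error = function(e) NULL)
        if (!is.null(eq1) &&
            metier_significant(eq1, alpha, joint) &&
            slope_significant(eq1, alpha)) {
          note("%s: EQ1 accepted (metier and transversal significant)", tv)
          fit <- eq1
        } else {
          note("%s: EQ1 rejected", tv)
        }
      }
    } else {
      note("%s: single prevalent metier, EQ1/EQ2 unavailable", tv)
    }
    if (is.null(fit)) {
      eq3 <- tryCatch(
        fit_cost_glm(observations, cost_variable, tv, "EQ3",
                     variable_composition),
        error = function(e) NULL)
      if (!is.null(eq3) && slope_significant(eq3, alpha)) {
        note("%s: EQ3 accepted (transversal slope significant)", tv)
        fit <- eq3
      } else {
        note("%s: EQ3 rejected, no model for this transversal", tv)
      }
    }
    if (!is.null(fit)) candidates[[tv]] <- fit
  }

  if (length(candidates) == 0L) {
    note("no candidate transversal qualified: no disaggregation model")
    out <- list(fleet_segment = seg, cost_variable = cost_variable,
                chosen_equation = "none", chosen_transversal = NA_character_,
                fit = NULL, rationale = rationale)
  } else {
    aics <- vapply(candidates, function(f) f$aic, numeric(1))
    best <- names(candidates)[which.min(aics)]
    if (length(candidates) > 1L) {
      note("several transversals qualified; %s has the lowest AIC (%.1f)",
           best, min(aics))
    }
    fit <- candidates[[best]]
    out <- list(fleet_segment = seg, cost_variable = cost_variable,
                chosen_equation = fit$equation, chosen_transversal = best,
                fit = fit, rationale = rationale)
  }
  class(out) <- "cost_model_selection"
  out
}

#' @export
print.cost_model_selection <- function(x, ...) {
  cat(sprintf("Model selection: %s, %s\n", x$fleet_segment, x$cost_variable))
  cat(sprintf("  chosen: %s%s\n", x$chosen_equation,
              if (x$chosen_equation == "none") "" else
                sprintf(" on %s", x$chosen_transversal)))
  cat("  decision trail:\n")
  for (r in x$rationale) cat("   -", r, "\n")
  if (!is.null(x$fit)) {
    cat("\n")
    print(x$fit)
  }
  invisible(x)
}

#' Run model selection for every fleet segment and cost variable
#'
#' @param observations coverage-filtered observation table (all segments).
#' @param candidates named list mapping cost variables to candidate
#'   transversals (see [default_candidates()]).
#' @param alpha,min_n,joint,variable_composition passed to
#'   [select_cost_model()].
#' @return list of class `cost_model_selection_set`: `selections` (list of
#'   `cost_model_selection`, named `segment.cost_variable`) and `summary`
#'   (one data-frame row per selection).
#' @export
run_glm <- function(observations, candidates = default_candidates(),
                    alpha = 0.05, min_n = 30, joint = FALSE,
                    variable_composition = c("fuel_cost_adj",
                                             "labour_cost_adj",
                                             "other_variable_adj")) {
  selections <- list()
  rows <- list()
  for (seg in sort(unique(observations$fleet_segment))) {
    obs_s <- observations[observations$fleet_segment == seg, , drop = FALSE]
    for (cv in names(candidates)) {
      sel <- select_cost_model(obs_s, cv, candidates[[cv]], alpha = alpha,
                               min_n = min_n, joint = joint,
                               variable_composition = variable_composition)
      selections[[paste(seg, cv, sep = ".")]] <- sel
      rows[[length(rows) + 1L]] <- data.frame(
        fleet_segment = seg, cost_variable = cv,
        chosen_equation = sel$chosen_equation,
        chosen_transversal = sel$chosen_transversal,
        n = if (is.null(sel$fit)) NA_integer_ else sel$fit$n,
        explained_deviance = if (is.null(sel$fit)) NA_real_ else
          sel$fit$explained_deviance,
        aic = if (is.null(sel$fit)) NA_real_ else sel$fit$aic,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- list(selections = selections, summary = do.call(rbind, rows))
  class(out) <- "cost_model_selection_set"
  out
}

#' @export
print.cost_model_selection_set <- function(x, ...) {
  cat("Disaggregation model selections\n")
  df <- x$summary
  df$explained_deviance <- round(df$explained_deviance, 1)
  df$aic <- round(df$aic, 0)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flatten fitted GLM coefficients into one table
#'
#' One row per term of every selected model: used for the written
#' `glm_summaries` result table.
#'
#' @param selection_set a `cost_model_selection_set` from [run_glm()].
#' @return data frame.
#' @export
glm_summary_table <- function(selection_set) {
  rows <- list()
  for (sel in selection_set$selections) {
    if (is.null(sel$fit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        fleet_segment = sel$fleet_segment, cost_variable = sel$cost_variable,
        equation = "none", transversal = NA_character_, term = NA_character_,
        role = NA_character_, estimate = NA_real_, std_error = NA_real_,
        p_value = NA_real_, explained_deviance = NA_real_, aic = NA_real_,
        n = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    tt <- sel$fit$terms
    rows[[length(rows) + 1L]] <- data.frame(
      fleet_segment = sel$fleet_segment, cost_variable = sel$cost_variable,
      equation = sel$chosen_equation, transversal = sel$chosen_transversal,
      term = tt$term, role = tt$role, estimate = tt$estimate,
      std_error = tt$std_error, p_value = tt$p_value,
      explained_deviance = sel$fit$explained_deviance, aic = sel$fit$aic,
      n = sel$fit$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
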