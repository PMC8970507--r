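# Gaussian identity-link GLMs testing the significance of the metier factor
# on variable costs, in cell-means coding (no global intercept): each metier
# gets its own coefficient alpha_m, directly usable in disaggregation.
#
# Three candidate models for adjusted cost y and transversal x:
#   EQ1:  y = alpha_m + beta * x            (metier and transversal, separate)
#   EQ2:  y = alpha_m + (beta + gamma_m) x  (plus metier-specific slopes;
#                                            gamma of the reference metier = 0)
#   EQ3:  y = alpha * x                     (transversal only, through origin)

#' Fit a variable-cost GLM for one fleet segment
#'
#' Gaussian family, identity link, no global intercept: the metier factor is
#' coded as cell means so that each metier has its own coefficient. The
#' explained deviance is `100 * (1 - residual deviance / null deviance)`,
#' with the null deviance that of the intercept-only model.
#'
#' @param observations observation table for a single fleet segment (see
#'   [build_observations()]); rows with a missing cost or transversal value
#'   are dropped.
#' @param cost_variable one of `"fuel_cost"`, `"fuel_consumption"`,
#'   `"labour_cost"`, `"other_variable"`.
#' @param transversal one of `"effort_hours"`, `"effort_dayskw"`,
#'   `"revenue"`, `"revenue_minus_variable"`, `"revenue_minus_fuel"`.
#' @param equation `"EQ1"`, `"EQ2"` or `"EQ3"`.
#' @param variable_composition see [run_ea()].
#' @return object of class `metier_glm`: list with the fitted `glm`, the
#'   `terms` table (term, role, estimate, std_error, p_value), `equation`,
#'   `explained_deviance` (percent), `aic`, `n`, `metiers`,
#'   `fleet_segment`, `cost_variable`, `transversal`.
#' @export
fit_cost_glm <- function(observations, cost_variable, transversal,
                         equation = c("EQ1", "EQ2", "EQ3"),
                         variable_composition = c("fuel_cost_adj",
                                                  "labour_cost_adj",
                                                  "other_variable_adj")) {
  equation <- match.arg(equation)
  seg <- unique(observations$fleet_segment)
  if (length(seg) > 1L) {
    stop("fit_cost_glm expects observations from a single fleet segment",
         call. = FALSE)
  }
  y <- cost_values(observations, cost_variable)
  x <- transversal_values(observations, transversal, variable_composition)
  keep <- is.finite(y) & is.finite(x)
  d <- data.frame(y = y[keep], x = x[keep],
                  metier = factor(observations$prevalent_metier[keep]))
  d$metier <- droplevels(d$metier)
  k <- nlevels(d$metier)
  if (nrow(d) < 2L) stop("not enough complete observations", call. = FALSE)

  if (equation %in% c("EQ1", "EQ2")) {
    if (k < 2L) {
      stop(equation, " requires at least two metiers; segment has one",
           call. = FALSE)
    }
    minper <- if (equation == "EQ1") 2L else 3L
    cnt <- table(d$metier)
    low <- names(cnt)[cnt < minper]
    if (length(low) > 0L) {
      stop("rank-deficient design for ", equation, ": metier(s) with too ",
           "few observations: ", paste(low, collapse = ", "), call. = FALSE)
    }
  }
  form <- switch(equation,
    EQ1 = y ~ 0 + metier + x,
    EQ2 = y ~ 0 + metier + x + metier:x,
    EQ3 = y ~ 0 + x
  )
  fit <- stats::glm(form, family = stats::gaussian(), data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: aliased term(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  nm <- rownames(cf)
  role <- ifelse(grepl("^metier.*:x$", nm), "interaction",
          ifelse(nm == "x", "slope", "metier"))
  level <- ifelse(role == "slope", NA_character_,
                  sub(":x$", "", sub("^metier", "", nm)))
  terms_tab <- data.frame(
    term = nm, role = role, level = level,
    estimate = unname(cf[, 1L]), std_error = unname(cf[, 2L]),
    p_value = unname(cf[, 4L]), stringsAsFactors = FALSE
  )
  # perfect fits: summary() yields NaN p-values when sigma is zero
  nanp <- !is.finite(terms_tab$p_value)
  if (any(nanp)) {
    terms_tab$p_value[nanp] <-
      ifelse(abs(terms_tab$estimate[nanp]) < .Machine$double.eps^0.5, 1, 0)
  }
  null_dev <- sum((d$y - mean(d$y))^2)
  expl <- if (null_dev > 0) 100 * (1 - stats::deviance(fit) / null_dev) else
    NA_real_

  out <- list(
    glm = fit, equation = equation, terms = terms_tab,
    explained_deviance = expl, null_deviance = null_dev,
    deviance = stats::deviance(fit), aic = stats::AIC(fit),
    n = nrow(d), metiers = levels(d$metier),
    fleet_segment = if (length(seg)) seg else NA_character_,
    cost_variable = cost_variable, transversal = transversal
  )
  class(out) <- "metier_glm"
  out
}

#' Coefficients of a cost GLM in disaggregation form
#'
#' Returns the pieces used by [disaggregate()]: metier intercepts `alpha`
#' (named by metier), common slope `beta`, and interaction slope offsets
#' `gamma` (named by metier, zero for the reference level). For EQ3,
#' `alpha` is empty and `beta` is the single through-origin slope.
#'
#' @param object a `metier_glm`.
#' @param ... unused.
#' @return list with `alpha`, `beta`, `gamma`.
#' @export
coef.metier_glm <- function(object, ...) {
  tt <- object$terms
  alpha <- tt$estimate[tt$role == "metier"]
  names(alpha) <- tt$level[tt$role == "metier"]
  beta <- if (any(tt$role == "slope")) tt$estimate[tt$role == "slope"] else
    NA_real_
  gamma <- stats::setNames(rep(0, length(object$metiers)), object$metiers)
  gi <- tt$role == "interaction"
  if (any(gi)) gamma[tt$level[gi]] <- tt$estimate[gi]
  if (object$equation != "EQ2") gamma <- gamma[0]
  list(alpha = alpha, beta = unname(beta), gamma = gamma)
}

#' Predict metier-level costs from a fitted cost GLM
#'
#' @param object a `metier_glm`.
#' @param newdata data frame with a numeric column `x` (the transversal
#'   value) and, for EQ1/EQ2, a `metier` column.
#' @param ... unused.
#' @return numeric vector of predicted costs.
#' @export
predict.metier_glm <- function(object, newdata, ...) {
  cf <- coef.metier_glm(object)
  x <- newdata$x
  if (object$equation == "EQ3") return(cf$beta * x)
  m <- as.character(newdata$metier)
  unknown <- setdiff(unique(m), names(cf$alpha))
  if (length(unknown) > 0L) {
    stop("metier(s) not in the fitted model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  a <- cf$alpha[m]
  b <- cf$beta
  if (object$equation == "EQ2") b <- b + cf$gamma[m]
  unname(a + b * x)
}

#' @export
fitted.metier_glm <- function(object, ...) stats::fitted(object$glm)

#' @export
residuals.metier_glm <- function(object, ...) stats::residuals(object$glm)

#' @export
simulate.metier_glm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$glm, nsim = nsim, seed = seed, ...)
}

#' @export
print.metier_glm <- function(x, digits = 4, ...) {
  cat(sprintf("Variable-cost GLM (%s): %s ~ %s  [%s]\n", x$equation,
              x$cost_variable, x$transversal, x$fleet_segment))
  cat(sprintf("  n = %d, explained deviance = %.1f%%, AIC = %.0f\n",
              x$n, x$explained_deviance, x$aic))
  tt <- x$terms
  tt$estimate <- signif(tt$estimate, digits)
  tt$std_error <- signif(tt$std_error, digits)
  tt$p_value <- signif(tt$p_value, 3)
  print(tt[, c("term", "estimate", "std_error", "p_value")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.metier_glm <- function(object, ...) {
  structure(list(fit = object, glm_summary = summary(object$glm)),
            class = "summary.metier_glm")
}

#' @export
print.summary.metier_glm <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying GLM summary:\n")
  print(x$glm_summary)
  invisible(x)
}

#' @export
plot.metier_glm <- function(x, ...) {
  d <- x$glm$data
  mets <- x$metiers
  cols <- if (length(mets)) grDevices::hcl.colors(max(3L, length(mets)),
                                                  "Dark 3")[seq_along(mets)]
          else "black"
  colv <- if (length(mets)) cols[match(as.character(d$metier), mets)] else
    "black"
  graphics::plot(d$x, d$y, col = colv, pch = 19, cex = 0.6,
                 xlab = x$transversal, ylab = x$cost_variable,
                 main = sprintf("%s (%s)", x$fleet_segment, x$equation), ...)
  cf <- coef.metier_glm(x)
  if (x$equation == "EQ3") {
    graphics::abline(0, cf$beta)
  } else {
    for (i in seq_along(mets)) {
      b <- cf$beta + if (x$equation == "EQ2") cf$gamma[mets[i]] else 0
      graphics::abline(cf$alpha[mets[i]], b, col = cols[i])
    }
    graphics::legend("topleft", legend = mets, col = cols, lty = 1,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Is the metier factor significant in a fitted cost GLM?
#'
#' Default rule: the metier is significant if at least one metier-level
#' coefficient has p < alpha (strict). This permissive per-level rule keeps
#' models in which a single metier differs detectably from zero. An optional
#' joint mode instead F-tests the metier factor against the nested model
#' with a single common intercept.
#'
#' @param fit a `metier_glm` of equation EQ1 or EQ2.
#' @param alpha significance level (default 0.05).
#' @param joint if `TRUE`, use the joint F-test of the metier factor.
#' @return logical.
#' @export
metier_significant <- function(fit, alpha = 0.05, joint = FALSE) {
  stopifnot(inherits(fit, "metier_glm"))
  if (fit$equation == "EQ3") {
    stop("metier significance is defined for EQ1/EQ2 fits only",
         call. = FALSE)
  }
  if (!joint) {
    p <- fit$terms$p_value[fit$terms$role == "metier"]
    return(any(is.finite(p) & p < alpha))
  }
  d <- fit$glm$data
  reduced <- stats::glm(y ~ 1 + x, family = stats::gaussian(), data = d)
  an <- stats::anova(reduced, fit$glm, test = "F")
  p <- an[["Pr(>F)"]][2L]
  is.finite(p) && p < alpha
}

# p < alpha for the common transversal slope
slope_significant <- function(fit, alpha = 0.05) {
  p <- fit$terms$p_value[fit$terms$role == "slope"]
  length(p) == 1L && is.finite(p) && p < alpha
}

# p < alpha for at least one metier-specific slope offset (EQ2)
interaction_significant <- function(fit, alpha = 0.05) {
  p <- fit$terms$p_value[fit$terms$role == "interaction"]
  any(is.finite(p) & p < alpha)
}
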