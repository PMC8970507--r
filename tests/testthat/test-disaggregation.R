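# Phase 2: applying selected coefficients to metier-level transversal data
# and reconciling against official totals.

# build a minimal selection object around a fitted metier_glm
make_selection <- function(fit, equation = fit$equation,
                           transversal = fit$transversal) {
  structure(list(fleet_segment = fit$fleet_segment,
                 cost_variable = fit$cost_variable,
                 chosen_equation = equation, chosen_transversal = transversal,
                 fit = fit, rationale = character(0)),
            class = "cost_model_selection")
}

test_that("EQ3 disaggregation multiplies the slope by the transversal", {
  # slope 12.5 per hour at sea, as for a hooks fleet's fuel cost
  h <- seq(100, 500, length.out = 40)
  obs <- make_obs(rep("LLD_LPF", 40), hours = h, fuel = 12.5 * h)
  fit <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ3")
  sel <- make_selection(fit)
  tv <- data.frame(year = 2015, fleet_segment = "SEG",
                   metier = c("LLD_LPF", "LLS_DEF"),
                   effort_hours = c(1000, 0), effort_dayskw = NA,
                   landings_value = c(1, 1))
  d <- disaggregate(sel, tv)
  expect_equal(d$estimated_value[d$metier == "LLD_LPF"], 12500,
               tolerance = 1e-9)
  expect_equal(d$estimated_value[d$metier == "LLS_DEF"], 0)  # X = 0 -> 0
  # EQ3 applies the same slope to every metier, modelled or not
  expect_equal(nrow(d), 2L)
})

test_that("EQ1 disaggregation adds the metier intercept to slope x
           transversal", {
  met <- rep(c("m1", "m2"), each = 20)
  h <- rep(c(1, 2, 3, 4, 5), 8)
  y <- ifelse(met == "m1", 10, 20) + 2 * h
  obs <- make_obs(met, hours = h, fuel = y)
  fit <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1")
  sel <- make_selection(fit)
  tv <- data.frame(year = 2015, fleet_segment = "SEG",
                   metier = c("m1", "m2"), effort_hours = c(5, 5),
                   effort_dayskw = NA, landings_value = c(1, 1))
  d <- disaggregate(sel, tv)
  expect_equal(d$estimated_value[d$metier == "m1"], 20, tolerance = 1e-8)
  expect_equal(d$estimated_value[d$metier == "m2"], 30, tolerance = 1e-8)
})

test_that("EQ2 disaggregation uses metier-specific slopes", {
  met <- rep(c("m1", "m2"), each = 20)
  h <- rep(seq(10, 100, length.out = 20), 2)
  y <- ifelse(met == "m1", 100, 300) + ifelse(met == "m1", 2, 5) * h
  obs <- make_obs(met, hours = h, fuel = y)
  fit <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ2")
  sel <- make_selection(fit)
  tv <- data.frame(year = 2015, fleet_segment = "SEG",
                   metier = c("m1", "m2"), effort_hours = c(10, 10),
                   effort_dayskw = NA, landings_value = c(1, 1))
  d <- disaggregate(sel, tv)
  expect_equal(d$estimated_value[d$metier == "m1"], 100 + 2 * 10,
               tolerance = 1e-7)
  expect_equal(d$estimated_value[d$metier == "m2"], 300 + 5 * 10,
               tolerance = 1e-7)
})

test_that("unmodelled metiers follow the fallback policy", {
  met <- rep(c("m1", "m2"), each = 20)
  h <- rep(seq(10, 100, length.out = 20), 2)
  y <- ifelse(met == "m1", 10, 20) + 2 * h
  obs <- make_obs(met, hours = h, fuel = y)
  fit <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1")
  sel <- make_selection(fit)
  tv <- data.frame(year = 2015, fleet_segment = "SEG",
                   metier = c("m1", "m2", "m9"), effort_hours = c(5, 5, 7),
                   effort_dayskw = NA, landings_value = c(1, 1, 1))
  d_skip <- disaggregate(sel, tv, fallback = "skip")
  expect_equal(nrow(d_skip), 2L)
  expect_equal(attr(d_skip, "skipped")$metier, "m9")

  pooled <- data.frame(fleet_segment = "SEG", metier = "ALL",
                       cost_variable = "fuel_cost",
                       transversal = "effort_hours", slope = 3,
                       stringsAsFactors = FALSE)
  d_pool <- disaggregate(sel, tv, fallback = "pooled",
                         pooled_slopes = pooled)
  expect_equal(nrow(d_pool), 3L)
  expect_equal(d_pool$estimated_value[d_pool$metier == "m9"], 21)
  expect_equal(d_pool$equation_used[d_pool$metier == "m9"], "pooled")
})

test_that("intercept scaling by vessel count is available but off by
           default", {
  met <- rep(c("m1", "m2"), each = 20)
  h <- rep(c(1, 2, 3, 4, 5), 8)
  y <- ifelse(met == "m1", 10, 20) + 2 * h
  obs <- make_obs(met, hours = h, fuel = y)
  sel <- make_selection(fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1"))
  tv <- data.frame(year = 2015, fleet_segment = "SEG",
                   metier = c("m1", "m2"), effort_hours = c(5, 5),
                   effort_dayskw = NA, landings_value = c(1, 1))
  counts <- data.frame(year = 2015, fleet_segment = "SEG",
                       metier = c("m1", "m2"), n_vessels = c(10, 4))
  d <- disaggregate(sel, tv, scale_intercepts_by_vessel_count = TRUE,
                    vessel_counts = counts)
  expect_equal(d$estimated_value[d$metier == "m1"], 10 * 10 + 2 * 5,
               tolerance = 1e-8)
  expect_equal(d$estimated_value[d$metier == "m2"], 20 * 4 + 2 * 5,
               tolerance = 1e-8)
  expect_error(disaggregate(sel, tv, scale_intercepts_by_vessel_count = TRUE),
               "vessel_counts")
})

test_that("consistency check computes signed and overall differences", {
  # identity: disaggregated equals official
  d <- data.frame(year = 2015, fleet_segment = "S", metier = c("a", "b"),
                  cost_variable = "fuel_cost",
                  transversal_value = c(1, 1), equation_used = "EQ3",
                  estimated_value = c(60, 40))
  sc <- data.frame(year = 2015, fleet_segment = "S",
                   variable_name = "fuel_costs", value = 100)
  cc <- consistency_check(d, sc)
  expect_equal(cc$table$relative_difference, 0)
  expect_equal(cc$overall_abs_relative_difference, 0)

  # +10% and -30% average to 20% in absolute value
  d2 <- rbind(d, transform(d, year = 2016, estimated_value = c(42, 28)))
  sc2 <- rbind(sc, transform(sc, year = 2016))
  sc2$value <- c(100 / 1.1, 100)
  cc2 <- consistency_check(d2, sc2)
  expect_equal(sort(round(cc2$table$relative_difference, 10)),
               c(-0.3, 0.1))
  expect_equal(cc2$overall_abs_relative_difference, 20)

  # official zero: flagged and excluded from the overall statistic
  sc3 <- sc2; sc3$value[2] <- 0
  expect_warning(cc3 <- consistency_check(d2, sc3), "official value 0")
  expect_equal(sum(cc3$table$flagged), 1L)
  expect_equal(cc3$overall_abs_relative_difference,
               100 * abs(100 / (100 / 1.1) - 1))

  # a disaggregated key without official counterpart is an error
  expect_error(consistency_check(transform(d, fleet_segment = "OTHER"), sc),
               "no official")
})

test_that("consistency output has one row per (year, segment, variable)", {
  d <- expand.grid(year = 2015:2016, fleet_segment = c("S1", "S2"),
                   metier = c("a", "b"), cost_variable = "fuel_cost",
                   stringsAsFactors = FALSE)
  d$transversal_value <- 1; d$equation_used <- "EQ3"; d$estimated_value <- 10
  sc <- expand.grid(year = 2015:2016, fleet_segment = c("S1", "S2"),
                    variable_name = "fuel_costs", stringsAsFactors = FALSE)
  sc$value <- 25
  cc <- consistency_check(d, sc)
  expect_equal(nrow(cc$table), 4L)
  expect_equal(cc$table$sum_costs_by_metier, rep(20, 4))
})

test_that("under EQ3 the metier estimates sum to slope x total transversal
           exactly", {
  h <- seq(50, 500, length.out = 40)
  obs <- make_obs(rep("M", 40), hours = h, fuel = 7 * h)
  sel <- make_selection(fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ3"))
  tv <- data.frame(year = 2015, fleet_segment = "SEG",
                   metier = paste0("m", 1:5),
                   effort_hours = c(100, 250, 3.5, 1000, 7),
                   effort_dayskw = NA, landings_value = 1)
  d <- disaggregate(sel, tv)
  expect_equal(sum(d$estimated_value), 7 * sum(tv$effort_hours),
               tolerance = 1e-12)
  # if the official total is alpha x segment transversal, the gap is zero
  sc <- data.frame(year = 2015, fleet_segment = "SEG",
                   variable_name = "fuel_costs",
                   value = 7 * sum(tv$effort_hours))
  cc <- consistency_check(d, sc)
  expect_lt(abs(cc$overall_abs_relative_difference), 1e-10)
})
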