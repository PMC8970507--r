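# Synthetic fleet generator: trip-level activity, annual vessel costs and
# the two aggregate tables (segment costs, metier transversal data), with
# known ground-truth coefficients. Emulates the structure of the individual
# vessel datasets the method needs -- vessels concentrated on a prevalent
# metier, metier-specific fuel-cost intercepts with a common effort slope,
# labour as a crew share of revenue -- without any confidential data.

#' Define a synthetic fleet scenario
#'
#' The generating model, on the metier-attributed (activity-adjusted) scale
#' on which the cost GLMs are defined, is
#' `fuel_m = alpha_m + (beta + gamma_m) * hours_m` and
#' `labour = crew_share * revenue`; observation noise is multiplicative
#' lognormal with coefficient of variation `noise_cv` (mean 1), or additive
#' Gaussian with sd `noise_cv` times the segment mean cost when
#' `noise = "gaussian"`.
#'
#' @param segments list of segment specs, each a list with `code`, `metiers`
#'   (character), `n_vessels`, and optionally `kw_range` (length 2).
#' @param true_fuel_intercepts named numeric, currency per metier.
#' @param true_fuel_slope common fuel slope beta, currency per hour at sea.
#' @param true_slope_offsets named numeric, per-metier slope offsets gamma
#'   (default all zero, i.e. a common slope).
#' @param true_crew_share labour cost as a fraction of revenue in `[0, 1]`.
#' @param fuel_structure `"linear"` (the model above) or `"independent"`
#'   (fuel cost unrelated to effort: the no-relationship case).
#' @param revenue_rates named numeric, expected landings value per hour at
#'   sea per metier (default 150 for unlisted metiers).
#' @param fuel_price currency per litre; fuel consumption is fuel cost
#'   divided by this price (with its own noise draw).
#' @param other_rate other variable costs as a fraction of revenue.
#' @param prevalence_concentration expected activity share of the designed
#'   prevalent metier, in (0, 1].
#' @param dirichlet_precision concentration of the Dirichlet allocating
#'   activity across metiers (larger = tighter around the expected shares).
#' @param noise_cv coefficient of variation of cost noise, >= 0.
#' @param noise `"lognormal"` (default) or `"gaussian"`.
#' @param trips_per_vessel mean trips per vessel-year.
#' @param mean_trip_hours mean hours at sea per trip.
#' @param years calendar years simulated.
#' @param seed integer seed stored with the scenario.
#' @return object of class `fleet_scenario`.
#' @export
fleet_scenario <- function(segments = default_segments(),
                           true_fuel_intercepts = c(OTB_DES = 10000,
                                                    OTB_MDD = 14000,
                                                    OTB_DWS = 20000,
                                                    LLD_LPF = 0),
                           true_fuel_slope = 25,
                           true_slope_offsets = NULL,
                           true_crew_share = 0.3,
                           fuel_structure = c("linear", "independent"),
                           revenue_rates = c(OTB_DES = 140, OTB_MDD = 160,
                                             OTB_DWS = 180, LLD_LPF = 120),
                           fuel_price = 0.6,
                           other_rate = 0.05,
                           prevalence_concentration = 0.8,
                           dirichlet_precision = 150,
                           noise_cv = 0.1,
                           noise = c("lognormal", "gaussian"),
                           trips_per_vessel = 13,
                           mean_trip_hours = 48,
                           years = 2015:2016,
                           seed = 1L) {
  noise <- match.arg(noise)
  fuel_structure <- match.arg(fuel_structure)
  stopifnot(length(segments) >= 1L)
  for (sg in segments) {
    if (is.null(sg$code) || is.null(sg$metiers) || is.null(sg$n_vessels)) {
      stop("each segment needs code, metiers and n_vessels", call. = FALSE)
    }
    if (sg$n_vessels < 1L) stop("vessel counts must be >= 1", call. = FALSE)
  }
  if (prevalence_concentration <= 0 || prevalence_concentration > 1) {
    stop("prevalence_concentration must be in (0, 1]", call. = FALSE)
  }
  if (true_crew_share < 0 || true_crew_share > 1) {
    stop("true_crew_share must be in [0, 1]", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (trips_per_vessel < 1) stop("trips_per_vessel must be >= 1", call. = FALSE)
  mets <- unique(unlist(lapply(segments, `[[`, "metiers")))
  missing_a <- setdiff(mets, names(true_fuel_intercepts))
  if (length(missing_a) > 0L) {
    stop("true_fuel_intercepts missing for metier(s): ",
         paste(missing_a, collapse = ", "), call. = FALSE)
  }
  gamma <- stats::setNames(rep(0, length(mets)), mets)
  if (!is.null(true_slope_offsets)) {
    gamma[names(true_slope_offsets)] <- true_slope_offsets
  }
  rr <- stats::setNames(rep(150, length(mets)), mets)
  rr[intersect(names(revenue_rates), mets)] <-
    revenue_rates[intersect(names(revenue_rates), mets)]
  out <- list(
    segments = segments,
    true_fuel_intercepts = true_fuel_intercepts[mets],
    true_fuel_slope = true_fuel_slope,
    true_slope_offsets = gamma,
    true_crew_share = true_crew_share,
    fuel_structure = fuel_structure,
    revenue_rates = rr,
    fuel_price = fuel_price,
    other_rate = other_rate,
    prevalence_concentration = prevalence_concentration,
    dirichlet_precision = dirichlet_precision,
    noise_cv = noise_cv,
    noise = noise,
    trips_per_vessel = trips_per_vessel,
    mean_trip_hours = mean_trip_hours,
    years = years,
    seed = as.integer(seed)
  )
  class(out) <- "fleet_scenario"
  out
}

#' Default segment structure mirroring a mixed Mediterranean fleet
#'
#' Three demersal-trawler length classes (two to three otter-trawl metiers
#' each) and one hooks segment with a single longline metier; roughly 450
#' vessels in total.
#'
#' @return list of segment specs for [fleet_scenario()].
#' @export
default_segments <- function() {
  list(
    list(code = "DTS_VL1218", metiers = c("OTB_DES", "OTB_MDD"),
         n_vessels = 146L, kw_range = c(80, 300)),
    list(code = "DTS_VL1824", metiers = c("OTB_DES", "OTB_MDD"),
         n_vessels = 125L, kw_range = c(150, 450)),
    list(code = "DTS_VL2440", metiers = c("OTB_DES", "OTB_DWS", "OTB_MDD"),
         n_vessels = 133L, kw_range = c(300, 900)),
    list(code = "HOK_VL1218", metiers = "LLD_LPF",
         n_vessels = 46L, kw_range = c(50, 200))
  )
}

#' @export
print.fleet_scenario <- function(x, ...) {
  cat("Synthetic fleet scenario\n")
  for (sg in x$segments) {
    cat(sprintf("  %s: %d vessels, metiers %s\n", sg$code, sg$n_vessels,
                paste(sg$metiers, collapse = ", ")))
  }
  cat(sprintf("  fuel: %s, beta = %g, alpha = [%s]\n", x$fuel_structure,
              x$true_fuel_slope,
              paste(sprintf("%s=%g", names(x$true_fuel_intercepts),
                            x$true_fuel_intercepts), collapse = ", ")))
  cat(sprintf("  crew share = %g, noise = %s (cv %g), years %s, seed %d\n",
              x$true_crew_share, x$noise, x$noise_cv,
              paste(range(x$years), collapse = "-"), x$seed))
  invisible(x)
}

# mean-1 multiplicative lognormal noise with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Dirichlet draw via independent gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha / sum(alpha)   # degenerate guard
  g / sum(g)
}

# largest-remainder allocation of n trips to shares s (designed prevalent
# metier, position `prev`, always gets at least one trip)
allocate_trips <- function(n, s, prev) {
  raw <- n * s
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  if (base[prev] == 0L) {
    donor <- which.max(base)
    base[donor] <- base[donor] - 1L
    base[prev] <- 1L
  }
  base
}

#' Generate a synthetic fleet dataset
#'
#' Draws trips, vessel-year costs and the exact aggregate tables for a
#' scenario. Activity is allocated across metiers by a Dirichlet draw
#' concentrated on each vessel's designed prevalent metier; trip hours are
#' gamma distributed and rescaled within metier so realised hour shares
#' equal the drawn shares. Costs are generated on the metier-attributed
#' scale (where the GLM is defined) and converted to vessel-year totals by
#' dividing by the activity share, so the proportional-attribution rule of
#' phase 1 is exact by construction. Aggregate tables are exact marginal
#' sums of the micro-data.
#'
#' @param scenario a [fleet_scenario()].
#' @param seed integer; defaults to the scenario's seed. The run is fully
#'   reproducible from it.
#' @return object of class `fleet_sim`: list with `trips`, `costs`,
#'   `segment_costs`, `transversal` (the four input layouts) and `truth`
#'   (generating parameters plus each vessel's designed prevalent metier).
#' @export
simulate_fleet <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "fleet_scenario"))
  set.seed(seed)
  sc <- scenario
  trips_l <- list()
  costs_l <- list()
  truth_prev <- list()

  for (sg in sc$segments) {
    k <- length(sg$metiers)
    nv <- sg$n_vessels
    kwr <- sg$kw_range %||% c(80, 400)
    vids <- sprintf("%s_V%04d", sg$code, seq_len(nv))
    kw <- stats::runif(nv, kwr[1], kwr[2])
    # round-robin designed prevalent metier so every metier has vessels
    designed <- rep_len(sg$metiers, nv)
    truth_prev[[sg$code]] <- data.frame(
      vessel_id = vids, fleet_segment = sg$code,
      designed_prevalent = designed, stringsAsFactors = FALSE)

    for (yr in sc$years) {
      for (v in seq_len(nv)) {
        ntr <- 1L + stats::rpois(1L, max(0, sc$trips_per_vessel - 1))
        if (k == 1L) {
          shares <- 1
        } else {
          p <- rep((1 - sc$prevalence_concentration) / (k - 1), k)
          p[match(designed[v], sg$metiers)] <- sc$prevalence_concentration
          shares <- rdirichlet1(sc$dirichlet_precision * p)
        }
        previ <- match(designed[v], sg$metiers)
        ntr_m <- if (k == 1L) ntr else allocate_trips(ntr, shares, previ)
        if (k == 1L) ntr_m <- ntr
        active <- which(ntr_m > 0L)
        # renormalise shares over metiers that actually received trips
        sh <- shares[active] / sum(shares[active])
        hraw <- stats::rgamma(ntr, shape = 4,
                              rate = 4 / sc$mean_trip_hours)
        H <- sum(hraw)
        met_trip <- rep(sg$metiers[active], ntr_m[active])
        # rescale hours within metier so hour shares match the draw exactly
        hrs <- hraw
        pos <- 1L
        for (j in seq_along(active)) {
          idx <- pos:(pos + ntr_m[active[j]] - 1L)
          hrs[idx] <- hraw[idx] * (sh[j] * H / sum(hraw[idx]))
          pos <- pos + ntr_m[active[j]]
        }
        rrate <- sc$revenue_rates[met_trip]
        val <- rrate * hrs * rlnorm_cv(ntr, 0.25)
        trips_l[[length(trips_l) + 1L]] <- data.frame(
          vessel_id = vids[v], year = yr, fleet_segment = sg$code,
          metier = met_trip, hours_at_sea = hrs,
          fishing_days = pmax(1, round(hrs / 14)), kw = kw[v],
          landings_weight = val / 5, landings_value = val,
          stringsAsFactors = FALSE)

        # costs on the metier-attributed scale
        hp <- sum(hrs[met_trip == designed[v]])
        share_real <- hp / H
        alpha <- sc$true_fuel_intercepts[[designed[v]]]
        beta_m <- sc$true_fuel_slope + sc$true_slope_offsets[[designed[v]]]
        fuel_attr <- if (sc$fuel_structure == "independent") {
          alpha
        } else {
          alpha + beta_m * hp
        }
        cons_attr <- fuel_attr / sc$fuel_price
        rev_tot <- sum(val)
        labour_tot <- sc$true_crew_share * rev_tot
        other_tot <- sc$other_rate * rev_tot
        if (sc$noise == "lognormal") {
          eps <- rlnorm_cv(4L, sc$noise_cv)
          fuel_attr <- fuel_attr * eps[1L]
          cons_attr <- cons_attr * eps[2L]
          labour_tot <- labour_tot * eps[3L]
          other_tot <- other_tot * eps[4L]
        }
        # gaussian-mode noise is added after the loop, once segment means
        # of the true attributed costs are known
        costs_l[[length(costs_l) + 1L]] <- data.frame(
          vessel_id = vids[v], year = yr,
          fuel_cost = fuel_attr / share_real,
          fuel_consumption = cons_attr / share_real,
          labour_cost = labour_tot,
          other_variable_costs = other_tot,
          .fuel_attr_true = if (sc$fuel_structure == "independent") alpha
                            else alpha + beta_m * hp,
          .share = share_real, .segment = sg$code,
          stringsAsFactors = FALSE)
      }
    }
  }
  trips <- do.call(rbind, trips_l)
  costs <- do.call(rbind, costs_l)
  rownames(trips) <- rownames(costs) <- NULL

  # gaussian mode: additive noise with sd = cv * segment mean of the true
  # (attributed-scale) cost, applied after the segment means are known
  if (sc$noise == "gaussian" && sc$noise_cv > 0) {
    for (segcode in unique(costs$.segment)) {
      i <- which(costs$.segment == segcode)
      sd_f <- sc$noise_cv * mean(costs$.fuel_attr_true[i])
      fuel_attr <- costs$.fuel_attr_true[i] + stats::rnorm(length(i), 0, sd_f)
      costs$fuel_cost[i] <- fuel_attr / costs$.share[i]
      cons_true <- costs$.fuel_attr_true[i] / sc$fuel_price
      sd_c <- sc$noise_cv * mean(cons_true)
      costs$fuel_consumption[i] <-
        (cons_true + stats::rnorm(length(i), 0, sd_c)) / costs$.share[i]
      sd_l <- sc$noise_cv * mean(costs$labour_cost[i])
      costs$labour_cost[i] <- costs$labour_cost[i] +
        stats::rnorm(length(i), 0, sd_l)
      sd_o <- sc$noise_cv * mean(costs$other_variable_costs[i])
      costs$other_variable_costs[i] <- costs$other_variable_costs[i] +
        stats::rnorm(length(i), 0, sd_o)
    }
  }
  costs <- costs[, c("vessel_id", "year", "fuel_cost", "fuel_consumption",
                     "labour_cost", "other_variable_costs")]

  # aggregate tables: exact marginal sums of the micro-data
  seg_of <- trips$fleet_segment[match(paste(costs$vessel_id, costs$year),
                                      paste(trips$vessel_id, trips$year))]
  agg <- function(value) {
    a <- stats::aggregate(list(value = value),
                          by = list(year = costs$year, fleet_segment = seg_of),
                          FUN = sum)
    a
  }
  sc_rows <- rbind(
    cbind(agg(costs$fuel_cost), variable_name = "fuel_costs"),
    cbind(agg(costs$labour_cost), variable_name = "labour_costs"),
    cbind(agg(costs$fuel_consumption), variable_name = "fuel_consumption"),
    cbind(agg(costs$other_variable_costs), variable_name = "other"))
  segment_costs <- sc_rows[, c("year", "fleet_segment", "variable_name",
                               "value")]
  segment_costs <- order_rows(segment_costs)
  rownames(segment_costs) <- NULL

  tv <- stats::aggregate(
    list(effort_hours = trips$hours_at_sea,
         effort_dayskw = trips$fishing_days * trips$kw,
         landings_value = trips$landings_value),
    by = list(year = trips$year, fleet_segment = trips$fleet_segment,
              metier = trips$metier),
    FUN = sum)
  tv <- tv[, c("year", "fleet_segment", "metier", "effort_hours",
               "effort_dayskw", "landings_value")]
  tv <- order_rows(tv)
  rownames(tv) <- NULL

  truth <- list(
    fuel_intercepts = sc$true_fuel_intercepts,
    fuel_slope = sc$true_fuel_slope,
    slope_offsets = sc$true_slope_offsets,
    consumption_intercepts = sc$true_fuel_intercepts / sc$fuel_price,
    consumption_slope = sc$true_fuel_slope / sc$fuel_price,
    crew_share = sc$true_crew_share,
    other_rate = sc$other_rate,
    fuel_structure = sc$fuel_structure,
    designed_prevalent = do.call(rbind, truth_prev),
    scenario = sc, seed = seed)
  rownames(truth$designed_prevalent) <- NULL

  out <- list(trips = trips, costs = costs, segment_costs = segment_costs,
              transversal = tv, truth = truth)
  class(out) <- "fleet_sim"
  out
}

#' @export
print.fleet_sim <- function(x, ...) {
  cat("Synthetic fleet dataset\n")
  cat(sprintf("  %d trips, %d vessel-year cost records, %d segment-cost rows, %d transversal rows\n",
              nrow(x$trips), nrow(x$costs), nrow(x$segment_costs),
              nrow(x$transversal)))
  cat(sprintf("  seed %d\n", x$truth$seed))
  invisible(x)
}

#' Expected disaggregation equation implied by a scenario's structure
#'
#' @param scenario a `fleet_scenario`.
#' @param segment segment code.
#' @return `"EQ1"`, `"EQ2"`, `"EQ3"` or `"none"`.
#' @export
true_equation <- function(scenario, segment) {
  sg <- Filter(function(s) s$code == segment, scenario$segments)[[1L]]
  if (scenario$fuel_structure == "independent") return("none")
  k <- length(sg$metiers)
  if (k == 1L) return("EQ3")
  gam <- scenario$true_slope_offsets[sg$metiers]
  if (any(gam != 0)) return("EQ2")
  "EQ1"
}
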