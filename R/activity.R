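# Phase-1 preprocessing: assign each vessel-year its prevalent metier, adjust
# annual costs proportionally to the activity share of that metier, and filter
# metiers by cumulative coverage within each fleet segment.

#' Prevalent metier of one vessel-year
#'
#' The prevalent metier is the one most frequently applied in terms of
#' fishing activity: the argmax of the summed activity metric over the
#' vessel-year's trips. The activity share is that metier's share of the
#' vessel-year total. Exact ties are broken towards the lexicographically
#' smaller metier code and flagged.
#'
#' @param trips data frame of trips for a single vessel-year.
#' @param activity_metric `"hours_at_sea"` (default), `"fishing_days"` or
#'   `"trip_count"`.
#' @return list with `metier`, `share` (in (0, 1]) and logical `tie`.
#' @export
assign_prevalent_metier <- function(trips, activity_metric = "hours_at_sea") {
  activity_metric <- match.arg(activity_metric,
                               c("hours_at_sea", "fishing_days", "trip_count"))
  if (nrow(trips) == 0L) stop("no trips supplied", call. = FALSE)
  w <- switch(activity_metric,
    hours_at_sea = trips$hours_at_sea,
    fishing_days = trips$fishing_days,
    trip_count   = rep(1, nrow(trips))
  )
  tot <- tapply(w, trips$metier, sum)
  total <- sum(tot)
  if (!is.finite(total) || total <= 0) {
    stop("no measurable activity for this vessel-year", call. = FALSE)
  }
  best <- max(tot)
  winners <- sort(names(tot)[tot == best])
  list(metier = winners[1L], share = unname(tot[[winners[1L]]] / total),
       tie = length(winners) > 1L)
}

#' Build metier observations from trips and annual vessel costs
#'
#' For every vessel-year present in `costs` and covered by trips, the
#' prevalent metier and its activity share are computed, and all annual
#' quantities -- costs and transversal totals alike -- are multiplied by the
#' share. This is the proportional-attribution rule: a vessel spending 75%
#' of its monitored activity on its prevalent metier contributes 75% of each
#' of its variable costs (and of its effort and revenue) to that metier. The
#' non-prevalent remainder is discarded. Applying the share to the
#' transversal totals as well as the costs keeps the per-unit cost rates of
#' the observation internally consistent; the run log flags this.
#'
#' @param trips validated trip table (see [read_trips()]).
#' @param costs validated vessel-year cost table (see [read_vessel_costs()]).
#' @param activity_metric passed to [assign_prevalent_metier()].
#' @return data frame with one row per vessel-year: `vessel_id`, `year`,
#'   `fleet_segment`, `prevalent_metier`, `activity_share`, adjusted
#'   transversal totals (`hours_at_sea`, `effort_dayskw`, `revenue`) and
#'   adjusted costs (`fuel_cost_adj`, `fuel_consumption_adj`,
#'   `labour_cost_adj`, `other_variable_adj`). Attribute `"ties"` lists
#'   vessel-years with tied prevalence.
#' @export
build_observations <- function(trips, costs, activity_metric = "hours_at_sea") {
  stopifnot(nrow(costs) > 0L)
  activity_metric <- match.arg(activity_metric,
                               c("hours_at_sea", "fishing_days", "trip_count"))
  key_t <- paste(trips$vessel_id, trips$year, sep = "\r")
  key_c <- paste(costs$vessel_id, costs$year, sep = "\r")

  nocov <- !(key_c %in% key_t)
  if (any(nocov)) {
    warning(sum(nocov), " vessel-year(s) with costs but no trips excluded",
            call. = FALSE)
  }
  w <- switch(activity_metric,
    hours_at_sea = trips$hours_at_sea,
    fishing_days = trips$fishing_days,
    trip_count   = rep(1, nrow(trips))
  )
  # activity per (vessel-year, metier), then argmax per vessel-year with
  # lexicographic tie-break on the metier code
  mkey <- paste(key_t, trips$metier, sep = "\r")
  wsum <- rowsum(w, mkey)
  parts <- do.call(rbind, strsplit(rownames(wsum), "\r", fixed = TRUE))
  gkey <- paste(parts[, 1L], parts[, 2L], sep = "\r")
  gmet <- parts[, 3L]
  gw <- wsum[, 1L]
  ord <- order(gkey, -gw, gmet)
  gkey <- gkey[ord]; gmet <- gmet[ord]; gw <- gw[ord]
  first <- !duplicated(gkey)
  prev_key <- gkey[first]
  prev_met <- gmet[first]
  prev_w <- gw[first]
  total_w <- rowsum(gw, gkey)[, 1L]
  total_w <- total_w[prev_key]
  # a tie is more than one metier at the winning weight
  maxw_all <- prev_w[match(gkey, prev_key)]
  n_at_max <- rowsum(as.numeric(gw == maxw_all), gkey)[, 1L]
  is_tie <- unname(n_at_max[prev_key] > 1)

  if (any(!is.finite(total_w) | total_w <= 0)) {
    bad <- prev_key[!is.finite(total_w) | total_w <= 0]
    stop("no measurable activity for vessel-year(s): ",
         paste(gsub("\r", "/", bad), collapse = ", "), call. = FALSE)
  }
  share <- prev_w / total_w

  hours <- rowsum(trips$hours_at_sea, key_t)
  dayskw <- rowsum(trips$fishing_days * trips$kw, key_t)
  revenue <- rowsum(trips$landings_value, key_t, na.rm = FALSE)
  seg <- tapply(trips$fleet_segment, key_t, function(s) s[1L])

  idx <- match(key_c[!nocov], prev_key)
  ck <- which(!nocov)
  s <- share[idx]
  out <- data.frame(
    vessel_id = costs$vessel_id[ck],
    year = costs$year[ck],
    fleet_segment = unname(seg[key_c[ck]]),
    prevalent_metier = prev_met[idx],
    activity_share = unname(s),
    hours_at_sea = unname(s * hours[key_c[ck], 1L]),
    effort_dayskw = unname(s * dayskw[key_c[ck], 1L]),
    revenue = unname(s * revenue[key_c[ck], 1L]),  # NA if a trip value missing
    fuel_cost_adj = unname(s * costs$fuel_cost[ck]),
    fuel_consumption_adj = unname(s * costs$fuel_consumption[ck]),
    labour_cost_adj = unname(s * costs$labour_cost[ck]),
    other_variable_adj = unname(s * costs$other_variable_costs[ck]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "ties") <- gsub("\r", "/", prev_key[idx][is_tie[idx]])
  out
}

#' Filter metiers by cumulative coverage within each fleet segment
#'
#' Within each fleet segment, metiers are sorted by descending observation
#' count (vessel-years with that prevalent metier) and the smallest prefix
#' whose cumulative share of observations reaches the threshold is retained;
#' observations of the remaining minor metiers are dropped. This avoids
#' spurious relationships and GLM convergence problems driven by poorly
#' represented metiers. Coverage can instead be measured in activity
#' (summed hours at sea) with `weighted = TRUE`.
#'
#' Coverage shares are always defined relative to the segment totals of the
#' dataset the filter first saw: the filtered result records those totals,
#' so re-applying the filter with the same threshold is a no-op
#' (idempotence).
#'
#' @param observations observation table from [build_observations()].
#' @param threshold coverage threshold in (0, 1]; default 0.8.
#' @param overrides optional named numeric vector of per-segment thresholds,
#'   e.g. `c(DTS_VL2440 = 0.95)`.
#' @param weighted if `TRUE`, coverage is activity-weighted (hours at sea)
#'   rather than observation-count based.
#' @return list with `observations` (retained rows) and `coverage` (one row
#'   per segment x metier: n_obs, share, cum_share, retained).
#' @export
filter_by_coverage <- function(observations, threshold = 0.8,
                               overrides = NULL, weighted = FALSE) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (threshold <= 0 || threshold > 1) {
    stop("coverage threshold must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(overrides) &&
      (any(overrides <= 0) || any(overrides > 1))) {
    stop("coverage threshold overrides must be in (0, 1]", call. = FALSE)
  }
  if (nrow(observations) == 0L) {
    warning("no observations to filter", call. = FALSE)
    return(list(observations = observations,
                coverage = data.frame(fleet_segment = character(),
                                      metier = character(), n_obs = integer(),
                                      share = numeric(), cum_share = numeric(),
                                      retained = logical())))
  }
  # segment totals from the first application keep the filter idempotent
  totals <- attr(observations, "coverage_totals")
  cov_rows <- list()
  keep_idx <- logical(nrow(observations))
  for (seg in sort(unique(observations$fleet_segment))) {
    sel <- observations$fleet_segment == seg
    obs_s <- observations[sel, , drop = FALSE]
    w <- if (weighted) {
      tapply(obs_s$hours_at_sea, obs_s$prevalent_metier, sum)
    } else {
      tapply(rep(1L, nrow(obs_s)), obs_s$prevalent_metier, sum)
    }
    # descending weight, ties broken by metier code for determinism
    ord <- order(-unname(w), names(w))
    w <- w[ord]
    denom <- if (!is.null(totals) && seg %in% names(totals)) {
      totals[[seg]]
    } else {
      sum(w)
    }
    cum <- cumsum(w) / denom
    thr <- if (!is.null(overrides) && seg %in% names(overrides)) {
      overrides[[seg]]
    } else {
      threshold
    }
    # retain metier j while the cumulative share before it is below the
    # threshold: the smallest prefix reaching the threshold
    before <- c(0, cum[-length(cum)])
    retained <- before < thr
    cov_rows[[seg]] <- data.frame(
      fleet_segment = seg, metier = names(w), n_obs = as.integer(
        if (weighted) tapply(rep(1L, nrow(obs_s)), obs_s$prevalent_metier,
                             sum)[names(w)] else unname(w)),
      share = unname(w) / denom, cum_share = unname(cum),
      retained = unname(retained), stringsAsFactors = FALSE
    )
    keep_m <- names(w)[retained]
    keep_idx[sel] <- obs_s$prevalent_metier %in% keep_m
  }
  coverage <- do.call(rbind, cov_rows)
  rownames(coverage) <- NULL
  out <- observations[keep_idx, , drop = FALSE]
  rownames(out) <- NULL
  segs <- sort(unique(observations$fleet_segment))
  seg_tot <- vapply(segs, function(seg) {
    if (!is.null(totals) && seg %in% names(totals)) totals[[seg]]
    else if (weighted) sum(observations$hours_at_sea[observations$fleet_segment == seg])
    else sum(observations$fleet_segment == seg)
  }, numeric(1))
  names(seg_tot) <- segs
  attr(out, "coverage_totals") <- seg_tot
  list(observations = out, coverage = coverage)
}
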