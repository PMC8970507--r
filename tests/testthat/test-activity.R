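# Prevalent-metier assignment, proportional cost adjustment and the
# coverage filter.

test_that("prevalent metier is the activity argmax with its share", {
  tr <- make_trips("V1", 2015, "SEG", c("OTB_DES", "OTB_MDD"),
                   hours = c(75, 25))
  pm <- assign_prevalent_metier(tr)
  expect_equal(pm$metier, "OTB_DES")
  expect_equal(pm$share, 0.75)
  expect_false(pm$tie)

  single <- assign_prevalent_metier(make_trips("V1", 2015, "SEG", "M1", 10))
  expect_equal(single$share, 1.0)

  tie <- assign_prevalent_metier(
    make_trips("V1", 2015, "SEG", c("B_MET", "A_MET"), hours = c(50, 50)))
  expect_equal(tie$metier, "A_MET")   # lexicographic tie-break
  expect_equal(tie$share, 0.5)
  expect_true(tie$tie)

  expect_error(
    assign_prevalent_metier(make_trips("V1", 2015, "SEG", "M1", hours = 0)),
    "no measurable activity")
})

test_that("alternative activity metrics change the argmax accordingly", {
  tr <- make_trips("V1", 2015, "SEG", c("M1", "M2", "M2"),
                   hours = c(60, 25, 25), days = c(1, 3, 3))
  expect_equal(assign_prevalent_metier(tr, "hours_at_sea")$metier, "M1")
  expect_equal(assign_prevalent_metier(tr, "fishing_days")$metier, "M2")
  expect_equal(assign_prevalent_metier(tr, "trip_count")$metier, "M2")
})

test_that("costs and transversal totals are adjusted by the activity share", {
  # the worked rule: a 75% prevalent share attributes 75% of each cost
  tr <- make_trips("V1", 2015, "SEG", c("OTB_DES", "OTB_MDD"),
                   hours = c(75, 25))
  co <- make_costs("V1", 2015, fuel = 10000, cons = 18000, labour = 30000,
                   other = 1000)
  obs <- build_observations(tr, co)
  expect_equal(obs$fuel_cost_adj, 7500)
  expect_equal(obs$fuel_consumption_adj, 13500)
  expect_equal(obs$labour_cost_adj, 22500)
  expect_equal(obs$other_variable_adj, 750)
  expect_equal(obs$hours_at_sea, 75)            # 0.75 * 100

  # share 1 leaves everything untouched
  tr1 <- make_trips("V2", 2015, "SEG", "OTB_DES", hours = 50)
  co1 <- make_costs("V2", 2015, fuel = 4000)
  obs1 <- build_observations(tr1, co1)
  expect_equal(obs1$fuel_cost_adj, 4000)
  expect_equal(obs1$activity_share, 1)
})

test_that("a multi-vessel multi-year fixture matches hand arithmetic", {
  set.seed(42)
  rows <- list()
  costs <- list()
  expect_share <- c()
  for (v in 1:4) for (yr in 2015:2016) {
    h1 <- 20 * v; h2 <- 2 * (yr %% 7) + 1   # h1 always the larger
    rows[[length(rows) + 1L]] <- make_trips(
      paste0("V", v), yr, "SEG", c("M1", "M2"), hours = c(h1, h2))
    costs[[length(costs) + 1L]] <- make_costs(paste0("V", v), yr,
                                              fuel = 1000 * v)
    expect_share[paste0("V", v, ".", yr)] <- h1 / (h1 + h2)
  }
  obs <- build_observations(do.call(rbind, rows), do.call(rbind, costs))
  expect_equal(nrow(obs), 8L)
  key <- paste0(obs$vessel_id, ".", obs$year)
  expect_equal(obs$activity_share, unname(expect_share[key]))
  expect_equal(obs$fuel_cost_adj,
               unname(expect_share[key]) * 1000 * as.integer(sub("V", "", obs$vessel_id)))
  # attributed costs never exceed the raw vessel-year cost
  expect_true(all(obs$fuel_cost_adj <= 1000 * as.integer(sub("V", "", obs$vessel_id)) + 1e-12))
})

test_that("vessel-years with costs but no trips are excluded with a warning", {
  tr <- make_trips("V1", 2015, "SEG", "M1", hours = 10)
  co <- rbind(make_costs("V1", 2015), make_costs("V2", 2015))
  expect_warning(obs <- build_observations(tr, co), "no trips")
  expect_equal(nrow(obs), 1L)
})

test_that("the vectorised observation builder agrees with the single
           vessel-year operation", {
  set.seed(7)
  rows <- list(); costs <- list()
  for (v in 1:10) {
    k <- sample(1:3, 1)
    rows[[v]] <- make_trips(paste0("V", v), 2015, "SEG",
                            paste0("M", sample(1:3, k)),
                            hours = runif(k, 1, 100))
    costs[[v]] <- make_costs(paste0("V", v), 2015, fuel = runif(1, 100, 1e4))
  }
  trips <- do.call(rbind, rows)
  obs <- build_observations(trips, do.call(rbind, costs))
  for (v in 1:10) {
    tt <- trips[trips$vessel_id == paste0("V", v), ]
    pm <- assign_prevalent_metier(tt)
    o <- obs[obs$vessel_id == paste0("V", v), ]
    expect_equal(o$prevalent_metier, pm$metier)
    expect_equal(o$activity_share, pm$share)
  }
})

test_that("coverage filter retains the smallest prefix reaching the threshold", {
  counts <- c(m1 = 50, m2 = 30, m3 = 15, m4 = 4, m5 = 1)
  obs <- make_obs(rep(names(counts), counts), hours = runif(100, 10, 100),
                  fuel = runif(100, 100, 1000))
  flt <- filter_by_coverage(obs, 0.80)
  kept <- sort(unique(flt$observations$prevalent_metier))
  expect_equal(kept, c("m1", "m2"))   # cumulative 80/100

  # threshold 1 keeps everything
  all_kept <- filter_by_coverage(obs, 1.0)
  expect_equal(nrow(all_kept$observations), 100L)

  # observation count after filtering equals the sum of retained counts
  cov <- flt$coverage
  expect_equal(nrow(flt$observations), sum(cov$n_obs[cov$retained]))
})

test_that("coverage prefix matches brute-force enumeration over random cases", {
  set.seed(11)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    counts <- sample(1:60, k, replace = TRUE)
    names(counts) <- paste0("m", seq_len(k))
    thr <- runif(1, 0.5, 1)
    obs <- make_obs(rep(names(counts), counts),
                    hours = runif(sum(counts), 10, 100),
                    fuel = runif(sum(counts), 100, 1000))
    flt <- filter_by_coverage(obs, thr)
    kept <- sort(unique(flt$observations$prevalent_metier))
    # oracle: enumerate prefixes of the count-sorted metier list
    ord <- names(counts)[order(-counts, names(counts))]
    tot <- sum(counts)
    best <- NULL
    for (j in seq_len(k)) {
      if (sum(counts[ord[seq_len(j)]]) / tot >= thr) { best <- ord[seq_len(j)]; break }
    }
    expect_equal(kept, sort(best))
  }
})

test_that("coverage filter is idempotent, including when the retained top
           metier exceeds the threshold on its own", {
  counts <- c(mA = 70, mB = 15, mC = 15)   # after one pass, 70/85 > 0.8
  obs <- make_obs(rep(names(counts), counts), hours = runif(100, 10, 100),
                  fuel = runif(100, 100, 1000))
  f1 <- filter_by_coverage(obs, 0.8)
  f2 <- filter_by_coverage(f1$observations, 0.8)
  expect_equal(sort(unique(f1$observations$prevalent_metier)),
               c("mA", "mB"))
  expect_identical(f2$observations$vessel_id, f1$observations$vessel_id)
  expect_equal(nrow(f2$observations), nrow(f1$observations))
})

test_that("per-segment threshold overrides apply", {
  obs <- rbind(
    make_obs(rep(c("m1", "m2", "m3"), c(60, 25, 15)),
             hours = runif(100, 10, 100), fuel = runif(100, 1, 10),
             segment = "SEG_A"),
    make_obs(rep(c("m1", "m2", "m3"), c(60, 25, 15)),
             hours = runif(100, 10, 100), fuel = runif(100, 1, 10),
             segment = "SEG_B"))
  flt <- filter_by_coverage(obs, 0.8, overrides = c(SEG_B = 0.95))
  kept_a <- unique(flt$observations$prevalent_metier[
    flt$observations$fleet_segment == "SEG_A"])
  kept_b <- unique(flt$observations$prevalent_metier[
    flt$observations$fleet_segment == "SEG_B"])
  expect_equal(sort(kept_a), c("m1", "m2"))
  expect_equal(sort(kept_b), c("m1", "m2", "m3"))
})

test_that("out-of-range thresholds are rejected", {
  obs <- make_obs(c("m1", "m2"), hours = c(1, 2), fuel = c(1, 2))
  expect_error(filter_by_coverage(obs, 1.5), "\\(0, 1\\]")
  expect_error(filter_by_coverage(obs, 0), "\\(0, 1\\]")
})
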