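# Gaussian cost GLMs in cell-means coding: exact recovery, oracle
# equivalence, nesting relations and the significance rules.

test_that("EQ1 recovers a noiseless metier-intercept structure exactly", {
  set.seed(31)
  met <- rep(c("OTB_DES", "OTB_MDD"), each = 20)
  h <- runif(40, 200, 900)
  a <- ifelse(met == "OTB_DES", 10000, 12000)
  obs <- make_obs(met, hours = h, fuel = a + 14 * h)
  fit <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1")
  cf <- coef(fit)
  expect_equal(unname(cf$alpha["OTB_DES"]), 10000, tolerance = 1e-8)
  expect_equal(unname(cf$alpha["OTB_MDD"]), 12000, tolerance = 1e-8)
  expect_equal(cf$beta, 14, tolerance = 1e-10)
  expect_equal(fit$explained_deviance, 100, tolerance = 1e-8)
})

test_that("coefficients equal the normal-equation solution of the
           cell-means design", {
  # tiny 6-point, 2-metier dataset solved by brute force
  met <- c("A", "A", "A", "B", "B", "B")
  h <- c(1, 2, 3, 1, 2, 4)
  y <- c(5, 8, 10, 7, 11, 18)
  obs <- make_obs(met, hours = h, fuel = y)
  fit <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1")
  X <- cbind(A = as.numeric(met == "A"), B = as.numeric(met == "B"), x = h)
  beta_o <- ls_oracle(X, y)
  cf <- coef(fit)
  expect_equal(unname(cf$alpha[c("A", "B")]), unname(beta_o[1:2]),
               tolerance = 1e-10)
  expect_equal(cf$beta, unname(beta_o[3]), tolerance = 1e-10)

  # randomized designs, EQ1 and EQ2, against the same oracle
  set.seed(37)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    npm <- sample(5:12, k, replace = TRUE)
    met <- rep(paste0("M", seq_len(k)), npm)
    n <- length(met)
    h <- runif(n, 10, 500)
    y <- 100 * match(met, unique(met)) + 3 * h + rnorm(n)
    obs <- make_obs(met, hours = h, fuel = y)

    f1 <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1")
    X1 <- cbind(sapply(sort(unique(met)), function(m) as.numeric(met == m)),
                x = h)
    o1 <- ls_oracle(X1, y)
    expect_equal(unname(c(f1$terms$estimate)),
                 unname(c(o1)), tolerance = 1e-8)

    f2 <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ2")
    lev <- sort(unique(met))
    X2 <- cbind(X1, sapply(lev[-1L], function(m) h * (met == m)))
    o2 <- ls_oracle(X2, y)
    expect_equal(unname(f2$terms$estimate), unname(c(o2)), tolerance = 1e-8)
  }
})

test_that("EQ3 equals the zero-intercept regression and EQ1 with one metier
           collapses to it", {
  set.seed(41)
  h <- runif(35, 50, 400)
  y <- 12.5 * h + rnorm(35, 0, 30)
  obs <- make_obs(rep("LLD_LPF", 35), hours = h, fuel = y)
  f3 <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ3")
  fz <- fit_zero_intercept(h, y)
  expect_equal(coef(f3)$beta, fz$slope, tolerance = 1e-12)
  expect_error(fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1"),
               "at least two metiers")

  # with >= 2 metiers but identical generating law, EQ1 deviance >= EQ3
  met <- rep(c("A", "B"), c(18, 17))
  obs2 <- make_obs(met, hours = h, fuel = y)
  f1 <- fit_cost_glm(obs2, "fuel_cost", "effort_hours", "EQ1")
  f3b <- fit_cost_glm(obs2, "fuel_cost", "effort_hours", "EQ3")
  expect_gte(f1$explained_deviance, f3b$explained_deviance - 1e-10)
})

test_that("explained deviance is non-decreasing along the nested chain
           EQ3 -> EQ1 -> EQ2", {
  set.seed(43)
  for (rep in 1:10) {
    met <- rep(c("A", "B", "C"), each = 15)
    h <- runif(45, 10, 300)
    y <- 50 * match(met, c("A", "B", "C")) + 2 * h + rnorm(45, 0, 20)
    obs <- make_obs(met, hours = h, fuel = y)
    e3 <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ3")$explained_deviance
    e1 <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1")$explained_deviance
    e2 <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ2")$explained_deviance
    expect_gte(e1, e3 - 1e-10)
    expect_gte(e2, e1 - 1e-10)
  }
})

test_that("AIC prefers EQ1 over EQ3 on EQ1-structured data", {
  set.seed(47)
  met <- rep(c("A", "B"), each = 25)
  h <- runif(50, 100, 600)
  y <- ifelse(met == "A", 5000, 9000) + 20 * h + rnorm(50, 0, 100)
  obs <- make_obs(met, hours = h, fuel = y)
  f1 <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1")
  f3 <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ3")
  expect_lt(f1$aic, f3$aic)
})

test_that("the explained-deviance reference is the intercept-only model", {
  met <- rep(c("A", "B"), each = 10)
  h <- seq_len(20)
  y <- 3 * h + rnorm(20, 0, 0.1)
  obs <- make_obs(met, hours = h, fuel = y)
  f <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1")
  expect_equal(f$null_deviance, sum((y - mean(y))^2))
  expect_true(f$explained_deviance >= 0 && f$explained_deviance <= 100)
})

test_that("rank-deficient designs name the offending metier", {
  met <- c(rep("A", 10), "B")     # B has a single observation
  obs <- make_obs(met, hours = seq_len(11), fuel = seq_len(11))
  expect_error(fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1"), "B")
  expect_error(fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ2"), "B")
})

test_that("metier significance follows the any-level rule with strict alpha", {
  set.seed(53)
  met <- rep(c("A", "B"), each = 30)
  h <- runif(60, 100, 500)
  # strong intercepts: clearly significant
  obs <- make_obs(met, hours = h,
                  fuel = ifelse(met == "A", 8000, 16000) + 10 * h +
                    rnorm(60, 0, 300))
  f <- fit_cost_glm(obs, "fuel_cost", "effort_hours", "EQ1")
  expect_true(metier_significant(f, 0.05))
  expect_true(metier_significant(f, 0.05, joint = TRUE))

  # boundary convention: p == alpha is NOT significant
  f_mod <- f
  f_mod$terms$p_value[f_mod$terms$role == "metier"] <- 0.05
  expect_false(metier_significant(f_mod, 0.05))
  f_mod$terms$p_value[f_mod$terms$role == "metier"] <- c(0.001, 0.08)
  expect_true(metier_significant(f_mod, 0.05))
  f_mod$terms$p_value[f_mod$terms$role == "metier"] <- c(0.51, 0.87)
  expect_false(metier_significant(f_mod, 0.05))

  expect_error(metier_significant(
    fit_cost_glm(make_obs(rep("A", 30), hours = h[1:30], fuel = 10 * h[1:30]),
                 "fuel_cost", "effort_hours", "EQ3")), "EQ1/EQ2")
})
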