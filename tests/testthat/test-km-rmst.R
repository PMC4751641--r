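test_that("product-limit estimate matches hand computation", {
  d <- survival_data(2, 1, 0)
  km <- kaplan_meier(d)
  expect_equal(km$surv, 0)

  d <- survival_data(c(1, 2, 3), c(1, 1, 1), c(0, 0, 0))
  km <- kaplan_meier(d)
  expect_equal(km$surv, c(2/3, 1/3, 0))

  ## censoring at 2: S(1) = 2/3, then one at risk at t = 3
  d <- survival_data(c(1, 2, 3), c(1, 0, 1), c(0, 0, 0))
  km <- kaplan_meier(d)
  expect_equal(km$times, c(1, 3))
  expect_equal(km$surv, c(2/3, 0))
  expect_equal(km$nrisk, c(3, 1))

  expect_error(kaplan_meier(d, arm = 1), "empty")
  expect_error(kaplan_meier(survival_data(1, 0, 0)), "no events")
})

test_that("product-limit curve agrees with survival::survfit", {
  for (d in fixture_battery()) {
    km <- kaplan_meier(d)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    at_ev <- summary(sf, times = km$times)
    expect_equal(km$surv, at_ev$surv, tolerance = 1e-12)
  }
})

test_that("RMST equals the sample mean of min(T, t*) without censoring", {
  d <- survival_data(1:5, rep(1, 5), rep(0, 5))
  expect_equal(rmst(d, 4)$mu, 2.8)

  ## t* below the smallest event time: S = 1 throughout
  expect_equal(rmst(d, 0.5)$mu, 0.5)

  ## oracle equivalence over many uncensored fixtures
  set.seed(31)
  for (i in 1:25) {
    tt <- rexp(50, rate = runif(1, 0.5, 2))
    d <- survival_data(tt, rep(1, 50), rep(0, 50))
    ts <- unname(quantile(tt, 0.8))
    expect_equal(rmst(d, ts)$mu, mean(pmin(tt, ts)), tolerance = 1e-10)
  }
})

test_that("RMST is refused beyond the largest event time", {
  d <- survival_data(c(1, 2, 5), c(1, 1, 0), c(0, 0, 0))
  expect_error(rmst(d, 3), "largest uncensored event time")
  expect_silent(rmst(d, 2))
})

test_that("asymptotic, jackknife and bootstrap SEs agree on an uncensored sample", {
  set.seed(7)
  tt <- rexp(200)
  d <- survival_data(tt, rep(1, 200), rep(0, 200))
  ts <- unname(quantile(tt, 0.85))
  se_a <- rmst(d, ts, variance = "asymptotic")$se
  se_j <- rmst(d, ts, variance = "jackknife")$se
  boot <- replicate(2000, {
    i <- sample.int(200, replace = TRUE)
    mean(pmin(tt[i], ts))
  })
  se_b <- sd(boot)
  expect_lt(abs(se_a - se_j) / se_j, 0.15)
  expect_lt(abs(se_a - se_b) / se_b, 0.15)
  expect_lt(abs(se_j - se_b) / se_b, 0.15)
})

test_that("RMST difference: sign, identity and area-between-curves", {
  d <- make_fixture(60, effect = "ph", hr = 0.5, horizon = 3, seed = 41)
  ts <- min(tapply(d$time[d$event == 1], d$arm[d$event == 1], max))
  r <- rmst_difference(d, ts)

  ## antisymmetry under arm-label swap
  d2 <- d; d2$arm <- 1 - d2$arm
  r2 <- rmst_difference(survival_data(d2$time, d2$event, d2$arm), ts)
  expect_equal(r2$diff, -r$diff)
  expect_equal(r2$chi2, r$chi2)

  ## identical arms: zero difference
  set.seed(42)
  base <- data.frame(time = rexp(30), event = rbinom(30, 1, 0.8))
  dd <- survival_data(rep(base$time, 2), rep(base$event, 2),
                      rep(c(0, 1), each = 30))
  ts0 <- max(base$time[base$event == 1]) * 0.9
  expect_equal(rmst_difference(dd, ts0)$diff, 0)
  expect_equal(rmst_difference(dd, ts0)$chi2, 0)

  ## signed area between the two KM curves, by rectangle summation
  a1 <- oracle_rmst_area(d$time[d$arm == 1], d$event[d$arm == 1], ts)
  a0 <- oracle_rmst_area(d$time[d$arm == 0], d$event[d$arm == 0], ts)
  expect_equal(r$diff, a1 - a0, tolerance = 1e-10)
})

test_that("chisquare of 8.11 maps to the 1-df tail probability 0.0044", {
  expect_equal(round(pchisq(8.11, df = 1, lower.tail = FALSE), 4), 0.0044)
})

test_that("the horizon grid follows the stated percentile convention", {
  d <- survival_data(1:10, rep(1, 10), rep(c(0, 1), 5))
  g <- make_grid(d, nt = 10)
  lo <- unname(quantile(1:10, 0.3, type = 7))
  expect_equal(g, seq(lo, 10, length.out = 10))

  expect_equal(make_grid(d, nt = 2), c(lo, 10))

  dsame <- survival_data(rep(2, 5), rep(1, 5), c(0, 0, 1, 1, 1))
  expect_error(make_grid(dsame), "distinct")
})

test_that("scan locates the maximal chisquare and matches a direct loop", {
  d <- make_fixture(120, effect = "early", hr_early = 0.3, hr_late = 1.3,
                    horizon = 6, seed = 55)
  g <- make_grid(d, 10)
  sc <- rmst_scan(d, grid = g)
  ok <- !sc$table$carried
  chi <- rep(NA_real_, length(g))
  chi[ok] <- vapply(g[ok], function(ts) rmst_difference(d, ts)$chi2,
                    numeric(1))
  expect_equal(sc$table$chi2[ok], chi[ok], tolerance = 1e-12)
  expect_equal(sc$C_max, max(sc$table$chi2))
  expect_equal(sc$t_opt, g[which.max(sc$table$chi2)])
  expect_equal(sc$P_max, pchisq(sc$C_max, 1, lower.tail = FALSE))

  ## single-point grid
  sc1 <- rmst_scan(d, grid = g[3])
  expect_equal(sc1$C_max, chi[3], tolerance = 1e-12)

  ## arm-label swap leaves C_max unchanged
  dsw <- survival_data(d$time, d$event, 1 - d$arm)
  expect_equal(rmst_scan(dsw, grid = g)$C_max, sc$C_max)
})

test_that("jackknife scan path agrees with per-horizon jackknife calls", {
  d <- make_fixture(40, effect = "ph", hr = 0.6, horizon = 3, seed = 77)
  g <- make_grid(d, 4)
  g <- g[g <= min(tapply(d$time[d$event == 1], d$arm[d$event == 1], max))]
  sc <- rmst_scan(d, grid = g, variance = "jackknife")
  for (i in seq_along(g)) {
    r <- rmst_difference(d, g[i], variance = "jackknife")
    expect_equal(sc$table$chi2[i], r$chi2, tolerance = 1e-12)
  }
})

test_that("RMST is nondecreasing in t* and bounded by t*", {
  d <- make_fixture(80, horizon = 4, accrual = 2, seed = 13)
  ts <- seq(0.2, max(d$time[d$event == 1]), length.out = 15)
  mus <- vapply(ts, function(s) rmst(d, s)$mu, numeric(1))
  expect_true(all(diff(mus) >= -1e-12))
  expect_true(all(mus <= ts + 1e-12))
  expect_true(all(mus > 0))
})
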