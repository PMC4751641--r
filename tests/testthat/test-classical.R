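test_that("logrank chisquare equals the Cox score statistic (Breslow)", {
  for (d in fixture_battery()) {
    lr <- logrank_test(d)
    cf <- cox_fit(d)
    expect_equal(lr$chi2, cf$chi2_score, tolerance = 1e-8)
    ## tie-free data: also identical to the classical
    ## hypergeometric-variance logrank of survival::survdiff
    if (!any(duplicated(d$time[d$event == 1]))) {
      sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = d)
      expect_equal(lr$chi2, unname(sd$chisq), tolerance = 1e-8)
    }
  }
})

test_that("logrank test degenerate and symmetry cases", {
  base <- data.frame(time = c(1, 2, 4, 6), event = c(1, 1, 0, 1))
  d <- survival_data(rep(base$time, 2), rep(base$event, 2),
                     rep(c(0, 1), each = 4))
  expect_equal(logrank_test(d)$chi2, 0, tolerance = 1e-12)

  d2 <- make_fixture(50, effect = "ph", hr = 0.5, horizon = 3, seed = 6)
  dsw <- survival_data(d2$time, d2$event, 1 - d2$arm)
  expect_equal(logrank_test(dsw)$chi2, logrank_test(d2)$chi2)

  expect_error(logrank_test(survival_data(c(1, 2), c(1, 1), c(0, 0))),
               "both arms")
})

test_that("Cox estimate maximizes the written-out partial likelihood", {
  d <- survival_data(c(1, 3, 2, 4), c(1, 1, 1, 1), c(0, 0, 1, 1))
  cf <- cox_fit(d)
  bgrid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(bgrid, oracle_cox_loglik, numeric(1),
               time = d$time, event = d$event, arm = d$arm)
  expect_equal(cf$beta, bgrid[which.max(ll)], tolerance = 1e-3)
  ## refined: the analytic maximizer via optimize on the oracle
  opt <- optimize(oracle_cox_loglik, c(-3, 3), maximum = TRUE,
                  time = d$time, event = d$event, arm = d$arm,
                  tol = 1e-10)
  expect_equal(cf$beta, opt$maximum, tolerance = 1e-6)
  expect_equal(cf$chi2_plr,
               2 * (opt$objective -
                    oracle_cox_loglik(0, d$time, d$event, d$arm)),
               tolerance = 1e-6)
})

test_that("Cox fit symmetry and degenerate cases", {
  set.seed(12)
  base <- data.frame(time = rexp(40), event = rbinom(40, 1, 0.8))
  d <- survival_data(rep(base$time, 2), rep(base$event, 2),
                     rep(c(0, 1), each = 40))
  cf <- cox_fit(d)
  expect_lt(abs(cf$beta), 1e-6)
  expect_lt(cf$chi2_plr, 1e-8)

  d2 <- make_fixture(60, effect = "ph", hr = 0.5, horizon = 3, seed = 8)
  cf2 <- cox_fit(d2)
  dsw <- survival_data(d2$time, d2$event, 1 - d2$arm)
  cfsw <- cox_fit(dsw)
  expect_equal(cfsw$beta, -cf2$beta, tolerance = 1e-7)
  expect_equal(cfsw$chi2_plr, cf2$chi2_plr, tolerance = 1e-9)

  ## monotone likelihood: all events in one arm
  dmono <- survival_data(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0),
                         c(0, 0, 0, 1, 1, 1))
  expect_error(cox_fit(dmono), "at least one event|separated")
})

test_that("scaled Schoenfeld residuals match explicit risk-set algebra", {
  d <- survival_data(c(1, 3, 2, 4), c(1, 1, 1, 1), c(0, 0, 1, 1))
  cf <- cox_fit(d)
  b <- cf$beta

  ## raw residuals: observed arm minus risk-set expectation at each event
  expect_at <- function(tk) {
    risk <- which(d$time >= tk)
    sum(d$arm[risk] * exp(b * d$arm[risk])) / sum(exp(b * d$arm[risk]))
  }
  ev_t <- sort(d$time)
  raw <- d$arm[order(d$time)] - vapply(ev_t, expect_at, numeric(1))
  expect_lt(abs(sum(raw)), 1e-8)  # score equation at the maximizer

  sr <- schoenfeld_scaled_residuals(cf, d)
  expect_equal(sr$time, ev_t)
  ## scaled residual = beta + d * I^{-1} * raw
  Iinv <- cf$se^2
  expect_equal(sr$scaled_residual, b + 4 * Iinv * raw, tolerance = 1e-6)

  dsingle <- survival_data(c(1, 2), c(1, 0), c(0, 1))
  expect_error(schoenfeld_scaled_residuals(cf, dsingle), "2 events")
})

test_that("Grambsch-Therneau statistic: transform affinity and degeneracies", {
  ## evenly spaced tie-free event times: rank transform is affine in time,
  ## so the statistic is identical under rank and identity
  d <- survival_data(seq(1, 40), rep(1, 40), rep(c(0, 1), 20))
  cf <- cox_fit(d)
  g_id <- grambsch_therneau(cf, d, transform = "identity")
  g_rk <- grambsch_therneau(cf, d, transform = "rank")
  expect_equal(g_id$chi2_gt, g_rk$chi2_gt, tolerance = 1e-8)

  dtie <- survival_data(c(2, 2, 2, 5), c(1, 1, 1, 0), c(0, 1, 0, 1))
  cftie <- cox_fit(dtie)
  expect_error(grambsch_therneau(cftie, dtie), "single time")
})

test_that("Grambsch-Therneau test holds its size under proportional hazards", {
  set.seed(17)
  rej <- 0; reps <- 400
  for (i in 1:reps) {
    d <- make_fixture(200, effect = "ph", hr = 0.7, horizon = 3)
    p <- grambsch_therneau(cox_fit(d), d)$p_gt
    rej <- rej + (p <= 0.05)
  }
  ## binomial 3 SE around 5%
  expect_lt(abs(rej / reps - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("joint test adds the chisquares on 2 df", {
  fake_cox <- structure(list(chi2_plr = 3.84), class = "cox_result")
  fake_gt <- structure(list(chi2_gt = 0), class = "gt_result")
  jt <- joint_test(fake_cox, fake_gt)
  expect_equal(jt$chi2_joint, 3.84)
  expect_equal(jt$p_joint, exp(-1.92), tolerance = 1e-12)

  fake_cox$chi2_plr <- 0
  expect_equal(joint_test(fake_cox, fake_gt)$p_joint, 1)

  ## monotone decreasing in each component
  p <- function(a, b) joint_test(structure(list(chi2_plr = a),
                                           class = "cox_result"),
                                 structure(list(chi2_gt = b),
                                           class = "gt_result"))$p_joint
  expect_true(p(1, 1) > p(2, 1) && p(2, 1) > p(2, 3))
})

test_that("Cox P-value holds its size under the global null", {
  set.seed(23)
  reps <- 2000; rej <- 0
  for (i in 1:reps) {
    d <- make_fixture(100, effect = "null", horizon = 2)
    rej <- rej + (cox_fit(d)$p_cox <= 0.05)
  }
  expect_lt(abs(rej / reps - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})
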