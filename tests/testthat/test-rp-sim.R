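test_that("spline fit recovers an exponential distribution", {
  d <- make_fixture(2500, control = list(rate = 0.5), seed = 61)
  m <- fit_rp(d, df = 3)
  qs <- unname(quantile(d$time, c(0.25, 0.5, 0.75)))
  expect_lt(max(abs(predict(m, qs) - exp(-0.5 * qs))), 0.02)

  ## df = 1 nests the Weibull: slope near 1 for exponential data
  m1 <- fit_rp(d, df = 1)
  expect_gt(m1$gamma[2], 0.95); expect_lt(m1$gamma[2], 1.05)

  expect_error(fit_rp(survival_data(c(1, 2, 3), c(1, 1, 1), c(0, 0, 0)),
                      df = 3), "distinct uncensored")
})

test_that("spline fit agrees with flexsurv on the same data", {
  skip_if_not_installed("flexsurv")
  d <- make_fixture(1000, family = "weibull",
                    control = list(shape = 1.3, scale = 2),
                    horizon = 5, accrual = 2, seed = 62)
  m <- fit_rp(d, df = 3)
  fs <- flexsurv::flexsurvspline(survival::Surv(time, event) ~ 1,
                                 data = d, k = 2, scale = "hazard")
  qs <- unname(quantile(d$time[d$event == 1], c(0.2, 0.4, 0.6, 0.8)))
  Sfs <- summary(fs, t = qs, type = "survival", ci = FALSE)[[1]]$est
  expect_lt(max(abs(predict(m, qs) - Sfs)), 0.01)
})

test_that("censoring-distribution fit covers the degenerate cases", {
  ## single administrative censoring time: point mass
  d <- make_fixture(200, horizon = 2, seed = 63)
  cm <- fit_censoring_model(d)
  expect_s3_class(cm, "censoring_point")
  expect_equal(cm$time, 2)
  expect_equal(simulate_survival(cm, 3), rep(2, 3))

  ## no censoring: sentinel
  d2 <- make_fixture(50, seed = 64)
  cm2 <- fit_censoring_model(d2)
  expect_s3_class(cm2, "censoring_none")
  expect_true(all(is.infinite(simulate_survival(cm2, 3))))

  ## uniform(0, 5) censoring: fitted censoring survival close to 1 - t/5.
  ## The uniform's log cumulative hazard is strongly curved near the upper
  ## support limit, so a df = 3 spline tracks it only to within ~0.05;
  ## more knots bring the fit inside 0.03.
  set.seed(65)
  tev <- rexp(4000, rate = 0.15)
  cens <- runif(4000, 0, 5)
  d3 <- survival_data(pmin(tev, cens), as.numeric(tev <= cens),
                      rep(c(0, 1), 2000))
  ts <- seq(0.5, 4.5, by = 0.5)
  cm3 <- fit_censoring_model(d3)
  expect_lt(max(abs(predict(cm3, ts) - (1 - ts / 5))), 0.06)
  cm6 <- fit_censoring_model(d3, df = 6)
  expect_lt(max(abs(predict(cm6, ts) - (1 - ts / 5))), 0.03)
})

test_that("inversion sampler reproduces the model's own distribution", {
  ## model encoding exponential(rate 1) exactly: s(x) = x
  m <- nphtest:::new_rp_model(gamma = c(0, 1), knots = log(c(0.05, 20)),
                              df = 1)
  set.seed(66)
  x <- simulate_survival(m, 1e5)
  expect_lt(abs(mean(x) - 1), 3 / sqrt(1e5))

  ## KS distance against the model-implied CDF
  set.seed(67)
  y <- simulate_survival(m, 1e4)
  ks <- max(abs(ecdf(y)(sort(y)) - (1 - predict(m, sort(y)))))
  expect_lt(ks, 0.02)

  ## fixed seed reproducibility
  expect_identical(simulate_survival(m, 100, seed = 5),
                   simulate_survival(m, 100, seed = 5))
})

test_that("round trip: refitting draws from a known model recovers it", {
  m0 <- nphtest:::canned_early_model()
  set.seed(68)
  tt <- simulate_survival(m0, 1e4)
  d <- survival_data(tt, rep(1, length(tt)), rep(c(0, 1), length(tt) / 2))
  m1 <- fit_rp(d, df = 3)
  qs <- quantile(tt, seq(0.05, 0.95, by = 0.05))
  expect_lt(max(abs(predict(m1, qs) - predict(m0, qs))), 0.02)
})

test_that("PH shift multiplies the cumulative hazard exactly", {
  m <- fit_rp(make_fixture(800, family = "weibull",
                           control = list(shape = 1.2, scale = 3),
                           seed = 69), df = 2)
  ms <- apply_ph_shift(m, log(0.75))
  ts <- exp(seq(log(0.05), log(15), length.out = 50))
  expect_equal(predict(ms, ts, type = "cumhaz") /
                 predict(m, ts, type = "cumhaz"),
               rep(0.75, 50), tolerance = 1e-12)
  expect_identical(apply_ph_shift(m, 0), m)

  ## shift commutes with sampling in distribution: transporting control
  ## draws through H1^{-1}(H0(t)) = H0^{-1}(H0(t)/0.75) must match draws
  ## from the shifted model
  set.seed(70)
  a <- simulate_survival(ms, 1e4)
  t0 <- simulate_survival(m, 1e4)
  tg <- exp(seq(log(min(t0, a)) - 0.5, log(max(t0, a)) + 0.5,
                length.out = 4000))
  Hg <- predict(m, tg, type = "cumhaz")
  t0_trans <- approx(Hg, tg, xout = predict(m, t0, type = "cumhaz") / 0.75,
                     rule = 2)$y
  ks <- suppressWarnings(ks.test(a, t0_trans)$statistic)
  expect_lt(unname(ks), 0.02)
})

test_that("scenario B recovers the target hazard ratio in a Cox fit", {
  sp <- scenario_spec("B", n = 20000, censoring = NULL)
  d <- scenario_generate(sp, seed = 71)
  hr <- cox_fit(d)$hr
  expect_gt(hr, 0.72); expect_lt(hr, 0.78)
})

test_that("late-effect perturbation has the required HR shape", {
  ctrl <- nphtest:::canned_control_model()
  ## zero asymptote: no perturbation
  l0 <- apply_late_effect(ctrl, theta = 0)
  expect_equal(hr_function(l0, c(0.5, 1, 3, 8)), rep(1, 4))

  ld <- apply_late_effect(ctrl)
  ts_early <- seq(0.05, 1, length.out = 50)
  expect_lt(max(abs(hr_function(ld, ts_early) - 1)), 0.02)
  expect_lt(hr_function(ld, 3), 0.8)
  ts_late <- seq(1.01, 20, length.out = 100)
  expect_true(all(hr_function(ld, ts_late) < 1))

  ## destructive parameters are rejected with the offending time
  expect_error(apply_late_effect(ctrl, theta = -4, tau = 0.05),
               "nonpositive hazard")
})

test_that("analytic late-effect HR matches large-sample cumulative hazards", {
  ctrl <- nphtest:::canned_control_model()
  ld <- apply_late_effect(ctrl)
  set.seed(72)
  t0 <- simulate_survival(ctrl, 1e5)
  t1 <- simulate_survival(ld, 1e5)
  ## binned hazard ratio: ratio of cumulative-hazard increments over bins,
  ## against the analytic HR averaged with the same weights
  edges <- seq(1, 5, by = 1)
  H0 <- -log(1 - ecdf(t0)(edges))
  H1 <- -log(1 - ecdf(t1)(edges))
  for (k in 1:(length(edges) - 1)) {
    emp <- (H1[k + 1] - H1[k]) / (H0[k + 1] - H0[k])
    mid <- exp(seq(log(edges[k]), log(edges[k + 1]), length.out = 20))
    w <- predict(ctrl, mid, type = "hazard")
    ana <- sum(hr_function(ld, mid) * w) / sum(w)
    expect_lt(abs(emp - ana), 0.03)
  }
})

test_that("scenario generator honours specs and passes data invariants", {
  for (sc in c("A", "B", "C", "D")) {
    sp <- scenario_spec(sc, n = 300,
                        censoring = list(accrual = 3, total = 6))
    d <- scenario_generate(sp, seed = 73)
    expect_s3_class(d, "survival_data")
    expect_equal(nrow(d), 300L)
    expect_equal(sum(d$arm), 150)
    expect_true(all(d$time > 0 & d$time <= 6 + 1e-9))
    ## reproducible
    expect_identical(d, scenario_generate(sp, seed = 73))
  }
  expect_error(scenario_spec("A", n = 301), "even")
})

test_that("scenario A random split is an exchangeable null for the logrank", {
  set.seed(74)
  reps <- 400; rej <- 0
  sp <- scenario_spec("A", n = 200, censoring = list(accrual = 3, total = 6))
  for (i in 1:reps) {
    d <- scenario_generate(sp)
    rej <- rej + (logrank_test(d)$p <= 0.05)
  }
  expect_lt(abs(rej / reps - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("canned early-effect scenario carries a detectable non-PH signal", {
  set.seed(75)
  reps <- 60; rej <- 0
  sp <- scenario_spec("C", n = 2000, censoring = NULL)
  for (i in 1:reps) {
    d <- scenario_generate(sp)
    rej <- rej + (grambsch_therneau(cox_fit(d), d)$p_gt <= 0.05)
  }
  expect_gt(rej / reps, 0.5)
})

test_that("models serialize to JSON and back", {
  m <- nphtest:::canned_early_model()
  f <- withr::local_tempfile(fileext = ".json")
  rp_to_json(m, f)
  m2 <- rp_from_json(f)
  expect_equal(m2$gamma, m$gamma)
  expect_equal(m2$knots, m$knots)
  expect_equal(m2$df, m$df)
})
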