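## Flexible parametric survival model: restricted cubic spline s(x) on
## x = log time, modelling the log cumulative hazard, S(t) =
## exp(-exp(s(ln t))). df = 3 places interior knots at the 33rd/67th
## centiles of the uncensored log event times; boundary knots at min/max.
## The restricted basis is linear beyond the boundary knots, which makes
## tail extrapolation stable and inversion sampling well posed.

## Basis and derivative. knots ascending on the log-time scale; returns a
## matrix with columns (1, x, v_1(x), ..., v_{m}(x)) for m interior knots.
rcs_basis <- function(x, knots, deriv = FALSE) {
  k <- length(knots)
  kmin <- knots[1]; kmax <- knots[k]
  out <- matrix(0, length(x), k)
  if (!deriv) {
    out[, 1] <- 1
    out[, 2] <- x
  } else {
    out[, 2] <- 1
  }
  if (k > 2) {
    for (j in 2:(k - 1)) {
      lam <- (kmax - knots[j]) / (kmax - kmin)
      if (!deriv) {
        out[, j + 1] <- pmax(x - knots[j], 0)^3 -
          lam * pmax(x - kmin, 0)^3 - (1 - lam) * pmax(x - kmax, 0)^3
      } else {
        out[, j + 1] <- 3 * (pmax(x - knots[j], 0)^2 -
          lam * pmax(x - kmin, 0)^2 - (1 - lam) * pmax(x - kmax, 0)^2)
      }
    }
  }
  out
}

rp_s <- function(model, x) drop(rcs_basis(x, model$knots) %*% model$gamma)
rp_sprime <- function(model, x)
  drop(rcs_basis(x, model$knots, deriv = TRUE) %*% model$gamma)

new_rp_model <- function(gamma, knots, df, loglik = NA_real_, note = NULL) {
  structure(list(gamma = as.numeric(gamma), knots = as.numeric(knots),
                 df = df, loglik = loglik, note = note),
            class = "rp_model")
}

#' @export
print.rp_model <- function(x, ...) {
  cat(sprintf("Flexible parametric model (df = %d) on the log cumulative hazard\n",
              x$df))
  cat("knots (log time):", paste(format(x$knots, digits = 4),
                                 collapse = ", "), "\n")
  cat("coefficients:", paste(format(x$gamma, digits = 4),
                             collapse = ", "), "\n")
  if (!is.na(x$loglik)) cat("log-likelihood:", format(x$loglik), "\n")
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

## Verify exp(s) is a valid cumulative hazard: s' > 0 over the knot span
## (checked on a 200-point grid, spanning slightly beyond the boundaries).
rp_check_monotone <- function(gamma, knots) {
  span <- knots[length(knots)] - knots[1]
  xs <- seq(knots[1] - 0.1 * span, knots[length(knots)] + 0.1 * span,
            length.out = 200)
  all(drop(rcs_basis(xs, knots, deriv = TRUE) %*% gamma) > 0)
}

#' Fit a flexible parametric survival model
#'
#' Maximum-likelihood fit of S(t) = exp(-exp(s(ln t))) with s a restricted
#' cubic spline with `df` degrees of freedom (df coefficients beyond the
#' intercept). Event contribution to the log likelihood:
#' s(x) + log s'(x) - x - exp(s(x)); censoring contribution: -exp(s(x)).
#' Interior knots sit at equally spaced centiles of the uncensored log
#' event times (33rd/67th for df = 3), boundary knots at their min/max.
#'
#' @param data a [survival_data] object or any data frame with `time` and
#'   `event` columns (the arm column is ignored: the model is fitted
#'   without covariates).
#' @param df spline degrees of freedom (default 3; df = 1 is
#'   Weibull-equivalent).
#' @return An `rp_model`: list with `gamma` (df + 1 coefficients), `knots`
#'   (log-time scale), `df`, `loglik`.
#' @examples
#' d <- make_fixture(500, control = list(rate = 0.5), seed = 1)
#' m <- fit_rp(d, df = 1)
#' predict(m, times = 1)  # close to exp(-0.5)
#' @export
fit_rp <- function(data, df = 3) {
  time <- data$time; event <- data$event
  ev <- time[event == 1]
  if (length(unique(ev)) < df + 2)
    stop("need at least df + 2 distinct uncensored event times",
         call. = FALSE)
  x <- log(time)
  xev <- log(ev)
  probs <- seq(0, 1, length.out = df + 1)
  knots <- unname(stats::quantile(xev, probs, type = 7))
  if (any(diff(knots) <= 0))
    stop("degenerate knot placement (tied centiles)", call. = FALSE)

  B <- rcs_basis(x, knots)
  Bd <- rcs_basis(x, knots, deriv = TRUE)
  is_ev <- event == 1

  negll <- function(gamma) {
    s <- drop(B %*% gamma)
    sp <- drop(Bd %*% gamma)
    if (any(sp[is_ev] <= 0)) return(1e10)
    -(sum(s[is_ev] + log(sp[is_ev]) - x[is_ev]) - sum(exp(s)))
  }

  ## initial values: regress the log Nelson-Aalen-type cumulative hazard
  ## (from the Kaplan-Meier curve) on the basis at the event times
  km <- km_compute(time, event)
  keep <- km$surv > 0 & km$surv < 1
  if (sum(keep) >= df + 1) {
    Bi <- rcs_basis(log(km$times[keep]), knots)
    init <- stats::lm.fit(Bi, log(-log(km$surv[keep])))$coefficients
    init[!is.finite(init)] <- 0
  } else init <- c(0, rep(0, df))
  if (!is.finite(negll(init))) init <- c(stats::median(log(-log(
    pmax(km$surv, 0.01)))), 1, rep(0, df - 1))

  opt <- stats::optim(init, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-10))
    if (opt2$value < opt$value) opt <- opt2
  }
  gamma <- opt$par
  if (!rp_check_monotone(gamma, knots))
    stop("fitted cumulative hazard is not monotone over the data support",
         call. = FALSE)
  new_rp_model(gamma, knots, df, loglik = -opt$value)
}

#' Fit the censoring distribution
#'
#' Reverses the event indicator and fits the same flexible parametric
#' model to the time-to-censoring distribution. Degenerate patterns are
#' handled explicitly: with no censored observations a `"none"` sentinel is
#' returned; with a single distinct censoring time (pure administrative
#' censoring) a point mass at that time; with too few distinct censoring
#' times for the requested df, the df is reduced.
#'
#' @param data a [survival_data] object.
#' @param df spline degrees of freedom for the censoring model.
#' @return An `rp_model`, or an object of class `censoring_none` /
#'   `censoring_point`.
#' @export
fit_censoring_model <- function(data, df = 3) {
  cens <- data$time[data$event == 0]
  if (!length(cens))
    return(structure(list(), class = "censoring_none"))
  u <- unique(cens)
  if (length(u) == 1L)
    return(structure(list(time = u), class = "censoring_point"))
  df_use <- min(df, length(u) - 2L)
  if (df_use < 1L)
    return(structure(list(time = max(u)), class = "censoring_point"))
  rev <- data.frame(time = data$time, event = 1 - data$event)
  fit_rp(rev, df = df_use)
}

#' Model-implied survival, cumulative hazard and hazard
#'
#' @param object an `rp_model`.
#' @param times positive times at which to evaluate.
#' @param type `"survival"`, `"cumhaz"` or `"hazard"`.
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.rp_model <- function(object, times,
                             type = c("survival", "cumhaz", "hazard"),
                             ...) {
  type <- match.arg(type)
  x <- log(times)
  H <- exp(rp_s(object, x))
  switch(type,
    survival = exp(-H),
    cumhaz = H,
    hazard = H * rp_sprime(object, x) / times)
}

## Inversion sampler on an arbitrary monotone log-cumulative-hazard
## function f(x) (x = log time) with derivative fp. Solves f(x) =
## log(-log U) by vectorised Newton from a monotone-interpolation start,
## with bisection fallback; tolerance 1e-10 on the log-time scale.
sample_from_logH <- function(f, fp, n, xrange) {
  u <- stats::runif(n)
  target <- log(-log(u))
  span <- max(xrange[2] - xrange[1], 1)
  lo <- xrange[1] - 2 * span; hi <- xrange[2] + 2 * span
  ## expand until the bracket covers all targets (f is increasing)
  for (rep in 1:60) {
    ok_lo <- f(lo) < min(target); ok_hi <- f(hi) > max(target)
    if (ok_lo && ok_hi) break
    if (!ok_lo) lo <- lo - span * 2^rep
    if (!ok_hi) hi <- hi + span * 2^rep
    if (rep == 60) stop("root not bracketed after expansion", call. = FALSE)
  }
  xg <- seq(lo, hi, length.out = 512)
  fg <- f(xg)
  if (is.unsorted(fg))
    stop("log cumulative hazard not monotone over the sampling range",
         call. = FALSE)
  x <- stats::approx(fg, xg, xout = target, rule = 2)$y
  for (it in 1:100) {
    gx <- f(x) - target
    step <- gx / pmax(fp(x), 1e-12)
    step <- pmin(pmax(step, -span), span)
    x <- pmin(pmax(x - step, lo), hi)
    if (max(abs(step)) < 1e-12) break
  }
  if (max(abs(f(x) - target)) > 1e-6)
    stop("inversion sampler failed to converge", call. = FALSE)
  exp(x)
}

#' Simulate event times from a fitted model
#'
#' Inversion sampling: solve exp(s(ln t)) = -ln U for U uniform(0, 1).
#' Beyond the boundary knots s is linearly extrapolated (a property of the
#' restricted spline basis).
#'
#' @param model an `rp_model` (or censoring sentinel from
#'   [fit_censoring_model()]).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return Vector of `n` positive times (`Inf` for a `"none"` censoring
#'   sentinel).
#' @export
simulate_survival <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  UseMethod("simulate_survival")
}

#' @export
simulate_survival.rp_model <- function(model, n, seed = NULL) {
  sample_from_logH(function(x) rp_s(model, x),
                   function(x) rp_sprime(model, x),
                   n, range(model$knots))
}

#' @export
simulate_survival.censoring_none <- function(model, n, seed = NULL)
  rep(Inf, n)

#' @export
simulate_survival.censoring_point <- function(model, n, seed = NULL)
  rep(model$time, n)

#' @export
simulate_survival.rp_late <- function(model, n, seed = NULL) {
  f <- function(x) rp_s(model$control, x) + late_logistic(model, x)
  fp <- function(x) rp_sprime(model$control, x) +
    late_logistic_deriv(model, x)
  sample_from_logH(f, fp, n, range(model$control$knots))
}

#' Simulate method for fitted flexible parametric models
#'
#' Standard-generic counterpart of [simulate_survival()].
#'
#' @param object an `rp_model`.
#' @param nsim number of draws.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return Vector of simulated event times.
#' @importFrom stats simulate
#' @export
simulate.rp_model <- function(object, nsim = 1, seed = NULL, ...)
  simulate_survival(object, nsim, seed = seed)

#' Shift a model by a constant log hazard ratio
#'
#' Adds `ln_hr` to the spline intercept, which multiplies the implied
#' cumulative hazard (and hazard) exactly by `exp(ln_hr)` at every time:
#' a proportional-hazards modification of the fitted distribution.
#'
#' @param model an `rp_model`.
#' @param ln_hr log hazard ratio (e.g. `log(0.75)`).
#' @return The shifted `rp_model`.
#' @export
apply_ph_shift <- function(model, ln_hr) {
  stopifnot(inherits(model, "rp_model"))
  model$gamma[1] <- model$gamma[1] + ln_hr
  model
}

## Decreasing logistic perturbation of the log cumulative hazard on the
## log-time scale: c(x) = theta / (1 + exp(-(x - x0)/tau)), theta < 0.
late_logistic <- function(obj, x)
  obj$theta / (1 + exp(-(x - obj$x0) / obj$tau))
late_logistic_deriv <- function(obj, x) {
  z <- exp(-(x - obj$x0) / obj$tau)
  obj$theta / obj$tau * z / (1 + z)^2
}

#' Construct a late-treatment-effect modification of a control model
#'
#' Adds a decreasing logistic function of log time, c(ln t), to the
#' control log cumulative hazard, giving a research arm whose hazard ratio
#' is essentially 1 early in follow-up and falls below 1 later. The hazard
#' ratio function is available analytically:
#' `HR(t) = exp(c(x)) * (1 + c'(x) / s0'(x))` with x = ln t.
#'
#' Default parameters (`theta = -0.6`, `t0_log = 1.5`, `tau = 0.25`) were
#' calibrated once against the shipped control models so that
#' |HR(t) - 1| < 0.02 for t in (0, 1\] and HR(t) < 1 thereafter.
#'
#' @param control an `rp_model` for the control arm.
#' @param theta asymptote of the perturbation (negative for a beneficial
#'   late effect).
#' @param t0_log centre of the logistic on the log-time scale.
#' @param tau scale of the logistic (log-time units).
#' @param check_range time range over which positivity of the hazard is
#'   verified.
#' @return Object of class `rp_late` with an `hr_function(t)` closure.
#' @export
apply_late_effect <- function(control, theta = -0.6, t0_log = 1.5,
                              tau = 0.25, check_range = c(0.01, 50)) {
  stopifnot(inherits(control, "rp_model"))
  obj <- structure(list(control = control, theta = theta, x0 = t0_log,
                        tau = tau),
                   class = "rp_late")
  ts <- exp(seq(log(check_range[1]), log(check_range[2]),
                length.out = 400))
  hr <- hr_function(obj, ts)
  if (any(hr <= 0))
    stop("perturbation produces nonpositive hazard, first at t = ",
         format(ts[which(hr <= 0)[1]]), call. = FALSE)
  obj
}

#' Hazard ratio function of a scenario model
#'
#' @param model an `rp_late` object (or an `rp_model` pair via
#'   [hr_between()]).
#' @param times evaluation times.
#' @return HR(times), research relative to control.
#' @export
hr_function <- function(model, times) {
  stopifnot(inherits(model, "rp_late"))
  x <- log(times)
  cc <- late_logistic(model, x)
  cp <- late_logistic_deriv(model, x)
  sp <- rp_sprime(model$control, x)
  exp(cc) * (1 + cp / sp)
}

#' Hazard ratio between two fitted models
#'
#' @param research,control `rp_model` objects.
#' @param times evaluation times.
#' @return `hazard_research(times) / hazard_control(times)`.
#' @export
hr_between <- function(research, control, times)
  predict(research, times, type = "hazard") /
  predict(control, times, type = "hazard")

#' Serialize a model to JSON (and back)
#'
#' @param model an `rp_model`.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
rp_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "rp_model"))
  js <- jsonlite::toJSON(list(gamma = model$gamma, knots = model$knots,
                              df = model$df),
                         digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname rp_to_json
#' @param json JSON string or file path to read.
#' @export
rp_from_json <- function(json) {
  src <- if (file.exists(json[1])) paste(readLines(json), collapse = "")
         else json
  obj <- jsonlite::fromJSON(src)
  new_rp_model(obj$gamma, obj$knots, obj$df)
}
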