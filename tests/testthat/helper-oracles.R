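## Independent oracles used across test files. These deliberately avoid the
## package's own code paths (and the survival package where the package
## itself relies on it), so that agreement is a genuine cross-check.

## Hand-rolled product-limit curve by explicit risk-set enumeration.
oracle_km <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  surv <- numeric(length(dt))
  s <- 1
  for (i in seq_along(dt)) {
    n_i <- sum(time >= dt[i])
    d_i <- sum(time == dt[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(times = dt, surv = surv)
}

## Area under a KM step function on (0, tstar) by direct rectangle
## summation on the step intervals.
oracle_rmst_area <- function(time, event, tstar) {
  km <- oracle_km(time, event)
  edges <- c(0, km$times[km$times < tstar], tstar)
  vals <- c(1, km$surv[km$times < tstar])
  sum(vals * diff(edges))
}

## Log partial likelihood for the one-covariate (binary arm) Cox model
## with Breslow ties, written out from the definition.
oracle_cox_loglik <- function(beta, time, event, arm) {
  dt <- sort(unique(time[event == 1]))
  ll <- 0
  for (tk in dt) {
    dead <- which(time == tk & event == 1)
    risk <- which(time >= tk)
    ll <- ll + beta * sum(arm[dead]) -
      length(dead) * log(sum(exp(beta * arm[risk])))
  }
  ll
}

## Cox score statistic at beta = 0 (equals the logrank chisquare under
## Breslow ties): U^2 / V with hypergeometric-style moments.
oracle_cox_score <- function(time, event, arm) {
  dt <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (tk in dt) {
    dead <- which(time == tk & event == 1)
    risk <- which(time >= tk)
    d <- length(dead)
    p <- mean(arm[risk])
    U <- U + sum(arm[dead]) - d * p
    V <- V + d * p * (1 - p)
  }
  U^2 / V
}

## Small deterministic two-arm datasets (with censoring and ties) used as
## a fixture battery for exact cross-checks.
fixture_battery <- function() {
  list(
    survival_data(c(1, 3, 2, 4), c(1, 1, 1, 1), c(0, 0, 1, 1)),
    survival_data(c(1, 2, 2, 3, 5, 5, 6, 7), c(1, 0, 1, 1, 1, 1, 0, 1),
                  c(0, 0, 1, 0, 1, 1, 0, 1)),
    make_fixture(30, effect = "null", horizon = 2, seed = 101),
    make_fixture(40, effect = "ph", hr = 0.5, horizon = 3, accrual = 1,
                 seed = 102),
    make_fixture(25, family = "weibull",
                 control = list(shape = 1.3, scale = 2),
                 effect = "ph", hr = 0.7, horizon = 4, seed = 103),
    ## heavy ties: discretised times
    {
      d <- make_fixture(50, effect = "ph", hr = 0.6, horizon = 3,
                        seed = 104)
      survival_data(ceiling(d$time * 4) / 4, d$event, d$arm)
    })
}
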