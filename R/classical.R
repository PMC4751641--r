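## Classical two-sample tests: logrank, Cox partial-likelihood-ratio,
## scaled Schoenfeld residuals, Grambsch-Therneau, and the joint test.
## All model fitting goes through the survival package; this file only
## shapes inputs and outputs.

#' Two-sample logrank test
#'
#' Logrank chisquare (1 df): at each distinct event time the observed
#' number of research-arm events is compared with its risk-set
#' expectation, with variance `d p (1 - p)` where `p` is the research-arm
#' share of the risk set. This is the score-test form of the Cox partial
#' likelihood under the Breslow tie convention, so the statistic equals
#' the Cox score chisquare exactly, ties included; with untied event
#' times it also coincides with the classical hypergeometric-variance
#' logrank statistic (the two differ only by the finite-sample factor
#' `(n - d)/(n - 1)` at tied event times).
#'
#' @param data a [survival_data] object.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(data) {
  data <- as_survival_data(data)
  check_two_arm(data)
  dt <- sort(unique(data$time[data$event == 1]))
  st <- sort(data$time)
  n <- length(st)
  U <- 0; V <- 0
  for (tk in dt) {
    risk <- data$time >= tk
    dead <- data$time == tk & data$event == 1
    p <- mean(data$arm[risk])
    U <- U + sum(data$arm[dead]) - sum(dead) * p
    V <- V + sum(dead) * p * (1 - p)
  }
  chi2 <- U^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit for the treatment arm
#'
#' One-covariate Cox model with the binary arm indicator, reporting the
#' partial-likelihood-ratio test. Breslow tie handling is the default so
#' that the score test equals the logrank chisquare exactly.
#'
#' @param data a [survival_data] object.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Object of class `cox_result`: list with `beta` (log hazard
#'   ratio), `se`, `hr`, `chi2_plr`, `p_cox`, `chi2_score`, `ties`,
#'   `converged`, and `fit` (the underlying `coxph` object).
#' @examples
#' d <- make_fixture(200, effect = "ph", hr = 0.6, horizon = 3, seed = 1)
#' cox_fit(d)
#' @export
cox_fit <- function(data, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  data <- as_survival_data(data)
  check_two_arm(data)
  if (any(tapply(data$event, data$arm, sum) == 0))
    stop("each arm needs at least one event", call. = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ arm, data = data,
                         ties = ties,
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 50))
  beta <- unname(stats::coef(fit))
  if (!is.finite(beta) || abs(beta) > 15)
    stop("monotone partial likelihood: events fully separated by arm",
         call. = FALSE)
  chi2_plr <- 2 * (fit$loglik[2] - fit$loglik[1])
  structure(list(beta = beta,
                 se = sqrt(unname(fit$var[1, 1])),
                 hr = exp(beta),
                 chi2_plr = chi2_plr,
                 p_cox = stats::pchisq(chi2_plr, df = 1, lower.tail = FALSE),
                 chi2_score = unname(fit$score),
                 ties = ties,
                 converged = fit$iter < 50,
                 fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox fit (ties = %s): HR = %.4f (beta = %.4f, SE %.4f)\n",
              x$ties, x$hr, x$beta, x$se))
  cat(sprintf("partial-likelihood-ratio chi2(1) = %.4f, P = %.4g\n",
              x$chi2_plr, x$p_cox))
  invisible(x)
}

#' Scaled Schoenfeld residuals for the treatment arm
#'
#' One residual per event, on the log-hazard-ratio scale: the estimated
#' coefficient plus (number of events) times the inverse information times
#' the raw Schoenfeld residual (observed arm minus risk-set expectation at
#' the event time). Trends of these residuals against time indicate
#' non-proportional hazards.
#'
#' @param fit a `cox_result` from [cox_fit()].
#' @param data the [survival_data] the model was fitted to.
#' @return Data frame with columns `time` (event times, ascending) and
#'   `scaled_residual`.
#' @export
schoenfeld_scaled_residuals <- function(fit, data) {
  stopifnot(inherits(fit, "cox_result"))
  data <- as_survival_data(data)
  if (sum(data$event) < 2)
    stop("at least 2 events are required", call. = FALSE)
  ## survival returns the residuals in event-time order with the
  ## coefficient already added (beta + d * I^{-1} * raw)
  r <- stats::resid(fit$fit, type = "scaledsch")
  data.frame(time = sort(data$time[data$event == 1]),
             scaled_residual = as.numeric(r))
}

#' Grambsch-Therneau test of proportional hazards
#'
#' Score test (1 df) of zero slope in the regression of the scaled
#' Schoenfeld residuals on transformed event time. The default transform is
#' untransformed (identity) time; `"rank"` and `"km"` are available. A
#' significant result indicates a time-dependent hazard ratio.
#'
#' @param fit a `cox_result` from [cox_fit()].
#' @param data the fitted [survival_data].
#' @param transform `"identity"`, `"rank"` or `"km"`.
#' @return Object of class `gt_result`: list with `chi2_gt`, `p_gt`,
#'   `transform`.
#' @export
grambsch_therneau <- function(fit, data,
                              transform = c("identity", "rank", "km")) {
  transform <- match.arg(transform)
  stopifnot(inherits(fit, "cox_result"))
  data <- as_survival_data(data)
  if (sum(data$event) < 2)
    stop("at least 2 events are required", call. = FALSE)
  if (length(unique(data$time[data$event == 1])) < 2)
    stop("all events at a single time: transform has zero variance",
         call. = FALSE)
  zp <- survival::cox.zph(fit$fit, transform = transform, global = FALSE)
  chi2 <- unname(zp$table[1, "chisq"])
  structure(list(chi2_gt = chi2,
                 p_gt = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 transform = transform),
            class = "gt_result")
}

#' @export
print.gt_result <- function(x, ...) {
  cat(sprintf("Grambsch-Therneau test (%s time): chi2(1) = %.4f, P = %.4g\n",
              x$transform, x$chi2_gt, x$p_gt))
  invisible(x)
}

#' Joint test of treatment effect and non-proportionality
#'
#' Sums the Cox partial-likelihood-ratio chisquare and the
#' Grambsch-Therneau chisquare and refers the total to chisquare with 2 df
#' (`p = exp(-chi2/2)`). Responds to either a shift in overall hazard or a
#' time-dependent effect, at the cost of power under exact proportional
#' hazards.
#'
#' @param cox a `cox_result`.
#' @param gt a `gt_result`.
#' @return List with `chi2_joint` and `p_joint`.
#' @export
joint_test <- function(cox, gt) {
  stopifnot(inherits(cox, "cox_result"), inherits(gt, "gt_result"))
  chi2 <- cox$chi2_plr + gt$chi2_gt
  list(chi2_joint = chi2,
       p_joint = stats::pchisq(chi2, df = 2, lower.tail = FALSE))
}
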