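## Trial-simulation scenarios. Four canonical treatment-effect patterns:
##   A  global null (one pooled model, random 1:1 split)
##   B  proportional hazards, default HR = 0.75 (intercept shift)
##   C  early effect (independent research-arm model whose hazard starts
##      near half the control hazard and rises above it later)
##   D  late effect (decreasing logistic perturbation of the control log
##      cumulative hazard on log time; HR = 1 up to ~1 year, < 1 after)

## Canned control distribution: Weibull-type, shape 1.2, median ~2.9
## (years), expressed exactly as a df = 1 spline on the log cumulative
## hazard. Realistic for an advanced-cancer overall-survival endpoint.
canned_control_model <- function()
  new_rp_model(gamma = c(-1.2 * log(4), 1.2),
               knots = log(c(0.25, 12)), df = 1,
               note = "canned control: Weibull shape 1.2, scale 4")

## Canned early-effect research arm: df = 3 spline calibrated by least
## squares to a piecewise pattern (hazard 0.5x control before the control
## median ~2.95, 1.2x after), smoothed by the spline. Synthetic stand-in
## for a trial-fitted model.
canned_early_model <- function()
  new_rp_model(gamma = c(-2.4496854646, 1.1525304765,
                         -0.1208245574, 0.1056773225),
               knots = log(c(0.3, 1.8, 4.5, 15)), df = 3,
               note = "canned early effect (synthetic calibration)")

#' Scenario specification for trial simulation
#'
#' Bundles everything [scenario_generate()] needs: the scenario letter, the
#' control-arm model, the research-arm modification, the censoring
#' mechanism and the sample size.
#'
#' @param scenario `"A"` (global null), `"B"` (proportional hazards),
#'   `"C"` (early effect), `"D"` (late effect).
#' @param n total sample size (must be even; split 1:1).
#' @param control control-arm `rp_model`; default: the canned
#'   Weibull-type control model described in Details.
#' @param ln_hr log hazard ratio for scenario B (default `log(0.75)`).
#' @param research research-arm `rp_model` for scenario C; default the
#'   canned early-effect model.
#' @param late parameter list `list(theta, t0_log, tau)` for scenario D;
#'   defaults as in [apply_late_effect()].
#' @param censoring `NULL` (none), a list `list(accrual = A, total = T)`
#'   for uniform staggered entry over A with administrative close-out at
#'   total duration T (censoring time uniform on (T - A, T)), or any model
#'   accepted by [simulate_survival()].
#' @param seed integer seed.
#' @return Object of class `scenario_spec`.
#' @examples
#' sp <- scenario_spec("B", n = 400, censoring = list(accrual = 4, total = 6))
#' d <- scenario_generate(sp, seed = 1)
#' @export
scenario_spec <- function(scenario = c("A", "B", "C", "D"), n = 500,
                          control = NULL, ln_hr = log(0.75),
                          research = NULL, late = list(),
                          censoring = list(accrual = 5, total = 8),
                          seed = NULL) {
  scenario <- match.arg(scenario)
  if (n < 4 || n %% 2 != 0)
    stop("n must be an even integer >= 4", call. = FALSE)
  if (is.null(control)) control <- canned_control_model()
  if (scenario == "C" && is.null(research))
    research <- canned_early_model()
  structure(list(scenario = scenario, n = n, control = control,
                 ln_hr = ln_hr, research = research, late = late,
                 censoring = censoring, seed = seed),
            class = "scenario_spec")
}

draw_censoring <- function(censoring, n) {
  if (is.null(censoring)) return(rep(Inf, n))
  if (is.list(censoring) && !is.null(censoring$total)) {
    A <- censoring$accrual %||% 0
    TT <- censoring$total
    if (A > 0) stats::runif(n, TT - A, TT) else rep(TT, n)
  } else {
    simulate_survival(censoring, n)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a simulated trial dataset under a scenario
#'
#' Scenario A draws the full sample from the control model and assigns
#' arms by a random 1:1 split; B draws the research arm from the control
#' model shifted by `ln_hr` on the log cumulative hazard; C draws the two
#' arms from independent models; D draws the research arm from the
#' late-effect construction ([apply_late_effect()]). Censoring times are
#' drawn independently from the censoring mechanism and applied as
#' `time = min(event, censoring)`.
#'
#' @param spec a [scenario_spec()].
#' @param seed overrides `spec$seed` when non-NULL.
#' @return A [survival_data] object with `spec$n` rows.
#' @export
scenario_generate <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n; n2 <- n / 2

  if (spec$scenario == "A") {
    tev <- simulate_survival(spec$control, n)
    arm <- sample(rep(c(0, 1), each = n2))
  } else {
    research_model <- switch(spec$scenario,
      B = apply_ph_shift(spec$control, spec$ln_hr),
      C = spec$research,
      D = do.call(apply_late_effect,
                  c(list(control = spec$control), spec$late)))
    t0 <- simulate_survival(spec$control, n2)
    t1 <- simulate_survival(research_model, n2)
    tev <- c(t0, t1)
    arm <- rep(c(0, 1), each = n2)
  }
  cens <- draw_censoring(spec$censoring, n)
  survival_data(pmin(tev, cens), as.numeric(tev <= cens), arm)
}
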