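## The combined test: analytic approximation to the permutation P-value of
## the maximal RMST chisquare, and the incomplete-beta correction of the
## minimum of the Cox and permutation P-values.

## Calibration constants. The Box-Tidwell coefficients map P_max (the
## uncorrected 1-df tail probability of C_max) to the expected permutation
## P-value; the curve is truncated at P_max = 0.85 where it plateaus at
## 0.9963 (the published plateau is kept verbatim although re-evaluating
## the rounded coefficients at 0.85 gives 0.9958). The Beta(1, b) null for
## P_min uses b = 1.5: the two component P-values are positively
## correlated, so the correction undercuts the Bonferroni factor b = 2.
.pperm_cal <- list(c1 = 1.762, p1 = 0.885, c2 = 0.802, p2 = 2.547,
                   trunc_at = 0.85, plateau = 0.9963)
.beta_b_default <- 1.5

#' Calibration constants of the combined test
#'
#' Returns the fixed constants used by [approx_pperm()] and
#' [combine_pvalues()]: the two-term power-law (Box-Tidwell) coefficients
#' of the permutation-P approximation, its truncation point and plateau,
#' and the Beta(1, b) parameter of the minimum-P correction.
#'
#' @return Named list of constants.
#' @export
calibration_constants <- function() {
  c(.pperm_cal, list(a = 1, b = .beta_b_default))
}

#' Approximate the permutation P-value from P_max
#'
#' Analytic stand-in for the permutation test of the maximal RMST
#' chisquare: `1.762 * P_max^0.885 - 0.802 * P_max^2.547` for
#' `P_max <= 0.85`, and the plateau 0.9963 beyond. The output is clamped to
#' \[0, 1\]. Deterministic, unlike the permutation estimate, and accurate
#' across the practical range; the exact permutation version
#' ([permutation_null()]) remains available as a check near decision
#' cutoffs.
#'
#' @param p_max uncorrected 1-df upper-tail probability of `C_max`
#'   (vectorised).
#' @return Approximate permutation P-value(s) in \[0, 1\].
#' @examples
#' approx_pperm(c(0, 0.01, 0.9))
#' @export
approx_pperm <- function(p_max) {
  if (any(!is.finite(p_max)) || any(p_max < 0) || any(p_max > 1))
    stop("p_max must lie in [0, 1]", call. = FALSE)
  k <- .pperm_cal
  out <- ifelse(p_max > k$trunc_at, k$plateau,
                k$c1 * p_max^k$p1 - k$c2 * p_max^k$p2)
  pmin(pmax(out, 0), 1)
}

#' Correct the minimum of the Cox and permutation P-values
#'
#' The smaller of the two component P-values is referred to its Beta(1, b)
#' null distribution with b = 1.5, giving the closed form
#' `p_comb = 1 - (1 - p_min)^1.5` (the regularized incomplete beta
#' function I(p_min; 1, 1.5)). For small `p_min` this is approximately
#' `1.5 * p_min`.
#'
#' @param p_cox Cox partial-likelihood-ratio P-value in \[0, 1\].
#' @param p_perm (approximate) permutation P-value in \[0, 1\].
#' @param b beta parameter; default 1.5.
#' @return List with `p_cox`, `p_perm`, `p_min`, `p_comb`, `b`.
#' @examples
#' combine_pvalues(0.052, 0.01)
#' @export
combine_pvalues <- function(p_cox, p_perm, b = .beta_b_default) {
  for (p in c(p_cox, p_perm))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("P-values must lie in [0, 1]", call. = FALSE)
  p_min <- min(p_cox, p_perm)
  list(p_cox = p_cox, p_perm = p_perm, p_min = p_min,
       p_comb = 1 - (1 - p_min)^b, b = b)
}

#' Significance threshold for P_min at a nominal combined-test level
#'
#' Inverts the Beta(1, 1.5) correction: the value x with
#' `1 - (1 - x)^1.5 = alpha`, i.e. `x = 1 - (1 - alpha)^(1/1.5)`. A
#' combined test at two-sided level alpha rejects when
#' `min(p_cox, p_perm) <= pmin_threshold(alpha)`; at alpha = 0.05 the
#' threshold is 0.0336. This is also the significance level at which to
#' power the logrank/Cox test when designing a trial for the combined test
#' (see [combined_design()]).
#'
#' @param alpha nominal two-sided level in (0, 1).
#' @param b beta parameter; default 1.5.
#' @return The equivalent threshold on `p_min`.
#' @examples
#' pmin_threshold(0.05)  # 0.0336
#' @export
pmin_threshold <- function(alpha, b = .beta_b_default) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1))
    stop("alpha must lie in (0, 1)", call. = FALSE)
  1 - (1 - alpha)^(1 / b)
}

#' Estimate the Beta(1, b) parameter from a null sample of P_min
#'
#' Constrained maximum likelihood for the Beta(1, b) family:
#' `b = -n / sum(log(1 - x))`. Intended for users recalibrating the
#' minimum-P correction against their own null simulations; the shipped
#' default b = 1.5 is not altered by this function.
#'
#' @param pmin_samples numeric vector of null P_min values, all in (0, 1).
#' @param min_n minimum sample size accepted (default 10).
#' @return The maximum-likelihood estimate of b.
#' @examples
#' set.seed(1)
#' x <- pmin(runif(1e4), runif(1e4))  # independent pair: b near 2
#' estimate_beta_b(x)
#' @export
estimate_beta_b <- function(pmin_samples, min_n = 10) {
  x <- pmin_samples
  if (length(x) < min_n)
    stop("need at least ", min_n, " samples", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop("samples must lie strictly inside (0, 1)", call. = FALSE)
  -length(x) / sum(log1p(-x))
}
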