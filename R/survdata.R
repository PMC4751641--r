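#' Construct and validate subject-level survival data
#'
#' A `survival_data` object is a data frame with columns `time` (positive
#' event or censoring time), `event` (1 = event observed, 0 = censored) and
#' `arm` (0 = control, 1 = research). All functions in the package take this
#' container as input. Times are used on whatever scale the caller supplies
#' (typically years); the package never rescales them.
#'
#' @param time numeric vector of strictly positive, finite follow-up times.
#' @param event integer/numeric vector of 0/1 event indicators.
#' @param arm integer/numeric vector of 0/1 treatment labels.
#' @return A data frame of class `c("survival_data", "data.frame")`.
#' @examples
#' d <- survival_data(time = c(1, 2, 3.5), event = c(1, 0, 1), arm = c(0, 1, 1))
#' nrow(d)
#' @export
survival_data <- function(time, event, arm) {
  d <- data.frame(time = as.numeric(time), event = as.numeric(event),
                  arm = as.numeric(arm))
  validate_survival_data(d)
}

#' @rdname survival_data
#' @param x a data frame with columns `time`, `event`, `arm`.
#' @export
as_survival_data <- function(x) {
  need <- c("time", "event", "arm")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  survival_data(x$time, x$event, x$arm)
}

validate_survival_data <- function(d) {
  bad <- which(!is.finite(d$time) | d$time <= 0)
  if (length(bad))
    stop("nonpositive or non-finite time at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!(d$event %in% c(0, 1)))
  if (length(bad))
    stop("event indicator not in {0,1} at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!(d$arm %in% c(0, 1)))
  if (length(bad))
    stop("arm label not in {0,1} at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  class(d) <- c("survival_data", "data.frame")
  d
}

## Guard used by the two-sample test operations: both arms represented and
## at least two events pooled.
check_two_arm <- function(d) {
  if (length(unique(d$arm)) < 2L)
    stop("both arms must be present", call. = FALSE)
  if (sum(d$event) < 2)
    stop("at least 2 pooled events are required", call. = FALSE)
  invisible(d)
}

#' Read subject-level survival data from a delimited text file
#'
#' Reads a comma- or tab-delimited file with a header row and returns a
#' validated [survival_data] object. Column names other than the default
#' `time`, `event`, `arm` can be remapped via `columns`. Row order is
#' preserved.
#'
#' @param path path to the file.
#' @param columns named character vector mapping the canonical names
#'   `time`, `event`, `arm` to the column names used in the file.
#' @param sep field separator; `""` (default) auto-detects comma vs tab from
#'   the header line.
#' @return A [survival_data] object.
#' @seealso [write_survival()]
#' @export
read_survival <- function(path,
                          columns = c(time = "time", event = "event", arm = "arm"),
                          sep = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (identical(sep, "")) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- columns[c("time", "event", "arm")]
  miss <- need[!(need %in% names(raw))]
  if (length(miss))
    stop("column(s) not found in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  survival_data(raw[[need[["time"]]]], raw[[need[["event"]]]],
                raw[[need[["arm"]]]])
}

#' Write subject-level survival data to a delimited text file
#'
#' Writes one subject per line with a header row; `read_survival()` on the
#' result recovers the records exactly (round-trip identity). Tied times are
#' written verbatim.
#'
#' @param data a [survival_data] object (or coercible data frame).
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_survival <- function(data, path, sep = ",") {
  data <- as_survival_data(data)
  utils::write.table(data[, c("time", "event", "arm")], file = path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate parametric two-arm survival fixtures
#'
#' Draws event times per arm from a named parametric family and applies
#' administrative and/or staggered-entry censoring. The generator covers the
#' qualitative effect patterns relevant for testing two-sample survival
#' procedures: a global null, proportional hazards, and early/late
#' treatment effects via a piecewise-exponential hazard in the research arm.
#'
#' Censoring: with an `accrual` window A and total study duration `horizon`
#' T, entry is uniform on (0, A) and a subject is administratively censored
#' at T minus their entry time (uniform recruitment, common calendar
#' close-out). With `accrual = 0`, censoring occurs at the fixed time
#' `horizon`. `horizon = Inf` disables censoring.
#'
#' @param n_per_arm subjects per arm (>= 2).
#' @param family `"exponential"`, `"weibull"` or `"piecewise-exponential"`.
#' @param control parameter list for the control arm:
#'   exponential `list(rate=)`; weibull `list(shape=, scale=)`;
#'   piecewise-exponential `list(rates=, breaks=)` with `length(rates) ==
#'   length(breaks) + 1`.
#' @param effect effect pattern: `"null"` (research arm identical to
#'   control), `"ph"` (hazard multiplied by `hr`), `"early"` (hazard ratio
#'   `hr_early` before `changepoint`, `hr_late` after), or `"late"`
#'   (`hr = 1` before `changepoint`, `hr_late` after).
#' @param hr hazard ratio for `effect = "ph"`.
#' @param hr_early,hr_late,changepoint piecewise hazard-ratio pattern for
#'   the `"early"`/`"late"` effects.
#' @param horizon total study duration for administrative censoring
#'   (default `Inf`, no censoring).
#' @param accrual accrual window length (staggered entry); 0 means
#'   simultaneous entry.
#' @param seed integer seed; fixed seed gives identical output.
#' @return A [survival_data] object with `2 * n_per_arm` rows.
#' @examples
#' d <- make_fixture(100, effect = "ph", hr = 0.5, horizon = 3, seed = 1)
#' table(d$arm, d$event)
#' @export
make_fixture <- function(n_per_arm,
                         family = c("exponential", "weibull",
                                    "piecewise-exponential"),
                         control = list(rate = 1),
                         effect = c("null", "ph", "early", "late"),
                         hr = 0.75,
                         hr_early = 0.5, hr_late = 1.1, changepoint = NULL,
                         horizon = Inf, accrual = 0, seed = NULL) {
  family <- match.arg(family)
  effect <- match.arg(effect)
  if (n_per_arm < 2) stop("n_per_arm must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  base <- fixture_hazard_spec(family, control)
  ## research-arm hazard as a multiple of the control hazard
  mult <- switch(effect,
    null  = NULL,
    ph    = list(ratios = hr, breaks = numeric(0)),
    early = {
      cp <- if (is.null(changepoint)) fixture_median(base) else changepoint
      list(ratios = c(hr_early, hr_late), breaks = cp)
    },
    late  = {
      cp <- if (is.null(changepoint)) fixture_median(base) else changepoint
      list(ratios = c(1, hr_late), breaks = cp)
    })

  t0 <- fixture_draw(base, n_per_arm)
  t1 <- if (is.null(mult)) fixture_draw(base, n_per_arm)
        else fixture_draw(fixture_multiply(base, mult), n_per_arm)
  tev <- c(t0, t1)
  arm <- rep(c(0, 1), each = n_per_arm)

  if (is.finite(horizon)) {
    entry <- if (accrual > 0) stats::runif(2 * n_per_arm, 0, accrual) else 0
    cens <- pmax(horizon - entry, .Machine$double.eps)
    event <- as.numeric(tev <= cens)
    time <- pmin(tev, cens)
  } else {
    event <- rep(1, 2 * n_per_arm)
    time <- tev
  }
  survival_data(time, event, arm)
}

## Internal canonical form for fixture hazards: piecewise-constant hazard
## with cut points `breaks` and rates `rates` (length(breaks) + 1), except
## weibull which is kept parametric.
fixture_hazard_spec <- function(family, control) {
  switch(family,
    exponential = {
      rate <- control$rate
      if (is.null(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
      list(kind = "pexp", rates = rate, breaks = numeric(0))
    },
    weibull = {
      if (is.null(control$shape) || is.null(control$scale) ||
          control$shape <= 0 || control$scale <= 0)
        stop("weibull needs positive shape and scale", call. = FALSE)
      list(kind = "weibull", shape = control$shape, scale = control$scale)
    },
    `piecewise-exponential` = {
      rates <- control$rates; breaks <- control$breaks
      if (is.null(rates) || any(rates <= 0))
        stop("rates must be > 0", call. = FALSE)
      if (length(rates) != length(breaks) + 1L)
        stop("need length(rates) == length(breaks) + 1", call. = FALSE)
      if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0))
        stop("breaks must be positive and increasing", call. = FALSE)
      list(kind = "pexp", rates = rates, breaks = breaks)
    })
}

fixture_median <- function(spec) {
  if (spec$kind == "weibull")
    return(stats::qweibull(0.5, spec$shape, spec$scale))
  qpexp(0.5, spec$rates, spec$breaks)
}

## Multiply a hazard spec by a piecewise-constant ratio function.
fixture_multiply <- function(spec, mult) {
  if (spec$kind == "weibull") {
    ## weibull hazard times a piecewise ratio -> handled by thinning on the
    ## cumulative-hazard scale below; represent as generic list
    return(list(kind = "weibull_mult", base = spec, ratios = mult$ratios,
                mbreaks = mult$breaks))
  }
  breaks <- sort(unique(c(spec$breaks, mult$breaks)))
  ## piecewise rate lookup at interval midpoints
  mids <- if (length(breaks))
    (c(0, breaks) + c(breaks, breaks[length(breaks)] + 2)) / 2
  else 1
  rate_at <- function(t, rates, brk)
    rates[findInterval(t, brk) + 1L]
  list(kind = "pexp",
       rates = rate_at(mids, spec$rates, spec$breaks) *
               rate_at(mids, mult$ratios, mult$breaks),
       breaks = breaks)
}

fixture_draw <- function(spec, n) {
  switch(spec$kind,
    weibull = stats::rweibull(n, spec$shape, spec$scale),
    pexp = qpexp(stats::runif(n), spec$rates, spec$breaks),
    weibull_mult = {
      ## inversion on the cumulative hazard: H(t) = sum over pieces of
      ## ratio_k * [H0 capped at piece] with H0 weibull
      u <- stats::runif(n)
      H0 <- function(t) (t / spec$base$scale)^spec$base$shape
      brk <- spec$mbreaks; r <- spec$ratios
      Ht <- function(t) {
        edges <- c(0, brk, Inf)
        tot <- 0
        for (k in seq_along(r)) {
          lo <- edges[k]; hi <- edges[k + 1]
          tot <- tot + r[k] * (H0(pmin(pmax(t, lo), hi)) - H0(lo))
        }
        tot
      }
      vapply(-log(u), function(target)
        stats::uniroot(function(t) Ht(t) - target,
                       lower = 1e-12, upper = 1e12, tol = 1e-12)$root,
        numeric(1))
    })
}

## Piecewise-exponential quantile function (inversion of the cumulative
## hazard), vectorised in p.
qpexp <- function(p, rates, breaks) {
  target <- -log(1 - p)
  if (!length(breaks)) return(target / rates)
  edges <- c(0, breaks)
  seg <- diff(c(edges, Inf))
  cumH <- c(0, cumsum(rates[-length(rates)] * diff(edges)))
  Hend <- c(cumH[-1], Inf)
  idx <- findInterval(target, c(0, Hend), rightmost.closed = FALSE)
  idx[idx > length(rates)] <- length(rates)
  edges[idx] + (target - cumH[idx]) / rates[idx]
}
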