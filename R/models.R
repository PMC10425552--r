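#' Evaluate the quadratic cumulative intake curve
#'
#' Returns predicted cumulative intake `E(t) = a*t^2 + b*t + c` at the given
#' meal times. Values are returned unclamped: predictions that are negative
#' or decreasing are data for downstream feasibility classification
#' (see [classify_feasibility()]), not errors.
#'
#' @param params a [quadratic_params()] object
#' @param t vector of meal times (minutes), all >= 0
#' @return numeric vector of predicted cumulative intake (g)
#' @export
#' @examples
#' quadratic_intake(quadratic_params(-0.5, 20, 0), t = 10)  # 150
quadratic_intake <- function(params, t) {
  stopifnot(inherits(params, "quadratic_params"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  params$a * t^2 + params$b * t + params$c
}

#' Invert the quadratic cumulative intake curve
#'
#' Solves `a*t^2 + b*t + c = e` for the meal time at which cumulative intake
#' `e` is reached, selecting the root on the increasing branch of the
#' parabola (pre-vertex for `a < 0`): intake must be locally increasing at
#' each bite. Inversions with no real root (intake beyond the curve maximum)
#' or a negative selected root return `NA`, the non-feasible marker, rather
#' than throwing, so that downstream error metrics can count them.
#'
#' @param params a [quadratic_params()] object
#' @param e vector of cumulative intake values (g), all >= 0
#' @return numeric vector of predicted bite times (min), `NA` where the
#'   inversion is non-feasible
#' @export
#' @examples
#' p <- quadratic_params(-0.5, 20, 0)
#' quadratic_time(p, 150)   # 10
#' quadratic_time(p, 300)   # NA: beyond the curve maximum of 200 g
quadratic_time <- function(params, e) {
  stopifnot(inherits(params, "quadratic_params"))
  e <- as.numeric(e)
  if (any(!is.finite(e)) || any(e < 0))
    stop("e must be finite and >= 0", call. = FALSE)
  a <- params$a; b <- params$b; c <- params$c
  if (a == 0) {
    if (b == 0)
      stop("degenerate quadratic model: a == 0 and b == 0", call. = FALSE)
    t <- (e - c) / b
  } else {
    disc <- b^2 - 4 * a * (c - e)
    t <- rep(NA_real_, length(e))
    ok <- disc >= 0
    # (-b + sqrt(disc)) / (2a) is the increasing-branch root for either sign
    # of a: pre-vertex for a < 0, post-vertex for a > 0.
    t[ok] <- (-b + sqrt(disc[ok])) / (2 * a)
  }
  t[!is.na(t) & t < 0] <- NA_real_
  t
}

#' Rate constant of the LODE model
#'
#' The LODE cumulative intake curve takes a form similar to exponential
#' decay with rate constant `k = (emax*r + theta)/emax = r + theta/emax`.
#' `k` reduces to `r` as `theta` tends to 0, and to `theta/emax` as the
#' doubling rate tends to 0.
#'
#' @param params a [lode_params()] object
#' @return the rate constant `k` (1/min)
#' @export
#' @examples
#' lode_k(lode_params(10, 0.3, 300))  # 1/3
lode_k <- function(params) {
  stopifnot(inherits(params, "lode_params"))
  params$r + params$theta / params$emax
}

#' Evaluate the LODE cumulative intake curve
#'
#' Closed-form solution of `dE/dt = (theta + r*E) * (1 - E/emax)` with
#' `E(0) = 0`:
#' `E(t) = (exp(k*t) - 1) / (exp(k*t)/emax + r/theta)` with `k` from
#' [lode_k()]. Evaluated in the factored form
#' `(1 - exp(-k*t)) / (1/emax + (r/theta)*exp(-k*t))` so that large `k*t`
#' approaches the asymptote `emax` without overflow.
#'
#' @param params a [lode_params()] object
#' @param t vector of meal times (minutes), all >= 0
#' @return numeric vector of predicted cumulative intake (g), strictly
#'   increasing in `t` and bounded above by `emax`
#' @export
#' @examples
#' lode_intake(lode_params(10, 0.3, 300), t = 5)  # about 90.1 g
lode_intake <- function(params, t) {
  stopifnot(inherits(params, "lode_params"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  k <- lode_k(params)
  ekt <- exp(-k * t)
  (1 - ekt) / (1 / params$emax + (params$r / params$theta) * ekt)
}

#' Invert the LODE cumulative intake curve
#'
#' Exact inverse of [lode_intake()]:
#' `t(e) = (1/k) * log((1 + e*r/theta) / (1 - e/emax))`.
#'
#' The asymptote is approached but never attained, so the boundary value
#' `e == emax` maps to `Inf`: a right-censored "asymptote" prediction that
#' is positive and increasing (hence feasible) but carries no finite
#' timing. Strictly exceeding the asymptote (`e > emax`) or negative intake
#' returns `NA`, the non-feasible marker.
#'
#' @param params a [lode_params()] object
#' @param e vector of cumulative intake values (g)
#' @return numeric vector of predicted bite times (min); `Inf` at the
#'   asymptote, `NA` where non-feasible
#' @export
#' @examples
#' p <- lode_params(10, 0.3, 300)
#' lode_time(p, lode_intake(p, 5))  # 5
#' lode_time(p, 300)                # Inf (asymptote)
#' lode_time(p, 301)                # NA  (non-feasible)
lode_time <- function(params, e) {
  stopifnot(inherits(params, "lode_params"))
  e <- as.numeric(e)
  if (any(!is.finite(e)))
    stop("e must be finite", call. = FALSE)
  k <- lode_k(params)
  emax <- params$emax
  t <- rep(NA_real_, length(e))
  at_asym <- abs(e - emax) <= 1e-12 * emax
  ok <- e >= 0 & e < emax & !at_asym
  t[ok] <- (log1p(e[ok] * params$r / params$theta) - log1p(-e[ok] / emax)) / k
  t[at_asym] <- Inf
  t
}

#' Classify predicted bites as feasible or non-feasible
#'
#' Checks a sequence of predicted bite values (timings and/or cumulative
#' intakes) for the non-feasible categories arising from approximation
#' error in recovered parameters: intake before the meal began (negative
#' time), negative intake, decreasing values relative to the previous bite,
#' and failed inversions (`NA` markers). An infinite timing prediction at
#' the LODE asymptote is positive and increasing, so it is classified
#' `"asymptote"`: feasible, but excluded from error summaries by
#' [curve_error()]. A case is convergent when at most 10% of its bites are
#' non-feasible.
#'
#' @param time optional vector of predicted bite timings (min); may contain
#'   `NA` markers and `Inf`
#' @param intake optional vector of predicted cumulative intakes (g); may
#'   contain `NA` markers
#' @return A list of class `"feasibility_flags"` with elements `n_bites`,
#'   `n_nonfeasible`, `reasons` (per-bite category: `"negative-time"`,
#'   `"negative-intake"`, `"decreasing-intake"`, `"inversion-failure"`,
#'   `"asymptote"`, or `"none"`), and `convergent`.
#' @export
#' @examples
#' f <- classify_feasibility(time = c(1, 2, NA, 4), intake = c(5, 10, 15, 20))
#' f$n_nonfeasible  # 1
#' f$convergent     # FALSE: 25% of bites non-feasible
classify_feasibility <- function(time = NULL, intake = NULL) {
  if (is.null(time) && is.null(intake))
    stop("at least one of time or intake must be supplied", call. = FALSE)
  n <- max(length(time), length(intake))
  if (n == 0L)
    stop("empty prediction sequence", call. = FALSE)
  if (!is.null(time) && !is.null(intake) && length(time) != length(intake))
    stop("time and intake predictions must have equal length", call. = FALSE)

  reasons <- rep("none", n)
  flag <- function(idx, why) {
    hit <- idx & reasons == "none"
    reasons[hit] <<- why
  }
  if (!is.null(time)) {
    flag(is.na(time), "inversion-failure")
    flag(!is.na(time) & time < 0, "negative-time")
    prev <- c(-Inf, time[-n])
    # a bite predicted earlier than its (finite) predecessor is a decrease
    dec <- !is.na(time) & !is.na(prev) & is.finite(time) & time <= prev
    flag(dec, "decreasing-intake")
    flag(!is.na(time) & is.infinite(time) & time > 0, "asymptote")
  }
  if (!is.null(intake)) {
    flag(is.na(intake), "inversion-failure")
    flag(!is.na(intake) & intake < 0, "negative-intake")
    prev <- c(-Inf, intake[-n])
    dec <- !is.na(intake) & !is.na(prev) & intake < prev
    flag(dec, "decreasing-intake")
  }
  nonfeasible <- !(reasons %in% c("none", "asymptote"))
  out <- list(n_bites = n,
              n_nonfeasible = sum(nonfeasible),
              reasons = reasons,
              convergent = sum(nonfeasible) / n <= 0.10)
  class(out) <- "feasibility_flags"
  out
}

#' @export
print.feasibility_flags <- function(x, ...) {
  cat(sprintf("%d bites: %d non-feasible (%.1f%%), %s\n", x$n_bites,
              x$n_nonfeasible, 100 * x$n_nonfeasible / x$n_bites,
              if (x$convergent) "convergent" else "non-convergent"))
  invisible(x)
}

# forward / inverse dispatch on model tag
model_intake <- function(params, t) {
  if (inherits(params, "quadratic_params")) quadratic_intake(params, t)
  else lode_intake(params, t)
}

model_time <- function(params, e) {
  if (inherits(params, "quadratic_params")) quadratic_time(params, e)
  else lode_time(params, e)
}
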