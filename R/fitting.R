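# Gaussian log-likelihood of observed intake with sigma profiled subject to
# a lower bound (the quantization noise of gram-resolution intake records).
# Minimizing SSE maximizes this likelihood for any sigma_min.
loglik_from_sse <- function(sse, n, sigma_min) {
  sigma2 <- max(sse / n, sigma_min^2)
  -n / 2 * log(2 * pi * sigma2) - sse / (2 * sigma2)
}

lode_sse <- function(par, times, intake, emax_fixed, total) {
  theta <- exp(par[[1L]]); r <- exp(par[[2L]])
  emax <- if (is.null(emax_fixed)) total + exp(par[[3L]]) else emax_fixed
  if (!is.finite(theta) || !is.finite(r) || !is.finite(emax) ||
      theta <= 0 || r <= 0 || emax <= 0) return(Inf)
  k <- r + theta / emax
  ekt <- exp(-k * times)
  pred <- (1 - ekt) / (1 / emax + (r / theta) * ekt)
  s <- sum((intake - pred)^2)
  if (!is.finite(s)) Inf else s
}

# data-driven starting heuristics: initial observed rate for theta and
# ln(2) / half-intake time for r
lode_start <- function(times, intake) {
  theta0 <- intake[1L] / times[1L]
  total <- intake[length(intake)]
  i_half <- which(intake >= total / 2)[1L]
  t_half <- if (i_half == 1L) times[1L] / 2 else {
    # linear interpolation of the half-intake crossing
    w <- (total / 2 - intake[i_half - 1L]) /
      (intake[i_half] - intake[i_half - 1L])
    times[i_half - 1L] + w * (times[i_half] - times[i_half - 1L])
  }
  r0 <- log(2) / max(t_half, 1e-3)
  c(theta0 = max(theta0, 1e-3), r0 = max(r0, 1e-4))
}

#' Fit a cumulative intake model to a bite sequence
#'
#' Maximum-likelihood estimation under independent Gaussian errors on
#' cumulative intake at the observed bite times, with the residual SD
#' profiled subject to the lower bound `sigma_min` (equivalently,
#' nonlinear least squares). The quadratic model's three coefficients are
#' solved in closed form by polynomial least squares. The LODE model's
#' `(theta, r)` are optimized on the log scale by Nelder-Mead with BFGS
#' polishing from five deterministic data-driven starts; by default the
#' asymptote `emax` is fixed at the observed final intake (the total gram
#' intake of the eating episode), may be fixed at a user-supplied value
#' (e.g. a known asymptote), or estimated freely above the observed total
#' with `emax = "free"` (used by the generating model).
#'
#' @param bites a [bite_sequence()]
#' @param model `"quadratic"` or `"lode"`
#' @param init optional starting values (an `intake_params` object)
#' @param emax for the LODE model: `NULL` (fix at observed final intake),
#'   a positive number, or `"free"`
#' @param sigma_min lower bound for the profiled residual SD (g). The
#'   default (`NULL`) floors it at the bite-size quantization noise
#'   `avg_bite_size / sqrt(12)`: cumulative intake is only observed as a
#'   ladder of discrete bites, so residuals below the bite discretization
#'   carry no information about the underlying smooth curve
#' @return an object of class `"bitecurve_fit"`: `model`, `estimates`,
#'   `loglik`, `sse`, `sigma`, `n`, `fixed` (record of fixed parameters),
#'   `diagnostics` (convergence flag, iteration counts, start used), and
#'   `ci` (filled by [profile_cis()])
#' @seealso [profile_confidence_interval()], [profile_cis()]
#' @export
fit_model <- function(bites, model = c("quadratic", "lode"), init = NULL,
                      emax = NULL, sigma_min = NULL) {
  model <- match.arg(model)
  validate_bite_sequence(bites)
  t <- bites$times; y <- bites$intake; n <- bites$bite_count
  if (is.null(sigma_min)) sigma_min <- (y[n] / n) / sqrt(12)

  if (model == "quadratic") {
    if (n < 4L)
      stop("under-determined: the quadratic model needs at least 4 bites",
           call. = FALSE)
    X <- cbind(1, t, t^2)
    beta <- stats::lm.fit(X, y)$coefficients
    est <- quadratic_params(a = beta[[3L]], b = beta[[2L]], c = beta[[1L]])
    sse <- sum((y - quadratic_intake(est, t))^2)
    out <- list(model = model, estimates = est,
                loglik = loglik_from_sse(sse, n, sigma_min),
                sse = sse, sigma = sqrt(max(sse / n, sigma_min^2)), n = n,
                fixed = list(),
                sigma_min = sigma_min,
                diagnostics = list(converged = TRUE, iterations = 0L,
                                   n_starts = 1L))
    class(out) <- "bitecurve_fit"
    return(out)
  }

  total <- y[n]
  free_emax <- identical(emax, "free")
  emax_fixed <- if (free_emax) NULL
                else if (is.null(emax)) total
                else {
                  stopifnot(is.numeric(emax), emax > 0)
                  as.numeric(emax)
                }
  n_free <- if (free_emax) 3L else 2L
  if (n < n_free + 1L)
    stop("under-determined: too few bites for the LODE model", call. = FALSE)

  s0 <- lode_start(t, y)
  starts <- list(c(1, 1), c(0.5, 1), c(2, 1), c(1, 0.5), c(1, 2))
  pars <- lapply(starts, function(f)
    c(log(s0[["theta0"]] * f[1L]), log(s0[["r0"]] * f[2L]),
      if (free_emax) log(0.1 * total)))
  if (!is.null(init)) {
    stopifnot(inherits(init, "lode_params"))
    ex <- if (free_emax) max(init$emax - total, 1e-6 * total) else NULL
    pars <- c(list(c(log(init$theta), log(init$r),
                     if (free_emax) log(ex))), pars)
  }

  best <- NULL
  for (p0 in pars) {
    o1 <- tryCatch(stats::optim(p0, lode_sse, times = t, intake = y,
                                emax_fixed = emax_fixed, total = total,
                                method = "Nelder-Mead",
                                control = list(maxit = 2000,
                                               reltol = 1e-12)),
                   error = function(e) NULL)
    if (is.null(o1)) next
    o2 <- tryCatch(stats::optim(o1$par, lode_sse, times = t, intake = y,
                                emax_fixed = emax_fixed, total = total,
                                method = "BFGS",
                                control = list(maxit = 500,
                                               reltol = 1e-12)),
                   error = function(e) o1)
    o <- if (!is.null(o2) && is.finite(o2$value) &&
             o2$value <= o1$value) o2 else o1
    if (is.finite(o$value) && (is.null(best) || o$value < best$value))
      best <- o
  }
  if (is.null(best))
    stop("LODE fit failed to converge from all starts", call. = FALSE)

  theta <- exp(best$par[[1L]]); r <- exp(best$par[[2L]])
  emax_hat <- if (free_emax) total + exp(best$par[[3L]]) else emax_fixed
  est <- lode_params(theta, r, emax_hat)
  sse <- best$value
  out <- list(model = model, estimates = est,
              loglik = loglik_from_sse(sse, n, sigma_min),
              sse = sse, sigma = sqrt(max(sse / n, sigma_min^2)), n = n,
              fixed = if (free_emax) list()
                      else list(emax = emax_hat,
                                source = if (is.null(emax)) "observed-total"
                                         else "user"),
              sigma_min = sigma_min,
              diagnostics = list(converged = best$convergence == 0L ||
                                   is.finite(sse),
                                 iterations = unname(best$counts[1L]),
                                 n_starts = length(pars)))
  class(out) <- "bitecurve_fit"
  out
}

#' @export
print.bitecurve_fit <- function(x, ...) {
  cat(sprintf("%s model fit (n = %d bites): logLik = %.3f, sigma = %.3f g\n",
              x$model, x$n, x$loglik, x$sigma))
  print(x$estimates)
  if (!is.null(x$ci)) print(x$ci, row.names = FALSE)
  invisible(x)
}

# profile log-likelihood with one free parameter pinned at `value`,
# re-optimizing the remaining free parameters
profile_loglik <- function(fit, bites, param, value) {
  t <- bites$times; y <- bites$intake; n <- bites$bite_count
  if (fit$model == "quadratic") {
    cols <- c(c = 1L, b = 2L, a = 3L)
    X <- cbind(1, t, t^2)
    j <- cols[[param]]
    resid <- y - value * X[, j]
    sse <- sum(stats::lm.fit(X[, -j, drop = FALSE], resid)$residuals^2)
    return(loglik_from_sse(sse, n, fit$sigma_min))
  }
  if (value <= 0) return(-Inf)
  emax_fixed <- fit$estimates$emax
  other_hat <- if (param == "theta") fit$estimates$r else fit$estimates$theta
  obj <- function(lp) {
    other <- exp(lp)
    th <- if (param == "theta") value else other
    rr <- if (param == "theta") other else value
    lode_sse(c(log(th), log(rr)), t, y, emax_fixed, y[n])
  }
  opt <- stats::optimize(obj, interval = log(other_hat) + c(-15, 15),
                         tol = 1e-9)
  loglik_from_sse(opt$objective, n, fit$sigma_min)
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Data-driven likelihood-profile interval: each bound is the parameter
#' value at which twice the drop of the re-optimized (profile)
#' log-likelihood from its maximum equals the chi-squared(1) quantile at
#' `level` (3.841 for 95%). Bounds are located by stepping outward from
#' the estimate (initial step 10% of its magnitude, doubling until the
#' cutoff is bracketed) followed by bisection to a relative tolerance of
#' 1e-4; the outer endpoint of the final bracket is reported, so stated
#' coverage is conservative. Positivity limits (theta, r > 0) clip the
#' lower search and set a censoring flag; a profile that never reaches
#' the cutoff yields an open (infinite) bound, flagged but not fatal.
#'
#' @param fit a converged [fit_model()] result
#' @param bites the [bite_sequence()] the model was fitted to
#' @param param parameter name (`"a"`, `"b"`, `"c"`, `"theta"`, or `"r"`)
#' @param level confidence level (default 0.95)
#' @return a list with `lower`, `upper`, `level`, and logical flags
#'   `censored_lower`, `censored_upper`, `open_lower`, `open_upper`
#' @export
profile_confidence_interval <- function(fit, bites, param, level = 0.95) {
  stopifnot(inherits(fit, "bitecurve_fit"))
  if (!isTRUE(fit$diagnostics$converged))
    stop("cannot profile a non-converged fit", call. = FALSE)
  if (!param %in% free_param_names(fit$model))
    stop(sprintf("'%s' is not a free parameter of the %s model",
                 param, fit$model), call. = FALSE)
  est <- param_vec(fit$estimates)[[param]]
  cutoff <- stats::qchisq(level, df = 1L)
  ll_hat <- max(fit$loglik, profile_loglik(fit, bites, param, est))
  positive <- fit$model == "lode"   # theta, r live on (0, Inf)
  drop_fn <- function(v) 2 * (ll_hat - profile_loglik(fit, bites, param, v)) -
    cutoff

  one_side <- function(dir) {
    step <- 0.1 * max(abs(est), 0.1)
    inner <- est
    censored <- FALSE; open <- FALSE; outer <- NA_real_
    for (i in seq_len(60L)) {
      v <- est + dir * step
      clipped <- FALSE
      if (positive && v <= 0) { v <- est * 1e-9; clipped <- TRUE }
      d <- drop_fn(v)
      if (is.finite(d) && d >= 0) { outer <- v; break }
      inner <- v
      if (clipped) { censored <- TRUE; break }
      if (step > 1e6 * max(abs(est), 1)) { open <- TRUE; break }
      step <- step * 2
    }
    if (censored) return(list(bound = 0, censored = TRUE, open = FALSE))
    if (open || is.na(outer))
      return(list(bound = dir * Inf, censored = FALSE, open = TRUE))
    tol <- 1e-4 * max(abs(est), 0.1)
    while (abs(outer - inner) > tol) {
      mid <- (outer + inner) / 2
      if (drop_fn(mid) >= 0) outer <- mid else inner <- mid
    }
    list(bound = outer, censored = FALSE, open = FALSE)
  }

  lo <- one_side(-1); hi <- one_side(+1)
  list(lower = min(lo$bound, est), upper = max(hi$bound, est),
       level = level,
       censored_lower = lo$censored, censored_upper = hi$censored,
       open_lower = lo$open, open_upper = hi$open)
}

#' Profile confidence intervals for all free parameters
#'
#' Convenience wrapper around [profile_confidence_interval()]; the result
#' table is attached to the fit as `$ci`.
#'
#' @inheritParams profile_confidence_interval
#' @return the fit, with `$ci` set to a data.frame with one row per free
#'   parameter (`param`, `estimate`, `lower`, `upper`, `level`, flags)
#' @export
profile_cis <- function(fit, bites, level = 0.95) {
  pn <- free_param_names(fit$model)
  rows <- lapply(pn, function(p) {
    ci <- profile_confidence_interval(fit, bites, p, level)
    data.frame(param = p, estimate = param_vec(fit$estimates)[[p]],
               lower = ci$lower, upper = ci$upper, level = level,
               censored_lower = ci$censored_lower,
               censored_upper = ci$censored_upper,
               open_lower = ci$open_lower, open_upper = ci$open_upper,
               stringsAsFactors = FALSE)
  })
  fit$ci <- do.call(rbind, rows)
  fit
}
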