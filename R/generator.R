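#' Sample from a zero-truncated logistic distribution
#'
#' Inverse-CDF sampling from a logistic distribution truncated at zero.
#' With the default location 0 the result is half-logistic: a monotonically
#' decreasing density whose sorted draws, used as bite times, produce the
#' decelerating (s-shaped from above) cumulative intake curves typical of
#' satiating meals.
#'
#' @param n number of draws
#' @param location,scale logistic parameters (defaults 0 and 1; the scale
#'   cancels under the generator's max-normalization)
#' @return numeric vector of positive draws
#' @export
rtrunclogis <- function(n, location = 0, scale = 1) {
  f0 <- stats::plogis(0, location, scale)
  stats::qlogis(f0 + stats::runif(n) * (1 - f0), location, scale)
}

#' Sample meal microstructure profiles
#'
#' Draws per-case meal-level behaviors (bite count, total intake, meal
#' duration) from the multivariate normal implied by a
#' [reference_stats()] object, truncated to positive values (and at least
#' two bites) by rejection. Average bite size and mean eating rate are
#' derived.
#'
#' @param ref a [reference_stats()] object
#' @param n number of profiles
#' @param seed integer seed
#' @return a data.frame with one row per case: `case_id`, `n_bites`
#'   (integer), `total_intake`, `meal_duration`, `avg_bite_size`,
#'   `eating_rate`
#' @export
#' @examples
#' head(sample_microstructure(reference_stats(), n = 5, seed = 1))
sample_microstructure <- function(ref, n, seed = 1L) {
  stopifnot(inherits(ref, "reference_stats"), n >= 1)
  set.seed(seed)
  keep <- matrix(numeric(0), 0, 3)
  tries <- 0L
  while (nrow(keep) < n) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("microstructure truncation leaves almost no mass above zero; ",
           "check the reference statistics", call. = FALSE)
    draw <- MASS::mvrnorm(max(2L * n, 100L), mu = ref$mean, Sigma = ref$cov)
    ok <- draw[, 1] >= 1.5 & draw[, 2] > 0 & draw[, 3] > 0
    keep <- rbind(keep, draw[ok, , drop = FALSE])
  }
  keep <- keep[seq_len(n), , drop = FALSE]
  n_bites <- pmax(2L, as.integer(round(keep[, 1])))
  data.frame(case_id = sprintf("gen%04d", seq_len(n)),
             n_bites = n_bites,
             total_intake = keep[, 2],
             meal_duration = keep[, 3],
             avg_bite_size = keep[, 2] / n_bites,
             eating_rate = keep[, 2] / keep[, 3],
             stringsAsFactors = FALSE)
}

#' Generate bite timings for a microstructure profile
#'
#' Builds one meal's bite sequence from a microstructure profile: samples
#' `n_bites` points from a zero-truncated logistic distribution, sorts them,
#' scales them so the final bite lands exactly at the meal duration
#' (`duration * value / max(value)`), jitters the timings with Gaussian
#' noise, and repairs/validates the result so timings are positive,
#' strictly increasing, and end at the meal duration. Cumulative intake is
#' the constant average-bite-size ladder. If a draw cannot be repaired the
#' generator retries from a fresh substream (up to 20 times).
#'
#' @param profile a single-row data.frame (or list) with fields `case_id`,
#'   `n_bites`, `total_intake`, `meal_duration`
#' @param jitter_sd Gaussian timing-jitter SD (min); default 2% of meal
#'   duration
#' @param seed integer seed
#' @return a [bite_sequence()]
#' @export
generate_bite_timings <- function(profile, jitter_sd = NULL, seed = 1L) {
  n <- as.integer(profile$n_bites)
  total <- as.numeric(profile$total_intake)
  dur <- as.numeric(profile$meal_duration)
  stopifnot(n >= 2, total > 0, dur > 0)
  if (is.null(jitter_sd)) jitter_sd <- 0.02 * dur
  stopifnot(jitter_sd >= 0)

  for (attempt in seq_len(20L)) {
    set.seed(substream_seed(seed, attempt))
    raw <- sort(rtrunclogis(n))
    t <- dur * raw / max(raw)
    # Gaussian jitter, reflected at the meal-start boundary so early bites
    # stay positive without piling up degenerately at zero
    t <- abs(t + stats::rnorm(n, 0, jitter_sd))
    t <- sort(t)
    t <- t * dur / max(t)          # re-anchor the final bite at the duration
    t[n] <- dur                    # snap away float error from the rescale
    ok <- all(t > 0) && all(diff(t) > 0) && t[n] <= dur + 1e-9 * dur
    if (ok) {
      return(bite_sequence(profile$case_id, t,
                           seq_len(n) * (total / n), meal_duration = dur))
    }
  }
  stop(sprintf("case '%s': could not generate valid bite timings",
               profile$case_id), call. = FALSE)
}

# curve-level feasibility of a fitted parameter set over one meal:
# predicted intake must be non-decreasing over [0, meal_duration] (for a
# parabola: non-negative derivative at both endpoints) and non-negative at
# the first bite. LODE curves satisfy this by construction.
fitted_curve_feasible <- function(params, bites) {
  if (inherits(params, "lode_params")) return(TRUE)
  dur <- bites$meal_duration
  params$b >= 0 && 2 * params$a * dur + params$b >= 0 &&
    quadratic_intake(params, bites$times[1L]) >= -1e-8
}

#' Build a feasible multivariate parameter distribution
#'
#' The generating model: for each microstructure profile, generates bite
#' timings, fits the requested intake model, and retains the fit only if
#' the optimizer converged, the fitted curve is feasible over the meal
#' (non-decreasing, non-negative at the first bite), and the estimates are
#' stable under re-optimization (relative change below 1e-4). Unstable or
#' infeasible cases are regenerated from fresh timing substreams up to 10
#' times. The retained fits, jointly with each case's bite count and total
#' intake, define a multivariate normal over model parameters (summarized
#' robustly, since curve-level parameters are heavy-tailed); their medians
#' are kept for goodness-of-fit scaling.
#'
#' For the LODE model the asymptote `emax` is estimated freely above the
#' observed total intake (a logistic asymptote is approached, never
#' attained, so it must lie strictly above anything eaten in finite time),
#' making `emax` a full member of the joint distribution.
#'
#' @param profiles data.frame from [sample_microstructure()]; at least 50
#'   rows are required to estimate a covariance
#' @param model `"quadratic"` or `"lode"`
#' @param seed integer seed
#' @param jitter_sd generator timing-jitter SD (min); default 2% of each
#'   meal's duration
#' @param max_iter regeneration attempts per case
#' @return an object of class `"parameter_distribution"`: fields `model`,
#'   `vars`, `mean`, `cov`, `medians`, `fits` (retained per-case parameter
#'   table), `n_retained`, `seed`
#' @export
build_parameter_distribution <- function(profiles, model, seed = 1L,
                                         jitter_sd = NULL, max_iter = 10L) {
  model <- check_model_tag(model)
  if (nrow(profiles) < 50L)
    stop("need at least 50 profiles to estimate a parameter distribution",
         call. = FALSE)
  pnames <- if (model == "quadratic") c("a", "b", "c")
            else c("theta", "r", "emax")
  rows <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    for (iter in seq_len(max_iter)) {
      bites <- generate_bite_timings(
        prof, jitter_sd = jitter_sd,
        seed = substream_seed(seed, i, iter))
      fit <- tryCatch(
        fit_model(bites, model,
                  emax = if (model == "lode") "free" else NULL),
        error = function(e) NULL)
      if (is.null(fit) || !fit$diagnostics$converged) next
      if (!fitted_curve_feasible(fit$estimates, bites)) next
      refit <- tryCatch(
        fit_model(bites, model,
                  emax = if (model == "lode") "free" else NULL,
                  init = fit$estimates),
        error = function(e) NULL)
      if (is.null(refit)) next
      relchg <- abs(param_vec(refit$estimates) - param_vec(fit$estimates)) /
        pmax(abs(param_vec(fit$estimates)), 1e-8)
      if (max(relchg) >= 1e-4) next
      est <- param_vec(fit$estimates)[pnames]
      rows[[i]] <- data.frame(case_id = prof$case_id,
                              n_bites = prof$n_bites,
                              total_intake = prof$total_intake,
                              as.list(est), stringsAsFactors = FALSE)
      break
    }
  }
  fits <- do.call(rbind, rows)
  if (is.null(fits) || nrow(fits) < 0.5 * nrow(profiles))
    stop("more than 50% of generating cases infeasible; ",
         "the reference statistics are likely misconfigured", call. = FALSE)
  vars <- c("n_bites", "total_intake", pnames)
  m <- as.matrix(fits[, vars])
  # curve-level parameters are heavy-tailed (meals with an early first
  # bite imply extreme initial rates), so the normal summary uses a
  # robust location/covariance (minimum covariance determinant) rather
  # than the raw moments, which a handful of outlying fits would dominate
  set.seed(substream_seed(seed, 99L))
  rob <- tryCatch(MASS::cov.rob(m, method = "mcd"),
                  error = function(e) list(center = colMeans(m),
                                           cov = stats::cov(m)))
  structure(list(model = model, vars = vars,
                 mean = rob$center, cov = rob$cov,
                 medians = apply(m, 2, stats::median),
                 fits = fits, n_retained = nrow(fits),
                 seed = as.integer(seed)),
            class = "parameter_distribution")
}

#' @export
print.parameter_distribution <- function(x, ...) {
  cat(sprintf("Parameter distribution (%s model), %d retained cases\n",
              x$model, x$n_retained))
  print(round(rbind(mean = x$mean, median = x$medians,
                    sd = sqrt(diag(x$cov))), 4))
  invisible(x)
}

#' Serialize / read a parameter distribution (JSON)
#'
#' @param dist a `"parameter_distribution"` object
#' @param path output path
#' @return `path` (write) or the restored object (read)
#' @export
write_parameter_distribution <- function(dist, path) {
  obj <- list(model = dist$model, vars = dist$vars,
              mean = as.list(dist$mean),
              cov = dist$cov, medians = as.list(dist$medians),
              n_retained = dist$n_retained, seed = dist$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameter_distribution
#' @export
read_parameter_distribution <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(model = obj$model, vars = obj$vars,
                 mean = unlist(obj$mean)[obj$vars],
                 cov = matrix(unlist(obj$cov), length(obj$vars),
                              dimnames = list(obj$vars, obj$vars)),
                 medians = unlist(obj$medians)[obj$vars],
                 fits = NULL, n_retained = obj$n_retained,
                 seed = obj$seed),
            class = "parameter_distribution")
}

# feasibility of one drawn parameter set for simulation purposes: a
# complete meal must be generatable, i.e. the curve reaches the drawn
# total intake through positive, strictly increasing bite times within a
# plausible meal duration
draw_feasible <- function(model, draw, max_duration) {
  n <- as.integer(round(draw[["n_bites"]]))
  total <- draw[["total_intake"]]
  # the simulated meal must be estimable by its model (free parameters + 1)
  n_min <- if (model == "lode") 3L else 4L
  if (n < n_min || !is.finite(total) || total <= 0) return(FALSE)
  if (model == "lode") {
    th <- draw[["theta"]]; r <- draw[["r"]]; em <- draw[["emax"]]
    if (!(is.finite(th) && is.finite(r) && is.finite(em) &&
          th > 0 && r > 0 && em > total)) return(FALSE)
    p <- lode_params(th, r, em)
  } else {
    a <- draw[["a"]]; b <- draw[["b"]]; cc <- draw[["c"]]
    if (!all(is.finite(c(a, b, cc)))) return(FALSE)
    if (a == 0 && b == 0) return(FALSE)
    p <- quadratic_params(a, b, cc)
  }
  e <- seq_len(n) * (total / n)
  t <- model_time(p, e)
  all(is.finite(t)) && all(t > 0) && all(diff(t) > 0) &&
    t[n] <= max_duration && t[n] >= 1
}

#' Draw true parameter sets for simulation
#'
#' Joint draws of model parameters, bite count, and total intake from a
#' constructed [build_parameter_distribution()]. Draws violating
#' positivity/feasibility constraints (fewer than two bites, non-positive
#' intake or rates, a LODE asymptote at or below the total intake, a
#' quadratic curve whose increasing branch cannot reach the drawn total,
#' or an implied constant-bite meal lasting under one minute or beyond
#' `max_duration` minutes) are rejected and redrawn; the rejection count
#' is recorded in the `"n_rejected"` attribute.
#'
#' @param dist a `"parameter_distribution"` object
#' @param n number of true parameter sets
#' @param seed integer seed
#' @param max_duration longest plausible meal (min); the study default is
#'   the reference mean duration plus four reference SDs
#' @return a data.frame with one row per case: `case_id`, `n_bites`,
#'   `total_intake`, and the model parameters
#' @export
sample_true_parameters <- function(dist, n, seed = 1L, max_duration = 35) {
  stopifnot(inherits(dist, "parameter_distribution"), n >= 1)
  set.seed(seed)
  out <- list(); kept <- 0L; rejected <- 0L
  while (kept < n) {
    draw <- MASS::mvrnorm(n, mu = dist$mean, Sigma = dist$cov)
    if (is.null(dim(draw))) draw <- matrix(draw, 1,
                                           dimnames = list(NULL, dist$vars))
    for (j in seq_len(nrow(draw))) {
      if (kept >= n) break
      d <- draw[j, ]
      if (draw_feasible(dist$model, d, max_duration)) {
        kept <- kept + 1L
        out[[kept]] <- d
      } else rejected <- rejected + 1L
    }
    if (rejected > 9L * (kept + n))
      stop("rejection rate above 90% when sampling true parameters",
           call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, out))
  df$n_bites <- pmax(2L, as.integer(round(df$n_bites)))
  df <- cbind(case_id = sprintf("%s%04d", substr(dist$model, 1, 1),
                                seq_len(n)),
              df, stringsAsFactors = FALSE)
  attr(df, "n_rejected") <- rejected
  df
}

# materialize an intake_params object from one row of a truth table
true_params_of <- function(model, row) {
  if (model == "lode") lode_params(row$theta, row$r, row$emax)
  else quadratic_params(row$a, row$b, row$c)
}
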