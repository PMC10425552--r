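# strictly-increasing repair for noisy cumulative intake: sort, clip into
# (0, total], pin the final value to the total, and break residual ties
repair_increasing <- function(x, total) {
  n <- length(x)
  x <- sort(x)
  x[n] <- total
  eps <- 1e-9 * total
  x <- pmin(pmax(x, eps), total)
  for (i in seq_len(n)[-1]) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
  if (x[n] > total) {            # squeeze back under the pinned total
    x <- x * total / x[n]
    for (i in seq_len(n)[-1]) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
    x[n] <- total
  }
  x
}

new_simulated_case <- function(case_id, condition, model, true_params,
                               bites, noise) {
  structure(list(case_id = case_id, condition = condition, model = model,
                 true_params = true_params, bites = bites, noise = noise),
            class = "simulated_case")
}

#' @export
print.simulated_case <- function(x, ...) {
  cat(sprintf("Simulated case '%s' (%s model, %s condition)\n",
              x$case_id, x$model, x$condition))
  print(x$bites)
  invisible(x)
}

#' Simulate a constant-bite meal
#'
#' The simplest simulation condition: cumulative intake at bite `i` is
#' `i * total_intake / n_bites` (every bite is the average bite size) and
#' bite timings are computed exactly from the true parameters by the
#' model's inverse, so the condition carries no noise of any kind.
#'
#' @param true_params a [quadratic_params()] or [lode_params()] object
#' @param n_bites number of bites (>= 2)
#' @param total_intake total meal intake (g)
#' @param case_id case identifier
#' @return a `"simulated_case"` (fields `case_id`, `condition`, `model`,
#'   `true_params`, `bites`, `noise`)
#' @export
#' @examples
#' simulate_constant_bite(lode_params(10, 0.3, 330), 20, 300)
simulate_constant_bite <- function(true_params, n_bites, total_intake,
                                   case_id = "sim") {
  stopifnot(n_bites >= 2, total_intake > 0)
  e <- seq_len(n_bites) * (total_intake / n_bites)
  t <- model_time(true_params, e)
  if (any(!is.finite(t)) || any(t <= 0) || any(diff(t) <= 0))
    stop(sprintf("case '%s': true parameters cannot generate the bite ladder",
                 case_id), call. = FALSE)
  bites <- bite_sequence(case_id, t, e)
  new_simulated_case(case_id, "constant", model_tag(true_params),
                     true_params, bites,
                     list(process_sd = 0, timing_jitter_sd = 0, seed = NA))
}

#' Simulate a variable-bite meal
#'
#' Emulates idealized continuous weight measurement: the constant-bite
#' intake ladder receives Gaussian process noise at every bite (so bite
#' sizes vary), is repaired to be strictly increasing with the final value
#' pinned to the total intake, and bite timings are then recomputed from
#' the noisy cumulative intake through the true model inverse - the
#' timings therefore carry no measurement error.
#'
#' @inheritParams simulate_constant_bite
#' @param process_sd SD of the Gaussian process noise on cumulative intake
#'   (g); the study default is 10% of the average bite size
#' @param seed integer seed
#' @return a `"simulated_case"`
#' @export
simulate_variable_bite <- function(true_params, n_bites, total_intake,
                                   process_sd = 0.10 * total_intake / n_bites,
                                   seed = 1L, case_id = "sim") {
  stopifnot(process_sd >= 0)
  base <- simulate_constant_bite(true_params, n_bites, total_intake, case_id)
  if (process_sd > 0) {
    done <- FALSE
    # a noise draw can push early intake outside the invertible range of
    # the true curve (e.g. below a quadratic intercept); such draws are
    # regenerated from a fresh substream
    for (attempt in seq_len(20L)) {
      set.seed(substream_seed(seed, 1L, attempt))
      e <- base$bites$intake + stats::rnorm(n_bites, 0, process_sd)
      e <- repair_increasing(e, total_intake)
      t <- model_time(true_params, e)
      if (all(is.finite(t)) && all(t > 0) && all(diff(t) > 0)) {
        base$bites <- bite_sequence(case_id, t, e)
        done <- TRUE
        break
      }
    }
    if (!done)
      stop(sprintf("case '%s': jittered intake not invertible", case_id),
           call. = FALSE)
  }
  base$condition <- "variable"
  base$noise <- list(process_sd = process_sd, timing_jitter_sd = 0,
                     seed = seed)
  base
}

#' Simulate a video-coded meal with bite measurement error
#'
#' Emulates video-coded meals, which require average bite size and carry
#' imprecise bite timings. Runs the variable-bite procedure, then - after
#' bite timings have been computed - (a) replaces cumulative intake with
#' the constant average-bite-size ladder (intake measurement error
#' relative to the timings) and (b) jitters the timings with Gaussian
#' noise, re-sorting and validating. Both cumulative intake and bite
#' timing therefore carry measurement error.
#'
#' @inheritParams simulate_variable_bite
#' @param timing_jitter_sd SD of the Gaussian timing measurement noise
#'   (min); the study default of 2/60 min emulates manual video-coding
#'   error of about two seconds
#' @return a `"simulated_case"`
#' @export
simulate_measurement_error <- function(true_params, n_bites, total_intake,
                                       process_sd = 0.10 * total_intake / n_bites,
                                       timing_jitter_sd = 2 / 60,
                                       seed = 1L, case_id = "sim") {
  stopifnot(timing_jitter_sd >= 0)
  base <- simulate_variable_bite(true_params, n_bites, total_intake,
                                 process_sd, seed, case_id)
  t <- base$bites$times
  if (timing_jitter_sd > 0) {
    set.seed(substream_seed(seed, 2L))
    t <- sort(t + stats::rnorm(n_bites, 0, timing_jitter_sd))
    t <- pmax(t, 1e-6 * max(t))
    eps <- 1e-9 * max(t)
    for (i in seq_len(n_bites)[-1]) if (t[i] <= t[i - 1]) t[i] <- t[i - 1] + eps
  }
  e <- seq_len(n_bites) * (total_intake / n_bites)
  base$bites <- bite_sequence(case_id, t, e)
  base$condition <- "measurement_error"
  base$noise$timing_jitter_sd <- timing_jitter_sd
  base
}

model_tag <- function(params) {
  if (inherits(params, "lode_params")) "lode" else "quadratic"
}

#' Simulate all cases for one condition
#'
#' Applies the requested simulation condition to every row of a truth
#' table drawn by [sample_true_parameters()].
#'
#' @param truths data.frame from [sample_true_parameters()]
#' @param model `"quadratic"` or `"lode"`
#' @param condition `"constant"`, `"variable"`, or `"measurement_error"`
#' @param config a [study_config()] (noise magnitudes and seed)
#' @return a list of `"simulated_case"` objects
#' @export
simulate_condition <- function(truths, model, condition, config = study_config()) {
  model <- check_model_tag(model)
  condition <- match.arg(condition,
                         c("constant", "variable", "measurement_error"))
  lapply(seq_len(nrow(truths)), function(i) {
    row <- truths[i, ]
    p <- true_params_of(model, row)
    sd_p <- config$process_sd_frac * row$total_intake / row$n_bites
    sseed <- substream_seed(config$seed, match(condition, c(
      "constant", "variable", "measurement_error")), i)
    switch(condition,
           constant = simulate_constant_bite(
             p, row$n_bites, row$total_intake, row$case_id),
           variable = simulate_variable_bite(
             p, row$n_bites, row$total_intake, sd_p, sseed, row$case_id),
           measurement_error = simulate_measurement_error(
             p, row$n_bites, row$total_intake, sd_p,
             config$timing_jitter_sd, sseed, row$case_id))
  })
}

#' Write a simulated condition to disk
#'
#' Emits the bite-level CSV dialect of [write_bite_csv()] plus a sidecar
#' JSON recording, per case, the condition, true parameters, seeds, and
#' noise settings - the ground-truth input of the recovery module.
#'
#' @param cases list of `"simulated_case"` objects
#' @param csv_path,json_path output paths
#' @return `csv_path`, invisibly
#' @export
write_simulated_cases <- function(cases, csv_path, json_path) {
  write_bite_csv(lapply(cases, `[[`, "bites"), csv_path)
  meta <- lapply(cases, function(cs) {
    list(case_id = cs$case_id, condition = cs$condition, model = cs$model,
         true_params = as.list(param_vec(cs$true_params)),
         noise = cs$noise)
  })
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
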