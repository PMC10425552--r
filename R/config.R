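#' Reference microstructure statistics
#'
#' Means, standard deviations, and correlation structure of the meal-level
#' behaviors the generator draws from: number of bites, total intake (g),
#' and meal duration (min). The shipped defaults are documented
#' approximations of child meal microstructure (roughly 40 +/- 15 bites,
#' 300 +/- 100 g, 15 +/- 5 min, with moderate positive correlations among
#' the three); studies with their own reference values should override
#' every field, either directly or through a YAML/JSON study config
#' (see [read_study_config()]).
#'
#' @param mean_n_bites,sd_n_bites bite count moments
#' @param mean_total_intake,sd_total_intake total intake moments (g)
#' @param mean_meal_duration,sd_meal_duration meal duration moments (min)
#' @param cor_bites_intake,cor_bites_duration,cor_intake_duration pairwise
#'   correlations among the three behaviors
#' @return an object of class `"reference_stats"` carrying the mean vector
#'   and covariance matrix
#' @export
reference_stats <- function(mean_n_bites = 40, sd_n_bites = 15,
                            mean_total_intake = 300, sd_total_intake = 100,
                            mean_meal_duration = 15, sd_meal_duration = 5,
                            cor_bites_intake = 0.5,
                            cor_bites_duration = 0.4,
                            cor_intake_duration = 0.3) {
  sds <- c(n_bites = sd_n_bites, total_intake = sd_total_intake,
           meal_duration = sd_meal_duration)
  if (any(sds < 0)) stop("reference SDs must be >= 0", call. = FALSE)
  R <- matrix(c(1, cor_bites_intake, cor_bites_duration,
                cor_bites_intake, 1, cor_intake_duration,
                cor_bites_duration, cor_intake_duration, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("reference correlation matrix is not positive semi-definite",
         call. = FALSE)
  mu <- c(n_bites = mean_n_bites, total_intake = mean_total_intake,
          meal_duration = mean_meal_duration)
  if (any(mu <= 0)) stop("reference means must be > 0", call. = FALSE)
  structure(list(mean = mu, sd = sds,
                 cor = R, cov = diag(sds) %*% R %*% diag(sds)),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat("Reference meal microstructure:\n")
  for (nm in names(x$mean))
    cat(sprintf("  %-14s %6.1f +/- %.1f\n", nm, x$mean[[nm]], x$sd[[nm]]))
  invisible(x)
}

#' Study configuration
#'
#' All knobs of the simulation-and-recovery study in one place. Defaults
#' are the package's reference study: 500 generating cases, 100 simulated
#' cases per condition, 95% profile confidence intervals, process noise of
#' 10% of the average bite size on cumulative intake, bite-timing
#' measurement noise of 2 s (0.033 min), and generator timing jitter of 2%
#' of meal duration.
#'
#' @param seed integer seed governing every random stream of the study
#' @param n_cases simulated cases per condition per model
#' @param n_generating_cases cases used to build the parameter distributions
#' @param ref a [reference_stats()] object
#' @param ci_level confidence level for profile intervals, in (0, 1)
#' @param process_sd_frac process-noise SD on cumulative intake, as a
#'   fraction of average bite size (variable-bite and measurement-error
#'   conditions)
#' @param timing_jitter_sd measurement-noise SD on bite timings (min),
#'   measurement-error condition
#' @param gen_jitter_frac generator timing-jitter SD as a fraction of meal
#'   duration
#' @param sigma_min lower bound for the profiled residual SD (g);
#'   `NULL` (the default) floors it per meal at the bite-size quantization
#'   noise `avg_bite_size / sqrt(12)`
#' @param models character vector of model tags to run
#' @param distinct_threshold_frac distinctness threshold as a fraction of
#'   the number of cases (an estimate is distinct when it falls within
#'   fewer than `threshold * n` other confidence intervals)
#' @return an object of class `"study_config"`
#' @export
study_config <- function(seed = 1L,
                         n_cases = 100L,
                         n_generating_cases = 500L,
                         ref = reference_stats(),
                         ci_level = 0.95,
                         process_sd_frac = 0.10,
                         timing_jitter_sd = 2 / 60,
                         gen_jitter_frac = 0.02,
                         sigma_min = NULL,
                         models = c("quadratic", "lode"),
                         distinct_threshold_frac = 0.15) {
  stopifnot(n_cases >= 1, n_generating_cases >= 1,
            ci_level > 0, ci_level < 1,
            process_sd_frac >= 0, timing_jitter_sd >= 0,
            gen_jitter_frac >= 0, is.null(sigma_min) || sigma_min >= 0,
            distinct_threshold_frac > 0, distinct_threshold_frac < 1)
  models <- match.arg(models, c("quadratic", "lode"), several.ok = TRUE)
  structure(list(seed = as.integer(seed),
                 n_cases = as.integer(n_cases),
                 n_generating_cases = as.integer(n_generating_cases),
                 ref = ref, ci_level = ci_level,
                 process_sd_frac = process_sd_frac,
                 timing_jitter_sd = timing_jitter_sd,
                 gen_jitter_frac = gen_jitter_frac,
                 sigma_min = sigma_min, models = models,
                 distinct_threshold_frac = distinct_threshold_frac),
            class = "study_config")
}

#' Read a study configuration from YAML or JSON
#'
#' Fields mirror the arguments of [study_config()]; reference statistics
#' are given under a `ref:` block whose fields mirror [reference_stats()].
#' Missing fields keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return an object of class `"study_config"`
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$ref)) raw$ref <- do.call(reference_stats, raw$ref)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown study config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(study_config, raw)
}

# derived, deterministic sub-seeds for the study's independent streams;
# kept below 2^31 - 1 so they are valid R integer seeds
substream_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed) %% 2147483647
  for (o in offs) s <- (s * 48271 + as.double(o)) %% 2147483647
  as.integer(s)
}
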