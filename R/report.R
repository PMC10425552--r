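#' Compare proportions of distinct estimates (Fisher's exact test)
#'
#' Two-sided Fisher's exact probability test on the 2x2 table of
#' distinct/not-distinct by group, used to compare distinctness between
#' models or conditions.
#'
#' @param distinct_a,distinct_b logical vectors of distinct flags
#' @return a list with `odds_ratio`, `p_value`, and the 2x2 `table`
#' @export
compare_proportions <- function(distinct_a, distinct_b) {
  if (!length(distinct_a) || !length(distinct_b))
    stop("both groups must be non-empty", call. = FALSE)
  tab <- matrix(c(sum(distinct_a), sum(!distinct_a),
                  sum(distinct_b), sum(!distinct_b)), nrow = 2,
                dimnames = list(c("distinct", "not"), c("A", "B")))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Compare skewed score distributions (Mann-Whitney U test)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with tie correction,
#' used for goodness-of-fit and error comparisons whose distributions are
#' skewed. Degenerate input (every value identical across both groups) is
#' flagged rather than tested.
#'
#' @param values_a,values_b numeric vectors
#' @return a list with `U` (the Mann-Whitney statistic for group A),
#'   `p_value`, and `degenerate`
#' @export
compare_distributions <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (!length(values_a) || !length(values_b))
    stop("both groups must contain finite values", call. = FALSE)
  if (length(unique(c(values_a, values_b))) == 1L)
    return(list(U = length(values_a) * length(values_b) / 2,
                p_value = 1, degenerate = TRUE))
  wt <- stats::wilcox.test(values_a, values_b, exact = FALSE,
                           correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value, degenerate = FALSE)
}

#' Pearson correlations among model parameters and meal behaviors
#'
#' Correlates the quadratic and LODE parameters fitted to the same
#' generated meals, jointly with bite count and total intake. Columns
#' with zero variance yield `NA` entries and are flagged in the
#' `"zero_variance"` attribute.
#'
#' @param quad_dist,lode_dist `"parameter_distribution"` objects built
#'   from the same generating profiles (their `$fits` tables are joined
#'   on `case_id`)
#' @return a Pearson correlation matrix over
#'   `a, b, c, theta, r, n_bites, total_intake`
#' @export
parameter_correlations <- function(quad_dist, lode_dist) {
  stopifnot(inherits(quad_dist, "parameter_distribution"),
            inherits(lode_dist, "parameter_distribution"),
            quad_dist$model == "quadratic", lode_dist$model == "lode")
  if (is.null(quad_dist$fits) || is.null(lode_dist$fits))
    stop("per-case fits are required (deserialized distributions lack them)",
         call. = FALSE)
  df <- merge(quad_dist$fits[, c("case_id", "a", "b", "c")],
              lode_dist$fits[, c("case_id", "theta", "r",
                                 "n_bites", "total_intake")],
              by = "case_id")
  m <- as.matrix(df[, c("a", "b", "c", "theta", "r",
                        "n_bites", "total_intake")])
  zv <- apply(m, 2, stats::sd) == 0
  cm <- suppressWarnings(stats::cor(m))
  cm[zv, ] <- NA_real_; cm[, zv] <- NA_real_
  attr(cm, "zero_variance") <- names(zv)[zv]
  cm
}

study_conditions <- c("constant", "variable", "measurement_error")

# all pairwise comparison statistics reported by the study: between-model
# distinctness/GOF contrasts per condition and between-condition contrasts
# per model, every contrast labelled
study_comparisons <- function(results) {
  rows <- list()
  add <- function(kind, condition, model, param_a, param_b, stat, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, condition = condition, model = model,
      param_a = param_a, param_b = param_b,
      statistic = stat, p_value = p, stringsAsFactors = FALSE)
  }
  have <- names(results)
  if (all(c("quadratic", "lode") %in% have)) {
    for (cond in study_conditions) {
      rq <- results$quadratic[[cond]]$report
      rl <- results$lode[[cond]]$report
      cp <- compare_proportions(rl$distinct$any_distinct,
                                rq$distinct$any_distinct)
      add("distinct_any_model", cond, "lode_vs_quadratic", NA, NA,
          cp$odds_ratio, cp$p_value)
      for (lp in c("theta", "r")) for (qp in c("a", "b", "c")) {
        cp <- compare_proportions(rl$distinct$distinct[, lp],
                                  rq$distinct$distinct[, qp])
        add("distinct_param_model", cond, "lode_vs_quadratic", lp, qp,
            cp$odds_ratio, cp$p_value)
        cd <- compare_distributions(rl$distinct$counts[, lp],
                                    rq$distinct$counts[, qp])
        add("overlap_param_model", cond, "lode_vs_quadratic", lp, qp,
            cd$U, cd$p_value)
        cg <- compare_distributions(rl$gof[[lp]], rq$gof[[qp]])
        add("gof_param_model", cond, "lode_vs_quadratic", lp, qp,
            cg$U, cg$p_value)
      }
    }
  }
  for (model in have) {
    pn <- free_param_names(model)
    for (i in 1:2) for (j in (i + 1):3) {
      ca <- study_conditions[i]; cb <- study_conditions[j]
      ra <- results[[model]][[ca]]$report
      rb <- results[[model]][[cb]]$report
      for (p in pn) {
        cg <- compare_distributions(ra$gof[[p]], rb$gof[[p]])
        add("gof_condition", paste(ca, cb, sep = "_vs_"), model, p, p,
            cg$U, cg$p_value)
      }
      for (m in c("rmse_timing", "rmse_intake", "r2_timing", "r2_intake")) {
        cg <- compare_distributions(
          ra$errors[[m]][ra$errors$convergent],
          rb$errors[[m]][rb$errors$convergent])
        add(paste0(m, "_condition"), paste(ca, cb, sep = "_vs_"), model,
            NA, NA, cg$U, cg$p_value)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full simulation-and-recovery study
#'
#' Orchestrates the whole pipeline: samples generating meal microstructure,
#' constructs feasible parameter distributions for each model, draws true
#' parameter sets, simulates the three data conditions, fits each case
#' with profile confidence intervals, runs the recovery battery, and
#' computes the between-model and between-condition comparison statistics
#' plus the parameter correlation matrix. Every random stream derives
#' deterministically from `config$seed`, so a repeated run reproduces the
#' study exactly.
#'
#' @param config a [study_config()]
#' @param progress print stage progress (default `FALSE`)
#' @return an object of class `"bitecurve_study"`: `config`, `profiles`,
#'   `dists`, `correlations`, `truths`, `results` (per model and
#'   condition: `cases`, `fits`, `report`), `comparisons`, and `manifest`
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (progress) message(sprintf(...))

  say("sampling %d generating microstructure profiles",
      config$n_generating_cases)
  profiles <- sample_microstructure(config$ref, config$n_generating_cases,
                                    seed = substream_seed(config$seed, 11))

  dists <- list()
  for (model in config$models) {
    say("building %s parameter distribution", model)
    dists[[model]] <- build_parameter_distribution(
      profiles, model, seed = substream_seed(config$seed, 12,
                                             match(model, c("quadratic",
                                                            "lode"))))
  }

  correlations <- if (all(c("quadratic", "lode") %in% config$models))
    parameter_correlations(dists$quadratic, dists$lode) else NULL

  truths <- results <- list()
  for (model in config$models) {
    truths[[model]] <- sample_true_parameters(
      dists[[model]], config$n_cases,
      seed = substream_seed(config$seed, 13,
                            match(model, c("quadratic", "lode"))),
      max_duration = config$ref$mean[["meal_duration"]] +
        4 * config$ref$sd[["meal_duration"]])
    results[[model]] <- list()
    for (cond in study_conditions) {
      say("%s model, %s condition: simulate + fit + profile CIs",
          model, cond)
      cases <- simulate_condition(truths[[model]], model, cond, config)
      # for LODE fits, emax is fixed at the meal's asymptotic total intake
      # (its defined value, known for a simulated meal); theta and r are
      # the estimated free parameters, as in the fitted-parameter reports
      fits <- lapply(seq_along(cases), function(i) {
        cs <- cases[[i]]
        f <- fit_model(cs$bites, model,
                       emax = if (model == "lode")
                         truths[[model]]$emax[i] else NULL,
                       sigma_min = config$sigma_min)
        profile_cis(f, cs$bites, level = config$ci_level)
      })
      report <- recovery_report(truths[[model]], fits, cases,
                                dists[[model]], condition = cond,
                                threshold_frac =
                                  config$distinct_threshold_frac)
      results[[model]][[cond]] <- list(cases = cases, fits = fits,
                                       report = report)
    }
  }

  say("comparison statistics")
  comparisons <- study_comparisons(results)

  manifest <- list(package = "bitecurve",
                   version = as.character(utils::packageVersion("bitecurve")),
                   seed = config$seed,
                   n_cases = config$n_cases,
                   n_generating_cases = config$n_generating_cases,
                   ci_level = config$ci_level,
                   process_sd_frac = config$process_sd_frac,
                   timing_jitter_sd = config$timing_jitter_sd,
                   gen_jitter_frac = config$gen_jitter_frac,
                   sigma_min = config$sigma_min,
                   models = config$models)

  structure(list(config = config, profiles = profiles, dists = dists,
                 correlations = correlations, truths = truths,
                 results = results, comparisons = comparisons,
                 manifest = manifest),
            class = "bitecurve_study")
}

#' @export
print.bitecurve_study <- function(x, ...) {
  cat(sprintf("bitecurve study (seed %d): %d cases/condition, models: %s\n",
              x$config$seed, x$config$n_cases,
              paste(names(x$results), collapse = ", ")))
  for (model in names(x$results)) for (cond in names(x$results[[model]])) {
    r <- x$results[[model]][[cond]]$report
    cat(sprintf("  %-9s %-18s coverage %s | distinct(any) %3.0f%% | excl %d\n",
                model, cond,
                paste(sprintf("%.2f", r$coverage), collapse = "/"),
                100 * r$distinct$prop_any, length(r$excluded)))
  }
  invisible(x)
}

#' Write all study artifacts to a directory
#'
#' Serializes the study: parameter distributions (JSON), truth tables and
#' simulated bite sequences (CSV, with sidecar ground-truth JSON),
#' recovery reports (tidy CSV + JSON summaries), comparison statistics and
#' parameter correlations (CSV), and a run manifest (JSON) recording the
#' seed and configuration that fully determine reproduction.
#'
#' @param study a `"bitecurve_study"`
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (model in names(study$dists))
    write_parameter_distribution(
      study$dists[[model]],
      file.path(outdir, sprintf("distribution_%s.json", model)))
  if (!is.null(study$correlations)) {
    cm <- study$correlations
    utils::write.csv(data.frame(param = rownames(cm), cm),
                     file.path(outdir, "parameter_correlations.csv"),
                     row.names = FALSE)
  }
  for (model in names(study$results)) {
    utils::write.csv(study$truths[[model]],
                     file.path(outdir, sprintf("true_parameters_%s.csv",
                                               model)),
                     row.names = FALSE)
    for (cond in names(study$results[[model]])) {
      res <- study$results[[model]][[cond]]
      stem <- sprintf("%s_%s", model, cond)
      write_simulated_cases(res$cases,
                            file.path(outdir, paste0(stem, "_bites.csv")),
                            file.path(outdir, paste0(stem, "_truth.json")))
      write_recovery_report(res$report, outdir)
    }
  }
  utils::write.csv(study$comparisons,
                   file.path(outdir, "comparisons.csv"), row.names = FALSE)
  jsonlite::write_json(study$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
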