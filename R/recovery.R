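#' Confidence-interval coverage of true parameter values
#'
#' The fraction of cases whose true parameter value lies inside the
#' recovered profile-likelihood confidence interval, per parameter. Open
#' bounds are treated as infinite, so an all-open interval always covers.
#'
#' @param truths data.frame of true parameter values (one row per case,
#'   columns named as the model parameters), aligned with `fits`
#' @param fits list of fits carrying `$ci` (see [profile_cis()])
#' @return named numeric vector of coverage proportions in `[0, 1]`
#' @export
coverage <- function(truths, fits) {
  stopifnot(length(fits) >= 1, nrow(truths) == length(fits))
  pn <- free_param_names(fits[[1L]]$model)
  sapply(pn, function(p) {
    hit <- vapply(seq_along(fits), function(i) {
      ci <- fits[[i]]$ci
      row <- ci[ci$param == p, ]
      tv <- truths[[p]][i]
      row$lower <= tv && tv <= row$upper
    }, logical(1L))
    mean(hit)
  })
}

#' Distinguishability of recovered estimates
#'
#' For each case and parameter, counts how many *other* cases' confidence
#' intervals contain this case's point estimate. An estimate is distinct
#' when that count is below `threshold_frac * n` (fewer than 15 of 100
#' other intervals at the default 15% threshold), i.e. it is
#' distinguishable from at least 85% of the estimates in the condition. A
#' whole cumulative intake curve counts as distinct if any of its model
#' parameters is distinct.
#'
#' @param fits list of fits carrying `$ci`, all from one simulated
#'   condition; at least two
#' @param threshold_frac distinctness threshold as a fraction of the
#'   number of cases
#' @return a list: `counts` and `distinct` (case x parameter matrices),
#'   `prop_distinct` (per parameter), `any_distinct` (per case), and
#'   `prop_any`
#' @export
distinguishability <- function(fits, threshold_frac = 0.15) {
  n <- length(fits)
  stopifnot(n >= 2)
  pn <- free_param_names(fits[[1L]]$model)
  counts <- matrix(NA_integer_, n, length(pn),
                   dimnames = list(NULL, pn))
  for (p in pn) {
    est <- vapply(fits, function(f)
      f$ci$estimate[f$ci$param == p], numeric(1L))
    lo <- vapply(fits, function(f)
      f$ci$lower[f$ci$param == p], numeric(1L))
    hi <- vapply(fits, function(f)
      f$ci$upper[f$ci$param == p], numeric(1L))
    inside <- outer(est, lo, ">=") & outer(est, hi, "<=")
    diag(inside) <- FALSE
    counts[, p] <- as.integer(rowSums(inside))
  }
  distinct <- counts < threshold_frac * n
  list(counts = counts, distinct = distinct,
       prop_distinct = colMeans(distinct),
       any_distinct = apply(distinct, 1L, any),
       prop_any = mean(apply(distinct, 1L, any)))
}

#' Goodness of Fit Index
#'
#' The absolute difference between recovered and true parameter values,
#' scaled by the median of the generating parameter distribution so that
#' parameters of different magnitude are comparable. Always non-negative;
#' smaller is better; 0 is perfect recovery.
#'
#' @param true,recovered named numeric vectors (or `intake_params`) of
#'   true and recovered parameter values
#' @param medians named numeric vector of generating-distribution medians
#'   (all non-zero)
#' @return named numeric vector of per-parameter indices
#' @export
#' @examples
#' gof_index(c(b = 2), c(b = 3), c(b = 4))  # 0.25
gof_index <- function(true, recovered, medians) {
  if (inherits(true, "intake_params")) true <- param_vec(true)
  if (inherits(recovered, "intake_params")) recovered <- param_vec(recovered)
  true <- unlist(true); recovered <- unlist(recovered)
  pn <- intersect(names(true), names(medians))
  if (!length(pn)) stop("no shared parameter names", call. = FALSE)
  if (any(medians[pn] == 0))
    stop("zero median in the generating distribution: cannot scale",
         call. = FALSE)
  abs(recovered[pn] - true[pn]) / abs(medians[pn])
}

#' Cumulative-intake-curve prediction error
#'
#' Compares the true and recovered curves bite by bite in both directions:
#' predicted cumulative intake at the true bite timings, and predicted
#' bite timing at the true cumulative intake. Reports RMSE (in grams and
#' minutes respectively) over feasible finite predictions, and a
#' pseudo-R-squared `1 - SS_res/SS_tot` (SS_tot about the per-case mean of
#' the true values) giving the proportion of variance in true intake or
#' timing explained by the predictions. Non-feasible predicted bites are
#' excluded from the error sums but counted toward the 10% non-convergence
#' rule; an infinite LODE timing prediction at the asymptote is feasible
#' but likewise excluded from the sums.
#'
#' @param true_params true model parameters (`intake_params`)
#' @param recovered_params recovered model parameters
#' @param true_bites the true [bite_sequence()]
#' @return a list: `rmse_timing`, `rmse_intake`, `r2_timing`,
#'   `r2_intake`, `n_excluded_timing`, `n_excluded_intake`, and `flags`
#'   (combined [classify_feasibility()] result; `flags$convergent` is the
#'   10% rule)
#' @export
curve_error <- function(true_params, recovered_params, true_bites) {
  validate_bite_sequence(true_bites)
  t_true <- true_bites$times; e_true <- true_bites$intake
  pred_e <- model_intake(recovered_params, t_true)
  pred_t <- model_time(recovered_params, e_true)

  flags_t <- classify_feasibility(time = pred_t)
  flags_e <- classify_feasibility(intake = pred_e)
  reasons <- ifelse(flags_t$reasons %in% c("none", "asymptote"),
                    flags_e$reasons, flags_t$reasons)
  reasons[flags_t$reasons == "asymptote" & reasons == "none"] <- "asymptote"
  nonfeasible <- !(reasons %in% c("none", "asymptote"))
  flags <- structure(list(n_bites = flags_t$n_bites,
                          n_nonfeasible = sum(nonfeasible),
                          reasons = reasons,
                          convergent = sum(nonfeasible) /
                            flags_t$n_bites <= 0.10),
                     class = "feasibility_flags")

  direction <- function(pred, obs, incl) {
    if (!any(incl)) return(list(rmse = NA_real_, r2 = NA_real_,
                                excluded = length(obs)))
    res <- pred[incl] - obs[incl]
    ss_tot <- sum((obs[incl] - mean(obs[incl]))^2)
    list(rmse = sqrt(mean(res^2)),
         r2 = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
         excluded = sum(!incl))
  }
  dt <- direction(pred_t, t_true,
                  flags_t$reasons == "none" & is.finite(pred_t))
  de <- direction(pred_e, e_true,
                  flags_e$reasons == "none" & is.finite(pred_e))
  list(rmse_timing = dt$rmse, rmse_intake = de$rmse,
       r2_timing = dt$r2, r2_intake = de$r2,
       n_excluded_timing = dt$excluded, n_excluded_intake = de$excluded,
       flags = flags)
}

q123 <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
  c(median = q[1L], q25 = q[2L], q75 = q[3L])
}

#' Parameter-recovery report for one simulated condition
#'
#' Runs the full validation battery for one model under one simulation
#' condition: per-parameter CI coverage, estimate distinguishability,
#' per-case Goodness of Fit Indices, and cumulative-intake-curve error in
#' both directions. Non-convergent cases (more than 10% non-feasible
#' predicted bites) are flagged and excluded from the RMSE and
#' pseudo-R-squared summaries, which report medians with 25th/75th
#' percentiles.
#'
#' @param truths truth table from [sample_true_parameters()]
#' @param fits aligned list of fits carrying `$ci`
#' @param cases aligned list of `"simulated_case"` objects
#' @param dist the generating [build_parameter_distribution()] (medians
#'   used for goodness-of-fit scaling)
#' @param condition condition label
#' @param threshold_frac distinctness threshold fraction
#' @return an object of class `"recovery_report"`: `condition`, `model`,
#'   `coverage`, `distinct` (see [distinguishability()]), `gof` (case x
#'   parameter data.frame), `errors` (per-case data.frame), `excluded`
#'   (non-convergent case ids), and `summary` (tidy quantile table)
#' @export
recovery_report <- function(truths, fits, cases, dist,
                            condition = "constant",
                            threshold_frac = 0.15) {
  stopifnot(nrow(truths) == length(fits), length(fits) == length(cases))
  model <- fits[[1L]]$model
  pn <- free_param_names(model)

  cov <- coverage(truths, fits)
  dis <- distinguishability(fits, threshold_frac)

  gof_rows <- lapply(seq_along(fits), function(i) {
    g <- gof_index(unlist(truths[i, pn]),
                   param_vec(fits[[i]]$estimates)[pn],
                   dist$medians[pn])
    data.frame(case_id = truths$case_id[i], t(g),
               stringsAsFactors = FALSE)
  })
  gof <- do.call(rbind, gof_rows)

  err_rows <- lapply(seq_along(fits), function(i) {
    ce <- curve_error(cases[[i]]$true_params, fits[[i]]$estimates,
                      cases[[i]]$bites)
    data.frame(case_id = truths$case_id[i],
               rmse_timing = ce$rmse_timing, rmse_intake = ce$rmse_intake,
               r2_timing = ce$r2_timing, r2_intake = ce$r2_intake,
               n_nonfeasible = ce$flags$n_nonfeasible,
               n_bites = ce$flags$n_bites,
               convergent = ce$flags$convergent,
               stringsAsFactors = FALSE)
  })
  errors <- do.call(rbind, err_rows)
  excluded <- errors$case_id[!errors$convergent]
  inc <- errors$convergent

  summ <- rbind(
    do.call(rbind, lapply(pn, function(p) data.frame(
      metric = "gof", param = p, t(q123(gof[[p]])),
      stringsAsFactors = FALSE))),
    do.call(rbind, lapply(c("rmse_timing", "rmse_intake",
                            "r2_timing", "r2_intake"), function(m)
      data.frame(metric = m, param = NA_character_,
                 t(q123(errors[[m]][inc])), stringsAsFactors = FALSE))),
    do.call(rbind, lapply(pn, function(p) data.frame(
      metric = "ci_overlap_count", param = p,
      t(q123(dis$counts[, p])), stringsAsFactors = FALSE))))

  structure(list(condition = condition, model = model,
                 coverage = cov, distinct = dis, gof = gof,
                 errors = errors, excluded = excluded, summary = summ),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery report: %s model, %s condition\n",
              x$model, x$condition))
  cat("  coverage: ",
      paste(sprintf("%s = %.2f", names(x$coverage), x$coverage),
            collapse = ", "), "\n")
  cat(sprintf("  distinct (any parameter): %.0f%%\n",
              100 * x$distinct$prop_any))
  cat(sprintf("  non-convergent cases excluded: %d\n", length(x$excluded)))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a recovery report to disk
#'
#' Emits tidy CSV tables (one row per case-parameter goodness of fit, one
#' per case for curve errors) plus a JSON summary of medians and
#' 25th/75th percentiles mirroring the report's quantile layout.
#'
#' @param report a `"recovery_report"`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_recovery_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_%s", report$model, report$condition)
  utils::write.csv(report$gof,
                   file.path(dir, paste0(stem, "_gof.csv")),
                   row.names = FALSE)
  utils::write.csv(report$errors,
                   file.path(dir, paste0(stem, "_errors.csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(schema_version = "1.0",
         model = report$model, condition = report$condition,
         coverage = as.list(report$coverage),
         prop_distinct = as.list(report$distinct$prop_distinct),
         prop_any_distinct = report$distinct$prop_any,
         excluded = report$excluded,
         summary = report$summary),
    file.path(dir, paste0(stem, "_summary.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
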