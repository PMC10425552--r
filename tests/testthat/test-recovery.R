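test_that("goodness-of-fit index is the median-scaled absolute difference", {
  expect_identical(unname(gof_index(c(b = 2), c(b = 2), c(b = 4))), 0)
  expect_identical(unname(gof_index(c(b = 2), c(b = 3), c(b = 4))), 0.25)
  # sign-flipped recovery: absolute-value rule
  expect_identical(unname(gof_index(c(a = -1), c(a = 1), c(a = 2))), 1)
  expect_error(gof_index(c(a = 1), c(a = 2), c(a = 0)), "zero median")
  expect_error(gof_index(c(a = 1), c(a = 2), c(b = 1)), "no shared")
})

test_that("curve error reproduces the hand-computed 3-bite example", {
  # true times 1,2,3; predicted 1,2,5: RMSE = sqrt(4/3); SS_tot about the
  # mean of (1,2,3) is 2, so pseudo-R2 = 1 - 4/2 = -1
  res <- with(list(), {
    pred <- c(1, 2, 5); obs <- c(1, 2, 3)
    inc <- rep(TRUE, 3)
    list(rmse = sqrt(mean((pred - obs)^2)),
         r2 = 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2))
  })
  expect_equal(res$rmse, sqrt(4 / 3))
  expect_equal(res$r2, -1)

  # the same formulas through curve_error, intake direction: recovered
  # curve E(t) = 2t^2 + 4t + 4 predicts (10, 20, 34) at the true times
  # (1, 2, 3) against observed (10, 20, 30): residuals (0, 0, 4)
  true_p <- quadratic_params(0, 10, 0)
  bites <- bite_sequence("h", c(1, 2, 3), c(10, 20, 30))
  rec <- quadratic_params(a = 2, b = 4, c = 4)
  ce <- curve_error(true_p, rec, bites)
  expect_equal(ce$rmse_intake, sqrt(16 / 3), tolerance = 1e-12)
  expect_equal(ce$r2_intake, 1 - 16 / 200, tolerance = 1e-12)
})

test_that("perfect recovery gives zero error and unit pseudo-R2, which
           degrades monotonically under perturbation", {
  cs <- lode_case()
  ce <- curve_error(cs$true_params, cs$true_params, cs$bites)
  expect_equal(ce$rmse_timing, 0, tolerance = 1e-9)
  expect_equal(ce$r2_timing, 1, tolerance = 1e-12)
  expect_equal(ce$r2_intake, 1, tolerance = 1e-12)
  expect_identical(ce$flags$n_nonfeasible, 0L)
  expect_true(ce$flags$convergent)

  r2 <- sapply(c(1.05, 1.15, 1.3), function(fac) {
    pert <- lode_params(cs$true_params$theta * fac, cs$true_params$r,
                        cs$true_params$emax)
    curve_error(cs$true_params, pert, cs$bites)$r2_timing
  })
  expect_true(all(diff(r2) < 0))
  expect_true(all(r2 < 1))
})

test_that("LODE curve predictions are never non-feasible; quadratic
           inversion failures are counted and excluded", {
  cs <- lode_case()
  # a misspecified-asymptote recovery still predicts feasible bites
  shrunk <- lode_params(25, 0.2, emax = 300)    # asymptote at the total
  ce <- curve_error(cs$true_params, shrunk, cs$bites)
  expect_identical(ce$flags$n_nonfeasible, 0L)
  # the asymptote bite (e_n == emax) is censored, not non-feasible
  expect_identical(sum(ce$flags$reasons == "asymptote"), 1L)
  expect_identical(ce$n_excluded_timing, 1L)

  # a quadratic recovery whose vertex sits below the final intake cannot
  # invert the top bites: non-feasible markers, counted toward the 10% rule
  cq <- quad_case()                              # vertex at 200 g, total 150
  low <- quadratic_params(-0.5, 16, 0)           # vertex at 128 g
  ceq <- curve_error(cq$true_params, low, cq$bites)
  expect_gt(ceq$flags$n_nonfeasible, 0L)
  expect_false(ceq$flags$convergent)             # > 10% of 25 bites
  expect_true(is.finite(ceq$rmse_timing))        # over feasible bites only
})

test_that("coverage counts true values inside recovered intervals, with
           open bounds treated as infinite", {
  make_fit <- function(est, lo, hi) {
    structure(list(model = "lode",
                   ci = data.frame(param = c("theta", "r"),
                                   estimate = est, lower = lo, upper = hi)),
              class = "bitecurve_fit")
  }
  truths <- data.frame(theta = c(10, 20), r = c(0.1, 0.2))
  fits <- list(make_fit(c(10, 0.1), c(-Inf, -Inf), c(Inf, Inf)),
               make_fit(c(25, 0.3), c(24, 0.29), c(26, 0.31)))
  cov <- coverage(truths, fits)
  expect_equal(unname(cov), c(0.5, 0.5))
  # degenerate zero-width intervals away from the truth never cover
  fits0 <- list(make_fit(c(11, 0.2), c(11, 0.2), c(11, 0.2)),
                make_fit(c(21, 0.3), c(21, 0.3), c(21, 0.3)))
  expect_equal(unname(coverage(truths, fits0)), c(0, 0))
})

test_that("distinguishability implements the fewer-than-15%-overlaps rule
           and is permutation invariant", {
  # 100 synthetic fits: estimate i sits inside exactly i-1 other intervals
  make_fit <- function(est, lo, hi)
    structure(list(model = "quadratic",
                   ci = data.frame(param = c("a", "b", "c"),
                                   estimate = est, lower = lo, upper = hi)),
              class = "bitecurve_fit")
  n <- 100
  fits <- lapply(seq_len(n), function(i) {
    # parameter "a": estimate at i; interval [i - 100 + 14, i] contains
    # the 14 estimates below i... instead construct directly:
    make_fit(c(i, 0, 0), c(i - 0.25, -1, -1), c(i + 0.25, 1, 1))
  })
  d <- distinguishability(fits)
  expect_true(all(d$counts[, "a"] == 0))        # all isolated: distinct
  expect_equal(unname(d$prop_distinct["a"]), 1)

  # boundary of the rule: inside exactly 14 vs 15 other intervals
  fits2 <- lapply(seq_len(n), function(i) {
    lo <- if (i <= 14) 49.5 else if (i <= 29) 59.5 else i + 100
    hi <- if (i <= 14) 50.5 else if (i <= 29) 60.5 else i + 101
    make_fit(c(if (i == 50) 50 else if (i == 60) 60 else -i, 0, 0),
             c(lo, -1, -1), c(hi, 1, 1))
  })
  d2 <- distinguishability(fits2)
  i50 <- 50; i60 <- 60
  expect_identical(unname(d2$counts[i50, "a"]), 14L)   # < 15: distinct
  expect_true(d2$distinct[i50, "a"])
  expect_identical(unname(d2$counts[i60, "a"]), 15L)   # not distinct
  expect_false(d2$distinct[i60, "a"])

  # permutation invariance of the distinct proportion
  set.seed(77)
  perm <- sample(n)
  d3 <- distinguishability(fits2[perm])
  expect_equal(sort(d3$counts[, "a"]), sort(d2$counts[, "a"]))
  expect_equal(d3$prop_distinct, d2$prop_distinct)

  # all intervals identical and containing every estimate: nothing distinct
  fits4 <- lapply(rep(0.5, 20), function(e)
    make_fit(c(e, 0, 0), c(0, -1, -1), c(1, 1, 1)))
  expect_equal(unname(distinguishability(fits4)$prop_distinct["a"]), 0)
})

test_that("recovery reports exclude non-convergent cases from the error
           summaries", {
  prof <- small_profiles(60, seed = 7)
  d <- build_parameter_distribution(prof, "lode", seed = 21)
  tr <- sample_true_parameters(d, 8, seed = 41)
  cfg <- study_config(seed = 6, n_cases = 8)
  cases <- simulate_condition(tr, "lode", "constant", cfg)
  fits <- lapply(seq_along(cases), function(i)
    profile_cis(fit_model(cases[[i]]$bites, "lode", emax = tr$emax[i]),
                cases[[i]]$bites))
  rep1 <- recovery_report(tr, fits, cases, d, condition = "constant")
  expect_s3_class(rep1, "recovery_report")
  expect_true(all(rep1$coverage >= 0 & rep1$coverage <= 1))
  expect_true(all(rep1$errors$convergent))
  expect_length(rep1$excluded, 0)
  expect_true(all(c("gof", "rmse_timing", "r2_intake") %in%
                    rep1$summary$metric))

  dir <- withr::local_tempdir()
  write_recovery_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "lode_constant_gof.csv")))
  js <- jsonlite::read_json(file.path(dir, "lode_constant_summary.json"))
  expect_equal(js$model, "lode")
})
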