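test_that("noise-free LODE data is recovered exactly; a coarse grid search
           agrees", {
  cs <- lode_case()
  f <- fit_model(cs$bites, "lode", emax = 330)
  expect_true(f$diagnostics$converged)
  expect_equal(f$estimates$theta, 30, tolerance = 1e-3)
  expect_equal(f$estimates$r, 0.15, tolerance = 1e-3)

  # independent oracle: brute-force grid search over (theta, r)
  grid <- expand.grid(theta = seq(10, 60, by = 2.5),
                      r = seq(0.05, 0.4, by = 0.025))
  sse <- apply(grid, 1, function(g) {
    p <- lode_params(g[["theta"]], g[["r"]], 330)
    sum((cs$bites$intake - lode_intake(p, cs$bites$times))^2)
  })
  best <- grid[which.min(sse), ]
  expect_equal(f$estimates$theta, best$theta, tolerance = 0.1)
  expect_equal(f$estimates$r, best$r, tolerance = 0.2)
  expect_lt(f$sse, min(sse) + 1e-8)
})

test_that("quadratic fitting is polynomial least squares", {
  set.seed(33)
  t <- sort(runif(40, 0.5, 15))
  y <- -0.4 * t^2 + 18 * t + 2 + rnorm(40, 0, 3)
  b <- bite_sequence("ols", t, cummax(pmax(y, 0.1)))
  f <- fit_model(b, "quadratic")
  ref <- stats::lm(b$intake ~ b$times + I(b$times^2))
  expect_equal(f$estimates$c, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(f$estimates$b, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(f$estimates$a, unname(coef(ref)[3]), tolerance = 1e-10)

  # noise-free case: residual SS is numerically zero
  cq <- quad_case()
  fq <- fit_model(cq$bites, "quadratic")
  expect_lt(fq$sse, 1e-16)
  expect_equal(unclass(fq$estimates), list(a = -0.5, b = 20, c = 0),
               tolerance = 1e-8)

  b3 <- bite_sequence("tiny", c(1, 2), c(5, 10))
  expect_error(fit_model(b3, "quadratic"), "under-determined")
})

test_that("profile intervals hit the chi-squared cutoff and match the
           closed-form linear-Gaussian bounds", {
  set.seed(101)
  n <- 30
  t <- sort(runif(n, 0.5, 15))
  y <- cummax(-0.3 * t^2 + 12 * t + 3 + rnorm(n, 0, 5))
  b <- bite_sequence("lin", t, pmax(y, 0.1))
  f <- fit_model(b, "quadratic")
  expect_gt(f$sse / n, f$sigma_min^2)   # floor inactive: noise dominates
  f <- profile_cis(f, b)

  # closed form: with sigma profiled, the bound solves
  # SSE(v) = SSE_hat * exp(qchisq(0.95, 1)/n), and for a linear model
  # SSE(v) = SSE_hat + (v - est)^2 / [(X'X)^-1]_jj
  X <- cbind(1, t, t^2)
  V <- diag(solve(crossprod(X)))
  q <- qchisq(0.95, 1)
  for (j in 1:3) {
    param <- c("c", "b", "a")[j]
    est <- f$ci$estimate[f$ci$param == param]
    half <- unname(sqrt(f$sse * (exp(q / n) - 1) * V[j]))
    expect_equal(f$ci$lower[f$ci$param == param], est - half,
                 tolerance = 3e-4)
    expect_equal(f$ci$upper[f$ci$param == param], est + half,
                 tolerance = 3e-4)
  }

  # the reported bounds satisfy the profile-likelihood cutoff equation
  for (param in c("a", "b", "c")) {
    for (side in c("lower", "upper")) {
      v <- f$ci[[side]][f$ci$param == param]
      drop <- 2 * (f$loglik - bitecurve:::profile_loglik(f, b, param, v))
      expect_equal(drop, q, tolerance = 2e-2)
    }
  }
})

test_that("noise-free confidence intervals contain the truth and shrink
           with bite count", {
  widths <- sapply(c(10, 20, 40), function(n) {
    cs <- lode_case(n = n, total = 300)
    f <- profile_cis(fit_model(cs$bites, "lode", emax = 330), cs$bites)
    ci <- f$ci
    expect_true(all(ci$lower <= c(30, 0.15) & c(30, 0.15) <= ci$upper))
    ci$upper[ci$param == "r"] - ci$lower[ci$param == "r"]
  })
  expect_true(all(diff(widths) < 0))
})

test_that("fitting data generated from a fitted curve returns the same
           estimates (parametric-bootstrap fixed point)", {
  cs <- lode_case(theta = 20, r = 0.2, emax = 350, n = 25, total = 320)
  f1 <- fit_model(cs$bites, "lode", emax = 350)
  regen <- bite_sequence("boot", cs$bites$times,
                         lode_intake(f1$estimates, cs$bites$times))
  f2 <- fit_model(regen, "lode", emax = 350)
  expect_equal(f2$estimates$theta, f1$estimates$theta, tolerance = 1e-5)
  expect_equal(f2$estimates$r, f1$estimates$r, tolerance = 1e-5)
})

test_that("profiling a constrained parameter censors at the positivity
           boundary instead of crossing it", {
  # two bites' worth of information on theta: wide interval, but the lower
  # bound can never go below zero
  cs <- lode_case(n = 6, total = 60, emax = 80, theta = 5, r = 0.05)
  f <- profile_cis(fit_model(cs$bites, "lode", emax = 80), cs$bites)
  expect_true(all(f$ci$lower >= 0))
})

test_that("free-asymptote fits recover an exact asymptote above the total", {
  cs <- lode_case(theta = 25, r = 0.2, emax = 360, n = 35, total = 300)
  f <- fit_model(cs$bites, "lode", emax = "free")
  expect_equal(f$estimates$emax, 360, tolerance = 1e-2)
  expect_equal(f$estimates$theta, 25, tolerance = 1e-2)
  expect_gt(f$estimates$emax, 300)
})
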