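test_that("quadratic forward evaluation matches direct arithmetic", {
  expect_equal(quadratic_intake(quadratic_params(0, 0, 5), 7), 5)
  expect_equal(quadratic_intake(quadratic_params(0, 20, 0), 3), 60)
  # -0.5 * 100 + 20 * 10 + 0
  expect_equal(quadratic_intake(quadratic_params(-0.5, 20, 0), 10), 150)
  expect_identical(quadratic_intake(quadratic_params(-0.5, 20, 3), 0), 3)
  expect_error(quadratic_params(NA, 1, 1), "finite")
  expect_error(quadratic_intake(quadratic_params(0, 1, 0), -1), ">= 0")
})

test_that("quadratic inversion selects the increasing branch and flags
           unreachable intake", {
  p <- quadratic_params(-0.5, 20, 0)
  expect_equal(quadratic_time(quadratic_params(0, 20, 0), 60), 3)
  expect_equal(quadratic_time(p, 150), 10)
  # curve maximum is b^2/(-4a) + c = 200 g: beyond it there is no real root
  expect_true(is.na(quadratic_time(p, 300)))
  # negative selected root is a non-feasible marker, not an error
  expect_true(is.na(quadratic_time(quadratic_params(-0.5, -20, 0), 10)))
  expect_error(quadratic_time(quadratic_params(0, 0, 5), 10), "degenerate")
})

test_that("quadratic round trip is the identity on the increasing branch", {
  for (p in random_quadratic_params(50, seed = 11)) {
    t_vertex <- -p$b / (2 * p$a)
    t <- seq(0.02, 0.98, length.out = 20) * t_vertex
    e <- quadratic_intake(p, t)
    ok <- e >= 0
    expect_equal(quadratic_time(p, e[ok]), t[ok], tolerance = 1e-8)
  }
})

test_that("lode_k matches its closed form and limits", {
  expect_equal(lode_k(lode_params(10, 0.3, 300)), 1 / 3)
  expect_equal(lode_k(lode_params(1e-9, 0.3, 300)), 0.3, tolerance = 1e-10)
  expect_equal(lode_k(lode_params(300, 1e-12, 300)), 1, tolerance = 1e-10)
  expect_error(lode_params(10, 0.3, 0), "> 0")
})

test_that("lode forward curve starts at zero, saturates at emax, and is
           numerically stable for large k*t", {
  p <- lode_params(10, 0.3, 300)
  expect_identical(lode_intake(p, 0), 0)
  expect_equal(lode_intake(p, 5), 90.1289, tolerance = 1e-5)
  expect_equal(lode_intake(p, 1e6), 300)         # asymptote, no overflow
  for (q in random_lode_params(30, seed = 3)) {
    t <- seq(0, 10 / lode_k(q), length.out = 50)
    e <- lode_intake(q, t)
    expect_true(all(diff(e) > 0))
    expect_true(all(e < q$emax))
  }
})

test_that("lode inversion is the exact inverse, with censored asymptote and
           non-feasible markers at the boundaries", {
  p <- lode_params(10, 0.3, 300)
  expect_identical(lode_time(p, 0), 0)
  expect_equal(lode_time(p, lode_intake(p, 5)), 5, tolerance = 1e-10)
  expect_true(is.finite(lode_time(p, 299.9999)))
  expect_identical(lode_time(p, 300), Inf)       # asymptote: censored
  expect_true(is.na(lode_time(p, 301)))          # beyond: non-feasible
  expect_true(is.na(lode_time(p, -1)))
  for (q in random_lode_params(50, seed = 5)) {
    k <- lode_k(q)
    t <- seq(1e-3, 10 / k, length.out = 20)
    expect_equal(lode_time(q, lode_intake(q, t)), t, tolerance = 1e-8)
  }
})

test_that("lode closed form solves the underlying logistic rate ODE", {
  for (q in random_lode_params(8, seed = 9)) {
    k <- lode_k(q)
    times <- seq(0, 8 / k, length.out = 40)
    sol <- deSolve::ode(
      y = c(E = 0), times = times,
      func = function(t, y, parms)
        list((q$theta + q$r * y) * (1 - y / q$emax)),
      parms = NULL, rtol = 1e-10, atol = 1e-10)
    expect_equal(lode_intake(q, times[-1]), unname(sol[-1, "E"]),
                 tolerance = 1e-6)
  }
})

test_that("feasibility classification implements the 10% convergence rule", {
  f <- classify_feasibility(time = 1:20, intake = seq(5, 100, by = 5))
  expect_identical(f$n_nonfeasible, 0L)
  expect_true(f$convergent)

  tt <- as.numeric(1:20); tt[c(3, 7)] <- NA      # 2/20 = 10%: still convergent
  expect_true(classify_feasibility(time = tt)$convergent)
  tt[12] <- NA                                   # 3/20 = 15%: non-convergent
  f <- classify_feasibility(time = tt)
  expect_false(f$convergent)
  expect_identical(f$n_nonfeasible, 3L)

  # per-bite reason categories
  f <- classify_feasibility(time = c(-1, 2, 1.5, NA, 5),
                            intake = c(10, 20, 30, 40, 50))
  expect_identical(f$reasons[1], "negative-time")
  expect_identical(f$reasons[3], "decreasing-intake")
  expect_identical(f$reasons[4], "inversion-failure")
  f <- classify_feasibility(intake = c(5, -2, 10))
  expect_identical(f$reasons[2], "negative-intake")

  # an infinite timing at the asymptote is censored, not non-feasible
  f <- classify_feasibility(time = c(1, 2, Inf))
  expect_identical(f$reasons[3], "asymptote")
  expect_identical(f$n_nonfeasible, 0L)

  expect_error(classify_feasibility(), "at least one")
  expect_error(classify_feasibility(time = numeric(0)), "empty")
})

test_that("LODE predictions over the open intake range are always feasible", {
  for (q in random_lode_params(25, seed = 13)) {
    e <- seq(0, 0.999, length.out = 40) * q$emax
    f <- classify_feasibility(time = lode_time(q, e))
    expect_identical(f$n_nonfeasible, 0L)
  }
})
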