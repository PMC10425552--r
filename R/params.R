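#' Quadratic cumulative-intake model parameters
#'
#' Bundles the three coefficients of the quadratic cumulative intake curve
#' `E(t) = a*t^2 + b*t + c`, where `E(t)` is total gram intake at time `t`
#' (minutes) within a meal. The linear coefficient `b` reflects the initial
#' eating rate (g/min), the quadratic coefficient `a` the change in eating
#' rate across the eating episode (g/min^2; `a < 0` marks a decelerating,
#' satiating-phase curve), and the intercept `c` (g) is a non-interpreted
#' fit term. The sign of `a` is recorded, not enforced.
#'
#' @param a quadratic coefficient (g/min^2)
#' @param b linear coefficient (g/min)
#' @param c intercept (g)
#' @return An object of class `c("quadratic_params", "intake_params")`.
#' @seealso [lode_params()], [quadratic_intake()], [quadratic_time()]
#' @export
#' @examples
#' quadratic_params(a = -0.5, b = 20, c = 0)
quadratic_params <- function(a, b, c) {
  vals <- c(a = a, b = b, c = c)
  if (length(vals) != 3L || !all(is.finite(vals)))
    stop("invalid quadratic parameters: a, b, c must be finite scalars",
         call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c)),
            class = c("quadratic_params", "intake_params"))
}

#' Logistic-ODE (LODE) cumulative-intake model parameters
#'
#' Parameters of the logistic ordinary-differential-equation intake model
#' `dE/dt = (theta + r*E) * (1 - E/emax)`: `theta` is the non-zero initial
#' eating rate (the "initial state", g/min), `r` the doubling rate (1/min;
#' `1/r` approximates the time taken to double intake), and `emax` the
#' asymptotic total gram intake of the eating episode. The derived
#' exponential-decay rate constant is `k = (emax*r + theta)/emax`
#' (see [lode_k()]).
#'
#' @param theta initial eating rate (g/min), must be > 0
#' @param r doubling rate (1/min), must be > 0
#' @param emax asymptotic total intake (g), must be > 0
#' @return An object of class `c("lode_params", "intake_params")`.
#' @seealso [quadratic_params()], [lode_intake()], [lode_time()]
#' @export
#' @examples
#' lode_params(theta = 10, r = 0.3, emax = 300)
lode_params <- function(theta, r, emax) {
  vals <- c(theta = theta, r = r, emax = emax)
  if (length(vals) != 3L || !all(is.finite(vals)) || any(vals <= 0))
    stop("invalid LODE parameters: theta, r, emax must be finite and > 0",
         call. = FALSE)
  structure(list(theta = as.numeric(theta), r = as.numeric(r),
                 emax = as.numeric(emax)),
            class = c("lode_params", "intake_params"))
}

#' @export
print.quadratic_params <- function(x, ...) {
  cat(sprintf("Quadratic intake model: E(t) = %.4g t^2 + %.4g t + %.4g\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' @export
print.lode_params <- function(x, ...) {
  cat(sprintf(
    "LODE intake model: theta = %.4g g/min, r = %.4g /min, emax = %.4g g (k = %.4g)\n",
    x$theta, x$r, x$emax, lode_k(x)))
  invisible(x)
}

#' @export
as.double.quadratic_params <- function(x, ...) c(a = x$a, b = x$b, c = x$c)

#' @export
as.double.lode_params <- function(x, ...) c(theta = x$theta, r = x$r, emax = x$emax)

# named parameter vector (as.numeric() strips names through as.double dispatch
# in some call paths, so internal code uses this)
param_vec <- function(x) {
  if (inherits(x, "quadratic_params")) c(a = x$a, b = x$b, c = x$c)
  else if (inherits(x, "lode_params")) c(theta = x$theta, r = x$r, emax = x$emax)
  else stop("not an intake_params object", call. = FALSE)
}

# names of the free (profiled) parameters for each model tag
free_param_names <- function(model) {
  switch(model,
         quadratic = c("a", "b", "c"),
         lode = c("theta", "r"),
         stop("unknown model tag: ", model, call. = FALSE))
}

check_model_tag <- function(model) {
  model <- match.arg(model, c("quadratic", "lode"))
  model
}
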