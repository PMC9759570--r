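#' Elimination-curve parameters
#'
#' Container for the two parameters of the single-peak elimination curve
#' \eqn{x(t) = t \cdot e^{B - A t}}: the rate-like parameter \eqn{A} (1/h),
#' which controls the exponential decay and fixes the peak time at
#' \eqn{1/A}, and the log-amplitude \eqn{B} (dimensionless on the log
#' scale; \eqn{e^B} carries the concentration-per-time units).
#'
#' @param A Elimination-rate-like parameter, 1/h. Must be strictly positive.
#' @param B Log-amplitude parameter. Must be finite.
#'
#' @return An object of class \code{pk_params}.
#' @examples
#' p <- pk_params(A = 2.168, B = 5.397)
#' evaluate_curve(1, p)
#' @export
pk_params <- function(A, B) {
  stopifnot(is.numeric(A), length(A) == 1L, is.numeric(B), length(B) == 1L)
  if (!is.finite(A) || A <= 0) {
    stop("'A' must be finite and strictly positive, got ", A)
  }
  if (!is.finite(B)) {
    stop("'B' must be finite, got ", B)
  }
  structure(list(A = as.numeric(A), B = as.numeric(B)), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("Elimination-curve parameters: A = %.4g 1/h, B = %.4g\n",
              x$A, x$B))
  invisible(x)
}

#' Evaluate the elimination curve
#'
#' Computes the concentration \eqn{x(t) = t \cdot e^{B - A t}} at the
#' requested times. The curve starts at zero, rises to a single maximum at
#' \eqn{t = 1/A} and then decays exponentially.
#'
#' @param t Time(s) in hours, non-negative. Vectorized.
#' @param params A \code{\link{pk_params}} object.
#'
#' @return Concentration(s) in ng/ml, same length as \code{t}.
#' @export
evaluate_curve <- function(t, params) {
  stopifnot(inherits(params, "pk_params"), is.numeric(t))
  if (any(t < 0)) {
    stop("negative time: the curve is defined for t >= 0")
  }
  t * exp(params$B - params$A * t)
}

#' Right-hand side of the elimination ODE
#'
#' The curve is the solution of \eqn{\dot{x} = (1 - A t) e^{B - A t}} with
#' \eqn{x(0) = 0}; this evaluates that time derivative. It is the exact
#' derivative of \code{\link{evaluate_curve}}.
#'
#' @inheritParams evaluate_curve
#' @return Rate of concentration change, ng/ml/h.
#' @export
ode_rhs <- function(t, params) {
  stopifnot(inherits(params, "pk_params"), is.numeric(t))
  (1 - params$A * t) * exp(params$B - params$A * t)
}

#' Time of peak concentration
#'
#' Closed form \eqn{t_{peak} = 1/A}, the unique stationary point of the
#' curve. \code{peak_time_numeric} maximizes the curve numerically and is
#' provided as a cross-check of the closed form.
#'
#' @param params A \code{\link{pk_params}} object.
#' @return Peak time in hours.
#' @export
peak_time <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  1 / params$A
}

#' @rdname peak_time
#' @param upper Upper end of the search interval, h.
#' @export
peak_time_numeric <- function(params, upper = 6) {
  stopifnot(inherits(params, "pk_params"))
  opt <- stats::optimize(function(t) -evaluate_curve(t, params),
                         interval = c(0, max(upper, 2 / params$A)),
                         tol = 1e-12)$minimum
  # polish to full precision on the stationary condition x'(t) = 0
  stats::uniroot(function(t) ode_rhs(t, params),
                 lower = opt / 2, upper = opt * 2, tol = 1e-14)$root
}

#' Peak concentration
#'
#' Concentration at the peak, \eqn{x_{peak} = x(t_{peak}) = e^{B-1}/A}.
#'
#' @param params A \code{\link{pk_params}} object.
#' @return Peak concentration, ng/ml.
#' @export
peak_concentration <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  exp(params$B - 1) / params$A
}

#' Elimination half-life
#'
#' Time for the concentration to fall from its peak to half the peak:
#' \eqn{x(t) = x_{peak}/2} is solved for the unique root \eqn{t > t_{peak}}
#' with a bracketed root-finder and the half-life is \eqn{t - t_{peak}}.
#' The result depends only on \eqn{A} (it scales as \eqn{1/A}); \eqn{B}
#' cancels.
#'
#' @param params A \code{\link{pk_params}} object.
#' @return Half-life in hours.
#' @export
half_life <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  tp <- peak_time(params)
  half <- peak_concentration(params) / 2
  f <- function(t) evaluate_curve(t, params) - half
  hi <- tp + 60 / params$A
  if (f(hi) >= 0) {
    stop("half-life root not bracketed in [t_peak, t_peak + 60/A]")
  }
  root <- stats::uniroot(f, lower = tp, upper = hi, tol = 1e-10)$root
  root - tp
}

#' Decay-phase area under the curve
#'
#' Integral of the fitted curve from the peak time to \code{t_end}
#' (default 6 h, the last scheduled sampling time). Computed from the
#' closed-form antiderivative
#' \eqn{e^B [-(t/A + 1/A^2) e^{-A t}]} evaluated at the bounds.
#'
#' @param params A \code{\link{pk_params}} object.
#' @param t_end End of integration, h; must exceed the peak time.
#' @return Area under the curve, ng*h/ml.
#' @export
auc_decay <- function(params, t_end = 6) {
  stopifnot(inherits(params, "pk_params"), is.numeric(t_end),
            length(t_end) == 1L)
  tp <- peak_time(params)
  if (t_end <= tp) {
    stop(sprintf("t_end (%.4g h) must exceed the peak time (%.4g h)",
                 t_end, tp))
  }
  A <- params$A
  antider <- function(t) -exp(params$B) * (t / A + 1 / A^2) * exp(-A * t)
  antider(t_end) - antider(tp)
}

#' Derived pharmacokinetic quantities from fitted parameters
#'
#' Bundles peak time, peak concentration, half-life and decay-phase AUC
#' extracted from one fitted elimination curve.
#'
#' @param params A \code{\link{pk_params}} object.
#' @param t_end AUC integration end, h.
#' @param sse Residual sum of squares of the generating fit (0 for exact
#'   parameters).
#' @return An object of class \code{pk_derived}: a list with fields
#'   \code{t_peak}, \code{x_peak}, \code{t_half}, \code{auc}, \code{sse}
#'   and the generating \code{params}.
#' @export
pk_derived <- function(params, t_end = 6, sse = 0) {
  structure(list(
    t_peak = peak_time(params),
    x_peak = peak_concentration(params),
    t_half = half_life(params),
    auc    = auc_decay(params, t_end = t_end),
    sse    = sse,
    params = params
  ), class = "pk_derived")
}

#' @export
print.pk_derived <- function(x, ...) {
  cat(sprintf(paste0(
    "Derived PK quantities (A = %.4g, B = %.4g):\n",
    "  t_peak = %.4g h, x_peak = %.4g ng/ml\n",
    "  t_1/2  = %.4g h, AUC(decay) = %.4g ng*h/ml\n"),
    x$params$A, x$params$B, x$t_peak, x$x_peak, x$t_half, x$auc))
  invisible(x)
}
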