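#' One animal x analyte concentration time course
#'
#' A single replicate's measured drug (or metabolite) concentrations at the
#' scheduled micro-sampling times. The pre-dose sample at t = 0 is kept with
#' value 0; post-dose values below the assay's limit of quantification can
#' be flagged with \code{below_loq} and are then excluded from fitting.
#'
#' @param animal_id Animal identifier.
#' @param group Dietary condition, one of \code{"control"},
#'   \code{"hfd_2wk"}, \code{"hfd_4wk"}.
#' @param analyte Analyte name (e.g. \code{"midazolam"}, \code{"caffeine"},
#'   \code{"codeine"} or a metabolite).
#' @param time_h Sampling times in hours, strictly increasing, >= 0.
#' @param conc_ng_ml Concentrations in ng/ml, same length as \code{time_h},
#'   non-negative.
#' @param below_loq Optional logical flag per sample; \code{TRUE} marks a
#'   value below the limit of quantification.
#' @param loq Optional scalar limit of quantification, ng/ml.
#'
#' @return An object of class \code{conc_series}.
#' @export
conc_series <- function(animal_id, group, analyte, time_h, conc_ng_ml,
                        below_loq = NULL, loq = NA_real_) {
  group <- match.arg(group, c("control", "hfd_2wk", "hfd_4wk"))
  stopifnot(length(time_h) == length(conc_ng_ml))
  if (any(time_h < 0)) stop("negative sampling time")
  if (any(diff(time_h) <= 0)) {
    stop("sampling times must be strictly increasing")
  }
  if (is.null(below_loq)) below_loq <- rep(FALSE, length(time_h))
  stopifnot(is.logical(below_loq), length(below_loq) == length(time_h))
  if (any(conc_ng_ml < 0 & !below_loq)) {
    stop("negative concentration not flagged below LOQ")
  }
  structure(list(
    animal_id = as.character(animal_id),
    group = group,
    analyte = as.character(analyte),
    time_h = as.numeric(time_h),
    conc_ng_ml = as.numeric(conc_ng_ml),
    below_loq = below_loq,
    loq = as.numeric(loq)
  ), class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("Concentration series: animal %s (%s), %s; %d time points\n",
              x$animal_id, x$group, x$analyte, length(x$time_h)))
  invisible(x)
}

# quantifiable post-dose points used for fitting
fit_points <- function(series) {
  keep <- series$time_h > 0 & !series$below_loq
  list(t = series$time_h[keep], c = series$conc_ng_ml[keep])
}

#' Initial parameter guess from a time course
#'
#' Heuristic starting values for the least-squares fit: the rate parameter
#' is taken from the log-linear slope of \eqn{\ln(c/t)} over the last three
#' quantifiable points (on the decay limb, \eqn{\ln(c/t) = B - A t}),
#' clamped to \[0.05, 50\]; the amplitude is then solved so the curve passes
#' through the observed maximum.
#'
#' @param series A \code{\link{conc_series}}.
#' @return A \code{\link{pk_params}} starting guess.
#' @export
init_guess <- function(series) {
  stopifnot(inherits(series, "conc_series"))
  pts <- fit_points(series)
  pos <- pts$c > 0
  if (sum(pos) < 3) {
    stop("need at least 3 quantifiable positive post-dose points")
  }
  tt <- pts$t[pos]
  cc <- pts$c[pos]
  n <- length(tt)
  tail_idx <- (n - 2):n
  slope <- stats::coef(stats::lm(log(cc[tail_idx] / tt[tail_idx])
                                 ~ tt[tail_idx]))[[2]]
  A0 <- min(max(-slope, 0.05), 50)
  imax <- which.max(cc)
  B0 <- log(cc[imax] / tt[imax]) + A0 * tt[imax]
  pk_params(A0, B0)
}

#' Per-replicate least-squares fit of the elimination curve
#'
#' Estimates (A, B) for one replicate by minimizing the residual sum of
#' squares \eqn{\sum_k (x(t_k; A, B) - c_k)^2} on the linear concentration
#' scale, via Levenberg-Marquardt with box constraints \[1e-6, 100\] on both
#' parameters (the same box as the Bayesian prior). Five starts are used:
#' the \code{\link{init_guess}} heuristic plus four seeded perturbations;
#' the lowest-SSE solution wins, so the result is deterministic given the
#' series and seed.
#'
#' @param series A \code{\link{conc_series}} with at least 3 quantifiable
#'   post-dose points.
#' @param seed Integer seed for the multistart perturbations.
#' @param n_starts Number of starts (first is the heuristic guess).
#' @return An object of class \code{fit_result}: list with \code{params}
#'   (\code{\link{pk_params}}), \code{sse}, \code{n_points},
#'   \code{converged}, and \code{message}.
#' @export
fit_replicate <- function(series, seed = 1L, n_starts = 5L) {
  stopifnot(inherits(series, "conc_series"))
  pts <- fit_points(series)
  if (length(pts$t) < 3) {
    stop("need at least 3 quantifiable post-dose points to fit")
  }
  guess <- init_guess(series)
  starts <- matrix(c(guess$A, guess$B), nrow = 1)
  if (n_starts > 1) {
    jit <- with_seed(seed, {
      cbind(guess$A * exp(stats::rnorm(n_starts - 1, 0, 0.5)),
            guess$B + stats::rnorm(n_starts - 1, 0, 1))
    })
    starts <- rbind(starts, jit)
  }
  starts[, 1] <- pmin(pmax(starts[, 1], 1e-6), 100)
  starts[, 2] <- pmin(pmax(starts[, 2], 1e-6), 100)

  resid_fn <- function(par) {
    pts$t * exp(par[2] - par[1] * pts$t) - pts$c
  }
  best <- NULL
  any_converged <- FALSE
  msg <- ""
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = c(1e-6, 1e-6), upper = c(100, 100),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    ok <- fit$info %in% 1:4
    any_converged <- any_converged || ok
    if (is.null(best) || sse < best$sse) {
      best <- list(par = fit$par, sse = sse, info = fit$info,
                   message = fit$message)
    }
  }
  if (is.null(best)) {
    stop("all optimizer starts failed for animal ", series$animal_id)
  }
  structure(list(
    params = pk_params(best$par[1], best$par[2]),
    sse = best$sse,
    n_points = length(pts$t),
    converged = any_converged,
    message = best$message
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Least-squares fit: A = %.4f, B = %.4f (SSE = %.3g, %d points%s)\n",
              x$params$A, x$params$B, x$sse, x$n_points,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fit a replicate and extract derived PK quantities
#'
#' Composes \code{\link{fit_replicate}} with the derived-quantity
#' calculations: peak time, peak concentration, half-life and the
#' decay-phase AUC integrated to \code{t_end}.
#'
#' @inheritParams fit_replicate
#' @param t_end AUC integration end, h (default 6, the last scheduled
#'   sampling time).
#' @return A \code{\link{pk_derived}} object carrying the fit's SSE.
#' @export
derive_pk <- function(series, t_end = 6, seed = 1L) {
  fit <- fit_replicate(series, seed = seed)
  if (!fit$converged) {
    warning("fit did not converge for animal ", series$animal_id)
  }
  pk_derived(fit$params, t_end = t_end, sse = fit$sse)
}
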