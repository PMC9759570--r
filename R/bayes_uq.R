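#' Uniform prior box for (A, B, sigma)
#'
#' The default reproduces the study's priors: A and B uniform on
#' \[0, 100\], the noise standard deviation sigma uniform on \[0, 1000\]
#' ng/ml.
#'
#' @param a_bounds Interval for A, 1/h.
#' @param b_bounds Interval for B.
#' @param sigma_bounds Interval for sigma, ng/ml.
#' @return An object of class \code{prior_spec}.
#' @export
prior_spec <- function(a_bounds = c(0, 100), b_bounds = c(0, 100),
                       sigma_bounds = c(0, 1000)) {
  chk <- function(b, nm) {
    if (length(b) != 2 || b[1] >= b[2] || b[1] < 0) {
      stop("invalid bounds for ", nm)
    }
    as.numeric(b)
  }
  structure(list(a_bounds = chk(a_bounds, "A"),
                 b_bounds = chk(b_bounds, "B"),
                 sigma_bounds = chk(sigma_bounds, "sigma")),
            class = "prior_spec")
}

# common time grid of a replicate list, erroring on mismatch
common_grid <- function(replicates) {
  stopifnot(length(replicates) >= 1)
  grid <- replicates[[1]]$time_h
  for (s in replicates) {
    stopifnot(inherits(s, "conc_series"))
    if (length(s$time_h) != length(grid) ||
        any(abs(s$time_h - grid) > 1e-9)) {
      stop("replicates must share a common time grid")
    }
  }
  grid
}

# N x T measurement matrix
measurement_matrix <- function(replicates) {
  do.call(rbind, lapply(replicates, function(s) s$conc_ng_ml))
}

#' Pooled Gaussian log-likelihood of the elimination curve
#'
#' Log of the likelihood
#' \deqn{L(\theta, \sigma) = \prod_{j=1}^{N} \prod_{k=1}^{T}
#'   \frac{1}{\sqrt{2\pi}\sigma}
#'   \exp\!\left(-\frac{(x(t_k,\theta) - m_j(t_k))^2}{2\sigma^2}\right)}
#' for N replicates measured on a shared grid of T time points, with
#' independent additive normal noise and a single sigma shared across
#' replicates within a condition.
#'
#' @param params A \code{\link{pk_params}} object (the shared curve).
#' @param sigma Noise standard deviation, ng/ml, > 0.
#' @param replicates List of \code{\link{conc_series}} sharing one grid.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, sigma, replicates) {
  stopifnot(inherits(params, "pk_params"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  grid <- common_grid(replicates)
  m <- measurement_matrix(replicates)
  x <- evaluate_curve(grid, params)
  sum(stats::dnorm(m, mean = matrix(x, nrow(m), ncol(m), byrow = TRUE),
                   sd = sigma, log = TRUE))
}

#' Log-posterior under the uniform prior box
#'
#' \code{\link{log_likelihood}} plus a flat prior: 0 inside the box,
#' \code{-Inf} outside.
#'
#' @inheritParams log_likelihood
#' @param prior A \code{\link{prior_spec}}.
#' @return Scalar log-posterior (unnormalized).
#' @export
log_posterior <- function(params, sigma, replicates, prior = prior_spec()) {
  stopifnot(inherits(prior, "prior_spec"))
  inside <- params$A >= prior$a_bounds[1] && params$A <= prior$a_bounds[2] &&
    params$B >= prior$b_bounds[1] && params$B <= prior$b_bounds[2] &&
    sigma >= max(prior$sigma_bounds[1], .Machine$double.xmin) &&
    sigma <= prior$sigma_bounds[2]
  if (!inside) return(-Inf)
  log_likelihood(params, sigma, replicates)
}

#' Sample the pooled posterior with adaptive parallel tempering
#'
#' Random-walk Metropolis over (A, B, sigma) on a geometric temperature
#' ladder (inverse temperatures from 1 down to \code{beta_min} across
#' \code{n_chains} rungs), with component-wise Gaussian proposals whose
#' scales adapt by Robbins-Monro towards 23.4\% acceptance during the
#' adaptation phase only, and adjacent-rung swap proposals every
#' \code{swap_every} iterations. The cold chain is retained; burn-in is
#' set by \code{\link{geweke_burnin}} (minimum cut 100) and per-parameter
#' effective sample sizes are recorded. Fully reproducible given
#' \code{seed}.
#'
#' @param replicates List of \code{\link{conc_series}} on one grid.
#' @param prior A \code{\link{prior_spec}}.
#' @param n_samples Number of MCMC iterations (cold-chain draws before
#'   burn-in removal). The study-scale budget is 200,000; the default
#'   20,000 is the desk-scale budget.
#' @param n_chains Number of tempered chains (default 4).
#' @param seed Integer seed.
#' @param beta_min Smallest inverse temperature of the ladder.
#' @param swap_every Iterations between swap proposals.
#' @param adapt_frac Fraction of the run over which proposal scales adapt.
#' @return An object of class \code{posterior_ensemble}: list with
#'   \code{samples} (matrix, columns A, B, sigma; cold chain after
#'   burn-in), \code{n_chains}, \code{n_samples_requested},
#'   \code{burn_in_index}, \code{ess} (per parameter), \code{acceptance}
#'   (cold-chain per-parameter rates), \code{swap_rate}, and \code{seed}.
#' @export
sample_posterior <- function(replicates, prior = prior_spec(),
                             n_samples = 20000L, n_chains = 4L,
                             seed = 1L, beta_min = 0.1,
                             swap_every = 100L, adapt_frac = 0.25) {
  stopifnot(inherits(prior, "prior_spec"), n_samples > 400,
            n_chains >= 2)
  grid <- common_grid(replicates)
  m <- measurement_matrix(replicates)
  if (max(m) - min(m) < .Machine$double.eps) {
    stop("degenerate data: all concentrations identical")
  }
  n_rep <- nrow(m)
  s1 <- colSums(m)
  s2 <- colSums(m^2)

  betas <- beta_min^(seq(0, 1, length.out = n_chains))

  # data-informed initial states, jittered per chain
  f0 <- fit_replicate(replicates[[1]], seed = seed)
  resid_sd <- stats::sd(as.vector(
    m - matrix(evaluate_curve(grid, f0$params), n_rep, length(grid),
               byrow = TRUE)))
  sigma0 <- max(resid_sd, 1e-3)
  clamp <- function(x, b) pmin(pmax(x, b[1] + 1e-8), b[2] - 1e-8)
  out <- with_seed(seed, {
    init <- cbind(
      clamp(f0$params$A * exp(stats::rnorm(n_chains, 0, 0.1)),
            prior$a_bounds),
      clamp(f0$params$B + stats::rnorm(n_chains, 0, 0.1), prior$b_bounds),
      clamp(sigma0 * exp(stats::rnorm(n_chains, 0, 0.1)),
            prior$sigma_bounds))
    scales0 <- matrix(rep(c(0.1, 0.1, sigma0 / 4), each = n_chains),
                      n_chains, 3)
    pt_sample_cpp(grid, s1, s2, n_rep, betas, as.integer(n_samples),
                  init, scales0,
                  lower = c(prior$a_bounds[1], prior$b_bounds[1],
                            max(prior$sigma_bounds[1], 1e-12)),
                  upper = c(prior$a_bounds[2], prior$b_bounds[2],
                            prior$sigma_bounds[2]),
                  as.integer(swap_every),
                  as.integer(round(adapt_frac * n_samples)))
  })
  cold <- out$cold_samples
  colnames(cold) <- c("A", "B", "sigma")
  burn <- geweke_burnin(cold, min_cut = 100L)
  kept <- cold[(burn + 1):nrow(cold), , drop = FALSE]
  ess <- apply(kept, 2, effective_sample_size)
  structure(list(
    samples = kept,
    n_chains = as.integer(n_chains),
    n_samples_requested = as.integer(n_samples),
    burn_in_index = burn,
    ess = ess,
    acceptance = out$acceptance[1, ],
    swap_rate = out$swap_rate,
    seed = seed
  ), class = "posterior_ensemble")
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat(sprintf(paste0(
    "Posterior ensemble: %d retained draws (%d requested, burn-in %d)\n",
    "  posterior means: A = %.4g, B = %.4g, sigma = %.4g\n",
    "  ESS: A = %.0f, B = %.0f, sigma = %.0f\n"),
    nrow(x$samples), x$n_samples_requested, x$burn_in_index,
    mean(x$samples[, "A"]), mean(x$samples[, "B"]),
    mean(x$samples[, "sigma"]),
    x$ess["A"], x$ess["B"], x$ess["sigma"]))
  invisible(x)
}

# Geweke z-scores for one cut: leading 10% vs trailing 50% of the
# remaining chain, variances via AR-fit spectral density at frequency zero.
geweke_z <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  n <- nrow(chain)
  i1 <- seq_len(max(2, floor(frac1 * n)))
  i2 <- seq.int(n - floor(frac2 * n) + 1, n)
  vapply(seq_len(ncol(chain)), function(p) {
    x1 <- chain[i1, p]; x2 <- chain[i2, p]
    s1 <- spectrum0_ar(x1); s2 <- spectrum0_ar(x2)
    # a window whose apparent autocorrelation time rivals its own length
    # (e.g. one containing a level shift) carries no stationarity evidence
    if (s1 > stats::var(x1) * length(x1) / 10 ||
        s2 > stats::var(x2) * length(x2) / 10) {
      return(Inf)
    }
    (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
  }, numeric(1))
}

# spectral density at frequency 0 via AIC-selected AR fit
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE,
              order.max = min(length(x) - 1L, floor(10 * log10(length(x))))),
    error = function(e) NULL)
  if (is.null(fit)) return(v)
  if (fit$order == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke burn-in selection
#'
#' Scans candidate cut points from \code{min_cut} up to half the chain and
#' returns the first cut after which the Geweke stationarity z-score
#' (comparing the mean of the leading 10\% against the trailing 50\% of
#' the remaining chain, with spectral-density variance estimates) satisfies
#' |z| < 2 for every parameter. At least \code{min_cut} samples are always
#' cut, even when the diagnostic would allow fewer. If no candidate
#' passes, half the chain is cut and a warning is issued.
#'
#' @param chain Numeric matrix (iterations x parameters) or vector.
#' @param min_cut Minimum number of leading samples to discard.
#' @return Integer cut index (number of discarded leading samples), with
#'   attribute \code{converged} (logical).
#' @export
geweke_burnin <- function(chain, min_cut = 100L) {
  if (is.null(dim(chain))) chain <- matrix(chain, ncol = 1)
  n <- nrow(chain)
  if (n <= 2 * min_cut) {
    stop("chain too short: need length > 2 * min_cut")
  }
  cuts <- unique(as.integer(round(seq(min_cut, floor(n / 2),
                                      length.out = 21L))))
  for (cut in cuts) {
    z <- geweke_z(chain[(cut + 1):n, , drop = FALSE])
    if (all(is.finite(z)) && all(abs(z) < 2)) {
      return(structure(as.integer(cut), converged = TRUE))
    }
  }
  warning("Geweke criterion not met at any candidate cut; discarding half")
  structure(as.integer(floor(n / 2)), converged = FALSE)
}

#' Effective sample size
#'
#' Autocorrelation-adjusted number of independent-equivalent draws,
#' \eqn{N / (1 + 2 \sum_t \rho_t)}, with the autocorrelation sum truncated
#' by the initial-positive-sequence rule (summation stops before the first
#' non-positive sum of adjacent autocorrelation pairs). Capped at N.
#'
#' @param chain Numeric vector of at least 100 draws.
#' @return Scalar effective sample size.
#' @export
effective_sample_size <- function(chain) {
  stopifnot(is.numeric(chain))
  n <- length(chain)
  if (n < 100) stop("chain too short for ESS (need >= 100)")
  if (stats::var(chain) == 0) {
    stop("constant chain: autocorrelation undefined")
  }
  lag_max <- min(n - 1L, 2000L)
  rho <- as.vector(stats::acf(chain, lag.max = lag_max,
                              plot = FALSE)$acf)[-1]
  # Geyer initial positive sequence on pair sums rho[2m-1] + rho[2m]
  n_pairs <- floor(length(rho) / 2)
  s <- 0
  for (mpair in seq_len(n_pairs)) {
    g <- rho[2 * mpair - 1] + rho[2 * mpair]
    if (g <= 0) break
    s <- s + g
  }
  min(n, n / (1 + 2 * s))
}

#' Posterior-predictive credibility band for the concentration curve
#'
#' Simulates the elimination curve forward for every retained posterior
#' draw over a time grid and summarizes pointwise: the band is the
#' equal-tailed (e.g. 2.5th-97.5th percentile) interval and the center is
#' the pointwise mean. By default the band describes the model output
#' (noise-free curve); \code{include_noise = TRUE} adds a measurement-noise
#' draw per sample for a predictive band on new observations.
#'
#' @param ensemble A \code{\link{posterior_ensemble}}.
#' @param time_grid Times (h) at which to evaluate the band.
#' @param level Credibility level, in (0, 1).
#' @param include_noise Add N(0, sigma_i) observation noise per draw.
#' @param seed Seed for the noise draws (only used with
#'   \code{include_noise}).
#' @return An object of class \code{credibility_band}: list with
#'   \code{time_grid}, \code{lower}, \code{upper}, \code{center},
#'   \code{level}.
#' @export
posterior_predictive_band <- function(ensemble, time_grid, level = 0.95,
                                      include_noise = FALSE, seed = 1L) {
  stopifnot(inherits(ensemble, "posterior_ensemble"),
            level > 0, level < 1)
  draws <- ensemble$samples
  if (nrow(draws) == 0) stop("empty ensemble")
  curves <- vapply(time_grid, function(t) {
    t * exp(draws[, "B"] - draws[, "A"] * t)
  }, numeric(nrow(draws)))
  curves <- matrix(curves, nrow = nrow(draws))
  if (include_noise) {
    curves <- curves + with_seed(seed, {
      matrix(stats::rnorm(length(curves), 0,
                          rep(draws[, "sigma"], ncol(curves))),
             nrow(curves), ncol(curves))
    })
  }
  alpha <- (1 - level) / 2
  structure(list(
    time_grid = as.numeric(time_grid),
    lower = apply(curves, 2, stats::quantile, probs = alpha, names = FALSE),
    upper = apply(curves, 2, stats::quantile, probs = 1 - alpha,
                  names = FALSE),
    center = colMeans(curves),
    level = level
  ), class = "credibility_band")
}

#' Do two credibility bands overlap at a time point?
#'
#' Non-overlapping bands at a time point are read as a significant
#' difference between the two conditions' dynamics there. Intervals are
#' treated as closed, so touching bands count as overlapping (the
#' conservative call).
#'
#' @param b1,b2 \code{\link{credibility_band}} objects.
#' @param t Time point, must lie on both grids.
#' @return Logical: \code{TRUE} if the intervals intersect at \code{t}.
#' @export
bands_overlap_at <- function(b1, b2, t) {
  stopifnot(inherits(b1, "credibility_band"),
            inherits(b2, "credibility_band"))
  i1 <- which(abs(b1$time_grid - t) < 1e-9)
  i2 <- which(abs(b2$time_grid - t) < 1e-9)
  if (length(i1) != 1 || length(i2) != 1) {
    stop("t = ", t, " is not on both band grids")
  }
  b1$lower[i1] <= b2$upper[i2] && b2$lower[i2] <= b1$upper[i1]
}
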