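# --- moment-matched truncated normal -----------------------------------

# mean and sd of a normal(mu, sigma) truncated to [a, b]
truncnorm_moments <- function(mu, sigma, a, b) {
  alpha <- (a - mu) / sigma
  beta <- (b - mu) / sigma
  z <- stats::pnorm(beta) - stats::pnorm(alpha)
  da <- stats::dnorm(alpha)
  db <- stats::dnorm(beta)
  adb <- if (is.finite(alpha)) alpha * da else 0
  bdb <- if (is.finite(beta)) beta * db else 0
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (adb - bdb) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# parent (mu, sigma) such that the [a, b]-truncated normal has the target
# mean and sd; near-identity when the bounds are several sds away
truncnorm_match <- function(target_mean, target_sd, a, b) {
  if (target_sd == 0) return(list(mu = target_mean, sigma = 0))
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), a, b)
    ((mo$mean - target_mean) / target_sd)^2 +
      ((mo$sd - target_sd) / target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# inverse-CDF draws from a truncated normal given uniforms u in (0, 1)
qtruncnorm <- function(u, mu, sigma, a, b) {
  if (sigma == 0) return(rep(mu, length(u)))
  pa <- stats::pnorm(a, mu, sigma)
  pb <- stats::pnorm(b, mu, sigma)
  stats::qnorm(pa + u * (pb - pa), mu, sigma)
}

# --- configuration ------------------------------------------------------

#' Default synthetic-study configuration
#'
#' Returns the generator configuration calibrated to the study's printed
#' group summaries: per-group feature means and SDs (lipid-droplet,
#' micro- and macrovesicular surface percentages; hepatic triglycerides;
#' ex-vivo CYP activities), per-group per-analyte elimination-curve truth
#' (A, B) with peak times between 15 min and 1 h, per-analyte measurement
#' noise, the ten scheduled sampling times over six hours, limits of
#' quantification, and the default cohort size of 6 animals per group.
#'
#' Feature calibration (mean, SD): lipid droplets 9.3 +/- 1.3 (2 wk) and
#' 13.9 +/- 2.7 (4 wk); microvesicular surface 48.6 +/- 12.9 (2 wk) and
#' 33.4 +/- 10.2 (4 wk); macrovesicular surface 20.7 +/- 7.1 (2 wk) and
#' 39.9 +/- 8.6 (4 wk); triglycerides 99.6 +/- 42.3 (control),
#' 252.8 +/- 43.0 (2 wk) and 296.1 +/- 91.6 (4 wk) nmol/100 mg. Control
#' steatosis surfaces default to small positive values (1 +/- 0.5 \%) so
#' no feature column is degenerate. CYP activities carry the observed
#' directions (CYP3A and CYP1A activity lower under the diet, CYP2E1
#' roughly doubled at four weeks) at plausible magnitudes.
#'
#' @return An object of class \code{synth_config}: list with
#'   \code{groups}, \code{features} (per group: named means/sds),
#'   \code{feature_bounds}, \code{pk_truth} (per analyte x group: A, B),
#'   \code{sigma} (per analyte, ng/ml), \code{loq} (per analyte),
#'   \code{time_grid_h}, \code{n_per_group}.
#' @export
default_config <- function() {
  groups <- c("control", "hfd_2wk", "hfd_4wk")
  feat <- list(
    control = list(
      mean = c(lipid_droplet_pct = 1, micro_pct = 1, macro_pct = 1,
               tg_nmol_per_100mg = 99.6, cyp3a_emnd = 250,
               cyp1a_erod = 60, cyp2e1_pnph = 400),
      sd = c(lipid_droplet_pct = 0.5, micro_pct = 0.5, macro_pct = 0.5,
             tg_nmol_per_100mg = 42.3, cyp3a_emnd = 60,
             cyp1a_erod = 15, cyp2e1_pnph = 100)),
    hfd_2wk = list(
      mean = c(lipid_droplet_pct = 9.3, micro_pct = 48.6, macro_pct = 20.7,
               tg_nmol_per_100mg = 252.8, cyp3a_emnd = 210,
               cyp1a_erod = 45, cyp2e1_pnph = 550),
      sd = c(lipid_droplet_pct = 1.3, micro_pct = 12.9, macro_pct = 7.1,
             tg_nmol_per_100mg = 43.0, cyp3a_emnd = 55,
             cyp1a_erod = 12, cyp2e1_pnph = 120)),
    hfd_4wk = list(
      mean = c(lipid_droplet_pct = 13.9, micro_pct = 33.4, macro_pct = 39.9,
               tg_nmol_per_100mg = 296.1, cyp3a_emnd = 170,
               cyp1a_erod = 35, cyp2e1_pnph = 750),
      sd = c(lipid_droplet_pct = 2.7, micro_pct = 10.2, macro_pct = 8.6,
             tg_nmol_per_100mg = 91.6, cyp3a_emnd = 50,
             cyp1a_erod = 10, cyp2e1_pnph = 180)))
  bounds <- rbind(
    lipid_droplet_pct = c(0, 100), micro_pct = c(0, 100),
    macro_pct = c(0, 100), tg_nmol_per_100mg = c(0, Inf),
    cyp3a_emnd = c(0, Inf), cyp1a_erod = c(0, Inf),
    cyp2e1_pnph = c(0, Inf))
  colnames(bounds) <- c("lower", "upper")
  # elimination truth per analyte x group; A in [1, 4] keeps the peak
  # within 15-60 min; diet slows midazolam elimination and speeds
  # caffeine elimination, codeine essentially unchanged
  pk <- list(
    caffeine = list(control = c(A = 1.2, B = 7.0),
                    hfd_2wk = c(A = 1.5, B = 7.0),
                    hfd_4wk = c(A = 1.4, B = 7.0)),
    midazolam = list(control = c(A = 2.5, B = 5.6),
                     hfd_2wk = c(A = 2.2, B = 5.7),
                     hfd_4wk = c(A = 1.8, B = 5.8)),
    codeine = list(control = c(A = 2.168, B = 5.397),
                   hfd_2wk = c(A = 2.1, B = 5.45),
                   hfd_4wk = c(A = 2.0, B = 5.5)))
  # noise: coefficient of variation at the control peak of about 10%
  sigma <- vapply(pk, function(an) {
    p <- pk_params(an$control[["A"]], an$control[["B"]])
    0.1 * peak_concentration(p)
  }, numeric(1))
  structure(list(
    groups = groups,
    features = feat,
    feature_bounds = bounds,
    pk_truth = pk,
    sigma = sigma,
    loq = c(caffeine = 10, midazolam = 1, codeine = 1),
    time_grid_h = c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 6),
    n_per_group = 6L
  ), class = "synth_config")
}

#' Generate a per-animal feature table
#'
#' Draws per-animal steatosis, triglyceride and CYP-activity features from
#' truncated normal distributions whose parent parameters are moment-
#' matched so that each truncated marginal has exactly the configured mean
#' and SD (percentages are bounded to \[0, 100\], concentrations and
#' activities to positive values). Cross-feature dependence can be induced
#' through a Gaussian copula with a supplied correlation matrix.
#'
#' @param config A \code{\link{default_config}}-style \code{synth_config}.
#' @param n_per_group Animals per group.
#' @param seed Integer seed; the output is a pure function of
#'   (config, n_per_group, seed).
#' @param corr Optional feature correlation matrix (positive definite,
#'   dimensions matching the feature count) applied within every group.
#' @return A data.frame with columns \code{animal_id}, \code{group} and
#'   one column per feature.
#' @export
generate_features <- function(config = default_config(),
                              n_per_group = config$n_per_group,
                              seed = 1L, corr = NULL) {
  stopifnot(inherits(config, "synth_config"), n_per_group >= 1)
  feat_names <- names(config$features[[1]]$mean)
  k <- length(feat_names)
  if (!is.null(corr)) {
    if (!is.matrix(corr) || any(dim(corr) != k)) {
      stop("corr must be a ", k, "x", k, " matrix")
    }
    ch <- tryCatch(chol(corr), error = function(e) {
      stop("corr is not positive definite")
    })
  }
  with_seed(seed, {
    rows <- lapply(config$groups, function(g) {
      mu <- config$features[[g]]$mean
      sd <- config$features[[g]]$sd
      z <- matrix(stats::rnorm(n_per_group * k), n_per_group, k)
      if (!is.null(corr)) z <- z %*% ch
      u <- stats::pnorm(z)
      cols <- lapply(seq_len(k), function(j) {
        b <- config$feature_bounds[feat_names[j], ]
        par <- truncnorm_match(mu[[j]], sd[[j]], b[1], b[2])
        qtruncnorm(u[, j], par$mu, par$sigma, b[1], b[2])
      })
      names(cols) <- feat_names
      data.frame(animal_id = sprintf("%s_%02d", g, seq_len(n_per_group)),
                 group = g, cols, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate drug-cocktail concentration time courses
#'
#' For every animal x analyte, simulates concentrations at the scheduled
#' sampling times from the group's elimination-curve truth with additive
#' Gaussian measurement noise, \eqn{c(t_k) = x(t_k; A_g, B_g) +
#' \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}, clamped at zero. The
#' pre-dose sample (t = 0) is exactly zero; post-dose values below the
#' analyte's limit of quantification are flagged.
#'
#' @inheritParams generate_features
#' @return A list of \code{\link{conc_series}} of length
#'   (groups x animals x analytes), each with the full ten-point grid.
#' @export
generate_timecourses <- function(config = default_config(),
                                 n_per_group = config$n_per_group,
                                 seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (any(config$sigma < 0)) stop("noise sigma must be non-negative")
  grid <- config$time_grid_h
  post <- grid > 0
  with_seed(seed, {
    out <- list()
    for (g in config$groups) {
      for (i in seq_len(n_per_group)) {
        for (an in names(config$pk_truth)) {
          truth <- config$pk_truth[[an]][[g]]
          p <- pk_params(truth[["A"]], truth[["B"]])
          conc <- evaluate_curve(grid, p)
          conc[post] <- pmax(
            conc[post] + stats::rnorm(sum(post), 0, config$sigma[[an]]), 0)
          conc[!post] <- 0
          loq <- config$loq[[an]]
          out[[length(out) + 1L]] <- conc_series(
            animal_id = sprintf("%s_%02d", g, i), group = g, analyte = an,
            time_h = grid, conc_ng_ml = conc,
            below_loq = grid > 0 & conc < loq, loq = loq)
        }
      }
    }
    out
  })
}

#' Generate a synthetic classified tile grid
#'
#' Emulates the tile classifier's output: multinomial tile labels whose
#' class probabilities match the requested surface percentages (over
#' non-lumen tiles) plus a configurable lumen fraction, so that
#' \code{\link{aggregate_tiles}} converges to the requested surfaces as
#' the tile count grows.
#'
#' @param surfaces A \code{\link{steatosis_surfaces}} target.
#' @param n_tiles Number of tiles, >= 30.
#' @param seed Integer seed.
#' @param lumen_frac Expected fraction of lumen tiles.
#' @return A \code{\link{tile_grid}}.
#' @export
generate_tile_grid <- function(surfaces, n_tiles, seed = 1L,
                               lumen_frac = 0.1) {
  stopifnot(inherits(surfaces, "steatosis_surfaces"), n_tiles >= 30,
            lumen_frac >= 0, lumen_frac < 1)
  if (surfaces$micro_pct + surfaces$macro_pct > 100 + 1e-9) {
    stop("surface percentages exceed 100")
  }
  tissue <- 1 - lumen_frac
  probs <- c(
    micro = tissue * surfaces$micro_pct / 100,
    macro = tissue * surfaces$macro_pct / 100,
    non_steatotic = tissue *
      (100 - surfaces$micro_pct - surfaces$macro_pct) / 100,
    lumen = lumen_frac)
  labels <- with_seed(seed, {
    sample(names(probs), n_tiles, replace = TRUE, prob = probs)
  })
  tile_grid(labels)
}

#' Worked-example fixture: codeine-6-glucuronide control replicate
#'
#' The packaged worked example: elimination-curve parameters A = 2.168,
#' B = 5.397 and the noiseless concentration series they generate on the
#' default ten-point sampling grid.
#'
#' @return A list with \code{params} (\code{\link{pk_params}}) and
#'   \code{series} (\code{\link{conc_series}}).
#' @export
fixture_worked_example <- function() {
  params <- pk_params(A = 2.168, B = 5.397)
  grid <- default_config()$time_grid_h
  series <- conc_series(
    animal_id = "control_replicate_4", group = "control",
    analyte = "codeine-6-glucuronide",
    time_h = grid, conc_ng_ml = evaluate_curve(grid, params), loq = 1)
  list(params = params, series = series)
}
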