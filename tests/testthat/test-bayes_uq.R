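make_replicates <- function(params, sigma, n_rep, seed,
                            grid = ten_point_grid) {
  mu <- evaluate_curve(grid, params)
  post <- grid > 0
  with_seed_local(seed, lapply(seq_len(n_rep), function(j) {
    cc <- mu
    cc[post] <- pmax(mu[post] + rnorm(sum(post), 0, sigma), 0)
    conc_series(paste0("a", j), "control", "probe", grid, cc)
  }))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

test_that("log-likelihood equals the sum of normal log-densities", {
  p <- pk_params(2, 5)
  # one replicate, one post-dose point with zero residual
  s1 <- conc_series("a", "control", "x", time_h = c(0.5, 1),
                    conc_ng_ml = evaluate_curve(c(0.5, 1), p))
  one_pt <- conc_series("a", "control", "x", time_h = 1,
                        conc_ng_ml = evaluate_curve(1, p))
  expect_equal(log_likelihood(p, 1, list(one_pt)), -0.5 * log(2 * pi))
  expect_equal(log_likelihood(p, 1, list(s1)), -log(2 * pi))
  # brute-force density oracle on a random small dataset
  reps <- make_replicates(p, sigma = 2, n_rep = 3, seed = 17)
  brute <- sum(vapply(reps, function(s) {
    sum(dnorm(s$conc_ng_ml, evaluate_curve(s$time_h, p), 2, log = TRUE))
  }, numeric(1)))
  expect_equal(log_likelihood(p, 2, reps), brute, tolerance = 1e-12)
  expect_error(log_likelihood(p, 0, reps), "positive")
  expect_error(log_likelihood(p, -1, reps), "positive")
})

test_that("log-posterior is flat-prior likelihood inside the box, -Inf outside", {
  p_in <- pk_params(2, 5)
  reps <- make_replicates(p_in, 1, 2, seed = 3)
  expect_identical(log_posterior(pk_params(101, 5), 1, reps), -Inf)
  expect_identical(log_posterior(pk_params(2, 101), 1, reps), -Inf)
  expect_identical(log_posterior(p_in, 1001, reps), -Inf)
  expect_equal(log_posterior(p_in, 1, reps), log_likelihood(p_in, 1, reps))
})

test_that("posterior mode coincides with the least-squares fit", {
  p <- pk_params(2.168, 5.397)
  reps <- list(noiseless_series(p))
  ls_fit <- fit_replicate(reps[[1]])
  opt <- optim(c(1, 4), function(par) {
    -log_posterior(pk_params(par[1], par[2]), sigma = 1, reps)
  }, method = "L-BFGS-B", lower = c(1e-3, 1e-3), upper = c(100, 100),
  control = list(factr = 10))
  expect_equal(opt$par[1], ls_fit$params$A, tolerance = 1e-4)
  expect_equal(opt$par[2], ls_fit$params$B, tolerance = 1e-4)
})

test_that("parallel tempering recovers tight synthetic truth", {
  p <- pk_params(2.168, 5.397)
  reps <- make_replicates(p, sigma = 0.1, n_rep = 20, seed = 8)
  ens <- sample_posterior(reps, n_samples = 5000, seed = 42)
  for (par_name in c("A", "B")) {
    truth <- p[[par_name]]
    m <- mean(ens$samples[, par_name])
    s <- sd(ens$samples[, par_name])
    expect_lt(abs(m - truth), 3 * s)
  }
  # support: all retained draws inside the prior box
  expect_true(all(ens$samples[, "A"] >= 0 & ens$samples[, "A"] <= 100))
  expect_true(all(ens$samples[, "B"] >= 0 & ens$samples[, "B"] <= 100))
  expect_true(all(ens$samples[, "sigma"] >= 0 &
                  ens$samples[, "sigma"] <= 1000))
  expect_gte(ens$burn_in_index, 100)
  expect_true(all(ens$ess > 0))
  # adapted cold-chain acceptance in a healthy band
  expect_true(all(ens$acceptance > 0.1 & ens$acceptance < 0.6))
})

test_that("sampling is bit-reproducible for a fixed seed", {
  p <- pk_params(2, 5)
  reps <- make_replicates(p, sigma = 1, n_rep = 4, seed = 10)
  e1 <- sample_posterior(reps, n_samples = 2000, seed = 77)
  e2 <- sample_posterior(reps, n_samples = 2000, seed = 77)
  expect_identical(e1$samples, e2$samples)
  e3 <- sample_posterior(reps, n_samples = 2000, seed = 78)
  expect_false(identical(e1$samples, e3$samples))
})

test_that("degenerate data are rejected before sampling", {
  flat <- conc_series("a", "control", "x", time_h = c(0, 1, 2, 3),
                      conc_ng_ml = c(0, 0, 0, 0))
  expect_error(sample_posterior(list(flat), n_samples = 2000),
               "degenerate")
})

test_that("Geweke burn-in returns the floor on a stationary chain and flags a level shift", {
  set.seed(123)
  chain <- matrix(rnorm(10000), ncol = 1)
  expect_identical(as.integer(geweke_burnin(chain, min_cut = 100L)), 100L)
  shifted <- chain
  shifted[1:5000, 1] <- shifted[1:5000, 1] + 5
  cut <- suppressWarnings(geweke_burnin(shifted, min_cut = 100L))
  expect_gte(as.integer(cut), 5000L)
  expect_error(geweke_burnin(rnorm(150), min_cut = 100L), "too short")
})

test_that("ESS matches iid and AR(1) expectations", {
  set.seed(11)
  iid <- rnorm(10000)
  ess <- effective_sample_size(iid)
  expect_gte(ess, 8000)
  expect_lte(ess, 12000)
  # AR(1) closed form N * (1 - phi) / (1 + phi)
  phi <- 0.9
  ar1 <- as.numeric(arima.sim(list(ar = phi), n = 20000))
  ess_ar <- effective_sample_size(ar1)
  expected <- 20000 * (1 - phi) / (1 + phi)
  expect_lt(abs(ess_ar - expected) / expected, 0.3)
  expect_error(effective_sample_size(rnorm(50)), "too short")
  expect_error(effective_sample_size(rep(1, 200)), "constant")
})

test_that("ESS agrees in order of magnitude with coda on a real chain", {
  skip_if_not_installed("coda")
  p <- pk_params(2, 5)
  reps <- make_replicates(p, sigma = 1, n_rep = 4, seed = 2)
  ens <- sample_posterior(reps, n_samples = 4000, seed = 5)
  ours <- effective_sample_size(ens$samples[, "A"])
  theirs <- unname(coda::effectiveSize(ens$samples[, "A"]))
  expect_lt(abs(log(ours / theirs)), log(2.5))
})

test_that("credibility bands behave at degenerate and boundary cases", {
  draws <- matrix(rep(c(2, 5, 1), each = 50), ncol = 3,
                  dimnames = list(NULL, c("A", "B", "sigma")))
  ens <- structure(list(samples = draws, n_chains = 4L,
                        n_samples_requested = 50L, burn_in_index = 0L,
                        ess = c(A = 50, B = 50, sigma = 50), seed = 1L),
                   class = "posterior_ensemble")
  grid <- c(0, 0.5, 1, 2)
  band <- posterior_predictive_band(ens, grid)
  curve <- evaluate_curve(grid, pk_params(2, 5))
  expect_equal(band$lower, curve)
  expect_equal(band$upper, curve)
  expect_equal(band$center, curve)
  expect_equal(band$lower[1], 0)
  expect_equal(band$upper[1], 0)
  expect_true(all(band$lower <= band$center & band$center <= band$upper))
})

test_that("wider measurement noise widens the posterior band", {
  p <- pk_params(2.168, 5.397)
  grid <- ten_point_grid[-1]
  widths <- vapply(c(0.1, 1, 5), function(sig) {
    reps <- make_replicates(p, sigma = sig, n_rep = 6, seed = 30)
    ens <- sample_posterior(reps, n_samples = 3000, seed = 31)
    band <- posterior_predictive_band(ens, grid)
    mean(band$upper - band$lower)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("band overlap uses closed intervals", {
  mk <- function(lo, hi) {
    structure(list(time_grid = c(1, 2), lower = c(lo, lo),
                   upper = c(hi, hi), center = c((lo + hi) / 2,
                                                 (lo + hi) / 2),
                   level = 0.95), class = "credibility_band")
  }
  expect_true(bands_overlap_at(mk(1, 2), mk(1, 2), 1))
  expect_false(bands_overlap_at(mk(1, 2), mk(3, 4), 1))
  expect_true(bands_overlap_at(mk(1, 2), mk(2, 3), 1))
  expect_error(bands_overlap_at(mk(1, 2), mk(2, 3), 5), "grid")
})
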