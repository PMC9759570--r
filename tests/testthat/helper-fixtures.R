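# shared fixtures and small independent oracles, built in code

worked_example_params <- function() pk_params(A = 2.168, B = 5.397)

ten_point_grid <- c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 6)

# noiseless series from given params on the scheduled grid
noiseless_series <- function(params, grid = ten_point_grid,
                             animal = "a1", group = "control",
                             analyte = "probe") {
  conc_series(animal_id = animal, group = group, analyte = analyte,
              time_h = grid, conc_ng_ml = evaluate_curve(grid, params))
}

# independent bisection solver for f(x) = 0 on [lo, hi], f(lo) and f(hi)
# of opposite sign; used as the half-life oracle
bisect <- function(f, lo, hi, tol = 1e-12, maxit = 200L) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# half-life oracle: solve u * exp(-u) = exp(-1)/2 for u > 1, then
# t_half = (u - 1) / A (B cancels)
half_life_oracle <- function(A) {
  u <- bisect(function(u) u * exp(-u) - exp(-1) / 2, lo = 1, hi = 60)
  (u - 1) / A
}
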