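#include <Rcpp.h>
using namespace Rcpp;

// Gaussian log-likelihood of the elimination curve x(t) = t*exp(B - A*t)
// against pooled replicates, expressed through per-time sufficient
// statistics: s1[k] = sum_j m_j(t_k), s2[k] = sum_j m_j(t_k)^2.
static double loglik_suff(double A, double B, double sigma,
                          const NumericVector& t,
                          const NumericVector& s1,
                          const NumericVector& s2,
                          int n_rep) {
  const int T = t.size();
  double sse = 0.0;
  for (int k = 0; k < T; ++k) {
    double x = t[k] * std::exp(B - A * t[k]);
    sse += n_rep * x * x - 2.0 * x * s1[k] + s2[k];
  }
  return -n_rep * T * (std::log(sigma) + 0.5 * std::log(2.0 * M_PI))
         - sse / (2.0 * sigma * sigma);
}

// Adaptive parallel-tempering random-walk Metropolis over (A, B, sigma)
// with a uniform box prior. Chains run at inverse temperatures `betas`
// (betas[0] = 1 is the cold chain); component-wise Gaussian proposals with
// Robbins-Monro scale adaptation towards 23.4% acceptance during the first
// `adapt_n` iterations only; adjacent-rung swap proposals every
// `swap_every` iterations. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List pt_sample_cpp(NumericVector t, NumericVector s1, NumericVector s2,
                   int n_rep, NumericVector betas, int n_samples,
                   NumericMatrix init, NumericMatrix scales0,
                   NumericVector lower, NumericVector upper,
                   int swap_every, int adapt_n) {
  const int n_chains = betas.size();
  const int n_par = 3;
  RNGScope rng;

  NumericMatrix state(n_chains, n_par);
  std::vector<double> ll(n_chains);
  NumericMatrix lscale(n_chains, n_par);
  for (int c = 0; c < n_chains; ++c) {
    for (int p = 0; p < n_par; ++p) {
      state(c, p) = init(c, p);
      lscale(c, p) = std::log(scales0(c, p));
    }
    ll[c] = loglik_suff(state(c, 0), state(c, 1), state(c, 2),
                        t, s1, s2, n_rep);
  }

  NumericMatrix cold(n_samples, n_par);
  NumericMatrix acc_count(n_chains, n_par);
  double swap_prop = 0.0, swap_acc = 0.0;

  for (int i = 0; i < n_samples; ++i) {
    for (int c = 0; c < n_chains; ++c) {
      for (int p = 0; p < n_par; ++p) {
        double cur = state(c, p);
        double prop = cur + R::norm_rand() * std::exp(lscale(c, p));
        bool accepted = false;
        if (prop >= lower[p] && prop <= upper[p]) {
          double saved = state(c, p);
          state(c, p) = prop;
          double ll_new = loglik_suff(state(c, 0), state(c, 1), state(c, 2),
                                      t, s1, s2, n_rep);
          double logr = betas[c] * (ll_new - ll[c]);
          if (logr >= 0.0 || R::unif_rand() < std::exp(logr)) {
            ll[c] = ll_new;
            accepted = true;
          } else {
            state(c, p) = saved;
          }
        }
        if (accepted) acc_count(c, p) += 1.0;
        if (i < adapt_n) {
          double gamma = std::pow((double)(i + 1), -0.6);
          lscale(c, p) += gamma * ((accepted ? 1.0 : 0.0) - 0.234);
        }
      }
    }
    if (swap_every > 0 && ((i + 1) % swap_every == 0)) {
      for (int c = n_chains - 2; c >= 0; --c) {
        swap_prop += 1.0;
        double logr = (betas[c] - betas[c + 1]) * (ll[c + 1] - ll[c]);
        if (logr >= 0.0 || R::unif_rand() < std::exp(logr)) {
          for (int p = 0; p < n_par; ++p)
            std::swap(state(c, p), state(c + 1, p));
          std::swap(ll[c], ll[c + 1]);
          swap_acc += 1.0;
        }
      }
    }
    for (int p = 0; p < n_par; ++p) cold(i, p) = state(0, p);
  }

  NumericMatrix acc_rate(n_chains, n_par);
  for (int c = 0; c < n_chains; ++c)
    for (int p = 0; p < n_par; ++p)
      acc_rate(c, p) = acc_count(c, p) / n_samples;

  return List::create(
    _["cold_samples"] = cold,
    _["acceptance"] = acc_rate,
    _["swap_rate"] = swap_prop > 0 ? swap_acc / swap_prop : NA_REAL);
}
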