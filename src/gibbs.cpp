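#include <Rcpp.h>
using namespace Rcpp;

// One Gibbs chain for a K-component normal mixture on a pooled thickness
// sample. Component weights use the normalized-gamma construction of a
// Dirichlet draw: g_k ~ Gamma(alpha_k + n_k, scale 1), floored at
// gamma_floor, pi_k = g_k / sum(g). Means get independent normal priors,
// precisions independent gamma priors; sigma = 1/sqrt(tau). Uses R's RNG so
// set.seed() on the R side makes the chain reproducible.
//
// Returns matrices of retained draws (rows = retained iterations) for mu,
// sigma and weight. When sort_means is true the *recorded* draw is relabeled
// so mu is ascending (ties broken by ascending sigma); the internal chain
// state is left untouched.

static void record_draw(int row, int K, bool sort_means,
                        const std::vector<double>& mu,
                        const std::vector<double>& tau,
                        const std::vector<double>& pi,
                        NumericMatrix& mu_out, NumericMatrix& sigma_out,
                        NumericMatrix& w_out) {
  std::vector<int> ord(K);
  for (int k = 0; k < K; ++k) ord[k] = k;
  if (sort_means) {
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (mu[a] != mu[b]) return mu[a] < mu[b];
      return tau[a] > tau[b];  // larger tau = smaller sigma
    });
  }
  for (int k = 0; k < K; ++k) {
    int j = ord[k];
    mu_out(row, k) = mu[j];
    sigma_out(row, k) = 1.0 / std::sqrt(tau[j]);
    w_out(row, k) = pi[j];
  }
}

// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
List gibbs_chain_cpp(NumericVector x, int K, NumericVector alpha,
                     int iterations, int burn_in, int thinning,
                     double gamma_floor, bool sort_means,
                     NumericVector prior_mean_location,
                     double prior_mean_precision,
                     double precision_shape, double precision_rate) {
  const int N = x.size();
  const int n_keep = (iterations - burn_in) / thinning;

  NumericMatrix mu_out(n_keep, K), sigma_out(n_keep, K), w_out(n_keep, K);
  std::vector<double> mu(K), tau(K), g(K), pi(K);
  std::vector<int> z(N);
  std::vector<double> sum_x(K);
  std::vector<int> n_k(K);

  // deterministic initialization: means at spread-out data quantiles
  // (type-7), shared precision from the pooled variance, weights at the
  // normalized prior alphas
  NumericVector xs = clone(x).sort();
  double xbar = mean(x);
  double v = var(x);
  if (!(v > 0)) v = 1e-6;
  for (int k = 0; k < K; ++k) {
    double h = (K == 1) ? 0.5 * (N - 1) : (double)k / (K - 1) * (N - 1);
    int lo = (int)std::floor(h);
    double frac = h - lo;
    int hi = lo + 1 < N ? lo + 1 : lo;
    mu[k] = (1.0 - frac) * xs[lo] + frac * xs[hi];
    tau[k] = 1.0 / v;
    g[k] = alpha[k] > gamma_floor ? alpha[k] : gamma_floor;
  }
  double gsum = 0.0;
  for (int k = 0; k < K; ++k) gsum += g[k];
  for (int k = 0; k < K; ++k) pi[k] = g[k] / gsum;

  std::vector<double> logp(K), p(K);
  int row = 0;

  for (int it = 1; it <= iterations; ++it) {
    // z | pi, mu, tau  (categorical per datum)
    for (int k = 0; k < K; ++k) {
      logp[k] = std::log(pi[k]) + 0.5 * std::log(tau[k]);
      sum_x[k] = 0.0;
      n_k[k] = 0;
    }
    for (int i = 0; i < N; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double d = x[i] - mu[k];
        p[k] = logp[k] - 0.5 * tau[k] * d * d;
        if (p[k] > mx) mx = p[k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = std::exp(p[k] - mx);
        tot += p[k];
      }
      double u = unif_rand() * tot, acc = 0.0;
      int zi = K - 1;
      for (int k = 0; k < K; ++k) {
        acc += p[k];
        if (u <= acc) { zi = k; break; }
      }
      z[i] = zi;
      n_k[zi] += 1;
      sum_x[zi] += x[i];
    }

    // mu_k | z, tau  (conjugate normal)
    for (int k = 0; k < K; ++k) {
      double prec = prior_mean_precision + n_k[k] * tau[k];
      double m = (prior_mean_precision * prior_mean_location[k] +
                  tau[k] * sum_x[k]) / prec;
      mu[k] = norm_rand() / std::sqrt(prec) + m;
    }

    // tau_k | z, mu  (conjugate gamma); residuals use the fresh mu
    for (int k = 0; k < K; ++k) {
      double ss = 0.0;
      for (int i = 0; i < N; ++i) {
        if (z[i] == k) {
          double d = x[i] - mu[k];
          ss += d * d;
        }
      }
      double shape = precision_shape + 0.5 * n_k[k];
      double rate = precision_rate + 0.5 * ss;
      tau[k] = R::rgamma(shape, 1.0 / rate);
      if (tau[k] < 1e-300) tau[k] = 1e-300;
    }

    // weights: floored gamma draws, then normalize
    gsum = 0.0;
    for (int k = 0; k < K; ++k) {
      g[k] = R::rgamma(alpha[k] + n_k[k], 1.0);
      if (g[k] < gamma_floor) g[k] = gamma_floor;
      gsum += g[k];
    }
    for (int k = 0; k < K; ++k) pi[k] = g[k] / gsum;

    for (int k = 0; k < K; ++k) {
      if (!R_finite(mu[k]) || !R_finite(tau[k]) || !(tau[k] > 0)) {
        stop("non-finite sampler state at iteration %d (component %d)", it,
             k + 1);
      }
    }

    if (it > burn_in && (it - burn_in) % thinning == 0 && row < n_keep) {
      record_draw(row, K, sort_means, mu, tau, pi, mu_out, sigma_out, w_out);
      ++row;
    }
  }

  return List::create(_["mu"] = mu_out, _["sigma"] = sigma_out,
                      _["weight"] = w_out);
}
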