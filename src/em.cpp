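#include <Rcpp.h>
using namespace Rcpp;

// EM for a univariate k-component Gaussian mixture. Returns the fit together
// with the per-iteration log-likelihood trace so callers can assert EM
// monotonicity. Convergence: relative log-likelihood change <= tol.
// Variances are floored at var_floor to prevent singular components.
// [[Rcpp::export]]
List em_gauss_mix(NumericVector x, NumericVector w0, NumericVector mu0,
                  NumericVector sd0, double tol, int max_iter,
                  double var_floor) {
  const int n = x.size();
  const int k = w0.size();
  const double inv_sqrt_2pi = 0.3989422804014327;
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  std::vector<double> coef(k), half_inv_var(k);
  std::vector<double> nj(k), sx(k), sxx(k), dens(k);
  std::vector<double> trace;
  trace.reserve(64);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int j = 0; j < k; ++j) {
      coef[j] = w[j] * inv_sqrt_2pi / sd[j];
      half_inv_var[j] = 0.5 / (sd[j] * sd[j]);
      nj[j] = sx[j] = sxx[j] = 0.0;
    }
    // E step with responsibility-weighted sufficient statistics accumulated
    // in the same pass
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int j = 0; j < k; ++j) {
        double d = x[i] - mu[j];
        dens[j] = coef[j] * std::exp(-d * d * half_inv_var[j]);
        tot += dens[j];
      }
      if (tot <= 0.0 || !R_finite(tot)) {
        // degenerate density; bail out with what we have
        return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                            _["means"] = NumericVector(mu.begin(), mu.end()),
                            _["sds"] = NumericVector(sd.begin(), sd.end()),
                            _["loglik"] = R_NegInf, _["n_iter"] = iter,
                            _["converged"] = false,
                            _["loglik_trace"] = NumericVector(trace.begin(), trace.end()));
      }
      ll += std::log(tot);
      for (int j = 0; j < k; ++j) {
        double r = dens[j] / tot;
        nj[j] += r;
        sx[j] += r * x[i];
        sxx[j] += r * x[i] * x[i];
      }
    }
    trace.push_back(ll);
    if (iter > 1 && std::fabs(ll - ll_old) <= tol * (std::fabs(ll_old) + tol)) {
      converged = true;
      break;
    }
    ll_old = ll;

    // M step from the sufficient statistics
    for (int j = 0; j < k; ++j) {
      if (nj[j] < 1e-10) continue;  // empty component: keep previous parameters
      double m = sx[j] / nj[j];
      double v = sxx[j] / nj[j] - m * m;
      if (v < var_floor) v = var_floor;
      w[j] = nj[j] / n;
      mu[j] = m;
      sd[j] = std::sqrt(v);
    }
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["means"] = NumericVector(mu.begin(), mu.end()),
                      _["sds"] = NumericVector(sd.begin(), sd.end()),
                      _["loglik"] = ll, _["n_iter"] = iter,
                      _["converged"] = converged,
                      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()));
}

// One run of the discrete-round CpG-deamination mutation model on a base-coded
// sequence (1=A, 2=C, 3=G, 4=T; 0 = N, never mutated). Per round the CpG
// context is re-evaluated first; the C of each CpG deaminates to T (and the G,
// as the reverse-strand partner C, to A) with probability p_deam, while every
// other site mutates to one of the three other bases uniformly with
// probability base_rate. Uses R's RNG so results are reproducible under
// set.seed().
// [[Rcpp::export]]
IntegerVector evolve_codes(IntegerVector codes, double base_rate,
                           double p_deam, int rounds) {
  IntegerVector b = clone(codes);
  const int n = b.size();
  std::vector<char> role(n);  // 0 none, 1 CpG C, 2 CpG G

  for (int r = 0; r < rounds; ++r) {
    std::fill(role.begin(), role.end(), 0);
    for (int i = 0; i + 1 < n; ++i) {
      if (b[i] == 2 && b[i + 1] == 3) {
        role[i] = 1;
        role[i + 1] = 2;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (b[i] == 0) continue;
      double u = unif_rand();
      if (role[i] == 1) {
        if (u < p_deam) b[i] = 4;  // C -> T
      } else if (role[i] == 2) {
        if (u < p_deam) b[i] = 1;  // G -> A (reverse-strand C -> T)
      } else if (u < base_rate) {
        int shift = 1 + (int)(unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        b[i] = ((b[i] - 1 + shift) % 4) + 1;
      }
    }
  }
  return b;
}
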