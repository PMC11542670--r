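// Joint posterior of the zero-inflated-beta gaze model and the
// ordered-logistic rating model, with analytic gradients, plus a
// Hamiltonian Monte Carlo sampler. Parameters live on an unconstrained
// scale (log for precisions and random-effect scales; first cutpoint plus
// log-increments for the ordered cutpoints); the prior densities are
// evaluated on the constrained scale with log-Jacobian terms added.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.9189385332046727; // log(sqrt(2*pi))

static inline double softplus(double x) {
  return x > 30.0 ? x : log1p(exp(x));
}
static inline double sigmoid(double x) {
  return 1.0 / (1.0 + exp(-x));
}

// digamma via upward recurrence + asymptotic series (|err| < 1e-12 on the
// positive axis); only used in gradients, the accept step uses exact
// log-posterior values, so sampler exactness is unaffected
static inline double fast_digamma(double x) {
  double r = 0.0;
  while (x < 6.0) { r -= 1.0 / x; x += 1.0; }
  const double f = 1.0 / (x * x);
  return r + log(x) - 0.5 / x -
         f * (1.0 / 12.0 - f * (1.0 / 120.0 - f * (1.0 / 252.0)));
}

// parameter-vector layout, driven by the data dimensions
struct Layout {
  bool zib;
  int NS, NF, K, Pord;
  int aZ, bZ, aB, bB, phi, bOrd, thc;
  int rZs, rZf, rBs, rBf, rRs, rRf;
  int sZs, sZf, sBs, sBf, sRs, sRf;
  int D;
};

static Layout make_layout(bool zib, int NS, int NF, int K, int Pord) {
  Layout L;
  L.zib = zib; L.NS = NS; L.NF = NF; L.K = K; L.Pord = Pord;
  int off = 0;
  if (zib) {
    L.aZ = off; off += 3; L.bZ = off; off += 15;
    L.aB = off; off += 3; L.bB = off; off += 15;
    L.phi = off; off += 3;
  }
  L.bOrd = off; off += Pord;
  L.thc = off; off += K - 1;
  if (zib) {
    L.rZs = off; off += 3 * NS; L.rZf = off; off += 3 * NF;
    L.rBs = off; off += 3 * NS; L.rBf = off; off += 3 * NF;
  }
  L.rRs = off; off += NS; L.rRf = off; off += NF;
  if (zib) {
    L.sZs = off; off += 3; L.sZf = off; off += 3;
    L.sBs = off; off += 3; L.sBf = off; off += 3;
  }
  L.sRs = off; off += 1; L.sRf = off; off += 1;
  L.D = off;
  return L;
}

static Layout layout_from_data(const List& data) {
  bool zib = as<bool>(data["include_zib"]);
  int NS = as<int>(data["NS"]), NF = as<int>(data["NF"]);
  int K = as<int>(data["K"]);
  NumericMatrix Xord = data["Xord"];
  return make_layout(zib, NS, NF, K, Xord.ncol());
}

// log-posterior and gradient; returns lp, fills grad (same length as par).
// With need_lp = false only the gradient is computed (the costly lgamma
// terms of the beta likelihood contribute nothing to the gradient); used
// for the interior leapfrog steps.
static double logpost_grad(const double* par, double* grad, const List& data,
                           const Layout& L, bool jacobian,
                           bool need_lp = true) {
  const int N = as<int>(data["N"]);
  const IntegerVector si = data["si"], fi = data["fi"];
  const NumericMatrix P = data["P"], Xord = data["Xord"];
  const IntegerVector Y = data["Y"];
  const int K = L.K, Pord = L.Pord, NS = L.NS, NF = L.NF;

  for (int d = 0; d < L.D; ++d) grad[d] = 0.0;
  double lp = 0.0;

  // --- ordered cutpoints from (c1, log-increments) ---
  std::vector<double> cc(K - 1), gc(K - 1, 0.0);
  cc[0] = par[L.thc];
  for (int m = 1; m < K - 1; ++m) cc[m] = cc[m - 1] + exp(par[L.thc + m]);

  // --- zero-inflated beta blocks ---
  if (L.zib) {
    const NumericMatrix G = data["G"], lG = data["lG"], l1G = data["l1G"];
    const IntegerMatrix Z = data["Z"];
    double phi[3], sZs[3], sZf[3], sBs[3], sBf[3], lgphi[3], dgphi[3];
    for (int k = 0; k < 3; ++k) {
      phi[k] = exp(par[L.phi + k]);
      lgphi[k] = need_lp ? R::lgammafn(phi[k]) : 0.0;
      dgphi[k] = fast_digamma(phi[k]);
      sZs[k] = exp(par[L.sZs + k]); sZf[k] = exp(par[L.sZf + k]);
      sBs[k] = exp(par[L.sBs + k]); sBf[k] = exp(par[L.sBf + k]);
    }
    for (int n = 0; n < N; ++n) {
      const int i = si[n], j = fi[n];
      for (int k = 0; k < 3; ++k) {
        // Bernoulli component: was the area looked at
        double etaZ = par[L.aZ + k] + par[L.rZs + k * NS + i] +
                      par[L.rZf + k * NF + j];
        for (int l = 0; l < 5; ++l) etaZ += par[L.bZ + k * 5 + l] * P(i, l);
        const int z = Z(n, k);
        if (need_lp) lp += z * etaZ - softplus(etaZ);
        const double dz = z - sigmoid(etaZ);
        grad[L.aZ + k] += dz;
        for (int l = 0; l < 5; ++l) grad[L.bZ + k * 5 + l] += dz * P(i, l);
        grad[L.rZs + k * NS + i] += dz;
        grad[L.rZf + k * NF + j] += dz;
        if (z == 1) {
          // beta component: how much it was looked at
          double etaB = par[L.aB + k] + par[L.rBs + k * NS + i] +
                        par[L.rBf + k * NF + j];
          for (int l = 0; l < 5; ++l) etaB += par[L.bB + k * 5 + l] * P(i, l);
          const double mu = sigmoid(etaB);
          const double a = phi[k] * mu, b = phi[k] * (1.0 - mu);
          const double lg = lG(n, k), l1g = l1G(n, k);
          if (need_lp) {
            lp += lgphi[k] - R::lgammafn(a) - R::lgammafn(b) +
                  (a - 1.0) * lg + (b - 1.0) * l1g;
          }
          const double da = fast_digamma(a), db = fast_digamma(b);
          const double dmu = phi[k] * (-da + db + lg - l1g);
          const double de = dmu * mu * (1.0 - mu);
          grad[L.aB + k] += de;
          for (int l = 0; l < 5; ++l) grad[L.bB + k * 5 + l] += de * P(i, l);
          grad[L.rBs + k * NS + i] += de;
          grad[L.rBf + k * NF + j] += de;
          const double dphi = dgphi[k] - mu * da - (1.0 - mu) * db +
                              mu * lg + (1.0 - mu) * l1g;
          grad[L.phi + k] += dphi * phi[k];
        }
      }
    }
    // priors: fixed effects N(0, 10), phi half-N(0, 10),
    // random effects N(0, sigma), sigma ~ Gamma(10, 10).
    // Covariates arrive centered (by p_bar); the intercept priors apply on
    // the raw scale, alpha_raw = alpha_centered - sum(beta * p_bar), so
    // centering stays a pure reparameterization of the same model.
    const NumericVector p_bar = data["p_bar"];
    for (int d = L.bZ; d < L.bZ + 15; ++d) {
      if (need_lp) lp += -par[d] * par[d] / 200.0 - log(10.0) - LOG_SQRT_2PI;
      grad[d] += -par[d] / 100.0;
    }
    for (int d = L.bB; d < L.bB + 15; ++d) {
      if (need_lp) lp += -par[d] * par[d] / 200.0 - log(10.0) - LOG_SQRT_2PI;
      grad[d] += -par[d] / 100.0;
    }
    for (int k = 0; k < 3; ++k) {
      double azraw = par[L.aZ + k], abraw = par[L.aB + k];
      for (int l = 0; l < 5; ++l) {
        azraw -= par[L.bZ + k * 5 + l] * p_bar[l];
        abraw -= par[L.bB + k * 5 + l] * p_bar[l];
      }
      if (need_lp) {
        lp += -azraw * azraw / 200.0 - log(10.0) - LOG_SQRT_2PI;
        lp += -abraw * abraw / 200.0 - log(10.0) - LOG_SQRT_2PI;
      }
      grad[L.aZ + k] += -azraw / 100.0;
      grad[L.aB + k] += -abraw / 100.0;
      for (int l = 0; l < 5; ++l) {
        grad[L.bZ + k * 5 + l] += azraw * p_bar[l] / 100.0;
        grad[L.bB + k * 5 + l] += abraw * p_bar[l] / 100.0;
      }
    }
    for (int k = 0; k < 3; ++k) {
      if (need_lp) {
        lp += log(2.0) - log(10.0) - LOG_SQRT_2PI - phi[k] * phi[k] / 200.0;
      }
      grad[L.phi + k] += -phi[k] * phi[k] / 100.0;
      if (jacobian) { if (need_lp) lp += par[L.phi + k]; grad[L.phi + k] += 1.0; }
    }
    struct { int r, s, n; double* sig; } blocks[4] = {
      { L.rZs, L.sZs, NS, sZs }, { L.rZf, L.sZf, NF, sZf },
      { L.rBs, L.sBs, NS, sBs }, { L.rBf, L.sBf, NF, sBf }
    };
    for (int blk = 0; blk < 4; ++blk) {
      for (int k = 0; k < 3; ++k) {
        const double s = blocks[blk].sig[k];
        const int us = blocks[blk].s + k;
        const double inv_s2 = 1.0 / (s * s);
        for (int t = 0; t < blocks[blk].n; ++t) {
          const int d = blocks[blk].r + k * blocks[blk].n + t;
          const double r = par[d];
          if (need_lp) lp += -r * r * 0.5 * inv_s2 - log(s) - LOG_SQRT_2PI;
          grad[d] += -r * inv_s2;
          grad[us] += r * r * inv_s2 - 1.0;
        }
        if (need_lp) {
          lp += 10.0 * log(10.0) - R::lgammafn(10.0) + 9.0 * log(s) - 10.0 * s;
        }
        grad[us] += 9.0 - 10.0 * s;
        if (jacobian) { if (need_lp) lp += par[us]; grad[us] += 1.0; }
      }
    }
  }

  // --- ordered-logistic rating block ---
  const double sRs = exp(par[L.sRs]), sRf = exp(par[L.sRf]);
  for (int n = 0; n < N; ++n) {
    const int i = si[n], j = fi[n];
    double eta = par[L.rRs + i] + par[L.rRf + j];
    for (int p = 0; p < Pord; ++p) eta += par[L.bOrd + p] * Xord(n, p);
    const int m = Y[n]; // 1..K
    const double Slo = (m == 1) ? 1.0 : sigmoid(eta - cc[m - 2]);
    const double Shi = (m == K) ? 0.0 : sigmoid(eta - cc[m - 1]);
    const double pm = Slo - Shi;
    if (need_lp) lp += log(pm);
    const double slo = (m == 1) ? 0.0 : Slo * (1.0 - Slo);
    const double shi = (m == K) ? 0.0 : Shi * (1.0 - Shi);
    const double de = (slo - shi) / pm;
    for (int p = 0; p < Pord; ++p) grad[L.bOrd + p] += de * Xord(n, p);
    grad[L.rRs + i] += de;
    grad[L.rRf + j] += de;
    if (m > 1) gc[m - 2] += -slo / pm;
    if (m < K) gc[m - 1] += shi / pm;
  }
  for (int p = L.bOrd; p < L.bOrd + Pord; ++p) {
    if (need_lp) lp += -par[p] * par[p] / 200.0 - log(10.0) - LOG_SQRT_2PI;
    grad[p] += -par[p] / 100.0;
  }
  // N(0, 10) prior on each cutpoint, on the raw covariate scale:
  // c_raw = c_centered + sum(beta_ord * xo_bar)
  const NumericVector xo_bar = data["xo_bar"];
  double shift = 0.0;
  for (int p = 0; p < Pord; ++p) shift += par[L.bOrd + p] * xo_bar[p];
  for (int m = 0; m < K - 1; ++m) {
    const double craw = cc[m] + shift;
    if (need_lp) lp += -craw * craw / 200.0 - log(10.0) - LOG_SQRT_2PI;
    gc[m] += -craw / 100.0;
    for (int p = 0; p < Pord; ++p) {
      grad[L.bOrd + p] += -craw * xo_bar[p] / 100.0;
    }
  }
  // chain rule cutpoints -> (c1, log-increments), plus Jacobian
  double acc = 0.0;
  for (int m = K - 2; m >= 1; --m) {
    acc += gc[m];
    grad[L.thc + m] += exp(par[L.thc + m]) * acc;
    if (jacobian) { if (need_lp) lp += par[L.thc + m]; grad[L.thc + m] += 1.0; }
  }
  grad[L.thc] += acc + gc[0];

  // rating random effects and scales
  const double inv_ss = 1.0 / (sRs * sRs), inv_sf = 1.0 / (sRf * sRf);
  for (int i = 0; i < NS; ++i) {
    const double r = par[L.rRs + i];
    if (need_lp) lp += -r * r * 0.5 * inv_ss - log(sRs) - LOG_SQRT_2PI;
    grad[L.rRs + i] += -r * inv_ss;
    grad[L.sRs] += r * r * inv_ss - 1.0;
  }
  for (int j = 0; j < NF; ++j) {
    const double r = par[L.rRf + j];
    if (need_lp) lp += -r * r * 0.5 * inv_sf - log(sRf) - LOG_SQRT_2PI;
    grad[L.rRf + j] += -r * inv_sf;
    grad[L.sRf] += r * r * inv_sf - 1.0;
  }
  if (need_lp) {
    lp += 10.0 * log(10.0) - R::lgammafn(10.0) + 9.0 * log(sRs) - 10.0 * sRs;
    lp += 10.0 * log(10.0) - R::lgammafn(10.0) + 9.0 * log(sRf) - 10.0 * sRf;
  }
  grad[L.sRs] += 9.0 - 10.0 * sRs;
  grad[L.sRf] += 9.0 - 10.0 * sRf;
  if (jacobian) {
    if (need_lp) lp += par[L.sRs] + par[L.sRf];
    grad[L.sRs] += 1.0; grad[L.sRf] += 1.0;
  }
  return need_lp ? lp : NA_REAL;
}

// [[Rcpp::export]]
List cpp_logpost_grad(NumericVector par, List data, bool jacobian = true) {
  Layout L = layout_from_data(data);
  if ((int)par.size() != L.D) stop("parameter vector has wrong length");
  NumericVector grad(L.D);
  double lp = logpost_grad(par.begin(), grad.begin(), data, L, jacobian);
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// [[Rcpp::export]]
int cpp_n_params(List data) { return layout_from_data(data).D; }

// Hamiltonian Monte Carlo with dual-averaging step-size adaptation and a
// diagonal mass matrix estimated during warmup.
// [[Rcpp::export]]
List cpp_hmc_sample(List data, NumericVector init, int n_warmup, int n_iter,
                    double init_step = 0.1, double target_accept = 0.8,
                    double traj_length = 1.2, int max_leapfrog = 64) {
  Layout L = layout_from_data(data);
  const int D = L.D;
  if ((int)init.size() != D) stop("init has wrong length");

  std::vector<double> q(init.begin(), init.end());
  std::vector<double> grad(D), qp(D), gp(D), p(D), inv_mass(D, 1.0);
  double lp = logpost_grad(q.data(), grad.data(), data, L, true);
  if (!R_finite(lp)) stop("initial point has non-finite log posterior");

  // dual averaging state
  double eps = init_step, mu = log(10.0 * init_step);
  double h_bar = 0.0, log_eps_bar = log(init_step);
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int adapt_count = 0;

  // mass-matrix accumulation window within warmup
  const int w1 = (int)(0.35 * n_warmup), w2 = (int)(0.85 * n_warmup);
  std::vector<double> m_mean(D, 0.0), m_m2(D, 0.0);
  int m_n = 0;

  NumericMatrix draws(n_iter, D);
  NumericVector lp_draws(n_iter);
  int n_accept = 0, n_div = 0;

  for (int it = 0; it < n_warmup + n_iter; ++it) {
    const bool warm = it < n_warmup;
    // momentum refresh: p ~ N(0, M) with M = diag(1/inv_mass)
    double kin0 = 0.0;
    for (int d = 0; d < D; ++d) {
      p[d] = R::norm_rand() / sqrt(inv_mass[d]);
      kin0 += 0.5 * p[d] * p[d] * inv_mass[d];
    }
    // jittered leapfrog count at fixed trajectory length
    double jitter = 0.8 + 0.4 * R::unif_rand();
    int Lf = (int)(jitter * traj_length / eps + 0.5);
    if (Lf < 1) Lf = 1;
    if (Lf > max_leapfrog) Lf = max_leapfrog;

    std::copy(q.begin(), q.end(), qp.begin());
    std::copy(grad.begin(), grad.end(), gp.begin());
    double lp_p = lp;
    bool diverged = false;
    for (int s = 0; s < Lf; ++s) {
      for (int d = 0; d < D; ++d) p[d] += 0.5 * eps * gp[d];
      for (int d = 0; d < D; ++d) qp[d] += eps * inv_mass[d] * p[d];
      // gradient-only evaluation inside the trajectory; full log
      // posterior once at the endpoint
      logpost_grad(qp.data(), gp.data(), data, L, true, false);
      bool bad = false;
      for (int d = 0; d < D; ++d) {
        if (!R_finite(gp[d])) { bad = true; break; }
      }
      if (bad) { diverged = true; break; }
      for (int d = 0; d < D; ++d) p[d] += 0.5 * eps * gp[d];
    }
    double alpha = 0.0;
    if (!diverged) {
      lp_p = logpost_grad(qp.data(), gp.data(), data, L, true, true);
      if (!R_finite(lp_p)) diverged = true;
    }
    if (!diverged) {
      double kin1 = 0.0;
      for (int d = 0; d < D; ++d) kin1 += 0.5 * p[d] * p[d] * inv_mass[d];
      double dH = (lp_p - kin1) - (lp - kin0);
      if (dH < -1000.0) diverged = true;
      else alpha = dH > 0.0 ? 1.0 : exp(dH);
    }
    if (diverged) { alpha = 0.0; if (!warm) ++n_div; }
    if (!diverged && R::unif_rand() < alpha) {
      std::swap(q, qp);
      std::swap(grad, gp);
      lp = lp_p;
      if (!warm) ++n_accept;
    }

    if (warm) {
      // dual averaging toward the target acceptance rate
      ++adapt_count;
      double w = 1.0 / (adapt_count + t0);
      h_bar = (1.0 - w) * h_bar + w * (target_accept - alpha);
      double log_eps = mu - sqrt((double)adapt_count) / gamma * h_bar;
      double w2k = pow((double)adapt_count, -kappa);
      log_eps_bar = w2k * log_eps + (1.0 - w2k) * log_eps_bar;
      eps = exp(log_eps);
      if (it >= w1 && it < w2) {
        ++m_n;
        for (int d = 0; d < D; ++d) {
          double delta = q[d] - m_mean[d];
          m_mean[d] += delta / m_n;
          m_m2[d] += delta * (q[d] - m_mean[d]);
        }
      }
      if (it == w2 - 1 && m_n > 10) {
        for (int d = 0; d < D; ++d) {
          double v = m_m2[d] / (m_n - 1);
          // shrink toward unit variance as a regularizer
          inv_mass[d] = (m_n * v + 5.0) / (m_n + 5.0);
        }
        // restart step-size adaptation around the current step size
        mu = log(10.0 * eps);
        h_bar = 0.0; log_eps_bar = log(eps); adapt_count = 0;
      }
      if (it == n_warmup - 1) eps = exp(log_eps_bar);
    } else {
      for (int d = 0; d < D; ++d) draws(it - n_warmup, d) = q[d];
      lp_draws[it - n_warmup] = lp;
    }
  }
  return List::create(
    _["draws"] = draws, _["lp"] = lp_draws, _["step_size"] = eps,
    _["accept_rate"] = (double)n_accept / n_iter,
    _["divergences"] = n_div);
}
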