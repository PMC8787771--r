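// Adaptive Hamiltonian Monte Carlo for hierarchical Bayesian logistic
// regression with independent normal priors on fixed-effect coefficients and
// non-centered normal random-effect blocks with half-normal scale hyperpriors.
//
// Model, for record i with linear predictor f_i:
//   y_i ~ Bernoulli(inv_logit(f_i))
//   f_i = X_i . theta + sum_k mult_k[i] * sigma_k * z_k[g_k[i]]
//   theta_j ~ Normal(prior_mean_j, prior_sd_j)
//   z_k[.] ~ Normal(0, 1)          (non-centered)
//   sigma_k ~ half-Normal(0, scale_k), sampled as lsig_k = log(sigma_k)
//
// One call samples one chain; R drives the chain loop and seeds R's RNG, so
// results are reproducible through set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Block {
  IntegerVector g;     // 1..m group index per record (0 rows allowed)
  NumericVector mult;  // per-record multiplier (1 for intercepts, T_i for slopes)
  int m;
  double scale;
};

struct Post {
  int n, d, K, dim;
  NumericMatrix X;
  IntegerVector y;
  NumericVector pm, ps;
  std::vector<Block> blocks;

  // layout: theta[0..d) | for each k: z_k[m_k] then lsig_k
  int z_off(int k) const {
    int off = d;
    for (int j = 0; j < k; ++j) off += blocks[j].m + 1;
    return off;
  }

  static double log1pexp(double x) {
    if (x > 0) return x + std::log1p(std::exp(-x));
    return std::log1p(std::exp(x));
  }

  // log posterior and gradient (grad overwritten)
  double operator()(const std::vector<double>& q, std::vector<double>& grad) const {
    std::fill(grad.begin(), grad.end(), 0.0);
    double lp = 0.0;

    std::vector<double> sig(K), f(n, 0.0);
    for (int k = 0; k < K; ++k) sig[k] = std::exp(q[z_off(k) + blocks[k].m]);

    for (int i = 0; i < n; ++i) {
      double fi = 0.0;
      for (int j = 0; j < d; ++j) fi += X(i, j) * q[j];
      for (int k = 0; k < K; ++k) {
        const Block& b = blocks[k];
        fi += b.mult[i] * sig[k] * q[z_off(k) + b.g[i] - 1];
      }
      f[i] = fi;
    }

    // likelihood and df
    std::vector<double> r(n);
    for (int i = 0; i < n; ++i) {
      lp += y[i] * f[i] - log1pexp(f[i]);
      r[i] = y[i] - 1.0 / (1.0 + std::exp(-f[i]));
    }

    // chain rule into theta
    for (int j = 0; j < d; ++j) {
      double gj = 0.0;
      for (int i = 0; i < n; ++i) gj += X(i, j) * r[i];
      double dev = (q[j] - pm[j]) / (ps[j] * ps[j]);
      lp += -0.5 * (q[j] - pm[j]) * (q[j] - pm[j]) / (ps[j] * ps[j]);
      grad[j] = gj - dev;
    }

    // blocks
    for (int k = 0; k < K; ++k) {
      const Block& b = blocks[k];
      int zo = z_off(k);
      double dl = 0.0;  // data gradient wrt lsig
      for (int i = 0; i < n; ++i) {
        double c = b.mult[i] * r[i];
        grad[zo + b.g[i] - 1] += sig[k] * c;
        dl += c * q[zo + b.g[i] - 1];
      }
      for (int j = 0; j < b.m; ++j) {
        lp += -0.5 * q[zo + j] * q[zo + j];
        grad[zo + j] -= q[zo + j];
      }
      // half-normal(scale) on sigma with log-scale Jacobian
      double l = q[zo + b.m];
      lp += -0.5 * sig[k] * sig[k] / (b.scale * b.scale) + l;
      grad[zo + b.m] = sig[k] * dl - sig[k] * sig[k] / (b.scale * b.scale) + 1.0;
    }
    return lp;
  }
};

double kinetic(const std::vector<double>& p, const std::vector<double>& minv) {
  double k = 0.0;
  for (size_t j = 0; j < p.size(); ++j) k += 0.5 * p[j] * p[j] * minv[j];
  return k;
}

// one leapfrog trajectory; returns proposal + Hamiltonian error info
struct Traj {
  std::vector<double> q;
  double lp;
  double accept_stat;  // min(1, exp(-dH))
  bool divergent;
};

Traj leapfrog(const Post& post, const std::vector<double>& q0, double lp0,
              const std::vector<double>& grad0, const std::vector<double>& minv,
              double eps, int L) {
  int dim = post.dim;
  std::vector<double> q = q0, grad = grad0, p(dim);
  for (int j = 0; j < dim; ++j) p[j] = norm_rand() / std::sqrt(minv[j]);
  double H0 = -lp0 + kinetic(p, minv);

  double lp = lp0;
  bool bad = false;
  for (int s = 0; s < L; ++s) {
    for (int j = 0; j < dim; ++j) p[j] += 0.5 * eps * grad[j];
    for (int j = 0; j < dim; ++j) q[j] += eps * minv[j] * p[j];
    lp = post(q, grad);
    if (!std::isfinite(lp)) { bad = true; break; }
    for (int j = 0; j < dim; ++j) p[j] += 0.5 * eps * grad[j];
  }

  Traj t;
  double dH = bad ? INFINITY : (-lp + kinetic(p, minv)) - H0;
  t.divergent = !std::isfinite(dH) || dH > 1000.0;
  t.accept_stat = t.divergent ? 0.0 : std::min(1.0, std::exp(-dH));
  if (!bad && std::isfinite(dH) && unif_rand() < std::exp(-dH)) {
    t.q = q; t.lp = lp;
  } else {
    t.q = q0; t.lp = lp0;
  }
  return t;
}

}  // namespace

// [[Rcpp::export]]
List hmc_chain(NumericMatrix X, IntegerVector y, NumericVector prior_mean,
               NumericVector prior_sd, List blocks, int warmup, int iter,
               double target_accept, int max_leapfrog, NumericVector init) {
  Post post;
  post.n = X.nrow();
  post.d = X.ncol();
  post.X = X;
  post.y = y;
  post.pm = prior_mean;
  post.ps = prior_sd;
  post.K = blocks.size();
  for (int k = 0; k < post.K; ++k) {
    List bl = blocks[k];
    Block b;
    b.g = as<IntegerVector>(bl["g"]);
    b.mult = as<NumericVector>(bl["mult"]);
    b.m = as<int>(bl["m"]);
    b.scale = as<double>(bl["scale"]);
    post.blocks.push_back(b);
  }
  int dim = post.d;
  for (int k = 0; k < post.K; ++k) dim += post.blocks[k].m + 1;
  post.dim = dim;

  std::vector<double> q(init.begin(), init.end());
  std::vector<double> grad(dim), minv(dim, 1.0);
  double lp = post(q, grad);
  if (!std::isfinite(lp)) stop("non-finite log posterior at initial values");

  // find a reasonable initial step size (single-step heuristic)
  double eps = 0.1;
  {
    std::vector<double> g0 = grad;
    for (int tries = 0; tries < 30; ++tries) {
      Traj t = leapfrog(post, q, lp, g0, minv, eps, 1);
      if (t.accept_stat > 0.5) {
        if (eps >= 2.0) break;
        eps *= 2.0;
      } else {
        if (eps <= 1e-6) break;
        eps /= 2.0;
      }
      if (t.accept_stat > 0.4 && t.accept_stat < 0.9) break;
    }
  }

  // dual averaging state
  double mu = std::log(10.0 * eps), Hbar = 0.0, logebar = std::log(eps);
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75, delta = target_accept;
  int da_count = 0;
  auto da_reset = [&](double e) {
    mu = std::log(10.0 * e); Hbar = 0.0; logebar = std::log(e); da_count = 0;
  };
  auto da_update = [&](double astat) {
    ++da_count;
    Hbar = (1.0 - 1.0 / (da_count + t0)) * Hbar + (delta - astat) / (da_count + t0);
    double loge = mu - std::sqrt((double)da_count) / gamma * Hbar;
    double w = std::pow((double)da_count, -kappa);
    logebar = w * loge + (1.0 - w) * logebar;
    eps = std::exp(loge);
  };

  // mass adaptation windows within warmup
  int b1 = (int)std::floor(0.25 * warmup);
  int b2 = (int)std::floor(0.55 * warmup);
  int b3 = (int)std::floor(0.90 * warmup);
  std::vector<double> wsum(dim, 0.0), wsum2(dim, 0.0);
  int wn = 0;
  auto w_clear = [&]() { std::fill(wsum.begin(), wsum.end(), 0.0);
                         std::fill(wsum2.begin(), wsum2.end(), 0.0); wn = 0; };
  auto mass_update = [&]() {
    if (wn < 10) { w_clear(); return; }
    for (int j = 0; j < dim; ++j) {
      double mean = wsum[j] / wn;
      double var = (wsum2[j] - wn * mean * mean) / (wn - 1.0);
      // regularize toward unity as Stan does toward a small diagonal
      minv[j] = std::max(1e-8, (wn / (wn + 5.0)) * var + (5.0 / (wn + 5.0)) * 1.0);
    }
    w_clear();
  };

  NumericMatrix draws(iter, dim);
  int divergences = 0;
  double acc_sum = 0.0;
  int total = warmup + iter;

  for (int it = 1; it <= total; ++it) {
    bool in_warmup = it <= warmup;
    double e_use = in_warmup ? eps : std::exp(logebar);
    int L = 1 + (int)std::floor(unif_rand() * max_leapfrog);
    if (L > max_leapfrog) L = max_leapfrog;
    Traj t = leapfrog(post, q, lp, grad, minv, e_use, L);
    q = t.q; lp = t.lp;
    post(q, grad);  // refresh gradient at current state

    if (in_warmup) {
      da_update(t.accept_stat);
      if (it > b1 && it <= b2) {
        for (int j = 0; j < dim; ++j) { wsum[j] += q[j]; wsum2[j] += q[j] * q[j]; }
        ++wn;
        if (it == b2) { mass_update(); da_reset(std::exp(logebar)); }
      } else if (it > b2 && it <= b3) {
        for (int j = 0; j < dim; ++j) { wsum[j] += q[j]; wsum2[j] += q[j] * q[j]; }
        ++wn;
        if (it == b3) { mass_update(); da_reset(std::exp(logebar)); }
      }
    } else {
      int s = it - warmup - 1;
      for (int j = 0; j < dim; ++j) draws(s, j) = q[j];
      if (t.divergent) ++divergences;
      acc_sum += t.accept_stat;
    }
  }

  return List::create(_["draws"] = draws,
                      _["divergences"] = divergences,
                      _["accept_rate"] = iter > 0 ? acc_sum / iter : NA_REAL,
                      _["step_size"] = std::exp(logebar));
}
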