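#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

// The whole penalized-mixture machinery works on per-cell sufficient
// statistics: a normal cell log-likelihood over n_g observations depends on
// the data only through (n_g, ybar_g, SS_g), where SS_g is the within-cell
// sum of squares about the cell mean.

namespace {

struct Stats {
  std::vector<double> n, ybar, ss;
  int G() const { return static_cast<int>(n.size()); }
};

struct EmResult {
  std::vector<double> mu, s2, p;
  double obj = R_NegInf;     // penalized marginal log-likelihood at the optimum
  int iter = 0;
  bool converged = false;
  double worst_drop = 0.0;   // largest relative decrease of the objective seen
};

inline double cell_ll(double n, double ybar, double ss, double mu, double s2) {
  const double d = ybar - mu;
  return -0.5 * n * std::log(2.0 * M_PI * s2) - (ss + n * d * d) / (2.0 * s2);
}

// E-step in log space; fills s (G x K, row-major) and returns the penalized
// marginal log-likelihood  sum_g logsumexp_k(log p_k + L_gk) + sum_k log p_k.
double e_step_obj(const Stats& st, const std::vector<double>& mu,
                  const std::vector<double>& s2, const std::vector<double>& p,
                  std::vector<double>& s) {
  const int G = st.G(), K = static_cast<int>(mu.size());
  std::vector<double> a(K);
  double obj = 0.0;
  for (int g = 0; g < G; ++g) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      a[k] = std::log(p[k]) + cell_ll(st.n[g], st.ybar[g], st.ss[g], mu[k], s2[k]);
      if (a[k] > m) m = a[k];
    }
    double sum = 0.0;
    for (int k = 0; k < K; ++k) sum += std::exp(a[k] - m);
    const double lse = m + std::log(sum);
    obj += lse;
    for (int k = 0; k < K; ++k) s[g * K + k] = std::exp(a[k] - lse);
  }
  for (int k = 0; k < K; ++k) obj += std::log(p[k]);
  return obj;
}

// M-step: weighted means/variances (variance floored) and the penalized
// mixing-proportion update p_k = (1 + sum_g s_gk) / (K + G), which sums to 1
// by construction.  A component with essentially no mass keeps its previous
// mean and variance.
void m_step(const Stats& st, const std::vector<double>& s, int K, double floor_,
            std::vector<double>& mu, std::vector<double>& s2,
            std::vector<double>& p) {
  const int G = st.G();
  for (int k = 0; k < K; ++k) {
    double W = 0.0, D = 0.0, num = 0.0;
    for (int g = 0; g < G; ++g) {
      const double w = s[g * K + k];
      W += w;
      D += w * st.n[g];
      num += w * st.n[g] * st.ybar[g];
    }
    p[k] = (1.0 + W) / static_cast<double>(K + G);
    if (D > 1e-12) {
      const double m = num / D;
      double v = 0.0;
      for (int g = 0; g < G; ++g) {
        const double d = st.ybar[g] - m;
        v += s[g * K + k] * (st.ss[g] + st.n[g] * d * d);
      }
      mu[k] = m;
      s2[k] = std::max(v / D, floor_);
    }
  }
}

EmResult em_run(const Stats& st, int K, const std::vector<int>& init_assign,
                int max_iter, double rel_tol, double floor_) {
  const int G = st.G();
  EmResult r;
  double N = 0.0, sy = 0.0;
  for (int g = 0; g < G; ++g) { N += st.n[g]; sy += st.n[g] * st.ybar[g]; }
  const double gm = sy / N;
  double tot = 0.0;
  for (int g = 0; g < G; ++g) {
    const double d = st.ybar[g] - gm;
    tot += st.ss[g] + st.n[g] * d * d;
  }
  const double gv = std::max(tot / N, floor_);
  r.mu.assign(K, gm);
  r.s2.assign(K, gv);
  r.p.assign(K, 1.0 / K);

  std::vector<double> s(static_cast<size_t>(G) * K, 0.0);
  for (int g = 0; g < G; ++g) s[g * K + init_assign[g]] = 1.0;
  m_step(st, s, K, floor_, r.mu, r.s2, r.p);

  double prev = R_NegInf;
  for (int it = 1; it <= max_iter; ++it) {
    const double obj = e_step_obj(st, r.mu, r.s2, r.p, s);
    r.iter = it;
    r.obj = obj;
    if (R_FINITE(prev)) {
      const double denom = std::fabs(prev) + 1e-10;
      const double drop = (prev - obj) / denom;
      if (drop > r.worst_drop) r.worst_drop = drop;
      if (std::fabs(obj - prev) / denom < rel_tol) {
        r.converged = true;
        return r;
      }
    }
    prev = obj;
    m_step(st, s, K, floor_, r.mu, r.s2, r.p);
  }
  // report the objective at the final parameter values
  r.obj = e_step_obj(st, r.mu, r.s2, r.p, s);
  return r;
}

// Rank-based initial hard assignments: cells ordered by mean, cut into K
// contiguous segments.  Start 0 uses equal-frequency quantile cuts; the
// remaining starts draw K-1 distinct cut points uniformly from the G-1 gaps.
std::vector<int> order_by(const std::vector<double>& x) {
  std::vector<int> ord(x.size());
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  return ord;
}

std::vector<int> assign_from_cuts(const std::vector<int>& ord,
                                  const std::vector<int>& cuts, int G) {
  std::vector<int> a(G);
  int k = 0;
  for (int r = 0; r < G; ++r) {
    while (k < static_cast<int>(cuts.size()) && r >= cuts[k]) ++k;
    a[ord[r]] = k;
  }
  return a;
}

std::vector<int> quantile_cuts(int G, int K) {
  std::vector<int> cuts;
  for (int j = 1; j < K; ++j) {
    int c = static_cast<int>(std::floor(static_cast<double>(G) * j / K + 0.5));
    c = std::max(j, std::min(c, G - (K - j)));  // keep segments nonempty
    cuts.push_back(c);
  }
  return cuts;
}

std::vector<int> random_cuts(int G, int K) {
  // draw K-1 distinct values from 1..G-1 (partial Fisher-Yates, R RNG)
  std::vector<int> pool(G - 1);
  std::iota(pool.begin(), pool.end(), 1);
  const int m = K - 1;
  for (int j = 0; j < m; ++j) {
    const int pick = j + static_cast<int>(unif_rand() * (pool.size() - j));
    std::swap(pool[j], pool[std::min<int>(pick, pool.size() - 1)]);
  }
  std::vector<int> cuts(pool.begin(), pool.begin() + m);
  std::sort(cuts.begin(), cuts.end());
  return cuts;
}

EmResult em_best(const Stats& st, int K, int n_starts, int max_iter,
                 double rel_tol, double floor_) {
  const int G = st.G();
  const std::vector<int> ord = order_by(st.ybar);
  EmResult best;
  const int starts = (K == 1) ? 1 : n_starts;
  for (int sidx = 0; sidx < starts; ++sidx) {
    std::vector<int> cuts =
        (sidx == 0) ? quantile_cuts(G, K) : random_cuts(G, K);
    const std::vector<int> a = assign_from_cuts(ord, cuts, G);
    EmResult r = em_run(st, K, a, max_iter, rel_tol, floor_);
    if (r.obj > best.obj) {
      const double wd = std::max(best.worst_drop, r.worst_drop);
      best = r;
      best.worst_drop = wd;
    } else if (r.worst_drop > best.worst_drop) {
      best.worst_drop = r.worst_drop;
    }
  }
  return best;
}

// canonical component order: ascending mean, ties by ascending variance
std::vector<int> canonical_order(const std::vector<double>& mu,
                                 const std::vector<double>& s2) {
  std::vector<int> ord(mu.size());
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (mu[a] != mu[b]) return mu[a] < mu[b];
    return s2[a] < s2[b];
  });
  return ord;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_mixture(NumericVector n, NumericVector ybar, NumericVector ss,
                     int K, int n_starts, int max_iter, double rel_tol,
                     double sigma2_floor) {
  Stats st;
  st.n = as<std::vector<double>>(n);
  st.ybar = as<std::vector<double>>(ybar);
  st.ss = as<std::vector<double>>(ss);
  const int G = st.G();

  EmResult r = em_best(st, K, n_starts, max_iter, rel_tol, sigma2_floor);

  const std::vector<int> ord = canonical_order(r.mu, r.s2);
  std::vector<double> mu(K), s2(K), p(K);
  for (int k = 0; k < K; ++k) {
    mu[k] = r.mu[ord[k]];
    s2[k] = r.s2[ord[k]];
    p[k] = r.p[ord[k]];
  }
  std::vector<double> s(static_cast<size_t>(G) * K);
  const double obj = e_step_obj(st, mu, s2, p, s);

  NumericMatrix smat(G, K);
  for (int g = 0; g < G; ++g)
    for (int k = 0; k < K; ++k) smat(g, k) = s[g * K + k];

  return List::create(_["mu"] = wrap(mu), _["sigma2"] = wrap(s2),
                      _["p"] = wrap(p), _["s"] = smat, _["objective"] = obj,
                      _["n_iter"] = r.iter, _["converged"] = r.converged,
                      _["worst_drop"] = r.worst_drop);
}

// Parametric bootstrap of the sequential LRT statistic: simulate datasets
// from the fitted K1-component model on the observed cell structure (same G
// and n_g; each cell drawn into a component by p, then its sufficient
// statistics drawn as ybar* ~ N(mu_z, s2_z/n_g), SS* ~ s2_z * chisq(n_g - 1)),
// refit both K1 and K2 from scratch, and return lambda* = -2(pl(K1)-pl(K2)).
// [[Rcpp::export]]
NumericVector cpp_boot_lambda(NumericVector n, NumericVector mu0,
                              NumericVector sigma20, NumericVector p0, int K2,
                              int n_boot, int n_starts, int max_iter,
                              double rel_tol, double floor_frac) {
  const int G = n.size();
  const int K1 = mu0.size();
  std::vector<double> cump(K1);
  double acc = 0.0;
  for (int k = 0; k < K1; ++k) { acc += p0[k]; cump[k] = acc; }
  cump[K1 - 1] = 1.0;

  NumericVector lambda(n_boot);
  Stats st;
  st.n = as<std::vector<double>>(n);
  st.ybar.assign(G, 0.0);
  st.ss.assign(G, 0.0);

  for (int b = 0; b < n_boot; ++b) {
    for (int g = 0; g < G; ++g) {
      const double u = unif_rand();
      int z = 0;
      while (z < K1 - 1 && u > cump[z]) ++z;
      st.ybar[g] = mu0[z] + norm_rand() * std::sqrt(sigma20[z] / st.n[g]);
      st.ss[g] = (st.n[g] > 1.0) ? sigma20[z] * R::rchisq(st.n[g] - 1.0) : 0.0;
    }
    double N = 0.0, sy = 0.0;
    for (int g = 0; g < G; ++g) { N += st.n[g]; sy += st.n[g] * st.ybar[g]; }
    const double gm = sy / N;
    double tot = 0.0;
    for (int g = 0; g < G; ++g) {
      const double d = st.ybar[g] - gm;
      tot += st.ss[g] + st.n[g] * d * d;
    }
    double floor_ = floor_frac * (tot / N);
    if (!(floor_ > 0.0)) floor_ = 1e-12;

    const EmResult f1 = em_best(st, K1, n_starts, max_iter, rel_tol, floor_);
    const EmResult f2 = em_best(st, K2, n_starts, max_iter, rel_tol, floor_);
    lambda[b] = -2.0 * (f1.obj - f2.obj);
  }
  return lambda;
}
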