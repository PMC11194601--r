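// Adaptive random-walk Metropolis-within-Gibbs sampler for the hierarchical
// Poisson richness model, in the non-centered parameterization:
//
//   log mu_i = offset_i + b0 + bimp * x_i + s0 * z0[city_i]
//              + I(grade_i > 0) * ( beta[grade_i] + s[grade_i] * zg[grade_i, city_i] )
//
// with b0, beta_g, bimp ~ Normal(0, prior_sd), z ~ Normal(0, 1), and the
// random-effect SDs s = exp(t) given Gamma(shape, rate) priors (sampled on
// the log scale with the Jacobian folded into the target). Proposal scales
// adapt toward a 0.44 acceptance rate during burn-in only. R's RNG supplies
// all randomness, so draws are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Model {
  NumericVector y, offset, x;
  IntegerVector city, grade; // 0-based; grade 0 = reference
  int n, C, K;               // K = number of non-reference grades
  bool include_x;
  double prior_sd, g_shape, g_rate;
  std::vector<bool> sigma_fixed;
  std::vector<double> sigma_fixed_val; // length K + 1 when fixed

  // state
  std::vector<double> beta;  // K non-reference grade effects
  double b0, bimp;
  std::vector<double> z0;        // C
  std::vector<double> zg;        // K * C, g-major: zg[g * C + c]
  std::vector<double> t;         // K + 1 log-SDs: t[0] intercept, t[1..K] slopes
  std::vector<double> eta, mu;

  double sigma(int j) const {
    return sigma_fixed[j] ? sigma_fixed_val[j] : std::exp(t[j]);
  }

  void recompute_eta() {
    for (int i = 0; i < n; ++i) {
      double e = offset[i] + b0 + sigma(0) * z0[city[i]];
      if (include_x) e += bimp * x[i];
      int g = grade[i];
      if (g > 0) e += beta[g - 1] + sigma(g) * zg[(g - 1) * C + city[i]];
      eta[i] = e;
      mu[i] = std::exp(e);
    }
  }
};

// log-likelihood change for a set of rows given per-row eta deltas
inline double delta_loglik(const Model& m, const std::vector<int>& rows,
                           const std::vector<double>& delta, bool& ok) {
  double d = 0.0;
  ok = true;
  for (size_t r = 0; r < rows.size(); ++r) {
    int i = rows[r];
    double eta_new = m.eta[i] + delta[r];
    if (eta_new > 700.0) { ok = false; return 0.0; }
    d += m.y[i] * delta[r] - (std::exp(eta_new) - m.mu[i]);
  }
  return d;
}

inline void apply_delta(Model& m, const std::vector<int>& rows,
                        const std::vector<double>& delta) {
  for (size_t r = 0; r < rows.size(); ++r) {
    int i = rows[r];
    m.eta[i] += delta[r];
    m.mu[i] = std::exp(m.eta[i]);
  }
}

} // namespace

// [[Rcpp::export(name = ".mwg_sample")]]
List mwg_sample(NumericVector y, NumericVector offset, NumericVector x,
                IntegerVector city, IntegerVector grade,
                int n_city, int n_grade, bool include_x,
                NumericVector init, int n_burn, int n_iter,
                double prior_sd, double gamma_shape, double gamma_rate,
                NumericVector fix_sigma) {
  Model m;
  m.y = y; m.offset = offset; m.x = x; m.city = city; m.grade = grade;
  m.n = y.size(); m.C = n_city; m.K = n_grade - 1;
  m.include_x = include_x;
  m.prior_sd = prior_sd; m.g_shape = gamma_shape; m.g_rate = gamma_rate;

  const int K = m.K, C = m.C;
  const int n_sd = K + 1;
  bool fixed = fix_sigma.size() > 0;
  m.sigma_fixed.assign(n_sd, fixed);
  m.sigma_fixed_val.assign(n_sd, 0.0);
  if (fixed) {
    if (fix_sigma.size() != n_sd) stop("fix_sigma must have length K + 1");
    for (int j = 0; j < n_sd; ++j) m.sigma_fixed_val[j] = fix_sigma[j];
  }

  // unpack init: b0, beta[K], bimp, z0[C], zg[K*C], t[K+1]
  int npar = 1 + K + 1 + C + K * C + n_sd;
  if (init.size() != npar) stop("init has wrong length");
  int pos = 0;
  m.b0 = init[pos++];
  m.beta.assign(K, 0.0);
  for (int g = 0; g < K; ++g) m.beta[g] = init[pos++];
  m.bimp = init[pos++];
  m.z0.assign(C, 0.0);
  for (int c = 0; c < C; ++c) m.z0[c] = init[pos++];
  m.zg.assign(K * C, 0.0);
  for (int j = 0; j < K * C; ++j) m.zg[j] = init[pos++];
  m.t.assign(n_sd, 0.0);
  for (int j = 0; j < n_sd; ++j) m.t[j] = init[pos++];
  if (fixed) for (int j = 0; j < n_sd; ++j) m.t[j] = std::log(m.sigma_fixed_val[j]);

  m.eta.assign(m.n, 0.0);
  m.mu.assign(m.n, 0.0);
  m.recompute_eta();

  // row index sets
  std::vector<int> rows_all(m.n);
  for (int i = 0; i < m.n; ++i) rows_all[i] = i;
  std::vector< std::vector<int> > rows_city(C), rows_grade(K + 1);
  std::vector< std::vector<int> > rows_cg(K * C);
  for (int i = 0; i < m.n; ++i) {
    rows_city[city[i]].push_back(i);
    rows_grade[grade[i]].push_back(i);
    if (grade[i] > 0) rows_cg[(grade[i] - 1) * C + city[i]].push_back(i);
  }

  // updatable parameter list: (kind, index)
  // kinds: 0 b0, 1 beta_g, 2 bimp, 3 z0_c, 4 zg_{g,c}, 5 t0, 6 t_g
  // likelihood-invariant group moves against hierarchical confounding:
  // 7 translate (b0, z0), 8 translate (beta_g, zg_g),
  // 9 rescale (t0, z0), 10 rescale (t_g, zg_g)
  std::vector< std::pair<int,int> > upd;
  upd.push_back(std::make_pair(0, 0));
  for (int g = 0; g < K; ++g) upd.push_back(std::make_pair(1, g));
  if (include_x) upd.push_back(std::make_pair(2, 0));
  for (int c = 0; c < C; ++c) upd.push_back(std::make_pair(3, c));
  for (int j = 0; j < K * C; ++j) upd.push_back(std::make_pair(4, j));
  if (!fixed) {
    upd.push_back(std::make_pair(5, 0));
    for (int g = 0; g < K; ++g) upd.push_back(std::make_pair(6, g));
  }
  upd.push_back(std::make_pair(7, 0));
  for (int g = 0; g < K; ++g) upd.push_back(std::make_pair(8, g));
  if (!fixed) {
    upd.push_back(std::make_pair(9, 0));
    for (int g = 0; g < K; ++g) upd.push_back(std::make_pair(10, g));
  }
  // 11: intercept-vs-grade-effects block move (b0 += eps, all beta_g -= eps);
  // equivalent to a random walk on the reference grade's own intercept, so
  // the per-grade likelihood blocks decouple and the correlated fixed-effect
  // posterior mixes quickly
  if (K > 0) upd.push_back(std::make_pair(11, 0));
  // 12: adaptive multivariate random walk on the whole fixed-effect block
  // (b0, beta_g, bimp), with covariance learned during burn-in; handles the
  // strong grade-covariate collinearity a grade-ordered urban-intensity
  // covariate induces
  upd.push_back(std::make_pair(12, 0));
  const int n_upd = upd.size();

  const int p_fix = 1 + K + (include_x ? 1 : 0);
  std::vector<double> fix_mean(p_fix, 0.0);
  std::vector<double> fix_m2(p_fix * p_fix, 0.0);
  long fix_n = 0;
  std::vector<double> fix_chol(p_fix * p_fix, 0.0);
  bool have_chol = false;
  std::vector<double> fix_cur(p_fix), fix_eps(p_fix), fix_raw(p_fix);

  // lower-triangular Cholesky of the (regularized) sample covariance
  auto update_chol = [&]() {
    if (fix_n < 20 * p_fix) return;
    std::vector<double> S(p_fix * p_fix);
    for (int a = 0; a < p_fix * p_fix; ++a) S[a] = fix_m2[a] / (fix_n - 1);
    for (int a = 0; a < p_fix; ++a) S[a * p_fix + a] += 1e-10 + 1e-6 * S[a * p_fix + a];
    for (int a = 0; a < p_fix; ++a) {
      for (int b2 = 0; b2 <= a; ++b2) {
        double s = S[a * p_fix + b2];
        for (int k2 = 0; k2 < b2; ++k2) {
          s -= fix_chol[a * p_fix + k2] * fix_chol[b2 * p_fix + k2];
        }
        if (a == b2) {
          if (s <= 0) return; // keep the previous factor
          fix_chol[a * p_fix + a] = std::sqrt(s);
        } else {
          fix_chol[a * p_fix + b2] = s / fix_chol[b2 * p_fix + b2];
        }
      }
    }
    have_chol = true;
  };

  std::vector<double> log_step(n_upd, std::log(0.2));
  log_step[n_upd - 1] = 0.0; // block move: unit scale on the learned factor
  std::vector<int> acc_count(n_upd, 0), prop_count(n_upd, 0);
  std::vector<double> acc_total(n_upd, 0.0), prop_total(n_upd, 0.0);

  // output: b0, beta[K], bimp, sigma[K+1], u0[C], ug[K*C]
  int ncol_out = 1 + K + 1 + n_sd + C + K * C;
  NumericMatrix draws(n_iter, ncol_out);

  RNGScope scope;
  std::vector<double> delta;
  std::vector<int> no_rows;

  for (int iter = 0; iter < n_burn + n_iter; ++iter) {
    bool adapting = iter < n_burn;
    for (int u = 0; u < n_upd; ++u) {
      int kind = upd[u].first, idx = upd[u].second;
      double step = std::exp(log_step[u]);
      double eps = R::norm_rand() * step;
      const std::vector<int>* rows = &no_rows;
      double dprior = 0.0;
      double cur = 0.0;

      if (kind == 12) {
        double s = std::exp(log_step[u]);
        for (int a = 0; a < p_fix; ++a) fix_raw[a] = R::norm_rand();
        if (have_chol) {
          for (int a = 0; a < p_fix; ++a) {
            double acc2 = 0.0;
            for (int b2 = 0; b2 <= a; ++b2) {
              acc2 += fix_chol[a * p_fix + b2] * fix_raw[b2];
            }
            fix_eps[a] = s * acc2;
          }
        } else {
          for (int a = 0; a < p_fix; ++a) fix_eps[a] = s * 0.05 * fix_raw[a];
        }
        delta.resize(m.n);
        for (int i = 0; i < m.n; ++i) {
          double d2 = fix_eps[0];
          if (m.grade[i] > 0) d2 += fix_eps[m.grade[i]];
          if (include_x) d2 += fix_eps[1 + K] * m.x[i];
          delta[i] = d2;
        }
        bool okb = true;
        double dll = delta_loglik(m, rows_all, delta, okb);
        double dp = 0.0;
        {
          double b = m.b0, bn = b + fix_eps[0];
          dp += (b * b - bn * bn) / (2 * prior_sd * prior_sd);
          for (int g = 0; g < K; ++g) {
            double bb = m.beta[g], bbn = bb + fix_eps[1 + g];
            dp += (bb * bb - bbn * bbn) / (2 * prior_sd * prior_sd);
          }
          if (include_x) {
            double bi = m.bimp, bin = bi + fix_eps[1 + K];
            dp += (bi * bi - bin * bin) / (2 * prior_sd * prior_sd);
          }
        }
        double log_alpha = okb ? (dll + dp) : R_NegInf;
        prop_count[u]++; prop_total[u] += 1.0;
        if (okb && (log_alpha >= 0.0 || std::log(unif_rand()) < log_alpha)) {
          acc_count[u]++; acc_total[u] += 1.0;
          apply_delta(m, rows_all, delta);
          m.b0 += fix_eps[0];
          for (int g = 0; g < K; ++g) m.beta[g] += fix_eps[1 + g];
          if (include_x) m.bimp += fix_eps[1 + K];
        }
        if (adapting && prop_count[u] == 50) {
          double rate = acc_count[u] / 50.0;
          double batch = (iter + 1) / 50.0;
          double gain = std::min(0.05, 1.0 / std::sqrt(batch));
          log_step[u] += (rate > 0.28 ? gain : -gain);
          prop_count[u] = 0; acc_count[u] = 0;
        }
        continue;
      }

      if (kind == 11) {
        // b0 += eps, beta_g -= eps for every g: eta changes on reference
        // grade rows only
        const std::vector<int>& rrows = rows_grade[0];
        delta.assign(rrows.size(), eps);
        bool ok11 = true;
        double dll = delta_loglik(m, rrows, delta, ok11);
        double dp = (m.b0 * m.b0 - (m.b0 + eps) * (m.b0 + eps)) /
          (2 * prior_sd * prior_sd);
        for (int g = 0; g < K; ++g) {
          double b = m.beta[g], bn = b - eps;
          dp += (b * b - bn * bn) / (2 * prior_sd * prior_sd);
        }
        double log_alpha = ok11 ? (dll + dp) : R_NegInf;
        prop_count[u]++; prop_total[u] += 1.0;
        if (ok11 && (log_alpha >= 0.0 || std::log(unif_rand()) < log_alpha)) {
          acc_count[u]++; acc_total[u] += 1.0;
          apply_delta(m, rrows, delta);
          m.b0 += eps;
          for (int g = 0; g < K; ++g) m.beta[g] -= eps;
        }
        if (adapting && prop_count[u] == 50) {
          double rate = acc_count[u] / 50.0;
          double batch = (iter + 1) / 50.0;
          double gain = std::min(0.05, 1.0 / std::sqrt(batch));
          log_step[u] += (rate > 0.44 ? gain : -gain);
          prop_count[u] = 0; acc_count[u] = 0;
        }
        continue;
      }

      if (kind >= 7) {
        // likelihood-invariant moves: eta and mu are untouched
        double log_alpha = 0.0;
        if (kind == 7 || kind == 8) {
          double b_cur = (kind == 7) ? m.b0 : m.beta[idx];
          double s = m.sigma(kind == 7 ? 0 : idx + 1);
          std::vector<double>& z = (kind == 7) ? m.z0 : m.zg;
          int lo = (kind == 7) ? 0 : idx * C;
          log_alpha += (b_cur * b_cur - (b_cur + eps) * (b_cur + eps)) /
            (2 * prior_sd * prior_sd);
          for (int c = 0; c < C; ++c) {
            double zc = z[lo + c], zn = zc - eps / s;
            log_alpha += (zc * zc - zn * zn) / 2.0;
          }
          prop_count[u]++; prop_total[u] += 1.0;
          if (log_alpha >= 0.0 || std::log(unif_rand()) < log_alpha) {
            acc_count[u]++; acc_total[u] += 1.0;
            if (kind == 7) m.b0 += eps; else m.beta[idx] += eps;
            for (int c = 0; c < C; ++c) z[lo + c] -= eps / s;
          }
        } else {
          // rescale: t += eps, z *= exp(-eps); u = sigma * z is invariant
          int j = (kind == 9) ? 0 : idx + 1;
          std::vector<double>& z = (kind == 9) ? m.z0 : m.zg;
          int lo = (kind == 9) ? 0 : idx * C;
          double t_cur = m.t[j];
          double s_old = std::exp(t_cur), s_new = std::exp(t_cur + eps);
          log_alpha += gamma_shape * eps - gamma_rate * (s_new - s_old);
          double shrink = std::exp(-eps);
          for (int c = 0; c < C; ++c) {
            double zc = z[lo + c], zn = zc * shrink;
            log_alpha += (zc * zc - zn * zn) / 2.0;
          }
          log_alpha += -static_cast<double>(C) * eps; // log-Jacobian
          prop_count[u]++; prop_total[u] += 1.0;
          if (log_alpha >= 0.0 || std::log(unif_rand()) < log_alpha) {
            acc_count[u]++; acc_total[u] += 1.0;
            m.t[j] += eps;
            for (int c = 0; c < C; ++c) z[lo + c] *= shrink;
          }
        }
        if (adapting && prop_count[u] == 50) {
          double rate = acc_count[u] / 50.0;
          double batch = (iter + 1) / 50.0;
          double gain = std::min(0.05, 1.0 / std::sqrt(batch));
          log_step[u] += (rate > 0.44 ? gain : -gain);
          prop_count[u] = 0; acc_count[u] = 0;
        }
        continue;
      }

      switch (kind) {
      case 0: { // b0
        rows = &rows_all;
        cur = m.b0;
        dprior = (cur * cur - (cur + eps) * (cur + eps)) / (2 * prior_sd * prior_sd);
        delta.assign(rows->size(), eps);
        break;
      }
      case 1: { // beta_g
        rows = &rows_grade[idx + 1];
        cur = m.beta[idx];
        dprior = (cur * cur - (cur + eps) * (cur + eps)) / (2 * prior_sd * prior_sd);
        delta.assign(rows->size(), eps);
        break;
      }
      case 2: { // bimp
        rows = &rows_all;
        cur = m.bimp;
        dprior = (cur * cur - (cur + eps) * (cur + eps)) / (2 * prior_sd * prior_sd);
        delta.resize(rows->size());
        for (size_t r = 0; r < rows->size(); ++r) delta[r] = eps * m.x[(*rows)[r]];
        break;
      }
      case 3: { // z0_c
        rows = &rows_city[idx];
        cur = m.z0[idx];
        dprior = (cur * cur - (cur + eps) * (cur + eps)) / 2.0;
        delta.assign(rows->size(), eps * m.sigma(0));
        break;
      }
      case 4: { // zg_{g,c}
        rows = &rows_cg[idx];
        cur = m.zg[idx];
        dprior = (cur * cur - (cur + eps) * (cur + eps)) / 2.0;
        int g = idx / C + 1;
        delta.assign(rows->size(), eps * m.sigma(g));
        break;
      }
      case 5: { // t0 (log sigma intercept)
        rows = &rows_all;
        cur = m.t[0];
        double s_old = std::exp(cur), s_new = std::exp(cur + eps);
        dprior = gamma_shape * eps - gamma_rate * (s_new - s_old);
        delta.resize(rows->size());
        for (size_t r = 0; r < rows->size(); ++r) {
          delta[r] = (s_new - s_old) * m.z0[m.city[(*rows)[r]]];
        }
        break;
      }
      case 6: { // t_g (log sigma slope, grade idx+1)
        int g = idx + 1;
        rows = &rows_grade[g];
        cur = m.t[g];
        double s_old = std::exp(cur), s_new = std::exp(cur + eps);
        dprior = gamma_shape * eps - gamma_rate * (s_new - s_old);
        delta.resize(rows->size());
        for (size_t r = 0; r < rows->size(); ++r) {
          delta[r] = (s_new - s_old) * m.zg[idx * C + m.city[(*rows)[r]]];
        }
        break;
      }
      }

      bool ok = true;
      double dll = delta_loglik(m, *rows, delta, ok);
      double log_alpha = ok ? (dll + dprior) : R_NegInf;
      prop_count[u]++; prop_total[u] += 1.0;
      bool accept = ok && (log_alpha >= 0.0 || std::log(unif_rand()) < log_alpha);
      if (accept) {
        acc_count[u]++; acc_total[u] += 1.0;
        apply_delta(m, *rows, delta);
        switch (kind) {
        case 0: m.b0 += eps; break;
        case 1: m.beta[idx] += eps; break;
        case 2: m.bimp += eps; break;
        case 3: m.z0[idx] += eps; break;
        case 4: m.zg[idx] += eps; break;
        case 5: m.t[0] += eps; break;
        case 6: m.t[idx + 1] += eps; break;
        }
      }

      if (adapting && prop_count[u] == 50) {
        double rate = acc_count[u] / 50.0;
        double batch = (iter + 1) / 50.0;
        double gain = std::min(0.05, 1.0 / std::sqrt(batch));
        log_step[u] += (rate > 0.44 ? gain : -gain);
        prop_count[u] = 0; acc_count[u] = 0;
      }
    }

    if (adapting) {
      // accumulate the fixed-effect block's running covariance (Welford)
      fix_cur[0] = m.b0;
      for (int g = 0; g < K; ++g) fix_cur[1 + g] = m.beta[g];
      if (include_x) fix_cur[1 + K] = m.bimp;
      fix_n++;
      for (int a = 0; a < p_fix; ++a) {
        fix_raw[a] = fix_cur[a] - fix_mean[a]; // pre-update deviation
        fix_mean[a] += fix_raw[a] / fix_n;
        fix_eps[a] = fix_cur[a] - fix_mean[a]; // post-update deviation
      }
      for (int a = 0; a < p_fix; ++a) {
        for (int b2 = 0; b2 < p_fix; ++b2) {
          fix_m2[a * p_fix + b2] += fix_raw[a] * fix_eps[b2];
        }
      }
      if (iter % 100 == 99) update_chol();
    }

    if (iter >= n_burn) {
      int r = iter - n_burn, c = 0;
      draws(r, c++) = m.b0;
      for (int g = 0; g < K; ++g) draws(r, c++) = m.beta[g];
      draws(r, c++) = m.bimp;
      for (int j = 0; j < n_sd; ++j) draws(r, c++) = m.sigma(j);
      for (int ci = 0; ci < C; ++ci) draws(r, c++) = m.sigma(0) * m.z0[ci];
      for (int j = 0; j < K * C; ++j) draws(r, c++) = m.sigma(j / C + 1) * m.zg[j];
    }
  }

  NumericVector acc_rates(n_upd);
  for (int u = 0; u < n_upd; ++u) {
    acc_rates[u] = prop_total[u] > 0 ? acc_total[u] / prop_total[u] : NA_REAL;
  }
  return List::create(_["draws"] = draws, _["acceptance"] = acc_rates);
}
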