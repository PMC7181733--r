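// Componentwise adaptive random-walk Metropolis for the two hierarchical
// model families (Normal identity-link, Gamma log-link, mean-shape form).
//
// Reported parameter layout (must match the R side, see hier_model()):
//   beta[0..p-1], u[0..nu-1], v[0..nv-1],
//   log_tau_u (if nu>0), log_tau_v (if nv>0), log_sigma | log_k
//
// Internally the pooled effects are sampled in NON-CENTERED form
// (u = tau_u * u_raw with u_raw ~ N(0,1), likewise v), which removes the
// funnel pathology of centered random-walk updates; draws are stored on the
// centered scale. The linear predictor eta_i = X_i beta + tau_u u_raw[g1_i]
// + tau_v v_raw[g2_i] * z_i is cached and updated incrementally, and exact
// Gibbs recentering moves shift each fixed effect along its
// likelihood-invariant direction against the pooled terms.
// Uses R's RNG so runs are reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const int LIK_NORMAL = 0;
const int LIK_GAMMA = 1;

struct HierData {
  NumericVector y, z;
  NumericMatrix X;
  IntegerVector g1, g2; // 1-based group index per row
  int lik, n, p, nu, nv;
  double beta_sd, cauchy_scale, shape_rate;
  std::vector<std::vector<int> > rows_u, rows_v;
  NumericVector logy; // log(y), gamma only
};

// pointwise log likelihood given eta and scale (sigma or k)
inline double ld_point(const HierData &d, int i, double eta, double scale) {
  if (d.lik == LIK_NORMAL) {
    double r = (d.y[i] - eta) / scale;
    return -0.918938533204672742 - std::log(scale) - 0.5 * r * r;
  }
  double k = scale; // Gamma: shape k, mean exp(eta)
  return k * std::log(k) - k * eta - R::lgammafn(k) + (k - 1.0) * d.logy[i] -
         k * d.y[i] * std::exp(-eta);
}

double loglik_all(const HierData &d, const NumericVector &eta, double scale) {
  double s = 0.0;
  for (int i = 0; i < d.n; ++i) s += ld_point(d, i, eta[i], scale);
  return s;
}

inline double log_half_cauchy(double x, double s) {
  return std::log(2.0) - std::log(M_PI) - std::log(s) - std::log1p((x / s) * (x / s));
}

// log prior of one scale parameter given its log value (with log-Jacobian)
inline double scale_logprior(const HierData &d, bool is_shape, double logval) {
  double val = std::exp(logval);
  if (!is_shape) return log_half_cauchy(val, d.cauchy_scale) + logval;
  return R::dexp(val, 1.0 / d.shape_rate, 1) + logval;
}

HierData build_data(List data) {
  HierData d;
  d.y = data["y"];
  d.X = as<NumericMatrix>(data["X"]);
  d.lik = as<int>(data["lik"]);
  d.n = d.y.size();
  d.p = d.X.ncol();
  d.beta_sd = as<double>(data["beta_sd"]);
  d.cauchy_scale = as<double>(data["cauchy_scale"]);
  d.shape_rate = as<double>(data["shape_rate"]);
  d.g1 = !Rf_isNull(data["g1"]) ? as<IntegerVector>(data["g1"]) : IntegerVector(0);
  d.g2 = !Rf_isNull(data["g2"]) ? as<IntegerVector>(data["g2"]) : IntegerVector(0);
  d.z = !Rf_isNull(data["z"]) ? as<NumericVector>(data["z"]) : NumericVector(0);
  d.nu = as<int>(data["nu"]);
  d.nv = as<int>(data["nv"]);
  d.rows_u.assign(d.nu, std::vector<int>());
  for (int i = 0; i < d.g1.size(); ++i) d.rows_u[d.g1[i] - 1].push_back(i);
  d.rows_v.assign(d.nv, std::vector<int>());
  for (int i = 0; i < d.g2.size(); ++i) d.rows_v[d.g2[i] - 1].push_back(i);
  if (d.lik == LIK_GAMMA) {
    d.logy = NumericVector(d.n);
    for (int i = 0; i < d.n; ++i) d.logy[i] = std::log(d.y[i]);
  }
  return d;
}

} // namespace

// Exact log posterior on the CENTERED parameterization; the reference for
// cross-checking against the pure-R log_posterior().
// [[Rcpp::export(name = ".lp_hier_cpp")]]
double lp_hier_cpp(List data, NumericVector params) {
  HierData d = build_data(data);
  int i_tau_u = d.p + d.nu + d.nv;
  int i_tau_v = i_tau_u + (d.nu > 0 ? 1 : 0);
  int i_scale = i_tau_v + (d.nv > 0 ? 1 : 0);
  if (i_scale + 1 != params.size()) stop("parameter vector length does not match model layout");
  double lp = 0.0;
  for (int j = 0; j < d.p; ++j) lp += R::dnorm(params[j], 0.0, d.beta_sd, 1);
  if (d.nu > 0) {
    double tau = std::exp(params[i_tau_u]);
    lp += scale_logprior(d, false, params[i_tau_u]);
    for (int g = 0; g < d.nu; ++g) lp += R::dnorm(params[d.p + g], 0.0, tau, 1);
  }
  if (d.nv > 0) {
    double tau = std::exp(params[i_tau_v]);
    lp += scale_logprior(d, false, params[i_tau_v]);
    for (int g = 0; g < d.nv; ++g) lp += R::dnorm(params[d.p + d.nu + g], 0.0, tau, 1);
  }
  lp += scale_logprior(d, d.lik == LIK_GAMMA, params[i_scale]);
  double scale = std::exp(params[i_scale]);
  for (int i = 0; i < d.n; ++i) {
    double e = 0.0;
    for (int j = 0; j < d.p; ++j) e += d.X(i, j) * params[j];
    if (d.nu > 0) e += params[d.p + (d.g1[i] - 1)];
    if (d.nv > 0) e += params[d.p + d.nu + (d.g2[i] - 1)] * d.z[i];
    lp += ld_point(d, i, e, scale);
  }
  return lp;
}

// [[Rcpp::export(name = ".mcmc_hier_cpp")]]
NumericVector mcmc_hier_cpp(List data, NumericVector init, int n_iter, int warmup,
                            int n_chains, double step_init,
                            IntegerVector recenter_type, List recenter_coef) {
  HierData d = build_data(data);
  int npar = init.size();
  int i_tau_u = d.p + d.nu + d.nv;
  int i_tau_v = i_tau_u + (d.nu > 0 ? 1 : 0);
  int i_scale = i_tau_v + (d.nv > 0 ? 1 : 0);
  if (i_scale + 1 != npar) stop("parameter vector length does not match model layout");
  if (recenter_type.size() != d.p) stop("recenter_type length must match fixed effects");

  NumericVector draws(Dimension(n_chains, n_iter, npar));
  RNGScope scope;

  for (int ch = 0; ch < n_chains; ++ch) {
    NumericVector th = clone(init); // u/v slots hold RAW (non-centered) effects
    double tau_u = d.nu > 0 ? std::exp(th[i_tau_u]) : 0.0;
    double tau_v = d.nv > 0 ? std::exp(th[i_tau_v]) : 0.0;
    for (int g = 0; g < d.nu; ++g) th[d.p + g] = init[d.p + g] / tau_u;
    for (int g = 0; g < d.nv; ++g) th[d.p + d.nu + g] = init[d.p + d.nu + g] / tau_v;

    NumericVector eta(d.n);
    for (int i = 0; i < d.n; ++i) {
      double e = 0.0;
      for (int j = 0; j < d.p; ++j) e += d.X(i, j) * th[j];
      if (d.nu > 0) e += tau_u * th[d.p + (d.g1[i] - 1)];
      if (d.nv > 0) e += tau_v * th[d.p + d.nu + (d.g2[i] - 1)] * d.z[i];
      eta[i] = e;
    }
    double scale = std::exp(th[i_scale]);
    double ll = loglik_all(d, eta, scale);
    if (!std::isfinite(ll)) stop("log likelihood not finite at init");
    std::vector<double> ls(npar, std::log(step_init));
    double ls_asis_u = std::log(step_init), ls_asis_v = std::log(step_init);

    for (int it = 0; it < n_iter; ++it) {
      double adapt = (it < warmup) ? std::min(0.25, 1.0 / std::sqrt((double)(it + 1))) : 0.0;

      // fixed effects: full-likelihood recompute with shifted eta
      for (int j = 0; j < d.p; ++j) {
        double delta = std::exp(ls[j]) * R::norm_rand();
        double cand = th[j] + delta;
        double ll_new = 0.0;
        for (int i = 0; i < d.n; ++i)
          ll_new += ld_point(d, i, eta[i] + d.X(i, j) * delta, scale);
        double dlp = ll_new - ll +
                     (cand * cand - th[j] * th[j]) * (-0.5 / (d.beta_sd * d.beta_sd));
        double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (R::unif_rand() < alpha) {
          th[j] = cand;
          for (int i = 0; i < d.n; ++i) eta[i] += d.X(i, j) * delta;
          ll = ll_new;
        }
        if (adapt > 0) ls[j] += adapt * (alpha - 0.44);
      }

      // raw group intercepts (prior N(0,1)): only their rows
      for (int g = 0; g < d.nu; ++g) {
        int j = d.p + g;
        double delta = std::exp(ls[j]) * R::norm_rand();
        double cand = th[j] + delta;
        const std::vector<int> &rows = d.rows_u[g];
        double ll_old = 0.0, ll_new = 0.0;
        for (size_t r = 0; r < rows.size(); ++r) {
          int i = rows[r];
          ll_old += ld_point(d, i, eta[i], scale);
          ll_new += ld_point(d, i, eta[i] + tau_u * delta, scale);
        }
        double dlp = ll_new - ll_old - 0.5 * (cand * cand - th[j] * th[j]);
        double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (R::unif_rand() < alpha) {
          th[j] = cand;
          for (size_t r = 0; r < rows.size(); ++r) eta[rows[r]] += tau_u * delta;
          ll += ll_new - ll_old;
        }
        if (adapt > 0) ls[j] += adapt * (alpha - 0.44);
      }

      // raw group slopes
      for (int g = 0; g < d.nv; ++g) {
        int j = d.p + d.nu + g;
        double delta = std::exp(ls[j]) * R::norm_rand();
        double cand = th[j] + delta;
        const std::vector<int> &rows = d.rows_v[g];
        double ll_old = 0.0, ll_new = 0.0;
        for (size_t r = 0; r < rows.size(); ++r) {
          int i = rows[r];
          ll_old += ld_point(d, i, eta[i], scale);
          ll_new += ld_point(d, i, eta[i] + tau_v * delta * d.z[i], scale);
        }
        double dlp = ll_new - ll_old - 0.5 * (cand * cand - th[j] * th[j]);
        double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (R::unif_rand() < alpha) {
          th[j] = cand;
          for (size_t r = 0; r < rows.size(); ++r)
            eta[rows[r]] += tau_v * delta * d.z[rows[r]];
          ll += ll_new - ll_old;
        }
        if (adapt > 0) ls[j] += adapt * (alpha - 0.44);
      }

      // pooling SDs: in non-centered form they scale the likelihood
      if (d.nu > 0) {
        int j = i_tau_u;
        double cand = th[j] + std::exp(ls[j]) * R::norm_rand();
        double tau_new = std::exp(cand);
        double ll_new = 0.0;
        for (int i = 0; i < d.n; ++i) {
          double e = eta[i] + (tau_new - tau_u) * th[d.p + (d.g1[i] - 1)];
          ll_new += ld_point(d, i, e, scale);
        }
        double dlp = ll_new - ll + scale_logprior(d, false, cand) -
                     scale_logprior(d, false, th[j]);
        double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (R::unif_rand() < alpha) {
          for (int i = 0; i < d.n; ++i)
            eta[i] += (tau_new - tau_u) * th[d.p + (d.g1[i] - 1)];
          th[j] = cand;
          tau_u = tau_new;
          ll = ll_new;
        }
        if (adapt > 0) ls[j] += adapt * (alpha - 0.44);
      }
      if (d.nv > 0) {
        int j = i_tau_v;
        double cand = th[j] + std::exp(ls[j]) * R::norm_rand();
        double tau_new = std::exp(cand);
        double ll_new = 0.0;
        for (int i = 0; i < d.n; ++i) {
          double e = eta[i] + (tau_new - tau_v) * th[d.p + d.nu + (d.g2[i] - 1)] * d.z[i];
          ll_new += ld_point(d, i, e, scale);
        }
        double dlp = ll_new - ll + scale_logprior(d, false, cand) -
                     scale_logprior(d, false, th[j]);
        double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (R::unif_rand() < alpha) {
          for (int i = 0; i < d.n; ++i)
            eta[i] += (tau_new - tau_v) * th[d.p + d.nu + (d.g2[i] - 1)] * d.z[i];
          th[j] = cand;
          tau_v = tau_new;
          ll = ll_new;
        }
        if (adapt > 0) ls[j] += adapt * (alpha - 0.44);
      }

      // interweaved (centered-form) tau updates: hold u = tau * u_raw fixed,
      // move tau against the centered prior, then refresh u_raw = u / tau.
      // Likelihood-invariant; complements the non-centered update above.
      if (d.nu > 0) {
        double cand = th[i_tau_u] + std::exp(ls_asis_u) * R::norm_rand();
        double tau_new = std::exp(cand);
        double dlp = scale_logprior(d, false, cand) - scale_logprior(d, false, th[i_tau_u]);
        for (int g = 0; g < d.nu; ++g) {
          double u_c = tau_u * th[d.p + g];
          dlp += R::dnorm(u_c, 0.0, tau_new, 1) - R::dnorm(u_c, 0.0, tau_u, 1);
        }
        double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (R::unif_rand() < alpha) {
          for (int g = 0; g < d.nu; ++g) th[d.p + g] *= tau_u / tau_new;
          th[i_tau_u] = cand;
          tau_u = tau_new;
        }
        if (adapt > 0) ls_asis_u += adapt * (alpha - 0.44);
      }
      if (d.nv > 0) {
        double cand = th[i_tau_v] + std::exp(ls_asis_v) * R::norm_rand();
        double tau_new = std::exp(cand);
        double dlp = scale_logprior(d, false, cand) - scale_logprior(d, false, th[i_tau_v]);
        for (int g = 0; g < d.nv; ++g) {
          double v_c = tau_v * th[d.p + d.nu + g];
          dlp += R::dnorm(v_c, 0.0, tau_new, 1) - R::dnorm(v_c, 0.0, tau_v, 1);
        }
        double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (R::unif_rand() < alpha) {
          for (int g = 0; g < d.nv; ++g) th[d.p + d.nu + g] *= tau_v / tau_new;
          th[i_tau_v] = cand;
          tau_v = tau_new;
        }
        if (adapt > 0) ls_asis_v += adapt * (alpha - 0.44);
      }

      // exact Gibbs recentering: beta_j += delta, raw effects -= delta c_g / tau
      // keeps eta fixed; delta has a Gaussian full conditional (priors only)
      for (int j = 0; j < d.p; ++j) {
        int rtype = recenter_type[j];
        if (rtype == 0) continue;
        double tau = (rtype == 1) ? tau_u : tau_v;
        if (!(tau > 0)) continue;
        NumericVector cg = recenter_coef[j];
        int off = (rtype == 1) ? d.p : d.p + d.nu;
        double prec = 1.0 / (d.beta_sd * d.beta_sd);
        double mp = -th[j] * prec;
        for (int g = 0; g < cg.size(); ++g) {
          prec += cg[g] * cg[g] / (tau * tau);
          mp += cg[g] * th[off + g] / tau;
        }
        double delta = mp / prec + R::norm_rand() / std::sqrt(prec);
        th[j] += delta;
        for (int g = 0; g < cg.size(); ++g) th[off + g] -= delta * cg[g] / tau;
      }

      // observation scale (sigma or k): full likelihood
      {
        int j = i_scale;
        double cand = th[j] + std::exp(ls[j]) * R::norm_rand();
        double scale_new = std::exp(cand);
        double ll_new = loglik_all(d, eta, scale_new);
        bool is_shape = (d.lik == LIK_GAMMA);
        double dlp = ll_new - ll + scale_logprior(d, is_shape, cand) -
                     scale_logprior(d, is_shape, th[j]);
        double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (R::unif_rand() < alpha) {
          th[j] = cand;
          scale = scale_new;
          ll = ll_new;
        }
        if (adapt > 0) ls[j] += adapt * (alpha - 0.44);
      }

      // store on the centered scale (u = tau * u_raw)
      for (int j = 0; j < npar; ++j) {
        double val = th[j];
        if (j >= d.p && j < d.p + d.nu) val *= tau_u;
        else if (j >= d.p + d.nu && j < d.p + d.nu + d.nv) val *= tau_v;
        draws[ch + n_chains * (it + (R_xlen_t)n_iter * j)] = val;
      }
    }
  }
  draws.attr("dim") = Dimension(n_chains, n_iter, npar);
  return draws;
}
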