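// No-U-Turn Hamiltonian Monte Carlo sampler with dual-averaging step-size
// adaptation and diagonal mass-matrix estimation, plus the log posterior
// densities (and analytic gradients) of the package's Bayesian models:
//   1. phylogenetic generalized linear mixed model (gaussian / bernoulli,
//      optional Gamma(1,2) penalty on sigma_P / sigma_R)
//   2. base Bayesian GLM (same covariates, no phylogeny term)
//   3. hierarchical pathway-carriage random effects model
//   4. regularized-horseshoe sparse regression over gene presence
// All scale parameters are sampled on the log scale (Jacobians included);
// random effect vectors use non-centered parameterizations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::vec;
using arma::mat;

// ---------------------------------------------------------------------------
// prior helpers (unnormalized log densities + gradients wrt the listed arg)
// ---------------------------------------------------------------------------

// half-Student-t(df, 0, scale) on s > 0, parameterized by a = log s
// (Jacobian term included); returns lp, sets dlp/da
static double half_t_log(double s, double df, double scale, double &g_a) {
  double q = s * s / (df * scale * scale);
  double lp = -0.5 * (df + 1.0) * std::log1p(q) + std::log(s);
  g_a = -(df + 1.0) * q / (1.0 + q) + 1.0;
  return lp;
}

// Student-t(df, mu, scale) on unconstrained x; returns lp, sets dlp/dx
static double t_log(double x, double df, double mu, double scale, double &g) {
  double r = x - mu;
  double lp = -0.5 * (df + 1.0) * std::log1p(r * r / (df * scale * scale));
  g = -(df + 1.0) * r / (df * scale * scale + r * r);
  return lp;
}

static inline double inv_logit(double x) {
  return x > 0 ? 1.0 / (1.0 + std::exp(-x)) : std::exp(x) / (1.0 + std::exp(x));
}

// log(1 + exp(x)) without overflow
static inline double log1p_exp(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// ---------------------------------------------------------------------------
// model interface
// ---------------------------------------------------------------------------

struct Model {
  virtual ~Model() {}
  virtual int dim() const = 0;
  virtual double logp_grad(const vec &th, vec &grad) const = 0;
};

// --------------------------- PGLMM -----------------------------------------
// theta = [beta (p), z (n), log sigma_P, (log sigma_R if gaussian)]
struct PglmmModel : Model {
  vec y; mat X; mat L;           // L: lower Cholesky factor of Omega
  int family;                    // 0 gaussian, 1 bernoulli
  bool regularized;
  double beta_sd, sp_df, sp_scale, sr_df, sr_scale;
  int n, p;

  PglmmModel(const List &d) {
    y = as<vec>(d["y"]); X = as<mat>(d["X"]); L = as<mat>(d["L"]);
    family = as<int>(d["family"]);
    regularized = as<bool>(d["regularized"]);
    beta_sd = as<double>(d["beta_sd"]);
    sp_df = as<double>(d["sp_df"]); sp_scale = as<double>(d["sp_scale"]);
    sr_df = as<double>(d["sr_df"]); sr_scale = as<double>(d["sr_scale"]);
    n = (int)y.n_elem; p = (int)X.n_cols;
  }
  int dim() const { return p + n + 1 + (family == 0 ? 1 : 0); }

  double logp_grad(const vec &th, vec &grad) const {
    grad.zeros(dim());
    vec beta = th.subvec(0, p - 1);
    vec z = th.subvec(p, p + n - 1);
    double a = th(p + n);
    double sp = std::exp(a);
    vec Lz = L * z;
    vec u = sp * Lz;
    vec mu = X * beta + u;
    double lp = 0.0;
    vec g_mu(n);

    if (family == 0) {
      double b = th(p + n + 1);
      double sr = std::exp(b);
      vec r = y - mu;
      double rss = arma::dot(r, r);
      lp += -n * b - 0.5 * rss / (sr * sr);
      g_mu = r / (sr * sr);
      double g_b = -n + rss / (sr * sr);
      double gp;
      lp += half_t_log(sr, sr_df, sr_scale, gp); g_b += gp;
      if (regularized) {
        double ratio = sp / sr;
        lp += std::log(2.0) - 2.0 * ratio;      // Gamma(1, 2) on the ratio
        g_b += 2.0 * ratio;
        grad(p + n) += -2.0 * ratio;
      }
      grad(p + n + 1) += g_b;
    } else {
      for (int i = 0; i < n; i++) {
        lp += y(i) * mu(i) - log1p_exp(mu(i));
        g_mu(i) = y(i) - inv_logit(mu(i));
      }
    }
    // beta: N(0, beta_sd)
    lp += -0.5 * arma::dot(beta, beta) / (beta_sd * beta_sd);
    grad.subvec(0, p - 1) = X.t() * g_mu - beta / (beta_sd * beta_sd);
    // z: N(0, 1)
    lp += -0.5 * arma::dot(z, z);
    vec Ltg = L.t() * g_mu;
    grad.subvec(p, p + n - 1) = sp * Ltg - z;
    // sigma_P: half-t prior + likelihood chain through u
    double gp;
    lp += half_t_log(sp, sp_df, sp_scale, gp);
    grad(p + n) += arma::dot(g_mu, u) + gp;
    return lp;
  }
};

// --------------------------- base GLM ---------------------------------------
// theta = [beta (p), (log sigma_R if gaussian)]
struct GlmModel : Model {
  vec y; mat X; int family; double beta_sd, sr_df, sr_scale;
  int n, p;
  GlmModel(const List &d) {
    y = as<vec>(d["y"]); X = as<mat>(d["X"]);
    family = as<int>(d["family"]);
    beta_sd = as<double>(d["beta_sd"]);
    sr_df = as<double>(d["sr_df"]); sr_scale = as<double>(d["sr_scale"]);
    n = (int)y.n_elem; p = (int)X.n_cols;
  }
  int dim() const { return p + (family == 0 ? 1 : 0); }
  double logp_grad(const vec &th, vec &grad) const {
    grad.zeros(dim());
    vec beta = th.subvec(0, p - 1);
    vec mu = X * beta;
    double lp = 0.0;
    vec g_mu(n);
    if (family == 0) {
      double b = th(p); double sr = std::exp(b);
      vec r = y - mu; double rss = arma::dot(r, r);
      lp += -n * b - 0.5 * rss / (sr * sr);
      g_mu = r / (sr * sr);
      double gp; lp += half_t_log(sr, sr_df, sr_scale, gp);
      grad(p) = -n + rss / (sr * sr) + gp;
    } else {
      for (int i = 0; i < n; i++) {
        lp += y(i) * mu(i) - log1p_exp(mu(i));
        g_mu(i) = y(i) - inv_logit(mu(i));
      }
    }
    lp += -0.5 * arma::dot(beta, beta) / (beta_sd * beta_sd);
    grad.subvec(0, p - 1) = X.t() * g_mu - beta / (beta_sd * beta_sd);
    return lp;
  }
};

// --------------------------- pathway model ----------------------------------
// theta = [alpha0, slope, eta (P), zeff (P), log s_int, log s_eff, log s_res]
// Parameterization: the likelihood uses pathway-level totals
// eta_p = alpha0 + intercept_p with hierarchical prior eta_p ~ N(alpha0,
// s_int) — the centered form, appropriate because hundreds of observations
// identify each total directly, and it removes the alpha0/intercept ridge a
// naive split would create. Group effects are non-centered
// (eff = s_eff * zeff): under the aggressive Exponential(3) shrinkage most
// effects sit near zero, where the centered form funnels.
struct PathwayModel : Model {
  vec y, x, g; arma::ivec pidx; int P, N; double EM;
  PathwayModel(const List &d) {
    y = as<vec>(d["y"]); x = as<vec>(d["x"]); g = as<vec>(d["g"]);
    pidx = as<arma::ivec>(d["pidx"]);       // 0-based pathway index
    P = as<int>(d["P"]); EM = as<double>(d["EM"]);
    N = (int)y.n_elem;
  }
  int dim() const { return 2 + 2 * P + 3; }
  double logp_grad(const vec &th, vec &grad) const {
    grad.zeros(dim());
    double a0 = th(0), slope = th(1);
    vec eta = th.subvec(2, 1 + P), zeff = th.subvec(2 + P, 1 + 2 * P);
    double li = th(2 + 2 * P), le = th(3 + 2 * P), lr = th(4 + 2 * P);
    double s_int = std::exp(li), s_eff = std::exp(le), s_res = std::exp(lr);
    vec effp = s_eff * zeff;
    double lp = 0.0;
    vec g_eta(P, arma::fill::zeros), g_eff(P, arma::fill::zeros);
    double g_slope = 0, rss = 0;
    for (int i = 0; i < N; i++) {
      int p = pidx(i);
      double mu = eta(p) + slope * x(i) + g(i) * effp(p);
      double r = y(i) - mu;
      rss += r * r;
      double gm = r / (s_res * s_res);
      g_slope += gm * x(i);
      g_eta(p) += gm; g_eff(p) += gm * g(i);
    }
    lp += -N * lr - 0.5 * rss / (s_res * s_res);
    // priors
    double gp, g_a0 = 0;
    lp += t_log(a0, 5.0, EM, 2.5, gp); g_a0 += gp;
    lp += -0.5 * (slope - 1.0) * (slope - 1.0); g_slope += -(slope - 1.0);
    grad(1) = g_slope;
    // eta_p ~ N(alpha0, s_int); zeff ~ N(0, 1)
    vec dev = eta - a0;
    double ssi = arma::dot(dev, dev);
    lp += -P * li - 0.5 * ssi / (s_int * s_int);
    lp += -0.5 * arma::dot(zeff, zeff);
    grad.subvec(2, 1 + P) = g_eta - dev / (s_int * s_int);
    grad.subvec(2 + P, 1 + 2 * P) = s_eff * g_eff - zeff;
    grad(0) = g_a0 + arma::accu(dev) / (s_int * s_int);
    lp += half_t_log(s_int, 5.0, 2.5, gp);
    grad(2 + 2 * P) = -P + ssi / (s_int * s_int) + gp;
    // sigma_effects ~ Exponential(3), Jacobian included
    lp += -3.0 * s_eff + le;
    grad(3 + 2 * P) = s_eff * arma::dot(zeff, g_eff) - 3.0 * s_eff + 1.0;
    lp += half_t_log(s_res, 3.0, 2.5, gp);
    grad(4 + 2 * P) = -N + rss / (s_res * s_res) + gp;
    return lp;
  }
};

// --------------------------- regularized horseshoe --------------------------
// theta = [beta (pc), zg (G), log lambda (G), log tau, log c2,
//          (log sigma if gaussian)]
struct HorseshoeModel : Model {
  vec y; mat X, Z; int family; double beta_sd, tau0, slab_scale, slab_df;
  int n, pc, G;
  HorseshoeModel(const List &d) {
    y = as<vec>(d["y"]); X = as<mat>(d["X"]); Z = as<mat>(d["Z"]);
    family = as<int>(d["family"]);
    beta_sd = as<double>(d["beta_sd"]); tau0 = as<double>(d["tau0"]);
    slab_scale = as<double>(d["slab_scale"]); slab_df = as<double>(d["slab_df"]);
    n = (int)y.n_elem; pc = (int)X.n_cols; G = (int)Z.n_cols;
  }
  int dim() const { return pc + 2 * G + 2 + (family == 0 ? 1 : 0); }
  double logp_grad(const vec &th, vec &grad) const {
    grad.zeros(dim());
    vec beta = th.subvec(0, pc - 1);
    vec zg = th.subvec(pc, pc + G - 1);
    vec ll = th.subvec(pc + G, pc + 2 * G - 1);
    double lt = th(pc + 2 * G), w = th(pc + 2 * G + 1);
    double tau = std::exp(lt), c2 = std::exp(w);
    vec lam2 = arma::exp(2.0 * ll);
    vec t2 = tau * tau * lam2;                // tau^2 lambda_g^2
    vec A = c2 + t2;
    vec m2 = c2 * t2 / A;                      // (tau * lambda_tilde)^2
    vec m = arma::sqrt(m2);
    vec gamma = m % zg;
    vec mu = X * beta + Z * gamma;
    double lp = 0.0;
    vec g_mu(n);
    if (family == 0) {
      double b = th(dim() - 1); double sr = std::exp(b);
      vec r = y - mu; double rss = arma::dot(r, r);
      lp += -n * b - 0.5 * rss / (sr * sr);
      g_mu = r / (sr * sr);
      double gp; lp += half_t_log(sr, 3.0, 2.5, gp);
      grad(dim() - 1) = -n + rss / (sr * sr) + gp;
    } else {
      for (int i = 0; i < n; i++) {
        lp += y(i) * mu(i) - log1p_exp(mu(i));
        g_mu(i) = y(i) - inv_logit(mu(i));
      }
    }
    lp += -0.5 * arma::dot(beta, beta) / (beta_sd * beta_sd);
    grad.subvec(0, pc - 1) = X.t() * g_mu - beta / (beta_sd * beta_sd);
    vec gZ = Z.t() * g_mu;                     // dlik/dgamma
    lp += -0.5 * arma::dot(zg, zg);
    grad.subvec(pc, pc + G - 1) = m % gZ - zg;
    // dm/d(log lambda_g) = dm/d(log tau) per-coordinate = c2^2 t2 / (m A^2)
    vec dm_dl = (c2 * c2) * t2 / (m % arma::square(A));
    vec chain = zg % gZ;                       // dlik/dm per gene
    // lambda_g ~ half-Cauchy(0,1)
    for (int g_i = 0; g_i < G; g_i++) {
      lp += -std::log1p(lam2(g_i)) + ll(g_i);
      grad(pc + G + g_i) = chain(g_i) * dm_dl(g_i)
        - 2.0 * lam2(g_i) / (1.0 + lam2(g_i)) + 1.0;
    }
    // tau ~ half-Cauchy(0, tau0)
    double q = tau * tau / (tau0 * tau0);
    lp += -std::log1p(q) + lt;
    grad(pc + 2 * G) = arma::dot(chain, dm_dl) - 2.0 * q / (1.0 + q) + 1.0;
    // c2 ~ InvGamma(slab_df/2, slab_df * slab_scale^2 / 2), on w = log c2
    double al = slab_df / 2.0, be = slab_df * slab_scale * slab_scale / 2.0;
    lp += -al * w - be / c2;
    // dm2/dw = c2 * t2^2 / A^2 ; dm/dw = dm2/dw / (2 m)
    vec dm_dw = (c2 * arma::square(t2) / arma::square(A)) / (2.0 * m);
    grad(pc + 2 * G + 1) = arma::dot(chain, dm_dw) - al + be / c2;
    return lp;
  }
};

static Model *make_model(const std::string &id, const List &data) {
  if (id == "pglmm") return new PglmmModel(data);
  if (id == "glm") return new GlmModel(data);
  if (id == "pathway") return new PathwayModel(data);
  if (id == "horseshoe") return new HorseshoeModel(data);
  stop("unknown model id");
  return nullptr;
}

// ---------------------------------------------------------------------------
// NUTS (Hoffman & Gelman 2014, Algorithm 6) with diagonal mass matrix
// ---------------------------------------------------------------------------

struct Hamiltonian {
  const Model &m;
  const vec &inv_mass;      // estimated posterior variances (M^-1 diagonal)
  Hamiltonian(const Model &m_, const vec &im) : m(m_), inv_mass(im) {}
  double joint(const vec &th, const vec &p, vec &grad) const {
    double lp = m.logp_grad(th, grad);
    return lp - 0.5 * arma::dot(arma::square(p), inv_mass);
  }
  void leapfrog(vec &th, vec &p, vec &grad, double eps) const {
    p += 0.5 * eps * grad;
    th += eps * (inv_mass % p);
    m.logp_grad(th, grad);
    p += 0.5 * eps * grad;
  }
};

struct TreeState {
  vec th_minus, p_minus, g_minus, th_plus, p_plus, g_plus, th_prop;
  double n_prop; bool s; double alpha; int n_alpha; bool divergent;
};

static const double DELTA_MAX = 1000.0;

static void build_tree(const Hamiltonian &H, const vec &th, const vec &p,
                       const vec &g, double log_u, int dir, int depth,
                       double eps, double joint0, TreeState &out) {
  if (depth == 0) {
    vec th1 = th, p1 = p, g1 = g;
    H.leapfrog(th1, p1, g1, dir * eps);
    vec gd;
    double lp = H.m.logp_grad(th1, gd);
    double joint = lp - 0.5 * arma::dot(arma::square(p1), H.inv_mass);
    if (!std::isfinite(joint)) joint = -INFINITY;
    out.th_minus = th1; out.p_minus = p1; out.g_minus = g1;
    out.th_plus = th1; out.p_plus = p1; out.g_plus = g1;
    out.th_prop = th1;
    out.n_prop = (log_u <= joint) ? 1.0 : 0.0;
    out.divergent = (log_u - DELTA_MAX) > joint;
    out.s = !out.divergent;
    double a = std::exp(std::min(0.0, joint - joint0));
    out.alpha = std::isfinite(a) ? a : 0.0;
    out.n_alpha = 1;
    return;
  }
  TreeState first;
  build_tree(H, th, p, g, log_u, dir, depth - 1, eps, joint0, first);
  out = first;
  if (first.s) {
    TreeState second;
    if (dir == -1) {
      build_tree(H, first.th_minus, first.p_minus, first.g_minus, log_u, dir,
                 depth - 1, eps, joint0, second);
      out.th_minus = second.th_minus; out.p_minus = second.p_minus;
      out.g_minus = second.g_minus;
    } else {
      build_tree(H, first.th_plus, first.p_plus, first.g_plus, log_u, dir,
                 depth - 1, eps, joint0, second);
      out.th_plus = second.th_plus; out.p_plus = second.p_plus;
      out.g_plus = second.g_plus;
    }
    double ntot = first.n_prop + second.n_prop;
    if (ntot > 0 && R::unif_rand() < second.n_prop / ntot)
      out.th_prop = second.th_prop;
    vec dth = out.th_plus - out.th_minus;
    bool uturn = (arma::dot(dth, H.inv_mass % out.p_minus) >= 0) &&
                 (arma::dot(dth, H.inv_mass % out.p_plus) >= 0);
    out.s = second.s && uturn;
    out.n_prop = ntot;
    out.alpha = first.alpha + second.alpha;
    out.n_alpha = first.n_alpha + second.n_alpha;
    out.divergent = first.divergent || second.divergent;
  }
}

// heuristic initial step size: scale until acceptance crosses 0.5
static double init_stepsize(const Hamiltonian &H, const vec &th) {
  int d = (int)th.n_elem;
  vec p(d), g(d);
  for (int j = 0; j < d; j++) p(j) = R::norm_rand() / std::sqrt(H.inv_mass(j));
  double j0 = H.joint(th, p, g);
  double eps = 1.0;
  vec th1 = th, p1 = p, g1 = g;
  H.leapfrog(th1, p1, g1, eps);
  vec gd;
  double j1 = H.m.logp_grad(th1, gd) -
              0.5 * arma::dot(arma::square(p1), H.inv_mass);
  if (!std::isfinite(j1)) j1 = -INFINITY;
  double dir = (j1 - j0 > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; it++) {
    th1 = th; p1 = p; g1 = g;
    H.leapfrog(th1, p1, g1, eps);
    j1 = H.m.logp_grad(th1, gd) -
         0.5 * arma::dot(arma::square(p1), H.inv_mass);
    if (!std::isfinite(j1)) j1 = -INFINITY;
    double da = j1 - j0;
    if (dir > 0 && da <= std::log(0.5)) break;
    if (dir < 0 && da >= std::log(0.5)) break;
    eps *= (dir > 0) ? 2.0 : 0.5;
    if (eps > 1e7 || eps < 1e-10) break;
  }
  return eps;
}

// [[Rcpp::export(name = ".nuts_chain")]]
List nuts_chain(std::string model_id, List data, NumericVector init,
                int n_warmup, int n_iter, int max_treedepth = 10,
                double adapt_delta = 0.8) {
  std::unique_ptr<Model> mod(make_model(model_id, data));
  int d = mod->dim();
  if ((int)init.size() != d) stop("init has wrong length");
  vec th = as<vec>(init);
  vec inv_mass(d, arma::fill::ones);
  RNGScope rng;

  Hamiltonian H(*mod, inv_mass);
  double eps = init_stepsize(H, th);
  // dual averaging state
  double mu_da = std::log(10.0 * eps), log_eps_bar = 0.0, h_bar = 0.0;
  const double gamma_da = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;
  // mass adaptation: doubling windows between fixed head/tail buffers
  int init_buf = 75, term_buf = 50, base_win = 25;
  if (n_warmup < 150) { init_buf = n_warmup / 5; term_buf = n_warmup / 5;
                        base_win = n_warmup - init_buf - term_buf; }
  int win_start = init_buf, win_size = base_win;
  int win_end = win_start + win_size;
  vec wm(d, arma::fill::zeros), ws(d, arma::fill::zeros);
  double wn = 0;

  mat draws(n_iter, d);
  vec lp_out(n_iter);
  int divergences = 0;
  double accept_sum = 0.0;
  int treedepth_hits = 0;

  vec grad(d);
  double lp = mod->logp_grad(th, grad);
  if (!std::isfinite(lp)) stop("initial log density is not finite");

  for (int it = 0; it < n_warmup + n_iter; it++) {
    bool warm = it < n_warmup;
    vec p(d);
    for (int j = 0; j < d; j++)
      p(j) = R::norm_rand() / std::sqrt(inv_mass(j));
    double joint0 = lp - 0.5 * arma::dot(arma::square(p), inv_mass);
    double log_u = joint0 - R::exp_rand();
    TreeState t;
    t.th_minus = th; t.p_minus = p; t.g_minus = grad;
    t.th_plus = th; t.p_plus = p; t.g_plus = grad;
    t.th_prop = th; t.n_prop = 1.0; t.s = true; t.divergent = false;
    double alpha = 0; int n_alpha = 1;
    int depth = 0;
    bool any_div = false;
    while (t.s && depth < max_treedepth) {
      int dir = (R::unif_rand() < 0.5) ? -1 : 1;
      TreeState sub;
      if (dir == -1)
        build_tree(H, t.th_minus, t.p_minus, t.g_minus, log_u, dir, depth,
                   eps, joint0, sub);
      else
        build_tree(H, t.th_plus, t.p_plus, t.g_plus, log_u, dir, depth,
                   eps, joint0, sub);
      if (dir == -1) {
        t.th_minus = sub.th_minus; t.p_minus = sub.p_minus;
        t.g_minus = sub.g_minus;
      } else {
        t.th_plus = sub.th_plus; t.p_plus = sub.p_plus; t.g_plus = sub.g_plus;
      }
      any_div = any_div || sub.divergent;
      if (sub.s && t.n_prop + sub.n_prop > 0 &&
          R::unif_rand() < sub.n_prop / (t.n_prop + sub.n_prop) &&
          sub.n_prop > 0)
        t.th_prop = sub.th_prop;
      t.n_prop += sub.n_prop;
      vec dth = t.th_plus - t.th_minus;
      bool uturn = (arma::dot(dth, inv_mass % t.p_minus) >= 0) &&
                   (arma::dot(dth, inv_mass % t.p_plus) >= 0);
      t.s = sub.s && uturn;
      alpha = sub.alpha; n_alpha = sub.n_alpha;
      depth++;
    }
    if (depth >= max_treedepth) treedepth_hits++;
    th = t.th_prop;
    lp = mod->logp_grad(th, grad);
    double a_stat = n_alpha > 0 ? alpha / n_alpha : 0.0;

    if (warm) {
      // dual averaging
      da_count++;
      double frac = 1.0 / (da_count + t0);
      h_bar = (1.0 - frac) * h_bar + frac * (adapt_delta - a_stat);
      double log_eps = mu_da - std::sqrt((double)da_count) / gamma_da * h_bar;
      double w = std::pow((double)da_count, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      // mass window accumulation
      if (it >= win_start && it < win_end && it < n_warmup - term_buf) {
        wn += 1.0;
        vec delta = th - wm;
        wm += delta / wn;
        ws += delta % (th - wm);
      }
      if (it + 1 == win_end && wn > 1) {
        vec v = ws / (wn - 1.0);
        inv_mass = (wn / (wn + 5.0)) * v + (5.0 / (wn + 5.0)) * 1e-3;
        inv_mass.elem(arma::find(inv_mass <= 0)).fill(1e-3);
        wm.zeros(); ws.zeros(); wn = 0;
        win_size *= 2;
        win_start = win_end;
        win_end = std::min(win_start + win_size, n_warmup - term_buf);
        if (n_warmup - term_buf - win_end < win_size * 2)
          win_end = n_warmup - term_buf;
        // restart step-size adaptation for the new metric
        eps = init_stepsize(H, th);
        mu_da = std::log(10.0 * eps);
        log_eps_bar = 0.0; h_bar = 0.0; da_count = 0;
      }
      if (it + 1 == n_warmup) eps = std::exp(log_eps_bar);
    } else {
      if (any_div) divergences++;
      accept_sum += a_stat;
      draws.row(it - n_warmup) = th.t();
      lp_out(it - n_warmup) = lp;
    }
  }

  return List::create(_["draws"] = draws, _["lp"] = lp_out,
                      _["divergences"] = divergences,
                      _["stepsize"] = eps,
                      _["accept_stat"] = accept_sum / std::max(n_iter, 1),
                      _["treedepth_hits"] = treedepth_hits,
                      _["inv_mass"] = inv_mass);
}

// [[Rcpp::export(name = ".model_logp_grad")]]
List model_logp_grad(std::string model_id, List data, NumericVector theta) {
  std::unique_ptr<Model> mod(make_model(model_id, data));
  vec th = as<vec>(theta), grad((arma::uword)mod->dim());
  double lp = mod->logp_grad(th, grad);
  return List::create(_["lp"] = lp, _["grad"] = grad);
}
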