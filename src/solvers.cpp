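// Closed-form propagation of linear compartment models across an event plan.
//
// The analytic path uses the spectral (Lagrange matrix-polynomial) form of the
// solution: for a diagonalizable rate matrix A with eigenvalues mu_i,
//   exp(A t)      = sum_i exp(mu_i t) P_i,
//   int_0^t exp(A s) ds = sum_i phi(mu_i, t) P_i,   phi(m,t) = expm1(m t)/m,
// with P_i = prod_{j != i} (A - mu_j I) / (mu_i - mu_j).  For the one- and
// two-compartment models with first-order absorption the eigenvalues are known
// in closed form (-ka and the hybrid disposition rates), so this reproduces the
// classic bi-/tri-exponential solution for arbitrary initial state and constant
// zero-order input.  Near-degenerate eigenvalues (e.g. ka ~ lambda1) fall back
// to a Pade/scaling-and-squaring matrix exponential on an augmented matrix,
// which needs no invertibility of A.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double DEGEN_RTOL = 1e-8;

// model codes: 1 = one-compartment (gut, central), theta = (CL, V, ka)
//              2 = two-compartment (gut, central, peripheral),
//                  theta = (CL, Q, Vcent, Vperi, ka)
static void model_matrix(const rowvec& theta, int model, mat& A, vec& mu) {
  if (model == 1) {
    double CL = theta(0), V = theta(1), ka = theta(2);
    double k10 = CL / V;
    A.set_size(2, 2);
    A(0, 0) = -ka;  A(0, 1) = 0.0;
    A(1, 0) = ka;   A(1, 1) = -k10;
    mu = { -ka, -k10 };
  } else if (model == 2) {
    double CL = theta(0), Q = theta(1), Vc = theta(2), Vp = theta(3),
           ka = theta(4);
    double k10 = CL / Vc, k12 = Q / Vc, k21 = Q / Vp;
    A.set_size(3, 3);
    A.zeros();
    A(0, 0) = -ka;
    A(1, 0) = ka; A(1, 1) = -(k10 + k12); A(1, 2) = k21;
    A(2, 1) = k12; A(2, 2) = -k21;
    double s = k10 + k12 + k21, p = k10 * k21;
    double disc = std::sqrt(std::max(s * s - 4.0 * p, 0.0));
    double l1 = 0.5 * (s + disc), l2 = 0.5 * (s - disc);
    mu = { -ka, -l1, -l2 };
  } else {
    Rcpp::stop("unknown model code");
  }
}

static inline double phi_fun(double m, double t) {
  if (m == 0.0 || std::abs(m * t) < 1e-300) return t;
  return std::expm1(m * t) / m;
}

// exp(A dt) u + particular solution for constant input b, via augmented matrix
static vec expm_advance(const mat& A, const vec& u, double dt, const vec& b) {
  uword n = A.n_rows;
  mat M(n + 1, n + 1, fill::zeros);
  M.submat(0, 0, n - 1, n - 1) = A * dt;
  M.submat(0, n, n - 1, n) = b * dt;
  mat E = expmat(M);
  return E.submat(0, 0, n - 1, n - 1) * u + E.submat(0, n, n - 1, n);
}

static bool degenerate_spectrum(const vec& mu) {
  double scale = std::max(mu.max(), -mu.min());
  if (scale <= 0.0) return false;  // A == 0, spectral form still exact
  for (uword i = 0; i < mu.n_elem; ++i)
    for (uword j = i + 1; j < mu.n_elem; ++j)
      if (std::abs(mu(i) - mu(j)) < DEGEN_RTOL * scale) return true;
  return false;
}

// transition matrix E = exp(A dt) and input integral Phi = int_0^dt exp(A s) ds
static void spectral_ops(const mat& A, const vec& mu, double dt,
                         mat& E, mat& Phi) {
  uword n = A.n_rows;
  E.zeros(n, n);
  Phi.zeros(n, n);
  mat I = eye(n, n);
  for (uword i = 0; i < n; ++i) {
    mat P = I;
    for (uword j = 0; j < n; ++j) {
      if (j == i) continue;
      P = P * (A - mu(j) * I) / (mu(i) - mu(j));
    }
    E += std::exp(mu(i) * dt) * P;
    Phi += phi_fun(mu(i), dt) * P;
  }
}

static vec advance_state(const mat& A, const vec& mu, const vec& u, double dt,
                         const vec& b) {
  if (dt == 0.0) return u;
  if (degenerate_spectrum(mu)) return expm_advance(A, u, dt, b);
  mat E, Phi;
  spectral_ops(A, mu, dt, E, Phi);
  return E * u + Phi * b;
}

static void em_phi(const mat& A, const vec& mu, double dt, mat& E, mat& Phi) {
  uword n = A.n_rows;
  if (!degenerate_spectrum(mu)) {
    spectral_ops(A, mu, dt, E, Phi);
    return;
  }
  E = expmat(A * dt);
  // Phi column-by-column via the augmented exponential
  Phi.set_size(n, n);
  for (uword k = 0; k < n; ++k) {
    vec ek(n, fill::zeros); ek(k) = 1.0;
    Phi.col(k) = expm_advance(A, vec(n, fill::zeros), dt, ek);
  }
}

static void check_dissipative(const vec& mu) {
  double scale = std::max(1.0, std::max(mu.max(), -mu.min()));
  if (mu.max() > -1e-12 * scale)
    Rcpp::stop("no steady state: system is not strictly dissipative");
}

// post-dose periodic steady state for a bolus of famt into compartment cmt
static vec steady_bolus(const mat& A, const vec& mu, double famt, double ii,
                        int cmt) {
  check_dissipative(mu);
  uword n = A.n_rows;
  mat E, Phi;
  em_phi(A, mu, ii, E, Phi);
  vec d(n, fill::zeros); d(cmt - 1) = famt;
  vec u;
  if (!solve(u, eye(n, n) - E, d))
    Rcpp::stop("no steady state: singular interdose map");
  return u;
}

// pre-infusion periodic steady state; infusion of duration tinf at rate into cmt
static vec steady_infusion(const mat& A, const vec& mu, double famt,
                           double rate, double ii, int cmt) {
  check_dissipative(mu);
  uword n = A.n_rows;
  double tinf = famt / rate;
  if (tinf > ii * (1.0 + 1e-12))
    Rcpp::stop("steady-state infusion longer than the interdose interval is not supported");
  vec b(n, fill::zeros); b(cmt - 1) = rate;
  mat E1, P1, E2, P2, Eii, Pii;
  em_phi(A, mu, tinf, E1, P1);
  em_phi(A, mu, ii - tinf, E2, P2);
  em_phi(A, mu, ii, Eii, Pii);
  vec rhs = E2 * (P1 * b);
  vec u;
  if (!solve(u, eye(n, n) - Eii, rhs))
    Rcpp::stop("no steady state: singular interdose map");
  return u;
}

// [[Rcpp::export]]
arma::vec cpp_advance_model(const arma::vec& u, const arma::rowvec& theta,
                            int model, double dt, const arma::vec& b) {
  mat A; vec mu;
  model_matrix(theta, model, A, mu);
  if (u.n_elem != A.n_rows || b.n_elem != A.n_rows)
    Rcpp::stop("state/input dimension does not match the model");
  return advance_state(A, mu, u, dt, b);
}

// [[Rcpp::export]]
arma::vec cpp_expm_advance(const arma::mat& A, const arma::vec& u, double dt,
                           const arma::vec& b) {
  if (A.n_rows != A.n_cols) Rcpp::stop("A must be square");
  if (u.n_elem != A.n_rows || b.n_elem != A.n_rows)
    Rcpp::stop("dimension mismatch between A, u and b");
  if (dt == 0.0) return u;
  return expm_advance(A, u, dt, b);
}

// [[Rcpp::export]]
arma::vec cpp_steady_state_model(const arma::rowvec& theta, int model,
                                 double famt, double rate, double ii,
                                 int cmt) {
  mat A; vec mu;
  model_matrix(theta, model, A, mu);
  if (cmt < 1 || (uword)cmt > A.n_rows) Rcpp::stop("cmt out of range");
  if (rate > 0.0) return steady_infusion(A, mu, famt, rate, ii, cmt);
  return steady_bolus(A, mu, famt, ii, cmt);
}

// [[Rcpp::export]]
arma::vec cpp_steady_state_matrix(const arma::mat& A, double famt, double rate,
                                  double ii, int cmt) {
  if (A.n_rows != A.n_cols) Rcpp::stop("A must be square");
  if (cmt < 1 || (uword)cmt > A.n_rows) Rcpp::stop("cmt out of range");
  cx_vec ev = eig_gen(A);
  vec re = real(ev);
  check_dissipative(re);
  // a general A need not have a real spectrum; use the exponential directly
  uword n = A.n_rows;
  mat E = expmat(A * ii);
  vec u;
  if (rate > 0.0) {
    double tinf = famt / rate;
    if (tinf > ii * (1.0 + 1e-12))
      Rcpp::stop("steady-state infusion longer than the interdose interval is not supported");
    vec b(n, fill::zeros); b(cmt - 1) = rate;
    vec inner = expm_advance(A, vec(n, fill::zeros), tinf, b);
    vec rhs = expmat(A * (ii - tinf)) * inner;
    if (!solve(u, eye(n, n) - E, rhs))
      Rcpp::stop("no steady state: singular interdose map");
  } else {
    vec d(n, fill::zeros); d(cmt - 1) = famt;
    if (!solve(u, eye(n, n) - E, d))
      Rcpp::stop("no steady state: singular interdose map");
  }
  return u;
}

// Per-parameter-set cache of the spectral decomposition: the projector
// matrices P_i depend only on theta, so a schedule solve reuses them across
// all interval advances.
struct ModelCache {
  mat A;
  vec mu;
  std::vector<mat> P;
  bool spectral;  // false => per-step expm fallback (degenerate spectrum)
};

static void build_cache(const rowvec& theta, int model, ModelCache& c) {
  model_matrix(theta, model, c.A, c.mu);
  c.spectral = !degenerate_spectrum(c.mu);
  c.P.clear();
  if (!c.spectral) return;
  uword n = c.A.n_rows;
  mat I = eye(n, n);
  for (uword i = 0; i < n; ++i) {
    mat P = I;
    for (uword j = 0; j < n; ++j) {
      if (j == i) continue;
      P = P * (c.A - c.mu(j) * I) / (c.mu(i) - c.mu(j));
    }
    c.P.push_back(P);
  }
}

static vec cache_advance(const ModelCache& c, const vec& u, double dt,
                         const vec& b, bool has_inf) {
  if (dt == 0.0) return u;
  if (!c.spectral) return expm_advance(c.A, u, dt, b);
  vec out(u.n_elem, fill::zeros);
  for (uword i = 0; i < c.mu.n_elem; ++i) {
    out += std::exp(c.mu(i) * dt) * (c.P[i] * u);
    if (has_inf) out += phi_fun(c.mu(i), dt) * (c.P[i] * b);
  }
  return out;
}

static mat solve_plan_impl(const mat& plan, const mat& theta, int model,
                           int n_record) {
  int nCmt = (model == 1) ? 2 : 3;
  mat out(nCmt, n_record, fill::zeros);
  vec u(nCmt, fill::zeros), binf(nCmt, fill::zeros);
  bool has_inf = false;
  double t = plan.n_rows > 0 ? plan(0, 0) : 0.0;
  ModelCache cache;
  int cur_theta = -1;
  for (uword i = 0; i < plan.n_rows; ++i) {
    int th = (int)plan(i, 7) - 1;
    if (theta.n_rows == 1) th = 0;
    if (th != cur_theta) {
      build_cache(theta.row(th), model, cache);
      cur_theta = th;
    }
    double ti = plan(i, 0);
    double dt = ti - t;
    if (dt < -1e-9) Rcpp::stop("solve plan times are not non-decreasing");
    if (dt > 0.0) {
      u = cache_advance(cache, u, dt, binf, has_inf);
      t = ti;
    }
    int op = (int)plan(i, 1);
    int cmt = (int)plan(i, 2);
    switch (op) {
      case 0: break;
      case 1: u(cmt - 1) += plan(i, 3); break;
      case 2: binf(cmt - 1) += plan(i, 4); has_inf = true; break;
      case 3: binf(cmt - 1) -= plan(i, 4);
              has_inf = any(binf != 0.0); break;
      case 4: u = steady_bolus(cache.A, cache.mu, plan(i, 3), plan(i, 5),
                               cmt); break;
      case 5: u = steady_infusion(cache.A, cache.mu, plan(i, 3), plan(i, 4),
                                  plan(i, 5), cmt); break;
      default: Rcpp::stop("unknown plan op");
    }
    int rec = (int)plan(i, 6);
    if (rec > 0) out.col(rec - 1) = u;
    if (!u.is_finite()) Rcpp::stop("non-finite state at plan row %d", (int)i + 1);
  }
  return out;
}

// Unnormalized log joint for the single-subject PK models on the
// unconstrained (log) scale: theta = exp(x), lognormal measurement error,
// per-parameter prior families coded 0 = lognormal(mu, sd),
// 1 = half-normal(scale), 2 = normal(mu, sd).  Must agree with the generic
// R-side assembly (log_joint) to double precision; tested there.
static double pk_lp_impl(const vec& x, const mat& plan, const uvec& obs,
                         const vec& log_y, const ivec& prior_family,
                         const mat& prior_pars, int model, int n_record) {
  static const double HALF_LOG_2PI = 0.9189385332046727;
  uword d = x.n_elem;
  vec th = exp(x);
  if (!th.is_finite()) return -datum::inf;
  uword npk = d - 1;
  double lp = 0.0;
  for (uword i = 0; i < d; ++i) {
    double mu = prior_pars(i, 0), sd = prior_pars(i, 1);
    switch (prior_family(i)) {
      case 0:  // lognormal prior + Jacobian x: the -log(theta) term cancels
        lp += -std::log(sd) - HALF_LOG_2PI -
          0.5 * std::pow((x(i) - mu) / sd, 2);
        break;
      case 1:  // half-normal(scale = mu slot)
        lp += x(i) + std::log(2.0) - std::log(mu) - HALF_LOG_2PI -
          0.5 * th(i) * th(i) / (mu * mu);
        break;
      case 2:  // normal
        lp += x(i) - std::log(sd) - HALF_LOG_2PI -
          0.5 * std::pow((th(i) - mu) / sd, 2);
        break;
      default: Rcpp::stop("unknown prior family code");
    }
  }
  mat sol;
  try {
    sol = solve_plan_impl(plan, th.subvec(0, npk - 1).t(), model, n_record);
  } catch (...) {
    return -datum::inf;
  }
  double Vc = (model == 1) ? th(1) : th(2);
  double sigma = th(npk);
  double inv2s2 = 0.5 / (sigma * sigma);
  double lsig = std::log(sigma);
  for (uword k = 0; k < obs.n_elem; ++k) {
    double chat = sol(1, obs(k) - 1) / Vc;
    if (!(chat > 0.0) || !std::isfinite(chat)) return -datum::inf;
    double r = log_y(k) - std::log(chat);
    lp += -log_y(k) - lsig - HALF_LOG_2PI - r * r * inv2s2;
  }
  return lp;
}

// [[Rcpp::export]]
double cpp_pk_lp(const arma::vec& x, const arma::mat& plan,
                 const arma::uvec& obs, const arma::vec& log_y,
                 const arma::ivec& prior_family, const arma::mat& prior_pars,
                 int model, int n_record) {
  return pk_lp_impl(x, plan, obs, log_y, prior_family, prior_pars, model,
                    n_record);
}

// central finite differences of cpp_pk_lp, h_i = eps^(1/3) max(1, |x_i|)
// [[Rcpp::export]]
arma::vec cpp_pk_lp_grad(const arma::vec& x, const arma::mat& plan,
                         const arma::uvec& obs, const arma::vec& log_y,
                         const arma::ivec& prior_family,
                         const arma::mat& prior_pars, int model,
                         int n_record) {
  double h0 = std::cbrt(std::numeric_limits<double>::epsilon());
  vec g(x.n_elem);
  vec xp = x;
  for (uword i = 0; i < x.n_elem; ++i) {
    double h = h0 * std::max(1.0, std::abs(x(i)));
    xp(i) = x(i) + h;
    double fp = pk_lp_impl(xp, plan, obs, log_y, prior_family, prior_pars,
                           model, n_record);
    xp(i) = x(i) - h;
    double fm = pk_lp_impl(xp, plan, obs, log_y, prior_family, prior_pars,
                           model, n_record);
    xp(i) = x(i);
    if (!std::isfinite(fp) || !std::isfinite(fm))
      Rcpp::stop("non-finite log density within the difference stencil of coordinate %d",
                 (int)i + 1);
    g(i) = (fp - fm) / (2.0 * h);
  }
  return g;
}

// Execute a compiled solve plan (see event_grid() on the R side).
// plan columns: 1 time, 2 op, 3 cmt, 4 amt (F-scaled), 5 rate, 6 ii,
//               7 record column (0 = none), 8 theta row (1-based).
// ops: 0 record-only, 1 bolus, 2 infusion start, 3 infusion end,
//      4 steady-state bolus, 5 steady-state infusion.
// [[Rcpp::export]]
arma::mat cpp_solve_plan(const arma::mat& plan, const arma::mat& theta,
                         int model, int n_record) {
  return solve_plan_impl(plan, theta, model, n_record);
}
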