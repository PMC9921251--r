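// Compiled numerical kernels: inequality-constrained quadratic programming
// (active set), damped Gauss-Newton / Levenberg-Marquardt nonlinear least
// squares, and batched (re)weighted linear solves used by the Monte-Carlo
// harness.  All linear-algebra conventions match the R level: parameter
// vectors have 28 entries (log S0, d6, c21).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Accelerated projected gradient on the dual
//   min_{lam >= 0} 1/2 lam' S lam - q' lam,  S = G H^-1 G', q = G H^-1 f - h.
// Guaranteed convergence for convex problems; used as the fallback when the
// active-set scheme stalls on degenerate working sets.
static bool qp_dual_pg(const mat& Hi, const vec& HiF, const mat& G,
                       const vec& h, double tol, vec& x, vec& lambda) {
  const uword m = G.n_rows;
  mat HiGt = Hi * G.t();
  mat S = G * HiGt;
  vec q = G * HiF - h;
  double L = norm(S, 2);
  if (!(L > 0)) { x = HiF; lambda.zeros(m); return true; }
  vec lam(m, fill::zeros), y = lam, lam_prev = lam;
  double t = 1.0;
  bool ok = false;
  for (int it = 0; it < 100000; ++it) {
    vec grad = S * y - q;
    lam = y - grad / L;
    lam.transform([](double v) { return v > 0 ? v : 0.0; });
    double tn = 0.5 * (1 + std::sqrt(1 + 4 * t * t));
    y = lam + ((t - 1) / tn) * (lam - lam_prev);
    t = tn;
    lam_prev = lam;
    if (it % 200 == 199) {
      x = HiF - HiGt * lam;
      vec v = G * x - h;
      // KKT: feasibility and complementary slackness
      double feas = v.max();
      double comp = std::abs(dot(lam, v));
      if (feas <= 10 * tol && comp <= 100 * tol * (1 + norm(x, 2))) {
        ok = true;
        break;
      }
    }
  }
  x = HiF - HiGt * lam;
  lambda = lam;
  return ok;
}

// Solve min 1/2 x'Hx - f'x  s.t.  G x <= h  for strictly convex H.
// Primal active-set scheme: repeatedly solve the equality-constrained
// problem on the working set, dropping constraints with negative
// multipliers and adding the most violated one.  Degenerate cases
// (dependent working sets, cycling) divert to the projected-gradient dual.
static bool qp_solve_core(const mat& H, const vec& f, const mat& G,
                          const vec& h, double tol, int maxit,
                          vec& x, vec& lambda, uvec& active, int& iters) {
  const uword m = G.n_rows;
  mat Hi;
  if (!inv_sympd(Hi, H)) {
    mat Hr = H + 1e-10 * trace(H) / H.n_rows * eye(H.n_rows, H.n_cols);
    if (!inv_sympd(Hi, Hr)) return false;
  }
  vec HiF = Hi * f;
  mat HiGt = Hi * G.t();            // n x m
  std::vector<uword> W;
  vec lamW;
  x = HiF;
  iters = 0;
  bool stalled = false;
  for (int it = 0; it < maxit; ++it) {
    iters = it + 1;
    const uword k = W.size();
    if (k > 0) {
      uvec Wi(k);
      for (uword i = 0; i < k; ++i) Wi[i] = W[i];
      mat SW = G.rows(Wi) * HiGt.cols(Wi);
      vec qW = G.rows(Wi) * HiF - h.elem(Wi);
      if (!solve(lamW, SW, qW, solve_opts::likely_sympd + solve_opts::no_approx)) {
        stalled = true;  // dependent working set
        break;
      }
      // drop the most negative multiplier, if any
      uword imin = lamW.index_min();
      if (lamW[imin] < -tol) {
        W.erase(W.begin() + imin);
        continue;
      }
      x = HiF - HiGt.cols(Wi) * lamW;
    } else {
      x = HiF;
    }
    vec v = G * x - h;
    uword imax = v.index_max();
    if (v[imax] <= tol) {
      lambda.zeros(m);
      active.set_size(W.size());
      for (uword i = 0; i < W.size(); ++i) {
        active[i] = W[i];
        lambda[W[i]] = lamW[i];
      }
      return true;
    }
    // re-adding a working-set row or exceeding the dimension means the
    // working set is degenerate
    bool inW = false;
    for (uword j : W) if (j == imax) { inW = true; break; }
    if (inW || W.size() >= H.n_rows) { stalled = true; break; }
    W.push_back(imax);
  }
  (void)stalled;
  bool ok = qp_dual_pg(Hi, HiF, G, h, tol, x, lambda);
  uvec act = find(lambda > tol);
  active = act;
  return ok;
}

// [[Rcpp::export(name = ".qp_active_set")]]
Rcpp::List qp_active_set(const arma::mat& H, const arma::vec& f,
                         const arma::mat& G, const arma::vec& h,
                         double tol = 1e-9, int maxit = 500) {
  vec x, lambda;
  uvec active;
  int iters = 0;
  bool ok = qp_solve_core(H, f, G, h, tol, maxit, x, lambda, active, iters);
  return Rcpp::List::create(
    Rcpp::Named("solution") = x,
    Rcpp::Named("lambda") = lambda,
    Rcpp::Named("active") = active + 1,  // 1-based for R
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("converged") = ok);
}

// Weighted linear least squares: minimize || w^{1/2} (y - A theta) ||^2
// via QR on the row-scaled system.
static vec wls_solve(const mat& A, const vec& y, const vec& wsqrt) {
  mat Aw = A.each_col() % wsqrt;
  vec yw = y % wsqrt;
  vec theta;
  if (!solve(theta, Aw, yw, solve_opts::no_approx)) {
    theta = pinv(Aw) * yw;
  }
  return theta;
}

// [[Rcpp::export(name = ".iwlls_batch")]]
Rcpp::List iwlls_batch(const arma::mat& A, const arma::mat& S, int nmax) {
  // A: N x p model matrix; S: N x R signal realizations (columns).
  // Iteration 1 weights come from the observed signal (WLLS); subsequent
  // iterations reweight with the model prediction.  Rows with non-positive
  // signal are dropped from the log-domain fit of that realization.
  const uword N = A.n_rows, R = S.n_cols, p = A.n_cols;
  mat Theta(p, R);
  ivec ndrop(R, fill::zeros);
  ivec status(R, fill::zeros);  // 0 ok, 1 fell back to earlier iterate
  for (uword r = 0; r < R; ++r) {
    vec s = S.col(r);
    uvec keep = find(s > 0);
    ndrop[r] = (int)(N - keep.n_elem);
    const mat Ak = A.rows(keep);
    const vec sk = s.elem(keep);
    vec y = log(sk);
    vec th = wls_solve(Ak, y, sk);          // weights s^2 on squared resid
    for (int it = 1; it < nmax; ++it) {
      vec pred = exp(Ak * th);
      if (!pred.is_finite()) { status[r] = 1; break; }
      vec th2 = wls_solve(Ak, y, pred);
      if (!th2.is_finite()) { status[r] = 1; break; }
      th = th2;
    }
    Theta.col(r) = th;
  }
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("dropped") = ndrop,
                            Rcpp::Named("status") = status);
}

// [[Rcpp::export(name = ".ciwlls_batch")]]
Rcpp::List ciwlls_batch(const arma::mat& A, const arma::mat& S,
                        const arma::mat& G, const arma::vec& h,
                        int nmax, double tol = 1e-9, int maxit = 500) {
  // Constrained IWLLS: identical iteration structure to iwlls_batch but each
  // weighted solve becomes min ||W^{1/2}(log s - A theta)||^2 s.t. G theta <= h.
  // The unconstrained solution is kept when already feasible.
  const uword N = A.n_rows, R = S.n_cols, p = A.n_cols;
  mat Theta(p, R);
  ivec nactive(R, fill::zeros);
  ivec status(R, fill::zeros);  // 0 ok, 2 qp fallback to unconstrained
  ivec ndrop(R, fill::zeros);
  for (uword r = 0; r < R; ++r) {
    vec s = S.col(r);
    uvec keep = find(s > 0);
    ndrop[r] = (int)(N - keep.n_elem);
    const mat Ak = A.rows(keep);
    const vec sk = s.elem(keep);
    vec y = log(sk);
    vec th;
    int nact = 0;
    for (int it = 0; it < nmax; ++it) {
      vec wsqrt = (it == 0) ? sk : exp(Ak * th);
      if (!wsqrt.is_finite()) { status[r] = 1; break; }
      vec thu = wls_solve(Ak, y, wsqrt);
      vec viol = G * thu - h;
      if (viol.max() <= tol) {
        th = thu;
        nact = 0;
      } else {
        vec w2 = square(wsqrt);
        mat H = Ak.t() * (Ak.each_col() % w2);
        vec f = Ak.t() * (w2 % y);
        vec x, lambda; uvec active; int iters;
        bool ok = qp_solve_core(H, f, G, h, tol, maxit, x, lambda, active, iters);
        if (ok && x.is_finite()) {
          th = x;
          nact = (int)active.n_elem;
        } else {
          th = thu;
          status[r] = 2;
          nact = 0;
        }
      }
    }
    Theta.col(r) = th;
    nactive[r] = nact;
  }
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("nactive") = nactive,
                            Rcpp::Named("dropped") = ndrop,
                            Rcpp::Named("status") = status);
}

// [[Rcpp::export(name = ".nls_lm_batch")]]
Rcpp::List nls_lm_batch(const arma::mat& A, const arma::mat& S,
                        const arma::mat& Theta0, double gtol = 1e-8,
                        double steptol = 1e-10, int maxit = 200) {
  // Levenberg-Marquardt on F(theta) = 1/2 || s - exp(A theta) ||^2 with
  // analytic Jacobian J = diag(exp(A theta)) A, one column of S per fit.
  const uword R = S.n_cols, p = A.n_cols;
  mat Theta(p, R);
  ivec status(R, fill::zeros);   // 0 converged, 1 max_iter
  ivec niter(R, fill::zeros);
  for (uword r = 0; r < R; ++r) {
    vec s = S.col(r);
    vec th = Theta0.col(r);
    double lam = 1e-3;
    vec pred = exp(clamp(A * th, -700.0, 700.0));
    vec res = s - pred;
    double F = 0.5 * dot(res, res);
    int it = 0;
    for (; it < maxit; ++it) {
      mat J = A.each_col() % pred;
      vec g = J.t() * res;                 // -grad of F
      if (norm(g, 2) < gtol) break;
      mat JtJ = J.t() * J;
      vec dJ = JtJ.diag();
      dJ.transform([](double v) { return std::max(v, 1e-12); });
      bool moved = false, tiny = false;
      for (int tries = 0; tries < 40; ++tries) {
        mat Hlm = JtJ;
        Hlm.diag() += lam * dJ;
        vec step;
        if (!solve(step, Hlm, g, solve_opts::likely_sympd + solve_opts::no_approx)) {
          lam *= 10; continue;
        }
        vec th2 = th + step;
        vec pred2 = exp(clamp(A * th2, -700.0, 700.0));
        vec res2 = s - pred2;
        double F2 = 0.5 * dot(res2, res2);
        if (F2 <= F) {
          tiny = norm(step, 2) < steptol;
          th = th2; pred = pred2; res = res2; F = F2;
          lam = std::max(lam / 3.0, 1e-12);
          moved = true;
          break;
        }
        lam *= 4.0;
      }
      if (!moved || tiny) break;  // converged by step size or stalled
    }
    if (it >= maxit) status[r] = 1;
    niter[r] = it;
    Theta.col(r) = th;
  }
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("status") = status,
                            Rcpp::Named("niter") = niter);
}
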