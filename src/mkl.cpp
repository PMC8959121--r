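// Sparse multiple kernel learning for epsilon-insensitive regression.
//
// The model minimises, over per-kernel functions f_m and intercept b,
//     sum_m ||f_m||_{H_m}  +  C * sum_i L_eps(y_i - sum_m f_m(x_i) - b)
// (block-L1 MKL; the group norm, not its square, so entire kernel weights
// are driven exactly to zero).  We use the variational identity
//     ||w|| = min_{d>0} ( ||w||^2/(2d) + d/2 )
// which turns the problem into min_{d>=0} J(d), J(d) = S(d) + 0.5*sum(d),
// where S(d) is a standard eps-SVR with combined kernel K(d) = sum d_m K_m.
// J is minimised by a spectral projected gradient (Barzilai-Borwein step,
// nonmonotone line search); at the optimum alpha' K_m alpha = 1 for every
// active kernel.
//
// All kernels here are linear kernels of (preprocessed) feature columns, so
// the inner eps-SVR is solved in the primal feature space (dimension = the
// number of active feature columns, tiny) by a damped Newton method on a
// Huber-smoothed epsilon-insensitive loss with a vanishing smoothing width.
// Unlike dual decomposition (SMO), its cost does not blow up for large C or
// rank-deficient combined kernels.  The dual vector alpha_i = C * dL/dr_i
// feeds the kernel-weight gradient alpha' K_m alpha = ||X_m' alpha||^2 and a
// duality-gap certificate for the block-L1 problem.

#include <RcppArmadillo.h>
#include <random>
#include <deque>
#include <vector>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// ------------------------------------------------------------------
// smoothed epsilon-insensitive loss helpers
// ------------------------------------------------------------------

// derivative of the Huberised tube loss w.r.t. the residual, in [-1, 1]
static inline double psi_gamma(double r, double eps, double gamma) {
  const double a = std::abs(r) - eps;
  if (a <= 0) return 0.0;
  const double s = (r > 0) ? 1.0 : -1.0;
  return (a >= gamma) ? s : s * a / gamma;
}

static inline double loss_gamma(double r, double eps, double gamma) {
  const double a = std::abs(r) - eps;
  if (a <= 0) return 0.0;
  return (a >= gamma) ? (a - 0.5 * gamma) : 0.5 * a * a / gamma;
}

// exact minimiser over b of sum_i L_gamma(r_i - b): the root of the
// monotone piecewise-linear h(b) = sum_i psi(r_i - b)
static double optimal_b_smoothed(const vec& r, double eps, double gamma) {
  const int n = (int)r.n_elem;
  std::vector<double> bp;
  bp.reserve(4 * n);
  for (int i = 0; i < n; ++i) {
    bp.push_back(r(i) - eps - gamma);
    bp.push_back(r(i) - eps);
    bp.push_back(r(i) + eps);
    bp.push_back(r(i) + eps + gamma);
  }
  std::sort(bp.begin(), bp.end());
  auto h = [&](double b) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += psi_gamma(r(i) - b, eps, gamma);
    return s;
  };
  // binary search for the sign change among breakpoints
  int lo = 0, hi = (int)bp.size() - 1;
  if (h(bp[lo]) <= 0) return bp[lo];
  if (h(bp[hi]) >= 0) return bp[hi];
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (h(bp[mid]) > 0) lo = mid; else hi = mid;
  }
  const double hl = h(bp[lo]), hh = h(bp[hi]);
  if (hl <= hh + 1e-300) return 0.5 * (bp[lo] + bp[hi]);
  return bp[lo] + (bp[hi] - bp[lo]) * hl / (hl - hh);
}

// Exact minimiser of sum_i max(0, |r_i - b| - eps) over b (unsmoothed):
// midpoint of the middle two elements of {r_i - eps, r_i + eps}.
static double optimal_b(const vec& r, double eps) {
  const int n = (int)r.n_elem;
  std::vector<double> bp(2 * n);
  for (int i = 0; i < n; ++i) {
    bp[2 * i] = r(i) - eps;
    bp[2 * i + 1] = r(i) + eps;
  }
  std::sort(bp.begin(), bp.end());
  return 0.5 * (bp[n - 1] + bp[n]);
}

// ------------------------------------------------------------------
// Solver: one damped Newton iteration stream on the jointly smoothed
// primal in the (tiny) feature space,
//   F(v, b) = sum_m phi_mu(||v_m||) + C sum_i L_{eps,gamma}(y - Xv - b),
// phi_mu(s) = sqrt(s^2 + mu^2) - mu, with continuation (gamma, mu) -> 0.
// The intercept is minimised exactly at every step.  Cost per iteration is
// O(n p^2 + p^3) with p <= #features, independent of C -- unlike dual
// decomposition, which zigzags for large C on rank-deficient kernels.
// ------------------------------------------------------------------
struct MklControl {
  double tol_kkt;    // reporting threshold on the kernel-weight KKT residual
  int max_outer;     // cap on total Newton iterations
  double inner_tol;  // gradient tolerance (absolute after scale_ctl)
  int inner_maxit;   // Newton iterations per continuation stage
  double gamma;      // final loss smoothing width (absolute after scale_ctl)
  double gamma0;     // initial (continuation) loss smoothing width
  double mu;         // final group-norm smoothing width (absolute)
};

struct MklFitOut {
  vec d, alpha, q, v;
  double b, primal, dual_lb;
  int iters;
  bool converged;
};

static MklFitOut mkl_fit_engine(const mat& X, const std::vector<uvec>& gcols,
                                const vec& y, double C, double eps,
                                bool squared, const MklControl& ctl,
                                const vec& d_warm, const vec& alpha_warm) {
  const int n = (int)X.n_rows;
  const int p = (int)X.n_cols;
  const int M = (int)gcols.size();

  // warm start via the representer relation v_m = d_m X_m' alpha
  vec v(p, fill::zeros);
  if ((int)d_warm.n_elem == M && (int)alpha_warm.n_elem == n &&
      abs(alpha_warm).max() > 0) {
    vec u = X.t() * alpha_warm;
    for (int m = 0; m < M; ++m)
      for (uword j : gcols[m]) v(j) = d_warm(m) * u(j);
  }

  const double gamma_f = squared ? 1.0 : ctl.gamma;
  const double gamma_start = squared ? 1.0 : std::max(ctl.gamma0, gamma_f);
  const double mu_f = ctl.mu;

  // continuation ladder; wide final widths (the CV tier) need no ladder,
  // and a warm start that is already near-stationary at the final widths
  // skips straight to them
  std::vector<std::pair<double, double>> stages;
  {
    double g0 = gamma_start;
    double m0 = std::max(0.3, mu_f);
    bool near = mu_f >= 0.01; // wide-smoothing tier: single stage
    if (!near && abs(v).max() > 0) {
      vec f = X * v;
      double b0;
      vec res;
      if (squared) { b0 = mean(y - f); res = y - f - b0; }
      else { b0 = optimal_b_smoothed(y - f, eps, gamma_f); res = y - f - b0; }
      vec a0(n);
      for (int i = 0; i < n; ++i)
        a0(i) = squared ? 2.0 * C * res(i)
                        : C * psi_gamma(res(i), eps, gamma_f);
      vec gp(p);
      for (int m = 0; m < M; ++m) {
        double rho = std::sqrt(accu(square(v(gcols[m]))) + mu_f * mu_f);
        for (uword j : gcols[m]) gp(j) = v(j) / rho;
      }
      near = abs(gp - X.t() * a0).max() <= 300.0 * ctl.inner_tol;
    }
    if (!near) {
      double ratio = std::max(g0 / gamma_f, m0 / mu_f);
      int ns = std::max(1, (int)std::ceil(std::log(ratio) / std::log(25.0)));
      for (int sidx = 0; sidx < ns; ++sidx) {
        double wgt = (double)sidx / ns;
        stages.push_back({std::pow(g0, 1 - wgt) * std::pow(gamma_f, wgt),
                          std::pow(m0, 1 - wgt) * std::pow(mu_f, wgt)});
      }
    }
    stages.push_back({gamma_f, mu_f});
  }

  int iters = 0;
  double b = 0;
  vec alpha(n, fill::zeros);
  bool converged = false;
  for (auto& st : stages) {
    const double gamma = st.first, mu = st.second;
    converged = false;
    for (int it = 0; it < ctl.inner_maxit && iters < ctl.max_outer; ++it) {
      ++iters;
      vec f = X * v;
      if (squared) b = mean(y - f);
      else b = optimal_b_smoothed(y - f, eps, gamma);
      vec res = y - f - b;
      vec wgt(n);
      for (int i = 0; i < n; ++i) {
        if (squared) {
          alpha(i) = 2.0 * C * res(i);
          wgt(i) = 2.0 * C;
        } else {
          alpha(i) = C * psi_gamma(res(i), eps, gamma);
          const double a = std::abs(res(i)) - eps;
          wgt(i) = (a > 0 && a < gamma) ? C / gamma : 0.0;
        }
      }
      // gradient of the b-reduced objective
      vec rho(M), grad(p);
      for (int m = 0; m < M; ++m) {
        rho(m) = std::sqrt(accu(square(v(gcols[m]))) + mu * mu);
        for (uword j : gcols[m]) grad(j) = v(j) / rho(m);
      }
      grad -= X.t() * alpha;
      if (abs(grad).max() <= ctl.inner_tol) { converged = true; break; }

      // generalized Hessian (penalty blocks + loss rows, b eliminated)
      mat H(p, p, fill::zeros);
      for (int m = 0; m < M; ++m) {
        const double r1 = 1.0 / rho(m), r3 = r1 * r1 * r1;
        for (uword j : gcols[m]) {
          for (uword k : gcols[m]) H(j, k) = -v(j) * v(k) * r3;
          H(j, j) += r1;
        }
      }
      uvec Z = find(wgt > 0);
      if (Z.n_elem > 0) {
        vec sw = sqrt(wgt(Z));
        mat Xz = X.rows(Z);
        Xz.each_col() %= sw;
        H += Xz.t() * Xz;
        vec u1 = Xz.t() * sw; // H_vb
        const double hbb = accu(wgt(Z));
        H -= u1 * u1.t() / hbb;
      }
      double F0 = 0.0;
      for (int m = 0; m < M; ++m) F0 += rho(m) - mu;
      for (int i = 0; i < n; ++i)
        F0 += squared ? C * res(i) * res(i)
                      : C * loss_gamma(res(i), eps, gamma);

      // Newton step with Levenberg safeguard: if the line search stalls,
      // re-damp towards a gradient step and retry
      bool moved = false;
      double lev = 1e-9 * (1.0 + trace(H) / p);
      for (int attempt = 0; attempt < 3 && !moved; ++attempt) {
        mat Hd = H;
        Hd.diag() += lev;
        vec pdir;
        bool ok = solve(pdir, Hd, -grad,
                        solve_opts::likely_sympd + solve_opts::no_approx);
        if (!ok || !pdir.is_finite()) { lev *= 1e4; continue; }
        const double slope = dot(grad, pdir);
        if (slope >= 0) { lev *= 1e4; continue; }
        double step = 1.0;
        for (int ls = 0; ls < 30; ++ls) {
          vec vt = v + step * pdir;
          vec ft = X * vt;
          double bt = squared ? mean(y - ft)
                              : optimal_b_smoothed(y - ft, eps, gamma);
          double Ft = 0.0;
          for (int m = 0; m < M; ++m)
            Ft += std::sqrt(accu(square(vt(gcols[m]))) + mu * mu) - mu;
          for (int i = 0; i < n; ++i) {
            const double rr = y(i) - ft(i) - bt;
            Ft += squared ? C * rr * rr : C * loss_gamma(rr, eps, gamma);
          }
          if (Ft <= F0 + 1e-4 * step * slope) { v = vt; moved = true; break; }
          step *= 0.5;
        }
        if (!moved) lev = std::max(lev * 1e4, 1e-6 * (1.0 + trace(H) / p));
      }
      if (!moved) break;
    }
  }

  // exact (unsmoothed) intercept and objective, evaluated at the returned
  // coefficients v themselves.  The dual vector is taken at the *smoothed*
  // intercept so that it stays consistent with v through the representer
  // relation (v_m ~ d_m X_m' alpha).
  vec f = X * v;
  double b_s;
  if (squared) b_s = mean(y - f);
  else b_s = optimal_b_smoothed(y - f, eps, gamma_f);
  vec res_s = y - f - b_s;
  for (int i = 0; i < n; ++i)
    alpha(i) = squared ? 2.0 * C * res_s(i)
                       : C * psi_gamma(res_s(i), eps, gamma_f);
  if (squared) b = mean(y - f);
  else b = optimal_b(y - f, eps);
  vec res = y - f - b;

  vec d(M), q(M);
  vec u = X.t() * alpha;
  double primal = 0.0;
  for (int m = 0; m < M; ++m) {
    d(m) = std::sqrt(accu(square(v(gcols[m]))));
    q(m) = accu(square(u(gcols[m])));
    primal += d(m);
  }
  double loss = 0.0;
  if (squared) loss = dot(res, res);
  else for (int i = 0; i < n; ++i)
    loss += std::max(0.0, std::abs(res(i)) - eps);
  primal += C * loss;

  // dual-feasible rescaling gives a lower bound for the block-L1 problem
  double lam_sc = 1.0;
  for (int m = 0; m < M; ++m) lam_sc = std::max(lam_sc, std::sqrt(q(m)));
  vec at = alpha / lam_sc;
  at -= mean(at); // enforce the equality constraint exactly
  at = clamp(at, -C, C);
  double dual_lb;
  if (squared) dual_lb = dot(y, at) - accu(square(at)) / (4.0 * C);
  else dual_lb = dot(y, at) - eps * accu(abs(at));

  MklFitOut out;
  out.d = d; out.alpha = alpha; out.q = q; out.v = v;
  out.b = b; out.primal = primal; out.dual_lb = dual_lb;
  out.iters = iters; out.converged = converged;
  return out;
}

// ------------------------------------------------------------------
// Fold-wise preprocessing (training-set statistics only):
// column demeaning, z-scoring of designated columns (confounds), and
// per-kernel normalisation to unit mean diagonal of the centred kernel.
// ------------------------------------------------------------------
struct Prep {
  rowvec mu, sc;
  vec gs;
};

static Prep make_prep(const mat& F, const uvec& tr,
                      const std::vector<uvec>& gcols, const uvec& zcols,
                      bool unit_trace) {
  Prep P;
  mat Ft = F.rows(tr);
  P.mu = mean(Ft, 0);
  P.sc = ones<rowvec>(F.n_cols);
  for (uword j : zcols) {
    const double s = stddev(Ft.col(j));
    P.sc(j) = (s > 1e-12) ? s : 1.0;
  }
  const int M = (int)gcols.size();
  P.gs = ones(M);
  const double m = (double)tr.n_elem;
  for (int g = 0; g < M; ++g) {
    double trc = 0.0;
    for (uword j : gcols[g])
      trc += accu(square((Ft.col(j) - P.mu(j)) / P.sc(j)));
    P.gs(g) = (trc > 1e-12) ? std::sqrt((unit_trace ? 1.0 : m) / trc) : 0.0;
  }
  return P;
}

static mat apply_prep(const mat& F, const uvec& rows, const Prep& P,
                      const std::vector<uvec>& gcols) {
  mat X = F.rows(rows);
  X.each_row() -= P.mu;
  X.each_row() /= P.sc;
  for (size_t g = 0; g < gcols.size(); ++g)
    for (uword j : gcols[g]) X.col(j) *= P.gs(g);
  return X;
}

struct Ctx {
  uvec tr, va;
  mat Xtr, Xva;
};

static Ctx make_ctx(const mat& F, const uvec& tr, const uvec& va,
                    const std::vector<uvec>& gcols, const uvec& zcols,
                    bool unit_trace) {
  Ctx c;
  c.tr = tr;
  c.va = va;
  Prep P = make_prep(F, tr, gcols, zcols, unit_trace);
  c.Xtr = apply_prep(F, tr, P, gcols);
  c.Xva = apply_prep(F, va, P, gcols);
  return c;
}

static std::vector<uvec> group_cols(const ivec& grp, int M) {
  std::vector<std::vector<uword>> tmp(M);
  for (uword j = 0; j < grp.n_elem; ++j) tmp[grp(j)].push_back(j);
  std::vector<uvec> out(M);
  for (int m = 0; m < M; ++m) out[m] = uvec(tmp[m]);
  return out;
}

static uword rint(std::mt19937& g, uword bound) { return g() % bound; }

static uvec shuffled(std::mt19937& g, const uvec& v) {
  uvec s = v;
  for (uword j = s.n_elem; j > 1; --j) std::swap(s(j - 1), s(rint(g, j)));
  return s;
}

// predictions of a fit on a preprocessed validation block
static vec predict_fit(const Ctx& cx, const std::vector<uvec>& gcols,
                       const MklFitOut& ft) {
  return cx.Xva * ft.v + ft.b;
}

struct Warm {
  std::vector<vec> d, a; // indexed by position on the C grid
};

// per-fit absolute scalings of the inner tolerances
static MklControl scale_ctl(const MklControl& base, const vec& ytr,
                            double eps) {
  MklControl c = base;
  double ysc = (ytr.max() - ytr.min()) + eps;
  if (ysc < 1e-12) ysc = 1.0;
  const int n = (int)ytr.n_elem;
  c.inner_tol = base.inner_tol * ysc * (1.0 + 0.1 * std::sqrt((double)n));
  c.gamma = base.gamma * std::max(eps, 0.02 * ysc);
  c.gamma0 = std::max(0.25 * eps, 0.02 * ysc);
  c.mu = base.mu * std::max(1.0, 0.02 * ysc);
  return c;
}

static double pearson_or_zero(const vec& a, const vec& b) {
  const double sa = stddev(a), sb = stddev(b);
  if (sa < 1e-14 || sb < 1e-14) return 0.0;
  return as_scalar(cor(a, b));
}


// hyperparameter choice from pooled held-out predictions: either minimal
// mean squared error, or the smallest C within one standard error of the
// best pooled Pearson r (the more regularized model among statistically
// indistinguishable ones); ties resolve to the smallest C
static int select_C_index(const vec& sse, const vec& score, bool crit_mse,
                          int nv, double sse_const, const uvec& active) {
  const int nC = (int)sse.n_elem;
  int best = 0;
  if (crit_mse) {
    for (int ci = 1; ci < nC; ++ci) if (sse(ci) < sse(best)) best = ci;
    return best;
  }
  // scale guard: a cost whose held-out error is worse than twice the
  // trivial constant predictor produces off-scale predictions and is not a
  // usable model, whatever its correlation.  Fully degenerate candidates
  // (every fold fits the all-zero model) are likewise excluded whenever a
  // usable active candidate exists: an intercept-only fit is the "no
  // model" outcome, not a competing predictor.
  uvec ok(nC);
  bool any_ok = false;
  for (int ci = 0; ci < nC; ++ci) {
    ok(ci) = (sse(ci) <= 2.0 * sse_const && active(ci)) ? 1 : 0;
    if (ok(ci)) any_ok = true;
  }
  if (!any_ok) {
    for (int ci = 0; ci < nC; ++ci) {
      ok(ci) = (sse(ci) <= 2.0 * sse_const) ? 1 : 0;
      if (ok(ci)) any_ok = true;
    }
  }
  if (!any_ok) return 0;
  double rmax = -2.0;
  for (int ci = 0; ci < nC; ++ci)
    if (ok(ci) && score(ci) > rmax) rmax = score(ci);
  double se = std::sqrt(std::max(0.0, 1.0 - rmax * rmax) /
                        std::max(1, nv - 3));
  const double thr = rmax - se;
  for (int ci = 0; ci < nC; ++ci) {
    if (ok(ci) && score(ci) >= thr) return ci;
  }
  return best;
}

// One full nested leave-one-out run: for each held-out subject, inner k-fold
// CV over the C grid (mean held-out squared error, ties -> smallest C), then
// a final fit on the n-1 training subjects.  All preprocessing statistics
// come from the corresponding training rows only (carried by the contexts).
static void nested_loo(const std::vector<std::vector<Ctx>>& inner_ctx,
                       const std::vector<Ctx>& outer_ctx,
                       const std::vector<uvec>& gcols, const vec& y,
                       const vec& Cgrid, double eps_frac, double eps_fixed,
                       bool squared, bool crit_mse, const MklControl& ctlCV,
                       const MklControl& ctlFit,
                       std::vector<std::vector<Warm>>& warmI,
                       std::vector<Warm>& warmO,
                       vec& pred, vec& Csel) {
  const int n = (int)y.n_elem;
  const int nC = (int)Cgrid.n_elem;
  pred.set_size(n);
  Csel.set_size(n);

  for (int i = 0; i < n; ++i) {
    const int kf = (int)inner_ctx[i].size();
    const int nv = (int)(y.n_elem - 1); // pooled held-out predictions
    vec sse(nC, fill::zeros);
    mat pool(nv, nC);
    vec act(nv);
    uvec active(nC, fill::zeros);
    int pos = 0;
    for (int f = 0; f < kf; ++f) {
      const Ctx& cx = inner_ctx[i][f];
      vec ytr = y(cx.tr), yva = y(cx.va);
      const double sdy = (ytr.n_elem > 1) ? stddev(ytr) : 0.0;
      const double eps = (eps_fixed >= 0) ? eps_fixed : eps_frac * sdy;
      MklControl ctl = scale_ctl(ctlCV, ytr, eps);
      Warm& wm = warmI[i][f];
      if (wm.d.empty()) { wm.d.resize(nC); wm.a.resize(nC); }
      vec d0, a0; // warm along the C path of the current sweep
      for (int ci = 0; ci < nC; ++ci) {
        MklFitOut ft = mkl_fit_engine(cx.Xtr, gcols, ytr, Cgrid(ci), eps,
                                      squared, ctl, d0, a0);
        d0 = ft.d;
        a0 = ft.alpha;
        wm.d[ci] = ft.d;
        wm.a[ci] = ft.alpha;
        // group-norm smoothing keeps "zero" weights at O(mu), so activity
        // is judged relative to the smoothing width
        if (ft.d.max() > 3.0 * ctl.mu) active(ci) = 1;
        vec pv = predict_fit(cx, gcols, ft);
        sse(ci) += accu(square(yva - pv));
        pool(span(pos, pos + pv.n_elem - 1), span(ci, ci)) = pv;
      }
      act.subvec(pos, pos + yva.n_elem - 1) = yva;
      pos += (int)yva.n_elem;
    }
    vec score(nC);
    for (int ci = 0; ci < nC; ++ci)
      score(ci) = pearson_or_zero(act, pool.col(ci));
    const double sse_const = accu(square(act - mean(act)));
    const int best = select_C_index(sse, score, crit_mse, nv, sse_const,
                                    active);

    const Ctx& ox = outer_ctx[i];
    vec ytr = y(ox.tr);
    const double sdy = stddev(ytr);
    const double eps = (eps_fixed >= 0) ? eps_fixed : eps_frac * sdy;
    MklControl ctl = scale_ctl(ctlFit, ytr, eps);
    Warm& wo = warmO[i];
    if (wo.d.empty()) { wo.d.resize(1); wo.a.resize(1); }
    MklFitOut ft = mkl_fit_engine(ox.Xtr, gcols, ytr, Cgrid(best), eps,
                                  squared, ctl, wo.d[0], wo.a[0]);
    wo.d[0] = ft.d;
    wo.a[0] = ft.alpha;
    pred(i) = as_scalar(predict_fit(ox, gcols, ft));
    Csel(i) = Cgrid(best);
  }
}

// builds the inner/outer contexts for a LOO run; fold shuffles are drawn
// from rng in a data-independent order (one shuffle per outer fold)
static void build_loo_ctx(const mat& F, const std::vector<uvec>& gcols,
                          const uvec& zcols, bool unit_trace, int n, int k,
                          std::mt19937& rng,
                          std::vector<std::vector<Ctx>>& inner_ctx,
                          std::vector<Ctx>& outer_ctx) {
  inner_ctx.assign(n, {});
  outer_ctx.clear();
  outer_ctx.reserve(n);
  for (int i = 0; i < n; ++i) {
    std::vector<uword> tr_;
    for (int j = 0; j < n; ++j) if (j != i) tr_.push_back(j);
    uvec tr(tr_);
    uvec sh = shuffled(rng, tr);
    const int kf = std::min<int>(k, (int)tr.n_elem);
    std::vector<std::vector<uword>> folds(kf);
    for (uword j = 0; j < sh.n_elem; ++j) folds[j % kf].push_back(sh(j));
    for (int f = 0; f < kf; ++f) {
      uvec va(folds[f]);
      std::vector<uword> t2;
      for (uword j : tr_) {
        bool inva = false;
        for (uword v : folds[f]) if (v == j) { inva = true; break; }
        if (!inva) t2.push_back(j);
      }
      inner_ctx[i].push_back(make_ctx(F, uvec(t2), va, gcols, zcols,
                                      unit_trace));
    }
    uvec va(1);
    va(0) = i;
    outer_ctx.push_back(make_ctx(F, tr, va, gcols, zcols, unit_trace));
  }
}

static MklControl make_ctl(double tol_kkt, int max_outer, double inner_rel,
                           int inner_maxit, double gamma_rel, double mu_rel) {
  MklControl c;
  c.tol_kkt = tol_kkt;
  c.max_outer = max_outer;
  c.inner_tol = inner_rel;   // scaled per fit by scale_ctl
  c.inner_maxit = inner_maxit;
  c.gamma = gamma_rel;       // scaled per fit by scale_ctl
  c.gamma0 = gamma_rel;
  c.mu = mu_rel;
  return c;
}

// ------------------------------------------------------------------
// exported interfaces
// ------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_mkl_fit(const arma::mat& X, const arma::ivec& grp, int M,
                 const arma::vec& y, double C, double eps, bool squared,
                 double tol_kkt, int max_outer, double inner_rel,
                 int inner_maxit, double gamma_rel, double mu_rel,
                 const arma::vec& d0, const arma::vec& a0) {
  std::vector<uvec> gcols = group_cols(grp, M);
  MklControl ctl = scale_ctl(
      make_ctl(tol_kkt, max_outer, inner_rel, inner_maxit, gamma_rel,
               mu_rel),
      y, eps);
  MklFitOut ft = mkl_fit_engine(X, gcols, y, C, eps, squared, ctl, d0, a0);
  return List::create(
      Named("d") = ft.d, Named("alpha") = ft.alpha, Named("w") = ft.v,
      Named("b") = ft.b, Named("objective") = ft.primal,
      Named("dual_lb") = ft.dual_lb, Named("q") = ft.q,
      Named("iters") = ft.iters, Named("converged") = ft.converged);
}

// [[Rcpp::export]]
List cpp_inner_select(const arma::mat& F, const arma::ivec& grp, int M,
                      const arma::uvec& zcols, const arma::uvec& train,
                      const arma::vec& y, const arma::vec& Cgrid,
                      double eps_frac, double eps_fixed, bool squared,
                      bool crit_mse, bool unit_trace, int k, int seed,
                      double tol_kkt, int max_outer, double inner_rel,
                      int inner_maxit, double gamma_rel, double mu_rel) {
  std::vector<uvec> gcols = group_cols(grp, M);
  std::mt19937 rng((unsigned)seed);
  uvec sh = shuffled(rng, train);
  const int kf = std::min<int>(k, (int)train.n_elem);
  std::vector<std::vector<uword>> folds(kf);
  for (uword j = 0; j < sh.n_elem; ++j) folds[j % kf].push_back(sh(j));

  MklControl base = make_ctl(tol_kkt, max_outer, inner_rel, inner_maxit,
                             gamma_rel, mu_rel);
  const int nC = (int)Cgrid.n_elem;
  const int nv = (int)train.n_elem;
  vec sse(nC, fill::zeros);
  mat pool(nv, nC);
  vec act(nv);
  uvec active(nC, fill::zeros);
  int pos = 0;
  for (int f = 0; f < kf; ++f) {
    uvec va(folds[f]);
    std::vector<uword> t2;
    for (uword j : train) {
      bool inva = false;
      for (uword v : folds[f]) if (v == j) { inva = true; break; }
      if (!inva) t2.push_back(j);
    }
    Ctx cx = make_ctx(F, uvec(t2), va, gcols, zcols, unit_trace);
    vec ytr = y(cx.tr), yva = y(cx.va);
    const double sdy = (ytr.n_elem > 1) ? stddev(ytr) : 0.0;
    const double eps = (eps_fixed >= 0) ? eps_fixed : eps_frac * sdy;
    MklControl ctl = scale_ctl(base, ytr, eps);
    vec d0, a0;
    for (int ci = 0; ci < nC; ++ci) {
      MklFitOut ft = mkl_fit_engine(cx.Xtr, gcols, ytr, Cgrid(ci), eps,
                                    squared, ctl, d0, a0);
      d0 = ft.d;
      a0 = ft.alpha;
      if (ft.d.max() > 3.0 * ctl.mu) active(ci) = 1;
      vec pv = predict_fit(cx, gcols, ft);
      sse(ci) += accu(square(yva - pv));
      pool(span(pos, pos + pv.n_elem - 1), span(ci, ci)) = pv;
    }
    act.subvec(pos, pos + yva.n_elem - 1) = yva;
    pos += (int)yva.n_elem;
  }
  vec score(nC);
  for (int ci = 0; ci < nC; ++ci)
    score(ci) = pearson_or_zero(act, pool.col(ci));
  const double sse_const = accu(square(act - mean(act)));
  const int best = select_C_index(sse, score, crit_mse, nv, sse_const,
                                  active);
  return List::create(Named("C") = Cgrid(best),
                      Named("cv_mse") = sse / (double)train.n_elem,
                      Named("cv_r") = score);
}

// [[Rcpp::export]]
List cpp_loo(const arma::mat& F, const arma::ivec& grp, int M,
             const arma::uvec& zcols, const arma::vec& y,
             const arma::vec& Cgrid, double eps_frac, double eps_fixed,
             bool squared, bool crit_mse, bool unit_trace, int k, int seed,
             double tol_kkt_cv,
             int max_outer_cv, double inner_rel_cv, int inner_maxit_cv,
             double gamma_rel_cv, double mu_rel_cv, double tol_kkt_fit,
             int max_outer_fit, double inner_rel_fit, int inner_maxit_fit,
             double gamma_rel_fit, double mu_rel_fit) {
  const int n = (int)y.n_elem;
  std::vector<uvec> gcols = group_cols(grp, M);
  std::mt19937 rng((unsigned)seed);
  std::vector<std::vector<Ctx>> inner_ctx;
  std::vector<Ctx> outer_ctx;
  build_loo_ctx(F, gcols, zcols, unit_trace, n, k, rng, inner_ctx,
                outer_ctx);

  std::vector<std::vector<Warm>> warmI(n);
  std::vector<Warm> warmO(n);
  for (int i = 0; i < n; ++i) warmI[i].resize(inner_ctx[i].size());

  MklControl ctlCV = make_ctl(tol_kkt_cv, max_outer_cv, inner_rel_cv,
                              inner_maxit_cv, gamma_rel_cv, mu_rel_cv);
  MklControl ctlFit = make_ctl(tol_kkt_fit, max_outer_fit, inner_rel_fit,
                               inner_maxit_fit, gamma_rel_fit, mu_rel_fit);
  vec pred, Csel;
  nested_loo(inner_ctx, outer_ctx, gcols, y, Cgrid, eps_frac, eps_fixed,
             squared, crit_mse, ctlCV, ctlFit, warmI, warmO, pred, Csel);
  const double r = pearson_or_zero(y, pred);
  const double rmse = std::sqrt(accu(square(y - pred)) / n);
  return List::create(Named("pred") = pred, Named("Csel") = Csel,
                      Named("r") = r, Named("rmse") = rmse);
}

// [[Rcpp::export]]
List cpp_perm(const arma::mat& F, const arma::ivec& grp, int M,
              const arma::uvec& zcols, const arma::vec& y,
              const arma::vec& Cgrid, double eps_frac, double eps_fixed,
              bool squared, bool crit_mse, bool unit_trace, int k, int n_perm,
              int seed, double tol_kkt_cv,
              int max_outer_cv, double inner_rel_cv, int inner_maxit_cv,
              double gamma_rel_cv, double mu_rel_cv, double tol_kkt_fit,
              int max_outer_fit, double inner_rel_fit, int inner_maxit_fit,
              double gamma_rel_fit, double mu_rel_fit) {
  const int n = (int)y.n_elem;
  std::vector<uvec> gcols = group_cols(grp, M);
  std::mt19937 rng((unsigned)seed);
  std::vector<std::vector<Ctx>> inner_ctx;
  std::vector<Ctx> outer_ctx;
  build_loo_ctx(F, gcols, zcols, unit_trace, n, k, rng, inner_ctx,
                outer_ctx);

  std::vector<std::vector<Warm>> warmI(n);
  std::vector<Warm> warmO(n);
  for (int i = 0; i < n; ++i) warmI[i].resize(inner_ctx[i].size());

  MklControl ctlCV = make_ctl(tol_kkt_cv, max_outer_cv, inner_rel_cv,
                              inner_maxit_cv, gamma_rel_cv, mu_rel_cv);
  MklControl ctlFit = make_ctl(tol_kkt_fit, max_outer_fit, inner_rel_fit,
                               inner_maxit_fit, gamma_rel_fit, mu_rel_fit);

  vec null_r(n_perm), null_rmse(n_perm);
  uvec idx = regspace<uvec>(0, n - 1);
  for (int p = 0; p < n_perm; ++p) {
    uvec sh = shuffled(rng, idx);
    vec yp = y(sh);
    vec pred, Csel;
    nested_loo(inner_ctx, outer_ctx, gcols, yp, Cgrid, eps_frac, eps_fixed,
               squared, crit_mse, ctlCV, ctlFit, warmI, warmO, pred, Csel);
    null_r(p) = pearson_or_zero(yp, pred);
    null_rmse(p) = std::sqrt(accu(square(yp - pred)) / n);
    if (p % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(Named("null_r") = null_r, Named("null_rmse") = null_rmse);
}
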