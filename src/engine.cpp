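// Core numerical engine: Lotka-Volterra right-hand side for the 3-guild
// multiplex community, an adaptive embedded Runge-Kutta integrator with
// equilibrium detection (called once per rewiring attempt, so it must be
// cheap), and a BRIM-style optimizer for Barber bipartite modularity.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct GuildSystem {
  arma::vec rP, rM, rH;
  arma::mat betaP, betaM, betaH; // within-guild competition
  arma::mat gamma;               // S_P x S_M mutualistic strengths
  arma::mat tau;                 // S_P x S_H antagonistic strengths
  arma::mat thMP;                // S_M x S_P binary incidence
  arma::mat thHP;                // S_H x S_P binary incidence
  double h, eps;
};

// Derivatives of (P, M, H). Saturation (type II) denominators:
//   plants' mutualistic gain saturates over the plant's own pollinator set;
//   herbivory saturates over each herbivore's OWN plant set (both in the
//   plant-loss and the herbivore-gain term).
static void guild_rhs(const GuildSystem& gs,
                      const arma::vec& P, const arma::vec& M, const arma::vec& H,
                      arma::vec& dP, arma::vec& dM, arma::vec& dH) {
  arma::vec DP = 1.0 + gs.h * (gs.thMP.t() * M); // per plant
  arma::vec EH = 1.0 + gs.h * (gs.thHP * P);     // per herbivore
  arma::vec DM = 1.0 + gs.h * (gs.thMP * P);     // per pollinator

  arma::vec gainP = (gs.gamma * M) / DP;
  arma::vec lossP = gs.tau * (H / EH);
  arma::vec gainM = (gs.gamma.t() * P) / DM;
  arma::vec gainH = gs.eps * (gs.tau.t() * P) / EH;

  dP = P % (gs.rP - gs.betaP * P + gainP - lossP);
  dM = M % (gs.rM - gs.betaM * M + gainM);
  dH = H % (gs.rH - gs.betaH * H + gainH);
}

static GuildSystem make_system(const arma::vec& rP, const arma::vec& rM,
                               const arma::vec& rH, const arma::mat& betaP,
                               const arma::mat& betaM, const arma::mat& betaH,
                               const arma::mat& gamma, const arma::mat& tau,
                               const arma::mat& thMP, const arma::mat& thHP,
                               double h, double eps) {
  GuildSystem gs;
  gs.rP = rP; gs.rM = rM; gs.rH = rH;
  gs.betaP = betaP; gs.betaM = betaM; gs.betaH = betaH;
  gs.gamma = gamma; gs.tau = tau; gs.thMP = thMP; gs.thHP = thHP;
  gs.h = h; gs.eps = eps;
  return gs;
}

// [[Rcpp::export]]
arma::vec rhs_guilds_cpp(const arma::vec& P, const arma::vec& M, const arma::vec& H,
                         const arma::vec& rP, const arma::vec& rM, const arma::vec& rH,
                         const arma::mat& betaP, const arma::mat& betaM,
                         const arma::mat& betaH, const arma::mat& gamma,
                         const arma::mat& tau, const arma::mat& thMP,
                         const arma::mat& thHP, double h, double eps) {
  GuildSystem gs = make_system(rP, rM, rH, betaP, betaM, betaH,
                               gamma, tau, thMP, thHP, h, eps);
  arma::vec dP, dM, dH;
  guild_rhs(gs, P, M, H, dP, dM, dH);
  return arma::join_cols(dP, arma::join_cols(dM, dH));
}

// Dormand-Prince 5(4) tableau.
static const double c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9;
static const double a21 = 1.0/5;
static const double a31 = 3.0/40, a32 = 9.0/40;
static const double a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9;
static const double a51 = 19372.0/6561, a52 = -25360.0/2187,
                    a53 = 64448.0/6561, a54 = -212.0/729;
static const double a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
                    a64 = 49.0/176, a65 = -5103.0/18656;
static const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
                    b5 = -2187.0/6784, b6 = 11.0/84;
// 4th-order embedded weights
static const double e1 = 5179.0/57600, e3 = 7571.0/16695, e4 = 393.0/640,
                    e5 = -92097.0/339200, e6 = 187.0/2100, e7 = 1.0/40;

struct StepResult { bool ok; int nsteps; };

static void apply_floor(arma::vec& y, double floor_val) {
  for (arma::uword i = 0; i < y.n_elem; ++i)
    if (y[i] != 0.0 && y[i] < floor_val) y[i] = floor_val;
}

static arma::vec full_rhs(const GuildSystem& gs, const arma::vec& y,
                          int SP, int SM, int SH) {
  arma::vec P = y.subvec(0, SP - 1);
  arma::vec M = y.subvec(SP, SP + SM - 1);
  arma::vec H = y.subvec(SP + SM, SP + SM + SH - 1);
  arma::vec dP, dM, dH;
  guild_rhs(gs, P, M, H, dP, dM, dH);
  return arma::join_cols(dP, arma::join_cols(dM, dH));
}

// Integrate over [0, t_span]; adaptive steps, biomass floor after each
// accepted step (exact zeros are absorbing and never lifted).
static StepResult dp45_span(const GuildSystem& gs, arma::vec& y, double t_span,
                            int SP, int SM, int SH, double rtol, double atol,
                            double floor_val, int max_steps) {
  double t = 0.0;
  double hstep = t_span / 10.0;
  int nsteps = 0;
  arma::vec k1 = full_rhs(gs, y, SP, SM, SH);
  while (t < t_span) {
    if (nsteps++ > max_steps) return {false, nsteps};
    if (hstep > t_span - t) hstep = t_span - t;
    arma::vec k2 = full_rhs(gs, y + hstep * (a21 * k1), SP, SM, SH);
    arma::vec k3 = full_rhs(gs, y + hstep * (a31 * k1 + a32 * k2), SP, SM, SH);
    arma::vec k4 = full_rhs(gs, y + hstep * (a41 * k1 + a42 * k2 + a43 * k3), SP, SM, SH);
    arma::vec k5 = full_rhs(gs, y + hstep * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4), SP, SM, SH);
    arma::vec k6 = full_rhs(gs, y + hstep * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5), SP, SM, SH);
    arma::vec y5 = y + hstep * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    arma::vec k7 = full_rhs(gs, y5, SP, SM, SH); // FSAL
    arma::vec y4 = y + hstep * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);

    double err = 0.0;
    for (arma::uword i = 0; i < y.n_elem; ++i) {
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = std::fabs(y5[i] - y4[i]) / sc;
      if (e > err) err = e;
    }
    if (!std::isfinite(err)) return {false, nsteps};
    if (err <= 1.0) {
      t += hstep;
      y = y5;
      apply_floor(y, floor_val);
      k1 = full_rhs(gs, y, SP, SM, SH); // recompute: floor may have moved y
      double fac = (err == 0.0) ? 5.0 : 0.9 * std::pow(err, -0.2);
      hstep *= std::min(5.0, std::max(0.2, fac));
    } else {
      hstep *= std::max(0.2, 0.9 * std::pow(err, -0.2));
    }
  }
  return {true, nsteps};
}

// Relative-derivative equilibrium measure; species pinned at the floor with a
// negative derivative cannot move further down and are not counted.
static double eq_measure(const GuildSystem& gs, const arma::vec& y,
                         int SP, int SM, int SH, double floor_val) {
  arma::vec f = full_rhs(gs, y, SP, SM, SH);
  double worst = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    if (y[i] <= floor_val && f[i] < 0.0) continue;
    double m = std::fabs(f[i]) / (1.0 + std::fabs(y[i]));
    if (m > worst) worst = m;
  }
  return worst;
}

// Chunked integration until the equilibrium criterion is met or max_time is
// exhausted. Returns the final state, elapsed model time and convergence flag.
// [[Rcpp::export]]
List integrate_guilds_cpp(const arma::vec& y0, int SP, int SM, int SH,
                          const arma::vec& rP, const arma::vec& rM, const arma::vec& rH,
                          const arma::mat& betaP, const arma::mat& betaM,
                          const arma::mat& betaH, const arma::mat& gamma,
                          const arma::mat& tau, const arma::mat& thMP,
                          const arma::mat& thHP, double h, double eps,
                          double chunk, double max_time, double tol,
                          double rtol, double atol, double floor_val) {
  GuildSystem gs = make_system(rP, rM, rH, betaP, betaM, betaH,
                               gamma, tau, thMP, thHP, h, eps);
  arma::vec y = y0;
  apply_floor(y, floor_val);
  double t = 0.0;
  bool converged = false, failed = false;
  long total_steps = 0;
  while (t < max_time) {
    double span = std::min(chunk, max_time - t);
    StepResult sr = dp45_span(gs, y, span, SP, SM, SH, rtol, atol, floor_val, 100000);
    total_steps += sr.nsteps;
    if (!sr.ok) { failed = true; break; }
    t += span;
    if (eq_measure(gs, y, SP, SM, SH, floor_val) < tol) { converged = true; break; }
  }
  if (!converged && !failed)
    converged = eq_measure(gs, y, SP, SM, SH, floor_val) < tol;
  return List::create(_["y"] = y, _["t"] = t, _["converged"] = converged,
                      _["failed"] = failed, _["nsteps"] = total_steps,
                      _["eq_measure"] = eq_measure(gs, y, SP, SM, SH, floor_val));
}

// ---------------------------------------------------------------------------
// Barber bipartite modularity, Q = (1/m) sum_ij (A_ij - k_i d_j / m) for
// row i and column j in the same module. Optimized by BRIM-style alternation
// plus single-node moves and module merges; restarts use R's RNG so runs are
// reproducible via set.seed().

static double barber_Q(const arma::mat& B, const arma::ivec& lr,
                       const arma::ivec& lc, double m) {
  double q = 0.0;
  for (arma::uword j = 0; j < B.n_cols; ++j)
    for (arma::uword i = 0; i < B.n_rows; ++i)
      if (lr[i] == lc[j]) q += B(i, j);
  return q / m;
}

// [[Rcpp::export]]
List brim_modularity_cpp(const arma::mat& A, int n_restarts) {
  const int nr = A.n_rows, nc = A.n_cols;
  const double m = arma::accu(A);
  if (m <= 0) stop("incidence matrix has no links");
  arma::vec k = arma::sum(A, 1);   // row degrees
  arma::rowvec d = arma::sum(A, 0); // column degrees
  arma::mat B = A - (k * d) / m;
  const int K = nr + nc; // more labels than ever needed

  double best_q = -2.0;
  arma::ivec best_lr(nr), best_lc(nc);

  for (int rs = 0; rs < n_restarts; ++rs) {
    arma::ivec lr(nr), lc(nc);
    int c0 = std::max(1, std::min(nr, nc));
    for (int i = 0; i < nr; ++i) lr[i] = (int)std::floor(unif_rand() * c0);
    for (int j = 0; j < nc; ++j) lc[j] = (int)std::floor(unif_rand() * c0);

    // BRIM alternation: given row labels, each column independently takes the
    // module with the best summed B; a spare label gives contribution 0.
    for (int it = 0; it < 200; ++it) {
      bool changed = false;
      for (int j = 0; j < nc; ++j) {
        arma::vec score(K, arma::fill::zeros);
        for (int i = 0; i < nr; ++i) score[lr[i]] += B(i, j);
        int bestg = lc[j];
        double bests = score[bestg];
        for (int g = 0; g < K; ++g)
          if (score[g] > bests + 1e-14) { bests = score[g]; bestg = g; }
        if (bestg != lc[j]) { lc[j] = bestg; changed = true; }
      }
      for (int i = 0; i < nr; ++i) {
        arma::vec score(K, arma::fill::zeros);
        for (int j = 0; j < nc; ++j) score[lc[j]] += B(i, j);
        int bestg = lr[i];
        double bests = score[bestg];
        for (int g = 0; g < K; ++g)
          if (score[g] > bests + 1e-14) { bests = score[g]; bestg = g; }
        if (bestg != lr[i]) { lr[i] = bestg; changed = true; }
      }
      if (!changed) break;
    }

    // Merge phase: combining two modules can escape alternation optima.
    bool merged = true;
    while (merged) {
      merged = false;
      // gain of merging modules g1,g2 = sum of cross terms B_ij with
      // (row in g1, col in g2) or (row in g2, col in g1)
      arma::mat cross(K, K, arma::fill::zeros);
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j)
          cross(lr[i], lc[j]) += B(i, j);
      double bestgain = 1e-12;
      int bg1 = -1, bg2 = -1;
      for (int g1 = 0; g1 < K; ++g1)
        for (int g2 = g1 + 1; g2 < K; ++g2) {
          double gain = cross(g1, g2) + cross(g2, g1);
          if (gain > bestgain) { bestgain = gain; bg1 = g1; bg2 = g2; }
        }
      if (bg1 >= 0) {
        for (int i = 0; i < nr; ++i) if (lr[i] == bg2) lr[i] = bg1;
        for (int j = 0; j < nc; ++j) if (lc[j] == bg2) lc[j] = bg1;
        merged = true;
      }
    }

    // Kernighan-Lin escape: tentatively move the best node (row or column)
    // even at a loss, each node at most once per pass, then revert to the
    // best prefix; repeat while a pass improves Q.
    const int n_nodes = nr + nc;
    for (int pass = 0; pass < 50; ++pass) {
      arma::ivec lr0 = lr, lc0 = lc;
      double q0 = barber_Q(B, lr, lc, m);
      std::vector<bool> moved(n_nodes, false);
      std::vector<std::pair<int, int>> seq; // (node, new label)
      double run_q = q0, best_prefix_q = q0;
      int best_prefix = 0;
      for (int step = 0; step < n_nodes; ++step) {
        double best_dq = -1e30;
        int bnode = -1, blab = -1;
        for (int node = 0; node < n_nodes; ++node) {
          if (moved[node]) continue;
          bool is_row = node < nr;
          int cur = is_row ? lr[node] : lc[node - nr];
          arma::vec score(K, arma::fill::zeros);
          if (is_row)
            for (int j = 0; j < nc; ++j) score[lc[j]] += B(node, j);
          else
            for (int i = 0; i < nr; ++i) score[lr[i]] += B(i, node - nr);
          for (int g = 0; g < K; ++g) {
            if (g == cur) continue;
            double dq = (score[g] - score[cur]) / m;
            if (dq > best_dq) { best_dq = dq; bnode = node; blab = g; }
          }
        }
        if (bnode < 0) break;
        if (bnode < nr) lr[bnode] = blab; else lc[bnode - nr] = blab;
        moved[bnode] = true;
        seq.push_back({bnode, blab});
        run_q += best_dq;
        if (run_q > best_prefix_q + 1e-14) {
          best_prefix_q = run_q;
          best_prefix = (int)seq.size();
        }
      }
      // revert to the best prefix
      lr = lr0; lc = lc0;
      for (int s = 0; s < best_prefix; ++s) {
        int node = seq[s].first, lab = seq[s].second;
        if (node < nr) lr[node] = lab; else lc[node - nr] = lab;
      }
      if (best_prefix_q <= q0 + 1e-14) break;
    }
    double q = barber_Q(B, lr, lc, m);
    if (q > best_q) { best_q = q; best_lr = lr; best_lc = lc; }
  }

  // compact labels to 1..n_modules
  std::map<int, int> relab;
  int nxt = 1;
  IntegerVector out_lr(nr), out_lc(nc);
  for (int i = 0; i < nr; ++i) {
    if (!relab.count(best_lr[i])) relab[best_lr[i]] = nxt++;
    out_lr[i] = relab[best_lr[i]];
  }
  for (int j = 0; j < nc; ++j) {
    if (!relab.count(best_lc[j])) relab[best_lc[j]] = nxt++;
    out_lc[j] = relab[best_lc[j]];
  }
  return List::create(_["Q"] = best_q, _["row_modules"] = out_lr,
                      _["col_modules"] = out_lc);
}
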