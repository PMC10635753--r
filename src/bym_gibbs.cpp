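#include <Rcpp.h>
using namespace Rcpp;

// Besag-York-Mollie Metropolis-within-Gibbs core.
//
// Model: O_i ~ Poisson(E_i * exp(alpha + u_i + v_i))
//   u | tau_u ~ intrinsic CAR (pairwise-difference kernel, binary weights),
//   v_i | tau_v ~ N(0, 1/tau_v), alpha flat,
//   tau_u, tau_v ~ Gamma(shape, rate) (conjugate full conditionals).
// alpha, u_i, v_i move by univariate random-walk Metropolis (the Poisson
// likelihood is non-conjugate); u is recentered to sum-to-zero each sweep
// with alpha absorbing the mean. Adjacency is passed flattened (CSR-style)
// as 0-based indices. All randomness comes from R's RNG, so results are
// bit-reproducible under set.seed().
//
// Island areas (degree 0) are only legal when the caller has substituted a
// proper N(0, 1/tau_u) prior for their structured effect; this is encoded
// by deg_prior_i = 1 with an empty neighbour slice.

static double icar_quadform(const NumericVector& u,
                            const IntegerVector& adj,
                            const IntegerVector& adj_start,
                            const LogicalVector& island) {
  double q = 0.0;
  int n = u.size();
  for (int i = 0; i < n; ++i) {
    if (island[i]) {            // proper-prior fallback for isolated areas
      q += u[i] * u[i];
      continue;
    }
    for (int k = adj_start[i]; k < adj_start[i + 1]; ++k) {
      int j = adj[k];
      if (j > i) {
        double d = u[i] - u[j];
        q += d * d;
      }
    }
  }
  return q;
}

// [[Rcpp::export]]
double draw_tau_v_cpp(NumericVector v, double shape, double rate) {
  double ss = 0.0;
  for (int i = 0; i < v.size(); ++i) ss += v[i] * v[i];
  return R::rgamma(shape + v.size() / 2.0, 1.0 / (rate + ss / 2.0));
}

// [[Rcpp::export]]
double draw_tau_u_cpp(NumericVector u, IntegerVector adj,
                      IntegerVector adj_start, LogicalVector island,
                      double shape, double rate, int rank) {
  double q = icar_quadform(u, adj, adj_start, island);
  return R::rgamma(shape + rank / 2.0, 1.0 / (rate + q / 2.0));
}

// [[Rcpp::export]]
List bym_run_cpp(NumericVector O, NumericVector E,
                 IntegerVector adj, IntegerVector adj_start,
                 NumericVector deg_prior, LogicalVector island,
                 int n_iter, int n_burn, int thin, int n_keep,
                 double a_u, double b_u, double a_v, double b_v,
                 bool fix_tau, int icar_rank,
                 double alpha0, NumericVector u0, NumericVector v0,
                 double tau_u0, double tau_v0,
                 NumericVector step0_u, NumericVector step0_v,
                 double step0_alpha, bool adapt) {
  int n = O.size();
  double alpha = alpha0;
  NumericVector u = clone(u0), v = clone(v0);
  double tau_u = tau_u0, tau_v = tau_v0;
  NumericVector s_u = clone(step0_u), s_v = clone(step0_v);
  double s_alpha = step0_alpha;

  NumericMatrix theta_keep(n_keep, n);
  NumericVector alpha_keep(n_keep), tau_u_keep(n_keep), tau_v_keep(n_keep);

  // acceptance bookkeeping: [0] adaptation window, [1] post-burn-in totals
  NumericVector acc_u(n), acc_v(n);
  double acc_alpha = 0.0;
  double post_acc_u = 0.0, post_acc_v = 0.0, post_acc_alpha = 0.0;
  int adapt_window = 100;
  int kept = 0;
  long post_sweeps = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- structured effects u_i ---
    for (int i = 0; i < n; ++i) {
      double s1 = 0.0;
      for (int k = adj_start[i]; k < adj_start[i + 1]; ++k) s1 += u[adj[k]];
      double cur = u[i];
      double prop = cur + s_u[i] * norm_rand();
      double lr = O[i] * (prop - cur)
        - E[i] * (std::exp(alpha + prop + v[i]) - std::exp(alpha + cur + v[i]))
        - 0.5 * tau_u * (deg_prior[i] * (prop * prop - cur * cur)
                         - 2.0 * s1 * (prop - cur));
      if (std::log(unif_rand()) < lr) {
        u[i] = prop;
        acc_u[i] += 1.0;
        if (iter > n_burn) post_acc_u += 1.0;
      }
    }
    // recenter: alpha absorbs the mean (ICAR identifiability constraint)
    double um = mean(u);
    for (int i = 0; i < n; ++i) u[i] -= um;
    alpha += um;

    // --- unstructured effects v_i ---
    for (int i = 0; i < n; ++i) {
      double cur = v[i];
      double prop = cur + s_v[i] * norm_rand();
      double lr = O[i] * (prop - cur)
        - E[i] * (std::exp(alpha + u[i] + prop) - std::exp(alpha + u[i] + cur))
        - 0.5 * tau_v * (prop * prop - cur * cur);
      if (std::log(unif_rand()) < lr) {
        v[i] = prop;
        acc_v[i] += 1.0;
        if (iter > n_burn) post_acc_v += 1.0;
      }
    }

    // --- intercept alpha (flat prior) ---
    {
      double prop = alpha + s_alpha * norm_rand();
      double sumO = 0.0, d = 0.0;
      for (int i = 0; i < n; ++i) {
        sumO += O[i];
        d += E[i] * (std::exp(prop + u[i] + v[i])
                     - std::exp(alpha + u[i] + v[i]));
      }
      double lr = sumO * (prop - alpha) - d;
      if (std::log(unif_rand()) < lr) {
        alpha = prop;
        acc_alpha += 1.0;
        if (iter > n_burn) post_acc_alpha += 1.0;
      }
    }

    // --- reallocation pass: exact Gibbs on u_i holding eta_i = u_i + v_i
    //     fixed. The likelihood depends on (u_i + v_i) only, so the split
    //     between structured and unstructured effect has a Gaussian full
    //     conditional; redrawing it directly is what lets tau_u and tau_v
    //     mix (single-site random walks move this direction very slowly).
    for (int i = 0; i < n; ++i) {
      double s1 = 0.0;
      for (int k = adj_start[i]; k < adj_start[i + 1]; ++k) s1 += u[adj[k]];
      double eta = u[i] + v[i];
      double prec = tau_u * deg_prior[i] + tau_v;
      double mu = (tau_u * s1 + tau_v * eta) / prec;
      u[i] = mu + norm_rand() / std::sqrt(prec);
      v[i] = eta - u[i];
    }
    um = mean(u);
    for (int i = 0; i < n; ++i) u[i] -= um;
    alpha += um;   // eta = alpha + u + v is untouched by the recentering

    // --- precisions (conjugate Gamma full conditionals) ---
    if (!fix_tau) {
      tau_u = draw_tau_u_cpp(u, adj, adj_start, island, a_u, b_u, icar_rank);
      tau_v = draw_tau_v_cpp(v, a_v, b_v);
    }

    // --- step-size adaptation, burn-in only (frozen afterwards so the
    //     post-burn-in kernel satisfies detailed balance) ---
    if (adapt && iter <= n_burn && iter % adapt_window == 0) {
      for (int i = 0; i < n; ++i) {
        s_u[i] *= std::exp((acc_u[i] / adapt_window) - 0.4);
        s_v[i] *= std::exp((acc_v[i] / adapt_window) - 0.4);
        s_u[i] = std::min(std::max(s_u[i], 1e-3), 10.0);
        s_v[i] = std::min(std::max(s_v[i], 1e-3), 10.0);
        acc_u[i] = 0.0;
        acc_v[i] = 0.0;
      }
      s_alpha *= std::exp((acc_alpha / adapt_window) - 0.4);
      s_alpha = std::min(std::max(s_alpha, 1e-4), 10.0);
      acc_alpha = 0.0;
    }

    if (iter > n_burn) {
      ++post_sweeps;
      if ((iter - n_burn) % thin == 0 && kept < n_keep) {
        for (int i = 0; i < n; ++i) {
          theta_keep(kept, i) = std::exp(alpha + u[i] + v[i]);
        }
        alpha_keep[kept] = alpha;
        tau_u_keep[kept] = tau_u;
        tau_v_keep[kept] = tau_v;
        ++kept;
      }
    }
  }

  double denom = post_sweeps > 0 ? (double)post_sweeps : 1.0;
  return List::create(
    _["theta"] = theta_keep,
    _["alpha"] = alpha_keep,
    _["tau_u"] = tau_u_keep,
    _["tau_v"] = tau_v_keep,
    _["n_kept"] = kept,
    _["final_state"] = List::create(
      _["alpha"] = alpha, _["u"] = u, _["v"] = v,
      _["tau_u"] = tau_u, _["tau_v"] = tau_v),
    _["step_sizes"] = List::create(
      _["alpha"] = s_alpha, _["u"] = s_u, _["v"] = s_v),
    _["acceptance"] = List::create(
      _["alpha"] = post_acc_alpha / denom,
      _["u"] = post_acc_u / (denom * n),
      _["v"] = post_acc_v / (denom * n))
  );
}
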