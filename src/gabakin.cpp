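// Compiled kernels: CTMC sampling, dead-time imposition, and the
// missed-event (HJC) survivor tables and likelihood inner loop.
// All matrices are in the package's state order; rates in 1/ms, times in ms.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Exact continuous-time Markov chain sampling from generator Q (row sums 0).
// Sojourns are exponential with rate -Q[i,i]; successors drawn from Q[i,j]/-Q[i,i].
// Uses R's RNG so set.seed() in R governs reproducibility.
// Stops after max_transitions sojourns or when total time exceeds max_time
// (the final sojourn is then truncated at max_time).
// [[Rcpp::export]]
List ctmc_sample_cpp(const arma::mat& Q, int start, int max_transitions,
                     double max_time) {
  const int k = Q.n_rows;
  std::vector<int> states;
  std::vector<double> durs;
  states.reserve(max_transitions > 0 ? max_transitions : 1024);
  durs.reserve(max_transitions > 0 ? max_transitions : 1024);
  int s = start - 1;  // 1-based from R
  double total = 0.0;
  bool truncated = false;
  const bool has_tmax = R_finite(max_time);
  int n = 0;
  while (true) {
    if (max_transitions > 0 && n >= max_transitions) break;
    double rate = -Q(s, s);
    if (rate <= 0.0) {  // absorbing state
      if (has_tmax && total < max_time) {
        states.push_back(s + 1);
        durs.push_back(max_time - total);
      }
      truncated = true;
      break;
    }
    double dt = ::exp_rand() / rate;
    if (has_tmax && total + dt >= max_time) {
      states.push_back(s + 1);
      durs.push_back(max_time - total);
      break;
    }
    states.push_back(s + 1);
    durs.push_back(dt);
    total += dt;
    ++n;
    // successor
    double u = ::unif_rand() * rate, acc = 0.0;
    int nxt = -1;
    for (int j = 0; j < k; ++j) {
      if (j == s) continue;
      acc += Q(s, j);
      if (u <= acc) { nxt = j; break; }
    }
    if (nxt < 0) {  // numerical guard: pick the largest off-diagonal
      double best = -1.0;
      for (int j = 0; j < k; ++j)
        if (j != s && Q(s, j) > best) { best = Q(s, j); nxt = j; }
    }
    s = nxt;
  }
  return List::create(_["state"] = wrap(states), _["duration"] = wrap(durs),
                      _["truncated"] = truncated);
}

// Monte-Carlo state occupancancy at probe times: n_traj independent chains
// started from p0, counted at each probe time. Returns (n_probe x k) counts.
// [[Rcpp::export]]
arma::imat ctmc_occupancy_cpp(const arma::mat& Q, const arma::vec& p0,
                              const arma::vec& probe_times, int n_traj) {
  const int k = Q.n_rows, np = probe_times.n_elem;
  arma::imat counts(np, k, arma::fill::zeros);
  const double tmax = probe_times.max();
  for (int tr = 0; tr < n_traj; ++tr) {
    // initial state from p0
    double u = ::unif_rand(), acc = 0.0;
    int s = k - 1;
    for (int j = 0; j < k; ++j) { acc += p0(j); if (u <= acc) { s = j; break; } }
    double t = 0.0;
    int ip = 0;
    while (ip < np) {
      double rate = -Q(s, s);
      double dt = (rate > 0.0) ? ::exp_rand() / rate : R_PosInf;
      double t_next = t + dt;
      while (ip < np && probe_times(ip) <= t_next) { counts(ip, s) += 1; ++ip; }
      if (t_next > tmax) break;
      t = t_next;
      double v = ::unif_rand() * rate, a2 = 0.0;
      int nxt = s;
      for (int j = 0; j < k; ++j) {
        if (j == s) continue;
        a2 += Q(s, j);
        if (v <= a2) { nxt = j; break; }
      }
      s = nxt;
    }
  }
  return counts;
}

// Dead-time (resolution) imposition, forward-concatenation convention:
// the record opens at the first event with duration >= tau; any later event
// shorter than tau is unresolvable and is absorbed -- together with its
// successor, which has the same class as the current resolved event -- into
// that resolved event. Durations are conserved from the first resolved event.
// [[Rcpp::export]]
List impose_resolution_cpp(const IntegerVector& cls, const NumericVector& dur,
                           double tau) {
  const int n = cls.size();
  std::vector<int> out_cls;
  std::vector<double> out_dur;
  int i = 0;
  while (i < n && dur[i] < tau) ++i;  // first resolved event opens the record
  if (i == n)
    return List::create(_["class"] = IntegerVector(0),
                        _["duration"] = NumericVector(0));
  int cur_cls = cls[i];
  double cur_dur = dur[i];
  for (++i; i < n; ++i) {
    if (dur[i] < tau) {
      cur_dur += dur[i];            // unresolved: absorbed into current event
    } else if (cls[i] == cur_cls) {
      cur_dur += dur[i];            // same class (follows an absorbed event)
    } else {
      out_cls.push_back(cur_cls);
      out_dur.push_back(cur_dur);
      cur_cls = cls[i];
      cur_dur = dur[i];
    }
  }
  out_cls.push_back(cur_cls);
  out_dur.push_back(cur_dur);
  return List::create(_["class"] = wrap(out_cls), _["duration"] = wrap(out_dur));
}

// ---- HJC missed-event machinery -------------------------------------------
// Survivor matrix R(u) for e-periods of the "stay" class (generator block
// Qaa), with excursions into the other class shorter than tau allowed.
// R(u) solves the delay integro-differential system obtained from its
// Laplace transform [sI - Qaa - Qaf * S_ff(s) * Qfa]^{-1}:
//   R'(u)   = R(u) Qaa + sum_j J_j(u) B_j
//   J_j'(u) = R(u) + mu_j J_j(u)                           (u <  tau)
//   J_j'(u) = R(u) - exp(mu_j tau) R(u - tau) + mu_j J_j(u) (u >= tau)
// where Qaf e^{Qff w} Qfa = sum_j e^{mu_j w} B_j is the spectral expansion of
// the return kernel. Integrated by RK4 on a uniform grid with cubic-Hermite
// interpolation of the stored solution for the delayed term.
// Returns R and R' on u = 0, h, ..., n_tau*tau with h = tau/m.
// [[Rcpp::export]]
List hjc_exact_tables_cpp(const arma::mat& Qaa, const arma::cube& B,
                          const arma::vec& mu, double tau, int m, int n_tau) {
  const int k = Qaa.n_rows, nj = mu.n_elem, N = n_tau * m;
  const double h = tau / m;
  arma::cube Rg(k, k, N + 1), Rd(k, k, N + 1);
  arma::cube J(k, k, nj, arma::fill::zeros);
  arma::mat R = arma::eye(k, k);

  // delayed value R(u - tau) for u = (i + theta) * h + tau, theta in [0, 1]
  auto delayed = [&](int p, double theta) -> arma::mat {
    if (theta <= 0.0) return Rg.slice(p);
    if (theta >= 1.0) return Rg.slice(p + 1);
    const double t2 = theta * theta, t3 = t2 * theta;
    return (2 * t3 - 3 * t2 + 1) * Rg.slice(p) + (t3 - 2 * t2 + theta) * h * Rd.slice(p) +
           (-2 * t3 + 3 * t2) * Rg.slice(p + 1) + (t3 - t2) * h * Rd.slice(p + 1);
  };

  arma::vec emt(nj);
  for (int j = 0; j < nj; ++j) emt(j) = std::exp(mu(j) * tau);

  // state derivative at absolute grid position i + theta (u = (i+theta)h)
  auto deriv = [&](int i, double theta, const arma::mat& Rv, const arma::cube& Jv,
                   arma::mat& dR, arma::cube& dJ) {
    dR = Rv * Qaa;
    for (int j = 0; j < nj; ++j) dR += Jv.slice(j) * B.slice(j);
    // the delay branch applies on whole steps [i*h, (i+1)*h] with i >= m:
    // J' has a kink at u = tau, and the stage at the left step's endpoint
    // must use the left-sided (no-delay) derivative or the quadrature
    // order collapses at the kink
    const bool past = (i >= m);
    arma::mat Rdel;
    if (past) Rdel = delayed(i - m, theta);
    for (int j = 0; j < nj; ++j) {
      dJ.slice(j) = Rv + mu(j) * Jv.slice(j);
      if (past) dJ.slice(j) -= emt(j) * Rdel;
    }
  };

  arma::mat k1R(k, k), k2R(k, k), k3R(k, k), k4R(k, k);
  arma::cube k1J(k, k, nj), k2J(k, k, nj), k3J(k, k, nj), k4J(k, k, nj);
  for (int i = 0; i <= N; ++i) {
    deriv(i, 0.0, R, J, k1R, k1J);
    Rg.slice(i) = R;
    Rd.slice(i) = k1R;
    if (i == N) break;
    arma::mat R2 = R + 0.5 * h * k1R;
    arma::cube J2 = J + 0.5 * h * k1J;
    deriv(i, 0.5, R2, J2, k2R, k2J);
    arma::mat R3 = R + 0.5 * h * k2R;
    arma::cube J3 = J + 0.5 * h * k2J;
    deriv(i, 0.5, R3, J3, k3R, k3J);
    arma::mat R4 = R + h * k3R;
    arma::cube J4 = J + h * k3J;
    deriv(i, 1.0, R4, J4, k4R, k4J);
    R += (h / 6.0) * (k1R + 2 * k2R + 2 * k3R + k4R);
    J += (h / 6.0) * (k1J + 2 * k2J + 2 * k3J + k4J);
  }
  return List::create(_["R"] = Rg, _["Rdot"] = Rd, _["h"] = h);
}

// Evaluate R(u) from the precomputed representation: exact Hermite-interpolated
// table over its span, asymptotic sum_i exp(s_i u) C_i beyond (and everywhere
// when tau = 0, where the table is empty and the asymptotic form is exact).
static inline arma::mat survivor_at(double u, double tau, const arma::cube& Rg,
                                    const arma::cube& Rd, double h,
                                    const arma::cube& C, const arma::vec& s) {
  const int k = C.n_rows;
  const double span = tau > 0.0 ? (Rg.n_slices - 1) * h : 0.0;
  if (tau > 0.0 && u < span - 1e-12) {
    double x = u / h;
    int p = (int)std::floor(x);
    const int N = Rg.n_slices - 1;
    if (p >= N) p = N - 1;
    double theta = x - p;
    if (theta <= 1e-12) return Rg.slice(p);
    const double t2 = theta * theta, t3 = t2 * theta;
    return (2 * t3 - 3 * t2 + 1) * Rg.slice(p) + (t3 - 2 * t2 + theta) * h * Rd.slice(p) +
           (-2 * t3 + 3 * t2) * Rg.slice(p + 1) + (t3 - t2) * h * Rd.slice(p + 1);
  }
  arma::mat out(k, k, arma::fill::zeros);
  for (arma::uword i = 0; i < s.n_elem; ++i) out += std::exp(s(i) * u) * C.slice(i);
  return out;
}

// Forward log-likelihood over alternating apparent dwell sequences.
// cls: 1 = open, 0 = shut per event; events grouped by cluster via
// cluster_start (1-based indices of each cluster's first event, ascending).
// eG_open(t) = Ropen(t - tau) * Mo,  eG_shut(t) = Rshut(t - tau) * Ms,
// with Mo = Qaf expm(Qff tau), Ms = Qfa expm(Qaa tau). Log-domain scaling.
// [[Rcpp::export]]
double hjc_loglik_cpp(const IntegerVector& cls, const NumericVector& dur,
                      const IntegerVector& cluster_start, double tau,
                      const arma::cube& Rgo, const arma::cube& Rdo, double ho,
                      const arma::cube& Co, const arma::vec& so,
                      const arma::cube& Rgs, const arma::cube& Rds, double hs,
                      const arma::cube& Cs, const arma::vec& ss,
                      const arma::mat& Mo, const arma::mat& Ms,
                      const arma::rowvec& phiA, const arma::rowvec& phiF) {
  const int n = cls.size(), ncl = cluster_start.size();
  double ll = 0.0;
  for (int c = 0; c < ncl; ++c) {
    const int from = cluster_start[c] - 1;
    const int to = (c + 1 < ncl) ? cluster_start[c + 1] - 1 : n;
    arma::rowvec v = (cls[from] == 1) ? phiA : phiF;
    for (int i = from; i < to; ++i) {
      double u = dur[i] - tau;
      if (u < 0.0) u = 0.0;
      arma::mat G;
      if (cls[i] == 1)
        G = survivor_at(u, tau, Rgo, Rdo, ho, Co, so) * Mo;
      else
        G = survivor_at(u, tau, Rgs, Rds, hs, Cs, ss) * Ms;
      v = v * G;
      double sc = arma::accu(v);
      if (!(sc > 0.0) || !std::isfinite(sc)) return R_NegInf;
      ll += std::log(sc);
      v /= sc;
    }
  }
  return ll;
}

// Determinant of W(s) = sI - Qaa - Qaf * S_ff(s) * Qfa on a grid of s values,
// using the spectral expansion of Qff: Paf = Qaf*V, Pfa = V^{-1}*Qfa, mu the
// eigenvalues, so S_ff(s) collapses to a diagonal of scalar integrals
// phi_j(s) = (1 - exp(-(s - mu_j) tau)) / (s - mu_j). Asymptotic roots of the
// missed-event densities are the zeros of this determinant.
// [[Rcpp::export]]
arma::vec hjc_detw_cpp(const arma::vec& svals, const arma::mat& Qaa,
                       const arma::mat& Paf, const arma::mat& Pfa,
                       const arma::vec& mu, double tau) {
  const int ka = Qaa.n_rows, nf = mu.n_elem, ns = svals.n_elem;
  arma::vec out(ns);
  arma::mat eye_a = arma::eye(ka, ka);
  for (int i = 0; i < ns; ++i) {
    const double s = svals(i);
    arma::vec phi(nf);
    for (int j = 0; j < nf; ++j) {
      double x = s - mu(j);
      phi(j) = (std::abs(x) < 1e-10) ? tau * (1.0 - 0.5 * x * tau)
                                     : (1.0 - std::exp(-x * tau)) / x;
    }
    arma::mat W = s * eye_a - Qaa - Paf * arma::diagmat(phi) * Pfa;
    out(i) = arma::det(W);
  }
  return out;
}
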