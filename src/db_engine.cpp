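#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Payoff to the focal (row) player with flag f1 / phase p1 meeting f2 / p2.
// Flags: 1 = communicative, 0 = non-communicative. cost1 is the focal node's
// own cost (per-node in degree-adjusted mode). Mirrors the R pair_payoff().
static inline double pair_payoff(int f1, int p1, int f2, int p2,
                                 double B0, double beta0, int d,
                                 double cost1) {
  int k = p1 - p2;
  if (k < 0) k = -k;
  if (d - k < k) k = d - k;
  double mult = 1.0 - static_cast<double>(k) / d;
  if (f1 == 1) return -cost1 + (f2 == 1 ? B0 : beta0) * mult;
  return f2 == 1 ? beta0 * mult : 0.0;
}

static double node_payoff(int i, const std::vector<std::vector<int> > &adj,
                          const std::vector<int> &flags,
                          const std::vector<int> &phases,
                          double B0, double beta0, int d,
                          const NumericVector &cost, bool mean_agg) {
  const std::vector<int> &nb = adj[i];
  if (nb.empty()) return 0.0;
  double s = 0.0;
  for (size_t a = 0; a < nb.size(); ++a) {
    int j = nb[a];
    s += pair_payoff(flags[i], phases[i], flags[j], phases[j],
                     B0, beta0, d, cost[i]);
  }
  if (mean_agg) s /= nb.size();
  return s;
}

static std::vector<std::vector<int> > convert_adj(const List &adj_r) {
  int n = adj_r.size();
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj_r[i];
    adj[i].reserve(nb.size());
    for (int a = 0; a < nb.size(); ++a) adj[i].push_back(nb[a] - 1);
  }
  return adj;
}

// Expected payoff of every node in the current configuration; used to pin
// the compiled payoff computation to the R reference in tests.
// [[Rcpp::export]]
NumericVector node_payoffs_cpp(List adj_r, IntegerVector flags_r,
                               IntegerVector phases_r, double B0,
                               double beta0, int d, NumericVector cost,
                               bool mean_agg) {
  std::vector<std::vector<int> > adj = convert_adj(adj_r);
  int n = adj.size();
  std::vector<int> flags(flags_r.begin(), flags_r.end());
  std::vector<int> phases(phases_r.begin(), phases_r.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = node_payoff(i, adj, flags, phases, B0, beta0, d, cost, mean_agg);
  }
  return out;
}

// Death-birth loop. Each iteration: uniform death; replacement strategy drawn
// from the neighbors' fitness profile, exp(delta * pi) normalized in the log
// domain; a node without neighbors keeps its strategy. Stops once the
// communicative count hits 0 or n (absorbing). Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List run_death_birth_cpp(List adj_r, IntegerVector flags_r,
                         IntegerVector phases_r, double B0, double beta0,
                         int d, double delta, NumericVector cost,
                         bool mean_agg, int max_iter) {
  std::vector<std::vector<int> > adj = convert_adj(adj_r);
  int n = adj.size();
  std::vector<int> flags(flags_r.begin(), flags_r.end());
  std::vector<int> phases(phases_r.begin(), phases_r.end());
  int countC = 0;
  for (int i = 0; i < n; ++i) countC += flags[i];

  std::vector<double> traj;
  traj.reserve(max_iter < 100000 ? max_iter : 100000);
  std::vector<double> w;
  bool absorbed = (countC == 0 || countC == n);
  int absorption_time = absorbed ? 0 : NA_INTEGER;
  int iters = 0;

  for (int it = 1; it <= max_iter && !absorbed; ++it) {
    int i = static_cast<int>(unif_rand() * n);
    if (i == n) i = n - 1;
    const std::vector<int> &nb = adj[i];
    if (!nb.empty()) {
      w.resize(nb.size());
      double mx = R_NegInf;
      for (size_t a = 0; a < nb.size(); ++a) {
        double pi = node_payoff(nb[a], adj, flags, phases, B0, beta0, d,
                                cost, mean_agg);
        w[a] = delta * pi;
        if (w[a] > mx) mx = w[a];
      }
      double tot = 0.0;
      for (size_t a = 0; a < nb.size(); ++a) {
        w[a] = std::exp(w[a] - mx);
        tot += w[a];
      }
      double u = unif_rand() * tot;
      size_t pick = nb.size() - 1;
      double acc = 0.0;
      for (size_t a = 0; a < nb.size(); ++a) {
        acc += w[a];
        if (u <= acc) { pick = a; break; }
      }
      int j = nb[pick];
      countC += flags[j] - flags[i];
      flags[i] = flags[j];
      phases[i] = phases[j];
    }
    traj.push_back(static_cast<double>(countC) / n);
    iters = it;
    if (countC == 0 || countC == n) {
      absorbed = true;
      absorption_time = it;
    }
  }

  return List::create(
      Named("flags") = IntegerVector(flags.begin(), flags.end()),
      Named("phases") = IntegerVector(phases.begin(), phases.end()),
      Named("trajectory") = NumericVector(traj.begin(), traj.end()),
      Named("iterations") = iters,
      Named("absorbed") = absorbed,
      Named("absorption_time") = absorption_time);
}
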