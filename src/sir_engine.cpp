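#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Discrete-time stochastic SIR on a weighted graph.
//
// Model: per step, every node infected at the start of the step attempts to
// infect each susceptible neighbour j independently with probability
// beta * w_ij; nodes infected *before* the step then recover with
// probability gamma (a node cannot recover in the step it was infected).
// A node infected at step t therefore attempts at steps t+1, ..., t+G,
// where G ~ Geometric(gamma) (>= 1) is its infectious period.
//
// Implementation: event-driven. Because per-link attempts are independent
// Bernoulli trials, the step of the first success from i to j is
// t_i + H_ij with H_ij ~ Geometric(beta * w_ij), valid while i is still
// infectious (H_ij <= G_i) and within the horizon T. Infection times are
// then shortest "first-success" times, computed Dijkstra-style. This is
// algebraically identical to simulating every step (the first success of a
// Bernoulli(p) sequence is Geometric(p)) but costs O(E log n) per
// realization instead of O(T E).
//
// Draws come from R's RNG (RNGScope), so set.seed() on the R side makes the
// whole simulation reproducible.

static inline double rgeom1(double p) {
  // first-success index (>= 1) of a Bernoulli(p) sequence
  if (p >= 1.0) return 1.0;
  if (p <= 0.0) return std::numeric_limits<double>::infinity();
  return std::ceil(std::log1p(-unif_rand()) / std::log1p(-p));
}

// [[Rcpp::export]]
List sir_engine(const NumericMatrix& W, const IntegerVector& seed0,
                double beta, double gamma, int T, int NR) {
  const int n = W.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  RNGScope scope;

  // adjacency lists (only positive weights)
  std::vector<std::vector<int> > nbr(n);
  std::vector<std::vector<double> > wt(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i != j && W(i, j) > 0.0) {
        nbr[i].push_back(j);
        wt[i].push_back(W(i, j));
      }
    }
  }

  std::vector<int> inf_count(n, 0);     // realizations in which node got infected
  std::vector<double> t_sum(n, 0.0);    // sum of first-infection steps
  NumericVector sizes(NR);              // fraction ever infected, per realization
  int n_truncated = 0;

  typedef std::pair<double, int> Ev;    // (infection time, node)
  std::vector<double> tinf(n);
  std::vector<double> inf_end(n);       // last step at which node attempts
  std::vector<char> done(n);

  for (int r = 0; r < NR; ++r) {
    std::fill(tinf.begin(), tinf.end(), INF);
    std::fill(inf_end.begin(), inf_end.end(), -1.0);
    std::fill(done.begin(), done.end(), 0);
    std::priority_queue<Ev, std::vector<Ev>, std::greater<Ev> > heap;
    for (int k = 0; k < seed0.size(); ++k) {
      tinf[seed0[k]] = 0.0;
      heap.push(Ev(0.0, seed0[k]));
    }

    while (!heap.empty()) {
      Ev ev = heap.top(); heap.pop();
      const int i = ev.second;
      if (done[i] || ev.first > tinf[i]) continue;   // stale entry
      done[i] = 1;
      const double t = tinf[i];
      const double G = (gamma <= 0.0) ? INF : rgeom1(gamma);
      inf_end[i] = std::min((double) T, t + G);      // attempt horizon
      if (beta <= 0.0) continue;
      const std::vector<int>& nb = nbr[i];
      const std::vector<double>& ww = wt[i];
      for (size_t b = 0; b < nb.size(); ++b) {
        const int j = nb[b];
        if (done[j]) continue;
        const double H = rgeom1(beta * ww[b]);
        const double tj = t + H;
        if (tj <= inf_end[i] && tj < tinf[j]) {
          tinf[j] = tj;
          heap.push(Ev(tj, j));
        }
      }
    }

    // truncated: at step T some node is still infectious next to a
    // never-infected neighbour it could eventually have infected
    if (beta > 0.0) {
      bool trunc = false;
      for (int i = 0; i < n && !trunc; ++i) {
        if (tinf[i] < INF && inf_end[i] >= (double) T) {
          const std::vector<int>& nb = nbr[i];
          for (size_t b = 0; b < nb.size(); ++b) {
            if (tinf[nb[b]] == INF) { trunc = true; break; }
          }
        }
      }
      if (trunc) ++n_truncated;
    }

    int n_inf = 0;
    for (int i = 0; i < n; ++i) {
      if (tinf[i] < INF) {
        ++n_inf;
        ++inf_count[i];
        t_sum[i] += tinf[i];
      }
    }
    sizes[r] = (double) n_inf / n;
  }

  NumericVector p_infected(n), mean_activation(n);
  for (int i = 0; i < n; ++i) {
    p_infected[i] = (double) inf_count[i] / NR;
    mean_activation[i] = inf_count[i] > 0 ? t_sum[i] / inf_count[i]
                                          : NA_REAL;
  }

  return List::create(
    _["p_infected"] = p_infected,
    _["mean_activation"] = mean_activation,
    _["sizes"] = sizes,
    _["truncated_fraction"] = (double) n_truncated / NR);
}
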