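// Structured-coalescent and mutation-overlay core.
// Uses R's RNG throughout (RNGScope via Rcpp attributes), so set.seed()
// on the R side makes every simulation reproducible.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Event {
  double time;
  int kind;   // 0 = size break (passive), 1 = merge child -> parent
  int child;
  int parent;
};

inline bool ev_lt(const Event& a, const Event& b) { return a.time < b.time; }

// piecewise-constant population size: last break with start <= t
inline double pop_size_at(const NumericMatrix& breaks, double t) {
  double n = breaks(0, 1);
  for (int i = 1; i < breaks.nrow(); ++i) {
    if (breaks(i, 0) <= t) n = breaks(i, 1); else break;
  }
  return n;
}

} // namespace

// Simulate one gene genealogy under the structured coalescent with
// population merges and piecewise-constant sizes.
//
// sample_pops: 0-based population index per tip (length n)
// size_breaks: list (length npop) of matrices [start_time, N], start ascending,
//              first row at time 0
// merge_time/merge_child/merge_parent: merge events (backward in time, all
//              lineages of child move to parent at merge_time)
// ploidy_c:    pair-coalescence rate is 1/(ploidy_c * N)
//
// Returns parent (0-based, -1 at root) and node ages in generations.
// Tips are nodes 0..n-1; internal nodes are appended in coalescence order,
// so parent index > child index always holds.
// [[Rcpp::export]]
List sim_genealogy_cpp(IntegerVector sample_pops, List size_breaks,
                       NumericVector merge_time, IntegerVector merge_child,
                       IntegerVector merge_parent, double ploidy_c) {
  const int n = sample_pops.size();
  const int npop = size_breaks.size();
  if (n < 1) stop("need at least one sampled copy");
  const int nnode = 2 * n - 1;

  std::vector<Event> ev;
  for (int i = 0; i < merge_time.size(); ++i) {
    Event e; e.time = merge_time[i]; e.kind = 1;
    e.child = merge_child[i]; e.parent = merge_parent[i];
    ev.push_back(e);
  }
  for (int p = 0; p < npop; ++p) {
    NumericMatrix b = size_breaks[p];
    for (int i = 1; i < b.nrow(); ++i) {
      Event e; e.time = b(i, 0); e.kind = 0; e.child = p; e.parent = p;
      ev.push_back(e);
    }
  }
  std::sort(ev.begin(), ev.end(), ev_lt);

  std::vector<NumericMatrix> breaks(npop);
  for (int p = 0; p < npop; ++p) breaks[p] = as<NumericMatrix>(size_breaks[p]);

  IntegerVector parent(nnode, -1);
  NumericVector age(nnode, 0.0);

  std::vector<int> act_node(n), act_pop(n);
  for (int i = 0; i < n; ++i) {
    act_node[i] = i;
    act_pop[i] = sample_pops[i];
    if (sample_pops[i] < 0 || sample_pops[i] >= npop)
      stop("tip population index out of range");
  }

  double t = 0.0;
  size_t ei = 0;
  int next_internal = n;
  std::vector<double> rate(npop);
  std::vector<int> kcount(npop);

  while ((int)act_node.size() > 1) {
    double seg_end = (ei < ev.size()) ? ev[ei].time : R_PosInf;
    if (seg_end < t) seg_end = t;  // events already in the past are applied now

    bool event_next = false;
    while (true) {
      std::fill(kcount.begin(), kcount.end(), 0);
      for (size_t i = 0; i < act_pop.size(); ++i) kcount[act_pop[i]]++;
      double total = 0.0;
      for (int p = 0; p < npop; ++p) {
        if (kcount[p] > 1) {
          double N = pop_size_at(breaks[p], t);
          if (N <= 0) stop("nonpositive population size encountered");
          rate[p] = 0.5 * kcount[p] * (kcount[p] - 1) / (ploidy_c * N);
        } else rate[p] = 0.0;
        total += rate[p];
      }
      double dt = (total > 0) ? R::exp_rand() / total : R_PosInf;
      if (t + dt >= seg_end) { event_next = true; break; }
      t += dt;
      // choose population, then a random pair within it
      double u = unif_rand() * total, acc = 0.0;
      int cp = -1;
      for (int p = 0; p < npop; ++p) { acc += rate[p]; if (u <= acc) { cp = p; break; } }
      if (cp < 0) cp = npop - 1;
      std::vector<int> idx;
      for (size_t i = 0; i < act_pop.size(); ++i)
        if (act_pop[i] == cp) idx.push_back((int)i);
      int i1 = (int)(unif_rand() * idx.size()); if (i1 == (int)idx.size()) i1--;
      int i2 = (int)(unif_rand() * (idx.size() - 1)); if (i2 == (int)idx.size() - 1) i2--;
      if (i2 >= i1) i2++;
      int a = idx[i1], b = idx[i2];
      int node = next_internal++;
      parent[act_node[a]] = node;
      parent[act_node[b]] = node;
      age[node] = t;
      // replace lineage a by the new node, drop b
      act_node[a] = node;
      int last = (int)act_node.size() - 1;
      act_node[b] = act_node[last]; act_pop[b] = act_pop[last];
      act_node.pop_back(); act_pop.pop_back();
      if ((int)act_node.size() <= 1) break;
    }
    if ((int)act_node.size() <= 1) break;
    if (event_next) {
      if (ei >= ev.size()) stop("internal error: ran out of events with >1 lineage and zero rate");
      t = std::max(t, ev[ei].time);
      if (ev[ei].kind == 1) {
        for (size_t i = 0; i < act_pop.size(); ++i)
          if (act_pop[i] == ev[ei].child) act_pop[i] = ev[ei].parent;
      }
      ei++;
    }
  }
  return List::create(_["parent"] = parent, _["age"] = age);
}

// HKY transition-probability row sampling along a tree.
//
// parent/age: as returned by sim_genealogy_cpp (node ages ascending with index)
// site_cat:   per-site rate category, 0 = invariant, 1..K indexes cat_rates
// cat_rates:  relative rates (mean 1) of the K discrete-Gamma categories
// freqs:      base frequencies (A, C, G, T)
// mu_site:    substitutions per site per generation at a rate-1 site
//
// Returns tip sequences coded 0=A, 1=C, 2=G, 3=T.
// [[Rcpp::export]]
IntegerMatrix evolve_hky_cpp(IntegerVector parent, NumericVector age, int n_tips,
                             IntegerVector site_cat, NumericVector cat_rates,
                             double kappa, NumericVector freqs, double mu_site) {
  const int nnode = parent.size();
  const int L = site_cat.size();
  const int K = cat_rates.size();
  const double fA = freqs[0], fC = freqs[1], fG = freqs[2], fT = freqs[3];
  const double pR = fA + fG, pY = fC + fT;
  const double beta = 1.0 / (2.0 * (pR * pY + kappa * (fA * fG + fC * fT)));

  // sites grouped by category
  std::vector<std::vector<int> > by_cat(K + 1);
  for (int s = 0; s < L; ++s) by_cat[site_cat[s]].push_back(s);

  std::vector<std::vector<int> > seq(nnode, std::vector<int>(L));
  int root = nnode - 1;

  // stationary root sequence
  double cumf[4] = {fA, fA + fC, fA + fC + fG, 1.0};
  for (int s = 0; s < L; ++s) {
    double u = unif_rand();
    int b = 0; while (b < 3 && u > cumf[b]) ++b;
    seq[root][s] = b;
  }

  double cum[4][4];
  for (int node = nnode - 2; node >= 0; --node) {
    int par = parent[node];
    double len = age[par] - age[node];
    std::vector<int>& child = seq[node];
    std::vector<int>& ps = seq[par];
    // invariant sites copy
    for (size_t ii = 0; ii < by_cat[0].size(); ++ii) child[by_cat[0][ii]] = ps[by_cat[0][ii]];
    for (int k = 1; k <= K; ++k) {
      if (by_cat[k].empty()) continue;
      double tsub = mu_site * cat_rates[k - 1] * len;
      double e1 = exp(-beta * tsub);
      double e2R = exp(-tsub * (1.0 + pR * (kappa - 1.0)) * beta);
      double e2Y = exp(-tsub * (1.0 + pY * (kappa - 1.0)) * beta);
      for (int i = 0; i < 4; ++i) {
        double row = 0.0;
        bool iR = (i == 0 || i == 2);
        for (int j = 0; j < 4; ++j) {
          bool jR = (j == 0 || j == 2);
          double fj = freqs[j], cj = jR ? pR : pY, e2 = jR ? e2R : e2Y;
          double pij;
          if (i == j)           pij = fj + fj * (1.0 / cj - 1.0) * e1 + ((cj - fj) / cj) * e2;
          else if (iR == jR)    pij = fj + fj * (1.0 / cj - 1.0) * e1 - (fj / cj) * e2;
          else                  pij = fj * (1.0 - e1);
          row += pij;
          cum[i][j] = row;
        }
        cum[i][3] = 1.0;  // guard against rounding
      }
      const std::vector<int>& sites = by_cat[k];
      for (size_t ii = 0; ii < sites.size(); ++ii) {
        int s = sites[ii];
        double u = unif_rand();
        const double* cr = cum[ps[s]];
        int b = 0; while (b < 3 && u > cr[b]) ++b;
        child[s] = b;
      }
    }
  }

  IntegerMatrix out(n_tips, L);
  for (int i = 0; i < n_tips; ++i)
    for (int s = 0; s < L; ++s) out(i, s) = seq[i][s];
  return out;
}

// Generalized stepwise mutation along a tree for one microsatellite locus.
// Mutation count per branch is Poisson(rate * length); each mutation moves
// the allele by a geometric(p_geom) number of repeat units, sign equiprobable,
// reflected into [lo, hi] when clamping is enabled (lo <= hi), unbounded when
// lo > hi.
// [[Rcpp::export]]
IntegerVector evolve_str_cpp(IntegerVector parent, NumericVector age, int n_tips,
                             double rate, double p_geom, int anc, int lo, int hi) {
  const int nnode = parent.size();
  std::vector<int> allele(nnode);
  allele[nnode - 1] = anc;
  const bool clamp = (lo <= hi);
  for (int node = nnode - 2; node >= 0; --node) {
    int par = parent[node];
    double len = age[par] - age[node];
    int a = allele[par];
    int m = (int)R::rpois(rate * len);
    for (int j = 0; j < m; ++j) {
      int step = 1 + (int)R::rgeom(p_geom);
      if (unif_rand() < 0.5) step = -step;
      a += step;
      if (clamp) {
        while (a < lo || a > hi) {
          if (a < lo) a = 2 * lo - a;
          if (a > hi) a = 2 * hi - a;
        }
      }
    }
    allele[node] = a;
  }
  IntegerVector out(n_tips);
  for (int i = 0; i < n_tips; ++i) out[i] = allele[i];
  return out;
}

// Pairwise Hamming distances over an integer-coded alignment.
// NA entries are excluded pairwise (a site counts only when both copies
// are non-missing).
// [[Rcpp::export]]
NumericMatrix pair_diff_cpp(IntegerMatrix seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int diff = 0;
      for (int s = 0; s < L; ++s) {
        int a = seqs(i, s), b = seqs(j, s);
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        if (a != b) ++diff;
      }
      d(i, j) = diff; d(j, i) = diff;
    }
  }
  return d;
}

// Sudden-expansion expected mismatch frequencies (finite theta1 > 0 case):
// F_i = F1_i + exp(-tau(theta1+1)/theta1) * sum_j tau^j/j! (F0_{i-j} - F1_{i-j}),
// truncated at d_max and renormalized. Negative round-off is clipped to 0.
// [[Rcpp::export]]
NumericVector expansion_mismatch_cpp(double theta0, double theta1, double tau,
                                     int d_max) {
  const int n = d_max + 1;
  std::vector<double> f0(n), f1(n), pois(n);
  double l0 = (theta0 > 0) ? log(theta0) : 0.0;
  double l1 = log(theta1);
  for (int i = 0; i < n; ++i) {
    if (theta0 > 0) f0[i] = exp(i * l0 - (i + 1) * log1p(theta0));
    else f0[i] = (i == 0) ? 1.0 : 0.0;
    f1[i] = exp(i * l1 - (i + 1) * log1p(theta1));
    if (tau > 0) pois[i] = exp(i * log(tau) - lgamma(i + 1.0));
    else pois[i] = (i == 0) ? 1.0 : 0.0;
  }
  double damp = exp(-tau * (theta1 + 1.0) / theta1);
  NumericVector out(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double conv = 0.0;
    for (int j = 0; j <= i; ++j) conv += pois[j] * (f0[i - j] - f1[i - j]);
    double v = f1[i] + damp * conv;
    if (v < 0) v = 0;
    out[i] = v;
    total += v;
  }
  for (int i = 0; i < n; ++i) out[i] /= total;
  return out;
}
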