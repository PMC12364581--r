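#include <Rcpp.h>
#include <random>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Unbiased draw in [0, k) from a mt19937 stream. Implemented by rejection so
// that results do not depend on the standard library's distribution objects
// (which are implementation-defined) -- runs are reproducible across builds.
static inline uint32_t rand_below(std::mt19937 &rng, uint32_t k) {
  if (k <= 1) return 0;
  uint64_t span = (uint64_t)1 << 32;
  uint64_t lim = span - span % k;
  uint64_t r;
  do {
    r = rng();
  } while (r >= lim);
  return (uint32_t)(r % k);
}

// Next level of node j under the multi-level asynchronous update.
// States are stored as integer levels m in {-l, ..., -1, +1, ..., +l};
// the expression value is m / l.  With l = 1 this is exactly the Ising
// update: sign of the weighted input sum, held on ties.
//
// The normalized input is s = sum_i Adj[i,j] * x_i / d_j where d_j counts
// nonzero incoming weights (self-edges included).  The target level index is
// k = ceil(|s| * l) capped at l, signed like s; s == 0 (and d_j == 0) holds
// the current value.  |s| * l equals |T| / d_j with T = sum_i Adj[i,j] * m_i,
// so for integer-weight networks the bracket comparison is exact in doubles.
//
// `focal` (0-based, -1 for none) implements the state-dependent asymmetric
// weight: outgoing edges of the focal node onto other nodes are scaled by
// `focal_w` whenever the focal node is high.
static inline int next_level(const NumericMatrix &adj, const std::vector<int> &m,
                             int j, int l, const std::vector<int> &indeg,
                             int focal, double focal_w) {
  if (indeg[j] == 0) return m[j];
  const int n = (int)m.size();
  double T = 0.0;
  for (int i = 0; i < n; ++i) {
    double w = adj(i, j);
    if (w == 0.0) continue;
    if (i == focal && i != j && m[i] > 0) w *= focal_w;
    T += w * (double)m[i];
  }
  if (T == 0.0) return m[j];
  double q = (T > 0 ? T : -T) / (double)indeg[j]; // |s| * l
  int k = (int)std::ceil(q);
  if (k > l) k = l;
  return T > 0 ? k : -k;
}

static inline bool is_fixed(const NumericMatrix &adj, const std::vector<int> &m,
                            const std::vector<int> &free_idx, int l,
                            const std::vector<int> &indeg, int focal,
                            double focal_w) {
  for (size_t a = 0; a < free_idx.size(); ++a) {
    int j = free_idx[a];
    if (next_level(adj, m, j, l, indeg, focal, focal_w) != m[j]) return false;
  }
  return true;
}

static std::vector<int> in_degrees(const NumericMatrix &adj) {
  int n = adj.nrow();
  std::vector<int> indeg(n, 0);
  for (int j = 0; j < n; ++j) {
    int d = 0;
    for (int i = 0; i < n; ++i)
      if (adj(i, j) != 0.0) ++d;
    indeg[j] = d;
  }
  return indeg;
}

// Asynchronous simulation from random (or supplied) initial conditions.
//
// adj:      square weight matrix, entry (i, j) = regulation from i onto j
// clamped:  nodes held at the top level throughout (cytokines); they are
//           never drawn for update and consume no RNG draws
// levels:   l, half the number of expression levels (l = 1 is Boolean)
// focal/focal_w: asymmetric-weight modification (-1 to disable)
// n_init:   number of trajectories
// max_steps: cap on single-node updates per trajectory
// init_states: optional matrix of integer level states, rows recycled;
//           when absent, initial conditions are uniform over levels
//
// Returns the distinct fixed points reached, their trajectory counts, and
// the number of converged trajectories.
// [[Rcpp::export]]
List sim_async_cpp(NumericMatrix adj, LogicalVector clamped, int levels,
                   int focal, double focal_w, int n_init, int max_steps,
                   int seed, Nullable<IntegerMatrix> init_states) {
  const int n = adj.nrow();
  if (adj.ncol() != n) stop("adjacency must be square");
  if (levels < 1) stop("levels must be >= 1");
  std::vector<int> free_idx;
  for (int i = 0; i < n; ++i)
    if (!clamped[i]) free_idx.push_back(i);
  const int nf = (int)free_idx.size();
  if (nf == 0) stop("no free (unclamped) nodes to simulate");
  std::vector<int> indeg = in_degrees(adj);

  std::mt19937 rng((uint32_t)seed);
  IntegerMatrix inits;
  const bool has_init = init_states.isNotNull();
  if (has_init) {
    inits = IntegerMatrix(init_states.get());
    if (inits.ncol() != n) stop("init_states must have one column per node");
  }

  std::unordered_map<std::string, double> tally;
  double n_conv = 0;
  std::vector<int> m(n);
  std::string key((size_t)n, 'a');

  for (int t = 0; t < n_init; ++t) {
    if (has_init) {
      int r = t % inits.nrow();
      for (int i = 0; i < n; ++i) m[i] = inits(r, i);
    } else {
      for (int a = 0; a < nf; ++a) {
        int i = free_idx[a];
        int u = (int)rand_below(rng, (uint32_t)(2 * levels));
        m[i] = u - levels;
        if (m[i] >= 0) m[i] += 1;
      }
    }
    for (int i = 0; i < n; ++i)
      if (clamped[i]) m[i] = levels;

    bool conv = false;
    int step = 0;
    for (;;) {
      if (is_fixed(adj, m, free_idx, levels, indeg, focal, focal_w)) {
        conv = true;
        break;
      }
      if (step >= max_steps) break;
      int burst = nf < (max_steps - step) ? nf : (max_steps - step);
      for (int b = 0; b < burst; ++b) {
        int j = free_idx[rand_below(rng, (uint32_t)nf)];
        m[j] = next_level(adj, m, j, levels, indeg, focal, focal_w);
      }
      step += burst;
    }
    if (conv) {
      n_conv += 1;
      for (int i = 0; i < n; ++i) key[(size_t)i] = (char)('a' + (m[i] + levels));
      tally[key] += 1;
    }
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  const int ns = (int)tally.size();
  IntegerMatrix states(ns, n);
  NumericVector counts(ns);
  int r = 0;
  for (std::unordered_map<std::string, double>::const_iterator it = tally.begin();
       it != tally.end(); ++it, ++r) {
    for (int i = 0; i < n; ++i)
      states(r, i) = (int)(it->first[(size_t)i] - 'a') - levels;
    counts[r] = it->second;
  }
  return List::create(_["states"] = states, _["counts"] = counts,
                      _["n_converged"] = n_conv, _["n_total"] = (double)n_init);
}

// Exhaustive fixed-point enumeration over the Boolean state space {-1,+1}^nf
// (clamped nodes held at +1).  Ground truth for the Monte-Carlo simulator.
// [[Rcpp::export]]
IntegerMatrix enum_fixed_boolean_cpp(NumericMatrix adj, LogicalVector clamped,
                                     int focal, double focal_w) {
  const int n = adj.nrow();
  std::vector<int> free_idx;
  for (int i = 0; i < n; ++i)
    if (!clamped[i]) free_idx.push_back(i);
  const int nf = (int)free_idx.size();
  if (nf > 24) stop("exhaustive enumeration limited to 24 free nodes");
  std::vector<int> indeg = in_degrees(adj);

  std::vector<int> m(n, 1);
  std::vector<std::vector<int> > found;
  const uint64_t total = (uint64_t)1 << nf;
  for (uint64_t mask = 0; mask < total; ++mask) {
    for (int a = 0; a < nf; ++a)
      m[free_idx[a]] = (mask >> a) & 1 ? 1 : -1;
    if (is_fixed(adj, m, free_idx, 1, indeg, focal, focal_w))
      found.push_back(m);
    if ((mask & 4095) == 0) Rcpp::checkUserInterrupt();
  }
  IntegerMatrix out((int)found.size(), n);
  for (int r = 0; r < (int)found.size(); ++r)
    for (int i = 0; i < n; ++i) out(r, i) = found[(size_t)r][(size_t)i];
  return out;
}
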