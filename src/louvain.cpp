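#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

// Weighted Louvain on a dense non-negative matrix.
//
// All mass is kept in "ordered pair" units: M is symmetric, M[i][j] is the
// weight of the (i,j) ordered pair, the diagonal of an aggregated graph holds
// the full internal (ordered) mass of the meta-node, k_i = sum_j M[i][j] and
// 2m = sum_ij M[i][j].  Modularity is then
//   Q = (1/2m) * sum_c [ in_c - gamma * (tot_c / 2m) * tot_c ]
// with in_c the ordered internal mass and tot_c the summed strengths, which
// matches the usual Q = (1/2m) sum_ij (w_ij - gamma k_i k_j / 2m) delta(ci,cj)
// evaluated on the original graph (zero diagonal).

static std::vector<int> one_level(const std::vector<std::vector<double> > &M,
                                  double two_m, double gamma,
                                  std::mt19937 &rng, bool &improved) {
  const int n = static_cast<int>(M.size());
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) k[i] += M[i][j];

  std::vector<int> comm(n);
  std::vector<double> tot(k);  // community strength sums; start as singletons
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) { comm[i] = i; order[i] = i; }

  std::vector<double> wcom(n);
  improved = false;
  bool moved = true;
  while (moved) {
    moved = false;
    std::shuffle(order.begin(), order.end(), rng);
    for (int idx = 0; idx < n; ++idx) {
      const int i = order[idx];
      const int a = comm[i];
      std::fill(wcom.begin(), wcom.end(), 0.0);
      for (int j = 0; j < n; ++j)
        if (j != i && M[i][j] != 0.0) wcom[comm[j]] += M[i][j];
      // take i out of its community, then evaluate every target (empty
      // communities included, so a singleton move with gain 0 is available)
      tot[a] -= k[i];
      int best = a;
      double best_gain = wcom[a] - gamma * k[i] * tot[a] / two_m;
      for (int c = 0; c < n; ++c) {
        if (c == a) continue;
        if (wcom[c] == 0.0 && tot[c] != 0.0) continue;  // non-neighbour, non-empty
        const double gain = wcom[c] - gamma * k[i] * tot[c] / two_m;
        if (gain > best_gain + 1e-12) { best_gain = gain; best = c; }
      }
      tot[best] += k[i];
      if (best != a) { comm[i] = best; moved = true; improved = true; }
    }
  }
  return comm;
}

// relabel communities to 0..K-1 in order of first appearance; returns K
static int compact_labels(std::vector<int> &comm) {
  std::vector<int> map(comm.size(), -1);
  int next = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = next++;
    comm[i] = map[comm[i]];
  }
  return next;
}

// [[Rcpp::export]]
IntegerVector louvain_cpp(NumericMatrix W, double gamma, int seed) {
  const int n0 = W.nrow();
  std::mt19937 rng(static_cast<unsigned int>(seed));

  std::vector<std::vector<double> > M(n0, std::vector<double>(n0, 0.0));
  double two_m = 0.0;
  for (int i = 0; i < n0; ++i)
    for (int j = 0; j < n0; ++j) { M[i][j] = W(i, j); two_m += W(i, j); }
  if (two_m <= 0.0) stop("total edge weight must be positive");

  std::vector<int> assign(n0);
  for (int i = 0; i < n0; ++i) assign[i] = i;

  for (;;) {
    bool improved = false;
    std::vector<int> comm = one_level(M, two_m, gamma, rng, improved);
    const int K = compact_labels(comm);
    for (int i = 0; i < n0; ++i) assign[i] = comm[assign[i]];
    if (!improved || K == static_cast<int>(M.size())) break;
    std::vector<std::vector<double> > A(K, std::vector<double>(K, 0.0));
    for (size_t i = 0; i < M.size(); ++i)
      for (size_t j = 0; j < M.size(); ++j)
        A[comm[i]][comm[j]] += M[i][j];
    M.swap(A);
  }

  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) out[i] = assign[i] + 1;
  return out;
}

// [[Rcpp::export]]
NumericMatrix agreement_cpp(IntegerMatrix memberships) {
  const int n = memberships.nrow();
  const int R = memberships.ncol();
  if (R < 1) stop("at least one partition required");
  NumericMatrix d(n, n);
  for (int r = 0; r < R; ++r) {
    for (int i = 0; i < n; ++i) {
      const int mi = memberships(i, r);
      for (int j = 0; j < i; ++j) {
        if (mi == memberships(j, r)) { d(i, j) += 1.0; d(j, i) += 1.0; }
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    d(i, i) = 1.0;
    for (int j = 0; j < i; ++j) {
      d(i, j) /= R;
      d(j, i) = d(i, j);
    }
  }
  return d;
}
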