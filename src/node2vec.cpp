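// node2vec: second-order biased random walks + skip-gram with negative
// sampling. Single-threaded; all randomness comes from one mt19937_64 stream
// seeded from R, so results are reproducible for a fixed seed.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

// binary search in the sorted neighbor slice of node u
inline bool is_neighbor(const std::vector<int>& adj, int lo, int hi, int x) {
  return std::binary_search(adj.begin() + lo, adj.begin() + hi, x);
}

inline double fast_sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = "node2vec_embed_cpp")]]
NumericMatrix node2vec_embed_cpp(IntegerVector offsets, IntegerVector adjacency,
                                 NumericVector weights, int n_nodes,
                                 double p, double q, int dim, int walk_length,
                                 int num_walks, int window, int epochs,
                                 int negative, double learning_rate,
                                 int seed) {
  std::vector<int> off(offsets.begin(), offsets.end());
  std::vector<int> adj(adjacency.begin(), adjacency.end());
  std::vector<double> w(weights.begin(), weights.end());
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // ---- walk corpus -------------------------------------------------------
  std::vector<std::vector<int>> walks;
  walks.reserve(static_cast<size_t>(n_nodes) * num_walks);
  std::vector<int> order(n_nodes);
  for (int i = 0; i < n_nodes; ++i) order[i] = i;
  std::vector<double> probs;

  for (int iter = 0; iter < num_walks; ++iter) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int s : order) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(s);
      int prev = -1, cur = s;
      while ((int)walk.size() < walk_length) {
        int lo = off[cur], hi = off[cur + 1];
        int k = hi - lo;
        if (k == 0) break;  // isolated node: walk of length 1
        int nxt;
        if (prev < 0) {
          // first step: plain weighted transition
          double tot = 0.0;
          for (int t = lo; t < hi; ++t) tot += w[t];
          double r = unif(rng) * tot, acc = 0.0;
          nxt = adj[hi - 1];
          for (int t = lo; t < hi; ++t) {
            acc += w[t];
            if (r <= acc) { nxt = adj[t]; break; }
          }
        } else {
          // second-order bias: weight * (1/p back, 1 to common, 1/q outward)
          probs.resize(k);
          double tot = 0.0;
          int plo = off[prev], phi = off[prev + 1];
          for (int t = lo; t < hi; ++t) {
            int x = adj[t];
            double b;
            if (x == prev) b = 1.0 / p;
            else if (is_neighbor(adj, plo, phi, x)) b = 1.0;
            else b = 1.0 / q;
            tot += w[t] * b;
            probs[t - lo] = tot;
          }
          double r = unif(rng) * tot;
          nxt = adj[hi - 1];
          for (int t = 0; t < k; ++t) {
            if (r <= probs[t]) { nxt = adj[lo + t]; break; }
          }
        }
        walk.push_back(nxt);
        prev = cur;
        cur = nxt;
      }
      walks.push_back(std::move(walk));
    }
  }

  // ---- negative-sampling table (unigram^0.75 over corpus frequencies) ----
  std::vector<double> freq(n_nodes, 0.0);
  size_t total_tokens = 0;
  for (const auto& walk : walks) {
    for (int v : walk) freq[v] += 1.0;
    total_tokens += walk.size();
  }
  std::vector<double> cum(n_nodes);
  double z = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    z += std::pow(freq[v] + 1e-12, 0.75);
    cum[v] = z;
  }

  // ---- skip-gram with negative sampling ----------------------------------
  std::vector<double> emb(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> ctx(static_cast<size_t>(n_nodes) * dim, 0.0);
  std::uniform_real_distribution<double> init(-0.5 / dim, 0.5 / dim);
  for (auto& x : emb) x = init(rng);

  std::uniform_int_distribution<int> win_draw(1, window);
  std::vector<double> grad(dim);
  const size_t total_pairs_est = static_cast<size_t>(epochs) * total_tokens;
  size_t done_tokens = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto& walk : walks) {
      int L = (int)walk.size();
      for (int pos = 0; pos < L; ++pos) {
        double lr = learning_rate *
          std::max(0.1, 1.0 - (double)done_tokens / (double)(total_pairs_est + 1));
        ++done_tokens;
        int b = win_draw(rng);  // dynamic window, word2vec-style
        int center = walk[pos];
        double* ec = &emb[(size_t)center * dim];
        for (int off2 = -b; off2 <= b; ++off2) {
          if (off2 == 0) continue;
          int cpos = pos + off2;
          if (cpos < 0 || cpos >= L) continue;
          int context = walk[cpos];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = context;
              label = 1.0;
            } else {
              double r = unif(rng) * z;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), r) -
                             cum.begin());
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double* ct = &ctx[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += ec[d] * ct[d];
            double g = (label - fast_sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * ct[d];
              ct[d] += g * ec[d];
            }
          }
          for (int d = 0; d < dim; ++d) ec[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v) {
    for (int d = 0; d < dim; ++d) out(v, d) = emb[(size_t)v * dim + d];
  }
  return out;
}
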