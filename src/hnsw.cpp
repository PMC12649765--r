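// Hierarchical navigable small-world (HNSW) approximate nearest-neighbour
// index over L2-normalized vectors with cosine distance (1 - dot).
// Standard construction: geometric level assignment with mL = 1/ln(M),
// greedy descent through upper layers, beam search (efConstruction) and
// top-M neighbour selection with bidirectional links pruned to M (2M at
// layer 0). Deterministic for a fixed seed and insertion order.

#include <Rcpp.h>
#include <queue>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Hnsw {
  int dim;
  int M;
  int maxM0;
  int ef_construction;
  double mult;                       // 1 / ln(M)
  std::vector<std::vector<double>> data;
  std::vector<int> levels;
  // links[node][layer] -> neighbour ids
  std::vector<std::vector<std::vector<int>>> links;
  int entry = -1;
  int max_level = -1;
  std::mt19937 rng;

  Hnsw(int dim_, int M_, int efc_, int seed)
      : dim(dim_), M(M_), maxM0(2 * M_), ef_construction(efc_),
        mult(1.0 / std::log(static_cast<double>(M_))), rng(seed) {}

  double dist(const std::vector<double>& a, const std::vector<double>& b) const {
    double dot = 0.0;
    for (int i = 0; i < dim; ++i) dot += a[i] * b[i];
    return 1.0 - dot;
  }
  double dist(int i, const std::vector<double>& q) const {
    return dist(data[i], q);
  }

  typedef std::pair<double, int> DistId;  // (distance, id)

  // Beam search on one layer; returns up to ef closest (ascending distance).
  std::vector<DistId> search_layer(const std::vector<double>& q, int ep,
                                   int ef, int layer) const {
    std::vector<char> visited(data.size(), 0);
    // candidates: min-heap by distance; results: max-heap by distance
    std::priority_queue<DistId, std::vector<DistId>, std::greater<DistId>> cand;
    std::priority_queue<DistId> res;
    double d0 = dist(ep, q);
    cand.push({d0, ep});
    res.push({d0, ep});
    visited[ep] = 1;
    while (!cand.empty()) {
      DistId c = cand.top();
      if (c.first > res.top().first && static_cast<int>(res.size()) >= ef) break;
      cand.pop();
      const std::vector<int>& nb = links[c.second][layer];
      for (int v : nb) {
        if (visited[v]) continue;
        visited[v] = 1;
        double d = dist(v, q);
        if (static_cast<int>(res.size()) < ef || d < res.top().first) {
          cand.push({d, v});
          res.push({d, v});
          if (static_cast<int>(res.size()) > ef) res.pop();
        }
      }
    }
    std::vector<DistId> out(res.size());
    for (int i = static_cast<int>(res.size()) - 1; !res.empty(); --i) {
      out[i] = res.top();
      res.pop();
    }
    return out;
  }

  int random_level() {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    double r = unif(rng);
    if (r <= 0.0) r = 1e-12;
    return static_cast<int>(std::floor(-std::log(r) * mult));
  }

  void insert(const std::vector<double>& v) {
    int id = static_cast<int>(data.size());
    int lvl = random_level();
    data.push_back(v);
    levels.push_back(lvl);
    links.push_back(std::vector<std::vector<int>>(lvl + 1));
    if (entry < 0) {
      entry = id;
      max_level = lvl;
      return;
    }
    int ep = entry;
    // greedy descent above the node's top layer
    for (int l = max_level; l > lvl; --l) {
      bool improved = true;
      double d = dist(ep, v);
      while (improved) {
        improved = false;
        for (int nb : links[ep][l]) {
          double dn = dist(nb, v);
          if (dn < d) { d = dn; ep = nb; improved = true; }
        }
      }
    }
    for (int l = std::min(lvl, max_level); l >= 0; --l) {
      std::vector<DistId> cands = search_layer(v, ep, ef_construction, l);
      int mmax = (l == 0) ? maxM0 : M;
      int take = std::min<int>(M, cands.size());
      for (int i = 0; i < take; ++i) {
        int nb = cands[i].second;
        links[id][l].push_back(nb);
        links[nb][l].push_back(id);
        if (static_cast<int>(links[nb][l].size()) > mmax) {
          // prune neighbour's list to the mmax closest
          std::vector<DistId> ds;
          ds.reserve(links[nb][l].size());
          for (int x : links[nb][l]) ds.push_back({dist(data[nb], data[x]), x});
          std::sort(ds.begin(), ds.end());
          links[nb][l].clear();
          for (int i2 = 0; i2 < mmax; ++i2) links[nb][l].push_back(ds[i2].second);
        }
      }
      if (!cands.empty()) ep = cands[0].second;
    }
    if (lvl > max_level) {
      max_level = lvl;
      entry = id;
    }
  }

  std::vector<DistId> search(const std::vector<double>& q, int k, int ef) const {
    std::vector<DistId> out;
    if (entry < 0) return out;
    int ep = entry;
    for (int l = max_level; l > 0; --l) {
      bool improved = true;
      double d = dist(ep, q);
      while (improved) {
        improved = false;
        for (int nb : links[ep][l]) {
          double dn = dist(nb, q);
          if (dn < d) { d = dn; ep = nb; improved = true; }
        }
      }
    }
    std::vector<DistId> res = search_layer(q, ep, std::max(ef, k), 0);
    if (static_cast<int>(res.size()) > k) res.resize(k);
    return res;
  }
};

}  // namespace

// [[Rcpp::export]]
SEXP hnsw_build_cpp(NumericMatrix x, int M, int ef_construction, int seed) {
  if (M < 2) stop("M must be >= 2");
  if (ef_construction < M) stop("ef_construction must be >= M");
  Hnsw* idx = new Hnsw(x.ncol(), M, ef_construction, seed);
  std::vector<double> v(x.ncol());
  for (int i = 0; i < x.nrow(); ++i) {
    for (int j = 0; j < x.ncol(); ++j) v[j] = x(i, j);
    idx->insert(v);
  }
  XPtr<Hnsw> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List hnsw_search_cpp(SEXP ptr_, NumericVector q, int k, int ef_search) {
  XPtr<Hnsw> ptr(ptr_);
  if (q.size() != ptr->dim) stop("query dimension mismatch");
  std::vector<double> v(q.begin(), q.end());
  std::vector<std::pair<double, int>> res = ptr->search(v, k, ef_search);
  IntegerVector idx(res.size());
  NumericVector sim(res.size());
  for (size_t i = 0; i < res.size(); ++i) {
    idx[i] = res[i].second + 1;       // 1-based
    sim[i] = 1.0 - res[i].first;      // back to cosine similarity
  }
  return List::create(_["idx"] = idx, _["similarity"] = sim);
}

// [[Rcpp::export]]
int hnsw_size_cpp(SEXP ptr_) {
  XPtr<Hnsw> ptr(ptr_);
  return static_cast<int>(ptr->data.size());
}
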