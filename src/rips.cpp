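// Vietoris-Rips persistence for small point clouds (sliding-window
// sequence embeddings). Simplices up to dimension max_dim + 1 are
// enumerated explicitly and filtered at the scale where the
// epsilon-balls of all vertices pairwise intersect (epsilon = max
// pairwise distance / 2). The boundary matrix is reduced over GF(2)
// dimension by dimension with the standard left-to-right column
// algorithm; columns are bitsets over the (d-1)-simplex rows so each
// column addition is a handful of 64-bit XORs. Intended for clouds of
// at most a few dozen points.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Simp {
  double f;
  std::array<int, 4> v;   // sorted vertex ids, -1 padded
};

inline bool simp_less(const Simp &a, const Simp &b) {
  if (a.f != b.f) return a.f < b.f;
  return a.v < b.v;      // lexicographic on padded vertex arrays
}

inline std::uint64_t vkey(const int *v, int nv) {
  std::uint64_t key = 0;
  for (int k = 0; k < nv; ++k)
    key = (key << 14) | static_cast<std::uint64_t>(v[k] + 1);
  return key;
}

// dense GF(2) column over `nrows` rows
struct BitCol {
  std::vector<std::uint64_t> w;
  explicit BitCol(int nrows) : w((nrows + 63) / 64, 0ull) {}
  void set(int r) { w[r >> 6] ^= (1ull << (r & 63)); }
  void operator^=(const BitCol &o) {
    for (size_t i = 0; i < w.size(); ++i) w[i] ^= o.w[i];
  }
  int top() const {                      // highest set bit, -1 if empty
    for (int i = static_cast<int>(w.size()) - 1; i >= 0; --i)
      if (w[i]) return (i << 6) | (63 - __builtin_clzll(w[i]));
    return -1;
  }
};

} // namespace

// [[Rcpp::export(name = ".rips_pairs_cpp")]]
List rips_pairs_cpp(NumericMatrix coords, int max_dim, double cap) {
  const int n = coords.nrow();
  const int d = coords.ncol();
  if (n < 1) stop("point cloud is empty");
  if (max_dim < 0 || max_dim > 2) stop("max_dim must be 0, 1 or 2");

  std::vector<double> dist(static_cast<size_t>(n) * n, 0.0);
  double diam = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = coords(i, k) - coords(j, k);
        s += diff * diff;
      }
      s = std::sqrt(s);
      dist[i * n + j] = dist[j * n + i] = s;
      if (s > diam) diam = s;
    }

  // cap < 0 requests the automatic policy: half the diameter (the full
  // dimension-0 merge tree is then observed); degenerate clouds use 1.
  double K = cap;
  if (K < 0) K = (diam > 0.0) ? diam / 2.0 : 1.0;

  const int top_dim = std::min(max_dim + 1, n - 1);

  // per-dimension simplex lists, sorted by (filtration value, lex)
  std::vector<std::vector<Simp>> simp(top_dim + 1);
  simp[0].reserve(n);
  for (int i = 0; i < n; ++i) simp[0].push_back({0.0, {i, -1, -1, -1}});
  if (top_dim >= 1)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double f = dist[i * n + j] / 2.0;
        if (f <= K) simp[1].push_back({f, {i, j, -1, -1}});
      }
  if (top_dim >= 2)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double fij = dist[i * n + j];
        for (int k = j + 1; k < n; ++k) {
          double f = std::max({fij, dist[i * n + k], dist[j * n + k]}) / 2.0;
          if (f <= K) simp[2].push_back({f, {i, j, k, -1}});
        }
      }
  if (top_dim >= 3)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        for (int k = j + 1; k < n; ++k) {
          double fijk = std::max({dist[i * n + j], dist[i * n + k],
                                  dist[j * n + k]});
          for (int l = k + 1; l < n; ++l) {
            double f = std::max({fijk, dist[i * n + l], dist[j * n + l],
                                 dist[k * n + l]}) / 2.0;
            if (f <= K) simp[3].push_back({f, {i, j, k, l}});
          }
        }
  for (int q = 1; q <= top_dim; ++q)
    std::sort(simp[q].begin(), simp[q].end(), simp_less);

  // creator flags and deaths per dimension (death = K until paired)
  std::vector<std::vector<char>> creator(top_dim + 1);
  std::vector<std::vector<double>> death(top_dim + 1);
  creator[0].assign(n, 1);
  death[0].assign(n, K);
  for (int q = 1; q <= top_dim; ++q) {
    creator[q].assign(simp[q].size(), 0);
    death[q].assign(simp[q].size(), K);
  }

  // reduce boundary_d for d = 1..top_dim
  for (int q = 1; q <= top_dim; ++q) {
    const int nrows = static_cast<int>(simp[q - 1].size());
    std::unordered_map<std::uint64_t, int> rowpos;
    rowpos.reserve(simp[q - 1].size() * 2);
    for (size_t r = 0; r < simp[q - 1].size(); ++r)
      rowpos[vkey(simp[q - 1][r].v.data(), q)] = static_cast<int>(r);

    std::vector<int> pivot_owner(nrows, -1);
    std::vector<BitCol> stored;            // reduced destroyer columns
    std::vector<int> stored_of(simp[q].size(), -1);

    int face[4];
    for (size_t c = 0; c < simp[q].size(); ++c) {
      BitCol col(nrows);
      const Simp &sp = simp[q][c];
      for (int omit = 0; omit <= q; ++omit) {
        int t = 0;
        for (int k = 0; k <= q; ++k)
          if (k != omit) face[t++] = sp.v[k];
        col.set(rowpos.at(vkey(face, q)));
      }
      int low = col.top();
      while (low >= 0 && pivot_owner[low] >= 0) {
        col ^= stored[stored_of[pivot_owner[low]]];
        low = col.top();
      }
      if (low < 0) {
        creator[q][c] = 1;
      } else {
        pivot_owner[low] = static_cast<int>(c);
        stored_of[c] = static_cast<int>(stored.size());
        stored.push_back(std::move(col));
        death[q - 1][low] = sp.f;          // row `low` dies here
      }
    }
  }

  std::vector<int> out_dim;
  std::vector<double> out_birth, out_death;
  for (int q = 0; q <= std::min(max_dim, top_dim); ++q)
    for (size_t s = 0; s < simp[q].size(); ++s)
      if (creator[q][s]) {
        out_dim.push_back(q);
        out_birth.push_back(simp[q][s].f);
        out_death.push_back(death[q][s]);
      }

  return List::create(_["dimension"] = wrap(out_dim),
                      _["birth"] = wrap(out_birth),
                      _["death"] = wrap(out_death),
                      _["cap"] = K,
                      _["n_points"] = n);
}
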