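// Vietoris-Rips filtration construction and persistence pairing by
// boundary-matrix column reduction over GF(2).
//
// Conventions (shared with the R surface):
//  - an edge enters the filtration at the pairwise distance d (not d/2);
//  - a simplex enters at the max pairwise distance among its vertices;
//  - infinite distance entries never form simplices;
//  - ties are broken by (value, dimension, lexicographic vertex tuple);
//  - zero-persistence pairs are dropped from the reported barcode.

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef unsigned long long u64;

// Pack a sorted vertex tuple (size <= 4, vertices < 2^16 - 1) into one key.
static inline u64 pack_key(const int *v, int len) {
  u64 k = 0;
  for (int i = 0; i < len; ++i) k = (k << 16) | (u64)(v[i] + 1);
  return k;
}

struct Simplex {
  double value;
  int dim;
  int v[4];
};

static bool simplex_less(const Simplex &a, const Simplex &b) {
  if (a.value != b.value) return a.value < b.value;
  if (a.dim != b.dim) return a.dim < b.dim;
  for (int i = 0; i <= a.dim; ++i) {
    if (a.v[i] != b.v[i]) return a.v[i] < b.v[i];
  }
  return false;
}

// Symmetric difference of two ascending index vectors (GF(2) column add).
static void sym_diff(std::vector<int> &a, const std::vector<int> &b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  a.swap(out);
}

// Standard persistence pairing. `bdry[i]` holds ascending filtration indices
// of the facets of simplex i; simplices are already in filtration order.
static List reduce_core(std::vector<std::vector<int> > &bdry,
                        const std::vector<int> &dims,
                        const std::vector<double> &values,
                        int homdim) {
  const int m = (int)bdry.size();
  std::vector<int> pivot_of(m, -1);      // row index -> column that owns it
  std::vector<char> positive(m, 0);      // creates a cycle
  std::vector<std::vector<int> > reduced(m);

  std::vector<int> bar_dim;
  std::vector<double> bar_birth, bar_death;

  for (int i = 0; i < m; ++i) {
    std::vector<int> col = bdry[i];
    while (!col.empty()) {
      int low = col.back();
      int j = pivot_of[low];
      if (j < 0) break;
      sym_diff(col, reduced[j]);
    }
    if (col.empty()) {
      positive[i] = 1;
    } else {
      int low = col.back();
      pivot_of[low] = i;
      reduced[i] = col;
      int k = dims[low];                 // dims[i] - 1
      if (k <= homdim && values[i] > values[low]) {
        bar_dim.push_back(k);
        bar_birth.push_back(values[low]);
        bar_death.push_back(values[i]);
      }
    }
  }
  for (int i = 0; i < m; ++i) {
    if (positive[i] && pivot_of[i] < 0 && dims[i] <= homdim) {
      bar_dim.push_back(dims[i]);
      bar_birth.push_back(values[i]);
      bar_death.push_back(R_PosInf);
    }
  }
  return List::create(_["dim"] = wrap(bar_dim),
                      _["birth"] = wrap(bar_birth),
                      _["death"] = wrap(bar_death));
}

static List reduce_simplex_list(std::vector<Simplex> &simp, int homdim) {
  std::sort(simp.begin(), simp.end(), simplex_less);
  const int m = (int)simp.size();
  std::unordered_map<u64, int> index_of;
  index_of.reserve((size_t)m * 2);
  for (int i = 0; i < m; ++i) index_of[pack_key(simp[i].v, simp[i].dim + 1)] = i;

  std::vector<std::vector<int> > bdry(m);
  std::vector<int> dims(m);
  std::vector<double> values(m);
  int face[4];
  for (int i = 0; i < m; ++i) {
    dims[i] = simp[i].dim;
    values[i] = simp[i].value;
    if (simp[i].dim == 0) continue;
    std::vector<int> &col = bdry[i];
    col.reserve(simp[i].dim + 1);
    for (int drop = 0; drop <= simp[i].dim; ++drop) {
      int p = 0;
      for (int q = 0; q <= simp[i].dim; ++q) {
        if (q != drop) face[p++] = simp[i].v[q];
      }
      std::unordered_map<u64, int>::const_iterator it =
          index_of.find(pack_key(face, simp[i].dim));
      if (it == index_of.end())
        stop("filtration is not closed under taking faces");
      if (it->second > i)
        stop("filtration order violates the face ordering constraint");
      col.push_back(it->second);
    }
    std::sort(col.begin(), col.end());
  }
  return reduce_core(bdry, dims, values, homdim);
}

// Rips persistence straight from a dissimilarity matrix (may contain +Inf).
// homdim: highest homology dimension reported; the complex is built to
// dimension homdim + 1.
// [[Rcpp::export]]
List cpp_rips_persistence(NumericMatrix d, int homdim, double thresh) {
  const int n = d.nrow();
  if (n != d.ncol()) stop("distance matrix must be square");
  if (homdim < 0 || homdim > 2) stop("homdim must be 0, 1 or 2");
  const int top = homdim + 1;

  std::vector<Simplex> simp;
  for (int i = 0; i < n; ++i) {
    Simplex s; s.value = 0.0; s.dim = 0; s.v[0] = i;
    simp.push_back(s);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dij = d(i, j);
      if (R_finite(dij) && dij <= thresh) {
        Simplex s; s.value = dij; s.dim = 1; s.v[0] = i; s.v[1] = j;
        simp.push_back(s);
      }
    }
  }
  if (top >= 2) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dij = d(i, j);
        if (!R_finite(dij) || dij > thresh) continue;
        for (int k = j + 1; k < n; ++k) {
          double dik = d(i, k), djk = d(j, k);
          if (!R_finite(dik) || !R_finite(djk)) continue;
          double val = std::max(dij, std::max(dik, djk));
          if (val > thresh) continue;
          Simplex s; s.value = val; s.dim = 2;
          s.v[0] = i; s.v[1] = j; s.v[2] = k;
          simp.push_back(s);
          if (top >= 3) {
            for (int l = k + 1; l < n; ++l) {
              double dil = d(i, l), djl = d(j, l), dkl = d(k, l);
              if (!R_finite(dil) || !R_finite(djl) || !R_finite(dkl)) continue;
              double v4 = std::max(val, std::max(dil, std::max(djl, dkl)));
              if (v4 > thresh) continue;
              Simplex t; t.value = v4; t.dim = 3;
              t.v[0] = i; t.v[1] = j; t.v[2] = k; t.v[3] = l;
              simp.push_back(t);
            }
          }
        }
      }
    }
  }
  return reduce_simplex_list(simp, homdim);
}

// Persistence of an explicit filtration. Simplices arrive flattened:
// verts (0-based, concatenated), offsets (0-based start of each simplex,
// length m + 1), values; already sorted in filtration order.
// [[Rcpp::export]]
List cpp_reduce_filtration(IntegerVector verts, IntegerVector offsets,
                           NumericVector values, int homdim) {
  const int m = offsets.size() - 1;
  std::vector<Simplex> simp(m);
  for (int i = 0; i < m; ++i) {
    int a = offsets[i], b = offsets[i + 1];
    int len = b - a;
    if (len < 1 || len > 4) stop("simplices must have 1 to 4 vertices");
    simp[i].dim = len - 1;
    simp[i].value = values[i];
    for (int q = 0; q < len; ++q) simp[i].v[q] = verts[a + q];
    std::sort(simp[i].v, simp[i].v + len);
  }
  return reduce_simplex_list(simp, homdim);
}
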