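// Convex hull volume in arbitrary (small) dimension by the incremental
// beneath-beyond construction, plus nearest-neighbour distance helpers.
// Written for morphospace point clouds: d <= ~6, n up to a few hundred.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <cmath>
#include <cstdlib>

using namespace Rcpp;

typedef std::vector<double> Vec;
typedef std::vector<int> IVec;

// determinant of a small square matrix (destroys its argument)
static double det_inplace(std::vector<Vec> &m) {
  int k = (int)m.size();
  double det = 1.0;
  for (int col = 0; col < k; ++col) {
    int piv = col;
    for (int r = col + 1; r < k; ++r)
      if (std::fabs(m[r][col]) > std::fabs(m[piv][col])) piv = r;
    if (std::fabs(m[piv][col]) == 0.0) return 0.0;
    if (piv != col) { std::swap(m[piv], m[col]); det = -det; }
    det *= m[col][col];
    for (int r = col + 1; r < k; ++r) {
      double f = m[r][col] / m[col][col];
      for (int c = col; c < k; ++c) m[r][c] -= f * m[col][c];
    }
  }
  return det;
}

struct Facet {
  IVec v;        // d vertex indices
  Vec  normal;   // outward unit normal
  double offset; // dot(normal, x) == offset on the plane
  bool alive;
};

// generalized cross product: normal of the hyperplane through d points
static bool facet_plane(const std::vector<Vec> &pts, const IVec &v,
                        int d, Vec &normal, double &offset) {
  // edge matrix (d-1) x d
  std::vector<Vec> E(d - 1, Vec(d));
  for (int i = 0; i < d - 1; ++i)
    for (int j = 0; j < d; ++j)
      E[i][j] = pts[v[i + 1]][j] - pts[v[0]][j];
  normal.assign(d, 0.0);
  for (int j = 0; j < d; ++j) {
    // minor: E without column j
    std::vector<Vec> M(d - 1, Vec(d - 1));
    for (int r = 0; r < d - 1; ++r) {
      int cc = 0;
      for (int c = 0; c < d; ++c)
        if (c != j) M[r][cc++] = E[r][c];
    }
    double mdet = det_inplace(M);
    normal[j] = ((j % 2) ? -1.0 : 1.0) * mdet;
  }
  double nn = 0.0;
  for (int j = 0; j < d; ++j) nn += normal[j] * normal[j];
  nn = std::sqrt(nn);
  if (nn <= 0.0) return false;
  for (int j = 0; j < d; ++j) normal[j] /= nn;
  offset = 0.0;
  for (int j = 0; j < d; ++j) offset += normal[j] * pts[v[0]][j];
  return true;
}

static double fact(int k) { double f = 1; for (int i = 2; i <= k; ++i) f *= i; return f; }

// [[Rcpp::export(name = ".convhull_cpp")]]
List convhull_cpp(NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  if (n == 0 || d == 0) stop("empty point set");
  std::vector<Vec> pts(n, Vec(d));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) pts[i][j] = X(i, j);

  if (d == 1) {
    int imin = 0, imax = 0;
    for (int i = 1; i < n; ++i) {
      if (pts[i][0] < pts[imin][0]) imin = i;
      if (pts[i][0] > pts[imax][0]) imax = i;
    }
    double vol = pts[imax][0] - pts[imin][0];
    bool degen = !(vol > 0.0);
    IntegerVector verts = degen ? IntegerVector::create(imin + 1)
                                : IntegerVector::create(imin + 1, imax + 1);
    return List::create(_["volume"] = degen ? 0.0 : vol,
                        _["vertices"] = verts, _["degenerate"] = degen);
  }

  // coordinate scale for tolerances
  double scale = 0.0;
  for (int j = 0; j < d; ++j) {
    double lo = pts[0][j], hi = pts[0][j];
    for (int i = 1; i < n; ++i) {
      if (pts[i][j] < lo) lo = pts[i][j];
      if (pts[i][j] > hi) hi = pts[i][j];
    }
    if (hi - lo > scale) scale = hi - lo;
  }
  if (scale <= 0.0)
    return List::create(_["volume"] = 0.0,
                        _["vertices"] = IntegerVector::create(1),
                        _["degenerate"] = true);
  double eps = 1e-9 * scale;

  // ---- initial affinely independent simplex (greedy Gram-Schmidt) ----
  IVec picked;
  picked.push_back(0);
  std::vector<Vec> basis; // orthonormal directions spanning picked - p0
  for (int step = 0; step < d; ++step) {
    double best = -1.0; int bi = -1; Vec bres;
    for (int i = 0; i < n; ++i) {
      Vec r(d);
      for (int j = 0; j < d; ++j) r[j] = pts[i][j] - pts[picked[0]][j];
      for (size_t b = 0; b < basis.size(); ++b) {
        double dp = 0.0;
        for (int j = 0; j < d; ++j) dp += r[j] * basis[b][j];
        for (int j = 0; j < d; ++j) r[j] -= dp * basis[b][j];
      }
      double nr = 0.0;
      for (int j = 0; j < d; ++j) nr += r[j] * r[j];
      nr = std::sqrt(nr);
      if (nr > best) { best = nr; bi = i; bres = r; }
    }
    if (best <= 1e-8 * scale) {
      // affinely dependent: flat in < d dimensions
      return List::create(_["volume"] = 0.0,
                          _["vertices"] = IntegerVector(0),
                          _["degenerate"] = true);
    }
    for (int j = 0; j < d; ++j) bres[j] /= best;
    basis.push_back(bres);
    picked.push_back(bi);
  }

  Vec interior(d, 0.0);
  for (size_t k = 0; k < picked.size(); ++k)
    for (int j = 0; j < d; ++j) interior[j] += pts[picked[k]][j];
  for (int j = 0; j < d; ++j) interior[j] /= (double)picked.size();

  std::vector<Facet> facets;
  for (int drop = 0; drop <= d; ++drop) {
    Facet f; f.alive = true;
    for (int k = 0; k <= d; ++k)
      if (k != drop) f.v.push_back(picked[k]);
    if (!facet_plane(pts, f.v, d, f.normal, f.offset))
      stop("degenerate initial simplex facet"); // cannot happen after rank check
    double val = -f.offset;
    for (int j = 0; j < d; ++j) val += f.normal[j] * interior[j];
    if (val > 0) {
      for (int j = 0; j < d; ++j) f.normal[j] = -f.normal[j];
      f.offset = -f.offset;
    }
    facets.push_back(f);
  }

  std::vector<bool> in_simplex(n, false);
  for (size_t k = 0; k < picked.size(); ++k) in_simplex[picked[k]] = true;

  // ---- incremental insertion ----
  for (int p = 0; p < n; ++p) {
    if (in_simplex[p]) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < facets.size(); ++f) {
      if (!facets[f].alive) continue;
      double val = -facets[f].offset;
      for (int j = 0; j < d; ++j) val += facets[f].normal[j] * pts[p][j];
      if (val > eps) visible.push_back((int)f);
    }
    if (visible.empty()) continue; // inside (or on) the current hull

    // horizon ridges: (d-1)-subsets occurring in exactly one visible facet
    std::map<IVec, std::pair<int, int> > ridges; // key -> (count, parent facet)
    for (size_t vi = 0; vi < visible.size(); ++vi) {
      const IVec &fv = facets[visible[vi]].v;
      for (int drop = 0; drop < d; ++drop) {
        IVec r;
        for (int k = 0; k < d; ++k)
          if (k != drop) r.push_back(fv[k]);
        std::sort(r.begin(), r.end());
        std::map<IVec, std::pair<int, int> >::iterator it = ridges.find(r);
        if (it == ridges.end()) ridges[r] = std::make_pair(1, visible[vi]);
        else it->second.first += 1;
      }
    }
    std::vector<Facet> newf;
    for (std::map<IVec, std::pair<int, int> >::iterator it = ridges.begin();
         it != ridges.end(); ++it) {
      if (it->second.first != 1) continue; // interior ridge
      Facet f; f.alive = true;
      f.v = it->first;
      f.v.push_back(p);
      if (!facet_plane(pts, f.v, d, f.normal, f.offset)) {
        // zero-area facet (p on the ridge's affine hull): inherit parent plane
        f.normal = facets[it->second.second].normal;
        f.offset = facets[it->second.second].offset;
      } else {
        double val = -f.offset;
        for (int j = 0; j < d; ++j) val += f.normal[j] * interior[j];
        if (val > 0) {
          for (int j = 0; j < d; ++j) f.normal[j] = -f.normal[j];
          f.offset = -f.offset;
        }
      }
      newf.push_back(f);
    }
    for (size_t vi = 0; vi < visible.size(); ++vi)
      facets[visible[vi]].alive = false;
    for (size_t k = 0; k < newf.size(); ++k) facets.push_back(newf[k]);
  }

  // ---- volume: fan of simplices from the interior point ----
  double vol = 0.0;
  std::set<int> vset;
  double dfac = fact(d);
  for (size_t f = 0; f < facets.size(); ++f) {
    if (!facets[f].alive) continue;
    std::vector<Vec> M(d, Vec(d));
    for (int i = 0; i < d; ++i)
      for (int j = 0; j < d; ++j)
        M[i][j] = pts[facets[f].v[i]][j] - interior[j];
    vol += std::fabs(det_inplace(M)) / dfac;
    for (int i = 0; i < d; ++i) vset.insert(facets[f].v[i]);
  }
  IntegerVector verts(vset.size());
  int k = 0;
  for (std::set<int>::iterator it = vset.begin(); it != vset.end(); ++it)
    verts[k++] = *it + 1;
  return List::create(_["volume"] = vol, _["vertices"] = verts,
                      _["degenerate"] = false);
}

// mean and sd (n-1 divisor) of nearest-neighbour Euclidean distances
// [[Rcpp::export(name = ".nnd_cpp")]]
NumericVector nnd_cpp(NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  if (n < 2) stop("need at least 2 points");
  std::vector<double> nn(n, R_PosInf);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double df = X(i, c) - X(j, c);
        s += df * df;
      }
      if (s < nn[i]) nn[i] = s;
      if (s < nn[j]) nn[j] = s;
    }
  double m = 0.0;
  for (int i = 0; i < n; ++i) { nn[i] = std::sqrt(nn[i]); m += nn[i]; }
  m /= n;
  double v = 0.0;
  for (int i = 0; i < n; ++i) v += (nn[i] - m) * (nn[i] - m);
  double sd = (n > 1) ? std::sqrt(v / (n - 1)) : 0.0;
  return NumericVector::create(m, sd);
}

// null distributions of (mNND, sdNND) for row-index permutations:
// idx is a reps x S matrix of 1-based row indices into coords
// [[Rcpp::export(name = ".nnd_null_cpp")]]
NumericMatrix nnd_null_cpp(NumericMatrix coords, IntegerMatrix idx) {
  int reps = idx.nrow(), S = idx.ncol(), d = coords.ncol();
  if (S < 2) stop("need at least 2 points");
  NumericMatrix out(reps, 2);
  std::vector<double> nn(S);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < S; ++i) nn[i] = R_PosInf;
    for (int i = 0; i < S; ++i) {
      int ri = idx(r, i) - 1;
      for (int j = i + 1; j < S; ++j) {
        int rj = idx(r, j) - 1;
        double s = 0.0;
        for (int c = 0; c < d; ++c) {
          double df = coords(ri, c) - coords(rj, c);
          s += df * df;
        }
        if (s < nn[i]) nn[i] = s;
        if (s < nn[j]) nn[j] = s;
      }
    }
    double m = 0.0;
    for (int i = 0; i < S; ++i) { nn[i] = std::sqrt(nn[i]); m += nn[i]; }
    m /= S;
    double v = 0.0;
    for (int i = 0; i < S; ++i) v += (nn[i] - m) * (nn[i] - m);
    out(r, 0) = m;
    out(r, 1) = (S > 1) ? std::sqrt(v / (S - 1)) : 0.0;
  }
  return out;
}
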