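// Exact 3D segment/polyline distance kernels and a uniform-grid spatial index.
// All coordinates are in nm. Polylines are n x 3 matrices of ordered points.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// Minimum distance between closed segments P0-P1 and Q0-Q1 (Eberly-style
// parameter clamping; degenerate point-segments handled).
static double seg_seg_dist(const double* P0, const double* P1,
                           const double* Q0, const double* Q1) {
  const double eps = 1e-14;
  double d1[3], d2[3], r[3];
  for (int i = 0; i < 3; ++i) {
    d1[i] = P1[i] - P0[i];
    d2[i] = Q1[i] - Q0[i];
    r[i]  = P0[i] - Q0[i];
  }
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  double s = 0.0, t = 0.0;
  if (a <= eps && e <= eps) {
    s = 0.0; t = 0.0;
  } else if (a <= eps) {
    s = 0.0; t = clamp01(f / e);
  } else {
    double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (e <= eps) {
      t = 0.0; s = clamp01(-c / a);
    } else {
      double b = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
      double denom = a*e - b*b;
      s = (denom > eps) ? clamp01((b*f - c*e) / denom) : 0.0;
      t = (b*s + f) / e;
      if (t < 0.0)      { t = 0.0; s = clamp01(-c / a); }
      else if (t > 1.0) { t = 1.0; s = clamp01((b - c) / a); }
    }
  }
  double dx = (P0[0] + s*d1[0]) - (Q0[0] + t*d2[0]);
  double dy = (P0[1] + s*d1[1]) - (Q0[1] + t*d2[1]);
  double dz = (P0[2] + s*d1[2]) - (Q0[2] + t*d2[2]);
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

static double point_seg_dist(const double* P,
                             const double* Q0, const double* Q1) {
  double d2[3], r[3];
  for (int i = 0; i < 3; ++i) {
    d2[i] = Q1[i] - Q0[i];
    r[i]  = P[i] - Q0[i];
  }
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double t = (e <= 1e-14) ? 0.0 : clamp01((d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2]) / e);
  double dx = r[0] - t*d2[0], dy = r[1] - t*d2[1], dz = r[2] - t*d2[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// [[Rcpp::export]]
double cpp_seg_seg_dist(NumericVector p0, NumericVector p1,
                        NumericVector q0, NumericVector q1) {
  return seg_seg_dist(p0.begin(), p1.begin(), q0.begin(), q1.begin());
}

static void get_point(const NumericMatrix& M, int i, double* out) {
  out[0] = M(i, 0); out[1] = M(i, 1); out[2] = M(i, 2);
}

// Min distance between two polylines: min over all segment pairs.
// [[Rcpp::export]]
double cpp_polyline_min_dist(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  double best = R_PosInf;
  double a0[3], a1[3], b0[3], b1[3];
  int segA = std::max(na - 1, 1), segB = std::max(nb - 1, 1);
  for (int i = 0; i < segA; ++i) {
    get_point(A, i, a0);
    get_point(A, std::min(i + 1, na - 1), a1);
    for (int j = 0; j < segB; ++j) {
      get_point(B, j, b0);
      get_point(B, std::min(j + 1, nb - 1), b1);
      double d = seg_seg_dist(a0, a1, b0, b1);
      if (d < best) best = d;
    }
  }
  return best;
}

// Distance from each row of P to polyline B (min over B's segments).
// [[Rcpp::export]]
NumericVector cpp_point_polyline_dist(NumericMatrix P, NumericMatrix B) {
  int np = P.nrow(), nb = B.nrow();
  NumericVector out(np);
  double p[3], b0[3], b1[3];
  int segB = std::max(nb - 1, 1);
  for (int i = 0; i < np; ++i) {
    get_point(P, i, p);
    double best = R_PosInf;
    for (int j = 0; j < segB; ++j) {
      get_point(B, j, b0);
      get_point(B, std::min(j + 1, nb - 1), b1);
      double d = point_seg_dist(p, b0, b1);
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// ---- flat segment store built from a list of polylines -------------------

struct SegStore {
  std::vector<double> s0, s1;  // 3*k coords
  std::vector<int> fil;        // polyline index (0-based) per segment
  int n() const { return (int)fil.size(); }
};

static SegStore build_segments(const List& polys) {
  SegStore st;
  for (int f = 0; f < polys.size(); ++f) {
    NumericMatrix M = polys[f];
    int n = M.nrow();
    int nseg = std::max(n - 1, 1);
    for (int i = 0; i < nseg; ++i) {
      int j = std::min(i + 1, n - 1);
      st.s0.push_back(M(i, 0)); st.s0.push_back(M(i, 1)); st.s0.push_back(M(i, 2));
      st.s1.push_back(M(j, 0)); st.s1.push_back(M(j, 1)); st.s1.push_back(M(j, 2));
      st.fil.push_back(f);
    }
  }
  return st;
}

// ---- uniform grid over segments ------------------------------------------

struct SegGrid {
  double cell, ox, oy, oz;
  std::unordered_map<int64_t, std::vector<int>> cells;
  static int64_t key(int64_t ix, int64_t iy, int64_t iz) {
    return (ix * 2097152LL + iy) * 2097152LL + iz;
  }
  int64_t ix(double x) const { return (int64_t)std::floor((x - ox) / cell); }
  int64_t iy(double y) const { return (int64_t)std::floor((y - oy) / cell); }
  int64_t iz(double z) const { return (int64_t)std::floor((z - oz) / cell); }
};

static SegGrid build_grid(const SegStore& st, double cell) {
  SegGrid g;
  g.cell = cell;
  g.ox = g.oy = g.oz = 0.0;
  double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int k = 0; k < st.n(); ++k) {
    for (int c = 0; c < 3; ++c) {
      mn[c] = std::min(mn[c], std::min(st.s0[3*k + c], st.s1[3*k + c]));
    }
  }
  if (st.n() > 0) { g.ox = mn[0]; g.oy = mn[1]; g.oz = mn[2]; }
  for (int k = 0; k < st.n(); ++k) {
    double lo[3], hi[3];
    for (int c = 0; c < 3; ++c) {
      lo[c] = std::min(st.s0[3*k + c], st.s1[3*k + c]);
      hi[c] = std::max(st.s0[3*k + c], st.s1[3*k + c]);
    }
    int64_t x0 = g.ix(lo[0]), x1 = g.ix(hi[0]);
    int64_t y0 = g.iy(lo[1]), y1 = g.iy(hi[1]);
    int64_t z0 = g.iz(lo[2]), z1 = g.iz(hi[2]);
    for (int64_t x = x0; x <= x1; ++x)
      for (int64_t y = y0; y <= y1; ++y)
        for (int64_t z = z0; z <= z1; ++z)
          g.cells[SegGrid::key(x, y, z)].push_back(k);
  }
  return g;
}

// Candidates for a point: segments registered in the 27-neighborhood of the
// point's cell. Complete for all segments within `cell` of the point.
static void point_candidates(const SegGrid& g, const double* p,
                             std::vector<int>& out) {
  out.clear();
  int64_t x = g.ix(p[0]), y = g.iy(p[1]), z = g.iz(p[2]);
  for (int64_t dx = -1; dx <= 1; ++dx)
    for (int64_t dy = -1; dy <= 1; ++dy)
      for (int64_t dz = -1; dz <= 1; ++dz) {
        auto it = g.cells.find(SegGrid::key(x + dx, y + dy, z + dz));
        if (it != g.cells.end())
          out.insert(out.end(), it->second.begin(), it->second.end());
      }
}

// Sparse point-to-filament distances. `pts` are query points with 0-based
// polyline index `pt_fil` (own filament excluded). Returns only entries with
// distance <= reach. With use_grid the grid cell is max(cell, reach), so
// results are exact and identical to the brute-force mode.
// [[Rcpp::export]]
DataFrame cpp_point_filament_dists(NumericMatrix pts, IntegerVector pt_fil,
                                   List polys, double reach, double cell,
                                   bool use_grid) {
  SegStore st = build_segments(polys);
  int nf = polys.size();
  int np = pts.nrow();
  std::vector<int> out_pt, out_fil;
  std::vector<double> out_d;
  std::vector<double> best(nf);
  double p[3];

  if (use_grid) {
    double c = std::max(cell, reach);
    SegGrid g = build_grid(st, c);
    std::vector<int> cand;
    for (int i = 0; i < np; ++i) {
      get_point(pts, i, p);
      std::fill(best.begin(), best.end(), R_PosInf);
      point_candidates(g, p, cand);
      for (int k : cand) {
        int f = st.fil[k];
        if (f == pt_fil[i]) continue;
        double d = point_seg_dist(p, &st.s0[3*k], &st.s1[3*k]);
        if (d < best[f]) best[f] = d;
      }
      for (int f = 0; f < nf; ++f)
        if (best[f] <= reach) {
          out_pt.push_back(i + 1); out_fil.push_back(f + 1);
          out_d.push_back(best[f]);
        }
    }
  } else {
    for (int i = 0; i < np; ++i) {
      get_point(pts, i, p);
      std::fill(best.begin(), best.end(), R_PosInf);
      for (int k = 0; k < st.n(); ++k) {
        int f = st.fil[k];
        if (f == pt_fil[i]) continue;
        double d = point_seg_dist(p, &st.s0[3*k], &st.s1[3*k]);
        if (d < best[f]) best[f] = d;
      }
      for (int f = 0; f < nf; ++f)
        if (best[f] <= reach) {
          out_pt.push_back(i + 1); out_fil.push_back(f + 1);
          out_d.push_back(best[f]);
        }
    }
  }
  return DataFrame::create(_["point"] = out_pt, _["filament"] = out_fil,
                           _["distance"] = out_d);
}

// Pairwise polyline min distances. Brute force gives the full exact matrix;
// grid mode gives exact entries <= reach and +Inf beyond (caller expands
// reach if a row needs it).
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_filament_dists(List polys, double reach,
                                          bool use_grid) {
  int nf = polys.size();
  NumericMatrix out(nf, nf);
  if (!use_grid) {
    for (int i = 0; i < nf; ++i) {
      for (int j = i + 1; j < nf; ++j) {
        double d = cpp_polyline_min_dist(polys[i], polys[j]);
        out(i, j) = d; out(j, i) = d;
      }
    }
    return out;
  }
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int i = 0; i < nf; ++i) out(i, i) = 0.0;
  SegStore st = build_segments(polys);
  SegGrid g = build_grid(st, reach);
  // For each segment, scan the 27-neighborhoods of all cells it overlaps.
  for (int k = 0; k < st.n(); ++k) {
    double lo[3], hi[3];
    for (int c = 0; c < 3; ++c) {
      lo[c] = std::min(st.s0[3*k + c], st.s1[3*k + c]);
      hi[c] = std::max(st.s0[3*k + c], st.s1[3*k + c]);
    }
    int64_t x0 = g.ix(lo[0]) - 1, x1 = g.ix(hi[0]) + 1;
    int64_t y0 = g.iy(lo[1]) - 1, y1 = g.iy(hi[1]) + 1;
    int64_t z0 = g.iz(lo[2]) - 1, z1 = g.iz(hi[2]) + 1;
    int fi = st.fil[k];
    for (int64_t x = x0; x <= x1; ++x)
      for (int64_t y = y0; y <= y1; ++y)
        for (int64_t z = z0; z <= z1; ++z) {
          auto it = g.cells.find(SegGrid::key(x, y, z));
          if (it == g.cells.end()) continue;
          for (int m : it->second) {
            int fj = st.fil[m];
            if (fj <= fi) continue;  // each unordered filament pair once
            double cur = out(fi, fj);
            double d = seg_seg_dist(&st.s0[3*k], &st.s1[3*k],
                                    &st.s0[3*m], &st.s1[3*m]);
            if (d < cur) { out(fi, fj) = d; out(fj, fi) = d; }
          }
        }
  }
  // entries beyond reach are not certified exact: reset them to +Inf
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < nf; ++j)
      if (i != j && out(i, j) > reach) out(i, j) = R_PosInf;
  return out;
}
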