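// Low-level image kernels shared by the morphometry modules.
// Array convention: R arrays arrive column-major; dims are (y, x) in 2D and
// (z, y, x) in 3D, so dim[0] is the fastest-varying index.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <map>
#include <utility>
using namespace Rcpp;

static const double BIG = 1e30;

// ---------------------------------------------------------------------------
// Connected components
// ---------------------------------------------------------------------------

// conn_level: 1 = faces only (4/6), 2 = faces+edges (8 in 2D, 18 in 3D),
// 3 = full (8 in 2D, 26 in 3D).
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(IntegerVector mask, IntegerVector dims, int conn_level) {
  int nd = dims.size();
  int d0 = dims[0], d1 = dims[1], d2 = (nd == 3) ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  std::vector<std::array<int, 3>> offs;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = (nd == 3 ? -1 : 0); c <= (nd == 3 ? 1 : 0); ++c) {
        int l1 = std::abs(a) + std::abs(b) + std::abs(c);
        if (l1 == 0 || l1 > conn_level) continue;
        offs.push_back({a, b, c});
      }
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i0 = cur % d0, i1 = (cur / d0) % d1, i2 = cur / ((R_xlen_t)d0 * d1);
      for (auto &o : offs) {
        int j0 = i0 + o[0], j1 = i1 + o[1], j2 = i2 + o[2];
        if (j0 < 0 || j0 >= d0 || j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2)
          continue;
        R_xlen_t j = j0 + (R_xlen_t)d0 * (j1 + (R_xlen_t)d1 * j2);
        if (mask[j] != 0 && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Anisotropic squared Euclidean distance transform (Felzenszwalb-Huttenlocher)
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -BIG; z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * h, s = 0;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared physical distance from every element to the nearest source element.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector src, IntegerVector dims,
                     NumericVector spacing) {
  int nd = dims.size();
  int d0 = dims[0], d1 = dims[1], d2 = (nd == 3) ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = src[i] ? 0.0 : BIG;
  std::vector<double> f, d;
  // pass along axis 0
  f.resize(d0); d.resize(d0);
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i1 = 0; i1 < d1; ++i1) {
      R_xlen_t base = (R_xlen_t)d0 * (i1 + (R_xlen_t)d1 * i2);
      for (int i = 0; i < d0; ++i) f[i] = out[base + i];
      dt1d(f, d, d0, spacing[0]);
      for (int i = 0; i < d0; ++i) out[base + i] = d[i];
    }
  // axis 1
  f.resize(d1); d.resize(d1);
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i0 = 0; i0 < d0; ++i0) {
      for (int i = 0; i < d1; ++i)
        f[i] = out[i0 + (R_xlen_t)d0 * (i + (R_xlen_t)d1 * i2)];
      dt1d(f, d, d1, spacing[1]);
      for (int i = 0; i < d1; ++i)
        out[i0 + (R_xlen_t)d0 * (i + (R_xlen_t)d1 * i2)] = d[i];
    }
  // axis 2
  if (nd == 3) {
    f.resize(d2); d.resize(d2);
    for (int i1 = 0; i1 < d1; ++i1)
      for (int i0 = 0; i0 < d0; ++i0) {
        for (int i = 0; i < d2; ++i)
          f[i] = out[i0 + (R_xlen_t)d0 * (i1 + (R_xlen_t)d1 * i)];
        dt1d(f, d, d2, spacing[2]);
        for (int i = 0; i < d2; ++i)
          out[i0 + (R_xlen_t)d0 * (i1 + (R_xlen_t)d1 * i)] = d[i];
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sub-pixel boundary contours: crack tracing -> midpoint polygon
// ---------------------------------------------------------------------------
// Cracks are unit pixel edges separating a foreground pixel from a background
// pixel; the midpoint of each crack is a contour vertex (equivalent to the
// 0.5-level marching-squares vertex on a binary image). At saddle corners the
// two cracks sharing the same *background* pixel are paired, which keeps
// diagonally touching foreground connected (8-connectivity convention).

struct Crack { double my, mx; int bg_r, bg_c; };

static void dp_rec(const std::vector<std::pair<double, double>> &pts, int i0,
                   int i1, double eps, std::vector<char> &keep) {
  if (i1 <= i0 + 1) return;
  double ax = pts[i0].second, ay = pts[i0].first;
  double bx = pts[i1].second, by = pts[i1].first;
  double dx = bx - ax, dy = by - ay;
  double nrm = std::sqrt(dx * dx + dy * dy);
  int worst = -1; double wd = -1;
  for (int i = i0 + 1; i < i1; ++i) {
    double d;
    if (nrm < 1e-12) {
      double ex = pts[i].second - ax, ey = pts[i].first - ay;
      d = std::sqrt(ex * ex + ey * ey);
    } else {
      d = std::fabs(dx * (ay - pts[i].first) - (ax - pts[i].second) * dy) / nrm;
    }
    if (d > wd) { wd = d; worst = i; }
  }
  if (wd > eps) {
    keep[worst] = 1;
    dp_rec(pts, i0, worst, eps, keep);
    dp_rec(pts, worst, i1, eps, keep);
  }
}

// Returns a list of closed polylines (matrices with columns y, x in pixel
// units, pixel centers at 0-based integer coordinates; first row == last row).
// eps <= 0 disables Douglas-Peucker simplification.
// [[Rcpp::export(name = ".trace_contours")]]
List trace_contours(LogicalVector mask, IntegerVector dims, double eps) {
  int nr = dims[0], nc = dims[1];
  auto at = [&](int r, int c) -> bool {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return false;
    return mask[r + (R_xlen_t)nr * c];
  };
  // corner lattice point (r,c) = pixel-corner at (r - 0.5, c - 0.5); each
  // crack joins two corners. key = corner r * (nc+1) + corner c.
  std::vector<Crack> cracks;
  std::map<long long, std::vector<int>> at_corner;
  auto corner_key = [&](int r, int c) { return (long long)r * (nc + 2) + c; };
  auto add_crack = [&](double my, double mx, int br, int bc, int r1, int c1,
                       int r2, int c2) {
    int id = cracks.size();
    cracks.push_back({my, mx, br, bc});
    at_corner[corner_key(r1, c1)].push_back(id);
    at_corner[corner_key(r2, c2)].push_back(id);
  };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!at(r, c)) continue;
      // vertical cracks (left/right of pixel) run between corners (r,c*) and
      // (r+1,c*); horizontal cracks between (r*,c) and (r*,c+1).
      if (!at(r, c - 1)) add_crack(r, c - 0.5, r, c - 1, r, c, r + 1, c);
      if (!at(r, c + 1)) add_crack(r, c + 0.5, r, c + 1, r, c + 1, r + 1, c + 1);
      if (!at(r - 1, c)) add_crack(r - 0.5, c, r - 1, c, r, c, r, c + 1);
      if (!at(r + 1, c)) add_crack(r + 0.5, c, r + 1, c, r + 1, c, r + 1, c + 1);
    }
  int ncr = cracks.size();
  // neighbor pairing at corners
  std::vector<std::array<int, 2>> nb(ncr, {-1, -1});
  auto link = [&](int a, int b) {
    if (nb[a][0] == -1) nb[a][0] = b; else nb[a][1] = b;
    if (nb[b][0] == -1) nb[b][0] = a; else nb[b][1] = a;
  };
  for (auto &kv : at_corner) {
    auto &v = kv.second;
    if (v.size() == 2) {
      link(v[0], v[1]);
    } else if (v.size() == 4) {
      // saddle: pair cracks sharing the same background pixel
      std::vector<int> used(4, 0);
      for (int i = 0; i < 4; ++i) {
        if (used[i]) continue;
        for (int j = i + 1; j < 4; ++j) {
          if (used[j]) continue;
          if (cracks[v[i]].bg_r == cracks[v[j]].bg_r &&
              cracks[v[i]].bg_c == cracks[v[j]].bg_c) {
            link(v[i], v[j]);
            used[i] = used[j] = 1;
            break;
          }
        }
      }
    }
  }
  // traverse cycles
  std::vector<char> seen(ncr, 0);
  List out;
  for (int s = 0; s < ncr; ++s) {
    if (seen[s]) continue;
    std::vector<std::pair<double, double>> loop;
    int prev = -1, cur = s;
    while (true) {
      seen[cur] = 1;
      loop.push_back({cracks[cur].my, cracks[cur].mx});
      int nxt = (nb[cur][0] != prev) ? nb[cur][0] : nb[cur][1];
      prev = cur; cur = nxt;
      if (cur == -1 || cur == s) break;
    }
    int m = loop.size();
    if (m < 2) continue;
    std::vector<int> keep_idx;
    if (eps > 0 && m > 4) {
      // closed loop: split at index 0 and the farthest vertex from it
      int far = 1; double best = -1;
      for (int i = 1; i < m; ++i) {
        double dy = loop[i].first - loop[0].first;
        double dx = loop[i].second - loop[0].second;
        double d = dy * dy + dx * dx;
        if (d > best) { best = d; far = i; }
      }
      std::vector<char> keep(m, 0);
      keep[0] = keep[far] = 1;
      dp_rec(loop, 0, far, eps, keep);
      std::vector<std::pair<double, double>> wrapped(loop.begin() + far,
                                                     loop.end());
      wrapped.push_back(loop[0]);
      std::vector<char> keep2(wrapped.size(), 0);
      keep2[0] = keep2[wrapped.size() - 1] = 1;
      dp_rec(wrapped, 0, wrapped.size() - 1, eps, keep2);
      for (int i = 0; i < m; ++i) if (keep[i]) keep_idx.push_back(i);
      for (size_t i = 1; i + 1 < wrapped.size(); ++i)
        if (keep2[i]) keep_idx.push_back(far + (int)i);
      std::sort(keep_idx.begin(), keep_idx.end());
    } else {
      for (int i = 0; i < m; ++i) keep_idx.push_back(i);
    }
    int k = keep_idx.size();
    NumericMatrix pm(k + 1, 2);
    for (int i = 0; i < k; ++i) {
      pm(i, 0) = loop[keep_idx[i]].first;
      pm(i, 1) = loop[keep_idx[i]].second;
    }
    pm(k, 0) = pm(0, 0); pm(k, 1) = pm(0, 1);
    out.push_back(pm);
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D homotopic thinning (distance-ordered, endpoint-preserving)
// ---------------------------------------------------------------------------

// simple-point test after Malandain & Bertrand: exactly one 26-component of
// foreground in the 26-neighborhood, and exactly one 6-component of
// background in the 18-neighborhood that touches a face neighbor.
static bool is_simple(const std::vector<char> &fg, int d0, int d1, int d2,
                      int i0, int i1, int i2) {
  char nbhd[27]; // local 3x3x3, index (a+1) + 3*(b+1) + 9*(c+1)
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        int j0 = i0 + a, j1 = i1 + b, j2 = i2 + c;
        bool v = false;
        if (j0 >= 0 && j0 < d0 && j1 >= 0 && j1 < d1 && j2 >= 0 && j2 < d2)
          v = fg[j0 + (R_xlen_t)d0 * (j1 + (R_xlen_t)d1 * j2)];
        nbhd[(a + 1) + 3 * (b + 1) + 9 * (c + 1)] = v;
      }
  // 26-components of FG in N26* (center excluded)
  int labels[27]; for (int i = 0; i < 27; ++i) labels[i] = 0;
  int ncomp_fg = 0;
  int stack[27], top;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nbhd[i] || labels[i]) continue;
    ++ncomp_fg;
    if (ncomp_fg > 1) break;
    labels[i] = ncomp_fg; top = 0; stack[top++] = i;
    while (top) {
      int cur = stack[--top];
      int ca = cur % 3, cb = (cur / 3) % 3, cc = cur / 9;
      for (int dc = -1; dc <= 1; ++dc)
        for (int db = -1; db <= 1; ++db)
          for (int da = -1; da <= 1; ++da) {
            int ja = ca + da, jb = cb + db, jc = cc + dc;
            if (ja < 0 || ja > 2 || jb < 0 || jb > 2 || jc < 0 || jc > 2)
              continue;
            int j = ja + 3 * jb + 9 * jc;
            if (j == 13 || !nbhd[j] || labels[j]) continue;
            labels[j] = ncomp_fg; stack[top++] = j;
          }
    }
  }
  if (ncomp_fg != 1) return false;
  // 6-components of BG within N18 touching a face neighbor of the center
  auto in18 = [](int a, int b, int c) {
    int l1 = std::abs(a - 1) + std::abs(b - 1) + std::abs(c - 1);
    return l1 >= 1 && l1 <= 2;
  };
  int blab[27]; for (int i = 0; i < 27; ++i) blab[i] = 0;
  int ncomp_bg = 0;
  for (int i = 0; i < 27; ++i) {
    int ca = i % 3, cb = (i / 3) % 3, cc = i / 9;
    if (!in18(ca, cb, cc) || nbhd[i] || blab[i]) continue;
    // seed only from face neighbors to count components 6-adjacent to center
    int l1 = std::abs(ca - 1) + std::abs(cb - 1) + std::abs(cc - 1);
    if (l1 != 1) continue;
    ++ncomp_bg;
    blab[i] = ncomp_bg; top = 0; stack[top++] = i;
    while (top) {
      int cur = stack[--top];
      int ua = cur % 3, ub = (cur / 3) % 3, uc = cur / 9;
      const int da[6] = {1, -1, 0, 0, 0, 0};
      const int db[6] = {0, 0, 1, -1, 0, 0};
      const int dc[6] = {0, 0, 0, 0, 1, -1};
      for (int k = 0; k < 6; ++k) {
        int ja = ua + da[k], jb = ub + db[k], jc = uc + dc[k];
        if (ja < 0 || ja > 2 || jb < 0 || jb > 2 || jc < 0 || jc > 2) continue;
        if (!in18(ja, jb, jc)) continue;
        int j = ja + 3 * jb + 9 * jc;
        if (nbhd[j] || blab[j]) continue;
        blab[j] = ncomp_bg; stack[top++] = j;
      }
    }
  }
  return ncomp_bg == 1;
}

static int n26_fg(const std::vector<char> &fg, int d0, int d1, int d2, int i0,
                  int i1, int i2) {
  int cnt = 0;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (!a && !b && !c) continue;
        int j0 = i0 + a, j1 = i1 + b, j2 = i2 + c;
        if (j0 < 0 || j0 >= d0 || j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2)
          continue;
        if (fg[j0 + (R_xlen_t)d0 * (j1 + (R_xlen_t)d1 * j2)]) ++cnt;
      }
  return cnt;
}

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask, IntegerVector dims,
                     NumericVector priority) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  std::vector<char> fg(n);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = mask[i];
  typedef std::pair<double, R_xlen_t> QE; // (priority, tiebreak counter<<32|idx)
  std::priority_queue<std::pair<std::pair<double, long long>, R_xlen_t>,
                      std::vector<std::pair<std::pair<double, long long>, R_xlen_t>>,
                      std::greater<>> pq;
  long long counter = 0;
  auto enqueue = [&](R_xlen_t i) {
    pq.push({{priority[i], counter++}, i});
  };
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!fg[i]) continue;
    int i0 = i % d0, i1 = (i / d0) % d1, i2 = i / ((R_xlen_t)d0 * d1);
    if (n26_fg(fg, d0, d1, d2, i0, i1, i2) < 26) enqueue(i);
  }
  while (!pq.empty()) {
    R_xlen_t i = pq.top().second; pq.pop();
    if (!fg[i]) continue;
    int i0 = i % d0, i1 = (i / d0) % d1, i2 = i / ((R_xlen_t)d0 * d1);
    if (n26_fg(fg, d0, d1, d2, i0, i1, i2) <= 1) continue; // endpoint
    if (!is_simple(fg, d0, d1, d2, i0, i1, i2)) continue;
    fg[i] = 0;
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a) {
          if (!a && !b && !c) continue;
          int j0 = i0 + a, j1 = i1 + b, j2 = i2 + c;
          if (j0 < 0 || j0 >= d0 || j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2)
            continue;
          R_xlen_t j = j0 + (R_xlen_t)d0 * (j1 + (R_xlen_t)d1 * j2);
          if (fg[j]) enqueue(j);
        }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (bool)fg[i];
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (3D, zero padding)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".gauss3d")]]
NumericVector gauss3d(NumericVector vol, IntegerVector dims, double sigma) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  int rad = std::max(1, (int)std::ceil(3 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (auto &k : ker) k /= s;
  NumericVector a(vol), b(n);
  auto pass = [&](NumericVector &src, NumericVector &dst, int axis) {
    int dd[3] = {d0, d1, d2};
    R_xlen_t stride = 1;
    for (int t = 0; t < axis; ++t) stride *= dd[t];
    int len = dd[axis];
    for (R_xlen_t i = 0; i < n; ++i) {
      int pos = (i / stride) % len;
      double acc = 0;
      for (int k = -rad; k <= rad; ++k) {
        int p = pos + k;
        if (p < 0 || p >= len) continue;
        acc += ker[k + rad] * src[i + (R_xlen_t)k * stride];
      }
      dst[i] = acc;
    }
  };
  pass(a, b, 0);
  pass(b, a, 1);
  pass(a, b, 2);
  return b;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra isosurface area
// ---------------------------------------------------------------------------

static double tri_area(const double *p, const double *q, const double *r) {
  double u[3] = {q[0] - p[0], q[1] - p[1], q[2] - p[2]};
  double v[3] = {r[0] - p[0], r[1] - p[1], r[2] - p[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// vol indexed (z,y,x) with dims (d0=z,d1=y,d2=x); spacing (sz,sy,sx) physical.
// [[Rcpp::export(name = ".mt_area")]]
double mt_area(NumericVector vol, IntegerVector dims, double level,
               NumericVector spacing) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  // cube corner offsets in (z,y,x); bit 0 -> +x? use (dz,dy,dx) explicit
  const int co[8][3] = {{0,0,0},{0,0,1},{0,1,0},{0,1,1},
                        {1,0,0},{1,0,1},{1,1,0},{1,1,1}};
  // 6 tetrahedra sharing diagonal 0-7 (equatorial cycle 1,3,2,6,4,5)
  const int tets[6][4] = {{0,1,3,7},{0,3,2,7},{0,2,6,7},
                          {0,6,4,7},{0,4,5,7},{0,5,1,7}};
  double total = 0;
  auto V = [&](int z, int y, int x) {
    return vol[z + (R_xlen_t)d0 * (y + (R_xlen_t)d1 * x)];
  };
  for (int x = 0; x + 1 < d2; ++x)
    for (int y = 0; y + 1 < d1; ++y)
      for (int z = 0; z + 1 < d0; ++z) {
        double cv[8]; double cp[8][3];
        bool any_hi = false, any_lo = false;
        for (int k = 0; k < 8; ++k) {
          cv[k] = V(z + co[k][0], y + co[k][1], x + co[k][2]);
          cp[k][0] = (z + co[k][0]) * sp[0];
          cp[k][1] = (y + co[k][1]) * sp[1];
          cp[k][2] = (x + co[k][2]) * sp[2];
          if (cv[k] > level) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int pos[4], npos = 0, neg[4], nneg = 0;
          for (int k = 0; k < 4; ++k) {
            if (cv[tv[k]] > level) pos[npos++] = tv[k];
            else neg[nneg++] = tv[k];
          }
          if (npos == 0 || npos == 4) continue;
          auto interp = [&](int a, int b, double *out) {
            double tfrac = (level - cv[a]) / (cv[b] - cv[a]);
            for (int d = 0; d < 3; ++d)
              out[d] = cp[a][d] + tfrac * (cp[b][d] - cp[a][d]);
          };
          if (npos == 1 || npos == 3) {
            int apex = (npos == 1) ? pos[0] : neg[0];
            int *others = (npos == 1) ? neg : pos;
            double p1[3], p2[3], p3[3];
            interp(apex, others[0], p1);
            interp(apex, others[1], p2);
            interp(apex, others[2], p3);
            total += tri_area(p1, p2, p3);
          } else { // 2-2: quad
            double q1[3], q2[3], q3[3], q4[3];
            interp(pos[0], neg[0], q1);
            interp(pos[0], neg[1], q2);
            interp(pos[1], neg[1], q3);
            interp(pos[1], neg[0], q4);
            total += tri_area(q1, q2, q3) + tri_area(q1, q3, q4);
          }
        }
      }
  return total;
}

// ---------------------------------------------------------------------------
// Maximum caliper (Feret) diameter over a point cloud
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".max_pairwise_dist")]]
double max_pairwise_dist(NumericMatrix pts) {
  int n = pts.nrow(), nc = pts.ncol();
  std::vector<int> idx;
  if (n > 3000) {
    // reduce to directional extremes (deterministic spherical Fibonacci set)
    std::vector<char> keep(n, 0);
    int ndir = 200;
    for (int d = 0; d < ndir; ++d) {
      double dir[3];
      if (nc == 3) {
        double phi = std::acos(1 - 2.0 * (d + 0.5) / ndir);
        double th = M_PI * (1 + std::sqrt(5.0)) * d;
        dir[0] = std::cos(phi);
        dir[1] = std::sin(phi) * std::cos(th);
        dir[2] = std::sin(phi) * std::sin(th);
      } else {
        dir[0] = std::cos(M_PI * d / ndir);
        dir[1] = std::sin(M_PI * d / ndir);
        dir[2] = 0;
      }
      int bi = 0, si = 0; double bv = -BIG, sv = BIG;
      for (int i = 0; i < n; ++i) {
        double pr = 0;
        for (int c = 0; c < nc; ++c) pr += dir[c] * pts(i, c);
        if (pr > bv) { bv = pr; bi = i; }
        if (pr < sv) { sv = pr; si = i; }
      }
      keep[bi] = keep[si] = 1;
    }
    for (int i = 0; i < n; ++i) if (keep[i]) idx.push_back(i);
  } else {
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
  }
  double best = 0;
  for (size_t i = 0; i < idx.size(); ++i)
    for (size_t j = i + 1; j < idx.size(); ++j) {
      double d = 0;
      for (int c = 0; c < nc; ++c) {
        double e = pts(idx[i], c) - pts(idx[j], c);
        d += e * e;
      }
      if (d > best) best = d;
    }
  return std::sqrt(best);
}
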