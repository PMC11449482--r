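#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Voxel indexing convention: R array with dim = c(nz, ny, nx), column-major,
// so linear index = z + nz * (y + ny * x), all 0-based in C++.

static inline long long vidx(int z, int y, int x, int nz, int ny) {
  return (long long)z + (long long)nz * ((long long)y + (long long)ny * x);
}

// 26-connected neighbor offsets
struct Neigh26 {
  int dz[26], dy[26], dx[26];
  Neigh26() {
    int k = 0;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dz[k] = a; dy[k] = b; dx[k] = c; ++k;
        }
  }
};
static const Neigh26 N26;

// ---------------------------------------------------------------------------
// Connected-component labeling, 26-connectivity, 3D logical mask
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cc_label_26(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const long long n = (long long)nz * ny * nx;
  if ((long long)mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<long long> stack;
  int cur = 0;
  for (long long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      long long v = stack.back(); stack.pop_back();
      int z = (int)(v % nz);
      long long r = v / nz;
      int y = (int)(r % ny);
      int x = (int)(r / ny);
      for (int k = 0; k < 26; ++k) {
        int zz = z + N26.dz[k], yy = y + N26.dy[k], xx = x + N26.dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        long long w = vidx(zz, yy, xx, nz, ny);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Component tree over a descending threshold sweep (incremental union-find).
// Node identity follows the larger component through merges; the smaller
// component closes with a parent link to the survivor.  Per-node MSER
// stability is evaluated online from a sliding window of volumes.
// ---------------------------------------------------------------------------

struct CTState {
  std::vector<int> uf_parent;   // union-find, -1 = voxel not yet added
  std::vector<int> uf_size;
  int find(int v) {
    int r = v;
    while (uf_parent[r] != r) r = uf_parent[r];
    while (uf_parent[v] != r) { int nx_ = uf_parent[v]; uf_parent[v] = r; v = nx_; }
    return r;
  }
};

// [[Rcpp::export]]
List ct_build_cpp(NumericVector vol, IntegerVector dims, NumericVector thr,
                  int delta_levels, double vmin, double vmax,
                  bool emit_records) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const long long n = (long long)nz * ny * nx;
  if ((long long)vol.size() != n) stop("volume length does not match dims");
  const int L = thr.size();
  if (L < 1) stop("need at least one threshold");
  for (int i = 1; i < L; ++i)
    if (thr[i] >= thr[i - 1]) stop("thresholds must be strictly decreasing");
  if (delta_levels < 1) stop("delta_levels must be >= 1");
  const int W = 2 * delta_levels + 1;   // volume history window width

  // entry level per voxel: first (highest) threshold the voxel reaches
  std::vector<int> entry(n);
  std::vector<long long> cnt(L + 1, 0);
  for (long long v = 0; v < n; ++v) {
    double x = vol[v];
    int e;
    if (x < thr[L - 1]) e = L;          // never enters
    else {
      // first index with thr[idx] <= x  (thr descending)
      int lo = 0, hi = L - 1;
      while (lo < hi) { int mid = (lo + hi) / 2; if (thr[mid] <= x) hi = mid; else lo = mid + 1; }
      e = lo;
    }
    entry[v] = e;
    cnt[e]++;
  }
  std::vector<long long> bucket_start(L + 2, 0);
  for (int l = 0; l <= L; ++l) bucket_start[l + 1] = bucket_start[l] + cnt[l];
  std::vector<int> order(n);
  { std::vector<long long> pos(bucket_start.begin(), bucket_start.end() - 1);
    for (long long v = 0; v < n; ++v) order[pos[entry[v]]++] = (int)v; }

  CTState st;
  st.uf_parent.assign(n, -1);
  st.uf_size.assign(n, 0);

  std::vector<int> node_of_root(n, -1);

  // node storage (0-based ids internally)
  std::vector<int> nd_birth, nd_parent, nd_rep, nd_close, nd_root;
  std::vector<int> nd_lastlev;                  // last level with recorded volume
  std::vector<int> nd_hist;                     // ring buffers, W per node
  std::vector<double> nd_best_stab;
  std::vector<int> nd_best_lev, nd_best_vol;
  std::vector<char> nd_alive;
  std::vector<int> alive;                       // alive node ids (may hold dead)

  std::vector<int> rec_node, rec_level, rec_vol;

  auto hist_get = [&](int nd, int level) -> int {
    // volume of node nd at 'level'; valid when nd_lastlev - W < level <= nd_lastlev
    return nd_hist[(size_t)nd * W + (level % W + W) % W];
  };
  auto hist_set = [&](int nd, int level, int volv) {
    nd_hist[(size_t)nd * W + (level % W + W) % W] = volv;
  };

  const double STAB_UNDEF = 1e300;

  auto finalize_level = [&](int nd, int j) {
    // evaluate MSER stability of node nd at level j (uses window around j)
    int b = nd_birth[nd], last = nd_lastlev[nd];
    if (j < b || j > last) return;
    int Vj = hist_get(nd, j);
    if (Vj < vmin || Vj > vmax) return;
    bool has_lo = (j - delta_levels >= b);
    bool has_hi = (j + delta_levels <= last);
    double stab;
    if (has_lo && has_hi)
      stab = (double)(hist_get(nd, j + delta_levels) - hist_get(nd, j - delta_levels)) / Vj;
    else if (has_hi)
      stab = (double)(hist_get(nd, j + delta_levels) - Vj) / Vj;
    else if (has_lo)
      stab = (double)(Vj - hist_get(nd, j - delta_levels)) / Vj;
    else
      stab = STAB_UNDEF;
    bool better = false;
    if (nd_best_lev[nd] < 0) better = true;
    else if (stab < nd_best_stab[nd]) better = true;
    else if (stab == nd_best_stab[nd]) {
      if (Vj < nd_best_vol[nd]) better = true;
      else if (Vj == nd_best_vol[nd] && j < nd_best_lev[nd]) better = true;
    }
    if (better) { nd_best_stab[nd] = stab; nd_best_lev[nd] = j; nd_best_vol[nd] = Vj; }
  };

  auto close_node = [&](int nd, int parent_nd, int level) {
    // node nd merges into parent_nd while processing 'level'; its last
    // existing level is level-1 (already recorded).  Finalize pending levels.
    nd_parent[nd] = parent_nd;
    nd_close[nd] = level;
    nd_alive[nd] = 0;
    int last = nd_lastlev[nd];
    for (int j = std::max(nd_birth[nd], last - delta_levels + 1); j <= last; ++j)
      finalize_level(nd, j);
  };

  std::vector<int> level_new;   // voxels added this level (candidate fresh roots)

  for (int l = 0; l < L; ++l) {
    level_new.clear();
    for (long long p = bucket_start[l]; p < bucket_start[l + 1]; ++p) {
      int v = order[p];
      st.uf_parent[v] = v;
      st.uf_size[v] = 1;
      level_new.push_back(v);
      int z = (int)(v % nz);
      long long r0 = v / nz;
      int y = (int)(r0 % ny);
      int x = (int)(r0 / ny);
      for (int k = 0; k < 26; ++k) {
        int zz = z + N26.dz[k], yy = y + N26.dy[k], xx = x + N26.dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        long long w = vidx(zz, yy, xx, nz, ny);
        if (st.uf_parent[w] < 0) continue;     // neighbor not yet in
        int ra = st.find(v), rb = st.find((int)w);
        if (ra == rb) continue;
        int na = node_of_root[ra], nb = node_of_root[rb];
        // union by size; survivor keeps identity
        int keep = (st.uf_size[ra] >= st.uf_size[rb]) ? ra : rb;
        int lose = (keep == ra) ? rb : ra;
        st.uf_parent[lose] = keep;
        st.uf_size[keep] += st.uf_size[lose];
        int nkeep;
        if (na >= 0 && nb >= 0) {
          // two mature components merge: larger keeps its node
          int nwin = (keep == ra) ? na : nb;
          int nlos = (keep == ra) ? nb : na;
          close_node(nlos, nwin, l);
          nkeep = nwin;
        } else if (na >= 0) nkeep = na;
        else if (nb >= 0) nkeep = nb;
        else nkeep = -1;
        node_of_root[keep] = nkeep;
        if (nkeep >= 0) nd_root[nkeep] = keep;
      }
    }
    // create nodes for fresh roots that survived the level
    for (int v : level_new) {
      if (st.find(v) != v) continue;
      if (node_of_root[v] >= 0) continue;      // mature node took this root
      int nd = (int)nd_birth.size();
      nd_birth.push_back(l);
      nd_parent.push_back(-1);
      nd_rep.push_back(v);
      nd_close.push_back(-1);
      nd_root.push_back(v);
      nd_lastlev.push_back(l - 1);             // set below when recording
      nd_hist.resize(nd_hist.size() + W, 0);
      nd_best_stab.push_back(STAB_UNDEF);
      nd_best_lev.push_back(-1);
      nd_best_vol.push_back(0);
      nd_alive.push_back(1);
      alive.push_back(nd);
      node_of_root[v] = nd;
    }
    // record volumes for all alive nodes; finalize level l - delta
    size_t out = 0;
    for (size_t i = 0; i < alive.size(); ++i) {
      int nd = alive[i];
      if (!nd_alive[nd]) continue;
      alive[out++] = nd;
      int sz = st.uf_size[st.find(nd_root[nd])];
      hist_set(nd, l, sz);
      nd_lastlev[nd] = l;
      if (emit_records) {
        rec_node.push_back(nd + 1);
        rec_level.push_back(l + 1);
        rec_vol.push_back(sz);
      }
      int j = l - delta_levels;
      if (j >= nd_birth[nd]) finalize_level(nd, j);
    }
    alive.resize(out);
  }
  // end of sweep: finalize trailing levels of surviving nodes
  for (int nd : alive) {
    if (!nd_alive[nd]) continue;
    int last = nd_lastlev[nd];
    for (int j = std::max(nd_birth[nd], last - delta_levels + 1); j <= last; ++j)
      finalize_level(nd, j);
  }

  int nnode = (int)nd_birth.size();
  IntegerVector birth(nnode), parent(nnode), rep(nnode), close_lv(nnode),
      best_lev(nnode), best_vol(nnode), last_lev(nnode);
  NumericVector best_stab(nnode);
  for (int i = 0; i < nnode; ++i) {
    birth[i] = nd_birth[i] + 1;
    parent[i] = nd_parent[i] + 1;              // 0 = none
    rep[i] = nd_rep[i] + 1;                    // 1-based voxel index
    close_lv[i] = nd_close[i] + 1;             // 0 = never closed
    best_lev[i] = nd_best_lev[i] + 1;          // 0 = no in-band level
    best_vol[i] = nd_best_vol[i];
    best_stab[i] = nd_best_stab[i];
    last_lev[i] = nd_lastlev[i] + 1;
  }
  List nodes = List::create(
      _["birth_level"] = birth, _["parent"] = parent, _["rep_voxel"] = rep,
      _["close_level"] = close_lv, _["last_level"] = last_lev,
      _["best_level"] = best_lev, _["best_volume"] = best_vol,
      _["best_stability"] = best_stab);
  if (emit_records) {
    return List::create(_["nodes"] = nodes,
                        _["records"] = List::create(
                            _["node"] = wrap(rec_node),
                            _["level"] = wrap(rec_level),
                            _["volume"] = wrap(rec_vol)));
  }
  return List::create(_["nodes"] = nodes);
}

// ---------------------------------------------------------------------------
// Paint selected tree nodes: flood fill from each seed at its threshold.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector ct_paint_cpp(NumericVector vol, IntegerVector dims,
                           IntegerVector seeds, NumericVector thresholds,
                           IntegerVector labels) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const long long n = (long long)nz * ny * nx;
  IntegerVector out(n, 0);
  std::vector<long long> stack;
  for (int i = 0; i < seeds.size(); ++i) {
    long long s = (long long)seeds[i] - 1;
    double t = thresholds[i];
    int lab = labels[i];
    if (s < 0 || s >= n) stop("seed out of range");
    if (vol[s] < t) stop("seed voxel below its threshold");
    if (out[s] != 0) stop("selected regions overlap");
    out[s] = lab;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      long long v = stack.back(); stack.pop_back();
      int z = (int)(v % nz);
      long long r = v / nz;
      int y = (int)(r % ny);
      int x = (int)(r / ny);
      for (int k = 0; k < 26; ++k) {
        int zz = z + N26.dz[k], yy = y + N26.dy[k], xx = x + N26.dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        long long w = vidx(zz, yy, xx, nz, ny);
        if (vol[w] >= t && out[w] == 0) { out[w] = lab; stack.push_back(w); }
        else if (vol[w] >= t && out[w] != lab && out[w] != 0)
          stop("selected regions overlap");
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Per-ROI 3D morphological opening with a ball structuring element.
// Returns the opened label volume; opening is anti-extensive so each opened
// ROI stays inside its original voxel set.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector open_labels_ball_cpp(IntegerVector labels, IntegerVector dims,
                                   int radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const long long n = (long long)nz * ny * nx;
  if (radius < 1) stop("radius must be >= 1");
  // ball offsets
  std::vector<int> bz, by, bx;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      for (int c = -radius; c <= radius; ++c)
        if (a * a + b * b + c * c <= radius * radius) {
          bz.push_back(a); by.push_back(b); bx.push_back(c);
        }
  const int nb = (int)bz.size();

  int maxlab = 0;
  for (long long v = 0; v < n; ++v) if (labels[v] > maxlab) maxlab = labels[v];
  if (maxlab == 0) { IntegerVector out(n, 0); out.attr("dim") = dims; return out; }

  // bounding boxes
  std::vector<int> z0(maxlab + 1, nz), z1(maxlab + 1, -1), y0(maxlab + 1, ny),
      y1(maxlab + 1, -1), x0(maxlab + 1, nx), x1(maxlab + 1, -1);
  for (long long v = 0; v < n; ++v) {
    int lab = labels[v];
    if (lab == 0) continue;
    int z = (int)(v % nz);
    long long r = v / nz;
    int y = (int)(r % ny);
    int x = (int)(r / ny);
    if (z < z0[lab]) z0[lab] = z; if (z > z1[lab]) z1[lab] = z;
    if (y < y0[lab]) y0[lab] = y; if (y > y1[lab]) y1[lab] = y;
    if (x < x0[lab]) x0[lab] = x; if (x > x1[lab]) x1[lab] = x;
  }

  IntegerVector out(n, 0);
  for (int lab = 1; lab <= maxlab; ++lab) {
    if (z1[lab] < 0) continue;
    int sz = z1[lab] - z0[lab] + 1, sy = y1[lab] - y0[lab] + 1,
        sx = x1[lab] - x0[lab] + 1;
    long long m = (long long)sz * sy * sx;
    std::vector<char> mask(m, 0), ero(m, 0);
    auto midx = [&](int z, int y, int x) {
      return (long long)(z - z0[lab]) +
             (long long)sz * ((long long)(y - y0[lab]) +
                              (long long)sy * (x - x0[lab]));
    };
    for (int x = x0[lab]; x <= x1[lab]; ++x)
      for (int y = y0[lab]; y <= y1[lab]; ++y)
        for (int z = z0[lab]; z <= z1[lab]; ++z)
          if (labels[vidx(z, y, x, nz, ny)] == lab) mask[midx(z, y, x)] = 1;
    // erosion: keep voxel iff whole ball inside mask (outside bbox = background)
    for (int x = x0[lab]; x <= x1[lab]; ++x)
      for (int y = y0[lab]; y <= y1[lab]; ++y)
        for (int z = z0[lab]; z <= z1[lab]; ++z) {
          if (!mask[midx(z, y, x)]) continue;
          bool keep = true;
          for (int k = 0; k < nb && keep; ++k) {
            int zz = z + bz[k], yy = y + by[k], xx = x + bx[k];
            if (zz < z0[lab] || zz > z1[lab] || yy < y0[lab] || yy > y1[lab] ||
                xx < x0[lab] || xx > x1[lab] || !mask[midx(zz, yy, xx)])
              keep = false;
          }
          if (keep) ero[midx(z, y, x)] = 1;
        }
    // dilation of the erosion
    for (int x = x0[lab]; x <= x1[lab]; ++x)
      for (int y = y0[lab]; y <= y1[lab]; ++y)
        for (int z = z0[lab]; z <= z1[lab]; ++z) {
          if (!ero[midx(z, y, x)]) continue;
          for (int k = 0; k < nb; ++k) {
            int zz = z + bz[k], yy = y + by[k], xx = x + bx[k];
            if (zz < z0[lab] || zz > z1[lab] || yy < y0[lab] || yy > y1[lab] ||
                xx < x0[lab] || xx > x1[lab]) continue;
            out[vidx(zz, yy, xx, nz, ny)] = lab;
          }
        }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Per-slice (2D) median filter with a disk footprint.  Window is clipped at
// image borders; even-sized windows use the mean of the two middle values,
// matching stats::median.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector median_disk_cpp(NumericVector vol, IntegerVector dims, int radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const long long n = (long long)nz * ny * nx;
  if (radius < 1) stop("radius must be >= 1");
  std::vector<int> oy, ox;
  for (int b = -radius; b <= radius; ++b)
    for (int c = -radius; c <= radius; ++c)
      if (b * b + c * c <= radius * radius) { oy.push_back(b); ox.push_back(c); }
  const int nb = (int)oy.size();
  // precomputed slice-local offsets for the interior fast path
  std::vector<long long> off(nb);
  for (int k = 0; k < nb; ++k) off[k] = (long long)oy[k] + (long long)ny * ox[k];
  NumericVector out(n);
  std::vector<double> slice((size_t)ny * nx), buf(nb);
  auto med_of = [&](int m) {
    std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
    double med = buf[m / 2];
    if (m % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
      med = 0.5 * (med + lo);
    }
    return med;
  };
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        slice[(size_t)y + (size_t)ny * x] = vol[vidx(z, y, x, nz, ny)];
    for (int x = 0; x < nx; ++x) {
      bool xin = (x >= radius && x < nx - radius);
      for (int y = 0; y < ny; ++y) {
        double med;
        if (xin && y >= radius && y < ny - radius) {
          const double *c = &slice[(size_t)y + (size_t)ny * x];
          for (int k = 0; k < nb; ++k) buf[k] = c[off[k]];
          med = med_of(nb);
        } else {
          int m = 0;
          for (int k = 0; k < nb; ++k) {
            int yy = y + oy[k], xx = x + ox[k];
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            buf[m++] = slice[(size_t)yy + (size_t)ny * xx];
          }
          med = med_of(m);
        }
        out[vidx(z, y, x, nz, ny)] = med;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Separable 3D Gaussian blur (zero padding), sigma in voxels per axis.
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double> &a, int nz, int ny, int nx,
                      double sigma, int axis) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (auto &v : k) v /= s;
  std::vector<double> line(std::max(nz, std::max(ny, nx)));
  int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
  if (axis == 0) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) line[z] = a[vidx(z, y, x, nz, ny)];
        for (int z = 0; z < nz; ++z) {
          double acc = 0;
          for (int i = -r; i <= r; ++i) {
            int zz = z + i;
            if (zz >= 0 && zz < len) acc += k[i + r] * line[zz];
          }
          a[vidx(z, y, x, nz, ny)] = acc;
        }
      }
  } else if (axis == 1) {
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) line[y] = a[vidx(z, y, x, nz, ny)];
        for (int y = 0; y < ny; ++y) {
          double acc = 0;
          for (int i = -r; i <= r; ++i) {
            int yy = y + i;
            if (yy >= 0 && yy < len) acc += k[i + r] * line[yy];
          }
          a[vidx(z, y, x, nz, ny)] = acc;
        }
      }
  } else {
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        for (int x = 0; x < nx; ++x) line[x] = a[vidx(z, y, x, nz, ny)];
        for (int x = 0; x < nx; ++x) {
          double acc = 0;
          for (int i = -r; i <= r; ++i) {
            int xx = x + i;
            if (xx >= 0 && xx < len) acc += k[i + r] * line[xx];
          }
          a[vidx(z, y, x, nz, ny)] = acc;
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector gauss_blur3_cpp(NumericVector vol, IntegerVector dims,
                              NumericVector sigma_vox) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const long long n = (long long)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end());
  blur_axis(a, nz, ny, nx, sigma_vox[0], 0);
  blur_axis(a, nz, ny, nx, sigma_vox[1], 1);
  blur_axis(a, nz, ny, nx, sigma_vox[2], 2);
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Per-slice (2D) grayscale erosion/dilation with a disk structuring element,
// window clipped at image borders: op 0 = erode (min), 1 = dilate (max).
// Decomposed into per-row horizontal runs of the disk for speed.
// ---------------------------------------------------------------------------

// 1-D min/max filter of half-width w along a contiguous line (monotonic deque)
static void line_minmax(const double *in, double *out, int n, int w, bool mx) {
  std::deque<int> q;   // indices, values monotonic
  for (int i = 0; i < n + w; ++i) {
    if (i < n) {
      while (!q.empty() &&
             (mx ? in[q.back()] <= in[i] : in[q.back()] >= in[i]))
        q.pop_back();
      q.push_back(i);
    }
    int c = i - w;                 // output centre index
    if (c >= 0) {
      while (q.front() < c - w) q.pop_front();
      out[c] = in[q.front()];
    }
  }
}

// [[Rcpp::export]]
NumericVector gray_disk_cpp(NumericVector vol, IntegerVector dims, int radius,
                            int op) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  if (radius < 1) stop("radius must be >= 1");
  // horizontal half-width of the disk at each dy
  std::vector<int> hw(2 * radius + 1);
  for (int dy = -radius; dy <= radius; ++dy)
    hw[dy + radius] = (int)std::floor(std::sqrt((double)radius * radius - dy * dy));
  const bool mx = (op == 1);
  NumericVector out((long long)nz * ny * nx);
  std::vector<double> slice((size_t)ny * nx);            // [y + ny*x] layout
  std::vector<double> line(ny), lineo(ny);
  // rowf[w]: per half-width 1-D filtered slice along y (the contiguous axis)
  std::vector<std::vector<double>> rowf(radius + 1,
                                        std::vector<double>((size_t)ny * nx));
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        slice[(size_t)y + (size_t)ny * x] = vol[vidx(z, y, x, nz, ny)];
    for (int w = 0; w <= radius; ++w)
      for (int x = 0; x < nx; ++x) {
        const double *in = &slice[(size_t)ny * x];
        double *o = &rowf[w][(size_t)ny * x];
        if (w == 0) std::copy(in, in + ny, o);
        else line_minmax(in, o, ny, w, mx);
      }
    // combine across dx with the disk's per-column half-widths (disk is
    // symmetric, so filtering y first then combining x is equivalent)
    for (int x = 0; x < nx; ++x) {
      double *o = &slice[0];       // reuse as output row buffer per x
      for (int y = 0; y < ny; ++y) {
        double acc = mx ? R_NegInf : R_PosInf;
        for (int dx = -radius; dx <= radius; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          double v = rowf[hw[dx + radius]][(size_t)y + (size_t)ny * xx];
          if (mx ? (v > acc) : (v < acc)) acc = v;
        }
        out[vidx(z, y, x, nz, ny)] = acc;
      }
      (void)o;
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// 3D grayscale morphology with a ball element (optional 3-D filtering mode):
// op 0 = erode (min), 1 = dilate (max), 2 = median.  Out-of-volume voxels are
// ignored (window clipped at the border).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector gray_ball_cpp(NumericVector vol, IntegerVector dims, int radius,
                            int op) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const long long n = (long long)nz * ny * nx;
  if (radius < 1) stop("radius must be >= 1");
  std::vector<int> bz, by, bx;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      for (int c = -radius; c <= radius; ++c)
        if (a * a + b * b + c * c <= radius * radius) {
          bz.push_back(a); by.push_back(b); bx.push_back(c);
        }
  const int nb = (int)bz.size();
  NumericVector out(n);
  std::vector<double> buf(nb);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int m = 0;
        double acc = (op == 0) ? R_PosInf : R_NegInf;
        for (int k = 0; k < nb; ++k) {
          int zz = z + bz[k], yy = y + by[k], xx = x + bx[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          double v = vol[vidx(zz, yy, xx, nz, ny)];
          if (op == 0) { if (v < acc) acc = v; }
          else if (op == 1) { if (v > acc) acc = v; }
          else buf[m++] = v;
        }
        if (op == 2) {
          std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
          acc = buf[m / 2];
          if (m % 2 == 0) {
            double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
            acc = 0.5 * (acc + lo);
          }
        }
        out[vidx(z, y, x, nz, ny)] = acc;
      }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Fast per-label statistics: volume, channel sums, coordinate sums, border.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List label_stats_cpp(IntegerVector labels, IntegerVector dims,
                     NumericVector donor, NumericVector acceptor) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const long long n = (long long)nz * ny * nx;
  int maxlab = 0;
  for (long long v = 0; v < n; ++v) if (labels[v] > maxlab) maxlab = labels[v];
  NumericVector s670(maxlab), s720(maxlab), sz_(maxlab), sy_(maxlab), sx_(maxlab);
  IntegerVector cnt(maxlab);
  LogicalVector border(maxlab);
  for (long long v = 0; v < n; ++v) {
    int lab = labels[v];
    if (lab == 0) continue;
    int z = (int)(v % nz);
    long long r = v / nz;
    int y = (int)(r % ny);
    int x = (int)(r / ny);
    cnt[lab - 1]++;
    s670[lab - 1] += donor[v];
    s720[lab - 1] += acceptor[v];
    sz_[lab - 1] += z; sy_[lab - 1] += y; sx_[lab - 1] += x;
    if (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 || x == 0 || x == nx - 1)
      border[lab - 1] = true;
  }
  return List::create(_["volume"] = cnt, _["sum_670"] = s670, _["sum_720"] = s720,
                      _["sum_z"] = sz_, _["sum_y"] = sy_, _["sum_x"] = sx_,
                      _["touches_border"] = border);
}
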