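// SLEUTH-style cellular automaton kernels plus raster helpers
// (connected-component labelling, edge-cell counts, exact segment-grid
// clipping). All randomness comes from R's RNG stream so set.seed() at the
// R level fully determines a trajectory. The CA keeps an incrementally
// updated urban-neighbor-count array so the annual edge-growth sweep is a
// flat scan instead of an 8-neighbor gather.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

struct Coeffs {
  double disp, breed, spread, slope_res, road_grav;
};

static Coeffs as_coeffs(const NumericVector& v) {
  if (v.size() != 5) stop("coefficient vector must have length 5");
  Coeffs k;
  k.disp = v[0]; k.breed = v[1]; k.spread = v[2];
  k.slope_res = v[3]; k.road_grav = v[4];
  return k;
}

// round-half-even, matching R's round()
static inline double rhe(double x) { return std::nearbyint(x); }

static inline double disp_value(double disp, int nr, int nc) {
  return rhe(0.005 * disp * std::sqrt((double)nr * nr + (double)nc * nc));
}

static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// pick two distinct indices in [0, 8)
static inline void two_distinct_neighbors(int& i1, int& i2) {
  i1 = rand_below(8);
  i2 = rand_below(7);
  if (i2 >= i1) ++i2;
}

static inline bool slope_ok(double s, double slope_res, double crit) {
  if (s >= crit) return false;
  if (slope_res <= 0.0) return true;
  double rej = std::pow(s / crit, slope_res / 25.0);
  return unif_rand() >= rej;
}

struct CAGrid {
  int nr, nc, pop;
  std::vector<int> urban;  // column-major 0/1
  std::vector<int> nb;     // urban Moore neighbors per cell
  const double* slope;
  const double* excl;
  const double* roads;

  inline int idx(int r, int c) const { return c * nr + r; }
  inline bool inb(int r, int c) const {
    return r >= 0 && r < nr && c >= 0 && c < nc;
  }
  void init(const IntegerMatrix& u, const NumericMatrix& s,
            const NumericMatrix& e, const NumericMatrix* rd) {
    nr = u.nrow(); nc = u.ncol();
    urban.assign(u.begin(), u.end());
    slope = s.begin(); excl = e.begin();
    roads = rd ? rd->begin() : (const double*)0;
    pop = 0;
    nb.assign((size_t)nr * nc, 0);
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        if (urban[idx(r, c)]) { ++pop; bump(r, c); }
  }
  void bump(int r, int c) {
    for (int j = 0; j < 8; ++j) {
      int r2 = r + DR[j], c2 = c + DC[j];
      if (inb(r2, c2)) ++nb[idx(r2, c2)];
    }
  }
  inline void mark(int r, int c) {
    urban[idx(r, c)] = 1;
    ++pop;
    bump(r, c);
  }
  IntegerMatrix urban_matrix() const {
    IntegerMatrix out(nr, nc);
    std::copy(urban.begin(), urban.end(), out.begin());
    return out;
  }
};

// shared urbanization gate: already-urban and fully excluded cells never
// flip; otherwise reject with probability exclusion/100, then apply the
// slope test; on acceptance the cell is marked urban in place.
static inline bool attempt(CAGrid& g, int r, int c, double slope_res,
                           double crit) {
  int i = g.idx(r, c);
  if (g.urban[i]) return false;
  double e = g.excl[i];
  if (e >= 100.0) return false;
  if (e > 0.0 && unif_rand() < e / 100.0) return false;
  if (!slope_ok(g.slope[i], slope_res, crit)) return false;
  g.mark(r, c);
  return true;
}

typedef std::vector<int> ivec;

static void phase_spontaneous(CAGrid& g, const Coeffs& k, double crit,
                              ivec& rr, ivec& cc) {
  int natt = (int)disp_value(k.disp, g.nr, g.nc);
  for (int i = 0; i < natt; ++i) {
    int r = rand_below(g.nr), c = rand_below(g.nc);
    if (attempt(g, r, c, k.slope_res, crit)) {
      rr.push_back(r); cc.push_back(c);
    }
  }
}

static void phase_spreading(CAGrid& g, const Coeffs& k, double crit,
                            const ivec& sr, const ivec& sc, ivec& rr,
                            ivec& cc) {
  if (k.breed <= 0.0) return;
  for (size_t i = 0; i < sr.size(); ++i) {
    if (unif_rand() >= k.breed / 100.0) continue;
    int i1, i2;
    two_distinct_neighbors(i1, i2);
    const int idx2[2] = {i1, i2};
    for (int j = 0; j < 2; ++j) {
      int r = sr[i] + DR[idx2[j]], c = sc[i] + DC[idx2[j]];
      if (!g.inb(r, c)) continue;
      if (attempt(g, r, c, k.slope_res, crit)) {
        rr.push_back(r); cc.push_back(c);
      }
    }
  }
}

// synchronous: candidacy uses the urban set at the start of the phase
static void phase_edge(CAGrid& g, const Coeffs& k, double crit,
                       int nb_threshold, ivec& rr, ivec& cc) {
  if (k.spread <= 0.0) return;
  std::vector<int> usnap(g.urban), nbsnap(g.nb);
  double p = k.spread / 100.0;
  size_t n = usnap.size();
  for (size_t i = 0; i < n; ++i) {
    if (usnap[i] || nbsnap[i] < nb_threshold) continue;
    if (unif_rand() >= p) continue;
    int r = (int)(i % g.nr), c = (int)(i / g.nr);
    if (attempt(g, r, c, k.slope_res, crit)) {
      rr.push_back(r); cc.push_back(c);
    }
  }
}

static void phase_road(CAGrid& g, const Coeffs& k, double crit,
                       const ivec& sr, const ivec& sc, ivec& rr, ivec& cc) {
  if (!g.roads) return;
  double rsearch = k.road_grav / 100.0 * (double)(g.nr + g.nc) / 16.0;
  if (rsearch <= 0.0 || k.breed <= 0.0) return;
  int R = (int)std::floor(rsearch);
  double r2max = rsearch * rsearch;
  int base_steps = (int)disp_value(k.disp, g.nr, g.nc);
  for (size_t i = 0; i < sr.size(); ++i) {
    if (unif_rand() >= k.breed / 100.0) continue;
    int r0 = sr[i], c0 = sc[i];
    // nearest road cell within the search radius (first hit on ties)
    int br = -1, bc = -1;
    double bd = r2max + 1.0;
    for (int dr = -R; dr <= R; ++dr) {
      int r = r0 + dr;
      if (r < 0 || r >= g.nr) continue;
      for (int dc = -R; dc <= R; ++dc) {
        int c = c0 + dc;
        if (c < 0 || c >= g.nc) continue;
        if (g.roads[g.idx(r, c)] <= 0.0) continue;
        double d2 = (double)dr * dr + (double)dc * dc;
        if (d2 <= r2max && d2 < bd) { bd = d2; br = r; bc = c; }
      }
    }
    if (br < 0) continue;
    // random walk along Moore-connected road cells; higher-weight roads
    // carry the walk further
    int steps = (int)rhe(base_steps * g.roads[g.idx(br, bc)]);
    int cr = br, ccur = bc;
    for (int s = 0; s < steps; ++s) {
      int cand[8], ncand = 0;
      for (int j = 0; j < 8; ++j) {
        int r = cr + DR[j], c = ccur + DC[j];
        if (!g.inb(r, c)) continue;
        if (g.roads[g.idx(r, c)] > 0.0) cand[ncand++] = j;
      }
      if (!ncand) break;
      int pick = rand_below(ncand);
      cr += DR[cand[pick]]; ccur += DC[cand[pick]];
    }
    // try one random neighbor of the walk terminus; a success seeds a new
    // nucleus that tries two further neighbors of its own
    int j = rand_below(8);
    int r1 = cr + DR[j], c1 = ccur + DC[j];
    if (!g.inb(r1, c1)) continue;
    if (!attempt(g, r1, c1, k.slope_res, crit)) continue;
    rr.push_back(r1); cc.push_back(c1);
    int i1, i2;
    two_distinct_neighbors(i1, i2);
    const int idx2[2] = {i1, i2};
    for (int q = 0; q < 2; ++q) {
      int r2 = r1 + DR[idx2[q]], c2 = c1 + DC[idx2[q]];
      if (!g.inb(r2, c2)) continue;
      if (attempt(g, r2, c2, k.slope_res, crit)) {
        rr.push_back(r2); cc.push_back(c2);
      }
    }
  }
}

static IntegerMatrix cells_to_matrix(const ivec& rr, const ivec& cc) {
  IntegerMatrix out(rr.size(), 2);
  for (size_t i = 0; i < rr.size(); ++i) {
    out(i, 0) = rr[i] + 1;  // 1-based for R
    out(i, 1) = cc[i] + 1;
  }
  return out;
}

static void matrix_to_cells(const IntegerMatrix& m, ivec& rr, ivec& cc) {
  for (int i = 0; i < m.nrow(); ++i) {
    rr.push_back(m(i, 0) - 1);
    cc.push_back(m(i, 1) - 1);
  }
}

// one annual step: spontaneous -> spreading centers -> edge -> road
static List do_step(CAGrid& g, const Coeffs& k, double crit,
                    int nb_threshold) {
  ivec r1, c1, r2, c2, r3, c3, r4, c4;
  phase_spontaneous(g, k, crit, r1, c1);
  phase_spreading(g, k, crit, r1, c1, r2, c2);
  phase_edge(g, k, crit, nb_threshold, r3, c3);
  ivec seeds_r(r1), seeds_c(c1);
  seeds_r.insert(seeds_r.end(), r2.begin(), r2.end());
  seeds_c.insert(seeds_c.end(), c2.begin(), c2.end());
  seeds_r.insert(seeds_r.end(), r3.begin(), r3.end());
  seeds_c.insert(seeds_c.end(), c3.begin(), c3.end());
  phase_road(g, k, crit, seeds_r, seeds_c, r4, c4);
  IntegerVector counts = IntegerVector::create(
      (int)r1.size(), (int)r2.size(), (int)r3.size(), (int)r4.size());
  return List::create(
      _["counts"] = counts,
      _["cells"] = List::create(cells_to_matrix(r1, c1),
                                cells_to_matrix(r2, c2),
                                cells_to_matrix(r3, c3),
                                cells_to_matrix(r4, c4)));
}

// [[Rcpp::export]]
bool slope_accept_cpp(double slope_value, double slope_resistance,
                      double critical_slope) {
  return slope_ok(slope_value, slope_resistance, critical_slope);
}

// [[Rcpp::export]]
List attempt_urbanize_cpp(IntegerMatrix urban, NumericMatrix slope,
                          NumericMatrix excl, int row, int col,
                          double slope_resistance, double critical_slope) {
  CAGrid g;
  g.init(urban, slope, excl, 0);
  bool ok = attempt(g, row - 1, col - 1, slope_resistance, critical_slope);
  return List::create(_["accepted"] = ok, _["urban"] = g.urban_matrix());
}

// [[Rcpp::export]]
List spontaneous_cpp(IntegerMatrix urban, NumericMatrix slope,
                     NumericMatrix excl, NumericVector coeffs,
                     double critical_slope) {
  CAGrid g;
  g.init(urban, slope, excl, 0);
  Coeffs k = as_coeffs(coeffs);
  ivec rr, cc;
  phase_spontaneous(g, k, critical_slope, rr, cc);
  return List::create(_["urban"] = g.urban_matrix(),
                      _["cells"] = cells_to_matrix(rr, cc));
}

// [[Rcpp::export]]
List spreading_cpp(IntegerMatrix urban, NumericMatrix slope,
                   NumericMatrix excl, NumericVector coeffs,
                   double critical_slope, IntegerMatrix spont_cells) {
  CAGrid g;
  g.init(urban, slope, excl, 0);
  Coeffs k = as_coeffs(coeffs);
  ivec sr, sc, rr, cc;
  matrix_to_cells(spont_cells, sr, sc);
  phase_spreading(g, k, critical_slope, sr, sc, rr, cc);
  return List::create(_["urban"] = g.urban_matrix(),
                      _["cells"] = cells_to_matrix(rr, cc));
}

// [[Rcpp::export]]
List edge_cpp(IntegerMatrix urban, NumericMatrix slope, NumericMatrix excl,
              NumericVector coeffs, double critical_slope,
              int neighbor_threshold) {
  CAGrid g;
  g.init(urban, slope, excl, 0);
  Coeffs k = as_coeffs(coeffs);
  ivec rr, cc;
  phase_edge(g, k, critical_slope, neighbor_threshold, rr, cc);
  return List::create(_["urban"] = g.urban_matrix(),
                      _["cells"] = cells_to_matrix(rr, cc));
}

// [[Rcpp::export]]
List road_cpp(IntegerMatrix urban, NumericMatrix slope, NumericMatrix excl,
              NumericMatrix roads, NumericVector coeffs,
              double critical_slope, IntegerMatrix new_cells) {
  CAGrid g;
  g.init(urban, slope, excl, &roads);
  Coeffs k = as_coeffs(coeffs);
  ivec sr, sc, rr, cc;
  matrix_to_cells(new_cells, sr, sc);
  phase_road(g, k, critical_slope, sr, sc, rr, cc);
  return List::create(_["urban"] = g.urban_matrix(),
                      _["cells"] = cells_to_matrix(rr, cc));
}

// [[Rcpp::export]]
List ca_step_cpp(IntegerMatrix urban, NumericMatrix slope, NumericMatrix excl,
                 NumericMatrix roads, NumericVector coeffs,
                 double critical_slope, int neighbor_threshold) {
  CAGrid g;
  g.init(urban, slope, excl, &roads);
  Coeffs k = as_coeffs(coeffs);
  List res = do_step(g, k, critical_slope, neighbor_threshold);
  return List::create(_["urban"] = g.urban_matrix(),
                      _["counts"] = res["counts"], _["cells"] = res["cells"]);
}

// urban cells with at least one non-urban Moore neighbor; cells outside
// the grid count as non-urban, so urban cells on the border are edge cells
static int edge_count_raw(const int* sp, int nr, int nc) {
  int n = 0;
  for (int c = 0; c < nc; ++c) {
    const int* colw = c > 0 ? sp + (size_t)(c - 1) * nr : 0;
    const int* col = sp + (size_t)c * nr;
    const int* cole = c < nc - 1 ? sp + (size_t)(c + 1) * nr : 0;
    for (int r = 0; r < nr; ++r) {
      if (!col[r]) continue;
      bool up = r > 0, dn = r < nr - 1;
      bool edge = !up || !dn || !colw || !cole;
      if (!edge) {
        edge = !colw[r] || !colw[r - 1] || !colw[r + 1] || !col[r - 1] ||
               !col[r + 1] || !cole[r] || !cole[r - 1] || !cole[r + 1];
      }
      if (edge) ++n;
    }
  }
  return n;
}

// [[Rcpp::export]]
int count_edge_cells_cpp(IntegerMatrix urban) {
  return edge_count_raw(urban.begin(), urban.nrow(), urban.ncol());
}

template <typename GET>
static int label_fill(GET value, int nr, int nc, IntegerMatrix* labels,
                      int connectivity) {
  std::vector<char> seen((size_t)nr * nc, 0);
  std::vector<int> stack;
  int ncomp = 0;
  int nnb = connectivity == 4 ? 4 : 8;
  static const int DR4[4] = {-1, 0, 0, 1};
  static const int DC4[4] = {0, -1, 1, 0};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = c * nr + r;
      if (seen[idx] || !value(idx)) continue;
      ++ncomp;
      stack.push_back(idx);
      seen[idx] = 1;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        if (labels) (*labels)[cur] = ncomp;
        int cr = cur % nr, ccur = cur / nr;
        for (int j = 0; j < nnb; ++j) {
          int r2 = cr + (connectivity == 4 ? DR4[j] : DR[j]);
          int c2 = ccur + (connectivity == 4 ? DC4[j] : DC[j]);
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int idx2 = c2 * nr + r2;
          if (!seen[idx2] && value(idx2)) {
            seen[idx2] = 1;
            stack.push_back(idx2);
          }
        }
      }
    }
  }
  return ncomp;
}

struct eq_target {
  const int* p;
  int target;
  bool operator()(int i) const { return p[i] == target; }
};

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix m, int target,
                                   int connectivity) {
  IntegerMatrix labels(m.nrow(), m.ncol());
  eq_target f = {m.begin(), target};
  label_fill(f, m.nrow(), m.ncol(), &labels, connectivity);
  return labels;
}

// [[Rcpp::export]]
int count_components_cpp(IntegerMatrix m, int target, int connectivity) {
  eq_target f = {m.begin(), target};
  return label_fill(f, m.nrow(), m.ncol(), (IntegerMatrix*)0, connectivity);
}

static void apply_selfmod(Coeffs& k, double growth_rate, bool enabled,
                          double crit_high, double crit_low, double boom,
                          double bust) {
  if (!enabled) return;
  double mult;
  if (growth_rate > crit_high) mult = boom;
  else if (growth_rate < crit_low) mult = bust;
  else return;
  double* f[3] = {&k.disp, &k.breed, &k.spread};
  for (int i = 0; i < 3; ++i) {
    double pre = *f[i];
    double post = rhe(pre * mult);
    if (post > 100.0) post = 100.0;
    if (post < 0.0) post = 0.0;
    if (pre > 0.0 && post < 1.0) post = 1.0;
    *f[i] = post;
  }
}

// run the CA for n_years annual steps (growth step, then self-modification)
// and report per-year phase counts plus population/edge/cluster statistics
// at requested snapshot offsets (sorted, 1-based years into the run);
// optionally accumulates Lee-Sallee overlap terms against obs_final
// [[Rcpp::export]]
List ca_run_cpp(IntegerMatrix urban0, NumericMatrix slope, NumericMatrix excl,
                NumericMatrix roads, NumericVector coeffs,
                double critical_slope, int neighbor_threshold, int n_years,
                IntegerVector snap_years, bool selfmod_enabled,
                double crit_high, double crit_low, double boom, double bust,
                bool keep_snapshots, List obs_snapshots) {
  if (n_years < 1) stop("n_years must be >= 1");
  CAGrid g;
  g.init(urban0, slope, excl, &roads);
  Coeffs k = as_coeffs(coeffs);
  NumericMatrix stats(n_years, 6);
  int ns = snap_years.size();
  bool want_overlap = obs_snapshots.size() > 0;
  if (want_overlap && obs_snapshots.size() != ns)
    stop("obs_snapshots must match snap_years");
  List snaps(keep_snapshots ? ns : 0);
  NumericMatrix snap_stats(ns, 3);
  NumericMatrix overlaps(ns, 2);
  int si = 0;
  eq_target is_urban = {g.urban.data(), 1};
  for (int y = 1; y <= n_years; ++y) {
    int pop0 = g.pop;
    List res = do_step(g, k, critical_slope, neighbor_threshold);
    IntegerVector counts = res["counts"];
    int total = counts[0] + counts[1] + counts[2] + counts[3];
    double gr = pop0 > 0 ? 100.0 * total / pop0 : 0.0;
    stats(y - 1, 0) = y;
    for (int j = 0; j < 4; ++j) stats(y - 1, j + 1) = counts[j];
    stats(y - 1, 5) = gr;
    apply_selfmod(k, gr, selfmod_enabled, crit_high, crit_low, boom, bust);
    while (si < ns && snap_years[si] == y) {
      if (keep_snapshots) snaps[si] = g.urban_matrix();
      snap_stats(si, 0) = g.pop;
      snap_stats(si, 1) = edge_count_raw(g.urban.data(), g.nr, g.nc);
      snap_stats(si, 2) = label_fill(is_urban, g.nr, g.nc,
                                     (IntegerMatrix*)0, 8);
      if (want_overlap) {
        IntegerMatrix obs = obs_snapshots[si];
        if (obs.size() != (int)g.urban.size())
          stop("observed snapshot size mismatch");
        const int* po = obs.begin();
        int inter = 0, uni = 0;
        for (size_t i = 0; i < g.urban.size(); ++i) {
          bool x = g.urban[i] != 0, yy = po[i] != 0;
          inter += (x && yy);
          uni += (x || yy);
        }
        overlaps(si, 0) = inter;
        overlaps(si, 1) = uni;
      }
      ++si;
    }
  }
  return List::create(
      _["final_urban"] = g.urban_matrix(),
      _["stats"] = stats,
      _["snapshots"] = snaps,
      _["snap_stats"] = snap_stats,
      _["overlaps"] = overlaps,
      _["final_coeffs"] = NumericVector::create(k.disp, k.breed, k.spread,
                                                k.slope_res, k.road_grav));
}

// intersection and union sizes of two 0/1 matrices (Lee-Sallee terms)
// [[Rcpp::export]]
IntegerVector overlap_counts_cpp(IntegerMatrix a, IntegerMatrix b) {
  if (a.size() != b.size()) stop("layers differ in size");
  int inter = 0, uni = 0;
  const int* pa = a.begin();
  const int* pb = b.begin();
  for (int i = 0; i < a.size(); ++i) {
    bool x = pa[i] != 0, y = pb[i] != 0;
    inter += (x && y);
    uni += (x || y);
  }
  return IntegerVector::create(inter, uni);
}

// exact per-cell polyline length by splitting each segment at every grid
// line it crosses; accumulates meters of line per cell
// [[Rcpp::export]]
NumericMatrix line_length_grid_cpp(NumericMatrix segs, int nrows, int ncols,
                                   double cell_size, double origin_x,
                                   double origin_y) {
  NumericMatrix out(nrows, ncols);
  std::vector<double> ts;
  for (int i = 0; i < segs.nrow(); ++i) {
    double x0 = segs(i, 0), y0 = segs(i, 1), x1 = segs(i, 2), y1 = segs(i, 3);
    double dx = x1 - x0, dy = y1 - y0;
    double len = std::sqrt(dx * dx + dy * dy);
    if (len <= 0) continue;
    ts.clear();
    ts.push_back(0.0);
    ts.push_back(1.0);
    if (dx != 0) {
      double xmin = std::min(x0, x1), xmax = std::max(x0, x1);
      int j0 = (int)std::ceil((xmin - origin_x) / cell_size);
      int j1 = (int)std::floor((xmax - origin_x) / cell_size);
      for (int j = j0; j <= j1; ++j) {
        double t = (origin_x + j * cell_size - x0) / dx;
        if (t > 0 && t < 1) ts.push_back(t);
      }
    }
    if (dy != 0) {
      double ymin = std::min(y0, y1), ymax = std::max(y0, y1);
      int i0 = (int)std::ceil((origin_y - ymax) / cell_size);
      int i1 = (int)std::floor((origin_y - ymin) / cell_size);
      for (int ii = i0; ii <= i1; ++ii) {
        double t = (y0 - (origin_y - ii * cell_size)) / dy;
        if (t > 0 && t < 1) ts.push_back(t);
      }
    }
    std::sort(ts.begin(), ts.end());
    for (size_t j = 0; j + 1 < ts.size(); ++j) {
      double dt = ts[j + 1] - ts[j];
      if (dt <= 0) continue;
      double tm = 0.5 * (ts[j] + ts[j + 1]);
      double xm = x0 + tm * dx, ym = y0 + tm * dy;
      int c = (int)std::floor((xm - origin_x) / cell_size);
      int r = (int)std::floor((origin_y - ym) / cell_size);
      if (r < 0 || r >= nrows || c < 0 || c >= ncols) continue;
      out(r, c) += dt * len;
    }
  }
  return out;
}

// cell weight = maximum weight among segments crossing the cell
// [[Rcpp::export]]
NumericMatrix rasterize_max_weight_cpp(NumericMatrix segs,
                                       NumericVector weights, int nrows,
                                       int ncols, double cell_size,
                                       double origin_x, double origin_y) {
  NumericMatrix out(nrows, ncols);
  for (int i = 0; i < segs.nrow(); ++i) {
    NumericMatrix one(1, 4);
    for (int j = 0; j < 4; ++j) one(0, j) = segs(i, j);
    NumericMatrix L = line_length_grid_cpp(one, nrows, ncols, cell_size,
                                           origin_x, origin_y);
    double w = weights[i];
    for (int j = 0; j < L.size(); ++j) {
      if (L[j] > 0 && w > out[j]) out[j] = w;
    }
  }
  return out;
}
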