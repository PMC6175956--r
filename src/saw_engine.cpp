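// Core lattice engine: self-avoiding-walk validity, local-move Monte Carlo,
// exact enumeration, and hypothetical-scanning (HSMC) chain reconstruction.
// All randomness comes from R's RNG (set.seed() upstream gives determinism).

#include <Rcpp.h>
#include <functional>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

typedef std::array<int, 3> Vec3;

// pack a lattice site into a 64-bit key; coordinates must stay in (-2^20, 2^20)
static inline long long pack(const Vec3 &v) {
  const long long OFF = 1LL << 20;
  return ((v[0] + OFF) << 42) | ((v[1] + OFF) << 21) | (v[2] + OFF);
}

// Flat open-addressing hash set of packed site keys (linear probing,
// backward-shift deletion). Keys are non-negative; EMPTY = -1. Sized for a
// load factor <= 1/8, so probes are short; this is the innermost loop of
// every validity check.
struct SiteSet {
  std::vector<long long> tab;
  size_t mask = 0;

  void init(size_t n_items) {
    size_t cap = 64;
    while (cap < 8 * (n_items + 1)) cap <<= 1;
    tab.assign(cap, -1LL);
    mask = cap - 1;
  }
  static inline size_t hash(long long k) {
    return (size_t)((unsigned long long)k * 0x9E3779B97F4A7C15ULL >> 17);
  }
  inline bool count(long long k) const {
    size_t i = hash(k) & mask;
    while (tab[i] != -1LL) {
      if (tab[i] == k) return true;
      i = (i + 1) & mask;
    }
    return false;
  }
  inline void insert(long long k) {
    size_t i = hash(k) & mask;
    while (tab[i] != -1LL) {
      if (tab[i] == k) return;
      i = (i + 1) & mask;
    }
    tab[i] = k;
  }
  inline void erase(long long k) {
    size_t i = hash(k) & mask;
    while (tab[i] != -1LL && tab[i] != k) i = (i + 1) & mask;
    if (tab[i] == -1LL) return;
    tab[i] = -1LL;
    size_t hole = i, j = i;
    for (;;) {
      j = (j + 1) & mask;
      long long k2 = tab[j];
      if (k2 == -1LL) break;
      size_t h = hash(k2) & mask;
      // move k2 into the hole iff its home slot is cyclically outside (hole, j]
      bool between = (hole < j) ? (h > hole && h <= j)
                                : (h > hole || h <= j);
      if (!between) {
        tab[hole] = k2;
        tab[j] = -1LL;
        hole = j;
      }
    }
  }
  void clear() { std::fill(tab.begin(), tab.end(), -1LL); }
};

struct Engine {
  std::vector<Vec3> dirs;        // allowed bond vectors
  std::vector<Vec3> excl;        // nonzero excluded offsets (shell)
  int sub_kind;                  // 0 none, 1 plane, 2 sphere_ext, 3 sphere_int, 4 cyl_ext
  double sub_r;                  // radius in lattice units
  bool ideal;                    // ideal-walk test mode: no exclusion, no substrate
  std::vector<Vec3> coords;
  SiteSet occ;

  int n_dirs() const { return (int)dirs.size(); }

  bool substrate_excluded(const Vec3 &s) const {
    switch (sub_kind) {
    case 1: return s[2] < 0; // solid half-space below the plane z = 0
    case 2: {
      double d2 = (double)s[0] * s[0] + (double)s[1] * s[1] + (double)s[2] * s[2];
      return d2 < sub_r * sub_r;
    }
    case 3: {
      double d2 = (double)s[0] * s[0] + (double)s[1] * s[1] + (double)s[2] * s[2];
      return d2 > sub_r * sub_r;
    }
    case 4: {
      double d2 = (double)s[0] * s[0] + (double)s[1] * s[1];
      return d2 < sub_r * sub_r;
    }
    default: return false;
    }
  }

  // site admissible against substrate and every bead currently in `occ`
  bool site_ok(const Vec3 &s) const {
    if (ideal) return true;
    if (substrate_excluded(s)) return false;
    if (occ.count(pack(s))) return false;
    for (size_t k = 0; k < excl.size(); ++k) {
      Vec3 t = { s[0] + excl[k][0], s[1] + excl[k][1], s[2] + excl[k][2] };
      if (occ.count(pack(t))) return false;
    }
    return true;
  }

  int dir_index(const Vec3 &v) const {
    for (int k = 0; k < (int)dirs.size(); ++k)
      if (dirs[k][0] == v[0] && dirs[k][1] == v[1] && dirs[k][2] == v[2]) return k;
    return -1;
  }

  bool bond_ok(const Vec3 &v) const { return dir_index(v) >= 0; }

  void occ_insert(const Vec3 &s) { occ.insert(pack(s)); }
  void occ_erase(const Vec3 &s) { occ.erase(pack(s)); }

  // One local-move attempt on a uniformly chosen movable bead in [lo, hi]
  // (0-based indices into coords; hi is the last bead). A bead with a frozen
  // predecessor proposes prev + random direction; the free head bead (index 0
  // movable) proposes coords[1] + random direction. Symmetric proposal,
  // accept iff valid. Returns true when accepted.
  bool attempt(int lo, int hi) {
    int span = hi - lo + 1;
    int m = lo + (int)(unif_rand() * span);
    if (m > hi) m = hi;
    int kd = (int)(unif_rand() * dirs.size());
    if (kd >= (int)dirs.size()) kd = (int)dirs.size() - 1;
    Vec3 base = (m == 0) ? coords[1] : coords[m - 1];
    Vec3 cand = { base[0] + dirs[kd][0], base[1] + dirs[kd][1], base[2] + dirs[kd][2] };
    if (cand[0] == coords[m][0] && cand[1] == coords[m][1] && cand[2] == coords[m][2])
      return true; // proposing the current site: always valid, chain unchanged
    int last = (int)coords.size() - 1;
    if (m < last) {
      Vec3 nb = { coords[m + 1][0] - cand[0], coords[m + 1][1] - cand[1],
                  coords[m + 1][2] - cand[2] };
      if (!bond_ok(nb)) return false;
    }
    if (!ideal) {
      occ_erase(coords[m]);
      if (!site_ok(cand)) { occ_insert(coords[m]); return false; }
      occ_insert(cand);
    }
    coords[m] = cand;
    return true;
  }

  // Deterministic depth-first placement of beads [from, to] continuing from
  // coords[from-1], trying directions in `order`; used for initial/extended
  // conformations. Places sites into occ. Returns false when no completion
  // exists within `budget` visited nodes.
  bool dfs_place(int from, int to, const std::vector<int> &order, long long budget) {
    std::vector<int> choice(to - from + 1, -1);
    long long visited = 0;
    int i = from;
    while (i <= to) {
      int &c = choice[i - from];
      bool placed = false;
      for (++c; c < (int)order.size(); ++c) {
        if (++visited > budget) return false;
        const Vec3 &d = dirs[order[c]];
        Vec3 cand = { coords[i - 1][0] + d[0], coords[i - 1][1] + d[1],
                      coords[i - 1][2] + d[2] };
        if (site_ok(cand)) {
          coords[i] = cand;
          occ_insert(cand);
          placed = true;
          break;
        }
      }
      if (placed) { ++i; continue; }
      choice[i - from] = -1;
      --i;                                   // backtrack
      if (i < from) return false;
      occ_erase(coords[i]);
    }
    return true;
  }

  // Pivot attempt for the future segment: choose a pivot bead p in
  // [j-1, n-1], a uniformly random signed coordinate permutation (full
  // octahedral group, 48 elements), and rotate beads p+1..n about bead p.
  // The group is closed under inversion, so the proposal is symmetric;
  // accept iff every rotated site is admissible. Direction sets are closed
  // under signed permutations, so bonds remain valid automatically.
  // at_root = true pivots about bead j-1 (re-randomizing bond j itself);
  // otherwise the pivot bead is uniform over [j-1, n-1].
  bool pivot_attempt(int j, int n, bool at_root = false) {
    static const int perms[6][3] = { {0,1,2}, {0,2,1}, {1,0,2},
                                     {1,2,0}, {2,0,1}, {2,1,0} };
    int p = at_root ? (j - 1)
                    : (j - 1) + (int)(unif_rand() * (n - j + 1));
    if (p > n - 1) p = n - 1;
    int pe = (int)(unif_rand() * 6); if (pe > 5) pe = 5;
    int sg[3];
    for (int d = 0; d < 3; ++d) sg[d] = (unif_rand() < 0.5) ? -1 : 1;
    const Vec3 &c0 = coords[p];
    if (!ideal)
      for (int i = p + 1; i <= n; ++i) occ_erase(coords[i]);
    std::vector<Vec3> nw(n - p);
    int placed = 0;
    bool ok = true;
    for (int i = p + 1; i <= n; ++i) {
      Vec3 off = { coords[i][0] - c0[0], coords[i][1] - c0[1],
                   coords[i][2] - c0[2] };
      Vec3 cand = { c0[0] + sg[0] * off[perms[pe][0]],
                    c0[1] + sg[1] * off[perms[pe][1]],
                    c0[2] + sg[2] * off[perms[pe][2]] };
      if (!site_ok(cand)) { ok = false; break; }
      nw[i - p - 1] = cand;
      if (!ideal) { occ_insert(cand); ++placed; }
    }
    if (!ok) {
      if (!ideal) {
        for (int k = 0; k < placed; ++k) occ_erase(nw[k]);
        for (int i = p + 1; i <= n; ++i) occ_insert(coords[i]);
      }
      return false;
    }
    for (int i = p + 1; i <= n; ++i) coords[i] = nw[i - p - 1];
    return true;
  }

  // Direction ordering that prefers the outward normal at s (so the
  // default extended conformation points away from the substrate).
  std::vector<int> outward_order(const Vec3 &s) const {
    std::vector<double> normal(3, 0.0);
    switch (sub_kind) {
    case 1: normal[2] = 1.0; break;
    case 2: normal[0] = s[0]; normal[1] = s[1]; normal[2] = s[2]; break;
    case 3: normal[0] = -s[0]; normal[1] = -s[1]; normal[2] = -s[2]; break;
    case 4: normal[0] = s[0]; normal[1] = s[1]; break;
    default: break;
    }
    std::vector<int> idx(dirs.size());
    std::vector<double> score(dirs.size());
    for (size_t k = 0; k < dirs.size(); ++k) {
      idx[k] = (int)k;
      score[k] = -(normal[0] * dirs[k][0] + normal[1] * dirs[k][1] +
                   normal[2] * dirs[k][2]);
    }
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return score[a] < score[b]; });
    return idx;
  }

  void load_coords(const IntegerMatrix &m) {
    coords.resize(m.nrow());
    occ.init(m.nrow());
    for (int i = 0; i < m.nrow(); ++i) {
      coords[i] = { m(i, 0), m(i, 1), m(i, 2) };
      occ_insert(coords[i]);
    }
  }
};

static std::vector<Vec3> as_vecs(const IntegerMatrix &m) {
  std::vector<Vec3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = { m(i, 0), m(i, 1), m(i, 2) };
  return v;
}

static Engine make_engine(const IntegerMatrix &dirs, const IntegerMatrix &excl,
                          int sub_kind, double sub_r, bool ideal = false) {
  Engine e;
  e.dirs = as_vecs(dirs);
  e.excl = as_vecs(excl);
  e.sub_kind = sub_kind;
  e.sub_r = sub_r;
  e.ideal = ideal;
  return e;
}

static IntegerMatrix coords_matrix(const std::vector<Vec3> &c) {
  IntegerMatrix m((int)c.size(), 3);
  for (size_t i = 0; i < c.size(); ++i) {
    m((int)i, 0) = c[i][0]; m((int)i, 1) = c[i][1]; m((int)i, 2) = c[i][2];
  }
  return m;
}

// [[Rcpp::export]]
bool cpp_is_valid(IntegerMatrix coords, IntegerMatrix dirs, IntegerMatrix excl,
                  int sub_kind, double sub_r) {
  Engine e = make_engine(dirs, excl, sub_kind, sub_r);
  int n = coords.nrow();
  e.occ.init(n);
  // bonds
  for (int i = 1; i < n; ++i) {
    Vec3 b = { coords(i, 0) - coords(i - 1, 0), coords(i, 1) - coords(i - 1, 1),
               coords(i, 2) - coords(i - 1, 2) };
    if (!e.bond_ok(b)) return false;
  }
  // incremental site checks: bead i against beads 0..i-1
  for (int i = 0; i < n; ++i) {
    Vec3 s = { coords(i, 0), coords(i, 1), coords(i, 2) };
    if (!e.site_ok(s)) return false;
    e.occ_insert(s);
  }
  return true;
}

// [[Rcpp::export]]
IntegerMatrix cpp_initial_conf(IntegerMatrix dirs, IntegerMatrix excl,
                               int sub_kind, double sub_r, int n_bonds,
                               IntegerVector start) {
  Engine e = make_engine(dirs, excl, sub_kind, sub_r);
  Vec3 s0 = { start[0], start[1], start[2] };
  e.occ.init(n_bonds + 1);
  if (!e.site_ok(s0)) stop("tether site is excluded by the substrate");
  e.coords.assign(n_bonds + 1, s0);
  e.occ_insert(s0);
  std::vector<int> order = e.outward_order(s0);
  if (!e.dfs_place(1, n_bonds, order, 10000000LL))
    stop("no valid extended conformation found from the tether site");
  return coords_matrix(e.coords);
}

// [[Rcpp::export]]
List cpp_mc_run(IntegerMatrix coords0, IntegerMatrix dirs, IntegerMatrix excl,
                int sub_kind, double sub_r, bool anchored, int n_steps,
                int thin) {
  RNGScope scope;
  Engine e = make_engine(dirs, excl, sub_kind, sub_r);
  e.load_coords(coords0);
  int last = (int)e.coords.size() - 1;
  int n_moves_per_step = last; // N local moves per MC step (N bonds)
  if (n_moves_per_step < 1) n_moves_per_step = 1;
  int lo = anchored ? 1 : 0;
  long long accepted = 0, attempted = 0;
  int n_samples = n_steps / thin;
  IntegerVector samples(n_samples * (last + 1) * 3);
  int si = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int mv = 0; mv < n_moves_per_step; ++mv) {
      ++attempted;
      if (e.attempt(lo, last)) ++accepted;
    }
    if (step % thin == 0 && si < n_samples) {
      for (int i = 0; i <= last; ++i)
        for (int d = 0; d < 3; ++d)
          samples[(long long)si * (last + 1) * 3 + (long long)i * 3 + d] =
              e.coords[i][d];
      ++si;
    }
  }
  samples.attr("dim") = IntegerVector::create(3, last + 1, n_samples);
  return List::create(_["samples"] = samples,
                      _["acceptance"] = (double)accepted / (double)attempted,
                      _["final"] = coords_matrix(e.coords));
}

// Accumulate Rg^2 and Ree^2 (lattice units^2) over an MC run; first
// `n_burn` MC steps are discarded, then observables are taken every
// `measure_every` steps and averaged within `n_blocks` equal blocks.
// [[Rcpp::export]]
List cpp_chain_observables(IntegerMatrix coords0, IntegerMatrix dirs,
                           IntegerMatrix excl, int sub_kind, double sub_r,
                           bool anchored, int n_steps, int n_burn,
                           int measure_every, int n_blocks, bool use_pivot) {
  RNGScope scope;
  Engine e = make_engine(dirs, excl, sub_kind, sub_r);
  e.load_coords(coords0);
  int last = (int)e.coords.size() - 1;
  int n_beads = last + 1;
  int nm = last < 1 ? 1 : last;
  int lo = anchored ? 1 : 0;
  for (int step = 0; step < n_burn; ++step) {
    for (int mv = 0; mv < nm; ++mv) e.attempt(lo, last);
    if (use_pivot) e.pivot_attempt(1, last);
  }
  int block_len = n_steps / n_blocks;
  NumericMatrix block_means(n_blocks, 2); // col 0: Rg^2, col 1: Ree^2
  for (int b = 0; b < n_blocks; ++b) {
    double s_rg2 = 0.0, s_ree2 = 0.0;
    long long n_obs = 0;
    for (int step = 1; step <= block_len; ++step) {
      for (int mv = 0; mv < nm; ++mv) e.attempt(lo, last);
      if (use_pivot) e.pivot_attempt(1, last);
      if (step % measure_every == 0) {
        double cx = 0, cy = 0, cz = 0;
        for (int i = 0; i < n_beads; ++i) {
          cx += e.coords[i][0]; cy += e.coords[i][1]; cz += e.coords[i][2];
        }
        cx /= n_beads; cy /= n_beads; cz /= n_beads;
        double rg2 = 0;
        for (int i = 0; i < n_beads; ++i) {
          double dx = e.coords[i][0] - cx, dy = e.coords[i][1] - cy,
                 dz = e.coords[i][2] - cz;
          rg2 += dx * dx + dy * dy + dz * dz;
        }
        rg2 /= n_beads;
        double ex = e.coords[last][0] - e.coords[0][0];
        double ey = e.coords[last][1] - e.coords[0][1];
        double ez = e.coords[last][2] - e.coords[0][2];
        s_rg2 += rg2;
        s_ree2 += ex * ex + ey * ey + ez * ez;
        ++n_obs;
      }
    }
    block_means(b, 0) = s_rg2 / n_obs;
    block_means(b, 1) = s_ree2 / n_obs;
  }
  return List::create(_["block_means"] = block_means);
}

// Exact depth-first count of valid walks of n_bonds bonds from `start`.
// [[Rcpp::export]]
double cpp_enumerate(IntegerMatrix dirs, IntegerMatrix excl, int sub_kind,
                     double sub_r, int n_bonds, IntegerVector start,
                     double budget) {
  Engine e = make_engine(dirs, excl, sub_kind, sub_r);
  Vec3 s0 = { start[0], start[1], start[2] };
  e.occ.init(n_bonds + 1);
  if (!e.site_ok(s0)) stop("start site is excluded by the substrate");
  e.coords.assign(n_bonds + 1, s0);
  e.occ_insert(s0);
  double count = 0;
  long long visited = 0;
  long long cap = (long long)budget;
  std::function<void(int)> rec = [&](int depth) {
    for (size_t k = 0; k < e.dirs.size(); ++k) {
      if (++visited > cap) stop("enumeration budget exceeded; use smaller N");
      Vec3 cand = { e.coords[depth - 1][0] + e.dirs[k][0],
                    e.coords[depth - 1][1] + e.dirs[k][1],
                    e.coords[depth - 1][2] + e.dirs[k][2] };
      if (!e.site_ok(cand)) continue;
      if (depth == n_bonds) { count += 1; continue; }
      e.coords[depth] = cand;
      e.occ_insert(cand);
      rec(depth + 1);
      e.occ_erase(cand);
    }
  };
  rec(1);
  return count;
}

// Internal: scan of bond j. Past beads 0..j-1 of `eng.coords` are frozen;
// beads j..n form the future segment, already valid. One MC step is a sweep
// of (n - j + 1) local-move attempts on the future segment. Runs n_eq
// equilibration steps then n_mc scan steps, tallying the direction of bond
// j after each scan step.
static std::vector<long long> scan_bond(Engine &eng, int j, int n,
                                        long long n_eq, long long n_mc) {
  std::vector<long long> counts(eng.n_dirs(), 0);
  int n_seg = n - j + 1;
  for (long long t = 0; t < n_eq; ++t) {
    for (int s = 0; s < n_seg; ++s) eng.attempt(j, n);
    eng.pivot_attempt(j, n);
    eng.pivot_attempt(j, n, true);
  }
  for (long long t = 0; t < n_mc; ++t) {
    for (int s = 0; s < n_seg; ++s) eng.attempt(j, n);
    eng.pivot_attempt(j, n);
    eng.pivot_attempt(j, n, true);
    Vec3 b = { eng.coords[j][0] - eng.coords[j - 1][0],
               eng.coords[j][1] - eng.coords[j - 1][1],
               eng.coords[j][2] - eng.coords[j - 1][2] };
    counts[eng.dir_index(b)] += 1;
  }
  return counts;
}

// [[Rcpp::export]]
List cpp_scan_bond(IntegerMatrix past, IntegerMatrix dirs, IntegerMatrix excl,
                   int sub_kind, double sub_r, int n_total_bonds,
                   double n_bar, double n_bar_prime, bool ideal) {
  RNGScope scope;
  Engine e = make_engine(dirs, excl, sub_kind, sub_r, ideal);
  int j = past.nrow();                 // bond being scanned (1-based)
  int n = n_total_bonds;
  if (j < 1 || j > n) stop("past must hold between 1 and n_total_bonds beads");
  e.coords.resize(n + 1);
  e.occ.init(n + 1);
  for (int i = 0; i < j; ++i) {
    e.coords[i] = { past(i, 0), past(i, 1), past(i, 2) };
    if (!e.ideal) e.occ_insert(e.coords[i]);
  }
  std::vector<int> order = e.outward_order(e.coords[j - 1]);
  if (!e.dfs_place(j, n, order, 10000000LL))
    stop("dead-end prefix: the future segment has no valid completion");
  int n_seg = n - j + 1;
  long long n_eq = (long long)(n_bar_prime * e.n_dirs() * n_seg);
  long long n_mc = (long long)(n_bar * e.n_dirs() * n_seg);
  std::vector<long long> counts = scan_bond(e, j, n, n_eq, n_mc);
  NumericVector out(e.n_dirs());
  for (int k = 0; k < e.n_dirs(); ++k) out[k] = (double)counts[k];
  return List::create(_["counts"] = out, _["n_mc"] = (double)n_mc);
}

// Full HSMC reconstruction of one chain of n_bonds bonds from `start`.
// Returns log reconstruction probability and per-bond probabilities, or
// dead_end = TRUE when a future segment could not be initialized.
// [[Rcpp::export]]
List cpp_hsmc_reconstruct(IntegerMatrix dirs, IntegerMatrix excl, int sub_kind,
                          double sub_r, int n_bonds, IntegerVector start,
                          double n_bar, double n_bar_prime, bool weighted,
                          bool ideal) {
  RNGScope scope;
  Engine e = make_engine(dirs, excl, sub_kind, sub_r, ideal);
  int n = n_bonds;
  Vec3 s0 = { start[0], start[1], start[2] };
  e.coords.assign(n + 1, s0);
  e.occ.init(n + 1);
  if (!e.ideal) {
    if (!e.site_ok(s0)) stop("tether site is excluded by the substrate");
    e.occ_insert(s0);
  }
  NumericVector p_bond(n);
  double log_p = 0.0;
  // invariant at the top of each iteration: occ holds exactly beads 0..j-1
  for (int j = 1; j <= n; ++j) {
    // rebuild an allowed extended conformation for beads j..n
    std::vector<int> order = e.outward_order(e.coords[j - 1]);
    bool ok;
    if (e.ideal) {
      for (int i = j; i <= n; ++i) {
        const Vec3 &d = e.dirs[order[0]];
        e.coords[i] = { e.coords[i - 1][0] + d[0], e.coords[i - 1][1] + d[1],
                        e.coords[i - 1][2] + d[2] };
      }
      ok = true;
    } else {
      ok = e.dfs_place(j, n, order, 10000000LL);
    }
    if (!ok)
      return List::create(_["dead_end"] = true, _["at_bond"] = j);
    int n_seg = n - j + 1;
    long long n_eq = (long long)(n_bar_prime * e.n_dirs() * n_seg);
    long long n_mc = (long long)(n_bar * e.n_dirs() * n_seg);
    std::vector<long long> counts = scan_bond(e, j, n, n_eq, n_mc);
    // draw the direction of bond j
    int pick = -1;
    if (weighted) {
      double u = unif_rand() * (double)n_mc;
      double acc = 0;
      for (int k = 0; k < e.n_dirs(); ++k) {
        acc += (double)counts[k];
        if (u <= acc && counts[k] > 0) { pick = k; break; }
      }
      if (pick < 0)
        for (int k = e.n_dirs() - 1; k >= 0; --k)
          if (counts[k] > 0) { pick = k; break; }
    } else {
      std::vector<int> seen;
      for (int k = 0; k < e.n_dirs(); ++k)
        if (counts[k] > 0) seen.push_back(k);
      int ii = (int)(unif_rand() * seen.size());
      if (ii >= (int)seen.size()) ii = (int)seen.size() - 1;
      pick = seen[ii];
    }
    double pj = (double)counts[pick] / (double)n_mc;
    p_bond[j - 1] = pj;
    log_p += std::log(pj);
    // freeze bond j at the drawn direction
    if (!e.ideal)
      for (int i = j; i <= n; ++i) e.occ_erase(e.coords[i]);
    e.coords[j] = { e.coords[j - 1][0] + e.dirs[pick][0],
                    e.coords[j - 1][1] + e.dirs[pick][1],
                    e.coords[j - 1][2] + e.dirs[pick][2] };
    if (!e.ideal) e.occ_insert(e.coords[j]);
  }
  return List::create(_["dead_end"] = false, _["log_p"] = log_p,
                      _["p_bond"] = p_bond,
                      _["coords"] = coords_matrix(e.coords));
}
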