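// Kinetic Monte Carlo engine for the paired-lattice synapse model.
//
// Two square lattices (T cell side, bilayer/APC side) share a node grid of
// side L with a circular active domain. Each node holds at most one agent
// per lattice. Bound receptor-ligand pairs occupy the identical node index
// on the two lattices and move as one unit. A third lattice carries the
// F-actin focus automaton. All randomness comes from two self-contained
// xoshiro256** streams (movement/kinetics and foci) so that trajectories
// are byte-reproducible given a seed and so that enabling the focus
// automaton does not perturb the kinetic stream.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  void seed(uint64_t sd) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sd);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in [0, n) via multiply-shift (avoids slow modulo)
  int below(int n) {
    return (int)(((__uint128_t)next() * (uint64_t)n) >> 64);
  }
};

// ------------------------------------------------------------- helpers ---

// species codes: 0 TCR, 1 pMHC, 2 LFA1, 3 ICAM1
// lattice side:  0 (T cell): TCR, LFA1;  1 (APC/bilayer): pMHC, ICAM1
static const int SP_SIDE[4] = {0, 1, 0, 1};
// complex class: 0 short (TCR-pMHC), 1 long (LFA1-ICAM1)

// foci states
enum { F_EMPTY = 0, F_NUC = 1, F_NUCPOL = 2, F_POL = 3 };

struct DiscOffset { int dn; double ux, uy; double r; };

// offsets (excluding 0) within radius_nodes, with outward unit vectors
static std::vector<DiscOffset> disc_offsets(int L, double radius_nodes,
                                            bool include_origin) {
  std::vector<DiscOffset> out;
  int rmax = (int)std::floor(radius_nodes);
  for (int dy = -rmax; dy <= rmax; ++dy)
    for (int dx = -rmax; dx <= rmax; ++dx) {
      double r = std::sqrt((double)(dx * dx + dy * dy));
      if (r > radius_nodes) continue;
      if (dx == 0 && dy == 0) {
        if (include_origin) out.push_back({0, 0.0, 0.0, 0.0});
        continue;
      }
      out.push_back({dy * L + dx, dx / r, dy / r, r});
    }
  // sort by radius so neighbourhood scans can early-exit on near hits
  std::sort(out.begin(), out.end(),
            [](const DiscOffset &a, const DiscOffset &b) { return a.r < b.r; });
  return out;
}

struct Engine {
  // geometry
  int L; double spacing, radius, tau;
  std::vector<uint8_t> active;     // 1 if node inside the synapse disk
  double cx, cy;                   // lattice centre in node coordinates

  // agents
  std::vector<int> species, node, partner; // partner -1 when free
  std::vector<long> bind_step;

  // grids: agent index + 1, or 0 when empty; [side][node]
  std::vector<int> grid[2];
  std::vector<int> fstate, fage;   // focus automaton

  // kinetic parameters (per-step probabilities)
  double p_move_sp[4], p_move_cx[2], p_on[2], p_off[2];
  double B_global;

  // forces
  bool coupling_enabled; double sbs_strength, cen_strength[2];
  double R_force; int force_interval; bool sbs_inverse_r;
  std::vector<DiscOffset> force_disc;
  std::vector<double> fx[2], fy[2]; // repulsion field felt by class c

  // foci
  bool foci_enabled, feedback_all_states;
  double p_nucleate, p_nuc_poly, p_poly, p_decay, foci_B;
  double R_neigh;
  std::vector<DiscOffset> neigh_disc;

  // external binding-field override (length L*L) or empty
  std::vector<double> b_override; bool has_override = false;

  Xoshiro rng_main, rng_foci;
  long step_no = 0;
  long clamp_events = 0;
  bool check_invariants = false, collect_lifetimes = false;
  std::vector<double> lifetimes;
  std::vector<int> counts0; // per-species totals at entry (conservation)

  inline bool in_bounds(int x, int y) const {
    return x >= 0 && x < L && y >= 0 && y < L;
  }
  inline int nx(int n) const { return n % L; }
  inline int ny(int n) const { return n / L; }

  void build_grids() {
    grid[0].assign(L * L, 0);
    grid[1].assign(L * L, 0);
    int n_ag = species.size();
    for (int i = 0; i < n_ag; ++i) {
      int side = SP_SIDE[species[i]];
      if (grid[side][node[i]] != 0)
        stop("occupancy violation: two agents share a node on one lattice");
      grid[side][node[i]] = i + 1;
    }
  }

  // --- size-based segregation repulsion field -------------------------
  void recompute_force_field() {
    for (int c = 0; c < 2; ++c) {
      fx[c].assign(L * L, 0.0);
      fy[c].assign(L * L, 0.0);
    }
    int n_ag = species.size();
    int rmax = (int)std::floor(R_force / spacing);
    for (int i = 0; i < n_ag; ++i) {
      if (partner[i] < 0) continue;
      int sp = species[i];
      if (sp != 0 && sp != 2) continue;      // one entry per pair (T side)
      int cls = (sp == 0) ? 0 : 1;           // this complex's class
      int other = 1 - cls;                   // class that feels it
      int x0 = nx(node[i]), y0 = ny(node[i]);
      for (int dy = -rmax; dy <= rmax; ++dy) {
        int y = y0 + dy; if (y < 0 || y >= L) continue;
        for (int dx = -rmax; dx <= rmax; ++dx) {
          if (dx == 0 && dy == 0) continue;
          int x = x0 + dx; if (x < 0 || x >= L) continue;
          double r = std::sqrt((double)(dx * dx + dy * dy));
          if (r * spacing > R_force) continue;
          double w = sbs_inverse_r ? 1.0 / r : 1.0;
          int t = y * L + x;
          fx[other][t] += w * dx / r;
          fy[other][t] += w * dy / r;
        }
      }
    }
  }

  // --- movement -------------------------------------------------------
  // direction offsets: 0 up(-y), 1 down(+y), 2 left(-x), 3 right(+x)
  inline int dir_dn(int d) const {
    switch (d) { case 0: return -L; case 1: return L; case 2: return -1; default: return 1; }
  }
  inline double dir_dx(int d) const { return d == 2 ? -1.0 : (d == 3 ? 1.0 : 0.0); }
  inline double dir_dy(int d) const { return d == 0 ? -1.0 : (d == 1 ? 1.0 : 0.0); }

  void move_phase() {
    // unit list: all free agents plus the T-side member of each bound pair
    int n_ag = species.size();
    std::vector<int> units; units.reserve(n_ag);
    for (int i = 0; i < n_ag; ++i) {
      if (partner[i] < 0 || species[i] == 0 || species[i] == 2)
        units.push_back(i);
    }
    // Fisher-Yates shuffle: fresh random update order each step
    for (int i = (int)units.size() - 1; i > 0; --i) {
      int j = rng_main.below(i + 1);
      std::swap(units[i], units[j]);
    }
    for (int i : units) {
      int sp = species[i], n = node[i];
      bool bound = partner[i] >= 0;
      double pm = bound ? p_move_cx[sp == 0 ? 0 : 1] : p_move_sp[sp];
      if (pm <= 0.0) continue;
      if (rng_main.unif() >= pm) continue;
      int d;
      if (!bound) {
        d = rng_main.below(4);
      } else {
        // biased direction choice over {stay, 4 neighbours}
        int cls = (sp == 0) ? 0 : 1;
        double fxv = 0.0, fyv = 0.0;
        if (sbs_strength > 0.0) {
          double gx = fx[cls][n], gy = fy[cls][n];
          double nr = std::sqrt(gx * gx + gy * gy);
          if (nr > 0) { fxv = gx / nr; fyv = gy / nr; }
        }
        double cs = cen_strength[cls];
        double cxv = 0.0, cyv = 0.0;
        if (coupling_enabled && cs > 0.0) {
          double gx = cx - nx(n), gy = cy - ny(n);
          double nr = std::sqrt(gx * gx + gy * gy);
          if (nr > 0) { cxv = gx / nr; cyv = gy / nr; }
        }
        double w[5]; w[0] = 1.0; double tot = 1.0;
        for (int k = 0; k < 4; ++k) {
          double dxk = dir_dx(k), dyk = dir_dy(k);
          double ws = 1.0 + sbs_strength * (fxv * dxk + fyv * dyk);
          double wc = 1.0 + cs * (cxv * dxk + cyv * dyk);
          if (!coupling_enabled) wc = 1.0;
          if (ws < 0) ws = 0; if (wc < 0) wc = 0;
          w[k + 1] = ws * wc; tot += w[k + 1];
        }
        double u = rng_main.unif() * tot, acc = 0.0; int pick = 0;
        for (int k = 0; k < 5; ++k) { acc += w[k]; if (u < acc) { pick = k; break; } }
        if (pick == 0) continue; // stay
        d = pick - 1;
      }
      int x = nx(n) + (int)dir_dx(d), y = ny(n) + (int)dir_dy(d);
      if (!in_bounds(x, y)) continue;
      int t = y * L + x;
      if (!active[t]) continue;
      if (!bound) {
        int side = SP_SIDE[sp];
        if (grid[side][t] != 0) continue;
        grid[side][n] = 0; grid[side][t] = i + 1; node[i] = t;
      } else {
        if (grid[0][t] != 0 || grid[1][t] != 0) continue;
        int j = partner[i];
        grid[0][n] = 0; grid[1][n] = 0;
        grid[0][t] = i + 1; grid[1][t] = j + 1;
        node[i] = t; node[j] = t;
      }
    }
  }

  // --- binding --------------------------------------------------------
  inline double b_field_at(int n) const {
    if (has_override) return b_override[n];
    if (!foci_enabled) return 1.0;
    int s = fstate[n];
    bool focus = feedback_all_states ? (s != F_EMPTY) : (s == F_POL);
    return focus ? foci_B : 1.0;
  }

  void bind_phase() {
    int n_ag = species.size();
    for (int i = 0; i < n_ag; ++i) {
      int sp = species[i];
      if ((sp != 0 && sp != 2) || partner[i] >= 0) continue;
      int n = node[i];
      int j = grid[1][n] - 1;
      if (j < 0 || partner[j] >= 0) continue;
      double p;
      if (sp == 0) {
        if (species[j] != 1) continue;
        p = p_on[0] * B_global * b_field_at(n);
      } else {
        if (species[j] != 3) continue;
        p = p_on[1] * B_global;
      }
      if (p > 1.0) { p = 1.0; ++clamp_events; }
      if (p <= 0.0) continue;
      if (rng_main.unif() < p) {
        partner[i] = j; partner[j] = i;
        bind_step[i] = step_no + 1; bind_step[j] = step_no + 1;
      }
    }
  }

  void unbind_phase() {
    int n_ag = species.size();
    for (int i = 0; i < n_ag; ++i) {
      int sp = species[i];
      if ((sp != 0 && sp != 2) || partner[i] < 0) continue;
      double p = p_off[sp == 0 ? 0 : 1];
      if (p <= 0.0) continue;
      if (rng_main.unif() < p) {
        if (collect_lifetimes && sp == 0)
          lifetimes.push_back((step_no + 1 - bind_step[i]) * tau);
        int j = partner[i];
        partner[i] = -1; partner[j] = -1;
      }
    }
  }

  // --- focus automaton ------------------------------------------------
  inline bool short_complex_at(int n) const {
    int i = grid[0][n] - 1;
    return i >= 0 && species[i] == 0 && partner[i] >= 0;
  }
  inline bool long_complex_at(int n) const {
    int i = grid[0][n] - 1;
    return i >= 0 && species[i] == 2 && partner[i] >= 0;
  }
  bool long_complex_near(int n) const {
    int x0 = nx(n), y0 = ny(n);
    for (const DiscOffset &o : neigh_disc) {
      int dx = (int)std::lround(o.ux * o.r), dy = (int)std::lround(o.uy * o.r);
      if (o.r == 0.0) { dx = 0; dy = 0; }
      int x = x0 + dx, y = y0 + dy;
      if (!in_bounds(x, y)) continue;
      if (long_complex_at(y * L + x)) return true;
    }
    return false;
  }

  void foci_phase() {
    int NN = L * L;
    for (int n = 0; n < NN; ++n) {
      if (!active[n]) continue;
      int s = fstate[n];
      if (s == F_EMPTY) {
        if (p_nucleate > 0.0 && short_complex_at(n) &&
            rng_foci.unif() < p_nucleate) {
          fstate[n] = F_NUC; fage[n] = 0;
        }
        continue;
      }
      // self-inhibition first, then forward transitions
      if (p_decay > 0.0 && rng_foci.unif() < p_decay) {
        fstate[n] = F_EMPTY; fage[n] = 0;
        continue;
      }
      if (s == F_NUC && p_nuc_poly > 0.0 && long_complex_at(n) &&
          rng_foci.unif() < p_nuc_poly) {
        fstate[n] = F_NUCPOL; fage[n] = 0;
        continue;
      }
      if ((s == F_NUC || s == F_NUCPOL) && p_poly > 0.0 &&
          long_complex_near(n) && rng_foci.unif() < p_poly) {
        fstate[n] = F_POL; fage[n] = 0;
        continue;
      }
      fage[n]++;
    }
  }

  // --- invariants -----------------------------------------------------
  void assert_invariants() const {
    std::vector<int> seen[2];
    seen[0].assign(L * L, 0); seen[1].assign(L * L, 0);
    std::vector<int> cnt(4, 0);
    int n_ag = species.size();
    for (int i = 0; i < n_ag; ++i) {
      int side = SP_SIDE[species[i]];
      if (++seen[side][node[i]] > 1) stop("exclusion violated");
      cnt[species[i]]++;
      if (partner[i] >= 0) {
        int j = partner[i];
        if (partner[j] != i) stop("partner links not mutual");
        if (node[j] != node[i]) stop("bound pair not colocalised");
        int a = species[i], b = species[j];
        bool ok = (a == 0 && b == 1) || (a == 1 && b == 0) ||
                  (a == 2 && b == 3) || (a == 3 && b == 2);
        if (!ok) stop("bound pair species mismatch");
      }
      if (!active[node[i]]) stop("agent outside the active domain");
    }
    for (int s = 0; s < 4; ++s)
      if (cnt[s] != counts0[s]) stop("species count not conserved");
  }

  // --- observation ----------------------------------------------------
  void observe(double *row) const {
    int freec[4] = {0, 0, 0, 0}; int bshort = 0, blong = 0;
    int n_ag = species.size();
    for (int i = 0; i < n_ag; ++i) {
      if (partner[i] < 0) freec[species[i]]++;
      else if (species[i] == 0) bshort++;
      else if (species[i] == 2) blong++;
    }
    int fc[4] = {0, 0, 0, 0};
    for (int n = 0; n < L * L; ++n) if (active[n]) fc[fstate[n]]++;
    // 4-connected clusters of polymerisation nodes
    int clusters = 0;
    std::vector<uint8_t> vis(L * L, 0);
    std::vector<int> stack;
    for (int n = 0; n < L * L; ++n) {
      if (fstate[n] != F_POL || vis[n]) continue;
      ++clusters; vis[n] = 1; stack.push_back(n);
      while (!stack.empty()) {
        int m = stack.back(); stack.pop_back();
        int x = nx(m), y = ny(m);
        const int dxs[4] = {0, 0, -1, 1}, dys[4] = {-1, 1, 0, 0};
        for (int k = 0; k < 4; ++k) {
          int xx = x + dxs[k], yy = y + dys[k];
          if (!in_bounds(xx, yy)) continue;
          int t = yy * L + xx;
          if (fstate[t] == F_POL && !vis[t]) { vis[t] = 1; stack.push_back(t); }
        }
      }
    }
    row[0] = (step_no) * tau;
    row[1] = freec[0]; row[2] = freec[1]; row[3] = bshort;
    row[4] = freec[2]; row[5] = freec[3]; row[6] = blong;
    row[7] = fc[F_NUC]; row[8] = fc[F_NUCPOL]; row[9] = fc[F_POL];
    row[10] = clusters;
  }
};

// ------------------------------------------------------------ interface --

// [[Rcpp::export]]
List cpp_run(List state, List params, int n_steps, IntegerVector record_steps,
             List phases) {
  Engine E;
  E.L = as<int>(state["L"]);
  E.spacing = as<double>(state["spacing"]);
  E.radius = as<double>(state["radius"]);
  E.tau = as<double>(state["tau"]);
  E.cx = (E.L - 1) / 2.0; E.cy = (E.L - 1) / 2.0;
  IntegerVector act = state["active"];
  E.active.assign(act.begin(), act.end());

  IntegerVector sp = state["species"], nd = state["node"], pr = state["partner"];
  if (sp.size() != nd.size() || sp.size() != pr.size())
    stop("species, node and partner vectors must have equal length");
  for (int i = 0; i < sp.size(); ++i) {
    if (sp[i] < 0 || sp[i] > 3) stop("invalid species code");
    if (nd[i] < 0 || nd[i] >= E.L * E.L) stop("node index out of range");
    if (pr[i] >= sp.size()) stop("partner index out of range");
  }
  E.species.assign(sp.begin(), sp.end());
  E.node.assign(nd.begin(), nd.end());
  E.partner.assign(pr.begin(), pr.end());
  E.bind_step.assign(E.species.size(), 0L);
  IntegerVector fs = state["fstate"], fa = state["fage"];
  E.fstate.assign(fs.begin(), fs.end());
  E.fage.assign(fa.begin(), fa.end());

  NumericVector pmsp = params["p_move_species"], pmcx = params["p_move_complex"];
  NumericVector pon = params["p_on"], poff = params["p_off"];
  for (int i = 0; i < 4; ++i) E.p_move_sp[i] = pmsp[i];
  for (int i = 0; i < 2; ++i) {
    E.p_move_cx[i] = pmcx[i]; E.p_on[i] = pon[i]; E.p_off[i] = poff[i];
  }
  E.B_global = as<double>(params["B_global"]);

  E.coupling_enabled = as<bool>(params["coupling_enabled"]);
  E.sbs_strength = as<double>(params["sbs_strength"]);
  NumericVector cen = params["centripetal_strength"];
  E.cen_strength[0] = cen[0];
  E.cen_strength[1] = cen.size() > 1 ? cen[1] : cen[0];
  E.R_force = as<double>(params["R_force"]);
  E.sbs_inverse_r = as<bool>(params["sbs_inverse_r"]);
  E.force_interval = as<int>(params["force_update_interval"]);

  E.foci_enabled = as<bool>(params["foci_enabled"]);
  E.feedback_all_states = as<bool>(params["feedback_all_states"]);
  E.p_nucleate = as<double>(params["p_nucleate"]);
  E.p_nuc_poly = as<double>(params["p_nuc_polymerize"]);
  E.p_poly = as<double>(params["p_polymerize"]);
  E.p_decay = as<double>(params["p_decay"]);
  E.foci_B = as<double>(params["B"]);
  E.R_neigh = as<double>(params["R_neighborhood"]);
  E.neigh_disc = disc_offsets(E.L, E.R_neigh / E.spacing, true);
  E.force_disc = disc_offsets(E.L, E.R_force / E.spacing, false);

  if (params.containsElementNamed("b_field") &&
      !Rf_isNull(params["b_field"])) {
    NumericVector bf = params["b_field"];
    E.b_override.assign(bf.begin(), bf.end());
    E.has_override = true;
  }

  E.check_invariants = as<bool>(params["check_invariants"]);
  E.collect_lifetimes = as<bool>(params["collect_lifetimes"]);
  bool track_nodes = as<bool>(params["track_nodes"]);

  E.step_no = (long)as<double>(state["step"]);
  // mix the starting step into the stream seeds so that continued runs
  // (repeated single-step calls) draw fresh randomness
  uint64_t seed = (uint64_t)as<double>(params["seed"]);
  uint64_t s0 = seed * 0x9e3779b97f4a7c15ULL + (uint64_t)E.step_no;
  E.rng_main.seed(splitmix64(s0));
  E.rng_foci.seed(splitmix64(s0));

  bool do_move = as<bool>(phases["move"]);
  bool do_unbind = as<bool>(phases["unbind"]);
  bool do_bind = as<bool>(phases["bind"]);
  bool do_foci = as<bool>(phases["foci"]) && E.foci_enabled;

  E.build_grids();
  E.counts0.assign(4, 0);
  for (size_t i = 0; i < E.species.size(); ++i) E.counts0[E.species[i]]++;

  const int OBS_COLS = 11;
  NumericMatrix obs(record_steps.size(), OBS_COLS);
  int rec_i = 0;
  IntegerMatrix tracked;
  if (track_nodes)
    tracked = IntegerMatrix(E.species.size(), record_steps.size());

  long step0 = E.step_no;
  for (int s = 0; s < n_steps; ++s) {
    if (do_move) {
      if (E.sbs_strength > 0.0 &&
          (s % E.force_interval == 0))
        E.recompute_force_field();
      E.move_phase();
    }
    if (do_unbind) E.unbind_phase();
    if (do_bind) E.bind_phase();
    if (do_foci) E.foci_phase();
    E.step_no++;
    if (E.check_invariants) E.assert_invariants();
    if (rec_i < record_steps.size() &&
        (E.step_no - step0) == record_steps[rec_i]) {
      double row[OBS_COLS];
      E.observe(row);
      for (int k = 0; k < OBS_COLS; ++k) obs(rec_i, k) = row[k];
      if (track_nodes)
        for (size_t i = 0; i < E.species.size(); ++i)
          tracked(i, rec_i) = E.node[i];
      rec_i++;
    }
    if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["node"] = IntegerVector(E.node.begin(), E.node.end()),
    _["partner"] = IntegerVector(E.partner.begin(), E.partner.end()),
    _["fstate"] = IntegerVector(E.fstate.begin(), E.fstate.end()),
    _["fage"] = IntegerVector(E.fage.begin(), E.fage.end()),
    _["step"] = (double)E.step_no,
    _["obs"] = obs,
    _["clamp_events"] = (double)E.clamp_events,
    _["lifetimes"] = NumericVector(E.lifetimes.begin(), E.lifetimes.end()));
  if (track_nodes) out["tracked"] = tracked;
  return out;
}

// Per-node 4-connected cluster count of an integer matrix == value.
// [[Rcpp::export]]
int cpp_cluster_count(IntegerVector fstate, int L, int value) {
  std::vector<uint8_t> vis(L * L, 0);
  std::vector<int> stack;
  int clusters = 0;
  for (int n = 0; n < L * L; ++n) {
    if (fstate[n] != value || vis[n]) continue;
    ++clusters; vis[n] = 1; stack.push_back(n);
    while (!stack.empty()) {
      int m = stack.back(); stack.pop_back();
      int x = m % L, y = m / L;
      const int dxs[4] = {0, 0, -1, 1}, dys[4] = {-1, 1, 0, 0};
      for (int k = 0; k < 4; ++k) {
        int xx = x + dxs[k], yy = y + dys[k];
        if (xx < 0 || xx >= L || yy < 0 || yy >= L) continue;
        int t = yy * L + xx;
        if (fstate[t] == value && !vis[t]) { vis[t] = 1; stack.push_back(t); }
      }
    }
  }
  return clusters;
}
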