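// Metropolis Monte Carlo kernel for the semi-grand-canonical actomyosin cortex.
//
// Lattice layout: W x H nodes, each with one vertical slot (north/south
// monomers) and one horizontal slot (east/west).  Crosslinkers (ACs) and
// myosin occupy lattice edges (east edge from node (x,y) to (x+1,y), north
// edge to (x,y+1)); an edge holds at most one AC and one myosin.
//
// Filament identity is bond-based: each monomer carries a "bonded behind"
// flag, set when it was inserted in front of the barbed end of a
// same-orientation run.  Chains are maximal bond-connected runs; a chain of
// >= 3 monomers is a filament.  The pointed terminal (first chain member)
// has its polymer bond destabilised: its removal energy omits E0.
//
// RNG: R's uniform generator, consumed in a fixed documented order per
// iteration: position x, position y, actin orientation, [actin acceptance],
// edge direction, [AC pair tie-break], [AC acceptance], [myosin pair
// tie-break], [myosin acceptance].  Draws in brackets are consumed only when
// the corresponding attempt is evaluated.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
#include <functional>
using namespace Rcpp;

namespace {

struct Chain {
  bool alive = false;
  int ori = 0;           // 1=N 2=S 3=E 4=W
  int px = 0, py = 0;    // pointed-end position
  int len = 0;
  double accrued = 0.0;  // frozen load: departed myosins + redistribution
  int nmyo = 0;          // currently attached active myosins
  double sum_attach = 0.0; // sum of their attachment times (seconds)
};

struct Link {
  int ex, ey, edir;      // edge: base node + direction (0 east, 1 north)
  int axa, axb;          // endpoint axes at base node (a) / far node (b)
  double attach_sec;     // myosin only
  int active;            // myosin only
};

struct Pars {
  int W, H;
  bool periodic;
  double mu0[3], N0[3], gamma[3], Elink[3];
  double E0, W3, kappa, loginv; // loginv = 1/log(base)
  bool forbid_interior, ac_any, independent_positions;
  int check_every;
};

inline int axis_of(int ori) { return (ori <= 2) ? 0 : 1; }
inline bool opposite(int o1, int o2) {
  return (o1 == 1 && o2 == 2) || (o1 == 2 && o2 == 1) ||
         (o1 == 3 && o2 == 4) || (o1 == 4 && o2 == 3);
}

struct Sim {
  Pars P;
  std::vector<int> ori[2], tins[2], bond[2], fid[2];
  std::vector<Chain> chains;
  std::vector<int> freeids;
  std::vector<Link> acv, myv;
  std::vector<int> ac_at[2], my_at[2]; // per-edge record index or -1
  double res[3];
  int n1grid;
  long it;
  // detachment event log rows: it, n_detached, monomers_released,
  // redistributed, discarded
  std::vector<double> events;

  int nidx(int x, int y) const { return x + P.W * y; }

  bool step_dir(int o, int x, int y, int &nx, int &ny) const {
    nx = x; ny = y;
    switch (o) {
      case 1: ny = y + 1; break;
      case 2: ny = y - 1; break;
      case 3: nx = x + 1; break;
      case 4: nx = x - 1; break;
    }
    if (P.periodic) {
      nx = (nx + P.W) % P.W;
      ny = (ny + P.H) % P.H;
      return true;
    }
    return nx >= 0 && nx < P.W && ny >= 0 && ny < P.H;
  }
  static int flip(int o) { return (o == 1) ? 2 : (o == 2) ? 1 : (o == 3) ? 4 : 3; }
  bool front_of(int o, int x, int y, int &nx, int &ny) const { return step_dir(o, x, y, nx, ny); }
  bool behind_of(int o, int x, int y, int &nx, int &ny) const { return step_dir(flip(o), x, y, nx, ny); }

  double t_sec(long iter) const {
    return (double)iter / (2.0 * P.W * P.H) * P.kappa * 60.0;
  }

  int new_chain() {
    int id;
    if (!freeids.empty()) { id = freeids.back(); freeids.pop_back(); }
    else { id = (int)chains.size(); chains.push_back(Chain()); }
    chains[id] = Chain();
    chains[id].alive = true;
    return id;
  }
  void free_chain(int id) { chains[id].alive = false; freeids.push_back(id); }

  double eload(const Chain &c, double t) const {
    return c.accrued + P.W3 * (c.nmyo * t - c.sum_attach);
  }

  // --- edge helpers ---------------------------------------------------
  bool edge_valid(int ex, int ey, int d, int &bx, int &by) const {
    bx = ex; by = ey;
    if (d == 0) bx = ex + 1; else by = ey + 1;
    if (P.periodic) { bx %= P.W; by %= P.H; return true; }
    return bx < P.W && by < P.H;
  }

  // incident edges of node (x,y): fills arrays of (ex,ey,dir,role) where
  // role 0 = node is base (a) endpoint, 1 = node is far (b) endpoint.
  int incident_edges(int x, int y, int ex[4], int ey[4], int ed[4], int role[4]) const {
    int n = 0;
    int bx, by;
    if (edge_valid(x, y, 0, bx, by)) { ex[n]=x; ey[n]=y; ed[n]=0; role[n]=0; n++; }
    if (edge_valid(x, y, 1, bx, by)) { ex[n]=x; ey[n]=y; ed[n]=1; role[n]=0; n++; }
    int px = x - 1, py = y;
    if (P.periodic) px = (px + P.W) % P.W;
    if (px >= 0 && edge_valid(px, py, 0, bx, by)) { ex[n]=px; ey[n]=py; ed[n]=0; role[n]=1; n++; }
    px = x; py = y - 1;
    if (P.periodic) py = (py + P.H) % P.H;
    if (py >= 0 && edge_valid(px, py, 1, bx, by)) { ex[n]=px; ey[n]=py; ed[n]=1; role[n]=1; n++; }
    return n;
  }

  void unregister_link(std::vector<Link> &v, std::vector<int> *at, int idx) {
    const Link &L = v[idx];
    at[L.edir][nidx(L.ex, L.ey)] = -1;
    if (idx != (int)v.size() - 1) {
      v[idx] = v.back();
      at[v[idx].edir][nidx(v[idx].ex, v[idx].ey)] = idx;
    }
    v.pop_back();
  }

  // --- myosin load bookkeeping ----------------------------------------
  void endpoint_chains(const Link &m, int &fa, int &fb) const {
    int bx, by;
    int exx = m.ex, eyy = m.ey;
    fa = fid[m.axa][nidx(exx, eyy)];
    edge_valid(exx, eyy, m.edir, bx, by);
    fb = fid[m.axb][nidx(bx, by)];
  }

  void freeze_myosin(Link &m, double t) {
    // freeze the accumulated contribution of an active myosin into both
    // bridged chains' accrued load and drop it from the live aggregates
    int fa, fb;
    endpoint_chains(m, fa, fb);
    double contrib = P.W3 * (t - m.attach_sec);
    int cs[2] = { fa, fb };
    for (int k = 0; k < 2; k++) {
      if (cs[k] >= 0 && chains[cs[k]].alive) {
        chains[cs[k]].accrued += contrib;
        chains[cs[k]].nmyo -= 1;
        chains[cs[k]].sum_attach -= m.attach_sec;
      }
    }
    m.active = 0;
  }

  void inactivate_myosins_on(int cid, double t) {
    for (size_t i = 0; i < myv.size(); i++) {
      if (!myv[i].active) continue;
      int fa, fb;
      endpoint_chains(myv[i], fa, fb);
      if (fa == cid || fb == cid) freeze_myosin(myv[i], t);
    }
  }

  // dissolve all AC / myosin links touching slot (x,y,axis); molecules
  // return to their reservoirs
  void dissolve_links_at(int x, int y, int axis, double t) {
    int ex[4], ey[4], ed[4], role[4];
    int ne = incident_edges(x, y, ex, ey, ed, role);
    for (int k = 0; k < ne; k++) {
      int ei = nidx(ex[k], ey[k]);
      int ai = ac_at[ed[k]][ei];
      if (ai >= 0) {
        const Link &L = acv[ai];
        if ((role[k] == 0 && L.axa == axis) || (role[k] == 1 && L.axb == axis)) {
          unregister_link(acv, ac_at, ai);
          res[1] += 1;
        }
      }
      int mi = my_at[ed[k]][ei];
      if (mi >= 0) {
        Link &M = myv[mi];
        if ((role[k] == 0 && M.axa == axis) || (role[k] == 1 && M.axb == axis)) {
          if (M.active) freeze_myosin(M, t);
          unregister_link(myv, my_at, mi);
          res[2] += 1;
        }
      }
    }
  }

  double link_energy_at(int x, int y, int axis) const {
    double E = 0.0;
    int ex[4], ey[4], ed[4], role[4];
    int ne = incident_edges(x, y, ex, ey, ed, role);
    for (int k = 0; k < ne; k++) {
      int ei = nidx(ex[k], ey[k]);
      int ai = ac_at[ed[k]][ei];
      if (ai >= 0) {
        const Link &L = acv[ai];
        if ((role[k] == 0 && L.axa == axis) || (role[k] == 1 && L.axb == axis))
          E += P.Elink[1];
      }
      int mi = my_at[ed[k]][ei];
      if (mi >= 0) {
        const Link &M = myv[mi];
        if ((role[k] == 0 && M.axa == axis) || (role[k] == 1 && M.axb == axis))
          E += P.Elink[2];
      }
    }
    return E;
  }

  // --- actin insertion / removal --------------------------------------
  void insert_monomer(int x, int y, int o, long iter) {
    int axis = axis_of(o), idx = nidx(x, y);
    ori[axis][idx] = o;
    tins[axis][idx] = (int)iter;
    int bx, by;
    bool bonded = false;
    if (behind_of(o, x, y, bx, by)) {
      int bidx = nidx(bx, by);
      if (ori[axis][bidx] == o) bonded = true;
    }
    bond[axis][idx] = bonded ? 1 : 0;
    if (bonded) {
      int c = fid[axis][nidx(bx, by)];
      fid[axis][idx] = c;
      chains[c].len += 1;
    } else {
      int c = new_chain();
      chains[c].ori = o;
      chains[c].px = x; chains[c].py = y;
      chains[c].len = 1;
      fid[axis][idx] = c;
    }
    n1grid += 1;
    res[0] -= 1;
  }

  bool is_interior(int x, int y, int axis) const {
    int idx = nidx(x, y);
    if (!bond[axis][idx]) return false;
    int o = ori[axis][idx];
    int fx, fy;
    if (!front_of(o, x, y, fx, fy)) return false;
    int fdx = nidx(fx, fy);
    return ori[axis][fdx] == o && bond[axis][fdx] == 1;
  }

  void remove_monomer(int x, int y, int axis, double t) {
    int idx = nidx(x, y);
    int o = ori[axis][idx];
    int c = fid[axis][idx];
    dissolve_links_at(x, y, axis, t);
    Chain &ch = chains[c];
    bool pointed = (ch.px == x && ch.py == y);
    int fx, fy, fdx = -1;
    bool has_front = false;
    if (front_of(o, x, y, fx, fy)) {
      fdx = nidx(fx, fy);
      has_front = (ori[axis][fdx] == o && bond[axis][fdx] == 1);
    }
    if (ch.len == 1) {
      free_chain(c);
    } else if (pointed) {
      bond[axis][fdx] = 0;
      ch.px = fx; ch.py = fy;
      ch.len -= 1;
      if (ch.len == 2) inactivate_myosins_on(c, t);
    } else if (!has_front) {           // barbed terminal
      ch.len -= 1;
      if (ch.len == 2) inactivate_myosins_on(c, t);
    } else {                            // interior: split the chain
      split_chain(c, x, y, axis, fx, fy, t);
    }
    ori[axis][idx] = 0;
    bond[axis][idx] = 0;
    tins[axis][idx] = 0;
    fid[axis][idx] = -1;
    n1grid -= 1;
    res[0] += 1;
  }

  void split_chain(int c, int x, int y, int axis, int fx, int fy, double t) {
    Chain &ch = chains[c];
    int o = ch.ori;
    int c2 = new_chain();
    Chain &nc = chains[c2];
    nc.ori = o; nc.px = fx; nc.py = fy;
    int cx = fx, cy = fy, len2 = 0;
    while (true) {
      int ci = nidx(cx, cy);
      fid[axis][ci] = c2;
      len2++;
      int nx2, ny2;
      if (!front_of(o, cx, cy, nx2, ny2)) break;
      int ni = nidx(nx2, ny2);
      if (ori[axis][ni] != o || bond[axis][ni] != 1) break;
      cx = nx2; cy = ny2;
    }
    bond[axis][nidx(fx, fy)] = 0;
    nc.len = len2;
    int len1 = ch.len - len2 - 1;
    double tot = ch.accrued;
    ch.len = len1;
    ch.accrued = (len1 + len2 > 0) ? tot * (double)len1 / (len1 + len2) : 0.0;
    nc.accrued = tot - ch.accrued;
    // rebuild live myosin aggregates for both fragments
    ch.nmyo = 0; ch.sum_attach = 0; nc.nmyo = 0; nc.sum_attach = 0;
    for (size_t i = 0; i < myv.size(); i++) {
      if (!myv[i].active) continue;
      int fa, fb; endpoint_chains(myv[i], fa, fb);
      int cs[2] = { fa, fb };
      for (int k = 0; k < 2; k++) {
        if (cs[k] == c) { ch.nmyo++; ch.sum_attach += myv[i].attach_sec; }
        if (cs[k] == c2) { nc.nmyo++; nc.sum_attach += myv[i].attach_sec; }
      }
    }
    if (ch.len < 3) inactivate_myosins_on(c, t);
    if (nc.len < 3) inactivate_myosins_on(c2, t);
    if (ch.len == 0) free_chain(c);
  }

  // --- AC / myosin eligibility ----------------------------------------
  // collects candidate endpoint-axis pairs at an edge; order pinned:
  // (vert,vert), (vert,horiz), (horiz,vert), (horiz,horiz)
  int eligible_pairs(int ex, int ey, int d, bool need_antiparallel,
                     int axa[4], int axb[4]) const {
    int bx, by;
    if (!edge_valid(ex, ey, d, bx, by)) return 0;
    int ia = nidx(ex, ey), ib = nidx(bx, by);
    int n = 0;
    for (int aa = 0; aa < 2; aa++) {
      int oa = ori[aa][ia];
      if (!oa) continue;
      for (int ab = 0; ab < 2; ab++) {
        int ob = ori[ab][ib];
        if (!ob) continue;
        int fa = fid[aa][ia], fb = fid[ab][ib];
        if (fa == fb) continue;
        if (!P.ac_any || need_antiparallel) {
          if (chains[fa].len < 3 || chains[fb].len < 3) continue;
        }
        if (need_antiparallel && !opposite(oa, ob)) continue;
        axa[n] = aa; axb[n] = ab; n++;
      }
    }
    return n;
  }

  // --- detachment processing ------------------------------------------
  void process_detachments(long iter) {
    double t = t_sec(iter);
    double E1 = P.Elink[0];
    while (true) {
      std::vector<int> D;
      for (size_t c = 0; c < chains.size(); c++) {
        if (!chains[c].alive || chains[c].len < 3) continue;
        if (eload(chains[c], t) > E1 * chains[c].len) D.push_back((int)c);
      }
      if (D.empty()) return;

      // connected components over filaments via AC + active myosin links
      std::vector<int> parent(chains.size());
      for (size_t i = 0; i < parent.size(); i++) parent[i] = (int)i;
      std::function<int(int)> find = [&](int a) {
        while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
        return a;
      };
      auto join = [&](int a, int b) { parent[find(a)] = find(b); };
      auto link_join = [&](const Link &L) {
        int fa, fb; endpoint_chains(L, fa, fb);
        if (fa >= 0 && fb >= 0 && chains[fa].alive && chains[fb].alive &&
            chains[fa].len >= 3 && chains[fb].len >= 3 && fa != fb)
          join(fa, fb);
      };
      for (size_t i = 0; i < acv.size(); i++) link_join(acv[i]);
      for (size_t i = 0; i < myv.size(); i++) if (myv[i].active) link_join(myv[i]);

      std::vector<bool> detaching(chains.size(), false);
      for (int d : D) detaching[d] = true;

      double redistributed = 0.0, discarded = 0.0;
      int monomers_released = 0;
      // redistribute each detaching filament's load among surviving
      // filaments of its component
      for (int d : D) {
        double load = eload(chains[d], t);
        int root = find(d);
        std::vector<int> recip;
        for (size_t c = 0; c < chains.size(); c++) {
          if (!chains[c].alive || chains[c].len < 3 || detaching[c]) continue;
          if (find((int)c) == root) recip.push_back((int)c);
        }
        if (recip.empty()) {
          discarded += load;
        } else {
          double share = load / recip.size();
          for (int r : recip) chains[r].accrued += share;
          redistributed += load;
        }
      }
      // teardown: monomers and attached linkers return to the reservoirs
      for (int d : D) {
        monomers_released += chains[d].len;
        teardown_chain(d, t);
      }
      events.push_back((double)iter);
      events.push_back((double)D.size());
      events.push_back((double)monomers_released);
      events.push_back(redistributed);
      events.push_back(discarded);
      // redistribution may push survivors over threshold: cascade
    }
  }

  void teardown_chain(int c, double t) {
    Chain &ch = chains[c];
    int o = ch.ori, axis = axis_of(o);
    int x = ch.px, y = ch.py;
    int n = ch.len;
    for (int k = 0; k < n; k++) {
      int idx = nidx(x, y);
      dissolve_links_at(x, y, axis, t);
      ori[axis][idx] = 0; bond[axis][idx] = 0; tins[axis][idx] = 0;
      fid[axis][idx] = -1;
      n1grid -= 1; res[0] += 1;
      if (k < n - 1) {
        int nx2, ny2;
        front_of(o, x, y, nx2, ny2);
        x = nx2; y = ny2;
      }
    }
    free_chain(c);
  }

  // --- chemical potential ----------------------------------------------
  // returns acceptance weight P+ = exp(mu_i); certain acceptance when the
  // grid is empty of species i and gamma > 0
  double insertion_weight(int sp) const {
    int N = (sp == 0) ? n1grid : (sp == 1) ? (int)acv.size() : (int)myv.size();
    if (P.gamma[sp] > 0 && N == 0) return R_PosInf;
    double mu = P.mu0[sp];
    if (P.gamma[sp] != 0)
      mu -= P.gamma[sp] * std::log((double)N / P.N0[sp]) * P.loginv;
    return std::exp(mu);
  }

  // --- one Monte Carlo iteration ---------------------------------------
  void mc_iteration(long iter) {
    int x = (int)std::floor(unif_rand() * P.W); if (x >= P.W) x = P.W - 1;
    int y = (int)std::floor(unif_rand() * P.H); if (y >= P.H) y = P.H - 1;
    double t = t_sec(iter);

    // ---- actin: orientation draw selects the slot ----
    int o = 1 + (int)std::floor(unif_rand() * 4.0); if (o > 4) o = 4;
    int axis = axis_of(o), idx = nidx(x, y);
    if (ori[axis][idx] == 0) {
      if (res[0] >= 1) {
        double Pacc = insertion_weight(0);
        if (unif_rand() < Pacc) insert_monomer(x, y, o, iter);
      }
    } else {
      bool interior = is_interior(x, y, axis);
      if (!(interior && P.forbid_interior)) {
        double E = P.Elink[0] + (bond[axis][idx] ? P.E0 : 0.0) +
                   link_energy_at(x, y, axis);
        if (unif_rand() < std::exp(-E)) remove_monomer(x, y, axis, t);
      }
    }

    // ---- shared edge draw for ACs and myosin ----
    if (P.independent_positions) {
      x = (int)std::floor(unif_rand() * P.W); if (x >= P.W) x = P.W - 1;
      y = (int)std::floor(unif_rand() * P.H); if (y >= P.H) y = P.H - 1;
    }
    int d = (unif_rand() < 0.5) ? 0 : 1;
    int bx, by;
    if (edge_valid(x, y, d, bx, by)) {
      int ei = nidx(x, y);
      // ---- AC ----
      int ai = ac_at[d][ei];
      if (ai >= 0) {
        if (unif_rand() < std::exp(-2.0 * P.Elink[1])) {
          unregister_link(acv, ac_at, ai);
          res[1] += 1;
        }
      } else if (res[1] >= 1) {
        int axa[4], axb[4];
        int np = eligible_pairs(x, y, d, false, axa, axb);
        if (np > 0) {
          int k = 0;
          if (np > 1) { k = (int)std::floor(unif_rand() * np); if (k >= np) k = np - 1; }
          if (unif_rand() < insertion_weight(1)) {
            Link L; L.ex = x; L.ey = y; L.edir = d;
            L.axa = axa[k]; L.axb = axb[k];
            L.attach_sec = 0; L.active = 0;
            ac_at[d][ei] = (int)acv.size();
            acv.push_back(L);
            res[1] -= 1;
          }
        }
      }
      // ---- myosin ----
      int mi = my_at[d][ei];
      if (mi >= 0) {
        if (!myv[mi].active) {
          // broken bridge: deterministic return to the reservoir
          unregister_link(myv, my_at, mi);
          res[2] += 1;
        } else if (unif_rand() < std::exp(-2.0 * P.Elink[2])) {
          freeze_myosin(myv[mi], t);
          unregister_link(myv, my_at, mi);
          res[2] += 1;
        }
      } else if (res[2] >= 1) {
        int axa[4], axb[4];
        int np = eligible_pairs(x, y, d, true, axa, axb);
        if (np > 0) {
          int k = 0;
          if (np > 1) { k = (int)std::floor(unif_rand() * np); if (k >= np) k = np - 1; }
          if (unif_rand() < insertion_weight(2)) {
            Link M; M.ex = x; M.ey = y; M.edir = d;
            M.axa = axa[k]; M.axb = axb[k];
            M.attach_sec = t; M.active = 1;
            my_at[d][ei] = (int)myv.size();
            myv.push_back(M);
            res[2] -= 1;
            int fa, fb; endpoint_chains(M, fa, fb);
            chains[fa].nmyo++; chains[fa].sum_attach += t;
            chains[fb].nmyo++; chains[fb].sum_attach += t;
          }
        }
      }
    }

    process_detachments(iter);
  }

  // --- invariants (fuzz-test support) ----------------------------------
  void check_invariants() const {
    int count = 0;
    for (int a = 0; a < 2; a++)
      for (int i = 0; i < P.W * P.H; i++) {
        if (ori[a][i]) {
          count++;
          if (axis_of(ori[a][i]) != a) stop("monomer on wrong axis slot");
          int c = fid[a][i];
          if (c < 0 || !chains[c].alive) stop("slot without live chain");
        } else if (fid[a][i] != -1) stop("empty slot carries a chain id");
      }
    if (count != n1grid) stop("actin grid count out of sync");
    if (std::abs(count + res[0] - P.N0[0]) > 1e-9) stop("actin conservation violated");
    if (std::abs((double)acv.size() + res[1] - P.N0[1]) > 1e-9) stop("AC conservation violated");
    if (std::abs((double)myv.size() + res[2] - P.N0[2]) > 1e-9) stop("myosin conservation violated");
    // chain registry consistent with bond structure
    std::vector<int> lens(chains.size(), 0);
    for (int a = 0; a < 2; a++)
      for (int i = 0; i < P.W * P.H; i++)
        if (ori[a][i]) lens[fid[a][i]]++;
    for (size_t c = 0; c < chains.size(); c++) {
      if (!chains[c].alive) continue;
      if (lens[c] != chains[c].len) stop("chain length out of sync");
      int axis = axis_of(chains[c].ori);
      int pidx = nidx(chains[c].px, chains[c].py);
      if (ori[axis][pidx] != chains[c].ori || fid[axis][pidx] != (int)c)
        stop("chain pointed end out of sync");
      if (bond[axis][pidx]) stop("pointed terminal carries a bond");
    }
    // links reference occupied slots
    for (size_t i = 0; i < acv.size() + myv.size(); i++) {
      const Link &L = (i < acv.size()) ? acv[i] : myv[i - acv.size()];
      int bx2, by2;
      if (!const_cast<Sim *>(this)->edge_valid(L.ex, L.ey, L.edir, bx2, by2))
        stop("link on invalid edge");
      if (!ori[L.axa][nidx(L.ex, L.ey)] || !ori[L.axb][nidx(bx2, by2)])
        stop("link endpoint slot is empty");
    }
  }
};

// ----------------------------------------------------------------------
// marshalling between the R state list and the kernel

Pars load_params(List params) {
  Pars P;
  P.W = as<int>(params["width"]);
  P.H = as<int>(params["height"]);
  P.periodic = as<bool>(params["periodic"]);
  NumericVector mu0 = params["mu0"], N0 = params["N0"],
                gamma = params["gamma"], El = params["E_link"];
  for (int i = 0; i < 3; i++) {
    P.mu0[i] = mu0[i]; P.N0[i] = N0[i]; P.gamma[i] = gamma[i]; P.Elink[i] = El[i];
  }
  P.E0 = as<double>(params["E0"]);
  P.W3 = as<double>(params["W3"]);
  P.kappa = as<double>(params["kappa"]);
  P.loginv = 1.0 / std::log(as<double>(params["log_base"]));
  P.forbid_interior = as<bool>(params["forbid_interior_removal"]);
  P.ac_any = as<bool>(params["ac_link_oligomers"]);
  P.independent_positions = as<bool>(params["independent_positions"]);
  P.check_every = as<int>(params["check_every"]);
  return P;
}

void import_links(Sim &S, DataFrame df, bool myosin) {
  IntegerVector xa = df["xa"], ya = df["ya"], axa = df["axa"],
                xb = df["xb"], yb = df["yb"], axb = df["axb"];
  NumericVector attach;
  IntegerVector active;
  if (myosin) { attach = df["attach_sec"]; active = df["active"]; }
  for (int i = 0; i < df.nrows(); i++) {
    Link L;
    // R-facing tables are 1-based; the kernel is 0-based
    int XA = xa[i] - 1, YA = ya[i] - 1, XB = xb[i] - 1, YB = yb[i] - 1;
    // identify the edge from the two endpoint nodes (base = a)
    int dx = XB - XA, dy = YB - YA;
    if (S.P.periodic) {
      dx = ((dx % S.P.W) + S.P.W) % S.P.W; if (dx == S.P.W - 1) dx = -1;
      dy = ((dy % S.P.H) + S.P.H) % S.P.H; if (dy == S.P.H - 1) dy = -1;
    }
    if (dx == 1 && dy == 0) { L.ex = XA; L.ey = YA; L.edir = 0; L.axa = axa[i]; L.axb = axb[i]; }
    else if (dx == -1 && dy == 0) { L.ex = XB; L.ey = YB; L.edir = 0; L.axa = axb[i]; L.axb = axa[i]; }
    else if (dx == 0 && dy == 1) { L.ex = XA; L.ey = YA; L.edir = 1; L.axa = axa[i]; L.axb = axb[i]; }
    else if (dx == 0 && dy == -1) { L.ex = XB; L.ey = YB; L.edir = 1; L.axa = axb[i]; L.axb = axa[i]; }
    else stop("link endpoints are not adjacent nodes");
    L.attach_sec = myosin ? attach[i] : 0.0;
    L.active = myosin ? active[i] : 0;
    std::vector<Link> &v = myosin ? S.myv : S.acv;
    std::vector<int> *at = myosin ? S.my_at : S.ac_at;
    int ei = S.nidx(L.ex, L.ey);
    if (at[L.edir][ei] >= 0) stop("two links of one type on a single edge");
    at[L.edir][ei] = (int)v.size();
    v.push_back(L);
  }
}

Sim load_state(List state, List params) {
  Sim S;
  S.P = load_params(params);
  int n = S.P.W * S.P.H;
  const char *mo[2] = { "vert_ori", "horiz_ori" };
  const char *mt[2] = { "vert_time", "horiz_time" };
  const char *mb[2] = { "vert_bond", "horiz_bond" };
  S.n1grid = 0;
  for (int a = 0; a < 2; a++) {
    IntegerMatrix O = state[mo[a]], T = state[mt[a]], B = state[mb[a]];
    S.ori[a].assign(O.begin(), O.end());
    S.tins[a].assign(T.begin(), T.end());
    S.bond[a].assign(B.begin(), B.end());
    S.fid[a].assign(n, -1);
    S.ac_at[a].assign(n, -1);
    S.my_at[a].assign(n, -1);
    for (int i = 0; i < n; i++) if (S.ori[a][i]) S.n1grid++;
  }
  // rebuild chains from bond flags (scan order: axis, then column-major)
  for (int a = 0; a < 2; a++) {
    for (int yy = 0; yy < S.P.H; yy++) for (int xx = 0; xx < S.P.W; xx++) {
      int i = S.nidx(xx, yy);
      int o = S.ori[a][i];
      if (!o || S.bond[a][i]) continue;    // chain starts at its pointed end
      int c = S.new_chain();
      S.chains[c].ori = o; S.chains[c].px = xx; S.chains[c].py = yy;
      int len = 0, cx = xx, cy = yy;
      while (true) {
        S.fid[a][S.nidx(cx, cy)] = c;
        len++;
        int nx2, ny2;
        if (!S.front_of(o, cx, cy, nx2, ny2)) break;
        int ni = S.nidx(nx2, ny2);
        if (S.ori[a][ni] != o || S.bond[a][ni] != 1) break;
        cx = nx2; cy = ny2;
      }
      S.chains[c].len = len;
    }
  }
  // orphan bonded monomers (bond flag set but behind neighbour differs)
  for (int a = 0; a < 2; a++)
    for (int i = 0; i < n; i++)
      if (S.ori[a][i] && S.fid[a][i] < 0)
        stop("inconsistent bond flags: bonded monomer without a chain");
  NumericVector res = state["reservoir"];
  for (int i = 0; i < 3; i++) S.res[i] = res[i];
  import_links(S, as<DataFrame>(state["acs"]), false);
  import_links(S, as<DataFrame>(state["myosins"]), true);
  // match stored accrued loads to rebuilt chains by pointed end + orientation
  DataFrame loads = as<DataFrame>(state["loads"]);
  if (loads.nrows() > 0) {
    IntegerVector lo = loads["ori"], lx = loads["px"], ly = loads["py"];
    NumericVector la = loads["accrued"];
    for (int i = 0; i < loads.nrows(); i++) {
      bool found = false;
      for (size_t c = 0; c < S.chains.size(); c++) {
        Chain &ch = S.chains[c];
        if (ch.alive && ch.ori == lo[i] && ch.px == lx[i] - 1 && ch.py == ly[i] - 1) {
          ch.accrued = la[i]; found = true; break;
        }
      }
      if (!found) stop("stored filament load does not match any chain");
    }
  }
  // live myosin aggregates
  for (size_t i = 0; i < S.myv.size(); i++) {
    if (!S.myv[i].active) continue;
    int fa, fb; S.endpoint_chains(S.myv[i], fa, fb);
    if (fa < 0 || fb < 0 || S.chains[fa].len < 3 || S.chains[fb].len < 3 || fa == fb) {
      S.myv[i].active = 0;  // hand-built state with a broken bridge
      continue;
    }
    S.chains[fa].nmyo++; S.chains[fa].sum_attach += S.myv[i].attach_sec;
    S.chains[fb].nmyo++; S.chains[fb].sum_attach += S.myv[i].attach_sec;
  }
  S.it = as<double>(state["iteration"]);
  return S;
}

List export_links(const Sim &S, const std::vector<Link> &v, bool myosin) {
  int n = (int)v.size();
  IntegerVector xa(n), ya(n), axa(n), xb(n), yb(n), axb(n), active(n);
  NumericVector attach(n);
  for (int i = 0; i < n; i++) {
    xa[i] = v[i].ex + 1; ya[i] = v[i].ey + 1; axa[i] = v[i].axa;
    int bx, by;
    S.edge_valid(v[i].ex, v[i].ey, v[i].edir, bx, by);
    xb[i] = bx + 1; yb[i] = by + 1; axb[i] = v[i].axb;
    attach[i] = v[i].attach_sec; active[i] = v[i].active;
  }
  if (myosin)
    return DataFrame::create(_["xa"] = xa, _["ya"] = ya, _["axa"] = axa,
                             _["xb"] = xb, _["yb"] = yb, _["axb"] = axb,
                             _["attach_sec"] = attach, _["active"] = active);
  return DataFrame::create(_["xa"] = xa, _["ya"] = ya, _["axa"] = axa,
                           _["xb"] = xb, _["yb"] = yb, _["axb"] = axb);
}

List export_state(const Sim &S) {
  int W = S.P.W, H = S.P.H;
  List out;
  const char *mo[2] = { "vert_ori", "horiz_ori" };
  const char *mt[2] = { "vert_time", "horiz_time" };
  const char *mb[2] = { "vert_bond", "horiz_bond" };
  for (int a = 0; a < 2; a++) {
    IntegerMatrix O(W, H), T(W, H), B(W, H);
    std::copy(S.ori[a].begin(), S.ori[a].end(), O.begin());
    std::copy(S.tins[a].begin(), S.tins[a].end(), T.begin());
    std::copy(S.bond[a].begin(), S.bond[a].end(), B.begin());
    out[mo[a]] = O; out[mt[a]] = T; out[mb[a]] = B;
  }
  out["acs"] = export_links(S, S.acv, false);
  out["myosins"] = export_links(S, S.myv, true);
  // persisted per-filament loads, keyed by pointed end + orientation
  std::vector<int> keep;
  for (size_t c = 0; c < S.chains.size(); c++)
    if (S.chains[c].alive && S.chains[c].accrued != 0.0) keep.push_back((int)c);
  int nl = (int)keep.size();
  IntegerVector lo(nl), lx(nl), ly(nl);
  NumericVector la(nl);
  for (int i = 0; i < nl; i++) {
    const Chain &ch = S.chains[keep[i]];
    lo[i] = ch.ori; lx[i] = ch.px + 1; ly[i] = ch.py + 1; la[i] = ch.accrued;
  }
  out["loads"] = DataFrame::create(_["ori"] = lo, _["px"] = lx, _["py"] = ly,
                                   _["accrued"] = la);
  out["reservoir"] = NumericVector::create(S.res[0], S.res[1], S.res[2]);
  out["iteration"] = (double)S.it;
  out["width"] = W; out["height"] = H;
  out["periodic"] = S.P.periodic;
  return out;
}

// network statistics over filaments (>= 3 monomers): number of components
// with >= 2 filaments, sizes of the two largest in monomers
void network_stats(const Sim &S, int &n_networks, int &largest, int &second) {
  std::vector<int> parent(S.chains.size());
  for (size_t i = 0; i < parent.size(); i++) parent[i] = (int)i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto link_join = [&](const Link &L) {
    int fa, fb; S.endpoint_chains(L, fa, fb);
    if (fa >= 0 && fb >= 0 && S.chains[fa].alive && S.chains[fb].alive &&
        S.chains[fa].len >= 3 && S.chains[fb].len >= 3 && fa != fb)
      parent[find(fa)] = find(fb);
  };
  for (size_t i = 0; i < S.acv.size(); i++) link_join(S.acv[i]);
  for (size_t i = 0; i < S.myv.size(); i++) if (S.myv[i].active) link_join(S.myv[i]);
  std::map<int, std::pair<int, int>> comp; // root -> (n filaments, monomers)
  for (size_t c = 0; c < S.chains.size(); c++) {
    if (!S.chains[c].alive || S.chains[c].len < 3) continue;
    auto &e = comp[find((int)c)];
    e.first += 1; e.second += S.chains[c].len;
  }
  n_networks = 0; largest = 0; second = 0;
  for (auto &kv : comp) {
    if (kv.second.first < 2) continue;
    n_networks++;
    int m = kv.second.second;
    if (m >= largest) { second = largest; largest = m; }
    else if (m > second) second = m;
  }
}

void record_row(const Sim &S, NumericMatrix &traj, int row) {
  double t = S.t_sec(S.it);
  int nfil = 0, in_fil = 0;
  double tension = 0.0;
  for (size_t c = 0; c < S.chains.size(); c++) {
    if (!S.chains[c].alive || S.chains[c].len < 3) continue;
    nfil++; in_fil += S.chains[c].len;
    tension += S.eload(S.chains[c], t);
  }
  int nn, lg, sec;
  network_stats(S, nn, lg, sec);
  traj(row, 0) = (double)S.it;
  traj(row, 1) = t / 60.0;                 // minutes
  traj(row, 2) = (double)S.n1grid;
  traj(row, 3) = (double)in_fil;
  traj(row, 4) = (double)(S.n1grid - in_fil);
  traj(row, 5) = (double)S.acv.size();
  traj(row, 6) = (double)S.myv.size();
  traj(row, 7) = (double)nfil;
  traj(row, 8) = 100.0 * S.n1grid / (2.0 * S.P.W * S.P.H);
  traj(row, 9) = (double)nn;
  traj(row, 10) = (double)lg;
  traj(row, 11) = (double)sec;
  traj(row, 12) = tension;
}

} // namespace

// [[Rcpp::export]]
List cpp_run(List state, List params, double n_iter, int record_every,
             int snapshot_every) {
  Sim S = load_state(state, params);
  long n = (long)n_iter;
  int nrows = (n > 0) ? (int)(n / record_every) + 1 : 0;
  NumericMatrix traj(nrows, 13);
  List snapshots;
  std::vector<List> snaps;
  RNGScope scope;
  int row = 0;
  if (n > 0) { record_row(S, traj, row++); }
  if (n > 0 && snapshot_every > 0) snaps.push_back(export_state(S));
  for (long k = 1; k <= n; k++) {
    S.it += 1;
    S.mc_iteration(S.it);
    if (k % record_every == 0) record_row(S, traj, row++);
    if (snapshot_every > 0 && k % snapshot_every == 0)
      snaps.push_back(export_state(S));
    if (S.P.check_every > 0 && k % S.P.check_every == 0) S.check_invariants();
    if (k % 262144 == 0) Rcpp::checkUserInterrupt();
  }
  if (nrows != row) traj = traj(Range(0, row - 1), Range(0, 12));
  int ne = (int)(S.events.size() / 5);
  NumericMatrix ev(ne, 5);
  for (int i = 0; i < ne; i++)
    for (int j = 0; j < 5; j++) ev(i, j) = S.events[5 * i + j];
  List out;
  out["state"] = export_state(S);
  out["trajectory"] = traj;
  out["events"] = ev;
  if (snapshot_every > 0) {
    List sl(snaps.size());
    for (size_t i = 0; i < snaps.size(); i++) sl[i] = snaps[i];
    out["snapshots"] = sl;
  }
  return out;
}

// [[Rcpp::export]]
void cpp_check_state(List state, List params) {
  Sim S = load_state(state, params);
  S.check_invariants();
}

// [[Rcpp::export]]
List cpp_state_summary(List state, List params) {
  // kernel-side recomputation of the trajectory row for a single state
  Sim S = load_state(state, params);
  NumericMatrix traj(1, 13);
  record_row(S, traj, 0);
  return List::create(_["row"] = traj);
}
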