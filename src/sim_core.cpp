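// Gillespie (direct method) engine for MukBEF dimer-of-dimers loop extrusion
// on a discretized circular chromosome.
//
// State lives in flat arrays indexed by "slot"; slots are recycled via a free
// list so complex ids remain stable across the run. Segment indices are
// 0-based. All random numbers come from R's RNG stream (seeded from R), so a
// run is reproducible with set.seed().
//
// Events and propensities:
//   BIND    k_bind * n_eligible_adjacent_free_pairs * n_free
//   MOVE    k_move * n_moveable_dimers   (stalled dimers carry zero propensity)
//   UNBIND  k_unbind * n_bound
// A bind whose pair intersects an active ter interval creates the complex and
// removes it instantly (a MatP displacement, never counted as bound time).
// A move into the active ter interval destroys the whole complex and its loop.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Engine {
  int n;                 // number of segments
  bool circular;
  int ter_lo, ter_len;   // half-open [ter_lo, ter_lo + ter_len) mod n
  bool matp;
  double k_bind, k_unbind, k_move;
  int n_total;
  int directionality;    // 0 = bidirectional, 1 = unidirectional

  std::vector<int> occ;          // segment -> slot or -1
  std::vector<char> pair_free;   // pair i = (i, i+1 mod n)
  long n_pairs;

  // per-slot complex state
  std::vector<int> id, left, right, anchor, moving_side; // side: 0 both, 1 left only, 2 right only
  std::vector<double> bind_time;
  std::vector<char> mv_left, mv_right;
  std::vector<int> act;          // active slot list
  std::vector<int> act_pos;      // slot -> index in act, -1 if inactive
  std::vector<int> free_slots;
  long n_moveable;
  int n_free;
  int next_id;

  // counters
  double binds = 0, unbinds = 0, moves = 0, displacements = 0;

  // optional unbind recording
  bool record;
  std::vector<double> ub_span, ub_life;

  int mod(int i) const { int r = i % n; return r < 0 ? r + n : r; }
  bool in_ter(int s) const {
    if (!matp || ter_len <= 0) return false;
    int d = mod(s - ter_lo);
    return d < ter_len;
  }
  bool pair_valid(int i) const { return circular || i < n - 1; }

  void upd_pair(int i) {
    if (!pair_valid(i)) return;
    char nf = (occ[i] < 0 && occ[mod(i + 1)] < 0) ? 1 : 0;
    if (nf != pair_free[i]) { n_pairs += nf ? 1 : -1; pair_free[i] = nf; }
  }

  // recompute moveability of one dimer of a slot
  void upd_mv(int slot, int side) { // side 0 = left dimer, 1 = right dimer
    char *flag = side == 0 ? &mv_left[slot] : &mv_right[slot];
    bool allowed = moving_side[slot] == 0 || moving_side[slot] == (side == 0 ? 1 : 2);
    int p = side == 0 ? left[slot] : right[slot];
    int d = side == 0 ? -1 : +1;
    bool ok = false;
    if (allowed) {
      int q = p + d;
      if (circular) q = mod(q);
      if (q >= 0 && q < n) ok = occ[q] < 0; // ter does not stall: moving in kills
    }
    char nf = ok ? 1 : 0;
    if (nf != *flag) { n_moveable += nf ? 1 : -1; *flag = nf; }
  }

  // after segment s changed occupancy, refresh dimers whose target is s
  void refresh_neighbors(int s) {
    for (int d = -1; d <= 1; d += 2) {
      int q = s + d;
      if (circular) q = mod(q); else if (q < 0 || q >= n) continue;
      int slot = occ[q];
      if (slot < 0) continue;
      if (left[slot] == q && d == 1) upd_mv(slot, 0);   // left dimer at q targets q-1 == s
      if (right[slot] == q && d == -1) upd_mv(slot, 1); // right dimer at q targets q+1 == s
    }
  }

  void occupy(int s, int slot) {
    occ[s] = slot;
    upd_pair(mod(s - 1)); upd_pair(s);
  }
  void vacate(int s) {
    occ[s] = -1;
    upd_pair(mod(s - 1)); upd_pair(s);
  }

  int span(int slot) const { return mod(right[slot] - left[slot]) + 1; }

  int alloc_slot() {
    if (!free_slots.empty()) { int s = free_slots.back(); free_slots.pop_back(); return s; }
    id.push_back(0); left.push_back(0); right.push_back(0); anchor.push_back(0);
    moving_side.push_back(0); bind_time.push_back(0);
    mv_left.push_back(0); mv_right.push_back(0); act_pos.push_back(-1);
    return (int)id.size() - 1;
  }

  void do_bind(double t) {
    // uniform choice among eligible free adjacent pairs (rejection sampling)
    int i = -1;
    int lim = circular ? n : n - 1;
    for (int tries = 0; tries < 20000; ++tries) {
      int c = (int)(unif_rand() * lim);
      if (c >= lim) c = lim - 1;
      if (pair_free[c]) { i = c; break; }
    }
    if (i < 0) { // pathological occupancy: exhaustive fallback
      long k = (long)(unif_rand() * n_pairs);
      for (int c = 0; c < lim; ++c) if (pair_free[c] && k-- == 0) { i = c; break; }
      if (i < 0) return;
    }
    int j = mod(i + 1);
    if (in_ter(i) || in_ter(j)) { displacements += 1; return; } // instant MatP displacement
    int slot = alloc_slot();
    id[slot] = next_id++;
    left[slot] = i; right[slot] = j; anchor[slot] = i;
    bind_time[slot] = t;
    moving_side[slot] = directionality == 0 ? 0 : (unif_rand() < 0.5 ? 1 : 2);
    mv_left[slot] = mv_right[slot] = 0;
    act_pos[slot] = (int)act.size(); act.push_back(slot);
    occupy(i, slot); occupy(j, slot);
    refresh_neighbors(i); refresh_neighbors(j);
    upd_mv(slot, 0); upd_mv(slot, 1);
    n_free -= 1; binds += 1;
  }

  void remove_complex(int slot) {
    int a = left[slot], b = right[slot];
    if (mv_left[slot]) { n_moveable -= 1; mv_left[slot] = 0; }
    if (mv_right[slot]) { n_moveable -= 1; mv_right[slot] = 0; }
    vacate(a); vacate(b);
    refresh_neighbors(a); refresh_neighbors(b);
    int pos = act_pos[slot], last = act.back();
    act[pos] = last; act_pos[last] = pos; act.pop_back(); act_pos[slot] = -1;
    free_slots.push_back(slot);
    n_free += 1;
  }

  void do_unbind(double t) {
    int slot = act[(int)(unif_rand() * act.size())];
    if (record) { ub_span.push_back(span(slot)); ub_life.push_back(t - bind_time[slot]); }
    remove_complex(slot);
    unbinds += 1;
  }

  void do_move() {
    // uniform among moveable dimers by rejection over (active slot, side)
    for (int tries = 0; tries < 200000; ++tries) {
      int slot = act[(int)(unif_rand() * act.size())];
      int side = unif_rand() < 0.5 ? 0 : 1;
      char mv = side == 0 ? mv_left[slot] : mv_right[slot];
      if (!mv) continue;
      int p = side == 0 ? left[slot] : right[slot];
      int d = side == 0 ? -1 : +1;
      int q = mod(p + d);
      if (in_ter(q)) { // moving into active ter destroys complex and loop
        remove_complex(slot);
        displacements += 1; moves += 1;
        return;
      }
      if (side == 0) left[slot] = q; else right[slot] = q;
      vacate(p); occupy(q, slot);
      refresh_neighbors(p); refresh_neighbors(q);
      upd_mv(slot, side);
      moves += 1;
      return;
    }
    stop("move selection failed: no moveable dimer found (internal invariant violated)");
  }
};

} // namespace

// [[Rcpp::export]]
List sim_core(int n_segments, bool circular, int ter_lo, int ter_len, bool matp_active,
              double k_bind, double k_unbind, double k_move,
              int n_total, int directionality,
              double t_start, double t_end,
              IntegerMatrix complexes0, NumericVector bind_time0, int next_id,
              double max_events, bool record_unbinds, int stop_after_unbinds) {
  Engine e;
  e.n = n_segments; e.circular = circular;
  e.ter_lo = ter_lo; e.ter_len = ter_len; e.matp = matp_active;
  e.k_bind = k_bind; e.k_unbind = k_unbind; e.k_move = k_move;
  e.n_total = n_total; e.directionality = directionality;
  e.occ.assign(n_segments, -1);
  e.pair_free.assign(n_segments, 0);
  e.n_pairs = 0; e.n_moveable = 0;
  e.record = record_unbinds;
  e.next_id = next_id;

  int nb = complexes0.nrow();
  for (int k = 0; k < nb; ++k) {
    int slot = e.alloc_slot();
    e.id[slot] = complexes0(k, 0);
    e.left[slot] = complexes0(k, 1);
    e.right[slot] = complexes0(k, 2);
    e.anchor[slot] = complexes0(k, 3);
    e.moving_side[slot] = complexes0(k, 4);
    e.bind_time[slot] = bind_time0[k];
    e.mv_left[slot] = e.mv_right[slot] = 0;
    e.act_pos[slot] = (int)e.act.size(); e.act.push_back(slot);
    if (e.occ[e.left[slot]] >= 0 || e.occ[e.right[slot]] >= 0)
      stop("inconsistent occupancy in initial state: segment already occupied");
    e.occ[e.left[slot]] = slot; e.occ[e.right[slot]] = slot;
  }
  for (int i = 0; i < n_segments; ++i) e.upd_pair(i);
  for (size_t k = 0; k < e.act.size(); ++k) { e.upd_mv(e.act[k], 0); e.upd_mv(e.act[k], 1); }
  e.n_free = n_total - nb;
  if (e.n_free < 0) stop("more bound complexes than n_total");

  RNGScope scope;
  double t = t_start;
  double events = 0;
  long unbinds_seen = 0;
  while (t < t_end && events < max_events) {
    double a_bind = e.k_bind * (double)e.n_pairs * (double)e.n_free;
    double a_move = e.k_move * (double)e.n_moveable;
    double a_unb  = e.k_unbind * (double)e.act.size();
    double a_tot = a_bind + a_move + a_unb;
    if (a_tot <= 0) { t = t_end; break; }
    t += exp_rand() / a_tot;
    if (t >= t_end) { t = t_end; break; }
    double r = unif_rand() * a_tot;
    if (r < a_bind) e.do_bind(t);
    else if (r < a_bind + a_move) e.do_move();
    else {
      e.do_unbind(t);
      if (stop_after_unbinds > 0 && ++unbinds_seen >= stop_after_unbinds) { events += 1; break; }
    }
    events += 1;
    if (((long)events & 0xFFFFF) == 0) checkUserInterrupt();
  }

  int nbf = (int)e.act.size();
  IntegerMatrix cx(nbf, 5);
  NumericVector bt(nbf);
  for (int k = 0; k < nbf; ++k) {
    int slot = e.act[k];
    cx(k, 0) = e.id[slot]; cx(k, 1) = e.left[slot]; cx(k, 2) = e.right[slot];
    cx(k, 3) = e.anchor[slot]; cx(k, 4) = e.moving_side[slot];
    bt[k] = e.bind_time[slot];
  }
  colnames(cx) = CharacterVector::create("id", "left", "right", "anchor", "moving_side");

  return List::create(
    _["time"] = t,
    _["complexes"] = cx,
    _["bind_time"] = bt,
    _["n_free"] = e.n_free,
    _["next_id"] = e.next_id,
    _["counters"] = NumericVector::create(
      _["binds"] = e.binds, _["unbinds"] = e.unbinds,
      _["moves"] = e.moves, _["displacements"] = e.displacements),
    _["n_events"] = events,
    _["unbind_spans"] = wrap(e.ub_span),
    _["unbind_lifetimes"] = wrap(e.ub_life));
}

// Zhang-Suen thinning of a binary mask to a 1-pixel-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix thin_mask(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> img((size_t)nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[(size_t)j * nr + i] = mask(i, j) ? 1 : 0;
  auto at = [&](int i, int j) -> char {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img[(size_t)j * nr + i];
  };
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int phase = 0; phase < 2; ++phase) {
      kill.clear();
      for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
        if (!at(i, j)) continue;
        // neighbours clockwise from north: p2..p9
        char p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
             p5 = at(i + 1, j + 1), p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
             p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
        int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
        if (B < 2 || B > 6) continue;
        int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) + (p4 == 0 && p5 == 1) +
                (p5 == 0 && p6 == 1) + (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
        if (A != 1) continue;
        if (phase == 0) {
          if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
        } else {
          if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
        }
        kill.push_back({i, j});
      }
      if (!kill.empty()) changed = true;
      for (auto &p : kill) img[(size_t)p.second * nr + p.first] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[(size_t)j * nr + i] != 0;
  return out;
}
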