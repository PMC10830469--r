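// Stochastic lattice engine for internal fibrinolysis.
//
// Geometry: nodes (i, j), 0 <= i < nx, 0 <= j < ny, node id = i + j*nx.
// Edge ids (0-based here, 1-based on the R side): x-edges first
// (i + j*(nx-1), joining (i,j)-(i+1,j)), then y-edges
// (ex + i + j*nx, joining (i,j)-(i,j+1)), then one z-edge per node
// (ex + ey + node). Reflecting in-plane boundaries; the out-of-plane
// direction is periodic with thickness one, so motion is in-plane.
//
// Time advances synchronously in steps of dt. All scheduled events
// (degradation, kinetic unbinding, small-FDP waiting) are applied at the
// first step boundary at or after their scheduled time. Within a boundary:
// degradations, then releases, then the state record, then one movement +
// binding sweep over molecules in index order.
//
// RNG draw protocol (all draws are unif_rand(); the order is part of the
// engine contract and is mirrored by the discrete-event oracle used in the
// tests):
//   init:       per molecule, 1 draw: node = floor(u * nnodes)
//   release of a large-FDP rider (in-plane edge, exact stepping):
//               1 draw: endpoint = floor(u * 2); z-edge: no draw
//   release of a fast-forwarded large-FDP rider: 1 draw to sample the
//               degraded component edge (degree-weighted), then the
//               endpoint draw as above
//   release of a fast-forwarded waiting molecule: 1 draw:
//               node = floor(u * nnodes)
//   movement:   free walker: 1 draw, dir = floor(u*4): +x, -x, +y, -y
//               (blocked moves leave the position unchanged);
//               large-FDP rider with k >= 1 adjacent degraded edges:
//               1 draw, target = floor(u*k) over ascending edge ids;
//               k = 0: no draw
//   binding:    if bind_prob < 1: 1 acceptance draw first; then 1 draw to
//               pick among the k >= 1 intact incident edges (ascending edge
//               ids); then 1 draw for the unbinding time, 1 draw for the
//               forced-unbinding branch (forced iff u < q), then the lysis
//               draw: empirical CDF: 1 draw; exponential: a censoring draw
//               first when lysis_prob < 1, then 1 draw iff lytic.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

typedef long long ll;
static const ll LL_INF = LLONG_MAX / 4;

enum MolState { UNBOUND = 0, BOUND = 1, ON_LARGE_FDP = 2, WAITING_SMALL_FDP = 3 };

struct Kinetics {
  int type; // 0 exponential, 1 empirical
  std::vector<double> unbind, lysis;
  double mean_unbind, mean_lysis, lysis_prob, q, koff_wait;
};

static inline double draw_empirical(const std::vector<double>& x) {
  double u = unif_rand();
  int n = (int)x.size();
  if (n == 1) return x[0];
  double h = u * (n - 1);
  int lo = (int)h;
  if (lo > n - 2) lo = n - 2;
  double frac = h - lo;
  if (frac == 0.0) return x[lo];
  if (!R_FINITE(x[lo]) || !R_FINITE(x[lo + 1])) return R_PosInf;
  return x[lo] + frac * (x[lo + 1] - x[lo]);
}

static inline double draw_unbind(const Kinetics& k) {
  if (k.type == 1) return draw_empirical(k.unbind);
  double u = unif_rand();
  return -k.mean_unbind * log1p(-u);
}

static inline double draw_lysis(const Kinetics& k) {
  if (k.type == 1) return draw_empirical(k.lysis);
  if (k.lysis_prob < 1.0) {
    double uc = unif_rand();
    if (uc >= k.lysis_prob) return R_PosInf;
  }
  double u = unif_rand();
  return -k.mean_lysis * log1p(-u);
}

static inline ll ceil_steps(double t, double dt) {
  if (!R_FINITE(t)) return LL_INF;
  double s = std::ceil(t / dt - 1e-9);
  if (s < 0) s = 0;
  if (s > (double)LL_INF) return LL_INF;
  return (ll)s;
}

struct Molecule {
  int state;
  int node;        // valid for UNBOUND / BOUND / WAITING
  int edge;        // valid for BOUND / ON_LARGE_FDP (-1 otherwise)
  ll release_step; // unbind boundary (BOUND/ON_LARGE_FDP), wait end (WAITING)
  bool forced;     // branch chosen at binding
  bool ffwd;       // position not tracked; sample stationary at release
  ll transit_start; // boundary step when the molecule started moving, -1 if none
};

// [[Rcpp::export(name = ".run_engine")]]
List run_engine(int nx, int ny, int n_tpa, double dt, double record_interval,
                double max_time, double bind_prob, double mix_threshold,
                NumericVector snapshot_fracs, List kinetics_in,
                bool keep_transits) {
  if (nx < 1 || ny < 1) stop("grid dimensions must be positive");
  if (n_tpa < 0) stop("n_tpa must be non-negative");
  if (dt <= 0 || record_interval <= 0) stop("dt and record_interval must be positive");
  if (bind_prob < 0 || bind_prob > 1) stop("bind_prob must lie in [0, 1]");

  Kinetics kin;
  kin.type = as<int>(kinetics_in["type_code"]);
  kin.unbind = as<std::vector<double> >(kinetics_in["unbind"]);
  kin.lysis = as<std::vector<double> >(kinetics_in["lysis"]);
  kin.mean_unbind = as<double>(kinetics_in["mean_unbind_s"]);
  kin.mean_lysis = as<double>(kinetics_in["mean_lysis_s"]);
  kin.lysis_prob = as<double>(kinetics_in["lysis_prob"]);
  kin.q = as<double>(kinetics_in["forced_unbind_prob"]);
  kin.koff_wait = as<double>(kinetics_in["koff_wait"]);
  if (kin.type == 1 && (kin.unbind.empty() || kin.lysis.empty()))
    stop("empirical kinetics need both unbind and lysis samples");

  const int nnodes = nx * ny;
  const int ex = (nx - 1) * ny, ey = nx * (ny - 1);
  const int E = ex + ey + nnodes;

  // incident edges per node, ascending edge id: x-left, x-right, y-down, y-up, z
  std::vector<std::vector<int> > incident(nnodes);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int nd = i + j * nx;
      std::vector<int>& inc = incident[nd];
      if (i > 0)      inc.push_back((i - 1) + j * (nx - 1));
      if (i < nx - 1) inc.push_back(i + j * (nx - 1));
      if (j > 0)      inc.push_back(ex + i + (j - 1) * nx);
      if (j < ny - 1) inc.push_back(ex + i + j * nx);
      inc.push_back(ex + ey + nd);
    }
  }
  // edge endpoints (z-edges: both endpoints equal)
  std::vector<int> end_a(E), end_b(E);
  for (int e = 0; e < E; ++e) {
    if (e < ex) {
      int i = e % (nx - 1), j = e / (nx - 1);
      end_a[e] = i + j * nx;
      end_b[e] = (i + 1) + j * nx;
    } else if (e < ex + ey) {
      int r = e - ex, i = r % nx, j = r / nx;
      end_a[e] = i + j * nx;
      end_b[e] = i + (j + 1) * nx;
    } else {
      end_a[e] = end_b[e] = e - ex - ey;
    }
  }

  std::vector<char> intact(E, 1);
  std::vector<ll> edge_step(E, LL_INF); // scheduled degradation boundary
  std::vector<double> edge_time(E, NA_REAL);
  typedef std::pair<ll, int> Ev;
  std::priority_queue<Ev, std::vector<Ev>, std::greater<Ev> > heap;

  // scratch for neighbour collection
  std::vector<int> cand;
  cand.reserve(10);

  // degraded edges adjacent to edge e, ascending, unique
  // (incident lists are ascending; endpoints share no incident order overlap
  //  guarantees, so collect then sort small vector)
  #define COLLECT_ADJ_DEGRADED(e)                                        \
    do {                                                                 \
      cand.clear();                                                      \
      int na = end_a[e], nb = end_b[e];                                  \
      for (size_t t_ = 0; t_ < incident[na].size(); ++t_) {              \
        int f = incident[na][t_];                                        \
        if (f != (e) && !intact[f]) cand.push_back(f);                   \
      }                                                                  \
      if (nb != na)                                                      \
        for (size_t t_ = 0; t_ < incident[nb].size(); ++t_) {            \
          int f = incident[nb][t_];                                      \
          if (f != (e) && !intact[f]) cand.push_back(f);                 \
        }                                                                \
      std::sort(cand.begin(), cand.end());                               \
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());     \
    } while (0)

  GetRNGstate();

  std::vector<Molecule> mol(n_tpa);
  IntegerVector init_nodes(n_tpa);
  for (int m = 0; m < n_tpa; ++m) {
    double u = unif_rand();
    int nd = (int)(u * nnodes);
    if (nd >= nnodes) nd = nnodes - 1;
    mol[m].state = UNBOUND;
    mol[m].node = nd;
    mol[m].edge = -1;
    mol[m].release_step = LL_INF;
    mol[m].forced = false;
    mol[m].ffwd = false;
    mol[m].transit_start = -1;
    init_nodes[m] = nd + 1;
  }

  const ll rec = std::max((ll)1, (ll)std::llround(record_interval / dt));
  const ll max_step = ceil_steps(max_time, dt);
  const ll wait_steps = ceil_steps(kin.koff_wait, dt);
  const double mix_thr = R_FINITE(mix_threshold) ? mix_threshold : (double)LL_INF;

  std::vector<double> rec_time, rec_frac;
  std::vector<int> tr_mol;
  std::vector<double> tr_start, tr_end;
  int n_deg = 0;
  long long n_binds = 0, n_forced = 0;

  NumericVector snap_targets = clone(snapshot_fracs).sort();
  int snap_next = 0;
  std::vector<double> snap_time, snap_attained;
  List snap_masks(snap_targets.size());

  ll step = 0;
  bool truncated = false;
  bool done = false;
  long long iter_guard = 0;

  while (!done) {
    if (++iter_guard % 4096 == 0) Rcpp::checkUserInterrupt();
    // --- scheduled degradations at this boundary ---
    while (!heap.empty() && heap.top().first <= step) {
      Ev ev = heap.top();
      heap.pop();
      int e = ev.second;
      if (!intact[e] || edge_step[e] != ev.first) continue; // stale entry
      intact[e] = 0;
      ++n_deg;
      edge_time[e] = ev.first * dt;
      for (int m = 0; m < n_tpa; ++m) {
        if (mol[m].state == BOUND && mol[m].edge == e) {
          // rides a large FDP until its previously assigned unbinding time;
          // the transit episode opens at that later release
          mol[m].state = ON_LARGE_FDP;
          mol[m].ffwd = (mol[m].release_step - step) > mix_thr;
        }
      }
    }
    // --- releases at this boundary (molecule index order) ---
    for (int m = 0; m < n_tpa; ++m) {
      Molecule& M = mol[m];
      if (M.release_step > step) continue;
      if (M.state == BOUND) {
        if (M.forced) {
          // forced unbinding: starts moving on a freely diffusing small
          // FDP; the transit episode opens here and includes the 1/k_off
          // wait before the molecule may rebind
          M.state = WAITING_SMALL_FDP;
          M.transit_start = M.release_step;
          M.release_step = step + wait_steps;
          M.ffwd = (double)wait_steps > mix_thr;
          M.edge = -1;
        } else {
          M.state = UNBOUND;
          M.transit_start = M.release_step;
          M.release_step = LL_INF;
          M.edge = -1;
        }
      } else if (M.state == ON_LARGE_FDP) {
        int e = M.edge;
        if (M.ffwd) {
          // sample release edge from the stationary law (degree-weighted)
          // of the walk on this edge's degraded component
          std::vector<int> comp;
          std::vector<int> deg;
          std::vector<char> seen(E, 0);
          comp.push_back(e);
          seen[e] = 1;
          for (size_t head = 0; head < comp.size(); ++head) {
            int f = comp[head];
            COLLECT_ADJ_DEGRADED(f);
            deg.push_back((int)cand.size());
            for (size_t t = 0; t < cand.size(); ++t) {
              if (!seen[cand[t]]) {
                seen[cand[t]] = 1;
                comp.push_back(cand[t]);
              }
            }
          }
          long total = 0;
          for (size_t t = 0; t < deg.size(); ++t) total += deg[t];
          if (comp.size() > 1 && total > 0) {
            double u = unif_rand();
            double acc = 0, target = u * total;
            size_t pick = 0;
            for (size_t t = 0; t < deg.size(); ++t) {
              acc += deg[t];
              if (target < acc) { pick = t; break; }
            }
            e = comp[pick];
          }
        }
        if (end_a[e] != end_b[e]) {
          double u = unif_rand();
          M.node = (u < 0.5) ? end_a[e] : end_b[e];
        } else {
          M.node = end_a[e];
        }
        M.state = UNBOUND;
        M.transit_start = step; // == its scheduled unbinding boundary
        M.release_step = LL_INF;
        M.edge = -1;
        M.ffwd = false;
      } else if (M.state == WAITING_SMALL_FDP) {
        if (M.ffwd) {
          double u = unif_rand();
          int nd = (int)(u * nnodes);
          if (nd >= nnodes) nd = nnodes - 1;
          M.node = nd;
          M.ffwd = false;
        }
        M.state = UNBOUND;
        M.release_step = LL_INF;
      }
    }
    // --- record ---
    double frac = (double)n_deg / (double)E;
    if (step % rec == 0) {
      rec_time.push_back(step * dt);
      rec_frac.push_back(frac);
      while (snap_next < snap_targets.size() && frac >= snap_targets[snap_next] - 1e-12) {
        LogicalVector mask(E);
        for (int e = 0; e < E; ++e) mask[e] = (bool)intact[e];
        snap_masks[snap_next] = mask;
        snap_time.push_back(step * dt);
        snap_attained.push_back(frac);
        ++snap_next;
      }
      if (n_deg == E) { done = true; break; }
    }
    if (step >= max_step) { truncated = (n_deg < E); done = true; break; }

    // --- movement + binding sweep, or event jump when nothing moves ---
    bool any_active = false;
    for (int m = 0; m < n_tpa && !any_active; ++m) {
      Molecule& M = mol[m];
      if (M.state == UNBOUND) any_active = true;
      else if (M.state == WAITING_SMALL_FDP && !M.ffwd) any_active = true;
      else if (M.state == ON_LARGE_FDP && !M.ffwd) {
        COLLECT_ADJ_DEGRADED(M.edge);
        if (!cand.empty()) any_active = true;
      }
    }
    if (!any_active) {
      ll target = max_step;
      if (!heap.empty() && heap.top().first < target) target = heap.top().first;
      for (int m = 0; m < n_tpa; ++m)
        if (mol[m].release_step < target) target = mol[m].release_step;
      ll next_rec = ((step / rec) + 1) * rec;
      if (next_rec < target) target = next_rec;
      if (target <= step) target = step + 1;
      // emit records skipped by the jump (fraction is unchanged in between)
      for (ll b = ((step / rec) + 1) * rec; b < target; b += rec) {
        rec_time.push_back(b * dt);
        rec_frac.push_back(frac);
      }
      step = target;
      if (n_tpa == 0 && heap.empty() && target >= max_step) {
        // nothing can ever happen again
        step = max_step;
      }
      continue;
    }

    // movement (index order)
    for (int m = 0; m < n_tpa; ++m) {
      Molecule& M = mol[m];
      if (M.state == UNBOUND || (M.state == WAITING_SMALL_FDP && !M.ffwd)) {
        double u = unif_rand();
        int dir = (int)(u * 4);
        if (dir > 3) dir = 3;
        int i = M.node % nx, j = M.node / nx;
        if (dir == 0 && i < nx - 1) ++i;
        else if (dir == 1 && i > 0) --i;
        else if (dir == 2 && j < ny - 1) ++j;
        else if (dir == 3 && j > 0) --j;
        M.node = i + j * nx;
      } else if (M.state == ON_LARGE_FDP && !M.ffwd) {
        COLLECT_ADJ_DEGRADED(M.edge);
        int k = (int)cand.size();
        if (k >= 1) {
          double u = unif_rand();
          int pick = (int)(u * k);
          if (pick >= k) pick = k - 1;
          M.edge = cand[pick];
        }
      }
    }
    // binding (index order); bind takes effect at boundary step+1
    for (int m = 0; m < n_tpa; ++m) {
      Molecule& M = mol[m];
      if (M.state != UNBOUND) continue;
      cand.clear();
      const std::vector<int>& inc = incident[M.node];
      for (size_t t = 0; t < inc.size(); ++t)
        if (intact[inc[t]]) cand.push_back(inc[t]);
      int k = (int)cand.size();
      if (k == 0) continue;
      if (bind_prob < 1.0) {
        double ua = unif_rand();
        if (ua >= bind_prob) continue;
      }
      double ue = unif_rand();
      int pick = (int)(ue * k);
      if (pick >= k) pick = k - 1;
      int e = cand[pick];
      M.state = BOUND;
      M.edge = e;
      if (M.transit_start >= 0 && keep_transits) {
        tr_mol.push_back(m + 1);
        tr_start.push_back(M.transit_start * dt);
        tr_end.push_back((step + 1) * dt);
      }
      M.transit_start = -1;
      double t_u = draw_unbind(kin);
      M.release_step = (step + 1) + ceil_steps(t_u, dt);
      double ur = unif_rand();
      M.forced = (ur < kin.q);
      ++n_binds;
      if (M.forced) ++n_forced;
      double t_l = draw_lysis(kin);
      if (R_FINITE(t_l)) {
        ll dstep = (step + 1) + ceil_steps(t_l, dt);
        if (dstep < edge_step[e]) {
          edge_step[e] = dstep;
          heap.push(Ev(dstep, e));
        }
      }
    }
    ++step;
  }

  PutRNGstate();

  IntegerVector f_state(n_tpa), f_node(n_tpa), f_edge(n_tpa);
  for (int m = 0; m < n_tpa; ++m) {
    f_state[m] = mol[m].state;
    f_node[m] = (mol[m].state == ON_LARGE_FDP) ? NA_INTEGER : mol[m].node + 1;
    f_edge[m] = (mol[m].edge >= 0) ? mol[m].edge + 1 : NA_INTEGER;
  }

  return List::create(
    _["record_time"] = rec_time,
    _["record_frac"] = rec_frac,
    _["edge_degrade_time"] = NumericVector(edge_time.begin(), edge_time.end()),
    _["snapshot_target"] = snap_targets,
    _["snapshot_time"] = snap_time,
    _["snapshot_attained"] = snap_attained,
    _["snapshot_masks"] = snap_masks,
    _["transit_mol"] = tr_mol,
    _["transit_start"] = tr_start,
    _["transit_end"] = tr_end,
    _["init_nodes"] = init_nodes,
    _["final_state"] = f_state,
    _["final_node"] = f_node,
    _["final_edge"] = f_edge,
    _["n_binds"] = (double)n_binds,
    _["n_forced"] = (double)n_forced,
    _["n_steps"] = (double)step,
    _["truncated"] = truncated
  );
}
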