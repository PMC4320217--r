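// Compiled agent tick.
//
// This mirrors the R reference step functions in R/behavior.R draw for
// draw: both engines consume the same uniform stream (unif_rand) in the
// same order, so a run under a common seed produces bitwise-identical
// trajectories whichever engine executes it.  Any behavioural change must
// be made in both places; test-engine.R enforces the equivalence.
//
// Padded-index convention (see R/state.R): the padded matrices are
// W x H with W = width + 4; cell (x, y) is the 0-based column-major
// element ci = (x + 2) + W * (y + 2), and d1/d2 hold the linear offsets
// of the radius-1/radius-2 Chebyshev neighbourhoods.

#include <Rcpp.h>
#include <Rmath.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Mirrors .pick_uniform: one draw, 0-based result; no draw when k == 1.
static inline int pick_uniform(int k) {
  if (k == 1) return 0;
  int j = (int)std::floor(unif_rand() * k);
  if (j >= k) j = k - 1;
  return j;
}

// Mirrors .pick_weighted: sequential double accumulation, u <= cumsum.
static inline int pick_weighted(const double* w, int k) {
  if (k == 1) return 0;
  double tot = 0;
  for (int i = 0; i < k; ++i) tot += w[i];
  double u = unif_rand() * tot;
  double cs = 0;
  for (int i = 0; i < k; ++i) {
    cs += w[i];
    if (u <= cs) return i;
  }
  return k - 1;
}

// OFF1 in the R construction order (expand.grid: dx fastest).
static const int DX1[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY1[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

// [[Rcpp::export]]
IntegerMatrix cpp_agents_tick(Environment st) {
  const int W = as<int>(st["W"]);
  const int n = as<int>(st["n_ants"]);
  const int tick = as<int>(st["tick"]);

  IntegerMatrix cls = st["cls"], spot = st["spot"], occ = st["occ"], mem = st["mem"];
  NumericMatrix space = st["space"], ground = st["ground"];
  IntegerVector d1 = st["d1"], d2 = st["d2"];
  IntegerVector ant_x = st["ant_x"], ant_y = st["ant_y"];
  IntegerVector ant_caste = st["ant_caste"], ant_state = st["ant_state"];
  IntegerVector ant_hx = st["ant_hx"], ant_hy = st["ant_hy"];
  IntegerVector ant_cargo = st["ant_cargo"], ant_chain = st["ant_chain"];
  IntegerVector chain_sizes = st["chain_sizes"];
  IntegerVector remaining = st["remaining"], delivered = st["delivered"];
  LogicalVector ant_carrying = st["ant_carrying"];

  List bp = st["behavior"];
  const int n_min = as<int>(bp["n"]);
  const double alpha = as<double>(bp["alpha"]);
  const bool model1 = as<std::string>(bp["entry_mode"]) == "model1";
  const double m2thr = as<double>(bp["model2_threshold"]);
  const bool pher_leave = as<std::string>(bp["leave_rule"]) == "pheromone";
  List lm = bp["leave"];
  const double l_a = as<double>(lm["a"]), l_eta = as<double>(lm["eta"]),
               l_eps = as<double>(lm["eps"]);
  List xm = bp["exit"];
  const double Cs0 = as<double>(xm["Cs0"]), Cs1 = as<double>(xm["Cs1"]),
               Cs2 = as<double>(xm["Cs2"]), nu = as<double>(xm["nu"]);
  const bool mds = as<bool>(bp["minor_deposit_in_search"]);
  const bool mjc = as<bool>(bp["majors_join_chains"]);

  List pp = st["pheromone"];
  const double dep_g = as<double>(pp["deposit_ground"]);
  const double diag_f = as<double>(pp["diagonal_deposit_factor"]);

  RObject nr = st["nest_rect"];
  const bool has_nest = !nr.isNULL();
  int nxmin = 0, nxmax = -1, nymin = 0, nymax = -1;
  if (has_nest) {
    List nl(nr);
    nxmin = as<int>(nl["x_min"]); nxmax = as<int>(nl["x_max"]);
    nymin = as<int>(nl["y_min"]); nymax = as<int>(nl["y_max"]);
  }

  std::vector<int> ev;  // rows of (tick, ant, from, to, x, y)
  auto event = [&](int ant1, int from, int to, int x, int y) {
    ev.push_back(tick); ev.push_back(ant1); ev.push_back(from);
    ev.push_back(to); ev.push_back(x); ev.push_back(y);
  };

  auto is_free = [&](int t) {
    int cl = cls[t];
    return occ[t] == 0 && (cl == 0 || cl == 2 || (cl == 1 && mem[t] > 0));
  };

  auto deposit = [&](int a0, int t, bool diag) {
    bool dep = ant_caste[a0] == 1 || ant_carrying[a0] ||
               (mds && ant_state[a0] == 1);
    if (dep) ground[t] += dep_g * (diag ? diag_f : 1.0);
  };

  auto dist_nest = [&](int px, int py) {
    int dx = std::max(std::max(nxmin - px, px - nxmax), 0);
    int dy = std::max(std::max(nymin - py, py - nymax), 0);
    return std::max(dx, dy);
  };

  auto search_step = [&](int a0) {
    int x = ant_x[a0], y = ant_y[a0];
    int ci = (x + 2) + W * (y + 2);
    int caste = ant_caste[a0];

    if (caste == 2) {  // Minor: take food within 1 Distance
      int s = 0;
      { int sp = spot[ci]; if (sp > 0 && remaining[sp - 1] > 0) s = sp; }
      if (s == 0) for (int k = 0; k < 8; ++k) {
        int sp = spot[ci + d1[k]];
        if (sp > 0 && remaining[sp - 1] > 0) { s = sp; break; }
      }
      if (s > 0) {
        remaining[s - 1] -= 1;
        ant_carrying[a0] = TRUE;
        ant_cargo[a0] = s;
        ant_state[a0] = 2;
        event(a0 + 1, 1, 2, x, y);
        deposit(a0, ci, false);
        return;
      }
    }

    if (caste == 2 || mjc) {  // chain entry
      bool trig;
      if (model1) {
        trig = false;
        for (int k = 0; k < 24; ++k)
          if (occ[ci + d2[k]] > 0) { trig = true; break; }
      } else {
        double mx = space[ci];
        for (int k = 0; k < 24; ++k) mx = std::max(mx, space[ci + d2[k]]);
        trig = mx >= m2thr;
      }
      if (trig) {
        int dit[8], nd = 0;
        for (int k = 0; k < 8; ++k) {
          int t = ci + d1[k];
          if (cls[t] == 1 && mem[t] == 0) dit[nd++] = k;
        }
        if (nd > 0) {
          int pool[8], np = 0;
          bool anyadj = false;
          bool adj[8];
          for (int i = 0; i < nd; ++i) {
            int t = ci + d1[dit[i]];
            bool a = false;
            for (int j = 0; j < 8; ++j)
              if (mem[t + d1[j]] > 0) { a = true; break; }
            adj[i] = a;
            if (a) anyadj = true;
          }
          for (int i = 0; i < nd; ++i)
            if (!anyadj || adj[i]) pool[np++] = dit[i];
          int k = pool[pick_uniform(np)];
          occ[ci] = 0;
          int ti = ci + d1[k];
          mem[ti] = a0 + 1;
          ant_x[a0] = x + DX1[k]; ant_y[a0] = y + DY1[k];
          ant_hx[a0] = 0; ant_hy[a0] = 0;
          ant_state[a0] = 3;
          event(a0 + 1, 1, 3, ant_x[a0], ant_y[a0]);
          return;
        }
      }
    }

    int idx[8], cnt = 0;
    for (int k = 0; k < 8; ++k)
      if (is_free(ci + d1[k])) idx[cnt++] = k;
    bool mdiag = false;
    int newci = ci;
    if (cnt > 0) {
      bool guided = false;
      if (caste == 2) {
        double mx = space[ci];
        for (int k = 0; k < 24; ++k) mx = std::max(mx, space[ci + d2[k]]);
        guided = mx > 0;
      }
      int k;
      if (guided) {
        double lv[8];
        bool allz = true;
        for (int i = 0; i < cnt; ++i) {
          lv[i] = space[ci + d1[idx[i]]];
          if (lv[i] != 0) allz = false;
        }
        int p = (cnt == 1) ? 0 : (allz ? pick_uniform(cnt) : pick_weighted(lv, cnt));
        k = idx[p];
      } else if (cnt == 1) {
        k = idx[0];
      } else {
        double w[8];
        for (int i = 0; i < cnt; ++i)
          w[i] = (DX1[idx[i]] == ant_hx[a0] && DY1[idx[i]] == ant_hy[a0]) ? 1.0 : alpha;
        k = idx[pick_weighted(w, cnt)];
      }
      occ[ci] = 0;
      newci = ci + d1[k];
      occ[newci] = a0 + 1;
      ant_x[a0] = x + DX1[k]; ant_y[a0] = y + DY1[k];
      ant_hx[a0] = DX1[k]; ant_hy[a0] = DY1[k];
      mdiag = DX1[k] != 0 && DY1[k] != 0;
    }
    deposit(a0, newci, mdiag);
  };

  auto return_step = [&](int a0) {
    int x = ant_x[a0], y = ant_y[a0];
    int ci = (x + 2) + W * (y + 2);

    if (cls[ci] == 2) {  // deliver on a nest cell
      int s = ant_cargo[a0];
      delivered[s - 1] += 1;
      ant_carrying[a0] = FALSE;
      ant_cargo[a0] = NA_INTEGER;
      ant_state[a0] = 1;
      event(a0 + 1, 2, 1, x, y);
      deposit(a0, ci, false);
      return;
    }

    int idx[8], cnt = 0;
    for (int k = 0; k < 8; ++k)
      if (is_free(ci + d1[k])) idx[cnt++] = k;
    bool mdiag = false;
    int newci = ci;
    if (cnt > 0) {
      bool ditch_near = cls[ci] == 1;
      if (!ditch_near) for (int k = 0; k < 8; ++k)
        if (cls[ci + d1[k]] == 1) { ditch_near = true; break; }
      int k = -1;
      if (ditch_near || !has_nest) {
        if (cnt == 1) {
          k = idx[0];
        } else {
          double w[8];
          for (int i = 0; i < cnt; ++i)
            w[i] = (DX1[idx[i]] == ant_hx[a0] && DY1[idx[i]] == ant_hy[a0]) ? 1.0 : alpha;
          k = idx[pick_weighted(w, cnt)];
        }
      } else {
        int cur = dist_nest(x, y);
        int d[8];
        int mind = cur;
        bool any_closer = false;
        for (int i = 0; i < cnt; ++i) {
          d[i] = dist_nest(x + DX1[idx[i]], y + DY1[idx[i]]);
          if (d[i] < cur) {
            any_closer = true;
            if (d[i] < mind) mind = d[i];
          }
        }
        if (any_closer) {
          int best[8], nb = 0;
          for (int i = 0; i < cnt; ++i)
            if (d[i] < cur && d[i] == mind) best[nb++] = i;
          k = idx[best[pick_uniform(nb)]];
        }
      }
      if (k >= 0) {
        occ[ci] = 0;
        newci = ci + d1[k];
        occ[newci] = a0 + 1;
        ant_x[a0] = x + DX1[k]; ant_y[a0] = y + DY1[k];
        ant_hx[a0] = DX1[k]; ant_hy[a0] = DY1[k];
        mdiag = DX1[k] != 0 && DY1[k] != 0;
      }
    }
    deposit(a0, newci, mdiag);
  };

  auto altruism_step = [&](int a0) {
    int ci = (ant_x[a0] + 2) + W * (ant_y[a0] + 2);
    int others = 0;
    for (int k = 0; k < 24; ++k) {
      int t = ci + d2[k];
      if (occ[t] > 0) ++others;
      if (mem[t] > 0) ++others;
    }
    int cha = ant_chain[a0];
    double Xi = (cha == NA_INTEGER) ? 1.0 : (double)chain_sizes[cha - 1];
    double P1;
    if (pher_leave) {
      double b = l_eta * std::log(space[ci] + 1.0) + l_eps;
      if (b > 1.0) b = 1.0;
      P1 = l_a / (1.0 + b * (Xi * Xi));
    } else {
      P1 = Cs0 + Cs1 / (Cs2 + R_pow(Xi, nu));
    }
    // a member pinned under a walker stays; short-circuits mirror the R
    // reference so no draw happens when pinned or under-crowded
    bool go = occ[ci] == 0;
    if (go) {
      go = others < n_min;
      if (!go) go = unif_rand() < P1;
    }
    if (go) {
      int idx[8], cnt = 0;
      for (int k = 0; k < 8; ++k) {
        int t = ci + d1[k];
        int cl = cls[t];
        if ((cl == 0 || cl == 2) && occ[t] == 0) idx[cnt++] = k;
      }
      if (cnt > 0) {
        int k = idx[pick_uniform(cnt)];
        mem[ci] = 0;
        int ti = ci + d1[k];
        occ[ti] = a0 + 1;
        ant_x[a0] += DX1[k]; ant_y[a0] += DY1[k];
        ant_hx[a0] = DX1[k]; ant_hy[a0] = DY1[k];
        ant_state[a0] = 1;
        ant_chain[a0] = NA_INTEGER;
        event(a0 + 1, 3, 1, ant_x[a0], ant_y[a0]);
        deposit(a0, ti, DX1[k] != 0 && DY1[k] != 0);
      }
    }
  };

  // Fisher-Yates mirroring .shuffle, then dispatch by state.
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  for (int i = n - 1; i >= 1; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
  for (int i = 0; i < n; ++i) {
    int a0 = ord[i];
    int s = ant_state[a0];
    if (s == 1) search_step(a0);
    else if (s == 2) return_step(a0);
    else altruism_step(a0);
  }

  int nev = (int)(ev.size() / 6);
  IntegerMatrix out(nev, 6);
  for (int r = 0; r < nev; ++r)
    for (int c = 0; c < 6; ++c) out(r, c) = ev[6 * r + c];
  return out;
}

// Space-layer diffusion plus ground/space exchange over the core (the
// padded border acts as the absorbing edge: it is read as zero and never
// written).  Matches the R reference arithmetic: orthogonal and diagonal
// neighbour sums accumulated in the .shift order, negative results clipped
// to zero and counted, then space += r_e * ground; ground *= 1 - r_e.
// Returns the number of clipped cells.

// [[Rcpp::export]]
int cpp_field_tick(Environment st) {
  const int W = as<int>(st["W"]);
  const int w = as<int>(st["w"]), h = as<int>(st["h"]);
  NumericMatrix space = st["space"], ground = st["ground"];
  List pp = st["pheromone"];
  const double rA = as<double>(pp["r_A"]), rB = as<double>(pp["r_B"]),
               rC = as<double>(pp["r_C"]), re = as<double>(pp["r_e"]);
  const double floor_v = as<double>(pp["floor"]);
  const bool conservative = as<std::string>(pp["kernel"]) == "conservative";

  NumericMatrix s2(w, h);
  int clipped = 0;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      int ci = (x + 2) + W * (y + 2);
      double s = space[ci];
      // .shift sum order: (1,0) + (-1,0) + (0,1) + (0,-1)
      double orth = space[ci - 1] + space[ci + 1] + space[ci - W] + space[ci + W];
      double diag = space[ci - 1 - W] + space[ci - 1 + W] +
                    space[ci + 1 - W] + space[ci + 1 + W];
      double v = conservative ? rA * s + rB * orth + rC * diag
                              : rA * s + rB * (orth - 4.0 * s) + rC * (diag - 4.0 * s);
      if (v < 0) { v = 0; ++clipped; }
      s2(x, y) = v;
    }
  }
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      int ci = (x + 2) + W * (y + 2);
      double g = ground[ci];
      double s = s2(x, y) + re * g;
      double g2 = g - re * g;
      space[ci] = (s < floor_v) ? 0.0 : s;
      ground[ci] = (g2 < floor_v) ? 0.0 : g2;
    }
  return clipped;
}
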