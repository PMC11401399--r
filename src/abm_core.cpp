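// Simulation core: the per-timestep agent loop of the on-lattice
// tumor-immune model. All randomness is drawn from R's RNG so that
// set.seed() in R makes full runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

const int CLS_C = 1, CLS_E = 2, CLS_R = 3;

struct Agent {
  int x, y;
  int cls;
  double div_length;
  double cycle_pos;
  bool doomed;
  double death_time;
  int hits_delivered;
  int hits_this_step;
  bool quiescent_prev;
  bool alive;
};

struct Params {
  int width, height;
  double p_a, p_m;
  int cancer_submoves, immune_submoves;
  double eta_directed, search_radius;
  int hits_to_kill, max_hits;
  double div_mean, div_sd, div_min, div_max;
  double zeta_apoptosis, zeta_effector, mu, zeta_regulatory, zeta_tx;
  double recruit_radius;
  double alpha[4], beta[4]; // indexed by class
  double xi_quiescent, cycle_delay, death_delay;
};

struct Ledger {
  int c_apoptosis = 0, c_effector = 0, c_tx = 0, c_mitosis = 0;
  std::vector<int> kill_x, kill_y;
};

struct Sim {
  Params par;
  std::vector<Agent> agents;
  std::vector<int> occ; // 0 = empty, else agent index + 1
  int n_alive[4] = {0, 0, 0, 0};
  std::vector<int> members[4]; // per-class agent indices, lazily pruned
  Ledger prev, cur;
  double acc_apop = 0, acc_eff = 0, acc_tx = 0, acc_reg = 0;
  int discarded_recruits = 0;

  int node(int x, int y) const { return x + par.width * y; }
  bool inb(int x, int y) const {
    return x >= 0 && x < par.width && y >= 0 && y < par.height;
  }

  int runif_int(int n) { // uniform on 0..n-1
    int k = (int)(unif_rand() * n);
    return k >= n ? n - 1 : k;
  }

  double trunc_normal() {
    // cycle-length draw: normal truncated to [div_min, div_max]
    for (int tries = 0; tries < 10000; ++tries) {
      double v = norm_rand() * par.div_sd + par.div_mean;
      if (v >= par.div_min && v <= par.div_max) return v;
    }
    return par.div_mean;
  }

  void remove_agent(int i) {
    Agent &a = agents[i];
    occ[node(a.x, a.y)] = 0;
    a.alive = false;
    n_alive[a.cls]--;
  }

  int add_agent(int x, int y, int cls, double div_length, double cycle_pos) {
    Agent a;
    a.x = x; a.y = y; a.cls = cls;
    a.div_length = div_length; a.cycle_pos = cycle_pos;
    a.doomed = false; a.death_time = 0;
    a.hits_delivered = 0; a.hits_this_step = 0;
    a.quiescent_prev = false; a.alive = true;
    agents.push_back(a);
    occ[node(x, y)] = (int)agents.size();
    n_alive[cls]++;
    members[cls].push_back((int)agents.size() - 1);
    return (int)agents.size() - 1;
  }

  void prune_members(int cls) {
    std::vector<int> keep;
    keep.reserve(n_alive[cls]);
    for (int i : members[cls])
      if (agents[i].alive && agents[i].cls == cls) keep.push_back(i);
    members[cls].swap(keep);
  }

  void move_agent(int i, int x, int y) {
    Agent &a = agents[i];
    occ[node(a.x, a.y)] = 0;
    a.x = x; a.y = y;
    occ[node(x, y)] = i + 1;
  }

  int vacant_moore(int x, int y, int *vx, int *vy) {
    int n = 0;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0) continue;
        int nx = x + dx, ny = y + dy;
        if (inb(nx, ny) && occ[node(nx, ny)] == 0) {
          vx[n] = nx; vy[n] = ny; ++n;
        }
      }
    return n;
  }

  // all Moore-adjacent alive agents of class cls
  int moore_targets(int x, int y, int cls, int *idx) {
    int n = 0;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0) continue;
        int nx = x + dx, ny = y + dy;
        if (!inb(nx, ny)) continue;
        int o = occ[node(nx, ny)];
        if (o > 0 && agents[o - 1].alive && agents[o - 1].cls == cls)
          idx[n++] = o - 1;
      }
    return n;
  }

  // Nearest agents of class cls within Euclidean radius r of (x, y):
  // fills `ties` with all minimizers, returns squared distance (or -1).
  // Uses a direct scan when targets are few, otherwise an expanding
  // Chebyshev-ring search over the occupancy grid.
  long nearest_targets(int x, int y, int cls, double r, std::vector<int> &ties) {
    ties.clear();
    long best = -1;
    double r2 = r * r;
    if (n_alive[cls] == 0) return -1;
    if (n_alive[cls] <= 64) {
      if ((int)members[cls].size() > 2 * n_alive[cls] + 64) prune_members(cls);
      for (int i : members[cls]) {
        const Agent &a = agents[i];
        if (!a.alive || a.cls != cls) continue;
        long dx = a.x - x, dy = a.y - y;
        long d2 = dx * dx + dy * dy;
        if (d2 == 0 || (double)d2 > r2) continue;
        if (best < 0 || d2 < best) { best = d2; ties.clear(); ties.push_back(i); }
        else if (d2 == best) ties.push_back(i);
      }
      return best;
    }
    int kmax = (int)std::floor(r);
    int span = std::max(par.width, par.height);
    if (kmax > span) kmax = span;
    for (int k = 1; k <= kmax; ++k) {
      if (best >= 0 && (long)k * k > best) break;
      int x0 = x - k, x1 = x + k, y0 = y - k, y1 = y + k;
      // walk the Chebyshev ring at distance k
      for (int cx = x0; cx <= x1; ++cx) {
        check_node(cx, y0, x, y, cls, r2, best, ties);
        check_node(cx, y1, x, y, cls, r2, best, ties);
      }
      for (int cy = y0 + 1; cy <= y1 - 1; ++cy) {
        check_node(x0, cy, x, y, cls, r2, best, ties);
        check_node(x1, cy, x, y, cls, r2, best, ties);
      }
    }
    return best;
  }

  void check_node(int cx, int cy, int x, int y, int cls, double r2,
                  long &best, std::vector<int> &ties) {
    if (!inb(cx, cy)) return;
    int o = occ[node(cx, cy)];
    if (o <= 0) return;
    const Agent &a = agents[o - 1];
    if (!a.alive || a.cls != cls) return;
    long dx = cx - x, dy = cy - y;
    long d2 = dx * dx + dy * dy;
    if ((double)d2 > r2) return;
    if (best < 0 || d2 < best) { best = d2; ties.clear(); ties.push_back(o - 1); }
    else if (d2 == best) ties.push_back(o - 1);
  }

  // --- per-agent rules -------------------------------------------------

  void step_cancer(int i, double hour) {
    Agent &a = agents[i];
    if (a.doomed && hour >= a.death_time) {
      remove_agent(i);
      cur.c_tx++;
      return;
    }
    if (par.p_a > 0 && unif_rand() < par.p_a) {
      remove_agent(i);
      cur.c_apoptosis++;
      return;
    }
    int vx[8], vy[8];
    int nv = vacant_moore(a.x, a.y, vx, vy);
    bool quiescent = (nv == 0);
    if (!quiescent) a.cycle_pos += 1.0;
    a.quiescent_prev = quiescent;
    if (!a.doomed && a.cycle_pos >= a.div_length && nv > 0) {
      int k = runif_int(nv);
      a.cycle_pos = 0.0; // reset before add_agent may reallocate `agents`
      double dl = trunc_normal();
      // daughter starts a fresh cycle; not stepped until the next hour
      add_agent(vx[k], vy[k], CLS_C, dl, 0.0);
      cur.c_mitosis++;
    }
    if (unif_rand() < par.p_m) {
      for (int s = 0; s < par.cancer_submoves; ++s) {
        nv = vacant_moore(agents[i].x, agents[i].y, vx, vy);
        if (nv == 0) break;
        int k = runif_int(nv);
        move_agent(i, vx[k], vy[k]);
      }
    }
  }

  void step_immune(int i, double hour, std::vector<int> &ties) {
    Agent &a = agents[i];
    if (a.doomed && hour >= a.death_time) {
      remove_agent(i); // radiation-killed immune cell; not a cancer death
      return;
    }
    int target_cls = (a.cls == CLS_E) ? CLS_C : CLS_E;
    int vx[8], vy[8];
    for (int s = 0; s < par.immune_submoves; ++s) {
      Agent &me = agents[i];
      long best = nearest_targets(me.x, me.y, target_cls, par.search_radius, ties);
      if (best < 0) {
        int nv = vacant_moore(me.x, me.y, vx, vy);
        if (nv == 0) continue;
        int k = runif_int(nv);
        move_agent(i, vx[k], vy[k]);
        continue;
      }
      const Agent &q = agents[ties[runif_int((int)ties.size())]];
      double ux = q.x - me.x, uy = q.y - me.y;
      double un = std::sqrt(ux * ux + uy * uy);
      ux /= un; uy /= un;
      double th = unif_rand() * 2.0 * M_PI;
      double wx = (1.0 - par.eta_directed) * std::cos(th) + par.eta_directed * ux;
      double wy = (1.0 - par.eta_directed) * std::sin(th) + par.eta_directed * uy;
      double wn = std::sqrt(wx * wx + wy * wy);
      int nv = vacant_moore(me.x, me.y, vx, vy);
      if (nv == 0) continue;
      if (wn < 1e-12) {
        int k = runif_int(nv);
        move_agent(i, vx[k], vy[k]);
        continue;
      }
      // pick the vacant neighbor minimizing the angle to w
      double best_cos = -2.0;
      int cand[8], ncand = 0;
      for (int k = 0; k < nv; ++k) {
        double dx = vx[k] - me.x, dy = vy[k] - me.y;
        double dn = std::sqrt(dx * dx + dy * dy);
        double c = (dx * wx + dy * wy) / (dn * wn);
        if (c > best_cos + 1e-9) { best_cos = c; cand[0] = k; ncand = 1; }
        else if (c > best_cos - 1e-9) cand[ncand++] = k;
      }
      int k = cand[runif_int(ncand)];
      move_agent(i, vx[k], vy[k]);
    }
    // following migration: deliver at most one hit this timestep
    Agent &me = agents[i];
    int idx[8];
    int nt = moore_targets(me.x, me.y, target_cls, idx);
    if (nt > 0) {
      int t = idx[runif_int(nt)];
      agents[t].hits_this_step++;
      me.hits_delivered++;
      if (me.hits_delivered >= par.max_hits) remove_agent(i); // exhausted
    }
  }

  // --- phases ----------------------------------------------------------

  int place_random_vacant() {
    int total = par.width * par.height;
    for (int t = 0; t < 30; ++t) {
      int n = runif_int(total);
      if (occ[n] == 0) return n;
    }
    std::vector<int> v;
    for (int n = 0; n < total; ++n)
      if (occ[n] == 0) v.push_back(n);
    if (v.empty()) return -1;
    return v[runif_int((int)v.size())];
  }

  void place_effector_global() {
    int n = place_random_vacant();
    if (n < 0) { discarded_recruits++; return; }
    add_agent(n % par.width, n / par.width, CLS_E, 0.0, 0.0);
  }

  void place_effector_postcode() {
    // postcode homing: near a kill site with probability mu
    if (!prev.kill_x.empty() && unif_rand() < par.mu) {
      int k = runif_int((int)prev.kill_x.size());
      int kx = prev.kill_x[k], ky = prev.kill_y[k];
      int rad = (int)std::floor(par.recruit_radius);
      double r2 = par.recruit_radius * par.recruit_radius;
      std::vector<int> v;
      for (int dy = -rad; dy <= rad; ++dy)
        for (int dx = -rad; dx <= rad; ++dx) {
          if ((double)(dx * dx + dy * dy) > r2) continue;
          int nx = kx + dx, ny = ky + dy;
          if (inb(nx, ny) && occ[node(nx, ny)] == 0) v.push_back(node(nx, ny));
        }
      if (!v.empty()) {
        int n = v[runif_int((int)v.size())];
        add_agent(n % par.width, n / par.width, CLS_E, 0.0, 0.0);
        return;
      }
      // disk full: fall back to global placement
    }
    place_effector_global();
  }

  void place_regulatory_global() {
    int n = place_random_vacant();
    if (n < 0) { discarded_recruits++; return; }
    add_agent(n % par.width, n / par.width, CLS_R, 0.0, 0.0);
  }

  static int take_floor(double rate, int count, double &acc) {
    double raw = rate * count + acc;
    int n = (int)std::floor(raw);
    acc = raw - n;
    return n;
  }

  void phase_recruit() {
    int n_apop = take_floor(par.zeta_apoptosis, prev.c_apoptosis, acc_apop);
    int n_eff = take_floor(par.zeta_effector, prev.c_effector, acc_eff);
    int n_tx = take_floor(par.zeta_tx, prev.c_tx, acc_tx);
    int n_reg = take_floor(par.zeta_regulatory, prev.c_mitosis, acc_reg);
    for (int k = 0; k < n_apop; ++k) place_effector_global();
    for (int k = 0; k < n_eff; ++k) place_effector_postcode();
    for (int k = 0; k < n_tx; ++k) place_effector_global();
    for (int k = 0; k < n_reg; ++k) place_regulatory_global();
  }

  void phase_radiation(const NumericMatrix &dose_map, double scale, double hour) {
    for (size_t i = 0; i < agents.size(); ++i) {
      Agent &a = agents[i];
      if (!a.alive) continue;
      double d = dose_map(a.x, a.y) * scale;
      if (d <= 0) continue;
      bool cycling = (a.cls == CLS_C) ? (!a.quiescent_prev && !a.doomed) : false;
      double xi = (a.cls == CLS_C && !cycling) ? par.xi_quiescent : 1.0;
      double de = d / xi;
      double p = std::exp(-par.alpha[a.cls] * de - par.beta[a.cls] * de * de);
      if (unif_rand() < p) {
        if (a.cls == CLS_C && cycling) a.div_length += par.cycle_delay * d;
      } else if (!a.doomed) {
        a.doomed = true;
        a.death_time = hour + par.death_delay;
      }
    }
  }

  void phase_resolve_hits() {
    for (size_t i = 0; i < agents.size(); ++i) {
      Agent &a = agents[i];
      if (!a.alive) { a.hits_this_step = 0; continue; }
      if (a.hits_this_step >= par.hits_to_kill) {
        if (a.cls == CLS_C) {
          cur.kill_x.push_back(a.x);
          cur.kill_y.push_back(a.y);
          remove_agent((int)i);
          cur.c_effector++;
        } else if (a.cls == CLS_E) {
          remove_agent((int)i); // regulatory-mediated effector death
        }
      }
      a.hits_this_step = 0; // sub-lethal damage fully repairs
    }
  }

  void compact() {
    std::vector<Agent> keep;
    keep.reserve(n_alive[1] + n_alive[2] + n_alive[3]);
    for (size_t i = 0; i < agents.size(); ++i)
      if (agents[i].alive) keep.push_back(agents[i]);
    agents.swap(keep);
    std::fill(occ.begin(), occ.end(), 0);
    for (int c = 1; c <= 3; ++c) members[c].clear();
    for (size_t i = 0; i < agents.size(); ++i) {
      occ[node(agents[i].x, agents[i].y)] = (int)i + 1;
      members[agents[i].cls].push_back((int)i);
    }
  }

  void step(double hour, const NumericMatrix &dose_map, double dose_scale,
            bool irradiate) {
    cur = Ledger();
    phase_recruit();
    if (irradiate) phase_radiation(dose_map, dose_scale, hour);
    // uniformly shuffled agent order (Fisher-Yates on alive indices)
    std::vector<int> order;
    order.reserve(agents.size());
    for (size_t i = 0; i < agents.size(); ++i)
      if (agents[i].alive) order.push_back((int)i);
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = runif_int(i + 1);
      std::swap(order[i], order[j]);
    }
    std::vector<int> ties;
    for (int i : order) {
      if (!agents[i].alive) continue;
      if (agents[i].cls == CLS_C) step_cancer(i, hour);
      else step_immune(i, hour, ties);
    }
    phase_resolve_hits();
    prev = cur;
    int alive = n_alive[1] + n_alive[2] + n_alive[3];
    if ((int)agents.size() > 2 * alive + 1024) compact();
  }
};

Params parse_params(const List &cfg) {
  Params p;
  p.width = as<int>(cfg["width"]);
  p.height = as<int>(cfg["height"]);
  p.p_a = as<double>(cfg["p_a"]);
  p.p_m = as<double>(cfg["p_m"]);
  p.cancer_submoves = as<int>(cfg["cancer_submoves"]);
  p.immune_submoves = as<int>(cfg["immune_submoves"]);
  p.eta_directed = as<double>(cfg["eta_directed"]);
  p.search_radius = as<double>(cfg["search_radius"]);
  p.hits_to_kill = as<int>(cfg["hits_to_kill"]);
  p.max_hits = as<int>(cfg["max_hits"]);
  p.div_mean = as<double>(cfg["div_mean"]);
  p.div_sd = as<double>(cfg["div_sd"]);
  p.div_min = as<double>(cfg["div_min"]);
  p.div_max = as<double>(cfg["div_max"]);
  p.zeta_apoptosis = as<double>(cfg["zeta_apoptosis"]);
  p.zeta_effector = as<double>(cfg["zeta_effector"]);
  p.mu = as<double>(cfg["mu"]);
  p.zeta_regulatory = as<double>(cfg["zeta_regulatory"]);
  p.zeta_tx = as<double>(cfg["zeta_tx"]);
  p.recruit_radius = as<double>(cfg["recruit_radius"]);
  NumericVector alpha = cfg["alpha"], beta = cfg["beta"];
  for (int k = 0; k < 3; ++k) {
    p.alpha[k + 1] = alpha[k];
    p.beta[k + 1] = beta[k];
  }
  p.xi_quiescent = as<double>(cfg["xi_quiescent"]);
  p.cycle_delay = as<double>(cfg["cycle_delay"]);
  p.death_delay = as<double>(cfg["death_delay"]);
  return p;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_sim(List agents_in, List cfg, List ledger_in, NumericVector acc_in,
                 int discarded_in, int start_hour, int end_hour,
                 NumericMatrix dose_map, IntegerVector schedule_hours,
                 NumericVector schedule_scale, bool record, bool stop_on_clearance) {
  Sim sim;
  sim.par = parse_params(cfg);
  int total = sim.par.width * sim.par.height;
  sim.occ.assign(total, 0);

  IntegerVector ax = agents_in["x"], ay = agents_in["y"], acls = agents_in["class"];
  NumericVector adiv = agents_in["div_length"], acyc = agents_in["cycle_position"];
  LogicalVector adoom = agents_in["doomed"], aqp = agents_in["quiescent_prev"];
  NumericVector adt = agents_in["death_time"];
  IntegerVector ahits = agents_in["hits_delivered"];
  int n0 = ax.size();
  sim.agents.reserve(n0 + 1024);
  for (int i = 0; i < n0; ++i) {
    if (!sim.inb(ax[i], ay[i]))
      stop("agent %d outside domain", i + 1);
    if (sim.occ[sim.node(ax[i], ay[i])] != 0)
      stop("two agents share node (%d, %d)", ax[i], ay[i]);
    int j = sim.add_agent(ax[i], ay[i], acls[i], adiv[i], acyc[i]);
    sim.agents[j].doomed = adoom[i];
    sim.agents[j].death_time = adt[i];
    sim.agents[j].hits_delivered = ahits[i];
    sim.agents[j].quiescent_prev = aqp[i];
  }

  sim.prev.c_apoptosis = as<int>(ledger_in["c_apoptosis"]);
  sim.prev.c_effector = as<int>(ledger_in["c_effector"]);
  sim.prev.c_tx = as<int>(ledger_in["c_tx"]);
  sim.prev.c_mitosis = as<int>(ledger_in["c_mitosis"]);
  IntegerVector kx = ledger_in["kill_x"], ky = ledger_in["kill_y"];
  sim.prev.kill_x.assign(kx.begin(), kx.end());
  sim.prev.kill_y.assign(ky.begin(), ky.end());
  sim.acc_apop = acc_in[0];
  sim.acc_eff = acc_in[1];
  sim.acc_tx = acc_in[2];
  sim.acc_reg = acc_in[3];
  sim.discarded_recruits = discarded_in;

  std::vector<int> t_hour, t_C, t_E, t_R, t_dapop, t_deff, t_dtx, t_mit;
  int nsteps = end_hour - start_hour;
  if (record && nsteps > 0) {
    t_hour.reserve(nsteps); t_C.reserve(nsteps); t_E.reserve(nsteps);
    t_R.reserve(nsteps); t_dapop.reserve(nsteps); t_deff.reserve(nsteps);
    t_dtx.reserve(nsteps); t_mit.reserve(nsteps);
  }

  bool cleared = (sim.n_alive[CLS_C] == 0);
  int clearance_hour = cleared ? start_hour : NA_INTEGER;
  int sched_i = 0, nsched = schedule_hours.size();

  int hour_done = start_hour;
  for (int hour = start_hour + 1;
       hour <= end_hour && !(stop_on_clearance && cleared); ++hour) {
    hour_done = hour;
    while (sched_i < nsched && schedule_hours[sched_i] < hour) ++sched_i;
    bool irr = (sched_i < nsched && schedule_hours[sched_i] == hour);
    double scale = irr ? schedule_scale[sched_i] : 0.0;
    sim.step((double)hour, dose_map, scale, irr);
    if (record) {
      t_hour.push_back(hour);
      t_C.push_back(sim.n_alive[1]);
      t_E.push_back(sim.n_alive[2]);
      t_R.push_back(sim.n_alive[3]);
      t_dapop.push_back(sim.prev.c_apoptosis);
      t_deff.push_back(sim.prev.c_effector);
      t_dtx.push_back(sim.prev.c_tx);
      t_mit.push_back(sim.prev.c_mitosis);
    }
    if (!cleared && sim.n_alive[CLS_C] == 0) {
      cleared = true;
      clearance_hour = hour;
    }
  }

  sim.compact();
  int n = (int)sim.agents.size();
  IntegerVector ox(n), oy(n), ocls(n), ohits(n);
  NumericVector odiv(n), ocyc(n), odt(n);
  LogicalVector odoom(n), oqp(n);
  for (int i = 0; i < n; ++i) {
    const Agent &a = sim.agents[i];
    ox[i] = a.x; oy[i] = a.y; ocls[i] = a.cls;
    odiv[i] = a.div_length; ocyc[i] = a.cycle_pos;
    odoom[i] = a.doomed; odt[i] = a.death_time;
    ohits[i] = a.hits_delivered; oqp[i] = a.quiescent_prev;
  }

  int last_hour = hour_done;

  return List::create(
    _["agents"] = List::create(
      _["x"] = ox, _["y"] = oy, _["class"] = ocls,
      _["div_length"] = odiv, _["cycle_position"] = ocyc,
      _["doomed"] = odoom, _["death_time"] = odt,
      _["hits_delivered"] = ohits, _["quiescent_prev"] = oqp
    ),
    _["hour"] = last_hour,
    _["ledger"] = List::create(
      _["c_apoptosis"] = sim.prev.c_apoptosis,
      _["c_effector"] = sim.prev.c_effector,
      _["c_tx"] = sim.prev.c_tx,
      _["c_mitosis"] = sim.prev.c_mitosis,
      _["kill_x"] = IntegerVector(sim.prev.kill_x.begin(), sim.prev.kill_x.end()),
      _["kill_y"] = IntegerVector(sim.prev.kill_y.begin(), sim.prev.kill_y.end())
    ),
    _["accumulators"] = NumericVector::create(
      sim.acc_apop, sim.acc_eff, sim.acc_tx, sim.acc_reg
    ),
    _["discarded_recruits"] = sim.discarded_recruits,
    _["cleared"] = cleared,
    _["clearance_hour"] = clearance_hour,
    _["trajectory"] = DataFrame::create(
      _["hour"] = IntegerVector(t_hour.begin(), t_hour.end()),
      _["C"] = IntegerVector(t_C.begin(), t_C.end()),
      _["E"] = IntegerVector(t_E.begin(), t_E.end()),
      _["R"] = IntegerVector(t_R.begin(), t_R.end()),
      _["deaths_apoptosis"] = IntegerVector(t_dapop.begin(), t_dapop.end()),
      _["deaths_effector"] = IntegerVector(t_deff.begin(), t_deff.end()),
      _["deaths_radiation"] = IntegerVector(t_dtx.begin(), t_dtx.end()),
      _["mitoses"] = IntegerVector(t_mit.begin(), t_mit.end())
    )
  );
}

// Nearest-target grid query exposed for cross-checking the ring search
// against the plain R implementation.
// [[Rcpp::export]]
List cpp_nearest_in_grid(int x, int y, double r, LogicalMatrix target_mask,
                         bool force_ring) {
  Sim sim;
  sim.par = Params();
  sim.par.width = target_mask.nrow();
  sim.par.height = target_mask.ncol();
  sim.occ.assign(sim.par.width * sim.par.height, 0);
  sim.agents.reserve(sim.par.width * sim.par.height);
  for (int j = 0; j < sim.par.height; ++j)
    for (int i = 0; i < sim.par.width; ++i)
      if (target_mask(i, j)) sim.add_agent(i, j, CLS_C, 24.0, 0.0);
  if (force_ring) {
    // pad the alive count so the direct-scan shortcut is bypassed
    sim.n_alive[CLS_C] += 1000;
  }
  std::vector<int> ties;
  long best = sim.nearest_targets(x, y, CLS_C, r, ties);
  if (force_ring) sim.n_alive[CLS_C] -= 1000;
  int n = (int)ties.size();
  IntegerVector tx(n), ty(n);
  for (int i = 0; i < n; ++i) {
    tx[i] = sim.agents[ties[i]].x;
    ty[i] = sim.agents[ties[i]].y;
  }
  return List::create(_["x"] = tx, _["y"] = ty, _["d2"] = (double)best);
}
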