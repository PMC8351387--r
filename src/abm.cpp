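#include <Rcpp.h>
using namespace Rcpp;

// Agent-based model of an obligate cross-feeding community on a toroidal
// patch grid. Yeast secrete amino acids and consume vitamin; bacteria do the
// reverse. Mutant bacteria secrete `mutant_secretion_fold` times more vitamin
// at proportional energy cost. The tick order is fixed:
// move -> secrete -> diffuse -> consume -> die -> divide.
//
// All randomness comes from R's RNG stream (RNGScope is injected by the
// Rcpp attribute wrappers), so set.seed() in R governs every draw.

namespace {

struct Params {
  int nr, nc;
  double mixing, diffusion, wander;
  int init_yeast, init_wt, init_mut;
  int doublings, n_transfers, max_ticks;
  double energy_init, division_threshold;
  double y_up, y_sec, y_cost, y_eff;
  double b_up, b_sec, b_cost, b_eff;
  double fold;
};

Params read_params(const List& cfg) {
  Params p;
  p.nr = as<int>(cfg["grid_height"]);
  p.nc = as<int>(cfg["grid_width"]);
  p.mixing = as<double>(cfg["mixing"]);
  p.diffusion = as<double>(cfg["diffusion_rate"]);
  p.wander = as<double>(cfg["wander_prob"]);
  p.init_yeast = as<int>(cfg["init_yeast"]);
  p.init_wt = as<int>(cfg["init_wt_bacteria"]);
  p.init_mut = as<int>(cfg["init_mutant_bacteria"]);
  p.doublings = as<int>(cfg["doublings_per_transfer"]);
  p.n_transfers = as<int>(cfg["n_transfers"]);
  p.max_ticks = as<int>(cfg["max_ticks_per_transfer"]);
  p.energy_init = as<double>(cfg["energy_init"]);
  p.division_threshold = as<double>(cfg["division_threshold"]);
  p.y_up = as<double>(cfg["yeast_uptake_max"]);
  p.y_sec = as<double>(cfg["yeast_secretion_rate"]);
  p.y_cost = as<double>(cfg["yeast_secretion_cost"]);
  p.y_eff = as<double>(cfg["yeast_conversion_efficiency"]);
  p.b_up = as<double>(cfg["bact_uptake_max"]);
  p.b_sec = as<double>(cfg["bact_secretion_rate"]);
  p.b_cost = as<double>(cfg["bact_secretion_cost"]);
  p.b_eff = as<double>(cfg["bact_conversion_efficiency"]);
  p.fold = as<double>(cfg["mutant_secretion_fold"]);
  return p;
}

struct World {
  // species: 0 = yeast, 1 = bacterium; strain: 0 = wild, 1 = mutant
  std::vector<int> species, strain, pr, pc;
  std::vector<double> energy;
  std::vector<double> aa, vit;  // column-major nr x nc
  int nr, nc, tick;

  int n() const { return (int)species.size(); }
  int idx(int r, int c) const { return r + nr * c; }
};

inline int rand_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

World world_from_list(const List& w) {
  World x;
  NumericMatrix aa = w["amino_acid"], vit = w["vitamin"];
  x.nr = aa.nrow();
  x.nc = aa.ncol();
  x.aa.assign(aa.begin(), aa.end());
  x.vit.assign(vit.begin(), vit.end());
  IntegerVector sp = w["species"], st = w["strain"], pr = w["row"], pc = w["col"];
  NumericVector en = w["energy"];
  x.species.assign(sp.begin(), sp.end());
  x.strain.assign(st.begin(), st.end());
  x.pr.assign(pr.begin(), pr.end());
  x.pc.assign(pc.begin(), pc.end());
  x.energy.assign(en.begin(), en.end());
  x.tick = as<int>(w["tick"]);
  return x;
}

List world_to_list(const World& x) {
  NumericMatrix aa(x.nr, x.nc), vit(x.nr, x.nc);
  std::copy(x.aa.begin(), x.aa.end(), aa.begin());
  std::copy(x.vit.begin(), x.vit.end(), vit.begin());
  List w = List::create(
      _["amino_acid"] = aa, _["vitamin"] = vit,
      _["species"] = IntegerVector(x.species.begin(), x.species.end()),
      _["strain"] = IntegerVector(x.strain.begin(), x.strain.end()),
      _["energy"] = NumericVector(x.energy.begin(), x.energy.end()),
      _["row"] = IntegerVector(x.pr.begin(), x.pr.end()),
      _["col"] = IntegerVector(x.pc.begin(), x.pc.end()),
      _["tick"] = x.tick);
  w.attr("class") = "abm_world";
  return w;
}

// 8-neighbour (Moore) diffusion on a torus: each patch keeps (1 - rate) and
// gives rate/8 to each neighbour. Mass-conserving by construction.
void diffuse_grid(std::vector<double>& g, int nr, int nc, double rate) {
  if (rate == 0.0) return;
  std::vector<double> out(g.size(), 0.0);
  const double share = rate / 8.0;
  for (int c = 0; c < nc; ++c) {
    int cl = (c == 0) ? nc - 1 : c - 1;
    int cr = (c == nc - 1) ? 0 : c + 1;
    for (int r = 0; r < nr; ++r) {
      int ru = (r == 0) ? nr - 1 : r - 1;
      int rd = (r == nr - 1) ? 0 : r + 1;
      double amt = g[r + nr * c];
      if (amt == 0.0) continue;
      out[r + nr * c] += amt * (1.0 - rate);
      double give = amt * share;
      out[ru + nr * cl] += give; out[ru + nr * c] += give; out[ru + nr * cr] += give;
      out[r + nr * cl] += give;                            out[r + nr * cr] += give;
      out[rd + nr * cl] += give; out[rd + nr * c] += give; out[rd + nr * cr] += give;
    }
  }
  g.swap(out);
}

void do_tick(World& w, const Params& p) {
  int n = w.n();

  // 1) movement: a local random-walk step (torus King move) with
  // probability p.wander models cell motility at the patch scale; a global
  // teleport with probability p.mixing models culture shaking. Mixing
  // takes precedence when both fire.
  if (p.mixing > 0.0 || p.wander > 0.0) {
    for (int i = 0; i < n; ++i) {
      if (p.mixing > 0.0 && unif_rand() < p.mixing) {
        w.pr[i] = rand_int(w.nr);
        w.pc[i] = rand_int(w.nc);
      } else if (p.wander > 0.0 && unif_rand() < p.wander) {
        int dr = rand_int(3) - 1, dc = rand_int(3) - 1;
        w.pr[i] = (w.pr[i] + dr + w.nr) % w.nr;
        w.pc[i] = (w.pc[i] + dc + w.nc) % w.nc;
      }
    }
  }

  // 2) secretion (unconditional; the agent pays even if it dies of it)
  for (int i = 0; i < n; ++i) {
    int k = w.idx(w.pr[i], w.pc[i]);
    if (w.species[i] == 0) {
      w.aa[k] += p.y_sec;
      w.energy[i] -= p.y_cost * p.y_sec;
    } else {
      double sec = p.b_sec * (w.strain[i] == 1 ? p.fold : 1.0);
      w.vit[k] += sec;
      w.energy[i] -= p.b_cost * sec;
    }
  }

  // 3) diffusion of both pools
  diffuse_grid(w.aa, w.nr, w.nc, p.diffusion);
  diffuse_grid(w.vit, w.nr, w.nc, p.diffusion);

  // 4) consumption in a freshly shuffled order (first-come within the shuffle)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  for (int i = n - 1; i > 0; --i) std::swap(ord[i], ord[rand_int(i + 1)]);
  for (int j = 0; j < n; ++j) {
    int i = ord[j];
    int k = w.idx(w.pr[i], w.pc[i]);
    if (w.species[i] == 0) {
      double take = std::min(p.y_up, w.vit[k]);
      w.vit[k] -= take;
      w.energy[i] += p.y_eff * take;
    } else {
      double take = std::min(p.b_up, w.aa[k]);
      w.aa[k] -= take;
      w.energy[i] += p.b_eff * take;
    }
  }

  // 5) death at energy <= 0, then 6) division at energy >= threshold.
  // Death first, so an agent cannot both die and divide in one tick.
  World next;
  next.nr = w.nr; next.nc = w.nc;
  next.aa.swap(w.aa); next.vit.swap(w.vit);
  next.species.reserve(n); next.strain.reserve(n);
  next.pr.reserve(n); next.pc.reserve(n); next.energy.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (w.energy[i] <= 0.0) continue;
    if (w.energy[i] >= p.division_threshold) {
      double half = w.energy[i] / 2.0;
      for (int d = 0; d < 2; ++d) {
        next.species.push_back(w.species[i]);
        next.strain.push_back(w.strain[i]);
        next.pr.push_back(w.pr[i]);
        next.pc.push_back(w.pc[i]);
        next.energy.push_back(half);
      }
    } else {
      next.species.push_back(w.species[i]);
      next.strain.push_back(w.strain[i]);
      next.pr.push_back(w.pr[i]);
      next.pc.push_back(w.pc[i]);
      next.energy.push_back(w.energy[i]);
    }
  }
  next.tick = w.tick + 1;
  w = std::move(next);
}

void init_world_internal(World& w, const Params& p) {
  w.nr = p.nr; w.nc = p.nc; w.tick = 0;
  w.aa.assign((size_t)p.nr * p.nc, 0.0);
  w.vit.assign((size_t)p.nr * p.nc, 0.0);
  int total = p.init_yeast + p.init_wt + p.init_mut;
  w.species.clear(); w.strain.clear(); w.pr.clear(); w.pc.clear(); w.energy.clear();
  w.species.reserve(total);
  for (int i = 0; i < p.init_yeast; ++i) { w.species.push_back(0); w.strain.push_back(0); }
  for (int i = 0; i < p.init_wt; ++i)    { w.species.push_back(1); w.strain.push_back(0); }
  for (int i = 0; i < p.init_mut; ++i)   { w.species.push_back(1); w.strain.push_back(1); }
  for (int i = 0; i < total; ++i) {
    w.pr.push_back(rand_int(p.nr));
    w.pc.push_back(rand_int(p.nc));
    w.energy.push_back(p.energy_init);
  }
}

// Serial transfer: sample init_total agents without replacement (all kept if
// fewer exist), reset both pools to zero, re-randomize positions, keep
// energies, reset tick to 0.
void apply_transfer_internal(World& w, const Params& p) {
  int total = p.init_yeast + p.init_wt + p.init_mut;
  int n = w.n();
  if (n > total) {
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(ord[i], ord[rand_int(i + 1)]);
    World keep;
    keep.nr = w.nr; keep.nc = w.nc;
    for (int j = 0; j < total; ++j) {
      int i = ord[j];
      keep.species.push_back(w.species[i]);
      keep.strain.push_back(w.strain[i]);
      keep.energy.push_back(w.energy[i]);
      keep.pr.push_back(0); keep.pc.push_back(0);
    }
    w.species.swap(keep.species); w.strain.swap(keep.strain);
    w.energy.swap(keep.energy); w.pr.swap(keep.pr); w.pc.swap(keep.pc);
  }
  w.aa.assign(w.aa.size(), 0.0);
  w.vit.assign(w.vit.size(), 0.0);
  for (int i = 0; i < w.n(); ++i) {
    w.pr[i] = rand_int(w.nr);
    w.pc[i] = rand_int(w.nc);
  }
  w.tick = 0;
}

struct Rec { int transfer, tick, ny, nwt, nmut; double aa, vit; };

void record(std::vector<Rec>& recs, const World& w, int transfer) {
  Rec r;
  r.transfer = transfer; r.tick = w.tick;
  r.ny = r.nwt = r.nmut = 0;
  for (int i = 0; i < w.n(); ++i) {
    if (w.species[i] == 0) ++r.ny;
    else if (w.strain[i] == 0) ++r.nwt;
    else ++r.nmut;
  }
  r.aa = std::accumulate(w.aa.begin(), w.aa.end(), 0.0);
  r.vit = std::accumulate(w.vit.begin(), w.vit.end(), 0.0);
  recs.push_back(r);
}

NumericMatrix recs_to_matrix(const std::vector<Rec>& recs) {
  NumericMatrix m(recs.size(), 7);
  for (size_t i = 0; i < recs.size(); ++i) {
    m(i, 0) = recs[i].transfer; m(i, 1) = recs[i].tick;
    m(i, 2) = recs[i].ny; m(i, 3) = recs[i].nwt; m(i, 4) = recs[i].nmut;
    m(i, 5) = recs[i].aa; m(i, 6) = recs[i].vit;
  }
  colnames(m) = CharacterVector::create("transfer", "tick", "n_yeast", "n_wt",
                                        "n_mutant", "total_aa", "total_vit");
  return m;
}

// outcome codes: 0 reached_threshold, 1 extinct, 2 timed_out
int cycle_internal(World& w, const Params& p, int transfer,
                   std::vector<Rec>* recs) {
  int total = p.init_yeast + p.init_wt + p.init_mut;
  double threshold = total * std::pow(2.0, p.doublings);
  for (;;) {
    if (w.n() == 0) return 1;
    if (w.n() >= threshold) return 0;
    if (w.tick >= p.max_ticks) return 2;
    do_tick(w, p);
    if (recs) record(*recs, w, transfer);
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix grid, double rate) {
  std::vector<double> g(grid.begin(), grid.end());
  diffuse_grid(g, grid.nrow(), grid.ncol(), rate);
  NumericMatrix out(grid.nrow(), grid.ncol());
  std::copy(g.begin(), g.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_init_world(List cfg) {
  Params p = read_params(cfg);
  World w;
  init_world_internal(w, p);
  return world_to_list(w);
}

// [[Rcpp::export]]
List cpp_tick(List world, List cfg) {
  Params p = read_params(cfg);
  World w = world_from_list(world);
  do_tick(w, p);
  return world_to_list(w);
}

// [[Rcpp::export]]
List cpp_apply_transfer(List world, List cfg) {
  Params p = read_params(cfg);
  World w = world_from_list(world);
  apply_transfer_internal(w, p);
  return world_to_list(w);
}

// [[Rcpp::export]]
List cpp_run_transfer_cycle(List world, List cfg, int transfer_index) {
  Params p = read_params(cfg);
  World w = world_from_list(world);
  std::vector<Rec> recs;
  int outcome = cycle_internal(w, p, transfer_index, &recs);
  return List::create(_["world"] = world_to_list(w),
                      _["records"] = recs_to_matrix(recs),
                      _["outcome"] = outcome);
}

// Full replicate: init, then n_transfers rounds of (grow to threshold,
// transfer). Stops early on extinction or timeout ("collapse").
// keep_records = FALSE skips per-tick bookkeeping for speed.
// [[Rcpp::export]]
List cpp_run_replicate(List cfg, bool keep_records) {
  Params p = read_params(cfg);
  World w;
  init_world_internal(w, p);
  std::vector<Rec> recs;
  if (keep_records) record(recs, w, 0);
  int outcome = 0, completed = 0;
  for (int t = 1; t <= p.n_transfers; ++t) {
    outcome = cycle_internal(w, p, t, keep_records ? &recs : nullptr);
    if (outcome != 0) break;
    apply_transfer_internal(w, p);
    completed = t;
    if (keep_records) record(recs, w, t);
  }
  int nmut = 0, nwt = 0, ny = 0;
  for (int i = 0; i < w.n(); ++i) {
    if (w.species[i] == 0) ++ny;
    else if (w.strain[i] == 1) ++nmut;
    else ++nwt;
  }
  bool collapsed = (completed < p.n_transfers);
  bool invaded = !collapsed && nmut > 0;
  double frac = (nmut + nwt > 0) ? (double)nmut / (nmut + nwt) : NA_REAL;
  return List::create(
      _["world"] = world_to_list(w),
      _["records"] = keep_records ? (SEXP)recs_to_matrix(recs) : R_NilValue,
      _["transfers_completed"] = completed,
      _["collapsed"] = collapsed,
      _["invaded"] = invaded,
      _["final_mutant_fraction"] = frac,
      _["n_yeast"] = ny, _["n_wt"] = nwt, _["n_mutant"] = nmut);
}
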