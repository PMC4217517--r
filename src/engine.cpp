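// Discrete-time stochastic replication engine.
//
// One sweep = the time a fork needs to traverse one bin (binsize / 50 bp/s).
// Within a sweep, per S-phase cell, in this order:
//   1. every engaged fork attempts to advance one bin (prob = fork_progress
//      at its bin); stepping out of the chromosome or into replicated DNA
//      disengages the fork (boundary / collision recycling);
//   2. every still-engaged fork is released with prob fork_release at its bin;
//   3. one initiation attempt per free fork PAIR (or one per cell, see
//      init_rule): a bin is drawn uniformly from the unreplicated bins and
//      fires with the landscape probability at that bin, engaging two forks
//      bidirectionally;
//   4. a fully replicated cell returns to G with a fresh normal G duration.
//
// Determinism: each cell owns an independent xoshiro128++ stream seeded from
// (master seed, stream id), so results do not depend on iteration order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

constexpr int FRAC_GRID = 1000;  // fine grid for exposure-by-fraction

// ---------------------------------------------------------------------------
// RNG: xoshiro128++ seeded via splitmix64; portable and reproducible.

struct Xoshiro {
  uint32_t s[4];

  static uint32_t rotl(uint32_t x, int k) { return (x << k) | (x >> (32 - k)); }

  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (stream * 0xBF58476D1CE4E5B9ULL + 0x9E3779B97F4A7C15ULL);
    for (int i = 0; i < 4; i += 2) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      z ^= z >> 31;
      s[i] = (uint32_t)z;
      s[i + 1] = (uint32_t)(z >> 32);
    }
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1u;
  }

  uint32_t next() {
    uint32_t result = rotl(s[0] + s[3], 7) + s[0];
    uint32_t t = s[1] << 9;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 11);
    return result;
  }

  double unif() { return next() * (1.0 / 4294967296.0); }  // [0, 1)

  // unbiased uniform integer in [0, n)
  int unif_int(int n) {
    uint32_t lim = UINT32_MAX - UINT32_MAX % (uint32_t)n;
    uint32_t r;
    do { r = next(); } while (r >= lim);
    return (int)(r % (uint32_t)n);
  }

  double norm(double mu, double sd) {
    double u1 = unif(), u2 = unif();
    if (u1 >= 1.0) u1 = 0.9999999999;
    return mu + sd * std::sqrt(-2.0 * std::log(1.0 - u1)) *
                     std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------------------------

struct Par {
  int nbins = 0, nfork = 0;
  int init_rule = 0;  // 0 = one attempt per free fork pair; 1 = one per cell
  double g_mean = 0, g_sd = 0;
  const double *initp = nullptr, *pprog = nullptr, *prel = nullptr;
  bool any_release = false;
};

struct Cell {
  int phase = 0;  // 0 = G, 1 = S
  long long g_clock = 0;     // sweeps remaining in G
  long long s_clock = 0;     // sweeps elapsed in S
  long long cycle_start = 0; // global sweep at S entry
  std::vector<uint8_t> mask;
  std::vector<int> rep_sweep;  // -1 while unreplicated
  std::vector<uint8_t> fk_eng;
  std::vector<int> fk_pos;
  std::vector<int> fk_dir;
  // O(1) uniform sampling over unreplicated bins
  std::vector<int> unrepl, where;
  int n_unrepl = 0;
  // current-cycle buffers (flushed on S completion)
  std::vector<int> ev_sweep, ev_bin;
  std::vector<double> ev_frac;
  std::vector<double> expo;  // exposure by fraction, FRAC_GRID bins
  Xoshiro rng;

  void alloc(const Par& P) {
    mask.assign(P.nbins, 0);
    rep_sweep.assign(P.nbins, -1);
    fk_eng.assign(P.nfork, 0);
    fk_pos.assign(P.nfork, -1);
    fk_dir.assign(P.nfork, 0);
    unrepl.resize(P.nbins);
    where.resize(P.nbins);
    expo.assign(FRAC_GRID, 0.0);
    reset_genome(P);
  }

  void reset_genome(const Par& P) {
    std::fill(mask.begin(), mask.end(), 0);
    std::fill(rep_sweep.begin(), rep_sweep.end(), -1);
    std::fill(fk_eng.begin(), fk_eng.end(), 0);
    std::fill(fk_pos.begin(), fk_pos.end(), -1);
    std::fill(fk_dir.begin(), fk_dir.end(), 0);
    for (int b = 0; b < P.nbins; ++b) { unrepl[b] = b; where[b] = b; }
    n_unrepl = P.nbins;
    ev_sweep.clear(); ev_bin.clear(); ev_frac.clear();
    std::fill(expo.begin(), expo.end(), 0.0);
  }

  void rebuild_unrepl(const Par& P) {
    n_unrepl = 0;
    for (int b = 0; b < P.nbins; ++b)
      if (!mask[b]) { unrepl[n_unrepl] = b; where[b] = n_unrepl; ++n_unrepl; }
  }
};

inline void mark_replicated(Cell& c, int b, long long sweep_in_s) {
  c.mask[b] = 1;
  c.rep_sweep[b] = (int)sweep_in_s;
  int k = c.where[b];
  int moved = c.unrepl[c.n_unrepl - 1];
  c.unrepl[k] = moved;
  c.where[moved] = k;
  --c.n_unrepl;
}

inline long long draw_g_duration(Xoshiro& rng, const Par& P) {
  long long g = (long long)std::llround(rng.norm(P.g_mean, P.g_sd));
  return g < 1 ? 1 : g;
}

// One S sweep on one cell; returns true when the genome completed this sweep.
bool sweep_S(Cell& c, const Par& P) {
  // 1. advance engaged forks (pool order: the lower-index fork wins a
  //    convergent bin; the loser sees replicated DNA and disengages)
  for (int i = 0; i < P.nfork; ++i) {
    if (!c.fk_eng[i]) continue;
    if (c.rng.unif() < P.pprog[c.fk_pos[i]]) {
      int tgt = c.fk_pos[i] + c.fk_dir[i];
      if (tgt < 0 || tgt >= P.nbins || c.mask[tgt]) {
        c.fk_eng[i] = 0;  // boundary or collision: fork recycled
      } else {
        c.fk_pos[i] = tgt;
        mark_replicated(c, tgt, c.s_clock);
      }
    }
  }

  // 2. stochastic release
  if (P.any_release) {
    for (int i = 0; i < P.nfork; ++i) {
      if (c.fk_eng[i] && c.rng.unif() < P.prel[c.fk_pos[i]]) c.fk_eng[i] = 0;
    }
  }

  // 3. initiation attempts
  int free_forks = 0;
  for (int i = 0; i < P.nfork; ++i) free_forks += !c.fk_eng[i];
  int attempts = (P.init_rule == 0) ? free_forks / 2 : (free_forks >= 2 ? 1 : 0);
  if (c.n_unrepl > 0) {
    int n0 = c.n_unrepl;
    double frac0 = 1.0 - (double)n0 / P.nbins;
    int g = (int)(frac0 * FRAC_GRID);
    if (g >= FRAC_GRID) g = FRAC_GRID - 1;
    c.expo[g] += n0;  // exposure: unreplicated-bin sweeps at this fraction
    for (int a = 0; a < attempts && c.n_unrepl > 0; ++a) {
      int bin = c.unrepl[c.rng.unif_int(c.n_unrepl)];
      if (c.rng.unif() < P.initp[bin]) {
        mark_replicated(c, bin, c.s_clock);
        c.ev_sweep.push_back((int)c.s_clock);
        c.ev_bin.push_back(bin);
        c.ev_frac.push_back(frac0);
        int got = 0;
        for (int i = 0; i < P.nfork && got < 2; ++i) {
          if (!c.fk_eng[i]) {
            c.fk_eng[i] = 1;
            c.fk_pos[i] = bin;
            c.fk_dir[i] = (got == 0) ? -1 : +1;
            ++got;
          }
        }
      }
    }
  }

  ++c.s_clock;
  return c.n_unrepl == 0;
}

// ---------------------------------------------------------------------------
// Accumulators for a full simulation run.

struct Recorder {
  long long ntherm = 0;
  int nbins = 0;
  std::vector<double> t_sum, t_sumsq;
  std::vector<int> t_count;
  long long n_cycles = 0;
  std::vector<int> ev_sweep, ev_bin;
  std::vector<double> ev_frac;
  std::vector<double> expo;

  void init(int nb, long long nt) {
    nbins = nb;
    ntherm = nt;
    t_sum.assign(nb, 0.0);
    t_sumsq.assign(nb, 0.0);
    t_count.assign(nb, 0);
    expo.assign(FRAC_GRID, 0.0);
  }

  void complete_cycle(const Cell& c) {
    if (c.cycle_start < ntherm) return;  // burn-in cycle: discard
    ++n_cycles;
    for (int b = 0; b < nbins; ++b) {
      double v = c.rep_sweep[b];
      t_sum[b] += v;
      t_sumsq[b] += v * v;
      ++t_count[b];
    }
    ev_sweep.insert(ev_sweep.end(), c.ev_sweep.begin(), c.ev_sweep.end());
    ev_bin.insert(ev_bin.end(), c.ev_bin.begin(), c.ev_bin.end());
    ev_frac.insert(ev_frac.end(), c.ev_frac.begin(), c.ev_frac.end());
    for (int g = 0; g < FRAC_GRID; ++g) expo[g] += c.expo[g];
  }
};

// Advance the whole population by one sweep.  `global_sweep` is the sweep
// index about to be executed.
void population_step(std::vector<Cell>& cells, const Par& P,
                     long long global_sweep, Recorder* rec,
                     List* completions, IntegerVector* comp_cell) {
  int idx = 0;
  for (Cell& c : cells) {
    if (c.phase == 0) {
      --c.g_clock;
      if (c.g_clock > 0) { ++idx; continue; }
      // G -> S at sweep start; the first S sweep may already initiate
      c.phase = 1;
      c.s_clock = 0;
      c.cycle_start = global_sweep;
      c.reset_genome(P);
    }
    if (sweep_S(c, P)) {
      if (rec) rec->complete_cycle(c);
      if (completions) {
        IntegerVector rs(c.rep_sweep.begin(), c.rep_sweep.end());
        IntegerMatrix log((int)c.ev_sweep.size(), 2);
        for (int e = 0; e < (int)c.ev_sweep.size(); ++e) {
          log(e, 0) = c.ev_sweep[e];
          log(e, 1) = c.ev_bin[e] + 1;  // 1-based bins for R
        }
        colnames(log) = CharacterVector::create("sweep", "bin");
        completions->push_back(List::create(
            _["cell"] = idx + 1, _["rep_sweep"] = rs, _["init_log"] = log,
            _["duration"] = (double)c.s_clock));
        if (comp_cell) comp_cell->push_back(idx + 1);
      }
      c.phase = 0;
      c.g_clock = draw_g_duration(c.rng, P);
      c.reset_genome(P);
    }
    ++idx;
  }
}

Par make_par(const NumericVector& initp, const NumericVector& pprog,
             const NumericVector& prel, int nfork, int init_rule,
             double g_mean, double g_sd) {
  Par P;
  P.nbins = initp.size();
  P.nfork = nfork;
  P.init_rule = init_rule;
  P.g_mean = g_mean;
  P.g_sd = g_sd;
  P.initp = &initp[0];
  P.pprog = &pprog[0];
  P.prel = &prel[0];
  for (double v : prel) if (v > 0) { P.any_release = true; break; }
  return P;
}

// --------------------------- R <-> C++ cell state ---------------------------

IntegerVector pack_rng(const Xoshiro& r) {
  IntegerVector v(4);
  for (int i = 0; i < 4; ++i) v[i] = (int32_t)r.s[i];
  return v;
}

void unpack_rng(Xoshiro& r, const IntegerVector& v) {
  for (int i = 0; i < 4; ++i) r.s[i] = (uint32_t)v[i];
}

List cell_to_r(const Cell& c, const Par& P) {
  LogicalVector mask(P.nbins);
  IntegerVector rep(P.nbins);
  for (int b = 0; b < P.nbins; ++b) {
    mask[b] = c.mask[b] != 0;
    rep[b] = c.mask[b] ? c.rep_sweep[b] : NA_INTEGER;
  }
  LogicalVector eng(P.nfork);
  IntegerVector pos(P.nfork), dir(P.nfork);
  for (int i = 0; i < P.nfork; ++i) {
    eng[i] = c.fk_eng[i] != 0;
    pos[i] = c.fk_eng[i] ? c.fk_pos[i] + 1 : NA_INTEGER;
    dir[i] = c.fk_eng[i] ? c.fk_dir[i] : NA_INTEGER;
  }
  IntegerMatrix log((int)c.ev_sweep.size(), 2);
  for (int e = 0; e < (int)c.ev_sweep.size(); ++e) {
    log(e, 0) = c.ev_sweep[e];
    log(e, 1) = c.ev_bin[e] + 1;
  }
  colnames(log) = CharacterVector::create("sweep", "bin");
  List out = List::create(
      _["phase"] = c.phase == 1 ? "S" : "G",
      _["phase_clock"] = (double)(c.phase == 1 ? c.s_clock : c.g_clock),
      _["mask"] = mask, _["rep_sweep"] = rep, _["fork_engaged"] = eng,
      _["fork_pos"] = pos, _["fork_dir"] = dir, _["init_log"] = log,
      _["rng_state"] = pack_rng(c.rng));
  out.attr("class") = "cell_state";
  return out;
}

Cell cell_from_r(const List& cl, const Par& P) {
  Cell c;
  c.alloc(P);
  std::string phase = as<std::string>(cl["phase"]);
  c.phase = (phase == "S") ? 1 : 0;
  double clock = as<double>(cl["phase_clock"]);
  if (c.phase == 1) c.s_clock = (long long)clock; else c.g_clock = (long long)clock;
  LogicalVector mask = cl["mask"];
  IntegerVector rep = cl["rep_sweep"];
  if ((int)mask.size() != P.nbins)
    stop("cell mask length does not match the landscape");
  for (int b = 0; b < P.nbins; ++b) {
    c.mask[b] = mask[b] ? 1 : 0;
    c.rep_sweep[b] = (mask[b] && rep[b] != NA_INTEGER) ? rep[b] : -1;
  }
  LogicalVector eng = cl["fork_engaged"];
  IntegerVector pos = cl["fork_pos"], dir = cl["fork_dir"];
  for (int i = 0; i < P.nfork; ++i) {
    c.fk_eng[i] = eng[i] ? 1 : 0;
    c.fk_pos[i] = (eng[i] && pos[i] != NA_INTEGER) ? pos[i] - 1 : -1;
    c.fk_dir[i] = (eng[i] && dir[i] != NA_INTEGER) ? dir[i] : 0;
  }
  IntegerMatrix log = cl["init_log"];
  for (int e = 0; e < log.nrow(); ++e) {
    c.ev_sweep.push_back(log(e, 0));
    c.ev_bin.push_back(log(e, 1) - 1);
    c.ev_frac.push_back(NA_REAL);
  }
  unpack_rng(c.rng, cl["rng_state"]);
  c.rebuild_unrepl(P);
  return c;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported entry points.

// [[Rcpp::export]]
IntegerVector cpp_seed_state(double seed, double stream) {
  Xoshiro r;
  r.seed((uint64_t)seed, (uint64_t)stream);
  return pack_rng(r);
}

// [[Rcpp::export]]
List cpp_new_cell(NumericVector init_prob, int nfork, double seed, double stream,
                  double g_mean, double g_sd) {
  Par P;
  P.nbins = init_prob.size();
  P.nfork = nfork;
  Cell c;
  c.alloc(P);
  c.rng.seed((uint64_t)seed, (uint64_t)stream);
  P.g_mean = g_mean;
  P.g_sd = g_sd;
  c.phase = 0;
  c.g_clock = draw_g_duration(c.rng, P);
  return cell_to_r(c, P);
}

// [[Rcpp::export]]
List cpp_cell_sweep(List cell, NumericVector init_prob, NumericVector pprog,
                    NumericVector prel, int nfork, int init_rule,
                    double g_mean, double g_sd) {
  Par P = make_par(init_prob, pprog, prel, nfork, init_rule, g_mean, g_sd);
  Cell c = cell_from_r(cell, P);
  if (c.phase != 1) stop("cell_sweep requires a cell in S phase");
  List completed = List::create();
  bool done = sweep_S(c, P);
  List last = R_NilValue;
  if (done) {
    IntegerVector rs(c.rep_sweep.begin(), c.rep_sweep.end());
    IntegerMatrix log((int)c.ev_sweep.size(), 2);
    for (int e = 0; e < (int)c.ev_sweep.size(); ++e) {
      log(e, 0) = c.ev_sweep[e];
      log(e, 1) = c.ev_bin[e] + 1;
    }
    colnames(log) = CharacterVector::create("sweep", "bin");
    last = List::create(_["rep_sweep"] = rs, _["init_log"] = log,
                        _["duration"] = (double)c.s_clock);
    c.phase = 0;
    c.g_clock = draw_g_duration(c.rng, P);
    c.reset_genome(P);
  }
  List out = cell_to_r(c, P);
  out["last_cycle"] = last;
  out.attr("class") = "cell_state";
  return out;
}

// [[Rcpp::export]]
List cpp_population_sweep(List cells, NumericVector init_prob,
                          NumericVector pprog, NumericVector prel, int nfork,
                          int init_rule, double g_mean, double g_sd,
                          int nsweeps) {
  Par P = make_par(init_prob, pprog, prel, nfork, init_rule, g_mean, g_sd);
  int n = cells.size();
  std::vector<Cell> pop;
  pop.reserve(n);
  for (int i = 0; i < n; ++i) pop.push_back(cell_from_r(cells[i], P));
  List completions = List::create();
  for (int s = 0; s < nsweeps; ++s)
    population_step(pop, P, s, nullptr, &completions, nullptr);
  List out_cells(n);
  for (int i = 0; i < n; ++i) out_cells[i] = cell_to_r(pop[i], P);
  return List::create(_["cells"] = out_cells, _["completed"] = completions);
}

// [[Rcpp::export]]
NumericVector cpp_pilot_s_durations(NumericVector init_prob, NumericVector pprog,
                                    NumericVector prel, int nfork, int init_rule,
                                    double seed, int n_pilot, double max_sweeps) {
  Par P = make_par(init_prob, pprog, prel, nfork, init_rule, 1.0, 0.0);
  NumericVector out(n_pilot);
  for (int i = 0; i < n_pilot; ++i) {
    Cell c;
    c.alloc(P);
    c.rng.seed((uint64_t)seed, 0x100000ULL + (uint64_t)i);  // pilot streams
    c.phase = 1;
    long long s = 0;
    while (!sweep_S(c, P)) {
      if (++s >= (long long)max_sweeps)
        stop("pilot S phase did not complete within %g sweeps; "
             "is the landscape nearly all-zero?", max_sweeps);
    }
    out[i] = (double)c.s_clock;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_simulation(NumericVector init_prob, NumericVector pprog,
                        NumericVector prel, int ncells, int nfork,
                        double ntherm, double nmeas, double stepsize,
                        double g_mean, double g_sd, double seed,
                        int init_rule, bool take_snapshots) {
  Par P = make_par(init_prob, pprog, prel, nfork, init_rule, g_mean, g_sd);
  long long NT = (long long)ntherm, NM = (long long)nmeas,
            SS = (long long)stepsize;

  std::vector<Cell> pop(ncells);
  for (int i = 0; i < ncells; ++i) {
    pop[i].alloc(P);
    pop[i].rng.seed((uint64_t)seed, (uint64_t)(i + 1));
    pop[i].phase = 0;
    pop[i].g_clock = draw_g_duration(pop[i].rng, P);
  }

  Recorder rec;
  rec.init(P.nbins, NT);

  long long sweep = 0;
  for (; sweep < NT; ++sweep) population_step(pop, P, sweep, &rec, nullptr, nullptr);

  // snapshot storage
  std::vector<int> sn_epoch, sn_cell, sn_phase, sn_eng, sn_time, sn_rle_id;
  std::vector<double> sn_frac;
  std::vector<int> rle_nrun;
  std::vector<uint8_t> rle_first;
  std::vector<int> rle_lengths;

  for (long long e = 0; e < NM; ++e) {
    for (long long k = 0; k < SS; ++k, ++sweep)
      population_step(pop, P, sweep, &rec, nullptr, nullptr);
    if (!take_snapshots) continue;
    for (int i = 0; i < ncells; ++i) {
      const Cell& c = pop[i];
      sn_epoch.push_back((int)(e + 1));
      sn_cell.push_back(i + 1);
      sn_phase.push_back(c.phase);
      int eng = 0;
      for (int f = 0; f < P.nfork; ++f) eng += c.fk_eng[f];
      sn_eng.push_back(eng);
      if (c.phase == 1) {
        sn_frac.push_back(1.0 - (double)c.n_unrepl / P.nbins);
        sn_time.push_back((int)c.s_clock);
        // run-length encode the replication mask
        int nrun = 0;
        uint8_t cur = c.mask[0];
        rle_first.push_back(cur);
        int len = 0;
        for (int b = 0; b < P.nbins; ++b) {
          if (c.mask[b] == cur) { ++len; continue; }
          rle_lengths.push_back(len);
          ++nrun;
          cur = c.mask[b];
          len = 1;
        }
        rle_lengths.push_back(len);
        ++nrun;
        rle_nrun.push_back(nrun);
        sn_rle_id.push_back((int)rle_nrun.size());  // 1-based
      } else {
        sn_frac.push_back(NA_REAL);
        sn_time.push_back(NA_INTEGER);
        sn_rle_id.push_back(NA_INTEGER);
      }
    }
    if (e % 64 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector ev_bin(rec.ev_bin.size());
  for (size_t i = 0; i < rec.ev_bin.size(); ++i) ev_bin[i] = rec.ev_bin[i] + 1;

  return List::create(
      _["timing_sum"] = NumericVector(rec.t_sum.begin(), rec.t_sum.end()),
      _["timing_sumsq"] = NumericVector(rec.t_sumsq.begin(), rec.t_sumsq.end()),
      _["timing_count"] = IntegerVector(rec.t_count.begin(), rec.t_count.end()),
      _["n_cycles"] = (double)rec.n_cycles,
      _["ev_sweep"] = IntegerVector(rec.ev_sweep.begin(), rec.ev_sweep.end()),
      _["ev_bin"] = ev_bin,
      _["ev_frac"] = NumericVector(rec.ev_frac.begin(), rec.ev_frac.end()),
      _["exposure"] = NumericVector(rec.expo.begin(), rec.expo.end()),
      _["sn_epoch"] = IntegerVector(sn_epoch.begin(), sn_epoch.end()),
      _["sn_cell"] = IntegerVector(sn_cell.begin(), sn_cell.end()),
      _["sn_phase"] = IntegerVector(sn_phase.begin(), sn_phase.end()),
      _["sn_frac"] = NumericVector(sn_frac.begin(), sn_frac.end()),
      _["sn_engaged"] = IntegerVector(sn_eng.begin(), sn_eng.end()),
      _["sn_time"] = IntegerVector(sn_time.begin(), sn_time.end()),
      _["sn_rle_id"] = IntegerVector(sn_rle_id.begin(), sn_rle_id.end()),
      _["rle_nrun"] = IntegerVector(rle_nrun.begin(), rle_nrun.end()),
      _["rle_first"] = LogicalVector(rle_first.begin(), rle_first.end()),
      _["rle_lengths"] = IntegerVector(rle_lengths.begin(), rle_lengths.end()));
}
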