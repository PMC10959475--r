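// Individual-based simulator core.
//
// Diploid individuals carry dominant mutations at dynamically created loci.
// Each locus has an expression trigger (an age, or a somatic stage index in
// somatic mode), an effect (lethal, or an increment d added to the per-step
// death probability), and a fecundity multiplier (pleiotropy). Per step:
// stochastic deaths (extrinsic + increment effects), deterministic lethal
// expression deaths, somatic stage advance, then density-dependent
// recruitment refilling vacancies (optionally capped). Recruits inherit one
// allele per locus per parent, may revert each inherited allele, and may
// acquire one new mutation. With no reverse mutation, fixed loci are folded
// into population-level state (lethals into the "wall", the minimum fixed
// lethal trigger) and their columns dropped, which keeps the genotype table
// small over long runs.
//
// Uses R's RNG throughout so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Loci {
  std::vector<int> id;
  std::vector<double> trig;
  std::vector<int> eff;        // 0 = lethal, 1 = mortality increment
  std::vector<double> dval;    // increment size (eff == 1)
  std::vector<double> pleio;
  std::vector<char> was_fixed; // currently at allele count 2n
  size_t size() const { return id.size(); }
  void drop(size_t l) {
    id.erase(id.begin() + l);
    trig.erase(trig.begin() + l);
    eff.erase(eff.begin() + l);
    dval.erase(dval.begin() + l);
    pleio.erase(pleio.begin() + l);
    was_fixed.erase(was_fixed.begin() + l);
  }
};

inline int transmit(int g, double rev) {
  if (g == 0) return 0;
  if (g == 1 && unif_rand() >= 0.5) return 0;
  if (rev > 0.0 && unif_rand() < rev) return 0;  // reversion at gamete formation
  return 1;
}

inline int sample_cum(const std::vector<double>& cw) {
  double u = unif_rand() * cw.back();
  return int(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
}

} // namespace

// [[Rcpp::export(name = ".ibm_steps_cpp")]]
List ibm_steps_cpp(List state, List cfg, int n_steps, int record_every) {
  // --- unpack config ---------------------------------------------------
  const int    N        = as<int>(cfg["N"]);
  const double mu_step  = as<double>(cfg["mu_step"]);
  const double dt       = as<double>(cfg["dt"]);
  const double U        = as<double>(cfg["U"]);
  const double rev      = as<double>(cfg["reverse_rate"]);
  const double F_max    = as<double>(cfg["F_max"]);
  const bool   somatic  = as<bool>(cfg["somatic_mode"]);
  const double p_adv    = as<double>(cfg["stage_advance_prob"]);
  const double grid     = as<double>(cfg["grid_step"]);
  const int    n_grid   = as<int>(cfg["n_grid"]);
  const bool   incr_onward = as<bool>(cfg["increment_onward"]);
  const double new_d    = as<double>(cfg["effect_d"]);   // 0 => lethal
  const double new_pleio = as<double>(cfg["new_pleiotropy"]);
  const bool   stop_idle = as<bool>(cfg["stop_when_idle"]);

  // --- unpack state ----------------------------------------------------
  std::vector<double> age = as<std::vector<double>>(state["age"]);
  std::vector<int> stage = as<std::vector<int>>(state["stage"]);
  List loci_in = state["loci"];
  Loci loci;
  loci.id   = as<std::vector<int>>(loci_in["id"]);
  loci.trig = as<std::vector<double>>(loci_in["trigger"]);
  loci.eff  = as<std::vector<int>>(loci_in["effect"]);
  loci.dval = as<std::vector<double>>(loci_in["d"]);
  loci.pleio = as<std::vector<double>>(loci_in["pleiotropy"]);
  loci.was_fixed = std::vector<char>(loci.size(), 0);
  {
    std::vector<int> wf = as<std::vector<int>>(loci_in["was_fixed"]);
    for (size_t l = 0; l < loci.size(); ++l) loci.was_fixed[l] = char(wf[l]);
  }
  IntegerMatrix geno_in = state["geno"];   // individuals x loci
  size_t n = age.size();
  std::vector<std::vector<int>> G(loci.size(), std::vector<int>(n, 0));
  for (size_t l = 0; l < loci.size(); ++l)
    for (size_t i = 0; i < n; ++i) G[l][i] = geno_in(i, l);

  double wall = as<double>(state["wall"]);
  std::vector<double> fx_tr = as<std::vector<double>>(state["folded_incr_trigger"]);
  std::vector<double> fx_d  = as<std::vector<double>>(state["folded_incr_d"]);
  int time = as<int>(state["time"]);
  int next_id = as<int>(state["next_locus_id"]);
  bool extinct = as<bool>(state["extinct"]);
  int n_lost = as<int>(state["n_lost"]);

  // fixation event log and records grow as we go
  std::vector<int> fe_id, fe_eff; std::vector<double> fe_time, fe_trig;
  std::vector<double> rec_t, rec_census, rec_nseg, rec_wall, rec_meanw;
  int extinction_time = NA_INTEGER;

  auto wall_now = [&]() -> double {
    double w = wall;
    for (size_t l = 0; l < loci.size(); ++l)
      if (loci.eff[l] == 0 && loci.was_fixed[l] && loci.trig[l] < w)
        w = loci.trig[l];
    return w;
  };
  auto record = [&]() {
    size_t nseg = 0;
    for (size_t l = 0; l < loci.size(); ++l) if (!loci.was_fixed[l]) ++nseg;
    double mw = 1.0, tot = 0.0;
    if (n > 0) {
      for (size_t i = 0; i < n; ++i) {
        double w = 1.0;
        for (size_t l = 0; l < loci.size(); ++l)
          if (G[l][i] > 0) w *= loci.pleio[l];
        tot += w;
      }
      mw = tot / double(n);
    }
    rec_t.push_back(time * dt);
    rec_census.push_back(double(n));
    rec_nseg.push_back(double(nseg));
    rec_wall.push_back(wall_now());
    rec_meanw.push_back(mw);
  };

  record();  // state on entry

  for (int step = 0; step < n_steps; ++step) {
    if (extinct) break;

    // (1) stochastic deaths: extrinsic + mortality-increment expression
    std::vector<char> dead(n, 0);
    for (size_t i = 0; i < n; ++i) {
      double p = mu_step;
      double attained = somatic ? double(stage[i]) : age[i];
      for (size_t l = 0; l < loci.size(); ++l) {
        if (loci.eff[l] != 1 || G[l][i] == 0) continue;
        bool on = incr_onward
          ? attained >= loci.trig[l]
          : (attained >= loci.trig[l] &&
             attained - (somatic ? 1.0 : dt) < loci.trig[l]);
        if (on) p += loci.dval[l];
      }
      for (size_t f = 0; f < fx_tr.size(); ++f) {
        bool on = incr_onward
          ? attained >= fx_tr[f]
          : (attained >= fx_tr[f] &&
             attained - (somatic ? 1.0 : dt) < fx_tr[f]);
        if (on) p += fx_d[f];
      }
      if (p > 1.0) p = 1.0;
      if (unif_rand() < p) dead[i] = 1;
    }

    // (2) deterministic lethal expression deaths (dominant)
    for (size_t i = 0; i < n; ++i) {
      if (dead[i]) continue;
      double attained = somatic ? double(stage[i]) : age[i];
      if (attained >= wall) { dead[i] = 1; continue; }
      for (size_t l = 0; l < loci.size(); ++l) {
        if (loci.eff[l] == 0 && G[l][i] > 0 && attained >= loci.trig[l]) {
          dead[i] = 1; break;
        }
      }
    }

    // compact survivors
    {
      size_t k = 0;
      for (size_t i = 0; i < n; ++i) {
        if (!dead[i]) {
          age[k] = age[i]; stage[k] = stage[i];
          for (size_t l = 0; l < loci.size(); ++l) G[l][k] = G[l][i];
          ++k;
        }
      }
      n = k;
      age.resize(n); stage.resize(n);
      for (size_t l = 0; l < loci.size(); ++l) G[l].resize(n);
    }

    if (n < 2) {  // extinction: too few individuals to mate
      extinct = true;
      extinction_time = time + 1;
      time += 1;
      record();
      break;
    }

    // (3) somatic stage advance
    if (somatic && p_adv > 0.0)
      for (size_t i = 0; i < n; ++i)
        if (p_adv >= 1.0 || unif_rand() < p_adv) stage[i] += 1;

    // (4) recruitment refills vacancies, possibly capped
    int vac = N - int(n);
    int nrec = vac > 0 ? vac : 0;
    if (R_finite(F_max)) {
      double cap = F_max * double(n) * dt;
      int capn = int(std::floor(cap));
      if (unif_rand() < cap - capn) ++capn;     // stochastic rounding
      if (capn < nrec) nrec = capn;
    }

    bool weighted = false;
    for (size_t l = 0; l < loci.size(); ++l)
      if (loci.pleio[l] != 1.0) { weighted = true; break; }
    std::vector<double> cw;
    if (weighted && nrec > 0) {
      cw.resize(n);
      double acc = 0.0;
      for (size_t i = 0; i < n; ++i) {
        double w = 1.0;
        for (size_t l = 0; l < loci.size(); ++l)
          if (G[l][i] > 0) w *= loci.pleio[l];
        acc += w;
        cw[i] = acc;
      }
    }

    size_t n_parents = n;
    std::vector<std::pair<int, int>> new_owner_trig;  // recruit idx, locus idx
    for (int r = 0; r < nrec; ++r) {
      int p1, p2;
      if (weighted) {
        p1 = sample_cum(cw);
        do { p2 = sample_cum(cw); } while (p2 == p1);
      } else {
        p1 = int(unif_rand() * n_parents); if (p1 >= int(n_parents)) p1 = n_parents - 1;
        do {
          p2 = int(unif_rand() * n_parents); if (p2 >= int(n_parents)) p2 = n_parents - 1;
        } while (p2 == p1);
      }
      age.push_back(0.0);
      stage.push_back(0);
      size_t me = age.size() - 1;
      for (size_t l = 0; l < loci.size(); ++l) {
        int a = transmit(G[l][p1], rev) + transmit(G[l][p2], rev);
        G[l].push_back(a);
      }
      if (U > 0.0 && unif_rand() < U) {
        int j = 1 + int(unif_rand() * n_grid); if (j > n_grid) j = n_grid;
        loci.id.push_back(next_id);
        loci.trig.push_back(grid * j);
        loci.eff.push_back(new_d > 0.0 ? 1 : 0);
        loci.dval.push_back(new_d);
        loci.pleio.push_back(new_pleio);
        loci.was_fixed.push_back(0);
        G.push_back(std::vector<int>(me, 0));   // filled below for recruits so far
        G.back().resize(me + 1, 0);
        G.back()[me] = 1;
        new_owner_trig.push_back(std::make_pair(int(me), int(loci.size() - 1)));
        ++next_id;
      }
    }
    n = age.size();
    for (size_t l = 0; l < loci.size(); ++l) G[l].resize(n, 0);
    for (size_t q = 0; q < new_owner_trig.size(); ++q)
      G[new_owner_trig[q].second][new_owner_trig[q].first] = 1;

    // (5) bookkeeping: losses, fixations, folding
    for (size_t l = loci.size(); l-- > 0; ) {
      long cnt = 0;
      for (size_t i = 0; i < n; ++i) cnt += G[l][i];
      if (cnt == 0) {
        loci.drop(l);
        G.erase(G.begin() + l);
        ++n_lost;
      } else if (cnt == 2L * long(n)) {
        if (!loci.was_fixed[l]) {
          fe_id.push_back(loci.id[l]);
          fe_time.push_back((time + 1) * dt);
          fe_trig.push_back(loci.trig[l]);
          fe_eff.push_back(loci.eff[l]);
          loci.was_fixed[l] = 1;
        }
        if (rev <= 0.0) {  // fold irreversibly fixed loci into population state
          if (loci.eff[l] == 0) {
            if (loci.trig[l] < wall) wall = loci.trig[l];
          } else {
            fx_tr.push_back(loci.trig[l]);
            fx_d.push_back(loci.dval[l]);
          }
          loci.drop(l);
          G.erase(G.begin() + l);
        }
      } else {
        loci.was_fixed[l] = 0;  // reversal can re-segregate a fixed locus
      }
    }

    // (6) aging
    for (size_t i = 0; i < n; ++i) age[i] += dt;
    time += 1;

    if (record_every > 0 && time % record_every == 0) record();

    if (stop_idle && U <= 0.0 && loci.size() == 0) break;
  }

  if (rec_t.empty() || rec_t.back() != time * dt) record();

  // --- repack ----------------------------------------------------------
  IntegerMatrix geno_out(int(n), int(loci.size()));
  for (size_t l = 0; l < loci.size(); ++l)
    for (size_t i = 0; i < n; ++i) geno_out(int(i), int(l)) = G[l][i];
  std::vector<int> wf_out(loci.size());
  for (size_t l = 0; l < loci.size(); ++l) wf_out[l] = int(loci.was_fixed[l]);

  List loci_out = List::create(
    _["id"] = wrap(loci.id), _["trigger"] = wrap(loci.trig),
    _["effect"] = wrap(loci.eff), _["d"] = wrap(loci.dval),
    _["pleiotropy"] = wrap(loci.pleio), _["was_fixed"] = wrap(wf_out));

  List rec = List::create(
    _["time"] = wrap(rec_t), _["census"] = wrap(rec_census),
    _["segregating"] = wrap(rec_nseg), _["max_age_at_death"] = wrap(rec_wall),
    _["mean_fecundity_weight"] = wrap(rec_meanw));

  List fix = List::create(
    _["id"] = wrap(fe_id), _["time"] = wrap(fe_time),
    _["trigger"] = wrap(fe_trig), _["effect"] = wrap(fe_eff));

  return List::create(
    _["age"] = wrap(age), _["stage"] = wrap(stage), _["geno"] = geno_out,
    _["loci"] = loci_out, _["wall"] = wall,
    _["folded_incr_trigger"] = wrap(fx_tr), _["folded_incr_d"] = wrap(fx_d),
    _["time"] = time, _["next_locus_id"] = next_id,
    _["extinct"] = extinct, _["extinction_time"] = extinction_time,
    _["n_lost"] = n_lost, _["records"] = rec, _["fixations"] = fix);
}
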