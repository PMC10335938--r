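#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete-time loop-extrusion kernel on a 1D lattice.
//
// Bins are 0-based here; R wrappers convert from/to 1-based indices.
// All randomness goes through R's RNG (unif_rand / R::rpois), so a single
// set.seed() in R makes any sequence of calls bit-reproducible.
//
// Step order (applied once per step):
//   1. loading:   Poisson(load_rate*dt) new extruders, positions ~ loading weights
//   2. movement:  each non-stalled anchor moves v bins outward; an occupied CBS
//                 whose blocking face opposes the travel direction halts the
//                 anchor at the CBS bin with probability p_stall
//   3. bypass:    each stalled anchor un-stalls with probability p_bypass
//   4. unloading: each extruder removed with probability unload_prob
//
// Orientation: blockdir = -1 blocks anchors moving toward decreasing bins
// (sites oriented toward T-DOM); blockdir = +1 blocks anchors moving toward
// increasing bins (sites oriented toward C-DOM).

struct Ext {
  int l, r;
  bool ls, rs;
  double birth;
};

static int sample_cum(const std::vector<double>& cum, double total) {
  // inverse-CDF sample on cumulative weights
  double u = unif_rand() * total;
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] >= u) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// [[Rcpp::export(name = ".ht_run_steps")]]
List ht_run_steps(List state, int n_steps, List params,
                  IntegerVector bar_bin, IntegerVector bar_dir,
                  NumericVector load_w,
                  IntegerVector gene_lo, IntegerVector gene_hi,
                  IntegerVector maint_lo, IntegerVector maint_hi,
                  LogicalVector enh_mask, int enh_first,
                  bool log_events) {
  const double dt = as<double>(params["dt"]);
  const int v = as<int>(params["v"]);
  const double load_rate = as<double>(params["load_rate"]);
  const double unload_prob = as<double>(params["unload_prob"]);
  const double stall_unload_factor = params.containsElementNamed("stall_unload_factor") ?
    as<double>(params["stall_unload_factor"]) : 1.0;
  const double p_stall = as<double>(params["p_stall"]);
  const double p_bypass = as<double>(params["p_bypass"]);
  const int n_bins = as<int>(params["n_bins"]);
  const int max_ext = as<int>(params["max_extruders"]);

  IntegerVector l0 = state["left"], r0 = state["right"];
  LogicalVector ls0 = state["left_stalled"], rs0 = state["right_stalled"];
  NumericVector b0 = state["birth"];
  double time = as<double>(state["time"]);

  std::vector<Ext> ex;
  ex.reserve(std::max((int)l0.size() * 2, 64));
  for (int i = 0; i < l0.size(); ++i)
    ex.push_back(Ext{l0[i], r0[i], (bool)ls0[i], (bool)rs0[i], b0[i]});

  const int nb = bar_bin.size();
  const int ng = gene_lo.size();

  // cumulative loading weights
  std::vector<double> cum(load_w.size());
  double total_w = 0.0;
  for (int i = 0; i < load_w.size(); ++i) { total_w += load_w[i]; cum[i] = total_w; }

  std::vector<double> haz(ng, 0.0), maint(ng, 0.0);
  std::vector<double> ev_time; std::vector<int> ev_kind, ev_pos;

  for (int step = 0; step < n_steps; ++step) {
    // 1. loading
    int n_new = (int)R::rpois(load_rate * dt);
    if (total_w > 0.0) {
      for (int k = 0; k < n_new; ++k) {
        if ((int)ex.size() >= max_ext) break;
        int bin = sample_cum(cum, total_w);
        ex.push_back(Ext{bin, bin, false, false, time});
        if (log_events) { ev_time.push_back(time); ev_kind.push_back(1); ev_pos.push_back(bin); }
      }
    }

    // 2. movement
    for (size_t i = 0; i < ex.size(); ++i) {
      Ext& e = ex[i];
      if (!e.ls) { // left anchor, direction -1
        int target = e.l - v;
        if (target < 0) target = 0;
        int pos = e.l;
        // barriers with blockdir -1 in [target, pos-1], nearest (largest bin) first
        for (int j = nb - 1; j >= 0; --j) {
          if (bar_bin[j] >= pos) continue;
          if (bar_bin[j] < target) break;
          if (bar_dir[j] != -1) continue;
          if (unif_rand() < p_stall) {
            pos = bar_bin[j]; e.ls = true;
            if (log_events) { ev_time.push_back(time); ev_kind.push_back(3); ev_pos.push_back(pos); }
            break;
          }
        }
        if (!e.ls) pos = target;
        e.l = pos;
      }
      if (!e.rs) { // right anchor, direction +1
        int target = e.r + v;
        if (target > n_bins - 1) target = n_bins - 1;
        int pos = e.r;
        for (int j = 0; j < nb; ++j) {
          if (bar_bin[j] <= pos) continue;
          if (bar_bin[j] > target) break;
          if (bar_dir[j] != 1) continue;
          if (unif_rand() < p_stall) {
            pos = bar_bin[j]; e.rs = true;
            if (log_events) { ev_time.push_back(time); ev_kind.push_back(3); ev_pos.push_back(pos); }
            break;
          }
        }
        if (!e.rs) pos = target;
        e.r = pos;
      }
    }

    // 3. bypass
    for (size_t i = 0; i < ex.size(); ++i) {
      Ext& e = ex[i];
      if (e.ls && unif_rand() < p_bypass) {
        e.ls = false;
        if (log_events) { ev_time.push_back(time); ev_kind.push_back(4); ev_pos.push_back(e.l); }
      }
      if (e.rs && unif_rand() < p_bypass) {
        e.rs = false;
        if (log_events) { ev_time.push_back(time); ev_kind.push_back(4); ev_pos.push_back(e.r); }
      }
    }

    // 4. unloading; CTCF-anchored (stalled) extruders are stabilized
    {
      size_t keep = 0;
      for (size_t i = 0; i < ex.size(); ++i) {
        double pu = (ex[i].ls || ex[i].rs) ? unload_prob * stall_unload_factor
                                           : unload_prob;
        if (unif_rand() < pu) {
          if (log_events) { ev_time.push_back(time); ev_kind.push_back(2); ev_pos.push_back(ex[i].l); }
        } else {
          ex[keep++] = ex[i];
        }
      }
      ex.resize(keep);
    }

    time += dt;

    // per-step gene-enhancer contact tallies:
    //  - coverage (activation): the extruded loop contains both the whole
    //    gene body and the first enhancer element, i.e. the gene has fallen
    //    into the positive loop domain shared with the enhancers
    //  - bridging (maintenance): left anchor parked in the gene's anchoring
    //    zone while the right anchor sits in an enhancer bin
    if (ng > 0) {
      for (size_t i = 0; i < ex.size(); ++i) {
        const Ext& e = ex[i];
        if (e.r >= enh_first) {
          for (int g = 0; g < ng; ++g)
            if (e.l <= gene_lo[g]) haz[g] += 1.0;
        }
        if (e.r >= 0 && e.r < (int)enh_mask.size() && enh_mask[e.r]) {
          for (int g = 0; g < ng; ++g)
            if (e.l >= maint_lo[g] && e.l <= maint_hi[g]) maint[g] += 1.0;
        }
      }
    }
  }

  int n = (int)ex.size();
  IntegerVector l(n), r(n);
  LogicalVector ls(n), rs(n);
  NumericVector b(n);
  for (int i = 0; i < n; ++i) {
    l[i] = ex[i].l; r[i] = ex[i].r; ls[i] = ex[i].ls; rs[i] = ex[i].rs; b[i] = ex[i].birth;
  }

  return List::create(
    _["left"] = l, _["right"] = r,
    _["left_stalled"] = ls, _["right_stalled"] = rs,
    _["birth"] = b, _["time"] = time,
    _["haz_contact"] = NumericVector(haz.begin(), haz.end()),
    _["maint_contact"] = NumericVector(maint.begin(), maint.end()),
    _["ev_time"] = NumericVector(ev_time.begin(), ev_time.end()),
    _["ev_kind"] = IntegerVector(ev_kind.begin(), ev_kind.end()),
    _["ev_pos"] = IntegerVector(ev_pos.begin(), ev_pos.end()));
}
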