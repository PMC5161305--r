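// Discrete-time simulation engine for the virtual lobule.
//
// One call advances a single Monte Carlo lobule variant through `horizon`
// one-second steps. Semantics mirror the single-cell reference operations
// in R/cascade.R and the reference percolation step in R/transport.R; this
// compiled path exists because a 14,000-agent, 86,400-step experiment is
// far outside what an interpreted loop can do.
//
// All randomness comes from R's RNG (unif_rand / R::rbinom / R::rnorm), so
// results are fully reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Per-object Bernoulli semantics, implemented as a binomial draw on the
// count (distributionally identical); small counts loop cheap uniforms.
static inline int rbinom_int(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  if (n < 48) {
    int k = 0;
    for (int i = 0; i < n; ++i)
      if (unif_rand() < p) ++k;
    return k;
  }
  return (int) R::rbinom((double) n, p);
}

// [[Rcpp::export]]
List cpp_sim_run(IntegerVector seg_zone, IntegerVector seg_len,
                 IntegerVector seg_col_off, IntegerVector out_off,
                 IntegerVector out_idx, IntegerVector entr_seg,
                 NumericVector entr_w, IntegerVector cell_col,
                 IntegerVector cell_band, NumericVector cell_dist,
                 NumericVector cp_met, NumericVector cp_nap,
                 NumericVector c_thr, NumericVector cp_mit, List cfg,
                 int horizon, int poll, bool perfusion, double input_rate,
                 bool toxicity, bool audit) {
  const int nseg = seg_zone.size();
  const int ncell = cell_col.size();
  const int ncol = seg_col_off[nseg];  // col offsets have nseg+1 entries

  const double p_gshdep = as<double>(cfg["p_gsh_depletion"]);
  const double p_react = as<double>(cfg["p_react"]);
  const double p_split = as<double>(cfg["p_mitod_split"]);
  const int amp_lo = as<int>(cfg["amp_lo"]);
  const int amp_hi = as<int>(cfg["amp_hi"]);
  const double p_nonmd = as<double>(cfg["p_nonmd_mitigation"]);
  const int trig_thr = as<int>(cfg["death_trigger_threshold"]);
  const int delay_type = as<int>(cfg["delay_type"]);  // 0 unif, 1 normal
  const double delay_a = as<double>(cfg["delay_a"]);  // seconds
  const double delay_b = as<double>(cfg["delay_b"]);
  const double k_abs = as<double>(cfg["k_abs"]);
  const double hep_frac = as<double>(cfg["hepatic_fraction"]);
  const double p_fwd = as<double>(cfg["p_fwd"]);
  const double p_bind = as<double>(cfg["p_bind"]);
  const double p_release = as<double>(cfg["p_release"]);
  const double p_uptake = as<double>(cfg["p_uptake"]);
  const double p_cexit = as<double>(cfg["p_cell_exit"]);

  long depot = as<double>(cfg["depot0"]);
  long body = as<double>(cfg["body0"]);
  long marker_depot = as<double>(cfg["marker_depot0"]);
  long marker_body = as<double>(cfg["marker_body0"]);
  long body_gs = 0;

  const long apap_total0 = depot + body;
  const long marker_total = marker_depot + marker_body;

  // ---- column state --------------------------------------------------
  std::vector<int> freeC(ncol, 0), boundC(ncol, 0), markC(ncol, 0);
  long cv_apap = 0, cv_marker = 0;
  long injected = 0, outflow_cum = 0;

  // per-column hepatocyte lists (alive prefix + index of each cell)
  std::vector<std::vector<int>> colCells(ncol);
  for (int i = 0; i < ncell; ++i) colCells[cell_col[i]].push_back(i);
  std::vector<int> colAlive(ncol, 0), cellPos(ncell, 0);
  for (int c = 0; c < ncol; ++c) {
    colAlive[c] = (int) colCells[c].size();
    for (size_t k = 0; k < colCells[c].size(); ++k)
      cellPos[colCells[c][k]] = (int) k;
  }

  // ---- cell state ----------------------------------------------------
  std::vector<int> apap(ncell, 0), napqi(ncell, 0), unamp(ncell, 0),
      amp(ncell, 0), nonmd(ncell, 0), gshev(ncell, 0), cgs(ncell, 0),
      cmit(ncell, 0);
  std::vector<char> trig(ncell, 0), dead(ncell, 0), inAct(ncell, 0);
  std::vector<double> trig_t(ncell, -1.0), death_t(ncell, -1.0);
  std::vector<int> active;
  active.reserve(ncell);

  long cum_napqi = 0, cum_gs = 0, cum_depl = 0, cum_mit_mitod = 0,
       cum_mit_nonmd = 0, n_trig = 0, n_dead = 0;

  // deaths bucketed by second (delays can run past the horizon; those
  // cells stay scheduled but are not processed within this run)
  std::vector<std::vector<int>> deathAt(horizon + 1);

  // segment processing order: descending zone, then descending id, so an
  // object moves at most one column per step
  std::vector<int> procOrder(nseg);
  for (int j = 0; j < nseg; ++j) procOrder[j] = nseg - 1 - j;

  // ---- recording -----------------------------------------------------
  const int npoll = horizon / poll + 1;
  NumericMatrix bodyM(npoll, 13);
  const int nbm = 5;  // napqi, gs, depletion, mitod, mitigation
  NumericMatrix bandM(npoll, 3 * nbm);
  NumericVector trig_sum(horizon + 1), trig_cnt(horizon + 1);
  NumericVector outflow(perfusion ? horizon + 1 : 1);
  int prow = 0;

  double entr_w_tot = 0;
  for (int e = 0; e < entr_seg.size(); ++e) entr_w_tot += entr_w[e];

  auto inject = [&](long n, std::vector<int> &col) {
    double wleft = entr_w_tot;
    long left = n;
    for (int e = 0; e < entr_seg.size() && left > 0; ++e) {
      int k = (e == entr_seg.size() - 1)
                  ? (int) left
                  : rbinom_int((int) left, entr_w[e] / wleft);
      col[seg_col_off[entr_seg[e]]] += k;
      left -= k;
      wleft -= entr_w[e];
    }
  };

  auto record = [&](int t) {
    long lf = 0, lb = 0, lm = 0;
    for (int c = 0; c < ncol; ++c) {
      lf += freeC[c];
      lb += boundC[c];
      lm += markC[c];
    }
    long ca = 0;
    for (int i = 0; i < ncell; ++i) ca += apap[i];
    bodyM(prow, 0) = t;
    bodyM(prow, 1) = depot;
    bodyM(prow, 2) = body;
    bodyM(prow, 3) = body_gs;
    bodyM(prow, 4) = marker_depot;
    bodyM(prow, 5) = marker_body;
    bodyM(prow, 6) = lf + lb;
    bodyM(prow, 7) = ca;
    bodyM(prow, 8) = lm;
    bodyM(prow, 9) = cum_napqi;
    bodyM(prow, 10) = cum_gs;
    bodyM(prow, 11) = n_trig;
    bodyM(prow, 12) = n_dead;
    for (int i = 0; i < ncell; ++i) {
      int b = cell_band[i];
      if (b > 0) {
        int r = (b - 1) * nbm;
        bandM(prow, r + 0) += napqi[i];
        bandM(prow, r + 1) += cgs[i];
        bandM(prow, r + 2) += gshev[i];
        bandM(prow, r + 3) += amp[i] + unamp[i];
        bandM(prow, r + 4) += cmit[i];
      }
    }
    if (audit) {
      long sys = depot + body + lf + lb + ca + cum_napqi + cum_gs +
                 cv_apap + (perfusion ? outflow_cum : 0);
      long expect = perfusion ? injected : apap_total0;
      if (sys != expect)
        stop("APAP mass balance violated at t=%d: system %ld vs dose %ld",
             t, sys, expect);
      long msys = marker_depot + marker_body + lm + cv_marker;
      if (msys != marker_total)
        stop("marker mass balance violated at t=%d", t);
    }
    ++prow;
  };

  GetRNGstate();
  record(0);

  std::vector<int> dying;
  int order[5] = {0, 1, 2, 3, 4};

  for (int t = 1; t <= horizon; ++t) {
    // -- dosing / absorption / hepatic delivery ------------------------
    if (perfusion) {
      long n = (long) input_rate;
      if (unif_rand() < input_rate - (double) n) ++n;
      injected += n;
      inject(n, freeC);
    } else {
      int a = rbinom_int((int) depot, k_abs);
      depot -= a;
      body += a;
      int am = rbinom_int((int) marker_depot, k_abs);
      marker_depot -= am;
      marker_body += am;
      int m = rbinom_int((int) body, hep_frac);
      body -= m;
      inject(m, freeC);
      int mm = rbinom_int((int) marker_body, hep_frac);
      marker_body -= mm;
      inject(mm, markC);
    }

    // -- percolation ---------------------------------------------------
    for (int oi = 0; oi < nseg; ++oi) {
      int j = procOrder[oi];
      int off = seg_col_off[j], L = seg_len[j];
      bool z3 = seg_zone[j] == 3;
      int no = out_off[j + 1] - out_off[j];
      for (int ci = L - 1; ci >= 0; --ci) {
        int c = off + ci;
        int rel = rbinom_int(boundC[c], p_release);
        boundC[c] -= rel;
        int f = freeC[c] + rel;
        if (f > 0) {
          freeC[c] = 0;
          int stay = 0;
          double pu = colAlive[c] > 0 ? p_uptake : 0.0;
          double pb_cut = pu + (1.0 - pu) * p_bind;
          for (int k = 0; k < f; ++k) {
            double u = unif_rand();
            if (u < pu) {
              int pick = (int) (unif_rand() * colAlive[c]);
              if (pick >= colAlive[c]) pick = colAlive[c] - 1;
              int i = colCells[c][pick];
              ++apap[i];
              if (!inAct[i]) {
                inAct[i] = 1;
                active.push_back(i);
              }
            } else if (u < pb_cut) {
              ++boundC[c];
            } else if (unif_rand() < p_fwd) {
              if (ci < L - 1) {
                ++freeC[c + 1];
              } else if (z3 || no == 0) {
                ++cv_apap;
              } else {
                int o = (int) (unif_rand() * no);
                if (o >= no) o = no - 1;
                ++freeC[seg_col_off[out_idx[out_off[j] + o]]];
              }
            } else {
              ++stay;
            }
          }
          freeC[c] += stay;
        }
        int mk = markC[c];
        if (mk > 0) {
          markC[c] = 0;
          int mstay = 0;
          for (int k = 0; k < mk; ++k) {
            if (unif_rand() < p_fwd) {
              if (ci < L - 1) {
                ++markC[c + 1];
              } else if (z3 || no == 0) {
                ++cv_marker;
              } else {
                int o = (int) (unif_rand() * no);
                if (o >= no) o = no - 1;
                ++markC[seg_col_off[out_idx[out_off[j] + o]]];
              }
            } else {
              ++mstay;
            }
          }
          markC[c] += mstay;
        }
      }
    }

    // -- central-vein return -------------------------------------------
    if (perfusion) {
      outflow[t] = cv_apap;
      outflow_cum += cv_apap;
      cv_apap = 0;
      cv_marker = 0;
    } else {
      body += cv_apap;
      marker_body += cv_marker;
      cv_apap = 0;
      cv_marker = 0;
    }

    // -- intra-hepatocyte cascade (shared per-step shuffled order) -----
    for (int k = 4; k > 0; --k) {
      int r = (int) (unif_rand() * (k + 1));
      if (r > k) r = k;
      int tmp = order[k];
      order[k] = order[r];
      order[r] = tmp;
    }
    size_t na = active.size();
    for (size_t ai = 0; ai < na;) {
      int i = active[ai];
      if (dead[i]) {  // died earlier this run; drop from the list
        inAct[i] = 0;
        active[ai] = active[na - 1];
        active[na - 1] = i;
        active.pop_back();
        --na;
        continue;
      }
      for (int s = 0; s < 5; ++s) {
        switch (order[s]) {
        case 0: {  // metabolism (+ cell exit of unmetabolized APAP)
          int n = apap[i];
          if (n == 0) break;
          if (trig[i]) {  // triggered cells stop metabolizing
            int ex = rbinom_int(n, p_cexit);
            apap[i] -= ex;
            freeC[cell_col[i]] += ex;
            break;
          }
          double pm = cp_met[i], pn = cp_nap[i];
          int met = 0, nap = 0, ex = 0;
          for (int k = 0; k < n; ++k) {
            if (unif_rand() < pm) {
              ++met;
              if (unif_rand() < pn) ++nap;
            } else if (unif_rand() < p_cexit) {
              ++ex;
            }
          }
          apap[i] -= met + ex;
          freeC[cell_col[i]] += ex;
          napqi[i] += nap;
          cum_napqi += nap;
          int gs = met - nap;
          cgs[i] += gs;
          cum_gs += gs;
          body_gs += gs;
          break;
        }
        case 1: {  // NAPQI fate
          if (!toxicity || napqi[i] == 0) break;
          if ((double) gshev[i] < c_thr[i]) {
            int d = rbinom_int(napqi[i], p_gshdep);
            napqi[i] -= d;
            gshev[i] += d;
            cum_depl += d;
          } else {
            int r = rbinom_int(napqi[i], p_react);
            if (r > 0) {
              napqi[i] -= r;
              int md = rbinom_int(r, p_split);
              unamp[i] += md;
              nonmd[i] += r - md;
            }
          }
          break;
        }
        case 2: {  // amplification (once per mitoD)
          if (!toxicity) break;
          int u = unamp[i];
          if (u == 0) break;
          int add = 0;
          int span = amp_hi - amp_lo + 1;
          for (int k = 0; k < u; ++k) {
            int n = amp_lo + (int) (unif_rand() * span);
            if (n > amp_hi) n = amp_hi;
            add += n;
          }
          amp[i] += u + add;
          unamp[i] = 0;
          break;
        }
        case 3: {  // mitigation
          if (!toxicity) break;
          double p = cp_mit[i];
          int dm = rbinom_int(amp[i], p);
          int du = rbinom_int(unamp[i], p);
          int dn = rbinom_int(nonmd[i], p_nonmd);
          amp[i] -= dm;
          unamp[i] -= du;
          nonmd[i] -= dn;
          cum_mit_mitod += dm + du;
          cmit[i] += dm + du;
          cum_mit_nonmd += dn;
          break;
        }
        case 4: {  // death trigger
          if (!toxicity || trig[i]) break;
          if (amp[i] + unamp[i] >= trig_thr) {
            trig[i] = 1;
            trig_t[i] = t;
            double delay =
                delay_type == 0
                    ? delay_a + unif_rand() * (delay_b - delay_a)
                    : std::max(0.0, norm_rand() * delay_b + delay_a);
            death_t[i] = t + delay;
            int dsec = (int) death_t[i];
            if (dsec <= horizon) deathAt[dsec].push_back(i);
            trig_sum[t] += cell_dist[i];
            trig_cnt[t] += 1;
            ++n_trig;
          }
          break;
        }
        }
      }
      if (apap[i] + napqi[i] + unamp[i] + amp[i] + nonmd[i] == 0) {
        inAct[i] = 0;
        active[ai] = active[na - 1];
        active[na - 1] = i;
        active.pop_back();
        --na;
      } else {
        ++ai;
      }
    }

    // -- deaths scheduled for this second ------------------------------
    for (int i : deathAt[t]) {
      if (dead[i]) continue;
      dead[i] = 1;
      ++n_dead;
      // necrotic cell releases unmetabolized APAP back to the sinusoid
      freeC[cell_col[i]] += apap[i];
      apap[i] = 0;
      napqi[i] = 0;
      unamp[i] = 0;
      amp[i] = 0;
      nonmd[i] = 0;
      // remove from its column's alive prefix
      int c = cell_col[i];
      int pos = cellPos[i], last = colAlive[c] - 1;
      int j = colCells[c][last];
      colCells[c][pos] = j;
      colCells[c][last] = i;
      cellPos[j] = pos;
      cellPos[i] = last;
      --colAlive[c];
    }
    deathAt[t].clear();

    if (t % poll == 0) record(t);
  }
  PutRNGstate();

  return List::create(
      _["body"] = bodyM, _["bands"] = bandM, _["trig_sum"] = trig_sum,
      _["trig_cnt"] = trig_cnt, _["outflow"] = outflow,
      _["trigger_time"] = NumericVector(trig_t.begin(), trig_t.end()),
      _["death_time"] = NumericVector(death_t.begin(), death_t.end()),
      _["dead"] = IntegerVector(dead.begin(), dead.end()),
      _["gshev"] = IntegerVector(gshev.begin(), gshev.end()),
      _["final_apap"] = IntegerVector(apap.begin(), apap.end()),
      _["totals"] = NumericVector::create(
          _["cum_napqi"] = cum_napqi, _["cum_gs"] = cum_gs,
          _["cum_depletion"] = cum_depl,
          _["cum_mitigation_mitod"] = cum_mit_mitod,
          _["cum_mitigation_nonmd"] = cum_mit_nonmd,
          _["injected"] = injected, _["outflow_total"] = outflow_cum,
          _["n_triggered"] = n_trig, _["n_dead"] = n_dead));
}
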