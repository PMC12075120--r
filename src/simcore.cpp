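// Time-stepped integration of the column: LIF membranes, AMPA/NMDA/GABA
// gating, per-neuron Poisson background, stimulus epochs, online STDP.
//
// Update order within one step [t, t+dt) (mirrored exactly by the R
// reference stepper used in the tests):
//   1. decay gating, accumulators and plasticity traces (exact exponentials);
//      NMDA saturation cross-term by forward Euler, weighted deltas pushed to
//      the per-postsynaptic NMDA accumulator
//   2. background Bernoulli draws (prob rate*dt) increment external gating
//   3. synaptic currents from start-of-step V and post-decay gating
//   4. exponential-Euler membrane update (non-refractory, non-inactivated)
//   5. threshold crossings spike at t+dt, reset to V_rest, start refractory
//   6. plastic weight updates from traces as they were before this step's
//      spikes are added (symmetric same-bin treatment, F(0) contributes 0)
//   7. trace increments for the spiking neurons
//   8. spike delivery: AMPA/GABA accumulators += weight, NMDA x += 1
// Gating is stored per presynaptic neuron; weights enter at delivery
// (AMPA/GABA) or via the incrementally maintained weighted NMDA sums.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clipw(double w, double lo, double hi) {
  return w < lo ? lo : (w > hi ? hi : w);
}

// Argument layout (flat vectors; the R wrapper builds them):
//  - bkg_prob: per-neuron Bernoulli probability per step (rate * dt)
//  - syn_*: synapses in CSR order by presynaptic neuron, 0-based ids;
//    syn_rec codes 0 = AMPA, 1 = NMDA, 2 = GABA
//  - nmda_ptr/nmda_idx: the NMDA subset, CSR by presynaptic neuron,
//    indices into the syn arrays
//  - pl_*: plastic E->E logical connections with their AMPA/NMDA synapse
//    slots (-1 if absent) and CSR adjacency by pre and by post
//  - ipl_*: plastic PV->E GABA synapses (indices into syn arrays)
//  - gaba_pre_reversal: false = GABA reverses at the postsynaptic V_rest
//    (V_I), true = at the presynaptic V_rest (second weighted accumulator)
//  - ep_*: stimulus epochs with CSR target lists
//  - inact_from: per-neuron inactivation time (Inf = never)
//
// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(
    int n,
    NumericVector C_m, NumericVector g_L, NumericVector tau_ref,
    NumericVector V_rest, NumericVector V_th, NumericVector V_I,
    LogicalVector is_exc,
    NumericVector bkg_prob,
    IntegerVector syn_ptr, IntegerVector syn_post, IntegerVector syn_rec,
    NumericVector syn_w_in,
    IntegerVector nmda_ptr, IntegerVector nmda_idx,
    IntegerVector pl_pre, IntegerVector pl_post, NumericVector pl_w_in,
    IntegerVector pl_ampa, IntegerVector pl_nmda,
    IntegerVector pl_by_pre_ptr, IntegerVector pl_by_pre,
    IntegerVector pl_by_post_ptr, IntegerVector pl_by_post,
    IntegerVector ipl_pre, IntegerVector ipl_post, IntegerVector ipl_syn,
    IntegerVector ipl_by_pre_ptr, IntegerVector ipl_by_pre,
    IntegerVector ipl_by_post_ptr, IntegerVector ipl_by_post,
    List consts, List stdp, List inh_stdp,
    bool stdp_on, bool inh_stdp_on,
    bool gaba_pre_reversal,
    NumericVector ep_on, NumericVector ep_off, NumericVector ep_amp,
    IntegerVector ep_ptr, IntegerVector ep_targets,
    NumericVector inact_from,
    double dt, double duration,
    IntegerVector rec_ids, double rec_every,
    NumericVector snap_times) {

  const double tau_AMPA = consts["tau_AMPA"], tau_GABA = consts["tau_GABA"];
  const double tau_Nd = consts["tau_NMDA_decay"], tau_Nr = consts["tau_NMDA_rise"];
  const double alpha = consts["alpha"], Mg = consts["Mg"];
  const double V_E = consts["V_E"];
  const double gA = consts["g_AMPA"], gN = consts["g_NMDA"], gG = consts["g_GABA"];
  const double w_ext = consts["w_ext"];

  const double A_plus = stdp["A_plus"], A_minus = stdp["A_minus"];
  const double tauP = stdp["tau_plus"], tauM = stdp["tau_minus"];
  const double w_min = stdp["w_min"], w_max = stdp["w_max"];
  const double B_plus = inh_stdp["B_plus"], B_minus = inh_stdp["B_minus"];
  const double itauP = inh_stdp["tau_plus"], itauM = inh_stdp["tau_minus"];
  const double iw_min = inh_stdp["w_min"], iw_max = inh_stdp["w_max"];

  const double dA = std::exp(-dt / tau_AMPA);
  const double dG = std::exp(-dt / tau_GABA);
  const double dNd = std::exp(-dt / tau_Nd);
  const double dNr = std::exp(-dt / tau_Nr);
  const double dP = std::exp(-dt / tauP), dM = std::exp(-dt / tauM);
  const double dIP = std::exp(-dt / itauP), dIM = std::exp(-dt / itauM);

  NumericVector syn_w = clone(syn_w_in);
  NumericVector pl_w = clone(pl_w_in);

  std::vector<double> V(n), mem_decay(n), refr_until(n, -1e300);
  std::vector<double> s_ext(n, 0.0), a_ampa(n, 0.0), a_gaba(n, 0.0),
      b_gaba(n, 0.0), a_nmda(n, 0.0), s_nmda(n, 0.0), x_nmda(n, 0.0);
  std::vector<double> tr_p(n, 0.0), tr_m(n, 0.0), tr_ip(n, 0.0), tr_im(n, 0.0);
  std::vector<double> I_ext(n, 0.0);
  for (int i = 0; i < n; ++i) {
    V[i] = V_rest[i];
    mem_decay[i] = std::exp(-dt * g_L[i] / C_m[i]);
  }

  const int n_steps = (int)std::lround(duration / dt);
  const int n_ep = ep_on.size();
  std::vector<char> ep_active(n_ep, 0);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 16);
  spike_t.reserve(1 << 16);
  std::vector<int> spiking;
  spiking.reserve(256);

  const int n_rec = rec_ids.size();
  int rec_stride = n_rec > 0 ? std::max(1, (int)std::lround(rec_every / dt)) : 0;
  int n_rec_rows = n_rec > 0 ? n_steps / rec_stride : 0;
  NumericMatrix V_rec(n_rec_rows, n_rec);
  NumericVector V_rec_t(n_rec_rows);
  int rec_row = 0;

  const int n_snap = snap_times.size();
  List snaps(n_snap);   // plastic logical weights at each checkpoint
  int snap_i = 0;

  GetRNGstate();
  double t = 0.0;
  for (int step = 0; step < n_steps; ++step) {
    const double t_next = t + dt;

    // 1. decay
    for (int i = 0; i < n; ++i) {
      s_ext[i] *= dA;
      a_ampa[i] *= dA;
      a_gaba[i] *= dG;
      b_gaba[i] *= dG;
      a_nmda[i] *= dNd;
      tr_p[i] *= dP; tr_m[i] *= dM;
      tr_ip[i] *= dIP; tr_im[i] *= dIM;
    }
    // NMDA saturation term: s <- s*dNd + alpha*dt*x*(1-s); the pure-decay
    // part was already applied to the weighted sums above, so only the rise
    // term is pushed to the accumulators
    // The accumulators already received the global decay factor; only the
    // rise term alpha*dt*x*(1-s) needs scattering to the targets. x dies
    // ~46 ms after a spike (tau 2 ms, cut at 1e-10, truncation error below
    // alpha*tau_rise*1e-10 in s), so silent presynaptic neurons cost nothing.
    for (int j = 0; j < n; ++j) {
      if (!is_exc[j]) continue;
      double x = x_nmda[j];
      if (x <= 1e-10) {
        x_nmda[j] = 0.0;
        s_nmda[j] *= dNd;
        continue;
      }
      double s = s_nmda[j];
      double rise = alpha * dt * x * (1.0 - s);
      s_nmda[j] = s * dNd + rise;
      x_nmda[j] = x * dNr;
      if (rise != 0.0) {
        for (int k = nmda_ptr[j]; k < nmda_ptr[j + 1]; ++k) {
          int si = nmda_idx[k];
          a_nmda[syn_post[si]] += syn_w[si] * rise;
        }
      }
    }

    // 2. background input
    for (int i = 0; i < n; ++i) {
      if (bkg_prob[i] > 0.0 && unif_rand() < bkg_prob[i]) s_ext[i] += 1.0;
    }

    // 9. (re)apply stimulus epochs active during [t, t+dt)
    for (int e = 0; e < n_ep; ++e) {
      char act = (t >= ep_on[e] && t < ep_off[e]) ? 1 : 0;
      if (act != ep_active[e]) {
        double d = act ? ep_amp[e] : -ep_amp[e];
        for (int k = ep_ptr[e]; k < ep_ptr[e + 1]; ++k) I_ext[ep_targets[k]] += d;
        ep_active[e] = act;
      }
    }

    // 3-5. currents, membrane update, spikes
    spiking.clear();
    for (int i = 0; i < n; ++i) {
      if (t_next >= inact_from[i]) { V[i] = V_rest[i]; continue; }
      if (t < refr_until[i]) { V[i] = V_rest[i]; continue; }
      double f_nmda = 1.0 / (1.0 + Mg * std::exp(-0.062 * V[i]) / 3.57);
      double I_gaba = gaba_pre_reversal
        ? gG * (V[i] * a_gaba[i] - b_gaba[i])
        : gG * (V[i] - V_I[i]) * a_gaba[i];
      double I = I_ext[i]
        - gA * (V[i] - V_E) * (w_ext * s_ext[i] + a_ampa[i])
        - gN * (V[i] - V_E) * f_nmda * a_nmda[i]
        - I_gaba;
      double V_inf = V_rest[i] + I / g_L[i];
      double v = V_inf + (V[i] - V_inf) * mem_decay[i];
      if (!std::isfinite(v)) {
        PutRNGstate();
        stop("integration fault: non-finite membrane potential for neuron %d at t = %g ms",
             i + 1, t_next);
      }
      if (v >= V_th[i]) {
        spiking.push_back(i);
        spike_id.push_back(i + 1);
        spike_t.push_back(t_next);
        V[i] = V_rest[i];
        refr_until[i] = t_next + tau_ref[i];
      } else {
        V[i] = v;
      }
    }

    // 6. plasticity from pre-increment traces
    if (stdp_on) {
      for (size_t si = 0; si < spiking.size(); ++si) {
        int i = spiking[si];
        // i as presynaptic: depression by earlier postsynaptic spikes
        for (int k = pl_by_pre_ptr[i]; k < pl_by_pre_ptr[i + 1]; ++k) {
          int c = pl_by_pre[k];
          double w_old = pl_w[c];
          double w_new = clipw(w_old - A_minus * tr_m[pl_post[c]], w_min, w_max);
          if (w_new != w_old) {
            pl_w[c] = w_new;
            if (pl_ampa[c] >= 0) syn_w[pl_ampa[c]] = w_new;
            if (pl_nmda[c] >= 0) {
              syn_w[pl_nmda[c]] = w_new;
              a_nmda[pl_post[c]] += (w_new - w_old) * s_nmda[pl_pre[c]];
            }
          }
        }
        // i as postsynaptic: potentiation by earlier presynaptic spikes
        for (int k = pl_by_post_ptr[i]; k < pl_by_post_ptr[i + 1]; ++k) {
          int c = pl_by_post[k];
          double w_old = pl_w[c];
          double w_new = clipw(w_old + A_plus * tr_p[pl_pre[c]], w_min, w_max);
          if (w_new != w_old) {
            pl_w[c] = w_new;
            if (pl_ampa[c] >= 0) syn_w[pl_ampa[c]] = w_new;
            if (pl_nmda[c] >= 0) {
              syn_w[pl_nmda[c]] = w_new;
              a_nmda[pl_post[c]] += (w_new - w_old) * s_nmda[pl_pre[c]];
            }
          }
        }
      }
    }
    if (inh_stdp_on) {
      for (size_t si = 0; si < spiking.size(); ++si) {
        int i = spiking[si];
        for (int k = ipl_by_pre_ptr[i]; k < ipl_by_pre_ptr[i + 1]; ++k) {
          int c = ipl_by_pre[k];
          int other = ipl_post[c];
          double w_new = clipw(syn_w[ipl_syn[c]] + B_plus * tr_ip[other]
                               - B_minus * tr_im[other], iw_min, iw_max);
          syn_w[ipl_syn[c]] = w_new;
        }
        for (int k = ipl_by_post_ptr[i]; k < ipl_by_post_ptr[i + 1]; ++k) {
          int c = ipl_by_post[k];
          int other = ipl_pre[c];
          double w_new = clipw(syn_w[ipl_syn[c]] + B_plus * tr_ip[other]
                               - B_minus * tr_im[other], iw_min, iw_max);
          syn_w[ipl_syn[c]] = w_new;
        }
      }
    }

    // 7. trace increments
    for (size_t si = 0; si < spiking.size(); ++si) {
      int i = spiking[si];
      tr_p[i] += 1.0; tr_m[i] += 1.0; tr_ip[i] += 1.0; tr_im[i] += 1.0;
    }

    // 8. spike delivery
    for (size_t si = 0; si < spiking.size(); ++si) {
      int j = spiking[si];
      if (is_exc[j]) x_nmda[j] += 1.0;
      for (int k = syn_ptr[j]; k < syn_ptr[j + 1]; ++k) {
        int r = syn_rec[k];
        if (r == 0) a_ampa[syn_post[k]] += syn_w[k];
        else if (r == 2) {
          a_gaba[syn_post[k]] += syn_w[k];
          if (gaba_pre_reversal) b_gaba[syn_post[k]] += syn_w[k] * V_rest[j];
        }
        // NMDA handled through x/s dynamics
      }
    }

    // 10. recording
    if (n_rec > 0 && (step + 1) % rec_stride == 0 && rec_row < n_rec_rows) {
      for (int k = 0; k < n_rec; ++k) V_rec(rec_row, k) = V[rec_ids[k]];
      V_rec_t[rec_row] = t_next;
      ++rec_row;
    }
    while (snap_i < n_snap && t_next >= snap_times[snap_i] - 1e-9) {
      snaps[snap_i] = clone(pl_w);
      ++snap_i;
    }

    t = t_next;
  }
  PutRNGstate();

  return List::create(
    _["spike_neuron"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["spike_time"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["V_rec"] = V_rec, _["V_rec_time"] = V_rec_t,
    _["syn_w"] = syn_w, _["plastic_w"] = pl_w,
    _["snapshots"] = snaps, _["snapshot_times"] = snap_times);
}
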