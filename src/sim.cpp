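#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Mg-block sigmoid of the NMDA conductance (Jahr-Stevens form, [Mg] = 1 mM)
static inline double mg_block(double v, double mg_fac, double mg_gamma) {
  return 1.0 / (1.0 + mg_fac * std::exp(-mg_gamma * v));
}

// Spiking network of H hidden neurons, each with D dendritic compartments
// star-coupled to a leaky integrate-and-fire soma, plus a single-compartment
// output neuron. Feedforward synapses are current-based at the somata;
// context synapses are conductance-based (AMPA + NMDA with Mg block) on the
// dendritic compartments. Units: ms, mV, nS, pF, pA.
// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(List par,
                     NumericMatrix Wff,        // H x n_ff
                     NumericVector ff_t, IntegerVector ff_ch,
                     NumericVector ctx_t, IntegerVector ctx_ch,
                     IntegerVector syn_neuron, IntegerVector syn_comp,
                     IntegerVector syn_ch, NumericVector syn_w,
                     NumericVector w_out,
                     double duration, double dt, double record_dt,
                     bool record_dend,
                     double clamp_v, bool clamped) {
  const int H = Wff.nrow();
  const int D = as<int>(par["n_comp"]);
  const int n_ctx_ch = as<int>(par["n_ctx_channels"]);

  const double C_s = par["c_m_soma"], gL_s = par["g_l_soma"];
  const double E_L = par["e_l"], V_th = par["v_th"], V_re = par["v_reset"];
  const double t_ref = par["t_ref"];
  const double C_d = par["c_m_dend"], gL_d = par["g_l_dend"], g_c = par["g_c"];
  const double tau_ff = par["tau_ff"];
  const double tau_a = par["tau_ampa"], ampa_ratio = par["ampa_ratio"];
  const double tau_r = par["tau_nmda_rise"], tau_dc = par["tau_nmda_decay"];
  const double mg_fac = par["mg_fac"], mg_gamma = par["mg_gamma"];
  const double e_syn = par["e_syn"];
  const double g_extra = par["g_extra_soma"], e_extra = par["e_extra_soma"];
  const double C_o = par["c_m_out"], gL_o = par["g_l_out"];
  const double V_th_o = par["v_th_out"], V_re_o = par["v_reset_out"];
  const double t_ref_o = par["t_ref_out"], tau_out = par["tau_out"];
  const double tau_pre = par["tau_pre"], tau_post = par["tau_post"];
  const double tau_v = par["tau_v"];

  // normalize the NMDA double-exponential to unit peak per unit weight
  double tpk = std::log(tau_dc / tau_r) * tau_dc * tau_r / (tau_dc - tau_r);
  double peak = std::exp(-tpk / tau_dc) - std::exp(-tpk / tau_r);

  const int n_steps = (int)std::ceil(duration / dt);
  const int rec_every = std::max(1, (int)std::round(record_dt / dt));
  const int n_rec = n_steps / rec_every + 1;

  const double d_ff = std::exp(-dt / tau_ff);
  const double d_a = std::exp(-dt / tau_a);
  const double d_r = std::exp(-dt / tau_r);
  const double d_dc = std::exp(-dt / tau_dc);
  const double d_out = std::exp(-dt / tau_out);
  const double d_pre = std::exp(-dt / tau_pre);
  const double d_post = std::exp(-dt / tau_post);

  std::vector<double> Vs(H, E_L), Iff(H, 0.0), refr(H, -1.0);
  std::vector<double> Vd(H * D, E_L), ga(H * D, 0.0),
      gn_a(H * D, 0.0), gn_r(H * D, 0.0), vtr(H * D, 0.0);
  std::vector<double> pre_tr(n_ctx_ch, 0.0), post_tr(H, 0.0);
  double Vo = E_L, Io = 0.0, refr_o = -1.0;

  // per-channel synapse index lists for event delivery
  std::vector< std::vector<int> > ch_syn(n_ctx_ch);
  for (int s = 0; s < syn_ch.size(); ++s) {
    int c = syn_ch[s] - 1;
    if (c < 0 || c >= n_ctx_ch) stop("context channel out of range");
    ch_syn[c].push_back(s);
  }

  std::vector<double> hid_spk_t; std::vector<int> hid_spk_n;
  std::vector<double> out_spk_t;
  NumericMatrix V_soma_rec(n_rec, H);
  NumericVector V_out_rec(n_rec), I_clamp_rec(n_rec), t_rec(n_rec);
  NumericMatrix V_dend_rec(record_dend ? n_rec : 1,
                           record_dend ? H * D : 1);

  if (clamped) for (int h = 0; h < H; ++h) Vs[h] = clamp_v;

  int i_ff = 0, i_ctx = 0, i_rec = 0;
  auto record = [&](double t) {
    t_rec[i_rec] = t;
    for (int h = 0; h < H; ++h) V_soma_rec(i_rec, h) = Vs[h];
    V_out_rec[i_rec] = Vo;
    if (record_dend)
      for (int k = 0; k < H * D; ++k) V_dend_rec(i_rec, k) = Vd[k];
    if (clamped) {
      double ic = gL_s * (Vs[0] - E_L) + g_extra * (Vs[0] - e_extra) - Iff[0];
      for (int d = 0; d < D; ++d) ic += g_c * (Vs[0] - Vd[d]);
      I_clamp_rec[i_rec] = ic;
    }
    ++i_rec;
  };
  record(0.0);

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt, t_next = t + dt;

    // synaptic state decay
    for (int h = 0; h < H; ++h) Iff[h] *= d_ff;
    for (int k = 0; k < H * D; ++k) {
      ga[k] *= d_a; gn_a[k] *= d_dc; gn_r[k] *= d_r;
    }
    Io *= d_out;
    for (int c = 0; c < n_ctx_ch; ++c) pre_tr[c] *= d_pre;
    for (int h = 0; h < H; ++h) post_tr[h] *= d_post;

    // deliver events falling in (t, t + dt]
    while (i_ff < ff_t.size() && ff_t[i_ff] <= t_next) {
      if (ff_t[i_ff] > t - 1e-12) {
        int c = ff_ch[i_ff] - 1;
        for (int h = 0; h < H; ++h) Iff[h] += Wff(h, c);
      }
      ++i_ff;
    }
    while (i_ctx < ctx_t.size() && ctx_t[i_ctx] <= t_next) {
      if (ctx_t[i_ctx] > t - 1e-12) {
        int c = ctx_ch[i_ctx] - 1;
        pre_tr[c] += 1.0;
        for (size_t j = 0; j < ch_syn[c].size(); ++j) {
          int s = ch_syn[c][j];
          int k = (syn_neuron[s] - 1) * D + (syn_comp[s] - 1);
          double w = syn_w[s];
          gn_a[k] += w / peak; gn_r[k] += w / peak;
          ga[k] += w * ampa_ratio;
        }
      }
      ++i_ctx;
    }

    // dendritic compartments (exponential Euler, conductances frozen in step)
    for (int h = 0; h < H; ++h) {
      for (int d = 0; d < D; ++d) {
        int k = h * D + d;
        double gn = (gn_a[k] - gn_r[k]) * mg_block(Vd[k], mg_fac, mg_gamma);
        if (gn < 0) gn = 0;
        double gsyn = ga[k] + gn;
        double gtot = gL_d + g_c + gsyn;
        double vinf = (gL_d * E_L + g_c * Vs[h] + gsyn * e_syn) / gtot;
        Vd[k] = vinf + (Vd[k] - vinf) * std::exp(-dt * gtot / C_d);
        vtr[k] += dt * ((Vd[k] - E_L) - vtr[k]) / tau_v;
      }
    }

    // somata
    for (int h = 0; h < H; ++h) {
      if (clamped) { Vs[h] = clamp_v; continue; }
      if (t_next < refr[h]) { Vs[h] = V_re; continue; }
      double gtot = gL_s + g_extra + D * g_c;
      double num = gL_s * E_L + g_extra * e_extra + Iff[h];
      for (int d = 0; d < D; ++d) num += g_c * Vd[h * D + d];
      double vinf = num / gtot;
      Vs[h] = vinf + (Vs[h] - vinf) * std::exp(-dt * gtot / C_s);
      if (Vs[h] >= V_th) {
        hid_spk_t.push_back(t_next); hid_spk_n.push_back(h + 1);
        post_tr[h] += 1.0;
        Io += w_out[h];
        Vs[h] = V_re; refr[h] = t_next + t_ref;
      }
    }

    // output neuron
    if (!clamped) {
      if (t_next < refr_o) {
        Vo = V_re_o;
      } else {
        double gtot = gL_o;
        double vinf = (gL_o * E_L + Io) / gtot;
        Vo = vinf + (Vo - vinf) * std::exp(-dt * gtot / C_o);
        if (Vo >= V_th_o) {
          out_spk_t.push_back(t_next);
          Vo = V_re_o; refr_o = t_next + t_ref_o;
        }
      }
    }

    if ((step + 1) % rec_every == 0 && i_rec < n_rec) record(t_next);
  }

  NumericMatrix vtrace(H, D);
  for (int h = 0; h < H; ++h)
    for (int d = 0; d < D; ++d) vtrace(h, d) = vtr[h * D + d];

  return List::create(
    _["hidden_spike_t"] = wrap(hid_spk_t),
    _["hidden_spike_neuron"] = wrap(hid_spk_n),
    _["output_spike_t"] = wrap(out_spk_t),
    _["t"] = t_rec,
    _["v_soma"] = V_soma_rec,
    _["v_out"] = V_out_rec,
    _["v_dend"] = V_dend_rec,
    _["i_clamp"] = I_clamp_rec,
    _["pre_trace"] = wrap(pre_tr),
    _["post_trace"] = wrap(post_tr),
    _["v_dend_trace"] = vtrace);
}
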