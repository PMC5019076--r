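#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Izhikevich lattice state for one nucleus.  Neuron index i is column-major
// over an n x n grid (row = i % n, col = i / n), matching R's matrix layout.
struct Lattice {
  int N;
  double a, b, c, d, vpeak;
  std::vector<double> v, u;
  std::vector<int> spk, spk_prev;

  Lattice(int N_, List p) : N(N_) {
    a = as<double>(p["a"]);
    b = as<double>(p["b"]);
    c = as<double>(p["c"]);
    d = as<double>(p["d"]);
    vpeak = as<double>(p["v_peak"]);
    v.assign(N, c);
    u.assign(N, b * c);
    spk.assign(N, 0);
    spk_prev.assign(N, 0);
  }

  // Forward-Euler update from the previous state; spike -> reset applied
  // after the update (v <- c, u <- u + d).
  void step(const std::vector<double>& I, double dt, const char* name,
            int stepno) {
    for (int i = 0; i < N; ++i) {
      const double vo = v[i], uo = u[i];
      double vn = vo + dt * (0.04 * vo * vo + 5.0 * vo + 140.0 - uo + I[i]);
      double un = uo + dt * a * (b * vo - uo);
      if (!std::isfinite(vn) || !std::isfinite(un))
        stop("numerical divergence in %s at step %d (neuron %d)", name,
             stepno, i + 1);
      int s = 0;
      if (vn >= vpeak) {
        s = 1;
        vn = c;
        un += d;
      }
      v[i] = vn;
      u[i] = un;
      spk[i] = s;
    }
  }
};

static inline void decay(std::vector<double>& tr, double f) {
  for (size_t i = 0; i < tr.size(); ++i) tr[i] *= f;
}

// Run one simulated trial (or a fixed number of open-loop steps when the
// race is disabled).  All stochastic draws use R's RNG so runs are
// reproducible under set.seed().
// [[Rcpp::export]]
List cpp_run_trial(List core, NumericVector rates,
                   Nullable<IntegerMatrix> msn_d1_,
                   Nullable<IntegerMatrix> msn_d2_, List collect) {
  const int n = as<int>(core["n"]);
  const int N = n * n;
  const double dt = as<double>(core["dt"]);

  Lattice stn(N, core["stn"]), gpe(N, core["gpe"]), gpi(N, core["gpi"]);

  const IntegerVector half_v = core["half"];
  const int* half = INTEGER(half_v);  // 1 or 2 per neuron
  const double w_sg = as<double>(core["w_sg"]);
  const double w_gs = as<double>(core["w_gs"]);
  const double w_strd1 = as<double>(core["w_strd1"]);
  const double w_strd2 = as<double>(core["w_strd2"]);
  const double w_stn_gpi = as<double>(core["w_stn_gpi"]);
  const double w_lat_stn = as<double>(core["w_lat_stn"]);
  const double w_lat_gpe = as<double>(core["w_lat_gpe"]);
  const double dec_glut = as<double>(core["dec_glut"]);
  const double dec_gaba = as<double>(core["dec_gaba"]);
  const double bg_stn = as<double>(core["bg_stn"]);
  const double bg_gpe = as<double>(core["bg_gpe"]);
  const double bg_gpi = as<double>(core["bg_gpi"]);
  const double bg_jitter = as<double>(core["bg_jitter"]);

  const IntegerVector nb_s_ptr_v = core["nb_s_ptr"],
      nb_s_idx_v = core["nb_s_idx"];
  const IntegerVector nb_g_ptr_v = core["nb_g_ptr"],
      nb_g_idx_v = core["nb_g_idx"];
  // convergent STN -> GPi projection disc (includes the aligned neuron)
  const IntegerVector nb_gi_ptr_v = core["nb_gi_ptr"],
      nb_gi_idx_v = core["nb_gi_idx"];
  const int* nb_s_ptr = INTEGER(nb_s_ptr_v);
  const int* nb_s_idx = INTEGER(nb_s_idx_v);
  const int* nb_g_ptr = INTEGER(nb_g_ptr_v);
  const int* nb_g_idx = INTEGER(nb_g_idx_v);
  const int* nb_gi_ptr = INTEGER(nb_gi_ptr_v);
  const int* nb_gi_idx = INTEGER(nb_gi_idx_v);

  const bool dbs_on = as<bool>(core["dbs_on"]);
  NumericVector dbs_stn_v(N), dbs_gpe_v(N);
  double dbs_period = 1.0;
  if (dbs_on) {
    dbs_stn_v = as<NumericVector>(core["dbs_stn"]);
    dbs_gpe_v = as<NumericVector>(core["dbs_gpe"]);
    dbs_period = as<double>(core["dbs_period_ms"]);
  }
  const double* dbs_stn = REAL(dbs_stn_v);
  const double* dbs_gpe = REAL(dbs_gpe_v);

  const bool race_enabled = as<bool>(core["race_enabled"]);
  const double threshold = as<double>(core["threshold"]);
  const double tau_race = as<double>(core["tau_race_ms"]);
  const int max_steps = as<int>(core["max_steps"]);

  // Poisson probabilities per step for the D1/D2 MSN fields, by half.
  const double p_d1[2] = { rates[0] * dt / 1000.0, rates[1] * dt / 1000.0 };
  const double p_d2[2] = { rates[2] * dt / 1000.0, rates[3] * dt / 1000.0 };

  const bool scripted = msn_d1_.isNotNull();
  IntegerMatrix msn_d1, msn_d2;
  if (scripted) {
    msn_d1 = msn_d1_.get();
    msn_d2 = msn_d2_.get();
    if (msn_d1.ncol() != N || msn_d2.ncol() != N)
      stop("scripted MSN fields must have one column per neuron");
    if (msn_d1.nrow() < max_steps || msn_d2.nrow() < max_steps)
      stop("scripted MSN fields shorter than the simulation horizon");
  }

  const bool col_rasters = as<bool>(collect["rasters"]);
  const bool col_stn_pop = as<bool>(collect["stn_pop"]);
  const bool col_gpi_half = as<bool>(collect["gpi_half_steps"]);
  const bool col_vtrace = as<bool>(collect["vtrace"]);
  const bool col_ztrace = as<bool>(collect["ztrace"]);

  IntegerMatrix ras_stn, ras_gpe, ras_gpi, gpi_half_steps;
  NumericMatrix vtrace, ztrace;
  if (col_rasters) {
    ras_stn = IntegerMatrix(max_steps, N);
    ras_gpe = IntegerMatrix(max_steps, N);
    ras_gpi = IntegerMatrix(max_steps, N);
  }
  IntegerVector stn_pop(col_stn_pop ? max_steps : 0);
  if (col_gpi_half) gpi_half_steps = IntegerMatrix(max_steps, 2);
  if (col_vtrace) vtrace = NumericMatrix(max_steps, 3);
  if (col_ztrace) ztrace = NumericMatrix(max_steps, 2);

  // Per-neuron baseline currents.  Tonic drive is heterogeneous across the
  // population (uniform jitter around the nominal value), redrawn at each
  // trial onset; this sustains firing-rate diversity in the lattices and
  // is a source of trial-to-trial variability in the decision.
  std::vector<double> bgv_stn(N, bg_stn), bgv_gpe(N, bg_gpe),
      bgv_gpi(N, bg_gpi);
  if (bg_jitter > 0.0) {
    for (int i = 0; i < N; ++i)
      bgv_stn[i] = bg_stn * (1.0 + bg_jitter * (2.0 * unif_rand() - 1.0));
    for (int i = 0; i < N; ++i)
      bgv_gpe[i] = bg_gpe * (1.0 + bg_jitter * (2.0 * unif_rand() - 1.0));
    for (int i = 0; i < N; ++i)
      bgv_gpi[i] = bg_gpi * (1.0 + bg_jitter * (2.0 * unif_rand() - 1.0));
  }

  // Synaptic traces (pA), one per afferent class.
  std::vector<double> stn_gaba(N, 0.0), stn_lat(N, 0.0);
  std::vector<double> gpe_glut(N, 0.0), gpe_d2(N, 0.0), gpe_lat(N, 0.0);
  std::vector<double> gpi_glut(N, 0.0), gpi_d1(N, 0.0);
  std::vector<double> I_stn(N), I_gpe(N), I_gpi(N);
  std::vector<int> d1_spk(N, 0), d2_spk(N, 0);

  // Race bookkeeping: cumulative GPi spike counts.
  std::vector<double> gpi_cum(N, 0.0);
  double cum_half[2] = { 0.0, 0.0 };
  double cum_max = 0.0;
  int n_half[2] = { 0, 0 };
  for (int i = 0; i < N; ++i) n_half[half[i] - 1]++;

  double z1 = 0.0, z2 = 0.0;
  int choice = NA_INTEGER;
  double rt = NA_REAL;
  bool censored = false;
  long tot_stn = 0, tot_gpe = 0, tot_gpi = 0;

  int last_pulse_bin = -1;
  int step = 0;
  for (; step < max_steps; ++step) {
    const double t0 = step * dt;  // time at the start of this step

    // DBS pulse gating: one integration step per pulse of the 130 Hz train.
    bool pulse = false;
    if (dbs_on) {
      int bin = (int)std::floor(t0 / dbs_period + 1e-9);
      if (bin != last_pulse_bin) {
        pulse = true;
        last_pulse_bin = bin;
      }
    }

    // Striatal MSN spike fields for this step.
    if (scripted) {
      for (int i = 0; i < N; ++i) d1_spk[i] = msn_d1(step, i);
      for (int i = 0; i < N; ++i) d2_spk[i] = msn_d2(step, i);
    } else {
      for (int i = 0; i < N; ++i)
        d1_spk[i] = (unif_rand() < p_d1[half[i] - 1]) ? 1 : 0;
      for (int i = 0; i < N; ++i)
        d2_spk[i] = (unif_rand() < p_d2[half[i] - 1]) ? 1 : 0;
    }

    // Exponential decay of all traces.
    decay(stn_gaba, dec_gaba);
    decay(stn_lat, dec_glut);
    decay(gpe_glut, dec_glut);
    decay(gpe_d2, dec_gaba);
    decay(gpe_lat, dec_gaba);
    decay(gpi_glut, dec_glut);
    decay(gpi_d1, dec_gaba);

    // Striatal input lands on the current step.
    for (int i = 0; i < N; ++i) {
      if (d1_spk[i]) gpi_d1[i] += w_strd1;
      if (d2_spk[i]) gpe_d2[i] += w_strd2;
    }
    // Spikes from the previous step propagate through the network.
    for (int i = 0; i < N; ++i) {
      if (stn.spk_prev[i]) {
        gpe_glut[i] += w_sg;       // STN -> GPe, one-to-one
        for (int k = nb_gi_ptr[i]; k < nb_gi_ptr[i + 1]; ++k)
          gpi_glut[nb_gi_idx[k]] += w_stn_gpi;  // STN -> GPi, convergent
        for (int k = nb_s_ptr[i]; k < nb_s_ptr[i + 1]; ++k)
          stn_lat[nb_s_idx[k]] += w_lat_stn;  // lateral within STN
      }
      if (gpe.spk_prev[i]) {
        stn_gaba[i] += w_gs;       // GPe -> STN, one-to-one
        for (int k = nb_g_ptr[i]; k < nb_g_ptr[i + 1]; ++k)
          gpe_lat[nb_g_idx[k]] += w_lat_gpe;  // lateral within GPe
      }
    }

    // Total currents (inhibitory classes enter with negative sign).
    for (int i = 0; i < N; ++i) {
      I_stn[i] = bgv_stn[i] + stn_lat[i] - stn_gaba[i];
      I_gpe[i] = bgv_gpe[i] + gpe_glut[i] - gpe_d2[i] - gpe_lat[i];
      I_gpi[i] = bgv_gpi[i] + gpi_glut[i] - gpi_d1[i];
      if (pulse) {
        I_stn[i] += dbs_stn[i];
        I_gpe[i] += dbs_gpe[i];
      }
    }

    stn.step(I_stn, dt, "STN", step + 1);
    gpe.step(I_gpe, dt, "GPe", step + 1);
    gpi.step(I_gpi, dt, "GPi", step + 1);

    int stn_ct = 0;
    for (int i = 0; i < N; ++i) {
      stn_ct += stn.spk[i];
      tot_gpe += gpe.spk[i];
      if (gpi.spk[i]) {
        ++tot_gpi;
        gpi_cum[i] += 1.0;
        cum_half[half[i] - 1] += 1.0;
        if (gpi_cum[i] > cum_max) cum_max = gpi_cum[i];
      }
    }
    tot_stn += stn_ct;

    if (col_rasters) {
      for (int i = 0; i < N; ++i) {
        ras_stn(step, i) = stn.spk[i];
        ras_gpe(step, i) = gpe.spk[i];
        ras_gpi(step, i) = gpi.spk[i];
      }
    }
    if (col_stn_pop) stn_pop[step] = stn_ct;
    if (col_gpi_half) {
      gpi_half_steps(step, 0) = (int)0;  // filled below as per-step counts
      int h1 = 0, h2 = 0;
      for (int i = 0; i < N; ++i)
        if (gpi.spk[i]) (half[i] == 1 ? h1 : h2)++;
      gpi_half_steps(step, 0) = h1;
      gpi_half_steps(step, 1) = h2;
    }
    if (col_vtrace) {
      vtrace(step, 0) = stn.v[0];
      vtrace(step, 1) = gpe.v[0];
      vtrace(step, 2) = gpi.v[0];
    }

    stn.spk_prev = stn.spk;
    gpe.spk_prev = gpe.spk;
    gpi.spk_prev = gpi.spk;

    if (race_enabled) {
      // Normalized, reversed GPi drive from cumulative counts; the elapsed
      // time cancels between the half mean and the per-neuron maximum.
      double f1 = 0.0, f2 = 0.0;
      if (cum_max > 0.0) {
        f1 = 1.0 - (cum_half[0] / n_half[0]) / cum_max;
        f2 = 1.0 - (cum_half[1] / n_half[1]) / cum_max;
      }
      const double k = dt / tau_race;
      const double z1n = z1 + k * (-z1 + f1 - z2);
      const double z2n = z2 + k * (-z2 + f2 - z1);
      z1 = z1n < 0.0 ? 0.0 : z1n;
      z2 = z2n < 0.0 ? 0.0 : z2n;
      if (col_ztrace) {
        ztrace(step, 0) = z1;
        ztrace(step, 1) = z2;
      }
      const bool c1 = z1 >= threshold, c2 = z2 >= threshold;
      if (c1 || c2) {
        if (c1 && c2)
          choice = (unif_rand() < 0.5) ? 1 : 2;  // simultaneous: fair coin
        else
          choice = c1 ? 1 : 2;
        rt = (step + 1) * dt;
        ++step;
        break;
      }
    }
  }

  if (race_enabled && choice == NA_INTEGER) {
    censored = true;
    rt = max_steps * dt;
    if (z1 > z2)
      choice = 1;
    else if (z2 > z1)
      choice = 2;
    else
      choice = (unif_rand() < 0.5) ? 1 : 2;
  }

  List out = List::create(
      _["choice"] = choice, _["rt_ms"] = rt, _["censored"] = censored,
      _["steps"] = step,
      _["spikes"] = List::create(_["stn"] = (double)tot_stn,
                                 _["gpe"] = (double)tot_gpe,
                                 _["gpi"] = (double)tot_gpi),
      _["gpi_half_cum"] = NumericVector::create(cum_half[0], cum_half[1]),
      _["gpi_cum_max"] = cum_max,
      _["z"] = NumericVector::create(z1, z2));
  if (col_rasters) {
    out["stn_raster"] = ras_stn;
    out["gpe_raster"] = ras_gpe;
    out["gpi_raster"] = ras_gpi;
  }
  if (col_stn_pop) out["stn_pop"] = stn_pop;
  if (col_gpi_half) out["gpi_half_steps"] = gpi_half_steps;
  if (col_vtrace) out["vtrace"] = vtrace;
  if (col_ztrace) out["ztrace"] = ztrace;
  return out;
}
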