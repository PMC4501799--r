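#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Poisson sampler specialised for the tiny per-step release means that
// dominate this simulation. For mu < 0.5 a single uniform decides the count
// (exp() is only evaluated when u < mu, i.e. for ~2% of draws at default
// parameters); larger means fall back to R::rpois. Both paths consume R's
// global RNG stream, so runs are reproducible from set.seed().
static inline int rpois_small(double mu) {
  if (mu <= 0.0) return 0;
  if (mu >= 0.5) return (int) R::rpois(mu);
  double u = unif_rand();
  if (u >= mu) return 0;               // P(N >= 1) = 1 - exp(-mu) <= mu
  double p0 = std::exp(-mu);
  double cum = p0 - (1.0 - mu);        // residual zero-mass inside [0, mu)
  int k = 0;
  double pk = p0;
  while (u >= cum) {
    k++;
    pk *= mu / k;
    cum += pk;
  }
  return k;
}

struct PendVes {      // vesicle awaiting its nearest *following* post spike
  double t;
  int i;
  int count;
};

// Full fixed-step loop of the vesicle-timing dependent plasticity network.
// All decaying subsystems use exact exponential update factors on the 1-ms
// grid; release sampling, pairing, homeostasis and bounds follow the model
// described in the package vignette. State is passed in and returned so a
// run can be resumed (used by the developmental driver between
// synaptogenesis/pruning blocks).
// [[Rcpp::export]]
List vtdp_core(List par, List state, NumericMatrix xi_sched) {
  const int n_pre  = as<int>(par["n_pre"]);
  const int n_post = as<int>(par["n_post"]);
  const double dt  = as<double>(par["dt"]);
  const int n_steps = xi_sched.nrow();

  const double v_rest = as<double>(par["v_rest"]);
  const double c_mem = as<double>(par["c_mem"]);
  const double tau_mem = as<double>(par["tau_mem"]);
  const double theta_rest = as<double>(par["theta_rest"]);
  const double theta_max = as<double>(par["theta_max"]);
  const double decay_mem = std::exp(-dt / tau_mem);
  const double decay_theta = std::exp(-dt / as<double>(par["tau_theta"]));
  const double decay_ca = std::exp(-dt / as<double>(par["tau_ca"]));
  const double decay_rec = std::exp(-dt / as<double>(par["tau_rec"]));

  const double n_ves = as<double>(par["n_ves_per_ap"]);
  const double pool_total = as<double>(par["pool_total"]);
  // per-spike calcium increment: discrete geometric sum of the aEVE rate
  // after one spike equals exactly n_ves vesicles
  const double ca_jump = n_ves * (1.0 - decay_ca) / dt;

  const double r_m_ms = as<double>(par["r_m_ms"]);   // population mean rate, per ms

  const double tau_alpha = as<double>(par["tau_alpha"]);
  const int K = (int) std::lround(as<double>(par["t_window"]) / dt);
  std::vector<double> kern(K);
  for (int k = 0; k < K; k++) kern[k] = std::exp(-k * dt / tau_alpha);

  const double lambda = as<double>(par["lambda_ltp"]);
  const double mu_exp = as<double>(par["mu"]);
  const double alpha_ltd = as<double>(par["alpha_ltd"]);
  const double tau_stdp = as<double>(par["tau_stdp"]);
  const double w0 = as<double>(par["w0"]);
  const double w_max = as<double>(par["w_max"]);
  const double cutoff = as<double>(par["pairing_cutoff"]);
  const double ltp_pref = lambda * std::pow(w0, 1.0 - mu_exp);

  const double tau_h_s = as<double>(par["tau_h_s"]);
  const int h_block = as<int>(par["h_block"]);       // steps between scaling
  const double block_s = h_block * dt / 1000.0;
  const double r_target_hz = as<double>(par["r_target_hz"]);

  const bool plasticity_on = as<bool>(par["plasticity_on"]);
  const bool homeostasis_on = as<bool>(par["homeostasis_on"]);
  const bool pools_on = as<bool>(par["pools_on"]);
  const bool log_events = as<bool>(par["log_events"]);
  const int snap_stride = as<int>(par["snapshot_stride"]);

  NumericMatrix w = clone(as<NumericMatrix>(state["w"]));
  IntegerMatrix conn = clone(as<IntegerMatrix>(state["conn"]));
  NumericMatrix pa = clone(as<NumericMatrix>(state["pa"]));
  NumericVector ca = clone(as<NumericVector>(state["ca"]));
  NumericVector v = clone(as<NumericVector>(state["v"]));
  NumericVector theta = clone(as<NumericVector>(state["theta"]));
  NumericVector rate_ms = as<NumericVector>(state["rate_ms"]);
  double t0 = as<double>(state["t"]);

  NumericVector last_post = clone(as<NumericVector>(state["last_post"]));
  NumericMatrix epsc_buf = clone(as<NumericMatrix>(state["epsc_buf"])); // K x n_post
  NumericMatrix spike_hist = clone(as<NumericMatrix>(state["spike_hist"])); // 12 x n_post
  IntegerVector hist_pos = clone(as<IntegerVector>(state["hist_pos"]));
  NumericVector spike_cum = clone(as<NumericVector>(state["spike_cum"]));
  const double homeo_t0 = as<double>(state["homeo_t0"]);

  // pending vesicles (awaiting LTP pairing), per postsynaptic neuron
  std::vector<std::deque<PendVes> > pend(n_post);
  {
    NumericMatrix pm = as<NumericMatrix>(state["pending"]); // cols t, i, j, count
    for (int r = 0; r < pm.nrow(); r++) {
      PendVes pv; pv.t = pm(r, 0); pv.i = (int) pm(r, 1); pv.count = (int) pm(r, 3);
      pend[(int) pm(r, 2)].push_back(pv);
    }
  }

  const long global_step0 = (long) std::lround(t0 / dt);

  int n_snap = (snap_stride > 0) ? n_steps / snap_stride : 0;
  NumericMatrix snapshots(n_snap > 0 ? n_pre * n_post : 1, n_snap > 0 ? n_snap : 1);
  NumericVector snap_times(n_snap > 0 ? n_snap : 1);
  int snap_idx = 0;

  std::vector<double> post_t;
  std::vector<int> post_j;
  double rel_mode[3] = {0.0, 0.0, 0.0};    // SVE, aEVE, sEVE totals
  std::vector<double> ev_t; std::vector<int> ev_i, ev_j, ev_mode, ev_count;
  std::vector<double> prespk_t; std::vector<int> prespk_i;

  std::vector<int> spiked(n_pre);
  std::vector<double> I_now(n_post);

  for (int s = 0; s < n_steps; s++) {
    const double t = t0 + (s + 1) * dt;   // end-of-step clock; events carry this time
    const long gstep = global_step0 + s;
    const int head = (int) (gstep % K);

    const double xi_sve = xi_sched(s, 0);
    const double xi_aeve = xi_sched(s, 1);
    const double xi_seve = xi_sched(s, 2);
    const double sve_term = n_ves * r_m_ms * xi_sve * dt;

    // presynaptic spikes and residual calcium
    for (int i = 0; i < n_pre; i++) {
      const double p = rate_ms[i] * dt;
      spiked[i] = (p > 0.0 && unif_rand() < p) ? 1 : 0;
      ca[i] = ca[i] * decay_ca + (spiked[i] ? ca_jump : 0.0);
      if (spiked[i] && log_events) { prespk_t.push_back(t); prespk_i.push_back(i + 1); }
    }

    // zero the EPSC buffer slot for this step before accumulating releases
    for (int j = 0; j < n_post; j++) epsc_buf(head, j) = 0.0;

    // vesicle release, pool flux, immediate-LTD pairing
    for (int j = 0; j < n_post; j++) {
      const double lp = last_post[j];
      for (int i = 0; i < n_pre; i++) {
        if (!conn(i, j)) continue;
        const double avail = pools_on ? (pa(i, j) / pool_total) : 1.0;
        if (avail <= 0.0) continue;
        const double mu_sve = sve_term * avail;
        const double mu_aeve = ca[i] * xi_aeve * dt * avail;
        const double mu_seve = spiked[i] ? (n_ves * xi_seve * avail) : 0.0;
        const double mu_tot = mu_sve + mu_aeve + mu_seve;
        if (mu_tot <= 0.0) continue;
        int c = rpois_small(mu_tot);
        if (c == 0) continue;
        if (pools_on && c > pa(i, j)) c = (int) std::floor(pa(i, j));
        if (c == 0) continue;
        // mode attribution by Poisson splitting (for diagnostics/logs)
        int c_sve = (int) R::rbinom(c, mu_sve / mu_tot);
        int c_aeve = (c_sve < c && mu_aeve + mu_seve > 0.0)
          ? (int) R::rbinom(c - c_sve, mu_aeve / (mu_aeve + mu_seve)) : 0;
        int c_seve = c - c_sve - c_aeve;
        rel_mode[0] += c_sve; rel_mode[1] += c_aeve; rel_mode[2] += c_seve;
        if (log_events) {
          if (c_sve)  { ev_t.push_back(t); ev_i.push_back(i + 1); ev_j.push_back(j + 1); ev_mode.push_back(1); ev_count.push_back(c_sve); }
          if (c_aeve) { ev_t.push_back(t); ev_i.push_back(i + 1); ev_j.push_back(j + 1); ev_mode.push_back(2); ev_count.push_back(c_aeve); }
          if (c_seve) { ev_t.push_back(t); ev_i.push_back(i + 1); ev_j.push_back(j + 1); ev_mode.push_back(3); ev_count.push_back(c_seve); }
        }

        if (pools_on) pa(i, j) -= c;
        epsc_buf(head, j) += c * w(i, j);

        if (plasticity_on) {
          // depression against the nearest preceding postsynaptic spike
          const double ds = t - lp;       // vesicle after spike => ds > 0 here
          if (lp > -1e17 && ds <= cutoff) {
            double wij = w(i, j) + c * (-lambda * alpha_ltd * w(i, j) * std::exp(-ds / tau_stdp));
            w(i, j) = (wij < 0.0) ? 0.0 : ((wij > w_max) ? w_max : wij);
          }
          PendVes pv; pv.t = t; pv.i = i; pv.count = c;
          pend[j].push_back(pv);
        }
      }
    }

    // pool recovery (exact exponential return from the recycling pool)
    if (pools_on) {
      for (int j = 0; j < n_post; j++)
        for (int i = 0; i < n_pre; i++)
          if (conn(i, j)) pa(i, j) = pool_total - (pool_total - pa(i, j)) * decay_rec;
    }

    // summed EPSC current over the truncation window
    for (int j = 0; j < n_post; j++) {
      double I = 0.0;
      for (int k = 0; k < K; k++) I += epsc_buf((head - k + K) % K, j) * kern[k];
      I_now[j] = I;
    }

    // LIF with adaptive threshold: exact solution for constant current per step
    for (int j = 0; j < n_post; j++) {
      const double v_inf = v_rest + I_now[j] * tau_mem / c_mem;
      v[j] = v_inf + (v[j] - v_inf) * decay_mem;
      theta[j] = theta_rest + (theta[j] - theta_rest) * decay_theta;
      // drop pairing candidates that have aged out of the window
      while (!pend[j].empty() && t - pend[j].front().t > cutoff) pend[j].pop_front();
      if (v[j] >= theta[j]) {
        post_t.push_back(t); post_j.push_back(j + 1);
        v[j] = v_rest;
        theta[j] = theta_max;
        if (plasticity_on) {
          // potentiation: every pending vesicle meets its nearest following spike
          for (std::deque<PendVes>::iterator it = pend[j].begin(); it != pend[j].end(); ++it) {
            double ds = t - it->t;
            if (ds == 0.0) ds = dt / 2.0;  // same-step vesicle counts as causal
            double wij = w(it->i, j);
            wij += it->count * ltp_pref * std::pow(wij, mu_exp) * std::exp(-ds / tau_stdp);
            w(it->i, j) = (wij < 0.0) ? 0.0 : ((wij > w_max) ? w_max : wij);
          }
          pend[j].clear();
        }
        last_post[j] = t;
        spike_hist(hist_pos[j] % 12, j) = t;
        hist_pos[j] += 1;
        spike_cum[j] += 1.0;
      }
    }

    // homeostatic scaling, once per block (equivalent to per-step at tau_h = 100 s)
    if (homeostasis_on && ((gstep + 1) % h_block == 0)) {
      for (int j = 0; j < n_post; j++) {
        double r_hz;
        if (hist_pos[j] >= 12) {
          const double t12 = spike_hist(hist_pos[j] % 12, j); // oldest of last 12
          r_hz = 12.0 / ((t - t12) / 1000.0);
        } else {
          const double elapsed = (t - homeo_t0) / 1000.0;
          r_hz = (elapsed > 0.0) ? spike_cum[j] / elapsed : 0.0;
        }
        double fac = 1.0 + (r_target_hz - r_hz) * block_s / tau_h_s;
        if (fac < 0.0) fac = 0.0;
        for (int i = 0; i < n_pre; i++) {
          if (!conn(i, j)) continue;
          double wij = w(i, j) * fac;
          w(i, j) = (wij > w_max) ? w_max : wij;
        }
      }
    }

    if (snap_stride > 0 && ((s + 1) % snap_stride == 0) && snap_idx < n_snap) {
      for (int j = 0; j < n_post; j++)
        for (int i = 0; i < n_pre; i++)
          snapshots(i + j * n_pre, snap_idx) = conn(i, j) ? w(i, j) : NA_REAL;
      snap_times[snap_idx] = t;
      snap_idx++;
    }
  }

  // serialize pending-pair queues so a subsequent call can resume exactly
  int n_pend = 0;
  for (int j = 0; j < n_post; j++) n_pend += (int) pend[j].size();
  NumericMatrix pending_out(n_pend, 4);
  {
    int r = 0;
    for (int j = 0; j < n_post; j++)
      for (std::deque<PendVes>::iterator it = pend[j].begin(); it != pend[j].end(); ++it, ++r) {
        pending_out(r, 0) = it->t; pending_out(r, 1) = it->i;
        pending_out(r, 2) = j; pending_out(r, 3) = it->count;
      }
  }

  List out_state = List::create(
    _["w"] = w, _["conn"] = conn, _["pa"] = pa, _["ca"] = ca,
    _["v"] = v, _["theta"] = theta, _["rate_ms"] = rate_ms,
    _["t"] = t0 + n_steps * dt, _["last_post"] = last_post,
    _["epsc_buf"] = epsc_buf, _["spike_hist"] = spike_hist,
    _["hist_pos"] = hist_pos, _["spike_cum"] = spike_cum,
    _["homeo_t0"] = homeo_t0, _["pending"] = pending_out);

  List out = List::create(
    _["state"] = out_state,
    _["snapshots"] = (n_snap > 0) ? snapshots : NumericMatrix(0, 0),
    _["snap_times"] = (n_snap > 0) ? snap_times : NumericVector(0),
    _["post_t"] = wrap(post_t), _["post_j"] = wrap(post_j),
    _["release_by_mode"] = NumericVector::create(
      _["SVE"] = rel_mode[0], _["aEVE"] = rel_mode[1], _["sEVE"] = rel_mode[2]));
  if (log_events) {
    out["events"] = List::create(_["t"] = wrap(ev_t), _["i"] = wrap(ev_i),
                                 _["j"] = wrap(ev_j), _["mode"] = wrap(ev_mode),
                                 _["count"] = wrap(ev_count));
    out["pre_spikes"] = List::create(_["t"] = wrap(prespk_t), _["i"] = wrap(prespk_i));
  }
  return out;
}
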