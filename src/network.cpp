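// Spiking two-channel CBGT network: conductance-based leaky integrate-and-fire
// neurons with exponential AMPA/GABA synapses, Ornstein-Uhlenbeck external
// drive, a ramping cortical input, a thalamic rate-threshold decision rule,
// and dopamine-gated eligibility-trace plasticity at corticostriatal synapses.
//
// All randomness is drawn from R's RNG so trials are reproducible under
// set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Proj {
  int src, dst;       // slot indices
  int receptor;       // 0 = AMPA, 1 = GABA
  NumericMatrix W;    // n_dst x n_src efficacies (0 = unconnected)
  bool plastic;
  int target_type;    // 1 = dSPN, 2 = iSPN (only for plastic projections)
};

// Fast local normal generator for the high-volume background-noise draws:
// xoshiro256+ seeded from R's RNG (so trials stay reproducible under
// set.seed) with Box-Muller pairs. All low-volume draws (initial conditions,
// rewards) keep using R's generator directly.
struct FastNorm {
  uint64_t s[4];
  double spare; bool has_spare;
  explicit FastNorm(double useed) : has_spare(false) {
    // splitmix64 expansion of a seed drawn from R's stream
    uint64_t x = (uint64_t)(useed * 9007199254740992.0) | 1ULL;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  inline uint64_t nextu() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = (s[3] << 45) | (s[3] >> 19);
    return result;
  }
  inline double unif() {  // in (0,1)
    return ((nextu() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0; v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

// dopamine modulation factor f(K_DA)
static inline double f_kda_cpp(double K, int target_type, double gamma,
                               double mu, double eps) {
  if (target_type == 1) {                 // dSPN
    return (K < -mu) ? -gamma : (gamma / mu) * K;
  } else {                                // iSPN
    return (K < mu) ? eps * (gamma / mu) * K : eps * gamma;
  }
}

// [[Rcpp::export]]
List run_trial_cpp(List net, double f_baseline, List learn) {
  // ---- unpack network description -------------------------------------
  IntegerVector slot_size = net["slot_size"];
  CharacterVector slot_label = net["slot_label"];
  int n_slots = slot_size.size();
  NumericMatrix neuron = net["neuron"];   // tau_m V_L V_th V_reset V_E V_I t_ref
  NumericMatrix ext    = net["ext"];      // E_ext N_ext tau_x f_const
  LogicalVector is_ctx = net["is_ctx"];
  List projections     = net["projections"];
  double tau_ampa = as<double>(net["tau_ampa"]);
  double tau_gaba = as<double>(net["tau_gaba"]);
  double dt       = as<double>(net["dt"]);
  double warmup   = as<double>(net["warmup_ms"]);
  double max_ms   = as<double>(net["max_ms"]);
  double bin_ms   = as<double>(net["bin_ms"]);
  double thresh   = as<double>(net["threshold_hz"]);
  double tau_sm   = as<double>(net["tau_smooth"]);
  int thal1 = as<int>(net["thal_slot1"]);   // 0-based slot indices
  int thal2 = as<int>(net["thal_slot2"]);
  double f_target  = as<double>(net["f_target"]);
  double ramp_rate = as<double>(net["ramp_rate"]);
  double onset_ms  = as<double>(net["onset_ms"]);  // input latency before ramp

  int n_proj = projections.size();
  std::vector<Proj> pr(n_proj);
  for (int p = 0; p < n_proj; ++p) {
    List pp = projections[p];
    pr[p].src = as<int>(pp["src"]);
    pr[p].dst = as<int>(pp["dst"]);
    pr[p].receptor = as<int>(pp["receptor"]);
    pr[p].W = as<NumericMatrix>(pp["W"]);
    pr[p].plastic = as<bool>(pp["plastic"]);
    pr[p].target_type = as<int>(pp["target_type"]);
  }
  // projections indexed by source slot for fast spike propagation
  std::vector< std::vector<int> > proj_by_src(n_slots);
  for (int p = 0; p < n_proj; ++p) proj_by_src[pr[p].src].push_back(p);

  // ---- learning / dopamine state --------------------------------------
  bool learning = as<bool>(learn["enabled"]);
  double tau_pre = 0, tau_post = 0, d_pre = 0, d_post = 0, tau_e = 0;
  double tau_da = 0, c_scale = 0, gamma = 0, mu_da = 0, eps = 0;
  double alpha_dspn = 0, alpha_ispn = 0;
  double wmin_d = 0, wmax_d = 0, wmin_i = 0, wmax_i = 0;
  double K_da = 0, alpha_q = 0, p_opt = 0, p_sub = 0, feedback_ms = 0;
  int rewarded_channel = 1;
  NumericVector Q(2);
  if (learning) {
    List pl = learn["plast"];
    tau_pre  = as<double>(pl["tau_pre"]);  tau_post = as<double>(pl["tau_post"]);
    d_pre    = as<double>(pl["d_pre"]);    d_post   = as<double>(pl["d_post"]);
    tau_e    = as<double>(pl["tau_e"]);    tau_da   = as<double>(pl["tau_da"]);
    c_scale  = as<double>(pl["c_scale"]);  gamma    = as<double>(pl["gamma"]);
    mu_da    = as<double>(pl["mu"]);       eps      = as<double>(pl["eps"]);
    alpha_dspn = as<double>(pl["alpha_dspn"]);
    alpha_ispn = as<double>(pl["alpha_ispn"]);
    wmin_d = as<double>(pl["wmin_dspn"]); wmax_d = as<double>(pl["wmax_dspn"]);
    wmin_i = as<double>(pl["wmin_ispn"]); wmax_i = as<double>(pl["wmax_ispn"]);
    K_da = as<double>(learn["K_da"]);
    Q = clone(as<NumericVector>(learn["Q"]));
    alpha_q = as<double>(learn["alpha_q"]);
    rewarded_channel = as<int>(learn["rewarded_channel"]);
    p_opt = as<double>(learn["p_opt"]);
    p_sub = as<double>(learn["p_sub"]);
    feedback_ms = as<double>(learn["feedback_ms"]);
  }

  FastNorm fn(unif_rand());

  // plasticity traces per plastic projection
  std::vector< std::vector<double> > A_pre(n_proj), A_post(n_proj);
  std::vector< NumericMatrix > E(n_proj);
  for (int p = 0; p < n_proj; ++p) {
    if (pr[p].plastic && learning) {
      A_pre[p].assign(slot_size[pr[p].src], 0.0);
      A_post[p].assign(slot_size[pr[p].dst], 0.0);
      E[p] = NumericMatrix(slot_size[pr[p].dst], slot_size[pr[p].src]);
    }
  }

  // ---- neuron state ----------------------------------------------------
  std::vector< std::vector<double> > V(n_slots), gA(n_slots), gG(n_slots),
      Sx(n_slots), ref_until(n_slots);
  for (int s = 0; s < n_slots; ++s) {
    int n = slot_size[s];
    V[s].assign(n, 0.0); gA[s].assign(n, 0.0); gG[s].assign(n, 0.0);
    Sx[s].assign(n, 0.0); ref_until[s].assign(n, -1.0);
    double VL = neuron(s, 1), Vth = neuron(s, 2);
    // start at stationary external-drive mean, voltages scattered below threshold
    double mu0 = 0.001 * ext(s, 0) * (is_ctx[s] ? f_baseline : ext(s, 3)) *
                 ext(s, 1) * ext(s, 2);
    for (int i = 0; i < n; ++i) {
      V[s][i] = VL + unif_rand() * (Vth - VL) * 0.9;
      Sx[s][i] = mu0;
    }
  }

  double decA = std::exp(-dt / tau_ampa), decG = std::exp(-dt / tau_gaba);
  double dec_sm = std::exp(-dt / tau_sm);
  double dec_pre = learning ? std::exp(-dt / tau_pre) : 0.0;
  double dec_post = learning ? std::exp(-dt / tau_post) : 0.0;
  double dec_e = learning ? std::exp(-dt / tau_e) : 0.0;
  double dec_da = learning ? std::exp(-dt / tau_da) : 0.0;

  int n_bins = (int)std::ceil(max_ms / bin_ms);
  NumericVector fb_rates(n_slots);    // mean rates during the feedback window
  double fb_ms = 0.0;
  NumericMatrix rates(n_bins, n_slots);   // Hz, from ramp onset to decision
  double r_th1 = 0, r_th2 = 0;            // smoothed thalamic rate estimates
  double framp = 0.0;
  int choice = 0;                          // 0 timeout, 1, 2
  double decision_ms = NA_REAL;
  double reward = NA_REAL, da_inc = NA_REAL;
  bool decided = false;

  double t_end = warmup + max_ms;          // extended after decision if learning
  double t = 0.0;
  long step = 0;
  // the ramp recurrence is defined per millisecond of simulated time, so
  // its time course does not depend on the integrator step
  int steps_per_ms = (int)std::max(1.0, std::round(1.0 / dt));
  std::vector< std::vector<int> > spikes(n_slots);

  while (t < t_end - 1e-9) {
    bool in_trial = t >= warmup;                 // decision clock runs
    bool ramp_on = t >= warmup + onset_ms;       // input has arrived
    if (ramp_on && !decided && step % steps_per_ms == 0)
      framp += ramp_rate * (f_target - framp);

    // --- integrate neurons, collect spikes ---
    for (int s = 0; s < n_slots; ++s) spikes[s].clear();
    for (int s = 0; s < n_slots; ++s) {
      int n = slot_size[s];
      double tau_m = neuron(s, 0), VL = neuron(s, 1), Vth = neuron(s, 2),
             Vre = neuron(s, 3), VE = neuron(s, 4), VI = neuron(s, 5),
             tref = neuron(s, 6);
      double f_now = is_ctx[s] ? (f_baseline + (in_trial ? framp : 0.0))
                               : ext(s, 3);
      double Ee = ext(s, 0), Ne = ext(s, 1), tx = ext(s, 2);
      double mu_x = 0.001 * Ee * f_now * Ne * tx;
      double sig_x = Ee * std::sqrt(0.0005 * f_now * Ne * tx);
      double diff_scale = std::sqrt(2.0 * dt / tx);
      for (int i = 0; i < n; ++i) {
        Sx[s][i] += (mu_x - Sx[s][i]) / tx * dt +
                    sig_x * diff_scale * fn.norm();
        if (Sx[s][i] < 0) Sx[s][i] = 0;
        gA[s][i] *= decA; gG[s][i] *= decG;
        if (t < ref_until[s][i]) continue;
        double v = V[s][i];
        v += dt / tau_m * (-(v - VL) - (gA[s][i] + Sx[s][i]) * (v - VE)
                           - gG[s][i] * (v - VI));
        if (v >= Vth) {
          V[s][i] = Vre;
          ref_until[s][i] = t + tref;
          spikes[s].push_back(i);
        } else V[s][i] = v;
      }
    }

    // --- plasticity traces and eligibility (learning trials only) ---
    if (learning) {
      for (int p = 0; p < n_proj; ++p) {
        if (!pr[p].plastic) continue;
        int ns = slot_size[pr[p].src], nd = slot_size[pr[p].dst];
        for (int j = 0; j < ns; ++j) A_pre[p][j] *= dec_pre;
        for (int i = 0; i < nd; ++i) A_post[p][i] *= dec_post;
        const std::vector<int> &sp_pre = spikes[pr[p].src];
        const std::vector<int> &sp_post = spikes[pr[p].dst];
        for (size_t k = 0; k < sp_pre.size(); ++k)
          A_pre[p][sp_pre[k]] += d_pre / tau_pre;
        for (size_t k = 0; k < sp_post.size(); ++k)
          A_post[p][sp_post[k]] += d_post / tau_post;
        NumericMatrix &Ep = E[p];
        double *e = Ep.begin();
        int ntot = nd * ns;
        for (int q = 0; q < ntot; ++q) e[q] *= dec_e;
        for (size_t k = 0; k < sp_post.size(); ++k) {
          int i = sp_post[k];
          for (int j = 0; j < ns; ++j) Ep(i, j) += A_pre[p][j] / tau_e;
        }
        for (size_t k = 0; k < sp_pre.size(); ++k) {
          int j = sp_pre[k];
          for (int i = 0; i < nd; ++i) Ep(i, j) -= A_post[p][i] / tau_e;
        }
      }
    }

    // --- propagate spikes ---
    for (int s = 0; s < n_slots; ++s) {
      if (spikes[s].empty()) continue;
      for (size_t pi = 0; pi < proj_by_src[s].size(); ++pi) {
        Proj &P = pr[proj_by_src[s][pi]];
        int nd = slot_size[P.dst];
        std::vector<double> &g = (P.receptor == 0) ? gA[P.dst] : gG[P.dst];
        for (size_t k = 0; k < spikes[s].size(); ++k) {
          int j = spikes[s][k];
          for (int i = 0; i < nd; ++i) g[i] += P.W(i, j);
        }
      }
    }

    // --- dopamine decay + soft-bounded weight drift (after conductances,
    //     so a conductance jump uses the pre-update weight) ---
    if (learning) {
      K_da *= dec_da;
      if (std::fabs(K_da) > 1e-12) {
        for (int p = 0; p < n_proj; ++p) {
          if (!pr[p].plastic) continue;
          bool dspn = pr[p].target_type == 1;
          double alpha = dspn ? alpha_dspn : alpha_ispn;
          double wmin = dspn ? wmin_d : wmin_i;
          double wmax = dspn ? wmax_d : wmax_i;
          double fk = f_kda_cpp(K_da, pr[p].target_type, gamma, mu_da, eps);
          NumericMatrix &Wp = pr[p].W;
          NumericMatrix &Ep = E[p];
          int ntot = Wp.nrow() * Wp.ncol();
          double *w = Wp.begin(); double *e = Ep.begin();
          for (int q = 0; q < ntot; ++q) {
            double d = alpha * e[q] * fk;
            double dw = (d > 0) ? d * (wmax - w[q]) : d * (w[q] - wmin);
            w[q] += dt * dw;
            if (w[q] > wmax) w[q] = wmax;
            if (w[q] < wmin) w[q] = wmin;
          }
        }
      }
    }

    if (decided && learning) {
      for (int s = 0; s < n_slots; ++s) fb_rates[s] += spikes[s].size();
      fb_ms += dt;
    }

    // --- thalamic rate estimate + decision rule ---
    double inst1 = spikes[thal1].size() / (slot_size[thal1] * dt * 1e-3);
    double inst2 = spikes[thal2].size() / (slot_size[thal2] * dt * 1e-3);
    r_th1 = r_th1 * dec_sm + (1.0 - dec_sm) * inst1;
    r_th2 = r_th2 * dec_sm + (1.0 - dec_sm) * inst2;

    if (in_trial && !decided) {
      int b = (int)((t - warmup) / bin_ms);
      if (b >= 0 && b < n_bins)
        for (int s = 0; s < n_slots; ++s)
          rates(b, s) += spikes[s].size();
      if (r_th1 >= thresh || r_th2 >= thresh) {
        decided = true;
        choice = (r_th1 >= r_th2) ? 1 : 2;
        decision_ms = t - warmup + dt;
        if (learning) {
          double p_rew = (choice == rewarded_channel) ? p_opt : p_sub;
          reward = (unif_rand() < p_rew) ? 1.0 : 0.0;
          da_inc = reward - Q[choice - 1];
          Q[choice - 1] += alpha_q * da_inc;
          K_da += c_scale * (da_inc - K_da);
          t_end = t + feedback_ms;       // keep simulating to apply plasticity
        } else {
          t_end = t;                     // probe trial: stop at decision
        }
      }
    }

    t += dt;
    if (++step % 500 == 0) {
      for (int s = 0; s < n_slots; ++s)
        if (!std::isfinite(V[s][0]))
          stop("numerical divergence in population '%s'",
               as<std::string>(slot_label[s]).c_str());
    }
  }

  // convert per-bin spike counts to Hz; bins after decision are NA
  double used_ms = decided ? decision_ms : max_ms;
  int bins_used = std::max(1, (int)std::ceil(used_ms / bin_ms));
  if (bins_used > n_bins) bins_used = n_bins;
  for (int b = 0; b < n_bins; ++b) {
    double bw = bin_ms;
    if (b == bins_used - 1) {
      bw = used_ms - b * bin_ms;          // last (partial) bin
      if (bw < dt) bw = dt;
    }
    for (int s = 0; s < n_slots; ++s) {
      if (b >= bins_used) { rates(b, s) = NA_REAL; continue; }
      rates(b, s) = rates(b, s) / (slot_size[s] * bw * 1e-3);
    }
  }

  if (fb_ms > 0)
    for (int s = 0; s < n_slots; ++s)
      fb_rates[s] = fb_rates[s] / (slot_size[s] * fb_ms * 1e-3);

  // return (possibly updated) plastic weight matrices
  List Wout(n_proj);
  for (int p = 0; p < n_proj; ++p) {
    if (pr[p].plastic) Wout[p] = pr[p].W; else Wout[p] = R_NilValue;
  }

  return List::create(
      _["choice"] = choice, _["decision_ms"] = decision_ms,
      _["timeout"] = !decided, _["reward"] = reward, _["da_inc"] = da_inc,
      _["rates"] = rates, _["bins_used"] = bins_used,
      _["feedback_rates"] = fb_rates,
      _["K_da"] = K_da, _["Q"] = Q, _["W"] = Wout);
}
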