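// Closed-loop simulation engines for reward-modulated rare-correlation
// Hebbian learning. Both engines advance the network with exactly the same
// per-step sequence as the R reference path (step_rchp): compute u from the
// previous outputs and the drive, emit noisy tanh outputs, detect threshold
// crossings of the lagged output product, update modulation with the reward
// input, decay traces and add events, apply the modulated weight update to
// plastic synapses, then adapt the thresholds homeostatically. All noise is
// drawn from R's RNG (one uniform per neuron per step, in neuron order), so
// runs are reproducible with set.seed() and bit-comparable with the R path.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Engine {
  // structure
  int n, n_exc, ns;
  std::vector<int> pre, post;          // 0-based, sorted by post
  std::vector<int> row_ptr;            // CSR over postsynaptic neurons
  std::vector<double> kappa;
  std::vector<std::vector<int>> members;  // all groups, 0-based neuron ids
  // parameters
  double gain, noise_hw, dt, wmin, wmax, drive;
  double alpha, beta, tau_c, tau_m, lambda, baseline;
  double mu, eta, band_hi, band_lo;
  int qlen;
  // dynamic state
  std::vector<double> w, c, v, vnew, u, vk, ext;
  double m, theta_hi, theta_lo, time;
  std::vector<double> cq, dq;          // circular event-count queues
  int qpos, qfill;
  double csum, dsum;
  // last-step diagnostics
  double rate_c, rate_d;

  void load(const List& net, const List& np, const List& pp) {
    IntegerVector pre1 = net["pre"], post1 = net["post"];
    NumericVector w1 = net["w"], kap = net["kappa"];
    n = as<int>(net["n"]);
    n_exc = as<int>(net["n_excitatory"]);
    ns = pre1.size();
    pre.resize(ns); post.resize(ns); w.resize(ns);
    for (int s = 0; s < ns; ++s) {
      pre[s] = pre1[s] - 1; post[s] = post1[s] - 1;
      w[s] = w1[s];
      if (s > 0 && post[s] < post[s - 1])
        stop("synapses must be sorted by postsynaptic neuron");
    }
    row_ptr.assign(n + 1, 0);
    for (int s = 0; s < ns; ++s) ++row_ptr[post[s] + 1];
    for (int i = 0; i < n; ++i) row_ptr[i + 1] += row_ptr[i];
    kappa.assign(kap.begin(), kap.end());
    List gl = net["groups"];
    members.resize(gl.size());
    for (int g = 0; g < gl.size(); ++g) {
      List gg = gl[g];
      IntegerVector mem = gg["members"];
      members[g].resize(mem.size());
      for (int i = 0; i < mem.size(); ++i) members[g][i] = mem[i] - 1;
    }

    gain = as<double>(np["gain"]);
    noise_hw = as<double>(np["noise_halfwidth"]);
    dt = as<double>(np["dt"]);
    wmin = as<double>(np["weight_min"]);
    wmax = as<double>(np["weight_max"]);
    drive = as<double>(np["input_drive"]);
    alpha = as<double>(pp["alpha"]);
    beta = as<double>(pp["beta"]);
    tau_c = as<double>(pp["tau_c"]);
    tau_m = as<double>(pp["tau_m"]);
    lambda = as<double>(pp["lambda"]);
    baseline = as<double>(pp["baseline"]);
    mu = as<double>(pp["mu_target"]);
    eta = as<double>(pp["eta"]);
    band_hi = as<double>(pp["band_hi_factor"]) * mu;
    band_lo = as<double>(pp["band_lo_factor"]) * mu;
    qlen = (int)std::lround(as<double>(pp["window"]) / dt);
    if (qlen < 1) qlen = 1;

    List st = net["state"];
    NumericVector v0 = st["v"], c0 = st["c"];
    v.assign(v0.begin(), v0.end());
    c.assign(c0.begin(), c0.end());
    m = as<double>(st["m"]);
    double th = as<double>(st["theta_hi"]);
    theta_hi = R_IsNA(th) ? as<double>(pp["theta_hi_init"]) : th;
    double tl = as<double>(st["theta_lo"]);
    theta_lo = R_IsNA(tl) ? as<double>(pp["theta_lo_init"]) : tl;
    time = as<double>(st["time"]);
    cq.assign(qlen, 0.0); dq.assign(qlen, 0.0);
    qpos = 0; qfill = 0; csum = 0.0; dsum = 0.0;
    NumericVector cq0 = st["corr_queue"], dq0 = st["decorr_queue"];
    int start = std::max(0, (int)cq0.size() - qlen);
    for (int i = start; i < cq0.size(); ++i) pushq(cq, csum, cq0[i]);
    // decorr queue shares qpos/qfill bookkeeping; replay it separately
    qpos = 0; qfill = 0;
    for (int i = std::max(0, (int)dq0.size() - qlen); i < dq0.size(); ++i) {
      dsum += dq0[i] - dq[qpos]; dq[qpos] = dq0[i];
      qpos = (qpos + 1) % qlen; if (qfill < qlen) ++qfill;
    }
    // align: both queues must have identical fill by construction
    vnew.resize(n); u.resize(n); vk.resize(n); ext.assign(n, 0.0);
    rate_c = 0.0; rate_d = 0.0;
  }

  void pushq(std::vector<double>& q, double& sum, double x) {
    sum += x - q[qpos]; q[qpos] = x;
    qpos = (qpos + 1) % qlen; if (qfill < qlen) ++qfill;
  }

  // one sampling step; ext must hold the external drive, r the reward input
  void step(double r) {
    for (int i = 0; i < n; ++i) vk[i] = v[i] * kappa[i];
    for (int i = 0; i < n; ++i) {
      double acc = ext[i];
      for (int s = row_ptr[i]; s < row_ptr[i + 1]; ++s)
        acc += w[s] * vk[pre[s]];
      u[i] = acc;
    }
    for (int i = 0; i < n; ++i) {
      double xi = R::runif(-noise_hw, noise_hw);
      vnew[i] = (u[i] >= 0) ? std::tanh(gain * u[i]) + xi : xi;
    }
    m = m * (1.0 - dt / tau_m) + (lambda * r + baseline) * dt;
    const double decay = 1.0 - dt / tau_c;
    const double mdt = m * dt;
    const bool learn = (m != 0.0);
    int ncorr = 0, ndecorr = 0;
    for (int i = 0; i < n; ++i) {
      const double vn = vnew[i];
      // afferents of excitatory neurons are plastic, of inhibitory fixed
      const bool pl = learn && i < n_exc;
      for (int s = row_ptr[i]; s < row_ptr[i + 1]; ++s) {
        double p = v[pre[s]] * vn;
        double cc = c[s] * decay;
        if (p > theta_hi) { cc += alpha; ++ncorr; }
        else if (p < theta_lo) { cc -= beta; ++ndecorr; }
        c[s] = cc;
        if (pl) {
          double ww = w[s] + mdt * cc;
          w[s] = ww < wmin ? wmin : (ww > wmax ? wmax : ww);
        }
      }
    }
    // homeostasis: push counts, compare windowed rates with the band
    {
      csum += ncorr - cq[qpos]; cq[qpos] = ncorr;
      dsum += ndecorr - dq[qpos]; dq[qpos] = ndecorr;
      qpos = (qpos + 1) % qlen; if (qfill < qlen) ++qfill;
      double denom = (double)qfill * dt * (double)ns;
      rate_c = csum / denom;
      rate_d = dsum / denom;
      double stp = eta * dt;
      if (rate_c > band_hi) theta_hi += stp;
      else if (rate_c < band_lo) theta_hi = std::max(0.0, theta_hi - stp);
      if (rate_d > band_hi) theta_lo -= stp;
      else if (rate_d < band_lo) theta_lo = std::min(0.0, theta_lo + stp);
    }
    std::swap(v, vnew);
    time += dt;
  }

  double activity(int g) const {
    const std::vector<int>& mem = members[g];
    double s = 0.0;
    for (size_t i = 0; i < mem.size(); ++i) s += v[mem[i]];
    return s / (double)mem.size();
  }

  List state_out() const {
    NumericVector cqo(qfill), dqo(qfill);
    for (int i = 0; i < qfill; ++i) {
      int at = (qpos - qfill + i + qlen * 4) % qlen;  // oldest first
      cqo[i] = cq[at]; dqo[i] = dq[at];
    }
    return List::create(
      _["v"] = NumericVector(v.begin(), v.end()),
      _["c"] = NumericVector(c.begin(), c.end()),
      _["m"] = m, _["theta_hi"] = theta_hi, _["theta_lo"] = theta_lo,
      _["corr_queue"] = cqo, _["decorr_queue"] = dqo, _["time"] = time);
  }
};

void record_pathways(const Engine& E,
                     const std::vector<std::vector<int>>& pidx,
                     NumericMatrix& out, int col) {
  for (size_t p = 0; p < pidx.size(); ++p) {
    double s = 0.0;
    for (size_t k = 0; k < pidx[p].size(); ++k) s += E.w[pidx[p][k]];
    out((int)p, col) = pidx[p].empty() ? 0.0 : s / (double)pidx[p].size();
  }
}

std::vector<std::vector<int>> load_pathways(const List& pathway_idx) {
  std::vector<std::vector<int>> pidx(pathway_idx.size());
  for (int p = 0; p < pathway_idx.size(); ++p) {
    IntegerVector iv = pathway_idx[p];
    pidx[p].resize(iv.size());
    for (int k = 0; k < iv.size(); ++k) pidx[p][k] = iv[k] - 1;
  }
  return pidx;
}

} // namespace

// Schedule-driven run (classical conditioning and variants): stimulus
// activation is precomputed per step and group; rewards arrive as a per-step
// r(t) vector.
// [[Rcpp::export]]
List cpp_run_schedule(List net, List np, List pp,
                      IntegerMatrix stim_on, IntegerVector input_groups,
                      NumericVector r_step,
                      List pathway_idx, int record_every) {
  Engine E;
  E.load(net, np, pp);
  const int nsteps = stim_on.ncol();
  if (r_step.size() != nsteps) stop("r_step length must equal the step count");
  const int G = (int)E.members.size();
  std::vector<std::vector<int>> pidx = load_pathways(pathway_idx);
  const int nrec = nsteps / record_every;

  NumericMatrix activity(G, nsteps), pathways((int)pidx.size(), nrec);
  NumericVector m_s(nsteps), thi_s(nsteps), tlo_s(nsteps),
                rc_s(nsteps), rd_s(nsteps), ptime(nrec);

  int prec = 0;
  for (int t = 0; t < nsteps; ++t) {
    std::fill(E.ext.begin(), E.ext.end(), 0.0);
    for (int gi = 0; gi < input_groups.size(); ++gi) {
      if (stim_on(gi, t)) {
        const std::vector<int>& mem = E.members[input_groups[gi] - 1];
        for (size_t k = 0; k < mem.size(); ++k) E.ext[mem[k]] += E.drive;
      }
    }
    E.step(r_step[t]);
    for (int g = 0; g < G; ++g) activity(g, t) = E.activity(g);
    m_s[t] = E.m; thi_s[t] = E.theta_hi; tlo_s[t] = E.theta_lo;
    rc_s[t] = E.rate_c; rd_s[t] = E.rate_d;
    if ((t + 1) % record_every == 0 && prec < nrec) {
      record_pathways(E, pidx, pathways, prec);
      ptime[prec] = E.time;
      ++prec;
    }
  }

  return List::create(
    _["w"] = NumericVector(E.w.begin(), E.w.end()),
    _["state"] = E.state_out(),
    _["activity"] = activity,
    _["m"] = m_s, _["theta_hi"] = thi_s, _["theta_lo"] = tlo_s,
    _["corr_rate"] = rc_s, _["decorr_rate"] = rd_s,
    _["pathways"] = pathways, _["pathway_time"] = ptime);
}

// Closed-loop operant run: trials present one color group each; output-group
// activity is monitored over a decision window; the selected action gets
// winner-take-all feedback (+drive winner members, -drive other output
// groups) and a delayed reward whose sign follows the tutor policy.
// [[Rcpp::export]]
List cpp_run_operant(List net, List np, List pp, int nsteps,
                     IntegerVector trial_onset, IntegerVector trial_group,
                     IntegerVector correct_action, IntegerVector punished_action,
                     double reward_correct, double reward_wrong,
                     double reward_punish,
                     double delay_min, double delay_max,
                     int stim_steps, int window_steps, int feedback_steps,
                     double threshold_abs,
                     IntegerVector output_groups,
                     List pathway_idx, int record_every) {
  Engine E;
  E.load(net, np, pp);
  const int G = (int)E.members.size();
  const int ntr = trial_onset.size();
  const int nout = output_groups.size();
  std::vector<std::vector<int>> pidx = load_pathways(pathway_idx);
  const int nrec = nsteps / record_every;

  NumericMatrix activity(G, nsteps), pathways((int)pidx.size(), nrec);
  NumericVector m_s(nsteps), thi_s(nsteps), tlo_s(nsteps),
                rc_s(nsteps), rd_s(nsteps), ptime(nrec);
  IntegerVector chosen(ntr, NA_INTEGER), decision_step(ntr, NA_INTEGER),
                reward_step(ntr, NA_INTEGER);
  NumericVector reward_mag(ntr, 0.0);

  std::vector<double> r_buf(nsteps, 0.0);
  int cur = 0;                       // current trial index
  int fb_from = -1, fb_until = -1, fb_winner = -1;
  int prec = 0;

  for (int t = 0; t < nsteps; ++t) {
    while (cur < ntr - 1 && t >= trial_onset[cur + 1]) ++cur;
    bool stim = (ntr > 0) && t >= trial_onset[cur] &&
                t < trial_onset[cur] + stim_steps;
    std::fill(E.ext.begin(), E.ext.end(), 0.0);
    if (stim) {
      const std::vector<int>& mem = E.members[trial_group[cur] - 1];
      for (size_t k = 0; k < mem.size(); ++k) E.ext[mem[k]] += E.drive;
    }
    if (t >= fb_from && t < fb_until) {
      for (int a = 0; a < nout; ++a) {
        const std::vector<int>& mem = E.members[output_groups[a] - 1];
        double d = (a == fb_winner) ? E.drive : -E.drive;
        for (size_t k = 0; k < mem.size(); ++k) E.ext[mem[k]] += d;
      }
    }
    E.step(r_buf[t]);
    for (int g = 0; g < G; ++g) activity(g, t) = E.activity(g);
    m_s[t] = E.m; thi_s[t] = E.theta_hi; tlo_s[t] = E.theta_lo;
    rc_s[t] = E.rate_c; rd_s[t] = E.rate_d;

    // decision: the window opens one propagation step after stimulus onset
    // (outputs cannot reflect the stimulus earlier); at the earliest step
    // where a group crosses the threshold the highest-activity crosser wins
    // (ties to the lowest index); if none crosses by the window end, the
    // overall argmax wins.
    if (ntr > 0 && chosen[cur] == NA_INTEGER &&
        t >= trial_onset[cur] + 1 && t <= trial_onset[cur] + window_steps) {
      int best = -1, best_cross = -1;
      double amax = -1e300, amax_cross = -1e300;
      for (int a = 0; a < nout; ++a) {
        double act = E.activity(output_groups[a] - 1);
        if (act > amax) { amax = act; best = a; }
        if (act >= threshold_abs && act > amax_cross) {
          amax_cross = act; best_cross = a;
        }
      }
      int pick = -1;
      if (best_cross >= 0) pick = best_cross;
      else if (t == trial_onset[cur] + window_steps) pick = best;
      if (pick >= 0) {
        chosen[cur] = pick + 1;
        decision_step[cur] = t + 1;            // 1-based for R
        fb_from = t + 1; fb_until = t + 1 + feedback_steps; fb_winner = pick;
        double r;
        if (punished_action[cur] > 0 && pick + 1 == punished_action[cur])
          r = reward_punish;
        else if (pick + 1 == correct_action[cur])
          r = reward_correct;
        else
          r = reward_wrong;
        double delay = R::runif(delay_min, delay_max);
        int rs = t + 1 + (int)std::floor(delay / E.dt);
        reward_mag[cur] = r;
        if (r != 0.0 && rs < nsteps) {
          r_buf[rs] += r;
          reward_step[cur] = rs + 1;           // 1-based
        }
      }
    }

    if ((t + 1) % record_every == 0 && prec < nrec) {
      record_pathways(E, pidx, pathways, prec);
      ptime[prec] = E.time;
      ++prec;
    }
  }

  return List::create(
    _["w"] = NumericVector(E.w.begin(), E.w.end()),
    _["state"] = E.state_out(),
    _["activity"] = activity,
    _["m"] = m_s, _["theta_hi"] = thi_s, _["theta_lo"] = tlo_s,
    _["corr_rate"] = rc_s, _["decorr_rate"] = rd_s,
    _["pathways"] = pathways, _["pathway_time"] = ptime,
    _["chosen"] = chosen, _["decision_step"] = decision_step,
    _["reward_step"] = reward_step, _["reward_mag"] = reward_mag);
}
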