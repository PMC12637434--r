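#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Trial loop for the extended Q-learning family.
//
// choice: 0 = left, 1 = right, NA = no choice (trial skipped by all updates
//   and excluded from the likelihood).
// target: per-trial update target for the chosen option when the trial is
//   rewarded-or-not under CS-as-reward semantics (1 on CS+, 0 on CS-; the
//   conditioned-reinforcer variant passes kappa on uncollected CS+ trials).
// stim:   1 when the stimulation was collected (used only in rpe_mode).
// rpe_mode: stimulation acts as the prediction error itself -- collected
//   trials add alpha_rew * 1 to the chosen value; everything else (CS- and
//   uncollected CS+) decays toward 0.
// literal_eq5: reproduce the printed unchosen-stay update, which decrements
//   the stay value by alpha_stay times the *reward* value of the unchosen
//   option (post forgetting) instead of its stay value.
//
// Returns pre-update trajectories, the choice probability for each trial,
// and per-trial log-likelihood contributions (NA on no-choice trials).
// [[Rcpp::export]]
List cpp_q_model(IntegerVector choice, NumericVector target,
                 IntegerVector stim,
                 double alpha_rew, double alpha_stay, double gamma_forget,
                 double beta_rew, double beta_stay, double bias,
                 bool rpe_mode, bool literal_eq5) {
  int n = choice.size();
  NumericMatrix traj(n, 4); // qrew_l, qrew_r, qstay_l, qstay_r (pre-update)
  NumericVector p_right(n), ll(n);
  double qr[2] = {0.0, 0.0};
  double qs[2] = {0.0, 0.0};
  for (int t = 0; t < n; ++t) {
    traj(t, 0) = qr[0]; traj(t, 1) = qr[1];
    traj(t, 2) = qs[0]; traj(t, 3) = qs[1];
    double pr = sigmoid(bias + beta_rew * (qr[1] - qr[0]) +
                        beta_stay * (qs[1] - qs[0]));
    p_right[t] = pr;
    if (IntegerVector::is_na(choice[t])) { ll[t] = NA_REAL; continue; }
    int a = choice[t];
    int u = 1 - a;
    double pa = (a == 1) ? pr : 1.0 - pr;
    if (pa < 1e-9) pa = 1e-9;
    if (pa > 1.0 - 1e-9) pa = 1.0 - 1e-9;
    ll[t] = std::log(pa);
    // reward-value updates
    if (rpe_mode) {
      if (stim[t] == 1) qr[a] += alpha_rew;            // stimulation as RPE
      else qr[a] += alpha_rew * (0.0 - qr[a]);          // treated unrewarded
    } else {
      qr[a] += alpha_rew * (target[t] - qr[a]);
    }
    qr[u] -= gamma_forget * qr[u];                      // forgetting
    // perseveration updates
    qs[a] += alpha_stay * (1.0 - qs[a]);
    if (literal_eq5) qs[u] += alpha_stay * (0.0 - qr[u]);
    else qs[u] += alpha_stay * (0.0 - qs[u]);
  }
  return List::create(_["traj"] = traj, _["p_right"] = p_right, _["ll"] = ll);
}

// Trial loop for the policy-gradient family (REINFORCE and actor-critic).
// The propensity pi accumulates evidence for Right over Left; the
// actor-critic multiplies each propensity update by the critic's prediction
// error delta = R - V and updates V with learning rate alpha_critic.
// [[Rcpp::export]]
List cpp_policy_model(IntegerVector choice, IntegerVector reward,
                      double alpha_win, double alpha_loss,
                      double beta_win, double beta_loss, double bias,
                      double alpha_critic, bool actor_critic) {
  int n = choice.size();
  NumericVector pi_pre(n), v_pre(n), delta(n), p_right(n), ll(n);
  double pi = 0.0, v = 0.0;
  for (int t = 0; t < n; ++t) {
    pi_pre[t] = pi; v_pre[t] = v;
    double pr = sigmoid(bias + pi);
    p_right[t] = pr;
    if (IntegerVector::is_na(choice[t])) {
      ll[t] = NA_REAL; delta[t] = NA_REAL; continue;
    }
    int a = choice[t];
    double pa = (a == 1) ? pr : 1.0 - pr;
    if (pa < 1e-9) pa = 1e-9;
    if (pa > 1.0 - 1e-9) pa = 1.0 - 1e-9;
    ll[t] = std::log(pa);
    double sgn = 2.0 * a - 1.0;
    double d = reward[t] - v;
    delta[t] = d;
    double alpha = (reward[t] == 1) ? alpha_win : alpha_loss;
    double beta  = (reward[t] == 1) ? beta_win  : beta_loss;
    double scale = actor_critic ? d : 1.0;
    pi = (1.0 - alpha) * pi + sgn * beta * (1.0 - pa) * scale;
    if (actor_critic) v += alpha_critic * d;
  }
  return List::create(_["pi"] = pi_pre, _["v"] = v_pre, _["delta"] = delta,
                      _["p_right"] = p_right, _["ll"] = ll);
}

// State-value trace V_t with prediction error delta_t = R_t - V_t and
// V_{t+1} = V_t + alpha * delta_t, skipping no-choice trials. Returns the
// pre-update value for every trial.
// [[Rcpp::export]]
List cpp_v_trace(IntegerVector choice, IntegerVector reward, double alpha) {
  int n = choice.size();
  NumericVector v_pre(n), delta(n);
  double v = 0.0;
  for (int t = 0; t < n; ++t) {
    v_pre[t] = v;
    if (IntegerVector::is_na(choice[t])) { delta[t] = NA_REAL; continue; }
    double d = reward[t] - v;
    delta[t] = d;
    v += alpha * d;
  }
  return List::create(_["v"] = v_pre, _["delta"] = delta);
}
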