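---
title: "Models and methods: behavioral value learning and striatal value coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: behavioral value learning and striatal value coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valuecode)
```

`valuecode` implements, end to end on synthetic data, the computational
pipeline of a study in which mice work for optogenetic stimulation of
dopamine neurons in a probabilistic reversal learning task, and striatal
populations are analyzed for trial-by-trial value signals. This vignette is
the package's own account of the models, the assumptions behind them, the
tunable parameters, and the numerical choices; the worked examples in the
README show actual output.

## The task and its simulator

The task is a two-alternative wheel-turning choice. On each trial one side
is the high-reward side (reward probability `p_high = 0.7`) and the other
pays at `p_low = 0.1`; rewards are not baited. A rewarded choice triggers a
tone (CS+) and, if the animal licks within 1 s, a 1 s train of dopamine
stimulation; unrewarded choices play a noise burst (CS−). The high side
reverses in blocks whose default length is uniform on [20, 40] trials, but a
block may not advance until the subject has chosen the high-probability side
at least 7 times within the preceding 10 completed choices (debiasing). Two
variants remove the lick requirement, delivering stimulation together with
the CS+ (`no_lick_with_cs`) or omitting the tone entirely while leaving the
reward schedule unchanged (`no_lick_without_cs`).

`simulate_session()` reproduces this structure exactly: Bernoulli outcomes
given choice and block side, uniform block draws, the debias gate, per-trial
event timestamps (quiescent period 0.2–0.5 s, a configurable movement
latency, outcome, lick latency within the 1 s window, 4–5 s inter-trial
interval), and a single seeded RNG stream consumed in a documented fixed
order, so identical inputs give byte-identical sessions. Decisions the task
description leaves open, resolved once here: the debias window is evaluated
only after 10 completed choices exist within the current block (the window
is undefined earlier); timed-out trials produce a CS− and do not count
toward the debias window (only choices are counted); the default block
length is not redrawn while debiasing extends a block; and collection of the
stimulation is modeled as an independent Bernoulli per CS+ trial
(`collection_prob`), since mice sometimes forgo collection but no model of
that behavior is given.

## Behavioral models

Four trial-by-trial learning models predict the choice sequence. All latent
values start at 0 each session and all models choose through a sigmoid.

**Extended Q-learning, CS+ as reward (`q_cs`).** The chosen option's reward
value moves toward a target: $Q^{rew}_{t+1}(a_t) = Q^{rew}_t(a_t) +
\alpha_{rew}(R_t - Q^{rew}_t(a_t))$ with $R_t = 1$ on CS+ trials (whether or
not the stimulation was collected) and 0 on CS− trials. The unchosen
option's value decays, $Q^{rew}_{t+1}(\tilde a_t) = (1 -
\gamma_{forget})\,Q^{rew}_t(\tilde a_t)$. A perseveration value tracks a
leaky average of past choices: the chosen side's $Q^{stay}$ moves toward 1
and the unchosen side's toward 0 at rate $\alpha_{stay}$. Choice probability
is $P_t(R) = \sigma(\mathrm{Bias} + \beta_{rew}\,\Delta Q^{rew}_t +
\beta_{stay}\,\Delta Q^{stay}_t)$ with $\Delta Q = Q(R) - Q(L)$. As printed,
the unchosen-stay update references the unchosen *reward* value on its
right-hand side; we treat that as a typographical slip and update the stay
value toward 0 (the perseveration analog of the unrewarded update), with a
`literal_eq5` flag reproducing the printed form.

**Extended Q-learning, stimulation as RPE (`q_rpe`).** Collected
stimulation adds directly to the chosen value, $Q^{rew}_{t+1}(a_t) =
Q^{rew}_t(a_t) + \alpha_{rew}$, and CS+ trials without collection are
treated as unrewarded. This value is unbounded above by construction (a
property the tests assert rather than hide).

**REINFORCE (`reinforce`).** A single propensity for Right over Left is
updated by $\pi_{t+1} = (1-\alpha_x)\pi_t + (2a_t - 1)\,\beta_x\,(1 -
P_t(a_t))$, with win/loss-specific rates and weights, and $P_t(R) =
\sigma(\mathrm{Bias} + \pi_t)$.

**Actor-critic (`actor_critic`).** A critic tracks state value through the
prediction error $\delta_t = R_t - V_t$, $V_{t+1} = V_t +
\alpha_{critic}\,\delta_t$, and the actor's propensity update is the
REINFORCE update multiplied by $\delta_t$.

A fifth variant (`kappa`) re-fits `q_cs` with the update target on CS+
trials *without* collected stimulation replaced by a free parameter
$\kappa$ (prior $N(0,1)$); $\kappa$ near 1 says an uncollected CS+
reinforces like a collected one — the signature of a conditioned
reinforcer. Sessions with fewer than 5 such trials are excluded.

`reference_q_params()` fixes the package's canonical simulation parameters:
$\alpha_{rew} = 0.24$ (the reported across-session mean for the
best-fitting model), moderate perseveration and forgetting
($\alpha_{stay} = 0.3$, $\gamma_{forget} = 0.2$), no bias, and decision
weights $\beta_{rew} = 2.4$, $\beta_{stay} = 0.9$ calibrated once so that
refitting the model to its own on-policy behavior reproduces the reported
fit quality on real behavior (about 77% accuracy and $-0.48$
log-likelihood per choice). The noise level matters beyond cosmetics: with
high decision weights an agent is far more deterministic than any mouse,
and conclusions that depend on realistic choice stochasticity — most
notably the near-indistinguishability of the model families — do not hold
there.

## Fitting, recovery, confusion

Likelihoods are Bernoulli over completed trials with probabilities clipped
to $[10^{-9}, 1-10^{-9}]$; no-choice trials are skipped by updates and
excluded from likelihoods. Fitting works on a latent scale — log-odds for
rates, identity for weights — with zero-centered Gaussian priors. The
published prior table is not reproduced in the available text beyond
"weakly informative"; weakly informative has to be judged per parameter:
$N(0,1)$ on the log-odds scale covers essentially all of $(0,1)$ for a
rate, but on an unbounded decision weight that routinely reaches 4–6 it is
strongly informative and visibly biases recovery. The defaults are
therefore prior SD 1 for rates (log-odds scale) and 5 for weights, bias,
and similar unbounded parameters, configurable per fit (the
conditioned-reinforcer value $\kappa$ keeps its stated $N(0,1)$ prior).
`fit_session_map()`
maximizes the log posterior from multiple restarts; `fit_hierarchical()`
samples the three-level Gaussian hierarchy (population, subject, session;
flat positive prior on session-level scales) with a Metropolis-within-Gibbs
scheme — conjugate draws for the Gaussian layers, random-walk proposals for
session parameters and scales — and reports split-R-hat. Desk-scale
defaults are 2 chains of 600 iterations (200 warm-up); the heavier
published-style schedule is a parameter, not a different code path.

"Accuracy" is never defined in the source text; the package defines it as
the fraction of trials on which the model assigns the observed choice
probability above one half, ties counted one half. Model comparison reports
within-sample accuracy and log-likelihood per choice, with an optional
blocked cross-validated variant. The confusion analysis follows the
published procedure: simulated data are generated from *the best model of
each family* — each family's best-fit parameters on common reference
behavior at realistic choice noise — every model is fit to every simulated
session, and the winner is scored by held-out likelihood on blocked folds
to avoid rewarding flexibility. At that noise level the held-out margins
between families are on the order of 0.002 log-likelihood units per
choice, and the policy families are recovered near chance. One caveat is
discussed honestly here because it shows up in the acceptance suite: when
a candidate model is the *exact* generator of the reference behavior (our
synthetic world, unlike real mice, has a true model), that model retains a
small but systematic held-out edge on its own simulated data and is
recovered well above chance under winner-take-all scoring. Reproducing
full indistinguishability appears to require the model misspecification
inherent to real behavior. The recovery analysis simulates on-policy at
dispersed known parameters and refits by MAP, optionally applying the
study's session-inclusion rule (at least 9 completed blocks and win-stay
behavior) to the simulated ground truth.

## Decision variables for neural analyses

`extract_decision_variables()` runs a fitted model off-policy over the
observed choices and outcomes and emits, for every trial, the *pre-update*
values — the values in force before that trial's outcome: composite side
values $Q(s) = \beta_{rew} Q^{rew}(s) + \beta_{stay} Q^{stay}(s)$, their
contralateral/ipsilateral relabeling (left hemisphere: contra = Right,
i.e., counterclockwise wheel turns), relative value `dq` (contra − ipsi),
state value `v` (updated by $\delta = R - V$ at rate $\alpha_{rew}$), and
reward-only action values used by the learning-rate sweep. Because slowly
learned values ramp over a session, encoding analyses use residuals from an
ordinary least-squares regression on trial number
(`detrend_trial_variable()`).

## The encoding model

Spiking is binned at 10 ms on a per-trial grid running from 0.6 s before
the go cue to 2 s after the last outcome event, z-scored per neuron with
mean and SD taken over kernel-covered bins only. Six events carry kernels:
go cue (window 0 to +1 s), left and right movement onset (−0.5 to +0.5 s),
CS+, stimulation onset, and CS− (0 to +2 s). Kernels live in a raised-cosine
basis, one cosine per 25 ms of span with half-period twice the spacing, so
the basis tiles each window (constant sum in the interior); spike history
uses 10 raised cosines log-spaced over 10 ms–1 s in the past, lagged at
least one bin so a bin never predicts itself. The design matrix convolves
event indicators (half-open bins, ties to the earlier bin) with the basis,
confined within trials.

The linear stage fits the z-scored activity by lasso, with the penalty
chosen by 5-fold cross-validation over 251 log-spaced values from $10^{-5}$
to $10^{5}$; folds are stratified over trials by block side, choice, and
outcome. The bilinear stage multiplies each event kernel on trial $T$ by a
gain $G_i(T) = \beta^{gain}_{i0} + \sum_k \beta^{gain}_{ik} U_k(T)$ linear
in the trial variables (e.g., `dq` and `v`: 18 predictors for 6 kernels and
2 variables), and alternates kernel estimation (lasso, gains fixed, kernels
unit-normalized each pass) with gain estimation (ridge, kernels fixed, the
intercept and history prediction supplied as a fixed offset). Both
penalties are chosen on the first iteration and frozen; gains start at 1,
so the first iteration coincides with the linear fit; iteration stops when
every coefficient changes by at most 0.001 for three consecutive
iterations. Nested comparisons use the held-out F statistic $F = (\Delta
SSE / \Delta DOF) / MSE_{full}$ on pooled 5-fold cross-validated
predictions; held-out F can be negative and is reported as-is.

**Null calibration.** Event-kernel significance is calibrated by circular
shifts of the binned activity (uniform on [L/10, 9L/10] bins, avoiding
near-zero shifts). Value-gain significance is calibrated by pseudosessions:
surrogate value series cut as contiguous chunks from a pool of other
sessions' values, preserving autocorrelation while breaking alignment; the
gain stage is refit per surrogate with the ridge penalty re-chosen, and the
empirical p is the fraction of null F at least as large as the real F (the
"at least" makes the test conservative when heavy shrinkage produces exact
ties). One design choice deserves emphasis: the kernels frozen for these
comparisons come from the *first* bilinear iteration (gains = 1), not the
last. Final-iteration kernels are estimated from a design scaled by gains
fitted to the real value series, so they embed the real values; freezing
them advantages the real series over every surrogate and inflates the
false-positive rate far above nominal (we measured p ≈ 0 for value-blind
neurons whose surrogate-as-real p-values were uniform). First-iteration
kernels never saw the trial variables, restoring exchangeability; the final
kernels are still used for gain estimates and the learning-rate sweep. Full
per-surrogate bilinear refits would make the same point at roughly a
hundred times the cost. Reported effect sizes are corrected
$\Delta R^2$: the real change in cross-validated variance explained minus
its mean over the null ensemble.

**Learning-rate sweep.** To ask at what timescale activity best reflects
value, reward-only action values are recomputed for 40 linearly spaced
learning rates (0.025–1), detrended, and the gain stage refit per grid
point (penalty re-chosen per point) with kernels frozen; pseudosession
pools are recomputed from the pool sessions at each grid value with chunk
positions shared across the grid. The same procedure sweeps the forgetting
rate, which is expected to move the encoding far less than the learning
rate.

## Population decoding

Linear lasso decoders predict pre-update values from population activity
re-binned at 100 ms, one decoder per time bin: state value from 0.5 s
before to 2 s after the outcome (rewarded trials only), relative value and
per-choice action values from 0.5 s around the go cue (contralateral
choices for relative value and the contralateral action value, ipsilateral
for the other). Evaluation is 5 × 5 nested stratified cross-validation:
trials are discretized by the Freedman–Diaconis rule ($2\,IQR\,n^{-1/3}$;
bins with fewer trials than folds merge into their nearest neighbor; a zero
IQR collapses to plain shuffled folds), the inner folds select the penalty
from eight log-spaced decades ($10^{-6}$–$10^{1}$), and the outer held-out
$R^2$ is averaged. Each decoder size (10–40 neurons) is repeated on random
combinations drawn without replacement. Decoded performance is corrected by
subtracting the mean over pseudosession target series (20 surrogates at
desk scale, the published-style 200 behind the same parameter), with
surrogate draws shared across time bins for variance reduction; negative
corrected values are reported, not clipped.

## The synthetic-data generator

`generate_neuron_spikes()` is the generative twin of the bilinear model and
shares its design-matrix code path, so ground truth lies exactly in the
model span and noiseless Gaussian recovery is exact by construction.
Neurons have unit-norm raised-cosine kernels with random coefficients,
per-event gain offsets, optional planted value-gain coefficients, and
either Gaussian noise on the continuous signal (exact-recovery and
calibration tests) or Poisson counts through a log link (count realism).
`generate_population()` mixes value-coding, event-only, and silent neurons
in stated fractions with ground-truth labels. The effective noise level of
real striatal units is unknowable without the recordings; the defaults
(noise SD 1 for calibration populations, 0.7 with planted gains of ±0.5 for
recovery populations) were pilot-calibrated once so that value-gain
$\Delta R^2$ falls in the printed range of roughly 0–0.05, and are not
revisited per test. What the generator does *not* emulate: drift and
nonstationarity of real recordings, correlated noise across neurons,
refractory structure, behavioral idiosyncrasies beyond the fitted models.
Passing tests therefore demonstrate correctness and calibration of the
pipeline under its own generative assumptions, not performance on real
data.

`synthesize_wheel_trace()` embeds smoothstep displacements at known onsets
in a 1 kHz position trace; the detector (200 ms coarse speed threshold at
1 cm/s, merge gaps under 100 ms, drop movements under 50 ms, precise onset
at the first 5 ms-averaged speed ≥ 0.2 cm/s, found by extending the coarse
period backward) recovers them within 20 ms. Moving averages are centered
(the description does not specify centered vs trailing; centered was chosen
for symmetry and is configurable).

## Numerical choices

Penalized fits use `glmnet` without predictor standardization (the response
is z-scored and the basis is bounded); the cross-validated lasso uses a
convergence threshold of $10^{-5}$ (differences against $10^{-7}$ are in
the fifth decimal of CV error at half the cost) while fixed-penalty refits
inside the bilinear alternation use $10^{-7}$ for iteration stability. The
18-column ridge gain stage is solved in closed form via per-trial
sufficient statistics and an eigendecomposition — exact for the ridge
objective $RSS + \lambda\lVert\beta\rVert^2$ and identical (to $10^{-10}$,
tested) to a row-space fit, which matters because null ensembles and sweeps
refit gains thousands of times. All stochastic steps take explicit seeds;
sub-seeds are derived reproducibly and kept below $2^{31}$.

## Problem sizes

The test and acceptance runs use desk-scale sizes chosen once: reference
sessions of 110 trials on the default encoding grid (≈39,000 10 ms bins),
40 value-blind neurons with 100 pseudosession nulls each for significance
calibration, 20 planted-gain neurons for encoding recovery, 20 neurons × 40
grid points × 10 nulls for the timescale sweeps, 40 QC-passing sessions of 500 trials
for behavioral parameter recovery, 30 simulated sessions of 400 trials for
the confusion analysis, and decoding populations of 45 neurons with 3 repeats and 6–11
surrogates. The published-scale settings (200 nulls, 4 × 1850 MCMC, 100
decoder repeats) are reachable through the same parameters.

## Known limitations

Single-session identifiability of the decision weights is
information-limited: at 500 trials the likelihood supports a standard
error near 1 on $\beta_{rew}$ (recovery errors match the Laplace standard
errors, i.e. the estimator is efficient), so recovered-vs-true
correlations for dispersed weights hover around 0.7 and individual
replicate batches scatter widely around that value; pooling sessions (as
the hierarchical fit does) is the remedy. Relatedly, with an exact
synthetic generator the generating model family retains a small held-out
edge on its own data, so model-confusion experiments reproduce the
near-equivalence of the families' fits but not complete
indistinguishability under winner-take-all scoring (see the confusion
section). The hierarchical sampler is a desk-scale
Metropolis-within-Gibbs scheme;
for large cohorts a Hamiltonian sampler would mix faster (the model
contract is identical). Significance comparisons freeze value-independent
first-iteration kernels, as discussed, which is a deliberate deviation from
freezing final-iteration kernels. The spike container is a plain-text
JSON + sparse-CSV pair rather than HDF5. Region-comparison hypothesis tests
across anatomical subdivisions are thin reporting wrappers around standard
tests and are not modeled further.
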