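# valuecode

Behavioral value models and neural value-coding analyses for a
two-alternative probabilistic reversal learning task in which mice work for
optogenetic stimulation of midbrain dopamine neurons. The package is aimed
at systems-neuroscience labs that need the full computational chain —
task simulation, trial-by-trial learning models, penalized spike-train
encoding and decoding with calibrated significance — as tested, reusable
code that runs end to end on synthetic data with known ground truth.

## What it implements

**Task.** A reversal task with 70%/10% reward blocks of uniform default
length 20–40 trials, a debiasing rule (blocks only advance after ≥ 7
high-side choices in the last 10), a lick-to-collect stimulation reward,
and the no-lick variants with and without the CS+ tone
(`task_config()`, `simulate_session()`).

**Behavioral models.** Four learning models predict choices through a
sigmoid policy: extended Q-learning with the CS+ as reward,

&nbsp;&nbsp;&nbsp;&nbsp;*Q<sup>rew</sup><sub>t+1</sub>(a) = Q<sup>rew</sup><sub>t</sub>(a) + α<sub>rew</sub>(R<sub>t</sub> − Q<sup>rew</sup><sub>t</sub>(a))*,&nbsp;&nbsp;
*P<sub>t</sub>(R) = σ(Bias + β<sub>rew</sub>ΔQ<sup>rew</sup> + β<sub>stay</sub>ΔQ<sup>stay</sup>)*,

with forgetting of the unchosen option and a perseveration value; a variant
where collected stimulation acts directly as the prediction error;
REINFORCE; and an actor-critic whose propensity updates are scaled by
δ = R − V. Fitting is MAP with latent-scale priors or a three-level
hierarchical Bayesian sampler; recovery, confusion, and model-comparison
diagnostics are built in, as is the conditioned-reinforcer re-fit in which
the value κ of an uncollected CS+ is a free parameter
(`fit_session_map()`, `fit_hierarchical()`, `recovery_analysis()`,
`confusion_analysis()`, `fit_csplus_value()`).

**Encoding.** A bilinear spike-train model: raised-cosine event kernels
(go cue, movement onsets, CS+, stimulation, CS−) scaled on each trial by
gains linear in model-derived values, *G<sub>i</sub>(T) = β<sub>i0</sub> +
Σ<sub>k</sub> β<sub>ik</sub> U<sub>k</sub>(T)*, alternating lasso (kernels)
and ridge (gains) with cross-validated penalties. Significance is
calibrated empirically: circular-shift nulls for event kernels,
pseudosession nulls for value gains, with null-mean-corrected ΔR² as the
effect size, plus a 40-point learning-rate sweep of the encoding
(`fit_bilinear_encoding()`, `encode_neuron()`, `sweep_value_timescale()`).

**Decoding.** Time-resolved lasso decoders of pre-update Q<sub>contra</sub>,
Q<sub>ipsi</sub>, ΔQ, and V with 5×5 nested stratified cross-validation
(Freedman–Diaconis strata) and pseudosession-corrected R²
(`nested_cv_decode()`, `time_resolved_decode()`, `correct_decoder_r2()`).

**Synthetic data.** Generators for spike trains from the bilinear model's
generative form (Gaussian or Poisson noise), labeled populations with
planted value gains, and wheel traces with known movement onsets, so every
stage is testable without recordings (`generate_population()`,
`synthesize_wheel_trace()`, `detect_wheel_onsets()`).

## Worked example

```r
library(valuecode)
params <- reference_q_params()
sim <- simulate_on_policy(params, "q_cs", task_config(), n_trials = 500, seed = 7)
print(sim$session)
#> <session_data 'sim'> 500 trials, 15 blocks, left hemisphere, 46.8% rewarded
round(unlist(sim$summary[c("p_stay_csplus", "p_stay_csminus")]), 3)
#>  p_stay_csplus p_stay_csminus
#>          0.828          0.677
```

The simulated agent completed 15 blocks and was rewarded on 46.8% of
trials; it repeats its previous choice more often after a CS+ (0.83) than
after a CS− (0.68) — win-stay behavior on top of a perseveration tendency.
Refitting the model to its own choices:

```r
fit <- fit_session_map(sim$session, "q_cs", seed = 1)
print(fit)
#> <fit_result q_cs> LL/choice -0.4513, accuracy 0.802
#>    alpha_rew   alpha_stay gamma_forget     beta_rew    beta_stay         bias
#>       0.3017       0.3009       0.2815       2.3155       0.9978      -0.0217
```

The fit assigns the observed choice probability > 0.5 on 80.2% of trials at
a mean log-likelihood of −0.451 per choice — close to the fit quality the
model achieves on real behavior — and the generative parameters
(α<sub>rew</sub> 0.24, β<sub>rew</sub> 2.4, β<sub>stay</sub> 0.9) are
recovered up to single-session noise. The decision variables fed to the
neural analyses are the pre-update values:

```r
values <- extract_decision_variables(sim$session, fit$params_obj, "q_cs")
head(round(values[, c("q_contra", "q_ipsi", "dq", "v", "p_right")], 3))
#>   q_contra q_ipsi    dq     v p_right
#> 1    0.000      0 0.000 0.000   0.495
#> 2    0.999      0 0.999 0.302   0.727
#> 3    1.697      0 1.697 0.512   0.842
```

Row 1 is all zeros (values are pre-update and initialized at zero); after a
rewarded first choice the contralateral composite value and the state value
rise, and the choice probability follows.

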