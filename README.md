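# sspflanker

Shrinking-spotlight diffusion modeling of attention in the arrow flanker
task, for cognitive scientists studying attentional control — including how
brief state inductions (focused attention, open monitoring, active control)
shift latent attentional parameters.

## The model

In the five-arrow flanker array (items of unit width, target centred at 0,
flankers at ±1, ±2), attention is a Gaussian spotlight whose standard
deviation narrows linearly,

    sd_a(t) = max(sd_a0 − r_d · t, 0.001)

Each item's activation a_i(t) is the spotlight's normal-CDF mass over its
slot (the five activations sum to 1). The drift of a single-accumulator
diffusion X_t = X_{t−1} + N(v_t, σ), σ = 7 at 1-ms steps, is

    v(t) = P · Σ_i (±1) a_i(t)

with flanker signs positive on congruent and negative on incongruent
trials, so congruent drift is exactly P while incongruent drift starts
negative and rises as the spotlight converges. A response fires when X
reaches +b (correct) or −b (error); response time adds a zero-truncated
normal nondecision component (mean Ndt, SD Ndtσ).

The six parameters [sd_a0, r_d, P, b, Ndt, Ndtσ] are estimated by fitting
binned RT distributions — CDF sextiles (0.1, 0.3, 0.5, 0.7, 0.9, 1) of
correct RTs and conditional-accuracy quartiles (0.25, 0.5, 0.75, 1) of all
trials — minimising summed −2 log binomial cell probabilities with
multistart Nelder-Mead over simulated predictions, then a four-stage
hierarchical scheme: population → condition deltas → participant deltas →
observation noise. Goodness of fit uses χ² = N_i Σ (p_ij − π_ij)²/π_ij and
RMSEA; condition effects use within-subject ANOVA with estimated-marginal-
means contrasts, plus the trade-invariant convergence ratio sd_a0/r_d (ms
to reach the minimal window).

## Worked example

```r
library(sspflanker)
p <- ssp_parameters(sd_a0 = 1.8, r_d = 0.017, p_input = 0.6,
                    boundary = 60, ndt_mean = 250, ndt_sd = 30)
trials <- simulate_trials(p, n_congruent = 1000, n_incongruent = 1000, seed = 1)
summarize_trials(trials)
#> congruent: n = 1000 (correct 826)
#>   CDF edges (ms): 253.2, 287, 312.5, 343.6, 400.5
#>   CAF accuracy:   0.804, 0.816, 0.856, 0.828
#> incongruent: n = 1000 (correct 508)
#>   CDF edges (ms): 268.2, 307.3, 342.4, 378.3, 442.1
#>   CAF accuracy:   0.368, 0.388, 0.492, 0.784
```

Congruent accuracy is flat across RT quartiles while incongruent accuracy
climbs from 0.37 to 0.78 — the fast-error signature of a wide early
spotlight. Refit the parameters from the data alone (the `"desk"` profile
is a scaled-down multistart budget for interactive use):

```r
fit <- fit_dataset(trials, control = fit_control("desk"), seed = 2)
fit
#> SSP fit: deviance 133.65 (best of 5 starts)
#>    sd_a0      r_d  p_input boundary ndt_mean   ndt_sd
#>   2.8642   0.0483   0.7335  52.4199 268.0884  39.8838
#> chi-square 17.7 on 12 df (acceptable fit)
convergence_ratio(fit$params[["sd_a0"]], fit$params[["r_d"]])
#> [1] 59.3
```

At this small scale sd_a0 and r_d are individually loose (they trade off
strongly — hence the stable ratio), while the fit is statistically
acceptable; recovery sharpens with the 25,000-trial datasets used in the
validation suite. For a full synthetic study and pipeline:

```r
study <- generate_study(study_design(n_participants = 8,
                                     trials_per_condition = 128), seed = 1)
res <- run_pipeline(pipeline_config(profile = "desk", seed = 1,
                                    n_participants = 8,
                                    trials_per_condition = 128),
                    out_dir = "ssp-out")
res$anova          # condition ANOVA per parameter
```

`run_pipeline()` writes trial data, per-stage estimates, fit statistics,
condition analyses and a JSON run manifest; rerunning from the same
configuration and seed reproduces every estimate exactly. A thin CLI over
the same functions lives at `inst/scripts/ssp-pipeline.R`.

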