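# gazetrade

Decisions often combine information learned from past outcomes with
information perceived right now. `gazetrade` studies that combination in a
two-armed bandit whose options are compound stimuli: a coloured circle whose
reward probability (0, 0.5 or 1) must be learned by trial and error, and a
ring of 12 Landolt Cs of which 3, 6 or 9 face upward, the up-count mapping
linearly onto reward probability. The two components contribute additively
with equal weight, so the true reward probability of a combined stimulus is
(p_color + p_cs) / 2. Perceptual evidence arrives only through fixations,
which makes information gathering observable with an eye tracker; the colour
value must be retrieved from memory. The package is for computational
cognitive scientists who want to simulate, fit and analyse this class of
gaze-contingent evidence-accumulation tasks.

## The model

A generative *gather/look/choose* agent makes a sequence of decisions within
each trial, indexed t = 1, 2, ... (event t follows t−1 completed fixations):

- **gather vs choose**:
  p(continue) = logistic(α_gather + β_ΔCs·|ΔV_Cs| + β_Δcolor·|ΔV_color| +
  β_time·(1 − τ^t)) — a negative β_Δcolor means decisive colour values
  suppress further perceptual sampling, the hypothesised trade-off;
- **where to look**:
  p(look right) = logistic(α_look + β_look-color·ΔV_color +
  β_look-Cs·ΔV_Cs + β_stay·I(last looked right)), the fixated C uniform over
  the ring's unseen Cs;
- **what to choose**:
  p(choose right) = logistic(β_choose·(ΔV_Cs + ω_color·ΔV_color)).

ΔV_Cs comes from a binomial posterior over each side's up-count given the
orientations fixated so far; ΔV_color comes from temporal-difference
learning with learning rate 1/(ε + n/2), retrieved within a trial at rate
1 − τ_color^t (at τ_color = 0.2324, 94.6% of the learned value is available
by the second event). A joint likelihood over fixation sequences, stops and
choices supports hierarchical empirical-Bayes fitting by iterative
importance sampling (`iis_fit()`), integrated-BIC comparison of the full
model against variants lacking the colour term in the gather or look
decision (`compare_models()`), fixation-report parsing with interest-area
assignment and repeat-fixation filtering, a synthetic-cohort generator with
known ground truth, and the regression-based trade-off analyses.

## Worked example

```r
library(gazetrade)

co  <- generate_cohort(cohort_spec(n_participants = 8, seed = 1))
fit <- iis_fit(co, n_samples = 1000, max_iters = 10, seed = 2)
fit
#> Hierarchical fit ('full' model): 8 participants, 1000 importance samples/iter
#> Stopped after 10 iteration(s); sum log marginal = -11121.97; iBIC = 22500.63

cor(co$true_params[, "omega_color"], fit$posterior_means[, "omega_color"])
#> [1] 0.75

cm <- fit_choice_model(lapply(co$data, build_predictors), formula = "combined")
cm
#> Choice model 'combined': 8 participants fit (total BIC 2542.3)
#>         term    mean      se      t        p
#>  (Intercept) 0.01187 0.06567 0.1808 0.861654
#>  z_dCs_instr 0.21107 0.04048 5.2141 0.001234
#>    z_dPcolor 0.55120 0.11793 4.6738 0.002277
```

The fit recovers the generating structure: the group tendency to keep
gathering is positive (α_gather ≈ 2.2), the colour influence on stopping is
negative (β_Δcolor ≈ −1.7), and per-participant colour weights correlate
r = 0.75 with their ground-truth values. The choice regression shows both
information sources driving decisions (both z-scored predictors positive and
significant across the 8 simulated participants). The trade-off's gaze
signature is visible directly: these participants fixate on average 1.0
fewer Cs on combined than on Cs-only trials, because a decisive colour
difference makes further perceptual sampling unnecessary.

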