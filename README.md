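# dichoptr

Simulation and analysis of dichoptic psychophysics experiments that track
short-term ocular dominance plasticity — for visual psychophysicists and
methodologists who want to exercise a full binocular-measurement pipeline
(stimuli, adaptive estimation, session statistics, power analysis) on
synthetic observers with known ground truth.

The package covers two measures, on the session schedule of a
deprivation experiment (one pre-deprivation session, five post-deprivation
sessions at 0/10/20/30/40 min):

* **Binocular phase combination.** Horizontal gratings with
  equal-and-opposite phase shifts of ±22.5° are fused; the perceived
  (cyclopean) phase indexes each eye's weight. A weighted vector-sum
  observer gives φ = atan(((a_d − a_n)/(a_d + a_n))·tan θ₀); averaging the
  two stimulus configurations as (φ₁ − φ₂)/2 cancels additive report bias
  exactly.
* **Interocular correlation (IOC) sensitivity.** Dichoptic noise pairs
  blend a shared carrier C_C with eye-specific carriers under
  complementary sinusoidal envelopes, M_C(x) = (1 + M sin 2πf_m x)/2 and
  M_eye = 1 − M_C, giving local interocular correlation
  ρ = M_C²/(M_C² + M_eye²) in closed form. Sensitivity versus spatial
  frequency follows the four-parameter truncated log-parabola
  (peak gain γ_max, peak frequency f_max, bandwidth β, truncation δ), and
  a quick Bayesian adaptive procedure (posterior over a 4-D lattice,
  expected-posterior-entropy stimulus selection, Weibull 2AFC link)
  estimates it in ~100 trials; `aulio_csf()` summarises it as the area
  under the log sensitivity function over 0.94–2.54 c/d.

Around these sit a synthetic cohort generator (null model: no change
across sessions; deprivation model: an immediate N(19.2, 7.0)° shift
decaying with τ = 15 min), repeated-measures ANOVA with Mauchly's test and
Greenhouse–Geisser correction, a BIC approximation to BF₀₁, and exact
noncentral-t power / minimum-sample-size calculations.

## Worked example

```r
library(dichoptr)

# canonical design numbers
min_sample_size_t(power_spec(1.39, 1.24))    # minimum n for a 1.39 ± 1.24 dB effect
#> [1] 7
min_sample_size_t(power_spec(19.2, 7.0))     # minimum n for a 19.2 ± 7.0 deg effect
#> [1] 3
alternation_schedule(7, 0.5)$occluded_ms_rounded   # per-eye occlusion at 7 Hz
#> [1] 71

# a full null experiment: 10 observers, 6 sessions, 16 phase trials each
cohort  <- make_cohort(10, "null", seed = 1)
dataset <- simulate_experiment(cohort, experiment_protocol(measures = "phase"))
analyze_sessions(dataset, "phase")
#> Session analysis of phase changes (post-deprivation sessions)
#> Repeated-measures ANOVA (n = 10 subjects)
#>   condition: F(4, 36) = 1.177, p = 0.3374
#> BF01 = 115.843 (decisive evidence for the null; BIC approximation)
```

The ANOVA row reads: across the five post-deprivation sessions, the
baseline-subtracted perceived-phase changes do not differ (F(4, 36) =
1.18, p = 0.34 — Mauchly's test did not reject sphericity, so the df are
uncorrected), and the Bayes factor favours the no-change model, as it
should for a null cohort. A deprivation cohort (`make_cohort(10,
"deprivation", ...)`) instead shows an immediate ~18° negative shift that
decays across sessions.

```r
# one adaptive estimation session against a known observer
fit <- run_qiocsf_session(iocsf_params(10, 1.5, 3, 0.5), seed = 1)
fit
#> Adaptive sensitivity-function fit (100 trials, 79% correct)
#> Truncated log-parabola sensitivity function
#>   peak gain      11.38 (log10 = 1.056)
#>   peak frequency 2.405 c/d
#>   bandwidth      4.288 octaves
#>   truncation     0.8044 log10 units
```

A single 100-trial session pins down the peak gain well (log10 error here
0.056; the test suite's calibration puts the median at ~0.04 over 100
sessions) while the shape parameters carry more single-session spread.
`tidy(fit)` sets estimates beside ground truth, `autoplot(fit)` overlays
the estimated and true sensitivity functions, and
`glance(analyze_sessions(dataset, "aulio"))` runs the same session
statistics on the area under the fitted log sensitivity functions.

See the vignette (`vignettes/dichoptic-simulation.Rmd`) for the models,
their assumptions, and every tunable default.

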