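# eegage

Peak alpha frequency (PAF) estimation and EEG-based age prediction from
resting-state spectra, with a fully synthetic test bed.

The alpha rhythm of resting, eyes-closed EEG slows with age, and both its
peak frequency and the shape of the broad 0.1–45 Hz spectrum are candidate
brain-age biomarkers. `eegage` is aimed at researchers who want a tested,
reproducible implementation of that analysis chain: DC-EEG cleaning
(Savitzky–Golay baseline, ±120 uV artifact flagging, greedy channel
exclusion, largest common clean segment, common-average reference),
autoregressive (covariance method, order 256) and Welch spectral
estimation on the log2-amplitude scale, five PAF estimators, partial
least squares age models with permutation factor selection and VIP,
recursive weighted PLS, PARAFAC/trilinear PLS on the
participant × channel × frequency tensor, and a method-agreement
statistics layer (Bland–Altman, Hotelling–Williams dependent-correlation
tests, MINQUE variance components, JZS Bayes factors).

The spectral model at the core (fitted for the M-PAF estimator) writes the
log2-amplitude spectrum as an aperiodic background plus five Gaussian band
peaks:

    log2 A(f) = A0 (0.1 f)^m + sum_i Ai exp(-((f - mu_i)^2) / (2 s_i^2)) + k,  m < 0

with band centres constrained to 1–7, 7–13, 13–21, 21–29 and 29–47 Hz.
The alpha centre mu_2 is the M-PAF. A synthetic cohort generator plants a
known alpha-slowing trend (0.25 Hz per decade by default) together with
drift, artifacts and demographics, so every stage is testable with known
ground truth and no data download.

## Worked example

Generate a small synthetic participant, synthesize two minutes of EEG,
clean it, and estimate PAF three ways:

```r
library(eegage)

coh <- generate_cohort(cohort_spec(n_participants = 2, seed = 2,
                                   paf_residual_sd = 0.3))
p   <- coh$participants[[1]]
p$true_params$bands$mu[2]          # ground-truth alpha centre
#> [1] 10.15836

eeg <- synthesize_timeseries(p, duration_s = 240, seed = 101)
cl  <- clean_eeg(eeg)
#> Warning: target duration 100 s unreachable; best segment 81.8 s
cl
#> clean_result: 15 channels, samples 13146-54067 (81.8 s), 4 dropped

sp  <- channel_log2_spectra(cl$segment, fs = cl$fs)
sv  <- svd_first_component(t(sp$values))
round(sv$variance_fraction, 3)     # first component dominates
#> [1] 0.997

naive_paf(sp)$value                # N-PAF: mean per-channel peak, Hz
#> [1] 10.04667
direct_paf(sv)$value               # D-PAF: SVD-component peak, Hz
#> [1] 10.1
fit <- fit_spectral_model(sv$component_spectrum, seed = 3)
modeled_paf(fit)$value             # M-PAF: fitted alpha centre, Hz
#> [1] 10.17671
round(fit$adj_r2, 4)
#> [1] 0.9956
```

This record drew two montage-wide artifact pulses, so the cleaner warns
that the 100 s target was unreachable and settles for the best 81.8 s
common segment after dropping four channels — plenty for the order-256
AR fit. The three estimates bracket the planted 10.16 Hz centre, and the spectral
model fits the summary spectrum with an adjusted R^2 above 0.99. A whole
cohort runs through `run_analysis(run_config(...))`, which writes the PAF
table, the PLS / R-PLS / trilinear-PLS EEG-age tables and the statistics
battery (correlation matrix, Bland–Altman grid, variance components,
Bayes factors) as CSV/JSON artefacts plus a manifest.

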