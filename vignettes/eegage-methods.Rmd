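---
title: "Methods: peak alpha frequency and EEG-based age estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak alpha frequency and EEG-based age estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The dominant rhythm of resting, eyes-closed human EEG — the alpha rhythm —
slows with age, and its peak frequency (PAF) is one of the oldest candidate
brain-age biomarkers. `eegage` implements a complete analysis chain for
this question: it cleans DC-coupled multichannel EEG, estimates amplitude
spectra, derives PAF by five estimators in common use, predicts
chronological age from the broad 0.1–45 Hz spectrum with latent-variable
regressions, and compares all the resulting brain-age estimates with a
method-agreement statistics battery. A synthetic cohort generator with
known ground truth makes every stage testable without recorded data.

## The spectral model

All spectral work happens on the log2-amplitude scale,
$\log_2 A(f) = \tfrac12 \log_2 P(f)$, which stops the very large
low-frequency power of DC-EEG from dominating least squares and
correlation analyses. The parametric model at the heart of the M-PAF
estimator writes the log2-amplitude spectrum as an aperiodic background
plus five Gaussian band peaks (theta, alpha, beta1, beta2, gamma):

$$
\log_2 A(f) \;=\; A_0\,(0.1 f)^{m} \;+\;
\sum_{i=1}^{5} A_i \exp\!\left(-\tfrac12
\left(\frac{f-\mu_i}{\sigma_i}\right)^{2}\right) \;+\; k,
\qquad m < 0 .
$$

The frequency is pre-scaled by 0.1 inside the power law, so the aperiodic
term equals $A_0$ at 10 Hz whatever the exponent; this normalisation is
fixed project-wide and shared by the generator and the fitter, so
round-trip recovery is well defined. Constraints follow common practice:
$m<0$, $0 \le A_i \le 10$, band centres $\mu_i$ within 1–7, 7–13, 13–21,
21–29 and 29–47 Hz, and maximum widths 15, 10, 30, 30 and 30 Hz. The fit
is bound-constrained Levenberg–Marquardt with an analytic Jacobian,
multi-started: one guided start (a lower-envelope aperiodic prefit whose
exponent is profiled on a grid, plus per-band peak detection on the
detrended residual), three variants of it (width rescalings and a
weak-bands-off version), and `n_starts` (default 10) random starts.
Because the SSE surface has peak-assignment local minima — a bloated
Gaussian in one band can absorb a neighbouring band's hump — the best
solution is refined by band-wise and pairwise re-detection and, when the
residual is still smooth (lag-1 autocorrelation above 0.3, the signature
of structured misfit rather than noise), by a coarse scan of one band
centre at a time. The round-trip tests assert that on noise-free
self-generated spectra every generating parameter comes back within its
stated tolerance (band centres to 0.05 Hz), and that on noisy spectra
the adjusted $R^2$ stays above the 0.96 floor that real-data fits of
this model family exhibit.

## The five PAF estimators

* **N-PAF** — per channel, the highest-amplitude local maximum of the AR
  log2-amplitude spectrum within 7–13 Hz (sign change of the first
  difference; band edges never count; exact ties go to the lower
  frequency); the summary is the unweighted mean over channels with a
  peak. Channels without a peak are recorded as missing, never invented.
* **D-PAF** — the same peak rule applied to the first component of the
  SVD of the channel-by-frequency matrix, i.e. a common-variance-weighted
  summary spectrum ($\sigma_1 v_1$, sign fixed so the mean channel
  loading is positive).
* **M-PAF** — the fitted alpha-Gaussian centre $\mu_2$ of the spectral
  model above, fitted to the same SVD component.
* **C-PAF** — channels are admitted only when the log power of their
  alpha peak (smoothed Welch spectrum) exceeds a linear background
  regression of log power on log frequency (1–40 Hz, alpha excluded) by
  at least one residual SD; admitted peak frequencies are averaged with
  SNR weights (peak minus predicted background). Fewer than
  `min_channels` (3) admissible channels gives a missing estimate.
* **K-PAF** — per channel, the individual alpha band is bounded by the
  nearest zero-gradient points on each side of the alpha peak within a
  5–15 Hz search window, and the channel PAF is the amplitude-weighted
  mean frequency (centre of gravity) over that band; channels without
  enclosing minima are missing. The summary weights channels equally
  (the amplitude weighting lives inside the CoG, not across channels).

Two open points in the description of the C and K procedures were fixed
as package decisions: the C-PAF background regression uses log frequency
as the predictor, and K-PAF falls back to a missing value when no
enclosing minima exist. The latter matters: on perfectly smooth steep
spectra the right-hand minimum may genuinely not exist, which is why the
estimator-agreement test uses a gentle aperiodic slope.

## Spectral estimation

The AR route uses the covariance method (non-windowed least squares) at
order 256 — a 512 ms lag window at 500 Hz — with the one-sided density
evaluated on the fixed 0.1–45 Hz grid at 0.1 Hz. The normal equations
are built by a shift recursion in compiled code ($O(np + p^2)$ rather
than $O(np^2)$) and solved with a condition check; a genuinely
band-limited signal with no out-of-band energy makes them singular,
which is a diagnostic, not a nuisance (see the generator notes below).
The Welch route uses a 4096 ms Hamming window with 50% overlap
(0.244 Hz bins), normalised by mean power over the analysis band and
smoothed with a 5th-order, 11-bin Savitzky–Golay filter, as the C/K
estimators expect. PSD scaling is one-sided density in uV^2/Hz with
taper power compensated; only spectral shape matters downstream, but a
fixed convention keeps Parseval tests meaningful.

## Cleaning

DC-EEG wanders. Each channel is demeaned, a time-varying baseline is
computed by a 3rd-order, 1025-sample (± 2.048 s) Savitzky–Golay filter,
and samples deviating from that baseline by more than ±120 uV are
flagged. At record boundaries the polynomial is fitted on the truncated
window rather than on padded data, to avoid fabricated extremes. A
sample is clean only if clean on **all** retained channels — required
for a common contiguous multichannel segment — and the largest such run
is selected. When it falls short of the 100 s target, a greedy loop
drops the channel whose removal most lengthens the segment (at most
`max_drop = 16`). The common average reference is applied after
cropping, so excluded channels cannot contaminate the average; whether
the ±120 uV criterion applies pre- or post-referencing is not settled
usage, and this package applies it pre-referencing. The full order is
fixed: demean, baseline, flag, exclude, crop, re-reference; flagging
never alters sample values.

## Age models

The predictor for the PLS age model is each participant's SVD summary
spectrum ($\sigma_1 v_1$; the singular-value scaling is retained so
overall amplitude differences stay visible to the model). PLS1 is
implemented as NIPALS with OLS on the latent scores. The number of
factors is chosen by permutation: factor $k$ is kept when its
incremental explained response variance has permutation p-value
$\le 0.05$ against `n_perm = 1000` full sequential refits with shuffled
ages, stopping at the first failure — the standard
$(1+\#\{perm \ge obs\})/(n_{perm}+1)$ convention, which is exactly
calibrated at the nominal level. VIP scores use the usual weighted
formula (mean squared VIP equals 1 by construction). R-PLS multiplies
each predictor column by $|\beta|/\max|\beta|$ per iteration, dropping
columns whose cumulative weight falls below $10^{-3}$ of the maximum,
until the support stabilises (cap 50 iterations); the reported model is
refitted on the surviving frequencies of the unweighted predictors.
Reported correlations and RMSEs are in-sample, matching how such
regressions are usually displayed alongside scatterplots; RMSE divides
by $n$ (the "error of estimation" convention), with the residual-df
divisor available as an option.

The tensor route keeps channels as a mode:
participants x channels x frequencies. PARAFAC is fitted by alternating
least squares from random starts (25 replications per factor count,
relative SSE tolerance 1e-8, cap 2500 iterations; best-SSE replicate
kept; unit-norm channel and frequency loadings with magnitudes absorbed
into participant scores), and the factor count is judged by SSE,
iteration counts and CORCONDIA — 100 times one minus the normalised
distance between the least-squares Tucker core implied by the loadings
and the superdiagonal identity. Trilinear PLS1 takes, per factor, the
dominant singular pair of the response-covariance matrix
$Z_{jk}=\sum_i y_i X_{ijk}$ on centred data, scores
$t_i=\sum_{jk}X_{ijk}w_j w_k$, deflates, and finally regresses age on
all scores jointly.

## Statistics layer

Bland–Altman agreement (bias, SD of differences, ±1.96 SD limits, and a
proportional-error slope of differences on pair means), paired t-tests
with documented degenerate handling, Pearson and partial correlations,
and a dependent-correlation test in the Hotelling–Williams form with
$df=n-3$ (among the textbook variants, this one was adopted and
Monte-Carlo calibrated: empirical type-I error is 0.05 ± 0.01 at 2000
null simulations). Variance components of the participants-by-channels
N-PAF grid use MINQUE with all prior weights 1 (scheme 1) on the
two-way crossed model $y_{pc}=\mu+a_p+b_c+e_{pc}$, supporting missing
cells; on balanced data it coincides with the ANOVA estimators, which is
the test oracle. Negative raw components are truncated to zero for the
reported proportions, raw values preserved. Bayes factors for nested
regressions use the JZS mixture-of-g prior with $r=0.354$, evaluated by
adaptive quadrature of the one-dimensional $g$-integral (cross-checked
against Monte-Carlo importance sampling within 2%); different numerical
schemes in other software can differ in the third digit.

## The synthetic cohort generator

The generator is the package's study design, not a tuning knob. Defaults:
60 participants, 10 per decade from 20–78; true alpha centre
$10.8 - 0.025 \cdot \mathrm{age}$ Hz plus Gaussian residual (0.9 Hz by
default, so the cohort-level PAF–age correlation lands near −0.5),
clipped to 7.2–11.8 Hz; band amplitude/width ranges
$A_2 \in [1,3]$, $\sigma_2 \in [0.8,1.5]$, other bands low-amplitude
($A_i \le 0.5$); aperiodic $A_0 \in [3.5,4.5]$, $k \in [-2.5,-1.5]$.
Demographics are linear-Gaussian: NART errors fall with age so that
NART-IQ correlates with age around +0.5, QMCI drifts weakly negative
with age, GDS-15 is Poisson(2) — signs only, mirroring how such panels
usually look.

Two generator choices deserve emphasis.

* **Aperiodic exponent.** On the log2-amplitude scale the term
  $A_0 (0.1f)^m$ grows explosively toward low frequencies. With
  $A_0 \approx 4$, an exponent of $-0.6$ would put the 0.25 Hz amplitude
  about $2^{30}$ times above alpha — no physiological recording looks
  like that, and the implied dynamic range destroys AR estimation in
  double precision. The default exponent range is therefore
  $[-0.35, -0.18]$, the magnitude real spectra imply for this
  functional form (low-frequency-to-alpha amplitude ratios of roughly
  10–300).
* **Out-of-band noise floor.** Time series are realised by inverse-FFT
  spectral shaping (random phases, 0.25–45 Hz) with a broadband noise
  floor at one quarter of the 45 Hz model power. Without it the record
  would be strictly band-limited at a 500 Hz rate, hence perfectly
  linearly predictable, and the AR normal equations would be singular —
  real amplifiers always contribute broadband noise.

One common scale factor per recording brings the cohort-average channel
RMS to 20 uV, preserving the posterior>anterior alpha-gain gradient
(0.5 frontal to 1.2 occipital across the default 19-channel 10–20
montage — a deliberately reduced but standard montage that keeps the
default cohort tractable; the topography is qualitative, not a map of
any particular dataset). Slow drift is a Gaussian-smoothed random walk
(~10 s timescale, 40 uV SD), and transient artifacts are Poisson-placed
half-sine pulses of 150–500 uV and 100–300 ms, 95% of them on 1–3
random channels and 5% montage-wide, logged so tests can verify that
every planted pulse is flagged.

What the generator does **not** emulate: eye movements and other
structured biological artifacts, electrode impedance effects, line
noise, nonstationarity of the rhythms, or any real scalp topography.
Passing tests therefore demonstrate that the estimators and models
recover what this spectral model plants under realistic noise, drift
and artifact load — not that they are robust to everything real EEG
contains. In the same spirit, the default cohort carries age information
only through the alpha-centre trend; real spectra carry broader age
structure, which is why the in-sample PLS age correlation here needs
about six latent factors to clear 0.6 while much stronger correlations
are reported on real cohorts with two.

## Problem sizes and numerical choices

The test suite runs the full pipeline once at the study scale (60
participants, 120 s each) and keeps every other check on reduced sizes
(tiny montages, 30–60 s records, tensors of a few hundred entries),
which together hold the suite to a few minutes while still exercising
each code path at scale once. Tolerances: noise-free round trips are
asserted to 0.05 Hz on band centres; stochastic recoveries use
Monte-Carlo error bands; calibration
checks use 0.05 ± 0.01 at 2000 simulations. Degenerate inputs have
defined behaviour throughout: constant responses give mean predictions
and zero coefficients, zero-variance paired differences give t = 0 or
±Inf explicitly, peakless spectra give missing PAF estimates, and empty
clean segments are an explicit empty-interval state.

## Known limitations

In-sample regression metrics overstate out-of-sample accuracy; the
package reports them because that is the convention it mirrors, and
additionally reports leave-one-out cross-validated predictions
(`pls_loocv()`, included in the pipeline's age-model output) as the
honest companion number — on synthetic cohorts the gap between the two
is a useful reminder of how much in-sample fits flatter. The EDF
binary format is not read — delimited channels-by-samples text is the
raw-EEG interchange format. PARAFAC rank scans at the full default
tensor size are expensive and therefore off by default in the pipeline;
the scan function is exported for interactive use.
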