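---
title: "Methods: dyadic fNIRS synchrony from raw intensity to mixed-model inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic fNIRS synchrony from raw intensity to mixed-model inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

`dyadsync` implements a complete analysis chain for mother--child fNIRS
hyperscanning of free conversation: two-wavelength raw intensities are
converted to oxy-/deoxy-hemoglobin concentration changes, neural synchrony
between homologous channels of the two partners is quantified by Morlet
wavelet transform coherence (WTC) averaged in the 0.06--0.15 Hz band over
30-s epochs, chance synchrony is estimated from random-pair and
phase-randomization surrogates, conversation-coding logs are reduced to
per-dyad composites (turn-taking, relevance, contingency, intrusiveness),
and the link between behavior and the time course of synchrony is tested
with beta-response mixed-effects models compared by likelihood ratio tests
(LRTs). A seeded synthetic-dyad generator provides ground truth for every
stage.

This vignette explains the model and procedure choices, the parameters
that matter, what the generator does and does not emulate, and the
numerical decisions a maintainer should know about.

## Data model and montage

The default cap has four 2x2 probe sets (8 sources, 8 detectors) yielding
16 channels at 30 mm separation, four per region of interest: left/right
dorsolateral prefrontal cortex (around AF3/AF4) and left/right
temporo-parietal junction (around CP5/CP6). No public per-channel lookup
table exists for this layout, so the channel-to-ROI map (1--4 dlPFC-L,
5--8 dlPFC-R, 9--12 TPJ-L, 13--16 TPJ-R) is a declared convention of the
package, stored in the montage object and overridable through
`make_montage()`.

Recordings travel in a self-describing TSV dialect (`#key<TAB>value`
header: sampling rate, role, dyad id, wavelengths; then one row per
sample, columns `w<wavelength>_ch<k>`). The dialect exists so that
fixtures are human-readable and exactly reproducible; SNIRF is not read by
this build. Unequal-length partners are reconciled by truncation to the
shorter series -- padding would invent data.

## Preprocessing

The stage order is fixed and recorded in a provenance field:
intensity &rarr; optical density &rarr; wavelet motion correction &rarr;
heart-band channel QC &rarr; band-pass &rarr; modified Beer--Lambert law.

**Optical density** uses the natural-log convention,
$\Delta OD = -\ln(I/\bar I)$, with each channel's own temporal mean as
baseline; OD is therefore invariant to per-channel gain.

**Motion correction** decomposes each OD series with a Daubechies-5
maximal-overlap discrete wavelet transform (MODWT, exactly invertible at
any series length) and zeroes detail coefficients further than
`iqr_alpha` (default 1.5) interquartile ranges from their level median;
motion spikes are broadband and concentrate in exactly those tails, while
an oscillatory physiological signal never exceeds the threshold (for a
sinusoid the most extreme coefficient sits at about 0.7 x 1.5 IQR). The
series is mirror-extended before the circular transform so the
wrap-around seam is not itself flagged; a few samples at the recording
edges still carry small reconstruction error, which is irrelevant
downstream because the cone of influence excludes the edges anyway.
`iqr_alpha = Inf` is an exact identity.

**Channel QC** automates the "clear heart band" screen: a channel with
good optode contact shows cardiac pulsation. We compute the Welch power
ratio of the 0.6--1.5 Hz band over 0.01--3 Hz and drop a channel whose
ratio falls below `power_ratio_min` (default 0.2) at either wavelength --
whole-channel exclusion, since a channel unusable at one wavelength
cannot be inverted to chromophores. The per-channel ratios are written to
a QC report for manual override.

**Band-pass** is a second-order Butterworth (0.01--0.5 Hz, 12 dB/octave
per edge) applied forward and backward. Zero-phase filtering matters
here: any phase lag applied asymmetrically to the two partners would bias
coherence phase. The implementation demeans and mirror-extends each
series before `signal::filtfilt`, suppressing the start-up transients of
direct-form filtering; the realized transfer function is checked in the
tests against the response computed analytically from the filter
polynomials (within 1% at 0.1 Hz and at 1 Hz, where the zero-phase pass
attenuates by >20 dB).

**Modified Beer--Lambert law** inverts the 2x2 extinction matrix
(Prahl 1998 compilation, 760/850 nm, cm^-1 per uM) at each sample:
$[\Delta HbO, \Delta HbR]^T = E^{-1}\,\Delta OD / (d \cdot DPF)$ with
$d = 3$ cm and differential pathlength factors 6.0 (mother) and 5.5
(child), identical at both wavelengths. The forward model `hb_to_od()` is
exported and the round trip is exact to float precision.

## Wavelet transform coherence

The continuous Morlet transform ($\omega_0 = 6$) is computed by FFT on a
dyadic scale grid ($s_0 = 2/f_s$, $\delta j = 1/12$, covering at least
2--64 s Fourier periods; Fourier period
$\lambda = 4\pi s/(\omega_0 + \sqrt{2+\omega_0^2})$). Coherence is

$$R^2(s,t) = \frac{|S(W_{xy}/s)|^2}{S(|W_x|^2/s)\; S(|W_y|^2/s)},$$

with smoothing $S$ Gaussian in time (standard deviation equal to the
scale, the Morlet decorrelation length) and a boxcar over 0.6
decorrelation lengths in scale; values are clipped to [0, 1].
Self-coherence is identically 1 inside the cone of influence (COI), and
coherence is symmetric and invariant to affine rescaling of either input
-- all asserted in tests.

The COI uses the standard $e$-folding distance: a time--scale cell is
dropped when its period exceeds $\lambda_{coi}(t) =
(4\pi/(\omega_0+\sqrt{2+\omega_0^2}))\, t_{edge}/\sqrt{2}$, with
$t_{edge}$ the distance to the nearer series edge. Band--epoch values are
unweighted means of retained (in-band, in-COI) cells in consecutive
non-overlapping 30-s windows aligned to the recording start; 240 s at
7.81 Hz gives exactly 8 epochs x 16 channels per dyad. An epoch with no
retained cell is missing and is dropped (with a count) when the model
frame is built. Averaging is unweighted over the dyadic grid so that a
brute-force masked mean over the raw spectrum array reproduces the
pipeline output exactly -- this oracle equality is a test.

For per-dyad tables the scale grid is restricted by default to the
analysis band widened by six scale-smoothing bins on each side; outside
that margin no grid point can influence an in-band smoothed value by more
than the boxcar edge effect, and the restricted grid reproduces the full
2--64 s grid to within ~1e-3 coherence units at a quarter of the cost.
Monte-Carlo suites in the tests use this restricted grid and cohorts of
2--4 channels; structural tests always use the full 16-channel montage.

## Surrogate controls

Two null distributions mirror the study's control analyses:

* **Random pairing**: each child is paired with mothers sampled uniformly
  *with replacement* from the non-partner mothers (1000 draws from 39
  candidates forces replacement; the sampling scheme is otherwise
  unstated, so replacement is the declared choice). The per-child mean
  over draws is the chance-synchrony reference -- a mean, not a quantile,
  with quantiles available from the stored draw array.
* **Phase randomization**: the mother series (only; randomizing one
  partner suffices to destroy phase alignment, and the choice is
  configurable) is replaced by an amplitude-preserving surrogate --
  positive-frequency phases i.i.d. uniform, conjugate symmetry enforced,
  DC and Nyquist left real -- and coherence recomputed per draw.

A deliberately adversarial generator option adds the same exogenous
0.1 Hz component to every subject: true coupling is absent but all
subjects share a rhythm. Random pairing cannot distinguish such a
cohort-wide confound from dyadic coupling, and the tests assert exactly
that -- original and surrogate coherence coincide -- which is the honest
statement of what this control does and does not rule out.

## Conversation coding

Turns are one speaker's speech bounded by pauses or the partner's speech:
same-speaker events separated by at most 3000 ms merge; a speaker change
with gap in [0, 3000] ms is an alternation; longer pauses break the chain
without alternation credit; a partner onset before the current offset is
an overlap, with its duration accumulated. Composites are equally
weighted means of sub-category counts, with the "ir-"/"non-" categories
entering negatively (relevance = mean(relevant, -irrelevant), contingency
likewise) so that larger always means more cohesive; intrusiveness is
mean(fails-to-leave-time, interrupts, simultaneous) and turn-taking is
mean(alternating, long turns). Long turns counting *toward* turn-taking
follows the coding scheme's own grouping; the sign convention is recorded
in the scores object. Counts (not rates) enter the composites, one value
per dyad over the 4 minutes, so in the models the dyad-constant score is
crossed with time.

Inter-rater reliability: ICC(2,1) -- two-way random effects, absolute
agreement, single rater -- computed from the ANOVA mean squares (the
specific ICC form is unnamed in common reporting, so the label is always
attached), and linearly weighted kappa for the ordinal duration codes.
Both are checked against direct ANOVA/confusion-matrix computations.

## Beta mixed models

Epoch-level coherence lies in (0, 1), so models use a logit-link beta
response. The frame joins coherence cells to dyad scores, z-standardizes
every continuous predictor over the included rows (epoch index 1--8
enters as linear z-time), and compresses boundary responses by
$y \leftarrow (y(n-1)+0.5)/n$ -- the standard device, applied only to
exact 0/1 values.

Fitting is maximum likelihood via the Laplace approximation (glmmTMB,
beta family). Every model carries a dyad random intercept, and every
fixed effect added along the ladder brings an *uncorrelated* dyad-level
random slope (the `||` structure, chosen for convergence). The ladder is:
null; +turn-taking (M1); +time (M2); +turn-taking x time (M3); then, each
added to M3: turn duration (M4), relevance (M5), intrusiveness (M6),
contingency (M7). M1--M3 are compared to their predecessor and M4--M7 to
M3 by LRTs; fixed-effect inference is by LRT only, no Wald p-values in
headline output. The intercept-only Laplace fit is cross-validated in the
tests against an adaptive Gauss--Hermite quadrature oracle (agreement to
1e-2 on all parameters at 80 observations per dyad), and the
zero-variance limit against a plain beta-regression MLE.

Interaction follow-up uses link-scale marginal trends: for moderator
value $m$ the turn-taking trend is exactly
$\beta_{tt} + \beta_{tt \times time}\, m$, with delta-method (here exact)
standard errors; the default levels are the early (epochs 1--4) and late
(5--8) means of z-time. The implementation is the closed form; emtrends
is used in the tests as an independent cross-check only.

The original-vs-random-pair comparison stacks original cells with the
per-child surrogate means under a pairing indicator, shares one random
intercept per child (originals and their surrogates are neither fully
dependent nor independent; a child-level intercept is the declared
compromise), and tests pairing, time, and pairing x time sequentially.

Per-ROI analysis is a configuration flag that filters the frame before
the ladder, since optical properties differ systematically between
regions; the HbR replication is the same pipeline with
`chromophore = "HbR"`.

## Synthetic dyads

`simulate_dyad()` builds each partner's HbO per channel as

* a **shared** narrowband (0.06--0.15 Hz, centered near 0.1 Hz) process
  weighted by the coupling $\kappa_e$ of the current epoch, plus a
  private narrowband process weighted $\sqrt{1-\kappa_e^2}$ (unit total
  variance);
* cardiac sinusoids at 1.0 Hz (mother) / 1.2 Hz (child) -- the role
  asymmetry keeps QC and filtering role-sensitive;
* respiration at 0.25 Hz, deliberately outside the analysis band;
* random-walk drift, white noise, and Poisson motion spikes
  (default 1/min, 2 uM, 0.5-s decay).

Default amplitudes (uM): band 0.3, cardiac 0.4, respiration 0.1, drift
0.2, white 0.05. Cardiac is set prominent because raw optical density in
a well-coupled channel is dominated by pulsation -- that is precisely
what the heart-band QC screens for. HbR is $-0.5\times$HbO plus
independent noise, giving the replication path weaker ground-truth
coupling. Intensities are produced by the *forward* Beer--Lambert model,
so the entire preprocessing path is exercised; the round trip back
through `od_to_hb()` recovers the band-passed latent signal to high
accuracy on spike-free specs.

Cohorts draw per-dyad turn-taking targets (mean 40, SD 12 utterance pairs
per 4 min) and set each dyad's coupling slope to
`behavior_link` x the standardized target, so high-turn-taking dyads gain
coherence across epochs -- the ground-truth analogue of the
turn-taking x time interaction. Coding logs come from an
alternating-renewal utterance process with gaps mainly in 200--700 ms and
occasional >3-s pauses.

The generator emulates the *spectral* and *coupling* structure of dyadic
fNIRS; it does not emulate optical photon transport, layered head models,
systemic physiology shared within a real dyad (beyond the explicit
global-signal option), or coded conversational semantics. Green tests
therefore certify the machinery -- filter responses, coherence
estimation, null calibration, model recovery -- not the biological claims
themselves.

For model-level studies `simulate_beta_frame()` generates epoch-level
frames directly from the beta GLMM. Its default interaction effect is
0.10 on the logit scale with dyad slope SD 0.05: with 20 dyads the
standard error of a dyad-level interaction cannot fall below
$0.05/\sqrt{20} \approx 0.011$ regardless of the number of channels, so
0.10 (~9 SE floors) is the smallest round value giving a comfortably
powered design for the 20-cohort power suite; it is of the same order as
the observed trend contrasts.

## Numerical choices and scales

* FFT-based CWT with zero padding to the next power of two; series are
  demeaned before transforming.
* Degenerate inputs: channels masked by QC are never touched by later
  stages and propagate as missing rows; epochs fully outside the COI are
  missing; an all-masked dyad is an error, not a silent drop.
* Coherence denominators are floored at the smallest positive double
  before division; values clipped to [0, 1].
* Random-effect variances are reported as estimated by glmmTMB (which
  bounds them at zero internally); non-convergence is flagged on the fit
  object rather than raised.
* Every stochastic component is a pure function of an integer seed; the
  pipeline manifest records the config hash (MD5 of the canonical YAML
  dump) and all seeds, and rerunning a config byte-reproduces the tables.
* Config files are YAML: human-readable, commentable, and parsed by a
  single lightweight dependency.
* Test-suite problem sizes: Monte-Carlo cohort suites use 20 dyads with
  2--4 channel montages and 2 surrogate draws per child; model recovery
  uses 40 dyads x 128 observations (50 seeds), LRT calibration 500
  fixed-effects replicates, power 20 cohorts of 20 dyads x 16 channels.
  These sizes are the package's own simulation design; all structural
  tests use the full 16-channel, 240-s configuration.

## Known limitations

* No short-separation-channel regression or superficial-signal GLM; the
  random-pair control addresses systemic confounds only at cohort level,
  and the global-signal test shows its blind spot explicitly.
* The restricted scale grid trades ~1e-3 coherence accuracy for a 4x
  speedup; set `period_range = c(2, 64)` wherever exact full-grid values
  are preferred.
* MODWT despiking leaves small reconstruction error at the outermost
  samples (excluded from analysis by the COI in practice).
* Laplace ML is slightly biased for variance components with few
  observations per dyad; the AGQ cross-check bounds this at the scales
  used here.
* SNIRF reading is not implemented in this build.
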