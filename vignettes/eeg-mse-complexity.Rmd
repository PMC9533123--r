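---
title: "Multiscale entropy analysis of resting-state EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy analysis of resting-state EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Cognitive capacity in older adults is usually assessed with face-to-face test
batteries. A candidate physiological complement is the *temporal complexity*
of resting-state EEG: the moment-to-moment irregularity of cortical dynamics,
which reflects the breadth of neural interactions rather than the power of
any one rhythm. `eegmse` implements the full analysis chain for a two-group
design — older adults split at the median of a cognitive test battery into
high- and low-scoring groups — in which complexity is quantified by
multiscale entropy (MSE) at the 19 electrodes of the 10-20 system, compared
between groups with a mixed-design repeated-measures ANCOVA, and contrasted
with a conventional spectral-power control analysis.

# Multiscale entropy

For a series $x_1,\dots,x_N$ and a scale factor $\tau$, the coarse-grained
series is the mean of consecutive non-overlapping windows,

$$y_j^{(\tau)} = \frac1\tau \sum_{i=(j-1)\tau+1}^{j\tau} x_i,
  \qquad 1 \le j \le \lfloor N/\tau \rfloor ,$$

and each coarse-grained series is z-scored (population SD). Sample entropy
with embedding dimension $m$ and tolerance $r$ is

$$\mathrm{SampEn}(m, r) = -\ln\frac{U^{m+1}(r)}{U^m(r)},$$

where $U^m(r)$ is the probability that two length-$m$ embedding vectors agree
within $r$ in the Chebyshev (max-coordinate) norm, self-matches excluded.
Defaults are the field's standard $m = 2$, $r = 0.2$, scales $\tau = 1,
\dots, 40$. The 40-scale profile is reduced to eight bins of five scales; at
the default 200 Hz analysis rate scale $\tau$ probes dynamics at
$\tau \times 5$ ms, so bin 1 covers 5–25 ms and bin 8 covers 180–200 ms.

Conventions that matter for reproducibility:

* **Counting.** Templates run over the first $N - m$ positions for both the
  $m$- and $(m+1)$-length counts (the Richman–Moorman convention);
  unordered pairs are counted once; matching uses the strict inequality
  $< r$. The pair-normalizing constants cancel in the ratio. The compiled
  kernel enumerates candidate pairs through the sorted first embedding
  coordinate, which changes nothing about the counts and makes the
  $O(n^2)$ loop fast enough for replicate studies; the test suite pins the
  kernel to a naive quadratic reference at $10^{-10}$.
* **Tolerance mode.** By default $r$ is applied *after* per-scale z-scoring
  (`r_mode = "per_scale"`), so $r = 0.2$ is in SD units of each normalized
  coarse series. This makes white noise scale-free with the analytic value
  $-\ln(\mathrm{erf}(r/2)) \approx 2.185$ at every scale, which the tests
  exploit. The original convention — a fixed tolerance of $0.2\,\mathrm{SD}$
  of the scale-1 series — is available as `r_mode = "global"`; the classic
  separation of $1/f^2$ from white noise at slow scales holds in that mode.
* **Undefined entries.** A coarse series with zero variance, or one whose
  $(m+1)$-match count is zero, yields an undefined (NA) entry. Epoch
  averaging skips undefined epochs; a cell undefined in every epoch stays
  missing, and subjects with missing cells are removed listwise (with a
  logged count) before the group statistics.
* **Bias.** SampEn is consistent but has a small positive finite-sample bias
  at short coarse lengths (Jensen's inequality on $-\ln$ of a noisy count
  ratio). At the default epoch length of 20 s the scale-40 series has 100
  points and the bias is an order of magnitude below the between-subject
  variation; tests on white noise bound deviations with simultaneous
  $t$-statistics rather than naive per-scale intervals, because 40 parallel
  two-SE checks would fail by multiplicity alone even for a perfect
  estimator.

# Preprocessing

Recordings are zero-phase band-pass filtered (Butterworth sections applied
forward-backward; defaults 1–60 Hz, matching the emulated acquisition band),
downsampled to the 200 Hz analysis rate by Fourier-domain resampling (exact
in amplitude for band-limited content), segmented into non-overlapping 20 s
epochs, and screened by a 100 µV peak-amplitude criterion — an automated
surrogate for manual artifact exclusion; clinical practice commonly uses
that threshold. The 200 Hz rate is a deliberate choice: it makes scale
$\tau$ correspond to exactly $\tau \times 5$ ms so that bin labels
(5–25 ms, …, 180–200 ms) are exact; the acquisition rate of 500 Hz can be
kept by setting `preprocess$target_fs` to 500, at the cost of re-scaling
the time axis. Epoch length is configurable; 20 s keeps the scale-40 series
at 100 points while epoch averaging (about 12 epochs per subject) controls
the variance.

# The synthetic cohort

The clinical recordings the design emulates are not distributable, so the
package ships a seeded generator whose defaults are the study conditions:
22 high / 21 low cognitive-function subjects; ages drawn from N(70, 4.3)
and N(74.14, 5.22) years respectively (so age is genuinely collinear with
group, exercising the covariate path); male/female ratios 6/16 and 7/14;
cognitive totals from N(168.27, 10.04) and N(142.52, 8.28); 8–16 epochs per
subject (mean ≈ 12); 500 Hz recordings of at least 180 s synthesized inside
a 1–60 Hz acquisition band.

Each channel is an independent realization of a `noise_mix`:

* a $1/f^{\beta}$ colored background ($\beta = 1.5 \pm 0.1$ across
  subjects/electrodes) with a 15% white-noise admixture — this produces the
  characteristic rising-then-plateauing MSE curve of band-limited
  field-potential data;
* an alpha rhythm: narrowband noise centered at $9.5 \pm 0.8$ Hz (half-width
  1 Hz), RMS 0.8 relative to the background at posterior electrodes and half
  that anteriorly, with log-normal between-subject amplitude variation;
* a slow rhythm centered at $1.4 \pm 0.1$ Hz (RMS 0.9, per-electrode
  log-normal amplitude jitter), the carrier of the group effect (below);
* subject- and electrode-level amplitude gains (log-normal, SD 0.2 on the
  log scale, truncated at ±2 SD) around a target channel SD of 8 µV, so
  clean recordings stay below the 100 µV rejection threshold.

**How the group effect is injected.** For a *Gaussian* process the power
spectrum determines sample entropy, so any complexity difference with
matched spectra must be non-Gaussian. The generator therefore varies the
*phase coherence* of the slow rhythm: in the low cognitive-function group
the slow rhythm at the 13 affected frontal/parietal/temporal electrodes is a
phase-locked periodic waveform (stereotyped slow-wave activity), while in
the high group (and at unaffected electrodes) it is phase-diffuse narrowband
noise of identical power. A coherent rhythm survives coarse-graining as a
predictable waveform and lowers sample entropy specifically at slow scales;
an incoherent one does not. Because the two variants differ only in sub-2 Hz
line width — below the 2–60 Hz grid of the Welch control analysis — and all
amplitudes are drawn from identical distributions in both groups, the
groups' power spectra are matched by construction: the pipeline's entropy
branch can detect what its spectral branch cannot, which is the study-level
behavior the generator exists to emulate. The direction (low group = more
stereotyped, lower slow-scale entropy) matches the finding that higher
cognitive function accompanies higher slow-scale complexity.

`effect_size` is the target high-minus-low difference in mean bins-3–8
sample entropy at the affected electrodes. It maps linearly onto the low
group's rhythm coherence through a calibration constant (0.07 nats at full
coherence, measured once on the default generation + preprocessing path
with 12 × 20 s epochs); the default is the full contrast, which produces an
omnibus group effect with partial $\eta^2 \approx 0.2$ — the magnitude of a
large clinical effect. Setting `effect_size = 0` makes the groups
exchangeable except for demographics, which is how the null-calibration
tests run. In practice the contrast expresses itself most strongly in bins
5–8 (105–200 ms) and tapers toward bin 3, so recovered effects concentrate
in the slow half of the grid.

What the generator does *not* emulate: volume conduction and inter-channel
correlation (channels are independent), eye-blink/muscle artifacts (beyond
what the amplitude screen would catch), non-stationary state changes
(drowsiness), and any genuine physiological coupling between age, sex and
the EEG. Passing tests therefore demonstrate that the pipeline's statistics
are calibrated and powerful under a faithful statistical emulation of the
design — not that the biomarker works on real patients.

# Group statistics

The omnibus model is a mixed-design repeated-measures ANCOVA: group
(between subjects), electrode × scale-bin (19 × 8 within), age and sex as
covariates. It is fitted by the univariate mixed-GLM approach: the
subjects × 152 response matrix is projected onto orthonormal within-subject
contrast bases (Helmert-derived) for each stratum — subject mean, scale
contrasts, electrode contrasts, and their interaction — and each projected
response is regressed on the between-subjects design (intercept, centered
age, sex indicator, sum-coded group). Group sums of squares are Type III
drop-term SS; with a two-level between factor and no between-factor
interactions these coincide with Type II. The four reported effects are
Group, Group × scale, Group × node, and Node × scale × group, each with
partial $\eta^2 = SS_{\text{effect}} / (SS_{\text{effect}} +
SS_{\text{error}})$.

Sphericity of within-subject effects is handled by the Greenhouse–Geisser
correction: $\hat\varepsilon = \mathrm{tr}(S)^2 / (d\,\mathrm{tr}(S^2))$
with $S$ the error SSP in the orthonormal contrast basis and $d$ the
contrast dimension, clamped to $[1/d, 1]$; both numerator and denominator
degrees of freedom are multiplied by $\hat\varepsilon$. The engine is
validated against `car::Anova(type = 3, idesign = ...)` on small designs
(they agree to at least six decimals, including the GG quantities); on the
full 19 × 8 grid with 43 subjects the multivariate error SSP is singular,
which the trace-based univariate computation handles by construction.
The adjusted p-value exceeds the unadjusted one whenever $F \ge 1$; for
$F < 1$ the inequality can reverse (a property of the F distribution, not a
bug), so the direction check in the tests is conditioned on $F \ge 1$.

Post-hoc comparisons are two-sample t-tests per (electrode, bin) cell —
pooled-variance by default, Welch behind a flag, positive t meaning the
high group is larger — without covariate adjustment, keeping the omnibus
ANCOVA and the descriptive post-hoc map separate. Multiplicity is controlled
by Benjamini–Hochberg step-up FDR over the full grid (152 tests for MSE,
19 × 59 = 1121 for the PSD control), with the critical p reported. The PSD
branch uses Welch's method: 2.0 s Hanning windows, 50% overlap, one-sided
density in dB re 1 µV²/Hz, reported on the 2–60 Hz / 1 Hz grid (59 points)
by decimating the native 0.5 Hz resolution; band-averaging is available as
an option.

# Numerical and design choices

* Population (divide-by-N) SD in z-scoring; fixed for bit-reproducibility.
* Median split assigns scores tied with the median to the low group, with a
  warning — a deterministic rule where the emulated design is silent.
* Filtering applies separate high- and low-pass Butterworth sections
  (order 4 each) forward-backward; the 1 Hz corner at 500 Hz is numerically
  stable in this form where a single narrow band-pass design is not.
* FFT-domain resampling was chosen after the available polyphase
  implementation showed a percent-level passband gain error; the FFT method
  is amplitude-exact for band-limited signals and standard in EEG tooling.
* EDF support is a minimal continuous-recording reader/writer (one-second
  records, 16-bit scaling per channel); physical units other than µV pass
  through with a warning.
* All randomness flows from explicit seeds: the cohort seed determines
  per-subject child seeds, so any subject's recording can be regenerated in
  isolation and identical configurations give byte-identical results.

# Problem sizes used by the test suite

The replicate-based checks run the full pipeline at reduced sizes chosen so
the whole suite completes in well under half an hour: effect-recovery runs
use the default cohort (22/21 subjects, 19 electrodes, all 40 scales) with
3 epochs of 8 s per subject at 200 Hz across 50 replicate cohorts;
null-calibration runs use 400 replicates with a 6-electrode montage,
scales 1–10 and 2 epochs of 2 s, which preserves the between/within
structure the group F-test depends on. The scale-40 coarse series must keep
at least $m + 2$ points, and short epochs raise the rate of undefined
slow-scale entries, so epoch lengths below ~8 s are not recommended with
the full 40-scale axis.

# Known limitations

Channels are generated independently, so nothing in the package exercises
spatial correlation structure; the amplitude screen is a crude artifact
surrogate; refined/composite MSE variants and multivariate extensions are
out of scope; and the ANCOVA assumes complete within-subject grids after
listwise deletion. The calibration constant linking `effect_size` to rhythm
coherence holds at the default rhythm amplitude — changing `slow_amp`
rescales the attainable effect range.
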