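# eegmse

Multiscale-entropy analysis of resting-state EEG for discriminating high
from low cognitive function in older adults.

## The problem

Conventional spectral analysis of EEG summarizes *how much* power each
rhythm carries, which mostly reflects local neural activity. The temporal
*complexity* of the signal — its irregularity across time scales — instead
reflects the breadth of interactions across neural networks, and falls when
cognition declines. `eegmse` implements the complete analysis chain for a
two-group resting-state design (older adults median-split on a cognitive
battery into high/low groups, 19-channel 10-20 montage, eyes-closed
recordings):

1. **Multiscale entropy (MSE).** Each channel is coarse-grained with
   non-overlapping windows of τ samples,
   `y_j = mean(x[(j−1)τ+1 .. jτ])`, z-scored, and summarized by sample
   entropy `SampEn(m, r) = −ln(U^{m+1}(r) / U^m(r))` with the standard
   m = 2, r = 0.2 (Chebyshev matching, self-matches excluded), over scales
   τ = 1…40. At the 200 Hz analysis rate scale τ probes τ×5 ms; the
   40-scale profile is averaged into 8 bins of 5 scales (5–25 ms … 180–200
   ms) and over ~12 artifact-free 20 s epochs per subject.
2. **Group inference.** A mixed-design repeated-measures ANCOVA (group
   between; electrode × scale-bin within; age and sex covariates; Type III,
   Greenhouse–Geisser correction, partial η²), followed by post-hoc
   two-sample t-tests over the 19×8 = 152-cell grid with Benjamini–Hochberg
   FDR at q < 0.05.
3. **Spectral control.** Welch PSD (2.0 s Hanning windows, dB/Hz) compared
   pointwise over 19 electrodes × 59 frequency bins (2–60 Hz) with the same
   FDR — the branch that is expected to find *nothing* when the groups
   differ only in complexity.
4. **Synthetic cohort.** The clinical recordings such a study uses cannot be
   redistributed, so the package ships a fully seeded generator that
   emulates the design: 22/21 subjects with realistic age/sex/score
   distributions, 1/f-background + alpha-rhythm channels inside a 1–60 Hz
   acquisition band, and a group effect carried by the *phase coherence* of
   a sub-2 Hz slow rhythm — which raises slow-scale entropy in the
   high-cognition group while leaving the 2–60 Hz spectra matched by
   construction.

Everything is driven from plain R functions plus a validated YAML/list
configuration; signals read and write as EDF or delimited text matrices.

## Worked example

A reduced synthetic study (default cohort design, 3 epochs of 8 s per
subject so it runs in seconds):

```r
library(eegmse)
res <- run_pipeline(list(
  seed = 42,
  cohort = list(fs = 200, duration = 24, epoch_len = 8,
                n_epochs_range = c(3, 3)),
  preprocess = list(epoch_len = 8)))
print(res)
#> <mse_pipeline_result> 43 subjects (22 high / 21 low)
#>
#> Mixed-design repeated-measures ANCOVA (43 subjects)
#> Covariates: age, sex
#> Within-subject grid: 19 electrodes x 8 scale bins
#>
#>                effect df1  df2     F         p gg_epsilon      gg_p partial_eta2
#>                 Group   1   39 7.190 1.069e-02         NA 0.0106900      0.15570
#>         Group x scale   7  273 5.504 6.182e-06     0.6988 0.0001063      0.12370
#>          Group x node  18  702 1.581 5.892e-02     0.6492 0.0960000      0.03896
#>  Node x scale x group 126 4914 1.543 1.140e-04     0.2173 0.0373100      0.03805
#>
#> Post-hoc entropy grid: <posthoc_grid> 19 electrodes x 8 scale bins (152 tests)
#> BH-FDR q = 0.05: 8 discoveries, critical p = 0.001663
#> electrodes with discoveries: F3, F4, F7, Fp1, Fp2, Pz
#> PSD control grid: <posthoc_grid> 19 electrodes x 59 frequency points (1121 tests)
#> BH-FDR q = 0.05: 0 discoveries, critical p = 0
```

Reading the output: the omnibus group effect is significant (F(1,39) = 7.19,
p ≈ 0.011, partial η² ≈ 0.16 — a large effect), the post-hoc map finds its
discoveries at frontal/parietal sites in the slow scale bins where the
generator injected the complexity difference, and the PSD control grid is
empty — the entropy branch detects what the spectral branch cannot, the
study-level behavior the pipeline exists to demonstrate. Setting
`cohort$effect_size = 0` makes the groups exchangeable and the group effect
rejects at the nominal 5% rate.

Individual stages are ordinary functions returning classed objects with
`print`/`plot` methods: `generate_cohort()`, `bandpass()`,
`resample_recording()`, `segment()`, `reject_epochs()`, `epoch_mse()`,
`bin_scales()`, `welch_psd()`, `fit_rm_ancova()`, `posthoc_ttests()`,
`psd_pointwise_tests()`, `bh_fdr()`, `render_heatmap()`. Set
`output_dir` in the config to get tidy CSVs of every grid plus a run log.
See the methods vignette (`vignettes/eeg-mse-complexity.Rmd`) for the model,
conventions and design decisions.

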