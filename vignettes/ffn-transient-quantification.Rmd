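---
title: "Quantifying evoked FFN transients: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying evoked FFN transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffnquant)
```

## The measurement problem

pH-sensitive fluorescent false neurotransmitters (FFNs) such as FFN102
are taken up into dopamine axons by the plasma-membrane transporter and
packaged into synaptic vesicles, where the acidic lumen quenches their
fluorescence. Exocytosis expels the probe into the neutral extracellular
space and produces a transient rise in fluorescence — an optical analog
of electrochemical release detection that still works where innervation
is far too sparse for voltammetry, such as the external globus pallidus
(GPe). In such regions there are few or no resolvable puncta to track,
so the unit of analysis is the whole field of view: the mean of all
pixels in each frame forms one fluorescence time course per field.

`ffnquant` implements that whole-field pipeline end to end, together
with a synthetic-data generator that emulates the experiments with known
ground truth, so that every stage — baseline correction, AUC scoring,
edge-based anatomy quantification, decay and derivative kinetics,
spatial hotspot analysis, and the inferential layer — is verifiable
without any raw recordings.

## Trace extraction

A recording is a uniformly sampled frame-mean trace (10 Hz by default).
Baseline fluorescence is estimated by an ordinary least-squares line
fitted to the 500 ms immediately preceding stimulus onset
(`fit_baseline()`, `window_s = 0.5`), then extrapolated over the whole
recording. The percent signal is

$$\%\Delta F/F(t) = 100\,\frac{F(t) - B(t)}{B(t)},$$

with $B(t)$ the fitted line evaluated per frame. Dividing by the
per-frame value rather than the window mean cancels a linear
photobleaching or washout trend exactly; the trade-off is that the
five-sample fit, extrapolated seconds beyond its window, is the dominant
noise term for late-trace statistics (see *Recovery benchmarks* below).

Transient size is the trapezoidal area under the %ΔF/F curve
(`auc()`). Windows are half-open, $[t_0, t_1)$: every inter-sample
segment whose left endpoint falls in the window contributes
$(v_i + v_{i+1})\,\Delta t/2$. This convention makes AUC exactly
additive over adjacent windows that share a sample. The abscissa is
seconds by default; a frame-index dialect (`abscissa = "frames"`) is
provided because integration "over frames" is a common alternative and
replayed external data may use either. For comparisons across stimulus
frequencies the pipeline driver integrates a fixed 0–300 ms post-onset
window, since a protocol-length window would shrink with frequency.

Repeated trains in one field are combined pointwise by
`average_transients()` (mean ± SEM, SEM = sample SD/√n).

## Punctate anatomy: Canny edge sum

Baseline images (pixelwise means of pre-stimulus frames) are scored for
punctate structure by Canny edge detection: Gaussian smoothing
(σ = 1.4 px), Sobel gradients, gradient magnitude normalized to a
maximum of 1, non-maximum suppression, and hysteresis thresholding at
(0.08, 0.2). Applying the thresholds to the *normalized* magnitude makes
the mask invariant to intensity offset and scale; the low threshold
keeps weak edges from thin varicosities. The edge *sum* (count of edge
pixels, `canny_edge_sum()`) is the per-field anatomy proxy; no punctum
segmentation or counting is attempted. Because edge-pixel counts are
sensitive to implementation details (smoothing width, suppression
scheme), the tests assert invariances, orderings, and agreement with an
independently computed reference mask on a fixed synthetic image, rather
than absolute counts on arbitrary images.

## Kinetics

`pulse_binned_derivative()` takes the first difference of %ΔF/F per
frame interval (100 ms bins at 10 Hz). A bin is indexed by its start
time; the response to a pulse delivered at time $t$ first appears in the
frame acquired at $t + \Delta t$, so the "bin after a pulse" is the bin
whose interval starts at the pulse time. When stimulation is faster than
the frame rate several pulses share a bin. `derivative_at_landmarks()`
reports the bins 100 ms before onset and after the first and second
pulses — a compact summary of how front-loaded release is.

`decay_metrics()` finds the post-stimulus peak (maximum between onset
and end-of-train + 0.5 s, earliest frame on ties), fits a line to the
log-transformed values over the contiguous post-peak run of samples
above `floor_fraction` (default 0.10) of the peak, and reports the time
for the fitted exponential to fall to that floor:
$t_{10\%} = -\ln(10)/\text{slope}$, together with the fit's $R^2$. For a
clean exponential with time constant τ this is τ·ln 10. Two documented
conventions exist for "decay time" (to 10% or to half-maximum);
`floor_fraction = 0.5` selects the latter. Non-positive samples are
excluded by the floor rule rather than offset-shifted before the log.
The statistic depends only on trace shape, not amplitude. The $R^2$
exists precisely because log-linear fits on drifting or noisy tails can
be poor; downstream summaries should inspect it.

## Spatial hotspot analysis

Fields of view within a slice are ranked by AUC and split into four
near-equal quartiles (`quartile_pair_analysis()`); ties are broken by
stable input order and, when n is not divisible by 4, the extra members
go to the lower-AUC quartiles, so assignments are deterministic. Pairs
of fields are classified by whether both members share the top (or
bottom) quartile, and the distance distributions are compared.

"Are the high-releasing fields clustered?" is made testable by
`hotspot_dispersion_test()`: the statistic is the median top-quartile
pair distance, and the null distribution is obtained by permuting AUC
values across the fixed field positions. Small statistics indicate
clustering; the p-value uses the add-one permutation convention, so with
199 permutations the test is exactly sized at the 0.05 level under the
null. This permutation operationalization is this package's choice of
formalization — visual inspection of pair-distance histograms is the
usual informal alternative.

## Inferential layer

`t_test()` is the two-tailed two-sample t-test, pooled-variance by
default (Welch by flag), paired on request; zero-variance input is an
explicit error rather than an infinite statistic. `ci95_mean()` is the
t-based interval mean ± t₀.₉₇₅,ₙ₋₁·SEM. `rm_anova()` is the one-way
within-subject ANOVA via the explicit subject/condition/residual
sum-of-squares partition (no sphericity correction by default;
Greenhouse–Geisser by flag), and `mixed_anova()` the split-plot design
with one between-subjects factor (region) and one within-subjects factor,
testing the between effect against subjects-within-groups. Both are
written as explicit partitions so that `stats::aov` error strata serve
as an independent cross-check in the test suite. No multiple-testing
correction is applied anywhere. With two conditions, `rm_anova()`
reproduces the paired t-test (F = t²).

## The synthetic-data generator

`simulate_trace()` generates frame-mean fluorescence as

$$F(t) = F_0\,(1 - b\,t) \;+\; \frac{F_0}{100}\sum_p A_p\,
  h(t - t_p) \;+\; \varepsilon(t),$$

with linear (optionally exponential) bleaching $b$, i.i.d. Gaussian
noise ε, and a difference-of-exponentials kernel
$h(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ normalized to unit peak.
This is the minimal kernel that produces both "sustained" and
"flash-like" transients through the decay constant alone. Per-pulse
amplitudes are

$$A_p = a \cdot \mathrm{hill}(\mathrm{Ca}) \cdot
  \Big(1 + f \sum_{q<p} e^{-(t_p - t_q)/\tau_f}\Big) \cdot r,$$

* **Calcium dependence** is a Hill function
  $c^h/(c^h + EC_{50}^h)$ with defaults EC₅₀ = 1 mM, h = 2: release
  rises steeply between 0.5 and 2 mM and saturates above 2 mM. Only the
  ordering and saturation are constrained by observation; the functional
  form is a modeling choice.
* **Facilitation** accumulates from preceding pulses with an exponential
  forgetting time τ_f (default 50 ms). With τ_f = ∞ this reduces to the
  classical linear ramp $1 + f(p-1)$. The finite default is deliberate:
  a pulse-number-only ramp is frequency-blind, and (by linearity of the
  integral) the whole-transient AUC of a fixed pulse count would then be
  frequency-invariant no matter the facilitation — contradicting the
  frequency sensitivity the generator must emulate. With a ~50 ms
  timescale, 50 Hz trains accumulate strong facilitation while 10 Hz
  trains barely do, which is what makes high-frequency stimulation
  selectively effective in the GPe preset while leaving the
  facilitation-free striatum preset frequency-invariant by construction.
* **Inter-train recovery** scales a train that follows a previous one by
  $1 - e^{-\Delta t/\tau_{rec}}$.

Two presets encode the regional contrast. The striatum preset has a
larger per-pulse amplitude (0.86 %ΔF/F vs 0.20, the ≈4:1 first-pulse
contrast), a slow decay (τ_d = 8 s, "sustained"), slow recovery
(60 s), and no facilitation. The GPe preset has a fast decay
(τ_d = 0.9 s, which puts the time-to-10% at ≈2.1 s, in the
empirically observed range), fast recovery (10 s), and strong
facilitation (f = 1.5). Amplitude presets are defined at saturating
calcium; at the standard 2.4 mM perfusate the Hill factor is ≈0.85.

`simulate_movie()` embeds the same trace in a 64×64 px, 10 Hz image
stack: a static background plus static 2-D Gaussian puncta, multiplied
by the bleaching trend, plus a spatially uniform evoked component
constructed so that the frame-mean of the noiseless movie equals the
simulated trace *exactly* (a conservation property the tests assert to
machine precision). Per-pixel noise is Gaussian or Poisson. No optics or
point-spread simulation is attempted.

`simulate_slice_session()` generates per-field summaries for the spatial
analysis: positions in a 1000 × 600 µm region, log-normal AUCs from a
low (ordinary GPe field, median ≈2 %ΔF/F·s) or high (hotspot, median
≈8.5) distribution, a configurable hotspot fraction (default 0.1 —
roughly one hotspot per handful of fields), and uniform or clustered
hotspot placement. Canny sums and initial fluorescence are drawn
independently of AUC, which encodes the empirical decoupling between
transient size and visible punctate anatomy; sessions simulated this way
should (and do, in the acceptance checks) show near-zero AUC–anatomy
correlations.

All generators are pure functions of their parameters and a seed; a
master seed deterministically spawns per-field and per-trial substreams,
and callers' RNG state is never disturbed.

### What the generator does and does not emulate

It reproduces the *structure* of the experiments: stimulus timing,
region-specific kinetics, calcium dependence, frequency facilitation,
recovery, bleaching, punctate anatomy, pixel noise, hotspot geometry. It
does not model vesicle-pool biophysics, diffusion from out-of-focus
release, axon morphology, optics, or correlated noise sources
(perfusion pulsation, slice drift). Passing tests therefore demonstrate
correctness of the *analysis* under the stated generative model, not
fidelity of that model to any particular tissue.

## Recovery benchmarks and numerical choices

The package's recovery checks use problem sizes chosen to run in seconds
on one CPU while keeping Monte-Carlo error small: 200 simulated fields
for parameter recovery, 10,000 replicates for t-test size and CI
coverage, 500 null sessions (199 permutations each) for the calibration
of the dispersion test, and 200 clustered sessions for its power.

Two findings from designing these benchmarks are worth recording. First,
peak-amplitude recovery through the full pipeline is comfortable: with
ten trains averaged per field at a single-trace peak SNR of 20 (the kind
of averaging these experiments use routinely), essentially all runs land
within 10% of the generative amplitude. Second, the 10%-floor decay time
is *much* harder to estimate precisely than the peak: the 500-ms,
five-sample baseline fit, extrapolated several seconds ahead, produces a
slowly varying error that is negligible against a transient's peak but
comparable to the signal near its 10% floor, where the log-linear fit
spends most of its leverage. Per-run decay constants scatter far more
than per-run peaks at any realistic noise level, and their distribution
under baseline drift is right-skewed (upward-drifting baselines flatten
the log tail). The benchmark therefore evaluates the decay estimator on
directly constructed noisy exponentials (SNR 20), where its *mean*
recovered constant is within a few percent of truth; the $R^2$ reported
by `decay_metrics()` is the practical guard against the skewed failures
in pipeline use. Users comparing decay times across conditions should
average several trains and treat low-$R^2$ fits with suspicion.

Other numerical conventions: ties at the transient peak resolve to the
earliest frame; quartile ties resolve by input order; windows are
half-open; the decay fit requires at least three samples above the
floor; degenerate inputs (zero-variance groups, non-positive baselines,
constant images) raise errors rather than propagating NaN or infinity.

## File formats and the pipeline driver

Movies travel as multi-page 32-bit-float TIFF with a JSON sidecar
(frame rate, pixel size, region, protocol, intensity scale); values are
preserved to single precision. Traces and per-field tables are plain
CSV (wide or long; `#`-prefixed metadata header), configuration is
plain-text YAML collecting every analysis constant in one auditable
place, and `run_pipeline()` executes
simulate → extract → kinetics → spatial → stats on a two-region,
two-frequency simulated experiment, writing per-field tables, mean
traces, a stats summary, and a manifest carrying the configuration and
its hash. Reruns with the same configuration are byte-identical. The
exported functions plus the configuration file are the intended
interface; there is no separate shell executable.

```{r example, eval = FALSE}
cfg <- default_config()
cfg$n_fovs <- 8
bundle <- run_pipeline(cfg, out_dir = "ffn_results")
bundle$stats
```

## Known limitations

* The linear baseline model is exact only for linear bleaching; strongly
  exponential bleaching over long recordings leaves curvature that the
  500-ms fit cannot see.
* Decay-time estimation inherits the baseline-extrapolation noise
  discussed above; it is a shape statistic best used on averaged traces.
* The facilitation model is phenomenological; it reproduces
  frequency-dependence orderings, not any specific short-term
  plasticity mechanism.
* Canny edge sums are comparable within an acquisition configuration
  only; changing smoothing width or image size changes absolute counts.
* The permutation test conditions on the observed field positions; it
  does not model uncertainty in position measurement.
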