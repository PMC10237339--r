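---
title: "Models and methods behind nmjquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmjquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nmjquant` re-creates, on synthetic data with known ground truth, a combined
electrophysiological and morphometric characterisation of neuromuscular
junction (NMJ) decline in the SOD1-G93A mouse model of ALS: quantal analysis
of miniature and evoked endplate potentials (mEPPs/EPPs), rundown of evoked
amplitude during 20 Hz stimulus trains, NMJ-morph style postsynaptic
variables from en-face acetylcholine-receptor (AChR) images, box-counting
fractal analysis of the endplate perimeter, intensity-histogram bimodality,
and qualitative disruption classification. Because the original recordings
and micrographs are not public, the package pairs every analysis operation
with a generator whose parameters encode the published group means, so that
the full pipeline can be exercised and validated by parameter recovery.

## The electrophysiology generator

Each age-by-genotype cell of the design is a scenario
(`build_scenario()`), shipped as an editable table
(`inst/extdata/ephys_scenarios.csv`). Cells with published diaphragm group
means carry them verbatim and are flagged `printed` (e.g. 1.48 mV mEPPs in
2-week wildtype, 0.94 mV at the early-symptomatic stage in the mutant,
34.3 mV wildtype EPPs at the age-matched 20-week point). Ages the source
did not print are interpolated along the described trajectories and flagged
`assumed`. Two 16-week mutant cells are *derived*: the generator's quantal
content is set so the genotype ratio equals the published 27.7% reduction
(by inverting the non-linear-summation correction, `epp_from_qc()`), and the
miniature rate is the wildtype rate scaled by the published 43.7% reduction.

A recording (`simulate_recording()`) is built at 20 kHz (default; any rate
at or above 10 kHz resolves the sub-millisecond rise times). Miniature
events arrive as a Poisson process; amplitudes at the -70 mV reference are
log-normal with the scenario mean and a CV of 0.3 — quantal amplitude
distributions are positive and right-skewed, and the source reports only
means and SEMs, so the shape and CV are package assumptions. The resting
membrane potential follows a per-minute Gaussian random walk (SD 1.5
mV/min) reflected inside [-85, -55] mV; a dedicated depolarized-fiber
variant (`scenario_depolarized()`) removes the bound so recordings cross
the -50 mV rejection line and exercise the exclusion rule. Instantaneous
amplitudes scale with driving force (|RMP|/70), which makes the -70 mV
correction exactly unbiased by construction. Events are
difference-of-exponentials waveforms whose rise constant is solved so the
onset-to-peak time equals the scenario's 0-100% rise time (0.8 ms default;
decay 4 ms). Evoked responses release Poisson numbers of quanta around the
scenario's true quantal content and are compressed by non-linear summation
(`E = L / (1 + f L / Vm)`), so the Martin-corrected estimator applied
downstream is unbiased for the true count. Gaussian instrument noise
(0.15 mV) is added throughout.

The 20 Hz, 2 min train (`simulate_train()`) uses a depletion/replenishment
pool: each pulse releases a fraction `p` of the current pool and a fraction
`r` of the deficit is restored per interval, with closed-form steady state
`N* = r N0 / (p + r - p r)` (`steady_state_pool()`). Pool parameters are
package inventions (the source plots rundown profiles without a mechanistic
fit): `p = 0.2` everywhere, `N0` set from the scenario's quantal content,
and `r` chosen per cell so late-train amplitudes decline modestly in healthy
adults and far more steeply in the mutant from 12 weeks. Note that the
*amplitude*-normalized plateau sits above `N*/N0`, because non-linear
summation compresses the large first EPP more than the depressed steady
state — exactly as in a real recording; the closed form is recovered on the
quantal scale (ground-truth quanta, or amplitudes passed back through the
Martin correction).

## Event detection and quantal analysis

`detect_mepps()` tracks the resting potential with a 200 ms running median —
long against a ~16 ms synaptic event, short against slow drift; shorter
windows bias the baseline upward under events and shave amplitudes by a few
percent. Candidates are local maxima of the 0.35 ms boxcar-smoothed
residual above 7 times its robust (MAD) SD, which is about 2.7 times the raw
noise SD — a conventional operating point; over a 600,000-sample trace a
3-SD rule admits hundreds of noise maxima. Candidates within two decay
constants merge into the larger event, covering the decay tail on which
noise maxima masquerade as secondary events. Amplitudes come from
least-squares scaling of the known template at the detected onset
(Clements-Bekkers style), fitted on the smoothed trace against the equally
smoothed template: the scaling estimate stays unbiased while the
SSE-based alignment search (+/-10 samples) becomes signal- rather than
noise-dominated. A raw peak reading instead carries a positive
noise-selection bias of about 2%, which matters against the 2-standard-error
parameter-recovery bands. Events are excluded, with a reason, from the
moment the fiber first depolarizes beyond -50 mV; fitted amplitudes below
the detection threshold are excluded as sub-threshold.

Evoked responses are measured at the known stimulus times
(`measure_epps()`): baseline is the median potential just before the
stimulus, amplitude the peak within 15 ms, and responses with 0-100% rise
times above 1.5 ms (the focal-recording criterion) or depolarized baselines
are excluded. Quantal content uses `QC = E / (M (1 - f E / Vm))` with
`f = 0.8`; `Vm` enters as a magnitude, and by default the -70 mV-corrected
means are used with `Vm = 70`, which keeps the estimate independent of the
momentary resting potential (a switch restores raw means at the measured
potential). Per-junction summaries (`summarize_nmj()`) emit both raw and
corrected evoked means, since the source does not state which enters its
figures.

## The image generator

`build_image_scenario()` encodes the published disruption trajectory: the
reduced-intensity (dim) area fraction plateaus near 40% in wildtype from 12
weeks and rises progressively to 60% at the early-symptomatic age in the
mutant; granular (floccular) texture appears in the mutant from 12 weeks
(never over half the receptor area in wildtype); small dim extrajunctional
clusters occur at ~10% incidence in both genotypes. Geometry (default
512 x 512 px at 0.25 um/px, a typical 40x field; endplate scale growing
from 25 to 40 um with age; 3 um ribbons) and all intensity levels
(background 20, dim 80, bright 185 on the 8-bit scale, pixel noise SD 5)
are package choices — the source reports no absolute intensity calibration.

`generate_nmj()` draws a harmonically distorted closed loop plus Bezier
chords, dilates to ribbon width ("pretzel"), and paints truncated-normal
intensity components: background TN(20, 3) on [10, 35], bright receptor
TN(185, 10) on [150, 235], reduced-intensity receptor TN(80, 25) on
[45, 158], satellites at half the bright level. The dim region is a
contiguous patch covering *exactly* the scenario fraction of receptor
pixels (distance ranking from random seeds), so recovery has a sharp truth.
Floccular texture is a contiguous region speckled with ~1 um round holes
punched in the ribbon interior and falling to background — "patches with
lower or no receptor", kept interior so they read as enclosed granularity
rather than edge nibbling. Satellites are 1.5-3 um blobs placed 2-10 um
beyond the endplate footprint. No optical point-spread blur is applied
(explicitly out of scope), so edges are sharp and histogram components are
governed by the truncated normals plus noise. With additive noise a small
fraction (< 1%) of dim pixels can fall below the 8-bit cutoff of 40; the
receptor-above-cutoff property is therefore asserted statistically, not
absolutely.

## Morphometry

Segmentation (`segment_achr()`) Gaussian-smooths (sigma 1 px), applies the
Huang fuzzy-entropy threshold — implemented in-package from the Huang &
Wang definition on the 256-bin histogram, since no installed R package
provides it — and removes specks below 0.5 um^2. The endplate footprint is
the largest connected component of the hole-filled 2 um morphological
closing of the foreground (the source never defines how the endplate
extends beyond the receptor clusters); receptor clusters are components
inside it; foreground components outside it are retained separately as
extrajunctional candidates. Areas are pixel counts times the squared pixel
size on a pixel-centered, row-major grid; perimeters are boundary-pixel
counts times the pixel size; the endplate diameter is the maximum Feret
diameter over pixel-corner coordinates (so a filled n-pixel square measures
n*sqrt(2)) — "diameter" is otherwise undefined in the source, and maximum
Feret is the NMJ-morph reading. Derived variables follow the printed
definitions: `g = d/f`, `h = a - d`, `j = 1 - 1/f`, and compactness
`i = (a/d) x 100` *as printed*, which yields values at or above 100 and
inverts the usual receptor-over-endplate convention; a documented switch
emits `(d/a) x 100` instead, and the printed form is the default because
the intent was not guessed.

Fractal analysis (`fractal_dimension()`) tiles the perimeter mask from a
single origin with boxes of 1-64 px per side (matching the ImageJ-style
single-grid counter; multi-offset averaging sits behind a flag), counts
boxes containing at least one perimeter pixel, and fits the log-log slope
of hits against inverse box size. Box sizes whose counts saturate (fewer
than 2 hits) are dropped; fewer than 3 usable sizes is an error. A straight
line yields ~0.98 rather than exactly 1 because the ceiling function in the
finite hit counts tilts the least-squares fit — within the stated +/-0.05
reading of "a totally smooth perimeter".

The intensity-variability analysis (`intensity_bimodality()`) median-filters
the minimal enclosing rectangle (removing sporadic pixel extrema without
moving edges), linearly rescales to 8-bit, builds a histogram smoothed with
a 5-bin moving average, and discards bins below 40 (background). The
receptor peak is the highest remaining bin; the shallow minimum is the
lowest bin between the start of the frequency curve and that peak, with
ties resolved to the lowest gray level. Leading *empty* bins at the cutoff
are skipped — they are not part of the frequency curve, and treating them
as the minimum collapses the valley onto the cutoff. The dim-area fraction
is the share of above-cutoff pixels at or below the valley; the count ratio
minimum/peak and the gray-level ratio valley/peak are both emitted, since
either reading of the published "ratio of the minimum to the peak maximum"
is defensible. Two limitations are worth stating plainly. First, the
procedure's peak is the *global* maximum above 40, so once the
reduced-intensity component carries more than roughly two-thirds of the
receptor area its mode overtakes the bright peak and the statistic
collapses — an intrinsic property of the published recipe; the study's
range (at most 60%) is unaffected, and recovery there is exact to about
0.1 percentage point. Second, on this generator the median pre-smoothing
empties the inter-mode bins, so the count-based valley/peak ratio is
typically 0; the monotone dependence on the generated dim fraction is
carried by the area-based statistic.

Disruption classification (`classify_disruption()`) scores granularity as
the local density of small enclosed holes: the image is re-thresholded on
an edge-preserving (median-filtered) view — Gaussian smoothing in the main
segmentation fills sub-resolution holes — holes are kept if small (at most
10 um^2), round (area at least 0.4 of the circumscribed disc) and no wider
than 3 um, which separates them from the elongated slivers any branched
ribbon geometry produces; a receptor pixel is granular when holes occupy
more than 4% of the local ribbon within a 4 um disc (hole share of
hole+ribbon, so inter-ribbon lakes do not dilute the score). The granular
area is classed `none` below 8% of the receptor area, otherwise `lt50` or
`gt50` against the 50% line. These constants were fixed once against the
generator's labeled clean and disrupted images — the same logic as the
source's iterative refinement of its threshold criteria against manual
tracing — giving full specificity on clean pretzels and over 85% three-way
accuracy at the default contrast. Extrajunctional clusters are foreground
components outside the endplate footprint that are both small (at most 10%
of the receptor area) and dimmer than the median receptor pixel; satellites
occasionally merge into the footprint during closing, so detection is a
high-rate property (about 80-90%), not a guarantee. The en-face criterion
("<10% obscured") is carried as generator/user metadata, not judged from
the image.

## Statistics

The comparisons delegate to base R behind the module surface: `aov` for the
two-way age-by-genotype ANOVA with per-age pooled t post-tests multiplied
by the number of ages (Bonferroni, capped at 1); `ansari.test` then
`wilcox.test` (normal approximations, avoiding exact-tie warnings) for the
skewed morphometric variables; `var.test` for per-age variance ratios. The
experimental unit is the junction, matching the source's n; muscle nesting
is reported but not modeled (the source's ANOVA is not mixed-effects). A
Monte-Carlo calibration suite in the tests verifies each test's type-I
error against binomial tolerance at 2,000 null replicates and its power
under the shifts the design implies.

## Reproducibility and problem sizes

`run_study()` derives every per-task seed from one master seed by a stable
hash of (seed, stage, group, replicate), so repeated runs are
byte-identical. The shipped analysis scripts use 10 junctions and 8 images
per group; the test-suite recovery checks use 50 junctions or images per
group — enough to place the recovery standard errors far inside the encoded
effects — and the bulk identity suite runs 500 miniature (128 px) junctions. These sizes were chosen so the whole
study re-runs in minutes on a single core while keeping the recovery
standard errors well inside the published effect sizes.

## What passing tests do and do not show

The generators emulate Poisson miniature traffic, driving-force scaling,
non-linear summation, pool depletion, and the published disruption
trajectory — but not electrode artifacts, action-potential breakthrough,
optical blur, uneven illumination, fiber curvature, or muscle-level
clustering of junctions. Parameter recovery therefore validates the
*analysis implementations* against a model that satisfies their
assumptions exactly; it does not certify performance on real recordings or
micrographs, where detection thresholds, the Huang split, and the
granularity constants would need re-examination against manual annotation.
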