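---
title: "Microstate segmentation and reliability: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate segmentation and reliability: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(microstates)
```

## The model

EEG microstate analysis treats the multichannel scalp potential as a
sequence of discrete quasi-stable states. At each time point the
average-referenced topography $v_t \in \mathbb{R}^N$ (N channels) is
modelled as a scaled copy of one of $K$ fixed unit-norm maps $m_k$, up to
polarity and noise:

$$ v_t = a_t\, m_{L_t} + \varepsilon_t, \qquad a_t \in \mathbb{R}, $$

where the label sequence $L_t$ changes on the tens-of-milliseconds scale.
Because the sign of $a_t$ oscillates with the dominant rhythm, all
comparisons between topographies are polarity-invariant: similarity is
the squared spatial (Pearson, across channels) correlation, and the
dissimilarity used throughout is $d(u, v) = \sqrt{1 - \mathrm{corr}(u,
v)^2}$.

The package implements the standard three-stage estimation pipeline plus
a reliability battery:

1. **Individual-level clustering.** Topographies at peaks of the global
   field power (GFP; the population SD across channels) are extracted.
   Fifty-ish resampling epochs, each a random subsample sized so that any
   given peak enters at least one epoch with probability 99.9%
   ($m = \lceil M(1 - (1 - 0.999)^{1/E})\rceil$ for $E$ epochs), are each
   clustered by polarity-invariant modified k-means over a range of k,
   and each epoch's k is chosen by the meta-criterion.
2. **Group-level clustering.** All subjects' per-epoch optimal maps are
   pooled and the same resampled clustering is applied (larger k range);
   the per-epoch optima are pooled again and clustered in a final pass
   whose meta-criterion curve *guides* the choice of k. An explicit
   `force_k` override exists because group-level model order is
   ultimately a researcher decision.
3. **Backfitting.** Each recording is normalized by its median GFP,
   every sample is labelled with the best-|correlation| group map
   (winner-take-all, 0.50 floor, ties to the smallest index), labels are
   smoothed by iterative windowed relabeling, segments shorter than
   32 ms are divided between their neighbours, and per-state temporal
   properties (GEV, mean duration, coverage, occurrence) plus
   first-order Markov transition statistics are computed.

### Modified k-means

Samples are centred and unit-normalized; each restart initializes k maps
from k distinct samples, alternates (a) assignment of every sample to the
map with the largest squared dot product and (b) re-estimation of each
map as the principal eigenvector of the scatter of its assigned samples
(power iteration warm-started from the current map), and stops when the
relative change in GEV falls below `tol` (default 1e-7). GEV weights each
sample's squared correlation by its squared GFP:

$$ \mathrm{GEV} = \frac{\sum_t (\mathrm{gfp}_t \cdot |\mathrm{corr}(v_t,
m_{L_t})|)^2}{\sum_t \mathrm{gfp}_t^2}. $$

Empty clusters are re-seeded deterministically from the worst-fitted
sample, so k never collapses and runs are reproducible from their seed.

### Validity criteria and the meta-criterion

Six internal validity criteria are computed on the polarity-invariant
dissimilarity: Hubert's Gamma, mean silhouette width, Davies–Bouldin
(sign-inverted so larger is better), point-biserial correlation, Dunn's
index, and Krzanowski–Lai (defined from the within-dispersion curve
across neighbouring k; undefined at the range ends). Each curve is
rescaled to [0, 1] across the searched k range and the aggregate at each
k is the **median** of the six rescaled values, so no single criterion
can dominate; ties break to the smaller k and k = 1 is assigned
aggregate 0. A partition containing an empty or singleton cluster takes
the worst value on every criterion: a "microstate class" with one member
is not a credible solution, and this rule is also what keeps group-level
selection from drifting to k+1 solutions that merely isolate one stray
pooled map.

### Temporal smoothing

Smoothing minimizes, by iterated conditional sweeps over all labeled
samples simultaneously,

$$ s_k(t) = (1 - \mathrm{corr}^2(v_t, m_k))\,\mathrm{gfp}_t^2 -
\lambda\, N_k(t), $$

where $N_k(t)$ counts labeled samples within ±w (the 32 ms half-window,
8 samples at 250 Hz) currently labeled k, the sample itself excluded.
The penalty weight is

$$ \lambda = \textrm{besag} \times \frac{\bar r}{2w + 1}, \qquad
\bar r = \operatorname{mean}_t\,(1 - \mathrm{corr}^2(v_t,
m_{L_t}))\,\mathrm{gfp}_t^2 , $$

i.e. the Besag factor (default 10) is normalized by the mean *residual*
power of the labeled samples, in the spirit of the noise-variance
normalization of the original segmentation smoother. This was a
genuinely open design point; we initially normalized by the mean GFP
power instead, which makes the neighbour term dominate the fit term by
an order of magnitude and turns smoothing into near-pure majority
voting: on synthetic data it erased genuine short segments, dropping
label accuracy below 85%. With the residual normalization the smoother
bridges the unclassifiable samples around envelope zero-crossings while
preserving real boundaries (label accuracy ~0.92 at SNR 4). Both
normalizations are scale-free: rescaling the recording in microvolts
changes nothing, consistent with the median-GFP normalization step.
Unlabeled samples (best |correlation| < 0.50) are never relabeled and do
not count as neighbours.

### Small-segment rejection and the duration resolution limit

Runs shorter than 32 ms are divided in half, the first
$\lceil L/2 \rceil$ samples joining the preceding segment and the rest
the following one (edge runs merge entirely into their single
neighbour), iteratively until no short run remains. Unlabeled runs are
treated like ordinary states so unclassifiable gaps get absorbed.

A consequence worth stating explicitly: with geometric (memoryless)
segment lengths of mean 60 ms, about 38% of *true* segments are shorter
than 32 ms. Any pipeline with a 32 ms minimum-duration rule therefore
reports mean durations well above the generative mean — this is a
resolution limit, not an estimation error. Our recovery tests
accordingly compare estimated durations against the planted label
sequence *passed through the same 32 ms rule* ("resolution-limited
truth"), where agreement is ~2%; comparing against the raw generative
mean would conflate the estimator with the resolution limit.

### Transition statistics

Transitions are counted between consecutive distinct labeled segments;
unlabeled runs break the chain. Observed probabilities normalize each
origin row to 1. The occurrence-matched null is
$\mathrm{expected}(A \to B) = \mathrm{segs}(B) / \sum_{C \neq A}
\mathrm{segs}(C)$, and the normalized matrix is the elementwise ratio,
so values above 1 mark transition directions preferred beyond what state
frequencies alone predict.

## The synthetic generator

`synth_spec()` / `generate_cohort()` emulate a high-density infant
resting-state study: 105 channels at 250 Hz on a hemispheric montage,
five planted maps built from randomly placed and oriented deep dipole
pairs (depth ≤ 0.5 of head radius, giving the broad scalp patterns of
real EEG; pairwise |correlation| ≤ 0.6), geometric segment durations of
mean 60 ms driven by a first-order Markov chain, a 10 Hz sinusoidal
envelope with a fresh phase per segment (so polarity alternates within
segments by construction), spatially white sensor noise at a
signal-to-noise ratio of 4 measured on GFP RMS, and per-subject
variation: log-normal jitter (SD 0.3) of per-state durations and
transition propensities, plus a small rotation of each map in channel
space (subject-to-group |correlation| ≥ 0.9). All randomness derives
from one master seed via `derive_seed()`.

What the generator deliberately does **not** emulate: 1/f background
spectra and alpha reactivity, muscle/eye artifacts, volume-conducted
correlated noise, electrode impedance drift, and discontinuities from
artifact rejection. Passing recovery tests on this generator therefore
demonstrates the correctness and internal consistency of the estimation
machinery — not that real infant EEG will yield equally clean
recoveries.

## Parameter defaults

| Parameter | Default | Units | Origin |
|---|---|---|---|
| individual epochs / restarts | 50 / 50 | — | standard analysis practice |
| individual k range | 1–12 | — | standard analysis practice |
| group epochs / restarts | 100 / 100 | — | standard analysis practice |
| group k range | 1–15 | — | standard analysis practice |
| resampling coverage | 0.999 | prob. | standard analysis practice |
| backfit correlation floor | 0.50 | — | standard analysis practice |
| smoothing half-window | 32 | ms | standard analysis practice |
| Besag factor | 10 | — | standard analysis practice |
| minimum segment | 32 | ms | standard analysis practice |
| split segments | 6 | — | standard analysis practice |
| outlier rule | Q1/Q3 ± 3·IQR | — | standard analysis practice |
| descriptor bands | 0.40 / 0.60 / 0.75 | — | standard analysis practice |
| k-means tolerance | 1e-7 | rel. GEV | implementation |
| ms→samples rounding | half up | — | implementation (32 ms = 8 samples at 250 Hz) |

The boxplot quartiles use linear interpolation between order statistics
(R's default type 7). The qualitative descriptor bands are applied
literally on the raw value with no rounding; values in the nominal gaps
(e.g. 0.595) fall into the lower band.

## Problem sizes used by the validation studies

The package's own validation studies (test suite and the acceptance
script) run the full pipeline at desk scale: recovery studies use 6 GFP
resampling epochs per subject at the individual level, 2 k-means
restarts, k searched over 2–6 individually and 2–8 at the group level
with 20 group epochs and 8 restarts; split-half studies use
16–32-channel montages. These sizes
were chosen once as the smallest at which the two-level pipeline is
comfortably stable (group-map recovery |corr| ≥ 0.99 and correct model
order across seeds); production analyses should prefer the full
defaults above.

## Numerical and policy choices

- **Tie-breaking** is everywhere "smallest state index" (assignment,
  backfitting, smoothing), making runs bit-reproducible.
- **Sign convention**: maps are serialized with their largest-|value|
  channel positive; all mathematics is sign-invariant.
- **Edge segments** (truncated by a recording or block boundary) are
  excluded from duration and occurrence by default but count towards
  coverage and GEV; with `exclude_edge_segments = FALSE` the identity
  `coverage = occurrence × duration/1000` holds exactly.
- **Unlabeled samples** stay visible: they are reported as
  `unlabeled_fraction`, count in coverage denominators, break transition
  chains, and are never silently relabeled (except by absorption in the
  minimum-duration rule, which treats them as ordinary runs).
- **Even/odd splits** treat block joins as hard boundaries: each of the
  six blocks is backfit independently (smoothing windows and transition
  chains never span a join) and the halves' metrics pool runs across
  blocks. Whether joins should instead be bridged is exposed by simply
  concatenating blocks before backfitting.
- **Outlier handling** in the split-half suite flags a subject (boxplot
  rule, factor 3, within either half) per metric × state × duration
  cell only, so one wild value does not delete a subject from the whole
  table; results are reported both with and without removal.
- **Spatial filtering** is an optional instantaneous robust-neighbour
  filter (median of the 6 nearest channels; replacement beyond 3 MADs of
  the channel-vs-median residuals; 50/50 blend; re-average-referenced).
  It is an approximation in the spirit of interpolation-based
  topographic cleaning and claims no equivalence with any specific
  software's filter.
- **File formats**: recordings travel as channels × samples TSV with a
  JSON sidecar (sampling rate, channel names/positions, reference,
  microvolts); maps as channels × K TSV; segmentations as per-sample
  TSV with 0-based sample indices; binary volumes as NIfTI-1. Reading
  EEGLAB/BrainVision/EDF containers is out of scope for this package:
  no maintained R reader ships in its dependency footprint, and
  preprocessed data are expected to be exported to the tabular format.

## Known limitations

- Group-level model order on real data ultimately requires judgment;
  the meta-criterion is guidance, and solutions containing visually
  transitional maps should be screened using the reported inter-map
  correlation matrix and, if needed, the `force_k` override.
- Mean durations inherit the 32 ms resolution limit discussed above.
- Transition statistics assume first-order dynamics; longer-range
  dependencies in real microstate syntax are outside the model.
- The split-half internal-consistency design says nothing about
  test-retest (between-session) reliability.
- The LME/ANOVA layer used for formal stability inference is not
  reimplemented here; the suites export tidy long-format tables meant to
  be consumed by standard mixed-model tooling.
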