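---
title: "Melt-curve barcoding: the generative model, QC rules and classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melt-curve barcoding: the generative model, QC rules and classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`meltbarcode` analyses two-channel real-time PCR melt curves for species
assignment. This vignette is the package's account of its science: the
generative model behind the synthetic corpus, the signature and
quality-control procedures, the classifier, the numerical choices that
matter, and what the synthetic data do and do not say about instrument
data.

## The measurement being modelled

A closed-tube barcoding assay amplifies the COI barcode asymmetrically and
lets mismatch-tolerant fluorescent probe pairs hybridize along two
mini-barcode segments (BS1, BS2), each read in its own dye channel. As the
instrument ramps temperature from 40 to 87 °C, each probe–target duplex
dissociates around its melting temperature and fluorescence drops. The
analysis object is the *fluorescent signature*: the first derivative
dF/dT, in which every dissociation is a trough at its Tm. BS1 additionally
contains an internal temperature marker — a spiked duplex that melts above
all species transitions, producing the rightmost BS1 trough at a nominal
84 °C — used to remove run-to-run temperature drift.

## Generative melt-curve model

No public model of these curves exists, so the simulator adopts the
simplest form that reproduces trough-type signatures: a decreasing
logistic mixture,

$$F(T) \;=\; b_0 + b_1\,(T - T_{min}) \;+\; \sum_k a_k\,
  \sigma\!\left(\frac{tm_k - T}{w_k}\right),
\qquad \sigma(z) = \frac{1}{1+e^{-z}},$$

one component per melting transition, with midpoint $tm_k$, steepness
$w_k$ (°C) and amplitude $a_k$ (relative fluorescence). Probe–target
dissociation is sigmoidal in temperature, so this is the natural minimal
stand-in; with a non-positive baseline slope and no noise the curve is
monotone non-increasing and the derivative signature is available in
closed form, which the tests use as an oracle.

Species models are drawn once per panel seed: 2–3 transitions per segment
with midpoints in 46–79 °C (separated by at least 3.5 °C so troughs stay
resolvable), widths 0.7–1.2 °C, amplitudes 0.5–1.3. A rejection step
re-draws any species whose noise-free signatures come within correlation
distance 0.15 of an already-drawn species in *both* segments, so
distinguishability failures are configured, never accidental. Three
look-alike pairs are then pinned by copying components: tiger shark ↔
giant shovelnose ray (identical in both segments), giant oceanic manta ↔
giant devil ray (identical in both), and silky ↔ blue shark (identical
BS1; BS2 midpoints shifted by 0.15 °C, i.e. resolvable in principle but
only barely). The marker is fixed at 84 °C, width 0.5, amplitude 0.8, and
is always the rightmost BS1 component.

### Acquisition grid

The default grid covers 40–87 °C with 4,076 evenly spaced points per
segment (step ≈ 0.0115 °C), so the two concatenated segments give the
8,152-variable feature space the classifier consumes. The instrument's
0.1 °C/s ramp is folded into the grid; time is not simulated.

### Noise model and its defaults

Four seeded noise sources act on each simulated curve:

| source | default | models |
|---|---|---|
| global amplitude scale (log-normal σ) | 0.08 fresh / 0.20 processed | DNA quantity and degradation |
| temperature offset (σ, °C, one draw per run, both channels) | 0.3 | instrument drift, removed by marker correction |
| additive fluorescence noise (σ) | 1e-4 | detector noise |
| per-transition amplitude jitter (log σ) | 0.02 | within-species variation |

Half of all specimens are flagged *processed* and use the degraded
amplitude σ. The additive σ deserves a note: the derivative is taken with
a narrow 11-point Savitzky–Golay window on a ≈ 0.01 °C grid, which
amplifies white fluorescence noise by roughly the inverse grid step.
Instrument exports are internally filtered and visually smooth, so the
simulator's additive noise is set small (1e-4 on a ≈ 1-unit fluorescence
scale) such that the derivative's noise floor stays well below trough
depths (~0.2–0.4), as in real signatures. Amplitude variation — the
dominant artefact in degraded trade samples — is deliberately left large
and un-normalized (see below).

### Corpus design

The default design reproduces the study scale: 130 training specimens
across the 28 species, three replicate runs each (390 runs), plus 68
independent single-run test specimens covering every species. Because
per-species specimen counts are not public, the package ships a fixed
allocation chosen once as a realistic opportunistic sample: the six
look-alike-pair species get the minimum 3 specimens, the two thresher
sharks 6, the rest 5 (and 2–3 test specimens each). A packaged manifest
pins exactly 33 failing runs — 12 BS1 hybridization failures placed on
species whose status sheet marks BS1 non-amplifying, 6 BS2 failures
likewise, and 15 replicate-inconsistent runs simulated from a pinned
contaminant species. Corpus generation injects exactly these failures and
no others, so the corpus and everything downstream are pure functions of
(panel seed, design seed).

## Signatures, marker detection, temperature correction

Signatures are computed by Savitzky–Golay local-polynomial
differentiation (default window 11 points, order 3 — narrow enough to
preserve trough shape, wide enough to be exact for cubics). The marker is
detected as the rightmost local minimum in 80–87 °C with depth ≥ 0.05 *and
prominence* ≥ 0.05; the prominence requirement (the smaller of the rises
separating the trough from any deeper point or the window edge) is what
rejects noise ripples riding on the marker's own slopes, which otherwise
masquerade as "rightmost" minima. Both channels of a run are then shifted
rigidly by (84 − detected Tm) and linearly re-interpolated onto the
canonical grid; regions shifted past an edge are zero-filled (zeros are
neutral for the energy-based QC and for the classifier, unlike clamping
or extrapolation). Runs with no detectable marker are left uncorrected
and flagged for QC. Per-segment min–max normalization exists as an
explicit switch (`normalize = TRUE`) but is off by default: amplitude
variation is a real weakness of signature-based assignment and the
pipeline preserves it rather than papering over it.

## Quality control

Two rules, applied in order, mirror run filtering practice:

1. **Hybridization failure.** BS1 fails if, after masking ±1.5 °C around
   the marker trough, the residual signature energy (sum of squares)
   falls below θ_h = 0.1 of the marker's energy — i.e. only the marker
   melted. BS2 fails if its total energy falls below θ_h of the
   corpus-median BS2 energy. The thresholds are package defaults
   calibrated to the default noise model; with trough energies two orders
   of magnitude above the noise floor the rule is insensitive to θ_h over
   a wide range.
2. **Replicate inconsistency.** Within a specimen, a run whose mean
   correlation distance (1 − Pearson r of the concatenated BS1+BS2
   signature) to its sibling replicates exceeds θ_c = 0.2 is removed —
   worst run first, distances recomputed, repeated. The worst-first
   iteration matters: with one aberrant replicate among three, a single
   simultaneous pass would also drag the two consistent siblings over the
   threshold (their means include the outlier). Singleton specimens are
   never flagged. Re-measurement obviously cannot exist in silico, so the
   wet-lab practice of re-running inconsistent reactions is modelled as a
   single flag-and-remove pass.

On the default corpus these rules retain exactly 357 of 390 runs and
recover the injected manifest with perfect sensitivity and specificity —
a property the test suite checks at default noise and at zero noise.

## Features and classifier

Each retained run contributes one row: the BS1 and BS2 signatures
concatenated into 8,152 named features (replicates are independent rows;
specimen identity is carried for the grouped split). A run retained with
one failed segment is zero-filled there, so single-segment species remain
classifiable.

The classifier is a multi-layer feedforward network (softmax output over
the 28 species) trained by minibatch SGD with backpropagation on the
multinomial cross-entropy, with l1 (sparsity) and l2 (weight decay)
penalties. Defaults: two hidden layers (64, 32), rectifier activation, 50
epochs, learning rate 0.003 with momentum 0.9, batch 16, l2 = 1e-4,
features standardized by training statistics. The learning rate was
chosen for stable convergence at the 8,152-input scale; larger steps
(≥ 0.02) can collapse the softmax to uniform. RMSE is reported alongside
accuracy and is defined conventionally on one-hot targets vs score
vectors. Exact score ties in prediction break to the alphabetically first
species — a real concern here, because the configured identical pairs
produce genuinely symmetric scores at zero noise.

Splitting is exact-count stratified by species (70–30 by default, each
stratum rounded to the nearest row); `group_by_specimen = TRUE` keeps all
replicates of a specimen on one side, the leak-aware alternative to the
run-level split used by default.

The random grid search enumerates a Cartesian parameter grid, visits it
in seeded random order and stops at `max_models` candidates or a runtime
budget; the best model maximizes validation accuracy with ties broken by
lower validation RMSE, then earlier evaluation. The shipped default grid
(5 architectures × 2 activations × 4 learning rates × 3 l1 × 4 l2 = 480
combinations) exceeds the 301-model stopping criterion used at study
scale.

Variable importance uses Garson-style first-layer aggregation (sum of
absolute first-layer weights per input, scaled by the maximum and
normalized to percentages). A caveat the tests make explicit: with few
SGD updates, importance is dominated by the random initialization; it
localizes to genuinely discriminative temperature bands only when the l1
penalty has had enough updates to prune uninformative weights.

## Evaluation and panel accounting

Confusion matrices are exact counts with classes fixed in panel-sheet
order. "Visual" distinguishability — human judgment in practice — is
replaced by a reproducible proxy: a species is flagged indistinguishable
if some other species' noise-free mean signature lies within correlation
distance δ = 0.05 in *both* segments (differing in one segment suffices
to tell species apart, since inspectors see both channels).
Classifier-based distinguishability requires that no test specimen of the
species is misassigned and that no other species' specimen is assigned to
it; correct assignments whose winning margin is below 0.1 are flagged as
misassignment risks. Species absent from a test set are reported
*unassessed*, never silently indistinguishable. Panel tallies (22
visually distinguishable, 23 by classifier, 22 CITES-listed of which 12
sharks, 17 visually distinguishable CITES species) are always recomputed
from the packaged status sheet's flags rather than hard-coded; the
combined visual-or-classifier union computed this way is 26 species (5
CITES among the 6 visually indistinguishable), and recomputing rather
than quoting is what lets any inconsistency in transcribed totals
surface instead of propagating.

## Problem sizes used by the tests

The unit tests run on reduced grids (256–2,048 points) and small panels so
the suite stays fast; the study-scale checks use the full default design —
390 runs at 4,076 points, QC to 357, a 357 × 8,152 feature matrix, one
default-config fit (validation accuracy ≥ 90 % with residual confusion
concentrated in the look-alike pairs), and a 301-candidate grid search on
an 8-species reduced corpus. These sizes are the package's chosen balance
between fidelity and a test suite that completes in about a minute.

## What the synthetic corpus does not show

The simulator emulates the *structure* of instrument data — grid,
channels, marker, amplitude/drift/degradation noise, failure modes,
look-alike species — not its physics. Real signatures carry sequence
polymorphism within species, probe-competition effects, fragment-length
dependent degradation, baseline chemistry drift and vendor-specific
smoothing, none of which are modelled; "processed" tissue is reduced to a
larger amplitude σ. Passing tests therefore demonstrate that the pipeline
is correct and well-calibrated under its stated generative assumptions,
not that any particular accuracy will transfer to field data. Thresholds
(θ_h, θ_c, marker prominence, δ) are defaults for the default noise model
and should be re-examined against real exports, for which the
`read_melt_export()` dialect (comma-separated, temperature column plus one
column per run) is the entry point.
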