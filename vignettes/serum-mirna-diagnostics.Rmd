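---
title: "Serum miRNA diagnostic models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum miRNA diagnostic models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seromiR)
```

## Scope

`seromiR` builds and evaluates case/control diagnostic models from serum
miRNA microarray intensities of the kind used in multi-cancer early detection
(MCED) studies. The pipeline runs from raw probe intensities to a deployable
decision rule: sample quality control, presence calls, background
subtraction, internal-control calibration, redundant-sample removal,
moderated-t differential expression, cross-validated panel-size selection, a
weighted diagnostic index with a zero-false-positive cut-point, and
screening-test evaluation. A synthetic cohort generator reproduces the
statistical structure this pipeline assumes, so every stage is testable
without patient-level data.

## Preprocessing model and its assumptions

The platform emulated carries three probe classes: 2588 target miRNA probes,
a block of negative-control probes with no target (50 by default; the true
count on the physical chip is not public, so it is configurable), and three
internal-control miRNAs (miR-149-3p, miR-2861, miR-4463) whose biological
variation across sera is assumed negligible.

**Sample QC.** A sample fails when the coefficient of variation of its
negative-control signals exceeds 0.15, or when more than 10 probes were
flagged by the scanner. Both comparisons are strict, so CV = 0.15 or 10
flags still pass. The CV is computed on *untrimmed* control signals: the
source procedure attaches the 5% trimming only to the presence-call and
background-subtraction statistics, so the QC rule is read as operating on the
raw control set. The trimmed alternative is exposed as an option
(`cv_trimmed`), since the original pipeline's exact reading cannot be
established from its description; the log2 step before modelling is fixed,
because the moderated-t framework presumes log-scale data.

**Trimming.** `floor(0.05 k)` values are removed from each end of the `k`
ranked control signals — deterministic, and a no-op below 20 controls. The
trimmed standard deviation uses the `n − 1` denominator, the conventional
choice for small control sets; this is a deliberate resolution of an
ambiguity (a population-`n` convention would change presence thresholds only
marginally) and is recorded here rather than silently in code.

**Presence and background.** A probe is present iff its raw signal strictly
exceeds trimmed mean + 2 × trimmed SD of the controls. Background
subtraction computes `max(signal − trimmed mean, floor)` with `floor = 1`
on the linear scale, making the subsequent `log2` total. Absent probes are
*kept* at their floor-derived values rather than dropped — the ranking in
the modelled procedure runs over the full candidate set — but a
presence-rate filter (`presence_filter`) is available and off by default.

**Calibration.** Arrays are normalized by a per-sample additive shift in
log2 space chosen so every sample's internal-control mean equals a common
reference (by default the grand mean over passing samples; equivalently,
ratio scaling on the linear scale). After calibration every sample's
internal-control mean equals the reference to within 1e-9, and adding a
constant to all of one array's log2 values before calibration leaves that
array's calibrated values unchanged (exactly so when a fixed reference level
is supplied; with the data-dependent grand-mean reference, all samples shift
by the same constant, which no downstream statistic sees).

One consequence worth knowing: a probe floored on some array takes the value
`log2(floor)` *before* calibration and therefore carries the (negated)
calibration shift afterwards. All floored probes on an array are perfectly
correlated with one another. If sample source sites were confounded with
class, absent probes would then carry genuine class signal. This is why the
generator assigns sites independently of class by default (see below) — and
why real studies match discovery controls to cases by source site.

## Differential expression

The two-group design is implemented directly (the modelled study contrasts
only cancer vs non-cancer): per-probe group means, `logFC` = case − control,
pooled residual variance `s²` on `d = n₁ + n₂ − 2` df. The empirical-Bayes
prior (d₀, s₀²) is fitted by the method of moments on `log s²`: under the
hierarchical model

* `E[log s²] = log s₀² + log(d₀/2) − ψ(d₀/2) + ψ(d/2) − log(d/2)`
* `Var[log s²] = ψ′(d₀/2) + ψ′(d/2)`

with digamma ψ and trigamma ψ′. The excess of the sample variance of
`log s²` over `ψ′(d/2)` is inverted through ψ′ (monotone bisection on the
log scale, tolerance 1e-12, range 1e-3–1e7); no excess spread gives
`d₀ = ∞` and, when the variances are literally identical, `s₀²` equal to
that common value. Zero variances are excluded from the moment fit; an
all-zero input is an error.

The moderated statistic is `s̃² = (d₀s₀² + d s²)/(d₀ + d)`,
`t̃ = logFC / (s̃ √(1/n₁ + 1/n₂))` on `d₀ + d` df, two-sided p-values
clamped below at 1e-300, reducing exactly to the pooled t-test at `d₀ = 0`
and to a normal-reference statistic at `d₀ = ∞`. This is the standard
moderated-t construction; bit-equivalence with any particular library
implementation is not claimed, and the widely used Bioconductor
implementation serves as an independent cross-check in the test suite, never
as the computation. Benjamini–Hochberg adjustment is the step-up rule
`adj_(i) = min_{j ≥ i} n p_(j) / j` capped at 1. Probes are ranked by
ascending adjusted p, then ascending raw p, then descending |t̃|, then probe
id — a total, deterministic order.

## Panel selection, index, and cut-points

**Cross-validation.** Folds (10 by default) are stratified by class under a
fixed, recorded seed. Probe ranking *and* weights are re-estimated inside
each training fold, so no information from held-out samples leaks into
selection; held-out samples are scored with the raw weighted index and the
fold AUC recorded. The chosen panel size maximizes the mean held-out AUC
over `k = 1..50`, ties resolved toward the smallest panel (parsimony).
Whether the original modelled procedure refit inside folds is not stated;
refitting is the leakage-safe choice.

**Diagnostic index.** Weights are the signed moderated-t statistics of the
top-k probes (options: `logFC` or signed `−log10 p` would be drop-in
alternatives; t is used because it is the ranking statistic and encodes both
effect and precision). The raw index `Σ w_g x_g` is mapped affinely to 0–10
by the discovery-set minimum and maximum; out-of-range validation samples
are *not* clamped. The index inherits the calibrated log2 expression scale.

**Cut-points.** The screening cut-point is the smallest multiple of
`grid_step` strictly greater than the largest discovery-control index
(positive iff index ≥ cut-point), so discovery specificity is exactly 1 by
construction. The default grid of 1.0 mirrors an integer cut-point
convention; 0.1 expresses finer thresholds. A small tolerance (1e-9 of a
grid unit) guards the strict inequality against floating-point
representation of values like 5.7/0.1. The alternative
`cutpoint_for_specificity` chooses the smallest observed control value whose
strictly-below fraction reaches the target (e.g. 95%), coinciding with the
zero-FP rule in the limit of target 1.0.

## What the generator emulates — and what it does not

Intensities are log-normal: each target probe has a baseline log2 mean drawn
from N(7, 1.5²) and a residual SD whose square follows a scaled inverse
chi-square prior (d₀ = 8, s₀² = 0.12, i.e. typical SD ≈ 0.35 log2 units) —
matching both heavy-tailed microarray intensities and the variance hierarchy
the moderated t assumes. Negative controls share one class-independent
distribution (log2 mean 4, SD 0.15) placed near the low end of target
baselines so presence calls are nontrivial; internal controls have near-zero
biological SD (0.02) plus the full array-level shift. Each array receives a
random effect (SD 0.3 log2) plus its site's fixed shift (±0.2 by default),
exactly the structure internal-control calibration removes. Flagged-probe
counts are Poisson(2), far below the threshold of 10 unless failures are
injected.

Planted markers are shifted by their effect size in cancer samples only,
with two heterogeneity mechanisms: a continuous per-case, per-marker level
N(effect, 0.85²) (default), and an optional all-or-nothing dropout
probability (off by default). The continuous form reflects that tumours shed
each marker at individual levels; it caps any single marker's AUC while a
panel, averaging over markers, remains strong. The discrete form was
deliberately *not* made the default: all-or-nothing dropout creates rare
cases far below the decision threshold, which cross-validation learns to
paper over by adding dozens of noise probes — a pathology of the simulation,
not of the method. Marker baselines are boosted (+1.5 log2) because
clinically useful circulating markers are reliably above background.
Defaults were fixed once, using small pilot simulations of the
discovery/validation design, before the test suite was frozen.

Sites are assigned independently of class, emulating a source-matched
discovery design (see the calibration note above for what happens
otherwise). `draw_probe_params()` draws the per-probe baselines once so that
discovery and validation cohorts share a platform and population — without
this, the discovery index normalization would not transfer, which is itself
a faithful lesson about applying fixed models across populations.

Not modelled: miRNA biology, hemolysis or other pre-analytic artifacts,
probe cross-hybridization, spatial array defects (flagged counts are taken
as given), and any attempt to match the marginal distributions of specific
public datasets. Passing tests on these cohorts therefore demonstrate the
*procedure's* correctness and calibration — not that any particular real
dataset would yield the same panel or performance.

## Numerical and degenerate-input conventions

* Presence/QC/cut-point comparisons are strict exactly where documented;
  boundary cases (CV = 0.15, 10 flags, signal = mean + 2SD, index =
  cut-point) are pinned by tests.
* `log2` is made total by the linear-scale floor of 1.0.
* A zero-variance profile makes Pearson correlation undefined → error, as
  does an empty class for ROC or fewer than 2 samples per class for the
  linear model.
* Bootstrap AUC comparison resamples within class (preserving balance);
  zero bootstrap SD with equal AUCs gives p = 1. The McNemar test switches
  from the exact two-sided binomial to the continuity-corrected chi-square
  at 25 discordant pairs (configurable); its bootstrap replicate count and
  variant in the modelled study are unknown, so defaults are documented
  choices, not claimed reproductions.
* All generators and resamplers consume an explicit seed and restore the
  caller's RNG state.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the design sizes of the emulated
study — a 208/208 discovery and a 1358/1970 validation cohort on 2588
probes — for signature recovery (10 seeds), and at 200/200 for null
calibration (10 seeds for the type-I rate; CV leakage checked over the full
k-grid on 3 seeds). Unit and property tests use smaller instances (tens of
probes/samples) chosen to finish in seconds; oracle comparisons (exhaustive
AUC pair enumeration, brute-force BH, binomial McNemar) run at up to
200 × 200 scores and 1000 p-values. The bootstrap comparison's type-I error
is estimated from 500 null simulations at 500 replicates each.

## Known limitations

* The two-group design admits no covariates; confounding by age, sex, or
  site must be handled by design (matching), as the source-matched generator
  default illustrates.
* The zero-FP cut-point is an order statistic of the discovery controls; its
  out-of-sample specificity depends on the control sample being
  representative, and nothing in the construction guarantees validation
  specificity of exactly 1.
* Near-duplicate removal is greedy (priority dataset first, then dataset
  order, then sample id); the retained representative of a redundant pair is
  a convention, not an inference.
* `read_expression_table()` accepts exported probes × samples matrices so
  externally preprocessed data can enter at any stage, but no part of the
  package depends on, or validates against, any specific public dataset.
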