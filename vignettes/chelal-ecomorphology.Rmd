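---
title: "Chelal lever mechanics and divergence ordination: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chelal lever mechanics and divergence ordination: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chelamorph)
```

This vignette is the package's account of its science: the mechanical and
statistical models it implements, the assumptions behind them, the choices
made where the design was genuinely open, and what the shipped tests do and
do not establish.

## The static lever model

Astigmatid mites comminute food between the fixed and moveable digits of
their cheliceral chelae.  The chela is modelled as a frictionless rigid
lever rotating in a condyle: the adductor muscle pulls on a tendon at input
moment arm `L1U`, and the moveable digit of length `L2M` delivers the force
at its tip.  The velocity ratio `VR = L1U/L2M` is the ideal mechanical
advantage — low values are fast "tweezers", high values slow, strong
"pliers".

Muscular force scales with fibre cross-section, which is not observable on
a slide, so two bracketing anatomical assumptions are used.  The pennate
estimate `F1P = (CHI/2)(CLI − 1.1·L2M)` treats the shaft behind the
moveable digit as packed with fibres; the 1.1 factor inflates the moveable
digit for the part of it that sits inside the base around the condyle, and
is a fixed constant here (exposed as the `inflation` argument).  The radial
estimate `F1C = π(CHI/2)²` treats the adductor as a half-height circular
cross-section; the half (the `shaft_fraction` argument, default 0.5) leaves
room for the opening abductor below it.  Both tendon forces are rectified
into tip ("crunch") forces by the velocity ratio, and their mean `F2AV` is
the consensus used everywhere downstream.  All forces are surrogates in
µm²; no absolute calibration is implied.  For cross-suborder comparison a
separate toughness surrogate `VR·CHI²` is used, because the comparative
oribatid literature records the full squared shaft height rather than the
half-height disc.

Species crunch-force summaries in the packaged reference table are stored
exactly as published.  They are per-individual averages, so recomputing
`F2AV` from the species mean primaries lands slightly low (a Jensen-type
gap).  Measured on the packaged table the gap is at most 3.4%, largest for
the two high-variance pyroglyphids; the shipped tests bound it at 3.5%.
Both conventions appear in outputs and are labelled: reference-table work
uses the published summaries, simulated individuals always derive their
force from their own primaries.

## The typical reference mite and the divergence transform

The analysis needs a yardstick.  The i-th "typical" individual is the mean
over the 47 species of each species' i-th individual, measure by measure;
its crunch force is computed from those averaged primaries.  This gives a
compact central pseudo-species (its spread is the between-draw variance of
a 47-species average, about `sd/√47` per measure) whose means reproduce the
published typical constants: size 216.42 µm, reach 98.17 µm, gape
26.45 µm, height 51.59 µm, input lever 12.66 µm, crunch force ≈ 926.5 µm².
Note the crunch-force column mean of the species summaries (≈ 985 µm²)
deliberately does **not** equal the typical value — the typical design's
force comes from its averaged geometry, not from averaging forces.

Each observation is then replaced by its individualised divergence: the
quadratic-discriminant log Bayes factor contrasting the species' Normal
model with the typical reference model.  It is zero in expectation for the
reference individuals themselves and grows with both mean displacement and
variance mismatch.  The formula is implemented with the published sign
convention, under which a strongly divergent species takes large *negative*
values in every measure (the reference SDs are an order of magnitude
smaller than any species SD, so the reference quadratic term dominates).
This is inverted relative to a textbook "species over reference" Bayes
factor; we flag it rather than correct it, because every downstream
constant (the nomogram weights) was fitted on this convention.

## The ordination and its conventions

Divergence columns are standardised (equipoise: each variable contributes
unit variance), 0/1 species indicators — including one for the reference
pseudo-species, which contributes only 1/48 of the generalised variance —
are appended and standardised likewise, and the correlation matrix of the
whole block is eigen-decomposed.  Three conventions make the output
deterministic and interpretable:

- **Sign orientation.** Component 1 is flipped so its summed loading on the
  six measure columns is non-negative; it is then the all-positive general
  scale axis, with the five chelal/cheliceral loadings exceeding the body
  size loading and cheliceral height among the largest.  Component 2 is
  flipped so the body-size loading is non-positive (the size-versus-aspect
  contrast).  Higher components use the summed-loading rule with the
  size-loading rule as tie-break.
- **Scores and the origin.**  Individuals are scored on all standardised
  columns and the whole cloud is translated so the typical pseudo-species'
  mean score is exactly the origin.  Distances and compass angles (0° =
  North = positive component 2, clockwise, East = 90°) are read from that
  origin.  Scoring the raw divergences alone also pins the typical to the
  origin but collapses every species onto one half-line (divergences are
  all negative), destroying the angular structure; the translated
  full-score convention keeps the species stellation.
- **Levels for hypothesis tests.**  Distances are tested at the species
  level (one polar point per species) by Welch's t — individual-level
  replication would make any distance contrast vacuously significant.
  Angles are tested at the individual level by the Watson U² and
  Mardia–Watson–Wheeler tests: species-level angles (21 vs 26 points for
  the main omnivore/fragmentary contrast) carry almost no directional
  power, and a randomization p-value of order 10⁻⁴ is only resolvable with
  hundreds of angular observations.  With individual angles the
  omnivore-versus-fragmentary contrast is significant (randomization
  p < 0.01) in every one of the 20 seeds the test suite runs.

On the default synthetic conditions the first two eigenvalues of the
six-measure (indicator-free) decomposition carry just over 80% of the
trace on average across seeds 1–20 — dominance is real but marginal under
within-species independence; real cohorts, with positively correlated
measures within species, would concentrate more variance in component 1.

## The heuristic classifier

Eight descriptors are coded +1 (above) or −1 (at or below) the typical
cuts: size `IL`, reach `CLI`, relative reach `CLI/IL`, hardness `F2AV`,
grip `F2AV/IL`, food size `L2M`, grab `L2M/IL` and oral stuffing
`L2M/CLI`.  Ratio descriptors compare the species' ratio of means against
the ratio of typical means; ties code −1, so the typical itself codes all
low.  The morsel class follows the (food size, hardness) pair — pan-,
macro-, micro-saprophage or fragmentary feeder — and the functional group
follows: large pan-saprophages are Type 1 omnivores, small fragmentary
feeders Type 2, small long-reach pan-saprophages small omnivores, and
everything else a specialist.  Habit is surface for large species,
interstitial for small.  This rule set was reverse-engineered from the
published verbal tables and is verified cell-by-cell by a shipped test:
all 47 × 8 descriptor labels plus the typical row, all morsel-class and
habit/foraging tokens, the 10/20/5/12 group partition and the 20/27
surface/interstitial split reproduce exactly.  The published binary
omnivore/fragmentary split of the 17 specialists is *not* rule-derivable
and ships as metadata only.

Banding against other suborders uses fixed published thresholds: toughness
boundaries at 1039.0, 2642.7 and 3807.0 µm², closing-speed boundaries at
VR = 0.276, 0.5 and 0.65, and a pest-range line at toughness 1100.6 µm².
Boundary values band low, consistent with the global tie rule.  These
constants are data, never re-derived.

## The nomogram and field prediction

The two-component nomogram applies fixed published weights to a field
sample's divergences, computed with the sample's own mean and SD against
the packaged typical constants, normalised by the original fit's
eigenvalues (5.48, 1.81).  A sample statistically identical to the typical
reference maps to (0, 0).  Samples under 10 individuals trigger a warning
(the sample SD entering the divergence is then noisy); a single specimen is
routed to the nearest-centroid rules instead: the raw Euclidean `d_j` over
the six measures against the 47 published species means (mixed µm/µm²
units exactly as published, so crunch force dominates; a standardised
variant exists but is marked non-canonical), and the ±1 sign-code lookup,
which tolerates missing measures and reports co-minimal species as ties.

## The synthetic cohort generator

The generator defines the study conditions: 20 individuals per species,
each primary measure independent Normal at the published per-species mean
and SD, with draws violating positivity or the pennate-space condition
`CLI > 1.1·L2M` redrawn (truncation by redraw preserves approximate
Normality near the boundary; over 100 consecutive rejections aborts with
the species named).  Independence is the default because the published
mean per-individual relative reach (0.466) is compatible with it — the
simulated value is ≈ 0.468 — and because no within-species covariances
were published; a correlation matrix can be supplied for sensitivity
analysis.  Per-species substreams are derived deterministically from the
single global seed, so adding or dropping a species leaves the others'
draws untouched.  Crunch force is always computed from the drawn
primaries, never drawn from the published force summaries, keeping the
generator and force model consistent; the published force SDs embed
unknown within-species covariance and are therefore not asserted against.

What the generator does not emulate: within-species correlation between
measures (on by option only), measurement error beyond the printed SDs,
ontogenetic or sex structure, and any non-Normality.  Consequently a
passing property suite shows the pipeline is correct under the published
summary structure, not that real cohorts would reproduce the published
eigenvalues, scores or p-values — those depend on the unpublished raw
specimens.

## Problem sizes and numerical choices

The test suite and acceptance script run at the study's own scale: 47
species × 20 individuals per cohort, 20 seeds for the stochastic property
suites, 199–1999 randomization replicates for the circular tests, 199–1000
iterations for the size-ratio null models, and one 2000-individual cohort
for parameter recovery.  Tolerances follow the data's precision: the
typical-row consistency check allows 0.02 (two-decimal transcription) on
directly averaged measures and 1 µm² on the recomputed crunch force;
sampling-based checks use standard-error bounds (4 SE for means, 5% ≈ 3 SE
for SDs at n = 2000).  Randomization p-values are `(1 + hits)/(B + 1)`, so
their floor is `1/(B+1)`, never zero.

## Known limitations

- Nearest-centroid recovery is the pipeline's weakest link: simulating a
  cohort from each reference species and asking for the truth among the
  top-3 `d_j` matches succeeds for 83% of species × seed combinations
  (780/940 over seeds 1–20), not 90%.  The cause is the reference table
  itself — more than a dozen species have crunch-force means within one
  sample-mean standard error of several neighbours in the 600–830 µm²
  range, and `d_j` is crunch-force-dominated by construction.  The
  corresponding acceptance test states the 90% aspiration and fails
  honestly; users matching real samples should read the full ranked list
  and the sign-code ties, not just the best match.
- The two-component dominance of the six-measure decomposition is marginal
  (≈ 0.80) under within-species independence, as noted above.
- The heuristic classifier is exact for the packaged reference species by
  construction-and-verification; applied to novel species it inherits all
  the brittleness of fixed cuts — species near a cut flip descriptors with
  small measurement error.
- The comparative cross-suborder table is carried verbatim from its
  sources, including rows whose recorded product column is not the product
  of its leverage and squared-height columns; no reconciliation is
  attempted.
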