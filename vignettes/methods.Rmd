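---
title: "Models and methods behind norcage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind norcage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(norcage)
```

# The scoring problem

Homecage NOR removes the experimenter from the loop: the animal lives in the
apparatus, objects rotate on a schedule, and behavior is read off a 2-fps
overhead video via pose keypoints. The analysis has to answer three
questions: *which frames are object exploration*, *how strongly does the
animal prefer the novel object*, and *how robust are those answers to
annotation disagreement and to environmental biases* (nest position,
corridor habits). This vignette documents the models and the choices made
where the design was genuinely open.

# Exploration classification

## Feature geometry

Per frame and side we compute snout–object distance (cm), heading alignment
(the angle between the ears-midpoint→snout axis and the snout→object vector,
degrees), body elongation (snout to tail base) and body-centre speed.
Coordinates are image pixels (origin top-left, y downward), converted by the
`px_per_cm` calibration; frames are 0-based and all windows half-open
`[start, end)`.

## The geometric rule

A frame is exploratory on a side iff distance ≤ 3 cm **and** alignment ≤ 45°
**and** the frame is reliable (all head keypoints above the 0.6 confidence
floor). Both thresholds are conventional NOR proximity-annulus values; both
are configurable and recorded in the output's metadata. Two refinements:

* **Near-field clause.** Within 1.5 cm of the object the alignment test is
  waived. When the snout is essentially on the object, the snout→object
  vector is shorter than the keypoint noise and the computed angle is
  meaningless; scorers treat snout-on-object contact as exploration
  regardless.
* **Tie-break.** If both sides qualify (possible only through noise — the
  windows sit on opposite walls), the nearer object wins.
* **Unreliable frames** inherit the previous frame's label only if that
  frame was exploratory (inside a bout); otherwise they are non-exploratory.
  This avoids opening bouts on untracked frames while not chopping bouts by
  single dropped frames.

## The random forest

The production classifier in this paradigm is a trained ensemble; here
`train_forest()` fits a standard random forest on the same feature set with
a fixed seed (deterministic) and reports out-of-bag error. Prediction
post-processing closes gaps ≤ 1 frame inside a side's bouts and drops bouts
shorter than 2 frames — at 2 fps these defaults remove single-frame flicker
while keeping 1-s bouts. The geometric rule remains available as a
transparent baseline, and the test suite requires the forest to at least
match it on synthetic data.

# Discrimination indices and windows

`DI = (T_nov − T_fam)/(T_nov + T_fam)`; `0/0` is flagged undefined (`NA`) and
excluded from cohort statistics rather than coerced to 0, because an animal
that never explored carries no preference information. The sample-phase DI
uses the entire sample phase; the test-phase DI uses the first 20 minutes
from the first classified exploratory frame on either side in the test phase
(the only machine-observable definition of "first interaction"), clipped at
the phase end. The relative DI, `DI_test − DI_sample`, is the recognition
measure: pairing the phases within animal cancels side preferences and other
per-animal biases, as the side-based DI columns make visible.

Time courses are 1-min bins of exploration seconds; Gaussian smoothing
(σ = 4 bins, kernel truncated at ±4σ and renormalized at the edges so
constants are preserved) is **display-only** — every statistic uses
unsmoothed bins. The "4 standard deviations" smoothing specification is read
as σ = 4 bins; this is ambiguous in the source methods, but since the
smoothed curve feeds no computation the choice affects plots only.

First-approach analysis uses an exact binomial test against 0.5, one-sided
toward novel-first (the directional hypothesis), two-sided available by
argument. The exact one-sided tails (e.g. 15/19 → p = 0.0096, 10/20 →
p = 0.588) are what the implementation returns; published analyses of this
design have printed slightly different binomial p-values (0.007 for 15/19),
consistent with a different sidedness or mid-p convention, and we deliberately
do not tune to match a convention that is not stated.

Cohort peak-exploration comparisons find the bin with maximal group-mean
exploration per phase and extract each animal's unsmoothed value there.
The ANOVA contract (`three_way_anova()`) is fixed-effects
facility × object × side with interactions, Type II sums of squares so
unbalanced cohorts are handled (types coincide in balanced designs). The BH
adjustment family is always the set of p-values reported together in one
table.

# Bias analyses

Dwell heatmaps (1-cm grid, body centre = mean of the spine keypoints — the
source methods do not state which point defines dwell) are accumulated over
sample + retention only, where the objects are side-symmetric. The
maximum-dwell cell is the nest; nest-left vs nest-right grouping is k-means
(k = 2, 10 restarts, fixed seed) on the (d_left, d_right) vectors, with
cluster identity resolved by comparing cluster means and a nearest-object
fallback (tie broken to the left, documented) for degenerate cohorts.

A corridor "visit" in synthetic data is an explicit event; when derived from
keypoints it is entry into the corridor radius for ≥ 2 frames, a software
stand-in for the hardware beam-break signal. Intervals between consecutive
corridor exits are scored 0/1 (same/opposite first object); intervals with no
exploration are skipped.

# The annotator-agreement surrogate model

With `N` true exploratory instances, an annotator's sample is `SS·N` frames
of which `Nexp = PEF·SS·N` are true, drawn uniformly without replacement;
false-positive frames are assumed never to coincide between annotators
(near-misses scatter around different bout edges). The expected overlap
between two independent annotators, normalized by `SS·N`, is then
`E|T₁∩T₂|/(SS·N) = (Nexp²/N)/(SS·N) = PEF²·SS`, independent of `N`;
`expected_overlap()` estimates it by Monte Carlo (default replicate count
keeps the SE under half a percentage point at N = 500) and the tests verify
the closed form against exhaustive subset enumeration at N ≤ 12. Across the
plausible range of true instance counts (500–13,600, i.e. 250 s to 113 min
of behavior at 2 fps) the grid shifts only by rounding/cap effects, within
~3 percentage points. When `PEF·SS > 1` the true-frame count is capped at
`N` with a warning, the excess going to false frames.

Surrogate DIs draw `SS₁, SS₂` independently and uniformly — the minimal
assumption for "randomly chosen sample sizes", and the one that reproduces
the expected negative-DI rate — and compute
`DI = (f·SS₁ − SS₂)/(f·SS₁ + SS₂)` with f = 1.67; `N` and `PEF` cancel. Over
the full 50–150% range, P(DI < 0) = P(SS₂ > 1.67·SS₁) = 0.1324 by direct
integration (about the 13th percentile); constrained to 80–120% the worst
case is `DI(0.8, 1.2) = 0.0536 > 0`, so the 1st percentile of the surrogate
distribution is positive — annotation variability of the empirically
observed magnitude cannot flip a true 67% novelty effect to a negative DI.

The empirical overlap matrix is oriented `M[A,B] = |A∩B|/|A|` (row =
reference annotator); the verbal definition of the matrix is grammatically
ambiguous between the two orientations, but both derive from the same stored
intersection counts and satisfy `M[A,B]·|A| = M[B,A]·|B|`.
`region_from_empirical()` widens the observed overlap range by a small
tolerance (default 0.01) so a point observation can match Monte-Carlo grid
cells.

# The synthetic session generator

A discrete-time Markov state process at the native 2-fps frame unit (frames
are the recording's atomic observation, so a continuous-time model would add
machinery without fidelity) over states nest / corridor / roam /
explore-left / explore-right. From roaming, a bout on side *s* starts with
per-frame probability `λ_s(t)·Δt` where

```
λ_s(t) = h₀ · b_s · (1 + A·exp(−(t − t_change)/τ)) · (f on the novel side in test)
```

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| frame rate | 2 fps | the recording standard emulated |
| phase durations | 9 d / 24 h / 24 h / 2 h | the task schedule (tests use scaled-down sessions, typically minutes-long phases, chosen for suite runtime; the generative law is identical) |
| baseline hazard h₀ | 0.004 /s/side | gives a realistic low pre-change exploration rate (~1–2 s/min) |
| boost amplitude A | 7 | with h₀ and 4-s bouts yields a post-change peak of roughly 10–13 s/min |
| decay τ | 480 s | 3τ ≈ 24 min, matching the observed 20–30 min recovery to baseline |
| novel factor f | 1.67 | the ~67% novel:familiar exploration increase, DI ≈ 0.25 |
| retention boost scale | 0.2 | the rebound at the return to familiar objects is much weaker than at the sample-phase change |
| bout duration | exponential, mean 4 s | a modelling convenience; the real bout-duration law is not characterized, so only bout *counts* and *total times* should be read quantitatively |
| nest entry / dwell | 0.002 /s, mean 300 s | produces realistic nest occupancy; constructed cohorts for nest-location tests raise the entry rate so resting dominates, as it does in day-long real recordings |
| corridor visits / dwell | 0.003 /s, mean 20 s | sparse drinking visits |
| corridor coupling | 0.5 | 0.5 means *no forcing*: the first bout after a corridor exit follows the hazards (which is the no-strategy null); values other than 0.5 force the first post-exit bout to the same side with that probability, in sample/retention only so the test-phase DI law stays exactly `f` |
| right-nest boost | 1 (off) | optional multiplier on the right-side hazard when the nest is in the right half, emulating the observed asymmetric nest bias |

With f = 1 and side bias 1 the law is exchangeable between sides; the
expected exploration-time ratio in the test window is exactly f (both sides
share the same boost and the same roaming opportunity), so cohort relative
DI converges to `(f−1)/(f+1)` — the parameter-recovery tests exploit this.
Bout starts can only occur from roaming, so the hazard-conservation test
conditions on the realized roaming frames: expected per-side starts equal
the sum of per-roam-frame probabilities.

Keypoints are emitted consistently with the labels: during a bout the snout
sits inside the object-access annulus (at 0.25–0.55 of the access radius,
keeping the heading geometry well-conditioned) with the head axis at the
object plus small angular noise; otherwise the body centre follows the
occupancy state (nest/corridor anchors, reflected random walk while
roaming). All parts get isotropic Gaussian jitter (SD 1 px) and confidences
drawn from a Beta peaked near 1 — the minimal degradation needed to make
classifier tests meaningful.

One global seed expands into independent substreams (state path, keypoint
noise) so adding draws to one component does not shift another, and an
identical seed + config reproduces a bit-identical session.

## What the generator does and does not emulate

It reproduces the *event structure* real pipelines consume: novelty-triggered
hazard dynamics, side factors, nest/corridor occupancy, label-consistent
geometry, tracking noise. It does not render video, model drinking
microstructure, circadian rhythm, posture idiosyncrasies, or annotator-style
systematic bout-boundary biases. Passing tests therefore demonstrate that
the *analysis* is correct under a faithful event model — not that the
classifiers would reach the same accuracy on real video-derived keypoints,
where posture features are far noisier.

# Numerical and degenerate-input conventions

* SS/PEF counts use R's round-half-to-even; the annotator simulator errors
  (naming the cap) when `PEF·SS > 1` is requested.
* DI on 0/0 → `NA` (flag), propagated through relative DI and excluded from
  cohort tests; negative times are a domain error.
* Test window undefined (no test-phase exploration) → flagged, not zero.
* Zero-variance or n < 2 inputs to the test wrappers return a flagged row
  instead of erroring, so cohort tables always assemble.
* k-means degeneracies (single mouse, identical nests, one-sided cohorts)
  fall back to the nearest-object rule with a warning; exact equidistance
  breaks to the left.
* Binning requires the bin width to be a multiple of the frame period;
  bout durations sum exactly to frame count × frame period.

# Problem sizes used by the test suite

The suite simulates minutes-scale sessions (typically 300/1800/600/1800 s
phases, ~9,000 frames) and cohorts of 8–20 mice; the overlap grid runs at
200 replicates per cell. These sizes keep every stochastic check at ≥3
standard errors of resolving power. All statistical acceptance checks are
self-calibrating (3-SE bands from the realized cohort), so scaling sessions
up only tightens them.

# Known limitations

* Exponential bout durations are unvalidated against real data.
* The near-field clause trades a little specificity for robustness; with
  very large `max_distance` it would dominate — it is intended for the
  conventional 3-cm annulus.
* The corridor-visit definition from keypoints (radius + 2 frames) is a
  proxy for the hardware beam-break and will differ at the margin.
* `first_approach` treats the first classified frame as the approach; brief
  sub-threshold approaches are invisible at 2 fps.
* The surrogate model assumes annotator errors are unshared (false frames
  never overlap); shared systematic biases would raise observed overlap
  without raising true agreement.
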