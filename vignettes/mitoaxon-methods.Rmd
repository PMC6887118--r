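---
title: "Models and measurement rules for axonal mitochondrial dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement rules for axonal mitochondrial dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoaxon)
```

# Overview

`mitoaxon` quantifies mitochondrial dynamics along quasi-1D sensory axons
from timelapse fluorescence stacks: fission and fusion event calling,
transport classification and run decomposition, morphometry, actin-patch
and Drp1-punctum analysis with the random-overlap probability statistic,
and immunofluorescence/FRAP quantification. All stages operate on a
calibrated kymograph representation: per frame, a 1D intensity profile
indexed by arc-length along an annotated axon path. Axons are quasi-1D at
the imaging scale (0.12 µm/pixel), so a 1D reduction loses nothing the
measurements need while keeping every stage simple enough to validate
exactly.

This vignette records the models and assumptions, every tunable parameter
with its default and rationale, what the synthetic-data generator emulates
(and deliberately does not), the numerical choices, and known limitations.
It states no empirical result that the package's tests or acceptance
script do not themselves compute.

# The kymograph representation

`extract_profiles()` samples the stack at one point per pixel of arc
length; intensity at each sample is the maximum over a transect
perpendicular to the path (default width 5 pixels), which follows small
lateral drift without mixing in off-axon background. The per-frame
background (mean and sd of off-mitochondria pixels) is estimated from the
profile itself by a median/MAD screen (retain values ≤ median + 3·MAD,
then take moments). The median of the profile is a robust background
estimator because mitochondria occupy a minority of the axon shaft
(roughly 15% in this preparation). Note that the max-transect makes the
profile background the maximum of several noisy pixels; its statistics
are estimated from the profile itself precisely so that thresholds refer
to the distribution segmentation actually sees.

# Segmentation

Detection and sub-pixel refinement are deliberately decoupled:

- **Detection** runs on a lightly smoothed profile (3-pixel boxcar):
  maximal runs above `background mean + 3·sd` (with a floor of 5% of the
  frame's dynamic range, so detection is defined on noise-free data).
  Three background sds is conservative against noise-driven false
  segments. Runs are recursively split at interior minima that fall below
  half the smaller flanking plateau: with a Gaussian PSF of σ = 0.1 µm,
  genuine inter-object gaps produce far deeper dips already at 3-pixel
  separations, while smoothed noise on a plateau rarely dips that far.
- **Edge refinement** uses the raw profile: endpoints are placed at the
  half-plateau crossing by linear interpolation, debounced so that a
  single noisy sub-half pixel cannot truncate a segment. For a symmetric
  PSF the half-amplitude crossing coincides with the true object edge,
  which is what makes ±1-pixel length recovery possible; a crossing at the
  low detection threshold would sit 2–3 PSF sigmas outside the edge and
  systematically overestimate lengths.

Segments shorter than 2 pixels (0.24 µm) are discarded as unresolvable.
Spatially overlapping mitochondria are recognizable by their additive
fluorescence; a segment whose plateau exceeds 1.6× the reference
single-mitochondrion plateau (series median) is flagged
`excluded_overlap`. Flagged segments are excluded from length statistics
but still counted for density — each flagged region contains at least one
mitochondrion, and dropping it from counts would bias density downward.
The 1.6 factor operationalizes "doubled plateau" with margin for noise
and for the unequal brightness of DsRed-labeled mitochondria.

# Track linking

Frame-to-frame assignment is greedy on interval overlap, penalized by
length mismatch (so a fast mover's new position does not capture a
differently-sized neighbour's track) with intensity difference as the tie
break; overlap-free links are allowed across a ≤ 2 µm centroid jump
because a mitochondrion at the maximum transport velocity (0.6 µm/s)
covers 1.8 µm between frames. Unmatched segments open or close tracks.
A leftover new segment overlapping (or nearly overlapping) a matched
previous segment becomes a candidate 1→2 split; a leftover previous
segment against a matched new one becomes a candidate 2→1 merge. Linking
asserts nothing about events — candidates are confirmed or rejected by
the event detectors.

# Event calling

**Fission** (`detect_fission()`): a candidate split is confirmed at the
first frame where (a) the minimum intensity in the gap has decreased to
the background level — operationalized as ≤ background mean + 2·sd, with
a floor of 1% of the parent plateau so the rule is defined at zero noise —
and (b) the edge-to-edge separation exceeds 0.6 µm (5 pixels). Transient
constrictions that dim but never reach background, or never separate
beyond 0.6 µm, are never confirmed. Two further guards reflect the
biology and protect exactness: the parent must have had a stable length
(within 2 pixels of its median over the preceding frames, one deviating
frame allowed because the opening gap can inflate the last pre-split
frame) — fission occurs along stalled mitochondria, and a "parent" whose
length keeps changing is another mitochondrion passing — and the
daughters' lengths must account for the parent (±2.5 pixels). A track
born from an unconfirmed merge is never accepted as a fission parent.

**Fusion** (`detect_fusion()`): a candidate merge is confirmed when the
product's profile is uniform (coefficient of variation of the smoothed,
background-subtracted interior < 0.15), its length is additive of the two
parents within 2 pixels and remains so over the following 3 frames
(rejecting transient apparent merges), and the parents are not the two
halves of a re-closing constriction (born by a common split and never
separated beyond 0.6 µm). When parents differed in brightness, the
redistribution of signal into the uniform product is recorded as evidence
(between-parent CV minus post-merge CV). The junction position is the
product's measured start plus the left parent's length; the call frame is
the frame where additivity is best, because the first apparent contact
can pass marginally while the partners still overlap mid-approach.

Event rates are reported as the percentage of mitochondria present at
window start that participate as event parents, scaled to a 10-minute
window; a mitochondrion fissioning twice counts once in the rate but both
events stay in the log.

# Motility

The leading end is the end facing the direction of motion (the distal end
at rest); detectable movement is a per-frame leading-end displacement
greater than 0.24 µm (2 pixels), suppressing localization jitter. Classes
are applied with precedence transported (> 1 µm excursion of either end
from its starting position) > oscillating (detectable bouts without
crossing 1 µm) > stalled; the precedence makes classification total and
deterministic where the verbal definitions overlap, and net displacement
for the oscillating class is evaluated over the whole movie. Tracks
observed under one minute are reported unclassifiable.

Runs are maximal movement episodes terminated by pauses of ≥ 6 s (two
frame intervals); run length sums distance regardless of direction, so it
always bounds the absolute net displacement, and switches are sign changes
between successive detectable-movement steps. Velocities are per
unidirectional bout: leading-end displacement over elapsed time. The run
decomposition is verified against an independent brute-force pause-scanning
oracle on 1 000 random traces, and runs still in progress at the end of a
movie are treated as censored in parameter-recovery analyses.

# Patches, puncta and the overlap statistic

Actin patches and Drp1 accumulations follow the same dynamics and share
one detector: transient supra-threshold elevations lasting ≥ 2 frames,
linked across frames by spatial overlap, with the extent taken at the
peak frame. Classification is by spatial relation: `fission_associated`
when the extent covers a fission position within ±1 frame of the call
(patches present at the first frame where fission is evident),
`mito_associated` when the extent overlaps any mitochondrial footprint
during the patch lifetime, else `non_mito`. Filopodial fates are taken
from annotation or simulation truth — filopodia are scored by eye in
practice and their image-based detection is out of scope.

For the overlap statistic, each fission event contributes the parent's
length A (at the last frame before the split), the summed patch length B
clipped to the parent, and the occupancy C = B/A. The probability of
observing patch overlap at all n sites under random placement is the
product of the C values, accumulated in log space. Two dialects are
reported: the full-precision product (default for new data) and the
product of two-decimal rounded proportions, which is the convention of the
published reference table bundled with the package — only the rounded
dialect reproduces that table's printed value, which is why both are kept.
Under the simulator's null (fission sites placed independently of
patches), the empirical site-in-patch colocalization rate equals the mean
per-event C — the calibration that justifies interpreting the product as
a chance probability.

# The synthetic-data generator

`simulate_dynamics()` is an event-driven stochastic simulation in
continuous 1D arc-length; the pixel grid enters only at render time.
Defaults mirror the imaging conditions: 110 frames at 3 s, 0.12 µm/pixel,
60 µm of axon. Mitochondria are intensity-labeled intervals (log-normal
lengths, median 2 µm; plateau intensities uniform in 80–120 counts to
mimic variable labeling). Per-10-min event probabilities convert to
per-frame hazards via `1 − (1 − p)^(Δt/600)`.

Study-condition defaults: fission probability 0.30 per 10 min per
(stalled, resolvable) mitochondrion; transport follows fission with
probability 0.80; 55% of runs contain a direction switch. Kinetics the
source literature leaves unquantified use plausible defaults documented
here as choices, not measurements: velocities uniform in 0.1–0.6 µm/s,
pauses 6 s + exponential (mean 12 s, so every scripted pause terminates a
run under the ≥ 6 s rule), run durations exponential (mean 15 s, minimum
4 frames) drawn once per run and split in two by a scheduled switch — so
run duration is independent of switching and censoring cannot bias the
switch fraction.

Several generator rules exist to keep the zero-noise ground truth
*operationally* consistent with the measurement rules, and are the
package's own design choices:

- **Fission daughters must be able to separate.** Both daughters receive
  a brief drift apart (0.9 µm total over 2 frames, budgeted between the
  two according to the free room on each side), so every true event
  becomes callable under the 0.6 µm criterion; a fission without room for
  separation defers — a constriction there would not complete. The drift
  displaces each daughter by ≤ 0.45 µm, below the 1 µm transport bound;
  transported daughters additionally run, directed into the freer side
  (the emergent mitochondrion moves into open axon space), with a first
  bout guaranteed past 1 µm.
- **Non-fusing mitochondria are impenetrable.** Movers stop at a 0.7 µm
  standoff from neighbours instead of passing through or dwelling in
  sub-resolution adjacency, which is indistinguishable from fusion — the
  acknowledged caveat of the fusion criteria (two ends within ~2 pixels
  can mimic a uniform fused product). With fusion enabled, approach to
  contact is allowed and resolved by the fusion hazard; movers stop at
  contact rather than jumping into overlap, fused products keep a
  resolvable clearance from neighbours and are refractory for 6 frames
  (membrane remodeling), which keeps chained multi-partner merges out of
  the pairwise event model.
- **Patches are independent of the dynamics** (uniform arrivals in space
  and time; log-normal extents, median 0.6 µm; lifetimes ≥ 2 frames,
  mean 30 s) — exactly the null the overlap statistic requires. Setting
  `fission_patch_bias = 1` conditions fission sites on patch overlap
  (with deferral when no patch is present), the alternative hypothesis
  used to verify the statistic's discrimination.

The renderer draws each interval with exact sub-pixel coverage on the
center row of a 7-pixel strip, convolves with a Gaussian PSF
(σ = 0.1 µm), adds overlapping intervals (fluorescence is additive),
then applies Poisson shot noise (gain 2 counts/photon) and Gaussian read
noise (sd 2) over a 10-count background. Scripted constrictions dim a
narrow zone without altering the true interval, for testing the
constriction-rejection rule.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: 2D/3D axon geometry and crossing axons, focus
drift and photobleaching, motion blur within a frame, membrane-potential
dependent intensity changes, organelle deformation during fission (events
are instantaneous splits), and filopodium formation. Validation on truth
shows the rules are implemented exactly; it cannot show robustness to
artifacts the generator does not produce.

# Statistics

Group comparisons mirror the field's reporting convention: per-group
normality by the Lilliefors-corrected Kolmogorov–Smirnov test (groups
under n = 5 are routed non-parametrically; the correction is what the
classic desktop packages actually compute behind their "KS normality
test"); two groups → Welch t (both normal) or Mann–Whitney; more groups →
one-way ANOVA with Bonferroni posthoc (all normal) or Kruskal–Wallis with
Dunn's posthoc; categorical 2×2 counts → Fisher's exact test. Dunn's
rank-sum posthoc (z on mean ranks with tie correction, Bonferroni
adjusted) is implemented in the package and checked against hand-computed
values. Corrections are applied within a comparison family only, matching
per-figure reporting practice.

# Problem sizes used in validation

The bundled validation scripts and tests use 50 noise-free axons (25
fission-prone, 25 fusion-prone) for oracle equivalence; 12 replicates of
500 mitochondria for the fission-rate coverage check; three sparse
populations of 240 mitochondria (> 200 events) for post-fission
transport; 40 movers over 12 minutes (> 300 completed runs) for the
switch fraction; 40 axon populations for the null calibration; and 1 000
random traces for the run-decomposition oracle. These sizes make binomial
confidence intervals tight enough to detect meaningful bias while keeping
a full validation run in minutes on a laptop.

# Known limitations

- Fusion junction position is fundamentally ambiguous after intensity
  redistribution; the reported junction assumes parents keep their
  lengths, which is exact in simulation and an approximation on real data.
- The overlap-exclusion rule (1.6× plateau) needs a representative
  single-mitochondrion reference; in a frame dominated by overlapping
  mitochondria the series-median reference can be misled.
- Sub-resolution adjacency (< 2 pixels) cannot be distinguished from
  fusion by any intensity criterion; the generator avoids creating it,
  and on real data such events remain a documented caveat.
- The pipeline assumes one axon per path annotation; crossing or
  fasciculated axons must be excluded upstream.
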