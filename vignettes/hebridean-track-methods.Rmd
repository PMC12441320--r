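---
title: "Measuring and classifying tridactyl dinosaur tracks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and classifying tridactyl dinosaur tracks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hebtracks)
```

## The measurement model

A tridactyl (three-toed) theropod pes track is reduced to a labelled 2D
landmark configuration in centimetres: the three digit tips (digits ii,
iii, iv, with iii central), the two hypexes (the interdigital notches
between ii-iii and iii-iv), and the posterior heel point. Tips are
digitized at the digit pad terminus; claw (ungual) marks are excluded
from all length measurements by this landmarking convention, because
their preservation is too variable to compare across tracks.

From a landmark set, `measure_track()` computes:

* **W**, the straight-line distance between the tips of digits ii and
  iv. This is the base of the *anterior triangle*, which makes the
  mesaxony ratio below the standard anterior-triangle ratio.
* **te**, the toe extension of digit iii: the perpendicular distance
  from tip iii to the width line. te is invariant under rigid motion of
  the landmark set (a property test verifies this).
* **digit axes**: each digit's axis runs from its proximal reference
  point to its tip - for digit ii the ii-iii hypex, for digit iv the
  iii-iv hypex, and for digit iii the midpoint of the two hypexes. The
  interdigital angles alpha (ii-iii) and beta (iii-iv) are the angles
  between these axes, and the total divarication is alpha + beta exactly,
  by construction. The primary literature delegates the precise axis
  construction to earlier methodological work without reproducing it;
  this is the simplest construction consistent with the published
  figures, and it reproduces the printed additivity of the angles.
* **L**, total track length, measured from the heel to the projection of
  tip iii along the track axis, taken as the bisector of the total
  divarication.
* **digit lengths** L~II~, L~III~, L~IV~ along the digit axes.

Derived ratios (`derive_metrics()`) are the dimensionless descriptors
the classification uses: l/w = L/W, mesaxony M = te/W, digit iii as a
percentage of track length (iii/L), and the iii/ii and iii/iv digit
length ratios. Missing measurements stay missing (`NA`): no operation
zero-fills, and a ratio whose denominator is missing or zero is
undefined rather than an error.

A note on digit lengths: the published measurement tables report digit
lengths that include the full proximal pad extent, which is *not* the
same quantity as the hypex-to-tip distance used here (the source leaves
the exact convention unstated). The two are geometrically incompatible
for large broad-toed tracks, so the package treats the printed digit
*ratios* as stored observational values carried alongside the record,
while its own landmark-derived digit lengths follow the hypex
convention. All reproduction checks against the printed tables are on
the printed columns themselves; nothing mixes the two conventions.

## Preservation grades, siding and cataloguing conventions

Each record carries an ordinal preservation grade 0-3 (0.5 steps):
grade 3 means sharply defined morphology; grades >= 1.5 are considered
reliable enough to *characterize* a morphotype; grade-1 tracks
characterize only when an explicit operator flag says surface wear is
acceptable (the published criterion is subjective, so the package makes
the judgement an input, defaulting to the conservative "referred");
grades below 1 are at best referred. Grading itself is qualitative
operator input, not something the package infers.

Positive-relief tracks are infill casts: on the base of a bed they
mirror the foot that made them, so `apply_relief_siding()` catalogues an
apparent right as a left (flagging the mirroring), and passes
negative-relief impressions through unchanged.

`validate_record()` cross-checks the arithmetic identities that link raw
and derived columns (|l/w - L/W| <= 0.02, |M - te/W| <= 0.02,
|iii/L - 100 L~III~/L| <= 0.05, divarication additivity to 0.02 deg, and
the size-class consistency of L). The tolerances absorb the 2-decimal
rounding of the printed inputs. Every row of the packaged 85-track table
passes with zero findings.

## The Hebridean morphotype rule engine

The Hebridean series (HBR_B1.1-B1.4, B2.1-B2.3, B3.1-B3.2, B4) is a
shape-and-size classification of tridactyl tracks, agnostic about
trackmaker identity. The package encodes each subgroup's published
diagnosis in a versioned YAML rules file (`hebridean_rules()`), split
into:

* **gates** - conditions that exclude a candidate outright: the
  length-size class implied by the diagnosed range (tiny < 10 cm,
  small 10-20, medium 20-30, large 30-50, giant >= 50), the admissible
  digit shapes (parallel-sided, sub-parallel, spindle, gracile,
  broad-round), the admissible hallux states (a posteriorly directed
  hallux occurs only in the tiny bird-like morphotype HBR_B4; an
  anterolateral padded hallux with an impressed heel defines HBR_B1.2),
  and hard metric bounds that the diagnoses state without hedging
  (e.g. l/w > 1.30 for HBR_B2.1 vs <= 1.30 for HBR_B2.2, track length
  < 15 cm for HBR_B3, < 10 cm for HBR_B4).
* **soft predicates** - bounds the diagnoses hedge with "generally",
  "typically" or "often". These contribute to a score, the satisfied
  fraction of the subgroup's soft predicates; a predicate on a missing
  metric counts as unsatisfied, never satisfied.
* **a combination rule** - "all" or "at least k of": the two small
  gracile subgroups are diagnosed exactly as *at least two of* three
  opposing criteria (HBR_B3.1: l/w > 1.50, M > 0.7, divarication
  < 50 deg; HBR_B3.2: l/w <= 1.40, M < 0.7, divarication > 50 deg).
  The B3.2 length-to-width bound is applied inclusively at 1.40 because
  the source's own worked examples treat a track at exactly 1.40 as
  satisfying it.

`classify_track()` filters by the gates, prefers candidates satisfying
their combination rule (falling back to partial scores when none does),
and picks the highest score; ties break by satisfied-predicate count and
then by a fixed preference order, with the co-maximal candidates
recorded as an explicit ambiguity. The result is deterministic and
order-independent. Because the two HBR_B3 subgroups (and HBR_B2.1/B2.2
near l/w 1.3-1.5) metrically grade into one another, the morphology
flags carry real discriminative weight: digit shape separates the
morphotype families, and the well-separated-digits flag separates the
"wide" gracile form from both its "narrow" sibling and the tiny
HBR_B4 tracks. Withholding flags strictly increases ambiguity - a
property the tests assert.

On the packaged 85-track table the engine reproduces the published
subgroup for all 85 rows (the acceptance floor is 80, with any
disagreement required to be flagged ambiguous rather than silently
misassigned).

One boundary choice: HBR_B1.3 is diagnosed at "approximately 30 cm",
which straddles the 30 cm medium/large class boundary, so its size gate
admits both classes. The source gives no resolution rule for tracks at
exactly the B2.1/B3.1 15 cm boundary; the < 15 cm gate is applied
exclusively, so boundary tracks default upward, and the soft scores
decide.

## Trackway kinematics

From n ordered track reference points (the intersection point of each
track's length and width lines), `trackway_geometry()` computes n-1
paces, n-2 strides, the width of the pes angulation pattern (WAP: the
perpendicular distance from a middle track to the stride line through
its neighbours), the pace angulation (interior angle between consecutive
pace segments; 180 deg in the straight zero-width limit), and, where
track long-axis bearings are supplied, the rotation of each track
relative to the trackway midline (the polyline through pace-line
midpoints), signed positive outward. Two-track sequences are accepted as
track associations yielding a pace or stride only, never kinematic
estimates.

Trackmaker estimates use the standard equations: hip height h = 4 FL
(FL the mean track length, in m), velocity
V = c g^0.5 lambda^1.67 h^-1.17 with g = 9.81 m s^-2 fixed and
c = 0.25 (Alexander) or 0.226 (Ruiz-Torices) - the two variants differ
by the exact factor 0.904 for every input - and the gait ratio
lambda/h, read as walking below 2.0 and running above. All estimates are
computed from unrounded intermediates; rounding happens only at
serialization (half-up at 2 decimals, the printing convention of the
source tables). Two documented consequences: the small-trackway gait
ratio evaluates to 1.27 at full precision (the printed 1.26 arises only
by rounding the stride to 0.52 m before dividing), and the printed
velocity pair for that trackway (0.67 / 0.74 m s^-1) is inconsistent
with the fixed 0.904 coefficient ratio - direct evaluation gives
approximately 0.75 / 0.68, so the package reproduces the pair as an
unordered range only.

The packaged trackway files are *reconstructions*: the source deposits
no coordinates, so reference-point positions were rebuilt from the
printed pace, stride, WAP and pace-angulation values (the law of cosines
confirms the printed values are mutually consistent), and axis bearings
from the printed rotation angles. The files are named `*_synthetic.csv`
to make their status explicit.

## Assemblage statistics

`summarize_assemblage()` averages each numeric column over the
characterized rows of each subgroup, matching the convention of the
published per-table average rows (means over present values only).
`metric_correlation()` computes sample Pearson correlations under an
explicit, named inclusion rule - the default "both-present" - because
the published figure captions name exclusion counts that cannot be
reconstructed uniquely from the tables; exact reproduction of the
printed coefficients is therefore not claimed, only their signs
(mesaxony falls as divarication widens, r < 0; the two digit length
ratios co-vary, r > 0). With the both-present rule the recomputed values
(about -0.41 and 0.63) in fact land close to the printed -0.408 and
0.625. `allometry_panel()` emits (L - te, te) pairs - central-digit
pronouncement against remaining track length - with a descriptive OLS
slope and no inferential statistics.

`bearing_rose()` bins bearings into 15-degree sectors by default (24
sectors, the conventional rose resolution; configurable, must divide
360) and reports the circular mean and mean resultant length R-bar,
computed from the standard trigonometric moments. R-bar near zero is
reported as "no preferred direction". No circular-statistics dependency
is used; the formulas are elementary and the tests pin them against
symmetry oracles (antipodal and four-point cancellation, rotation
equivariance).

## The synthetic generator and what passing tests mean

`sample_metrics()` draws uniformly within each subgroup's diagnosed
ranges - uniform because the source reports ranges, not distributions,
making uniformity the least-informative choice; "strict" draws use
nested ranges that are exclusive to the subgroup given its flag
profile. Internal consistency is enforced by construction (W from l/w,
te from M, digit iii length from iii/L, the divarication split
uniformly 0.42-0.58 between alpha and beta). Lateral digit lengths are
derived from the geometry: the hypex midpoint must sit at depth L~III~
along the digit iii axis, which fixes the combined hypex depth; a
0.92-1.08 asymmetry factor splits it between digits ii and iv, so the
digit ratios are emergent rather than sampled.

`construct_landmarks()` is the exact geometric inverse of
`measure_track()`: with the digit iii axis at tilt phi from the width
line's anterior normal, the angle constraints reduce the whole
configuration to one sinusoidal equation in phi, solved in closed form.
Solutions exist iff an explicit amplitude condition holds
(infeasibility errors name the violated constraint, e.g. te >= L);
solutions whose central-digit axis deviates more than 60 degrees from
anterior are rejected as non-anatomical. The identity
measure(construct(m)) = m holds to machine precision, and the test
suite asserts it at 1e-6 over 1000 random draws across all subgroups.

`wear_model()` degrades landmark sets with Gaussian jitter, inward tip
erosion, optional-landmark dropout, and a monotone severity-to-grade
map (severity 0 = identity, grade 3; severity 1 = grade 0.5). The
default magnitudes - about 0.4 cm of landmark uncertainty and 1 cm of
margin loss at full severity - are calibrated to the grade map's
meaning: grade 0.5 morphology is in practice too effaced to
characterize. A scientifically meaningful consequence shows up in the
robustness experiments: because the diagnostic criteria are *ratios*,
and proportional erosion shrinks te and W together, strict-region draws
remain correctly classified even under severe wear; accuracy is
monotone non-increasing in severity (the asserted property) but
declines only when asymmetric jitter at tiny track scales finally
crosses criterion boundaries. Ratio-based criteria resisting uniform
wear is precisely why the field uses ratios.

`generate_trackway()` inverts the kinematic equations (stride =
gait x 4 x mean track length), so `estimate_trackway()` recovers the
requested gait ratio exactly at zero step width and within 1% generally.
`generate_assemblage()` composes all of the above with a bearing model -
von Mises (aligned, "gregarious" movement) versus uniform ("milling") -
and writes a manifest carrying every parameter and the seed, so any run
is reproducible from its manifest alone.

What the synthetic data does *not* emulate: within-subgroup
distributions beyond range containment (the source reports only
min/max), substrate mechanics, 3D relief, outline shape, or correlated
measurement error between neighbouring landmarks. Passing recovery
tests therefore demonstrates the internal consistency of measurement,
classification and kinematics - not that the classifier would achieve
the same accuracy on newly digitized field material.

## Numerical conventions and problem sizes

* Angles in degrees, lengths in cm at the measurement layer; paces and
  strides in m, WAP in cm, matching the reporting convention of
  trackway tables.
* Stored values are full precision; printed-table comparison rounds
  half-up at the displayed decimals. Tolerances for table reproduction:
  0.02 on ratios and degree sums, 0.05 on the iii/L percentage; 0.01 on
  recomputed subgroup means (0.05 for iii/L).
* Collinear digit tips within 1e-8 cm give te = 0 with a warning;
  coincident required landmarks are an error.
* Random draws always run under a caller-supplied seed through a local
  RNG stream that restores the caller's state.
* The test and acceptance problem sizes - 1000 inverse-identity draws,
  25 strict draws per subgroup, 120 draws per wear severity, 36-bearing
  roses against a 300-replicate null - were chosen as the smallest
  sizes at which the Monte-Carlo properties are stable across seeds.

## Known limitations

* Locality and formation columns in the packaged table are best-effort
  transcriptions from descriptive prose; the source tables carry no
  locality column. No reproduced quantity depends on them.
* The rule engine is deliberately not probabilistic: it reproduces a
  deterministic published key, reports ambiguity, and abstains
  (unclassified) on contradictions. It does not estimate uncertainty.
* Digit-length semantics differ between the landmark layer (hypex to
  tip) and the published tables (pad-inclusive); see above.
* The exact exclusion sets behind the published correlation
  coefficients are ambiguous, so only their signs are asserted.
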