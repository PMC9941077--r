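---
title: "Assessing corneal suturing skill from multiple metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing corneal suturing skill from multiple metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suturemetrics)
```

## The assessment problem

Corneal suturing — closing a corneal wound with fine 10-0 nylon interrupted
stitches under an operating microscope — is a foundational microsurgical
skill, yet objective assessment tools for it are scarce. `suturemetrics`
implements a multiple-metrics assessment of recorded training sessions in
which a participant closes a 4 mm linear penetrating wound with three
stitches on a donor cornea mounted in an artificial anterior chamber. Four
independent data streams are analyzed per session:

1. **Instrument handling** — a time-stamped 2-D trace of the instrument tip
   position in the microscope field, classified into three zones.
2. **Stitch geometry** — entry/exit coordinates of each stitch digitized
   from an end-of-session photograph of the cornea.
3. **Timing** — a surgical event log of needle entries and thread cuts.
4. **Rater scores** — a 12-item wound-closure quality rubric (two blinded
   raters) and RULA ergonomic posture observations.

Cohorts of sessions from groups of differing experience (senior, junior,
novice) are then compared metric by metric with nonparametric tests.

## Zone analysis

The microscope working area is partitioned by two concentric circles: zone 1
is the corneal surface (default radius 5.5 mm, the standard 11 mm cornea),
zone 2 the surface of the mounting base excluding the cornea (default outer
radius 9.5 mm, a 19 mm artificial anterior chamber), zone 3 everything
outside. The trace is resampled at 1 Hz (nearest sample per tick, ties to
the earlier sample, both endpoints inclusive) and each retained sample is
attributed a zone by its distance from the center. Two conventions matter
and are fixed here:

* **Boundary inclusivity.** A distance exactly equal to a radius belongs to
  the inner zone, so zone 1 is topologically closed — a tool resting on the
  corneal rim is on the cornea.
* **Invisibility.** A sample in which no tool is visible in the field of
  view is allocated zone 3, whatever its last known coordinates: leaving
  the field is an excursion outside the base.

When several tools are visible, the trace carries one position per sample —
the innermost tool — because a tool working on the cornea dominates the
assessment. From the zone timeline we report the fraction of time per zone,
the full 3×3 transition table, and a *back-and-forth* count: the number of
direct 1→2 and 2→1 moves, raw and per minute. Experienced surgeons
concentrate their time in zone 1 and make few such moves; novices shuttle
between cornea and base frequently.

An image-based path is also provided: `render_frames()` draws synthetic
microscope frames (faint zone circles at intensity 0.2, a bright Gaussian
instrument blob), and `detect_instrument()` recovers the blob as the
intensity-weighted centroid of the largest connected component above an
Otsu threshold floored above the annotation intensity. This is an idealized
stand-in for real video: it exercises the detect→attribute pipeline, not
instrument segmentation in real footage. Centroid quantization can flip a
sample lying within a sub-pixel distance of a circle, which is why the
round-trip equivalence we test is ≥ 99% agreement rather than equality.

## Geometry analysis

From the calibrated stitch endpoints (pixel input requires an explicit
`mm_per_px` scale) four criteria are computed over *completed* stitches
only — an uncompleted stitch has no final endpoints in the photograph:

* **Length** of each stitch (entry–exit Euclidean distance, mm). A suitable
  corneal stitch is about 2 mm long.
* **Length ratio** of stitch *k* ≥ 2 to stitch 1, a drift measure: ratios
  above 1 mean stitches grow over the session, below 1 they shrink.
* **Distance between successive stitches** — the package defines this as
  the Euclidean distance between stitch midpoints, a convention the
  underlying assessment leaves open; midpoints are well-defined for
  non-parallel stitches and capture spacing along the wound (about 1 mm is
  satisfactory for three stitches on a 4 mm wound). Entry-point distance
  would be an alternative; the midpoint default is deliberate and
  documented rather than configurable silently.
* **Angle between successive stitches** — the acute angle between the
  undirected segment directions via |cos θ|, in [0°, 90°]; 0° is perfect
  parallelism. Only consecutive index pairs (1,2) and (2,3) are evaluated.

These definitions make the metrics exactly invariant to rigid motions of
the photograph and covariant (lengths, distances) or invariant (ratios,
angles) under scale — properties the test suite checks to 1e-9 over
randomized stitch sets.

For group statistics, geometry rows pool individual measurements (each
stitch for lengths, each pair for distances/angles, each k ≥ 2 stitch for
ratios) across a group's sessions, since per-session medians of two values
are noisy; per-session aggregation can be layered on top by the user.

## Time analysis

Times derive from the event log: the total raw time spans the first needle
entry to the last thread cut; each stitch's time runs from its needle entry
to its thread cut; the intermediate time is the mean gap between one
stitch's cut and the next stitch's entry, over consecutive completed pairs
(gaps bordering an uncompleted stitch have no defined endpoint and are
excluded). A fixed penalty of 300 s per required-but-uncompleted stitch is
added to the penalized total, so that abandoning the task early is never
mistaken for finishing fast. A session with no completed stitch at all
still gets a total: the raw span up to its last recorded event, flagged as
such, plus three penalties — non-finishers must remain rankable. Seconds
are used internally; reports print minutes.

## Scoring

The quality rubric is a data file, not code: the default ships the 12-item
modification of the Zhang corneal-suturing scale (three of the original 15
items — preoperative preparation, postoperative clean-up, knot rotation —
are not part of it), each item rated 1–5, giving totals in 12–60. The exact
item wording of the original instrument is not redistributed here; the
shipped file uses descriptive labels and any rubric file with its own items
can be substituted. Per-rater totals are combined as their unrounded
arithmetic mean; group medians are computed over the aggregated values.

The RULA (Rapid Upper Limb Assessment) ergonomic instrument is implemented
from its three published lookup tables, stored as editable CSV fixtures
with md5 checksums (an edited fixture warns). Table A scores the arm-wrist
side, Table B the neck-trunk-legs side, muscle-use and force additions give
scores C and D, and Table C combines them into the grand score on the
published 1–7 scale, saturating at the table margins. The transcription is
audited exhaustively in the tests: over the full posture grid the grand
score stays within 1–7 and is monotone non-decreasing in every input. Note
that assessment sheets sometimes print RULA out of 10; the published grand
score tops out at 7, and that is what the package reports.

## Group statistics

The study design this package serves compares three experience groups whose
exposure differs *between* sessions: seniors and juniors keep operating
between training sessions, novices do not. The `"paper"` session-selection
policy therefore pools all three sessions of each novice participant while
keeping only the first session of juniors and seniors; `"first"` and
`"all"` are available for sensitivity analyses. The report states n per
group explicitly because the unit of analysis (sessions vs individual
geometry measurements) differs by row.

Comparisons use the Kruskal–Wallis rank test across the three groups and
the two-sided Mann–Whitney test for pairs, at α = 0.05, with no correction
across the report's rows (each row is interpreted as its own hypothesis).
Two numerical choices are worth stating:

* **Quartiles** use linear interpolation (`stats::quantile` type 7).
* **Small samples.** The chi-square approximation to the Kruskal–Wallis
  null is poor below a dozen observations (errors up to ~0.08 in p at
  n = 9). `kruskal_wallis()` therefore enumerates the exact permutation
  null whenever the total sample size is at most 10 (configurable), and
  uses the tie-corrected chi-square approximation above that — which is
  also what the common scipy/R implementations do at study scale.
  Mann–Whitney uses the exact null for small untied samples and the
  normal approximation with tie and continuity corrections otherwise.
  With all values identical, H = 0 and p = 1 by convention.

## The synthetic session generator

The recordings behind the original study are not publicly deposited, so the
package carries a first-class generator that emulates all four streams with
skill-dependent structure, calibrated loosely to the published group
medians:

* **Completion** is an independent Bernoulli draw per stitch
  (senior/junior probability 1, novice 0.9, matching the ~73% of novice
  sessions that complete all three stitches). Real novice failure is
  bimodal — some participants complete nothing — which independent draws
  cannot reproduce; the generator accepts this mismatch in the "none"
  achievement row.
* **Durations and gaps** are log-normal (positive, right-skewed, matching
  minute-scale medians with wide spreads): per-stitch medians 108/134/185 s
  and gap medians 67/57/78 s for senior/junior/novice.
* **The zone process** is a continuous-time 3-state Markov chain — the
  observable downstream is exactly a zone label per 1 Hz sample, so nothing
  richer is needed. Rates are reversible (`q_ij = c_ij / pi_i`) with
  stationary zone-1 occupancy 69.2% (senior), 54.7% (junior), 61.0%
  (novice) and 1↔2 flow intensities rising from senior to novice, so
  seniors dwell and novices shuttle. Positions are drawn uniformly within
  the occupied zone region; zone-3 samples are invisible.
* **Stitch geometry** perturbs the ideal template (midpoints evenly spaced
  on the wound, stitches perpendicular to it) with Gaussian spacing noise,
  length noise, per-stitch multiplicative drift (1.10 senior, 1.03 junior,
  0.88 novice) and angle jitter (3°/6°/7° sd). With all jitter set to zero
  the template is recovered exactly — a test anchor.
* **Scores**: rubric items are integer-rounded clamped-normal draws per
  item and rater (means 4.85/4.21/3.00, giving totals near 58/50/36);
  inter-rater correlation is not modeled. The RULA stream emits a posture
  realizing the profile's modal grand score (3 in all groups, so the
  ergonomics row is deliberately non-discriminating).

Sessions are generated independently given the participant's profile —
within-participant correlation across sessions and learning between
sessions are not modeled, which is acceptable for the cross-sectional
comparisons the report performs. Determinism is strict: a session is a pure
function of (profile, scenario, seed), and cohorts derive per-session seeds
from one master seed by a fixed counter scheme, so a cohort serializes
byte-identically under the same seed.

What passing tests on these data do show: the metric definitions, the
penalty and selection rules, the statistics, and the pipeline plumbing are
correct, and group structure of the assumed kind is recovered at study
scale. What they do not show: performance on real video (no segmentation
or tracking is implemented), robustness to digitization error in real
photographs, or the adequacy of the distributional assumptions to real
surgeons.

## Problem sizes and runtime choices

The packaged checks run at deliberate desk scale: zone round-trips use
1 000-sample traces; geometry invariances 1 000 random stitch sets; the
type-I calibration simulates 1 000 null cohorts of 8 participants per group
(event streams only — traces are skipped via the generator's `streams`
argument since they do not enter that statistic); group-structure recovery
uses the full default cohort (5/8/11 participants × 3 sessions, policy
`"paper"`, i.e. 5 + 8 + 33 analysis sessions). The long-run occupancy check
uses a 10 000-sample trace with a ±0.05 tolerance.

## Known limitations

* Zone analysis reports a single partition per sample; assessments that
  track instruments separately can attribute overlapping zone percentages
  that sum above 100%, which this package deliberately does not emulate.
* The inter-stitch distance and angle conventions (midpoints; acute
  undirected angle) are choices the field leaves open; comparisons across
  tools should confirm conventions match.
* The rubric aggregation (mean across raters) is a convention; no
  inter-rater reliability statistics are computed.
* `detect_instrument()` is built for the synthetic renderer's contrast
  regime, not for real microscope footage.
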