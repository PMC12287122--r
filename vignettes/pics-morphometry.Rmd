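---
title: "Levator ani morphometry in the 3D pelvic inclination correction system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Levator ani morphometry in the 3D pelvic inclination correction system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picsmorph)
library(dplyr)
```

## The measurement problem

Pelvic organ prolapse (POP) is a spatial condition: the positions of the
levator ani muscle (LAM) attachments shift posteriorly and caudally, and the
muscles lengthen. Scanner coordinates of MRI landmarks are not comparable
across subjects because every pelvis sits in the scanner with its own tilt
and position. The 3D Pelvic Inclination Correction System (PICS) fixes this
by anchoring a patient-specific Cartesian frame on bony landmarks:

* origin 0/0/0 at the **inferior pubic point**;
* **+x** anterior-to-posterior, **+y** superior-to-inferior, **+z**
  left-to-right (right-handed);
* the frame is tilted so that measurements mimic the physiologically upright
  pelvis, independent of supine scanner pose.

`picsmorph` implements the full chain: annotation I/O and validation, frame
construction and rigid transformation, muscle length/angle morphometry,
group summaries and differences, two-rater intraclass correlation, and a
synthetic cohort generator so that every stage is testable without patient
data.

## Frame construction

Four bony landmarks define the frame: the inferior pubic point and the
sacrococcygeal articulation in the midsagittal plane, and the bilateral
ischial spines in the axial plane. The algorithm in `build_frame()`:

1. `z` = unit vector from the left to the right ischial spine;
2. the pubis-to-sacrococcygeal vector is orthogonalized against `z`
   (Gram–Schmidt) to give a midsagittal direction `x0`;
3. `x` = `x0` rotated by the **pelvic inclination angle** about `z`, tilting
   the pubis–sacrococcygeal line down toward the PICS horizontal;
4. `y` completes the right-handed triad.

The sacrococcygeal articulation therefore lands on the midsagittal plane
(z = 0), posterior and superior to the pubis, and the pubis–sacrococcygeal
line subtends exactly the inclination angle with the PICS horizontal.
Whether the midsagittal plane should instead be defined through the spines'
midpoint is an open design point; the Gram–Schmidt construction was chosen
because it uses each landmark in the role its imaging plane suggests and is
insensitive to a symmetric error in spine depth.

**Inclination angle.** `inclination_deg` (default **34°**, range (0°, 90°))
is a configuration value, not an estimate. The default is the population
average pelvic tilt implied by the packaged landmark table: the left-side
coccyx mean (91.7, −61.8, 0) mm subtends atan2(61.8, 91.7) ≈ 34° below the
horizontal. Downstream lengths are invariant to this parameter (it rotates
the frame rigidly); signed plane angles and per-axis coordinates are not, so
it is surfaced in every relevant API.

Degenerate configurations (coincident spines, sacrococcygeal point at the
pubis, pubis on the inter-spine line) raise geometry errors naming the
violated condition rather than producing a silently ill-conditioned frame,
with absolute tolerances of 1e-6 mm on the defining lengths. Orthonormality
of the resulting rotation is asserted at 1e-9.

Midline structures (coccyx tip, sacrococcygeal articulation) are *asserted*
to land within `midline_tolerance_mm` of z = 0 after transformation, never
projected there: annotation noise should be visible. The default tolerance
of 1e-6 mm suits synthetic data; around 2 mm is realistic for manual
annotation.

## Morphometry

Muscles are measured as straight origin-to-insertion segments (no curved
centerlines). Point-selection rules follow the annotation protocol:

* **PAM** (puboanal): only the middle of its three marked insertion points
  (index 2) is used;
* **PVM** (pubovisceral) and **ICM** (iliococcygeus) origins: only the two
  border points (indices 1/3 and 1/4);
* three **auxiliary points** are interpolated at 1/4, 1/2, 3/4 between the
  PVM border origins, so the five points are equally spaced; they serve as
  effective origins of the fan-like PVM subdivisions.

The origin-to-insertion *pairing* per subdivision is genuinely
underdetermined by the measurement protocol, so it is configuration
(`default_muscle_graph()`, serializable to YAML) rather than code. The
packaged default: PVaM = auxiliary 1 → midpoint of its two insertions
(a symmetric compromise, since neither insertion alone is privileged);
PPM = auxiliary 2 → its insertion; PAM = auxiliary 3 → middle insertion;
PVM = border origin 1 → PAM middle insertion (the longest fan path,
consistent with the muscle splitting downward into its insertions);
PRM = origin 2 → insertion 1; ICM = origin 1 → insertion 1 and origin 4 →
insertion 2 (two segments); COC = ischial spine → each coccygeus insertion.
Alternative pairings can be tested by editing the YAML and re-running —
no package change needed.

**Angles.** With directional vector v = insertion − origin, the angle to
each reference plane is `asin(v·n/|v|)` in degrees, where n is the plane's
unit normal: posterior (1,0,0) for the coronal plane, inferior (0,1,0) for
the transverse plane, right (0,0,1) for the sagittal plane. Angles lie in
[−90°, 90°]; posterior/inferior/rightward vectors are positive. The asin
argument is clamped to [−1, 1] to absorb rounding at axis-aligned vectors;
zero-length segments raise an error rather than returning 0°, because they
indicate annotation mistakes. The three plane normals are orthonormal, so
sin²(coronal) + sin²(transverse) + sin²(sagittal) = 1 for every segment —
a property the test suite exercises.

```{r morpho-example}
subject <- generate_cohort(cohort_spec("control", n_subjects = 1, seed = 7))
compute_morphometry(subject) |>
  filter(side == "left") |>
  select(segment, length_mm, angle_coronal_deg, angle_sagittal_deg)
```

## Group statistics

Coordinates and morphometry are summarized per group with the sample mean
and SD (n−1 denominator); lengths and angles additionally get the median and
first/third quartiles. Quartiles use linear interpolation between order
statistics (`stats::quantile` type 7, the "inclusive" convention) — the
convention is stated because interquartile ranges are otherwise not
reproducible. Presentation rounding is half-even to one decimal and happens
only at `export_summary_table()`; all internal math is full precision.
Between-group differences are case-minus-control differences of means at
full precision. Muscle-length increases are reported against the control
mean as denominator (the natural "longer than normal" reading); the pooled
denominator gives slightly smaller percentages and can be derived from the
same table.

Summaries are computed per side and never pooled across sides: the two
sides are separate measurements of a roughly, but not exactly, symmetric
anatomy.

## Two-rater reliability

`icc()` estimates the intraclass correlation from the two-way ANOVA
decomposition (value ~ subject + rater). The default form is **ICC(2,1)** —
two-way random effects, absolute agreement, single rater: raters are a
sample from a population of raters, and single-rater coordinates are the
unit of analysis. The consistency form ICC(3,1) is available for
sensitivity analyses; a constant between-rater offset yields ICC(3,1) = 1
but ICC(2,1) < 1, which is the behavior one wants when absolute positions
matter. 95% confidence intervals use the classical F-distribution
construction; for perfect-agreement grids the residual mean square is
floored (at 1e-12 of the dominant mean square, for the interval only) so
the limits degenerate gracefully to [1, 1].

Grids with zero total variance are flagged `defined = FALSE` rather than
given a number: a coordinate that is 0 by definition for every subject and
rater (the coccyx z coordinate on the midsagittal plane) carries no
agreement information. The symphysis point is excluded from
`reliability_report()` entirely since all of its coordinates are 0 by
definition. The qualitative Landis–Koch bands as conventionally printed
have gaps (0.2–0.21, 0.4–0.41, 0.8–0.81); they are resolved as contiguous
half-open intervals — poor [−1, 0.2), fair [0.2, 0.4], moderate (0.4, 0.7],
substantial (0.7, 0.8], almost perfect (0.8, 1] — so every estimate gets
exactly one label, with boundary values assigned to the lower band.

ICC magnitudes are scale-dependent: points close to the frame origin have
small between-subject variance, so the same 2 mm rater noise yields a much
smaller ICC there. The reliability report of the synthetic cohort
reproduces exactly this pattern (poor/fair labels concentrate at the
near-origin puborectal origin points).

## The synthetic cohort generator

`generate_cohort()` emulates cohorts whose per-point coordinate
distributions match the packaged left-side group means and SDs
(`table2_point_model()`), with:

* independent Gaussian axes per point (an optional exchangeable
  within-point axis correlation is available to stress the statistics;
  the default is 0 because no covariance information is published);
* right-side points drawn independently with mirrored means (z negated) and
  identical SDs;
* frame-consistent bony landmarks, so each generated subject is exactly in
  its own PICS frame: the symphysis sits at (0, 0, 0) (its printed SD is
  0.0), the sacrococcygeal articulation is synthesized deterministically on
  the midsagittal plane 110 mm from the pubis along the inclination
  direction (it is needed by frame construction but has no published
  coordinate distribution; 110 mm matches the coccyx lying ~110 mm out
  along the same line), and the right ischial spine mirrors the left draw
  exactly. This bilateral-symmetry idealization of the bony pelvis is what
  makes generate → pose → re-frame an exact round trip;
* per-subject scanner poses drawn uniformly within ±15° per rotation axis
  and ±50 mm per translation axis — representative scanner positioning
  variation, purely a test-harness choice;
* second-rater annotation noise as independent zero-mean Gaussians
  (default SD 2 mm per axis), leaving defined-zero coordinates untouched.

**Randomness contract.** Every operation takes one master seed and derives
per-subject sub-streams as L'Ecuyer–CMRG streams
(`parallel::nextRNGStream`), which are provably non-overlapping; cohorts
are reproducible component-wise and the caller's RNG state is restored.

**What passing tests do not show.** The generator draws structures
independently, so correlated descent of neighboring organs, real left-right
asymmetry, rater bias (systematic offsets), and non-Gaussian annotation
errors are all absent. Tests against synthetic cohorts validate the
geometry, the statistics, and the plumbing — not the anatomical realism of
any particular dataset.

## Numerical and test design choices

* Rigid-transform identities are asserted at 1e-9 mm, end-to-end pipeline
  round trips at 1e-6 mm.
* Problem sizes in the test suite: mean-recovery checks use 500 subjects
  per group; ICC parameter recovery uses 200 replicates of 10-subject ×
  2-rater grids; pose invariance uses 100 random poses. These give
  Monte-Carlo errors comfortably below the asserted tolerances while
  keeping the suite fast.
* The per-axis Monte-Carlo bound 3·SD/√n used in the mean-recovery check is
  a 3-standard-error bound per coordinate. Applied jointly to all ~228
  group × structure × axis combinations it is deliberately strict: under a
  perfectly unbiased generator the expected number of chance exceedances is
  about 0.6 per run, so an isolated exceedance at ~3σ with no repeatable
  location is the expected behavior of a correct implementation, whereas a
  repeatable or many-axis failure indicates real bias. The suite keeps the
  strict per-axis form (with fixed seeds) rather than a multiplicity-
  adjusted bound so that genuine bias has nowhere to hide.
* ICC estimates are validated two ways: against a direct sums-of-squares
  oracle (explicit summation, no shared code) to 1e-10, and against frozen
  reference values from an independent implementation of the same
  two-way random-effects model.

## Known limitations

* Straight-segment lengths underestimate curved muscle paths by
  construction; no centerline or volumetric measures are provided.
* The muscle-graph pairing is a documented choice, not ground truth;
  results for fan-like subdivisions depend on it.
* The inclination angle is a parameter; no estimation from imaging is
  attempted.
* Only inter-rater (not test-retest) reliability is implemented.
* The generator's bilateral bone symmetry means frame-recovery tests do not
  exercise asymmetric spine configurations; `build_frame()` itself is
  tested separately under arbitrary poses and degenerate inputs.
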