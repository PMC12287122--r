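# picsmorph

Quantitative, landmark-based morphometry of the levator ani muscle (LAM)
subdivisions in a patient-specific pelvic coordinate frame — the 3D Pelvic
Inclination Correction System (PICS) — for researchers studying pelvic organ
prolapse (POP) with MRI-annotated 3D landmarks.

Scanner coordinates of pelvic landmarks are not comparable across subjects:
every pelvis lies in the scanner with its own tilt and position. PICS
anchors a Cartesian frame on four bony landmarks — origin 0/0/0 at the
inferior pubic point, +x anterior→posterior, +y superior→inferior,
+z left→right — with the frame tilted by a pelvic inclination angle
(default 34°) so that supine measurements mimic the upright pelvis. In that
frame the package computes, per subject and side:

* **muscle lengths** `‖insertion − origin‖` (straight Euclidean segments),
  with fan-like subdivisions measured from auxiliary points interpolated at
  1/4, 1/2, 3/4 between the pubovisceral border origins;
* **signed plane angles** `asin(v·n/‖v‖) ∈ [−90°, 90°]` of the directional
  vector v = insertion − origin against the coronal/transverse/sagittal
  plane normals (posterior, inferior, right are positive);
* **group summaries** (mean ± SD, median, quartiles) and case-minus-control
  differences of point coordinates;
* **two-rater reliability** as ICC(2,1) — two-way random effects, absolute
  agreement, single rater — with Shrout–Fleiss 95% CIs and Landis–Koch
  labels, per point, axis, and side.

A seeded synthetic-cohort generator emulates control and POP-case groups
from the packaged per-point means/SDs, so the entire pipeline is testable
without patient data.

## Worked example

The `analysis/` scripts run the study workflow end-to-end (simulate 22 + 22
subjects → PICS transform → morphometry → summaries → reliability →
figures), writing under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_transform_to_pics.R
Rscript analysis/03_morphometry.R
Rscript analysis/04_group_summaries.R
Rscript analysis/05_reliability.R
Rscript analysis/06_visualize.R
```

`03_morphometry.R` prints the mean segment length per muscle:

```
  muscle case control longer_in_cases_pct
1    coc 58.7    59.0                -0.6
2    icm 55.1    50.1                 9.8
3    pam 60.7    44.7                35.7
4    ppm 48.3    37.2                29.9
5    prm 53.5    44.0                21.6
6   pvam 28.4    23.9                18.7
7    pvm 62.8    50.8                23.6
```

— in the simulated cohorts the vertically oriented pubovisceral
subdivisions (PAM, PPM, PVaM, PVM) are markedly longer in cases, the
coccygeus barely differs. `04_group_summaries.R` prints the insertion
displacements along the superior–inferior axis (y, inferior positive; mm):

```
  structure index mean_control mean_case difference
1       pam     2         1.88     11.59       9.71
2       ppm     1        -2.97      3.07       6.03
3       prm     1        -7.51     -3.78       3.74
4      pvam     1       -12.33     -5.67       6.66
```

positive differences meaning the case insertions sit lower. (These are
sample statistics of one simulated 22 + 22 cohort and scatter around the
generating means accordingly.) `05_reliability.R` reports the ICC label
distribution for a 5 + 5 subject second-reading with 2 mm rater noise —
mostly `almost_perfect`, with `poor`/`fair` concentrated at points close to
the 0/0/0 origin, where between-subject variance is small relative to rater
noise.

In code, the same pipeline is three calls:

```r
library(picsmorph)
pts <- generate_cohort(cohort_spec("control", n_subjects = 22, seed = 1))
rec <- compute_morphometry(pts)          # lengths + angles per segment/side
summarize_morphometry(rec)               # mean/SD/median/quartiles per group
```

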