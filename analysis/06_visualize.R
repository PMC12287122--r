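#!/usr/bin/env Rscript
# Render the PICS-space landmark cloud of both cohorts, colored by muscle
# subdivision (pubovisceral origin bright red, pubovaginal insertion dark
# red, puboperineal orange, puboanal yellow, puborectal green, iliococcygeus
# blue, coccygeus gray).

library(picsmorph)

pics <- read_annotations("results/annotations_pics.csv")
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
for (grp in c("control", "case")) {
  path <- sprintf("results/figures/cohort_3d_%s.png", grp)
  render_cohort_3d(pics[pics$group == grp, ], path)
  cat("->", path, "\n")
}
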