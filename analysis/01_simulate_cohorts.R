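#!/usr/bin/env Rscript
# Simulate the two study cohorts (22 nulliparous controls, 22 prolapse cases)
# as landmark annotation sets, place each subject at a random scanner pose,
# and write the scanner-space annotation file that the rest of the analysis
# consumes. Everything downstream is deterministic given the seed.

library(picsmorph)

seed <- 1
dir.create("results", showWarnings = FALSE)

ctrl <- generate_cohort(cohort_spec("control", n_subjects = 22, seed = seed))
case <- generate_cohort(cohort_spec("case", n_subjects = 22, seed = seed + 1))
cohort <- dplyr::bind_rows(ctrl, case)

scanner <- apply_pose(cohort, seed = seed + 2)
write_annotations(scanner, "results/annotations_scanner.csv")

cat(sprintf("wrote %d points for %d subjects (%d controls, %d cases)\n",
            nrow(scanner), dplyr::n_distinct(scanner$subject_id),
            dplyr::n_distinct(ctrl$subject_id),
            dplyr::n_distinct(case$subject_id)))
cat("-> results/annotations_scanner.csv\n")
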