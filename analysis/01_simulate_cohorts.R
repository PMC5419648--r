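#!/usr/bin/env Rscript
# Generates the two synthetic study cohorts: a modeling cohort (65 courses,
# 221 gentamicin levels) drawn from the endocarditis population model, and a
# validation cohort (14 courses, 30 levels). Demographics, dosing (3 mg/kg
# once daily, 30-min infusions) and the peak/mid-interval sampling scheme
# follow the documented cohort structure; assay-error noise uses the EMIT
# polynomial. Writes the datasets and hidden truth tables under results/.

library(gentapk)

seed <- 1
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

mod <- generate_cohort(cohort_spec(rng_seed = seed))
val <- generate_cohort(validation_cohort_spec(rng_seed = seed + 1))

write_dataset(mod$cohort, "results/data/modeling_courses.csv",
              "results/data/modeling_events.csv")
write_dataset(val$cohort, "results/data/validation_courses.csv",
              "results/data/validation_events.csv")
write.csv(mod$truth, "results/data/modeling_truth.csv", row.names = FALSE)
write.csv(val$truth, "results/data/validation_truth.csv", row.names = FALSE)

n_obs <- function(g) sum(vapply(g$cohort, function(r) nrow(r$observations), 0L))
cat(sprintf("modeling cohort:   %d courses, %d observations\n",
            length(mod$cohort), n_obs(mod)))
cat(sprintf("validation cohort: %d courses, %d observations\n",
            length(val$cohort), n_obs(val)))
cat("datasets and truth tables written to results/data/\n")
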