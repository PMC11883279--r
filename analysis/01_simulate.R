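#!/usr/bin/env Rscript

# Step 1: generate the synthetic study cohort.
#
# Emulates the filmed design: 10 male subjects (3 jumps each) and 12
# female subjects (3 jumps each, one female with 2), at 5000 frames/s
# across a 40 mm gap, with 2 um Gaussian tracking jitter. Every trial is
# exported in the digitizer interchange format (tracks CSV + metadata
# config + ground-truth sidecar) under scratch/cohort/ -- bulky,
# regenerable raw data kept out of results/.

library(saltijump)

seed <- 20
out_raw <- "scratch/cohort"
dir.create(out_raw, showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_cohort(n_male = 10, n_female = 12, noise_sd = 0.002,
                          seed = seed)
for (i in seq_along(cohort)) {
  sim <- cohort[[i]]
  stem <- paste0(sim$trial$meta$subject_id, "_", sim$trial$meta$trial_id)
  export_sim(sim, out_raw, stem = stem)
}

n_by_sex <- table(vapply(cohort, function(s) s$trial$meta$sex, character(1)))
cat(sprintf("simulated %d jumps (%d male, %d female) -> %s\n",
            length(cohort), n_by_sex[["male"]], n_by_sex[["female"]],
            out_raw))
cat(sprintf("seed %d; frame interval 0.2 ms; gap 40 mm; noise 0.002 mm\n",
            seed))
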