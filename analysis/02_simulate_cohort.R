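#!/usr/bin/env Rscript
# Simulate a synthetic study emulating the acquisition: 19 subjects,
# 360 volumes at TR = 1 s, symptom effects following the published pattern
# (positive-symptom load raises within-region inhibition, lowers
# between-region excitation).
suppressPackageStartupMessages(library(fsdcm))

truth <- synthetic_truth(seed = 7)
coh <- generate_cohort(truth, n = 19)
write_cohort(coh, "results/cohort")
cat("wrote results/cohort: clinical.csv, truth.json and 19 series files\n")
cat(sprintf("generating effects (log units per centered covariate unit):\n"))
print(truth$beta)
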