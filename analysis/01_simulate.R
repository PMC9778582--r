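#!/usr/bin/env Rscript
# Step 1: simulate a dispensing dataset emulating the administrative source.
#
# Generates 5000 men with the default drug profiles (seven study drugs, market
# shares and median discontinuation times anchored to the published exposure
# counts and survival medians), plus the contaminant subpopulations that
# cohort selection must remove. Writes records/deaths/truth CSVs.

suppressMessages(library(bphpersist))

seed <- 20180401
out_dir <- "results/data"

params <- simulation_params(n_patients = 5000, seed = seed)
dataset <- generate_dataset(params)
write_dataset(dataset, out_dir)

status <- table(dataset$truth$eligibility_status[
  !duplicated(dataset$truth$patient_id)])
cat("simulated", params$n_patients, "patients with seed", seed, "\n")
cat("dispensing records:", nrow(dataset$records),
    "| deaths:", nrow(dataset$deaths), "\n")
cat("truth statuses:\n")
print(status)
cat("written to", out_dir, "\n")
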