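#!/usr/bin/env Rscript
# Step 4: drug-prescription networks and polypharmacy by age.
#
# Counts, for every pair of study drugs, the men prescribed both during
# follow-up, and tabulates the number of classes (1/2) and distinct drugs
# (1/2/>=3) prescribed per age group, with the younger/older summary as the
# arithmetic mean of per-age-group percentages.

suppressMessages(library(bphpersist))

data_dir <- "results/data"
out_dir <- "results/tables"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

records <- read_dispensing_records(file.path(data_dir, "records.csv"))$records
deaths <- read_death_records(file.path(data_dir, "deaths.csv"))
config <- study_config()

cohort <- select_cohort(records, deaths, config)$cohort

net <- build_pair_network(cohort)
write.csv(net$edges, file.path(out_dir, "network_edges.csv"), row.names = FALSE)
write.csv(net$nodes, file.path(out_dir, "network_nodes.csv"), row.names = FALSE)

poly <- polypharmacy_by_age(cohort, config)
write.csv(poly$classes_by_age, file.path(out_dir, "classes_by_age.csv"),
          row.names = FALSE)
write.csv(poly$drugs_by_age, file.path(out_dir, "drugs_by_age.csv"),
          row.names = FALSE)

ab <- class_drug_count_by_age(cohort, config, "AB")
write.csv(ab$by_age, file.path(out_dir, "ab_count_by_age.csv"),
          row.names = FALSE)

cat(net$n_detected_pairs, "of", net$n_possible_pairs,
    "possible drug pairs detected in", net$n_cohort, "men\n")
top <- net$edges[order(-net$edges$n), ][1:3, ]
cat("most common pairs:\n"); print(top, row.names = FALSE)
cat("\nsingle-AB percentage (mean of age-group percentages): younger",
    ab$single_drug_mean_pct[["younger"]], "vs older",
    ab$single_drug_mean_pct[["older"]], "\n")
cat("tables written to", out_dir, "\n")
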