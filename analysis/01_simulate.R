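#!/usr/bin/env Rscript
# Step 1: simulate the working cohort.
#
# One synthetic gastric-cancer cohort under the default study conditions:
# ~59% latent node-negative patients, mean 41 (sd 16.5) retrieved nodes,
# Weibull proportional-hazards survival driven by true nodal burden
# (log-HR 0.7 per true-LODDS unit), administrative censoring at 120 months
# plus 15% uniform dropout.

library(nodalstage)

seed <- 20160624L
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(n_patients = 4000, seed = seed)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort.csv")
jsonlite::write_json(unclass(cfg), "results/simulation_config.json",
                     auto_unbox = TRUE, digits = NA)

summary_tab <- data.frame(
  quantity = c("patients", "mean retrieved nodes", "sd retrieved nodes",
               "mean positive nodes", "sd positive nodes",
               "observed node-negative fraction",
               "latent node-negative fraction", "deaths",
               "median follow-up (censored, months)",
               "5-year overall survival"),
  value = round(c(nrow(cohort), mean(cohort$tnod), sd(cohort$tnod),
                  mean(cohort$pnod), sd(cohort$pnod),
                  mean(cohort$pnod == 0), mean(cohort$theta == 0),
                  sum(cohort$event),
                  median(cohort$time[cohort$event == 0]),
                  as.numeric(survival_at(km_estimate(cohort$time,
                                                     cohort$event), 60))),
                3))
write.csv(summary_tab, "results/cohort_summary.csv", row.names = FALSE)
print(summary_tab, row.names = FALSE)

message("Note: the observed node-negative fraction (",
        round(100 * mean(cohort$pnod == 0), 1),
        "%) exceeds the latent mass (",
        round(100 * mean(cohort$theta == 0), 1),
        "%) by the binomial false-negative rate at ~41-node retrieval -- ",
        "the mechanism behind stage migration.")
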