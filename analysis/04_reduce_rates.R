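#!/usr/bin/env Rscript
# Reduce the simulated campaign's sample log to metabolic rates.
#
# Reads the interchange CSVs written by 03_simulate_case_study.R back
# through the validating readers (so this stage is identical for real
# field logs), blank-corrects every treatment cycle against its site-day
# controls, and applies the alkalinity-anomaly and oxygen-flux equations.

suppressMessages(library(chamberflux))

samples <- read_sample_log("results/case_study_samples.csv")
colonies <- read_colony_metadata("results/case_study_colonies.csv")
volumes <- readr::read_csv("results/case_study_volumes.csv",
                           show_col_types = FALSE)

rates <- process_incubation_set(samples, colonies, volumes)
print(rates)

cfg <- run_config(seed = 20260927)
write_rates(rates, "results/case_study_rates.csv", cfg)
readr::write_csv(rates$daily, "results/case_study_daily.csv")
readr::write_csv(rates$cycles, "results/case_study_cycles.csv")

# site-level summary against the generating truth
suppressMessages(library(dplyr))
truth <- readr::read_csv("results/case_study_truth.csv",
                         show_col_types = FALSE) |>
  distinct(species, site, cell_p_net, cell_respiration, cell_g)
summary <- rates$colonies |>
  group_by(species, site) |>
  summarise(across(c(p_net, respiration, g, p_gross), mean),
            .groups = "drop") |>
  inner_join(truth, by = c("species", "site"))
print(summary, width = Inf)
readr::write_csv(summary, "results/case_study_cell_means.csv")
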