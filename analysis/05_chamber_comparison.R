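#!/usr/bin/env Rscript
# Chamber-equivalence comparison (flexible bag versus rigid glass vessel).
#
# Emulates the validation design under the null hypothesis of method
# equivalence: both chamber types are simulated with identical true rates
# and deployed simultaneously, sharing the same seawater controls -- so
# the blank correction is common to both designs and cancels from the
# comparison, as in a real side-by-side deployment. Ten colonies are
# measured in both designs (paired); fifteen further colonies per design
# are measured once (independent).

suppressMessages({library(chamberflux); library(dplyr)})
dir.create("results", showWarnings = FALSE)

seed <- 20260927
schedule <- tibble::tibble(cycle = c("L1", "D1"),
                           phase = c("light", "dark"),
                           start_h = c(0, 4.5), end_h = c(3, 7.5))

draw_colonies <- function(n, seed) {
  set.seed(seed)
  tibble(surface_area_m2 = runif(n, 8e-4, 16e-4),
         g = rnorm(n, 5.3, 0.8), p_net = rnorm(n, 4.1, 0.6),
         respiration = rnorm(n, 3.1, 0.5))
}

# one incubation set holding both designs' chambers + shared controls
measure_joint <- function(truth, seed) {
  s <- simulate_incubation(truth, schedule, volume_l = 1.05, seed = seed)
  process_incubation_set(s, truth, attr(s, "volumes"))$colonies
}

results <- list()

# paired: the same ten colonies enclosed in one chamber of each design
base <- draw_colonies(10, seed)
paired_truth <- bind_rows(
  mutate(base, colony_id = sprintf("c%02d.flexi", dplyr::row_number()),
         chamber_id = colony_id),
  mutate(base, colony_id = sprintf("c%02d.glass", dplyr::row_number()),
         chamber_id = colony_id))
rates_p <- measure_joint(paired_truth, seed + 1) |>
  tidyr::separate(colony_id, c("colony", "design"), sep = "\\.")
for (m in c("g", "p_net", "respiration")) {
  by_design <- split(rates_p, rates_p$design)
  results[[length(results) + 1]] <- compare_chambers(
    tibble(colony_id = by_design$flexi$colony,
           value = by_design$flexi[[m]]),
    tibble(colony_id = by_design$glass$colony,
           value = by_design$glass[[m]]),
    design = "paired", metric = m)
}

# independent: fifteen distinct colonies per design, same deployment
ind_truth <- bind_rows(
  mutate(draw_colonies(15, seed + 2),
         colony_id = sprintf("f%02d", dplyr::row_number()),
         chamber_id = colony_id, design = "flexi"),
  mutate(draw_colonies(15, seed + 3),
         colony_id = sprintf("v%02d", dplyr::row_number()),
         chamber_id = colony_id, design = "glass"))
rates_i <- measure_joint(select(ind_truth, -design), seed + 4) |>
  left_join(select(ind_truth, colony_id, design), by = "colony_id")
for (m in c("g", "p_net", "respiration")) {
  by_design <- split(rates_i, rates_i$design)
  results[[length(results) + 1]] <- compare_chambers(
    by_design$flexi[[m]], by_design$glass[[m]],
    design = "independent", metric = m)
}

out <- bind_rows(results)
print(out)
readr::write_csv(out, "results/chamber_comparison.csv")
cat("\ncomparisons rejecting at alpha = 0.05:", sum(out$p_value < 0.05),
    "of", nrow(out), "\n")
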