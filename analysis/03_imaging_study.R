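#!/usr/bin/env Rscript
# Imaging arm: generate en-face receptor images for every age x genotype
# cell, run the full morphometry (NMJ-morph style variables, perimeter
# fractal dimension, intensity bimodality, disruption classification), and
# write per-image records plus incidence tables.

library(nmjquant)
suppressMessages(library(dplyr))

dir.create("results", showWarnings = FALSE)

tab <- image_scenario_table()
rows <- list()
for (r in seq_len(nrow(tab))) {
  scen <- build_image_scenario(tab$age_weeks[r], tab$genotype[r])
  for (i in 1:8) {
    seed <- 45000 + 200 * r + i
    gen <- generate_nmj(scen, seed = seed)
    rec <- analyze_nmj_image(gen$image)
    rows[[length(rows) + 1]] <- bind_cols(
      tibble(age_weeks = scen$age_weeks, genotype = scen$genotype, seed = seed,
             truth_dim_fraction = scen$dim_fraction,
             truth_floccular_fraction = scen$floccular_fraction),
      rec
    )
  }
}
morpho <- bind_rows(rows)
write.csv(morpho, "results/morphometry_records.csv", row.names = FALSE)

recov <- morpho |>
  group_by(age_weeks, genotype) |>
  summarise(dim_est = mean(dim_area_fraction),
            dim_truth = first(truth_dim_fraction),
            fractal_median = median(fractal_dimension), .groups = "drop")
print(as.data.frame(recov), digits = 3)

sympt <- recov[recov$age_weeks == 20 & recov$genotype == "SOD1", ]
message(sprintf(
  "early-symptomatic mutant dim-area fraction: %.1f%% measured vs %.0f%% generated",
  100 * sympt$dim_est, 100 * sympt$dim_truth))

incidence <- morpho |>
  group_by(age_weeks, genotype) |>
  summarise(n_none = sum(floccular_category == "none"),
            n_lt50 = sum(floccular_category == "lt50"),
            n_gt50 = sum(floccular_category == "gt50"),
            n_extrajunctional = sum(has_extrajunctional),
            n_total = n(), .groups = "drop")
write.csv(incidence, "results/floccular_incidence.csv", row.names = FALSE)
message("majority-floccular junctions seen only in the mutant: ",
        all(incidence$n_gt50[incidence$genotype == "WT"] == 0))
message("records written to results/morphometry_records.csv")
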