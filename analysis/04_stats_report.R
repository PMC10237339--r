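#!/usr/bin/env Rscript
# Study-level statistics over the outputs of 01 (electrophysiology) and 03
# (morphometry): two-way ANOVA with Bonferroni post-tests for the
# mean-based electrophysiological measures, Ansari-Bradley + Mann-Whitney
# for the skewed morphometric variables, and per-age variance-ratio F tests
# for receptor area and cluster count.

library(nmjquant)
suppressMessages(library(dplyr))

stopifnot(file.exists("results/ephys/ephys_summaries.csv"),
          file.exists("results/morphometry_records.csv"))
ephys <- read.csv("results/ephys/ephys_summaries.csv")
morpho <- read.csv("results/morphometry_records.csv")
dir.create("results/stats", showWarnings = FALSE)

for (m in c("mepp_mean_corrected", "epp_mean_corrected", "qc", "mepp_frequency")) {
  tab <- ephys[!is.na(ephys[[m]]), c("age_weeks", "genotype")]
  tab$value <- ephys[[m]][!is.na(ephys[[m]])]
  res <- two_way_anova_bonferroni(tibble::as_tibble(tab))
  write.csv(res$anova, sprintf("results/stats/anova_%s.csv", m), row.names = FALSE)
  write.csv(res$post_tests, sprintf("results/stats/posttests_%s.csv", m),
            row.names = FALSE)
  sig <- res$post_tests$age_weeks[res$post_tests$adjusted_p < 0.05]
  message(sprintf("%-22s genotype differences at ages: %s", m,
                  if (length(sig)) paste(sig, collapse = ", ") else "none"))
}

for (m in c("fractal_dimension", "dim_area_fraction", "d_achr_area")) {
  tab <- tibble::tibble(age_weeks = morpho$age_weeks, genotype = morpho$genotype,
                        value = morpho[[m]])
  res <- nonparametric_compare(tab)
  write.csv(res, sprintf("results/stats/nonparametric_%s.csv", m), row.names = FALSE)
  sig <- res$age_weeks[!is.na(res$mann_whitney_p) & res$mann_whitney_p < 0.05]
  message(sprintf("%-22s median differences at ages: %s", m,
                  if (length(sig)) paste(sig, collapse = ", ") else "none"))
}

for (m in c("d_achr_area", "f_n_clusters")) {
  tab <- tibble::tibble(age_weeks = morpho$age_weeks, genotype = morpho$genotype,
                        value = morpho[[m]])
  res <- tryCatch(variance_f_test(tab), error = function(e) NULL)
  if (!is.null(res)) {
    write.csv(res, sprintf("results/stats/ftest_%s.csv", m), row.names = FALSE)
  }
}

report <- build_report(tibble::as_tibble(ephys), tibble::as_tibble(morpho),
                       out_dir = "results/report")
message("report bundle written to results/report/ (",
        length(report), " tables)")
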