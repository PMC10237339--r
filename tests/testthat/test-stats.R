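test_that("percent change reproduces the published reduction arithmetic", {
  expect_equal(round(percent_change(1.19, 0.94), 1), 21.0)
  expect_equal(percent_change(3, 3), 0)
  expect_equal(percent_change(2.0, 3.0), -50)  # an increase
  expect_error(percent_change(0, 1), "non-zero")
  # asymmetry follows from the definition
  expect_equal(percent_change(2, 1), 50)
  expect_equal(percent_change(1, 2), -100)
})

make_groups <- function(n, delta = 0, scale = 1, ages = c(8, 16), seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(ages, function(a) {
    tibble::tibble(
      age_weeks = a,
      genotype = rep(c("WT", "SOD1"), each = n),
      value = c(rnorm(n), rnorm(n, delta, scale))
    )
  }))
}

test_that("two-way ANOVA post-tests behave at the null and under a shift", {
  # identical groups: genotype effect indistinguishable from noise
  tab <- make_groups(40, delta = 0, seed = 3)
  res <- two_way_anova_bonferroni(tab)
  expect_gt(res$anova$p_value[res$anova$term == "genotype"], 0.01)
  expect_true(all(res$post_tests$adjusted_p >= res$post_tests$p_value))
  # Bonferroni is p times the number of per-age post-tests, capped at 1
  expect_equal(res$post_tests$adjusted_p,
               pmin(1, res$post_tests$p_value * nrow(res$post_tests)))

  # a 0.25 mV shift at one age with n = 60/group is detected with high power
  set.seed(11)
  hits <- 0
  for (rep in 1:40) {
    tab1 <- do.call(rbind, lapply(c(8, 16), function(a) {
      tibble::tibble(
        age_weeks = a, genotype = rep(c("WT", "SOD1"), each = 60),
        value = c(rnorm(60, 1.19, 0.3),
                  rnorm(60, ifelse(a == 16, 1.19 - 0.25, 1.19), 0.3))
      )
    }))
    r <- two_way_anova_bonferroni(tab1)
    hits <- hits + (r$post_tests$adjusted_p[r$post_tests$age_weeks == 16] < 0.05)
  }
  expect_gt(hits / 40, 0.9)

  empty <- tab[!(tab$age_weeks == 16 & tab$genotype == "SOD1"), ]
  expect_error(two_way_anova_bonferroni(empty), "empty design cell")
})

test_that("the nonparametric pair separates location from dispersion effects", {
  # identical samples: Mann-Whitney near 1
  set.seed(4)
  v0 <- rnorm(30)
  tab0 <- tibble::tibble(age_weeks = 8, genotype = rep(c("WT", "SOD1"), each = 30),
                         value = rep(v0, 2))
  r0 <- nonparametric_compare(tab0)
  expect_gt(r0$mann_whitney_p, 0.9)

  # location-only shift: Mann-Whitney fires, Ansari-Bradley mostly does not
  set.seed(5)
  loc_mw <- loc_ab <- scale_mw <- scale_ab <- numeric(30)
  for (i in 1:30) {
    shift <- tibble::tibble(age_weeks = 8,
                            genotype = rep(c("WT", "SOD1"), each = 40),
                            value = c(rnorm(40), rnorm(40, 1.0)))
    rs <- nonparametric_compare(shift)
    loc_mw[i] <- rs$mann_whitney_p; loc_ab[i] <- rs$ansari_p
    disp <- tibble::tibble(age_weeks = 8,
                           genotype = rep(c("WT", "SOD1"), each = 40),
                           value = c(rnorm(40), rnorm(40, 0, 3)))
    rd <- nonparametric_compare(disp)
    scale_mw[i] <- rd$mann_whitney_p; scale_ab[i] <- rd$ansari_p
  }
  expect_gt(mean(loc_mw < 0.05), 0.9)     # location detected
  expect_lt(mean(loc_ab < 0.05), 0.3)     # dispersion not implicated
  expect_gt(mean(scale_ab < 0.05), 0.9)   # converse pattern for scale
  expect_lt(mean(scale_mw < 0.05), 0.3)

  tiny <- tibble::tibble(age_weeks = 8, genotype = c("WT", "WT", "SOD1", "SOD1"),
                         value = c(1, 2, 3, 4))
  rt <- nonparametric_compare(tiny)
  expect_true(rt$underpowered)
  expect_true(is.na(rt$mann_whitney_p))
})

test_that("variance F tests detect inflated variability and reject degenerate input", {
  # analytic power oracle for a two-sided F test of a 3-fold variance
  # inflation at n = 40 per group, alpha = 0.005
  crit_hi <- qf(1 - 0.0025, 39, 39)
  crit_lo <- qf(0.0025, 39, 39)
  # observed ratio is 3F with F ~ F(39, 39)
  power <- (1 - pf(crit_hi / 3, 39, 39)) + pf(crit_lo / 3, 39, 39)
  set.seed(7)
  n_rep <- 60
  hits <- 0
  for (i in seq_len(n_rep)) {
    tab <- tibble::tibble(age_weeks = 12, genotype = rep(c("WT", "SOD1"), each = 40),
                          value = c(rnorm(40, 0, sqrt(3)), rnorm(40, 0, 1)))
    hits <- hits + (variance_f_test(tab)$p_value < 0.005)
  }
  expect_lt(abs(hits / n_rep - power), 3 * sqrt(power * (1 - power) / n_rep))

  single <- tibble::tibble(age_weeks = 12, genotype = c("WT", rep("SOD1", 5)),
                           value = c(1, rnorm(5)))
  expect_error(variance_f_test(single), "n >= 3")
  flat <- tibble::tibble(age_weeks = 12, genotype = rep(c("WT", "SOD1"), each = 5),
                         value = c(rep(1, 5), rnorm(5)))
  expect_error(variance_f_test(flat), "zero variance")
})

test_that("report tables conserve counts and track the generator ordering", {
  set.seed(21)
  morpho <- tibble::tibble(
    age_weeks = rep(c(16, 20), each = 40),
    genotype = rep(rep(c("WT", "SOD1"), each = 20), 2),
    a_endplate_area = runif(80, 200, 400),
    d_achr_area = runif(80, 100, 200),
    fractal_dimension = runif(80, 1, 1.5),
    dim_area_fraction = runif(80, 0.2, 0.6),
    floccular_category = ifelse(
      rep(rep(c(TRUE, FALSE), each = 20), 2) | runif(80) < 0.5, "none",
      sample(c("lt50", "gt50"), 80, replace = TRUE)),
    has_extrajunctional = runif(80) < 0.1
  )
  ephys <- tibble::tibble(
    age_weeks = rep(c(16, 20), each = 20),
    genotype = rep(rep(c("WT", "SOD1"), each = 10), 2),
    mepp_mean_corrected = rnorm(40, 1.1, 0.1),
    qc = rnorm(40, 40, 5)
  )
  out_dir <- file.path(tempdir(), "report_test")
  rep_tabs <- build_report(ephys, morpho, out_dir = out_dir)

  inc <- rep_tabs$incidence
  expect_equal(inc$n_none + inc$n_lt50 + inc$n_gt50, inc$n_total)
  expect_equal(sum(inc$n_total), nrow(morpho))
  expect_true(all(c("ephys_mepp_mean_corrected", "ephys_qc",
                    "morpho_dim_area_fraction") %in% names(rep_tabs)))
  expect_true(file.exists(file.path(out_dir, "incidence.csv")))
  unlink(out_dir, recursive = TRUE)

  # mutant symptomatic scenarios produce more floccular junctions than wildtype
  wt_flocc <- sum(inc$n_lt50[inc$genotype == "WT"] + inc$n_gt50[inc$genotype == "WT"])
  mut_flocc <- sum(inc$n_lt50[inc$genotype == "SOD1"] + inc$n_gt50[inc$genotype == "SOD1"])
  expect_gt(mut_flocc, wt_flocc)
})
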