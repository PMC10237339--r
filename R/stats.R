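#' Percent change relative to a reference
#'
#' `100 * (reference - observed) / reference`: positive values are reductions
#' (e.g. miniature amplitudes of 1.19 mV vs 0.94 mV give a 21.0% reduction),
#' negative values are increases.
#'
#' @param reference reference (control) value, non-zero
#' @param observed observed value
#' @export
percent_change <- function(reference, observed) {
  if (any(reference == 0)) stop_nmj("reference must be non-zero")
  100 * (reference - observed) / reference
}

check_group_table <- function(table, value_col = "value") {
  stopifnot(all(c("age_weeks", "genotype", value_col) %in% names(table)))
  if (!all(is.finite(table[[value_col]]))) stop_nmj("values must be finite")
  invisible(table)
}

#' Two-way ANOVA with Bonferroni-corrected per-age post-tests
#'
#' Fits `value ~ age * genotype` (both as factors, the junction as the
#' experimental unit), then compares genotypes at each age with two-sample
#' t-tests whose p-values are Bonferroni-adjusted across the ages tested
#' within the measure.
#'
#' @param table tibble with columns `age_weeks`, `genotype`, `value`
#' @return list with `anova` (main/interaction terms) and `post_tests`
#'   (per-age genotype comparison with group means, SEMs, raw and adjusted p)
#' @export
two_way_anova_bonferroni <- function(table) {
  check_group_table(table)
  tab <- table
  tab$age <- factor(tab$age_weeks)
  tab$genotype <- factor(tab$genotype)
  cells <- table(tab$age, tab$genotype)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop_nmj("empty design cell(s): %s",
             paste(sprintf("age %s x %s", rownames(cells)[empty[, 1]],
                           colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  if (nlevels(tab$age) < 2 || nlevels(tab$genotype) < 2) {
    stop_nmj("need at least 2 levels per factor")
  }

  fit <- aov(value ~ age * genotype, data = tab)
  an <- as.data.frame(anova(fit))
  anova_tbl <- tibble::tibble(
    term = rownames(an),
    df = an$Df, statistic = an$`F value`, p_value = an$`Pr(>F)`
  )

  ages <- levels(tab$age)
  post <- lapply(ages, function(a) {
    sub <- tab[tab$age == a, ]
    g <- split(sub$value, droplevels(sub$genotype))
    tt <- t.test(g[[1]], g[[2]], var.equal = TRUE)
    tibble::tibble(
      age_weeks = as.numeric(a),
      group_1 = names(g)[1], group_2 = names(g)[2],
      mean_1 = mean(g[[1]]), sem_1 = sd(g[[1]]) / sqrt(length(g[[1]])),
      mean_2 = mean(g[[2]]), sem_2 = sd(g[[2]]) / sqrt(length(g[[2]])),
      n_1 = length(g[[1]]), n_2 = length(g[[2]]),
      statistic = unname(tt$statistic), p_value = tt$p.value
    )
  })
  post <- dplyr::bind_rows(post)
  post$adjusted_p <- pmin(1, post$p_value * length(ages))
  list(anova = anova_tbl, post_tests = post)
}

#' Ansari-Bradley dispersion test followed by Mann-Whitney location test
#'
#' The non-parametric pair used for skewed morphometric variables: at each
#' age, genotype groups are compared first for dispersion (Ansari-Bradley)
#' and then for a difference between medians (Mann-Whitney U / Wilcoxon rank
#' sum). Groups smaller than 3 are flagged underpowered and reported without
#' p-values.
#'
#' @param table tibble with columns `age_weeks`, `genotype`, `value`
#' @return tibble with medians, IQRs and both tests per age
#' @export
nonparametric_compare <- function(table) {
  check_group_table(table)
  ages <- sort(unique(table$age_weeks))
  out <- lapply(ages, function(a) {
    sub <- table[table$age_weeks == a, ]
    g <- split(sub$value, sub$genotype)
    if (length(g) != 2L) stop_nmj("need exactly two groups per comparison")
    underpowered <- any(lengths(g) < 3L)
    if (underpowered) {
      ab_p <- mw_p <- NA_real_
    } else {
      ab_p <- ansari.test(g[[1]], g[[2]], exact = FALSE)$p.value
      mw_p <- wilcox.test(g[[1]], g[[2]], exact = FALSE)$p.value
    }
    tibble::tibble(
      age_weeks = a, group_1 = names(g)[1], group_2 = names(g)[2],
      median_1 = median(g[[1]]), iqr_1 = IQR(g[[1]]),
      median_2 = median(g[[2]]), iqr_2 = IQR(g[[2]]),
      n_1 = length(g[[1]]), n_2 = length(g[[2]]),
      ansari_p = ab_p, mann_whitney_p = mw_p,
      underpowered = underpowered
    )
  })
  dplyr::bind_rows(out)
}

#' Variance-ratio F test per age
#'
#' Compares genotype variances at each age for a designated morphometric
#' variable (the measure that flagged sustained variability increases in the
#' mutant from 12 weeks).
#'
#' @param table tibble with columns `age_weeks`, `genotype`, `value`
#' @return tibble with per-age variance ratios and p-values
#' @export
variance_f_test <- function(table) {
  check_group_table(table)
  ages <- sort(unique(table$age_weeks))
  out <- lapply(ages, function(a) {
    sub <- table[table$age_weeks == a, ]
    g <- split(sub$value, sub$genotype)
    if (length(g) != 2L) stop_nmj("need exactly two groups per comparison")
    if (any(lengths(g) < 3L)) stop_nmj("need n >= 3 per group at age %s", a)
    v <- vapply(g, var, numeric(1))
    if (any(v == 0)) stop_nmj("zero variance in a group at age %s", a)
    ft <- var.test(g[[1]], g[[2]])
    tibble::tibble(
      age_weeks = a, group_1 = names(g)[1], group_2 = names(g)[2],
      var_1 = v[[1]], var_2 = v[[2]],
      statistic = unname(ft$statistic), p_value = ft$p.value
    )
  })
  dplyr::bind_rows(out)
}

#' Assemble the study-level report tables
#'
#' Builds the figure-analogue summary tables from per-junction
#' electrophysiology summaries and per-image morphometry records: group mean
#' +/- SEM trajectories for each electrophysiological measure, median/IQR
#' trajectories for each morphometric measure, and incidence tables for the
#' floccular categories and extrajunctional clusters. If `out_dir` is given,
#' each table is also written as CSV.
#'
#' @param ephys per-junction summaries with `age_weeks`, `genotype` plus
#'   measure columns (as produced by [run_study()])
#' @param morpho per-image morphometry records with `age_weeks`, `genotype`
#' @param out_dir optional output directory for CSVs
#' @return named list of tibbles
#' @export
build_report <- function(ephys = NULL, morpho = NULL, out_dir = NULL) {
  report <- list()

  if (!is.null(ephys) && nrow(ephys)) {
    measures <- intersect(
      c("mepp_mean_corrected", "epp_mean_corrected", "qc", "mepp_frequency",
        "epp_rise_time", "rmp", "rundown_plateau"),
      names(ephys)
    )
    for (m in measures) {
      vals <- ephys[!is.na(ephys[[m]]), c("age_weeks", "genotype", m)]
      if (!nrow(vals)) next
      tabm <- dplyr::summarise(
        dplyr::group_by(vals, .data$age_weeks, .data$genotype),
        mean = mean(.data[[m]]), sem = sd(.data[[m]]) / sqrt(dplyr::n()),
        n = dplyr::n(), .groups = "drop"
      )
      report[[paste0("ephys_", m)]] <- tabm
    }
  }

  if (!is.null(morpho) && nrow(morpho)) {
    measures <- intersect(
      c("a_endplate_area", "d_achr_area", "f_n_clusters", "fractal_dimension",
        "dim_area_fraction", "valley_peak_ratio"),
      names(morpho)
    )
    for (m in measures) {
      vals <- morpho[!is.na(morpho[[m]]), c("age_weeks", "genotype", m)]
      if (!nrow(vals)) next
      tabm <- dplyr::summarise(
        dplyr::group_by(vals, .data$age_weeks, .data$genotype),
        median = median(.data[[m]]), iqr = IQR(.data[[m]]),
        n = dplyr::n(), .groups = "drop"
      )
      report[[paste0("morpho_", m)]] <- tabm
    }
    if ("floccular_category" %in% names(morpho)) {
      inc <- dplyr::summarise(
        dplyr::group_by(morpho, .data$age_weeks, .data$genotype),
        n_none = sum(.data$floccular_category == "none"),
        n_lt50 = sum(.data$floccular_category == "lt50"),
        n_gt50 = sum(.data$floccular_category == "gt50"),
        n_extrajunctional = sum(.data$has_extrajunctional),
        n_total = dplyr::n(), .groups = "drop"
      )
      report$incidence <- inc
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report)) {
      write.csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  report
}

#' @importFrom rlang .data
NULL
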