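#' Scenario presets for synthetic NMJ electrophysiology
#'
#' The study design crosses genotype (wildtype `WT` vs mutant-SOD1 `SOD1`) with
#' postnatal age. Ages with published diaphragm group means carry them directly
#' (`source = "printed"` in the shipped table); the remaining cells are
#' realistic defaults flagged `"assumed"`, and two 16-week mutant cells are
#' derived in code from the published relative effects at that age (a 27.7%
#' quantal-content reduction and a 43.7% mEPP-frequency reduction).
#'
#' The preset table ships as `inst/extdata/ephys_scenarios.csv` and can be
#' inspected with [ephys_scenario_table()].
#'
#' @param age_weeks Postnatal age in weeks. Valid ages are 2, 4, 8, 12, 16 and
#'   20 for `WT`; for `SOD1` the early-symptomatic group spans 18-22 weeks, and
#'   any age in that range selects it.
#' @param genotype `"WT"` or `"SOD1"`.
#' @param n_nmjs Number of junctions the scenario is intended to generate
#'   (metadata only).
#' @return An object of class `ephys_scenario`: a list with the amplitude,
#'   kinetic, membrane-potential, noise and vesicle-pool parameters used by
#'   [simulate_recording()] and [simulate_train()]. Amplitudes are means at the
#'   -70 mV reference potential.
#' @examples
#' build_scenario(2, "WT")$mepp_mean      # 1.48 mV
#' build_scenario(20, "SOD1")$mepp_mean   # 0.94 mV (early symptomatic)
#' @export
build_scenario <- function(age_weeks, genotype = c("WT", "SOD1"), n_nmjs = 10L) {
  genotype <- match.arg(genotype)
  tab <- ephys_scenario_table()
  age <- resolve_age(age_weeks, genotype, tab)
  row <- tab[tab$genotype == genotype & tab$age_weeks == age, ]
  if (nrow(row) != 1L) {
    stop_nmj("no scenario for genotype %s at %s weeks", genotype, age_weeks)
  }

  mepp_mean <- row$mepp_mean
  epp_mean <- row$epp_mean
  if (is.na(epp_mean)) {
    # encode the printed relative quantal-content effect against the
    # age-matched wildtype by inverting the non-linear-summation correction
    wt <- tab[tab$genotype == "WT" & tab$age_weeks == age, ]
    qc_wt <- quantal_content(wt$epp_mean, wt$mepp_mean, 70, 0.8)
    epp_mean <- epp_from_qc(qc_wt * (1 - row$qc_reduction_vs_wt), mepp_mean)
  }
  qc <- quantal_content(epp_mean, mepp_mean, 70, 0.8)

  structure(list(
    age_weeks = age,
    genotype = genotype,
    stage = row$stage,
    mepp_mean = mepp_mean,
    mepp_cv = row$mepp_cv,
    mepp_rate = row$mepp_rate,
    epp_mean = epp_mean,
    rise_time = row$rise_time,
    decay_tau = row$decay_tau,
    rmp_mean = row$rmp_mean,
    rmp_drift_sd = row$rmp_drift_sd,
    rmp_bounded = TRUE,
    noise_sd = row$noise_sd,
    pool_size = max(1L, as.integer(round(qc / row$release_fraction))),
    release_fraction = row$release_fraction,
    replenish_rate = row$replenish_rate,
    qc_true = qc,
    n_nmjs = as.integer(n_nmjs),
    id = sprintf("%s_%02dwk", genotype, age)
  ), class = "ephys_scenario")
}

#' @export
print.ephys_scenario <- function(x, ...) {
  cat(sprintf(
    "<ephys_scenario %s>\n  mEPP %.2f mV (CV %.2f) at %.2f /s; EPP %.2f mV (QC %.1f)\n  RMP %.0f mV, noise %.2f mV; pool N0=%d, p=%.2f, r=%.2f\n",
    x$id, x$mepp_mean, x$mepp_cv, x$mepp_rate, x$epp_mean, x$qc_true,
    x$rmp_mean, x$noise_sd, x$pool_size, x$release_fraction, x$replenish_rate
  ))
  invisible(x)
}

resolve_age <- function(age_weeks, genotype, tab) {
  if (is.character(age_weeks)) {
    if (grepl("^sympt", age_weeks, ignore.case = TRUE) || age_weeks == "18-22") {
      return(20L)
    }
    age_weeks <- suppressWarnings(as.numeric(age_weeks))
  }
  if (length(age_weeks) != 1L || is.na(age_weeks)) {
    stop_nmj("age_weeks must be a single age in weeks or \"symptomatic\"")
  }
  if (genotype == "SOD1" && age_weeks >= 18 && age_weeks <= 22) {
    return(20L)
  }
  ages <- sort(unique(tab$age_weeks[tab$genotype == genotype]))
  if (!age_weeks %in% ages) {
    stop_nmj(
      "age %s weeks is not in the %s design (valid: %s%s)",
      age_weeks, genotype, paste(ages, collapse = ", "),
      if (genotype == "SOD1") "; 18-22 selects the early-symptomatic group" else ""
    )
  }
  as.integer(age_weeks)
}

#' Full preset table of electrophysiology scenarios
#'
#' @return A tibble of per-age, per-genotype generator parameters with
#'   provenance flags (`printed` for published group means, `assumed` for
#'   package defaults, `derived_printed_ratio` for cells derived from published
#'   relative effects).
#' @export
ephys_scenario_table <- function() {
  path <- system.file("extdata", "ephys_scenarios.csv", package = "nmjquant")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Observed EPP amplitude implied by a quantal content
#'
#' Inverts the Martin non-linear-summation correction: given a true number of
#' quanta per stimulus `qc` and a mean single-quantum amplitude `m` (both at the
#' reference potential), the depolarization actually observed is compressed by
#' the falling driving force, `E = qc * m / (1 + f * qc * m / vm)`.
#'
#' @param qc quanta per stimulus
#' @param m mean miniature amplitude, mV
#' @param vm resting membrane potential magnitude, mV
#' @param f correction factor (0.8 by default, as in the source protocol)
#' @return observed EPP amplitude in mV
#' @export
epp_from_qc <- function(qc, m, vm = 70, f = 0.8) {
  linear <- qc * m
  linear / (1 + f * linear / vm)
}

#' Depolarized-fiber variant of a scenario
#'
#' Returns a copy of the scenario whose resting membrane potential starts near
#' the -50 mV rejection boundary and drifts without the usual physiological
#' bound, so that recordings cross -50 mV and exercise the rejection rule.
#'
#' @param scenario an `ephys_scenario`
#' @param rmp_mean starting membrane potential, mV
#' @param rmp_drift_sd drift scale, mV per minute
#' @export
scenario_depolarized <- function(scenario, rmp_mean = -54, rmp_drift_sd = 6) {
  stopifnot(inherits(scenario, "ephys_scenario"))
  scenario$rmp_mean <- rmp_mean
  scenario$rmp_drift_sd <- rmp_drift_sd
  scenario$rmp_bounded <- FALSE
  scenario$id <- paste0(scenario$id, "_depol")
  scenario
}
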