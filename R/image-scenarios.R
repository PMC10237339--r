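#' Scenario presets for synthetic en-face NMJ micrographs
#'
#' Encodes the published trajectory of postsynaptic receptor disruption: the
#' reduced-intensity (dim) area fraction plateaus near 40% in wildtype from 12
#' weeks while rising progressively to 60% at the early-symptomatic age in the
#' mutant; granular (floccular) texture appears in the mutant from 12 weeks
#' and never exceeds half the receptor area in wildtype; small dim
#' extrajunctional clusters occur at ~10% incidence in both genotypes.
#' Geometry and intensity levels are package defaults (arbitrary 8-bit units;
#' the imaging study reported no absolute intensity calibration).
#'
#' @param age_weeks 4, 8, 12, 16 or 20 for `WT`; for `SOD1` any age in 18-22
#'   selects the early-symptomatic preset.
#' @param genotype `"WT"` or `"SOD1"`
#' @param image_size image side, px
#' @param pixel_size microns per pixel (default 0.25, a typical 40x field)
#' @return an `image_scenario` list
#' @export
build_image_scenario <- function(age_weeks, genotype = c("WT", "SOD1"),
                                 image_size = 512L, pixel_size = 0.25) {
  genotype <- match.arg(genotype)
  tab <- image_scenario_table()
  age <- resolve_age(age_weeks, genotype, tab)
  row <- tab[tab$genotype == genotype & tab$age_weeks == age, ]
  if (nrow(row) != 1L) {
    stop_nmj("no image scenario for genotype %s at %s weeks", genotype, age_weeks)
  }
  structure(list(
    age_weeks = age, genotype = genotype, stage = row$stage,
    image_size = as.integer(image_size), pixel_size = pixel_size,
    endplate_scale = row$endplate_scale, ribbon_width = row$ribbon_width,
    n_branches = row$n_branches,
    dim_fraction = row$dim_fraction,
    floccular_fraction = row$floccular_fraction,
    p_extrajunctional = row$p_extrajunctional,
    n_extrajunctional_max = 3L,
    bright_intensity = row$bright_intensity,
    dim_intensity = row$dim_intensity,
    background_level = row$background_level,
    noise_sd = row$noise_sd,
    id = sprintf("img_%s_%02dwk", genotype, age)
  ), class = "image_scenario")
}

#' @export
print.image_scenario <- function(x, ...) {
  cat(sprintf(
    "<image_scenario %s>\n  %dpx at %.2f um/px; endplate %.0f um, ribbon %.1f um\n  dim %.0f%%, floccular %.0f%%, P(extrajunctional) %.0f%%\n",
    x$id, x$image_size, x$pixel_size, x$endplate_scale, x$ribbon_width,
    100 * x$dim_fraction, 100 * x$floccular_fraction, 100 * x$p_extrajunctional
  ))
  invisible(x)
}

#' @rdname build_image_scenario
#' @export
image_scenario_table <- function() {
  path <- system.file("extdata", "image_scenarios.csv", package = "nmjquant")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
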