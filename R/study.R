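#' Configure a full synthetic study
#'
#' One configuration drives the whole simulate-analyze-report pipeline: the
#' age x genotype design, group sizes, and a master seed from which every
#' per-task seed is derived deterministically (stable hash of master seed,
#' stage, group and replicate), so a fixed master seed reproduces every file
#' byte-identically.
#'
#' @param ages ages (weeks) for the electrophysiology arm
#' @param image_ages ages (weeks) for the imaging arm
#' @param genotypes genotypes included
#' @param n_nmjs_per_group junctions recorded per age x genotype group
#' @param n_images_per_group images analyzed per age x genotype group
#' @param with_trains also run the 20 Hz train protocol at each junction
#' @param master_seed master seed (integer)
#' @param output_dir optional directory for CSV outputs
#' @export
study_config <- function(ages = c(2, 4, 8, 12, 16, 20),
                         image_ages = c(4, 8, 12, 16, 20),
                         genotypes = c("WT", "SOD1"),
                         n_nmjs_per_group = 10L,
                         n_images_per_group = 5L,
                         with_trains = FALSE,
                         master_seed = 1L,
                         output_dir = NULL) {
  stopifnot(n_nmjs_per_group > 0, n_images_per_group >= 0)
  structure(list(
    ages = ages, image_ages = image_ages, genotypes = genotypes,
    n_nmjs_per_group = as.integer(n_nmjs_per_group),
    n_images_per_group = as.integer(n_images_per_group),
    with_trains = isTRUE(with_trains),
    master_seed = as.integer(master_seed),
    output_dir = output_dir
  ), class = "study_config")
}

#' Simulate and analyze one junction end to end
#'
#' Runs the full per-junction recording session (30 s spontaneous, 3 evoked
#' responses at 0.1 Hz, optionally a 20 Hz train), detects and measures
#' events, and returns the one-row summary.
#'
#' @param scenario an [build_scenario()] preset
#' @param seed integer seed
#' @param with_train include the 20 Hz train
#' @param sampling_rate samples per second
#' @export
run_nmj_session <- function(scenario, seed = 1L, with_train = FALSE,
                            sampling_rate = 20000) {
  spont <- simulate_recording(scenario, protocol_spontaneous(), seed = seed,
                              sampling_rate = sampling_rate)
  evoked <- simulate_recording(scenario, protocol_evoked(), seed = seed + 1L,
                               sampling_rate = sampling_rate)
  mepps <- detect_mepps(spont$trace)
  epps <- measure_epps(evoked$trace)
  prof <- NULL
  if (with_train) {
    tr <- simulate_train(scenario, seed = seed + 2L, sampling_rate = sampling_rate)
    prof <- rundown_profile(train_amplitudes(tr$trace))
  }
  summarize_nmj(mepps, epps, prof, duration = spont$trace$duration)
}

#' Run the full synthetic study
#'
#' For every age x genotype group, simulates and analyzes
#' `n_nmjs_per_group` recording sessions and `n_images_per_group`
#' micrographs, then assembles the report tables with [build_report()]. All
#' randomness derives from the master seed; re-running the same configuration
#' reproduces identical outputs. If `output_dir` is set, per-junction,
#' per-image and report CSVs plus a run manifest are written there.
#'
#' @param config an [study_config()]
#' @return list with `ephys` (per-junction summaries), `morpho` (per-image
#'   records), `report` (tables) and `manifest`
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  ms <- config$master_seed

  ephys <- list()
  for (gt in config$genotypes) {
    for (age in config$ages) {
      scen <- build_scenario(age, gt)
      group <- scen$id
      rows <- lapply(seq_len(config$n_nmjs_per_group), function(i) {
        seed <- derive_seed(ms, "ephys", group, i)
        s <- run_nmj_session(scen, seed = seed, with_train = config$with_trains)
        dplyr::bind_cols(
          tibble::tibble(unit_id = sprintf("%s_nmj%03d", group, i),
                         age_weeks = scen$age_weeks, genotype = gt, seed = seed),
          s
        )
      })
      ephys[[group]] <- dplyr::bind_rows(rows)
    }
  }
  ephys <- dplyr::bind_rows(ephys)

  morpho <- NULL
  if (config$n_images_per_group > 0) {
    morpho <- list()
    for (gt in config$genotypes) {
      for (age in config$image_ages) {
        scen <- build_image_scenario(age, gt)
        group <- scen$id
        rows <- lapply(seq_len(config$n_images_per_group), function(i) {
          seed <- derive_seed(ms, "image", group, i)
          gen <- generate_nmj(scen, seed = seed)
          rec <- analyze_nmj_image(gen$image)
          dplyr::bind_cols(
            tibble::tibble(unit_id = sprintf("%s_img%03d", group, i),
                           age_weeks = scen$age_weeks, genotype = gt, seed = seed),
            rec
          )
        })
        morpho[[group]] <- dplyr::bind_rows(rows)
      }
    }
    morpho <- dplyr::bind_rows(morpho)
  }

  report <- build_report(ephys, morpho,
                         out_dir = if (!is.null(config$output_dir))
                           file.path(config$output_dir, "report"))

  manifest <- tibble::tibble(
    package_version = as.character(utils::packageVersion("nmjquant")),
    master_seed = ms,
    n_nmjs_per_group = config$n_nmjs_per_group,
    n_images_per_group = config$n_images_per_group,
    with_trains = config$with_trains,
    ages = paste(config$ages, collapse = ","),
    image_ages = paste(config$image_ages, collapse = ","),
    genotypes = paste(config$genotypes, collapse = ",")
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(ephys, file.path(config$output_dir, "ephys_summaries.csv"),
              row.names = FALSE)
    if (!is.null(morpho)) {
      write.csv(morpho, file.path(config$output_dir, "morphometry_records.csv"),
                row.names = FALSE)
    }
    write.csv(manifest, file.path(config$output_dir, "manifest.csv"),
              row.names = FALSE)
  }

  list(ephys = ephys, morpho = morpho, report = report, manifest = manifest)
}
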