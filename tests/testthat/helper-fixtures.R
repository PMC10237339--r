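# Shared fixtures, built once per test run and memoised across files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, fn(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# one synthetic image + masks per (scenario, seed), across the preset grid
fixture_images <- function(n_per_scenario = 2L) {
  memo(paste0("images_", n_per_scenario), function() {
    tab <- image_scenario_table()
    out <- list()
    for (r in seq_len(nrow(tab))) {
      scen <- build_image_scenario(tab$age_weeks[r], tab$genotype[r])
      for (i in seq_len(n_per_scenario)) {
        out[[paste(scen$id, i, sep = "_")]] <-
          generate_nmj(scen, seed = 9000 + 100 * r + i)
      }
    }
    out
  })
}

fixture_segmentations <- function(n_per_scenario = 2L) {
  memo(paste0("segs_", n_per_scenario), function() {
    lapply(fixture_images(n_per_scenario), function(g) segment_achr(g$image))
  })
}

# small pretzels for bulk property suites (cheap to generate and segment)
small_image_scenario <- function(dim_fraction = 0.3, floccular_fraction = 0) {
  scen <- build_image_scenario(8, "WT", image_size = 128L)
  scen$endplate_scale <- 14
  scen$dim_fraction <- dim_fraction
  scen$floccular_fraction <- floccular_fraction
  scen$p_extrajunctional <- 0
  scen
}

square_mask <- function(size, r0, r1, c0 = r0, c1 = r1) {
  m <- matrix(FALSE, size, size)
  m[r0:r1, c0:c1] <- TRUE
  m
}

boundary_of <- function(mask) {
  er <- EBImage::imageData(EBImage::erode(mask * 1L, EBImage::makeBrush(3L, "box"))) > 0.5
  mask & !er
}

# analytic box-count oracle for an axis-aligned 1-px horizontal line starting
# at the tiling origin: a line of length L covers ceil(L/s) boxes of side s
line_hits_oracle <- function(length_px, sizes) ceiling(length_px / sizes)

loglog_slope <- function(hits, sizes) {
  unname(coef(lm(log(hits) ~ log(1 / sizes)))[2])
}
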