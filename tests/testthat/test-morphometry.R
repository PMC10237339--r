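test_that("the Huang threshold separates well-separated modes", {
  # two-component image: background near 20, foreground near 180
  set.seed(1)
  img <- matrix(round(c(rnorm(6000, 20, 4), rnorm(4000, 180, 10))), 100, 100)
  thr <- huang_threshold(pmin(pmax(img, 0), 255))
  expect_gt(thr, 35)
  expect_lt(thr, 160)
  expect_error(huang_threshold(matrix(7, 10, 10)), "single gray level")
})

test_that("segmentation recovers the receptor mask on undisrupted junctions", {
  sc <- build_image_scenario(12, "WT")
  sc$floccular_fraction <- 0
  jac <- vapply(1:4, function(i) {
    g <- generate_nmj(sc, seed = 40 + i, n_extrajunctional = 0)
    seg <- segment_achr(g$image)
    sum(seg$achr_mask & g$masks$achr_mask) / sum(seg$achr_mask | g$masks$achr_mask)
  }, numeric(1))
  expect_true(all(jac >= 0.9))
})

test_that("segmentation counts disjoint objects and rejects blank fields", {
  img <- matrix(15L, 256, 256)
  img[40:80, 40:80] <- 200L
  img[150:190, 150:190] <- 200L
  seg <- segment_achr(img, pixel_size = 0.25)
  expect_equal(seg$n_clusters, 2L)
  expect_error(segment_achr(matrix(10L, 64, 64), pixel_size = 0.25),
               "single gray level|empty segmentation")
})

test_that("core variables are exact on a filled square", {
  img <- matrix(10L, 64, 64)
  img[20:29, 20:29] <- 220L  # 10x10 px square
  seg <- segment_achr(img, pixel_size = 1, smooth_sigma = 0)
  core <- core_variables(seg, pixel_size = 1)
  expect_equal(core$d_achr_area, 100)
  expect_equal(core$f_n_clusters, 1L)
  expect_gte(core$a_endplate_area, core$d_achr_area)
  # corner-to-corner Feret of a 10 um square
  expect_equal(core$b_endplate_diameter, 10 * sqrt(2), tolerance = 0.08)
  expect_error(core_variables(seg, pixel_size = 0), "pixel_size")
})

test_that("derived variables satisfy their defining identities", {
  expect_equal(derived_variables(100, 80, 1)$j_fragmentation, 0)
  expect_equal(derived_variables(100, 80, 4)$j_fragmentation, 0.75)
  expect_equal(derived_variables(100, 100, 2)$h_unoccupied_area, 0)
  expect_error(derived_variables(100, 80, 0), "zero clusters")
  d <- derived_variables(120, 80, 4)
  expect_equal(d$g_avg_cluster_area, 20)
  expect_equal(d$i_compactness, 150)  # (a/d)*100 as printed, >= 100
  expect_equal(derived_variables(120, 80, 4,
               convention = "achr_over_endplate")$i_compactness, 100 * 80 / 120)

  # property suite: identities hold exactly on randomized records
  set.seed(99)
  for (i in 1:500) {
    d_area <- runif(1, 10, 400)
    a_area <- d_area + runif(1, 0, 200)
    f <- sample(1:12, 1)
    rec <- derived_variables(a_area, d_area, f)
    expect_identical(rec$h_unoccupied_area, a_area - d_area)
    expect_identical(rec$g_avg_cluster_area, d_area / f)
    expect_identical(rec$j_fragmentation, 1 - 1 / f)
  }
})

test_that("box counting matches the analytic oracle on a straight line", {
  sizes <- c(1, 2, 4, 8, 16, 32, 64)
  m <- matrix(FALSE, 512, 512)
  m[256, 1:400] <- TRUE  # aligned with the tiling origin
  expect_equal(box_count(m, sizes), line_hits_oracle(400, sizes))
  fd <- fractal_dimension(m)
  expect_equal(fd, loglog_slope(line_hits_oracle(400, sizes), sizes))
  expect_lt(abs(fd - 1), 0.05)
})

test_that("the perimeter of a large filled square is near-smooth", {
  sq <- square_mask(512, 51, 450)
  fd <- fractal_dimension(boundary_of(sq))
  expect_lt(abs(fd - 1), 0.05)
})

test_that("fractal dimension validates its box sizes and degenerate inputs", {
  m <- matrix(FALSE, 64, 64); m[32, 10:50] <- TRUE
  expect_error(fractal_dimension(m, box_sizes = c(1, 3, 9)), "powers of two")
  expect_error(fractal_dimension(m, box_sizes = c(4, 2, 1)))
  expect_error(fractal_dimension(matrix(FALSE, 8, 8)), "empty perimeter")
  # a single point saturates every box size
  pt <- matrix(FALSE, 512, 512); pt[100, 100] <- TRUE
  expect_error(fractal_dimension(pt), "usable box sizes")
})

test_that("fractal dimension is invariant under whole-box translations", {
  seg <- fixture_segmentations(2)[[1]]
  per <- seg$perimeter_mask
  fd0 <- fractal_dimension(per)
  # embed on a larger canvas and translate by 64 px (a whole multiple of
  # every box size): the single-origin count must be unchanged
  shifted <- matrix(FALSE, nrow(per) + 128, ncol(per) + 128)
  shifted[65:(64 + nrow(per)), 65:(64 + ncol(per))] <- per
  expect_equal(fractal_dimension(shifted), fd0, tolerance = 1e-10)
})

test_that("every synthetic junction perimeter has dimension between 1 and 2", {
  fds <- vapply(fixture_segmentations(2), function(seg) {
    fractal_dimension(seg$perimeter_mask)
  }, numeric(1))
  expect_true(all(fds <= 2))
  expect_true(all(fds >= 0.95))  # fit tolerance below the theoretical floor
})

test_that("intensity bimodality recovers the generator dim fraction", {
  # uniform bright junction: essentially no reduced-intensity area
  sc0 <- build_image_scenario(8, "WT")
  sc0$dim_fraction <- 0; sc0$floccular_fraction <- 0
  g0 <- generate_nmj(sc0, seed = 9, n_extrajunctional = 0)
  expect_lt(intensity_bimodality(g0$image)$dim_area_fraction, 0.05)

  # 60% generator truth recovered within 5 percentage points
  sc <- build_image_scenario(20, "SOD1")
  est <- vapply(1:5, function(i) {
    g <- generate_nmj(sc, seed = 50 + i)
    intensity_bimodality(g$image)$dim_area_fraction
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.60), 0.05)

  expect_error(intensity_bimodality(matrix(10L, 64, 64)),
               "single gray level|no AChR signal")
})

test_that("estimated dim fraction is monotone in the generated fraction", {
  grid <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  est <- vapply(grid, function(df) {
    sc <- build_image_scenario(16, "SOD1")
    sc$dim_fraction <- df; sc$floccular_fraction <- 0
    mean(vapply(1:3, function(i) {
      g <- generate_nmj(sc, seed = 600 + i, n_extrajunctional = 0)
      intensity_bimodality(g$image)$dim_area_fraction
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_true(all(abs(est - grid) < 0.05))
})

test_that("disruption classification separates clean, partial and majority floccular", {
  correct <- 0; total <- 0
  for (ff in c(0, 0.3, 0.7)) {
    sc <- build_image_scenario(16, "SOD1")
    sc$floccular_fraction <- ff
    want <- if (ff == 0) "none" else if (ff < 0.5) "lt50" else "gt50"
    for (i in 1:5) {
      g <- generate_nmj(sc, seed = 100 + i, n_extrajunctional = 0)
      got <- classify_disruption(g$image, segment_achr(g$image))$floccular_category
      total <- total + 1
      correct <- correct + (got == want)
    }
  }
  expect_gte(correct / total, 0.85)
})

test_that("clean pretzels are classified undisrupted in at least 90% of replicates", {
  ok <- 0
  for (i in 1:10) {
    sc <- build_image_scenario(12, if (i %% 2) "WT" else "SOD1")
    sc$floccular_fraction <- 0
    g <- generate_nmj(sc, seed = 300 + i, n_extrajunctional = 0)
    cls <- classify_disruption(g$image, segment_achr(g$image))
    ok <- ok + (cls$floccular_category == "none" && !cls$has_extrajunctional)
  }
  expect_gte(ok / 10, 0.9)
})

test_that("satellite clusters are reported as extrajunctional", {
  hits <- 0
  for (i in 1:5) {
    g <- generate_nmj(build_image_scenario(20, "SOD1"), seed = 400 + i,
                      n_extrajunctional = 2)
    cls <- classify_disruption(g$image, segment_achr(g$image))
    hits <- hits + cls$has_extrajunctional
  }
  expect_gte(hits / 5, 0.8)
  expect_error(classify_disruption(matrix(0L, 4, 4),
                                   list(achr_mask = matrix(FALSE, 4, 4),
                                        pixel_size = 0.25)),
               "empty segmentation")
})

test_that("full image records keep the derived identities", {
  for (g in fixture_images(2)[1:6]) {
    rec <- analyze_nmj_image(g$image)
    expect_equal(rec$h_unoccupied_area, rec$a_endplate_area - rec$d_achr_area)
    expect_equal(rec$g_avg_cluster_area, rec$d_achr_area / rec$f_n_clusters)
    expect_equal(rec$j_fragmentation, 1 - 1 / rec$f_n_clusters)
    expect_lte(rec$d_achr_area, rec$a_endplate_area)
    expect_true(rec$fractal_dimension >= 1 - 0.05 && rec$fractal_dimension <= 2)
  }
})
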