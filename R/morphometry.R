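#' Huang fuzzy-entropy threshold
#'
#' Implements the Huang & Wang (1995) automatic threshold on a 256-bin
#' histogram: for each candidate threshold the image is split into background
#' and foreground with mean gray levels `mu0`, `mu1`; each pixel's membership
#' to its region is `1 / (1 + |g - mu| / C)` with `C` the gray-level range,
#' and the threshold minimizing the total Shannon fuzziness
#' `-sum h(g) [mu ln mu + (1-mu) ln(1-mu)]` is returned.
#'
#' @param x integer gray levels 0-255 (vector or matrix)
#' @return the threshold gray level; foreground is `x > threshold`
#' @export
huang_threshold <- function(x) {
  g <- as.integer(round(x))
  h <- tabulate(g + 1L, nbins = 256L)
  first <- which(h > 0)[1] - 1L
  last <- tail(which(h > 0), 1) - 1L
  if (is.na(first) || first == last) {
    stop_nmj("degenerate histogram: single gray level")
  }
  C <- last - first
  gg <- 0:255
  w <- h * gg
  cs_h <- cumsum(h)
  cs_w <- cumsum(w)
  n <- sum(h)
  sw <- sum(w)

  ent <- rep(Inf, 256)
  for (t in first:(last - 1L)) {
    n0 <- cs_h[t + 1L]
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- cs_w[t + 1L] / n0
    mu1 <- (sw - cs_w[t + 1L]) / n1
    mu <- ifelse(gg <= t, 1 / (1 + abs(gg - mu0) / C), 1 / (1 + abs(gg - mu1) / C))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ent[t + 1L] <- -sum(h * (mu * log(mu) + (1 - mu) * log(1 - mu)))
  }
  which.min(ent) - 1L
}

#' Segment the receptor distribution of a single-NMJ field
#'
#' The image is lightly Gaussian-smoothed, thresholded with the semi-automated
#' Huang approach, and cleaned of sub-resolution specks (components below
#' `min_cluster_um2`). The endplate footprint is the largest connected
#' component of the hole-filled morphological closing (2 um disc) of the
#' foreground; receptor clusters are the connected components inside it, and
#' foreground components outside it are kept separately as extrajunctional
#' candidates. The perimeter mask is the 1-px outer boundary of the endplate.
#'
#' @param image an `nmj_image` (or plain integer matrix with `pixel_size`)
#' @param pixel_size microns per pixel
#' @param min_cluster_um2 minimum receptor cluster area retained, um^2
#' @param smooth_sigma Gaussian pre-smoothing sigma, px
#' @return `nmj_segmentation` list: `achr_mask`, `endplate_mask`,
#'   `cluster_labels`, `n_clusters`, `perimeter_mask`,
#'   `extrajunctional_labels`, `threshold_value`, `pixel_size`
#' @export
segment_achr <- function(image, pixel_size = NULL, min_cluster_um2 = 0.5,
                         smooth_sigma = 1) {
  px <- if (inherits(image, "nmj_image")) image$pixels else image
  ps <- pixel_size %||% (if (inherits(image, "nmj_image")) image$pixel_size else NULL)
  if (is.null(ps) || ps <= 0) stop_nmj("pixel size must be known and positive")

  sm <- if (smooth_sigma > 0) EBImage::gblur(px / 255, sigma = smooth_sigma) * 255
        else px
  thr <- tryCatch(huang_threshold(sm), error = function(e) NA_integer_)
  if (is.na(thr)) stop_nmj("empty segmentation: no foreground above threshold")
  fg <- EBImage::imageData(sm) > thr
  if (!any(fg)) stop_nmj("empty segmentation: no foreground above threshold")

  min_px <- max(1L, round(min_cluster_um2 / ps^2))
  fg <- drop_small_components(fg, min_px)
  if (!any(fg)) stop_nmj("empty segmentation: no foreground above threshold")

  close_r <- odd_window(2 / ps)
  closed <- bin_mat(EBImage::fillHull(
    EBImage::closing(fg * 1L, EBImage::makeBrush(close_r, "disc"))
  ))
  # the endplate footprint keeps every substantial closed component (a
  # fragmented junction can split); only minor components — candidate
  # extrajunctional satellites — stay outside
  lab_closed <- EBImage::imageData(EBImage::bwlabel(closed * 1L))
  sizes <- tabulate(lab_closed[lab_closed > 0])
  major <- which(sizes >= 0.25 * max(sizes))
  endplate <- matrix(lab_closed %in% major, nrow(fg), ncol(fg))

  achr <- fg & endplate
  cluster_labels <- EBImage::imageData(EBImage::bwlabel(achr * 1L))
  n_clusters <- max(cluster_labels)

  extra <- fg & !endplate
  extrajunctional_labels <- EBImage::imageData(EBImage::bwlabel(extra * 1L))

  perim <- endplate & !bin_mat(EBImage::erode(endplate * 1L,
                                              EBImage::makeBrush(3L, "box")))

  structure(list(
    achr_mask = achr, endplate_mask = endplate,
    cluster_labels = cluster_labels,
    n_clusters = as.integer(n_clusters),
    perimeter_mask = perim,
    extrajunctional_labels = extrajunctional_labels,
    threshold_value = thr, pixel_size = ps
  ), class = "nmj_segmentation")
}

drop_small_components <- function(mask, min_px) {
  lab <- EBImage::bwlabel(mask * 1L)
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Core postsynaptic variables (a-f)
#'
#' Areas are pixel counts times the squared pixel size; perimeters are
#' boundary-pixel counts times the pixel size; the endplate diameter is the
#' maximum Feret diameter, computed on pixel-corner coordinates so a filled
#' square of side n px has diameter `n * sqrt(2)` px.
#'
#' @param seg an [segment_achr()] result
#' @param pixel_size microns per pixel (defaults to the segmentation's)
#' @return one-row tibble: `a_endplate_area`, `b_endplate_diameter`,
#'   `c_endplate_perimeter`, `d_achr_area`, `e_achr_perimeter`,
#'   `f_n_clusters`
#' @export
core_variables <- function(seg, pixel_size = seg$pixel_size) {
  if (is.null(pixel_size) || pixel_size <= 0) stop_nmj("pixel_size must be positive")
  if (!any(seg$achr_mask)) stop_nmj("empty segmentation")
  ps <- pixel_size
  achr_boundary <- seg$achr_mask &
    !bin_mat(EBImage::erode(seg$achr_mask * 1L, EBImage::makeBrush(3L, "box")))
  tibble::tibble(
    a_endplate_area = sum(seg$endplate_mask) * ps^2,
    b_endplate_diameter = feret_diameter(seg$endplate_mask) * ps,
    c_endplate_perimeter = sum(seg$perimeter_mask) * ps,
    d_achr_area = sum(seg$achr_mask) * ps^2,
    e_achr_perimeter = sum(achr_boundary) * ps,
    f_n_clusters = seg$n_clusters
  )
}

# maximum Feret diameter over the pixel-corner convex hull, in px
feret_diameter <- function(mask) {
  b <- mask & !bin_mat(EBImage::erode(mask * 1L, EBImage::makeBrush(3L, "box")))
  co <- which(b, arr.ind = TRUE)
  if (nrow(co) == 0L) co <- which(mask, arr.ind = TRUE)
  corners <- rbind(
    co + matrix(c(-0.5, -0.5), nrow(co), 2, byrow = TRUE),
    co + matrix(c(-0.5, 0.5), nrow(co), 2, byrow = TRUE),
    co + matrix(c(0.5, -0.5), nrow(co), 2, byrow = TRUE),
    co + matrix(c(0.5, 0.5), nrow(co), 2, byrow = TRUE)
  )
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  d2max <- 0
  for (i in seq_len(nrow(hull))) {
    d2 <- (hull[, 1] - hull[i, 1])^2 + (hull[, 2] - hull[i, 2])^2
    d2max <- max(d2max, d2)
  }
  sqrt(d2max)
}

#' Derived postsynaptic variables (g-j)
#'
#' `g = d/f` (average cluster area), `h = a - d` (endplate area unoccupied by
#' receptor), `i = (a/d) * 100` (compactness, as printed in the source
#' protocol, giving values >= 100; `convention = "achr_over_endplate"` emits
#' the conventional `(d/a) * 100` instead), `j = 1 - 1/f` (fragmentation).
#'
#' @param a endplate area, um^2
#' @param d receptor area, um^2 (`d <= a`)
#' @param f number of receptor clusters (>= 1)
#' @param convention compactness convention (see above)
#' @return one-row tibble: `g_avg_cluster_area`, `h_unoccupied_area`,
#'   `i_compactness`, `j_fragmentation`
#' @export
derived_variables <- function(a, d, f,
                              convention = c("endplate_over_achr",
                                             "achr_over_endplate")) {
  convention <- match.arg(convention)
  if (any(f == 0)) stop_nmj("f must be >= 1 (zero clusters)")
  stopifnot(all(f >= 1), all(d > 0), all(a >= d))
  tibble::tibble(
    g_avg_cluster_area = d / f,
    h_unoccupied_area = a - d,
    i_compactness = if (convention == "endplate_over_achr") (a / d) * 100
                    else (d / a) * 100,
    j_fragmentation = 1 - 1 / f
  )
}

#' Box-counting hits of a binary mask
#'
#' Tiles the image with boxes of side `s` from the (0,0) origin and counts
#' boxes containing at least one foreground pixel (a "hit"). A multi-offset
#' variant averages hits over a small grid of tiling origins.
#'
#' @param mask logical matrix
#' @param sizes box sides, px
#' @param offsets matrix of (row, col) tiling origins; default a single (0,0)
#'   origin, matching the common single-grid box counter
#' @return numeric vector of hits per size
#' @export
box_count <- function(mask, sizes, offsets = matrix(0L, 1, 2)) {
  co <- which(mask, arr.ind = TRUE) - 1L
  if (nrow(co) == 0L) stop_nmj("empty mask")
  vapply(sizes, function(s) {
    mean(apply(offsets, 1, function(off) {
      bx <- (co[, 1] + off[1]) %/% s
      by <- (co[, 2] + off[2]) %/% s
      length(unique(bx * 1e6 + by))
    }))
  }, numeric(1))
}

#' Box-counting fractal dimension of a perimeter mask
#'
#' Covers the perimeter with boxes of 1, 2, 4, 8, 16, 32 and 64 px per side
#' and returns the least-squares slope of log(hits) against log(1/side): 1 for
#' a totally smooth perimeter, approaching 2 for a space-filling one. Box
#' sizes where the count saturates (fewer than 2 hits) are dropped; fewer than
#' 3 usable sizes is an error.
#'
#' @param perimeter_mask logical matrix, 1-px boundary line
#' @param box_sizes strictly increasing powers of two
#' @param multi_offset average hits over a 2x2 grid of tiling origins instead
#'   of the single-origin count
#' @export
fractal_dimension <- function(perimeter_mask, box_sizes = c(1, 2, 4, 8, 16, 32, 64),
                              multi_offset = FALSE) {
  stopifnot(all(diff(box_sizes) > 0))
  if (any(abs(log2(box_sizes) - round(log2(box_sizes))) > 1e-9)) {
    stop_nmj("box_sizes must be powers of two")
  }
  if (!any(perimeter_mask)) stop_nmj("empty perimeter mask")
  offsets <- if (multi_offset) {
    as.matrix(expand.grid(r = c(0L, 1L), c = c(0L, 1L)))
  } else matrix(0L, 1, 2)
  hits <- box_count(perimeter_mask, box_sizes, offsets)
  usable <- hits >= 2
  if (sum(usable) < 3) {
    stop_nmj("fewer than 3 usable box sizes (hit counts saturate)")
  }
  x <- log(1 / box_sizes[usable])
  y <- log(hits[usable])
  unname(coef(lm(y ~ x))[2])
}

#' Settings for the intensity-variability analysis
#'
#' @param background_cutoff gray level below which pixels are treated as
#'   background/non-receptor label and excluded (40 on the 8-bit scale)
#' @param smoothing_window moving-average window applied to the histogram, bins
#' @param median_radius median-filter radius applied to the image to remove
#'   sporadic pixel extrema, px
#' @param rescale `"minmax"` linearly rescales the ROI to 0-255 during 8-bit
#'   conversion; `"none"` keeps already-8-bit values
#' @export
intensity_config <- function(background_cutoff = 40L, smoothing_window = 5L,
                             median_radius = 1L, rescale = c("minmax", "none")) {
  stopifnot(background_cutoff > 0, background_cutoff < 255)
  list(background_cutoff = as.integer(background_cutoff),
       smoothing_window = as.integer(smoothing_window),
       median_radius = as.integer(median_radius),
       rescale = match.arg(rescale))
}

#' Bimodality of receptor labeling intensity
#'
#' Reproduces the histogram analysis of labeling variability: a minimal
#' rectangle around the junction is median-smoothed and converted to 8-bit;
#' an intensity histogram is built and smoothed; bins below the background
#' cutoff (40) are excluded; the receptor peak is the highest remaining bin
#' and the shallow minimum is the lowest bin between the cutoff and that
#' peak (ties resolved to the lowest gray level). The count ratio
#' minimum/peak indexes the proportion of receptor area with reduced
#' labeling, and the dim area fraction is the share of above-cutoff pixels
#' at or below the valley gray level. The gray-level ratio valley/peak is
#' also emitted, since either reading of "ratio of the minimum to the peak
#' maximum" is defensible.
#'
#' @param image an `nmj_image`
#' @param roi `c(row0, row1, col0, col1)` rectangle enclosing the junction;
#'   default is the padded bounding box of the Huang foreground
#' @param config an [intensity_config()]
#' @return one-row tibble: `valley_peak_ratio`, `dim_area_fraction`,
#'   `valley_gray`, `peak_gray`, `valley_peak_gray_ratio`, `n_pixels_achr`
#' @export
intensity_bimodality <- function(image, roi = NULL, config = intensity_config()) {
  px <- if (inherits(image, "nmj_image")) image$pixels else image
  if (is.null(roi)) {
    thr <- huang_threshold(px)
    fg <- which(px > thr, arr.ind = TRUE)
    if (nrow(fg) == 0L) stop_nmj("no AChR signal above threshold")
    pad <- 5L
    roi <- c(max(1L, min(fg[, 1]) - pad), min(nrow(px), max(fg[, 1]) + pad),
             max(1L, min(fg[, 2]) - pad), min(ncol(px), max(fg[, 2]) + pad))
  }
  sub <- px[roi[1]:roi[2], roi[3]:roi[4]]

  if (config$median_radius > 0) {
    sub <- EBImage::imageData(
      EBImage::medianFilter(sub / 255, config$median_radius)) * 255
  }
  if (config$rescale == "minmax") {
    rng <- range(sub)
    if (diff(rng) <= 0) stop_nmj("no AChR signal: flat ROI")
    sub <- (sub - rng[1]) / diff(rng) * 255
  }
  g <- as.integer(round(sub))

  counts <- tabulate(g + 1L, nbins = 256L)
  w <- config$smoothing_window
  sm <- as.numeric(stats::filter(counts, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]

  cutoff <- config$background_cutoff
  achr_bins <- (cutoff + 1L):256L  # gray >= cutoff
  n_achr <- sum(counts[achr_bins])
  if (n_achr == 0L) stop_nmj("no AChR signal: no pixels at or above the cutoff")

  peak_gray <- (achr_bins[which.max(sm[achr_bins])]) - 1L
  # the frequency curve starts at the first populated bin at/above the
  # cutoff; leading empty bins are not part of the curve and must not be
  # mistaken for the shallow minimum
  lo <- achr_bins[which(sm[achr_bins] > 0)[1]]
  valley_range <- lo:(peak_gray + 1L)
  valley_gray <- (valley_range[which.min(sm[valley_range])]) - 1L

  dim_px <- sum(counts[(cutoff + 1L):(valley_gray + 1L)])
  tibble::tibble(
    valley_peak_ratio = sm[valley_gray + 1L] / sm[peak_gray + 1L],
    dim_area_fraction = dim_px / n_achr,
    valley_gray = valley_gray,
    peak_gray = peak_gray,
    valley_peak_gray_ratio = valley_gray / peak_gray,
    n_pixels_achr = n_achr
  )
}

#' Qualitative disruption of the receptor distribution
#'
#' Scores granular (floccular) texture as the local density of small enclosed
#' holes in the receptor mask: holes no larger than `max_hole_um2` (obtained
#' by hole-filling, so ordinary inter-ribbon lakes are excluded by size) are
#' counted in a disc neighborhood of radius `neighborhood_um` around each
#' receptor pixel, and pixels whose neighborhood hole density exceeds
#' `granularity_density` are called granular. The granular area is classed
#' `none` below `min_area_fraction` of the receptor area, otherwise `lt50` or
#' `gt50` against the 50% line. Extrajunctional clusters are foreground
#' components outside the endplate footprint that are both small (at most 10%
#' of the receptor area) and dimmer than the median receptor pixel.
#'
#' @param image the `nmj_image` the segmentation came from
#' @param seg an [segment_achr()] result
#' @param granularity_density neighborhood hole-density above which a pixel is
#'   granular
#' @param neighborhood_um neighborhood radius, um
#' @param max_hole_um2 maximum area of a "sub-resolution" hole, um^2
#' @param min_area_fraction floccular fraction below which the category is
#'   `none`
#' @return one-row tibble: `floccular_category` (`none`/`lt50`/`gt50`),
#'   `floccular_area_fraction`, `has_extrajunctional`, `n_extrajunctional`
#' @export
classify_disruption <- function(image, seg, granularity_density = 0.04,
                                neighborhood_um = 4, max_hole_um2 = 10,
                                min_area_fraction = 0.08) {
  px <- if (inherits(image, "nmj_image")) image$pixels else image
  achr <- seg$achr_mask
  if (!any(achr)) stop_nmj("empty segmentation")
  ps <- seg$pixel_size

  # granular holes are sub-resolution, so re-threshold an edge-preserving
  # (median-filtered) view of the image: Gaussian pre-smoothing in the main
  # segmentation fills them in
  fine <- EBImage::imageData(EBImage::medianFilter(px / 255, 1L)) * 255
  fine_fg <- fine > seg$threshold_value & seg$endplate_mask
  filled <- bin_mat(EBImage::fillHull(fine_fg * 1L))
  holes <- filled & !fine_fg
  speckle <- matrix(FALSE, nrow(achr), ncol(achr))
  if (any(holes)) {
    lab <- EBImage::imageData(EBImage::bwlabel(holes * 1L))
    co <- which(lab > 0)
    ids <- lab[co]
    rr <- (co - 1L) %% nrow(lab) + 1L
    cc <- (co - 1L) %/% nrow(lab) + 1L
    sizes <- tabulate(ids)
    span_r <- tapply(rr, ids, function(z) diff(range(z)) + 1L)
    span_c <- tapply(cc, ids, function(z) diff(range(z)) + 1L)
    maxdim <- pmax(span_r, span_c)
    # a granular hole is small AND round; elongated slivers between adjacent
    # ribbons share the size range but not the shape
    roundness <- sizes / (pi / 4 * maxdim^2)
    keep <- which(sizes >= 5 & sizes <= max_hole_um2 / ps^2 &
                    maxdim <= 3 / ps & roundness >= 0.4)
    speckle <- matrix(lab %in% keep, nrow(achr), ncol(achr))
  }

  r_px <- max(2L, round(neighborhood_um / ps))
  kern <- EBImage::makeBrush(2L * r_px + 1L, "disc")
  kern <- kern / sum(kern)
  dens_hole <- EBImage::imageData(EBImage::filter2(speckle * 1, kern, boundary = 0))
  dens_achr <- EBImage::imageData(EBImage::filter2(fine_fg * 1, kern, boundary = 0))
  # hole share of the local ribbon, so inter-ribbon lakes do not dilute the score
  local_frac <- dens_hole / pmax(dens_hole + dens_achr, 1e-9)
  granular <- achr & local_frac > granularity_density
  frac <- sum(granular) / sum(achr)
  category <- if (frac < min_area_fraction) "none"
              else if (frac < 0.5) "lt50" else "gt50"

  # small, dim clusters beyond the endplate footprint
  extra_lab <- seg$extrajunctional_labels
  n_extra <- 0L
  if (max(extra_lab) > 0) {
    main_median <- median(px[achr])
    for (k in seq_len(max(extra_lab))) {
      comp <- extra_lab == k
      if (!any(comp)) next
      if (sum(comp) <= 0.1 * sum(achr) && median(px[comp]) < main_median) {
        n_extra <- n_extra + 1L
      }
    }
  }

  tibble::tibble(
    floccular_category = category,
    floccular_area_fraction = frac,
    has_extrajunctional = n_extra > 0L,
    n_extrajunctional = n_extra
  )
}

#' Full morphometry record for one junction image
#'
#' Runs segmentation, the core and derived NMJ-morph style variables, the
#' perimeter fractal dimension, the intensity-bimodality statistics and the
#' disruption classification, returning one tidy row per junction.
#'
#' @param image an `nmj_image`
#' @param pixel_size microns per pixel (defaults to the image's)
#' @param compactness_convention see [derived_variables()]
#' @param ... passed to [segment_achr()]
#' @return one-row tibble with all morphometry fields
#' @export
analyze_nmj_image <- function(image, pixel_size = NULL,
                              compactness_convention = "endplate_over_achr",
                              ...) {
  seg <- segment_achr(image, pixel_size = pixel_size, ...)
  core <- core_variables(seg)
  der <- derived_variables(core$a_endplate_area, core$d_achr_area,
                           core$f_n_clusters,
                           convention = compactness_convention)
  fd <- fractal_dimension(seg$perimeter_mask)
  bim <- intensity_bimodality(image)
  cls <- classify_disruption(image, seg)
  dplyr::bind_cols(
    core, der,
    tibble::tibble(fractal_dimension = fd),
    bim[, c("valley_peak_ratio", "dim_area_fraction")],
    cls
  )
}
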