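#' Synthetic en-face "pretzel" micrograph with ground-truth masks
#'
#' Draws a branched ribbon skeleton (a harmonically distorted closed loop plus
#' Bezier chords), dilates it to the scenario ribbon width, and paints
#' receptor label over background at 8-bit intensities. Disease features are
#' applied with exact bookkeeping so measured quantities have a known truth:
#'
#' * a contiguous *dim* region covering exactly `dim_fraction` of the
#'   receptor pixels is drawn from a broad reduced-intensity distribution;
#' * a contiguous *floccular* region covering `floccular_fraction` of the
#'   ribbon is speckled with small sub-resolution holes that drop to
#'   background (granular texture);
#' * with probability `p_extrajunctional`, 1-3 small dim satellite clusters
#'   are placed 2-10 um beyond the endplate perimeter.
#'
#' Intensities are arbitrary units on the 8-bit scale; no optical point-spread
#' blur is applied (out of scope), so component separation in the intensity
#' histogram is governed by the scenario's truncated-normal components plus
#' pixel noise.
#'
#' @param scenario an [build_image_scenario()] preset
#' @param seed integer seed; fixing it reproduces the image exactly
#' @param n_extrajunctional optional explicit satellite count (overrides the
#'   scenario's stochastic incidence)
#' @return list with `image` (an `nmj_image`: integer pixel matrix 0-255 plus
#'   pixel size and metadata) and `masks` (logical matrices `achr_mask`,
#'   `endplate_mask`, `dim_mask`, `floccular_mask`, and integer
#'   `satellite_labels`)
#' @export
generate_nmj <- function(scenario, seed = 1L, n_extrajunctional = NULL) {
  stopifnot(inherits(scenario, "image_scenario"))
  set.seed(seed)
  size <- scenario$image_size
  ps <- scenario$pixel_size
  r0 <- scenario$endplate_scale / 2 / ps
  ribbon_r <- max(1L, round(scenario$ribbon_width / ps / 2))
  if (2 * (r0 * 1.6 + ribbon_r) > size - 16) {
    stop_nmj("endplate (%.0f um) larger than the %d px image field",
             scenario$endplate_scale, size)
  }

  cx <- size / 2 + runif(1, -10, 10)
  cy <- size / 2 + runif(1, -10, 10)

  # closed loop with low-order harmonic distortion
  theta <- seq(0, 2 * pi, length.out = 2500)
  rr <- rep(1, length(theta))
  for (k in 2:5) {
    rr <- rr + (runif(1, 0.06, 0.2) / sqrt(k)) * cos(k * theta + runif(1, 0, 2 * pi))
  }
  rr <- r0 * rr
  xs <- cx + rr * cos(theta)
  ys <- cy + rr * sin(theta)

  # internal chords give the pretzel its branching ribbons
  for (b in seq_len(scenario$n_branches)) {
    i1 <- sample(length(theta), 1L)
    i2 <- ((i1 + sample(round(length(theta) * c(0.25, 0.45)), 1L) - 1L) %%
             length(theta)) + 1L
    p1 <- c(xs[i1], ys[i1]); p2 <- c(xs[i2], ys[i2])
    ctrl <- c(cx, cy) + runif(2, -0.5, 0.5) * r0
    tt <- seq(0, 1, length.out = 600)
    bx <- (1 - tt)^2 * p1[1] + 2 * tt * (1 - tt) * ctrl[1] + tt^2 * p2[1]
    by <- (1 - tt)^2 * p1[2] + 2 * tt * (1 - tt) * ctrl[2] + tt^2 * p2[2]
    xs <- c(xs, bx); ys <- c(ys, by)
  }

  skel <- matrix(0L, size, size)
  px <- pmin(pmax(round(xs), 1), size)
  py <- pmin(pmax(round(ys), 1), size)
  skel[cbind(px, py)] <- 1L

  brush_ribbon <- EBImage::makeBrush(2L * ribbon_r + 1L, "disc")
  achr0 <- bin_mat(EBImage::dilate(skel, brush_ribbon))

  # floccular (granular) region: exact-area contiguous patch, speckled with
  # sub-resolution holes that fall to background
  floccular_mask <- matrix(FALSE, size, size)
  achr <- achr0
  if (scenario$floccular_fraction > 0) {
    floccular_mask <- grow_region(achr0, scenario$floccular_fraction, n_seeds = 2L)
    centers <- matrix(0L, size, size)
    # punch holes in the ribbon interior only, so the granular texture reads
    # as enclosed sub-resolution patches rather than edge nibbling
    core <- bin_mat(EBImage::erode(achr0 * 1L, EBImage::makeBrush(7L, "disc")))
    reg_idx <- which(floccular_mask & core)
    hit <- reg_idx[runif(length(reg_idx)) < 0.02]
    centers[hit] <- 1L
    holes <- bin_mat(EBImage::dilate(centers, EBImage::makeBrush(5L, "disc")))
    holes <- holes & floccular_mask
    achr <- achr0 & !holes
    floccular_mask <- floccular_mask & achr
  }

  # dim region: exact dim_fraction of the (visible) receptor pixels
  dim_mask <- matrix(FALSE, size, size)
  if (scenario$dim_fraction > 0) {
    dim_mask <- grow_region(achr, scenario$dim_fraction, n_seeds = 3L)
  }

  # endplate footprint of the intact ribbons (closing + hole fill)
  close_r <- odd_window(2 / ps)  # 2 um structuring disc
  endplate_mask <- bin_mat(EBImage::fillHull(
    EBImage::closing(achr0 * 1L, EBImage::makeBrush(close_r, "disc"))
  ))

  # extrajunctional satellite clusters beyond the perimeter
  satellite_labels <- matrix(0L, size, size)
  n_sat <- n_extrajunctional %||%
    (if (runif(1) < scenario$p_extrajunctional)
       sample(scenario$n_extrajunctional_max, 1L) else 0L)
  if (n_sat > 0) {
    ac <- which(achr, arr.ind = TRUE)
    for (k in seq_len(n_sat)) {
      for (try in 1:20) {
        ang <- runif(1, 0, 2 * pi)
        u <- c(cos(ang), sin(ang))
        proj <- (ac[, 1] - cx) * u[1] + (ac[, 2] - cy) * u[2]
        extent <- max(proj)
        dist <- extent + runif(1, 2, 10) / ps
        ctr <- round(c(cx, cy) + dist * u)
        rs <- sample(3:6, 1L)
        if (any(ctr < rs + 2) || any(ctr > size - rs - 1)) next
        blob <- matrix(0L, size, size)
        blob[ctr[1], ctr[2]] <- 1L
        blob <- bin_mat(EBImage::dilate(blob, EBImage::makeBrush(2L * rs + 1L, "disc")))
        blob <- blob & !endplate_mask & !achr
        if (sum(blob) < 5) next
        satellite_labels[blob] <- k
        break
      }
    }
  }

  # paint intensities (truncated normals keep components on bounded supports)
  img <- matrix(0, size, size)
  n_all <- length(img)
  img[] <- rtnorm(n_all, scenario$background_level, 3,
                  scenario$background_level - 10, scenario$background_level + 15)
  bright_px <- achr & !dim_mask
  img[bright_px] <- rtnorm(sum(bright_px), scenario$bright_intensity, 10, 150, 235)
  img[dim_mask] <- rtnorm(sum(dim_mask), scenario$dim_intensity, 25, 45, 158)
  sat_px <- satellite_labels > 0
  img[sat_px] <- rtnorm(sum(sat_px), 0.5 * scenario$bright_intensity, 10, 60, 130)
  img <- img + rnorm(n_all, 0, scenario$noise_sd)
  img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), size, size)

  image <- structure(list(
    pixels = img, pixel_size = ps,
    metadata = list(scenario_id = scenario$id, seed = seed,
                    dim_fraction = scenario$dim_fraction,
                    floccular_fraction = scenario$floccular_fraction,
                    n_extrajunctional = n_sat,
                    en_face = TRUE)
  ), class = "nmj_image")

  list(image = image,
       masks = list(achr_mask = achr, endplate_mask = endplate_mask,
                    dim_mask = dim_mask, floccular_mask = floccular_mask,
                    satellite_labels = satellite_labels))
}

#' @export
print.nmj_image <- function(x, ...) {
  cat(sprintf("<nmj_image %s: %dx%d px at %.2f um/px, seed %s>\n",
              x$metadata$scenario_id %||% "?", nrow(x$pixels), ncol(x$pixels),
              x$pixel_size, x$metadata$seed %||% "?"))
  invisible(x)
}

bin_mat <- function(x) {
  m <- EBImage::imageData(x)
  matrix(m > 0.5, nrow(m), ncol(m))
}

# exact-area contiguous sub-region: pixels of `mask` ranked by distance to the
# nearest of `n_seeds` random seed pixels; the closest `fraction` are taken,
# so the truth area fraction is exact up to one pixel
grow_region <- function(mask, fraction, n_seeds = 3L) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (fraction <= 0) return(out)
  coords <- which(mask, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0L) return(out)
  seeds <- coords[sample(n, min(n_seeds, n)), , drop = FALSE]
  d2 <- rep(Inf, n)
  for (s in seq_len(nrow(seeds))) {
    d2 <- pmin(d2, (coords[, 1] - seeds[s, 1])^2 + (coords[, 2] - seeds[s, 2])^2)
  }
  take <- order(d2)[seq_len(min(n, round(fraction * n)))]
  out[coords[take, , drop = FALSE]] <- TRUE
  out
}

#' Write / read an `nmj_image` as grayscale TIFF
#'
#' 8-bit single-channel TIFF; pixel size is not stored in the file and must be
#' supplied on read.
#'
#' @param image an `nmj_image`
#' @param path TIFF path
#' @param pixel_size microns per pixel (on read)
#' @export
write_nmj_tiff <- function(image, path) {
  stopifnot(inherits(image, "nmj_image"))
  EBImage::writeImage(EBImage::Image(image$pixels / 255), path, type = "tiff",
                      bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_nmj_tiff
#' @export
read_nmj_tiff <- function(path, pixel_size) {
  img <- EBImage::readImage(path)
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2L) m <- m[, , 1]
  mx <- max(m)
  scale <- if (mx <= 1) 255 else if (mx <= 255) 1 else 255 / 65535
  structure(list(
    pixels = matrix(as.integer(round(m * scale)), nrow(m), ncol(m)),
    pixel_size = pixel_size,
    metadata = list(source = path)
  ), class = "nmj_image")
}
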