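#' Synthetic experiment generator settings
#'
#' Defines the ground truth for a simulated two-modality experiment:
#' fluorescence microscopy frames of disk-shaped cells plus matched
#' flow-cytometry event samples, both drawn from the same per-cell intensity
#' distribution per group. Defaults emulate the acquisition regime this
#' pipeline models: 10--20 images per group (default 15) of roughly
#' 1000x750 px at ~2.7 px/um, cell diameters 18--38 um, on the order of a
#' thousand cells per imaging condition versus ~20,000 flow events, and
#' channel-dependent signal-to-background ratios (SBR) of ~20 (microscopy) /
#' ~10 (flow) for the glucose-uptake-like channel and ~80 / ~1000 for the
#' mitochondrial-membrane-potential-like channel.
#'
#' Per-cell intensities default to a lognormal: fluorescence intensity
#' histograms of dye-loaded cells are right-skewed and unimodal. The flow
#' modality applies multiplicative lognormal measurement noise and a small
#' SBR-derived baseline; the microscopy modality applies a Gaussian PSF blur,
#' signal-dependent shot noise (Gaussian approximation to Poisson) and
#' additive read noise.
#'
#' @param channel `"glucose_like"` or `"mmp_like"`; selects the default SBR
#'   pair.
#' @param image_width_px,image_height_px Frame size in px.
#' @param pitch_um_per_px Pixel pitch (um/px), default `1/2.7`.
#' @param n_images Images per group (default 15).
#' @param cells_per_image Target cell count per frame.
#' @param diameter_range_um Cell diameter range (um), sampled uniformly.
#' @param intensity_family `"lognormal"`, `"gaussian"` or `"mixture"`
#'   (two-component lognormal; stresses multimodal histograms).
#' @param intensity_median Median per-cell true intensity of the control
#'   group, normalized scale `(0, 1]`.
#' @param intensity_sdlog Log-scale spread of the per-cell distribution
#'   (for `"gaussian"`, the coefficient of variation).
#' @param fold_changes Named vector of multiplicative location shifts per
#'   group relative to control; must contain `control = 1`.
#' @param sbr_microscopy Target in-cell mean over background mean, measured
#'   on the rendered frame against the ground-truth mask. The background
#'   level starts from `mean_intensity / sbr_microscopy` and is then
#'   calibrated (two fixed-point steps on a rendered calibration frame) so
#'   the measured ratio matches the target despite PSF spill-over into the
#'   background and noise clipping at zero.
#' @param sbr_flow Flow signal-to-baseline ratio; the event baseline is
#'   `control mean / sbr_flow`.
#' @param psf_sigma_px Gaussian PSF sigma in px.
#' @param photon_scale Photons at full scale for the shot-noise model: a
#'   pixel of normalized intensity `I` gets Gaussian noise of standard
#'   deviation `sqrt(I / photon_scale)`.
#' @param read_noise_sd Additive Gaussian read noise (normalized units).
#' @param flow_n_events Flow events per group (default 20000).
#' @param flow_n_tubes Flow replicate tubes per group; events are split
#'   evenly across tubes, which serve as the statistical units for the flow
#'   group comparison (typically 3--6 samples per group; default 4).
#' @param flow_noise_sdlog Sdlog of the multiplicative lognormal flow
#'   measurement noise.
#' @param min_gap_px Minimum edge-to-edge gap between placed cells.
#' @param seed Master seed for the generator.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(channel = c("glucose_like", "mmp_like"),
                             image_width_px = 1000L, image_height_px = 750L,
                             pitch_um_per_px = 1 / 2.7,
                             n_images = 15L, cells_per_image = 45L,
                             diameter_range_um = c(18, 38),
                             intensity_family = c("lognormal", "gaussian",
                                                  "mixture"),
                             intensity_median = 0.35,
                             intensity_sdlog = 0.2,
                             fold_changes = c(control = 1, treated = 1.3),
                             sbr_microscopy = NULL,
                             sbr_flow = NULL,
                             psf_sigma_px = 1,
                             photon_scale = 5000,
                             read_noise_sd = 0.002,
                             flow_n_events = 20000L,
                             flow_n_tubes = 4L,
                             flow_noise_sdlog = 0.15,
                             min_gap_px = 2,
                             seed = 1L) {
  channel <- match.arg(channel)
  intensity_family <- match.arg(intensity_family)
  if (is.null(sbr_microscopy)) {
    sbr_microscopy <- if (channel == "glucose_like") 20 else 80
  }
  if (is.null(sbr_flow)) {
    sbr_flow <- if (channel == "glucose_like") 10 else 1000
  }
  fold_changes <- unlist(fold_changes)
  if (is.null(names(fold_changes)) || !"control" %in% names(fold_changes)) {
    abort("`fold_changes` must be a named vector containing `control`.")
  }
  if (length(fold_changes) < 1L) abort("at least one group is required.")
  if (any(fold_changes <= 0)) abort("fold changes must be > 0.")
  if (intensity_median <= 0 || intensity_median > 1) {
    abort("`intensity_median` must lie in (0, 1].")
  }
  if (sbr_microscopy < 1 || sbr_flow < 1) abort("SBR must be >= 1.")
  if (diameter_range_um[1] >= diameter_range_um[2] ||
      diameter_range_um[1] <= 0) {
    abort("`diameter_range_um` must be an increasing positive pair.")
  }
  max_d_px <- diameter_range_um[2] / pitch_um_per_px
  if (max_d_px > min(image_width_px, image_height_px)) {
    abort("largest cell diameter does not fit inside the frame.")
  }
  structure(
    list(channel = channel,
         image_width_px = as.integer(image_width_px),
         image_height_px = as.integer(image_height_px),
         pitch_um_per_px = pitch_um_per_px,
         n_images = as.integer(n_images),
         cells_per_image = as.integer(cells_per_image),
         diameter_range_um = as.numeric(diameter_range_um),
         intensity_family = intensity_family,
         intensity_median = intensity_median,
         intensity_sdlog = intensity_sdlog,
         fold_changes = fold_changes,
         sbr_microscopy = sbr_microscopy,
         sbr_flow = sbr_flow,
         psf_sigma_px = psf_sigma_px,
         photon_scale = photon_scale,
         read_noise_sd = read_noise_sd,
         flow_n_events = as.integer(flow_n_events),
         flow_n_tubes = as.integer(flow_n_tubes),
         flow_noise_sdlog = flow_noise_sdlog,
         min_gap_px = min_gap_px,
         seed = as.integer(seed)),
    class = "generator_params"
  )
}

# Mean of the configured per-cell true-intensity distribution for one group.
group_mean_intensity <- function(params, fold = 1) {
  med <- params$intensity_median * fold
  switch(params$intensity_family,
    lognormal = med * exp(params$intensity_sdlog^2 / 2),
    gaussian = med,
    mixture = {
      m1 <- med * exp(params$intensity_sdlog^2 / 2)
      m2 <- 1.8 * med * exp((params$intensity_sdlog / 2)^2 / 2)
      0.7 * m1 + 0.3 * m2
    })
}

# Draw n per-cell true intensities for one group; truncated into (0, 1].
draw_intensities <- function(n, params, fold = 1) {
  med <- params$intensity_median * fold
  draw_once <- function(m) {
    switch(params$intensity_family,
      lognormal = rlnorm(m, meanlog = log(med), sdlog = params$intensity_sdlog),
      gaussian = rnorm(m, mean = med, sd = params$intensity_sdlog * med),
      mixture = {
        pick <- runif(m) < 0.7
        ifelse(pick,
               rlnorm(m, log(med), params$intensity_sdlog),
               rlnorm(m, log(1.8 * med), params$intensity_sdlog / 2))
      })
  }
  x <- draw_once(n)
  bad <- x <= 0 | x > 1
  tries <- 0L
  while (any(bad) && tries < 50L) {
    x[bad] <- draw_once(sum(bad))
    bad <- x <= 0 | x > 1
    tries <- tries + 1L
  }
  if (any(bad)) abort("intensity distribution escapes (0, 1]; lower the median or fold change.")
  x
}

#' Place non-overlapping disk cells in a frame
#'
#' Dart-throwing with rejection: disk centers are drawn uniformly, a
#' placement is accepted when the disk lies fully inside the frame and keeps
#' at least `min_gap_px` edge-to-edge clearance from every accepted disk.
#' Diameters are drawn uniformly from `diameter_range_um` and placed largest
#' first, which raises the feasible packing density. Deterministic for a
#' fixed seed.
#'
#' @param image_shape `c(height_px, width_px)`.
#' @param n_cells Number of disks to place.
#' @param diameter_range_um Diameter range in um.
#' @param pitch_um_per_px Pixel pitch.
#' @param seed Seed (`NULL` = use the current RNG state).
#' @param min_gap_px Minimum edge-to-edge gap.
#' @param max_attempts_per_cell Rejection budget per disk.
#' @return A tibble: `cell_id`, `center_row`, `center_col` (0-based px),
#'   `radius_px`.
#' @export
place_cells <- function(image_shape, n_cells, diameter_range_um = c(18, 38),
                        pitch_um_per_px = 1 / 2.7, seed = NULL,
                        min_gap_px = 2, max_attempts_per_cell = 2000L) {
  run <- function() {
    h <- image_shape[1]; w <- image_shape[2]
    radii <- sort(runif(n_cells, diameter_range_um[1], diameter_range_um[2]),
                  decreasing = TRUE) / 2 / pitch_um_per_px
    if (sum(pi * radii^2) > 0.4 * h * w) {
      abort(sprintf(
        "requested packing infeasible: %d disks cover %.0f%% of the frame (limit 40%%)",
        n_cells, 100 * sum(pi * radii^2) / (h * w)))
    }
    cr <- numeric(0); cc <- numeric(0); rr <- numeric(0)
    for (i in seq_len(n_cells)) {
      r <- radii[i]
      placed <- FALSE
      for (a in seq_len(max_attempts_per_cell)) {
        y <- runif(1, r, h - r)
        x <- runif(1, r, w - r)
        if (length(cr) == 0L ||
            all(sqrt((cr - y)^2 + (cc - x)^2) >= rr + r + min_gap_px)) {
          cr <- c(cr, y); cc <- c(cc, x); rr <- c(rr, r)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "cell placement failed after %d attempts: placed %d of %d cells",
          max_attempts_per_cell, length(cr), n_cells))
      }
    }
    tibble(cell_id = seq_len(n_cells), center_row = cr, center_col = cc,
           radius_px = rr)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Render a synthetic fluorescence frame
#'
#' Paints each disk at its true intensity on a uniform background, applies a
#' Gaussian PSF blur, then signal-dependent shot noise (Gaussian
#' approximation to Poisson with `photon_scale` photons at full scale) plus
#' additive read noise, and clips to `[0, 1]`. The returned label mask is the
#' pre-blur ground truth.
#'
#' @param placements Tibble from [place_cells()].
#' @param true_intensities Numeric vector in `(0, 1]`, one per placement.
#' @param background Background level (normalized); typically
#'   `mean intensity / SBR`.
#' @param image_shape `c(height_px, width_px)`.
#' @param psf_sigma_px Gaussian PSF sigma in px (0 = off).
#' @param photon_scale Photons at full scale (`Inf` or `0` = shot noise off).
#' @param read_noise_sd Additive read-noise sigma (0 = off).
#' @param pitch_um_per_px,channel,image_id Metadata for the output image.
#' @param seed Seed for the noise draws (`NULL` = current RNG state).
#' @return A list: `image` ([fluor_image]), `mask` (integer ground-truth
#'   label matrix, labels = `cell_id`).
#' @export
render_image <- function(placements, true_intensities, background,
                         image_shape, psf_sigma_px = 1,
                         photon_scale = 5000, read_noise_sd = 0.005,
                         pitch_um_per_px = 1 / 2.7,
                         channel = "other", image_id = "synthetic",
                         seed = NULL) {
  stopifnot(nrow(placements) == length(true_intensities))
  if (any(true_intensities > 1) || background > 1) {
    abort("intensity saturation: pre-noise values must be <= 1.")
  }
  if (any(true_intensities <= 0) || background < 0) {
    abort("intensities must be positive and background non-negative.")
  }
  h <- image_shape[1]; w <- image_shape[2]
  canvas <- matrix(background, h, w)
  mask <- matrix(0L, h, w)
  for (i in seq_len(nrow(placements))) {
    cy <- placements$center_row[i]; cx <- placements$center_col[i]
    r <- placements$radius_px[i]
    rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r + 2))
    cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r + 2))
    # pixel (i, j) has 0-based center (i - 1, j - 1)
    dy <- (rows - 1) - cy
    dx <- (cols - 1) - cx
    inside <- outer(dy^2, dx^2, "+") <= r^2
    sub_c <- canvas[rows, cols]; sub_m <- mask[rows, cols]
    sub_c[inside] <- true_intensities[i]
    sub_m[inside] <- placements$cell_id[i]
    canvas[rows, cols] <- sub_c
    mask[rows, cols] <- sub_m
  }
  add_noise <- function() {
    out <- canvas
    if (psf_sigma_px > 0) {
      out <- matrix(as.numeric(EBImage::gblur(out, sigma = psf_sigma_px)),
                    h, w)
    }
    if (is.finite(photon_scale) && photon_scale > 0) {
      out <- out + rnorm(h * w, sd = sqrt(pmax(out, 0) / photon_scale))
    }
    if (read_noise_sd > 0) out <- out + rnorm(h * w, sd = read_noise_sd)
    pmin(pmax(out, 0), 1)
  }
  px <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  list(
    image = fluor_image(px, pitch_um_per_px, channel, image_id),
    mask = mask
  )
}

#' Generate a full synthetic experiment
#'
#' For every group in `params$fold_changes`: `n_images` rendered microscopy
#' frames whose per-cell true intensities are i.i.d. draws from the group's
#' distribution, a ground-truth table, and `flow_n_events` flow events drawn
#' from the same distribution, multiplied by lognormal measurement noise and
#' offset by the SBR-derived baseline (clamped at full scale). All RNG
#' streams are derived from `params$seed`, so identical parameters give
#' byte-identical output.
#'
#' @param params A [generator_params()] list.
#' @return A list of class `cyto_experiment`: `images` (named list of
#'   [fluor_image]), `masks` (named list of ground-truth label matrices),
#'   `truth` (tibble: `cell_id`, `image_id`, `group`, `center_row`,
#'   `center_col`, `radius_px`, `true_intensity`), `flow_events` (tibble as
#'   from [event_table()] plus `intensity_norm`), `flow_baseline`, `params`.
#' @export
generate_experiment <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  groups <- names(params$fold_changes)
  shape <- c(params$image_height_px, params$image_width_px)
  flow_baseline <- group_mean_intensity(params,
                                        params$fold_changes[["control"]]) /
    params$sbr_flow

  # Calibrate the background level so the measured in-cell / background
  # ratio of a rendered frame hits the target SBR. The naive level
  # mean / SBR undershoots once the PSF spills cell signal into the
  # background and zero-clipping biases dim backgrounds upward; two
  # fixed-point steps on a rendered calibration frame absorb both effects.
  calibrate_background <- function() {
    fold <- params$fold_changes[["control"]]
    pl <- place_cells(shape, params$cells_per_image,
                      params$diameter_range_um, params$pitch_um_per_px,
                      seed = NULL, min_gap_px = params$min_gap_px)
    ints <- draw_intensities(nrow(pl), params, fold)
    bg <- group_mean_intensity(params, fold) / params$sbr_microscopy
    for (it in 1:2) {
      rend <- render_image(pl, ints, bg, shape,
                           psf_sigma_px = params$psf_sigma_px,
                           photon_scale = params$photon_scale,
                           read_noise_sd = params$read_noise_sd,
                           pitch_um_per_px = params$pitch_um_per_px,
                           seed = NULL)
      in_eff <- mean(rend$image$pixels[rend$mask > 0L])
      bg_eff <- mean(rend$image$pixels[rend$mask == 0L])
      excess <- bg_eff - bg
      bg <- max(in_eff / params$sbr_microscopy - excess, 1e-5)
    }
    bg
  }

  build <- function() {
    bg <- calibrate_background()
    images <- list(); masks <- list(); truth <- list(); flow <- list()
    for (g in groups) {
      fold <- params$fold_changes[[g]]
      for (k in seq_len(params$n_images)) {
        img_id <- sprintf("%s_img%02d", g, k)
        pl <- place_cells(shape, params$cells_per_image,
                          params$diameter_range_um, params$pitch_um_per_px,
                          seed = NULL, min_gap_px = params$min_gap_px)
        ints <- draw_intensities(nrow(pl), params, fold)
        rend <- render_image(pl, ints, bg, shape,
                             psf_sigma_px = params$psf_sigma_px,
                             photon_scale = params$photon_scale,
                             read_noise_sd = params$read_noise_sd,
                             pitch_um_per_px = params$pitch_um_per_px,
                             channel = params$channel, image_id = img_id,
                             seed = NULL)
        images[[img_id]] <- rend$image
        masks[[img_id]] <- rend$mask
        truth[[img_id]] <- dplyr::mutate(pl, image_id = img_id, group = g,
                                         true_intensity = ints)
      }
      ev <- draw_intensities(params$flow_n_events, params, fold)
      noise <- rlnorm(params$flow_n_events, 0, params$flow_noise_sdlog)
      ev_obs <- pmin(ev * noise + flow_baseline, 1)
      tube <- rep(seq_len(params$flow_n_tubes),
                  length.out = params$flow_n_events)
      flow[[g]] <- dplyr::mutate(
        event_table(ev_obs * 255, "flow", g,
                    sprintf("flow_%s_t%d", g, tube)),
        intensity_norm = ev_obs)
    }
    list(images = images, masks = masks,
         truth = dplyr::bind_rows(truth),
         flow_events = dplyr::bind_rows(flow),
         background = bg)
  }
  res <- withr::with_seed(params$seed, build())
  structure(
    c(res, list(flow_baseline = flow_baseline, params = params)),
    class = "cyto_experiment"
  )
}

#' @export
print.cyto_experiment <- function(x, ...) {
  cat(sprintf(
    "<cyto_experiment> %d group(s) x %d image(s), %d cells total, %d flow events\n",
    length(x$params$fold_changes), x$params$n_images, nrow(x$truth),
    nrow(x$flow_events)))
  invisible(x)
}

#' Measure the signal-to-background ratio of a rendered frame
#'
#' Mean pixel intensity over the ground-truth cell mask divided by the mean
#' over background pixels — the calibration check for the generator's SBR
#' settings.
#'
#' @param image A [fluor_image] (or matrix).
#' @param mask Ground-truth label matrix (0 = background).
#' @return A single ratio.
#' @export
measure_image_sbr <- function(image, mask) {
  px <- if (inherits(image, "fluor_image")) image$pixels else image
  mean(px[mask > 0L]) / mean(px[mask == 0L])
}

#' Match recovered cells to ground truth
#'
#' Nearest-centroid matching: each measured cell is assigned the closest
#' ground-truth cell of the same image when the centroid distance is below
#' `max_dist_px`. Used for parameter-recovery checks (count and intensity
#' recovery).
#'
#' @param cells Tibble from [measure_cells()].
#' @param truth Ground-truth tibble from [generate_experiment()].
#' @param max_dist_px Maximum centroid distance for a match.
#' @return `cells` with `true_intensity`, `true_radius_px` and
#'   `match_dist_px` joined (NA where unmatched).
#' @export
match_cells_to_truth <- function(cells, truth, max_dist_px = 15) {
  one_image <- function(cl, tr) {
    if (nrow(tr) == 0L || nrow(cl) == 0L) {
      return(dplyr::mutate(cl, true_intensity = NA_real_,
                           true_radius_px = NA_real_,
                           match_dist_px = NA_real_))
    }
    d2 <- outer(cl$centroid_row, tr$center_row, "-")^2 +
      outer(cl$centroid_col, tr$center_col, "-")^2
    j <- apply(d2, 1L, which.min)
    dist <- sqrt(d2[cbind(seq_len(nrow(cl)), j)])
    ok <- dist <= max_dist_px
    dplyr::mutate(cl,
                  true_intensity = ifelse(ok, tr$true_intensity[j], NA_real_),
                  true_radius_px = ifelse(ok, tr$radius_px[j], NA_real_),
                  match_dist_px = ifelse(ok, dist, NA_real_))
  }
  cells |>
    dplyr::group_split(.data$image_id) |>
    purrr::map(function(cl) {
      one_image(cl, dplyr::filter(truth, .data$image_id == cl$image_id[1L]))
    }) |>
    dplyr::bind_rows()
}
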