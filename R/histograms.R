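#' Convert normalized intensities to the 8-bit axis
#'
#' Multiplies normalized `[0, 1]` intensities by 255. No rounding is applied:
#' keeping the scale continuous avoids quantization bias in the kernel
#' density estimate downstream.
#'
#' @param values_norm Numeric vector in `[0, 1]`.
#' @return `values_norm * 255`.
#' @export
to_8bit <- function(values_norm) {
  if (anyNA(values_norm) || min(values_norm) < 0 || max(values_norm) > 1) {
    abort("values must lie in [0, 1].")
  }
  values_norm * 255
}

#' Crop a random analysis window from an image
#'
#' Draws a uniformly random top-left corner such that the window lies fully
#' inside the image; with a fixed seed the same window is returned every
#' time. The 1000x750 px default reproduces the random analysis windows the
#' pipeline models.
#'
#' @param image A [fluor_image].
#' @param width_px,height_px Window size.
#' @param seed Seed (`NULL` = current RNG state).
#' @return The cropped [fluor_image] (id suffixed with `_crop`).
#' @export
random_crop <- function(image, width_px = 1000L, height_px = 750L,
                        seed = NULL) {
  stopifnot(inherits(image, "fluor_image"))
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  if (h < height_px || w < width_px) {
    abort(sprintf("image (%d x %d) smaller than the %d x %d crop window",
                  h, w, height_px, width_px))
  }
  corner <- if (is.null(seed)) {
    crop_corner(c(h, w), width_px, height_px)
  } else {
    withr::with_seed(seed, crop_corner(c(h, w), width_px, height_px))
  }
  px <- image$pixels[corner[1]:(corner[1] + height_px - 1L),
                     corner[2]:(corner[2] + width_px - 1L)]
  fluor_image(px, image$pitch_um_per_px, image$channel,
              paste0(image$image_id, "_crop"))
}

# Uniform draw of the (1-based) top-left corner over the valid grid.
crop_corner <- function(image_shape, width_px, height_px) {
  c(sample.int(image_shape[1] - height_px + 1L, 1L),
    sample.int(image_shape[2] - width_px + 1L, 1L))
}

# Normal-reference (Silverman) bandwidth: h = 1.06 * s * n^(-1/5).
silverman_bw <- function(x) {
  1.06 * sd(x) * length(x)^(-1 / 5)
}

#' Kernel density estimate of an intensity distribution
#'
#' Gaussian-kernel density estimate on a regular grid of `n_grid` points
#' spanning `[min(x) - 3h, max(x) + 3h]`, with the normal-reference
#' bandwidth `h = 1.06 * s * n^(-1/5)` unless a bandwidth is supplied. This
#' is the smoothed "frequency plot" standing in for a flow-cytometry
#' histogram.
#'
#' @param values_8bit Numeric vector on the 8-bit axis, `n >= 2` with
#'   positive spread.
#' @param n_grid Grid size (default 512, minimum 64).
#' @param bandwidth Optional fixed bandwidth.
#' @return A tibble `(grid, density)` with attributes `bandwidth` and `n`.
#' @export
kde_curve <- function(values_8bit, n_grid = 512L, bandwidth = NULL) {
  x <- as.numeric(values_8bit)
  if (length(x) < 2L) {
    abort("need at least 2 values for a density estimate; report raw values instead.")
  }
  if (sd(x) == 0) {
    abort("zero variance: no density estimate; report raw values instead.")
  }
  if (n_grid < 64L) abort("`n_grid` must be >= 64.")
  h <- bandwidth %||% silverman_bw(x)
  d <- stats::density(x, bw = h, kernel = "gaussian", n = n_grid, cut = 3)
  out <- tibble(grid = d$x, density = d$y)
  attr(out, "bandwidth") <- h
  attr(out, "n") <- length(x)
  out
}

# Linear interpolation of the half-maximum crossings bracketing the global
# peak: leftmost upward crossing left of the peak, rightmost downward
# crossing right of it.
fwhm_from_curve <- function(grid, dens, peak_idx) {
  half <- dens[peak_idx] / 2
  interp <- function(i) {
    grid[i] + (half - dens[i]) / (dens[i + 1L] - dens[i]) *
      (grid[i + 1L] - grid[i])
  }
  left <- grid[1L]
  if (peak_idx > 1L) {
    up <- which(dens[seq_len(peak_idx - 1L)] < half &
                  dens[seq_len(peak_idx - 1L) + 1L] >= half)
    if (length(up) > 0L) left <- interp(min(up))
  }
  n <- length(grid)
  right <- grid[n]
  if (peak_idx < n) {
    ii <- peak_idx:(n - 1L)
    down <- ii[dens[ii] >= half & dens[ii + 1L] < half]
    if (length(down) > 0L) right <- interp(max(down))
  }
  right - left
}

#' Histogram characteristics of one intensity distribution
#'
#' The four metrics used to compare distributions within and across
#' modalities: the KDE peak location (grid argmax; ties break to the
#' smallest grid value), the full width at half maximum around that global
#' peak (outermost half-maximum crossings, linearly interpolated), and the
#' mean and median of the raw sample. Peak and FWHM describe the smoothed
#' frequency curve; mean and median describe the cell population itself.
#'
#' @inheritParams kde_curve
#' @return A one-row tibble: `peak_8bit`, `fwhm_8bit`, `mean_8bit`,
#'   `median_8bit`, `n_cells`, `bandwidth`.
#' @export
summarize_histogram <- function(values_8bit, n_grid = 512L,
                                bandwidth = NULL) {
  curve <- kde_curve(values_8bit, n_grid, bandwidth)
  peak_idx <- which.max(curve$density)  # first maximum = smallest grid value
  tibble(
    peak_8bit = curve$grid[peak_idx],
    fwhm_8bit = fwhm_from_curve(curve$grid, curve$density, peak_idx),
    mean_8bit = mean(values_8bit),
    median_8bit = median(values_8bit),
    n_cells = length(values_8bit),
    bandwidth = attr(curve, "bandwidth")
  )
}

#' Histogram characteristics per group and modality
#'
#' Pools events within each `group` x `modality` cell of an event table and
#' summarizes each pooled distribution with [summarize_histogram()].
#'
#' @param events An event table (see [event_table()]).
#' @inheritParams kde_curve
#' @return A tibble keyed by `modality`, `group` with the summary columns.
#' @export
histogram_summaries <- function(events, n_grid = 512L, bandwidth = NULL) {
  stopifnot(all(c("intensity_8bit", "modality", "group") %in% names(events)))
  events |>
    dplyr::group_by(.data$modality, .data$group) |>
    dplyr::reframe(summarize_histogram(.data$intensity_8bit, n_grid,
                                       bandwidth))
}

#' Relative changes of histogram characteristics versus control
#'
#' For each non-control group and each metric (peak, FWHM, mean, median),
#' the percent change `100 * (group - control) / control`, computed within
#' modality. A record whose control value is 0 is flagged undefined.
#'
#' @param summaries Output of [histogram_summaries()].
#' @param control_group Name of the reference group.
#' @return A tibble: `modality`, `group`, `control`, `metric`,
#'   `value_group`, `value_control`, `rel_change_pct`, `undefined`.
#' @export
relative_changes <- function(summaries, control_group = "control") {
  stopifnot(all(c("modality", "group") %in% names(summaries)))
  if (!control_group %in% summaries$group) {
    abort(paste0("control group '", control_group, "' not present."))
  }
  long <- summaries |>
    dplyr::select(dplyr::all_of(c("modality", "group", "peak_8bit",
                                  "fwhm_8bit", "mean_8bit", "median_8bit"))) |>
    tidyr::pivot_longer(cols = dplyr::ends_with("_8bit"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = sub("_8bit$", "", .data$metric))
  ctrl <- long |>
    dplyr::filter(.data$group == control_group) |>
    dplyr::select(dplyr::all_of(c("modality", "metric", "value"))) |>
    dplyr::rename(value_control = "value")
  long |>
    dplyr::filter(.data$group != control_group) |>
    dplyr::rename(value_group = "value") |>
    dplyr::inner_join(ctrl, by = c("modality", "metric")) |>
    dplyr::mutate(
      control = control_group,
      undefined = .data$value_control == 0,
      rel_change_pct = dplyr::if_else(
        .data$undefined, NA_real_,
        100 * (.data$value_group - .data$value_control) / .data$value_control)
    ) |>
    dplyr::select(dplyr::all_of(c("modality", "group", "control", "metric",
                                  "value_group", "value_control",
                                  "rel_change_pct", "undefined")))
}
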