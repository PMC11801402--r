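#' Segmentation parameters
#'
#' Settings for primary object identification: global minimum cross-entropy
#' thresholding, connected-component labeling with optional declumping, and
#' equivalent-diameter gating.
#'
#' @param n_bins Number of histogram bins for the threshold search. 256
#'   matches 8-bit quantization of the images the pipeline models.
#' @param connectivity Pixel connectivity for labeling, 4 or 8.
#' @param declump Split touching objects by seeded watershed on the distance
#'   transform. On by default: at realistic plating densities adjacent cells
#'   frequently touch.
#' @param declump_min_sep_um Minimum separation between declumping seeds, in
#'   um. Defaults to half the lower diameter gate: two seeds closer than half
#'   a minimal cell cannot both be cell centers.
#' @param d_min_um,d_max_um Equivalent-diameter gate in um, bounds inclusive.
#'   The defaults 18 and 38 um correspond to 50--100 pixel units at the
#'   ~2.7 px/um pitch of the modeled imager.
#' @param smooth_sigma Gaussian pre-smoothing of the image before
#'   thresholding, in px (0 = off).
#' @param declump_smooth_sigma Gaussian smoothing of the distance transform
#'   before seed detection, in px.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(n_bins = 256L, connectivity = 8L,
                                declump = TRUE, declump_min_sep_um = 9,
                                d_min_um = 18, d_max_um = 38,
                                smooth_sigma = 0,
                                declump_smooth_sigma = 2) {
  if (n_bins < 2L) abort("`n_bins` must be >= 2.")
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8.")
  if (d_min_um >= d_max_um) abort("`d_min_um` must be < `d_max_um`.")
  structure(
    list(n_bins = as.integer(n_bins), connectivity = as.integer(connectivity),
         declump = isTRUE(declump),
         declump_min_sep_um = declump_min_sep_um,
         d_min_um = d_min_um, d_max_um = d_max_um,
         smooth_sigma = smooth_sigma,
         declump_smooth_sigma = declump_smooth_sigma),
    class = "segmentation_params"
  )
}

#' Global minimum cross-entropy threshold
#'
#' Li's thresholding criterion: intensities are quantized to `n_bins` bin
#' centers `g` with counts `h(g)`; for every candidate boundary `t` between
#' occupied bins the two-level reconstruction cost
#' \deqn{-\sum_{g<t} g\,h(g)\log\mu_{low}(t) - \sum_{g\ge t} g\,h(g)\log\mu_{high}(t)}
#' is evaluated, where \eqn{\mu_{low}, \mu_{high}} are the intensity-weighted
#' means of the two sides, and the boundary minimizing the cost is returned.
#' Candidates with an empty side are skipped; ties break toward the smaller
#' boundary.
#'
#' @param image A [fluor_image] or a numeric matrix in `[0, 1]` with at least
#'   two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold value in `[0, 1]`; pixels `>= threshold` are foreground
#'   (see [binarize()]).
#' @export
mce_threshold <- function(image, n_bins = 256L) {
  px <- if (inherits(image, "fluor_image")) image$pixels else image
  px <- as.vector(px)
  rng <- range(px)
  if (rng[1] == rng[2]) abort("degenerate histogram: image is constant.")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(px, edges, rightmost.closed = TRUE)
  h <- tabulate(idx, nbins = n_bins)
  g <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2

  w <- g * h
  cw <- cumsum(w); ch <- cumsum(h)
  k <- seq_len(n_bins - 1L)
  wl <- cw[k]; hl <- ch[k]
  wh <- cw[n_bins] - wl; hh <- ch[n_bins] - hl
  valid <- hl > 0 & hh > 0
  mu_lo <- wl / hl; mu_hi <- wh / hh
  cost <- rep(Inf, n_bins - 1L)
  # g >= 0 so mu_lo = 0 can only occur when the low side carries no signal
  # mass; its contribution to the cost is then 0 (0 * log is taken as 0).
  term <- function(wsum, mu) ifelse(wsum > 0, -wsum * log(mu), 0)
  cost[valid] <- term(wl[valid], mu_lo[valid]) + term(wh[valid], mu_hi[valid])
  if (!any(is.finite(cost))) abort("degenerate histogram: no valid boundary.")
  k_best <- which.min(cost)  # which.min takes the first minimum: smaller t
  edges[k_best + 1L]
}

#' @rdname mce_threshold
#' @param threshold Threshold as returned by `mce_threshold()`.
#' @return `binarize()`: a logical matrix, `TRUE` for foreground.
#' @export
binarize <- function(image, threshold) {
  px <- if (inherits(image, "fluor_image")) image$pixels else image
  px >= threshold
}

# Merge 4-connected component labels that touch diagonally into
# 8-connected components.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- list()
  a <- lab[-nr, -nc]; b <- lab[-1L, -1L]      # down-right diagonal
  s <- a > 0L & b > 0L & a != b
  if (any(s)) pairs[[1L]] <- cbind(a[s], b[s])
  a <- lab[-nr, -1L]; b <- lab[-1L, -nc]      # down-left diagonal
  s <- a > 0L & b > 0L & a != b
  if (any(s)) pairs[[2L]] <- cbind(a[s], b[s])
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0L) return(lab)
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Label objects in a binary mask
#'
#' Connected-component labeling at the configured connectivity. With
#' declumping enabled, touching objects are split: seeds are local maxima of
#' the Gaussian-smoothed distance transform, thinned so that no two seeds lie
#' closer than the configured minimum separation, and labels are grown from
#' the seeds by seeded watershed on the negated distance transform within the
#' mask. Components left without a seed keep a label of their own.
#'
#' @param mask Logical or 0/1 matrix.
#' @param params A [segmentation_params()] list.
#' @param pitch_um_per_px Pixel pitch, needed to convert the seed-separation
#'   setting from um to px when declumping.
#' @return Integer label matrix; background 0, objects 1..n.
#' @export
label_objects <- function(mask, params = segmentation_params(),
                          pitch_um_per_px = 1 / 2.7) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (params$connectivity == 8L) lab <- merge_diagonal_labels(lab)

  if (!params$declump) return(lab)

  dist <- EBImage::distmap(m)
  sig <- params$declump_smooth_sigma
  dist_s <- if (sig > 0) EBImage::gblur(dist, sigma = sig) else dist
  dist_s <- matrix(as.numeric(dist_s), nrow(m), ncol(m))

  min_sep_px <- max(1, params$declump_min_sep_um / pitch_um_per_px)
  brush_size <- 2L * as.integer(ceiling(min_sep_px / 2)) + 1L
  local_max <- EBImage::dilate(dist_s, EBImage::makeBrush(brush_size, "disc"))
  cand <- which(m > 0 & dist_s >= as.numeric(local_max) - 1e-9,
                arr.ind = TRUE)
  if (nrow(cand) == 0L) return(lab)
  cand <- cand[order(-dist_s[cand], cand[, 1L], cand[, 2L]), , drop = FALSE]

  keep <- matrix(numeric(0), ncol = 2L)
  sep2 <- min_sep_px^2
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(keep) == 0L ||
        all((keep[, 1L] - p[1L])^2 + (keep[, 2L] - p[2L])^2 >= sep2)) {
      keep <- rbind(keep, p)
    }
  }
  seeds <- matrix(0L, nrow(m), ncol(m))
  seeds[keep] <- seq_len(nrow(keep))

  out <- EBImage::propagate(-dist_s, seeds = seeds, mask = m)
  out <- matrix(as.integer(out), nrow(m), ncol(m))
  orphan <- m > 0 & out == 0L
  if (any(orphan)) {
    extra <- EBImage::bwlabel(matrix(as.numeric(orphan), nrow(m), ncol(m)))
    extra <- matrix(as.integer(extra), nrow(m), ncol(m))
    out[orphan] <- extra[orphan] + max(out)
  }
  out
}

#' Gate labeled objects by equivalent diameter
#'
#' Keeps objects whose equivalent diameter
#' `2 * sqrt(area_px / pi) * pitch_um_per_px` lies inside
#' `[d_min_um, d_max_um]` (bounds inclusive). The physical (um) gate is
#' canonical; out-of-range objects are excluded rather than referred to a
#' manual review step, and their count is reported.
#'
#' @param labels Integer label matrix.
#' @param pitch_um_per_px Pixel pitch in um/px.
#' @param d_min_um,d_max_um Inclusive diameter bounds in um.
#' @return A list: `labels` (gated mask, original label ids retained),
#'   `objects` (tibble of label, area_px, equivalent_diameter_um, kept flag),
#'   `n_kept`, `n_removed`.
#' @export
gate_by_diameter <- function(labels, pitch_um_per_px,
                             d_min_um = 18, d_max_um = 38) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) {
    return(list(labels = labels,
                objects = tibble(label = integer(), area_px = integer(),
                                 equivalent_diameter_um = numeric(),
                                 kept = logical()),
                n_kept = 0L, n_removed = 0L))
  }
  area <- tabulate(labels[labels > 0L], nbins = max(ids))[ids]
  d_um <- 2 * sqrt(area / pi) * pitch_um_per_px
  kept <- d_um >= d_min_um & d_um <= d_max_um
  out <- labels
  drop_ids <- ids[!kept]
  if (length(drop_ids) > 0L) out[out %in% drop_ids] <- 0L
  list(
    labels = out,
    objects = tibble(label = ids, area_px = as.integer(area),
                     equivalent_diameter_um = d_um, kept = kept),
    n_kept = sum(kept),
    n_removed = sum(!kept)
  )
}

#' Measure whole-cell mean intensities
#'
#' One record per labeled object: pixel area, equivalent diameter, centroid
#' and the arithmetic mean of the image pixels under the label — the whole
#' cell region, without isolating the nucleus and with no background
#' subtraction. The 8-bit mean is exactly `255 * mean_intensity_norm`.
#'
#' @param image A [fluor_image] (or numeric matrix in `[0, 1]`).
#' @param labels Integer label matrix of the same shape.
#' @param image_id Identifier recorded per cell; defaults to the image's.
#' @param pitch_um_per_px Pixel pitch; defaults to the image's.
#' @return A tibble (one row per cell): `cell_id`, `image_id`, `label`,
#'   `area_px`, `equivalent_diameter_um`, `centroid_row`, `centroid_col`
#'   (0-based px), `mean_intensity_norm`, `mean_intensity_8bit`.
#' @export
measure_cells <- function(image, labels, image_id = NULL,
                          pitch_um_per_px = NULL) {
  if (inherits(image, "fluor_image")) {
    if (is.null(image_id)) image_id <- image$image_id
    if (is.null(pitch_um_per_px)) pitch_um_per_px <- image$pitch_um_per_px
    px <- image$pixels
  } else {
    px <- image
    if (is.null(image_id)) image_id <- "image"
    if (is.null(pitch_um_per_px)) abort("`pitch_um_per_px` is required.")
  }
  if (!all(dim(px) == dim(labels))) {
    abort("image and label mask must have the same shape.")
  }
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) {
    return(tibble(cell_id = character(), image_id = character(),
                  label = integer(), area_px = integer(),
                  equivalent_diameter_um = numeric(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  mean_intensity_norm = numeric(),
                  mean_intensity_8bit = numeric()))
  }
  in_mask <- labels > 0L
  lab_v <- labels[in_mask]
  f <- factor(lab_v, levels = ids)
  area <- as.integer(tabulate(f, nbins = length(ids)))
  mean_int <- rowsum(px[in_mask], f)[, 1L] / area
  rows0 <- row(labels)[in_mask] - 1
  cols0 <- col(labels)[in_mask] - 1
  tibble(
    cell_id = paste0(image_id, "_c", ids),
    image_id = image_id,
    label = as.integer(ids),
    area_px = area,
    equivalent_diameter_um = 2 * sqrt(area / pi) * pitch_um_per_px,
    centroid_row = rowsum(rows0, f)[, 1L] / area,
    centroid_col = rowsum(cols0, f)[, 1L] / area,
    mean_intensity_norm = as.numeric(mean_int),
    mean_intensity_8bit = 255 * as.numeric(mean_int)
  )
}

#' Segment one image end to end
#'
#' Threshold (minimum cross-entropy), label (with optional declumping), gate
#' by equivalent diameter, and measure whole-cell mean intensities.
#'
#' @param image A [fluor_image].
#' @param params A [segmentation_params()] list.
#' @return A list of class `cyto_segmentation`: `cells` (tibble from
#'   [measure_cells()]), `labels` (gated label mask), `threshold`,
#'   `n_removed` (objects outside the diameter gate), `objects` (gating
#'   detail).
#' @export
segment_image <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "fluor_image"))
  px <- image$pixels
  if (params$smooth_sigma > 0) {
    px <- matrix(as.numeric(EBImage::gblur(px, params$smooth_sigma)),
                 nrow(px), ncol(px))
    px <- pmin(pmax(px, 0), 1)
  }
  thr <- mce_threshold(px, params$n_bins)
  mask <- px >= thr
  labels <- label_objects(mask, params, image$pitch_um_per_px)
  gated <- gate_by_diameter(labels, image$pitch_um_per_px,
                            params$d_min_um, params$d_max_um)
  cells <- measure_cells(image, gated$labels)
  structure(
    list(cells = cells, labels = gated$labels, threshold = thr,
         n_removed = gated$n_removed, objects = gated$objects,
         params = params),
    class = "cyto_segmentation"
  )
}

#' @export
print.cyto_segmentation <- function(x, ...) {
  cat(sprintf(
    "<cyto_segmentation> threshold %.4f; %d cells kept, %d gated out\n",
    x$threshold, nrow(x$cells), x$n_removed))
  invisible(x)
}

#' @export
#' @method tidy cyto_segmentation
tidy.cyto_segmentation <- function(x, ...) x$cells
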