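# Independent reference implementations used to cross-check the package.
# They are deliberately naive (explicit loops, direct formulas) and share no
# code with the implementations they guard.

# Minimum cross-entropy threshold by exhaustive scan: quantize to n_bins bin
# centers, evaluate the cross-entropy cost at every boundary with direct
# sums, return the boundary (bin edge) with minimal cost, ties to smaller t.
mce_oracle <- function(px, n_bins) {
  px <- as.vector(px)
  edges <- seq(min(px), max(px), length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  idx <- findInterval(px, edges, rightmost.closed = TRUE)
  h <- tabulate(idx, nbins = n_bins)
  best_cost <- Inf
  best_k <- NA_integer_
  for (k in 1:(n_bins - 1)) {
    lo <- 1:k
    hi <- (k + 1):n_bins
    if (sum(h[lo]) == 0 || sum(h[hi]) == 0) next
    mu_lo <- sum(centers[lo] * h[lo]) / sum(h[lo])
    mu_hi <- sum(centers[hi] * h[hi]) / sum(h[hi])
    cost <- 0
    if (sum(centers[lo] * h[lo]) > 0) {
      cost <- cost - sum(centers[lo] * h[lo]) * log(mu_lo)
    }
    if (sum(centers[hi] * h[hi]) > 0) {
      cost <- cost - sum(centers[hi] * h[hi]) * log(mu_hi)
    }
    if (cost < best_cost) {
      best_cost <- cost
      best_k <- k
    }
  }
  edges[best_k + 1]
}

# Per-label mean intensity by an explicit per-pixel loop.
naive_cell_means <- function(px, labels) {
  ids <- sort(unique(labels[labels > 0]))
  out <- numeric(length(ids))
  for (j in seq_along(ids)) {
    s <- 0
    n <- 0
    for (i in seq_along(labels)) {
      if (labels[i] == ids[j]) {
        s <- s + px[i]
        n <- n + 1
      }
    }
    out[j] <- s / n
  }
  setNames(out, ids)
}

# Paint hard-edged disks (no blur, no noise) on a constant background;
# returns image matrix and label mask. Centers are 0-based pixel coords.
draw_disks <- function(shape, centers_row, centers_col, radii, values,
                       background = 0) {
  px <- matrix(background, shape[1], shape[2])
  mask <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(nrow(px))) {
    for (j in seq_len(ncol(px))) {
      for (k in seq_along(radii)) {
        if ((i - 1 - centers_row[k])^2 + (j - 1 - centers_col[k])^2 <=
            radii[k]^2) {
          px[i, j] <- values[k]
          mask[i, j] <- k
        }
      }
    }
  }
  list(pixels = px, mask = mask)
}

# A small random blob image for threshold tests: lognormal-ish background
# plus a few bright patches; guaranteed non-constant.
random_blob_image <- function(seed, shape = c(60, 60)) {
  withr::with_seed(seed, {
    px <- matrix(runif(prod(shape), 0, 0.1), shape[1], shape[2])
    n_blob <- sample(1:4, 1)
    for (b in seq_len(n_blob)) {
      cy <- runif(1, 5, shape[1] - 5)
      cx <- runif(1, 5, shape[2] - 5)
      r <- runif(1, 3, 10)
      val <- runif(1, 0.3, 0.9)
      for (i in seq_len(shape[1])) {
        for (j in seq_len(shape[2])) {
          if ((i - cy)^2 + (j - cx)^2 <= r^2) px[i, j] <- val
        }
      }
    }
    px
  })
}

# Compact generator settings for fast tests: small frames, few cells.
tiny_params <- function(...) {
  args <- list(image_width_px = 400, image_height_px = 300,
               n_images = 2, cells_per_image = 5, flow_n_events = 2000)
  args[names(list(...))] <- list(...)
  do.call(generator_params, args)
}
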