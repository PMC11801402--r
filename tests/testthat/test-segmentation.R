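test_that("threshold separates a perfectly bimodal image", {
  px <- matrix(rep(c(0.1, 0.9), each = 50), 10, 10)
  thr <- mce_threshold(px)
  expect_gt(thr, 0.1)
  expect_lte(thr, 0.9)
  fg <- binarize(px, thr)
  expect_identical(unname(fg), unname(px == 0.9))

  expect_error(mce_threshold(matrix(0.5, 5, 5)), "degenerate")
})

test_that("threshold equals the exhaustive cross-entropy scan", {
  for (seed in 1:12) {
    px <- random_blob_image(seed)
    for (nb in c(64L, 256L)) {
      expect_identical(mce_threshold(px, nb), mce_oracle(px, nb))
    }
  }
})

test_that("adding a constant shifts the threshold by about that constant", {
  px <- random_blob_image(99)
  thr0 <- mce_threshold(px, 256L)
  bin_w <- diff(range(px)) / 256
  for (c_shift in c(0.02, 0.05)) {
    thr_c <- mce_threshold(px + c_shift, 256L)
    expect_lt(abs(thr_c - (thr0 + c_shift)), 2 * bin_w)
  }
})

test_that("labeling counts disjoint objects and handles the empty mask", {
  mask <- matrix(FALSE, 60, 80)
  mask[10:20, 10:20] <- TRUE
  mask[40:50, 50:70] <- TRUE
  p <- segmentation_params(declump = FALSE)
  lab <- label_objects(mask, p)
  expect_equal(max(lab), 2L)

  empty <- label_objects(matrix(FALSE, 10, 10), p)
  expect_equal(max(empty), 0L)
})

test_that("8-connectivity joins diagonal pixels, 4 does not", {
  mask <- matrix(FALSE, 6, 6)
  mask[2, 2] <- TRUE
  mask[3, 3] <- TRUE
  lab8 <- label_objects(mask, segmentation_params(connectivity = 8,
                                                  declump = FALSE))
  lab4 <- label_objects(mask, segmentation_params(connectivity = 4,
                                                  declump = FALSE))
  expect_equal(max(lab8), 1L)
  expect_equal(max(lab4), 2L)
})

test_that("declumping splits two overlapping disks at their true centers", {
  # equal disks of radius 30 px, centers 1.8 r apart (20% radius overlap)
  r <- 30
  fix <- draw_disks(c(160, 200), c(80, 80), c(70, 124), c(r, r), c(1, 1))
  params <- segmentation_params(declump = TRUE, declump_min_sep_um = 9)
  lab <- label_objects(fix$pixels > 0.5, params, pitch_um_per_px = 1 / 2.7)
  expect_equal(max(lab), 2L)
  cent <- measure_cells(matrix(0.5, 160, 200), lab, image_id = "fix",
                        pitch_um_per_px = 1 / 2.7)
  got <- cent[order(cent$centroid_col), ]
  expect_lt(abs(got$centroid_row[1] - 80), 2)
  expect_lt(abs(got$centroid_col[1] - 70), 2)
  expect_lt(abs(got$centroid_row[2] - 80), 2)
  expect_lt(abs(got$centroid_col[2] - 124), 2)
})

test_that("diameter gate keeps 18-38 um inclusively and conserves objects", {
  pitch <- 1 / 2.7
  d_um <- c(10, 19, 25, 37, 45)
  r_px <- d_um / 2 / pitch
  centers_col <- cumsum(2 * r_px + 20) - r_px
  shape <- c(200, ceiling(max(centers_col + r_px)) + 10)
  fix <- draw_disks(shape, rep(90, 5), centers_col, r_px, rep(0.8, 5))
  gated <- gate_by_diameter(fix$mask, pitch, 18, 38)

  # rasterized disks: check against the analytic equivalent diameter from
  # independent pixel counts
  for (k in 1:5) {
    area_k <- sum(fix$mask == k)
    expect_equal(gated$objects$equivalent_diameter_um[k],
                 2 * sqrt(area_k / pi) * pitch, tolerance = 1e-12)
  }
  # rasterization shifts equivalent diameters by well under 1 um here, so
  # the kept set is exactly the nominally in-range diameters
  expect_equal(gated$objects$kept, d_um >= 18 & d_um <= 38)
  expect_equal(gated$n_kept + gated$n_removed, 5L)

  # bounds are inclusive: an object whose computed diameter equals the
  # bound exactly stays in; an infinitesimally tighter gate drops it
  sq <- matrix(0L, 20, 20)
  sq[6:15, 6:15] <- 1L               # area exactly 100 px
  d_exact <- 2 * sqrt(100 / pi) * pitch
  expect_equal(gate_by_diameter(sq, pitch, d_exact, 38)$n_kept, 1L)
  expect_equal(gate_by_diameter(sq, pitch, 1, d_exact)$n_kept, 1L)
  expect_equal(gate_by_diameter(sq, pitch, d_exact * (1 + 1e-12), 38)$n_kept,
               0L)

  # idempotence: gating a gated mask removes nothing further
  again <- gate_by_diameter(gated$labels, pitch, 18, 38)
  expect_identical(again$labels, gated$labels)
  expect_equal(again$n_removed, 0L)

  # single-pixel object is far below the gate
  tinym <- matrix(0L, 10, 10)
  tinym[5, 5] <- 1L
  expect_equal(gate_by_diameter(tinym, 0.37, 18, 38)$n_removed, 1L)
})

test_that("whole-cell means are exact and symmetric under label swap", {
  fix <- draw_disks(c(100, 160), c(50, 50), c(40, 110), c(15, 15),
                    c(0.2, 0.8), background = 0.01)
  cells <- measure_cells(fix$pixels, fix$mask, image_id = "two",
                         pitch_um_per_px = 0.37)
  expect_equal(sort(cells$mean_intensity_norm), c(0.2, 0.8))
  expect_equal(cells$mean_intensity_8bit, 255 * cells$mean_intensity_norm)

  swapped <- fix$mask
  swapped[fix$mask == 1L] <- 2L
  swapped[fix$mask == 2L] <- 1L
  cells_sw <- measure_cells(fix$pixels, swapped, image_id = "two",
                            pitch_um_per_px = 0.37)
  expect_equal(cells_sw$mean_intensity_norm[order(cells_sw$label)],
               rev(cells$mean_intensity_norm[order(cells$label)]))
})

test_that("per-cell means match a naive per-pixel loop on noisy data", {
  gp <- tiny_params(seed = 17)
  ex <- generate_experiment(gp)
  img <- ex$images[[1]]
  mask <- ex$masks[[1]]
  cells <- measure_cells(img, mask)
  oracle <- naive_cell_means(img$pixels, mask)
  expect_equal(cells$mean_intensity_norm, unname(oracle), tolerance = 1e-12)
})

test_that("noise-free non-overlapping frames are recovered exactly", {
  gp <- tiny_params(psf_sigma_px = 0, photon_scale = Inf, read_noise_sd = 0,
                    n_images = 3, seed = 4)
  ex <- generate_experiment(gp)
  for (id in names(ex$images)) {
    seg <- segment_image(ex$images[[id]])
    truth_id <- ex$truth[ex$truth$image_id == id, ]
    expect_equal(nrow(seg$cells), nrow(truth_id))
    m <- match_cells_to_truth(seg$cells, truth_id)
    expect_true(all(!is.na(m$true_intensity)))
    # plateau means equal the drawn intensities exactly
    expect_equal(m$mean_intensity_norm, m$true_intensity, tolerance = 1e-12)
  }
})
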