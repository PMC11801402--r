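test_that("place_cells keeps disks inside the frame, apart, and deterministic", {
  one <- place_cells(c(240, 320), 1, seed = 3)
  expect_equal(nrow(one), 1L)
  expect_true(one$center_row >= one$radius_px &
                one$center_row <= 240 - one$radius_px)
  expect_true(one$center_col >= one$radius_px &
                one$center_col <= 320 - one$radius_px)

  a <- place_cells(c(520, 700), 30, c(18, 38), 1 / 2.7, seed = 1)
  b <- place_cells(c(520, 700), 30, c(18, 38), 1 / 2.7, seed = 1)
  expect_identical(a, b)

  # exhaustive pairwise check: every disk pair keeps the configured margin
  expect_equal(nrow(a), 30L)
  for (i in 1:29) {
    for (j in (i + 1):30) {
      centre_dist <- sqrt((a$center_row[i] - a$center_row[j])^2 +
                            (a$center_col[i] - a$center_col[j])^2)
      expect_gte(centre_dist, a$radius_px[i] + a$radius_px[j] + 2)
    }
  }
  r_px <- c(18, 38) / 2 / (1 / 2.7)
  expect_true(all(a$radius_px >= r_px[1] & a$radius_px <= r_px[2]))
})

test_that("infeasible packing is rejected with the achieved count", {
  # 100 large disks cannot fit a 200x200 frame at <= 40% coverage
  expect_error(place_cells(c(200, 200), 100, c(18, 38), 1 / 2.7, seed = 1),
               "infeasible|failed")
})

test_that("noiseless rendering paints exact plateaus", {
  pl <- tibble::tibble(cell_id = 1L, center_row = 60, center_col = 80,
                       radius_px = 25)
  rend <- render_image(pl, 0.6, background = 0.03, image_shape = c(120, 160),
                       psf_sigma_px = 0, photon_scale = Inf,
                       read_noise_sd = 0)
  px <- rend$image$pixels
  expect_true(all(px[rend$mask == 1L] == 0.6))
  expect_true(all(px[rend$mask == 0L] == 0.03))
  expect_error(
    render_image(pl, 1.2, 0.03, c(120, 160), psf_sigma_px = 0,
                 photon_scale = Inf, read_noise_sd = 0),
    "saturation")
})

test_that("blur preserves the plateau interior within 1%", {
  pl <- tibble::tibble(cell_id = 1L, center_row = 60, center_col = 80,
                       radius_px = 25)
  rend <- render_image(pl, 0.6, 0.03, c(120, 160), psf_sigma_px = 1,
                       photon_scale = Inf, read_noise_sd = 0)
  eroded <- EBImage::erode(matrix(as.numeric(rend$mask > 0), 120, 160),
                           EBImage::makeBrush(5, "disc"))
  interior <- rend$image$pixels[as.numeric(eroded) > 0]
  expect_equal(mean(interior), 0.6, tolerance = 0.01)
})

test_that("rendered frames reproduce the configured SBR within 10%", {
  for (ch in c("glucose_like", "mmp_like")) {
    gp <- generator_params(channel = ch, n_images = 1,
                           fold_changes = c(control = 1), seed = 101)
    ex <- generate_experiment(gp)
    sbr <- measure_image_sbr(ex$images[[1]], ex$masks[[1]])
    expect_equal(sbr, gp$sbr_microscopy, tolerance = 0.10)
  }
})

test_that("fold changes propagate exactly into the ground truth", {
  gp <- tiny_params(fold_changes = c(control = 1, a = 1, b = 1), seed = 2)
  ex <- generate_experiment(gp)
  mu <- tapply(ex$truth$true_intensity, ex$truth$group, mean)
  # all folds equal: group means differ only by sampling noise
  expect_lt(diff(range(mu)) / mean(mu), 0.2)

  # noiseless construction: the lognormal medians scale exactly with fold
  gp2 <- tiny_params(fold_changes = c(control = 1, treated = 1.3), seed = 2,
                     intensity_sdlog = 1e-9)
  ex2 <- generate_experiment(gp2)
  mu2 <- tapply(ex2$truth$true_intensity, ex2$truth$group, mean)
  expect_equal(unname(mu2[["treated"]] / mu2[["control"]]), 1.3,
               tolerance = 1e-6)
})

test_that("flow events match the configured distribution mean", {
  gp <- generator_params(image_width_px = 320, image_height_px = 240,
                         n_images = 1, cells_per_image = 4,
                         fold_changes = c(control = 1),
                         flow_noise_sdlog = 0, seed = 9)
  ex <- generate_experiment(gp)
  m <- gp$intensity_median
  s <- gp$intensity_sdlog
  mean_true <- m * exp(s^2 / 2)           # closed-form lognormal mean
  se <- sqrt((exp(s^2) - 1) * exp(s^2)) * m / sqrt(gp$flow_n_events)
  obs <- mean(ex$flow_events$intensity_norm) - ex$flow_baseline
  expect_lt(abs(obs - mean_true), 3 * se)
  flow_sbr <- (mean(ex$flow_events$intensity_norm) - ex$flow_baseline) /
    ex$flow_baseline
  expect_equal(flow_sbr, gp$sbr_flow, tolerance = 0.1)
})

test_that("same params and seed give identical experiments", {
  gp <- tiny_params(seed = 33)
  e1 <- generate_experiment(gp)
  e2 <- generate_experiment(gp)
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$flow_events, e2$flow_events)
  expect_identical(e1$images[[1]]$pixels, e2$images[[1]]$pixels)
})

test_that("truth table counts match connected components of the label mask", {
  gp <- tiny_params(seed = 12)
  ex <- generate_experiment(gp)
  for (id in names(ex$masks)) {
    mask <- ex$masks[[id]]
    cc <- max(EBImage::bwlabel(matrix(as.numeric(mask > 0), nrow(mask),
                                      ncol(mask))))
    expect_equal(cc, sum(ex$truth$image_id == id))
  }
})

test_that("imaging truth and noise-free flow draws share one distribution", {
  gp <- generator_params(image_width_px = 480, image_height_px = 360,
                         n_images = 8, cells_per_image = 8,
                         fold_changes = c(control = 1),
                         flow_noise_sdlog = 0, sbr_flow = 1e6, seed = 21)
  ex <- generate_experiment(gp)
  flow_vals <- ex$flow_events$intensity_norm - ex$flow_baseline
  # two-sample location test on the log scale at large n
  tt <- t.test(log(ex$truth$true_intensity), log(flow_vals))
  expect_gt(tt$p.value, 0.01)
})
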