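test_that("8-bit conversion is exact multiplication by 255", {
  expect_equal(to_8bit(1.0), 255)
  expect_equal(to_8bit(0.0), 0)
  expect_equal(to_8bit(0.5), 127.5)
  expect_error(to_8bit(1.01), "\\[0, 1\\]")
  expect_error(to_8bit(-0.1), "\\[0, 1\\]")
})

test_that("random crops are in-bounds, deterministic, and uniform", {
  px <- matrix(withr::with_seed(1, runif(300 * 400)), 300, 400)
  img <- fluor_image(px, 0.37, "other", "big")

  # exact-size image: the only valid window is the full image
  full <- random_crop(img, width_px = 400, height_px = 300, seed = 5)
  expect_identical(full$pixels, px)

  a <- random_crop(img, 100, 80, seed = 7)
  b <- random_crop(img, 100, 80, seed = 7)
  expect_identical(a$pixels, b$pixels)
  expect_equal(dim(a$pixels), c(80L, 100L))

  expect_error(random_crop(img, 500, 80), "smaller")

  # corner coordinates uniform over the valid grid (chi-square on binned
  # marginals of the internal corner draw)
  corners <- withr::with_seed(11, t(replicate(10000, {
    opticyto:::crop_corner(c(1500, 2000), 1000, 750)
  })))
  expect_true(all(corners[, 1] >= 1 & corners[, 1] <= 751))
  expect_true(all(corners[, 2] >= 1 & corners[, 2] <= 1001))
  for (col in 1:2) {
    n_lev <- if (col == 1) 751 else 1001
    bins <- cut(corners[, col], breaks = seq(0.5, n_lev + 0.5,
                                             length.out = 11))
    expect_gt(chisq.test(table(bins))$p.value, 0.001)
  }
})

test_that("kde_curve matches its contract", {
  expect_error(kde_curve(rep(100, 50)), "zero variance")
  expect_error(kde_curve(42), "at least 2")

  # symmetric two-point sample: density symmetric about the midpoint
  cv <- kde_curve(c(50, 150))
  mid <- 100
  expect_equal(cv$density, rev(cv$density), tolerance = 1e-9)
  expect_equal(mean(range(cv$grid)), mid, tolerance = 1e-9)

  # density integrates to ~1 on the grid
  x <- withr::with_seed(3, rnorm(500, 128, 12))
  cv2 <- kde_curve(x)
  integral <- sum(diff(cv2$grid) * (head(cv2$density, -1) +
                                      tail(cv2$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 0.01)

  # the normal-reference bandwidth rule is applied exactly
  expect_equal(attr(cv2, "bandwidth"), 1.06 * sd(x) * 500^(-1 / 5))

  # peak of a large normal sample sits at the true mode
  xx <- withr::with_seed(4, rnorm(10000, 128, 20))
  cv3 <- kde_curve(xx)
  expect_lt(abs(cv3$grid[which.max(cv3$density)] - 128), 2)
})

test_that("summary metrics: mean/median from raw sample, peak/FWHM from KDE", {
  s <- summarize_histogram(c(1, 2, 3))
  expect_equal(s$mean_8bit, 2)
  expect_equal(s$median_8bit, 2)
  expect_equal(s$n_cells, 3L)

  # Gaussian KDE of Gaussian data is Normal(mu, sigma^2 + h^2):
  # FWHM = 2.3548 * sqrt(sigma^2 + h^2)
  x <- withr::with_seed(8, rnorm(50000, 128, 15))
  s2 <- summarize_histogram(x)
  h <- s2$bandwidth
  expect_equal(s2$fwhm_8bit, 2 * sqrt(2 * log(2)) * sqrt(15^2 + h^2),
               tolerance = 0.03)
  expect_lt(abs(s2$peak_8bit - 128), 1.5)
})

test_that("FWHM follows the main peak, not a distant light outlier", {
  # tight cluster at 100 plus one event at 240: the outlier carries ~0.1%
  # of the mass and must not widen the main peak's half-max interval
  x <- c(withr::with_seed(9, rnorm(999, 100, 5)), 240)
  s <- summarize_histogram(x)
  h <- s$bandwidth
  sigma_eff <- sqrt(var(x[x < 200]) + h^2)
  expect_equal(s$fwhm_8bit, 2.3548 * sigma_eff, tolerance = 0.05)
  expect_lt(s$fwhm_8bit, 40)
})

test_that("histogram metrics are scale- and shift-equivariant", {
  x <- withr::with_seed(10, 80 + 30 * rbeta(4000, 2, 5))
  s <- summarize_histogram(x)
  for (k in c(0.5, 2)) {
    sk <- summarize_histogram(k * x)
    expect_equal(sk$peak_8bit, k * s$peak_8bit, tolerance = 1e-6)
    expect_equal(sk$fwhm_8bit, k * s$fwhm_8bit, tolerance = 1e-6)
    expect_equal(sk$mean_8bit, k * s$mean_8bit, tolerance = 1e-9)
    expect_equal(sk$median_8bit, k * s$median_8bit, tolerance = 1e-9)
  }
  grid_step <- 6 * attr(kde_curve(x), "bandwidth") / 511 +
    diff(range(x)) / 511
  for (cc in c(-20, 35)) {
    sc <- summarize_histogram(x + cc)
    expect_lt(abs(sc$peak_8bit - (s$peak_8bit + cc)), grid_step)
    expect_lt(abs(sc$fwhm_8bit - s$fwhm_8bit), grid_step)
    expect_equal(sc$mean_8bit, s$mean_8bit + cc, tolerance = 1e-9)
    expect_equal(sc$median_8bit, s$median_8bit + cc, tolerance = 1e-9)
  }
})

test_that("relative changes use the control as denominator", {
  summaries <- tibble::tibble(
    modality = "flow",
    group = c("control", "up", "same"),
    peak_8bit = c(100, 120, 100),
    fwhm_8bit = c(50, 60, 50),
    mean_8bit = c(100, 120, 100),
    median_8bit = c(80, 60, 80)
  )
  rel <- relative_changes(summaries)
  up <- rel[rel$group == "up", ]
  expect_equal(up$rel_change_pct[up$metric == "mean"], 20)
  expect_equal(up$rel_change_pct[up$metric == "peak"], 20)
  expect_equal(up$rel_change_pct[up$metric == "fwhm"], 20)
  expect_equal(up$rel_change_pct[up$metric == "median"], -25)
  same <- rel[rel$group == "same", ]
  expect_true(all(same$rel_change_pct == 0))

  # zero control flagged undefined
  summaries$mean_8bit[1] <- 0
  rel0 <- relative_changes(summaries)
  expect_true(all(rel0$undefined[rel0$metric == "mean"]))
  expect_true(all(is.na(rel0$rel_change_pct[rel0$metric == "mean"])))
  expect_error(relative_changes(summaries, "absent"), "not present")
})

test_that("configured fold change appears in noise-free flow rel-changes", {
  gp <- tiny_params(fold_changes = c(control = 1, treated = 1.3),
                    flow_noise_sdlog = 0, sbr_flow = 1e6,
                    flow_n_events = 20000, seed = 14)
  ex <- generate_experiment(gp)
  s <- histogram_summaries(ex$flow_events)
  rel <- relative_changes(s)
  mean_rel <- rel$rel_change_pct[rel$metric == "mean"]
  expect_lt(abs(mean_rel - 30), 2)
})
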