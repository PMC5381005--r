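test_that("all beads of a noise-free phantom are found at their true centres", {
  ph <- cached_render(bead_cfg())
  cands <- detect_beads(ph$stack, min_separation = 3)
  truth <- ph$truth$bead_centers
  expect_equal(nrow(cands), nrow(truth))
  half_vox <- sqrt(sum((ph$stack$voxel_size / 2)^2))
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt(colSums((t(cands[, 1:3, drop = FALSE]) - truth[i, ])^2))
    expect_lt(min(dd), half_vox)
  }
})

test_that("a uniform image yields no candidates", {
  st <- image_stack(array(100, c(10, 10, 10)), c(1, 1, 1))
  expect_equal(nrow(detect_beads(st, min_separation = 3)), 0L)
})

test_that("two maxima closer than min_separation are suppressed to one", {
  v <- array(0, c(15, 15, 15))
  v[8, 8, 7] <- 100
  v[8, 8, 9] <- 90      # 2 um away at 1 um pitch
  st <- image_stack(v, c(1, 1, 1))
  got <- detect_beads(st, min_separation = 3, intensity_percentile = 99,
                      border_margin = 1)
  expect_equal(nrow(got), 1L)
  got2 <- detect_beads(st, min_separation = 1.5, intensity_percentile = 99,
                       border_margin = 1)
  expect_equal(nrow(got2), 2L)
})

test_that("FWHM of a synthetic Gaussian spot matches 2.3548 sigma", {
  n <- 41
  u <- seq_len(n)
  vs <- c(0.5, 0.4, 0.4)
  sig_um <- c(1.2, 0.8, 0.8)
  s <- sig_um / vs
  g <- function(k, ax) exp(-(k - 21)^2 / (2 * s[ax]^2))
  v <- 500 * outer(outer(g(u, 1), g(u, 2)), g(u, 3)) + 20
  st <- image_stack(v, vs)
  rec <- measure_fwhm(st, centroid = (c(21, 21, 21) - 0.5) * vs)
  expect_true(rec$accepted)
  expect_equal(rec$fwhm_z, 2.3548 * 1.2, tolerance = 0.02)
  expect_equal(rec$fwhm_y, 2.3548 * 0.8, tolerance = 0.02)
  expect_equal(rec$fwhm_x, 2.3548 * 0.8, tolerance = 0.02)

  scaled <- image_stack(v * 37, vs)  # FWHM invariant under intensity scaling
  rec2 <- measure_fwhm(scaled, centroid = (c(21, 21, 21) - 0.5) * vs)
  expect_equal(c(rec2$fwhm_z, rec2$fwhm_y, rec2$fwhm_x),
               c(rec$fwhm_z, rec$fwhm_y, rec$fwhm_x), tolerance = 1e-9)
})

test_that("flat profiles and out-of-bounds windows are rejected, not errors", {
  flat <- image_stack(array(50, c(31, 31, 31)), c(1, 1, 1))
  rec <- measure_fwhm(flat, centroid = c(15, 15, 15))
  expect_false(rec$accepted)

  ph <- cached_render(bead_cfg())
  edge <- measure_fwhm(ph$stack, centroid = c(0.5, 0.5, 0.5))
  expect_false(edge$accepted)
  expect_match(edge$reason, "bounds")
})

test_that("lognormal population parameters are recovered from known draws", {
  set.seed(99)
  n <- 200
  fake <- data.frame(z = 0, y = 0, x = 0,
                     fwhm_z = stats::rlnorm(n, 0.5, 0.2),
                     fwhm_y = stats::rlnorm(n, 0.5, 0.2),
                     fwhm_x = stats::rlnorm(n, 0.5, 0.2),
                     r2_z = 1, r2_y = 1, r2_x = 1,
                     accepted = TRUE, reason = "")
  pop <- fit_psf_population(fake)
  expect_true(pop$available)
  for (ax in c("z", "y", "x")) {
    s <- pop$stats[pop$stats$axis == ax, ]
    expect_lt(abs(s$meanlog - 0.5), 0.05)
    expect_lt(abs(s$sdlog - 0.2), 0.05)
  }
})

test_that("degenerate populations are handled", {
  same <- data.frame(z = 0, y = 0, x = 0,
                     fwhm_z = rep(2, 10), fwhm_y = rep(2, 10),
                     fwhm_x = rep(2, 10),
                     r2_z = 1, r2_y = 1, r2_x = 1,
                     accepted = TRUE, reason = "")
  pop <- fit_psf_population(same)
  expect_lt(max(abs(pop$stats$sdlog)), 1e-8)
  expect_equal(pop$stats$lognormal_median, rep(2, 3), tolerance = 1e-9)

  few <- same[1:4, ]
  pop4 <- fit_psf_population(few)
  expect_false(pop4$available)
  expect_true(all(is.na(pop4$stats$meanlog)))
})

test_that("population median FWHM on a noisy bead phantom tracks the PSF", {
  cfg <- bead_cfg(bead_count = 50, tm_diameter = 40,
                  noise_model = "poisson", background_level = 10,
                  rng_seed = 31)
  ph <- render_phantom(cfg)
  recs <- measure_psf(ph$stack, min_separation = 3)
  pop <- fit_psf_population(recs)
  expect_true(pop$available)
  expected <- 2.3548 * cfg$psf_sigma
  for (i in 1:3) {
    ax <- c("z", "y", "x")[i]
    med <- pop$stats$lognormal_median[pop$stats$axis == ax]
    expect_lt(abs(med - expected[i]) / expected[i], 0.10)
  }
})

test_that("attenuation dims deep beads without biasing accepted FWHMs", {
  cfg <- bead_cfg(bead_count = 40, tm_diameter = 40,
                  mfp_illum = 0.05, mfp_det = 1e9,
                  noise_model = "gaussian", noise_sd = 40,
                  peak_signal = 2000, background_level = 10, rng_seed = 17)
  ph <- render_phantom(cfg)
  recs <- measure_psf(ph$stack, min_separation = 3,
                      intensity_percentile = 99.9)
  acc <- recs[recs$accepted, ]
  expect_gt(nrow(acc), 5)
  expect_lt(abs(stats::median(acc$fwhm_x) - 2.3548 * 0.6) / (2.3548 * 0.6),
            0.15)
  # rejection hits the attenuated (low-x, deep) side harder
  cen_x <- ph$truth$tm_center[3]
  deep <- recs$x < cen_x
  if (any(deep) && any(!deep)) {
    rej_deep <- mean(!recs$accepted[deep])
    rej_shallow <- mean(!recs$accepted[!deep])
    expect_gte(rej_deep, rej_shallow)
  }
})
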