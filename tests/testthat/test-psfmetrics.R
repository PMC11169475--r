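test_that("puncta detection finds isolated maxima and applies the crowding rule", {
  s <- image_stack(array(0, c(9, 9, 9)), voxel_size = c(1, 1, 1))
  s$voxels[5, 5, 5] <- 100
  pk <- detect_puncta(s, min_separation = 3, threshold = 50)
  expect_equal(nrow(pk), 1)
  expect_equal(unname(pk[1, ]), c(5, 5, 5))
  # two bright voxels 2 um apart with a 10 um separation rule: both go
  s$voxels[5, 5, 7] <- 90
  expect_equal(nrow(detect_puncta(s, min_separation = 10, threshold = 50)), 0)
  # generous spacing keeps both
  expect_equal(nrow(detect_puncta(s, min_separation = 1.5, threshold = 50)), 2)
})

test_that("seeded phantoms are mostly recovered by detection", {
  ph <- gen_bead_stack(n_beads = 20, shape = c(40L, 64L, 64L),
                       min_separation_um = 30, seed = 9)
  pk <- detect_puncta(ph$stack, min_separation = 20, threshold = 50)
  expect_gte(nrow(pk), round(0.9 * nrow(ph$truth)))
})

test_that("per-punctum FWHM matches generator truth on clean data", {
  ph <- gen_bead_stack(n_beads = 8, snr = Inf, seed = 21)
  pk <- detect_puncta(ph$stack, 20, 50)
  # keep puncta whose z window fits inside the volume
  nz <- dim(ph$stack$voxels)[1]
  pk <- pk[pk[, "z"] > 8 & pk[, "z"] <= nz - 8, , drop = FALSE]
  expect_gt(nrow(pk), 0)
  for (i in seq_len(min(4, nrow(pk)))) {
    v <- fwhm_at(ph$stack, pk[i, ], "z", expected_fwhm = 7.2)
    pos <- (pk[i, ] - 0.5) * ph$stack$voxel_size
    j <- which.min((ph$truth$z_um - pos[1])^2 + (ph$truth$y_um - pos[2])^2 +
                     (ph$truth$x_um - pos[3])^2)
    expect_equal(v, ph$truth$axial_fwhm_true[j], tolerance = 0.1)
  }
  # boundary punctum is rejected
  expect_error(fwhm_at(ph$stack, c(2L, 10L, 10L), "z", 7.2), "boundary")
})

test_that("isotropic blur gives matching axial and lateral widths", {
  ph <- gen_bead_stack(n_beads = 6, shape = c(40L, 40L, 40L),
                       voxel_size = c(3, 3, 3), lateral_fwhm = 7.2,
                       axial_fwhm_focus = 7.2, rayleigh_length = 1e9,
                       snr = Inf, seed = 13)
  pk <- detect_puncta(ph$stack, 20, 50)
  # most central punctum so both axis windows fit
  ctr <- dim(ph$stack$voxels) / 2
  i <- which.min(rowSums((t(t(pk) - ctr))^2))
  vz <- fwhm_at(ph$stack, pk[i, ], "z", 7.2)
  vx <- fwhm_at(ph$stack, pk[i, ], "x", 7.2)
  expect_equal(vz, vx, tolerance = 0.02)
})

test_that("smallest-N summaries follow their definition", {
  s <- summarize_fwhm(rep(5, 12))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  s2 <- summarize_fwhm(sample(1:20), n_select = 10)
  expect_equal(s2$mean, mean(1:10))
  expect_equal(s2$sd, sd(1:10))
  s3 <- summarize_fwhm(c(3, 1, 2), n_select = 10)
  expect_true(s3$short)
  expect_equal(s3$mean, 2)
  expect_error(summarize_fwhm(numeric(0)), "no finite")
})

test_that("summaries are permutation invariant", {
  set.seed(5)
  v <- runif(25, 4, 9)
  a <- summarize_fwhm(v)
  b <- summarize_fwhm(sample(v))
  expect_equal(a$mean, b$mean)
  expect_equal(a$sd, b$sd)
})

test_that("elongation ratios reproduce the printed mode comparisons", {
  ax <- summarize_fwhm(rep(7.2, 10)); lat <- summarize_fwhm(rep(4.4, 10))
  expect_equal(round(elongation_ratio(ax, lat), 2), 1.64)
  expect_equal(elongation_ratio(lat, lat), 1)
  ff_ax <- summarize_fwhm(rep(26.0, 10)); ff_lat <- summarize_fwhm(rep(4.2, 10))
  expect_equal(elongation_ratio(ff_ax, ff_lat), 26 / 4.2)
})

test_that("pipeline recovers the generator blur on noise-free phantoms", {
  m <- psf_pipeline(gen_bead_stack(seed = 1, snr = Inf)$stack,
                    axis = "z", expected_fwhm = 7.2)$mean
  expect_equal(m, 7.2, tolerance = 0.02 * 7.2)
})

test_that("pipeline stays within 7 percent at SNR 10 over 20 seeds", {
  means <- vapply(1:20, function(sd)
    psf_pipeline(gen_bead_stack(seed = sd, snr = 10)$stack,
                 axis = "z", expected_fwhm = 7.2)$mean, numeric(1))
  expect_equal(mean(means), 7.2, tolerance = 0.07 * 7.2)
})
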