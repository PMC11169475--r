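test_that("bead phantoms are deterministic under a fixed seed", {
  a <- gen_bead_stack(n_beads = 10, seed = 11)
  b <- gen_bead_stack(n_beads = 10, seed = 11)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth, b$truth)
  c <- gen_bead_stack(n_beads = 10, seed = 12)
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("bead truth manifests record every centre and the beam-law width", {
  ph <- gen_bead_stack(n_beads = 15, seed = 2, snr = Inf)
  expect_equal(nrow(ph$truth), 15)
  extent <- dim(ph$stack$voxels) * ph$stack$voxel_size
  expect_true(all(ph$truth$z_um > 0 & ph$truth$z_um < extent[1]))
  expect_true(all(ph$truth$x_um > 0 & ph$truth$x_um < extent[3]))
  p <- attr(ph$truth, "params")
  # beam law plus the bead ball variance r^2/5, folded per axis
  off <- abs(ph$truth$x_um - p$focus_x)
  beam_sigma <- 7.2 * sqrt(1 + (off / p$rayleigh_length)^2) /
    (2 * sqrt(2 * log(2)))
  expected <- 2 * sqrt(2 * log(2)) * sqrt(beam_sigma^2 + 0.5^2 / 5)
  expect_equal(ph$truth$axial_fwhm_true, expected, tolerance = 1e-12)
})

test_that("a bead at one Rayleigh length has sqrt(2)-enlarged axial width", {
  # learn where the seeded bead lands, then put the focus one Rayleigh
  # length away from it and measure the stack
  args <- list(n_beads = 1, shape = c(60L, 12L, 40L),
               voxel_size = c(3, 3.45, 3.45), snr = Inf,
               rayleigh_length = 100, seed = 5)
  probe <- do.call(gen_bead_stack, args)
  args$focus_x <- probe$truth$x_um[1] - 100
  ph <- do.call(gen_bead_stack, args)
  expect_equal(ph$truth$axial_fwhm_true[1], sqrt(2) * 7.2, tolerance = 0.01)
  pk <- detect_puncta(ph$stack, 20, 50)
  v <- fwhm_at(ph$stack, pk[1, ], "z", expected_fwhm = 10)
  expect_equal(v, sqrt(2) * 7.2, tolerance = 0.15)
})

test_that("blur-free beads rasterize as bare spheres", {
  ph <- gen_bead_stack(n_beads = 1, shape = c(11L, 11L, 11L),
                       voxel_size = c(1, 1, 1), bead_radius_um = 2,
                       lateral_fwhm = 0, axial_fwhm_focus = 0,
                       snr = Inf, peak = 100, seed = 3)
  vox <- ph$stack$voxels
  ctr <- as.numeric(ph$truth[1, c("z_um", "y_um", "x_um")])
  # voxels well inside the sphere are full, well outside empty
  pos <- (seq_len(11) - 0.5)
  d2 <- outer(outer((pos - ctr[1])^2, (pos - ctr[2])^2, `+`),
              (pos - ctr[3])^2, `+`)
  expect_true(all(vox[d2 < (2 - 0.9)^2] == 100))
  expect_true(all(vox[d2 > (2 + 0.9)^2] == 0))
})

test_that("illumination references follow the generating Gaussian", {
  img <- gen_illumination_profile(c(64L, 16L), sigma_y = 15, peak = 1000,
                                  peak_row = 30)
  med <- apply(img, 1, median)
  expect_equal(which.max(med), 30)
  expect_equal(med, 1000 * exp(-((1:64 - 30)^2) / (2 * 15^2)),
               tolerance = 1e-12)
  flat <- gen_illumination_profile(c(16L, 8L), sigma_y = 1e9, peak = 10)
  expect_lt(diff(range(flat)), 1e-6)
})

test_that("vessel/drug phantoms encode the halo radius as ground truth", {
  vd <- gen_vessel_drug_masks(shape = c(96L, 96L), n_vessels = 2,
                              halo_px = 6, seed = 4)
  expect_true(all(vd$drug[vd$vessel == 1] == 1))  # drug superset of vessel
  expect_equal(vd$truth$halo_px, c(6, 6))
  # zero halo means identical masks
  vd0 <- gen_vessel_drug_masks(shape = c(96L, 96L), n_vessels = 1,
                               halo_px = 0, seed = 4)
  expect_identical(vd0$vessel, vd0$drug)
})

test_that("tls pairs share geometry and record the focus midpoint", {
  tp <- gen_tls_pair(seed = 6)
  expect_equal(tp$truth$midpoint_um,
               (tp$truth$focus_x1 + tp$truth$focus_x2) / 2)
  expect_equal(dim(tp$stack1$voxels), dim(tp$stack2$voxels))
  same <- gen_tls_pair(shape = c(40L, 8L, 120L), n_nuclei = 30,
                       focus_x1 = 200, focus_x2 = 200, snr = Inf, seed = 6)
  expect_identical(same$stack1$voxels, same$stack2$voxels)
  # focus contrast is higher near each stack's own focus
  c1 <- focus_contrast(reslice_xz(tp$stack1))
  c2 <- focus_contrast(reslice_xz(tp$stack2))
  x1_px <- tp$truth$focus_x1 / tp$stack1$voxel_size[3]
  x2_px <- tp$truth$focus_x2 / tp$stack1$voxel_size[3]
  near1 <- which.min(abs(c1$window_x_centers - x1_px))
  near2 <- which.min(abs(c1$window_x_centers - x2_px))
  expect_gt(c1$sd_values[near1], c2$sd_values[near1])
  expect_gt(c2$sd_values[near2], c1$sd_values[near2])
})

test_that("stripe shadows attenuate rows multiplicatively when enabled", {
  off <- gen_bead_stack(n_beads = 10, seed = 3, snr = Inf)
  on <- gen_bead_stack(n_beads = 10, seed = 3, snr = Inf,
                       stripe_amplitude = 0.5, stripe_period_px = 8)
  expect_identical(off$truth$x_um, on$truth$x_um)
  expect_true(all(on$stack$voxels <= off$stack$voxels + 1))
  expect_false(identical(on$stack$voxels, off$stack$voxels))
  # default remains stripe-free
  again <- gen_bead_stack(n_beads = 10, seed = 3, snr = Inf)
  expect_identical(again$stack$voxels, off$stack$voxels)
})
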