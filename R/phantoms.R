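#' @keywords internal
gaussian_beam_fwhm <- function(x, fwhm0, focus_x, rayleigh) {
  fwhm0 * sqrt(1 + ((x - focus_x) / rayleigh)^2)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# Renders spheres as Gaussian-equivalent emitters: each sphere contributes a
# separable Gaussian whose variance is the PSF variance plus the ball's
# per-axis variance r^2/5 (exact in second moments; the spheres here are at
# or below the resolution limit, so higher moments are negligible). The
# axial PSF width follows the Gaussian-beam law in the bead's x position;
# axial defocus conserves flux, so the amplitude dims by the ratio of the
# in-focus to local axial width.
render_spheres <- function(shape, voxel_size, centers, radius_um,
                           lateral_fwhm, axial_fwhm_focus, focus_x,
                           rayleigh, peak) {
  vox <- array(0, shape)
  if (!nrow(centers)) return(vox)
  ball_var <- radius_um^2 / 5
  sig_z_focus <- sqrt(fwhm_to_sigma(axial_fwhm_focus)^2 + ball_var)
  for (b in seq_len(nrow(centers))) {
    cz <- centers[b, 1]; cy <- centers[b, 2]; cx <- centers[b, 3]
    fz <- gaussian_beam_fwhm(cx, axial_fwhm_focus, focus_x, rayleigh)
    sig <- c(sqrt(fwhm_to_sigma(fz)^2 + ball_var),
             sqrt(fwhm_to_sigma(lateral_fwhm)^2 + ball_var),
             sqrt(fwhm_to_sigma(lateral_fwhm)^2 + ball_var))
    amp <- peak * sig_z_focus / sig[1L]
    ctr <- c(cz, cy, cx)
    prof <- vector("list", 3L)
    idx <- vector("list", 3L)
    for (ax in 1:3) {
      d <- voxel_size[ax]
      pos <- (seq_len(shape[ax]) - 0.5) * d
      keep <- which(abs(pos - ctr[ax]) <= 4.5 * sig[ax] + d)
      if (!length(keep)) keep <- which.min(abs(pos - ctr[ax]))
      idx[[ax]] <- keep
      prof[[ax]] <- exp(-(pos[keep] - ctr[ax])^2 / (2 * sig[ax]^2))
    }
    blob <- outer(outer(prof[[1]], prof[[2]]), prof[[3]])
    dim(blob) <- c(length(idx[[1]]), length(idx[[2]]), length(idx[[3]]))
    vox[idx[[1]], idx[[2]], idx[[3]]] <-
      vox[idx[[1]], idx[[2]], idx[[3]]] + amp * blob
  }
  vox
}

# Rasterized sphere occupancy (sub-voxel, 5^3 subsampling); used for the
# blur-free branch of gen_bead_stack.
rasterize_spheres <- function(shape, voxel_size, centers, radius_um, peak) {
  vox <- array(0, shape)
  sub <- (seq_len(5) - 3) / 5
  for (b in seq_len(nrow(centers))) {
    ctr <- centers[b, ]
    rng <- lapply(1:3, function(ax) {
      d <- voxel_size[ax]
      pos <- (seq_len(shape[ax]) - 0.5) * d
      which(abs(pos - ctr[ax]) <= radius_um + d)
    })
    for (iz in rng[[1]]) for (iy in rng[[2]]) for (ix in rng[[3]]) {
      pz <- (iz - 0.5 + sub) * voxel_size[1] - ctr[1]
      py <- (iy - 0.5 + sub) * voxel_size[2] - ctr[2]
      px <- (ix - 0.5 + sub) * voxel_size[3] - ctr[3]
      occ <- outer(outer(pz^2, py^2, `+`), px^2, `+`) <= radius_um^2
      vox[iz, iy, ix] <- vox[iz, iy, ix] + peak * mean(occ)
    }
  }
  vox
}

# Poisson shot noise + additive Gaussian read noise on top of a camera
# baseline offset. 'snr' is the peak signal to total noise sd ratio: the
# variance budget at peak intensity, (peak/snr)^2, is split 3:1 between
# shot noise (n_photons = 4/3 * snr^2 at peak) and read noise
# (sd = peak/(2*snr)). The baseline keeps the read noise clear of the
# zero clip, as a real camera's bias offset does; without it the clipped
# tails skew downstream profile fits.
add_noise <- function(vox, peak, snr, baseline = 10) {
  if (!is.finite(snr)) return(vox)
  n_photons <- snr^2 / 0.75
  shot <- stats::rpois(length(vox), pmax(vox, 0) / peak * n_photons) *
    (peak / n_photons)
  baseline + shot + stats::rnorm(length(vox), sd = peak / (2 * snr))
}

# Multiplicative stripe-shadow artifact: absorbing particles in the
# one-sided illumination path cast shadows along x, so the attenuation
# varies across y. Factor bounded in [1 - amplitude, 1].
apply_stripes <- function(vox, amplitude, period_px, phase = 0) {
  if (amplitude <= 0) return(vox)
  d <- dim(vox)
  s <- 1 - amplitude * (0.5 + 0.5 * sin(2 * pi * seq_len(d[2L]) / period_px +
                                          phase))
  vox * array(rep(s, each = d[1L]), d)
}

#' Generate a synthetic bead-in-gel stack with known ground truth
#'
#' Emulates a z-stack of sub-resolution fluorescent beads embedded in a
#' cleared gel: spheres are rendered, blurred by an anisotropic Gaussian
#' PSF whose axial width grows away from the sheet focus following the
#' Gaussian-beam law `FWHM(x) = FWHM0 * sqrt(1 + ((x - focus_x)/z_R)^2)`,
#' and corrupted by Poisson-Gaussian noise. Defaults emulate the fine-axial
#' imaging regime: 3.45 um lateral pixels, 3 um z-step, 1 um beads,
#' 7.2 um axial / 4.4 um lateral FWHM at focus, 445 um Rayleigh length.
#'
#' @param n_beads number of beads to place.
#' @param shape stack dimensions `(z, y, x)` in voxels.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param bead_radius_um bead radius, um (<= a few voxels).
#' @param lateral_fwhm,axial_fwhm_focus PSF FWHMs at the sheet focus, um.
#'   Setting both to 0 disables blur and rasterizes the bare spheres.
#' @param focus_x sheet focus position along x, um (default: volume centre).
#' @param rayleigh_length Rayleigh length of the sheet, um.
#' @param snr peak-signal to noise-sd ratio; `Inf` for noise-free.
#' @param peak peak bead intensity (8-bit scale).
#' @param min_separation_um minimum centre-to-centre bead distance.
#' @param stripe_amplitude optional stripe-shadow artifact: multiplicative
#'   attenuation bands running along x (depth 0..1, 0 = off). A basic
#'   one-sided-illumination instrument has no stripe-removal device, so
#'   this emulates that acknowledged limitation.
#' @param stripe_period_px stripe period across y, pixels.
#' @param seed RNG seed; identical seed and arguments give identical output.
#' @return list with `stack` (an [image_stack]) and `truth`, a data frame of
#'   bead centres (um), the per-bead true axial FWHM, and the generator
#'   parameters as attributes.
#' @examples
#' ph <- gen_bead_stack(n_beads = 5, seed = 1)
#' ph$truth
#' @export
gen_bead_stack <- function(n_beads = 30,
                           shape = c(40L, 48L, 48L),
                           voxel_size = c(3, 3.45, 3.45),
                           bead_radius_um = 0.5,
                           lateral_fwhm = 4.4,
                           axial_fwhm_focus = 7.2,
                           focus_x = NULL,
                           rayleigh_length = 445,
                           snr = 20,
                           peak = 150,
                           min_separation_um = 25,
                           stripe_amplitude = 0,
                           stripe_period_px = 9,
                           seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 3L), bead_radius_um > 0)
  set.seed(seed)
  extent <- shape * voxel_size
  if (is.null(focus_x)) focus_x <- extent[3] / 2
  margin <- pmax(2 * voxel_size,
                 1.2 * c(axial_fwhm_focus, lateral_fwhm, lateral_fwhm))
  if (any(extent - 2 * margin <= 0))
    stop("volume too small for the requested PSF widths")
  centers <- matrix(NA_real_, 0L, 3L)
  rejected <- 0L
  tries <- 0L
  while (nrow(centers) < n_beads && tries < 200L * n_beads) {
    tries <- tries + 1L
    cand <- margin + stats::runif(3) * (extent - 2 * margin)
    if (nrow(centers) &&
        min(sqrt(colSums((t(centers) - cand)^2))) < min_separation_um) {
      rejected <- rejected + 1L
      next
    }
    centers <- rbind(centers, cand)
  }
  if (nrow(centers) < n_beads)
    warning(sprintf("placed %d of %d beads (separation constraint)",
                    nrow(centers), n_beads))
  blur <- lateral_fwhm > 0 || axial_fwhm_focus > 0
  vox <- if (blur)
    render_spheres(shape, voxel_size, centers, bead_radius_um,
                   lateral_fwhm, axial_fwhm_focus, focus_x,
                   rayleigh_length, peak)
  else
    rasterize_spheres(shape, voxel_size, centers, bead_radius_um, peak)
  vox <- apply_stripes(vox, stripe_amplitude, stripe_period_px,
                       phase = stats::runif(1, 0, 2 * pi))
  vox <- add_noise(vox, peak, snr)
  vox <- array(clamp_to_depth(round(vox), 8), shape)
  truth <- data.frame(
    bead = seq_len(nrow(centers)),
    z_um = centers[, 1], y_um = centers[, 2], x_um = centers[, 3],
    axial_fwhm_true = if (blur)
      sigma_to_fwhm(sqrt(fwhm_to_sigma(
        gaussian_beam_fwhm(centers[, 3], axial_fwhm_focus, focus_x,
                           rayleigh_length))^2 + bead_radius_um^2 / 5))
      else bead_radius_um * 2
  )
  attr(truth, "params") <- list(
    lateral_fwhm = lateral_fwhm, axial_fwhm_focus = axial_fwhm_focus,
    focus_x = focus_x, rayleigh_length = rayleigh_length,
    bead_radius_um = bead_radius_um, snr = snr, peak = peak, seed = seed)
  list(stack = image_stack(vox, voxel_size = voxel_size, bit_depth = 8),
       truth = truth)
}

#' Generate a dye-solution illumination reference image
#'
#' Emulates the flat-field reference acquired from a homogeneous
#' fluorescein solution: the one-sided sheet illumination falls off as a
#' Gaussian along y and is constant along x.
#'
#' @param shape `(ny, nx)` in pixels.
#' @param sigma_y Gaussian fall-off scale along y, pixels (`Inf` = flat).
#' @param peak peak intensity at the illumination centre row.
#' @param peak_row row of maximum intensity (default: centre row).
#' @param noise_sd additive Gaussian noise sd (0 = noise-free).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return numeric matrix `(y, x)`.
#' @export
gen_illumination_profile <- function(shape = c(128L, 64L), sigma_y = 40,
                                     peak = 2000, peak_row = NULL,
                                     noise_sd = 0, seed = 1L) {
  stopifnot(sigma_y > 0, peak > 0)
  if (is.null(peak_row)) peak_row <- (shape[1] + 1) / 2
  prof <- peak * exp(-((seq_len(shape[1]) - peak_row)^2) / (2 * sigma_y^2))
  img <- matrix(prof, shape[1], shape[2])
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                        shape[1], shape[2])
  }
  img
}

#' Generate paired vessel and drug-halo masks with known halo radii
#'
#' Emulates one binarized MIP slice of a vessel channel and a drug channel:
#' vessels are random polylines dilated to tubes, and the drug mask is the
#' union of each vessel dilated further by its halo radius, so the true
#' drug-to-vessel contour distance is the halo radius.
#'
#' @param shape `(ny, nx)` in pixels.
#' @param n_vessels number of vessel polylines.
#' @param vessel_radius_px tube radius in pixels.
#' @param halo_px halo radius in pixels; scalar (all vessels) or one per
#'   vessel. 0 makes the drug mask equal the vessel mask.
#' @param n_segments segments per polyline.
#' @param seed RNG seed.
#' @return list with binary matrices `vessel` and `drug` and a `truth` data
#'   frame of per-vessel halo radii.
#' @export
gen_vessel_drug_masks <- function(shape = c(128L, 128L), n_vessels = 3L,
                                  vessel_radius_px = 2L, halo_px = 8L,
                                  n_segments = 3L, seed = 1L) {
  set.seed(seed)
  halo_px <- rep_len(halo_px, n_vessels)
  vessel <- matrix(0L, shape[1], shape[2])
  drug <- matrix(0L, shape[1], shape[2])
  margin <- vessel_radius_px + max(halo_px) + 2L
  span <- shape - 2L * margin
  if (any(span <= 4L)) stop("mask too small for the requested radii")
  truth <- data.frame(vessel = seq_len(n_vessels)[0], halo_px = numeric(0))
  for (v in seq_len(n_vessels)) {
    pts <- matrix(NA_real_, n_segments + 1L, 2L)
    pts[1L, ] <- margin + stats::runif(2) * span
    for (s in seq_len(n_segments)) {
      step <- stats::runif(2, -0.4, 0.4) * span
      pts[s + 1L, ] <- pmin(pmax(pts[s, ] + step, margin), margin + span)
    }
    line <- matrix(0L, shape[1], shape[2])
    for (s in seq_len(n_segments)) {
      px <- bresenham_line(round(pts[s, 1]), round(pts[s, 2]),
                           round(pts[s + 1, 1]), round(pts[s + 1, 2]))
      line[px] <- 1L
    }
    tube <- dilate_mask(line, vessel_radius_px)
    halo <- if (halo_px[v] > 0) dilate_mask(tube, halo_px[v]) else tube
    vessel <- pmax(vessel, tube)
    drug <- pmax(drug, halo)
    truth <- rbind(truth, data.frame(vessel = v, halo_px = halo_px[v]))
  }
  list(vessel = vessel, drug = drug, truth = truth)
}

# binary dilation by a disc of the given radius (EBImage brush)
dilate_mask <- function(mask, radius) {
  if (radius < 1) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::dilate(mask, brush)
  matrix(as.integer(out > 0), nrow(mask), ncol(mask))
}

#' Generate a pair of focus-shifted nuclei stacks for tiling fusion
#'
#' The same random nuclei volume is rendered twice with the sheet focus at
#' two x positions; axial blur grows away from each focus per the
#' Gaussian-beam law, so focus quality along x inverts between the two
#' stacks at the midpoint `(focus_x1 + focus_x2)/2`, which the truth
#' records.
#'
#' @param shape stack dimensions `(z, y, x)` in voxels.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param n_nuclei number of nuclei.
#' @param nucleus_radius_um nucleus radius, um.
#' @param focus_x1,focus_x2 sheet focus positions, um (defaults: 1/4 and
#'   3/4 of the x extent).
#' @param axial_fwhm_focus,lateral_fwhm,rayleigh_length PSF parameters as in
#'   [gen_bead_stack()].
#' @param snr approximate peak-to-noise ratio.
#' @param seed RNG seed.
#' @return list with `stack1`, `stack2` ([image_stack]s) and `truth`
#'   (focus positions and their midpoint, in um and x-pixels).
#' @export
gen_tls_pair <- function(shape = c(100L, 16L, 400L),
                         voxel_size = c(5, 3.45, 3.45),
                         n_nuclei = 120L, nucleus_radius_um = 4,
                         focus_x1 = NULL, focus_x2 = NULL,
                         axial_fwhm_focus = 7.2, lateral_fwhm = 4.4,
                         rayleigh_length = 300, snr = 20, peak = 150,
                         seed = 1L) {
  set.seed(seed)
  extent <- shape * voxel_size
  if (is.null(focus_x1)) focus_x1 <- extent[3] * 0.25
  if (is.null(focus_x2)) focus_x2 <- extent[3] * 0.75
  margin <- pmax(2 * voxel_size, 2 * nucleus_radius_um)
  centers <- cbind(margin[1] + stats::runif(n_nuclei) * (extent[1] - 2 * margin[1]),
                   margin[2] + stats::runif(n_nuclei) * (extent[2] - 2 * margin[2]),
                   margin[3] + stats::runif(n_nuclei) * (extent[3] - 2 * margin[3]))
  mk <- function(fx) {
    vox <- render_spheres(shape, voxel_size, centers, nucleus_radius_um,
                          lateral_fwhm, axial_fwhm_focus, fx,
                          rayleigh_length, peak)
    vox <- add_noise(vox, peak, snr)
    image_stack(array(clamp_to_depth(round(vox), 8), shape),
                voxel_size = voxel_size, bit_depth = 8)
  }
  list(stack1 = mk(focus_x1), stack2 = mk(focus_x2),
       truth = list(focus_x1 = focus_x1, focus_x2 = focus_x2,
                    midpoint_um = (focus_x1 + focus_x2) / 2,
                    midpoint_px = (focus_x1 + focus_x2) / 2 / voxel_size[3],
                    centers = centers))
}
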