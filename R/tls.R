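#' x-z reslice of a stack for focus-quality analysis
#'
#' Returns the stack viewed in the x-z plane: a matrix with rows = z and
#' columns = x, obtained by maximum projection over the selected y rows
#' (default: all of them). Projection over y concentrates the in-focus
#' structures that the focus-contrast measure responds to.
#'
#' @param stack an [image_stack].
#' @param y_range optional integer vector of y rows to project over.
#' @return numeric matrix `(z, x)`.
#' @export
reslice_xz <- function(stack, y_range = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (is.null(y_range)) y_range <- seq_len(d[2L])
  apply(stack$voxels[, y_range, , drop = FALSE], c(1L, 3L), max)
}

#' Focus-contrast curve of an x-z reslice
#'
#' Band-pass filters the reslice (difference of Gaussians passing structure
#' sizes between `band[1]` and `band[2]` pixels), tiles it with
#' non-overlapping kernels (`kernel[1]` px along x, `kernel[2]` px along z),
#' and takes the standard deviation of the filtered values in each kernel.
#' Where the sheet is in focus, high-contrast axial structure survives the
#' band-pass and the SD rises. Kernels in the same x column are averaged,
#' giving one value per x window.
#'
#' @param xz_image numeric matrix `(z, x)`, e.g. from [reslice_xz()].
#' @param kernel integer length-2, `(x, z)` kernel size in pixels.
#' @param band structure-size pass band in pixels, `(small, large)`.
#' @return an object of class `"focus_contrast_curve"`: list with
#'   `window_x_centers` (px), `sd_values`, `boundaries_px` (right edge of
#'   each window), `kernel`, `band`.
#' @export
focus_contrast <- function(xz_image, kernel = c(50L, 100L), band = c(3, 40)) {
  if (!is.matrix(xz_image)) stop("'xz_image' must be a 2-D matrix (z, x)")
  kx <- as.integer(kernel[1L]); kz <- as.integer(kernel[2L])
  nz <- nrow(xz_image); nx <- ncol(xz_image)
  if (nx < kx || nz < kz)
    stop(sprintf("image (%d x %d px) smaller than the kernel (%d x %d)",
                 nx, nz, kx, kz))
  filt <- dog_bandpass(xz_image, band[1L], band[2L])
  n_x <- nx %/% kx
  n_z <- nz %/% kz
  sds <- matrix(0, n_z, n_x)
  for (j in seq_len(n_x)) for (i in seq_len(n_z)) {
    win <- filt[(i - 1L) * kz + seq_len(kz), (j - 1L) * kx + seq_len(kx)]
    sds[i, j] <- stats::sd(as.numeric(win))
  }
  structure(list(window_x_centers = (seq_len(n_x) - 0.5) * kx,
                 sd_values = colMeans(sds),
                 boundaries_px = seq_len(n_x) * kx,
                 kernel = c(kx, kz), band = band),
            class = "focus_contrast_curve")
}

# difference-of-Gaussians band-pass: keeps structures between 'small' and
# 'large' pixels (sigma = size / 2); constant images map to (near) zero
dog_bandpass <- function(img, small, large) {
  s_small <- max(small / 2, 0.4)
  s_large <- large / 2
  lo <- ebimage_gblur(img, s_small)
  hi <- ebimage_gblur(img, s_large)
  lo - hi
}

# EBImage::gblur needs an odd kernel extent smaller than the image
ebimage_gblur <- function(img, sigma) {
  r <- min(ceiling(3 * sigma), nrow(img) %/% 2 - 1L, ncol(img) %/% 2 - 1L)
  r <- max(r, 1L)
  if (r %% 2L == 0L) r <- r - 1L
  as.matrix(EBImage::gblur(img, sigma = sigma, radius = r))
}

#' Find the focus-inversion x coordinate between two focus-shifted stacks
#'
#' Compares two focus-contrast curves on the same window grid and returns
#' the window boundary (in pixels from the left edge) where the sign of
#' `sd1 - sd2` changes, i.e. where focus quality inverts between the two
#' stacks. With several crossings, the one nearest the midpoint between the
#' two curves' maxima wins.
#'
#' @param curve1,curve2 [focus_contrast()] results on the same grid.
#' @return x_split in pixels: the number of columns to take from the first
#'   stack.
#' @export
find_inversion <- function(curve1, curve2) {
  stopifnot(inherits(curve1, "focus_contrast_curve"),
            inherits(curve2, "focus_contrast_curve"))
  if (!isTRUE(all.equal(curve1$window_x_centers, curve2$window_x_centers)))
    stop("curves are not on the same window grid")
  dif <- curve1$sd_values - curve2$sd_values
  n <- length(dif)
  s <- sign(dif)
  cross <- which(s[-n] * s[-1L] < 0 | (s[-n] != 0 & s[-1L] == 0))
  if (!length(cross))
    stop("no focus inversion found: the stacks are indistinguishable")
  mid <- (curve1$window_x_centers[which.max(curve1$sd_values)] +
          curve2$window_x_centers[which.max(curve2$sd_values)]) / 2
  bnd <- curve1$boundaries_px[cross]
  bnd[which.min(abs(bnd - mid))]
}

#' Combine two focus-shifted stacks at a tiling coordinate
#'
#' The fused stack takes the first stack left of the split and the second
#' right of it. In `"blend"` mode a linear ramp mixes the two across an
#' `overlap`-pixel band centred on `x_split`; `"hard"` reproduces a plain
#' side-by-side combine (columns `1..x_split` from the first stack, the
#' rest from the second).
#'
#' @param stack1,stack2 congruent [image_stack]s.
#' @param x_split split coordinate in pixels (columns taken from `stack1`).
#' @param overlap blend width in pixels (default 100).
#' @param mode `"blend"` or `"hard"`.
#' @return the fused [image_stack].
#' @export
combine_tiles <- function(stack1, stack2, x_split, overlap = 100L,
                          mode = c("blend", "hard")) {
  stopifnot(inherits(stack1, "image_stack"), inherits(stack2, "image_stack"))
  mode <- match.arg(mode)
  d <- dim(stack1$voxels)
  if (!identical(d, dim(stack2$voxels)))
    stop("stacks must be congruent in shape")
  nx <- d[3L]
  if (x_split < 1 || x_split >= nx)
    stop("'x_split' must lie inside the image width")
  if (mode == "hard") {
    out <- stack2$voxels
    out[, , seq_len(x_split)] <- stack1$voxels[, , seq_len(x_split)]
  } else {
    h <- overlap / 2
    if (x_split - h < 0 || x_split + h > nx)
      stop("the overlap band extends past the image edge")
    cols <- seq_len(nx)
    w <- pmin(pmax((x_split + h - (cols - 0.5)) / overlap, 0), 1)
    warr <- array(rep(w, each = d[1L] * d[2L]), d)
    out <- warr * stack1$voxels + (1 - warr) * stack2$voxels
  }
  image_stack(out, voxel_size = stack1$voxel_size,
              bit_depth = stack1$bit_depth)
}

#' Tiling light-sheet fusion of two or more focus-shifted stacks
#'
#' Pairwise left-to-right fusion: for each adjacent pair the x-z focus
#' contrast curves are computed, the inversion coordinate found, and the
#' stacks combined with a blended overlap. Stacks must be ordered by
#' increasing sheet focus position.
#'
#' @param stacks list of congruent [image_stack]s, left to right.
#' @param kernel,band see [focus_contrast()].
#' @param overlap blend width in pixels.
#' @param mode `"blend"` or `"hard"`.
#' @return list with `fused` ([image_stack]) and `x_splits` (integer vector,
#'   one per adjacent pair).
#' @export
tls_fuse <- function(stacks, kernel = c(50L, 100L), band = c(3, 40),
                     overlap = 100L, mode = "blend") {
  if (length(stacks) < 2L) stop("need at least two stacks to fuse")
  fused <- stacks[[1L]]
  splits <- integer(length(stacks) - 1L)
  for (i in seq_len(length(stacks) - 1L)) {
    c1 <- focus_contrast(reslice_xz(fused), kernel = kernel, band = band)
    c2 <- focus_contrast(reslice_xz(stacks[[i + 1L]]), kernel = kernel,
                         band = band)
    splits[i] <- find_inversion(c1, c2)
    fused <- combine_tiles(fused, stacks[[i + 1L]], splits[i],
                           overlap = overlap, mode = mode)
  }
  list(fused = fused, x_splits = splits)
}
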