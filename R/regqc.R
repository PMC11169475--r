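#' Normalized mutual information of two corresponding slices
#'
#' Entropies are computed in bits from the `bins x bins` joint histogram of
#' paired intensities (each image binned over its own value range, so the
#' score is invariant under affine intensity rescaling up to binning):
#' `MI = H(X) + H(Y) - H(X, Y)`, normalized as `MI / sqrt(H(X) * H(Y))`.
#' A slice with zero entropy (constant) makes the normalized score
#' undefined; both values are returned as `NA` with a warning.
#'
#' @param x,y congruent numeric matrices (or vectors) of intensities.
#' @param bins number of histogram bins per image (default 256, aligned to
#'   8-bit levels).
#' @return list with `mi` and `mi_normalized` (bits / dimensionless).
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' mutual_information(img, img)$mi_normalized  # 1
#' @export
mutual_information <- function(x, y, bins = 256L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || !length(x))
    stop("'x' and 'y' must be congruent and non-empty")
  bx <- bin_indices(x, bins)
  by <- bin_indices(y, bins)
  if (is.null(bx) || is.null(by)) {
    warning("constant slice: entropy is zero, normalized MI undefined")
    return(list(mi = NA_real_, mi_normalized = NA_real_))
  }
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins)
  p <- joint[joint > 0] / length(x)
  hxy <- -sum(p * log2(p))
  hx <- marginal_entropy(bx, bins, length(x))
  hy <- marginal_entropy(by, bins, length(y))
  mi <- hx + hy - hxy
  list(mi = mi, mi_normalized = mi / sqrt(hx * hy))
}

bin_indices <- function(v, bins) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(NULL)
  idx <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(as.integer(idx), bins)
}

marginal_entropy <- function(b, bins, n) {
  p <- tabulate(b, nbins = bins)
  p <- p[p > 0] / n
  -sum(p * log2(p))
}

#' Zero-mean normalized cross-correlation of two slices
#'
#' `sum((X - mX)(Y - mY)) / sqrt(sum((X - mX)^2) * sum((Y - mY)^2))`,
#' in `[-1, 1]`, with 1 for identical (up to positive affine rescaling)
#' slices and -1 for inverted ones.
#'
#' @param x,y congruent numeric matrices (or vectors), each with nonzero
#'   variance.
#' @return the correlation, dimensionless.
#' @export
zncc <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || !length(x))
    stop("'x' and 'y' must be congruent and non-empty")
  xc <- x - mean(x); yc <- y - mean(y)
  vx <- sum(xc^2); vy <- sum(yc^2)
  if (vx == 0 || vy == 0) stop("zero-variance slice: ZNCC undefined")
  sum(xc * yc) / sqrt(vx * vy)
}

#' Per-slice registration quality profile of two stacks
#'
#' Computes normalized MI and ZNCC for every corresponding z-slice of two
#' congruent stacks. Constant (degenerate) slices are flagged and excluded
#' from the summary means.
#'
#' @param stack_a,stack_b congruent [image_stack]s.
#' @param bins histogram bins for [mutual_information()].
#' @return an object of class `"regqc_profile"`: data frame with columns
#'   `z`, `mi`, `mi_normalized`, `zncc`, `degenerate`; summary means in
#'   attributes `mean_mi_normalized` and `mean_zncc`.
#' @export
metric_profile <- function(stack_a, stack_b, bins = 256L) {
  stopifnot(inherits(stack_a, "image_stack"), inherits(stack_b, "image_stack"))
  if (!identical(dim(stack_a$voxels), dim(stack_b$voxels)))
    stop("stacks must be congruent")
  nz <- dim(stack_a$voxels)[1L]
  out <- data.frame(z = seq_len(nz), mi = NA_real_, mi_normalized = NA_real_,
                    zncc = NA_real_, degenerate = FALSE)
  for (z in seq_len(nz)) {
    a <- stack_a$voxels[z, , ]; b <- stack_b$voxels[z, , ]
    if (stats::var(as.numeric(a)) == 0 || stats::var(as.numeric(b)) == 0) {
      out$degenerate[z] <- TRUE
      next
    }
    m <- suppressWarnings(mutual_information(a, b, bins = bins))
    out$mi[z] <- m$mi
    out$mi_normalized[z] <- m$mi_normalized
    out$zncc[z] <- zncc(a, b)
  }
  ok <- !out$degenerate
  attr(out, "mean_mi_normalized") <- mean(out$mi_normalized[ok])
  attr(out, "mean_zncc") <- mean(out$zncc[ok])
  class(out) <- c("regqc_profile", "data.frame")
  out
}

#' Estimate and correct an integer z shift between replicate stacks
#'
#' Replicate acquisitions of the same volume can start a few slices apart;
#' `estimate_z_shift()` returns the integer slice shift `s` of `stack_b`
#' relative to `stack_a` maximizing the mean ZNCC over the overlapping
#' slices, with the convention `b[z] ~ a[z - s]`: a phantom delayed by +3
#' slices yields 3. Ties go to the smallest absolute shift. The best score
#' is attached so callers can gate on it; even an anti-correlated best
#' match is returned.
#'
#' @param stack_a,stack_b congruent [image_stack]s.
#' @param max_shift largest absolute shift to scan, slices.
#' @return integer shift with attribute `score` (mean ZNCC at the optimum).
#' @export
estimate_z_shift <- function(stack_a, stack_b, max_shift = 10L) {
  stopifnot(inherits(stack_a, "image_stack"), inherits(stack_b, "image_stack"))
  if (!identical(dim(stack_a$voxels), dim(stack_b$voxels)))
    stop("stacks must be congruent")
  nz <- dim(stack_a$voxels)[1L]
  max_shift <- as.integer(max_shift)
  if (max_shift >= nz) stop("'max_shift' must be smaller than the stack depth")
  shifts <- -max_shift:max_shift
  scores <- vapply(shifts, function(s) {
    # b[z] ~ a[z - s]: compare a[z] with b[z + s] over the overlap
    za <- seq_len(nz)
    ok <- za + s >= 1L & za + s <= nz
    if (!any(ok)) return(NA_real_)
    vals <- vapply(za[ok], function(z) {
      tryCatch(zncc(stack_a$voxels[z, , ], stack_b$voxels[z + s, , ]),
               error = function(e) NA_real_)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(scores))) stop("no usable overlap at any shift")
  best <- max(scores, na.rm = TRUE)
  cand <- shifts[!is.na(scores) & scores >= best - 1e-12]
  shift <- cand[order(abs(cand), cand)][1L]
  structure(shift, score = best)
}

#' @rdname estimate_z_shift
#' @param shift integer shift as returned by `estimate_z_shift()`.
#' @return `apply_z_shift()`: `stack_b` realigned to `stack_a`'s frame
#'   (`aligned[z] = b[z + shift]`); slices shifted in are zero-filled, the
#'   depth is preserved.
#' @export
apply_z_shift <- function(stack_b, shift) {
  stopifnot(inherits(stack_b, "image_stack"))
  shift <- as.integer(shift)
  d <- dim(stack_b$voxels)
  out <- array(0, d)
  src <- seq_len(d[1L]) + shift
  ok <- src >= 1L & src <= d[1L]
  out[which(ok), , ] <- stack_b$voxels[src[ok], , ]
  image_stack(out, voxel_size = stack_b$voxel_size,
              bit_depth = stack_b$bit_depth)
}
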