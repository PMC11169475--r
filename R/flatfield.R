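#' Fit a y-axis flat-field model from a dye-solution reference image
#'
#' The one-sided sheet illumination falls off along y. A reference image of
#' a homogeneous dye solution captures that fall-off: the per-row medians
#' `m(y)` are taken (the median itself suppresses reference noise) and
#' turned into multiplicative gain coefficients `c(y) = max(m) / m(y)`,
#' so the peak row has coefficient 1 and every other row is lifted to it.
#'
#' @param reference numeric matrix `(y, x)`, the dye-solution image.
#' @param smooth optional odd window length for a running-median smoothing
#'   of the coefficient profile (`NULL`, the default, applies none).
#' @return an object of class `"flatfield_model"`: list with
#'   `median_profile` and `coefficients`, both of length `nrow(reference)`.
#' @examples
#' ref <- gen_illumination_profile(c(64, 32), sigma_y = 20)
#' m <- fit_flatfield(ref)
#' range(m$coefficients)
#' @export
fit_flatfield <- function(reference, smooth = NULL) {
  if (!is.matrix(reference)) stop("'reference' must be a 2-D matrix (y, x)")
  med <- apply(reference, 1L, stats::median)
  if (max(med) <= 0) stop("degenerate reference: no positive row median")
  zero <- which(med <= 0)
  if (length(zero))
    stop(sprintf("row median is zero at row %d; coefficient undefined",
                 zero[1L]))
  coef <- max(med) / med
  if (!is.null(smooth)) coef <- stats::runmed(coef, smooth)
  structure(list(median_profile = med, coefficients = as.numeric(coef)),
            class = "flatfield_model")
}

#' @export
print.flatfield_model <- function(x, ...) {
  cat(sprintf("flatfield_model: %d rows, coefficients in [%.4g, %.4g]\n",
              length(x$coefficients), min(x$coefficients),
              max(x$coefficients)))
  invisible(x)
}

#' Apply a flat-field model to a stack
#'
#' Every voxel in row y is multiplied by the model's coefficient `c(y)`;
#' z and x are untouched. The result is clamped to the stack's bit-depth
#' range (clamping, not rescaling, preserves the 8-bit contract).
#'
#' @param stack an [image_stack] whose y extent matches the model.
#' @param model a [fit_flatfield()] result.
#' @return the corrected [image_stack].
#' @export
apply_flatfield <- function(stack, model) {
  stopifnot(inherits(stack, "image_stack"), inherits(model, "flatfield_model"))
  d <- dim(stack$voxels)
  if (d[2L] != length(model$coefficients))
    stop(sprintf("stack height (%d) does not match model length (%d)",
                 d[2L], length(model$coefficients)))
  gain <- array(rep(model$coefficients, each = d[1L]), d)
  out <- clamp_to_depth(stack$voxels * gain, stack$bit_depth)
  image_stack(array(out, d), voxel_size = stack$voxel_size,
              bit_depth = stack$bit_depth)
}
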