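#' Virtual H&E color model
#'
#' Beer-Lambert false coloring maps a nuclear-stain channel and a
#' general-protein channel to the purple/pink appearance of
#' hematoxylin-eosin histology: each channel attenuates a white background
#' exponentially with per-color absorption coefficients. The default
#' triplets are the published virtual-H&E literature values
#' (hematoxylin-like `(0.860, 1.000, 0.300)`, eosin-like
#' `(0.050, 1.000, 0.544)` for R, G, B); substitute measured values as
#' needed.
#'
#' @param k_nuclear,k_cytoplasm RGB absorption triplets, all `>= 0`.
#' @param background RGB white level in `[0, 1]`.
#' @param gain_nuclear,gain_cytoplasm scalar exposure gains.
#' @return an object of class `"he_color_model"`.
#' @export
he_color_model <- function(k_nuclear = c(0.860, 1.000, 0.300),
                           k_cytoplasm = c(0.050, 1.000, 0.544),
                           background = c(1, 1, 1),
                           gain_nuclear = 1, gain_cytoplasm = 1) {
  stopifnot(length(k_nuclear) == 3L, length(k_cytoplasm) == 3L,
            all(k_nuclear >= 0), all(k_cytoplasm >= 0),
            length(background) == 3L, all(background >= 0),
            all(background <= 1), gain_nuclear >= 0, gain_cytoplasm >= 0)
  structure(list(k_nuclear = k_nuclear, k_cytoplasm = k_cytoplasm,
                 background = background, gain_nuclear = gain_nuclear,
                 gain_cytoplasm = gain_cytoplasm),
            class = "he_color_model")
}

#' Render a two-channel stack as virtual H&E
#'
#' Per voxel and color channel c:
#' `RGB_c = background_c * exp(-k_nuclear_c * g_n * I_n - k_cytoplasm_c *
#' g_p * I_p)` with intensities normalized to `[0, 1]` by the stack bit
#' depth. Zero input gives the pure white background; output is monotone
#' non-increasing in each input intensity, and the two channels compose
#' multiplicatively (Beer-Lambert).
#'
#' @param nuclear,protein congruent [image_stack]s (nuclear stain and
#'   general-protein stain).
#' @param model an [he_color_model()].
#' @return numeric 4-D array `(z, y, x, rgb)` with values in `[0, 1]`.
#' @export
render_he <- function(nuclear, protein, model = he_color_model()) {
  stopifnot(inherits(nuclear, "image_stack"), inherits(protein, "image_stack"),
            inherits(model, "he_color_model"))
  d <- dim(nuclear$voxels)
  if (!identical(d, dim(protein$voxels)))
    stop("nuclear and protein stacks must be congruent")
  i_n <- nuclear$voxels / (2^nuclear$bit_depth - 1)
  i_p <- protein$voxels / (2^protein$bit_depth - 1)
  out <- array(0, c(d, 3L))
  for (c3 in 1:3) {
    out[, , , c3] <- model$background[c3] *
      exp(-model$k_nuclear[c3] * model$gain_nuclear * i_n -
            model$k_cytoplasm[c3] * model$gain_cytoplasm * i_p)
  }
  out
}
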