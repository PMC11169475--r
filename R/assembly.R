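#' Concatenate split movie files
#'
#' Camera software commonly splits a long time-lapse into ~1 GB parts;
#' this re-joins them in list order. All parts must agree in frame shape,
#' bit depth and exposure.
#'
#' @param parts list of [movie_stack] objects, in acquisition order.
#' @return a single [movie_stack] with `sum` of the frame counts.
#' @export
concat_movie_parts <- function(parts) {
  if (!length(parts)) stop("'parts' must contain at least one movie")
  lapply(parts, function(p) if (!inherits(p, "movie_stack"))
    stop("all parts must be movie_stack objects"))
  ref <- parts[[1L]]
  ref_shape <- dim(ref$frames)[2:3]
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (!identical(dim(p$frames)[2:3], ref_shape))
      stop(sprintf("part %d frame shape (%s) differs from part 1 (%s)",
                   i, paste(dim(p$frames)[2:3], collapse = "x"),
                   paste(ref_shape, collapse = "x")))
    if (p$bit_depth != ref$bit_depth)
      stop(sprintf("part %d bit depth (%d) differs from part 1 (%d)",
                   i, p$bit_depth, ref$bit_depth))
    if (!isTRUE(all.equal(p$exposure, ref$exposure)))
      stop(sprintf("part %d exposure (%g) differs from part 1 (%g)",
                   i, p$exposure, ref$exposure))
  }
  total <- sum(vapply(parts, function(p) dim(p$frames)[1L], integer(1)))
  out <- array(0, c(total, ref_shape))
  at <- 0L
  for (p in parts) {
    nt <- dim(p$frames)[1L]
    out[at + seq_len(nt), , ] <- p$frames
    at <- at + nt
  }
  movie_stack(out, exposure = ref$exposure, bit_depth = ref$bit_depth,
              source_files = unlist(lapply(parts, `[[`, "source_files")))
}

#' Convert a time-lapse movie to a z-stack
#'
#' Re-indexes the frames of a synchronised continuous-scan movie as
#' z-slices. No resampling takes place: pixel values are carried over
#' bit-exactly, frame t becomes slice z = t, and the axial voxel size is
#' the plan's z-interval.
#'
#' @param movie a [movie_stack].
#' @param plan an `acquisition_plan` from [plan_acquisition()]; its exposure
#'   must match the movie's.
#' @param pixel_size camera pixel size in um (applied to both y and x).
#' @return an [image_stack] with `voxel_size = c(z_interval, pixel_size,
#'   pixel_size)`.
#' @export
movie_to_stack <- function(movie, plan, pixel_size = 3.45) {
  stopifnot(inherits(movie, "movie_stack"), inherits(plan, "acquisition_plan"))
  if (!isTRUE(all.equal(movie$exposure, plan$exposure)))
    stop(sprintf("movie exposure (%g s) does not match plan exposure (%g s)",
                 movie$exposure, plan$exposure))
  image_stack(movie$frames,
              voxel_size = c(plan$z_interval, pixel_size, pixel_size),
              bit_depth = movie$bit_depth)
}

#' Orient an opposite-direction stack to match a reference stack
#'
#' A stack acquired after rotating the sample by 180 degrees is brought
#' into the reference frame by reversing the z order and mirroring x
#' (the "Flip Z" + "Flip Horizontally" convention). The operation is an
#' involution: applying it twice returns the original stack bit-exactly.
#'
#' @param stack an [image_stack].
#' @return the re-oriented [image_stack]; voxel sizes unchanged.
#' @export
orient_opposite_view <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  out <- stack$voxels[rev(seq_len(d[1L])), , rev(seq_len(d[3L])), drop = FALSE]
  image_stack(out, voxel_size = stack$voxel_size, bit_depth = stack$bit_depth)
}

#' Downsize a stack for registration
#'
#' Registration of large stacks is run on reduced data: xy is scaled by a
#' block-mean (area) factor of 0.5 or 0.25 and z is subsampled keeping one
#' slice in every `z_keep_every` (slices 1, 1+k, 1+2k, ...). Voxel sizes
#' are updated accordingly. Trailing rows/columns that do not fill a block
#' are dropped.
#'
#' @param stack an [image_stack].
#' @param xy_factor 0.5, 0.25 or 1 (no xy scaling).
#' @param z_keep_every keep every k-th slice, `>= 1`.
#' @return the downsized [image_stack].
#' @export
downsize_for_registration <- function(stack, xy_factor = 0.5, z_keep_every = 4L) {
  stopifnot(inherits(stack, "image_stack"))
  if (!xy_factor %in% c(1, 0.5, 0.25))
    stop("'xy_factor' must be 1, 0.5 or 0.25")
  z_keep_every <- as.integer(z_keep_every)
  if (z_keep_every < 1L) stop("'z_keep_every' must be >= 1")
  d <- dim(stack$voxels)
  block <- as.integer(round(1 / xy_factor))
  ny <- d[2L] %/% block
  nx <- d[3L] %/% block
  zi <- seq.int(1L, d[1L], by = z_keep_every)
  if (ny < 1L || nx < 1L || !length(zi))
    stop("downsizing would produce a degenerate (empty) stack")
  vox <- stack$voxels[zi, seq_len(ny * block), seq_len(nx * block), drop = FALSE]
  if (block > 1L) {
    # block mean over (block x block) xy tiles, per slice
    dv <- dim(vox)
    dim(vox) <- c(dv[1L], block, ny, block, nx)
    vox <- apply(vox, c(1L, 3L, 5L), mean)
  }
  image_stack(array(vox, c(length(zi), ny, nx)),
              voxel_size = stack$voxel_size * c(z_keep_every, block, block),
              bit_depth = stack$bit_depth)
}
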