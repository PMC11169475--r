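#' Image and movie stack containers
#'
#' `image_stack()` wraps a 3-D voxel array indexed `(z, y, x)` together with
#' its physical voxel size in micrometres and a nominal bit depth.
#' `movie_stack()` wraps a time-ordered frame sequence indexed `(t, y, x)`
#' with the camera exposure time. These two containers are the currency of
#' the whole toolkit: every operation consumes and returns one of them.
#'
#' @param voxels numeric 3-D array, dimensions `(z, y, x)`.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in micrometres, all > 0.
#' @param bit_depth one of 8, 12, 16. Values are expected (but not forced)
#'   to lie in `[0, 2^bit_depth - 1]`; arithmetic that can overflow clamps.
#' @return an object of class `"image_stack"`.
#' @examples
#' s <- image_stack(array(0, c(4, 8, 8)), voxel_size = c(10, 3.45, 3.45))
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, voxel_size = c(1, 1, 1), bit_depth = 8) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array indexed (z, y, x)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive numbers (dz, dy, dx) in um")
  if (!bit_depth %in% c(8, 12, 16))
    stop("'bit_depth' must be 8, 12 or 16")
  structure(list(voxels = voxels, voxel_size = voxel_size, bit_depth = bit_depth),
            class = "image_stack")
}

#' @rdname image_stack
#' @param frames numeric 3-D array, dimensions `(t, y, x)`.
#' @param exposure exposure time per frame in seconds.
#' @param source_files optional character vector of originating file names.
#' @export
movie_stack <- function(frames, exposure, bit_depth = 8, source_files = character()) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a 3-D array indexed (t, y, x)")
  if (dim(frames)[1L] < 1L) stop("movie must contain at least one frame")
  exposure <- as.numeric(exposure)
  if (length(exposure) != 1L || !is.finite(exposure) || exposure <= 0)
    stop("'exposure' must be a single positive number (seconds)")
  if (!bit_depth %in% c(8, 12, 16))
    stop("'bit_depth' must be 8, 12 or 16")
  structure(list(frames = frames, exposure = exposure, bit_depth = bit_depth,
                 source_files = as.character(source_files)),
            class = "movie_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel size: %.4g x %.4g x %.4g um (dz, dy, dx)\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  bit depth: %d-bit, intensity range [%.4g, %.4g]\n",
              x$bit_depth, min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack: %d frames of %d x %d px (t, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  exposure: %.4g s, bit depth: %d-bit\n", x$exposure, x$bit_depth))
  if (length(x$source_files))
    cat("  sources:", paste(x$source_files, collapse = ", "), "\n")
  invisible(x)
}

clamp_to_depth <- function(v, bit_depth) {
  pmin(pmax(v, 0), 2^bit_depth - 1)
}

#' Read and write image stacks as multi-page TIFF
#'
#' Pages are z-slices; pixel values are rescaled from the TIFF unit interval
#' to `[0, 2^bit_depth - 1]` on read and back on write. A JSON sidecar
#' (`<path>.json`) carries the voxel size and bit depth, which plain TIFF
#' does not preserve; `read_stack()` uses it when present.
#'
#' @param path TIFF file path.
#' @param voxel_size,bit_depth used when no sidecar exists (read) or recorded
#'   into the sidecar (write).
#' @return `read_stack()`: an [image_stack]. `write_stack()`: `path`, invisibly.
#' @export
read_stack <- function(path, voxel_size = c(1, 1, 1), bit_depth = 8) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size)) voxel_size <- as.numeric(meta$voxel_size)
    if (!is.null(meta$bit_depth)) bit_depth <- as.integer(meta$bit_depth)
  }
  d <- dim(pages[[1L]])
  vox <- array(0, c(length(pages), d[1L], d[2L]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  vox <- round(vox * (2^bit_depth - 1))
  image_stack(vox, voxel_size = voxel_size, bit_depth = bit_depth)
}

#' @rdname read_stack
#' @param stack an [image_stack].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(dim(stack$voxels)[1L]), function(i) {
    m <- stack$voxels[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(stack$voxels)[2L])
    pmin(pmax(m / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = if (stack$bit_depth == 8) 8L else 16L)
  jsonlite::write_json(list(voxel_size = stack$voxel_size, bit_depth = stack$bit_depth),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
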