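#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image by a
#' ball structuring element of the given radius (erosion then dilation
#' with heights `sqrt(r^2 - d^2)`) and subtracts it. Broad smooth
#' background is removed while features narrower than the ball survive.
#' The output is non-negative.
#'
#' @param image numeric matrix `(y, x)`.
#' @param radius ball radius in pixels, `>= 1`.
#' @return background-subtracted matrix of the same shape.
#' @export
subtract_background <- function(image, radius = 4L) {
  if (!is.matrix(image)) stop("'image' must be a 2-D matrix")
  radius <- as.integer(radius)
  if (radius < 1L) stop("'radius' must be >= 1")
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  keep <- offs$dy^2 + offs$dx^2 <= radius^2
  offs <- offs[keep, ]
  height <- sqrt(radius^2 - offs$dy^2 - offs$dx^2)
  eroded <- sweep_extremum(image, offs$dy, offs$dx, -height, min_op = TRUE)
  opened <- sweep_extremum(eroded, offs$dy, offs$dx, height, min_op = FALSE)
  pmax(image - opened, 0)
}

# grayscale erosion (min_op) or dilation over a set of offsets with
# per-offset additive heights; out-of-image samples are ignored
sweep_extremum <- function(m, dys, dxs, heights, min_op) {
  ny <- nrow(m); nx <- ncol(m)
  acc <- matrix(if (min_op) Inf else -Inf, ny, nx)
  for (k in seq_along(dys)) {
    dy <- dys[k]; dx <- dxs[k]
    ys <- max(1L, 1L - dy):min(ny, ny - dy)
    xs <- max(1L, 1L - dx):min(nx, nx - dx)
    sub <- m[ys + dy, xs + dx, drop = FALSE] + heights[k]
    if (min_op) acc[ys, xs] <- pmin(acc[ys, xs], sub)
    else acc[ys, xs] <- pmax(acc[ys, xs], sub)
  }
  acc
}

#' Grouped maximum intensity projections
#'
#' Splits the stack into consecutive non-overlapping groups of `group`
#' slices (a trailing partial group is kept) and takes the per-pixel
#' maximum of each group.
#'
#' @param stack an [image_stack].
#' @param group slices per projection (default 10).
#' @return list of numeric matrices `(y, x)`, one per group.
#' @export
grouped_mip <- function(stack, group = 10L) {
  stopifnot(inherits(stack, "image_stack"))
  group <- as.integer(group)
  if (group < 1L) stop("'group' must be >= 1")
  nz <- dim(stack$voxels)[1L]
  starts <- seq.int(1L, nz, by = group)
  lapply(starts, function(s) {
    zi <- s:min(s + group - 1L, nz)
    apply(stack$voxels[zi, , , drop = FALSE], c(2L, 3L), max)
  })
}

#' Otsu threshold from one reference slice, applied globally
#'
#' The threshold maximizing the between-class variance of the reference
#' MIP's intensity histogram is computed once and applied to every MIP,
#' so all slices of a channel share a single binarization threshold.
#' Pixels strictly above the threshold are foreground.
#'
#' @param mips list of numeric matrices (e.g. from [grouped_mip()]).
#' @param reference_index which MIP to compute the threshold on (the
#'   central slice of the volume is customary).
#' @param levels number of histogram levels (256 for 8-bit data).
#' @return list with `threshold` (on the 0..levels-1 scale) and `masks`
#'   (list of 0/1 integer matrices).
#' @export
otsu_global_threshold <- function(mips, reference_index, levels = 256L) {
  if (!length(mips)) stop("'mips' is empty")
  if (reference_index < 1L || reference_index > length(mips))
    stop("'reference_index' out of range")
  ref <- mips[[reference_index]]
  if (diff(range(ref)) == 0)
    stop("reference slice is constant; Otsu threshold undefined")
  thr <- otsu_threshold(ref, levels = levels)
  masks <- lapply(mips, function(m)
    matrix(as.integer(m > thr), nrow(m), ncol(m)))
  list(threshold = thr, masks = masks)
}

#' @rdname otsu_global_threshold
#' @param image a single numeric matrix with values in `[0, levels - 1]`.
#' @return `otsu_threshold()`: the scalar threshold; values `> threshold`
#'   are foreground.
#' @export
otsu_threshold <- function(image, levels = 256L) {
  v <- pmin(pmax(round(as.numeric(image)), 0), levels - 1L)
  h <- tabulate(v + 1L, nbins = levels)
  p <- h / sum(h)
  lev <- 0:(levels - 1L)
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[levels]
  # between-class variance for cut after level t (classes <=t, >t)
  w1 <- 1 - w0
  bcv <- ifelse(w0 > 0 & w1 > 0, (mu_t * w0 - mu)^2 / (w0 * w1), -Inf)
  bcv <- bcv[-levels]
  lev[which.max(bcv)]
}

# outer-boundary pixels of a binary mask: foreground pixels with at least
# one 4-neighbour outside the mask (image border counts as outside)
mask_contour <- function(mask) {
  m <- mask > 0
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  inner <- pad[2:(ny + 1L), 2:(nx + 1L)]
  core <- inner &
    pad[1:ny, 2:(nx + 1L)] & pad[3:(ny + 2L), 2:(nx + 1L)] &
    pad[2:(ny + 1L), 1:nx] & pad[2:(ny + 1L), 3:(nx + 2L)]
  which(inner & !core, arr.ind = TRUE)
}

# 8-connected component labelling (BFS on pixel offsets)
label_components <- function(mask) {
  m <- mask > 0
  ny <- nrow(m); nx <- ncol(m)
  lab <- matrix(0L, ny, nx)
  nb <- expand.grid(dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dy == 0 & nb$dx == 0), ]
  cur <- 0L
  todo <- which(m & lab == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    queue <- todo[1L]
    lab[queue] <- cur
    while (length(queue)) {
      yx <- arrayInd(queue, c(ny, nx))
      nxt <- integer(0)
      for (k in seq_len(nrow(nb))) {
        yy <- yx[, 1L] + nb$dy[k]
        xx <- yx[, 2L] + nb$dx[k]
        ok <- yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
        lin <- (xx[ok] - 1L) * ny + yy[ok]
        lin <- lin[m[lin] & lab[lin] == 0L]
        if (length(lin)) {
          lab[lin] <- cur
          nxt <- c(nxt, lin)
        }
      }
      queue <- unique(nxt)
    }
    todo <- which(m & lab == 0L)
  }
  lab
}

#' Drug-to-vessel distances on one binarized slice pair
#'
#' For every point on the drug-distribution contour the nearest point on
#' the vessel contour is found with a kd-tree. The straight segment
#' between the two, rasterized with Bresenham, must lie entirely inside
#' the drug mask or the line is omitted (it would cross tissue the drug
#' never reached). Valid distances are then grouped by their vessel point
#' - several drug-contour points may share one nearest vessel point - and
#' averaged, giving one mean distance per vessel point.
#'
#' @param vessel_mask,drug_mask congruent 0/1 matrices.
#' @param pixel_size pixel pitch in um.
#' @return an object of class `"distance_table"`: data frame with columns
#'   `vessel_y`, `vessel_x`, `mean_distance_um`, `n_drug_points`; the
#'   per-drug-point measurements (including omitted lines) are in
#'   attribute `"per_point"`. Empty drug mask gives an empty table; empty
#'   vessel mask flags every drug point invalid.
#' @export
drug_vessel_distances <- function(vessel_mask, drug_mask, pixel_size = 3.45) {
  if (!identical(dim(vessel_mask), dim(drug_mask)))
    stop("masks must be congruent")
  empty <- function(per_point = NULL) {
    out <- data.frame(vessel_y = integer(0), vessel_x = integer(0),
                      mean_distance_um = numeric(0),
                      n_drug_points = integer(0))
    attr(out, "per_point") <- per_point
    class(out) <- c("distance_table", "data.frame")
    out
  }
  drug_pts <- mask_contour(drug_mask)
  if (!nrow(drug_pts)) return(empty())
  vessel_pts <- mask_contour(vessel_mask)
  if (!nrow(vessel_pts)) {
    pp <- data.frame(drug_y = drug_pts[, 1L], drug_x = drug_pts[, 2L],
                     vessel_index = NA_integer_, distance_um = NA_real_,
                     valid = FALSE)
    warning("empty vessel mask: no nearest-neighbour target, all lines invalid")
    return(empty(pp))
  }
  tree <- kdtree_build(vessel_pts)
  n <- nrow(drug_pts)
  vi <- integer(n)
  dist_px <- numeric(n)
  valid <- logical(n)
  drug_fg <- drug_mask > 0
  for (i in seq_len(n)) {
    nn <- kdtree_nearest(tree, drug_pts[i, ])
    vi[i] <- nn$index
    dist_px[i] <- sqrt(nn$dist2)
    seg <- bresenham_line(drug_pts[i, 1L], drug_pts[i, 2L],
                          vessel_pts[nn$index, 1L], vessel_pts[nn$index, 2L])
    valid[i] <- all(drug_fg[seg])
  }
  per_point <- data.frame(drug_y = drug_pts[, 1L], drug_x = drug_pts[, 2L],
                          vessel_index = vi,
                          distance_um = dist_px * pixel_size,
                          valid = valid)
  if (!any(valid)) return(empty(per_point))
  agg <- stats::aggregate(distance_um ~ vessel_index,
                          data = per_point[per_point$valid, ], FUN = mean)
  cnt <- table(per_point$vessel_index[per_point$valid])
  out <- data.frame(
    vessel_y = vessel_pts[agg$vessel_index, 1L],
    vessel_x = vessel_pts[agg$vessel_index, 2L],
    mean_distance_um = agg$distance_um,
    n_drug_points = as.integer(cnt[as.character(agg$vessel_index)]))
  attr(out, "per_point") <- per_point
  class(out) <- c("distance_table", "data.frame")
  out
}

#' Summarize per-slice distance tables
#'
#' Pools the per-vessel-point mean distances of several slices: per-slice
#' boxplot statistics (quartiles and whiskers), a pooled histogram, and
#' the pooled 95th percentile (linear interpolation).
#'
#' @param tables list of [drug_vessel_distances()] results (one per MIP
#'   slice), or a single `distance_table`.
#' @param breaks histogram breaks passed to [hist()] (default
#'   `"Sturges"`).
#' @return list with `per_slice` (data frame of boxplot stats), `pooled`
#'   (all distances, um), `histogram` (a [hist()] object, not plotted) and
#'   `percentile_95` (um).
#' @export
summarize_distances <- function(tables, breaks = "Sturges") {
  if (inherits(tables, "distance_table")) tables <- list(tables)
  dists <- lapply(tables, function(tb) tb$mean_distance_um)
  pooled <- unlist(dists)
  if (!length(pooled)) stop("no valid distance records to summarize")
  per_slice <- do.call(rbind, lapply(seq_along(dists), function(i) {
    d <- dists[[i]]
    if (!length(d)) return(NULL)
    bs <- grDevices::boxplot.stats(d)
    data.frame(slice = i, n = length(d),
               whisker_low = bs$stats[1L], q1 = bs$stats[2L],
               median = bs$stats[3L], q3 = bs$stats[4L],
               whisker_high = bs$stats[5L])
  }))
  list(per_slice = per_slice,
       pooled = pooled,
       histogram = graphics::hist(pooled, breaks = breaks, plot = FALSE),
       percentile_95 = unname(stats::quantile(pooled, 0.95, type = 7)))
}

#' Classify vessels as drug-associating or not
#'
#' Labels the 8-connected components of the vessel mask and marks a
#' component "associating" when it overlaps the drug mask in at least one
#' pixel.
#'
#' @param vessel_mask,drug_mask congruent 0/1 matrices.
#' @return data frame with columns `component`, `n_pixels`,
#'   `overlap_pixels`, `associating`; the label matrix is in attribute
#'   `"labels"`.
#' @export
classify_vessels <- function(vessel_mask, drug_mask) {
  if (!identical(dim(vessel_mask), dim(drug_mask)))
    stop("masks must be congruent")
  lab <- label_components(vessel_mask)
  ncomp <- max(lab)
  out <- data.frame(component = seq_len(ncomp),
                    n_pixels = NA_integer_,
                    overlap_pixels = NA_integer_,
                    associating = NA)
  for (k in seq_len(ncomp)) {
    px <- lab == k
    out$n_pixels[k] <- sum(px)
    out$overlap_pixels[k] <- sum(px & drug_mask > 0)
    out$associating[k] <- out$overlap_pixels[k] >= 1L
  }
  attr(out, "labels") <- lab
  out
}
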