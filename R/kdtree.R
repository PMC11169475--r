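# Static 2-D kd-tree for exact nearest-neighbour queries on pixel
# coordinate sets. Median splits on alternating axes; queries prune with
# squared distances and break exact ties deterministically toward the
# lowest point index, matching an all-pairs scan on integer coordinates.

kdtree_build <- function(pts) {
  if (!is.matrix(pts) || ncol(pts) != 2L || !nrow(pts))
    stop("'pts' must be a non-empty n x 2 matrix")
  n <- nrow(pts)
  node_pt <- integer(n); node_axis <- integer(n)
  node_left <- integer(n); node_right <- integer(n)
  cnt <- 0L
  build <- function(idx, depth) {
    if (!length(idx)) return(0L)
    ax <- depth %% 2L + 1L
    ord <- idx[order(pts[idx, ax], idx)]
    m <- (length(ord) + 1L) %/% 2L
    cnt <<- cnt + 1L
    me <- cnt
    node_pt[me] <<- ord[m]
    node_axis[me] <<- ax
    node_left[me] <<- build(ord[seq_len(m - 1L)], depth + 1L)
    node_right[me] <<- build(ord[m + seq_len(length(ord) - m)], depth + 1L)
    me
  }
  root <- build(seq_len(n), 0L)
  structure(list(pts = pts, pt = node_pt, axis = node_axis,
                 left = node_left, right = node_right, root = root),
            class = "kdtree2d")
}

kdtree_nearest <- function(tree, q) {
  pts <- tree$pts
  best_d <- Inf
  best_i <- 0L
  rec <- function(node) {
    if (node == 0L) return(invisible(NULL))
    i <- tree$pt[node]
    d <- (pts[i, 1L] - q[1L])^2 + (pts[i, 2L] - q[2L])^2
    if (d < best_d || (d == best_d && i < best_i)) {
      best_d <<- d
      best_i <<- i
    }
    ax <- tree$axis[node]
    dif <- q[ax] - pts[i, ax]
    if (dif < 0) {
      rec(tree$left[node])
      if (dif^2 <= best_d) rec(tree$right[node])
    } else {
      rec(tree$right[node])
      if (dif^2 <= best_d) rec(tree$left[node])
    }
    invisible(NULL)
  }
  rec(tree$root)
  list(index = best_i, dist2 = unname(best_d))
}

#' Bresenham rasterization of a pixel-to-pixel segment
#'
#' Integer line rasterization between two pixel centres, endpoints
#' included; used to test whether a distance line stays inside a mask.
#'
#' @param y0,x0,y1,x1 integer pixel coordinates (row, column).
#' @return integer matrix with columns `(row, col)` covering the segment.
#' @export
bresenham_line <- function(y0, x0, y1, x1) {
  y0 <- as.integer(round(y0)); x0 <- as.integer(round(x0))
  y1 <- as.integer(round(y1)); x1 <- as.integer(round(x1))
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  n <- dx + dy + 1L
  out <- matrix(0L, n, 2L)
  k <- 0L
  repeat {
    k <- k + 1L
    out[k, ] <- c(y0, x0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; y0 <- y0 + sy }
  }
  out[seq_len(k), , drop = FALSE]
}
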