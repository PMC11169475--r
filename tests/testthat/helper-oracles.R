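# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain enumeration and closed forms only.

# mutual information (bits) by direct enumeration of the joint value
# distribution - no histogram binning
oracle_mi <- function(x, y) {
  x <- as.vector(x); y <- as.vector(y)
  n <- length(x)
  joint <- table(paste(x, y, sep = "|")) / n
  px <- table(x) / n
  py <- table(y) / n
  ent <- function(p) -sum(p * log2(p))
  list(mi = ent(px) + ent(py) - ent(joint),
       mi_normalized = (ent(px) + ent(py) - ent(joint)) /
         sqrt(ent(px) * ent(py)))
}

# exhaustive between-class variance search over all integer cut points
oracle_otsu <- function(image, levels = 256L) {
  v <- pmin(pmax(round(as.vector(image)), 0), levels - 1L)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:(levels - 2L)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    bc <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bc > best_v) { best_v <- bc; best_t <- t }
  }
  best_t
}

# all-pairs nearest neighbour with lowest-index tie break, squared ints
oracle_nn <- function(targets, query) {
  d2 <- (targets[, 1L] - query[1L])^2 + (targets[, 2L] - query[2L])^2
  i <- which(d2 == min(d2))[1L]
  list(index = i, dist2 = unname(d2[i]))
}

# bilinear upsampling (row-wise then column-wise linear interpolation);
# reconstruction oracle for the downsize round-trip property
oracle_upsize2d <- function(m, ny, nx) {
  r1 <- t(apply(m, 1L, function(row)
    stats::approx(seq_along(row), row, n = nx, rule = 2)$y))
  apply(r1, 2L, function(col)
    stats::approx(seq_along(col), col, n = ny, rule = 2)$y)
}

make_test_stack <- function(d = c(6L, 8L, 10L), seed = 1, bit_depth = 8) {
  set.seed(seed)
  image_stack(array(sample(0:255, prod(d), replace = TRUE), d),
              voxel_size = c(10, 3.45, 3.45), bit_depth = bit_depth)
}
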