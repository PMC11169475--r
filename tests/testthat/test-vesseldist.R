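test_that("rolling-ball subtraction removes background, keeps spikes", {
  const <- matrix(40, 20, 20)
  expect_true(all(subtract_background(const, 4) == 0))
  spike <- matrix(10, 25, 25)
  spike[13, 13] <- 200
  out <- subtract_background(spike, 4)
  # the spike survives up to the ball's sub-pixel height wobble
  expect_gt(out[13, 13], 189)
  expect_lte(out[13, 13], 190)
  expect_lt(max(out[-(13 * 25 - 12)]), 1e-9)
  # a broad plateau wider than the ball is treated as background
  plateau <- matrix(0, 30, 30)
  plateau[5:26, 5:26] <- 100
  out2 <- subtract_background(plateau, 3)
  expect_lt(mean(out2[10:20, 10:20]), 5)
  expect_true(all(out2 >= 0))
})

test_that("grouped MIPs tile the stack and take per-pixel maxima", {
  s <- make_test_stack(c(30L, 6L, 7L), seed = 1)
  mips <- grouped_mip(s, 10)
  expect_length(mips, 3)
  expect_equal(mips[[1]], apply(s$voxels[1:10, , ], c(2, 3), max))
  # group 1 is the identity slicing
  ident <- grouped_mip(s, 1)
  expect_equal(ident[[17]], s$voxels[17, , ])
  # monotone stack: each MIP equals its group's last slice
  mono <- image_stack(array(rep(1:12, 5 * 4), c(12, 5, 4)))
  m <- grouped_mip(mono, 4)
  expect_equal(m[[2]], mono$voxels[8, , ])
  # trailing partial group kept
  expect_length(grouped_mip(s, 8), 4)
})

test_that("Otsu equals the exhaustive between-class-variance search", {
  set.seed(2)
  for (i in 1:12) {
    img <- matrix(sample(0:255, 400, replace = TRUE,
                         prob = runif(256)^2), 20, 20)
    expect_equal(otsu_threshold(img), oracle_otsu(img))
  }
  # bimodal two-level image: threshold strictly between the modes
  two <- matrix(c(rep(10, 160), rep(200, 240)), 20, 20)
  thr <- otsu_threshold(two)
  expect_gt(thr, 10 - 1)
  expect_lt(thr, 200)
})

test_that("one global threshold binarizes every MIP", {
  set.seed(3)
  mips <- replicate(5, matrix(sample(0:255, 100, replace = TRUE), 10, 10),
                    simplify = FALSE)
  res <- otsu_global_threshold(mips, reference_index = 3)
  for (k in 1:5)
    expect_equal(res$masks[[k]],
                 matrix(as.integer(mips[[k]] > res$threshold), 10, 10))
  expect_error(otsu_global_threshold(list(matrix(5, 4, 4)), 1), "constant")
})

test_that("kd-tree nearest neighbours match the all-pairs oracle exactly", {
  set.seed(4)
  for (rep in 1:5) {
    mask <- matrix(as.integer(runif(64 * 64) < 0.08), 64, 64)
    if (!sum(mask)) next
    pts <- which(mask == 1L, arr.ind = TRUE)
    tree <- descspim:::kdtree_build(pts)
    queries <- cbind(sample(1:64, 40, TRUE), sample(1:64, 40, TRUE))
    for (q in seq_len(nrow(queries))) {
      got <- descspim:::kdtree_nearest(tree, queries[q, ])
      ora <- oracle_nn(pts, queries[q, ])
      expect_identical(got$index, ora$index)
      expect_identical(unname(got$dist2), ora$dist2)
    }
  }
})

test_that("disk phantom distances respect the geometry bound", {
  # vessel: single pixel at the disk centre; drug: filled disk radius r
  n <- 41L; r <- 12
  vessel <- matrix(0L, n, n); vessel[21, 21] <- 1L
  drug <- matrix(0L, n, n)
  for (y in 1:n) for (x in 1:n)
    if ((y - 21)^2 + (x - 21)^2 <= r^2) drug[y, x] <- 1L
  tab <- drug_vessel_distances(vessel, drug, pixel_size = 1)
  expect_equal(nrow(tab), 1)  # one vessel point receives all lines
  expect_lte(tab$mean_distance_um, r + 0.5)
  expect_gte(tab$mean_distance_um, r - 1.5)
  per <- attr(tab, "per_point")
  expect_true(all(per$valid))
  expect_true(all(per$distance_um <= r + 0.5))
})

test_that("lines crossing outside the drug area are omitted", {
  # two drug lobes; vessel inside lobe A only; lobe B's nearest-vessel
  # segments must traverse background and be dropped
  m <- matrix(0L, 20, 40)
  drug <- m; drug[8:12, 3:12] <- 1L; drug[8:12, 28:37] <- 1L
  vessel <- m; vessel[10, 7] <- 1L
  tab <- drug_vessel_distances(vessel, drug, pixel_size = 1)
  per <- attr(tab, "per_point")
  lobe_b <- per$drug_x >= 28
  expect_true(all(!per$valid[lobe_b]))
  expect_true(any(per$valid[!lobe_b]))
  # dropping the validity rule only adds records, never changes retained
  expect_true(all(per$distance_um[per$valid] <= max(per$distance_um)))
})

test_that("degenerate masks are handled as contracted", {
  empty <- matrix(0L, 10, 10)
  disk <- matrix(0L, 10, 10); disk[4:6, 4:6] <- 1L
  expect_equal(nrow(drug_vessel_distances(disk, empty, 1)), 0)
  expect_warning(tab <- drug_vessel_distances(empty, disk, 1),
                 "empty vessel")
  expect_equal(nrow(tab), 0)
  expect_true(all(!attr(tab, "per_point")$valid))
})

test_that("distance summaries interpolate percentiles as documented", {
  mk_tab <- function(d) {
    out <- data.frame(vessel_y = seq_along(d),
                      vessel_x = rep(1L, length(d)),
                      mean_distance_um = d,
                      n_drug_points = rep(1L, length(d)))
    class(out) <- c("distance_table", "data.frame")
    out
  }
  s <- summarize_distances(mk_tab(rep(4, 25)))
  expect_equal(s$percentile_95, 4)
  expect_equal(s$per_slice$median, 4)
  s2 <- summarize_distances(mk_tab(1:100))
  expect_equal(s2$percentile_95, 95.05)
  expect_error(summarize_distances(list(mk_tab(numeric(0)))), "no valid")
})

test_that("phantom 95th percentile recovers the halo radius over seeds", {
  p95 <- vapply(1:10, function(sd) {
    vd <- gen_vessel_drug_masks(seed = sd, halo_px = 8)
    summarize_distances(
      drug_vessel_distances(vd$vessel, vd$drug, pixel_size = 1)
    )$percentile_95
  }, numeric(1))
  expect_true(all(p95 >= 0.9 * 8 & p95 <= 1.1 * 8))
})

test_that("vessel components classify by drug colocalization", {
  vessel <- matrix(0L, 20, 20)
  vessel[3:5, 3:5] <- 1L       # inside drug
  vessel[14:16, 14:16] <- 1L   # disjoint from drug
  drug <- matrix(0L, 20, 20); drug[1:8, 1:8] <- 1L
  cls <- classify_vessels(vessel, drug)
  expect_equal(nrow(cls), 2)
  expect_true(cls$associating[1])
  expect_false(cls$associating[2])
  # one touching pixel is enough
  drug2 <- matrix(0L, 20, 20); drug2[14, 14] <- 1L
  cls2 <- classify_vessels(vessel, drug2)
  expect_false(cls2$associating[1])
  expect_true(cls2$associating[2])
  # 8-connectivity: diagonal chains form one component
  diagm <- matrix(0L, 10, 10); for (i in 1:6) diagm[i, i] <- 1L
  expect_equal(nrow(classify_vessels(diagm, matrix(0L, 10, 10))), 1)
})
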