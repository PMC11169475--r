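test_that("movie parts concatenate in order and validate their headers", {
  set.seed(1)
  mk <- function(nt) movie_stack(array(runif(nt * 4 * 5), c(nt, 4, 5)),
                                 exposure = 0.2)
  joined <- concat_movie_parts(list(mk(300), mk(300), mk(300)))
  expect_equal(dim(joined$frames)[1], 900)
  one <- mk(7)
  expect_identical(concat_movie_parts(list(one))$frames, one$frames)
  a <- mk(3); b <- mk(3)
  ab <- concat_movie_parts(list(a, b))$frames
  ba <- concat_movie_parts(list(b, a))$frames
  expect_false(identical(ab, ba))
  expect_identical(ab[1:3, , ], ba[4:6, , ])
  bad <- movie_stack(array(0, c(2, 9, 5)), exposure = 0.2)
  expect_error(concat_movie_parts(list(a, bad)), "part 2")
  bad2 <- movie_stack(array(0, c(2, 4, 5)), exposure = 0.5)
  expect_error(concat_movie_parts(list(a, bad2)), "exposure")
})

test_that("movie to stack conversion is bit-exact re-indexing", {
  set.seed(2)
  frames <- array(sample(0:255, 20 * 6 * 7, replace = TRUE), c(20, 6, 7))
  movie <- movie_stack(frames, exposure = 0.2)
  plan <- plan_acquisition(50, 0.2, 20, 1.52)
  stack <- movie_to_stack(movie, plan)
  expect_identical(stack$voxels, frames)
  expect_equal(stack$voxel_size, c(10, 3.45, 3.45))
  # multiset of pixel values preserved exactly
  expect_identical(sort(as.vector(stack$voxels)), sort(as.vector(frames)))
  expect_error(movie_to_stack(movie, plan_acquisition(50, 0.3, 20, 1.52)),
               "exposure")
  one <- movie_to_stack(movie_stack(frames[1, , , drop = FALSE],
                                    exposure = 0.2),
                        plan_acquisition(50, 0.2, 1, 1.52))
  expect_equal(dim(one$voxels)[1], 1)
})

test_that("opposite-view orientation is an involution that mirrors z and x", {
  s <- make_test_stack(c(5L, 6L, 7L), seed = 3)
  twice <- orient_opposite_view(orient_opposite_view(s))
  expect_identical(twice$voxels, s$voxels)
  probe <- image_stack(array(0, c(4, 3, 5)))
  probe$voxels[1, 1, 1] <- 9
  flipped <- orient_opposite_view(probe)
  expect_equal(flipped$voxels[4, 1, 5], 9)
  expect_equal(sum(flipped$voxels), 9)
  sym <- image_stack(array(1, c(3, 3, 3)))
  expect_identical(orient_opposite_view(sym)$voxels, sym$voxels)
})

test_that("registration downsizing scales shapes and voxel sizes", {
  s <- make_test_stack(c(16L, 12L, 20L), seed = 4)
  d <- downsize_for_registration(s, 0.5, 4)
  expect_equal(dim(d$voxels), c(4, 6, 10))
  expect_equal(d$voxel_size, s$voxel_size * c(4, 2, 2))
  expect_identical(downsize_for_registration(s, 1, 1)$voxels, s$voxels)
  const <- image_stack(array(5, c(8, 8, 8)))
  expect_true(all(downsize_for_registration(const, 0.25, 2)$voxels == 5))
  tiny <- image_stack(array(0, c(3, 3, 3)))
  expect_error(downsize_for_registration(tiny, 0.25, 1), "degenerate")
})

test_that("downsize/upsize round trip of a smooth phantom is accurate", {
  # band-limited phantom: low-frequency separable cosine ramp
  ny <- 40L; nx <- 48L
  img <- outer(1 + 0.5 * cos(seq(0, pi, length.out = ny)),
               1 + 0.5 * sin(seq(0, pi, length.out = nx))) * 100
  s <- image_stack(array(img, c(1L, ny, nx)))
  down <- downsize_for_registration(s, 0.5, 1)
  up <- oracle_upsize2d(down$voxels[1, , ], ny, nx)
  rms <- sqrt(mean((up - img)^2)) / sqrt(mean(img^2))
  expect_lt(rms, 0.05)
})

test_that("stacks round-trip through multi-page TIFF with sidecar", {
  s <- make_test_stack(c(4L, 5L, 6L), seed = 5)
  path <- file.path(withr::local_tempdir(), "s.tif")
  write_stack(s, path)
  back <- read_stack(path)
  expect_equal(back$voxels, s$voxels)
  expect_equal(back$voxel_size, s$voxel_size)
  expect_equal(back$bit_depth, s$bit_depth)
})
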