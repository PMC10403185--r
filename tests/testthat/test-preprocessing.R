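test_that("bounding box equals the exhaustive-scan oracle on random masks", {
  set.seed(42)
  for (trial in 1:100) {
    dims <- sample(6:20, 3, replace = TRUE)
    m <- random_mask(dims, n_pts = sample(1:8, 1))
    sm <- segmentation_mask(m, spacing = c(1, 1, 1))
    bc <- compute_bounding_cube(sm, make_cube = FALSE)
    or <- oracle_bounding_box(m)
    expect_identical(bc$min_index, as.integer(or$min_index))
    expect_identical(bc$max_index, as.integer(or$max_index))
  }
})

test_that("bounding cube handles point, full-grid and expansion cases", {
  m <- array(0, c(10, 10, 10)); m[4, 6, 8] <- 1   # voxel (3,5,7) 0-based
  bc <- compute_bounding_cube(segmentation_mask(m), make_cube = FALSE)
  expect_equal(bc$min_index, c(3L, 5L, 7L))
  expect_equal(bc$max_index, c(3L, 5L, 7L))

  full <- compute_bounding_cube(segmentation_mask(array(1, c(10, 10, 10))))
  expect_equal(full$min_index, c(0L, 0L, 0L))
  expect_equal(full$max_index, c(9L, 9L, 9L))
  expect_equal(full$cube_side, 10L)

  # anisotropic support expands to a cube, clamped inside the grid
  m2 <- array(0, c(20, 20, 20)); m2[2:9, 9:12, 19:20] <- 1
  cube <- compute_bounding_cube(segmentation_mask(m2), make_cube = TRUE)
  ext <- cube$max_index - cube$min_index + 1L
  expect_true(all(ext == 8L))           # side = longest extent
  expect_true(all(cube$min_index >= 0L))
  expect_true(all(cube$max_index <= 19L))
  # the tight box is contained in the cube
  tight <- compute_bounding_cube(segmentation_mask(m2), make_cube = FALSE)
  expect_true(all(cube$min_index <= tight$min_index))
  expect_true(all(cube$max_index >= tight$max_index))
  expect_error(segmentation_mask(array(0, c(5, 5, 5))), "empty")
})

test_that("crop_and_resample is exact for same-grid crops and linear fields", {
  # identity: cube of exactly the target side on the same grid
  set.seed(5)
  a <- array(rnorm(24^3), c(24, 24, 24))
  vol <- modality_volume(a, c(1, 1, 1), "d2", "c")
  m <- array(0, c(24, 24, 24)); m[5:12, 5:12, 5:12] <- 1
  cube <- compute_bounding_cube(segmentation_mask(m, spacing = c(1, 1, 1)))
  out <- crop_and_resample(vol, cube, target_side = 8L)
  expect_equal(out, a[5:12, 5:12, 5:12], tolerance = 1e-12)

  # trilinear interpolation reproduces a trilinear field exactly, including
  # across grids with different spacing
  f <- function(x, y, z) 2 + x + 2 * y + 3 * z + 0.5 * x * y
  g1 <- expand.grid(x = (0:23) * 1.0, y = (0:23) * 1.0, z = (0:11) * 2.0)
  vol2 <- modality_volume(array(f(g1$x, g1$y, g1$z), c(24, 24, 12)),
                          c(1, 1, 2), "T2WI", "c")
  out2 <- crop_and_resample(vol2, cube, target_side = 17L)
  co <- seq(4, 11, length.out = 17)   # physical mm along each axis
  gg <- expand.grid(x = co, y = co, z = co)
  expect_equal(as.vector(out2), f(gg$x, gg$y, gg$z), tolerance = 1e-9)

  # border-straddling cube zero-pads outside the image
  m3 <- array(0, c(24, 24, 24)); m3[1:8, 1:8, 1:8] <- 1
  cube3 <- compute_bounding_cube(segmentation_mask(m3, spacing = c(1, 1, 1)))
  cube3$min_index <- c(-4L, -4L, -4L); cube3$max_index <- c(3L, 3L, 3L)
  out3 <- crop_and_resample(vol, cube3, target_side = 8L)
  expect_true(all(out3[1:4, , ] == 0))
  expect_equal(out3[5:8, 5:8, 5:8], a[1:4, 1:4, 1:4], tolerance = 1e-12)

  cube4 <- cube3
  cube4$min_index <- c(100L, 100L, 100L); cube4$max_index <- c(120L, 120L, 120L)
  expect_error(crop_and_resample(vol, cube4), "outside")
})

test_that("min-max normalization follows the formula and its conventions", {
  x <- array(c(1, 2, 3, 1, 2, 3, 1, 2), c(2, 2, 2))
  n <- minmax_normalize(x)
  expect_equal(sort(unique(as.vector(n$voxels))), c(0, 0.5, 1))
  expect_equal(n$x_min, 1); expect_equal(n$x_max, 3)

  # one voxel at the minimum, rest at the maximum
  y <- array(7, c(3, 3, 3)); y[2, 2, 2] <- 5
  ny <- minmax_normalize(y)
  expect_equal(ny$voxels[2, 2, 2], 0)
  expect_equal(sum(ny$voxels == 1), 26)

  # exact range and idempotence for non-constant input
  set.seed(6)
  z <- array(rnorm(64), c(4, 4, 4))
  nz <- minmax_normalize(z)
  expect_equal(range(nz$voxels), c(0, 1))
  expect_equal(minmax_normalize(nz$voxels)$voxels, nz$voxels,
               tolerance = 1e-12)

  expect_warning(nc <- minmax_normalize(array(4, c(2, 2, 2))), "constant")
  expect_true(all(nc$voxels == 0))
})

test_that("2D Sobel matches a hand-convolved oracle and its symmetries", {
  gx_k <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gy_k <- matrix(c(1, 0, -1, 2, 0, -2, 1, 0, -1), 3, 3)

  expect_error(sobel_gradient_2d(matrix(1, 2, 5)), "smaller")

  # constant image: zero gradient everywhere (any padding)
  g0 <- sobel_gradient_2d(matrix(3.7, 6, 6))
  expect_true(all(g0$magnitude == 0))

  # vertical step: interior edge pixels carry |Gx| = 4, Gy = 0, G = 4
  step <- cbind(matrix(0, 6, 3), matrix(1, 6, 3))
  gs <- sobel_gradient_2d(step)
  expect_true(all(abs(gs$gx[2:5, 3:4]) == 4))
  expect_true(all(gs$gy == 0))
  expect_true(all(gs$magnitude[2:5, 3:4] == 4))

  # random image: equality with the double-loop oracle
  set.seed(7)
  img <- matrix(rnorm(80), 8, 10)
  g <- sobel_gradient_2d(img)
  expect_equal(g$gx, oracle_conv3x3(img, gx_k), tolerance = 1e-12)
  expect_equal(g$gy, oracle_conv3x3(img, gy_k), tolerance = 1e-12)
  expect_equal(g$magnitude, sqrt(g$gx^2 + g$gy^2))
  expect_equal(g$direction, atan2(g$gy, g$gx))

  # transposition swaps the two kernels' roles; magnitude is invariant
  gt <- sobel_gradient_2d(t(img))
  expect_equal(gt$magnitude, t(g$magnitude), tolerance = 1e-12)
})

test_that("volumetric Sobel channel: zeros, homogeneity, shell geometry", {
  z <- minmax_normalize(array(0.5, c(8, 8, 8)), case_id = "c") |>
    suppressWarnings()
  expect_true(all(sobel_channel(z)$magnitude == 0))

  set.seed(8)
  a <- array(runif(12^3), c(12, 12, 12))
  na <- minmax_normalize(a)
  for (mode in c("slicewise_2d", "full_3d")) {
    g1 <- sobel_channel(na, mode, renormalize = FALSE)$magnitude
    n2 <- na; n2$voxels <- 2 * na$voxels
    g2 <- sobel_channel(n2, mode, renormalize = FALSE)$magnitude
    expect_equal(g2, 2 * g1, tolerance = 1e-12)
    gn <- sobel_channel(na, mode)$magnitude
    expect_equal(range(gn), c(0, 1))
  }

  # solid ball: gradient magnitude peaks on the shell, zero deep inside
  d <- 17; ctr <- 9; r <- 5
  gr <- expand.grid(1:d, 1:d, 1:d)
  ball <- array(as.numeric((gr[[1]] - ctr)^2 + (gr[[2]] - ctr)^2 +
                             (gr[[3]] - ctr)^2 <= r^2), c(d, d, d))
  nb <- minmax_normalize(ball)
  mag <- sobel_channel(nb, "full_3d")$magnitude
  peak <- which(mag == max(mag), arr.ind = TRUE)[1, ]
  expect_equal(sqrt(sum((peak - ctr)^2)), r, tolerance = 1.5)
  expect_equal(mag[ctr, ctr, ctr], 0)
})

test_that("channel fusion obeys C = M * (1 + sobel) and validates inputs", {
  set.seed(9)
  mk <- function(mod, id = "c") {
    minmax_normalize(array(runif(6^3), c(6, 6, 6)), modality = mod,
                     case_id = id)
  }
  mods <- MODALITY_TAGS
  for (M in 1:6) for (s in c(FALSE, TRUE)) {
    cubes <- lapply(mods[1:M], mk)
    tens <- fuse_channels(cubes, include_sobel = s, label = "benign")
    expect_equal(dim(tens$channels)[4], M * (1 + s))
    expect_equal(tens$channel_labels,
                 c(mods[1:M], if (s) paste0(mods[1:M], "_sobel")))
  }
  # the four-modality fused model has exactly 8 channels
  t8 <- fuse_channels(lapply(mods[1:4], mk), include_sobel = TRUE)
  expect_equal(dim(t8$channels)[4], 8L)
  expect_true(all(t8$channels >= 0 & t8$channels <= 1))

  expect_error(fuse_channels(list(mk("d1", "a"), mk("d2", "b"))), "mixed")
  bad <- mk("d2"); bad$voxels <- array(0.5, c(5, 5, 5))
  expect_error(fuse_channels(list(mk("d1"), bad)), "shape")
})
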