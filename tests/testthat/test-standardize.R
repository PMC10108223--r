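test_that("rotate90 swaps dimensions and calibration losslessly", {
  set.seed(3)
  a <- array(sample(0:255, 2 * 512 * 1920 / 64, TRUE), c(2, 64, 240))
  img <- vol_image(a, c(0.1, 0.2, 1), "8")
  cw <- rotate90(img, "clockwise")
  expect_equal(img_dim(cw), c(2, 240, 64), ignore_attr = TRUE)
  expect_equal(as.numeric(cw$voxel_size), c(0.2, 0.1, 1))
  ## spot-check the index permutation on one slice
  m <- matrix(a[1, , ], 64, 240)
  expect_equal(matrix(get_channel(cw)[1, , ], 240, 64),
               t(m)[, 64:1], ignore_attr = TRUE)
  back <- rotate90(cw, "anticlockwise")
  expect_equal(get_channel(back), a, ignore_attr = TRUE)
  expect_equal(as.numeric(back$voxel_size), c(0.1, 0.2, 1))
  r4 <- img
  for (i in 1:4) r4 <- rotate90(r4, "clockwise")
  expect_equal(get_channel(r4), a, ignore_attr = TRUE)
})

test_that("subregion output shape follows the dimension arithmetic", {
  ## voxel 0.5 um iso, ROI length 40 um, width 60, sigma 10 ->
  ## 100 rows x 120 cols
  a <- array(0, c(4, 160, 160))
  img <- vol_image(a, c(0.5, 0.5, 1), "8")
  roi <- line_roi(c(80, 30), c(80, 110))      # 80 px * 0.5 = 40 um
  sub <- extract_subregion(img, roi, subregion_params(60, 4, 10))
  expect_equal(img_dim(sub), c(4, 100, 120), ignore_attr = TRUE)

  ## 20 random parameter draws: shape is a pure function of params/voxel/L
  set.seed(99)
  for (i in 1:20) {
    vs <- c(runif(1, 0.2, 1), 0, runif(1, 0.5, 2)); vs[2] <- vs[1]
    dims <- c(sample(3:6, 1), sample(60:120, 1), sample(60:120, 1))
    img_i <- vol_image(array(0, dims), vs, "8")
    L_px <- runif(1, 10, dims[2] / 2)
    x0 <- dims[3] / 2
    roi_i <- line_roi(c(x0, 10), c(x0, 10 + L_px))
    w <- runif(1, 5, 40); dpt <- runif(1, 1, 6); sg <- runif(1, 0, 8)
    sub_i <- suppressWarnings(
      extract_subregion(img_i, roi_i, subregion_params(w, dpt, sg)))
    expect_equal(img_dim(sub_i)[2], ceiling((L_px * vs[2] + sg) / vs[2]),
                 ignore_attr = TRUE)
    expect_equal(img_dim(sub_i)[3], ceiling(w / vs[1]), ignore_attr = TRUE)
    expect_equal(img_dim(sub_i)[1], min(dims[1], ceiling(dpt / vs[3])),
                 ignore_attr = TRUE)
  }
})

test_that("axis-aligned ROI with sigma 0 is a bit-exact crop", {
  a <- array(0, c(4, 40, 30)); a[] <- seq_along(a)
  img <- vol_image(a, c(0.5, 0.5, 1), "float")
  roi <- line_roi(c(14, 5), c(14, 25))
  sub <- extract_subregion(img, roi, subregion_params(5.5, 3, 0))
  expect_equal(img_dim(sub), c(3, 20, 11), ignore_attr = TRUE)
  expect_equal(get_channel(sub), a[1:3, 6:25, 10:20], ignore_attr = TRUE)
  ## idempotence for the already-standardized stack (vertical centre ROI)
  roi2 <- line_roi(c(5, 0), c(5, 19))
  p2 <- subregion_params(5.5, 3, 0, interpolation = "nearest")
  once <- extract_subregion(sub, roi2, p2)
  twice <- extract_subregion(once, roi2, p2)
  expect_equal(get_channel(twice), get_channel(once), tolerance = 1e-6)
})

test_that("45-degree ROI resampling matches the inverse-rotation oracle", {
  ## label every source pixel uniquely; nearest-neighbour sampling must pick
  ## the label of the independently computed rotated coordinate
  ny <- 60; nx <- 60
  a <- array(0, c(1, ny, nx))
  a[1, , ] <- outer(seq_len(ny), seq_len(nx),
                    function(y, x) 1000 * y + x)
  img <- vol_image(a, c(1, 1, 1), "float")
  s <- c(15, 15); e <- c(35, 35)      # 45 degrees, length ~28.3 px
  roi <- line_roi(s, e)
  prm <- subregion_params(width_um = 14, depth_um = 1, sigma_um = 0,
                          interpolation = "nearest")
  sub <- extract_subregion(img, roi, prm)
  d <- img_dim(sub)
  u <- (e - s) / sqrt(sum((e - s)^2)); w <- c(u[2], -u[1])
  bad <- 0
  for (r in seq_len(d[2]) - 1) for (cc in seq_len(d[3]) - 1) {
    src <- s + u * r + w * (cc - (d[3] - 1) / 2)
    xi <- round(src[1]); yi <- round(src[2])
    if (xi < 0 || xi >= nx || yi < 0 || yi >= ny) next
    got <- get_channel(sub)[1, r + 1, cc + 1]
    want <- a[1, yi + 1, xi + 1]
    ## allow 1-voxel positional tolerance at rotation ties
    if (got != want) {
      gy <- got %/% 1000; gx <- got %% 1000
      if (abs(gy - (yi + 1)) > 1 || abs(gx - (xi + 1)) > 1) bad <- bad + 1
    }
  }
  expect_equal(bad, 0)
})

test_that("within-stack variant centres the z window and shifts to fit", {
  img <- vol_image(array(rep(1:50, each = 1), c(50, 12, 12)) * 1.0,
                   c(1, 1, 1), "float")
  prm <- subregion_params(6, 10, 0, interpolation = "nearest")
  mkroi <- function(z) line_roi(c(5, 1), c(5, 10), slice_index = z)
  s1 <- extract_subregion_within_stack(img, mkroi(25L), prm)
  expect_equal(get_channel(s1)[, 1, 1], as.numeric(21:30))
  s2 <- extract_subregion_within_stack(img, mkroi(2L), prm)
  expect_equal(get_channel(s2)[, 1, 1], as.numeric(1:10))
  s3 <- extract_subregion_within_stack(img, mkroi(48L), prm)
  expect_equal(get_channel(s3)[, 1, 1], as.numeric(41:50))
  ## depth >= stack keeps everything
  whole <- extract_subregion_within_stack(
    img, mkroi(10L), subregion_params(6, 100, 0, interpolation = "nearest"))
  expect_equal(img_dim(whole)[1], 50, ignore_attr = TRUE)
})

test_that("cropping with zero fill never increases total intensity", {
  set.seed(12)
  a <- array(runif(5 * 50 * 50) * 100, c(5, 50, 50))
  img <- vol_image(a, c(1, 1, 1), "float")
  for (i in 1:5) {
    s <- c(runif(1, 10, 40), runif(1, 5, 20))
    e <- s + c(runif(1, -10, 10), runif(1, 10, 25))
    sub <- extract_subregion(img, line_roi(s, e),
                             subregion_params(20, 4, 5))
    expect_lte(sum(get_channel(sub)), sum(a) + 1e-6)
  }
  expect_error(line_roi(c(1, 1), c(1, 1)), "degenerate")
})
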