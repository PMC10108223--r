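test_that("each global method attains the brute-force optimum on random 8-bit histograms", {
  ## the oracle scans all 255 candidate thresholds with an independent
  ## class-sum formulation; ties (criterion plateaus) are accepted whenever
  ## the package threshold attains the optimal criterion value
  for (seed in 1:12) {
    img <- make_random_stack8(seed)
    counts <- tabulate(as.integer(get_channel(img)) + 1L, nbins = 256L)
    for (m in c("otsu", "moments", "percentile", "max_entropy")) {
      t_pkg <- global_threshold(img, m)$threshold
      orc <- oracle_best_threshold(counts, m)
      expect_equal(orc$values[t_pkg + 1], orc$value, tolerance = 1e-9,
                   label = sprintf("seed %d method %s T=%d", seed, m, t_pkg))
    }
  }
})

test_that("two-value histograms threshold inside the gap; constants error", {
  v <- array(c(rep(20, 5000), rep(200, 5000)), dim = c(10, 10, 100))
  img <- vol_image(v, c(1, 1, 1), "8")
  for (m in c("otsu", "moments", "percentile", "max_entropy")) {
    res <- global_threshold(img, m)
    expect_gt(res$threshold, 20)
    expect_lt(res$threshold, 200)
    expect_equal(sum(res$mask$voxels), 5000)
  }
  ## percentile target: foreground fraction closest to 50%
  res <- global_threshold(img, "percentile", percentile_target = 0.5)
  expect_equal(mean(res$mask$voxels), 0.5)
  expect_error(global_threshold(vol_image(array(9, c(3, 3, 3)),
                                          c(1, 1, 1), "8"), "otsu"),
               "constant")
})

test_that("16-bit stacks are thresholded via their 8-bit histogram", {
  set.seed(2)
  v <- array(c(rep(2000, 500), rep(40000, 500)), c(10, 10, 10))
  res <- global_threshold(vol_image(v, c(1, 1, 1), "16"), "otsu")
  expect_equal(sum(res$mask$voxels), 500)
})

test_that("hysteresis keeps the connected halo and drops detached blobs", {
  a <- array(0, c(10, 10, 10))
  a[5, 3:5, 5] <- c(220, 100, 100)  # bright core with touching mid halo
  a[5, 8, 8] <- 100                 # detached mid-intensity blob
  img <- vol_image(a, c(1, 1, 1), "8")
  m <- hysteresis_threshold(img, high = 200, low = 80)
  oracle <- oracle_hysteresis(a, 80, 200)
  expect_equal(m$voxels, array(as.integer(oracle), dim = dim(a)))
  expect_equal(sum(m$voxels), 3)
  expect_equal(m$voxels[5, 8, 8], 0L)
  ## low = high degenerates to the global threshold, exact voxel equality
  m2 <- hysteresis_threshold(img, high = 150, low = 150)
  expect_equal(m2$voxels, array(as.integer(a > 150), dim = dim(a)))
  ## nothing above high -> empty
  expect_equal(sum(hysteresis_threshold(img, high = 250, low = 10)$voxels), 0)
  expect_error(hysteresis_threshold(img, high = 10, low = 50), "low <= high")
})

test_that("property: random stacks, hysteresis equals the flood-fill oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    a <- array(sample(0:255, 8 * 12 * 12, TRUE), c(8, 12, 12))
    img <- vol_image(a, c(1, 1, 1), "8")
    lo <- sample(40:100, 1); hi <- lo + sample(20:100, 1)
    m <- hysteresis_threshold(img, high = hi, low = lo)
    expect_equal(m$voxels,
                 array(as.integer(oracle_hysteresis(a, lo, hi)), dim = dim(a)))
  }
})

test_that("simple_3d labels components and filters by size", {
  a <- array(0, c(8, 20, 20))
  a[2:5, 2:6, 2:6] <- 100     # 100-voxel block
  a[7, 15, 15] <- 100
  a[7, 15, 16] <- 100
  a[7, 16, 15] <- 100          # 3-voxel blob
  img <- vol_image(a, c(1, 1, 1), "8")
  res <- simple_3d(img, 50, min_object_vox = 10)
  expect_equal(res$n_objects, 1)
  expect_equal(sum(res$mask$voxels), 100)
  res1 <- simple_3d(img, 50, min_object_vox = 1)
  expect_equal(res1$mask$voxels,
               array(as.integer(a > 50), dim = dim(a)))
  empty <- simple_3d(vol_image(array(0, c(3, 3, 3)), c(1, 1, 1), "8"), 10)
  expect_equal(empty$n_objects, 0)
})

test_that("remove_speckles drops small components, never adds, idempotent", {
  a <- array(0L, c(10, 30, 30))
  a[2:6, 2:11, 2:11] <- 1L                      # 500 voxels
  a[8, 20:22, 20:22] <- 1L                      # 9 voxels
  a[1, 28, 28] <- 1L; a[1, 28, 29] <- 1L        # 2 voxels
  m <- binary_mask(a, c(1, 1, 1))
  cleaned <- remove_speckles(m, 10)
  expect_equal(sum(cleaned$voxels), 500)
  expect_true(all(cleaned$voxels <= m$voxels))
  expect_equal(remove_speckles(cleaned, 10)$voxels, cleaned$voxels)
  expect_equal(remove_speckles(m, 0)$voxels, m$voxels)
  expect_equal(sum(remove_speckles(m, 1000)$voxels), 0)
})

test_that("preprocess_stack median filter matches the sorting oracle", {
  set.seed(6)
  a <- array(runif(5 * 7 * 7) * 100, c(5, 7, 7))
  a[3, 4, 4] <- 1000  # speckle
  img <- vol_image(a, c(1, 1, 1), "float")
  p <- segmentation_params(median_radius_vox = c(1, 1, 1))
  out <- get_channel(preprocess_stack(img, p))
  ## brute-force median over the truncated 3x3x3 box at a few positions
  for (pos in list(c(3, 4, 4), c(1, 1, 1), c(5, 7, 7), c(2, 3, 6))) {
    zz <- max(1, pos[1] - 1):min(5, pos[1] + 1)
    yy <- max(1, pos[2] - 1):min(7, pos[2] + 1)
    xx <- max(1, pos[3] - 1):min(7, pos[3] + 1)
    expect_equal(out[pos[1], pos[2], pos[3]],
                 median(a[zz, yy, xx]))
  }
  expect_lt(out[3, 4, 4], 1000)  # speckle removed
  ## zero radii and no rolling ball: identity
  ident <- preprocess_stack(img, segmentation_params())
  expect_equal(get_channel(ident), a)
})

test_that("rolling-ball background removal flattens a gradient, keeps objects", {
  ny <- 40; nx <- 40
  bgslope <- outer(seq_len(ny), seq_len(nx), function(y, x) 0.5 * (y + x))
  a <- array(0, c(1, ny, nx))
  a[1, , ] <- bgslope
  a[1, 18:22, 18:22] <- a[1, 18:22, 18:22] + 100   # small object
  img <- vol_image(a, c(1, 1, 1), "float")
  p <- segmentation_params(rolling_ball_radius_px = 12)
  out <- get_channel(preprocess_stack(img, p))
  expect_gt(out[1, 20, 20], 80)                     # object retained
  expect_lt(max(out[1, 2:10, 2:10]), 6)             # background near zero
  expect_true(all(out >= 0))
})

test_that("segmentation pipelines recover phantom foreground", {
  spec <- phantom_spec(seed = 9L)
  ph <- generate_glia_phantom(spec)
  deg <- degrade_stack(ph$image, spec)
  mask <- segment_pipeline(deg, "cytosol")
  truth_frac <- mean(ph$truth$mask$voxels)
  expect_equal(mean(mask$voxels), truth_frac, tolerance = 0.2)
  expect_equal(mask$provenance$profile, "cytosol")
  ## membrane profile keeps a hollow shell hollow
  sh <- c(9, 24, 24)
  a <- array(10, sh)
  for (z in 1:9) for (y in 1:24) {
    rr <- (z - 5)^2 * 4 + (y - 12)^2 + (seq_len(24) - 12)^2
    a[z, y, ] <- ifelse(rr <= 64 & rr >= 25, 200, a[z, y, ])
  }
  shell <- vol_image(a, c(1, 1, 2), "8")
  mm <- segment_pipeline(shell, "membrane")
  expect_equal(mm$voxels[5, 12, 12], 0L)          # hollow centre
  expect_gt(sum(mm$voxels), 0)
  ## all-zero stack fails in the threshold stage, by name
  expect_error(segment_pipeline(vol_image(array(0, c(4, 8, 8)),
                                          c(1, 1, 1), "8"), "cytosol"),
               "threshold")
})

test_that("compare_methods reports a row per method and survives failures", {
  v <- array(c(rep(20, 500), rep(200, 500)), c(10, 10, 10))
  img <- vol_image(v, c(1, 1, 1), "8")
  res <- compare_methods(img, with_preprocess = FALSE)
  expect_equal(nrow(res$results), 6)
  ## all global methods agree on a two-value image (thresholds in the gap)
  glob <- res$masks[paste0("raw_", c("otsu", "moments", "percentile",
                                     "max_entropy"))]
  for (m in glob[-1]) expect_equal(m$voxels, glob[[1]]$voxels)
  ## constant image: every method reports a failure row, none fatal
  cst <- compare_methods(vol_image(array(3, c(4, 4, 4)), c(1, 1, 1), "8"),
                         with_preprocess = FALSE)
  expect_true(all(!is.na(cst$results$error)))
  ## phantom: 6 methods x 2 variants foreground-fraction table
  spec <- phantom_spec(seed = 2L, shape = c(8L, 60L, 50L))
  deg <- degrade_stack(generate_glia_phantom(spec)$image, spec)
  tab <- compare_methods(deg)$results
  expect_equal(nrow(tab), 12)
  expect_true(all(is.finite(tab$foreground_fraction)))
})
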