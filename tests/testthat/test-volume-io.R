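test_that("TIFF stacks round-trip bit-identically with calibration", {
  set.seed(11)
  for (depth in c("8", "16")) {
    hi <- if (depth == "8") 255 else 65535
    a <- array(sample(0:hi, 4 * 4 * 4, TRUE), dim = c(4, 4, 4))
    img <- vol_image(a, c(0.0496225, 0.0496225, 0.19), depth, name = "rt")
    p <- file.path(tempdir(), paste0("rt", depth, ".tif"))
    write_stack(img, p)
    back <- read_stack(p)
    expect_equal(get_channel(back), a, ignore_attr = TRUE)
    expect_equal(as.numeric(back$voxel_size), c(0.0496225, 0.0496225, 0.19),
                 tolerance = 1e-6)
    expect_identical(back$bit_depth, depth)
  }
  ## float stacks round-trip at 32-bit precision
  f <- vol_image(array(abs(rnorm(3 * 5 * 7)) * 100, c(3, 5, 7)),
                 c(1, 1, 2), "float")
  p <- file.path(tempdir(), "rtf.tif")
  write_stack(f, p)
  back <- read_stack(p)
  expect_lt(max(abs(get_channel(back) - get_channel(f))), 1e-3)
  expect_identical(back$bit_depth, "float")
})

test_that("our TIFFs are readable by an independent reader and vice versa", {
  ## python/tifffile ships in the runtime image and serves as the
  ## cross-implementation oracle for the format layer
  set.seed(7)
  a <- array(sample(0:60000, 2 * 6 * 5, TRUE), dim = c(2, 6, 5))
  img <- vol_image(a, c(0.2, 0.2, 0.7), "16", name = "x")
  p <- file.path(tempdir(), "cross.tif")
  write_stack(img, p)
  py <- sprintf(paste0(
    "import tifffile, numpy as np, json, sys\n",
    "t = tifffile.TiffFile(%s)\n",
    "a = t.asarray()\n",
    "print(json.dumps({'shape': list(a.shape), 'sum': int(a.sum()),",
    " 'v': int(a[1,2,3])}))\n"), deparse(p))
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  res <- jsonlite::fromJSON(out[length(out)])
  expect_equal(res$shape, c(2, 6, 5))
  expect_equal(res$sum, sum(a))
  expect_equal(res$v, a[2, 3, 4])

  p2 <- file.path(tempdir(), "pyw.tif")
  py2 <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "arr = (np.arange(24).reshape(2,3,4) * 9).astype(np.uint16)\n",
    "tifffile.imwrite(%s, arr, imagej=True, resolution=(4.0, 4.0),\n",
    "  metadata={'spacing': 0.6, 'unit': 'micron', 'axes': 'ZYX'})\n"),
    deparse(p2))
  system2("python", c("-c", shQuote(py2)))
  back <- read_stack(p2)
  expect_equal(img_dim(back), c(2, 3, 4), ignore_attr = TRUE)
  expect_equal(as.numeric(back$voxel_size), c(0.25, 0.25, 0.6))
  expect_equal(get_channel(back)[2, 3, 4], 23 * 9)
})

test_that("read_stack errors and calibration fallbacks behave as specified", {
  expect_error(read_stack(file.path(tempdir(), "definitely_absent.tif")),
               "file not found")
  ## a TIFF with no resolution tags: explicit override wins, else warn+1um
  p <- file.path(tempdir(), "nocal.tif")
  py <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "tifffile.imwrite(%s, np.zeros((2,3,3), dtype=np.uint8) + 5,",
    " photometric='minisblack')\n"),
    deparse(p))
  system2("python", c("-c", shQuote(py)))
  img <- read_stack(p, voxel_size = c(0.05, 0.05, 0.19))
  expect_equal(as.numeric(img$voxel_size), c(0.05, 0.05, 0.19))
  expect_warning(img2 <- read_stack(p), "calibration")
  expect_equal(as.numeric(img2$voxel_size), c(1, 1, 1))
  expect_true(isTRUE(attr(img2, "calibration_defaulted")))
})

test_that("max_projection matches the per-pixel max oracle and conventions", {
  s <- array(0, c(6, 3, 4)); s[4, 2, 2] <- 200
  mip <- max_projection(vol_image(s, c(1, 1, 1), "8", name = "one"))
  expect_equal(img_dim(mip)[1], 1)
  expect_equal(get_channel(mip)[1, 2, 2], 200)
  expect_match(mip$name, "^MAX_")
  ## single-slice identity
  one <- vol_image(array(runif(12), c(1, 3, 4)), c(1, 1, 1), "float")
  expect_equal(get_channel(max_projection(one)), get_channel(one))
  ## random stack vs brute-force z max; MIP idempotence
  set.seed(5)
  a <- array(sample(0:255, 5 * 8 * 8, TRUE), c(5, 8, 8))
  img <- vol_image(a, c(1, 1, 1), "8")
  m <- max_projection(img)
  oracle <- apply(a, c(2, 3), max)
  expect_equal(matrix(get_channel(m)[1, , ], 8, 8), oracle,
               ignore_attr = TRUE)
  expect_equal(get_channel(max_projection(m)), get_channel(m))
})

test_that("split_channels writes XC names into XCDir folders, conserves sums", {
  a1 <- array(sample(0:255, 3 * 4 * 4, TRUE), c(3, 4, 4))
  a2 <- a1 * 0 + 7; a3 <- a1
  img <- vol_image(a1, c(1, 1, 1), "8", name = "stackA",
                   channels = list(a2, a3))
  out <- file.path(tempdir(), "splitout")
  unlink(out, recursive = TRUE)
  chans <- split_channels(img, out_dir = out)
  expect_length(chans, 3)
  expect_equal(vapply(chans, function(x) x$name, ""),
               c("1C-stackA", "2C-stackA", "3C-stackA"))
  for (i in 1:3) {
    f <- file.path(out, sprintf("%dCDir", i), sprintf("%dC-stackA.tif", i))
    expect_true(file.exists(f))
    expect_equal(sum(get_channel(read_stack(f))),
                 sum(img$channels[[i]]))
  }
  ## single channel pass-through; >4 channels rejected
  expect_length(split_channels(vol_image(a1, c(1, 1, 1), "8")), 1)
  five <- vol_image(a1, c(1, 1, 1), "8",
                    channels = rep(list(a1), 4))
  expect_error(split_channels(five), "unsupported channel count")
  ## mismatched channel shapes violate the container invariant
  expect_error(vol_image(a1, c(1, 1, 1), "8",
                         channels = list(array(0, c(3, 4, 5)))),
               "share the same shape")
})

test_that("convert_8bit maps min..max to 0..255, round-half-up, monotone", {
  a <- array(seq(0, 65535, length.out = 64), c(4, 4, 4))
  img8 <- convert_8bit(vol_image(a, c(1, 1, 1), "16"))
  expect_equal(min(get_channel(img8)), 0)
  expect_equal(max(get_channel(img8)), 255)
  expect_identical(img8$bit_depth, "8")
  ## constant stack degenerates to 0
  expect_true(all(get_channel(convert_8bit(
    vol_image(array(7, c(2, 2, 2)), c(1, 1, 1), "16"))) == 0))
  ## ramp matches the per-voxel formula and is monotone
  r <- array(0:1000, c(11, 13, 7))
  got <- get_channel(convert_8bit(vol_image(r, c(1, 1, 1), "16")))
  expected <- floor(255 * (r - min(r)) / (max(r) - min(r)) + 0.5)
  expect_equal(got, expected)
  expect_true(all(diff(got[order(r)]) >= 0))
})

test_that("ROI archives round-trip in both dialects and pair by sort order", {
  rois <- list(line_roi(c(3, 4), c(3, 40)),
               line_roi(c(5.5, 6.25), c(20, 30.5), slice_index = 4L),
               oval_roi(c(10, 12), c(4, 3), slice_index = 2L))
  zip_p <- file.path(tempdir(), "RoiSetLine.zip")
  write_roi_archive(rois, zip_p)
  back <- read_roi_archive(zip_p)
  expect_length(back, 3)
  expect_s3_class(back[[1]], "line_roi")
  expect_equal(back[[2]]$start, c(5.5, 6.25))
  expect_equal(back[[2]]$slice_index, 4L)
  expect_s3_class(back[[3]], "oval_roi")
  expect_equal(back[[3]]$center, c(10, 12))
  expect_equal(back[[3]]$radii, c(4, 3))

  json_p <- file.path(tempdir(), "rois.json")
  write_roi_archive(rois, json_p)
  bj <- read_roi_archive(json_p)
  expect_equal(bj[[1]]$end, c(3, 40))
  expect_equal(bj[[3]]$slice_index, 2L)

  ## the binary records follow the published ImageJ layout
  tmp <- tempfile(); dir.create(tmp)
  utils::unzip(zip_p, exdir = tmp)
  buf <- readBin(list.files(tmp, full.names = TRUE)[1], "raw", 200)
  expect_identical(rawToChar(buf[1:4]), "Iout")
  expect_identical(as.integer(buf[7]), 3L)   # straight-line type code
  expect_equal(readBin(buf[19:22], "numeric", size = 4, endian = "big"), 3)

  expect_error(read_roi_archive(file.path(tempdir(), "nope.zip")),
               "RoiSetLine.zip")

  paths <- c("b.tif", "a.tif", "c.tif")
  pairs <- pair_rois_with_images(rois, paths)
  expect_equal(unname(vapply(pairs, function(p) p$path, "")),
               c("a.tif", "b.tif", "c.tif"))
  expect_error(pair_rois_with_images(rois[1:2], paths), "does not match")
})
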