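test_that("volume, coverage and object count follow the definitions", {
  full <- binary_mask(array(1L, c(4, 5, 5)), c(0.5, 0.5, 2))
  vc <- compute_volume_coverage(full)
  expect_equal(vc$coverage_pct, 100)
  expect_equal(vc$volume_um3, 100 * 0.5 * 0.5 * 2)
  expect_equal(vc$n_objects, 1)
  empty <- binary_mask(array(0L, c(4, 5, 5)), c(1, 1, 1))
  vc0 <- compute_volume_coverage(empty)
  expect_equal(unlist(vc0), c(volume_um3 = 0, coverage_pct = 0,
                              n_objects = 0))
  ## digitized cylinder r=10 vox, h=50 vox, 0.5 um iso vs analytic volume
  cyl <- make_cylinder_mask(nz = 23, ny = 60, nx = 23, r_vox = 10,
                            y0 = 6, y1 = 55, voxel_size = c(0.5, 0.5, 0.5))
  v <- compute_volume_coverage(cyl)$volume_um3
  expect_equal(v, pi * 5^2 * 25, tolerance = 0.05)
})

test_that("surface voxels and S:V ratio match the neighbour-scan oracle", {
  one <- binary_mask(array(c(0L, 1L, rep(0L, 25)), c(3, 3, 3)), c(1, 1, 1))
  expect_equal(compute_surface(one)$sv_ratio, 1)
  ## solid 10^3 cube: surface = 10^3 - 8^3 = 488
  cube <- array(0L, c(12, 12, 12)); cube[2:11, 2:11, 2:11] <- 1L
  s <- compute_surface(binary_mask(cube, c(1, 1, 1)))
  expect_equal(s$surface_voxels, 488)
  expect_equal(s$surface_um3, 488)
  expect_equal(s$sv_ratio, 488 / 1000)
  ## 1-voxel sheet: everything is surface
  sheet <- array(0L, c(5, 6, 6)); sheet[3, , ] <- 1L
  expect_equal(compute_surface(binary_mask(sheet, c(1, 1, 1)))$sv_ratio, 1)
  ## border voxels count as surface
  flush <- binary_mask(array(1L, c(2, 2, 2)), c(1, 1, 1))
  expect_equal(compute_surface(flush)$sv_ratio, 1)
  expect_equal(compute_surface(binary_mask(array(0L, c(2, 2, 2)),
                                           c(1, 1, 1)))$surface_um3, 0)
})

test_that("EDM distances are physical and anisotropy-aware", {
  ## half-space: EDM at depth d rows = d * dy
  a <- array(0L, c(3, 12, 4)); a[, 3:12, ] <- 1L
  m <- binary_mask(a, c(10, 0.7, 10))   # dy small: nearest bg is along y
  edm <- compute_edm_thickness(m, skeleton = skeletonize_3d(m))$edm
  for (drow in 1:6) {
    expect_equal(edm[2, 2 + drow, 2], drow * 0.7, tolerance = 1e-9)
  }
  ## tiny brute-force oracle on a random anisotropic mask
  set.seed(31)
  b <- array(as.integer(runif(4 * 5 * 5) > 0.4), c(4, 5, 5))
  mb <- binary_mask(b, c(0.4, 0.6, 1.1))
  got <- compute_edm_thickness(mb,
                               skeleton = skeletonize_3d(mb))$edm
  bgi <- which(b == 0, arr.ind = TRUE)
  if (nrow(bgi) && any(b == 1)) {
    fgi <- which(b == 1, arr.ind = TRUE)
    for (k in seq_len(min(10, nrow(fgi)))) {
      p <- fgi[k, ]
      dists <- sqrt(((bgi[, 1] - p[1]) * 1.1)^2 +
                      ((bgi[, 2] - p[2]) * 0.6)^2 +
                      ((bgi[, 3] - p[3]) * 0.4)^2)
      expect_equal(got[p[1], p[2], p[3]], min(dists), tolerance = 1e-9)
    }
  }
  ## single voxel object
  sv <- array(0L, c(3, 3, 3)); sv[2, 2, 2] <- 1L
  msv <- binary_mask(sv, c(0.5, 0.7, 1.2))
  r <- compute_edm_thickness(msv)
  expect_lte(r$thickness_um, 0.5 + 1e-9)
  expect_equal(r$thickness_um, min(c(0.5, 0.7, 1.2)), tolerance = 1e-9)
})

test_that("cylinder thickness approximates the analytic radius", {
  cyl <- make_cylinder_mask(nz = 13, ny = 50, nx = 13, r_vox = 5,
                            y0 = 6, y1 = 45, voxel_size = c(0.5, 0.5, 0.5))
  sk <- skeletonize_3d(cyl)
  t_um <- compute_edm_thickness(cyl, sk)$thickness_um
  expect_equal(t_um, 5 * 0.5, tolerance = 0.5 / (5 * 0.5))  # within 1 voxel
})

test_that("skeletonization recovers the topology of canonical solids", {
  cyl <- make_cylinder_mask(nz = 11, ny = 70, nx = 11, r_vox = 3,
                            y0 = 6, y1 = 65)
  st <- skeleton_statistics(skeletonize_3d(cyl))
  expect_equal(st$n_trees, 1)
  expect_equal(st$n_endpoints, 2)
  expect_equal(st$n_junctions, 0)
  expect_equal(st$n_branches, 1)
  expect_equal(st$total_length_um, 59, tolerance = 0.1)  # rows 6..65 span

  y <- make_y_mask()
  sty <- skeleton_statistics(skeletonize_3d(y))
  expect_equal(sty$n_trees, 1)
  expect_equal(sty$n_endpoints, 3)
  expect_equal(sty$n_junctions, 1)
  expect_equal(sty$n_triple_points, 1)
  expect_equal(sty$n_quadruple_points, 0)
  expect_equal(sty$n_branches, 3)

  tor <- make_torus_mask()
  stt <- skeleton_statistics(skeletonize_3d(tor))
  expect_equal(stt$n_trees, 1)
  expect_equal(stt$n_endpoints, 0)
  expect_equal(stt$n_branches, 1)   # one closed cycle

  e <- skeletonize_3d(binary_mask(array(0L, c(3, 3, 3)), c(1, 1, 1)))
  se <- skeleton_statistics(e)
  expect_equal(se$sum_voxels, 0)
  expect_equal(se$n_branches, 0)
})

test_that("skeleton stats use calibrated anisotropic path lengths", {
  ## straight 11-voxel path along y, dy = 0.5 -> L = 5 um
  a <- array(0L, c(3, 15, 3)); a[2, 3:13, 2] <- 1L
  m <- binary_mask(a, c(1, 0.5, 2))
  st <- skeleton_statistics(skeletonize_3d(m))
  expect_equal(st$n_trees, 1)
  expect_equal(st$n_branches, 1)
  expect_equal(st$n_junctions, 0)
  expect_equal(st$n_endpoints, 2)
  expect_equal(st$total_length_um, 5)
  expect_equal(st$sum_voxels, 11)
  ## diagonal steps combine axes: 5 steps of sqrt(dy^2 + dx^2)
  b <- array(0L, c(3, 8, 8))
  for (k in 0:5) b[2, 2 + k, 2 + k] <- 1L
  stb <- skeleton_statistics(skeletonize_3d(binary_mask(b, c(0.3, 0.4, 1))))
  expect_equal(stb$total_length_um, 5 * sqrt(0.4^2 + 0.3^2))
})

test_that("skeleton is contained in the mask and trees match objects", {
  spec <- phantom_spec(seed = 13L)
  truth <- generate_glia_phantom(spec)$truth
  sk <- skeletonize_3d(truth$mask)
  expect_true(all(sk$voxels <= truth$mask$voxels))
  expect_equal(sk$n_trees, compute_volume_coverage(truth$mask)$n_objects)
})

test_that("unit scaling: doubling voxel size scales V and S by 8, L by 2", {
  y <- make_y_mask()
  y2 <- binary_mask(y$voxels, c(2, 2, 2))
  expect_equal(compute_volume_coverage(y2)$volume_um3,
               8 * compute_volume_coverage(y)$volume_um3)
  expect_equal(compute_surface(y2)$surface_um3,
               8 * compute_surface(y)$surface_um3)
  expect_equal(skeleton_statistics(skeletonize_3d(y2))$total_length_um,
               2 * skeleton_statistics(skeletonize_3d(y))$total_length_um)
})

test_that("pruning removes short terminal branches", {
  y <- make_y_mask()        # arm is ~15 px long
  pruned <- skeletonize_3d(y, prune_below_um = 18)
  stp <- skeleton_statistics(pruned)
  expect_equal(stp$n_junctions, 0)
  expect_equal(stp$n_endpoints, 2)
  ## default (no pruning) keeps the arm
  expect_equal(skeleton_statistics(skeletonize_3d(y))$n_junctions, 1)
})

test_that("quantify_stack produces the feature record and output tree", {
  spec <- phantom_spec(seed = 4L)
  ph <- generate_glia_phantom(spec)
  out <- file.path(tempdir(), "quant_t")
  unlink(out, recursive = TRUE)
  rec <- quantify_stack(ph$truth$mask, original = ph$image, sigma_um = 0,
                        out_dir = out, name = "ph4")
  expect_gte(rec$coverage_pct, 0); expect_lte(rec$coverage_pct, 100)
  expect_gte(rec$sv_ratio, 0); expect_lte(rec$sv_ratio, 1)
  expect_equal(rec$volume_um3, ph$truth$volume_um3)
  expect_equal(rec$n_endpoints, ph$truth$n_endpoints)
  expect_equal(rec$n_junctions, ph$truth$n_junctions)
  qr <- utils::read.csv(file.path(out, "QuantificationResults.csv"),
                        check.names = FALSE)
  expect_identical(colnames(qr)[2:5],
                   c("Volume [um3]", "PercCov [%]", "SurfaceVol [um3]",
                     "Thickness [um]"))
  ss <- utils::read.csv(file.path(out, "SkeletonStats.csv"),
                        check.names = FALSE)
  expect_true(all(c("max branch length", "mean branch length", "# of trees",
                    "# of branches", "# of junctions", "# of endpoints",
                    "# of triple points", "# of quadruple points",
                    "sum of voxels") %in% colnames(ss)))
  expect_true(dir.exists(file.path(out, "QuantEDM")))
  expect_true(dir.exists(file.path(out, "QuantSkel")))
  expect_true(file.exists(file.path(out, "QuantEDM", "MAX_EDM_ph4.tif")))
  ## non-binary input is rejected with guidance
  expect_error(quantify_stack(ph$image), "segment")
  ## empty mask: zero row with warning
  w <- testthat::capture_warnings(
    rec0 <- quantify_stack(binary_mask(array(0L, c(3, 5, 5)), c(1, 1, 1))))
  expect_true(any(grepl("empty", w)))
  expect_equal(rec0$volume_um3, 0)
  expect_equal(rec0$total_length_um, 0)
})

test_that("apicobasal texture localizes branches to their zone", {
  spec <- phantom_spec(seed = 6L)
  ph <- generate_glia_phantom(spec)
  sk <- skeletonize_3d(ph$truth$mask)
  tex <- apicobasal_texture(ph$image, ph$truth$mask, sk)
  expect_named(tex, c("original", "segmented", "skeleton"))
  expect_equal(tex$segmented$values,
               apply(ph$truth$mask$voxels, 2, mean))
  ## skeleton occupancy off the stalk is confined to the branch zone rows
  ny <- img_dim(ph$image)[2]
  zone <- round(spec$branch_zones[[1]]$row_frac * ny)
  prof <- tex$skeleton$values
  stalk_level <- stats::median(prof[prof > 0])
  elevated <- which(prof > stalk_level * 1.5)
  if (length(elevated)) {
    expect_true(all(elevated >= zone[1] - 8 & elevated <= zone[2] + 8))
  }
  sm <- binary_mask(array(0L, dim(ph$truth$mask$voxels)),
                    ph$truth$mask$voxel_size)
  expect_error(apicobasal_texture(ph$image, ph$truth$mask,
                                  skeletonize_3d(sm)), NA)
})
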