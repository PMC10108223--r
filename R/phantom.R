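#' Radial-glia phantom specification
#'
#' The stated world of the synthetic test bed: vertical radial columns
#' (stalks) spanning the apicobasal (row) axis with an ellipsoidal soma, a
#' conical basal endfoot, and straight lateral branches confined to declared
#' plexiform-like zones; intensity-coded foreground over a dim background,
#' degradable with PSF blur, exponential z decay, Poisson resampling and
#' Gaussian read noise. Rows run basal (row 0) to apical (last row), the
#' orientation produced by subregion standardization.
#'
#' All geometry is voxelized at pixel centres and the ground truth is derived
#' from the voxelized (not continuous) primitives, so exact equalities are
#' testable. One seed fixes every stochastic stage.
#'
#' @param shape `(z, y, x)` voxel extents.
#' @param voxel_size `(dx, dy, dz)` um.
#' @param n_cells number of columns, spread evenly across x.
#' @param stalk_radius_um stalk cylinder radius (um).
#' @param stalk_row_frac `(basal, apical)` row-fraction span of the stalk.
#' @param soma `(center_row_frac, rx_um, ry_um, rz_um)` ellipsoid.
#' @param endfoot `(row_frac_from, row_frac_to, radius_um)` basal cone,
#'   widening towards row 0.
#' @param branch_zones list of zones, each
#'   `list(row_frac = c(from, to), branches_per_cell = k, length_um = L,
#'   radius_um = r)`.
#' @param foreground,background intensity levels.
#' @param gaussian_sd additive Gaussian noise SD (0 = off).
#' @param poisson logical, Poisson resampling.
#' @param z_decay_tau_um exponential z-decay constant (Inf = off).
#' @param psf_blur optional [psf_params] for optical blur.
#' @param bit_depth output depth.
#' @param seed integer seed fixing all randomness.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(12L, 160L, 140L),
                         voxel_size = c(0.5, 0.5, 1.0),
                         n_cells = 2L,
                         stalk_radius_um = 1.5,
                         stalk_row_frac = c(0.06, 0.94),
                         soma = c(0.5, 2.5, 4, 2.5),
                         endfoot = c(0.06, 0.14, 3),
                         branch_zones = list(list(row_frac = c(0.25, 0.45),
                                                  branches_per_cell = 3L,
                                                  length_um = 5,
                                                  radius_um = 1.0)),
                         foreground = 200, background = 10,
                         gaussian_sd = 5, poisson = FALSE,
                         z_decay_tau_um = 50, psf_blur = NULL,
                         bit_depth = "8", seed = 1L) {
  stopifnot(all(shape >= 1), all(voxel_size > 0), n_cells >= 1,
            stalk_radius_um > 0,
            all(stalk_row_frac >= 0 & stalk_row_frac <= 1))
  structure(list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
                 n_cells = as.integer(n_cells),
                 stalk_radius_um = stalk_radius_um,
                 stalk_row_frac = stalk_row_frac,
                 soma = soma, endfoot = endfoot,
                 branch_zones = branch_zones,
                 foreground = foreground, background = background,
                 gaussian_sd = gaussian_sd, poisson = isTRUE(poisson),
                 z_decay_tau_um = z_decay_tau_um, psf_blur = psf_blur,
                 bit_depth = bit_depth, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a radial-glia phantom with ground truth
#'
#' Builds the clean intensity stack (foreground level on the voxelized cell
#' union, background elsewhere) plus the analytic ground truth: the exact
#' mask, per-cell and whole-image volume, height, skeleton length (stalk span
#' plus branch lengths), junction count (one triple point per lateral
#' branch) and endpoint count (two stalk ends plus one per branch tip).
#' Deterministic for a fixed spec; degradation is a separate step
#' ([degrade_stack]).
#'
#' @param spec a [phantom_spec].
#' @return list with `image` (clean [vol_image]), `truth` (list: `mask`
#'   [binary_mask], `per_cell`, `volume_um3`, `height_um`,
#'   `skeleton_length_um`, `n_junctions`, `n_endpoints`, `n_cells`).
#' @export
generate_glia_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape; vs <- spec$voxel_size
  nz <- sh[1]; ny <- sh[2]; nx <- sh[3]
  dx <- vs[1]; dy <- vs[2]; dz <- vs[3]
  ## voxel-centre coordinate grids (um), broadcast as (z,y,x)
  zc <- (seq_len(nz) - 1) * dz
  yc <- (seq_len(ny) - 1) * dy
  xc <- (seq_len(nx) - 1) * dx
  Z <- array(rep(zc, times = ny * nx), dim = sh)
  Y <- array(rep(rep(yc, each = nz), times = nx), dim = sh)
  X <- array(rep(xc, each = nz * ny), dim = sh)

  height_um <- (ny - 1) * dy
  z_mid <- (nz - 1) * dz / 2
  cell_x <- ((seq_len(spec$n_cells) - 0.5) / spec$n_cells) * (nx - 1) * dx

  mask <- array(FALSE, dim = sh)
  per_cell <- list()
  total_skel <- 0; total_j <- 0L; total_ep <- 0L
  y0 <- spec$stalk_row_frac[1] * height_um
  y1 <- spec$stalk_row_frac[2] * height_um

  for (ci in seq_len(spec$n_cells)) {
    cx <- cell_x[ci]
    cellm <- array(FALSE, dim = sh)
    r2 <- (X - cx)^2 + (Z - z_mid)^2
    ## stalk
    cellm <- cellm | (r2 <= spec$stalk_radius_um^2 & Y >= y0 & Y <= y1)
    ## soma (ellipsoid)
    sy <- spec$soma[1] * height_um
    cellm <- cellm | (((X - cx) / spec$soma[2])^2 +
                        ((Y - sy) / spec$soma[3])^2 +
                        ((Z - z_mid) / spec$soma[4])^2 <= 1)
    ## basal endfoot: cone widening from stalk radius to endfoot radius
    e0 <- spec$endfoot[1] * height_um; e1 <- spec$endfoot[2] * height_um
    if (e1 > e0) {
      frac <- pmin(pmax((e1 - Y) / (e1 - e0), 0), 1)
      rr <- spec$stalk_radius_um +
        frac * (spec$endfoot[3] - spec$stalk_radius_um)
      cellm <- cellm | (r2 <= rr^2 & Y >= e0 & Y <= e1)
    }
    ## lateral branches
    n_br <- 0L
    skel_len <- y1 - y0
    for (zone in spec$branch_zones) {
      k <- zone$branches_per_cell
      if (k < 1) next
      ys <- seq(zone$row_frac[1], zone$row_frac[2],
                length.out = k) * height_um
      for (b in seq_len(k)) {
        sgn <- if (b %% 2 == 0) -1 else 1
        xa <- cx; xb <- cx + sgn * zone$length_um
        lo <- min(xa, xb); hi <- max(xa, xb)
        if (lo < 0 || hi > (nx - 1) * dx) {
          stop("branch extends outside the volume; shrink length_um or grid")
        }
        cellm <- cellm | ((Y - ys[b])^2 + (Z - z_mid)^2 <= zone$radius_um^2 &
                            X >= lo & X <= hi)
        n_br <- n_br + 1L
        skel_len <- skel_len + zone$length_um
      }
    }
    mask <- mask | cellm
    per_cell[[ci]] <- list(
      x_um = cx,
      volume_um3 = sum(cellm) * prod(vs),
      skeleton_length_um = skel_len,
      n_junctions = n_br,
      n_endpoints = 2L + n_br)
    total_skel <- total_skel + skel_len
    total_j <- total_j + n_br
    total_ep <- total_ep + 2L + n_br
  }

  vox <- array(spec$background, dim = sh)
  vox[mask] <- spec$foreground
  img <- vol_image(vox, vs, spec$bit_depth,
                   name = sprintf("phantom_seed%d", spec$seed))
  mrows <- which(apply(mask, 2, any))
  truth <- list(
    mask = binary_mask(array(as.integer(mask), dim = sh), vs,
                       provenance = list(method = "phantom")),
    per_cell = per_cell,
    volume_um3 = sum(mask) * prod(vs),
    height_um = if (length(mrows)) (max(mrows) - min(mrows) + 1) * dy else 0,
    skeleton_length_um = total_skel,
    n_junctions = total_j,
    n_endpoints = total_ep,
    n_cells = spec$n_cells)
  list(image = img, truth = truth)
}

## internal: convolve a stack with a PSF (reflective padding, fft)
convolve_psf <- function(image, psf) {
  parr <- if (inherits(psf, "vol_image")) get_channel(psf) else psf
  parr <- parr / sum(parr)
  d <- img_dim(image)
  sh <- dim(parr)
  pz <- min(sh[1] %/% 2, d[1] - 1); py <- min(sh[2] %/% 2, d[2] - 1)
  px <- min(sh[3] %/% 2, d[3] - 1)
  iz <- reflect_index(d[1], pz); iy <- reflect_index(d[2], py)
  ix <- reflect_index(d[3], px)
  dims <- c(length(iz), length(iy), length(ix))
  otf <- stats::fft(embed_kernel(parr, dims))
  map_channels(image, function(a) {
    obs <- a[iz, iy, ix]
    res <- Re(stats::fft(stats::fft(obs) * otf, inverse = TRUE)) / prod(dims)
    res[pz + seq_len(d[1]), py + seq_len(d[2]), px + seq_len(d[3]),
        drop = FALSE]
  })
}

#' Degrade a clean phantom like a confocal acquisition
#'
#' Applies, in order: PSF blur (when the spec carries one), multiplicative
#' exponential z decay `exp(-z dz / tau)`, Poisson resampling (when enabled),
#' additive Gaussian noise, and clipping to the bit range. All randomness is
#' drawn from one stream seeded by `spec$seed`.
#'
#' @param image a [vol_image] (typically the clean phantom).
#' @param spec the [phantom_spec] holding the degradation parameters.
#' @return The degraded [vol_image].
#' @export
degrade_stack <- function(image, spec) {
  set.seed(spec$seed)
  out <- image
  if (!is.null(spec$psf_blur)) {
    out <- convolve_psf(out, theoretical_psf(spec$psf_blur))
  }
  tau <- spec$z_decay_tau_um
  if (is.finite(tau) && tau > 0) {
    d <- img_dim(out)
    dz <- out$voxel_size[["dz"]]
    fac <- exp(-(seq_len(d[1]) - 1) * dz / tau)
    out <- map_channels(out, function(a) {
      for (z in seq_len(d[1])) a[z, , ] <- a[z, , ] * fac[z]
      a
    })
  }
  if (spec$poisson) {
    out <- map_channels(out, function(a) {
      array(stats::rpois(length(a), lambda = pmax(a, 0)), dim = dim(a))
    })
  }
  if (spec$gaussian_sd > 0) {
    out <- map_channels(out, function(a) {
      a + array(stats::rnorm(length(a), sd = spec$gaussian_sd), dim = dim(a))
    })
  }
  hi <- switch(image$bit_depth, "8" = 255, "16" = 65535, Inf)
  out <- map_channels(out, function(a) {
    a[a < 0] <- 0
    a[a > hi] <- hi
    if (image$bit_depth == "float") a else round(a)
  })
  out
}

#' Quality-metric phantom
#'
#' A small stack carrying three labelled patches with the requested signal
#' mean, non-signal mean, and background standard deviation, plus the
#' matching oval ROI set, for end-to-end SNR/CNR tests
#' (`roi_statistics` -> `compute_cnr`/`compute_snr`).
#'
#' @param mu_s,mu_ns planted means of signal / non-signal patches.
#' @param sigma_bg planted SD of the background patch (mean 50).
#' @param seed RNG seed.
#' @return list with `image` (float [vol_image]) and `rois` (named list of
#'   [oval_roi]: `signal`, `nonSignal`, `outsideRetina`).
#' @export
generate_quality_phantom <- function(mu_s = 100, mu_ns = 20, sigma_bg = 10,
                                     seed = 1L) {
  set.seed(seed)
  sh <- c(3L, 48L, 96L)
  vox <- array(0, dim = sh)
  patch <- function(cy, cx, half, mean, sd) {
    ys <- (cy - half):(cy + half); xs <- (cx - half):(cx + half)
    vox[2, ys, xs] <<- mean + if (sd > 0) {
      stats::rnorm(length(ys) * length(xs), sd = sd)
    } else 0
  }
  patch(24, 16, 10, mu_s, 2)
  patch(24, 48, 10, mu_ns, 2)
  patch(24, 80, 10, 50, sigma_bg)
  img <- vol_image(vox, c(0.5, 0.5, 1), "float", name = "quality_phantom")
  rois <- list(
    signal = oval_roi(c(15, 23), c(7, 7), slice_index = 1L),
    nonSignal = oval_roi(c(47, 23), c(7, 7), slice_index = 1L),
    outsideRetina = oval_roi(c(79, 23), c(7, 7), slice_index = 1L))
  list(image = img, rois = rois)
}
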