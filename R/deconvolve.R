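#' Theoretical PSF parameters
#'
#' Emission-wavelength presets follow common fluorophores (GFP 510 nm,
#' dsRed 586 nm). The numerical aperture must be smaller than the immersion
#' refractive index, and all grid extents must be odd so the PSF peak sits on
#' a voxel centre.
#'
#' @param emission_wavelength_nm emission wavelength in nm (300-800).
#' @param numerical_aperture objective NA (0 < NA < n).
#' @param refractive_index immersion refractive index (default water 1.33).
#' @param voxel_size `(dx, dy, dz)` in um.
#' @param shape `(z, y, x)` extents, all odd.
#' @return A `psf_params` list.
#' @export
psf_params <- function(emission_wavelength_nm = 510,
                       numerical_aperture = 1.0,
                       refractive_index = 1.33,
                       voxel_size = c(0.05, 0.05, 0.19),
                       shape = c(17L, 33L, 33L)) {
  if (emission_wavelength_nm <= 300 || emission_wavelength_nm >= 800) {
    stop("emission wavelength must lie in (300, 800) nm")
  }
  if (numerical_aperture <= 0 || numerical_aperture >= refractive_index) {
    stop("numerical aperture must satisfy 0 < NA < refractive index")
  }
  shape <- as.integer(shape)
  if (any(shape %% 2L == 0L)) stop("PSF extents must be odd")
  structure(list(emission_wavelength_nm = emission_wavelength_nm,
                 numerical_aperture = numerical_aperture,
                 refractive_index = refractive_index,
                 voxel_size = as.numeric(voxel_size),
                 shape = shape),
            class = "psf_params")
}

#' Theoretical widefield/confocal PSF (paraxial Born-Wolf)
#'
#' Scalar-diffraction PSF sampled on the voxel grid. The in-focus lateral
#' profile is the squared Airy pattern `[2 J1(v)/v]^2` with
#' `v = 2 pi NA r / lambda`; defocus follows the paraxial pupil integral
#' `I(u, v) = |int_0^1 J0(v rho) exp(-i u rho^2 / 2) rho d rho|^2` with
#' `u = 2 pi NA^2 z / (n lambda)`. The result is normalized to sum exactly 1
#' and peaks at the centre voxel.
#'
#' @param params a [psf_params].
#' @return A float [vol_image] of the given shape.
#' @export
theoretical_psf <- function(params) {
  stopifnot(inherits(params, "psf_params"))
  lam_um <- params$emission_wavelength_nm / 1000
  na <- params$numerical_aperture
  n_imm <- params$refractive_index
  vs <- params$voxel_size
  sh <- params$shape
  cz <- (sh[1] + 1) %/% 2; cy <- (sh[2] + 1) %/% 2; cx <- (sh[3] + 1) %/% 2

  yy <- (seq_len(sh[2]) - cy) * vs[2]
  xx <- (seq_len(sh[3]) - cx) * vs[1]
  r <- sqrt(outer(yy^2, xx^2, `+`))
  v <- 2 * pi * na * r / lam_um

  ## Simpson quadrature over the pupil radius
  nq <- 129L
  rho <- seq(0, 1, length.out = nq)
  wts <- c(1, rep(c(4, 2), length.out = nq - 2), 1)
  wts[nq] <- 1
  wts <- wts * (rho[2] - rho[1]) / 3
  j0k <- lapply(seq_len(nq), function(k) besselJ(v * rho[k], 0))

  out <- array(0, dim = sh)
  for (zi in seq_len(sh[1])) {
    z_um <- (zi - cz) * vs[3]
    u <- 2 * pi * na^2 * z_um / (n_imm * lam_um)
    re <- matrix(0, sh[2], sh[3]); im <- matrix(0, sh[2], sh[3])
    for (k in seq_len(nq)) {
      ph <- u * rho[k]^2 / 2
      wrho <- wts[k] * rho[k]
      re <- re + wrho * cos(ph) * j0k[[k]]
      im <- im - wrho * sin(ph) * j0k[[k]]
    }
    out[zi, , ] <- re^2 + im^2
  }
  out <- out / sum(out)
  vol_image(out, vs, "float", name = "PSF_theoretical")
}

#' Load and renormalize an existing PSF
#'
#' Reads a user-supplied (experimental or theoretical) PSF TIFF and
#' renormalizes it to sum 1, the form [richardson_lucy] expects.
#'
#' @param path PSF TIFF path.
#' @param voxel_size optional calibration override.
#' @return A float [vol_image] summing to 1.
#' @export
load_psf <- function(path, voxel_size = NULL) {
  psf <- read_stack(path, voxel_size = voxel_size)
  a <- get_channel(psf)
  s <- sum(a)
  if (s <= 0) stop("PSF sums to zero; cannot normalize")
  vol_image(a / s, psf$voxel_size, "float", name = psf$name)
}

## circular convolution machinery: kernel embedded with its centre at the
## origin of the padded grid, so fft-based products implement conv/correlate
embed_kernel <- function(psf_arr, dims) {
  sh <- dim(psf_arr)
  if (any(sh > dims)) stop("PSF larger than padded image; cannot convolve")
  ctr <- (sh + 1) %/% 2
  k <- array(0, dim = dims)
  zi <- ((seq_len(sh[1]) - ctr[1]) %% dims[1]) + 1
  yi <- ((seq_len(sh[2]) - ctr[2]) %% dims[2]) + 1
  xi <- ((seq_len(sh[3]) - ctr[3]) %% dims[3]) + 1
  k[zi, yi, xi] <- psf_arr
  k
}

reflect_index <- function(n, p) {
  if (p >= n) stop("image too small for reflective padding by ", p)
  c(if (p > 0) p:1 else integer(0), seq_len(n),
    if (p > 0) n:(n - p + 1) else integer(0))
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative RL update applied `iterations` times (default 1,
#' the protocol's setting for confocal pre-processing). Boundaries are
#' handled by reflective padding by half the PSF extent; the output is
#' non-negative, clipped to the input bit range, and has the input shape.
#'
#' @param image a [vol_image] with non-negative intensities.
#' @param psf PSF as a [vol_image] or 3D array; must sum to 1 (within 1e-6).
#' @param iterations non-negative integer; 0 returns the input unchanged.
#' @return The deconvolved [vol_image] (float for float input, else the
#'   original integer depth).
#' @export
richardson_lucy <- function(image, psf, iterations = 1L) {
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 0)
  if (iterations == 0L) return(image)
  parr <- if (inherits(psf, "vol_image")) get_channel(psf) else psf
  s <- sum(parr)
  if (s <= 0) stop("all-zero PSF")
  if (abs(s - 1) > 1e-6) stop("PSF must be normalized to sum 1 (see load_psf)")
  d <- img_dim(image)
  sh <- dim(parr)
  pz <- sh[1] %/% 2; py <- sh[2] %/% 2; px <- sh[3] %/% 2
  iz <- reflect_index(d[1], pz); iy <- reflect_index(d[2], py)
  ix <- reflect_index(d[3], px)
  dims <- c(length(iz), length(iy), length(ix))
  otf <- stats::fft(embed_kernel(parr, dims))
  npx <- prod(dims)
  cv <- function(x, tf) Re(stats::fft(stats::fft(x) * tf, inverse = TRUE)) / npx
  eps <- 1e-12

  out <- map_channels(image, function(a) {
    obs <- a[iz, iy, ix]
    est <- pmax(obs, eps)
    for (it in seq_len(iterations)) {
      denom <- cv(est, otf)
      ratio <- obs / pmax(denom, eps)
      est <- est * cv(ratio, Conj(otf))
      est[est < 0] <- 0
    }
    res <- est[pz + seq_len(d[1]), py + seq_len(d[2]), px + seq_len(d[3]),
               drop = FALSE]
    hi <- switch(image$bit_depth, "8" = 255, "16" = 65535, Inf)
    res[res > hi] <- hi
    if (image$bit_depth == "float") res else round(res)
  })
  out
}
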