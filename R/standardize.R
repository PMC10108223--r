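#' Subregion extraction parameters
#'
#' Defaults follow the published tool GUI: output width 60 um (spans roughly
#' 5-6 Muller glia laterally), output depth 10 um (1-2 cells), sigma 10 um of
#' extra length beyond the basal ROI end to accommodate retinal curvature and
#' the vasculature underlying the endfeet.
#'
#' @param width_um output width in um (`xySize`).
#' @param depth_um output depth in um (`zDepth`).
#' @param sigma_um basal extension in um.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return A `subregion_params` list.
#' @export
subregion_params <- function(width_um = 60, depth_um = 10, sigma_um = 10,
                             interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(width_um > 0, depth_um > 0, sigma_um >= 0)
  structure(list(width_um = width_um, depth_um = depth_um,
                 sigma_um = sigma_um, interpolation = interpolation),
            class = "subregion_params")
}

#' Rotate a stack by 90 degrees in x-y
#'
#' A lossless index permutation applied per slice (for non-square
#' acquisitions, e.g. 512 x 1920, applied before subregion extraction so the
#' apicobasal axis can be made vertical). x/y dimensions and the dx/dy
#' calibration are swapped.
#'
#' @param image a [vol_image].
#' @param direction `"clockwise"` or `"anticlockwise"`.
#' @return The rotated [vol_image].
#' @export
rotate90 <- function(image, direction = c("clockwise", "anticlockwise")) {
  direction <- match.arg(direction)
  d <- img_dim(image)
  out <- map_channels(image, function(a) {
    b <- array(0, dim = c(d[1], d[3], d[2]))
    for (z in seq_len(d[1])) {
      m <- matrix(a[z, , ], nrow = d[2], ncol = d[3])
      b[z, , ] <- if (direction == "clockwise") {
        t(m)[, d[2]:1, drop = FALSE]        # out[i,j] = m[H-j+1, i]
      } else {
        t(m)[d[3]:1, , drop = FALSE]        # out[i,j] = m[j, W-i+1]
      }
    }
    b
  })
  vs <- image$voxel_size
  out$voxel_size <- stats::setNames(c(vs[["dy"]], vs[["dx"]], vs[["dz"]]),
                                    c("dx", "dy", "dz"))
  out
}

## bilinear / nearest sampling of a (y,x) slice at fractional 0-based coords,
## zero fill outside the slice
sample_slice <- function(sl, xs, ys, method) {
  h <- nrow(sl); w <- ncol(sl)
  if (method == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- numeric(length(xs))
    v[ok] <- sl[cbind(yi[ok] + 1, xi[ok] + 1)]
    return(v)
  }
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  gv <- function(yi, xi) {
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- numeric(length(xi))
    v[ok] <- sl[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  gv(y0, x0) * (1 - fx) * (1 - fy) +
    gv(y0, x0 + 1) * fx * (1 - fy) +
    gv(y0 + 1, x0) * (1 - fx) * fy +
    gv(y0 + 1, x0 + 1) * fx * fy
}

subregion_geometry <- function(image, roi, params) {
  vs <- image$voxel_size
  dx <- vs[["dx"]]; dy <- vs[["dy"]]; dz <- vs[["dz"]]
  if (abs(dx - dy) / dy > 1e-3) {
    warning("in-plane rotation assumes dx == dy; using dy along the axis")
  }
  L_px <- roi_length_px(roi)
  if (L_px <= 0) stop("degenerate line ROI")
  L_um <- L_px * dy
  rows <- as.integer(ceiling((L_um + params$sigma_um) / dy))
  cols <- as.integer(ceiling(params$width_um / dx))
  nz_out <- as.integer(ceiling(params$depth_um / dz))
  u <- (roi$end - roi$start) / L_px       # basal -> apical, maps to +row
  list(rows = rows, cols = cols, nz_out = nz_out,
       u = u, w = c(u[2], -u[1]),
       sigma_px = params$sigma_um / dy, start = roi$start)
}

extract_subregion_core <- function(image, roi, params, z_start, nz_out) {
  g <- subregion_geometry(image, roi, params)
  d <- img_dim(image)
  ## source coordinates for the full output grid (0-based px)
  r <- rep(seq_len(g$rows) - 1, times = g$cols)
  cc <- rep(seq_len(g$cols) - 1, each = g$rows)
  a <- r - g$sigma_px                      # axial offset from ROI start
  b <- cc - (g$cols - 1) / 2               # lateral offset from the ROI line
  xs <- g$start[1] + g$u[1] * a + g$w[1] * b
  ys <- g$start[2] + g$u[2] * a + g$w[2] * b
  zs <- z_start + seq_len(nz_out)          # 1-based input slices
  out <- map_channels(image, function(arr) {
    o <- array(0, dim = c(nz_out, g$rows, g$cols))
    for (k in seq_along(zs)) {
      z <- zs[k]
      if (z < 1 || z > d[1]) next
      sl <- matrix(arr[z, , ], nrow = d[2], ncol = d[3])
      o[k, , ] <- matrix(sample_slice(sl, xs, ys, params$interpolation),
                         nrow = g$rows, ncol = g$cols)
    }
    o
  })
  out$name <- image$name
  out
}

#' Standardize a stack to the apicobasal frame
#'
#' Rotates each slice about the ROI midpoint so the line ROI (drawn basal to
#' apical) becomes vertical with the basal side at row 0, then crops to a
#' fixed physical size: `ceil((L + sigma)/dy)` rows (the sigma extension lies
#' beyond the basal ROI end, i.e. the ROI start sits `sigma/dy` rows into the
#' output), `ceil(width/dx)` columns centred on the ROI line, and
#' `ceil(depth/dz)` slices starting at slice 0. Out-of-bounds regions are
#' zero-filled, so the output shape is a pure function of
#' `(params, voxel_size, ROI length)` -- the point of the tool is that stacks
#' of a batch come out the same size.
#'
#' @param image a [vol_image].
#' @param roi a [line_roi] (start = basal/inner, end = apical/outer).
#' @param params a [subregion_params].
#' @return The standardized [vol_image].
#' @export
extract_subregion <- function(image, roi, params = subregion_params()) {
  d <- img_dim(image)
  nz_out <- as.integer(ceiling(params$depth_um / image$voxel_size[["dz"]]))
  if (nz_out > d[1]) {
    warning("requested depth exceeds stack (", nz_out, " > ", d[1],
            " slices); truncating")
    nz_out <- d[1]
  }
  extract_subregion_core(image, roi, params, z_start = 0L, nz_out = nz_out)
}

#' Subregion extraction centred within the stack
#'
#' As [extract_subregion], but for ROIs drawn on a slice inside a large
#' stack: the z window of `ceil(depth/dz)` slices is centred on the ROI's
#' `slice_index` and shifted minimally so it fits inside the stack.
#'
#' @inheritParams extract_subregion
#' @return The standardized [vol_image].
#' @export
extract_subregion_within_stack <- function(image, roi,
                                           params = subregion_params()) {
  d <- img_dim(image)
  if (is.null(roi$slice_index)) stop("ROI has no slice_index")
  zc <- as.integer(roi$slice_index)
  if (zc < 0L || zc >= d[1]) stop("ROI slice_index out of range")
  nz_out <- as.integer(ceiling(params$depth_um / image$voxel_size[["dz"]]))
  if (nz_out >= d[1]) {
    z_start <- 0L
    nz_out <- d[1]
  } else {
    z_start <- zc - nz_out %/% 2L
    z_start <- max(0L, min(z_start, d[1] - nz_out))
  }
  extract_subregion_core(image, roi, params, z_start = z_start,
                         nz_out = nz_out)
}
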