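#' Calibrated volumetric image
#'
#' The universal currency of the pipeline: a 3D (optionally multi-channel)
#' intensity stack with physical voxel calibration. Voxel grids are stored as
#' R arrays with dimension order `(z, y, x)` (slice, row, column); all
#' micrometre-scaled outputs use the calibration `(dx, dy, dz)` explicitly.
#'
#' @param voxels 3D numeric array, dimension `(z, y, x)`, or a 2D matrix
#'   (interpreted as a single slice `(y, x)`).
#' @param voxel_size numeric length-3, physical voxel size `(dx, dy, dz)` in
#'   micrometres.
#' @param bit_depth one of `"8"`, `"16"`, `"float"`.
#' @param name source identifier carried through the pipeline (drives output
#'   file naming).
#' @param channels optional list of further per-channel grids sharing the
#'   shape of `voxels`; `voxels` itself is channel 1.
#'
#' @return An object of class `vol_image` with fields `channels` (list of 3D
#'   arrays), `voxel_size`, `bit_depth`, `name`.
#' @export
vol_image <- function(voxels, voxel_size = c(1, 1, 1), bit_depth = "16",
                      name = "stack", channels = NULL) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, nrow(voxels), ncol(voxels)))
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  bit_depth <- match.arg(as.character(bit_depth), c("8", "16", "float"))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel_size must be three positive values (dx, dy, dz) in um")
  }
  chans <- c(list(voxels), if (is.null(channels)) list() else channels)
  shapes <- vapply(chans, function(a) paste(dim(a), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("all channel grids must share the same shape")
  }
  if (bit_depth != "float") {
    for (a in chans) {
      if (any(a < 0)) stop("integer bit depths require non-negative intensities")
    }
  }
  structure(
    list(channels = chans,
         voxel_size = stats::setNames(voxel_size, c("dx", "dy", "dz")),
         bit_depth = bit_depth,
         name = name),
    class = "vol_image")
}

#' @export
print.vol_image <- function(x, ...) {
  d <- img_dim(x)
  cat(sprintf("<vol_image> '%s': %d x %d x %d (z,y,x), %d channel(s), %s-bit\n",
              x$name, d[1], d[2], d[3], n_channels(x), x$bit_depth))
  vs <- x$voxel_size
  cat(sprintf("  voxel size %.6g x %.6g x %.6g um (dx,dy,dz)\n",
              vs[1], vs[2], vs[3]))
  invisible(x)
}

#' Image dimensions as (z, y, x)
#' @param image a `vol_image`
#' @return integer length-3 vector `(nz, ny, nx)`.
#' @export
img_dim <- function(image) dim(image$channels[[1L]])

#' Number of channels
#' @param image a `vol_image`
#' @return integer count.
#' @export
n_channels <- function(image) length(image$channels)

#' Extract one channel grid
#' @param image a `vol_image`
#' @param ch channel index (1-based)
#' @return 3D array `(z, y, x)`.
#' @export
get_channel <- function(image, ch = 1L) {
  if (ch < 1L || ch > n_channels(image)) stop("channel index out of range")
  image$channels[[ch]]
}

## apply f to every channel grid, keeping metadata
map_channels <- function(image, f, ...) {
  image$channels <- lapply(image$channels, f, ...)
  image
}

#' Maximum intensity projection (MIP)
#'
#' Per-(y,x) maximum over z, computed per channel. The result keeps the
#' calibration and is named with the conventional `MAX_` prefix.
#'
#' @param image a `vol_image` with at least one slice.
#' @return A single-slice `vol_image` named `MAX_<name>`.
#' @export
max_projection <- function(image) {
  out <- map_channels(image, function(a) {
    d <- dim(a)
    m <- apply(a, c(2L, 3L), max)
    array(m, dim = c(1L, d[2], d[3]))
  })
  out$name <- paste0("MAX_", sub("^MAX_", "", image$name))
  out
}

#' Split a multi-channel stack into single-channel stacks
#'
#' Each channel becomes its own `vol_image` named `XC-<name>` where `X` is the
#' 1-based channel number. When `out_dir` is given, channel `X` is written to
#' the sub-folder `XCDir` (the folder convention of the original toolkit).
#'
#' @param image a `vol_image` with 1--4 channels.
#' @param out_dir optional directory under which `XCDir` folders are created.
#' @return A list of single-channel `vol_image` objects, invisibly paths when
#'   written.
#' @export
split_channels <- function(image, out_dir = NULL) {
  nc <- n_channels(image)
  if (nc > 4L) stop("unsupported channel count: ", nc, " (1-4 supported)")
  out <- lapply(seq_len(nc), function(i) {
    vol_image(image$channels[[i]], image$voxel_size, image$bit_depth,
              name = sprintf("%dC-%s", i, image$name))
  })
  if (!is.null(out_dir)) {
    for (i in seq_len(nc)) {
      d <- file.path(out_dir, sprintf("%dCDir", i))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_stack(out[[i]], file.path(d, paste0(out[[i]]$name, ".tif")))
    }
  }
  out
}

#' Convert a stack to 8-bit
#'
#' Linear map of the whole-stack `[min, max]` (across all channels) to
#' `[0, 255]` with round-half-up. A constant stack maps to 0 (degenerate case,
#' documented).
#'
#' @param image a `vol_image`.
#' @return An 8-bit `vol_image`.
#' @export
convert_8bit <- function(image) {
  lo <- min(vapply(image$channels, min, 0))
  hi <- max(vapply(image$channels, max, 0))
  out <- map_channels(image, function(a) {
    if (hi > lo) {
      array(floor(255 * (a - lo) / (hi - lo) + 0.5), dim = dim(a))
    } else {
      array(0, dim = dim(a))
    }
  })
  out$bit_depth <- "8"
  out
}
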