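#' Apicobasal intensity profile
#'
#' Collapses a standardized stack to the 1D vector
#' `values[y] = mean over all (z, x) at row y`, the apicobasal texture
#' readout. Works identically on intensity stacks, binary masks (profile =
#' per-row foreground fraction) and skeleton images. Profiles are computed
#' basal-to-apical (row 0 first) and carry their orientation so apical-first
#' plots are a presentation flip, not a recomputation.
#'
#' @param x a [vol_image] or [binary_mask].
#' @return A `zonation_profile`: list with `values`, `spacing_um` (dy),
#'   `orientation`, `name`.
#' @export
apicobasal_profile <- function(x) {
  if (inherits(x, "binary_mask")) {
    a <- x$voxels
    dy <- x$voxel_size[["dy"]]
    nm <- "mask"
  } else {
    a <- get_channel(x)
    dy <- x$voxel_size[["dy"]]
    nm <- x$name
  }
  vals <- vapply(seq_len(dim(a)[2]), function(y) mean(a[, y, ]), 0)
  structure(list(values = vals, spacing_um = dy,
                 orientation = "basal_to_apical", name = nm),
            class = "zonation_profile")
}

#' Rescale a profile to a common length
#'
#' Linear resampling to exactly `target_rows` values with endpoints mapped to
#' endpoints, so stacks of different heights become comparable.
#'
#' @param profile a `zonation_profile`.
#' @param target_rows integer >= 2.
#' @return The resampled `zonation_profile` (with `normalized_length` set).
#' @export
normalize_profile <- function(profile, target_rows) {
  target_rows <- as.integer(target_rows)
  stopifnot(target_rows >= 2L)
  n <- length(profile$values)
  if (n < 2L) stop("cannot resample a length-1 profile")
  out <- stats::approx(x = seq(0, 1, length.out = n), y = profile$values,
                       xout = seq(0, 1, length.out = target_rows))$y
  profile$spacing_um <- profile$spacing_um * (n - 1) / (target_rows - 1)
  profile$values <- out
  profile$normalized_length <- target_rows
  profile
}

#' Image and cell heights along the apicobasal axis
#'
#' `I_N` is the total image height `rows * dy`; the tissue (retina) height is
#' `I_N - sigma_um` (subtracting the basal extension added during subregion
#' extraction); `MG_N` is the radial extension of the cells, i.e. the row
#' extent of the mask foreground times `dy`.
#'
#' @param x a [binary_mask] (or [vol_image]; nonzero voxels count as
#'   foreground for `MG_N`).
#' @param sigma_um the sigma used during subregion extraction (um).
#' @return list with `image_height_um` (I_N), `retina_height_um`,
#'   `mg_height_um` (MG_N).
#' @export
measure_heights <- function(x, sigma_um = 0) {
  if (inherits(x, "binary_mask")) {
    a <- x$voxels; dy <- x$voxel_size[["dy"]]
  } else {
    a <- get_channel(x); dy <- x$voxel_size[["dy"]]
  }
  rows <- dim(a)[2]
  i_n <- rows * dy
  fg_rows <- which(apply(a > 0, 2, any))
  mg <- if (length(fg_rows)) {
    (max(fg_rows) - min(fg_rows) + 1) * dy
  } else {
    warning("empty mask: MG height reported as 0")
    0
  }
  list(image_height_um = i_n, retina_height_um = i_n - sigma_um,
       mg_height_um = mg)
}

## fire-style LUT (black -> purple -> red -> orange -> white), 256 x 3 in 0..255
fire_lut <- function() {
  anchors_x <- c(0, 0.25, 0.5, 0.75, 1)
  anchors <- rbind(c(0, 0, 0), c(120, 0, 160), c(230, 60, 0),
                   c(255, 180, 0), c(255, 255, 255))
  x <- seq(0, 1, length.out = 256)
  sapply(1:3, function(ch) {
    stats::approx(anchors_x, anchors[, ch], xout = x)$y
  })
}

#' Export zonation profiles
#'
#' Writes, into `<out_dir>/ZonationTool/`: `ZonationToolProfiles.csv` (one
#' named column per image, one row per apicobasal position; profiles of mixed
#' length are padded with empty cells, with a warning), `ZonationResults.csv`
#' (height measurements when supplied), and one fire-colormap strip TIFF per
#' profile.
#'
#' @param profiles list of `zonation_profile` objects (names used as column
#'   headers; falls back to each profile's `name`).
#' @param out_dir parent output directory.
#' @param results optional data.frame of measurements for
#'   `ZonationResults.csv`.
#' @return The `ZonationTool` directory path, invisibly.
#' @export
export_zonation <- function(profiles, out_dir, results = NULL) {
  stopifnot(length(profiles) >= 1)
  zdir <- file.path(out_dir, "ZonationTool")
  dir.create(zdir, recursive = TRUE, showWarnings = FALSE)
  nms <- names(profiles)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(profiles, function(p) p$name, "")
    nms <- make.unique(nms)
  }
  lens <- vapply(profiles, function(p) length(p$values), 0L)
  n <- max(lens)
  if (length(unique(lens)) > 1L) {
    warning("profiles have mixed lengths; padding CSV columns with empty ",
            "cells (consider normalize_profile)")
  }
  cols <- lapply(profiles, function(p) {
    c(p$values, rep(NA_real_, n - length(p$values)))
  })
  df <- as.data.frame(cols, col.names = nms, check.names = FALSE)
  utils::write.csv(df, file.path(zdir, "ZonationToolProfiles.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(results)) {
    utils::write.csv(results, file.path(zdir, "ZonationResults.csv"),
                     row.names = FALSE)
  }
  lut <- fire_lut()
  for (i in seq_along(profiles)) {
    v <- profiles[[i]]$values
    rng <- range(v)
    v8 <- if (diff(rng) > 0) round(255 * (v - rng[1]) / diff(rng)) else v * 0
    strip <- matrix(rep(v8, each = 12), nrow = length(v8), ncol = 12,
                    byrow = TRUE)
    write_palette_tiff(strip, file.path(zdir, paste0(nms[i], "_zonation.tif")),
                       lut)
  }
  invisible(zdir)
}
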