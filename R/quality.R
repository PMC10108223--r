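#' ROI presets for quality measurement
#'
#' The protocol suggests oval ROI sizes for Muller-glia compartments: cell
#' body 5 x 5 um, protrusion 2 x 5 um, endfoot 5 x 3 um. These ship as named
#' presets converted to pixel radii via the image calibration.
#'
#' @param label one of `"cellBody"`, `"protrusion"`, `"endfoot"`.
#' @param center `(x, y)` centre in pixels.
#' @param voxel_size `(dx, dy, dz)` in um.
#' @param slice_index 0-based slice.
#' @return An [oval_roi] with radii in pixels.
#' @export
roi_preset <- function(label = c("cellBody", "protrusion", "endfoot"),
                       center, voxel_size, slice_index = 0L) {
  label <- match.arg(label)
  size_um <- switch(label,
                    cellBody = c(5, 5), protrusion = c(2, 5),
                    endfoot = c(5, 3))
  oval_roi(center, radii = size_um / 2 / voxel_size[1:2],
           slice_index = slice_index)
}

#' Pixel statistics inside an oval ROI
#'
#' Mean/standard deviation over the pixels of one slice whose centres satisfy
#' the inclusive ellipse inequality
#' `((x-cx)/rx)^2 + ((y-cy)/ry)^2 <= 1`. Measurement is single-slice by
#' design (matching histogram measurement on the selected slice only).
#'
#' @param image a [vol_image] (channel 1 is measured).
#' @param roi an [oval_roi]; `slice_index` selects the slice (0-based).
#' @param roi_label optional label carried into reports.
#' @return A list with `mean`, `std` (population SD), `n_pixels`, `roi_label`.
#' @export
roi_statistics <- function(image, roi, roi_label = "custom") {
  stopifnot(inherits(roi, "oval_roi"))
  d <- img_dim(image)
  z <- roi$slice_index + 1L
  if (z < 1L || z > d[1]) stop("ROI slice_index out of range")
  sl <- get_channel(image)[z, , , drop = TRUE]
  sl <- matrix(sl, nrow = d[2], ncol = d[3])
  cx <- roi$center[1]; cy <- roi$center[2]
  rx <- roi$radii[1]; ry <- roi$radii[2]
  xs <- (seq_len(d[3]) - 1 - cx) / rx      # pixel centres, 0-based coords
  ys <- (seq_len(d[2]) - 1 - cy) / ry
  member <- outer(ys^2, xs^2, `+`) <= 1
  n <- sum(member)
  if (n == 0L) stop("oval ROI covers no pixel (fully outside image?)")
  v <- sl[member]
  list(mean = mean(v),
       std = sqrt(sum((v - mean(v))^2) / n),
       n_pixels = n,
       roi_label = roi_label)
}

#' Contrast-to-noise ratio
#'
#' `CNR = (mu_s - mu_ns) / sigma_bg`, where `mu_s` is the mean signal,
#' `mu_ns` the mean non-signal (background inside the tissue), and `sigma_bg`
#' the standard deviation of the background outside the tissue.
#'
#' @param mu_s,mu_ns,sigma_bg scalars as above.
#' @return CNR (float).
#' @export
compute_cnr <- function(mu_s, mu_ns, sigma_bg) {
  if (!is.finite(sigma_bg) || sigma_bg <= 0) {
    stop("CNR undefined: sigma_bg must be > 0")
  }
  (mu_s - mu_ns) / sigma_bg
}

#' Signal-to-noise ratio (plain difference)
#'
#' `SNR = mu_s - mu_ns`, implemented verbatim as the protocol defines it: a
#' difference of means, not the conventional ratio with a noise denominator.
#' This is deliberate -- do not "fix" it silently; use [compute_cnr] when a
#' noise-normalized quantity is needed.
#'
#' @param mu_s,mu_ns mean signal and mean non-signal.
#' @return SNR (float).
#' @export
compute_snr <- function(mu_s, mu_ns) mu_s - mu_ns

#' Per-slice mean intensity profile along z
#'
#' Returns the mean intensity of every z slice plus a least-squares
#' exponential decay constant `tau` (um) fitted to `log` of the positive
#' slice means -- a quantitative stand-in for the visual z-decay inspection.
#' The fit is an addition of this package and is labelled as such in reports.
#'
#' @param image a [vol_image].
#' @return list with `means` (length nz), `z_um` (slice depths), `tau_um`
#'   (`Inf` for flat/no-decay profiles, `NA` when undefined).
#' @export
z_profile <- function(image) {
  a <- get_channel(image)
  nz <- dim(a)[1]
  means <- vapply(seq_len(nz), function(z) mean(a[z, , ]), 0)
  dz <- image$voxel_size[["dz"]]
  z_um <- (seq_len(nz) - 1) * dz
  tau <- NA_real_
  pos <- means > 0
  if (sum(pos) >= 2) {
    fit <- stats::lm.fit(cbind(1, z_um[pos]), log(means[pos]))
    slope <- fit$coefficients[2]
    tau <- if (is.na(slope) || slope >= -1e-12) Inf else -1 / slope
  }
  list(means = means, z_um = z_um, tau_um = unname(tau))
}

#' Quality report for one stack
#'
#' Combines per-ROI statistics, SNR/CNR and the z profile into one record,
#' optionally written as CSV (per-ROI rows plus a summary row).
#'
#' @param image a [vol_image].
#' @param signal_roi oval ROI on the structure of interest (`mu_s`).
#' @param nonsignal_roi oval ROI on tissue background (`mu_ns`).
#' @param background_roi oval ROI outside the tissue (`sigma_bg`).
#' @param csv optional output CSV path.
#' @return list with `snr`, `cnr`, `rois` (list of stats), `z_profile`.
#' @export
quality_report <- function(image, signal_roi, nonsignal_roi, background_roi,
                           csv = NULL) {
  s <- roi_statistics(image, signal_roi, "signal")
  ns <- roi_statistics(image, nonsignal_roi, "nonSignal")
  bg <- roi_statistics(image, background_roi, "outsideRetina")
  rep <- list(snr = compute_snr(s$mean, ns$mean),
              cnr = compute_cnr(s$mean, ns$mean, bg$std),
              rois = list(signal = s, nonSignal = ns, outsideRetina = bg),
              z_profile = z_profile(image))
  if (!is.null(csv)) {
    df <- data.frame(
      roi_label = c(s$roi_label, ns$roi_label, bg$roi_label, "summary"),
      mean = c(s$mean, ns$mean, bg$mean, NA),
      std = c(s$std, ns$std, bg$std, NA),
      n_pixels = c(s$n_pixels, ns$n_pixels, bg$n_pixels, NA),
      snr = c(NA, NA, NA, rep$snr),
      cnr = c(NA, NA, NA, rep$cnr))
    utils::write.csv(df, csv, row.names = FALSE)
  }
  rep
}
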