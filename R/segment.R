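#' Binary segmentation mask
#'
#' Foreground/background labelling of a stack (`1` = cell voxels, `0` =
#' background) with calibration and a provenance record (method and
#' parameters that produced it).
#'
#' @param voxels 3D array of 0/1 (or logical).
#' @param voxel_size `(dx, dy, dz)` in um.
#' @param provenance named list describing the producing method.
#' @return A `binary_mask`.
#' @export
binary_mask <- function(voxels, voxel_size, provenance = list()) {
  if (is.logical(voxels)) voxels <- array(as.integer(voxels), dim = dim(voxels))
  stopifnot(length(dim(voxels)) == 3L)
  if (!all(voxels %in% c(0L, 1L))) stop("mask values must be 0/1")
  structure(list(voxels = voxels,
                 voxel_size = stats::setNames(as.numeric(voxel_size),
                                              c("dx", "dy", "dz")),
                 provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d (z,y,x), %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' Convert a mask to a writable image
#'
#' Masks are stored 0/1 in memory but written as 0/255 8-bit TIFFs for
#' viewer compatibility.
#' @param mask a [binary_mask].
#' @return An 8-bit [vol_image] with values 0/255.
#' @export
mask_to_image <- function(mask, name = "mask") {
  vol_image(mask$voxels * 255L, mask$voxel_size, "8", name = name)
}

#' Segmentation parameters
#'
#' @param median_radius_vox `(rz, ry, rx)` box radii of the 3D median filter
#'   (0 = off).
#' @param rolling_ball_radius_px slice-wise rolling-ball background radius in
#'   pixels (0 = off).
#' @param method one of `"otsu"`, `"moments"`, `"percentile"`,
#'   `"max_entropy"`, `"hysteresis"`, `"simple3d"`.
#' @param hysteresis_low_frac low threshold as a fraction of the high one.
#' @param min_object_vox components smaller than this are removed as
#'   speckles.
#' @param percentile_target target foreground-complement fraction of the
#'   percentile method.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(median_radius_vox = c(0L, 0L, 0L),
                                rolling_ball_radius_px = 0L,
                                method = "otsu",
                                hysteresis_low_frac = 0.5,
                                min_object_vox = 27L,
                                percentile_target = 0.5) {
  stopifnot(all(median_radius_vox >= 0), rolling_ball_radius_px >= 0,
            hysteresis_low_frac > 0, hysteresis_low_frac <= 1,
            percentile_target > 0, percentile_target < 1)
  structure(list(median_radius_vox = as.integer(median_radius_vox),
                 rolling_ball_radius_px = as.integer(rolling_ball_radius_px),
                 method = method,
                 hysteresis_low_frac = hysteresis_low_frac,
                 min_object_vox = as.integer(min_object_vox),
                 percentile_target = percentile_target),
            class = "segmentation_params")
}

#' Pre-process a stack for segmentation
#'
#' 3D median filter (box neighbourhood, truncated at borders) followed by
#' slice-wise rolling-ball background subtraction (grayscale opening with a
#' ball structuring element, subtracted and clipped at 0). Either stage is
#' skipped when its radius is 0.
#'
#' @param image a [vol_image].
#' @param params a [segmentation_params].
#' @return The filtered [vol_image].
#' @export
preprocess_stack <- function(image, params = segmentation_params()) {
  r <- params$median_radius_vox
  out <- image
  if (any(r > 0)) {
    out <- map_channels(out, function(a) {
      array(cpp_median3d(as.numeric(a), dim(a), r[1], r[2], r[3]),
            dim = dim(a))
    })
  }
  if (params$rolling_ball_radius_px > 0) {
    rb <- params$rolling_ball_radius_px
    out <- map_channels(out, function(a) {
      d <- dim(a)
      for (z in seq_len(d[1])) {
        sl <- matrix(a[z, , ], d[2], d[3])
        bg <- cpp_rollball(sl, rb)
        a[z, , ] <- pmax(sl - bg, 0)
      }
      a
    })
  }
  out
}

## 256-bin histogram of the (8-bit converted) stack
hist256 <- function(image) {
  img8 <- if (image$bit_depth == "8") image else convert_8bit(image)
  v <- as.integer(get_channel(img8))
  list(counts = tabulate(v + 1L, nbins = 256L), img8 = img8)
}

## threshold criteria on a 256-bin histogram; threshold T means fg = value > T
threshold_from_hist <- function(counts, method, percentile_target = 0.5) {
  n <- sum(counts)
  p <- counts / n
  lev <- 0:255
  nz <- which(counts > 0) - 1L
  if (length(nz) < 2L) {
    stop("no valid threshold: image is constant (single gray level)")
  }
  cumw <- cumsum(p)
  cumm <- cumsum(p * lev)
  mu_t <- cumm[256]
  cand <- 0:254
  ok <- cumw[cand + 1] > 0 & cumw[cand + 1] < 1
  cand <- cand[ok]
  ## plateau-aware argmax: flat criteria (e.g. a two-mode histogram, where
  ## every threshold in the gap is optimal) resolve to the plateau midpoint
  pick <- function(crit, maximize = TRUE) {
    if (!maximize) crit <- -crit
    best <- max(crit)
    at <- cand[crit >= best - 1e-12 * max(1, abs(best))]
    ## midpoint of the first contiguous run of optima
    run_end <- which(diff(at) > 1L)
    at <- at[seq_len(if (length(run_end)) run_end[1] else length(at))]
    as.integer(floor(stats::median(at)))
  }
  if (method == "otsu") {
    w0 <- cumw[cand + 1]
    m0 <- cumm[cand + 1] / w0
    m1 <- (mu_t - cumm[cand + 1]) / (1 - w0)
    return(pick(w0 * (1 - w0) * (m0 - m1)^2))
  }
  if (method == "percentile") {
    return(pick(abs(cumw[cand + 1] - percentile_target), maximize = FALSE))
  }
  if (method == "max_entropy") {
    crit <- vapply(cand, function(t) {
      p0 <- p[1:(t + 1)]; p1 <- p[(t + 2):256]
      w0 <- sum(p0); w1 <- sum(p1)
      if (w0 <= 0 || w1 <= 0) return(-Inf)
      q0 <- p0[p0 > 0] / w0; q1 <- p1[p1 > 0] / w1
      -sum(q0 * log(q0)) - sum(q1 * log(q1))
    }, 0)
    return(pick(crit))
  }
  if (method == "moments") {
    m1 <- sum(p * lev); m2 <- sum(p * lev^2); m3 <- sum(p * lev^3)
    cd <- m2 - m1^2
    c0 <- (-m2^2 + m1 * m3) / cd
    c1 <- (-m3 + m2 * m1) / cd
    z0 <- 0.5 * (-c1 - sqrt(c1^2 - 4 * c0))
    z1 <- 0.5 * (-c1 + sqrt(c1^2 - 4 * c0))
    pfrac <- (z1 - m1) / (z1 - z0)    # fraction of the population below z
    return(pick(abs(cumw[cand + 1] - pfrac), maximize = FALSE))
  }
  stop("unknown threshold method: ", method)
}

#' Global histogram thresholding
#'
#' Computes a single global threshold `T` from the whole-stack 256-bin
#' histogram (8-bit conversion applied first when needed; the methods are
#' defined on 8-bit histograms) and returns the mask `image > T`. Criteria:
#' Otsu maximizes the between-class variance, Moments preserves the first
#' three gray-level moments (Tsai), Percentile picks the cumulative fraction
#' closest to `percentile_target` (default 0.5), Max-Entropy maximizes the
#' summed class entropies (Kapur-Sahoo-Wong). Ties resolve to the lowest
#' candidate threshold.
#'
#' @param image a [vol_image].
#' @param method `"otsu"`, `"moments"`, `"percentile"` or `"max_entropy"`.
#' @param percentile_target see above.
#' @return list with `threshold` (on the 8-bit scale) and `mask`
#'   ([binary_mask]).
#' @export
global_threshold <- function(image,
                             method = c("otsu", "moments", "percentile",
                                        "max_entropy"),
                             percentile_target = 0.5) {
  method <- match.arg(method)
  h <- hist256(image)
  t8 <- threshold_from_hist(h$counts, method, percentile_target)
  a <- get_channel(h$img8)
  mask <- binary_mask(array(as.integer(a > t8), dim = dim(a)),
                      image$voxel_size,
                      provenance = list(method = method, threshold = t8,
                                        percentile_target = percentile_target))
  list(threshold = t8, mask = mask)
}

#' Hysteresis thresholding
#'
#' Voxels above `high` seed the mask; voxels above `low` are kept when
#' 26-connected (in 3D) to a seed. Defaults are histogram-derived:
#' `high` = Otsu threshold of the 8-bit stack, `low = low_frac * high`.
#'
#' @param image a [vol_image].
#' @param high,low thresholds (`low <= high`); both `NULL` for the
#'   histogram-derived defaults.
#' @param low_frac fraction used for the default `low`.
#' @return A [binary_mask].
#' @export
hysteresis_threshold <- function(image, high = NULL, low = NULL,
                                 low_frac = 0.5) {
  a <- get_channel(image)
  if (is.null(high)) {
    h <- hist256(image)
    high <- threshold_from_hist(h$counts, "otsu")
    a <- get_channel(h$img8)
  }
  if (is.null(low)) low <- low_frac * high
  if (low > high) stop("hysteresis requires low <= high")
  keep <- cpp_hysteresis(as.numeric(a), dim(a), low, high)
  binary_mask(array(as.integer(keep), dim = dim(a)), image$voxel_size,
              provenance = list(method = "hysteresis", high = high,
                                low = low))
}

#' Simple 3D segmentation (threshold + size filter)
#'
#' Thresholds at `value_threshold`, labels 26-connected components, and
#' discards components smaller than `min_object_vox`.
#'
#' @param image a [vol_image].
#' @param value_threshold intensity threshold (foreground = `>`).
#' @param min_object_vox minimum surviving component size in voxels.
#' @return list with `labels` (3D integer array, 0 = background, compacted
#'   labels), `n_objects`, and `mask` ([binary_mask]).
#' @export
simple_3d <- function(image, value_threshold, min_object_vox = 1L) {
  a <- get_channel(image)
  fg <- a > value_threshold
  lab <- array(cpp_label26(as.vector(fg), dim(a)), dim = dim(a))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_object_vox)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- array(0L, dim = dim(a))
  out[lab > 0] <- relab[lab[lab > 0]]
  list(labels = out, n_objects = length(keep),
       mask = binary_mask(array(as.integer(out > 0), dim = dim(a)),
                          image$voxel_size,
                          provenance = list(method = "simple3d",
                                            threshold = value_threshold,
                                            min_object_vox = min_object_vox)))
}

#' Remove small speckles from a mask
#'
#' Deletes 26-connected components smaller than `min_object_vox`. Never adds
#' voxels and is idempotent.
#'
#' @param mask a [binary_mask].
#' @param min_object_vox minimum size kept; 0 is the identity.
#' @return The cleaned [binary_mask].
#' @export
remove_speckles <- function(mask, min_object_vox) {
  if (min_object_vox <= 0) return(mask)
  lab <- cpp_label26(as.vector(mask$voxels > 0), dim(mask$voxels))
  nlab <- attr(lab, "n_components")
  if (nlab == 0) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- sizes >= min_object_vox
  v <- array(0L, dim = dim(mask$voxels))
  sel <- lab > 0
  v[sel] <- as.integer(keep[lab[sel]])
  mask$voxels <- v
  mask$provenance <- c(mask$provenance,
                       list(speckles_removed_below = min_object_vox))
  mask
}

#' Reference segmentation pipelines
#'
#' Two end-to-end profiles mirroring the cytosolic- and membrane-reporter
#' workflows: `cytosol` = in-plane median (0,1,1) + Otsu + speckle removal;
#' `membrane` = in-plane median (0,1,1) + hysteresis (high = Otsu,
#' low = 0.5 high) + speckle removal. Full provenance is recorded; stage
#' failures are reported with the stage name.
#'
#' @param image single-channel [vol_image].
#' @param profile `"cytosol"` or `"membrane"`.
#' @param params optional [segmentation_params] overriding the profile
#'   defaults.
#' @return A [binary_mask].
#' @export
segment_pipeline <- function(image, profile = c("cytosol", "membrane"),
                             params = NULL) {
  profile <- match.arg(profile)
  if (is.null(params)) {
    params <- if (profile == "cytosol") {
      ## in-plane median only: confocal dz >> dx and thin processes can be a
      ## single voxel thick in z, which an isotropic-in-voxels median erases
      segmentation_params(median_radius_vox = c(0L, 1L, 1L),
                          method = "otsu", min_object_vox = 27L)
    } else {
      segmentation_params(median_radius_vox = c(0L, 1L, 1L),
                          method = "hysteresis", min_object_vox = 27L)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("segmentation stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  pre <- stage("preprocess", preprocess_stack(image, params))
  mask <- if (profile == "cytosol") {
    stage("threshold", global_threshold(pre, "otsu")$mask)
  } else {
    stage("threshold",
          hysteresis_threshold(pre, low_frac = params$hysteresis_low_frac))
  }
  mask <- stage("speckles", remove_speckles(mask, params$min_object_vox))
  mask$provenance <- c(list(profile = profile,
                            median_radius_vox = params$median_radius_vox,
                            rolling_ball_radius_px =
                              params$rolling_ball_radius_px),
                       mask$provenance)
  mask
}

#' Compare segmentation methods
#'
#' Runs the six supported approaches (four global histogram criteria,
#' hysteresis, simple 3D) on the raw and, optionally, pre-processed stack,
#' reporting the threshold and foreground fraction per method. Per-method
#' failures are recorded as rows, not raised.
#'
#' @param image a [vol_image].
#' @param params a [segmentation_params] (pre-processing radii used for the
#'   pre-processed variant).
#' @param with_preprocess include the pre-processed variant.
#' @param out_dir optional directory for masks (+ `MIP/` folder).
#' @return list with `results` (data.frame: variant, method, threshold,
#'   foreground_fraction, error) and `masks` (named list of [binary_mask]).
#' @export
compare_methods <- function(image,
                            params = segmentation_params(
                              median_radius_vox = c(1L, 1L, 1L)),
                            with_preprocess = TRUE, out_dir = NULL) {
  variants <- list(raw = image)
  if (with_preprocess) variants$preprocessed <- preprocess_stack(image, params)
  methods <- c("otsu", "moments", "percentile", "max_entropy", "hysteresis",
               "simple3d")
  rows <- list(); masks <- list()
  for (vn in names(variants)) {
    vi <- variants[[vn]]
    for (m in methods) {
      res <- tryCatch({
        mask <- switch(m,
          hysteresis = hysteresis_threshold(vi,
                                            low_frac = params$hysteresis_low_frac),
          simple3d = {
            h <- hist256(vi)
            t8 <- threshold_from_hist(h$counts, "otsu")
            simple_3d(h$img8, t8, params$min_object_vox)$mask
          },
          global_threshold(vi, m,
                           percentile_target = params$percentile_target)$mask)
        thr <- mask$provenance$threshold
        if (is.null(thr)) thr <- mask$provenance$high
        list(threshold = thr, frac = mean(mask$voxels), mask = mask,
             error = NA_character_)
      }, error = function(e) {
        list(threshold = NA_real_, frac = NA_real_, mask = NULL,
             error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, method = m,
        threshold = as.numeric(if (is.null(res$threshold)) NA else res$threshold),
        foreground_fraction = res$frac, error = res$error,
        stringsAsFactors = FALSE)
      if (!is.null(res$mask)) {
        key <- paste(vn, m, sep = "_")
        masks[[key]] <- res$mask
        if (!is.null(out_dir)) {
          img <- mask_to_image(res$mask, name = paste0(key, "_", image$name))
          write_stack(img, file.path(out_dir, paste0(img$name, ".tif")))
          mip <- max_projection(img)
          write_stack(mip, file.path(out_dir, "MIP",
                                     paste0(mip$name, ".tif")))
        }
      }
    }
  }
  list(results = do.call(rbind, rows), masks = masks)
}
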