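## Step-per-subcommand batch pipeline over folders of TIFFs, mirroring the
## protocol's unidirectional folder hierarchy: every step creates its output
## folder inside its input folder, reruns overwrite deterministically, and a
## plain-text log records folders and parameters.

list_stacks <- function(dir) {
  all <- list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                    full.names = TRUE)
  mips <- grepl("^MAX_", basename(all))
  if (length(all) && all(mips)) {
    stop("stack required: the input folder contains only MIPs (MAX_*); ",
         "select the folder with the 3D stacks")
  }
  sort(all[!mips])
}

log_line <- function(log_path, ...) {
  cat(paste0(..., "\n"), file = log_path, append = TRUE)
}

#' Coefficient-of-variation comparability check
#'
#' Within a group of equivalently acquired and standardized stacks, features
#' are expected to vary by less than about 20% CoV; larger spread usually
#' means a staging/standardization problem. CoV is `sd/mean * 100` with the
#' population SD.
#'
#' @param records list of `feature_record`s, or a data.frame of numeric
#'   feature columns, or a `QuantificationResults.csv` path.
#' @param cov_threshold flagging threshold in percent (default 20).
#' @return A report: data.frame with `feature`, `mean`, `sd`, `cov_pct`,
#'   `flagged`; or a list `list(status = "insufficient replicates")` for < 2
#'   rows.
#' @export
validate_run <- function(records, cov_threshold = 20) {
  df <- if (is.character(records)) {
    utils::read.csv(records, check.names = FALSE)
  } else if (is.data.frame(records)) {
    records
  } else {
    records_to_df(records)
  }
  num <- df[vapply(df, is.numeric, TRUE)]
  if (nrow(num) < 2L) {
    return(list(status = "insufficient replicates", n = nrow(num)))
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- data.frame(
    feature = names(num),
    mean = vapply(num, mean, 0),
    sd = vapply(num, pop_sd, 0),
    row.names = NULL)
  out$cov_pct <- ifelse(out$mean != 0, 100 * out$sd / abs(out$mean), NA)
  out$flagged <- !is.na(out$cov_pct) & out$cov_pct > cov_threshold
  attr(out, "cov_threshold") <- cov_threshold
  out
}

#' Feature records as a data.frame
#' @param records list of `feature_record`s from [quantify_stack].
#' @return one row per record, numeric feature columns.
#' @export
records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    as.data.frame(r[vapply(r, function(v) is.numeric(v) && length(v) == 1,
                           TRUE)])
  }))
}

#' Run a multi-step pipeline over a folder of stacks
#'
#' `config` is a list (or JSON file) with `input` (folder of TIFFs) and
#' `steps`, an ordered list of `list(name = ..., params = list(...))`.
#' Supported steps: `rotate90`, `subregion`, `split`, `deconvolve`,
#' `zonation`, `segment`, `quantify`. Each step writes its conventional
#' output folder (`90DegreeRotated`, `zDir`, `XCDir`, `DeconvDir`/`PSFDir`,
#' `ZonationTool`, `TH`, quantification CSVs) inside its input folder and
#' the next step consumes it. Ordering is validated: `quantify` requires a
#' preceding `segment`, and `deconvolve` may not follow `segment`.
#'
#' @param config list or path to a JSON config.
#' @return list with `records` (when quantify ran), `validation`, `folders`
#'   (named step output folders), `log` (log file path).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  input <- config$input
  steps <- config$steps
  if (is.null(input) || !dir.exists(input)) stop("input folder not found")
  nms <- vapply(steps, function(s) s$name, "")
  seg_at <- match("segment", nms)
  if ("quantify" %in% nms) {
    if (is.na(seg_at) || match("quantify", nms) < seg_at) {
      stop("invalid step order: quantify requires a preceding segment step")
    }
  }
  if ("deconvolve" %in% nms && !is.na(seg_at) &&
      match("deconvolve", nms) > seg_at) {
    stop("invalid step order: deconvolve is forbidden after segmentation")
  }
  log_path <- file.path(input, "gliaquant_log.txt")
  cat("", file = log_path)  # reruns overwrite
  cur <- input
  folders <- list()
  records <- NULL
  validation <- NULL
  masks_dir <- NULL
  sigma_seen <- 0

  for (s in steps) {
    p <- if (is.null(s$params)) list() else s$params
    files <- list_stacks(cur)
    if (!length(files)) stop("no input files: no TIFF stacks in ", cur)
    log_line(log_path, "step=", s$name, " input=", cur,
             " params=", jsonlite::toJSON(p, auto_unbox = TRUE))
    if (s$name == "rotate90") {
      out <- file.path(cur, "90DegreeRotated")
      dir.create(out, showWarnings = FALSE)
      for (f in files) {
        img <- rotate90(read_stack(f),
                        direction = if (is.null(p$direction)) "clockwise"
                                    else p$direction)
        write_stack(img, file.path(out, basename(f)))
        write_stack(max_projection(img),
                    file.path(out, paste0("MAX_", basename(f))))
      }
      cur <- out
    } else if (s$name == "subregion") {
      roi_path <- file.path(cur, "RoiSetLine.zip")
      if (!file.exists(roi_path)) roi_path <- file.path(cur, "RoiSetLine.json")
      rois <- read_roi_archive(roi_path)
      pairs <- pair_rois_with_images(rois, files)
      prm <- subregion_params(
        width_um = if (is.null(p$width)) 60 else p$width,
        depth_um = if (is.null(p$depth)) 10 else p$depth,
        sigma_um = if (is.null(p$sigma)) 10 else p$sigma)
      sigma_seen <- prm$sigma_um
      out <- file.path(cur, "zDir")
      dir.create(out, showWarnings = FALSE)
      for (pr in pairs) {
        img <- read_stack(pr$path)
        sub <- if (isTRUE(p$within_stack)) {
          extract_subregion_within_stack(img, pr$roi, prm)
        } else {
          extract_subregion(img, pr$roi, prm)
        }
        write_stack(sub, file.path(out, basename(pr$path)))
      }
      cur <- out
    } else if (s$name == "split") {
      use_ch <- if (is.null(p$use_channel)) 1L else as.integer(p$use_channel)
      for (f in files) split_channels(read_stack(f), out_dir = cur)
      cur <- file.path(cur, sprintf("%dCDir", use_ch))
    } else if (s$name == "deconvolve") {
      wl <- if (is.null(p$wavelengths)) 510 else unlist(p$wavelengths)
      na <- if (is.null(p$na)) 1.0 else p$na
      img0 <- read_stack(files[1])
      d0 <- img_dim(img0)
      odd_fit <- function(pref, n) min(pref, 2L * n - 1L) %/% 2L * 2L + 1L
      pp <- psf_params(emission_wavelength_nm = wl[1],
                       numerical_aperture = na,
                       voxel_size = as.numeric(img0$voxel_size),
                       shape = c(odd_fit(17L, d0[1]), odd_fit(33L, d0[2]),
                                 odd_fit(33L, d0[3])))
      psf <- theoretical_psf(pp)
      psf_dir <- file.path(cur, "PSFDir")
      write_stack(psf, file.path(psf_dir, "PSF_C1.tif"))
      out <- file.path(cur, "DeconvDir")
      dir.create(out, showWarnings = FALSE)
      for (f in files) {
        img <- read_stack(f)
        dec <- richardson_lucy(img, psf,
                               iterations = if (is.null(p$iterations)) 1L
                                            else p$iterations)
        write_stack(dec, file.path(out, basename(f)))
      }
      cur <- out
    } else if (s$name == "zonation") {
      profs <- list()
      heights <- list()
      for (f in files) {
        img <- read_stack(f)
        pr <- apicobasal_profile(img)
        if (!is.null(p$target_rows)) pr <- normalize_profile(pr, p$target_rows)
        profs[[img$name]] <- pr
        sg <- if (is.null(p$sigma)) sigma_seen else p$sigma
        h <- measure_heights(img, sigma_um = sg)
        heights[[img$name]] <- data.frame(
          image = img$name, image_height_um = h$image_height_um,
          retina_height_um = h$retina_height_um,
          mg_height_um = h$mg_height_um)
      }
      export_zonation(profs, cur, results = do.call(rbind, heights))
      folders$zonation <- file.path(cur, "ZonationTool")
    } else if (s$name == "segment") {
      out <- file.path(cur, "TH")
      dir.create(out, showWarnings = FALSE)
      for (f in files) {
        img <- read_stack(f)
        mask <- segment_pipeline(img,
                                 profile = if (is.null(p$profile)) "cytosol"
                                           else p$profile)
        mimg <- mask_to_image(mask, name = img$name)
        write_stack(mimg, file.path(out, basename(f)))
        write_stack(max_projection(mimg),
                    file.path(out, "MIP", paste0("MAX_", basename(f))))
        jsonlite::write_json(mask$provenance,
                             file.path(out, paste0(img$name, "_provenance.json")),
                             auto_unbox = TRUE, null = "null")
      }
      cur <- out
      masks_dir <- out
    } else if (s$name == "quantify") {
      records <- list()
      for (f in files) {
        img <- read_stack(f)
        a <- get_channel(img)
        mask <- binary_mask(array(as.integer(a > 0), dim = dim(a)),
                            as.numeric(img$voxel_size),
                            provenance = list(source = f))
        records[[img$name]] <- quantify_stack(
          mask, sigma_um = if (is.null(p$sigma)) sigma_seen else p$sigma,
          prune_below_um = if (is.null(p$prune_um)) 0 else p$prune_um,
          out_dir = cur, name = img$name)
      }
      write_quant_outputs(records, cur)
      validation <- validate_run(records)
      folders$quantify <- cur
    } else {
      stop("unknown pipeline step: ", s$name)
    }
    folders[[s$name]] <- cur
    log_line(log_path, "step=", s$name, " output=", cur)
  }
  list(records = records, validation = validation, folders = folders,
       log = log_path)
}
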