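## Minimal baseline TIFF input/output.
##
## No TIFF package exists in the supported dependency set, so the format layer
## is implemented here directly: uncompressed baseline TIFF, grayscale
## (8/16-bit unsigned, 32-bit float) multi-page stacks, little- or big-endian
## on read, little-endian on write, with calibration persisted via
## XResolution/YResolution rationals plus an ImageJ-style ImageDescription
## (images/channels/slices/spacing/unit) that mainstream readers understand.

## ---- raw-buffer readers ----------------------------------------------------

rd_u16 <- function(buf, off, le) {
  b <- as.integer(buf[off + 1:2])
  if (le) b[1] + 256L * b[2] else b[2] + 256L * b[1]
}

rd_u32 <- function(buf, off, le) {
  b <- as.numeric(buf[off + 1:4])
  if (!le) b <- rev(b)
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

## decode one IFD entry value (vector) given type/count
rd_tag_values <- function(buf, entry_off, le) {
  typ <- rd_u16(buf, entry_off + 2, le)
  cnt <- rd_u32(buf, entry_off + 4, le)
  tsize <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[typ]
  nbytes <- tsize * cnt
  voff <- if (nbytes <= 4) entry_off + 8 else rd_u32(buf, entry_off + 8, le)
  if (typ == 2L) {                       # ASCII
    raw_s <- buf[voff + seq_len(max(cnt - 1, 0))]
    return(rawToChar(raw_s[raw_s != as.raw(0)]))
  }
  if (typ == 3L) {                       # SHORT
    return(vapply(seq_len(cnt), function(i) rd_u16(buf, voff + 2 * (i - 1), le), 0L))
  }
  if (typ == 4L) {                       # LONG
    return(vapply(seq_len(cnt), function(i) rd_u32(buf, voff + 4 * (i - 1), le), 0))
  }
  if (typ == 5L) {                       # RATIONAL -> numerator/denominator
    return(vapply(seq_len(cnt), function(i) {
      num <- rd_u32(buf, voff + 8 * (i - 1), le)
      den <- rd_u32(buf, voff + 8 * (i - 1) + 4, le)
      if (den == 0) NA_real_ else num / den
    }, 0))
  }
  if (typ == 1L) return(as.integer(buf[voff + seq_len(cnt)]))
  NA
}

parse_ifd <- function(buf, off, le) {
  n <- rd_u16(buf, off, le)
  tags <- list()
  for (i in seq_len(n)) {
    eo <- off + 2 + 12 * (i - 1)
    tag <- rd_u16(buf, eo, le)
    tags[[as.character(tag)]] <- rd_tag_values(buf, eo, le)
  }
  list(tags = tags, next_ifd = rd_u32(buf, off + 2 + 12 * n, le))
}

parse_imagej_desc <- function(desc) {
  out <- list()
  if (is.null(desc) || !nzchar(desc)) return(out)
  for (ln in strsplit(desc, "\n", fixed = TRUE)[[1]]) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) out[[kv[1]]] <- kv[2]
  }
  out
}

#' Read a calibrated TIFF stack
#'
#' Reads an uncompressed grayscale baseline TIFF (8/16-bit unsigned or 32-bit
#' float, multi-page, either byte order). Calibration is taken from the
#' resolution tags and ImageJ-style description when present; otherwise an
#' explicit `voxel_size` override is used. With neither, a default of 1 um is
#' applied with a warning, and the result is flagged
#' (`attr(, "calibration_defaulted")`) because wrong voxel dimensions make
#' downstream quantification meaningless.
#'
#' @param path TIFF file path.
#' @param voxel_size optional `(dx, dy, dz)` um override used when the file
#'   carries no calibration.
#' @param name optional name; defaults to the file base name.
#' @return A [vol_image].
#' @export
read_stack <- function(path, voxel_size = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 8) stop("not a TIFF (too short): ", path)
  order_tag <- rawToChar(buf[1:2])
  le <- order_tag == "II"
  if (!le && order_tag != "MM") stop("not a TIFF (bad byte-order mark): ", path)
  if (rd_u16(buf, 2, le) != 42L) stop("not a TIFF (bad magic): ", path)

  off <- rd_u32(buf, 4, le)
  pages <- list()
  first_tags <- NULL
  while (off != 0) {
    ifd <- parse_ifd(buf, off, le)
    t <- ifd$tags
    if (is.null(first_tags)) first_tags <- t
    w <- as.integer(t[["256"]][1]); h <- as.integer(t[["257"]][1])
    bits <- if (is.null(t[["258"]])) 1L else as.integer(t[["258"]][1])
    comp <- if (is.null(t[["259"]])) 1L else as.integer(t[["259"]][1])
    spp <- if (is.null(t[["277"]])) 1L else as.integer(t[["277"]][1])
    fmt <- if (is.null(t[["339"]])) 1L else as.integer(t[["339"]][1])
    if (comp != 1L) stop("unsupported TIFF compression scheme ", comp)
    if (spp != 1L) stop("only single-sample (grayscale) TIFFs are supported")
    offs <- t[["273"]]; cnts <- t[["279"]]
    bytes <- raw(0)
    for (i in seq_along(offs)) {
      bytes <- c(bytes, buf[offs[i] + seq_len(cnts[i])])
    }
    px <- if (bits == 8L) {
      as.numeric(as.integer(bytes))
    } else if (bits == 16L) {
      readBin(bytes, "integer", n = w * h, size = 2, signed = FALSE,
              endian = if (le) "little" else "big")
    } else if (bits == 32L && fmt == 3L) {
      readBin(bytes, "numeric", n = w * h, size = 4,
              endian = if (le) "little" else "big")
    } else {
      stop("unsupported TIFF sample layout: ", bits, "-bit, format ", fmt)
    }
    ## TIFF stores row-major (x fastest); our slices are (y, x)
    pages[[length(pages) + 1L]] <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    bitdepth <- if (bits == 8L) "8" else if (bits == 16L) "16" else "float"
    off <- ifd$next_ifd
  }
  if (!length(pages)) stop("TIFF contains no image pages: ", path)

  ij <- parse_imagej_desc(first_tags[["270"]])
  ## ImageJ-style contiguous hyperstacks: one IFD, remaining slices follow
  ## the first strip back to back
  n_desc <- if (!is.null(ij$images)) as.integer(ij$images) else length(pages)
  if (length(pages) == 1L && n_desc > 1L) {
    h1 <- nrow(pages[[1]]); w1 <- ncol(pages[[1]])
    bits <- as.integer(first_tags[["258"]][1])
    fmt <- if (is.null(first_tags[["339"]])) 1L else as.integer(first_tags[["339"]][1])
    bpp <- bits %/% 8L
    base <- first_tags[["273"]][1]
    for (k in 2:n_desc) {
      o <- base + (k - 1) * h1 * w1 * bpp
      bytes <- buf[o + seq_len(h1 * w1 * bpp)]
      px <- if (bits == 8L) {
        as.numeric(as.integer(bytes))
      } else if (bits == 16L) {
        readBin(bytes, "integer", n = w1 * h1, size = 2, signed = FALSE,
                endian = if (le) "little" else "big")
      } else {
        readBin(bytes, "numeric", n = w1 * h1, size = 4,
                endian = if (le) "little" else "big")
      }
      pages[[k]] <- matrix(px, nrow = h1, ncol = w1, byrow = TRUE)
    }
  }
  n_ch <- if (!is.null(ij$channels)) as.integer(ij$channels) else 1L
  n_img <- length(pages)
  if (n_img %% n_ch != 0) n_ch <- 1L
  nz <- n_img %/% n_ch

  ## calibration: resolution tags are pixels per unit
  dx <- dy <- dz <- NA_real_
  xres <- first_tags[["282"]]; yres <- first_tags[["283"]]
  runit <- if (is.null(first_tags[["296"]])) 1L else as.integer(first_tags[["296"]][1])
  ## per-unit scale to um; RESUNIT none is only meaningful when an
  ## ImageJ-style description declares the unit
  scale_um <- if (identical(ij$unit, "micron") || identical(ij$unit, "um")) {
    1
  } else if (runit == 2L) {
    25400            # inch
  } else if (runit == 3L) {
    10000            # centimetre
  } else {
    NA_real_
  }
  if (!is.null(xres) && is.finite(xres[1]) && xres[1] > 0 &&
      is.finite(scale_um)) {
    dx <- scale_um / xres[1]
    dy <- if (!is.null(yres) && is.finite(yres[1]) && yres[1] > 0) {
      scale_um / yres[1]
    } else dx
  }
  if (!is.null(ij$spacing)) dz <- as.numeric(ij$spacing)
  defaulted <- FALSE
  if (any(is.na(c(dx, dy, dz)))) {
    if (!is.null(voxel_size)) {
      vs <- as.numeric(voxel_size)
      if (is.na(dx)) dx <- vs[1]
      if (is.na(dy)) dy <- vs[2]
      if (is.na(dz)) dz <- vs[3]
    } else {
      warning("no calibration in TIFF and no override given; defaulting to ",
              "1 um voxels -- quantified outputs will be meaningless if wrong")
      if (is.na(dx)) dx <- 1
      if (is.na(dy)) dy <- 1
      if (is.na(dz)) dz <- 1
      defaulted <- TRUE
    }
  }

  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  chans <- lapply(seq_len(n_ch), function(ci) {
    a <- array(0, dim = c(nz, h, w))
    for (z in seq_len(nz)) {
      ## channel-fastest page interleave (ImageJ hyperstack order)
      a[z, , ] <- pages[[(z - 1L) * n_ch + ci]]
    }
    a
  })
  img <- vol_image(chans[[1]], c(dx, dy, dz), bitdepth,
                   name = if (is.null(name)) {
                     sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
                   } else name,
                   channels = if (n_ch > 1L) chans[-1] else NULL)
  if (defaulted) attr(img, "calibration_defaulted") <- TRUE
  img
}

## ---- writer ----------------------------------------------------------------

w_u16 <- function(con, v) {
  v <- as.integer(v)
  writeBin(as.raw(c(rbind(v %% 256L, v %/% 256L))), con)
}

w_u32 <- function(con, v) {
  v <- as.numeric(v)
  b <- cbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
             (v %/% 16777216) %% 256)
  writeBin(as.raw(c(t(b))), con)
}

w_entry <- function(con, tag, typ, cnt, val_or_off, inline_short = FALSE) {
  w_u16(con, tag); w_u16(con, typ); w_u32(con, cnt)
  if (inline_short) {            # one SHORT packed into the 4 value bytes
    w_u16(con, val_or_off); w_u16(con, 0L)
  } else {
    w_u32(con, val_or_off)
  }
}

#' Write a calibrated TIFF stack
#'
#' Writes an uncompressed little-endian baseline TIFF. 8/16-bit stacks
#' round-trip losslessly; float stacks are stored as 32-bit IEEE float.
#' Calibration is persisted in XResolution/YResolution (pixels per micron) and
#' an ImageJ-style description (slice spacing, unit, channel/slice counts).
#'
#' @param image a [vol_image].
#' @param path output path (`.tif`/`.tiff`); parent directory must exist or be
#'   creatable.
#' @return `path`, invisibly.
#' @export
write_stack <- function(image, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  d <- img_dim(image); nz <- d[1]; h <- d[2]; w <- d[3]
  nc <- n_channels(image)
  n_pages <- nz * nc
  bits <- switch(image$bit_depth, "8" = 8L, "16" = 16L, "float" = 32L)
  fmt <- if (image$bit_depth == "float") 3L else 1L
  bpp <- bits %/% 8L
  page_bytes <- h * w * bpp
  vs <- image$voxel_size

  desc <- sprintf(paste0("ImageJ=1.53t\nimages=%d\nchannels=%d\nslices=%d\n",
                         "hyperstack=true\nspacing=%.9g\nunit=micron\n"),
                  n_pages, nc, nz, vs[["dz"]])
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  ## layout: header | pixel data | desc | xres | yres | IFDs
  data_off <- 8
  desc_off <- data_off + n_pages * page_bytes
  xres_off <- desc_off + length(desc_raw)
  yres_off <- xres_off + 8
  ifd0_off <- yres_off + 8
  n_entries <- function(p) if (p == 1) 13L else 12L
  ifd_size <- function(p) 2 + 12 * n_entries(p) + 4
  ifd_offs <- numeric(n_pages)
  o <- ifd0_off
  for (p in seq_len(n_pages)) { ifd_offs[p] <- o; o <- o + ifd_size(p) }

  ## resolution rationals: pixels per micron = 1/dx as num/den
  rat <- function(px_per_um) {
    den <- 1e6
    num <- round(px_per_um * den)
    c(num, den)
  }
  xr <- rat(1 / vs[["dx"]]); yr <- rat(1 / vs[["dy"]])

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("II"), con); w_u16(con, 42L); w_u32(con, ifd0_off)

  for (z in seq_len(nz)) for (ci in seq_len(nc)) {
    sl <- image$channels[[ci]][z, , , drop = TRUE]
    sl <- matrix(sl, nrow = h, ncol = w)
    px <- as.vector(t(sl))                       # row-major
    if (bits == 8L) {
      writeBin(as.raw(as.integer(round(px))), con)
    } else if (bits == 16L) {
      w_u16(con, as.integer(round(px)))
    } else {
      writeBin(as.numeric(px), con, size = 4, endian = "little")
    }
  }
  writeBin(desc_raw, con)
  w_u32(con, xr[1]); w_u32(con, xr[2])
  w_u32(con, yr[1]); w_u32(con, yr[2])

  for (p in seq_len(n_pages)) {
    ne <- n_entries(p)
    w_u16(con, ne)
    w_entry(con, 256L, 4L, 1, w)
    w_entry(con, 257L, 4L, 1, h)
    w_entry(con, 258L, 3L, 1, bits, inline_short = TRUE)
    w_entry(con, 259L, 3L, 1, 1L, inline_short = TRUE)
    w_entry(con, 262L, 3L, 1, 1L, inline_short = TRUE)
    if (p == 1) w_entry(con, 270L, 2L, length(desc_raw), desc_off)
    w_entry(con, 273L, 4L, 1, data_off + (p - 1) * page_bytes)
    w_entry(con, 277L, 3L, 1, 1L, inline_short = TRUE)
    w_entry(con, 278L, 4L, 1, h)
    w_entry(con, 279L, 4L, 1, page_bytes)
    w_entry(con, 282L, 5L, 1, xres_off)
    w_entry(con, 283L, 5L, 1, yres_off)
    w_entry(con, 339L, 3L, 1, fmt, inline_short = TRUE)
    w_u32(con, if (p < n_pages) ifd_offs[p + 1] else 0)
  }
  invisible(path)
}

## 2D 8-bit palette TIFF (used for colormapped profile strips)
write_palette_tiff <- function(mat, path, lut) {
  stopifnot(is.matrix(mat), is.matrix(lut), nrow(lut) == 256, ncol(lut) == 3)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  h <- nrow(mat); w <- ncol(mat)
  data_off <- 8
  cmap_off <- data_off + h * w
  ifd_off <- cmap_off + 3 * 256 * 2
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("II"), con); w_u16(con, 42L); w_u32(con, ifd_off)
  writeBin(as.raw(as.integer(round(as.vector(t(mat))))), con)
  w_u16(con, as.integer(round(c(lut[, 1], lut[, 2], lut[, 3]) * 257)))
  w_u16(con, 9L)
  w_entry(con, 256L, 4L, 1, w)
  w_entry(con, 257L, 4L, 1, h)
  w_entry(con, 258L, 3L, 1, 8L, inline_short = TRUE)
  w_entry(con, 259L, 3L, 1, 1L, inline_short = TRUE)
  w_entry(con, 262L, 3L, 1, 3L, inline_short = TRUE)  # palette color
  w_entry(con, 273L, 4L, 1, data_off)
  w_entry(con, 278L, 4L, 1, h)
  w_entry(con, 279L, 4L, 1, h * w)
  w_entry(con, 320L, 3L, 3 * 256, cmap_off)
  w_u32(con, 0)
  invisible(path)
}
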