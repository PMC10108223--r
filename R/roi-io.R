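#' Line and oval regions of interest
#'
#' `line_roi` is the annotation that drives subregion standardization: a
#' straight segment drawn from the inner (basal) side of the retina outwards
#' (apical), so `start` is basal and `end` is apical by convention.
#' `oval_roi` is used for quality measurement (elliptical pixel sets on one
#' slice). Coordinates are 0-based pixel positions `(x, y)` as in ImageJ.
#'
#' @param start,end numeric `(x, y)` endpoints in pixels.
#' @param slice_index optional 0-based z index (within-stack variant); `NULL`
#'   for ROIs drawn on projections.
#' @param image_name optional name of the paired stack.
#' @return A `line_roi` / `oval_roi` object.
#' @export
line_roi <- function(start, end, slice_index = NULL, image_name = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 2, length(end) == 2)
  if (sqrt(sum((end - start)^2)) <= 0) stop("degenerate line ROI (length 0)")
  structure(list(start = start, end = end, slice_index = slice_index,
                 image_name = image_name),
            class = c("line_roi", "roi"))
}

#' @rdname line_roi
#' @param center numeric `(x, y)` centre in pixels.
#' @param radii numeric `(rx, ry)` in pixels, both positive.
#' @export
oval_roi <- function(center, radii, slice_index = 0L) {
  center <- as.numeric(center); radii <- as.numeric(radii)
  stopifnot(length(center) == 2, length(radii) == 2)
  if (any(radii <= 0)) stop("oval ROI radii must be positive")
  structure(list(center = center, radii = radii,
                 slice_index = as.integer(slice_index)),
            class = c("oval_roi", "roi"))
}

#' ROI length in pixels
#' @param roi a `line_roi`
#' @return Euclidean length in pixels.
#' @export
roi_length_px <- function(roi) sqrt(sum((roi$end - roi$start)^2))

## ---- ImageJ .roi binary records (big-endian) -------------------------------
## Layout per the published RoiDecoder format: magic "Iout", version short,
## type byte at 6 (line = 3, oval = 2), bounding box shorts at 8..15, line
## endpoint floats at 18..33, stack position int at 56.

rd_be16 <- function(buf, off) {
  b <- as.integer(buf[off + 1:2]); v <- b[2] + 256L * b[1]
  if (v >= 32768L) v - 65536L else v
}
rd_be32 <- function(buf, off) {
  b <- as.numeric(buf[off + 1:4])
  b[4] + 256 * b[3] + 65536 * b[2] + 16777216 * b[1]
}
rd_bef32 <- function(buf, off) {
  readBin(buf[off + 1:4], "numeric", size = 4, endian = "big")
}
w_be16 <- function(v) {
  v <- as.integer(round(v)); v <- ifelse(v < 0, v + 65536L, v)
  as.raw(c(rbind(v %/% 256L, v %% 256L)))
}
w_be32 <- function(v) {
  v <- as.numeric(round(v))
  as.raw(c(rbind((v %/% 16777216) %% 256, (v %/% 65536) %% 256,
                 (v %/% 256) %% 256, v %% 256)))
}
w_bef32 <- function(v) {
  writeBin(as.numeric(v), raw(), size = 4, endian = "big")
}

decode_roi <- function(buf) {
  if (length(buf) < 64 || rawToChar(buf[1:4]) != "Iout") {
    stop("unreadable ROI record (missing 'Iout' magic)")
  }
  type <- as.integer(buf[7])
  top <- rd_be16(buf, 8); left <- rd_be16(buf, 10)
  bottom <- rd_be16(buf, 12); right <- rd_be16(buf, 14)
  pos <- rd_be32(buf, 56)
  slice <- if (pos > 0) as.integer(pos - 1) else NULL
  if (type == 3L) {                      # straight line
    line_roi(start = c(rd_bef32(buf, 18), rd_bef32(buf, 22)),
             end = c(rd_bef32(buf, 26), rd_bef32(buf, 30)),
             slice_index = slice)
  } else if (type == 2L) {               # oval
    oval_roi(center = c((left + right) / 2, (top + bottom) / 2),
             radii = c((right - left) / 2, (bottom - top) / 2),
             slice_index = if (is.null(slice)) 0L else slice)
  } else {
    stop("unsupported ROI type code ", type, " (only line and oval)")
  }
}

encode_roi <- function(roi) {
  buf <- raw(64)
  buf[1:4] <- charToRaw("Iout")
  buf[5:6] <- w_be16(227L)               # format version
  if (inherits(roi, "line_roi")) {
    buf[7] <- as.raw(3L)
    xs <- c(roi$start[1], roi$end[1]); ys <- c(roi$start[2], roi$end[2])
    buf[9:10] <- w_be16(floor(min(ys))); buf[11:12] <- w_be16(floor(min(xs)))
    buf[13:14] <- w_be16(ceiling(max(ys))); buf[15:16] <- w_be16(ceiling(max(xs)))
    buf[19:22] <- w_bef32(roi$start[1]); buf[23:26] <- w_bef32(roi$start[2])
    buf[27:30] <- w_bef32(roi$end[1]); buf[31:34] <- w_bef32(roi$end[2])
  } else if (inherits(roi, "oval_roi")) {
    buf[7] <- as.raw(2L)
    cx <- roi$center[1]; cy <- roi$center[2]
    rx <- roi$radii[1]; ry <- roi$radii[2]
    buf[9:10] <- w_be16(cy - ry); buf[11:12] <- w_be16(cx - rx)
    buf[13:14] <- w_be16(cy + ry); buf[15:16] <- w_be16(cx + rx)
  } else stop("unsupported ROI class")
  if (!is.null(roi$slice_index)) buf[57:60] <- w_be32(roi$slice_index + 1)
  buf
}

## ---- store-only ZIP writer -------------------------------------------------
## No external `zip` binary is guaranteed; archives are written directly
## (method 0 = stored), with a table-driven CRC32 (entries are tiny).

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        cc <- i
        for (k in 1:8) {
          cc <- if (bitwAnd(cc, 1L)) {
            bitwXor(-306674912L, bitwShiftR(cc, 1L))   # 0xEDB88320
          } else bitwShiftR(cc, 1L)
        }
        t[i + 1] <- cc
      }
      tab <<- t
    }
    tab
  }
})

crc32_raw <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 4294967296 else as.numeric(crc)
}

zip_store <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  offsets <- numeric(length(entries))
  pos <- 0
  names_raw <- lapply(names(entries), charToRaw)
  crcs <- vapply(entries, crc32_raw, 0)
  for (i in seq_along(entries)) {
    data <- entries[[i]]; nm <- names_raw[[i]]
    offsets[i] <- pos
    hdr <- c(charToRaw("PK\003\004"),
             as.raw(c(20, 0, 0, 0, 0, 0, 0, 0, 0, 0)))  # ver, flags, stored, time
    writeBin(hdr, con)
    w_u32(con, crcs[i]); w_u32(con, length(data)); w_u32(con, length(data))
    w_u16(con, length(nm)); w_u16(con, 0L)
    writeBin(nm, con); writeBin(data, con)
    pos <- pos + 30 + length(nm) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    nm <- names_raw[[i]]
    writeBin(c(charToRaw("PK\001\002"),
               as.raw(c(20, 0, 20, 0, 0, 0, 0, 0, 0, 0, 0, 0))), con)
    w_u32(con, crcs[i])
    w_u32(con, length(entries[[i]])); w_u32(con, length(entries[[i]]))
    w_u16(con, length(nm))
    w_u16(con, 0L); w_u16(con, 0L); w_u16(con, 0L); w_u16(con, 0L)
    w_u32(con, 0); w_u32(con, offsets[i])
    writeBin(nm, con)
    pos <- pos + 46 + length(nm)
  }
  writeBin(charToRaw("PK\005\006"), con)
  w_u16(con, 0L); w_u16(con, 0L)
  w_u16(con, length(entries)); w_u16(con, length(entries))
  w_u32(con, pos - cd_start); w_u32(con, cd_start); w_u16(con, 0L)
  invisible(path)
}

#' Read a ROI archive
#'
#' Reads either an ImageJ ROI archive (`.zip` of binary `.roi` records, e.g.
#' `RoiSetLine.zip`) or the package's JSON dialect (`.json` with a top-level
#' `rois` array of `{"type": "line"|"oval", ...}` records). Entry order is
#' preserved: ROI `i` pairs with the `i`-th TIFF of the lexicographically
#' sorted input folder (see [pair_rois_with_images]).
#'
#' @param path archive path.
#' @return A list of [line_roi]/[oval_roi] objects.
#' @export
read_roi_archive <- function(path) {
  if (!file.exists(path)) {
    stop("ROI archive not found: ", path,
         " (the subregion step expects 'RoiSetLine.zip' or a .json ",
         "equivalent next to the input TIFFs)")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rois <- if (!is.null(doc$rois)) doc$rois else doc
    return(lapply(rois, function(r) {
      if (identical(r$type, "line")) {
        line_roi(unlist(r$start), unlist(r$end),
                 slice_index = r$slice, image_name = r$image)
      } else if (identical(r$type, "oval")) {
        oval_roi(unlist(r$center), unlist(r$radii),
                 slice_index = if (is.null(r$slice)) 0L else r$slice)
      } else stop("unknown ROI type in JSON archive: ", r$type)
    }))
  }
  exdir <- tempfile("roiset")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  listing <- utils::unzip(path, list = TRUE)
  files <- listing$Name[grepl("\\.roi$", listing$Name, ignore.case = TRUE)]
  if (!length(files)) stop("ROI archive contains no .roi entries: ", path)
  utils::unzip(path, files = files, exdir = exdir)
  lapply(files, function(f) {
    decode_roi(readBin(file.path(exdir, f), "raw",
                       n = file.size(file.path(exdir, f))))
  })
}

#' Write a ROI archive
#'
#' Writes line/oval ROIs either as an ImageJ-compatible `.zip` of binary
#' `.roi` records or as the JSON dialect, chosen by the file extension.
#'
#' @param rois list of [line_roi]/[oval_roi].
#' @param path output path ending in `.zip` or `.json`.
#' @return `path`, invisibly.
#' @export
write_roi_archive <- function(rois, path) {
  stopifnot(length(rois) >= 1)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- list(rois = lapply(rois, function(r) {
      if (inherits(r, "line_roi")) {
        list(type = "line", start = r$start, end = r$end,
             slice = r$slice_index, image = r$image_name)
      } else {
        list(type = "oval", center = r$center, radii = r$radii,
             slice = r$slice_index)
      }
    }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(path))
  }
  entries <- lapply(rois, encode_roi)
  names(entries) <- sprintf("%04d-0000.roi", seq_along(rois))
  zip_store(path, entries)
  invisible(path)
}

#' Pair ROIs with stack files
#'
#' Images are paired with ROIs by lexicographic filename order (the headless
#' replacement for the manual "open images in folder order" convention); a
#' count mismatch is an error rather than a silent mispairing.
#'
#' @param rois list of ROIs as returned by [read_roi_archive].
#' @param paths character vector of TIFF paths.
#' @return A list of `list(path =, roi =)` pairs in sorted path order.
#' @export
pair_rois_with_images <- function(rois, paths) {
  paths <- sort(paths)
  if (length(rois) != length(paths)) {
    stop("ROI count (", length(rois), ") does not match TIFF count (",
         length(paths), "); check RoiSetLine.zip against the input folder")
  }
  Map(function(p, r) list(path = p, roi = r), paths, rois)
}
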