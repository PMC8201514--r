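# Minimal DICOM support: an explicit-VR little-endian reader for single-frame
# CT series (the subset needed to assemble a HU volume: geometry, rescale
# slope/intercept, pixel data) and an internal writer used to create synthetic
# series for tests and examples. No installed R package provides DICOM I/O in
# this stack, so the subset is implemented here; sequences, compressed
# transfer syntaxes and multi-frame objects are rejected, not guessed at.

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

dcm_u32 <- function(raw, pos) {
  sum(as.numeric(raw[pos + 0:3]) * 256^(0:3))
}

dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# parse one file into a named list of raw element values keyed "gggg,eeee"
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    abort_sctgan(paste0("not a DICOM file: ", path), "sctgan_io_error")
  }
  pos <- 133L
  out <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- dcm_u16(raw, pos)
    elem <- dcm_u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% dcm_long_vrs) {
      len <- dcm_u32(raw, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- dcm_u16(raw, pos + 6L)
      pos <- pos + 8L
    }
    if (vr == "SQ" || len == 4294967295) {
      abort_sctgan(paste0("unsupported DICOM sequence/undefined length in ", path),
                   "sctgan_io_error")
    }
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- list(vr = vr, value = raw[seq.int(pos, length.out = len)])
    pos <- pos + len
  }
  out
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}

dcm_num <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])
}

dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", n = length(el$value) / 2, size = 2,
          signed = FALSE, endian = "little")
}

# Read a directory of DICOM instances as one HU volume
read_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  validate_that(length(files) >= 1, paste0("no files in ", path),
                class = "sctgan_io_error")
  parsed <- lapply(files, parse_dicom_file)
  uids <- vapply(parsed, function(p) dcm_str(p[["0020,000e"]]) %||% "", "")
  if (length(unique(uids)) != 1L) {
    abort_sctgan("mixed series UIDs in DICOM directory",
                 "sctgan_validation_error")
  }
  zs <- vapply(parsed, function(p) {
    ipp <- dcm_num(p[["0020,0032"]])
    if (!is.null(ipp)) ipp[3] else dcm_num(p[["0020,1041"]]) %||% NA_real_
  }, numeric(1))
  validate_that(!anyNA(zs), "DICOM instances lack slice position")
  ord <- order(zs)
  parsed <- parsed[ord]
  zs <- zs[ord]
  if (length(zs) > 2) {
    dz <- diff(zs)
    if ((max(dz) - min(dz)) > 0.01 * stats::median(dz)) {
      abort_sctgan("non-uniform DICOM slice spacing beyond 1% tolerance",
                   "sctgan_validation_error")
    }
  }
  first <- parsed[[1]]
  rows <- dcm_us(first[["0028,0010"]])
  cols <- dcm_us(first[["0028,0011"]])
  ps <- dcm_num(first[["0028,0030"]])  # (row spacing, column spacing)
  dz <- if (length(zs) > 1) zs[2] - zs[1] else
    (dcm_num(first[["0018,0050"]]) %||% 1)
  ipp <- dcm_num(first[["0020,0032"]]) %||% c(0, 0, zs[1])
  vox <- array(0, dim = c(length(parsed), rows, cols))
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    rep_signed <- (dcm_us(p[["0028,0103"]]) %||% 1L) == 1L
    bits <- dcm_us(p[["0028,0100"]]) %||% 16L
    validate_that(bits == 16L, "only 16-bit DICOM pixel data is supported")
    px <- readBin(p[["7fe0,0010"]]$value, "integer",
                  n = rows * cols, size = 2, signed = rep_signed,
                  endian = "little")
    slope <- dcm_num(p[["0028,1053"]]) %||% 1
    intercept <- dcm_num(p[["0028,1052"]]) %||% 0
    vox[i, , ] <- matrix(px * slope + intercept, nrow = rows, byrow = TRUE)
  }
  hu_volume(vox, spacing = c(ps[2], ps[1], dz),
            origin = c(ipp[1], ipp[2], zs[1]))
}

# ---- synthetic-series writer (fixture generation only) --------------------

dcm_put <- function(con, group, elem, vr, value_raw) {
  writeBin(as.integer(c(group %% 256, group %/% 256,
                        elem %% 256, elem %/% 256)),
           con, size = 1)
  writeChar(vr, con, eos = NULL)
  len <- length(value_raw)
  if (vr %in% dcm_long_vrs) {
    writeBin(as.integer(c(0, 0)), con, size = 1)
    writeBin(len, con, size = 4, endian = "little")
  } else {
    writeBin(len, con, size = 2, endian = "little")
  }
  if (len) writeBin(value_raw, con)
}

dcm_str_raw <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

dcm_us_raw <- function(x) {
  writeBin(as.integer(x), raw(), size = 2, endian = "little")
}

# Write `volume` as a synthetic explicit-VR little-endian DICOM series,
# storing round(.) of (HU - intercept)/slope as int16. For test fixtures.
write_dicom_series <- function(volume, dir, slope = 1, intercept = -1024,
                               series_uid = "1.2.826.0.1.3680043.2.1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$voxels)
  zs <- slice_positions(volume)
  for (i in seq_len(d[1])) {
    path <- file.path(dir, sprintf("slice_%04d.dcm", i))
    con <- file(path, "wb")
    writeBin(raw(128), con)
    writeChar("DICM", con, eos = NULL)
    dcm_put(con, 0x0002, 0x0010, "UI", dcm_str_raw("1.2.840.10008.1.2.1"))
    dcm_put(con, 0x0008, 0x0018, "UI",
            dcm_str_raw(paste0(series_uid, ".", i)))
    dcm_put(con, 0x0020, 0x000E, "UI", dcm_str_raw(series_uid))
    dcm_put(con, 0x0020, 0x0032, "DS", dcm_str_raw(
      sprintf("%g\\%g\\%g", volume$origin[1], volume$origin[2], zs[i])))
    dcm_put(con, 0x0028, 0x0010, "US", dcm_us_raw(d[2]))
    dcm_put(con, 0x0028, 0x0011, "US", dcm_us_raw(d[3]))
    dcm_put(con, 0x0028, 0x0030, "DS", dcm_str_raw(
      sprintf("%g\\%g", volume$spacing[2], volume$spacing[1])))
    dcm_put(con, 0x0018, 0x0050, "DS", dcm_str_raw(sprintf("%g", volume$spacing[3])))
    dcm_put(con, 0x0028, 0x0100, "US", dcm_us_raw(16))
    dcm_put(con, 0x0028, 0x0103, "US", dcm_us_raw(1))
    dcm_put(con, 0x0028, 0x1052, "DS", dcm_str_raw(sprintf("%g", intercept)))
    dcm_put(con, 0x0028, 0x1053, "DS", dcm_str_raw(sprintf("%g", slope)))
    stored <- round((t(volume$voxels[i, , ]) - intercept) / slope)
    # row-major pixel order: transpose so writeBin emits rows consecutively
    dcm_put(con, 0x7FE0, 0x0010, "OW",
            writeBin(as.integer(stored), raw(), size = 2, endian = "little"))
    close(con)
  }
  invisible(dir)
}
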