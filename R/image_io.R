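#' HU image container
#'
#' A 2-D raster of Hounsfield units with isotropic-or-not pixel spacing in mm.
#' Values are calibrated HU (rescale slope/intercept already applied); they are
#' held as floating point so that downstream fitting works on continuous
#' values.
#'
#' @param pixels numeric matrix of HU values, indexed `[row, col]`
#' @param spacing_mm numeric length-1 or length-2 vector, pixel size in mm
#'   (row, col). Non-square spacing is accepted with a warning; all radial
#'   distances are computed anisotropically.
#' @param origin physical position (mm) of the corner of pixel (1,1);
#'   default c(0, 0)
#' @return object of class `hu_image`
#' @export
hu_image <- function(pixels, spacing_mm, origin = c(0, 0)) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L || !is.numeric(pixels))
    stop_ttfqa("pixels must be a non-empty numeric matrix", "ttfqa_bad_image")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop_ttfqa("spacing_mm must be two positive finite values (row, col)",
               "ttfqa_bad_spacing")
  if (abs(spacing_mm[1] - spacing_mm[2]) > 1e-9 * mean(spacing_mm))
    warn_ttfqa(sprintf(
      "non-square pixel spacing (%g x %g mm); distances use anisotropic spacing",
      spacing_mm[1], spacing_mm[2]), "ttfqa_anisotropic_spacing")
  structure(list(pixels = pixels * 1.0, spacing_mm = spacing_mm,
                 origin = as.numeric(origin)),
            class = "hu_image")
}

#' @export
print.hu_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<hu_image> %d x %d px, %.4g x %.4g mm/px, HU range [%.1f, %.1f]\n",
              d[1], d[2], x$spacing_mm[1], x$spacing_mm[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.hu_image <- function(x) dim(x$pixels)

## ---------------------------------------------------------------------------
## Minimal single-frame CT DICOM (explicit VR little endian).
## Only the tags the pipeline needs are interpreted; everything else is
## skipped structurally. Stored pixels are signed 16-bit with rescale
## slope/intercept, so HU round-trips within 0.5 HU.
## ---------------------------------------------------------------------------

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"

dcm_pad <- function(raw_val, pad = as.raw(0L)) {
  if (length(raw_val) %% 2L == 1L) c(raw_val, pad) else raw_val
}

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                endian = "little")

# one explicit-VR element as a raw vector
dcm_element <- function(group, elem, vr, value) {
  long_vr <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  if (vr %in% c("UI"))       val <- dcm_pad(charToRaw(value))
  else if (vr %in% c("CS", "DS", "IS", "LO", "SH"))
    val <- dcm_pad(charToRaw(value), charToRaw(" "))
  else if (vr == "US")       val <- dcm_u16(value)
  else if (vr == "UL")       val <- writeBin(as.integer(value), raw(),
                                             size = 4L, endian = "little")
  else if (vr == "OW")       val <- value        # already raw
  else stop("unsupported VR ", vr)
  hdr <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (long_vr) {
    c(hdr, as.raw(c(0L, 0L)),
      writeBin(length(val), raw(), size = 4L, endian = "little"), val)
  } else {
    c(hdr, dcm_u16(length(val)), val)
  }
}

#' Write an HU image as a single-frame CT DICOM file
#'
#' Pixels are stored as signed 16-bit values with RescaleSlope 1 and
#' RescaleIntercept -1024, so any HU in \[-1024, 3071\] (and well beyond)
#' round-trips within 0.5 HU. The file uses the explicit VR little endian
#' transfer syntax.
#'
#' @param img an [hu_image]
#' @param path output file path
#' @return `path`, invisibly
#' @export
save_slice <- function(img, path) {
  stopifnot(inherits(img, "hu_image"))
  d <- dim(img$pixels)
  intercept <- -1024
  stored <- round(img$pixels - intercept)
  if (any(stored < -32768 | stored > 32767))
    stop_ttfqa("HU values out of storable 16-bit range", "ttfqa_io_error")
  # row-major pixel order
  pix_raw <- writeBin(as.integer(t(stored)), raw(), size = 2L,
                      endian = "little")
  sop_uid <- paste0("1.2.826.0.1.3680043.2.1125.",
                    format(as.integer(Sys.time()) %% 100000L), ".",
                    sample.int(.Machine$integer.max, 1L))
  meta <- c(
    dcm_element(0x0002, 0x0002, "UI", SOP_CLASS_CT),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", SOP_CLASS_CT),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", d[1]),
    dcm_element(0x0028, 0x0011, "US", d[2]),
    dcm_element(0x0028, 0x0030, "DS",
                sprintf("%.8g\\%.8g", img$spacing_mm[1], img$spacing_mm[2])),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 1L),
    dcm_element(0x0028, 0x1052, "DS", format(intercept)),
    dcm_element(0x0028, 0x1053, "DS", "1"),
    dcm_element(0x7FE0, 0x0010, "OW", pix_raw))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_ttfqa(
                    paste0("cannot open '", path, "' for writing"),
                    "ttfqa_io_error"))
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

#' Load a single-frame CT DICOM slice into an HU image
#'
#' Reads a single-frame, uncompressed (explicit VR little endian) CT DICOM
#' file and returns calibrated HU values: stored pixels times RescaleSlope
#' plus RescaleIntercept. Pixel spacing (mm) comes from the PixelSpacing tag.
#'
#' @param path path to the DICOM file
#' @return an [hu_image]
#' @export
load_slice <- function(path) {
  if (!file.exists(path))
    stop_ttfqa(paste0("file not found: ", path), "ttfqa_io_error")
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 200L || rawToChar(bytes[129:132]) != "DICM")
    stop_ttfqa(paste0("not a DICOM file (missing DICM magic): ", path),
               "ttfqa_format_error")
  pos <- 133L
  u16 <- function(at) sum(as.integer(bytes[at + 0:1]) * c(1L, 256L))
  u32 <- function(at) sum(as.numeric(bytes[at + 0:3]) * 256^(0:3))
  tags <- new.env(parent = emptyenv())
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[pos + 4:5])
    if (!grepl("^[A-Z]{2}$", vr))
      stop_ttfqa("unsupported transfer syntax (implicit VR or compressed)",
                 "ttfqa_format_error")
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    key <- sprintf("%04x%04x", group, elem)
    if (key %in% c("00280010", "00280011", "00280100", "00280103",
                   "00280030", "00281052", "00281053", "7fe00010",
                   "00020010", "00080060")) {
      assign(key, list(vr = vr, start = vstart, len = len), envir = tags)
    }
    pos <- vstart + len
  }
  getv <- function(key) if (exists(key, envir = tags))
    get(key, envir = tags) else NULL
  str_of <- function(t) trimws(rawToChar(bytes[t$start + seq_len(t$len) - 1L]))
  ts <- getv("00020010")
  if (!is.null(ts) && !str_of(ts) %in% TRANSFER_SYNTAX_EXPLICIT_LE)
    stop_ttfqa(paste0("unsupported transfer syntax: ", str_of(ts)),
               "ttfqa_format_error")
  need <- function(key, what, cls) {
    t <- getv(key)
    if (is.null(t)) stop_ttfqa(paste0("DICOM missing ", what), cls)
    t
  }
  rows <- u16(need("00280010", "Rows tag", "ttfqa_format_error")$start)
  cols <- u16(need("00280011", "Columns tag", "ttfqa_format_error")$start)
  sp_t <- need("00280030", "PixelSpacing (calibration)",
               "ttfqa_calibration_error")
  spacing <- as.numeric(strsplit(str_of(sp_t), "\\\\")[[1]])
  ri_t <- need("00281052", "RescaleIntercept (calibration)",
               "ttfqa_calibration_error")
  rs_t <- need("00281053", "RescaleSlope (calibration)",
               "ttfqa_calibration_error")
  intercept <- as.numeric(str_of(ri_t)); slope <- as.numeric(str_of(rs_t))
  px_t <- need("7fe00010", "PixelData", "ttfqa_format_error")
  signed <- TRUE
  pr <- getv("00280103")
  if (!is.null(pr)) signed <- u16(pr$start) == 1L
  stored <- readBin(bytes[px_t$start + seq_len(px_t$len) - 1L], "integer",
                    n = rows * cols, size = 2L, signed = signed,
                    endian = "little")
  pixels <- t(matrix(stored, nrow = cols, ncol = rows))
  hu_image(pixels * slope + intercept, spacing_mm = spacing)
}
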