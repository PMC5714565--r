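# Minimal DICOM support: explicit VR little endian only, flat datasets (no
# sequences). Covers exactly what the pipeline needs — writing RT Dose
# objects and reading/writing simple single-frame image series — because no
# DICOM toolkit is available to R here. Not a general DICOM implementation.

.ts_explicit_le <- "1.2.840.10008.1.2.1"
.sop_rtdose <- "1.2.840.10008.5.1.4.1.1.481.2"
.sop_secondary <- "1.2.840.10008.5.1.4.1.1.7"
.uid_root <- "1.2.826.0.1.3680043.10.424"

.uid_env <- new.env(parent = emptyenv())
.uid_env$counter <- 0L

# deterministic-per-process unique UIDs under a fixed org root
new_uid <- function() {
  .uid_env$counter <- .uid_env$counter + 1L
  paste0(.uid_root, ".", Sys.getpid() %% 100000L, ".",
         as.integer(Sys.time()) %% 1000000L, ".", .uid_env$counter)
}

# ---- encoding helpers -------------------------------------------------------

u16_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(as.vector(rbind(v %% 256, (v %/% 256) %% 256)))
}

u32_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(as.vector(rbind(v %% 256, (v %/% 256) %% 256,
                         (v %/% 65536) %% 256, (v %/% 16777216) %% 256)))
}

raw_u16 <- function(r) {
  m <- matrix(as.integer(r), nrow = 2)
  m[1, ] + 256 * m[2, ]
}

raw_u32 <- function(r) {
  m <- matrix(as.integer(r), nrow = 4)
  m[1, ] + 256 * m[2, ] + 65536 * m[3, ] + 16777216 * m[4, ]
}

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_element <- function(group, element, vr, value) {
  val <- if (is.raw(value)) {
    value
  } else if (vr %in% c("US")) {
    u16_raw(value)
  } else if (vr %in% c("UL")) {
    u32_raw(value)
  } else if (vr == "AT") {
    c(u16_raw(value[1]), u16_raw(value[2]))
  } else {
    s <- paste(as.character(value), collapse = "\\")
    r <- charToRaw(s)
    if (length(r) %% 2 == 1)
      r <- c(r, if (vr == "UI") as.raw(0) else charToRaw(" "))
    r
  }
  n <- length(val)
  hdr <- c(u16_raw(group), u16_raw(element), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(hdr, as.raw(c(0, 0)), u32_raw(n), val)
  } else {
    if (n > 65534) stop("value too long for short-form VR ", vr)
    c(hdr, u16_raw(n), val)
  }
}

# file meta group + preamble; returns raw
dcm_file_head <- function(sop_class, sop_instance) {
  meta <- c(
    dcm_element(2L, 1L, "OB", as.raw(c(0, 1))),
    dcm_element(2L, 2L, "UI", sop_class),
    dcm_element(2L, 3L, "UI", sop_instance),
    dcm_element(2L, 16L, "UI", .ts_explicit_le),
    dcm_element(2L, 18L, "UI", paste0(.uid_root, ".1"))
  )
  c(raw(128), charToRaw("DICM"),
    dcm_element(2L, 0L, "UL", length(meta)), meta)
}

# ---- parser -----------------------------------------------------------------

# parse a flat explicit-VR-LE dataset into a named list "gggg,eeee" -> value.
# SQ and undefined lengths are skipped/rejected; numeric string VRs parsed.
parse_dicom_file <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM (part-10) file: ", path, call. = FALSE)
  out <- list()
  pos <- 133L
  n <- length(r)
  ts <- NULL
  while (pos + 8 <= n + 1) {
    grp <- raw_u16(r[pos:(pos + 1)]); el <- raw_u16(r[(pos + 2):(pos + 3)])
    vr <- rawToChar(r[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR or corrupt element at offset ", pos,
           " in ", path, call. = FALSE)
    if (vr %in% .long_vrs) {
      len <- raw_u32(r[(pos + 8):(pos + 11)])
      vstart <- pos + 12L
    } else {
      len <- raw_u16(r[(pos + 6):(pos + 7)])
      vstart <- pos + 8L
    }
    if (len == 4294967295)
      stop("undefined-length element unsupported (", sprintf("%04x,%04x", grp, el),
           ") in ", path, call. = FALSE)
    val_raw <- if (len > 0) r[vstart:(vstart + len - 1)] else raw(0)
    key <- sprintf("%04X,%04X", grp, el)
    out[[key]] <- switch(
      vr,
      US = raw_u16(val_raw),
      UL = raw_u32(val_raw),
      DS = as.numeric(strsplit(trimws(rawToChar(val_raw)), "\\\\")[[1]]),
      IS = as.integer(strsplit(trimws(rawToChar(val_raw)), "\\\\")[[1]]),
      FD = readBin(val_raw, "double", len / 8, size = 8, endian = "little"),
      OW = val_raw,
      OB = val_raw,
      SQ = NULL,
      trimws(rawToChar(val_raw))
    )
    if (identical(key, "0002,0010")) ts <- out[[key]]
    pos <- vstart + len
  }
  if (!is.null(ts) && ts != .ts_explicit_le)
    stop("unsupported transfer syntax ", ts, " in ", path, call. = FALSE)
  out
}

# ---- RT Dose ----------------------------------------------------------------

#' Write an absorbed-dose grid as a DICOM RT Dose object
#'
#' Dose is stored as unsigned integers with a `DoseGridScaling` chosen so
#' the maximum voxel uses 90% of the integer range (16-bit by default,
#' 32-bit optionally), `DoseUnits` GY, `DoseType` PHYSICAL,
#' `DoseSummationType` PLAN, and slice positions encoded in
#' `GridFrameOffsetVector`. Reading the file back reproduces every voxel to
#' within one scaling quantum.
#'
#' @param dose an [image_grid()] with quantity `"DOSE"`; values must be
#'   finite and non-negative.
#' @param path output file.
#' @param frame_of_reference Frame of Reference UID tying the dose to the
#'   anatomy it was computed on; a fresh UID is generated if omitted.
#' @param bits 16 (default) or 32 bit integer storage.
#' @return the `DoseGridScaling` used, invisibly.
#' @export
write_rtdose <- function(dose, path, frame_of_reference = NULL, bits = 16L) {
  stopifnot(inherits(dose, "image_grid"))
  if (dose$quantity != "DOSE")
    stop("write_rtdose() needs an image_grid with quantity DOSE", call. = FALSE)
  if (any(dose$values < 0))
    stop("dose values must be non-negative", call. = FALSE)
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32", call. = FALSE)
  d <- dim(dose$values)
  maxint <- 2^bits - 1
  mx <- max(dose$values)
  scaling <- if (mx > 0) mx / (0.9 * maxint) else 1
  ints <- round(dose$values / scaling)
  if (is.null(frame_of_reference)) frame_of_reference <- new_uid()
  sop_instance <- new_uid()
  offsets <- (seq_len(d[3]) - 1) * dose$spacing[3]
  fmt <- function(x) sprintf("%.10g", x)
  pix <- if (bits == 16L) u16_raw(as.vector(ints)) else u32_raw(as.vector(ints))
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", .sop_rtdose),
    dcm_element(0x0008, 0x0018, "UI", sop_instance),
    dcm_element(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_element(0x0020, 0x000D, "UI", new_uid()),
    dcm_element(0x0020, 0x000E, "UI", new_uid()),
    dcm_element(0x0020, 0x0032, "DS", fmt(dose$origin)),
    dcm_element(0x0020, 0x0037, "DS", c("1", "0", "0", "0", "1", "0")),
    dcm_element(0x0020, 0x0052, "UI", frame_of_reference),
    dcm_element(0x0028, 0x0002, "US", 1),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0008, "IS", as.character(d[3])),
    dcm_element(0x0028, 0x0009, "AT", c(0x3004, 0x000C)),
    dcm_element(0x0028, 0x0010, "US", d[2]),           # Rows    = ny
    dcm_element(0x0028, 0x0011, "US", d[1]),           # Columns = nx
    dcm_element(0x0028, 0x0030, "DS", fmt(dose$spacing[c(2, 1)])),
    dcm_element(0x0028, 0x0100, "US", bits),
    dcm_element(0x0028, 0x0101, "US", bits),
    dcm_element(0x0028, 0x0102, "US", bits - 1),
    dcm_element(0x0028, 0x0103, "US", 0),
    dcm_element(0x3004, 0x0002, "CS", "GY"),
    dcm_element(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_element(0x3004, 0x000A, "CS", "PLAN"),
    dcm_element(0x3004, 0x000C, "DS", fmt(offsets)),
    dcm_element(0x3004, 0x000E, "DS", fmt(scaling)),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  writeBin(c(dcm_file_head(.sop_rtdose, sop_instance), body), path)
  invisible(scaling)
}

#' Read a DICOM RT Dose file
#'
#' Counterpart of [write_rtdose()]; supports the explicit-VR-little-endian,
#' unsigned 16/32-bit layout that writer produces.
#'
#' @param path RT Dose file.
#' @return an [image_grid()] with quantity `"DOSE"`.
#' @export
read_rtdose <- function(path) {
  el <- parse_dicom_file(path)
  need <- function(key, what) {
    v <- el[[key]]
    if (is.null(v)) stop("RT Dose missing ", what, " (", key, ")", call. = FALSE)
    v
  }
  rows <- need("0028,0010", "Rows")
  cols <- need("0028,0011", "Columns")
  nframes <- el[["0028,0008"]]; if (is.null(nframes)) nframes <- 1L
  bits <- need("0028,0100", "BitsAllocated")
  scaling <- need("3004,000E", "DoseGridScaling")
  ps <- need("0028,0030", "PixelSpacing")       # row spacing (dy), col (dx)
  ipp <- need("0020,0032", "ImagePositionPatient")
  gfov <- need("3004,000C", "GridFrameOffsetVector")
  pix_raw <- need("7FE0,0010", "PixelData")
  ints <- if (bits == 16) raw_u16(pix_raw) else raw_u32(pix_raw)
  if (length(ints) != cols * rows * nframes)
    stop("PixelData size does not match Rows x Columns x NumberOfFrames",
         call. = FALSE)
  dz <- if (nframes > 1) {
    steps <- diff(gfov)
    if (max(abs(steps - steps[1])) > 1e-6 * max(abs(steps[1]), 1))
      stop("non-uniform GridFrameOffsetVector", call. = FALSE)
    abs(steps[1])
  } else 1
  vals <- array(ints * scaling, dim = c(cols, rows, nframes))
  image_grid(vals, spacing = c(ps[2], ps[1], dz), origin = ipp,
             quantity = "DOSE")
}

# ---- simple image series (synthetic PET) ------------------------------------

#' Write an image grid as a synthetic single-frame DICOM series
#'
#' Test/demonstration writer emulating a quantitative PET series: one file
#' per slice, 16-bit stored integers with the given `RescaleSlope`/
#' `RescaleIntercept`, units in tag (0054,1001). Intended to feed
#' [read_image()]; not a conformant PET IOD.
#'
#' @param grid an [image_grid()].
#' @param dir output directory (created if absent).
#' @param slope,intercept rescale applied on read:
#'   `value = stored * slope + intercept`. `slope = NULL` picks
#'   `max/32000` automatically.
#' @param units DICOM units string; `"CPS"` maps to quantity COUNT_RATE and
#'   `"BQML"` to ACTIVITY_CONC on read.
#' @return the directory, invisibly.
#' @export
write_dicom_series <- function(grid, dir, slope = NULL, intercept = 0,
                               units = "CPS") {
  stopifnot(inherits(grid, "image_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(grid$values)
  if (is.null(slope)) {
    mx <- max(grid$values - intercept)
    slope <- if (mx > 0) mx / 32000 else 1
  }
  series_uid <- new_uid()
  study_uid <- new_uid()
  for_uid <- new_uid()
  for (k in seq_len(d[3])) {
    stored <- round((grid$values[, , k] - intercept) / slope)
    if (any(stored < 0 | stored > 65535))
      stop("stored values out of 16-bit range; adjust slope/intercept",
           call. = FALSE)
    sop_instance <- new_uid()
    ipp <- c(grid$origin[1], grid$origin[2],
             grid$origin[3] + (k - 1) * grid$spacing[3])
    fmt <- function(x) sprintf("%.10g", x)
    body <- c(
      dcm_element(0x0008, 0x0016, "UI", .sop_secondary),
      dcm_element(0x0008, 0x0018, "UI", sop_instance),
      dcm_element(0x0008, 0x0060, "CS", "PT"),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS", fmt(ipp)),
      dcm_element(0x0020, 0x0037, "DS", c("1", "0", "0", "0", "1", "0")),
      dcm_element(0x0020, 0x0052, "UI", for_uid),
      dcm_element(0x0028, 0x0002, "US", 1),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[2]),
      dcm_element(0x0028, 0x0011, "US", d[1]),
      dcm_element(0x0028, 0x0030, "DS", fmt(grid$spacing[c(2, 1)])),
      dcm_element(0x0028, 0x0100, "US", 16),
      dcm_element(0x0028, 0x0101, "US", 16),
      dcm_element(0x0028, 0x0102, "US", 15),
      dcm_element(0x0028, 0x0103, "US", 0),
      dcm_element(0x0028, 0x1052, "DS", fmt(intercept)),
      dcm_element(0x0028, 0x1053, "DS", fmt(slope)),
      dcm_element(0x0054, 0x1001, "CS", units),
      dcm_element(0x7FE0, 0x0010, "OW", u16_raw(as.vector(stored)))
    )
    writeBin(c(dcm_file_head(.sop_secondary, sop_instance), body),
             file.path(dir, sprintf("slice%04d.dcm", k)))
  }
  invisible(dir)
}

# read a directory of single-frame DICOM files as one volume
read_dicom_series <- function(dir, quantity = NULL, reference_time = 0) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0)
    stop("no .dcm files in ", dir, call. = FALSE)
  slices <- lapply(files, parse_dicom_file)
  get1 <- function(s, key, what) {
    v <- s[[key]]
    if (is.null(v)) stop("DICOM slice missing ", what, call. = FALSE)
    v
  }
  iops <- t(vapply(slices, get1, numeric(6), key = "0020,0037",
                   what = "ImageOrientationPatient"))
  if (nrow(unique(round(iops, 6))) != 1)
    stop("mixed-orientation DICOM series", call. = FALSE)
  ipps <- t(vapply(slices, get1, numeric(3), key = "0020,0032",
                   what = "ImagePositionPatient"))
  ord <- order(ipps[, 3])
  slices <- slices[ord]; ipps <- ipps[ord, , drop = FALSE]
  nz <- length(slices)
  if (nz > 1) {
    steps <- diff(ipps[, 3])
    if (max(steps) - min(steps) > 1e-3 * max(abs(steps)))
      stop("inconsistent slice spacing in DICOM series", call. = FALSE)
    dz <- steps[1]
  } else dz <- 1
  s1 <- slices[[1]]
  rows <- get1(s1, "0028,0010", "Rows"); cols <- get1(s1, "0028,0011", "Columns")
  ps <- get1(s1, "0028,0030", "PixelSpacing")
  vals <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    slope <- s[["0028,1053"]]; if (is.null(slope)) slope <- 1
    icpt <- s[["0028,1052"]]; if (is.null(icpt)) icpt <- 0
    stored <- raw_u16(get1(s, "7FE0,0010", "PixelData"))
    if (length(stored) != rows * cols)
      stop("PixelData size mismatch in DICOM series", call. = FALSE)
    vals[, , k] <- array(stored * slope + icpt, dim = c(cols, rows))
  }
  if (is.null(quantity)) {
    u <- s1[["0054,1001"]]
    quantity <- if (identical(u, "CPS")) "COUNT_RATE"
      else if (identical(u, "BQML")) "ACTIVITY_CONC"
      else {
        warning("DICOM series has no recognised units; assuming COUNT_RATE",
                call. = FALSE)
        "COUNT_RATE"
      }
  }
  image_grid(vals, spacing = c(ps[2], ps[1], dz), origin = ipps[1, ],
             quantity = quantity, reference_time = reference_time)
}
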