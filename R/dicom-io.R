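# Minimal classic DICOM part-10 I/O (explicit VR little endian).
#
# Scope: the tag set a preclinical PET/MR conversion pipeline needs —
# identity, study/series structure, geometry, timing, diffusion gradients and
# 16-bit unsigned pixel data. Classic one-file-per-slice series are written;
# reading additionally supports multi-slice single files (NumberOfFrames > 1).
# Only the explicit-VR little-endian transfer syntax (1.2.840.10008.1.2.1) is
# handled; anything else is rejected rather than mis-parsed.

.DCM_TRANSFER_SYNTAX <- "1.2.840.10008.1.2.1"
.DCM_IMPL_UID <- "1.2.826.0.1.3680043.10.1234.1"

# keyword -> (group, element, VR). VM handled per VR (numeric vectors allowed).
.dcm_dict <- list(
  FileMetaInformationVersion = c(0x0002L, 0x0001L, "OB"),
  MediaStorageSOPClassUID    = c(0x0002L, 0x0002L, "UI"),
  MediaStorageSOPInstanceUID = c(0x0002L, 0x0003L, "UI"),
  TransferSyntaxUID          = c(0x0002L, 0x0010L, "UI"),
  ImplementationClassUID     = c(0x0002L, 0x0012L, "UI"),
  ImageType                  = c(0x0008L, 0x0008L, "CS"),
  SOPClassUID                = c(0x0008L, 0x0016L, "UI"),
  SOPInstanceUID             = c(0x0008L, 0x0018L, "UI"),
  StudyDate                  = c(0x0008L, 0x0020L, "DA"),
  SeriesDate                 = c(0x0008L, 0x0021L, "DA"),
  StudyTime                  = c(0x0008L, 0x0030L, "TM"),
  Modality                   = c(0x0008L, 0x0060L, "CS"),
  SeriesDescription          = c(0x0008L, 0x103EL, "LO"),
  PatientName                = c(0x0010L, 0x0010L, "PN"),
  PatientID                  = c(0x0010L, 0x0020L, "LO"),
  PatientSex                 = c(0x0010L, 0x0040L, "CS"),
  PatientWeight              = c(0x0010L, 0x1030L, "DS"),
  SliceThickness             = c(0x0018L, 0x0050L, "DS"),
  RepetitionTime             = c(0x0018L, 0x0080L, "DS"),
  EchoTime                   = c(0x0018L, 0x0081L, "DS"),
  EchoNumbers                = c(0x0018L, 0x0086L, "IS"),
  SpacingBetweenSlices       = c(0x0018L, 0x0088L, "DS"),
  PixelBandwidth             = c(0x0018L, 0x0095L, "DS"),
  FlipAngle                  = c(0x0018L, 0x1314L, "DS"),
  DiffusionBValue            = c(0x0018L, 0x9087L, "FD"),
  DiffusionGradientOrientation = c(0x0018L, 0x9089L, "FD"),
  StudyInstanceUID           = c(0x0020L, 0x000DL, "UI"),
  SeriesInstanceUID          = c(0x0020L, 0x000EL, "UI"),
  StudyID                    = c(0x0020L, 0x0010L, "SH"),
  SeriesNumber               = c(0x0020L, 0x0011L, "IS"),
  InstanceNumber             = c(0x0020L, 0x0013L, "IS"),
  ImagePositionPatient       = c(0x0020L, 0x0032L, "DS"),
  ImageOrientationPatient    = c(0x0020L, 0x0037L, "DS"),
  TemporalPositionIdentifier = c(0x0020L, 0x0100L, "IS"),
  NumberOfTemporalPositions  = c(0x0020L, 0x0105L, "IS"),
  SamplesPerPixel            = c(0x0028L, 0x0002L, "US"),
  PhotometricInterpretation  = c(0x0028L, 0x0004L, "CS"),
  NumberOfFrames             = c(0x0028L, 0x0008L, "IS"),
  Rows                       = c(0x0028L, 0x0010L, "US"),
  Columns                    = c(0x0028L, 0x0011L, "US"),
  PixelSpacing               = c(0x0028L, 0x0030L, "DS"),
  BitsAllocated              = c(0x0028L, 0x0100L, "US"),
  BitsStored                 = c(0x0028L, 0x0101L, "US"),
  HighBit                    = c(0x0028L, 0x0102L, "US"),
  PixelRepresentation        = c(0x0028L, 0x0103L, "US"),
  RescaleIntercept           = c(0x0028L, 0x1052L, "DS"),
  RescaleSlope               = c(0x0028L, 0x1053L, "DS"),
  FrameReferenceTime         = c(0x0054L, 0x1300L, "DS"),
  PixelData                  = c(0x7FE0L, 0x0010L, "OW")
)

.dcm_tag_lookup <- local({
  m <- do.call(rbind, lapply(.dcm_dict, function(x) x[1:2]))
  key <- sprintf("%04X,%04X", as.integer(m[, 1]), as.integer(m[, 2]))
  stats::setNames(names(.dcm_dict), key)
})

.dcm_string_vrs <- c("UI", "SH", "LO", "PN", "DA", "TM", "CS", "IS", "DS", "AE", "AS", "LT", "ST")

.dcm_format_number <- function(x) {
  s <- sprintf("%.10g", x)
  if (any(nchar(s) > 16)) s <- sprintf("%.8g", x)
  s
}

.dcm_encode_value <- function(vr, value) {
  if (vr %in% .dcm_string_vrs) {
    if (is.numeric(value)) value <- .dcm_format_number(value)
    s <- paste(value, collapse = "\\")
    b <- charToRaw(enc2utf8(s))
    if (length(b) %% 2L == 1L) {
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    }
    b
  } else if (vr == "US") {
    writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "UL") {
    writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr == "FD") {
    writeBin(as.double(value), raw(), size = 8, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    as.raw(value)
  } else {
    stop("unsupported VR for writing: ", vr)
  }
}

.dcm_encode_element <- function(group, element, vr, value_raw) {
  head <- writeBin(as.integer(c(group, element)), raw(), size = 2, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    if (length(value_raw) > 65534L) stop("value too long for short-form VR ", vr)
    c(head, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

#' Write a classic DICOM part-10 file
#'
#' Serializes a named list of DICOM attributes plus an unsigned 16-bit pixel
#' array to an explicit-VR little-endian part-10 file. Attribute names must be
#' keywords known to the internal dictionary; elements are emitted in ascending
#' tag order as the standard requires.
#'
#' @param path Output file path.
#' @param meta Named list of attribute values keyed by DICOM keyword
#'   (e.g. `PatientID`, `ImagePositionPatient`). `Rows`, `Columns`,
#'   `BitsAllocated` etc. are derived from `pixel` and need not be given.
#' @param pixel Integer matrix (rows x columns) or 3-D array
#'   (rows x columns x frames) of values in `[0, 65535]`; stored as
#'   unsigned 16-bit. A 3-D array additionally emits `NumberOfFrames`.
#' @return `path`, invisibly.
#' @export
dcm_write <- function(path, meta, pixel) {
  if (is.matrix(pixel)) pixel <- array(pixel, dim = c(dim(pixel), 1L))
  stopifnot(length(dim(pixel)) == 3L)
  if (any(pixel < 0 | pixel > 65535)) stop("pixel values outside unsigned 16-bit range")
  nr <- dim(pixel)[1]; nc <- dim(pixel)[2]; nf <- dim(pixel)[3]

  ds <- meta
  ds$SOPClassUID <- ds$SOPClassUID %||% "1.2.840.10008.5.1.4.1.1.4"
  ds$SOPInstanceUID <- ds$SOPInstanceUID %||% .dcm_uid()
  ds$SamplesPerPixel <- 1L
  ds$PhotometricInterpretation <- "MONOCHROME2"
  ds$Rows <- nr
  ds$Columns <- nc
  if (nf > 1L) ds$NumberOfFrames <- nf
  ds$BitsAllocated <- 16L
  ds$BitsStored <- 16L
  ds$HighBit <- 15L
  ds$PixelRepresentation <- 0L

  # pixel cells are row-major per frame in DICOM; R arrays are column-major
  px <- aperm(pixel, c(2L, 1L, 3L))
  pixel_raw <- writeBin(as.integer(px), raw(), size = 2, endian = "little")

  enc_one <- function(keyword, value) {
    d <- .dcm_dict[[keyword]]
    if (is.null(d)) stop("unknown DICOM keyword: ", keyword)
    vraw <- if (keyword == "PixelData") value else .dcm_encode_value(d[3], value)
    .dcm_encode_element(as.integer(d[1]), as.integer(d[2]), d[3], vraw)
  }

  ds$PixelData <- pixel_raw
  ord <- names(ds)[order(vapply(names(ds), function(k) {
    d <- .dcm_dict[[k]]
    if (is.null(d)) stop("unknown DICOM keyword: ", k)
    as.integer(d[1]) * 2^16 + as.integer(d[2])
  }, numeric(1)))]
  body <- do.call(c, lapply(ord, function(k) enc_one(k, ds[[k]])))

  fmi <- list(
    FileMetaInformationVersion = as.raw(c(0L, 1L)),
    MediaStorageSOPClassUID = ds$SOPClassUID,
    MediaStorageSOPInstanceUID = ds$SOPInstanceUID,
    TransferSyntaxUID = .DCM_TRANSFER_SYNTAX,
    ImplementationClassUID = .DCM_IMPL_UID
  )
  fmi_raw <- do.call(c, lapply(names(fmi), function(k) enc_one(k, fmi[[k]])))
  group_len <- .dcm_encode_element(0x0002L, 0x0000L, "UL",
                                   .dcm_encode_value("UL", length(fmi_raw)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, fmi_raw, body), con)
  invisible(path)
}

.dcm_uid_counter <- new.env(parent = emptyenv())
.dcm_uid_counter$n <- 0L

.dcm_uid <- function() {
  .dcm_uid_counter$n <- .dcm_uid_counter$n + 1L
  paste0(.DCM_IMPL_UID, ".", format(as.integer(Sys.time()) %% 100000L), ".",
         .dcm_uid_counter$n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.dcm_decode_value <- function(vr, bytes) {
  if (vr %in% .dcm_string_vrs) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    s <- sub("[ ]+$", "", s)
    parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
    if (vr %in% c("DS", "IS", "FD")) suppressWarnings(as.numeric(parts)) else parts
  } else if (vr == "US") {
    readBin(bytes, "integer", n = length(bytes) / 2L, size = 2,
            signed = FALSE, endian = "little")
  } else if (vr == "UL") {
    readBin(bytes, "integer", n = length(bytes) / 4L, size = 4, endian = "little")
  } else if (vr == "FD") {
    readBin(bytes, "double", n = length(bytes) / 8L, size = 8, endian = "little")
  } else {
    bytes
  }
}

#' Read a classic DICOM part-10 file
#'
#' Parses an explicit-VR little-endian part-10 file into a named list of
#' attribute values. Unknown tags are kept under a `"GGGG,EEEE"` key; the
#' pixel payload is decoded into an integer array (rows x columns x frames).
#'
#' @param path File to read.
#' @param pixel If `FALSE`, parsing stops just before PixelData (fast header
#'   scan for indexing).
#' @return Named list of attributes; when pixels are read, the array is in
#'   element `pixel_array`.
#' @export
dcm_read <- function(path, pixel = TRUE) {
  n <- file.size(path)
  if (is.na(n) || n < 140) stop("not a DICOM file: ", path)
  buf <- readBin(path, "raw", n)
  if (rawToChar(buf[129:132]) != "DICM") stop("not a DICOM file: ", path)

  u16 <- function(i) readBin(buf[i:(i + 1L)], "integer", size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(i) readBin(buf[i:(i + 3L)], "integer", size = 4, endian = "little")

  pos <- 133L
  out <- list()
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (len < 0 || vstart + len - 1L > n) stop("corrupt DICOM element in ", path)
    key <- sprintf("%04X,%04X", group, element)
    keyword <- unname(.dcm_tag_lookup[key])
    if (is.na(keyword)) keyword <- key
    is_pixel <- group == 0x7FE0L && element == 0x0010L
    if (is_pixel && !pixel) break
    value <- buf[seq.int(vstart, length.out = len)]
    if (is_pixel) {
      nr <- out$Rows; nc <- out$Columns
      nf <- if (!is.null(out$NumberOfFrames)) as.integer(out$NumberOfFrames) else 1L
      if (is.null(nr) || is.null(nc)) stop("PixelData before Rows/Columns in ", path)
      v <- readBin(value, "integer", n = len / 2L, size = 2,
                   signed = FALSE, endian = "little")
      out$pixel_array <- aperm(array(v, dim = c(nc, nr, nf)), c(2L, 1L, 3L))
    } else if (!(group == 0x0002L && element == 0x0000L)) {
      vrr <- .dcm_dict[[keyword]]
      out[[keyword]] <- .dcm_decode_value(if (is.null(vrr)) vr else vrr[3], value)
      if (keyword == "TransferSyntaxUID" && out[[keyword]] != .DCM_TRANSFER_SYNTAX)
        stop("unsupported transfer syntax '", out[[keyword]], "' in ", path)
    }
    pos <- vstart + len
  }
  out
}

#' Quick check whether a file looks like DICOM part-10
#' @param path File path.
#' @return Logical scalar.
#' @keywords internal
is_dicom_file <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 132) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 128)
  identical(rawToChar(readBin(con, "raw", 4)), "DICM")
}
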