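# dicom_ingest: discover and group raw DICOM files and assemble them into
# oriented volume stacks. Raw-data folder organization varies between sites,
# so the directory roles (subject / session / series) are declared through a
# small layout descriptor rather than hard-coded.

#' Declare how a raw DICOM tree is organized
#'
#' Gives the directory depth (1 = directly under the root) at which subject,
#' session and series folders sit. Single-session studies set `session = NULL`.
#'
#' @param subject Depth of the subject folder.
#' @param session Depth of the session folder, or `NULL` when the study has a
#'   single unlabelled session per subject.
#' @param series Depth of the series folder (its files form one series,
#'   further split by SeriesInstanceUID if mixed).
#' @return A `dicom_layout` object.
#' @export
dicom_layout <- function(subject = 1L, session = 2L, series = if (is.null(session)) 2L else 3L) {
  stopifnot(subject >= 1L, series > subject,
            is.null(session) || (session > subject && series > session))
  structure(list(subject = as.integer(subject),
                 session = if (is.null(session)) NULL else as.integer(session),
                 series = as.integer(series)),
            class = "dicom_layout")
}

.strip_label <- function(x, prefix) {
  sub(paste0("^", prefix, "-?"), "", x)
}

#' Index a raw DICOM tree into series records
#'
#' Walks the tree, assigns every readable DICOM file to exactly one series
#' (grouped by series folder + SeriesInstanceUID) and extracts subject/session
#' labels according to the layout. Non-DICOM files are skipped with a warning.
#' A series whose files disagree on image dimensions is flagged invalid rather
#' than silently merged.
#'
#' @param root Root directory of the raw tree.
#' @param layout A [dicom_layout()].
#' @return A list of `series_record` objects, each with fields `series_id`,
#'   `subject_label`, `session_label` (`NA` in single-session mode),
#'   `modality_hint` (series description), `file_paths`, `echo_times` (s),
#'   `frame_count`, `acquisition_year`, `n_slices`, `valid`.
#' @export
index_dicom_tree <- function(root, layout = dicom_layout()) {
  if (!dir.exists(root)) stop("unreadable root directory: ", root)
  files <- list.files(root, recursive = TRUE, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) {
    warning("no files found under ", root)
    return(list())
  }
  rel <- substring(files, nchar(root) + 2L)
  parts <- strsplit(rel, "/", fixed = TRUE)

  groups <- new.env(parent = emptyenv())
  skipped <- 0L
  for (i in seq_along(files)) {
    p <- parts[[i]]
    if (length(p) <= layout$series) { skipped <- skipped + 1L; next }
    if (!is_dicom_file(files[i])) { skipped <- skipped + 1L; next }
    hdr <- tryCatch(dcm_read(files[i], pixel = FALSE), error = function(e) NULL)
    if (is.null(hdr)) { skipped <- skipped + 1L; next }
    series_dir <- paste(p[seq_len(layout$series)], collapse = "/")
    uid <- hdr$SeriesInstanceUID %||% ""
    key <- paste0(series_dir, "::", uid)
    entry <- groups[[key]]
    if (is.null(entry)) {
      entry <- list(series_dir = series_dir,
                    subject = p[layout$subject],
                    session = if (is.null(layout$session)) NA_character_ else p[layout$session],
                    files = character(0), headers = list())
    }
    entry$files <- c(entry$files, files[i])
    entry$headers[[length(entry$headers) + 1L]] <- hdr
    groups[[key]] <- entry
  }
  if (skipped > 0L)
    warning(skipped, " non-DICOM or unreadable file(s) skipped under ", root)

  keys <- sort(ls(groups))
  records <- lapply(keys, function(key) {
    g <- groups[[key]]
    hs <- g$headers
    inst <- vapply(hs, function(h) as.integer(h$InstanceNumber %||% NA_integer_), 1L)
    ord <- order(inst, g$files)
    hs <- hs[ord]
    fls <- g$files[ord]
    dims <- vapply(hs, function(h) paste(h$Rows, h$Columns), "")
    valid <- length(unique(dims)) == 1L
    tes <- sort(unique(stats::na.omit(vapply(hs, function(h)
      as.numeric(h$EchoTime %||% NA_real_), 1))))
    tpi <- vapply(hs, function(h)
      as.integer(h$TemporalPositionIdentifier %||% NA_integer_), 1L)
    ntp <- vapply(hs, function(h)
      as.integer(h$NumberOfTemporalPositions %||% NA_integer_), 1L)
    frame_count <- if (any(!is.na(ntp))) max(ntp, na.rm = TRUE)
      else if (any(!is.na(tpi))) length(unique(stats::na.omit(tpi)))
      else 1L
    year <- NA_integer_
    sd <- hs[[1]]$StudyDate %||% NULL
    if (!is.null(sd) && nchar(sd[1]) >= 4L) year <- as.integer(substr(sd[1], 1, 4))
    structure(list(
      series_id = key,
      subject_label = .strip_label(g$subject, "sub"),
      session_label = if (is.na(g$session)) NA_character_ else .strip_label(g$session, "ses"),
      modality_hint = (hs[[1]]$SeriesDescription %||% basename(g$series_dir))[1],
      file_paths = fls,
      echo_times = tes / 1000,          # DICOM EchoTime is ms; records carry seconds
      frame_count = frame_count,
      acquisition_year = year,
      n_slices = length(fls),
      valid = valid
    ), class = "series_record")
  })
  records
}

#' @export
print.series_record <- function(x, ...) {
  cat("<series_record> ", x$modality_hint, " sub-", x$subject_label,
      if (!is.na(x$session_label)) paste0(" ses-", x$session_label),
      " | ", length(x$file_paths), " file(s), ",
      x$frame_count, " frame(s), ", length(x$echo_times), " echo(es)",
      if (!x$valid) " [INVALID: inconsistent dimensions]", "\n", sep = "")
  invisible(x)
}

# slice-normal projection used for spatial ordering
.slice_position <- function(hdr) {
  iop <- hdr$ImageOrientationPatient
  ipp <- hdr$ImagePositionPatient
  if (is.null(iop) || is.null(ipp)) return(NA_real_)
  r <- iop[1:3]; c_ <- iop[4:6]
  nrm <- c(r[2] * c_[3] - r[3] * c_[2],
           r[3] * c_[1] - r[1] * c_[3],
           r[1] * c_[2] - r[2] * c_[1])
  sum(nrm * ipp)
}

# RAS affine from DICOM geometry of the first slice + slice step vector.
# DICOM patient coordinates are LPS; NIfTI wants RAS, so x and y flip sign.
.affine_from_dicom <- function(iop, ipp_first, slice_step, pixel_spacing) {
  r <- iop[1:3]; c_ <- iop[4:6]
  lps <- cbind(r * pixel_spacing[2], c_ * pixel_spacing[1], slice_step)
  A <- diag(4)
  A[1:3, 1:3] <- diag(c(-1, -1, 1)) %*% lps
  A[1:3, 4] <- c(-ipp_first[1], -ipp_first[2], ipp_first[3])
  A
}

#' Assemble a series record into a volume stack
#'
#' Reads the record's files, orders slices by spatial position along the slice
#' normal (instance number as fallback), disambiguates the echo axis (distinct
#' EchoTime values) from the frame axis (temporal position / one volume per
#' multi-slice file) and builds the RAS+ affine from the DICOM geometry tags.
#'
#' @param record A `series_record` from [index_dicom_tree()].
#' @param intensity_units Unit label stored on the stack.
#' @return A [volume_stack()]. Slice axis ascends with spatial position.
#' @export
assemble_volume <- function(record, intensity_units = "arbitrary") {
  stopifnot(inherits(record, "series_record"))
  if (!record$valid)
    stop("series ", record$series_id, " has inconsistent image dimensions")
  objs <- lapply(record$file_paths, dcm_read, pixel = TRUE)
  objs <- lapply(objs, function(o) {
    s <- as.numeric((o$RescaleSlope %||% 1)[1])
    ic <- as.numeric((o$RescaleIntercept %||% 0)[1])
    if (s != 1 || ic != 0) o$pixel_array <- o$pixel_array * s + ic
    o
  })

  multi <- vapply(objs, function(o) dim(o$pixel_array)[3] > 1L, TRUE)
  if (any(multi) && !all(multi))
    stop("series ", record$series_id, " mixes single- and multi-slice files")

  ps <- objs[[1]]$PixelSpacing
  if (is.null(ps)) stop("series ", record$series_id, " lacks PixelSpacing")
  for (o in objs) if (max(abs(o$PixelSpacing - ps)) > 1e-6)
    stop("inconsistent pixel spacing across slices in ", record$series_id)
  iop <- objs[[1]]$ImageOrientationPatient
  if (is.null(iop)) stop("series ", record$series_id, " lacks ImageOrientationPatient")

  if (all(multi)) {
    vol <- .assemble_multislice(objs, record, iop, ps, intensity_units)
  } else {
    vol <- .assemble_per_slice(objs, record, iop, ps, intensity_units)
  }
  vol
}

# one file per frame, all slices of that frame inside the file
.assemble_multislice <- function(objs, record, iop, ps, intensity_units) {
  key <- vapply(objs, function(o)
    as.numeric((o$TemporalPositionIdentifier %||% o$InstanceNumber %||% NA)[1]), 1)
  if (anyNA(key)) stop("multi-slice series ", record$series_id,
                       " lacks temporal position and instance number")
  objs <- objs[order(key)]
  nz <- dim(objs[[1]]$pixel_array)[3]
  nx <- objs[[1]]$Columns; ny <- objs[[1]]$Rows
  nf <- length(objs)
  vox <- array(0, dim = c(nx, ny, nz, nf))
  for (f in seq_len(nf)) {
    px <- objs[[f]]$pixel_array              # rows x cols x slices
    vox[, , , f] <- aperm(px, c(2L, 1L, 3L))
  }
  step <- objs[[1]]$SpacingBetweenSlices %||% objs[[1]]$SliceThickness %||% 1
  r <- iop[1:3]; c_ <- iop[4:6]
  nrm <- c(r[2] * c_[3] - r[3] * c_[2], r[3] * c_[1] - r[1] * c_[3],
           r[1] * c_[2] - r[2] * c_[1])
  A <- .affine_from_dicom(iop, objs[[1]]$ImagePositionPatient, nrm * step, ps)
  ft <- .frame_times_from_objs(objs, record)
  if (nf == 1L) vox <- array(vox, dim = c(nx, ny, nz))
  volume_stack(vox, spacing = c(ps[2], ps[1], step), affine = A,
               echo_times = if (length(record$echo_times)) record$echo_times else NULL,
               frame_times = if (nf > 1L) ft$start else NULL,
               frame_durations = if (nf > 1L) ft$dur else NULL,
               intensity_units = intensity_units)
}

.frame_times_from_objs <- function(objs, record) {
  frt <- vapply(objs, function(o) as.numeric((o$FrameReferenceTime %||% NA)[1]), 1)
  if (!anyNA(frt) && length(frt) > 1L) {
    start <- frt / 1000
    dur <- c(diff(start), if (length(start) > 1L) diff(start)[length(start) - 1L] else 1)
    list(start = start, dur = dur)
  } else {
    n <- length(objs)
    list(start = seq_len(n) - 1, dur = rep(1, n))
  }
}

# classic one file per slice; group by echo and frame, order slices spatially
.assemble_per_slice <- function(objs, record, iop, ps, intensity_units) {
  te <- vapply(objs, function(o) as.numeric((o$EchoTime %||% 0)[1]), 1)
  tes <- sort(unique(te))
  fr <- vapply(objs, function(o)
    as.integer((o$TemporalPositionIdentifier %||% 1L)[1]), 1L)
  frames <- sort(unique(fr))
  n_echo <- length(tes); n_frame <- length(frames)

  nx <- objs[[1]]$Columns; ny <- objs[[1]]$Rows
  nz <- length(objs) / (n_echo * n_frame)
  if (nz != round(nz))
    stop("series ", record$series_id, ": file count ", length(objs),
         " not divisible into ", n_echo, " echo(es) x ", n_frame, " frame(s)")
  nz <- as.integer(nz)

  pos <- vapply(objs, .slice_position, 1)
  inst <- vapply(objs, function(o) as.numeric((o$InstanceNumber %||% NA)[1]), 1)
  if (anyNA(pos) && anyNA(inst))
    stop("series ", record$series_id,
         ": slices have neither spatial position nor instance number")

  vox <- array(0, dim = c(nx, ny, nz, n_echo, n_frame))
  ref_order <- NULL
  for (e in seq_len(n_echo)) for (f in seq_len(n_frame)) {
    sel <- which(te == tes[e] & fr == frames[f])
    if (length(sel) != nz)
      stop("series ", record$series_id, ": incomplete slice set for echo ", e,
           ", frame ", f)
    p <- pos[sel]
    if (anyNA(p)) {
      o <- order(inst[sel])
    } else {
      if (anyDuplicated(p)) stop("series ", record$series_id,
                                 ": tied slice positions - refusing to guess order")
      o <- order(p)
    }
    sel <- sel[o]
    if (e == 1L && f == 1L) ref_order <- sel
    for (k in seq_len(nz))
      vox[, , k, e, f] <- t(objs[[sel[k]]]$pixel_array[, , 1])
  }

  first <- objs[[ref_order[1]]]
  if (nz > 1L && !anyNA(pos)) {
    last <- objs[[ref_order[nz]]]
    step_vec <- (last$ImagePositionPatient - first$ImagePositionPatient) / (nz - 1L)
  } else {
    thick <- first$SliceThickness %||% 1
    r <- iop[1:3]; c_ <- iop[4:6]
    step_vec <- c(r[2] * c_[3] - r[3] * c_[2], r[3] * c_[1] - r[1] * c_[3],
                  r[1] * c_[2] - r[2] * c_[1]) * thick
  }
  A <- .affine_from_dicom(iop, first$ImagePositionPatient, step_vec, ps)

  dims <- c(nx, ny, nz)
  if (n_echo > 1L && n_frame > 1L) dim(vox) <- c(dims, n_echo, n_frame)
  else if (n_echo > 1L) dim(vox) <- c(dims, n_echo)
  else if (n_frame > 1L) dim(vox) <- c(dims, n_frame)
  else dim(vox) <- dims

  step_len <- sqrt(sum(step_vec^2))
  volume_stack(vox, spacing = c(ps[2], ps[1], step_len), affine = A,
               echo_times = if (n_echo > 1L) tes / 1000
                            else if (length(record$echo_times)) record$echo_times else NULL,
               frame_times = if (n_frame > 1L) frames - 1 else NULL,
               frame_durations = if (n_frame > 1L) rep(1, n_frame) else NULL,
               intensity_units = intensity_units)
}

#' Extract diffusion gradient tables from a series
#'
#' Reads per-volume b-values and gradient orientations, ordered as the volumes
#' appear in the assembled 4-D stack (ascending temporal position). b = 0
#' volumes get a zero vector.
#'
#' @param record A diffusion `series_record`.
#' @return List with `bvals` (numeric vector, s/mm^2) and `bvecs` (matrix,
#'   one unit or zero 3-vector per row).
#' @export
extract_diffusion_tables <- function(record) {
  stopifnot(inherits(record, "series_record"))
  hs <- lapply(record$file_paths, dcm_read, pixel = FALSE)
  fr <- vapply(hs, function(h)
    as.integer((h$TemporalPositionIdentifier %||% 1L)[1]), 1L)
  frames <- sort(unique(fr))
  bvals <- numeric(length(frames))
  bvecs <- matrix(0, length(frames), 3L)
  for (i in seq_along(frames)) {
    h <- hs[[which(fr == frames[i])[1]]]
    if (is.null(h$DiffusionBValue))
      stop("series ", record$series_id, ": diffusion gradient tags absent; ",
           "supply b-values through the sequence-overview config fallback")
    bvals[i] <- h$DiffusionBValue[1]
    if (bvals[i] > 0) {
      g <- h$DiffusionGradientOrientation
      if (is.null(g) || length(g) != 3L)
        stop("series ", record$series_id, ": gradient orientation missing for b>0 volume")
      nrm <- sqrt(sum(g^2))
      if (abs(nrm - 1) > 1e-3)
        stop("series ", record$series_id, ": gradient vector not unit norm")
      bvecs[i, ] <- g
    }
  }
  list(bvals = bvals, bvecs = bvecs)
}
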