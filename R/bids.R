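# bids_builder: sidecar resolution with a fixed, auditable precedence
# (dose config > DICOM via tag map > overview fallback), BIDS naming, and the
# dataset writer (NIfTI-1 + JSON sidecars + dwi gradient tables + the
# mandatory dataset-level files).

.PET_DOSE_KEYS <- c("TracerName", "InjectedRadioactivity", "InjectedMass",
                    "SpecificRadioactivity")
.SECONDS_KEYS <- c("EchoTime", "RepetitionTime")   # DICOM stores these in ms

.SUFFIX_DATATYPE <- c(T1w = "anat", T2w = "anat", T2starw = "anat",
                      FLAIR = "anat", angio = "anat", T1map = "anat",
                      dwi = "dwi", dce = "perf", dsc = "perf", asl = "perf",
                      pet = "pet")

#' Match a series record against the sequence overview
#'
#' @param record A `series_record`.
#' @param overview Overview config from [load_configs()].
#' @return The matching row index; `NA` (with a warning) when nothing matches.
#'   Two or more matches are an error — ambiguity is never auto-resolved.
#' @export
match_overview <- function(record, overview) {
  hits <- which(vapply(overview$match_pattern, function(p)
    grepl(p, record$modality_hint), TRUE))
  if (length(hits) == 0L) {
    warning("no sequence-overview row matches '", record$modality_hint,
            "'; series skipped")
    return(NA_integer_)
  }
  if (length(hits) > 1L)
    stop("series '", record$modality_hint, "' matches ", length(hits),
         " overview rows (", paste(overview$match_pattern[hits], collapse = ", "),
         "); patterns must be unambiguous")
  hits
}

#' Resolve the BIDS sidecar for one acquisition
#'
#' Fills every key the overview row requires, by fixed precedence:
#' PET dose keys come from the dose config; everything else first from the
#' DICOM header through the tag map, then from the overview row's fallback
#' values. Each key records where its value came from (`dose_config`,
#' `dicom` or `fallback`) in the `provenance` attribute. An unresolvable
#' required key is an error, never a silent omission.
#'
#' @param dicom_meta Named list of DICOM attributes (one representative file).
#' @param record The `series_record` being converted.
#' @param overview,tagmap,doses Configs from [load_configs()].
#' @param row Overview row index; defaults to [match_overview()].
#' @return Named list (the sidecar payload) with attribute `provenance`, or
#'   `NULL` when no overview row matches.
#' @export
resolve_sidecar <- function(dicom_meta, record, overview, tagmap, doses = NULL,
                            row = NULL) {
  if (is.null(row)) row <- match_overview(record, overview)
  if (is.na(row)) return(NULL)
  required <- overview$.required[[row]]
  fallback <- overview$.fallback[[row]]
  entities <- overview$.entities[[row]]
  suffix <- overview$bids_suffix[row]
  is_pet <- identical(suffix, "pet")

  payload <- list()
  prov <- character(0)

  dose_row <- NULL
  if (is_pet && any(required %in% .PET_DOSE_KEYS)) {
    if (is.null(doses))
      stop("PET series selected for sub-", record$subject_label,
           " but no PET doses file was provided")
    trc <- entities$trc %||% ""
    sess <- if (is.na(record$session_label)) "" else record$session_label
    hit <- which(doses$subject == record$subject_label &
                 (doses$session == sess | (!nzchar(sess) & !nzchar(doses$session))) &
                 doses$tracer == trc)
    if (length(hit) >= 1L) dose_row <- doses[hit[1L], ]
  }

  schedule <- NULL
  if ("frame_schedule" %in% names(overview) &&
      nzchar(overview$frame_schedule[row] %||% "") &&
      !is.na(overview$frame_schedule[row])) {
    schedule <- expand_frame_schedule(overview$frame_schedule[row])
    if ("declared_frames" %in% names(overview)) {
      decl <- suppressWarnings(as.integer(overview$declared_frames[row]))
      if (!is.na(decl) && decl != length(schedule$FrameDuration))
        warning("overview row ", row, " declares ", decl, " frames but the ",
                "schedule expands to ", length(schedule$FrameDuration),
                "; trusting the schedule arithmetic")
    }
  }

  for (key in required) {
    value <- NULL; src <- NULL
    if (key %in% .PET_DOSE_KEYS && !is.null(dose_row)) {
      v <- if (key == "TracerName") dose_row$tracer else dose_row[[key]]
      if (!is.null(v) && !is.na(v)) { value <- v; src <- "dose_config" }
    }
    if (is.null(value) && key %in% c("FrameTimesStart", "FrameDuration") &&
        !is.null(schedule)) {
      value <- schedule[[key]]; src <- "fallback"
    }
    if (is.null(value) && key == "EchoTime" && length(record$echo_times) > 1L) {
      value <- record$echo_times      # multi-echo: full vector, already seconds
      src <- "dicom"
    }
    if (is.null(value)) {
      tag <- tagmap$dicom_tag[match(key, tagmap$bids_key)]
      if (!is.na(tag) && !is.null(dicom_meta[[tag]])) {
        value <- dicom_meta[[tag]]
        if (key %in% .SECONDS_KEYS) value <- value / 1000
        src <- "dicom"
      }
    }
    if (is.null(value) && key %in% names(fallback)) {
      value <- fallback[[key]]; src <- "fallback"
    }
    if (is.null(value))
      stop("required sidecar key '", key, "' unresolvable for series '",
           record$modality_hint, "' (sub-", record$subject_label,
           "): not in DICOM, tag map fallback chain or dose config")
    payload[[key]] <- value
    prov[key] <- src
  }

  if (!is.null(payload$FrameTimesStart)) {
    n <- length(payload$FrameTimesStart)
    if (n != length(payload$FrameDuration))
      stop("FrameTimesStart and FrameDuration lengths differ")
    if (n > 1L && any(diff(payload$FrameTimesStart) <= 0))
      stop("FrameTimesStart must be strictly increasing")
  }
  attr(payload, "provenance") <- prov
  payload
}

.BIDS_ENTITY_ORDER <- c("task", "acq", "ce", "trc", "rec", "dir", "run",
                        "mod", "echo", "part")

#' Build a BIDS-relative file path
#'
#' @param subject,session Labels (alphanumeric; `session = NULL` in
#'   single-session mode, in which case no `ses-` entity appears anywhere).
#' @param entities Named list/vector of BIDS entities (e.g. `list(trc = "PK11195")`);
#'   values are sanitized to alphanumerics.
#' @param suffix BIDS suffix (T1w, T2w, dwi, pet, ...).
#' @param extension File extension including the dot.
#' @param datatype Datatype folder; inferred from the suffix when omitted.
#' @return Relative path such as
#'   `sub-01/ses-01/pet/sub-01_ses-01_trc-PK11195_pet.nii.gz`.
#' @export
bids_name <- function(subject, session = NULL, entities = list(), suffix,
                      extension = ".nii.gz", datatype = NULL) {
  chk <- function(lbl, what) {
    if (!grepl("^[A-Za-z0-9]+$", lbl))
      stop("illegal characters in ", what, " label: '", lbl, "'")
    lbl
  }
  subject <- chk(subject, "subject")
  if (!is.null(session)) session <- chk(session, "session")
  if (is.null(datatype)) {
    datatype <- .SUFFIX_DATATYPE[[suffix]]
    if (is.null(datatype)) stop("unknown BIDS suffix '", suffix,
                                "'; give datatype explicitly")
  }
  parts <- paste0("sub-", subject)
  if (!is.null(session)) parts <- c(parts, paste0("ses-", session))
  ents <- entities[order(match(names(entities), .BIDS_ENTITY_ORDER))]
  for (k in names(ents)) {
    v <- gsub("[^A-Za-z0-9]", "", as.character(ents[[k]]))
    if (!nzchar(v)) stop("entity '", k, "' empty after sanitization")
    parts <- c(parts, paste0(k, "-", v))
  }
  fname <- paste0(paste(parts, collapse = "_"), "_", suffix, extension)
  dirpath <- if (is.null(session)) file.path(paste0("sub-", subject), datatype)
             else file.path(paste0("sub-", subject), paste0("ses-", session), datatype)
  file.path(dirpath, fname)
}

.write_json_sidecar <- function(payload, path) {
  payload <- payload[order(names(payload))]
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(txt, path)
}

.write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  img <- RNifti::`pixdim<-`(img, c(vol$spacing, rep(1, length(dim(vol$voxels)) - 3L)))
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' Read a BIDS image + sidecar back into a volume stack
#'
#' @param nifti_path Path to a `.nii(.gz)` written by [write_dataset()].
#' @return A [volume_stack()]; echo/frame axes are reconstructed from the
#'   sidecar's `EchoTime`/`FrameTimesStart` arrays when present.
#' @export
read_bids_volume <- function(nifti_path) {
  img <- RNifti::readNifti(nifti_path)
  A <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(A) <- list(dim = dim(A))
  side_path <- sub("\\.nii(\\.gz)?$", ".json", nifti_path)
  side <- if (file.exists(side_path)) jsonlite::fromJSON(side_path) else list()
  vox <- array(as.numeric(img), dim = dim(img))
  spacing <- RNifti::pixdim(img)[1:3]
  et <- side$EchoTime
  ft <- side$FrameTimesStart
  fd <- side$FrameDuration
  nd <- length(dim(vox))
  # a plain 4-D image is a frame axis unless the sidecar declares multi-echo
  if (nd == 4L && (is.null(et) || length(et) == 1L) && is.null(ft)) {
    ft <- seq_len(dim(vox)[4]) - 1
    fd <- rep(1, dim(vox)[4])
  }
  volume_stack(vox, spacing = spacing, affine = A,
               echo_times = if (!is.null(et) && length(et) > 1L) et else
                 if (!is.null(et)) et else NULL,
               frame_times = if (!is.null(ft) && length(ft) > 1L) ft else NULL,
               frame_durations = if (!is.null(fd) && length(fd) > 1L) fd else NULL)
}

#' Write a BIDS dataset from assembled volumes and resolved sidecars
#'
#' @param conversions List of items, each a list with fields `volume`
#'   (a `volume_stack`), `sidecar` (from [resolve_sidecar()]), `subject`,
#'   `session` (`NA` for single-session), `entities`, `suffix`, `datatype`,
#'   and optionally `diffusion` (from [extract_diffusion_tables()]).
#' @param out_root Output directory (created if needed).
#' @param dataset_name Name for `dataset_description.json`.
#' @param participants Optional data frame written as `participants.tsv`;
#'   when omitted a template with the standard columns is generated from the
#'   subject labels.
#' @param overwrite Refuse to clobber existing image files unless `TRUE`.
#' @return Character vector of files written (relative to `out_root`),
#'   invisibly.
#' @export
write_dataset <- function(conversions, out_root, dataset_name = "converted",
                          participants = NULL, overwrite = FALSE) {
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (cv in conversions) {
    session <- if (is.null(cv$session) || is.na(cv$session)) NULL else cv$session
    rel <- bids_name(cv$subject, session, cv$entities %||% list(),
                     cv$suffix, ".nii.gz", cv$datatype)
    path <- file.path(out_root, rel)
    if (file.exists(path) && !overwrite)
      stop("refusing to overwrite existing ", rel, " (use overwrite = TRUE)")
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    .write_nifti_volume(cv$volume, path)
    written <- c(written, rel)
    if (!is.null(cv$sidecar)) {
      jrel <- sub("\\.nii(\\.gz)?$", ".json", rel)
      .write_json_sidecar(cv$sidecar, file.path(out_root, jrel))
      written <- c(written, jrel)
    }
    if (!is.null(cv$diffusion)) {
      brel <- sub("\\.nii(\\.gz)?$", ".bval", rel)
      vrel <- sub("\\.nii(\\.gz)?$", ".bvec", rel)
      writeLines(paste(format(cv$diffusion$bvals, trim = TRUE), collapse = " "),
                 file.path(out_root, brel))
      bv <- t(cv$diffusion$bvecs)        # FSL layout: 3 rows of n directions
      writeLines(apply(bv, 1, function(r)
        paste(format(r, trim = TRUE), collapse = " ")),
        file.path(out_root, vrel))
      written <- c(written, brel, vrel)
    }
  }
  dd <- file.path(out_root, "dataset_description.json")
  if (!file.exists(dd))
    .write_json_sidecar(list(Name = dataset_name, BIDSVersion = "1.8.0",
                             DatasetType = "raw"), dd)
  pt <- file.path(out_root, "participants.tsv")
  if (!file.exists(pt)) {
    if (is.null(participants)) {
      subs <- sort(unique(vapply(conversions, function(cv)
        paste0("sub-", cv$subject), "")))
      participants <- data.frame(participant_id = subs, species = NA,
                                 age = NA, sex = NA, weight = NA)
    }
    utils::write.table(participants, pt, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "n/a")
  }
  invisible(written)
}

#' Convert a raw DICOM tree to a BIDS dataset
#'
#' End-to-end driver: index the tree, match each series against the sequence
#' overview, assemble volumes, reorient to the target axis code, resolve
#' sidecars and write the BIDS tree.
#'
#' @param raw_root Raw DICOM tree root.
#' @param out_root Output BIDS root.
#' @param configs From [load_configs()], or a list(overview, tagmap, doses).
#' @param layout [dicom_layout()] describing the raw tree.
#' @param subjects,sessions,sequences Optional selection filters (labels /
#'   bids_suffix values); `NULL` selects everything.
#' @param orientation Target three-letter axis code for all written images.
#' @param participants Optional participants data frame.
#' @param overwrite Passed to [write_dataset()].
#' @param dataset_name Dataset name.
#' @return Invisibly, the list of conversion items written.
#' @export
convert_to_bids <- function(raw_root, out_root, configs,
                            layout = dicom_layout(), subjects = NULL,
                            sessions = NULL, sequences = NULL,
                            orientation = "RPI", participants = NULL,
                            overwrite = FALSE, dataset_name = "converted") {
  records <- index_dicom_tree(raw_root, layout)
  conversions <- list()
  for (rec in records) {
    if (!rec$valid) {
      warning("skipping series with inconsistent dimensions: ", rec$series_id)
      next
    }
    if (!is.null(subjects) && !(rec$subject_label %in% subjects)) next
    if (!is.null(sessions) && !is.na(rec$session_label) &&
        !(rec$session_label %in% sessions)) next
    row <- tryCatch(match_overview(rec, configs$overview),
                    warning = function(w) { warning(w); NA_integer_ })
    if (is.na(row)) next
    suffix <- configs$overview$bids_suffix[row]
    if (!is.null(sequences) && !(suffix %in% sequences)) next

    vol <- assemble_volume(rec)
    src_code <- orientation_code(vol$affine)
    vol <- reorient(vol, orientation)
    meta <- dcm_read(rec$file_paths[1], pixel = FALSE)
    sidecar <- resolve_sidecar(meta, rec, configs$overview, configs$tagmap,
                               configs$doses, row = row)
    diffusion <- NULL
    if (identical(suffix, "dwi")) {
      diffusion <- extract_diffusion_tables(rec)
      diffusion$bvecs <- reorient_bvecs(diffusion$bvecs, src_code, orientation)
    }
    conversions[[length(conversions) + 1L]] <- list(
      volume = vol, sidecar = sidecar,
      subject = rec$subject_label, session = rec$session_label,
      entities = configs$overview$.entities[[row]],
      suffix = suffix, datatype = configs$overview$datatype[row],
      diffusion = diffusion, record = rec)
  }
  write_dataset(conversions, out_root, dataset_name = dataset_name,
                participants = participants, overwrite = overwrite)
  invisible(conversions)
}

#' Rule-based structural check of a BIDS tree
#'
#' Verifies the dataset-level required files, that every image file follows
#' the `sub-XX[_ses-YY][_entities]_suffix` naming grammar, sits under the
#' matching subject/session/datatype folder, and has a JSON sidecar; dwi
#' images must carry .bval/.bvec.
#'
#' @param root BIDS root.
#' @return List with `ok` (logical) and `problems` (character vector).
#' @export
validate_bids_tree <- function(root) {
  problems <- character(0)
  for (f in c("dataset_description.json", "participants.tsv"))
    if (!file.exists(file.path(root, f)))
      problems <- c(problems, paste("missing", f))
  imgs <- list.files(root, pattern = "\\.nii(\\.gz)?$", recursive = TRUE)
  if (length(imgs) == 0L) problems <- c(problems, "no images in tree")
  rx <- paste0("^sub-[A-Za-z0-9]+(/ses-[A-Za-z0-9]+)?/(anat|dwi|perf|pet|func|fmap)/",
               "sub-[A-Za-z0-9]+(_ses-[A-Za-z0-9]+)?(_[a-z]+-[A-Za-z0-9]+)*",
               "_[A-Za-z0-9]+\\.nii(\\.gz)?$")
  for (im in imgs) {
    if (!grepl(rx, im)) {
      problems <- c(problems, paste("bad name:", im))
      next
    }
    pp <- strsplit(im, "/")[[1]]
    base <- basename(im)
    if (!startsWith(base, paste0(pp[1], if (length(pp) == 4L) paste0("_", pp[2]) else "")))
      problems <- c(problems, paste("folder/name mismatch:", im))
    side <- sub("\\.nii(\\.gz)?$", ".json", im)
    if (!file.exists(file.path(root, side)))
      problems <- c(problems, paste("missing sidecar for", im))
    if (grepl("_dwi\\.nii", im)) {
      for (ext in c(".bval", ".bvec"))
        if (!file.exists(file.path(root, sub("\\.nii(\\.gz)?$", ext, im))))
          problems <- c(problems, paste0("missing ", ext, " for ", im))
    }
  }
  list(ok = length(problems) == 0L, problems = problems)
}
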