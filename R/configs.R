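# The three configuration files driving a conversion:
#   * sequence overview — which series to convert, where they go in the BIDS
#     tree, which sidecar keys they require and replacement values for tags
#     missing from the DICOM headers;
#   * PET doses — per subject/session/tracer injected-radioactivity values
#     required by the BIDS PET sidecar;
#   * tag map — the DICOM keyword supplying each BIDS sidecar key.
# All three are UTF-8 comma-separated files with a header row.

.split_kv <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- paste(x[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[`, "", 1L))
}

.split_list <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Parse a frame-schedule string into blocks
#'
#' A schedule such as `"8x4;4x6;6x10;8x20"` means 8 frames of 4 s, then 4 of
#' 6 s, 6 of 10 s and 8 of 20 s.
#'
#' @param s Schedule string, blocks separated by `;` (or `,`), each
#'   `<repeat>x<duration_s>`.
#' @return A `frame_schedule`: data frame with columns `repeats`, `duration`.
#' @export
parse_frame_schedule <- function(s) {
  s <- gsub(",", ";", s, fixed = TRUE)
  parts <- .split_list(s)
  if (length(parts) == 0L) stop("empty frame schedule")
  m <- regmatches(parts, regexec("^\\s*([0-9]+)\\s*[xX]\\s*([0-9.]+)\\s*$", parts))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed frame-schedule block(s): ",
                     paste(parts[bad], collapse = ", "))
  out <- data.frame(repeats = as.integer(vapply(m, `[`, "", 2L)),
                    duration = as.numeric(vapply(m, `[`, "", 3L)))
  if (any(out$repeats < 1L) || any(out$duration <= 0))
    stop("frame schedule needs repeats >= 1 and duration > 0")
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Expand a frame schedule into start times and durations
#'
#' Frame starts are cumulative: the first frame starts at 0 s and each
#' subsequent frame starts when the previous one ends.
#'
#' @param schedule A `frame_schedule` (from [parse_frame_schedule()]) or a
#'   schedule string.
#' @return List with `FrameTimesStart` and `FrameDuration`, both in seconds,
#'   one entry per frame.
#' @export
expand_frame_schedule <- function(schedule) {
  if (is.character(schedule)) schedule <- parse_frame_schedule(schedule)
  stopifnot(inherits(schedule, "frame_schedule"))
  if (nrow(schedule) == 0L) stop("empty frame schedule")
  durations <- rep(schedule$duration, times = schedule$repeats)
  starts <- cumsum(c(0, durations[-length(durations)]))
  list(FrameTimesStart = starts, FrameDuration = durations)
}

#' Load and validate the three conversion configuration files
#'
#' @param overview_path CSV with columns `match_pattern`, `bids_suffix`,
#'   `datatype`, `entities` (`k=v;k=v`), `required_keys` (`;`-separated),
#'   `fallback_values` (`k=v;k=v`), optional `frame_schedule` and
#'   `declared_frames`.
#' @param tagmap_path CSV with columns `bids_key`, `dicom_tag` (DICOM keyword).
#' @param doses_path CSV with columns `subject`, `session`, `tracer`,
#'   `InjectedRadioactivity` (MBq), `InjectedMass` (nmol),
#'   `SpecificRadioactivity` (GBq/umol). Only needed when PET series are
#'   converted; may be `NULL` otherwise.
#' @return List with elements `overview`, `tagmap`, `doses` (the latter `NULL`
#'   when not supplied).
#' @export
load_configs <- function(overview_path, tagmap_path, doses_path = NULL) {
  if (!file.exists(overview_path)) stop("sequence overview not found: ", overview_path)
  if (!file.exists(tagmap_path)) stop("tag map not found: ", tagmap_path)
  ov <- utils::read.csv(overview_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("match_pattern", "bids_suffix", "datatype", "entities",
            "required_keys", "fallback_values")
  miss <- setdiff(need, names(ov))
  if (length(miss)) stop("sequence overview lacks column(s): ",
                         paste(miss, collapse = ", "))
  dup <- duplicated(ov$match_pattern)
  if (any(dup)) stop("duplicate match_pattern in sequence overview, row(s): ",
                     paste(which(dup), collapse = ", "))
  ov$.entities <- lapply(ov$entities, .split_kv)
  ov$.required <- lapply(ov$required_keys, .split_list)
  ov$.fallback <- lapply(ov$fallback_values, .split_kv)

  tm <- utils::read.csv(tagmap_path, stringsAsFactors = FALSE)
  if (!all(c("bids_key", "dicom_tag") %in% names(tm)))
    stop("tag map needs columns bids_key, dicom_tag")
  if (anyDuplicated(tm$bids_key))
    stop("duplicate bids_key in tag map, row(s): ",
         paste(which(duplicated(tm$bids_key)), collapse = ", "))

  doses <- NULL
  if (!is.null(doses_path)) {
    if (!file.exists(doses_path)) stop("PET doses file not found: ", doses_path)
    doses <- utils::read.csv(doses_path, stringsAsFactors = FALSE,
                             colClasses = c(subject = "character",
                                            session = "character"))
    dn <- c("subject", "session", "tracer", "InjectedRadioactivity",
            "InjectedMass", "SpecificRadioactivity")
    miss <- setdiff(dn, names(doses))
    if (length(miss)) stop("PET doses file lacks column(s): ",
                           paste(miss, collapse = ", "))
    for (col in dn[4:6]) {
      bad <- which(!is.na(doses[[col]]) & doses[[col]] <= 0)
      if (length(bad)) stop("non-positive ", col, " in PET doses row(s): ",
                            paste(bad, collapse = ", "))
    }
    if (any(is.na(doses$tracer) | !nzchar(doses$tracer)))
      stop("empty tracer in PET doses file")
    doses$subject <- as.character(doses$subject)
    doses$session <- as.character(doses$session)
  }
  list(overview = ov, tagmap = tm, doses = doses)
}
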