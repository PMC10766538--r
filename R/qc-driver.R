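# QC over a converted BIDS tree: one record per image, plus PNECR curves
# from optional per-frame count tables.

#' Read a per-frame prompts/randoms count table
#'
#' @param path CSV with columns `frame_index`, `start_s`, `duration_s`,
#'   `prompts`, `randoms`.
#' @return A [count_rate_series()].
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("start_s", "duration_s", "prompts", "randoms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("count table ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[order(df$start_s), ]
  count_rate_series(df$start_s, df$duration_s, df$prompts, df$randoms)
}

.parse_bids_name <- function(rel) {
  base <- sub("\\.nii(\\.gz)?$", "", basename(rel))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  getent <- function(p) {
    hit <- grep(paste0("^", p, "-"), parts, value = TRUE)
    if (length(hit)) sub(paste0("^", p, "-"), "", hit[1]) else NA_character_
  }
  list(subject = getent("sub"), session = getent("ses"),
       suffix = parts[length(parts)],
       trc = getent("trc"))
}

#' Run the QC battery over a BIDS dataset
#'
#' Computes the Otsu-VOI metrics for every image (with the dynamic /
#' multi-echo averaging rules), attaches PNECR curves for PET acquisitions
#' with a matching count table, and optionally writes the QC table as TSV.
#'
#' @param bids_root BIDS dataset root.
#' @param counts Character vector of count-table CSVs; matched to PET images
#'   by `sub-XX_ses-YY_trc-TT` in the file name.
#' @param out_dir If given, `qc_records.tsv` (and curves) are written there.
#' @return List with `records` (QC data frame, one row per image) and
#'   `count_series` (named list of [pnecr_series()] outputs).
#' @export
qc_bids_dataset <- function(bids_root, counts = character(0), out_dir = NULL) {
  imgs <- list.files(bids_root, pattern = "\\.nii(\\.gz)?$", recursive = TRUE)
  if (length(imgs) == 0L) stop("no images under ", bids_root)
  count_keys <- vapply(counts, function(p) {
    b <- basename(p)
    sub("_counts\\.csv$", "", b)
  }, "")
  rows <- list(); series_out <- list()
  for (rel in imgs) {
    info <- .parse_bids_name(rel)
    vol <- read_bids_volume(file.path(bids_root, rel))
    seq_lab <- if (!is.na(info$trc)) paste0("trc-", info$trc, "_", info$suffix)
               else info$suffix
    year <- NA_integer_
    side_path <- file.path(bids_root, sub("\\.nii(\\.gz)?$", ".json", rel))
    if (file.exists(side_path)) {
      side <- jsonlite::fromJSON(side_path)
      if (!is.null(side$AcquisitionYear)) year <- as.integer(side$AcquisitionYear)
    }
    rows[[rel]] <- qc_acquisition(vol, subject = info$subject,
                                  session = info$session,
                                  sequence = seq_lab, year = year)
    rows[[rel]]$pnecr_max <- NA_real_
    if (identical(info$suffix, "pet") && length(counts)) {
      key <- paste0("sub-", info$subject,
                    if (!is.na(info$session)) paste0("_ses-", info$session),
                    if (!is.na(info$trc)) paste0("_trc-", info$trc))
      hit <- which(count_keys == key)
      if (length(hit) == 1L) {
        cs <- pnecr_series(read_count_table(counts[hit]))
        lbl <- key
        series_out[[lbl]] <- cs
        rows[[rel]]$pnecr_max <- attr(cs, "pnecr_max")
      }
    }
  }
  records <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(records, file.path(out_dir, "qc_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(records = records, count_series = series_out)
}
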