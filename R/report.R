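# cohort_report: dataset-level aggregation — the availability counter /
# heatmap over the BIDS tree, the participants summary table and the
# violin + strip distribution exports of the QC metrics.

#' Availability matrix of a BIDS tree
#'
#' Counts, for every subject-session row, how many images of each sequence
#' column (BIDS suffix plus distinguishing entities such as the PET tracer)
#' are present. Missing acquisitions appear as 0.
#'
#' @param bids_root BIDS dataset root.
#' @return Integer matrix; rows `sub-XX` or `sub-XX_ses-YY`, columns sequence
#'   labels, attribute `files` holding the indexed file table.
#' @export
availability_matrix <- function(bids_root) {
  imgs <- list.files(bids_root, pattern = "\\.nii(\\.gz)?$", recursive = TRUE)
  if (length(imgs) == 0L) {
    m <- matrix(integer(0), 0, 0)
    return(m)
  }
  base <- sub("\\.nii(\\.gz)?$", "", basename(imgs))
  parts <- strsplit(base, "_", fixed = TRUE)
  ok <- vapply(parts, function(p) grepl("^sub-", p[1]), TRUE)
  if (any(!ok)) warning(sum(!ok), " non-BIDS image name(s) ignored")
  parts <- parts[ok]
  rowlab <- vapply(parts, function(p) {
    ses <- grep("^ses-", p, value = TRUE)
    paste(c(p[1], ses), collapse = "_")
  }, "")
  collab <- vapply(parts, function(p) {
    suffix <- p[length(p)]
    ents <- p[-c(1, length(p))]
    ents <- ents[!grepl("^ses-", ents)]
    paste(c(ents, suffix), collapse = "_")
  }, "")
  rows <- sort(unique(rowlab))
  cols <- sort(unique(collab))
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_along(rowlab))
    m[rowlab[i], collab[i]] <- m[rowlab[i], collab[i]] + 1L
  attr(m, "files") <- data.frame(file = imgs[ok], row = rowlab, column = collab,
                                 stringsAsFactors = FALSE)
  m
}

#' Summarize a participants table
#'
#' For each numeric variable: mean, sample SD (n-1 denominator) and n; plus a
#' value -> (count, percent) distribution table, optionally over bins.
#'
#' @param table Data frame, e.g. read from `participants.tsv`.
#' @param variables Columns to summarize (default: all numeric columns).
#' @param bins Optional named list of cut points per variable; a variable with
#'   bins is tabulated over intervals `[a, b)` (last interval closed).
#' @return List with `stats` (data frame variable/mean/sd/n) and
#'   `distributions` (named list of data frames value/count/percent).
#' @export
summarize_participants <- function(table, variables = NULL, bins = NULL) {
  if (is.null(variables))
    variables <- names(table)[vapply(table, is.numeric, TRUE)]
  stats_rows <- list()
  dists <- list()
  for (v in variables) {
    x <- table[[v]]
    if (is.null(x)) stop("variable not found: ", v)
    bad <- which(!is.na(x) & !is.numeric(x))
    if (!is.numeric(x)) {
      xn <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(xn))
      if (length(bad)) stop("non-numeric entries in '", v, "' at row(s): ",
                            paste(bad, collapse = ", "))
      x <- xn
    }
    x <- x[!is.na(x)]
    n <- length(x)
    stats_rows[[v]] <- data.frame(
      variable = v, mean = mean(x),
      sd = if (n > 1L) stats::sd(x) else NA_real_, n = n)
    if (!is.null(bins) && v %in% names(bins)) {
      cuts <- bins[[v]]
      lab <- paste0("[", utils::head(cuts, -1), ";", cuts[-1], ")")
      lab[length(lab)] <- sub("\\)$", "]", lab[length(lab)])
      f <- cut(x, cuts, labels = lab, right = FALSE, include.lowest = TRUE)
      tab <- table(f)
    } else {
      tab <- table(x)
    }
    dists[[v]] <- data.frame(value = names(tab),
                             count = as.integer(tab),
                             percent = 100 * as.integer(tab) / n,
                             stringsAsFactors = FALSE)
  }
  list(stats = do.call(rbind, c(stats_rows, list(make.row.names = FALSE))),
       distributions = dists)
}

#' Export QC metric distributions as long tables and violin + strip figures
#'
#' One category per sequence; each acquisition contributes one point. A PNECR
#' dynamic figure (log scale, non-positive frames dropped and counted) is
#' produced when count-rate series are supplied.
#'
#' @param records QC data frame from [qc_acquisition()] rows.
#' @param out_dir Output directory for TSV tables and figures.
#' @param metrics Metric columns to export.
#' @param count_series Optional named list of [pnecr_series()] outputs keyed
#'   by acquisition label.
#' @param figures Render PNG figures (TRUE) or only write tables.
#' @return Invisibly, list with `long` (the long-format table) and
#'   `pnecr_dropped` (named dropped-frame counts, when curves were given).
#' @export
export_distributions <- function(records, out_dir, metrics = c("snr", "cnr",
                                 "median_intensity"), count_series = NULL,
                                 figures = TRUE) {
  stopifnot(nrow(records) >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(subject = records$subject, session = records$session,
               sequence = records$sequence, year = records$year,
               metric = m, value = records[[m]], stringsAsFactors = FALSE)))
  utils::write.table(long, file.path(out_dir, "qc_metrics_long.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (figures) {
    for (m in metrics) {
      dat <- long[long$metric == m, ]
      p <- ggplot2::ggplot(dat, ggplot2::aes(x = sequence, y = value)) +
        ggplot2::geom_violin(fill = "grey85", colour = "grey40", scale = "width") +
        ggplot2::geom_jitter(ggplot2::aes(colour = factor(year)),
                             width = 0.12, size = 1.6) +
        ggplot2::labs(x = NULL, y = m, colour = "year") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
      ggplot2::ggsave(file.path(out_dir, paste0("qc_", m, ".png")), p,
                      width = 7, height = 4, dpi = 120)
    }
  }
  dropped <- NULL
  if (!is.null(count_series)) {
    curves <- list()
    dropped <- integer(0)
    for (lbl in names(count_series)) {
      ex <- pnecr_log_export(count_series[[lbl]])
      dropped[lbl] <- ex$dropped_frames
      if (nrow(ex$table)) {
        ex$table$acquisition <- lbl
        curves[[lbl]] <- ex$table
      }
    }
    curve_tab <- do.call(rbind, curves)
    utils::write.table(curve_tab, file.path(out_dir, "pnecr_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (figures && !is.null(curve_tab) && nrow(curve_tab)) {
      p <- ggplot2::ggplot(curve_tab,
                           ggplot2::aes(x = time, y = pnecr, group = acquisition)) +
        ggplot2::geom_line(alpha = 0.6) +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "time (s)", y = "PNECR (counts/s)") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(out_dir, "pnecr_dynamic.png"), p,
                      width = 7, height = 4, dpi = 120)
    }
  }
  invisible(list(long = long, pnecr_dropped = dropped))
}

#' Render the availability heatmap
#'
#' @param m Matrix from [availability_matrix()].
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
availability_heatmap <- function(m, path) {
  df <- expand.grid(row = rownames(m), column = colnames(m),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$count <- as.vector(m)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = column, y = row, fill = count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey95", high = "steelblue4") +
    ggplot2::labs(x = NULL, y = NULL, fill = "n") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  ggplot2::ggsave(path, p, width = 8,
                  height = max(3, 0.25 * nrow(m) + 1.5), dpi = 120)
  invisible(path)
}
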