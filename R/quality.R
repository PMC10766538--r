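# quality_metrics: Otsu-threshold VOI segmentation and the three image
# metrics (SNR, CNR, median intensity), their averaging rules for dynamic and
# multi-echo acquisitions, the PET counting-statistics metric PNECR, and a
# robust outlier flag over cohort QC tables.
#
# Definitions:
#   SNR = mean(VOI) / sd(background)        (sd with n-1 denominator)
#   CNR = (max(VOI) - min(VOI)) / sd(background)
#   median intensity = median(VOI)
#   PNECR = (P - D)^2 / P   per frame, P prompts and D randoms
# The VOI is the set of voxels at or above the Otsu threshold computed on the
# single 3-D volume with the highest mean intensity; voxels below the
# threshold are background for the noise measurement.

#' Otsu threshold of a sample or histogram
#'
#' Picks the threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over all histogram cut points. A plain sample is
#' binned into `bins` equal-width bins between its min and max; a histogram is
#' given as `list(counts, mids)`. Ties resolve to the lowest threshold.
#' The returned value is the upper edge of the last background bin, so
#' `x >= threshold` selects the foreground class.
#'
#' @param x Numeric vector of intensities, or `list(counts=, mids=)`.
#' @param bins Number of equal-width bins for vector input.
#' @return Threshold (intensity scalar).
#' @export
otsu_threshold <- function(x, bins = 256L) {
  if (is.list(x)) {
    counts <- as.numeric(x$counts)
    mids <- as.numeric(x$mids)
    stopifnot(length(counts) == length(mids), length(counts) >= 2L)
    if (length(mids) > 1L) {
      width <- mids[2] - mids[1]
    } else width <- 1
    edges <- c(mids - width / 2, mids[length(mids)] + width / 2)
  } else {
    x <- x[is.finite(x)]
    if (length(unique(x)) < 2L) stop("degenerate image: fewer than 2 distinct values")
    rng <- range(x)
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), bins)
    counts <- tabulate(idx, nbins = bins)
    mids <- (edges[-1] + edges[-length(edges)]) / 2
  }
  n <- sum(counts)
  if (n == 0 || sum(counts > 0) < 2L) stop("degenerate image: fewer than 2 occupied bins")
  p <- counts / n
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, length(p))
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv)              # which.max takes the first (lowest) maximizer
  edges[k + 1L]
}

#' Segment the volume of interest of a stack
#'
#' The reference volume is the 3-D (echo, frame) sub-volume with the highest
#' mean intensity; the Otsu threshold computed on it defines a single VOI /
#' background mask pair that is applied to every volume of the stack.
#'
#' @param vol A [volume_stack()].
#' @param bins Histogram bins for [otsu_threshold()].
#' @return A `voi_segmentation`: list with `threshold`, `voi_mask`,
#'   `background_mask` (3-D logical arrays), `reference_index`
#'   `c(echo, frame)`, `voi_voxels`, `background_voxels`.
#' @export
segment_voi <- function(vol, bins = 256L) {
  stopifnot(inherits(vol, "volume_stack"))
  ne <- .n_echo(vol); nf <- .n_frame(vol)
  best <- c(1L, 1L); best_mean <- -Inf
  for (e in seq_len(ne)) for (f in seq_len(nf)) {
    m <- mean(.get_volume3d(vol, e, f))
    if (m > best_mean) { best_mean <- m; best <- c(e, f) }
  }
  ref <- .get_volume3d(vol, best[1], best[2])
  thr <- otsu_threshold(as.numeric(ref), bins = bins)
  voi <- ref >= thr
  if (!any(voi) || all(voi))
    stop("degenerate segmentation: empty VOI or empty background")
  structure(list(threshold = thr, voi_mask = voi, background_mask = !voi,
                 reference_index = best,
                 voi_voxels = sum(voi), background_voxels = sum(!voi)),
            class = "voi_segmentation")
}

.check_sigma <- function(sigma) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("noiseless background (sigma = 0); SNR/CNR undefined")
  sigma
}

#' Signal-to-noise ratio of one 3-D volume under a VOI segmentation
#' @param volume3d Numeric 3-D array.
#' @param seg A `voi_segmentation`.
#' @return `mean(VOI) / sd(background)` (sd with n-1 denominator).
#' @export
compute_snr <- function(volume3d, seg) {
  sigma <- .check_sigma(stats::sd(volume3d[seg$background_mask]))
  mean(volume3d[seg$voi_mask]) / sigma
}

#' Contrast-to-noise ratio of one 3-D volume under a VOI segmentation
#' @inheritParams compute_snr
#' @return `(max(VOI) - min(VOI)) / sd(background)`, literal max and min.
#' @export
compute_cnr <- function(volume3d, seg) {
  sigma <- .check_sigma(stats::sd(volume3d[seg$background_mask]))
  v <- volume3d[seg$voi_mask]
  (max(v) - min(v)) / sigma
}

#' Median intensity inside the VOI
#' @inheritParams compute_snr
#' @return `median(VOI)` (mean-of-middle convention for even counts).
#' @export
compute_median_intensity <- function(volume3d, seg) {
  stats::median(volume3d[seg$voi_mask])
}

#' Quality-control record for one acquisition
#'
#' Applies the reporting rules for composite acquisitions: dynamic series
#' average the per-frame metrics across frames; multi-echo series average the
#' median intensity across echoes but take SNR and CNR from the first echo
#' only (where SNR is maximal); a static 3-D volume reduces to the plain
#' metrics. Masks come from one segmentation of the whole stack; background
#' noise is measured per volume.
#'
#' @param vol A [volume_stack()].
#' @param subject,session,sequence,year Bookkeeping labels attached to the row.
#' @param seg Optional precomputed segmentation.
#' @return One-row data frame: subject, session, sequence, year, snr, cnr,
#'   median_intensity, voi_voxels, background_voxels, threshold.
#' @export
qc_acquisition <- function(vol, subject = NA, session = NA, sequence = NA,
                           year = NA, seg = NULL) {
  stopifnot(inherits(vol, "volume_stack"))
  if (is.null(seg)) seg <- segment_voi(vol)
  ne <- .n_echo(vol); nf <- .n_frame(vol)

  snr_e <- matrix(NA_real_, ne, nf)
  cnr_e <- matrix(NA_real_, ne, nf)
  med_e <- matrix(NA_real_, ne, nf)
  for (e in seq_len(ne)) for (f in seq_len(nf)) {
    v3 <- .get_volume3d(vol, e, f)
    snr_e[e, f] <- compute_snr(v3, seg)
    cnr_e[e, f] <- compute_cnr(v3, seg)
    med_e[e, f] <- compute_median_intensity(v3, seg)
  }
  data.frame(
    subject = as.character(subject), session = as.character(session),
    sequence = as.character(sequence), year = year,
    snr = mean(snr_e[1L, ]),           # first echo, averaged over frames
    cnr = mean(cnr_e[1L, ]),
    median_intensity = mean(med_e),    # averaged over echoes and frames
    voi_voxels = seg$voi_voxels, background_voxels = seg$background_voxels,
    threshold = seg$threshold,
    stringsAsFactors = FALSE)
}

#' Pseudo noise-equivalent count rate of one frame's totals
#'
#' `PNECR = (P - D)^2 / P` with P total prompts and D total randoms. An empty
#' frame (P = 0) is defined as 0; D > P is an error.
#'
#' @param P Total prompt counts (vectorized).
#' @param D Total random counts.
#' @return Numeric, same length as `P`.
#' @export
pnecr <- function(P, D) {
  stopifnot(length(P) == length(D))
  if (any(P < 0) || any(D < 0)) stop("counts must be non-negative")
  if (any(D > P)) stop("randoms exceed prompts")
  out <- numeric(length(P))
  nz <- P > 0
  out[nz] <- (P[nz] - D[nz])^2 / P[nz]
  out
}

#' Construct a per-frame count-rate series
#'
#' @param start,duration Frame start times and durations (s).
#' @param prompts,randoms Per-frame total prompt / random counts.
#' @return A `count_rate_series` data frame.
#' @export
count_rate_series <- function(start, duration, prompts, randoms) {
  n <- length(start)
  stopifnot(length(duration) == n, length(prompts) == n, length(randoms) == n,
            all(duration > 0), all(prompts >= 0), all(randoms >= 0))
  if (any(randoms > prompts)) stop("randoms exceed prompts")
  structure(data.frame(start = start, duration = duration,
                       prompts = prompts, randoms = randoms),
            class = c("count_rate_series", "data.frame"))
}

#' Fill a count-rate series with its PNECR curve
#'
#' Adds per-frame `pnecr_total` (the formula on frame totals) and `pnecr`
#' (the total divided by the frame duration, a rate in counts/s that is
#' comparable across schedules), plus the attributes `pnecr_max` (maximum of
#' the rate over frames) and `pnecr_max_frame`.
#'
#' @param series A [count_rate_series()].
#' @param schedule Optional `frame_schedule` cross-checked against the series.
#' @return The series with the PNECR columns and attributes set.
#' @export
pnecr_series <- function(series, schedule = NULL) {
  stopifnot(inherits(series, "count_rate_series"))
  if (!is.null(schedule)) {
    exp_sched <- expand_frame_schedule(schedule)
    if (length(exp_sched$FrameDuration) != nrow(series))
      stop("count table has ", nrow(series), " frames but the schedule expands to ",
           length(exp_sched$FrameDuration))
  }
  series$pnecr_total <- pnecr(series$prompts, series$randoms)
  series$pnecr <- series$pnecr_total / series$duration
  attr(series, "pnecr_max") <- max(series$pnecr)
  attr(series, "pnecr_max_frame") <- which.max(series$pnecr)
  series
}

#' Export a PNECR curve for log-scale plotting
#'
#' Frames with non-positive PNECR cannot be drawn on a log axis; they are
#' dropped and their number reported.
#'
#' @param series Output of [pnecr_series()].
#' @return List with `table` (frames with pnecr > 0, columns time/pnecr) and
#'   `dropped_frames` (count of non-positive frames).
#' @export
pnecr_log_export <- function(series) {
  stopifnot(!is.null(series$pnecr))
  keep <- series$pnecr > 0
  list(table = data.frame(time = series$start[keep] + series$duration[keep] / 2,
                          pnecr = series$pnecr[keep]),
       dropped_frames = sum(!keep))
}

#' Flag outlying acquisitions within sequence groups
#'
#' Robust rule: within each sequence group, flag records whose metric deviates
#' from the group median by more than `k` times the scaled median absolute
#' deviation (MAD, consistency constant 1.4826) *and* by at least
#' `min_rel_dev` of the group median. The relative floor keeps the rule from
#' degenerating on near-constant groups, where the MAD shrinks to the
#' sampling noise and would otherwise flag practically irrelevant
#' fluctuations. Groups smaller than `min_group` get no flags, with a
#' warning.
#'
#' @param records Data frame of QC rows (from [qc_acquisition()]).
#' @param metric Column name to screen, e.g. `"snr"`.
#' @param k Flagging multiple of the scaled MAD.
#' @param min_group Minimal group size for flagging.
#' @param min_rel_dev Minimal practically relevant deviation, as a fraction
#'   of the absolute group median (no effect when the median is 0; set to 0
#'   to disable).
#' @return `records` with logical column `outlier` and character column
#'   `outlier_reason` added.
#' @export
flag_outliers <- function(records, metric = "snr", k = 3, min_group = 4L,
                          min_rel_dev = 0.05) {
  stopifnot(metric %in% names(records))
  records$outlier <- FALSE
  records$outlier_reason <- NA_character_
  for (sq in unique(records$sequence)) {
    idx <- which(records$sequence == sq)
    if (length(idx) < min_group) {
      warning("sequence group '", sq, "' has ", length(idx),
              " record(s) (< ", min_group, "); no outlier flags")
      next
    }
    x <- records[[metric]][idx]
    med <- stats::median(x)
    s <- stats::mad(x)               # 1.4826 * median(|x - med|)
    if (s == 0) next
    dev <- abs(x - med)
    hit <- dev > k * s & dev >= min_rel_dev * abs(med)
    records$outlier[idx[hit]] <- TRUE
    records$outlier_reason[idx[hit]] <-
      sprintf("%s deviates %.2f x scaled MAD from group median", metric,
              dev[hit] / s)
  }
  records
}
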