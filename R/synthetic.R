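# synthetic_fixtures: ground-truthed phantom cohorts written as classic DICOM
# trees, with controlled tag dropout, multi-echo T2* decay, dynamic PET with
# Poisson counting statistics, planted missing acquisitions and planted
# outlier sessions — so the whole ingest -> convert -> QC -> report loop is
# testable without any real dataset.
#
# The noise model is additive Gaussian on MR magnitude images (the Rician
# tail is negligible at the SNR levels generated) and Poisson on PET counts;
# intensities are quantized to integers before writing, and the quantized
# array IS the ground truth, so DICOM round trips are bit-exact.

#' Specify a synthetic phantom
#'
#' @param dims Grid size (voxels), length 3.
#' @param spacing_mm Voxel size, mm.
#' @param center,semi_axes Ellipsoid center and semi-axes in voxel units.
#' @param mu Tissue mean intensity (must be > 0).
#' @param sigma Gaussian noise SD (> 0), added everywhere; background mean 0.
#' @param echo_times Echo times (s) for multi-echo variants, or `NULL`.
#' @param t2star_s T2* decay constant (s): tissue scales by `exp(-TE/T2*)`.
#' @param tac Gamma-variate time-activity parameters for dynamic PET:
#'   `list(amplitude, t0, alpha, beta)` — peak `amplitude` at `t0 + alpha*beta` s.
#' @param frame_schedule A `frame_schedule` (or schedule string) for dynamic
#'   PET.
#' @param peak_count_rate True-coincidence rate (counts/s) at the TAC peak.
#' @param randoms_rate Randoms floor rate (counts/s).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(64L, 64L, 32L), spacing_mm = c(2, 2, 2),
                         center = (dims + 1) / 2,
                         semi_axes = c(22, 26, 12),
                         mu = 1000, sigma = 50,
                         echo_times = NULL, t2star_s = 0.030,
                         tac = list(amplitude = 20000, t0 = 10,
                                    alpha = 3, beta = 4),
                         frame_schedule = "8x4;4x6;6x10;8x20",
                         peak_count_rate = 5e4, randoms_rate = 2000) {
  stopifnot(mu > 0, sigma > 0, length(dims) == 3L, all(dims >= 4L),
            all(spacing_mm > 0), all(semi_axes > 0),
            all(center + semi_axes <= dims + 1), all(center - semi_axes >= 0))
  if (is.character(frame_schedule))
    frame_schedule <- parse_frame_schedule(frame_schedule)
  stopifnot(tac$amplitude >= 0)
  structure(list(dims = as.integer(dims), spacing_mm = spacing_mm,
                 center = center, semi_axes = semi_axes, mu = mu,
                 sigma = sigma, echo_times = echo_times, t2star_s = t2star_s,
                 tac = tac, frame_schedule = frame_schedule,
                 peak_count_rate = peak_count_rate,
                 randoms_rate = randoms_rate),
            class = "phantom_spec")
}

.ellipsoid_mask <- function(dims, center, semi_axes) {
  x <- (seq_len(dims[1]) - center[1]) / semi_axes[1]
  y <- (seq_len(dims[2]) - center[2]) / semi_axes[2]
  z <- (seq_len(dims[3]) - center[3]) / semi_axes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

.phantom_affine <- function(dims, spacing) {
  ipp <- c(-(dims[1] - 1) * spacing[1] / 2,
           -(dims[2] - 1) * spacing[2] / 2,
           -(dims[3] - 1) * spacing[3] / 2)
  .affine_from_dicom(c(1, 0, 0, 0, 1, 0), ipp, c(0, 0, spacing[3]),
                     c(spacing[2], spacing[1]))
}

#' Generate a structural (optionally multi-echo) phantom
#'
#' An ellipsoid of tissue mean `mu` over a zero-mean background, Gaussian
#' noise of SD `sigma` everywhere, quantized to integers. Multi-echo variants
#' scale the tissue signal by `exp(-TE / T2*)` per echo.
#'
#' @param spec A [phantom_spec()].
#' @param seed RNG seed; identical seeds give identical arrays.
#' @return List with `volume` (a [volume_stack()]) and `truth`
#'   (`mask`, `mu`, `sigma`, `echo_means`, `voi_voxels_analytic`).
#' @export
make_structural_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  mask <- .ellipsoid_mask(spec$dims, spec$center, spec$semi_axes)
  tes <- spec$echo_times
  n_echo <- if (is.null(tes)) 1L else length(tes)
  echo_means <- if (is.null(tes)) spec$mu else spec$mu * exp(-tes / spec$t2star_s)
  vox <- array(0, dim = c(spec$dims, n_echo))
  for (e in seq_len(n_echo)) {
    clean <- ifelse(mask, echo_means[e], 0)
    vox[, , , e] <- round(clean + stats::rnorm(prod(spec$dims), 0, spec$sigma))
  }
  if (n_echo == 1L) dim(vox) <- spec$dims
  vol <- volume_stack(vox, spacing = spec$spacing_mm,
                      affine = .phantom_affine(spec$dims, spec$spacing_mm),
                      echo_times = tes)
  analytic <- 4 / 3 * pi * prod(spec$semi_axes)
  list(volume = vol,
       truth = list(mask = mask, mu = spec$mu, sigma = spec$sigma,
                    echo_means = echo_means, voi_voxels_analytic = analytic))
}

#' Gamma-variate time-activity curve
#'
#' Normalized form peaking at `amplitude` when `t = t0 + alpha * beta`:
#' `A * ((t - t0)/(alpha*beta))^alpha * exp(alpha - (t - t0)/beta)` for
#' `t > t0`, 0 before.
#'
#' @param t Times (s).
#' @param amplitude,t0,alpha,beta Curve parameters.
#' @return Activity values, same length as `t`.
#' @export
gamma_variate <- function(t, amplitude, t0, alpha, beta) {
  dt <- pmax(t - t0, 0)
  ifelse(dt > 0,
         amplitude * (dt / (alpha * beta))^alpha * exp(alpha - dt / beta),
         0)
}

#' Generate a dynamic PET phantom with counting statistics
#'
#' Tissue intensity per frame follows the gamma-variate curve averaged over
#' the frame; per-frame prompts are Poisson with mean proportional to the
#' frame's true-coincidence integral plus a randoms floor, randoms Poisson on
#' the floor alone (clipped so randoms never exceed prompts).
#'
#' @param spec A [phantom_spec()].
#' @param seed RNG seed.
#' @return List with `volume` (frame axis last), `counts`
#'   (a [count_rate_series()]), and `truth` (`mask`, `sigma`, `frame_means`,
#'   `peak_frame`, `true_rate`, `tac_mode_s`).
#' @export
make_dynamic_pet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  sched <- expand_frame_schedule(spec$frame_schedule)
  starts <- sched$FrameTimesStart; durs <- sched$FrameDuration
  nfr <- length(starts)
  # frame average of the curve on a fine grid (0.1 s)
  frame_means <- vapply(seq_len(nfr), function(f) {
    tt <- seq(starts[f], starts[f] + durs[f], by = 0.1)
    mean(gamma_variate(tt, spec$tac$amplitude, spec$tac$t0,
                       spec$tac$alpha, spec$tac$beta))
  }, 1)
  mask <- .ellipsoid_mask(spec$dims, spec$center, spec$semi_axes)
  vox <- array(0, dim = c(spec$dims, nfr))
  for (f in seq_len(nfr)) {
    clean <- ifelse(mask, frame_means[f], 0)
    vox[, , , f] <- round(clean + stats::rnorm(prod(spec$dims), 0, spec$sigma))
  }
  true_rate <- if (spec$tac$amplitude > 0)
    spec$peak_count_rate * frame_means / spec$tac$amplitude
  else rep(0, nfr)
  lam_true <- true_rate * durs
  lam_rand <- spec$randoms_rate * durs
  prompts <- stats::rpois(nfr, lam_true + lam_rand)
  randoms <- pmin(stats::rpois(nfr, lam_rand), prompts)
  vol <- volume_stack(vox, spacing = spec$spacing_mm,
                      affine = .phantom_affine(spec$dims, spec$spacing_mm),
                      frame_times = starts, frame_durations = durs,
                      intensity_units = "arbitrary")
  list(volume = vol,
       counts = count_rate_series(starts, durs, prompts, randoms),
       truth = list(mask = mask, sigma = spec$sigma, frame_means = frame_means,
                    peak_frame = which.max(frame_means),
                    true_rate = true_rate,
                    tac_mode_s = spec$tac$t0 + spec$tac$alpha * spec$tac$beta))
}

.GEOMETRY_TAGS <- c("ImagePositionPatient", "ImageOrientationPatient",
                    "PixelSpacing", "Rows", "Columns")
.DCM_OFFSET <- 32768L   # stored = value + offset; RescaleIntercept undoes it

#' Write a volume stack as a synthetic classic DICOM series
#'
#' One file per slice (or, with `multislice = TRUE`, one multi-slice file per
#' frame). Intensities are stored as unsigned 16-bit with a rescale intercept
#' so signed values round-trip exactly. Listed `dropout` tags are omitted from
#' every header; geometry-critical tags can only be dropped with
#' `force = TRUE` (that breaks assembly by design, for negative tests).
#'
#' @param vol A [volume_stack()] whose voxels are integers in
#'   `[-32768, 32767]`.
#' @param out_dir Series directory (created).
#' @param base_meta Named list of attributes common to every file
#'   (e.g. `PatientID`, `SeriesDescription`, `StudyDate`, `EchoTime` in ms).
#' @param per_frame_meta Optional list (one element per frame) of attribute
#'   lists, e.g. diffusion gradient tags.
#' @param dropout Character vector of tag keywords to omit.
#' @param force Allow dropping geometry-critical tags.
#' @param multislice One file per frame holding all slices.
#' @param series_uid Series instance UID (deterministic UIDs give
#'   reproducible trees).
#' @return Character vector of files written, invisibly.
#' @export
write_synthetic_dicom <- function(vol, out_dir, base_meta = list(),
                                  per_frame_meta = NULL,
                                  dropout = character(), force = FALSE,
                                  multislice = FALSE, series_uid = NULL) {
  stopifnot(inherits(vol, "volume_stack"))
  bad <- intersect(dropout, .GEOMETRY_TAGS)
  if (length(bad) && !force)
    stop("refusing to drop geometry-critical tag(s) ",
         paste(bad, collapse = ", "), " without force = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(series_uid)) series_uid <- .dcm_uid()

  dims <- dim(vol$voxels)[1:3]
  ne <- .n_echo(vol); nf <- .n_frame(vol)
  sp <- vol$spacing
  ipp0 <- c(-(dims[1] - 1) * sp[1] / 2, -(dims[2] - 1) * sp[2] / 2,
            -(dims[3] - 1) * sp[3] / 2)

  rng <- range(vol$voxels)
  if (rng[1] < -.DCM_OFFSET || rng[2] > 65535 - .DCM_OFFSET)
    stop("voxel intensities outside the signed 16-bit encodable range")

  common <- list(
    Modality = base_meta$Modality %||% "MR",
    SeriesInstanceUID = series_uid,
    StudyInstanceUID = paste0(series_uid, ".0"),
    ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
    PixelSpacing = c(sp[2], sp[1]),
    SliceThickness = sp[3],
    SpacingBetweenSlices = sp[3],
    RescaleSlope = 1,
    RescaleIntercept = -.DCM_OFFSET
  )
  common[names(base_meta)] <- base_meta
  files <- character(0)
  inst <- 0L

  emit <- function(meta, px, path) {
    for (tg in dropout) meta[[tg]] <- NULL
    dcm_write(path, meta, px + .DCM_OFFSET)
  }

  if (multislice) {
    for (f in seq_len(nf)) {
      inst <- inst + 1L
      meta <- common
      meta$ImagePositionPatient <- ipp0
      meta$InstanceNumber <- inst
      meta$SOPInstanceUID <- paste0(series_uid, ".", inst)
      if (nf > 1L) {
        meta$TemporalPositionIdentifier <- f
        meta$NumberOfTemporalPositions <- nf
        meta$FrameReferenceTime <- vol$frame_times[f] * 1000
      }
      if (!is.null(per_frame_meta)) meta[names(per_frame_meta[[f]])] <- per_frame_meta[[f]]
      v3 <- .get_volume3d(vol, 1L, f)
      px <- aperm(v3, c(2L, 1L, 3L))         # rows x cols x slices
      path <- file.path(out_dir, sprintf("IM%05d.dcm", inst))
      emit(meta, px, path)
      files <- c(files, path)
    }
  } else {
    for (f in seq_len(nf)) for (e in seq_len(ne)) {
      v3 <- .get_volume3d(vol, e, f)
      for (k in seq_len(dims[3])) {
        inst <- inst + 1L
        meta <- common
        meta$ImagePositionPatient <- ipp0 + c(0, 0, (k - 1) * sp[3])
        meta$InstanceNumber <- inst
        meta$SOPInstanceUID <- paste0(series_uid, ".", inst)
        if (ne > 1L) {
          meta$EchoTime <- vol$echo_times[e] * 1000
          meta$EchoNumbers <- e
        } else if (!is.null(vol$echo_times) && is.null(meta$EchoTime)) {
          meta$EchoTime <- vol$echo_times[1] * 1000
        }
        if (nf > 1L) {
          meta$TemporalPositionIdentifier <- f
          meta$NumberOfTemporalPositions <- nf
        }
        if (!is.null(per_frame_meta)) meta[names(per_frame_meta[[f]])] <- per_frame_meta[[f]]
        px <- t(v3[, , k])
        path <- file.path(out_dir, sprintf("IM%05d.dcm", inst))
        emit(meta, px, path)
        files <- c(files, path)
      }
    }
  }
  invisible(files)
}

# deterministic, seed-reproducible series UID
.cohort_uid <- function(seed, subject, session, seq_idx) {
  paste0("1.2.826.0.1.3680043.10.4242.", seed %% 100000L, ".",
         as.integer(subject), ".", as.integer(session), ".", seq_idx)
}

#' Generate a full synthetic raw cohort with configs and manifest
#'
#' Emulates a multi-session preclinical PET/MR study: per session a T1w, T2w,
#' multi-echo T2*w, diffusion series and a dynamic PET acquisition with a
#' per-frame prompts/randoms count table, plus the three conversion configs
#' and a participants table. Missingness, outlier sessions (noise scaled in
#' one sequence) and DICOM tag dropout are planted per plan and recorded in
#' the returned manifest; the tree is byte-identical for identical seeds.
#'
#' @param out_dir Output root; `raw/` DICOM tree, `counts/` CSVs and config
#'   files are created beneath it.
#' @param n_subjects Number of subjects.
#' @param retest_subjects Integer vector of subjects that get a second
#'   (test-retest) session.
#' @param missingness List of `list(subject=, session=, sequence=)` entries
#'   to omit from the tree (`session` optional, default "01").
#' @param outliers List of `list(subject=, session=, sequence=,
#'   sigma_factor=)` entries; that acquisition's noise SD is multiplied.
#' @param tag_dropout List of `list(subject=, session=, sequence=, tags=)`
#'   entries; listed DICOM tags are omitted from that series.
#' @param spec Base [phantom_spec()] shared by all subjects.
#' @param seed RNG seed; the manifest plus the seed fully determine the tree.
#' @return A `cohort_manifest` list: `root`, `raw_root`, paths of configs and
#'   counts, `sessions` (data frame), `planted` (the plans), `truth`
#'   (per-acquisition mu/sigma), `participants`.
#' @export
make_cohort <- function(out_dir, n_subjects = 20L,
                        retest_subjects = NULL,
                        missingness = NULL, outliers = NULL,
                        tag_dropout = NULL,
                        spec = phantom_spec(), seed = 1L) {
  stopifnot(n_subjects >= 1L)
  # standard study plan (two retest subjects, a couple of missing series, one
  # noise-doubled retest session, one dropped tag), trimmed to the cohort size
  keep <- function(plans) Filter(function(p)
    as.integer(p$subject) <= n_subjects, plans)
  if (is.null(retest_subjects))
    retest_subjects <- c(4L, 11L)[c(4L, 11L) <= n_subjects]
  if (is.null(missingness))
    missingness <- keep(list(list(subject = 7L, sequence = "pet"),
                             list(subject = 13L, sequence = "T2w")))
  if (is.null(outliers))
    outliers <- if (4L %in% retest_subjects)
      list(list(subject = 4L, session = "02", sequence = "T2w",
                sigma_factor = 2))
    else list()
  if (is.null(tag_dropout))
    tag_dropout <- keep(list(list(subject = 2L, sequence = "T1w",
                                  tags = "EchoTime")))
  for (pl in c(missingness, outliers, tag_dropout))
    if (as.integer(pl$subject) > n_subjects)
      stop("plan references unknown subject ", pl$subject)
  if (any(retest_subjects > n_subjects))
    stop("retest plan references unknown subject(s)")
  set.seed(seed)
  raw_root <- file.path(out_dir, "raw")
  counts_dir <- file.path(out_dir, "counts")
  dir.create(raw_root, recursive = TRUE, showWarnings = FALSE)
  dir.create(counts_dir, recursive = TRUE, showWarnings = FALSE)

  subj_lab <- sprintf("%02d", seq_len(n_subjects))
  years <- 2016L + (seq_len(n_subjects) - 1L) %% 4L

  # participants emulating the cohort composition: ages 5/6/7 y in 4/12/4
  # proportion, weights spread over 5.5-10 kg
  age_pool <- rep(c(5, 6, 7), times = round(n_subjects * c(0.2, 0.6, 0.2)))
  while (length(age_pool) < n_subjects) age_pool <- c(age_pool, 6)
  ages <- sample(age_pool[seq_len(n_subjects)])
  weights <- round(stats::runif(n_subjects, 5.6, 9.9), 1)
  participants <- data.frame(
    participant_id = paste0("sub-", subj_lab),
    species = "macaca fascicularis",
    age = ages, sex = "M", weight = weights)

  sequences <- c("T1w", "T2w", "T2starw", "dwi", "pet")
  plan_hit <- function(plan, sub, ses, sq) {
    for (pl in plan) {
      psub <- sprintf("%02d", as.integer(pl$subject))
      pses <- pl$session %||% "01"
      if (psub == sub && pses == ses && pl$sequence == sq) return(pl)
    }
    NULL
  }

  sessions <- list(); truth <- list(); doses_rows <- list()
  counts_files <- character(0)
  b <- 1000   # b-value for the diffusion shell, s/mm^2
  bvec6 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
                 c(0, 1, 1) / sqrt(2))

  for (i in seq_len(n_subjects)) {
    sub <- subj_lab[i]
    ses_list <- if (i %in% retest_subjects) c("01", "02") else "01"
    for (ses in ses_list) {
      study_date <- sprintf("%d0601", years[i])
      dose <- round(stats::rnorm(1, 255, 15), 1)
      doses_rows[[length(doses_rows) + 1L]] <- data.frame(
        subject = sub, session = ses, tracer = "H2O",
        InjectedRadioactivity = dose, InjectedMass = 3.5,
        SpecificRadioactivity = 48.0)
      for (sq in sequences) {
        if (!is.null(plan_hit(missingness, sub, ses, sq))) {
          sessions[[length(sessions) + 1L]] <- data.frame(
            subject = sub, session = ses, sequence = sq, year = years[i],
            present = FALSE, outlier = FALSE)
          next
        }
        ol <- plan_hit(outliers, sub, ses, sq)
        sp <- spec
        if (!is.null(ol)) sp$sigma <- sp$sigma * ol$sigma_factor
        dropout <- character(0)
        td <- plan_hit(tag_dropout, sub, ses, sq)
        if (!is.null(td)) dropout <- td$tags
        seq_idx <- match(sq, sequences)
        sdir <- file.path(raw_root, paste0("sub-", sub), paste0("ses-", ses),
                          sq)
        uid <- .cohort_uid(seed, i, as.integer(ses), seq_idx)
        sub_seed <- seed * 10000L + i * 100L + as.integer(ses) * 10L + seq_idx
        base_meta <- list(PatientID = paste0("sub-", sub),
                          StudyDate = study_date,
                          SeriesNumber = seq_idx,
                          SeriesDescription = switch(sq,
                            T1w = "t1_mprage_T1w", T2w = "t2_spc_T2w",
                            T2starw = "t2star_me_T2starw",
                            dwi = "ep2d_diff_dwi", pet = "pet_h2o_dyn"))
        tr <- NULL
        if (sq == "T2starw") {
          sp$echo_times <- c(0.00445, 0.011, 0.018)
          ph <- make_structural_phantom(sp, sub_seed)
          base_meta <- c(base_meta, list(RepetitionTime = 205,
                                         FlipAngle = 20, PixelBandwidth = 219))
          write_synthetic_dicom(ph$volume, sdir, base_meta,
                                dropout = dropout, series_uid = uid)
          tr <- ph$truth
        } else if (sq == "dwi") {
          vols <- list(); pfm <- list()
          nv <- nrow(bvec6) + 1L
          set.seed(sub_seed)
          mask <- .ellipsoid_mask(sp$dims, sp$center, sp$semi_axes)
          vox <- array(0, dim = c(sp$dims, nv))
          for (v in seq_len(nv)) {
            att <- if (v == 1L) 1 else 0.5     # uniform diffusion attenuation
            clean <- ifelse(mask, sp$mu * att, 0)
            vox[, , , v] <- round(clean + stats::rnorm(prod(sp$dims), 0, sp$sigma))
            pfm[[v]] <- if (v == 1L) list(DiffusionBValue = 0)
              else list(DiffusionBValue = b,
                        DiffusionGradientOrientation = bvec6[v - 1L, ])
          }
          vol <- volume_stack(vox, sp$spacing_mm,
                              .phantom_affine(sp$dims, sp$spacing_mm),
                              frame_times = seq_len(nv) - 1,
                              frame_durations = rep(1, nv))
          base_meta <- c(base_meta, list(EchoTime = 68.1, RepetitionTime = 11200,
                                         FlipAngle = 180, PixelBandwidth = 898))
          write_synthetic_dicom(vol, sdir, base_meta, per_frame_meta = pfm,
                                dropout = dropout, series_uid = uid)
          tr <- list(mu = sp$mu, sigma = sp$sigma, mask_voxels = sum(mask))
        } else if (sq == "pet") {
          pet <- make_dynamic_pet(sp, sub_seed)
          base_meta$Modality <- "PT"
          write_synthetic_dicom(pet$volume, sdir, base_meta,
                                dropout = dropout, multislice = TRUE,
                                series_uid = uid)
          cf <- file.path(counts_dir,
                          sprintf("sub-%s_ses-%s_trc-H2O_counts.csv", sub, ses))
          utils::write.csv(data.frame(
            frame_index = seq_len(nrow(pet$counts)),
            start_s = pet$counts$start, duration_s = pet$counts$duration,
            prompts = pet$counts$prompts, randoms = pet$counts$randoms),
            cf, row.names = FALSE)
          counts_files <- c(counts_files, cf)
          tr <- pet$truth[c("sigma", "peak_frame", "tac_mode_s")]
          tr$frame_means <- pet$truth$frame_means
        } else {                              # T1w / T2w static
          ph <- make_structural_phantom(sp, sub_seed)
          extra <- if (sq == "T1w")
            list(EchoTime = 4.2, RepetitionTime = 2650, FlipAngle = 9,
                 PixelBandwidth = 190)
          else
            list(EchoTime = 99, RepetitionTime = 3260, FlipAngle = 180,
                 PixelBandwidth = 262)
          base_meta <- c(base_meta, extra)
          write_synthetic_dicom(ph$volume, sdir, base_meta,
                                dropout = dropout, series_uid = uid)
          tr <- ph$truth[c("mu", "sigma", "echo_means", "voi_voxels_analytic")]
        }
        truth[[paste(sub, ses, sq, sep = "_")]] <-
          c(tr, list(sigma_planted = sp$sigma, outlier = !is.null(ol),
                     dropped_tags = dropout))
        sessions[[length(sessions) + 1L]] <- data.frame(
          subject = sub, session = ses, sequence = sq, year = years[i],
          present = TRUE, outlier = !is.null(ol))
      }
    }
  }
  sessions <- do.call(rbind, sessions)

  overview_path <- file.path(out_dir, "sequence_overview.csv")
  utils::write.csv(data.frame(
    match_pattern = c("T1w$", "T2w$", "T2starw$", "dwi$", "h2o"),
    bids_suffix = c("T1w", "T2w", "T2starw", "dwi", "pet"),
    datatype = c("anat", "anat", "anat", "dwi", "pet"),
    entities = c("", "", "", "", "trc=H2O"),
    required_keys = c(rep("EchoTime;RepetitionTime;FlipAngle;PixelBandwidth", 4),
                      paste0("TracerName;InjectedRadioactivity;InjectedMass;",
                             "SpecificRadioactivity;FrameTimesStart;FrameDuration")),
    fallback_values = c("EchoTime=0.0042", "", "", "", ""),
    frame_schedule = c("", "", "", "", "8x4;4x6;6x10;8x20"),
    declared_frames = c(NA, NA, NA, NA, 26)),
    overview_path, row.names = FALSE, na = "")

  tagmap_path <- file.path(out_dir, "tag_map.csv")
  utils::write.csv(data.frame(
    bids_key = c("EchoTime", "RepetitionTime", "FlipAngle", "PixelBandwidth"),
    dicom_tag = c("EchoTime", "RepetitionTime", "FlipAngle", "PixelBandwidth")),
    tagmap_path, row.names = FALSE)

  doses_path <- file.path(out_dir, "pet_doses.csv")
  utils::write.csv(do.call(rbind, doses_rows), doses_path, row.names = FALSE)

  participants_path <- file.path(out_dir, "participants.csv")
  utils::write.csv(participants, participants_path, row.names = FALSE)

  manifest <- structure(list(
    root = out_dir, raw_root = raw_root,
    overview = overview_path, tagmap = tagmap_path, doses = doses_path,
    counts_files = counts_files, participants_path = participants_path,
    sessions = sessions,
    planted = list(missingness = missingness, outliers = outliers,
                   tag_dropout = tag_dropout,
                   retest_subjects = retest_subjects),
    truth = truth, participants = participants, seed = seed),
    class = "cohort_manifest")
  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest[c("sessions", "planted", "seed")],
                              auto_unbox = TRUE, pretty = TRUE, digits = NA),
             manifest_path)
  manifest
}
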