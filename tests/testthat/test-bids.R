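# Config loading, sidecar precedence, frame-schedule expansion, BIDS naming
# and dataset writing.

make_configs <- function(dir, doses = TRUE) {
  ov <- file.path(dir, "overview.csv")
  utils::write.csv(data.frame(
    match_pattern = c("T1w$", "h2o"),
    bids_suffix = c("T1w", "pet"),
    datatype = c("anat", "pet"),
    entities = c("", "trc=H2O"),
    required_keys = c("EchoTime;RepetitionTime;FlipAngle;PixelBandwidth",
                      paste0("TracerName;InjectedRadioactivity;InjectedMass;",
                             "SpecificRadioactivity;FrameTimesStart;FrameDuration")),
    fallback_values = c("EchoTime=0.0042", ""),
    frame_schedule = c("", "8x4;4x6;6x10;8x20"),
    declared_frames = c(NA, 26)), ov, row.names = FALSE, na = "")
  tm <- file.path(dir, "tagmap.csv")
  utils::write.csv(data.frame(
    bids_key = c("EchoTime", "RepetitionTime", "FlipAngle", "PixelBandwidth"),
    dicom_tag = c("EchoTime", "RepetitionTime", "FlipAngle", "PixelBandwidth")),
    tm, row.names = FALSE)
  ds <- NULL
  if (doses) {
    ds <- file.path(dir, "doses.csv")
    utils::write.csv(data.frame(subject = "01", session = "01", tracer = "H2O",
                                InjectedRadioactivity = 255, InjectedMass = 3.5,
                                SpecificRadioactivity = 48), ds, row.names = FALSE)
  }
  list(overview = ov, tagmap = tm, doses = ds)
}

test_that("a valid config trio loads; doses are optional for MR-only work", {
  d <- withr::local_tempdir()
  p <- make_configs(d)
  cfg <- load_configs(p$overview, p$tagmap, p$doses)
  expect_s3_class(cfg$overview, "data.frame")
  expect_equal(nrow(cfg$doses), 1L)
  cfg2 <- load_configs(p$overview, p$tagmap)        # MR-only: no doses file
  expect_null(cfg2$doses)
})

test_that("config schema violations are reported with row context", {
  d <- withr::local_tempdir()
  ov <- file.path(d, "ov.csv")
  utils::write.csv(data.frame(
    match_pattern = c("T1w$", "T1w$"), bids_suffix = c("T1w", "T1w"),
    datatype = "anat", entities = "", required_keys = "EchoTime",
    fallback_values = ""), ov, row.names = FALSE)
  tm <- make_configs(d)$tagmap
  expect_error(load_configs(ov, tm), "duplicate match_pattern")

  ds <- file.path(d, "bad_doses.csv")
  utils::write.csv(data.frame(subject = "01", session = "01", tracer = "H2O",
                              InjectedRadioactivity = -5, InjectedMass = 3.5,
                              SpecificRadioactivity = 48), ds, row.names = FALSE)
  p <- make_configs(d)
  expect_error(load_configs(p$overview, p$tagmap, ds), "InjectedRadioactivity")
})

test_that("the water-PET frame schedule expands to 26 cumulative frames", {
  ex <- expand_frame_schedule("8x4;4x6;6x10;8x20")
  expect_length(ex$FrameTimesStart, 26L)
  expect_equal(ex$FrameTimesStart[1], 0)
  expect_equal(ex$FrameTimesStart[26], 256)
  expect_equal(sum(ex$FrameDuration), 276)
  expect_true(all(diff(ex$FrameTimesStart) > 0))
  expect_equal(ex$FrameTimesStart[-1],
               cumsum(ex$FrameDuration)[-26])

  ex1 <- expand_frame_schedule("1x60")
  expect_equal(ex1$FrameTimesStart, 0)
  expect_equal(ex1$FrameDuration, 60)

  # the long-tracer schedule also sums to 26 frames by block arithmetic
  ex2 <- expand_frame_schedule("6x10;6x20;6x120;8x300")
  expect_length(ex2$FrameTimesStart, 26L)
  expect_error(expand_frame_schedule(""), "empty|malformed")
})

test_that("a declared frame count disagreeing with the schedule warns", {
  d <- withr::local_tempdir()
  ov <- file.path(d, "ov.csv")
  utils::write.csv(data.frame(
    match_pattern = "pk", bids_suffix = "pet", datatype = "pet",
    entities = "trc=PK11195", required_keys = "FrameTimesStart;FrameDuration",
    fallback_values = "", frame_schedule = "6x10;6x20;6x120;8x300",
    declared_frames = 28), ov, row.names = FALSE)
  p <- make_configs(d)
  cfg <- load_configs(ov, p$tagmap)
  rec <- structure(list(modality_hint = "pk_dyn", subject_label = "01",
                        session_label = "01", echo_times = numeric(0)),
                   class = "series_record")
  expect_warning(
    sc <- resolve_sidecar(list(), rec, cfg$overview, cfg$tagmap, row = 1L),
    "28 frames.*26|declares 28")
  expect_length(sc$FrameTimesStart, 26L)
})

test_that("sidecar precedence is dose config > DICOM > fallback, with provenance", {
  d <- withr::local_tempdir()
  p <- make_configs(d)
  cfg <- load_configs(p$overview, p$tagmap, p$doses)
  rec <- structure(list(modality_hint = "t1_mprage_T1w", subject_label = "01",
                        session_label = "01", echo_times = 0.0051),
                   class = "series_record")
  # value present in DICOM wins over the fallback
  sc <- resolve_sidecar(list(EchoTime = 5.1, RepetitionTime = 2650,
                             FlipAngle = 9, PixelBandwidth = 190),
                        rec, cfg$overview, cfg$tagmap)
  expect_equal(sc$EchoTime, 0.0051)        # converted ms -> s
  prov <- attr(sc, "provenance")
  expect_identical(unname(prov["EchoTime"]), "dicom")
  expect_setequal(names(prov), names(sc))  # every key has one provenance entry

  # dropped EchoTime falls back to the configured replacement value
  sc2 <- resolve_sidecar(list(RepetitionTime = 2650, FlipAngle = 9,
                              PixelBandwidth = 190),
                         rec, cfg$overview, cfg$tagmap)
  expect_equal(sc2$EchoTime, 0.0042)
  expect_identical(unname(attr(sc2, "provenance")["EchoTime"]), "fallback")

  # PET dose values come from the dose config with their own provenance
  pet_rec <- structure(list(modality_hint = "pet_h2o_dyn", subject_label = "01",
                            session_label = "01", echo_times = numeric(0)),
                       class = "series_record")
  sc3 <- resolve_sidecar(list(), pet_rec, cfg$overview, cfg$tagmap, cfg$doses)
  expect_equal(sc3$InjectedRadioactivity, 255)
  expect_identical(unname(attr(sc3, "provenance")["InjectedRadioactivity"]),
                   "dose_config")
  expect_identical(sc3$TracerName, "H2O")

  # an unresolvable required key is an error
  expect_error(
    resolve_sidecar(list(EchoTime = 5.1), rec, cfg$overview, cfg$tagmap),
    "RepetitionTime")
})

test_that("overview matching skips unknown series and rejects ambiguity", {
  d <- withr::local_tempdir()
  p <- make_configs(d)
  cfg <- load_configs(p$overview, p$tagmap)
  rec <- structure(list(modality_hint = "localizer", subject_label = "01",
                        session_label = NA, echo_times = numeric(0)),
                   class = "series_record")
  expect_warning(row <- match_overview(rec, cfg$overview), "skipped")
  expect_true(is.na(row))
  ov2 <- cfg$overview
  ov2$match_pattern <- c("T1", "T1w")      # both hit a T1w description
  rec2 <- structure(list(modality_hint = "t1_mprage_T1w"),
                    class = "series_record")
  expect_error(match_overview(rec2, ov2), "unambiguous|matches 2")
})

test_that("BIDS names order entities and respect single-session mode", {
  expect_identical(
    bids_name("01", "01", list(trc = "PK11195"), "pet"),
    "sub-01/ses-01/pet/sub-01_ses-01_trc-PK11195_pet.nii.gz")
  expect_identical(
    bids_name("04", "02", list(), "T2w"),
    "sub-04/ses-02/anat/sub-04_ses-02_T2w.nii.gz")
  single <- bids_name("07", NULL, list(), "T1w")
  expect_identical(single, "sub-07/anat/sub-07_T1w.nii.gz")
  expect_false(grepl("ses-", single))
  expect_error(bids_name("0 1", "01", list(), "T1w"), "illegal")
  # tracer entity is sanitized to alphanumerics
  expect_identical(
    bids_name("01", NULL, list(trc = "[11C]PK11195"), "pet"),
    "sub-01/pet/sub-01_trc-11CPK11195_pet.nii.gz")
})

test_that("written images and sidecars round trip and are deterministic", {
  sp <- tiny_spec()
  ph <- make_structural_phantom(sp, seed = 30)
  payload <- list(EchoTime = 0.0042, RepetitionTime = 2.65, FlipAngle = 9,
                  PixelBandwidth = 190)
  cvs <- list(list(volume = ph$volume, sidecar = payload, subject = "01",
                   session = "01", entities = list(), suffix = "T1w",
                   datatype = "anat"))
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  write_dataset(cvs, o1)
  write_dataset(cvs, o2)
  img <- file.path(o1, "sub-01", "ses-01", "anat", "sub-01_ses-01_T1w.nii.gz")
  back <- read_bids_volume(img)
  expect_identical(back$voxels + 0, ph$volume$voxels + 0)   # voxels bit-exact
  side <- jsonlite::fromJSON(sub("\\.nii\\.gz$", ".json", img))
  expect_equal(side[order(names(side))], payload[order(names(payload))])
  # byte-identical sidecars across runs
  j1 <- readLines(sub("\\.nii\\.gz$", ".json", img))
  j2 <- readLines(file.path(o2, "sub-01", "ses-01", "anat",
                            "sub-01_ses-01_T1w.json"))
  expect_identical(j1, j2)
  # collision guard
  expect_error(write_dataset(cvs, o1), "overwrite")
  expect_silent(write_dataset(cvs, o1, overwrite = TRUE))
})

test_that("selection filters exclude whole modalities from the tree", {
  out <- withr::local_tempdir()
  man <- make_cohort(file.path(out, "c"), n_subjects = 1L,
                     retest_subjects = integer(0), missingness = list(),
                     outliers = list(), tag_dropout = list(),
                     spec = tiny_spec(), seed = 21)
  cfg <- load_configs(man$overview, man$tagmap, man$doses)
  bids <- file.path(out, "bids")
  convert_to_bids(man$raw_root, bids, cfg,
                  sequences = c("T1w", "T2w", "T2starw", "dwi"),
                  participants = man$participants)
  expect_length(list.files(bids, pattern = "_pet", recursive = TRUE), 0L)
  expect_false(any(dir.exists(file.path(bids, "sub-01", "ses-01", "pet"))))
  expect_gt(length(list.files(bids, pattern = "_T1w\\.nii\\.gz$",
                              recursive = TRUE)), 0L)
})

test_that("a converted cohort passes the structural BIDS check", {
  out <- withr::local_tempdir()
  man <- make_cohort(file.path(out, "c"), n_subjects = 2L,
                     retest_subjects = 2L, missingness = list(),
                     outliers = list(), tag_dropout = list(),
                     spec = tiny_spec(), seed = 22)
  cfg <- load_configs(man$overview, man$tagmap, man$doses)
  bids <- file.path(out, "bids")
  convert_to_bids(man$raw_root, bids, cfg, participants = man$participants)
  v <- validate_bids_tree(bids)
  expect_true(v$ok)
  expect_length(v$problems, 0L)
  # 1 single-session + 1 retest subject -> 3 session folders
  ses_dirs <- grep("ses-[0-9]+$",
                   list.dirs(bids, recursive = TRUE, full.names = FALSE),
                   value = TRUE)
  expect_length(ses_dirs, 3L)
})
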