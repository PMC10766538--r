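# Indexing raw trees, volume assembly (slice ordering, echo vs frame axes),
# reorientation and diffusion tables.

test_that("a 2-subject tree indexes into records with correct labels", {
  root <- withr::local_tempdir()
  sp <- tiny_spec()
  manifest <- list()
  for (sub in c("01", "02")) for (nm in c("T1w", "T2w", "FLAIR")) {
    ph <- make_structural_phantom(sp, seed = sum(utf8ToInt(paste0(sub, nm))))
    write_series(root, sub, "01", nm, ph$volume,
                 list(SeriesDescription = paste0("seq_", nm),
                      StudyDate = "20180601"))
    manifest[[paste(sub, nm)]] <- ph$volume$voxels
  }
  recs <- index_dicom_tree(root, dicom_layout(1, 2, 3))
  expect_length(recs, 6L)
  expect_setequal(vapply(recs, `[[`, "", "subject_label"), c("01", "02"))
  expect_true(all(vapply(recs, `[[`, "", "session_label") == "01"))
  expect_true(all(vapply(recs, `[[`, 1L, "acquisition_year") == 2018L))
  # assembled arrays equal the generator ground truth, bit-exact
  for (r in recs) {
    key <- paste(r$subject_label, sub("seq_", "", r$modality_hint))
    expect_identical(assemble_volume(r)$voxels, manifest[[key]])
  }
})

test_that("an empty directory yields an empty index with a warning", {
  root <- withr::local_tempdir()
  expect_warning(recs <- index_dicom_tree(root), "no files")
  expect_length(recs, 0L)
})

test_that("two sessions of one subject carry session labels 01 and 02", {
  root <- withr::local_tempdir()
  sp <- tiny_spec()
  for (ses in c("01", "02")) {
    ph <- make_structural_phantom(sp, seed = as.integer(ses))
    write_series(root, "04", ses, "T2w", ph$volume,
                 list(SeriesDescription = "t2w"))
  }
  recs <- index_dicom_tree(root, dicom_layout(1, 2, 3))
  expect_setequal(vapply(recs, `[[`, "", "session_label"), c("01", "02"))
})

test_that("volume assembly produces the declared shapes", {
  root <- withr::local_tempdir()
  # 127 thin slices, single echo, single frame
  sp <- phantom_spec(dims = c(12L, 12L, 127L), semi_axes = c(4, 4, 40))
  ph <- make_structural_phantom(sp, seed = 2)
  write_series(root, "01", NULL, "stack", ph$volume,
               list(SeriesDescription = "s"))
  rec <- index_dicom_tree(root, dicom_layout(1, NULL, 2))[[1]]
  expect_equal(dim(assemble_volume(rec)$voxels), c(12L, 12L, 127L))

  # 2 echoes x 64 slices in one series -> 4-D with ascending echo times
  root2 <- withr::local_tempdir()
  sp2 <- phantom_spec(dims = c(8L, 8L, 64L), semi_axes = c(3, 3, 20),
                      echo_times = c(0.005, 0.015))
  ph2 <- make_structural_phantom(sp2, seed = 3)
  write_series(root2, "01", NULL, "me", ph2$volume,
               list(SeriesDescription = "me"))
  rec2 <- index_dicom_tree(root2, dicom_layout(1, NULL, 2))[[1]]
  vol2 <- assemble_volume(rec2)
  expect_equal(dim(vol2$voxels), c(8L, 8L, 64L, 2L))
  expect_equal(vol2$echo_times, c(0.005, 0.015))
  expect_identical(vol2$voxels, ph2$volume$voxels)

  # a single slice still assembles as a 3-D volume
  f <- tempfile(fileext = ".dcm")
  px <- matrix(1:64, 8, 8)
  dcm_write(f, list(SeriesInstanceUID = "1.9", InstanceNumber = 1L,
                    ImagePositionPatient = c(0, 0, 0),
                    ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
                    PixelSpacing = c(1, 1), SliceThickness = 2), px)
  rec3 <- structure(list(series_id = "single", valid = TRUE, file_paths = f,
                         echo_times = numeric(0), modality_hint = "x",
                         subject_label = "x", session_label = NA,
                         frame_count = 1L), class = "series_record")
  expect_equal(dim(assemble_volume(rec3)$voxels), c(8L, 8L, 1L))
})

test_that("a series with inconsistent dimensions is flagged, not merged", {
  root <- withr::local_tempdir()
  d <- file.path(root, "sub-01", "bad")
  dir.create(d, recursive = TRUE)
  dcm_write(file.path(d, "a.dcm"),
            list(SeriesInstanceUID = "1.1", InstanceNumber = 1L,
                 ImagePositionPatient = c(0, 0, 0),
                 ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
                 PixelSpacing = c(1, 1)), matrix(0L, 8, 8))
  dcm_write(file.path(d, "b.dcm"),
            list(SeriesInstanceUID = "1.1", InstanceNumber = 2L,
                 ImagePositionPatient = c(0, 0, 2),
                 ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
                 PixelSpacing = c(1, 1)), matrix(0L, 6, 6))
  recs <- index_dicom_tree(root, dicom_layout(1, NULL, 2))
  expect_false(recs[[1]]$valid)
  expect_error(assemble_volume(recs[[1]]), "inconsistent")
})

test_that("per-frame files and multi-slice frame files assemble identically", {
  sp <- tiny_spec(frame_schedule = "3x2;2x4")
  pet <- make_dynamic_pet(sp, seed = 8)
  r1 <- withr::local_tempdir(); r2 <- withr::local_tempdir()
  write_series(r1, "01", NULL, "pet", pet$volume,
               list(SeriesDescription = "p", Modality = "PT"),
               multislice = TRUE)
  write_series(r2, "01", NULL, "pet", pet$volume,
               list(SeriesDescription = "p", Modality = "PT"),
               multislice = FALSE)
  v1 <- assemble_volume(index_dicom_tree(r1, dicom_layout(1, NULL, 2))[[1]])
  v2 <- assemble_volume(index_dicom_tree(r2, dicom_layout(1, NULL, 2))[[1]])
  expect_identical(v1$voxels, v2$voxels)
  expect_identical(v1$voxels, pet$volume$voxels)
})

test_that("reorientation hits the target code, round-trips exactly and composes", {
  sp <- tiny_spec()
  ph <- make_structural_phantom(sp, seed = 4)
  vol <- ph$volume
  orig <- orientation_code(vol$affine)
  for (target in c("RPI", "RSA", "LAI", "SRA")) {
    v <- reorient(vol, target)
    expect_identical(orientation_code(v$affine), target)
    back <- reorient(v, orig)
    expect_identical(back$voxels, vol$voxels)
    expect_equal(back$affine, vol$affine)
  }
  # group property: composing reorientations equals the direct one
  via <- reorient(reorient(vol, "RSA"), "RPI")
  direct <- reorient(vol, "RPI")
  expect_identical(via$voxels, direct$voxels)
  expect_equal(via$affine, direct$affine)
})

test_that("a corner marker keeps its world position under reorientation", {
  sp <- tiny_spec()
  ph <- make_structural_phantom(sp, seed = 6)
  vol <- ph$volume
  vol$voxels[2, 3, 1] <- 30000   # asymmetric marker
  w_ref <- as.numeric(vol$affine %*% c(1, 2, 0, 1))[1:3]  # 0-based index
  for (target in c("RPI", "RSA", "ASL")) {
    v <- reorient(vol, target)
    idx <- which(v$voxels == 30000, arr.ind = TRUE)[1, ]
    # independent check: map found voxel through the new affine
    w <- as.numeric(v$affine %*% c(idx[1] - 1, idx[2] - 1, idx[3] - 1, 1))[1:3]
    expect_equal(w, w_ref)
  }
})

test_that("reorienting to the current code is the identity", {
  sp <- tiny_spec()
  vol <- make_structural_phantom(sp, seed = 10)$volume
  v <- reorient(vol, orientation_code(vol$affine))
  expect_identical(v$voxels, vol$voxels)
})

test_that("an oblique affine warns and snaps to the nearest code", {
  sp <- tiny_spec()
  vol <- make_structural_phantom(sp, seed = 11)$volume
  th <- 25 * pi / 180                      # beyond the 20 degree tolerance
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  vol$affine[1:3, 1:3] <- R %*% vol$affine[1:3, 1:3]
  expect_warning(code <- orientation_code(vol$affine), "oblique")
  expect_match(code, "^[LR][AP][SI]$")
})

test_that("diffusion tables reproduce the gradient scheme in stack order", {
  root <- withr::local_tempdir()
  sp <- tiny_spec()
  set.seed(20)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2))
  nv <- 7L
  vox <- array(round(stats::rnorm(prod(sp$dims) * nv, 500, 20)),
               c(sp$dims, nv))
  vol <- volume_stack(vox, sp$spacing_mm,
                      petmrbids:::.phantom_affine(sp$dims, sp$spacing_mm),
                      frame_times = 0:(nv - 1), frame_durations = rep(1, nv))
  pfm <- c(list(list(DiffusionBValue = 0)),
           lapply(seq_len(6), function(i)
             list(DiffusionBValue = 1000,
                  DiffusionGradientOrientation = dirs[i, ])))
  d <- file.path(root, "sub-01", "dwi")
  write_synthetic_dicom(vol, d, list(SeriesDescription = "dwi"),
                        per_frame_meta = pfm, series_uid = "1.3.1")
  rec <- index_dicom_tree(root, dicom_layout(1, NULL, 2))[[1]]
  tab <- extract_diffusion_tables(rec)
  expect_equal(tab$bvals, c(0, rep(1000, 6)))
  expect_equal(tab$bvecs[1, ], c(0, 0, 0))
  expect_equal(tab$bvecs[-1, ], dirs, tolerance = 1e-9)

  # all-b0 series: all-zero vectors and b-values
  pfm0 <- rep(list(list(DiffusionBValue = 0)), nv)
  d0 <- file.path(root, "sub-02", "dwi")
  write_synthetic_dicom(vol, d0, list(SeriesDescription = "dwi"),
                        per_frame_meta = pfm0, series_uid = "1.3.2")
  rec0 <- index_dicom_tree(root, dicom_layout(1, NULL, 2))
  rec0 <- rec0[[which(vapply(rec0, `[[`, "", "subject_label") == "02")]]
  tab0 <- extract_diffusion_tables(rec0)
  expect_true(all(tab0$bvals == 0))
  expect_true(all(tab0$bvecs == 0))

  # gradient vectors stay unit norm under axis-code changes
  bv <- reorient_bvecs(tab$bvecs, "LPS", "RPI")
  norms <- sqrt(rowSums(bv^2))
  expect_equal(norms[-1], rep(1, 6), tolerance = 1e-9)
})

test_that("missing gradient tags point the user to the config fallback", {
  root <- withr::local_tempdir()
  sp <- tiny_spec()
  vol <- make_structural_phantom(sp, seed = 12)$volume
  write_series(root, "01", NULL, "dwi", vol, list(SeriesDescription = "dwi"))
  rec <- index_dicom_tree(root, dicom_layout(1, NULL, 2))[[1]]
  expect_error(extract_diffusion_tables(rec), "fallback")
})
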