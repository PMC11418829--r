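# NIfTI round-trip, temporal resampling and spatial preprocessing.

write_test_nifti <- function(dir, H = 64, W = 64, S = 3, Tn = 20, seed = 5) {
  set.seed(seed)
  vol <- array(runif(W * H * S * Tn), dim = c(W, H, S, Tn))  # (x, y, z, t)
  for (t in seq_len(Tn)) vol[, , , t] <- vol[, , , t] + t    # ordered means
  path <- file.path(dir, "patient042_4d.nii.gz")
  RNifti::writeNifti(vol, path)
  list(path = path, vol = vol)
}

test_that("read_cine_volume round-trips a 4D NIfTI slice with frame order intact", {
  dir <- withr::local_tempdir()
  fx <- write_test_nifti(dir)
  seq <- read_cine_volume(fx$path, slice_index = 1L)
  expect_s3_class(seq, "cine_sequence")
  expect_identical(dim(seq$frames), c(20L, 64L, 64L))
  expect_equal(seq$patient_id, "patient042")
  expect_equal(seq$label, "unknown")
  # per-frame means must match the fixture generator's array, in order
  got <- sapply(1:20, function(t) mean(seq$frames[t, , ]))
  want <- sapply(1:20, function(t) mean(fx$vol[, , 2, t]))
  expect_equal(got, want, tolerance = 1e-12)
  # exact pixel correspondence under the (t, row=y, col=x) convention
  expect_equal(seq$frames[3, 10, 20], fx$vol[20, 10, 2, 3])
})

test_that("read_cine_volume reports bounds and format errors", {
  dir <- withr::local_tempdir()
  fx <- write_test_nifti(dir, S = 3)
  expect_error(read_cine_volume(fx$path, slice_index = 5L), "out of range")
  expect_error(read_cine_volume(file.path(dir, "nope.nii")), "not found")
  v3 <- array(0, dim = c(8, 8, 4))
  p3 <- file.path(dir, "vol3d.nii.gz")
  RNifti::writeNifti(v3, p3)
  expect_error(read_cine_volume(p3), "3D")
})

test_that("labels are read from the Info.cfg dialect next to the volume", {
  dir <- withr::local_tempdir()
  fx <- write_test_nifti(dir)
  writeLines(c("Group: DCM", "NbFrame: 20"), file.path(dir, "Info.cfg"))
  expect_equal(read_cine_volume(fx$path, 0L)$label, "DCM")
})

test_that("resample_cycle picks rounded uniformly spaced indices incl. endpoints", {
  mk <- function(L) cine_sequence(array(seq_len(L * 8 * 8), c(L, 8, 8)))
  # identity when L == target
  s13 <- resample_cycle(mk(13), 13)
  expect_identical(s13$frame_indices, 0:12)
  # L = 25 -> every other frame
  s25 <- resample_cycle(mk(25), 13)
  expect_identical(s25$frame_indices, as.integer(seq(0, 24, by = 2)))
  # short cycle is extended by nearest-index repetition
  s7 <- resample_cycle(mk(7), 13)
  expect_length(s7$frame_indices, 13)
  expect_identical(s7$frame_indices[1], 0L)
  expect_identical(s7$frame_indices[13], 6L)
  expect_true(all(diff(s7$frame_indices) >= 0))
  expect_error(resample_cycle(mk(5), 1), "target_len")
})

test_that("resample_cycle endpoints and idempotence hold across cycle lengths", {
  for (L in c(2L, 3L, 5L, 13L, 14L, 30L, 56L)) {
    s <- resample_cycle(cine_sequence(array(rnorm(L * 64), c(L, 8, 8))), 13)
    expect_length(s$frame_indices, 13)
    expect_identical(s$frame_indices[1], 0L)
    expect_identical(s$frame_indices[13], L - 1L)
    # resampling an already-13-frame sequence is the identity selection
    s2 <- resample_cycle(s, 13)
    expect_identical(s2$frames, s$frames)
  }
})

test_that("preprocess_frames crops to square, resizes and normalizes to [0,1]", {
  set.seed(7)
  seq <- cine_sequence(array(runif(5 * 64 * 80, 2, 9), c(5, 64, 80)))
  out <- preprocess_frames(seq, 128)
  expect_identical(dim(out$frames), c(5L, 128L, 128L))
  expect_gte(min(out$frames), 0)
  expect_lte(max(out$frames), 1)
  expect_equal(max(out$frames) - min(out$frames), 1, tolerance = 1e-12)
  # constant input maps to all zeros
  cst <- preprocess_frames(cine_sequence(array(7, c(3, 16, 16))), 32)
  expect_true(all(cst$frames == 0))
  # ramp hits exactly 0 and 1
  ramp <- cine_sequence(array(rep(1:16, each = 2, times = 16), c(2, 16, 16)))
  pr <- preprocess_frames(ramp, 16)
  expect_equal(min(pr$frames), 0)
  expect_equal(max(pr$frames), 1)
})

test_that("pipeline configurations round-trip through YAML", {
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(size = 32, channels = c("div", "vor"), mode = "e2e",
                         flow = flow_config(window = 9),
                         net = conv3d_config(epochs = 4L),
                         forest = forest_config(n_trees = 50L))
  p <- file.path(dir, "cfg.yaml")
  save_pipeline_config(cfg, p)
  back <- load_pipeline_config(p)
  expect_equal(back$size, 32L)
  expect_equal(back$channels, c("div", "vor"))
  expect_equal(back$mode, "e2e")
  expect_equal(back$flow$window, 9L)
  expect_equal(back$net$epochs, 4L)
  expect_equal(back$forest$n_trees, 50L)
  expect_equal(back$aggregate, cfg$aggregate)
})

test_that("archives round-trip with a JSON sidecar", {
  dir <- withr::local_tempdir()
  seq <- cine_sequence(array(runif(2 * 64), c(2, 8, 8)), patient_id = "p1",
                       label = "HCM")
  p <- file.path(dir, "seq")
  save_archive(seq, p)
  expect_true(file.exists(paste0(p, ".rds")))
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(meta$patient_id, "p1")
  expect_equal(meta$label, "HCM")
  expect_identical(load_archive(p)$frames, seq$frames)
})
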