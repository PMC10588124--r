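# DICOM reading is cross-checked against fixtures written by pydicom;
# TIFF stacks must round-trip losslessly; curation follows the stated
# retention rule.

test_that("grayscale multiframe DICOM round-trips through the reader", {
  H <- 12; W <- 10; Tn <- 40
  fr <- array(rep(as.integer(matrix(seq_len(H * W) %% 256, H, W)), Tn),
              c(H, W, Tn))
  path <- tempfile(fileext = ".dcm")
  write_dicom_fixture(fr, path)
  v <- read_dicom_video(path)
  expect_s3_class(v, "echo_video")
  expect_equal(dim(v$frames), c(H, W, Tn))
  expect_equal(v$frames[, , 1] * 255, fr[, , 1], tolerance = 1e-9)
  for (t in 2:Tn) expect_equal(v$frames[, , t], v$frames[, , 1])
  expect_equal(v$class_label, "unknown")
})

test_that("implicit VR little endian parses identically", {
  fr <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
  p1 <- tempfile(fileext = ".dcm"); p2 <- tempfile(fileext = ".dcm")
  write_dicom_fixture(fr, p1, transfer = "explicit")
  write_dicom_fixture(fr, p2, transfer = "implicit")
  expect_identical(read_dicom_video(p1)$frames, read_dicom_video(p2)$frames)
})

test_that("frame-time metadata sets fps; absent metadata falls back to 30", {
  fr <- array(0L, c(8, 8, 2))
  p <- tempfile(fileext = ".dcm")
  write_dicom_fixture(fr, p, frame_time = "33.333333")
  expect_equal(read_dicom_video(p)$fps, 30, tolerance = 1e-4)
  p2 <- tempfile(fileext = ".dcm")
  write_dicom_fixture(fr, p2)
  expect_equal(read_dicom_video(p2)$fps, 30)
})

test_that("pure-gray RGB payloads equal the grayscale read (luma oracle)", {
  H <- 8; W <- 8; Tn <- 2
  g <- array(sample(0:255, H * W * Tn, replace = TRUE), c(H, W, Tn))
  rgb <- array(0L, c(H, W, Tn, 3))
  for (ch in 1:3) rgb[, , , ch] <- g
  p1 <- tempfile(fileext = ".dcm"); p2 <- tempfile(fileext = ".dcm")
  write_dicom_fixture(g, p1)
  write_dicom_fixture(rgb, p2, photometric = "RGB")
  v1 <- read_dicom_video(p1); v2 <- read_dicom_video(p2)
  expect_equal(v2$frames, v1$frames, tolerance = 1e-6)
})

test_that("MONOCHROME1 is inverted, unsupported payloads error loudly", {
  fr <- array(255L, c(8, 8, 1))
  p <- tempfile(fileext = ".dcm")
  write_dicom_fixture(fr, p, photometric = "MONOCHROME1")
  expect_equal(max(read_dicom_video(p)$frames), 0)
  p2 <- tempfile(fileext = ".dcm")
  ybr <- array(7L, c(8, 8, 1, 3))
  write_dicom_fixture(ybr, p2, photometric = "YBR_FULL")
  expect_error(read_dicom_video(p2), "unsupported photometric")
  expect_error(read_dicom_video(tempfile()), "DICOM")
})

test_that("TIFF stacks are lossless after the export quantization", {
  set.seed(21)
  v <- echo_video(array(runif(16 * 16 * 5), c(16, 16, 5)), fps = 30,
                  video_id = "rt")
  p1 <- tempfile(fileext = ".tif")
  write_video_tiff(v, p1)
  v1 <- read_video_tiff(p1)
  p2 <- tempfile(fileext = ".tif")
  write_video_tiff(v1, p2)
  v2 <- read_video_tiff(p2)
  expect_identical(v1$frames, v2$frames)
  expect_equal(v1$frames, v$frames, tolerance = 1 / 65535)
})

test_that("curation keeps 300-frame videos, excludes 301, and is idempotent", {
  mk <- function(Tn, id) echo_video(array(0.5, c(8, 8, Tn)), video_id = id)
  vids <- list(mk(300, "ok"), mk(301, "long"), mk(10, "short"))
  cu <- curate(vids)
  expect_equal(sapply(cu$kept, function(v) v$video_id), c("ok", "short"))
  expect_equal(cu$log$video_id, "long")
  expect_equal(cu$log$reason, "too_long")
  cu2 <- curate(cu$kept)
  expect_equal(length(cu2$kept), length(cu$kept))
  expect_equal(nrow(cu2$log), 0)
})

test_that("curation quality predicate and empty input behave by contract", {
  cu <- curate(list())
  expect_length(cu$kept, 0)
  expect_equal(nrow(cu$log), 0)
  vids <- list(echo_video(array(0.5, c(8, 8, 4)), video_id = "flat"))
  cu <- curate(vids, quality_predicate = function(v) FALSE)
  expect_length(cu$kept, 0)
  expect_equal(cu$log$reason, "quality")
  # constant frames fail the variance heuristic
  cu <- curate(vids, quality_predicate = variance_quality_predicate())
  expect_length(cu$kept, 0)
})

test_that("dataset export writes a readable manifest and truth sidecar", {
  cfg <- synthetic_config(n_frames = 20, frame_height = 16,
                          frame_width = 16, period_frames = 8)
  ds <- generate_dataset(4, videos_per_subject = 1, split_ratio = 0.5,
                         seed = 3, config = cfg)
  dir <- file.path(tempdir(), "dsout")
  write_dataset(ds, dir)
  man <- read_manifest(dir)
  expect_equal(nrow(man), 4)
  v <- load_manifest_video(dir, man[1, ])
  expect_equal(n_frames(v), 20)
  expect_equal(v$class_label, man$class[1])
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_length(truth[[man$video_id[1]]]$phases, 20)
})
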