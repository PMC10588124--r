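# Run-length decoding of ES/ED timings and the trainable phase detector.

test_that("worked decode example: runs, boundary drops, last-index rule", {
  tm <- extract_timings(c(0, 0, 1, 1, 1, 0, 0, 1, 1), min_run = 1)
  expect_equal(as.numeric(tm$es), 6)
  expect_equal(as.numeric(tm$ed), 4)
  # without boundary dropping every run contributes its last index
  tm2 <- extract_timings(c(0, 0, 1, 1, 1, 0, 0, 1, 1), min_run = 1,
                         drop_boundary_runs = FALSE)
  expect_equal(as.numeric(tm2$es), c(1, 6))
  expect_equal(as.numeric(tm2$ed), c(4, 8))
})

test_that("degenerate sequences decode to empty timing lists", {
  expect_length(extract_timings(rep(0L, 12), min_run = 1)$es, 0)
  expect_length(extract_timings(rep(1L, 12), min_run = 1)$ed, 0)
  expect_length(extract_timings(c(0L), min_run = 1)$es, 0)
})

test_that("decode equals the naive scan oracle on random strings", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(3:14, 1)
    x <- sample(0:1, n, replace = TRUE)
    for (mr in 1:2) for (db in c(TRUE, FALSE)) {
      got <- extract_timings(x, min_run = mr, drop_boundary_runs = db)
      want <- oracle_extract_timings(x, min_run = mr,
                                     drop_boundary_runs = db)
      expect_equal(as.numeric(got$es), want$es)
      expect_equal(as.numeric(got$ed), want$ed)
    }
  }
})

test_that("ES and ED indices strictly interleave after decoding", {
  set.seed(32)
  for (rep in 1:100) {
    x <- sample(0:1, 40, replace = TRUE)
    tm <- extract_timings(x, min_run = 2)
    ed <- sort(tm$ed)
    if (length(ed) >= 2) {
      for (i in seq_len(length(ed) - 1))
        expect_equal(sum(tm$es > ed[i] & tm$es < ed[i + 1]), 1)
    }
  }
})

test_that("short-run denoising absorbs single-frame flips", {
  x <- c(rep(0L, 3), rep(1L, 6), 0L, rep(1L, 6), rep(0L, 3))
  tm <- extract_timings(x, min_run = 2)
  # the lone 0 is absorbed into one interior diastole run ending at 15
  expect_equal(as.numeric(tm$ed), 15)
  expect_length(tm$es, 0)
})

test_that("probabilities at the threshold are called diastole", {
  cfg <- timing_model_config(epochs = 1)
  # thresholding contract exercised directly on the rule
  prob <- c(0.2, 0.5, 0.7)
  expect_equal(as.integer(prob >= cfg$threshold), c(0L, 1L, 1L))
})

test_that("the detector errors on videos shorter than its minimum window", {
  cfg <- synthetic_config(n_frames = 40, frame_height = 32, frame_width = 32,
                          period_frames = 16)
  ds <- lapply(1:2, function(i)
    generate_video(cfg, c("N", "HTCM")[i], seed = i))
  m <- train_timing_model(ds, timing_model_config(epochs = 1, seed = 1))
  short <- echo_video(array(0.5, c(32, 32, 4)))
  expect_error(predict_frame_phases(m, short), "at least")
  expect_error(train_timing_model(ds[1]), "at least 2")
})

test_that("training is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_frames = 48, frame_height = 32, frame_width = 32,
                          period_frames = 16, noise_sigma = 0.01)
  ds <- lapply(1:3, function(i)
    generate_video(cfg, c("N", "HTCM", "N")[i], seed = i))
  m1 <- train_timing_model(ds, timing_model_config(epochs = 2, seed = 7))
  m2 <- train_timing_model(ds, timing_model_config(epochs = 2, seed = 7))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log, m2$log)
  v <- ds[[1]]$video
  expect_identical(predict_frame_phases(m1, v), predict_frame_phases(m2, v))
})

test_that("decoding predicted phases of ground-truth labels is exact", {
  # min_run = 1: ground-truth labels are noise-free, so no denoising —
  # merging would absorb the legitimate single-frame boundary runs
  cfg <- synthetic_config(n_frames = 180, period_frames = 36)
  s <- generate_video(cfg, "N", seed = 8)
  dec <- extract_timings(s$phase_labels, min_run = 1)
  expect_equal(as.numeric(dec$ed), as.numeric(s$true_timings$ed))
  expect_equal(as.numeric(dec$es), as.numeric(s$true_timings$es))
})
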