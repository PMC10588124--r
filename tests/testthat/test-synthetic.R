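# The phantom generator: exact timing ground truth, analytic geometry,
# determinism, class contrast, dataset split arithmetic.

test_that("invalid configurations name the violated invariant", {
  expect_error(synthetic_config(period_frames = 3), "period_frames")
  expect_error(synthetic_config(systole_fraction = 1), "systole_fraction")
  expect_error(synthetic_config(contraction_amplitude = 1),
               "contraction_amplitude")
  expect_error(synthetic_config(n_frames = 0), "n_frames")
})

test_that("zero motion and zero noise give pixel-identical frames", {
  cfg <- synthetic_config(contraction_amplitude = 0, noise_sigma = 0,
                          blur_sigma = 0, n_frames = 12)
  s <- generate_video(cfg, "N", seed = 1, use_presets = FALSE)
  f1 <- s$video$frames[, , 1]
  for (t in 2:12) expect_identical(s$video$frames[, , t], f1)
})

test_that("true ED indices are arithmetic with the configured period", {
  cfg <- synthetic_config(period_frames = 64, n_frames = 200)
  s <- generate_video(cfg, "N", seed = 2)
  expect_equal(diff(s$true_timings$ed), rep(64, length(s$true_timings$ed) - 1))
  expect_equal(s$true_timings$ed, c(64, 128, 192))
  # phase labels and timings are mutually consistent under the decode rule
  dec <- extract_timings(s$phase_labels, min_run = 1)
  expect_equal(as.numeric(dec$es), as.numeric(s$true_timings$es))
  expect_equal(as.numeric(dec$ed), as.numeric(s$true_timings$ed))
})

test_that("decode rule recovers true timings across configurations", {
  for (period in c(24, 48, 64)) for (sf in c(0.3, 0.5)) {
    cfg <- synthetic_config(period_frames = period, systole_fraction = sf,
                            n_frames = 150)
    s <- generate_video(cfg, "HTCM", seed = period)
    dec <- extract_timings(s$phase_labels, min_run = 1)
    expect_equal(as.numeric(dec$es), as.numeric(s$true_timings$es))
    expect_equal(as.numeric(dec$ed), as.numeric(s$true_timings$ed))
  }
})

test_that("ED/ES cavity-area ratio matches the analytic disc oracle", {
  amp <- 0.35
  cfg <- synthetic_config(noise_sigma = 0, blur_sigma = 0,
                          contraction_amplitude = amp, n_frames = 200)
  s <- generate_video(cfg, "N", seed = 3, use_presets = FALSE)
  ed <- s$true_timings$ed[1]; es <- s$true_timings$es[1]
  ratio <- cavity_area(s$video$frames[, , ed + 1]) /
    cavity_area(s$video$frames[, , es + 1])
  expect_equal(ratio, 1 / (1 - amp)^2, tolerance = 0.05)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_frames = 30)
  a <- generate_video(cfg, "HTCM", seed = 9)
  b <- generate_video(cfg, "HTCM", seed = 9)
  expect_identical(a$video$frames, b$video$frames)
  expect_identical(a$phase_labels, b$phase_labels)
  c <- generate_video(cfg, "HTCM", seed = 10)
  expect_false(identical(a$video$frames, c$video$frames))
})

test_that("disease preset leaves a larger cavity at end-systole", {
  cfg <- synthetic_config(noise_sigma = 0, blur_sigma = 0, n_frames = 150)
  areas <- sapply(c("N", "HTCM"), function(cl) {
    s <- generate_video(cfg, cl, seed = 5)
    mean(sapply(s$true_timings$es, function(e)
      cavity_area(s$video$frames[, , e + 1])))
  })
  expect_gt(areas["HTCM"], areas["N"])
})

test_that("subject-wise split arithmetic matches the stated ratios", {
  cfg <- synthetic_config(n_frames = 16, frame_height = 16,
                          frame_width = 16, period_frames = 8)
  ds <- generate_dataset(12, videos_per_subject = 1, split_ratio = 5 / 6,
                         seed = 1, config = cfg)
  expect_equal(length(ds$train), 10)
  expect_equal(length(ds$test), 2)
  tr_subj <- unique(ds$manifest$subject_id[ds$manifest$split == "train"])
  te_subj <- unique(ds$manifest$subject_id[ds$manifest$split == "test"])
  expect_length(intersect(tr_subj, te_subj), 0)
  expect_false(anyDuplicated(ds$manifest$domain_id) > 0)
})

test_that("a 297-subject cohort splits 247/50 with class-stratified floors", {
  # split arithmetic only: class-stratified floor(split_ratio * n_class)
  n <- 297; n_htcm <- 185; n_n <- 112
  expect_equal(floor(5 / 6 * n_n), 93)
  expect_equal(floor(5 / 6 * n_htcm), 154)
  cfg <- synthetic_config(n_frames = 2, frame_height = 8, frame_width = 8,
                          period_frames = 4)
  ds <- generate_dataset(297, videos_per_subject = 1,
                         class_balance = n_htcm / n, split_ratio = 5 / 6,
                         seed = 2, config = cfg)
  expect_equal(length(ds$train), 247)
  expect_equal(length(ds$test), 50)
  m <- ds$manifest
  expect_equal(sum(m$split == "train" & m$class == "N"), 93)
  expect_equal(sum(m$split == "train" & m$class == "HTCM"), 154)
})

test_that("too few subjects to fill both splits and classes errors", {
  cfg <- synthetic_config(n_frames = 2, frame_height = 8, frame_width = 8,
                          period_frames = 4)
  expect_error(generate_dataset(2, videos_per_subject = 1,
                                split_ratio = 0.5, seed = 1, config = cfg),
               "too few subjects")
})

test_that("config round-trips through YAML", {
  cfg <- synthetic_config(period_frames = 48, noise_sigma = 0.01)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  cfg2 <- synthetic_config_from_file(path)
  expect_equal(cfg2$period_frames, 48L)
  expect_equal(cfg2$noise_sigma, 0.01)
})
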