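# Snippet proposal geometry: one clip per end-diastole, boundary
# skipping, uniform spacing, and the fixed-length invariant.

mk_video <- function(Tn, id = "v") {
  echo_video(array(0.5, c(8, 8, Tn)), video_id = id, class_label = "N")
}

test_that("a cycle clip covers e, e+s, ..., e+s(L-1)", {
  v <- mk_video(100)
  bag <- propose_cycle_snippets(v, list(es = numeric(), ed = 10),
                                clip_len = 32, stride = 2)
  expect_length(bag$snippets, 1)
  s <- bag$snippets[[1]]
  expect_equal(s$start_frame, 10)
  expect_equal(s$source_ed_index, 10)
  expect_equal(dim(s$frames)[3], 32)
  expect_equal(bag$sampling_mode, "cycle")
})

test_that("clips that would overrun the video end are skipped", {
  v <- mk_video(300)
  bag <- propose_cycle_snippets(v, list(es = numeric(), ed = c(100, 240)),
                                clip_len = 32, stride = 2)
  # 240 + 2*31 = 302 >= 300: skipped
  expect_length(bag$snippets, 1)
  expect_equal(bag$snippets[[1]]$source_ed_index, 100)
  expect_equal(attr(bag, "skipped"), 240)
})

test_that("cycle snippets count the fitting interior EDs of a phantom", {
  cfg <- synthetic_config(period_frames = 64, n_frames = 260,
                          frame_height = 16, frame_width = 16)
  s <- generate_video(cfg, "N", seed = 4)
  tm <- extract_timings(s$phase_labels, min_run = 1)
  bag <- propose_cycle_snippets(s$video, tm)
  fits <- sum(tm$ed + 2 * 31 <= 259)
  expect_length(bag$snippets, fits)
  expect_equal(length(bag$snippets), 3)  # EDs 64, 128, 192 all fit
  # each clip spans 63 raw frames, about one full cycle
  expect_equal(2 * 31, 62)
})

test_that("no fitting ED falls back to uniform with padding", {
  v <- mk_video(20)
  bag <- propose_cycle_snippets(v, list(es = numeric(), ed = 10))
  expect_equal(bag$sampling_mode, "uniform")
  expect_true(isTRUE(attr(bag, "fallback")))
  expect_length(bag$snippets[[1]]$frames[1, 1, ], 32)
})

test_that("uniform starts are evenly spaced over the valid range", {
  v <- mk_video(153)  # max start = 152 - 62 = 90
  bag <- propose_uniform_snippets(v, clip_len = 32, stride = 2,
                                  n_snippets = 4)
  starts <- sapply(bag$snippets, function(s) s$start_frame)
  expect_equal(starts, c(0, 30, 60, 90))
})

test_that("a video exactly one clip long yields the single start 0", {
  v <- mk_video(63)  # s(L-1)+1 = 63
  bag <- propose_uniform_snippets(v, n_snippets = 1)
  expect_length(bag$snippets, 1)
  expect_equal(bag$snippets[[1]]$start_frame, 0)
  expect_error(propose_uniform_snippets(mk_video(62), n_snippets = 1),
               "shorter")
})

test_that("every emitted snippet has exactly L in-range frames (fuzz)", {
  set.seed(41)
  for (rep in 1:25) {
    Tn <- sample(30:200, 1)
    v <- mk_video(Tn)
    eds <- sort(sample(0:(Tn - 1), sample(1:5, 1)))
    L <- sample(c(8, 16, 32), 1); st <- sample(1:3, 1)
    bag <- propose_cycle_snippets(v, list(es = numeric(), ed = eds),
                                  clip_len = L, stride = st)
    for (s in bag$snippets) {
      expect_equal(dim(s$frames)[3], L)
      expect_lte(s$start_frame + s$stride * (L - 1), Tn - 1)
      expect_gte(s$start_frame, 0)
    }
    starts <- sapply(bag$snippets, function(s) s$start_frame)
    expect_true(all(diff(starts) > 0) || length(starts) == 1)
  }
})

test_that("the bag cap keeps the earliest clips", {
  v <- mk_video(300)
  eds <- seq(0, 200, by = 10)
  bag <- propose_cycle_snippets(v, list(es = numeric(), ed = eds),
                                max_snippets = 4)
  expect_length(bag$snippets, 4)
  expect_equal(sapply(bag$snippets, function(s) s$source_ed_index),
               c(0, 10, 20, 30))
})

test_that("bag manifests serialize the clip geometry", {
  v <- mk_video(100)
  bag <- propose_cycle_snippets(v, list(es = numeric(), ed = c(0, 10)))
  m <- bag_manifest(bag)
  expect_equal(m$mode, "cycle")
  expect_equal(m$snippets[[2]]$start_frame, 10)
  expect_equal(m$snippets[[1]]$stride, 2)
})
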