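# ROC/AUC, the eight diagnostic metrics, subject aggregation, report files.

test_that("trapezoidal AUC handles separation and the worked example", {
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 1)
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC equals pairwise concordance (ties counted half)", {
  set.seed(81)
  for (rep in 1:60) {
    n <- sample(4:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(s, y)$auc, oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("the hand-derived confusion fixture yields the stated metrics", {
  # TP=30, FN=1, FP=3, TN=16
  scores <- c(rep(0.9, 30), rep(0.1, 1), rep(0.9, 3), rep(0.1, 16))
  labels <- c(rep(1, 31), rep(0, 19))
  m <- compute_metrics(scores, labels, ci = FALSE)
  expect_equal(unname(m$confusion), c(30, 3, 16, 1))
  expect_equal(round(m$sen, 3), 0.968)
  expect_equal(round(m$spe, 3), 0.842)
  expect_equal(round(m$acc, 3), 0.920)
  expect_equal(round(m$ppv, 3), 0.909)
  expect_equal(round(m$npv, 3), 0.941)
  expect_equal(round(m$plr, 2), 6.13)
  expect_equal(round(m$nlr, 3), 0.038)
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(82)
  for (rep in 1:100) {
    tp <- sample(0:20, 1); fn <- sample(0:20, 1)
    fp <- sample(0:20, 1); tn <- sample(0:20, 1)
    if (tp + fn == 0 || fp + tn == 0) next
    scores <- c(rep(0.9, tp), rep(0.1, fn), rep(0.9, fp), rep(0.1, tn))
    labels <- c(rep(1, tp + fn), rep(0, fp + tn))
    m <- compute_metrics(scores, labels, ci = FALSE)
    n <- tp + fn + fp + tn
    expect_equal(sum(m$confusion), n)
    expect_equal(m$acc, (tp + tn) / n)
    if (!is.na(m$ppv)) expect_equal(m$ppv * (tp + fp), tp)
    if (!is.na(m$plr)) expect_equal(m$plr * (1 - m$spe), m$sen)
    if (!is.na(m$nlr)) expect_equal(m$nlr * m$spe, 1 - m$sen)
    expect_true(all(unlist(m[c("acc", "sen", "spe")]) >= 0, na.rm = TRUE))
  }
})

test_that("perfect and degenerate classifiers exercise the guards", {
  m <- compute_metrics(c(0.9, 0.9, 0.1), c(1, 1, 0), ci = FALSE)
  expect_equal(m$acc, 1); expect_equal(m$sen, 1)
  expect_equal(m$spe, 1); expect_equal(m$nlr, 0)
  expect_true("PLR" %in% m$undefined)
  # labels all positive: SPE undefined path
  m2 <- compute_metrics(c(0.9, 0.8), c(1, 1), ci = FALSE)
  expect_true(is.na(m2$spe))
  expect_true(all(c("PLR", "NLR") %in% m2$undefined))
})

test_that("bootstrap CI brackets the point AUC and is seeded", {
  set.seed(83)
  s <- c(runif(20, 0.4, 1), runif(20, 0, 0.6))
  y <- rep(1:0, each = 20)
  m1 <- compute_metrics(s, y, n_boot = 200, seed = 7)
  m2 <- compute_metrics(s, y, n_boot = 200, seed = 7)
  expect_identical(m1$auc_ci, m2$auc_ci)
  expect_lte(m1$auc_ci[1], m1$auc)
  expect_gte(m1$auc_ci[2], m1$auc)
})

test_that("subject aggregation averages last-layer outputs", {
  one <- data.frame(subject_id = "a", score_N = 1.2, score_HTCM = 0.3,
                    label = 0)
  ag <- aggregate_subjects(one)
  expect_equal(ag$score_N, 1.2)
  expect_equal(ag$prob_HTCM, echomil:::softmax(c(1.2, 0.3))[2])
  # probability-mode worked example: [0.2, 0.8] and [0.4, 0.6] -> [0.3, 0.7]
  two <- data.frame(subject_id = "b",
                    score_N = log(c(0.2, 0.4)), score_HTCM = log(c(0.8, 0.6)),
                    label = 1)
  agp <- aggregate_subjects(two, mode = "probabilities")
  expect_equal(agp$prob_HTCM, 0.7, tolerance = 1e-12)
})

test_that("logit and probability averaging can flip a borderline subject", {
  d <- data.frame(subject_id = "s",
                  score_N = c(5, 5, 0), score_HTCM = c(0, 0, 12),
                  label = 1)
  lg <- aggregate_subjects(d, mode = "logits")
  pr <- aggregate_subjects(d, mode = "probabilities")
  expect_gt(lg$prob_HTCM, 0.5)   # logit mean (10/3, 4) favors HTCM
  expect_lt(pr$prob_HTCM, 0.5)   # probability mean favors N
})

test_that("aggregation preserves the probability simplex", {
  set.seed(84)
  d <- data.frame(subject_id = sample(letters[1:3], 12, replace = TRUE),
                  score_N = rnorm(12), score_HTCM = rnorm(12))
  for (mode in c("logits", "probabilities")) {
    ag <- aggregate_subjects(d, mode = mode)
    expect_true(all(ag$prob_HTCM >= 0 & ag$prob_HTCM <= 1))
  }
})

test_that("reports write one row per method x granularity, byte-stable", {
  s <- c(0.9, 0.8, 0.3, 0.2); y <- c(1, 1, 0, 0)
  reps <- list("ours/video" = compute_metrics(s, y, ci = FALSE),
               "ours/subject" = compute_metrics(s, y, ci = FALSE,
                                                granularity = "subject"),
               "baseline/video" = compute_metrics(rev(s), y, ci = FALSE),
               "baseline/subject" = compute_metrics(rev(s), y, ci = FALSE,
                                                    granularity = "subject"))
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  make_report(reps, d1); make_report(reps, d2)
  t1 <- read.csv(file.path(d1, "metrics.csv"))
  expect_equal(nrow(t1), 4)
  expect_equal(sort(unique(t1$granularity)), c("subject", "video"))
  expect_identical(unname(tools::md5sum(file.path(d1, "metrics.csv"))),
                   unname(tools::md5sum(file.path(d2, "metrics.csv"))))
})
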