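# Attention ensemble contracts, gradient reversal, label smoothing, and
# the training loop's sampler/iteration structure.

tiny_model <- function(n_domains = 3, attn_type = "bilstm", seed = 1) {
  video_model(backbone_config(input_size = 32, feature_dim = 8, seed = seed),
              n_domains = n_domains, attn_hidden = 4,
              attn_type = attn_type, seed = seed)
}

rand_bag <- function(seed, n_snip = 3, Tn = 30, class = "HTCM", dom = 0L) {
  set.seed(seed)
  v <- echo_video(array(runif(16 * 16 * Tn), c(16, 16, Tn)),
                  video_id = paste0("v", seed),
                  subject_id = paste0("s", seed),
                  class_label = class, domain_id = dom)
  propose_uniform_snippets(v, clip_len = 8, stride = 2, n_snippets = n_snip)
}

test_that("attention weights live on the simplex for fuzzed bags", {
  m <- tiny_model()
  set.seed(61)
  for (rep in 1:20) {
    H <- matrix(rnorm(sample(1:6, 1) * 8, sd = runif(1, 0.1, 5)), ncol = 8)
    at <- attention_ensemble(m, H)
    expect_true(all(at$weights >= 0))
    expect_equal(sum(at$weights), 1, tolerance = 1e-6)
    # z in the per-coordinate convex hull of the representations
    for (j in 1:8) {
      expect_gte(at$z[j], min(H[, j]) - 1e-9)
      expect_lte(at$z[j], max(H[, j]) + 1e-9)
    }
  }
})

test_that("a single-snippet bag gets weight 1 and z = h1 exactly", {
  m <- tiny_model()
  h <- matrix(rnorm(8), 1, 8)
  at <- attention_ensemble(m, h)
  expect_equal(at$weights, 1)
  expect_equal(at$z, as.vector(h))
})

test_that("equal scores yield uniform weights and the mean representation", {
  m <- tiny_model()
  m$params$score$W[] <- 0
  m$params$score$b[] <- 0
  H <- matrix(rnorm(4 * 8), 4, 8)
  at <- attention_ensemble(m, H)
  expect_equal(at$weights, rep(0.25, 4))
  expect_equal(at$z, colMeans(H))
})

test_that("temporal attention is order-sensitive, gated attention is not", {
  set.seed(62)
  m <- tiny_model(attn_type = "bilstm", seed = 5)
  g <- tiny_model(attn_type = "gated", seed = 5)
  changed <- logical(0)
  for (rep in 1:10) {
    H <- matrix(rnorm(5 * 8), 5, 8)
    wb <- attention_ensemble(m, H)$weights
    wb_rev <- attention_ensemble(m, H[5:1, ])$weights
    changed <- c(changed, max(abs(wb_rev - rev(wb))) > 1e-8)
    wg <- attention_ensemble(g, H)$weights
    wg_rev <- attention_ensemble(g, H[5:1, ])$weights
    expect_equal(wg_rev, rev(wg), tolerance = 1e-10)
  }
  expect_true(mean(changed) >= 0.8)
})

test_that("gradient reversal is the identity forward and -lambda backward", {
  x <- array(rnorm(12), c(3, 4))
  expect_identical(grl_forward(x, 2.5), x)
  expect_equal(grl_backward(x, 0), x * 0)
  # toy graph: f(g(x)) with the node between g and f
  lam <- 1.7
  g <- function(x) c(2 * x[1] + x[2], x[1] * x[2])
  f <- function(u) sum((u + 1)^2)
  x0 <- c(0.3, -0.8)
  fd <- num_grad(function(x) f(g(x)), x0)
  # analytic chain with the node inserted: upstream grad times -lambda
  du <- 2 * (g(x0) + 1)
  du <- grl_backward(du, lam)
  J <- rbind(c(2, 1), c(x0[2], x0[1]))
  expect_equal(as.vector(t(J) %*% du), -lam * fd, tolerance = 1e-6)
})

test_that("the reversal scales the domain loss's feature gradient by
           -lambda inside the full model", {
  m <- tiny_model(n_domains = 3)
  bag <- rand_bag(71, dom = 1L)
  fw <- echomil:::video_forward(m, bag, dropout = 0)
  ld <- echomil:::ce_loss(fw$dom_logits, smoothed_targets(2, 3, 0))
  g1 <- echomil:::video_backward(m, bag, fw, ddom = ld$dlogits,
                                 lambda = 1)
  g2 <- echomil:::video_backward(m, bag, fw, ddom = ld$dlogits,
                                 lambda = 2.5)
  g0 <- echomil:::video_backward(m, bag, fw, ddom = ld$dlogits,
                                 lambda = 0)
  # feature-path gradients scale linearly in -lambda ...
  expect_equal(g2$backbone$conv3$W, 2.5 * g1$backbone$conv3$W,
               tolerance = 1e-10)
  expect_equal(g2$attn$fwd$W, 2.5 * g1$attn$fwd$W, tolerance = 1e-10)
  expect_equal(max(abs(g0$backbone$conv1$W)), 0)
  # ... while the domain head itself trains identically at any lambda
  expect_equal(g2$dom$W, g1$dom$W)
  # and the feature gradient direction is reversed relative to a
  # descent direction on the domain loss: adding it to the parameters
  # (a descent step) increases the domain loss
  eps <- 1e-4
  m2 <- m
  m2$params$backbone$conv3$W <- m2$params$backbone$conv3$W -
    eps * g1$backbone$conv3$W
  fw2 <- echomil:::video_forward(m2, bag, dropout = 0)
  l2 <- echomil:::ce_loss(fw2$dom_logits, smoothed_targets(2, 3, 0))$loss
  expect_gt(l2, ld$loss)
})

test_that("label smoothing follows the stated mixture", {
  expect_equal(smoothed_targets(2, 2, 0.1), c(0.05, 0.95))
  expect_equal(smoothed_targets(1, 2, 0), c(1, 0))
  set.seed(63)
  for (rep in 1:20) {
    K <- sample(2:6, 1); eps <- runif(1, 0, 0.99)
    t <- smoothed_targets(sample(K, 1), K, eps)
    expect_equal(sum(t), 1, tolerance = 1e-12)
    expect_true(all(t >= 0))
  }
})

test_that("untrained models emit simplex probabilities and attention", {
  m <- tiny_model()
  p <- classify_video(m, rand_bag(72))
  expect_equal(sum(p$class_probabilities), 1, tolerance = 1e-9)
  expect_true(all(p$class_probabilities >= 0))
  expect_equal(sum(p$attention), 1, tolerance = 1e-6)
  expect_length(p$domain_scores, 3)
})

test_that("the balanced sampler draws equal class counts per epoch", {
  bags <- c(lapply(1:2, function(i) rand_bag(i, class = "N",
                                             dom = as.integer(i - 1))),
            lapply(3:8, function(i) rand_bag(i, class = "HTCM",
                                             dom = as.integer(i - 1))))
  m <- tiny_model(n_domains = 8)
  cfg <- mil_train_config(lr = 1e-3, epochs = 2, iters_per_epoch = 12,
                          dropout = 0, seed = 4)
  tr <- train_mil(m, bags, bags, cfg)
  expect_equal(tr$epoch_counts$n_N, c(6, 6))
  expect_equal(tr$epoch_counts$n_HTCM, c(6, 6))
  expect_equal(nrow(tr$log), 24)
  expect_equal(tr$log$lr[1], 1e-3)
  expect_lt(tr$log$lr[24], 1e-8)
})

test_that("training rejects duplicate or out-of-range domain ids", {
  bags <- list(rand_bag(1, class = "N", dom = 0L),
               rand_bag(2, class = "HTCM", dom = 0L))
  m <- tiny_model(n_domains = 2)
  expect_error(train_mil(m, bags, bags, mil_train_config(epochs = 1)),
               "unique domain_id")
  bags2 <- list(rand_bag(1, class = "N", dom = 0L),
                rand_bag(2, class = "HTCM", dom = 5L))
  expect_error(train_mil(m, bags2, bags2, mil_train_config(epochs = 1)),
               "unique domain_id")
})

test_that("training is deterministic under a fixed seed", {
  bags <- list(rand_bag(1, class = "N", dom = 0L),
               rand_bag(2, class = "HTCM", dom = 1L))
  cfg <- mil_train_config(lr = 1e-3, epochs = 1, iters_per_epoch = 4,
                          dropout = 0.5, seed = 11)
  m1 <- train_mil(tiny_model(n_domains = 2), bags, bags, cfg)
  m2 <- train_mil(tiny_model(n_domains = 2), bags, bags, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
})
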