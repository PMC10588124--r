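# Image-based comparison methods: a small 2D frame classifier fed either
# randomly selected frames or the ES/ED frames themselves, with
# video-level scores obtained by averaging frame scores. These exist for
# pipeline-ordering comparisons, not as faithful reimplementations of the
# methods they stand in for.

#' Frame selection policy
#'
#' @param mode `"random"` (seeded uniform sample without replacement) or
#'   `"esed"` (the decoded ES and ED frames themselves).
#' @param n_frames frames per video in random mode.
#' @param seed RNG seed for random mode.
#' @return A `frame_selection_policy` list.
#' @export
frame_selection_policy <- function(mode = c("random", "esed"), n_frames = 8,
                                   seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 1)
  list(mode = mode, n_frames = n_frames, seed = seed)
}

#' Select frames from a video under a policy
#'
#' Random mode draws `n_frames` distinct indices (capped at the video
#' length); ES/ED mode returns the decoded turning-point frames and falls
#' back to random with a warning when the timing list is empty.
#'
#' @param video an [echo_video()].
#' @param timings decoded timings (required by `"esed"` mode).
#' @param policy a [frame_selection_policy()].
#' @return Sorted 0-based frame indices.
#' @export
select_frames <- function(video, timings = NULL, policy) {
  Tn <- n_frames(video)
  if (policy$mode == "esed") {
    idx <- sort(unique(c(timings$es, timings$ed)))
    if (length(idx) > 0) return(idx)
    warning("select_frames: empty timings; falling back to random selection")
  }
  set.seed(derive_seed(policy$seed, paste0("frames_", video$video_id)))
  k <- min(policy$n_frames, Tn)
  sort(sample(Tn, k) - 1L)
}

## ---- 2D frame classifier ---------------------------------------------------

#' Configuration of the image-baseline classifier
#'
#' A compact 2D ConvNet (two conv+pool blocks on a 16x16 grid, global
#' average pooling, linear head) trained on individual frames with
#' label-smoothed cross-entropy.
#'
#' @param feature_dim representation width.
#' @param epochs,lr,momentum,weight_decay,label_smoothing SGD settings.
#' @param seed RNG seed.
#' @return An `image_baseline_config` list.
#' @export
image_baseline_config <- function(feature_dim = 16, epochs = 10, lr = 0.05,
                                  momentum = 0.9, weight_decay = 1e-5,
                                  label_smoothing = 0.1, seed = 1) {
  list(feature_dim = feature_dim, epochs = epochs, lr = lr,
       momentum = momentum, weight_decay = weight_decay,
       label_smoothing = label_smoothing, seed = seed)
}

image_prepare_frame <- function(frame) {
  d <- dim(frame)
  f <- max(1L, min(d) %/% 16L)
  fr <- crop_to_multiple(array(frame, c(d, 1)), f)
  pool3d(array(fr, c(dim(fr), 1)), c(f, f, 1))  # (16,16,1,1)
}

image_forward <- function(model, Xp) {
  c1 <- conv3d_forward(model$arch$conv1, model$params$conv1, Xp)
  a1 <- relu(c1$out)
  p1 <- pool3d(a1, c(2, 2, 1))
  c2 <- conv3d_forward(model$arch$conv2, model$params$conv2, p1)
  a2 <- relu(c2$out)
  d2 <- dim(a2)
  h <- colMeans(matrix(a2, nrow = prod(d2[1:3])))
  logits <- as.vector(dense_forward(model$params$head, matrix(h, 1)))
  list(logits = logits,
       cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, h = h))
}

image_backward <- function(model, cache, dlogits) {
  gh <- dense_backward(model$params$head, matrix(cache$h, 1),
                       matrix(dlogits, 1))
  d2 <- dim(cache$a2)
  da2 <- array(rep(as.vector(gh$dX) / prod(d2[1:3]),
                   each = prod(d2[1:3])), d2)
  dc2 <- relu_backward(cache$c2$out, da2)
  g2 <- conv3d_backward(model$arch$conv2, model$params$conv2,
                        cache$c2$cache, dc2)
  da1 <- unpool3d(g2$dX, c(2, 2, 1))
  dc1 <- relu_backward(cache$c1$out, da1)
  g1 <- conv3d_backward(model$arch$conv1, model$params$conv1,
                        cache$c1$cache, dc1)
  list(conv1 = list(W = g1$dW, b = g1$db),
       conv2 = list(W = g2$dW, b = g2$db),
       head = list(W = gh$dW, b = gh$db))
}

#' Train an image-based baseline classifier
#'
#' @param frame_sets list of `list(frames = <0-based indices>, video =
#'   <echo_video>)` training items; each selected frame becomes one
#'   training example with the video's class label.
#' @param config an [image_baseline_config()].
#' @return A trained `image_baseline` model with a per-epoch log.
#' @export
train_image_baseline <- function(frame_sets, config = image_baseline_config()) {
  set.seed(derive_seed(config$seed, "image_init"))
  d <- config$feature_dim
  arch <- list(conv1 = conv3d_arch(c(3, 3, 1), 1, 8),
               conv2 = conv3d_arch(c(3, 3, 1), 8, d))
  params <- list(conv1 = conv3d_init(arch$conv1),
                 conv2 = conv3d_init(arch$conv2),
                 head = dense_init(d, 2))
  model <- structure(list(config = config, arch = arch, params = params),
                     class = "image_baseline")
  X <- list(); y <- integer()
  for (fs in frame_sets) {
    for (fi in fs$frames) {
      X[[length(X) + 1]] <- image_prepare_frame(fs$video$frames[, , fi + 1])
      y <- c(y, class_index(fs$video$class_label))
    }
  }
  if (length(X) == 0) stop("train_image_baseline: no training frames")
  state <- sgd_state(params)
  total <- config$epochs * length(X)
  it <- 0
  log <- data.frame(epoch = integer(), loss = numeric())
  for (ep in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, sprintf("image_ep%d", ep)))
    ord <- sample(length(X))
    ep_loss <- 0
    for (i in ord) {
      it <- it + 1
      fw <- image_forward(model, X[[i]])
      tgt <- smoothed_targets(y[i], 2, config$label_smoothing)
      l <- ce_loss(fw$logits, tgt)
      grads <- image_backward(model, fw$cache, l$dlogits)
      up <- sgd_step(model$params, grads, state,
                     cosine_lr(it, total, config$lr),
                     momentum = config$momentum,
                     weight_decay = config$weight_decay)
      model$params <- up$p; state <- up$v
      ep_loss <- ep_loss + l$loss
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / length(X)))
  }
  model$log <- log
  model
}

#' Score a video with an image baseline
#'
#' The video score is the mean of its selected frames' last-layer
#' outputs; probabilities are the softmax of the mean.
#'
#' @param model a trained `image_baseline`.
#' @param video an [echo_video()].
#' @param frames 0-based frame indices to score.
#' @return `list(video_id, subject_id, class_scores,
#'   class_probabilities, class_label)`.
#' @export
predict_image_baseline <- function(model, video, frames) {
  stopifnot(length(frames) >= 1)
  L <- vapply(frames, function(fi)
    image_forward(model, image_prepare_frame(video$frames[, , fi + 1]))$logits,
    numeric(2))
  m <- rowMeans(matrix(L, nrow = 2))
  list(video_id = video$video_id, subject_id = video$subject_id,
       class_scores = m, class_probabilities = softmax(m),
       class_label = video$class_label)
}
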