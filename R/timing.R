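# End-systole / end-diastole timing: run-length decoding of per-frame
# phase labels, and a small trainable per-frame phase detector
# (3D spatiotemporal convolution features + bidirectional LSTM).

#' Decode ES/ED timings from per-frame phase labels
#'
#' Phases are decomposed into maximal constant runs; the last index of
#' each systole (0) run is an end-systole candidate and the last index of
#' each diastole (1) run an end-diastole candidate. Runs shorter than
#' `min_run` are first denoised: repeatedly, the leftmost too-short run is
#' relabeled to its longer neighbour (ties go to the left neighbour; a
#' boundary run merges into its only neighbour) until no short run
#' remains. Candidates from runs touching either video boundary are
#' dropped when `drop_boundary_runs` — the last frame of a truncated run
#' is an artifact of truncation, not a physiologic turning point.
#'
#' @param phases integer 0/1 vector of per-frame phases (0 = systole,
#'   1 = diastole).
#' @param min_run minimum run length kept before decoding.
#' @param drop_boundary_runs drop candidates from runs touching either
#'   end of the video.
#' @return `list(es = <0-based indices>, ed = <0-based indices>)`, both
#'   sorted; possibly empty.
#' @export
extract_timings <- function(phases, min_run = 2, drop_boundary_runs = TRUE) {
  stopifnot(length(phases) >= 1, all(phases %in% c(0L, 1L)))
  phases <- as.integer(phases)
  if (min_run > 1) {
    repeat {
      r <- rle(phases)
      k <- length(r$lengths)
      short <- which(r$lengths < min_run)
      if (length(short) == 0 || k == 1) break
      i <- short[1]
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      left <- if (i > 1) r$lengths[i - 1] else -1L
      right <- if (i < k) r$lengths[i + 1] else -1L
      take_left <- left >= right  # ties go left; -1 marks a missing side
      nb <- if (take_left) i - 1 else i + 1
      phases[starts[i]:ends[i]] <- r$values[nb]
    }
  }
  r <- rle(phases)
  k <- length(r$lengths)
  ends0 <- cumsum(r$lengths) - 1L  # 0-based last index of each run
  keep <- rep(TRUE, k)
  if (drop_boundary_runs) {
    keep[1] <- FALSE
    keep[k] <- FALSE
  }
  list(es = ends0[keep & r$values == 0L],
       ed = ends0[keep & r$values == 1L])
}

#' Mean absolute localization error of decoded timings
#'
#' For each true index, the distance to the nearest predicted index;
#' averaged. `Inf` when nothing was predicted.
#'
#' @param predicted,truth numeric index vectors (e.g. ED indices).
#' @return Mean absolute frame error.
#' @export
timing_localization_error <- function(predicted, truth) {
  if (length(truth) == 0) return(NA_real_)
  if (length(predicted) == 0) return(Inf)
  mean(vapply(truth, function(t) min(abs(predicted - t)), numeric(1)))
}

## ---- timing detector ------------------------------------------------------

#' Configuration of the ES/ED timing detector
#'
#' A compact per-frame phase classifier: spatial average pooling, one 3D
#' convolution (temporal extent 3, so filters can express local
#' frame-to-frame motion), ReLU, further spatial pooling, global spatial
#' averaging into a per-frame feature vector, a bidirectional LSTM over
#' the frame sequence, and a per-frame sigmoid diastole probability
#' trained with binary cross-entropy.
#'
#' @param conv_channels 3D-conv filters.
#' @param spatial_pool,post_pool spatial average-pooling factors before /
#'   after the convolution.
#' @param hidden LSTM hidden size per direction.
#' @param threshold decision threshold on the diastole probability, in
#'   (0, 1); ties go to diastole.
#' @param epochs,lr,momentum,weight_decay SGD settings (cosine-decayed
#'   learning rate).
#' @param min_frames minimum video length the detector accepts.
#' @param seed RNG seed for initialisation and data order.
#' @return A `timing_model_config` list.
#' @export
timing_model_config <- function(conv_channels = 8, spatial_pool = 4,
                                post_pool = 2, hidden = 8, threshold = 0.5,
                                epochs = 40, lr = 0.05, momentum = 0.9,
                                weight_decay = 1e-5, min_frames = 8,
                                seed = 1) {
  stopifnot(threshold > 0, threshold < 1)
  list(conv_channels = conv_channels, spatial_pool = spatial_pool,
       post_pool = post_pool, hidden = hidden, threshold = threshold,
       epochs = epochs, lr = lr, momentum = momentum,
       weight_decay = weight_decay, min_frames = min_frames, seed = seed)
}

# Center-crop H and W to multiples of `f` so pooling factors divide.
crop_to_multiple <- function(frames, f) {
  d <- dim(frames)
  H <- (d[1] %/% f) * f; W <- (d[2] %/% f) * f
  oh <- (d[1] - H) %/% 2; ow <- (d[2] - W) %/% 2
  frames[oh + seq_len(H), ow + seq_len(W), , drop = FALSE]
}

timing_pooled_input <- function(cfg, video) {
  f <- cfg$spatial_pool * cfg$post_pool
  X <- crop_to_multiple(video$frames, f)
  d <- dim(X)
  X <- array(X, c(d, 1))
  pool3d(X, c(cfg$spatial_pool, cfg$spatial_pool, 1))
}

timing_forward <- function(model, Xp) {
  cfg <- model$config
  cv <- conv3d_forward(model$arch$conv, model$params$conv, Xp)
  a <- relu(cv$out)
  pp <- pool3d(a, c(cfg$post_pool, cfg$post_pool, 1))
  d <- dim(pp)
  # global spatial average -> T x C features
  feats <- matrix(colMeans(matrix(pp, nrow = d[1] * d[2])), d[3], d[4])
  st <- std_forward(feats)
  bl <- bilstm_forward(model$params$lstm, st$Y)
  logits <- dense_forward(model$params$head, bl$H)
  prob <- sigmoid(as.vector(logits))
  list(prob = prob,
       cache = list(cv = cv, a = a, ppdim = d, st = st, bl = bl))
}

timing_backward <- function(model, Xp, cache, dlogit) {
  cfg <- model$config
  gh <- dense_backward(model$params$head, cache$bl$H,
                       matrix(dlogit, ncol = 1))
  gl <- bilstm_backward(model$params$lstm, cache$bl$cache, gh$dX)
  dfeat <- std_backward(cache$st$cache, gl$dX)
  d <- cache$ppdim
  dpp <- array(rep(as.vector(dfeat) / (d[1] * d[2]), each = d[1] * d[2]), d)
  da <- unpool3d(dpp, c(cfg$post_pool, cfg$post_pool, 1))
  dcv <- relu_backward(cache$cv$out, da)
  gc <- conv3d_backward(model$arch$conv, model$params$conv, cache$cv$cache,
                        dcv)
  list(conv = list(W = gc$dW, b = gc$db),
       lstm = list(fwd = gl$fwd, bwd = gl$bwd),
       head = list(W = gh$dW, b = gh$db))
}

#' Train the ES/ED timing detector
#'
#' Per-frame binary cross-entropy against 0/1 phase labels; one SGD step
#' per video with a cosine-decayed learning rate. Deterministic given the
#' config seed.
#'
#' @param samples list of training items; each either a
#'   `synthetic_sample` or a `list(video = <echo_video>, phases = <0/1>)`.
#' @param config a [timing_model_config()].
#' @return A `timing_model` with the training log (`$log`: per-epoch loss
#'   and frame accuracy) attached.
#' @export
train_timing_model <- function(samples, config = timing_model_config()) {
  if (length(samples) < 2)
    stop("train_timing_model: need at least 2 labeled videos")
  get_phases <- function(s) if (!is.null(s$phase_labels)) s$phase_labels else s$phases
  if (sum(vapply(samples, function(s) length(get_phases(s)), numeric(1))) == 0)
    stop("train_timing_model: no labeled frames")
  set.seed(derive_seed(config$seed, "timing_init"))
  arch <- list(conv = conv3d_arch(c(3, 3, 3), cin = 1,
                                  cout = config$conv_channels))
  params <- list(conv = conv3d_init(arch$conv),
                 lstm = bilstm_init(config$conv_channels, config$hidden),
                 head = dense_init(2 * config$hidden, 1))
  model <- structure(list(config = config, arch = arch, params = params),
                     class = "timing_model")
  Xs <- lapply(samples, function(s) timing_pooled_input(config, s$video))
  Ys <- lapply(samples, get_phases)
  state <- sgd_state(params)
  total <- config$epochs * length(samples)
  it <- 0
  log <- data.frame(epoch = integer(), loss = numeric(), acc = numeric())
  for (ep in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, sprintf("timing_ep%d", ep)))
    ord <- sample(length(samples))
    ep_loss <- 0; ep_hit <- 0; ep_n <- 0
    for (i in ord) {
      it <- it + 1
      fw <- timing_forward(model, Xs[[i]])
      y <- Ys[[i]]
      p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
      loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
      dlogit <- (fw$prob - y) / length(y)
      grads <- timing_backward(model, Xs[[i]], fw$cache, dlogit)
      lr <- cosine_lr(it, total, config$lr)
      up <- sgd_step(model$params, grads, state, lr,
                     momentum = config$momentum,
                     weight_decay = config$weight_decay)
      model$params <- up$p; state <- up$v
      ep_loss <- ep_loss + loss
      ep_hit <- ep_hit + sum((fw$prob >= config$threshold) == (y == 1))
      ep_n <- ep_n + length(y)
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / length(samples),
                                 acc = ep_hit / ep_n))
  }
  model$log <- log
  model
}

#' Predict per-frame systole/diastole phases
#'
#' @param model a trained `timing_model`.
#' @param video an [echo_video()] with at least the model's minimum
#'   frame count.
#' @return `list(phases = <0/1 vector>, probabilities = <diastole
#'   probabilities>)`, both of length `T`. A probability exactly at the
#'   threshold is called diastole.
#' @export
predict_frame_phases <- function(model, video) {
  if (n_frames(video) < model$config$min_frames)
    stop("predict_frame_phases: video has ", n_frames(video),
         " frames; the detector needs at least ", model$config$min_frames)
  fw <- timing_forward(model, timing_pooled_input(model$config, video))
  list(phases = as.integer(fw$prob >= model$config$threshold),
       probabilities = fw$prob)
}

#' Detect cycle timings of a video with a trained detector
#'
#' Convenience wrapper: [predict_frame_phases()] followed by
#' [extract_timings()].
#'
#' @inheritParams predict_frame_phases
#' @inheritParams extract_timings
#' @return As [extract_timings()].
#' @export
detect_timings <- function(model, video, min_run = 2,
                           drop_boundary_runs = TRUE) {
  ph <- predict_frame_phases(model, video)
  extract_timings(ph$phases, min_run = min_run,
                  drop_boundary_runs = drop_boundary_runs)
}
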