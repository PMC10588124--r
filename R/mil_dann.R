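# The pipeline's core: temporally correlated multiple-instance attention
# over snippet representations, a disease head, a domain-adversarial head
# behind a gradient-reversal node, and the two-video training procedure
# (every video is its own acquisition domain; the second, domain-only
# video may come from the test split — its class label is never consumed).

#' Training configuration for the MIL/DANN model
#'
#' Defaults follow the study regime: SGD with initial learning rate 1e-4
#' under cosine decay, weight decay 4e-5, dropout 0.5, label smoothing
#' 0.1, batch size one video, 100 epochs of 500 class-balanced draws.
#' Desk-scale experiments override the sizes and learning rate; the
#' structure of an iteration is unchanged.
#'
#' @param lr initial learning rate.
#' @param epochs training epochs.
#' @param iters_per_epoch class-balanced video draws per epoch.
#' @param momentum SGD momentum.
#' @param weight_decay L2 coefficient.
#' @param dropout dropout probability on the video representation before
#'   the disease head.
#' @param label_smoothing smoothing `eps` for [smoothed_targets()].
#' @param grl_lambda gradient-reversal strength (constant by default).
#' @param grl_ramp use the warm-up ramp `2/(1+exp(-10 p)) - 1` over
#'   training progress `p` instead of a constant lambda.
#' @param clip global gradient-norm clip; keeps the adversarial updates
#'   stable at batch size one (`Inf` disables).
#' @param augment_subbag with probability 1/2, forward a random
#'   one-snippet-smaller sub-bag instead of the full bag (both video A
#'   and video B). Creates within-video variability so the domain head
#'   must generalize instead of memorizing one point per video.
#' @param gate_lr_mult learning-rate multiplier for the scalar
#'   intensity-normalization gate (a single clamped parameter needs
#'   larger steps than the weight tensors).
#' @param gate_decay restoring pull of the gate toward 0 (raw
#'   features). Where the loss surface is flat in the gate, an
#'   amplified scalar would otherwise random-walk and can ratchet into
#'   the fully-normalized absorbing state; only a consistent
#'   adversarial gradient should hold the gate open.
#' @param dom_lr_mult learning-rate multiplier for the domain head. At
#'   one-video batches the discriminator must fit faster than the
#'   features drift, or it stays at chance and provides no adversarial
#'   signal.
#' @param cls_lr_mult learning-rate multiplier for the disease head, for
#'   the same reason: a linear head fed one sample per step needs to
#'   lock onto the class direction faster than the features move under
#'   it.
#' @param head_grad how the head-input standardization backpropagates
#'   into the features: `"straight_through"` (forward-only
#'   preconditioner; natural-scale feature updates, preferred for
#'   classification training) or `"exact"` (true chain rule with an
#'   absolute floor on the calibrated sd so the amplification is
#'   bounded; the amplified, exact adversarial gradient is what drives
#'   the intensity-normalization gate in domain-adversarial studies).
#' @param head_sd_floor absolute sd floor used by the `"exact"` mode.
#' @param dom_refit number of full-batch refit steps applied to the
#'   domain head each iteration on a cache of all bags' conditioned
#'   representations (refreshed periodically). The reversed gradient
#'   only points toward domain-information removal when the
#'   discriminator is near its best response; a head co-trained one
#'   sample at a time lags the features and the instantaneous gradient
#'   can point the wrong way. 0 disables.
#' @param dom_refit_refresh iterations between cache refreshes.
#' @param loss_weights length-3 weights for (classification, domain loss
#'   of video A, domain loss of video B).
#' @param n_classes number of disease classes (2).
#' @param seed RNG seed.
#' @return A `mil_train_config` list.
#' @export
mil_train_config <- function(lr = 1e-4, epochs = 100, iters_per_epoch = 500,
                             momentum = 0.9, weight_decay = 4e-5,
                             dropout = 0.5, label_smoothing = 0.1,
                             grl_lambda = 1, grl_ramp = FALSE,
                             loss_weights = c(1, 1, 1), clip = 5,
                             augment_subbag = FALSE, gate_lr_mult = 25,
                             gate_decay = 0.05, dom_lr_mult = 10,
                             cls_lr_mult = 10,
                             head_grad = c("straight_through", "exact"),
                             head_sd_floor = 0.1, dom_refit = 0,
                             dom_refit_refresh = 25, n_classes = 2,
                             seed = 1) {
  head_grad <- match.arg(head_grad)
  stopifnot(label_smoothing >= 0, label_smoothing < 1, grl_lambda >= 0,
            n_classes == 2, length(loss_weights) == 3, clip > 0)
  list(lr = lr, epochs = epochs, iters_per_epoch = iters_per_epoch,
       momentum = momentum, weight_decay = weight_decay, dropout = dropout,
       label_smoothing = label_smoothing, grl_lambda = grl_lambda,
       grl_ramp = grl_ramp, loss_weights = loss_weights, clip = clip,
       augment_subbag = augment_subbag, gate_lr_mult = gate_lr_mult,
       gate_decay = gate_decay, dom_lr_mult = dom_lr_mult,
       cls_lr_mult = cls_lr_mult, head_grad = head_grad,
       head_sd_floor = head_sd_floor, dom_refit = dom_refit,
       dom_refit_refresh = dom_refit_refresh, n_classes = n_classes,
       seed = seed)
}

#' Create an untrained video classification model
#'
#' @param backbone_cfg a [backbone_config()].
#' @param n_domains total number of domains `D` (= all videos in train
#'   and test).
#' @param attn_hidden hidden size per direction of the attention LSTM.
#' @param attn_type `"bilstm"` (temporally correlated attention, the
#'   default) or `"gated"` (classical permutation-invariant
#'   attention-MIL, kept as an ablation).
#' @param use_gate enable the adversarially gated input intensity
#'   normalization (off by default; intended for domain-adversarial
#'   configurations where acquisition gain is a nuisance to remove —
#'   when the gain level carries class information the gate would
#'   compete with the classification objective).
#' @param n_classes number of disease classes.
#' @param seed RNG seed for initialisation.
#' @return A `video_model`.
#' @export
video_model <- function(backbone_cfg = backbone_config(), n_domains,
                        attn_hidden = 8, attn_type = "bilstm",
                        use_gate = FALSE, n_classes = 2, seed = 1) {
  stopifnot(n_domains >= 1, attn_type %in% c("bilstm", "gated"))
  bb <- build_backbone(backbone_cfg)
  d <- backbone_cfg$feature_dim
  set.seed(derive_seed(seed, "video_model"))
  params <- list(backbone = bb$params)
  if (attn_type == "bilstm") {
    params$attn <- bilstm_init(d, attn_hidden)
    params$score <- dense_init(2 * attn_hidden, 1)
  } else {
    params$attn <- list(V = glorot(d, attn_hidden))
    params$score <- dense_init(attn_hidden, 1)
  }
  params$cls <- dense_init(d, n_classes)
  params$dom <- dense_init(d, n_domains)
  # Adversarially gated input intensity normalization:
  # alpha = clamp(gate, 0, 1) blends the raw clip (alpha = 0) with the
  # clip divided by its relative mean intensity (alpha = 1, exact gain
  # invariance). Acquisition gain is multiplicative, so no downstream
  # ReLU network can cancel it exactly; the gate gives the feature
  # extractor a realizable path to gain invariance that the reversed
  # domain gradient can select, while a detached domain head leaves the
  # gate near its raw start. Clamped-linear parametrization
  # (straight-through gradient): a scalar sigmoid saturates and freezes.
  params$gate <- c(a = if (use_gate) 0.02 else 0)
  structure(list(backbone = bb, params = params, attn_type = attn_type,
                 attn_hidden = attn_hidden, use_gate = isTRUE(use_gate),
                 n_classes = n_classes,
                 n_domains = as.integer(n_domains), seed = seed,
                 # head-input conditioning: global average pooling leaves
                 # the raw video representation dominated by a DC
                 # component, with across-video variance orders of
                 # magnitude smaller, so unconditioned linear heads learn
                 # far too slowly (the domain head then provides no
                 # adversarial signal at all). Both heads therefore read
                 # the per-dimension standardization (z - mu)/sd, with mu
                 # and sd calibrated once by train_mil() on the initial
                 # representations of all bags and frozen. The backward
                 # pass treats the standardization as a forward-only
                 # preconditioner (see video_backward).
                 head_stats = list(mu = rep(0, d), sd = rep(1, d))),
            class = "video_model")
}

## ---- attention ensemble ---------------------------------------------------

attention_forward <- function(model, H) {
  n <- nrow(H)
  st <- std_forward(H)
  if (model$attn_type == "bilstm") {
    bl <- bilstm_forward(model$params$attn, st$Y)
    s <- dense_forward(model$params$score, bl$H)
  } else {
    U <- tanh(st$Y %*% model$params$attn$V)
    s <- dense_forward(model$params$score, U)
    bl <- list(H = U)
  }
  s <- as.vector(s)
  e <- exp(s - max(s)); a <- e / sum(e)
  z <- as.vector(crossprod(H, a))
  list(z = z, a = a,
       cache = list(H = H, st = st, bl = bl, a = a, n = n))
}

# Backward of (z, a) wrt dz (and optionally da); returns dH plus grads of
# the attention parameters.
attention_backward <- function(model, cache, dz, da_extra = NULL) {
  H <- cache$H; a <- cache$a; n <- cache$n
  dH <- a %o% dz                      # z = sum_k a_k h_k
  da <- as.vector(H %*% dz)
  if (!is.null(da_extra)) da <- da + da_extra
  ds <- a * (da - sum(a * da))        # softmax backward
  dsm <- matrix(ds, ncol = 1)
  if (model$attn_type == "bilstm") {
    gs <- dense_backward(model$params$score, cache$bl$H, dsm)
    gl <- bilstm_backward(model$params$attn, cache$bl$cache, gs$dX)
    dY <- gl$dX
    attn_grads <- list(fwd = gl$fwd, bwd = gl$bwd)
  } else {
    gs <- dense_backward(model$params$score, cache$bl$H, dsm)
    dU <- gs$dX * (1 - cache$bl$H^2)
    attn_grads <- list(V = crossprod(cache$st$Y, dU))
    dY <- tcrossprod(dU, model$params$attn$V)
  }
  dH <- dH + std_backward(cache$st$cache, dY)
  list(dH = dH, attn = attn_grads, score = list(W = gs$dW, b = gs$db))
}

#' Attention ensemble over ordered snippet representations
#'
#' A bidirectional LSTM pass over the ordered (standardized)
#' representations yields one score per snippet; a softmax over scores
#' gives non-negative weights summing to one, and the video
#' representation is the attention-weighted sum `z = sum_k a_k h_k` of
#' the raw representations. With a single snippet the weight is exactly 1
#' and `z = h_1`.
#'
#' @param model a [video_model()].
#' @param reps `n x d` matrix of ordered snippet representations.
#' @return `list(z = <d-vector>, weights = <n-vector on the simplex>)`.
#' @export
attention_ensemble <- function(model, reps) {
  stopifnot(is.matrix(reps), nrow(reps) >= 1)
  fw <- attention_forward(model, reps)
  list(z = fw$z, weights = fw$a)
}

## ---- full forward / classify ----------------------------------------------

.gate_ref <- 0.25  # reference mean intensity; the scale alpha=1 divides by

video_forward <- function(model, bag, dropout = 0, lambda = 1) {
  n <- length(bag$snippets)
  if (n < 1) stop("video_forward: empty bag")
  feats <- vector("list", n)
  H <- matrix(0, n, model$backbone$config$feature_dim)
  r <- numeric(n)
  alpha <- if (isTRUE(model$use_gate))
    min(max(model$params$gate[["a"]], 0), 1) else 0
  dgate <- numeric(n)
  for (k in seq_len(n)) {
    Xp <- backbone_prepare_clip(model$backbone,
                                bag$snippets[[k]]$frames)
    r[k] <- max(mean(Xp), 1e-2) / .gate_ref
    dgate[k] <- 1 - alpha + alpha * r[k]
    bb <- model$backbone
    bb$params <- model$params$backbone
    feats[[k]] <- backbone_forward(bb, Xp / dgate[k])
    H[k, ] <- feats[[k]]$h
  }
  at <- attention_forward(model, H)
  z <- at$z
  # saturating bound: near-linear over the calibrated range, capped
  # beyond it so the reversed gradient cannot inflate the domain loss
  # by running the representation off to infinity. The exact-gradient
  # mode is already damped by the sd floor, so its bound is loose.
  tau <- if (identical(model$head_grad, "exact")) 20 else 3
  zs <- tau * tanh((z - model$head_stats$mu) / model$head_stats$sd / tau)
  if (dropout > 0) {
    mask <- (stats::runif(length(zs)) >= dropout) / (1 - dropout)
  } else mask <- rep(1, length(zs))
  zd <- zs * mask
  cls_logits <- as.vector(dense_forward(model$params$cls,
                                        matrix(zd, 1)))
  # domain head sits behind the gradient-reversal node (forward identity)
  zg <- grl_forward(zs, lambda)
  dom_logits <- as.vector(dense_forward(model$params$dom, matrix(zg, 1)))
  list(H = H, r = r, dgate = dgate, alpha = alpha, at = at,
       z = z, mask = mask, zd = zd, zs = zs,
       cls_logits = cls_logits, dom_logits = dom_logits, feats = feats)
}

# Backpropagate classification and/or domain losses through the whole
# graph; either dcls or ddom may be NULL. Returns a gradient tree
# congruent with model$params.
video_backward <- function(model, bag, fw, dcls = NULL, ddom = NULL,
                           lambda = 1) {
  d <- length(fw$z)
  dzs <- rep(0, d)
  grads <- list()
  if (!is.null(dcls)) {
    g <- dense_backward(model$params$cls, matrix(fw$zd, 1),
                        matrix(dcls, 1))
    grads$cls <- list(W = g$dW, b = g$db)
    dzs <- dzs + as.vector(g$dX) * fw$mask
  }
  if (!is.null(ddom)) {
    g <- dense_backward(model$params$dom, matrix(fw$zs, 1),
                        matrix(ddom, 1))
    grads$dom <- list(W = g$dW, b = g$db)
    dzs <- dzs + grl_backward(as.vector(g$dX), lambda)
  }
  # Backward through the head standardization: the tanh factor always
  # applies; "straight_through" skips the division by the tiny
  # calibrated sd (the exact chain rule would amplify the feature-path
  # gradient by orders of magnitude, and features would then move so
  # fast per step that the heads chase a permanently whirling
  # representation), while "exact" divides by the floor-bounded sd —
  # the amplified adversarial gradient is what reaches the
  # normalization gate in domain-adversarial training.
  tau <- if (identical(model$head_grad, "exact")) 20 else 3
  dz <- dzs * (1 - (fw$zs / tau)^2)
  if (identical(model$head_grad, "exact"))
    dz <- dz / model$head_stats$sd
  ab <- attention_backward(model, fw$at$cache, dz)
  grads$attn <- ab$attn
  grads$score <- ab$score
  # input gate: backbone input is Xg = Xp / d_k, d_k = 1 - alpha(1 - r_k)
  bb <- model$backbone
  bb$params <- model$params$backbone
  gB <- NULL
  da <- 0
  for (k in seq_len(nrow(ab$dH))) {
    gk <- backbone_backward(bb, fw$feats[[k]]$cache, ab$dH[k, ])
    if (isTRUE(model$use_gate)) {
      # dL/dd_k = -sum(dXg * Xg)/d_k; dd_k/d(alpha) = r_k - 1;
      # straight-through d(alpha)/d(a) = 1
      Xg <- fw$feats[[k]]$cache$Xp
      da <- da - sum(gk$dX * Xg) / fw$dgate[k] * (fw$r[k] - 1)
    }
    gB <- grad_add(gB, gk[setdiff(names(gk), "dX")])
  }
  grads$gate <- c(a = da)
  grads$backbone <- gB
  grads
}

#' Classify a video from its snippet bag
#'
#' Runs feature extraction, the attention ensemble, the disease head and
#' (through gradient reversal, identity at inference) the domain head.
#'
#' @param model a trained or initialized [video_model()].
#' @param bag a `snippet_bag`.
#' @return A prediction record: `video_id`, `subject_id`, `class_scores`
#'   (last-layer outputs), `class_probabilities` (softmax),
#'   `domain_scores`, `attention` (simplex weights), `class_label`.
#' @export
classify_video <- function(model, bag) {
  fw <- video_forward(model, bag, dropout = 0)
  list(video_id = bag$video_id, subject_id = bag$subject_id,
       class_scores = fw$cls_logits,
       class_probabilities = softmax(fw$cls_logits),
       domain_scores = fw$dom_logits,
       attention = fw$at$a, class_label = bag$class_label)
}

## ---- training -------------------------------------------------------------

class_index <- function(label) match(label, c("N", "HTCM"))

#' Train the MIL/DANN model
#'
#' Per iteration, a training video A — drawn by a class-balanced sampler
#' (equal numbers of healthy and hypertensive draws per epoch,
#' oversampling the minority class with replacement) — contributes the
#' classification loss (cross-entropy against label-smoothed targets)
#' plus its domain loss; a second video B, drawn uniformly from all
#' videos including the test split, contributes its domain loss only (its
#' class label is never consumed). The total loss is
#' `w1*L_cls + w2*L_domA + w3*L_domB`, one SGD step per iteration with a
#' cosine-decayed learning rate. Deterministic given the config seed.
#'
#' @param model a [video_model()] whose `n_domains` covers every video.
#' @param train_bags list of `snippet_bag`s with class labels (subset of
#'   `all_bags`).
#' @param all_bags list of every bag in train and test (domain pool).
#' @param config a [mil_train_config()].
#' @return The trained model, with `$log` (per-iteration losses and
#'   learning rate) and `$epoch_counts` (per-epoch sampled class counts)
#'   attached.
#' @export
train_mil <- function(model, train_bags, all_bags,
                      config = mil_train_config()) {
  D <- model$n_domains
  doms <- vapply(all_bags, function(b) b$domain_id, numeric(1))
  if (any(doms >= D) || anyDuplicated(doms))
    stop("train_mil: every video needs a unique domain_id < n_domains")
  cls <- vapply(train_bags, function(b) class_index(b$class_label),
                numeric(1))
  if (any(is.na(cls))) stop("train_mil: training bag without class label")
  idx_n <- which(cls == 1); idx_h <- which(cls == 2)
  if (length(idx_n) == 0 || length(idx_h) == 0)
    stop("train_mil: both classes are required for balanced sampling")

  # one-off head-input calibration on the initial representations of
  # every bag (class labels are not consumed)
  Z <- t(vapply(all_bags, function(b)
    video_forward(model, b, dropout = 0)$z,
    numeric(model$backbone$config$feature_dim)))
  mu <- colMeans(Z)
  sdz <- apply(Z, 2, stats::sd)
  model$head_grad <- config$head_grad
  model$head_stats <- if (identical(config$head_grad, "exact")) {
    list(mu = mu, sd = sqrt(sdz^2 + config$head_sd_floor^2))
  } else {
    list(mu = mu, sd = pmax(sdz, 0.05 * sqrt(mean(sdz^2)), 1e-9))
  }

  total <- config$epochs * config$iters_per_epoch
  state <- sgd_state(model$params)
  .zs_cache <- NULL; .ydom <- NULL
  log <- vector("list", total)
  epoch_counts <- data.frame(epoch = integer(), n_N = integer(),
                             n_HTCM = integer())
  it <- 0
  for (ep in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, sprintf("mil_ep%d", ep)))
    half <- config$iters_per_epoch %/% 2
    pool <- c(idx_n[sample.int(length(idx_n), half, replace = TRUE)],
              idx_h[sample.int(length(idx_h),
                               config$iters_per_epoch - half,
                               replace = TRUE)])
    pool <- pool[sample.int(length(pool))]
    bsel <- sample(length(all_bags), config$iters_per_epoch, replace = TRUE)
    epoch_counts <- rbind(epoch_counts, data.frame(
      epoch = ep, n_N = sum(cls[pool] == 1), n_HTCM = sum(cls[pool] == 2)))
    for (j in seq_len(config$iters_per_epoch)) {
      it <- it + 1
      if (config$dom_refit > 0) {
        if (it %% config$dom_refit_refresh == 1 || is.null(.zs_cache)) {
          .zs_cache <- t(vapply(all_bags, function(b)
            video_forward(model, b, dropout = 0)$zs,
            numeric(length(model$head_stats$mu))))
          .ydom <- diag(D)[vapply(all_bags, function(b) b$domain_id,
                                  numeric(1)) + 1, , drop = FALSE]
        }
        for (k in seq_len(config$dom_refit)) {
          S <- .zs_cache %*% model$params$dom$W
          S <- S + rep(model$params$dom$b, each = nrow(S))
          S <- S - apply(S, 1, max)
          P <- exp(S); P <- P / rowSums(P)
          model$params$dom$W <- model$params$dom$W -
            0.5 * crossprod(.zs_cache, P - .ydom) / nrow(.zs_cache)
          model$params$dom$b <- model$params$dom$b -
            0.5 * colSums(P - .ydom) / nrow(.zs_cache)
        }
      }
      lam <- config$grl_lambda
      if (config$grl_ramp)
        lam <- config$grl_lambda * (2 / (1 + exp(-10 * it / total)) - 1)
      A <- train_bags[[pool[j]]]
      B <- all_bags[[bsel[j]]]
      if (isTRUE(config$augment_subbag)) {
        sub <- function(b) {
          n <- length(b$snippets)
          if (n > 1 && stats::runif(1) < 0.5)
            b$snippets <- b$snippets[-sample.int(n, 1)]
          b
        }
        A <- sub(A); B <- sub(B)
      }

      w <- config$loss_weights
      fwA <- video_forward(model, A, dropout = config$dropout, lambda = lam)
      tgt <- smoothed_targets(class_index(A$class_label),
                              model$n_classes, config$label_smoothing)
      lc <- ce_loss(fwA$cls_logits, tgt)
      domA <- smoothed_targets(A$domain_id + 1L, D, 0)
      ldA <- ce_loss(fwA$dom_logits, domA)
      gA <- video_backward(model, A, fwA,
                           dcls = w[1] * lc$dlogits,
                           ddom = if (w[2] > 0) w[2] * ldA$dlogits,
                           lambda = lam)

      if (w[3] > 0) {
        fwB <- video_forward(model, B, dropout = 0, lambda = lam)
        domB <- smoothed_targets(B$domain_id + 1L, D, 0)
        ldB <- ce_loss(fwB$dom_logits, domB)
        gB <- video_backward(model, B, fwB, dcls = NULL,
                             ddom = w[3] * ldB$dlogits, lambda = lam)
      } else {
        ldB <- list(loss = NA_real_)
        gB <- NULL
      }

      grads <- grad_add(gA, gB)
      if (isTRUE(model$use_gate)) {
        grads$gate <- grads$gate * config$gate_lr_mult +
          config$gate_decay * model$params$gate
      } else grads$gate <- c(a = 0)
      if (!is.null(grads$dom) && !is.null(config$dom_lr_mult) &&
          config$dom_lr_mult != 1)
        grads$dom <- rapply(grads$dom, function(x) x * config$dom_lr_mult,
                            how = "replace")
      if (!is.null(grads$cls) && !is.null(config$cls_lr_mult) &&
          config$cls_lr_mult != 1)
        grads$cls <- rapply(grads$cls, function(x) x * config$cls_lr_mult,
                            how = "replace")
      if (is.finite(config$clip)) {
        # per-group clipping: a single global norm would let the
        # (conditioned, hence amplified) feature-path gradient crush the
        # head gradients to nothing whenever it dominates the norm
        for (nm in names(grads)) {
          gn <- sqrt(sum(unlist(rapply(grads[nm], function(x) sum(x^2),
                                       how = "list"))))
          if (gn > config$clip)
            grads[[nm]] <- rapply(grads[nm], function(x)
              x * (config$clip / gn), how = "replace")[[nm]]
        }
      }
      lr <- cosine_lr(it, total, config$lr)
      up <- sgd_step(model$params, grads, state, lr,
                     momentum = config$momentum,
                     weight_decay = config$weight_decay)
      model$params <- up$p; state <- up$v
      if (isTRUE(model$use_gate)) {
        # projected step: before the domain head carries signal the
        # reversed gradient is noise and can drive the gate far outside
        # its effective range, from where it cannot recover in budget
        model$params$gate[["a"]] <-
          min(max(model$params$gate[["a"]], -0.2), 1.2)
      }
      log[[it]] <- c(iter = it, loss_cls = lc$loss, loss_domA = ldA$loss,
                     loss_domB = ldB$loss, lr = lr)
    }
  }
  model$log <- as.data.frame(do.call(rbind, log))
  model$epoch_counts <- epoch_counts
  model
}

## ---- domain probe ---------------------------------------------------------

#' Linear domain probe on frozen representations
#'
#' Softmax regression (full-batch gradient descent, deterministic)
#' trained to predict the domain identity from frozen video
#' representations; top-1 accuracy on the held-out rows measures how much
#' domain information the representation still carries.
#'
#' @param X `n x d` matrix of frozen representations.
#' @param domains integer domain ids (0-based), length `n`.
#' @param train_idx,test_idx row indices for probe fitting / evaluation.
#' @param iters gradient-descent iterations.
#' @param lr learning rate.
#' @return Top-1 accuracy on `test_idx`.
#' @export
domain_probe <- function(X, domains, train_idx, test_idx, iters = 300,
                         lr = 0.5) {
  Xs <- scale(X)
  Xs[!is.finite(Xs)] <- 0
  D <- max(domains) + 1L
  Y <- matrix(0, length(domains), D)
  Y[cbind(seq_along(domains), domains + 1L)] <- 1
  Xtr <- cbind(1, Xs[train_idx, , drop = FALSE])
  Ytr <- Y[train_idx, , drop = FALSE]
  W <- matrix(0, ncol(Xtr), D)
  for (i in seq_len(iters)) {
    S <- Xtr %*% W
    S <- S - apply(S, 1, max)
    P <- exp(S); P <- P / rowSums(P)
    G <- crossprod(Xtr, P - Ytr) / nrow(Xtr)
    W <- W - lr * G
  }
  Xte <- cbind(1, Xs[test_idx, , drop = FALSE])
  pred <- max.col(Xte %*% W, ties.method = "first") - 1L
  mean(pred == domains[test_idx])
}

#' Video representations from snippet sub-bags
#'
#' For probing, each video yields several representations computed from
#' random snippet subsets (the full bag plus jittered sub-bags), all
#' sharing the video's domain id.
#'
#' @param model a trained [video_model()].
#' @param bags list of `snippet_bag`s.
#' @param reps_per_bag representations per video.
#' @param seed RNG seed for the subset draws.
#' @param jitter_sd Gaussian intensity jitter added to the clips of each
#'   drawn representation. Jitter gives the probe within-domain
#'   variability so its accuracy measures generalizable domain
#'   information, not memorization of one deterministic point per video.
#' @param subsample also vary the snippet subset (random
#'   one-snippet-smaller sub-bags after the first draw). Leave `FALSE`
#'   when representations feed a probe split into fit/held-out halves:
#'   the small number of distinct subsets would recur across the split
#'   and let the probe memorize them.
#' @param space `"conditioned"` (default) returns the standardized,
#'   bounded representation both heads consume; `"raw"` returns the
#'   attention-weighted feature vector before conditioning.
#' @return `list(X = <matrix>, domains = <0-based ids>, video =
#'   <bag index per row>)`.
#' @export
subbag_representations <- function(model, bags, reps_per_bag = 4, seed = 1,
                                   jitter_sd = 0, subsample = FALSE,
                                   space = c("conditioned", "raw")) {
  space <- match.arg(space)
  set.seed(derive_seed(seed, "subbag"))
  X <- list(); dom <- integer(); vid <- integer()
  for (i in seq_along(bags)) {
    b <- bags[[i]]
    n <- length(b$snippets)
    for (r in seq_len(reps_per_bag)) {
      keep <- if (!subsample || n == 1 || r == 1) seq_len(n)
              else sort(sample(n, max(1, n - 1)))
      sb <- b; sb$snippets <- b$snippets[keep]
      if (jitter_sd > 0) {
        sb$snippets <- lapply(sb$snippets, function(s) {
          s$frames <- s$frames +
            array(stats::rnorm(length(s$frames), 0, jitter_sd),
                  dim(s$frames))
          s
        })
      }
      fw <- video_forward(model, sb, dropout = 0)
      X[[length(X) + 1]] <- if (space == "raw") fw$z else fw$zs
      dom <- c(dom, b$domain_id)
      vid <- c(vid, i)
    }
  }
  list(X = do.call(rbind, X), domains = dom, video = vid)
}
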