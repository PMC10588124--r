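# Minimal neural-network primitives used by the timing detector, the 3D
# backbone, the attention ensemble and the baselines. All layers come in
# (arch, params) pairs: `arch` is static metadata (kernel sizes, cached
# gather indices), `params` is a nested list of plain numeric arrays so a
# single recursive SGD walker can update any model. Backward passes are
# analytic and are verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a module seed from a global seed
#'
#' One global seed drives every stage; per-module seeds are derived
#' deterministically from it so each stage is independently reproducible.
#'
#' @param seed integer global seed.
#' @param name character scope name (e.g. "synth", "train").
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 1000003
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}

## ---- initialisation -------------------------------------------------------

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

## ---- 3D convolution (im2col) ----------------------------------------------

# `kernel` = c(kh, kw, kt); stride 1, zero "same" padding (odd kernels).
conv3d_arch <- function(kernel, cin, cout) {
  stopifnot(all(kernel %% 2 == 1))
  list(type = "conv3d", kernel = kernel, cin = cin, cout = cout,
       env = new.env(parent = emptyenv()))
}

conv3d_init <- function(arch) {
  K <- prod(arch$kernel) * arch$cin
  list(W = glorot(K, arch$cout), b = rep(0, arch$cout))
}

# Cache the im2col gather-index matrix per input geometry.
conv3d_index <- function(arch, d) {
  key <- paste(d, collapse = "x")
  if (!is.null(arch$env[[key]])) return(arch$env[[key]])
  H <- d[1]; W <- d[2]; Tt <- d[3]; C <- arch$cin
  k <- arch$kernel; ph <- k[1] %/% 2; pw <- k[2] %/% 2; pt <- k[3] %/% 2
  Hp <- H + 2 * ph; Wp <- W + 2 * pw; Tp <- Tt + 2 * pt
  i <- rep(seq_len(H), times = W * Tt)
  j <- rep(rep(seq_len(W), each = H), times = Tt)
  tt <- rep(seq_len(Tt), each = H * W)
  pos0 <- i + Hp * (j - 1) + Hp * Wp * (tt - 1)
  di <- rep(seq_len(k[1]) - 1L, times = k[2] * k[3] * C)
  dj <- rep(rep(seq_len(k[2]) - 1L, each = k[1]), times = k[3] * C)
  dt <- rep(rep(seq_len(k[3]) - 1L, each = k[1] * k[2]), times = C)
  cc <- rep(seq_len(C) - 1L, each = prod(k))
  offs <- di + Hp * dj + Hp * Wp * dt + Hp * Wp * Tp * cc
  idx <- outer(pos0, offs, "+")
  info <- list(idx = idx, pad = c(ph, pw, pt), pdim = c(Hp, Wp, Tp, C),
               dim = c(H, W, Tt, C))
  arch$env[[key]] <- info
  info
}

# X: array (H, W, T, C) -> list(out = (H, W, T, cout), cache)
conv3d_forward <- function(arch, params, X) {
  d <- dim(X)
  info <- conv3d_index(arch, d[1:3])
  Xp <- array(0, info$pdim)
  Xp[info$pad[1] + seq_len(d[1]), info$pad[2] + seq_len(d[2]),
     info$pad[3] + seq_len(d[3]), ] <- X
  Xcol <- matrix(Xp[info$idx], nrow(info$idx), ncol(info$idx))
  Y <- Xcol %*% params$W
  Y <- Y + rep(params$b, each = nrow(Y))
  list(out = array(Y, c(d[1:3], arch$cout)),
       cache = list(Xcol = Xcol, info = info))
}

conv3d_backward <- function(arch, params, cache, dY) {
  info <- cache$info
  P <- nrow(info$idx)
  dYm <- matrix(dY, P, arch$cout)
  dW <- crossprod(cache$Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- tcrossprod(dYm, params$W)
  dXp <- numeric(prod(info$pdim))
  for (k in seq_len(ncol(info$idx)))
    dXp[info$idx[, k]] <- dXp[info$idx[, k]] + dXcol[, k]
  dXp <- array(dXp, info$pdim)
  d <- info$dim
  dX <- dXp[info$pad[1] + seq_len(d[1]), info$pad[2] + seq_len(d[2]),
            info$pad[3] + seq_len(d[3]), , drop = FALSE]
  list(dX = array(dX, d), dW = dW, db = db)
}

## ---- average pooling ------------------------------------------------------

pool_axis <- function(X, axis, f) {
  if (f == 1) return(X)
  d <- dim(X)
  stopifnot(d[axis] %% f == 0)
  perm <- c(axis, setdiff(seq_along(d), axis))
  Xp <- aperm(X, perm)
  m <- colMeans(matrix(Xp, nrow = f))
  d2 <- d[perm]; d2[1] <- d2[1] %/% f
  aperm(array(m, d2), order(perm))
}

unpool_axis <- function(dY, axis, f) {
  if (f == 1) return(dY)
  d <- dim(dY)
  perm <- c(axis, setdiff(seq_along(d), axis))
  dYp <- aperm(dY, perm)
  v <- rep(as.vector(dYp), each = f) / f
  d2 <- d[perm]; d2[1] <- d2[1] * f
  aperm(array(v, d2), order(perm))
}

# Non-overlapping average pooling over the first three axes of (H, W, T, C).
pool3d <- function(X, f) {
  for (ax in 1:3) X <- pool_axis(X, ax, f[ax])
  X
}

unpool3d <- function(dY, f) {
  for (ax in 3:1) dY <- unpool_axis(dY, ax, f[ax])
  dY
}

## ---- dense / activations / losses -----------------------------------------

dense_init <- function(nin, nout) list(W = glorot(nin, nout), b = rep(0, nout))

dense_forward <- function(params, X) {
  Y <- X %*% params$W
  Y + rep(params$b, each = nrow(Y))
}

dense_backward <- function(params, X, dY) {
  list(dX = tcrossprod(dY, params$W), dW = crossprod(X, dY), db = colSums(dY))
}

relu <- function(x) x * (x > 0)
relu_backward <- function(x, dy) dy * (x > 0)

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Cross-entropy of a logit vector against a target distribution.
ce_loss <- function(logits, target) {
  p <- softmax(logits)
  lse <- max(logits) + log(sum(exp(logits - max(logits))))
  list(loss = -sum(target * (logits - lse)), dlogits = p - target, prob = p)
}

#' Label-smoothed classification targets
#'
#' The hard label is mixed with the uniform distribution: the true class
#' receives `1 - eps + eps/K` and every other class `eps/K`, so the target
#' always sums to one.
#'
#' @param label integer true class index in `1..K`.
#' @param K number of classes.
#' @param eps smoothing strength in `[0, 1)`.
#' @return Numeric length-`K` target distribution.
#' @examples
#' smoothed_targets(2, K = 2, eps = 0.1)  # c(0.05, 0.95)
#' @export
smoothed_targets <- function(label, K, eps) {
  stopifnot(eps >= 0, eps < 1, label >= 1, label <= K)
  t <- rep(eps / K, K)
  t[label] <- t[label] + 1 - eps
  t
}

#' Cosine-decay learning-rate schedule
#'
#' Decays from `lr0` at the first iteration to 0 at the last.
#'
#' @param iter current iteration, 1-based.
#' @param total total number of iterations.
#' @param lr0 initial learning rate.
#' @return The learning rate for `iter`.
#' @export
cosine_lr <- function(iter, total, lr0) {
  if (total <= 1) return(lr0)
  lr0 * 0.5 * (1 + cos(pi * (iter - 1) / (total - 1)))
}

## ---- gradient reversal ----------------------------------------------------

#' Gradient-reversal node
#'
#' The building block of domain-adversarial training: the forward pass is
#' the identity, while during backpropagation the upstream gradient is
#' multiplied by `-lambda`. The domain head is trained to discriminate
#' domains while the features feeding it are pushed to confuse them.
#'
#' @param x input (any numeric array); returned unchanged by
#'   `grl_forward`.
#' @param grad gradient arriving from downstream of the node.
#' @param lambda non-negative reversal strength; 0 detaches the domain
#'   loss from the features.
#' @return `grl_forward`: `x` unchanged. `grl_backward`: `-lambda * grad`.
#' @export
grl_forward <- function(x, lambda) {
  stopifnot(lambda >= 0)
  x
}

#' @rdname grl_forward
#' @export
grl_backward <- function(grad, lambda) {
  stopifnot(lambda >= 0)
  -lambda * grad
}

## ---- LSTM -----------------------------------------------------------------

# Gate order along the 4h axis: input, forget, output, candidate.
lstm_init <- function(d, h) {
  p <- list(W = glorot(d, 4 * h), U = glorot(h, 4 * h), b = rep(0, 4 * h))
  p$b[h + seq_len(h)] <- 1  # forget-gate bias
  p
}

lstm_forward <- function(params, X, reverse = FALSE) {
  Tt <- nrow(X); h <- ncol(params$U) %/% 4
  if (reverse) X <- X[Tt:1, , drop = FALSE]
  XW <- X %*% params$W
  I <- Fg <- O <- G <- Cs <- Hs <- Tc <- matrix(0, Tt, h)
  hp <- rep(0, h); cp <- rep(0, h)
  i1 <- seq_len(h); i2 <- h + i1; i3 <- 2 * h + i1; i4 <- 3 * h + i1
  for (t in seq_len(Tt)) {
    a <- XW[t, ] + as.vector(hp %*% params$U) + params$b
    i <- sigmoid(a[i1]); f <- sigmoid(a[i2]); o <- sigmoid(a[i3]); g <- tanh(a[i4])
    cp <- f * cp + i * g
    tc <- tanh(cp)
    hp <- o * tc
    I[t, ] <- i; Fg[t, ] <- f; O[t, ] <- o; G[t, ] <- g
    Cs[t, ] <- cp; Tc[t, ] <- tc; Hs[t, ] <- hp
  }
  Hout <- if (reverse) Hs[Tt:1, , drop = FALSE] else Hs
  list(H = Hout,
       cache = list(X = X, I = I, Fg = Fg, O = O, G = G, Cs = Cs, Tc = Tc,
                    Hs = Hs, reverse = reverse))
}

lstm_backward <- function(params, cache, dH) {
  Tt <- nrow(dH); h <- ncol(dH)
  if (cache$reverse) dH <- dH[Tt:1, , drop = FALSE]
  dW <- params$W * 0; dU <- params$U * 0; db <- params$b * 0
  dX <- matrix(0, Tt, nrow(params$W))
  dh_next <- rep(0, h); dc_next <- rep(0, h)
  for (t in Tt:1) {
    dh <- dH[t, ] + dh_next
    o <- cache$O[t, ]; tc <- cache$Tc[t, ]
    i <- cache$I[t, ]; f <- cache$Fg[t, ]; g <- cache$G[t, ]
    cprev <- if (t > 1) cache$Cs[t - 1, ] else rep(0, h)
    hprev <- if (t > 1) cache$Hs[t - 1, ] else rep(0, h)
    do <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    di <- dc * g; df <- dc * cprev; dg <- dc * i
    da <- c(di * i * (1 - i), df * f * (1 - f), do * o * (1 - o),
            dg * (1 - g^2))
    dX[t, ] <- da %*% t(params$W)
    dW <- dW + outer(cache$X[t, ], da)
    dU <- dU + outer(hprev, da)
    db <- db + da
    dh_next <- as.vector(da %*% t(params$U))
    dc_next <- dc * f
  }
  if (cache$reverse) dX <- dX[Tt:1, , drop = FALSE]
  list(dX = dX, dW = dW, dU = dU, db = db)
}

bilstm_init <- function(d, h) list(fwd = lstm_init(d, h), bwd = lstm_init(d, h))

bilstm_forward <- function(params, X) {
  f <- lstm_forward(params$fwd, X, reverse = FALSE)
  b <- lstm_forward(params$bwd, X, reverse = TRUE)
  list(H = cbind(f$H, b$H), cache = list(f = f$cache, b = b$cache))
}

bilstm_backward <- function(params, cache, dH) {
  h <- ncol(dH) %/% 2
  gf <- lstm_backward(params$fwd, cache$f, dH[, seq_len(h), drop = FALSE])
  gb <- lstm_backward(params$bwd, cache$b, dH[, h + seq_len(h), drop = FALSE])
  list(dX = gf$dX + gb$dX,
       fwd = list(W = gf$dW, U = gf$dU, b = gf$db),
       bwd = list(W = gb$dW, U = gb$dU, b = gb$db))
}

## ---- per-column standardization (sequence feature conditioning) -----------

# Standardize each column of a T x C feature matrix to zero mean and unit
# variance (population variance, eps inside the sqrt). Keeps sequence
# features O(1) regardless of raw signal amplitude.
std_forward <- function(X, eps = 1e-6) {
  mu <- colMeans(X)
  v <- colMeans(X^2) - mu^2
  s <- sqrt(v + eps)
  Y <- sweep(sweep(X, 2, mu), 2, s, "/")
  list(Y = Y, cache = list(Y = Y, s = s))
}

std_backward <- function(cache, dY) {
  Y <- cache$Y
  m1 <- colMeans(dY)
  m2 <- colMeans(dY * Y)
  sweep(dY - rep(m1, each = nrow(dY)) - Y * rep(m2, each = nrow(Y)),
        2, cache$s, "/")
}

## ---- SGD with momentum, weight decay, recursive over param trees ----------

sgd_state <- function(params) rapply(params, function(x) x * 0, how = "replace")

sgd_step <- function(params, grads, state, lr, momentum = 0.9,
                     weight_decay = 0) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_v[[nm]] <- r$v
      }
      list(p = out_p, v = out_v)
    } else {
      if (is.null(g)) g <- p * 0
      g <- g + weight_decay * p
      v <- momentum * v + g
      list(p = p - lr * v, v = v)
    }
  }
  walk(params, grads, state)
}

# Elementwise sum of two congruent gradient trees.
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grad_add(a[[nm]], b[[nm]])
    a
  } else a + b
}
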