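# Snippet feature extraction: a pluggable 3D spatiotemporal ConvNet
# registry. `tiny3d` is a compact backbone that trains end-to-end on CPU;
# it exists so the pipeline's logic is exercisable without pretrained
# weights or a GPU, and is part of the trained graph (gradients flow
# through it into the full model).

#' Backbone configuration
#'
#' @param name registered backbone name (`"tiny3d"`; `"i3d_nonlocal"` is
#'   reserved for an externally supplied pretrained feature extractor).
#' @param input_size spatial side length clips are reduced to before the
#'   first convolution stage (>= 32 for clinical imagery; the phantom
#'   studies use 64).
#' @param feature_dim representation dimensionality `d` (>= 8).
#' @param pretrained logical; only meaningful for weight-file backbones.
#' @param weights_file optional path to pretrained weights (never
#'   downloaded).
#' @param seed RNG seed for initialisation.
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(name = "tiny3d", input_size = 64,
                            feature_dim = 16, pretrained = FALSE,
                            weights_file = NULL, seed = 1) {
  stopifnot(input_size >= 32, feature_dim >= 8)
  list(name = name, input_size = input_size, feature_dim = feature_dim,
       pretrained = pretrained, weights_file = weights_file, seed = seed)
}

.backbone_registry <- new.env(parent = emptyenv())

#' Register a backbone builder
#'
#' @param name registry key.
#' @param builder `function(config) -> backbone` returning an object with
#'   the tiny3d backbone's forward/backward contract.
#' @return Invisibly, `name`.
#' @export
register_backbone <- function(name, builder) {
  assign(name, builder, envir = .backbone_registry)
  invisible(name)
}

#' Build a backbone from its configuration
#' @param config a [backbone_config()].
#' @return A backbone object.
#' @export
build_backbone <- function(config) {
  if (!exists(config$name, envir = .backbone_registry))
    stop("build_backbone: unknown backbone '", config$name, "'")
  get(config$name, envir = .backbone_registry)(config)
}

# tiny3d: pre-pool to 16x16, three conv(3,3,3)+ReLU blocks with
# average pooling, global average pooling to a d-vector.
tiny3d_build <- function(config) {
  set.seed(derive_seed(config$seed, "tiny3d"))
  d <- config$feature_dim
  arch <- list(conv1 = conv3d_arch(c(3, 3, 3), 1, 8),
               conv2 = conv3d_arch(c(3, 3, 3), 8, 16),
               conv3 = conv3d_arch(c(3, 3, 3), 16, d))
  params <- list(conv1 = conv3d_init(arch$conv1),
                 conv2 = conv3d_init(arch$conv2),
                 conv3 = conv3d_init(arch$conv3))
  structure(list(config = config, arch = arch, params = params,
                 grid = 16L),
            class = c("tiny3d", "echo_backbone"))
}

register_backbone("tiny3d", tiny3d_build)
register_backbone("i3d_nonlocal", function(config) {
  if (is.null(config$weights_file) || !file.exists(config$weights_file))
    stop("i3d_nonlocal requires a pretrained weights file ",
         "(pretraining is consumed, never reproduced); none was supplied")
  stop("i3d_nonlocal weight loading is not bundled; register a builder ",
       "with register_backbone() to plug in an external extractor")
})

# Reduce a clip (H, W, L) to the backbone grid (16 x 16 x L x 1) by
# center-crop to a pooling-compatible size and average pooling. Fixed-range
# intensities are kept as-is so acquisition gain/offset cues remain visible
# to the domain head.
backbone_prepare_clip <- function(bb, clip) {
  d <- dim(clip)
  fh <- max(1L, d[1] %/% bb$grid); fw <- max(1L, d[2] %/% bb$grid)
  clip <- crop_to_multiple(clip, max(fh * 1L, fw * 1L))
  d <- dim(clip)
  fh <- d[1] %/% bb$grid; fw <- d[2] %/% bb$grid
  X <- array(clip, c(d, 1))
  pool3d(X, c(fh, fw, 1))
}

tiny3d_forward <- function(bb, Xp) {
  c1 <- conv3d_forward(bb$arch$conv1, bb$params$conv1, Xp)
  a1 <- relu(c1$out)
  p1 <- pool3d(a1, c(2, 2, 2))
  c2 <- conv3d_forward(bb$arch$conv2, bb$params$conv2, p1)
  a2 <- relu(c2$out)
  p2 <- pool3d(a2, c(2, 2, 2))
  c3 <- conv3d_forward(bb$arch$conv3, bb$params$conv3, p2)
  a3 <- relu(c3$out)
  d3 <- dim(a3)
  h <- colMeans(matrix(a3, nrow = prod(d3[1:3])))
  list(h = h, cache = list(Xp = Xp, c1 = c1, a1 = a1, p1dim = dim(p1),
                           c2 = c2, a2 = a2, p2dim = dim(p2),
                           c3 = c3, a3 = a3))
}

# Returns parameter gradients plus `dX`, the gradient with respect to
# the prepared input clip (consumed by the input-normalization gate).
tiny3d_backward <- function(bb, cache, dh) {
  d3 <- dim(cache$a3)
  da3 <- array(rep(dh / prod(d3[1:3]), each = prod(d3[1:3])), d3)
  dc3 <- relu_backward(cache$c3$out, da3)
  g3 <- conv3d_backward(bb$arch$conv3, bb$params$conv3, cache$c3$cache, dc3)
  dp2 <- g3$dX
  da2 <- unpool3d(dp2, c(2, 2, 2))
  dc2 <- relu_backward(cache$c2$out, da2)
  g2 <- conv3d_backward(bb$arch$conv2, bb$params$conv2, cache$c2$cache, dc2)
  da1 <- unpool3d(g2$dX, c(2, 2, 2))
  dc1 <- relu_backward(cache$c1$out, da1)
  g1 <- conv3d_backward(bb$arch$conv1, bb$params$conv1, cache$c1$cache, dc1)
  list(conv1 = list(W = g1$dW, b = g1$db),
       conv2 = list(W = g2$dW, b = g2$db),
       conv3 = list(W = g3$dW, b = g3$db),
       dX = g1$dX)
}

backbone_forward <- function(bb, Xp) UseMethod("backbone_forward")
#' @export
backbone_forward.tiny3d <- function(bb, Xp) tiny3d_forward(bb, Xp)
backbone_backward <- function(bb, cache, dh) UseMethod("backbone_backward")
#' @export
backbone_backward.tiny3d <- function(bb, cache, dh) tiny3d_backward(bb, cache, dh)

#' Extract one representation per snippet of a bag
#'
#' Order preserved; deterministic for fixed weights. All snippets in a
#' bag must share their geometry.
#'
#' @param backbone a built backbone (see [build_backbone()]).
#' @param bag a `snippet_bag`.
#' @return An `n x d` matrix of snippet representations, rows aligned
#'   with `bag$snippets`.
#' @export
extract_features <- function(backbone, bag) {
  dims <- vapply(bag$snippets, function(s) paste(dim(s$frames),
                                                 collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1)
    stop("extract_features: mixed snippet geometries in one bag")
  H <- t(vapply(bag$snippets, function(s)
    backbone_forward(backbone, backbone_prepare_clip(backbone, s$frames))$h,
    numeric(backbone$config$feature_dim)))
  H
}
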