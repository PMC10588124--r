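# Synthetic beating-ventricle phantom: a bright myocardial annulus around a
# dark cavity whose radius follows a periodic piecewise-cosine trajectory.
# Ground-truth phase labels and ES/ED indices come with every video, so the
# timing detector, snippet proposer and classifier are all testable without
# clinical data.

#' Configuration of the synthetic echo generator
#'
#' Defaults emulate the acquisition regime of the clinical data the
#' pipeline targets: nominal 30 fps, a cardiac period of 64 raw frames so
#' that one proposed clip (32 frames at stride 2) spans a full cycle, and
#' mild per-acquisition nuisances. Class contrast is carried by
#' contraction amplitude and wall thickness (see [synthetic_presets()]):
#' the hypertensive class contracts less and has a thicker wall, mirroring
#' the direction of the strain and wall-thickness contrasts seen
#' clinically.
#'
#' @param frame_height,frame_width frame size in pixels.
#' @param fps nominal frames per second.
#' @param period_frames integer raw frames per cardiac cycle (>= 4).
#' @param systole_fraction fraction of the cycle spent contracting, in
#'   (0, 1).
#' @param ed_cavity_radius cavity radius at end-diastole, pixels.
#' @param contraction_amplitude fractional radius reduction at
#'   end-systole, in `[0, 1)`.
#' @param wall_thickness myocardial annulus thickness, pixels.
#' @param noise_sigma additive Gaussian noise scale (intensity units).
#' @param blur_sigma Gaussian blur scale, pixels (0 = none).
#' @param gain multiplicative intensity factor.
#' @param zoom geometric scale factor.
#' @param n_frames total frames (>= 1).
#' @param seed RNG seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(frame_height = 64, frame_width = 64, fps = 30,
                             period_frames = 64, systole_fraction = 0.35,
                             ed_cavity_radius = 18,
                             contraction_amplitude = 0.35,
                             wall_thickness = 6, noise_sigma = 0.02,
                             blur_sigma = 0, gain = 1, zoom = 1,
                             n_frames = 200, seed = 1) {
  cfg <- list(frame_height = frame_height, frame_width = frame_width,
              fps = fps, period_frames = as.integer(period_frames),
              systole_fraction = systole_fraction,
              ed_cavity_radius = ed_cavity_radius,
              contraction_amplitude = contraction_amplitude,
              wall_thickness = wall_thickness, noise_sigma = noise_sigma,
              blur_sigma = blur_sigma, gain = gain, zoom = zoom,
              n_frames = as.integer(n_frames), seed = seed)
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$period_frames < 4)
    stop("synthetic_config: period_frames must be >= 4")
  if (cfg$systole_fraction <= 0 || cfg$systole_fraction >= 1)
    stop("synthetic_config: systole_fraction must be in (0, 1)")
  if (cfg$contraction_amplitude < 0 || cfg$contraction_amplitude >= 1)
    stop("synthetic_config: contraction_amplitude must be in [0, 1)")
  if (cfg$n_frames < 1) stop("synthetic_config: n_frames must be >= 1")
  if (cfg$frame_height < 8 || cfg$frame_width < 8)
    stop("synthetic_config: frame size must be at least 8x8")
  if (cfg$noise_sigma < 0) stop("synthetic_config: noise_sigma must be >= 0")
  if (cfg$gain <= 0) stop("synthetic_config: gain must be > 0")
  if (cfg$zoom <= 0) stop("synthetic_config: zoom must be > 0")
  invisible(cfg)
}

#' Read a generator configuration from YAML or JSON
#' @param path file whose top-level keys mirror [synthetic_config()]
#'   arguments.
#' @return A `synthetic_config`.
#' @export
synthetic_config_from_file <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
          else yaml::read_yaml(path)
  do.call(synthetic_config, vals)
}

#' Default class presets
#'
#' The healthy class contracts strongly with a thin wall; the
#' hypertensive class contracts weakly with a thick wall. Magnitudes are
#' free parameters of the phantom; only the direction of the contrast is
#' meaningful.
#'
#' @return Named list with `N` and `HTCM` presets
#'   (`contraction_amplitude`, `wall_thickness`).
#' @export
synthetic_presets <- function() {
  list(N = list(contraction_amplitude = 0.35, wall_thickness = 6),
       HTCM = list(contraction_amplitude = 0.15, wall_thickness = 10))
}

# Cavity radius at 0-based frame t. Piecewise cosine: contraction over the
# first `S` frames of each cycle, dilation over the rest; smooth at the
# turning points so a frame exactly at a turning point is the last frame
# of its run.
cavity_radius <- function(t, period, systole_fraction, r_ed, amplitude) {
  S <- max(1L, min(period - 1L, round(systole_fraction * period)))
  m <- t %% period
  r_es <- r_ed * (1 - amplitude)
  r <- ifelse(m <= S,
              r_es + (r_ed - r_es) * (1 + cos(pi * m / S)) / 2,
              r_es + (r_ed - r_es) * (1 - cos(pi * (m - S) / (period - S))) / 2)
  r
}

# Per-frame phase labels: 0 = contracting (systole), 1 = dilating
# (diastole). Frame at cycle position S (the radius minimum) is the last
# frame of its 0-run; the frame at position 0 (the maximum) the last of
# its 1-run.
phase_label <- function(t, period, systole_fraction) {
  S <- max(1L, min(period - 1L, round(systole_fraction * period)))
  m <- t %% period
  as.integer(!(m >= 1 & m <= S))
}

gaussian_blur_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- -half:half
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  M <- matrix(0, n, n)
  for (k in seq_along(x)) {
    idx <- pmin(pmax(seq_len(n) + x[k], 1), n)  # replicate-pad at borders
    M[cbind(seq_len(n), idx)] <- M[cbind(seq_len(n), idx)] + g[k]
  }
  M
}

#' Generate one synthetic echo-like video
#'
#' Renders a bright annulus (myocardium) around a dark cavity whose inner
#' radius contracts during the systole fraction of each cycle and dilates
#' during the remainder, then applies the acquisition nuisances (gain,
#' blur, additive noise). Deterministic given `(config, class_label,
#' seed)`.
#'
#' @param config a [synthetic_config()].
#' @param class_label `"N"` or `"HTCM"`; with `use_presets = TRUE` the
#'   class preset overrides `contraction_amplitude` and `wall_thickness`.
#' @param seed RNG seed (defaults to `config$seed`).
#' @param domain_id integer acquisition-domain identifier.
#' @param use_presets apply [synthetic_presets()] for the class.
#' @return A `synthetic_sample`: list with `video` ([echo_video()]),
#'   `phase_labels` (length-`T` 0/1 vector), `true_timings`
#'   (`list(es, ed)`, 0-based interior indices), `class_label`,
#'   `domain_id`.
#' @export
generate_video <- function(config, class_label = "N", seed = config$seed,
                           domain_id = 0L, use_presets = TRUE) {
  validate_synthetic_config(config)
  stopifnot(class_label %in% c("N", "HTCM"))
  cfg <- config
  if (use_presets) {
    pre <- synthetic_presets()[[class_label]]
    cfg$contraction_amplitude <- pre$contraction_amplitude
    cfg$wall_thickness <- pre$wall_thickness
  }
  set.seed(seed)
  H <- cfg$frame_height; W <- cfg$frame_width; n <- cfg$n_frames
  P <- cfg$period_frames
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  D <- sqrt(outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+"))
  r_ed <- cfg$ed_cavity_radius * cfg$zoom
  wt <- cfg$wall_thickness * cfg$zoom
  tt <- seq_len(n) - 1L
  radius <- cavity_radius(tt, P, cfg$systole_fraction, r_ed,
                          cfg$contraction_amplitude)
  phases <- phase_label(tt, P, cfg$systole_fraction)

  edge <- function(x) pmin(pmax(x + 0.5, 0), 1)  # 1-px linear ramp
  Bh <- if (cfg$blur_sigma > 0) gaussian_blur_matrix(H, cfg$blur_sigma)
  Bw <- if (cfg$blur_sigma > 0) gaussian_blur_matrix(W, cfg$blur_sigma)
  frames <- array(0, c(H, W, n))
  for (t in seq_len(n)) {
    r <- radius[t]
    inner <- edge(D - r)          # 0 in cavity, 1 outside
    outer_e <- edge(D - (r + wt)) # 0 inside annulus outer rim
    img <- 0.05 + 0.80 * inner            # cavity -> wall
    img <- img * (1 - outer_e) + 0.22 * outer_e  # wall -> background
    img <- img * cfg$gain
    if (cfg$blur_sigma > 0) img <- Bh %*% img %*% t(Bw)
    if (cfg$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, cfg$noise_sigma), H, W)
    frames[, , t] <- pmin(pmax(img, 0), 1)
  }

  S <- max(1L, min(P - 1L, round(cfg$systole_fraction * P)))
  # Interior turning points: runs touching either video boundary excluded.
  ks <- 0:(n %/% P)
  es <- ks * P + S; es <- es[es >= 1 & es <= n - 2]
  ed <- ks * P;     ed <- ed[ed >= 1 & ed <= n - 2]

  video <- echo_video(frames, fps = cfg$fps,
                      subject_id = "synthetic", video_id = "synthetic",
                      class_label = class_label, domain_id = domain_id,
                      source = "synthetic")
  structure(list(video = video, phase_labels = phases,
                 true_timings = list(es = es, ed = ed),
                 class_label = class_label, domain_id = as.integer(domain_id),
                 config = cfg),
            class = "synthetic_sample")
}

#' Cavity area of a noise-free phantom frame
#'
#' Pixel count below an intensity threshold separating the dark cavity
#' from wall and background; intended for noise-free, unit-gain phantom
#' frames where it approximates the analytic disc area.
#'
#' @param frame an `H x W` matrix.
#' @param threshold intensity cut between cavity and background (just
#'   below the background level, minimizing edge-ramp bias).
#' @return Pixel count of the cavity.
#' @export
cavity_area <- function(frame, threshold = 0.21) sum(frame < threshold)

#' Acquisition-domain nuisance scheme
#'
#' Ranges from which per-video nuisance parameters are drawn; each video
#' is its own domain. The defaults are mild; widen the gain and noise
#' ranges to create strongly separated domains.
#'
#' @param gain,noise_sigma,blur_sigma,zoom length-2 numeric ranges.
#' @param period_frames optional integer range for per-subject cycle
#'   length; `NULL` keeps the configured period.
#' @return A `domain_scheme` list.
#' @export
domain_scheme <- function(gain = c(0.85, 1.15), noise_sigma = c(0.01, 0.04),
                          blur_sigma = c(0, 0.7), zoom = c(0.92, 1.08),
                          period_frames = NULL) {
  list(gain = gain, noise_sigma = noise_sigma, blur_sigma = blur_sigma,
       zoom = zoom, period_frames = period_frames)
}

#' Generate a labeled train/test dataset of synthetic videos
#'
#' Each subject carries one fixed class; every video has a unique
#' `domain_id` and its own nuisance draw from the `scheme`. The split
#' assigns whole subjects to train or test — no subject straddles the
#' split — stratified by class with `floor(split_ratio * n_class)`
#' training subjects per class.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param videos_per_subject videos per subject.
#' @param class_balance fraction of subjects in the HTCM class.
#' @param scheme a [domain_scheme()].
#' @param split_ratio fraction of subjects assigned to training, in
#'   (0, 1).
#' @param seed RNG seed.
#' @param config base [synthetic_config()] shared by all videos.
#' @param use_presets apply class presets (see [generate_video()]).
#' @return `list(train, test, manifest)`: lists of `synthetic_sample`
#'   objects plus a manifest `data.frame`.
#' @export
generate_dataset <- function(n_subjects, videos_per_subject = 2,
                             class_balance = 0.5, scheme = domain_scheme(),
                             split_ratio = 5 / 6, seed = 1,
                             config = synthetic_config(),
                             use_presets = TRUE) {
  stopifnot(n_subjects >= 2, split_ratio > 0, split_ratio < 1)
  set.seed(derive_seed(seed, "dataset"))
  n_pos <- round(class_balance * n_subjects)
  classes <- sample(c(rep("HTCM", n_pos), rep("N", n_subjects - n_pos)))
  split <- character(n_subjects)
  for (cl in c("N", "HTCM")) {
    idx <- which(classes == cl)
    n_tr <- floor(split_ratio * length(idx))
    tr <- idx[sample.int(length(idx), n_tr)]
    split[tr] <- "train"
    split[setdiff(idx, tr)] <- "test"
  }
  for (sp in c("train", "test")) for (cl in c("N", "HTCM"))
    if (!any(split == sp & classes == cl))
      stop("generate_dataset: too few subjects to populate the ", sp,
           " split with class ", cl)

  draw <- function(rg) stats::runif(1, rg[1], rg[2])
  train <- list(); test <- list(); rows <- list()
  dom <- 0L
  for (s in seq_len(n_subjects)) {
    period_s <- if (!is.null(scheme$period_frames))
      as.integer(round(draw(scheme$period_frames))) else config$period_frames
    for (v in seq_len(videos_per_subject)) {
      cfg <- config
      cfg$period_frames <- period_s
      cfg$gain <- draw(scheme$gain)
      cfg$noise_sigma <- draw(scheme$noise_sigma)
      cfg$blur_sigma <- draw(scheme$blur_sigma)
      cfg$zoom <- draw(scheme$zoom)
      vseed <- derive_seed(seed, sprintf("video_%d_%d", s, v))
      smp <- generate_video(cfg, class_label = classes[s], seed = vseed,
                            domain_id = dom, use_presets = use_presets)
      smp$video$subject_id <- sprintf("subj%03d", s)
      smp$video$video_id <- sprintf("subj%03d_v%d", s, v)
      rows[[length(rows) + 1]] <- data.frame(
        video_id = smp$video$video_id, subject_id = smp$video$subject_id,
        class = classes[s], domain_id = dom, split = split[s],
        period_frames = period_s, gain = cfg$gain,
        noise_sigma = cfg$noise_sigma, blur_sigma = cfg$blur_sigma,
        zoom = cfg$zoom)
      if (split[s] == "train") train[[length(train) + 1]] <- smp
      else test[[length(test) + 1]] <- smp
      dom <- dom + 1L
    }
  }
  list(train = train, test = test, manifest = do.call(rbind, rows))
}
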