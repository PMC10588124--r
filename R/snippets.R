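# Snippet proposal: convert a video plus decoded timings into an ordered
# bag of fixed-length clips — cardiac-cycle-based (one clip per
# end-diastole) or uniform (baseline).

snippet_new <- function(video, start, stride, clip_len, source_ed = NA,
                        pad = FALSE) {
  Tn <- n_frames(video)
  idx <- start + stride * (seq_len(clip_len) - 1)  # 0-based raw indices
  if (pad) idx <- pmin(idx, Tn - 1)
  stopifnot(all(idx >= 0), all(idx <= Tn - 1))
  list(frames = video$frames[, , idx + 1, drop = FALSE],
       start_frame = start, stride = stride, source_ed_index = source_ed)
}

bag_new <- function(video, snippets, mode) {
  stopifnot(length(snippets) >= 1)
  starts <- vapply(snippets, function(s) s$start_frame, numeric(1))
  stopifnot(!is.unsorted(starts, strictly = FALSE))
  structure(list(snippets = snippets, video_id = video$video_id,
                 subject_id = video$subject_id,
                 class_label = video$class_label,
                 domain_id = video$domain_id, sampling_mode = mode),
            class = "snippet_bag")
}

#' @export
print.snippet_bag <- function(x, ...) {
  cat(sprintf("<snippet_bag %s: %d snippets (%s), class=%s, domain=%d>\n",
              x$video_id, length(x$snippets), x$sampling_mode,
              x$class_label, x$domain_id))
  invisible(x)
}

#' Propose cardiac-cycle snippets
#'
#' One clip per end-diastole index `e`, covering raw frames
#' `e, e+s, ..., e+s*(L-1)` so that each clip spans a full contraction
#' and dilation. ED indices whose clip would run past the video end are
#' skipped (recorded in the `skipped` attribute); if no clip fits, the
#' proposal falls back to uniform sampling with padding so every video
#' still yields a bag (`sampling_mode` then reads `"uniform"`).
#'
#' @param video an [echo_video()].
#' @param timings decoded timings for this video
#'   (see [extract_timings()]).
#' @param clip_len clip length `L` in sampled frames (default 32).
#' @param stride temporal subsampling step `s` over raw frames
#'   (default 2).
#' @param max_snippets bag-size cap; earliest clips are kept.
#' @param fallback_n snippets requested from the uniform fallback.
#' @return A `snippet_bag`.
#' @export
propose_cycle_snippets <- function(video, timings, clip_len = 32, stride = 2,
                                   max_snippets = 16, fallback_n = 2) {
  Tn <- n_frames(video)
  eds <- sort(timings$ed)
  fits <- eds[eds + stride * (clip_len - 1) <= Tn - 1]
  skipped <- setdiff(eds, fits)
  if (length(fits) == 0) {
    bag <- propose_uniform_snippets(video, clip_len, stride,
                                    n_snippets = fallback_n, pad = TRUE)
    attr(bag, "skipped") <- skipped
    attr(bag, "fallback") <- TRUE
    return(bag)
  }
  if (length(fits) > max_snippets) fits <- fits[seq_len(max_snippets)]
  sn <- lapply(fits, function(e)
    snippet_new(video, e, stride, clip_len, source_ed = e))
  bag <- bag_new(video, sn, "cycle")
  attr(bag, "skipped") <- skipped
  bag
}

#' Propose uniformly spaced snippets
#'
#' `n_snippets` start frames evenly spaced over the valid start range,
#' with the same clip geometry as the cycle mode. Duplicate starts
#' produced by rounding are collapsed so the bag stays strictly ordered.
#'
#' @inheritParams propose_cycle_snippets
#' @param n_snippets requested number of clips.
#' @param pad when the video is shorter than one clip, clamp indices to
#'   the last frame instead of erroring.
#' @return A `snippet_bag`.
#' @export
propose_uniform_snippets <- function(video, clip_len = 32, stride = 2,
                                     n_snippets = 4, pad = FALSE) {
  Tn <- n_frames(video)
  span <- stride * (clip_len - 1)
  max_start <- Tn - 1 - span
  if (max_start < 0) {
    if (!pad)
      stop("propose_uniform_snippets: video of ", Tn,
           " frames is shorter than one clip (", span + 1,
           " raw frames); enable pad")
    sn <- list(snippet_new(video, 0, stride, clip_len, pad = TRUE))
    return(bag_new(video, sn, "uniform"))
  }
  starts <- unique(round(seq(0, max_start, length.out = n_snippets)))
  sn <- lapply(starts, function(s0)
    snippet_new(video, s0, stride, clip_len))
  bag_new(video, sn, "uniform")
}

#' Assemble a snippet bag from explicit clips
#'
#' For constructed experiments (e.g. mixed bags combining snippets from
#' different source videos). The list order is taken as the bag's
#' temporal order.
#'
#' @param snippets list of snippets (as produced inside proposal bags:
#'   `frames`, `start_frame`, `stride`, `source_ed_index`).
#' @param video_id,subject_id,class_label,domain_id bag metadata.
#' @param sampling_mode recorded sampling mode.
#' @return A `snippet_bag`.
#' @export
snippet_bag <- function(snippets, video_id = "bag", subject_id = video_id,
                        class_label = "unknown", domain_id = 0L,
                        sampling_mode = "cycle") {
  stopifnot(length(snippets) >= 1)
  structure(list(snippets = snippets, video_id = video_id,
                 subject_id = subject_id, class_label = class_label,
                 domain_id = as.integer(domain_id),
                 sampling_mode = sampling_mode),
            class = "snippet_bag")
}

#' Serialize a bag's geometry as a manifest list
#'
#' @param bag a `snippet_bag`.
#' @return A JSON-ready list (video_id, mode, per-snippet
#'   `start_frame`/`stride`/`source_ed_index`).
#' @export
bag_manifest <- function(bag) {
  list(video_id = bag$video_id, mode = bag$sampling_mode,
       snippets = lapply(bag$snippets, function(s)
         list(start_frame = s$start_frame, stride = s$stride,
              source_ed_index = s$source_ed_index)))
}
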