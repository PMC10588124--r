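# EchoVideo container, multiframe DICOM reading, lossless TIFF stack I/O,
# manifests and the curation filter.

#' EchoVideo: an ordered grayscale frame stack with acquisition metadata
#'
#' The common representation every pipeline stage consumes. Frames are
#' stored as an `H x W x T` numeric array with intensities in `[0, 1]`;
#' frame indexing is 0-based and intervals half-open throughout the
#' package.
#'
#' @param frames numeric `H x W x T` array, finite, in `[0, 1]`.
#' @param fps frames per second (nominal acquisition setting 30).
#' @param subject_id,video_id opaque identifier strings.
#' @param class_label one of `"N"`, `"HTCM"`, `"unknown"`.
#' @param domain_id non-negative integer; each video is its own
#'   acquisition domain.
#' @param source one of `"dicom"`, `"synthetic"`, `"array"`.
#' @return An object of class `echo_video`.
#' @export
echo_video <- function(frames, fps = 30, subject_id = "s0", video_id = "v0",
                       class_label = "unknown", domain_id = 0L,
                       source = "array") {
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 1)
  if (!all(is.finite(frames)))
    stop("echo_video: frames contain non-finite intensities")
  if (min(frames) < -1e-9 || max(frames) > 1 + 1e-9)
    stop("echo_video: intensities must lie in [0, 1]")
  if (!class_label %in% c("N", "HTCM", "unknown"))
    stop("echo_video: class_label must be N, HTCM or unknown")
  if (domain_id < 0) stop("echo_video: domain_id must be >= 0")
  structure(list(frames = frames, fps = fps, subject_id = subject_id,
                 video_id = video_id, class_label = class_label,
                 domain_id = as.integer(domain_id), source = source),
            class = "echo_video")
}

#' @export
print.echo_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<echo_video %s subject=%s %dx%d, %d frames @ %.3g fps, class=%s, domain=%d, %s>\n",
    x$video_id, x$subject_id, d[1], d[2], d[3], x$fps, x$class_label,
    x$domain_id, x$source))
  invisible(x)
}

#' Number of frames of a video
#' @param video an `echo_video`.
#' @return Integer frame count `T`.
#' @export
n_frames <- function(video) dim(video$frames)[3]

## ---- DICOM ----------------------------------------------------------------

.u16 <- function(b, p) {
  as.integer(b[p]) + 256L * as.integer(b[p + 1])
}
.u32 <- function(b, p) {
  as.double(b[p]) + 256 * as.double(b[p + 1]) + 65536 * as.double(b[p + 2]) +
    16777216 * as.double(b[p + 3])
}
.str <- function(b) {
  s <- rawToChar(b[b != as.raw(0)])
  trimws(s)
}

# Skip an undefined-length sequence: scan items until the sequence
# delimitation item (FFFE,E0DD) at nesting depth zero.
.skip_undefined <- function(bytes, p) {
  depth <- 0L
  repeat {
    g <- .u16(bytes, p); e <- .u16(bytes, p + 2); len <- .u32(bytes, p + 4)
    p <- p + 8
    if (g == 0xFFFE && e == 0xE0DD) {
      if (depth == 0L) return(p)
      depth <- depth - 1L
    } else if (g == 0xFFFE && e == 0xE000) {
      if (len == 4294967295) depth <- depth + 0L else p <- p + len
    } else if (g == 0xFFFE && e == 0xE00D) {
      # item delimiter
    } else {
      if (len == 4294967295) stop("read_dicom_video: unparseable sequence")
      p <- p + len
    }
    if (p > length(bytes)) stop("read_dicom_video: truncated sequence")
  }
}

#' Read a multiframe DICOM ultrasound video
#'
#' A minimal reader for uncompressed little-endian DICOM (implicit and
#' explicit VR): standard pixel-module tags plus frame-time metadata.
#' Color payloads (`RGB`) are converted to intensity by the Rec. 601 luma
#' weights; `MONOCHROME1` is inverted. Compressed transfer syntaxes and
#' other photometric interpretations raise explicit errors rather than
#' decoding silently to garbage.
#'
#' @param path path to a DICOM file with a multiframe pixel payload.
#' @param default_fps frame rate to assume when neither Frame Time
#'   (0018,1063) nor Recommended Display Frame Rate (0008,2144) is
#'   present; the nominal acquisition setting 30.
#' @return An [echo_video()] with `class_label = "unknown"` (the manifest
#'   assigns labels) and `source = "dicom"`.
#' @export
read_dicom_video <- function(path, default_fps = 30) {
  n <- file.size(path)
  if (is.na(n) || n < 140) stop("read_dicom_video: not a DICOM file: ", path)
  bytes <- readBin(path, "raw", n)
  if (rawToChar(bytes[129:132]) != "DICM")
    stop("read_dicom_video: missing DICM magic in ", path)
  p <- 133L
  ts <- "1.2.840.10008.1.2.1"
  # file meta group (0002): always explicit VR little endian
  while (p + 7 <= n && .u16(bytes, p) == 2L) {
    elem <- .u16(bytes, p + 2)
    vr <- rawToChar(bytes[(p + 4):(p + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- .u32(bytes, p + 8); vp <- p + 12
    } else {
      len <- .u16(bytes, p + 6); vp <- p + 8
    }
    if (elem == 0x0010) ts <- .str(bytes[vp:(vp + len - 1)])
    p <- vp + len
  }
  explicit <- ts == "1.2.840.10008.1.2.1"
  if (!explicit && ts != "1.2.840.10008.1.2")
    stop("read_dicom_video: unsupported transfer syntax ", ts)

  tags <- list()
  long_vr <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (p + 7 <= n) {
    g <- .u16(bytes, p); e <- .u16(bytes, p + 2)
    if (explicit && g != 0xFFFE) {
      vr <- rawToChar(bytes[(p + 4):(p + 5)])
      if (vr %in% long_vr) {
        len <- .u32(bytes, p + 8); vp <- p + 12
      } else {
        len <- .u16(bytes, p + 6); vp <- p + 8
      }
    } else {
      vr <- ""
      len <- .u32(bytes, p + 4); vp <- p + 8
    }
    key <- sprintf("%04x,%04x", g, e)
    if (len == 4294967295) {
      if (key == "7fe0,0010")
        stop("read_dicom_video: encapsulated (compressed) pixel data is unsupported")
      p <- .skip_undefined(bytes, vp)
      next
    }
    if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0002",
                   "0028,0103", "0028,0006", "0028,0008", "0028,0004",
                   "0018,1063", "0008,2144", "7fe0,0010")) {
      tags[[key]] <- bytes[vp + seq_len(len) - 1]
    }
    p <- vp + len
  }

  if (is.null(tags[["7fe0,0010"]]))
    stop("read_dicom_video: no pixel data in ", path)
  us <- function(key, default = NULL) {
    if (is.null(tags[[key]])) return(default)
    .u16(tags[[key]], 1)
  }
  istr <- function(key, default = NULL) {
    if (is.null(tags[[key]])) return(default)
    .str(tags[[key]])
  }
  rows <- us("0028,0010"); cols <- us("0028,0011")
  if (is.null(rows) || is.null(cols))
    stop("read_dicom_video: missing Rows/Columns")
  nf <- as.integer(istr("0028,0008", "1"))
  bits <- us("0028,0100", 8L)
  spp <- us("0028,0002", 1L)
  pixrep <- us("0028,0103", 0L)
  planar <- us("0028,0006", 0L)
  photometric <- istr("0028,0004", "MONOCHROME2")
  if (pixrep != 0)
    stop("read_dicom_video: signed pixel representation is unsupported")
  pix <- tags[["7fe0,0010"]]
  if (bits == 8) {
    vals <- as.integer(pix); maxv <- 255
  } else if (bits == 16) {
    vals <- readBin(pix, "integer", n = length(pix) %/% 2, size = 2,
                    signed = FALSE, endian = "little")
    maxv <- 65535
  } else stop("read_dicom_video: unsupported bits allocated: ", bits)

  need <- rows * cols * nf * spp
  if (length(vals) < need) stop("read_dicom_video: pixel data shorter than declared geometry")
  vals <- vals[seq_len(need)]

  frames <- array(0, c(rows, cols, nf))
  for (f in seq_len(nf)) {
    off <- (f - 1) * rows * cols * spp
    if (spp == 1) {
      v <- vals[off + seq_len(rows * cols)]
      img <- matrix(v, nrow = rows, byrow = TRUE) / maxv
      if (photometric == "MONOCHROME1") img <- 1 - img
      else if (photometric != "MONOCHROME2")
        stop("read_dicom_video: unsupported photometric interpretation ",
             photometric)
    } else if (spp == 3 && photometric == "RGB") {
      v <- vals[off + seq_len(rows * cols * 3)]
      if (planar == 0) {
        r <- v[seq(1, length(v), 3)]; gch <- v[seq(2, length(v), 3)]
        b <- v[seq(3, length(v), 3)]
      } else {
        np <- rows * cols
        r <- v[seq_len(np)]; gch <- v[np + seq_len(np)]; b <- v[2 * np + seq_len(np)]
      }
      lum <- (0.299 * r + 0.587 * gch + 0.114 * b) / maxv
      img <- matrix(lum, nrow = rows, byrow = TRUE)
    } else {
      stop("read_dicom_video: unsupported photometric interpretation ",
           photometric)
    }
    frames[, , f] <- img
  }
  frames <- pmin(pmax(frames, 0), 1)

  fps <- default_fps
  ft <- istr("0018,1063")
  if (!is.null(ft) && !is.na(suppressWarnings(as.numeric(ft))) &&
      as.numeric(ft) > 0) {
    fps <- 1000 / as.numeric(ft)
  } else {
    rr <- istr("0008,2144")
    if (!is.null(rr) && !is.na(suppressWarnings(as.numeric(rr))))
      fps <- as.numeric(rr)
  }
  id <- tools::file_path_sans_ext(basename(path))
  echo_video(frames, fps = fps, subject_id = id, video_id = id,
             class_label = "unknown", source = "dicom")
}

## ---- lossless TIFF stacks -------------------------------------------------

#' Write / read a video as a lossless multi-page TIFF stack
#'
#' Intensities are quantized to 16 bits at export; a read/re-write
#' round trip of an exported stack is bit-identical.
#'
#' @param video an [echo_video()].
#' @param path output `.tif` path.
#' @return `write_video_tiff`: the path, invisibly. `read_video_tiff`: an
#'   [echo_video()].
#' @export
write_video_tiff <- function(video, path) {
  pages <- lapply(seq_len(n_frames(video)),
                  function(t) video$frames[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_video_tiff
#' @param fps,subject_id,video_id,class_label,domain_id metadata to attach
#'   (TIFF stores pixels only; metadata travels in the manifest).
#' @export
read_video_tiff <- function(path, fps = 30, subject_id = NULL,
                            video_id = NULL, class_label = "unknown",
                            domain_id = 0L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages)))
  id <- tools::file_path_sans_ext(basename(path))
  echo_video(frames, fps = fps,
             subject_id = if (is.null(subject_id)) id else subject_id,
             video_id = if (is.null(video_id)) id else video_id,
             class_label = class_label, domain_id = domain_id,
             source = "array")
}

## ---- curation -------------------------------------------------------------

#' Frame-variance quality heuristic
#'
#' An optional stand-in for an image-quality filter: a video is kept when
#' the mean per-frame intensity variance exceeds `min_var` (near-constant
#' frames carry no anatomy).
#'
#' @param min_var minimum mean frame variance.
#' @return A predicate `function(video) -> logical` for [curate()].
#' @export
variance_quality_predicate <- function(min_var = 1e-4) {
  function(video) {
    v <- mean(apply(video$frames, 3, stats::var))
    v >= min_var
  }
}

#' Curate a set of videos
#'
#' Applies the study's retention rule — videos with no more than
#' `max_frames` frames are kept — plus a pluggable per-video quality
#' predicate (default: keep everything). Every exclusion is logged with a
#' reason code. Idempotent.
#'
#' @param videos list of [echo_video()] objects.
#' @param max_frames maximum frame count to keep (default 300).
#' @param quality_predicate `NULL` (always keep) or a
#'   `function(video) -> logical`.
#' @return `list(kept = <videos>, log = <data.frame video_id, reason>)`.
#' @export
curate <- function(videos, max_frames = 300, quality_predicate = NULL) {
  stopifnot(max_frames >= 1)
  kept <- list(); log <- data.frame(video_id = character(),
                                    reason = character())
  for (v in videos) {
    if (n_frames(v) > max_frames) {
      log <- rbind(log, data.frame(video_id = v$video_id, reason = "too_long"))
    } else if (!is.null(quality_predicate) && !isTRUE(quality_predicate(v))) {
      log <- rbind(log, data.frame(video_id = v$video_id, reason = "quality"))
    } else {
      kept[[length(kept) + 1]] <- v
    }
  }
  list(kept = kept, log = log)
}

## ---- manifests and dataset export -----------------------------------------

#' Write a synthetic dataset to disk
#'
#' Each video becomes a lossless multi-page TIFF; a CSV manifest records
#' identity, labels and acquisition nuisances, and a JSON sidecar stores
#' per-frame phase labels and true ES/ED indices.
#'
#' @param ds a dataset from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); truth <- list()
  for (split in c("train", "test")) {
    for (s in ds[[split]]) {
      fn <- file.path(dir, paste0(s$video$video_id, ".tif"))
      write_video_tiff(s$video, fn)
      rows[[length(rows) + 1]] <- data.frame(
        video_id = s$video$video_id, subject_id = s$video$subject_id,
        class = s$class_label, domain_id = s$domain_id,
        fps = s$video$fps, split = split, path = basename(fn))
      truth[[s$video$video_id]] <- list(
        phases = s$phase_labels,
        es = s$true_timings$es, ed = s$true_timings$ed)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read a dataset manifest
#' @param dir directory written by [write_dataset()].
#' @return The manifest `data.frame`.
#' @export
read_manifest <- function(dir) {
  utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
}

#' Load one video listed in a dataset manifest
#' @param dir dataset directory; `row` one manifest row.
#' @return An [echo_video()] carrying the manifest's metadata.
#' @export
load_manifest_video <- function(dir, row) {
  read_video_tiff(file.path(dir, row$path), fps = row$fps,
                  subject_id = row$subject_id, video_id = row$video_id,
                  class_label = row$class, domain_id = row$domain_id)
}
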