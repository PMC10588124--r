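# Video- and subject-level scoring: ROC/AUC by the trapezoidal rule,
# the eight diagnostic metrics with confidence intervals, subject
# aggregation of last-layer outputs, and report files.

#' ROC curve and AUC by the trapezoidal rule
#'
#' The ROC is swept over all distinct score thresholds (tied scores move
#' together), and the area is accumulated by the trapezoidal rule, which
#' makes the AUC equal to the Mann-Whitney concordance probability with
#' ties counted one half.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 (or logical) true labels.
#' @return `list(auc = <number>, roc = <data.frame fpr, tpr>)`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("roc_auc: both classes must be present; AUC is undefined")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / P); fpr <- c(0, fp[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Diagnostic metrics at a decision threshold
#'
#' Positive call when the positive-class score is at or above the
#' threshold (ties are called positive). Reports the confusion matrix and
#' ACC, AUC, SEN, SPE, PPV, NPV, PLR, NLR computed from unrounded rates;
#' PLR is undefined at SPE = 1 and NLR at SPE = 0 (returned as `NA` with
#' the `undefined` flag listing them). The AUC confidence interval is a
#' seeded stratified bootstrap (percentile).
#'
#' @param scores positive-class scores (probabilities or any monotone
#'   score; the threshold applies to these values).
#' @param labels 0/1 true labels (1 = positive class).
#' @param threshold decision threshold in (0, 1) for probability scores.
#' @param granularity `"video"` or `"subject"`, recorded in the report.
#' @param ci compute the bootstrap AUC confidence interval.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return A `metrics_report` list.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5,
                            granularity = "video", ci = TRUE,
                            n_boot = 2000, conf = 0.95, seed = 1) {
  labels <- as.integer(labels)
  stopifnot(length(scores) >= 1, threshold > 0, threshold < 1)
  call_pos <- scores >= threshold
  tp <- sum(call_pos & labels == 1); fn <- sum(!call_pos & labels == 1)
  fp <- sum(call_pos & labels == 0); tn <- sum(!call_pos & labels == 0)
  n <- length(labels)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  undefined <- character()
  plr <- nlr <- NA_real_
  if (!is.na(sen) && !is.na(spe)) {
    if (spe < 1) plr <- sen / (1 - spe) else undefined <- c(undefined, "PLR")
    if (spe > 0) nlr <- (1 - sen) / spe else undefined <- c(undefined, "NLR")
  } else undefined <- c(undefined, "PLR", "NLR")
  auc <- NA_real_; auc_ci <- c(NA_real_, NA_real_); roc <- NULL
  if (sum(labels == 1) > 0 && sum(labels == 0) > 0) {
    r <- roc_auc(scores, labels)
    auc <- r$auc; roc <- r$roc
    if (ci) {
      set.seed(derive_seed(seed, "auc_boot"))
      ip <- which(labels == 1); ineg <- which(labels == 0)
      bs <- replicate(n_boot, {
        i <- c(ip[sample.int(length(ip), replace = TRUE)],
               ineg[sample.int(length(ineg), replace = TRUE)])
        roc_auc(scores[i], labels[i])$auc
      })
      a <- (1 - conf) / 2
      auc_ci <- unname(stats::quantile(bs, c(a, 1 - a)))
    }
  }
  structure(list(granularity = granularity,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 acc = acc, auc = auc, sen = sen, spe = spe, ppv = ppv,
                 npv = npv, plr = plr, nlr = nlr, auc_ci = auc_ci,
                 undefined = undefined, roc_points = roc, n = n,
                 threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report %s, n=%d> ACC %.3f AUC %.3f (%.3f-%.3f)\n",
              x$granularity, x$n, x$acc, x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  SEN %.3f SPE %.3f PPV %.3f NPV %.3f PLR %.3g NLR %.3g\n",
              x$sen, x$spe, x$ppv, x$npv, x$plr, x$nlr))
  invisible(x)
}

#' Aggregate video predictions to subject predictions
#'
#' Per subject, the last-layer outputs of its videos are averaged
#' component-wise and a softmax yields the subject probabilities
#' (`mode = "logits"`, the default). Averaging post-softmax probabilities
#' instead is exposed as `mode = "probabilities"`; the two can disagree
#' on borderline subjects.
#'
#' @param preds data.frame with columns `subject_id`, `score_N`,
#'   `score_HTCM` (last-layer outputs) and optionally `prob_HTCM`.
#' @param mode `"logits"` or `"probabilities"`.
#' @return data.frame, one row per subject: `subject_id`, `score_N`,
#'   `score_HTCM`, `prob_HTCM`, `label` (if present in `preds`,
#'   carried through).
#' @export
aggregate_subjects <- function(preds, mode = c("logits", "probabilities")) {
  mode <- match.arg(mode)
  stopifnot(nrow(preds) >= 1, !any(is.na(preds$subject_id)))
  out <- lapply(split(preds, preds$subject_id), function(g) {
    if (mode == "logits") {
      m <- c(mean(g$score_N), mean(g$score_HTCM))
      p <- softmax(m)
    } else {
      pr <- t(apply(cbind(g$score_N, g$score_HTCM), 1, softmax))
      p <- colMeans(pr)
      m <- log(pmax(p, 1e-300))
    }
    data.frame(subject_id = g$subject_id[1], score_N = m[1],
               score_HTCM = m[2], prob_HTCM = p[2],
               label = if ("label" %in% names(g)) g$label[1] else NA)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write metric tables, confusion matrices, ROC points and plots
#'
#' One metrics row per (method, granularity); deterministic output so
#' re-running on identical inputs reproduces byte-identical CSVs.
#'
#' @param reports named list of `metrics_report` objects; names become
#'   the `method` column (use e.g. `"ours/video"`).
#' @param out_dir output directory (created).
#' @param plots also render ROC curves to a PNG.
#' @return Invisibly, the paths written.
#' @export
make_report <- function(reports, out_dir, plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(method = nm, granularity = r$granularity, n = r$n,
               acc = r$acc, auc = r$auc, auc_lo = r$auc_ci[1],
               auc_hi = r$auc_ci[2], sen = r$sen, spe = r$spe,
               ppv = r$ppv, npv = r$npv, plr = r$plr, nlr = r$nlr)
  })
  paths <- file.path(out_dir, "metrics.csv")
  utils::write.csv(do.call(rbind, rows), paths, row.names = FALSE)
  for (nm in names(reports)) {
    r <- reports[[nm]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    cm <- file.path(out_dir, paste0("confusion_", safe, ".csv"))
    utils::write.csv(data.frame(t(r$confusion)), cm, row.names = FALSE)
    paths <- c(paths, cm)
    if (!is.null(r$roc_points)) {
      rp <- file.path(out_dir, paste0("roc_", safe, ".csv"))
      utils::write.csv(r$roc_points, rp, row.names = FALSE)
      paths <- c(paths, rp)
    }
  }
  if (plots) {
    png_path <- file.path(out_dir, "roc.png")
    grDevices::png(png_path, width = 640, height = 640)
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                   xlab = "False positive rate",
                   ylab = "True positive rate", main = "ROC")
    i <- 0
    for (nm in names(reports)) {
      r <- reports[[nm]]
      if (is.null(r$roc_points)) next
      i <- i + 1
      graphics::lines(r$roc_points$fpr, r$roc_points$tpr, col = i, lwd = 2)
    }
    graphics::legend("bottomright", legend = names(reports),
                     col = seq_along(reports), lwd = 2, cex = 0.8)
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
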