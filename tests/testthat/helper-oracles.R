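# Independent oracles used to cross-check the implementation. These are
# deliberately written with naive index scans, not the package's rle-based
# code path.

# Naive run-length decode: explicit scan over positions.
oracle_extract_timings <- function(phases, min_run = 2,
                                   drop_boundary_runs = TRUE) {
  x <- as.integer(phases)
  n <- length(x)
  runs_of <- function(x) {
    st <- c(); en <- c(); va <- c()
    i <- 1
    while (i <= length(x)) {
      j <- i
      while (j < length(x) && x[j + 1] == x[i]) j <- j + 1
      st <- c(st, i); en <- c(en, j); va <- c(va, x[i])
      i <- j + 1
    }
    list(st = st, en = en, va = va)
  }
  if (min_run > 1) {
    repeat {
      r <- runs_of(x)
      k <- length(r$st)
      lens <- r$en - r$st + 1
      short <- which(lens < min_run)
      if (length(short) == 0 || k == 1) break
      i <- short[1]
      left <- if (i > 1) lens[i - 1] else -1
      right <- if (i < k) lens[i + 1] else -1
      nb <- if (left >= right) i - 1 else i + 1
      x[r$st[i]:r$en[i]] <- r$va[nb]
    }
  }
  r <- runs_of(x)
  k <- length(r$st)
  es <- c(); ed <- c()
  for (i in seq_len(k)) {
    if (drop_boundary_runs && (i == 1 || i == k)) next
    if (r$va[i] == 0) es <- c(es, r$en[i] - 1) else ed <- c(ed, r$en[i] - 1)
  }
  list(es = as.numeric(es), ed = as.numeric(ed))
}

# Pairwise Mann-Whitney concordance with ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
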