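# Independent oracles, kept free of the package's implementation paths.

# Direct evaluation of the enrichment equation on raw count vectors:
# log2 of within-pool fraction ratio, floor on sorted zeros, NA on
# initial zeros.
eq1_brute <- function(initial, sorted, floor = -10) {
  out <- numeric(length(initial))
  for (i in seq_along(initial)) {
    if (initial[i] == 0) {
      out[i] <- NA_real_
    } else if (sorted[i] == 0) {
      out[i] <- floor
    } else {
      out[i] <- log2((sorted[i] / sum(sorted)) / (initial[i] / sum(initial)))
    }
  }
  out
}

# Exhaustive maximization over the global-alignment graph by memoized
# recursion over (i, j, previous-move); affine gap run of length g scores
# open + (g - 1) * ext. Independent of the package's DP implementation.
enum_align_score <- function(q, h, sub, open, ext) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  hc <- strsplit(h, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(hc)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, last)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sub[qc[i], hc[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      g <- if (last == "X") ext else open
      best <- max(best, g + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      g <- if (last == "Y") ext else open
      best <- max(best, g + rec(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "start")
}

# Re-score an alignment from its aligned strings; checks that a reported
# alignment realizes its reported score.
score_alignment <- function(a, mat, open, ext) {
  qc <- strsplit(a$aligned_query, "")[[1]]
  hc <- strsplit(a$aligned_homolog, "")[[1]]
  s <- 0
  last_gap <- ""
  for (i in seq_along(qc)) {
    if (qc[i] == "-" || hc[i] == "-") {
      side <- if (qc[i] == "-") "q" else "h"
      s <- s + if (last_gap == side) ext else open
      last_gap <- side
    } else {
      s <- s + mat[qc[i], hc[i]]
      last_gap <- ""
    }
  }
  s
}

# Plain enumeration without memoization (tiny inputs only); validates the
# memoized oracle itself.
enum_align_score_plain <- function(q, h, sub, open, ext) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  hc <- strsplit(h, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(hc)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sub[qc[i], hc[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      best <- max(best, (if (last == "X") ext else open) + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      best <- max(best, (if (last == "Y") ext else open) + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "start")
}
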