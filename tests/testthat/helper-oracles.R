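# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the package's own code paths: the segmentation oracle
# checks interval maximality directly, the Fisher oracle enumerates tables on
# fixed margins with log-binomial arithmetic, and the tree oracle
# exhaustively searches all depth-<=2 axis-aligned trees.

# Maximal constant-state run enumeration by direct interval checking: an
# interval [i, j] is a run iff all states equal, non-neutral, and neither
# endpoint can be extended.
oracle_segment <- function(v) {
  n <- length(v)
  runs <- list()
  if (n == 0) return(data.frame(state = integer(), start = integer(),
                                length = integer()))
  for (i in seq_len(n)) {
    for (j in i:n) {
      seg <- v[i:j]
      if (any(seg == 0) || length(unique(seg)) != 1) next
      left_max <- i == 1 || v[i - 1] != v[i]
      right_max <- j == n || v[j + 1] != v[j]
      if (left_max && right_max)
        runs[[length(runs) + 1]] <- data.frame(state = v[i], start = i - 1L,
                                               length = j - i + 1L)
    }
  }
  if (!length(runs)) return(data.frame(state = integer(), start = integer(),
                                       length = integer()))
  out <- do.call(rbind, runs)
  out[order(out$start), , drop = FALSE]
}

# Two-sided Fisher by full enumeration of all tables with the observed
# margins; probability-mass ordering with the same relative tie tolerance the
# implementation declares.
oracle_fisher <- function(tab) {
  x <- as.numeric(tab)
  a <- x[1]; b <- x[3]; c <- x[2]; d <- x[4]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  lp <- vapply(lo:hi, function(k)
    lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1), 0)
  probs <- exp(lp)
  p_obs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Best achievable training accuracy over all axis-aligned trees of depth <= 2
# (root split, each child optionally split once; leaves predict the majority
# class of their subset).
oracle_best_depth2_accuracy <- function(X, y) {
  n <- length(y)
  thresholds <- function(v) {
    u <- sort(unique(v))
    if (length(u) < 2) return(numeric(0))
    (u[-1] + u[-length(u)]) / 2
  }
  majority_correct <- function(idx) {
    if (!length(idx)) return(0L)
    max(sum(y[idx]), sum(!y[idx]))
  }
  best_child <- function(idx) {
    best <- majority_correct(idx)        # child stays a leaf
    if (length(idx) >= 2) {
      for (j in seq_len(ncol(X))) {
        for (t in thresholds(X[idx, j])) {
          l <- idx[X[idx, j] <= t]
          r <- setdiff(idx, l)
          best <- max(best, majority_correct(l) + majority_correct(r))
        }
      }
    }
    best
  }
  best <- majority_correct(seq_len(n))   # depth-0 tree
  for (j in seq_len(ncol(X))) {
    for (t in thresholds(X[, j])) {
      l <- which(X[, j] <= t)
      r <- which(X[, j] > t)
      best <- max(best, best_child(l) + best_child(r))
    }
  }
  best / n
}

# Hypergeometric lower-tail by enumeration (mutual-exclusivity oracle).
oracle_hyper_lower <- function(q, m, n, k) {
  lo <- max(0, k - n)
  if (q < lo) return(0)
  sum(vapply(lo:min(q, m, k), function(i)
    exp(lchoose(m, i) + lchoose(n, k - i) - lchoose(m + n, k)), 0))
}
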