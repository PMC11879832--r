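# Independent brute-force oracles. Each re-derives an expected result from
# first principles, by a different route than the implementation, so the two
# can disagree when either is wrong.

# Windows from the two rules alone: scan sentence by sentence.
oracle_windows <- function(word_counts, cap, stride) {
  offsets <- c(0, cumsum(word_counts))[seq_along(word_counts)]
  n <- length(word_counts)
  res <- list()
  s <- 1
  while (s <= n) {
    e <- s
    total <- word_counts[s]
    while (e < n && total + word_counts[e + 1] <= cap) {
      e <- e + 1
      total <- total + word_counts[e]
    }
    res[[length(res) + 1]] <- c(first = s - 1, last = e - 1, words = total)
    nxt <- n + 1
    for (j in seq_len(n)) {
      if (offsets[j] >= offsets[s] + stride) { nxt <- j; break }
    }
    s <- min(nxt, e + 1)
  }
  do.call(rbind, res)
}

# Per-sentence positive coverage by an explicit double loop.
oracle_coverage <- function(first, last, positive, n_sentences) {
  counts <- integer(n_sentences)
  for (i in seq_len(n_sentences)) {
    for (w in seq_along(first)) {
      if (positive[w] && first[w] <= i - 1 && i - 1 <= last[w]) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

# Shrinking-edge moving average by direct per-index means.
oracle_smooth <- function(x, radius) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - radius):min(n, i + radius)])
  }, numeric(1))
}

# Contiguous above-threshold runs by a simple state machine (no rle).
oracle_runs <- function(selected) {
  runs <- list()
  start <- NA
  for (i in seq_along(selected)) {
    if (selected[i] && is.na(start)) start <- i
    if (!selected[i] && !is.na(start)) {
      runs[[length(runs) + 1]] <- c(start - 1, i - 2)
      start <- NA
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1]] <- c(start - 1, length(selected) - 1)
  runs
}

# Exhaustive ordered partitions of weights into k contiguous parts; returns
# the minimal k for which some partition fits `budget`, and that partition's
# minimal achievable maximum part weight.
oracle_min_batches <- function(weights, budget) {
  n <- length(weights)
  for (k in 1:n) {
    cuts <- utils::combn(seq_len(n - 1), k - 1, simplify = FALSE)
    best <- Inf
    for (cut in cuts) {
      bounds <- c(0, cut, n)
      parts <- vapply(seq_len(k), function(j) {
        sum(weights[(bounds[j] + 1):bounds[j + 1]])
      }, numeric(1))
      if (max(parts) <= budget) best <- min(best, max(parts))
    }
    if (is.finite(best)) return(list(k = k, min_max = best))
  }
  stop("unreachable")
}

# Cohen's kappa from the 2x2 table via e1071 (independent implementation).
oracle_kappa <- function(tp, tn, fp, fn) {
  tab <- matrix(c(tp, fn, fp, tn), nrow = 2)
  e1071::classAgreement(tab)$kappa
}
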