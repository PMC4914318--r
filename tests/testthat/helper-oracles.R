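# Independent brute-force oracles, deliberately naive and kept separate from
# the package's own code paths.

# Exact two-sided Wilcoxon rank-sum p by full enumeration of the rank
# assignments of the first sample.
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  w <- sum(rank(c(x, y))[seq_len(n1)])
  sums <- apply(utils::combn(n, n1), 2L, sum)
  lo <- mean(sums <= w); hi <- mean(sums >= w)
  min(1, 2 * min(lo, hi))
}

# BH step-up written from the definition, element by element.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) p[o[j]] * m / j)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# One-sided Fisher p by enumerating every table with the same margins and
# summing the hypergeometric probabilities of tables at least as enriched.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  avals <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- sapply(avals, function(aa)
    choose(c1, aa) * choose(n - c1, r1 - aa) / choose(n, r1))
  sum(probs[avals >= a])
}

# Naive O(n^3) UPGMA: at every step recompute the average of the ORIGINAL
# pairwise distances across every cross pair of the two clusters; ties
# broken by the lexicographically smallest (min leaf, min leaf) pair.
oracle_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  merges <- list(); heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        cc <- expand.grid(clusters[[i]], clusters[[j]])
        avg <- mean(d[cbind(cc[[1L]], cc[[2L]])])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || avg < best$avg - 1e-12 ||
            (abs(avg - best$avg) <= 1e-12 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(i = i, j = j, avg = avg, key = key)
        }
      }
    merges[[length(merges) + 1L]] <-
      sort(c(clusters[[best$i]], clusters[[best$j]]))
    heights <- c(heights, best$avg)
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
  }
  list(members = merges, heights = heights)
}

# Leaf sets of each merge of a mirna_dendrogram, for comparison with the
# oracle's merge history.
dendro_merge_members <- function(dendro) {
  n <- length(dendro$labels)
  members <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    members[[s]] <- sort(unlist(lapply(dendro$merge[s, ], function(code)
      if (code < 0L) -code else members[[code]])))
  }
  members
}
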