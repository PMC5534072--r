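# Independent brute-force oracles used across the suite. These never
# call the implementation paths they check.

# Exact Mann-Whitney p by enumerating all C(m+n, m) group assignments of
# the pooled (tie-free) values.
bruteRankSumP <- function(x, y, tail = "lower") {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  uAll <- apply(combos, 2L, function(ix)
    sum(r[ix]) - m * (m + 1) / 2)
  switch(tail,
         lower = mean(uAll <= uObs),
         upper = mean(uAll >= uObs),
         two.sided = min(1, 2 * min(mean(uAll <= uObs),
                                    mean(uAll >= uObs))))
}

# Exact two-sided permutation p for Spearman's rho (distinct values).
bruteSpearmanP <- function(x, y) {
  rObs <- abs(stats::cor(rank(x), rank(y)))
  perms <- permuteAll(length(y))
  rx <- rank(x)
  ry <- rank(y)
  rAll <- apply(perms, 1L, function(ix) stats::cor(rx, ry[ix]))
  mean(abs(rAll) >= rObs - 1e-12)
}

permuteAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permuteAll(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# O(n^2) consensus: intervals of set 1 (0-based half-open data.frames
# with columns start, end) overlapping >= minOv bp with >= 1 interval in
# every other set.
bruteConsensus <- function(sets0, minOv = 1L) {
  a <- sets0[[1L]]
  keep <- vapply(seq_len(nrow(a)), function(i) {
    all(vapply(sets0[-1L], function(b) {
      any(pmin(a$end[i], b$end) - pmax(a$start[i], b$start) >= minOv)
    }, logical(1L)))
  }, logical(1L))
  a[keep, , drop = FALSE]
}

# brute nearest distance from a 0-based TSS to 0-based half-open peaks
# (bases strictly between; 0 inside)
bruteNearestDist <- function(t0, peaks0) {
  d <- ifelse(t0 >= peaks0$start & t0 < peaks0$end, 0,
              ifelse(t0 < peaks0$start, peaks0$start - t0 - 1,
                     t0 - peaks0$end))
  min(d)
}

grToBed0 <- function(gr) {
  data.frame(start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}
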