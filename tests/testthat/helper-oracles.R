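# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (GRanges coverage / countOverlaps / phyper / ks.test),
# looping over bases, draws or label assignments instead.

# per-base coverage by looping over every base of a chromosome
brute_coverage <- function(starts, ends, chrom_len) {
  v <- numeric(chrom_len)
  for (b in seq_len(chrom_len))
    v[b] <- sum(starts <= b & ends >= b)
  v
}

# read-per-feature counts by pairwise interval comparison
brute_count <- function(read_blocks, feat_start, feat_end) {
  # read_blocks: list of data.frames with start, end
  vapply(seq_along(feat_start), function(j) {
    sum(vapply(read_blocks, function(bl)
      any(bl$start <= feat_end[j] & bl$end >= feat_start[j]), logical(1)))
  }, numeric(1))
}

# upper-tail hypergeometric by exhaustive enumeration of all draws
brute_hypergeom <- function(N, k, n, x) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(k)            # first k population members carry term
  hits <- apply(draws, 2L, function(d) sum(d %in% annotated))
  mean(hits >= x)
}

# exact two-sample KS p by enumeration of label assignments (no ties)
brute_ks_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  D_of <- function(x, y) {
    xs <- sort(unique(pool))
    max(abs(vapply(xs, function(v) mean(x <= v) - mean(y <= v), numeric(1))))
  }
  obs <- D_of(a, b)
  assigns <- utils::combn(length(pool), n)
  ds <- apply(assigns, 2L, function(idx) D_of(pool[idx], pool[-idx]))
  mean(ds >= obs - 1e-12)
}

# textbook one-way fixed-effects ANOVA
brute_anova_f <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- tapply(values, groups, mean)
  ssb <- sum(tapply(values, groups, length) * (gm - mean(values))^2)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# junction support by looping over reads and comparing gaps
brute_junction_support <- function(reads_list, gap_start, gap_end) {
  # reads_list: list of data.frames (start, end) sorted blocks
  n <- 0L
  for (bl in reads_list) {
    if (nrow(bl) < 2L) next
    for (i in seq_len(nrow(bl) - 1L)) {
      if (bl$end[i] + 1L == gap_start && bl$start[i + 1L] - 1L == gap_end)
        n <- n + 1L
    }
  }
  n
}
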