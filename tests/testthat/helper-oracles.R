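# Shared fixture builders and independent oracles for the test suite.

iv <- function(chrom, start, end, name = NA_character_, score = NA_real_,
               strand = ".") {
  genomic_intervals(chrom, start, end, name, score, strand)
}

coords <- function(x)
  data.frame(start = as.integer(x$start), end = as.integer(x$end))

tx1 <- function(id, chrom, strand, exon_starts, exon_ends, gene = id) {
  ernatools:::transcript_table(list(ernatools:::make_transcript(
    id, gene, chrom, strand,
    data.frame(start = exon_starts, end = exon_ends))))
}

bind_tx <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, parts)
  class(out) <- unique(c("transcript_table", class(out)))
  out
}

# per-base coverage counter: number of distinct marker sets covering each
# position of a small genome (brute force, one chromosome)
brute_support <- function(windowed_sets, genome_len) {
  counts <- matrix(0L, nrow = genome_len, ncol = length(windowed_sets))
  for (j in seq_along(windowed_sets)) {
    covered <- rep(FALSE, genome_len)
    s <- windowed_sets[[j]]
    for (i in seq_len(nrow(s))) {
      lo <- max(0L, s$start[i]) + 1L
      hi <- min(genome_len, s$end[i])
      if (hi >= lo) covered[lo:hi] <- TRUE
    }
    counts[, j] <- as.integer(covered)
  }
  rowSums(counts)
}

# positions (0-based) covered by an interval table, as a logical mask
brute_mask <- function(intervals, genome_len) {
  mask <- rep(FALSE, genome_len)
  for (i in seq_len(nrow(intervals))) {
    lo <- max(0L, intervals$start[i]) + 1L
    hi <- min(genome_len, intervals$end[i])
    if (hi >= lo) mask[lo:hi] <- TRUE
  }
  mask
}

# quadratic-time Benjamini-Hochberg: q_i = min over {j: p_j >= p_i} of
# m * p_j / rank(p_j), clipped at 1
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(m * p[cand] / r[cand]))
  }, 0)
}

# hypergeometric upper tail by direct combinatorial sum
hyper_tail_oracle <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# rank-then-Pearson Spearman oracle (mid-ranks)
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# undirected edge list -> erna_network with all-pcg roles
net_from_pairs <- function(pairs) {
  edges <- data.frame(source = pairs[, 1], target = pairs[, 2],
                      kind = "coexpr", stringsAsFactors = FALSE)
  as_network(edges)
}

# random undirected simple graph on ids with edge probability p
random_net <- function(ids, p) {
  cmb <- t(combn(ids, 2))
  keep <- runif(nrow(cmb)) < p
  net_from_pairs(cmb[keep, , drop = FALSE])
}

module_density <- function(members, adj) {
  k <- length(members)
  e <- sum(vapply(members, function(v)
    length(intersect(adj[[v]], members)), 0L)) / 2
  2 * e / (k * (k - 1))
}
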