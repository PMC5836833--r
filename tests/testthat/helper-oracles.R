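# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force enumeration, hand-rolled BFS,
# direct running sums.

# Binomial upper tail by exhaustive enumeration of all 2^N outcomes.
oracle_binom_tail <- function(x, N, p) {
  if (x <= 0) return(1)
  if (N == 0) return(0)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), N)))
  hits <- rowSums(outcomes)
  sum(ifelse(hits >= x, p^hits * (1 - p)^(N - hits), 0))
}

# F-Match cutoff optimization by direct threshold scan with scalar
# arithmetic (no cumulative-count trick).
oracle_optimize <- function(yes, no, seq_yes, seq_no, alpha = 0.01,
                            min_yes = 5, pseudo = 0.5) {
  thr <- sort(unique(c(yes, no)), decreasing = TRUE)
  best <- NULL
  for (t in thr) {
    sy <- sum(yes >= t); sn <- sum(no >= t)
    ratio <- (sy / ifelse(sn == 0, pseudo, sn)) / (seq_yes / seq_no)
    p <- if (sy == 0) 1 else {
      sum(stats::dbinom(sy:(sy + sn), sy + sn,
                        seq_yes / (seq_yes + seq_no)))
    }
    if (p <= alpha && sy >= min_yes) {
      cand <- list(cutoff = t, ratio = ratio, p = p)
      if (is.null(best) || ratio > best$ratio ||
          (ratio == best$ratio && p < best$p) ||
          (ratio == best$ratio && p == best$p && t > best$cutoff)) {
        best <- cand
      }
    }
  }
  best
}

# Shortest directed distances by plain queue-based BFS on an edge list.
oracle_bfs <- function(edges, from, radius) {
  dist <- c(stats::setNames(0L, from))
  frontier <- from
  for (d in seq_len(radius)) {
    nxt <- unique(edges$target[edges$source %in% frontier])
    nxt <- setdiff(nxt, names(dist))
    if (length(nxt) == 0) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist[names(dist) != from]
}

# GSEA running sum computed step by step with explicit loops.
oracle_es <- function(genes, weights, member) {
  hit <- genes %in% member
  nr <- sum(abs(weights[hit]))
  run <- 0; hi <- -Inf; lo <- Inf
  miss_step <- 1 / (length(genes) - sum(hit))
  for (i in seq_along(genes)) {
    run <- run + if (hit[i]) abs(weights[i]) / nr else -miss_step
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (hi >= -lo) hi else lo
}

# Wilcoxon U through explicit pairwise comparisons (ties count 1/2);
# exact null by enumerating every split of the pooled values.
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

oracle_wilcoxon_exact <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  na <- length(a)
  splits <- utils::combn(length(pooled), na)
  u_obs <- oracle_u(a, b)
  u_null <- apply(splits, 2, function(ix) {
    oracle_u(pooled[ix], pooled[-ix])
  })
  p_ge <- mean(u_null >= u_obs); p_le <- mean(u_null <= u_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Match-style score computed directly from the definition.
oracle_match_score <- function(counts, seq) {
  f <- sweep(counts + 0.25, 2, colSums(counts) + 1, "/")
  info <- colSums(f * log(4 * f))
  b <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  cur <- sum(info * f[cbind(b, seq_along(b))])
  mx <- sum(info * apply(f, 2, max))
  mn <- sum(info * apply(f, 2, min))
  if (mx == mn) 0 else (cur - mn) / (mx - mn)
}

tiny_pwm <- function() {
  # strongly conserved ACGT motif with a soft final column
  m <- matrix(c(
    90, 4, 3, 3,
    2, 92, 3, 3,
    1, 2, 95, 2,
    5, 5, 5, 85
  ), nrow = 4)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

# local mirror of the package-internal safe sampler (length-1 safe)
safe_sample <- function(x, size, ...) {
  x[sample.int(length(x), size, ...)]
}
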