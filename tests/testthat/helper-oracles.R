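# Independent brute-force oracles, deliberately written as plain loops
# so they share no code with the package implementations they check.

# Greedy depth-first clustering: at each step scan all unassigned
# coordinates, take the deepest (ties: transcription-proximal, then
# lowest genomic), absorb everything within the window.
oracle_cluster <- function(ends, window = 20L, strand = "+") {
  pool <- sort(ends)
  clusters <- list()
  while (length(pool) > 0L) {
    uc <- unique(pool)
    depth <- vapply(uc, function(x) sum(pool == x), 0L)
    deepest <- uc[depth == max(depth)]
    peak <- if (strand == "+") min(deepest) else max(deepest)
    members <- uc[abs(uc - peak) <= window]
    clusters[[length(clusters) + 1L]] <-
      list(peak = peak, members = sort(members),
           depth = sum(pool %in% members))
    pool <- pool[!pool %in% members]
  }
  clusters
}

# Signed KS via an explicit scan over every distinct threshold.
oracle_ks <- function(a, b) {
  ts <- sort(unique(c(a, b)))
  dplus <- 0; dminus <- 0
  for (t in ts) {
    fa <- sum(a <= t) / length(a)
    fb <- sum(b <= t) / length(b)
    if (fa - fb > dplus) dplus <- fa - fb
    if (fb - fa > dminus) dminus <- fb - fa
  }
  list(D = max(dplus, dminus),
       signed = if (dplus >= dminus) dplus else -dminus)
}

# Step-up BH by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
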