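# Internal interval utilities. All intervals are 0-based, half-open
# [start, end), stored as 2-column integer matrices with columns
# "start" and "end", sorted by start and non-overlapping after iv_merge().

iv <- function(start = integer(0), end = integer(0)) {
  stopifnot(length(start) == length(end))
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (any(m[, "end"] < m[, "start"])) stop("interval end < start")
  m
}

iv_empty <- function() iv()

# Merge overlapping or bookended intervals into a minimal sorted set.
iv_merge <- function(m) {
  if (nrow(m) == 0L) return(m)
  ir <- IRanges::reduce(IRanges::IRanges(m[, "start"] + 1L, m[, "end"]))
  iv(IRanges::start(ir) - 1L, IRanges::end(ir))
}

iv_union <- function(a, b) iv_merge(rbind(a, b))

# Is each point (0-based coordinate) inside the union of intervals?
iv_contains <- function(m, pos) {
  if (nrow(m) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= m[, "start"] & p < m[, "end"]), logical(1))
}

iv_width <- function(m) sum(m[, "end"] - m[, "start"])

# Region-level subset test: is `a` contained in the union `b`?
iv_within <- function(a, b) {
  if (nrow(a) == 0L) return(TRUE)
  if (nrow(b) == 0L) return(FALSE)
  ira <- IRanges::IRanges(a[, "start"] + 1L, a[, "end"])
  irb <- IRanges::reduce(IRanges::IRanges(b[, "start"] + 1L, b[, "end"]))
  all(IRanges::countOverlaps(ira, irb, type = "within") > 0L)
}

# Parts of `a` strictly strand-wise 3' of coordinate `pos` (0-based base).
# On "+" keeps bases > pos; on "-" keeps bases < pos.
iv_downstream_of <- function(a, pos, strand) {
  if (nrow(a) == 0L) return(a)
  out <- if (strand == "+") {
    keep <- a[, "end"] > pos + 1L
    m <- a[keep, , drop = FALSE]
    m[, "start"] <- pmax(m[, "start"], pos + 1L)
    m
  } else {
    keep <- a[, "start"] < pos
    m <- a[keep, , drop = FALSE]
    m[, "end"] <- pmin(m[, "end"], pos)
    m
  }
  iv_merge(out)
}
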