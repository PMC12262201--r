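#' Extract transcription-oriented sequences around sites
#'
#' Fetches the `-up..+down` nt window (position 0 = the site base) for
#' each site, reverse-complementing minus-strand windows, and converts
#' T to U so all sequence analysis downstream is in RNA space. Sites
#' whose window would run off a chromosome end are dropped (default) or
#' padded with N.
#'
#' @param sites A data.frame with columns `chrom`, `pos` (0-based),
#'   `strand`.
#' @param genome A `DNAStringSet`.
#' @param up,down Flank sizes in nt (defaults 100/100).
#' @param clipped One of `"drop"` (default) or `"pad"`.
#' @return Character vector of RNA sequences of length `up + 1 + down`,
#'   with attributes `up`, `down` and `n_dropped`.
#' @export
site_sequences <- function(sites, genome, up = 100L, down = 100L,
                           clipped = c("drop", "pad")) {
  clipped <- match.arg(clipped)
  stopifnot(all(c("chrom", "pos", "strand") %in% names(sites)))
  seqs <- character(0)
  n_dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- suppressMessages(
      fetch_flank(genome, sites$chrom[i], sites$pos[i], up, down,
                  sites$strand[i]))
    c5 <- attr(s, "clip5"); c3 <- attr(s, "clip3")
    if (c5 > 0L || c3 > 0L) {
      if (clipped == "drop") { n_dropped <- n_dropped + 1L; next }
      s <- paste0(strrep("N", c5), s, strrep("N", c3))
    }
    seqs <- c(seqs, chartr("T", "U", as.character(s)))
  }
  structure(seqs, up = up, down = down, n_dropped = n_dropped)
}

#' Positional nucleotide composition
#'
#' Column-wise A/C/G/U fractions over a set of equal-length oriented
#' sequences; N bases are excluded from both numerator and denominator
#' at their column, so a column covered only by N has `NA` fractions.
#'
#' @param seqs Character vector of equal-length RNA sequences (e.g. from
#'   [site_sequences()]).
#' @param center 1-based index of the site position within each
#'   sequence; defaults to the `up` attribute plus one when present,
#'   else the middle.
#' @param smooth Optional centered moving-average window (odd integer)
#'   for an additional smoothed track; `NULL` for none.
#' @return A data.frame with `position` (0 = site), fractions `A`, `C`,
#'   `G`, `U`, coverage `n`, and `A_smooth` etc. when `smooth` is set.
#' @export
nucleotide_profile <- function(seqs, center = NULL, smooth = NULL) {
  if (length(seqs) == 0L) stop("need at least one sequence")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length")
  if (is.null(center))
    center <- if (!is.null(attr(seqs, "up"))) attr(seqs, "up") + 1L
      else (L + 1L) %/% 2L
  mat <- do.call(rbind, strsplit(seqs, ""))
  prof <- data.frame(position = seq_len(L) - center)
  denom <- colSums(mat != "N")
  for (b in c("A", "C", "G", "U"))
    prof[[b]] <- ifelse(denom > 0, colSums(mat == b) / denom, NA_real_)
  prof$n <- denom
  if (!is.null(smooth)) {
    stopifnot(smooth %% 2L == 1L)
    ma <- function(x) as.numeric(stats::filter(x, rep(1 / smooth, smooth)))
    for (b in c("A", "C", "G", "U")) prof[[paste0(b, "_smooth")]] <- ma(prof[[b]])
    attr(prof, "smooth_window") <- smooth
  }
  prof
}

#' Motif incidence profile around sites
#'
#' Per position, the fraction of sequences with a motif match starting
#' there (overlapping matches all counted); optionally an aggregate:
#' the fraction of sequences with at least one match starting inside a
#' relative-position window.
#'
#' @param seqs Equal-length RNA sequences (from [site_sequences()]).
#' @param motif RNA motif over `A,C,G,U` (e.g. `"AAUAAA"`, `"UGUA"`).
#' @param window Optional `c(start, end)` of relative match-start
#'   positions for the aggregate presence fraction.
#' @param center As in [nucleotide_profile()].
#' @return List with `profile` (data.frame `position`, `fraction`),
#'   `aggregate` (or `NA` when no window given), `motif`, `window`,
#'   `n_sequences`.
#' @export
motif_incidence <- function(seqs, motif, window = NULL, center = NULL) {
  if (length(seqs) == 0L) stop("need at least one sequence")
  if (grepl("[^ACGU]", motif)) stop("motif must be over A,C,G,U: ", motif)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length")
  m <- nchar(motif)
  if (m > L) stop("motif longer than sequences")
  if (is.null(center))
    center <- if (!is.null(attr(seqs, "up"))) attr(seqs, "up") + 1L
      else (L + 1L) %/% 2L
  starts <- seq_len(L - m + 1L)
  hit <- vapply(starts, function(j)
    substr(seqs, j, j + m - 1L) == motif, logical(length(seqs)))
  hit <- matrix(hit, nrow = length(seqs))
  prof <- data.frame(position = starts - center,
                     fraction = colMeans(hit))
  aggregate <- NA_real_
  if (!is.null(window)) {
    sel <- prof$position >= window[1L] & prof$position <= window[2L]
    aggregate <- mean(rowSums(hit[, sel, drop = FALSE]) > 0)
  }
  list(profile = prof, aggregate = aggregate, motif = motif,
       window = window, n_sequences = length(seqs))
}

#' Group PASs by PAU enrichment between conditions
#'
#' Reproduces the site-group definitions used for motif comparisons:
#' among PASs whose every sample exceeds a depth floor, those with
#' delta PAU (b minus a) above `delta` are enriched in b, below
#' `-delta` enriched in a; `all_expressed` is the depth criterion
#' alone.
#'
#' @param pm A `pau_matrix` with conditions (or pass `conditions`).
#' @param condition_a,condition_b Condition labels.
#' @param delta PAU-change threshold (default 0.1).
#' @param min_reads Per-sample depth floor; a PAS qualifies only when
#'   every sample's count is strictly greater (default 20).
#' @param conditions Optional override map.
#' @return List of `pas_id` character vectors: `enriched_b`,
#'   `enriched_a`, `all_expressed`.
#' @export
group_sites <- function(pm, condition_a, condition_b, delta = 0.1,
                        min_reads = 20L, conditions = NULL) {
  stopifnot(inherits(pm, "pau_matrix"))
  dp <- delta_pau(pm, condition_a, condition_b, conditions = conditions)
  deep <- rownames(pm$counts)[apply(pm$counts > min_reads, 1L, all)]
  list(enriched_b = deep[!is.na(dp[deep]) & dp[deep] > delta],
       enriched_a = deep[!is.na(dp[deep]) & dp[deep] < -delta],
       all_expressed = deep)
}
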