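#' Count reads at called PASs
#'
#' Assigns every read to the nearest retained PAS of its gene when that
#' peak lies within `window` nt of the read's 3' end; equidistant ties
#' go to the transcription-wise proximal PAS (lower rank). Reads farther
#' than `window` nt from every retained peak are dropped and tallied per
#' gene.
#'
#' @param table A `read_end_table`.
#' @param catalog A `pas_catalog` built from the same (or a superset)
#'   read pool.
#' @param window Maximum read-to-peak distance in nt (default, the
#'   catalog's clustering window).
#' @return An integer PAS x sample matrix (rows in catalog order) with
#'   a `dropped` attribute: a named integer vector of per-gene dropped
#'   read counts.
#' @export
count_reads_at_pas <- function(table, catalog, window = NULL) {
  stopifnot(inherits(table, "read_end_table"), inherits(catalog, "pas_catalog"))
  if (is.null(window)) window <- catalog$params$window
  reads <- table$reads
  samples <- sort(unique(reads$sample_id))
  pas <- catalog$pas
  counts <- matrix(0L, nrow = nrow(pas), ncol = length(samples),
                   dimnames = list(pas$pas_id, samples))
  dropped <- integer(0)
  for (g in unique(reads$gene_id)) {
    prow <- which(pas$gene_id == g)
    ridx <- which(reads$gene_id == g)
    if (length(prow) == 0L) { dropped[g] <- length(ridx); next }
    peaks <- pas$peak[prow]                  # in rank (proximal-first) order
    ends <- reads$end3[ridx]
    dmat <- abs(outer(ends, peaks, "-"))
    nearest <- apply(dmat, 1L, which.min)    # ties -> first = proximal rank
    mind <- dmat[cbind(seq_along(ends), nearest)]
    ok <- mind <= window
    dropped[g] <- sum(!ok)
    if (any(ok)) {
      tt <- table(factor(prow[nearest[ok]], levels = prow),
                  factor(reads$sample_id[ridx][ok], levels = samples))
      counts[prow, ] <- counts[prow, ] + matrix(as.integer(tt), nrow = length(prow))
    }
  }
  attr(counts, "dropped") <- dropped
  counts
}

#' Compute per-sample PAS usage (PAU)
#'
#' PAU of a PAS in a sample is its read count divided by the sample's
#' total over the gene's retained PASs. A gene-sample with fewer than
#' `min_gene_reads` total reads is considered too shallow: its PAU
#' values are set to `NA` (ineligible) while the counts are kept.
#'
#' @param counts Integer PAS x sample matrix from [count_reads_at_pas()].
#' @param catalog The `pas_catalog` the counts refer to.
#' @param min_gene_reads Minimum per-gene per-sample depth for PAU
#'   (default 10).
#' @param conditions Optional sample-to-condition map carried along.
#' @return A `pau_matrix`: list with `counts`, `pau` (same shape, NA
#'   where ineligible), `gene_totals` (gene x sample), `gene` (gene of
#'   each PAS row), `conditions`, `min_gene_reads`.
#' @export
compute_pau <- function(counts, catalog, min_gene_reads = 10L,
                        conditions = NULL) {
  stopifnot(inherits(catalog, "pas_catalog"))
  gene <- catalog$pas$gene_id[match(rownames(counts), catalog$pas$pas_id)]
  if (anyNA(gene)) stop("counts rows do not match catalog PAS ids")
  gt <- rowsum(counts, gene)
  totals <- gt[gene, , drop = FALSE]
  pau <- counts / totals
  pau[totals < min_gene_reads] <- NA_real_
  pau[is.nan(pau)] <- NA_real_
  structure(list(counts = counts, pau = pau, gene_totals = gt, gene = gene,
                 conditions = conditions, min_gene_reads = min_gene_reads),
            class = "pau_matrix")
}

#' @export
print.pau_matrix <- function(x, ...) {
  elig <- colSums(!is.na(x$pau))
  cat(sprintf("pau_matrix: %d PASs x %d samples (%d genes, min depth %d)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$gene)),
              x$min_gene_reads))
  cat("  eligible PAS-samples per sample:",
      paste(sprintf("%s=%d", names(elig), elig), collapse = ", "), "\n")
  invisible(x)
}

#' Per-PAS PAU change between conditions
#'
#' Delta PAU = mean PAU in condition `condition_b` minus mean PAU in
#' `condition_a`, means taken over depth-eligible samples only. `NA`
#' when a condition has no eligible sample for the gene.
#'
#' @param pm A `pau_matrix` whose `conditions` map covers both
#'   conditions (or pass `conditions`).
#' @param condition_a,condition_b Condition labels (change is b minus a).
#' @param conditions Optional override of the stored map.
#' @return Named numeric vector of delta PAU per PAS (catalog order).
#' @export
delta_pau <- function(pm, condition_a, condition_b, conditions = NULL) {
  stopifnot(inherits(pm, "pau_matrix"))
  cond <- if (is.null(conditions)) pm$conditions else conditions
  if (is.null(cond)) stop("no sample-to-condition map available")
  sa <- names(cond)[cond == condition_a]
  sb <- names(cond)[cond == condition_b]
  sa <- intersect(sa, colnames(pm$pau)); sb <- intersect(sb, colnames(pm$pau))
  if (length(sa) == 0L || length(sb) == 0L)
    stop("conditions not found among samples")
  ma <- rowMeans(pm$pau[, sa, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(pm$pau[, sb, drop = FALSE], na.rm = TRUE)
  ma[!is.finite(ma)] <- NA_real_; mb[!is.finite(mb)] <- NA_real_
  mb - ma
}

#' Write count and PAU matrices to TSV
#'
#' @param pm A `pau_matrix`.
#' @param counts_path,pau_path,long_path Output paths (`NULL` skips).
#'   `long_path` writes a long-format table with condition labels.
#' @return Invisibly, the written paths.
#' @export
write_pau_matrix <- function(pm, counts_path = NULL, pau_path = NULL,
                             long_path = NULL) {
  stopifnot(inherits(pm, "pau_matrix"))
  wide <- function(m) cbind(data.frame(pas_id = rownames(m),
                                       gene_id = pm$gene), as.data.frame(m))
  if (!is.null(counts_path))
    utils::write.table(wide(pm$counts), counts_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(pau_path))
    utils::write.table(wide(pm$pau), pau_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(long_path)) {
    df <- expand.grid(pas_id = rownames(pm$counts),
                      sample_id = colnames(pm$counts),
                      stringsAsFactors = FALSE)
    df$gene_id <- pm$gene[match(df$pas_id, rownames(pm$counts))]
    df$count <- pm$counts[cbind(df$pas_id, df$sample_id)]
    df$pau <- pm$pau[cbind(df$pas_id, df$sample_id)]
    df$condition <- if (!is.null(pm$conditions))
      unname(pm$conditions[df$sample_id]) else NA_character_
    utils::write.table(df, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(counts = counts_path, pau = pau_path, long = long_path))
}
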