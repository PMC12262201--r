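#' Construct a read-end table
#'
#' The central per-read container: one row per uniquely gene-assigned
#' read with the genomic coordinate of its 3'-terminal aligned base
#' (0-based), the host gene, and the sample it came from. Strand is the
#' host gene's strand.
#'
#' @param reads A data.frame with columns `read_id`, `gene_id`, `chrom`,
#'   `strand`, `end3`, `sample_id`.
#' @param conditions Optional named character vector mapping
#'   `sample_id` to a condition label; required for differential
#'   analysis.
#' @return A `read_end_table` object.
#' @export
read_end_table <- function(reads, conditions = NULL) {
  req <- c("read_id", "gene_id", "chrom", "strand", "end3", "sample_id")
  missing_cols <- setdiff(req, names(reads))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  reads <- as.data.frame(reads)[, req]
  rownames(reads) <- NULL
  if (!is.numeric(reads$end3) || any(reads$end3 != floor(reads$end3)))
    stop("end3 must be integer genomic coordinates")
  reads$end3 <- as.integer(reads$end3)
  if (any(reads$end3 < 0L)) stop("end3 must be >= 0")
  if (!all(reads$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'; found: ",
         paste(unique(setdiff(reads$strand, c("+", "-"))), collapse = ", "))
  dup <- duplicated(reads[, c("sample_id", "read_id")])
  if (any(dup))
    stop("duplicated read_id within a sample (reads must be uniquely ",
         "assigned): e.g. ", reads$read_id[which(dup)[1L]])
  if (!is.null(conditions)) {
    if (is.null(names(conditions)))
      stop("conditions must be a named vector (sample_id -> condition)")
    missing_smp <- setdiff(unique(reads$sample_id), names(conditions))
    if (length(missing_smp))
      stop("samples without a condition label: ",
           paste(missing_smp, collapse = ", "))
  }
  structure(list(reads = reads, conditions = conditions),
            class = "read_end_table")
}

#' @export
print.read_end_table <- function(x, ...) {
  cat(sprintf("read_end_table: %d reads, %d genes, %d sample(s)\n",
              nrow(x$reads), length(unique(x$reads$gene_id)),
              length(unique(x$reads$sample_id))))
  if (!is.null(x$conditions))
    cat("  conditions:", paste(sprintf("%s=%s", names(x$conditions),
                                       x$conditions), collapse = ", "), "\n")
  invisible(x)
}

#' Load a read-end table from TSV
#'
#' @param tsv Path to a tab-separated file with header columns
#'   `read_id`, `gene_id`, `chrom`, `strand`, `end3`, `sample_id`.
#' @param conditions Optional sample-to-condition map, see
#'   [read_end_table()].
#' @return A `read_end_table`.
#' @export
load_read_end_table <- function(tsv, conditions = NULL) {
  if (!file.exists(tsv)) stop("read-end TSV not found: ", tsv)
  df <- utils::read.table(tsv, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  req <- c("read_id", "gene_id", "chrom", "strand", "end3", "sample_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", tsv, ": ",
         paste(missing_cols, collapse = ", "))
  bad <- grepl("\\D", df$end3)
  if (any(bad))
    stop(sprintf("non-integer end3 at line %d of %s", which(bad)[1L] + 1L, tsv))
  df$end3 <- as.integer(df$end3)
  read_end_table(df, conditions)
}

#' Write a read-end table to TSV
#'
#' @param x A `read_end_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_read_end_table <- function(x, path) {
  stopifnot(inherits(x, "read_end_table"))
  utils::write.table(x$reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Combine per-sample read-end tables
#'
#' @param ... `read_end_table` objects (or a single list of them).
#' @param conditions Optional sample-to-condition map applied to the
#'   combined table (overrides any maps on the inputs).
#' @return A `read_end_table`.
#' @export
bind_read_ends <- function(..., conditions = NULL) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "read_end_table")) xs <- xs[[1L]]
  reads <- do.call(rbind, lapply(xs, function(x) x$reads))
  if (is.null(conditions)) {
    maps <- lapply(xs, `[[`, "conditions")
    maps <- maps[!vapply(maps, is.null, logical(1))]
    if (length(maps)) conditions <- do.call(c, maps)
  }
  read_end_table(reads, conditions)
}

#' Extract read 3' ends from a BAM plus gene assignments
#'
#' Takes primary alignments from a coordinate-sorted indexed BAM and an
#' IsoQuant-style read-to-gene assignment TSV, and records each uniquely
#' assigned read's 3'-terminal aligned reference base: the last aligned
#' base for genes on `+`, the first aligned base for genes on `-`
#' (long-read cDNA may align antisense, so orientation comes from the
#' assigned gene, not the alignment flag). Soft-clipped bases are never
#' counted. Secondary and supplementary alignments are skipped; reads
#' assigned non-uniquely, absent from the BAM, or assigned to genes
#' missing from `models` are dropped with counts reported via message.
#'
#' @param bam Path to a coordinate-sorted BAM with a `.bai` index.
#' @param assignments Path to a TSV with columns `read_id`, `gene_id`
#'   and optionally `assignment_type` (only rows whose type starts with
#'   `"unique"` are kept, as in IsoQuant read_assignments output;
#'   comment lines starting with `#` are ignored).
#' @param sample_id Sample label stored on every record.
#' @param models `gene_models` supplying each gene's strand and chrom.
#' @return A `read_end_table` for this sample (no condition map).
#' @export
extract_read_ends <- function(bam, assignments, sample_id, models) {
  if (!file.exists(bam)) stop("BAM not found: ", bam)
  if (!file.exists(assignments)) stop("assignment TSV not found: ", assignments)
  asn <- utils::read.table(assignments, sep = "\t", header = TRUE,
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE)
  if (!all(c("read_id", "gene_id") %in% names(asn)))
    stop("assignment TSV needs read_id and gene_id columns")
  n0 <- nrow(asn)
  if ("assignment_type" %in% names(asn))
    asn <- asn[startsWith(asn$assignment_type, "unique"), , drop = FALSE]
  # a read listed for several genes is ambiguous even if each row says unique
  multi <- asn$read_id %in% asn$read_id[duplicated(asn$read_id)]
  asn <- asn[!multi, , drop = FALSE]
  n_dropped_assign <- n0 - nrow(asn)

  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE),
    what = "qname")
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  qname <- S4Vectors::mcols(aln)$qname
  aln_first <- !duplicated(qname)
  aln <- aln[aln_first]
  qname <- qname[aln_first]
  idx <- match(asn$read_id, qname)
  n_missing_bam <- sum(is.na(idx))
  keep <- !is.na(idx)
  asn <- asn[keep, , drop = FALSE]
  idx <- idx[keep]

  known <- asn$gene_id %in% names(models)
  n_unknown_gene <- sum(!known)
  asn <- asn[known, , drop = FALSE]
  idx <- idx[known]

  gstrand <- vapply(models[asn$gene_id], `[[`, "", "strand")
  gchrom <- vapply(models[asn$gene_id], `[[`, "", "chrom")
  astart <- GenomicAlignments::start(aln)[idx] - 1L       # first aligned base
  aend <- GenomicAlignments::end(aln)[idx] - 1L           # last aligned base
  end3 <- ifelse(gstrand == "+", aend, astart)

  if (n_dropped_assign || n_missing_bam || n_unknown_gene)
    message(sprintf(paste0("extract_read_ends(%s): dropped %d non-unique/",
                           "ambiguous assignments, %d reads absent from BAM, ",
                           "%d reads with unknown gene"),
                    sample_id, n_dropped_assign, n_missing_bam, n_unknown_gene))

  read_end_table(data.frame(
    read_id = asn$read_id, gene_id = asn$gene_id, chrom = gchrom,
    strand = gstrand, end3 = as.integer(end3), sample_id = sample_id,
    stringsAsFactors = FALSE))
}
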