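#' Parse gene models from a GTF annotation
#'
#' Reads a GENCODE-dialect GTF and builds one gene model per `gene`
#' feature: exon/CDS/3'UTR interval sets, the union of per-transcript
#' last exons, and the stop-codon position. All coordinates are stored
#' 0-based half-open; GTF input (1-based inclusive) is converted at this
#' boundary. The 3'UTR is derived from the annotated CDS/stop codon (the
#' exonic region strand-wise 3' of the stop), so genes lacking a CDS get
#' an empty 3'UTR and no stop-codon position.
#'
#' @param gtf_path Path to a GTF file with at least `gene` and `exon`
#'   features; `CDS` and `stop_codon` features are used when present.
#' @return A named list of gene models (class `gene_models`). Each model
#'   is a list with `gene_id`, `gene_name`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open gene span), and interval matrices
#'   `exons`, `cds`, `utr3`, `last_exon_union`, plus `stop_codon_pos`
#'   (0-based coordinate of the strand-wise 3'-most stop-codon base, or
#'   `NA` for non-coding genes).
#' @export
parse_gene_models <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  .check_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id)) stop("GTF has no gene_id attributes")
  type <- as.character(mc$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  gene_id <- as.character(mc$gene_id)
  gene_name <- if (!is.null(mc$gene_name)) as.character(mc$gene_name) else gene_id
  tx_id <- if (!is.null(mc$transcript_id)) as.character(mc$transcript_id) else
    rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  gids <- unique(gene_id[is_gene])
  if (length(gids) == 0L) gids <- unique(gene_id)

  models <- vector("list", length(gids))
  names(models) <- gids
  for (g in gids) {
    sel <- gene_id == g
    gstrand <- unique(strand[sel & is_gene])
    if (length(gstrand) == 0L) gstrand <- unique(strand[sel])
    gstrand <- gstrand[1L]
    if (!gstrand %in% c("+", "-")) {
      warning("gene ", g, " has strand '", gstrand, "'; skipped")
      next
    }
    gchrom <- chrom[sel][1L]
    exon_sel <- sel & type == "exon"
    cds_sel <- sel & type == "CDS"
    stop_sel <- sel & type == "stop_codon"

    exons <- iv_merge(iv(start0[exon_sel], end0[exon_sel]))
    cds <- iv_merge(iv(start0[cds_sel], end0[cds_sel]))

    # per-transcript structures: last exon and stop position
    txs <- unique(stats::na.omit(tx_id[exon_sel]))
    last_ex <- iv_empty()
    utr3 <- iv_empty()
    stop_pos <- NA_integer_
    if (length(txs) == 0L && any(exon_sel)) {
      # exons without transcript ids: treat the gene as one transcript
      txs <- NA_character_
    }
    for (tx in txs) {
      tsel <- if (is.na(tx)) exon_sel else exon_sel & tx_id == tx
      if (!any(tsel)) {
        warning("transcript ", tx, " of gene ", g, " has no exons; skipped")
        next
      }
      tex <- iv(start0[tsel], end0[tsel])
      tex <- tex[order(tex[, "start"]), , drop = FALSE]
      le <- if (gstrand == "+") tex[nrow(tex), , drop = FALSE] else
        tex[1L, , drop = FALSE]
      last_ex <- iv_union(last_ex, le)
      # transcript stop: 3'-most stop_codon base, else 3'-most CDS base
      ssel <- if (is.na(tx)) stop_sel else stop_sel & tx_id == tx
      csel <- if (is.na(tx)) cds_sel else cds_sel & tx_id == tx
      tstop <- NA_integer_
      if (any(ssel)) {
        tstop <- if (gstrand == "+") max(end0[ssel]) - 1L else min(start0[ssel])
      } else if (any(csel)) {
        tstop <- if (gstrand == "+") max(end0[csel]) - 1L else min(start0[csel])
      }
      if (!is.na(tstop)) {
        utr3 <- iv_union(utr3, iv_downstream_of(iv_merge(tex), tstop, gstrand))
        stop_pos <- if (is.na(stop_pos)) tstop
          else if (gstrand == "+") max(stop_pos, tstop) else min(stop_pos, tstop)
      }
    }

    gstart <- if (any(sel & is_gene)) min(start0[sel & is_gene]) else
      min(start0[sel])
    gend <- if (any(sel & is_gene)) max(end0[sel & is_gene]) else max(end0[sel])

    models[[g]] <- structure(list(
      gene_id = g,
      gene_name = gene_name[sel][1L],
      chrom = gchrom,
      strand = gstrand,
      start = as.integer(gstart),
      end = as.integer(gend),
      exons = exons,
      cds = cds,
      utr3 = utr3,
      last_exon_union = last_ex,
      stop_codon_pos = as.integer(stop_pos)
    ), class = "gene_model")
  }
  models <- models[!vapply(models, is.null, logical(1))]
  structure(models, class = "gene_models")
}

# Cheap structural pre-scan so malformed lines are reported by number.
.check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1L]]
    stop(sprintf("malformed GTF line %d in %s: expected 9 tab-separated fields",
                 bad, path))
  }
  invisible(TRUE)
}

#' @export
print.gene_models <- function(x, ...) {
  ncod <- sum(vapply(x, function(m) !is.na(m$stop_codon_pos), logical(1)))
  cat(sprintf("gene_models: %d genes (%d coding) on %d sequence(s)\n",
              length(x), ncod,
              length(unique(vapply(x, `[[`, "", "chrom")))))
  invisible(x)
}

#' Write gene models back to GTF
#'
#' Single-transcript export: each gene is written as one transcript
#' carrying the gene's merged exon set, its CDS intervals, and a 3-nt
#' stop codon ending at `stop_codon_pos`. Coordinates are converted back
#' to the 1-based inclusive GTF convention.
#'
#' @param models A `gene_models` object.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  lines <- character(0)
  fmt <- function(chrom, feat, s0, e0, strand, attrs) {
    sprintf("%s\tlongapa\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, s0 + 1L, e0, strand, attrs)
  }
  for (m in models) {
    at <- sprintf('gene_id "%s"; gene_name "%s";', m$gene_id, m$gene_name)
    att <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s.t1";',
                   m$gene_id, m$gene_name, m$gene_id)
    lines <- c(lines, fmt(m$chrom, "gene", m$start, m$end, m$strand, at),
               fmt(m$chrom, "transcript", m$start, m$end, m$strand, att))
    ex <- m$exons
    for (i in seq_len(nrow(ex)))
      lines <- c(lines, fmt(m$chrom, "exon", ex[i, 1L], ex[i, 2L], m$strand, att))
    cd <- m$cds
    for (i in seq_len(nrow(cd)))
      lines <- c(lines, fmt(m$chrom, "CDS", cd[i, 1L], cd[i, 2L], m$strand, att))
    if (!is.na(m$stop_codon_pos)) {
      sp <- m$stop_codon_pos
      if (m$strand == "+")
        lines <- c(lines, fmt(m$chrom, "stop_codon", sp - 2L, sp + 1L, m$strand, att))
      else
        lines <- c(lines, fmt(m$chrom, "stop_codon", sp, sp + 3L, m$strand, att))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a reference PAS set from BED
#'
#' Reads a BED6-style file of annotated polyadenylation sites (for
#' example a PolyA_DB export). The PAS coordinate is taken as the
#' strand-wise 3' base of each interval; entries are deduplicated and
#' sorted ascending per chromosome and strand. The BED name column, when
#' not ".", is kept as an optional host-gene label used for
#' same-host-gene concordance when classifying called PASs.
#'
#' @param bed_path Path to a BED file with a strand column.
#' @return A `pas_reference` object.
#' @export
load_reference_pas <- function(bed_path) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  df <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 6L)
    stop("reference PAS BED must have 6 columns including strand")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(df$strand %in% c("+", "-")))
    stop("reference PASs are strand-specific; found strand values: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  coord <- ifelse(df$strand == "+", df$end - 1L, df$start)
  sites <- data.frame(chrom = df$chrom, strand = df$strand,
                      coord = as.integer(coord),
                      name = ifelse(df$name == ".", NA_character_, df$name),
                      stringsAsFactors = FALSE)
  sites <- unique(sites)
  sites <- sites[order(sites$chrom, sites$strand, sites$coord), , drop = FALSE]
  rownames(sites) <- NULL
  key <- paste(sites$chrom, sites$strand)
  structure(list(
    sites = sites,
    coords = lapply(split(sites$coord, key), function(x) sort(unique(x))),
    labels = split(sites[, c("coord", "name")], key)
  ), class = "pas_reference")
}

#' @export
print.pas_reference <- function(x, ...) {
  cat(sprintf("pas_reference: %d sites on %d chrom/strand combinations\n",
              nrow(x$sites), length(x$coords)))
  invisible(x)
}
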