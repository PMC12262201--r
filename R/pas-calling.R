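#' Greedy depth-first clustering of read 3' ends
#'
#' Repeatedly selects the unassigned coordinate carrying the most reads
#' as a peak and absorbs all unassigned coordinates within `window` nt
#' on either side, until every end is assigned. Depth ties are broken
#' toward the transcription-wise proximal coordinate (the lower genomic
#' coordinate on `+`, the higher on `-`), then toward the lower genomic
#' coordinate, so clustering is deterministic.
#'
#' @param ends Integer vector (multiset) of 3'-end coordinates for one
#'   gene, pooled over samples.
#' @param window Maximum distance (nt) from a peak for an end to join
#'   its cluster; default 20.
#' @param strand Gene strand, used only for the tie-break.
#' @return A list of clusters, each a list with `peak` (coordinate of
#'   the maximum-depth position), `members` (sorted unique member
#'   coordinates) and `depth` (total reads in the cluster). Empty input
#'   gives an empty list.
#' @export
cluster_read_ends <- function(ends, window = 20L, strand = "+") {
  if (length(ends) == 0L) return(list())
  stopifnot(window >= 0L)
  tab <- table(ends)
  coord <- as.integer(names(tab))
  depth <- as.integer(tab)
  unassigned <- rep(TRUE, length(coord))
  out <- list()
  while (any(unassigned)) {
    cand <- which(unassigned)
    d <- depth[cand]
    top <- cand[d == max(d)]
    peak <- if (strand == "+") coord[top][which.min(coord[top])] else
      coord[top][which.max(coord[top])]
    mem <- cand[abs(coord[cand] - peak) <= window]
    out[[length(out) + 1L]] <- list(peak = peak,
                                    members = coord[mem],
                                    depth = sum(depth[mem]))
    unassigned[mem] <- FALSE
  }
  out
}

#' Call polyadenylation sites per gene
#'
#' Pools read 3' ends across all samples, clusters them per gene with
#' [cluster_read_ends()], and keeps peaks whose overall PAU (fraction of
#' the gene's pooled reads) is at least `min_overall_pau`. Retained PASs
#' are ranked proximal to distal in transcription orientation and, when
#' a reference set / genome are supplied, classified against annotated
#' PASs, located within the gene structure, and flagged for potential
#' internal priming. Overall PAU is not renormalised after filtering: it
#' stays the fraction of all pooled reads of the gene.
#'
#' @param table A `read_end_table` (all samples).
#' @param models `gene_models` from [parse_gene_models()].
#' @param min_overall_pau Minimum overall PAU to retain a peak
#'   (default 0.01; a peak at exactly the cutoff is retained).
#' @param window Clustering window in nt (default 20).
#' @param ref Optional `pas_reference` for match/proximity/novel calls.
#' @param genome Optional `DNAStringSet` for internal-priming flagging.
#' @param max_ref_dist Maximum distance (nt) for the `proximity` class.
#' @param ip_window,ip_min_a Internal-priming rule: flag when either
#'   10-nt flank immediately 5' or 3' of the peak carries at least
#'   `ip_min_a` adenosines on the sense strand (defaults 10 and 7,
#'   i.e. strictly more than 6 A).
#' @return A `pas_catalog`: list with `pas` (one row per retained PAS:
#'   `pas_id`, `gene_id`, `chrom`, `strand`, `peak`, `rank`, `depth`,
#'   `overall_pau`, `ref_class`, `ref_distance`, `region`,
#'   `internal_priming`), `counts` (PAS x sample matrix of supporting
#'   reads from cluster membership), `gene_totals_pooled`, `params`.
#' @export
call_pas <- function(table, models, min_overall_pau = 0.01, window = 20L,
                     ref = NULL, genome = NULL, max_ref_dist = 20L,
                     ip_window = 10L, ip_min_a = 7L) {
  stopifnot(inherits(table, "read_end_table"))
  reads <- table$reads
  samples <- sort(unique(reads$sample_id))
  gene_split <- split(seq_len(nrow(reads)), reads$gene_id)

  unknown <- setdiff(names(gene_split), names(models))
  if (length(unknown)) {
    warning(length(unknown), " gene(s) absent from models skipped: ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ..." else "")
    gene_split <- gene_split[setdiff(names(gene_split), unknown)]
  }

  rows <- list()
  cnts <- list()
  totals <- integer(0)
  for (g in names(gene_split)) {
    idx <- gene_split[[g]]
    m <- models[[g]]
    ends <- reads$end3[idx]
    total <- length(ends)
    cl <- cluster_read_ends(ends, window = window, strand = m$strand)
    peak <- vapply(cl, `[[`, 0L, "peak")
    depth <- vapply(cl, `[[`, 0L, "depth")
    pau <- depth / total
    keep <- which(pau >= min_overall_pau)
    if (length(keep) == 0L) next
    cl <- cl[keep]; peak <- peak[keep]; depth <- depth[keep]; pau <- pau[keep]
    ord <- if (m$strand == "+") order(peak) else order(-peak)
    cl <- cl[ord]; peak <- peak[ord]; depth <- depth[ord]; pau <- pau[ord]
    k <- length(peak)
    # per-sample supporting counts from cluster membership
    cmat <- matrix(0L, nrow = k, ncol = length(samples),
                   dimnames = list(NULL, samples))
    smp <- reads$sample_id[idx]
    for (i in seq_len(k)) {
      inmem <- ends %in% cl[[i]]$members
      tt <- table(factor(smp[inmem], levels = samples))
      cmat[i, ] <- as.integer(tt)
    }
    ref_class <- rep(NA_character_, k); ref_distance <- rep(NA_integer_, k)
    if (!is.null(ref)) {
      for (i in seq_len(k)) {
        rc <- classify_vs_reference(m$chrom, m$strand, peak[i], g, ref,
                                    max_dist = max_ref_dist)
        ref_class[i] <- rc$ref_class; ref_distance[i] <- rc$ref_distance
      }
    }
    region <- vapply(peak, annotate_region, "", model = m)
    ip <- rep(NA, k)
    if (!is.null(genome))
      ip <- vapply(peak, function(p)
        flag_internal_priming(genome, m$chrom, p, m$strand,
                              window = ip_window, min_a = ip_min_a),
        logical(1))
    rows[[g]] <- data.frame(
      pas_id = sprintf("%s:PAS%d", g, seq_len(k)),
      gene_id = g, chrom = m$chrom, strand = m$strand,
      peak = peak, rank = seq_len(k), depth = depth, overall_pau = pau,
      ref_class = ref_class, ref_distance = ref_distance,
      region = region, internal_priming = ip,
      stringsAsFactors = FALSE)
    cnts[[g]] <- cmat
    totals[g] <- total
  }
  pas <- do.call(rbind, rows)
  counts <- do.call(rbind, cnts)
  if (is.null(pas)) {
    pas <- data.frame(pas_id = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      peak = integer(0), rank = integer(0),
                      depth = integer(0), overall_pau = numeric(0),
                      ref_class = character(0), ref_distance = integer(0),
                      region = character(0), internal_priming = logical(0))
    counts <- matrix(0L, 0L, length(samples), dimnames = list(NULL, samples))
  }
  rownames(pas) <- pas$pas_id
  rownames(counts) <- pas$pas_id
  structure(list(pas = pas, counts = counts, gene_totals_pooled = totals,
                 params = list(window = window,
                               min_overall_pau = min_overall_pau,
                               max_ref_dist = max_ref_dist,
                               ip_window = ip_window, ip_min_a = ip_min_a)),
            class = "pas_catalog")
}

#' @export
print.pas_catalog <- function(x, ...) {
  cat(sprintf("pas_catalog: %d PASs in %d genes (window=%d nt, min PAU=%g)\n",
              nrow(x$pas), length(unique(x$pas$gene_id)),
              x$params$window, x$params$min_overall_pau))
  if (!all(is.na(x$pas$ref_class)))
    print(table(ref_class = x$pas$ref_class))
  invisible(x)
}

#' Classify a called PAS against a reference PAS set
#'
#' A PAS at zero distance from a reference site whose host-gene label is
#' compatible (absent, or equal to `gene_id`) is a `match`; otherwise a
#' PAS within `max_dist` nt of any reference site is `proximity`, with
#' the signed transcription-oriented distance to the nearest site
#' recorded (positive = reference lies 3' of the peak); anything farther
#' is `novel`.
#'
#' @param chrom,strand,peak Location of the called peak (0-based).
#' @param gene_id Host gene of the peak.
#' @param ref A `pas_reference`.
#' @param max_dist Proximity window in nt (default 20).
#' @return List with `ref_class` and `ref_distance` (NA when novel).
#' @export
classify_vs_reference <- function(chrom, strand, peak, gene_id, ref,
                                  max_dist = 20L) {
  key <- paste(chrom, strand)
  coords <- ref$coords[[key]]
  if (is.null(coords) || length(coords) == 0L)
    return(list(ref_class = "novel", ref_distance = NA_integer_))
  i <- findInterval(peak, coords)
  cand <- coords[unique(pmin(pmax(c(i, i + 1L), 1L), length(coords)))]
  d <- abs(cand - peak)
  nearest <- cand[which.min(d)]
  dist <- min(d)
  if (dist == 0L) {
    lab <- ref$labels[[key]]
    nm <- lab$name[lab$coord == peak]
    if (all(is.na(nm)) || gene_id %in% nm)
      return(list(ref_class = "match", ref_distance = 0L))
    # positional coincidence with another gene's site: proximity at 0 nt
    return(list(ref_class = "proximity", ref_distance = 0L))
  }
  if (dist <= max_dist) {
    signed <- if (strand == "+") nearest - peak else peak - nearest
    return(list(ref_class = "proximity", ref_distance = as.integer(signed)))
  }
  list(ref_class = "novel", ref_distance = NA_integer_)
}

#' Locate a PAS peak within the gene structure
#'
#' Labels by priority `utr3_exon` > `cds_exon` > `intron` > `downstream`
#' (strand-wise 3' of the gene span) > `other` (upstream, or exonic but
#' neither 3'UTR nor CDS), testing membership against the unions of the
#' respective annotated intervals.
#'
#' @param peak 0-based peak coordinate.
#' @param model A `gene_model`.
#' @return One of `"utr3_exon"`, `"cds_exon"`, `"intron"`,
#'   `"downstream"`, `"other"`.
#' @export
annotate_region <- function(peak, model) {
  if (iv_contains(model$utr3, peak)) return("utr3_exon")
  if (iv_contains(model$cds, peak)) return("cds_exon")
  in_span <- peak >= model$start && peak < model$end
  if (in_span && !iv_contains(model$exons, peak)) return("intron")
  if ((model$strand == "+" && peak >= model$end) ||
      (model$strand == "-" && peak < model$start)) return("downstream")
  "other"
}

#' Flag a PAS peak as a potential internal-priming artifact
#'
#' Oligo-dT priming on genomically encoded A-rich stretches produces
#' false 3' ends. A peak is flagged when the 10-nt sense-strand window
#' immediately 5' of the peak or immediately 3' of the peak (the peak
#' base itself excluded) contains strictly more than 6 adenosines
#' (>= `min_a`, not necessarily consecutive). Windows clipped at
#' chromosome ends are evaluated on the available bases.
#'
#' @param genome A `DNAStringSet`.
#' @param chrom,peak,strand Peak location (0-based) and gene strand.
#' @param window Flank width in nt (default 10).
#' @param min_a Minimum A count to flag (default 7, i.e. ">6 A").
#' @return Logical scalar.
#' @export
flag_internal_priming <- function(genome, chrom, peak, strand,
                                  window = 10L, min_a = 7L) {
  up <- suppressMessages(
    fetch_flank(genome, chrom, peak, upstream = window, downstream = 0L,
                strand = strand))
  up <- substr(up, 1L, nchar(up) - 1L)                 # drop the peak base
  dn <- suppressMessages(
    fetch_flank(genome, chrom, peak, upstream = 0L, downstream = window,
                strand = strand))
  dn <- substr(dn, 2L, nchar(dn))
  count_a <- function(s) sum(strsplit(s, "")[[1]] == "A")
  count_a(up) >= min_a || count_a(dn) >= min_a
}

#' Classify a gene's APA configuration
#'
#' A gene with a single retained PAS is `single`; with two or more PASs
#' that all lie in the union of last exons (or strand-wise downstream of
#' the gene span) it is `last_exon_tandem` (pure tandem 3'UTR APA); any
#' other multi-PAS configuration (e.g. intronic plus last-exon sites) is
#' `mixed`.
#'
#' @param peaks Integer vector of retained peak coordinates for one gene.
#' @param model The gene's `gene_model`.
#' @return `"single"`, `"last_exon_tandem"`, or `"mixed"`.
#' @export
classify_gene_apa_type <- function(peaks, model) {
  if (length(peaks) <= 1L) return("single")
  in_last <- iv_contains(model$last_exon_union, peaks)
  dnstr <- if (model$strand == "+") peaks >= model$end else peaks < model$start
  if (all(in_last | dnstr)) "last_exon_tandem" else "mixed"
}

#' Write a PAS catalog to BED6+ and TSV
#'
#' @param catalog A `pas_catalog`.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_pas_catalog <- function(catalog, bed_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(catalog, "pas_catalog"))
  p <- catalog$pas
  if (!is.null(bed_path)) {
    bed <- data.frame(p$chrom, p$peak, p$peak + 1L, p$pas_id, p$depth,
                      p$strand, p$overall_pau, p$ref_class, p$ref_distance,
                      p$region, p$internal_priming)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    utils::write.table(cbind(p, catalog$counts), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}
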