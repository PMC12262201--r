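#' Per-gene APA visualisation
#'
#' Renders the three single-gene panels: per-condition density of read
#' 3' ends along the gene, per-condition cumulative PAU curves over
#' transcription-oriented 3'-end positions (monotone, ending at 1), and
#' a per-PAS bar plot of the PAU change between conditions. The arrays
#' behind each panel are returned (and optionally written as TSV) so
#' downstream checks never need to read pixels.
#'
#' @param gene_id Gene to plot (must be present in the catalog).
#' @param table A `read_end_table` with conditions (or pass
#'   `conditions`).
#' @param catalog A `pas_catalog`.
#' @param pm A `pau_matrix`.
#' @param condition_a,condition_b Condition labels (change is b - a).
#' @param file Optional PDF path; when `NULL` nothing is drawn unless
#'   `draw = TRUE` on an open device.
#' @param tsv_prefix Optional path prefix; writes
#'   `<prefix>_density.tsv`, `<prefix>_cumulative.tsv`,
#'   `<prefix>_dpau.tsv`.
#' @param conditions Optional override of the table's condition map.
#' @param draw Draw on the current device when no `file` is given.
#' @return Invisibly, a list with `density`, `cumulative` and `dpau`
#'   data.frames.
#' @export
plot_gene <- function(gene_id, table, catalog, pm, condition_a, condition_b,
                      file = NULL, tsv_prefix = NULL, conditions = NULL,
                      draw = FALSE) {
  stopifnot(inherits(table, "read_end_table"), inherits(catalog, "pas_catalog"))
  pas <- catalog$pas[catalog$pas$gene_id == gene_id, , drop = FALSE]
  if (nrow(pas) == 0L) stop("unknown gene: ", gene_id)
  cond <- if (is.null(conditions)) table$conditions else conditions
  if (is.null(cond)) stop("a sample-to-condition map is required")
  reads <- table$reads[table$reads$gene_id == gene_id, , drop = FALSE]
  reads$condition <- unname(cond[reads$sample_id])
  reads <- reads[reads$condition %in% c(condition_a, condition_b), ,
                 drop = FALSE]
  strand <- pas$strand[1L]

  # densities: read counts per coordinate, per condition
  xs <- sort(unique(reads$end3))
  dens <- data.frame(position = xs)
  for (cc in c(condition_a, condition_b)) {
    e <- reads$end3[reads$condition == cc]
    cnt <- as.integer(table(factor(e, levels = xs)))
    dens[[cc]] <- if (length(e)) cnt / length(e) else 0
  }

  # cumulative PAU over oriented positions
  ox <- sort(unique(oriented_positions(reads$end3, strand)))
  cum <- data.frame(oriented_position = ox)
  for (cc in c(condition_a, condition_b)) {
    e <- oriented_positions(reads$end3[reads$condition == cc], strand)
    cum[[cc]] <- if (length(e)) stats::ecdf(e)(ox) else NA_real_
  }

  dp <- delta_pau(pm, condition_a, condition_b, conditions = cond)
  dpau <- data.frame(pas_id = pas$pas_id, rank = pas$rank, peak = pas$peak,
                     delta_pau = unname(dp[pas$pas_id]))

  if (!is.null(tsv_prefix)) {
    utils::write.table(dens, paste0(tsv_prefix, "_density.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cum, paste0(tsv_prefix, "_cumulative.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dpau, paste0(tsv_prefix, "_dpau.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(file) || draw) {
    if (!is.null(file)) {
      grDevices::pdf(file, width = 7, height = 9)
      on.exit(grDevices::dev.off())
    }
    graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
    cols <- c("grey30", "firebrick")
    graphics::matplot(dens$position, as.matrix(dens[, -1L]), type = "h",
                      lty = 1, col = grDevices::adjustcolor(cols, 0.6),
                      xlab = sprintf("genomic position (%s)", strand),
                      ylab = "3'-end density", main = gene_id)
    graphics::abline(v = pas$peak, lty = 3)
    graphics::legend("topright", legend = c(condition_a, condition_b),
                     col = cols, lty = 1, bty = "n")
    graphics::matplot(cum$oriented_position, as.matrix(cum[, -1L]),
                      type = "s", lty = 1, col = cols,
                      xlab = "oriented 3'-end position",
                      ylab = "cumulative fraction")
    graphics::barplot(dpau$delta_pau, names.arg = dpau$pas_id, las = 2,
                      col = ifelse(dpau$delta_pau >= 0, "firebrick",
                                   "steelblue"),
                      ylab = sprintf("PAU change (%s - %s)", condition_b,
                                     condition_a))
  }
  invisible(list(density = dens, cumulative = cum, dpau = dpau))
}

#' Transcriptome-wide APA volcano plot
#'
#' APA change versus `-log10` q-value, points coloured by the direction
#' call (lengthening red, shortening blue) at the thresholds stored on
#' the result set.
#'
#' @param gene_results A non-empty `gene_apa_results`.
#' @param file Optional PDF path.
#' @param draw Draw on the current device when no `file` is given.
#' @return Invisibly, the plotted data.frame (`gene_id`, `apa_change`,
#'   `neg_log10_q`, `direction`).
#' @export
plot_volcano <- function(gene_results, file = NULL, draw = FALSE) {
  if (is.null(gene_results) || nrow(gene_results) == 0L)
    stop("no gene-level results to plot")
  alpha <- attr(gene_results, "alpha"); tau <- attr(gene_results, "tau")
  df <- data.frame(gene_id = gene_results$gene_id,
                   apa_change = gene_results$apa_change,
                   neg_log10_q = -log10(pmax(gene_results$qvalue, 1e-300)),
                   direction = gene_results$direction)
  if (!is.null(file) || draw) {
    if (!is.null(file)) {
      grDevices::pdf(file, width = 6, height = 5)
      on.exit(grDevices::dev.off())
    }
    cols <- c(lengthening = "firebrick", shortening = "steelblue",
              none = "grey60")
    graphics::plot(df$apa_change, df$neg_log10_q, pch = 16, cex = 0.6,
                   col = cols[df$direction], xlim = c(-1, 1),
                   xlab = "APA change", ylab = "-log10 adjusted p")
    graphics::abline(v = c(-tau, tau), h = -log10(alpha), lty = 3)
  }
  invisible(df)
}
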