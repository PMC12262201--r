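#' Orient 3'-end coordinates along transcription
#'
#' Maps genomic coordinates so that larger oriented values are always
#' more distal (3'): identity on `+`, negation on `-`.
#'
#' @param ends Numeric vector of 3'-end coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Oriented coordinates.
#' @export
oriented_positions <- function(ends, strand) {
  stopifnot(strand %in% c("+", "-"))
  if (strand == "+") ends else -ends
}

#' Signed two-sample Kolmogorov-Smirnov shift statistic
#'
#' Compares the empirical CDFs of two multisets of transcription-
#' oriented 3'-end positions. With `D+ = max(F_a - F_b)` and
#' `D- = max(F_b - F_a)` evaluated at all distinct positions, the APA
#' change is `D+` when `D+ >= D-` and `-D-` otherwise, so a positive
#' value means condition b's 3' ends are stochastically larger — a
#' distal shift, i.e. 3'UTR lengthening in b. The two-sided p-value
#' uses the asymptotic Kolmogorov distribution at effective sample size
#' `n_a * n_b / (n_a + n_b)`; ties (discrete coordinates) are permitted
#' and no tie correction is applied, which is conservative.
#'
#' @param ends_a,ends_b Oriented positions for the two conditions
#'   (pooled across replicates), both non-empty.
#' @return List with `apa_change` (signed, in `[-1, 1]`), `D` (the
#'   unsigned KS statistic), `pvalue`, `n_a`, `n_b`.
#' @export
ks_signed <- function(ends_a, ends_b) {
  n_a <- length(ends_a); n_b <- length(ends_b)
  if (n_a == 0L || n_b == 0L) stop("both samples must be non-empty")
  xs <- sort(unique(c(ends_a, ends_b)))
  fa <- stats::ecdf(ends_a)(xs)
  fb <- stats::ecdf(ends_b)(xs)
  diff <- fa - fb
  dplus <- max(diff); dminus <- max(-diff)
  dplus <- max(dplus, 0); dminus <- max(dminus, 0)
  D <- max(dplus, dminus)
  apa_change <- if (dplus >= dminus) dplus else -dminus
  n_eff <- n_a * n_b / (n_a + n_b)
  pvalue <- .kolmogorov_sf(sqrt(n_eff) * D)
  list(apa_change = apa_change, D = D, pvalue = pvalue, n_a = n_a, n_b = n_b)
}

# Survival function of the Kolmogorov distribution,
# P(K > t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2).
.kolmogorov_sf <- function(t) {
  if (t < 1e-8) return(1)
  k <- seq_len(101L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Benjamini-Hochberg adjustment with validation
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (`NA` allowed
#'   and propagated).
#' @return BH step-up adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-level APA testing between two conditions
#'
#' For every gene with at least two retained PASs, pools the
#' transcription-oriented 3' ends of each condition's reads (restricted,
#' by default, to reads lying within the clustering window of a retained
#' PAS, consistent with the PAU definition) and applies [ks_signed()].
#' P-values are BH-adjusted across tested genes; a gene is called
#' `lengthening` when `apa_change > tau` at `qvalue < alpha`,
#' `shortening` when `apa_change < -tau`, otherwise `none`. Each tested
#' gene is also labelled `last_exon_tandem` or `mixed` from the location
#' of its retained PASs.
#'
#' @param table A `read_end_table` with a condition map (or pass
#'   `conditions`).
#' @param catalog A `pas_catalog`.
#' @param models `gene_models` (for the APA-type label).
#' @param condition_a,condition_b Condition labels; positive APA change
#'   means lengthening in `condition_b`.
#' @param min_reads Minimum pooled reads per condition per gene
#'   (default 10).
#' @param alpha,tau Significance and effect-size thresholds for the
#'   direction call (defaults 0.05 and 0.1).
#' @param all_reads If `TRUE`, use all of a gene's reads rather than
#'   only those attributable to retained PASs.
#' @param exclude_internal_priming If `TRUE`, reads supporting
#'   internal-priming-flagged PASs are excluded (default `FALSE`:
#'   flagged sites are labelled, not removed, at gene level).
#' @param conditions Optional sample-to-condition map overriding the
#'   table's.
#' @return A data.frame (class `gene_apa_results`) with one row per
#'   tested gene: `gene_id`, `apa_change`, `D`, `pvalue`, `qvalue`,
#'   `n_a`, `n_b`, `direction`, `apa_type`.
#' @export
gene_level_apa <- function(table, catalog, models, condition_a, condition_b,
                           min_reads = 10L, alpha = 0.05, tau = 0.1,
                           all_reads = FALSE,
                           exclude_internal_priming = FALSE,
                           conditions = NULL) {
  stopifnot(inherits(table, "read_end_table"), inherits(catalog, "pas_catalog"))
  cond <- if (is.null(conditions)) table$conditions else conditions
  if (is.null(cond)) stop("a sample-to-condition map is required")
  reads <- table$reads
  reads$condition <- unname(cond[reads$sample_id])
  reads <- reads[reads$condition %in% c(condition_a, condition_b), ,
                 drop = FALSE]
  pas <- catalog$pas
  if (exclude_internal_priming && !all(is.na(pas$internal_priming)))
    pas <- pas[!pas$internal_priming %in% TRUE, , drop = FALSE]
  window <- catalog$params$window

  rows <- list()
  for (g in intersect(unique(pas$gene_id), unique(reads$gene_id))) {
    peaks <- pas$peak[pas$gene_id == g]
    if (length(peaks) < 2L) next
    m <- models[[g]]
    if (is.null(m)) next
    ridx <- reads$gene_id == g
    ends <- reads$end3[ridx]
    cc <- reads$condition[ridx]
    if (!all_reads) {
      near <- vapply(ends, function(e) min(abs(e - peaks)) <= window,
                     logical(1))
      ends <- ends[near]; cc <- cc[near]
    }
    ea <- ends[cc == condition_a]; eb <- ends[cc == condition_b]
    if (length(ea) < min_reads || length(eb) < min_reads) next
    ks <- ks_signed(oriented_positions(ea, m$strand),
                    oriented_positions(eb, m$strand))
    rows[[g]] <- data.frame(
      gene_id = g, apa_change = ks$apa_change, D = ks$D,
      pvalue = ks$pvalue, n_a = ks$n_a, n_b = ks$n_b,
      apa_type = classify_gene_apa_type(peaks, m),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(structure(data.frame(gene_id = character(0),
                                apa_change = numeric(0), D = numeric(0),
                                pvalue = numeric(0), qvalue = numeric(0),
                                n_a = integer(0), n_b = integer(0),
                                direction = character(0),
                                apa_type = character(0)),
                     class = c("gene_apa_results", "data.frame"),
                     alpha = alpha, tau = tau))
  res$qvalue <- bh_adjust(res$pvalue)
  res$direction <- ifelse(res$qvalue < alpha & res$apa_change > tau,
                          "lengthening",
                   ifelse(res$qvalue < alpha & res$apa_change < -tau,
                          "shortening", "none"))
  res <- res[, c("gene_id", "apa_change", "D", "pvalue", "qvalue",
                 "n_a", "n_b", "direction", "apa_type")]
  rownames(res) <- NULL
  structure(res, class = c("gene_apa_results", "data.frame"),
            alpha = alpha, tau = tau)
}

#' @export
print.gene_apa_results <- function(x, ...) {
  cat(sprintf("gene_apa_results: %d genes tested; %d lengthening, %d shortening (alpha=%g, tau=%g)\n",
              nrow(x), sum(x$direction == "lengthening"),
              sum(x$direction == "shortening"),
              attr(x, "alpha"), attr(x, "tau")))
  NextMethod()
}

#' Pearson correlation of gene-level APA change with proximal and
#' distal PAU changes
#'
#' For each tested gene takes the PAU change (condition b minus a) at
#' its proximal (rank-1) and distal (highest-rank) PAS and correlates
#' each across genes with the gene's signed APA change. In lengthening
#' regimes the proximal correlation is expected negative and the distal
#' positive.
#'
#' @param gene_results A `gene_apa_results`.
#' @param pm A `pau_matrix` with conditions.
#' @param catalog The `pas_catalog`.
#' @param condition_a,condition_b Condition labels (b minus a).
#' @return List with `r_prox`, `r_dist` (NA when variance is
#'   degenerate) and `n_genes` used.
#' @export
proximal_distal_correlation <- function(gene_results, pm, catalog,
                                        condition_a, condition_b) {
  dp <- delta_pau(pm, condition_a, condition_b)
  pas <- catalog$pas
  gids <- gene_results$gene_id
  prox <- pas$pas_id[match(gids, pas$gene_id)]             # rank 1
  dist_id <- vapply(gids, function(g) {
    sel <- pas$gene_id == g
    pas$pas_id[sel][which.max(pas$rank[sel])]
  }, character(1))
  df <- data.frame(apa = gene_results$apa_change,
                   dprox = dp[prox], ddist = dp[dist_id])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3L) stop("need at least 3 genes with both quantities")
  safe_cor <- function(a, b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  list(r_prox = safe_cor(df$apa, df$dprox),
       r_dist = safe_cor(df$apa, df$ddist),
       n_genes = nrow(df))
}
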