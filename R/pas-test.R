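#' Method-of-moments NB dispersion with trend shrinkage
#'
#' Estimates a negative-binomial dispersion per PAS from its
#' this-site-versus-rest-of-gene counts across samples, conditionally on
#' the gene-sample totals: the expected count is the total times the
#' condition-mean usage, so library-depth variation does not inflate the
#' estimate. The raw moment estimate (df-corrected, floored at 1e-8) is
#' then shrunk toward a lowess mean-dispersion trend fitted across all
#' PASs, with a configurable raw/trend weight.
#'
#' @param this_counts PAS x sample matrix of counts at each PAS.
#' @param total_counts PAS x sample matrix of the host gene's totals
#'   (same shape).
#' @param conditions Named sample-to-condition map covering the columns.
#' @param prior_weight Weight of the raw estimate in the shrunk value
#'   (default 0.5; the remainder goes to the trend).
#' @return Numeric vector of shrunk dispersions (one per row; `NA` for
#'   all-zero rows), with attributes `raw` and `trend`.
#' @export
estimate_dispersion <- function(this_counts, total_counts, conditions,
                                prior_weight = 0.5) {
  stopifnot(all(dim(this_counts) == dim(total_counts)))
  cond <- unname(conditions[colnames(this_counts)])
  if (anyNA(cond)) stop("conditions must cover all sample columns")
  if (any(table(cond) < 2L)) stop("need >= 2 samples per condition")
  ncond <- length(unique(cond))
  n <- ncol(this_counts)
  raw <- rep(NA_real_, nrow(this_counts))
  mu_mean <- rep(NA_real_, nrow(this_counts))
  for (i in seq_len(nrow(this_counts))) {
    y <- this_counts[i, ]
    N <- total_counts[i, ]
    if (all(y == 0)) next
    # expected counts under condition-mean usage, given totals
    mu <- numeric(n)
    for (cc in unique(cond)) {
      s <- cond == cc
      p <- sum(y[s]) / max(sum(N[s]), 1)
      mu[s] <- N[s] * p
    }
    use <- mu > 0
    if (sum(use) <= ncond) next
    num <- sum((y[use] - mu[use])^2) * sum(use) / (sum(use) - ncond) -
      sum(mu[use])
    raw[i] <- min(max(num / sum(mu[use]^2), 1e-8), 10)
    mu_mean[i] <- mean(mu[use])
  }
  ok <- !is.na(raw) & !is.na(mu_mean) & mu_mean > 0
  trend <- rep(NA_real_, length(raw))
  if (sum(ok) >= 10L && length(unique(mu_mean[ok])) >= 2L) {
    lo <- stats::lowess(log(mu_mean[ok]), log(raw[ok]), f = 0.5)
    trend[ok] <- exp(stats::approx(lo$x, lo$y, xout = log(mu_mean[ok]),
                                   rule = 2, ties = mean)$y)
  } else {
    trend[ok] <- stats::median(raw[ok])
  }
  shrunk <- ifelse(is.na(trend), raw,
                   pmax(prior_weight * raw + (1 - prior_weight) * trend, 1e-8))
  attr(shrunk, "raw") <- raw
  attr(shrunk, "trend") <- trend
  shrunk
}

#' Per-PAS differential usage test (DEXSeq-style NB-GLM LRT)
#'
#' For each PAS of a multi-PAS gene, fits negative-binomial GLMs to the
#' two-column counts (reads at this PAS versus the rest of the gene,
#' per sample): a null model with sample and column effects, and an
#' alternative adding the condition-by-column interaction — the usage
#' shift. Significance is a likelihood-ratio test against chi-square
#' with one degree of freedom, using the trend-shrunk dispersion from
#' [estimate_dispersion()]. This retains the structure of the DEXSeq
#' exon-usage test (interaction on usage, conditioned on total gene
#' output through the sample effects) without its Cox-Reid shrinkage
#' machinery. Internal-priming-flagged PASs are excluded by default.
#'
#' @param pm A `pau_matrix` with a condition map (or pass `conditions`).
#' @param catalog The `pas_catalog`.
#' @param condition_a,condition_b Condition labels; fold changes are
#'   b over a.
#' @param fc_threshold,alpha Usage fold-change and q-value thresholds
#'   for the `significant` call (defaults 1.5 and 0.05).
#' @param exclude_internal_priming Drop flagged PASs before testing
#'   (default `TRUE`).
#' @param prior_weight Dispersion shrinkage weight, see
#'   [estimate_dispersion()].
#' @param conditions Optional override of the stored condition map.
#' @return A data.frame (class `pas_diff_results`): `pas_id`,
#'   `gene_id`, `log2fc_usage` (log2 mean-PAU ratio b/a with a
#'   0.5/gene-total pseudo-usage guard), `pvalue`, `qvalue`,
#'   `significant`, `dispersion`.
#' @export
pas_usage_test <- function(pm, catalog, condition_a, condition_b,
                           fc_threshold = 1.5, alpha = 0.05,
                           exclude_internal_priming = TRUE,
                           prior_weight = 0.5, conditions = NULL) {
  stopifnot(inherits(pm, "pau_matrix"), inherits(catalog, "pas_catalog"))
  cond <- if (is.null(conditions)) pm$conditions else conditions
  if (is.null(cond)) stop("a sample-to-condition map is required")
  samples <- colnames(pm$counts)
  cvec <- unname(cond[samples])
  keep_s <- cvec %in% c(condition_a, condition_b)
  samples <- samples[keep_s]; cvec <- cvec[keep_s]
  if (any(table(cvec) < 2L))
    stop("each condition needs >= 2 replicates for the PAS-level test; ",
         "use gene-level KS analysis for unreplicated designs")
  counts <- pm$counts[, samples, drop = FALSE]
  pas <- catalog$pas[match(rownames(counts), catalog$pas$pas_id), ]

  multi <- pas$gene_id %in% names(which(table(pas$gene_id) >= 2L))
  testable <- multi
  if (exclude_internal_priming && !all(is.na(pas$internal_priming)))
    testable <- testable & !pas$internal_priming %in% TRUE
  idx <- which(testable)
  if (length(idx) == 0L)
    stop("no testable PASs (need multi-PAS genes)")

  totals <- pm$gene_totals[pas$gene_id, samples, drop = FALSE]
  this <- counts[idx, , drop = FALSE]
  tot <- totals[idx, , drop = FALSE]
  disp <- estimate_dispersion(this, tot, cond[samples],
                              prior_weight = prior_weight)

  n <- length(samples)
  sample_f <- factor(rep(samples, 2L))
  col_f <- factor(rep(c("this", "other"), each = n))
  cond_f <- factor(rep(cvec, 2L), levels = c(condition_a, condition_b))
  pvals <- rep(NA_real_, length(idx))
  for (j in seq_along(idx)) {
    y <- c(this[j, ], tot[j, ] - this[j, ])
    if (all(this[j, ] == 0) || is.na(disp[j])) next
    theta <- min(1 / max(disp[j], 1e-8), 1e8)
    fam <- MASS::negative.binomial(theta = theta)
    fit <- try({
      full <- stats::glm(y ~ sample_f + col_f + col_f:cond_f, family = fam)
      null <- stats::glm(y ~ sample_f + col_f, family = fam)
      stat <- max(null$deviance - full$deviance, 0)
      stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    }, silent = TRUE)
    if (!inherits(fit, "try-error")) pvals[j] <- fit
  }

  # usage fold change with a small pseudo-usage guard
  sa <- samples[cvec == condition_a]; sb <- samples[cvec == condition_b]
  pau <- pm$pau[rownames(counts)[idx], , drop = FALSE]
  ma <- rowMeans(pau[, sa, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(pau[, sb, drop = FALSE], na.rm = TRUE)
  p0 <- 0.5 / pmax(rowMeans(tot), 1)
  lfc <- log2((mb + p0) / (ma + p0))
  lfc[!is.finite(lfc)] <- NA_real_

  res <- data.frame(pas_id = rownames(counts)[idx],
                    gene_id = pas$gene_id[idx],
                    log2fc_usage = lfc, pvalue = pvals,
                    qvalue = bh_adjust(pvals),
                    dispersion = as.numeric(disp),
                    stringsAsFactors = FALSE)
  res$significant <- !is.na(res$qvalue) & res$qvalue < alpha &
    !is.na(res$log2fc_usage) & abs(res$log2fc_usage) > log2(fc_threshold)
  rownames(res) <- NULL
  structure(res[, c("pas_id", "gene_id", "log2fc_usage", "pvalue",
                    "qvalue", "significant", "dispersion")],
            class = c("pas_diff_results", "data.frame"),
            fc_threshold = fc_threshold, alpha = alpha)
}

#' @export
print.pas_diff_results <- function(x, ...) {
  cat(sprintf("pas_diff_results: %d PASs tested; %d significant (|FC|>%g, q<%g)\n",
              sum(!is.na(x$pvalue)), sum(x$significant, na.rm = TRUE),
              attr(x, "fc_threshold"), attr(x, "alpha")))
  NextMethod()
}
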