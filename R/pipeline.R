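#' Build a validated pipeline configuration
#'
#' Collects the input paths, the sample-to-condition map, and every
#' tunable threshold of the analysis into a single validated list that
#' round-trips losslessly through YAML ([write_apa_config()] /
#' [read_apa_config()]).
#'
#' @param annotation Path to the GTF annotation.
#' @param genome Path to the genome FASTA.
#' @param read_ends Character vector of read-end TSV paths.
#' @param conditions Named character vector, sample_id -> condition.
#' @param condition_a,condition_b The two condition labels compared
#'   (positive APA change = lengthening in `condition_b`).
#' @param reference_pas Optional BED of annotated PASs.
#' @param out_dir Output directory.
#' @param window Clustering window, nt (default 20).
#' @param min_overall_pau Overall-PAU cutoff for PAS calling (0.01).
#' @param min_gene_reads Per-gene per-sample depth for PAU (10).
#' @param min_ks_reads Pooled per-condition depth for the KS test (10).
#' @param alpha,tau,fc_threshold Significance, APA-change, and usage
#'   fold-change thresholds (0.05, 0.1, 1.5).
#' @param ip_window,ip_min_a Internal-priming rule (10 nt, 7 A).
#' @param seed Seed recorded for provenance (the statistics themselves
#'   are deterministic).
#' @return A validated list of class `apa_config`.
#' @export
apa_config <- function(annotation, genome, read_ends, conditions,
                       condition_a, condition_b, reference_pas = NULL,
                       out_dir = "longapa_out", window = 20L,
                       min_overall_pau = 0.01, min_gene_reads = 10L,
                       min_ks_reads = 10L, alpha = 0.05, tau = 0.1,
                       fc_threshold = 1.5, ip_window = 10L, ip_min_a = 7L,
                       seed = 1L) {
  cfg <- list(annotation = annotation, genome = genome,
              read_ends = as.character(read_ends),
              conditions = as.list(conditions),
              condition_a = condition_a, condition_b = condition_b,
              reference_pas = reference_pas, out_dir = out_dir,
              window = as.integer(window),
              min_overall_pau = min_overall_pau,
              min_gene_reads = as.integer(min_gene_reads),
              min_ks_reads = as.integer(min_ks_reads),
              alpha = alpha, tau = tau, fc_threshold = fc_threshold,
              ip_window = as.integer(ip_window),
              ip_min_a = as.integer(ip_min_a), seed = as.integer(seed))
  validate_apa_config(cfg)
  structure(cfg, class = "apa_config")
}

#' Validate an `apa_config`
#'
#' Checks every threshold's domain and that the referenced input files
#' exist; fails before any computation.
#'
#' @param cfg A config list.
#' @return `cfg`, invisibly, or an error.
#' @export
validate_apa_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(is.character(cfg$annotation) && file.exists(cfg$annotation),
      paste("annotation GTF not found:", cfg$annotation))
  chk(is.character(cfg$genome) && file.exists(cfg$genome),
      paste("genome FASTA not found:", cfg$genome))
  chk(all(file.exists(cfg$read_ends)),
      paste("read-end TSV(s) not found:",
            paste(cfg$read_ends[!file.exists(cfg$read_ends)], collapse = ", ")))
  if (!is.null(cfg$reference_pas))
    chk(file.exists(cfg$reference_pas),
        paste("reference PAS BED not found:", cfg$reference_pas))
  chk(length(cfg$conditions) >= 2L, "conditions map needs >= 2 samples")
  conds <- unlist(cfg$conditions)
  chk(all(c(cfg$condition_a, cfg$condition_b) %in% conds),
      "condition_a/condition_b must appear in the conditions map")
  chk(cfg$window >= 0L, "window must be >= 0")
  chk(cfg$min_overall_pau >= 0 && cfg$min_overall_pau <= 1,
      "min_overall_pau must be in [0, 1]")
  chk(cfg$min_gene_reads >= 0L, "min_gene_reads must be >= 0")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$tau >= 0 && cfg$tau <= 1, "tau must be in [0, 1]")
  chk(cfg$fc_threshold >= 1, "fc_threshold must be >= 1")
  chk(cfg$ip_window > 0L && cfg$ip_min_a > 0L,
      "internal-priming thresholds must be positive")
  invisible(cfg)
}

#' @rdname apa_config
#' @param cfg An `apa_config`.
#' @param path YAML file path.
#' @export
write_apa_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname apa_config
#' @export
read_apa_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$conditions <- unlist(cfg$conditions)
  do.call(apa_config, cfg[!vapply(cfg, is.null, logical(1))])
}

#' Run the full APA analysis pipeline
#'
#' Loads annotation, genome, optional reference PASs and the per-sample
#' read-end tables; calls and classifies PASs; builds the count and PAU
#' matrices; runs the gene-level KS analysis and (when both conditions
#' have at least two replicates) the PAS-level NB-GLM test; and writes
#' every result table plus a machine-readable run log recording all
#' thresholds actually used. The run is deterministic given the config.
#'
#' @param cfg An `apa_config`.
#' @return An `apa_run` object: list with `catalog`, `pau`,
#'   `gene_results`, `pas_results` (or `NULL`), `paths`, `config`.
#' @export
run_apa_pipeline <- function(cfg) {
  validate_apa_config(cfg)
  models <- parse_gene_models(cfg$annotation)
  genome <- read_genome(cfg$genome)
  gtf_chroms <- unique(vapply(models, `[[`, "", "chrom"))
  bad <- setdiff(gtf_chroms, names(genome))
  if (length(bad))
    stop("chromosomes in annotation missing from genome FASTA: ",
         paste(bad, collapse = ", "))
  ref <- if (!is.null(cfg$reference_pas)) load_reference_pas(cfg$reference_pas)
  conditions <- unlist(cfg$conditions)
  tables <- lapply(cfg$read_ends, load_read_end_table)
  table <- bind_read_ends(tables, conditions = conditions)

  catalog <- call_pas(table, models, min_overall_pau = cfg$min_overall_pau,
                      window = cfg$window, ref = ref, genome = genome,
                      ip_window = cfg$ip_window, ip_min_a = cfg$ip_min_a)
  counts <- count_reads_at_pas(table, catalog)
  pm <- compute_pau(counts, catalog, min_gene_reads = cfg$min_gene_reads,
                    conditions = conditions)
  gene_results <- gene_level_apa(table, catalog, models,
                                 cfg$condition_a, cfg$condition_b,
                                 min_reads = cfg$min_ks_reads,
                                 alpha = cfg$alpha, tau = cfg$tau)
  reps <- table(conditions[conditions %in% c(cfg$condition_a, cfg$condition_b)])
  pas_results <- NULL
  if (all(reps >= 2L)) {
    pas_results <- pas_usage_test(pm, catalog, cfg$condition_a,
                                  cfg$condition_b,
                                  fc_threshold = cfg$fc_threshold,
                                  alpha = cfg$alpha)
  } else {
    message("PAS-level test skipped: needs >= 2 replicates per condition")
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  write_pas_catalog(catalog, bed_path = p("pas_catalog.bed"),
                    tsv_path = p("pas_catalog.tsv"))
  write_pau_matrix(pm, counts_path = p("pas_counts.tsv"),
                   pau_path = p("pau.tsv"), long_path = p("pau_long.tsv"))
  utils::write.table(gene_results, p("gene_apa.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(pas_results))
    utils::write.table(pas_results, p("pas_diff.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  yaml::write_yaml(c(unclass(cfg),
                     list(longapa_version =
                            as.character(utils::packageVersion("longapa")),
                          n_pas = nrow(catalog$pas),
                          n_genes_tested = nrow(gene_results))),
                   p("run_log.yaml"))

  structure(list(catalog = catalog, pau = pm, gene_results = gene_results,
                 pas_results = pas_results, config = cfg,
                 paths = vapply(c("pas_catalog.bed", "pas_catalog.tsv",
                                  "pas_counts.tsv", "pau.tsv", "pau_long.tsv",
                                  "gene_apa.tsv", "run_log.yaml"), p, "")),
            class = "apa_run")
}

#' @export
print.apa_run <- function(x, ...) {
  cat("longapa pipeline run\n")
  print(x$catalog)
  cat(sprintf("  gene-level: %d tested, %d lengthening, %d shortening\n",
              nrow(x$gene_results),
              sum(x$gene_results$direction == "lengthening"),
              sum(x$gene_results$direction == "shortening")))
  if (!is.null(x$pas_results))
    cat(sprintf("  PAS-level: %d tested, %d significant\n",
                sum(!is.na(x$pas_results$pvalue)),
                sum(x$pas_results$significant, na.rm = TRUE)))
  cat("  outputs:", x$config$out_dir, "\n")
  invisible(x)
}
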