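# Run code under a local RNG state so simulation is reproducible without
# disturbing the caller's random stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Simulate a reference: genome, annotation, and true PASs
#'
#' Generates a random-sequence genome carrying `n_genes` two-exon genes
#' on both strands, each with 2-5 true PASs (tandem sites in the 3'UTR
#' and, for a fraction of genes, one intronic site), at least 40 nt
#' apart so the 20-nt calling window cannot merge them. A canonical
#' AAUAAA signal is planted with its start 20-30 nt upstream of every
#' true PAS; the 10-nt flanks of every true PAS are repaired to carry at
#' most 5 sense-strand adenosines so no clean site can trip the
#' internal-priming rule, while genes selected for an artifact receive
#' an extra decoy position whose upstream flank is made A-rich.
#' Per-condition PAS usage vectors are drawn on the simplex; genes with
#' a planted lengthening (shortening) effect move `delta_pau` of usage
#' from the proximal (distal) to the distal (proximal) PAS in the
#' second condition. FASTA, GTF, and reference-PAS BED files are
#' written deterministically given the seed.
#'
#' @param n_genes Number of genes (>= 1).
#' @param genome_len Optional genome length; must fit the gene layout
#'   (about 2,600 nt per gene), error when too small. Default: sized to
#'   fit.
#' @param out_dir Directory to write `genome.fa`, `annotation.gtf`,
#'   `reference_pas.bed` into (created if needed).
#' @param prop_lengthening,prop_shortening Fractions of genes given a
#'   planted distal/proximal usage shift of `delta_pau` (defaults 0).
#' @param delta_pau Planted usage shift (default 0.3).
#' @param prop_intronic Fraction of genes whose most proximal PAS is
#'   intronic, giving mixed-type genes (default 0.3).
#' @param prop_artifact Fraction of genes given a planted A-rich
#'   internal-priming decoy site (default 0).
#' @param seed Random seed; the full output is byte-reproducible.
#' @return List with `genome` (`DNAStringSet`), `models`
#'   (`gene_models`), `truth` (per-gene list: pas coordinates in
#'   proximal-to-distal rank order, usage vectors per condition, planted
#'   `effect`, `artifact_pos`), and `paths` (fasta/gtf/bed).
#' @export
simulate_reference <- function(n_genes, genome_len = NULL,
                               out_dir = tempfile("simref"),
                               prop_lengthening = 0, prop_shortening = 0,
                               delta_pau = 0.3, prop_intronic = 0.3,
                               prop_artifact = 0, seed = 1L) {
  stopifnot(n_genes >= 1L)
  slot <- 2600L; margin <- 400L
  needed <- n_genes * slot + margin
  if (is.null(genome_len)) genome_len <- needed
  if (genome_len < needed)
    stop(sprintf("genome too small for %d genes: need >= %d, got %d",
                 n_genes, needed, genome_len))
  .with_seed(seed, {
    chrom <- "chrS"
    gseq <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE,
                   prob = c(0.28, 0.22, 0.22, 0.28))
    n_len <- round(prop_lengthening * n_genes)
    n_sht <- round(prop_shortening * n_genes)
    effects <- sample(c(rep("lengthening", n_len), rep("shortening", n_sht),
                        rep("null", n_genes - n_len - n_sht)))
    intronic <- stats::runif(n_genes) < prop_intronic
    artifact <- stats::runif(n_genes) < prop_artifact
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)

    glen <- 2000L
    models <- vector("list", n_genes)
    truth <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      gid <- sprintf("G%04d", i)
      gs <- (i - 1L) * slot + 200L
      ge <- gs + glen
      strand <- strands[i]
      to_gen <- function(rel) if (strand == "+") gs + rel else ge - 1L - rel
      rel_iv_to_gen <- function(a, b)   # rel [a,b) -> genomic interval
        if (strand == "+") c(gs + a, gs + b) else c(ge - b, ge - a)

      # layout (transcription-relative): exon1 [0,300), intron [300,700),
      # last exon [700,2000); CDS [100,300)+[700,800); stop codon [800,803)
      n_utr <- sample(2:5, 1L) - as.integer(intronic[i])
      n_utr <- max(n_utr, if (intronic[i]) 1L else 2L)
      utr_rel <- 880L + cumsum(c(0L, sample(60:120, n_utr - 1L, replace = TRUE)))
      pas_rel <- c(if (intronic[i]) 500L, utr_rel)
      k <- length(pas_rel)

      # usage on the simplex; planted effects move delta from one end to
      # the other, so the moving components need headroom
      u <- stats::runif(k, 1, 2); u <- u / sum(u)
      eff <- effects[i]
      if (k < 2L) eff <- "null"
      if (eff == "lengthening") {
        u[1L] <- delta_pau + 0.15
        u[-1L] <- u[-1L] / sum(u[-1L]) * (1 - u[1L])
      } else if (eff == "shortening") {
        u[k] <- delta_pau + 0.15
        u[-k] <- u[-k] / sum(u[-k]) * (1 - u[k])
      }
      ub <- u
      if (eff == "lengthening") {
        ub[1L] <- ub[1L] - delta_pau; ub[k] <- ub[k] + delta_pau
      } else if (eff == "shortening") {
        ub[k] <- ub[k] - delta_pau; ub[1L] <- ub[1L] + delta_pau
      }

      # plant AAUAAA (sense) with match start 20-30 nt upstream of each PAS
      for (p in pas_rel) {
        s <- sample(20:30, 1L)
        rel_pos <- (p - s) + 0:5
        motif <- c("A", "A", "T", "A", "A", "A")
        gpos <- to_gen(rel_pos)
        gseq[gpos + 1L] <- if (strand == "+") motif else
          unname(.complement[motif])
      }

      art_rel <- NA_integer_
      if (artifact[i]) {
        art_rel <- utr_rel[length(utr_rel)] + 200L
        # A-rich upstream flank (8 of 10 sense A) triggers the rule
        rel_pos <- art_rel - 10:1
        bases <- c("A", "A", "C", "A", "A", "A", "G", "A", "A", "A")
        gpos <- to_gen(rel_pos)
        gseq[gpos + 1L] <- if (strand == "+") bases else .complement[bases]
      }

      # repair: clean sites must stay below the A-content rule
      for (p in pas_rel) {
        for (flank in list((p - 10L):(p - 1L), (p + 1L):(p + 10L))) {
          gpos <- to_gen(flank)
          sense <- if (strand == "+") gseq[gpos + 1L] else
            unname(.complement[gseq[gpos + 1L]])
          n_a <- sum(sense == "A")
          if (n_a > 5L) {
            fix <- which(sense == "A")
            fix <- fix[seq_len(n_a - 5L)]
            gseq[gpos[fix] + 1L] <-
              if (strand == "+") "C" else unname(.complement["C"])
          }
        }
      }

      ex1 <- rel_iv_to_gen(0L, 300L); ex2 <- rel_iv_to_gen(700L, 2000L)
      cds1 <- rel_iv_to_gen(100L, 300L); cds2 <- rel_iv_to_gen(700L, 800L)
      utr <- rel_iv_to_gen(803L, 2000L)
      exons <- iv_merge(iv(c(ex1[1L], ex2[1L]), c(ex1[2L], ex2[2L])))
      models[[i]] <- structure(list(
        gene_id = gid, gene_name = gid, chrom = chrom, strand = strand,
        start = gs, end = ge,
        exons = exons,
        cds = iv_merge(iv(c(cds1[1L], cds2[1L]), c(cds1[2L], cds2[2L]))),
        utr3 = iv(utr[1L], utr[2L]),
        last_exon_union = iv(ex2[1L], ex2[2L]),
        stop_codon_pos = to_gen(802L)
      ), class = "gene_model")
      truth[[i]] <- list(
        gene_id = gid, chrom = chrom, strand = strand,
        gene_start = gs, gene_end = ge,
        pas = as.integer(to_gen(pas_rel)),       # rank order proximal->distal
        usage_a = u, usage_b = ub, effect = eff, delta = delta_pau,
        intronic = intronic[i],
        artifact_pos = if (is.na(art_rel)) NA_integer_ else
          as.integer(to_gen(art_rel)))
    }
    names(models) <- vapply(models, `[[`, "", "gene_id")
    names(truth) <- names(models)
    models <- structure(models, class = "gene_models")

    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(out_dir, "genome.fa")
    gtf <- file.path(out_dir, "annotation.gtf")
    bed <- file.path(out_dir, "reference_pas.bed")
    genome <- Biostrings::DNAStringSet(paste(gseq, collapse = ""))
    names(genome) <- chrom
    Biostrings::writeXStringSet(genome, fasta)
    if (file.exists(paste0(fasta, ".fai"))) file.remove(paste0(fasta, ".fai"))
    try(Rsamtools::indexFa(fasta), silent = TRUE)
    write_gene_models_gtf(models, gtf)
    bed_df <- do.call(rbind, lapply(truth, function(tr)
      data.frame(tr$chrom, tr$pas, tr$pas + 1L, tr$gene_id, 0L, tr$strand)))
    bed_df <- bed_df[order(bed_df[[1L]], bed_df[[2L]]), ]
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    list(genome = genome, models = models, truth = truth,
         paths = list(fasta = fasta, gtf = gtf, bed = bed))
  })
}

#' Simulate per-sample read 3' ends from a reference
#'
#' For every gene and sample, the total read count is drawn
#' negative-binomially around `depth_mean`, reads are allocated to the
#' gene's true PASs multinomially by the condition's usage vector, and
#' each 3' end is jittered by a discretized normal (rejection-truncated
#' at +/-15 nt, keeping true clusters inside the 20-nt calling window).
#' Genes with a planted A-rich decoy additionally emit artifact reads
#' at that position at `artifact_rate` times the gene's depth.
#'
#' @param ref A reference from [simulate_reference()].
#' @param depth_mean Mean reads per gene per sample (default 67, about
#'   200 pooled per condition with 3 replicates).
#' @param n_replicates Replicates per condition (default 3).
#' @param jitter_sd SD of the 3'-end jitter in nt (default 5; 0 gives
#'   exact ends).
#' @param depth_dispersion NB dispersion of per-gene-sample depth
#'   (default 0.1).
#' @param artifact_rate Expected artifact reads as a fraction of gene
#'   depth, for genes carrying a decoy (default 0.08).
#' @param condition_names Two condition labels (default
#'   `c("ctrl", "expt")`; planted effects apply to the second).
#' @param seed Random seed.
#' @return A `read_end_table` covering all samples, with its
#'   sample-to-condition map set.
#' @export
simulate_read_ends <- function(ref, depth_mean = 67, n_replicates = 3L,
                               jitter_sd = 5, depth_dispersion = 0.1,
                               artifact_rate = 0.08,
                               condition_names = c("ctrl", "expt"),
                               seed = 1L) {
  stopifnot(depth_mean > 0, length(condition_names) == 2L)
  jit <- function(n) {
    if (n == 0L) return(integer(0))
    if (jitter_sd == 0) return(integer(n))
    out <- round(stats::rnorm(n, 0, jitter_sd))
    bad <- abs(out) > 15
    while (any(bad)) {
      out[bad] <- round(stats::rnorm(sum(bad), 0, jitter_sd))
      bad <- abs(out) > 15
    }
    as.integer(out)
  }
  .with_seed(seed, {
    samples <- paste0(rep(condition_names, each = n_replicates), "_",
                      rep(seq_len(n_replicates), 2L))
    conditions <- stats::setNames(rep(condition_names, each = n_replicates),
                                  samples)
    out <- vector("list", length(ref$truth) * length(samples))
    j <- 0L
    for (tr in ref$truth) {
      for (s in samples) {
        usage <- if (conditions[[s]] == condition_names[2L]) tr$usage_b
          else tr$usage_a
        n <- stats::rnbinom(1L, mu = depth_mean, size = 1 / depth_dispersion)
        ends <- integer(0)
        if (n > 0L) {
          alloc <- as.integer(stats::rmultinom(1L, n, usage))
          ends <- rep(tr$pas, alloc) + jit(n)
        }
        if (!is.na(tr$artifact_pos)) {
          # internal-priming ends are templated by the genomic A-tract,
          # so unlike true cleavage they carry no jitter
          n_art <- stats::rpois(1L, artifact_rate * depth_mean)
          if (n_art > 0L)
            ends <- c(ends, rep(tr$artifact_pos, n_art))
        }
        if (length(ends) == 0L) next
        j <- j + 1L
        out[[j]] <- data.frame(
          read_id = sprintf("%s|%s|r%05d", s, tr$gene_id, seq_along(ends)),
          gene_id = tr$gene_id, chrom = tr$chrom, strand = tr$strand,
          end3 = ends, sample_id = s, stringsAsFactors = FALSE)
      }
    }
    read_end_table(do.call(rbind, out[seq_len(j)]), conditions)
  })
}
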