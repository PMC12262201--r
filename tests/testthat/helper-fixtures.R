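# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from stored data files.

# A minimal gene model without going through GTF parsing.
make_gene_model <- function(gene_id = "G1", chrom = "chr1", strand = "+",
                            start = 0L, end = 1000L,
                            exons = cbind(start = c(0L, 600L),
                                          end = c(300L, 1000L)),
                            cds = cbind(start = c(100L, 600L),
                                        end = c(300L, 700L)),
                            utr3 = cbind(start = 703L, end = 1000L),
                            last_exon = cbind(start = 600L, end = 1000L),
                            stop_codon_pos = 702L) {
  colnames(exons) <- colnames(cds) <- colnames(utr3) <-
    colnames(last_exon) <- c("start", "end")
  structure(list(gene_id = gene_id, gene_name = gene_id, chrom = chrom,
                 strand = strand, start = as.integer(start),
                 end = as.integer(end),
                 exons = exons, cds = cds, utr3 = utr3,
                 last_exon_union = last_exon,
                 stop_codon_pos = as.integer(stop_codon_pos)),
            class = "gene_model")
}

as_models <- function(...) {
  ms <- list(...)
  names(ms) <- vapply(ms, `[[`, "", "gene_id")
  structure(ms, class = "gene_models")
}

# A read_end_table with `counts[s]` reads at each coordinate per sample.
make_table <- function(coords_by_sample, gene_id = "G1", chrom = "chr1",
                       strand = "+", conditions = NULL) {
  rows <- lapply(names(coords_by_sample), function(s) {
    e <- coords_by_sample[[s]]
    if (length(e) == 0L) return(NULL)
    data.frame(read_id = sprintf("%s_r%04d", s, seq_along(e)),
               gene_id = gene_id, chrom = chrom, strand = strand,
               end3 = as.integer(e), sample_id = s,
               stringsAsFactors = FALSE)
  })
  read_end_table(do.call(rbind, rows), conditions)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Mirror a simulated reference: reverse-complement the genome, reflect
# every coordinate x -> L-1-x and flip strands. Used to assert that all
# calls and statistics are invariant under genome orientation.
mirror_coord <- function(x, L) L - 1L - x

mirror_models <- function(models, L) {
  ms <- lapply(models, function(m) {
    flip_iv <- function(v) {
      if (nrow(v) == 0L) return(v)
      out <- cbind(start = L - v[, "end"], end = L - v[, "start"])
      out[order(out[, "start"]), , drop = FALSE]
    }
    m2 <- m
    m2$strand <- if (m$strand == "+") "-" else "+"
    m2$start <- L - m$end; m2$end <- L - m$start
    for (f in c("exons", "cds", "utr3", "last_exon_union"))
      m2[[f]] <- flip_iv(m[[f]])
    if (!is.na(m$stop_codon_pos))
      m2$stop_codon_pos <- mirror_coord(m$stop_codon_pos, L)
    m2
  })
  structure(ms, class = "gene_models")
}

mirror_table <- function(tab, L) {
  r <- tab$reads
  r$end3 <- mirror_coord(r$end3, L)
  r$strand <- ifelse(r$strand == "+", "-", "+")
  read_end_table(r, tab$conditions)
}

mirror_genome <- function(genome) {
  g <- Biostrings::reverseComplement(genome)
  names(g) <- names(genome)
  g
}
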