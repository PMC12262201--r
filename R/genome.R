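#' Load a genome FASTA into memory
#'
#' Reads a (small) genome FASTA as a `DNAStringSet` with sequence names
#' trimmed at the first whitespace, the container used by all sequence
#' operations in this package. For genomes at this package's working
#' scale (simulated references, targeted regions) in-memory access is
#' simplest and fastest; the `.fai` index is created alongside when
#' missing so external tools can share the file.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(paste0(fasta_path, ".fai")))
    try(Rsamtools::indexFa(fasta_path), silent = TRUE)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Fetch a transcription-oriented flanking sequence
#'
#' Returns the uppercase nucleotide window covering `upstream` bases 5'
#' of `pos` through `downstream` bases 3' of `pos`, inclusive of the
#' base at `pos` itself (coordinates 0-based). For minus-strand sites
#' the genomic window is reverse-complemented so returned indices always
#' run 5' to 3' in transcription orientation. Windows running off a
#' chromosome end are clipped; the clipped lengths are recorded in the
#' `clip5`/`clip3` attributes of the result.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param pos 0-based coordinate of the anchor base.
#' @param upstream,downstream Number of flanking bases on each side.
#' @param strand `"+"` or `"-"` (transcription orientation).
#' @return A character scalar over `A,C,G,T,N` with `clip5`/`clip3`
#'   attributes giving how many requested bases fell outside the
#'   chromosome.
#' @export
fetch_flank <- function(genome, chrom, pos, upstream, downstream, strand) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  len <- length(genome[[chrom]])
  if (pos < 0L || pos >= len)
    stop(sprintf("position %d outside chromosome %s [0, %d)", pos, chrom, len))
  if (strand == "+") {
    g0 <- pos - upstream; g1 <- pos + downstream
  } else {
    g0 <- pos - downstream; g1 <- pos + upstream
  }
  c0 <- max(g0, 0L); c1 <- min(g1, len - 1L)
  if (c1 < c0) stop("window fully outside chromosome ", chrom)
  s <- as.character(Biostrings::subseq(genome[[chrom]], c0 + 1L, c1 + 1L))
  clip_left <- c0 - g0; clip_right <- g1 - c1
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    clip5 <- clip_right; clip3 <- clip_left
  } else {
    clip5 <- clip_left; clip3 <- clip_right
  }
  s <- toupper(s)
  if (clip5 > 0L || clip3 > 0L)
    message(sprintf("fetch_flank: window at %s:%d clipped (5': %d nt, 3': %d nt)",
                    chrom, pos, clip5, clip3))
  structure(s, clip5 = clip5, clip3 = clip3)
}

.revcomp <- function(s) {
  vapply(s, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    character(1), USE.NAMES = FALSE)
}
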