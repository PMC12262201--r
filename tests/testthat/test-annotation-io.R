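gtf_line <- function(chrom, feat, s1, e1, strand, gid, tid = NULL) {
  attrs <- sprintf('gene_id "%s"; gene_name "%s";', gid, gid)
  if (!is.null(tid)) attrs <- paste0(attrs, sprintf(' transcript_id "%s";', tid))
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, feat, s1, e1, strand, attrs)
}

test_that("gene models capture exons, last exon, stop codon and derived 3'UTR", {
  gtf <- write_tmp(c(
    gtf_line("chr1", "gene", 101, 400, "+", "GP"),
    gtf_line("chr1", "transcript", 101, 400, "+", "GP", "GP.t1"),
    gtf_line("chr1", "exon", 101, 200, "+", "GP", "GP.t1"),
    gtf_line("chr1", "exon", 301, 400, "+", "GP", "GP.t1"),
    gtf_line("chr1", "CDS", 131, 348, "+", "GP", "GP.t1"),
    gtf_line("chr1", "stop_codon", 349, 351, "+", "GP", "GP.t1"),
    # same exon structure on the minus strand, stop codon near the 5' end
    gtf_line("chr1", "gene", 101, 400, "-", "GM"),
    gtf_line("chr1", "transcript", 101, 400, "-", "GM", "GM.t1"),
    gtf_line("chr1", "exon", 101, 200, "-", "GM", "GM.t1"),
    gtf_line("chr1", "exon", 301, 400, "-", "GM", "GM.t1"),
    gtf_line("chr1", "stop_codon", 131, 133, "-", "GM", "GM.t1")
  ), ".gtf")
  models <- parse_gene_models(gtf)
  gp <- models$GP
  expect_equal(gp$start, 100L)
  expect_equal(gp$end, 400L)
  expect_equal(unname(gp$exons[, "start"]), c(100L, 300L))
  expect_equal(unname(gp$exons[, "end"]), c(200L, 400L))
  expect_equal(unname(gp$last_exon_union), unname(cbind(300L, 400L)))
  expect_equal(gp$stop_codon_pos, 350L)
  expect_equal(unname(gp$utr3), unname(cbind(351L, 400L)))
  # strand mirror: the 3'-most exon of the minus-strand gene is the left one
  gm <- models$GM
  expect_equal(unname(gm$last_exon_union), unname(cbind(100L, 200L)))
  expect_equal(gm$stop_codon_pos, 130L)
  expect_equal(unname(gm$utr3), unname(cbind(100L, 130L)))
})

test_that("last exons of multiple transcripts are unioned as a region", {
  gtf <- write_tmp(c(
    gtf_line("chr1", "gene", 101, 450, "+", "G2"),
    gtf_line("chr1", "exon", 101, 200, "+", "G2", "t1"),
    gtf_line("chr1", "exon", 301, 400, "+", "G2", "t1"),
    gtf_line("chr1", "exon", 101, 200, "+", "G2", "t2"),
    gtf_line("chr1", "exon", 351, 450, "+", "G2", "t2")
  ), ".gtf")
  m <- parse_gene_models(gtf)$G2
  expect_equal(unname(m$last_exon_union), unname(cbind(300L, 450L)))
  # non-coding: no CDS anywhere
  expect_true(is.na(m$stop_codon_pos))
  expect_equal(nrow(m$utr3), 0L)
})

test_that("malformed GTF lines are reported by line number", {
  gtf <- write_tmp(c(gtf_line("chr1", "gene", 1, 100, "+", "G"),
                     "chr1\tbroken line"))
  expect_error(parse_gene_models(gtf), "line 2")
})

test_that("parsed genes with exons always have a last exon", {
  ref <- simulate_reference(8, seed = 11)
  models <- parse_gene_models(ref$paths$gtf)
  for (m in models) {
    expect_gt(nrow(m$last_exon_union), 0L)
    expect_true(longapa:::iv_within(m$last_exon_union, m$exons))
    for (f in c("exons", "cds", "utr3", "last_exon_union")) {
      v <- m[[f]]
      if (nrow(v)) {
        expect_true(all(v[, "start"] >= m$start))
        expect_true(all(v[, "end"] <= m$end))
      }
    }
  }
})

test_that("gene models round-trip through GTF", {
  ref <- simulate_reference(6, seed = 12)
  f <- tempfile(fileext = ".gtf")
  write_gene_models_gtf(ref$models, f)
  back <- parse_gene_models(f)
  expect_equal(names(back), names(ref$models))
  for (g in names(back))
    for (field in c("strand", "start", "end", "exons", "cds", "utr3",
                    "last_exon_union", "stop_codon_pos"))
      expect_equal(back[[g]][[field]], ref$models[[g]][[field]],
                   info = paste(g, field))
})

test_that("reference PAS sets use the strand-wise 3' base, dedup and sort", {
  bed <- write_tmp(c("chr1\t999\t1000\t.\t0\t+",
                     "chr1\t999\t1000\t.\t0\t+",
                     "chr1\t500\t520\t.\t0\t-",
                     "chr1\t100\t120\tGENEX\t0\t+"))
  ref <- load_reference_pas(bed)
  expect_equal(ref$coords[["chr1 +"]], c(119L, 999L))   # sorted, deduped
  expect_equal(ref$coords[["chr1 -"]], 500L)            # minus: 5'-most base
  expect_equal(nrow(ref$sites), 3L)
})

test_that("reference PAS loading requires a strand column", {
  bed <- write_tmp("chr1\t10\t11\t.\t0\t.")
  expect_error(load_reference_pas(bed), "strand")
  bed5 <- write_tmp("chr1\t10\t11\t.\t0")
  expect_error(load_reference_pas(bed5), "6 columns")
})

test_that("fetch_flank is transcription-oriented and clips at ends", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "TTACGTATT"))
  # pos 4 is the G; two flanking bases each side
  expect_equal(as.character(fetch_flank(genome, "chr1", 4, 2, 2, "+")), "ACGTA")
  expect_equal(as.character(fetch_flank(genome, "chr1", 4, 2, 2, "-")), "TACGT")
  expect_error(fetch_flank(genome, "chrX", 4, 2, 2, "+"), "unknown")
  expect_error(fetch_flank(genome, "chr1", 20, 2, 2, "+"), "outside")
  s <- suppressMessages(fetch_flank(genome, "chr1", 1, 100, 1, "+"))
  expect_equal(as.character(s), "TTA")
  expect_equal(attr(s, "clip5"), 99L)
  # palindromic sequence reads the same from either strand
  pal <- Biostrings::DNAStringSet(c(p = "GAATTC"))
  expect_equal(as.character(fetch_flank(pal, "p", 2, 2, 3, "+")),
               as.character(fetch_flank(pal, "p", 3, 2, 3, "-")))
})
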