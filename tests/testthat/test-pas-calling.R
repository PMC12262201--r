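test_that("greedy clustering collapses ends to maximum-depth peaks", {
  cl <- cluster_read_ends(c(rep(100L, 5), rep(103L, 2), rep(150L, 3)),
                          window = 20L)
  expect_equal(length(cl), 2L)
  expect_equal(vapply(cl, `[[`, 0L, "peak"), c(100L, 150L))
  expect_equal(vapply(cl, `[[`, 0L, "depth"), c(7L, 3L))

  expect_equal(cluster_read_ends(500L),
               list(list(peak = 500L, members = 500L, depth = 1L)))
  expect_equal(cluster_read_ends(integer(0)), list())
})

test_that("depth ties break to the transcription-proximal coordinate", {
  ends <- c(rep(100L, 3), rep(115L, 3))
  plus <- cluster_read_ends(ends, window = 20L, strand = "+")
  expect_equal(length(plus), 1L)
  expect_equal(plus[[1]]$peak, 100L)
  minus <- cluster_read_ends(ends, window = 20L, strand = "-")
  expect_equal(minus[[1]]$peak, 115L)   # proximal = higher coordinate on '-'
})

test_that("clustering matches the brute-force oracle and conserves reads", {
  set.seed(42)
  for (i in 1:150) {
    n <- sample(1:200, 1)
    strand <- sample(c("+", "-"), 1)
    # narrow ranges force heavy ties and overlapping windows
    ends <- sample(0:80, n, replace = TRUE)
    got <- cluster_read_ends(ends, window = 20L, strand = strand)
    want <- oracle_cluster(ends, window = 20L, strand = strand)
    expect_equal(lapply(got, function(x) x[c("peak", "depth")]),
                 lapply(want, function(x) x[c("peak", "depth")]))
    expect_equal(sum(vapply(got, `[[`, 0L, "depth")), length(ends))
    for (cl in got) expect_true(all(abs(cl$members - cl$peak) <= 20L))
  }
})

test_that("PAS calling applies the overall-PAU cutoff at >= and ranks sites", {
  m <- make_gene_model("G1", strand = "+", end = 1000L)
  tab <- make_table(list(s1 = c(rep(650L, 990), rep(900L, 10))))
  cat1 <- call_pas(tab, as_models(m), min_overall_pau = 0.01)
  expect_equal(nrow(cat1$pas), 2L)             # 10/1000 = 1% retained
  expect_equal(cat1$pas$overall_pau, c(0.99, 0.01))
  expect_equal(cat1$pas$rank, c(1L, 2L))
  expect_equal(cat1$pas$pas_id, c("G1:PAS1", "G1:PAS2"))

  tab2 <- make_table(list(s1 = c(rep(650L, 990), rep(900L, 9))))
  cat2 <- call_pas(tab2, as_models(m), min_overall_pau = 0.01)
  expect_equal(nrow(cat2$pas), 1L)             # 9/999 < 1% removed
  # overall PAU stays the fraction of all pooled reads, not renormalised
  expect_equal(cat2$pas$overall_pau, 990 / 999)

  tab3 <- make_table(list(s1 = rep(650L, 50)))
  cat3 <- call_pas(tab3, as_models(m))
  expect_equal(cat3$pas$rank, 1L)
})

test_that("minus-strand PAS ranks run proximal to distal in transcription order", {
  m <- make_gene_model("G1", strand = "-", end = 1000L,
                       utr3 = cbind(start = 0L, end = 300L),
                       last_exon = cbind(start = 0L, end = 400L),
                       exons = cbind(start = c(0L, 600L), end = c(400L, 1000L)),
                       stop_codon_pos = 300L)
  tab <- make_table(list(s1 = c(rep(100L, 60), rep(250L, 40))), strand = "-")
  ct <- call_pas(tab, as_models(m))
  expect_equal(ct$pas$peak, c(250L, 100L))     # 250 is proximal on '-'
  expect_equal(ct$pas$rank, c(1L, 2L))
})

test_that("reference classification distinguishes match, proximity, novel", {
  bed <- write_tmp(c("chr1\t999\t1000\tG1\t0\t+",
                     "chr1\t1015\t1016\t.\t0\t+",
                     "chr1\t2000\t2001\tOTHER\t0\t+"))
  ref <- load_reference_pas(bed)
  expect_equal(classify_vs_reference("chr1", "+", 999L, "G1", ref),
               list(ref_class = "match", ref_distance = 0L))
  # within 20 nt of an annotated site
  r <- classify_vs_reference("chr1", "+", 1000L, "G1", ref)
  expect_equal(r$ref_class, "proximity")
  expect_equal(abs(r$ref_distance), 1L)
  expect_equal(classify_vs_reference("chr1", "+", 1041L, "G1", ref)$ref_class,
               "novel")
  # exact coordinate but labelled with a different host gene: not a match
  expect_equal(classify_vs_reference("chr1", "+", 2000L, "G1", ref)$ref_class,
               "proximity")
  # empty reference: everything novel
  empty <- load_reference_pas(write_tmp("chr9\t1\t2\t.\t0\t-"))
  expect_equal(classify_vs_reference("chr1", "+", 999L, "G1", empty)$ref_class,
               "novel")
})

test_that("region labels follow the stated priority", {
  m <- make_gene_model("G1", strand = "+", end = 1000L)
  expect_equal(annotate_region(800L, m), "utr3_exon")
  expect_equal(annotate_region(650L, m), "cds_exon")
  expect_equal(annotate_region(400L, m), "intron")
  expect_equal(annotate_region(1500L, m), "downstream")
  expect_equal(annotate_region(50L, m), "other")       # 5'UTR exon
  # 3'UTR wins over CDS when annotations overlap
  m2 <- make_gene_model("G2", strand = "+", end = 1000L,
                        utr3 = cbind(start = 600L, end = 1000L))
  expect_equal(annotate_region(650L, m2), "utr3_exon")
  # downstream is strand-wise: upstream of a minus gene span is 'other'
  m3 <- make_gene_model("G3", strand = "-", end = 1000L)
  expect_equal(annotate_region(1500L, m3), "other")
  expect_equal(annotate_region(-5L + 0L, m3), "downstream")
})

test_that("internal priming flags >6 A in either 10-nt flank", {
  mk <- function(up10, dn10)
    Biostrings::DNAStringSet(c(chr1 = paste0(
      strrep("G", 20), up10, "T", dn10, strrep("G", 20))))
  peak <- 30L  # the T between the two flanks
  expect_true(flag_internal_priming(mk(strrep("C", 10), strrep("A", 10)),
                                    "chr1", peak, "+"))
  # exactly 6 A is NOT flagged: the rule is strictly more than 6
  expect_false(flag_internal_priming(mk("AAAAAACCCC", strrep("C", 10)),
                                     "chr1", peak, "+"))
  expect_true(flag_internal_priming(mk("ATAAACAAAA", strrep("C", 10)),
                                    "chr1", peak, "+"))
  # sense-strand A count: a genomic A-run reads as U upstream of a '-' site
  g <- mk(strrep("A", 10), strrep("C", 10))
  expect_true(flag_internal_priming(g, "chr1", peak, "+"))
  expect_false(flag_internal_priming(g, "chr1", peak, "-"))
})

test_that("gene APA type separates tandem last-exon from mixed configurations", {
  m <- make_gene_model("G1", strand = "+", end = 1000L)
  expect_equal(classify_gene_apa_type(c(700L, 800L, 900L, 950L), m),
               "last_exon_tandem")
  expect_equal(classify_gene_apa_type(c(400L, 900L), m), "mixed")
  expect_equal(classify_gene_apa_type(900L, m), "single")
  # downstream-of-gene sites still count as tandem 3'UTR usage
  expect_equal(classify_gene_apa_type(c(900L, 1100L), m), "last_exon_tandem")
})

test_that("PAS calls, flags and regions are invariant under genome mirroring", {
  ref <- simulate_reference(12, prop_artifact = 0.4, prop_intronic = 0.5,
                            seed = 51)
  tab <- simulate_read_ends(ref, seed = 52)
  genome <- ref$genome
  L <- length(genome[[1]])
  cat_fwd <- call_pas(tab, ref$models, genome = genome)
  cat_rev <- call_pas(mirror_table(tab, L), mirror_models(ref$models, L),
                      genome = mirror_genome(genome))
  for (g in unique(cat_fwd$pas$gene_id)) {
    a <- cat_fwd$pas[cat_fwd$pas$gene_id == g, ]
    b <- cat_rev$pas[cat_rev$pas$gene_id == g, ]
    expect_equal(mirror_coord(b$peak, L), a$peak)
    expect_equal(b$rank, a$rank)
    expect_equal(b$region, a$region)
    expect_equal(b$internal_priming, a$internal_priming)
    expect_equal(b$overall_pau, a$overall_pau)
  }
})
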