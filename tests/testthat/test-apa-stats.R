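test_that("oriented positions make larger values distal on both strands", {
  expect_equal(oriented_positions(c(100, 200), "+"), c(100, 200))
  expect_equal(oriented_positions(c(100, 200), "-"), c(-100, -200))
  expect_equal(oriented_positions(numeric(0), "-"), numeric(0))
})

test_that("signed KS statistic matches hand-computable cases", {
  r <- ks_signed(rep(100, 50), rep(200, 50))
  expect_equal(r$apa_change, 1)      # disjoint supports: complete lengthening
  expect_equal(r$D, 1)
  expect_lt(r$pvalue, 1e-10)

  same <- ks_signed(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$apa_change, 0)
  expect_equal(same$pvalue, 1)

  r2 <- ks_signed(c(0, 0, 0, 10), c(0, 10, 10, 10))
  expect_equal(r2$apa_change, 0.5)   # F_a - F_b = 0.75 - 0.25 at position 0

  expect_error(ks_signed(numeric(0), c(1)), "non-empty")
})

test_that("signed KS equals the brute-force CDF scan on random inputs", {
  set.seed(7)
  for (i in 1:200) {
    a <- sample(0:50, sample(1:500, 1), replace = TRUE)
    b <- sample(0:50, sample(1:500, 1), replace = TRUE)
    got <- ks_signed(a, b)
    want <- oracle_ks(a, b)
    expect_equal(got$D, want$D, tolerance = 1e-12)
    expect_equal(got$apa_change, want$signed, tolerance = 1e-12)
    # the unsigned statistic agrees with the stock two-sample KS test
    expect_equal(got$D, unname(suppressWarnings(
      stats::ks.test(a, b)$statistic)), tolerance = 1e-12)
  }
})

test_that("signed KS is antisymmetric and order-invariant", {
  set.seed(8)
  for (i in 1:50) {
    a <- rpois(40, 30); b <- rpois(60, 35)
    f <- ks_signed(a, b); g <- ks_signed(b, a)
    expect_identical(f$apa_change, -g$apa_change)
    expect_identical(f$pvalue, g$pvalue)
    # coordinate shift and monotone relabeling leave everything unchanged
    s <- ks_signed(a + 1000, b + 1000)
    expect_identical(s[c("apa_change", "D", "pvalue")],
                     f[c("apa_change", "D", "pvalue")])
    m <- ks_signed(a^3, b^3)
    expect_identical(m[c("apa_change", "D", "pvalue")],
                     f[c("apa_change", "D", "pvalue")])
  }
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(9)
  p <- runif(100)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dispersion estimates recover Poisson and NB simulations", {
  set.seed(10)
  n <- 50L
  cond <- setNames(rep(c("a", "b"), each = n / 2), paste0("s", 1:n))
  totals <- matrix(200L, nrow = 60, ncol = n,
                   dimnames = list(NULL, names(cond)))
  # Poisson counts around a usage of 0.4: true dispersion 0
  pois <- matrix(rpois(60 * n, 80), nrow = 60,
                 dimnames = list(NULL, names(cond)))
  d0 <- estimate_dispersion(pois, totals, cond)
  expect_lt(mean(d0), 0.05)
  # NB with dispersion 0.5
  nb <- matrix(rnbinom(60 * n, mu = 80, size = 2), nrow = 60,
               dimnames = list(NULL, names(cond)))
  d5 <- estimate_dispersion(nb, totals, cond)
  expect_gt(median(d5), 0.25)
  expect_lt(median(d5), 0.9)
  # constant counts: raw estimate floored
  const <- matrix(80L, nrow = 12, ncol = n,
                  dimnames = list(NULL, names(cond)))
  dc <- estimate_dispersion(const, totals[1:12, , drop = FALSE], cond)
  expect_equal(unname(attr(dc, "raw")), rep(1e-8, 12))
  three <- c(1L, 2L, 26L)   # two 'a' replicates but a single 'b'
  expect_error(estimate_dispersion(pois[, three, drop = FALSE],
                                   totals[, three, drop = FALSE],
                                   cond[three]), ">= 2 samples")
})

pas_test_fixture <- function(usage_a, usage_b, reads_per_sample = 100L,
                             n_rep = 3L, seed = 1L) {
  # two PASs 60 nt apart; deterministic allocation per usage vector
  m <- make_gene_model("G1", strand = "+", end = 1000L,
                       utr3 = cbind(start = 650L, end = 1000L))
  cond <- setNames(rep(c("a", "b"), each = n_rep),
                   paste0(rep(c("a", "b"), each = n_rep), 1:n_rep))
  set.seed(seed)
  mk <- function(u) {
    k1 <- rbinom(1, reads_per_sample, u[1])
    c(rep(700L, k1), rep(760L, reads_per_sample - k1))
  }
  ends <- lapply(cond, function(cc) if (cc == "a") mk(usage_a) else mk(usage_b))
  names(ends) <- names(cond)
  tab <- make_table(ends, conditions = cond)
  catalog <- call_pas(tab, as_models(m))
  pm <- compute_pau(count_reads_at_pas(tab, catalog), catalog,
                    conditions = cond)
  list(tab = tab, catalog = catalog, pm = pm, models = as_models(m))
}

test_that("a planted usage switch is significant with the right sign", {
  fx <- pas_test_fixture(c(0.7, 0.3), c(0.2, 0.8), seed = 3)
  res <- pas_usage_test(fx$pm, fx$catalog, "a", "b")
  r1 <- res[res$pas_id == "G1:PAS1", ]
  expect_true(r1$significant)
  expect_lt(r1$log2fc_usage, 0)
  r2 <- res[res$pas_id == "G1:PAS2", ]
  expect_gt(r2$log2fc_usage, 0)
})

test_that("identical counts in every sample give p near 1", {
  m <- make_gene_model("G1", strand = "+", end = 1000L,
                       utr3 = cbind(start = 650L, end = 1000L))
  cond <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b")
  ends <- lapply(cond, function(cc) c(rep(700L, 40), rep(760L, 60)))
  tab <- make_table(ends, conditions = cond)
  ct <- call_pas(tab, as_models(m))
  pm <- compute_pau(count_reads_at_pas(tab, ct), ct, conditions = cond)
  res <- pas_usage_test(pm, ct, "a", "b")
  expect_true(all(res$pvalue > 0.99))
  expect_equal(res$log2fc_usage, c(0, 0))
})

test_that("the PAS-level test refuses unreplicated designs", {
  fx <- pas_test_fixture(c(0.5, 0.5), c(0.5, 0.5), n_rep = 1L)
  expect_error(pas_usage_test(fx$pm, fx$catalog, "a", "b"),
               "2 replicates")
})

test_that("gene-level KS detects a planted distal shift and is antisymmetric", {
  ref <- simulate_reference(40, prop_lengthening = 0.25, seed = 61)
  tab <- simulate_read_ends(ref, seed = 62)
  ct <- call_pas(tab, ref$models)
  fwd <- gene_level_apa(tab, ct, ref$models, "ctrl", "expt")
  rev <- gene_level_apa(tab, ct, ref$models, "expt", "ctrl")
  expect_identical(fwd$apa_change, -rev$apa_change)
  expect_identical(fwd$pvalue, rev$pvalue)
  planted <- names(Filter(function(t) t$effect == "lengthening", ref$truth))
  called <- fwd[fwd$gene_id %in% planted, ]
  expect_true(all(called$apa_change > 0))
  expect_true(mean(called$direction == "lengthening") >= 0.8)
  # no opposite-direction calls on null genes
  nulls <- fwd[!fwd$gene_id %in% planted, ]
  expect_false(any(nulls$direction == "shortening"))
})

test_that("genes with fewer than two retained PASs are not KS-tested", {
  m <- make_gene_model("G1", strand = "+", end = 1000L)
  cond <- c(a1 = "a", b1 = "b")
  tab <- make_table(list(a1 = rep(800L, 30), b1 = rep(800L, 30)),
                    conditions = cond)
  ct <- call_pas(tab, as_models(m))
  res <- gene_level_apa(tab, ct, as_models(m), "a", "b")
  expect_equal(nrow(res), 0L)
})

test_that("proximal/distal correlation needs 3 genes and finite variance", {
  ref <- simulate_reference(10, prop_lengthening = 0.3, seed = 63)
  tab <- simulate_read_ends(ref, seed = 64)
  ct <- call_pas(tab, ref$models)
  pm <- compute_pau(count_reads_at_pas(tab, ct), ct,
                    conditions = tab$conditions)
  gr <- gene_level_apa(tab, ct, ref$models, "ctrl", "expt")
  expect_error(proximal_distal_correlation(gr[1:2, ], pm, ct, "ctrl", "expt"),
               "3 genes")
  pdc <- proximal_distal_correlation(gr, pm, ct, "ctrl", "expt")
  expect_true(is.finite(pdc$r_prox) && is.finite(pdc$r_dist))
})
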