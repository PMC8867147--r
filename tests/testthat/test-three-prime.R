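mk_reads <- function(gene_id, end3, condition, replicate = 1L) {
  tibble::tibble(
    read_id = sprintf("r%d", seq_along(end3)),
    gene_id = gene_id,
    align_start = pmax(0L, as.integer(end3) - 99L),
    align_end = as.integer(end3) + 1L,
    end3 = as.integer(end3),
    polya_len = NA_real_,
    condition = condition,
    replicate = replicate
  )
}

test_that("overlap filter keeps reads at or above the fraction threshold", {
  loci <- tibble::tibble(gene_id = "g1", locus_start = 0, locus_end = 1000)
  reads <- tibble::tibble(
    read_id = c("in", "out", "edge"),
    gene_id = "g1",
    align_start = c(100L, 900L, 800L),
    align_end = c(300L, 1900L, 1800L),
    condition = "wt", replicate = 1L
  )
  kept <- filter_reads_overlap(reads, loci)
  # fully inside: fraction 1; 100/1000 overlap: 0.1 removed;
  # exactly 200/1000 = 0.2: kept (rule removes strictly below)
  expect_setequal(kept$read_id, c("in", "edge"))

  degen <- dplyr::bind_rows(
    reads[1, ],
    tibble::tibble(read_id = "z", gene_id = "g1", align_start = 5L,
                   align_end = 5L, condition = "wt", replicate = 1L))
  expect_warning(res <- filter_reads_overlap(degen, loci), "degenerate")
  expect_equal(res$read_id, "in")
})

test_that("end usage normalizes per condition within gene", {
  reads <- dplyr::bind_rows(
    mk_reads("g1", c(100, 100, 150), "wt"),
    mk_reads("g1", c(150, 150), "mut"))
  u <- end_usage(reads)
  expect_equal(u$usage_wt[u$position == 100], 2 / 3)
  expect_equal(u$usage_wt[u$position == 150], 1 / 3)
  expect_equal(u$usage_mut[u$position == 150], 1)
  expect_equal(u$usage_mut[u$position == 100], 0)
  expect_equal(sum(u$usage_wt), 1)
  expect_equal(sum(u$usage_mut), 1)
  # single read: usage 1 at its end
  u1 <- end_usage(mk_reads("g2", 42, "wt"))
  expect_equal(u1$usage_wt, 1)
})

test_that("KS test matches examples and the permutation oracle", {
  same <- apa_test(c(100, 110, 120), c(100, 110, 120))
  expect_equal(same$ks_stat, 0)
  expect_equal(same$p, 1)

  disjoint <- apa_test(c(100, 110, 120), c(300, 310, 320))
  expect_equal(disjoint$ks_stat, 1)
  # D = 1 at n = m = 3: exact permutation p = 2/20
  expect_equal(disjoint$p, 0.1, tolerance = 1e-12)
  expect_equal(disjoint$p, perm_ks_p(c(100, 110, 120), c(300, 310, 320)))

  # symmetry
  expect_equal(apa_test(c(1, 5, 9), c(2, 3, 4))$ks_stat,
               apa_test(c(2, 3, 4), c(1, 5, 9))$ks_stat)
  expect_error(apa_test(numeric(0), 1:3), "non-empty")
})

test_that("KS statistic equals the brute-force ECDF sup on random pairs", {
  set.seed(5)
  for (i in 1:300) {
    x <- sample(1:50, sample(5:40, 1), replace = TRUE)
    y <- sample(1:50, sample(5:40, 1), replace = TRUE)
    expect_equal(apa_test(x, y)$ks_stat, ks_brute(x, y), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up definition and its properties", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.8)), c(0.015, 0.06, 0.8))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_direct(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order-preserving
  }
})

test_that("shift classification follows the usage-difference extremes", {
  # wt {800 x9, 500 x1}, mut {800 x4, 500 x6}:
  # delta(500) = +0.5, delta(800) = -0.5 -> proximal shift of 300
  reads <- dplyr::bind_rows(
    mk_reads("g1", rep(c(800, 500), c(9, 1)), "wt"),
    mk_reads("g1", rep(c(800, 500), c(4, 6)), "mut"))
  u <- end_usage(reads)
  cs <- classify_shift(u)
  expect_equal(cs$pos_most_reduced, 800)
  expect_equal(cs$pos_most_increased, 500)
  expect_equal(cs$direction, "proximal")
  expect_equal(cs$distance, 300)

  # swap conditions: distal
  reads2 <- dplyr::bind_rows(
    mk_reads("g1", rep(c(800, 500), c(4, 6)), "wt"),
    mk_reads("g1", rep(c(800, 500), c(9, 1)), "mut"))
  cs2 <- classify_shift(end_usage(reads2))
  expect_equal(cs2$direction, "distal")
  expect_equal(cs2$distance, 300)

  # identical usage: no direction
  reads3 <- dplyr::bind_rows(
    mk_reads("g1", c(500, 800), "wt"), mk_reads("g1", c(500, 800), "mut"))
  expect_equal(classify_shift(end_usage(reads3))$direction, "none")
})

test_that("classification distance is invariant under coordinate translation", {
  set.seed(21)
  ends_wt <- sample(c(400, 700), 60, replace = TRUE, prob = c(0.2, 0.8))
  ends_mut <- sample(c(400, 700), 60, replace = TRUE, prob = c(0.6, 0.4))
  base <- classify_shift(end_usage(dplyr::bind_rows(
    mk_reads("g", ends_wt, "wt"), mk_reads("g", ends_mut, "mut"))))
  shifted <- classify_shift(end_usage(dplyr::bind_rows(
    mk_reads("g", ends_wt + 1000, "wt"),
    mk_reads("g", ends_mut + 1000, "mut"))))
  expect_equal(base$distance, shifted$distance)
  expect_equal(base$direction, shifted$direction)
})

test_that("low-support stray positions are absorbed by binning", {
  # one stray single-read end at 305 should not displace the extremes
  reads <- dplyr::bind_rows(
    mk_reads("g1", c(rep(800, 20), rep(500, 5)), "wt"),
    mk_reads("g1", c(rep(800, 10), rep(500, 14), 305), "mut"))
  cs <- classify_shift(end_usage(reads))
  expect_equal(cs$direction, "proximal")
  expect_equal(cs$pos_most_increased, 500)
})

test_that("APA detection excludes small genes and classifies significant ones", {
  set.seed(31)
  reads <- dplyr::bind_rows(
    # strong proximal shift, 60 reads each
    mk_reads("g_shift", rep(c(900, 600), c(55, 5)), "wt"),
    mk_reads("g_shift", rep(c(900, 600), c(25, 35)), "mut"),
    # null gene
    mk_reads("g_null", rep(c(900, 600), c(50, 10)), "wt"),
    mk_reads("g_null", rep(c(900, 600), c(48, 12)), "mut"),
    # too few reads
    mk_reads("g_small", c(100, 110), "wt"),
    mk_reads("g_small", c(100, 120), "mut"))
  res <- detect_apa_shifts(reads, min_reads = 10)
  expect_setequal(res$gene_id, c("g_shift", "g_null"))
  expect_equal(attr(res, "excluded"), 1L)
  shift_row <- res[res$gene_id == "g_shift", ]
  expect_true(shift_row$significant)
  expect_equal(shift_row$direction, "proximal")
  expect_equal(shift_row$distance, 300)
  expect_true(is.na(res$direction[res$gene_id == "g_null"]))
})

test_that("site-to-end distances use the signed 3' convention", {
  sites <- tibble::tibble(gene_id = "g1", position = 100L)
  reads <- mk_reads("g1", c(100, 150, 180, 80), "wt")
  d <- site_end_distances(sites, reads)
  expect_setequal(d$distance, c(0L, 50L, 80L, -20L))
  h <- distance_histogram(d, bin_width = 50)
  expect_equal(sum(h$count), 4L)
  # site on a gene with no reads is skipped
  d2 <- site_end_distances(tibble::tibble(gene_id = "gX", position = 1L),
                           reads)
  expect_equal(nrow(d2), 0L)
})

test_that("poly(A) comparison matches Mann-Whitney examples", {
  mk_pa <- function(gene, lens, cond) {
    r <- mk_reads(gene, seq(100, by = 1, length.out = length(lens)), cond)
    r$polya_len <- lens
    r
  }
  # identical constant samples: p = 1
  reads <- dplyr::bind_rows(mk_pa("g1", rep(50, 12), "wt"),
                            mk_pa("g1", rep(50, 12), "mut"))
  res <- polya_compare(reads, min_reads = 10)
  expect_equal(res$p, 1)

  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 0.1
  reads2 <- dplyr::bind_rows(mk_pa("g2", c(1, 2, 3), "wt"),
                             mk_pa("g2", c(4, 5, 6), "mut"))
  res2 <- polya_compare(reads2, min_reads = 3)
  expect_equal(res2$u_stat, 0)
  expect_equal(res2$p, 0.1)
  expect_equal(res2$p, perm_mw_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res2$delta_median, 3)

  # min_reads filter
  expect_equal(nrow(polya_compare(reads2, min_reads = 10)), 0L)
})

test_that("a +30 nt poly(A) shift at n=m=50 is detected at FDR < 0.05", {
  set.seed(17)
  hits <- 0L
  n_sim <- 60
  for (i in seq_len(n_sim)) {
    reads <- dplyr::bind_rows(
      {r <- mk_reads("g1", 1:50 + 100, "wt"); r$polya_len <- rnorm(50, 100, 25); r},
      {r <- mk_reads("g1", 1:50 + 100, "mut"); r$polya_len <- rnorm(50, 130, 25); r})
    res <- polya_compare(reads, min_reads = 10)
    if (res$fdr < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.9)
})
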