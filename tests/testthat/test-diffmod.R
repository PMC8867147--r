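test_that("mod_rate applies the coverage floor", {
  expect_equal(mod_rate(0, 50), 0)
  expect_equal(mod_rate(30, 60), 0.5)
  expect_true(is.na(mod_rate(5, 10)))  # below the default floor of 20
  expect_equal(mod_rate(5, 10, min_cov = 10), 0.5)
  expect_error(mod_rate(-1, 10), "non-negative")
  expect_error(mod_rate(11, 10), "<=")
})

test_that("two-proportion z-test matches its closed form and symmetries", {
  r <- two_prop_ztest(80, 100, 40, 100)
  expect_equal(r$dmr, 0.4)
  expect_equal(r$z, 5.7735, tolerance = 1e-4)
  expect_equal(r$p, 7.73e-9, tolerance = 1e-2)

  # identical rates
  r0 <- two_prop_ztest(50, 100, 50, 100)
  expect_equal(r0$dmr, 0)
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)

  # antisymmetry: swapping groups negates dmr and z, preserves p
  rs <- two_prop_ztest(40, 100, 80, 100)
  expect_equal(rs$dmr, -r$dmr)
  expect_equal(rs$z, -r$z)
  expect_equal(rs$p, r$p)

  # degenerate pooled rate 0 or 1: no demonstrable difference
  expect_equal(two_prop_ztest(0, 50, 0, 80)$p, 1)
  expect_equal(two_prop_ztest(50, 50, 80, 80)$p, 1)
  expect_equal(two_prop_ztest(0, 50, 0, 80)$z, 0)
})

test_that("z^2 equals the chi-square statistic without continuity correction", {
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    z <- two_prop_ztest(x1, n1, x2, n2)$z
    chi <- suppressWarnings(
      stats::chisq.test(matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2,
                               byrow = TRUE), correct = FALSE)$statistic)
    expect_equal(z^2, unname(chi), tolerance = 1e-10)
  }
})

test_that("p-value is non-increasing in coverage at fixed rates", {
  cov <- c(30, 60, 120, 240, 480)
  p <- two_prop_ztest(0.6 * cov, cov, 0.2 * cov, cov)$p
  expect_true(all(diff(p) <= 0))
})

test_that("a site is called only when every replicate passes p and sign", {
  # replicate counts chosen so one replicate is clearly non-significant
  strong <- list(wt_mod = c(80, 80, 80), wt_n = c(100, 100, 100),
                 mut_mod = c(40, 40, 40), mut_n = c(100, 100, 100))
  mixed <- strong; mixed$mut_mod <- c(40, 75, 40)  # replicate 2 near-null
  reversed <- list(wt_mod = c(40, 40, 40), wt_n = c(100, 100, 100),
                   mut_mod = c(80, 80, 80), mut_n = c(100, 100, 100))

  expect_true(do.call(make_site_calls, strong) |>
                call_hypo_sites() |> dplyr::pull(called))
  expect_false(do.call(make_site_calls, mixed) |>
                 call_hypo_sites() |> dplyr::pull(called))
  # hypermethylated direction (dmr < 0) is never called
  expect_false(do.call(make_site_calls, reversed) |>
                 call_hypo_sites() |> dplyr::pull(called))
})

test_that("sites with any under-covered replicate are excluded and counted", {
  calls <- dplyr::bind_rows(
    make_site_calls(position = 10, wt_mod = c(80, 80, 8), wt_n = c(100, 100, 10),
                    mut_mod = c(40, 40, 4), mut_n = c(100, 100, 10)),
    make_site_calls(position = 20, wt_mod = c(80, 80, 80),
                    wt_n = c(100, 100, 100),
                    mut_mod = c(40, 40, 40), mut_n = c(100, 100, 100))
  )
  res <- call_hypo_sites(calls)
  expect_equal(nrow(res), 1L)
  expect_equal(res$position, 20)
  expect_equal(attr(res, "excluded"), 1L)
})

test_that("replicate pooling and BH options change the decision rule only", {
  # marginal per-replicate evidence that pooling rescues
  calls <- make_site_calls(wt_mod = c(30, 30, 30), wt_n = c(100, 100, 100),
                           mut_mod = c(18, 18, 18), mut_n = c(100, 100, 100))
  per_rep <- call_hypo_sites(calls)
  pooled <- call_hypo_sites(calls, pool_replicates = TRUE)
  expect_false(per_rep$called)
  expect_true(pooled$called)
  expect_equal(pooled$n_rep, 1L)
  # BH across one site is the identity, so the strong site stays called
  strong <- make_site_calls(wt_mod = c(80, 80, 80), wt_n = c(100, 100, 100),
                            mut_mod = c(40, 40, 40), mut_n = c(100, 100, 100))
  expect_true(call_hypo_sites(strong, adjust = "BH")$called)
})

test_that("called sites are annotated with segment and metagene coordinate", {
  calls <- make_site_calls(position = 250,
                           wt_mod = c(80, 80, 80), wt_n = c(100, 100, 100),
                           mut_mod = c(40, 40, 40), mut_n = c(100, 100, 100))
  res <- call_hypo_sites(calls, models = toy_models())
  expect_equal(res$gene_id, "g1")
  expect_equal(res$segment, "CDS")
  expect_equal(res$metagene_coord, 1.5)
})

test_that("dmr histogram bins right-closed over (0,1] and conserves counts", {
  sites <- tibble::tibble(dmr = c(0.1, 0.12, 0.45))
  h <- dmr_histogram(sites, bin_width = 0.25, called_only = FALSE)
  expect_equal(h$count[h$bin_lo == 0], 2L)
  expect_equal(h$count[h$bin_lo == 0.25], 1L)
  expect_equal(sum(h$count), nrow(sites))

  empty <- dmr_histogram(sites[0, ], bin_width = 0.25, called_only = FALSE)
  expect_true(all(empty$count == 0L))

  set.seed(1)
  rnd <- tibble::tibble(dmr = runif(200))
  expect_equal(sum(dmr_histogram(rnd, 0.05, called_only = FALSE)$count), 200L)
})
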