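#' Per-site modification rate with a coverage floor
#'
#' Returns `n_modified / n_reads` where coverage reaches `min_cov`, and `NA`
#' below the floor. A stable proportion needs a minimum read depth; sites
#' failing the floor are excluded from testing rather than tested noisily.
#'
#' @param n_modified,n_reads Non-negative counts (vectorized).
#' @param min_cov Minimum reads required to report a rate (default 20).
#' @return Numeric vector of rates in \[0, 1\], NA below `min_cov`.
#' @examples
#' mod_rate(c(0, 30, 5), c(50, 60, 10), min_cov = 20)
#' @export
mod_rate <- function(n_modified, n_reads, min_cov = 20) {
  if (any(n_modified < 0 | n_reads < 0)) abort("counts must be non-negative")
  if (any(n_modified > n_reads)) abort("n_modified must be <= n_reads")
  if_else(n_reads >= min_cov, n_modified / n_reads, NA_real_)
}

#' Two-proportion z-test on modification rates
#'
#' The site-level differential test: the difference of modification rates
#' (DMR = rate1 - rate2) is standardized with the pooled-variance
#' two-proportion statistic
#' \deqn{z = (\hat p_1 - \hat p_2) / \sqrt{\bar p (1 - \bar p)(1/n_1 + 1/n_2)}}
#' and referred to the standard normal, two-sided. `z^2` equals the 2x2
#' chi-square statistic without continuity correction. When the pooled rate
#' is exactly 0 or 1 no between-group difference is demonstrable and the
#' test degenerates to `z = 0`, `p = 1`.
#'
#' @param n1_mod,n1 Modified and total reads in group 1 (vectorized).
#' @param n2_mod,n2 Modified and total reads in group 2.
#' @return A tibble with columns `dmr`, `z`, `p`.
#' @examples
#' two_prop_ztest(80, 100, 40, 100)
#' @export
two_prop_ztest <- function(n1_mod, n1, n2_mod, n2) {
  if (any(c(n1_mod, n1, n2_mod, n2) < 0)) {
    abort("counts must be non-negative")
  }
  if (any(n1_mod > n1 | n2_mod > n2)) abort("n_mod must be <= n")
  if (any(n1 == 0 | n2 == 0)) abort("group sizes must be positive")
  p1 <- n1_mod / n1
  p2 <- n2_mod / n2
  pooled <- (n1_mod + n2_mod) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- if_else(se > 0, (p1 - p2) / se, 0)
  p <- if_else(se > 0, 2 * pnorm(-abs(z)), 1)
  tibble(dmr = p1 - p2, z = z, p = p)
}

#' Call replicate-consistent hypomethylated sites
#'
#' For every site, each replicate's wild-type and mutant counts are paired by
#' replicate index and tested with [two_prop_ztest()] (DMR = wild-type rate
#' minus mutant rate, so positive DMR means hypomethylated in the mutant).
#' A site is called when, in every replicate, both conditions meet the
#' coverage floor, the two-sided p-value is below `alpha`, and the DMR is
#' positive — the replicate-intersection reading of "consistently detected
#' in all replicates". Sites with any replicate below coverage are excluded
#' and counted in the returned summary attribute.
#'
#' @param mod_calls A `mod_calls` tibble (see [read_mod_calls()]).
#' @param models Optional `tx_models`; when supplied, called and uncalled
#'   sites on coding transcripts are annotated with `segment` and
#'   `metagene_coord`.
#' @param alpha Per-replicate significance threshold (default 0.01), applied
#'   to raw p-values; set `adjust = "BH"` to threshold per-replicate
#'   BH-adjusted values instead.
#' @param min_cov Coverage floor per condition per replicate (default 20).
#' @param pool_replicates If TRUE, counts are summed across replicates and a
#'   single pooled test decides the call (alternative reading of replicate
#'   consistency; default FALSE).
#' @param adjust `"none"` (default) or `"BH"` (adjust each replicate's
#'   p-values across sites before thresholding).
#' @return A tibble of class `hypo_sites`, one row per testable site:
#'   `transcript_id`, `position`, `kmer`, `n_rep`, `dmr` (mean over
#'   replicates), `p_max` (largest per-replicate p), `called`, and a nested
#'   `replicates` list-column with per-replicate `rate_wt`, `rate_mut`,
#'   `dmr`, `z`, `p`. Attribute `excluded` counts sites dropped for
#'   coverage. With `models`, adds `gene_id`, `segment`, `metagene_coord`.
#' @export
call_hypo_sites <- function(mod_calls, models = NULL, alpha = 0.01,
                            min_cov = 20, pool_replicates = FALSE,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  check_prob(alpha, "alpha")
  check_count(min_cov, "min_cov")
  calls <- validate_mod_calls(mod_calls)

  wide <- calls |>
    tidyr::pivot_wider(
      id_cols = c("transcript_id", "position", "kmer", "replicate"),
      names_from = "condition",
      values_from = c("n_reads", "n_modified")
    )
  check_cols(wide, c("n_reads_wt", "n_reads_mut"), "mod-call table (both conditions)")

  if (pool_replicates) {
    wide <- wide |>
      group_by(.data$transcript_id, .data$position, .data$kmer) |>
      summarise(replicate = 1L,
                n_reads_wt = sum(.data$n_reads_wt),
                n_modified_wt = sum(.data$n_modified_wt),
                n_reads_mut = sum(.data$n_reads_mut),
                n_modified_mut = sum(.data$n_modified_mut),
                .groups = "drop")
  }

  covered <- !is.na(wide$n_reads_wt) & !is.na(wide$n_reads_mut) &
    wide$n_reads_wt >= min_cov & wide$n_reads_mut >= min_cov
  wide$ok <- covered

  # drop whole sites where any replicate pair is missing or under-covered
  site_ok <- wide |>
    group_by(.data$transcript_id, .data$position, .data$kmer) |>
    summarise(all_ok = all(.data$ok), .groups = "drop")
  n_excluded <- sum(!site_ok$all_ok)
  wide <- wide |>
    inner_join(filter(site_ok, .data$all_ok),
               by = c("transcript_id", "position", "kmer"))

  if (nrow(wide) == 0) {
    out <- tibble(transcript_id = character(), position = integer(),
                  kmer = character(), n_rep = integer(), dmr = double(),
                  p_max = double(), called = logical(),
                  replicates = list())
    attr(out, "excluded") <- n_excluded
    class(out) <- c("hypo_sites", class(out))
    return(out)
  }

  tst <- two_prop_ztest(wide$n_modified_wt, wide$n_reads_wt,
                        wide$n_modified_mut, wide$n_reads_mut)
  wide$rate_wt <- wide$n_modified_wt / wide$n_reads_wt
  wide$rate_mut <- wide$n_modified_mut / wide$n_reads_mut
  wide$dmr <- tst$dmr
  wide$z <- tst$z
  wide$p <- tst$p
  wide$p_thresh <- if (adjust == "BH") {
    stats::ave(wide$p, wide$replicate,
               FUN = function(p) p.adjust(p, method = "BH"))
  } else {
    wide$p
  }

  out <- wide |>
    select("transcript_id", "position", "kmer", "replicate", "rate_wt",
           "rate_mut", "dmr", "z", "p", "p_thresh") |>
    tidyr::nest(replicates = c("replicate", "rate_wt", "rate_mut", "dmr",
                               "z", "p", "p_thresh")) |>
    mutate(
      n_rep = purrr::map_int(.data$replicates, nrow),
      dmr = purrr::map_dbl(.data$replicates, ~ mean(.x$dmr)),
      p_max = purrr::map_dbl(.data$replicates, ~ max(.x$p)),
      called = purrr::map_lgl(
        .data$replicates,
        ~ all(.x$p_thresh < alpha) && all(.x$dmr > 0))
    ) |>
    select("transcript_id", "position", "kmer", "n_rep", "dmr", "p_max",
           "called", "replicates")

  if (!is.null(models)) out <- annotate_sites(out, models)
  attr(out, "excluded") <- n_excluded
  class(out) <- c("hypo_sites", setdiff(class(out), "hypo_sites"))
  out
}

#' Histogram of differential modification rates
#'
#' Bins the DMR of (called) sites over (0, 1\] with right-closed bins of
#' width `bin_width`; counts sum to the number of sites binned.
#'
#' @param sites A `hypo_sites` tibble (or any tibble with a `dmr` column).
#' @param bin_width Bin width in DMR units (default 0.05).
#' @param called_only Restrict to `called` sites when the column is present
#'   (default TRUE).
#' @return A tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
dmr_histogram <- function(sites, bin_width = 0.05, called_only = TRUE) {
  check_prob(bin_width, "bin_width", open = c(TRUE, FALSE))
  df <- as_tibble(sites)
  if (called_only && "called" %in% names(df)) df <- filter(df, .data$called)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  out <- tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  if (nrow(df) == 0) {
    out$count <- 0L
    return(out)
  }
  idx <- cut(df$dmr, breaks = breaks, right = TRUE, include.lowest = FALSE)
  out$count <- as.integer(tabulate(idx, nbins = nrow(out)))
  out
}
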