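#' Filter reads by fractional overlap with their gene locus
#'
#' A read is retained when the overlap between its aligned span and the gene
#' locus, divided by the read's aligned length, is at least `min_frac`
#' (reads overlapping "less than" the threshold are removed, so a fraction
#' exactly at `min_frac` is kept). The denominator is the read's aligned
#' length, not the locus length, so long genes do not shed all their reads.
#' Degenerate reads (`align_start == align_end`) are removed with a warning.
#'
#' @param reads Read table with `gene_id`, `align_start`, `align_end`.
#' @param loci Tibble with `gene_id`, `locus_start`, `locus_end` (0-based,
#'   half-open). Reads of genes absent from `loci` are dropped.
#' @param min_frac Minimum overlap fraction (default 0.2).
#' @return The retained rows of `reads`.
#' @export
filter_reads_overlap <- function(reads, loci, min_frac = 0.2) {
  check_prob(min_frac, "min_frac", open = c(TRUE, FALSE))
  check_cols(reads, c("gene_id", "align_start", "align_end"), "reads")
  check_cols(loci, c("gene_id", "locus_start", "locus_end"), "loci")
  if (any(loci$locus_end <= loci$locus_start)) {
    abort("locus length must be positive")
  }
  degenerate <- reads$align_start == reads$align_end
  if (any(degenerate)) {
    warn(paste0("removing ", sum(degenerate), " degenerate read(s) with ",
                "align_start == align_end"))
    reads <- reads[!degenerate, ]
  }
  joined <- inner_join(as_tibble(reads), as_tibble(loci), by = "gene_id")
  ov <- pmax(0, pmin(joined$align_end, joined$locus_end) -
               pmax(joined$align_start, joined$locus_start))
  frac <- ov / (joined$align_end - joined$align_start)
  joined |>
    filter(frac >= min_frac) |>
    select(-"locus_start", -"locus_end")
}

#' Per-gene normalized 3'-end usage
#'
#' Counts read 3'-end positions per gene and condition and normalizes each
#' condition's counts to its total, so usage sums to 1 per condition within
#' each gene (where the condition has reads).
#'
#' @param reads Read table with `gene_id`, `end3`, `condition`.
#' @return A tibble with `gene_id`, `position`, `n_wt`, `n_mut`,
#'   `usage_wt`, `usage_mut`.
#' @export
end_usage <- function(reads) {
  check_cols(reads, c("gene_id", "end3", "condition"), "reads")
  as_tibble(reads) |>
    count(.data$gene_id, position = .data$end3, .data$condition) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n",
                       values_fill = 0L, names_prefix = "n_") |>
    (\(d) {
      if (!"n_wt" %in% names(d)) d$n_wt <- 0L
      if (!"n_mut" %in% names(d)) d$n_mut <- 0L
      d
    })() |>
    group_by(.data$gene_id) |>
    mutate(usage_wt = if (sum(.data$n_wt) > 0)
             .data$n_wt / sum(.data$n_wt) else NA_real_,
           usage_mut = if (sum(.data$n_mut) > 0)
             .data$n_mut / sum(.data$n_mut) else NA_real_) |>
    ungroup() |>
    arrange(.data$gene_id, .data$position)
}

#' Two-sample Kolmogorov-Smirnov test of 3'-end distributions
#'
#' Compares the two conditions' read 3'-end position multisets with the
#' two-sample KS statistic (the supremum distance between the two empirical
#' CDFs). The p-value is exact for small untied samples and otherwise comes
#' from the asymptotic two-sample distribution (ties make the asymptotic
#' p-value conservative/approximate, as usual for KS on discrete data).
#'
#' @param ends_wt,ends_mut Numeric vectors of 3'-end coordinates.
#' @return A tibble with `ks_stat`, `p`, `n_wt`, `n_mut`.
#' @export
apa_test <- function(ends_wt, ends_mut) {
  if (length(ends_wt) == 0 || length(ends_mut) == 0) {
    abort("both samples must be non-empty")
  }
  kt <- suppressWarnings(ks.test(ends_wt, ends_mut))
  tibble(ks_stat = unname(kt$statistic), p = kt$p.value,
         n_wt = length(ends_wt), n_mut = length(ends_mut))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment (wraps `stats::p.adjust(method = "BH")`):
#' order-preserving, adjusted values are at least the raw values and at most
#' 1.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.005, 0.04, 0.8))
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Classify the direction and distance of a 3'-end usage shift
#'
#' For one gene's usage table, the per-position usage difference
#' Delta(pos) = usage_mut(pos) - usage_wt(pos) is computed over the union of
#' observed positions; the position minimizing Delta is the most-reduced
#' site and the position maximizing Delta the most-increased site. The shift
#' is `proximal` when the increased site lies 5' (upstream) of the reduced
#' site, `distal` when downstream, and `none` when all differences vanish.
#' Distance is the absolute coordinate difference. Positions supported by
#' fewer than `min_support` reads in both conditions are collapsed into
#' `bin_width`-nt bins (represented by the bin midpoint) before the
#' argmin/argmax, which stabilizes the extremes against isolated stray
#' ends; exact ties at an extreme are broken toward the position nearest
#' the annotated 3' end.
#'
#' @param usage One gene's rows from [end_usage()].
#' @param bin_width Bin width for low-support positions (default 10 nt).
#' @param min_support Support threshold below which positions are binned
#'   (default 2 reads).
#' @param tx_end Optional annotated 3'-end coordinate used for tie-breaking;
#'   defaults to the largest observed position.
#' @return A one-row tibble: `pos_most_reduced`, `pos_most_increased`,
#'   `direction` (`proximal`/`distal`/`none`), `distance`.
#' @export
classify_shift <- function(usage, bin_width = 10, min_support = 2,
                           tx_end = NULL) {
  check_cols(usage, c("position", "n_wt", "n_mut", "usage_wt", "usage_mut"),
             "usage")
  if ("gene_id" %in% names(usage) &&
      length(unique(usage$gene_id)) > 1) {
    abort("classify_shift expects a single gene's usage table")
  }
  u <- as_tibble(usage)
  u$usage_wt[is.na(u$usage_wt)] <- 0
  u$usage_mut[is.na(u$usage_mut)] <- 0
  low <- u$n_wt < min_support & u$n_mut < min_support
  u$repr <- if_else(low,
                    floor(u$position / bin_width) * bin_width + bin_width / 2,
                    as.numeric(u$position))
  agg <- u |>
    group_by(position = .data$repr) |>
    summarise(delta = sum(.data$usage_mut) - sum(.data$usage_wt),
              .groups = "drop")
  if (is.null(tx_end)) tx_end <- max(u$position)
  if (all(abs(agg$delta) < 1e-12)) {
    return(tibble(pos_most_reduced = NA_real_,
                  pos_most_increased = NA_real_,
                  direction = "none", distance = NA_real_))
  }
  pick <- function(cand) cand[which.min(abs(cand - tx_end))]
  pos_red <- pick(agg$position[agg$delta == min(agg$delta)])
  pos_inc <- pick(agg$position[agg$delta == max(agg$delta)])
  direction <- dplyr::case_when(
    pos_inc < pos_red ~ "proximal",
    pos_inc > pos_red ~ "distal",
    TRUE ~ "none"
  )
  tibble(pos_most_reduced = pos_red, pos_most_increased = pos_inc,
         direction = direction,
         distance = abs(pos_red - pos_inc))
}

#' Detect alternative-polyadenylation shifts across genes
#'
#' Pipeline: (optional) overlap filtering against gene loci, per-gene
#' two-sample KS test of 3'-end distributions between conditions
#' (replicates pooled within condition), BH adjustment across genes, and
#' per-position usage-difference classification ([classify_shift()]) for
#' genes passing the FDR threshold. Genes with fewer than `min_reads` reads
#' in either condition are excluded (count kept in attribute `excluded`).
#'
#' @param reads Read table (see [read_reads()]).
#' @param loci Optional loci tibble for [filter_reads_overlap()]; built from
#'   `models` when those are given instead.
#' @param models Optional `tx_models`; the gene locus is taken as
#'   `[0, max total_len)` over the gene's transcripts, and the annotated 3'
#'   end anchors tie-breaking.
#' @param min_reads Minimum reads per condition per gene (default 10).
#' @param fdr FDR threshold for classification (default 0.05).
#' @param min_frac Overlap-fraction threshold (default 0.2).
#' @param bin_width,min_support Passed to [classify_shift()].
#' @return A tibble of class `apa_shifts`: `gene_id`, `n_wt`, `n_mut`,
#'   `ks_stat`, `p`, `fdr`, `significant`, `pos_most_reduced`,
#'   `pos_most_increased`, `direction`, `distance` (classification columns
#'   NA for non-significant genes).
#' @export
detect_apa_shifts <- function(reads, loci = NULL, models = NULL,
                              min_reads = 10, fdr = 0.05, min_frac = 0.2,
                              bin_width = 10, min_support = 2) {
  check_count(min_reads, "min_reads", min = 1)
  check_prob(fdr, "fdr")
  reads <- as_tibble(reads)
  tx_ends <- NULL
  if (is.null(loci) && !is.null(models)) {
    loci <- as_tibble(models) |>
      group_by(.data$gene_id) |>
      summarise(locus_start = 0, locus_end = max(.data$total_len),
                .groups = "drop")
  }
  if (!is.null(loci)) {
    tx_ends <- setNames(loci$locus_end - 1, loci$gene_id)
    reads <- filter_reads_overlap(reads, loci, min_frac = min_frac)
  }

  usage <- end_usage(reads)
  totals <- usage |>
    group_by(.data$gene_id) |>
    summarise(tot_wt = sum(.data$n_wt), tot_mut = sum(.data$n_mut),
              .groups = "drop")
  testable <- totals$gene_id[totals$tot_wt >= min_reads &
                               totals$tot_mut >= min_reads]
  n_excluded <- nrow(totals) - length(testable)

  ends <- filter(reads, .data$gene_id %in% testable)
  tests <- ends |>
    group_by(.data$gene_id) |>
    summarise(apa_test(.data$end3[.data$condition == "wt"],
                       .data$end3[.data$condition == "mut"]),
              .groups = "drop")
  tests$fdr <- bh_adjust(tests$p)
  tests$significant <- tests$fdr < fdr

  cls <- purrr::map_dfr(seq_len(nrow(tests)), function(i) {
    if (!tests$significant[i]) {
      return(tibble(pos_most_reduced = NA_real_,
                    pos_most_increased = NA_real_,
                    direction = NA_character_, distance = NA_real_))
    }
    g <- tests$gene_id[i]
    classify_shift(filter(usage, .data$gene_id == g),
                   bin_width = bin_width, min_support = min_support,
                   tx_end = if (!is.null(tx_ends)) unname(tx_ends[g]) else NULL)
  })
  out <- dplyr::bind_cols(tests, cls)
  attr(out, "excluded") <- n_excluded
  class(out) <- c("apa_shifts", class(out))
  out
}

#' Distances from hypomethylated sites to read 3' ends
#'
#' For every (site, read) pair within a gene, distance = read `end3` minus
#' site position: positive when the read ends 3' (downstream) of the site.
#' Sites on genes with no reads are skipped.
#'
#' @param sites Tibble with `gene_id` and `position` (e.g. annotated called
#'   sites).
#' @param reads Read table with `gene_id`, `end3`.
#' @return A tibble `gene_id`, `position`, `end3`, `condition`, `distance`.
#' @export
site_end_distances <- function(sites, reads) {
  check_cols(sites, c("gene_id", "position"), "sites")
  check_cols(reads, c("gene_id", "end3"), "reads")
  s <- select(as_tibble(sites), "gene_id", "position")
  r <- select(as_tibble(reads), "gene_id", "end3",
              dplyr::any_of("condition"))
  out <- inner_join(s, r, by = "gene_id", relationship = "many-to-many")
  out$distance <- out$end3 - out$position
  out
}

#' Histogram of site-to-end distances
#'
#' @param distances Output of [site_end_distances()] (or any tibble with a
#'   `distance` column).
#' @param bin_width Bin width in nt (default 25).
#' @return A tibble `bin_lo`, `bin_hi`, `count`.
#' @export
distance_histogram <- function(distances, bin_width = 25) {
  d <- distances$distance
  if (length(d) == 0) {
    return(tibble(bin_lo = numeric(), bin_hi = numeric(), count = integer()))
  }
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling((max(d) + 1) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
         count = as.integer(tabulate(idx, nbins = length(breaks) - 1)))
}

#' Per-gene poly(A) length comparison
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of poly(A) tail lengths
#' between conditions for every gene with at least `min_reads` measured
#' reads per condition, with BH adjustment across genes. The p-value is
#' exact for small untied samples and uses the tie-corrected normal
#' approximation otherwise.
#'
#' @param reads Read table with `gene_id`, `polya_len`, `condition`; rows
#'   with missing `polya_len` are ignored.
#' @param min_reads Minimum measured reads per condition (default 10).
#' @return A tibble: `gene_id`, `n_wt`, `n_mut`, `median_wt`, `median_mut`,
#'   `delta_median` (mut - wt), `u_stat`, `p`, `fdr`.
#' @export
polya_compare <- function(reads, min_reads = 10) {
  check_count(min_reads, "min_reads", min = 1)
  check_cols(reads, c("gene_id", "polya_len", "condition"), "reads")
  r <- filter(as_tibble(reads), !is.na(.data$polya_len))
  out <- r |>
    group_by(.data$gene_id) |>
    summarise(
      n_wt = sum(.data$condition == "wt"),
      n_mut = sum(.data$condition == "mut"),
      median_wt = median(.data$polya_len[.data$condition == "wt"]),
      median_mut = median(.data$polya_len[.data$condition == "mut"]),
      u_stat = {
        x <- .data$polya_len[.data$condition == "wt"]
        y <- .data$polya_len[.data$condition == "mut"]
        if (length(x) && length(y))
          unname(suppressWarnings(wilcox.test(x, y))$statistic)
        else NA_real_
      },
      p = {
        x <- .data$polya_len[.data$condition == "wt"]
        y <- .data$polya_len[.data$condition == "mut"]
        if (length(x) && length(y)) {
          if (length(unique(c(x, y))) == 1L) 1 else
            suppressWarnings(wilcox.test(x, y))$p.value
        } else NA_real_
      },
      .groups = "drop"
    ) |>
    filter(.data$n_wt >= min_reads, .data$n_mut >= min_reads) |>
    mutate(delta_median = .data$median_mut - .data$median_wt,
           fdr = bh_adjust(.data$p)) |>
    select("gene_id", "n_wt", "n_mut", "median_wt", "median_mut",
           "delta_median", "u_stat", "p", "fdr")
  out
}
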