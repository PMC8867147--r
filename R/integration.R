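#' Simple differential expression on a count matrix
#'
#' A deliberately simple DE procedure for plumbing and simulation work —
#' not a negative-binomial model. Counts are normalized to counts-per-million
#' with a pseudocount of 1, log2-transformed, and compared between
#' conditions with a per-gene two-sample t-test; p-values are BH-adjusted.
#' The log2 fold change is the difference of mean log2 CPM (mutant minus
#' wild type). An externally produced DE table (e.g. from a dedicated DE
#' package) can be supplied to downstream steps instead via
#' [read_de_table()].
#'
#' @param counts Gene-by-sample count matrix with gene rownames, or a tibble
#'   whose first column is `gene_id` and remaining columns are samples.
#' @param condition Character vector (one per sample) over `wt`/`mut`.
#' @return A tibble: `gene_id`, `log2fc`, `pvalue`, `padj`. All-zero genes
#'   get `log2fc = 0`, `pvalue = 1`.
#' @export
simple_de <- function(counts, condition) {
  if (is.data.frame(counts)) {
    ids <- counts[[1]]
    mat <- as.matrix(counts[, -1, drop = FALSE])
    rownames(mat) <- ids
  } else {
    mat <- as.matrix(counts)
    if (is.null(rownames(mat))) abort("counts must carry gene identifiers")
  }
  if (length(condition) != ncol(mat)) {
    abort("length(condition) must equal the number of samples")
  }
  if (!all(condition %in% c("wt", "mut"))) {
    abort("condition must be 'wt' or 'mut'")
  }
  if (sum(condition == "wt") < 2 || sum(condition == "mut") < 2) {
    abort("need at least 2 samples per condition")
  }
  cpm <- t(t(mat) / colSums(mat)) * 1e6
  lg <- log2(cpm + 1)
  wt <- lg[, condition == "wt", drop = FALSE]
  mut <- lg[, condition == "mut", drop = FALSE]
  all_zero <- rowSums(mat) == 0
  lfc <- rowMeans(mut) - rowMeans(wt)
  pv <- vapply(seq_len(nrow(lg)), function(i) {
    if (all_zero[i]) return(1)
    x <- wt[i, ]; y <- mut[i, ]
    if (sd(x) == 0 && sd(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    t.test(y, x)$p.value
  }, numeric(1))
  lfc[all_zero] <- 0
  tibble(gene_id = rownames(mat), log2fc = unname(lfc), pvalue = pv,
         padj = bh_adjust(pv))
}

#' Association between hypomethylation and expression change
#'
#' Two-sided Mann-Whitney test comparing the log2 fold changes of genes
#' carrying hypomethylated sites against all other genes in the DE table;
#' group medians give the direction of the association (a lower
#' hypomethylated-gene median means hypomethylated genes tend to be
#' downregulated). Genes absent from the DE table are excluded rather than
#' imputed.
#'
#' @param de DE tibble with `gene_id`, `log2fc` (see [simple_de()] /
#'   [read_de_table()]).
#' @param hypo_genes Character vector of gene ids with called
#'   hypomethylated sites.
#' @return An object of class `lfc_association`: list with `n_hypo`,
#'   `n_other`, `mw_statistic`, `p`, `median_lfc_hypo`, `median_lfc_other`.
#' @export
lfc_association <- function(de, hypo_genes) {
  check_cols(de, c("gene_id", "log2fc"), "de")
  is_hypo <- de$gene_id %in% hypo_genes
  x <- de$log2fc[is_hypo]
  y <- de$log2fc[!is_hypo]
  if (length(x) == 0) abort("no hypomethylated genes found in the DE table")
  if (length(y) == 0) abort("no background genes left in the DE table")
  mw <- suppressWarnings(wilcox.test(x, y))
  structure(
    list(n_hypo = length(x), n_other = length(y),
         mw_statistic = unname(mw$statistic), p = mw$p.value,
         median_lfc_hypo = median(x), median_lfc_other = median(y)),
    class = "lfc_association")
}

#' @export
print.lfc_association <- function(x, ...) {
  cat("Hypomethylation-expression association (two-sided Mann-Whitney)\n")
  cat(sprintf("  %d hypomethylated vs %d other genes\n", x$n_hypo, x$n_other))
  cat(sprintf("  median log2FC: %.3f (hypo) vs %.3f (other)\n",
              x$median_lfc_hypo, x$median_lfc_other))
  cat(sprintf("  U = %.1f, p = %.3g\n", x$mw_statistic, x$p))
  invisible(x)
}

#' Overlap classes of hypomethylated and differentially expressed genes
#'
#' A gene is DE when `|log2fc| > log2(fc_thresh)` and `padj < padj_thresh`.
#' Classes partition the union of the hypomethylated and DE gene sets:
#' `down_hypo` / `up_hypo` (DE and hypomethylated), `down_only` / `up_only`
#' (DE only), `hypo_only`.
#'
#' @param de DE tibble with `gene_id`, `log2fc`, `padj`.
#' @param hypo_genes Character vector of hypomethylated gene ids.
#' @param fc_thresh Fold-change threshold on the natural scale (default
#'   1.5).
#' @param padj_thresh Adjusted-p threshold (default 0.05).
#' @return A tibble with `class` and `n`; the counts sum to the size of the
#'   union of the two gene sets.
#' @export
overlap_classes <- function(de, hypo_genes, fc_thresh = 1.5,
                            padj_thresh = 0.05) {
  if (!is.numeric(fc_thresh) || fc_thresh <= 0) {
    abort("fc_thresh must be positive")
  }
  check_prob(padj_thresh, "padj_thresh")
  check_cols(de, c("gene_id", "log2fc", "padj"), "de")
  lfc_cut <- log2(fc_thresh)
  de2 <- as_tibble(de) |>
    mutate(is_de = abs(.data$log2fc) > lfc_cut & .data$padj < padj_thresh,
           is_hypo = .data$gene_id %in% hypo_genes)
  hypo_only_extra <- setdiff(hypo_genes, de2$gene_id)
  cls <- de2 |>
    filter(.data$is_de | .data$is_hypo) |>
    mutate(class = dplyr::case_when(
      .data$is_de & .data$log2fc < 0 & .data$is_hypo ~ "down_hypo",
      .data$is_de & .data$log2fc > 0 & .data$is_hypo ~ "up_hypo",
      .data$is_de & .data$log2fc < 0 ~ "down_only",
      .data$is_de & .data$log2fc > 0 ~ "up_only",
      TRUE ~ "hypo_only"
    )) |>
    count(.data$class, name = "n")
  lv <- c("down_hypo", "up_hypo", "down_only", "up_only", "hypo_only")
  out <- tibble(class = lv) |>
    left_join(cls, by = "class") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  out$n[out$class == "hypo_only"] <-
    out$n[out$class == "hypo_only"] + length(hypo_only_extra)
  out
}
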