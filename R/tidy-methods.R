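#' Tidy a hypomethylation-expression association
#'
#' @param x A `lfc_association` object.
#' @param ... Ignored.
#' @return A one-row tibble with the test statistic, p-value and group
#'   medians.
#' @export
tidy.lfc_association <- function(x, ...) {
  tibble(statistic = x$mw_statistic, p.value = x$p,
         median_lfc_hypo = x$median_lfc_hypo,
         median_lfc_other = x$median_lfc_other,
         method = "two-sided Mann-Whitney")
}

#' @rdname tidy.lfc_association
#' @export
glance.lfc_association <- function(x, ...) {
  tibble(n_hypo = x$n_hypo, n_other = x$n_other, statistic = x$mw_statistic,
         p.value = x$p)
}

#' Tidy a consensus motif
#'
#' @param x A `consensus_motif` object.
#' @param ... Ignored.
#' @return The per-position nucleotide frequency matrix in long form
#'   (`pos`, `base`, `freq`) — the sequence-logo matrix.
#' @export
tidy.consensus_motif <- function(x, ...) {
  x$pfm
}

#' @rdname tidy.consensus_motif
#' @export
glance.consensus_motif <- function(x, ...) {
  tibble(motif = x$motif, n_sites = x$n_sites, n_matching = x$n_matching,
         background_freq = x$background_freq, p.value = x$p)
}

#' Flatten per-replicate site results
#'
#' @param x A `hypo_sites` tibble.
#' @param ... Ignored.
#' @return One row per (site, replicate) with rates, DMR, z and p.
#' @export
tidy.hypo_sites <- function(x, ...) {
  as_tibble(x) |>
    tidyr::unnest("replicates", names_sep = "_") |>
    rename(rate_wt = "replicates_rate_wt", rate_mut = "replicates_rate_mut",
           replicate = "replicates_replicate", dmr_rep = "replicates_dmr",
           z = "replicates_z", p = "replicates_p",
           p_thresh = "replicates_p_thresh")
}

#' @rdname tidy.hypo_sites
#' @export
glance.hypo_sites <- function(x, ...) {
  called <- filter(as_tibble(x), .data$called)
  tibble(n_tested = nrow(x), n_called = nrow(called),
         n_excluded = attr(x, "excluded") %||% NA_integer_,
         mean_dmr_called = if (nrow(called)) mean(called$dmr) else NA_real_)
}
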