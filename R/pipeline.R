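#' Run the full downstream analysis pipeline
#'
#' Composes the stages on one dataset: replicate-consistent hypomethylated
#' site calling, metagene placement and segment summaries, k-mer/consensus
#' motif analysis against the transcript background, alternative-
#' polyadenylation shift detection from read 3' ends, poly(A) length
#' comparison, differential expression (internal [simple_de()] unless a DE
#' table is supplied) and the hypomethylation-expression association and
#' overlap classes. All thresholds default to the analysis' standard values
#' (alpha 0.01, coverage floor 20, FDR 0.05, fold change 1.5, padj 0.05,
#' 10 reads, 20% overlap). Given `out_dir`, every stage table is written as
#' TSV alongside a JSON run manifest (inputs, parameters, package version);
#' a rerun with identical inputs and parameters reproduces the outputs
#' byte-for-byte.
#'
#' @param data A `m6adiff_sim` object, a list from [read_dataset()], or a
#'   dataset directory path.
#' @param out_dir Optional output directory.
#' @param de Optional externally produced DE tibble (`gene_id`, `log2fc`,
#'   `padj`); replaces the internal [simple_de()] fit.
#' @param alpha Per-replicate significance threshold for site calling.
#' @param min_cov Coverage floor per condition per replicate.
#' @param fdr FDR threshold for APA classification.
#' @param fc_thresh,padj_thresh DE thresholds for [overlap_classes()].
#' @param min_reads Minimum reads per condition for APA and poly(A) tests.
#' @param overlap_frac Read/locus overlap-fraction filter.
#' @return A list of class `m6adiff_run` with elements `sites`, `called`,
#'   `segment_fractions`, `metagene`, `sites_per_tx`, `kmer_freq`,
#'   `last3_freq`, `motif`, `apa`, `polya`, `de`, `association`, `overlap`,
#'   `distances`, `distance_hist`, `summary`, `params`.
#' @export
run_pipeline <- function(data, out_dir = NULL, de = NULL,
                         alpha = 0.01, min_cov = 20, fdr = 0.05,
                         fc_thresh = 1.5, padj_thresh = 0.05,
                         min_reads = 10, overlap_frac = 0.2) {
  check_prob(alpha, "alpha")
  check_prob(fdr, "fdr")
  check_prob(padj_thresh, "padj_thresh")
  check_prob(overlap_frac, "overlap_frac", open = c(TRUE, FALSE))
  if (is.character(data) && length(data) == 1L) data <- read_dataset(data)
  if (inherits(data, "m6adiff_sim")) {
    data <- list(models = data$models, mod_calls = data$mod_calls,
                 reads = data$reads, counts = data$counts,
                 truth = data$truth)
  }
  models <- data$models

  sites <- call_hypo_sites(data$mod_calls, models = models, alpha = alpha,
                           min_cov = min_cov)
  called <- filter(as_tibble(sites), .data$called)
  hypo_genes <- unique(called$gene_id)

  coding_called <- filter(called, !is.na(.data$segment))
  seg <- if (nrow(coding_called)) segment_fractions(coding_called) else NULL
  mg <- metagene_histogram(called)
  spt <- sites_per_transcript(called)

  kf <- kmer_frequencies(called)
  l3 <- last3_frequencies(called$kmer)
  motif <- NULL
  if (nrow(called) > 0 && "sequence" %in% names(models) &&
      any(!is.na(models$sequence))) {
    motif <- consensus_motif(called$kmer, background_kmers(models))
  }

  apa <- detect_apa_shifts(data$reads, models = models,
                           min_reads = min_reads, fdr = fdr,
                           min_frac = overlap_frac)
  polya <- polya_compare(data$reads, min_reads = min_reads)

  if (is.null(de)) {
    condition <- sub("_.*$", "", names(data$counts)[-1])
    de <- simple_de(data$counts, condition)
  }
  assoc <- if (length(hypo_genes) && nrow(de)) {
    lfc_association(de, hypo_genes)
  }
  ovl <- overlap_classes(de, hypo_genes, fc_thresh = fc_thresh,
                         padj_thresh = padj_thresh)
  dists <- site_end_distances(called, data$reads)
  dist_hist <- distance_histogram(dists)

  params <- list(alpha = alpha, min_cov = min_cov, fdr = fdr,
                 fc_thresh = fc_thresh, padj_thresh = padj_thresh,
                 min_reads = min_reads, overlap_frac = overlap_frac)

  run <- structure(
    list(sites = sites, called = called, segment_fractions = seg,
         metagene = mg, sites_per_tx = spt, kmer_freq = kf,
         last3_freq = l3, motif = motif, apa = apa, polya = polya, de = de,
         association = assoc, overlap = ovl, distances = dists,
         distance_hist = dist_hist, params = params,
         truth = data$truth),
    class = "m6adiff_run")
  run$summary <- pipeline_summary(run)

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Aggregate summary of a pipeline run
#'
#' One row per headline quantity: tested/called site and gene counts,
#' segment percentages, the top k-mer and consensus motif with its
#' enrichment p, APA test/direction counts, poly(A) calls, and the
#' expression-association statistics.
#'
#' @param run A `m6adiff_run`.
#' @return A tibble with `metric` and `value` (character-coded) columns.
#' @export
pipeline_summary <- function(run) {
  called <- run$called
  seg_pct <- function(s) {
    if (is.null(run$segment_fractions)) return(NA_real_)
    v <- run$segment_fractions$percent[run$segment_fractions$segment == s]
    if (length(v)) v else 0
  }
  apa_sig <- filter(as_tibble(run$apa), .data$significant)
  vals <- list(
    n_sites_tested = nrow(run$sites),
    n_sites_called = nrow(called),
    n_hypo_genes = length(unique(called$gene_id)),
    pct_utr5 = seg_pct("UTR5"),
    pct_cds = seg_pct("CDS"),
    pct_utr3 = seg_pct("UTR3"),
    top_kmer = if (nrow(run$kmer_freq)) run$kmer_freq$kmer[1] else NA,
    top_last3 = if (nrow(run$last3_freq)) run$last3_freq$last3[1] else NA,
    consensus_motif = if (!is.null(run$motif)) run$motif$motif else NA,
    motif_p = if (!is.null(run$motif)) run$motif$p else NA_real_,
    n_apa_tested = nrow(run$apa),
    n_apa_significant = nrow(apa_sig),
    n_apa_proximal = sum(apa_sig$direction == "proximal", na.rm = TRUE),
    n_apa_distal = sum(apa_sig$direction == "distal", na.rm = TRUE),
    n_polya_tested = nrow(run$polya),
    n_polya_significant = sum(run$polya$fdr < run$params$fdr, na.rm = TRUE),
    n_de_genes = sum(abs(run$de$log2fc) > log2(run$params$fc_thresh) &
                       run$de$padj < run$params$padj_thresh, na.rm = TRUE),
    association_p = if (!is.null(run$association))
      run$association$p else NA_real_,
    median_lfc_hypo = if (!is.null(run$association))
      run$association$median_lfc_hypo else NA_real_,
    median_lfc_other = if (!is.null(run$association))
      run$association$median_lfc_other else NA_real_
  )
  tibble(metric = names(vals),
         value = vapply(vals, function(v) as.character(v[1]), character(1)))
}

#' @export
print.m6adiff_run <- function(x, ...) {
  cat("m6adiff pipeline run\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) readr::write_tsv(as_tibble(df),
                                       file.path(out_dir, name))
  }
  sites_flat <- run$sites |>
    as_tibble() |>
    select(-"replicates")
  wr(sites_flat, "sites.tsv")
  wr(run$called |> select(-"replicates"), "hypo_sites.tsv")
  if (nrow(run$called)) {
    write_sites_bed(run$called, file.path(out_dir, "hypo_sites.bed"))
  }
  wr(run$segment_fractions, "segment_fractions.tsv")
  wr(run$metagene, "metagene_histogram.tsv")
  wr(run$sites_per_tx, "sites_per_transcript.tsv")
  wr(run$kmer_freq, "kmer_frequencies.tsv")
  wr(run$last3_freq, "last3_frequencies.tsv")
  if (!is.null(run$motif)) wr(run$motif$pfm, "motif_pfm.tsv")
  wr(run$apa, "apa_shifts.tsv")
  wr(run$polya, "polya_comparison.tsv")
  wr(run$de, "differential_expression.tsv")
  wr(run$overlap, "overlap_classes.tsv")
  wr(run$distance_hist, "site_end_distance_histogram.tsv")
  wr(run$summary, "summary.tsv")
  manifest <- list(
    package = "m6adiff",
    version = as.character(utils::packageVersion("m6adiff")),
    parameters = run$params,
    outputs = list.files(out_dir, pattern = "\\.(tsv|bed)$")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
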