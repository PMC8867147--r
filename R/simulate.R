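#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a desk-scale two-condition direct-RNA-seq experiment:
#' 500 coding transcripts (one gene each), 5 candidate A-centered sites per
#' transcript of which 10% carry a planted hypomethylation effect
#' (wild-type rate 0.2 + `effect_dmr`, mutant rate 0.2, consistent with
#' mostly-moderate DMR magnitudes), a small background modification rate at
#' the remaining sites, ~100x site coverage in each of 3 replicates per
#' condition, 100 reads per gene per condition whose 3' ends follow a
#' distal/proximal two-site mixture with a planted proximal shift in 10% of
#' genes, normally distributed poly(A) lengths with a planted location
#' shift in a small gene subset, and Poisson-lognormal expression counts
#' with a planted negative log2 fold change on hypomethylated genes.
#'
#' @param seed Integer seed; identical configs and seeds give identical
#'   datasets.
#' @param n_transcripts Number of transcripts/genes.
#' @param utr5_range,cds_range,utr3_range Segment length ranges (nt).
#' @param n_replicates Replicates per condition for modification calls.
#' @param coverage Mean reads per site per replicate per condition
#'   (Poisson).
#' @param sites_per_transcript Candidate A-centered sites per transcript.
#' @param site_segment_probs Probabilities that a candidate site falls in
#'   the 5'UTR, CDS and 3'UTR (default `c(0.05, 0.80, 0.15)`, a
#'   CDS-dominated placement typical of writer-dependent sites).
#' @param effect_fraction Fraction of candidate sites with a planted effect.
#' @param effect_dmr Planted differential modification rate (wt - mut).
#' @param base_rate Mutant-condition modification rate at effect sites.
#' @param background_rate Modification rate at non-effect sites (both
#'   conditions).
#' @param motif IUPAC motif planted at effect sites (default `"YHAGA"`).
#' @param apa_fraction Fraction of genes with a planted proximal 3'-end
#'   shift.
#' @param apa_shift_distance Distance (nt) from distal to proximal site.
#' @param apa_shift_mass Usage mass moved to the proximal site in the
#'   mutant.
#' @param proximal_base_weight Baseline proximal-site usage in both
#'   conditions.
#' @param reads_per_gene Reads per gene per condition.
#' @param end_jitter Uniform jitter (+/- nt) on read 3' ends.
#' @param polya_mean,polya_sd Baseline poly(A) length distribution (nt).
#' @param polya_shift Planted poly(A) location shift (nt, mutant minus wild
#'   type) in `polya_fraction` of genes.
#' @param polya_fraction Fraction of genes with the poly(A) shift.
#' @param expr_base_meanlog,expr_base_sdlog Log-normal baseline for per-gene
#'   mean counts.
#' @param expr_lfc Planted log2 fold change (mutant vs wt) on hypomethylated
#'   genes.
#' @param expr_noise_sd Per-sample log2-scale noise SD.
#' @param n_samples Expression samples per condition.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 500,
                       utr5_range = c(50, 150),
                       cds_range = c(300, 900),
                       utr3_range = c(150, 350),
                       n_replicates = 3,
                       coverage = 100,
                       sites_per_transcript = 5,
                       site_segment_probs = c(0.05, 0.80, 0.15),
                       effect_fraction = 0.10,
                       effect_dmr = 0.4,
                       base_rate = 0.2,
                       background_rate = 0.02,
                       motif = "YHAGA",
                       apa_fraction = 0.10,
                       apa_shift_distance = 100,
                       apa_shift_mass = 0.3,
                       proximal_base_weight = 0.1,
                       reads_per_gene = 100,
                       end_jitter = 5,
                       polya_mean = 100,
                       polya_sd = 25,
                       polya_shift = -20,
                       polya_fraction = 0.06,
                       expr_base_meanlog = log(200),
                       expr_base_sdlog = 1,
                       expr_lfc = -0.5,
                       expr_noise_sd = 0.5,
                       n_samples = 3) {
  cfg <- as.list(environment())
  check_count(cfg$seed, "seed")
  check_count(cfg$n_transcripts, "n_transcripts", min = 1)
  check_count(cfg$n_replicates, "n_replicates", min = 1)
  check_prob(cfg$effect_fraction, "effect_fraction", open = c(FALSE, FALSE))
  check_prob(cfg$effect_dmr, "effect_dmr", open = c(TRUE, FALSE))
  check_prob(cfg$apa_shift_mass, "apa_shift_mass")
  check_prob(cfg$apa_fraction, "apa_fraction", open = c(FALSE, FALSE))
  if (cfg$base_rate + cfg$effect_dmr > 1) {
    abort("base_rate + effect_dmr must not exceed 1")
  }
  if (cfg$apa_shift_mass + cfg$proximal_base_weight > 1) {
    abort("apa_shift_mass + proximal_base_weight must not exceed 1")
  }
  if (min(cfg$cds_range) < 6 * cfg$sites_per_transcript + 10) {
    abort("CDS too short to place the requested candidate sites")
  }
  if (length(cfg$site_segment_probs) != 3 ||
      any(cfg$site_segment_probs < 0) || sum(cfg$site_segment_probs) <= 0) {
    abort("site_segment_probs must be 3 non-negative weights")
  }
  structure(cfg, class = "sim_config")
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one concrete instance of an IUPAC motif
motif_instance <- function(motif) {
  paste(vapply(strsplit(normalize_seq(motif), "")[[1]],
               function(ch) sample(iupac_expand(ch), 1), character(1)),
        collapse = "")
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Emits transcript models and sequences, a per-site mod-call table, a
#' per-read table, an expression count matrix, and truth tables identifying
#' every planted effect, in exactly the layouts the readers in this package
#' consume. Candidate sites are spaced across the CDS; effect sites carry a
#' concrete instance of the configured motif (central A at the site), other
#' candidate sites a random A-centered 5-mer. Modification counts are
#' binomial; 3' ends come from a distal/proximal mixture with condition-
#' dependent weights in shifted genes plus uniform end jitter; poly(A)
#' lengths are truncated normal; counts are Poisson around a log-normal
#' baseline with the planted fold change on hypomethylated genes.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `m6adiff_sim`: `config`, `models` (tx_models
#'   with sequences), `mod_calls`, `reads`, `counts`, and `truth` (list of
#'   `sites`, `apa`, `polya`, `expression` tibbles).
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("config must be a sim_config")
  cfg <- config
  set.seed(cfg$seed)

  n <- cfg$n_transcripts
  utr5 <- sample(seq(cfg$utr5_range[1], cfg$utr5_range[2]), n, replace = TRUE)
  cds <- sample(seq(cfg$cds_range[1], cfg$cds_range[2]), n, replace = TRUE)
  utr3 <- sample(seq(cfg$utr3_range[1], cfg$utr3_range[2]), n, replace = TRUE)
  models <- tibble(
    transcript_id = sprintf("t%04d", seq_len(n)),
    gene_id = sprintf("g%04d", seq_len(n)),
    utr5_len = utr5, cds_len = cds, utr3_len = utr3,
    total_len = utr5 + cds + utr3, coding = TRUE
  )

  # candidate sites: segment drawn from the configured mix, position
  # uniform within the segment, resampled until sites are >= 5 nt apart
  # so planted 5-mer windows never collide
  k_sites <- cfg$sites_per_transcript
  site_list <- purrr::map(seq_len(n), function(i) {
    total <- models$total_len[i]
    segs <- sample(c("UTR5", "CDS", "UTR3"), k_sites, replace = TRUE,
                   prob = cfg$site_segment_probs)
    draw <- function() {
      vapply(segs, function(s) {
        rng <- switch(s,
          UTR5 = c(2L, utr5[i] - 1L),
          CDS = c(utr5[i], utr5[i] + cds[i] - 1L),
          UTR3 = c(utr5[i] + cds[i], total - 4L))
        as.integer(rng[1] + floor(runif(1) * (rng[2] - rng[1] + 1)))
      }, integer(1))
    }
    pos <- draw()
    while (k_sites > 1 && min(dist(pos)) < 5) pos <- draw()
    tibble(transcript_id = models$transcript_id[i],
           gene_id = models$gene_id[i], position = sort(unname(pos)))
  })
  sites <- bind_rows(site_list)
  n_sites <- nrow(sites)
  n_effect <- round(cfg$effect_fraction * n_sites)
  effect_idx <- sample.int(n_sites, n_effect)
  sites$is_effect <- FALSE
  sites$is_effect[effect_idx] <- TRUE

  # sequences with planted windows (motif instance at effect sites,
  # random A-centered 5-mer elsewhere)
  seqs <- vapply(models$total_len, rand_seq, character(1))
  names(seqs) <- models$transcript_id
  sites$kmer <- NA_character_
  for (i in seq_len(n_sites)) {
    km <- if (sites$is_effect[i]) {
      motif_instance(cfg$motif)
    } else {
      paste0(rand_seq(2), "A", rand_seq(2))
    }
    tx <- sites$transcript_id[i]
    p <- sites$position[i]
    substr(seqs[tx], p - 1, p + 3) <- km  # 1-based window around 0-based p
    sites$kmer[i] <- km
  }
  models$sequence <- unname(seqs)

  # per-site binomial modification calls
  rate_wt <- if_else(sites$is_effect, cfg$base_rate + cfg$effect_dmr,
                     cfg$background_rate)
  rate_mut <- if_else(sites$is_effect, cfg$base_rate, cfg$background_rate)
  grid <- tidyr::expand_grid(
    site = seq_len(n_sites),
    condition = c("wt", "mut"),
    replicate = seq_len(cfg$n_replicates)
  )
  grid$n_reads <- pmax(1L, rpois(nrow(grid), cfg$coverage))
  grid$rate <- if_else(grid$condition == "wt", rate_wt[grid$site],
                       rate_mut[grid$site])
  grid$n_modified <- rbinom(nrow(grid), grid$n_reads, grid$rate)
  mod_calls <- tibble(
    transcript_id = sites$transcript_id[grid$site],
    position = sites$position[grid$site],
    kmer = sites$kmer[grid$site],
    condition = grid$condition,
    replicate = grid$replicate,
    n_reads = grid$n_reads,
    n_modified = grid$n_modified
  ) |>
    arrange(.data$transcript_id, .data$position, .data$condition,
            .data$replicate)

  # reads: distal/proximal 3'-end mixture with planted proximal shifts
  n_apa <- round(cfg$apa_fraction * n)
  apa_genes <- sample(models$gene_id, n_apa)
  reads <- purrr::map_dfr(seq_len(n), function(i) {
    total <- models$total_len[i]
    distal <- total - 1L
    proximal <- distal - cfg$apa_shift_distance
    shifted <- models$gene_id[i] %in% apa_genes
    purrr::map_dfr(c("wt", "mut"), function(cond) {
      m <- cfg$reads_per_gene
      w_prox <- cfg$proximal_base_weight +
        if (shifted && cond == "mut") cfg$apa_shift_mass else 0
      use_prox <- runif(m) < w_prox
      end3 <- if_else(use_prox, proximal, distal) +
        sample(seq(-cfg$end_jitter, cfg$end_jitter), m, replace = TRUE)
      end3 <- pmin(pmax(end3, 1L), total - 1L)
      rlen <- pmin(end3 + 1L,
                   as.integer(round(runif(m, 0.4, 0.9) * total)))
      tibble(
        gene_id = models$gene_id[i],
        align_start = end3 + 1L - rlen,
        align_end = end3 + 1L,
        end3 = as.integer(end3),
        condition = cond,
        replicate = sample(seq_len(cfg$n_replicates), m, replace = TRUE)
      )
    })
  })
  reads$read_id <- sprintf("r%06d", seq_len(nrow(reads)))

  # poly(A) lengths with a planted location shift in a gene subset
  n_pa <- round(cfg$polya_fraction * n)
  polya_genes <- sample(models$gene_id, n_pa)
  mu <- cfg$polya_mean +
    if_else(reads$gene_id %in% polya_genes & reads$condition == "mut",
            cfg$polya_shift, 0)
  reads$polya_len <- round(pmax(rnorm(nrow(reads), mu, cfg$polya_sd), 5), 1)
  reads <- validate_reads(
    select(reads, "read_id", "gene_id", "align_start", "align_end", "end3",
           "polya_len", "condition", "replicate"))

  # expression counts with planted negative lfc on hypomethylated genes
  hypo_genes <- unique(sites$gene_id[sites$is_effect])
  base_mu <- stats::rlnorm(n, cfg$expr_base_meanlog, cfg$expr_base_sdlog)
  true_lfc <- if_else(models$gene_id %in% hypo_genes, cfg$expr_lfc, 0)
  samples <- c(paste0("wt_", seq_len(cfg$n_samples)),
               paste0("mut_", seq_len(cfg$n_samples)))
  cond_of <- rep(c("wt", "mut"), each = cfg$n_samples)
  mat <- sapply(seq_along(samples), function(j) {
    lam <- base_mu * 2^(true_lfc * (cond_of[j] == "mut")) *
      2^rnorm(n, 0, cfg$expr_noise_sd)
    rpois(n, lam)
  })
  colnames(mat) <- samples
  counts <- dplyr::bind_cols(tibble(gene_id = models$gene_id),
                             as_tibble(mat))

  truth <- list(
    sites = tibble(transcript_id = sites$transcript_id,
                   gene_id = sites$gene_id,
                   position = sites$position, kmer = sites$kmer,
                   is_effect = sites$is_effect,
                   rate_wt = rate_wt, rate_mut = rate_mut,
                   true_dmr = rate_wt - rate_mut),
    apa = tibble(gene_id = models$gene_id,
                 shifted = models$gene_id %in% apa_genes,
                 direction = if_else(models$gene_id %in% apa_genes,
                                     "proximal", "none"),
                 distance = if_else(models$gene_id %in% apa_genes,
                                    cfg$apa_shift_distance, 0),
                 mass = if_else(models$gene_id %in% apa_genes,
                                cfg$apa_shift_mass, 0)),
    polya = tibble(gene_id = models$gene_id,
                   shift = if_else(models$gene_id %in% polya_genes,
                                   cfg$polya_shift, 0)),
    expression = tibble(gene_id = models$gene_id, true_lfc = true_lfc,
                        is_hypo_gene = models$gene_id %in% hypo_genes)
  )

  structure(
    list(config = cfg, models = new_tx_models(models),
         mod_calls = validate_mod_calls(mod_calls), reads = reads,
         counts = counts, truth = truth),
    class = "m6adiff_sim")
}

#' @export
print.m6adiff_sim <- function(x, ...) {
  cat("Synthetic direct-RNA-seq dataset\n")
  cat(sprintf("  %d transcripts, %d candidate sites (%d with planted DMR %.2f)\n",
              nrow(x$models), nrow(x$truth$sites),
              sum(x$truth$sites$is_effect), x$config$effect_dmr))
  cat(sprintf("  %d reads, %d genes with planted proximal APA shift\n",
              nrow(x$reads), sum(x$truth$apa$shifted)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `models.tsv`, `transcripts.fa`, `mod_calls.tsv`, `reads.tsv`,
#' `counts.tsv`, `truth_*.tsv` and `config.json` under `dir`, in the
#' dialects the package readers consume.
#'
#' @param sim A `m6adiff_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!inherits(sim, "m6adiff_sim")) abort("sim must be a m6adiff_sim")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcript_models(sim$models, file.path(dir, "models.tsv"))
  ss <- Biostrings::DNAStringSet(
    setNames(sim$models$sequence, sim$models$transcript_id))
  Biostrings::writeXStringSet(ss, file.path(dir, "transcripts.fa"))
  write_mod_calls(sim$mod_calls, file.path(dir, "mod_calls.tsv"))
  write_reads(sim$reads, file.path(dir, "reads.tsv"))
  readr::write_tsv(sim$counts, file.path(dir, "counts.tsv"))
  for (nm in names(sim$truth)) {
    readr::write_tsv(sim$truth[[nm]], file.path(dir, paste0("truth_", nm,
                                                            ".tsv")))
  }
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing the dataset files.
#' @return A list with `models` (sequences attached when `transcripts.fa`
#'   is present), `mod_calls`, `reads`, `counts`, and `truth` (NULL when no
#'   truth tables are present).
#' @export
read_dataset <- function(dir) {
  models <- read_transcript_models(file.path(dir, "models.tsv"))
  fa <- file.path(dir, "transcripts.fa")
  if (file.exists(fa)) models <- attach_sequences(models, fa)
  truth_files <- list.files(dir, pattern = "^truth_.*\\.tsv$",
                            full.names = TRUE)
  truth <- if (length(truth_files)) {
    setNames(lapply(truth_files, readr::read_tsv, show_col_types = FALSE,
                    progress = FALSE),
             sub("^truth_(.*)\\.tsv$", "\\1", basename(truth_files)))
  }
  list(
    models = models,
    mod_calls = read_mod_calls(file.path(dir, "mod_calls.tsv")),
    reads = read_reads(file.path(dir, "reads.tsv")),
    counts = readr::read_tsv(file.path(dir, "counts.tsv"),
                             show_col_types = FALSE, progress = FALSE),
    truth = truth
  )
}
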