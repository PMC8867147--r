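#' Read transcript models from GTF/GFF or a transcript-model TSV
#'
#' Builds one row per transcript with 5'UTR/CDS/3'UTR lengths expressed in
#' transcript coordinates (0-based, half-open, 5'->3'). For GTF/GFF input the
#' UTR lengths are derived from the exon-minus-CDS extents: the 5'UTR length
#' is the number of exonic bases strictly upstream of the first coding base
#' (strand-aware), the CDS length is the summed CDS width, and the 3'UTR is
#' the remainder. Transcripts with no CDS feature are flagged non-coding
#' (`coding = FALSE`, zero-length segments with the full length in `total_len`)
#' and are excluded from metagene/motif stages downstream, but retained for
#' 3'-end and poly(A) analyses.
#'
#' The TSV dialect has columns `transcript_id`, `gene_id`, `utr5_len`,
#' `cds_len`, `utr3_len` and optionally `coding` (logical; default
#' `cds_len > 0`).
#'
#' @param path Path to a `.gtf`/`.gff`/`.gff3` annotation or a `.tsv` model
#'   table.
#' @param format `"auto"` (by file extension), `"gtf"` or `"tsv"`.
#' @return A tibble of class `tx_models` with columns `transcript_id`,
#'   `gene_id`, `utr5_len`, `cds_len`, `utr3_len`, `total_len`, `coding`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' readr::write_tsv(tibble::tibble(
#'   transcript_id = "t1", gene_id = "g1",
#'   utr5_len = 100, cds_len = 300, utr3_len = 200), tsv)
#' read_transcript_models(tsv)
#' @export
read_transcript_models <- function(path, format = c("auto", "gtf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff3?)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "tsv"
  }
  models <- if (format == "gtf") {
    models_from_gtf(path)
  } else {
    models_from_tsv(path)
  }
  new_tx_models(models)
}

new_tx_models <- function(df) {
  df <- as_tibble(df)
  check_cols(df, c("transcript_id", "gene_id", "utr5_len", "cds_len",
                   "utr3_len"), "transcript model table")
  if (anyDuplicated(df$transcript_id)) {
    abort("duplicate transcript_id in transcript model table")
  }
  if (!"total_len" %in% names(df)) {
    df$total_len <- df$utr5_len + df$cds_len + df$utr3_len
  }
  if (!"coding" %in% names(df)) df$coding <- df$cds_len > 0
  bad <- df$coding &
    df$total_len != df$utr5_len + df$cds_len + df$utr3_len
  if (any(bad)) {
    abort(paste0("segment lengths do not sum to total_len for: ",
                 paste(head(df$transcript_id[bad], 5), collapse = ", ")))
  }
  if (any(df$total_len <= 0)) abort("total_len must be positive")
  class(df) <- c("tx_models", class(df))
  df
}

models_from_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(df, c("transcript_id", "gene_id", "utr5_len", "cds_len",
                   "utr3_len"), paste0("'", path, "'"))
  df
}

models_from_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) abort(paste0("failed to parse '", path, "': ",
                                     conditionMessage(e)))
  )
  df <- as_tibble(as.data.frame(gr))
  check_cols(df, c("type", "start", "end", "strand", "transcript_id"),
             paste0("annotation '", path, "'"))
  if (!"gene_id" %in% names(df)) df$gene_id <- df$transcript_id
  df <- filter(df, .data$type %in% c("exon", "CDS"),
               !is.na(.data$transcript_id))
  if (nrow(df) == 0) abort(paste0("no exon/CDS features in '", path, "'"))

  one_tx <- function(d, tx_id) {
    exons <- filter(d, .data$type == "exon")
    if (nrow(exons) == 0) {
      abort(paste0("transcript ", tx_id, " has CDS but no exons"))
    }
    total <- sum(exons$end - exons$start + 1)
    cds <- filter(d, .data$type == "CDS")
    if (nrow(cds) == 0) {
      return(tibble(gene_id = exons$gene_id[1], utr5_len = 0L, cds_len = 0L,
                    utr3_len = 0L, total_len = total, coding = FALSE))
    }
    # every CDS base must fall inside an exon
    in_exon <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(in_exon)) {
      abort(paste0("CDS outside exons for transcript ", tx_id))
    }
    cds_len <- sum(cds$end - cds$start + 1)
    minus <- as.character(exons$strand[1]) == "-"
    if (!minus) {
      first_coding <- min(cds$start)
      utr5 <- sum(pmax(0, pmin(exons$end, first_coding - 1) - exons$start + 1))
    } else {
      first_coding <- max(cds$end)
      utr5 <- sum(pmax(0, exons$end - pmax(exons$start, first_coding + 1) + 1))
    }
    tibble(gene_id = exons$gene_id[1], utr5_len = as.integer(utr5),
           cds_len = as.integer(cds_len),
           utr3_len = as.integer(total - utr5 - cds_len),
           total_len = as.integer(total),
           coding = TRUE)
  }

  df |>
    group_by(transcript_id = .data$transcript_id) |>
    dplyr::group_modify(~ one_tx(.x, .y$transcript_id)) |>
    ungroup() |>
    mutate(utr5_len = if_else(.data$coding, .data$utr5_len, 0L),
           cds_len = if_else(.data$coding, .data$cds_len, 0L),
           utr3_len = if_else(.data$coding, .data$utr3_len, 0L))
}

#' Write transcript models to TSV
#'
#' Inverse of the TSV branch of [read_transcript_models()]; a write/read
#' round trip reproduces all fields.
#'
#' @param models A `tx_models` tibble.
#' @param path Output path.
#' @export
write_transcript_models <- function(models, path) {
  check_cols(models, c("transcript_id", "gene_id", "utr5_len", "cds_len",
                       "utr3_len", "coding"), "models")
  readr::write_tsv(
    select(as_tibble(models), "transcript_id", "gene_id", "utr5_len",
           "cds_len", "utr3_len", "coding"),
    path)
  invisible(path)
}

#' Attach transcript sequences from FASTA
#'
#' @param models A `tx_models` tibble.
#' @param fasta Path to a FASTA of transcript sequences, or a named character
#'   vector. Names are matched to `transcript_id` (FASTA descriptions after
#'   the first whitespace are dropped). U is normalized to T.
#' @param strict Error if a sequence length disagrees with `total_len`
#'   (default TRUE).
#' @return `models` with a `sequence` character column (NA where absent).
#' @export
attach_sequences <- function(models, fasta, strict = TRUE) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    seqs <- fasta
  }
  seqs <- toupper(gsub("U", "T", seqs, fixed = TRUE))
  models$sequence <- unname(seqs[models$transcript_id])
  have <- !is.na(models$sequence)
  mismatch <- have & nchar(models$sequence) != models$total_len
  if (any(mismatch)) {
    msg <- paste0("sequence length != total_len for: ",
                  paste(head(models$transcript_id[mismatch], 5),
                        collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }
  models
}

#' Read a per-site modification-call table
#'
#' Long-format TSV with one row per (site, condition, replicate):
#' columns `transcript_id`, `position` (0-based coordinate of the central A),
#' `kmer` (5 characters, center A), `condition` (`wt`/`mut`), `replicate`
#' (integer), `n_reads`, `n_modified`.
#'
#' @param path TSV path.
#' @return A validated tibble of class `mod_calls`.
#' @export
read_mod_calls <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_mod_calls(df)
}

#' @rdname read_mod_calls
#' @param calls A data frame in the mod-call layout.
#' @export
validate_mod_calls <- function(calls) {
  df <- as_tibble(calls)
  check_cols(df, c("transcript_id", "position", "kmer", "condition",
                   "replicate", "n_reads", "n_modified"), "mod-call table")
  if (any(df$n_modified < 0 | df$n_reads < 0)) {
    abort("negative counts in mod-call table")
  }
  if (any(df$n_modified > df$n_reads)) {
    abort("n_modified > n_reads in mod-call table")
  }
  if (any(nchar(df$kmer) != 5L)) abort("kmer must have 5 characters")
  if (any(substr(df$kmer, 3, 3) != "A")) {
    abort("kmer center (3rd character) must be 'A'")
  }
  if (!all(df$condition %in% c("wt", "mut"))) {
    abort("condition must be 'wt' or 'mut'")
  }
  dup <- duplicated(df[c("transcript_id", "position", "condition",
                         "replicate")])
  if (any(dup)) {
    abort("duplicate (site, condition, replicate) rows in mod-call table")
  }
  class(df) <- c("mod_calls", setdiff(class(df), "mod_calls"))
  df
}

#' @rdname read_mod_calls
#' @export
write_mod_calls <- function(calls, path) {
  readr::write_tsv(as_tibble(calls), path)
  invisible(path)
}

#' Parse an xPore-style differential-modification table
#'
#' Ingests the `diffmod` TSV dialect produced by signal-level differential
#' modification callers: a header with `id`, `position`, `kmer`, one
#' `diff_mod_rate*` column, one `pval*` column, and per-condition-replicate
#' `mod_rate_<condition>-rep<r>` columns. Rows are mapped into the same
#' per-site differential layout produced internally so downstream
#' metagene/motif/integration stages run identically on either source.
#' Unknown columns are ignored with a warning.
#'
#' @param path TSV path.
#' @return A tibble with columns `transcript_id`, `position`, `kmer`, `dmr`,
#'   `p`, and a nested `rates` list-column of per-(condition, replicate)
#'   modification rates (NULL when the input carries none).
#' @export
parse_diffmod_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(df, c("id", "position", "kmer"), paste0("'", path, "'"))
  dmr_col <- grep("^diff_mod_rate", names(df), value = TRUE)[1]
  p_col <- grep("^pval", names(df), value = TRUE)[1]
  if (is.na(dmr_col) || is.na(p_col)) {
    abort(paste0("'", path, "' must contain columns: id, position, kmer, ",
                 "diff_mod_rate*, pval*, [mod_rate_<cond>-rep<r> ...]"))
  }
  if (!is.numeric(df[[p_col]])) {
    abort(paste0("p-value column '", p_col, "' is not numeric"))
  }
  if (!is.numeric(df[[dmr_col]])) {
    abort(paste0("column '", dmr_col, "' is not numeric"))
  }
  rate_cols <- grep("^mod_rate_.+-rep[0-9]+$", names(df), value = TRUE)
  known <- c("id", "position", "kmer", dmr_col, p_col, rate_cols)
  extra <- setdiff(names(df), c(known, "z_score", grep("^z_score",
                                                       names(df), value = TRUE)))
  if (length(extra)) {
    warn(paste0("ignoring unrecognized column(s): ",
                paste(extra, collapse = ", ")))
  }
  out <- tibble(
    transcript_id = as.character(df$id),
    position = as.integer(df$position),
    kmer = toupper(gsub("U", "T", df$kmer, fixed = TRUE)),
    dmr = df[[dmr_col]],
    p = df[[p_col]]
  )
  if (length(rate_cols)) {
    meta <- stringr::str_match(rate_cols, "^mod_rate_(.+)-rep([0-9]+)$")
    out$rates <- lapply(seq_len(nrow(df)), function(i) {
      tibble(condition = meta[, 2], replicate = as.integer(meta[, 3]),
             rate = as.numeric(df[i, rate_cols]))
    })
  } else {
    out$rates <- vector("list", nrow(df))
  }
  out
}

#' Write called sites as BED6 in transcript space
#'
#' One 1-nt half-open interval per site at the central A, `name` = k-mer,
#' `score` = `round(1000 * dmr)` clipped to \[0, 1000\], strand `+`
#' (transcript orientation).
#'
#' @param sites Tibble with `transcript_id`, `position`, `kmer`, `dmr`.
#' @param path Output path.
#' @param models Optional `tx_models`; sites on transcripts absent from the
#'   models are skipped with a warning.
#' @export
write_sites_bed <- function(sites, path, models = NULL) {
  check_cols(sites, c("transcript_id", "position", "kmer", "dmr"), "sites")
  sites <- as_tibble(sites)
  if (!is.null(models)) {
    drop <- !(sites$transcript_id %in% models$transcript_id)
    if (any(drop)) {
      warn(paste0("skipping ", sum(drop),
                  " site(s) without an attached transcript model"))
      sites <- sites[!drop, ]
    }
  }
  bed <- tibble(
    chrom = sites$transcript_id,
    start = as.integer(sites$position),
    end = as.integer(sites$position) + 1L,
    name = sites$kmer,
    score = as.integer(round(1000 * pmin(pmax(sites$dmr, 0), 1))),
    strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a per-read alignment table
#'
#' TSV with columns `read_id`, `gene_id`, `align_start`, `align_end`
#' (0-based half-open in the gene's transcript frame), `end3` (0-based
#' coordinate of the read 3' end; derived as `align_end - 1` when absent),
#' optional `polya_len`, `condition` (`wt`/`mut`), `replicate`.
#'
#' @param path TSV path.
#' @return A validated tibble of class `read_records`.
#' @export
read_reads <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_reads(df)
}

#' @rdname read_reads
#' @param reads A data frame in the read-record layout.
#' @export
validate_reads <- function(reads) {
  df <- as_tibble(reads)
  check_cols(df, c("read_id", "gene_id", "align_start", "align_end",
                   "condition", "replicate"), "read table")
  if (any(df$align_start >= df$align_end)) {
    abort("align_start must be < align_end for every read")
  }
  if (!"end3" %in% names(df)) {
    df$end3 <- df$align_end - 1L
  } else if (any(df$end3 != df$align_end - 1L)) {
    abort("end3 must equal align_end - 1 (transcript orientation)")
  }
  if (!"polya_len" %in% names(df)) df$polya_len <- NA_real_
  if (!all(df$condition %in% c("wt", "mut"))) {
    abort("condition must be 'wt' or 'mut'")
  }
  class(df) <- c("read_records", setdiff(class(df), "read_records"))
  df
}

#' @rdname read_reads
#' @export
write_reads <- function(reads, path) {
  readr::write_tsv(as_tibble(reads), path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with columns `gene_id`, `log2fc` (mutant vs wild type) and `padj`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_de_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(df, c("gene_id", "log2fc", "padj"), paste0("'", path, "'"))
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE)) {
    abort("padj must lie in [0, 1]")
  }
  df
}
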