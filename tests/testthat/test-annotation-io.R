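write_gtf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

gtf_line <- function(start, end, type, tx, gene = "g1", strand = "+") {
  sprintf("chr1\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          type, start, end, strand, gene, tx)
}

test_that("GTF-derived segment lengths match hand-computed extents", {
  path <- write_gtf(c(
    # 600-nt single-exon transcript, CDS at transcript positions 100-399
    gtf_line(1, 600, "exon", "tx_plus"),
    gtf_line(101, 400, "CDS", "tx_plus"),
    # CDS covering the full exonic span
    gtf_line(1000, 1299, "exon", "tx_full", gene = "g2"),
    gtf_line(1000, 1299, "CDS", "tx_full", gene = "g2"),
    # no CDS feature -> non-coding
    gtf_line(2000, 2500, "exon", "tx_nc", gene = "g3"),
    # spliced minus-strand transcript
    gtf_line(1400, 1599, "exon", "tx_minus", gene = "g4", strand = "-"),
    gtf_line(1000, 1199, "exon", "tx_minus", gene = "g4", strand = "-"),
    gtf_line(1400, 1550, "CDS", "tx_minus", gene = "g4", strand = "-"),
    gtf_line(1100, 1199, "CDS", "tx_minus", gene = "g4", strand = "-")
  ))
  m <- read_transcript_models(path)
  m <- m[match(c("tx_plus", "tx_full", "tx_nc", "tx_minus"),
               m$transcript_id), ]
  expect_equal(m$utr5_len, c(100L, 0L, 0L, 49L))
  expect_equal(m$cds_len, c(300L, 300L, 0L, 251L))
  expect_equal(m$utr3_len, c(200L, 0L, 0L, 100L))
  expect_equal(m$total_len, c(600L, 300L, 501L, 400L))
  expect_equal(m$coding, c(TRUE, TRUE, FALSE, TRUE))
  # segment sums always reproduce the total for coding transcripts
  coding <- m[m$coding, ]
  expect_equal(coding$utr5_len + coding$cds_len + coding$utr3_len,
               coding$total_len)
})

test_that("CDS outside exons is a validation error", {
  path <- write_gtf(c(
    gtf_line(1, 600, "exon", "t1"),
    gtf_line(700, 800, "CDS", "t1")
  ))
  expect_error(read_transcript_models(path), "CDS outside exons")
})

test_that("transcript-model TSV round trip reproduces all fields", {
  models <- toy_models()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transcript_models(models, path)
  back <- read_transcript_models(path)
  expect_equal(as.data.frame(back)[names(models)], as.data.frame(models),
               ignore_attr = TRUE)
})

test_that("mod-call validation enforces counts, kmer center and uniqueness", {
  good <- make_site_calls(wt_mod = c(10, 12), wt_n = c(50, 50),
                          mut_mod = c(5, 6), mut_n = c(50, 50))
  expect_s3_class(validate_mod_calls(good), "mod_calls")

  bad_counts <- good
  bad_counts$n_modified[1] <- 60
  expect_error(validate_mod_calls(bad_counts), "n_modified > n_reads")

  bad_kmer <- good
  bad_kmer$kmer <- "CCGGA"
  expect_error(validate_mod_calls(bad_kmer), "center")

  dup <- dplyr::bind_rows(good, good[1, ])
  expect_error(validate_mod_calls(dup), "duplicate")
})

test_that("read_mod_calls parses a well-formed file into one site", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(make_site_calls(wt_mod = 10, wt_n = 50, mut_mod = 5,
                                   mut_n = 50), path)
  calls <- read_mod_calls(path)
  expect_equal(nrow(calls), 2L)
  expect_equal(nrow(dplyr::distinct(calls, transcript_id, position)), 1L)
})

test_that("xPore-style diffmod tables map into the internal layout", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("id", "position", "kmer", "diff_mod_rate_wt_vs_mut",
          "pval_wt_vs_mut", "mod_rate_wt-rep1", "mod_rate_mut-rep1",
          sep = "\t"),
    paste("t1", "250", "CCAGA", "0.4", "1e-8", "0.6", "0.2", sep = "\t")
  ), path)
  res <- parse_diffmod_table(path)
  expect_equal(res$transcript_id, "t1")
  expect_equal(res$position, 250L)
  expect_equal(res$dmr, 0.4)
  expect_equal(res$p, 1e-8)
  expect_equal(res$rates[[1]]$rate, c(0.6, 0.2))

  # unknown extra columns are ignored with a warning
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("id", "position", "kmer", "diff_mod_rate", "pval", "bogus",
          sep = "\t"),
    paste("t1", "10", "AAAAA", "0.1", "0.5", "x", sep = "\t")
  ), path2)
  expect_warning(parse_diffmod_table(path2), "bogus")

  # non-numeric p-value column is an error
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("id", "position", "kmer", "diff_mod_rate", "pval", sep = "\t"),
    paste("t1", "10", "AAAAA", "0.1", "not_a_number", sep = "\t")
  ), path3)
  expect_error(parse_diffmod_table(path3), "not numeric")

  # missing required column names the expected header
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("id", "position", "kmer", sep = "\t"),
               paste("t1", "10", "AAAAA", sep = "\t")), path4)
  expect_error(parse_diffmod_table(path4), "diff_mod_rate")
})

test_that("BED output is half-open, 1 nt wide, with the DMR score encoding", {
  sites <- tibble::tibble(transcript_id = c("t1", "t1", "t2"),
                          position = c(250L, 10L, 30L),
                          kmer = c("CCAGA", "CAAGA", "TCAGA"),
                          dmr = c(0.40, 0, 1.7))
  path <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, path)
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "name", "score", "strand"),
                         show_col_types = FALSE)
  expect_equal(bed$end - bed$start, rep(1L, 3))
  expect_true(all(bed$start >= 0))
  expect_equal(bed$score, c(400L, 0L, 1000L))  # clipped to [0, 1000]

  # sites without an attached model are skipped with a warning
  expect_warning(
    write_sites_bed(sites, path, models = toy_models()[1, ]),
    "without an attached transcript model")
  bed2 <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  expect_equal(nrow(bed2), 2L)

  # empty site list -> empty valid BED
  write_sites_bed(sites[0, ], path)
  expect_length(readLines(path), 0L)
})

test_that("read tables derive and enforce the end3 convention", {
  df <- tibble::tibble(read_id = c("r1", "r2"), gene_id = "g1",
                       align_start = c(0L, 10L), align_end = c(100L, 300L),
                       condition = c("wt", "mut"), replicate = 1L)
  v <- validate_reads(df)
  expect_equal(v$end3, c(99L, 299L))
  df$end3 <- c(98L, 299L)
  expect_error(validate_reads(df), "end3 must equal")
  df2 <- df
  df2$end3 <- NULL
  df2$align_end <- c(0L, 300L)
  expect_error(validate_reads(df2), "align_start")
})
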