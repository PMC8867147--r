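# Independent brute-force oracles used to cross-check the implementation.

# two-sample KS statistic as an explicit sup over the merged breakpoints
ks_brute <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- ecdf(x)(pts)
  Fy <- ecdf(y)(pts)
  max(abs(Fx - Fy))
}

# exact two-sided permutation p-value for the Mann-Whitney U statistic
# (enumerates all labelings; feasible for n + m <= ~12)
perm_mw_p <- function(x, y) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n <- length(x)
  center <- n * length(y) / 2
  obs <- abs(u_stat(x, y) - center)
  labelings <- utils::combn(length(pooled), n)
  stats <- apply(labelings, 2, function(idx) {
    abs(u_stat(pooled[idx], pooled[-idx]) - center)
  })
  mean(stats >= obs - 1e-12)
}

# exact permutation p-value for the two-sample KS statistic
perm_ks_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  obs <- ks_brute(x, y)
  labelings <- utils::combn(length(pooled), n)
  stats <- apply(labelings, 2, function(idx) {
    ks_brute(pooled[idx], pooled[-idx])
  })
  mean(stats >= obs - 1e-12)
}

# BH adjustment written directly from the step-up definition
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# brute-force IUPAC scan: expand the pattern to all concrete strings and
# match each window literally
scan_brute <- function(sequence, motif) {
  sequence <- toupper(gsub("U", "T", sequence, fixed = TRUE))
  chars <- strsplit(toupper(gsub("U", "T", motif, fixed = TRUE)), "")[[1]]
  sets <- lapply(chars, m6adiff::iupac_expand)
  concrete <- apply(do.call(expand.grid, c(sets, stringsAsFactors = FALSE)),
                    1, paste, collapse = "")
  k <- length(chars)
  n <- nchar(sequence)
  if (n < k) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - k + 1)) {
    if (substr(sequence, i, i + k - 1) %in% concrete) {
      starts <- c(starts, i - 1L)
    }
  }
  starts
}

# small helper: build a long mod-call table from per-replicate count pairs
make_site_calls <- function(transcript_id = "t1", position = 50,
                            kmer = "CCAGA",
                            wt_mod, wt_n, mut_mod, mut_n) {
  r <- length(wt_mod)
  dplyr::bind_rows(
    tibble::tibble(transcript_id = transcript_id, position = position,
                   kmer = kmer, condition = "wt", replicate = seq_len(r),
                   n_reads = wt_n, n_modified = wt_mod),
    tibble::tibble(transcript_id = transcript_id, position = position,
                   kmer = kmer, condition = "mut", replicate = seq_len(r),
                   n_reads = mut_n, n_modified = mut_mod)
  )
}

toy_models <- function() {
  m6adiff:::new_tx_models(tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g2", "g3"),
    utr5_len = c(100L, 0L, 30L),
    cds_len = c(300L, 600L, 90L),
    utr3_len = c(200L, 0L, 60L),
    coding = TRUE
  ))
}
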