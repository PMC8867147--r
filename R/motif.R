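# IUPAC nucleotide codes over the DNA alphabet (U is normalized to T).
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

normalize_seq <- function(x) toupper(gsub("U", "T", x, fixed = TRUE))

#' Expand an IUPAC code to its concrete nucleotides
#'
#' @param code A single IUPAC character (U treated as T).
#' @return Character vector of concrete bases (subset of A/C/G/T).
#' @examples
#' iupac_expand("Y")  # C T
#' @export
iupac_expand <- function(code) {
  code <- normalize_seq(code)
  out <- IUPAC_MAP[[code]]
  if (is.null(out)) abort(paste0("invalid IUPAC code: '", code, "'"))
  out
}

# minimal IUPAC symbol covering a set of concrete bases
iupac_code_for <- function(bases) {
  bases <- sort(unique(bases))
  hit <- names(IUPAC_MAP)[vapply(IUPAC_MAP, function(b)
    identical(sort(b), bases), logical(1))]
  if (length(hit) == 0) abort("no IUPAC code covers an empty base set")
  hit[1]
}

#' Extract the A-centered 5-mer at a site
#'
#' Returns `sequence[position - 2 .. position + 2]` (0-based `position`),
#' uppercased with U normalized to T. The central base must be A and the
#' window must lie inside the sequence.
#'
#' @param sequence Nucleotide string.
#' @param position 0-based coordinate of the central A.
#' @param k Window size (odd; default 5).
#' @return The k-mer string.
#' @examples
#' extract_kmer("GGCAAGATT", 4)  # "CAAGA"
#' @export
extract_kmer <- function(sequence, position, k = 5) {
  if (k %% 2 != 1) abort("k must be odd")
  half <- (k - 1) / 2
  sequence <- normalize_seq(sequence)
  n <- nchar(sequence)
  if (any(position - half < 0 | position + half >= n)) {
    abort("k-mer window out of sequence bounds")
  }
  center <- substr(sequence, position + 1, position + 1)
  if (any(center != "A")) {
    abort(paste0("central base must be 'A', got '", center[1], "'"))
  }
  substring(sequence, position + 1 - half, position + 1 + half)
}

#' Ranked k-mer frequencies at sites
#'
#' @param sites A tibble with a `kmer` column, or a character vector of
#'   k-mers.
#' @return A tibble `kmer`, `count`, sorted by decreasing count with
#'   lexicographic tie-breaking; counts sum to the number of inputs.
#' @export
kmer_frequencies <- function(sites) {
  kmers <- if (is.data.frame(sites)) sites$kmer else sites
  if (length(kmers) == 0) return(tibble(kmer = character(), count = integer()))
  tibble(kmer = normalize_seq(kmers)) |>
    count(.data$kmer, name = "count") |>
    arrange(desc(.data$count), .data$kmer)
}

#' Frequencies of the last three k-mer nucleotides
#'
#' For A-centered 5-mers, positions 3-5 are the central A plus the two
#' downstream bases (e.g. every k-mer ending in `AGA` maps to `AGA`).
#'
#' @param kmers Character vector of 5-mers (or tibble with `kmer` column).
#' @return A tibble `last3`, `count`, ranked as in [kmer_frequencies()].
#' @export
last3_frequencies <- function(kmers) {
  kmers <- if (is.data.frame(kmers)) kmers$kmer else kmers
  if (length(kmers) == 0) {
    return(tibble(last3 = character(), count = integer()))
  }
  if (any(nchar(kmers) != 5L)) abort("all k-mers must have length 5")
  tibble(last3 = substr(normalize_seq(kmers), 3, 5)) |>
    count(.data$last3, name = "count") |>
    arrange(desc(.data$count), .data$last3)
}

#' Scan a sequence for a degenerate IUPAC motif
#'
#' Reports every (possibly overlapping) window matching the exact IUPAC
#' expansion of `motif`. RNA and DNA alphabets are equivalent (U == T).
#'
#' @param sequence A single nucleotide string.
#' @param motif IUPAC pattern, e.g. `"YHAGA"`.
#' @return Integer vector of 0-based match start positions.
#' @examples
#' motif_scan("GCCAGAGCCAGAGCCAGAGCCAGA", "YHAGA")  # 1 7 13 19
#' @export
motif_scan <- function(sequence, motif) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0) {
    abort("sequence must be a single non-empty string")
  }
  sequence <- normalize_seq(sequence)
  rx <- motif_regex(motif)
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

motif_regex <- function(motif) {
  chars <- strsplit(normalize_seq(motif), "")[[1]]
  if (length(chars) == 0) abort("motif must be non-empty")
  paste0(vapply(chars, function(ch) {
    bases <- iupac_expand(ch)
    if (length(bases) == 1) bases else
      paste0("[", paste(bases, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Does a k-mer match a degenerate motif?
#'
#' @param kmers Character vector, same length as the motif.
#' @param motif IUPAC pattern.
#' @return Logical vector.
#' @export
motif_matches <- function(kmers, motif) {
  grepl(paste0("^", motif_regex(motif), "$"), normalize_seq(kmers))
}

#' Derive a degenerate consensus motif and its enrichment
#'
#' Builds the per-position nucleotide frequency matrix over the site k-mers;
#' at each position the consensus symbol is the minimal IUPAC code covering
#' every nucleotide whose frequency reaches `threshold` (default 0.20, which
#' reproduces Y/H-style codes from skewed frequency matrices). Enrichment is
#' a one-sided binomial test of the number of site k-mers matching the
#' derived motif against the fraction of background k-mers matching it —
#' a defined, dependency-free alternative to motif-discovery scoring.
#'
#' @param site_kmers Character vector of k-mers at called sites (or tibble
#'   with `kmer` column).
#' @param background_kmers Character vector of background A-centered k-mers,
#'   typically all eligible positions of expressed transcripts.
#' @param threshold Per-position inclusion frequency (default 0.2).
#' @return An object of class `consensus_motif`: list with `motif` (IUPAC
#'   string), `pfm` (position frequency tibble), `n_sites`, `n_matching`,
#'   `background_freq`, `p` (one-sided binomial enrichment p-value).
#' @export
consensus_motif <- function(site_kmers, background_kmers, threshold = 0.2) {
  check_prob(threshold, "threshold", open = c(TRUE, TRUE))
  site_kmers <- normalize_seq(
    if (is.data.frame(site_kmers)) site_kmers$kmer else site_kmers)
  background_kmers <- normalize_seq(
    if (is.data.frame(background_kmers)) background_kmers$kmer
    else background_kmers)
  if (length(site_kmers) == 0 || length(background_kmers) == 0) {
    abort("site and background k-mer sets must be non-empty")
  }
  k <- nchar(site_kmers[1])
  if (any(nchar(c(site_kmers, background_kmers)) != k)) {
    abort("all k-mers must share one length")
  }

  mat <- do.call(rbind, strsplit(site_kmers, ""))
  pfm <- purrr::map_dfr(seq_len(k), function(j) {
    f <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    tibble(pos = j, base = names(f),
           freq = as.integer(f) / length(site_kmers))
  })
  codes <- vapply(seq_len(k), function(j) {
    keep <- pfm$base[pfm$pos == j & pfm$freq >= threshold]
    if (length(keep) == 0) {  # no base reaches threshold: take the max
      jf <- pfm[pfm$pos == j, ]
      keep <- jf$base[which.max(jf$freq)]
    }
    iupac_code_for(keep)
  }, character(1))
  motif <- paste(codes, collapse = "")

  n_match <- sum(motif_matches(site_kmers, motif))
  bg_freq <- mean(motif_matches(background_kmers, motif))
  p <- if (bg_freq >= 1) 1 else
    binom.test(n_match, length(site_kmers), p = max(bg_freq, .Machine$double.xmin),
               alternative = "greater")$p.value

  structure(
    list(motif = motif, pfm = pfm, n_sites = length(site_kmers),
         n_matching = n_match, background_freq = bg_freq, p = p),
    class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat("Consensus motif:", x$motif, "\n")
  cat(sprintf("  %d / %d site k-mers match (background frequency %.4f)\n",
              x$n_matching, x$n_sites, x$background_freq))
  cat(sprintf("  one-sided binomial enrichment p = %.3g\n", x$p))
  invisible(x)
}

#' Collect background A-centered k-mers from transcript sequences
#'
#' Every position with an A at the center and a full 5-nt window contributes
#' one k-mer; use as the background set for [consensus_motif()].
#'
#' @param sequences Named character vector of transcript sequences (or a
#'   `tx_models` tibble with a `sequence` column).
#' @param k Window size (default 5).
#' @return Character vector of k-mers.
#' @export
background_kmers <- function(sequences, k = 5) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$transcript_id)
    sequences <- sequences[!is.na(sequences)]
  }
  half <- (k - 1) / 2
  unlist(lapply(normalize_seq(sequences), function(s) {
    pos <- motif_scan(s, "A")  # 0-based A positions
    pos <- pos[pos - half >= 0 & pos + half < nchar(s)]
    if (length(pos) == 0) return(character(0))
    substring(s, pos + 1 - half, pos + 1 + half)
  }), use.names = FALSE)
}
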