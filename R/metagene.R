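#' Assign a transcript position to a segment
#'
#' Segments are half-open in transcript coordinates: positions in
#' `[0, utr5_len)` are 5'UTR, `[utr5_len, utr5_len + cds_len)` are CDS
#' (the stop codon's three bases belong to the CDS), and the remainder is
#' 3'UTR.
#'
#' @param position 0-based transcript coordinate(s).
#' @param utr5_len,cds_len,utr3_len Segment lengths (nt), vectorized.
#' @return Character vector over `"UTR5"`, `"CDS"`, `"UTR3"`.
#' @examples
#' assign_segment(c(0, 100, 399, 400), 100, 300, 200)
#' @export
assign_segment <- function(position, utr5_len, cds_len, utr3_len) {
  total <- utr5_len + cds_len + utr3_len
  if (any(position < 0 | position >= total)) {
    abort("position out of range [0, total_len)")
  }
  dplyr::case_when(
    position < utr5_len ~ "UTR5",
    position < utr5_len + cds_len ~ "CDS",
    TRUE ~ "UTR3"
  )
}

#' Metagene coordinate on the 0-3 axis
#'
#' Rescales a transcript position so that the 5'UTR, CDS and 3'UTR each span
#' one unit: 5'UTR positions map to `position/utr5_len` in \[0,1), CDS to
#' `1 + (position - utr5_len)/cds_len` in \[1,2), 3'UTR to
#' `2 + (position - utr5_len - cds_len)/utr3_len` in \[2,3). When the
#' containing segment has zero length the coordinate is undefined (`NA`);
#' such sites are still reported with their segment.
#'
#' @inheritParams assign_segment
#' @return Numeric vector in \[0, 3), NA where the segment length is 0.
#' @examples
#' metagene_coord(250, 100, 300, 200)  # 1.5, mid-CDS
#' @export
metagene_coord <- function(position, utr5_len, cds_len, utr3_len) {
  seg <- assign_segment(position, utr5_len, cds_len, utr3_len)
  dplyr::case_when(
    seg == "UTR5" & utr5_len > 0 ~ position / utr5_len,
    seg == "CDS" & cds_len > 0 ~ 1 + (position - utr5_len) / cds_len,
    seg == "UTR3" & utr3_len > 0 ~
      2 + (position - utr5_len - cds_len) / utr3_len,
    TRUE ~ NA_real_
  )
}

#' Annotate sites with gene, segment and metagene coordinate
#'
#' Joins sites to transcript models and adds `gene_id`, `segment` and
#' `metagene_coord`. Sites on non-coding transcripts get NA for both
#' (segments are undefined without a CDS); sites on transcripts absent from
#' the models are dropped with a warning.
#'
#' @param sites Tibble with `transcript_id` and `position`.
#' @param models A `tx_models` tibble.
#' @return `sites` with `gene_id`, `segment`, `metagene_coord` columns.
#' @export
annotate_sites <- function(sites, models) {
  check_cols(sites, c("transcript_id", "position"), "sites")
  check_cols(models, c("transcript_id", "gene_id", "utr5_len", "cds_len",
                       "utr3_len", "coding"), "models")
  miss <- setdiff(unique(sites$transcript_id), models$transcript_id)
  if (length(miss)) {
    warn(paste0("dropping sites on ", length(miss),
                " transcript(s) absent from the models"))
  }
  out <- sites |>
    inner_join(select(as_tibble(models), "transcript_id", "gene_id",
                      "utr5_len", "cds_len", "utr3_len", "coding"),
               by = "transcript_id") |>
    mutate(
      segment = if_else(
        .data$coding,
        assign_segment(.data$position, .data$utr5_len, .data$cds_len,
                       .data$utr3_len),
        NA_character_),
      metagene_coord = if_else(
        .data$coding,
        metagene_coord(.data$position, .data$utr5_len, .data$cds_len,
                       .data$utr3_len),
        NA_real_)
    ) |>
    select(-"utr5_len", -"cds_len", -"utr3_len", -"coding")
  out
}

#' Segment fractions of site placements
#'
#' @param placements Tibble with a `segment` column (NA segments are
#'   dropped), or a character vector of segments.
#' @return A tibble with `segment`, `n`, `percent` for UTR5/CDS/UTR3;
#'   percentages sum to 100.
#' @export
segment_fractions <- function(placements) {
  seg <- if (is.data.frame(placements)) placements$segment else placements
  seg <- seg[!is.na(seg)]
  if (length(seg) == 0) abort("no placements with a defined segment")
  seg <- factor(seg, levels = c("UTR5", "CDS", "UTR3"))
  if (anyNA(seg)) abort("segment values must be UTR5, CDS or UTR3")
  tab <- table(seg)
  tibble(segment = names(tab), n = as.integer(tab),
         percent = 100 * as.integer(tab) / length(seg))
}

#' Sites-per-transcript frequency table
#'
#' @param sites Tibble with a `transcript_id` column.
#' @return A tibble with `n_sites` and `n_transcripts`; the inner product of
#'   the two columns equals the total number of sites.
#' @export
sites_per_transcript <- function(sites) {
  if (nrow(sites) == 0) {
    return(tibble(n_sites = integer(), n_transcripts = integer()))
  }
  sites |>
    count(.data$transcript_id, name = "n_sites") |>
    count(.data$n_sites, name = "n_transcripts") |>
    arrange(.data$n_sites)
}

#' Metagene histogram over the 0-3 axis
#'
#' Unweighted per-site histogram of metagene coordinates with
#' `bins_per_segment` equal bins in each of the three segments (90 bins by
#' default).
#'
#' @param placements Tibble with a `metagene_coord` column; NAs dropped.
#' @param bins_per_segment Bins per segment (default 30).
#' @return A tibble with `bin_lo`, `bin_hi`, `mid`, `segment`, `count`.
#' @export
metagene_histogram <- function(placements, bins_per_segment = 30) {
  check_count(bins_per_segment, "bins_per_segment", min = 1)
  coord <- placements$metagene_coord
  coord <- coord[!is.na(coord)]
  breaks <- seq(0, 3, length.out = 3 * bins_per_segment + 1)
  idx <- findInterval(coord, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    mid = (breaks[-length(breaks)] + breaks[-1]) / 2
  )
  out$segment <- c("UTR5", "CDS", "UTR3")[pmin(floor(out$mid) + 1, 3)]
  out$count <- as.integer(tabulate(idx, nbins = nrow(out)))
  out
}
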