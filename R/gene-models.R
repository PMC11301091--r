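# Gene model container.
#
# A `gene_models` object is a tibble of transcript features (exon / CDS /
# five_prime_UTR / three_prime_UTR) with 0-based half-open coordinates, one
# row per feature, plus a `coding` attribute flagging transcripts whose CDS
# length is a multiple of 3 (the only ones eligible for recoding analysis).

FEATURE_TYPES <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")

#' Construct a gene-model table
#'
#' Validates and normalizes a feature table into the `gene_models` container
#' used by annotation, expression and editome functions.  Coordinates are
#' 0-based half-open.  Exons of a transcript must be disjoint; CDS intervals
#' must lie inside the exon union.  Transcripts whose total CDS length is not
#' a multiple of 3 are flagged non-coding (with a warning) and excluded from
#' recoding analyses; transcripts without CDS are non-coding silently.
#'
#' @param features A data frame with columns `gene_id`, `transcript_id`,
#'   `type` (one of `exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`),
#'   `chrom`, `start`, `end` (0-based half-open) and `strand` (`+` or `-`).
#' @return A `gene_models` tibble sorted by chromosome, gene and position,
#'   with a `coding` attribute (tibble `transcript_id`, `coding`).
#' @examples
#' gm <- gene_models(tibble::tibble(
#'   gene_id = "g1", transcript_id = "g1.t1",
#'   type = c("exon", "CDS"), chrom = "chr1",
#'   start = c(100L, 100L), end = c(250L, 250L), strand = "+"
#' ))
#' gene_spans(gm)
#' @export
gene_models <- function(features) {
  x <- as_tibble(features)
  required <- c("gene_id", "transcript_id", "type", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("gene_models(): missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(x$type %in% FEATURE_TYPES)) {
    abort("gene_models(): `type` must be exon/CDS/five_prime_UTR/three_prime_UTR.")
  }
  if (!all(x$strand %in% c("+", "-"))) abort("gene_models(): strand must be '+' or '-'.")
  if (any(x$start >= x$end)) abort("gene_models(): intervals must satisfy start < end.")
  x <- x |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$chrom, .data$gene_id, .data$transcript_id,
            factor(.data$type, levels = FEATURE_TYPES), .data$start)

  # exons sorted & disjoint, CDS within exon union, per transcript
  bad_exon <- x |>
    filter(.data$type == "exon") |>
    group_by(.data$transcript_id) |>
    summarise(ok = all(.data$start[-1] >= .data$end[-length(.data$end)]) || n() == 1L) |>
    filter(!.data$ok)
  if (nrow(bad_exon) > 0L) {
    abort(paste0("gene_models(): overlapping exons in transcript(s): ",
                 paste(bad_exon$transcript_id, collapse = ", ")))
  }
  cds <- filter(x, .data$type == "CDS")
  if (nrow(cds) > 0L) {
    exon_by_tx <- x |> filter(.data$type == "exon") |> group_by(.data$transcript_id)
    cds_cover <- cds |>
      left_join(
        exon_by_tx |> summarise(exon_start = list(.data$start), exon_end = list(.data$end)),
        by = "transcript_id"
      ) |>
      mutate(covered = pmap(list(.data$start, .data$end, .data$exon_start, .data$exon_end),
                            function(s, e, es, ee) any(s >= es & e <= ee))) |>
      filter(!unlist(.data$covered))
    if (nrow(cds_cover) > 0L) {
      abort(paste0("gene_models(): CDS outside exon union in transcript(s): ",
                   paste(unique(cds_cover$transcript_id), collapse = ", ")))
    }
  }

  cds_len <- cds |>
    group_by(.data$transcript_id) |>
    summarise(cds_len = sum(.data$end - .data$start))
  coding <- x |>
    distinct(.data$transcript_id) |>
    left_join(cds_len, by = "transcript_id") |>
    mutate(cds_len = dplyr::coalesce(.data$cds_len, 0L),
           coding = .data$cds_len > 0L & .data$cds_len %% 3L == 0L)
  frameshifted <- coding$transcript_id[coding$cds_len > 0L & coding$cds_len %% 3L != 0L]
  if (length(frameshifted) > 0L) {
    warn(paste0("CDS length not divisible by 3; flagged non-coding for recoding: ",
                paste(frameshifted, collapse = ", ")))
  }
  structure(x, coding = coding, class = c("gene_models", class(x)))
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d features, %d genes, %d transcripts\n",
              nrow(x), dplyr::n_distinct(x$gene_id), dplyr::n_distinct(x$transcript_id)))
  NextMethod()
}

#' Per-gene genomic spans
#'
#' @param gm A [gene_models()] object.
#' @return A tibble `gene_id`, `chrom`, `start`, `end`, `strand` (0-based
#'   half-open span over all transcript features of the gene).
#' @export
gene_spans <- function(gm) {
  gm |>
    as_tibble() |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
              strand = .data$strand[1], .groups = "drop")
}

#' Canonical (longest-CDS) transcript per gene
#'
#' The canonical transcript carries the recoding annotation of CDS editing
#' sites.  Ties are broken by transcript id; genes without a coding
#' transcript get `NA`.
#'
#' @param gm A [gene_models()] object.
#' @return A tibble `gene_id`, `transcript_id`, `cds_len`.
#' @export
canonical_transcripts <- function(gm) {
  coding <- attr(gm, "coding")
  gm |>
    as_tibble() |>
    distinct(.data$gene_id, .data$transcript_id) |>
    left_join(coding, by = "transcript_id") |>
    filter(.data$coding) |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$cds_len), .data$transcript_id, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select("gene_id", "transcript_id", "cds_len")
}

#' Number of exons and transcripts per gene
#'
#' Exon count is taken from the transcript with the most exons (distinct
#' exon intervals of the gene give the same ordering on simulated data);
#' transcript count is the number of distinct transcript ids, the
#' annotation-based isoform count.
#'
#' @param gm A [gene_models()] object.
#' @return A tibble `gene_id`, `n_exons`, `n_transcripts`.
#' @export
gene_exon_counts <- function(gm) {
  gm |>
    as_tibble() |>
    filter(.data$type == "exon") |>
    group_by(.data$gene_id) |>
    summarise(
      n_exons = max(table(.data$transcript_id)),
      n_transcripts = dplyr::n_distinct(.data$transcript_id),
      .groups = "drop"
    ) |>
    mutate(n_exons = as.integer(.data$n_exons))
}

# regions transcribed on both strands: intersect union of + gene spans with
# union of - gene spans, per chromosome; tibble(chrom, start, end)
bidirectional_regions <- function(gm) {
  spans <- gene_spans(gm)
  plus <- filter(spans, .data$strand == "+")
  minus <- filter(spans, .data$strand == "-")
  if (nrow(plus) == 0L || nrow(minus) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr_p <- GenomicRanges::reduce(GenomicRanges::GRanges(plus$chrom, IRanges::IRanges(plus$start + 1L, plus$end)))
  gr_m <- GenomicRanges::reduce(GenomicRanges::GRanges(minus$chrom, IRanges::IRanges(minus$start + 1L, minus$end)))
  ov <- GenomicRanges::intersect(gr_p, gr_m)
  tibble(chrom = as.character(GenomicRanges::seqnames(ov)),
         start = GenomicRanges::start(ov) - 1L,
         end = GenomicRanges::end(ov))
}
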