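# Gene expression from exonic read counts.

#' Exon union length per gene
#'
#' Gene length for RPKM is the length of the union of all exon intervals over
#' all isoforms, so alternative transcripts sharing exons are not double
#' counted.
#'
#' @param gm A [gene_models()] object.
#' @return A tibble `gene_id`, `exon_union_len` (bp).
#' @export
exon_union_length <- function(gm) {
  ex <- gm |> as_tibble() |> filter(.data$type == "exon")
  if (nrow(ex) == 0L) abort("exon_union_length(): no exon features.")
  ex |>
    group_by(.data$gene_id) |>
    summarise(exon_union_len = interval_union_length(.data$start, .data$end),
              .groups = "drop")
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = exonic_reads / (exon_union_len/1e3 * total_mapped_reads/1e6)`.
#' Only exonic reads enter the numerator; the library size normalizer is the
#' total number of mapped reads.
#'
#' @param exonic_reads Non-negative read counts (vectorized).
#' @param exon_union_len Gene exon-union lengths in bp, > 0.
#' @param total_mapped_reads Library size, > 0.
#' @return Numeric vector of RPKM values; 0 reads give exactly 0.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(exonic_reads, exon_union_len, total_mapped_reads) {
  stopifnot_scalar_number(total_mapped_reads, "total_mapped_reads", min = 1)
  if (any(exon_union_len <= 0)) abort("rpkm(): exon_union_len must be > 0.")
  if (any(exonic_reads < 0)) abort("rpkm(): exonic_reads must be >= 0.")
  exonic_reads / (exon_union_len / 1e3 * total_mapped_reads / 1e6)
}

#' Per-gene expression table
#'
#' Joins exonic read counts to exon-union gene lengths and computes RPKM.
#'
#' @param read_counts A tibble `gene_id`, `exonic_reads`.
#' @param gm A [gene_models()] object covering the counted genes.
#' @param total_mapped_reads Library size; defaults to the sum of
#'   `exonic_reads`.
#' @return A tibble `gene_id`, `exonic_reads`, `exon_union_len`, `rpkm`.
#' @export
gene_expression <- function(read_counts, gm, total_mapped_reads = sum(read_counts$exonic_reads)) {
  read_counts |>
    inner_join(exon_union_length(gm), by = "gene_id") |>
    mutate(rpkm = rpkm(.data$exonic_reads, .data$exon_union_len, total_mapped_reads))
}

#' Aggregate gene expression to ortho-groups
#'
#' Per-OG expression is the mean RPKM over member genes (the per-OG boxplot
#' statistic); the member gene count is carried along so aggregation is
#' auditable.
#'
#' @param expression Output of [gene_expression()].
#' @param og_membership A tibble `og_id`, `gene_id`.
#' @return A tibble `og_id`, `n_genes`, `rpkm`.
#' @export
og_expression <- function(expression, og_membership) {
  og_membership |>
    inner_join(expression, by = "gene_id") |>
    group_by(.data$og_id) |>
    summarise(n_genes = n(), rpkm = mean(.data$rpkm), .groups = "drop")
}

#' Spearman correlation of isoform and exon counts per gene
#'
#' Tests whether genes with more exons have more annotated isoforms: ranks
#' with average-rank ties, exact permutation p for n <= 10 untied genes,
#' t-approximation otherwise.  A constant vector makes rho undefined and is
#' reported as `NA` rather than an error.
#'
#' @param gene_counts A tibble `gene_id`, `n_exons`, `n_transcripts`
#'   (e.g. from [gene_exon_counts()]); at least 3 genes.
#' @return A one-row tibble `n`, `rho`, `p_value`.
#' @export
isoform_exon_correlation <- function(gene_counts) {
  n <- nrow(gene_counts)
  if (n < 3L) abort("isoform_exon_correlation(): need at least 3 genes.")
  x <- gene_counts$n_exons
  y <- gene_counts$n_transcripts
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(n = n, rho = NA_real_, p_value = NA_real_))
  }
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = n <= 10L && !has_ties))
  tibble(n = n, rho = unname(ct$estimate), p_value = ct$p.value)
}
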