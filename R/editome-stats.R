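# Enrichment statistics linking the editome to diet genes, repeats and
# read-backed linkage disequilibrium.

#' Build a per-gene class/diet table
#'
#' Joins OG membership, OG classification and gene diet flags into the
#' per-gene grouping used by the editing enrichment panels.
#'
#' @param og_membership A tibble `og_id`, `gene_id` (focal-species genes).
#' @param classified Output of [og_classify()].
#' @param gene_flags Output of [flag_diet_genes()].
#' @return A tibble `gene_id`, `og_id`, `class`, `diet`.
#' @export
gene_class_table <- function(og_membership, classified, gene_flags) {
  og_membership |>
    inner_join(select(classified, "og_id", "category", "class"), by = "og_id") |>
    left_join(gene_flags, by = "gene_id") |>
    mutate(diet = dplyr::coalesce(.data$diet, FALSE)) |>
    select("gene_id", "og_id", "category", "class", "diet")
}

#' Editing enrichment in diet genes
#'
#' Within each class, compares diet and non-diet genes on (a) the fraction
#' of genes carrying at least one genic editing site (Fisher's exact test)
#' and (b) the per-gene editing-site count (two-sided Wilcoxon rank-sum).
#'
#' @param sites Annotated editing-site tibble (genic sites carry `gene_id`).
#' @param gene_classes Output of [gene_class_table()].
#' @return A list of class `edited_gene_enrichment`: `genes` (per-gene site
#'   counts), `summary` (per class x diet: `n_genes`, `n_edited`,
#'   `fraction_edited`, `mean_sites`), `fisher` and `ranksum` (one row per
#'   class; tests are skipped — zero rows — when there are no sites).
#' @export
gene_editing_enrichment <- function(sites, gene_classes) {
  genic <- sites |> filter(!is.na(.data$gene_id))
  genes <- gene_classes |>
    left_join(count(genic, .data$gene_id, name = "n_sites"), by = "gene_id") |>
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
           edited = .data$n_sites > 0L)
  summary <- genes |>
    group_by(.data$class, .data$diet) |>
    summarise(n_genes = n(), n_edited = sum(.data$edited),
              fraction_edited = mean(.data$edited),
              mean_sites = mean(.data$n_sites), .groups = "drop")
  no_sites <- nrow(genic) == 0L
  run_class <- function(cls) {
    g <- filter(genes, .data$class == cls)
    if (no_sites || sum(g$diet) == 0L || sum(!g$diet) == 0L) return(NULL)
    m <- matrix(c(sum(g$edited[g$diet]), sum(!g$edited[g$diet]),
                  sum(g$edited[!g$diet]), sum(!g$edited[!g$diet])), 2L, byrow = TRUE)
    list(
      fisher = bind_cols(tibble(class = cls), fisher_2x2(m)),
      ranksum = bind_cols(tibble(class = cls),
                          ranksum_compare(mutate(g, grp = ifelse(.data$diet, "diet", "non_diet")),
                                          "n_sites", "grp"))
    )
  }
  res <- purrr::map(c("class1", "class2"), run_class)
  res <- res[!vapply(res, is.null, logical(1))]
  structure(list(
    genes = genes, summary = summary,
    fisher = purrr::map(res, "fisher") |> list_rbind(),
    ranksum = purrr::map(res, "ranksum") |> list_rbind()
  ), class = "edited_gene_enrichment")
}

# strand-aware upstream interval per gene, clipped at the nearest other gene
upstream_regions <- function(gm, window = 5000) {
  spans <- gene_spans(gm) |> arrange(.data$chrom, .data$start)
  spans |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      n <- nrow(d)
      # for each gene, nearest other-gene end before it / start after it
      up_start <- integer(n); up_end <- integer(n)
      for (i in seq_len(n)) {
        if (d$strand[i] == "+") {
          prev_end <- suppressWarnings(max(d$end[d$end <= d$start[i]], 0L))
          up_start[i] <- max(d$start[i] - window, prev_end)
          up_end[i] <- d$start[i]
        } else {
          next_start <- suppressWarnings(min(d$start[d$start >= d$end[i]], Inf))
          up_start[i] <- d$end[i]
          up_end[i] <- as.integer(min(d$end[i] + window, next_start))
        }
      }
      mutate(d, up_start = up_start, up_end = up_end)
    }) |>
    ungroup() |>
    filter(.data$up_start < .data$up_end) |>
    select("gene_id", "chrom", start = "up_start", end = "up_end")
}

#' Enrichment of upstream intergenic editing in diet genes
#'
#' Flags each gene by whether its upstream intergenic region — from the TSS
#' outward up to `min(window, distance to the previous gene)`, optionally
#' intersected with the repeat track — contains at least one intergenic
#' editing site, then tests diet vs non-diet within each class with
#' Fisher's exact test.
#'
#' @param sites Annotated editing-site tibble.
#' @param gm A [gene_models()] object.
#' @param gene_classes Output of [gene_class_table()].
#' @param repeats Optional repeat tibble (`chrom`, `start`, `end`).
#' @param window Maximum upstream distance in bp (default 5000).
#' @param repeats_only Restrict the upstream region to repeat intervals
#'   (requires `repeats`).
#' @return A list of class `upstream_enrichment` with `genes` (per-gene
#'   flags) and `fisher` (one row per class).
#' @export
upstream_edited_enrichment <- function(sites, gm, gene_classes, repeats = NULL,
                                       window = 5000, repeats_only = FALSE) {
  regions <- upstream_regions(gm, window = window)
  if (repeats_only) {
    if (is.null(repeats)) abort("upstream_edited_enrichment(): repeats_only requires a repeat track.")
    merged <- merge_intervals(repeats)
    regions <- regions |>
      group_by(.data$gene_id) |>
      group_modify(function(d, key) {
        r <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
        rep_gr <- GenomicRanges::GRanges(merged$chrom,
                                         IRanges::IRanges(merged$start + 1L, merged$end))
        ov <- GenomicRanges::intersect(r, rep_gr)
        if (length(ov) == 0L) return(tibble(chrom = character(), start = integer(), end = integer()))
        tibble(chrom = as.character(GenomicRanges::seqnames(ov)),
               start = GenomicRanges::start(ov) - 1L, end = GenomicRanges::end(ov))
      }) |>
      ungroup()
  }
  inter <- sites |> filter(.data$category == "intergenic")
  flag_one <- function(d) {
    any(pos_in_intervals(inter$chrom, inter$pos, d))
  }
  flags <- regions |>
    group_by(.data$gene_id) |>
    summarise(upstream_edited = flag_one(pick("chrom", "start", "end")), .groups = "drop")
  genes <- gene_classes |>
    left_join(flags, by = "gene_id") |>
    mutate(upstream_edited = dplyr::coalesce(.data$upstream_edited, FALSE))
  run_class <- function(cls) {
    g <- filter(genes, .data$class == cls)
    if (sum(g$diet) == 0L || sum(!g$diet) == 0L) return(NULL)
    m <- matrix(c(sum(g$upstream_edited[g$diet]), sum(!g$upstream_edited[g$diet]),
                  sum(g$upstream_edited[!g$diet]), sum(!g$upstream_edited[!g$diet])),
                2L, byrow = TRUE)
    bind_cols(tibble(class = cls,
                     fraction_diet = mean(g$upstream_edited[g$diet]),
                     fraction_non_diet = mean(g$upstream_edited[!g$diet])),
              fisher_2x2(m))
  }
  fisher <- purrr::map(c("class1", "class2"), run_class) |> purrr::compact() |> list_rbind()
  structure(list(genes = genes, fisher = fisher), class = "upstream_enrichment")
}

#' Repeat overlap enrichment by editing-site category
#'
#' Tests, for each genomic category, whether its editing sites are enriched
#' or depleted in repeats relative to all other sites: two-sided Fisher on
#' the 2x2 table (in category vs rest) x (in repeat vs not).  Degenerate
#' tables report an infinite or `NaN` odds ratio as-is.
#'
#' @param sites Annotated editing-site tibble.
#' @param repeats A repeat tibble (`chrom`, `start`, `end`); merged
#'   internally.
#' @return A tibble, one row per category, with the table cells, the
#'   fraction of category sites in repeats, odds ratio and p.
#' @export
repeat_overlap_enrichment <- function(sites, repeats) {
  merged <- merge_intervals(repeats)
  in_rep <- pos_in_intervals(sites$chrom, sites$pos, merged)
  purrr::map(unique(sites$category), function(cat) {
    sel <- sites$category == cat
    m <- matrix(c(sum(sel & in_rep), sum(sel & !in_rep),
                  sum(!sel & in_rep), sum(!sel & !in_rep)), 2L, byrow = TRUE)
    bind_cols(tibble(category = cat, fraction_in_repeat = mean(in_rep[sel])),
              fisher_2x2(m))
  }) |> list_rbind()
}

#' Read-backed linkage-disequilibrium contrast
#'
#' Computes r-squared from the 2x2 haplotype table of reads co-covering each
#' pair of variant sites and contrasts the distribution over genomic SNP
#' pairs with the distribution over editing-site pairs (two-sided Wilcoxon
#' rank-sum).  Genomic SNPs ride on phased haplotypes and should show strong
#' LD even in RNA-seq reads; independent stochastic editing events should
#' not.
#'
#' @param read_obs Observations tibble (`read_id`, `chrom`, `pos`,
#'   `allele` in ref/alt), e.g. from [read_read_obs()].
#' @param site_labels A tibble `chrom`, `pos`, `type` (`snp` or `editing`)
#'   covering the observed sites.
#' @param min_reads Minimum number of co-covering reads per pair
#'   (default 10).
#' @return A list of class `ld_contrast`: `pairs` (per-pair r-squared with
#'   pair type), `medians` and the rank-sum `p_value`.  With no qualifying
#'   pairs, an empty result with a warning.
#' @export
ld_contrast <- function(read_obs, site_labels, min_reads = 10) {
  labeled <- read_obs |>
    inner_join(select(site_labels, "chrom", "pos", "type"), by = c("chrom", "pos"))
  pairs <- labeled |>
    inner_join(labeled, by = c("read_id", "chrom"), suffix = c("_1", "_2"),
               relationship = "many-to-many") |>
    filter(.data$pos_1 < .data$pos_2) |>
    group_by(.data$chrom, .data$pos_1, .data$pos_2, .data$type_1, .data$type_2) |>
    summarise(n_reads = n(),
              p1 = mean(.data$allele_1 == "alt"),
              p2 = mean(.data$allele_2 == "alt"),
              p11 = mean(.data$allele_1 == "alt" & .data$allele_2 == "alt"),
              .groups = "drop") |>
    filter(.data$n_reads >= min_reads,
           .data$type_1 == .data$type_2,
           .data$p1 > 0, .data$p1 < 1, .data$p2 > 0, .data$p2 < 1) |>
    mutate(pair_type = .data$type_1,
           r2 = (.data$p11 - .data$p1 * .data$p2)^2 /
                (.data$p1 * (1 - .data$p1) * .data$p2 * (1 - .data$p2))) |>
    select("chrom", "pos_1", "pos_2", "pair_type", "n_reads", "r2")
  if (nrow(pairs) == 0L || dplyr::n_distinct(pairs$pair_type) < 2L) {
    warn("ld_contrast(): no qualifying site pairs in one or both classes.")
    return(structure(list(pairs = pairs,
                          medians = tibble(pair_type = character(), median_r2 = double()),
                          p_value = NA_real_),
                     class = "ld_contrast"))
  }
  medians <- pairs |>
    group_by(.data$pair_type) |>
    summarise(n_pairs = n(), median_r2 = median(.data$r2), .groups = "drop")
  p <- ranksum_compare(pairs, "r2", "pair_type")$p_value
  structure(list(pairs = pairs, medians = medians, p_value = p),
            class = "ld_contrast")
}

#' @export
print.ld_contrast <- function(x, ...) {
  cat("<ld_contrast>\n")
  print(x$medians)
  cat(sprintf("rank-sum p = %.3g\n", x$p_value))
  invisible(x)
}
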