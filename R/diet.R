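# Diet-gene flagging and enrichment statistics.

#' Flag diet-related genes from Pfam domain assignments
#'
#' A gene is diet-related iff it carries at least one domain from the diet
#' catalog (see [diet_catalog()]).
#'
#' @param domains A tibble `gene_id`, `accession` (one row per assignment; a
#'   gene may appear multiple times or, with no domains, not at all).
#' @param catalog A catalog tibble as returned by [diet_catalog()].
#' @return A tibble `gene_id`, `diet` (logical), one row per input gene.
#' @examples
#' flag_diet_genes(tibble::tibble(gene_id = "g1", accession = "PF00067"))
#' @export
flag_diet_genes <- function(domains, catalog = diet_catalog()) {
  if (nrow(domains) > 0L && !all(grepl("^PF\\d{5}$", domains$accession))) {
    abort("flag_diet_genes(): malformed accession (expected PF + 5 digits).")
  }
  domains |>
    group_by(.data$gene_id) |>
    summarise(diet = any(.data$accession %in% catalog$accession), .groups = "drop")
}

#' Flag diet-related ortho-groups
#'
#' An OG is diet-related iff at least one member gene is diet-flagged (the
#' most sensitive aggregation; the alternative "all members" rule can be
#' obtained by pre-filtering).  Genes without an OG are dropped with a
#' warning.
#'
#' @param og_membership A tibble `og_id`, `gene_id`.
#' @param gene_flags Output of [flag_diet_genes()]; every member gene must be
#'   present.
#' @return A tibble `og_id`, `diet` (logical).
#' @export
flag_diet_ogs <- function(og_membership, gene_flags) {
  orphan <- setdiff(gene_flags$gene_id, og_membership$gene_id)
  if (length(orphan) > 0L) {
    warn(sprintf("flag_diet_ogs(): %d gene(s) without an OG excluded.", length(orphan)))
  }
  joined <- og_membership |> left_join(gene_flags, by = "gene_id")
  if (any(is.na(joined$diet))) {
    abort("flag_diet_ogs(): member gene(s) missing a diet flag.")
  }
  joined |>
    group_by(.data$og_id) |>
    summarise(diet = any(.data$diet), .groups = "drop")
}

# two-sided Fisher's exact test on a 2x2 matrix; returns tidy one-row tibble.
# Odds ratio is the sample (cross-product) ratio, with Inf/NaN for degenerate
# tables reported as-is.
fisher_2x2 <- function(m, alternative = "two.sided") {
  p <- fisher.test(m, alternative = alternative)$p.value
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  tibble(n11 = m[1, 1], n12 = m[1, 2], n21 = m[2, 1], n22 = m[2, 2],
         odds_ratio = or, p_value = p)
}

#' Diet enrichment across OG categories
#'
#' For each category (and for pooled class1 vs class2) computes the fraction
#' of diet-flagged OGs and a Fisher's exact test of the 2x2 table
#' (in group vs rest) x (diet vs non-diet).
#'
#' @param classified Output of [og_classify()].
#' @param og_flags A tibble `og_id`, `diet` covering every classified OG.
#' @param alternative Sidedness of the Fisher test (default two-sided).
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column
#'   (default `FALSE`; the raw p-values are always reported).
#' @return A tibble of class `diet_enrichment`, one row per comparison, with
#'   group sizes, diet counts and fractions on both sides, odds ratio and p.
#'   Empty groups get `NA` fractions and no test.
#' @export
diet_enrichment <- function(classified, og_flags, alternative = "two.sided",
                            adjust = FALSE) {
  x <- classified |> left_join(select(og_flags, "og_id", "diet"), by = "og_id")
  if (any(is.na(x$diet))) abort("diet_enrichment(): OG(s) missing a diet flag.")
  one <- function(in_group, label) {
    n_in <- sum(in_group); n_out <- sum(!in_group)
    d_in <- sum(x$diet[in_group]); d_out <- sum(x$diet[!in_group])
    base <- tibble(comparison = label,
                   n_in = n_in, n_diet_in = d_in,
                   fraction_in = if (n_in == 0L) NA_real_ else d_in / n_in,
                   n_out = n_out, n_diet_out = d_out,
                   fraction_out = if (n_out == 0L) NA_real_ else d_out / n_out)
    if (n_in == 0L || n_out == 0L) {
      return(mutate(base, odds_ratio = NA_real_, p_value = NA_real_))
    }
    m <- matrix(c(d_in, n_in - d_in, d_out, n_out - d_out), 2L, byrow = TRUE)
    bind_cols(base, select(fisher_2x2(m, alternative), "odds_ratio", "p_value"))
  }
  out <- bind_rows(
    purrr::map(OG_CATEGORIES, ~ one(x$category == .x, paste0(.x, "_vs_rest"))) |> list_rbind(),
    one(x$class == "class1", "class1_vs_class2")
  )
  if (adjust) out <- mutate(out, p_adj = p.adjust(.data$p_value, method = "BH"))
  class(out) <- c("diet_enrichment", class(out))
  out
}

#' Two-group Wilcoxon rank-sum comparison of per-OG statistics
#'
#' Compares per-OG values (RPKM, exon counts, editing-site counts, ...)
#' between two groups with a two-sided Wilcoxon rank-sum test: exact
#' enumeration when both groups have at most 15 untied values, otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param values A data frame with a value column and a grouping column.
#' @param value Name of the numeric value column.
#' @param group Name of the two-level grouping column.
#' @return A one-row tibble with group labels, sizes, medians, the rank-sum
#'   statistic `W` and the two-sided `p_value`.
#' @examples
#' d <- tibble::tibble(v = c(1, 2, 3, 10, 20, 30),
#'                     g = rep(c("a", "b"), each = 3))
#' ranksum_compare(d, "v", "g")  # exact p = 0.1
#' @export
ranksum_compare <- function(values, value = "value", group = "group") {
  g <- values[[group]]
  v <- values[[value]]
  levels <- unique(g)
  if (length(levels) != 2L) abort("ranksum_compare(): grouping must have exactly 2 levels.")
  x <- v[g == levels[1]]
  y <- v[g == levels[2]]
  if (length(x) == 0L || length(y) == 0L) abort("ranksum_compare(): a group is empty.")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- length(x) <= 15L && length(y) <= 15L && !has_ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = TRUE))
  tibble(group1 = as.character(levels[1]), group2 = as.character(levels[2]),
         n1 = length(x), n2 = length(y),
         median1 = median(x), median2 = median(y),
         W = unname(wt$statistic), p_value = wt$p.value, exact = use_exact)
}
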