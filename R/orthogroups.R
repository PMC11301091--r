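# Ortho-group classification.
#
# Each ortho-group (OG) carries a gene count in the focal predaceous species
# and in two non-predaceous relatives.  OGs are assigned to exactly one of
# four categories by strict count inequalities, evaluated in fixed precedence
# focal_unique -> focal_more -> gradient -> other:
#
#   focal_unique : focal > j  and both relatives = 0            (default j = 2)
#   focal_more   : focal > k * max(relatives), max(relatives) >= 1  (default k = 2)
#   gradient     : focal > g * rel1  and  rel1 > g * rel2       (default g = 1.5)
#   other        : everything else
#
# focal_unique + focal_more form class1 (focal-specific); gradient + other
# form class2 (shared).  The max(relatives) >= 1 condition on focal_more
# keeps the unique and more categories disjoint: without it every focal-only
# OG would satisfy focal > k * 0.

#' Classification thresholds for ortho-group categories
#'
#' @param j Unique cutoff: `focal_unique` requires focal count strictly
#'   greater than `j` with both relatives absent.  Default 2.
#' @param k Overrepresentation multiplier for `focal_more`.  Default 2.
#' @param g Gradient multiplier: `gradient` requires a strict monotone
#'   decrease focal > g*rel1 > g^2*rel2 through the intermediate species.
#'   Default 1.5 (a multiplier of 2 would make gradient a subset of class1).
#' @return A list of class `og_thresholds`.
#' @examples
#' og_thresholds(j = 3)
#' @export
og_thresholds <- function(j = 2, k = 2, g = 1.5) {
  if (!is.numeric(j) || j < 0) abort("`j` must be >= 0.")
  if (!is.numeric(k) || k <= 0) abort("`k` must be > 0.")
  if (!is.numeric(g) || g <= 1) abort("`g` must be > 1.")
  structure(list(j = j, k = k, g = g), class = "og_thresholds")
}

OG_CATEGORIES <- c("focal_unique", "focal_more", "gradient", "other")

#' Classify ortho-groups by per-species gene counts
#'
#' Assigns every OG to exactly one category (see [og_thresholds()]) and
#' derives the binary class: class1 = focal-specific (unique + more),
#' class2 = shared (gradient + other).  All inequalities are strict;
#' categories are evaluated in precedence unique, more, gradient, other, and
#' gradient is only reachable for OGs outside class1.
#'
#' @param og_counts A tibble with column `og_id` plus one count column per
#'   species (exactly three for the focal comparison).
#' @param focal Name of the focal (predaceous) species column.
#' @param rel1,rel2 Names of the two relative species columns; `rel1` is the
#'   intermediate species of the gradient definition.
#' @param thresholds An [og_thresholds()] object.
#' @return The input tibble with `category` (factor over the four levels) and
#'   `class` (`class1`/`class2`) columns added.
#' @examples
#' counts <- tibble::tibble(og_id = c("a", "b"), focal = c(5L, 3L),
#'                          rel1 = c(0L, 1L), rel2 = c(0L, 1L))
#' og_classify(counts, focal = "focal", rel1 = "rel1", rel2 = "rel2")
#' @export
og_classify <- function(og_counts, focal, rel1, rel2, thresholds = og_thresholds()) {
  for (col in c(focal, rel1, rel2)) {
    if (!col %in% names(og_counts)) abort(sprintf("og_classify(): missing species column `%s`.", col))
    if (any(is.na(og_counts[[col]]))) abort(sprintf("og_classify(): missing counts in `%s`.", col))
  }
  f <- og_counts[[focal]]
  a <- og_counts[[rel1]]
  b <- og_counts[[rel2]]
  t <- thresholds
  category <- dplyr::case_when(
    f > t$j & a == 0L & b == 0L ~ "focal_unique",
    f > t$k * pmax(a, b) & pmax(a, b) >= 1L ~ "focal_more",
    f > t$g * a & a > t$g * b ~ "gradient",
    TRUE ~ "other"
  )
  og_counts |>
    mutate(category = factor(category, levels = OG_CATEGORIES),
           class = ifelse(category %in% c("focal_unique", "focal_more"),
                          "class1", "class2"))
}

#' Summarize a classified OG table
#'
#' @param classified Output of [og_classify()].
#' @return A tibble with one row per category (`n`, `fraction`) plus the
#'   derived class1/class2 totals; counts always sum to the table size.
#' @export
og_class_summary <- function(classified) {
  n_total <- nrow(classified)
  by_cat <- classified |>
    count(.data$category, .drop = FALSE, name = "n") |>
    mutate(level = "category", label = as.character(.data$category)) |>
    select("level", "label", "n")
  by_class <- classified |>
    count(.data$class, name = "n") |>
    right_join(tibble(class = c("class1", "class2")), by = "class") |>
    mutate(n = dplyr::coalesce(.data$n, 0L), level = "class", label = .data$class) |>
    select("level", "label", "n")
  bind_rows(by_cat, by_class) |>
    mutate(n_total = n_total, fraction = .data$n / n_total)
}

#' Sweep classification cutoffs and track diet fractions
#'
#' Reclassifies the table across a grid of `j` (unique cutoff) and `k`
#' (more multiplier) values, reporting category size and the fraction of
#' diet-flagged OGs in the category at each cutoff.  Stringent-enough
#' cutoffs should give a stable, elevated diet fraction among focal-specific
#' OGs; an empty category yields an undefined (`NA`) fraction, not 0.
#'
#' @inheritParams og_classify
#' @param diet_flags A tibble `og_id`, `diet` (logical).
#' @param j_values,k_values Numeric vectors of cutoffs to try.
#' @return A tibble `parameter` (`"j"` or `"k"`), `value`, `category`,
#'   `n_category`, `n_diet`, `diet_fraction`.
#' @export
og_cutoff_sweep <- function(og_counts, focal, rel1, rel2, diet_flags,
                            j_values = 0:6, k_values = numeric(0)) {
  if (length(j_values) == 0L && length(k_values) == 0L) {
    abort("og_cutoff_sweep(): at least one of j_values/k_values must be nonempty.")
  }
  flags <- select(diet_flags, "og_id", "diet")
  one <- function(parameter, value) {
    t <- if (parameter == "j") og_thresholds(j = value) else og_thresholds(k = value)
    cat_name <- if (parameter == "j") "focal_unique" else "focal_more"
    cls <- og_classify(og_counts, focal, rel1, rel2, t) |>
      left_join(flags, by = "og_id") |>
      filter(.data$category == cat_name)
    n_cat <- nrow(cls)
    n_diet <- sum(cls$diet, na.rm = TRUE)
    tibble(parameter = parameter, value = value, category = cat_name,
           n_category = n_cat, n_diet = n_diet,
           diet_fraction = if (n_cat == 0L) NA_real_ else n_diet / n_cat)
  }
  bind_rows(
    purrr::map(j_values, ~ one("j", .x)) |> list_rbind(),
    purrr::map(k_values, ~ one("k", .x)) |> list_rbind()
  )
}

#' Global pairwise protein identity
#'
#' Needleman-Wunsch global alignment with a fixed scoring scheme (BLOSUM62,
#' gap opening 10, gap extension 0.5); identity is the number of identical
#' aligned residues divided by the number of alignment columns (a column
#' gapped in both sequences cannot occur in a pairwise alignment).
#'
#' @param seq_a,seq_b Nonempty protein strings over the 20 amino-acid
#'   letters plus `X`.
#' @return A number in \[0, 1\].
#' @examples
#' pairwise_identity("MKVLA", "MKVLA")  # 1
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("pairwise_identity(): empty sequence.")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

# alignment score under the same scheme (used by tests against a DP oracle)
pairwise_alignment_score <- function(seq_a, seq_b) {
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global"))
}

#' Intra- versus inter-OG identity contrast
#'
#' Checks that sequences clustered into one OG are more similar to each other
#' than to genes of different OGs.  The intra statistic is the mean pairwise
#' identity within each multi-gene OG.  For the inter statistic, multi-gene
#' OGs are shuffled into `n_bins` near-equal bins, one gene is sampled per
#' member OG and the mean pairwise identity within the bin is recorded.  The
#' two sets of means are compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param og_sequences A tibble `og_id`, `gene_id`, `sequence` (protein).
#' @param n_bins Number of inter-OG bins (default 100).
#' @param seed Integer seed fixing the bin assignment and gene sampling.
#' @return A list of class `og_identity_contrast` with tibbles `intra`
#'   (`og_id`, `mean_identity`), `inter` (`bin`, `mean_identity`) and the
#'   rank-sum `p_value`.
#' @export
og_identity_contrast <- function(og_sequences, n_bins = 100, seed = 1) {
  multi <- og_sequences |>
    group_by(.data$og_id) |>
    filter(n() >= 2L) |>
    ungroup()
  og_ids <- unique(multi$og_id)
  if (length(og_ids) < n_bins) {
    abort(sprintf(paste0("og_identity_contrast(): %d multi-gene OGs < %d bins; ",
                         "use a smaller n_bins."), length(og_ids), n_bins))
  }
  mean_pairwise <- function(seqs) {
    pairs <- utils::combn(length(seqs), 2L)
    mean(purrr::map_dbl(seq_len(ncol(pairs)),
                        ~ pairwise_identity(seqs[pairs[1, .x]], seqs[pairs[2, .x]])))
  }
  intra <- multi |>
    group_by(.data$og_id) |>
    summarise(mean_identity = mean_pairwise(.data$sequence), .groups = "drop")

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  inter <- withr_seed({
    bins <- sample(rep_len(seq_len(n_bins), length(og_ids)))
    assignment <- tibble(og_id = og_ids, bin = bins)
    multi |>
      left_join(assignment, by = "og_id") |>
      group_by(.data$bin, .data$og_id) |>
      slice_sample(n = 1L) |>
      group_by(.data$bin) |>
      summarise(mean_identity = mean_pairwise(.data$sequence), .groups = "drop")
  })
  p <- wilcox.test(intra$mean_identity, inter$mean_identity, exact = FALSE)$p.value
  structure(list(intra = intra, inter = inter, p_value = p),
            class = "og_identity_contrast")
}

#' @export
print.og_identity_contrast <- function(x, ...) {
  cat(sprintf("<og_identity_contrast> intra mean %.3f (%d OGs) vs inter mean %.3f (%d bins), p = %.3g\n",
              mean(x$intra$mean_identity), nrow(x$intra),
              mean(x$inter$mean_identity), nrow(x$inter), x$p_value))
  invisible(x)
}
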