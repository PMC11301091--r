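# Cross-species directional expansion test.
#
# For each OG, per-species gene counts are log2(n+1)-transformed and the
# predaceous and phytophagous groups compared with a two-sided Welch t-test.
# Direction is assigned from the transformed group means when p < alpha.
# OGs with zero variance in both groups are untestable when the means are
# equal; when the means differ (e.g. a constant nonzero count against all
# zeros) a variance floor makes the comparison decidable with p -> 0, which
# is the intended reading of a constant, perfectly separated OG.

#' Per-OG predaceous vs phytophagous group test
#'
#' @param panel A wide tibble `og_id` plus one integer count column per
#'   species.
#' @param labels A tibble `species`, `diet` (`predaceous` / `phytophagous` /
#'   `outgroup`); every panel species must be labeled.  Outgroup species are
#'   excluded from both groups.
#' @param alpha Significance level for direction calls and stars
#'   (default 0.05).
#' @param var_floor Variance floor used only when both groups are constant
#'   with different means (default 1e-12).
#' @return A tibble of class `og_direction_test`, one row per OG:
#'   group means and standard errors on the raw counts, Welch `t`, `df`,
#'   two-sided `p_value`, `direction` (`pred_higher` / `phyt_higher` /
#'   `none`), `stars` and `testable`.
#' @export
per_og_group_test <- function(panel, labels, alpha = 0.05, var_floor = 1e-12) {
  species <- setdiff(names(panel), "og_id")
  missing_lab <- setdiff(species, labels$species)
  if (length(missing_lab) > 0L) {
    abort(paste0("per_og_group_test(): unlabeled species: ",
                 paste(missing_lab, collapse = ", ")))
  }
  lab <- setNames(labels$diet, labels$species)[species]
  pred <- species[lab == "predaceous"]
  phyt <- species[lab == "phytophagous"]
  if (length(pred) < 2L || length(phyt) < 2L) {
    abort("per_og_group_test(): need at least 2 species per diet group.")
  }
  mp <- as.matrix(panel[pred])
  mh <- as.matrix(panel[phyt])
  lp <- log2(mp + 1)
  lh <- log2(mh + 1)

  sem <- function(m) apply(m, 1L, sd) / sqrt(ncol(m))
  n1 <- length(pred); n2 <- length(phyt)
  m1 <- rowMeans(lp); m2 <- rowMeans(lh)
  v1 <- apply(lp, 1L, var); v2 <- apply(lh, 1L, var)
  both_const <- v1 == 0 & v2 == 0
  untestable <- both_const & m1 == m2
  v1f <- ifelse(both_const & !untestable, var_floor, v1)
  v2f <- ifelse(both_const & !untestable, var_floor, v2)
  se2 <- v1f / n1 + v2f / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1f / n1)^2 / (n1 - 1) + (v2f / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p[untestable] <- NA_real_
  t_stat[untestable] <- NA_real_

  tibble(
    og_id = panel$og_id,
    mean_pred = rowMeans(mp), sem_pred = sem(mp),
    mean_phyt = rowMeans(mh), sem_phyt = sem(mh),
    t = t_stat, df = ifelse(untestable, NA_real_, df), p_value = p,
    testable = !untestable,
    direction = dplyr::case_when(
      is.na(p) | p >= alpha ~ "none",
      m1 > m2 ~ "pred_higher",
      TRUE ~ "phyt_higher"
    ),
    stars = star_code(p)
  ) |>
    structure(class = c("og_direction_test", class(tibble())))
}

#' Count significant OGs by direction
#'
#' @param results Output of [per_og_group_test()].
#' @return A one-row tibble `n_pred_higher`, `n_phyt_higher`, `n_tested`,
#'   `n_total`; the two directional counts partition the significant OGs.
#' @export
count_directional_significant <- function(results) {
  if (nrow(results) == 0L) abort("count_directional_significant(): empty results.")
  tibble(
    n_pred_higher = sum(results$direction == "pred_higher"),
    n_phyt_higher = sum(results$direction == "phyt_higher"),
    n_tested = sum(results$testable),
    n_total = nrow(results)
  )
}

#' One-sided Fisher test on the directional summary
#'
#' Tests whether significantly predaceous-higher OGs outnumber
#' phytophagous-higher OGs among `n_total` tested OGs: one-sided (greater)
#' exact hypergeometric p for the table
#' `[[n_a, n_total - n_a], [n_b, n_total - n_b]]`.
#'
#' @param n_a Number of OGs significant in the first direction.
#' @param n_b Number significant in the opposite direction.
#' @param n_total Number of OGs tested in each direction.
#' @return The one-sided p-value.
#' @examples
#' direction_fisher(18, 0, 47)  # ~5.1e-7
#' @export
direction_fisher <- function(n_a, n_b, n_total) {
  if (n_a < 0 || n_b < 0 || n_a > n_total || n_b > n_total) {
    abort("direction_fisher(): counts must lie in [0, n_total].")
  }
  m <- matrix(c(n_a, n_total - n_a, n_b, n_total - n_b), 2L, byrow = TRUE)
  fisher.test(m, alternative = "greater")$p.value
}
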