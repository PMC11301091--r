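mk_panel <- function(counts_pred, counts_phyt, og_id = "og1") {
  n1 <- length(counts_pred); n2 <- length(counts_phyt)
  species <- c(sprintf("pred_%02d", seq_len(n1)), sprintf("phyt_%02d", seq_len(n2)))
  panel <- tibble::as_tibble(setNames(as.list(c(counts_pred, counts_phyt)), species))
  panel <- dplyr::bind_cols(tibble::tibble(og_id = og_id), panel)
  labels <- tibble::tibble(species = species,
                           diet = c(rep("predaceous", n1), rep("phytophagous", n2)))
  list(panel = panel, labels = labels)
}

test_that("identical counts in both groups are untestable, not significant", {
  px <- mk_panel(rep(3L, 5), rep(3L, 28))
  res <- per_og_group_test(px$panel, px$labels)
  expect_false(res$testable)
  expect_true(is.na(res$p_value))
  expect_equal(res$direction, "none")
  expect_equal(res$stars, "")
})

test_that("constant separated counts are decided by the variance-floor rule", {
  px <- mk_panel(rep(8L, 5), rep(0L, 28))
  res <- per_og_group_test(px$panel, px$labels)
  expect_true(res$testable)
  expect_equal(res$direction, "pred_higher")
  expect_lt(res$p_value, 0.001)
  expect_equal(res$stars, "***")
  expect_equal(res$mean_pred, 8)
  expect_equal(res$mean_phyt, 0)
  expect_equal(res$sem_pred, 0)
})

test_that("group means and SEM are reported on the raw count scale", {
  px <- mk_panel(c(1L, 2L, 3L, 4L, 5L), rep(c(0L, 2L), 14))
  res <- per_og_group_test(px$panel, px$labels)
  expect_equal(res$mean_pred, 3)
  expect_equal(res$sem_pred, sd(1:5) / sqrt(5))
  # t and p agree with stats::t.test on the transformed values
  tt <- t.test(log2(c(1, 2, 3, 4, 5) + 1), log2(rep(c(0, 2), 14) + 1))
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
})

test_that("outgroup species are excluded and unlabeled species rejected", {
  px <- mk_panel(rep(6L, 5), rep(1L, 28))
  panel <- dplyr::mutate(px$panel, outgroup_sp = 99L)
  labels <- dplyr::bind_rows(px$labels,
                             tibble::tibble(species = "outgroup_sp", diet = "outgroup"))
  res <- per_og_group_test(panel, labels)
  expect_equal(res$mean_pred, 6)   # the 99-count outgroup never enters
  expect_equal(res$mean_phyt, 1)
  expect_error(per_og_group_test(panel, px$labels), "unlabeled")
  few <- mk_panel(5L, rep(1L, 28))
  expect_error(per_og_group_test(few$panel, few$labels), "2 species")
})

test_that("directional counting partitions significant OGs", {
  px1 <- mk_panel(rep(8L, 5), rep(0L, 28), "up")
  px2 <- mk_panel(rep(0L, 5), rep(8L, 28), "down")
  px3 <- mk_panel(rep(3L, 5), rep(3L, 28), "flat")
  panel <- dplyr::bind_rows(px1$panel, px2$panel, px3$panel)
  res <- per_og_group_test(panel, px1$labels)
  counts <- count_directional_significant(res)
  expect_equal(counts$n_pred_higher, 1L)
  expect_equal(counts$n_phyt_higher, 1L)
  expect_equal(counts$n_total, 3L)
  expect_lte(counts$n_pred_higher + counts$n_phyt_higher, counts$n_total)
  g <- glance(res)
  expect_equal(g$fraction_pred_higher, 1 / 3)
  expect_error(count_directional_significant(res[0, ]), "empty")
})

test_that("directional Fisher p matches exhaustive enumeration and is symmetric", {
  # all tables with n_total <= 20: single aggregated comparison
  worst <- 0
  for (n_total in 1:20) {
    grid <- expand.grid(n_a = 0:n_total, n_b = 0:n_total)
    for (i in seq_len(nrow(grid))) {
      n_a <- grid$n_a[i]; n_b <- grid$n_b[i]
      m <- matrix(c(n_a, n_total - n_a, n_b, n_total - n_b), 2L, byrow = TRUE)
      worst <- max(worst, abs(direction_fisher(n_a, n_b, n_total) -
                                fisher_oracle_greater(m)))
    }
  }
  expect_lt(worst, 1e-12)
  expect_gte(direction_fisher(7, 7, 20), 0.5)
  expect_error(direction_fisher(5, 1, 3), "n_total")
})
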