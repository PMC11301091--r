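test_that("category definitions follow the strict inequalities and precedence", {
  counts <- tibble::tibble(
    og_id = c("unique", "more", "gradient", "boundary", "zero"),
    focal = c(5L, 3L, 4L, 2L, 0L),
    rel1 = c(0L, 1L, 2L, 0L, 0L),
    rel2 = c(0L, 1L, 1L, 0L, 0L))
  cls <- og_classify(counts, "focal", "rel1", "rel2")
  expect_equal(as.character(cls$category),
               c("focal_unique", "focal_more", "gradient", "other", "other"))
  # focal = 2 fails the strict > 2; the disjointness rule blocks focal_more
  expect_equal(cls$class, c("class1", "class1", "class2", "class2", "class2"))
  expect_error(og_classify(counts[, 1:3], "focal", "rel1", "rel2"), "missing species")
  expect_error(og_classify(dplyr::mutate(counts, focal = NA_integer_),
                           "focal", "rel1", "rel2"), "missing counts")
})

test_that("category partition and class bookkeeping hold on random tables", {
  set.seed(31)
  tbl <- tibble::tibble(og_id = as.character(1:500),
                        focal = rpois(500, 3), rel1 = rpois(500, 3), rel2 = rpois(500, 3))
  cls <- og_classify(tbl, "focal", "rel1", "rel2")
  s <- og_class_summary(cls)
  cat_counts <- s$n[s$level == "category"]
  expect_equal(sum(cat_counts), 500L)
  class_counts <- s$n[s$level == "class"]
  expect_equal(sum(class_counts), 500L)
  expect_equal(class_counts[s$label[s$level == "class"] == "class2"],
               500L - class_counts[s$label[s$level == "class"] == "class1"])
})

test_that("unique and more categories nest monotonically in their cutoffs", {
  set.seed(32)
  tbl <- tibble::tibble(og_id = as.character(1:400),
                        focal = rpois(400, 4), rel1 = rpois(400, 2), rel2 = rpois(400, 2))
  ids_at <- function(t) {
    cls <- og_classify(tbl, "focal", "rel1", "rel2", t)
    split(cls$og_id, cls$category)
  }
  for (j in 0:5) {
    a <- ids_at(og_thresholds(j = j))$focal_unique
    b <- ids_at(og_thresholds(j = j + 1))$focal_unique
    expect_true(all(b %in% a))
  }
  for (k in c(1, 1.5, 2, 3)) {
    a <- ids_at(og_thresholds(k = k))$focal_more
    b <- ids_at(og_thresholds(k = k + 1))$focal_more
    expect_true(all(b %in% a))
  }
})

test_that("the cutoff sweep reports undefined fractions for empty categories", {
  tbl <- tibble::tibble(og_id = c("a", "b"), focal = c(4L, 5L),
                        rel1 = c(0L, 0L), rel2 = c(0L, 0L))
  flags <- tibble::tibble(og_id = c("a", "b"), diet = c(TRUE, FALSE))
  sw <- og_cutoff_sweep(tbl, "focal", "rel1", "rel2", flags, j_values = c(2, 10))
  expect_equal(sw$n_category, c(2L, 0L))
  expect_equal(sw$diet_fraction, c(0.5, NA))
  expect_true(all(diff(dplyr::filter(
    og_cutoff_sweep(tbl, "focal", "rel1", "rel2", flags, j_values = 0:6)
  )$n_category) <= 0))
  expect_error(og_cutoff_sweep(tbl, "focal", "rel1", "rel2", flags,
                               j_values = integer(0)), "nonempty")
})

test_that("sweep on simulated truth shows the planted diet stabilization", {
  sim <- get_default_sim()
  ogf <- flag_diet_ogs(sim$og_membership, flag_diet_genes(sim$domains))
  sw <- og_cutoff_sweep(sim$og_counts, "focal", "rel1", "rel2", ogf, j_values = 0:6)
  # planted unique OGs all have focal count > 2, so the unique set is stable
  # from j = 0..2 and its diet fraction stays well above the genomic baseline
  baseline <- mean(ogf$diet)
  expect_true(all(sw$diet_fraction[sw$value <= 2] > baseline))
  expect_true(all(diff(sw$n_category) <= 0))
})

test_that("pairwise identity matches its definition and a DP oracle", {
  expect_equal(pairwise_identity("MKVLAWYS", "MKVLAWYS"), 1)
  expect_equal(pairwise_identity("AAAA", "AAAV"), 0.75)
  expect_error(pairwise_identity("", "MK"), "empty")

  set.seed(41)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:10) {
    a <- paste0(sample(aa, 50, replace = TRUE), collapse = "")
    b <- paste0(sample(aa, sample(40:60, 1), replace = TRUE), collapse = "")
    o <- nw_oracle(a, b)
    expect_equal(dietshift:::pairwise_alignment_score(a, b), o$score)
    # co-optimal alignments can differ in identity by a few columns
    expect_lt(abs(pairwise_identity(a, b) - o$identity), 0.1)
  }
})

test_that("intra-OG identity exceeds inter-OG identity on separated sequences", {
  set.seed(42)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  rand_seq <- function() paste0(sample(aa, 30, replace = TRUE), collapse = "")
  # each OG: one sequence duplicated (intra identity 1); different OGs random
  ogs <- purrr::map(1:12, function(i) {
    s <- rand_seq()
    tibble::tibble(og_id = paste0("og", i), gene_id = paste0("og", i, "_", 1:2),
                   sequence = s)
  }) |> purrr::list_rbind()
  res <- og_identity_contrast(ogs, n_bins = 4, seed = 1)
  expect_equal(mean(res$intra$mean_identity), 1)
  expect_gt(mean(res$intra$mean_identity), mean(res$inter$mean_identity))
  expect_lt(res$p_value, 0.05)
  # fixed seed: identical bins and sampling
  res2 <- og_identity_contrast(ogs, n_bins = 4, seed = 1)
  expect_identical(res$inter, res2$inter)
  expect_error(og_identity_contrast(ogs, n_bins = 50, seed = 1), "smaller n_bins")
  g <- glance(res)
  expect_equal(g$n_ogs, 12L)
})
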