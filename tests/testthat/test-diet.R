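test_that("the built-in diet catalog pins the full accession list", {
  cat <- diet_catalog()
  expect_equal(nrow(cat), 27L)
  expect_equal(dplyr::n_distinct(cat$term), 19L)
  expect_true(all(grepl("^PF\\d{5}$", cat$accession)))
  expected <- c(
    "Cytochrome P450" = "PF00067", "Glutathione S-transferase" = "PF00043",
    "Carboxylesterase" = "PF00135", "ATP-binding cassette transporter" = "PF00005",
    "Ionotropic receptor" = "PF00060", "Odorant-binding protein" = "PF01395",
    "Chemosensory protein" = "PF03392", "Sensory neuron membrane protein" = "PF01130",
    "Serine protease" = "PF00089", "Serpin" = "PF00079",
    "Carboxypeptidase" = "PF00246", "Aspartic protease" = "PF00026",
    "Alpha amylase" = "PF00128", "Thioredoxin" = "PF00085",
    "CUB" = "PF00431", "Ptu family" = "PF08117")
  for (term in names(expected)) {
    expect_equal(cat$accession[cat$term == term], unname(expected[term]))
  }
  expect_setequal(cat$accession[cat$term == "Gustatory receptor"],
                  c("PF06151", "PF08395"))
  expect_setequal(cat$accession[cat$term == "Odorant receptor"],
                  c("PF13853", "PF02949"))
  expect_setequal(cat$accession[cat$term == "Lipase"],
                  c("PF00151", "PF01764", "PF06350", "PF04083", "PF01734",
                    "PF00657", "PF13472"))
})

test_that("gene flagging is an any-catalog-domain rule", {
  dom <- tibble::tibble(gene_id = c("g1", "g2", "g2", "g3"),
                        accession = c("PF00067", "PF99999", "PF90001", "PF99998"))
  flags <- flag_diet_genes(dom)
  expect_true(flags$diet[flags$gene_id == "g1"])
  expect_false(flags$diet[flags$gene_id == "g2"])
  expect_error(flag_diet_genes(tibble::tibble(gene_id = "g", accession = "XF1")),
               "malformed")
})

test_that("OG flagging uses the any-member rule and handles orphans", {
  mem <- tibble::tibble(og_id = c("A", "A", "A", "B", "B"),
                        gene_id = paste0("g", 1:5))
  flags <- tibble::tibble(gene_id = paste0("g", 1:6),
                          diet = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_warning(ogf <- flag_diet_ogs(mem, flags), "without an OG")
  expect_true(ogf$diet[ogf$og_id == "A"])
  expect_false(ogf$diet[ogf$og_id == "B"])
})

test_that("category enrichment bookkeeping and null behavior are exact", {
  set.seed(21)
  tbl <- tibble::tibble(og_id = as.character(1:200),
                        focal = rpois(200, 3), rel1 = rpois(200, 3), rel2 = rpois(200, 3))
  cls <- og_classify(tbl, "focal", "rel1", "rel2")
  flags <- tibble::tibble(og_id = tbl$og_id, diet = runif(200) < 0.2)
  enr <- diet_enrichment(cls, flags)
  # margins: diet counts inside + outside each comparison sum to total diet OGs
  expect_true(all(enr$n_diet_in + enr$n_diet_out == sum(flags$diet)))
  expect_true(all(enr$n_in + enr$n_out == 200L))
  # empty categories yield NA fractions and no test
  empty <- enr[enr$n_in == 0L, ]
  expect_true(all(is.na(empty$fraction_in)) && all(is.na(empty$p_value)))

  # identical composition in group and rest: odds ratio 1, p = 1
  cls2 <- og_classify(tibble::tibble(og_id = as.character(1:40),
                                     focal = rep(c(5L, 1L), each = 20),
                                     rel1 = 0L, rel2 = 0L), "focal", "rel1", "rel2")
  flags2 <- tibble::tibble(og_id = cls2$og_id, diet = rep(c(TRUE, FALSE), 20))
  enr2 <- diet_enrichment(cls2, flags2)
  row <- enr2[enr2$comparison == "focal_unique_vs_rest", ]
  expect_equal(row$odds_ratio, 1)
  expect_equal(row$p_value, 1)
})

test_that("Fisher enrichment p-values match exhaustive enumeration on small tables", {
  set.seed(22)
  for (i in 1:50) {
    m <- matrix(rpois(4, 5), 2, 2)
    if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) next
    expect_equal(dietshift:::fisher_2x2(m)$p_value, fisher_oracle_two_sided(m),
                 tolerance = 1e-10)
  }
})

test_that("rank-sum comparison uses exact enumeration for small untied groups", {
  d <- tibble::tibble(v = c(1, 2, 3, 10, 20, 30), g = rep(c("a", "b"), each = 3))
  res <- ranksum_compare(d, "v", "g")
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)   # 2/20 two-sided over C(6,3) assignments
  expect_equal(res$p_value, ranksum_enum_oracle(c(1, 2, 3), c(10, 20, 30)))

  same <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_gt(ranksum_compare(same, "v", "g")$p_value, 0.99)

  expect_error(ranksum_compare(tibble::tibble(v = 1, g = "a"), "v", "g"),
               "2 levels")
})
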