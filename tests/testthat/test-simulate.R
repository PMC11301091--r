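test_that("the simulator is deterministic for a fixed seed", {
  cfg <- sim_config(seed = 11, n_chroms = 1, chrom_len = 4e5, n_genes = 40,
                    n_ogs = 300, n_editing_sites = 200, n_snps = 50,
                    n_contaminant_snps = 10, n_background_sites = 100,
                    n_panel_ogs = 30, n_bidirectional_sites = 5)
  s1 <- get_small_sim()
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$pileup, s2$pileup)
  expect_identical(s1$og_counts, s2$og_counts)
  expect_identical(s1$truth$editing, s2$truth$editing)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$genome$sequence, s2$genome$sequence)
})

test_that("editing sites and SNPs occupy disjoint positions", {
  sim <- get_small_sim()
  ek <- paste(sim$truth$editing$chrom, sim$truth$editing$pos)
  sk <- paste(sim$snps$chrom, sim$snps$pos)
  expect_length(intersect(ek, sk), 0L)
})

test_that("pileup alternative-allele fractions track planted editing levels", {
  sim <- get_small_sim()
  tr <- dplyr::filter(sim$truth$editing, !bidirectional, depth > 0)
  p <- dplyr::inner_join(sim$pileup, tr, by = c("chrom", "pos"),
                         suffix = c("", "_truth"))
  alt_tx <- substr(p$sub, 3, 3)
  alt_genome <- ifelse(p$strand == "-", dietshift:::complement_base(alt_tx), alt_tx)
  counts <- as.matrix(p[, c("nA", "nC", "nG", "nT")])
  alt_n <- counts[cbind(seq_len(nrow(p)), match(alt_genome, c("A", "C", "G", "T")))]
  # binomial consistency: standardized residuals of alt counts against the
  # planted Binomial(depth, level) law are centred and rarely extreme
  lv <- pmin(pmax(p$level, 1e-6), 1 - 1e-6)
  z <- (alt_n - p$depth * lv) / sqrt(p$depth * lv * (1 - lv))
  expect_lt(abs(mean(z)), 0.2)
  expect_gte(mean(abs(z) <= 3), 0.95)
})

test_that("planted category and diet proportions are recovered exactly", {
  sim <- get_small_sim()
  cls <- og_classify(sim$og_counts, "focal", "rel1", "rel2")
  truth <- sim$truth$og
  expect_identical(as.character(cls$category),
                   truth$category[match(cls$og_id, truth$og_id)])
  planted <- round(300 * c(unique = 0.008, more = 0.008, gradient = 0.0025))
  counts <- table(truth$category)
  expect_equal(unname(counts[["focal_unique"]]), unname(planted[["unique"]]))
  expect_equal(unname(counts[["focal_more"]]), unname(planted[["more"]]))
  expect_equal(sum(counts), 300L)
  # diet flags flow intact through domain assignments and membership
  ogf <- flag_diet_ogs(sim$og_membership, flag_diet_genes(sim$domains))
  expect_identical(ogf$diet, truth$diet[match(ogf$og_id, truth$og_id)])
})

test_that("boundary and degenerate configurations behave as documented", {
  expect_error(sim_config(n_genes = 1000, chrom_len = 1e5, n_chroms = 1),
               "infeasible")
  expect_error(sim_config(n_editing_sites = 1e6, chrom_len = 1e5, n_chroms = 1,
                          n_genes = 5), "infeasible")
  expect_error(sim_config(target_AtoG_fraction = 1.2), "fractions")
  expect_error(sim_config(og_proportions = c(unique = 0.5, more = 0.2,
                                             gradient = 0.1, other = 0.1)),
               "sum to 1")

  # null editing config: pileup holds only reference and SNP-carrying sites
  sn <- simulate_dataset(sim_config(
    seed = 3, n_chroms = 1, chrom_len = 4e5, n_genes = 40, n_ogs = 300,
    n_editing_sites = 0, n_bidirectional_sites = 0, n_snps = 50,
    n_contaminant_snps = 10, n_background_sites = 100, n_panel_ogs = 30))
  expect_equal(nrow(sn$truth$editing), 0L)
  snp_keys <- paste(sn$snps$chrom, sn$snps$pos)
  non_snp <- dplyr::filter(sn$pileup, !(paste(chrom, pos) %in% snp_keys))
  counts <- as.matrix(non_snp[, c("nA", "nC", "nG", "nT")])
  ref_n <- counts[cbind(seq_len(nrow(non_snp)), match(non_snp$ref, c("A", "C", "G", "T")))]
  # only miscalls deviate from reference
  expect_gt(sum(ref_n) / sum(counts), 0.995)

  # every planted site is A-on-transcript-strand to G at the boundary fraction
  sa <- simulate_dataset(sim_config(
    seed = 4, n_chroms = 1, chrom_len = 4e5, n_genes = 40, n_ogs = 300,
    n_editing_sites = 100, target_AtoG_fraction = 1, n_snps = 20,
    n_contaminant_snps = 0, n_background_sites = 50, n_panel_ogs = 30,
    n_bidirectional_sites = 0))
  expect_true(all(sa$truth$editing$sub == "A>G"))
})

test_that("planted depth and level laws give CDS highest coverage, lowest level", {
  sim <- get_default_sim()
  ed <- sim$truth$editing
  med <- tapply(ed$depth, ed$category, median)
  expect_gt(med[["CDS"]], med[["intergenic"]])
  lev <- tapply(ed$level, ed$category, median)
  expect_lt(lev[["CDS"]], lev[["intergenic"]])
})

test_that("null panel effect keeps groups exchangeable; labels are enforced", {
  ps <- simulate_panel(50, n_expanded = 10, effect = 1, seed = 5)
  ps2 <- simulate_panel(50, n_expanded = 10, effect = 1, seed = 5)
  expect_identical(ps$panel, ps2$panel)
  # effect = 1 leaves the base draw untouched
  base <- ps$panel
  planted <- plant_panel_effect(base, ps$labels, effect = 1,
                                diet_flags = ps$truth)
  expect_identical(planted, base)
  expect_error(plant_panel_effect(base, ps$labels[-1, ], 2, ps$truth),
               "unlabeled")
  expect_error(plant_panel_effect(base[, 1:3], ps$labels, 2, ps$truth),
               ">= 2 species")
})
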