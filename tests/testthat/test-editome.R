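mk_pileup <- function(...) {
  rows <- list(...)
  purrr::map(rows, function(r) {
    tibble::tibble(chrom = r[[1]], pos = as.integer(r[[2]]), ref = r[[3]],
                   nA = as.integer(r[[4]]), nC = as.integer(r[[5]]),
                   nG = as.integer(r[[6]]), nT = as.integer(r[[7]]))
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(depth = nA + nC + nG + nT)
}

test_that("RDD calling applies thresholds and a deterministic tie-break", {
  p <- mk_pileup(
    list("chr1", 50, "A", 7, 0, 3, 0),    # level 0.3 A>G candidate
    list("chr1", 60, "A", 9, 0, 1, 0),    # rejected: min_alt
    list("chr1", 70, "A", 2, 0, 2, 0),    # rejected: min_depth
    list("chr1", 80, "A", 6, 0, 3, 3))    # G/T tie -> G by base order
  v <- call_rdd(p)
  expect_equal(v$pos, c(50L, 80L))
  expect_equal(v$sub[1], "A>G")
  expect_equal(v$level[1], 0.3)
  expect_equal(v$alt[v$pos == 80L], "G")
  log <- stage_log(v)
  expect_equal(log$n_in, 4L)
  expect_equal(log$n_out, 2L)
  expect_equal(nrow(call_rdd(p[0, ])), 0L)
})

test_that("SNP exclusion removes by position regardless of allele", {
  p <- mk_pileup(list("chr1", 50, "A", 7, 0, 3, 0),
                 list("chr1", 90, "A", 7, 0, 3, 0))
  v <- call_rdd(p)
  snps <- tibble::tibble(chrom = "chr1", pos = 50L, ref = "A", alt = "T")
  out <- exclude_snps(v, snps)
  expect_equal(out$pos, 90L)
  expect_equal(dplyr::last(stage_log(out)$n_removed), 1L)
  # empty SNP table is the identity
  expect_equal(nrow(exclude_snps(v, snps[0, ])), 2L)
  expect_error(exclude_snps(v, dplyr::mutate(snps, chrom = "scaffold_9")),
               "shared chromosome")
})

test_that("bidirectional masking removes opposite-strand overlaps only", {
  gm <- gene_models(tibble::tibble(
    gene_id = c("a", "b", "nest_out", "nest_in"),
    transcript_id = c("a.t", "b.t", "no.t", "ni.t"),
    type = "exon", chrom = "chr1",
    start = c(0L, 50L, 300L, 350L),
    end = c(100L, 150L, 500L, 400L),
    strand = c("+", "-", "+", "+")))
  p <- mk_pileup(list("chr1", 75, "A", 7, 0, 3, 0),    # inside a(+) and b(-)
                 list("chr1", 375, "A", 7, 0, 3, 0))   # nested same strand
  v <- mask_bidirectional(call_rdd(p), gm)
  expect_equal(v$pos, 375L)
  expect_equal(dplyr::last(stage_log(v)$n_removed), 1L)
})

test_that("strand resolution complements minus-gene calls and majority-votes clusters", {
  gm <- gene_models(tibble::tibble(
    gene_id = c("plus", "minus"), transcript_id = c("p.t", "m.t"),
    type = "exon", chrom = "chr1",
    start = c(0L, 200L), end = c(100L, 300L), strand = c("+", "-")))
  p <- mk_pileup(list("chr1", 50, "A", 7, 0, 3, 0),    # + gene: A>G stays
                 list("chr1", 250, "T", 0, 3, 0, 7))   # - gene: T>C -> A>G
  v <- resolve_strand(call_rdd(p), gm)
  expect_equal(v$sub, c("A>G", "A>G"))
  expect_equal(v$strand, c("+", "-"))
  expect_equal(v$sub_genome, c("A>G", "T>C"))

  # intergenic cluster of T>C calls resolves to the minus strand as one unit
  rows <- purrr::map(1:10, function(i) list("chr1", 5000 + 50 * i, "T", 0, 3, 0, 7))
  pc <- do.call(mk_pileup, rows)
  vc <- resolve_strand(call_rdd(pc), gm)
  expect_true(all(vc$strand == "-"))
  expect_true(all(vc$sub == "A>G"))
})

test_that("recoding annotation reproduces the genetic code consequences", {
  fx <- micro_fixture()
  # g1 CDS (+) frame starts at genomic 100: codons TAT | CGA | TAA
  p <- mk_pileup(
    list("chr1", 102, "A", 7, 0, 3, 0),  # TAT pos2 -> TGT: Tyr -> Cys
    list("chr1", 106, "A", 7, 0, 3, 0),  # CGA pos3 -> CGG: Arg -> Arg
    list("chr1", 108, "A", 7, 0, 3, 0))  # TAA pos2 -> TGA: stop retained
  v <- call_editome(p, fx$gm, fx$genome, snps = tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character()))
  v <- dplyr::arrange(v, pos)
  expect_equal(v$category, rep("CDS", 3))
  expect_equal(v$codon_ref, c("TAT", "CGA", "TAA"))
  expect_equal(v$codon_alt, c("TGT", "CGG", "TGA"))
  expect_equal(v$coding_effect, c("nonsynonymous", "synonymous", "synonymous"))
})

test_that("recoding works through minus-strand genes", {
  fx <- micro_fixture()
  # find a genomic T inside g2 (minus strand CDS [400, 490)) whose codon we
  # can predict: transcript base A at that position
  tpos <- which(fx$chars[401:490] == "T") + 400L
  skip_if(length(tpos) == 0L)
  pos <- tpos[1]
  p <- mk_pileup(list("chr1", pos, "T", 0, 3, 0, 7))
  v <- call_editome(p, fx$gm, fx$genome, snps = tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character()))
  expect_equal(v$strand, "-")
  expect_equal(v$sub, "A>G")
  expect_equal(v$category, "CDS")
  # oracle: build the transcript CDS, edit it, translate both
  cds <- paste0(rev(unname(dietshift:::COMPLEMENT[fx$chars[401:490]])), collapse = "")
  offset <- 490L - pos  # 0-based offset in transcript orientation
  edited <- cds
  substr(edited, offset + 1L, offset + 1L) <- "G"
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                               no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(edited),
                                               no.init.codon = TRUE))
  codon_i <- offset %/% 3L
  ref_aa <- substr(aa_ref, codon_i + 1L, codon_i + 1L)
  alt_aa <- substr(aa_alt, codon_i + 1L, codon_i + 1L)
  expected <- if (ref_aa == alt_aa) "synonymous"
              else if (alt_aa == "*") "stop_gain"
              else if (ref_aa == "*") "stop_loss"
              else "nonsynonymous"
  expect_equal(v$coding_effect, expected)
})

test_that("editome summary fractions are complete and closed", {
  fx <- micro_fixture()
  p <- mk_pileup(list("chr1", 102, "A", 7, 0, 3, 0),
                 list("chr1", 106, "A", 7, 0, 3, 0))
  v <- call_editome(p, fx$gm, fx$genome, snps = tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character()))
  s <- summarize_editome(v)
  expect_equal(sum(s$substitutions$fraction), 1)
  expect_equal(glance(s)$atog_fraction, 1)
  expect_error(summarize_editome(v[0, ]), "empty")
})

test_that("per-gene editing enrichment conserves Fisher margins", {
  sim <- get_small_sim()
  res <- call_editome(sim$pileup, sim$gene_models, sim$genome, sim$snps)
  cls <- og_classify(sim$og_counts, "focal", "rel1", "rel2")
  gcl <- gene_class_table(
    dplyr::semi_join(sim$og_membership, sim$truth$genes, by = "gene_id"),
    cls, flag_diet_genes(sim$domains))
  ge <- gene_editing_enrichment(res, gcl)
  expect_equal(sum(ge$summary$n_genes), nrow(gcl))
  for (i in seq_len(nrow(ge$fisher))) {
    f <- ge$fisher[i, ]
    s <- dplyr::filter(ge$summary, class == f$class)
    expect_equal(f$n11 + f$n12, s$n_genes[s$diet])
    expect_equal(f$n21 + f$n22, s$n_genes[!s$diet])
  }
  # no sites: fractions zero, tests skipped
  ge0 <- gene_editing_enrichment(res[0, ], gcl)
  expect_true(all(ge0$summary$fraction_edited == 0))
  expect_equal(nrow(ge0$fisher), 0L)
})

test_that("upstream region flagging is strand-aware and distance-capped", {
  gm <- gene_models(tibble::tibble(
    gene_id = c("up", "g"), transcript_id = c("up.t", "g.t"), type = "exon",
    chrom = "chr1", start = c(1000L, 10000L), end = c(2000L, 11000L),
    strand = "+"))
  gcl <- tibble::tibble(gene_id = c("up", "g"), og_id = "A",
                        category = "focal_unique", class = "class1",
                        diet = c(TRUE, FALSE))
  site_up <- tibble::tibble(chrom = "chr1", pos = 9900L, category = "intergenic")
  site_down <- tibble::tibble(chrom = "chr1", pos = 10050L, category = "intergenic")
  up1 <- upstream_edited_enrichment(site_up, gm, gcl)
  expect_true(up1$genes$upstream_edited[up1$genes$gene_id == "g"])
  up2 <- upstream_edited_enrichment(site_down, gm, gcl)
  expect_false(up2$genes$upstream_edited[up2$genes$gene_id == "g"])
  # beyond the window: not flagged (TSS - 5000 < 4000 < site impossible here);
  # cap the window instead
  up3 <- upstream_edited_enrichment(site_up, gm, gcl, window = 50)
  expect_false(up3$genes$upstream_edited[up3$genes$gene_id == "g"])
})

test_that("repeat-overlap enrichment handles boundary tables with sentinels", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 110L),
                          category = c("intergenic", "intergenic", "CDS"))
  reps <- tibble::tibble(chrom = "chr1", start = 0L, end = 50L)
  ro <- repeat_overlap_enrichment(sites, reps)
  inter <- ro[ro$category == "intergenic", ]
  expect_equal(inter$fraction_in_repeat, 1)
  expect_true(is.infinite(inter$odds_ratio))
  expect_true(all(ro$n11 + ro$n12 + ro$n21 + ro$n22 == 3L))
})

test_that("r-squared is 1 for perfectly co-occurring alleles and ~0 under independence", {
  obs_perfect <- purrr::map(1:12, function(i) {
    allele <- if (i <= 6) "alt" else "ref"
    tibble::tibble(read_id = paste0("r", i), chrom = "chr1",
                   pos = c(10L, 20L), allele = allele)
  }) |> purrr::list_rbind()
  labels <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L),
                           type = "snp")
  suppressWarnings(res <- ld_contrast(obs_perfect, labels, min_reads = 10))
  expect_equal(res$pairs$r2, 1)

  set.seed(61)
  obs_ind <- purrr::map(1:600, function(i) {
    tibble::tibble(read_id = paste0("q", i), chrom = "chr1",
                   pos = c(110L, 120L),
                   allele = sample(c("ref", "alt"), 2, replace = TRUE))
  }) |> purrr::list_rbind()
  labels2 <- tibble::tibble(chrom = "chr1", pos = c(110L, 120L), type = "editing")
  suppressWarnings(res2 <- ld_contrast(obs_ind, labels2, min_reads = 10))
  expect_lt(res2$pairs$r2, 0.05)   # Monte-Carlo: r2 ~ 1/n under independence

  suppressWarnings(res3 <- ld_contrast(obs_perfect[0, ], labels))
  expect_true(is.na(res3$p_value))
})

test_that("filter chain is monotone and fully logged on simulated data", {
  sim <- get_small_sim()
  res <- call_editome(sim$pileup, sim$gene_models, sim$genome, sim$snps)
  log <- stage_log(res)
  expect_equal(log$stage, c("call_rdd", "exclude_snps", "mask_bidirectional",
                            "resolve_strand", "annotate_sites"))
  expect_true(all(log$n_out <= log$n_in))
  expect_equal(log$n_in[-1], log$n_out[-nrow(log)])
  expect_true(all(res$level >= 0 & res$level <= 1))
  expect_equal(res$level, res$alt_reads / res$depth)
  # every emitted coding effect belongs to a CDS site and vice versa
  expect_identical(!is.na(res$coding_effect), res$category == "CDS")
})
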