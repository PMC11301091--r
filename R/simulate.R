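# Planted-truth simulator.
#
# Generates every input the pipeline consumes — toy genomes, gene models
# with exon/intron/UTR structure and overlapping opposite-strand pairs,
# repeat tracks, three-species and panel OG count matrices, genomic SNPs,
# A-to-I editing sites with realistic level/depth laws, site pileups,
# read-level allele co-observations and per-gene expression counts —
# together with truth tables that record exactly what was planted.  All
# randomness flows from one seed; the same seed gives identical output.
#
# Default laws (see the methods vignette for rationale):
#   * editing levels: CDS Beta(1, 3) (low, as recoding sites are), other
#     genic Beta(2, 2), intergenic hyper-editing Beta(3, 1) (high);
#   * site depth: Poisson(30) genic, Poisson(8) for intergenic clusters —
#     so CDS sites have the highest coverage and the lowest level;
#   * intergenic editing is planted in clusters of ~10 sites inside repeats;
#   * 97% of planted substitutions are A-to-G on the transcript strand.

#' Simulation configuration
#'
#' Builds and validates the parameter set of [simulate_dataset()].  All
#' fractions are in \[0, 1\]; category proportions must sum to 1.
#'
#' @param seed Integer master seed; fixed seed implies identical output.
#' @param n_chroms,chrom_len Number and length (bp) of toy chromosomes.
#' @param n_genes Number of primary genes laid out on the genome.
#' @param n_ogs Number of ortho-groups in the three-species table.
#' @param og_proportions Named fractions (`unique`, `more`, `gradient`,
#'   `other`) of planted OG categories; defaults mirror the relative
#'   category sizes of a three-species true-bug comparison.
#' @param diet_fraction Named per-category fractions of diet-flagged OGs.
#' @param n_editing_sites,n_snps,n_contaminant_snps Planted counts; the
#'   contaminant SNPs are genomic SNPs that surface in the pileup as A>G
#'   calls, giving the SNP-exclusion filter true positives.
#' @param target_AtoG_fraction Fraction of planted editing sites that are
#'   A-to-G on the transcript strand (default 0.97).
#' @param site_category_fractions Named fractions (`CDS`, `UTR`, `intron`,
#'   `intergenic`) of planted editing sites.
#' @param cds_level_shape,genic_level_shape,intergenic_level_shape
#'   `c(alpha, beta)` of the Beta editing-level law per compartment.
#' @param depth_genic_mean,depth_intergenic_mean Poisson depth means.
#' @param base_miscall_rate Flat per-base sequencing miscall rate.
#' @param cluster_size,cluster_span Sites per intergenic hyper-editing
#'   cluster and the span (bp) they occupy.
#' @param fraction_bidirectional_genes Fraction of genes given an
#'   overlapping opposite-strand partner; editing planted inside the
#'   overlap is flagged unrecoverable truth.
#' @param n_bidirectional_sites Editing sites planted inside bidirectional
#'   regions (all must be removed by masking).
#' @param editing_diet_propensity Multiplier on the genic editing rate of
#'   diet genes.
#' @param upstream_bias_fraction Fraction of class1 diet genes given an
#'   upstream intergenic editing cluster (class2 genes get only the
#'   baseline rate).
#' @param utr_gene_fraction Fraction of genes annotated with UTRs.
#' @param expression_diet_effect Multiplier on diet-gene expression rate.
#' @param n_panel_ogs,n_panel_expanded Panel size and number of
#'   diet-flagged (expanded) OGs in the 33-species panel.
#' @param n_predaceous,n_phytophagous Panel group sizes (plus one
#'   outgroup species).
#' @param predaceous_effect Multiplicative expansion of diet-OG counts in
#'   predaceous species (>= 1; 1 = null panel).
#' @param panel_lambda_shape,panel_lambda_rate Gamma law of per-OG mean
#'   gene counts in the panel.
#' @param n_background_sites Reference-matching pileup positions.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 42,
                       n_chroms = 2, chrom_len = 1.6e6, n_genes = 400,
                       n_ogs = 2000,
                       og_proportions = c(unique = 0.008, more = 0.008,
                                          gradient = 0.0025, other = 0.9815),
                       diet_fraction = c(unique = 0.133, more = 0.148,
                                         gradient = 0.02, other = 0.042),
                       n_editing_sites = 2000, n_snps = 500,
                       n_contaminant_snps = 50,
                       target_AtoG_fraction = 0.97,
                       site_category_fractions = c(CDS = 0.02, UTR = 0.08,
                                                   intron = 0.30, intergenic = 0.60),
                       cds_level_shape = c(1, 3),
                       genic_level_shape = c(2, 2),
                       intergenic_level_shape = c(3, 1),
                       depth_genic_mean = 30, depth_intergenic_mean = 8,
                       base_miscall_rate = 0.001,
                       cluster_size = 10, cluster_span = 600,
                       fraction_bidirectional_genes = 0.05,
                       n_bidirectional_sites = 40,
                       editing_diet_propensity = 2,
                       upstream_bias_fraction = 0.8,
                       utr_gene_fraction = 0.7,
                       expression_diet_effect = 2,
                       n_panel_ogs = 200, n_panel_expanded = 47,
                       n_predaceous = 5, n_phytophagous = 28,
                       predaceous_effect = 4,
                       panel_lambda_shape = 4, panel_lambda_rate = 0.8,
                       n_background_sites = 2000) {
  cfg <- as.list(environment())
  fracs <- c(cfg$og_proportions, cfg$diet_fraction, cfg$target_AtoG_fraction,
             cfg$site_category_fractions, cfg$fraction_bidirectional_genes,
             cfg$upstream_bias_fraction, cfg$utr_gene_fraction,
             cfg$base_miscall_rate)
  if (any(fracs < 0 | fracs > 1)) abort("sim_config(): fractions must be in [0, 1].")
  if (abs(sum(cfg$og_proportions) - 1) > 1e-9) {
    abort("sim_config(): og_proportions must sum to 1.")
  }
  if (abs(sum(cfg$site_category_fractions) - 1) > 1e-9) {
    abort("sim_config(): site_category_fractions must sum to 1.")
  }
  if (cfg$predaceous_effect < 1) abort("sim_config(): predaceous_effect must be >= 1.")
  genome_len <- cfg$n_chroms * cfg$chrom_len
  if (cfg$n_genes * 7500 > 0.95 * genome_len) {
    abort("sim_config(): infeasible — genome too short for n_genes.")
  }
  if (cfg$n_editing_sites + cfg$n_snps > 0.1 * genome_len) {
    abort("sim_config(): infeasible — more planted sites than the genome can hold.")
  }
  structure(cfg, class = "sim_config")
}

# ---- internal generation helpers -------------------------------------------

# one gene's features starting at `cursor`; returns list(features, end)
sim_one_gene <- function(gene_id, chrom, strand, cursor, has_utr) {
  n_exons <- min(1L + rpois(1L, 6), 12L)
  exon_len <- sample(150:300, n_exons, replace = TRUE)
  intron_len <- if (n_exons > 1L) sample(100:400, n_exons - 1L, replace = TRUE) else integer(0)
  starts <- cursor + cumsum(c(0L, head(exon_len, -1L) + intron_len))
  ends <- starts + exon_len
  tx_id <- paste0(gene_id, ".t1")

  # UTR trimming in transcript orientation; CDS length forced to 3k
  total <- sum(exon_len)
  if (has_utr) {
    u5 <- sample(60:min(140, exon_len[1] - 10L), 1L)
    u3 <- sample(60:min(140, exon_len[n_exons] - 10L), 1L)
  } else {
    u5 <- 0L; u3 <- 0L
  }
  cds_len <- total - u5 - u3
  u3 <- u3 + cds_len %% 3L  # absorb the frame remainder into the 3' trim
  lo <- if (strand == "+") u5 else u3   # bases trimmed at the genomic low end
  hi <- if (strand == "+") u3 else u5

  cds <- tibble(start = starts, end = ends)
  cds$start[1] <- cds$start[1] + lo
  cds$end[n_exons] <- cds$end[n_exons] - hi
  feats <- bind_rows(
    tibble(type = "exon", start = starts, end = ends),
    tibble(type = "CDS", start = cds$start, end = cds$end)
  )
  if (has_utr && lo > 0L) {
    feats <- bind_rows(feats, tibble(
      type = if (strand == "+") "five_prime_UTR" else "three_prime_UTR",
      start = starts[1], end = starts[1] + lo))
  }
  if (has_utr && hi > 0L) {
    feats <- bind_rows(feats, tibble(
      type = if (strand == "+") "three_prime_UTR" else "five_prime_UTR",
      start = ends[n_exons] - hi, end = ends[n_exons]))
  }
  feats <- mutate(feats, gene_id = gene_id, transcript_id = tx_id,
                  chrom = chrom, strand = strand)

  # extra isoforms: contiguous exon subsets, annotation only (no CDS)
  n_tx <- 1L + rpois(1L, n_exons / 5)
  if (n_tx > 1L && n_exons > 1L) {
    for (k in seq_len(n_tx - 1L)) {
      keep_n <- sample(seq_len(n_exons - 1L), 1L)
      first <- sample(seq_len(n_exons - keep_n + 1L), 1L)
      idx <- first:(first + keep_n - 1L)
      feats <- bind_rows(feats, tibble(
        type = "exon", start = starts[idx], end = ends[idx],
        gene_id = gene_id, transcript_id = paste0(gene_id, ".t", k + 1L),
        chrom = chrom, strand = strand))
    }
  }
  list(features = feats, end = ends[n_exons])
}

# positions (1-based) of `base` within [start, end) of a split chromosome
base_positions <- function(chars, base, start, end) {
  idx <- (start + 1L):end
  idx[chars[idx] == base]
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# ---- main entry -------------------------------------------------------------

#' Simulate a full pipeline input bundle with planted truth
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_data` holding every pipeline input as a
#'   tibble (`genome`, `gene_models`, `repeats`, `og_counts`,
#'   `og_membership`, `domains`, `snps`, `pileup`, `read_obs`,
#'   `expression`, `panel`, `panel_labels`, `panel_tree`) plus `truth`, a
#'   list of truth tables (`og`, `genes`, `editing`, `snps`, `ld_sites`,
#'   `panel`), and the `config`.  Use [write_sim_data()] to materialize the
#'   bundle as files.
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)

  # ---- genome ---------------------------------------------------------------
  chrom_ids <- paste0("chr", seq_len(cfg$n_chroms))
  sequences <- vapply(chrom_ids, function(i) {
    paste0(sample(BASES, cfg$chrom_len, replace = TRUE), collapse = "")
  }, character(1))
  genome <- tibble(chrom = chrom_ids, sequence = unname(sequences),
                   length = nchar(unname(sequences)))
  chars <- lapply(genome$sequence, function(s) strsplit(s, "")[[1]])
  names(chars) <- chrom_ids

  # ---- ortho-group count table ---------------------------------------------
  n_cat <- round(cfg$n_ogs * cfg$og_proportions)
  n_cat["other"] <- cfg$n_ogs - sum(n_cat[c("unique", "more", "gradient")])
  draw_counts <- function(category, n) {
    if (n == 0L) return(tibble(focal = integer(), rel1 = integer(), rel2 = integer()))
    switch(category,
      unique = tibble(focal = 3L + rpois(n, 2), rel1 = 0L, rel2 = 0L),
      more = {
        mx <- 1L + rpois(n, 2)
        lo <- rpois(n, 1)
        rel1_first <- runif(n) < 0.5
        tibble(focal = 2L * mx + 1L + rpois(n, 2),
               rel1 = ifelse(rel1_first, mx, pmin(lo, mx)),
               rel2 = ifelse(rel1_first, pmin(lo, mx), mx))
      },
      gradient = {
        rel1 <- 4L + rpois(n, 2)
        rel2 <- vapply(rel1, function(l) sample_one(0:floor((l - 1) / 1.5)), numeric(1))
        focal <- vapply(rel1, function(l) sample_one((floor(1.5 * l) + 1L):(2L * l)), numeric(1))
        tibble(focal = as.integer(focal), rel1 = rel1, rel2 = as.integer(rel2))
      },
      other = {
        out <- tibble(focal = integer(n), rel1 = integer(n), rel2 = integer(n))
        filled <- 0L
        while (filled < n) {
          m <- (n - filled) * 2L
          cand <- tibble(focal = rpois(m, 3), rel1 = rpois(m, 3), rel2 = rpois(m, 3))
          cat <- og_classify(mutate(cand, og_id = as.character(seq_len(m))),
                             "focal", "rel1", "rel2")$category
          ok <- cand[cat == "other", , drop = FALSE]
          take <- min(nrow(ok), n - filled)
          if (take > 0L) {
            out[(filled + 1L):(filled + take), ] <- ok[seq_len(take), ]
            filled <- filled + take
          }
        }
        out
      })
  }
  og_rows <- purrr::imap(c(unique = "focal_unique", more = "focal_more",
                           gradient = "gradient", other = "other"),
                         function(catname, key) {
    n <- n_cat[[key]]
    cnt <- draw_counts(key, n)
    n_diet <- round(n * cfg$diet_fraction[[key]])
    mutate(cnt, category = catname,
           diet = seq_len(n) <= n_diet)
  }) |> list_rbind()
  og_rows <- og_rows[sample(nrow(og_rows)), ]  # shuffle row order
  og_rows <- mutate(og_rows,
                    og_id = sprintf("OG%06d", seq_len(nrow(og_rows))),
                    class = ifelse(.data$category %in% c("focal_unique", "focal_more"),
                                   "class1", "class2"))
  og_counts <- select(og_rows, "og_id", "focal", "rel1", "rel2")
  og_truth <- select(og_rows, "og_id", "category", "class", "diet")

  # ---- gene layout ----------------------------------------------------------
  feats_list <- list()
  gene_meta <- list()
  gi <- 0L
  for (ci in seq_along(chrom_ids)) {
    cursor <- sample(800:2000, 1L)
    while (gi < cfg$n_genes && cursor < cfg$chrom_len - 6000L) {
      gi <- gi + 1L
      id <- sprintf("g%04d", gi)
      strand <- sample(c("+", "-"), 1L)
      g <- sim_one_gene(id, chrom_ids[ci], strand, cursor,
                        has_utr = runif(1) < cfg$utr_gene_fraction)
      feats_list[[gi]] <- g$features
      gene_meta[[gi]] <- tibble(gene_id = id, chrom = chrom_ids[ci],
                                start = cursor, end = g$end, strand = strand,
                                partner = FALSE)
      cursor <- g$end + sample(2800L:4500L, 1L)
    }
    if (gi >= cfg$n_genes) break
  }
  genes <- list_rbind(gene_meta)
  n_primary <- nrow(genes)

  # overlapping opposite-strand partners -> bidirectional regions
  n_partner <- round(n_primary * cfg$fraction_bidirectional_genes)
  partner_hosts <- sample(seq_len(n_primary), n_partner)
  for (k in seq_along(partner_hosts)) {
    host <- genes[partner_hosts[k], ]
    gi <- gi + 1L
    id <- sprintf("g%04d", gi)
    p_len <- 900L
    p_start <- max(host$end - 600L, host$start)
    p_strand <- if (host$strand == "+") "-" else "+"
    feats_list[[gi]] <- tibble(
      type = c("exon", "CDS"), start = p_start, end = p_start + p_len,
      gene_id = id, transcript_id = paste0(id, ".t1"),
      chrom = host$chrom, strand = p_strand)
    gene_meta[[gi]] <- tibble(gene_id = id, chrom = host$chrom,
                              start = p_start, end = p_start + p_len,
                              strand = p_strand, partner = TRUE)
  }
  genes <- list_rbind(gene_meta)
  gm <- gene_models(list_rbind(feats_list)[, c("gene_id", "transcript_id", "type",
                                               "chrom", "start", "end", "strand")])
  bidir <- bidirectional_regions(gm)

  # ---- gene -> OG assignment ------------------------------------------------
  class1_ogs <- filter(og_rows, .data$class == "class1")
  class2_ogs <- filter(og_rows, .data$class == "class2", .data$focal > 0L)
  slots <- bind_rows(
    class1_ogs |> select("og_id", "focal", "diet", "class"),
    class2_ogs[sample(nrow(class2_ogs)), ] |> select("og_id", "focal", "diet", "class")
  )
  slot_tbl <- slots[rep(seq_len(nrow(slots)), slots$focal), ] |> head(nrow(genes))
  if (nrow(slot_tbl) < nrow(genes)) {
    abort("simulate_dataset(): not enough focal OG slots for the genes; increase n_ogs.")
  }
  gene_truth <- genes |>
    mutate(og_id = slot_tbl$og_id, diet = slot_tbl$diet, class = slot_tbl$class) |>
    select("gene_id", "og_id", "class", "diet", "chrom", "start", "end", "strand",
           "partner")

  # ---- full OG membership and domain table ---------------------------------
  real_by_og <- gene_truth |> group_by(.data$og_id) |>
    summarise(real = list(.data$gene_id), .groups = "drop")
  membership <- og_rows |>
    left_join(real_by_og, by = "og_id") |>
    pmap(function(og_id, focal, rel1, rel2, diet, real = NULL, ...) {
      real <- if (is.null(real)) character(0) else real
      n_virtual_focal <- max(focal - length(real), 0L)
      species <- c(rep("focal", length(real) + n_virtual_focal),
                   rep("rel1", rel1), rep("rel2", rel2))
      gene_id <- c(real,
                   if (n_virtual_focal > 0L) paste0(og_id, "_focal_", seq_len(n_virtual_focal)) else character(0),
                   if (rel1 > 0L) paste0(og_id, "_rel1_", seq_len(rel1)) else character(0),
                   if (rel2 > 0L) paste0(og_id, "_rel2_", seq_len(rel2)) else character(0))
      tibble(og_id = og_id, species = species, gene_id = gene_id)
    }) |> list_rbind()
  catalog_acc <- diet_catalog()$accession
  diet_by_og <- setNames(og_rows$diet, og_rows$og_id)
  domains <- membership |>
    mutate(diet = unname(diet_by_og[.data$og_id]),
           accession = ifelse(.data$diet,
                              sample(catalog_acc, n(), replace = TRUE),
                              sprintf("PF9%04d", sample(0:9999, n(), replace = TRUE)))) |>
    select("gene_id", "accession")

  # ---- repeats --------------------------------------------------------------
  # upstream repeat for every primary gene (hosting potential upstream
  # clusters) plus random intergenic repeats
  spans <- gene_spans(gm)
  upstream_rep <- genes |>
    filter(!.data$partner) |>
    transmute(gene_id = .data$gene_id, chrom = .data$chrom,
              start = ifelse(.data$strand == "+", .data$start - 900L, .data$end + 150L)) |>
    mutate(end = .data$start + 750L, kind = "upstream") |>
    filter(.data$start > 0L, .data$end < cfg$chrom_len)
  n_rand_cand <- 400L
  rand_cand <- tibble(
    chrom = sample(chrom_ids, n_rand_cand, replace = TRUE),
    start = as.integer(runif(n_rand_cand, 0, cfg$chrom_len - 2000L))
  ) |>
    mutate(end = .data$start + as.integer(runif(n_rand_cand, 400L, 1200L)),
           kind = "random", gene_id = NA_character_)
  pad <- function(x, by = 1000L) mutate(x, start = pmax(.data$start - by, 0L), end = .data$end + by)
  clash <- pos_in_intervals(rand_cand$chrom, rand_cand$start,
                            pad(bind_rows(select(spans, "chrom", "start", "end"),
                                          select(upstream_rep, "chrom", "start", "end")))) |
           pos_in_intervals(rand_cand$chrom, rand_cand$end,
                            pad(bind_rows(select(spans, "chrom", "start", "end"),
                                          select(upstream_rep, "chrom", "start", "end"))))
  rand_rep <- rand_cand[!clash, , drop = FALSE] |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    filter(c(TRUE, diff(.data$start) > 2500L)) |>
    ungroup()
  repeats_all <- bind_rows(upstream_rep, rand_rep)
  repeats <- select(repeats_all, "chrom", "start", "end") |>
    arrange(.data$chrom, .data$start)

  # occupied positions per chromosome, kept as growing integer sets (cheap
  # membership tests against the small candidate vectors)
  used <- new.env()
  for (ch in chrom_ids) assign(ch, integer(0), envir = used)
  claim <- function(ch, pos) {
    assign(ch, c(get(ch, envir = used), pos), envir = used)
    invisible(TRUE)
  }
  is_free <- function(ch, pos) !(pos %in% get(ch, envir = used))
  drop_used <- function(ch, cand) cand[!(cand %in% get(ch, envir = used))]

  # ---- editing sites --------------------------------------------------------
  draw_sub <- function(n) {
    ifelse(runif(n) < cfg$target_AtoG_fraction, "A>G",
           sample(setdiff(SUBSTITUTION_TYPES, "A>G"), n, replace = TRUE))
  }
  region_by_type <- function(gene_ids, type) {
    f <- as_tibble(gm) |> filter(.data$gene_id %in% gene_ids)
    if (type == "CDS") f |> filter(.data$type == "CDS")
    else if (type == "UTR") f |> filter(.data$type %in% c("five_prime_UTR", "three_prime_UTR"))
    else {  # intron: gaps between the distinct exon intervals of each gene
      f |> filter(.data$type == "exon") |>
        group_by(.data$gene_id) |>
        reframe({
          es <- sort(unique(.data$start)); ee <- sort(unique(.data$end))
          ch <- .data$chrom[1]; st <- .data$strand[1]
          tibble(chrom = ch, strand = st, start = head(ee, -1L), end = es[-1])
        }) |>
        filter(.data$start < .data$end)
    }
  }
  # per-chromosome masks avoid interval queries in the planting loops
  mask_from <- function(intervals) {
    m <- lapply(setNames(chrom_ids, chrom_ids), function(ch) logical(cfg$chrom_len))
    for (i in seq_len(nrow(intervals))) {
      m[[intervals$chrom[i]]][(intervals$start[i] + 1L):intervals$end[i]] <- TRUE
    }
    m
  }
  bidir_mask <- mask_from(bidir)
  genic_mask <- mask_from(select(spans, "chrom", "start", "end"))

  plant_genic <- function(n, type) {
    if (n == 0L) return(NULL)
    host <- gene_truth |> filter(!.data$partner)
    if (type %in% c("CDS", "UTR")) {
      canon <- canonical_transcripts(gm)
      reg <- region_by_type(host$gene_id, type)
      if (type == "CDS") reg <- semi_join(reg, canon, by = "transcript_id")
    } else {
      reg <- region_by_type(host$gene_id, "intron")
    }
    reg <- reg |> left_join(select(gene_truth, "gene_id", "diet"), by = "gene_id") |>
      mutate(w = (.data$end - .data$start) *
               ifelse(.data$diet, cfg$editing_diet_propensity, 1))
    if (nrow(reg) == 0L) return(NULL)
    subs <- draw_sub(n)
    acc_chrom <- character(n); acc_pos <- integer(n)
    acc_strand <- character(n); acc_gene <- character(n)
    ok <- logical(n)
    for (i in seq_len(n)) {
      for (attempt in 1:50) {
        r <- reg[sample.int(nrow(reg), 1L, prob = reg$w), ]
        g_strand <- r$strand
        ref_tx <- substr(subs[i], 1L, 1L)
        ref_genome <- if (g_strand == "-") complement_base(ref_tx) else ref_tx
        cand <- base_positions(chars[[r$chrom]], ref_genome, r$start, r$end)
        cand <- cand[!bidir_mask[[r$chrom]][cand]]
        cand <- drop_used(r$chrom, cand)
        if (length(cand) == 0L) next
        p <- sample_one(cand)
        claim(r$chrom, p)
        acc_chrom[i] <- r$chrom; acc_pos[i] <- p
        acc_strand[i] <- g_strand; acc_gene[i] <- r$gene_id
        ok[i] <- TRUE
        break
      }
    }
    tibble(chrom = acc_chrom[ok], pos = acc_pos[ok], strand = acc_strand[ok],
           sub = subs[ok], category = type, gene_id = acc_gene[ok],
           bidirectional = FALSE)
  }

  plant_cluster <- function(region, strand, n_sites, category = "intergenic",
                            gene_id = NA_character_, bidirectional = FALSE) {
    subs <- draw_sub(n_sites)
    ref_tx <- substr(subs, 1L, 1L)
    ref_genome <- if (strand == "-") complement_base(ref_tx) else ref_tx
    acc_pos <- integer(n_sites); ok <- logical(n_sites)
    for (i in seq_len(n_sites)) {
      cand <- base_positions(chars[[region$chrom]], ref_genome[i],
                             region$start, region$end)
      cand <- drop_used(region$chrom, cand)
      if (length(cand) == 0L) next
      p <- sample_one(cand)
      claim(region$chrom, p)
      acc_pos[i] <- p; ok[i] <- TRUE
    }
    tibble(chrom = region$chrom, pos = acc_pos[ok], strand = strand,
           sub = subs[ok], category = category, gene_id = gene_id,
           bidirectional = bidirectional)
  }

  n_site <- round(cfg$n_editing_sites * cfg$site_category_fractions)
  n_site["intergenic"] <- cfg$n_editing_sites - sum(n_site[c("CDS", "UTR", "intron")])
  sites <- list(
    plant_genic(n_site[["CDS"]], "CDS"),
    plant_genic(n_site[["UTR"]], "UTR"),
    plant_genic(n_site[["intron"]], "intron")
  )

  # intergenic clusters: biased upstream of class1 diet genes, baseline
  # upstream of other genes, remainder in random intergenic repeats
  if (n_site[["intergenic"]] > 0L) {
    n_clusters <- ceiling(n_site[["intergenic"]] / cfg$cluster_size)
    c1_diet <- gene_truth |> filter(.data$class == "class1", .data$diet, !.data$partner)
    biased <- c1_diet[runif(nrow(c1_diet)) < cfg$upstream_bias_fraction, ]
    baseline_pool <- gene_truth |>
      filter(!.data$partner, !(.data$gene_id %in% biased$gene_id))
    n_baseline <- min(round(0.08 * nrow(baseline_pool)),
                      max(n_clusters - nrow(biased), 0L))
    baseline <- baseline_pool[sample.int(nrow(baseline_pool), n_baseline), ]
    cluster_genes <- bind_rows(biased, baseline)
    gene_strands <- setNames(genes$strand, genes$gene_id)
    cluster_regions <- upstream_rep |>
      semi_join(cluster_genes, by = "gene_id") |>
      mutate(strand = unname(gene_strands[.data$gene_id])) |>
      select("chrom", "start", "end", "strand")
    rr <- rand_rep[sample.int(nrow(rand_rep)), ] |>
      mutate(strand = sample(c("+", "-"), n(), replace = TRUE)) |>
      select("chrom", "start", "end", "strand")
    cluster_regions <- bind_rows(cluster_regions, rr)
    remaining <- n_site[["intergenic"]]
    for (r in seq_len(nrow(cluster_regions))) {
      take <- min(cfg$cluster_size, remaining)
      if (take == 0L) break
      region <- cluster_regions[r, ]
      strand <- region$strand
      planted <- plant_cluster(region, strand, take)
      if (nrow(planted) > 0L) {
        # drop any that fell inside a gene span or bidirectional region
        inside <- vapply(seq_len(nrow(planted)),
                         function(i) genic_mask[[planted$chrom[i]]][planted$pos[i]],
                         logical(1))
        planted <- planted[!inside, , drop = FALSE]
        sites <- c(sites, list(planted))
        remaining <- remaining - nrow(planted)
      }
    }
  }

  # bidirectional-region sites (unrecoverable by construction)
  if (cfg$n_bidirectional_sites > 0L && nrow(bidir) > 0L) {
    per <- ceiling(cfg$n_bidirectional_sites / nrow(bidir))
    planted_b <- 0L
    for (r in sample(seq_len(nrow(bidir)))) {
      take <- min(per, cfg$n_bidirectional_sites - planted_b)
      if (take == 0L) break
      pb <- plant_cluster(bidir[r, ], "+", take, category = "bidirectional",
                          bidirectional = TRUE)
      if (!is.null(pb)) { sites <- c(sites, list(pb)); planted_b <- planted_b + nrow(pb) }
    }
  }
  editing <- list_rbind(purrr::compact(sites))
  if (nrow(editing) > 0L) {
    editing <- editing |>
      mutate(level = dplyr::case_when(
               .data$category == "CDS" ~ rbeta(n(), cfg$cds_level_shape[1], cfg$cds_level_shape[2]),
               .data$category %in% c("UTR", "intron") ~
                 rbeta(n(), cfg$genic_level_shape[1], cfg$genic_level_shape[2]),
               TRUE ~ rbeta(n(), cfg$intergenic_level_shape[1], cfg$intergenic_level_shape[2])),
             depth = rpois(n(), ifelse(.data$category %in% c("CDS", "UTR", "intron"),
                                       cfg$depth_genic_mean, cfg$depth_intergenic_mean)))
  } else {
    editing <- tibble(chrom = character(), pos = integer(), strand = character(),
                      sub = character(), category = character(),
                      gene_id = character(), bidirectional = logical(),
                      level = double(), depth = integer())
  }

  # ---- SNPs -----------------------------------------------------------------
  exonic <- as_tibble(gm) |> filter(.data$type == "exon") |>
    semi_join(filter(gene_truth, !.data$partner), by = "gene_id")
  contaminants <- NULL
  if (cfg$n_contaminant_snps > 0L) {
    # nearby pairs inside exons of + genes: genomic A, alt G, het in RNA
    n_pairs <- ceiling(cfg$n_contaminant_snps / 2L)
    pool <- exonic |>
      left_join(select(gene_truth, "gene_id", g_strand = "strand"), by = "gene_id") |>
      filter(.data$g_strand == "+", .data$end - .data$start > 120L)
    picked <- list()
    for (k in seq_len(n_pairs)) {
      for (attempt in 1:50) {
        e <- pool[sample.int(nrow(pool), 1L), ]
        cand <- base_positions(chars[[e$chrom]], "A", e$start, e$end)
        cand <- drop_used(e$chrom, cand)
        if (length(cand) < 2L) next
        p1 <- sample_one(cand)
        near <- cand[abs(cand - p1) >= 10L & abs(cand - p1) <= 120L & cand != p1]
        if (length(near) == 0L) next
        p2 <- sample_one(near)
        claim(e$chrom, p1); claim(e$chrom, p2)
        picked[[k]] <- tibble(chrom = e$chrom, pos = c(p1, p2), pair = k)
        break
      }
    }
    contaminants <- list_rbind(purrr::compact(picked)) |>
      head(cfg$n_contaminant_snps) |>
      mutate(ref = "A", alt = "G", contaminant = TRUE,
             rna_level = 0.5, depth = rpois(n(), cfg$depth_genic_mean))
  }
  n_plain <- cfg$n_snps - (if (is.null(contaminants)) 0L else nrow(contaminants))
  plain <- tibble(chrom = sample(chrom_ids, n_plain * 2L, replace = TRUE),
                  pos = as.integer(runif(n_plain * 2L, 1, cfg$chrom_len))) |>
    distinct(.data$chrom, .data$pos) |>
    filter(vapply(seq_len(n()), function(i) is_free(chrom[i], pos[i]), logical(1))) |>
    head(n_plain)
  for (i in seq_len(nrow(plain))) claim(plain$chrom[i], plain$pos[i])
  plain <- plain |>
    mutate(ref = purrr::map2_chr(.data$chrom, .data$pos, ~ chars[[.x]][.y]),
           alt = vapply(.data$ref, function(r) sample_one(setdiff(BASES, r)), character(1)),
           contaminant = FALSE, rna_level = NA_real_, depth = NA_integer_)
  snps_truth <- bind_rows(contaminants %||null% NULL, plain) |>
    arrange(.data$chrom, .data$pos)
  snps <- select(snps_truth, "chrom", "pos", "ref", "alt")

  # ---- pileup ---------------------------------------------------------------
  # vectorized pileup assembly: alt reads ~ Binomial(depth, level) at the
  # planted allele, remaining reads show the reference with a flat miscall
  mk_counts <- function(chrom, pos, depth, alt_genome, alt_frac) {
    n <- length(pos)
    ref <- vapply(seq_len(n), function(i) chars[[chrom[i]]][pos[i]], character(1))
    n_alt <- rbinom(n, depth, alt_frac)
    n_ref <- depth - n_alt
    mis <- rbinom(n, n_ref, cfg$base_miscall_rate)
    counts <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
    counts[cbind(seq_len(n), match(ref, BASES))] <- n_ref - mis
    for (i in which(mis > 0L)) {
      wrong <- sample(setdiff(BASES, ref[i]), mis[i], replace = TRUE)
      for (w in wrong) counts[i, w] <- counts[i, w] + 1L
    }
    idx_alt <- cbind(seq_len(n), match(alt_genome, BASES))
    counts[idx_alt] <- counts[idx_alt] + n_alt
    tibble(chrom = chrom, pos = pos, ref = ref,
           nA = counts[, "A"], nC = counts[, "C"], nG = counts[, "G"], nT = counts[, "T"])
  }
  pile_rows <- list()
  if (nrow(editing) > 0L) {
    alt_tx <- substr(editing$sub, 3L, 3L)
    alt_genome <- ifelse(editing$strand == "-", complement_base(alt_tx), alt_tx)
    pile_rows <- c(pile_rows, list(mk_counts(editing$chrom, editing$pos,
                                             editing$depth, alt_genome, editing$level)))
  }
  if (!is.null(contaminants) && nrow(contaminants) > 0L) {
    pile_rows <- c(pile_rows, list(mk_counts(contaminants$chrom, contaminants$pos,
                                             contaminants$depth, rep("G", nrow(contaminants)),
                                             contaminants$rna_level)))
  }
  bg <- tibble(chrom = sample(chrom_ids, cfg$n_background_sites * 2L, replace = TRUE),
               pos = as.integer(runif(cfg$n_background_sites * 2L, 1, cfg$chrom_len))) |>
    distinct(.data$chrom, .data$pos) |>
    filter(vapply(seq_len(n()), function(i) is_free(chrom[i], pos[i]), logical(1))) |>
    head(cfg$n_background_sites)
  if (nrow(bg) > 0L) {
    pile_rows <- c(pile_rows, list(mk_counts(bg$chrom, bg$pos,
                                             rpois(nrow(bg), cfg$depth_genic_mean),
                                             rep("A", nrow(bg)), 0)))
  }
  pileup <- list_rbind(pile_rows) |>
    arrange(.data$chrom, .data$pos) |>
    mutate(depth = .data$nA + .data$nC + .data$nG + .data$nT)

  # ---- read-level co-observations for the LD contrast -----------------------
  read_rows <- list()
  ld_sites <- list()
  rid <- 0L
  n_reads_pair <- 30L
  if (!is.null(contaminants) && nrow(contaminants) > 0L) {
    pairs <- split(contaminants, contaminants$pair)
    for (pr in pairs) {
      if (nrow(pr) < 2L) next
      ld_sites[[length(ld_sites) + 1L]] <- tibble(chrom = pr$chrom, pos = pr$pos, type = "snp")
      hap <- runif(n_reads_pair) < 0.5
      for (j in seq_len(n_reads_pair)) {
        rid <- rid + 1L
        read_rows[[length(read_rows) + 1L]] <- tibble(
          read_id = sprintf("r%06d", rid), chrom = pr$chrom[1:2], pos = pr$pos[1:2],
          allele = if (hap[j]) c("alt", "alt") else c("ref", "ref"))
      }
    }
  }
  edit_inter <- editing |> filter(.data$category == "intergenic")
  if (nrow(edit_inter) >= 2L) {
    # adjacent same-cluster site pairs
    ei <- edit_inter |> arrange(.data$chrom, .data$pos)
    adj <- which(diff(ei$pos) <= 200 & ei$chrom[-1] == ei$chrom[-nrow(ei)])
    adj <- head(adj[seq_along(adj) %% 2L == 1L], 25L)
    for (a in adj) {
      pr <- ei[a:(a + 1L), ]
      ld_sites[[length(ld_sites) + 1L]] <- tibble(chrom = pr$chrom, pos = pr$pos, type = "editing")
      for (j in seq_len(n_reads_pair)) {
        rid <- rid + 1L
        read_rows[[length(read_rows) + 1L]] <- tibble(
          read_id = sprintf("r%06d", rid), chrom = pr$chrom, pos = pr$pos,
          allele = ifelse(runif(2L) < pr$level, "alt", "ref"))
      }
    }
  }
  read_obs <- if (length(read_rows) > 0L) list_rbind(read_rows) else
    tibble(read_id = character(), chrom = character(), pos = integer(), allele = character())
  ld_sites <- if (length(ld_sites) > 0L) distinct(list_rbind(ld_sites)) else
    tibble(chrom = character(), pos = integer(), type = character())

  # ---- expression -----------------------------------------------------------
  ex_len <- exon_union_length(gm)
  expression <- gene_truth |>
    left_join(ex_len, by = "gene_id") |>
    mutate(noise = exp(stats::rnorm(n(), 0, 0.5)),
           rate = .data$exon_union_len / 1000 * 50 * .data$noise *
             ifelse(.data$diet, cfg$expression_diet_effect, 1),
           exonic_reads = rpois(n(), .data$rate)) |>
    select("gene_id", "exonic_reads")

  # ---- cross-species panel --------------------------------------------------
  panel_sim <- simulate_panel(
    n_ogs = cfg$n_panel_ogs, n_expanded = cfg$n_panel_expanded,
    n_predaceous = cfg$n_predaceous, n_phytophagous = cfg$n_phytophagous,
    effect = cfg$predaceous_effect,
    lambda_shape = cfg$panel_lambda_shape, lambda_rate = cfg$panel_lambda_rate,
    seed = NULL)  # inherits the ambient RNG stream
  panel_tree <- ape::rtree(nrow(panel_sim$labels),
                           tip.label = sample(panel_sim$labels$species))

  structure(list(
    genome = genome, gene_models = gm, repeats = repeats,
    og_counts = og_counts, og_membership = select(membership, "og_id", "species", "gene_id"),
    domains = domains, snps = snps, pileup = pileup, read_obs = read_obs,
    expression = expression,
    panel = panel_sim$panel, panel_labels = panel_sim$labels, panel_tree = panel_tree,
    truth = list(og = og_truth, genes = gene_truth, editing = editing,
                 snps = snps_truth, ld_sites = ld_sites, panel = panel_sim$truth),
    config = cfg
  ), class = "sim_data")
}

`%||null%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf(paste0("<sim_data> %d chrom(s), %d genes, %d OGs, %d editing sites, ",
                     "%d SNPs, panel %d x %d\n"),
              nrow(x$genome), dplyr::n_distinct(x$truth$genes$gene_id),
              nrow(x$og_counts), nrow(x$truth$editing), nrow(x$snps),
              nrow(x$panel), nrow(x$panel_labels)))
  invisible(x)
}

#' Simulate a cross-species gene-count panel
#'
#' Per-OG mean counts are Gamma-distributed; per-species counts are Poisson
#' around the OG mean.  Diet-flagged OGs are then expanded in predaceous
#' species with [plant_panel_effect()].
#'
#' @param n_ogs Number of panel OGs.
#' @param n_expanded Number of diet-flagged (expanded) OGs.
#' @param n_predaceous,n_phytophagous Group sizes; one outgroup species is
#'   appended.
#' @param effect Multiplicative predaceous expansion (1 = null).
#' @param lambda_shape,lambda_rate Gamma law of per-OG means.
#' @param seed Optional seed; `NULL` uses the ambient RNG stream.
#' @return A list `panel` (wide count tibble), `labels`, `truth`
#'   (`og_id`, `diet`, `lambda`).
#' @export
simulate_panel <- function(n_ogs, n_expanded = round(0.235 * n_ogs),
                           n_predaceous = 5, n_phytophagous = 28,
                           effect = 4, lambda_shape = 4, lambda_rate = 0.8,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- c(sprintf("pred_%02d", seq_len(n_predaceous)),
               sprintf("phyt_%02d", seq_len(n_phytophagous)),
               "outgroup_sp")
  labels <- tibble(species = species,
                   diet = c(rep("predaceous", n_predaceous),
                            rep("phytophagous", n_phytophagous), "outgroup"))
  lambda <- rgamma(n_ogs, lambda_shape, lambda_rate)
  counts <- vapply(seq_along(species), function(j) rpois(n_ogs, lambda),
                   integer(n_ogs))
  colnames(counts) <- species
  panel <- bind_cols(tibble(og_id = sprintf("OGP%05d", seq_len(n_ogs))),
                     as_tibble(counts))
  diet_flags <- tibble(og_id = panel$og_id,
                       diet = seq_len(n_ogs) <= n_expanded)
  panel <- plant_panel_effect(panel, labels, effect, diet_flags, means = lambda)
  list(panel = panel,
       labels = labels,
       truth = mutate(diet_flags, lambda = lambda))
}

#' Plant a predaceous expansion effect on a panel
#'
#' Multiplies the per-species count means of diet-flagged OGs in predaceous
#' species by `effect`, with Poisson rounding.  When the per-OG means are
#' known (the `means` argument, as supplied by [simulate_panel()]), the
#' expanded cells are redrawn as `rpois(effect * mean)` — an exact
#' multiplicative mean shift.  Without means, the realized counts stand in
#' for the mean and cells are redrawn as `rpois(effect * count)` (this
#' couples the shift to sampling zeros and is noisier).  `effect = 1`
#' leaves the panel untouched so the two groups stay exchangeable under the
#' null.
#'
#' @param panel Wide count tibble (`og_id` + species columns).
#' @param labels Species label tibble (`species`, `diet`); every panel
#'   species must be labeled.
#' @param effect Multiplier, >= 1.
#' @param diet_flags A tibble `og_id`, `diet` (logical) marking the OGs to
#'   expand.
#' @param means Optional numeric vector of per-OG mean counts (aligned with
#'   `panel` rows).
#' @return The panel with expanded counts.
#' @export
plant_panel_effect <- function(panel, labels, effect, diet_flags, means = NULL) {
  if (effect < 1) abort("plant_panel_effect(): effect must be >= 1.")
  species <- setdiff(names(panel), "og_id")
  unlabeled <- setdiff(species, labels$species)
  if (length(unlabeled) > 0L) {
    abort(paste0("plant_panel_effect(): unlabeled species: ",
                 paste(unlabeled, collapse = ", ")))
  }
  groups <- setNames(labels$diet, labels$species)
  if (sum(groups[species] == "predaceous") < 2L ||
      sum(groups[species] == "phytophagous") < 2L) {
    abort("plant_panel_effect(): need >= 2 species per diet group.")
  }
  if (effect == 1) return(panel)
  pred_cols <- species[groups[species] == "predaceous"]
  expand <- panel$og_id %in% diet_flags$og_id[diet_flags$diet]
  for (col in pred_cols) {
    base <- if (is.null(means)) panel[[col]][expand] else means[expand]
    panel[[col]][expand] <- rpois(sum(expand), effect * base)
  }
  panel
}

#' Editome recovery against planted truth
#'
#' Precision is the fraction of final called sites that are planted editing
#' sites.  Sensitivity is computed over the callable truth: planted,
#' non-bidirectional sites whose realized pileup depth reaches the caller's
#' own `min_depth` floor — a site sequenced below the depth floor is
#' undetectable by construction and measures the sequencing, not the
#' pipeline.  Bidirectional-region sites are unrecoverable by design (their
#' strand is undecidable) and are excluded from the denominator; use the
#' truth flag to assert they were all removed.
#'
#' @param sites Final annotated site tibble from [call_editome()].
#' @param truth_editing The simulator's `truth$editing` table.
#' @param min_depth The depth floor used in calling (default 5).
#' @return A one-row tibble `n_called`, `n_truth`, `n_callable`,
#'   `precision`, `sensitivity`.
#' @export
editome_recovery <- function(sites, truth_editing, min_depth = 5) {
  key <- function(d) paste(d$chrom, d$pos)
  called <- key(sites)
  truth_all <- key(truth_editing)
  callable <- truth_editing |>
    filter(!.data$bidirectional, .data$depth >= min_depth)
  tp_precision <- sum(called %in% truth_all)
  tp_sens <- sum(key(callable) %in% called)
  tibble(n_called = length(called),
         n_truth = nrow(truth_editing),
         n_callable = nrow(callable),
         precision = if (length(called) == 0L) NA_real_ else tp_precision / length(called),
         sensitivity = if (nrow(callable) == 0L) NA_real_ else tp_sens / nrow(callable))
}

#' Write a simulated bundle to disk
#'
#' Materializes every input of a [simulate_dataset()] bundle in its on-disk
#' format (FASTA, GFF3, BED, TSVs, Newick) plus the truth tables as TSV and
#' a JSON run summary.  Writers are deterministic: the same bundle always
#' produces byte-identical files.
#'
#' @param sim A `sim_data` bundle.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(dir, name)
  write_genome_fasta(sim$genome, f("genome.fa"))
  write_gff3(sim$gene_models, f("annotation.gff3"))
  write_bed(sim$repeats, f("repeats.bed"))
  write_og_counts(sim$og_counts, f("og_counts.tsv"))
  readr::write_tsv(arrange(sim$og_membership, .data$og_id, .data$species, .data$gene_id),
                   f("og_membership.tsv"))
  write_domain_table(sim$domains, f("domains.tsv"))
  write_snp_table(sim$snps, f("snps.tsv"))
  write_pileup(sim$pileup, f("pileup.tsv"))
  write_read_obs(sim$read_obs, f("read_obs.tsv"))
  readr::write_tsv(arrange(sim$expression, .data$gene_id), f("expression.tsv"))
  write_og_counts(sim$panel, f("panel_counts.tsv"))
  write_species_labels(sim$panel_labels, f("panel_labels.tsv"))
  ape::write.tree(sim$panel_tree, f("panel_tree.nwk"))
  for (nm in names(sim$truth)) {
    readr::write_tsv(sim$truth[[nm]], f(paste0("truth_", nm, ".tsv")))
  }
  jsonlite::write_json(list(
    seed = sim$config$seed,
    n_genes = dplyr::n_distinct(sim$truth$genes$gene_id),
    n_ogs = nrow(sim$og_counts),
    n_editing_sites = nrow(sim$truth$editing),
    n_snps = nrow(sim$snps)
  ), f("run_summary.json"), auto_unbox = TRUE)
  invisible(dir)
}
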