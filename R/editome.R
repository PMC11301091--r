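# A-to-I RNA editome characterization.
#
# Candidate RNA-DNA differences (RDDs) are called from per-site pileups,
# cleaned by two filters in the printed order (genomic-SNP exclusion by
# position, then removal of everything in bidirectionally transcribed
# regions where A>G and T>C are indistinguishable in non-strand-specific
# data), strand-resolved, and annotated with genomic category and, for CDS
# sites, the recoding consequence.  Every filter logs its in/out counts.

#' Call candidate RNA-DNA differences from a pileup
#'
#' At most one variant is called per site: the majority non-reference allele
#' (ties broken deterministically by base order A < C < G < T).  Sites must
#' pass the depth, alternative-read and editing-level thresholds; the
#' substitution is reported on the genome plus strand at this stage.
#'
#' @param pileup A pileup tibble from [read_pileup()] (or the simulator).
#' @param min_depth Minimum total depth (default 5).
#' @param min_alt Minimum alternative-allele reads (default 2).
#' @param min_level Minimum editing level alt/depth (default 0.01).
#' @return A tibble `chrom`, `pos` (1-based), `ref`, `alt`, `alt_reads`,
#'   `depth`, `level`, `sub` (genome-strand substitution `"X>Y"`), with a
#'   stage log attribute (see [stage_log()]).
#' @export
call_rdd <- function(pileup, min_depth = 5, min_alt = 2, min_level = 0.01) {
  if (nrow(pileup) == 0L) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), alt_reads = integer(), depth = integer(),
                  level = double(), sub = character())
    return(add_stage_log(out, "call_rdd", 0L, 0L))
  }
  counts <- as.matrix(pileup[, c("nA", "nC", "nG", "nT")])
  colnames(counts) <- BASES
  depth <- rowSums(counts)
  ref_idx <- match(pileup$ref, BASES)
  alt_counts <- counts
  alt_counts[cbind(seq_len(nrow(counts)), ref_idx)] <- -1L
  # which.max on the row picks the majority non-reference base, first (A<C<G<T) on ties
  alt_idx <- max.col(alt_counts, ties.method = "first")
  alt_reads <- counts[cbind(seq_len(nrow(counts)), alt_idx)]
  out <- pileup |>
    mutate(depth = as.integer(depth),
           alt = BASES[alt_idx],
           alt_reads = as.integer(alt_reads),
           level = ifelse(depth > 0, alt_reads / depth, 0)) |>
    filter(.data$depth >= min_depth,
           .data$alt_reads >= min_alt,
           .data$level >= min_level) |>
    mutate(sub = paste0(.data$ref, ">", .data$alt)) |>
    select("chrom", "pos", "ref", "alt", "alt_reads", "depth", "level", "sub")
  add_stage_log(out, "call_rdd", nrow(pileup), nrow(out))
}

#' Exclude genomic SNP positions from candidate variants
#'
#' Any variant at a SNP position is removed regardless of allele match
#' (conservative: a genomic polymorphism at the site makes the RNA call
#' unreliable whatever the alleles are).
#'
#' @param variants Output of [call_rdd()] (or a later stage).
#' @param snps A SNP tibble (`chrom`, `pos` 1-based) on the same assembly.
#' @return The filtered variants; removal counts are appended to the stage
#'   log.
#' @export
exclude_snps <- function(variants, snps) {
  n_in <- nrow(variants)
  if (nrow(snps) > 0L && n_in > 0L &&
      length(intersect(unique(variants$chrom), unique(snps$chrom))) == 0L) {
    abort("exclude_snps(): no shared chromosome names between variants and SNP table.")
  }
  out <- anti_join(variants, distinct(snps, .data$chrom, .data$pos),
                   by = c("chrom", "pos"))
  attr(out, "stage_log") <- attr(variants, "stage_log")
  add_stage_log(out, "exclude_snps", n_in, nrow(out))
}

#' Remove variants in bidirectionally transcribed regions
#'
#' A position covered by gene spans on both strands cannot be assigned a
#' transcript strand in non-strand-specific RNA-seq (an apparent A>G may be
#' a T>C on the opposite strand), so all such variants are discarded.
#'
#' @param variants Candidate variant tibble.
#' @param gm A [gene_models()] object.
#' @return The filtered variants with an updated stage log.
#' @export
mask_bidirectional <- function(variants, gm) {
  n_in <- nrow(variants)
  regions <- bidirectional_regions(gm)
  drop <- pos_in_intervals(variants$chrom, variants$pos, regions)
  out <- variants[!drop, , drop = FALSE]
  attr(out, "stage_log") <- attr(variants, "stage_log")
  add_stage_log(out, "mask_bidirectional", n_in, nrow(out))
}

# gene span hits (same-strand containment) for variant positions
overlapping_genes <- function(chrom, pos, spans) {
  if (nrow(spans) == 0L || length(pos) == 0L) {
    return(tibble(variant = integer(), gene_id = character(), strand = character()))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  tibble(variant = S4Vectors::queryHits(hits),
         gene_id = spans$gene_id[S4Vectors::subjectHits(hits)],
         strand = spans$strand[S4Vectors::subjectHits(hits)])
}

#' Resolve the transcript strand of candidate variants
#'
#' Inside a gene the transcript strand is the gene strand and the genome
#' substitution is complemented for minus-strand genes.  Intergenic variants
#' are clustered (single-linkage, gap <= `cluster_window`) and each cluster
#' is assigned the strand under which the majority of its members read as
#' A>G (i.e. minus if T>C calls outnumber A>G calls), plus strand on ties —
#' hyper-edited clusters are transcribed as one unit, so one strand per
#' cluster.
#'
#' @param variants Candidate variant tibble (genome-strand `sub`).
#' @param gm A [gene_models()] object.
#' @param cluster_window Maximum gap (bp) joining intergenic variants into
#'   one cluster (default 1000).
#' @return The variants with `strand` and transcript-strand `sub` columns
#'   (genome-strand call kept as `sub_genome`); `gene_id` is set for genic
#'   variants.
#' @export
resolve_strand <- function(variants, gm, cluster_window = 1000) {
  n_in <- nrow(variants)
  spans <- gene_spans(gm)
  if (n_in == 0L) {
    out <- mutate(variants, strand = character(0), gene_id = character(0),
                  sub_genome = character(0))
    attr(out, "stage_log") <- attr(variants, "stage_log")
    return(add_stage_log(out, "resolve_strand", 0L, 0L))
  }
  hits <- overlapping_genes(variants$chrom, variants$pos, spans) |>
    group_by(.data$variant) |>
    summarise(gene_id = .data$gene_id[1], strand = .data$strand[1],
              n_strands = dplyr::n_distinct(.data$strand), .groups = "drop")
  # bidirectional positions should already be masked; treat leftovers as genic
  # on the first gene's strand
  x <- variants |>
    mutate(.row = dplyr::row_number()) |>
    left_join(hits, by = c(".row" = "variant")) |>
    mutate(genic = !is.na(.data$strand))

  # intergenic: cluster by proximity and take the majority A>G orientation
  inter <- x |> filter(!.data$genic) |> arrange(.data$chrom, .data$pos)
  if (nrow(inter) > 0L) {
    inter <- inter |>
      group_by(.data$chrom) |>
      mutate(cluster = cumsum(c(1L, as.integer(diff(.data$pos) > cluster_window)))) |>
      group_by(.data$chrom, .data$cluster) |>
      mutate(strand = ifelse(sum(.data$sub == "T>C") > sum(.data$sub == "A>G"),
                             "-", "+")) |>
      ungroup() |>
      select(-"cluster")
  }
  out <- bind_rows(filter(x, .data$genic), inter) |>
    arrange(.data$.row) |>
    mutate(sub_genome = .data$sub,
           sub = ifelse(.data$strand == "-", complement_substitution(.data$sub), .data$sub),
           ref = substr(.data$sub, 1L, 1L),
           alt = substr(.data$sub, 3L, 3L)) |>
    select(-".row", -"genic", -"n_strands")
  attr(out, "stage_log") <- attr(variants, "stage_log")
  add_stage_log(out, "resolve_strand", n_in, nrow(out))
}

# translate a codon with the standard genetic code ("*" = stop)
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

classify_effect <- function(ref_aa, alt_aa) {
  dplyr::case_when(
    is.na(ref_aa) | is.na(alt_aa) ~ NA_character_,
    ref_aa == alt_aa ~ "synonymous",   # includes stop-retaining changes
    alt_aa == "*" ~ "stop_gain",
    ref_aa == "*" ~ "stop_loss",
    TRUE ~ "nonsynonymous"
  )
}

# recoding consequence for one site in a coding transcript
recode_site <- function(pos, alt_tx, tx_cds, tx_strand, chrom_seq) {
  # tx_cds: tibble(start, end) 0-based half-open, sorted ascending
  widths <- tx_cds$end - tx_cds$start
  idx <- which(pos - 1L >= tx_cds$start & pos - 1L < tx_cds$end)
  if (length(idx) == 0L) return(c(NA_character_, NA_character_, NA_character_))
  offset_genomic <- sum(widths[seq_len(idx - 1L)]) + (pos - 1L - tx_cds$start[idx])
  cds_seq <- paste0(substring(chrom_seq, tx_cds$start + 1L, tx_cds$end), collapse = "")
  if (tx_strand == "-") {
    cds_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
    offset <- nchar(cds_seq) - 1L - offset_genomic
  } else {
    offset <- offset_genomic
  }
  codon_i <- offset %/% 3L
  codon_pos <- offset %% 3L + 1L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) != 3L) return(c(NA_character_, NA_character_, NA_character_))
  alt_codon <- codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_tx
  c(codon, alt_codon, paste0(codon_pos))
}

#' Annotate strand-resolved variants with category and coding effect
#'
#' Categories follow the precedence CDS > UTR > intron > intergenic over the
#' transcripts of the gene on the variant's strand; the UTR category only
#' exists when the annotation contains UTR features.  CDS sites are recoded
#' on the canonical (longest-CDS) transcript: the edited base is substituted
#' at its in-frame codon position and the consequence read off the standard
#' genetic code (`synonymous`, `nonsynonymous`, `stop_gain`, `stop_loss`;
#' stop-retaining changes count as synonymous).  Sites in the CDS of a
#' non-canonical or frame-inconsistent transcript are flagged with `NA`
#' effect.
#'
#' @param variants Output of [resolve_strand()].
#' @param gm A [gene_models()] object.
#' @param genome A genome tibble (`chrom`, `sequence`) for codon lookup.
#' @return The variants with `category`, `gene_id`, `codon_ref`,
#'   `codon_alt`, `codon_pos` and `coding_effect` columns (`coding_effect`
#'   non-`NA` only for CDS sites).
#' @export
annotate_sites <- function(variants, gm, genome) {
  n_in <- nrow(variants)
  feats <- as_tibble(gm)
  has_utr <- any(feats$type %in% c("five_prime_UTR", "three_prime_UTR"))
  spans <- gene_spans(gm)
  canon <- canonical_transcripts(gm)

  if (n_in == 0L) {
    out <- mutate(variants, category = character(0), coding_effect = character(0))
    attr(out, "stage_log") <- attr(variants, "stage_log")
    return(add_stage_log(out, "annotate_sites", 0L, 0L))
  }

  # same-strand gene containment
  hits <- overlapping_genes(variants$chrom, variants$pos, spans)
  same <- hits |>
    mutate(var_strand = variants$strand[.data$variant]) |>
    filter(.data$strand == .data$var_strand)

  categorize_one <- function(i, gene_ids) {
    pos <- variants$pos[i]
    f <- feats |> filter(.data$gene_id %in% gene_ids,
                         .data$start < pos, .data$end >= pos)
    if (any(f$type == "CDS")) "CDS"
    else if (has_utr && any(f$type %in% c("five_prime_UTR", "three_prime_UTR"))) "UTR"
    else "intron"
  }
  genic <- same |>
    group_by(.data$variant) |>
    summarise(gene_id = sort(.data$gene_id)[1],
              gene_ids = list(unique(.data$gene_id)), .groups = "drop")
  cat_vec <- rep("intergenic", n_in)
  gene_vec <- rep(NA_character_, n_in)
  if (nrow(genic) > 0L) {
    cats <- purrr::map2_chr(genic$variant, genic$gene_ids, categorize_one)
    cat_vec[genic$variant] <- cats
    gene_vec[genic$variant] <- genic$gene_id
  }

  out <- variants |>
    mutate(category = cat_vec,
           gene_id = gene_vec,
           codon_ref = NA_character_, codon_alt = NA_character_,
           codon_pos = NA_integer_, coding_effect = NA_character_)

  cds_rows <- which(out$category == "CDS")
  if (length(cds_rows) > 0L) {
    seq_by_chrom <- setNames(genome$sequence, genome$chrom)
    cds_feats <- feats |> filter(.data$type == "CDS")
    for (i in cds_rows) {
      g <- out$gene_id[i]
      tx <- canon$transcript_id[canon$gene_id == g]
      if (length(tx) == 0L) next  # no frame-consistent coding transcript: effect stays NA
      tx_cds <- cds_feats |> filter(.data$transcript_id == tx) |> arrange(.data$start)
      res <- recode_site(out$pos[i], out$alt[i], tx_cds, out$strand[i],
                         seq_by_chrom[[out$chrom[i]]])
      if (!is.na(res[1])) {
        out$codon_ref[i] <- res[1]
        out$codon_alt[i] <- res[2]
        out$codon_pos[i] <- as.integer(res[3])
        out$coding_effect[i] <- classify_effect(translate_codon(res[1]),
                                                translate_codon(res[2]))
      }
    }
  }
  attr(out, "stage_log") <- attr(variants, "stage_log")
  add_stage_log(out, "annotate_sites", n_in, nrow(out))
}

#' Run the full editome pipeline
#'
#' Chains [call_rdd()], [exclude_snps()], [mask_bidirectional()],
#' [resolve_strand()] and [annotate_sites()] with a cumulative stage log.
#'
#' @inheritParams call_rdd
#' @inheritParams resolve_strand
#' @param gm A [gene_models()] object.
#' @param genome Genome tibble (`chrom`, `sequence`).
#' @param snps SNP tibble (may be empty).
#' @return Annotated editing-site tibble; inspect filtering with
#'   [stage_log()].
#' @export
call_editome <- function(pileup, gm, genome, snps,
                         min_depth = 5, min_alt = 2, min_level = 0.01,
                         cluster_window = 1000) {
  call_rdd(pileup, min_depth = min_depth, min_alt = min_alt, min_level = min_level) |>
    exclude_snps(snps) |>
    mask_bidirectional(gm) |>
    resolve_strand(gm, cluster_window = cluster_window) |>
    annotate_sites(gm, genome)
}

#' Summarize an editome
#'
#' @param sites Annotated editing-site tibble.
#' @return A list of class `editome_summary`: `substitutions` (type
#'   fractions on the transcript strand, summing to 1), `categories`
#'   (per-category site counts) and `coverage` (per-category depth and
#'   editing-level quantiles).
#' @export
summarize_editome <- function(sites) {
  if (nrow(sites) == 0L) abort("summarize_editome(): empty site list.")
  subs <- sites |>
    count(.data$sub, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(desc(.data$n))
  cats <- sites |>
    count(.data$category, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n))
  qtiles <- c(0, 0.25, 0.5, 0.75, 1)
  coverage <- sites |>
    group_by(.data$category) |>
    reframe(quantile_label = paste0("q", qtiles * 100),
            depth = quantile(.data$depth, qtiles),
            level = quantile(.data$level, qtiles))
  structure(list(substitutions = subs, categories = cats, coverage = coverage,
                 n_sites = nrow(sites)),
            class = "editome_summary")
}

#' @export
print.editome_summary <- function(x, ...) {
  ag <- x$substitutions$fraction[x$substitutions$sub == "A>G"]
  cat(sprintf("<editome_summary> %d sites; A>G fraction %.3f\n", x$n_sites,
              ifelse(length(ag) == 0L, 0, ag)))
  print(x$categories)
  invisible(x)
}
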