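# Readers and writers for every on-disk format the pipeline touches.
#
# Conventions: GFF3, pileup and SNP tables are 1-based on disk and converted
# to the internal 0-based half-open convention at this boundary; BED is
# already 0-based half-open.  Writers emit rows in a deterministic order so
# identical inputs produce byte-identical files.

#' Read a genome FASTA
#'
#' @param path Path to an (uncompressed) FASTA file of DNA sequences.
#' @return A tibble `chrom`, `sequence` (uppercase over A/C/G/T/N) and
#'   `length`.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- tibble(chrom = names(seqs),
                sequence = toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", out$sequence)
  if (any(bad)) abort("read_genome_fasta(): sequence alphabet must be A/C/G/T/N.")
  if (any(nchar(out$sequence) == 0L)) abort("read_genome_fasta(): empty sequence.")
  mutate(out, length = nchar(.data$sequence))
}

#' @rdname read_genome_fasta
#' @param genome A tibble with columns `chrom`, `sequence`.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$chrom))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` / `mRNA` / `exon` / `CDS` (and optional UTR) features,
#' resolves parent-child links and converts 1-based inclusive coordinates to
#' the internal 0-based half-open convention.  Annotations without UTR
#' features are accepted; downstream site categorization then simply has no
#' UTR category.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  keep <- df$type %in% c("gene", "mRNA", FEATURE_TYPES)
  df <- df[keep, , drop = FALSE]
  parent <- vapply(df$Parent, function(p) if (length(p) == 0L) NA_character_ else p[[1]],
                   character(1))
  ids <- if ("ID" %in% names(df)) df$ID else rep(NA_character_, nrow(df))

  mrna <- df$type == "mRNA"
  tx2gene <- setNames(parent[mrna], ids[mrna])
  feat <- df$type %in% FEATURE_TYPES
  bad <- feat & (is.na(parent) | !(parent %in% names(tx2gene)))
  if (any(bad)) {
    offender <- parent[bad][1]
    lines <- readr::read_lines(path)
    hit <- which(grepl(paste0("Parent=", offender), lines, fixed = TRUE))[1]
    abort(sprintf(
      "read_gff3(): feature with Parent=%s has no mRNA parent (line %s).",
      offender %||% "<missing>", ifelse(is.na(hit), "?", hit)))
  }

  features <- tibble(
    gene_id = unname(tx2gene[parent[feat]]),
    transcript_id = parent[feat],
    type = as.character(df$type[feat]),
    chrom = as.character(df$seqnames[feat]),
    start = df$start[feat] - 1L,  # 1-based inclusive -> 0-based half-open
    end = df$end[feat],
    strand = as.character(df$strand[feat])
  )
  gene_models(features)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @rdname read_gff3
#' @param gm A [gene_models()] object.
#' @export
write_gff3 <- function(gm, path) {
  feats <- as_tibble(gm)
  spans <- gene_spans(gm)
  tx <- feats |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
              strand = .data$strand[1], .groups = "drop")
  lines <- character(0)
  spans <- arrange(spans, .data$chrom, .data$start, .data$gene_id)
  for (i in seq_len(nrow(spans))) {
    g <- spans[i, ]
    lines <- c(lines, sprintf("%s\tdietshift\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, g$start + 1L, g$end, g$strand, g$gene_id))
    gtx <- tx |> filter(.data$gene_id == g$gene_id) |> arrange(.data$transcript_id)
    for (j in seq_len(nrow(gtx))) {
      t <- gtx[j, ]
      lines <- c(lines, sprintf("%s\tdietshift\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                t$chrom, t$start + 1L, t$end, t$strand,
                                t$transcript_id, g$gene_id))
      tf <- feats |>
        filter(.data$transcript_id == t$transcript_id) |>
        arrange(factor(.data$type, levels = FEATURE_TYPES), .data$start)
      lines <- c(lines, sprintf("%s\tdietshift\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                                tf$chrom, tf$type, tf$start + 1L, tf$end, tf$strand,
                                tf$transcript_id))
    }
  }
  readr::write_lines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read an RNA-seq site pileup
#'
#' The pileup is a TSV of per-position base counts (`chrom`, `pos` 1-based,
#' `ref`, `nA`, `nC`, `nG`, `nT`), the minimal sufficient statistic for
#' RNA-DNA difference calling; read mapping itself happens upstream.
#'
#' @param path Path to a pileup TSV with header.
#' @return A tibble with the input columns plus `depth = nA+nC+nG+nT`.
#' @export
read_pileup <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = "c", pos = "i", ref = "c",
                         nA = "i", nC = "i", nG = "i", nT = "i"))
  if (nrow(x) == 0L) return(mutate(x, depth = integer(0)))
  if (!all(x$ref %in% BASES)) abort("read_pileup(): ref base must be one of A/C/G/T.")
  counts <- as.matrix(x[, c("nA", "nC", "nG", "nT")])
  if (any(counts < 0) || any(is.na(counts))) abort("read_pileup(): negative or missing counts.")
  mutate(x, depth = .data$nA + .data$nC + .data$nG + .data$nT)
}

#' @rdname read_pileup
#' @param pileup A tibble with columns `chrom`, `pos`, `ref`, `nA`, `nC`,
#'   `nG`, `nT`.
#' @export
write_pileup <- function(pileup, path) {
  pileup |>
    select("chrom", "pos", "ref", "nA", "nC", "nG", "nT") |>
    arrange(.data$chrom, .data$pos) |>
    readr::write_tsv(path)
  invisible(path)
}

#' Read an ortho-group gene-count table
#'
#' @param path TSV with an `og_id` column and one integer column per species.
#' @return A wide tibble of non-negative integer counts, one row per OG.
#'   Missing cells are filled with 0 (with a warning); all-zero rows are
#'   retained but reported via the `degenerate` attribute.
#' @export
read_og_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"og_id" %in% names(x)) abort("read_og_counts(): first column must be `og_id`.")
  species <- setdiff(names(x), "og_id")
  vals <- x[species]
  if (any(vapply(vals, function(v) any(!is.na(v) & (v != floor(v) | v < 0)), logical(1)))) {
    abort("read_og_counts(): counts must be non-negative integers.")
  }
  n_missing <- sum(vapply(vals, function(v) sum(is.na(v)), integer(1)))
  if (n_missing > 0L) {
    warn(sprintf("read_og_counts(): %d missing cells set to 0.", n_missing))
    x <- mutate(x, across(all_of(species), ~ dplyr::coalesce(as.integer(.x), 0L)))
  } else {
    x <- mutate(x, across(all_of(species), as.integer))
  }
  zero <- rowSums(as.matrix(x[species])) == 0L
  attr(x, "degenerate") <- x$og_id[zero]
  x
}

#' @rdname read_og_counts
#' @param og_counts A wide OG-by-species count tibble with an `og_id` column.
#' @export
write_og_counts <- function(og_counts, path) {
  og_counts |> arrange(.data$og_id) |> readr::write_tsv(path)
  invisible(path)
}

#' Read a BED repeat track
#'
#' BED intervals are 0-based half-open, matching the internal convention.
#'
#' @param path Path to a 3+ column BED file.
#' @param merge Merge overlapping intervals (default `FALSE`).
#' @return A tibble `chrom`, `start`, `end`.
#' @export
read_bed <- function(path, merge = FALSE) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr))
  if (merge) out <- merge_intervals(out)
  arrange(out, .data$chrom, .data$start)
}

#' @rdname read_bed
#' @param intervals A tibble `chrom`, `start`, `end` (0-based half-open).
#' @export
write_bed <- function(intervals, path) {
  intervals |>
    arrange(.data$chrom, .data$start) |>
    mutate(line = sprintf("%s\t%d\t%d", .data$chrom, .data$start, .data$end)) |>
    pull("line") |>
    readr::write_lines(path)
  invisible(path)
}

#' Read a genomic SNP table
#'
#' @param path TSV with header `chrom`, `pos` (1-based), `ref`, `alt`.
#' @return A tibble of validated SNP records (`ref != alt`, bases A/C/G/T).
#' @export
read_snp_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c", pos = "i",
                                               ref = "c", alt = "c"))
  if (nrow(x) > 0L) {
    if (!all(x$ref %in% BASES) || !all(x$alt %in% BASES)) {
      abort("read_snp_table(): ref/alt must be A/C/G/T.")
    }
    if (any(x$ref == x$alt)) abort("read_snp_table(): ref must differ from alt.")
  }
  distinct(x)
}

#' @rdname read_snp_table
#' @param snps A tibble `chrom`, `pos`, `ref`, `alt`.
#' @export
write_snp_table <- function(snps, path) {
  snps |> arrange(.data$chrom, .data$pos) |> readr::write_tsv(path)
  invisible(path)
}

#' Read per-gene Pfam domain assignments
#'
#' @param path TSV with header `gene_id`, `accession`; one row per assignment.
#' @return A tibble with validated `PF\\d{5}` accessions.
#' @export
read_domain_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(gene_id = "c", accession = "c"))
  if (nrow(x) > 0L && !all(grepl("^PF\\d{5}$", x$accession))) {
    abort("read_domain_table(): accessions must match PF + 5 digits.")
  }
  x
}

#' @rdname read_domain_table
#' @param domains A tibble `gene_id`, `accession`.
#' @export
write_domain_table <- function(domains, path) {
  domains |> arrange(.data$gene_id, .data$accession) |> readr::write_tsv(path)
  invisible(path)
}

#' Read a species diet-label table
#'
#' @param path TSV with header `species`, `diet`; `diet` is one of
#'   `predaceous`, `phytophagous` or `outgroup`.
#' @return A tibble `species`, `diet`.
#' @export
read_species_labels <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(species = "c", diet = "c"))
  ok <- x$diet %in% c("predaceous", "phytophagous", "outgroup")
  if (!all(ok)) abort("read_species_labels(): diet must be predaceous/phytophagous/outgroup.")
  x
}

#' @rdname read_species_labels
#' @param labels A tibble `species`, `diet`.
#' @export
write_species_labels <- function(labels, path) {
  labels |> arrange(.data$species) |> readr::write_tsv(path)
  invisible(path)
}

#' Read read-level allele observations
#'
#' Each row records the allele (`ref` or `alt`) one read carries at one
#' variant site; co-observations of site pairs on the same read back the
#' linkage-disequilibrium contrast of [ld_contrast()].
#'
#' @param path TSV with header `read_id`, `chrom`, `pos` (1-based), `allele`.
#' @return A tibble of observations.
#' @export
read_read_obs <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(read_id = "c", chrom = "c",
                                               pos = "i", allele = "c"))
  if (nrow(x) > 0L && !all(x$allele %in% c("ref", "alt"))) {
    abort("read_read_obs(): allele must be 'ref' or 'alt'.")
  }
  x
}

#' @rdname read_read_obs
#' @param obs A tibble `read_id`, `chrom`, `pos`, `allele`.
#' @export
write_read_obs <- function(obs, path) {
  obs |> arrange(.data$read_id, .data$chrom, .data$pos) |> readr::write_tsv(path)
  invisible(path)
}

#' Read a Newick species tree
#'
#' Thin wrapper over [ape::read.tree()]; the tree is used only for display
#' ordering of cross-species panels.
#'
#' @param path Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_species_tree <- function(path) {
  ape::read.tree(path)
}
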