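# Internal helpers shared across modules.
#
# All genomic intervals inside the package are 0-based half-open [start, end).
# GFF3, pileup and SNP inputs are 1-based and converted at the boundary, so
# any off-by-one handling lives in the readers/writers only.

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# the 12 substitution types on a given strand, "X>Y"
SUBSTITUTION_TYPES <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, ">", b)))[
  as.vector(outer(BASES, BASES, `!=`))
]

complement_base <- function(x) unname(COMPLEMENT[x])

complement_substitution <- function(sub) {
  ref <- substr(sub, 1L, 1L)
  alt <- substr(sub, 3L, 3L)
  paste0(complement_base(ref), ">", complement_base(alt))
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)))
  }
  invisible(x)
}

#' Total length of the union of a set of intervals
#'
#' Intervals are 0-based half-open; overlapping intervals are merged before
#' summing so shared bases are counted once.
#'
#' @param start,end Integer vectors of interval starts (0-based) and ends
#'   (exclusive).
#' @return A single non-negative integer length in bp.
#' @keywords internal
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::IRanges(start = start + 1L, end = end)
  sum(IRanges::width(IRanges::reduce(ir)))
}

# merge possibly-overlapping intervals of a (chrom, start, end) tibble
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(x)
  x |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

# positions (1-based) falling in any interval of tibble(chrom,start,end), 0-based half-open
pos_in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0L || length(pos) == 0L) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start + 1L, intervals$end))
  IRanges::overlapsAny(q, s)
}

# deterministic sub-seed derivation: keeps all derived seeds < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1103L + as.integer(offset) * 12347L) %% 2147483587L
}

star_code <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

# attach / extend a per-stage record-count log on a pipeline tibble
add_stage_log <- function(x, stage, n_in, n_out) {
  log <- attr(x, "stage_log")
  entry <- tibble(stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out),
                  n_removed = as.integer(n_in - n_out))
  attr(x, "stage_log") <- if (is.null(log)) entry else bind_rows(log, entry)
  x
}

#' Retrieve the per-stage filter log of a pipeline result
#'
#' Editome filter stages record how many sites entered and left each step, so
#' every removal is auditable.
#'
#' @param x A tibble returned by an editome pipeline stage or [call_editome()].
#' @return A tibble with columns `stage`, `n_in`, `n_out`, `n_removed`.
#' @export
stage_log <- function(x) {
  log <- attr(x, "stage_log")
  if (is.null(log)) {
    tibble(stage = character(), n_in = integer(), n_out = integer(),
           n_removed = integer())
  } else {
    log
  }
}
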