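# Independent oracles used across the suite.  Each reimplements the checked
# quantity from first principles (enumeration, brute-force DP, per-base
# counting) without touching the package's code paths.

# ---- global affine-gap alignment oracle (Needleman-Wunsch, 3-matrix DP) ----
# gap of length L costs open + ext * L, matching the package's fixed scheme
nw_oracle <- function(a, b, open = 10, ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in y (x aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in x
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- S[x[i], y[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])

  # traceback for identity (one optimal path)
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    cols <- cols + 1L
    if (state == 1L && i > 0 && j > 0) {
      s <- S[x[i], y[j]]
      prev <- c(M[i, j], X[i, j], Y[i, j])
      if (x[i] == y[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2L && i > 0) {
      prev <- c(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      i <- i - 1L
      state <- if (which.max(prev) == 1L) 1L else 2L
    } else {
      prev <- c(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      j <- j - 1L
      state <- if (which.max(prev) == 1L) 1L else 3L
    }
  }
  list(score = score, identity = matches / cols)
}

# ---- exact hypergeometric (Fisher) oracles via choose() --------------------
# two-sided: sum of point probabilities <= that of the observed table
fisher_oracle_two_sided <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  N <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1)
  p <- exp(logp)
  sum(p[p <= p[xs == a] * (1 + 1e-7)])
}

# one-sided (greater in cell [1,1])
fisher_oracle_greater <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  N <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  p <- exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1))
  sum(p[xs >= a])
}

# ---- exact rank-sum oracles ------------------------------------------------
# full enumeration of group assignments (small n, handles ties)
ranksum_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  W_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}

# DP over the exact null distribution of the rank-sum (no ties): number of
# n1-subsets of ranks 1..N with each possible sum
ranksum_dp_oracle <- function(x, y) {
  stopifnot(anyDuplicated(c(x, y)) == 0L)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  S_obs <- sum(r[seq_len(n1)])
  max_sum <- n1 * N
  # ways[k+1, s+1] = number of size-k subsets of {1..N} with rank sum s
  ways <- matrix(0, n1 + 1, max_sum + 1)
  ways[1, 1] <- 1
  for (rank_i in seq_len(N)) {
    for (k in rev(seq_len(min(rank_i, n1)))) {
      s_idx <- (rank_i + 1):(max_sum + 1)
      ways[k + 1, s_idx] <- ways[k + 1, s_idx] + ways[k, s_idx - rank_i]
    }
  }
  dist <- ways[n1 + 1, ] / choose(N, n1)
  s_vals <- 0:max_sum
  mu <- n1 * (N + 1) / 2   # null mean of the rank sum
  sum(dist[abs(s_vals - mu) >= abs(S_obs - mu) - 1e-9])
}

# ---- Spearman permutation oracle -------------------------------------------
spearman_perm_oracle <- function(x, y) {
  rho_obs <- stats::cor(x, y, method = "spearman")
  perms <- combinat_permn(length(y))
  rhos <- vapply(perms, function(p) stats::cor(x, y[p], method = "spearman"), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-9)
}

combinat_permn <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- combinat_permn(n - 1L)
  out <- vector("list", 0L)
  for (p in smaller) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# ---- per-base interval union oracle ----------------------------------------
union_len_oracle <- function(start, end) {
  covered <- logical(max(end))
  for (i in seq_along(start)) covered[(start[i] + 1):end[i]] <- TRUE
  sum(covered)
}

# ---- shared fixtures --------------------------------------------------------
# micro genome + two genes (one on each strand) used by editome tests
micro_fixture <- function() {
  # chr1: 600 bp; plus-strand gene g1 with one 120 bp exon/CDS at [100, 220);
  # minus-strand gene g2 with one 90 bp exon/CDS at [400, 490)
  set.seed(7)
  seq_chars <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
  # plant known codons inside g1 CDS (plus strand, frame starts at 100):
  # codon 1 TAT (Tyr), codon 2 CGA (Arg), codon 3 TAA would stop; use TAC later
  seq_chars[101:103] <- c("T", "A", "T")
  seq_chars[104:106] <- c("C", "G", "A")
  seq_chars[107:109] <- c("T", "A", "A")
  genome <- tibble::tibble(chrom = "chr1",
                           sequence = paste0(seq_chars, collapse = ""),
                           length = 600L)
  gm <- gene_models(tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2"),
    transcript_id = c("g1.t1", "g1.t1", "g2.t1", "g2.t1"),
    type = c("exon", "CDS", "exon", "CDS"),
    chrom = "chr1",
    start = c(100L, 100L, 400L, 400L),
    end = c(220L, 220L, 490L, 490L),
    strand = c("+", "+", "-", "-")
  ))
  list(genome = genome, gm = gm, chars = seq_chars)
}

# small simulated bundle cached across tests in one run
.sim_cache <- new.env()
get_small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    .sim_cache$small <- simulate_dataset(sim_config(
      seed = 11, n_chroms = 1, chrom_len = 4e5, n_genes = 40, n_ogs = 300,
      n_editing_sites = 200, n_snps = 50, n_contaminant_snps = 10,
      n_background_sites = 100, n_panel_ogs = 30, n_bidirectional_sites = 5))
  }
  .sim_cache$small
}

get_default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    .sim_cache$default <- simulate_dataset(sim_config())
  }
  .sim_cache$default
}
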