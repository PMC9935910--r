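# Independent oracles, deliberately implemented with different algorithms
# than the package (brute force, enumeration, plain DP) so each check has
# two routes.

# All 4-mer windows matching the SPKK-related pattern, by brute force.
oracle_spkk_hits <- function(sequence, cterm_window = 50) {
  len <- nchar(sequence)
  cstart <- max(1L, len - cterm_window + 1L)
  starts <- integer()
  for (i in seq.int(cstart, max(cstart, len - 3L))) {
    pep <- substr(sequence, i, i + 3L)
    if (nchar(pep) == 4L && grepl("^[ST]P[KR][KR]$", pep))
      starts <- c(starts, i)
  }
  starts
}

# Identity of the match-maximizing global alignment: LCS length divided by
# the corresponding alignment length (m + n - lcs).
oracle_lcs_identity <- function(a, b) {
  x <- strsplit(a, NULL)[[1]]
  y <- strsplit(b, NULL)[[1]]
  m <- length(x); n <- length(y)
  d <- matrix(0L, m + 1L, n + 1L)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    d[i + 1L, j + 1L] <- if (x[i] == y[j]) d[i, j] + 1L
    else max(d[i, j + 1L], d[i + 1L, j])
  }
  lcs <- d[m + 1L, n + 1L]
  lcs / (m + n - lcs)
}

# Exhaustive score-and-diversity selection: sort by score (ties by id),
# keep a candidate unless it is >= threshold identical to a kept one.
oracle_rank <- function(df, cterm_window, threshold) {
  ct <- substr(df$sequence,
               pmax(1L, nchar(df$sequence) - cterm_window + 1L),
               nchar(df$sequence))
  ord <- order(-df$score, df$id)
  kept <- integer()
  for (i in ord) {
    dup <- FALSE
    for (j in kept)
      if (oracle_lcs_identity(ct[i], ct[j]) >= threshold) dup <- TRUE
    if (!dup) kept <- c(kept, i)
  }
  df$id[kept]
}

# Needleman-Wunsch with affine gaps (Gotoh), plain-matrix implementation.
# Gap of length L costs open + L * extend (both negative). Returns the score.
oracle_nw_affine_score <- function(a, b, match = 2, mismatch = -1,
                                   gap_open = -6, gap_extend = -1) {
  x <- strsplit(a, NULL)[[1]]
  y <- strsplit(b, NULL)[[1]]
  m <- length(x); n <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, m + 1L, n + 1L)  # ends in match/mismatch
  X <- matrix(NEG, m + 1L, n + 1L)  # ends in gap in y (x consumed)
  Y <- matrix(NEG, m + 1L, n + 1L)  # ends in gap in x (y consumed)
  M[1, 1] <- 0
  for (i in seq_len(m))
    X[i + 1L, 1L] <- gap_open + i * gap_extend
  for (j in seq_len(n))
    Y[1L, j + 1L] <- gap_open + j * gap_extend
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (x[i] == y[j]) match else mismatch
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open + gap_extend,
                               X[i, j + 1L] + gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open + gap_extend,
                               Y[i + 1L, j] + gap_extend)
    }
  }
  max(M[m + 1L, n + 1L], X[m + 1L, n + 1L], Y[m + 1L, n + 1L])
}

# Minimal IUPAC cover by full enumeration over all 15 codes.
oracle_iupac <- function(p, threshold = 0.9) {
  sets <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  ok <- names(sets)[vapply(sets, function(s) sum(p[s]) >= threshold,
                           logical(1))]
  sizes <- lengths(sets)[ok]
  ok[order(sizes, match(ok, names(sets)))][1]
}

# Exact upper binomial tail by direct summation.
oracle_binom_tail <- function(k, n, p) {
  sum(vapply(k:n, function(x)
    choose(n, x) * p^x * (1 - p)^(n - x), numeric(1)))
}

# Eligible deamination sites of a genome for a -1-context weight vector:
# per-context counts of plus-strand Cs and (as minus-strand Cs) plus-strand
# Gs, enumerated position by position.
oracle_eligible_contexts <- function(reference, weights) {
  chars <- strsplit(reference, NULL)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  for (i in seq_along(chars)) {
    if (chars[i] == "C" && i >= 2L)
      counts[chars[i - 1L]] <- counts[chars[i - 1L]] + 1L
    if (chars[i] == "G" && i < length(chars))
      counts[comp[chars[i + 1L]]] <- counts[comp[chars[i + 1L]]] + 1L
  }
  counts[weights[names(counts)] > 0]
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal pileup row constructor for threshold tests.
pileup_row <- function(ref, counts, chrom = "chr", pos = 100L,
                       phred = 37L) {
  row <- data.frame(chrom = chrom, pos = pos, ref = ref,
                    A = 0L, C = 0L, G = 0L, T = 0L, N = 0L, del = 0L,
                    depth = 0L, phred = phred, stringsAsFactors = FALSE)
  for (b in names(counts)) row[[b]] <- as.integer(counts[[b]])
  row$depth <- sum(row$A, row$C, row$G, row$T, row$N, row$del)
  row
}
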