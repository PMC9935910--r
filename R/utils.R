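# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# IUPAC degenerate codes in the fixed tie-break order A<C<G<T<R<Y<S<W<K<M<B<D<H<V<N;
# the order is already graded by set size, so a linear scan returns the minimal cover.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse complement for plain character vectors (short windows; Biostrings
# handles whole-sequence objects elsewhere).
revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), NULL),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

# Draw a random genome as a character vector of bases with the requested
# G+C fraction; G and C (and A and T) are equiprobable within their pair.
random_genome_chars <- function(length, gc_fraction) {
  sample(DNA_BASES, length, replace = TRUE,
         prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                  gc_fraction / 2, (1 - gc_fraction) / 2))
}

#' Generate a random reference sequence
#'
#' Draws an i.i.d. DNA sequence with a given G+C fraction. Used by the
#' simulators to build E. coli-like and human-mtDNA-like references.
#'
#' @param length Sequence length in bp.
#' @param gc_fraction Fraction of G+C bases in `[0, 1]`.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A single character string of `A/C/G/T`.
#' @export
random_genome <- function(length, gc_fraction = 0.5, seed = NULL) {
  check_count(length, "length")
  check_prob(gc_fraction, "gc_fraction")
  with_seed(seed, paste(random_genome_chars(length, gc_fraction),
                        collapse = ""))
}
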