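# Deamination-context profiling: SNV calling from pileups, strand-normalized
# flanking-context extraction, probability logos and IUPAC preference calls.

#' Call deamination SNVs from a pileup
#'
#' Emits C-to-T and G-to-A single-nucleotide variants passing all three
#' validation thresholds (all strict inequalities): variant frequency
#' `> min_freq`, coverage `> min_cov` reads, and a one-sided binomial
#' p-value `< max_p` against the expected sequencing error,
#' `P(X >= alt_count | depth, error_rate)`. Substitutions other than
#' C-to-T / G-to-A are never deamination calls; the strongest other alt is
#' reported in the `other_alt`/`other_count` side-channel columns.
#'
#' @param pileup Pileup `data.frame` (see [read_pileup()]).
#' @param min_freq Minimum variant frequency (exclusive; default 0.01).
#' @param min_cov Minimum coverage in reads (exclusive; default 50).
#' @param max_p Maximum binomial p-value (exclusive; default 0.01).
#' @param error_rate Expected per-base miscall rate under the null
#'   (default 0.001).
#' @return `data.frame` of variant calls: `chrom`, `pos`, `ref_base`,
#'   `alt_base`, `depth`, `alt_count`, `frequency`, `p_value`, `other_alt`,
#'   `other_count`. Rows of the pileup with non-positive depth are skipped
#'   with a warning.
#' @export
call_variants <- function(pileup, min_freq = 0.01, min_cov = 50,
                          max_p = 0.01, error_rate = 0.001) {
  check_prob(min_freq, "min_freq")
  check_prob(max_p, "max_p")
  check_prob(error_rate, "error_rate")
  bad <- pileup$depth <= 0
  if (any(bad)) {
    warning(sum(bad), " pileup row(s) with non-positive depth skipped")
    pileup <- pileup[!bad, , drop = FALSE]
  }
  cg <- pileup[pileup$ref %in% c("C", "G"), , drop = FALSE]
  if (!nrow(cg)) return(empty_variant_frame())
  alt_base <- ifelse(cg$ref == "C", "T", "A")
  alt_count <- ifelse(cg$ref == "C", cg$T, cg$A)
  freq <- alt_count / cg$depth
  pval <- stats::pbinom(alt_count - 1L, cg$depth, error_rate,
                        lower.tail = FALSE)
  keep <- freq > min_freq & cg$depth > min_cov & pval < max_p
  cg <- cg[keep, , drop = FALSE]
  if (!nrow(cg)) return(empty_variant_frame())
  alt_kept <- alt_base[keep]
  other <- as.matrix(cg[, DNA_BASES])
  # zero out the reference and the deamination alt, keep the best remainder
  for (i in seq_len(nrow(cg))) other[i, c(cg$ref[i], alt_kept[i])] <- 0L
  oi <- max.col(other, ties.method = "first")
  out <- data.frame(chrom = cg$chrom, pos = cg$pos, ref_base = cg$ref,
                    alt_base = alt_base[keep], depth = cg$depth,
                    alt_count = alt_count[keep], frequency = freq[keep],
                    p_value = pval[keep],
                    other_alt = DNA_BASES[oi],
                    other_count = other[cbind(seq_len(nrow(other)), oi)],
                    stringsAsFactors = FALSE)
  out$other_alt[out$other_count == 0L] <- NA_character_
  rownames(out) <- NULL
  out
}

empty_variant_frame <- function() {
  data.frame(chrom = character(), pos = integer(), ref_base = character(),
             alt_base = character(), depth = integer(),
             alt_count = integer(), frequency = numeric(),
             p_value = numeric(), other_alt = character(),
             other_count = integer(), stringsAsFactors = FALSE)
}

#' Extract strand-normalized flanking contexts around deamination SNVs
#'
#' For a C-to-T call the window `reference[pos - flank .. pos + flank]` is
#' returned as-is; for a G-to-A call its reverse complement is returned, so
#' the center is always the deaminated C and offset -1 is its 5' neighbor on
#' the deaminated strand. Variants within `flank` of a contig edge are
#' dropped (no wraparound) and counted in the `n_dropped` attribute.
#'
#' @param variants Variant calls from [call_variants()].
#' @param reference Reference sequence: a character string, or a named
#'   character vector / `DNAStringSet` whose name matches `variants$chrom`.
#' @param flank Flank width in bp on each side (default 5).
#' @param chrom Reference name to check variants against (defaults to the
#'   name of `reference` when it has one).
#' @return Character vector of oriented contexts (length `2 * flank + 1`),
#'   with attribute `n_dropped`.
#' @export
extract_contexts <- function(variants, reference, flank = 5, chrom = NULL) {
  check_count(flank, "flank")
  if (inherits(reference, "XStringSet")) reference <- as.character(reference)
  if (!is.null(names(reference)) && length(reference) == 1L)
    chrom <- chrom %||% sub("\\s.*$", "", names(reference))
  reference <- unname(reference)
  stopifnot(is.character(reference), length(reference) == 1L)
  if (!is.null(chrom) && nrow(variants) &&
      !all(variants$chrom == chrom))
    stop("variant chrom does not match the reference sequence name",
         call. = FALSE)
  L <- nchar(reference)
  ok <- variants$pos - flank >= 1L & variants$pos + flank <= L
  n_dropped <- sum(!ok)
  if (n_dropped)
    message(n_dropped, " variant(s) within ", flank,
            " bp of a contig edge dropped")
  v <- variants[ok, , drop = FALSE]
  ctx <- substring(reference, v$pos - flank, v$pos + flank)
  g <- v$ref_base == "G"
  if (any(g)) ctx[g] <- revcomp(ctx[g])
  structure(ctx, n_dropped = n_dropped)
}

#' Build a position probability matrix from oriented contexts
#'
#' Column-wise base frequencies over windows centered on the deaminated C,
#' with per-offset information content `2 + sum(p * log2(p))` bits.
#'
#' @param contexts Character vector of same-length, odd-length oriented
#'   context strings whose center base is C.
#' @return An object of class `context_profile`: list with `offsets`
#'   (`-flank..flank`), `ppm` (4 x width matrix, rows A/C/G/T, columns sum
#'   to 1), `information` (bits per offset), `n_sites`.
#' @export
build_probability_logo <- function(contexts) {
  contexts <- as.character(contexts)
  if (!length(contexts))
    stop("no sites passed filters", call. = FALSE)
  w <- unique(nchar(contexts))
  if (length(w) != 1L || w %% 2L == 0L)
    stop("contexts must all share one odd length", call. = FALSE)
  flank <- (w - 1L) / 2L
  center <- substr(contexts, flank + 1L, flank + 1L)
  if (!all(center == "C"))
    stop("every context must have C at its center (post-orientation)",
         call. = FALSE)
  m <- matrix(unlist(strsplit(contexts, NULL), use.names = FALSE),
              ncol = w, byrow = TRUE)
  counts <- vapply(seq_len(w), function(j)
    tabulate(match(m[, j], DNA_BASES), 4L), integer(4))
  dimnames(counts) <- list(DNA_BASES, NULL)
  ppm <- counts / length(contexts)
  plog <- ifelse(ppm > 0, ppm * log2(ppm), 0)
  structure(list(offsets = seq.int(-flank, flank),
                 ppm = ppm,
                 information = 2 + colSums(plog),
                 n_sites = length(contexts)),
            class = "context_profile")
}

#' @export
print.context_profile <- function(x, ...) {
  cat(sprintf("Context profile over %d site(s), offsets %d..%d\n",
              x$n_sites, min(x$offsets), max(x$offsets)))
  mat <- round(x$ppm, 3)
  colnames(mat) <- x$offsets
  print(mat)
  invisible(x)
}

#' Classify the -1 base preference as a minimal IUPAC code
#'
#' Returns the IUPAC degenerate code covering the fewest bases whose total
#' probability at the chosen offset reaches `mass_threshold`; ties are broken
#' by the fixed code order A<C<G<T<R<Y<S<W<K<M<B<D<H<V<N. A call of `"T"`
#' means a TC dinucleotide preference, `"D"` a DC (A/G/T) compatibility,
#' `"H"` an HC (A/C/T) compatibility, and so on.
#'
#' @param profile A [build_probability_logo()] result.
#' @param offset Offset to classify (default -1, the 5' neighbor).
#' @param mass_threshold Probability mass the code's bases must reach
#'   (default 0.9).
#' @return A single IUPAC code letter.
#' @export
classify_preference <- function(profile, offset = -1, mass_threshold = 0.9) {
  stopifnot(inherits(profile, "context_profile"))
  check_prob(mass_threshold, "mass_threshold")
  j <- match(offset, profile$offsets)
  if (is.na(j)) stop("offset not present in profile", call. = FALSE)
  p <- profile$ppm[, j]
  for (code in names(IUPAC_SETS)) {
    if (sum(p[IUPAC_SETS[[code]]]) >= mass_threshold) return(code)
  }
  "N"  # unreachable: N always covers total mass 1
}

#' Pileup-to-preference profiling in one call
#'
#' Runs [call_variants()], [extract_contexts()], [build_probability_logo()]
#' and [classify_preference()] with the standard thresholds.
#'
#' @param pileup Pileup `data.frame`.
#' @param reference Reference sequence (string or named vector).
#' @param flank Flank width (default 5).
#' @param ... Passed to [call_variants()].
#' @param mass_threshold Passed to [classify_preference()].
#' @return List with `variants`, `contexts`, `profile`, `preference`.
#' @export
profile_contexts <- function(pileup, reference, flank = 5, ...,
                             mass_threshold = 0.9) {
  variants <- call_variants(pileup, ...)
  contexts <- extract_contexts(variants, reference, flank = flank)
  profile <- build_probability_logo(contexts)
  list(variants = variants, contexts = contexts, profile = profile,
       preference = classify_preference(profile,
                                        mass_threshold = mass_threshold))
}

#' Write a context profile as JSON and a logo matrix TSV
#'
#' The TSV (`offset` then one column per base) is directly consumable by
#' standard logo plotters; the JSON carries the full profile.
#'
#' @param profile A `context_profile`.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_context_profile <- function(profile, json_path = NULL,
                                  tsv_path = NULL) {
  stopifnot(inherits(profile, "context_profile"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(offsets = profile$offsets,
           ppm = as.data.frame(t(profile$ppm)),
           information = profile$information,
           n_sites = profile$n_sites),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(offset = profile$offsets, t(profile$ppm))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(json = json_path, tsv = tsv_path))
}
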