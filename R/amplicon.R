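# Amplicon editing quantification: global affine-gap alignment of reads to
# the reference amplicon, per-position nucleotide percentages, editing
# efficiencies, and windowed indel frequency.

#' Align reads globally to a reference amplicon
#'
#' Optimal Needleman-Wunsch alignment with affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`). The default scores make a
#' short 1-3 bp indel cheaper than three scattered mismatches, which suits
#' base-editing amplicons where true indels are rare and short. Traceback is
#' deterministic.
#'
#' @param reads Character vector (or `DNAStringSet`) of full-length reads.
#' @param amplicon Reference amplicon sequence (character string).
#' @param match,mismatch Substitution scores (defaults +2 / -1). `N` scores
#'   0 against everything.
#' @param gap_open,gap_extend Gap penalties as negative scores (defaults
#'   -6 / -1 per base).
#' @return A `data.frame` of alignment records: `id`, `aligned_read`,
#'   `aligned_ref` (equal-length gapped strings), `score`.
#' @export
align_to_amplicon <- function(reads, amplicon, match = 2, mismatch = -1,
                              gap_open = -6, gap_extend = -1) {
  if (inherits(reads, "XStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  stopifnot(length(reads) >= 1L, all(nchar(reads) >= 1L),
            is.character(amplicon), nchar(amplicon) >= 1L)
  alphabet <- c(DNA_BASES, "N")
  sm <- matrix(mismatch, 5, 5, dimnames = list(alphabet, alphabet))
  diag(sm) <- match
  sm["N", ] <- 0
  sm[, "N"] <- 0
  # amplicon read sets are highly redundant: align each distinct sequence
  # once and expand back to reads
  uniq <- unique(reads)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(uniq), Biostrings::DNAString(amplicon),
    type = "global", substitutionMatrix = sm,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  j <- match(reads, uniq)
  ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
  data.frame(id = ids,
             aligned_read = as.character(Biostrings::alignedPattern(al))[j],
             aligned_ref = as.character(Biostrings::alignedSubject(al))[j],
             score = Biostrings::score(al)[j],
             stringsAsFactors = FALSE)
}

# Map one alignment record onto reference coordinates.
# Returns list(base = per-reference-position call ("A/C/G/T/N/del"),
#              ins_anchor = 0-based interbase coordinates of insertions).
project_alignment <- function(aligned_read, aligned_ref) {
  rp <- strsplit(aligned_read, NULL)[[1]]
  sp <- strsplit(aligned_ref, NULL)[[1]]
  is_ref <- sp != "-"
  refpos <- cumsum(is_ref)
  base <- rp[is_ref]
  base[base == "-"] <- "del"
  list(base = base, ins_anchor = refpos[!is_ref])
}

#' Per-position nucleotide percentage table with editing efficiencies
#'
#' For each reference position, the percentage of reads presenting each base
#' or a deletion (columns sum to 100; insertions do not create reference
#' positions). Editing efficiency is %T at reference-C positions and %A at
#' reference-G positions, `NA` elsewhere.
#'
#' @param alignments Alignment records from [align_to_amplicon()].
#' @param amplicon Reference amplicon sequence.
#' @param min_reads_warn Warn when fewer reads than this are quantified
#'   (default 10000, the recommended minimum amplicon coverage).
#' @return A `data.frame` with columns `pos`, `ref`, `A`, `C`, `G`, `T`,
#'   `N`, `del` (percent) and `efficiency` (percent), with attribute
#'   `n_reads`.
#' @export
nucleotide_percentage_table <- function(alignments, amplicon,
                                        min_reads_warn = 10000) {
  stopifnot(is.data.frame(alignments))
  n <- nrow(alignments)
  if (n < 1L) stop("no alignments supplied", call. = FALSE)
  if (n < min_reads_warn)
    warning("only ", n, " reads quantified; recommended amplicon coverage ",
            "is at least ", min_reads_warn, "x", call. = FALSE)
  amp <- strsplit(toupper(amplicon), NULL)[[1]]
  L <- length(amp)
  keys <- c(DNA_BASES, "N", "del")
  counts <- matrix(0L, nrow = 6L, ncol = L, dimnames = list(keys, NULL))
  for (k in seq_len(n)) {
    pr <- project_alignment(alignments$aligned_read[k],
                            alignments$aligned_ref[k])
    stopifnot(length(pr$base) == L)
    cells <- cbind(match(pr$base, keys), seq_len(L))
    counts[cells] <- counts[cells] + 1L
  }
  pct <- counts / n * 100
  eff <- rep(NA_real_, L)
  eff[amp == "C"] <- pct["T", amp == "C"]
  eff[amp == "G"] <- pct["A", amp == "G"]
  out <- data.frame(pos = seq_len(L), ref = amp,
                    A = pct["A", ], C = pct["C", ], G = pct["G", ],
                    T = pct["T", ], N = pct["N", ], del = pct["del", ],
                    efficiency = eff, stringsAsFactors = FALSE)
  attr(out, "n_reads") <- n
  out
}

#' Fraction of reads with an indel touching a window
#'
#' A read counts if its alignment contains at least one deleted reference
#' base inside the window, or an insertion anchored strictly inside it.
#' The window is 0-based half-open (BED convention) on the amplicon.
#'
#' @param alignments Alignment records from [align_to_amplicon()].
#' @param window A [target_window()] row, or a length-2 numeric
#'   `c(start, end)`.
#' @return The indel frequency as a fraction in `[0, 1]`.
#' @export
indel_frequency <- function(alignments, window) {
  if (is.data.frame(window)) window <- c(window$start[1], window$end[1])
  start <- window[1]; end <- window[2]
  stopifnot(start >= 0, end > start)
  hit <- vapply(seq_len(nrow(alignments)), function(k) {
    ar <- alignments$aligned_read[k]
    as <- alignments$aligned_ref[k]
    if (!grepl("-", ar, fixed = TRUE) && !grepl("-", as, fixed = TRUE))
      return(FALSE)
    pr <- project_alignment(ar, as)
    del_pos <- which(pr$base == "del")          # 1-based reference positions
    if (any(del_pos - 1L >= start & del_pos - 1L < end)) return(TRUE)
    any(pr$ins_anchor > start & pr$ins_anchor < end)
  }, logical(1))
  mean(hit)
}

#' Quantify an amplicon read set end to end
#'
#' Convenience wrapper: align, build the percentage table, and compute the
#' indel frequency over the editing window.
#'
#' @param reads Read sequences (character vector or `DNAStringSet`).
#' @param amplicon Reference amplicon.
#' @param window Editing window for [indel_frequency()] (0-based half-open);
#'   defaults to the span of all C/G positions in the amplicon.
#' @param ... Passed to [align_to_amplicon()].
#' @param min_reads_warn Passed to [nucleotide_percentage_table()].
#' @return List with `table` (the percentage table), `indel_frequency`,
#'   `n_reads`, `alignments`.
#' @export
quantify_amplicon <- function(reads, amplicon, window = NULL, ...,
                              min_reads_warn = 10000) {
  al <- align_to_amplicon(reads, amplicon, ...)
  tab <- nucleotide_percentage_table(al, amplicon,
                                     min_reads_warn = min_reads_warn)
  if (is.null(window)) {
    cg <- which(strsplit(toupper(amplicon), NULL)[[1]] %in% c("C", "G"))
    window <- c(min(cg) - 1L, max(cg))
  }
  list(table = tab, indel_frequency = indel_frequency(al, window),
       n_reads = nrow(al), alignments = al)
}
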