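# SPKK-motif triage of candidate dsDNA deaminases.
#
# Short Ser/Thr-Pro-basic-basic peptides bind A/T-rich minor grooves; their
# presence in a deaminase C-terminus is used as a triage feature for dsDNA
# activity. The default pattern is (S|T) P (K|R) (K|R); the C-terminal
# window and the pattern are configurable because neither is a universal
# constant of the motif family.

SPKK_PATTERN <- "[ST]P[KR][KR]"

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYX", NULL)[[1]]

check_protein <- function(sequence) {
  chars <- strsplit(sequence, NULL)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    stop(sprintf("illegal residue '%s' at position %d", chars[bad[1]],
                 bad[1]), call. = FALSE)
  chars
}

#' Scan a protein C-terminus for SPKK-related motifs
#'
#' Finds all (possibly overlapping) matches of the SPKK-related pattern
#' within the last `cterm_window` residues, left to right, then marks a
#' greedy maximal non-overlapping subset (`kept`) used for counting. With
#' the default pattern overlapping matches cannot actually occur (the basic
#' positions 3-4 and the S/T/P positions 1-2 are disjoint residue sets), so
#' all hits are normally kept.
#'
#' @param sequence Protein sequence (20-letter alphabet plus X).
#' @param cterm_window Number of C-terminal residues scanned (default 50).
#' @param pattern Regular expression for the motif; must match exactly 4
#'   residues.
#' @return A `data.frame` with columns `start` (1-based index in the full
#'   sequence), `peptide` (4 residues), `pattern_id`, `kept` (logical).
#' @examples
#' scan_spkk("MSPKKASPRK")
#' @export
scan_spkk <- function(sequence, cterm_window = 50, pattern = SPKK_PATTERN) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L)
  check_count(cterm_window, "cterm_window")
  check_protein(sequence)
  len <- nchar(sequence)
  cstart <- max(1L, len - as.integer(cterm_window) + 1L)
  region <- substr(sequence, cstart, len)
  m <- gregexpr(paste0("(?=", pattern, ")"), region, perl = TRUE)[[1]]
  empty <- data.frame(start = integer(), peptide = character(),
                      pattern_id = character(), kept = logical(),
                      stringsAsFactors = FALSE)
  if (m[1] < 0) return(empty)
  starts <- cstart + as.integer(m) - 1L
  starts <- starts[starts + 3L <= len]  # lookahead can over-run at the edge
  if (!length(starts)) return(empty)
  peptides <- substring(sequence, starts, starts + 3L)
  kept <- logical(length(starts))
  last_end <- 0L
  for (i in seq_along(starts)) {
    if (starts[i] > last_end) {
      kept[i] <- TRUE
      last_end <- starts[i] + 3L
    }
  }
  data.frame(start = starts, peptide = peptides, pattern_id = peptides,
             kept = kept, stringsAsFactors = FALSE)
}

#' Classify a candidate by its motif count
#'
#' Applies the triage labels: no SPKK-related motif in the C-terminal region
#' gives `"-"`, one gives `"+"`, two or more give `"++"`.
#'
#' @param hits Hit table from [scan_spkk()]; only rows with `kept = TRUE`
#'   are counted (all rows if the column is absent).
#' @return One of `"-"`, `"+"`, `"++"`.
#' @export
classify_candidate <- function(hits) {
  n <- if (is.data.frame(hits)) {
    if ("kept" %in% names(hits)) sum(hits$kept) else nrow(hits)
  } else length(hits)
  c("-", "+", "++")[min(n, 2L) + 1L]
}

# Fraction identical: global alignment maximizing matches (match 1,
# mismatch 0, gap 0), identity = matches / alignment length.
cterm_identity <- function(a, b) {
  sm <- diag(1, length(AA_ALPHABET))
  dimnames(sm) <- list(AA_ALPHABET, AA_ALPHABET)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 0)
  Biostrings::nmatch(al) / nchar(as.character(Biostrings::alignedPattern(al)))
}

#' Rank candidates by score with C-terminal-diversity deduplication
#'
#' Sorts candidates by score (descending; ties broken by id), then walks the
#' list keeping a candidate only if its C-terminal identity to every
#' already-kept candidate is below `identity_threshold` — so among homologs
#' with similar C-termini only the highest-scoring one survives.
#'
#' @param candidates `data.frame` with columns `id`, `sequence`, `score`.
#' @param cterm_window C-terminal window compared (default 50 residues).
#' @param identity_threshold Pairwise identity at or above which two
#'   C-termini are considered redundant, in `(0, 1]` (default 0.5).
#' @return The surviving rows, score-sorted, with columns `id`, `sequence`,
#'   `score` plus `cterm_identity_max` (highest identity to a previously
#'   kept candidate, `NA` for the first).
#' @export
rank_candidates <- function(candidates, cterm_window = 50,
                            identity_threshold = 0.5) {
  stopifnot(is.data.frame(candidates),
            all(c("id", "sequence", "score") %in% names(candidates)))
  if (!(identity_threshold > 0 && identity_threshold <= 1))
    stop("'identity_threshold' must lie in (0, 1]", call. = FALSE)
  ord <- order(-candidates$score, candidates$id)
  cand <- candidates[ord, , drop = FALSE]
  ct <- substr(cand$sequence,
               pmax(1L, nchar(cand$sequence) - as.integer(cterm_window) + 1L),
               nchar(cand$sequence))
  keep <- logical(nrow(cand))
  maxid <- rep(NA_real_, nrow(cand))
  kept_idx <- integer()
  for (i in seq_len(nrow(cand))) {
    ids <- vapply(kept_idx, function(j) cterm_identity(ct[i], ct[j]),
                  numeric(1))
    maxid[i] <- if (length(ids)) max(ids) else NA_real_
    if (!length(ids) || max(ids) < identity_threshold) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out$cterm_identity_max <- maxid[keep]
  rownames(out) <- NULL
  out
}

#' Triage a candidate panel: scan, label, rank
#'
#' Convenience wrapper running [scan_spkk()] and [classify_candidate()] on
#' every sequence and [rank_candidates()] over the panel.
#'
#' @param sequences Named character vector of protein sequences.
#' @param scores Numeric vector of scores, parallel to `sequences` (or a
#'   `data.frame` with `id` and `score`).
#' @param cterm_window,identity_threshold Passed through.
#' @return `data.frame` with `id`, `score`, `n_motifs`, `label`, `kept`.
#' @export
triage_candidates <- function(sequences, scores, cterm_window = 50,
                              identity_threshold = 0.5) {
  ids <- names(sequences)
  if (is.data.frame(scores)) scores <- scores$score[match(ids, scores$id)]
  hits <- lapply(sequences, scan_spkk, cterm_window = cterm_window)
  n_motifs <- vapply(hits, function(h) sum(h$kept), integer(1))
  label <- vapply(hits, classify_candidate, character(1))
  ranked <- rank_candidates(
    data.frame(id = ids, sequence = unname(sequences), score = scores,
               stringsAsFactors = FALSE),
    cterm_window = cterm_window, identity_threshold = identity_threshold)
  out <- data.frame(id = ids, score = scores, n_motifs = unname(n_motifs),
                    label = unname(label), kept = ids %in% ranked$id,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$id), , drop = FALSE]
}
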