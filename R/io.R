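# Readers and writers for the package's plain-text interchange formats.
#
# Coordinate conventions, stated once and used everywhere:
#   * pileup tables, variant tables, truth tables: 1-based positions;
#   * target windows (BED): 0-based half-open intervals.

PILEUP_CORE_COLS <- c("chrom", "pos", "ref", "A", "C", "G", "T", "N", "del",
                      "depth")

#' Write a per-base pileup table to TSV
#'
#' Columns are `chrom pos ref A C G T N del depth` (1-based `pos`), followed
#' by the quality bookkeeping columns (`phred`, and when low-quality calls
#' were injected, `A_lowq..T_lowq` and `lowq_phred`).
#'
#' @param pileup A pileup `data.frame` as produced by the simulators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  stopifnot(all(PILEUP_CORE_COLS %in% names(pileup)))
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-base pileup table from TSV
#'
#' @param path File written by [write_pileup()] (or any TSV with at least the
#'   core `chrom pos ref A C G T N del depth` columns).
#' @return A pileup `data.frame`.
#' @export
read_pileup <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character",
                                         ref = "character"),
                          stringsAsFactors = FALSE)
  missing <- setdiff(PILEUP_CORE_COLS, names(df))
  if (length(missing))
    stop("pileup file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' Read target windows from a BED file
#'
#' Plain 3+ column BED: `chrom start end`, 0-based half-open. Extra columns
#' are ignored.
#'
#' @param path BED file path.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns", call. = FALSE)
  out <- df[, 1:3]
  names(out) <- c("chrom", "start", "end")
  if (any(out$start < 0) || any(out$end <= out$start))
    stop("BED intervals must satisfy 0 <= start < end", call. = FALSE)
  out
}

#' Write target windows to a BED file
#'
#' @param windows `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(windows, path) {
  utils::write.table(windows[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a truth table to TSV
#' @param truth Truth `data.frame` from a simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth()]
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# Write named character sequences as FASTA via Biostrings.
write_fasta <- function(seqs, path, protein = FALSE) {
  set <- if (protein) Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Read (DNA) FASTA into a named character vector.
read_fasta_chr <- function(path, protein = FALSE) {
  set <- if (protein) Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write reads as FASTQ with a fixed quality line
#'
#' All simulated bases carry one PHRED value (the simulators' single-quality
#' model), so the quality line is constant per read.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @param phred PHRED score used for every base (default 37).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, phred = 37L) {
  qchar <- rawToChar(as.raw(33L + as.integer(phred)))
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(qchar, n), character(1)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path,
                              format = "fastq", qualities = quals)
  invisible(path)
}

#' Read amplicon reads from FASTQ or FASTA
#'
#' @param path Read file; format chosen by extension (`.fq`/`.fastq` vs
#'   anything else treated as FASTA). Qualities are not used downstream
#'   (alignment-based quantification).
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
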