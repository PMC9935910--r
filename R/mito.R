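# Mitochondrial genome-wide off-target quantification: per-base C:G -> T:A
# editing frequencies with a PHRED quality filter, on-target and cell-line
# SNV exclusions, off-target calling, and the average off-target editing
# frequency statistic.
#
# Coordinates: windows are 0-based half-open (BED); site positions are
# 1-based, as in every report this package writes.

#' Per-base C:G -> T:A editing frequencies from a pileup
#'
#' Emits only reference-C and reference-G rows. The frequency is the
#' fraction of quality-passing calls that are T (at C rows) or A (at G
#' rows); calls carried at a PHRED value not exceeding `min_phred` (the
#' optional `*_lowq` pileup columns) are excluded from both numerator and
#' denominator. Rows whose quality-passing depth falls below `min_depth`
#' are flagged (`low_depth`), not dropped.
#'
#' @param pileup Pileup `data.frame`.
#' @param reference Reference sequence (character string, or named vector /
#'   `DNAStringSet` of length 1); must match the pileup length and bases.
#' @param min_phred Quality cutoff; only calls with PHRED strictly greater
#'   are counted (default 30).
#' @param min_depth Depth QC threshold (default 3000).
#' @return `data.frame` with `pos` (1-based), `ref_base`, `frequency`,
#'   `depth` (quality-passing), `low_depth` (logical).
#' @export
per_base_editing <- function(pileup, reference, min_phred = 30,
                             min_depth = 3000) {
  if (inherits(reference, "XStringSet")) reference <- as.character(reference)
  reference <- unname(reference)
  stopifnot(is.character(reference), length(reference) == 1L)
  if (nchar(reference) != max(pileup$pos))
    stop("reference length does not match the pileup", call. = FALSE)
  refv <- strsplit(reference, NULL)[[1]][pileup$pos]
  if (!all(refv == pileup$ref))
    stop("pileup ref column disagrees with the reference sequence",
         call. = FALSE)

  counts <- as.matrix(pileup[, DNA_BASES])
  hi_ok <- (pileup$phred %||% rep(37L, nrow(pileup))) > min_phred
  lq_cols <- paste0(DNA_BASES, "_lowq")
  if (all(lq_cols %in% names(pileup))) {
    lowq <- as.matrix(pileup[, lq_cols])
    lq_ok <- (pileup$lowq_phred %||% rep(0L, nrow(pileup))) > min_phred
    # subtract low-quality calls unless their PHRED passes the cutoff
    counts <- counts - lowq * ifelse(lq_ok, 0L, 1L)
  }
  counts <- counts * ifelse(hi_ok, 1L, 0L)

  is_cg <- pileup$ref %in% c("C", "G")
  counts <- counts[is_cg, , drop = FALSE]
  ref <- pileup$ref[is_cg]
  qdepth <- rowSums(counts)
  alt <- ifelse(ref == "C", counts[, "T"], counts[, "A"])
  freq <- ifelse(qdepth > 0, alt / qdepth, 0)
  data.frame(pos = pileup$pos[is_cg], ref_base = ref, frequency = freq,
             depth = qdepth, low_depth = qdepth < min_depth,
             stringsAsFactors = FALSE)
}

in_any_window <- function(pos, windows) {
  if (is.null(windows) || !nrow(windows)) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(windows)))
    hit <- hit | (pos - 1L >= windows$start[i] & pos - 1L < windows$end[i])
  hit
}

#' Exclude on-target windows and cell-line SNVs
#'
#' Removes sites inside any target window (the spacing region between the
#' two TALE binding sites) and sites whose untreated-sample frequency is
#' strictly greater than `snv_threshold` (fixed SNVs of the cell line).
#' Removed sites leave both the numerator and the denominator of the
#' downstream average.
#'
#' @param freqs Treated-sample site table from [per_base_editing()].
#' @param windows `data.frame` of target windows (`chrom`, `start`, `end`,
#'   0-based half-open), or `NULL`/empty for TALE-free deaminase pairs.
#' @param untreated Untreated-sample site table covering the same positions.
#' @param snv_threshold Untreated frequency above which a site is treated as
#'   a cell-line SNV (exclusive; default 0.5).
#' @return The filtered site table, with attributes `n_window_excluded` and
#'   `n_snv_excluded`.
#' @export
exclude_sites <- function(freqs, windows, untreated, snv_threshold = 0.5) {
  check_prob(snv_threshold, "snv_threshold")
  u <- untreated$frequency[match(freqs$pos, untreated$pos)]
  if (anyNA(u))
    stop("untreated sample does not cover all treated positions",
         call. = FALSE)
  in_win <- in_any_window(freqs$pos, windows)
  is_snv <- u > snv_threshold
  out <- freqs[!in_win & !is_snv, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_window_excluded") <- sum(in_win)
  attr(out, "n_snv_excluded") <- sum(is_snv & !in_win)
  out
}

#' Call off-target sites
#'
#' Sites (after exclusions) whose editing frequency is strictly greater
#' than `min_freq` (default 0.1%), sorted by position.
#'
#' @param filtered Output of [exclude_sites()].
#' @param min_freq Off-target calling threshold (exclusive; default 0.001).
#' @return The called rows, position-sorted.
#' @export
call_offtargets <- function(filtered, min_freq = 0.001) {
  check_prob(min_freq, "min_freq")
  out <- filtered[filtered$frequency > min_freq, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average off-target editing frequency
#'
#' The sum of editing frequencies over all called off-target sites divided
#' by the total number of retained (non-target, non-SNV) C:G bases — so
#' genomes with many clean C:G positions dilute a fixed amount of off-target
#' editing.
#'
#' @param offtargets Called off-target sites ([call_offtargets()] output, or
#'   any table with a `frequency` column; a bare numeric vector also works).
#' @param total_nontarget_CG Number of C:G bases surviving the exclusions
#'   (> 0).
#' @return The average off-target editing frequency (fraction).
#' @export
average_offtarget_frequency <- function(offtargets, total_nontarget_CG) {
  if (is.data.frame(offtargets)) offtargets <- offtargets$frequency
  if (!is.numeric(total_nontarget_CG) || total_nontarget_CG <= 0)
    stop("'total_nontarget_CG' must be a positive count", call. = FALSE)
  sum(offtargets) / total_nontarget_CG
}

#' Genome-track plot data for mtDNA-wide editing
#'
#' Sites with editing frequency strictly above `min_plot_freq` (default 1%),
#' labelled on-target or off-target by window membership, position-sorted —
#' ready for a genome-track plot.
#'
#' @param freqs Site table from [per_base_editing()].
#' @param windows Target windows (`NULL` for none).
#' @param min_plot_freq Plot inclusion threshold (exclusive; default 0.01).
#' @return `data.frame` with `pos`, `frequency`, `label`
#'   (`"on_target"`/`"off_target"`).
#' @export
mtdna_wide_plot_data <- function(freqs, windows, min_plot_freq = 0.01) {
  check_prob(min_plot_freq, "min_plot_freq")
  keep <- freqs$frequency > min_plot_freq
  out <- data.frame(pos = freqs$pos[keep],
                    frequency = freqs$frequency[keep],
                    label = ifelse(in_any_window(freqs$pos[keep], windows),
                                   "on_target", "off_target"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full mitochondrial off-target summary
#'
#' Runs the whole chain — per-base frequencies for treated and untreated
#' pileups, exclusions, off-target calling, the average statistic and the
#' plot table — and returns one summary object.
#'
#' @param treated,untreated Pileup `data.frame`s sharing the reference.
#' @param reference Reference sequence.
#' @param windows Target windows (`NULL` for TALE-free pairs).
#' @param min_phred,min_depth Passed to [per_base_editing()].
#' @param snv_threshold Passed to [exclude_sites()].
#' @param min_freq Passed to [call_offtargets()].
#' @param min_plot_freq Passed to [mtdna_wide_plot_data()].
#' @return An `offtarget_summary` list: `offtarget_sites`, `n_offtarget`,
#'   `total_nontarget_CG`, `average_frequency`, `plot_sites`,
#'   `n_window_excluded`, `n_snv_excluded`.
#' @export
summarize_offtargets <- function(treated, untreated, reference,
                                 windows = NULL, min_phred = 30,
                                 min_depth = 3000, snv_threshold = 0.5,
                                 min_freq = 0.001, min_plot_freq = 0.01) {
  ft <- per_base_editing(treated, reference, min_phred, min_depth)
  fu <- per_base_editing(untreated, reference, min_phred, min_depth)
  filtered <- exclude_sites(ft, windows, fu, snv_threshold)
  ot <- call_offtargets(filtered, min_freq)
  structure(list(
    offtarget_sites = ot,
    n_offtarget = nrow(ot),
    total_nontarget_CG = nrow(filtered),
    average_frequency = average_offtarget_frequency(ot, nrow(filtered)),
    plot_sites = mtdna_wide_plot_data(ft, windows, min_plot_freq),
    n_window_excluded = attr(filtered, "n_window_excluded"),
    n_snv_excluded = attr(filtered, "n_snv_excluded")),
    class = "offtarget_summary")
}

#' @export
print.offtarget_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Off-target summary: %d site(s) over %d retained non-target C:G ",
    "bases\naverage off-target editing frequency: %.4g\n"),
    x$n_offtarget, x$total_nontarget_CG, x$average_frequency))
  invisible(x)
}

#' Write an off-target summary to disk
#'
#' @param summary An `offtarget_summary`.
#' @param json_path Summary JSON path (`NULL` to skip).
#' @param sites_path Off-target site TSV path (`NULL` to skip).
#' @param plot_path Plot-data TSV path (`NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_offtarget_summary <- function(summary, json_path = NULL,
                                    sites_path = NULL, plot_path = NULL) {
  stopifnot(inherits(summary, "offtarget_summary"))
  if (!is.null(json_path))
    jsonlite::write_json(
      list(n_offtarget = summary$n_offtarget,
           total_nontarget_CG = summary$total_nontarget_CG,
           average_frequency = summary$average_frequency,
           n_window_excluded = summary$n_window_excluded,
           n_snv_excluded = summary$n_snv_excluded),
      json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(sites_path))
    utils::write.table(summary$offtarget_sites, sites_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(plot_path))
    utils::write.table(summary$plot_sites, plot_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(list(json = json_path, sites = sites_path, plot = plot_path))
}
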