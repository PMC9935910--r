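# Pipeline orchestration: run simulators and analysis stages from one
# validated config, writing every result to disk plus a checksum manifest.
# Logging goes to stderr; results only ever live on disk.

# Allowed parameter keys per stage (the schema). Defaults mirror the
# analysis thresholds: variant frequency > 0.01, coverage > 50, p < 0.01,
# PHRED > 30, untreated SNV > 0.5, off-target > 0.001, plot > 0.01.
STAGE_SCHEMA <- list(
  simulate = c("what", "length", "gc_fraction", "weights", "base_rate",
               "depth", "error_rate", "mut_freq", "chrom",
               "genome_length", "window_start", "window_end",
               "on_target_rates", "bystander_rates", "n_offtarget_sites",
               "offtarget_freq_range", "cellline_snv_sites",
               "amplicon", "edit_rates", "indel_rate", "n_reads",
               "read_error", "motif_plan", "cterm_window"),
  `scan-motifs` = c("fasta", "scores", "cterm_window", "identity"),
  `context-profile` = c("pileup", "ref", "flank", "min_freq", "min_cov",
                        "max_p", "error_rate", "mass_threshold"),
  `amplicon-edit` = c("reads", "amplicon", "window_start", "window_end",
                      "match", "mismatch", "gap_open", "gap_extend"),
  `mito-offtarget` = c("treated", "untreated", "ref", "windows", "min_freq",
                       "snv_threshold", "min_phred", "min_depth",
                       "min_plot_freq")
)

log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

validate_stage <- function(stage) {
  if (is.null(stage$stage) || !stage$stage %in% names(STAGE_SCHEMA))
    stop("unknown or missing stage name: ",
         stage$stage %||% "<none>", call. = FALSE)
  params <- stage$params %||% list()
  unknown <- setdiff(names(params), STAGE_SCHEMA[[stage$stage]])
  if (length(unknown))
    stop(sprintf("unknown parameter key(s) for stage '%s': %s", stage$stage,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  params
}

resolve_path <- function(p, outdir) {
  if (file.exists(p)) p else file.path(outdir, p)
}

run_stage_simulate <- function(params, dir, seed) {
  what <- params$what %||% "mutagenized_genome"
  if (what == "mutagenized_genome") {
    pref <- context_preference(unlist(params$weights %||%
                                        c(A = 0, C = 0, G = 0, T = 1)),
                               params$base_rate %||% 0.02)
    sim <- simulate_mutagenized_genome(
      length = params$length %||% 100000,
      gc_fraction = params$gc_fraction %||% 0.5, pref = pref,
      depth = params$depth %||% 100,
      error_rate = params$error_rate %||% 0.001,
      mut_freq = params$mut_freq %||% 0.5, seed = seed,
      chrom = params$chrom %||% "sim_chr")
    write_fasta(stats::setNames(sim$reference, params$chrom %||% "sim_chr"),
                file.path(dir, "reference.fa"))
    write_pileup(sim$pileup, file.path(dir, "pileup.tsv"))
    write_truth(sim$truth, file.path(dir, "truth.tsv"))
  } else if (what == "mito_pileups") {
    chrom <- params$chrom %||% "chrM"
    spec <- mito_sim_spec(
      genome_length = params$genome_length %||% 16569,
      target_window = target_window(chrom,
                                    params$window_start %||% 5000,
                                    params$window_end %||% 5014),
      on_target_rates = unlist(params$on_target_rates %||% c(`5007` = 0.4)),
      bystander_rates = unlist(params$bystander_rates),
      n_offtarget_sites = params$n_offtarget_sites %||% 20,
      offtarget_freq_range = unlist(params$offtarget_freq_range %||%
                                      c(0.002, 0.05)),
      cellline_snv_sites = unlist(params$cellline_snv_sites %||%
                                    c(`12000` = 0.8)),
      depth = params$depth %||% 3000,
      error_rate = params$error_rate %||% 1e-4,
      gc_fraction = params$gc_fraction %||% 0.44,
      seed = seed, chrom = chrom)
    sim <- simulate_mito_pileups(spec)
    write_fasta(stats::setNames(sim$reference, chrom),
                file.path(dir, "reference.fa"))
    write_pileup(sim$treated, file.path(dir, "treated.tsv"))
    write_pileup(sim$untreated, file.path(dir, "untreated.tsv"))
    write_truth(sim$truth, file.path(dir, "truth.tsv"))
    write_bed(spec$target_window, file.path(dir, "windows.bed"))
  } else if (what == "amplicon_reads") {
    reads <- simulate_amplicon_reads(
      amplicon = params$amplicon,
      edit_rates = unlist(params$edit_rates),
      indel_rate = params$indel_rate %||% 0,
      n_reads = params$n_reads %||% 10000,
      read_error = params$read_error %||% 0.001, seed = seed)
    write_fasta(stats::setNames(params$amplicon, "amplicon"),
                file.path(dir, "amplicon.fa"))
    write_fastq(reads, file.path(dir, "reads.fastq"))
  } else if (what == "candidate_proteins") {
    gen <- generate_candidate_proteins(
      motif_plan = unlist(params$motif_plan),
      cterm_window = params$cterm_window %||% 50, seed = seed)
    write_fasta(gen$sequences, file.path(dir, "candidates.fa"),
                protein = TRUE)
    write_truth(gen$truth, file.path(dir, "truth.tsv"))
    utils::write.table(gen$truth[, c("id", "score")],
                       file.path(dir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else stop("unknown simulate target: ", what, call. = FALSE)
  invisible(NULL)
}

run_stage_scan_motifs <- function(params, dir, outdir) {
  seqs <- read_fasta_chr(resolve_path(params$fasta, outdir), protein = TRUE)
  scores <- utils::read.table(resolve_path(params$scores, outdir),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  res <- triage_candidates(seqs, scores,
                           cterm_window = params$cterm_window %||% 50,
                           identity_threshold = params$identity %||% 0.5)
  utils::write.table(res, file.path(dir, "motif_triage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

run_stage_context_profile <- function(params, dir, outdir) {
  pileup <- read_pileup(resolve_path(params$pileup, outdir))
  ref <- read_fasta_chr(resolve_path(params$ref, outdir))
  res <- profile_contexts(pileup, ref,
                          flank = params$flank %||% 5,
                          min_freq = params$min_freq %||% 0.01,
                          min_cov = params$min_cov %||% 50,
                          max_p = params$max_p %||% 0.01,
                          error_rate = params$error_rate %||% 0.001,
                          mass_threshold = params$mass_threshold %||% 0.9)
  utils::write.table(res$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_context_profile(res$profile,
                        json_path = file.path(dir, "context_profile.json"),
                        tsv_path = file.path(dir, "logo_matrix.tsv"))
  jsonlite::write_json(list(preference = res$preference,
                            n_sites = res$profile$n_sites),
                       file.path(dir, "preference.json"),
                       auto_unbox = TRUE, digits = NA)
}

run_stage_amplicon_edit <- function(params, dir, outdir) {
  reads <- read_reads(resolve_path(params$reads, outdir))
  amp <- read_fasta_chr(resolve_path(params$amplicon, outdir))[[1]]
  window <- if (!is.null(params$window_start))
    c(params$window_start, params$window_end) else NULL
  res <- quantify_amplicon(reads, amp, window = window,
                           match = params$match %||% 2,
                           mismatch = params$mismatch %||% -1,
                           gap_open = params$gap_open %||% -6,
                           gap_extend = params$gap_extend %||% -1)
  utils::write.table(res$table, file.path(dir, "editing_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_reads = res$n_reads,
                            indel_frequency = res$indel_frequency),
                       file.path(dir, "amplicon_summary.json"),
                       auto_unbox = TRUE, digits = NA)
}

run_stage_mito_offtarget <- function(params, dir, outdir) {
  treated <- read_pileup(resolve_path(params$treated, outdir))
  untreated <- read_pileup(resolve_path(params$untreated, outdir))
  ref <- read_fasta_chr(resolve_path(params$ref, outdir))
  windows <- if (!is.null(params$windows))
    read_bed(resolve_path(params$windows, outdir)) else NULL
  res <- summarize_offtargets(
    treated, untreated, ref, windows,
    min_phred = params$min_phred %||% 30,
    min_depth = params$min_depth %||% 3000,
    snv_threshold = params$snv_threshold %||% 0.5,
    min_freq = params$min_freq %||% 0.001,
    min_plot_freq = params$min_plot_freq %||% 0.01)
  write_offtarget_summary(res,
                          json_path = file.path(dir, "offtarget_summary.json"),
                          sites_path = file.path(dir, "offtarget_sites.tsv"),
                          plot_path = file.path(dir, "plot_data.tsv"))
}

#' Run a multi-stage pipeline from a config
#'
#' Executes the configured stages in order, writing each stage's outputs
#' under `<outdir>/<index>_<stage>/` and a `manifest.json` recording the
#' config, seed, package version and an MD5 checksum of every output file.
#' Re-running with the same config and seed reproduces byte-identical
#' TSV/JSON/FASTA outputs. Unknown stage names or parameter keys fail
#' validation with a message naming the offender.
#'
#' @param config A YAML file path, or an equivalent list, with fields
#'   `seed`, `outdir` (optional, overridable) and `stages` (list of
#'   `list(stage = <name>, params = <named list>)`). Stage names:
#'   `simulate`, `scan-motifs`, `context-profile`, `amplicon-edit`,
#'   `mito-offtarget`. Relative input paths are resolved against `outdir`,
#'   so stages can consume earlier stages' files.
#' @param outdir Output directory (overrides the config).
#' @param seed Integer seed (overrides the config; default 1).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("missing input file: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  known_top <- c("seed", "outdir", "stages")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$stages) || !length(config$stages))
    stop("config must declare at least one stage", call. = FALSE)
  outdir <- outdir %||% config$outdir %||%
    stop("no output directory given", call. = FALSE)
  seed <- seed %||% config$seed %||% 1L
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package = "deamprofiler",
                   version = as.character(utils::packageVersion("deamprofiler")),
                   seed = seed, stages = list())
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    params <- validate_stage(st)
    sdir <- file.path(outdir, sprintf("%02d_%s", i, st$stage))
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    log_stage(st$stage, "running (outputs in ", sdir, ")")
    switch(st$stage,
      simulate = run_stage_simulate(params, sdir, seed),
      `scan-motifs` = run_stage_scan_motifs(params, sdir, outdir),
      `context-profile` = run_stage_context_profile(params, sdir, outdir),
      `amplicon-edit` = run_stage_amplicon_edit(params, sdir, outdir),
      `mito-offtarget` = run_stage_mito_offtarget(params, sdir, outdir))
    files <- list.files(sdir, full.names = TRUE)
    sums <- as.list(tools::md5sum(files))
    names(sums) <- basename(files)
    manifest$stages[[length(manifest$stages) + 1L]] <-
      list(stage = st$stage, params = params, dir = sdir, outputs = sums)
    log_stage(st$stage, "done (", length(files), " file(s))")
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
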