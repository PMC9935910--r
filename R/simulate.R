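# Synthetic-data module: generators with known ground truth for every
# downstream stage. The random model is deliberately pileup-level: per-site
# planted frequencies are deterministic given the spec, read sampling is
# binomial per position, and no read-length or mapping artifacts are modeled.

#' Sequence-context preference of a deaminase
#'
#' Relative deamination propensity by the base immediately 5' of the target
#' cytosine, read on the deaminated strand, plus a per-cytosine base rate.
#' Weights are normalized internally so the most-preferred context is planted
#' at exactly `base_rate`.
#'
#' @param weights Named non-negative numeric vector with entries for all of
#'   `A`, `C`, `G`, `T`; at least one must be positive.
#' @param base_rate Per-eligible-cytosine mutation probability in `[0, 1]`.
#' @return An object of class `context_preference`.
#' @examples
#' context_preference(c(A = 0, C = 0, G = 0, T = 1), base_rate = 0.02)
#' @export
context_preference <- function(weights = c(A = 0, C = 0, G = 0, T = 1),
                               base_rate = 0.02) {
  if (!all(DNA_BASES %in% names(weights)))
    stop("'weights' must have entries named A, C, G, T", call. = FALSE)
  w <- as.numeric(weights[DNA_BASES])
  names(w) <- DNA_BASES
  if (any(is.na(w)) || any(w < 0))
    stop("'weights' must be non-negative numbers", call. = FALSE)
  if (all(w == 0))
    stop("'weights' must have at least one positive entry", call. = FALSE)
  check_prob(base_rate, "base_rate")
  structure(list(weights = w, base_rate = base_rate),
            class = "context_preference")
}

# Draw a pileup around deterministic planted alt frequencies.
# `alt_freq` is a numeric vector named by 1-based position; the alt base is
# T at reference C and A at reference G. Counts at each row sum to `depth`.
sample_pileup <- function(genome_chars, chrom, depth, error_rate,
                          alt_freq = NULL, phred = 37L) {
  L <- length(genome_chars)
  ref <- genome_chars
  f <- numeric(L)
  if (length(alt_freq)) f[as.integer(names(alt_freq))] <- unname(alt_freq)

  alt_n <- integer(L)
  idx <- which(f > 0)
  if (length(idx)) alt_n[idx] <- stats::rbinom(length(idx), depth, f[idx])

  err <- stats::rbinom(L, depth - alt_n, error_rate)
  e1 <- stats::rbinom(L, err, 1 / 3)
  e2 <- stats::rbinom(L, err - e1, 1 / 2)
  e3 <- err - e1 - e2

  counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, DNA_BASES))
  ri <- match(ref, DNA_BASES)
  others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  oth <- others[ri, , drop = FALSE]
  rows <- seq_len(L)
  counts[cbind(rows, oth[, 1])] <- e1
  counts[cbind(rows, oth[, 2])] <- e2
  counts[cbind(rows, oth[, 3])] <- e3
  if (length(idx)) {
    ai <- ifelse(ref[idx] == "C", 4L, 1L)  # T at C rows, A at G rows
    cells <- cbind(idx, ai)
    counts[cells] <- counts[cells] + alt_n[idx]
  }
  counts[cbind(rows, ri)] <- depth - alt_n - err

  data.frame(chrom = chrom, pos = rows, ref = ref,
             A = as.integer(counts[, "A"]), C = as.integer(counts[, "C"]),
             G = as.integer(counts[, "G"]), T = as.integer(counts[, "T"]),
             N = 0L, del = 0L, depth = as.integer(depth),
             phred = as.integer(phred), stringsAsFactors = FALSE)
}

#' Simulate a mutagenized genome with context-dependent C-to-T mutations
#'
#' Emulates whole-genome sequencing of a UNG-deficient host overexpressing a
#' dsDNA cytidine deaminase: strand-symmetric C-to-T / G-to-A mutations are
#' planted so that the base 5' of the deaminated cytosine (read on the
#' deaminated strand) follows the preference vector, and a pileup is drawn
#' around the planted frequencies with uniform sequencing error.
#'
#' A plus-strand C at position `i` is eligible with context base
#' `genome[i-1]`; a plus-strand G at `i` is a minus-strand C whose context
#' base is the complement of `genome[i+1]`. Each eligible site is planted
#' independently with probability `base_rate * w / max(w)`.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc_fraction G+C fraction of the random reference.
#' @param pref A [context_preference()].
#' @param depth Sequencing depth per base (>= 50).
#' @param error_rate Per-base miscall probability (uniform over the three
#'   non-reference bases).
#' @param mut_freq Planted variant frequency at every mutated site (the
#'   population fraction carrying the mutation); deterministic given the spec.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   outputs.
#' @param chrom Reference sequence name.
#' @return A list with elements `reference` (character string), `pileup`
#'   (data.frame), and `truth` (data.frame with one row per planted site:
#'   `pos`, `ref_base`, `strand` of the deaminated C, `context` = 5'
#'   neighbor on the deaminated strand, `programmed_frequency`).
#' @export
simulate_mutagenized_genome <- function(length = 100000, gc_fraction = 0.5,
                                        pref = context_preference(),
                                        depth = 100, error_rate = 0.001,
                                        mut_freq = 0.5, seed = 1,
                                        chrom = "sim_chr") {
  check_count(length, "length", min = 1000L)
  check_count(depth, "depth", min = 50L)
  check_prob(gc_fraction, "gc_fraction")
  check_prob(error_rate, "error_rate")
  check_prob(mut_freq, "mut_freq")
  stopifnot(inherits(pref, "context_preference"))

  with_seed(seed, {
    genome <- random_genome_chars(length, gc_fraction)
    w <- pref$weights / max(pref$weights)

    # Plus-strand C sites (context = base at i-1, plus strand).
    cpos <- which(genome == "C")
    cpos <- cpos[cpos >= 2L]
    cctx <- genome[cpos - 1L]
    # Plus-strand G sites = minus-strand C (context = complement of i+1).
    gpos <- which(genome == "G")
    gpos <- gpos[gpos <= length - 1L]
    gctx <- unname(COMPLEMENT[genome[gpos + 1L]])

    pc <- pref$base_rate * w[cctx]
    pg <- pref$base_rate * w[gctx]
    hitc <- stats::runif(base::length(cpos)) < pc
    hitg <- stats::runif(base::length(gpos)) < pg

    truth <- data.frame(
      pos = c(cpos[hitc], gpos[hitg]),
      ref_base = c(rep("C", sum(hitc)), rep("G", sum(hitg))),
      strand = c(rep("+", sum(hitc)), rep("-", sum(hitg))),
      context = c(cctx[hitc], gctx[hitg]),
      programmed_frequency = rep(mut_freq, sum(hitc) + sum(hitg)),
      stringsAsFactors = FALSE)
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL

    alt_freq <- if (nrow(truth))
      stats::setNames(rep(mut_freq, nrow(truth)), truth$pos) else NULL
    pileup <- sample_pileup(genome, chrom, depth, error_rate, alt_freq)

    list(reference = paste(genome, collapse = ""), pileup = pileup,
         truth = truth)
  })
}

#' Target window between two TALE binding sites
#'
#' The spacing region where on-target editing occurs, as a 0-based half-open
#' interval on a named sequence (BED convention).
#'
#' @param chrom Sequence name.
#' @param start,end Interval bounds, `0 <= start < end`.
#' @return A `data.frame` with one row (`chrom`, `start`, `end`) usable
#'   anywhere a window list is accepted.
#' @export
target_window <- function(chrom, start, end) {
  if (!(start >= 0 && start < end))
    stop("window must satisfy 0 <= start < end", call. = FALSE)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Specification for a simulated mitochondrial editing experiment
#'
#' Describes treated/untreated pileups over an mtDNA-like genome: on-target
#' edits (and optional bystanders) inside the spacing window, sparse
#' off-target sites outside it, fixed cell-line SNVs present in both samples,
#' and uniform sequencing error.
#'
#' @param genome_length Genome size in bp (default 16569, human-mtDNA-like;
#'   treated as linear for windowing).
#' @param target_window A [target_window()] row.
#' @param on_target_rates Named numeric vector, 1-based position ->
#'   editing frequency, positions inside the window.
#' @param bystander_rates Optional named numeric vector of additional edited
#'   cytosines inside the window.
#' @param n_offtarget_sites Number of off-target sites to plant outside the
#'   window.
#' @param offtarget_freq_range Length-2 numeric, uniform range of off-target
#'   frequencies.
#' @param cellline_snv_sites Named numeric vector, position -> frequency
#'   (> 0.5), present in both treated and untreated samples.
#' @param depth Reads per base (> 0).
#' @param error_rate Per-base miscall probability (default 1e-4; the residual
#'   rate after a PHRED>30 call filter).
#' @param gc_fraction G+C fraction of the random reference (default 0.44,
#'   human-mtDNA-like).
#' @param seed Integer seed.
#' @param chrom Sequence name (default "chrM").
#' @return An object of class `mito_sim_spec`.
#' @export
mito_sim_spec <- function(genome_length = 16569,
                          target_window = deamprofiler::target_window(
                            "chrM", 5000L, 5014L),
                          on_target_rates = c(`5007` = 0.4),
                          bystander_rates = NULL,
                          n_offtarget_sites = 20,
                          offtarget_freq_range = c(0.002, 0.05),
                          cellline_snv_sites = c(`12000` = 0.8),
                          depth = 3000, error_rate = 1e-4,
                          gc_fraction = 0.44, seed = 1, chrom = "chrM") {
  check_count(genome_length, "genome_length")
  check_count(depth, "depth")
  check_prob(error_rate, "error_rate")
  check_prob(gc_fraction, "gc_fraction")
  n_offtarget_sites <- check_count(n_offtarget_sites, "n_offtarget_sites",
                                   min = 0L)
  stopifnot(is.data.frame(target_window),
            nrow(target_window) == 1L,
            target_window$end <= genome_length)
  for (nm in c("on_target_rates", "bystander_rates")) {
    v <- get(nm)
    if (length(v)) {
      if (any(v < 0 | v > 1))
        stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
      p0 <- as.integer(names(v)) - 1L  # 0-based
      if (any(p0 < target_window$start | p0 >= target_window$end))
        stop(sprintf("'%s' positions must lie inside the target window", nm),
             call. = FALSE)
    }
  }
  if (any(offtarget_freq_range < 0 | offtarget_freq_range > 1) ||
      offtarget_freq_range[1] > offtarget_freq_range[2])
    stop("'offtarget_freq_range' must be an increasing pair in [0, 1]",
         call. = FALSE)
  if (length(cellline_snv_sites)) {
    if (any(cellline_snv_sites <= 0.5 | cellline_snv_sites > 1))
      stop("'cellline_snv_sites' frequencies must be > 0.5 and <= 1",
           call. = FALSE)
    p0 <- as.integer(names(cellline_snv_sites)) - 1L
    if (any(p0 >= target_window$start & p0 < target_window$end))
      stop("'cellline_snv_sites' must lie outside the target window",
           call. = FALSE)
  }
  structure(list(genome_length = as.integer(genome_length),
                 target_window = target_window,
                 on_target_rates = on_target_rates,
                 bystander_rates = bystander_rates,
                 n_offtarget_sites = n_offtarget_sites,
                 offtarget_freq_range = offtarget_freq_range,
                 cellline_snv_sites = cellline_snv_sites,
                 depth = as.integer(depth), error_rate = error_rate,
                 gc_fraction = gc_fraction, seed = seed, chrom = chrom),
            class = "mito_sim_spec")
}

#' Simulate treated and untreated mitochondrial pileups
#'
#' The untreated pileup carries only sequencing error plus the cell-line
#' SNVs; the treated pileup additionally carries on-target, bystander and
#' off-target C-to-T / G-to-A frequencies. Both share the reference and
#' depth. The genome is forced to C at specified edit/SNV positions that the
#' random draw did not make C or G, so programmed sites are always C:G pairs.
#'
#' @param spec A [mito_sim_spec()].
#' @return A list with `reference`, `treated`, `untreated` (pileup
#'   data.frames) and `truth` (data.frame: `pos`, `kind` in
#'   `on_target`/`bystander`/`off_target`/`cellline_snv`,
#'   `programmed_frequency`).
#' @export
simulate_mito_pileups <- function(spec) {
  stopifnot(inherits(spec, "mito_sim_spec"))
  with_seed(spec$seed, {
    genome <- random_genome_chars(spec$genome_length, spec$gc_fraction)

    fixed <- c(as.integer(names(spec$on_target_rates) %||% character()),
               as.integer(names(spec$bystander_rates) %||% character()),
               as.integer(names(spec$cellline_snv_sites) %||% character()))
    force_c <- fixed[!genome[fixed] %in% c("C", "G")]
    genome[force_c] <- "C"

    win <- spec$target_window
    cg <- which(genome %in% c("C", "G"))
    in_win <- cg - 1L >= win$start & cg - 1L < win$end
    avail <- setdiff(cg[!in_win], fixed)
    if (spec$n_offtarget_sites > length(avail))
      stop("requested off-target sites exceed available non-target C/G ",
           "positions", call. = FALSE)
    off_pos <- sort(sample(avail, spec$n_offtarget_sites))
    off_freq <- stats::runif(spec$n_offtarget_sites,
                             spec$offtarget_freq_range[1],
                             spec$offtarget_freq_range[2])

    truth <- rbind(
      if (length(spec$on_target_rates))
        data.frame(pos = as.integer(names(spec$on_target_rates)),
                   kind = "on_target",
                   programmed_frequency = unname(spec$on_target_rates)),
      if (length(spec$bystander_rates))
        data.frame(pos = as.integer(names(spec$bystander_rates)),
                   kind = "bystander",
                   programmed_frequency = unname(spec$bystander_rates)),
      if (spec$n_offtarget_sites > 0)
        data.frame(pos = off_pos, kind = "off_target",
                   programmed_frequency = off_freq),
      if (length(spec$cellline_snv_sites))
        data.frame(pos = as.integer(names(spec$cellline_snv_sites)),
                   kind = "cellline_snv",
                   programmed_frequency = unname(spec$cellline_snv_sites)))
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL

    snv <- spec$cellline_snv_sites
    edit <- truth[truth$kind != "cellline_snv", , drop = FALSE]
    treated_f <- c(snv %||% numeric(),
                   stats::setNames(edit$programmed_frequency, edit$pos))

    # The samples are paired: the treated pileup shares the untreated draws
    # (including the cell-line SNV counts) everywhere except at edited
    # positions, which are redrawn around their programmed frequencies.
    untreated <- sample_pileup(genome, spec$chrom, spec$depth,
                               spec$error_rate, snv)
    redraw <- sample_pileup(genome, spec$chrom, spec$depth,
                            spec$error_rate, treated_f)
    treated <- untreated
    if (nrow(edit)) treated[edit$pos, ] <- redraw[edit$pos, ]

    list(reference = paste(genome, collapse = ""), treated = treated,
         untreated = untreated, truth = truth)
  })
}

#' Simulate amplicon reads with programmed editing and indels
#'
#' Each read independently carries a C-to-T (or G-to-A at reference-G
#' positions) conversion at each edit position with its programmed rate; with
#' probability `indel_rate` a 1-3 bp insertion or deletion is placed
#' uniformly inside the window spanned by the edit positions; each base is
#' then miscalled with probability `read_error`.
#'
#' @param amplicon Reference amplicon sequence (character string).
#' @param edit_rates Named numeric vector, 1-based position -> editing rate;
#'   every position must be a C or G in the amplicon.
#' @param indel_rate Per-read probability of carrying one indel.
#' @param n_reads Number of reads.
#' @param read_error Per-base miscall probability.
#' @param seed Integer seed.
#' @return Named character vector of reads (`read_000001`, ...).
#' @export
simulate_amplicon_reads <- function(amplicon, edit_rates = NULL,
                                    indel_rate = 0, n_reads = 10000,
                                    read_error = 0.001, seed = 1) {
  stopifnot(is.character(amplicon), length(amplicon) == 1L,
            nchar(amplicon) >= 1L)
  check_count(n_reads, "n_reads")
  check_prob(indel_rate, "indel_rate")
  check_prob(read_error, "read_error")
  amp <- strsplit(toupper(amplicon), NULL)[[1]]
  L <- length(amp)
  epos <- as.integer(names(edit_rates) %||% character())
  if (length(edit_rates)) {
    if (any(is.na(epos)) || any(epos < 1L | epos > L))
      stop("edit position out of range of the amplicon", call. = FALSE)
    if (!all(amp[epos] %in% c("C", "G")))
      stop("edit positions must be C or G in the amplicon", call. = FALSE)
    if (any(edit_rates < 0 | edit_rates > 1))
      stop("'edit_rates' must lie in [0, 1]", call. = FALSE)
  }
  if (indel_rate > 0 && length(epos) == 0L)
    stop("'indel_rate' > 0 requires at least one edit position to define ",
         "the indel window", call. = FALSE)

  with_seed(seed, {
    mat <- matrix(rep(amp, each = n_reads), nrow = n_reads)
    for (k in seq_along(epos)) {
      hit <- stats::runif(n_reads) < edit_rates[k]
      mat[hit, epos[k]] <- if (amp[epos[k]] == "C") "T" else "A"
    }
    if (read_error > 0) {
      nerr <- n_reads * L
      err <- which(stats::runif(nerr) < read_error)
      if (length(err)) {
        cur <- mat[err]
        sub <- vapply(cur, function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1))
        mat[err] <- sub
      }
    }
    reads <- apply(mat, 1L, paste, collapse = "")
    if (indel_rate > 0) {
      wmin <- min(epos); wmax <- max(epos)
      has <- which(stats::runif(n_reads) < indel_rate)
      for (i in has) {
        len <- sample(1:3, 1L)
        at <- if (wmin < wmax) sample(wmin:wmax, 1L) else wmin
        if (stats::runif(1) < 0.5) {  # deletion
          dl <- min(len, L - at + 1L)
          reads[i] <- paste0(substr(reads[i], 1L, at - 1L),
                             substr(reads[i], at + dl, L))
        } else {                      # insertion after position `at`
          ins <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
          reads[i] <- paste0(substr(reads[i], 1L, at), ins,
                             substr(reads[i], at + 1L, L))
        }
      }
    }
    names(reads) <- sprintf("read_%06d", seq_len(n_reads))
    reads
  })
}

# The eight members of the (S|T)P(K|R)(K|R) family.
SPKK_PEPTIDES <- as.vector(outer(
  c("SPK", "SPR", "TPK", "TPR"), c("K", "R"), paste0))

# Replace the proline of any motif match with alanine until none remain.
scrub_motifs <- function(chars) {
  repeat {
    s <- paste(chars, collapse = "")
    m <- regexpr("[ST]P[KR][KR]", s)
    if (m < 0) return(chars)
    chars[m + 1L] <- "A"
  }
}

#' Generate candidate deaminase protein sequences with planted SPKK motifs
#'
#' Builds random protein sequences that contain exactly the planned number of
#' SPKK-related motifs inside the C-terminal window and none elsewhere
#' (planted motifs are flanked by alanines and the background is scrubbed of
#' accidental matches). A PSI-BLAST-style score is attached to each
#' candidate for ranking exercises.
#'
#' @param motif_plan Integer vector with entries in `{0, 1, 2}`; one
#'   candidate is generated per entry.
#' @param cterm_window C-terminal window length in residues (default 50).
#' @param len_range Length-2 integer range of sequence lengths.
#' @param seed Integer seed.
#' @return A list with `sequences` (named character vector) and `truth`
#'   (data.frame: `id`, `score`, `n_motifs`, `label`).
#' @export
generate_candidate_proteins <- function(motif_plan, cterm_window = 50,
                                        len_range = c(150, 300), seed = 1) {
  if (!length(motif_plan) || !all(motif_plan %in% 0:2))
    stop("'motif_plan' must be a vector with entries in {0, 1, 2}",
         call. = FALSE)
  check_count(cterm_window, "cterm_window", min = 20L)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]]
  with_seed(seed, {
    n <- length(motif_plan)
    seqs <- character(n)
    for (i in seq_len(n)) {
      len <- sample(len_range[1]:len_range[2], 1L)
      chars <- scrub_motifs(sample(aa20, len, replace = TRUE))
      k <- motif_plan[i]
      if (k > 0) {
        cstart <- len - cterm_window + 1L
        # Non-overlapping 6-residue slots (A + motif + A) inside the window.
        slots <- seq.int(cstart + 1L, len - 6L, by = 7L)
        at <- sort(sample(slots, k))
        # Alanine flanks guarantee planting cannot create additional
        # matches: every pattern position requires S/T/P/K/R, never A.
        for (a in at) {
          pep <- sample(SPKK_PEPTIDES, 1L)
          chars[a:(a + 5L)] <- c("A", strsplit(pep, NULL)[[1]], "A")
        }
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    ids <- sprintf("cand_%03d", seq_len(n))
    names(seqs) <- ids
    scores <- round(stats::runif(n, 50, 250), 1)
    labels <- c("-", "+", "++")[pmin(motif_plan, 2L) + 1L]
    list(sequences = seqs,
         truth = data.frame(id = ids, score = scores,
                            n_motifs = as.integer(motif_plan),
                            label = labels, stringsAsFactors = FALSE))
  })
}

#' Inject low-quality base calls into a pileup
#'
#' Converts `n` reference-base calls at `pos` into `base` calls carried at a
#' low PHRED value, so quality-aware frequency computations can be exercised
#' without a full per-read quality model. Adds/updates the `A_lowq..T_lowq`
#' and `lowq_phred` columns.
#'
#' @param pileup Pileup data.frame.
#' @param pos 1-based position to modify.
#' @param base The miscalled base to inject.
#' @param n Number of calls to convert (taken from the reference base).
#' @param phred PHRED value of the injected calls (default 20).
#' @return The modified pileup.
#' @export
inject_low_quality <- function(pileup, pos, base, n, phred = 20L) {
  stopifnot(base %in% DNA_BASES)
  lq <- paste0(DNA_BASES, "_lowq")
  for (cn in lq) if (!cn %in% names(pileup)) pileup[[cn]] <- 0L
  i <- match(pos, pileup$pos)
  if (is.na(i)) stop("position not present in pileup", call. = FALSE)
  refb <- pileup$ref[i]
  if (pileup[[refb]][i] < n)
    stop("not enough reference calls to convert", call. = FALSE)
  pileup[[refb]][i] <- pileup[[refb]][i] - as.integer(n)
  pileup[[base]][i] <- pileup[[base]][i] + as.integer(n)
  pileup[[paste0(base, "_lowq")]][i] <-
    pileup[[paste0(base, "_lowq")]][i] + as.integer(n)
  pileup$lowq_phred <- as.integer(phred)
  pileup
}
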