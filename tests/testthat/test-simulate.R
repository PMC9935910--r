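# Synthetic-data generators: ground truth, noise models, determinism.

test_that("zero mutation rate and zero error give a pure-reference pileup", {
  sim <- simulate_mutagenized_genome(
    length = 2000, pref = context_preference(base_rate = 0),
    error_rate = 0, seed = 11)
  expect_equal(nrow(sim$truth), 0L)
  ref_counts <- mapply(function(b, i) sim$pileup[[b]][i],
                       sim$pileup$ref, seq_len(nrow(sim$pileup)))
  expect_true(all(ref_counts == sim$pileup$depth))
})

test_that("zero-weight contexts are never planted", {
  pref <- context_preference(c(A = 1, G = 1, T = 1, C = 0), base_rate = 0.02)
  sim <- simulate_mutagenized_genome(length = 50000, pref = pref, seed = 4)
  expect_gt(nrow(sim$truth), 0L)
  expect_false(any(sim$truth$context == "C"))
})

test_that("planted context counts match brute-force enumeration of eligible sites", {
  pref <- context_preference(c(A = 0, C = 0, G = 0, T = 1), base_rate = 0.02)
  sim <- simulate_mutagenized_genome(length = 50000, pref = pref, seed = 9)
  expect_true(all(sim$truth$context == "T"))
  eligible <- oracle_eligible_contexts(sim$reference, pref$weights)
  expected <- as.numeric(eligible["T"]) * 0.02
  sd3 <- 3 * sqrt(expected * (1 - 0.02))
  expect_lt(abs(nrow(sim$truth) - expected), sd3)
})

test_that("pileup rows always conserve the simulated depth", {
  sim <- simulate_mutagenized_genome(length = 5000, seed = 2,
                                     error_rate = 0.01)
  sums <- rowSums(sim$pileup[, c("A", "C", "G", "T", "N", "del")])
  expect_true(all(sums == sim$pileup$depth))
  ms <- simulate_mito_pileups(mito_sim_spec(genome_length = 3000,
    target_window = target_window("chrM", 1000, 1014),
    on_target_rates = c(`1007` = 0.4), cellline_snv_sites = c(`2000` = 0.8),
    n_offtarget_sites = 5, depth = 500, seed = 2))
  for (p in list(ms$treated, ms$untreated))
    expect_true(all(rowSums(p[, c("A", "C", "G", "T", "N", "del")]) ==
                      p$depth))
})

test_that("truth sites reappear in the pileup near their programmed frequency", {
  # depth 3000 so the 3-SD binomial band is tight
  ms <- simulate_mito_pileups(mito_sim_spec(seed = 8, depth = 3000))
  alt_of <- function(ref) ifelse(ref == "C", "T", "A")
  pp <- ms$treated
  for (i in seq_len(nrow(ms$truth))) {
    pos <- ms$truth$pos[i]
    f <- ms$truth$programmed_frequency[i]
    j <- match(pos, pp$pos)
    obs <- pp[[alt_of(pp$ref[j])]][j] / pp$depth[j]
    expect_lt(abs(obs - f), 3 * sqrt(f * (1 - f) / 3000) + 1e-9)
  }
})

test_that("identical spec and seed reproduce bit-identical outputs", {
  a <- simulate_mutagenized_genome(length = 3000, seed = 42)
  b <- simulate_mutagenized_genome(length = 3000, seed = 42)
  expect_identical(a, b)
  spec <- mito_sim_spec(genome_length = 4000,
                        target_window = target_window("chrM", 500, 514),
                        on_target_rates = c(`507` = 0.3),
                        cellline_snv_sites = c(`3000` = 0.9),
                        depth = 200, seed = 7)
  expect_identical(simulate_mito_pileups(spec), simulate_mito_pileups(spec))
  amp <- random_dna(60, seed = 1)
  expect_identical(
    simulate_amplicon_reads(amp, n_reads = 50, seed = 3),
    simulate_amplicon_reads(amp, n_reads = 50, seed = 3))
  expect_identical(generate_candidate_proteins(c(0, 2), seed = 5),
                   generate_candidate_proteins(c(0, 2), seed = 5))
})

test_that("without off-target sites or error, treated equals untreated outside the window", {
  win <- target_window("chrM", 1000, 1014)
  ms <- simulate_mito_pileups(mito_sim_spec(
    genome_length = 3000, target_window = win,
    on_target_rates = c(`1005` = 0.5), n_offtarget_sites = 0,
    cellline_snv_sites = c(`2500` = 0.8), error_rate = 0, depth = 500,
    seed = 3))
  outside <- ms$treated$pos - 1 < win$start | ms$treated$pos - 1 >= win$end
  expect_identical(ms$treated[outside, ], ms$untreated[outside, ])
})

test_that("cell-line SNVs appear in both samples near their frequency", {
  ms <- simulate_mito_pileups(mito_sim_spec(
    genome_length = 3000, target_window = target_window("chrM", 100, 114),
    on_target_rates = c(`105` = 0.4), cellline_snv_sites = c(`2000` = 0.8),
    n_offtarget_sites = 0, depth = 3000, seed = 6))
  for (p in list(ms$treated, ms$untreated)) {
    j <- match(2000L, p$pos)
    alt <- if (p$ref[j] == "C") "T" else "A"
    obs <- p[[alt]][j] / p$depth[j]
    expect_lt(abs(obs - 0.8), 3 * sqrt(0.8 * 0.2 / 3000))
  }
})

test_that("impossible off-target requests are rejected", {
  expect_error(
    simulate_mito_pileups(mito_sim_spec(
      genome_length = 1100, target_window = target_window("chrM", 100, 114),
      on_target_rates = c(`105` = 0.4), cellline_snv_sites = NULL,
      n_offtarget_sites = 5000, depth = 100, seed = 1)),
    "exceed")
})

test_that("invalid simulator arguments are rejected naming the field", {
  expect_error(simulate_mutagenized_genome(length = 2000, gc_fraction = 1.4),
               "gc_fraction")
  expect_error(simulate_mutagenized_genome(length = 2000, error_rate = -1),
               "error_rate")
  expect_error(context_preference(c(A = 0, C = 0, G = 0, T = 0)),
               "positive")
  expect_error(context_preference(base_rate = 2), "base_rate")
  expect_error(mito_sim_spec(cellline_snv_sites = c(`12000` = 0.3)),
               "cellline_snv_sites")
})

test_that("amplicon reads reproduce the reference when nothing is programmed", {
  amp <- random_dna(50, seed = 10)
  reads <- simulate_amplicon_reads(amp, edit_rates = NULL, indel_rate = 0,
                                   n_reads = 20, read_error = 0, seed = 1)
  expect_true(all(reads == amp))
})

test_that("programmed per-cytosine edit rates are recovered in the raw reads", {
  amp <- paste0(random_dna(20, seed = 3), "C", random_dna(20))
  k <- 21L
  reads <- simulate_amplicon_reads(amp, stats::setNames(0.3, k),
                                   n_reads = 10000, read_error = 0, seed = 2)
  frac <- mean(substr(reads, k, k) == "T")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("edit positions must be cytosines or guanines in range", {
  amp <- "AACCGGTT"
  expect_error(simulate_amplicon_reads(amp, c(`1` = 0.5), n_reads = 5),
               "C or G")
  expect_error(simulate_amplicon_reads(amp, c(`99` = 0.5), n_reads = 5),
               "range")
})

test_that("planted motif plans are exactly recovered by scanning", {
  plan <- c(0, 1, 2, 2, 1, 0)
  gen <- generate_candidate_proteins(plan, seed = 21)
  for (i in seq_along(plan)) {
    hits <- scan_spkk(gen$sequences[[i]])
    expect_identical(sum(hits$kept), as.integer(plan[i]))
    # nothing outside the C-terminal window either
    full <- oracle_spkk_hits(gen$sequences[[i]],
                             cterm_window = nchar(gen$sequences[[i]]))
    expect_identical(length(full), as.integer(plan[i]))
  }
  expect_identical(gen$truth$label, c("-", "+", "++", "++", "+", "-"))
})

test_that("low-quality injection preserves depth and marks the calls", {
  sim <- simulate_mutagenized_genome(length = 2000,
    pref = context_preference(base_rate = 0), error_rate = 0, seed = 1)
  i <- which(sim$pileup$ref == "G")[1]
  pp <- inject_low_quality(sim$pileup, sim$pileup$pos[i], "A", 10,
                           phred = 20)
  expect_equal(pp$A[i], 10L)
  expect_equal(pp$A_lowq[i], 10L)
  expect_equal(sum(pp[i, c("A", "C", "G", "T")]), pp$depth[i])
})
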