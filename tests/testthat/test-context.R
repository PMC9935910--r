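# Variant calling, context extraction, probability logos, IUPAC preference.

test_that("variant thresholds behave as strict inequalities", {
  # coverage 40 <= 50: excluded even with a strong signal
  p1 <- pileup_row("C", c(C = 30, T = 10))
  expect_identical(nrow(call_variants(p1)), 0L)
  # frequency 1/200 = 0.005 <= 0.01: excluded
  p2 <- pileup_row("C", c(C = 199, T = 1))
  expect_identical(nrow(call_variants(p2)), 0L)
  # depth 100, alt 5: all three thresholds pass; p-value matches the
  # exact binomial sum
  p3 <- pileup_row("C", c(C = 95, T = 5))
  v <- call_variants(p3, error_rate = 0.001)
  expect_identical(nrow(v), 1L)
  expect_lt(v$p_value, 0.01)
  expect_equal(v$p_value, oracle_binom_tail(5, 100, 0.001), tolerance = 1e-12)
  expect_equal(v$frequency, 0.05)
  expect_identical(v$alt_base, "T")
})

test_that("only C-to-T and G-to-A substitutions become deamination calls", {
  p <- rbind(pileup_row("A", c(A = 80, G = 20), pos = 10L),
             pileup_row("G", c(G = 80, A = 20), pos = 20L),
             pileup_row("C", c(C = 80, G = 20), pos = 30L))
  v <- call_variants(p)
  expect_identical(v$pos, 20L)
  expect_identical(v$alt_base, "A")
})

test_that("non-positive depth rows are skipped with a warning", {
  p <- rbind(pileup_row("C", c(C = 90, T = 10)),
             pileup_row("C", c(), pos = 5L))
  expect_warning(v <- call_variants(p), "non-positive depth")
  expect_identical(nrow(v), 1L)
})

test_that("relaxing any threshold never removes a call", {
  sim <- simulate_mutagenized_genome(length = 20000, seed = 19,
                                     error_rate = 0.005)
  base <- call_variants(sim$pileup)
  for (relaxed in list(call_variants(sim$pileup, min_freq = 0.001),
                       call_variants(sim$pileup, min_cov = 10),
                       call_variants(sim$pileup, max_p = 0.1))) {
    expect_true(all(base$pos %in% relaxed$pos))
  }
})

test_that("contexts are oriented onto the deaminated strand", {
  v1 <- data.frame(chrom = "c", pos = 3L, ref_base = "G", alt_base = "A")
  expect_identical(as.character(extract_contexts(v1, "TTGCC", flank = 1)),
                   "GCA")
  v2 <- data.frame(chrom = "c", pos = 3L, ref_base = "C", alt_base = "T")
  expect_identical(as.character(extract_contexts(v2, "ATCGA", flank = 1)),
                   "TCG")
})

test_that("a genome and its reverse complement yield identical context multisets", {
  ref <- random_dna(200, seed = 23)
  chars <- strsplit(ref, NULL)[[1]]
  pos <- which(chars %in% c("C", "G"))
  pos <- pos[pos > 5 & pos < 196]
  v <- data.frame(chrom = "c", pos = pos,
                  ref_base = chars[pos],
                  alt_base = ifelse(chars[pos] == "C", "T", "A"),
                  stringsAsFactors = FALSE)
  ctx_fwd <- extract_contexts(v, ref, flank = 5)
  rc <- function(x) chartr("ACGT", "TGCA",
                           vapply(lapply(strsplit(x, NULL), rev), paste,
                                  character(1), collapse = ""))
  ref_rc <- rc(ref)
  v_rc <- data.frame(chrom = "c", pos = 201L - v$pos,
                     ref_base = ifelse(v$ref_base == "C", "G", "C"),
                     alt_base = ifelse(v$ref_base == "C", "A", "T"),
                     stringsAsFactors = FALSE)
  ctx_rev <- extract_contexts(v_rc, ref_rc, flank = 5)
  expect_identical(sort(as.character(ctx_fwd)), sort(as.character(ctx_rev)))
})

test_that("edge variants are dropped and counted", {
  v <- data.frame(chrom = "c", pos = c(2L, 10L), ref_base = c("C", "C"),
                  alt_base = c("T", "T"))
  ref <- "ACAAAAAAACAAAAAAAAAA"
  ctx <- extract_contexts(v, ref, flank = 5)
  expect_identical(length(ctx), 1L)
  expect_identical(attr(ctx, "n_dropped"), 1L)
})

test_that("chrom mismatches against the reference are rejected", {
  v <- data.frame(chrom = "other", pos = 3L, ref_base = "C",
                  alt_base = "T")
  expect_error(extract_contexts(v, c(myref = "ATCGA"), flank = 1),
               "chrom")
})

test_that("probability logos count correctly and report information content", {
  prof <- build_probability_logo(c("TCA", "TCG"))
  expect_equal(unname(prof$ppm["T", prof$offsets == -1]), 1)
  expect_equal(unname(prof$ppm["A", prof$offsets == 1]), 0.5)
  expect_equal(unname(prof$ppm["G", prof$offsets == 1]), 0.5)
  expect_equal(colSums(prof$ppm), rep(1, 3), ignore_attr = TRUE)
  # identical contexts: point masses, 2 bits everywhere
  prof2 <- build_probability_logo(rep("ATCGG", 7))
  expect_true(all(prof2$ppm %in% c(0, 1)))
  expect_equal(prof2$information, rep(2, 5), ignore_attr = TRUE)
  expect_identical(prof2$n_sites, 7L)
})

test_that("uniform contexts give uniform off-center columns", {
  set.seed(41)
  n <- 10000
  ctx <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), "C",
                sample(c("A", "C", "G", "T"), n, replace = TRUE))
  prof <- build_probability_logo(ctx)
  sd3 <- 3 * sqrt(0.25 * 0.75 / n)
  for (j in which(prof$offsets != 0))
    expect_true(all(abs(prof$ppm[, j] - 0.25) < sd3))
})

test_that("degenerate logo inputs are rejected", {
  expect_error(build_probability_logo(character()), "no sites")
  expect_error(build_probability_logo(c("TCA", "TC")), "length")
  expect_error(build_probability_logo("TAG"), "center")
})

test_that("IUPAC preference calls match the exhaustive minimal-cover oracle", {
  cases <- list(
    c(A = 0.01, C = 0.01, G = 0.01, T = 0.97),   # "T"
    c(A = 0.31, C = 0.03, G = 0.33, T = 0.33),   # "D"
    c(A = 0.40, C = 0.25, G = 0.03, T = 0.32))   # "H"
  expected <- c("T", "D", "H")
  for (i in seq_along(cases)) {
    p <- cases[[i]][c("A", "C", "G", "T")]
    prof <- structure(list(offsets = c(-1L, 0L, 1L),
                           ppm = cbind(p, c(0, 1, 0, 0), p),
                           n_sites = 100L),
                      class = "context_profile")
    dimnames(prof$ppm) <- list(c("A", "C", "G", "T"), NULL)
    got <- classify_preference(prof)
    expect_identical(got, expected[i])
    expect_identical(got, oracle_iupac(p))
  }
  # randomized agreement with the oracle
  set.seed(91)
  for (rep in 1:50) {
    p <- stats::runif(4)
    p <- stats::setNames(p / sum(p), c("A", "C", "G", "T"))
    prof <- structure(list(offsets = -1L, ppm = matrix(p, 4, 1,
      dimnames = list(names(p), NULL)), n_sites = 1L),
      class = "context_profile")
    expect_identical(classify_preference(prof), oracle_iupac(p))
  }
})

test_that("simulated preferences are recovered end to end", {
  # desk-scale single-seed version of the genome-wide logo experiment
  cases <- list(list(w = c(A = 0, C = 0, G = 0, T = 1), code = "T"),
                list(w = c(A = 1, C = 0, G = 1, T = 1), code = "D"),
                list(w = c(A = 1, C = 1, G = 0, T = 1), code = "H"))
  for (cs in cases) {
    sim <- simulate_mutagenized_genome(
      length = 60000, pref = context_preference(cs$w, 0.02), seed = 27)
    res <- profile_contexts(sim$pileup, sim$reference)
    expect_identical(res$preference, cs$code)
    expect_equal(colSums(res$profile$ppm),
                 rep(1, length(res$profile$offsets)), ignore_attr = TRUE)
    expect_identical(res$profile$n_sites, length(res$contexts))
  }
})
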