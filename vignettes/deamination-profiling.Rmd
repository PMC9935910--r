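---
title: "Profiling dsDNA cytidine deaminases and mitochondrial base editors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling dsDNA cytidine deaminases and mitochondrial base editors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deamprofiler)
```

# The problem

Double-stranded-DNA cytidine deaminases (DddA-like toxins) deaminate C to U
directly in duplex DNA. Split in two and fused to a pair of TALE
DNA-binding arrays, they become mitochondrial base editors (DdCBEs) that
install C·G→T·A changes in the spacing region between the two TALE binding
sites. Characterizing such an enzyme requires four computational stages,
which this package implements as reusable, individually testable modules:

1. **Candidate triage** (`scan_spkk()`, `classify_candidate()`,
   `rank_candidates()`): short Ser/Thr–Pro–basic–basic (SPKK-related)
   peptides bind A/T-rich minor grooves; their presence in a deaminase
   C-terminus is a cheap triage feature for dsDNA activity. Candidates are
   labelled `-`/`+`/`++` by motif count and ranked by a homology-search
   score with C-terminal-diversity deduplication.
2. **Sequence-context profiling** (`call_variants()`,
   `extract_contexts()`, `build_probability_logo()`,
   `classify_preference()`): deep sequencing of a uracil-glycosylase
   deficient (UNG−) host overexpressing the enzyme reads persistent
   deamination events out as C→T (and, on the other strand, G→A) variants.
   The 5′ neighbor of each deaminated cytosine summarizes the enzyme's
   sequence preference (TC, HC, DC, …).
3. **Amplicon editing quantification** (`align_to_amplicon()`,
   `nucleotide_percentage_table()`, `indel_frequency()`): targeted amplicon
   sequencing of an edited locus, reduced to per-position nucleotide
   percentages, per-cytosine editing efficiencies, and an indel frequency.
4. **Mitochondrial off-target quantification** (`per_base_editing()`,
   `exclude_sites()`, `call_offtargets()`,
   `average_offtarget_frequency()`): genome-wide per-base C·G→T·A
   frequencies, with the spacing region and fixed cell-line SNVs excluded,
   summarized as the average off-target editing frequency.

A synthetic-data module generates every input with known ground truth, so
each stage's statistical behavior can be verified at desk scale.

# Models and procedures

## Variant calling and the binomial error model

`call_variants()` emits a C→T or G→A call when all three validation
thresholds pass, each a strict inequality: variant frequency $f > 0.01$,
coverage $d > 50$ reads, and p-value $p < 0.01$. The p-value is the
one-sided binomial tail against the expected miscall rate $e$ (default
$10^{-3}$):

$$p = P(X \ge k \mid X \sim \mathrm{Bin}(d, e)),$$

with $k$ the alt-allele count. Established pileup callers compute a
Fisher's exact test of observed counts against counts expected from error;
in this one-sample setting the binomial tail is the same comparison and is
fully specified, which makes it the better contract for a reusable module.
The error rate is a parameter because it is a property of the sequencing
run, not of the method.

A consequence worth knowing: at depth 100, an alt count of 2 already
passes all three thresholds ($f = 0.02$; $P(X \ge 2 \mid 100, 10^{-3})
\approx 0.0047$). At that depth the caller therefore admits
error-derived doubletons at a rate of roughly $5\times10^{-4}$ per C/G
position, and a preference logo built from few true sites (a strongly
single-context enzyme in a small genome) is visibly diluted by these
uniform-context false positives. Deeper sequencing removes the effect
(at depth 1000 the frequency threshold requires 11 reads, which errors
essentially never produce); logos built from many true sites are barely
affected. The classification layer is robust to this dilution because its
0.9 probability-mass threshold tolerates it.

## Strand normalization and the probability logo

`extract_contexts()` orients every flanking window onto the deaminated
strand: windows around C→T calls are taken as-is, windows around G→A calls
are reverse-complemented. Offset −1 is then always the 5′ neighbor of the
deaminated C. The default flank is ±5 bp — wide enough to show that
positions beyond −1 carry no signal, narrow enough that edge effects are
rare; variants closer than `flank` to a contig edge are dropped and
counted rather than wrapped, since linear contigs have no meaningful
wraparound.

`build_probability_logo()` is plain column-wise counting: the position
probability matrix entry is $\hat p_{b,j} = n_{b,j}/N$, with per-offset
information content $2 + \sum_b \hat p_{b,j}\log_2 \hat p_{b,j}$ bits.

`classify_preference()` reduces the −1 column to the smallest IUPAC
degenerate code whose base set reaches 0.9 probability mass; ties are
broken by the fixed order A<C<G<T<R<Y<S<W<K<M<B<D<H<V<N. The 0.9 default
is the conventional "dominant preference" reading: a single base at 0.97
reads as TC; an even three-way A/G/T spread reads as DC.

## Amplicon quantification

Reads are aligned to the reference amplicon with global Needleman–Wunsch
and affine gaps (match +2, mismatch −1, gap of length $L$ costs
$-6 - L$). These defaults make a 1–3 bp indel cheaper than three scattered
mismatches, which is the right prior for base-editing amplicons where true
indels are rare and short. The alignment engine is
`Biostrings::pairwiseAlignment()`; co-optimal alignments are resolved by
its canonical deterministic traceback, so reruns are byte-identical.
Because amplicon read sets are highly redundant, each distinct read
sequence is aligned once and the result expanded back — an exact
optimization, not an approximation.

`nucleotide_percentage_table()` projects each alignment onto reference
coordinates: every reference position receives one call per read (a base
or a deletion), so percentages sum to 100 by construction; insertion
columns do not create reference positions. Editing efficiency is %T at
reference-C positions and %A at reference-G positions. A warning is
issued below 10,000× coverage, the conventional minimum for amplicon
quantification. `indel_frequency()` counts reads whose alignment has a
deleted reference base inside the quantification window or an insertion
anchored strictly inside it; the window defaults to the spacing region
(equivalently, the span of C/G positions for a synthetic amplicon),
because indels outside the editing window are PCR/sequencing artifacts,
not editing outcomes. Reads are assumed pre-merged and full-length;
paired-end merging and trimming belong upstream.

## Mitochondrial off-target statistic

`per_base_editing()` keeps only reference-C and reference-G rows and
computes the C·G→T·A frequency from calls with PHRED quality strictly
greater than 30 (both numerator and denominator). Rows whose
quality-passing depth falls below 3000× are flagged, not dropped — depth
QC is a property of the sample, and silent dropping would bias the
denominator. `exclude_sites()` removes the spacing region (all editing
there is on-target by definition) and sites whose untreated-sample
frequency exceeds 50% (fixed SNVs of the cell line, not editing).
`call_offtargets()` keeps sites strictly above 0.1%. The summary statistic
is

$$\bar f_{\mathrm{off}} = \frac{\sum_{i \in \mathrm{off\text{-}target}} f_i}
{\#\{\mathrm{retained\ non\text{-}target\ C{:}G\ bases}\}}.$$

Two conventions are the package's own decisions where the procedure's
description leaves them open: (i) excluded sites (on-target, cell-line
SNVs) leave the denominator as well as the numerator, so the statistic is
"editing per assayable non-target C:G base"; (ii) with replicates, the
>0.1% threshold is applied per replicate and the per-replicate statistics
are averaged (arithmetic mean), rather than thresholding replicate-mean
frequencies — per-replicate calling keeps the statistic monotone in each
replicate's signal. TALE-free deaminase pairs are handled by an empty
window list. Windows are BED-convention 0-based half-open; all reported
positions are 1-based, and every output header says so.

## Candidate triage details

The SPKK-related pattern defaults to `(S|T) P (K|R) (K|R)`, the
Ser/Thr–Pro–basic–basic family from the minor-groove-binding peptide
literature; the motif family has no single canonical regular expression,
so the pattern is a configurable argument, and broader variants can be
supplied without code changes. A useful structural fact: matches of this
pattern can never overlap (positions 3–4 require K/R, positions 1–2
require S/T/P, and the sets are disjoint), so the greedy non-overlap
reduction the scanner applies is provably a no-op for the default
pattern — it exists for user-supplied patterns where overlaps are
possible. The C-terminal window defaults to 50 residues, comfortably
covering the tandem-motif arrangements seen in active enzymes.

For deduplication, C-terminal identity is computed from the
match-maximizing global alignment (match 1, mismatch 0, gap 0 — an
LCS-style alignment) as matches divided by alignment length, and
candidates are kept greedily in score order (ties by id) unless they reach
the identity threshold (default 0.5) against an already-kept candidate.
Greedy-by-score makes "among similar candidates, keep the best-scoring
one" exact for pairs and well-defined for chained near-duplicate groups.

# The synthetic-data generators

The generators define the study conditions; their defaults are the
conditions under which the package's claims are tested.

* `simulate_mutagenized_genome()` — an E. coli-like random genome
  (default 100 kb, GC 0.5, depth 100×). Each plus-strand C (context =
  preceding base) and plus-strand G (a minus-strand C; context =
  complement of the following base) is planted independently with
  probability `base_rate × w/max(w)`. Normalizing by the maximum weight
  makes the most-preferred context mutate at exactly `base_rate`, so
  "eligible sites × base_rate" is the planted-count expectation for any
  single-context preference. Planted sites carry a fixed variant frequency
  `mut_freq` (default 0.5: deamination early in the outgrowth of a
  near-clonal culture); per-site frequencies are deterministic given the
  arguments, and only the read sampling is random — binomial alt counts
  plus a uniform miscall rate (default $10^{-3}$, a typical post-filter
  Illumina value) spread evenly over the three non-reference bases.
* `simulate_mito_pileups()` — a human-mtDNA-like genome (16,569 bp,
  GC 0.44), one spacing window, programmed on-target/bystander rates,
  uniformly drawn off-target frequencies outside the window, cell-line
  SNVs (>50%) present in both samples, depth 3000×. The default miscall
  rate is $10^{-4}$: this pileup models the calls that survive the
  PHRED>30 filter the analysis applies, and the residual miscall rate
  after a Q30 cut is an order of magnitude below the raw rate. The treated
  pileup shares the untreated sample's draws everywhere except at edited
  positions, which are redrawn around their programmed frequencies — the
  samples are paired, and this makes "identical outside the window when
  nothing is planted" an exact property rather than a statistical one.
* `simulate_amplicon_reads()` — per-read independent C→T/G→A conversion
  at each programmed position, a 1–3 bp insertion or deletion with
  probability `indel_rate` placed uniformly inside the span of the edit
  positions, then uniform miscalls.
* `generate_candidate_proteins()` — random protein sequences scrubbed of
  accidental SPKK-related matches, with the planned number of motifs
  planted in the C-terminal window between alanine flanks (alanine matches
  no pattern position, so planting cannot create extra matches).

What the generators deliberately do **not** model: read-level artifacts
(mapping, duplicates, strand bias, position-dependent quality), PCR bias,
and the circularity of the mitochondrial genome (the reference is treated
as linear for windowing; origin-spanning windows are out of scope). A
passing test suite therefore demonstrates that the statistics are computed
correctly and recover programmed truth under pileup-level binomial noise —
it does not validate upstream alignment pipelines on real reads. Base
qualities use a single-PHRED model (default 37) with a dedicated
low-quality injection helper (`inject_low_quality()`) so the quality
filter is exercised explicitly rather than through a full quality model.

# Numerical and degenerate-input choices

* Every threshold is a strict inequality, exactly as stated in its
  definition (frequency > 0.01, coverage > 50, p < 0.01, PHRED > 30,
  untreated SNV > 0.5, off-target > 0.001, plot > 0.01); boundary values
  are excluded, and the test suite pins each boundary.
* Empty context lists, zero-depth rows, zero denominators, and
  over-subscribed off-target requests are rejected (or warned and
  skipped, for zero-depth rows) with messages naming the offending field.
* All generators accept a seed and restore the caller's RNG state;
  identical arguments and seed give bit-identical outputs, including
  on-disk files (checksummed in the pipeline manifest).
* The test suite and acceptance script run the genome-wide recovery at
  100 kb × depth 100 (three preference vectors × three seeds), the
  off-target chain at 16,569 bp × depth 3000 with 20 planted sites, and
  amplicon quantification at 10,000 reads — sizes chosen so every
  statistical check has tight binomial bands while the whole suite stays
  interactive.

# Worked example

```{r example, eval = FALSE}
library(deamprofiler)

## genome-wide context preference of a TC-preferring enzyme
sim <- simulate_mutagenized_genome(
  length = 100000, depth = 100,
  pref = context_preference(c(A = 0, C = 0, G = 0, T = 1),
                            base_rate = 0.02),
  seed = 1)
res <- profile_contexts(sim$pileup, sim$reference)
res$preference          # "T": a TC-context enzyme
res$profile             # probability matrix over offsets -5..+5

## mitochondrial off-target statistic with planted truth
win <- target_window("chrM", 8000, 8014)
ms <- simulate_mito_pileups(mito_sim_spec(
  target_window = win, on_target_rates = c(`8007` = 0.4),
  n_offtarget_sites = 20, cellline_snv_sites = c(`12000` = 0.8),
  seed = 101))
summarize_offtargets(ms$treated, ms$untreated, ms$reference, win)
```

# Known limitations

* Pileup-level simulation only; no read simulator, no mapping artifacts.
* The mitochondrial reference is linear for windowing purposes.
* The binomial p-value model assumes a single uniform error rate; it does
  not model position- or context-dependent error.
* At shallow depth the strict frequency threshold admits error doubletons
  (see above); logos from few true sites inherit that dilution.
* `rank_candidates()` is greedy; for adversarial chains of near-duplicates
  a clustering formulation could keep a different set, but the
  keep-the-best-scoring-representative behavior is exact for the pairwise
  case the procedure describes.
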