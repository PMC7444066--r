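---
title: "Methods: tsRNA discovery, classification and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tsRNA discovery, classification and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRFkit)
```

# The problem

Transfer RNAs are cleaved into discrete, biologically active fragments —
tRNA-derived small RNAs (tsRNAs, also called tRFs). In small RNA-seq of a
differentiating cell population, tsRNAs appear as short reads (mostly 17–23
or 30–36 nt) that map to mature tRNA bodies, to the CCA end, or to the 3'
trailer of the primary transcript. `tRFkit` implements the desk side of such
a study end to end: building the tRNA reference that makes these fragments
mappable, filtering and annotating reads, classifying fragments into the six
canonical classes, profiling their expression over timepoints (days 0, 7,
14, 21 of induced adipogenesis in the motivating design), calling
differential expression at fold-change/FDR cut-offs, and scanning 3'-UTRs
for candidate binding sites of a tsRNA of interest.

Because tsRNA read sets of this kind are rarely deposited, the package
ships a first-class synthetic-data generator that emulates the sequencing
experiment, so that every stage is testable and the whole pipeline can be
demonstrated without downloads.

# The extended mature reference

A pre-tRNA gene contributes three sequence layers: the spliced mature body,
the post-transcriptionally appended CCA, and the genomic 3' trailer that
ends the primary transcript. `build_mature_reference()` constructs, per
gene:

```
extended = spliced mature body + "CCA" + first 50 genomic nt 3' of the gene
```

so that `length(extended) − length(mature) = 53` always. Coordinates are
0-based and half-open everywhere, on the mature sense strand; minus-strand
genes are reverse-complemented at build time. Intron removal is exact
interval excision with no splice-site sequence checks. CCA is appended
*unconditionally*: when a toy gene happens to encode CCA at its 3' end the
mature+CCA sequence ends in `CCACCA`. This is deliberate — the reference
recipe adds CCA to every mature body without testing for a genomic copy —
and is worth knowing when building fixtures by hand.

Structural landmarks (D-loop, anticodon loop, anticodon, T-loop) ride along
in mature coordinates. The synthetic gene generator fixes them at the
canonical cloverleaf positions of a 76-nt body — `d_loop = [13,22)`,
`anticodon_loop = [31,39)`, `anticodon = [33,36)`, `t_loop = [53,61)` — and
allows per-gene overrides, since real tRNAs vary by a few bases. The mature
body length defaults to 76 nt and may be set between 70 and 90.

# Fragment classification

The six classes are defined by where a fragment's ends sit relative to the
mature body. With `M` the mature+CCA length and `W` the anticodon loop
widened by `loop_tol` on both sides, `classify_fragment()` applies, in
order:

1. `start ≥ M − end_tol` → **tRF-1** (trailer fragment);
2. 5'-anchored (`start ≤ end_tol`) and `end ∈ W` → **5p-half**;
3. 5'-anchored and `end < min(W)` → **tRF-5**;
4. 3'-anchored (`end ≥ M − end_tol`) and `start ∈ W` → **3p-half**;
5. 3'-anchored and `start > max(W)` → **tRF-3**;
6. interior on both sides → **i-tRF**;
7. otherwise → **unclassified**.

Two tolerances matter. `end_tol` (default 1) absorbs one base of softness
at the anchored ends, e.g. untemplated additions or imprecise 5' ends.
`loop_tol` (default 3) widens the anticodon-loop cut window into the
adjacent stem: anticodon-site cleavage in practice falls a few bases to
either side of the loop proper, and a canonical 39-nt 3' half of a 76-nt
tRNA starts at position 40, two bases 5' of the loop — it requires
`loop_tol ≥ 2` to be recognised as a half rather than left unclassified.
The default of 3 keeps the window symmetric and accepts stem-adjacent
cleavage on both sides.

Rule order resolves the ambiguous cases deterministically: a full-length
mature tRNA (`[0, M)`) matches no rule and is *unclassified* — full-length
tRNAs are not tsRNAs — as are most fragments straddling the mature/trailer
boundary. A fragment whose start falls in or beyond `W` but whose end runs
past `M` is still called a 3' class by rules 4–5, since the 3'-anchoring
test is one-sided; this is intentional, mirroring the end softness above.

## License plates

Each distinct fragment sequence receives a deterministic, reversible,
alignment-free identifier of the form `tRF-<length>-<code>`: the sequence
is split into consecutive 5-mers (a final chunk of 1–4 nt is allowed) and
each chunk maps through a fixed lookup table to a token over a 32-symbol
alphabet (the 22 letters other than A/C/G/T, plus the 10 digits — codes can
never be mistaken for sequence). Chunks of 1–2 nt map to 1-symbol tokens
and chunks of 3–5 nt to 2-symbol tokens, so a 39-nt fragment always gets a
16-character code. `decode_license_plate()` inverts `encode_license_plate()`
exactly, and distinct sequences always get distinct plates.

The lookup table here (`trf_lookup_table()`) is the package's own
deterministic enumeration: chunks in lexicographic order paired with
consecutive tokens. It has the same shape as the tables behind public tRF
databases but is not numerically identical to them, so plates minted by
this package are stable identifiers *within* analyses run with it, not
cross-database accessions. If the published table is available it can be
substituted, after which plates become database-compatible.

# Read processing

`trim_adapter()` removes the 3' sequencing adapter by exact overlap: a full
internal adapter occurrence truncates the read at its first position;
otherwise the longest read suffix equal to an adapter prefix, with at least
6 nt of overlap, is removed. Six bases is the conventional floor below
which suffix matches are mostly chance (a 5-nt suffix matches a fixed
prefix with probability ~1/1000 per read). Quality-based trimming is
deliberately reduced to N-content rejection (reads over 10% N are
unmapped), since the synthetic data carries constant qualities.

`length_filter()` retains 12–50 nt reads by default, the window in which
both tRF classes and halves live; the stricter 24–33 nt variant sometimes
used to enrich halves is available through the arguments.

`hierarchical_assign()` annotates each read with the *first* category in
the fixed order miRNA → rRNA → tRNA in which it has an ungapped placement
with at most `max_mismatch` (default 1) mismatches. The alignment engine is
an exhaustive, deterministic substring placement (via
`Biostrings::matchPattern`) rather than a heuristic read mapper: at the
scale of a tRNA reference set this is exact, reproducible, and directly
checkable against a brute-force oracle, which the test suite does. Within
the tRNA category the single best placement is kept — minimal mismatches,
ties broken by lexicographic reference id and then smallest start — so
multi-mapping reads are counted once, reproducibly, rather than
fractionally.

# Profiling

Summaries are deliberately plain:

* `length_histogram()` — count-weighted fragment-length fractions per
  sample;
* `tsrna_fraction()` — tsRNA reads as a fraction of the per-sample total;
  the denominator is the library's post-filter mapped-read total by
  default, carried in `trf_counts$totals` and settable by the caller, since
  "total reads" and "total non-coding reads" are both defensible choices;
* `class_fractions()` — per-class fractions over the six classes plus
  `unclassified`;
* `positional_coverage()` — per-base start/end depth along one extended
  reference, one unit per distinct fragment;
* `tpm()` — reads per million mapped reads: `count / total × 1e6`, with
  **no** transcript-length normalisation. Fragments are counted as
  molecules, not sampled along a transcript, so the length correction of
  mRNA-style TPM has no meaning here. Column masses are conserved at the
  1e6 scale and values are invariant under uniform library scaling.

# Differential expression

Size factors are median-of-ratios, computed over fragments detected in
every sample and rescaled to geometric mean 1, falling back to column
totals when no fragment is detected everywhere (common for very sparse
matrices).

The per-fragment test is a *two-sided exact conditional binomial test on
pooled counts*: conditional on a fragment's total raw count across both
groups, the count in group B is Binomial(n, p0) under the null, with p0 =
group B's share of the summed library sizes. Fold changes are computed on
size-factor-normalised means with a pseudocount of 1 (so fragments absent
at day 0 — the "not detectable, then peaking" pattern — get finite, large
fold changes rather than infinities). FDR is Benjamini–Hochberg.
`call_significant()` applies the joint cut-offs: fold change > 2 or < 0.5
(equivalently |log2FC| > 1), p < 0.05, FDR < 0.05.

Two properties of this test should be understood before using it:

* **It is calibrated under Poisson (count-sampling) noise.** On null
  Poisson simulations its type-I error sits at the nominal level (the suite
  checks 500 null fragments at mean 100, 3 vs 3, against 0.05 within three
  binomial standard errors), and on planted simulations (300 fragments, 6
  planted at fold 4, 3 vs 3) it recovers exactly the planted set across
  seeds.
* **It is anticonservative under biological overdispersion.** Pooling
  replicates by summation discards the replicate-to-replicate variance, so
  when counts are negative binomial (the generator's default dispersion is
  0.1, i.e. variance = mu + 0.1 mu² — a realistic level) null fragments
  receive inflated significance, and at 300 fragments a handful of false
  calls at the joint cut-offs is typical. This is the price of an exact,
  assumption-light, deterministic test; a dispersion-aware model (e.g.
  negative-binomial GLMs) is the right tool when replicate variance
  matters, and the recovery guarantees quoted above are stated for the
  Poisson regime the test actually models.

# Target-site prediction

`scan_utr()` aligns the tsRNA locally against the reverse-complement sense
of the UTR with affine gaps: Watson–Crick match +5, G:U wobble +1, mismatch
−3, gap open −8, gap extend −2, and substitution scores doubled across the
seed (tsRNA positions 2–8), echoing the seed-weighted scoring of
miRNA-target tools. A perfect complement of length L scores 5·(L+7), a
strict optimum over all alignments of that length. The stability proxy
counts paired columns (−3 per G:C, −2 per A:T, −1 per G:U); it is a
monotone surrogate for duplex stability, not a free-energy estimate —
thermodynamic folding is out of scope. Sites are reported non-overlapping,
best first, down to the score threshold (default 80), by masking each
reported site and re-scanning the remaining segments.

One practical caveat the test suite quantifies: the *null* score attainable
on random sequence grows with tsRNA length once gaps are allowed. For a
20-nt tsRNA against 500 nt of random UTR the best alignment scores around
60–80 (below the default threshold); a 39-nt tsRNA reaches 70–100, so at
threshold 80 occasional sites on random sequence are expected for long
tsRNAs. Read thresholds relative to the perfect-site score 5·(L+7) — the
default of 80 is roughly 60% of the optimum for a 20-nt tsRNA but only 35%
for a 39-nt one — and raise the threshold accordingly when scanning with
halves.

`mutate_site()` builds the matched mutant UTR used by reporter-style
comparisons: it substitutes the `n_mut` paired UTR positions inside the
seed-pairing region whose substitution loses the most score, choosing
replacement bases that are neither complementary nor wobble partners of the
paired tsRNA base (ties resolved by a seeded draw, so a fixed seed gives an
identical mutant). Rescanning the mutant gives a strictly lower score, and
each additional seed mutation never increases it. Note that a local aligner
may partially rescue a mutated site with shifted or gapped alignments, so
the mutant's score does not drop by exactly the naive per-mutation loss.

# qPCR utilities

`ddct_fold_change()` implements relative quantification from threshold
cycles: `ddCt = (Ct_target − Ct_ref)_treated − (Ct_target − Ct_ref)_control`
and fold change `2^(−ddCt)`; it is invariant to a constant shift of all
four Ct values. `group_compare()` picks the conventional test by arity —
two-sample two-tailed Student t test for two groups (Welch optional),
one-way ANOVA F test for more — and returns p = 1 by convention for fully
degenerate (all-identical) inputs. No post-hoc tests are provided.

# The synthetic-data generator

`simulate_reads()` emulates the *structure* of the sequencing experiment:

* four timepoints (days 0/7/14/21), 3 replicate libraries each by default —
  three donor lots motivate the replicate count, though per-timepoint
  replication in such designs is often unstated;
* per-read class sampled from a six-class mixture (defaults: tRF-5 0.25,
  tRF-3 0.20, i-tRF 0.20, 5p-half 0.15, 3p-half 0.10, tRF-1 0.10), then cut
  positions drawn consistently with that class's coordinate rule on a
  random reference, preferring lengths inside the 17–23 / 30–36 nt modes
  where the class geometry allows (3' halves of a 76-nt body are
  necessarily 38–51 nt, which is why they sit outside both modes and are
  given a modest default share);
* miRNA (15%) and rRNA (10%) contamination drawn from random contaminant
  references, the full 3' adapter appended to every read, constant `I`
  qualities;
* optionally, planted fragments with per-day abundance multipliers;
  `plant_absent_then_peak()` builds the characteristic absent-at-day-0,
  peak-at-day-7 pattern;
* a truth table covering every read (parent, class, interval), and
  byte-identical FASTQ/TSV outputs for a fixed seed.

It does **not** emulate sequencing errors, quality-score structure, PCR
duplicates, tRNA modifications (which cause misincorporations at specific
positions in real data), or multi-locus tRNA families beyond what the
supplied reference set contains. Passing tests on this generator therefore
demonstrate the pipeline's logic — coordinate arithmetic, precedence,
counting, calibration — not robustness to base-calling noise or
modification artefacts.

`simulate_count_experiment()` generates the count-matrix side: negative
binomial counts (default dispersion 0.1; 0 gives Poisson) for day-0 and
day-7 groups, with exactly `n_de` rows at a true fold change of `effect`,
either as a mean shift or as the absent-then-peak pattern.

# Problem sizes and numerical choices

The shipped test suite runs the full pipeline at deliberately desk-scale
sizes — reference sets of four toy genes, 800–10 000 reads per simulated
library, 300–500-fragment count matrices, 500-nt UTRs — chosen so the whole
suite exercises every stage in well under a minute of alignment work while
keeping binomial standard errors tight enough for the calibration checks
(3-SE bands at n = 500–10 000). Tolerances are exact where the computation
is exact (coordinate arithmetic, round trips, plates) and 3-binomial-SE
bands where the check is a simulation. Ties are broken deterministically
everywhere (lexicographic reference ids, smallest start, seeded draws), so
every result in the package is reproducible from a seed.

Known limitations, summarised: plates are package-local identifiers; the
DE test is anticonservative under overdispersion; the target scanner is a
complementarity score, not thermodynamics, with a length-dependent null;
5'-UTR/CDS scanning is possible by passing those regions as the "UTR" but
3'-UTRs are the intended use; and mitochondrial tRNAs are not treated as a
separate category.
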