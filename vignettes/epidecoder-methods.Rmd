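---
title: "Methods: barcode-ChIP quantification of a locus-specific proteome"
author: "epidecodr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-ChIP quantification of a locus-specific proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

A pooled barcode-ChIP experiment couples every epitope-tagged clone in a
yeast library to a strain-specific DNA barcode pair integrated at one
common reporter locus: BC_UP on the promoter-proximal side and BC_DN on
the terminator-proximal side. After pooling, cross-linking and a single
anti-tag immunoprecipitation, the barcodes are amplified separately from
the IP and the input chromatin, indexed per sample, and sequenced. The
count of clone $i$'s barcode in the IP, relative to the input, measures
the occupancy of protein $i$ at the barcoded locus.

Formally, with $n_{s,i}$ the matched read count of barcode $i$ in sample
$s$, $N_s=\sum_i n_{s,i}$, $B$ barcodes in the position class, and
pseudocount $a$:

$$\mathrm{score}_i \;=\;
\frac{(n_{\mathrm{IP},i}+a)\,/\,(N_\mathrm{IP}+aB)}
     {(n_{\mathrm{in},i}+a)\,/\,(N_\mathrm{in}+aB)}.$$

The ratio of within-sample proportions cancels clone abundance in the
pool, amplification efficiency of the barcode, and sequencing depth; it
is exactly invariant to multiplying either sample's counts by a constant
when $a=0$, and to better than 1% for $a=0.5$ once counts exceed ~50.
Two consequences shape everything downstream:

* **Scores are relative.** The sample-level proportionality constant is
  the (unknown) mean enrichment of the pool, so a clone's score is its
  enrichment divided by the pool mean. Comparisons across conditions
  implicitly assume that most of the pool is unchanged — the pool itself
  is the internal standard. The contrast functions therefore report
  reference-relative quantities and never claim absolute occupancy; the
  package does not attempt to estimate the pool-level constant.
* **Position classes are separate experiments.** BC_UP and BC_DN are
  amplified and sequenced with their own primers, so proportions are
  computed within a position class over *matched* reads of that class.
  Normalising by total reads per sample instead would couple the two
  libraries through their unmatched fractions; matched-reads-per-class
  was chosen and is used throughout.

## Scoring and aggregation parameters

* `pseudocount` ($a$, default 0.5): regularises zero counts. The raw
  ratio ($a=0$) is available and is what the exactness properties are
  stated for.
* `min_input` (default 10 reads): an input count below this makes the
  denominator too noisy to trust; the score is still computed but the
  replicate is flagged `low_input` and excluded from aggregation.
* Aggregation is the arithmetic mean (and sample SD, $n-1$) of the
  IP/input ratios over the usable barcode replicates, as in
  mean-of-three-replicates displays; log2 is applied for plotting and
  per-replicate log2 scores are retained for time-course work. Keys with
  no usable replicate are reported `missing`, never as zero.
* Replicate QC is Spearman's rank correlation on log2 scores over clones
  usable in both members of a pair (log2 is rank-preserving; ties are
  mid-ranked). Rank correlation is the right instrument here because the
  relation between two barcode replicates is monotone but not
  necessarily linear in raw score space.
* `filter_binders` keeps a clone if its aggregate score exceeds the
  threshold (default 0.5, strict inequality) at any timepoint of any
  scoped condition series, at either position — the rule used to select
  proteins for heatmap display.

## Counting: demultiplexing, extraction, matching

Reads are single-end with a fixed architecture
`index + flank5 + barcode + flank3 + padding`; primer and index
sequences vary between amplicon designs, so the layout is configuration
(`read_layout()`), not a constant.

* **Demultiplexing** matches the leading index bases exactly by default
  (`max_index_mismatch = 0`, conservative). If mismatches are allowed,
  the sample sheet is rejected up front when any two indexes are within
  $2\,m$ of each other, which would make ambiguity possible by
  construction.
* **Extraction** anchors on `flank5` at its expected offset with a
  1-substitution tolerance; anchor failure yields an unusable read (a
  null, not an error), counted as unmatched. Coordinates are 0-based,
  half-open internally.
* **Matching** lets an exact hit win immediately; otherwise all library
  barcodes within Hamming distance 1 are found via masked-position
  lookup tables (for each position $j$, the probe with $j$ blanked is
  matched against the library with $j$ blanked). This is exactly
  equivalent to a brute-force Hamming scan — the test suite checks the
  equivalence on random and adversarial probes — and is robust to
  arbitrary probe characters (an `N` is just a mismatch). A unique
  candidate is assigned; several distinct candidates at the minimal
  distance are `ambiguous` (counted, never fractionally assigned); none
  is `unmatched`. Probes of the wrong length are unmatched, since
  barcode length is fixed per library.
* Libraries generated by `make_barcode_library()` guarantee pairwise
  Hamming distance ≥ 3 within each position class, which makes
  one-mismatch correction provably unambiguous; with such a library,
  `ambiguous` cannot occur at `max_mismatch = 1`. Both exact-only and
  1-mismatch modes are supported because published pipelines differ on
  this point.
* The conservation identity `assigned + unmatched + ambiguous =
  total_reads` is asserted per sample on every run, and counting is
  invariant to read order.

## The synthetic-data generator

The generator stands in for the deposited raw sequencing data and
produces exactly the statistical structure the analysis assumes:

* **Libraries**: barcodes of fixed length 16–20 nt drawn by rejection
  sampling against the minimum-distance constraint (default 3). An
  infeasible request fails with a capacity error rather than silently
  truncating.
* **Ground truth kinetics**: each clone has a baseline enrichment $e_0$
  and a dynamic class. Evicted clones decay exponentially toward a
  floor, $e(t) = f + (e_0-f)e^{-kt}$; recruited clones follow the
  mirrored saturating rise; stable clones are constant. The floor and
  ceiling are clamped per clone (`min(f, e_0)`, `max(c, e_0)`) so the
  class invariants — eviction never rises, recruitment never falls —
  hold for any baseline, including sampled ones. Default kinetics
  (evicted: $e_0 = 2$ to floor 0.25; recruited: $e_0 = 0.5$ to ceiling
  2.25; half-change time 10 min) are chosen to be symmetric around the
  pool mean, so that a mixed pool keeps a constant mean enrichment over
  time and stable clones read out near delta 0 — the situation in which
  the whole-pool internal standard is valid. Baselines default to
  log2-uniform on $[-3, 4]$ (1/8× to 16×), the dynamic range the assay
  spans.
* **Reads**: input samples draw per-barcode counts multinomially with
  equal expected proportions (the pool is approximately an equimolar
  clone mixture); IP samples with proportions weighted by enrichment.
  Reads are assembled per the layout, padded with random sequence, and
  subjected to i.i.d. per-base substitutions (each error is one of the
  three other bases uniformly). The exact pre-error counts are emitted
  as ground truth, and output is byte-identical given the seed. Base
  qualities are constant because nothing downstream uses them.
* **Optional realism**: log-normal clone-abundance skew and
  gamma-distributed per-barcode PCR efficiency (jackpotting) can be
  switched on; both default to off.

What the generator does *not* emulate — and what passing tests therefore
do not certify about real data: indels and quality-dependent errors,
PCR duplicates (no UMIs exist in this assay), chromatin/crosslinking
variability between clones, barcode-sequence-specific amplification
bias, and index hopping. The replicate-correlation QC exists precisely
because barcode-specific bias in real data cannot be ruled out by
simulation.

## Time-course and condition analysis

Profiles are expressed as $\Delta\log_2(t) = \log_2 s(t) - \log_2
s(\mathrm{ref})$ per barcode replicate, with the reference either the
pre-treatment timepoint of the same series (default $t=0$) or a
designated reference condition (e.g. a vehicle sample collected at the
last timepoint). Classification per replicate:

* evicted — final $\Delta\log_2 \le -1$ (2-fold) and non-increasing
  within a 0.25 log2 tolerance between consecutive timepoints;
* recruited — mirrored;
* stable — $\max|\Delta\log_2| < 0.5$.

A clone's call requires 2 of 3 replicates to agree (stable requires all
usable replicates); anything else is `unclassified`, including profiles
with fewer than two post-reference timepoints. All four thresholds are
configuration: they operationalise qualitative language ("rapidly and
progressively evicted"), and the monotonicity tolerance absorbs sampling
noise at the simulated depths. Because classification consumes only
score ratios, it inherits the scale invariance of the scores.

Condition contrasts report $\log_2$ differences of aggregate scores
between two labelled states, exactly antisymmetric in their arguments.
Genes usable in only one state are flagged rather than given a ratio
against a missing value — no detection-floor imputation is performed.
Heatmap matrices group rows by manually curated functional subcategory
(unannotated genes trail in an `other` block) and order columns
position-major; serialisation to TSV is lossless and byte-stable, with
`NA` cells distinct from zero.

## qPCR helpers

RT-qPCR levels are $E^{-(Ct_\mathrm{target}-Ct_\mathrm{spike})}$,
referenced to the untreated sample (exactly 1 by construction), with
technical duplicates averaged before any ratio and mean ± SD taken over
biological replicates after normalisation. Because the spike enters as a
Ct difference, a global additive Ct shift cancels exactly — an algebraic
identity the tests exercise with random shifts. ChIP-qPCR enrichment is
$100 \cdot d \cdot E^{(Ct_\mathrm{input}-Ct_\mathrm{IP})}$ percent of
input with dilution factor $d$. Amplification efficiency defaults to 2.0
(perfect doubling) and is configurable per run; no standard-curve
fitting is attempted. SD is the sample standard deviation ($n-1$),
matching the ± SD convention at $n = 3$.

## Validation scale and numerical choices

The package validates itself on simulation at a deliberate scale: pools
of 200 clones × 3 barcode replicates (600 barcodes per position class),
500 input reads per barcode for recovery and classification checks, and
10,000 probes for matcher/brute-force agreement — large enough that
binomial counting noise is the dominant error term, small enough to run
in about a minute on one core. At that depth the pipeline recovers
enrichments with a median absolute log2 error well inside 0.15 and
classifies mixed kinetics essentially perfectly; the acceptance script
(`scripts/acceptance.R`) recomputes these numbers from scratch for any
seed. Determinism is end-to-end: a seed fixes the library, the truth,
the reads (byte-identical FASTQ) and hence every downstream table.

Known limitations, restated: scores are relative within a sample pair;
cross-condition comparability leans on the whole-pool internal standard
and degrades if a large fraction of the pool changes in one direction
(the generator's balanced defaults model the favourable case); no
statistical testing framework for differential binding is provided, by
design; and real-data effects outside the simulator's error model are
covered only by the replicate QC, not by construction.
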