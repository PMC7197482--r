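# epidecodr

Quantification of the **local chromatin proteome at a single genomic
locus** from pooled barcode-ChIP ("Epi-Decoder") sequencing data.

In an Epi-Decoder experiment, a genome-wide library of yeast clones — each
expressing one TAP-tagged protein and carrying a strain-specific DNA
barcode pair (BC_UP at the promoter side, BC_DN at the terminator side of
a common reporter locus) — is pooled, cross-linked and subjected to a
single anti-tag ChIP. Sequencing the barcodes in the immunoprecipitated
(IP) and input fractions turns protein occupancy at that one locus into a
counting problem: the **binding score** of clone *i* is its relative
barcode abundance in IP over input,

```
score_i = ( (n_IP,i + a) / (N_IP + aB) ) / ( (n_in,i + a) / (N_in + aB) )
```

with counts *n*, per-sample totals *N* (matched reads of the barcode's
position class), *B* barcodes per class and pseudocount *a* (default 0.5).
Each clone is linked to three independent barcode pairs (replicate
libraries I, II, III), so every occupancy estimate comes with internal
replication; Spearman correlation between the replicates is the standard
reproducibility QC. Time courses (e.g. transcription inhibition by
1,10-phenanthroline or 6-azauracil) and state contrasts (mid-log vs
quiescent vs nonquiescent cells) are analysed as reference-relative log2
profiles, with an explicit eviction/recruitment/stable classifier.

The package covers the full desk side of such a study:

* **simulate** — barcode libraries with guaranteed pairwise Hamming
  separation, ground-truth binding kinetics, and FASTQ read simulation
  (index + flank + barcode reads, i.i.d. substitution errors) with exact
  pre-error counts as ground truth;
* **count** — index demultiplexing, anchored barcode extraction,
  error-tolerant (≤ 1 mismatch) barcode matching, count tables with exact
  read conservation;
* **quantify** — binding scores, triple-replicate aggregation
  (mean ± SD), replicate Spearman QC, binder selection by score
  threshold;
* **dynamics** — reference-relative profiles, dynamic-class calls,
  annotation-grouped heatmap matrices, condition contrasts;
* **qpcr** — spike-in-normalized RT-qPCR levels and ChIP-qPCR
  percent-of-input arithmetic.

## Worked example

Simulate a 24-clone pool (three barcode replicates each) through a
three-point inhibition time course, count, score and classify:

```r
library(epidecodr)

lib    <- make_barcode_library(n_clones = 24, n_replicates = 3, seed = 7)
clones <- unique(lib$clone_id)
classes <- setNames(rep(c("evicted", "stable", "recruited"), each = 8), clones)
design <- data.frame(condition = "PH", timepoint = c(0, 20, 40))
truth  <- make_truth_profile(lib, design, classes,
            baseline = setNames(c(2, 1, 0.5)[match(classes,
              c("evicted", "stable", "recruited"))], clones))
sheet  <- make_sample_sheet(design, positions = "UP", seed = 8)
sim    <- simulate_reads(lib, truth, read_layout(), sheet, depth = 300,
                         error_rate = 0.005, seed = 9, dir = tempdir())

cp <- count_pipeline(sim$fastq, lib, sheet, read_layout())
cp$summary
#>   sample_id            total_reads assigned unmatched ambiguous
#> 1 pool1_PH_t0_UP_IP          20964    20875        89         0
#> 2 pool1_PH_t0_UP_input       20930    20859        71         0
#> 3 pool1_PH_t20_UP_IP         20964    20869        95         0
#> ...
```

With a 0.5% per-base error rate, ~99.6% of demultiplexed reads are
assigned (one barcode mismatch tolerated); `assigned + unmatched +
ambiguous = total_reads` holds exactly. Scoring and replicate QC:

```r
sc <- binding_score(cp$counts, sheet, lib)
round(replicate_correlation(sc), 3)
#>         I    II   III
#> I   1.000 0.945 0.938
#> II  0.945 1.000 0.938
#> III 0.938 0.938 1.000
```

The three barcode replicates of each clone rank the pool almost
identically (Spearman ρ ≈ 0.94), i.e. inferred binding is essentially
independent of the barcode sequence. Time-course classification recovers
the simulated dynamics perfectly at this depth:

```r
calls <- classify_dynamics(relative_to_reference(sc))
table(called = calls$dynamic_class, truth = classes[calls$clone_id])
#>            truth
#> called      evicted recruited stable
#>   evicted         8         0      0
#>   recruited       0         8      0
#>   stable          0         0      8
```

## Analysis workflow

`analysis/01_simulate.R` … `analysis/05_qpcr.R` run a full study-scale
scenario (200 clones × 3 barcode replicates, BC_UP and BC_DN, PH/AU time
courses plus mid-log/Q/NQ states, ~2.2M reads): simulation, counting,
scoring with QC, dynamics/heatmap/contrast analysis, and the qPCR
helpers. Each script prints what it found and writes its tables under
`results/` (FASTQ intermediates under `scratch/`).

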