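#!/usr/bin/env Rscript
# Binding scores (relative barcode count IP/input), aggregation of the
# three barcode replicates, and replicate-agreement QC: the pairwise
# Spearman correlations that establish that inferred binding is largely
# independent of the barcode sequences.

suppressMessages({library(epidecodr); library(dplyr)})

lib <- parse_reference_table("results/sim/library.tsv")

for (expt in c("timecourse", "states")) {
  counts <- read_count_table(sprintf("results/counts_%s.tsv", expt))
  counts$count <- as.integer(counts$count)
  sheet <- read_sample_sheet(sprintf("results/sim/samples_%s.tsv", expt))
  sc <- binding_score(counts, sheet, lib, pseudocount = 0.5,
                      min_input = 10)
  agg <- aggregate_replicates(sc)
  write_score_table(sc, sprintf("results/scores_%s.tsv", expt))
  write_score_table(agg, sprintf("results/scores_%s_agg.tsv", expt))
  cat(sprintf("%s: %d per-replicate scores, %d aggregated keys, %d flagged low-input\n",
              expt, nrow(sc), nrow(agg), sum(sc$low_input)))
  for (pos in c("UP", "DN")) {
    rho <- replicate_correlation(sc, position = pos)
    cat(sprintf("  %s replicate Spearman rho: I-II %.3f, I-III %.3f, II-III %.3f\n",
                pos, rho["I", "II"], rho["I", "III"], rho["II", "III"]))
  }
  qc <- replicate_correlation(sc, position = "both")
  write.table(data.frame(replicate = rownames(qc), qc),
              sprintf("results/qc_spearman_%s.tsv", expt),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
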