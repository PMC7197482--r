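#!/usr/bin/env Rscript
# Validation arithmetic on synthetic qPCR measurements: RT-qPCR RNA levels
# normalized to an untreated fission-yeast spike-in, and ChIP-qPCR
# percent-of-input enrichment, both as mean +/- SD over three biological
# replicates. The Ct fixture is generated here (synthetic), mirroring the
# assay design: two technical duplicates per measurement, averaged first.

suppressMessages({library(epidecodr); library(dplyr); library(tidyr)})
set.seed(2031)

## RT-qPCR: transcript decay after Pol II inhibition, one induced gene
samples <- c("Pre", "PH_20", "PH_40")
true_level <- list(KanMX = c(1, 0.9, 0.85),   # little decay at low temp
                   ZRT1 = c(1, 3.5, 6.0),     # PH-responsive induction
                   ACT1 = c(1, 0.8, 0.7))
rt <- expand_grid(target = names(true_level), sample = samples,
                  role = c("target", "spike"), bio_replicate = 1:3,
                  tech_replicate = 1:2)
lvl <- mapply(function(tg, smp) true_level[[tg]][match(smp, samples)],
              rt$target, rt$sample)
noise <- rnorm(nrow(rt), 0, 0.05)
# loading differences shift all Cts of a (sample, replicate) together;
# the spike-in is there to cancel them
loading <- rnorm(nrow(rt), 0, 0.3)[as.integer(
  factor(paste(rt$sample, rt$bio_replicate)))]
rt$ct <- ifelse(rt$role == "target", 20 - log2(lvl), 18) + noise + loading
write.table(rt, "results/qpcr_ct_rna_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rna <- spike_normalized_rna(rt, reference_sample = "Pre")
write_score_table(rna, "results/qpcr_rna_levels.tsv")
cat("RT-qPCR relative RNA levels (spike-normalized, Pre = 1):\n")
print(as.data.frame(rna), digits = 3)

## ChIP-qPCR: Pol II at the barcoded locus, before and after PH
chip <- expand_grid(target = c("BC_UP", "BC_DN", "nontranscribed"),
                    sample = c("Pre", "PH_15", "PH_60"),
                    role = c("ip", "input"), bio_replicate = 1:3,
                    tech_replicate = 1:2)
pct <- list(BC_UP = c(8, 4, 1.5), BC_DN = c(10, 5, 2),
            nontranscribed = c(0.3, 0.3, 0.3))
true_pct <- mapply(function(tg, smp)
  pct[[tg]][match(smp, c("Pre", "PH_15", "PH_60"))],
  chip$target, chip$sample)
chip$ct <- ifelse(chip$role == "input", 20,
                  20 - log2(true_pct / 100)) + rnorm(nrow(chip), 0, 0.08)
write.table(chip, "results/qpcr_ct_chip_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

enr <- chip_qpcr_enrichment(chip, input_dilution_factor = 1)
write_score_table(enr, "results/qpcr_chip_enrichment.tsv")
cat("\nChIP-qPCR enrichment (% input, mean +/- SD of 3 replicates):\n")
print(as.data.frame(enr), digits = 3)
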