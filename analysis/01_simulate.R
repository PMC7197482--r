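#!/usr/bin/env Rscript
# Simulate a pooled barcode-ChIP study: a 200-clone chromatin pool in which
# every TAP-tagged clone carries three independent barcode pairs, profiled
# (i) through a transcription-inhibition time course (PH, with AU in
# parallel) and (ii) across mid-log, quiescent (Q) and nonquiescent (NQ)
# states. Reference tables and ground truth go to results/sim/; FASTQ goes
# to scratch/sim/ (regenerated on demand).

suppressMessages({library(epidecodr); library(dplyr)})
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)

n_clones <- 200
lib <- make_barcode_library(n_clones, n_replicates = 3, seed = 2026)
clones <- unique(lib$clone_id)
layout <- read_layout()

# functional subcategories, used later for heatmap grouping and to pick
# plausible dynamics per group
subcats <- rep(c("Pol II", "elongation", "basal TFs", "termination",
                 "replication", "remodelers", "folding", "metabolic",
                 "other"),
               c(25, 25, 20, 20, 25, 25, 20, 20, 20))
annotation <- tibble(gene = unique(lib$gene), subcategory = subcats,
                     rank = ave(seq_along(subcats), subcats,
                                FUN = seq_along))
write.table(annotation, "results/sim/annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# transcription machinery evicted on Pol II inhibition, remodelers /
# folding / metabolic enzymes recruited, replication proteins stable
class_of <- c("Pol II" = "evicted", elongation = "evicted",
              "basal TFs" = "evicted", termination = "evicted",
              replication = "stable", remodelers = "recruited",
              folding = "recruited", metabolic = "recruited",
              other = "stable")
classes <- setNames(class_of[subcats], clones)
e0 <- setNames(c(evicted = 2, recruited = 0.5, stable = 1)[classes],
               clones)
# unannotated clones are weak/background binders, below the selection
# threshold used for heatmap display
e0[subcats == "other"] <- 0.2

## PH / AU time course (minutes after drug addition; 0 = pre-treatment)
design_tc <- data.frame(condition = rep(c("PH", "AU"), each = 3),
                        timepoint = rep(c(0, 20, 40), 2))
kin_ph <- list(evicted = list(floor = 0.25, rate = log(2) / 10),
               recruited = list(ceiling = 2.25, rate = log(2) / 10))
kin_au <- list(evicted = list(floor = 1.0, rate = log(2) / 10),   # milder
               recruited = list(ceiling = 1.5, rate = log(2) / 10))
truth_tc <- bind_rows(
  make_truth_profile(lib, design_tc[design_tc$condition == "PH", ],
                     classes, kinetics = kin_ph, baseline = e0),
  make_truth_profile(lib, design_tc[design_tc$condition == "AU", ],
                     classes, kinetics = kin_au, baseline = e0))
sheet_tc <- make_sample_sheet(design_tc, positions = c("UP", "DN"),
                              pool = "tc", seed = 2027)
sim_tc <- simulate_reads(lib, truth_tc, layout, sheet_tc, depth = 100,
                         error_rate = 0.002, seed = 2028,
                         dir = "scratch/sim/tc")

## mid-log vs quiescence states (single timepoint each)
design_q <- data.frame(condition = c("midlog", "Q", "NQ"), timepoint = 0)
e_state <- function(fold) setNames(e0 * fold[classes], clones)
truth_q <- bind_rows(
  make_truth_profile(lib, design_q[1, ], classes, baseline = e0),
  # stronger rewiring than PH: machinery down 8x, remodelers up 4x
  make_truth_profile(lib, design_q[2, ], classes,
                     baseline = e_state(c(evicted = 1 / 8, recruited = 4,
                                          stable = 1))),
  make_truth_profile(lib, design_q[3, ], classes,
                     baseline = e_state(c(evicted = 1 / 4, recruited = 2,
                                          stable = 1))))
sheet_q <- make_sample_sheet(design_q, positions = c("UP", "DN"),
                             pool = "qstate", seed = 2029)
sim_q <- simulate_reads(lib, truth_q, layout, sheet_q, depth = 100,
                        error_rate = 0.002, seed = 2030,
                        dir = "scratch/sim/qstate")

write_reference_table(lib, "results/sim/library.tsv")
write_sample_sheet(sheet_tc, "results/sim/samples_timecourse.tsv")
write_sample_sheet(sheet_q, "results/sim/samples_states.tsv")
write.table(truth_tc, "results/sim/truth_timecourse.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth_q, "results/sim/truth_states.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_run_config(layout, kin_ph, "results/sim/run_config.yaml")
tc_class <- tibble(clone_id = clones, dynamic_class = unname(classes))
write.table(tc_class, "results/sim/truth_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("library: %d clones x 3 barcode replicates (%d barcodes/position)\n",
            n_clones, nrow(lib)))
cat(sprintf("time course: %d samples, %s reads\n", nrow(sheet_tc),
            format(sum(sim_tc$n_reads), big.mark = ",")))
cat(sprintf("states: %d samples, %s reads\n", nrow(sheet_q),
            format(sum(sim_q$n_reads), big.mark = ",")))
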