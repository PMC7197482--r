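# Shared fixture builders and independent oracles.

# Brute-force Hamming matcher over a whole barcode set, via one-hot
# matrix products: dist[i, j] = L - sum_a (probe_i == a) & (bc_j == a).
# Independent of the masked-key index used by the package.
brute_force_match <- function(probes, bcs, max_mismatch = 1L) {
  L <- nchar(bcs[1])
  enc <- function(x) {
    m <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                nrow = length(x), byrow = TRUE)
    lapply(c("A", "C", "G", "T"), function(a) (m == a) * 1L)
  }
  ok <- nchar(probes) == L
  status <- rep("unmatched", length(probes))
  row <- rep(NA_integer_, length(probes))
  if (any(ok)) {
    P <- enc(probes[ok])
    B <- enc(bcs)
    matches <- Reduce(`+`, Map(function(p, b) p %*% t(b), P, B))
    dist <- L - matches
    dmin <- apply(dist, 1, min)
    nmin <- rowSums(dist == dmin)
    st <- ifelse(dmin > max_mismatch, "unmatched",
                 ifelse(nmin > 1L, "ambiguous", "assigned"))
    # exact match always wins uniquely (barcodes are distinct)
    rw <- ifelse(st == "assigned", apply(dist, 1, which.min), NA_integer_)
    status[ok] <- st
    row[ok] <- rw
  }
  list(status = status, row = row)
}

# Mutate a sequence at k distinct positions (guaranteed Hamming distance k).
mutate_at <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# A small complete simulated experiment shared by several tests.
tiny_experiment <- function(n_clones = 12, depth = 200, error_rate = 0,
                            seed = 42, positions = "UP",
                            timepoints = c(0, 20, 40),
                            classes = NULL, baseline = NULL) {
  lib <- make_barcode_library(n_clones, n_replicates = 3, seed = seed)
  clones <- unique(lib$clone_id)
  if (is.null(classes)) {
    classes <- stats::setNames(rep("stable", n_clones), clones)
  }
  design <- data.frame(condition = "PH", timepoint = timepoints)
  truth <- make_truth_profile(lib, design, classes, baseline = baseline,
                              seed = seed + 1)
  sheet <- make_sample_sheet(design, positions = positions,
                             seed = seed + 2)
  layout <- read_layout()
  sim <- simulate_reads(lib, truth, layout, sheet, depth = depth,
                        error_rate = error_rate, seed = seed + 3,
                        dir = tempfile("sim"))
  list(lib = lib, truth = truth, sheet = sheet, layout = layout, sim = sim,
       classes = classes)
}

# Hand-built binding-score rows for aggregation / filtering tests.
score_row <- function(clone, rep, score, low_input = FALSE,
                      condition = "PH", timepoint = 0, position = "UP") {
  tibble::tibble(clone_id = clone, gene = toupper(clone), replicate = rep,
                 position = position, condition = condition,
                 timepoint = timepoint, pair_id = "p",
                 ip_count = 100L, input_count = if (low_input) 3L else 100L,
                 score = score, log2_score = log2(score),
                 low_input = low_input)
}
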