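test_that("barcode library satisfies structure and distance guarantees", {
  lib <- make_barcode_library(2, n_replicates = 3, bc_length = 16,
                              min_distance = 3, seed = 7)
  expect_equal(nrow(lib), 6)
  expect_equal(length(unique(lib$bc_up)), 6)
  expect_equal(length(unique(lib$bc_dn)), 6)
  expect_true(all(nchar(c(lib$bc_up, lib$bc_dn)) == 16))
  # exhaustive pairwise check within each position class (brute force)
  for (bcs in list(lib$bc_up, lib$bc_dn)) {
    pairs <- combn(length(bcs), 2)
    d <- hamming_distance(bcs[pairs[1, ]], bcs[pairs[2, ]])
    expect_true(all(d >= 3))
  }
  # deterministic given seed
  expect_identical(lib, make_barcode_library(2, 3, 16, 3, seed = 7))
  expect_false(identical(lib, make_barcode_library(2, 3, 16, 3, seed = 8)))
})

test_that("empty and minimal libraries are handled", {
  empty <- make_barcode_library(0)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("clone_id", "gene", "replicate", "bc_up", "bc_dn"))
  one <- make_barcode_library(1, n_replicates = 1, seed = 3)
  expect_equal(nrow(one), 1)
  expect_false(one$bc_up == one$bc_dn)
})

test_that("infeasible barcode requests raise a capacity error", {
  set.seed(1)
  expect_error(
    epidecodr:::generate_separated_barcodes(500, 16, 14, max_attempts = 600),
    "capacity")
  expect_error(make_barcode_library(2, min_distance = 2), "min_distance")
})

test_that("truth profiles follow the stated kinetics", {
  lib <- make_barcode_library(3, n_replicates = 1, seed = 1)
  clones <- unique(lib$clone_id)
  design <- data.frame(condition = "PH", timepoint = c(0, 1, 2))

  # stable: constant at every timepoint
  tr <- make_truth_profile(lib, design,
                           stats::setNames(rep("stable", 3), clones),
                           baseline = 1.0)
  expect_true(all(tr$enrichment == 1.0))

  # evicted closed form: e0=4, floor=0, rate=ln2, t=1 -> 2.0
  tr <- make_truth_profile(lib, design,
                           stats::setNames(rep("evicted", 3), clones),
                           kinetics = list(evicted = list(floor = 0,
                                                          rate = log(2)),
                                           recruited = list(ceiling = 4,
                                                            rate = log(2))),
                           baseline = 4)
  expect_equal(unique(tr$enrichment[tr$timepoint == 1]), 2.0)
  expect_equal(unique(tr$enrichment[tr$timepoint == 2]), 1.0)

  # rate -> infinity limit: enrichment equals the floor at all t > 0
  tr <- make_truth_profile(lib, design,
                           stats::setNames(rep("evicted", 3), clones),
                           kinetics = list(evicted = list(floor = 0.5,
                                                          rate = 1e9),
                                           recruited = list(ceiling = 4,
                                                            rate = 1e9)),
                           baseline = 4)
  expect_equal(unique(tr$enrichment[tr$timepoint > 0]), 0.5)
})

test_that("truth profile classes are monotone and inputs validated", {
  lib <- make_barcode_library(6, n_replicates = 1, seed = 5)
  clones <- unique(lib$clone_id)
  design <- data.frame(condition = "Qentry", timepoint = c(0, 5, 10, 20))
  cls <- stats::setNames(rep(c("evicted", "recruited", "stable"), 2),
                         clones)
  for (seed in 1:5) {
    tr <- make_truth_profile(lib, design, cls, seed = seed)
    expect_true(all(tr$enrichment > 0))
    chk <- tapply(seq_len(nrow(tr)), paste(tr$clone_id, tr$position),
                  function(i) {
      p <- tr[i, ][order(tr$timepoint[i]), ]
      switch(p$dynamic_class[1],
             evicted = all(diff(p$enrichment) <= 1e-12),
             recruited = all(diff(p$enrichment) >= -1e-12),
             stable = all(p$enrichment == p$enrichment[1]))
    })
    expect_true(all(unlist(chk)))
  }
  expect_error(make_truth_profile(lib, design, cls, baseline = -1), "e0")
  expect_error(make_truth_profile(lib, design, cls[-1]), "missing clones")
  expect_error(
    make_truth_profile(lib, design,
                       stats::setNames(rep("wobbly", 6), clones)),
    "unknown dynamic class")
})

test_that("simulated FASTQ is deterministic, conserved and parseable", {
  exp1 <- tiny_experiment(n_clones = 4, depth = 30, seed = 11)
  exp2 <- tiny_experiment(n_clones = 4, depth = 30, seed = 11)
  expect_identical(readLines(exp1$sim$fastq[["UP"]]),
                   readLines(exp2$sim$fastq[["UP"]]))

  # conservation: ground-truth counts sum to reads emitted per sample
  per_sample <- tapply(exp1$sim$truth_counts$count,
                       exp1$sim$truth_counts$sample_id, sum)
  expect_equal(per_sample[names(exp1$sim$n_reads)],
               exp1$sim$n_reads[names(exp1$sim$n_reads)],
               ignore_attr = TRUE)
  reads <- read_fastq(exp1$sim$fastq[["UP"]])
  expect_equal(length(reads), sum(exp1$sim$truth_counts$count))
  expect_true(all(nchar(reads) == exp1$layout$read_length))

  # independent exact-substring scan: with error_rate = 0 every read
  # contains one of the library barcodes verbatim
  has_bc <- Reduce(`|`, lapply(exp1$lib$bc_up,
                               function(b) grepl(b, reads, fixed = TRUE)))
  expect_true(all(has_bc))
})

test_that("empty library simulates to valid empty outputs", {
  lib <- make_barcode_library(0)
  design <- data.frame(condition = "PH", timepoint = 0)
  truth <- make_truth_profile(lib, design, character(0))
  sheet <- make_sample_sheet(design, positions = "UP", seed = 1)
  sim <- simulate_reads(lib, truth, read_layout(), sheet,
                        dir = tempfile("empty"))
  expect_equal(nrow(sim$truth_counts), 0)
  expect_equal(length(read_fastq(sim$fastq[["UP"]])), 0)
})

test_that("substitution error rate matches the binomial closed form", {
  n_clones <- 5
  depth <- 680  # 5 clones x 3 replicates x 680 ~ 10,200 reads per sample
  exp <- tiny_experiment(n_clones = n_clones, depth = depth,
                         error_rate = 0.01, seed = 19, timepoints = 0)
  reads <- read_fastq(exp$sim$fastq[["UP"]])
  lay <- exp$layout
  bc_obs <- substr(reads, lay$barcode_offset + 1,
                   lay$barcode_offset + lay$bc_length)
  frac_err <- mean(!bc_obs %in% exp$lib$bc_up)
  p <- 1 - 0.99^16
  sigma <- sqrt(p * (1 - p) / length(reads))
  expect_lt(abs(frac_err - p), 3 * sigma)
})

test_that("IP proportions converge to enrichment-weighted proportions", {
  lib <- make_barcode_library(8, n_replicates = 3, seed = 23)
  clones <- unique(lib$clone_id)
  e <- stats::setNames(2^seq(-2, 1.5, length.out = 8), clones)
  design <- data.frame(condition = "PH", timepoint = 0)
  truth <- make_truth_profile(lib, design,
                              stats::setNames(rep("stable", 8), clones),
                              baseline = e)
  sheet <- make_sample_sheet(design, positions = "UP", seed = 2)
  sim <- simulate_reads(lib, truth, read_layout(), sheet, depth = 2000,
                        seed = 3, dir = tempfile("gof"))
  ip <- sim$truth_counts[grepl("_IP$", sim$truth_counts$sample_id), ]
  expected <- e[ip$clone_id] / sum(e[ip$clone_id])
  pval <- suppressWarnings(
    stats::chisq.test(ip$count, p = expected)$p.value)
  expect_gt(pval, 0.001)
})

test_that("truth keys required by the sample sheet are enforced", {
  exp <- tiny_experiment(n_clones = 3, depth = 10, seed = 31)
  truncated <- exp$truth[exp$truth$timepoint != 40, ]
  expect_error(
    simulate_reads(exp$lib, truncated, exp$layout, exp$sheet,
                   dir = tempfile()),
    "missing \\(PH, t=40")
})

test_that("run configuration round-trips through YAML", {
  lay <- read_layout(index_length = 8, bc_length = 18, read_length = 60)
  kin <- list(evicted = list(floor = 0.25, rate = 0.0693))
  path <- tempfile(fileext = ".yaml")
  write_run_config(lay, kin, path)
  cfg <- read_run_config(path)
  expect_equal(unclass(cfg$layout), unclass(lay))
  expect_equal(cfg$kinetics$evicted$floor, 0.25)
})
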