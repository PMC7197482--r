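# Per-replicate score rows over a time course.
tc_scores <- function(clone, rep_scores, timepoints = c(0, 20, 40),
                      condition = "PH") {
  dplyr::bind_rows(lapply(names(rep_scores), function(r) {
    dplyr::bind_rows(lapply(seq_along(timepoints), function(i) {
      score_row(clone, r, rep_scores[[r]][i], condition = condition,
                timepoint = timepoints[i])
    }))
  }))
}

test_that("reference-relative profiles are zero at reference", {
  s <- tc_scores("c1", list(I = c(2, 2, 2)))
  d <- relative_to_reference(s)
  expect_equal(d$delta_log2, c(0, 0, 0))

  s <- tc_scores("c1", list(I = c(2, 1, 0.5)))
  d <- relative_to_reference(s)
  expect_equal(d$delta_log2[d$timepoint == 0], 0)
  expect_equal(d$delta_log2[d$timepoint == 20], -1)
  expect_equal(d$delta_log2[d$timepoint == 40], -2)
})

test_that("profiles lacking a usable reference are skipped with warning", {
  s <- dplyr::bind_rows(
    tc_scores("c1", list(I = c(2, 1, 0.5))),
    tc_scores("c2", list(I = c(1, 1, 1)))[-1, ])  # no t = 0 row
  expect_warning(d <- relative_to_reference(s), "skipped")
  expect_setequal(unique(d$clone_id), "c1")
})

test_that("a vehicle series can serve as the reference", {
  s <- dplyr::bind_rows(
    tc_scores("c1", list(I = c(4, 4, 4)), condition = "vehicle"),
    tc_scores("c1", list(I = c(4, 2, 1)), condition = "PH"))
  d <- relative_to_reference(s, reference_timepoint = 0,
                             reference_condition = "vehicle")
  ph <- d[d$condition == "PH", ]
  expect_equal(ph$delta_log2[order(ph$timepoint)], c(0, -1, -2))
})

test_that("dynamic classes follow the stated decision rules", {
  ev <- tc_scores("c1", list(I = 2^c(0, -1.2, -2.5),
                             II = 2^c(0, -1.2, -2.5),
                             III = 2^c(0, -1.2, -2.5)))
  expect_equal(classify_dynamics(relative_to_reference(ev))$dynamic_class,
               "evicted")

  st <- tc_scores("c1", list(I = 2^c(0, 0.1, -0.1),
                             II = 2^c(0, -0.2, 0.2),
                             III = 2^c(0, 0, 0)))
  expect_equal(classify_dynamics(relative_to_reference(st))$dynamic_class,
               "stable")

  rc <- tc_scores("c1", list(I = 2^c(0, 0.8, 1.6),
                             II = 2^c(0, 1.0, 2.1),
                             III = 2^c(0, 0.2, 0.1)))  # 2 of 3 agree
  expect_equal(classify_dynamics(relative_to_reference(rc))$dynamic_class,
               "recruited")

  # large but non-monotone swings stay unclassified
  un <- tc_scores("c1", list(I = 2^c(0, -2.5, -1.2),
                             II = 2^c(0, -2.5, -1.2),
                             III = 2^c(0, -2.5, -1.2)))
  expect_equal(classify_dynamics(relative_to_reference(un))$dynamic_class,
               "unclassified")

  # a single post-reference timepoint cannot be classified
  short <- tc_scores("c1", list(I = c(2, 1), II = c(2, 1), III = c(2, 1)),
                     timepoints = c(0, 20))
  expect_equal(classify_dynamics(relative_to_reference(short))$dynamic_class,
               "unclassified")
})

test_that("classification recovers simulated kinetics and ignores scaling", {
  n <- 30
  lib <- make_barcode_library(n, n_replicates = 3, seed = 51)
  clones <- unique(lib$clone_id)
  classes <- stats::setNames(rep(c("evicted", "recruited", "stable"), n / 3),
                             clones)
  e0 <- stats::setNames(
    c(evicted = 2, recruited = 0.5, stable = 1)[classes], clones)
  design <- data.frame(condition = "PH", timepoint = c(0, 20, 40))
  truth <- make_truth_profile(lib, design, classes, baseline = e0)
  sheet <- make_sample_sheet(design, positions = "UP", seed = 52)
  sim <- simulate_reads(lib, truth, read_layout(), sheet, depth = 400,
                        seed = 53, dir = tempfile("cls"))
  cp <- count_pipeline(sim$fastq, lib, sheet, read_layout())
  sc <- binding_score(cp$counts, sheet, lib, pseudocount = 0)
  calls <- classify_dynamics(relative_to_reference(sc))
  expect_gte(mean(calls$dynamic_class == classes[calls$clone_id]), 0.9)

  # uniform per-sample count scaling leaves every call unchanged
  scaled <- cp$counts
  one <- scaled$sample_id == scaled$sample_id[1]
  scaled$count[one] <- scaled$count[one] * 11L
  sc2 <- binding_score(scaled, sheet, lib, pseudocount = 0)
  calls2 <- classify_dynamics(relative_to_reference(sc2))
  expect_identical(calls2, calls)
})

test_that("heatmap rows group by subcategory and serialise losslessly", {
  agg <- tibble::tibble(
    clone_id = c("c1", "c2", "c3"),
    gene = c("RPB1", "ORC1", "ZUZ1"),
    position = "UP", condition = "PH", timepoint = 0,
    mean_score = c(2, 3, 0.4), sd_score = 0, n_replicates = 3L,
    missing = FALSE)
  ann <- tibble::tibble(gene = c("ORC1", "RPB1"),
                        subcategory = c("replication", "Pol II"),
                        rank = c(1L, 1L))
  hm <- build_heatmap_matrix(agg, ann)
  # subcategory order from the annotation, unannotated genes trail
  expect_equal(rownames(hm$matrix), c("ORC1", "RPB1", "ZUZ1"))
  expect_equal(hm$row_meta$subcategory,
               c("replication", "Pol II", "other"))
  expect_equal(hm$matrix["RPB1", 1], 2)

  # missing cells are NA, not zero (no DN measurement for ORC1)
  agg2 <- dplyr::bind_rows(
    agg, dplyr::mutate(agg[-2, ], position = "DN", mean_score = c(5, 6)))
  hm2 <- build_heatmap_matrix(agg2, ann)
  expect_true(is.na(hm2$matrix["ORC1", "DN_PH_t0"]))
  expect_equal(colnames(hm2$matrix), c("UP_PH_t0", "DN_PH_t0"))

  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_heatmap_matrix(hm2, p1)
  rt <- read_heatmap_matrix(p1)
  expect_equal(rt$matrix, hm2$matrix)
  write_heatmap_matrix(rt, p2)
  for (suffix in c("", ".rows.tsv", ".cols.tsv")) {
    a <- paste0(p1, suffix)
    b <- paste0(p2, suffix)
    expect_identical(readBin(a, "raw", file.size(a)),
                     readBin(b, "raw", file.size(b)))
  }
})

test_that("condition contrasts are exact and antisymmetric", {
  agg_state <- function(cond, scores) {
    tibble::tibble(clone_id = paste0("c", seq_along(scores)),
                   gene = paste0("G", seq_along(scores)),
                   position = "UP", condition = cond, timepoint = 0,
                   mean_score = scores, sd_score = 0,
                   n_replicates = 3L, missing = is.na(scores))
  }
  agg <- dplyr::bind_rows(agg_state("midlog", c(2, 1, NA)),
                          agg_state("Q", c(0.5, 1, 4)))
  ct <- compare_conditions(agg, "Q", "midlog")
  expect_equal(ct$delta_log2[ct$clone_id == "c1"], -2)
  expect_equal(ct$delta_log2[ct$clone_id == "c2"], 0)
  expect_equal(ct$flag[ct$clone_id == "c3"], "a_only")
  expect_true(is.na(ct$delta_log2[ct$clone_id == "c3"]))

  rev <- compare_conditions(agg, "midlog", "Q")
  both <- ct$flag == "both"
  expect_identical(ct$delta_log2[both],
                   -rev$delta_log2[match(ct$clone_id[both], rev$clone_id)])

  same <- dplyr::bind_rows(agg_state("Q", c(2, 3)), agg_state("NQ", c(2, 3)))
  expect_equal(compare_conditions(same, "Q", "NQ")$delta_log2, c(0, 0))

  disjoint <- dplyr::bind_rows(agg_state("Q", c(2, NA)),
                               agg_state("NQ", c(NA, 3)))
  expect_error(compare_conditions(disjoint[c(1, 4), ], "Q", "NQ"),
               "no shared genes")
})

test_that("condition contrasts recover simulated state changes in sign", {
  n <- 20
  lib <- make_barcode_library(n, n_replicates = 3, seed = 61)
  clones <- unique(lib$clone_id)
  # transcription machinery down 8-fold, remodelers up 4-fold in Q
  e_mid <- stats::setNames(rep(2, n), clones)
  e_q <- stats::setNames(rep(c(2 / 8, 2 * 4), n / 2), clones)
  design <- data.frame(condition = c("midlog", "Q"), timepoint = 0)
  sheet <- make_sample_sheet(design, positions = "UP", seed = 62)
  truth <- dplyr::bind_rows(
    make_truth_profile(lib, design[1, ],
                       stats::setNames(rep("stable", n), clones),
                       baseline = e_mid),
    make_truth_profile(lib, design[2, ],
                       stats::setNames(rep("stable", n), clones),
                       baseline = e_q))
  sim <- simulate_reads(lib, truth, read_layout(), sheet, depth = 500,
                        seed = 63, dir = tempfile("qc"))
  cp <- count_pipeline(sim$fastq, lib, sheet, read_layout())
  agg <- aggregate_replicates(binding_score(cp$counts, sheet, lib))
  ct <- compare_conditions(agg, "Q", "midlog")
  # scores are relative within a sample pair, so the observed contrast is
  # the true per-clone change minus the pool-level normalisation shift;
  # adding the shift back recovers the true sign
  truth_sign <- rep(c(-1, 1), n / 2)[match(ct$clone_id, clones)]
  norm_shift <- log2(mean(e_q) / mean(e_mid))
  expect_gte(mean(sign(ct$delta_log2 + norm_shift) == truth_sign), 0.95)
})
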