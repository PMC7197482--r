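#' Compute binding scores (relative barcode count, IP/input)
#'
#' The binding score of a barcode is its relative abundance in the
#' immunoprecipitated sample divided by its relative abundance in the
#' matched input sample:
#' `score = ((ip + a) / (ip_total + a * B)) / ((input + a) / (input_total + a * B))`
#' with pseudocount `a` and `B` barcodes in the sample's position class.
#' Proportions are computed within a position class over matched reads only,
#' because the upstream and downstream barcodes are amplified and sequenced
#' as separate libraries. Scores are invariant to uniform per-sample count
#' scaling (exactly so at `a = 0`).
#'
#' @param counts Count tibble from [count_pipeline()] / [count_barcodes()].
#' @param sample_sheet A `SampleSheet`; every IP sample must pair with one
#'   input sample via `pair_id` (orphans are an error).
#' @param library Optional `LibraryTable` used to annotate gene symbols.
#' @param pseudocount Pseudocount `a` added to every count (default 0.5;
#'   `0` gives the unregularised ratio, undefined for zero input counts).
#' @param min_input Input-count floor below which the `low_input` flag is
#'   set (default 10); the score is still computed.
#' @return A `BindingScoreTable` tibble keyed by (`clone_id`, `gene`,
#'   `replicate`, `position`, `condition`, `timepoint`) with `ip_count`,
#'   `input_count`, `score`, `log2_score`, `low_input`.
#' @export
binding_score <- function(counts, sample_sheet, library = NULL,
                          pseudocount = 0.5, min_input = 10L) {
  stopifnot(pseudocount >= 0)
  sheet <- sample_sheet[, c("sample_id", "fraction", "position",
                            "condition", "timepoint", "pair_id")]
  have <- unique(counts$sample_id)
  sheet <- sheet[sheet$sample_id %in% have, ]
  pair_n <- table(sheet$pair_id,
                  factor(sheet$fraction, c("IP", "input")))
  orphan <- rownames(pair_n)[pair_n[, "IP", drop = TRUE] != 1 |
                               pair_n[, "input", drop = TRUE] != 1]
  if (length(orphan)) {
    stop("unpaired sample pair_id(s): ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::inner_join(counts, sheet, by = "sample_id",
                         suffix = c("", ".sheet"))
  x <- dplyr::group_by(x, .data$sample_id)
  x <- dplyr::mutate(x,
                     total = sum(.data$count),
                     B = dplyr::n(),
                     prop = (.data$count + pseudocount) /
                       (.data$total + pseudocount * .data$B))
  x <- dplyr::ungroup(x)
  key <- c("pair_id", "clone_id", "replicate", "condition", "timepoint")
  if ("position.sheet" %in% names(x)) x$position.sheet <- NULL
  ip <- x[x$fraction == "IP",
          c(key, "position", "count", "prop")]
  inp <- x[x$fraction == "input", c(key, "count", "prop")]
  sc <- dplyr::inner_join(ip, inp, by = key, suffix = c("_ip", "_input"))
  sc$score <- sc$prop_ip / sc$prop_input
  out <- tibble::tibble(
    clone_id = sc$clone_id,
    gene = if (is.null(library)) NA_character_ else
      library$gene[match(sc$clone_id, library$clone_id)],
    replicate = sc$replicate,
    position = sc$position,
    condition = sc$condition,
    timepoint = sc$timepoint,
    pair_id = sc$pair_id,
    ip_count = sc$count_ip,
    input_count = sc$count_input,
    score = sc$score,
    log2_score = log2(sc$score),
    low_input = sc$count_input < min_input
  )
  out
}

#' Aggregate the three barcode replicates of each clone
#'
#' Arithmetic mean and sample standard deviation (n - 1) of the IP/input
#' score over usable replicates — those with a finite score and no
#' `low_input` flag. Keys with no usable replicate are kept and flagged
#' `missing` rather than reported as zero; `sd_score` is `NA` when fewer
#' than two replicates contribute.
#'
#' @param scores A `BindingScoreTable` from [binding_score()].
#' @return An `AggregateScore` tibble keyed by (`clone_id`, `gene`,
#'   `position`, `condition`, `timepoint`) with `mean_score`, `sd_score`,
#'   `n_replicates`, `missing`.
#' @export
aggregate_replicates <- function(scores) {
  x <- dplyr::mutate(scores,
                     usable = is.finite(.data$score) & !.data$low_input)
  x <- dplyr::group_by(x, .data$clone_id, .data$gene, .data$position,
                       .data$condition, .data$timepoint)
  out <- dplyr::summarise(
    x,
    mean_score = if (any(.data$usable))
      mean(.data$score[.data$usable]) else NA_real_,
    sd_score = if (sum(.data$usable) >= 2L)
      stats::sd(.data$score[.data$usable]) else NA_real_,
    n_replicates = sum(.data$usable),
    .groups = "drop"
  )
  out$missing <- out$n_replicates == 0L
  out
}

#' Pairwise Spearman correlation between barcode replicates
#'
#' Reproducibility QC across the three independent barcode replicates:
#' Spearman rank correlation of log2 binding scores over the clones usable
#' in both members of each pair (I-II, I-III, II-III). Log2 is
#' rank-preserving, so the coefficient equals that on raw scores; ties are
#' mid-ranked (the `stats::cor` convention). Pairs sharing fewer than
#' `min_shared` clones yield `NA` with a warning.
#'
#' @param scores A `BindingScoreTable`.
#' @param position `"UP"`, `"DN"`, or `"both"` (pool both position classes
#'   as separate observations).
#' @param min_shared Minimum shared observations per pair (default 3).
#' @return Symmetric correlation matrix with unit diagonal, one row/column
#'   per replicate present.
#' @export
replicate_correlation <- function(scores, position = c("both", "UP", "DN"),
                                  min_shared = 3L) {
  position <- match.arg(position)
  x <- scores[is.finite(scores$log2_score) & !scores$low_input, ]
  if (position != "both") x <- x[x$position == position, ]
  x$key <- paste(x$clone_id, x$position, x$condition, x$timepoint,
                 sep = "\r")
  reps <- sort(unique(x$replicate))
  m <- diag(1, length(reps))
  dimnames(m) <- list(reps, reps)
  for (i in seq_along(reps)) {
    for (j in seq_along(reps)) {
      if (j <= i) next
      a <- x[x$replicate == reps[i], ]
      b <- x[x$replicate == reps[j], ]
      shared <- intersect(a$key, b$key)
      if (length(shared) < min_shared) {
        warning(sprintf("replicates %s-%s share only %d usable scores",
                        reps[i], reps[j], length(shared)))
        m[i, j] <- m[j, i] <- NA_real_
      } else {
        m[i, j] <- m[j, i] <- stats::cor(
          a$log2_score[match(shared, a$key)],
          b$log2_score[match(shared, b$key)],
          method = "spearman")
      }
    }
  }
  m
}

#' Select binders by aggregate score threshold across series
#'
#' Retains a clone iff its mean binding score exceeds `threshold` at any
#' (condition, timepoint) of any series in `scope`, at either barcode
#' position — the selection used to restrict heatmaps to proteins detected
#' in at least one of the profiled time series.
#'
#' @param agg An `AggregateScore` table.
#' @param threshold Score threshold (default 0.5; strictly greater-than).
#' @param scope Character vector of condition labels defining the series
#'   examined; must be non-empty.
#' @return The rows of `agg` belonging to retained clones.
#' @export
filter_binders <- function(agg, threshold = 0.5, scope) {
  if (missing(scope) || length(scope) == 0L) {
    stop("scope must name at least one condition series", call. = FALSE)
  }
  hit <- agg$condition %in% scope & !is.na(agg$mean_score) &
    agg$mean_score > threshold
  keep <- unique(agg$clone_id[hit])
  agg[agg$clone_id %in% keep, ]
}

#' Read / write a binding-score or aggregate table as TSV
#' @param tab Tibble to write.
#' @param path File path.
#' @export
write_score_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
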