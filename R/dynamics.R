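#' Express log2 binding scores relative to a reference timepoint
#'
#' For every (clone, replicate, position, condition) profile, subtracts the
#' log2 score at the reference from every timepoint:
#' `delta_log2(t) = log2_score(t) - log2_score(reference)`. The reference is
#' either a timepoint within the same condition series (default `t = 0`,
#' the pre-treatment sample) or a separate reference condition (e.g. a
#' vehicle-treated sample collected alongside the series). Profiles whose
#' reference is missing or unusable are skipped with a warning; the
#' reference row itself is exactly 0.
#'
#' @param scores A `BindingScoreTable` from [binding_score()].
#' @param reference_timepoint Reference timepoint (default 0).
#' @param reference_condition Optional condition label providing the
#'   reference; `NULL` (default) takes the reference from each profile's
#'   own condition.
#' @return Tibble with the profile keys, `timepoint`, `log2_score` and
#'   `delta_log2`.
#' @export
relative_to_reference <- function(scores, reference_timepoint = 0,
                                  reference_condition = NULL) {
  x <- scores
  x$usable <- is.finite(x$log2_score) & !x$low_input
  ref <- x[x$timepoint == reference_timepoint & x$usable, ]
  if (!is.null(reference_condition)) {
    ref <- ref[ref$condition == reference_condition, ]
  } else {
    ref$ref_condition <- ref$condition
  }
  key_of <- function(d, cond) {
    paste(d$clone_id, d$replicate, d$position, cond, sep = "\r")
  }
  ref_key <- key_of(ref, if (is.null(reference_condition)) ref$condition
                    else "")
  out <- x
  probe_key <- key_of(out, if (is.null(reference_condition)) out$condition
                      else "")
  ref_log2 <- ref$log2_score[match(probe_key, ref_key)]
  out$delta_log2 <- ifelse(out$usable, out$log2_score - ref_log2, NA_real_)
  dropped <- is.na(ref_log2)
  if (any(dropped)) {
    n_prof <- length(unique(probe_key[dropped]))
    warning(sprintf("%d profile(s) skipped: reference unusable or missing",
                    n_prof))
    out <- out[!dropped, ]
  }
  out[, c("clone_id", "gene", "replicate", "position", "condition",
          "timepoint", "log2_score", "delta_log2", "low_input")]
}

#' Classify time-course profiles as evicted, recruited or stable
#'
#' Operationalises qualitative time-course calls on reference-relative
#' profiles. Per replicate (reference included as delta 0):
#' \itemize{
#'   \item evicted: final `delta_log2 <= -min_effect` and non-increasing
#'     within `monotone_tol` log2 units between consecutive timepoints;
#'   \item recruited: the mirrored rise;
#'   \item stable: `max(|delta_log2|) < stable_band`.
#' }
#' A clone is called evicted/recruited when at least
#' `min_consistent_replicates` usable replicates agree, stable when all
#' usable replicates are stable, and unclassified otherwise (including
#' profiles with fewer than two post-reference timepoints). Thresholds are
#' configuration, not biology: the defaults ask for a 2-fold final change
#' and absorb 0.25 log2 units of sampling noise in the monotonicity check.
#'
#' @param delta Output of [relative_to_reference()].
#' @param min_effect Minimum final |delta_log2| (default 1, i.e. 2-fold).
#' @param min_consistent_replicates Replicates that must agree (default 2).
#' @param stable_band Half-width of the stable corridor (default 0.5).
#' @param monotone_tol Tolerated counter-movement between consecutive
#'   timepoints (default 0.25).
#' @return Tibble: `clone_id`, `gene`, `position`, `condition`,
#'   `dynamic_class`, `n_replicates_used`.
#' @export
classify_dynamics <- function(delta, min_effect = 1,
                              min_consistent_replicates = 2L,
                              stable_band = 0.5, monotone_tol = 0.25) {
  grp <- dplyr::group_by(delta, .data$clone_id, .data$gene, .data$position,
                         .data$condition)
  per_rep <- function(d) {
    votes <- c(evicted = 0L, recruited = 0L, stable = 0L)
    used <- 0L
    for (r in unique(d$replicate)) {
      p <- d[d$replicate == r, ]
      p <- p[order(p$timepoint), ]
      if (nrow(p) < 3L || any(!is.finite(p$delta_log2))) next
      used <- used + 1L
      dd <- diff(p$delta_log2)
      final <- p$delta_log2[nrow(p)]
      if (final <= -min_effect && all(dd <= monotone_tol)) {
        votes["evicted"] <- votes["evicted"] + 1L
      }
      if (final >= min_effect && all(dd >= -monotone_tol)) {
        votes["recruited"] <- votes["recruited"] + 1L
      }
      if (max(abs(p$delta_log2)) < stable_band) {
        votes["stable"] <- votes["stable"] + 1L
      }
    }
    cls <- "unclassified"
    if (used > 0L) {
      if (votes["evicted"] >= min_consistent_replicates &&
          votes["evicted"] > votes["recruited"]) {
        cls <- "evicted"
      } else if (votes["recruited"] >= min_consistent_replicates &&
                 votes["recruited"] > votes["evicted"]) {
        cls <- "recruited"
      } else if (votes["stable"] == used) {
        cls <- "stable"
      }
    }
    tibble::tibble(dynamic_class = cls, n_replicates_used = used)
  }
  dplyr::ungroup(dplyr::summarise(grp, per_rep(dplyr::pick(dplyr::everything())),
                                  .groups = "drop"))
}

#' Parse a gene-to-subcategory annotation map
#'
#' Tab-separated with columns `gene`, `subcategory` and optional integer
#' `rank` (display order within subcategory). Genes may appear at most once;
#' genes absent from the map fall into a trailing `"other"` block when a
#' heatmap is built.
#'
#' @param path File path.
#' @return Tibble `gene`, `subcategory`, `rank`.
#' @export
parse_annotation_map <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  stopifnot(all(c("gene", "subcategory") %in% names(tab)))
  if (anyDuplicated(tab$gene)) {
    stop("gene annotated more than once: ",
         tab$gene[duplicated(tab$gene)][1], call. = FALSE)
  }
  tab$rank <- if ("rank" %in% names(tab)) as.integer(tab$rank) else
    seq_len(nrow(tab))
  tibble::as_tibble(tab[, c("gene", "subcategory", "rank")])
}

#' Build an annotation-grouped binding-score matrix
#'
#' Arranges aggregate scores as a genes x samples matrix ready for heatmap
#' display: rows grouped by functional subcategory (in the order the
#' subcategories first appear in the annotation, unannotated genes in a
#' trailing `"other"` block) and ranked within subcategory; columns
#' position-major (all `UP` columns, then all `DN`), then by condition in
#' the order given, then by timepoint. Cells without a usable aggregate are
#' `NA`, distinct from zero.
#'
#' @param agg An `AggregateScore` table (e.g. after [filter_binders()]).
#' @param annotation Annotation tibble from [parse_annotation_map()].
#' @param conditions Condition order; default: order of appearance.
#' @param positions Position order (default `c("UP", "DN")`).
#' @param value Column of `agg` to place in cells (default `mean_score`).
#' @return A `binding_heatmap` list: `matrix`, `row_meta` (gene,
#'   subcategory, rank), `col_meta` (position, condition, timepoint).
#' @export
build_heatmap_matrix <- function(agg, annotation,
                                 conditions = NULL,
                                 positions = c("UP", "DN"),
                                 value = "mean_score") {
  conditions <- conditions %||% unique(agg$condition)
  genes <- unique(agg$gene)
  ann <- annotation[annotation$gene %in% genes, ]
  sub_order <- unique(ann$subcategory)
  extra <- setdiff(genes, ann$gene)
  if (length(extra)) {
    ann <- rbind(ann, tibble::tibble(gene = sort(extra),
                                     subcategory = "other",
                                     rank = seq_along(extra)))
    sub_order <- c(sub_order, "other")
  }
  ann$sub_idx <- match(ann$subcategory, sub_order)
  ann <- ann[order(ann$sub_idx, ann$rank, ann$gene), ]

  cols <- list()
  for (pos in positions) {
    for (cond in conditions) {
      tps <- sort(unique(agg$timepoint[agg$condition == cond &
                                         agg$position == pos]))
      for (tp in tps) {
        cols[[length(cols) + 1L]] <- tibble::tibble(
          position = pos, condition = cond, timepoint = tp)
      }
    }
  }
  col_meta <- dplyr::bind_rows(cols)
  col_meta$column <- sprintf("%s_%s_t%g", col_meta$position,
                             col_meta$condition, col_meta$timepoint)
  m <- matrix(NA_real_, nrow(ann), nrow(col_meta),
              dimnames = list(ann$gene, col_meta$column))
  a_key <- sprintf("%s\r%s_%s_t%g", agg$gene, agg$position, agg$condition,
                   agg$timepoint)
  cell <- expand.grid(gene = ann$gene, column = col_meta$column,
                      stringsAsFactors = FALSE)
  hit <- match(paste(cell$gene, cell$column, sep = "\r"), a_key)
  vals <- agg[[value]][hit]
  m[cbind(match(cell$gene, ann$gene), match(cell$column, col_meta$column))] <-
    vals
  structure(list(matrix = m,
                 row_meta = ann[, c("gene", "subcategory", "rank")],
                 col_meta = col_meta[, c("column", "position", "condition",
                                         "timepoint")]),
            class = "binding_heatmap")
}

#' Serialise / parse a binding heatmap losslessly
#'
#' The matrix is written as TSV (first column `gene`), with row and column
#' metadata in `<path>.rows.tsv` / `<path>.cols.tsv` sidecars. A
#' write -> read -> write cycle is byte-identical.
#'
#' @param hm A `binding_heatmap`.
#' @param path Matrix TSV path.
#' @return `read_heatmap_matrix()` returns the `binding_heatmap`.
#' @export
write_heatmap_matrix <- function(hm, path) {
  stopifnot(inherits(hm, "binding_heatmap"))
  tab <- data.frame(gene = rownames(hm$matrix), hm$matrix,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(hm$row_meta, paste0(path, ".rows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(hm$col_meta, paste0(path, ".cols.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_matrix
#' @export
read_heatmap_matrix <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  row_meta <- tibble::as_tibble(
    utils::read.delim(paste0(path, ".rows.tsv"), sep = "\t",
                      colClasses = c("character", "character", "integer")))
  col_meta <- tibble::as_tibble(
    utils::read.delim(paste0(path, ".cols.tsv"), sep = "\t",
                      colClasses = c("character", "character", "character",
                                     "numeric")))
  structure(list(matrix = m, row_meta = row_meta, col_meta = col_meta),
            class = "binding_heatmap")
}

#' Contrast aggregate binding between two conditions
#'
#' Per-gene, per-position log2 difference between two labelled states (e.g.
#' quiescent vs mid-log): `delta_log2 = log2(mean_a) - log2(mean_b)`, with
#' replicate support from both states. Genes usable in only one state are
#' flagged (`"a_only"` / `"b_only"`) with `NA` contrast — no ratio is
#' fabricated against a missing value. Exactly antisymmetric in its
#' arguments.
#'
#' @param agg An `AggregateScore` table containing both conditions.
#' @param state_a,state_b Condition labels to contrast (a vs b).
#' @param timepoint Optional timepoint selecting within each condition;
#'   default uses each condition's single timepoint (error if several).
#' @return Tibble: `clone_id`, `gene`, `position`, `delta_log2`,
#'   `n_replicates_a`, `n_replicates_b`, `flag`.
#' @export
compare_conditions <- function(agg, state_a, state_b, timepoint = NULL) {
  pick <- function(state) {
    x <- agg[agg$condition == state, ]
    if (!is.null(timepoint)) x <- x[x$timepoint == timepoint, ]
    if (length(unique(x$timepoint)) > 1L) {
      stop(sprintf("condition '%s' has several timepoints; pick one", state),
           call. = FALSE)
    }
    x
  }
  a <- pick(state_a)
  b <- pick(state_b)
  key <- function(d) paste(d$clone_id, d$position, sep = "\r")
  shared <- union(key(a), key(b))
  if (length(intersect(key(a), key(b))) == 0L) {
    stop("no shared genes between states", call. = FALSE)
  }
  ia <- match(shared, key(a))
  ib <- match(shared, key(b))
  usable <- function(d, i) {
    !is.na(i) & !is.na(d$mean_score[i]) & d$mean_score[i] > 0
  }
  ua <- usable(a, ia)
  ub <- usable(b, ib)
  src <- ifelse(is.na(ia), b$clone_id[ib], a$clone_id[ia])
  gene <- ifelse(is.na(ia), b$gene[ib], a$gene[ia])
  posn <- ifelse(is.na(ia), b$position[ib], a$position[ia])
  tibble::tibble(
    clone_id = src,
    gene = gene,
    position = posn,
    delta_log2 = ifelse(ua & ub,
                        log2(a$mean_score[ia]) - log2(b$mean_score[ib]),
                        NA_real_),
    n_replicates_a = ifelse(is.na(ia), 0L, a$n_replicates[ia]),
    n_replicates_b = ifelse(is.na(ib), 0L, b$n_replicates[ib]),
    flag = dplyr::case_when(ua & ub ~ "both",
                            ua & !ub ~ "a_only",
                            !ua & ub ~ "b_only",
                            TRUE ~ "neither")
  )
}

#' Render a binding heatmap
#'
#' Convenience wrapper around `pheatmap` (suggested dependency) preserving
#' the annotation-grouped row order and position-major column order.
#'
#' @param hm A `binding_heatmap`.
#' @param log2_transform Plot `log2(value)` (default TRUE).
#' @param ... Passed to `pheatmap::pheatmap`.
#' @export
plot_binding_heatmap <- function(hm, log2_transform = TRUE, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_binding_heatmap() needs the 'pheatmap' package",
         call. = FALSE)
  }
  m <- hm$matrix
  if (log2_transform) m <- log2(m)
  ann_row <- data.frame(subcategory = hm$row_meta$subcategory,
                        row.names = hm$row_meta$gene)
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     annotation_row = ann_row, ...)
}
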