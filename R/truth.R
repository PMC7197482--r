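#' Generate ground-truth binding kinetics for a simulated experiment
#'
#' Assigns every clone an expected IP/input enrichment at each
#' (condition, timepoint, barcode position) of the experimental design,
#' following one of three kinetic classes:
#' \describe{
#'   \item{evicted}{`enrichment(t) = floor + (e0 - floor) * exp(-rate * t)` —
#'     exponential loss toward a floor, the pattern of factors progressively
#'     lost from chromatin after transcription inhibition.}
#'   \item{recruited}{the mirrored saturating rise,
#'     `ceiling - (ceiling - e0) * exp(-rate * t)`.}
#'   \item{stable}{constant `e0` at every timepoint.}
#' }
#' Enrichments are expected relative IP/input scores: scores within a sample
#' pair are relative, so only ratios between clones matter downstream.
#'
#' @param library A `LibraryTable` (see [make_barcode_library()]).
#' @param design Data frame with columns `condition` and numeric `timepoint`
#'   (ordered within condition; 0 is the pre-treatment reference).
#' @param class_assignment Named character vector mapping every `clone_id`
#'   to a class in `c("evicted", "recruited", "stable")`.
#' @param kinetics List with elements `evicted = list(floor, rate)` and
#'   `recruited = list(ceiling, rate)`. `floor >= 0`; rates per unit of
#'   `timepoint`.
#' @param baseline Baseline enrichment `e0` at t = 0: a single value, a named
#'   vector per clone, or `NULL` to sample log2-uniformly from
#'   `baseline_range` (default 1/8x to 16x, the dynamic range the assay
#'   spans).
#' @param baseline_range Length-2 numeric, log2 limits for sampled baselines.
#' @param positions Barcode positions to emit (`"UP"`, `"DN"`).
#' @param seed Integer seed used when baselines are sampled.
#' @return A tibble (`TruthProfile`) with columns `clone_id`, `condition`,
#'   `timepoint`, `position`, `enrichment`, `dynamic_class`.
#' @export
#' @examples
#' lib <- make_barcode_library(2, n_replicates = 1, seed = 1)
#' design <- data.frame(condition = "PH", timepoint = c(0, 1, 2))
#' cls <- stats::setNames(c("evicted", "stable"), unique(lib$clone_id))
#' make_truth_profile(lib, design, cls, baseline = 4)
make_truth_profile <- function(library,
                               design,
                               class_assignment,
                               kinetics = list(
                                 evicted = list(floor = 0.25, rate = log(2) / 10),
                                 recruited = list(ceiling = 2.25, rate = log(2) / 10)
                               ),
                               baseline = NULL,
                               baseline_range = c(-3, 4),
                               positions = c("UP", "DN"),
                               seed = 1L) {
  stopifnot(all(c("condition", "timepoint") %in% names(design)))
  clones <- unique(library$clone_id)
  if (length(clones) == 0L) {
    return(tibble::tibble(clone_id = character(0), condition = character(0),
                          timepoint = numeric(0), position = character(0),
                          enrichment = numeric(0), dynamic_class = character(0)))
  }
  missing_cls <- setdiff(clones, names(class_assignment))
  if (length(missing_cls)) {
    stop("class_assignment missing clones: ",
         paste(utils::head(missing_cls, 5), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(class_assignment),
                 c("evicted", "recruited", "stable"))
  if (length(bad)) stop("unknown dynamic class: ", bad[1], call. = FALSE)

  if (is.null(baseline)) {
    set.seed(seed)
    e0 <- stats::setNames(
      2^stats::runif(length(clones), baseline_range[1], baseline_range[2]),
      clones)
  } else if (length(baseline) == 1L && is.null(names(baseline))) {
    e0 <- stats::setNames(rep(baseline, length(clones)), clones)
  } else {
    missing_e0 <- setdiff(clones, names(baseline))
    if (length(missing_e0)) {
      stop("baseline missing clones: ",
           paste(utils::head(missing_e0, 5), collapse = ", "), call. = FALSE)
    }
    e0 <- baseline[clones]
  }
  if (any(e0 <= 0)) stop("baseline enrichment e0 must be > 0", call. = FALSE)
  flr <- kinetics$evicted$floor %||% 0.25
  if (flr < 0) stop("eviction floor must be >= 0", call. = FALSE)

  grid <- tidyr::expand_grid(
    clone_id = clones,
    design[, c("condition", "timepoint")],
    position = positions
  )
  cls <- class_assignment[grid$clone_id]
  b <- e0[grid$clone_id]
  t <- grid$timepoint
  enr <- b
  ev <- cls == "evicted"
  rc <- cls == "recruited"
  # per-clone effective asymptotes: eviction never rises toward a floor
  # above the baseline, recruitment never falls toward a lower ceiling
  fl_ev <- pmin(flr, b[ev])
  enr[ev] <- fl_ev + (b[ev] - fl_ev) * exp(-kinetics$evicted$rate * t[ev])
  ceil <- kinetics$recruited$ceiling %||% 2.25
  ce_rc <- pmax(ceil, b[rc])
  enr[rc] <- ce_rc - (ce_rc - b[rc]) * exp(-kinetics$recruited$rate * t[rc])
  if (any(enr <= 0)) {
    stop("kinetics produced nonpositive enrichment", call. = FALSE)
  }
  tibble::tibble(
    clone_id = grid$clone_id,
    condition = grid$condition,
    timepoint = grid$timepoint,
    position = grid$position,
    enrichment = unname(enr),
    dynamic_class = unname(cls)
  )
}
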