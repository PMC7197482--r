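#' Generate a clone-to-barcode reference library
#'
#' Builds the clone/barcode map of a pooled barcode-ChIP library: each tagged
#' clone is linked to `n_replicates` independent barcode pairs (replicate
#' libraries I, II, III), one barcode upstream of the reporter (`bc_up`,
#' promoter-proximal) and one downstream (`bc_dn`, terminator-proximal).
#' Barcodes are drawn by rejection sampling so that every pair of distinct
#' barcodes in the table (across both position classes) differs by at least
#' `min_distance` substitutions. With `min_distance >= 3`, one-mismatch
#' barcode correction is provably unambiguous: a read one substitution away
#' from barcode A is at least two away from every other barcode.
#'
#' @param n_clones Number of tagged clones (>= 0).
#' @param n_replicates Barcode replicates per clone (1-3; labelled I, II, III).
#' @param bc_length Barcode length, 16-20 nt.
#' @param min_distance Minimum pairwise Hamming distance (>= 3).
#' @param seed Integer seed; the table is deterministic given the seed.
#' @param genes Optional character vector of gene symbols, length `n_clones`.
#' @return A tibble (`LibraryTable`) with columns `clone_id`, `gene`,
#'   `replicate`, `bc_up`, `bc_dn`; one row per (clone, replicate).
#' @export
#' @examples
#' lib <- make_barcode_library(4, n_replicates = 3, seed = 1)
#' lib
make_barcode_library <- function(n_clones,
                                 n_replicates = 3L,
                                 bc_length = 16L,
                                 min_distance = 3L,
                                 seed = 1L,
                                 genes = NULL) {
  stopifnot(n_clones >= 0, n_replicates >= 1, n_replicates <= 3)
  if (bc_length < 16L || bc_length > 20L) {
    stop("bc_length must be in [16, 20]", call. = FALSE)
  }
  if (min_distance < 3L) {
    stop("min_distance must be >= 3 for unambiguous 1-mismatch correction",
         call. = FALSE)
  }
  rep_labels <- c("I", "II", "III")[seq_len(n_replicates)]
  if (n_clones == 0L) {
    return(tibble::tibble(clone_id = character(0), gene = character(0),
                          replicate = character(0), bc_up = character(0),
                          bc_dn = character(0)))
  }
  if (is.null(genes)) {
    genes <- sprintf("GENE%04d", seq_len(n_clones))
  }
  stopifnot(length(genes) == n_clones)

  set.seed(seed)
  n_bc <- 2L * n_clones * n_replicates
  bcs <- generate_separated_barcodes(n_bc, bc_length, min_distance)
  bc_up <- bcs[seq_len(n_clones * n_replicates)]
  bc_dn <- bcs[n_clones * n_replicates + seq_len(n_clones * n_replicates)]

  tab <- tibble::tibble(
    clone_id = rep(sprintf("clone%04d", seq_len(n_clones)),
                   each = n_replicates),
    gene = rep(genes, each = n_replicates),
    replicate = rep(rep_labels, times = n_clones),
    bc_up = bc_up,
    bc_dn = bc_dn
  )
  validate_library_table(tab)
}

# Rejection-sample n barcodes of the given length with all pairwise Hamming
# distances >= min_distance. Errors (capacity) rather than silently
# truncating when the constraint cannot be met in a bounded number of draws.
generate_separated_barcodes <- function(n, bc_length, min_distance,
                                        max_attempts = NULL) {
  max_attempts <- max_attempts %||% max(1000L, 200L * n)
  accepted <- matrix(integer(0), nrow = 0, ncol = bc_length)
  out <- character(n)
  k <- 0L
  attempts <- 0L
  while (k < n) {
    batch <- random_dna(min(256L, max_attempts - attempts + 1L), bc_length)
    for (cand in batch) {
      attempts <- attempts + 1L
      ci <- utf8ToInt(cand)
      ok <- k == 0L ||
        min(rowSums(accepted[seq_len(k), , drop = FALSE] !=
                      matrix(ci, k, bc_length, byrow = TRUE))) >= min_distance
      if (ok) {
        k <- k + 1L
        out[k] <- cand
        accepted <- rbind(accepted, ci)
        if (k == n) break
      }
    }
    if (attempts >= max_attempts && k < n) {
      stop(sprintf(paste0("barcode capacity exceeded: placed %d of %d ",
                          "barcodes of length %d at min distance %d"),
                   k, n, bc_length, min_distance), call. = FALSE)
    }
  }
  out
}

#' Validate a clone-to-barcode reference table
#'
#' Checks the structural invariants of a `LibraryTable`: required columns;
#' ACGT-only barcodes of length 16-20; barcode uniqueness within each
#' position class (all `bc_up` distinct, all `bc_dn` distinct); exactly one
#' row per (clone, replicate); and distinct barcode pairs across replicates
#' of the same clone.
#'
#' @param tab A data frame with columns `clone_id`, `gene`, `replicate`,
#'   `bc_up`, `bc_dn`.
#' @return The validated table as a tibble, barcodes uppercased.
#' @export
validate_library_table <- function(tab) {
  required <- c("clone_id", "gene", "replicate", "bc_up", "bc_dn")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("reference table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- tibble::as_tibble(tab)
  tab$bc_up <- toupper(tab$bc_up)
  tab$bc_dn <- toupper(tab$bc_dn)
  if (nrow(tab) == 0L) return(tab)
  assert_dna(tab$bc_up, "bc_up")
  assert_dna(tab$bc_dn, "bc_dn")
  lens <- c(nchar(tab$bc_up), nchar(tab$bc_dn))
  if (any(lens < 16L | lens > 20L)) {
    stop("barcode lengths must be in [16, 20]", call. = FALSE)
  }
  for (col in c("bc_up", "bc_dn")) {
    dup <- tab[[col]][duplicated(tab[[col]])]
    if (length(dup)) {
      rows <- which(tab[[col]] == dup[1])
      stop(sprintf("duplicate %s barcode '%s' in rows %s", col, dup[1],
                   paste(rows, collapse = ", ")), call. = FALSE)
    }
  }
  key <- paste(tab$clone_id, tab$replicate)
  if (anyDuplicated(key)) {
    stop("each clone must have exactly one row per replicate; duplicated: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  tab
}

#' Read / write a reference table (clone-barcode map) as TSV
#'
#' Tab-separated with a header; columns `clone_id`, `gene`, `replicate`,
#' `bc_up`, `bc_dn`. Barcodes are accepted case-insensitively and normalised
#' to uppercase on read; all invariants of [validate_library_table()] are
#' enforced, naming the offending rows on failure.
#'
#' @param path File path.
#' @return `parse_reference_table()` returns a validated `LibraryTable`.
#' @export
parse_reference_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  validate_library_table(tab)
}

#' @rdname parse_reference_table
#' @param tab A `LibraryTable`.
#' @export
write_reference_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Barcodes of one position class, named by library row.
library_barcodes <- function(library, position) {
  position <- match.arg(position, c("UP", "DN"))
  if (position == "UP") library$bc_up else library$bc_dn
}
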