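#' Build a sample sheet for a pooled, indexed sequencing run
#'
#' One row per sequencing sample. Every (condition, timepoint, position)
#' yields an IP sample and its matched input sample, linked by `pair_id`;
#' the pair shares the chromatin preparation, so IP/input ratios cancel
#' clone abundance and amplification effects. Index sequences are generated
#' with pairwise Hamming distance >= 3 so demultiplexing is unambiguous
#' even with one allowed index mismatch.
#'
#' @param design Data frame with columns `condition` and numeric `timepoint`.
#' @param positions Barcode position classes sequenced (`"UP"`, `"DN"`);
#'   each position is amplified and sequenced as its own library.
#' @param index_length Sample index length, nt.
#' @param pool Pool label.
#' @param bio_replicate Biological replicate label (integer).
#' @param seed Integer seed for index generation.
#' @return A tibble (`SampleSheet`) with columns `sample_id`, `index_seq`,
#'   `fraction` (IP/input), `position`, `condition`, `timepoint`, `pool`,
#'   `bio_replicate`, `pair_id`.
#' @export
#' @examples
#' make_sample_sheet(data.frame(condition = "PH", timepoint = c(0, 20)))
make_sample_sheet <- function(design,
                              positions = c("UP", "DN"),
                              index_length = 6L,
                              pool = "pool1",
                              bio_replicate = 1L,
                              seed = 1L) {
  stopifnot(all(c("condition", "timepoint") %in% names(design)))
  grid <- tidyr::expand_grid(design[, c("condition", "timepoint")],
                             position = positions,
                             fraction = c("IP", "input"))
  n <- nrow(grid)
  set.seed(seed)
  idx <- generate_separated_barcodes(n, index_length, min_distance = 3L)
  pair <- sprintf("%s_%s_t%g_%s", pool, grid$condition, grid$timepoint,
                  grid$position)
  tibble::tibble(
    sample_id = paste0(pair, "_", grid$fraction),
    index_seq = idx,
    fraction = grid$fraction,
    position = grid$position,
    condition = grid$condition,
    timepoint = grid$timepoint,
    pool = pool,
    bio_replicate = as.integer(bio_replicate),
    pair_id = pair
  )
}

#' Validate a sample sheet
#'
#' Checks index uniqueness (and, when `max_index_mismatch > 0`, that no two
#' indexes are within `2 * max_index_mismatch` of each other, which would
#' make demultiplexing ambiguous by construction), and that every IP
#' sample's `pair_id` resolves to exactly one input sample with matching
#' position, condition and timepoint.
#'
#' @param sheet A `SampleSheet` tibble.
#' @param max_index_mismatch Mismatches demultiplexing will tolerate.
#' @return The sheet, invisibly; errors describe the offending samples.
#' @export
validate_sample_sheet <- function(sheet, max_index_mismatch = 0L) {
  required <- c("sample_id", "index_seq", "fraction", "position",
                "condition", "timepoint", "pair_id")
  missing <- setdiff(required, names(sheet))
  if (length(missing)) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(nchar(sheet$index_seq))) > 1L) {
    stop("all index sequences must have the same length", call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1], call. = FALSE)
  }
  if (anyDuplicated(sheet$index_seq)) {
    stop("duplicate index_seq: ",
         sheet$index_seq[duplicated(sheet$index_seq)][1], call. = FALSE)
  }
  if (max_index_mismatch > 0L && nrow(sheet) > 1L) {
    pairs <- utils::combn(nrow(sheet), 2)
    d <- hamming_distance(sheet$index_seq[pairs[1, ]],
                          sheet$index_seq[pairs[2, ]])
    bad <- which(d <= 2L * max_index_mismatch)
    if (length(bad)) {
      i <- pairs[, bad[1]]
      stop(sprintf(paste0("indexes of samples '%s' and '%s' are within ",
                          "2*max_index_mismatch; demultiplexing would be ",
                          "ambiguous"),
                   sheet$sample_id[i[1]], sheet$sample_id[i[2]]),
           call. = FALSE)
    }
  }
  ip <- sheet[sheet$fraction == "IP", ]
  inp <- sheet[sheet$fraction == "input", ]
  for (i in seq_len(nrow(ip))) {
    m <- inp[inp$pair_id == ip$pair_id[i] &
               inp$position == ip$position[i] &
               inp$condition == ip$condition[i] &
               inp$timepoint == ip$timepoint[i], ]
    if (nrow(m) != 1L) {
      stop(sprintf("IP sample '%s' resolves to %d input samples (need 1)",
                   ip$sample_id[i], nrow(m)), call. = FALSE)
    }
  }
  invisible(sheet)
}

#' Read / write a sample sheet as TSV
#' @param path File path.
#' @return `read_sample_sheet()` returns a tibble.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  tab$timepoint <- as.numeric(tab$timepoint)
  if ("bio_replicate" %in% names(tab)) {
    tab$bio_replicate <- as.integer(tab$bio_replicate)
  }
  tibble::as_tibble(tab)
}

#' @rdname read_sample_sheet
#' @param sheet A `SampleSheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
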