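#' Demultiplex pooled reads by their leading sample index
#'
#' Assigns each read to the unique sample whose index sequence matches the
#' read's leading bases within `max_index_mismatch` substitutions. Reads
#' matching no sample, or more than one at the tolerated distance, are
#' discarded and tallied. Sample-sheet indexes closer than
#' `2 * max_index_mismatch + 1` would make ambiguity possible by
#' construction and are rejected up front.
#'
#' @param reads Character vector of read sequences.
#' @param sample_sheet A `SampleSheet` (all `index_seq` the same length).
#' @param max_index_mismatch Allowed substitutions in the index (default 0,
#'   conservative demultiplexing).
#' @return List with `samples` (named list of per-sample read vectors, in
#'   input order) and `discarded` (integer tally).
#' @export
demultiplex <- function(reads, sample_sheet, max_index_mismatch = 0L) {
  validate_sample_sheet(sample_sheet, max_index_mismatch)
  ilen <- nchar(sample_sheet$index_seq[1])
  idx <- substr(reads, 1L, ilen)
  assign <- match(idx, sample_sheet$index_seq)
  if (max_index_mismatch > 0L) {
    todo <- which(is.na(assign) & nchar(idx) == ilen)
    if (length(todo)) {
      hits <- matrix(0L, length(todo), nrow(sample_sheet))
      for (s in seq_len(nrow(sample_sheet))) {
        mm <- integer(length(todo))
        target <- strsplit(sample_sheet$index_seq[s], "")[[1]]
        for (j in seq_len(ilen)) {
          mm <- mm + (substr(idx[todo], j, j) != target[j])
        }
        hits[, s] <- mm <= max_index_mismatch
      }
      nhit <- rowSums(hits)
      ok <- nhit == 1L
      assign[todo[ok]] <- max.col(hits[ok, , drop = FALSE],
                                  ties.method = "first")
    }
  }
  samples <- lapply(seq_len(nrow(sample_sheet)),
                    function(s) reads[which(assign == s)])
  names(samples) <- sample_sheet$sample_id
  list(samples = samples, discarded = sum(is.na(assign)))
}

#' Extract the barcode window from reads via the 5' flank anchor
#'
#' Locates `flank5` at its expected offset (immediately after the index),
#' allowing up to `flank_mismatch_tolerance` substitutions, and returns the
#' following `bc_length` bases. Reads whose anchor fails, or that are too
#' short, yield `NA` — an unusable read, not an error. All coordinates are
#' 0-based half-open internally; the barcode window is
#' `[barcode_offset, barcode_offset + bc_length)`.
#'
#' @param reads Character vector of read sequences (vectorised).
#' @param layout A [read_layout()].
#' @param flank_mismatch_tolerance Allowed substitutions in the anchor
#'   (default 1).
#' @return Character vector of barcodes, `NA` where extraction failed.
#' @export
extract_barcode <- function(reads, layout, flank_mismatch_tolerance = 1L) {
  stopifnot(inherits(layout, "read_layout"))
  n <- length(reads)
  if (n == 0L) return(character(0))
  f5 <- strsplit(layout$flank5, "")[[1]]
  off <- layout$index_length
  min_len <- layout$barcode_offset + layout$bc_length
  mm <- integer(n)
  for (j in seq_along(f5)) {
    mm <- mm + (substr(reads, off + j, off + j) != f5[j])
  }
  ok <- mm <= flank_mismatch_tolerance & nchar(reads) >= min_len
  out <- rep(NA_character_, n)
  out[ok] <- substr(reads[ok], layout$barcode_offset + 1L, min_len)
  out
}

#' Build a 1-mismatch barcode matching index for one position class
#'
#' Precomputes, for each masked position of the fixed barcode length, the
#' library barcodes with that position blanked. A probe then matches a
#' barcode at Hamming distance <= 1 iff some masked version of the probe
#' equals the corresponding masked barcode; this makes error-tolerant
#' matching a handful of exact `match()` calls and is robust to any probe
#' character (an `N` is simply a mismatch).
#'
#' @param library A `LibraryTable`.
#' @param position `"UP"` or `"DN"`.
#' @return An object of class `barcode_index`.
#' @export
barcode_index <- function(library, position) {
  bcs <- library_barcodes(library, position)
  L <- if (length(bcs)) nchar(bcs[1]) else 0L
  if (length(bcs) && any(nchar(bcs) != L)) {
    stop("barcode lengths must be fixed within a library", call. = FALSE)
  }
  masked <- lapply(seq_len(L), function(j) mask_position(bcs, j))
  structure(list(barcodes = bcs, length = L, masked = masked,
                 library = library, position = position),
            class = "barcode_index")
}

mask_position <- function(x, j) {
  paste0(substr(x, 1L, j - 1L), substring(x, j + 1L))
}

#' Match barcode sequences against a library with error tolerance
#'
#' An exact match wins immediately. Otherwise all library barcodes within
#' Hamming distance `max_mismatch` are collected: exactly one at the minimal
#' distance is assigned; several distinct candidates make the read
#' `ambiguous`; none leaves it `unmatched`. Probes whose length differs from
#' the library barcode length are `unmatched` (barcode length is fixed per
#' library). With a library built at minimum pairwise distance >= 3 and
#' `max_mismatch = 1`, ambiguity is impossible.
#'
#' @param seqs Character vector of extracted barcodes (`NA` allowed;
#'   reported as `unmatched`).
#' @param index A [barcode_index()] (or a `LibraryTable` plus `position`).
#' @param position Position class, used when `index` is a `LibraryTable`.
#' @param max_mismatch 0 (exact only) or 1 (default).
#' @return A tibble with columns `seq`, `status` in
#'   `c("assigned", "ambiguous", "unmatched")`, `row` (library row index or
#'   `NA`), `clone_id`, `replicate`.
#' @export
match_barcode <- function(seqs, index, position = NULL, max_mismatch = 1L) {
  if (!inherits(index, "barcode_index")) {
    index <- barcode_index(index, position)
  }
  if (!max_mismatch %in% c(0L, 1L)) {
    stop("max_mismatch must be 0 or 1", call. = FALSE)
  }
  n <- length(seqs)
  row <- match(seqs, index$barcodes)
  status <- ifelse(is.na(row), "unmatched", "assigned")
  if (max_mismatch >= 1L && index$length > 0L) {
    todo <- which(is.na(row) & !is.na(seqs) & nchar(seqs) == index$length)
    if (length(todo)) {
      cand <- matrix(NA_integer_, length(todo), index$length)
      for (j in seq_len(index$length)) {
        cand[, j] <- match(mask_position(seqs[todo], j), index$masked[[j]])
      }
      res <- apply(cand, 1L, function(x) {
        u <- unique(x[!is.na(x)])
        if (length(u) == 1L) u else if (length(u) > 1L) -1L else NA_integer_
      })
      amb <- !is.na(res) & res == -1L
      hit <- !is.na(res) & res > 0L
      status[todo[amb]] <- "ambiguous"
      status[todo[hit]] <- "assigned"
      row[todo[hit]] <- res[hit]
    }
  }
  lib <- index$library
  tibble::tibble(
    seq = seqs,
    status = status,
    row = row,
    clone_id = ifelse(is.na(row), NA_character_, lib$clone_id[row]),
    replicate = ifelse(is.na(row), NA_character_, lib$replicate[row])
  )
}

#' Count barcodes in demultiplexed reads
#'
#' Composes [extract_barcode()] and [match_barcode()] over per-sample read
#' streams and fills a zero-initialised count table: one row per
#' (sample, clone, replicate, position), plus a per-sample summary in which
#' `assigned + unmatched + ambiguous = total_reads` holds exactly (failed
#' extractions count as unmatched).
#'
#' @param sample_reads Named list of per-sample read vectors (as produced by
#'   [demultiplex()]).
#' @param library A `LibraryTable`.
#' @param layout A [read_layout()].
#' @param sample_sheet A `SampleSheet` covering the samples (for their
#'   position class).
#' @param max_mismatch Barcode mismatch tolerance (0 or 1; default 1).
#' @param flank_mismatch_tolerance Anchor tolerance (default 1).
#' @return List with `counts` (tibble: `sample_id`, `clone_id`, `replicate`,
#'   `position`, `count`) and `summary` (tibble: `sample_id`, `total_reads`,
#'   `assigned`, `unmatched`, `ambiguous`).
#' @export
count_barcodes <- function(sample_reads, library, layout, sample_sheet,
                           max_mismatch = 1L,
                           flank_mismatch_tolerance = 1L) {
  idx_by_pos <- lapply(stats::setNames(nm = unique(sample_sheet$position)),
                       function(p) barcode_index(library, p))
  counts <- list()
  summ <- list()
  for (sid in names(sample_reads)) {
    pos <- sample_sheet$position[match(sid, sample_sheet$sample_id)]
    if (is.na(pos)) stop("sample '", sid, "' absent from sample sheet",
                         call. = FALSE)
    reads <- sample_reads[[sid]]
    bcs <- extract_barcode(reads, layout, flank_mismatch_tolerance)
    m <- match_barcode(bcs, idx_by_pos[[pos]], max_mismatch = max_mismatch)
    tab <- tabulate(m$row[m$status == "assigned"], nbins = nrow(library))
    counts[[sid]] <- tibble::tibble(
      sample_id = sid,
      clone_id = library$clone_id,
      replicate = library$replicate,
      position = pos,
      count = as.integer(tab)
    )
    summ[[sid]] <- tibble::tibble(
      sample_id = sid,
      total_reads = length(reads),
      assigned = sum(m$status == "assigned"),
      unmatched = sum(m$status == "unmatched"),
      ambiguous = sum(m$status == "ambiguous")
    )
  }
  list(counts = dplyr::bind_rows(counts), summary = dplyr::bind_rows(summ))
}

#' Run the full counting pipeline on pooled FASTQ files
#'
#' Reads one pooled FASTQ per position class, demultiplexes by sample index,
#' extracts and matches barcodes, and returns the combined count table with
#' per-sample summaries and per-position demultiplexing discard tallies.
#'
#' @param fastq Named character vector of FASTQ paths, names are position
#'   classes (`"UP"`, `"DN"`).
#' @param library A `LibraryTable`.
#' @param sample_sheet A `SampleSheet`.
#' @param layout A [read_layout()].
#' @param max_index_mismatch Index mismatches tolerated in demultiplexing.
#' @param max_mismatch Barcode mismatch tolerance (0 or 1).
#' @param flank_mismatch_tolerance Anchor tolerance.
#' @return List with `counts`, `summary` (as [count_barcodes()]) and
#'   `demux_discarded` (named integer per position).
#' @export
count_pipeline <- function(fastq, library, sample_sheet, layout,
                           max_index_mismatch = 0L, max_mismatch = 1L,
                           flank_mismatch_tolerance = 1L) {
  counts <- list()
  summ <- list()
  discarded <- stats::setNames(integer(length(fastq)), names(fastq))
  for (pos in names(fastq)) {
    sub <- sample_sheet[sample_sheet$position == pos, ]
    reads <- read_fastq(fastq[[pos]])
    dm <- demultiplex(reads, sub, max_index_mismatch)
    res <- count_barcodes(dm$samples, library, layout, sub,
                          max_mismatch, flank_mismatch_tolerance)
    counts[[pos]] <- res$counts
    summ[[pos]] <- res$summary
    discarded[pos] <- dm$discarded
  }
  list(counts = dplyr::bind_rows(counts),
       summary = dplyr::bind_rows(summ),
       demux_discarded = discarded)
}

#' Read / write a count table as TSV
#'
#' Plain tab-separated with header; a write -> read -> write cycle is
#' byte-identical.
#'
#' @param counts Count tibble (`sample_id`, `clone_id`, `replicate`,
#'   `position`, `count`).
#' @param path File path.
#' @return `read_count_table()` returns the tibble with integer counts.
#' @export
write_count_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  tab$count <- as.integer(tab$count)
  tibble::as_tibble(tab)
}
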