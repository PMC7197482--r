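#' Simulate pooled barcode-ChIP sequencing reads
#'
#' Emulates the sequencing readout of a pooled barcode-ChIP experiment.
#' For every sample in the sheet, per-barcode read counts are drawn from a
#' multinomial: input samples with equal expected proportions across all
#' barcodes of the position class (the pool is an approximately equimolar
#' clone mixture), IP samples with proportions weighted by each clone's
#' ground-truth enrichment. Every read is assembled as
#' `index + flank5 + barcode + flank3 + random padding` to `read_length`,
#' then subjected to i.i.d. per-base substitution errors. Reads of all
#' samples sharing a position class are pooled into one FASTQ file per
#' position, mirroring separate amplification and sequencing of the upstream
#' and downstream barcodes. The exact pre-error per-(sample, barcode) counts
#' are returned as ground truth; output is byte-identical given the seed.
#'
#' @param library A `LibraryTable`; barcode lengths must equal
#'   `layout$bc_length`.
#' @param truth A `TruthProfile` covering every (clone, condition,
#'   timepoint, position) required by the sample sheet.
#' @param layout A [read_layout()].
#' @param sample_sheet A `SampleSheet`; each IP paired with an input sample.
#' @param depth Expected reads per barcode in an input sample; every sample
#'   draws `round(depth * B)` reads, with `B` barcodes in its position class.
#' @param error_rate Per-base substitution probability in `[0, 0.25)`.
#' @param seed Integer seed.
#' @param dir Output directory for FASTQ files.
#' @param gzip Compress FASTQ output.
#' @param abundance_skew_sd Optional log-normal sd of per-clone abundance
#'   skew in the pool (0 = equimolar, the default).
#' @param pcr_gamma_shape Optional shape of a gamma-distributed per-barcode
#'   amplification efficiency emulating PCR jackpotting (`NULL` = off).
#' @return List with `fastq` (named character vector of file paths, one per
#'   position class), `truth_counts` (tibble: `sample_id`, `clone_id`,
#'   `replicate`, `position`, `count`), and `n_reads` per sample.
#' @export
simulate_reads <- function(library, truth, layout, sample_sheet,
                           depth = 100, error_rate = 0, seed = 1L,
                           dir = tempdir(), gzip = FALSE,
                           abundance_skew_sd = 0,
                           pcr_gamma_shape = NULL) {
  stopifnot(inherits(layout, "read_layout"))
  if (error_rate < 0 || error_rate >= 0.25) {
    stop("error_rate must be in [0, 0.25)", call. = FALSE)
  }
  validate_sample_sheet(sample_sheet)
  if (nrow(library) > 0 &&
      any(nchar(c(library$bc_up, library$bc_dn)) != layout$bc_length)) {
    stop("library barcode lengths differ from layout bc_length",
         call. = FALSE)
  }
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  clones <- unique(library$clone_id)
  skew <- if (abundance_skew_sd > 0) {
    stats::setNames(stats::rlnorm(length(clones), 0, abundance_skew_sd),
                    clones)
  } else {
    stats::setNames(rep(1, length(clones)), clones)
  }

  fastq <- character(0)
  truth_counts <- list()
  n_reads <- stats::setNames(integer(nrow(sample_sheet)),
                             sample_sheet$sample_id)
  for (pos in unique(sample_sheet$position)) {
    sub <- sample_sheet[sample_sheet$position == pos, ]
    bcs <- library_barcodes(library, pos)
    reads_pool <- vector("list", nrow(sub))
    for (i in seq_len(nrow(sub))) {
      smp <- sub[i, ]
      counts <- draw_sample_counts(library, truth, smp, bcs, depth, skew,
                                   pcr_gamma_shape)
      n_reads[smp$sample_id] <- sum(counts)
      truth_counts[[smp$sample_id]] <- tibble::tibble(
        sample_id = smp$sample_id,
        clone_id = library$clone_id,
        replicate = library$replicate,
        position = pos,
        count = counts
      )
      reads_pool[[i]] <- build_reads(smp$index_seq, bcs, counts, layout)
    }
    reads <- unlist(reads_pool, use.names = FALSE) %||% character(0)
    reads <- mutate_reads(reads, error_rate)
    file <- file.path(dir, paste0("reads_", pos,
                                  if (gzip) ".fastq.gz" else ".fastq"))
    write_fastq(reads, file, compress = gzip)
    fastq[pos] <- file
  }
  truth_tab <- if (length(truth_counts)) {
    dplyr::bind_rows(truth_counts)
  } else {
    tibble::tibble(sample_id = character(0), clone_id = character(0),
                   replicate = character(0), position = character(0),
                   count = integer(0))
  }
  list(fastq = fastq, truth_counts = truth_tab, n_reads = n_reads)
}

# Multinomial per-barcode counts for one sample.
draw_sample_counts <- function(library, truth, smp, bcs, depth, skew,
                               pcr_gamma_shape) {
  B <- length(bcs)
  if (B == 0L) return(integer(0))
  w <- skew[library$clone_id]
  if (smp$fraction == "IP") {
    sel <- truth[truth$condition == smp$condition &
                   truth$timepoint == smp$timepoint &
                   truth$position == smp$position, ]
    enr <- sel$enrichment[match(library$clone_id, sel$clone_id)]
    if (anyNA(enr)) {
      miss <- unique(library$clone_id[is.na(enr)])
      stop(sprintf("truth profile missing (%s, t=%g, %s) for clone(s): %s",
                   smp$condition, smp$timepoint, smp$position,
                   paste(utils::head(miss, 5), collapse = ", ")),
           call. = FALSE)
    }
    w <- w * enr
  }
  if (!is.null(pcr_gamma_shape)) {
    w <- w * stats::rgamma(B, shape = pcr_gamma_shape,
                           rate = pcr_gamma_shape)
  }
  total <- as.integer(round(depth * B))
  as.integer(stats::rmultinom(1, total, w / sum(w)))
}

# Assemble reads: index + flank5 + barcode + flank3, truncated/padded to
# read_length; padding is random sequence, drawn per read.
build_reads <- function(index_seq, bcs, counts, layout) {
  if (sum(counts) == 0L) return(character(0))
  prefix <- substr(paste0(index_seq, layout$flank5, bcs, layout$flank3),
                   1L, layout$read_length)
  reads <- rep(prefix, counts)
  pad_len <- layout$read_length - nchar(prefix[1])
  if (pad_len > 0L) {
    pads <- random_dna(length(reads), pad_len)
    reads <- paste0(reads, pads)
  }
  reads
}

# i.i.d. per-base substitutions; each error replaces the base with one of
# the three other bases, uniformly.
mutate_reads <- function(reads, error_rate) {
  n <- length(reads)
  if (error_rate <= 0 || n == 0L) return(reads)
  L <- nchar(reads[1])
  for (j in seq_len(L)) {
    hit <- which(stats::runif(n) < error_rate)
    if (length(hit)) {
      cur <- substring(reads[hit], j, j)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      substring(reads[hit], j, j) <-
        DNA_ALPHABET[(match(cur, DNA_ALPHABET) + shift - 1L) %% 4L + 1L]
    }
  }
  reads
}

#' Write / read FASTQ (4-line records, constant 'I' qualities)
#'
#' Thin wrappers over Biostrings. Base qualities are not used anywhere in
#' the pipeline, so simulated reads carry a constant quality string.
#'
#' @param reads Character vector of read sequences.
#' @param path FASTQ path (`.gz` honoured by `read_fastq()`).
#' @param compress Write gzip-compressed output.
#' @return `read_fastq()` returns a character vector of read sequences.
#' @export
write_fastq <- function(reads, path, compress = FALSE) {
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- sprintf("r%07d", seq_along(reads))
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(dss)))
  Biostrings::writeXStringSet(dss, path, format = "fastq",
                              qualities = quals, compress = compress)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(unname(dss))
}
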