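#' Define the read architecture of a barcode amplicon library
#'
#' Pooled barcode amplicons are sequenced single-end (> 50 bp) with custom
#' primers, so every read has the same fixed architecture:
#' `index + flank5 + barcode + flank3 + padding`. The sample index occupies
#' the leading bases; `flank5` is the constant sequence between the index and
#' the barcode (the primer-proximal anchor used to locate the barcode);
#' `flank3` is constant sequence after the barcode. The exact primer and
#' index sequences differ between amplicon designs, so the layout is
#' configuration rather than a package constant.
#'
#' @param index_length Length of the leading sample index, in nt.
#' @param flank5 Constant DNA sequence between index and barcode.
#' @param flank3 Constant DNA sequence following the barcode (may be
#'   truncated by the read end).
#' @param bc_length Barcode length in nt (16-20 for this assay family).
#' @param read_length Total read length; must exceed 50 and accommodate
#'   index, flank5 and the full barcode.
#' @return A `read_layout` list with the fields above plus `barcode_offset`,
#'   the 0-based position of the barcode start within the read.
#' @export
#' @examples
#' read_layout(index_length = 6, flank5 = "TCCGTTCGTC", flank3 = "GAGCTCAG")
read_layout <- function(index_length = 6L,
                        flank5 = "TCCGTTCGTC",
                        flank3 = "GAGCTCAG",
                        bc_length = 16L,
                        read_length = 51L) {
  index_length <- as.integer(index_length)
  bc_length <- as.integer(bc_length)
  read_length <- as.integer(read_length)
  assert_dna(flank5, "flank5")
  assert_dna(flank3, "flank3")
  if (bc_length < 16L || bc_length > 20L) {
    stop("bc_length must be in [16, 20]", call. = FALSE)
  }
  if (read_length <= 50L) {
    stop("read_length must be > 50 (single-end amplicon sequencing)",
         call. = FALSE)
  }
  if (read_length < index_length + nchar(flank5) + bc_length) {
    stop("read_length too short for index + flank5 + barcode", call. = FALSE)
  }
  structure(
    list(index_length = index_length,
         flank5 = flank5,
         flank3 = flank3,
         bc_length = bc_length,
         read_length = read_length,
         barcode_offset = index_length + nchar(flank5)),
    class = "read_layout"
  )
}

#' @export
print.read_layout <- function(x, ...) {
  cat("read_layout:", x$read_length, "nt reads;",
      "index", x$index_length, "nt; flank5", x$flank5, ";",
      "barcode", x$bc_length, "nt at offset", x$barcode_offset,
      "; flank3", x$flank3, "\n")
  invisible(x)
}

#' Write or read a run configuration (read layout plus kinetics parameters)
#'
#' The configuration file is YAML with two top-level keys: `layout` (the
#' fields of [read_layout()]) and `kinetics` (free-form parameter list, e.g.
#' per-class floor/rate/ceiling used by [make_truth_profile()]).
#'
#' @param layout A `read_layout`.
#' @param kinetics Named list of kinetics parameters (may be `NULL`).
#' @param path File path.
#' @return `read_run_config()` returns `list(layout = , kinetics = )`.
#' @export
write_run_config <- function(layout, kinetics = NULL, path) {
  stopifnot(inherits(layout, "read_layout"))
  cfg <- list(layout = unclass(layout)[c("index_length", "flank5", "flank3",
                                         "bc_length", "read_length")],
              kinetics = kinetics)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  layout <- do.call(read_layout, cfg$layout)
  list(layout = layout, kinetics = cfg$kinetics)
}
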