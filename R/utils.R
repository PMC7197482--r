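DNA_ALPHABET <- c("A", "C", "G", "T")

#' Hamming distance between equal-length DNA strings
#'
#' Vectorised over `a` and `b` (recycled to common length). Both strings of a
#' pair must have the same number of characters.
#'
#' @param a,b Character vectors of equal-length sequences.
#' @return Integer vector of pairwise mismatch counts.
#' @export
#' @examples
#' hamming_distance("ACGT", c("ACGT", "ACGA", "TTTT"))
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop("hamming_distance() requires equal-length sequences", call. = FALSE)
  }
  mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

# Random DNA strings of a fixed length, one call to sample() for determinism.
random_dna <- function(n, length) {
  if (n == 0L) return(character(0))
  chars <- sample(DNA_ALPHABET, n * length, replace = TRUE)
  m <- matrix(chars, nrow = n, ncol = length)
  do.call(paste0, asplit(m, 2))
}

# Split equal-length strings into a character matrix (rows = strings).
seq_to_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), byrow = TRUE)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
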