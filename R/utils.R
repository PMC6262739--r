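# Small sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (ACGT).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[nz])
    ))
  }
  out
}

# Hamming distance between equal-length strings (vectorised over x).
hamming_to <- function(x, key) {
  kc <- strsplit(key, "", fixed = TRUE)[[1]]
  m <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
              ncol = length(kc), byrow = TRUE)
  rowSums(m != matrix(kc, nrow(m), length(kc), byrow = TRUE))
}

# Lexicographically smallest rotation of a repeat unit (canonical motif).
canonical_rotation <- function(unit) {
  n <- nchar(unit)
  rots <- vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(unit, k + 1L, n), substr(unit, 1L, k))
  }, character(1))
  min(rots)
}

# Phred+33 encoding helpers.
phred_to_int <- function(q) as.integer(charToRaw(q)) - 33L
int_to_phred <- function(x) rawToChar(as.raw(x + 33L))

# sample() that never interprets a length-1 vector as 1:n.
resample <- function(x, size = 1L, ...) x[sample.int(length(x), size, ...)]

# Stable order: by primary key descending, ties by lexicographic secondary.
order_desc_then_lex <- function(count, key) order(-count, key, method = "radix")

stop_row <- function(row, fmt, ...) {
  stop(sprintf("row %d: %s", row, sprintf(fmt, ...)), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
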