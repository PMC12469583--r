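# Low-level sequence helpers. Sequences are plain uppercase character
# scalars over A/C/G/T/N; Biostrings is used where it is the natural tool.

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Complement (without reversal) of a DNA string
#' @param x character scalar.
#' @return character scalar.
#' @export
dna_complement <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

#' Reverse (without complementation) of a DNA string
#' @param x character scalar.
#' @return character scalar.
#' @export
dna_reverse <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

# GC fraction of a string; N excluded from the denominator.
gc_fraction <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(NA_real_)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(x), c("G", "C", "A", "T"))
  denom <- sum(counts)
  if (denom == 0) return(NA_real_)
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

# Extract a subsequence on a circle (1-based inclusive); `start` may exceed
# `end`, meaning the interval wraps through the origin.
circular_substr <- function(seq, start, end) {
  n <- nchar(seq)
  start <- ((start - 1L) %% n) + 1L
  end <- ((end - 1L) %% n) + 1L
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, n), substr(seq, 1L, end))
  }
}

# Validate an A/C/G/T/N alphabet; dies naming the offending characters.
check_dna_alphabet <- function(seq, context = "sequence") {
  bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "", fixed = TRUE)[[1]])
  if (length(bad) > 0) {
    stop(sprintf("%s contains unsupported characters (only A/C/G/T/N allowed): %s",
                 context, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Seeded sampling of an i.i.d. background sequence at a given GC fraction
# (A/T and G/C each split evenly).
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
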