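# GenomeRecord: a circular (or linear) DNA sequence plus typed, stranded,
# possibly multi-interval feature annotations.  Coordinates are 1-based
# inclusive throughout, the GenBank convention.

#' Construct a genome record
#'
#' @param id accession or identifier string.
#' @param sequence DNA string (uppercase A/C/G/T/N).
#' @param circular logical; is the molecule circular?
#' @param features a feature table as built by [feature_table()], or `NULL`
#'   for an unannotated record.
#' @return an object of class `genome_record` with elements `id`,
#'   `sequence`, `circular`, `features`.
#' @export
genome_record <- function(id, sequence, circular = TRUE, features = NULL) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence must be nonempty", call. = FALSE)
  check_dna_alphabet(sequence, context = sprintf("record '%s'", id))
  if (is.null(features)) features <- feature_table()
  g <- structure(
    list(id = as.character(id), sequence = sequence,
         circular = isTRUE(circular), features = features),
    class = "genome_record")
  validate_genome_record(g)
  g
}

#' Build a feature table
#'
#' @param gene character vector of gene names.
#' @param kind character vector: one of `"CDS"`, `"tRNA"`, `"rRNA"`,
#'   `"other"`.
#' @param strand character vector of `"+"` / `"-"`.
#' @param intervals list of two-column integer matrices (`start`, `end`),
#'   1-based inclusive, in transcription order.
#' @param notes optional character vector of free-text notes.
#' @return data.frame with a list-column `intervals`.
#' @export
feature_table <- function(gene = character(), kind = character(),
                          strand = character(), intervals = list(),
                          notes = NULL) {
  if (is.null(notes)) notes <- rep("", length(gene))
  stopifnot(length(kind) == length(gene), length(strand) == length(gene),
            length(intervals) == length(gene), length(notes) == length(gene))
  df <- data.frame(gene = as.character(gene), kind = as.character(kind),
                   strand = as.character(strand), notes = as.character(notes),
                   stringsAsFactors = FALSE)
  df$intervals <- lapply(intervals, function(m) {
    m <- matrix(as.integer(m), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    m
  })
  df
}

validate_genome_record <- function(g) {
  n <- nchar(g$sequence)
  ft <- g$features
  if (nrow(ft) > 0) {
    for (i in seq_len(nrow(ft))) {
      m <- ft$intervals[[i]]
      if (nrow(m) < 1) stop("feature with no intervals: ", ft$gene[i], call. = FALSE)
      if (any(m < 1L) || any(m > n))
        stop(sprintf("feature '%s' has intervals outside [1, %d]", ft$gene[i], n),
             call. = FALSE)
      if (any(m[, "end"] < m[, "start"]))
        stop(sprintf("feature '%s' has an interval with end < start", ft$gene[i]),
             call. = FALSE)
      if (!ft$strand[i] %in% c("+", "-"))
        stop("feature strand must be '+' or '-': ", ft$gene[i], call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, %d features\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  if (nrow(x$features) > 0) {
    tab <- table(x$features$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total length of a genome record
#' @param g a `genome_record`.
#' @return integer length in bp.
#' @export
genome_length <- function(g) nchar(g$sequence)

# Spliced, strand-resolved sequence of one feature row (1-based intervals in
# annotation order; minus strand => reverse complement of the concatenation).
splice_feature <- function(g, i) {
  m <- g$features$intervals[[i]]
  parts <- vapply(seq_len(nrow(m)),
                  function(k) substr(g$sequence, m[k, 1], m[k, 2]), "")
  s <- paste(parts, collapse = "")
  if (g$features$strand[i] == "-") s <- revcomp(s)
  s
}
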