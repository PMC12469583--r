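# Dispersed (interspersed) repeat mining: maximal repeat pairs of the four
# REPuter types -- forward (F), palindromic (P, reverse complement),
# reverse (R) and complement (C) -- of length >= 30 bp within a Hamming
# distance of 3, found by seed-and-extend on each strand transform.

#' Find maximal dispersed repeats
#'
#' For each transform t in \{identity (F), reverse complement (P), reverse
#' (R), complement (C)\}, reports every maximal pair `(pos1, pos2, length)`
#' with `Hamming(S[pos1..], t-image of S[pos2..]) <= max_mismatch` and
#' `length >= min_len`.  Maximal means no one-base extension on either side
#' keeps the pair within the mismatch budget.  Each unordered pair is
#' reported once (`pos1 <= pos2`; a self-centered palindrome once).
#'
#' @param genome a [genome_record()] or DNA string.
#' @param min_len minimum repeat length in bp (default 30).
#' @param max_mismatch Hamming-distance budget (default 3).
#' @param layout optional `quadripartite_layout`; palindromic pairs whose
#'   coordinates coincide with the IRa/IRb pair are tagged `is_ir_pair`.
#' @param types subset of `c("F", "P", "R", "C")`.
#' @return data.frame (type, pos1, pos2, length, mismatches, is_ir_pair),
#'   coordinates 1-based starts of the two copies as read on the forward
#'   strand.
#' @export
find_dispersed <- function(genome, min_len = 30, max_mismatch = 3,
                           layout = NULL, types = c("F", "P", "R", "C")) {
  s <- if (inherits(genome, "genome_record")) genome$sequence else toupper(genome)
  n <- nchar(s)
  out <- list()
  for (ty in types) {
    t_s <- switch(ty, F = s, P = revcomp(s), R = dna_reverse(s),
                  C = dna_complement(s))
    hits <- maximal_pairs_cpp(s, t_s, as.integer(min_len),
                              as.integer(max_mismatch), ty == "F")
    if (nrow(hits) == 0) next
    # map the position in the transformed string back to a forward-strand
    # start of the second copy
    j2 <- switch(ty,
                 F = hits$j,
                 P = n - hits$j - hits$len + 2L,
                 R = n - hits$j - hits$len + 2L,
                 C = hits$j)
    df <- data.frame(type = ty,
                     pos1 = pmin(hits$i, j2), pos2 = pmax(hits$i, j2),
                     length = hits$len, mismatches = hits$mism)
    if (ty == "C") df <- df[hits$i != j2, , drop = FALSE]
    df <- unique(df)
    out[[length(out) + 1L]] <- df
  }
  if (length(out) == 0) {
    return(data.frame(type = character(), pos1 = integer(), pos2 = integer(),
                      length = integer(), mismatches = integer(),
                      is_ir_pair = logical()))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$type, c("F", "P", "R", "C")), res$pos1, res$pos2), ]
  rownames(res) <- NULL
  res$is_ir_pair <- FALSE
  if (!is.null(layout)) {
    # a window under a mismatch budget can extend a little past the exact
    # IR copies, so tag palindromic pairs whose two intervals each contain
    # the corresponding IR copy
    irb <- layout$regions[layout$regions$region == "IRb", ]
    ira <- layout$regions[layout$regions$region == "IRa", ]
    s1 <- pmin(irb$start, ira$start); e1 <- s1 + irb$length - 1L
    s2 <- pmax(irb$start, ira$start); e2 <- s2 + ira$length - 1L
    res$is_ir_pair <- res$type == "P" &
      res$pos1 <= s1 & res$pos1 + res$length - 1L >= e1 &
      res$pos2 <= s2 & res$pos2 + res$length - 1L >= e2
  }
  res
}

#' Summarize dispersed repeats by type
#'
#' @param repeats data.frame from [find_dispersed()].
#' @param include_ir_pair include the IRa/IRb self-pair in the counts
#'   (default `FALSE`, since published totals usually exclude it).
#' @return list with `by_type` counts and `total`.
#' @export
summarize_dispersed <- function(repeats, include_ir_pair = FALSE) {
  if (!include_ir_pair && "is_ir_pair" %in% names(repeats))
    repeats <- repeats[!repeats$is_ir_pair, , drop = FALSE]
  by_type <- data.frame(
    type = c("F", "P", "R", "C"),
    n = as.integer(table(factor(repeats$type, levels = c("F", "P", "R", "C")))))
  list(by_type = by_type, total = nrow(repeats))
}
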