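# Microsatellite (SSR) mining under MISA-style thresholds: perfect tandem
# repeats of 1-6 nt motifs, with minimum unit counts of 10 (mono), 6 (di),
# 4 (tri) and 3 (tetra/penta/hexa).

#' Minimum unit counts per SSR motif length
#'
#' MISA-style thresholds: 10 repeats for mononucleotide motifs, 6 for
#' dinucleotide, 4 for trinucleotide and 3 for tetra-, penta- and
#' hexanucleotide motifs.
#' @format integer vector of length 6, indexed by motif length.
#' @export
MISA_THRESHOLDS <- c(10L, 6L, 4L, 3L, 3L, 3L)

#' Find simple sequence repeats (microsatellites)
#'
#' Left-to-right scan for maximal perfect tandem runs of period 1-6.  Each
#' run is assigned its smallest primitive period (so `(AT)6` is one
#' dinucleotide SSR, not overlapping mononucleotide runs) and reported when
#' its unit count reaches the class threshold.  Runs wholly contained in a
#' reported run of smaller period are not double-reported.
#'
#' @param genome a [genome_record()] or DNA string.
#' @param layout optional `quadripartite_layout`; adds a region column.
#' @param thresholds integer vector of minimum unit counts for motif
#'   lengths 1-6.
#' @return data.frame (motif, motif_length, unit_count, start, end,
#'   region), coordinates 1-based inclusive; `end - start + 1` equals
#'   `motif_length * unit_count`.
#' @export
find_ssrs <- function(genome, layout = NULL, thresholds = MISA_THRESHOLDS) {
  s <- if (inherits(genome, "genome_record")) genome$sequence else toupper(genome)
  n <- nchar(s)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  cand <- list()
  for (p in 1:6) {
    if (n < p * thresholds[p]) next
    eq <- x[seq_len(n - p)] == x[seq.int(p + 1L, n)] & x[seq_len(n - p)] %in% c("A", "C", "G", "T")
    r <- rle(eq)
    ends_eq <- cumsum(r$lengths)
    starts_eq <- ends_eq - r$lengths + 1L
    hit <- which(r$values & r$lengths + p >= p * thresholds[p])
    for (h in hit) {
      i <- starts_eq[h]                      # run spans s[i .. i + len + p - 1]
      total <- r$lengths[h] + p
      units <- total %/% p
      if (units < thresholds[p]) next
      motif <- substr(s, i, i + p - 1L)
      if (!is_primitive(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        motif = motif, motif_length = p, unit_count = units,
        start = i, end = i + units * p - 1L, run_end = i + total - 1L)
    }
  }
  if (length(cand) == 0) {
    out <- data.frame(motif = character(), motif_length = integer(),
                      unit_count = integer(), start = integer(),
                      end = integer(), region = character())
    return(out)
  }
  df <- do.call(rbind, cand)
  df <- df[order(df$motif_length, df$start), ]
  # drop runs contained in an accepted run of smaller period
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    smaller <- which(keep & df$motif_length < df$motif_length[i])
    if (any(df$start[smaller] <= df$start[i] & df$run_end[smaller] >= df$run_end[i]))
      keep[i] <- FALSE
  }
  df <- df[keep, c("motif", "motif_length", "unit_count", "start", "end")]
  df <- df[order(df$start), ]
  rownames(df) <- NULL
  df$region <- if (is.null(layout)) NA_character_ else
    vapply(df$start, function(p) locate_region(layout, p), "")
  df
}

# a motif is primitive when it is not a repetition of a shorter motif
is_primitive <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (q in seq_len(p - 1L)) {
    if (p %% q == 0L &&
        motif == paste(rep(substr(motif, 1L, q), p %/% q), collapse = ""))
      return(FALSE)
  }
  TRUE
}

#' Summarize SSR loci by motif and by class
#'
#' Motifs are tallied exactly as read on the forward strand (A and T runs
#' are separate entries; no canonical collapsing).
#'
#' @param loci data.frame from [find_ssrs()].
#' @return list with `by_motif` and `by_class` count data.frames and
#'   `total`.
#' @export
summarize_ssrs <- function(loci) {
  class_names <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  by_class <- data.frame(
    class = class_names,
    n = as.integer(table(factor(loci$motif_length, levels = 1:6))))
  by_motif <- if (nrow(loci) == 0) {
    data.frame(motif = character(), n = integer())
  } else {
    out <- as.data.frame(table(motif = loci$motif), stringsAsFactors = FALSE)
    names(out) <- c("motif", "n")
    out <- out[order(-out$n, out$motif), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(by_motif = by_motif, by_class = by_class, total = nrow(loci))
}
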