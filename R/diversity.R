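# Nucleotide diversity (Pi): the mean number of pairwise differences per
# site across aligned sequences, with complete deletion of columns holding
# any gap or ambiguity (DnaSP's default site treatment), and no
# multiple-hit correction.

#' Nucleotide diversity of one gene alignment
#'
#' Columns containing any non-ACGT character (gap, N, ambiguity) are
#' excluded.  Pi is the sum over unordered sequence pairs of their
#' per-retained-column difference counts, divided by the number of pairs
#' and by the number of retained columns.
#'
#' @param aln a [gene_alignment()] with at least 2 rows.
#' @return a `pi_result`: list with `gene_name`, `pi`, `n_taxa`,
#'   `sites_used`, and `windows` (here the single whole-gene window).  When
#'   no columns survive filtering, `pi` is `NA`.
#' @export
gene_pi <- function(aln) {
  if (length(aln$rows) < 2) stop("need >= 2 sequences for Pi", call. = FALSE)
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  keep <- colSums(!matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))) == 0
  pi <- pi_from_matrix(mat[, keep, drop = FALSE])
  structure(list(gene_name = aln$gene_name, pi = pi,
                 n_taxa = nrow(mat), sites_used = sum(keep),
                 windows = data.frame(start = 1L, end = aln$ncol, pi = pi)),
            class = "pi_result")
}

# mean pairwise differences per column of a filtered character matrix
pi_from_matrix <- function(m) {
  n <- nrow(m)
  L <- ncol(m)
  if (L == 0L) return(NA_real_)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      tot <- tot + sum(m[i, ] != m[j, ])
    }
  }
  tot / choose(n, 2) / L
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf("<pi_result> %s: pi = %s over %d taxa, %d sites\n",
              x$gene_name, format(x$pi, digits = 5), x$n_taxa, x$sites_used))
  invisible(x)
}

#' Sliding-window nucleotide diversity
#'
#' Windows of `window` alignment columns advance by `step`; per-window Pi
#' uses the same complete-deletion rule as [gene_pi()] within the window.
#' After the last full window, one trailing partial window is added only
#' when at least `step` columns follow it and some columns are not yet
#' covered.
#'
#' @param aln a [gene_alignment()].
#' @param window window width in alignment columns.
#' @param step step size in columns (default 25).
#' @return data.frame (start, end, pi), columns 1-based inclusive.
#' @export
sliding_pi <- function(aln, window, step = 25) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  if (window > aln$ncol) stop("window exceeds alignment length", call. = FALSE)
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  good <- colSums(!matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))) == 0
  starts <- seq(1L, aln$ncol - window + 1L, by = step)
  ends <- starts + window - 1L
  last_end <- ends[length(ends)]
  nxt <- starts[length(starts)] + step
  if (last_end < aln$ncol && nxt <= aln$ncol && (aln$ncol - nxt + 1L) >= step) {
    starts <- c(starts, nxt)
    ends <- c(ends, aln$ncol)
  }
  pi <- vapply(seq_along(starts), function(k) {
    cols <- seq.int(starts[k], ends[k])
    cols <- cols[good[cols]]
    pi_from_matrix(mat[, cols, drop = FALSE])
  }, 0)
  data.frame(start = starts, end = ends, pi = pi)
}

#' Rank hypervariable genes by Pi
#'
#' @param results list of `pi_result`s.
#' @param threshold genes with `pi > threshold` are reported (default
#'   0.08).
#' @return data.frame (gene, pi) sorted by descending Pi, ties broken
#'   alphabetically.
#' @export
rank_hypervariable <- function(results, threshold = 0.08) {
  df <- data.frame(gene = vapply(results, `[[`, "", "gene_name"),
                   pi = vapply(results, `[[`, 0, "pi"))
  df <- df[!is.na(df$pi) & df$pi > threshold, , drop = FALSE]
  df <- df[order(-df$pi, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write per-gene FASTA of genes shared across genomes
#'
#' Intersects CDS gene names across the given annotated genomes and writes
#' one unaligned multi-FASTA per shared gene (first annotated copy per
#' genome, spliced and strand-resolved), ready for external alignment.
#'
#' @param genomes list of [genome_record()]s.
#' @param out_dir output directory (created if needed).
#' @return character vector of shared gene names, invisibly.
#' @export
extract_shared_genes <- function(genomes, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  name_sets <- lapply(genomes, function(g)
    unique(g$features$gene[g$features$kind == "CDS"]))
  shared <- Reduce(intersect, name_sets)
  for (gene in shared) {
    seqs <- vapply(genomes, function(g) {
      i <- which(g$features$gene == gene & g$features$kind == "CDS")[1]
      splice_feature(g, i)
    }, "")
    names(seqs) <- vapply(genomes, `[[`, "", "id")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                file.path(out_dir, paste0(gene, ".fasta")))
  }
  invisible(shared)
}
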