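# GenBank flat-file reading and writing.  The parser covers the subset of
# the format that annotated organelle records use: a LOCUS line (molecule
# topology), a FEATURES table with join()/complement() locations, and an
# ORIGIN sequence block.  Coordinates are kept 1-based inclusive, so a
# record written by write_genbank() reads back losslessly.

#' Read a GenBank flat file
#'
#' @param path path to a GenBank flat file with an ORIGIN sequence block.
#' @return a [genome_record()].  Feature locations (including `join(...)`
#'   and `complement(...)`) are resolved to interval lists; the circular
#'   flag is taken from the LOCUS line.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty GenBank file: ", path, call. = FALSE)

  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0) stop("no LOCUS line in ", path, call. = FALSE)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- if (length(locus) >= 2) locus[2] else "unknown"
  circular <- any(grepl("circular", lines[locus_i[1]], ignore.case = TRUE))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0) stop("no ORIGIN sequence block in ", path, call. = FALSE)
  orig_i <- orig_i[1]

  # --- sequence ---
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) min(end_i[end_i > orig_i]) else length(lines) + 1L
  seq_lines <- lines[seq(orig_i + 1L, end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("ORIGIN block contains no sequence in ", path, call. = FALSE)

  # --- features ---
  gene <- kind <- strand <- notes <- character()
  intervals <- list()
  if (length(feat_i) > 0) {
    block <- lines[seq(feat_i[1] + 1L, orig_i - 1L)]
    # split into per-feature chunks: a feature starts with 5 spaces + key
    starts <- grep("^ {5}\\S", block)
    if (length(starts) > 0) {
      bounds <- c(starts, length(block) + 1L)
      for (k in seq_along(starts)) {
        chunk <- block[seq(bounds[k], bounds[k + 1L] - 1L)]
        key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1])
        if (key %in% c("source")) next
        # location may continue over lines until the first qualifier
        qual_start <- grep("^\\s+/", chunk)
        loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(chunk)
        loc <- paste(trimws(sub("^ {5}\\S+\\s*", "", chunk[1])),
                     paste(trimws(chunk[seq_len(loc_end)[-1]]), collapse = ""),
                     sep = "")
        loc <- gsub("\\s", "", loc)
        parsed <- tryCatch(parse_location(loc), error = function(e)
          stop(sprintf("malformed feature location '%s' (feature starting at line %d of %s)",
                       loc, feat_i[1] + bounds[k], path), call. = FALSE))
        quals <- parse_qualifiers(chunk[seq.int(loc_end + 1L, length.out = max(0L, length(chunk) - loc_end))])
        gname <- quals[["gene"]] %||% quals[["locus_tag"]] %||%
          quals[["product"]] %||% sprintf("%s_%d", key, k)
        gene <- c(gene, gname)
        kind <- c(kind, if (key %in% c("CDS", "tRNA", "rRNA")) key else "other")
        strand <- c(strand, if (parsed$minus) "-" else "+")
        intervals <- c(intervals, list(parsed$intervals))
        notes <- c(notes, quals[["note"]] %||% "")
      }
    }
  }

  genome_record(id = id, sequence = sequence, circular = circular,
                features = feature_table(gene, kind, strand, intervals, notes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse a GenBank location string into an interval matrix plus strand flag.
# Handles nesting of complement()/join()/order() and partial markers (< >).
parse_location <- function(loc) {
  loc <- gsub("[<>]", "", loc)
  rec <- function(s, minus) {
    if (grepl("^complement\\(", s)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", s)
      return(rec(inner, !minus))
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
      parts <- split_top_level(inner)
      out <- lapply(parts, rec, minus = minus)
      mm <- do.call(rbind, lapply(out, `[[`, "intervals"))
      any_minus <- any(vapply(out, `[[`, TRUE, "minus"))
      return(list(intervals = mm, minus = any_minus))
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", s)) {
      ab <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
      return(list(intervals = matrix(ab, ncol = 2,
                                     dimnames = list(NULL, c("start", "end"))),
                  minus = minus))
    }
    if (grepl("^[0-9]+$", s)) {
      p <- as.integer(s)
      return(list(intervals = matrix(c(p, p), ncol = 2,
                                     dimnames = list(NULL, c("start", "end"))),
                  minus = minus))
    }
    stop("unparseable location component: ", s, call. = FALSE)
  }
  rec(loc, FALSE)
}

# Split "a..b,complement(c..d),..." at top-level commas only.
split_top_level <- function(s) {
  depth <- 0L
  cuts <- integer()
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts),
         function(k) paste(chars[starts[k]:ends[k]], collapse = ""), "")
}

parse_qualifiers <- function(lines) {
  if (length(lines) == 0) return(list())
  # re-join continuation lines onto their qualifier
  recs <- character()
  for (ln in trimws(lines)) {
    if (startsWith(ln, "/")) recs <- c(recs, ln)
    else if (length(recs)) recs[length(recs)] <- paste(recs[length(recs)], ln)
  }
  out <- list()
  for (r in recs) {
    m <- regmatches(r, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', r))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

#' Write a genome record as a GenBank flat file
#'
#' @param g a [genome_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  n <- nchar(g$sequence)
  topo <- if (g$circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s PLN 01-JAN-2026",
                   g$id, n, topo),
           sprintf("DEFINITION  %s synthetic or re-exported record.", g$id),
           sprintf("ACCESSION   %s", g$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  key_of <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", other = "misc_feature")
  ft <- g$features
  for (i in seq_len(nrow(ft))) {
    m <- ft$intervals[[i]]
    spans <- sprintf("%d..%d", m[, "start"], m[, "end"])
    loc <- if (nrow(m) > 1) sprintf("join(%s)", paste(spans, collapse = ",")) else spans
    if (ft$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     %-15s %s", key_of[[ft$kind[i]]], loc),
             sprintf('                     /gene="%s"', ft$gene[i]))
    if (nzchar(ft$notes[i]))
      out <- c(out, sprintf('                     /note="%s"', ft$notes[i]))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(g$sequence)
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, n))
    grp <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(grp, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read a genome from a FASTA file
#'
#' @param path FASTA file; the first record is used.
#' @param circular logical, assumed topology.
#' @return an unannotated [genome_record()].
#' @export
read_fasta_genome <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no sequences in ", path, call. = FALSE)
  genome_record(id = sub("\\s.*$", "", names(ss)[1]),
                sequence = as.character(ss[[1]]), circular = circular)
}

#' Write a genome (or any named set of sequences) as FASTA
#' @param g a `genome_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path) {
  ss <- Biostrings::DNAStringSet(setNames(g$sequence, g$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a multi-FASTA gene alignment
#'
#' @param path multi-FASTA file of equal-length aligned rows (gap `-`).
#' @param gene_name optional gene name; defaults to the file stem.
#' @return a `gene_alignment`: list with `gene_name`, `taxa`, `rows`
#'   (character vector of aligned sequences) and `ncol`.
#' @export
read_alignment <- function(path, gene_name = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no sequences in ", path, call. = FALSE)
  w <- Biostrings::width(ss)
  if (length(unique(w)) > 1) {
    ref <- w[1]
    bad <- names(ss)[w != ref]
    stop(sprintf("ragged alignment in %s: rows of differing length for taxa: %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  gene_alignment(gene_name %||% sub("\\.[^.]*$", "", basename(path)),
                 taxa = sub("\\s.*$", "", names(ss)),
                 rows = toupper(as.character(ss)))
}

#' Construct a gene alignment object
#' @param gene_name gene name string.
#' @param taxa character vector of taxon ids.
#' @param rows character vector of equal-length aligned sequences.
#' @return a `gene_alignment` object.
#' @export
gene_alignment <- function(gene_name, taxa, rows) {
  stopifnot(length(taxa) == length(rows))
  w <- unique(nchar(rows))
  if (length(w) > 1) stop("alignment rows have differing lengths", call. = FALSE)
  structure(list(gene_name = gene_name, taxa = as.character(taxa),
                 rows = unname(toupper(rows)),
                 ncol = if (length(rows)) w else 0L),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d taxa x %d columns\n",
              x$gene_name, length(x$taxa), x$ncol))
  invisible(x)
}
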