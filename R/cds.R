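# Coding-sequence extraction and the quality filter applied before codon
# analysis: length > 300 nt, ATG start, standard stop, no in-frame stop,
# and removal of IR-duplicated copies.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Extract and filter coding sequences from an annotated genome
#'
#' Each CDS feature is spliced across its intervals (reverse-complemented
#' on the minus strand) and screened against the analysis filter.  Failing
#' records are flagged, never dropped:
#' \itemize{
#'   \item `non_triplet` — length not a multiple of 3;
#'   \item `too_short` — spliced length not strictly greater than 300 nt;
#'   \item `bad_start` — first codon is not ATG;
#'   \item `bad_stop` — last codon not in TAA/TAG/TGA;
#'   \item `internal_stop` — a stop codon at an interior position;
#'   \item `ir_duplicate` — among CDSs with identical gene name and
#'     identical spliced sequence, every copy after the first.
#' }
#'
#' @param genome a [genome_record()].
#' @param layout optional [quadripartite layout][detect_inverted_repeats];
#'   when given, each record carries its source region (LSC/SSC/IRa/IRb or
#'   `spanning`).
#' @return list of `cds_record` objects (`gene_name`, `seq`, `codons`,
#'   `length_nt`, `source_region`, `filter_flags`).
#' @export
extract_cds <- function(genome, layout = NULL) {
  ft <- genome$features
  idx <- which(ft$kind == "CDS")
  recs <- vector("list", length(idx))
  seqs <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    s <- splice_feature(genome, i)
    seqs[k] <- s
    len <- nchar(s)
    flags <- character()
    if (len %% 3L != 0L) flags <- c(flags, "non_triplet")
    if (len <= 300L) flags <- c(flags, "too_short")
    codons <- substring(s, seq(1L, len - len %% 3L, by = 3L),
                        pmin(seq(3L, len + 2L, by = 3L), len))
    codons <- codons[nchar(codons) == 3L]
    if (length(codons) == 0 || codons[1] != "ATG") flags <- c(flags, "bad_start")
    if (length(codons) == 0 || !(codons[length(codons)] %in% STOP_CODONS))
      flags <- c(flags, "bad_stop")
    if (length(codons) > 2 &&
        any(codons[seq(2L, length(codons) - 1L)] %in% STOP_CODONS))
      flags <- c(flags, "internal_stop")
    region <- if (is.null(layout)) NA_character_ else {
      m <- ft$intervals[[i]]
      r1 <- locate_region(layout, min(m[, "start"]))
      r2 <- locate_region(layout, max(m[, "end"]))
      if (identical(r1, r2)) r1 else "spanning"
    }
    recs[[k]] <- structure(
      list(gene_name = ft$gene[i], seq = s, codons = codons, length_nt = len,
           source_region = region, filter_flags = flags),
      class = "cds_record")
  }
  # IR duplicates: identical (name, sequence) pairs keep exactly one copy
  key <- paste(vapply(recs, `[[`, "", "gene_name"), seqs, sep = "\r")
  dup <- duplicated(key)
  for (k in which(dup))
    recs[[k]]$filter_flags <- union(recs[[k]]$filter_flags, "ir_duplicate")
  recs
}

#' Keep only CDS records that pass every filter
#' @param cds list of `cds_record`s from [extract_cds()].
#' @return the subset with empty `filter_flags`.
#' @export
cds_passing <- function(cds) {
  Filter(function(r) length(r$filter_flags) == 0, cds)
}

#' Summarize CDS records as a data frame
#' @param cds list of `cds_record`s.
#' @return data.frame with one row per CDS.
#' @export
cds_summary <- function(cds) {
  data.frame(
    gene = vapply(cds, `[[`, "", "gene_name"),
    length_nt = vapply(cds, `[[`, 0L, "length_nt"),
    region = vapply(cds, `[[`, "", "source_region"),
    flags = vapply(cds, function(r) paste(r$filter_flags, collapse = ";"), ""),
    passes = vapply(cds, function(r) length(r$filter_flags) == 0, TRUE),
    stringsAsFactors = FALSE)
}

# Functional group of a plastid gene, by the field's naming conventions.
plastid_gene_group <- function(name) {
  base <- sub("[-_.].*$", "", name)
  if (grepl("^psa", base)) return("Photosystem I")
  if (grepl("^psb", base)) return("Photosystem II")
  if (grepl("^pet", base)) return("Cytochrome b6/f complex")
  if (grepl("^atp", base)) return("ATP synthase")
  if (grepl("^ndh", base)) return("NADH dehydrogenase")
  if (base == "rbcL") return("Rubisco")
  if (grepl("^rpl", base)) return("Ribosomal proteins (LSU)")
  if (grepl("^rps", base)) return("Ribosomal proteins (SSU)")
  if (grepl("^rpo", base)) return("RNA polymerase")
  if (grepl("^rrn", base)) return("Ribosomal RNAs")
  if (grepl("^trn", base)) return("Transfer RNAs")
  if (grepl("^ycf", base)) return("Other/ycf")
  if (base %in% c("matK", "clpP", "ccsA", "cemA", "accD", "infA",
                  "chlB", "chlL", "chlN", "cysA", "cysT")) return("Other genes")
  "unclassified"
}

#' Tally annotated genes by kind and functional group
#'
#' Counts are reported two ways: as annotated (IR-duplicated copies counted
#' twice) and by unique gene name (duplicates counted once), since either
#' convention appears in published gene totals.
#'
#' @param genome a [genome_record()].
#' @return list with `kind_counts` (annotated copies), `kind_counts_unique`
#'   (unique names), `group_counts` (data.frame of functional groups over
#'   unique names), and `intron_genes` (unique names of cis genes annotated
#'   with two or more intervals).
#' @export
classify_genes <- function(genome) {
  ft <- genome$features
  kinds <- c("CDS", "tRNA", "rRNA", "other")
  kc <- setNames(integer(length(kinds)), kinds)
  kcu <- kc
  if (nrow(ft) > 0) {
    tab <- table(factor(ft$kind, levels = kinds))
    kc[names(tab)] <- as.integer(tab)
    uft <- ft[!duplicated(paste(ft$gene, ft$kind)), ]
    tabu <- table(factor(uft$kind, levels = kinds))
    kcu[names(tabu)] <- as.integer(tabu)
  }
  kc <- c(kc, total = sum(kc))
  kcu <- c(kcu, total = sum(kcu))

  groups <- character(0)
  if (nrow(ft) > 0) {
    uniq <- ft[!duplicated(ft$gene), ]
    groups <- vapply(uniq$gene, plastid_gene_group, "")
    unknown <- uniq$gene[groups == "unclassified"]
    if (length(unknown))
      message("unclassified gene name(s): ", paste(unknown, collapse = ", "))
  }
  gc_df <- if (length(groups) == 0) {
    data.frame(group = character(), n_genes = integer())
  } else {
    out <- as.data.frame(table(group = groups), stringsAsFactors = FALSE)
    names(out) <- c("group", "n_genes")
    out
  }

  n_int <- character(0)
  if (nrow(ft) > 0) {
    multi <- vapply(ft$intervals, nrow, 0L) >= 2L
    cis <- !grepl("trans", ft$notes, ignore.case = TRUE)
    n_int <- unique(ft$gene[multi & cis])
  }
  list(kind_counts = kc, kind_counts_unique = kcu,
       group_counts = gc_df, intron_genes = n_int)
}
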