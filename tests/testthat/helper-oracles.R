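# Independent oracles used across the suite.  These deliberately take the
# slow, direct route (per-diagonal enumeration, closed-form homozygosity)
# so they share no code path with the package implementations they check.

ACGT <- c("A", "C", "G", "T")

rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(ACGT, n, replace = TRUE, prob = p), collapse = "")
}

# --- brute-force maximal-pair enumeration, one transform at a time ------
# Walks every diagonal of the comparison s vs transform(s), lists mismatch
# positions, and reads the maximal windows straight off the definition.
brute_maximal_pairs <- function(s, type, min_len = 30, max_mismatch = 3) {
  n <- nchar(s)
  t_s <- switch(type, F = s, P = revcomp(s), R = dna_reverse(s),
                C = dna_complement(s))
  x1 <- strsplit(s, "", fixed = TRUE)[[1]]
  x2 <- strsplit(t_s, "", fixed = TRUE)[[1]]
  mm <- max_mismatch
  rows <- list()
  for (d in seq(-(n - 1L), n - 1L)) {
    i0 <- max(1L, 1L - d)
    j0 <- i0 + d
    len <- min(n - i0, n - j0) + 1L
    if (len < min_len) next
    if (type == "F" && d == 0L) next
    ii <- seq.int(i0, i0 + len - 1L)
    jj <- seq.int(j0, j0 + len - 1L)
    bad <- which(x1[ii] != x2[jj] | !(x1[ii] %in% ACGT) | !(x2[jj] %in% ACGT))
    mpos <- c(0L, bad, len + 1L)
    T <- length(mpos)
    if (T - 2L < mm) {
      ws <- 1L; we <- len; nm <- T - 2L
    } else {
      t <- seq_len(T - mm - 1L)
      ws <- mpos[t] + 1L
      we <- mpos[t + mm + 1L] - 1L
      nm <- rep(mm, length(t))
    }
    keep <- (we - ws + 1L) >= min_len
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        i = i0 + ws[keep] - 1L, j = j0 + ws[keep] - 1L,
        len = we[keep] - ws[keep] + 1L, mism = nm[keep])
    }
  }
  if (length(rows) == 0) {
    return(data.frame(type = character(), pos1 = integer(), pos2 = integer(),
                      length = integer(), mismatches = integer()))
  }
  df <- do.call(rbind, rows)
  j2 <- switch(type, F = df$j, C = df$j,
               P = n - df$j - df$len + 2L, R = n - df$j - df$len + 2L)
  out <- data.frame(type = type, pos1 = pmin(df$i, j2), pos2 = pmax(df$i, j2),
                    length = df$len, mismatches = df$mism)
  if (type == "C") out <- out[df$i != j2, , drop = FALSE]
  out <- unique(out)
  out[order(out$pos1, out$pos2, out$length), , drop = FALSE]
}

# plant one copy-pair of each repeat type into a random background
plant_repeats_in <- function(s, lengths = c(34L, 40L, 36L, 38L),
                             mismatches = NULL) {
  n <- nchar(s)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  types <- c("F", "P", "R", "C")
  if (is.null(mismatches)) mismatches <- sample(0:3, 4, replace = TRUE)
  slots <- floor(seq(50, n - max(lengths) - 50, length.out = 8))
  for (k in seq_along(types)) {
    L <- lengths[k]
    core <- strsplit(rand_seq(L), "", fixed = TRUE)[[1]]
    img <- switch(types[k],
                  F = core,
                  P = strsplit(revcomp(paste(core, collapse = "")), "")[[1]],
                  R = rev(core),
                  C = strsplit(dna_complement(paste(core, collapse = "")), "")[[1]])
    m <- mismatches[k]
    if (m > 0) {
      at <- sample(seq.int(2L, L - 1L), m)
      for (a in at) img[a] <- sample(setdiff(ACGT, img[a]), 1)
    }
    x[seq(slots[2 * k - 1], length.out = L)] <- core
    x[seq(slots[2 * k], length.out = L)] <- img
  }
  paste(x, collapse = "")
}

# --- independent ENC computation ---------------------------------------
# Recomputes Wright's estimator from the genetic code directly, using its
# own family bookkeeping.
enc_oracle <- function(counts) {
  code <- Biostrings::GENETIC_CODE
  counts <- counts[names(code)[code != "*"]]
  aa <- code[names(counts)]
  fam_sizes <- table(aa)
  Fs <- tapply(seq_along(counts), aa, function(idx) {
    nn <- sum(counts[idx])
    if (nn < 2) return(NA_real_)
    pp <- counts[idx] / nn
    (nn * sum(pp^2) - 1) / (nn - 1)
  })
  avg <- function(k) {
    v <- Fs[names(fam_sizes)[fam_sizes == k]]
    v <- v[!is.na(v) & v > 0]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  f2 <- avg(2); f3 <- avg(3); f4 <- avg(4); f6 <- avg(6)
  if (is.na(f3)) f3 <- mean(c(f2, f4))
  min(61, 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6)
}

# one codon chosen per amino-acid family, preferring A-ending then T-ending
one_per_family <- function() {
  fams <- plastchar:::codon_tables$families
  vapply(fams, function(codons) {
    third <- substr(codons, 3, 3)
    if (any(third == "A")) codons[third == "A"][1]
    else if (any(third == "T")) codons[third == "T"][1]
    else codons[1]
  }, "")
}

# small annotated genome built by hand for feature-level tests
tiny_genome <- function(seq, ...) {
  genome_record(id = "tiny", sequence = seq, circular = FALSE,
                features = feature_table(...))
}
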