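# Codon-usage-bias suite: positional GC composition, RSCU, the effective
# number of codons (ENC, Wright's homozygosity estimator as implemented by
# CodonW: six-fold families kept whole, a missing three-fold mean imputed
# from the two- and four-fold means), neutrality and PR2 plot data,
# parameter correlations, and optimal-codon identification from ENC-ranked
# high/low-expression gene pools.

# --- genetic-code bookkeeping (standard code; DNA alphabet internally) ---

codon_tables <- local({
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  fam <- split(names(sense), sense)             # amino acid -> codons
  sizes <- vapply(fam, length, 0L)
  list(code = gc, sense = names(sense), aa = sense,
       families = fam, family_size = sizes,
       stops = names(gc)[gc == "*"],
       nondeg = names(sense)[sizes[sense] == 1])  # ATG, TGG
})

dna_to_rna <- function(x) chartr("T", "U", x)

#' Tally codon usage
#' @param cds a `cds_record`, a character vector of codons, or a list of
#'   either (pooled).
#' @return named integer vector of counts over the 64 codons (DNA
#'   alphabet).
#' @export
codon_counts <- function(cds) {
  grab <- function(x) if (inherits(x, "cds_record")) x$codons else as.character(x)
  codons <- if (inherits(cds, "cds_record")) grab(cds)
            else if (is.list(cds)) unlist(lapply(cds, grab))
            else grab(cds)
  codons <- toupper(chartr("U", "T", codons))
  counts <- table(factor(codons, levels = names(codon_tables$code)))
  setNames(as.integer(counts), names(codon_tables$code))
}

# codons entering composition analysis: terminal stop dropped
analysis_codons <- function(cds) {
  codons <- if (inherits(cds, "cds_record")) cds$codons else toupper(chartr("U", "T", as.character(cds)))
  if (length(codons) && codons[length(codons)] %in% codon_tables$stops)
    codons <- codons[-length(codons)]
  codons
}

#' Per-gene codon composition statistics
#'
#' The terminal stop codon is excluded from every tally; the start codon is
#' included.  GC1, GC2 and GCall are fractions over all remaining codons;
#' all third-position statistics (A3/T3/G3/C3, GC3, GC3s) are computed over
#' the synonymously variable codons only (ATG and TGG excluded along with
#' stops), since the third position of a nondegenerate codon cannot vary.
#' Under this convention GC3 and GC3s coincide; both columns are kept for
#' the standard report layout.  ENC is computed by [enc()].
#'
#' @param cds a `cds_record` (or codon character vector).
#' @param gene_name used when `cds` is a plain codon vector.
#' @return one-row data.frame: gene, length_nt, n_codons, A3, T3, G3, C3,
#'   GC1, GC2, GC3, GC12, GC3s, GCall, ENC.
#' @export
codon_composition <- function(cds, gene_name = NULL) {
  codons <- analysis_codons(cds)
  codons <- codons[!codons %in% codon_tables$stops]   # internal stops never counted
  if (length(codons) == 0)
    stop("no analyzable codons: composition undefined", call. = FALSE)
  gene <- gene_name %||% if (inherits(cds, "cds_record")) cds$gene_name else "gene"
  base_at <- function(pos, set) {
    ch <- substr(set, pos, pos)
    ch
  }
  gcfrac <- function(ch) mean(ch %in% c("G", "C"))
  p1 <- base_at(1, codons); p2 <- base_at(2, codons); p3 <- base_at(3, codons)
  gc1 <- gcfrac(p1); gc2 <- gcfrac(p2)
  syn <- codons[!codons %in% codon_tables$nondeg]
  if (length(syn) > 0) {
    s3 <- base_at(3, syn)
    a3 <- mean(s3 == "A"); t3 <- mean(s3 == "T")
    g3 <- mean(s3 == "G"); c3 <- mean(s3 == "C")
    gc3s <- mean(s3 %in% c("G", "C"))
  } else {
    a3 <- t3 <- g3 <- c3 <- gc3s <- NA_real_
  }
  gc3 <- gc3s
  data.frame(gene = gene,
             length_nt = if (inherits(cds, "cds_record")) cds$length_nt
                         else 3L * length(codons),
             n_codons = length(codons),
             A3 = a3, T3 = t3, G3 = g3, C3 = c3,
             GC1 = gc1, GC2 = gc2, GC3 = gc3, GC12 = (gc1 + gc2) / 2,
             GC3s = gc3s, GCall = mean(c(p1, p2, p3) %in% c("G", "C")),
             ENC = enc(codon_counts(codons)))
}

#' Codon composition table for a set of genes
#' @param cds_list list of `cds_record`s (use [cds_passing()] first).
#' @return data.frame with one row per gene.
#' @export
codon_stats_table <- function(cds_list) {
  out <- do.call(rbind, lapply(cds_list, codon_composition))
  rownames(out) <- NULL
  out
}

#' Effective number of codons (ENC)
#'
#' Wright's estimator: for each synonymous family with n >= 2 codons
#' observed, the homozygosity F = (n * sum(p_i^2) - 1)/(n - 1); class means
#' over 2-, 3-, 4- and 6-fold families give
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, capped at 61.  Families with
#' F <= 0 (all observed codons distinct) carry no information and are
#' dropped from their class mean.  A missing 3-fold mean (Ile unobserved)
#' is imputed as the average of the 2- and 4-fold means; if any other
#' class mean is missing, ENC is `NA`.
#'
#' @param counts named codon count vector from [codon_counts()].
#' @return ENC in `[20, 61]`, or `NA` when undefined.
#' @export
enc <- function(counts) {
  counts <- counts[codon_tables$sense]
  fam_F <- function(codons) {
    x <- counts[codons]
    n <- sum(x)
    if (n < 2) return(NA_real_)
    p <- x / n
    (n * sum(p^2) - 1) / (n - 1)
  }
  sizes <- codon_tables$family_size
  class_mean <- function(k) {
    fams <- codon_tables$families[sizes == k & names(sizes) != "*"]
    Fs <- vapply(fams, fam_F, 0)
    Fs <- Fs[!is.na(Fs) & Fs > 0]
    if (length(Fs) == 0) NA_real_ else mean(Fs)
  }
  F2 <- class_mean(2); F3 <- class_mean(3); F4 <- class_mean(4); F6 <- class_mean(6)
  if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- (F2 + F4) / 2
  if (anyNA(c(F2, F3, F4, F6))) return(NA_real_)
  min(61, 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6)
}

#' Expected ENC under mutation pressure alone
#'
#' The null curve for the ENC plot: codon usage shaped only by the GC
#' content at third positions, `ENC = 2 + GC3 + 29/(GC3^2 + (1 - GC3)^2)`.
#'
#' @param gc3 third-position GC fraction(s) in `[0, 1]`.
#' @return expected ENC value(s).
#' @export
enc_expected <- function(gc3) {
  stopifnot(all(gc3 >= 0 & gc3 <= 1))
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the mean count of its
#' synonymous family (observed/expected under uniform within-family use).
#' Methionine and tryptophan carry RSCU 1 by definition when observed;
#' unobserved families are reported as missing, not zero.
#'
#' @param counts named codon count vector from [codon_counts()], per gene
#'   or pooled.
#' @return data.frame (codon in RNA letters, amino acid, count, rscu) over
#'   the 61 sense codons; class `rscu_table`.
#' @export
rscu <- function(counts) {
  counts <- counts[codon_tables$sense]
  out <- data.frame(codon = dna_to_rna(codon_tables$sense),
                    aa = unname(codon_tables$aa),
                    count = unname(counts), rscu = NA_real_)
  for (aa in names(codon_tables$families)) {
    codons <- codon_tables$families[[aa]]
    tot <- sum(counts[codons])
    if (tot == 0) next
    idx <- match(codons, codon_tables$sense)
    out$rscu[idx] <- counts[codons] / (tot / length(codons))
  }
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' Neutrality-plot regression (GC12 on GC3)
#'
#' Ordinary least squares of GC12 (mean of first- and second-position GC)
#' on GC3, the classic test of mutation pressure versus selection: a slope
#' near 1 indicates mutation pressure dominating all three positions
#' equally, a flat slope indicates selection constraining positions 1-2.
#'
#' @param stats data.frame from [codon_stats_table()].
#' @return list: slope, intercept, r_squared, p_cor (two-tailed test of
#'   the correlation), p_slope (t test of the regression slope; identical
#'   for simple regression), n_above / n_below the y = x diagonal, and
#'   `points` (GC3, GC12 per gene).
#' @export
neutrality_regression <- function(stats) {
  ok <- stats[!is.na(stats$GC3) & !is.na(stats$GC12), , drop = FALSE]
  if (nrow(ok) < 3) stop("need >= 3 genes for the neutrality regression", call. = FALSE)
  if (var(ok$GC3) == 0) stop("zero variance in GC3: slope undefined", call. = FALSE)
  fit <- lm(GC12 ~ GC3, data = ok)
  flat <- var(ok$GC12) == 0    # constant response: r^2 and tests degenerate
  sm <- if (flat) NULL else summary(fit)
  ct_p <- if (flat) NA_real_ else cor.test(ok$GC3, ok$GC12)$p.value
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (flat) 0 else sm$r.squared,
       p_cor = ct_p,
       p_slope = if (flat) NA_real_ else sm$coefficients[2, 4],
       n_above = sum(ok$GC12 > ok$GC3), n_below = sum(ok$GC12 < ok$GC3),
       points = ok[, c("gene", "GC3", "GC12")])
}

#' PR2 (parity rule 2) plot coordinates
#'
#' Per gene, `x = G3/(G3 + C3)` and `y = A3/(A3 + T3)` over third
#' positions of synonymously variable codons; (0.5, 0.5) is the no-bias
#' point where complementary bases are used equally.
#'
#' @param stats data.frame from [codon_stats_table()].
#' @return list with `points` (gene, x, y; `NA` where a denominator is
#'   zero) and `quadrants` (counts relative to (0.5, 0.5); ties fall in
#'   `on_boundary`).
#' @export
pr2_coordinates <- function(stats) {
  x <- ifelse(stats$G3 + stats$C3 > 0, stats$G3 / (stats$G3 + stats$C3), NA_real_)
  y <- ifelse(stats$A3 + stats$T3 > 0, stats$A3 / (stats$A3 + stats$T3), NA_real_)
  pts <- data.frame(gene = stats$gene, x = x, y = y)
  ok <- !is.na(x) & !is.na(y)
  quadrants <- c(
    G3_high_A3_low = sum(ok & x > 0.5 & y < 0.5),
    G3_high_A3_high = sum(ok & x > 0.5 & y > 0.5),
    G3_low_A3_low = sum(ok & x < 0.5 & y < 0.5),
    G3_low_A3_high = sum(ok & x < 0.5 & y > 0.5),
    on_boundary = sum(ok & (x == 0.5 | y == 0.5)))
  list(points = pts, quadrants = quadrants)
}

#' Pairwise Pearson correlations of codon parameters
#'
#' @param stats data.frame from [codon_stats_table()].
#' @param vars variables to correlate (default GC1, GC2, GC3, GC3s, GCall,
#'   ENC, length).
#' @return list with symmetric matrices `r` and `p` (two-tailed) and a
#'   `stars` matrix (`*` p<0.05, `**` p<0.01, `***` p<0.001).
#' @export
correlation_matrix <- function(stats,
                               vars = c("GC1", "GC2", "GC3", "GC3s",
                                        "GCall", "ENC", "length_nt")) {
  m <- as.matrix(stats[, vars])
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    ok <- complete.cases(m[, c(i, j)])
    if (sum(ok) >= 3 && var(m[ok, i]) > 0 && var(m[ok, j]) > 0) {
      ct <- cor.test(m[ok, i], m[ok, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = list(vars, vars))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  diag(stars) <- ""
  list(r = r, p = p, stars = stars)
}

#' Identify optimal codons from ENC-ranked gene pools
#'
#' Genes are sorted by ascending ENC (most biased first; ties broken by
#' gene name).  The first `ceiling(0.1 n)` genes form the high-expression
#' pool and the last `ceiling(0.1 n)` the low-expression pool.  RSCU is
#' computed on the pooled codon counts of each pool and of all genes;
#' `dRSCU = RSCU_high - RSCU_low`.  A codon is high-frequency when its
#' all-gene RSCU exceeds 1, high-expression when `dRSCU >= delta_threshold`,
#' and optimal when both hold.
#'
#' @param cds_list list of unflagged `cds_record`s (>= 10 genes).
#' @param delta_threshold dRSCU cutoff (default 0.08).
#' @return list: `high_pool`, `low_pool` (gene names), `table` (codon, aa,
#'   rscu_all, rscu_high, rscu_low, delta, high_frequency,
#'   high_expression, optimal), `optimal` (RNA codon strings).
#' @export
optimal_codons <- function(cds_list, delta_threshold = 0.08) {
  n <- length(cds_list)
  names_ <- vapply(cds_list, `[[`, "", "gene_name")
  encs <- vapply(cds_list, function(r) enc(codon_counts(analysis_codons(r))), 0)
  ord <- order(encs, names_)
  m <- ceiling(0.1 * n)
  if (2 * m > n) stop("too few genes: ENC deciles overlap", call. = FALSE)
  hi_idx <- ord[seq_len(m)]
  lo_idx <- ord[seq.int(n - m + 1L, n)]
  pool_counts <- function(idx)
    codon_counts(lapply(cds_list[idx], analysis_codons))
  r_all <- rscu(pool_counts(seq_len(n)))
  r_hi <- rscu(pool_counts(hi_idx))
  r_lo <- rscu(pool_counts(lo_idx))
  tab <- data.frame(codon = r_all$codon, aa = r_all$aa,
                    rscu_all = r_all$rscu, rscu_high = r_hi$rscu,
                    rscu_low = r_lo$rscu,
                    delta = r_hi$rscu - r_lo$rscu)
  tab$high_frequency <- !is.na(tab$rscu_all) & tab$rscu_all > 1
  tab$high_expression <- !is.na(tab$delta) & tab$delta >= delta_threshold
  tab$optimal <- tab$high_frequency & tab$high_expression
  list(high_pool = names_[hi_idx], low_pool = names_[lo_idx],
       table = tab, optimal = tab$codon[tab$optimal])
}
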