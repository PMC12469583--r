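# Seeded synthetic plastomes with a ground-truth manifest: quadripartite
# layout with exact-copy IRs, region-specific GC, planted SSRs of all six
# motif classes, planted F/P/R/C dispersed repeats with engineered
# maximality (blocking mismatches at both flanks), planted genes
# (including IR-duplicated and intron-split ones) and junction-straddling
# features.  Everything is deterministic under the spec's seed.

#' Specification for a synthetic plastome
#'
#' Defaults mirror a moss plastome: 124,264 bp total (LSC 85,572, SSC
#' 18,608, IRs 10,042 each), AT-rich single-copy regions (GC 0.26 / 0.251)
#' and GC-rich IRs (0.433), for an overall GC near 28.7%.
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bp.
#' @param lsc_gc,ssc_gc,ir_gc background GC fractions per region.
#' @param planted_ssrs data.frame (motif, unit_count, region) or `NULL`
#'   for a default set covering all six motif classes.
#' @param planted_repeats data.frame (type, length, mismatches, region1,
#'   region2) or `NULL` for a default F/P/R/C set.
#' @param genes data.frame (name, kind, n_codons, strand, region,
#'   introns, ir_duplicated) or `NULL` for a default gene set.
#' @param junction_genes data.frame (name, junction, overlap): features
#'   planted at a junction; `overlap > 0` crosses by that many bp,
#'   `overlap <= 0` leaves a gap of `-overlap` bp.  `NULL` for a default.
#' @param at_bias_3 third-position A/T bias of planted CDSs (see
#'   [cub_profile()]).
#' @param seed integer RNG seed.
#' @return a `plastome_spec` list.
#' @export
plastome_spec <- function(lsc_len = 85572, ssc_len = 18608, ir_len = 10042,
                          lsc_gc = 0.260, ssc_gc = 0.251, ir_gc = 0.433,
                          planted_ssrs = NULL, planted_repeats = NULL,
                          genes = NULL, junction_genes = NULL,
                          at_bias_3 = 0.85, seed = 1L) {
  if (is.null(planted_ssrs)) {
    planted_ssrs <- data.frame(
      motif = c("T", "A", "AT", "TA", "AAT", "TTTA", "AATAT", "AATTAT"),
      unit_count = c(12L, 10L, 7L, 6L, 5L, 4L, 3L, 3L),
      region = c("LSC", "LSC", "LSC", "SSC", "LSC", "SSC", "LSC", "LSC"))
  }
  if (is.null(planted_repeats)) {
    planted_repeats <- data.frame(
      type = c("F", "P", "R", "C", "F", "P"),
      length = c(40L, 45L, 38L, 36L, 55L, 34L),
      mismatches = c(0L, 0L, 0L, 0L, 3L, 3L),
      region1 = c("LSC", "LSC", "LSC", "SSC", "LSC", "SSC"),
      region2 = c("LSC", "SSC", "LSC", "SSC", "LSC", "SSC"))
  }
  if (is.null(genes)) {
    genes <- data.frame(
      name = c("psbA", "rbcL", "matK", "atpB", "ndhF", "rpoC2", "ycf1",
               "rpl2", "rrn16", "trnH-GUG", "trnL-UAA", "clpP"),
      kind = c(rep("CDS", 8), "rRNA", "tRNA", "tRNA", "CDS"),
      n_codons = c(354L, 476L, 510L, 498L, 740L, 1360L, 680L, 274L,
                   NA, NA, NA, 196L),
      strand = c("+", "+", "-", "-", "-", "+", "+", "+", "+", "-", "+", "+"),
      region = c("LSC", "LSC", "LSC", "LSC", "SSC", "LSC", "SSC",
                 "IRa", "IRa", "LSC", "LSC", "LSC"),
      introns = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 1L, 2L),
      stringsAsFactors = FALSE)
  }
  if (is.null(junction_genes)) {
    junction_genes <- data.frame(
      name = c("ndhF-j", "trnN-j", "chlL-j"),
      junction = c("JSB", "JLB", "JSA"),
      overlap = c(76L, -150L, 0L))
  }
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len),
                 lsc_gc = lsc_gc, ssc_gc = ssc_gc, ir_gc = ir_gc,
                 planted_ssrs = planted_ssrs, planted_repeats = planted_repeats,
                 genes = genes, junction_genes = junction_genes,
                 at_bias_3 = at_bias_3, seed = as.integer(seed)),
            class = "plastome_spec")
}

#' Codon-usage profile for synthetic CDS generation
#'
#' Per synonymous family, a probability vector over its codons.  With
#' `at_bias_3`, codons ending in A or T get weight `at_bias_3` and codons
#' ending in G or C weight `1 - at_bias_3`, normalized within each family.
#' With `preferred`, each listed codon gets probability `strength` within
#' its family and the rest share the remainder.
#'
#' @param at_bias_3 scalar in `[0, 1]` tilting third-position A/T.
#' @param preferred optional character vector of codons (DNA or RNA
#'   letters) to favor.
#' @param strength within-family probability of a preferred codon.
#' @return named list: per amino acid, a named probability vector.
#' @export
cub_profile <- function(at_bias_3 = 0.5, preferred = NULL, strength = 0.9) {
  preferred <- toupper(chartr("U", "T", preferred %||% character()))
  prof <- lapply(codon_tables$families, function(codons) {
    k <- length(codons)
    if (k == 1) return(setNames(1, codons))
    w <- ifelse(substr(codons, 3, 3) %in% c("A", "T"), at_bias_3, 1 - at_bias_3)
    if (all(w == 0)) w <- rep(1, k)
    pref <- codons %in% preferred
    if (any(pref)) {
      w <- rep((1 - strength * sum(pref)) / sum(!pref), k)
      w[pref] <- strength
    }
    setNames(w / sum(w), codons)
  })
  structure(prof, class = "cub_profile")
}

#' Generate a synthetic CDS gene set
#'
#' Genes are sampled codon by codon from a [cub_profile()]; each gets an
#' ATG start and a uniformly sampled standard stop, so every record passes
#' the analysis filter by construction (codon counts vary around
#' `mean_codons`, never below 101 codons so length always exceeds 300 nt).
#'
#' @param n_genes number of genes (>= 10).
#' @param mean_codons mean number of sense codons per gene.
#' @param profile a [cub_profile()].
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @param prefix gene-name prefix.
#' @return list of `cds_record`s with empty filter flags.
#' @export
generate_cds_set <- function(n_genes, mean_codons = 300, profile = cub_profile(),
                             seed = NULL, prefix = "gene") {
  if (!is.null(seed)) set.seed(seed)
  aas <- names(profile)
  lapply(seq_len(n_genes), function(g) {
    n_cod <- max(101L, stats::rpois(1, mean_codons))
    fam_draw <- sample(aas, n_cod - 1L, replace = TRUE)
    codons <- vapply(fam_draw, function(aa) {
      p <- profile[[aa]]
      if (length(p) == 1) names(p) else sample(names(p), 1, prob = p)
    }, "")
    codons <- c("ATG", unname(codons), sample(STOP_CODONS, 1))
    structure(list(gene_name = sprintf("%s%03d", prefix, g),
                   seq = paste(codons, collapse = ""),
                   codons = codons, length_nt = 3L * length(codons),
                   source_region = NA_character_, filter_flags = character()),
              class = "cds_record")
  })
}

#' Generate a gene alignment with a target nucleotide diversity
#'
#' Rows are mutated independently from a common ancestor: each site of
#' each taxon mutates with probability p to a uniformly chosen different
#' base, where p solves `2p(1-p) + (2/3)p^2 = pairwise_diversity` so the
#' expected pairwise difference rate equals the target.
#'
#' @param n_taxa number of rows (>= 2).
#' @param length alignment columns.
#' @param pairwise_diversity target Pi in `[0, 0.75]`.
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @param gene_name alignment label.
#' @return a [gene_alignment()] (no gaps).
#' @export
generate_alignment <- function(n_taxa, length, pairwise_diversity,
                               seed = NULL, gene_name = "synth") {
  stopifnot(n_taxa >= 2, pairwise_diversity >= 0, pairwise_diversity <= 0.75)
  if (!is.null(seed)) set.seed(seed)
  # 2p(1-p) + (2/3)p^2 = d  =>  (4/3)p^2 - 2p + d = 0
  d <- pairwise_diversity
  p <- if (d == 0) 0 else (2 - sqrt(4 - (16 / 3) * d)) / (8 / 3)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length, replace = TRUE)
  rows <- vapply(seq_len(n_taxa), function(i) {
    x <- anc
    mut <- runif(length) < p
    if (any(mut)) {
      x[mut] <- vapply(x[mut], function(b) sample(setdiff(bases, b), 1), "")
    }
    paste(x, collapse = "")
  }, "")
  gene_alignment(gene_name, taxa = sprintf("taxon%02d", seq_len(n_taxa)),
                 rows = rows)
}

# ---- plastome assembly -------------------------------------------------

#' Generate a synthetic plastome with ground truth
#'
#' Builds the circular genome LSC + IRb + SSC + IRa with IRb the exact
#' reverse complement of IRa, per-region background GC, and all planted
#' elements at recorded coordinates.  Planted SSRs get flanking bases that
#' break the tandem period so detected runs match the plant exactly;
#' planted dispersed repeats get one blocking mismatch immediately outside
#' each end so the planted window is itself maximal; the IR boundaries are
#' likewise blocked so inverted-repeat detection recovers the planted
#' layout exactly.
#'
#' @param spec a [plastome_spec()].
#' @return list with `genome` (a [genome_record()]) and `manifest`
#'   (layout, ssrs, repeats, genes, junction_genes data.frames with
#'   absolute 1-based coordinates).
#' @export
generate_plastome <- function(spec = plastome_spec()) {
  set.seed(spec$seed)
  n <- spec$lsc_len + 2L * spec$ir_len + spec$ssc_len
  # region character buffers (IRa generated; IRb derived)
  reg <- list(
    LSC = strsplit(random_dna(spec$lsc_len, spec$lsc_gc), "")[[1]],
    SSC = strsplit(random_dna(spec$ssc_len, spec$ssc_gc), "")[[1]],
    IRa = strsplit(random_dna(spec$ir_len, spec$ir_gc), "")[[1]])
  cursor <- c(LSC = 200L, SSC = 200L, IRa = 200L)
  gap <- function() sample(80:240, 1)

  alloc <- function(region, len) {
    start <- cursor[[region]]
    end <- start + len - 1L
    if (end + 200L > length(reg[[region]]))
      stop(sprintf("planted elements overflow region %s", region), call. = FALSE)
    cursor[[region]] <<- end + gap()
    c(start, end)
  }
  put <- function(region, start, chars) {
    reg[[region]][seq(start, start + length(chars) - 1L)] <<- chars
  }

  # --- SSRs ---
  ssr_rows <- list()
  for (i in seq_len(nrow(spec$planted_ssrs))) {
    motif <- spec$planted_ssrs$motif[i]
    u <- spec$planted_ssrs$unit_count[i]
    region <- spec$planted_ssrs$region[i]
    p <- nchar(motif)
    run <- strsplit(strrep(motif, u), "")[[1]]
    pos <- alloc(region, length(run) + 2L)  # room for breaking flanks
    put(region, pos[1] + 1L, run)
    mchars <- strsplit(motif, "")[[1]]
    # a run of period p extends left iff s[start-1] == s[start-1+p] and
    # right iff s[end+1] == s[end+1-p]; pick flanks that break both
    put(region, pos[1], setdiff(c("A", "C", "G", "T"), mchars[p])[1])
    put(region, pos[1] + 1L + length(run),
        setdiff(c("A", "C", "G", "T"), mchars[1])[1])
    ssr_rows[[i]] <- data.frame(motif = motif, motif_length = p,
                                unit_count = u, region = region,
                                rel_start = pos[1] + 1L)
  }

  # --- dispersed repeats (planted in LSC/SSC only) ---
  rep_rows <- list()
  for (i in seq_len(nrow(spec$planted_repeats))) {
    ty <- spec$planted_repeats$type[i]
    L <- spec$planted_repeats$length[i]
    mm <- spec$planted_repeats$mismatches[i]
    r1 <- spec$planted_repeats$region1[i]
    r2 <- spec$planted_repeats$region2[i]
    core <- strsplit(random_dna(L, 0.5), "")[[1]]
    copy2 <- switch(ty,
      F = core,
      P = strsplit(revcomp(paste(core, collapse = "")), "")[[1]],
      R = rev(core),
      C = strsplit(dna_complement(paste(core, collapse = "")), "")[[1]])
    if (mm > 0) {
      at <- sample(seq.int(4L, L - 3L), mm)   # keep mismatches interior
      for (a in at) copy2[a] <- sample(setdiff(c("A", "C", "G", "T"), copy2[a]), 1)
    }
    p1 <- alloc(r1, L + 2L)
    p2 <- alloc(r2, L + 2L)
    put(r1, p1[1] + 1L, core)
    put(r2, p2[1] + 1L, copy2)
    rep_rows[[i]] <- data.frame(type = ty, region1 = r1, region2 = r2,
                                rel1 = p1[1] + 1L, rel2 = p2[1] + 1L,
                                length = L, mismatches = mm)
  }

  # --- genes ---
  gene_rows <- list()
  for (i in seq_len(nrow(spec$genes))) {
    gs <- spec$genes[i, ]
    if (gs$kind == "CDS") {
      rec <- generate_cds_set(1, mean_codons = gs$n_codons,
                              profile = cub_profile(at_bias_3 = spec$at_bias_3),
                              prefix = gs$name)[[1]]
      body <- rec$seq
    } else {
      body <- random_dna(if (gs$kind == "rRNA") 1490L else 72L,
                         if (gs$kind == "rRNA") 0.5 else 0.52)
    }
    if (gs$strand == "-") body <- revcomp(body)
    n_int <- gs$introns
    if (n_int > 0) {
      # split into n_int + 1 exons separated by random intron spacers
      blen <- nchar(body)
      cuts <- sort(sample(seq.int(30L, blen - 30L), n_int))
      exons <- substring(body, c(1L, cuts + 1L), c(cuts, blen))
      ilens <- sample(120:400, n_int, replace = TRUE)
      total <- blen + sum(ilens)
      pos <- alloc(gs$region, total)
      at <- pos[1]
      ivs <- matrix(0L, nrow = n_int + 1L, ncol = 2)
      for (e in seq_along(exons)) {
        put(gs$region, at, strsplit(exons[e], "")[[1]])
        ivs[e, ] <- c(at, at + nchar(exons[e]) - 1L)
        at <- at + nchar(exons[e]) + if (e <= n_int) ilens[e] else 0L
        if (e <= n_int) put(gs$region, ivs[e, 2] + 1L,
                            strsplit(random_dna(ilens[e], 0.3), "")[[1]])
      }
    } else {
      pos <- alloc(gs$region, nchar(body))
      put(gs$region, pos[1], strsplit(body, "")[[1]])
      ivs <- matrix(pos, nrow = 1)
    }
    gene_rows[[i]] <- list(name = gs$name, kind = gs$kind, strand = gs$strand,
                           region = gs$region, rel_intervals = ivs)
  }

  # --- assemble: LSC, IRb = revcomp(IRa), SSC, IRa ---
  irb <- strsplit(revcomp(paste(reg$IRa, collapse = "")), "")[[1]]
  offs <- c(LSC = 0L, IRb = spec$lsc_len,
            SSC = spec$lsc_len + spec$ir_len,
            IRa = spec$lsc_len + spec$ir_len + spec$ssc_len)
  chars <- c(reg$LSC, irb, reg$SSC, reg$IRa)

  # block IR extension at all four boundaries so detection is exact:
  # outward: LSC's last base vs the base after IRa (circularly, LSC's first);
  # inward: SSC's first base vs SSC's last base.
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  fix_pair <- function(i1, i2) {
    # ensure chars[i1] != comp(chars[i2]) by changing chars[i1]
    if (chars[i1] == comp1(chars[i2]))
      chars[i1] <<- setdiff(c("A", "C", "G", "T"),
                            c(comp1(chars[i2]), chars[i1]))[1]
  }
  fix_pair(offs[["IRb"]], 1L)                                  # JLB vs after-JLA
  fix_pair(offs[["SSC"]] + 1L, offs[["SSC"]] + spec$ssc_len)   # JSB vs before-JSA

  # block extension of planted dispersed repeats (one mismatching flank
  # position outside each end, under the pair's own transform)
  reps <- if (length(rep_rows)) do.call(rbind, rep_rows) else NULL
  if (!is.null(reps)) {
    reps$pos1 <- abs_of_v(offs, reps$region1, reps$rel1)
    reps$pos2 <- abs_of_v(offs, reps$region2, reps$rel2)
    for (i in seq_len(nrow(reps))) {
      a1 <- reps$pos1[i]; b1 <- a1 + reps$length[i] - 1L
      a2 <- reps$pos2[i]; b2 <- a2 + reps$length[i] - 1L
      ty <- reps$type[i]
      block <- function(iA, iB, complemented) {
        # force a mismatch between chars[iA] and (transform of chars[iB])
        img <- if (complemented) comp1(chars[iB]) else chars[iB]
        if (chars[iA] == img)
          chars[iA] <<- setdiff(c("A", "C", "G", "T"), c(img, chars[iA]))[1]
      }
      switch(ty,
        F = { block(a1 - 1L, a2 - 1L, FALSE); block(b1 + 1L, b2 + 1L, FALSE) },
        P = { block(a1 - 1L, b2 + 1L, TRUE);  block(b1 + 1L, a2 - 1L, TRUE) },
        R = { block(a1 - 1L, b2 + 1L, FALSE); block(b1 + 1L, a2 - 1L, FALSE) },
        C = { block(a1 - 1L, a2 - 1L, TRUE);  block(b1 + 1L, b2 + 1L, TRUE) })
    }
  }

  # --- features (IRa-planted genes get a mirrored IRb copy) ---
  f_gene <- f_kind <- f_strand <- f_notes <- character()
  f_iv <- list()
  add_feature <- function(name, kind, strand, iv, note = "") {
    f_gene <<- c(f_gene, name); f_kind <<- c(f_kind, kind)
    f_strand <<- c(f_strand, strand); f_notes <<- c(f_notes, note)
    f_iv <<- c(f_iv, list(iv))
  }
  manifest_genes <- list()
  for (gr in gene_rows) {
    iv_abs <- gr$rel_intervals + offs[[gr$region]]
    add_feature(gr$name, gr$kind, gr$strand, iv_abs)
    manifest_genes[[length(manifest_genes) + 1L]] <-
      data.frame(name = gr$name, kind = gr$kind, strand = gr$strand,
                 region = gr$region, start = min(iv_abs), end = max(iv_abs),
                 n_intervals = nrow(iv_abs))
    if (gr$region == "IRa") {
      # mirrored copy inside IRb: IRb[t] pairs with IRa[ir_len - t + 1]
      rel <- gr$rel_intervals
      mir <- cbind(spec$ir_len - rel[, 2] + 1L, spec$ir_len - rel[, 1] + 1L)
      mir <- mir[rev(seq_len(nrow(mir))), , drop = FALSE] + offs[["IRb"]]
      mstrand <- if (gr$strand == "+") "-" else "+"
      add_feature(gr$name, gr$kind, mstrand, mir, note = "IR duplicate")
      manifest_genes[[length(manifest_genes) + 1L]] <-
        data.frame(name = gr$name, kind = gr$kind, strand = mstrand,
                   region = "IRb", start = min(mir), end = max(mir),
                   n_intervals = nrow(mir))
    }
  }

  # --- junction-straddling features ---
  jpos <- c(JLB = spec$lsc_len, JSB = spec$lsc_len + spec$ir_len,
            JSA = spec$lsc_len + spec$ir_len + spec$ssc_len, JLA = n)
  jg <- spec$junction_genes
  for (i in seq_len(nrow(jg))) {
    b <- jpos[[jg$junction[i]]]
    ov <- jg$overlap[i]
    # overlap > 0: 150 bp before the boundary plus `ov` bp across it;
    # overlap <= 0: 150 bp ending `-ov` bp short of the boundary.
    if (ov > 0L) { s0 <- b - 149L; e0 <- b + ov }
    else { s0 <- b + ov - 149L; e0 <- b + ov }
    add_feature(jg$name[i], "CDS", "+", matrix(c(s0, e0), nrow = 1),
                note = "junction marker")
  }

  sequence <- paste(chars, collapse = "")
  genome <- genome_record(id = sprintf("SYNTH%06d", spec$seed),
                          sequence = sequence, circular = TRUE,
                          features = feature_table(f_gene, f_kind, f_strand,
                                                   f_iv, f_notes))

  ssrs <- if (length(ssr_rows)) do.call(rbind, ssr_rows) else NULL
  if (!is.null(ssrs)) {
    ssrs$start <- abs_of_v(offs, ssrs$region, ssrs$rel_start)
    ssrs$end <- ssrs$start + ssrs$motif_length * ssrs$unit_count - 1L
    ssrs$rel_start <- NULL
  }
  if (!is.null(reps)) {
    reps$pos1a <- pmin(reps$pos1, reps$pos2)
    reps$pos2a <- pmax(reps$pos1, reps$pos2)
    reps$pos1 <- reps$pos1a; reps$pos2 <- reps$pos2a
    reps <- reps[, c("type", "pos1", "pos2", "length", "mismatches")]
  }
  layout_df <- data.frame(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(1L, offs[["IRb"]] + 1L, offs[["SSC"]] + 1L, offs[["IRa"]] + 1L),
    end = c(offs[["IRb"]], offs[["SSC"]], offs[["IRa"]], n),
    length = c(spec$lsc_len, spec$ir_len, spec$ssc_len, spec$ir_len))
  jg$expected_distance <- -jg$overlap
  list(genome = genome,
       manifest = list(layout = layout_df, junctions = jpos,
                       ssrs = ssrs, repeats = reps,
                       genes = do.call(rbind, manifest_genes),
                       junction_genes = jg,
                       seed = spec$seed))
}

# vectorized region-offset lookup
abs_of_v <- function(offs, region, rel) unname(offs[region]) + as.integer(rel)

#' Generate a pair of near-identical synthetic plastomes
#'
#' Emulates two sequenced specimens of the same species: the second genome
#' is generated from the same specification with slightly perturbed
#' single-copy lengths and its own RNG stream.
#'
#' @param spec a [plastome_spec()] for the first specimen.
#' @param lsc_delta,ssc_delta,ir_delta length perturbations (bp) for the
#'   second specimen.
#' @return list of two `generate_plastome()` results.
#' @export
generate_specimen_pair <- function(spec = plastome_spec(),
                                   lsc_delta = 159L, ssc_delta = 1L,
                                   ir_delta = 8L) {
  first <- generate_plastome(spec)
  spec2 <- spec
  spec2$lsc_len <- spec$lsc_len + as.integer(lsc_delta)
  spec2$ssc_len <- spec$ssc_len + as.integer(ssc_delta)
  spec2$ir_len <- spec$ir_len + as.integer(ir_delta)
  spec2$seed <- spec$seed + 1L
  second <- generate_plastome(spec2)
  list(first, second)
}
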