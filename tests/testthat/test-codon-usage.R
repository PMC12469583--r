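test_that("codon composition matches hand counts", {
  st <- codon_composition(c("ATG", "GCT", "GCA", "TAA"), gene_name = "demo")
  expect_equal(st$GC3, 0)                 # thirds of GCT, GCA are T, A
  expect_equal(st$GC1, 2 / 3)             # firsts A, G, G
  expect_equal(st$n_codons, 3L)           # stop dropped
  expect_equal(st$A3 + st$T3 + st$G3 + st$C3, 1)
  expect_equal(st$GC12, (st$GC1 + st$GC2) / 2)
  # only nondegenerate codons: GC3s and PR2 inputs undefined
  st2 <- codon_composition(c("ATG", "TGG", "TAA"))
  expect_true(is.na(st2$GC3s))
  expect_error(codon_composition(character()), "no analyzable codons")
})

test_that("ENC reaches its theoretical limits", {
  # extreme bias: one codon per amino acid, many observations -> 20
  counts <- codon_counts(rep(one_per_family(), 200))
  expect_equal(enc(counts), 20)
  # uniform synonymous usage, large n -> 61 (capped)
  uniform <- codon_counts(rep(plastchar:::codon_tables$sense, 1000))
  expect_equal(enc(uniform), 61)
})

test_that("ENC equals an independent homozygosity computation", {
  set.seed(30)
  genes <- generate_cds_set(20, mean_codons = 500,
                            profile = cub_profile(at_bias_3 = 0.8))
  for (g in genes[1:10]) {
    counts <- codon_counts(plastchar:::analysis_codons(g))
    expect_equal(enc(counts), enc_oracle(counts), tolerance = 1e-9)
  }
})

test_that("ENC never increases when usage concentrates within families", {
  set.seed(31)
  for (i in 1:5) {
    g <- generate_cds_set(1, mean_codons = 400,
                          profile = cub_profile(at_bias_3 = 0.55))[[1]]
    counts <- codon_counts(plastchar:::analysis_codons(g))
    before <- enc(counts)
    # concentrate: move every family's counts onto its largest codon
    conc <- counts
    for (codons in plastchar:::codon_tables$families) {
      tot <- sum(conc[codons])
      conc[codons] <- 0L
      conc[codons[which.max(counts[codons])]] <- tot
    }
    expect_lte(enc(conc), before)
  }
})

test_that("the expected-ENC curve evaluates the printed formula exactly", {
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(1), 32)
  expect_error(enc_expected(1.2))
})

test_that("expected ENC tracks simulated mutation-pressure-only genes", {
  set.seed(32)
  for (gc3 in c(0.2, 0.5, 0.8)) {
    # codons sampled with third-position GC = gc3 and no selection:
    # within each family, weight by the third base only
    prof <- lapply(plastchar:::codon_tables$families, function(codons) {
      w <- ifelse(substr(codons, 3, 3) %in% c("G", "C"),
                  gc3, 1 - gc3)
      setNames(w / sum(w), codons)
    })
    class(prof) <- "cub_profile"
    genes <- generate_cds_set(10, mean_codons = 3000, profile = prof)
    stats <- codon_stats_table(genes)
    expect_equal(mean(stats$ENC), mean(enc_expected(stats$GC3s)),
                 tolerance = 0.03)
  }
})

test_that("RSCU follows its definition and normalization", {
  # uniform usage within every family -> all RSCU 1
  r <- rscu(codon_counts(rep(plastchar:::codon_tables$sense, 3)))
  expect_true(all(r$rscu == 1))
  # Phe {TTT: 3, TTC: 1} -> 1.5 / 0.5
  r2 <- rscu(codon_counts(c(rep("TTT", 3), "TTC")))
  expect_equal(r2$rscu[r2$codon == "UUU"], 1.5)
  expect_equal(r2$rscu[r2$codon == "UUC"], 0.5)
  # unobserved families are missing, not zero
  expect_true(all(is.na(r2$rscu[r2$aa == "A"])))
  # family means equal 1 for every observed family (random genes)
  set.seed(33)
  g <- generate_cds_set(1, mean_codons = 600)[[1]]
  r3 <- rscu(codon_counts(plastchar:::analysis_codons(g)))
  means <- tapply(r3$rscu, r3$aa, mean)
  expect_true(all(abs(means[!is.na(means)] - 1) < 1e-12))
})

test_that("neutrality regression handles exact and degenerate layouts", {
  mk <- function(gc3, gc12) data.frame(gene = paste0("g", seq_along(gc3)),
                                       GC3 = gc3, GC12 = gc12)
  on_diag <- mk(c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.2, 0.3, 0.4))
  # lm flags the deliberately exact fit; the values are what matter here
  fit <- suppressWarnings(neutrality_regression(on_diag))
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)
  flat <- neutrality_regression(mk(c(0.1, 0.2, 0.3), c(0.2, 0.2, 0.2)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(neutrality_regression(mk(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.3))),
               "zero variance")
})

test_that("PR2 coordinates flag bias direction and degenerate genes", {
  st <- data.frame(gene = c("even", "allT"),
                   A3 = c(0.25, 0), T3 = c(0.25, 1),
                   G3 = c(0.25, 0), C3 = c(0.25, 0))
  pr <- pr2_coordinates(st)
  expect_equal(pr$points$x[1], 0.5)
  expect_equal(pr$points$y[1], 0.5)
  expect_true(is.na(pr$points$x[2]))      # G3 + C3 == 0
  expect_equal(pr$points$y[2], 0)
  expect_equal(unname(pr$quadrants["on_boundary"]), 1L)
})

test_that("AT-biased genes fall in the A/T-rich PR2 quadrant", {
  set.seed(34)
  genes <- generate_cds_set(30, mean_codons = 300,
                            profile = cub_profile(at_bias_3 = 0.9))
  st <- codon_stats_table(genes)
  pr <- pr2_coordinates(st)
  ok <- !is.na(pr$points$x) & !is.na(pr$points$y)
  expect_true(mean(pr$points$y[ok] < 0.75) > 0.9)  # x/y near their A/T split
  expect_true(all(st$GC3s < 0.3))
})

test_that("correlation matrix is symmetric with unit diagonal", {
  set.seed(35)
  genes <- generate_cds_set(25, mean_codons = 300,
                            profile = cub_profile(at_bias_3 = 0.75))
  cm <- correlation_matrix(codon_stats_table(genes))
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 7))
  # proportional columns correlate exactly
  st <- codon_stats_table(genes)
  st$GCall <- 2 * st$GC1
  cm2 <- correlation_matrix(st, vars = c("GC1", "GCall"))
  expect_equal(cm2$r["GC1", "GCall"], 1)
})

test_that("optimal codons require both high frequency and pool enrichment", {
  # literally identical genes: both pools share one usage, dRSCU == 0
  proto <- generate_cds_set(1, mean_codons = 400, seed = 37)[[1]]
  same <- lapply(1:20, function(i) {
    g <- proto
    g$gene_name <- sprintf("g%02d", i)
    g
  })
  rep_same <- optimal_codons(same)
  expect_equal(length(rep_same$high_pool), 2L)   # ceiling(0.1 * 20)
  expect_equal(length(rep_same$low_pool), 2L)
  expect_length(intersect(rep_same$high_pool, rep_same$low_pool), 0)
  expect_true(all(rep_same$table$delta[!is.na(rep_same$table$delta)] == 0))
  expect_length(rep_same$optimal, 0)
  expect_error(optimal_codons(same[1]), "too few genes")
})

test_that("planted pool enrichment is recovered exactly", {
  set.seed(38)
  preferred <- one_per_family()
  multi <- preferred[vapply(plastchar:::codon_tables$families, length, 0L) > 1]
  biased <- generate_cds_set(20, mean_codons = 300,
                             profile = cub_profile(preferred = preferred,
                                                   strength = 0.9),
                             prefix = "hi")
  neutral <- generate_cds_set(20, mean_codons = 300,
                              profile = cub_profile(at_bias_3 = 0.5),
                              prefix = "lo")
  rep_ <- optimal_codons(c(biased, neutral))
  expect_true(all(grepl("^hi", rep_$high_pool)))
  expect_true(all(grepl("^lo", rep_$low_pool)))
  expect_setequal(rep_$optimal,
                  plastchar:::dna_to_rna(unname(multi)))
})

test_that("high-frequency codons on AT-biased genes end in A or U", {
  set.seed(39)
  genes <- generate_cds_set(30, mean_codons = 400,
                            profile = cub_profile(at_bias_3 = 0.9))
  pooled <- rscu(codon_counts(lapply(genes, plastchar:::analysis_codons)))
  hf <- pooled$codon[!is.na(pooled$rscu) & pooled$rscu > 1]
  expect_gt(length(hf), 15)
  expect_true(all(substr(hf, 3, 3) %in% c("A", "U")))
})
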