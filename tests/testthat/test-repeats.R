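# SSR mining ------------------------------------------------------------

test_that("SSR thresholds and primitive periods behave as specified", {
  set.seed(7)
  flank <- function() rand_seq(60, gc = 0.6)
  # 12 T's: one mononucleotide SSR
  s <- paste0("CG", strrep("T", 12), "CG", flank())
  hit <- find_ssrs(s)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "T")
  expect_equal(hit$unit_count, 12L)
  expect_equal(hit$end - hit$start + 1L, 12L)
  # 9 A's: below the >=10 mononucleotide threshold
  expect_equal(nrow(find_ssrs(paste0("CG", strrep("A", 9), "CG", flank()))), 0L)
  # (AT)6 is one dinucleotide SSR, not mono runs or a non-primitive tetramer
  hit2 <- find_ssrs(paste0("GC", strrep("AT", 6), "GC", flank()))
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$motif, "AT")
  expect_equal(hit2$unit_count, 6L)
})

test_that("every reported SSR re-validates against the raw sequence", {
  set.seed(8)
  for (rep_i in 1:5) {
    s <- rand_seq(4000, gc = 0.25)   # AT-rich: plenty of chance runs
    hits <- find_ssrs(s)
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      expect_equal(substr(s, h$start, h$end),
                   strrep(h$motif, h$unit_count))
      expect_true(plastchar:::is_primitive(h$motif))
      expect_gte(h$unit_count, MISA_THRESHOLDS[h$motif_length])
      # maximality: the run does not extend by a whole unit either side
      before <- substr(s, h$start - h$motif_length, h$start - 1L)
      after <- substr(s, h$end + 1L, h$end + h$motif_length)
      expect_false(identical(before, h$motif) && h$start - h$motif_length >= 1)
    }
  }
})

test_that("SSR class tallies are strand-consistent", {
  set.seed(9)
  for (rep_i in 1:5) {
    s <- rand_seq(3000, gc = 0.3)
    a <- summarize_ssrs(find_ssrs(s))$by_class
    b <- summarize_ssrs(find_ssrs(revcomp(s)))$by_class
    expect_equal(a, b)
  }
})

test_that("motif tallies keep A/T and AT/TA separate", {
  set.seed(10)
  s <- paste0(rand_seq(50, 0.8), strrep("AT", 6), rand_seq(50, 0.8),
              strrep("AT", 7), rand_seq(50, 0.8), strrep("TA", 6),
              rand_seq(50, 0.8))
  sm <- summarize_ssrs(find_ssrs(s))
  expect_equal(sm$by_motif$n[sm$by_motif$motif == "AT"], 2L)
  expect_equal(sm$by_motif$n[sm$by_motif$motif == "TA"], 1L)
  expect_equal(summarize_ssrs(find_ssrs(rand_seq(10, 1)))$total, 0L)
})

# dispersed repeats ------------------------------------------------------

test_that("sequences shorter than the minimum length yield no repeats", {
  expect_equal(nrow(find_dispersed("ACGTACGTACGTACGTACGTACGTACGT")), 0L)
})

test_that("a planted exact duplicate is found as the only F repeat", {
  set.seed(11)
  s <- strsplit(rand_seq(5000, gc = 0.5), "")[[1]]
  core <- strsplit(rand_seq(40, gc = 0.5), "")[[1]]
  s[seq(1001, length.out = 40)] <- core
  s[seq(3001, length.out = 40)] <- core
  s <- paste(s, collapse = "")
  got <- find_dispersed(s, min_len = 30, max_mismatch = 0, types = "F")
  planted <- got[got$pos1 <= 1001 & got$pos2 >= 3001, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(brute_maximal_pairs(s, "F", 30, 0),
               got[, names(got) != "is_ir_pair"],
               ignore_attr = TRUE)
})

test_that("a planted reverse-complement copy is found as a P repeat", {
  set.seed(12)
  s <- strsplit(rand_seq(5000, gc = 0.5), "")[[1]]
  core <- rand_seq(45, gc = 0.5)
  s[seq(501, length.out = 45)] <- strsplit(core, "")[[1]]
  s[seq(4001, length.out = 45)] <- strsplit(revcomp(core), "")[[1]]
  s <- paste(s, collapse = "")
  got <- find_dispersed(s, min_len = 30, max_mismatch = 0, types = "P")
  expect_true(any(got$pos1 <= 501 & got$pos2 >= 3990 & got$length >= 45))
})

test_that("seed-and-extend equals the brute-force oracle on planted instances", {
  set.seed(13)
  for (rep_i in 1:10) {
    s <- plant_repeats_in(rand_seq(2000, gc = runif(1, 0.25, 0.6)))
    for (ty in c("F", "P", "R", "C")) {
      got <- find_dispersed(s, min_len = 30, max_mismatch = 3, types = ty)
      got <- got[order(got$pos1, got$pos2, got$length),
                 c("type", "pos1", "pos2", "length", "mismatches")]
      want <- brute_maximal_pairs(s, ty, 30, 3)
      expect_equal(got, want, ignore_attr = TRUE,
                   info = paste("instance", rep_i, "type", ty))
    }
  }
})

test_that("reported dispersed repeats re-validate their Hamming distance", {
  set.seed(14)
  s <- plant_repeats_in(rand_seq(3000, gc = 0.35))
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  got <- find_dispersed(s, min_len = 30, max_mismatch = 3)
  expect_gt(nrow(got), 0)
  for (i in seq_len(nrow(got))) {
    h <- got[i, ]
    c1 <- x[seq(h$pos1, length.out = h$length)]
    c2 <- x[seq(h$pos2, length.out = h$length)]
    img <- switch(h$type,
                  F = c2,
                  P = strsplit(revcomp(paste(c2, collapse = "")), "")[[1]],
                  R = rev(c2),
                  C = strsplit(dna_complement(paste(c2, collapse = "")), "")[[1]])
    expect_equal(sum(c1 != img), h$mismatches, info = paste("row", i))
  }
})
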