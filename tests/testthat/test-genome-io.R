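test_that("GenBank location grammar resolves join/complement to intervals", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       MINI             12 bp    DNA     circular PLN 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..12",
    "     CDS             complement(join(1..3,7..9))",
    '                     /gene="demo"',
    "ORIGIN",
    "        1 atgaaattta ag",
    "//"), path)
  g <- read_genbank(path)
  expect_equal(genome_length(g), 12L)
  expect_true(g$circular)
  expect_equal(nrow(g$features), 1L)
  expect_equal(g$features$strand, "-")
  expect_equal(g$features$gene, "demo")
  expect_equal(g$features$intervals[[1]],
               matrix(c(1L, 7L, 3L, 9L), ncol = 2,
                      dimnames = list(NULL, c("start", "end"))))
  # spliced on minus strand: revcomp of concatenated intervals
  expect_equal(plastchar:::splice_feature(g, 1), revcomp("ATGTTT"))
})

test_that("malformed records fail with informative errors", {
  p1 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X  10 bp DNA linear", "FEATURES",
               "     CDS             join(1..oops)", "ORIGIN",
               "        1 acgtacgtac", "//"), p1)
  expect_error(read_genbank(p1), "malformed feature location")
  p2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X  10 bp DNA linear", "//"), p2)
  expect_error(read_genbank(p2), "ORIGIN")
})

test_that("ambiguity codes other than N are rejected", {
  expect_error(genome_record("x", "ACGTRYACGT"), "unsupported characters")
  expect_silent(genome_record("x", "ACGTNACGT"))
})

test_that("synthetic GenBank round-trips sequence and features", {
  res <- generate_plastome(plastome_spec(
    lsc_len = 30000, ssc_len = 12000, ir_len = 4000, seed = 11))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(res$genome, path)
  back <- read_genbank(path)
  expect_equal(back$sequence, res$genome$sequence)
  expect_equal(back$circular, res$genome$circular)
  expect_equal(back$features$gene, res$genome$features$gene)
  expect_equal(back$features$kind, res$genome$features$kind)
  expect_equal(back$features$strand, res$genome$features$strand)
  expect_equal(back$features$intervals, res$genome$features$intervals)
})

test_that("CDS filter flags follow the analysis criteria", {
  # 300 nt exactly (100 codons incl stop): too_short under the strict rule
  body300 <- paste(c("ATG", rep("GCT", 98), "TAA"), collapse = "")
  # 303 nt: passes
  body303 <- paste(c("ATG", rep("GCT", 99), "TAA"), collapse = "")
  internal <- paste(c("ATG", rep("GCT", 50), "TGA", rep("GCT", 49), "TAA"),
                    collapse = "")
  seqs <- paste0(body300, body303, internal)
  g <- tiny_genome(seqs,
    gene = c("g300", "g303", "gint"),
    kind = rep("CDS", 3), strand = rep("+", 3),
    intervals = list(matrix(c(1L, 300L), 1),
                     matrix(c(301L, 603L), 1),
                     matrix(c(604L, 909L), 1)))
  cds <- extract_cds(g)
  expect_equal(cds[[1]]$filter_flags, "too_short")
  expect_equal(cds[[2]]$filter_flags, character())
  expect_equal(cds[[3]]$filter_flags, "internal_stop")
})

test_that("IR-duplicated CDSs keep exactly one unflagged copy", {
  body <- paste(c("ATG", rep("GCA", 100), "TAG"), collapse = "")
  g <- tiny_genome(paste0(body, "AC", revcomp(body)),
    gene = c("rpl2", "rpl2"), kind = c("CDS", "CDS"), strand = c("+", "-"),
    intervals = list(matrix(c(1L, 306L), 1), matrix(c(309L, 614L), 1)))
  cds <- extract_cds(g)
  flags <- lapply(cds, `[[`, "filter_flags")
  expect_equal(sum(vapply(flags, function(f) "ir_duplicate" %in% f, TRUE)), 1L)
  expect_equal(sum(vapply(flags, length, 0L) == 0), 1L)
  # idempotence: extracting twice yields identical flags
  expect_identical(lapply(extract_cds(g), `[[`, "filter_flags"), flags)
})

test_that("minus-strand splicing is the reverse complement of plus-strand", {
  set.seed(42)
  s <- rand_seq(200)
  iv <- list(matrix(c(11L, 40L, 30L, 90L), ncol = 2))
  gp <- tiny_genome(s, gene = "f", kind = "CDS", strand = "+", intervals = iv)
  gm <- tiny_genome(s, gene = "f", kind = "CDS", strand = "-", intervals = iv)
  plus <- plastchar:::splice_feature(gp, 1)
  expect_equal(nchar(plus), (30 - 11 + 1) + (90 - 40 + 1))
  expect_equal(plastchar:::splice_feature(gm, 1), revcomp(plus))
})

test_that("gene classification tallies kinds, groups and introns", {
  empty <- tiny_genome("ACGT")
  cls0 <- classify_genes(empty)
  expect_equal(unname(cls0$kind_counts["total"]), 0L)

  res <- generate_plastome(plastome_spec(
    lsc_len = 30000, ssc_len = 12000, ir_len = 4000, seed = 3))
  cls <- suppressMessages(classify_genes(res$genome))
  expect_equal(unname(cls$kind_counts["tRNA"]), 2L)
  expect_equal(unname(cls$kind_counts["rRNA"]),
               sum(res$manifest$genes$kind == "rRNA"))
  # annotated copies count IR duplicates twice, unique names once:
  # rpl2 sits in the IRs, so exactly one extra annotated CDS copy
  expect_equal(cls$kind_counts[["CDS"]], cls$kind_counts_unique[["CDS"]] + 1L)
  expect_setequal(cls$intron_genes, c("rpl2", "trnL-UAA", "clpP"))
})

test_that("alignment reader enforces rectangular input", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "ACGTACGTAC", ">t2", "ACGTACGTAC"), p)
  aln <- read_alignment(p, gene_name = "demo")
  expect_equal(aln$ncol, 10L)
  expect_equal(aln$taxa, c("t1", "t2"))
  writeLines(c(">t1", "ACGTACGTAC", ">t2", "ACGTACGTA"), p)
  expect_error(read_alignment(p), "t2")
})

test_that("shared-gene extraction writes one FASTA per common CDS", {
  set.seed(43)
  body <- function() paste(c("ATG", rep("GGA", 110), "TAA"), collapse = "")
  g1 <- tiny_genome(paste0(body(), rand_seq(50)),
                    gene = c("rbcL"), kind = "CDS", strand = "+",
                    intervals = list(matrix(c(1L, 336L), 1)))
  g2 <- tiny_genome(paste0(rand_seq(20), body()),
                    gene = c("rbcL"), kind = "CDS", strand = "+",
                    intervals = list(matrix(c(21L, 356L), 1)))
  g2$id <- "tiny2"
  dir <- withr::local_tempdir()
  shared <- extract_shared_genes(list(g1, g2), dir)
  expect_equal(shared, "rbcL")
  expect_true(file.exists(file.path(dir, "rbcL.fasta")))
  ss <- Biostrings::readDNAStringSet(file.path(dir, "rbcL.fasta"))
  expect_equal(length(ss), 2L)
  expect_equal(as.character(ss[[1]]), as.character(ss[[2]]))
})
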