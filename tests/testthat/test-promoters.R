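# Upstream-FASTA parsing and genome+GFF3 upstream extraction.

test_that("parse_upstream_fasta applies the header-token contract", {
  fa <- write_fasta_fixture(list(
    "AT1G00010.1 | chr1:3631-4130 FORWARD" = strrep("A", 500),
    "AT1G00020.1" = paste0(strrep("C", 492), "ggatattc")))
  ps <- parse_upstream_fasta(fa)
  expect_s3_class(ps, "promoter_set")
  expect_equal(ps$gene_model_id, c("AT1G00010.1", "AT1G00020.1"))
  # lowercase input is uppercased
  expect_equal(substr(ps$sequence[2], 493, 500), "GGATATTC")
  expect_false(any(ps$truncated))
})

test_that("parse_upstream_fasta handles empty, multi-line and CRLF input", {
  empty <- tempfile(fileext = ".fa"); file.create(empty)
  expect_equal(nrow(parse_upstream_fasta(empty)), 0L)

  fa <- write_fasta_fixture(list("G1.1" = strrep("ACGT", 125)),
                            wrap = 60, eol = "\r\n")
  ps <- parse_upstream_fasta(fa)
  expect_equal(nchar(ps$sequence), 500L)
  expect_equal(ps$sequence, strrep("ACGT", 125))
})

test_that("parse_upstream_fasta enforces window and uniqueness", {
  short <- write_fasta_fixture(list("G1.1" = strrep("A", 300)))
  ps <- parse_upstream_fasta(short, window = 500)
  expect_true(ps$truncated)

  long <- write_fasta_fixture(list("G1.1" = strrep("A", 501)))
  expect_error(parse_upstream_fasta(long, window = 500), "G1.1")

  dup <- write_fasta_fixture(list("G1.1 a" = strrep("A", 10),
                                  "G1.1 b" = strrep("C", 10)))
  expect_error(parse_upstream_fasta(dup, window = 10), "duplicate.*G1.1")

  notfasta <- tempfile()
  writeLines("this is not fasta", notfasta)
  expect_error(parse_upstream_fasta(notfasta), "malformed|FASTA|serious")
})

test_that("promoter_set validates its invariants", {
  expect_error(promoter_set("G1", "ACGTX", 5), "invalid")
  expect_error(promoter_set(c("G1", "G1"), c("ACGT", "ACGT"), 4), "duplicate")
  expect_error(promoter_set("", "ACGT", 4), "non-empty")
  # ambiguity letters degrade to N
  ps <- promoter_set("G1", "ACGRY", 5)
  expect_equal(ps$sequence, "ACGNN")
})

# --- extraction from genome + GFF3 ---------------------------------------

make_toy_genome <- function(seed = 5, len = 2000) {
  set.seed(seed)
  chr1 <- random_dna(len)
  fa <- write_fasta_fixture(list("chr1 toy assembly" = chr1), wrap = 80)
  list(seq = chr1, fasta = fa)
}

test_that("extract_upstream: plus strand, start-codon anchor", {
  g <- make_toy_genome()
  gff <- write_gff3_fixture(data.frame(
    seqid = "chr1", type = c("mRNA", "CDS"),
    start = c(950, 1001), end = c(1900, 1600), strand = "+",
    attributes = c("ID=AT1T0001.1", "ID=cds1;Parent=AT1T0001.1")))
  ps <- extract_upstream(g$fasta, gff, window = 500)
  expect_equal(ps$gene_model_id, "AT1T0001.1")
  expect_equal(ps$sequence, substr(g$seq, 501, 1000))
  expect_false(ps$truncated)
})

test_that("extract_upstream: minus strand takes the reverse complement", {
  g <- make_toy_genome(seed = 6)
  # start codon's first base (on its own strand) at genome position 200
  gff <- write_gff3_fixture(data.frame(
    seqid = "chr1", type = "CDS", start = 100, end = 200, strand = "-",
    attributes = "ID=cds1;Parent=AT1T0002.1"))
  ps <- extract_upstream(g$fasta, gff, window = 500)
  expect_equal(ps$sequence, revcomp(substr(g$seq, 201, 700)))
  expect_false(ps$truncated)
})

test_that("extract_upstream clips at chromosome boundaries", {
  g <- make_toy_genome(seed = 7)
  gff <- write_gff3_fixture(data.frame(
    seqid = "chr1", type = "CDS", start = c(300, 1800), end = c(900, 1950),
    strand = c("+", "-"),
    attributes = c("ID=c1;Parent=M1.1", "ID=c2;Parent=M2.1")))
  ps <- extract_upstream(g$fasta, gff, window = 500)
  expect_equal(nchar(ps$sequence[ps$gene_model_id == "M1.1"]), 299L)
  expect_true(ps$truncated[ps$gene_model_id == "M1.1"])
  expect_equal(ps$sequence[ps$gene_model_id == "M1.1"],
               substr(g$seq, 1, 299))
  # minus-strand model near the 3' end: only 50 bp available
  expect_equal(nchar(ps$sequence[ps$gene_model_id == "M2.1"]), 50L)
  expect_true(ps$truncated[ps$gene_model_id == "M2.1"])
})

test_that("extract_upstream uses the anchor argument", {
  g <- make_toy_genome(seed = 8)
  gff <- write_gff3_fixture(data.frame(
    seqid = "chr1", type = c("mRNA", "CDS"),
    start = c(901, 1001), end = c(1900, 1600), strand = "+",
    attributes = c("ID=AT1T0003.1", "ID=cds1;Parent=AT1T0003.1")))
  tss <- extract_upstream(g$fasta, gff, window = 500,
                          anchor = "transcription_start")
  expect_equal(tss$sequence, substr(g$seq, 401, 900))
})

test_that("extract_upstream: multi-part CDS anchors at the first coding base", {
  g <- make_toy_genome(seed = 9)
  gff <- write_gff3_fixture(data.frame(
    seqid = "chr1", type = "CDS", start = c(1001, 1301), end = c(1100, 1500),
    strand = "+",
    attributes = rep("ID=cds1;Parent=M3.1", 2)))
  ps <- extract_upstream(g$fasta, gff, window = 100)
  expect_equal(ps$sequence, substr(g$seq, 901, 1000))
})

test_that("extract_upstream errors on chromosome mismatch, warns on no-anchor", {
  g <- make_toy_genome(seed = 10)
  gff <- write_gff3_fixture(data.frame(
    seqid = "chr9", type = "CDS", start = 1001, end = 1600, strand = "+",
    attributes = "ID=c;Parent=M.1"))
  expect_error(extract_upstream(g$fasta, gff), "chr9")

  gff2 <- write_gff3_fixture(data.frame(
    seqid = "chr1", type = c("CDS", "CDS"), start = c(1001, 1200),
    end = c(1600, 1400), strand = "+",
    attributes = c("ID=c1;Parent=M.1", "ID=c2")))  # second has no Parent
  expect_warning(ps <- extract_upstream(g$fasta, gff2), "skipped")
  expect_equal(ps$gene_model_id, "M.1")
})

test_that("round trip: write then re-read reproduces the records", {
  g <- make_toy_genome(seed = 11)
  gff <- write_gff3_fixture(data.frame(
    seqid = "chr1", type = "CDS", start = c(600, 1400), end = c(900, 1800),
    strand = c("+", "-"),
    attributes = c("ID=a;Parent=RT1.1", "ID=b;Parent=RT2.1")))
  ps <- extract_upstream(g$fasta, gff, window = 500)
  fa <- tempfile(fileext = ".fa")
  write_promoter_fasta(ps, fa)
  back <- parse_upstream_fasta(fa, window = 500)
  expect_equal(as.data.frame(back), as.data.frame(ps))

  idx <- tempfile(fileext = ".tsv")
  write_promoter_index(ps, idx)
  ix <- read.delim(idx, stringsAsFactors = FALSE)
  expect_equal(ix$length, nchar(ps$sequence))
})

test_that("extraction recovers planted promoters from a constructed genome", {
  # genome = [promoter1][CDS1][promoter2][CDS2], all plus strand
  set.seed(12)
  prom <- c(random_dna(500), random_dna(500))
  cds <- c(random_dna(300), random_dna(300))
  chr <- paste0(prom[1], cds[1], prom[2], cds[2])
  fa <- write_fasta_fixture(list(chrT = chr), wrap = 70)
  gff <- write_gff3_fixture(data.frame(
    seqid = "chrT", type = "CDS", start = c(501, 1301), end = c(800, 1600),
    strand = "+",
    attributes = c("ID=x;Parent=P1.1", "ID=y;Parent=P2.1")))
  ps <- extract_upstream(fa, gff, window = 500)
  expect_equal(ps$sequence, prom)
})
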