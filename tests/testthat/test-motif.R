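# Degenerate pattern compilation, reverse complement, and scanning.

test_that("compile_pattern expands IUPAC codes into per-position base sets", {
  p <- compile_pattern("GNATATNC")
  expect_s3_class(p, "iupac_pattern")
  expect_equal(p$k, 8L)
  expect_equal(p$position_sets,
               list("G", c("A", "C", "G", "T"), "A", "T", "A", "T",
                    c("A", "C", "G", "T"), "C"))

  q <- compile_pattern("acgt")  # case-insensitive
  expect_equal(q$text, "ACGT")
  expect_equal(q$position_sets, list("A", "C", "G", "T"))

  expect_error(compile_pattern("GXAT"), "position 2")
  expect_error(compile_pattern("AC9T"), "position 3")
  expect_error(compile_pattern(""), "non-empty")
})

test_that("reverse_complement_pattern reverses and complements position sets", {
  # P1BS is an imperfect palindrome: its own reverse complement
  p <- compile_pattern("GNATATNC")
  expect_equal(reverse_complement_pattern(p)$text, "GNATATNC")
  expect_true(pattern_is_palindromic(p))

  expect_equal(reverse_complement_pattern(compile_pattern("GGAT"))$text, "ATCC")
  expect_equal(reverse_complement_pattern(compile_pattern("NNNN"))$text, "NNNN")
  # degenerate codes complement to canonical codes
  expect_equal(reverse_complement_pattern(compile_pattern("RYK"))$text, "MRY")
  expect_false(pattern_is_palindromic(compile_pattern("GGAT")))
})

test_that("scan_sequence finds the printed SULTR1;3 motif word", {
  p <- compile_pattern("GNATATNC")
  h <- scan_sequence("TTGGATATTCTT", p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$offset, 3L)
  expect_equal(h$matched_sequence, "GGATATTC")
  expect_equal(h$strand, "±")  # self-palindromic pattern, deduplicated

  expect_equal(nrow(scan_sequence("CCCCCCCCCCCC", p)), 0L)
})

test_that("sequence N never matches, even against pattern N", {
  p <- compile_pattern("GNATATNC")
  expect_equal(nrow(scan_sequence("TTGNATATTCTT", p)), 0L)
  expect_equal(nrow(scan_sequence("GNATATNC", p)), 0L)
  expect_equal(nrow(scan_sequence("NNNN", compile_pattern("NNNN"))), 0L)
  # but N elsewhere in the sequence is harmless
  expect_equal(scan_sequence("NNGGATATTCNN", p)$offset, 3L)
})

test_that("overlapping windows are all reported", {
  # ACATATGT matches GNATATNC? no; build overlap with pattern ATAT
  p <- compile_pattern("ATAT")
  h <- scan_sequence("ATATATAT", p, strands = "forward")
  expect_equal(h$offset, c(1L, 3L, 5L))
})

test_that("scan_sequence agrees with the brute-force oracle", {
  set.seed(101)
  p1bs <- compile_pattern("GNATATNC")
  for (rep in 1:10) {
    s <- random_dna(2000)
    expect_equal(scan_sequence(s, p1bs), oracle_scan(s, "GNATATNC"))
    expect_equal(scan_sequence(s, p1bs, strands = "forward"),
                 oracle_scan(s, "GNATATNC", strands = "forward"))
  }
  for (rep in 1:10) {
    pat <- random_iupac_pattern(sample(3:8, 1))
    s <- random_dna(1500, alphabet = c("A", "C", "G", "T", "N"))
    expect_equal(scan_sequence(s, compile_pattern(pat)), oracle_scan(s, pat),
                 info = pat)
  }
})

test_that("strand symmetry: hits reflect onto the reverse complement", {
  set.seed(102)
  for (rep in 1:5) {
    pat <- random_iupac_pattern(6)
    p <- compile_pattern(pat)
    s <- random_dna(800)
    h_fwd <- scan_sequence(s, p)
    h_rc <- scan_sequence(revcomp(s), reverse_complement_pattern(p))
    # a window at offset i in s is the window at offset L - i - k + 2 in rc(s)
    L <- nchar(s); k <- p$k
    expect_setequal(h_fwd$offset, L - h_rc$offset - k + 2L)
  }
})

test_that("P1BS: forward-only equals both-strand scanning (self-palindromy)", {
  set.seed(103)
  p <- compile_pattern("GNATATNC")
  for (rep in 1:10) {
    s <- random_dna(1000)
    fwd <- scan_sequence(s, p, strands = "forward")
    both <- scan_sequence(s, p, strands = "both")
    expect_equal(both$offset, fwd$offset)
    expect_equal(both$matched_sequence, fwd$matched_sequence)
  }
})

test_that("scan_promoter reports bp-upstream-of-anchor distances", {
  p <- compile_pattern("GNATATNC")
  # plant at offsets 69-76 of a 500-bp promoter -> 432 bp upstream
  sp <- synth_promoters(1, length = 500, composition = c(A = 0, C = 0.5,
                                                         G = 0.5, T = 0),
                        planted = data.frame(promoter = 1,
                                             upstream_distance = 432,
                                             strand = "+",
                                             word = "GGATATTC"),
                        seed = 1)
  h <- scan_promoter(sp$promoters[1, ], p)
  expect_equal(h$upstream_distance, 432L)
  expect_equal(h$matched_sequence, "GGATATTC")

  # boundary: match at offset 1 -> distance 500
  s2 <- paste0("GGATATTC", strrep("C", 492))
  h2 <- scan_promoter(list(gene_model_id = "X.1", sequence = s2), p)
  expect_equal(h2$upstream_distance, 500L)

  # promoter shorter than k: empty, not an error
  h3 <- scan_promoter(list(gene_model_id = "Y.1", sequence = "GGATA"), p)
  expect_equal(nrow(h3), 0L)
})

test_that("screen_promoters counts models once regardless of multiplicity", {
  p <- compile_pattern("GNATATNC")
  two_sites <- paste0("GGATATTC", strrep("C", 100), "GGATATAC",
                      strrep("G", 84))
  no_site <- strrep("CG", 100)
  ps <- promoter_set(c("A.1", "B.1"), c(two_sites, no_site), window = 200)
  res <- screen_promoters(ps, p)
  expect_equal(res$n_models_scanned, 2L)
  expect_equal(res$n_models_with_hit, 1L)
  expect_equal(nrow(res$hits), 2L)
  expect_equal(res$hits$gene_model_id, c("A.1", "A.1"))

  # empty input
  empty <- screen_promoters(promoter_set(character(0), character(0), 500), p)
  expect_equal(empty$n_models_scanned, 0L)
  expect_equal(empty$n_models_with_hit, 0L)

  expect_error(screen_promoters(
    promoter_set(c("A.1", "B.1"), c("ACGT", "ACGT"), 4)[c(1, 1), ], p),
    "unique")
})

test_that("screen matches scan_promoter record by record", {
  set.seed(104)
  p <- compile_pattern("GNATATNC")
  sp <- synth_promoters(50, length = 300, seed = 9)
  res <- screen_promoters(sp$promoters, p)
  per_rec <- do.call(rbind, lapply(seq_len(50), function(i)
    scan_promoter(sp$promoters[i, ], p)))
  rownames(per_rec) <- NULL
  expect_equal(res$hits, per_rec[, names(res$hits)])
  expect_equal(res$n_models_with_hit,
               length(unique(per_rec$gene_model_id)))
})

test_that("locus collapsing strips splice-variant suffixes", {
  p <- compile_pattern("GNATATNC")
  site <- paste0(strrep("C", 92), "GGATATTC")
  ps <- promoter_set(c("AT1G01010.1", "AT1G01010.2", "AT1G02020.1"),
                     c(site, site, strrep("G", 100)), window = 100)
  res <- screen_promoters(ps, p, collapse_loci = TRUE)
  expect_equal(res$n_models_with_hit, 2L)
  expect_equal(res$n_loci_with_hit, 1L)
})

test_that("hit exports are well-formed", {
  p <- compile_pattern("GNATATNC")
  sp <- synth_promoters(5, length = 200,
                        planted = data.frame(promoter = 1:2,
                                             upstream_distance = c(100, 50),
                                             strand = c("+", "-")),
                        seed = 3)
  res <- screen_promoters(sp$promoters, p)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  bed <- tempfile(fileext = ".bed")
  write_hits_tsv(res, tsv)
  write_screen_json(res, js)
  write_hits_bed(res, sp$promoters, bed)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back$upstream_distance, res$hits$upstream_distance)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$n_models_with_hit, res$n_models_with_hit)
  bd <- read.delim(bed, header = FALSE, stringsAsFactors = FALSE)
  expect_equal(ncol(bd), 6L)
  # BED window length is always k, 0-based half-open
  expect_true(all(bd$V3 - bd$V2 == 8L))
})
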