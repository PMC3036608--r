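# Programmatic fixtures: tiny FASTA / GFF3 / CT tables built in code.

write_fasta_fixture <- function(entries, path = tempfile(fileext = ".fa"),
                                eol = "\n", wrap = NULL) {
  lines <- unlist(lapply(names(entries), function(h) {
    s <- entries[[h]]
    body <- if (is.null(wrap)) s else {
      starts <- seq(1, nchar(s), by = wrap)
      substring(s, starts, pmin(starts + wrap - 1, nchar(s)))
    }
    c(paste0(">", h), body)
  }))
  con <- file(path, "wb")
  writeLines(lines, con, sep = eol)
  close(con)
  path
}

write_gff3_fixture <- function(rows, path = tempfile(fileext = ".gff3")) {
  # rows: data.frame(seqid, type, start, end, strand, attributes)
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     rows$seqid, rows$type, rows$start, rows$end,
                     rows$strand, rows$attributes))
  writeLines(lines, path)
  path
}

make_ct_record <- function(genotype, tissue, treatment, gene, bio_rep, ct,
                           sample_id = NULL) {
  data.frame(sample_id = sample_id %||%
               paste(genotype, tissue, treatment, bio_rep, sep = "."),
             genotype = genotype, tissue = tissue, treatment = treatment,
             gene = gene, bio_rep = bio_rep,
             ct_1 = ct[1], ct_2 = ct[min(2, length(ct))],
             ct_3 = ct[min(3, length(ct))],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny CT table: one target, one reference, arbitrary (condition -> dct)
make_ct_table <- function(dcts, target = "TGT", ref = "UBQ10",
                          genotype = "WT", tissue = "root",
                          ref_ct = 20) {
  rows <- list()
  for (tr in names(dcts)) {
    for (b in seq_along(dcts[[tr]])) {
      rows[[length(rows) + 1L]] <-
        make_ct_record(genotype, tissue, tr, target, b,
                       rep(ref_ct + dcts[[tr]][b], 3))
      rows[[length(rows) + 1L]] <-
        make_ct_record(genotype, tissue, tr, ref, b, rep(ref_ct, 3))
    }
  }
  do.call(rbind, rows)
}
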