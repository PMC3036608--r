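# Promoter (upstream-region) handling: reading pre-extracted upstream FASTA
# sets and extracting fixed-length upstream windows from genome FASTA + GFF3.
#
# A promoter record is anchored at the start codon by default: the last base
# of the stored sequence is the base immediately 5' of the anchor, read
# 5'→3' on the gene's coding strand.

#' Construct / validate a promoter set
#'
#' A promoter set is a data.frame with one row per gene model and columns
#' `gene_model_id`, `sequence` (uppercase, alphabet `{A,C,G,T,N}`),
#' `window` (requested length in bp) and `truncated` (flag set when a
#' chromosome end shortened the region).
#'
#' @param gene_model_id character vector of unique, non-empty ids.
#' @param sequence character vector of DNA strings.
#' @param window requested window length (bp).
#' @param truncated logical vector; defaults to `nchar(sequence) < window`.
#' @return data.frame of class `promoter_set`.
#' @export
promoter_set <- function(gene_model_id, sequence, window,
                         truncated = nchar(sequence) < window) {
  gene_model_id <- as.character(gene_model_id)
  sequence <- vapply(as.character(sequence), normalize_dna, character(1),
                     USE.NAMES = FALSE)
  if (any(!nzchar(gene_model_id)))
    stop("gene_model_id must be non-empty", call. = FALSE)
  dup <- unique(gene_model_id[duplicated(gene_model_id)])
  if (length(dup))
    stop("duplicate gene_model_id: ", paste(dup, collapse = ", "), call. = FALSE)
  too_long <- gene_model_id[nchar(sequence) > window]
  if (length(too_long))
    stop("sequence longer than window for: ",
         paste(too_long, collapse = ", "), call. = FALSE)
  short_unflagged <- gene_model_id[nchar(sequence) < window & !truncated]
  if (length(short_unflagged))
    stop("sequence shorter than window but not flagged truncated for: ",
         paste(short_unflagged, collapse = ", "), call. = FALSE)
  n <- length(gene_model_id)
  structure(data.frame(gene_model_id = gene_model_id,
                       sequence = sequence,
                       window = rep_len(as.integer(window), n),
                       truncated = rep_len(as.logical(truncated), n),
                       stringsAsFactors = FALSE),
            class = c("promoter_set", "data.frame"))
}

as_promoter_set <- function(x) {
  if (inherits(x, "promoter_set")) return(x)
  stopifnot(is.data.frame(x),
            all(c("gene_model_id", "sequence") %in% names(x)))
  promoter_set(x$gene_model_id, x$sequence,
               window = x$window %||% max(nchar(x$sequence), 1L),
               truncated = x$truncated %||% (nchar(x$sequence) < (x$window %||% max(nchar(x$sequence), 1L))))
}

#' Read a pre-extracted upstream-sequence FASTA
#'
#' Reads a FASTA of fixed-length upstream regulatory regions (the dialect
#' used by TAIR upstream-sequence releases, whose headers carry coordinate
#' metadata after a pipe). The gene model id is the first
#' whitespace-delimited token of each header; the rest is ignored.
#' Sequences are uppercased; records shorter than `window` are flagged
#' `truncated`; records longer than `window` are rejected.
#'
#' @param path FASTA file (multi-line and CRLF-tolerant).
#' @param window expected window length in bp (default 500).
#' @return a [promoter_set()]. An empty file yields a zero-row set.
#' @export
parse_upstream_fasta <- function(path, window = 500L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  stopifnot(is.numeric(window), window >= 1)
  seqs <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                   error = function(e)
                     stop("malformed FASTA in ", path, ": ",
                          conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L)
    return(promoter_set(character(0), character(0), window))
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  blank <- which(is.na(ids) | !nzchar(ids))
  if (length(blank))
    stop("malformed FASTA: empty header for record ", blank[1],
         " ('>", headers[blank[1]], "')", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene_model_id in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  raw <- as.character(seqs)
  # CRLF input leaves \r on line fragments under some writers; strip defensively
  raw <- gsub("\r", "", raw, fixed = TRUE)
  promoter_set(ids, raw, window)
}

#' Extract fixed-length upstream regions from a genome + GFF3 annotation
#'
#' For a plus-strand gene model whose anchor's first base is at 1-based
#' position `p`, the upstream region is `genome[p-window .. p-1]` in genome
#' orientation; for a minus-strand model with the anchor's first base (on
#' its own strand) at position `p`, it is the reverse complement of
#' `genome[p+1 .. p+window]`. Windows clipped at chromosome boundaries are
#' flagged `truncated`.
#'
#' @param genome FASTA file of chromosome sequences.
#' @param annotation GFF3 file (1-based inclusive coordinates).
#' @param window window length in bp (default 500).
#' @param anchor `"start_codon"` (first base of the CDS; default, matching
#'   the "bp upstream of the start codon" convention) or
#'   `"transcription_start"` (first base of the mRNA feature).
#' @return a [promoter_set()], one record per gene model, in annotation
#'   order. Models lacking the required anchor feature are skipped with one
#'   summarizing warning.
#' @export
extract_upstream <- function(genome, annotation, window = 500L,
                             anchor = c("start_codon", "transcription_start")) {
  anchor <- match.arg(anchor)
  stopifnot(is.numeric(window), window >= 1)
  window <- as.integer(window)
  chrs <- Biostrings::readDNAStringSet(genome)
  names(chrs) <- vapply(strsplit(names(chrs), "[ \t]+"), `[`, character(1), 1L)
  gff <- rtracklayer::import(annotation, format = "gff3")

  feat_type <- if (anchor == "start_codon") "CDS" else "mRNA"
  feats <- gff[as.character(gff$type) == feat_type]
  if (length(feats) == 0L)
    stop("annotation has no ", feat_type, " features", call. = FALSE)

  # gene model id: CDS features point at their transcript via Parent;
  # mRNA features carry their own ID
  model_of <- function(f) {
    if (feat_type == "CDS") {
      par <- f$Parent
      vapply(seq_along(par), function(i) {
        p <- par[[i]]
        if (length(p) == 0L) NA_character_ else sub("^[A-Za-z]+:", "", p[1])
      }, character(1))
    } else {
      id <- f$ID
      sub("^[A-Za-z]+:", "", ifelse(is.na(id) | !nzchar(id),
                                    NA_character_, id))
    }
  }
  ids <- model_of(feats)
  keep <- !is.na(ids)
  n_skipped <- sum(!keep)
  feats <- feats[keep]; ids <- ids[keep]

  chr <- as.character(GenomicRanges::seqnames(feats))
  missing_chr <- setdiff(unique(chr), names(chrs))
  if (length(missing_chr))
    stop("chromosome(s) in GFF3 absent from genome FASTA: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)

  st <- GenomicRanges::start(feats)
  en <- GenomicRanges::end(feats)
  strand <- as.character(GenomicRanges::strand(feats))

  # anchor first base per model: plus strand -> min(start) of its parts;
  # minus strand -> max(end)
  o <- !duplicated(ids)
  model_ids <- ids[o]
  model_chr <- chr[o]
  model_strand <- strand[o]
  anchor_pos <- integer(length(model_ids))
  for (i in seq_along(model_ids)) {
    sel <- ids == model_ids[i]
    anchor_pos[i] <- if (model_strand[i] == "-") max(en[sel]) else min(st[sel])
  }
  bad_strand <- model_ids[!model_strand %in% c("+", "-")]
  if (length(bad_strand)) {
    warning(length(bad_strand), " model(s) without usable strand skipped: ",
            paste(utils::head(bad_strand, 5), collapse = ", "))
    sel <- model_strand %in% c("+", "-")
    model_ids <- model_ids[sel]; model_chr <- model_chr[sel]
    model_strand <- model_strand[sel]; anchor_pos <- anchor_pos[sel]
  }
  if (n_skipped > 0L)
    warning(n_skipped, " ", feat_type,
            " feature(s) without a gene model id skipped")

  seqs <- character(length(model_ids))
  trunc <- logical(length(model_ids))
  for (i in seq_along(model_ids)) {
    L_chr <- Biostrings::width(chrs[model_chr[i]])
    p <- anchor_pos[i]
    if (model_strand[i] == "+") {
      from <- max(1L, p - window); to <- p - 1L
      if (to < from) { seqs[i] <- ""; trunc[i] <- TRUE; next }
      s <- Biostrings::subseq(chrs[[model_chr[i]]], from, to)
      seqs[i] <- as.character(s)
      trunc[i] <- (p - window) < 1L
    } else {
      from <- p + 1L; to <- min(L_chr, p + window)
      if (to < from) { seqs[i] <- ""; trunc[i] <- TRUE; next }
      s <- Biostrings::reverseComplement(
        Biostrings::subseq(chrs[[model_chr[i]]], from, to))
      seqs[i] <- as.character(s)
      trunc[i] <- (p + window) > L_chr
    }
  }
  promoter_set(model_ids, seqs, window, truncated = trunc)
}

#' Write a promoter set as FASTA
#'
#' Round-trips with [parse_upstream_fasta()].
#'
#' @param ps a [promoter_set()].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(ps, path) {
  ps <- as_promoter_set(ps)
  x <- Biostrings::BStringSet(ps$sequence)
  names(x) <- ps$gene_model_id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Write a promoter index TSV
#'
#' Columns: `gene_model_id`, `length`, `truncated`.
#'
#' @param ps a [promoter_set()].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_promoter_index <- function(ps, path) {
  ps <- as_promoter_set(ps)
  write_tsv(data.frame(gene_model_id = ps$gene_model_id,
                       length = nchar(ps$sequence),
                       truncated = ps$truncated), path)
}
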