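# Degenerate (IUPAC) motif compilation and promoter scanning.
#
# The scanner is the core of the genome-wide P1BS screen: every fixed-length
# window of a promoter is tested, on one or both strands, against the
# per-position base sets of the compiled pattern.  A sequence 'N' never
# matches any position set: an unknown base is evidence of nothing.

#' Compile an IUPAC degenerate pattern
#'
#' Expands an IUPAC nucleotide string (e.g. the P1BS element `"GNATATNC"`)
#' into per-position base subsets of `{A,C,G,T}`.
#'
#' @param iupac_text non-empty IUPAC string; case-insensitive.
#' @return An object of class `iupac_pattern`: a list with elements
#'   `text` (canonical uppercase pattern), `position_sets` (list of
#'   character vectors) and `k` (pattern length).
#' @examples
#' p <- compile_pattern("GNATATNC")
#' p$k
#' p$position_sets[[2]]
#' @export
compile_pattern <- function(iupac_text) {
  if (!is.character(iupac_text) || length(iupac_text) != 1L || !nzchar(iupac_text))
    stop("pattern must be a single non-empty string", call. = FALSE)
  text <- toupper(iupac_text)
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC character '%s' at position %d in pattern '%s'",
                 ch[bad[1]], bad[1], text), call. = FALSE)
  }
  structure(list(text = text,
                 position_sets = unname(IUPAC_SETS[ch]),
                 k = length(ch)),
            class = "iupac_pattern")
}

#' @export
print.iupac_pattern <- function(x, ...) {
  cat(sprintf("IUPAC pattern '%s' (k = %d)\n", x$text, x$k))
  invisible(x)
}

#' Reverse complement of a degenerate pattern
#'
#' Position sets are reversed in order and complemented element-wise; the
#' text is re-encoded in canonical IUPAC codes.  The P1BS element GNATATNC
#' is its own reverse complement (an imperfect palindrome).
#'
#' @param p an `iupac_pattern`.
#' @return an `iupac_pattern`.
#' @export
reverse_complement_pattern <- function(p) {
  stopifnot(inherits(p, "iupac_pattern"))
  sets <- lapply(rev(p$position_sets),
                 function(s) sort(unname(COMPLEMENT[s])))
  text <- paste(IUPAC_CODE_OF_SET[vapply(sets, .set_key, character(1))],
                collapse = "")
  structure(list(text = text, position_sets = sets, k = p$k),
            class = "iupac_pattern")
}

#' Is a degenerate pattern its own reverse complement?
#'
#' @param p an `iupac_pattern`.
#' @return logical.
#' @export
pattern_is_palindromic <- function(p) {
  identical(p$position_sets, reverse_complement_pattern(p)$position_sets)
}

# fast position-set membership: one 256-slot logical lookup table per
# pattern position, indexed by the byte value of the sequence character
.pattern_luts <- function(p) {
  lapply(p$position_sets, function(s) {
    lut <- logical(256L)
    lut[utf8ToInt(paste(s, collapse = ""))] <- TRUE
    lut
  })
}

# forward-strand window starts of p in the integer-coded sequence
.match_starts <- function(codes, luts, k) {
  n_win <- length(codes) - k + 1L
  if (n_win < 1L) return(integer(0))
  ok <- luts[[1L]][codes[seq_len(n_win)]]
  for (j in seq_len(k - 1L)) {
    if (!any(ok)) break
    ok <- ok & luts[[j + 1L]][codes[seq_len(n_win) + j]]
  }
  which(ok)
}

#' Scan a sequence for a degenerate pattern
#'
#' Reports every window (overlaps included) that matches the pattern's
#' per-position base sets.  With `strands = "both"` the reverse strand is
#' scanned by matching the reverse-complemented pattern against the forward
#' sequence; for a self-reverse-complementary pattern such as P1BS each
#' matching window is reported exactly once with strand `"±"`.
#'
#' @param seq single DNA string over `{A,C,G,T,N}` (lowercase accepted).
#'   A sequence `N` never matches any position set.
#' @param p an `iupac_pattern`.
#' @param strands `"both"` (default) or `"forward"`.
#' @return data.frame with columns `offset` (1-based window start within
#'   `seq`), `strand` (`"+"`, `"-"` or `"±"`) and `matched_sequence`
#'   (the k-mer as read 5'→3' on the matching strand).
#' @examples
#' scan_sequence("TTGGATATTCTT", compile_pattern("GNATATNC"))
#' @export
scan_sequence <- function(seq, p, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(inherits(p, "iupac_pattern"))
  if (!is.character(seq) || length(seq) != 1L)
    stop("seq must be a single string", call. = FALSE)
  seq <- normalize_dna(seq)
  codes <- utf8ToInt(seq)
  k <- p$k
  luts <- .pattern_luts(p)

  fwd <- .match_starts(codes, luts, k)
  word_at <- function(i) substr(seq, i, i + k - 1L)

  if (strands == "forward") {
    hits <- data.frame(offset = fwd,
                       strand = rep("+", length(fwd)),
                       matched_sequence = vapply(fwd, word_at, character(1)),
                       stringsAsFactors = FALSE)
  } else if (pattern_is_palindromic(p)) {
    # a window matches the minus strand iff it matches rc(p) == p on the
    # forward strand: identical window set, deduplicated as "±"
    hits <- data.frame(offset = fwd,
                       strand = rep("±", length(fwd)),
                       matched_sequence = vapply(fwd, word_at, character(1)),
                       stringsAsFactors = FALSE)
  } else {
    rcl <- .pattern_luts(reverse_complement_pattern(p))
    rev_ <- .match_starts(codes, rcl, k)
    hits <- rbind(
      data.frame(offset = fwd, strand = rep("+", length(fwd)),
                 matched_sequence = vapply(fwd, word_at, character(1)),
                 stringsAsFactors = FALSE),
      data.frame(offset = rev_, strand = rep("-", length(rev_)),
                 matched_sequence = revcomp(vapply(rev_, word_at, character(1))),
                 stringsAsFactors = FALSE)
    )
    hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Scan one promoter record, reporting upstream distances
#'
#' Coordinates follow the "bp upstream of the anchor" convention: for a
#' window starting at 1-based offset `i` in a promoter of length `L`, the
#' upstream distance of its 5'-most base is `L - i + 1`; the match occupies
#' distances `upstream_distance ... upstream_distance - k + 1`.
#'
#' @param rec one-row subset of a [promoter_set()] (or a list with
#'   `gene_model_id` and `sequence`).
#' @param p an `iupac_pattern`.
#' @param strands passed to [scan_sequence()].
#' @return data.frame of motif hits: `gene_model_id`, `upstream_distance`,
#'   `strand`, `matched_sequence`. A promoter shorter than `k` yields zero
#'   rows.
#' @export
scan_promoter <- function(rec, p, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (is.data.frame(rec)) {
    stopifnot(nrow(rec) == 1L)
    rec <- as.list(rec)
  }
  L <- nchar(rec$sequence)
  hits <- scan_sequence(rec$sequence, p, strands)
  data.frame(gene_model_id = rep(rec$gene_model_id, nrow(hits)),
             upstream_distance = if (nrow(hits)) L - hits$offset + 1L else integer(0),
             strand = hits$strand,
             matched_sequence = hits$matched_sequence,
             stringsAsFactors = FALSE)
}

#' Genome-wide promoter screen
#'
#' Scans every record of a promoter set and counts how many gene models
#' carry at least one match (each model counted once regardless of hit
#' multiplicity). Output order follows input order.
#'
#' @param records a [promoter_set()].
#' @param p an `iupac_pattern`.
#' @param strands passed to [scan_sequence()].
#' @param collapse_loci if `TRUE`, additionally report the number of
#'   distinct loci with a hit after stripping the splice-variant suffix
#'   (`".n"`) from gene model ids.
#' @return An object of class `screen_result`: list with
#'   `n_models_scanned`, `n_models_with_hit`, `hits` (data.frame of all
#'   motif hits in input order), `pattern`, and optionally `n_loci_with_hit`.
#' @export
screen_promoters <- function(records, p, strands = c("both", "forward"),
                             collapse_loci = FALSE) {
  strands <- match.arg(strands)
  records <- as_promoter_set(records)
  if (anyDuplicated(records$gene_model_id))
    stop("gene_model_id values must be unique for a screen", call. = FALSE)

  luts <- .pattern_luts(p)
  palind <- pattern_is_palindromic(p)
  rcl <- if (!palind && strands == "both") .pattern_luts(reverse_complement_pattern(p))
  k <- p$k

  hit_list <- vector("list", nrow(records))
  has_hit <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    codes <- utf8ToInt(s)
    L <- length(codes)
    fwd <- .match_starts(codes, luts, k)
    if (palind || strands == "forward") {
      if (length(fwd)) {
        strand <- if (palind && strands == "both") "±" else "+"
        hit_list[[i]] <- data.frame(
          gene_model_id = rep(records$gene_model_id[i], length(fwd)),
          upstream_distance = L - fwd + 1L,
          strand = rep(strand, length(fwd)),
          matched_sequence = substring(s, fwd, fwd + k - 1L),
          stringsAsFactors = FALSE)
        has_hit[i] <- TRUE
      }
    } else {
      rev_ <- .match_starts(codes, rcl, k)
      if (length(fwd) || length(rev_)) {
        off <- c(fwd, rev_)
        strand <- c(rep("+", length(fwd)), rep("-", length(rev_)))
        word <- substring(s, off, off + k - 1L)
        if (length(rev_)) word[strand == "-"] <- revcomp(word[strand == "-"])
        o <- order(off, strand)
        hit_list[[i]] <- data.frame(
          gene_model_id = rep(records$gene_model_id[i], length(off)),
          upstream_distance = (L - off + 1L)[o],
          strand = strand[o], matched_sequence = word[o],
          stringsAsFactors = FALSE)
        has_hit[i] <- TRUE
      }
    }
  }
  hits <- do.call(rbind, hit_list[has_hit])
  if (is.null(hits))
    hits <- data.frame(gene_model_id = character(0),
                       upstream_distance = integer(0),
                       strand = character(0),
                       matched_sequence = character(0),
                       stringsAsFactors = FALSE)
  res <- list(n_models_scanned = nrow(records),
              n_models_with_hit = sum(has_hit),
              hits = hits,
              pattern = p$text)
  if (collapse_loci) {
    loci <- sub("\\.\\d+$", "", records$gene_model_id)
    res$n_loci_with_hit <- length(unique(loci[has_hit]))
  }
  structure(res, class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Promoter screen for '%s': %d/%d models with ≥1 hit (%d hits)\n",
              x$pattern, x$n_models_with_hit, x$n_models_scanned, nrow(x$hits)))
  if (!is.null(x$n_loci_with_hit))
    cat(sprintf("  collapsed to loci: %d with ≥1 hit\n", x$n_loci_with_hit))
  invisible(x)
}

#' Write motif hits as TSV
#'
#' @param x a `screen_result` or a hits data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(x, path) {
  hits <- if (inherits(x, "screen_result")) x$hits else x
  write_tsv(hits, path)
}

#' Write a screen summary as JSON
#'
#' @param x a `screen_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_screen_json <- function(x, path) {
  stopifnot(inherits(x, "screen_result"))
  out <- list(pattern = x$pattern,
              n_models_scanned = x$n_models_scanned,
              n_models_with_hit = x$n_models_with_hit,
              n_hits = nrow(x$hits))
  if (!is.null(x$n_loci_with_hit)) out$n_loci_with_hit <- x$n_loci_with_hit
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export hit windows in BED-like promoter-local coordinates
#'
#' Six columns (`gene_model_id`, `start`, `end`, `name`, `score`, `strand`)
#' with 0-based half-open coordinates within each promoter.
#'
#' @param x a `screen_result`.
#' @param records the scanned [promoter_set()] (for promoter lengths).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(x, records, path) {
  stopifnot(inherits(x, "screen_result"))
  hits <- x$hits
  L <- stats::setNames(nchar(records$sequence), records$gene_model_id)
  k <- nchar(x$pattern)
  start0 <- L[hits$gene_model_id] - hits$upstream_distance  # 0-based
  bed <- data.frame(chrom = hits$gene_model_id,
                    start = as.integer(start0),
                    end = as.integer(start0 + k),
                    name = hits$matched_sequence,
                    score = 0L,
                    strand = ifelse(hits$strand == "±", ".", hits$strand),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
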