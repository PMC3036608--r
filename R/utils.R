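# Shared low-level helpers: alphabets, complements, small I/O utilities.

# IUPAC nucleotide codes expanded to base subsets of {A,C,G,T}.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# canonical code for each sorted base subset (inverse of IUPAC_SETS)
.set_key <- function(bases) paste(sort(bases), collapse = "")
IUPAC_CODE_OF_SET <- local({
  keys <- vapply(IUPAC_SETS, .set_key, character(1))
  stats::setNames(names(IUPAC_SETS), keys)
})

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the alphabet `{A,C,G,T,N}`.
#' Used throughout for minus-strand coordinates; heavier lifting on whole
#' chromosomes goes through [Biostrings::reverseComplement()] instead.
#'
#' @param x character vector of uppercase DNA strings.
#' @return character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    cc <- COMPLEMENT[ch]
    if (anyNA(cc)) {
      stop("revcomp(): invalid character(s) ",
           paste(unique(ch[is.na(cc)]), collapse = ", "),
           " (alphabet is A,C,G,T,N)", call. = FALSE)
    }
    paste(rev(cc), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Validate/normalize a sequence string: uppercase; ACGTN kept; other IUPAC
# ambiguity letters degraded to N; anything else is an error.
normalize_dna <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    letters_left <- unique(strsplit(bad, "", fixed = TRUE)[[1]])
    amb <- letters_left %in% setdiff(names(IUPAC_SETS), c("A", "C", "G", "T", "N"))
    if (all(amb)) {
      seq <- chartr(paste(letters_left, collapse = ""),
                    strrep("N", length(letters_left)), seq)
    } else {
      stop(what, " contains invalid character(s): ",
           paste(letters_left[!amb], collapse = ", "), call. = FALSE)
    }
  }
  seq
}

# write a data.frame as TSV (no quoting surprises, NA as empty)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
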