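# Independent oracles, deliberately implemented on different code paths
# from the package: naive per-window scanning, a dynamic-programming exact
# occurrence probability, and ptukey-based group flagging.

iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive sliding-window scan; returns data.frame(offset, strand, word)
# matching scan_sequence()'s contract (palindrome dedup as "±")
oracle_scan <- function(seq, pattern_text, strands = "both") {
  sets <- iupac_sets_oracle[strsplit(toupper(pattern_text), "")[[1]]]
  k <- length(sets)
  rc_text <- {
    comp_code <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                   S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                   D = "H", H = "D", N = "N")
    paste(rev(comp_code[strsplit(toupper(pattern_text), "")[[1]]]),
          collapse = "")
  }
  rc_sets <- iupac_sets_oracle[strsplit(rc_text, "")[[1]]]
  palin <- identical(unname(lapply(sets, sort)),
                     unname(lapply(rc_sets, sort)))
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  win_match <- function(i, ss) {
    for (j in seq_len(k)) {
      if (!ch[i + j - 1L] %in% ss[[j]]) return(FALSE)  # 'N' never matches
    }
    TRUE
  }
  out <- list()
  if (L >= k) for (i in 1:(L - k + 1L)) {
    f <- win_match(i, sets)
    if (strands == "forward") {
      if (f) out[[length(out) + 1L]] <- data.frame(
        offset = i, strand = "+",
        matched_sequence = paste(ch[i:(i + k - 1L)], collapse = ""),
        stringsAsFactors = FALSE)
    } else if (palin) {
      if (f) out[[length(out) + 1L]] <- data.frame(
        offset = i, strand = "±",
        matched_sequence = paste(ch[i:(i + k - 1L)], collapse = ""),
        stringsAsFactors = FALSE)
    } else {
      if (f) out[[length(out) + 1L]] <- data.frame(
        offset = i, strand = "+",
        matched_sequence = paste(ch[i:(i + k - 1L)], collapse = ""),
        stringsAsFactors = FALSE)
      if (win_match(i, rc_sets)) out[[length(out) + 1L]] <- data.frame(
        offset = i, strand = "-",
        matched_sequence = oracle_revcomp(paste(ch[i:(i + k - 1L)],
                                                collapse = "")),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(offset = integer(0), strand = character(0),
                      matched_sequence = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exact P(>= 1 forward-strand occurrence of an 8-long degenerate pattern in
# an i.i.d. uniform sequence of length L), by DP over the last-(k-1) bases
oracle_exact_hit_prob <- function(pattern_text = "GNATATNC", L = 500L) {
  base_of <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  psets <- lapply(strsplit(toupper(pattern_text), "")[[1]],
                  function(cc) unname(base_of[iupac_sets_oracle[[cc]]]))
  k <- length(psets)
  S <- 4L^(k - 1L)
  m <- 0:(4L^k - 1L)
  hit <- rep(TRUE, length(m)); mm <- m
  for (j in k:1) { b <- mm %% 4L; hit <- hit & (b %in% psets[[j]]); mm <- mm %/% 4L }
  ns <- m %% S
  p <- rep(1 / S, S)
  for (step in k:L) {
    pm <- rep(p / 4, each = 4L)
    pm[hit] <- 0
    p <- rowsum(pm, ns)[, 1]
  }
  1 - sum(p)
}

# ptukey-based vs-reference flags (reference = column 1 of the n x g matrix)
oracle_tukey_ref_flags <- function(x, alpha = 0.05) {
  n <- nrow(x); g <- ncol(x)
  means <- colMeans(x)
  mse <- sum(sweep(x, 2, means)^2) / (g * (n - 1))
  qs <- abs(means[1] - means[-1]) / sqrt(mse / n)
  stats::ptukey(qs, nmeans = g, df = g * (n - 1), lower.tail = FALSE) < alpha
}

random_dna <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

random_iupac_pattern <- function(k) {
  codes <- names(iupac_sets_oracle)
  paste(sample(codes, k, replace = TRUE, prob = c(rep(4, 4), rep(1, 11))),
        collapse = "")
}
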