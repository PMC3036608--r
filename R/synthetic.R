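# Synthetic-data generators with known ground truth for every pipeline
# stage: promoter sets with planted degenerate-motif sites, CT tables with
# known log2 condition effects, and replicate group data parameterized by
# published mean ± SD summaries.
#
# All generators are deterministic under a fixed seed. Noise is normal;
# physical quantities (concentrations, percentages) are truncated at 0 —
# a modelling choice, not a claim about the original measurements.

#' Base-composition presets
#'
#' `"uniform"` draws each base with probability 1/4; `"arabidopsis"` uses
#' an Arabidopsis-like 36% GC composition (A = T = 0.32, C = G = 0.18).
#' Chance P1BS frequency depends strongly on composition, so the preset is
#' an explicit parameter, never implicit.
#'
#' @param preset `"uniform"`, `"arabidopsis"`, or a named numeric vector of
#'   probabilities over `A,C,G,T` summing to 1.
#' @return named numeric vector of probabilities.
#' @export
base_composition <- function(preset = "uniform") {
  if (is.character(preset)) {
    preset <- match.arg(preset, c("uniform", "arabidopsis"))
    return(switch(preset,
                  uniform = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                  arabidopsis = c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)))
  }
  stopifnot(is.numeric(preset), setequal(names(preset), c("A", "C", "G", "T")))
  if (abs(sum(preset) - 1) > 1e-8)
    stop("base composition must sum to 1", call. = FALSE)
  preset[c("A", "C", "G", "T")]
}

# instantiate a degenerate pattern into one concrete word
.instantiate_pattern <- function(p, word = NA_character_) {
  if (!is.na(word)) {
    word <- toupper(word)
    if (nchar(word) != p$k)
      stop("planted word length differs from pattern length", call. = FALSE)
    ch <- strsplit(word, "", fixed = TRUE)[[1]]
    ok <- mapply(function(c_, s_) c_ %in% s_, ch, p$position_sets)
    if (!all(ok))
      stop("planted word '", word, "' does not match pattern '", p$text, "'",
           call. = FALSE)
    return(word)
  }
  paste(vapply(p$position_sets,
               function(s) s[sample.int(length(s), 1L)], character(1)),
        collapse = "")
}

#' Generate synthetic promoters with planted motif sites
#'
#' Background sequence is drawn i.i.d. from `composition`; planted sites
#' are written at the requested upstream distances (reverse-complemented
#' when `strand == "-"`), and the truth table records every planted site.
#' Planted windows within one promoter must not overlap.
#'
#' @param n number of promoters.
#' @param length promoter length in bp (default 500).
#' @param composition see [base_composition()].
#' @param planted `NULL`, or a data.frame with columns `promoter` (index in
#'   `1..n`), `upstream_distance`, `strand` (`"+"`/`"-"`) and optionally
#'   `word` (a concrete k-mer matching the pattern; `NA` = random
#'   instantiation of the degenerate positions).
#' @param pattern IUPAC text of the planted motif (default `"GNATATNC"`).
#' @param seed integer seed (required: generators are a stated world, and
#'   the world must be reproducible).
#' @return list with `promoters` (a [promoter_set()], ids `SYN00001.1` ...)
#'   and `truth` (data.frame of planted sites: `gene_model_id`,
#'   `upstream_distance`, `strand`, `word`).
#' @export
synth_promoters <- function(n, length = 500L, composition = "uniform",
                            planted = NULL, pattern = "GNATATNC", seed) {
  stopifnot(n >= 0, length >= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  comp <- base_composition(composition)
  p <- compile_pattern(pattern)
  k <- p$k

  ids <- if (n > 0) sprintf("SYN%05d.1", seq_len(n)) else character(0)
  truth <- data.frame(gene_model_id = character(0),
                      upstream_distance = integer(0),
                      strand = character(0), word = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(promoters = promoter_set(ids, character(0), length),
                truth = truth))

  bases <- c("A", "C", "G", "T")
  draws <- sample(bases, n * length, replace = TRUE, prob = comp)
  mat <- matrix(draws, nrow = n, ncol = length, byrow = TRUE)

  if (!is.null(planted) && nrow(planted)) {
    stopifnot(all(c("promoter", "upstream_distance", "strand") %in% names(planted)))
    if (is.null(planted$word)) planted$word <- NA_character_
    if (any(planted$promoter < 1L | planted$promoter > n))
      stop("planted promoter index out of range", call. = FALSE)
    if (any(planted$upstream_distance < k | planted$upstream_distance > length))
      stop("planted upstream_distance out of range [k, length]", call. = FALSE)
    if (any(!planted$strand %in% c("+", "-")))
      stop("planted strand must be '+' or '-'", call. = FALSE)
    # overlap check within each promoter: site at distance u occupies
    # offsets i .. i+k-1 with i = length - u + 1
    off <- length - planted$upstream_distance + 1L
    for (pr in unique(planted$promoter)) {
      oo <- sort(off[planted$promoter == pr])
      if (length(oo) > 1L && any(diff(oo) < k))
        stop("overlapping planted sites in promoter ", pr, call. = FALSE)
    }
    words <- character(nrow(planted))
    for (j in seq_len(nrow(planted))) {
      w <- .instantiate_pattern(p, planted$word[j])
      words[j] <- w
      wr <- if (planted$strand[j] == "-") revcomp(w) else w
      mat[planted$promoter[j], off[j]:(off[j] + k - 1L)] <-
        strsplit(wr, "", fixed = TRUE)[[1]]
    }
    truth <- data.frame(gene_model_id = ids[planted$promoter],
                        upstream_distance = as.integer(planted$upstream_distance),
                        strand = planted$strand,
                        word = words,
                        stringsAsFactors = FALSE)
  }
  seqs <- apply(mat, 1L, paste, collapse = "")
  list(promoters = promoter_set(ids, seqs, length), truth = truth)
}

#' qPCR experiment design for the synthetic CT generator
#'
#' The default design mirrors a two-genotype phosphate/sulfate starvation
#' expression experiment: genotypes WT and phr1, shoot and root tissue,
#' treatments `+Pi` (the calibrator condition), `-Pi`, `+Phi` and `-S`,
#' with `n_bio = 3` biological replicates (published designs state n ≥ 3)
#' and technical triplicates.
#'
#' @param conditions data.frame with columns `genotype`, `tissue`,
#'   `treatment` (the condition grid).
#' @param effects data.frame with columns `gene`, `genotype`, `tissue`,
#'   `treatment`, `log2_effect`: the true log2 expression of each target
#'   gene in each condition, relative to the calibrator. Conditions absent
#'   from `effects` have effect 0.
#' @param calibrator named list (`genotype`, `treatment`); its true effect
#'   must be 0 in every tissue.
#' @param genes character vector of target gene symbols.
#' @param ref_gene reference gene symbol (default `"UBQ10"`).
#' @param ref_baseline mean reference-gene CT (cycles; default 20, a
#'   typical abundant-transcript value).
#' @param gene_offset CT offset of each target above the reference baseline
#'   at the calibrator condition (default 5 cycles, i.e. ~32-fold less
#'   abundant than the reference).
#' @param bio_sd biological (per-replicate) CT noise SD in cycles.
#' @param ref_drift_sd additional reference-gene drift SD per sample
#'   (loading artifact absorbed by normalization).
#' @param tech_sd technical replicate CT noise SD in cycles.
#' @param n_bio biological replicates per condition.
#' @param n_tech technical replicates per reaction (default 3).
#' @return list of class `qpcr_design`.
#' @export
qpcr_design <- function(conditions = NULL, effects = NULL,
                        calibrator = list(genotype = "WT", treatment = "+Pi"),
                        genes = "SULTR1;3", ref_gene = "UBQ10",
                        ref_baseline = 20, gene_offset = 5,
                        bio_sd = 0.2, ref_drift_sd = 0.2, tech_sd = 0.15,
                        n_bio = 3L, n_tech = 3L) {
  if (is.null(conditions))
    conditions <- expand.grid(genotype = c("WT", "phr1"),
                              tissue = c("shoot", "root"),
                              treatment = c("+Pi", "-Pi", "+Phi", "-S"),
                              stringsAsFactors = FALSE)
  if (is.null(effects))
    effects <- data.frame(gene = character(0), genotype = character(0),
                          tissue = character(0), treatment = character(0),
                          log2_effect = numeric(0), stringsAsFactors = FALSE)
  stopifnot(all(c("genotype", "tissue", "treatment") %in% names(conditions)),
            n_bio >= 1L, n_tech >= 1L,
            bio_sd >= 0, ref_drift_sd >= 0, tech_sd >= 0)
  cal_eff <- effects$log2_effect[effects$genotype == calibrator$genotype &
                                   effects$treatment == calibrator$treatment]
  if (any(cal_eff != 0))
    stop("calibrator condition must have true effect 0", call. = FALSE)
  structure(list(conditions = conditions, effects = effects,
                 calibrator = calibrator, genes = genes, ref_gene = ref_gene,
                 ref_baseline = ref_baseline, gene_offset = gene_offset,
                 bio_sd = bio_sd, ref_drift_sd = ref_drift_sd,
                 tech_sd = tech_sd, n_bio = as.integer(n_bio),
                 n_tech = as.integer(n_tech)),
            class = "qpcr_design")
}

#' Generate a synthetic CT table with known effects
#'
#' Per biological replicate, the reference-gene CT is
#' `ref_baseline + biological noise + drift`; each target gene's CT is the
#' same replicate baseline plus `gene_offset - log2_effect` plus its own
#' biological noise; every technical replicate adds technical noise.
#' Because target and reference share the replicate drift, normalization
#' removes it exactly.
#'
#' @param spec a [qpcr_design()].
#' @param seed integer seed (required).
#' @return list with `ct` (data.frame in [read_ct_table()] layout) and
#'   `truth` (the effects table, zero-effect conditions filled in).
#' @export
synth_qpcr <- function(spec, seed) {
  stopifnot(inherits(spec, "qpcr_design"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  cond <- spec$conditions
  rows <- list()
  truth <- list()
  sample_no <- 0L
  for (ci in seq_len(nrow(cond))) {
    for (b in seq_len(spec$n_bio)) {
      sample_no <- sample_no + 1L
      sid <- sprintf("S%04d", sample_no)
      drift <- stats::rnorm(1, 0, spec$ref_drift_sd)
      ref_ct <- spec$ref_baseline + drift + stats::rnorm(1, 0, spec$bio_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, genotype = cond$genotype[ci],
        tissue = cond$tissue[ci], treatment = cond$treatment[ci],
        gene = spec$ref_gene, bio_rep = b,
        t(ref_ct + stats::rnorm(spec$n_tech, 0, spec$tech_sd)),
        stringsAsFactors = FALSE)
      for (g in spec$genes) {
        eff <- spec$effects$log2_effect[
          spec$effects$gene == g &
            spec$effects$genotype == cond$genotype[ci] &
            spec$effects$tissue == cond$tissue[ci] &
            spec$effects$treatment == cond$treatment[ci]]
        eff <- if (length(eff)) eff[1] else 0
        tgt_ct <- spec$ref_baseline + drift + spec$gene_offset - eff +
          stats::rnorm(1, 0, spec$bio_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, genotype = cond$genotype[ci],
          tissue = cond$tissue[ci], treatment = cond$treatment[ci],
          gene = g, bio_rep = b,
          t(tgt_ct + stats::rnorm(spec$n_tech, 0, spec$tech_sd)),
          stringsAsFactors = FALSE)
        if (b == 1L)
          truth[[length(truth) + 1L]] <- data.frame(
            gene = g, genotype = cond$genotype[ci],
            tissue = cond$tissue[ci], treatment = cond$treatment[ci],
            log2_effect = eff, stringsAsFactors = FALSE)
      }
    }
  }
  ct <- do.call(rbind, rows)
  names(ct)[grep("^X\\d+$", names(ct))] <- paste0("ct_", seq_len(spec$n_tech))
  rownames(ct) <- NULL
  list(ct = ct, truth = do.call(rbind, truth))
}

#' Generate replicate group data from mean ± SD specifications
#'
#' Normal draws per group, truncated at 0 (concentrations and percentages
#' are physical quantities).
#'
#' @param specs data.frame with columns `group`, `mean`, `sd`, `n`
#'   (`sd ≥ 0`, `n ≥ 2`).
#' @param seed integer seed (required).
#' @param truncate_at_zero clamp negative draws to 0 (default `TRUE`).
#' @return data.frame with columns `group`, `value`.
#' @export
synth_groups <- function(specs, seed, truncate_at_zero = TRUE) {
  stopifnot(is.data.frame(specs),
            all(c("group", "mean", "sd", "n") %in% names(specs)))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (any(specs$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (any(specs$n < 2)) stop("n must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  out <- lapply(seq_len(nrow(specs)), function(i) {
    v <- stats::rnorm(specs$n[i], specs$mean[i], specs$sd[i])
    if (truncate_at_zero) v[v < 0] <- 0
    data.frame(group = specs$group[i], value = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Published tracer-transfer parameter set (shoot-to-root, -Pi)
#'
#' The shoot-to-root transfer percentages under phosphate starvation as
#' printed for wild type and the phr1, sultr1;3 and sultr2;1 mutants
#' (mean ± SD): WT 1.51 ± 0.27, phr1 0.83 ± 0.12, sultr1;3 0.63 ± 0.28,
#' sultr2;1 1.42 ± 0.42.  The replicate count behind the published SDs is
#' not stated; `n` is therefore an explicit argument (default 4).
#'
#' @param n plants per genotype.
#' @return data.frame usable as `specs` for [synth_groups()].
#' @export
table1_tracer_specs <- function(n = 4L) {
  stopifnot(n >= 2L)
  data.frame(group = c("WT", "phr1", "sultr1;3", "sultr2;1"),
             mean = c(1.51, 0.83, 0.63, 1.42),
             sd = c(0.27, 0.12, 0.28, 0.42),
             n = as.integer(n),
             stringsAsFactors = FALSE)
}
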