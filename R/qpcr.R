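# Comparative-CT (delta-delta-CT) relative quantification.
#
# Model: with ideal per-cycle doubling, transcript abundance relative to a
# reference gene and a calibrator condition is 2^(-ddCT), where
#   dCT  = mean technical CT(target) - mean technical CT(reference)
#   ddCT = dCT(sample) - mean dCT over calibrator replicates (same tissue)
# and log2 relative quantity = -ddCT.  Amplification efficiency is assumed
# to be 2 in the quantification itself; the dilution-series efficiency
# screen (pass threshold 1.85) is quality control, not a correction.

#' Read a long-format CT table
#'
#' Expects columns `sample_id`, `genotype`, `tissue`, `treatment`, `gene`,
#' `bio_rep` and one or more technical CT columns `ct_1`, `ct_2`, ...
#' (TSV or CSV, chosen by file extension).
#'
#' @param path input file.
#' @return data.frame of CT records.
#' @export
read_ct_table <- function(path) {
  df <- read_table_auto(path)
  need <- c("sample_id", "genotype", "tissue", "treatment", "gene", "bio_rep")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CT table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!length(grep("^ct_\\d+$", names(df))))
    stop("CT table lacks technical CT columns (ct_1, ct_2, ...)", call. = FALSE)
  validate_ct_table(df)
  df
}

validate_ct_table <- function(df) {
  ctc <- grep("^ct_\\d+$", names(df), value = TRUE)
  cts <- as.matrix(df[ctc])
  n_tech <- rowSums(!is.na(cts))
  if (any(n_tech < 1L))
    stop("record(s) without any technical CT value: row ",
         paste(which(n_tech < 1L), collapse = ", "), call. = FALSE)
  if (any(cts[!is.na(cts)] <= 0) || any(!is.finite(cts[!is.na(cts)])))
    stop("CT values must be positive and finite", call. = FALSE)
  key <- with(df, paste(genotype, tissue, treatment, gene, bio_rep, sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (genotype, tissue, treatment, gene, bio_rep) record(s)",
         call. = FALSE)
  invisible(df)
}

# mean technical CT per record, flagging wide technical ranges
.tech_means <- function(df, flag_range = 0.5) {
  ctc <- grep("^ct_\\d+$", names(df), value = TRUE)
  cts <- as.matrix(df[ctc])
  m <- rowMeans(cts, na.rm = TRUE)
  rng <- apply(cts, 1L, function(x) diff(range(x, na.rm = TRUE)))
  list(mean = m, wide = rng > flag_range)
}

#' Comparative-CT relative expression
#'
#' Computes per-replicate log2 relative quantities of `target_gene`
#' normalized to `ref_gene` and expressed against a calibrator condition,
#' then summarizes mean ± SD across biological replicates.  Calibration is
#' per tissue: the calibrator delta-CT is the mean over the calibrator
#' condition's biological replicates of the same tissue, so the calibrator
#' condition's summary is 0 by construction.
#'
#' @param table data.frame of CT records (see [read_ct_table()]).
#' @param target_gene gene symbol to quantify.
#' @param ref_gene reference (normalizer) gene symbol; default `"UBQ10"`.
#' @param calibrator named list or vector with elements `genotype` and
#'   `treatment` identifying the calibrator condition (applied within each
#'   tissue).
#' @param flag_range technical replicates spanning more than this many
#'   cycles are flagged (attribute `wide_technical_range`); they are never
#'   auto-dropped.
#' @return data.frame of class `rel_expression` with columns `gene`,
#'   `genotype`, `tissue`, `treatment`, `log2_rq` (mean over biological
#'   replicates), `sd` (NA when `n_bio < 2`) and `n_bio`.  The
#'   per-replicate values are attached as attribute `replicates`.
#' @export
ddct <- function(table, target_gene, ref_gene = "UBQ10",
                 calibrator, flag_range = 0.5) {
  validate_ct_table(table)
  calibrator <- as.list(calibrator)
  if (is.null(calibrator$genotype) || is.null(calibrator$treatment))
    stop("calibrator must provide genotype and treatment", call. = FALSE)

  tm <- .tech_means(table, flag_range)
  dt <- data.table::data.table(table[c("sample_id", "genotype", "tissue",
                                       "treatment", "gene", "bio_rep")],
                               ct = tm$mean, wide = tm$wide)
  tgt <- dt[dt$gene == target_gene]
  ref <- dt[dt$gene == ref_gene]
  if (nrow(tgt) == 0L) stop("no records for target gene ", target_gene,
                            call. = FALSE)
  if (nrow(ref) == 0L) stop("no records for reference gene ", ref_gene,
                            call. = FALSE)

  key <- c("genotype", "tissue", "treatment", "bio_rep")
  merged <- merge(tgt, ref[, c(key, "ct"), with = FALSE],
                  by = key, suffixes = c("_target", "_ref"), all.x = TRUE)
  no_ref <- is.na(merged$ct_ref)
  if (any(no_ref))
    stop("missing reference-gene (", ref_gene, ") record for sample(s): ",
         paste(merged$sample_id[no_ref], collapse = ", "), call. = FALSE)
  merged$dct <- merged$ct_target - merged$ct_ref

  is_cal <- merged$genotype == calibrator$genotype &
    merged$treatment == calibrator$treatment
  cal <- merged[is_cal, list(cal_dct = mean(dct)), by = "tissue"]
  merged <- merge(merged, cal, by = "tissue", all.x = TRUE)
  no_cal <- unique(merged$tissue[is.na(merged$cal_dct)])
  if (length(no_cal))
    stop("no calibrator (", calibrator$genotype, ", ", calibrator$treatment,
         ") replicates for tissue(s): ", paste(no_cal, collapse = ", "),
         call. = FALSE)
  merged$log2_rq <- -(merged$dct - merged$cal_dct)

  summ <- merged[, list(log2_rq = mean(log2_rq),
                        sd = if (.N >= 2L) stats::sd(log2_rq) else NA_real_,
                        n_bio = .N),
                 by = c("genotype", "tissue", "treatment")]
  out <- data.frame(gene = target_gene,
                    as.data.frame(summ),
                    stringsAsFactors = FALSE)
  attr(out, "replicates") <- as.data.frame(
    merged[, c("genotype", "tissue", "treatment", "bio_rep", "dct",
               "cal_dct", "log2_rq"), with = FALSE])
  attr(out, "wide_technical_range") <- unique(merged$sample_id[merged$wide])
  attr(out, "ref_gene") <- ref_gene
  attr(out, "calibrator") <- calibrator
  class(out) <- c("rel_expression", "data.frame")
  out
}

#' Relative quantity from log2 relative expression
#'
#' `2^(log2_rq)`, the linear-scale fold change versus the calibrator.
#'
#' @param x a `rel_expression` data.frame or numeric log2 values.
#' @return numeric vector of relative quantities.
#' @export
relative_quantity <- function(x) {
  if (is.data.frame(x)) x <- x$log2_rq
  2^x
}

#' Amplification-efficiency quality control from a dilution series
#'
#' Ordinary least squares of CT on log10(dilution); efficiency is
#' `10^(-1/slope)`; a primer pair passes when efficiency meets the
#' threshold (default 1.85, with 2.0 the ideal per-cycle doubling).
#'
#' @param dilution_series data.frame with columns `log10_dilution` and `ct`
#'   (at least 3 distinct dilutions).
#' @param threshold minimum acceptable efficiency.
#' @param primer_id optional label.
#' @return object of class `efficiency_qc`: list with `primer_id`, `slope`,
#'   `efficiency`, `pass` and `r_squared`.  A non-negative slope fails with
#'   a diagnostic (efficiency `NA`).
#' @export
efficiency_qc <- function(dilution_series, threshold = 1.85,
                          primer_id = NA_character_) {
  stopifnot(is.data.frame(dilution_series),
            all(c("log10_dilution", "ct") %in% names(dilution_series)))
  if (length(unique(dilution_series$log10_dilution)) < 3L)
    stop("need at least 3 distinct dilutions", call. = FALSE)
  fit <- stats::lm(ct ~ log10_dilution, data = dilution_series)
  slope <- unname(stats::coef(fit)[["log10_dilution"]])
  if (slope >= 0) {
    res <- list(primer_id = primer_id, slope = slope, efficiency = NA_real_,
                pass = FALSE,
                diagnostic = "non-negative slope: CT must fall as template rises",
                r_squared = summary(fit)$r.squared)
  } else {
    eff <- 10^(-1 / slope)
    res <- list(primer_id = primer_id, slope = slope, efficiency = eff,
                pass = eff >= threshold, diagnostic = NULL,
                r_squared = summary(fit)$r.squared)
  }
  structure(res, class = "efficiency_qc")
}

#' @export
print.efficiency_qc <- function(x, ...) {
  cat(sprintf("Efficiency QC%s: slope %.4f, efficiency %s -> %s\n",
              if (is.na(x$primer_id)) "" else paste0(" [", x$primer_id, "]"),
              x$slope,
              if (is.na(x$efficiency)) "NA" else sprintf("%.3f", x$efficiency),
              if (x$pass) "PASS" else "FAIL"))
  if (!is.null(x$diagnostic)) cat("  ", x$diagnostic, "\n")
  invisible(x)
}

#' Write relative-expression results as TSV
#'
#' @param x a `rel_expression` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rel_expression_tsv <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}
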