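# Pipeline driver: subcommand-style orchestration of the analysis stages,
# with a key=value config file overridable by command-line flags (flags
# win), a JSON manifest and a plain-text log per run.

.log_lines <- function(path, lines) {
  cat(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), lines, "\n"),
      file = path, sep = "", append = TRUE)
}

.write_manifest <- function(outdir, subcommand, params, outputs, counts = list()) {
  man <- list(subcommand = subcommand,
              package = "p1bspipe",
              version = as.character(utils::packageVersion("p1bspipe")),
              r_version = as.character(getRversion()),
              parameters = params,
              counts = counts,
              outputs = outputs)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

#' Read a key=value config file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values are kept as strings; consumers coerce.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed config line: ", lines[bad][1], call. = FALSE)
  stats::setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, `[`, character(1), 2L))
}

#' Run one pipeline stage
#'
#' Subcommands: `extract` (genome + GFF3 → promoter FASTA + index),
#' `scan` (promoter FASTA → hits TSV), `screen` (scan + JSON summary),
#' `qpcr` (CT table → relative-expression TSV), `physiology` (tracer +
#' anion tables → group statistics), `simulate` (write a seeded synthetic
#' bundle) and `all` (simulate, then screen + qpcr + physiology on the
#' bundle).  Every run writes `manifest.json` and `run.log` into the
#' output directory.
#'
#' @param config named list. Common keys: `subcommand`, `out` (output
#'   directory), `pattern` (default `"GNATATNC"`), `window` (500),
#'   `anchor` (`start_codon`), `strands` (`both`), `ref_gene` (`UBQ10`),
#'   `calibrator` (`"genotype,treatment"`, default `"WT,+Pi"`),
#'   `reference` (`WT`), `alpha` (0.05), `seed` (required for `simulate`
#'   and `all`). Stage inputs: `in` (FASTA or CT table), `genome`, `gff`,
#'   `tracer`, `anion`, `target`.
#' @return invisibly, a list with `status` (0 on success) and `outputs`.
#'   Validation errors raise conditions; the CLI wrapper maps them to a
#'   nonzero exit status.
#' @export
run_pipeline <- function(config) {
  sub <- config$subcommand %||% stop("no subcommand given", call. = FALSE)
  known <- c("extract", "scan", "screen", "qpcr", "physiology",
             "simulate", "all")
  if (!sub %in% known)
    stop("unknown subcommand '", sub, "' (expected one of ",
         paste(known, collapse = ", "), ")", call. = FALSE)
  outdir <- config$out %||% stop("config must name an output directory ('out')",
                                 call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outdir, "run.log")
  cat("", file = log)  # truncate
  .log_lines(log, paste("subcommand:", sub))

  outputs <- character(0)
  counts <- list()
  params <- config[setdiff(names(config), "subcommand")]

  num <- function(key, default) as.numeric(config[[key]] %||% default)
  chr <- function(key, default) as.character(config[[key]] %||% default)

  if (sub %in% c("scan", "screen")) {
    infile <- config[["in"]] %||% stop("'in' (promoter FASTA) required",
                                       call. = FALSE)
    ps <- parse_upstream_fasta(infile, window = num("window", 500))
    p <- compile_pattern(chr("pattern", "GNATATNC"))
    res <- screen_promoters(ps, p, strands = chr("strands", "both"),
                            collapse_loci = isTRUE(as.logical(
                              chr("collapse_loci", "FALSE"))))
    hits_path <- file.path(outdir, "hits.tsv")
    write_hits_tsv(res, hits_path)
    outputs <- c(outputs, hits_path)
    counts$n_models_scanned <- res$n_models_scanned
    counts$n_models_with_hit <- res$n_models_with_hit
    counts$n_hits <- nrow(res$hits)
    if (sub == "screen") {
      sj <- file.path(outdir, "screen_summary.json")
      write_screen_json(res, sj)
      outputs <- c(outputs, sj)
    }
    .log_lines(log, sprintf("scanned %d models; %d with >=1 hit",
                            res$n_models_scanned, res$n_models_with_hit))
  } else if (sub == "extract") {
    genome <- config$genome %||% stop("'genome' required", call. = FALSE)
    gff <- config$gff %||% stop("'gff' required", call. = FALSE)
    anchor <- chr("anchor", "start_codon")
    if (anchor == "tss") anchor <- "transcription_start"
    ps <- extract_upstream(genome, gff, window = num("window", 500),
                           anchor = anchor)
    fa <- file.path(outdir, "upstream.fasta")
    idx <- file.path(outdir, "upstream_index.tsv")
    write_promoter_fasta(ps, fa)
    write_promoter_index(ps, idx)
    outputs <- c(outputs, fa, idx)
    counts$n_models <- nrow(ps)
    counts$n_truncated <- sum(ps$truncated)
    .log_lines(log, sprintf("extracted %d upstream regions (%d truncated)",
                            nrow(ps), sum(ps$truncated)))
  } else if (sub == "qpcr") {
    infile <- config[["in"]] %||% stop("'in' (CT table) required", call. = FALSE)
    ct <- read_ct_table(infile)
    target <- config$target %||% stop("'target' gene required", call. = FALSE)
    calib <- strsplit(chr("calibrator", "WT,+Pi"), ",", fixed = TRUE)[[1]]
    if (length(calib) != 2L)
      stop("calibrator must be 'genotype,treatment'", call. = FALSE)
    rel <- ddct(ct, target_gene = target, ref_gene = chr("ref_gene", "UBQ10"),
                calibrator = list(genotype = calib[1], treatment = calib[2]))
    rp <- file.path(outdir, "rel_expression.tsv")
    write_rel_expression_tsv(rel, rp)
    outputs <- c(outputs, rp)
    counts$n_conditions <- nrow(rel)
    .log_lines(log, sprintf("ddct: %d conditions summarized", nrow(rel)))
  } else if (sub == "physiology") {
    alpha <- num("alpha", 0.05)
    refg <- chr("reference", "WT")
    if (!is.null(config$tracer)) {
      tr <- read_table_auto(config$tracer)
      tt <- tracer_table(tr, reference = refg, alpha = alpha)
      tp <- file.path(outdir, "tracer_table.tsv")
      write_tsv(tt$table, tp)
      outputs <- c(outputs, tp)
      for (cell in names(tt$stats)) {
        sp <- file.path(outdir, paste0("tracer_stats_",
                                       gsub("[^A-Za-z0-9._-]", "_", cell),
                                       ".tsv"))
        write_group_stats_tsv(tt$stats[[cell]], sp)
        outputs <- c(outputs, sp)
      }
      counts$n_tracer_cells <- length(tt$stats)
    }
    if (!is.null(config$anion)) {
      an <- read_table_auto(config$anion)
      need <- c("genotype", "tissue", "treatment", "anion", "concentration")
      miss <- setdiff(need, names(an))
      if (length(miss))
        stop("anion table lacks column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      cells <- unique(an[c("tissue", "treatment", "anion")])
      res_rows <- list()
      for (i in seq_len(nrow(cells))) {
        sel <- an$tissue == cells$tissue[i] &
          an$treatment == cells$treatment[i] & an$anion == cells$anion[i]
        gs <- compare_groups(data.frame(group = an$genotype[sel],
                                        value = an$concentration[sel]),
                             reference = refg, alpha = alpha)
        res_rows[[i]] <- data.frame(cells[i, , drop = FALSE],
                                    as.data.frame(gs), row.names = NULL)
      }
      ap <- file.path(outdir, "anion_stats.tsv")
      write_tsv(do.call(rbind, res_rows), ap)
      outputs <- c(outputs, ap)
      counts$n_anion_cells <- nrow(cells)
    }
    if (is.null(config$tracer) && is.null(config$anion))
      stop("physiology needs 'tracer' and/or 'anion' input", call. = FALSE)
  } else if (sub %in% c("simulate", "all")) {
    seed <- config$seed %||% stop("'seed' is required for simulate",
                                  call. = FALSE)
    seed <- as.integer(seed)
    bundle <- simulate_bundle(outdir, seed = seed,
                              n_promoters = as.integer(num("n_promoters", 1000)),
                              n_planted = as.integer(num("n_planted", 250)),
                              pattern = chr("pattern", "GNATATNC"),
                              window = as.integer(num("window", 500)))
    outputs <- c(outputs, unlist(bundle$files, use.names = FALSE))
    counts <- c(counts, bundle$counts)
    .log_lines(log, "synthetic bundle written")
    if (sub == "all") {
      sub_cfg <- function(...) utils::modifyList(config, list(...))
      r1 <- run_pipeline(sub_cfg(subcommand = "screen",
                                 `in` = bundle$files$promoters,
                                 out = file.path(outdir, "screen")))
      r2 <- run_pipeline(sub_cfg(subcommand = "qpcr",
                                 `in` = bundle$files$qpcr,
                                 target = "SULTR1;3",
                                 out = file.path(outdir, "qpcr")))
      r3 <- run_pipeline(sub_cfg(subcommand = "physiology",
                                 tracer = bundle$files$tracer,
                                 anion = NULL,
                                 out = file.path(outdir, "physiology")))
      outputs <- c(outputs, r1$outputs, r2$outputs, r3$outputs)
    }
  }

  # manifest: every listed output must exist and be non-empty
  stopifnot(all(file.exists(outputs)), all(file.size(outputs) > 0))
  man <- .write_manifest(outdir, sub, params, outputs, counts)
  .log_lines(log, "done")
  invisible(list(status = 0L, outputs = outputs, manifest = man,
                 counts = counts))
}

# Write one seeded synthetic bundle: promoters + truth, CT table, tracer
# table. Sub-seeds are derived deterministically from the master seed.
simulate_bundle <- function(outdir, seed, n_promoters = 1000L,
                            n_planted = 250L, pattern = "GNATATNC",
                            window = 500L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  k <- nchar(pattern)
  set.seed(seed)
  planted <- NULL
  if (n_planted > 0L) {
    idx <- sample.int(n_promoters, min(n_planted, n_promoters))
    planted <- data.frame(promoter = idx,
                          upstream_distance = sample(k:window, length(idx),
                                                     replace = TRUE),
                          strand = sample(c("+", "-"), length(idx),
                                          replace = TRUE),
                          stringsAsFactors = FALSE)
  }
  sp <- synth_promoters(n_promoters, length = window, planted = planted,
                        pattern = pattern, seed = seed + 1L)
  fa <- file.path(outdir, "promoters.fasta")
  truth <- file.path(outdir, "promoters_truth.tsv")
  write_promoter_fasta(sp$promoters, fa)
  write_tsv(sp$truth, truth)

  eff <- data.frame(gene = "SULTR1;3",
                    genotype = c("WT", "WT", "phr1", "phr1"),
                    tissue = c("root", "shoot", "root", "shoot"),
                    treatment = "-Pi",
                    log2_effect = c(3, 2.5, 1, 0.8),
                    stringsAsFactors = FALSE)
  qd <- qpcr_design(effects = eff)
  sq <- synth_qpcr(qd, seed = seed + 2L)
  qp <- file.path(outdir, "ct_table.csv")
  utils::write.csv(sq$ct, qp, row.names = FALSE, quote = FALSE)
  qt <- file.path(outdir, "ct_truth.tsv")
  write_tsv(sq$truth, qt)

  gg <- synth_groups(table1_tracer_specs(), seed = seed + 3L)
  # lay out as raw tracer counts so the physiology stage exercises
  # transfer_percent: percent p -> cpm_root = 100*p, cpm_shoot = 100*(100-p)
  tr <- data.frame(plant_id = sprintf("P%03d", seq_len(nrow(gg))),
                   genotype = gg$group,
                   treatment = "-Pi",
                   direction = "shoot_to_root",
                   cpm_shoot = round(100 * (100 - gg$value), 3),
                   cpm_root = round(100 * gg$value, 3),
                   stringsAsFactors = FALSE)
  tp <- file.path(outdir, "tracer.csv")
  utils::write.csv(tr, tp, row.names = FALSE, quote = FALSE)

  list(files = list(promoters = fa, promoter_truth = truth, qpcr = qp,
                    qpcr_truth = qt, tracer = tp),
       counts = list(n_promoters = n_promoters,
                     n_planted = if (is.null(planted)) 0L else nrow(planted)))
}

#' Command-line entry point
#'
#' `p1bspipe <subcommand> [--config FILE] [--flag value ...]`. Flags win
#' over config-file values. Installed as the executable script
#' `exec/p1bspipe`, runnable as
#' `Rscript -e 'p1bspipe::p1bs_cli()' <args>` or via the script directly.
#'
#' @param args character vector of command-line arguments; defaults to
#'   `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status (0 on success), invisibly.
#' @export
p1bs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    cat("usage: p1bspipe <extract|scan|screen|qpcr|physiology|simulate|all>",
        "[--config FILE] [--in PATH] [--genome PATH] [--gff PATH]",
        "[--tracer PATH] [--anion PATH] [--pattern IUPAC] [--window N]",
        "[--anchor start_codon|tss] [--strands forward|both]",
        "[--target GENE] [--ref-gene GENE] [--calibrator GENOTYPE,TREATMENT]",
        "[--reference GROUP] [--alpha A] [--seed N] [--out DIR]\n",
        sep = "\n")
    return(invisible(if (length(args)) 0L else 2L))
  }
  sub <- args[1]
  rest <- args[-1]

  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--in", type = "character", default = NULL,
                          dest = "infile"),
    optparse::make_option("--genome", type = "character", default = NULL),
    optparse::make_option("--gff", type = "character", default = NULL),
    optparse::make_option("--tracer", type = "character", default = NULL),
    optparse::make_option("--anion", type = "character", default = NULL),
    optparse::make_option("--pattern", type = "character", default = NULL),
    optparse::make_option("--window", type = "character", default = NULL),
    optparse::make_option("--anchor", type = "character", default = NULL),
    optparse::make_option("--strands", type = "character", default = NULL),
    optparse::make_option("--target", type = "character", default = NULL),
    optparse::make_option("--ref-gene", type = "character", default = NULL,
                          dest = "ref_gene"),
    optparse::make_option("--calibrator", type = "character", default = NULL),
    optparse::make_option("--reference", type = "character", default = NULL),
    optparse::make_option("--alpha", type = "character", default = NULL),
    optparse::make_option("--seed", type = "character", default = NULL),
    optparse::make_option("--n-promoters", type = "character", default = NULL,
                          dest = "n_promoters"),
    optparse::make_option("--n-planted", type = "character", default = NULL,
                          dest = "n_planted"),
    optparse::make_option("--out", type = "character", default = NULL)
  ))
  status <- tryCatch({
    opts <- optparse::parse_args(parser, args = rest)
    opts$help <- NULL
    names(opts)[names(opts) == "infile"] <- "in"
    config <- list()
    if (!is.null(opts$config)) config <- read_config(opts$config)
    opts$config <- NULL
    for (k in names(opts)) if (!is.null(opts[[k]])) config[[k]] <- opts[[k]]
    config$subcommand <- sub
    res <- run_pipeline(config)
    res$status
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
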