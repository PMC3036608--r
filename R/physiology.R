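# Radiotracer transfer percentages and anion group statistics.
#
# Transfer assays feed 35S-sulfate to one organ and measure, after a fixed
# labelling period, the fraction of whole-plant radioactivity recovered in
# the other organ.  Group comparisons follow the standard plant-physiology
# recipe: one-way ANOVA followed by Tukey's HSD, mutants starred against
# the wild-type reference at P < 0.05.

#' Tracer transfer percentage
#'
#' Percentage of whole-plant radioactivity recovered in the destination
#' organ: `root_to_shoot` reports `100 * cpm_shoot / (cpm_shoot + cpm_root)`
#' and `shoot_to_root` reports `100 * cpm_root / (cpm_shoot + cpm_root)`.
#' The two directions are complementary on the same counts (they sum to
#' 100).
#'
#' @param m data.frame of tracer measurements with columns `direction`
#'   (`"root_to_shoot"` or `"shoot_to_root"`), `cpm_shoot`, `cpm_root`
#'   (non-negative counts, positive total), or a single-row list.
#' @return numeric vector of percentages in `[0, 100]`.
#' @examples
#' transfer_percent(data.frame(direction = "root_to_shoot",
#'                             cpm_shoot = 3105, cpm_root = 6895))
#' @export
transfer_percent <- function(m) {
  if (!is.data.frame(m)) m <- as.data.frame(m, stringsAsFactors = FALSE)
  stopifnot(all(c("direction", "cpm_shoot", "cpm_root") %in% names(m)))
  if (any(!m$direction %in% c("root_to_shoot", "shoot_to_root")))
    stop("direction must be root_to_shoot or shoot_to_root", call. = FALSE)
  if (any(m$cpm_shoot < 0 | m$cpm_root < 0))
    stop("counts must be non-negative", call. = FALSE)
  total <- m$cpm_shoot + m$cpm_root
  if (any(total <= 0)) {
    who <- if ("plant_id" %in% names(m)) m$plant_id[total <= 0] else which(total <= 0)
    stop("zero total counts for: ", paste(who, collapse = ", "), call. = FALSE)
  }
  dest <- ifelse(m$direction == "root_to_shoot", m$cpm_shoot, m$cpm_root)
  100 * dest / total
}

#' Compare groups by one-way ANOVA + Tukey HSD
#'
#' Runs the omnibus one-way ANOVA and Tukey's honest significant
#' difference, flagging each group against the reference at the stated
#' alpha.  When every group has zero within-group variance the F statistic
#' is 0/0; following the degenerate-case convention here, significance is
#' then decided by exact equality of means (a group is flagged iff its mean
#' differs from the reference's).
#'
#' @param values named list of numeric replicate vectors, or a data.frame
#'   with columns `group` and `value`.
#' @param reference name of the reference group (e.g. `"WT"`).
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame of class `group_stats` with columns `group`, `n`,
#'   `mean`, `sd`, `p_adj` (Tukey-adjusted p vs the reference; NA for the
#'   reference itself) and `significant`.  Attributes: `anova_p` (omnibus
#'   p), `tukey` (full pairwise matrix), `alpha`, `reference`.
#' @export
compare_groups <- function(values, reference, alpha = 0.05) {
  if (is.data.frame(values)) {
    stopifnot(all(c("group", "value") %in% names(values)))
    values <- split(values$value, values$group)
  }
  if (length(values) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (!reference %in% names(values))
    stop("reference group '", reference, "' not present", call. = FALSE)
  ns <- lengths(values)
  if (any(ns < 2L))
    stop("group(s) with fewer than 2 replicates: ",
         paste(names(values)[ns < 2L], collapse = ", "), call. = FALSE)
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)

  groups <- names(values)
  df <- data.frame(group = factor(rep(groups, ns), levels = groups),
                   value = unlist(values, use.names = FALSE))
  means <- vapply(values, mean, numeric(1))
  sds <- vapply(values, stats::sd, numeric(1))

  if (all(sds == 0)) {
    # degenerate: no within-group variance anywhere
    sig <- means != means[[reference]]
    p_adj <- ifelse(sig, 0, 1)
    p_adj[groups == reference] <- NA_real_
    anova_p <- if (length(unique(means)) > 1L) 0 else 1
    tukey <- NULL
  } else {
    fit <- stats::aov(value ~ group, data = df)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tukey <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    # rows are "a-b" contrasts; pick those involving the reference
    p_adj <- rep(NA_real_, length(groups))
    names(p_adj) <- groups
    rn <- rownames(tukey)
    for (g in setdiff(groups, reference)) {
      row <- rn == paste0(g, "-", reference) | rn == paste0(reference, "-", g)
      if (any(row)) p_adj[g] <- tukey[row, "p adj"][1]
    }
    sig <- !is.na(p_adj) & p_adj < alpha
  }

  out <- data.frame(group = groups, n = as.integer(ns),
                    mean = unname(means), sd = unname(sds),
                    p_adj = unname(p_adj),
                    significant = unname(sig),
                    stringsAsFactors = FALSE)
  attr(out, "anova_p") <- anova_p
  attr(out, "tukey") <- tukey
  attr(out, "alpha") <- alpha
  attr(out, "reference") <- reference
  class(out) <- c("group_stats", "data.frame")
  out
}

#' Fold change between two group summaries
#'
#' Ratio of means, reported with its direction.
#'
#' @param summary_a,summary_b single rows of a `group_stats` data.frame,
#'   lists with a `mean` element, or bare positive numbers.
#' @return list with `ratio` (`mean_a / mean_b`), `direction`
#'   (`"increase"`, `"decrease"` or `"none"`) and `fold` (the ratio folded
#'   to be ≥ 1, the way "1.8-fold decrease" is usually printed).
#' @export
fold_change <- function(summary_a, summary_b) {
  get_mean <- function(x) {
    if (is.numeric(x) && length(x) == 1L) return(x)
    if (is.data.frame(x)) { stopifnot(nrow(x) == 1L); return(x$mean) }
    if (is.list(x) && !is.null(x$mean)) return(x$mean)
    stop("cannot extract a mean", call. = FALSE)
  }
  a <- get_mean(summary_a); b <- get_mean(summary_b)
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("fold_change() requires positive means", call. = FALSE)
  ratio <- a / b
  list(ratio = ratio,
       direction = if (ratio > 1) "increase" else if (ratio < 1) "decrease" else "none",
       fold = max(ratio, 1 / ratio))
}

#' Format group statistics as "mean ± SD" strings with significance stars
#'
#' @param stats a `group_stats` data.frame.
#' @param digits decimal places (default 2, matching how transfer tables
#'   are usually printed).
#' @return named character vector, one entry per group; significant groups
#'   carry a trailing `*`.
#' @export
format_group_table <- function(stats, digits = 2) {
  stopifnot(inherits(stats, "group_stats"))
  stats::setNames(
    sprintf(paste0("%.", digits, "f ± %.", digits, "f%s"),
            stats$mean, stats$sd, ifelse(stats$significant, "*", "")),
    stats$group)
}

#' Tracer transfer summary table (genotype × direction × treatment)
#'
#' Computes per-plant transfer percentages, runs [compare_groups()] within
#' each (direction, treatment) cell with genotypes as groups, and lays the
#' results out as a "mean ± SD" matrix with stars against the reference.
#'
#' @param tracer data.frame of tracer measurements with columns `plant_id`,
#'   `genotype`, `treatment`, `direction`, `cpm_shoot`, `cpm_root`.
#' @param reference reference genotype (default `"WT"`).
#' @param alpha significance level.
#' @return list with `table` (data.frame, genotypes × direction:treatment
#'   cells) and `stats` (list of `group_stats` per cell).
#' @export
tracer_table <- function(tracer, reference = "WT", alpha = 0.05) {
  tracer$percent <- transfer_percent(tracer)
  cells <- unique(tracer[c("direction", "treatment")])
  genotypes <- unique(tracer$genotype)
  tab <- data.frame(genotype = genotypes, stringsAsFactors = FALSE)
  stats_list <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- tracer$direction == cells$direction[i] &
      tracer$treatment == cells$treatment[i]
    gs <- compare_groups(data.frame(group = tracer$genotype[sel],
                                    value = tracer$percent[sel]),
                         reference = reference, alpha = alpha)
    label <- paste(cells$direction[i], cells$treatment[i], sep = ".")
    stats_list[[label]] <- gs
    fmt <- format_group_table(gs)
    tab[[label]] <- unname(fmt[match(genotypes, names(fmt))])
  }
  list(table = tab, stats = stats_list)
}

#' Write group statistics as TSV
#'
#' @param x a `group_stats` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_group_stats_tsv <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}
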