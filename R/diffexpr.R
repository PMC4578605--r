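# Fold-change differential-expression calling and classification of each
# responsive gene's dependence on the depleted factor.

#' Differential-expression calling configuration
#'
#' A gene is called induced when its combined expression ratio is strictly
#' higher than `up_threshold` and repressed when strictly lower than
#' `down_threshold`.
#'
#' @param up_threshold Ratio above which a gene is called up (default 2.0).
#' @param down_threshold Ratio below which a gene is called down
#'   (default 0.50).
#' @return A list of class `de_config`.
#' @export
de_config <- function(up_threshold = 2.0, down_threshold = 0.50) {
  if (!(up_threshold > 1 && 1 > down_threshold && down_threshold > 0))
    stop("configuration error: need up_threshold > 1 > down_threshold > 0")
  structure(list(up_threshold = up_threshold,
                 down_threshold = down_threshold),
            class = "de_config")
}

#' Call up-/down-regulated genes for one comparison
#'
#' @param table A gene expression table (see [combine_to_gene_table()]).
#' @param comparison_id Comparison to call.
#' @param cfg A [de_config()].
#' @return A list of class `de_gene_set`: `comparison_id`, `up` and `down`
#'   (character vectors of gene ids), `n_valid`.
#' @export
call_de <- function(table, comparison_id, cfg = de_config()) {
  sub <- table[table$comparison_id == comparison_id, ]
  if (nrow(sub) == 0L)
    stop("unknown comparison: ", comparison_id)
  valid <- sub[sub$valid & !is.na(sub$ratio), ]
  structure(list(comparison_id = comparison_id,
                 up = sort(valid$gene_id[valid$ratio > cfg$up_threshold]),
                 down = sort(valid$gene_id[valid$ratio < cfg$down_threshold]),
                 n_valid = nrow(valid)),
            class = "de_gene_set")
}

#' @export
print.de_gene_set <- function(x, ...) {
  cat(sprintf("de_gene_set %s: %d up, %d down (of %d valid genes)\n",
              x$comparison_id, length(x$up), length(x$down), x$n_valid))
  invisible(x)
}

#' Summarize differential-expression calls across comparisons
#'
#' @param desets A list of [call_de()] results.
#' @return Data.frame with per-comparison counts and the percentage of valid
#'   genes changed, rounded to 1 decimal (`NA` when no gene is valid).
#' @export
summarize_de <- function(desets) {
  if (inherits(desets, "de_gene_set")) desets <- list(desets)
  rows <- lapply(desets, function(d) {
    total <- length(d$up) + length(d$down)
    pct <- if (d$n_valid > 0) round(100 * total / d$n_valid, 1) else NA_real_
    data.frame(comparison_id = d$comparison_id, n_up = length(d$up),
               n_down = length(d$down), n_changed = total,
               n_valid = d$n_valid, pct_changed = pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dependence-classification configuration
#'
#' The dependence ratio X compares a gene's response in the depleted mutant
#' with its response in the wild type.  Classes follow the published
#' intervals: weakly dependent for 0.67 > X >= 0.50, strongly dependent for
#' 0.50 > X > 0.25, totally dependent for X <= 0.25, independent for
#' X >= 0.67 (the unstated boundaries X = 0.50 and X = 0.67 are assigned to
#' the weaker-dependence side).  A special rule also classifies as totally
#' dependent any gene induced more than 2.5-fold in the wild type whose
#' mutant ratio stays below 1.3 (mirrored for repressed genes).
#'
#' @param wd_interval Weak-dependence interval (default `c(0.50, 0.67)`,
#'   closed at 0.50, open at 0.67).
#' @param sd_interval Strong-dependence interval (default `c(0.25, 0.50)`,
#'   open at both ends).
#' @param td_cutoff Total dependence for X at or below this value
#'   (default 0.25).
#' @param special_wt_fc,special_mut_fc Special-rule thresholds
#'   (defaults 2.5 and 1.3).
#' @param scale `"log2_ratio_of_fc"` (default; X is the ratio of log2 fold
#'   changes, symmetric for induction and repression) or `"linear_fc"` (X is
#'   the ratio of linear fold changes, mutant/wild-type for induced genes and
#'   wild-type/mutant for repressed genes).
#' @param mirror_special If `TRUE` (default) the special rule also applies,
#'   mirrored, to repressed genes.
#' @return A list of class `dependence_config`.
#' @export
dependence_config <- function(wd_interval = c(0.50, 0.67),
                              sd_interval = c(0.25, 0.50),
                              td_cutoff = 0.25,
                              special_wt_fc = 2.5, special_mut_fc = 1.3,
                              scale = c("log2_ratio_of_fc", "linear_fc"),
                              mirror_special = TRUE) {
  scale <- match.arg(scale)
  if (!(td_cutoff == sd_interval[1] && sd_interval[2] == wd_interval[1] &&
        wd_interval[1] < wd_interval[2]))
    stop("configuration error: class intervals must be ordered and abut: ",
         "td_cutoff = sd lower bound, sd upper = wd lower")
  if (!(special_wt_fc > special_mut_fc && special_mut_fc > 1))
    stop("configuration error: need special_wt_fc > special_mut_fc > 1")
  structure(list(wd_interval = wd_interval, sd_interval = sd_interval,
                 td_cutoff = td_cutoff, special_wt_fc = special_wt_fc,
                 special_mut_fc = special_mut_fc, scale = scale,
                 mirror_special = mirror_special),
            class = "dependence_config")
}

# class label from the dependence ratio X
.class_from_x <- function(x, cfg) {
  ifelse(x <= cfg$td_cutoff, "TD",
         ifelse(x < cfg$sd_interval[2], "SD",
                ifelse(x < cfg$wd_interval[2], "WD", "independent")))
}

#' Classify a responsive gene's dependence on the depleted factor
#'
#' For induced genes (wild-type ratio above the up threshold): the special
#' rule fires first — wild-type fold change above `special_wt_fc` with mutant
#' ratio below `special_mut_fc` means totally dependent.  Otherwise
#' `X = log2(fc_mut) / log2(fc_wt)` (or the linear-scale alternative); a
#' non-induced or inverted mutant response gives X <= 0 and is totally
#' dependent.  Repressed genes are handled by mirror symmetry: both log fold
#' changes are negative for a confirming response, so X is again positive,
#' and the mirrored special rule is `fc_wt < 1/special_wt_fc` with
#' `fc_mut > 1/special_mut_fc`.
#'
#' Vectorized over genes.
#'
#' @param fc_wt,fc_mut Linear expression ratios in the wild-type and mutant
#'   comparisons.  Every `fc_wt` must be responsive (above the up threshold
#'   or below the down threshold of `de_cfg`).
#' @param cfg A [dependence_config()].
#' @param de_cfg A [de_config()] supplying the responsiveness thresholds.
#' @param gene_id Optional gene identifiers carried into the result.
#' @return Data.frame of dependence calls: `gene_id`, `direction`, `fc_wt`,
#'   `fc_mut`, `X`, `class`, `special_rule_fired`.
#' @export
classify_dependence <- function(fc_wt, fc_mut, cfg = dependence_config(),
                                de_cfg = de_config(),
                                gene_id = as.character(seq_along(fc_wt))) {
  stopifnot(length(fc_wt) == length(fc_mut), all(fc_wt > 0), all(fc_mut > 0))
  up <- fc_wt > de_cfg$up_threshold
  down <- fc_wt < de_cfg$down_threshold
  if (any(!up & !down))
    stop("precondition error: gene(s) not responsive in the wild type: ",
         paste(utils::head(gene_id[!up & !down], 5), collapse = ", "))
  direction <- ifelse(up, "up", "down")
  special <- ifelse(up,
                    fc_wt > cfg$special_wt_fc & fc_mut < cfg$special_mut_fc,
                    cfg$mirror_special &
                      fc_wt < 1 / cfg$special_wt_fc &
                      fc_mut > 1 / cfg$special_mut_fc)
  if (cfg$scale == "log2_ratio_of_fc") {
    x <- log2(fc_mut) / log2(fc_wt)
  } else {
    x <- ifelse(up, fc_mut / fc_wt, fc_wt / fc_mut)
  }
  cls <- .class_from_x(x, cfg)
  cls[special] <- "TD"
  data.frame(gene_id = gene_id, direction = direction,
             fc_wt = fc_wt, fc_mut = fc_mut, X = x, class = cls,
             special_rule_fired = special, stringsAsFactors = FALSE)
}

#' Dependence calls for all wild-type-responsive genes of a comparison pair
#'
#' Joins the gene expression table on the wild-type and mutant comparisons,
#' restricts to genes valid in both, classifies those responsive in the wild
#' type, and reports genes responsive only in the mutant separately (they are
#' not classified).
#'
#' @param table A gene expression table covering both comparisons.
#' @param wt_comparison,mut_comparison Comparison ids of the wild-type and
#'   mutant responses.
#' @param cfg A [dependence_config()].
#' @param de_cfg A [de_config()].
#' @return A list of class `dependence_calls`: `calls` (the classification
#'   data.frame), `mutant_only` (ids responsive only in the mutant),
#'   `n_both_valid`.
#' @export
dependence_calls <- function(table, wt_comparison, mut_comparison,
                             cfg = dependence_config(),
                             de_cfg = de_config()) {
  wt <- table[table$comparison_id == wt_comparison & table$valid, ]
  mut <- table[table$comparison_id == mut_comparison & table$valid, ]
  if (nrow(wt) == 0L) stop("unknown or empty comparison: ", wt_comparison)
  if (nrow(mut) == 0L) stop("unknown or empty comparison: ", mut_comparison)
  shared <- intersect(wt$gene_id, mut$gene_id)
  fc_wt <- wt$ratio[match(shared, wt$gene_id)]
  fc_mut <- mut$ratio[match(shared, mut$gene_id)]
  responsive <- fc_wt > de_cfg$up_threshold | fc_wt < de_cfg$down_threshold
  mut_responsive <- fc_mut > de_cfg$up_threshold |
    fc_mut < de_cfg$down_threshold
  calls <- if (any(responsive)) {
    classify_dependence(fc_wt[responsive], fc_mut[responsive], cfg, de_cfg,
                        gene_id = shared[responsive])
  } else {
    classify_dependence(numeric(), numeric(), cfg, de_cfg,
                        gene_id = character())
  }
  structure(list(calls = calls,
                 mutant_only = sort(shared[mut_responsive & !responsive]),
                 n_both_valid = length(shared)),
            class = "dependence_calls")
}

#' Summarize dependence calls
#'
#' @param calls A `dependence_calls` object or its `calls` data.frame.
#' @return A list with `by_class` (counts and percentages per class and
#'   direction), `n_responsive`, `n_dependent` (WD+SD+TD) and
#'   `pct_dependent` (1 decimal; `NA` when there are no responsive genes).
#' @export
dependence_summary <- function(calls) {
  if (inherits(calls, "dependence_calls")) calls <- calls$calls
  classes <- c("independent", "WD", "SD", "TD")
  n <- nrow(calls)
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    sub <- calls[calls$class == cl, ]
    data.frame(class = cl, n = nrow(sub),
               n_up = sum(sub$direction == "up"),
               n_down = sum(sub$direction == "down"),
               pct = if (n > 0) round(100 * nrow(sub) / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  n_dep <- sum(calls$class != "independent")
  list(by_class = by_class, n_responsive = n, n_dependent = n_dep,
       pct_dependent = if (n > 0) round(100 * n_dep / n, 1) else NA_real_)
}

#' Venn overlap of two differential-expression gene sets
#'
#' Counts genes unique to each set and shared, per direction, restricted to
#' genes valid in both comparisons when a gene expression table is supplied.
#'
#' @param set_a,set_b Two [call_de()] results.
#' @param table Optional gene expression table used to restrict the
#'   comparison to genes valid in both comparisons.
#' @return A list with `up` and `down`, each `c(only_a, shared, only_b)`.
#' @export
venn_overlap <- function(set_a, set_b, table = NULL) {
  restrict <- function(g) {
    if (is.null(table)) return(g)
    va <- table$gene_id[table$comparison_id == set_a$comparison_id &
                          table$valid]
    vb <- table$gene_id[table$comparison_id == set_b$comparison_id &
                          table$valid]
    intersect(g, intersect(va, vb))
  }
  one <- function(a, b) {
    a <- restrict(a); b <- restrict(b)
    c(only_a = length(setdiff(a, b)), shared = length(intersect(a, b)),
      only_b = length(setdiff(b, a)))
  }
  list(up = one(set_a$up, set_b$up), down = one(set_a$down, set_b$down))
}
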