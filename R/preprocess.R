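# Spot QC, orientation-corrected log2 ratios, per-array median normalization,
# and combining duplicate spots + dye-swap replicas into one expression value
# per gene per comparison.

#' Quality-control and preprocessing configuration
#'
#' Defaults implement the platform's spot-exclusion rule: spots with a
#' diameter below 120 micrometres, or with both channel foregrounds below 150
#' fluorescence units, are discarded.  All inequalities are strict, so a spot
#' sitting exactly on a threshold passes.
#'
#' @param min_diameter_um Minimum spot diameter in micrometres (default 120).
#' @param min_intensity Minimum foreground fluorescence (default 150).
#' @param intensity_rule `"both_below"` (fail only when both channels are
#'   below `min_intensity`; the default, a literal reading of the rule) or
#'   `"either_below"`.
#' @param background_subtract If `TRUE`, use `max(foreground - background, 1)`
#'   when computing ratios.  Off by default.
#' @param normalize If `TRUE` (default), median-center the passing-spot log2
#'   ratios of each array before combining.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_diameter_um = 120, min_intensity = 150,
                      intensity_rule = c("both_below", "either_below"),
                      background_subtract = FALSE, normalize = TRUE) {
  intensity_rule <- match.arg(intensity_rule)
  stopifnot(min_diameter_um > 0, min_intensity > 0,
            is.logical(background_subtract), is.logical(normalize))
  structure(list(min_diameter_um = min_diameter_um,
                 min_intensity = min_intensity,
                 intensity_rule = intensity_rule,
                 background_subtract = background_subtract,
                 normalize = normalize),
            class = "qc_config")
}

#' Apply spot quality control to an array scan
#'
#' A spot fails when its diameter is strictly below the cutoff, when its
#' foreground medians fall below the intensity cutoff under the configured
#' rule, or when it carries a negative (manually flagged) `flags` value.
#'
#' @param scan An [array_scan()].
#' @param qc A [qc_config()].
#' @return The scan with a logical `qc_pass` column added to its spot table.
#' @export
qc_filter <- function(scan, qc = qc_config()) {
  stopifnot(inherits(scan, "array_scan"), inherits(qc, "qc_config"))
  s <- scan$spots
  dim_fail <- if (qc$intensity_rule == "both_below") {
    s$f635 < qc$min_intensity & s$f532 < qc$min_intensity
  } else {
    s$f635 < qc$min_intensity | s$f532 < qc$min_intensity
  }
  s$qc_pass <- !(s$diameter_um < qc$min_diameter_um | dim_fail | s$flags < 0L)
  scan$spots <- s
  scan
}

#' Orientation-corrected spot log2 ratio (test / reference)
#'
#' In forward orientation the test sample is in the 635 nm channel, so the
#' ratio is `log2(F635/F532)`; in swapped orientation the channels trade
#' roles and the ratio is `log2(F532/F635)`.  With background subtraction
#' enabled, each foreground is replaced by `max(foreground - background, 1)`.
#' Spots whose corrected intensity is non-positive get `NA` (demoted to fail).
#'
#' @param spots Spot table (rows of an [array_scan()]).
#' @param orientation `"forward"` or `"swapped"`.
#' @param qc A [qc_config()].
#' @return Numeric vector of log2 ratios, `NA` where undefined.
#' @export
spot_log2_ratio <- function(spots, orientation, qc = qc_config()) {
  orientation <- match.arg(orientation, c("forward", "swapped"))
  f635 <- spots$f635
  f532 <- spots$f532
  if (qc$background_subtract) {
    f635 <- pmax(f635 - spots$b635, 1)
    f532 <- pmax(f532 - spots$b532, 1)
  }
  ok <- f635 > 0 & f532 > 0
  out <- rep(NA_real_, nrow(spots))
  lr <- log2(f635[ok]) - log2(f532[ok])
  out[ok] <- if (orientation == "forward") lr else -lr
  out
}

#' Median-center the log2 ratios of one array
#'
#' Subtracts the median of the passing-spot log2 ratios, so the centered
#' passing ratios have median zero.  Centering is idempotent.
#'
#' @param log2_ratios Numeric vector of per-spot log2 ratios (`NA` allowed).
#' @param pass Logical vector marking spots that passed QC; the median is
#'   taken over passing spots only, but the shift is applied to all.
#' @return Centered numeric vector.
#' @export
normalize_array <- function(log2_ratios, pass = !is.na(log2_ratios)) {
  med <- stats::median(log2_ratios[pass & !is.na(log2_ratios)])
  if (is.na(med)) return(log2_ratios)
  log2_ratios - med
}

#' Combine a dye-swap pair into per-gene expression values
#'
#' For each gene: the mean of passing-spot log2 ratios within each array, then
#' the unweighted mean of the two array values (replica-level averaging).  A
#' gene is valid for the comparison only if it has at least one passing spot
#' on EACH of the two arrays — a one-armed gene has no dye-bias cancellation
#' and carries no value.  Control spots (`gene_id` `"EMPTY"` or blank) are
#' skipped.
#'
#' @param forward,swapped The two [array_scan()]s of one comparison, in
#'   `"forward"` and `"swapped"` orientation respectively.
#' @param qc A [qc_config()]; its `normalize` flag controls per-array median
#'   centering, `combine` the replica-combining scheme.
#' @param combine `"mean_of_means"` (default; replica-level averaging) or
#'   `"pooled"` (mean over all passing spots of both arrays).
#' @return A data.frame (the gene expression table for one comparison) with
#'   columns `gene_id`, `comparison_id`, `log2_ratio`, `ratio`, `valid`,
#'   `n_spots_forward`, `n_spots_swapped`.  Invalid entries carry `NA`
#'   ratios.
#' @export
combine_to_gene_table <- function(forward, swapped, qc = qc_config(),
                                  combine = c("mean_of_means", "pooled")) {
  combine <- match.arg(combine)
  stopifnot(inherits(forward, "array_scan"), inherits(swapped, "array_scan"))
  if (forward$orientation != "forward" || swapped$orientation != "swapped")
    stop("design pairing violation: expected one forward and one swapped scan")
  if (forward$comparison_id != swapped$comparison_id)
    stop("design pairing violation: scans belong to different comparisons (",
         forward$comparison_id, ", ", swapped$comparison_id, ")")

  per_array <- lapply(list(forward, swapped), function(scan) {
    scan <- qc_filter(scan, qc)
    s <- scan$spots
    lr <- spot_log2_ratio(s, scan$orientation, qc)
    pass <- s$qc_pass & !is.na(lr)
    if (qc$normalize && any(pass)) lr <- normalize_array(lr, pass)
    keep <- pass & !(s$gene_id %in% c("", "EMPTY"))
    data.frame(gene_id = s$gene_id[keep], log2_ratio = lr[keep],
               stringsAsFactors = FALSE)
  })

  genes <- sort(unique(c(
    forward$spots$gene_id, swapped$spots$gene_id)))
  genes <- setdiff(genes, c("", "EMPTY"))

  agg <- lapply(per_array, function(d) {
    n <- tapply(d$log2_ratio, factor(d$gene_id, levels = genes), length)
    m <- tapply(d$log2_ratio, factor(d$gene_id, levels = genes), mean)
    s <- tapply(d$log2_ratio, factor(d$gene_id, levels = genes), sum)
    list(n = ifelse(is.na(n), 0L, n), mean = m, sum = s)
  })
  n_f <- as.integer(agg[[1L]]$n); n_s <- as.integer(agg[[2L]]$n)
  valid <- n_f >= 1L & n_s >= 1L
  log2_ratio <- rep(NA_real_, length(genes))
  if (combine == "mean_of_means") {
    log2_ratio[valid] <- (agg[[1L]]$mean[valid] + agg[[2L]]$mean[valid]) / 2
  } else {
    log2_ratio[valid] <- (agg[[1L]]$sum[valid] + agg[[2L]]$sum[valid]) /
      (n_f[valid] + n_s[valid])
  }
  data.frame(gene_id = genes,
             comparison_id = forward$comparison_id,
             log2_ratio = log2_ratio,
             ratio = 2^log2_ratio,
             valid = valid,
             n_spots_forward = n_f,
             n_spots_swapped = n_s,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the full gene expression table from a design table
#'
#' Reads every array file referenced by the design, combines each dye-swap
#' pair with [combine_to_gene_table()], and stacks the per-comparison tables.
#'
#' @param design A `design_table` from [read_design()].
#' @param qc A [qc_config()].
#' @param base_dir Directory that relative `path` entries are resolved
#'   against (default `"."`).
#' @param ... Passed on to [combine_to_gene_table()].
#' @return A gene expression table covering all comparisons in the design.
#' @export
build_gene_table <- function(design, qc = qc_config(), base_dir = ".", ...) {
  tables <- lapply(unique(design$comparison_id), function(cmp) {
    sub <- design[design$comparison_id == cmp, ]
    resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
    fwd <- read_gpr(resolve(sub$path[sub$orientation == "forward"]))
    swp <- read_gpr(resolve(sub$path[sub$orientation == "swapped"]))
    combine_to_gene_table(fwd, swp, qc, ...)
  })
  do.call(rbind, tables)
}

#' Write a gene expression table as TSV
#'
#' @param table A gene expression table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(table, path) {
  out <- table
  out$log2_ratio <- ifelse(is.na(out$log2_ratio), "NA",
                           sprintf("%.6f", out$log2_ratio))
  out$ratio <- ifelse(is.na(out$ratio), "NA", sprintf("%.6f", out$ratio))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
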