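# End-to-end orchestration: from a design table and annotation files to a
# report bundle (gene table, DE calls, dependence calls, enrichments,
# regressions, clusters, summary), plus the simulation-based recovery
# benchmark.

#' Pipeline configuration
#'
#' Collects everything one run needs.  Paths are resolved against
#' `base_dir`.  Validation checks that referenced files exist and that the
#' dependence pairing names comparisons present in the design.
#'
#' @param design Path to the design TSV (see [read_design()]).
#' @param out_dir Output directory for the report bundle.
#' @param base_dir Directory paths are resolved against (default: the
#'   design file's directory).
#' @param qc A [qc_config()].
#' @param de A [de_config()].
#' @param dep A [dependence_config()].
#' @param comparisons Comparison ids to analyze (default: all in design).
#' @param dependence_pairing `list(wt = <comparison_id>,
#'   mut = <comparison_id>)` to classify mutant-vs-wild-type dependence, or
#'   `NULL` to skip.
#' @param categories,tf_targets,paralog_pairs,universe Optional annotation
#'   file paths (see the `read_*` helpers).
#' @param cluster If `TRUE` (default), cluster the DE genes.
#' @param seed Integer seed echoed into the report (the pipeline itself is
#'   deterministic; the seed matters for simulated inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design, out_dir, base_dir = dirname(design),
                            qc = qc_config(), de = de_config(),
                            dep = dependence_config(), comparisons = NULL,
                            dependence_pairing = NULL, categories = NULL,
                            tf_targets = NULL, paralog_pairs = NULL,
                            universe = NULL, cluster = TRUE, seed = 1L) {
  cfg <- structure(list(design = design, out_dir = out_dir,
                        base_dir = base_dir, qc = qc, de = de, dep = dep,
                        comparisons = comparisons,
                        dependence_pairing = dependence_pairing,
                        categories = categories, tf_targets = tf_targets,
                        paralog_pairs = paralog_pairs, universe = universe,
                        cluster = isTRUE(cluster), seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg A [pipeline_config()] (or conforming list).
#' @return `cfg`, invisibly; errors name the offending entity.
#' @export
validate_pipeline_config <- function(cfg) {
  resolve <- function(p) if (file.exists(p)) p else file.path(cfg$base_dir, p)
  for (f in c("design", "categories", "tf_targets", "paralog_pairs",
              "universe")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(resolve(p)))
      stop("configuration error: ", f, " file not found: ", p)
  }
  design <- read_design(resolve(cfg$design))
  cmps <- unique(design$comparison_id)
  for (cmp in cfg$comparisons)
    if (!cmp %in% cmps)
      stop("configuration error: comparison not in design: ", cmp)
  pairing <- cfg$dependence_pairing
  if (!is.null(pairing)) {
    for (cmp in c(pairing$wt, pairing$mut))
      if (!cmp %in% cmps)
        stop("configuration error: dependence pairing references unknown ",
             "comparison: ", cmp)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `qc`, `de` and
#' `dep` are nested maps passed to their constructors.
#'
#' @param path Path to the YAML config.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, if (is.null(args)) list()
                                        else args)
  out_dir <- y[["out_dir"]]
  if (!is.null(out_dir) && !startsWith(out_dir, "/"))
    out_dir <- file.path(dirname(path), out_dir)
  # [[ indexing throughout: $ would partially match (e.g. $de -> $design)
  pipeline_config(
    design = y[["design"]],
    out_dir = out_dir,
    base_dir = if (is.null(y[["base_dir"]])) dirname(path)
               else y[["base_dir"]],
    qc = build(qc_config, y[["qc"]]), de = build(de_config, y[["de"]]),
    dep = build(dependence_config, y[["dep"]]),
    comparisons = unlist(y[["comparisons"]]),
    dependence_pairing = y[["dependence_pairing"]],
    categories = y[["categories"]], tf_targets = y[["tf_targets"]],
    paralog_pairs = y[["paralog_pairs"]], universe = y[["universe"]],
    cluster = if (is.null(y[["cluster"]])) TRUE else y[["cluster"]],
    seed = if (is.null(y[["seed"]])) 1L else y[["seed"]])
}

.stage <- function(name, expr, log) {
  log(sprintf("[%s] start", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — design validation, gene-table
#' construction, DE calling, dependence classification, enrichment,
#' regression, clustering — and writes the report bundle into
#' `cfg$out_dir`: `gene_table.tsv`, `de_calls.tsv`, `de_summary.tsv`,
#' `dependence.tsv`, `enrichment_*.tsv`, `tf_ranking_*.tsv`,
#' `regression.txt`, `clusters.cdt`/`.gtr`, `merges.tsv` and `summary.txt`.
#' The run is deterministic given inputs and seed; the configuration is
#' echoed into the summary for provenance.
#'
#' @param cfg A [pipeline_config()].
#' @param validate_only If `TRUE`, validate the configuration and design and
#'   return without writing any output.
#' @param quiet Suppress stage log messages.
#' @return Invisibly, a list with the in-memory results (`gene_table`,
#'   `desets`, `de_summary`, `dependence`, `enrichment`, `regressions`,
#'   `dendrogram`).
#' @export
run_pipeline <- function(cfg, validate_only = FALSE, quiet = FALSE) {
  log <- if (quiet) function(...) invisible() else function(m) message(m)
  validate_pipeline_config(cfg)
  resolve <- function(p) if (file.exists(p)) p else file.path(cfg$base_dir, p)
  design <- read_design(resolve(cfg$design))
  if (validate_only) return(invisible(NULL))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)

  table <- .stage("gene_table", {
    t <- build_gene_table(design, cfg$qc, base_dir = cfg$base_dir)
    write_gene_table(t, out("gene_table.tsv"))
    log(sprintf("[gene_table] %d gene/comparison entries, %d valid",
                nrow(t), sum(t$valid)))
    t
  }, log)

  comparisons <- cfg$comparisons
  if (is.null(comparisons)) comparisons <- unique(design$comparison_id)

  desets <- .stage("de_calls", {
    d <- lapply(comparisons, function(cmp) call_de(table, cmp, cfg$de))
    names(d) <- comparisons
    calls <- do.call(rbind, lapply(d, function(s) {
      sub <- table[table$comparison_id == s$comparison_id & table$valid, ]
      sub$call <- ifelse(sub$gene_id %in% s$up, "up",
                         ifelse(sub$gene_id %in% s$down, "down", "none"))
      sub[c("gene_id", "comparison_id", "ratio", "call")]
    }))
    utils::write.table(calls, out("de_calls.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    d
  }, log)

  de_summary <- .stage("de_summary", {
    s <- summarize_de(desets)
    utils::write.table(s, out("de_summary.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    s
  }, log)

  dependence <- NULL
  if (!is.null(cfg$dependence_pairing)) {
    dependence <- .stage("dependence", {
      dc <- dependence_calls(table, cfg$dependence_pairing$wt,
                             cfg$dependence_pairing$mut, cfg$dep, cfg$de)
      utils::write.table(dc$calls, out("dependence.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log(sprintf("[dependence] %d responsive genes classified, %d mutant-only",
                  nrow(dc$calls), length(dc$mutant_only)))
      dc
    }, log)
  }

  enrichment <- list()
  for (cmp in comparisons) {
    uni <- table$gene_id[table$comparison_id == cmp & table$valid]
    if (!is.null(cfg$universe))
      uni <- readLines(resolve(cfg$universe), warn = FALSE)
    query <- desets[[cmp]]$up
    if (length(query) == 0L) next
    if (!is.null(cfg$categories)) {
      enrichment[[paste0("categories_", cmp)]] <- .stage("enrichment", {
        res <- enrich(query, read_category_map(resolve(cfg$categories)), uni)
        utils::write.table(res, out(paste0("enrichment_", cmp, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res
      }, log)
    }
    if (!is.null(cfg$tf_targets)) {
      enrichment[[paste0("tf_", cmp)]] <- .stage("tf_ranking", {
        res <- rank_by_tf(query, read_tf_map(resolve(cfg$tf_targets)), uni)
        utils::write.table(res, out(paste0("tf_ranking_", cmp, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res
      }, log)
    }
  }

  regressions <- NULL
  if (!is.null(cfg$dependence_pairing)) {
    regressions <- .stage("regression", {
      wt_cmp <- cfg$dependence_pairing$wt; mut_cmp <- cfg$dependence_pairing$mut
      wt <- table[table$comparison_id == wt_cmp & table$valid, ]
      mut <- table[table$comparison_id == mut_cmp & table$valid, ]
      shared <- intersect(wt$gene_id, mut$gene_id)
      x <- wt$log2_ratio[match(shared, wt$gene_id)]
      y <- mut$log2_ratio[match(shared, mut$gene_id)]
      fits <- list()
      for (dir in c("up", "down")) {
        g <- desets[[wt_cmp]][[dir]]
        keep <- shared %in% g
        if (sum(keep) >= 2L && stats::var(x[keep]) > 0)
          fits[[dir]] <- fit_line(x[keep], y[keep])
      }
      lines <- vapply(names(fits), function(d) {
        f <- fits[[d]]
        sprintf("%s-regulated in %s vs %s: slope %.4f, intercept %.4f, R^2 %.4f, n %d",
                d, wt_cmp, mut_cmp, f$slope, f$intercept, f$r_squared,
                f$n_points)
      }, "")
      writeLines(lines, out("regression.txt"))
      fits
    }, log)
  }

  esr <- NULL
  if (!is.null(cfg$paralog_pairs)) {
    esr <- .stage("esr_contrast", {
      pairs <- read_paralog_pairs(resolve(cfg$paralog_pairs))
      res <- lapply(comparisons, function(cmp)
        esr_paralog_contrast(table, pairs, cmp))
      names(res) <- comparisons
      lines <- vapply(comparisons, function(cmp)
        sprintf("%s: ESR mean %.2f, paralog mean %.2f (n = %d pairs, %d dropped)",
                cmp, res[[cmp]]$esr_mean, res[[cmp]]$paralog_mean,
                res[[cmp]]$n_pairs, res[[cmp]]$n_dropped), "")
      writeLines(lines, out("esr_contrast.txt"))
      res
    }, log)
  }

  dendrogram <- NULL
  if (cfg$cluster && any(vapply(desets, function(d)
    length(d$up) + length(d$down), 0L) > 0)) {
    dendrogram <- .stage("cluster", {
      mat <- select_cluster_input(desets, table)
      if (nrow(mat) >= 2L) {
        dend <- hclust_complete(mat)
        write_cdt_gtr(dend, mat, out("clusters"))
        utils::write.table(
          cbind(node = sprintf("NODE%dX", seq_along(dend$height)),
                dend$merges),
          out("merges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        dend
      } else NULL
    }, log)
  }

  .stage("summary", {
    lines <- c("# pipeline summary", "", "## differential expression")
    for (i in seq_len(nrow(de_summary))) {
      s <- de_summary[i, ]
      lines <- c(lines, sprintf(
        "%s: %d up, %d down, %d changed (%s%% of %d genes with valid data)",
        s$comparison_id, s$n_up, s$n_down, s$n_changed,
        ifelse(is.na(s$pct_changed), "NA", format(s$pct_changed)), s$n_valid))
    }
    if (!is.null(dependence)) {
      ds <- dependence_summary(dependence)
      lines <- c(lines, "", "## dependence on the depleted factor",
                 sprintf("%d of %d responsive genes (%s%%) dependent (WD+SD+TD)",
                         ds$n_dependent, ds$n_responsive,
                         ifelse(is.na(ds$pct_dependent), "NA",
                                format(ds$pct_dependent))),
                 utils::capture.output(print(ds$by_class, row.names = FALSE)))
    }
    lines <- c(lines, "", "## configuration",
               utils::capture.output(utils::str(
                 cfg[c("design", "qc", "de", "dep", "comparisons",
                       "dependence_pairing", "seed")])))
    writeLines(lines, out("summary.txt"))
  }, log)

  invisible(list(gene_table = table, desets = desets,
                 de_summary = de_summary, dependence = dependence,
                 enrichment = enrichment, regressions = regressions,
                 esr = esr, dendrogram = dendrogram))
}

#' Null calibration of the enrichment p-value
#'
#' Draws random annotation sets and random query sets from a fixed universe
#' and records the fraction of repetitions with an enrichment p-value below
#' `alpha`.  For a calibrated (here: conservative, because discrete) test
#' this fraction must not exceed `alpha` beyond binomial noise.
#'
#' @param n_reps Repetitions (default 1000).
#' @param n_genes Universe size (default 1000).
#' @param set_size,query_size Sizes of the random annotation and query sets.
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed.
#' @return A list: `rate`, `alpha`, `n_reps`, `se` (binomial SE at `alpha`).
#' @export
calibrate_null <- function(n_reps = 1000L, n_genes = 1000L, set_size = 100L,
                           query_size = 50L, alpha = 0.05, seed = 1L) {
  set.seed(seed)
  universe <- sprintf("g%04d", seq_len(n_genes))
  p <- vapply(seq_len(n_reps), function(i) {
    set_genes <- sample(universe, set_size)
    query <- sample(universe, query_size)
    hypergeom_tail(n_genes, set_size, query_size,
                   length(intersect(set_genes, query)))
  }, 0.0)
  list(rate = mean(p < alpha), alpha = alpha, n_reps = n_reps,
       se = sqrt(alpha * (1 - alpha) / n_reps), p_values = p)
}

#' Simulation-based recovery benchmark
#'
#' Generates a synthetic experiment, runs the analysis, and scores it
#' against the planted truth: direction-aware DE recall and precision, and
#' (when a scenario is supplied) per-class dependence accuracy, plus a null
#' calibration of the enrichment p-value.
#'
#' @param config A [sim_config()].
#' @param scenario Optional [dependence_scenario()] for the heat-shock
#'   dependence benchmark.
#' @param qc A [qc_config()] (normalization on by default).
#' @param de_cfg A [de_config()].
#' @param dep_cfg A [dependence_config()].
#' @param floors Named list of minimum acceptable values; metrics below
#'   their floor are flagged.
#' @param calibration_reps Repetitions for the null calibration (default
#'   200; set 0 to skip).
#' @param out Optional path for a metrics TSV.
#' @return Data.frame of class `recovery_benchmark` with columns `metric`,
#'   `value`, `floor`, `pass`.
#' @export
run_recovery_benchmark <- function(config, scenario = NULL,
                                   qc = qc_config(), de_cfg = de_config(),
                                   dep_cfg = dependence_config(),
                                   floors = list(de_recall = 0.90,
                                                 de_precision = 0.90,
                                                 dependence_accuracy = 0.85,
                                                 calibration = NULL),
                                   calibration_reps = 200L, out = NULL) {
  universe <- generate_universe(config)
  truth <- plant_de_truth(universe, config, "bench")
  sim <- simulate_comparison(universe, truth, config)
  table <- combine_to_gene_table(sim$forward, sim$swapped, qc)
  des <- call_de(table, "bench", de_cfg)

  called <- c(stats::setNames(rep("up", length(des$up)), des$up),
              stats::setNames(rep("down", length(des$down)), des$down))
  truth_lab <- stats::setNames(truth$de_label, truth$gene_id)
  n_correct <- sum(truth_lab[names(called)] == called)
  n_planted <- sum(truth_lab != "none")
  metrics <- data.frame(
    metric = c("de_recall", "de_precision"),
    value = c(if (n_planted > 0) n_correct / n_planted else NA_real_,
              if (length(called) > 0) n_correct / length(called) else
                NA_real_),
    stringsAsFactors = FALSE)

  if (!is.null(scenario)) {
    hs <- simulate_heat_shock_experiment(universe, scenario, config)
    t_wt <- combine_to_gene_table(hs$comparisons$wt_heat$forward,
                                  hs$comparisons$wt_heat$swapped, qc)
    t_mut <- combine_to_gene_table(hs$comparisons$mut_heat$forward,
                                   hs$comparisons$mut_heat$swapped, qc)
    dc <- dependence_calls(rbind(t_wt, t_mut), "wt_heat", "mut_heat",
                           dep_cfg, de_cfg)
    acc <- dependence_class_accuracy(dc, hs$truth)
    metrics <- rbind(metrics, data.frame(
      metric = paste0("dependence_accuracy_", names(acc)),
      value = unname(acc), stringsAsFactors = FALSE))
  }

  if (calibration_reps > 0L) {
    cal <- calibrate_null(n_reps = calibration_reps, seed = config$seed)
    metrics <- rbind(metrics, data.frame(
      metric = "null_calibration_rate", value = cal$rate,
      stringsAsFactors = FALSE))
  }

  metrics$floor <- NA_real_
  metrics$floor[metrics$metric == "de_recall"] <-
    floors$de_recall %||% NA_real_
  metrics$floor[metrics$metric == "de_precision"] <-
    floors$de_precision %||% NA_real_
  metrics$floor[grepl("^dependence_accuracy", metrics$metric)] <-
    floors$dependence_accuracy %||% NA_real_
  metrics$pass <- is.na(metrics$floor) | metrics$value >= metrics$floor
  if (!is.null(out))
    utils::write.table(metrics, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  class(metrics) <- c("recovery_benchmark", class(metrics))
  metrics
}

#' Per-class dependence classification accuracy against planted truth
#'
#' @param dc A [dependence_calls()] result.
#' @param truth Truth table of a `sim_heat_shock` (columns `gene_id`,
#'   `dependence_label`, `special`).
#' @return Named numeric vector of accuracies for `independent`, `WD`, `SD`,
#'   `TD` and `TD_special` (planted classes with zero genes are dropped).
#' @export
dependence_class_accuracy <- function(dc, truth) {
  pred <- stats::setNames(dc$calls$class, dc$calls$gene_id)
  planted <- truth[!is.na(truth$dependence_label), ]
  grp <- ifelse(planted$special, "TD_special", planted$dependence_label)
  vapply(split(seq_len(nrow(planted)), grp), function(idx) {
    p <- pred[planted$gene_id[idx]]
    # an unclassified planted gene (invalid or not responsive) is an error
    mean(!is.na(p) & p == planted$dependence_label[idx])
  }, 0.0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
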