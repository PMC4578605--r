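# Synthetic dye-swapped two-channel array experiments with known ground
# truth: planted fold changes, QC-failing spots, dye bias, and planted
# dependence-class structure for the mutant-vs-wild-type heat-shock design.

#' Simulation configuration
#'
#' Parameters of the synthetic two-channel array generator.  The noise model
#' is per-channel multiplicative log-normal (additive Gaussian in log2),
#' independent across spots and channels.  Dye bias is a single scalar
#' multiplying the 635 nm (Cy5) channel of every spot on every array; because
#' it follows the physical dye, dye-swap combining cancels it exactly.
#'
#' @param n_genes Number of genes on the array (>= 10).
#' @param spots_per_gene Duplicate spots per gene per array (default 2).
#' @param baseline_log2_mean,baseline_log2_sd Mean and sd of the per-spot
#'   log2 baseline intensity (defaults 10 and 1, i.e. typical foregrounds
#'   around 1000 fluorescence units, well above the 150-unit QC cutoff).
#' @param noise_sd Per-channel measurement noise sd in log2 units
#'   (default 0.2).
#' @param dye_bias Multiplicative factor applied to the Cy5 channel
#'   (default 1.5, a typical label-incorporation imbalance).
#' @param bad_spot_rate Probability a spot's diameter is drawn below the QC
#'   cutoff (default 0.02).
#' @param dim_spot_rate Probability both channels of a spot are scaled below
#'   the intensity cutoff (default 0.02).
#' @param frac_up,frac_down Fractions of genes planted as up-/down-regulated
#'   (defaults 0.10 and 0.05).
#' @param effect_log2_range Interval for |planted log2 fold change|; the
#'   lower bound must exceed 1 so planted effects stay away from the 2-fold
#'   calling boundary (default `c(1.5, 3)`).
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes, spots_per_gene = 2L,
                       baseline_log2_mean = 10, baseline_log2_sd = 1,
                       noise_sd = 0.2, dye_bias = 1.5,
                       bad_spot_rate = 0.02, dim_spot_rate = 0.02,
                       frac_up = 0.10, frac_down = 0.05,
                       effect_log2_range = c(1.5, 3), seed = 1L) {
  rates <- c(bad_spot_rate, dim_spot_rate, frac_up, frac_down)
  if (any(rates < 0 | rates > 1))
    stop("configuration error: all rates must lie in [0, 1]")
  if (frac_up + frac_down > 1)
    stop("configuration error: frac_up + frac_down must not exceed 1")
  if (n_genes < 10)
    stop("configuration error: n_genes must be at least 10")
  if (spots_per_gene < 1)
    stop("configuration error: spots_per_gene must be at least 1")
  if (length(effect_log2_range) != 2L || effect_log2_range[1] <= 1 ||
      diff(effect_log2_range) < 0)
    stop("configuration error: effect_log2_range must be an interval with ",
         "lower bound > 1")
  if (noise_sd < 0 || dye_bias <= 0)
    stop("configuration error: noise_sd >= 0 and dye_bias > 0 required")
  structure(list(n_genes = as.integer(n_genes),
                 spots_per_gene = as.integer(spots_per_gene),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_sd = noise_sd, dye_bias = dye_bias,
                 bad_spot_rate = bad_spot_rate,
                 dim_spot_rate = dim_spot_rate,
                 frac_up = frac_up, frac_down = frac_down,
                 effect_log2_range = effect_log2_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic gene universe with annotation fixtures
#'
#' Produces gene identifiers plus the annotation structures the downstream
#' statistics consume: a gene-to-category map (standing in for a functional
#' catalogue), a TF-to-target map (standing in for a regulatory database),
#' stress-response (ESR-like) flags, and one-to-one pairs of flagged genes
#' with non-flagged paralogs.
#'
#' @param config A [sim_config()].
#' @param n_categories Number of functional categories (0 allowed).
#' @param n_tfs Number of transcription factors.
#' @param esr_fraction Fraction of genes flagged as stress-response members
#'   (default 0.1).
#' @param paralog_fraction Fraction of flagged genes that get a non-flagged
#'   paralog partner (default 1).
#' @return A list of class `sim_universe` with elements `genes`,
#'   `categories` (gene_id, category_id, category_name), `tf_targets`
#'   (tf_name, target_gene_id), `esr_genes`, `paralog_pairs`
#'   (esr_gene, paralog_gene).
#' @export
generate_universe <- function(config, n_categories = 10L, n_tfs = 5L,
                              esr_fraction = 0.1, paralog_fraction = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (n_categories < 0 || n_tfs < 0)
    stop("configuration error: n_categories and n_tfs must be non-negative")
  if (esr_fraction < 0 || esr_fraction > 0.5)
    stop("configuration error: esr_fraction must lie in [0, 0.5]")
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(n))

  categories <- data.frame(gene_id = character(), category_id = character(),
                           category_name = character(),
                           stringsAsFactors = FALSE)
  if (n_categories > 0L) {
    cat_ids <- sprintf("CAT%02d", seq_len(n_categories))
    k <- sample(0:3, n, replace = TRUE, prob = c(0.2, 0.4, 0.3, 0.1))
    rows <- lapply(seq_len(n), function(i) {
      if (k[i] == 0L) return(NULL)
      data.frame(gene_id = genes[i],
                 category_id = sample(cat_ids, k[i]),
                 stringsAsFactors = FALSE)
    })
    categories <- do.call(rbind, c(rows, list(categories[0, 1:2])))
    if (is.null(categories))
      categories <- data.frame(gene_id = character(),
                               category_id = character(),
                               stringsAsFactors = FALSE)
    categories$category_name <- sub("CAT", "category_", categories$category_id)
    categories <- categories[order(categories$gene_id,
                                   categories$category_id), ]
    rownames(categories) <- NULL
  }

  tf_targets <- data.frame(tf_name = character(), target_gene_id = character(),
                           stringsAsFactors = FALSE)
  if (n_tfs > 0L) {
    tf_names <- sprintf("TF%02d", seq_len(n_tfs))
    rows <- lapply(tf_names, function(tf) {
      size <- max(1L, round(stats::runif(1, 0.05, 0.15) * n))
      data.frame(tf_name = tf, target_gene_id = sort(sample(genes, size)),
                 stringsAsFactors = FALSE)
    })
    tf_targets <- do.call(rbind, rows)
    rownames(tf_targets) <- NULL
  }

  n_esr <- round(esr_fraction * n)
  esr_genes <- sort(sample(genes, n_esr))
  n_pairs <- round(paralog_fraction * n_esr)
  paired_esr <- if (n_pairs > 0L) esr_genes[seq_len(n_pairs)] else character()
  partners <- if (n_pairs > 0L) {
    sample(setdiff(genes, esr_genes), n_pairs)
  } else character()
  paralog_pairs <- data.frame(esr_gene = paired_esr, paralog_gene = partners,
                              stringsAsFactors = FALSE)

  structure(list(genes = genes, categories = categories,
                 tf_targets = tf_targets, esr_genes = esr_genes,
                 paralog_pairs = paralog_pairs, config = config),
            class = "sim_universe")
}

#' Plant differential-expression truth for one comparison
#'
#' Randomly assigns `frac_up` of genes a positive and `frac_down` a negative
#' log2 fold change drawn uniformly (in absolute value) from
#' `effect_log2_range`; all other genes are null.
#'
#' @param universe A [generate_universe()] result.
#' @param config A [sim_config()].
#' @param comparison_id Comparison identifier recorded in the truth table.
#' @param seed Seed for the truth draw (default `config$seed`).
#' @return Truth data.frame: `gene_id`, `comparison_id`, `true_log2fc`,
#'   `de_label` (`"up"`, `"down"`, `"none"`).
#' @export
plant_de_truth <- function(universe, config, comparison_id = "cmp1",
                           seed = config$seed) {
  set.seed(seed)
  genes <- universe$genes
  n <- length(genes)
  n_up <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  chosen <- sample(genes, n_up + n_down)
  fc <- stats::setNames(rep(0, n), genes)
  rng <- config$effect_log2_range
  fc[chosen[seq_len(n_up)]] <- stats::runif(n_up, rng[1], rng[2])
  if (n_down > 0)
    fc[chosen[n_up + seq_len(n_down)]] <- -stats::runif(n_down, rng[1], rng[2])
  data.frame(gene_id = genes, comparison_id = comparison_id,
             true_log2fc = unname(fc),
             de_label = ifelse(fc > 0, "up", ifelse(fc < 0, "down", "none")),
             stringsAsFactors = FALSE)
}

# lay spots out on a single-block grid with unique (block, column, row)
.spot_grid <- function(n_spots, n_cols = 24L) {
  idx <- seq_len(n_spots) - 1L
  data.frame(block = 1L,
             column = idx %% n_cols + 1L,
             row = idx %/% n_cols + 1L)
}

# Simulate the spot table for one hybridization.  `test_log2` is the per-gene
# true log2 fold change (test over reference).  The Cy5 (635 nm) channel
# carries the dye bias on every array; in forward orientation it holds the
# test sample, in swapped orientation the reference.
.simulate_scan <- function(genes, test_log2, config, array_id, comparison_id,
                           orientation, background = 30) {
  n_spots <- length(genes) * config$spots_per_gene
  gene_idx <- rep(seq_along(genes), each = config$spots_per_gene)
  grid <- .spot_grid(n_spots)
  baseline <- 2^stats::rnorm(n_spots, config$baseline_log2_mean,
                             config$baseline_log2_sd)
  eps_test <- if (config$noise_sd > 0)
    stats::rnorm(n_spots, 0, config$noise_sd) else 0
  eps_ref <- if (config$noise_sd > 0)
    stats::rnorm(n_spots, 0, config$noise_sd) else 0
  test_int <- baseline * 2^(test_log2[gene_idx] + eps_test)
  ref_int <- baseline * 2^eps_ref
  if (orientation == "forward") {
    f635 <- test_int * config$dye_bias
    f532 <- ref_int
  } else {
    f635 <- ref_int * config$dye_bias
    f532 <- test_int
  }
  diameter <- rep(150, n_spots)
  bad <- stats::runif(n_spots) < config$bad_spot_rate
  diameter[bad] <- stats::runif(sum(bad), 60, 119)
  dim_spot <- stats::runif(n_spots) < config$dim_spot_rate
  if (any(dim_spot)) {
    scale <- 100 / pmax(f635[dim_spot], f532[dim_spot])
    f635[dim_spot] <- f635[dim_spot] * scale
    f532[dim_spot] <- f532[dim_spot] * scale
  }
  spots <- data.frame(block = grid$block, column = grid$column, row = grid$row,
                      name = genes[gene_idx], gene_id = genes[gene_idx],
                      diameter_um = diameter,
                      f635 = f635, b635 = background,
                      f532 = f532, b532 = background,
                      flags = 0L, stringsAsFactors = FALSE)
  array_scan(array_id, comparison_id, orientation, spots)
}

#' Simulate one dye-swapped comparison
#'
#' Generates the forward and swapped hybridizations of one comparison from a
#' per-gene truth table.  On the forward array the test sample sits in the
#' Cy5 (635 nm) channel at intensity
#' `baseline * 2^(true log2 FC) * dye_bias * noise`; the swapped array
#' exchanges the channel roles while the dye bias stays with the physical
#' Cy5 channel.  Bad spots get diameters in [60, 119] um; dim spots have both
#' channels scaled below the 150-unit intensity cutoff.
#'
#' @param universe A [generate_universe()] result.
#' @param truth A truth table from [plant_de_truth()] (or with the same
#'   columns), covering all genes.
#' @param config A [sim_config()].
#' @param comparison_id Comparison identifier (default taken from `truth`).
#' @param seed Seed for the measurement draw (default `config$seed`).
#' @return A list of class `sim_comparison`: `forward` and `swapped`
#'   [array_scan()]s plus the `truth` table.
#' @export
simulate_comparison <- function(universe, truth, config,
                                comparison_id = truth$comparison_id[1],
                                seed = config$seed) {
  stopifnot(inherits(universe, "sim_universe"), inherits(config, "sim_config"))
  if (!all(universe$genes %in% truth$gene_id))
    stop("truth table must cover every gene in the universe")
  fc <- truth$true_log2fc[match(universe$genes, truth$gene_id)]
  set.seed(seed)
  forward <- .simulate_scan(universe$genes, fc, config,
                            array_id = paste0(comparison_id, "_fwd"),
                            comparison_id = comparison_id,
                            orientation = "forward")
  swapped <- .simulate_scan(universe$genes, fc, config,
                            array_id = paste0(comparison_id, "_swp"),
                            comparison_id = comparison_id,
                            orientation = "swapped")
  structure(list(forward = forward, swapped = swapped, truth = truth),
            class = "sim_comparison")
}

#' Dependence-class scenario for the heat-shock design
#'
#' Defines how many genes to plant in each dependence class and the
#' attenuation ranges used to generate them.  For a responsive gene the
#' mutant log2 fold change is the wild-type log2 fold change times an
#' attenuation factor `a` drawn uniformly from the class's range.  The
#' default ranges sit strictly inside the classifier's class intervals so no
#' planted gene straddles a decision boundary.  Special totally-dependent
#' genes are generated directly: wild-type fold change above 2.5 and mutant
#' fold change below 1.3, the configuration in which the classifier's special
#' rule fires.
#'
#' @param n_independent,n_wd,n_sd,n_td,n_td_special Genes per class
#'   (defaults 100 each).
#' @param independent_range,wd_range,sd_range,td_range Attenuation intervals
#'   per class (defaults `[0.75, 0.95]`, `[0.56, 0.61]`, `[0.30, 0.45]`,
#'   `[0.02, 0.18]`).
#' @param wt_effect_log2_range Interval for the wild-type log2 fold change of
#'   responsive genes (default `c(1.5, 3)`; fold changes 2.8-8, safely above
#'   the 2-fold calling threshold).
#' @param special_wt_log2_range,special_mut_log2_range Log2 fold-change
#'   intervals for special-TD genes (defaults `c(1.6, 2.5)` i.e. WT fold
#'   change 3.0-5.7 > 2.5, and `c(0.05, 0.28)` i.e. mutant fold change
#'   1.04-1.21 < 1.3).
#' @param dep_cfg A [dependence_config()] whose class intervals the
#'   attenuation ranges are validated against.
#' @return A list of class `dependence_scenario`.
#' @export
dependence_scenario <- function(n_independent = 100L, n_wd = 100L,
                                n_sd = 100L, n_td = 100L, n_td_special = 100L,
                                independent_range = c(0.75, 0.95),
                                wd_range = c(0.56, 0.61),
                                sd_range = c(0.30, 0.45),
                                td_range = c(0.02, 0.18),
                                wt_effect_log2_range = c(1.5, 3),
                                special_wt_log2_range = c(1.6, 2.5),
                                special_mut_log2_range = c(0.05, 0.28),
                                dep_cfg = dependence_config()) {
  counts <- c(n_independent, n_wd, n_sd, n_td, n_td_special)
  if (any(counts < 0)) stop("configuration error: negative class count")
  inside <- function(rng, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    a <- if (lo_open) rng[1] > lo else rng[1] >= lo
    b <- if (hi_open) rng[2] < hi else rng[2] <= hi
    a && b && rng[1] <= rng[2]
  }
  if (!inside(independent_range, dep_cfg$wd_interval[2], Inf))
    stop("independent_range must lie at or above ", dep_cfg$wd_interval[2])
  if (!inside(wd_range, dep_cfg$wd_interval[1], dep_cfg$wd_interval[2],
              hi_open = TRUE))
    stop("wd_range must lie strictly inside the WD interval")
  if (!inside(sd_range, dep_cfg$sd_interval[1], dep_cfg$sd_interval[2],
              lo_open = TRUE, hi_open = TRUE))
    stop("sd_range must lie strictly inside the SD interval")
  if (!inside(td_range, 0, dep_cfg$td_cutoff, lo_open = TRUE))
    stop("td_range must lie strictly inside (0, ", dep_cfg$td_cutoff, "]")
  if (2^special_wt_log2_range[1] <= dep_cfg$special_wt_fc)
    stop("special_wt_log2_range must keep WT fold change above ",
         dep_cfg$special_wt_fc)
  if (2^special_mut_log2_range[2] >= dep_cfg$special_mut_fc)
    stop("special_mut_log2_range must keep mutant fold change below ",
         dep_cfg$special_mut_fc)
  structure(list(n_per_class = c(independent = n_independent, WD = n_wd,
                                 SD = n_sd, TD = n_td,
                                 TD_special = n_td_special),
                 independent_range = independent_range, wd_range = wd_range,
                 sd_range = sd_range, td_range = td_range,
                 wt_effect_log2_range = wt_effect_log2_range,
                 special_wt_log2_range = special_wt_log2_range,
                 special_mut_log2_range = special_mut_log2_range),
            class = "dependence_scenario")
}

#' Simulate the heat-shock dependence experiment
#'
#' Generates the two expression comparisons of the dependence design — the
#' wild-type strain heat-shocked vs unstressed (`"wt_heat"`) and the depleted
#' mutant heat-shocked vs unstressed (`"mut_heat"`) — as dye-swap array pairs
#' (four arrays in total), with class structure planted per the scenario.
#' For each responsive gene the mutant log2 fold change equals the wild-type
#' log2 fold change times an attenuation drawn from the gene's class range;
#' special-TD genes get wild-type fold change above 2.5 and mutant fold
#' change below 1.3.  Remaining genes are null in both strains.
#'
#' @param universe A [generate_universe()] result.
#' @param scenario A [dependence_scenario()].
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed`).
#' @return A list of class `sim_heat_shock`: `comparisons` (named list of
#'   [simulate_comparison()] results for `wt_heat` and `mut_heat`) and
#'   `truth` (gene_id, true_log2fc_wt, true_log2fc_mut, dependence_label,
#'   special).
#' @export
simulate_heat_shock_experiment <- function(universe, scenario, config,
                                           seed = config$seed) {
  stopifnot(inherits(universe, "sim_universe"),
            inherits(scenario, "dependence_scenario"),
            inherits(config, "sim_config"))
  n_class <- sum(scenario$n_per_class)
  genes <- universe$genes
  if (n_class > length(genes))
    stop("configuration error: class counts (", n_class,
         ") exceed n_genes (", length(genes), ")")
  set.seed(seed)
  chosen <- sample(genes, n_class)
  labels <- rep(names(scenario$n_per_class), scenario$n_per_class)
  wt <- stats::setNames(rep(0, length(genes)), genes)
  mut <- wt
  dep <- stats::setNames(rep(NA_character_, length(genes)), genes)
  special <- stats::setNames(rep(FALSE, length(genes)), genes)
  rngs <- list(independent = scenario$independent_range,
               WD = scenario$wd_range, SD = scenario$sd_range,
               TD = scenario$td_range)
  wrng <- scenario$wt_effect_log2_range
  for (cls in names(rngs)) {
    g <- chosen[labels == cls]
    if (length(g) == 0L) next
    wt[g] <- stats::runif(length(g), wrng[1], wrng[2])
    a <- stats::runif(length(g), rngs[[cls]][1], rngs[[cls]][2])
    mut[g] <- wt[g] * a
    dep[g] <- cls
  }
  g <- chosen[labels == "TD_special"]
  if (length(g) > 0L) {
    wt[g] <- stats::runif(length(g), scenario$special_wt_log2_range[1],
                          scenario$special_wt_log2_range[2])
    mut[g] <- stats::runif(length(g), scenario$special_mut_log2_range[1],
                           scenario$special_mut_log2_range[2])
    dep[g] <- "TD"           # the special rule is another route to TD
    special[g] <- TRUE
  }
  de_label <- function(fc) ifelse(fc > 1, "up", ifelse(fc < -1, "down", "none"))
  truth_wt <- data.frame(gene_id = genes, comparison_id = "wt_heat",
                         true_log2fc = unname(wt),
                         de_label = de_label(unname(wt)),
                         stringsAsFactors = FALSE)
  truth_mut <- data.frame(gene_id = genes, comparison_id = "mut_heat",
                          true_log2fc = unname(mut),
                          de_label = de_label(unname(mut)),
                          stringsAsFactors = FALSE)
  comparisons <- list(
    wt_heat = simulate_comparison(universe, truth_wt, config, "wt_heat",
                                  seed = seed + 1L),
    mut_heat = simulate_comparison(universe, truth_mut, config, "mut_heat",
                                   seed = seed + 2L))
  truth <- data.frame(gene_id = genes,
                      true_log2fc_wt = unname(wt),
                      true_log2fc_mut = unname(mut),
                      dependence_label = unname(dep),
                      special = unname(special),
                      stringsAsFactors = FALSE)
  structure(list(comparisons = comparisons, truth = truth,
                 scenario = scenario),
            class = "sim_heat_shock")
}

#' Write a simulated experiment to disk
#'
#' Writes every array as a GPR file, the design table, and the truth table
#' (TSV: gene_id, comparison_id, true_log2fc, de_label, dependence_label).
#'
#' @param comparisons A list of [simulate_comparison()] results (or a
#'   `sim_heat_shock`'s `comparisons` element).
#' @param dir Output directory (created if missing).
#' @param strain,condition Optional character vectors (one per comparison)
#'   recorded in the design table.
#' @param dependence_truth Optional `sim_heat_shock` truth table merged into
#'   the written truth file.
#' @return Paths of the written files, invisibly.
#' @export
write_simulation <- function(comparisons, dir, strain = NULL,
                             condition = NULL, dependence_truth = NULL) {
  if (inherits(comparisons, "sim_comparison"))
    comparisons <- list(comparisons)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(comparisons)
  if (is.null(strain)) strain <- rep("synthetic", n)
  if (is.null(condition)) condition <- rep("synthetic", n)
  rows <- list(); truths <- list(); paths <- character()
  for (i in seq_len(n)) {
    cmp <- comparisons[[i]]
    for (side in c("forward", "swapped")) {
      scan <- cmp[[side]]
      fname <- paste0(scan$array_id, ".gpr")
      write_gpr(scan, file.path(dir, fname))
      paths <- c(paths, file.path(dir, fname))
      rows[[length(rows) + 1L]] <- data.frame(
        comparison_id = scan$comparison_id, array_id = scan$array_id,
        orientation = scan$orientation, path = fname,
        strain = strain[i], condition = condition[i],
        stringsAsFactors = FALSE)
    }
    truths[[i]] <- cmp$truth
  }
  design <- as_design_table(do.call(rbind, rows))
  write_design(design, file.path(dir, "design.tsv"))
  truth <- do.call(rbind, truths)
  if (!is.null(dependence_truth)) {
    truth$dependence_label <-
      dependence_truth$dependence_label[match(truth$gene_id,
                                              dependence_truth$gene_id)]
    truth$special <-
      dependence_truth$special[match(truth$gene_id,
                                     dependence_truth$gene_id)]
  } else {
    truth$dependence_label <- NA_character_
    truth$special <- FALSE
  }
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, file.path(dir, c("design.tsv", "truth.tsv"))))
}

#' Write universe annotation fixtures to disk
#'
#' Emits the annotation formats consumed by the gene-set statistics:
#' `categories.tsv` (gene_id, category_id, category_name), `tf_targets.tsv`
#' (tf_name, target_gene_id), `esr_genes.txt` (one id per line),
#' `paralog_pairs.tsv` (esr_gene, paralog_gene) and `universe.txt`.
#'
#' @param universe A [generate_universe()] result.
#' @param dir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_annotations <- function(universe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, c("categories.tsv", "tf_targets.tsv", "esr_genes.txt",
                        "paralog_pairs.tsv", "universe.txt"))
  utils::write.table(universe$categories, p[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(universe$tf_targets, p[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(universe$esr_genes, p[3])
  utils::write.table(universe$paralog_pairs, p[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(universe$genes, p[5])
  invisible(p)
}
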