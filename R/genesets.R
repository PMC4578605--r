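# Gene-set overrepresentation (hypergeometric upper tail, fold over
# expected), transcription-factor target ranking, published-list overlap,
# stress-response paralog contrast, and cross-experiment regression.

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `n_overlap` members of a set of size
#' `n_set` in a random draw of `n_query` genes from a universe of
#' `n_universe` — the overrepresentation p-value used for category and TF
#' enrichment.  Computed in log space (via the stable tail of the
#' hypergeometric distribution), exact for small universes.
#'
#' @param n_universe Universe size.
#' @param n_set Genes in the annotated set.
#' @param n_query Genes in the query list.
#' @param n_overlap Observed overlap.
#' @return P(overlap >= `n_overlap`).
#' @export
hypergeom_tail <- function(n_universe, n_set, n_query, n_overlap) {
  if (n_set > n_universe || n_query > n_universe ||
      n_overlap > min(n_set, n_query) || any(c(n_universe, n_set, n_query,
                                               n_overlap) < 0))
    stop("inconsistent counts for hypergeometric tail")
  stats::phyper(n_overlap - 1, n_set, n_universe - n_set, n_query,
                lower.tail = FALSE)
}

# one enrichment row: overlap, expected under independence, fold, tail p
.enrich_row <- function(set_name, set_genes, query, universe) {
  n_universe <- length(universe)
  set_genes <- intersect(set_genes, universe)
  n_set <- length(set_genes)
  n_query <- length(query)
  n_overlap <- length(intersect(set_genes, query))
  expected <- n_set * n_query / n_universe
  data.frame(set = set_name, n_universe = n_universe, n_set = n_set,
             n_query = n_query, n_overlap = n_overlap, expected = expected,
             fold = if (expected > 0) n_overlap / expected else NA_real_,
             p_value = hypergeom_tail(n_universe, n_set, n_query, n_overlap),
             stringsAsFactors = FALSE)
}

#' Gene-set enrichment of a query list against a collection
#'
#' One hypergeometric upper-tail test per set, with fold-over-expected
#' (`n_overlap / (n_set * n_query / n_universe)`), ranked by raw p-value with
#' a stable tie-break by set name.  Raw p-values are the primary statistic;
#' Benjamini-Hochberg adjusted values are reported alongside.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `universe`).
#' @param collection Named list of gene-id vectors, or a data.frame with
#'   columns `gene_id` and `category_id` (optionally `category_name`), or a
#'   TF map data.frame with `tf_name` and `target_gene_id`.
#' @param universe Character vector: the gene universe (typically the genes
#'   with valid data in the relevant comparison).
#' @return Data.frame of enrichment results, one row per set, ranked by p.
#' @export
enrich <- function(query, collection, universe) {
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  sets <- as_geneset_collection(collection)
  if (length(sets) == 0L)
    return(data.frame(set = character(), n_universe = integer(),
                      n_set = integer(), n_query = integer(),
                      n_overlap = integer(), expected = numeric(),
                      fold = numeric(), p_value = numeric(),
                      adjusted_p = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, lapply(names(sets), function(nm)
    .enrich_row(nm, sets[[nm]], query, universe)))
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set), ]
  rownames(res) <- NULL
  res
}

#' Coerce annotation inputs to a named list of gene sets
#'
#' @param collection A named list, a category map data.frame
#'   (`gene_id`, `category_id`) or a TF map data.frame
#'   (`tf_name`, `target_gene_id`).
#' @return Named list of character vectors.
#' @export
as_geneset_collection <- function(collection) {
  if (is.data.frame(collection)) {
    if (all(c("tf_name", "target_gene_id") %in% names(collection))) {
      return(split(collection$target_gene_id, collection$tf_name))
    }
    if (all(c("gene_id", "category_id") %in% names(collection))) {
      return(split(collection$gene_id, collection$category_id))
    }
    stop("unrecognized annotation data.frame")
  }
  stopifnot(is.list(collection))
  collection
}

#' Rank transcription factors by target overrepresentation
#'
#' Identical statistic to [enrich()] over a TF-to-target map, reported with
#' per-TF counts of target genes present in the query (the "number of target
#' genes" column of a TF ranking table).
#'
#' @param query Query gene ids.
#' @param tf_map TF map data.frame (`tf_name`, `target_gene_id`) or named
#'   list of target sets.
#' @param universe Gene universe.
#' @return Data.frame ranked by p with columns `tf`, `n_targets_in_query`,
#'   `n_targets`, `p_value`, `adjusted_p`, ...
#' @export
rank_by_tf <- function(query, tf_map, universe) {
  res <- enrich(query, tf_map, universe)
  out <- data.frame(tf = res$set, n_targets_in_query = res$n_overlap,
                    n_targets = res$n_set, expected = res$expected,
                    fold = res$fold, p_value = res$p_value,
                    adjusted_p = res$adjusted_p, stringsAsFactors = FALSE)
  out
}

#' Overlap enrichment of a query list with one reference list
#'
#' Observed overlap against the expected overlap under independence
#' (`|reference| * |query| / |universe|`), with fold enrichment and the
#' hypergeometric upper-tail p-value — the statistic behind statements like
#' "a 5-fold enrichment over the number expected for independent events".
#'
#' @param query Query gene ids.
#' @param reference_list Reference gene ids (e.g. a published
#'   stress-response list).
#' @param universe Gene universe.
#' @return One-row enrichment data.frame.
#' @export
overlap_enrichment <- function(query, reference_list, universe) {
  if (length(universe) == 0L) stop("empty universe")
  if (!all(query %in% universe) || !all(reference_list %in% universe))
    stop("query and reference must be subsets of the universe")
  res <- .enrich_row("reference", reference_list, unique(query), universe)
  res$adjusted_p <- res$p_value
  res
}

#' Mean expression-change contrast between paired gene sets
#'
#' For pairs of (stress-response gene, non-responsive paralog), compares the
#' mean combined log2 fold change of the two pair members in one comparison.
#' Pairs with either member invalid are dropped and counted.
#'
#' @param table A gene expression table.
#' @param pairs Data.frame with columns `esr_gene` and `paralog_gene`.
#' @param comparison_id Comparison to contrast.
#' @return A list: `esr_mean` and `paralog_mean` (full precision),
#'   `esr_mean_2dp`/`paralog_mean_2dp` (rounded to 2 decimals), `pairs`
#'   (per-pair values), `n_pairs`, `n_dropped`.  Means are `NA` when no pair
#'   is retained.
#' @export
esr_paralog_contrast <- function(table, pairs, comparison_id) {
  sub <- table[table$comparison_id == comparison_id & table$valid, ]
  val <- stats::setNames(sub$log2_ratio, sub$gene_id)
  esr <- val[pairs$esr_gene]
  par <- val[pairs$paralog_gene]
  keep <- !is.na(esr) & !is.na(par)
  per_pair <- data.frame(esr_gene = pairs$esr_gene[keep],
                         paralog_gene = pairs$paralog_gene[keep],
                         esr_log2 = unname(esr[keep]),
                         paralog_log2 = unname(par[keep]),
                         stringsAsFactors = FALSE)
  n <- sum(keep)
  esr_mean <- if (n > 0) mean(per_pair$esr_log2) else NA_real_
  par_mean <- if (n > 0) mean(per_pair$paralog_log2) else NA_real_
  list(esr_mean = esr_mean, paralog_mean = par_mean,
       esr_mean_2dp = round(esr_mean, 2), paralog_mean_2dp = round(par_mean, 2),
       pairs = per_pair, n_pairs = n, n_dropped = sum(!keep))
}

#' Ordinary least-squares line through matched log2 fold changes
#'
#' Fits `y = intercept + slope * x` with a free intercept; pairs with a
#' missing value on either side are dropped.  `r_squared` is the squared
#' Pearson correlation, so it is blind to the sign of the slope.
#'
#' @param x,y Matched numeric vectors (e.g. log2 fold changes of the same
#'   genes in two experiments).
#' @return A list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 complete pairs")
  if (stats::var(x) == 0) stop("zero variance in x; slope is undefined")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r^2, n_points = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope %.4f, intercept %.4f, R^2 = %.4f\n",
              x$n_points, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Read a gene-to-category annotation map
#'
#' TSV with columns `gene_id`, `category_id` and optionally `category_name`.
#' @param path File path.
#' @return Data.frame.
#' @export
read_category_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("gene_id", "category_id") %in% names(d)))
    stop("category map needs columns gene_id and category_id")
  d
}

#' Read a TF-to-target annotation map
#'
#' TSV with columns `tf_name`, `target_gene_id`.
#' @param path File path.
#' @return Data.frame.
#' @export
read_tf_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("tf_name", "target_gene_id") %in% names(d)))
    stop("TF map needs columns tf_name and target_gene_id")
  d
}

#' Read a gene-list file
#'
#' One gene id per line, with an optional second tab-separated column of
#' reference log2 fold changes (for regression against published data).
#'
#' @param path File path.
#' @return Data.frame with `gene_id` and (possibly all-`NA`) `ref_log2fc`.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(gene_id = vapply(parts, `[`, "", 1L),
             ref_log2fc = vapply(parts, function(p)
               if (length(p) > 1L) suppressWarnings(as.numeric(p[2L]))
               else NA_real_, 0.0),
             stringsAsFactors = FALSE)
}

#' Read a paralog-pair table
#'
#' TSV with columns `esr_gene`, `paralog_gene`.
#' @param path File path.
#' @return Data.frame.
#' @export
read_paralog_pairs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("esr_gene", "paralog_gene") %in% names(d)))
    stop("paralog pair table needs columns esr_gene and paralog_gene")
  d
}
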