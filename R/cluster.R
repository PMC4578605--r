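# Complete-linkage hierarchical clustering of gene log2-fold-change profiles
# under uncentered-correlation distance, with TreeView-compatible CDT/GTR
# output.

#' Assemble the clustering input matrix from DE calls
#'
#' Rows are the union of up- and down-regulated genes across the given DE
#' sets; columns are those comparisons; entries are the combined log2 ratios,
#' `NA` where a gene has no valid value in a comparison.
#'
#' @param desets A list of [call_de()] results.
#' @param table The gene expression table the calls were made from.
#' @return A numeric matrix (genes x comparisons).
#' @export
select_cluster_input <- function(desets, table) {
  if (inherits(desets, "de_gene_set")) desets <- list(desets)
  stopifnot(length(desets) >= 1L)
  genes <- sort(unique(unlist(lapply(desets, function(d) c(d$up, d$down)))))
  if (length(genes) == 0L)
    stop("no differentially expressed genes to cluster")
  comparisons <- vapply(desets, `[[`, "", "comparison_id")
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(comparisons),
                dimnames = list(genes, comparisons))
  for (cmp in comparisons) {
    sub <- table[table$comparison_id == cmp & table$valid, ]
    hit <- sub$gene_id %in% genes
    mat[sub$gene_id[hit], cmp] <- sub$log2_ratio[hit]
  }
  mat
}

#' Uncentered-correlation distance between two profiles
#'
#' `1 - sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`, computed over the
#' indices where both profiles are non-missing — the cosine-type similarity
#' of the classic gene-clustering programs, taken without mean-centering, so
#' it ignores overall magnitude.  Distances lie in [0, 2]; anti-correlated
#' profiles have d > 1.
#'
#' @param x,y Numeric profiles of equal length (`NA` allowed).
#' @return The distance, a scalar in [0, 2].
#' @export
uncentered_distance <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("profiles share no non-missing index")
  x <- x[ok]; y <- y[ok]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm profile")
  d <- 1 - sum(x * y) / (nx * ny)
  min(max(d, 0), 2)
}

# full pairwise distance matrix; names the offending pair on error
.profile_dist_matrix <- function(mat, dist_fun) {
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d <- tryCatch(dist_fun(mat[i, ], mat[j, ]), error = function(e)
      stop(sprintf("distance error for gene pair (%s, %s): %s",
                   rownames(mat)[i], rownames(mat)[j], conditionMessage(e)),
           call. = FALSE))
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

#' Complete-linkage agglomerative clustering
#'
#' Agglomerates rows under complete linkage (inter-cluster distance = maximum
#' pairwise distance), by default with [uncentered_distance()] over
#' pairwise-complete entries.  Ties in the minimum linkage distance are
#' broken deterministically by the lowest (row index, row index) pair, where
#' a cluster is indexed by its smallest member row.  Complete linkage is
#' monotone, so merge heights never decrease.
#'
#' @param mat Numeric matrix (genes x comparisons) with >= 2 rows, or a
#'   precomputed symmetric distance matrix when `precomputed = TRUE`.
#' @param dist_fun Distance function taking two profile vectors
#'   (default [uncentered_distance()]; replaceable as a test hook).
#' @param precomputed If `TRUE`, `mat` is already a distance matrix.
#' @return A list of class `gene_dendrogram`: `merge` (the standard
#'   agglomeration matrix: negative entries are leaves, positive entries
#'   earlier merges), `height`, `order` (leaf order as merged), `labels`,
#'   and `merges` (a data.frame view with node labels and heights).
#' @export
hclust_complete <- function(mat, dist_fun = uncentered_distance,
                            precomputed = FALSE) {
  if (precomputed) {
    D <- as.matrix(mat)
  } else {
    stopifnot(is.matrix(mat), nrow(mat) >= 2L)
    D <- .profile_dist_matrix(mat, dist_fun)
  }
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 rows to cluster")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  active <- seq_len(n)            # smallest member row of each live cluster
  cluster_id <- -seq_len(n)       # hclust convention: -leaf or merge number
  members <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    live <- which(!is.na(active))
    sub <- D[live, live, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    best_d <- min(sub)
    hits <- which(sub == best_d, arr.ind = TRUE)
    # ties broken by the lowest (row index, row index) pair; a cluster is
    # indexed by its smallest member row, which is its slot by construction
    pick <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
    i <- live[pick[1L]]; j <- live[pick[2L]]
    merge[step, ] <- sort(c(cluster_id[i], cluster_id[j]))
    height[step] <- best_d
    # Lance-Williams update for complete linkage: new distance is the max
    for (k in live) {
      if (k == i || k == j) next
      D[i, k] <- max(D[i, k], D[j, k]); D[k, i] <- D[i, k]
    }
    members[[i]] <- c(members[[i]], members[[j]])
    cluster_id[i] <- step
    active[j] <- NA_integer_
  }

  # leaf order: flatten the merge tree as merged
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  ord <- expand(n - 1L)
  node_label <- function(v) ifelse(v < 0L, paste0("GENE", -v, "X"),
                                   paste0("NODE", v, "X"))
  merges <- data.frame(node_a = node_label(merge[, 1L]),
                       node_b = node_label(merge[, 2L]),
                       height = height, stringsAsFactors = FALSE)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, merges = merges),
            class = "gene_dendrogram")
}

#' @export
print.gene_dendrogram <- function(x, ...) {
  cat(sprintf("gene_dendrogram: %d leaves, %d merges, heights [%.4g, %.4g]\n",
              length(x$labels), length(x$height), min(x$height),
              max(x$height)))
  invisible(x)
}

#' Convert a gene dendrogram to a stats::hclust object
#'
#' @param dend A [hclust_complete()] result.
#' @return An object of class `hclust` (for plotting or cutting).
#' @export
as_hclust <- function(dend) {
  structure(list(merge = dend$merge, height = dend$height,
                 order = dend$order, labels = dend$labels,
                 method = "complete", call = match.call(),
                 dist.method = "uncentered correlation"),
            class = "hclust")
}

#' Write TreeView-compatible CDT and GTR files
#'
#' CDT: tab-delimited table with `GID`, `ORF`, `NAME` columns followed by the
#' per-comparison log2 values, rows in dendrogram leaf order, missing values
#' as empty fields.  GTR: one line per merge,
#' `NODEkX <child> <child> <similarity>` with similarity = 1 - merge height.
#'
#' @param dend A [hclust_complete()] result.
#' @param mat The matrix that was clustered.
#' @param path_prefix Output prefix; writes `<prefix>.cdt` and
#'   `<prefix>.gtr`.
#' @return The two paths, invisibly.
#' @export
write_cdt_gtr <- function(dend, mat, path_prefix) {
  stopifnot(inherits(dend, "gene_dendrogram"))
  cdt_path <- paste0(path_prefix, ".cdt")
  gtr_path <- paste0(path_prefix, ".gtr")

  gtr <- sprintf("NODE%dX\t%s\t%s\t%s", seq_along(dend$height),
                 dend$merges$node_a, dend$merges$node_b,
                 .fmt_sim(1 - dend$height))
  writeLines(gtr, gtr_path)

  ord <- dend$order
  vals <- apply(mat[ord, , drop = FALSE], 1L, function(r)
    paste(ifelse(is.na(r), "", sprintf("%.6f", r)), collapse = "\t"))
  header <- paste(c("GID", "ORF", "NAME", colnames(mat)), collapse = "\t")
  rows <- paste(paste0("GENE", ord, "X"), dend$labels[ord], dend$labels[ord],
                vals, sep = "\t")
  writeLines(c(header, rows), cdt_path)
  invisible(c(cdt = cdt_path, gtr = gtr_path))
}

.fmt_sim <- function(x) sprintf("%.6f", x)
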