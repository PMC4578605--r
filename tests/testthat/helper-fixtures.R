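# In-code fixtures shared across test files.

# random valid scan whose numeric fields are representable at the dialect's
# 1-decimal precision, so file round trips are exact
random_scan <- function(n_spots = 8L, array_id = "a1", comparison_id = "c1",
                        orientation = "forward") {
  idx <- seq_len(n_spots) - 1L
  spots <- data.frame(
    block = 1L, column = idx %% 4L + 1L, row = idx %/% 4L + 1L,
    name = sprintf("g%02d", idx + 1L), gene_id = sprintf("g%02d", idx + 1L),
    diameter_um = round(runif(n_spots, 100, 200), 1),
    f635 = round(runif(n_spots, 0, 2000), 1),
    b635 = round(runif(n_spots, 20, 40), 1),
    f532 = round(runif(n_spots, 0, 2000), 1),
    b532 = round(runif(n_spots, 20, 40), 1),
    flags = sample(c(0L, 0L, 0L, -100L), n_spots, replace = TRUE),
    stringsAsFactors = FALSE)
  array_scan(array_id, comparison_id, orientation, spots)
}

# minimal hand-built dye-swap pair: each gene's spot intensities chosen so
# the orientation-corrected log2 ratios are known exactly
tiny_pair <- function(fwd_ratios, swp_ratios, genes_fwd = names(fwd_ratios),
                      genes_swp = names(swp_ratios), comparison_id = "c1") {
  mk <- function(lr, genes, orientation, array_id) {
    n <- length(lr)
    raw <- if (orientation == "forward") 2^lr else 2^(-lr)
    spots <- data.frame(
      block = 1L, column = seq_len(n), row = 1L,
      name = genes, gene_id = genes, diameter_um = 150,
      f635 = 1000 * raw, b635 = 30, f532 = 1000, b532 = 30,
      flags = 0L, stringsAsFactors = FALSE)
    array_scan(array_id, comparison_id, orientation, spots)
  }
  list(forward = mk(fwd_ratios, genes_fwd, "forward", "a_fwd"),
       swapped = mk(swp_ratios, genes_swp, "swapped", "a_swp"))
}

# exhaustive combinatorial oracle for the hypergeometric upper tail
hyper_tail_oracle <- function(N, K, n, k) {
  kk <- seq.int(k, min(K, n))
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# brute-force complete-linkage oracle: recomputes the max linkage over
# explicit cluster membership at every step, lowest-index tie-break
hclust_oracle <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      d <- max(D[clusters[[a]], clusters[[b]]])
      key <- c(min(clusters[[a]]), min(clusters[[b]]))
      if (d < best_d ||
          (d == best_d && (key[1] < best$key[1] ||
                           (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best_d <- d; best <- list(a = a, b = b, key = key)
      }
    }
    heights <- c(heights, best_d)
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  heights
}

# gene expression table built directly (bypassing arrays) for DE-level tests
toy_table <- function(ratios, comparison_id = "c1",
                      genes = sprintf("g%02d", seq_along(ratios)),
                      valid = rep(TRUE, length(ratios))) {
  data.frame(gene_id = genes, comparison_id = comparison_id,
             log2_ratio = ifelse(valid, log2(ratios), NA_real_),
             ratio = ifelse(valid, ratios, NA_real_), valid = valid,
             n_spots_forward = 2L, n_spots_swapped = 2L,
             stringsAsFactors = FALSE)
}
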