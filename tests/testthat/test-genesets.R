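test_that("hypergeometric tail matches exhaustive enumeration", {
  # worked values computable by hand
  expect_equal(hypergeom_tail(20, 5, 4, 4), 5 / 4845, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_tail(100, 10, 7, 0), 1.0)
  # every configuration with universe <= 12
  for (N in 2:12) for (K in 0:N) for (n in 0:N)
    for (k in 0:min(K, n)) {
      expect_equal(hypergeom_tail(N, K, n, k), hyper_tail_oracle(N, K, n, k),
                   tolerance = 1e-12)
    }
  expect_error(hypergeom_tail(10, 12, 5, 3), "inconsistent")
  expect_error(hypergeom_tail(10, 4, 5, 5), "inconsistent")
})

test_that("enrichment reports expected overlap, fold and BH-adjusted p", {
  universe <- sprintf("g%04d", 1:1000)
  set_a <- universe[1:100]
  query <- c(universe[1:25], universe[101:125])   # 25 of 50 in set_a
  res <- enrich(query, list(A = set_a, B = universe[301:400]), universe)
  a <- res[res$set == "A", ]
  expect_equal(a$expected, 5.0)
  expect_equal(a$fold, 5.0)
  expect_equal(a$n_overlap, 25L)
  expect_equal(res$set[1], "A")                    # smallest p ranks first
  expect_true(all(res$adjusted_p >= res$p_value))
  # a query that is exactly one category ranks that category first
  res2 <- enrich(set_a[1:10],
                 list(whole = set_a[1:10], other = universe[500:700]),
                 universe)
  expect_equal(res2$set[1], "whole")
  expect_error(enrich(query, list(A = set_a), character()), "empty universe")
  expect_error(enrich(c(query, "nope"), list(A = set_a), universe),
               "outside the universe")
})

test_that("p-value is monotone decreasing in overlap at fixed margins", {
  p <- vapply(0:20, function(k) hypergeom_tail(500, 50, 20, k), 0.0)
  expect_true(all(diff(p) <= 0))
})

test_that("TF ranking reports per-TF target counts with stable tie-break", {
  universe <- sprintf("g%03d", 1:200)
  query <- universe[1:20]
  tf_map <- data.frame(
    tf_name = c(rep("Msn2", 30), rep("Aft1", 30), rep("Hsf1", 10)),
    target_gene_id = c(universe[1:30], universe[1:30], universe[101:110]),
    stringsAsFactors = FALSE)
  res <- rank_by_tf(query, tf_map, universe)
  # identical target sets: identical p, alphabetical tie-break
  expect_equal(res$p_value[1], res$p_value[2])
  expect_equal(res$tf[1:2], c("Aft1", "Msn2"))
  expect_equal(res$n_targets_in_query[1:2], c(20L, 20L))
  hsf1 <- res[res$tf == "Hsf1", ]
  expect_equal(hsf1$n_targets_in_query, 0L)
  expect_equal(hsf1$p_value, 1.0)
})

test_that("overlap enrichment reproduces the fold-over-expected algebra", {
  universe <- sprintf("g%04d", 1:3645)
  reference <- universe[1:585]
  query <- c(universe[1:86], universe[1000:1141])  # 228 genes, 86 overlap
  res <- overlap_enrichment(query, reference, universe)
  expect_equal(res$n_query, 228L)
  expect_equal(res$expected, 585 * 228 / 3645, tolerance = 1e-12)
  expect_equal(round(res$expected, 2), 36.59)
  expect_equal(round(res$fold, 2), 2.35)
  expect_lt(res$p_value, 1e-10)
  # query identical to the reference: fold = universe/set
  small_u <- sprintf("u%02d", 1:40)
  r2 <- overlap_enrichment(small_u[1:8], small_u[1:8], small_u)
  expect_equal(r2$fold, 40 / 8)
  r3 <- overlap_enrichment(small_u[1:5], small_u[21:25], small_u)
  expect_equal(r3$fold, 0)
})

test_that("ESR-paralog contrast averages retained pairs and drops invalid", {
  tab <- toy_table(2^c(1, 2, 0, 0.1, 3), "c1",
                   genes = c("e1", "e2", "p1", "p2", "e3"),
                   valid = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  pairs <- data.frame(esr_gene = c("e1", "e2", "e3"),
                      paralog_gene = c("p1", "p2", "p1"),
                      stringsAsFactors = FALSE)
  res <- esr_paralog_contrast(tab, pairs, "c1")
  expect_equal(res$esr_mean_2dp, 1.50)
  expect_equal(res$paralog_mean_2dp, 0.05)
  expect_equal(res$n_pairs, 2L)
  expect_equal(res$n_dropped, 1L)          # e3 invalid
  # symmetric inputs give equal means
  sym <- esr_paralog_contrast(tab, data.frame(esr_gene = c("e1", "e2"),
                                              paralog_gene = c("e1", "e2")),
                              "c1")
  expect_equal(sym$esr_mean, sym$paralog_mean)
  none <- esr_paralog_contrast(tab, data.frame(esr_gene = "e3",
                                               paralog_gene = "e3"), "c1")
  expect_true(is.na(none$esr_mean))
})

test_that("planted group contrast is recovered within the CLT bound", {
  cfg <- sim_config(n_genes = 500, noise_sd = 0.2, seed = 21,
                    frac_up = 0, frac_down = 0)
  u <- generate_universe(cfg, esr_fraction = 0.4)  # 200 pairs
  tr <- plant_de_truth(u, cfg)
  tr$true_log2fc[match(u$paralog_pairs$esr_gene, tr$gene_id)] <- 1.0
  tr$true_log2fc[match(u$paralog_pairs$paralog_gene, tr$gene_id)] <- 0.0
  sim <- simulate_comparison(u, tr, cfg)
  # normalization off: with 40% of this small universe planted, the spot
  # median is not a null baseline
  tab <- combine_to_gene_table(sim$forward, sim$swapped,
                               qc_config(normalize = FALSE))
  res <- esr_paralog_contrast(tab, u$paralog_pairs, "cmp1")
  expect_gt(res$n_pairs, 150)
  expect_lt(abs(res$esr_mean - 1.0), 0.05)
  expect_lt(abs(res$paralog_mean - 0.0), 0.05)
})

test_that("fit_line performs OLS with Pearson r-squared", {
  f <- fit_line(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope, 1); expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  f2 <- fit_line(c(0, 1, 2), c(0, 2, 3))
  expect_equal(f2$slope, 1.5, tolerance = 1e-12)
  expect_equal(f2$intercept, 1 / 6, tolerance = 1e-12)
  expect_equal(f2$r_squared, 0.9643, tolerance = 1e-4)
  f3 <- fit_line(c(0, 1, 2), c(0, -1, -2))
  expect_equal(f3$slope, -1); expect_equal(f3$r_squared, 1)
  # equivariance: scaling y scales the slope; shifting y moves the intercept
  set.seed(5)
  x <- rnorm(30); y <- 0.7 * x + rnorm(30, 0, 0.1)
  base <- fit_line(x, y)
  expect_equal(fit_line(x, 3 * y)$slope, 3 * base$slope, tolerance = 1e-9)
  shifted <- fit_line(x, y + 2)
  expect_equal(shifted$slope, base$slope, tolerance = 1e-9)
  expect_equal(shifted$intercept, base$intercept + 2, tolerance = 1e-9)
  # NA pairs dropped; degenerate x rejected
  expect_equal(fit_line(c(0, 1, 2, NA), c(0, 1, 2, 5))$n_points, 3L)
  expect_error(fit_line(c(1, 1, 1), c(0, 1, 2)), "zero variance")
})

test_that("annotation files round-trip through their readers", {
  cfg <- sim_config(n_genes = 50, seed = 6)
  u <- generate_universe(cfg, n_categories = 4, n_tfs = 3)
  dir <- withr::local_tempdir()
  write_annotations(u, dir)
  expect_equal(read_category_map(file.path(dir, "categories.tsv")),
               u$categories)
  expect_equal(read_tf_map(file.path(dir, "tf_targets.tsv")), u$tf_targets)
  expect_equal(read_paralog_pairs(file.path(dir, "paralog_pairs.tsv")),
               u$paralog_pairs)
  gl <- file.path(dir, "list.txt")
  writeLines(c("g1\t0.5", "g2", "g3\t-1.25"), gl)
  d <- read_gene_list(gl)
  expect_equal(d$gene_id, c("g1", "g2", "g3"))
  expect_equal(d$ref_log2fc, c(0.5, NA, -1.25))
})
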