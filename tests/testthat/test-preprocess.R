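make_spot <- function(diameter = 150, f635 = 1000, f532 = 1000, b635 = 30,
                      b532 = 30, flags = 0L) {
  data.frame(block = 1L, column = 1L, row = 1L, name = "g1", gene_id = "g1",
             diameter_um = diameter, f635 = f635, b635 = b635, f532 = f532,
             b532 = b532, flags = flags, stringsAsFactors = FALSE)
}

test_that("spot QC applies strict diameter and intensity cutoffs", {
  qc <- qc_config()
  pass1 <- function(spots, qc) {
    scan <- array_scan("a", "c", "forward", spots)
    qc_filter(scan, qc)$spots$qc_pass
  }
  expect_false(pass1(make_spot(diameter = 119), qc))
  # both thresholds met exactly: strict inequalities mean the spot passes
  expect_true(pass1(make_spot(diameter = 120, f635 = 150, f532 = 150), qc))
  expect_false(pass1(make_spot(f635 = 149, f532 = 149), qc))
  # one dim channel: rule decides
  expect_true(pass1(make_spot(f635 = 140, f532 = 500), qc))
  expect_false(pass1(make_spot(f635 = 140, f532 = 500),
                     qc_config(intensity_rule = "either_below")))
  # manual flag
  expect_false(pass1(make_spot(flags = -100L), qc))
})

test_that("spot log2 ratios respect orientation and background handling", {
  s <- make_spot(f635 = 400, f532 = 100)
  expect_equal(spot_log2_ratio(s, "forward", qc_config()), 2)
  expect_equal(spot_log2_ratio(s, "swapped", qc_config()), -2)
  s2 <- make_spot(f635 = 400, b635 = 100, f532 = 160, b532 = 10)
  expect_equal(spot_log2_ratio(s2, "forward",
                               qc_config(background_subtract = TRUE)),
               log2(300 / 150))
  # zero foreground demotes the spot rather than erroring
  s3 <- make_spot(f635 = 0)
  expect_true(is.na(spot_log2_ratio(s3, "forward", qc_config())))
})

test_that("median normalization centers and is idempotent", {
  expect_equal(normalize_array(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(normalize_array(c(0.9, 1.0, 1.4)), c(-0.1, 0, 0.4))
  set.seed(1)
  x <- rnorm(31)
  expect_equal(normalize_array(normalize_array(x)), normalize_array(x))
  expect_equal(median(normalize_array(x)), 0)
})

test_that("combining is mean of array means with the two-armed validity rule", {
  pair <- tiny_pair(fwd_ratios = c(g1 = 1, g1 = 3, g2 = 2),
                    swp_ratios = c(g1 = 2),
                    genes_fwd = c("g1", "g1", "g2"), genes_swp = "g1")
  # distinct grid positions for duplicate gene spots are set by tiny_pair
  tab <- combine_to_gene_table(pair$forward, pair$swapped,
                               qc_config(normalize = FALSE))
  g1 <- tab[tab$gene_id == "g1", ]
  expect_true(g1$valid)
  expect_equal(g1$log2_ratio, (mean(c(1, 3)) + 2) / 2)  # = 2
  expect_equal(g1$n_spots_forward, 2L)
  # g2 has no passing spot on the swapped array: invalid, no value
  g2 <- tab[tab$gene_id == "g2", ]
  expect_false(g2$valid)
  expect_true(is.na(g2$log2_ratio))
})

test_that("pooled-spot combining is available as an alternative", {
  pair <- tiny_pair(fwd_ratios = c(g1 = 1, g1 = 3), swp_ratios = c(g1 = 2),
                    genes_fwd = c("g1", "g1"), genes_swp = "g1")
  tab <- combine_to_gene_table(pair$forward, pair$swapped,
                               qc_config(normalize = FALSE),
                               combine = "pooled")
  expect_equal(tab$log2_ratio[tab$gene_id == "g1"], mean(c(1, 3, 2)))
})

test_that("dye-swap symmetry: channel exchange + orientation flip is a no-op", {
  cfg <- sim_config(n_genes = 60, noise_sd = 0.3, dye_bias = 1.7, seed = 9)
  u <- generate_universe(cfg)
  tr <- plant_de_truth(u, cfg)
  sim <- simulate_comparison(u, tr, cfg)
  flip <- function(scan) {
    s <- scan$spots
    s[c("f635", "f532", "b635", "b532")] <- s[c("f532", "f635", "b532",
                                                "b635")]
    array_scan(scan$array_id, scan$comparison_id,
               if (scan$orientation == "forward") "swapped" else "forward", s)
  }
  tab <- combine_to_gene_table(sim$forward, sim$swapped, qc_config())
  tab_flipped <- combine_to_gene_table(flip(sim$swapped), flip(sim$forward),
                                       qc_config())
  expect_equal(tab_flipped$log2_ratio, tab$log2_ratio, tolerance = 1e-12)
  expect_equal(tab_flipped$valid, tab$valid)
})

test_that("a constant dye bias cancels exactly even without normalization", {
  cfg_b <- sim_config(n_genes = 50, noise_sd = 0, dye_bias = 3.7,
                      bad_spot_rate = 0, dim_spot_rate = 0, seed = 10)
  cfg_1 <- sim_config(n_genes = 50, noise_sd = 0, dye_bias = 1,
                      bad_spot_rate = 0, dim_spot_rate = 0, seed = 10)
  u <- generate_universe(cfg_b)
  tr <- plant_de_truth(u, cfg_b)
  tb <- combine_to_gene_table(simulate_comparison(u, tr, cfg_b)$forward,
                              simulate_comparison(u, tr, cfg_b)$swapped,
                              qc_config(normalize = FALSE))
  t1 <- combine_to_gene_table(simulate_comparison(u, tr, cfg_1)$forward,
                              simulate_comparison(u, tr, cfg_1)$swapped,
                              qc_config(normalize = FALSE))
  expect_equal(tb$log2_ratio, t1$log2_ratio, tolerance = 1e-12)
  expect_equal(tb$log2_ratio,
               tr$true_log2fc[match(tb$gene_id, tr$gene_id)],
               tolerance = 1e-12)
})

test_that("removing a failing spot never changes any gene's value", {
  cfg <- sim_config(n_genes = 40, noise_sd = 0.2, bad_spot_rate = 0.2,
                    dim_spot_rate = 0.1, seed = 11)
  u <- generate_universe(cfg)
  tr <- plant_de_truth(u, cfg)
  sim <- simulate_comparison(u, tr, cfg)
  tab <- combine_to_gene_table(sim$forward, sim$swapped, qc_config())
  drop_failing <- function(scan) {
    keep <- qc_filter(scan, qc_config())$spots$qc_pass
    if (all(keep)) return(scan)
    array_scan(scan$array_id, scan$comparison_id, scan$orientation,
               scan$spots[keep, ])
  }
  tab2 <- combine_to_gene_table(drop_failing(sim$forward),
                                drop_failing(sim$swapped), qc_config())
  shared <- intersect(tab$gene_id[tab$valid], tab2$gene_id[tab2$valid])
  expect_equal(tab2$log2_ratio[match(shared, tab2$gene_id)],
               tab$log2_ratio[match(shared, tab$gene_id)], tolerance = 1e-12)
  expect_setequal(shared, tab$gene_id[tab$valid])
})

test_that("pairing violations are rejected", {
  pair <- tiny_pair(c(g1 = 1), c(g1 = 1))
  expect_error(combine_to_gene_table(pair$swapped, pair$forward),
               "pairing")
  other <- tiny_pair(c(g1 = 1), c(g1 = 1), comparison_id = "c2")
  expect_error(combine_to_gene_table(pair$forward, other$swapped),
               "different comparisons")
})
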