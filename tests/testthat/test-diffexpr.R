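test_that("DE calling applies strict fold-change thresholds", {
  ratios <- c(4.0, 2.5, 2.0, 1.0, 0.5, 0.4, 0.25, 1.5, 3.0, 0.9)
  tab <- toy_table(ratios)
  d <- call_de(tab, "c1")
  expect_length(d$up, 3L)      # 4.0, 2.5, 3.0 — exactly 2.0 is not "higher"
  expect_length(d$down, 2L)    # 0.4, 0.25 — exactly 0.5 is not "lower"
  expect_false("g03" %in% d$up)
  expect_false("g05" %in% d$down)
  expect_equal(d$n_valid, 10L)
  expect_error(call_de(tab, "nope"), "unknown comparison")

  all_invalid <- toy_table(ratios, valid = rep(FALSE, 10))
  d0 <- call_de(all_invalid, "c1")
  expect_length(d0$up, 0L)
  expect_equal(d0$n_valid, 0L)
})

test_that("raising the up threshold never adds a gene to up", {
  set.seed(3)
  tab <- toy_table(2^rnorm(200, 0, 1.2))
  prev <- call_de(tab, "c1", de_config(up_threshold = 1.5))$up
  for (th in c(2, 2.5, 3, 4)) {
    cur <- call_de(tab, "c1", de_config(up_threshold = th))$up
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("DE summaries report counts and one-decimal percentages", {
  d <- list(comparison_id = "c8h", up = sprintf("u%03d", 1:81),
            down = sprintf("d%03d", 1:32), n_valid = 3645L)
  class(d) <- "de_gene_set"
  s <- summarize_de(list(d))
  expect_equal(s$n_changed, 113L)
  expect_equal(s$pct_changed, 3.1)
  empty <- list(comparison_id = "e", up = character(), down = character(),
                n_valid = 100L)
  class(empty) <- "de_gene_set"
  expect_equal(summarize_de(list(empty))$pct_changed, 0)
  none <- empty; none$n_valid <- 0L
  expect_true(is.na(summarize_de(list(none))$pct_changed))
})

test_that("dependence classification follows the X intervals and special rule", {
  one <- function(fc_wt, fc_mut, ...)
    classify_dependence(fc_wt, fc_mut, ...)[1, ]
  expect_equal(one(4, 4)$class, "independent")        # X = 1
  r <- one(2.6, 1.2)
  expect_equal(r$class, "TD")                          # special rule
  expect_true(r$special_rule_fired)
  r <- one(4, 2.3)
  expect_equal(r$X, log2(2.3) / 2, tolerance = 1e-12)  # 0.6008 -> WD
  expect_equal(r$class, "WD")
  r <- one(4, 1.32)                                    # 1.32 >= 1.3: no special
  expect_false(r$special_rule_fired)
  expect_equal(r$X, log2(1.32) / 2, tolerance = 1e-12) # 0.20 -> TD
  expect_equal(r$class, "TD")
  # boundaries: TD closed at 0.25; X = 0.50 goes to the weaker (WD) side
  expect_equal(one(4, 2)$class, "WD")                  # X exactly 0.50
  expect_equal(one(16, 2)$class, "TD")                 # X exactly 0.25
  expect_equal(one(4, 2^1.35)$class, "independent")    # X = 0.675
  expect_equal(one(4, 2^1.32)$class, "WD")             # X = 0.66
  # inverted mutant response: X <= 0 -> TD
  expect_equal(one(4, 0.8)$class, "TD")
  expect_error(classify_dependence(1.5, 1.5), "not responsive")
})

test_that("repressed genes are classified by mirror symmetry", {
  one <- function(fc_wt, fc_mut, ...)
    classify_dependence(fc_wt, fc_mut, ...)[1, ]
  r <- one(1 / 4, 1 / 2.3)
  expect_equal(r$direction, "down")
  expect_equal(r$X, log2(1 / 2.3) / log2(1 / 4), tolerance = 1e-12)
  expect_equal(r$class, "WD")
  # mirrored special rule: strongly repressed in WT, flat in mutant
  r <- one(1 / 2.6, 1 / 1.2)
  expect_equal(r$class, "TD")
  expect_true(r$special_rule_fired)
  r_off <- classify_dependence(1 / 2.6, 1 / 1.2,
                               dependence_config(mirror_special = FALSE))[1, ]
  expect_false(r_off$special_rule_fired)
  # de-repressed in the mutant: X <= 0 -> TD
  expect_equal(one(1 / 4, 1.5)$class, "TD")
})

test_that("every responsive gene gets exactly one class, monotone in fc_mut", {
  set.seed(7)
  fc_wt <- 2^runif(300, 1.05, 3)
  fc_mut <- 2^runif(300, -1, 3)
  calls <- classify_dependence(fc_wt, fc_mut)
  expect_true(all(calls$class %in% c("independent", "WD", "SD", "TD")))
  # monotone: for fixed fc_wt outside the special region, class order
  # TD -> SD -> WD -> independent never reverses as fc_mut grows
  lv <- c(TD = 1, SD = 2, WD = 3, independent = 4)
  fc_mut_grid <- 2^seq(-0.5, 2.2, length.out = 60)
  cls <- classify_dependence(rep(2.4, 60), fc_mut_grid)$class
  expect_true(all(diff(lv[cls]) >= 0))
})

test_that("linear-scale X is available as a configured alternative", {
  cfg <- dependence_config(scale = "linear_fc")
  r <- classify_dependence(4, 2.3, cfg)[1, ]
  expect_equal(r$X, 2.3 / 4)
  r <- classify_dependence(1 / 4, 1 / 2.3, cfg)[1, ]
  expect_equal(r$X, (1 / 4) / (1 / 2.3))
})

test_that("dependence summary partitions calls and reports the fraction", {
  calls <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    direction = rep(c("up", "down"), 5),
    fc_wt = 4, fc_mut = 4,
    X = 1,
    class = c(rep("independent", 4), "WD", "WD", "SD", "TD", "TD", "TD"),
    special_rule_fired = FALSE, stringsAsFactors = FALSE)
  s <- dependence_summary(calls)
  expect_equal(s$n_dependent, 6L)
  expect_equal(s$pct_dependent, 60)
  expect_equal(sum(s$by_class$n), 10L)
  all_ind <- calls; all_ind$class <- "independent"
  expect_equal(dependence_summary(all_ind)$pct_dependent, 0)
})

test_that("venn overlap partitions the union per direction", {
  mk <- function(cmp, up, down = character()) {
    structure(list(comparison_id = cmp, up = up, down = down,
                   n_valid = 100L), class = "de_gene_set")
  }
  a <- mk("c1", c("g1", "g2", "g3"))
  b <- mk("c2", c("g2", "g3", "g4"))
  expect_equal(unname(venn_overlap(a, b)$up), c(1, 2, 1))
  expect_equal(unname(venn_overlap(a, a)$up), c(0, 3, 0))
  dis <- mk("c2", c("x1", "x2"))
  expect_equal(unname(venn_overlap(a, dis)$up), c(3, 0, 2))
  # restriction to genes valid in both comparisons
  tab <- rbind(toy_table(rep(4, 4), "c1", genes = c("g1", "g2", "g3", "g4")),
               toy_table(rep(4, 4), "c2", genes = c("g1", "g2", "g3", "g4"),
                         valid = c(TRUE, TRUE, FALSE, TRUE)))
  expect_equal(unname(venn_overlap(a, b, tab)$up), c(1, 1, 1))
})
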