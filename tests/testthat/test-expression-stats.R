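test_that("CV is sample sd over mean, scale-invariant, NA on zero mean", {
  expect_equal(cv_percent(c(5, 5, 5, 5)), 0)
  expect_equal(cv_percent(c(1, 2, 3)), 50)
  x <- c(2, 9, 4, 7)
  expect_equal(cv_percent(3.7 * x), cv_percent(x))
  expect_true(is.na(cv_percent(c(-1, 1))))
})

test_that("fold-change screen applies the cutoff, direction and floor", {
  vals <- rbind(up = c(1, 1, 4, 4), flat = c(2, 2, 2, 2),
                low = c(0.5, 0.5, 0.8, 0.8), down = c(8, 8, 2, 2))
  colnames(vals) <- c("a1", "a2", "b1", "b2")
  r <- fold_change_screen(vals, c("a1", "a2"), c("b1", "b2"),
                          log2_cutoff = 1, pseudocount = 0)
  expect_equal(r$log2fc[r$gene == "up"], 2)
  expect_equal(r$direction[r$gene == "up"], "up")
  expect_true(r$flag[r$gene == "up"])
  expect_false(r$flag[r$gene == "flat"])
  expect_true(r$excluded[r$gene == "low"])
  expect_false(r$flag[r$gene == "low"])
  expect_equal(r$direction[r$gene == "down"], "down")
  # without the floor rule the low gene is assessed normally
  r2 <- fold_change_screen(vals, c("a1", "a2"), c("b1", "b2"),
                           floor_exclusion = FALSE, pseudocount = 0)
  expect_false(r2$excluded[r2$gene == "low"])
  expect_error(fold_change_screen(vals, character(), "b1"), "empty group")
  expect_error(fold_change_screen(vals, c("a1", "b1"), c("b1", "b2")),
               "overlap")
})

test_that("noiseless planted effects are recovered exactly by the screen", {
  genes <- sprintf("g%02d", 1:40)
  planted <- stats::setNames(c(2, 2, -2, 1.5), genes[c(3, 11, 25, 38)])
  sim <- simulate_expression(genes,
                             de = list(effects = planted, noise_sd = 0),
                             seed = 99)
  a <- rownames(sim$samples)[sim$samples$condition == "A"]
  b <- rownames(sim$samples)[sim$samples$condition == "B"]
  r <- fold_change_screen(sim$values, a, b, log2_cutoff = 1, pseudocount = 0)
  expect_setequal(r$gene[r$flag], names(planted))
  expect_equal(r$log2fc[match(names(planted), r$gene)], unname(planted))
})

test_that("SAM d-statistic is zero under equal means and q respects its contract", {
  set.seed(15)
  vals <- matrix(rep(c(3, 5, 3, 5, 3, 5), each = 10), 10)
  colnames(vals) <- paste0("s", 1:6)
  rownames(vals) <- paste0("g", 1:10)
  vals <- vals + rnorm(60, 0, 0.3)
  # perfectly mirrored groups: recompute with equal group means
  eq <- matrix(rnorm(10 * 6), 10, dimnames = dimnames(vals))
  eq[, 4:6] <- eq[, 1:3]
  r0 <- sam_test(eq, rep(c("A", "B"), each = 3), n_permutations = 50)
  expect_true(all(abs(r0$d) < 1e-12))

  r <- sam_test(vals, rep(c("A", "B"), 3), n_permutations = 100, seed = 2)
  expect_true(all(r$q >= 0 & r$q <= 1))
  # q monotone non-increasing in |d|
  ord <- order(-abs(r$d))
  expect_true(all(diff(r$q[ord]) >= -1e-12))
  expect_error(sam_test(vals, rep("A", 6), n_permutations = 10),
               "two levels")
})

test_that("SAM recovers strong planted effects and controls the null", {
  hits <- sapply(1:10, function(seed) {
    set.seed(seed + 400)
    n_null <- 150; n_de <- 20
    vals <- matrix(rnorm((n_null + n_de) * 8), n_null + n_de, 8,
                   dimnames = list(sprintf("g%03d", 1:(n_null + n_de)),
                                   paste0("s", 1:8)))
    truth <- rownames(vals)[seq_len(n_de)]
    vals[seq_len(n_de), 5:8] <- vals[seq_len(n_de), 5:8] + 5
    r <- sam_test(vals, rep(c("A", "B"), each = 4),
                  n_permutations = 300, seed = seed)
    called <- r$gene[r$flag]
    c(tp = length(intersect(called, truth)),
      fp = length(setdiff(called, truth)))
  })
  expect_gte(mean(hits["tp", ]), 18)
  expect_lte(mean(hits["fp", ]), 2)
})

test_that("two-way ANOVA matches the closed-form sums of squares", {
  fa <- rep(c("lo", "hi"), each = 4)
  fb <- rep(rep(c("early", "late"), each = 2), 2)
  y <- c(3, 4, 7, 8, 5, 6, 13, 15)
  vals <- matrix(y, 1, dimnames = list("g1", paste0("s", 1:8)))
  r <- two_way_anova(vals, fa, fb)
  o <- anova_oracle(y, fa, fb)
  expect_equal(r$F_a, o$F_a)
  expect_equal(r$F_b, o$F_b)
  expect_equal(r$F_ab, o$F_ab)

  # purely additive main effects leave zero interaction SS
  add <- outer(c(0, 2), c(0, 3), "+") # cell means
  y2 <- as.vector(add[cbind(match(fa, c("lo", "hi")),
                            match(fb, c("early", "late")))])
  v2 <- matrix(y2 + rep(c(-.1, .1), 4), 1,
               dimnames = list("g1", paste0("s", 1:8)))
  # replicate deviations are symmetric within each cell, so the
  # interaction mean square is exactly zero
  r2 <- two_way_anova(v2, fa, fb)
  expect_equal(r2$F_ab, 0, tolerance = 1e-10)

  # BH-adjusted p are monotone in raw p and bounded by 1
  set.seed(16)
  v3 <- matrix(rnorm(30 * 8), 30, dimnames = list(paste0("g", 1:30),
                                                  paste0("s", 1:8)))
  r3 <- two_way_anova(v3, fa, fb)
  expect_true(all(r3$padj_a <= 1))
  expect_true(all(diff(r3$padj_a[order(r3$p_a)]) >= -1e-12))
  expect_error(two_way_anova(v3[, 1:6], rep(c("a", "b"), 3),
                             rep(c("c", "d", "d"), 2)), "unbalanced")
})

test_that("duplicate-pair expression PCC handles self, negation and missingness", {
  set.seed(17)
  vals <- matrix(rnorm(40), 4, 10,
                 dimnames = list(c("a", "b", "c", "z"), paste0("s", 1:10)))
  vals["b", ] <- -vals["a", ]
  vals["z", ] <- 7
  pairs <- data.frame(gene_a = c("a", "a", "a", "missing", "a"),
                      gene_b = c("a", "b", "c", "c", "z"))
  r <- duplicate_pair_pcc(vals, pairs)
  expect_equal(r$pcc[1], 1)
  expect_equal(r$pcc[2], -1)
  expect_equal(r$pcc[3], cor(vals["a", ], vals["c", ]))
  expect_true(is.na(r$pcc[4]))  # missing gene
  expect_true(is.na(r$pcc[5]))  # zero variance
})

test_that("identity-vs-expression correlation over the published pairs is 0.19", {
  tab <- bd_duplicate_pairs()
  keep <- !is.na(tab$expr_pcc)
  expect_equal(sum(keep), 12L)
  expect_equal(round(cor(tab$identity_pct[keep], tab$expr_pcc[keep]), 2),
               0.19)
})

test_that("isoform fold change is antisymmetric and zero at equality", {
  vals <- rbind(`x.1` = c(4, 4, 8, 8), `x.2` = c(4, 4, 2, 2))
  colnames(vals) <- paste0("s", 1:4)
  conds <- c("ctrl", "ctrl", "stress", "stress")
  pairs <- data.frame(t1 = "x.1", t2 = "x.2")
  fc <- isoform_fold_change(vals, pairs, conds, pseudocount = 0)
  expect_equal(fc["x.1/x.2", "ctrl"], 0)
  expect_equal(fc["x.1/x.2", "stress"], 2)
  swapped <- isoform_fold_change(vals, data.frame(t1 = "x.2", t2 = "x.1"),
                                 conds, pseudocount = 0)
  expect_equal(unname(swapped[1, ]), -unname(fc[1, ]))
})
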