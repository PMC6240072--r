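test_that("paired t statistic matches the closed form on litter differences", {
  # per-litter log differences {1, 2, 3, 4}
  d <- c(1, 2, 3, 4)
  tab <- table_from_diffs(d)
  tt <- paired_ttest(tab)
  t_manual <- mean(d) / (stats::sd(d) / sqrt(4))
  expect_equal(tt$t, t_manual, tolerance = 1e-12)
  expect_equal(tt$p_raw, 2 * stats::pt(-abs(t_manual), df = 3),
               tolerance = 1e-12)
  # cross-check against stats::t.test as an independent reference
  ref <- stats::t.test(d)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p_raw, ref$p.value, tolerance = 1e-12)

  # symmetric differences: t = 0, p = 1
  ts <- paired_ttest(table_from_diffs(c(0.4, -0.4, 0.4, -0.4)))
  expect_equal(ts$t, 0, tolerance = 1e-12)
  expect_equal(ts$p_raw, 1, tolerance = 1e-12)

  # all-zero differences are degenerate, flagged, p = 1
  tz <- paired_ttest(table_from_diffs(c(0, 0, 0, 0)))
  expect_true(tz$degenerate)
  expect_equal(tz$p_raw, 1)

  expect_error(paired_ttest(table_from_diffs(1)), "2 litters")
})

test_that("same-genotype littermates are collapsed by mean before pairing", {
  # 2 litters x (2 cystic + 2 control); within-litter replicates differ
  ab <- exp(matrix(c(5.0, 5.4, 4.0, 4.2,    # litter 1: cys 5.0/5.4, ctl 4.0/4.2
                     6.0, 6.2, 5.5, 5.9),   # litter 2
                   ncol = 1))
  rownames(ab) <- paste0("s", 1:8)
  colnames(ab) <- "met1"
  meta <- data.frame(sample_id = rownames(ab),
                     litter = rep(1:2, each = 4),
                     genotype = rep(c("cystic", "cystic", "control",
                                      "control"), 2))
  tab <- paired_abundance_table(ab, meta)
  d <- c(mean(c(5.0, 5.4)) - mean(c(4.0, 4.2)),
         mean(c(6.0, 6.2)) - mean(c(5.5, 5.9)))
  expect_equal(paired_ttest(tab)$t, mean(d) / (stats::sd(d) / sqrt(2)),
               tolerance = 1e-12)
})

test_that("BH adjustment matches the reference implementation", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(2)
  p <- stats::runif(300)
  expect_equal(adjust_pvalues(p), stats::p.adjust(p, "BH"))
  expect_equal(adjust_pvalues(p, "bonferroni"),
               stats::p.adjust(p, "bonferroni"))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # BH output dominates the raw p-values elementwise
  expect_true(all(adjust_pvalues(p) >= p))
})

test_that("fold changes are raw-scale group-mean ratios", {
  ab <- matrix(c(4, 4, 2, 2,   # met1: cystic mean 4, control mean 2
                 3, 3, 3, 3),  # met2: equal means
               ncol = 2)
  rownames(ab) <- paste0("s", 1:4); colnames(ab) <- c("met1", "met2")
  meta <- data.frame(sample_id = rownames(ab), litter = c(1, 2, 1, 2),
                     genotype = rep(c("cystic", "control"), each = 2))
  fc <- fold_change(paired_abundance_table(ab, meta))
  expect_equal(fc$fold_change, c(2, 1))
  expect_equal(fc$log2_fc, c(1, 0))
})

test_that("volcano classification applies joint thresholds", {
  rec <- data.frame(metabolite_id = paste0("m", 1:5),
                    p_adj = c(1, 0.01, 0.01, 0.01, 0.04),
                    fold_change = c(1, 3, 0.2, 1.5, 2.5),
                    degenerate = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- volcano_classify(rec, alpha = 0.05, fc_threshold = 2)
  expect_equal(out$volcano_class, c("ns", "up", "down", "ns", "ns"))
  s <- attr(out, "summary")
  expect_equal(s$n_sig, 3)   # m4 significant but small FC; degenerate excluded
  expect_equal(s$n_up, 1)
  expect_equal(s$n_down, 1)
  expect_lte(s$n_up + s$n_down, s$n_sig)
})

test_that("planted effects are recovered from a simulated study", {
  sim <- simulate_metabolomics(seed = 20)
  dm <- differential_metabolomics(sim$table)
  s <- attr(dm, "summary")
  expect_gt(s$n_up, 171 * 0.95); expect_lt(s$n_up, 171 * 1.05)
  expect_gt(s$n_down, 213 * 0.95); expect_lt(s$n_down, 213 * 1.05)
  # estimated FC of planted-up metabolites concentrates near the truth
  up_ids <- sim$ground_truth$metabolite_id[sim$ground_truth$planted == "up"]
  expect_equal(mean(dm$fold_change[dm$metabolite_id %in% up_ids]), 2.5,
               tolerance = 0.1)
})

test_that("null data keep the type-I error near nominal", {
  sim <- simulate_metabolomics(n_metabolites = 2000, n_planted_up = 0,
                               n_planted_down = 0, seed = 31)
  tt <- paired_ttest(sim$table)
  frac <- mean(tt$p_raw < 0.05)
  ci <- stats::binom.test(sum(tt$p_raw < 0.05), 2000, p = 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("PCA separates genotypes with a planted shift and is deterministic", {
  sim <- simulate_metabolomics(seed = 5)
  pc <- pca_scores(sim$table)
  expect_equal(ncol(pc$scores), 2L)
  expect_true(!is.unsorted(rev(pc$explained)))
  # silhouette of genotype split on PC1 is positive
  x <- pc$scores[, 1]
  g <- pc$genotype == "cystic"
  gap <- abs(mean(x[g]) - mean(x[!g]))
  spread <- (stats::sd(x[g]) + stats::sd(x[!g])) / 2
  expect_gt(gap / spread, 1)

  # duplicated sample gets identical scores
  tab <- sim$table
  ab <- tab$abundances
  ab2 <- rbind(ab, dup = ab[1, ])
  rownames(ab2) <- c(rownames(ab), "dup")
  meta2 <- rbind(tab$sample_meta,
                 data.frame(sample_id = "dup",
                            litter = tab$sample_meta$litter[1],
                            genotype = tab$sample_meta$genotype[1]))
  pc2 <- pca_scores(paired_abundance_table(ab2, meta2))
  expect_equal(unname(pc2$scores["dup", ]),
               unname(pc2$scores[rownames(ab)[1], ]), tolerance = 1e-9)
})

test_that("hierarchical clustering recovers genotype labels on separated data", {
  sim <- simulate_metabolomics(seed = 6, effect_fc = 4,
                               n_planted_up = 150, n_planted_down = 150)
  hc <- hclust_linkage(sim$table)
  cl <- stats::cutree(hc, k = 2)
  g <- sim$table$sample_meta$genotype[match(names(cl),
                                            sim$table$sample_meta$sample_id)]
  expect_true(all(table(cl, g) %in% c(0, 8)))  # pure clusters

  # an identical pair merges first, at height zero; a two-sample tree has
  # a single merge whose height is the pairwise distance
  ab <- exp(rbind(a = c(1, 5, 2), b = c(1, 5, 2),
                  c = c(4, 1, 6), d = c(4, 1.5, 6)))
  colnames(ab) <- paste0("m", 1:3)
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     litter = c(1, 1, 2, 2),
                     genotype = c("cystic", "control", "cystic", "control"))
  hc2 <- hclust_linkage(paired_abundance_table(ab, meta))
  expect_equal(sort(hc2$merge[1, ]), c(-2, -1))  # a-b first
  expect_equal(hc2$height[1], 0)

  ab2 <- ab[1:2, , drop = FALSE]
  ab2["b", ] <- exp(c(2, 4, 1))
  hc3 <- hclust_linkage(paired_abundance_table(ab2, meta[1:2, ]))
  expect_equal(hc3$height,
               as.numeric(stats::dist(log(ab2))), tolerance = 1e-12)
})
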