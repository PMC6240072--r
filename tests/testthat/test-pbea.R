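kegg_ids <- function(n) sprintf("C0%04d", seq_len(n))

test_that("ranked lists sort descending, deduplicate and filter by KEGG id", {
  L <- ranked_list(c("C00001", "C00002", "C00003"), c(1, 3, 2))
  expect_equal(L$entries$kegg_id, c("C00002", "C00003", "C00001"))
  expect_error(ranked_list("C00001", 1), "at least 2")
  expect_error(ranked_list(c("C00001", "C00001"), c(1, 2)), "duplicated")

  src <- data.frame(
    metabolite_id = paste0("m", 1:5),
    kegg_id = c("C00001", NA, "C00002", NA, "C00003"),
    fold_change = c(2, 9, 0.5, 9, 1.2))
  built <- build_ranked_list(src, "fold_change")
  expect_equal(built$N, 3L)  # records without KEGG ids dropped
  expect_equal(built$entries$kegg_id, c("C00001", "C00003", "C00002"))

  # compartmental duplicates of one compound collapse to a single entry
  dup <- data.frame(kegg_id = c("C00158", "C00158", "C00026"),
                    score = c(1, 3, 5))
  bd <- build_ranked_list(dup, "dfa_score")
  expect_equal(bd$N, 2L)
  expect_equal(bd$entries$metric[bd$entries$kegg_id == "C00158"], 4)  # summed

  expect_error(build_ranked_list(src[2, ], "fold_change"), "fewer than 2")
})

test_that("unweighted extremes: members all at top give ES 1, all at bottom -1", {
  ids <- kegg_ids(8)
  L <- ranked_list(ids, 8:1)
  top <- enrichment_score(L, ids[1:3], weight_p = 0)
  expect_equal(top$es, 1, tolerance = 1e-12)
  bottom <- enrichment_score(L, ids[6:8], weight_p = 0)
  expect_equal(bottom$es, -1, tolerance = 1e-12)
  # single member at position 2 of 4 (unweighted): running sum
  # [-1/3, 2/3, 1/3, 0], maximum deviation 2/3
  L4 <- ranked_list(kegg_ids(4), 4:1)
  one <- enrichment_score(L4, kegg_ids(4)[2], weight_p = 0)
  expect_equal(one$es, 2 / 3, tolerance = 1e-12)
  expect_equal(one$running_sum, c(-1 / 3, 2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
})

test_that("running sum returns to zero and errors on degenerate sets", {
  L <- ranked_list(kegg_ids(9), c(4, 3, 2, 1, 0.5, -0.2, -1, -2, -5))
  for (p in c(0, 1, 2)) {
    r <- enrichment_score(L, kegg_ids(9)[c(2, 5, 8)], weight_p = p)
    expect_lt(abs(r$running_sum[9]), 1e-12)
  }
  expect_error(enrichment_score(L, "C09999"), "not represented")
  expect_error(enrichment_score(L, kegg_ids(9)), "miss decrement")
})

test_that("streaming ES equals the exhaustive oracle for every placement, N <= 8", {
  set.seed(81)
  for (N in c(5, 8)) {
    metrics <- sort(stats::rnorm(N, sd = 2), decreasing = TRUE)
    L <- ranked_list(kegg_ids(N), metrics)
    for (k in 1:(N - 1)) {
      for (pos in utils::combn(N, k, simplify = FALSE)) {
        hit <- seq_len(N) %in% pos
        for (p in c(0, 1)) {
          expected <- oracle_es(metrics, hit, p)
          got <- enrichment_score(L, kegg_ids(N)[pos], weight_p = p)
          expect_equal(got$es, expected, tolerance = 1e-12)
          # the O(k) streaming kernel used inside permutations agrees too
          w <- abs(metrics)^p
          expect_equal(fluxda:::es_stream(w, pos, 1 / (N - k)), expected,
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("agreement with fgsea on the weighted statistic", {
  skip_if_not_installed("fgsea")
  set.seed(11)
  N <- 40
  metrics <- sort(stats::rnorm(N, sd = 2), decreasing = TRUE)
  L <- ranked_list(kegg_ids(N), metrics)
  pos <- c(2, 9, 17, 18, 31)
  ours <- enrichment_score(L, kegg_ids(N)[pos], weight_p = 1)$es
  theirs <- fgsea::calcGseaStat(stats::setNames(metrics, kegg_ids(N)),
                                selectedStats = pos, gseaParam = 1)
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("exhaustive permutation p equals the enumeration fraction (N = 4, |S| = 1)", {
  L <- ranked_list(kegg_ids(4), c(5, 2, 1, 0.5))
  obs <- enrichment_score(L, kegg_ids(4)[2], weight_p = 0)
  all_es <- vapply(1:4, function(pos) {
    enrichment_score(L, kegg_ids(4)[pos], weight_p = 0)$es
  }, numeric(1))
  exact_p <- mean(abs(all_es) >= abs(obs$es))
  r <- permutation_pvalue(L, kegg_ids(4)[2], weight_p = 0, exhaustive = TRUE)
  expect_equal(r$p_value, exact_p, tolerance = 1e-12)
  expect_equal(r$n_permutations, 4L)
})

test_that("p-value grid, zero-score edge case, and seed reproducibility", {
  set.seed(3)
  L <- ranked_list(kegg_ids(30), stats::rnorm(30))
  r1 <- permutation_pvalue(L, kegg_ids(30)[c(3, 11, 25)], n_perm = 200,
                           seed = 9)
  r2 <- permutation_pvalue(L, kegg_ids(30)[c(3, 11, 25)], n_perm = 200,
                           seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$p_value * 200, round(r1$p_value * 200))
  expect_gte(r1$p_value, 0); expect_lte(r1$p_value, 1)

  # es = 0 is never beaten in absolute value: p must be 1. A symmetric
  # two-entry list with one hit mid-list gives es = 0 only in contrived
  # cases, so assert through the definition instead: p of the least
  # extreme observable score is 1 under exhaustive enumeration of a
  # symmetric list.
  Ls <- ranked_list(kegg_ids(2), c(1, -1))
  rs <- permutation_pvalue(Ls, kegg_ids(2)[1], weight_p = 0,
                           exhaustive = TRUE)
  expect_equal(rs$p_value, 1)
})

test_that("rank-only statistic is invariant to monotone metric transforms when p = 0", {
  set.seed(5)
  x <- sort(stats::rexp(20), decreasing = TRUE)
  L1 <- ranked_list(kegg_ids(20), x)
  L2 <- ranked_list(kegg_ids(20), log(x + 1))
  members <- kegg_ids(20)[c(2, 7, 15)]
  p1 <- permutation_pvalue(L1, members, weight_p = 0, n_perm = 100, seed = 4)
  p2 <- permutation_pvalue(L2, members, weight_p = 0, n_perm = 100, seed = 4)
  expect_identical(p1$p_value, p2$p_value)
  expect_equal(p1$es, p2$es, tolerance = 1e-12)
})

test_that("enrich_all applies BH across tested pathways and skips unrepresented sets", {
  sim <- simulate_null_ranked_list(40, seed = 2)
  sets <- sim$random_sets(5, size = 6, seed = 3)
  sets[[6]] <- pathway_set("absent", "C99999")
  res <- NULL
  expect_warning(
    res <- enrich_all(sim$list, sets, weight_p = 1, n_perm = 50, seed = 1),
    "skipped")
  expect_equal(nrow(res), 5L)
  expect_equal(res$fdr, stats::p.adjust(res$p_value, "BH")[order(
    order(res$p_value, -abs(res$es), res$pathway))], tolerance = 1e-12)
  expect_true(!is.unsorted(res$p_value))

  # BH arithmetic on two known p-values; m = 1 leaves p untouched
  expect_equal(adjust_pvalues(c(0.01, 1), "BH"), c(0.02, 1))
  expect_equal(adjust_pvalues(0.2, "BH"), 0.2)
})

test_that("null permutation p-values are uniform on the grid", {
  sim <- simulate_null_ranked_list(120, seed = 8)
  sets <- sim$random_sets(200, size = 10, seed = 9)
  pv <- vapply(seq_along(sets), function(i) {
    permutation_pvalue(sim$list, sets[[i]], weight_p = 1, n_perm = 200,
                       seed = 100 + i)$p_value
  }, numeric(1))
  counts <- table(cut(pv, breaks = seq(0, 1, by = 0.1),
                      include.lowest = TRUE))
  gof <- stats::chisq.test(as.vector(counts))
  expect_gt(gof$p.value, 0.01)
})
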