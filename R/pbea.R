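# KEGG-Pathway Based Enrichment Analysis (PBEA): a weighted
# Kolmogorov-Smirnov-like running-sum statistic on a ranked metabolite list,
# with permutation p-values and FDR across pathways.

#' Construct a ranked metabolite list
#'
#' @param kegg_ids Character vector of unique KEGG compound ids.
#' @param metrics Numeric ranking metric, same length; the list is stored in
#'   descending metric order.
#' @return A list of class `"ranked_list"` with `entries`, a `data.frame`
#'   (`kegg_id`, `metric`) sorted descending (id tie-break), `N = nrow`.
#' @export
ranked_list <- function(kegg_ids, metrics) {
  stopifnot(length(kegg_ids) == length(metrics))
  if (length(kegg_ids) < 2L) stop("a ranked list needs at least 2 entries")
  if (anyDuplicated(kegg_ids)) {
    stop("duplicated KEGG id(s) in ranked list: ",
         paste(unique(kegg_ids[duplicated(kegg_ids)]), collapse = ", "))
  }
  ord <- order(-metrics, kegg_ids, method = "radix")
  structure(list(entries = data.frame(kegg_id = kegg_ids[ord],
                                      metric = metrics[ord],
                                      stringsAsFactors = FALSE),
                 N = length(kegg_ids)),
            class = "ranked_list")
}

#' Build a ranked list from differential records
#'
#' Restricts the input to records carrying a KEGG identifier (metabolites
#' without one are not eligible for enrichment), collapses compartmental
#' duplicates of the same compound, and sorts descending by the chosen
#' metric.
#'
#' @param source A `data.frame`: either differential-metabolomics records
#'   (columns `kegg_id`, `fold_change`) or DFA metabolite ranks from
#'   [rank_metabolites()] (columns `kegg_id`, `score`).
#' @param metric `"fold_change"` or `"dfa_score"`.
#' @param collapse How to combine duplicate KEGG ids: `"sum"` (default for
#'   DFA incidence scores) or `"mean"` (default for fold changes).
#' @return A [ranked_list()].
#' @export
build_ranked_list <- function(source, metric = c("fold_change", "dfa_score"),
                              collapse = NULL) {
  metric <- match.arg(metric)
  col <- if (metric == "fold_change") "fold_change" else "score"
  if (!col %in% names(source)) {
    stop("source records lack the '", col, "' column required for metric '",
         metric, "'")
  }
  if (is.null(collapse)) collapse <- if (metric == "fold_change") "mean" else "sum"
  keep <- !is.na(source$kegg_id) & !is.na(source[[col]])
  src <- source[keep, c("kegg_id", col)]
  if (nrow(src) < 2L) stop("fewer than 2 KEGG-mapped entries; cannot rank")
  fun <- if (collapse == "sum") sum else mean
  agg <- stats::aggregate(src[[col]], by = list(kegg_id = src$kegg_id), FUN = fun)
  ranked_list(agg$kegg_id, agg$x)
}

# ES from sorted hit positions without materialising the running sum.
# w: |metric|^p over the full list (descending order); md: miss decrement.
# Deviation extremes occur at hit positions (after the jump) or one step
# before a hit (after the preceding miss run), so 2k candidates suffice.
es_stream <- function(w, pos, md) {
  pos <- sort.int(pos)
  k <- length(pos)
  wh <- w[pos]
  tw <- sum(wh)
  if (tw <= 0) stop("zero total hit weight; cannot normalise increments")
  cw <- cumsum(wh) / tw
  drop_ <- (pos - seq_len(k)) * md
  at_hit <- cw - drop_
  before_hit <- c(0, cw[-k]) - drop_
  # interleave in list order (just-before-hit, then at-hit) so ties (within
  # 1e-12) resolve to the earliest position, matching the full running sum
  cand <- as.vector(rbind(before_hit, at_hit))
  cand[which(abs(cand) >= max(abs(cand)) - 1e-12)[1]]
}

#' Enrichment score of a pathway set on a ranked list
#'
#' Walks down the list accumulating a running sum: at a list member belonging
#' to the set ("hit") it increases by that entry's normalised weight
#' `|metric|^weight_p / sum(hit weights)`; at a non-member ("miss") it
#' decreases by `1/(N - n_hits)`. The enrichment score is the running-sum
#' value of maximum absolute deviation from zero, kept signed. With
#' `weight_p = 0` this is the classical Kolmogorov-Smirnov statistic; the
#' GSEA-style default is `weight_p = 1`. The final running-sum value is 0 by
#' construction of the two normalisers.
#'
#' @param L A [ranked_list()].
#' @param S A [pathway_set()] (or character vector of KEGG ids).
#' @param weight_p Non-negative weighting exponent (default 1).
#' @return A list with `es` (signed score), `running_sum` (numeric, length
#'   `N`), `n_hits`.
#' @export
enrichment_score <- function(L, S, weight_p = 1) {
  stopifnot(inherits(L, "ranked_list"), weight_p >= 0)
  members <- if (inherits(S, "pathway_set")) S$members else as.character(S)
  hit <- L$entries$kegg_id %in% members
  k <- sum(hit)
  N <- L$N
  if (k == 0L) stop("pathway not represented in the ranked list")
  if (k == N) stop("pathway covers the whole list; miss decrement undefined")
  w <- abs(L$entries$metric)^weight_p
  pos <- which(hit)
  tw <- sum(w[pos])
  if (tw <= 0) stop("zero total hit weight; cannot normalise increments")
  md <- 1 / (N - k)
  inc <- rep(-md, N)
  inc[pos] <- w[pos] / tw
  run <- cumsum(inc)
  es <- run[which(abs(run) >= max(abs(run)) - 1e-12)[1]]
  list(es = es, running_sum = run, n_hits = k)
}

#' Permutation p-value of an enrichment score
#'
#' The metric-to-id assignment is permuted uniformly at random `n_perm`
#' times (equivalently, the set's hit positions are redrawn uniformly without
#' replacement, since the metric column stays sorted), the score recomputed
#' each time, and `p` is the fraction of permutations at least as extreme as
#' the observed score: on `|es|` by default, or on the signed score with
#' `extremeness = "signed"`. With the default estimator `p` lies on the grid
#' `{0, 1/n_perm, ..., 1}`; `smoothed = TRUE` uses `(k + 1)/(n_perm + 1)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the RNG state is restored on exit.
#' @param extremeness `"absolute"` (two-sided, default) or `"signed"`.
#' @param smoothed Add-one smoothing of the p estimate (off by default).
#' @param exhaustive Enumerate all `choose(N, n_hits)` distinct hit-position
#'   sets instead of sampling (exact null; only sensible for tiny lists).
#' @return A list of class `"enrichment_result"`: `pathway`, `es`, `p_value`,
#'   `n_hits`, `n_permutations`.
#' @export
permutation_pvalue <- function(L, S, weight_p = 1, n_perm = 1000, seed = 1,
                               extremeness = c("absolute", "signed"),
                               smoothed = FALSE, exhaustive = FALSE) {
  extremeness <- match.arg(extremeness)
  stopifnot(n_perm >= 1)
  obs <- enrichment_score(L, S, weight_p)
  N <- L$N; k <- obs$n_hits
  w <- abs(L$entries$metric)^weight_p
  md <- 1 / (N - k)
  perm_es <- if (exhaustive) {
    vapply(utils::combn(N, k, simplify = FALSE),
           function(pos) es_stream(w, pos, md), numeric(1))
  } else {
    with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        es_stream(w, sample.int(N, k), md)
      }, numeric(1))
    })
  }
  if (exhaustive) n_perm <- length(perm_es)
  extreme <- if (extremeness == "absolute") {
    abs(perm_es) >= abs(obs$es)
  } else if (obs$es >= 0) perm_es >= obs$es else perm_es <= obs$es
  p <- if (smoothed) (sum(extreme) + 1) / (n_perm + 1) else mean(extreme)
  name <- if (inherits(S, "pathway_set")) S$name else NA_character_
  structure(list(pathway = name, es = obs$es, p_value = p, n_hits = k,
                 n_permutations = n_perm),
            class = "enrichment_result")
}

#' Enrichment of every pathway set against a ranked list
#'
#' Runs [permutation_pvalue()] for each pathway with at least one metabolite
#' captured in the list (others are skipped with a warning), then adjusts the
#' p-values across the tested pathways.
#'
#' @inheritParams permutation_pvalue
#' @param pathway_sets A list of [pathway_set()] objects (e.g. from
#'   [read_pathway_sets()]).
#' @param fdr_method `"BH"` (default) or `"bonferroni"`.
#' @return A `data.frame` sorted by `p_value` then decreasing `|es|`, with
#'   columns `pathway`, `es`, `n_hits`, `p_value`, `fdr`, `n_permutations`.
#' @export
enrich_all <- function(L, pathway_sets, weight_p = 1, n_perm = 1000, seed = 1,
                       extremeness = c("absolute", "signed"),
                       fdr_method = c("BH", "bonferroni"), smoothed = FALSE) {
  extremeness <- match.arg(extremeness)
  fdr_method <- match.arg(fdr_method)
  res <- list()
  for (j in seq_along(pathway_sets)) {
    S <- pathway_sets[[j]]
    r <- tryCatch(
      permutation_pvalue(L, S, weight_p = weight_p, n_perm = n_perm,
                         seed = seed + j, extremeness = extremeness,
                         smoothed = smoothed),
      error = function(e) {
        warning("pathway '", S$name, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(r)) res[[length(res) + 1L]] <- r
  }
  if (length(res) == 0L) stop("no pathway passed the representation check")
  out <- data.frame(pathway = vapply(res, `[[`, "", "pathway"),
                    es = vapply(res, `[[`, 0, "es"),
                    n_hits = vapply(res, `[[`, 0L, "n_hits"),
                    p_value = vapply(res, `[[`, 0, "p_value"),
                    stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p_value, method = fdr_method)
  out$n_permutations <- n_perm
  ord <- order(out$p_value, -abs(out$es), out$pathway, method = "radix")
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
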