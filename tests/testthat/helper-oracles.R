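# Independent oracles and fixture builders used across the suite.

# Brute-force LP oracle: enumerate every basic solution of
# {S v = 0, lb <= v <= ub} (all choices of n - rank(S) active bounds),
# keep the feasible ones, and return the best objective value. Exponential,
# usable only for the small networks it is called on.
oracle_lp_max <- function(S, lb, ub, cvec, tol = 1e-7) {
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  best <- -Inf
  if (k == 0L) {
    # unique steady state candidate: v = 0 if feasible
    if (all(lb <= tol) && all(ub >= -tol)) best <- 0
    return(best)
  }
  for (J in utils::combn(n, k, simplify = FALSE)) {
    free <- setdiff(seq_len(n), J)
    A <- S[, free, drop = FALSE]
    qa <- qr(A)
    if (qa$rank < length(free)) next
    for (mask in 0:(2^k - 1)) {
      at_ub <- bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0
      vJ <- ifelse(at_ub, ub[J], lb[J])
      b <- -as.numeric(S[, J, drop = FALSE] %*% vJ)
      x <- qr.coef(qa, b)
      if (anyNA(x)) next
      if (max(abs(A %*% x - b)) > tol) next
      v <- numeric(n)
      v[J] <- vJ
      v[free] <- x
      if (all(v >= lb - tol) && all(v <= ub + tol)) {
        best <- max(best, sum(cvec * v))
      }
    }
  }
  best
}

# Random small feasible network: the first m reactions are per-metabolite
# boundary reactions (identity block, so rank(S) = m and v = 0 is always
# feasible); k extra sparse internal reactions connect them.
random_small_model <- function(m = 6, k = 3, seed = 1) {
  set.seed(seed)
  n <- m + k
  S <- cbind(diag(m), matrix(0, m, k))
  for (j in seq_len(k)) {
    nz <- sample(m, sample(2:3, 1))
    S[nz, m + j] <- sample(c(-1, 1, -2, 2), length(nz), replace = TRUE)
  }
  lb <- ifelse(stats::runif(n) < 0.3, -round(stats::runif(n, 1, 5), 1), 0)
  ub <- round(stats::runif(n, 1, 10), 1)
  mets <- do.call(rbind, lapply(seq_len(m), function(i) {
    metabolite(sprintf("m%02d", i), compartment = "c")
  }))
  rxns <- lapply(seq_len(n), function(j) {
    s <- S[, j]
    reaction(sprintf("r%02d", j), stats::setNames(s[s != 0],
                                                  mets$id[s != 0]),
             lower_bound = lb[j], upper_bound = ub[j])
  })
  metabolic_model(mets, rxns, compartments = "c")
}

# Plain-loop recomputation of the weighted running-sum enrichment score:
# walks the list position by position, tracking the maximum deviation.
oracle_es <- function(metrics_sorted, hit, weight_p) {
  N <- length(metrics_sorted)
  k <- sum(hit)
  w <- abs(metrics_sorted)^weight_p
  tw <- sum(w[hit])
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) w[i] / tw else -1 / (N - k)
    if (abs(run) > abs(best) + 1e-12) best <- run
  }
  best
}

# Minimal linear chain model: uptake -> A -> B -> export.
chain_model <- function(uptake_ub = 10) {
  mets <- rbind(metabolite("A", compartment = "c"),
                metabolite("B", compartment = "c"))
  rxns <- list(
    reaction("uptake", c(A = 1), 0, uptake_ub),
    reaction("conv", c(A = -1, B = 1), 0, 100),
    reaction("export", c(B = -1), 0, 100))
  metabolic_model(mets, rxns, compartments = "c")
}

# Small paired table from explicit per-litter log differences: one cystic
# and one control sample per litter, control fixed at log-abundance `base`.
table_from_diffs <- function(d, base = 5) {
  nlit <- length(d)
  ab <- matrix(c(exp(base + d), rep(exp(base), nlit)), ncol = 1)
  rownames(ab) <- c(sprintf("cys%d", seq_len(nlit)),
                    sprintf("ctl%d", seq_len(nlit)))
  colnames(ab) <- "met1"
  meta <- data.frame(sample_id = rownames(ab),
                     litter = rep(seq_len(nlit), 2),
                     genotype = rep(c("cystic", "control"), each = nlit),
                     stringsAsFactors = FALSE)
  paired_abundance_table(ab, meta)
}
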