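# Dense two-phase bounded-variable revised simplex.
#
# Solves  min/max c'x  s.t.  A x = b,  lb <= x <= ub  with A of full row
# rank. Written for the moderate problem sizes of curated metabolic models
# (tens of reactions): the basis system is re-solved from the original data
# every iteration, so no error accumulates in a tableau, and Bland's rule
# guarantees termination on degenerate bases.

#' Solve a bounded-variable linear program
#'
#' @param A Constraint matrix (`m x n`), full row rank (see
#'   [independent_rows()]).
#' @param b Right-hand side, length `m`.
#' @param lb,ub Variable bounds (finite, except artificial handling
#'   internally); `lb <= ub`.
#' @param cvec Objective coefficients, length `n`.
#' @param maximize Maximise instead of minimise.
#' @param tol Feasibility/pricing tolerance.
#' @param maxit Iteration cap per phase pair.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxit"`, `"singular"`), `x` (solution), `value` (objective).
#' @keywords internal
lp_simplex <- function(A, b, lb, ub, cvec, maximize = FALSE, tol = 1e-9,
                       maxit = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(lb) == n, length(ub) == n,
            length(cvec) == n, all(lb <= ub + tol))
  csign <- if (maximize) -1 else 1
  # start: every structural variable at the finite bound nearer zero
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  where <- ifelse(abs(lb) <= abs(ub), 1L, 2L)  # 1 at lower, 2 at upper
  r <- b - as.numeric(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Ae <- cbind(A, diag(sgn, m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  xe <- c(x, abs(r))
  where <- c(where, rep(0L, m))          # artificials start basic
  basis <- n + seq_len(m)
  art <- n + seq_len(m)
  phase <- 1L
  cost <- c(rep(0, n), rep(1, m))

  refresh_basics <- function() {
    nb <- which(where != 0L)
    B <- Ae[, basis, drop = FALSE]
    rhs <- b - as.numeric(Ae[, nb, drop = FALSE] %*% xe[nb])
    sol <- tryCatch(solve(B, rhs), error = function(e) NULL)
    if (is.null(sol)) return(FALSE)
    xe[basis] <<- sol
    TRUE
  }

  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) return(list(status = "maxit"))
    if (!refresh_basics()) return(list(status = "singular"))
    B <- Ae[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
    if (is.null(y)) return(list(status = "singular"))
    nb <- which(where != 0L)
    dj <- cost[nb] - as.numeric(crossprod(Ae[, nb, drop = FALSE], y))
    elig <- (where[nb] == 1L & dj < -tol) | (where[nb] == 2L & dj > tol)
    if (!any(elig)) {
      # phase optimum reached
      if (phase == 1L) {
        if (sum(xe[art]) > 1e-7) return(list(status = "infeasible"))
        # pin artificials to zero and switch to the real objective
        ube[art] <- 0
        xe[art] <- 0
        phase <- 2L
        cost <- c(csign * cvec, rep(0, m))
        next
      }
      xs <- xe[seq_len(n)]
      return(list(status = "optimal", x = xs,
                  value = sum(cvec * xs)))
    }
    j <- nb[elig][which.min(nb[elig])]     # Bland: smallest eligible index
    w <- solve(B, Ae[, j])
    up <- where[j] == 1L                   # entering variable moves up?
    d <- if (up) -w else w                 # basic change per unit t >= 0
    # ratio test: how far can the entering variable move before a basic
    # variable hits a bound, or the entering variable reaches its other one
    ts <- rep(Inf, m); tos <- integer(m)
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (d[i] < -tol) {
        ts[i] <- max((xe[bi] - lbe[bi]) / (-d[i]), 0); tos[i] <- 1L
      } else if (d[i] > tol && is.finite(ube[bi])) {
        ts[i] <- max((ube[bi] - xe[bi]) / d[i], 0); tos[i] <- 2L
      }
    }
    flip_t <- ube[j] - lbe[j]
    tmin <- min(ts)
    if (!is.finite(tmin) && !is.finite(flip_t)) {
      return(list(status = "unbounded"))
    }
    if (flip_t < tmin - tol) {
      # entering variable flips to its other bound; basis unchanged
      xe[basis] <- xe[basis] + d * flip_t
      xe[j] <- if (up) ube[j] else lbe[j]
      where[j] <- if (up) 2L else 1L
    } else {
      cand <- which(ts <= tmin + tol)
      leave <- cand[which.min(basis[cand])]  # Bland tie-break
      step <- ts[leave]
      xe[basis] <- xe[basis] + d * step
      xe[j] <- if (up) lbe[j] + step else ube[j] - step
      out_var <- basis[leave]
      xe[out_var] <- if (tos[leave] == 1L) lbe[out_var] else ube[out_var]
      where[out_var] <- tos[leave]
      basis[leave] <- j
      where[j] <- 0L
    }
  }
}
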