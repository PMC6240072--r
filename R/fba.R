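# Flux balance analysis: LP solves with parsimonious canonicalisation,
# objective sweeps, and condition perturbations.

FD_TOL_FEAS <- 1e-9    # bound violation tolerance
FD_TOL_SS <- 1e-6      # steady-state residual tolerance
FD_TOL_CLAMP <- 1e-9   # reported fluxes below this magnitude are set to 0

# Drop linearly dependent rows of S (conserved moieties) so the equality
# block passed to the simplex has full row rank. With a zero right-hand
# side the dropped rows are implied by the kept ones.
independent_rows <- function(S) {
  qrS <- qr(t(S))
  S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
}

# Solve max/min c'v s.t. S v = b, lb <= v <= ub with the bounded-variable
# simplex, after eliminating fixed (zero-width) reactions into the RHS and
# reducing the constraint rows to an independent set. The full residual is
# re-checked afterwards so a rank reduction can never hide inconsistency.
fd_lp_solve <- function(S, b, lb, ub, cvec, maximize) {
  n <- ncol(S)
  fixed <- which(ub - lb < 1e-12)
  free <- setdiff(seq_len(n), fixed)
  bred <- b - if (length(fixed)) {
    as.numeric(S[, fixed, drop = FALSE] %*% lb[fixed])
  } else 0
  Sf <- S[, free, drop = FALSE]
  keep <- qr(t(Sf))
  rows <- keep$pivot[seq_len(keep$rank)]
  out <- lp_simplex(Sf[rows, , drop = FALSE], bred[rows],
                    lb[free], ub[free], cvec[free], maximize = maximize)
  if (out$status != "optimal") return(out)
  v <- numeric(n)
  v[fixed] <- lb[fixed]
  v[free] <- out$x
  if (max(abs(S %*% v - b)) > FD_TOL_SS) {
    return(list(status = "infeasible"))
  }
  list(status = "optimal", x = v, value = sum(cvec * v))
}

# Parsimonious canonicalisation: minimise sum(|v|) over the optimal face
# (pFBA-style secondary LP). The optimal face is pinned through the
# objective reaction's bounds when the objective is a single reaction, or
# through an extra equality row otherwise. Only reversible reactions
# (lb < 0) are split v = p - q; irreversible ones contribute |v| = v.
fd_canonicalize <- function(S, lb, ub, cvec, zstar) {
  n <- ncol(S)
  nz <- which(cvec != 0)
  if (length(nz) == 1L) {
    val <- min(max(zstar / cvec[nz], lb[nz]), ub[nz])
    lb[nz] <- val
    ub[nz] <- val
    Spin <- S
    bpin <- rep(0, nrow(S))
  } else {
    Spin <- rbind(S, cvec)
    bpin <- c(rep(0, nrow(S)), zstar)
  }
  rev_ <- which(lb < 0)
  if (length(rev_) == 0L) {
    out <- fd_lp_solve(Spin, bpin, lb, ub, rep(1, n), maximize = FALSE)
    if (out$status != "optimal") stop("secondary LP not solved")
    return(out$x)
  }
  Saug <- cbind(Spin, -Spin[, rev_, drop = FALSE])
  lba <- c(pmax(lb, 0), pmax(-ub[rev_], 0))
  uba <- c(ub, -pmin(lb[rev_], 0))
  uba[rev_] <- pmax(ub[rev_], 0)
  out <- fd_lp_solve(Saug, bpin, lba, uba, rep(1, n + length(rev_)),
                     maximize = FALSE)
  if (out$status != "optimal") stop("secondary LP not solved")
  v <- out$x[seq_len(n)]
  v[rev_] <- v[rev_] - out$x[n + seq_along(rev_)]
  v
}

resolve_objective <- function(model, objective) {
  rxn_ids <- model$reactions$id
  if (is.character(objective)) {
    missing <- setdiff(objective, rxn_ids)
    if (length(missing)) {
      stop("objective references unknown reaction(s): ",
           paste(missing, collapse = ", "))
    }
    cf <- stats::setNames(rep(0, length(rxn_ids)), rxn_ids)
    cf[objective] <- 1
    list(coef = cf, id = paste(objective, collapse = "+"))
  } else if (is.numeric(objective) && !is.null(names(objective))) {
    missing <- setdiff(names(objective), rxn_ids)
    if (length(missing)) {
      stop("objective references unknown reaction(s): ",
           paste(missing, collapse = ", "))
    }
    cf <- stats::setNames(rep(0, length(rxn_ids)), rxn_ids)
    cf[names(objective)] <- objective
    list(coef = cf, id = paste(names(objective), collapse = "+"))
  } else {
    stop("objective must be a reaction id vector or a named coefficient vector")
  }
}

#' Solve a flux balance analysis problem
#'
#' Finds a steady-state flux vector `v` with `S v = 0` and
#' `lb <= v <= ub` optimising a linear objective. Among alternate optima a
#' canonical solution is returned: after fixing the objective at its optimum,
#' the sum of absolute fluxes is minimised (parsimonious secondary LP), which
#' suppresses futile cycles and makes averages over objective sweeps
#' reproducible. Reported fluxes with magnitude below `1e-9` are clamped to
#' zero.
#'
#' @param model A [metabolic_model()]. All bounds are finite by construction,
#'   so the LP is never unbounded; the `status` field still carries the full
#'   enum for interface stability.
#' @param objective A reaction id (or several, summed), or a named numeric
#'   vector of objective coefficients keyed by reaction id.
#' @param sense `"max"` (default) or `"min"`.
#' @param canonical Apply the parsimonious canonicalisation (default
#'   `TRUE`).
#' @return A list of class `"flux_solution"` with `fluxes` (named numeric over
#'   all reactions), `objective_id`, `objective_value`, and `status` (one of
#'   `"optimal"`, `"infeasible"`, `"unbounded"`). For non-optimal status the
#'   flux map is `NULL`.
#' @export
solve_fba <- function(model, objective, sense = c("max", "min"),
                      canonical = TRUE) {
  sense <- match.arg(sense)
  obj <- resolve_objective(model, objective)
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- length(lb)

  out <- fd_lp_solve(S, rep(0, nrow(S)), lb, ub, unname(obj$coef),
                     maximize = (sense == "max"))
  if (out$status != "optimal") {
    status <- if (out$status == "unbounded") "unbounded" else "infeasible"
    return(structure(list(fluxes = NULL, objective_id = obj$id,
                          objective_value = NA_real_, status = status),
                     class = "flux_solution"))
  }
  v <- out$x
  zstar <- sum(obj$coef * v)

  if (canonical) {
    v2 <- tryCatch(fd_canonicalize(S, lb, ub, unname(obj$coef), zstar),
                   error = function(e) NULL)
    if (!is.null(v2)) v <- v2
    else warning("canonicalisation failed; returning raw vertex solution",
                 call. = FALSE)
  }
  v[abs(v) < FD_TOL_CLAMP] <- 0
  names(v) <- model$reactions$id

  resid <- max(abs(S %*% v))
  if (resid > FD_TOL_SS) {
    warning("steady-state residual ", format(resid), " exceeds tolerance")
  }
  if (any(v < lb - 1e-6) || any(v > ub + 1e-6)) {
    warning("flux bound violation beyond tolerance in solution")
  }
  structure(list(fluxes = v, objective_id = obj$id,
                 objective_value = sum(obj$coef * v), status = "optimal"),
            class = "flux_solution")
}

#' Average fluxes across a sweep of metabolic objectives
#'
#' Solves one FBA problem per objective and averages the canonical flux of
#' each reaction over the solved objectives. Infeasible objectives are
#' skipped with a warning and excluded from the mean denominator.
#'
#' @param model A [metabolic_model()].
#' @param objectives Character vector of reaction ids, or a list whose
#'   elements are accepted by [solve_fba()] as objectives.
#' @param sense `"max"` or `"min"`, applied to every objective.
#' @param condition_label Label stored on the profile (e.g. `"wild-type"`).
#' @param keep_solutions Also return the individual [solve_fba()] solutions.
#' @return A list of class `"average_flux_profile"` with `mean_flux` (named
#'   numeric over every model reaction), `n_objectives`, `objective_ids`, and
#'   `condition_label` (and `solutions` if requested).
#' @export
objective_sweep <- function(model, objectives, sense = c("max", "min"),
                            condition_label = "condition",
                            keep_solutions = FALSE) {
  sense <- match.arg(sense)
  if (length(objectives) == 0L) stop("objectives must be non-empty")
  if (is.character(objectives)) objectives <- as.list(objectives)
  sols <- list(); ids <- character(0)
  for (objv in objectives) {
    sol <- solve_fba(model, objv, sense = sense)
    if (sol$status != "optimal") {
      warning("objective '", sol$objective_id, "' is ", sol$status,
              "; skipped from sweep", call. = FALSE)
      next
    }
    sols[[length(sols) + 1L]] <- sol
    ids <- c(ids, sol$objective_id)
  }
  if (length(sols) == 0L) stop("all objectives infeasible; no sweep average")
  fluxmat <- do.call(rbind, lapply(sols, `[[`, "fluxes"))
  prof <- structure(list(mean_flux = colMeans(fluxmat),
                         n_objectives = length(sols),
                         objective_ids = ids,
                         condition_label = condition_label),
                    class = "average_flux_profile")
  if (keep_solutions) prof$solutions <- sols
  prof
}

#' Specify a model perturbation
#'
#' @param disabled_reactions Character vector of reaction ids to shut off
#'   (`lb = ub = 0`), e.g. tissue-specific functions removed by configuration.
#' @param direction_blocks Data frame with columns `reaction_id`, `lower_bound`,
#'   `upper_bound`: bounds applied verbatim, typically to make a transport or
#'   enzymatic step irreversible.
#' @param forced_uptake Data frame with columns `reaction_id`, `factor`
#'   (positive): each listed reaction's lower bound is raised to
#'   `factor * baseline_mean_flux`, forcing at least that flux in every
#'   subsequent solve. The headline use is forcing glucose transporters to
#'   1.6x their wild-type sweep average.
#' @return A list of class `"perturbation_spec"`.
#' @export
perturbation_spec <- function(disabled_reactions = character(0),
                              direction_blocks = NULL,
                              forced_uptake = NULL) {
  if (!is.null(direction_blocks)) {
    stopifnot(all(c("reaction_id", "lower_bound", "upper_bound") %in%
                    names(direction_blocks)))
    if (any(direction_blocks$lower_bound > direction_blocks$upper_bound)) {
      stop("direction_blocks must preserve lower_bound <= upper_bound")
    }
  }
  if (!is.null(forced_uptake)) {
    stopifnot(all(c("reaction_id", "factor") %in% names(forced_uptake)))
    if (any(forced_uptake$factor <= 0)) stop("forced_uptake factors must be > 0")
  }
  structure(list(disabled_reactions = disabled_reactions,
                 direction_blocks = direction_blocks,
                 forced_uptake = forced_uptake),
            class = "perturbation_spec")
}

#' Apply a perturbation to a model
#'
#' Pure function: returns a modified copy, never mutating the input. Disabled
#' reactions get `lb = ub = 0`; direction blocks are applied verbatim; each
#' forced-uptake reaction `r` gets `lower_bound = factor * baseline$mean_flux[r]`
#' with the upper bound unchanged.
#'
#' @param model A [metabolic_model()].
#' @param baseline An [objective_sweep()] profile of the unperturbed model;
#'   required when `spec` contains forced uptakes.
#' @param spec A [perturbation_spec()].
#' @return A new, validated `"metabolic_model"`.
#' @export
apply_perturbation <- function(model, baseline = NULL, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  rx <- model$reactions
  idx <- function(id) {
    i <- match(id, rx$id)
    if (anyNA(i)) stop("perturbation references unknown reaction(s): ",
                       paste(id[is.na(i)], collapse = ", "))
    i
  }
  if (length(spec$disabled_reactions)) {
    i <- idx(spec$disabled_reactions)
    rx$lower_bound[i] <- 0; rx$upper_bound[i] <- 0
  }
  if (!is.null(spec$direction_blocks)) {
    i <- idx(spec$direction_blocks$reaction_id)
    rx$lower_bound[i] <- spec$direction_blocks$lower_bound
    rx$upper_bound[i] <- spec$direction_blocks$upper_bound
  }
  if (!is.null(spec$forced_uptake)) {
    if (is.null(baseline)) stop("forced_uptake requires a baseline profile")
    fu <- spec$forced_uptake
    i <- idx(fu$reaction_id)
    base <- baseline$mean_flux[fu$reaction_id]
    if (anyNA(base)) {
      stop("forced reaction(s) absent from baseline profile: ",
           paste(fu$reaction_id[is.na(base)], collapse = ", "))
    }
    if (any(base <= 0)) {
      stop("baseline mean flux <= 0 for forced reaction(s): ",
           paste(fu$reaction_id[base <= 0], collapse = ", "),
           " (threshold ill-defined)")
    }
    new_lb <- fu$factor * base
    if (any(new_lb > rx$upper_bound[i])) {
      stop("forced lower bound exceeds upper bound for: ",
           paste(fu$reaction_id[new_lb > rx$upper_bound[i]], collapse = ", "))
    }
    rx$lower_bound[i] <- new_lb
  }
  out <- model
  out$reactions <- rx
  validate_model(out)
  out
}

#' Find reactions by external reference
#'
#' @param model A [metabolic_model()].
#' @param external_ref Character vector of external references (e.g. TCDB
#'   accessions) to look up.
#' @return Character vector of matching reaction ids.
#' @export
reactions_by_ref <- function(model, external_ref) {
  model$reactions$id[model$reactions$external_ref %in% external_ref]
}
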