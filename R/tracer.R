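# Stable-isotope tracer arithmetic: mass-isotopologue distributions (MID),
# natural-abundance correction by the binomial convolution-matrix method,
# and medium consumption/release rates normalised to protein growth.

# default natural abundances of the heavy isotope
FD_NA_C13 <- 0.0107
FD_NA_N15 <- 0.00364

#' Fractions of a mass-isotopologue distribution
#'
#' @param raw_intensities Non-negative intensities over isotopologues
#'   `M+0 .. M+n` (at least one positive).
#' @return Fractions `raw / sum(raw)`, summing to 1. Scale-invariant:
#'   `mid_fractions(k * v)` equals `mid_fractions(v)` for `k > 0`.
#' @export
mid_fractions <- function(raw_intensities) {
  stopifnot(is.numeric(raw_intensities))
  if (any(raw_intensities < 0)) stop("intensities must be non-negative")
  tot <- sum(raw_intensities)
  if (tot <= 0) stop("all-zero intensity vector; MID undefined")
  raw_intensities / tot
}

#' Natural-abundance convolution matrix
#'
#' Lower-triangular matrix `C` with
#' `C[i, j] = choose(n - j, i - j) * a^(i-j) * (1-a)^(n-i)` (0-based
#' isotopologue indices, `i >= j`): column `j` is the measured distribution
#' produced by a species with `j` tracer atoms when each of the remaining
#' `n - j` atoms is heavy with probability `a`. Column sums are at most 1.
#'
#' @param n_atoms Number of atoms of the labelled element.
#' @param isotope_abundance Natural abundance `a` of the heavy isotope,
#'   `0 < a < 1`.
#' @return `(n_atoms + 1) x (n_atoms + 1)` matrix.
#' @export
correction_matrix <- function(n_atoms, isotope_abundance) {
  stopifnot(n_atoms >= 0, isotope_abundance > 0, isotope_abundance < 1)
  a <- isotope_abundance
  n <- n_atoms
  C <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    k <- 0:(n - j)
    C[j + 1 + k, j + 1] <- stats::dbinom(k, n - j, a)
  }
  C
}

#' Correct a measured MID for natural isotope abundance
#'
#' Solves the forward model `C x = raw` (with `C` from
#' [correction_matrix()]), clamps small negative solution entries caused by
#' noise to zero, and renormalises to sum 1. When the clamped mass exceeds
#' 1\% of the distribution a QC flag is raised via the `"clamped"` attribute.
#' This is the standard matrix method used throughout isotope-tracing
#' software.
#'
#' @param raw_fractions Measured fractions over `M+0 .. M+n_atoms`.
#' @param n_atoms Number of atoms of the labelled element
#'   (`length(raw_fractions) == n_atoms + 1`).
#' @param isotope_abundance Natural heavy-isotope abundance (defaults:
#'   carbon-13 0.0107; use 0.00364 for nitrogen-15).
#' @return Corrected fractions summing to 1, with attribute `"clamped"`
#'   (total negative mass removed) and `"qc_flag"` (`TRUE` if clamped mass
#'   > 1\%).
#' @export
natural_abundance_correct <- function(raw_fractions, n_atoms,
                                      isotope_abundance = FD_NA_C13) {
  if (length(raw_fractions) != n_atoms + 1L) {
    stop("expected ", n_atoms + 1L, " fractions (M+0 .. M+", n_atoms,
         "), got ", length(raw_fractions))
  }
  if (n_atoms == 0L) {
    out <- raw_fractions / sum(raw_fractions)
    attr(out, "clamped") <- 0; attr(out, "qc_flag") <- FALSE
    return(out)
  }
  C <- correction_matrix(n_atoms, isotope_abundance)
  x <- solve(C, raw_fractions)
  clamped <- -sum(x[x < 0])
  x[x < 0] <- 0
  if (sum(x) <= 0) stop("corrected distribution vanished; bad input")
  out <- x / sum(x)
  attr(out, "clamped") <- clamped
  attr(out, "qc_flag") <- clamped > 0.01
  out
}

#' Forward natural-abundance convolution of a true MID
#'
#' The forward model inverted by [natural_abundance_correct()]; composing
#' the two is the identity on any valid MID.
#'
#' @inheritParams natural_abundance_correct
#' @param true_fractions Tracer-only MID over `M+0 .. M+n_atoms`.
#' @return The distribution that would be measured.
#' @export
natural_abundance_convolve <- function(true_fractions, n_atoms,
                                       isotope_abundance = FD_NA_C13) {
  stopifnot(length(true_fractions) == n_atoms + 1L)
  if (n_atoms == 0L) return(true_fractions)
  as.numeric(correction_matrix(n_atoms, isotope_abundance) %*% true_fractions)
}

#' Medium consumption / release rate normalised to protein growth
#'
#' `rate = (spent_pool - fresh_pool) / (protein_t24 - protein_t0)`: the net
#' change of a metabolite's total pool between fresh medium (incubated
#' without cells) and spent medium, per unit of protein generated during the
#' incubation. Negative rates are net consumption, positive net release.
#'
#' @param fresh_pool,spent_pool Metabolite pools (same units).
#' @param protein_t0,protein_t24 Protein mass at the start and end of the
#'   incubation; growth (`t24 > t0`) is required for the normalisation.
#' @return The signed rate (pool units per protein mass).
#' @export
consumption_release <- function(fresh_pool, spent_pool, protein_t0,
                                protein_t24) {
  if (any(protein_t24 <= protein_t0)) {
    stop("protein must grow during incubation (protein_t24 > protein_t0)")
  }
  (spent_pool - fresh_pool) / (protein_t24 - protein_t0)
}

#' Count atoms of an element in an elemental formula
#'
#' @param formula Formula string such as `"C6H12O6"`.
#' @param element Element symbol (default `"C"`).
#' @return Integer atom count (0 if the element is absent).
#' @export
count_atoms <- function(formula, element = "C") {
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  total <- 0L
  for (p in parts) {
    sym <- gsub("[0-9]", "", p)
    if (sym == element) {
      num <- gsub("[A-Za-z]", "", p)
      total <- total + if (nzchar(num)) as.integer(num) else 1L
    }
  }
  total
}

#' Process an isotopologue intensity table
#'
#' For each metabolite: raw MID fractions, then natural-abundance correction
#' using the atom count of the labelled element parsed from the formula.
#'
#' @param tracer_table `data.frame` with columns `metabolite_id`, `formula`,
#'   `isotopologue` (0-based index), `intensity`.
#' @param label_element `"C13"` or `"N15"` (selects both the element counted
#'   in the formula and the default natural abundance).
#' @param isotope_abundance Override the natural abundance.
#' @return A `data.frame` with columns `metabolite_id`, `isotopologue`,
#'   `raw_fraction`, `corrected_fraction`, `qc_flag`.
#' @export
process_tracer_table <- function(tracer_table,
                                 label_element = c("C13", "N15"),
                                 isotope_abundance = NULL) {
  label_element <- match.arg(label_element)
  elem <- if (label_element == "C13") "C" else "N"
  if (is.null(isotope_abundance)) {
    isotope_abundance <- if (label_element == "C13") FD_NA_C13 else FD_NA_N15
  }
  out <- lapply(split(tracer_table, tracer_table$metabolite_id), function(tt) {
    tt <- tt[order(tt$isotopologue), ]
    n_atoms <- count_atoms(tt$formula[1], elem)
    if (nrow(tt) != n_atoms + 1L) {
      stop("metabolite '", tt$metabolite_id[1], "': expected ", n_atoms + 1L,
           " isotopologues for ", elem, " labelling, got ", nrow(tt))
    }
    raw <- mid_fractions(tt$intensity)
    corr <- natural_abundance_correct(raw, n_atoms, isotope_abundance)
    data.frame(metabolite_id = tt$metabolite_id[1],
               isotopologue = tt$isotopologue,
               raw_fraction = raw, corrected_fraction = as.numeric(corr),
               qc_flag = attr(corr, "qc_flag"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
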