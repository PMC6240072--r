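# Differential flux analysis: condition deltas, reaction/metabolite ranking,
# and the per-pathway Differential Abundance (DA) score.

#' Differential fluxes between two sweep profiles
#'
#' For every reaction `r`, `delta[r] = perturbed_mean[r] - baseline_mean[r]`.
#' With this sign convention a positive delta means the flux increased under
#' the perturbation, so a pathway in which every flux rises scores DA = +1
#' (see [compute_da()]).
#'
#' @param baseline,perturbed [objective_sweep()] profiles over identical
#'   reaction sets.
#' @return A list of class `"differential_flux"` with `delta` (named numeric),
#'   `baseline_label`, `perturbed_label`.
#' @export
differential_flux <- function(baseline, perturbed) {
  b <- baseline$mean_flux; p <- perturbed$mean_flux
  if (!setequal(names(b), names(p))) {
    stop("profiles cover different reaction sets; symmetric difference: ",
         paste(union(setdiff(names(b), names(p)), setdiff(names(p), names(b))),
               collapse = ", "))
  }
  p <- p[names(b)]
  structure(list(delta = p - b,
                 baseline_label = baseline$condition_label,
                 perturbed_label = perturbed$condition_label),
            class = "differential_flux")
}

#' Rank reactions by absolute differential flux
#'
#' @param diff A [differential_flux()] result.
#' @return A `data.frame` with columns `reaction_id`, `u`, `abs_u`, `rank`,
#'   ordered by decreasing `abs_u`; ties broken lexicographically by reaction
#'   id so the ranking is deterministic.
#' @export
rank_reactions <- function(diff) {
  u <- diff$delta
  ord <- order(-abs(u), names(u), method = "radix")
  data.frame(reaction_id = names(u)[ord], u = unname(u[ord]),
             abs_u = unname(abs(u[ord])), rank = seq_along(u),
             stringsAsFactors = FALSE)
}

#' Rank metabolites by summed absolute differential flux of incident reactions
#'
#' A metabolite's score is the sum of `|u_r|` over every reaction whose
#' stoichiometry involves it (producers, consumers and transporters alike).
#' Compartmental instances of a compound are distinct metabolites here; use
#' `collapse_kegg = TRUE` (the default used when feeding enrichment) to merge
#' instances sharing a KEGG id, summing their scores.
#'
#' @param diff A [differential_flux()] result.
#' @param model The [metabolic_model()] the deltas were computed on.
#' @param collapse_kegg Merge compartmental instances by KEGG id (entries
#'   without a KEGG id are kept as-is).
#' @return A `data.frame` with columns `metabolite_id`, `kegg_id`, `score`,
#'   `rank`, ordered by decreasing score with deterministic id tie-break.
#' @export
rank_metabolites <- function(diff, model, collapse_kegg = FALSE) {
  u <- diff$delta
  missing <- setdiff(names(model$stoichiometry), names(u))
  if (length(missing)) {
    stop("deltas missing for reaction(s): ", paste(missing, collapse = ", "))
  }
  score <- stats::setNames(rep(0, nrow(model$metabolites)), model$metabolites$id)
  for (rid in names(model$stoichiometry)) {
    mets <- names(model$stoichiometry[[rid]])
    score[mets] <- score[mets] + abs(u[[rid]])
  }
  out <- data.frame(metabolite_id = names(score),
                    kegg_id = model$metabolites$kegg_id[
                      match(names(score), model$metabolites$id)],
                    score = unname(score), stringsAsFactors = FALSE)
  if (collapse_kegg) {
    has <- !is.na(out$kegg_id)
    if (any(has)) {
      agg <- stats::aggregate(score ~ kegg_id, data = out[has, ], FUN = sum)
      agg$metabolite_id <- agg$kegg_id
      out <- rbind(agg[, c("metabolite_id", "kegg_id", "score")],
                   out[!has, c("metabolite_id", "kegg_id", "score")])
    }
  }
  ord <- order(-out$score, out$metabolite_id, method = "radix")
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Differential Abundance score of a pathway
#'
#' `DA = sum(u_r) / sum(|u_r|)` over the pathway's reactions. The score lies
#' in `[-1, 1]`: -1 means every non-zero flux in the pathway decreased under
#' the perturbation, +1 means every one increased, and intermediate values
#' capture the net tendency. When all deltas are zero the score is undefined
#' and flagged rather than reported as 0.
#'
#' @param diff A [differential_flux()] result.
#' @param pathway_reactions Character vector of reaction ids (must be a
#'   subset of the model's reactions present in `diff`).
#' @param pathway Optional label stored on the result.
#' @return A list of class `"pathway_score"`: `pathway`, `da` (`NA` when
#'   undefined), `n_reactions` (count with non-zero delta), `defined` flag.
#' @export
compute_da <- function(diff, pathway_reactions, pathway = NA_character_) {
  missing <- setdiff(pathway_reactions, names(diff$delta))
  if (length(missing)) {
    stop("pathway reaction(s) absent from differential result: ",
         paste(missing, collapse = ", "))
  }
  u <- diff$delta[pathway_reactions]
  denom <- sum(abs(u))
  if (denom == 0) {
    return(structure(list(pathway = pathway, da = NA_real_, n_reactions = 0L,
                          defined = FALSE), class = "pathway_score"))
  }
  structure(list(pathway = pathway, da = sum(u) / denom,
                 n_reactions = sum(u != 0), defined = TRUE),
            class = "pathway_score")
}

#' DA scores for every pathway of a model
#'
#' @param diff A [differential_flux()] result.
#' @param model A [metabolic_model()] whose `pathways` map supplies the
#'   reaction groupings.
#' @return A `data.frame` with columns `pathway`, `da`, `n_reactions`,
#'   `defined`.
#' @export
pathway_da <- function(diff, model) {
  rows <- lapply(names(model$pathways), function(pw) {
    s <- compute_da(diff, model$pathways[[pw]], pathway = pw)
    data.frame(pathway = pw, da = s$da, n_reactions = s$n_reactions,
               defined = s$defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
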