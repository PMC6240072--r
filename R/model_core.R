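# Data model for compartmentalised stoichiometric metabolic networks.
#
# A model is a plain list with class "metabolic_model":
#   metabolites  data.frame(id, name, compartment, kegg_id, formula)
#   reactions    data.frame(id, lower_bound, upper_bound, pathway, external_ref)
#   stoichiometry named list (by reaction id) of named numeric vectors
#                 (by metabolite id); signed coefficients, consumers negative
#   compartments character vector of declared compartment labels (ordered)
#   pathways     named list (pathway label -> character vector of reaction ids)

#' Create a metabolite record
#'
#' @param id Unique metabolite identifier within the model (conventionally
#'   `<name>_<compartment>`).
#' @param name Human-readable name; defaults to `id`.
#' @param compartment Compartment label; must be one of the model's declared
#'   compartments once the metabolite is placed in a model.
#' @param kegg_id Optional KEGG compound identifier (`"C"` followed by five
#'   digits). Only metabolites carrying a KEGG id are eligible for pathway
#'   enrichment.
#' @param formula Optional elemental formula string (e.g. `"C6H12O6"`).
#' @return A one-row `data.frame` with columns `id`, `name`, `compartment`,
#'   `kegg_id`, `formula`.
#' @export
metabolite <- function(id, name = id, compartment, kegg_id = NA_character_,
                       formula = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.na(kegg_id) && !is_kegg_id(kegg_id)) {
    stop("invalid KEGG compound id for metabolite '", id, "': ", kegg_id)
  }
  data.frame(id = id, name = name, compartment = compartment,
             kegg_id = as.character(kegg_id), formula = as.character(formula),
             stringsAsFactors = FALSE)
}

#' Create a reaction record
#'
#' @param id Unique reaction identifier.
#' @param stoichiometry Named numeric vector of signed coefficients keyed by
#'   metabolite id (substrates negative, products positive). Must be non-empty
#'   with no zero coefficients. Exchange reactions may reference a single
#'   metabolite.
#' @param lower_bound,upper_bound Flux bounds (arbitrary but consistent
#'   units); `lower_bound <= upper_bound`. Reversibility is encoded solely by
#'   `lower_bound < 0`.
#' @param pathway Optional subsystem label used for pathway-level summaries.
#' @param external_ref Optional transporter/enzyme identifier (e.g. a TCDB
#'   accession) used to address reactions in perturbation specs.
#' @return A list of class `"fd_reaction"`.
#' @export
reaction <- function(id, stoichiometry, lower_bound, upper_bound,
                     pathway = NA_character_, external_ref = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector")
  }
  if (any(stoichiometry == 0)) {
    stop("reaction '", id, "': stoichiometric coefficients must be non-zero")
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  }
  if (!is.finite(lower_bound) || !is.finite(upper_bound)) {
    stop("reaction '", id, "': bounds must be finite (use a large finite bound)")
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound")
  }
  structure(list(id = id, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 pathway = as.character(pathway),
                 external_ref = as.character(external_ref)),
            class = "fd_reaction")
}

#' Assemble and validate a metabolic model
#'
#' @param metabolites A `data.frame` as produced by row-binding
#'   [metabolite()] records.
#' @param reactions A list of [reaction()] objects.
#' @param compartments Character vector of declared compartment labels. If
#'   `NULL`, taken from the metabolites in order of first appearance.
#' @param pathways Named list mapping pathway labels to character vectors of
#'   member reaction ids. If `NULL`, derived from the reactions' `pathway`
#'   fields.
#' @return A validated object of class `"metabolic_model"`.
#' @seealso [validate_model()], [stoichiometric_matrix()]
#' @export
metabolic_model <- function(metabolites, reactions, compartments = NULL,
                            pathways = NULL) {
  stopifnot(is.data.frame(metabolites), is.list(reactions))
  if (is.null(compartments)) compartments <- unique(metabolites$compartment)
  rxn_tab <- do.call(rbind, lapply(reactions, function(r) {
    data.frame(id = r$id, lower_bound = r$lower_bound,
               upper_bound = r$upper_bound, pathway = r$pathway,
               external_ref = r$external_ref, stringsAsFactors = FALSE)
  }))
  stoich <- lapply(reactions, `[[`, "stoichiometry")
  names(stoich) <- rxn_tab$id
  if (is.null(pathways)) {
    with_pw <- !is.na(rxn_tab$pathway)
    pathways <- split(rxn_tab$id[with_pw], rxn_tab$pathway[with_pw])
    pathways <- lapply(pathways, as.character)
  }
  model <- structure(list(metabolites = metabolites, reactions = rxn_tab,
                          stoichiometry = stoich,
                          compartments = as.character(compartments),
                          pathways = pathways),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model against its structural invariants
#'
#' Checks id uniqueness, compartment membership, bound ordering, that every
#' stoichiometry key resolves to a declared metabolite and every pathway
#' member to a declared reaction, and that matrix dimensions are consistent.
#' Violations raise an error naming the offending element.
#'
#' @param model A `"metabolic_model"`.
#' @return `model`, invisibly, when valid.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop("duplicated metabolite id(s): ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicated reaction id(s): ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }
  bad_comp <- setdiff(unique(mets$compartment), model$compartments)
  if (length(bad_comp)) {
    stop("metabolite compartment(s) not declared: ",
         paste(bad_comp, collapse = ", "))
  }
  bad_kegg <- mets$id[!is.na(mets$kegg_id) & !vapply(mets$kegg_id, is_kegg_id, TRUE)]
  if (length(bad_kegg)) {
    stop("invalid KEGG id on metabolite(s): ", paste(bad_kegg, collapse = ", "))
  }
  if (any(rxns$lower_bound > rxns$upper_bound)) {
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rxns$id[rxns$lower_bound > rxns$upper_bound], collapse = ", "))
  }
  for (rid in rxns$id) {
    s <- model$stoichiometry[[rid]]
    dangling <- setdiff(names(s), mets$id)
    if (length(dangling)) {
      stop("reaction '", rid, "' references undeclared metabolite(s): ",
           paste(dangling, collapse = ", "))
    }
    if (length(s) == 0L || any(s == 0)) {
      stop("reaction '", rid, "': empty stoichiometry or zero coefficient")
    }
  }
  for (pw in names(model$pathways)) {
    dangling <- setdiff(model$pathways[[pw]], rxns$id)
    if (length(dangling)) {
      stop("pathway '", pw, "' references undeclared reaction(s): ",
           paste(dangling, collapse = ", "))
    }
  }
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `"metabolic_model"`.
#' @return A dense numeric matrix with one row per metabolite and one column
#'   per reaction (dimnames set to the ids); entries are the declared signed
#'   coefficients, zero elsewhere.
#' @export
stoichiometric_matrix <- function(model) {
  m <- nrow(model$metabolites)
  n <- nrow(model$reactions)
  S <- matrix(0, m, n, dimnames = list(model$metabolites$id, model$reactions$id))
  for (rid in model$reactions$id) {
    s <- model$stoichiometry[[rid]]
    S[names(s), rid] <- s
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,", length(x$compartments),
      "compartments,", length(x$pathways), "pathways\n")
  invisible(x)
}

is_kegg_id <- function(x) {
  is.character(x) && length(x) == 1L && grepl("^C[0-9]{5}$", x)
}

#' Create a pathway membership set
#'
#' @param name Pathway name.
#' @param members Character vector of KEGG compound identifiers; duplicates
#'   are removed.
#' @return A list of class `"pathway_set"` with elements `name` and `members`.
#' @export
pathway_set <- function(name, members) {
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("pathway set '", name, "' has no members")
  ok <- vapply(members, is_kegg_id, TRUE)
  if (any(!ok)) {
    stop("pathway set '", name, "': invalid KEGG compound id(s): ",
         paste(members[!ok], collapse = ", "))
  }
  structure(list(name = name, members = members), class = "pathway_set")
}
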