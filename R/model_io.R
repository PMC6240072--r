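# Model I/O: a self-defined JSON schema, a 3-file TSV dialect, a minimal
# read-only SBML Level-3 core subset, and GMT pathway-set files.

#' Read a metabolic model
#'
#' Supported formats:
#' \describe{
#'   \item{`json`}{One file with top-level keys `compartments`, `metabolites`,
#'     `reactions` (each reaction with a `stoichiometry` object keyed by
#'     metabolite id), and `pathways`.}
#'   \item{`tsv`}{Three files sharing a prefix: `<prefix>_metabolites.tsv`,
#'     `<prefix>_reactions.tsv`, `<prefix>_stoichiometry.tsv`. The metabolite
#'     file starts with a `# compartments:` comment recording compartment
#'     order. `path` is the prefix.}
#'   \item{`sbml-min`}{Read-only subset of SBML Level-3 core:
#'     compartments, species and reactions with reactant/product
#'     stoichiometries; the `reversible` attribute maps to bounds
#'     `[-default_bound, default_bound]` vs `[0, default_bound]`.}
#' }
#' Unknown fields in JSON records are ignored with a warning.
#'
#' @param path File path (or prefix for `tsv`).
#' @param format One of `"json"`, `"tsv"`, `"sbml-min"`. Default guesses from
#'   the file extension (`.json`, `.xml`/`.sbml`, otherwise `tsv`).
#' @param default_bound Bound magnitude used for SBML reactions (no bound
#'   information is read from SBML); default 1000.
#' @return A validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("guess", "json", "tsv", "sbml-min"),
                       default_bound = 1000) {
  format <- match.arg(format)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json"
      else if (ext %in% c("xml", "sbml")) "sbml-min" else "tsv"
  }
  switch(format,
         json = read_model_json(path),
         tsv = read_model_tsv(path),
         `sbml-min` = read_model_sbml(path, default_bound))
}

#' Write a metabolic model
#'
#' Writes the `json` or `tsv` dialect documented in [read_model()];
#' `read_model(write_model(...))` is the identity on the data model.
#'
#' @param model A `"metabolic_model"`.
#' @param path Output path (prefix for `tsv`).
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "json") {
    obj <- list(
      compartments = model$compartments,
      metabolites = model$metabolites,
      reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
        r <- model$reactions[i, ]
        list(id = r$id, stoichiometry = as.list(model$stoichiometry[[r$id]]),
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             pathway = r$pathway, external_ref = r$external_ref)
      }),
      pathways = model$pathways
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    mt <- paste0(path, "_metabolites.tsv")
    con <- file(mt, "w")
    writeLines(paste0("# compartments: ",
                      paste(model$compartments, collapse = ",")), con)
    utils::write.table(model$metabolites, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    rx <- model$reactions
    utils::write.table(rx, paste0(path, "_reactions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    st <- do.call(rbind, lapply(names(model$stoichiometry), function(rid) {
      s <- model$stoichiometry[[rid]]
      data.frame(reaction_id = rid, metabolite_id = names(s),
                 coefficient = unname(s), stringsAsFactors = FALSE)
    }))
    utils::write.table(st, paste0(path, "_stoichiometry.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

read_model_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in '", path,
                                           "': ", conditionMessage(e)))
  known_rxn <- c("id", "stoichiometry", "lower_bound", "upper_bound",
                 "pathway", "external_ref")
  mets <- do.call(rbind, lapply(obj$metabolites, function(m) {
    metabolite(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment,
               kegg_id = m$kegg_id %||% NA_character_,
               formula = m$formula %||% NA_character_)
  }))
  rxns <- lapply(obj$reactions, function(r) {
    unknown <- setdiff(names(r), known_rxn)
    if (length(unknown)) {
      warning("ignoring unknown reaction field(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    st <- unlist(r$stoichiometry)
    reaction(id = r$id, stoichiometry = st,
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             pathway = null_na(r$pathway), external_ref = null_na(r$external_ref))
  })
  pathways <- lapply(obj$pathways,
                     function(p) unname(vapply(p, as.character, "")))
  metabolic_model(mets, rxns, compartments = unlist(obj$compartments),
                  pathways = pathways)
}

read_model_tsv <- function(prefix) {
  mt_path <- paste0(prefix, "_metabolites.tsv")
  if (!file.exists(mt_path)) stop("file not found: ", mt_path)
  header <- readLines(mt_path, n = 1L)
  comps <- if (grepl("^# compartments:", header)) {
    strsplit(sub("^# compartments:\\s*", "", header), ",")[[1]]
  } else NULL
  mets <- utils::read.table(mt_path, sep = "\t", header = TRUE,
                            comment.char = "#", stringsAsFactors = FALSE,
                            na.strings = "NA")
  rx <- utils::read.table(paste0(prefix, "_reactions.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  st <- utils::read.table(paste0(prefix, "_stoichiometry.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  rxns <- lapply(seq_len(nrow(rx)), function(i) {
    rows <- st[st$reaction_id == rx$id[i], ]
    if (nrow(rows) == 0L) stop("reaction '", rx$id[i], "' has no stoichiometry rows")
    s <- stats::setNames(rows$coefficient, rows$metabolite_id)
    reaction(id = rx$id[i], stoichiometry = s,
             lower_bound = rx$lower_bound[i], upper_bound = rx$upper_bound[i],
             pathway = rx$pathway[i], external_ref = rx$external_ref[i])
  })
  orphan <- setdiff(unique(st$reaction_id), rx$id)
  if (length(orphan)) {
    stop("stoichiometry rows reference undeclared reaction(s): ",
         paste(orphan, collapse = ", "))
  }
  metabolic_model(mets, rxns, compartments = comps)
}

read_model_sbml <- function(path, default_bound = 1000) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  comp_nodes <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
  comps <- xml2::xml_attr(comp_nodes, "id")
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- do.call(rbind, lapply(sp_nodes, function(n) {
    metabolite(id = xml2::xml_attr(n, "id"),
               name = xml2::xml_attr(n, "name") %||% xml2::xml_attr(n, "id"),
               compartment = xml2::xml_attr(n, "compartment"))
  }))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rxn_nodes, function(n) {
    rid <- xml2::xml_attr(n, "id")
    rev <- identical(xml2::xml_attr(n, "reversible"), "true")
    refs <- function(xp, sign) {
      nodes <- xml2::xml_find_all(n, xp, ns)
      if (length(nodes) == 0L) return(numeric(0))
      coef <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, xml2::xml_attr(nodes, "species"))
    }
    s <- c(refs(".//s:listOfReactants/s:speciesReference", -1),
           refs(".//s:listOfProducts/s:speciesReference", 1))
    reaction(id = rid, stoichiometry = s,
             lower_bound = if (rev) -default_bound else 0,
             upper_bound = default_bound)
  })
  metabolic_model(mets, rxns, compartments = comps)
}

#' Read pathway membership sets from a GMT file
#'
#' Each line holds a pathway name, an optional description, and one or more
#' KEGG compound identifiers, tab-separated. Duplicate members on a line are
#' dropped with a warning; a line with zero members is an error.
#'
#' @param path Path to the GMT file.
#' @return A named list of [pathway_set()] objects, in file order.
#' @export
read_pathway_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("GMT line ", i, " ('", parts[1], "') has no members")
    }
    members <- parts[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " ('", parts[1], "'): duplicate members removed",
              call. = FALSE)
    }
    pathway_set(parts[1], members)
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write pathway sets to a GMT file
#'
#' @param sets A list of [pathway_set()] objects.
#' @param path Output path.
#' @param description Description field written in column 2.
#' @return `path`, invisibly.
#' @export
write_pathway_sets <- function(sets, path, description = "na") {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
null_na <- function(x) if (is.null(x) || length(x) == 0L) NA_character_ else as.character(x)
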