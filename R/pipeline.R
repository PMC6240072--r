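# Pipeline orchestration: run the synthetic study end to end from one
# configuration, writing tabular outputs and a reproducibility manifest.

#' Default pipeline configuration
#'
#' @param seed Master seed; stage seeds derive from it.
#' @param factor Forced-uptake factor for the glucose transporters.
#' @param weight_p,n_perm Enrichment parameters (see [enrich_all()]).
#' @param alpha,fc_threshold Volcano thresholds (see [volcano_classify()]).
#' @param metabolomics List of overrides for [simulate_metabolomics()].
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1, factor = 1.6, weight_p = 1,
                            n_perm = 1000, alpha = 0.05, fc_threshold = 2,
                            metabolomics = list()) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (factor <= 0) stop("factor must be > 0")
  list(seed = seed, factor = factor, weight_p = weight_p, n_perm = n_perm,
       alpha = alpha, fc_threshold = fc_threshold,
       metabolomics = metabolomics)
}

#' Pathway sets of a model, keyed by KEGG compound ids
#'
#' For each pathway label, collects the KEGG ids of all metabolites incident
#' to the pathway's reactions; pathways without any KEGG-mapped metabolite
#' are dropped.
#'
#' @param model A [metabolic_model()].
#' @return A list of [pathway_set()] objects.
#' @export
model_pathway_sets <- function(model) {
  out <- list()
  for (pw in names(model$pathways)) {
    mets <- unique(unlist(lapply(model$pathways[[pw]], function(rid) {
      names(model$stoichiometry[[rid]])
    })))
    kegg <- model$metabolites$kegg_id[match(mets, model$metabolites$id)]
    kegg <- unique(kegg[!is.na(kegg)])
    if (length(kegg)) out[[pw]] <- pathway_set(pw, kegg)
  }
  out
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order: build the toy network, sweep the
#' wild-type model, apply the forced-glucose perturbation, sweep the
#' perturbed model, compute differential fluxes, reaction/metabolite
#' rankings and pathway DA scores, run enrichment on the DFA-ranked
#' metabolite list against the model's pathway sets; in parallel, simulate
#' the paired metabolomics study, run the differential analysis and enrich
#' the fold-change-ranked list against seeded random pathway sets. All
#' randomness is seeded from `config$seed`, so a rerun with the same
#' configuration reproduces every output byte for byte.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file with the
#'   same fields).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_config()
  config <- utils::modifyList(defaults, config)
  if (config$n_perm < 1) stop("invalid config: n_perm must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # --- in silico branch -----------------------------------------------
  toy <- make_toy_network(forced_uptake_factor = config$factor)
  write_model(toy$model, file.path(out_dir, "model.json"), format = "json")
  writeLines(toy$objectives, file.path(out_dir, "objectives.txt"))
  wt <- objective_sweep(toy$model, toy$objectives,
                        condition_label = "wild-type")
  perturbed_model <- apply_perturbation(toy$model, wt, toy$perturbation)
  ko <- objective_sweep(perturbed_model, toy$objectives,
                        condition_label = "forced-glucose")
  diff <- differential_flux(wt, ko)
  tsv(data.frame(reaction_id = names(wt$mean_flux),
                 wild_type = unname(wt$mean_flux),
                 forced_glucose = unname(ko$mean_flux[names(wt$mean_flux)])),
      "mean_fluxes.tsv")
  tsv(rank_reactions(diff), "reactions_ranked.tsv")
  met_rank <- rank_metabolites(diff, toy$model, collapse_kegg = TRUE)
  tsv(met_rank, "metabolites_ranked.tsv")
  tsv(pathway_da(diff, toy$model), "pathway_da.tsv")
  sets <- model_pathway_sets(toy$model)
  L_dfa <- build_ranked_list(met_rank, metric = "dfa_score")
  enr_dfa <- enrich_all(L_dfa, sets, weight_p = config$weight_p,
                        n_perm = config$n_perm, seed = config$seed)
  tsv(enr_dfa, "enrichment_dfa.tsv")

  # --- metabolomics branch --------------------------------------------
  sim <- do.call(simulate_metabolomics,
                 utils::modifyList(list(seed = config$seed + 1),
                                   config$metabolomics))
  dm <- differential_metabolomics(sim$table, alpha = config$alpha,
                                  fc_threshold = config$fc_threshold)
  tsv(dm, "differential.tsv")
  vs <- attr(dm, "summary")
  jsonlite::write_json(vs, file.path(out_dir, "volcano_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  pca <- pca_scores(sim$table, n_components = 2)
  tsv(data.frame(sample_id = rownames(pca$scores), pca$scores,
                 genotype = pca$genotype), "pca_scores.tsv")
  L_met <- build_ranked_list(dm, metric = "fold_change")
  met_sets <- with_seed(config$seed + 3, {
    ids <- L_met$entries$kegg_id
    lapply(1:20, function(i) {
      pathway_set(sprintf("random_set_%02d", i),
                  sample(ids, min(15, length(ids))))
    })
  })
  enr_met <- enrich_all(L_met, met_sets, weight_p = config$weight_p,
                        n_perm = config$n_perm, seed = config$seed + 4)
  tsv(enr_met, "enrichment_metabolomics.tsv")

  # --- manifest --------------------------------------------------------
  outputs <- list.files(out_dir, full.names = FALSE)
  outputs <- setdiff(outputs, "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, outputs))
  manifest <- list(
    package = "fluxda",
    package_version = as.character(utils::packageVersion("fluxda")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    output_md5 = as.list(stats::setNames(unname(hashes), outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(diff = diff, da = pathway_da(diff, toy$model),
                 enrichment_dfa = enr_dfa, differential = dm,
                 volcano = vs, enrichment_metabolomics = enr_met,
                 manifest = manifest))
}
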