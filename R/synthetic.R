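# Synthetic inputs: a hand-curated central-carbon toy network able to
# reproduce the qualitative flux rewiring under forced glucose uptake,
# paired-metabolomics simulators with planted effects, and null ranked
# lists for enrichment calibration.

#' Build the curated central-carbon toy network
#'
#' A three-compartment (extracellular `s`, cytosol `c`, mitochondrion `m`)
#' network of ~40 reactions covering glycolysis to pyruvate, an irreversible
#' LDH (pyruvate to lactate only) with a capacity-limited lactate export, an
#' oxidative PPP branch with a pentose demand, irreversible
#' cytosol-to-mitochondrion pyruvate transport, a TCA loop, a lumped
#' NADH+O2 -> ATP oxidative phosphorylation proxy, glutaminolysis (GLS,
#' glutamate dehydrogenase, and alanine transaminase exporting alanine),
#' reductive carboxylation of alpha-ketoglutarate to citrate, citrate export
#' to the cytosol (the reverse direction blocked) fuelling an
#' acetyl-CoA -> palmitate synthesis sink, a growth (biomass) demand, and a
#' fatty acid oxidation input. Two glucose transporters carry the TCDB tags
#' used by the forced-uptake perturbation; the sodium-coupled one pays an
#' ATP cost through the sodium pump. Mitochondrial anaplerosis is
#' glutamine-dependent (no pyruvate carboxylase), so net citrate export for
#' lipogenesis draws on glutamine — the coupling the directional analysis
#' exercises. ATP demand is capacity-limited, so glycolytic ATP from forced
#' glucose displaces oxidative ATP production (the Warburg-like shift).
#'
#' Every reaction balances the tracked carbon counts (energy and redox
#' carriers are untracked); this is asserted at build time.
#'
#' @param n_glucose_transporters Number of tagged glucose transporters
#'   (1 or 2; default 2).
#' @param forced_uptake_factor Factor stored in the default perturbation
#'   spec (default 1.6, the observed fold increase in glucose uptake).
#' @return A list with `model` (a [metabolic_model()]), `objectives`
#'   (character vector of >= 8 demand/exchange reaction ids), and
#'   `perturbation` (a default [perturbation_spec()] forcing the tagged
#'   transporters).
#' @export
make_toy_network <- function(n_glucose_transporters = 2,
                             forced_uptake_factor = 1.6) {
  stopifnot(n_glucose_transporters %in% c(1L, 2L))
  big <- 1000

  met <- function(short, comp, kegg, formula = NA_character_) {
    metabolite(id = paste0(short, "_", comp), name = short, compartment = comp,
               kegg_id = kegg, formula = formula)
  }
  mets <- rbind(
    met("na", "s", "C01330"), met("na", "c", "C01330"),
    met("glc", "s", "C00031", "C6H12O6"), met("glc", "c", "C00031", "C6H12O6"),
    met("g6p", "c", "C00092", "C6H13O9P"),
    met("r5p", "c", "C00117", "C5H11O8P"),
    met("pyr", "c", "C00022", "C3H4O3"), met("pyr", "m", "C00022", "C3H4O3"),
    met("lac", "c", "C00186", "C3H6O3"), met("lac", "s", "C00186", "C3H6O3"),
    met("accoa", "m", "C00024", NA), met("accoa", "c", "C00024", NA),
    met("cit", "m", "C00158", "C6H8O7"), met("cit", "c", "C00158", "C6H8O7"),
    met("akg", "m", "C00026", "C5H6O5"),
    met("oaa", "m", "C00036", "C4H4O5"), met("oaa", "c", "C00036", "C4H4O5"),
    met("gln", "s", "C00064", "C5H10N2O3"), met("gln", "c", "C00064", "C5H10N2O3"),
    met("glu", "c", "C00025", "C5H9NO4"),
    met("ala", "c", "C00041", "C3H7NO2"), met("ala", "s", "C00041", "C3H7NO2"),
    met("palm", "c", "C00249", "C16H32O2"), met("palm", "s", "C00249", "C16H32O2"),
    met("fa", "s", "C00162", NA), met("fa", "m", "C00162", NA),
    met("co2", "c", "C00011", "CO2"), met("co2", "m", "C00011", "CO2"),
    met("co2", "s", "C00011", "CO2"),
    met("o2", "s", "C00007", "O2"), met("o2", "m", "C00007", "O2"),
    met("nadh", "m", NA_character_, NA), met("atp", "c", NA_character_, NA)
  )

  # tracked carbon counts; energy/redox carriers untracked (acetyl-CoA and
  # the generic fatty acid count only the acyl carbons)
  carbons <- c(glc = 6, g6p = 6, r5p = 5, pyr = 3, lac = 3, accoa = 2,
               cit = 6, akg = 5, oaa = 4, gln = 5, glu = 5, palm = 16,
               ala = 3, fa = 16, co2 = 1, o2 = 0, na = 0, nadh = NA,
               atp = NA)

  rx <- list(
    # exchanges and demands (system boundary)
    reaction("EX_glc", c(glc_s = 1), 0, 12, "exchange"),
    reaction("EX_gln", c(gln_s = 1), 0, 5, "exchange"),
    reaction("EX_fa", c(fa_s = 1), 0, 2, "exchange"),
    reaction("EX_o2", c(o2_s = 1), 0, big, "exchange"),
    reaction("EX_co2", c(co2_s = -1), 0, 60, "exchange"),
    reaction("EX_lac", c(lac_s = -1), 0, 3, "exchange"),
    reaction("EX_ala", c(ala_s = -1), 0, big, "exchange"),
    reaction("EX_palm", c(palm_s = -1), 0, 0.4, "exchange"),
    reaction("DM_r5p", c(r5p_c = -1), 0, 1, "demand"),
    reaction("DM_akg", c(akg_m = -1), 0, 2, "demand"),
    reaction("ATPM", c(atp_c = -1), 0, 20, "demand"),
    reaction("BIOMASS", c(r5p_c = -0.2, palm_c = -0.02, akg_m = -0.05,
                          atp_c = -1), 0, big, "demand"),
    # transport (SGLT couples glucose entry to the sodium gradient, which
    # the ATP-driven pump NKA restores; GLUT is the facilitated uniporter)
    reaction("GLUT", c(glc_s = -1, glc_c = 1), 0, 2, "transport",
             external_ref = "TCDB:2.A.1.1.29"),
    reaction("SGLT", c(glc_s = -1, na_s = -1, glc_c = 1, na_c = 1), 0, 12,
             "transport", external_ref = "TCDB:2.A.21.3.6"),
    reaction("NKA", c(na_c = -1, atp_c = -0.2, na_s = 1), 0, big,
             "transport"),
    reaction("LACT", c(lac_c = -1, lac_s = 1), 0, big, "transport"),
    reaction("ALAT", c(ala_c = -1, ala_s = 1), 0, big, "transport"),
    reaction("PYT", c(pyr_c = -1, pyr_m = 1), 0, big, "transport"),
    reaction("CITT", c(cit_m = -1, cit_c = 1), 0, big, "transport"),
    reaction("GLNT", c(gln_s = -1, gln_c = 1), 0, big, "transport"),
    reaction("O2T", c(o2_s = -1, o2_m = 1), 0, big, "OXPHOS"),
    reaction("CO2Tm", c(co2_m = -1, co2_c = 1), -big, big, "transport"),
    reaction("CO2Tc", c(co2_c = -1, co2_s = 1), 0, big, "transport"),
    reaction("PALMT", c(palm_c = -1, palm_s = 1), 0, big, "transport"),
    reaction("FAT", c(fa_s = -1, fa_m = 1), 0, big, "FAO"),
    # glycolysis and lactate fermentation
    reaction("HK", c(glc_c = -1, g6p_c = 1), 0, big, "GLY"),
    reaction("GLY2", c(g6p_c = -1, pyr_c = 2, atp_c = 2), 0, big, "GLY"),
    reaction("LDH", c(pyr_c = -1, lac_c = 1), 0, big, "GLY"),
    # pentose phosphate (oxidative branch, lumped)
    reaction("PPP1", c(g6p_c = -1, r5p_c = 1, co2_c = 1), 0, big, "PPP"),
    # TCA (RC is the reductive carboxylation of alpha-ketoglutarate to
    # citrate, the anaplerotic route feeding lipogenic citrate)
    reaction("PDH", c(pyr_m = -1, accoa_m = 1, co2_m = 1, nadh_m = 1),
             0, big, "TCA"),
    reaction("CS", c(accoa_m = -1, oaa_m = -1, cit_m = 1), 0, big, "TCA"),
    reaction("IDH", c(cit_m = -1, akg_m = 1, co2_m = 1), 0, big, "TCA"),
    reaction("AKGDH", c(akg_m = -1, oaa_m = 1, co2_m = 1, nadh_m = 2),
             0, big, "TCA"),
    reaction("RC", c(akg_m = -1, co2_m = -1, cit_m = 1), 0, big, "TCA"),
    # oxidative phosphorylation proxy
    reaction("OXPHOS", c(nadh_m = -1, o2_m = -0.5, atp_c = 2.5),
             0, big, "OXPHOS"),
    # glutaminolysis
    reaction("GLS", c(gln_c = -1, glu_c = 1), 0, big, "GLN"),
    reaction("GLUD", c(glu_c = -1, akg_m = 1), 0, big, "GLN"),
    reaction("ALT", c(pyr_c = -1, glu_c = -1, ala_c = 1, akg_m = 1),
             0, big, "GLN"),
    # fatty acid synthesis (citrate shuttle, lipogenesis, OAA recycling)
    reaction("ACLY", c(cit_c = -1, accoa_c = 1, oaa_c = 1), 0, big, "FAS"),
    reaction("ME", c(oaa_c = -1, pyr_c = 1, co2_c = 1), 0, big, "FAS"),
    reaction("FASN", c(accoa_c = -8, atp_c = -7, palm_c = 1), 0, big, "FAS"),
    # fatty acid oxidation
    reaction("FAO", c(fa_m = -1, accoa_m = 8, nadh_m = 7), 0, big, "FAO")
  )
  if (n_glucose_transporters == 1L) {
    rx <- Filter(function(r) r$id != "SGLT", rx)
  }

  model <- metabolic_model(mets, rx, compartments = c("s", "c", "m"))

  # carbon conservation assertion: internal reactions balance tracked carbon
  boundary <- c("EX_glc", "EX_gln", "EX_fa", "EX_o2", "EX_co2", "EX_lac",
                "EX_ala", "EX_palm", "DM_r5p", "DM_akg", "ATPM", "BIOMASS")
  short <- sub("_[a-z]$", "", model$metabolites$id)
  cmap <- stats::setNames(carbons[short], model$metabolites$id)
  for (rid in setdiff(model$reactions$id, boundary)) {
    s <- model$stoichiometry[[rid]]
    cc <- cmap[names(s)]
    bal <- sum(s[!is.na(cc)] * cc[!is.na(cc)])
    if (abs(bal) > 1e-9) {
      stop("internal error: reaction '", rid, "' unbalances carbon by ", bal)
    }
  }

  transporters <- reactions_by_ref(model,
                                   c("TCDB:2.A.21.3.6", "TCDB:2.A.1.1.29"))
  pert <- perturbation_spec(
    forced_uptake = data.frame(reaction_id = transporters,
                               factor = forced_uptake_factor,
                               stringsAsFactors = FALSE))
  objectives <- c("ATPM", "EX_lac", "EX_palm", "DM_r5p", "DM_akg",
                  "EX_co2", "BIOMASS", "OXPHOS")
  list(model = model, objectives = objectives, perturbation = pert)
}

#' Simulate a litter-paired metabolomics study
#'
#' Abundances are log-normal around per-metabolite baselines, with an
#' additive log-scale litter random intercept and i.i.d. log-scale noise.
#' Planted metabolites are multiplied by `effect_fc` (up) or `1/effect_fc`
#' (down) in cystic samples. Defaults mirror a 4-litter, 2 cystic + 2
#' control design with 550 detected metabolites.
#'
#' @param n_litters Number of litters (default 4).
#' @param n_per_genotype_per_litter Replicates per genotype per litter
#'   (default 2).
#' @param n_metabolites Number of metabolites (default 550).
#' @param n_planted_up,n_planted_down Planted effect counts (defaults 171 up,
#'   213 down).
#' @param effect_fc Planted fold-change magnitude (> 1; default 2.5).
#' @param noise_sigma SD of log-scale residual noise (default 0.15).
#' @param litter_sigma SD of the log-scale litter intercept (default 0.05).
#' @param frac_kegg Fraction of metabolites assigned a (synthetic) KEGG id
#'   (default 0.8).
#' @param seed Integer seed; the full output is reproducible from it.
#' @return A list with `table` (a [paired_abundance_table()]) and
#'   `ground_truth` (`data.frame`: `metabolite_id`, `planted` in
#'   `{"up","down","null"}`).
#' @export
simulate_metabolomics <- function(n_litters = 4, n_per_genotype_per_litter = 2,
                                  n_metabolites = 550, n_planted_up = 171,
                                  n_planted_down = 213, effect_fc = 2.5,
                                  noise_sigma = 0.15, litter_sigma = 0.05,
                                  frac_kegg = 0.8, seed = 1) {
  stopifnot(n_planted_up + n_planted_down <= n_metabolites,
            effect_fc > 1, noise_sigma > 0, n_litters >= 2)
  with_seed(seed, {
    mids <- sprintf("met%04d", seq_len(n_metabolites))
    planted <- rep("null", n_metabolites)
    planted[seq_len(n_planted_up)] <- "up"
    if (n_planted_down > 0) {
      planted[n_planted_up + seq_len(n_planted_down)] <- "down"
    }
    planted <- sample(planted)  # scatter planted effects over the panel
    kegg <- rep(NA_character_, n_metabolites)
    has_kegg <- sample.int(n_metabolites, round(frac_kegg * n_metabolites))
    kegg[has_kegg] <- sprintf("C9%04d", seq_along(has_kegg))

    base_mu <- stats::rnorm(n_metabolites, mean = 10, sd = 1)
    eff <- ifelse(planted == "up", log(effect_fc),
                  ifelse(planted == "down", -log(effect_fc), 0))

    n_per_litter <- 2L * n_per_genotype_per_litter
    n_samples <- n_litters * n_per_litter
    litter <- rep(seq_len(n_litters), each = n_per_litter)
    genotype <- rep(rep(c("cystic", "control"),
                        each = n_per_genotype_per_litter), n_litters)
    sample_id <- sprintf("L%d_%s_%d", litter, substr(genotype, 1, 3),
                         stats::ave(seq_len(n_samples),
                                    paste(litter, genotype),
                                    FUN = seq_along))
    litter_fx <- stats::rnorm(n_litters, 0, litter_sigma)
    logab <- matrix(base_mu, n_samples, n_metabolites, byrow = TRUE) +
      litter_fx[litter] +
      outer(genotype == "cystic", eff) +
      matrix(stats::rnorm(n_samples * n_metabolites, 0, noise_sigma),
             n_samples, n_metabolites)
    ab <- exp(logab)
    dimnames(ab) <- list(sample_id, mids)
    tab <- paired_abundance_table(
      ab,
      sample_meta = data.frame(sample_id = sample_id, litter = litter,
                               genotype = genotype, stringsAsFactors = FALSE),
      metabolite_meta = data.frame(metabolite_id = mids, kegg_id = kegg,
                                   stringsAsFactors = FALSE))
    list(table = tab,
         ground_truth = data.frame(metabolite_id = mids, planted = planted,
                                   stringsAsFactors = FALSE))
  })
}

#' Simulate a null ranked list and random pathway sets
#'
#' Metrics are i.i.d. standard normal over synthetic KEGG ids; pathway sets
#' are drawn uniformly without replacement from the list's ids. Used to
#' calibrate the enrichment permutation test.
#'
#' @param n List length (>= 10).
#' @param seed Integer seed.
#' @return A list with `list` (a [ranked_list()]) and `random_sets`, a
#'   function `(n_sets, size, seed)` returning a list of [pathway_set()]s.
#' @export
simulate_null_ranked_list <- function(n, seed = 1) {
  stopifnot(n >= 10)
  ids <- sprintf("C9%04d", seq_len(n))
  L <- with_seed(seed, ranked_list(ids, stats::rnorm(n)))
  random_sets <- function(n_sets, size, seed = 1) {
    with_seed(seed, {
      lapply(seq_len(n_sets), function(i) {
        pathway_set(sprintf("null_set_%03d", i), sample(ids, size))
      })
    })
  }
  list(list = L, random_sets = random_sets)
}
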