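test_that("single-path chain reaches the uptake bound", {
  model <- chain_model(uptake_ub = 10)
  sol <- solve_fba(model, "export")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes), rep(10, 3), tolerance = 1e-9)

  # shut objective reaction
  m2 <- chain_model()
  m2$reactions$upper_bound[m2$reactions$id == "export"] <- 0
  sol2 <- solve_fba(m2, "export")
  expect_equal(sol2$objective_value, 0, tolerance = 1e-12)
})

test_that("optimal solutions satisfy steady state and bounds", {
  toy <- make_toy_network()
  S <- stoichiometric_matrix(toy$model)
  lb <- toy$model$reactions$lower_bound
  ub <- toy$model$reactions$upper_bound
  for (ob in toy$objectives) {
    sol <- solve_fba(toy$model, ob)
    expect_equal(sol$status, "optimal")
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
    expect_true(all(sol$fluxes >= lb - 1e-9 & sol$fluxes <= ub + 1e-9))
  }
})

test_that("LP optimum matches the vertex-enumeration oracle on random instances", {
  n_match <- 0L
  for (seed in 1:24) {
    model <- random_small_model(m = 5 + seed %% 3, k = 2 + seed %% 3,
                                seed = seed)
    S <- stoichiometric_matrix(model)
    lb <- model$reactions$lower_bound
    ub <- model$reactions$upper_bound
    j <- 1 + seed %% nrow(model$reactions)
    cvec <- numeric(nrow(model$reactions)); cvec[j] <- 1
    oracle <- oracle_lp_max(S, lb, ub, cvec)
    sol <- solve_fba(model, model$reactions$id[j])
    expect_equal(sol$status, "optimal")
    expect_equal(sol$objective_value, oracle, tolerance = 1e-6)
    n_match <- n_match + 1L
  }
  expect_gte(n_match, 20L)
})

test_that("repeated solves return identical canonical flux vectors", {
  toy <- make_toy_network()
  a <- solve_fba(toy$model, "ATPM")
  b <- solve_fba(toy$model, "ATPM")
  expect_identical(a$fluxes, b$fluxes)
})

test_that("sweeps average canonical solutions and skip infeasible objectives", {
  model <- chain_model()
  one <- objective_sweep(model, "export")
  expect_equal(one$mean_flux, solve_fba(model, "export")$fluxes)
  expect_equal(one$n_objectives, 1L)

  # two objectives: mean equals the average of the two canonical solves
  toy <- make_toy_network()
  pair <- c("ATPM", "EX_lac")
  prof <- objective_sweep(toy$model, pair)
  manual <- (solve_fba(toy$model, "ATPM")$fluxes +
               solve_fba(toy$model, "EX_lac")$fluxes) / 2
  expect_equal(prof$mean_flux, manual, tolerance = 1e-12)
  expect_equal(prof$n_objectives, 2L)

  # an empty feasible region (forced lactate export with its transporter
  # blocked) makes every objective infeasible: the sweep has no average
  m3 <- toy$model
  i <- m3$reactions$id == "EX_lac"
  m3$reactions$lower_bound[i] <- 3; m3$reactions$upper_bound[i] <- 3
  m3$reactions$upper_bound[m3$reactions$id == "LACT"] <- 0
  expect_equal(solve_fba(m3, "ATPM")$status, "infeasible")
  expect_error(suppressWarnings(objective_sweep(m3, pair)),
               "all objectives infeasible")
})

test_that("perturbations raise forced bounds without mutating the input model", {
  toy <- make_toy_network()
  wt <- objective_sweep(toy$model, toy$objectives)
  before <- toy$model$reactions
  pert <- apply_perturbation(toy$model, wt, toy$perturbation)
  expect_identical(toy$model$reactions, before)  # pure function

  ids <- toy$perturbation$forced_uptake$reaction_id
  expect_setequal(ids, reactions_by_ref(toy$model, c("TCDB:2.A.21.3.6",
                                                     "TCDB:2.A.1.1.29")))
  i <- match(ids, pert$reactions$id)
  expect_equal(pert$reactions$lower_bound[i],
               1.6 * unname(wt$mean_flux[ids]), tolerance = 1e-12)
  expect_equal(pert$reactions$upper_bound[i],
               toy$model$reactions$upper_bound[match(ids, before$id)])

  # factor 1.0 pins the bound exactly at the baseline mean
  spec1 <- perturbation_spec(forced_uptake = data.frame(
    reaction_id = ids, factor = 1))
  p1 <- apply_perturbation(toy$model, wt, spec1)
  expect_equal(p1$reactions$lower_bound[match(ids, p1$reactions$id)],
               unname(wt$mean_flux[ids]), tolerance = 1e-12)

  # every post-perturbation solution respects the forced bound
  ko <- objective_sweep(pert, toy$objectives, keep_solutions = TRUE)
  for (s in ko$solutions) {
    expect_true(all(s$fluxes[ids] >= 1.6 * wt$mean_flux[ids] - 1e-9))
  }
})

test_that("perturbation errors: non-positive baseline and lb > ub", {
  toy <- make_toy_network()
  wt <- objective_sweep(toy$model, toy$objectives)
  bad <- perturbation_spec(forced_uptake = data.frame(
    reaction_id = "LDH", factor = 1.6))
  wt0 <- wt; wt0$mean_flux["LDH"] <- 0
  expect_error(apply_perturbation(toy$model, wt0, bad), "ill-defined")

  too_big <- perturbation_spec(forced_uptake = data.frame(
    reaction_id = "GLUT", factor = 1e6))
  expect_error(apply_perturbation(toy$model, wt, too_big),
               "exceeds upper bound")
  expect_error(perturbation_spec(forced_uptake = data.frame(
    reaction_id = "GLUT", factor = -1)), "> 0")

  # disabled reactions and direction blocks are applied verbatim
  spec <- perturbation_spec(
    disabled_reactions = "FAO",
    direction_blocks = data.frame(reaction_id = "GLUT",
                                  lower_bound = 0, upper_bound = 1))
  p <- apply_perturbation(toy$model, wt, spec)
  expect_equal(p$reactions$upper_bound[p$reactions$id == "FAO"], 0)
  expect_equal(p$reactions$upper_bound[p$reactions$id == "GLUT"], 1)
})
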