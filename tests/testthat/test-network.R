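test_that("constructor validates ids, stoichiometry and bounds", {
  net <- toy_linear_network()
  expect_s3_class(net, "metabolic_network")
  expect_identical(net$reactions$kind,
                   c("exchange", "internal", "internal", "internal",
                     "internal", "biomass"))
  mets <- net$metabolites
  expect_error(
    metabolic_network(mets, data.frame(id = "R1", lb = 0, ub = 1000),
                      list(R1 = c(ghost = -1)), biomass_id = "R1"),
    "undeclared metabolite")
  expect_error(
    metabolic_network(mets, data.frame(id = c("R1", "R1"), lb = 0, ub = 1000),
                      list(R1 = c(A_c = -1), R1 = c(B = -1)), biomass_id = "R1"),
    "duplicate reaction")
  expect_error(
    metabolic_network(mets, data.frame(id = "R1", lb = 5, ub = 1),
                      list(R1 = c(A_c = -1)), biomass_id = "R1"),
    "lower bound above upper")
  expect_error(
    metabolic_network(mets, data.frame(id = "R1", lb = 0, ub = 1000),
                      list(R1 = numeric(0)), biomass_id = "R1"),
    "empty stoichiometry")
  expect_error(
    metabolic_network(mets, data.frame(id = "R1", lb = 0, ub = 1000),
                      list(R1 = c(A_c = -1)), biomass_id = "nope"),
    "biomass")
})

test_that("splitting reversible reactions gives opposing non-negative components", {
  net <- toy_linear_network()
  sp <- split_reversible(net)
  # EX_A is reversible: two components with bounds [0, 1000]
  ex <- sp$components[sp$components$base_id == "EX_A", ]
  expect_setequal(ex$direction, c("forward", "reverse"))
  expect_true(all(ex$ub == 1000))
  # irreversible reactions keep a single forward component
  expect_identical(sp$components$direction[sp$components$base_id == "T"], "forward")
  # opposite stoichiometry of the two EX_A components
  expect_equal(as.numeric(sp$S[, "EX_A__fwd"]), -as.numeric(sp$S[, "EX_A__rev"]))
})

test_that("any feasible split flux recombines to a mass-balanced base flux", {
  net <- generate_network(n_pathways = 2, pathway_length = 2, n_decoys = 2,
                          reversible_fraction = 0.5, n_orphans = 1, seed = 9)
  sp <- split_reversible(net)
  media <- media_condition("m", c(EX_s1 = 10))
  found <- 0
  for (s in 1:5) {
    flux <- random_feasible_flux(sp, media, seed = s)
    if (is.null(flux)) next
    found <- found + 1
    nv <- net_fluxes(sp, flux)
    resid <- as.numeric(net$S %*% nv)
    expect_lt(max(abs(resid)), 1e-8)
    # and the net flux respects the base bounds
    expect_true(all(nv >= net$reactions$lb - 1e-8))
    expect_true(all(nv <= net$reactions$ub + 1e-8))
  }
  expect_gt(found, 0)
})

test_that("base-feasible fluxes have a split representation", {
  # maximize biomass on the base toy, then check the split network admits
  # the same biomass optimum (split soundness, converse direction)
  net <- toy_linear_network()
  media <- media_condition("m", c(EX_A = 10))
  split_opt <- fba_growth(net, media)
  # base-network LP solved directly on signed fluxes
  obj <- as.numeric(net$reactions$id == "BIO")
  lb <- net$reactions$lb; ub <- net$reactions$ub
  lb[net$reactions$id == "EX_A"] <- -10
  base_opt <- solve_lp(obj, net$S, lb = lb, ub = ub, sense = "max")
  expect_equal(split_opt, base_opt$objective, tolerance = 1e-8)
})

test_that("media application touches only exchange uptake bounds", {
  net <- toy_linear_network()
  sp <- split_reversible(net)
  med <- apply_media(sp, media_condition("m", c(EX_A = 7.5)))
  expect_equal(med$components$ub[med$components$id == "EX_A__rev"], 7.5)
  # secretion unchanged
  expect_equal(med$components$ub[med$components$id == "EX_A__fwd"], 1000)
  # internal bounds unchanged
  internal <- med$components$base_id %in% c("T", "C1", "C2", "SHORT", "BIO")
  expect_equal(med$components$ub[internal], sp$components$ub[internal])
  # empty media closes all uptakes and starves biomass
  closed <- apply_media(sp, media_condition("none", numeric(0)))
  expect_equal(closed$components$ub[closed$components$id == "EX_A__rev"], 0)
  expect_equal(fba_growth(net, media_condition("none", numeric(0))), 0)
  # media naming an internal reaction is rejected
  expect_error(apply_media(sp, media_condition("bad", c(T = 5))),
               "non-exchange")
})

test_that("remove_reactions drops reactions and keeps orphan metabolites", {
  net <- toy_linear_network()
  red <- remove_reactions(net, c("SHORT", "C1"))
  expect_setequal(red$reactions$id, c("EX_A", "T", "C2", "BIO"))
  expect_identical(red$metabolites$id, net$metabolites$id)
  expect_identical(remove_reactions(net, character(0)), net)
  expect_error(remove_reactions(net, "nope"), "unknown reaction")
  expect_error(remove_reactions(net, "BIO"), "biomass")
})
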