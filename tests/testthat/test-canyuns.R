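# Toy with a false-positive trap: the organism catabolizes source A only,
# but the universal network carries a high-evidence route for source B, so
# training on the A+B condition pulls the B route into the model and the
# B-only condition becomes a false positive -- until the route is pruned.
fp_trap_fixture <- function() {
  mets <- data.frame(id = c("a_e", "a_c", "b_e", "b_c", "bm_c"),
                     formula = "X", charge = 0L,
                     compartment = c("e", "c", "e", "c", "c"),
                     stringsAsFactors = FALSE)
  stoich <- list(EX_a = c(a_e = -1), EX_b = c(b_e = -1),
                 TR_a = c(a_e = -1, a_c = 1), CH_a = c(a_c = -1, bm_c = 1),
                 TR_b = c(b_e = -1, b_c = 1), FEED_b = c(b_c = -1, bm_c = 1),
                 BIO = c(bm_c = -1))
  rxns <- data.frame(id = names(stoich),
                     lb = c(-1000, -1000, 0, 0, 0, 0, 0), ub = 1000,
                     stringsAsFactors = FALSE)
  net <- metabolic_network(mets, rxns, stoich, biomass_id = "BIO")
  media <- list(
    cA = media_condition("cA", c(EX_a = 10)),
    cAB = media_condition("cAB", c(EX_a = 10, EX_b = 10)),
    cB = media_condition("cB", c(EX_b = 10)))
  phen <- data.frame(condition_id = c("cA", "cAB", "cB"),
                     call = c("growth", "growth", "no_growth"),
                     stringsAsFactors = FALSE)
  evidence <- data.frame(reaction_id = c("TR_a", "CH_a", "TR_b", "FEED_b"),
                         bitscore = c(900, 900, 950, 950),
                         stringsAsFactors = FALSE)
  list(net = net, media = media, phen = phen, evidence = evidence)
}

test_that("certainty values are per-direction condition frequencies", {
  sets <- list(c1 = make_fcrs(c("r1", "r2"), c("forward", "forward")),
               c2 = make_fcrs(c("r1", "r2"), c("forward", "forward")),
               c3 = make_fcrs(c("r1", "r2"), c("forward", "reverse")),
               c4 = empty_fcr_set())
  cv <- compute_cvs(sets)
  expect_identical(attr(cv, "n_conditions"), 4L)
  get <- function(r, d) cv$cv[cv$reaction_id == r & cv$direction == d]
  expect_equal(get("r1", "forward"), 0.75)
  expect_equal(get("r2", "forward"), 0.5)
  expect_equal(get("r2", "reverse"), 0.25)
  # absent reactions have no row rather than a zero row
  expect_false("r9" %in% cv$reaction_id)
  expect_error(compute_cvs(list()), "no training conditions")
  # infeasible solves enlarge the denominator but add no counts
  cv2 <- compute_cvs(sets[1:3], n_conditions = 6)
  expect_equal(cv2$cv[cv2$reaction_id == "r1" & cv2$direction == "forward"], 0.5)
})

test_that("model assembly restricts directionality to certain directions", {
  net <- toy_linear_network()
  net$reactions$lb[net$reactions$id %in% c("C1", "C2")] <- -1000
  cert <- compute_cvs(list(
    c1 = make_fcrs(c("T", "C1", "C2", "BIO"),
                   c("forward", "forward", "forward", "forward")),
    c2 = make_fcrs(c("T", "C1", "C2", "BIO"),
                   c("forward", "forward", "reverse", "forward"))))
  ev <- data.frame(reaction_id = "SHORT", bitscore = 900)
  model <- assemble_model(net, cert, evidence = ev)
  rx <- model$network$reactions
  # high evidence but CV = 0: excluded
  expect_false("SHORT" %in% rx$id)
  # forward-only CV on a reversible reaction: forced irreversible
  expect_equal(rx$lb[rx$id == "C1"], 0)
  # CVs in both directions: stays reversible
  expect_equal(rx$lb[rx$id == "C2"], -1000)
  expect_equal(rx$ub[rx$id == "C2"], 1000)
  # exchanges and biomass are retained as structural necessities
  expect_true(all(c("EX_A", "BIO") %in% rx$id))
  expect_error(assemble_model(net, make_fcrs("ghost", "forward")), "unknown")
})

test_that("phenotype simulation applies the strict growth threshold", {
  net <- toy_linear_network()
  media <- list(hi = media_condition("hi", c(EX_A = 10)),
                lo = media_condition("lo", c(EX_A = 0.1)),  # flux exactly 0.1
                off = media_condition("off", numeric(0)))
  pred <- simulate_phenotypes(net, media)
  expect_identical(pred$call, c("growth", "no_growth", "no_growth"))
  expect_equal(pred$biomass_flux, c(10, 0.1, 0))
})

test_that("confusion statistics follow the standard formulas", {
  mk <- function(pred, obs) {
    n <- length(pred)
    evaluate_predictions(
      data.frame(condition_id = paste0("c", 1:n), call = pred),
      data.frame(condition_id = paste0("c", 1:n), call = obs))
  }
  g <- "growth"; n <- "no_growth"
  perfect <- mk(rep(c(g, n), each = 5), rep(c(g, n), each = 5))
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$mcc, 1)
  inverted <- mk(rep(c(g, n), each = 5), rep(c(n, g), each = 5))
  expect_equal(inverted$accuracy, 0); expect_equal(inverted$mcc, -1)
  coin <- mk(rep(c(g, n), times = 50), rep(c(g, g, n, n), times = 25))
  expect_equal(coin$tp, 25); expect_equal(coin$fp, 25)
  expect_equal(coin$accuracy, 0.5); expect_equal(coin$mcc, 0)
  # degenerate margin: everything predicted growth
  allg <- mk(rep(g, 4), c(g, g, n, n))
  expect_true(allg$mcc_degenerate); expect_equal(allg$mcc, 0)
})

test_that("conditional essentiality matches the exhaustive knockout oracle", {
  # single linear pathway: every internal reaction essential
  net <- remove_reactions(toy_linear_network(), "SHORT")
  media <- list(m = media_condition("m", c(EX_A = 10)))
  ess <- conditional_essentiality(net, media)
  expect_setequal(ess$reaction_id, c("T", "C1", "C2"))
  # redundant parallel routes: neither route essential alone
  net2 <- toy_linear_network()
  ess2 <- conditional_essentiality(net2, media)
  expect_setequal(ess2$reaction_id, "T")
  # oracle equivalence on generated networks
  for (seed in 1:3) {
    g <- generate_network(n_pathways = 2, pathway_length = 3, n_decoys = 3,
                          reversible_fraction = 0.4, n_orphans = 1, seed = seed)
    md <- list(x = media_condition("x", c(EX_s1 = 10, EX_o1 = 10)))
    got <- conditional_essentiality(g, md)
    expect_setequal(got$reaction_id, knockout_oracle(g, md$x))
  }
})

test_that("net benefit is false positives corrected minus true positives lost", {
  # the worked removal case: essential in 38 false-positive and 7
  # true-positive conditions
  fp_ids <- paste0("fp", 1:38); tp_ids <- paste0("tp", 1:7)
  ess <- data.frame(condition_id = c(fp_ids, tp_ids),
                    reaction_id = "RUB", stringsAsFactors = FALSE)
  pred <- data.frame(condition_id = c(fp_ids, tp_ids),
                     call = "growth", stringsAsFactors = FALSE)
  obs <- data.frame(condition_id = c(fp_ids, tp_ids),
                    call = c(rep("no_growth", 38), rep("growth", 7)),
                    stringsAsFactors = FALSE)
  rk <- net_benefit_ranking(ess, pred, obs,
                            data.frame(reaction_id = "RUB", bitscore = 0))
  expect_equal(rk$fp_corrected, 38L)
  expect_equal(rk$tp_lost, 7L)
  expect_equal(rk$net_benefit, 31L)
  # tie-break: equal net benefit ranks the least-evidenced reaction first
  ess2 <- rbind(ess,
                data.frame(condition_id = paste0("fp", 1:38),
                           reaction_id = "OTHER"))
  ev <- data.frame(reaction_id = c("RUB", "OTHER"), bitscore = c(600, 0))
  rk2 <- net_benefit_ranking(ess2, pred, obs, ev)
  expect_identical(rk2$reaction_id, c("OTHER", "RUB"))
  expect_equal(rk2$net_benefit, c(38L, 31L))
})

test_that("pruning the top net-benefit reaction raises training accuracy", {
  fx <- fp_trap_fixture()
  model <- canyuns_build(fx$net, fx$evidence, fx$media, fx$phen)
  expect_equal(model$evaluation$fp, 1)  # the B-only trap fires
  ess <- conditional_essentiality(model, fx$media, model$predictions)
  rk <- net_benefit_ranking(ess, model$predictions, fx$phen, fx$evidence)
  expect_gt(rk$net_benefit[1], 0)
  pruned <- prune_model(model, rk$reaction_id[1])
  after <- evaluate_predictions(
    simulate_phenotypes(pruned, fx$media), fx$phen)
  expect_gt(after$accuracy, model$evaluation$accuracy)
  expect_equal(after$fp, 0)
  # removing a nowhere-essential reaction changes nothing
  idle <- setdiff(model$network$reactions$id[
    model$network$reactions$kind == "internal"], ess$reaction_id)
  if (length(idle)) {
    same <- evaluate_predictions(
      simulate_phenotypes(prune_model(model, idle[1]), fx$media), fx$phen)
    expect_equal(same$accuracy, model$evaluation$accuracy)
  }
})

test_that("rarefaction curves have the exhaustion and monotonicity properties", {
  sets <- list(a = make_fcrs(c("r1", "r2"), c("forward", "forward")),
               b = make_fcrs(c("r2", "r3"), c("forward", "forward")),
               c = make_fcrs(c("r1", "r4", "r5"), rep("forward", 3)),
               d = make_fcrs("r1", "forward"))
  rc <- rarefaction(sets, n_samples = 500, seed = 42)
  expect_equal(rc$k, 1:4)
  # k = N: every sample is the full union
  expect_equal(rc$min[4], 5); expect_equal(rc$max[4], 5); expect_equal(rc$mean[4], 5)
  # k = 1: extremes are the smallest and largest single-condition sets
  expect_equal(rc$min[1], 1); expect_equal(rc$max[1], 3)
  # mean accumulation is nondecreasing
  expect_true(all(diff(rc$mean) >= 0))
  # seeded determinism
  expect_identical(rarefaction(sets, n_samples = 200, seed = 7),
                   rarefaction(sets, n_samples = 200, seed = 7))
})

test_that("discovery categories and discovery accuracy follow their definitions", {
  mets <- data.frame(id = c("A_e", "A_c", "P"), formula = "X", charge = 0L,
                     compartment = c("e", "c", "c"), stringsAsFactors = FALSE)
  stoich <- list(EX_A = c(A_e = -1), T = c(A_e = -1, A_c = 1),
                 r1 = c(A_c = -1, P = 1), r2 = c(A_c = -1, P = 1),
                 r3 = c(A_c = -1, P = 1), r4 = c(A_c = -1, P = 1),
                 BIO = c(P = -1))
  rxns <- data.frame(id = names(stoich), lb = c(-1000, rep(0, 6)), ub = 1000)
  net <- metabolic_network(mets, rxns, stoich, biomass_id = "BIO")
  cert <- compute_cvs(list(
    c1 = make_fcrs(c("T", "r1", "r2", "r3", "r4"), rep("forward", 5)),
    c2 = make_fcrs(c("T", "r1"), rep("forward", 2))))
  ev <- data.frame(reaction_id = c("T", "r1", "r2", "r3", "r4"),
                   bitscore = c(800, 600, 0, 600, 0))
  model <- assemble_model(net, cert, evidence = ev)
  dm <- discovery_metrics(model, reference = c("T", "r1", "r2"), evidence = ev)
  expect_equal(unname(dm$categories),
               c(2L, 1L, 1L, 1L))  # confirmed, true_disc, likely, false_disc
  expect_equal(dm$discovery_accuracy, 0.5)
  # degenerate: every compared reaction evidenced and confirmed
  dm2 <- discovery_metrics(model, reference = c("T", "r1", "r2", "r3", "r4"),
                           evidence = data.frame(
                             reaction_id = c("T", "r1", "r2", "r3", "r4"),
                             bitscore = 900))
  expect_true(is.na(dm2$discovery_accuracy))
  expect_equal(dm2$overlap, 1)
})
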