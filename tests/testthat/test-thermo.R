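mkSol <- function(inflow, outflow, flows = c(r1 = 1L), steps = sum(flows > 0)) {
  new("FlowSolution", flows = flows,
      inflow = vapply(inflow, as.integer, integer(1)),
      outflow = vapply(outflow, as.integer, integer(1)),
      objective = 1000 * steps + sum(flows), steps = as.integer(steps),
      status = "feasible")
}

toyEnergy <- readEnergyTable(
  system.file("extdata", "toy_energy.tsv", package = "crnflow"))
toyCfg <- readCofactorConfig(
  system.file("extdata", "toy_cofactors.json", package = "crnflow"))

test_that("reaction energies follow products minus reactants", {
  tab <- data.frame(compound = c("A", "B", "C"),
                    dfG_prime_kJ_per_mol = c(-10, -20, -35))
  expect_identical(reactionEnergy(list(educts = numeric(), products = numeric()),
                                  tab), 0)
  net <- list(educts = c(A = 1, B = 1), products = c(C = 1))
  expect_identical(reactionEnergy(net, tab), -5)
  # stoichiometry weighting
  net2 <- list(educts = c(A = 2), products = c(B = 1, C = 1))
  expect_identical(reactionEnergy(net2, tab), (-20 - 35) - 2 * (-10))
})

test_that("reaction energy is additive and antisymmetric", {
  tab <- toyChem$energyTable
  set.seed(5)
  sp <- tab$compound
  for (k in 1:10) {
    e1 <- stats::setNames(sample(0:3, 3, TRUE), sample(sp, 3))
    p1 <- stats::setNames(sample(0:3, 3, TRUE), sample(sp, 3))
    e2 <- stats::setNames(sample(0:3, 2, TRUE), sample(sp, 2))
    p2 <- stats::setNames(sample(0:3, 2, TRUE), sample(sp, 2))
    g1 <- reactionEnergy(list(educts = e1, products = p1), tab)
    g2 <- reactionEnergy(list(educts = e2, products = p2), tab)
    gcat <- reactionEnergy(list(educts = c(e1, e2), products = c(p1, p2)), tab)
    expect_equal(gcat, g1 + g2)
    grev <- reactionEnergy(list(educts = p1, products = e1), tab)
    expect_equal(grev, -g1)
  }
})

test_that("missing formation energies raise, never default to zero", {
  tab <- data.frame(compound = "A", dfG_prime_kJ_per_mol = -1)
  expect_error(
    reactionEnergy(list(educts = c(A = 1), products = c(Mystery = 1)), tab),
    "Mystery")
  expect_error(readEnergyTable(
    withr::local_tempfile(lines = "wrong\theader\n1\t2", fileext = ".tsv")),
    "compound")
})

test_that("cofactor counting sums ATP-role and reduced-redox inflows", {
  cfg <- list(atp_species = "ATP",
              redox_reduced_species = c("NADPH", "NADH", "Fd_red"),
              carbon_species = c("CO2", "HCO3-"))
  none <- mkSol(c(A = 1), c(A = 2))
  expect_identical(countCofactors(none, cfg),
                   list(atpUnits = 0L, redoxUnits = 0L, total = 0L))
  s <- mkSol(c(ATP = 2, NADPH = 2, NADH = 1, Fd_red = 2, A = 1), c(A = 2))
  expect_identical(countCofactors(s, cfg),
                   list(atpUnits = 2L, redoxUnits = 5L, total = 7L))
  expect_identical(carbonUnitsFixed(mkSol(c(CO2 = 1, `HCO3-` = 1), c(A = 2)), cfg),
                   2L)
  expect_identical(carbonUnitsFixed(none, cfg), 0L)
})

test_that("the shortest toy cycle annotates with the planted bookkeeping", {
  s <- solve(toyQuery(toyCRN1))
  net <- netReaction(s)
  expect_identical(net$educts[["replicator"]], 1L)
  expect_identical(net$products[["replicator"]], 2L)
  expect_identical(net$educts[["CO2"]], 1L)
  ann <- annotateSolution(s, toyCfg, toyEnergy)
  expect_identical(ann@atpUnits, 1L)      # one thiyl donor per cycle
  expect_identical(ann@redoxUnits, 1L)    # one dithiol per cycle
  expect_identical(ann@cofactorsTotal, 2L)
  expect_identical(ann@carbonUnits, 1L)   # one CO2 fixed
  expect_identical(ann@steps, 4L)
  expect_identical(ann@atpPerCarbon, 1)
  expect_identical(ann@cofactorsPerCarbon, 2)
  expect_identical(ann@cofactorsPerStep, 0.5)
  # drG' of the planted net reaction, by hand from the shipped table:
  # products 2*(-30) + 2*(-237) + (-10) minus
  # educts (-30) + (-394) + 100 + (-16) + 50 = -544 - (-290) = -254
  expect_equal(ann@deltaG, -254)
  # element balance of the net reaction (all toy rules conserve atoms)
  lhs <- sort(unlist(lapply(names(net$educts), function(n)
    rep(atomMultiset(toyMol(n)), net$educts[[n]]))))
  rhs <- sort(unlist(lapply(names(net$products), function(n)
    rep(atomMultiset(toyMol(n)), net$products[[n]]))))
  expect_identical(lhs, rhs)
})

test_that("annotation ratios are invariant under uniform flow scaling", {
  s1 <- mkSol(c(thiyl = 1, dithiol = 2, CO2 = 2, replicator = 1),
              c(replicator = 3), flows = c(a = 1L, b = 1L), steps = 2)
  s2 <- mkSol(c(thiyl = 2, dithiol = 4, CO2 = 4, replicator = 2),
              c(replicator = 6), flows = c(a = 2L, b = 2L), steps = 2)
  cfg <- list(atp_species = "thiyl", redox_reduced_species = "dithiol",
              carbon_species = "CO2")
  a1 <- annotateSolution(s1, cfg)
  a2 <- annotateSolution(s2, cfg)
  expect_identical(a1@atpPerCarbon, a2@atpPerCarbon)
  expect_identical(a1@cofactorsPerCarbon, a2@cofactorsPerCarbon)
  expect_identical(2L * a1@cofactorsTotal, a2@cofactorsTotal)
})

test_that("zero-carbon annotations mark ratios as undefined", {
  cfg <- list(atp_species = "T", redox_reduced_species = character(),
              carbon_species = "CO2")
  ann <- annotateSolution(mkSol(c(A = 1), c(A = 2)), cfg)
  expect_true(is.na(ann@atpPerCarbon))
  expect_true(is.na(ann@cofactorsPerCarbon))
  expect_identical(ann@carbonUnits, 0L)
})

test_that("solution summaries average the per-solution annotations", {
  cfg <- list(atp_species = "T", redox_reduced_species = "R",
              carbon_species = "F")
  s1 <- mkSol(c(T = 2, R = 4, F = 1, A = 1), c(A = 2),
              flows = c(a = 1L, b = 1L, c = 1L), steps = 3)
  s2 <- mkSol(c(T = 3, R = 5, F = 1, A = 1), c(A = 2),
              flows = c(a = 1L, d = 1L), steps = 2)
  one <- summarizeSolutions(list(s1), cfg)
  expect_identical(one$summary$meanSteps, 3)
  expect_identical(one$summary$meanCofactors, 6)
  both <- summarizeSolutions(list(s1, s2), cfg)
  expect_identical(both$summary$meanCofactors, 7)  # (6 + 8) / 2
  expect_identical(both$summary$meanSteps, 2.5)
  expect_equal(both$summary$cofactorsPerStep, 7 / 2.5)
  expect_identical(nrow(both$perSolution), 2L)
})
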