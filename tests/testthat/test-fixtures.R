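test_that("the toy chemistry is reproducible and seed-sensitive", {
  a <- makeToyChemistry(0)
  b <- makeToyChemistry(0)
  expect_identical(vapply(a$molecules, canonicalKey, character(1)),
                   vapply(b$molecules, canonicalKey, character(1)))
  expect_identical(lapply(a$rules, writeRuleGML), lapply(b$rules, writeRuleGML))
  # different seeds differ in at least one rule context, but never in the
  # planted cycle or the molecule isomorphism classes
  c1 <- makeToyChemistry(1)
  expect_false(identical(lapply(a$rules, writeRuleGML),
                         lapply(c1$rules, writeRuleGML)))
  expect_identical(sort(vapply(a$molecules, canonicalKey, character(1))),
                   sort(vapply(c1$molecules, canonicalKey, character(1))))
  expect_identical(a$knownOptimum, c1$knownOptimum)
})

test_that("the planted optimum is recovered after expansion, for several seeds", {
  for (seed in c(0L, 1L)) {
    toy <- makeToyChemistry(seed)
    crn <- expandCRN(initCRN(toy$molecules), toy$rules, 1)
    q <- FlowQuery(crn, toy$config$autocatalyst, sources = toy$config$sources,
                   sinks = toy$config$sinks, flowCap = 4L)
    s <- solve(q)
    expect_identical(steps(s), toy$knownOptimum$steps)
    rx <- reactions(crn)
    expect_setequal(rx$rule[match(support(s), rx$id)],
                    toy$knownOptimum$supportRules)
    # certified by exhaustive search
    bf <- bruteforceFlows(q, maxSupport = toy$knownOptimum$steps, maxFlow = 2L)
    expect_identical(objective(s), objective(bf[[1]]))
  }
})

test_that("two-step expansion keeps the planted optimum (no shortcut appears)", {
  crn2 <- expandCRN(toyCRN1, toyChem$rules, 1)
  q2 <- toyQuery(crn2)
  s2 <- solve(q2)
  expect_identical(steps(s2), toyChem$knownOptimum$steps)
  expect_identical(objective(s2), 4004)
  rx <- reactions(crn2)
  expect_setequal(rx$rule[match(support(s2), rx$id)],
                  toyChem$knownOptimum$supportRules)
  # exhaustive certification on the full two-step network (supports up to
  # the planted length)
  bf2 <- bruteforceFlows(q2, maxSupport = toyChem$knownOptimum$steps,
                         maxFlow = 2L, sizeGuard = 40L)
  expect_identical(objective(bf2[[1]]), objective(s2))
})

test_that("random hypernetworks are reproducible and plant a feasible route", {
  h1 <- makeRandomHypernetwork(8, 12, seed = 4)
  h2 <- makeRandomHypernetwork(8, 12, seed = 4)
  expect_identical(crnflow:::reactionSignatures(h1$crn@reactions),
                   crnflow:::reactionSignatures(h2$crn@reactions))
  expect_identical(reactionCount(h1$crn), 12L)
  q <- FlowQuery(h1$crn, h1$autocatalyst, sources = h1$source, flowCap = 3L)
  s <- solve(q)  # must not raise: the planted route guarantees feasibility
  # the planted route itself (unit flow on each of its edges) is feasible,
  # so the optimum can cost at most that
  expect_lte(objective(s), 1000 * length(h1$plantedIds) + length(h1$plantedIds))
  expect_length(h1$plantedIds, 4L)
})

test_that("toy chemistry files round-trip through the study-space loader", {
  dir <- withr::local_tempdir()
  writeToyChemistry(toyChem, dir)
  expect_message(
    sp <- loadStudySpace(file.path(dir, "rules"), file.path(dir, "molecules")),
    "12 molecules and 9 rules")
  expect_length(sp$molecules, 12L)
  expect_length(sp$rules, 9L)
  expect_setequal(vapply(sp$molecules, canonicalKey, character(1)),
                  vapply(toyChem$molecules, canonicalKey, character(1)))
  # the reloaded space expands identically
  crn <- expandCRN(initCRN(sp$molecules), sp$rules, 1)
  expect_identical(reactionCount(crn), reactionCount(toyCRN1))
  # energy table and cofactor config also round-trip
  et <- readEnergyTable(file.path(dir, "toy_energy.tsv"))
  expect_identical(nrow(et), nrow(toyChem$energyTable))
  cfg <- readCofactorConfig(file.path(dir, "cofactors.json"))
  expect_identical(cfg$autocatalyst, "replicator")
})

test_that("the loader reports missing and malformed inputs per file", {
  empty <- withr::local_tempdir()
  expect_error(loadStudySpace(empty, empty), "does not exist|no .gml files")
  dir <- withr::local_tempdir()
  writeToyChemistry(toyChem, dir)
  bad <- file.path(dir, "molecules", "broken.gml")
  writeLines("graph [ node [ id 1 ] ]", bad)
  expect_error(loadStudySpace(file.path(dir, "rules"), file.path(dir, "molecules")),
               "broken.gml")
  expect_warning(
    sp <- loadStudySpace(file.path(dir, "rules"), file.path(dir, "molecules"),
                         strict = FALSE),
    "broken.gml")
  expect_length(sp$molecules, 12L)
})
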