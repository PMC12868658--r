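test_that("initCRN validates its inputs", {
  expect_error(initCRN(list()), "non-empty")
  sevenC <- MolGraph(
    data.frame(id = 1:7, label = "C"),
    data.frame(from = 1:6, to = 2:7, order = "-"), name = "heptane-skeleton")
  expect_error(initCRN(list(sevenC), cMax = 6), "heptane-skeleton")
  expect_silent(initCRN(list(sevenC), cMax = 7))
  crn <- initCRN(toyChem$molecules)
  expect_identical(molCount(crn), 12L)
  expect_identical(reactionCount(crn), 0L)
  expect_identical(crn@expansionLog$step, 0L)
})

test_that("one expansion step equals the independent brute-force oracle", {
  oracle <- oracleExpandOnce(toyCRN0@molecules, toyChem$rules)
  # the oracle does not apply the carbon/CoA filter; at this scale no
  # product violates it, which the package's own counts confirm
  expect_identical(reactionCount(toyCRN1), oracle$nReactions)
  expect_identical(molCount(toyCRN1), molCount(toyCRN0) + length(oracle$newKeys))
  expect_setequal(setdiff(names(toyCRN1@molecules), names(toyCRN0@molecules)),
                  oracle$newKeys)
})

test_that("expansion is deterministic and independent of rule order", {
  a <- expandCRN(toyCRN0, toyChem$rules, 1)
  b <- expandCRN(toyCRN0, rev(toyChem$rules), 1)
  sig <- function(crn) sort(crnflow:::reactionSignatures(crn@reactions))
  expect_identical(sig(a), sig(b))
  expect_identical(sort(names(a@molecules)), sort(names(b@molecules)))
  # rerunning the same expansion gives identical objects
  expect_identical(sig(a), sig(expandCRN(toyCRN0, toyChem$rules, 1)))
})

test_that("expansion counts are monotone and reach a fixed point when closed", {
  log <- expandCRN(toyCRN0, toyChem$rules, 2)@expansionLog
  expect_true(all(diff(log$nMolecules) >= 0))
  expect_true(all(diff(log$nReactions) >= 0))
  # a closed sub-chemistry: water + identity-free rules that cannot fire
  inert <- initCRN(list(toyMol("water"), toyMol("ammonia")))
  done <- expandCRN(inert, toyChem$rules["carboxylation"], 2)
  expect_identical(molCount(done), 2L)
  expect_identical(reactionCount(done), 0L)
})

test_that("constraint-violating products drop the whole generating reaction", {
  # with cMax = 1 the carboxylation product (2 carbons) is inadmissible
  crn <- expandCRN(initCRN(list(toyMol("replicator"), toyMol("CO2")), cMax = 1),
                   toyChem$rules["carboxylation"], 1)
  expect_identical(reactionCount(crn), 0L)
  expect_identical(molCount(crn), 2L)
  # with the default cMax = 6 the same expansion fires
  crn6 <- expandCRN(initCRN(list(toyMol("replicator"), toyMol("CO2"))),
                    toyChem$rules["carboxylation"], 1)
  expect_identical(reactionCount(crn6), 1L)
  # the CoA cap guards the input pool and the CRN validity alike
  expect_error(initCRN(list(toyMol("coa-thiol")), coaMax = 0), "coa-thiol")
  bisCoA <- MolGraph(data.frame(id = 1:3, label = c("CoA", "C", "CoA")),
                     data.frame(from = c(1, 2), to = c(2, 3), order = "-"),
                     name = "bis-CoA adduct")
  expect_error(initCRN(list(bisCoA)), "2 CoA")
  broken <- toyCRN1
  broken@molecules[[canonicalKey(bisCoA)]] <- bisCoA
  expect_match(paste(validObject(broken, test = TRUE), collapse = " "),
               "CoA limit")
  # every stored molecule respects the constraints (validity re-assertion)
  expect_true(validObject(toyCRN1, test = TRUE))
})

test_that("expanding past five steps warns", {
  small <- initCRN(list(toyMol("water")))
  expect_warning(expandCRN(small, toyChem$rules["carboxylation"], 6), "5 steps")
})

test_that("edge-set comparison splits a pathway into intersection and difference", {
  rx <- reactions(toyCRN1)
  # the planted cycle: one reaction per planted rule, the cleavage variant
  # being the one that yields two replicator copies
  repKey <- canonicalKey(toyMol("replicator"))
  pick <- vapply(seq_len(nrow(rx)), function(i)
    rx$rule[i] %in% toyChem$knownOptimum$supportRules &&
      (rx$rule[i] != "thiolytic_cleavage" ||
         identical(rx$products[[i]], c(repKey, repKey))), logical(1))
  planted <- rx[pick, ]
  expect_identical(nrow(planted), 4L)
  ref <- lapply(seq_len(nrow(planted)), function(i)
    list(educts = planted$educts[[i]], products = planted$products[[i]]))
  cmp <- edgeSetCompare(ref, toyCRN1)
  expect_length(cmp$difference, 0L)
  expect_length(cmp$intersection, 4L)
  fabricated <- list(educts = names(toyCRN1@molecules)[1],
                     products = names(toyCRN1@molecules)[2])
  cmp2 <- edgeSetCompare(c(ref, list(fabricated)), toyCRN1)
  expect_length(cmp2$difference, 1L)
  expect_identical(cmp2$difference[[1]], fabricated)
  # random subsets agree with naive per-reaction membership
  set.seed(7)
  sigs <- crnflow:::reactionSignatures(rx)
  for (k in 1:5) {
    pick <- sample(nrow(rx), 3)
    subset <- lapply(pick, function(i)
      list(educts = rx$educts[[i]], products = rx$products[[i]]))
    cmp3 <- edgeSetCompare(subset, toyCRN1)
    expect_length(cmp3$intersection, 3L)
  }
})

test_that("CRN JSON serialization round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  writeCRN(toyCRN1, path)
  back <- readCRN(path)
  expect_identical(sort(names(back@molecules)), sort(names(toyCRN1@molecules)))
  expect_identical(crnflow:::reactionSignatures(back@reactions),
                   crnflow:::reactionSignatures(toyCRN1@reactions))
  expect_identical(back@cMax, toyCRN1@cMax)
  expect_identical(back@expansionLog, toyCRN1@expansionLog)
  dot <- withr::local_tempfile(fileext = ".dot")
  exportDOT(toyCRN1, dot, highlight = reactions(toyCRN1)$id[1])
  expect_true(any(grepl("digraph", readLines(dot))))
})
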