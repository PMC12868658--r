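test_that("wildcard patterns match the declared element set only", {
  hydrog <- toyChem$rules[["hydrogenation"]]
  # aldehyde: C(=O)H matches with X bound to O
  ald <- toyMol("formyl-replicator")
  ms <- findMatches(hydrog, list(ald, toyMol("dithiol")))
  expect_length(ms, 1L)
  # an alkene C(=C)H matches with X bound to C
  alkene <- MolGraph(
    data.frame(id = 1:6, label = c("C", "C", "H", "H", "H", "H")),
    data.frame(from = c(1, 1, 1, 2, 2), to = c(2, 3, 4, 5, 6),
               order = c("=", "-", "-", "-", "-")))
  ms2 <- findMatches(hydrog, list(alkene, toyMol("dithiol")))
  expect_gt(length(ms2), 0L)
  # but C=S does not (S is not in the class of X)
  thioald <- MolGraph(
    data.frame(id = 1:4, label = c("C", "S", "H", "H")),
    data.frame(from = c(1, 1, 1), to = c(2, 3, 4), order = c("=", "-", "-")))
  expect_length(findMatches(hydrog, list(thioald, toyMol("dithiol"))), 0L)
})

test_that("a rule requiring an absent label finds no match", {
  cleave <- toyChem$rules[["thiolytic_cleavage"]]
  expect_length(findMatches(cleave, list(toyMol("water"))), 0L)
  expect_identical(nrow(deriveReactions(cleave,
    list(w = toyMol("water"), a = toyMol("ammonia")))), 0L)
})

test_that("match enumeration agrees with the brute-force injective-map oracle", {
  # run every toy rule against assorted educt multisets and compare the full
  # set of valid embeddings (not deduplicated) with the oracle's maps
  pools <- list(
    list(toyMol("replicator"), toyMol("CO2")),
    list(toyMol("carboxy-replicator"), toyMol("dithiol")),
    list(toyMol("formyl-replicator"), toyMol("ammonia")),
    list(toyMol("amino-replicator"), toyMol("thiyl")),
    list(toyMol("amino-replicator"), toyMol("coa-thiol")),
    list(toyMol("carboxy-replicator")),
    list(toyMol("replicator"), toyMol("replicator")),
    list(toyMol("water"), toyMol("CO2")))
  nChecked <- 0L
  for (rule in toyChem$rules) {
    for (educts in pools) {
      got <- findMatches(rule, educts, dedupe = FALSE)
      want <- oracleMatchMaps(rule, educts)
      expect_identical(length(got), length(want),
                       label = sprintf("%s on {%s}", rule@name,
                                       paste(vapply(educts, molName, ""),
                                             collapse = ", ")))
      if (length(got)) {
        gotSet <- sort(vapply(got, function(m)
          paste(m$mapping[order(as.integer(names(m$mapping)))], collapse = ","),
          character(1)))
        nd <- rule@nodes[rule@nodes$inLeft, , drop = FALSE]
        wantSet <- sort(vapply(want, function(mp) paste(mp, collapse = ","),
                               character(1)))
        expect_identical(gotSet, wantSet)
      }
      nChecked <- nChecked + 1L
    }
  }
  expect_gte(nChecked, 70L)
})

test_that("rule application conserves the atom multiset across the toy space", {
  crn <- expandCRN(toyCRN1, toyChem$rules, 1)
  rx <- reactions(crn)
  for (i in seq_len(nrow(rx))) {
    ed <- unlist(lapply(rx$educts[[i]], function(k) atomMultiset(crn@molecules[[k]])))
    pr <- unlist(lapply(rx$products[[i]], function(k) atomMultiset(crn@molecules[[k]])))
    expect_identical(sort(ed), sort(pr),
                     label = sprintf("atom balance of %s (%s)", rx$id[i], rx$rule[i]))
  }
  expect_gt(nrow(rx), 20L)
})

test_that("apply output is independent of host vertex numbering", {
  rule <- toyChem$rules[["carboxylation"]]
  educts1 <- list(toyMol("replicator"), toyMol("CO2"))
  educts2 <- lapply(educts1, permuteMol, seed = 99)
  p1 <- findMatches(rule, educts1)[[1]]$products
  p2 <- findMatches(rule, educts2)[[1]]$products
  expect_identical(sort(vapply(p1, canonicalKey, character(1))),
                   sort(vapply(p2, canonicalKey, character(1))))
})

test_that("the Fig-5-style reduction reduces the double bond and adds hydrogens", {
  hydrog <- toyChem$rules[["hydrogenation"]]
  ald <- toyMol("formyl-replicator")
  ms <- findMatches(hydrog, list(ald, toyMol("dithiol")))
  prods <- ms[[1]]$products
  keys <- vapply(prods, canonicalKey, character(1))
  # the disulfide leaves oxidized
  expect_true(canonicalKey(toyMol("disulfide")) %in% keys)
  reduced <- prods[[which(keys != canonicalKey(toyMol("disulfide")))[1]]]
  # C=O became C-O-H and C gained one H
  expect_identical(sum(reduced@bonds$order == "="), 0L)
  expect_identical(atomMultiset(reduced),
                   sort(c(atomMultiset(ald), "H", "H")))
})

test_that("deleting rules obey the dangling condition", {
  # delete an O reached through a single O-H bond
  del <- readRuleGML('
    rule [ ruleID "deleter"
      left [ node [ id 1 label "O" ]
        edge [ source 1 target 2 label "-" ] ]
      context [ node [ id 2 label "H" ] ]
      right [ ] ]')
  # in water the O keeps a second, unmatched H bond: the dangling condition
  # rejects every embedding
  expect_length(findMatches(del, list(toyMol("water"))), 0L)
  # a bare hydroxide has no extra bonds, deletion is clean
  oh <- MolGraph(data.frame(id = 1:2, label = c("O", "H")),
                 data.frame(from = 1, to = 2, order = "-"))
  ms <- findMatches(del, list(oh))
  expect_length(ms, 1L)
  prods <- ms[[1]]$products
  expect_identical(vapply(prods, function(p) p@atoms$label, character(1)), "H")
  # direct application at an invalid embedding errors instead of repairing
  badMatch <- list(mapping = stats::setNames(
    c(which(toyMol("water")@atoms$label == "O"),
      which(toyMol("water")@atoms$label == "H")[1]), c("1", "2")))
  # remap to host global indices: water is the single educt, ids = row order
  expect_error(applyRule(del, badMatch, list(toyMol("water"))), "dangling")
})

test_that("deriveReactions collapses duplicates and is idempotent", {
  pool <- toyCRN0@molecules
  for (rule in toyChem$rules) {
    t1 <- deriveReactions(rule, pool)
    t2 <- deriveReactions(rule, pool)
    expect_identical(t1$educts, t2$educts)
    expect_identical(t1$products, t2$products)
    if (nrow(t1)) {
      sig <- paste(vapply(t1$educts, paste, "", collapse = "+"),
                   vapply(t1$products, paste, "", collapse = "+"))
      expect_false(anyDuplicated(sig) > 0)
    }
  }
})

test_that("a generic reduction applied to two distinct carbonyls gives two reactions", {
  # drop the context H requirement so any C=O qualifies
  generic <- readRuleGML('
    rule [ ruleID "generic_reduction"
      left [
        edge [ source 1 target 2 label "=" ]
        edge [ source 3 target 4 label "-" ]
        edge [ source 5 target 6 label "-" ]
        edge [ source 3 target 5 label "-" ] ]
      context [
        node [ id 1 label "C" ] node [ id 2 label "O" ] node [ id 3 label "S" ]
        node [ id 4 label "H" ] node [ id 5 label "S" ] node [ id 6 label "H" ] ]
      right [
        edge [ source 1 target 2 label "-" ]
        edge [ source 1 target 4 label "-" ]
        edge [ source 2 target 6 label "-" ]
        edge [ source 3 target 5 label "=" ] ] ]')
  pool <- list(k1 = toyMol("formyl-replicator"),
               k2 = toyMol("carboxy-replicator"),
               red = toyMol("dithiol"))
  names(pool) <- vapply(pool, canonicalKey, character(1))
  tab <- deriveReactions(generic, pool)
  expect_identical(nrow(tab), 2L)
})
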