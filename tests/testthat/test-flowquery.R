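# small helper: a CRN of opaque species with hand-chosen reactions
handCRN <- function(rxns, nSpecies = 6L) {
  hn <- makeRandomHypernetwork(nSpecies, 1L, seed = 1L, planted = FALSE)
  crn <- hn$crn
  crn@reactions <- crnflow:::emptyCrnReactions()
  nm <- molNames(crn)
  byName <- stats::setNames(names(nm), nm)
  crnflow:::addReactionsRaw(crn, lapply(rxns, function(r)
    list(rule = r$rule, educts = unname(byName[r$educts]),
         products = unname(byName[r$products]))))
}

test_that("a single autocatalytic reaction is forced by conservation", {
  crn <- handCRN(list(list(rule = "dup", educts = c("v01", "v02"),
                           products = c("v01", "v01"))))
  q <- FlowQuery(crn, "v01", sources = "v02")
  s <- solve(q)
  expect_identical(unname(flows(s)[support(s)]), 1L)
  expect_identical(s@inflow[["v01"]], 1L)
  expect_identical(s@outflow[["v01"]], 2L)
  expect_identical(steps(s), 1L)
  expect_identical(objective(s), 1001)
})

test_that("model structure matches the formulation", {
  rxns <- list(
    list(rule = "r1", educts = c("v01", "v02"), products = "v03"),
    list(rule = "r2", educts = "v03", products = "v04"),
    list(rule = "r3", educts = "v04", products = c("v01", "v01")),
    list(rule = "r4", educts = "v05", products = "v04"),
    list(rule = "r5", educts = "v03", products = "v05"))
  crn <- handCRN(rxns)
  q <- FlowQuery(crn, "v01", sources = "v02", sinks = character(),
                 forbidden = reactions(crn)$id[4])
  m <- buildModel(q)
  E <- 5L
  expect_length(m$xIdx, E)
  expect_length(m$zIdx, E)
  # one balance row per molecule incident to a reaction
  expect_identical(sum(startsWith(m$labels, "balance:")), 5L)
  expect_identical(sum(startsWith(m$labels, "cap:")), E)
  expect_identical(sum(startsWith(m$labels, "use:")), E)
  # forbidden edge fixed to zero
  expect_true(any(startsWith(m$labels, "forbid:")))
  # a hand-built feasible flow satisfies every constraint row:
  # x = (1,1,1,0,0), z likewise, in/out for v01 (1,2), v02 in 1
  x <- numeric(m$nVars)
  x[m$xIdx[1:3]] <- 1; x[m$zIdx[1:3]] <- 1
  x[m$inIdx[[q@autocatalyst]]] <- 1
  x[m$outIdx[[q@autocatalyst]]] <- 2
  v02 <- names(molNames(crn))[molNames(crn) == "v02"]
  x[m$inIdx[[v02]]] <- 1
  lhs <- as.numeric(m$A %*% x)
  ok <- ifelse(m$dir == "<=", lhs <= m$rhs + 1e-9,
        ifelse(m$dir == ">=", lhs >= m$rhs - 1e-9, abs(lhs - m$rhs) < 1e-9))
  expect_true(all(ok))
  # and the solver finds exactly this optimum
  s <- solve(q)
  expect_identical(objective(s), 3003)
})

test_that("the solver matches the brute-force oracle on the planted toy cycle", {
  q <- toyQuery(toyCRN1)
  s <- solve(q)
  bf <- bruteforceFlows(q, maxSupport = 4, maxFlow = 2)
  expect_gt(length(bf), 0L)
  expect_identical(objective(s), objective(bf[[1]]))
  expect_identical(objective(s), 4L * 1000 + 4)
  rx <- reactions(toyCRN1)
  expect_setequal(rx$rule[match(support(s), rx$id)],
                  toyChem$knownOptimum$supportRules)
  expect_identical(steps(s), toyChem$knownOptimum$steps)
  expectConservation(s, q)
})

test_that("solutions satisfy conservation and net autocatalysis exactly", {
  q <- toyQuery(toyCRN1, numSolutions = 5L)
  sols <- enumerateDistinct(q)
  expect_gte(length(sols), 2L)
  for (s in sols) {
    expectConservation(s, q)
    gain <- s@outflow[["replicator"]] - s@inflow[["replicator"]]
    expect_gte(gain, q@autocatGain)
    expect_gte(s@inflow[["replicator"]], q@autocatIn)
    # z/x consistency: steps equals the number of positive flows
    expect_identical(steps(s), sum(flows(s) > 0L))
  }
})

test_that("uniformly doubled flows stay feasible but cost strictly more", {
  q <- toyQuery(toyCRN1, flowCap = 8L)
  s <- solve(q)
  doubled <- 2L * flows(s)
  expect_null(crnflow:::flowInfeasibleReason(q, doubled))
  objDoubled <- 1000 * sum(doubled > 0) + sum(doubled)
  expect_identical(sum(doubled > 0), steps(s))  # same support
  expect_gt(objDoubled, objective(s))           # strictly worse total flow
})

test_that("enumeration yields distinct supports, ordered objectives, exhaustion", {
  q <- toyQuery(toyCRN1, numSolutions = 5L, flowCap = 2L)
  sols <- enumerateDistinct(q)
  supports <- vapply(sols, function(s) paste(sort(support(s)), collapse = ","),
                     character(1))
  expect_false(anyDuplicated(supports) > 0)
  objs <- vapply(sols, objective, numeric(1))
  expect_true(all(diff(objs) >= 0))
  expect_true(attr(sols, "exhausted"))
  expect_match(attr(sols, "reason"), "exhausted")
  # support count equals the oracle's count of feasible supports at the same
  # flow bound
  bf <- bruteforceFlows(q, maxSupport = reactionCount(toyCRN1), maxFlow = 2L)
  expect_identical(length(sols), length(bf))
  expect_setequal(supports,
                  vapply(bf, function(s) paste(sort(support(s)), collapse = ","),
                         character(1)))
})

test_that("required and forbidden edges steer the search", {
  rx <- reactions(toyCRN1)
  plantedIds <- rx$id[rx$rule %in% toyChem$knownOptimum$supportRules]
  qf <- toyQuery(toyCRN1, forbidden = plantedIds[1])
  res <- tryCatch(solve(qf), crnflow_infeasible = function(e) "infeasible")
  if (!identical(res, "infeasible")) {
    expect_false(plantedIds[1] %in% support(res))
    expect_gt(objective(res), 4004)
  }
  qr <- toyQuery(toyCRN1, required = rx$id[rx$rule == "decarboxylation"])
  sr <- solve(qr)
  expect_true(all(qr@required %in% support(sr)))
  expect_gt(objective(sr), 4004)
})

test_that("solve and the oracle agree across random hypernetworks", {
  nAgree <- 0L; nInf <- 0L
  for (seed in 1:20) {
    hn <- makeRandomHypernetwork(7, 9, seed = seed, planted = seed %% 2 == 0,
                                 cycleLength = 3)
    q <- FlowQuery(hn$crn, hn$autocatalyst, sources = hn$source, flowCap = 3L)
    bf <- bruteforceFlows(q, maxSupport = reactionCount(hn$crn), maxFlow = 3L)
    sol <- tryCatch(solve(q), crnflow_infeasible = function(e) "infeasible")
    if (identical(sol, "infeasible")) {
      expect_length(bf, 0L)
      nInf <- nInf + 1L
    } else {
      expect_gt(length(bf), 0L)
      expect_identical(objective(sol), objective(bf[[1]]))
      nAgree <- nAgree + 1L
    }
  }
  expect_gte(nAgree + nInf, 20L)
  expect_gte(nAgree, 8L)  # the planted half is always feasible
})

test_that("infeasible queries and the size guard are reported distinctly", {
  crn <- handCRN(list(list(rule = "sink", educts = "v01", products = "v02")))
  q <- FlowQuery(crn, "v01", sources = character(), sinks = "v02")
  expect_error(solve(q), class = "crnflow_infeasible")
  expect_length(bruteforceFlows(q, maxSupport = 1, maxFlow = 2), 0L)
  big <- makeRandomHypernetwork(8, 30, seed = 3, planted = FALSE)
  qb <- FlowQuery(big$crn, big$autocatalyst, sources = big$source)
  expect_error(bruteforceFlows(qb), "size guard")
  expect_error(FlowQuery(toyCRN1, "no-such-molecule"), "not found")
})
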