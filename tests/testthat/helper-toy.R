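# Shared fixtures, built once per test run.

toyChem <- makeToyChemistry(0)
toyCRN0 <- initCRN(toyChem$molecules)
toyCRN1 <- expandCRN(toyCRN0, toyChem$rules, 1)

toyQuery <- function(crn, flowCap = 4L, ...) {
  FlowQuery(crn, toyChem$config$autocatalyst,
            sources = toyChem$config$sources,
            sinks = toyChem$config$sinks, flowCap = flowCap, ...)
}

toyMol <- function(name) {
  for (m in toyChem$molecules) if (identical(m@name, name)) return(m)
  stop("no toy molecule named ", name)
}

# exact conservation re-check of a solution from first principles
expectConservation <- function(sol, query) {
  crn <- query@crn
  st <- crnflow:::stoichMatrices(crn)
  net <- as.numeric(st$net %*% sol@flows[crn@reactions$id])
  names(net) <- rownames(st$net)
  nm <- crn@molNames
  for (k in names(net)) {
    isSrc <- k %in% query@sources
    isSnk <- k %in% query@sinks
    inN <- if (nm[[k]] %in% names(sol@inflow)) sol@inflow[[nm[[k]]]] else 0L
    outN <- if (nm[[k]] %in% names(sol@outflow)) sol@outflow[[nm[[k]]]] else 0L
    if (!isSrc && !isSnk) {
      expect_identical(unname(net[[k]]), 0, label = sprintf("net of internal %s", nm[[k]]))
    } else {
      expect_equal(unname(net[[k]]), outN - inN,
                   label = sprintf("in/out closure of %s", nm[[k]]))
    }
  }
  invisible(TRUE)
}
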