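# Hyperflow queries: the ILP pathway-search model on a CRN.
#
# A pathway is an integer hyperflow: x_e units of flow on each reaction
# hyperedge, conservation at every molecule that is not an allowed source
# or sink, inflow/outflow variables for the allowed species, and the
# autocatalysis condition that the designated molecule enters the pathway
# (inflow >= autocatIn) and leaves it with a strict net gain
# (outflow >= inflow + autocatGain). The objective min sum_e (w z_e + x_e)
# with a large edge weight w makes the support size (pathway length) the
# primary criterion and the total flow the tie-breaker, which suppresses
# uniformly up-scaled copies of the same route.

#' Construct a hyperflow query
#'
#' @param crn a [CRN-class].
#' @param autocatalyst molecule display name or canonical key.
#' @param sources,sinks display names or keys of species allowed to flow in /
#'   out (cofactors, the carbon sources, ...). The autocatalyst is added to
#'   both automatically.
#' @param autocatIn minimum autocatalyst inflow (default 1).
#' @param autocatGain minimum net gain of the autocatalyst (default 1).
#' @param w edge-count weight in the objective (default 1000).
#' @param flowCap per-edge flow upper bound used in the indicator linking
#'   constraints (default 10).
#' @param required,forbidden reaction ids whose use is forced / banned.
#' @param numSolutions number of topologically distinct solutions for
#'   [enumerateDistinct()] (default 1).
#' @return a [FlowQuery-class].
#' @export
FlowQuery <- function(crn, autocatalyst, sources = character(),
                      sinks = character(), autocatIn = 1L, autocatGain = 1L,
                      w = 1000L, flowCap = 10L, required = character(),
                      forbidden = character(), numSolutions = 1L) {
  ak <- resolveKeys(crn, autocatalyst)
  so <- unique(c(ak, if (length(sources)) resolveKeys(crn, sources)))
  si <- unique(c(ak, if (length(sinks)) resolveKeys(crn, sinks)))
  new("FlowQuery", crn = crn, autocatalyst = ak, sources = so, sinks = si,
      autocatIn = as.integer(autocatIn), autocatGain = as.integer(autocatGain),
      w = as.integer(w), flowCap = as.integer(flowCap),
      required = required, forbidden = forbidden,
      numSolutions = as.integer(numSolutions))
}

setMethod("show", "FlowQuery", function(object) {
  cat(sprintf(
    "FlowQuery: autocatalyst %s on %d-edge CRN; %d sources, %d sinks, w = %d\n",
    object@crn@molNames[object@autocatalyst], nrow(object@crn@reactions),
    length(object@sources), length(object@sinks), object@w))
})

# stoichiometry matrices of a CRN: molecules x reactions counts of educt
# (tail) and product (head) multiplicities
stoichMatrices <- function(crn) {
  keys <- names(crn@molecules)
  E <- nrow(crn@reactions)
  tail <- matrix(0L, length(keys), E, dimnames = list(keys, crn@reactions$id))
  head <- tail
  for (j in seq_len(E)) {
    et <- table(crn@reactions$educts[[j]])
    pt <- table(crn@reactions$products[[j]])
    tail[names(et), j] <- as.integer(et)
    head[names(pt), j] <- as.integer(pt)
  }
  list(tail = tail, head = head, net = head - tail)
}

#' Build the ILP hyperflow model of a query
#'
#' Variables: one integer flow \code{x_e} in \code{[0, flowCap]} and one
#' binary indicator \code{z_e} per hyperedge, linked by
#' \code{x_e <= flowCap z_e} and \code{x_e >= z_e}; one inflow variable per
#' allowed source and one outflow variable per allowed sink. Constraints:
#' flow conservation at every molecule (inflow/outflow terms only for
#' allowed species), the autocatalysis rows, forbidden edges fixed to zero
#' and required edges to at least one. Objective:
#' \code{min sum_e (w z_e + x_e)}.
#'
#' @param query a [FlowQuery-class].
#' @return list describing the model: variable table, objective, constraint
#'   matrix/directions/rhs, and index bookkeeping. Consumed by [solve()];
#'   exposed for inspection and testing.
#' @export
buildModel <- function(query) {
  crn <- query@crn
  E <- nrow(crn@reactions)
  if (E == 0L) stop("the CRN has no reactions to route flow through", call. = FALSE)
  st <- stoichMatrices(crn)
  keys <- names(crn@molecules)
  act <- keys[rowSums(st$tail) + rowSums(st$head) > 0 |
              keys %in% c(query@sources, query@sinks)]
  nIn <- length(query@sources); nOut <- length(query@sinks)
  nv <- 2L * E + nIn + nOut
  xIdx <- seq_len(E)
  zIdx <- E + seq_len(E)
  inIdx <- stats::setNames(2L * E + seq_len(nIn), query@sources)
  outIdx <- stats::setNames(2L * E + nIn + seq_len(nOut), query@sinks)

  rows <- list(); dirs <- character(); rhs <- numeric(); labels <- character()
  addRow <- function(coef, d, r, lab) {
    rows[[length(rows) + 1L]] <<- coef
    dirs[[length(dirs) + 1L]] <<- d
    rhs[[length(rhs) + 1L]] <<- r
    labels[[length(labels) + 1L]] <<- lab
  }
  # conservation per active molecule
  for (k in act) {
    coef <- numeric(nv)
    coef[xIdx] <- st$net[k, ]
    if (k %in% query@sources) coef[inIdx[[k]]] <- 1
    if (k %in% query@sinks) coef[outIdx[[k]]] <- -1
    addRow(coef, "==", 0, paste0("balance:", k))
  }
  # linking x_e <= cap z_e ; x_e >= z_e ; z_e <= 1
  for (j in seq_len(E)) {
    coef <- numeric(nv); coef[xIdx[j]] <- 1; coef[zIdx[j]] <- -query@flowCap
    addRow(coef, "<=", 0, paste0("cap:", crn@reactions$id[j]))
    coef <- numeric(nv); coef[xIdx[j]] <- 1; coef[zIdx[j]] <- -1
    addRow(coef, ">=", 0, paste0("use:", crn@reactions$id[j]))
    coef <- numeric(nv); coef[zIdx[j]] <- 1
    addRow(coef, "<=", 1, paste0("bin:", crn@reactions$id[j]))
  }
  # autocatalysis
  coef <- numeric(nv); coef[inIdx[[query@autocatalyst]]] <- 1
  addRow(coef, ">=", query@autocatIn, "autocat:in")
  coef <- numeric(nv)
  coef[outIdx[[query@autocatalyst]]] <- 1
  coef[inIdx[[query@autocatalyst]]] <- -1
  addRow(coef, ">=", query@autocatGain, "autocat:gain")
  # required / forbidden edges
  for (id in query@forbidden) {
    j <- match(id, crn@reactions$id)
    coef <- numeric(nv); coef[xIdx[j]] <- 1
    addRow(coef, "<=", 0, paste0("forbid:", id))
    coef <- numeric(nv); coef[zIdx[j]] <- 1
    addRow(coef, "<=", 0, paste0("forbidz:", id))
  }
  for (id in query@required) {
    j <- match(id, crn@reactions$id)
    coef <- numeric(nv); coef[zIdx[j]] <- 1
    addRow(coef, ">=", 1, paste0("require:", id))
  }
  obj <- numeric(nv)
  obj[xIdx] <- 1
  obj[zIdx] <- query@w
  list(obj = obj, A = do.call(rbind, rows), dir = dirs, rhs = rhs,
       labels = labels, xIdx = xIdx, zIdx = zIdx, inIdx = inIdx,
       outIdx = outIdx, reactionIds = crn@reactions$id, stoich = st,
       nVars = nv)
}

# canonical inflow/outflow from the net production vector of a flow
canonicalInOut <- function(net, query) {
  inflow <- integer(0); outflow <- integer(0)
  for (k in names(net)) {
    v <- net[[k]]
    if (k == query@autocatalyst) {
      inflow[k] <- query@autocatIn
      outflow[k] <- v + query@autocatIn
    } else if (v < 0) {
      inflow[k] <- -v
    } else if (v > 0) {
      outflow[k] <- v
    }
  }
  list(inflow = inflow, outflow = outflow)
}

# exact integer feasibility check of a flow vector against a query;
# returns NULL (ok) or a character reason
flowInfeasibleReason <- function(query, x) {
  st <- stoichMatrices(query@crn)
  if (any(x < 0L)) return("negative flow")
  if (any(x > query@flowCap)) return("flow exceeds flowCap")
  if (length(query@forbidden) &&
      any(x[match(query@forbidden, query@crn@reactions$id)] > 0L))
    return("forbidden edge used")
  if (length(query@required) &&
      any(x[match(query@required, query@crn@reactions$id)] == 0L))
    return("required edge unused")
  net <- as.integer(st$net %*% x)
  names(net) <- rownames(st$net)
  for (k in names(net)) {
    v <- net[[k]]
    if (k == query@autocatalyst) next
    if (v < 0 && !(k %in% query@sources)) return(sprintf("%s consumed but not a source", k))
    if (v > 0 && !(k %in% query@sinks)) return(sprintf("%s produced but not a sink", k))
  }
  if (net[[query@autocatalyst]] < query@autocatGain)
    return("autocatalyst net gain below autocatGain")
  NULL
}

makeFlowSolution <- function(query, x, status = "optimal") {
  st <- stoichMatrices(query@crn)
  net <- as.integer(st$net %*% x)
  names(net) <- rownames(st$net)
  io <- canonicalInOut(net[net != 0L | names(net) == query@autocatalyst], query)
  support <- sum(x > 0L)
  # report inflow/outflow by display name (keys are solver-internal)
  nm <- query@crn@molNames
  names(io$inflow) <- unname(nm[names(io$inflow)])
  names(io$outflow) <- unname(nm[names(io$outflow)])
  new("FlowSolution",
      flows = stats::setNames(as.integer(x), query@crn@reactions$id),
      inflow = io$inflow, outflow = io$outflow,
      objective = as.numeric(query@w) * support + sum(x),
      steps = as.integer(support), status = status)
}

#' @describeIn FlowQuery solve the hyperflow ILP to optimality. Infeasible
#'   queries raise a condition of class \code{crnflow_infeasible}; solver
#'   breakdowns (node/iteration limits) raise \code{crnflow_solver_error}.
#' @param a a FlowQuery (argument name fixed by the \code{solve} generic).
#' @param b unused.
#' @param extraCuts internal: additional constraint rows (no-good cuts).
#' @param ... unused.
#' @return a [FlowSolution-class].
#' @export
setMethod("solve", signature(a = "FlowQuery"), function(a, b, extraCuts = NULL, ...) {
  model <- buildModel(a)
  A <- model$A; dir <- model$dir; rhs <- model$rhs
  if (!is.null(extraCuts) && length(extraCuts$dir)) {
    A <- rbind(A, extraCuts$A); dir <- c(dir, extraCuts$dir)
    rhs <- c(rhs, extraCuts$rhs)
  }
  res <- solveILP(model$obj, A, dir, rhs, branchFirst = model$zIdx)
  if (res$status == "infeasible")
    stop(structure(class = c("crnflow_infeasible", "error", "condition"),
                   list(message = "flow query is infeasible: no hyperflow satisfies the constraints",
                        call = NULL)))
  x <- res$x[model$xIdx]
  bad <- flowInfeasibleReason(a, as.integer(x))
  if (!is.null(bad))
    stop(structure(class = c("crnflow_solver_error", "error", "condition"),
                   list(message = paste("solver returned an invalid flow:", bad),
                        call = NULL)))
  makeFlowSolution(a, as.integer(x))
})

setMethod("show", "FlowSolution", function(object) {
  cat(sprintf("FlowSolution (%s): %d steps, objective %g\n",
              object@status, object@steps, object@objective))
  used <- object@flows[object@flows > 0L]
  if (length(used))
    cat("  flows:", paste(sprintf("%s=%d", names(used), used), collapse = " "), "\n")
  cat("  inflow:", paste(sprintf("%s:%d", names(object@inflow), object@inflow),
                         collapse = " "), "\n")
  cat("  outflow:", paste(sprintf("%s:%d", names(object@outflow), object@outflow),
                          collapse = " "), "\n")
})

#' FlowSolution accessors
#'
#' @param sol a [FlowSolution-class].
#' @return \code{flows()}: named integer vector of per-reaction flows;
#'   \code{support()}: ids of the used reactions; \code{steps()}: support
#'   size (pathway length); \code{objective()}: the integer objective value.
#' @name flowsolution-accessors
NULL

#' @rdname flowsolution-accessors
#' @export
flows <- function(sol) sol@flows

#' @rdname flowsolution-accessors
#' @export
support <- function(sol) names(sol@flows)[sol@flows > 0L]

#' @rdname flowsolution-accessors
#' @export
steps <- function(sol) sol@steps

#' @rdname flowsolution-accessors
#' @export
objective <- function(sol) sol@objective

#' Enumerate topologically distinct flow solutions
#'
#' Repeatedly solves the query, after each solution adding a no-good cut
#' \eqn{\sum_{e \in S}(1 - z_e) + \sum_{e \notin S} z_e \ge 1} that excludes
#' the found support \eqn{S}, so returned solutions have pairwise distinct
#' supports and nondecreasing objectives. Enumeration stops early when the
#' solution space is exhausted; the result then carries
#' \code{attr(, "exhausted") = TRUE} and the stop reason.
#'
#' @param query a [FlowQuery-class]; \code{numSolutions} solutions are
#'   requested.
#' @return list of [FlowSolution-class] objects with attributes
#'   \code{exhausted} (logical) and \code{reason} (character or NULL).
#' @export
enumerateDistinct <- function(query) {
  model <- buildModel(query)
  nv <- model$nVars
  cuts <- list(A = matrix(0, 0, nv), dir = character(), rhs = numeric())
  out <- list()
  exhausted <- FALSE; reason <- NULL
  for (i in seq_len(query@numSolutions)) {
    sol <- tryCatch(solve(query, extraCuts = cuts), crnflow_infeasible = function(e) e)
    if (inherits(sol, "crnflow_infeasible")) {
      exhausted <- TRUE
      reason <- sprintf("solution space exhausted after %d solution(s)", length(out))
      break
    }
    if (length(out) && sol@objective < out[[length(out)]]@objective - 1e-9)
      stop("enumeration produced a decreasing objective; this is a bug", call. = FALSE)
    out[[length(out) + 1L]] <- sol
    inS <- sol@flows > 0L
    coef <- numeric(nv)
    coef[model$zIdx[inS]] <- -1
    coef[model$zIdx[!inS]] <- 1
    cuts$A <- rbind(cuts$A, coef)
    cuts$dir <- c(cuts$dir, ">=")
    cuts$rhs <- c(cuts$rhs, 1 - sum(inS))
  }
  attr(out, "exhausted") <- exhausted
  attr(out, "reason") <- reason
  out
}

#' Exhaustive brute-force hyperflow enumeration (test oracle)
#'
#' Enumerates every edge subset up to \code{maxSupport} edges and every
#' integer flow assignment with per-edge flow in \code{1..maxFlow}, keeping
#' the assignments that satisfy conservation, source/sink membership and the
#' autocatalysis condition. Independent of the ILP path: used to certify
#' [solve()] and [enumerateDistinct()] on small fixtures.
#'
#' @param query a [FlowQuery-class].
#' @param maxSupport largest support size enumerated.
#' @param maxFlow largest per-edge flow enumerated.
#' @param sizeGuard refuse CRNs with more reactions than this (default 25);
#'   the enumeration is exponential and intended for fixtures only.
#' @return list of [FlowSolution-class] objects, one per feasible support
#'   (its minimum-total-flow assignment), sorted by objective; empty list
#'   when no feasible flow exists.
#' @export
bruteforceFlows <- function(query, maxSupport = 6L, maxFlow = 3L, sizeGuard = 25L) {
  crn <- query@crn
  E <- nrow(crn@reactions)
  if (E > sizeGuard)
    stop(sprintf("CRN has %d edges, above the brute-force size guard (%d)",
                 E, sizeGuard), call. = FALSE)
  st <- stoichMatrices(crn)
  keys <- rownames(st$net)
  isSrc <- keys %in% query@sources
  isSnk <- keys %in% query@sinks
  acRow <- match(query@autocatalyst, keys)
  reqIdx <- match(query@required, crn@reactions$id)
  forIdx <- match(query@forbidden, crn@reactions$id)
  grids <- lapply(seq_len(maxSupport), function(s)
    t(as.matrix(expand.grid(rep(list(seq_len(maxFlow)), s)))))
  results <- list()
  for (s in seq_len(min(maxSupport, E))) {
    combos <- utils::combn(E, s)
    G <- grids[[s]]
    for (ci in seq_len(ncol(combos))) {
      S <- combos[, ci]
      if (length(forIdx) && any(forIdx %in% S)) next
      if (length(reqIdx) && !all(reqIdx %in% S)) next
      net <- st$net[, S, drop = FALSE] %*% G
      okInternal <- colSums(abs(net[!isSrc & !isSnk, , drop = FALSE])) == 0
      okSrc <- colSums((net[isSrc & !isSnk, , drop = FALSE]) > 0) == 0
      okSnk <- colSums((net[!isSrc & isSnk, , drop = FALSE]) < 0) == 0
      okAC <- net[acRow, ] >= query@autocatGain
      ok <- okInternal & okSrc & okSnk & okAC
      if (!any(ok)) next
      tot <- colSums(G[, ok, drop = FALSE])
      best <- which(ok)[which.min(tot)]
      x <- integer(E); x[S] <- G[, best]
      results[[length(results) + 1L]] <- makeFlowSolution(query, x, status = "feasible")
    }
  }
  if (!length(results)) return(list())
  results[order(vapply(results, function(sln) sln@objective, numeric(1)),
                vapply(results, function(sln) paste(support(sln), collapse = ","),
                       character(1)))]
}
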