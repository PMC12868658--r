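# Exact integer linear programming by branch-and-bound.
#
# No MILP library ships with this R installation, so the package carries its
# own exact solver: LP relaxations are solved by the two-phase primal
# simplex below (dense tableau, Dantzig pricing with a Bland's-rule
# fallback for anti-cycling), branching is depth-first on the most
# fractional variable (indicator variables first, "use the edge" branch
# explored first, which dives quickly to good incumbents under an
# edge-weight-dominated objective), and every accepted solution is
# re-verified against all constraints in exact integer arithmetic.

# Two-phase tableau simplex for min c'x s.t. A x (dir) b, x >= 0.
# dir entries: "<=", ">=", "=="; b may be negative (rows are flipped).
# Returns list(status = optimal|infeasible|error, x, value).
lpSolveDense <- function(obj, A, dir, rhs, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]
  }
  le <- which(dir == "<="); ge <- which(dir == ">=")
  nSlack <- length(le); nSurp <- length(ge)
  nArt <- m - nSlack  # artificials for >= and == rows
  ncols <- n + nSlack + nSurp + nArt
  T <- matrix(0, m, ncols)
  T[, seq_len(n)] <- A
  basis <- integer(m)
  slackCol <- n; surpCol <- n + nSlack; artCol <- n + nSlack + nSurp
  iArt <- 0L
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      slackCol <- slackCol + 1L; T[i, slackCol] <- 1; basis[i] <- slackCol
    } else {
      if (dir[i] == ">=") { surpCol <- surpCol + 1L; T[i, surpCol] <- -1 }
      iArt <- iArt + 1L
      T[i, artCol + iArt] <- 1
      basis[i] <- artCol + iArt
    }
  }
  b <- rhs
  isArt <- seq_len(ncols) > artCol

  pivot <- function(r, c) {
    piv <- T[r, c]
    T[r, ] <<- T[r, ] / piv
    b[r] <<- b[r] / piv
    other <- setdiff(seq_len(m), r)
    fac <- T[other, c]
    T[other, ] <<- T[other, , drop = FALSE] - outer(fac, T[r, ])
    b[other] <<- b[other] - fac * b[r]
    basis[r] <<- c
  }

  runPhase <- function(cost, allowed) {
    # returns TRUE on optimality, "unbounded" on unbounded column; the
    # reduced-cost row is maintained incrementally and refreshed
    # periodically against numerical drift
    it <- 0L; maxIt <- 2000L + 40L * (m + ncols); blandAt <- 500L + 5L * m
    red <- cost - as.numeric(crossprod(cost[basis], T))
    repeat {
      it <- it + 1L
      if (it > maxIt) return("maxit")
      if (it %% 200L == 0L)
        red <- cost - as.numeric(crossprod(cost[basis], T))
      redv <- ifelse(allowed, red, Inf)
      if (it <= blandAt) {
        j <- which.min(redv)
        if (redv[j] >= -tol) return(TRUE)
      } else {  # Bland's rule
        neg <- which(redv < -tol)
        if (!length(neg)) return(TRUE)
        j <- neg[1L]
      }
      col <- T[, j]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratio <- pmax(b[pos], 0) / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      r <- cand[which.min(basis[cand])]  # smallest basis index on ties
      rc <- red[j]
      pivot(r, j)
      red <- red - rc * T[r, ]
      red[j] <- 0
    }
  }

  if (nArt > 0L) {
    cost1 <- as.numeric(isArt)
    st <- runPhase(cost1, rep(TRUE, ncols))
    if (!isTRUE(st)) return(list(status = "error", message = paste("phase 1:", st)))
    if (sum(b[isArt[basis]]) > 1e-7) return(list(status = "infeasible"))
    # drive remaining artificials out of the basis
    for (i in which(isArt[basis])) {
      j <- which(abs(T[i, ]) > tol & !isArt)
      if (length(j)) pivot(i, j[1L]) else b[i] <- 0  # redundant row
    }
  }
  cost2 <- c(obj, rep(0, ncols - n))
  st <- runPhase(cost2, !isArt)
  if (identical(st, "unbounded"))
    return(list(status = "error", message = "LP unbounded"))
  if (!isTRUE(st)) return(list(status = "error", message = paste("phase 2:", st)))
  x <- numeric(ncols)
  x[basis] <- b
  list(status = "optimal", x = x[seq_len(n)], value = sum(obj * x[seq_len(n)]))
}

#' Exact branch-and-bound integer linear program solver
#'
#' Minimizes \code{obj'x} subject to \code{A x dir rhs} and \code{x >= 0}
#' integer. Designed for the hyperflow models of this package (all-integer
#' constraint data, objective dominated by large indicator weights).
#'
#' @param obj objective coefficients.
#' @param A dense constraint matrix.
#' @param dir character vector of "<=", ">=", "==" per row.
#' @param rhs right-hand sides.
#' @param branchFirst indices of variables to prefer when branching
#'   (typically the 0/1 indicator variables), explored upward first.
#' @param intTol integrality tolerance on the LP relaxation (default 1e-6).
#' @param objIsInt TRUE when all attainable objective values are integers
#'   (allows pruning with a unit gap).
#' @param nodeLimit abort after this many nodes (reported as solver failure,
#'   distinct from infeasibility).
#' @return list with \code{status} ("optimal"/"infeasible"), \code{x}
#'   (integer vector) and \code{objective}.
#' @keywords internal
solveILP <- function(obj, A, dir, rhs, branchFirst = integer(),
                     intTol = 1e-6, objIsInt = TRUE, nodeLimit = 50000L) {
  n <- ncol(A)
  incumbent <- NULL
  incObj <- Inf
  nodes <- 0L
  # a node is a list of extra bound rows: list(var, dir, val)
  stack <- list(list())
  isBranchPref <- logical(n); isBranchPref[branchFirst] <- TRUE

  exactFeasible <- function(xi) {
    lhs <- as.numeric(A %*% xi)
    ok <- ifelse(dir == "<=", lhs <= rhs + 1e-9,
          ifelse(dir == ">=", lhs >= rhs - 1e-9, abs(lhs - rhs) <= 1e-9))
    all(ok) && all(xi >= 0L)
  }

  while (length(stack)) {
    nodes <- nodes + 1L
    if (nodes > nodeLimit)
      stop(structure(class = c("crnflow_solver_error", "error", "condition"),
                     list(message = sprintf("branch-and-bound node limit (%d) reached",
                                            nodeLimit), call = NULL)))
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nb <- length(node)
    if (nb) {
      Ab <- matrix(0, nb, n)
      db <- character(nb); rb <- numeric(nb)
      for (i in seq_len(nb)) {
        Ab[i, node[[i]]$var] <- 1
        db[i] <- node[[i]]$dir
        rb[i] <- node[[i]]$val
      }
      Anode <- rbind(A, Ab); dnode <- c(dir, db); rnode <- c(rhs, rb)
    } else {
      Anode <- A; dnode <- dir; rnode <- rhs
    }
    lp <- lpSolveDense(obj, Anode, dnode, rnode)
    if (lp$status == "infeasible") next
    if (lp$status == "error")
      stop(structure(class = c("crnflow_solver_error", "error", "condition"),
                     list(message = paste("LP relaxation failed:", lp$message),
                          call = NULL)))
    gap <- if (objIsInt) 0.99 else 1e-7
    if (lp$value >= incObj - gap) next
    frac <- abs(lp$x - round(lp$x))
    if (max(frac) <= intTol) {
      xi <- as.integer(round(lp$x))
      if (exactFeasible(xi)) {
        v <- sum(obj * xi)
        if (v < incObj) { incObj <- v; incumbent <- xi }
        next
      }
      # numerically integral but exactly infeasible: fall through and branch
    }
    cand <- which(frac > intTol)
    pref <- cand[isBranchPref[cand]]
    pick <- if (length(pref)) pref[which.max(frac[pref])] else cand[which.max(frac[cand])]
    lo <- floor(lp$x[pick]); hi <- lo + 1
    # push "down" child first so the "up" child is explored first (LIFO)
    stack[[length(stack) + 1L]] <- c(node, list(list(var = pick, dir = "<=", val = lo)))
    stack[[length(stack) + 1L]] <- c(node, list(list(var = pick, dir = ">=", val = hi)))
  }
  if (is.null(incumbent)) return(list(status = "infeasible"))
  list(status = "optimal", x = incumbent,
       objective = sum(obj * incumbent), nodes = nodes)
}
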