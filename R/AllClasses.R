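#' @import methods
NULL

BOND_ORDERS <- c("-", "=", "#", ":")

#' MolGraph: a labeled molecular graph
#'
#' A molecule is an undirected, connected graph whose vertices are atoms
#' (element symbol, integer formal charge) and whose edges are bonds with
#' order \code{"-"} (single), \code{"="} (double), \code{"#"} (triple) or
#' \code{":"} (aromatic). Coenzyme A is abstracted to a single pseudo-atom
#' with the reserved label \code{"CoA"}; its internal carbons are thereby
#' excluded from carbon counting. Hydrogens are explicit vertices because
#' transformation rules move them.
#'
#' @slot atoms data.frame with columns \code{id} (integer, unique),
#'   \code{label} (character) and \code{charge} (integer).
#' @slot bonds data.frame with columns \code{from}, \code{to} (atom ids) and
#'   \code{order} (one of \code{-}, \code{=}, \code{#}, \code{:}).
#' @slot name optional display name.
#' @seealso [MolGraph()], [canonicalKey()], [countCarbons()], [countCoA()]
#' @exportClass MolGraph
setClass("MolGraph",
  representation(atoms = "data.frame", bonds = "data.frame", name = "character"),
  prototype(
    atoms = data.frame(id = integer(), label = character(), charge = integer()),
    bonds = data.frame(from = integer(), to = integer(), order = character()),
    name = NA_character_
  )
)

setValidity("MolGraph", function(object) {
  a <- object@atoms
  b <- object@bonds
  msgs <- character()
  if (nrow(a) == 0L) msgs <- c(msgs, "molecule must contain at least one atom")
  if (anyDuplicated(a$id)) msgs <- c(msgs, "atom ids must be unique")
  if (!is.integer(a$charge)) msgs <- c(msgs, "charges must be integers")
  if (nrow(b) > 0L) {
    if (!all(b$from %in% a$id) || !all(b$to %in% a$id))
      msgs <- c(msgs, "bond endpoint references a missing atom id")
    if (any(b$from == b$to)) msgs <- c(msgs, "self-loop bonds are not allowed")
    key <- paste(pmin(b$from, b$to), pmax(b$from, b$to))
    if (anyDuplicated(key)) msgs <- c(msgs, "at most one bond per atom pair")
    if (!all(b$order %in% BOND_ORDERS))
      msgs <- c(msgs, sprintf("bond order must be one of %s", paste(BOND_ORDERS, collapse = " ")))
  }
  if (length(msgs) == 0L && nrow(a) > 1L && !.molConnected(a, b))
    msgs <- c(msgs, "molecule graph must be connected (one molecule = one component)")
  if (length(msgs)) msgs else TRUE
})

.molConnected <- function(atoms, bonds) {
  n <- nrow(atoms)
  if (n <= 1L) return(TRUE)
  if (nrow(bonds) == 0L) return(FALSE)
  idx <- seq_len(n)
  names(idx) <- as.character(atoms$id)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- idx[[as.character(bonds$from[k])]]
    j <- idx[[as.character(bonds$to[k])]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
  }
  all(seen)
}

#' ReactionRule: a graph transformation rule (reaction class)
#'
#' A rule is a span of pattern graphs: the left side L (bonds and charges
#' before the reaction), the context K (the part that is preserved), and the
#' right side R (bonds and charges afterwards), with vertex identities shared
#' across the three. Applying the rule to a host graph deletes L-only
#' elements, keeps K, and adds R-only elements (double-pushout semantics with
#' an explicit dangling-edge check). Wildcard vertex labels (for example
#' \code{"X"}) stand for a declared finite set of elements and are bound
#' independently per matched vertex.
#'
#' @slot name rule identifier.
#' @slot nodes data.frame with one row per pattern vertex: \code{id},
#'   \code{inLeft}, \code{inRight} (logical), \code{leftLabel},
#'   \code{rightLabel}, \code{leftCharge}, \code{rightCharge}.
#'   Context vertices have \code{inLeft & inRight} and identical attributes.
#' @slot edges data.frame with \code{from}, \code{to}, \code{leftOrder},
#'   \code{rightOrder} (NA when absent on that side).
#' @slot wildcards named list mapping a wildcard label to the character
#'   vector of element symbols it may bind.
#' @seealso [readRuleGML()], [findMatches()], [applyRule()]
#' @exportClass ReactionRule
setClass("ReactionRule",
  representation(name = "character", nodes = "data.frame", edges = "data.frame",
                 wildcards = "list"))

setValidity("ReactionRule", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character()
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "rule vertex ids must be unique")
  if (nrow(ed) > 0L) {
    if (!all(ed$from %in% nd$id) || !all(ed$to %in% nd$id))
      msgs <- c(msgs, "rule edge references an undeclared vertex id")
    # an edge present on a side needs both endpoints present on that side
    for (k in seq_len(nrow(ed))) {
      ends <- match(c(ed$from[k], ed$to[k]), nd$id)
      if (!is.na(ed$leftOrder[k]) && !all(nd$inLeft[ends]))
        msgs <- c(msgs, "left-side edge endpoint not present on the left side")
      if (!is.na(ed$rightOrder[k]) && !all(nd$inRight[ends]))
        msgs <- c(msgs, "right-side edge endpoint not present on the right side")
    }
  }
  used <- unique(c(nd$leftLabel[nd$inLeft], nd$rightLabel[nd$inRight]))
  wl <- used[!(used %in% c(PERIODIC_LABELS, "CoA")) & !is.na(used)]
  undecl <- setdiff(wl, names(object@wildcards))
  if (length(undecl))
    msgs <- c(msgs, sprintf("wildcard label(s) %s used but not declared in a labelclass",
                            paste(undecl, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

PERIODIC_LABELS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Se", "Br", "I")

#' CRN: a directed multi-hypergraph chemical reaction network
#'
#' Vertices are molecule isomorphism classes (keyed by [canonicalKey()]) and
#' hyperedges are reactions, each a pair of educt and product multisets of
#' molecule keys plus the name of the generating rule. A CRN carries the
#' expansion constraints it was built under: molecules with more than
#' \code{cMax} carbons (CoA pseudo-atoms exempt) or more than \code{coaMax}
#' CoA pseudo-atoms are never admitted.
#'
#' @slot molecules named list of [MolGraph-class] objects, names are
#'   canonical keys.
#' @slot molNames named character, canonical key -> display name.
#' @slot reactions data.frame with columns \code{id}, \code{rule} and
#'   list-columns \code{educts}, \code{products} (character vectors of keys,
#'   with repetition, sorted).
#' @slot inputKeys keys of the initial molecule pool.
#' @slot cMax,coaMax integer expansion constraints.
#' @slot expansionLog data.frame with per-step molecule/reaction counts.
#' @seealso [initCRN()], [expandCRN()], [edgeSetCompare()]
#' @exportClass CRN
setClass("CRN",
  representation(molecules = "list", molNames = "character",
                 reactions = "data.frame", inputKeys = "character",
                 cMax = "integer", coaMax = "integer",
                 expansionLog = "data.frame"))

setValidity("CRN", function(object) {
  msgs <- character()
  keys <- names(object@molecules)
  if (nrow(object@reactions) > 0L) {
    ref <- unique(unlist(c(object@reactions$educts, object@reactions$products)))
    if (!all(ref %in% keys))
      msgs <- c(msgs, "reaction references a molecule key absent from the CRN")
    if (anyDuplicated(object@reactions$id))
      msgs <- c(msgs, "reaction ids must be unique")
    sig <- reactionSignatures(object@reactions)
    if (anyDuplicated(sig))
      msgs <- c(msgs, "(educts, products, rule) must be unique per reaction")
  }
  for (k in keys) {
    m <- object@molecules[[k]]
    if (countCarbons(m) > object@cMax)
      msgs <- c(msgs, sprintf("molecule %s violates the %d-carbon limit", k, object@cMax))
    if (countCoA(m) > object@coaMax)
      msgs <- c(msgs, sprintf("molecule %s violates the CoA limit of %d", k, object@coaMax))
  }
  if (length(msgs)) msgs else TRUE
})

#' FlowQuery: an autocatalytic hyperflow query on a CRN
#'
#' Describes the ILP hyperflow model: which molecule is the autocatalyst,
#' which species may enter (sources) and leave (sinks) the pathway, the
#' edge-count weight \code{w} of the objective
#' \eqn{\min \sum_e (w z_e + x_e)}, the per-edge flow cap used in the
#' indicator linking constraints, and required/forbidden reactions.
#' The autocatalyst is always a member of both sources and sinks.
#'
#' @slot crn the [CRN-class] searched.
#' @slot autocatalyst canonical key of the autocatalytic molecule.
#' @slot sources,sinks canonical keys allowed inflow / outflow.
#' @slot autocatIn minimum autocatalyst inflow (default 1).
#' @slot autocatGain minimum net autocatalyst gain (default 1).
#' @slot w integer edge-count weight (default 1000).
#' @slot flowCap integer upper bound on per-edge flow (default 10).
#' @slot required,forbidden reaction ids fixed to be used / unused.
#' @slot numSolutions number of topologically distinct solutions requested.
#' @seealso [FlowQuery()], [buildModel()], [solve()], [enumerateDistinct()]
#' @exportClass FlowQuery
setClass("FlowQuery",
  representation(crn = "CRN", autocatalyst = "character",
                 sources = "character", sinks = "character",
                 autocatIn = "integer", autocatGain = "integer",
                 w = "integer", flowCap = "integer",
                 required = "character", forbidden = "character",
                 numSolutions = "integer"))

setValidity("FlowQuery", function(object) {
  msgs <- character()
  if (!(object@autocatalyst %in% names(object@crn@molecules)))
    msgs <- c(msgs, "autocatalyst is absent from the CRN")
  if (!(object@autocatalyst %in% object@sources) ||
      !(object@autocatalyst %in% object@sinks))
    msgs <- c(msgs, "autocatalyst must be in both sources and sinks")
  if (object@w < 1L) msgs <- c(msgs, "w must be >= 1")
  if (object@flowCap < 1L) msgs <- c(msgs, "flowCap must be >= 1")
  if (object@autocatIn < 1L) msgs <- c(msgs, "autocatIn must be >= 1")
  if (object@autocatGain < 1L) msgs <- c(msgs, "autocatGain must be >= 1")
  if (object@numSolutions < 1L) msgs <- c(msgs, "numSolutions must be >= 1")
  bad <- setdiff(c(object@required, object@forbidden), object@crn@reactions$id)
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown reaction id(s): %s", paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' FlowSolution: an integer hyperflow satisfying a query
#'
#' Integer flow per hyperedge plus inflow/outflow per allowed molecule.
#' Internal molecules (not sources or sinks) are produced and consumed in
#' equal amounts; the autocatalyst has outflow exceeding inflow by at least
#' the queried net gain. \code{steps} is the number of reactions with
#' positive flow (the support size), the pathway-length measure.
#'
#' @slot flows named integer vector, reaction id -> flow (x_e >= 0).
#' @slot inflow,outflow named integer vectors over source / sink keys
#'   (zero entries dropped).
#' @slot objective the exact integer objective sum(w z_e + x_e).
#' @slot steps number of used reactions (support size).
#' @slot status "optimal" for solver results, "feasible" for oracle output.
#' @exportClass FlowSolution
setClass("FlowSolution",
  representation(flows = "integer", inflow = "integer", outflow = "integer",
                 objective = "numeric", steps = "integer", status = "character"))

#' Annotation: post-annotation of one flow solution
#'
#' @slot netEducts,netProducts named numeric stoichiometric multisets of the
#'   solution's net reaction (by molecule display name).
#' @slot deltaG standard transformed Gibbs reaction energy in kJ/mol, NA when
#'   no energy table was supplied.
#' @slot atpUnits,redoxUnits,cofactorsTotal,carbonUnits integer counts.
#' @slot steps support size of the annotated solution.
#' @slot atpPerCarbon,cofactorsPerCarbon,cofactorsPerStep derived ratios.
#' @exportClass Annotation
setClass("Annotation",
  representation(netEducts = "numeric", netProducts = "numeric",
                 deltaG = "numeric", atpUnits = "integer",
                 redoxUnits = "integer", cofactorsTotal = "integer",
                 carbonUnits = "integer", steps = "integer",
                 atpPerCarbon = "numeric", cofactorsPerCarbon = "numeric",
                 cofactorsPerStep = "numeric"))

reactionSignatures <- function(reactions) {
  if (nrow(reactions) == 0L) return(character())
  vapply(seq_len(nrow(reactions)), function(i) {
    paste(reactions$rule[i],
          paste(sort(reactions$educts[[i]]), collapse = "+"),
          paste(sort(reactions$products[[i]]), collapse = "+"),
          sep = " :: ")
  }, character(1))
}
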