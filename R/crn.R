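# The chemical reaction network: a directed multi-hypergraph whose vertices
# are molecule isomorphism classes and whose hyperedges are reactions.

#' Initialize a CRN from an input molecule pool
#'
#' @param molecules list of [MolGraph-class] input molecules (the initial
#'   pool; intermediates and helper species).
#' @param cMax maximum number of carbon atoms per admitted molecule
#'   (default 6; CoA pseudo-atoms are exempt).
#' @param coaMax maximum number of CoA pseudo-atoms per admitted molecule
#'   (default 1).
#' @return a [CRN-class] with the input pool, no reactions, and an expansion
#'   log recording step 0.
#' @export
initCRN <- function(molecules, cMax = 6L, coaMax = 1L) {
  if (length(molecules) == 0L)
    stop("the input molecule list must be non-empty", call. = FALSE)
  cMax <- as.integer(cMax); coaMax <- as.integer(coaMax)
  keys <- character(0); mols <- list(); nms <- character(0)
  for (i in seq_along(molecules)) {
    m <- molecules[[i]]
    nm <- if (is.na(m@name)) sprintf("input_%d", i) else m@name
    if (countCarbons(m) > cMax)
      stop(sprintf("input molecule '%s' has %d carbons, exceeding cMax = %d",
                   nm, countCarbons(m), cMax), call. = FALSE)
    if (countCoA(m) > coaMax)
      stop(sprintf("input molecule '%s' has %d CoA units, exceeding coaMax = %d",
                   nm, countCoA(m), coaMax), call. = FALSE)
    k <- canonicalKey(m)
    if (k %in% keys) next  # duplicate isomorphism class in the input
    keys <- c(keys, k); mols[[k]] <- m; nms[k] <- nm
  }
  new("CRN", molecules = mols, molNames = nms,
      reactions = emptyCrnReactions(), inputKeys = keys,
      cMax = cMax, coaMax = coaMax,
      expansionLog = data.frame(step = 0L, nMolecules = length(mols),
                                nReactions = 0L))
}

emptyCrnReactions <- function() {
  out <- data.frame(id = character(), rule = character(), stringsAsFactors = FALSE)
  out$educts <- list(); out$products <- list()
  out
}

#' @describeIn initCRN number of molecule vertices.
#' @param crn a CRN.
#' @export
molCount <- function(crn) length(crn@molecules)

#' @describeIn initCRN number of reaction hyperedges.
#' @export
reactionCount <- function(crn) nrow(crn@reactions)

#' @describeIn initCRN display names of the molecules (named by key).
#' @export
molNames <- function(crn) crn@molNames

#' @describeIn initCRN the reaction table (id, rule, educt/product key lists).
#' @export
reactions <- function(crn) crn@reactions

setMethod("show", "CRN", function(object) {
  cat(sprintf("CRN: %d molecules, %d reactions (cMax = %d, coaMax = %d)\n",
              length(object@molecules), nrow(object@reactions),
              object@cMax, object@coaMax))
  if (nrow(object@expansionLog) > 0L) {
    cat("expansion log:\n")
    print(object@expansionLog, row.names = FALSE)
  }
})

#' Expand a CRN by iterative rule application
#'
#' One step matches every rule against the molecule pool as it existed at
#' the start of the step; all derived reactions whose products satisfy the
#' carbon and CoA constraints are added simultaneously, and new product
#' molecules become matchable in the next step. Reactions producing any
#' constraint-violating molecule are dropped entirely. The result is
#' deterministic and independent of rule order.
#'
#' @param crn a [CRN-class].
#' @param rules list of [ReactionRule-class] objects.
#' @param steps number of expansion rounds (>= 1). Expanding beyond 5 steps
#'   is allowed but warned against: hypergraph growth is combinatorial and
#'   downstream flow queries become impractically large.
#' @param quiet suppress the per-step log line.
#' @return the expanded [CRN-class] with an updated expansion log.
#' @export
expandCRN <- function(crn, rules, steps = 1L, quiet = TRUE) {
  stopifnot(steps >= 1L)
  if (max(crn@expansionLog$step) + steps > 5L)
    warning("expanding beyond 5 steps: expect combinatorial growth", call. = FALSE)
  if (is(rules, "ReactionRule")) rules <- list(rules)
  sigs <- reactionSignatures(crn@reactions)
  nextId <- nrow(crn@reactions) + 1L
  for (s in seq_len(steps)) {
    pool <- crn@molecules
    newRxns <- list()
    newMols <- list()
    for (rule in rules) {
      tab <- deriveReactions(rule, pool)
      for (i in seq_len(nrow(tab))) {
        prodMols <- tab$productMols[[i]]
        nc <- vapply(prodMols, countCarbons, integer(1))
        na <- vapply(prodMols, countCoA, integer(1))
        if (any(nc > crn@cMax) || any(na > crn@coaMax)) next
        sig <- paste(tab$rule[i],
                     paste(tab$educts[[i]], collapse = "+"),
                     paste(tab$products[[i]], collapse = "+"), sep = " :: ")
        if (sig %in% sigs) next
        sigs <- c(sigs, sig)
        newRxns[[length(newRxns) + 1L]] <- list(
          rule = tab$rule[i], educts = tab$educts[[i]], products = tab$products[[i]],
          sig = sig)
        for (pm in prodMols) {
          k <- canonicalKey(pm)
          if (!(k %in% names(pool)) && !(k %in% names(newMols))) newMols[[k]] <- pm
        }
      }
    }
    # deterministic ordering: sort new reactions by signature, molecules by key
    if (length(newRxns)) {
      ord <- order(vapply(newRxns, `[[`, character(1), "sig"))
      newRxns <- newRxns[ord]
      add <- data.frame(
        id = sprintf("e%04d", seq(nextId, length.out = length(newRxns))),
        rule = vapply(newRxns, `[[`, character(1), "rule"),
        stringsAsFactors = FALSE)
      add$educts <- lapply(newRxns, `[[`, "educts")
      add$products <- lapply(newRxns, `[[`, "products")
      crn@reactions <- rbind(crn@reactions, add)
      nextId <- nextId + length(newRxns)
    }
    if (length(newMols)) {
      ks <- sort(names(newMols))
      for (k in ks) {
        crn@molecules[[k]] <- newMols[[k]]
        nm <- newMols[[k]]@name
        crn@molNames[k] <- if (!is.na(nm)) nm else
          sprintf("m%03d", length(crn@molecules))
      }
    }
    stepNo <- max(crn@expansionLog$step) + 1L
    crn@expansionLog <- rbind(crn@expansionLog,
      data.frame(step = stepNo, nMolecules = length(crn@molecules),
                 nReactions = nrow(crn@reactions)))
    if (!quiet)
      message(sprintf("step %d: %d molecules, %d reactions", stepNo,
                      length(crn@molecules), nrow(crn@reactions)))
  }
  validObject(crn)
  crn
}

# append externally constructed reactions (used by the random-hypernetwork
# fixture); educts/products are key multisets over existing molecules
addReactionsRaw <- function(crn, rxns) {
  sigs <- reactionSignatures(crn@reactions)
  nextId <- nrow(crn@reactions) + 1L
  for (r in rxns) {
    stopifnot(all(c(r$educts, r$products) %in% names(crn@molecules)))
    sig <- paste(r$rule, paste(sort(r$educts), collapse = "+"),
                 paste(sort(r$products), collapse = "+"), sep = " :: ")
    if (sig %in% sigs) next
    sigs <- c(sigs, sig)
    add <- data.frame(id = sprintf("e%04d", nextId), rule = r$rule,
                      stringsAsFactors = FALSE)
    add$educts <- list(sort(r$educts))
    add$products <- list(sort(r$products))
    crn@reactions <- rbind(crn@reactions, add)
    nextId <- nextId + 1L
  }
  validObject(crn)
  crn
}

#' Compare a reference pathway against a CRN's reaction set
#'
#' Membership is decided on educt/product key multisets (the net chemical
#' event), ignoring reaction ids and rule names, so a literature pathway can
#' be checked against an expanded space regardless of which rule generated
#' each step.
#'
#' @param pathway list of reactions, each \code{list(educts = , products = )}
#'   with character key multisets, or a reaction data.frame as in a CRN.
#' @param crn a [CRN-class].
#' @return \code{list(intersection =, difference =)}, each a list of the
#'   pathway's reactions present in / absent from the CRN.
#' @export
edgeSetCompare <- function(pathway, crn) {
  if (is.data.frame(pathway)) {
    pathway <- lapply(seq_len(nrow(pathway)), function(i)
      list(educts = pathway$educts[[i]], products = pathway$products[[i]]))
  }
  crnSigs <- vapply(seq_len(nrow(crn@reactions)), function(i)
    paste(paste(sort(crn@reactions$educts[[i]]), collapse = "+"),
          paste(sort(crn@reactions$products[[i]]), collapse = "+"), sep = ">>"),
    character(1))
  inCrn <- vapply(pathway, function(p)
    paste(paste(sort(p$educts), collapse = "+"),
          paste(sort(p$products), collapse = "+"), sep = ">>") %in% crnSigs,
    logical(1))
  list(intersection = pathway[inCrn], difference = pathway[!inCrn])
}

#' Serialize a CRN to JSON
#'
#' The document stores the molecule table (canonical key, display name, GML
#' payload), the reaction list, the constraint parameters and the expansion
#' log. There is no standard hypergraph exchange format; this schema is the
#' package's own and is read back by [readCRN()].
#'
#' @param crn a [CRN-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCRN <- function(crn, path) {
  doc <- list(
    format = "crnflow-crn", version = 1L,
    cMax = crn@cMax, coaMax = crn@coaMax,
    inputKeys = crn@inputKeys,
    molecules = lapply(names(crn@molecules), function(k) list(
      key = k, name = unname(crn@molNames[k]),
      gml = writeMoleculeGML(crn@molecules[[k]]))),
    reactions = lapply(seq_len(nrow(crn@reactions)), function(i) list(
      id = crn@reactions$id[i], rule = crn@reactions$rule[i],
      educts = crn@reactions$educts[[i]], products = crn@reactions$products[[i]])),
    expansionLog = crn@expansionLog)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a CRN serialized by [writeCRN()]
#'
#' Canonical keys are recomputed from the GML payloads and verified against
#' the stored keys.
#'
#' @param path path to the JSON document.
#' @return a [CRN-class].
#' @export
readCRN <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "crnflow-crn"))
    stop("not a crnflow CRN document", call. = FALSE)
  mols <- list(); nms <- character(0)
  for (m in doc$molecules) {
    g <- readMoleculeGML(m$gml)
    k <- canonicalKey(g)
    if (!identical(k, m$key))
      stop(sprintf("stored key of molecule '%s' does not match its structure",
                   m$name), call. = FALSE)
    mols[[k]] <- g; nms[k] <- m$name
  }
  rx <- emptyCrnReactions()
  if (length(doc$reactions)) {
    rx <- data.frame(id = vapply(doc$reactions, `[[`, character(1), "id"),
                     rule = vapply(doc$reactions, `[[`, character(1), "rule"),
                     stringsAsFactors = FALSE)
    rx$educts <- lapply(doc$reactions, function(r) unlist(r$educts))
    rx$products <- lapply(doc$reactions, function(r) unlist(r$products))
  }
  log <- do.call(rbind, lapply(doc$expansionLog, as.data.frame))
  new("CRN", molecules = mols, molNames = nms, reactions = rx,
      inputKeys = unlist(doc$inputKeys), cMax = as.integer(doc$cMax),
      coaMax = as.integer(doc$coaMax), expansionLog = log)
}

#' Export the bipartite molecule/reaction view of a CRN as Graphviz DOT
#'
#' Molecules are ovals, reactions rectangles; arcs run educt -> reaction ->
#' product, with multiplicities as arc labels.
#'
#' @param crn a [CRN-class].
#' @param path output path for the DOT text.
#' @param highlight optional character vector of reaction ids to fill.
#' @return \code{path}, invisibly.
#' @export
exportDOT <- function(crn, path, highlight = character()) {
  esc <- function(s) gsub('"', '\\\\"', s)
  lines <- c("digraph CRN {", "  rankdir=LR;",
             "  node [fontsize=10];")
  for (k in names(crn@molecules))
    lines <- c(lines, sprintf('  "%s" [shape=oval label="%s"];',
                              esc(k), esc(crn@molNames[k])))
  for (i in seq_len(nrow(crn@reactions))) {
    id <- crn@reactions$id[i]
    fill <- if (id %in% highlight) ' style=filled fillcolor="gold"' else ""
    lines <- c(lines, sprintf('  "%s" [shape=box label="%s\\n%s"%s];',
                              id, id, esc(crn@reactions$rule[i]), fill))
    et <- table(crn@reactions$educts[[i]])
    pt <- table(crn@reactions$products[[i]])
    for (k in names(et))
      lines <- c(lines, sprintf('  "%s" -> "%s"%s;', esc(k), id,
        if (et[[k]] > 1L) sprintf(' [label="%d"]', et[[k]]) else ""))
    for (k in names(pt))
      lines <- c(lines, sprintf('  "%s" -> "%s"%s;', id, esc(k),
        if (pt[[k]] > 1L) sprintf(' [label="%d"]', pt[[k]]) else ""))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

# resolve display names or keys to keys
resolveKeys <- function(crn, x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    if (x[i] %in% names(crn@molecules)) { out[i] <- x[i]; next }
    hit <- names(crn@molNames)[crn@molNames == x[i]]
    if (length(hit) != 1L)
      stop(sprintf("molecule '%s' not found in the CRN (or ambiguous)", x[i]),
           call. = FALSE)
    out[i] <- hit
  }
  out
}
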