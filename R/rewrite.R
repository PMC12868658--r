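# Subgraph matching and double-pushout rewriting.
#
# The combined pattern of a rule is L (left-side vertices and edges,
# including the context). A match is an injective map from pattern vertices
# into the disjoint union of the educt molecules that preserves labels
# (wildcard vertices may take any element of their declared class, bound
# independently per vertex), left-side charges, and every left-side edge
# with its bond order (monomorphism: the host may carry extra bonds).
# Each connected pattern component must land inside a single molecule;
# several components may share a molecule instance.

# combined left pattern of a rule
rulePattern <- function(rule) {
  nd <- rule@nodes[rule@nodes$inLeft, , drop = FALSE]
  ed <- rule@edges[!is.na(rule@edges$leftOrder), , drop = FALSE]
  list(nodes = nd, edges = ed)
}

# connected components of the pattern; returns list of integer id vectors
patternComponents <- function(pat) {
  ids <- pat$nodes$id
  if (!length(ids)) return(list())
  parent <- stats::setNames(as.character(ids), as.character(ids))
  root <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(pat$edges))) {
    a <- root(as.character(pat$edges$from[k])); b <- root(as.character(pat$edges$to[k]))
    if (a != b) parent[[a]] <- b
  }
  split(ids, vapply(as.character(ids), root, character(1)))
}

# host disjoint union of educt molecules
buildHost <- function(educts) {
  atoms <- list(); bonds <- list(); offset <- 0L
  for (i in seq_along(educts)) {
    a <- educts[[i]]@atoms; b <- educts[[i]]@bonds
    atoms[[i]] <- data.frame(gid = offset + seq_len(nrow(a)), mol = i,
                             label = a$label, charge = a$charge,
                             stringsAsFactors = FALSE)
    if (nrow(b) > 0L)
      bonds[[i]] <- data.frame(from = offset + match(b$from, a$id),
                               to = offset + match(b$to, a$id),
                               order = b$order, stringsAsFactors = FALSE)
    offset <- offset + nrow(a)
  }
  atoms <- do.call(rbind, atoms)
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(from = integer(), to = integer(), order = character())
  adj <- vector("list", nrow(atoms))
  ordm <- vector("list", nrow(atoms))
  for (k in seq_len(nrow(bonds))) {
    f <- bonds$from[k]; t <- bonds$to[k]; o <- bonds$order[k]
    adj[[f]] <- c(adj[[f]], t); adj[[t]] <- c(adj[[t]], f)
    ordm[[f]] <- c(ordm[[f]], o); ordm[[t]] <- c(ordm[[t]], o)
  }
  list(atoms = atoms, bonds = bonds, adj = adj, ord = ordm)
}

hostBondOrder <- function(host, f, t) {
  hit <- which(host$adj[[f]] == t)
  if (!length(hit)) NA_character_ else host$ord[[f]][hit[1]]
}

labelCompatible <- function(patLabel, wildcards, hostLabel) {
  if (patLabel %in% names(wildcards)) hostLabel %in% wildcards[[patLabel]]
  else patLabel == hostLabel
}

#' Find matches of a rule's pattern in a multiset of educt molecules
#'
#' Enumerates injective, label/charge/bond-preserving embeddings of the
#' rule's left-hand pattern into the disjoint union of \code{educts}. Every
#' educt molecule must be touched by the embedding (supply the exact educt
#' multiset of the reaction instance). By default, matches that induce the
#' same reaction (identical educt and product isomorphism classes) are
#' reported once.
#'
#' @param rule a [ReactionRule-class].
#' @param educts list of [MolGraph-class] educts (the multiset; repeats allowed).
#' @param maxMatches stop after this many distinct matches (default unlimited).
#' @param dedupe collapse matches inducing the same reaction (default TRUE).
#' @return list of match objects: \code{list(mapping, products)} where
#'   \code{mapping} is a named integer vector (pattern vertex id -> host
#'   global vertex index) and \code{products} the list of product MolGraphs
#'   from applying the rule at that match.
#' @export
findMatches <- function(rule, educts, maxMatches = Inf, dedupe = TRUE) {
  pat <- rulePattern(rule)
  if (nrow(pat$nodes) == 0L) return(list())
  host <- buildHost(educts)
  comps <- patternComponents(pat)
  if (length(comps) > 3L)
    stop(sprintf("rule '%s' has %d pattern components; at most 3 educts are supported",
                 rule@name, length(comps)), call. = FALSE)

  # order pattern vertices: component by component, BFS from the rarest label
  labCount <- table(host$atoms$label)
  rarity <- function(lab) {
    if (lab %in% names(rule@wildcards))
      sum(labCount[names(labCount) %in% rule@wildcards[[lab]]])
    else if (lab %in% names(labCount)) labCount[[lab]] else 0L
  }
  patAdj <- function(id) {
    e <- pat$edges
    c(e$to[e$from == id], e$from[e$to == id])
  }
  orderIds <- integer(0)
  for (cp in comps) {
    labs <- pat$nodes$leftLabel[match(cp, pat$nodes$id)]
    start <- cp[which.min(vapply(labs, rarity, numeric(1)))]
    seen <- start; queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- setdiff(intersect(patAdj(v), cp), seen)
      seen <- c(seen, nb); queue <- c(queue, nb)
    }
    orderIds <- c(orderIds, seen)
  }

  nd <- pat$nodes[match(orderIds, pat$nodes$id), , drop = FALSE]
  k <- nrow(nd)
  # precompute, for position i, earlier positions adjacent in the pattern
  prevAdj <- lapply(seq_len(k), function(i) {
    nb <- patAdj(nd$id[i])
    hit <- match(nb, nd$id[seq_len(i - 1L)])
    keep <- !is.na(hit)
    if (!any(keep)) return(NULL)
    data.frame(pos = hit[keep],
               order = vapply(nb[keep], function(b) {
                 e <- pat$edges
                 w <- which((e$from == nd$id[i] & e$to == b) |
                            (e$to == nd$id[i] & e$from == b))
                 e$leftOrder[w[1]]
               }, character(1)))
  })

  matches <- list()
  sigs <- character(0)
  eductSig <- if (dedupe)
    paste(sort(vapply(educts, canonicalKey, character(1))), collapse = "+") else ""
  assign <- integer(k)
  used <- logical(nrow(host$atoms))
  nEduct <- length(educts)

  recurse <- function(i) {
    if (length(matches) >= maxMatches) return()
    if (i > k) {
      if (length(unique(host$atoms$mol[assign])) != nEduct) return()
      mapping <- stats::setNames(assign, as.character(nd$id))
      prods <- applyRuleMapping(rule, mapping, host, onDangling = "skip")
      if (is.null(prods)) return()  # dangling condition failed
      if (dedupe) {
        sig <- paste(
          eductSig,
          paste(sort(vapply(prods, canonicalKey, character(1))), collapse = "+"),
          sep = ">>")
        if (sig %in% sigs) return()
        sigs[[length(sigs) + 1L]] <<- sig
      }
      matches[[length(matches) + 1L]] <<- list(mapping = mapping, products = prods)
      return()
    }
    cand <- if (is.null(prevAdj[[i]])) seq_len(nrow(host$atoms))
            else {
              # vertices adjacent (with right order) to the first anchored neighbor
              p1 <- prevAdj[[i]]$pos[1]
              host$adj[[assign[p1]]]
            }
    for (h in cand) {
      if (used[h]) next
      if (!labelCompatible(nd$leftLabel[i], rule@wildcards, host$atoms$label[h])) next
      if (!is.na(nd$leftCharge[i]) && nd$leftCharge[i] != host$atoms$charge[h]) next
      ok <- TRUE
      pa <- prevAdj[[i]]
      if (!is.null(pa)) {
        for (r in seq_len(nrow(pa))) {
          ho <- hostBondOrder(host, h, assign[pa$pos[r]])
          if (is.na(ho) || ho != pa$order[r]) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assign[i] <<- h; used[h] <<- TRUE
      recurse(i + 1L)
      used[h] <<- FALSE
    }
  }
  recurse(1L)
  matches
}

# Apply a rule at a mapping over a prebuilt host. When the dangling
# condition fails (a deleted vertex still has unmatched host bonds) the
# application errors, or returns NULL with onDangling = "skip" (used during
# match enumeration, where such embeddings are simply not valid matches).
applyRuleMapping <- function(rule, mapping, host, onDangling = "error") {
  nd <- rule@nodes; ed <- rule@edges
  atoms <- host$atoms
  bonds <- host$bonds
  bkey <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))

  hostOf <- function(id) mapping[[as.character(id)]]

  # dangling check: deleted vertices must have all their host bonds matched
  delIds <- nd$id[nd$inLeft & !nd$inRight]
  if (length(delIds)) {
    leftE <- ed[!is.na(ed$leftOrder), , drop = FALSE]
    for (id in delIds) {
      h <- hostOf(id)
      patNb <- c(leftE$to[leftE$from == id], leftE$from[leftE$to == id])
      mappedNb <- vapply(patNb, hostOf, integer(1))
      extra <- setdiff(host$adj[[h]], mappedNb)
      if (length(extra)) {
        if (identical(onDangling, "skip")) return(NULL)
        stop(sprintf(
          "dangling edge: rule '%s' deletes a vertex that retains %d host bond(s)",
          rule@name, length(extra)), call. = FALSE)
      }
    }
  }

  # remove left-only edges and edges changing order; add right-side versions
  drop <- rep(FALSE, nrow(bonds))
  addF <- integer(0); addT <- integer(0); addO <- character(0)
  for (r in seq_len(nrow(ed))) {
    lo <- ed$leftOrder[r]; ro <- ed$rightOrder[r]
    if (!is.na(lo) && !is.na(ro) && lo == ro) next  # context edge
    if (!is.na(lo)) {
      hf <- hostOf(ed$from[r]); ht <- hostOf(ed$to[r])
      drop[bkey == paste(min(hf, ht), max(hf, ht))] <- TRUE
    }
    if (!is.na(ro)) {
      # endpoints may be created vertices, resolved below
      addF <- c(addF, ed$from[r]); addT <- c(addT, ed$to[r]); addO <- c(addO, ro)
    }
  }

  # created vertices
  newIds <- nd$id[!nd$inLeft & nd$inRight]
  nextG <- nrow(atoms)
  for (id in newIds) {
    nextG <- nextG + 1L
    atoms <- rbind(atoms, data.frame(gid = nextG, mol = NA_integer_,
                                     label = nd$rightLabel[match(id, nd$id)],
                                     charge = nd$rightCharge[match(id, nd$id)],
                                     stringsAsFactors = FALSE))
    mapping[[as.character(id)]] <- nextG
  }

  # relabel / recharge retained vertices (wildcard right labels keep the
  # matched host label)
  for (r in which(nd$inLeft & nd$inRight)) {
    h <- hostOf(nd$id[r])
    rl <- nd$rightLabel[r]
    if (!(rl %in% names(rule@wildcards)) && rl != atoms$label[h])
      atoms$label[h] <- rl
    if (!is.na(nd$rightCharge[r])) atoms$charge[h] <- nd$rightCharge[r]
  }

  bonds <- bonds[!drop, , drop = FALSE]
  if (length(addF)) {
    gf <- vapply(addF, hostOf, integer(1))
    gt <- vapply(addT, hostOf, integer(1))
    clash <- paste(pmin(gf, gt), pmax(gf, gt)) %in%
      paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
    if (any(clash)) {
      # adding a bond that already exists would create a parallel edge; such
      # an embedding is not a valid rewrite in the simple-graph category
      if (identical(onDangling, "skip")) return(NULL)
      stop(sprintf("rule '%s' would create a parallel bond at this match",
                   rule@name), call. = FALSE)
    }
    bonds <- rbind(bonds, data.frame(from = gf, to = gt, order = addO,
                                     stringsAsFactors = FALSE))
  }

  # delete left-only vertices
  if (length(delIds)) {
    gdel <- vapply(delIds, hostOf, integer(1))
    atoms <- atoms[!(atoms$gid %in% gdel), , drop = FALSE]
  }

  splitComponents(atoms, bonds)
}

# split an atom/bond table into connected components, one MolGraph each
splitComponents <- function(atoms, bonds) {
  n <- nrow(atoms)
  idx <- stats::setNames(seq_len(n), as.character(atoms$gid))
  parent <- seq_len(n)
  root <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (kk in seq_len(nrow(bonds))) {
    a <- root(idx[[as.character(bonds$from[kk])]])
    b <- root(idx[[as.character(bonds$to[kk])]])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), root, integer(1))
  lapply(unique(comp), function(cc) {
    sel <- comp == cc
    a <- atoms[sel, , drop = FALSE]
    b <- bonds[bonds$from %in% a$gid, , drop = FALSE]
    MolGraph(data.frame(id = a$gid, label = a$label, charge = a$charge),
             b[, c("from", "to", "order")])
  })
}

#' Apply a rule at a previously found match
#'
#' Double-pushout rewriting: left-only edges (and vertices) are removed,
#' context is preserved, right-only edges (and vertices) are added, and
#' right-side labels and charges are applied. The result is split into
#' connected components, one product molecule each. Applications that would
#' delete a vertex still holding unmatched host bonds are rejected with an
#' error (dangling condition), not silently repaired.
#'
#' @param rule a [ReactionRule-class].
#' @param match one element of the list returned by [findMatches()].
#' @param educts the same educt list the match was found in.
#' @return list of product [MolGraph-class] objects.
#' @export
applyRule <- function(rule, match, educts) {
  host <- buildHost(educts)
  applyRuleMapping(rule, match$mapping, host)
}

#' Derive all distinct reactions of a rule over a molecule pool
#'
#' Matches the rule against every multiset of pool molecules up to the
#' number of connected components of its pattern (components may share one
#' molecule instance). Reactions are identified by (educt key multiset,
#' product key multiset, rule name); duplicates collapse.
#'
#' @param rule a [ReactionRule-class].
#' @param pool named list of [MolGraph-class], names being canonical keys
#'   (as in a [CRN-class] molecule table).
#' @return data.frame with columns \code{rule} and list-columns
#'   \code{educts}, \code{products} (sorted key multisets); zero rows when
#'   the rule has no match.
#' @export
deriveReactions <- function(rule, pool) {
  stopifnot(length(pool) > 0L)
  keys <- names(pool)
  ncomp <- length(patternComponents(rulePattern(rule)))
  if (ncomp == 0L) return(emptyReactionTable())

  # cheap prefilter: labels required by non-wildcard pattern vertices
  pat <- rulePattern(rule)
  concrete <- pat$nodes$leftLabel[!(pat$nodes$leftLabel %in% names(rule@wildcards))]
  need <- table(concrete)
  labelTabs <- lapply(pool, function(m) table(m@atoms$label))

  results <- list()
  seen <- character(0)
  addReaction <- function(eductKeys, prods) {
    pkeys <- sort(vapply(prods, canonicalKey, character(1)))
    sig <- paste(paste(sort(eductKeys), collapse = "+"),
                 paste(pkeys, collapse = "+"), sep = ">>")
    if (sig %in% seen) return()
    seen[[length(seen) + 1L]] <<- sig
    results[[length(results) + 1L]] <<- list(
      educts = sort(eductKeys), products = pkeys, productMols = prods)
  }

  combos <- multisetsUpTo(length(pool), ncomp)
  for (cmb in combos) {
    ekeys <- keys[cmb]
    tot <- Reduce(`+`, lapply(labelTabs[cmb], function(tb) {
      v <- rep(0L, length(need)); names(v) <- names(need)
      hit <- intersect(names(tb), names(need)); v[hit] <- tb[hit]; v
    }))
    if (length(need) && any(tot < as.integer(need))) next
    ms <- findMatches(rule, pool[cmb], dedupe = TRUE)
    for (m in ms) addReaction(ekeys, m$products)
  }
  if (!length(results)) return(emptyReactionTable())
  out <- data.frame(rule = rep(rule@name, length(results)), stringsAsFactors = FALSE)
  out$educts <- lapply(results, `[[`, "educts")
  out$products <- lapply(results, `[[`, "products")
  out$productMols <- lapply(results, `[[`, "productMols")
  out
}

emptyReactionTable <- function() {
  out <- data.frame(rule = character(), stringsAsFactors = FALSE)
  out$educts <- list(); out$products <- list(); out$productMols <- list()
  out
}

# all multisets (as sorted index vectors) of sizes 1..maxSize from n items
multisetsUpTo <- function(n, maxSize) {
  out <- list()
  grow <- function(prefix, startAt) {
    for (i in startAt:n) {
      cur <- c(prefix, i)
      out[[length(out) + 1L]] <<- cur
      if (length(cur) < maxSize) grow(cur, i)
    }
  }
  grow(integer(0), 1L)
  out
}
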