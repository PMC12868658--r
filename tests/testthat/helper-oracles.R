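# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's matching/canonicalization code paths: isomorphism is
# decided by enumerating label-consistent vertex bijections, and subgraph
# matches by enumerating all injective vertex maps.

# all label/charge-consistent bijections between two molecules; TRUE when
# one preserves all bonds with orders in both directions
oracleIsomorphic <- function(a, b) {
  A <- a@atoms; B <- b@atoms
  if (nrow(A) != nrow(B)) return(FALSE)
  la <- paste(A$label, A$charge); lb <- paste(B$label, B$charge)
  if (!identical(sort(la), sort(lb))) return(FALSE)
  if (nrow(a@bonds) != nrow(b@bonds)) return(FALSE)
  bondKey <- function(m, idx = NULL) {
    bo <- m@bonds
    f <- bo$from; t <- bo$to
    if (!is.null(idx)) { f <- idx[as.character(f)]; t <- idx[as.character(t)] }
    sort(paste(pmin(f, t), pmax(f, t), bo$order))
  }
  target <- bondKey(b)
  groupsA <- split(A$id, la)
  groupsB <- split(B$id, lb)
  # enumerate per-label permutations, composing a candidate bijection
  labs <- names(groupsA)
  permsOf <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { out[[length(out) + 1L]] <<- prefix; return() }
      for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
    }
    rec(c(), v)
    out
  }
  permSets <- lapply(labs, function(l) permsOf(groupsB[[l]]))
  idxGrid <- do.call(expand.grid, lapply(permSets, seq_along))
  for (r in seq_len(nrow(idxGrid))) {
    map <- character(0)
    for (ci in seq_along(labs)) {
      tgt <- permSets[[ci]][[idxGrid[r, ci]]]
      map[as.character(groupsA[[labs[ci]]])] <- tgt
    }
    mapv <- stats::setNames(as.integer(map), names(map))
    if (identical(bondKey(a, mapv), target)) return(TRUE)
  }
  FALSE
}

# all injective maps of a rule's left pattern into the disjoint union of
# educts that preserve labels (wildcards via the declared class), charges
# and left edges with orders, touch every educt, and do not ask for an
# already-existing bond to be created
oracleMatchMaps <- function(rule, educts) {
  nd <- rule@nodes[rule@nodes$inLeft, , drop = FALSE]
  edAll <- rule@edges
  edL <- edAll[!is.na(edAll$leftOrder), , drop = FALSE]
  # host tables
  atoms <- list(); off <- 0L
  bondSet <- character(0)
  for (i in seq_along(educts)) {
    a <- educts[[i]]@atoms
    atoms[[i]] <- data.frame(g = off + seq_len(nrow(a)), mol = i,
                             label = a$label, charge = a$charge)
    b <- educts[[i]]@bonds
    if (nrow(b)) {
      f <- off + match(b$from, a$id); t <- off + match(b$to, a$id)
      bondSet <- c(bondSet, paste(pmin(f, t), pmax(f, t), b$order))
    }
    off <- off + nrow(a)
  }
  host <- do.call(rbind, atoms)
  bondPlain <- sub(" [^ ]+$", "", bondSet)
  k <- nrow(nd)
  maps <- list()
  rec <- function(i, assign) {
    if (i > k) {
      # all educts touched?
      if (length(unique(host$mol[assign])) != length(educts)) return()
      # created bonds must not already exist
      for (r in seq_len(nrow(edAll))) {
        if (is.na(edAll$leftOrder[r]) && !is.na(edAll$rightOrder[r])) {
          hf <- assign[match(edAll$from[r], nd$id)]
          ht <- assign[match(edAll$to[r], nd$id)]
          if (is.na(hf) || is.na(ht)) next  # endpoint created by the rule
          if (paste(min(hf, ht), max(hf, ht)) %in% bondPlain) return()
        }
      }
      maps[[length(maps) + 1L]] <<- assign
      return()
    }
    for (h in host$g) {
      if (h %in% assign) next
      lab <- nd$leftLabel[i]
      okLab <- if (lab %in% names(rule@wildcards))
        host$label[h] %in% rule@wildcards[[lab]] else host$label[h] == lab
      if (!okLab) next
      if (nd$leftCharge[i] != host$charge[h]) next
      ok <- TRUE
      for (r in seq_len(nrow(edL))) {
        p1 <- match(edL$from[r], nd$id); p2 <- match(edL$to[r], nd$id)
        h1 <- if (p1 == i) h else assign[p1]
        h2 <- if (p2 == i) h else assign[p2]
        if (is.na(h1) || is.na(h2)) next
        if (!(paste(min(h1, h2), max(h1, h2), edL$leftOrder[r]) %in% bondSet)) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign[i] <- h
      rec(i + 1L, assign)
      assign[i] <- NA_integer_
    }
  }
  rec(1L, rep(NA_integer_, k))
  maps
}

# independent one-step expansion count: apply every rule to every educt
# multiset (size <= pattern components) drawn from the pool, collect
# distinct reactions by educt/product key multisets + rule name
oracleExpandOnce <- function(pool, rules) {
  keys <- names(pool)
  n <- length(keys)
  sigs <- character(0)
  prodKeys <- character(0)
  for (rule in rules) {
    ncomp <- length(crnflow:::patternComponents(crnflow:::rulePattern(rule)))
    combos <- list()
    for (i in seq_len(n)) {
      combos[[length(combos) + 1L]] <- i
      if (ncomp >= 2L) for (j in i:n) combos[[length(combos) + 1L]] <- c(i, j)
    }
    for (cmb in combos) {
      maps <- oracleMatchMaps(rule, pool[cmb])
      if (!length(maps)) next
      host <- crnflow:::buildHost(pool[cmb])
      nd <- rule@nodes[rule@nodes$inLeft, , drop = FALSE]
      for (mp in maps) {
        prods <- crnflow:::applyRuleMapping(
          rule, stats::setNames(mp, as.character(nd$id)), host, onDangling = "skip")
        if (is.null(prods)) next
        pk <- sort(vapply(prods, canonicalKey, character(1)))
        sig <- paste(rule@name, paste(sort(keys[cmb]), collapse = "+"),
                     paste(pk, collapse = "+"), sep = "::")
        if (!(sig %in% sigs)) {
          sigs <- c(sigs, sig)
          prodKeys <- unique(c(prodKeys, pk))
        }
      }
    }
  }
  list(nReactions = length(sigs), sigs = sigs,
       newKeys = setdiff(prodKeys, keys))
}

# atom-label multiset of a molecule (CoA counts as its own symbol)
atomMultiset <- function(mol) sort(paste(mol@atoms$label))

randomConnectedMol <- function(n, seed, labels = c("C", "O", "H", "N", "S")) {
  set.seed(seed)
  atoms <- data.frame(id = seq_len(n), label = sample(labels, n, TRUE),
                      charge = sample(c(0L, 0L, 0L, 1L, -1L), n, TRUE))
  # random spanning tree plus a few extra edges
  from <- integer(0); to <- integer(0)
  for (v in 2:n) { from <- c(from, sample(v - 1L, 1L)); to <- c(to, v) }
  extra <- min(n, 3L)
  for (k in seq_len(extra)) {
    cand <- sample(n, 2L)
    key <- paste(pmin(from, to), pmax(from, to))
    if (!(paste(min(cand), max(cand)) %in% key) && cand[1] != cand[2]) {
      from <- c(from, cand[1]); to <- c(to, cand[2])
    }
  }
  bonds <- data.frame(from = from, to = to,
                      order = sample(c("-", "=", "#", ":"), length(from), TRUE,
                                     prob = c(.7, .2, .05, .05)))
  MolGraph(atoms, bonds)
}

permuteMol <- function(mol, seed) {
  set.seed(seed)
  perm <- sample(mol@atoms$id)
  remap <- stats::setNames(perm, mol@atoms$id)
  a <- mol@atoms; a$id <- unname(remap[as.character(a$id)])
  ord <- sample(nrow(a)); a <- a[ord, ]
  b <- mol@bonds
  if (nrow(b)) {
    b$from <- unname(remap[as.character(b$from)])
    b$to <- unname(remap[as.character(b$to)])
  }
  MolGraph(a, b, name = mol@name)
}
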