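# GML-dialect reader/writer for molecules and rules.
#
# The dialect is the subset used for reaction modeling: nested key [ ... ]
# blocks, node records with `id` and `label`, edge records with `source`,
# `target`, `label`; rules as rule [ ruleID "..." left [...] context [...]
# right [...] ] with optional labelclass [ label "X" member "C" ... ]
# wildcard declarations. Atom labels carry the charge as a suffix
# ("O-", "H+", "Fe2+"); bond labels are "-", "=", "#", ":".

gmlTokenize <- function(text) {
  # returns data.frame(token, type, line)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- list()
  pat <- '"[^"]*"|\\[|\\]|[^\\s\\[\\]"]+'
  for (ln in seq_along(lines)) {
    s <- lines[ln]
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    tk <- regmatches(s, list(m))[[1]]
    toks[[length(toks) + 1L]] <- data.frame(token = tk, line = ln)
  }
  if (!length(toks)) return(data.frame(token = character(), line = integer()))
  do.call(rbind, toks)
}

gmlParseError <- function(line, msg) {
  stop(sprintf("GML parse error (line %s): %s", line, msg), call. = FALSE)
}

# Parse token stream into a list of entries list(key=, value=, line=),
# value being a scalar (string/number) or a nested entry list.
gmlParse <- function(text) {
  toks <- gmlTokenize(text)
  pos <- 1L
  n <- nrow(toks)
  parseList <- function(closing) {
    out <- list()
    repeat {
      if (pos > n) {
        if (closing) gmlParseError(toks$line[n], "unexpected end of input, missing ']'")
        return(out)
      }
      tk <- toks$token[pos]
      line <- toks$line[pos]
      if (tk == "]") {
        if (!closing) gmlParseError(line, "unmatched ']'")
        pos <<- pos + 1L
        return(out)
      }
      if (tk == "[") gmlParseError(line, "expected a key before '['")
      key <- tk
      pos <<- pos + 1L
      if (pos > n) gmlParseError(line, sprintf("key '%s' has no value", key))
      vt <- toks$token[pos]
      if (vt == "[") {
        pos <<- pos + 1L
        val <- parseList(TRUE)
      } else if (vt == "]") {
        gmlParseError(line, sprintf("key '%s' has no value", key))
      } else {
        pos <<- pos + 1L
        if (startsWith(vt, '"')) {
          val <- substr(vt, 2L, nchar(vt) - 1L)
        } else if (grepl("^-?[0-9]+$", vt)) {
          val <- as.integer(vt)
        } else if (grepl("^-?[0-9]*\\.[0-9]+$", vt)) {
          val <- as.numeric(vt)
        } else {
          val <- vt
        }
      }
      out[[length(out) + 1L]] <- list(key = key, value = val, line = line)
    }
  }
  parseList(FALSE)
}

gmlEntries <- function(lst, key) lst[vapply(lst, function(e) e$key == key, logical(1))]

gmlScalar <- function(lst, key, line = NA, required = TRUE) {
  hit <- gmlEntries(lst, key)
  if (!length(hit)) {
    if (required) gmlParseError(line, sprintf("missing required field '%s'", key))
    return(NULL)
  }
  hit[[1]]$value
}

# "O-" -> label O charge -1; "Fe2+" -> Fe +2; "CoA" kept verbatim.
parseAtomLabel <- function(s, line = NA) {
  m <- regmatches(s, regexec("^([A-Za-z]+)([0-9]*)([+-]?)$", s))[[1]]
  if (length(m) == 0L || m[2] == "")
    gmlParseError(line, sprintf("malformed atom label '%s'", s))
  mag <- if (m[3] == "") 1L else as.integer(m[3])
  charge <- if (m[4] == "+") mag else if (m[4] == "-") -mag else 0L
  list(label = m[2], charge = charge)
}

formatAtomLabel <- function(label, charge) {
  if (charge == 0L) return(label)
  suff <- if (abs(charge) == 1L) "" else as.character(abs(charge))
  paste0(label, suff, if (charge > 0L) "+" else "-")
}

# parse the node/edge records of one graph-like block into atom/bond tables;
# extraIds: vertex ids declared elsewhere (other sides of a rule) that edges
# of this block may legitimately reference
gmlGraphTables <- function(entries, allowWildcards = FALSE, wildcards = character(),
                           extraIds = integer()) {
  nodes <- gmlEntries(entries, "node")
  edges <- gmlEntries(entries, "edge")
  ids <- integer(0); labels <- character(0); charges <- integer(0)
  for (nd in nodes) {
    if (!is.list(nd$value)) gmlParseError(nd$line, "node must be a [ ... ] record")
    id <- gmlScalar(nd$value, "id", nd$line)
    lab <- gmlScalar(nd$value, "label", nd$line)
    if (lab %in% wildcards || (allowWildcards && !grepl("[0-9+-]", lab) &&
                               !(lab %in% c(PERIODIC_LABELS, "CoA")))) {
      al <- list(label = lab, charge = 0L)
      ch <- gmlScalar(nd$value, "charge", nd$line, required = FALSE)
      if (!is.null(ch)) al$charge <- as.integer(ch)
    } else {
      al <- parseAtomLabel(lab, nd$line)
    }
    ids <- c(ids, as.integer(id)); labels <- c(labels, al$label)
    charges <- c(charges, al$charge)
  }
  from <- integer(0); to <- integer(0); ord <- character(0)
  for (ed in edges) {
    if (!is.list(ed$value)) gmlParseError(ed$line, "edge must be a [ ... ] record")
    s <- as.integer(gmlScalar(ed$value, "source", ed$line))
    t <- as.integer(gmlScalar(ed$value, "target", ed$line))
    o <- gmlScalar(ed$value, "label", ed$line)
    if (!(o %in% BOND_ORDERS))
      gmlParseError(ed$line, sprintf("bond label '%s' not in {-, =, #, :}", o))
    if (!(s %in% c(ids, extraIds)) || !(t %in% c(ids, extraIds)))
      gmlParseError(ed$line, sprintf("edge %d--%d references a missing node id", s, t))
    from <- c(from, s); to <- c(to, t); ord <- c(ord, o)
  }
  list(atoms = data.frame(id = ids, label = labels, charge = charges,
                          stringsAsFactors = FALSE),
       bonds = data.frame(from = from, to = to, order = ord,
                          stringsAsFactors = FALSE))
}

#' Read molecules from GML text
#'
#' Parses one or more \code{graph [ ... ]} blocks, each describing one
#' connected molecule with \code{node [ id label ]} and
#' \code{edge [ source target label ]} records. Charges are written as label
#' suffixes (\code{"O-"}, \code{"H+"}); a \code{name} field supplies the
#' display name.
#'
#' @param text GML text, or a file path when \code{file = TRUE}.
#' @param file interpret \code{text} as a path.
#' @return a [MolGraph-class] (single block) or list of MolGraphs.
#' @examples
#' co2 <- readMoleculeGML('
#'   graph [ name "CO2"
#'     node [ id 0 label "C" ] node [ id 1 label "O" ] node [ id 2 label "O" ]
#'     edge [ source 0 target 1 label "=" ]
#'     edge [ source 0 target 2 label "=" ] ]')
#' countCarbons(co2)
#' @export
readMoleculeGML <- function(text, file = FALSE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  top <- gmlParse(text)
  blocks <- gmlEntries(top, "graph")
  if (!length(blocks))
    stop("no 'graph [ ... ]' block found in GML input", call. = FALSE)
  mols <- lapply(blocks, function(bl) {
    tb <- gmlGraphTables(bl$value)
    nm <- gmlScalar(bl$value, "name", bl$line, required = FALSE)
    MolGraph(tb$atoms, tb$bonds, name = if (is.null(nm)) NA_character_ else nm)
  })
  if (length(mols) == 1L) mols[[1]] else mols
}

#' Write a molecule as GML text
#'
#' Inverse of [readMoleculeGML()] up to vertex renumbering.
#'
#' @param mol a [MolGraph-class].
#' @param con optional connection or path to write to.
#' @return the GML text, invisibly when written to \code{con}.
#' @export
writeMoleculeGML <- function(mol, con = NULL) {
  a <- mol@atoms; b <- mol@bonds
  out <- c("graph [",
           if (!is.na(mol@name)) sprintf('  name "%s"', mol@name),
           vapply(seq_len(nrow(a)), function(i)
             sprintf('  node [ id %d label "%s" ]', a$id[i],
                     formatAtomLabel(a$label[i], a$charge[i])), character(1)),
           vapply(seq_len(nrow(b)), function(i)
             sprintf('  edge [ source %d target %d label "%s" ]',
                     b$from[i], b$to[i], b$order[i]), character(1)),
           "]")
  txt <- paste(out, collapse = "\n")
  if (!is.null(con)) { writeLines(txt, con); return(invisible(txt)) }
  txt
}

#' Read transformation rules from GML text
#'
#' Parses \code{rule [ ruleID "..." left [...] context [...] right [...] ]}
#' blocks. Vertices are identified by \code{id} across the three sides: a
#' vertex in \code{context} is preserved unchanged; a vertex appearing in
#' \code{left} and \code{right} may change label or charge; left-only
#' vertices are deleted and right-only vertices created. Edges follow the
#' same convention. Wildcard labels are declared as
#' \code{labelclass [ label "X" member "C" member "H" ]}.
#'
#' @param text GML text, or a file path when \code{file = TRUE}.
#' @param file interpret \code{text} as a path.
#' @return a [ReactionRule-class] (single block) or list of rules.
#' @export
readRuleGML <- function(text, file = FALSE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  top <- gmlParse(text)
  blocks <- gmlEntries(top, "rule")
  if (!length(blocks))
    stop("no 'rule [ ... ]' block found in GML input", call. = FALSE)
  rules <- lapply(blocks, function(bl) .parseRuleBlock(bl$value, bl$line))
  if (length(rules) == 1L) rules[[1]] else rules
}

.parseRuleBlock <- function(entries, line) {
  name <- gmlScalar(entries, "ruleID", line)
  wc <- list()
  for (lc in gmlEntries(entries, "labelclass")) {
    lab <- gmlScalar(lc$value, "label", lc$line)
    members <- vapply(gmlEntries(lc$value, "member"), function(e) e$value, character(1))
    if (!length(members))
      gmlParseError(lc$line, sprintf("labelclass '%s' declares no members", lab))
    wc[[lab]] <- members
  }
  collectIds <- function(key) {
    hit <- gmlEntries(entries, key)
    if (!length(hit)) return(integer())
    vapply(gmlEntries(hit[[1]]$value, "node"),
           function(nd) as.integer(gmlScalar(nd$value, "id", nd$line)), integer(1))
  }
  allIds <- unique(c(collectIds("left"), collectIds("context"), collectIds("right")))
  side <- function(key) {
    hit <- gmlEntries(entries, key)
    if (!length(hit)) return(list(atoms = data.frame(id = integer(), label = character(),
                                                     charge = integer()),
                                  bonds = data.frame(from = integer(), to = integer(),
                                                     order = character())))
    gmlGraphTables(hit[[1]]$value, allowWildcards = TRUE, wildcards = names(wc),
                   extraIds = allIds)
  }
  L <- side("left"); K <- side("context"); R <- side("right")

  both <- intersect(K$atoms$id, c(L$atoms$id, R$atoms$id))
  if (length(both))
    gmlParseError(line, sprintf(
      "rule '%s': vertex id(s) %s appear in context and in left/right",
      name, paste(both, collapse = ", ")))
  onlyR <- setdiff(R$atoms$id, c(L$atoms$id, K$atoms$id))
  ids <- unique(c(L$atoms$id, K$atoms$id, onlyR))

  pick <- function(tb, id) {
    i <- match(id, tb$atoms$id)
    if (is.na(i)) NULL else tb$atoms[i, ]
  }
  rows <- lapply(ids, function(id) {
    l <- pick(L, id); k <- pick(K, id); r <- pick(R, id)
    if (!is.null(k))
      return(data.frame(id = id, inLeft = TRUE, inRight = TRUE,
                        leftLabel = k$label, rightLabel = k$label,
                        leftCharge = k$charge, rightCharge = k$charge,
                        stringsAsFactors = FALSE))
    data.frame(id = id, inLeft = !is.null(l), inRight = !is.null(r),
               leftLabel = if (is.null(l)) NA_character_ else l$label,
               rightLabel = if (is.null(r)) NA_character_ else r$label,
               leftCharge = if (is.null(l)) NA_integer_ else l$charge,
               rightCharge = if (is.null(r)) NA_integer_ else r$charge,
               stringsAsFactors = FALSE)
  })
  nodes <- do.call(rbind, rows)

  ekey <- function(f, t) paste(pmin(f, t), pmax(f, t))
  eL <- L$bonds; eK <- K$bonds; eR <- R$bonds
  dup <- intersect(ekey(eK$from, eK$to), c(ekey(eL$from, eL$to), ekey(eR$from, eR$to)))
  if (length(dup))
    gmlParseError(line, sprintf("rule '%s': edge(s) %s appear in context and left/right",
                                name, paste(dup, collapse = "; ")))
  allk <- unique(c(ekey(eL$from, eL$to), ekey(eK$from, eK$to), ekey(eR$from, eR$to)))
  edges <- do.call(rbind, lapply(allk, function(k) {
    iL <- match(k, ekey(eL$from, eL$to))
    iK <- match(k, ekey(eK$from, eK$to))
    iR <- match(k, ekey(eR$from, eR$to))
    ft <- as.integer(strsplit(k, " ")[[1]])
    lo <- if (!is.na(iK)) eK$order[iK] else if (!is.na(iL)) eL$order[iL] else NA_character_
    ro <- if (!is.na(iK)) eK$order[iK] else if (!is.na(iR)) eR$order[iR] else NA_character_
    data.frame(from = ft[1], to = ft[2], leftOrder = lo, rightOrder = ro,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(from = integer(), to = integer(),
                        leftOrder = character(), rightOrder = character())
  new("ReactionRule", name = name, nodes = nodes, edges = edges, wildcards = wc)
}

#' Write a rule as GML text
#' @param rule a [ReactionRule-class].
#' @param con optional connection or path.
#' @return GML text.
#' @export
writeRuleGML <- function(rule, con = NULL) {
  nd <- rule@nodes; ed <- rule@edges
  isCtx <- nd$inLeft & nd$inRight &
    nd$leftLabel == nd$rightLabel & nd$leftCharge == nd$rightCharge
  nodeLine <- function(id, lab, ch) {
    shown <- if (lab %in% names(rule@wildcards)) lab else formatAtomLabel(lab, ch)
    sprintf('    node [ id %d label "%s" ]', id, shown)
  }
  ctxE <- .ctxEdge(ed)
  lines <- c("rule [", sprintf('  ruleID "%s"', rule@name))
  for (w in names(rule@wildcards))
    lines <- c(lines, sprintf('  labelclass [ label "%s"%s ]', w,
      paste0(vapply(rule@wildcards[[w]], function(m) sprintf(' member "%s"', m),
                    character(1)), collapse = "")))
  emit <- function(title, nodeRows, labCol, chCol, edgeRows, ordCol) {
    out <- sprintf("  %s [", title)
    for (i in seq_len(nrow(nodeRows)))
      out <- c(out, nodeLine(nodeRows$id[i], nodeRows[[labCol]][i], nodeRows[[chCol]][i]))
    for (i in seq_len(nrow(edgeRows)))
      out <- c(out, sprintf('    edge [ source %d target %d label "%s" ]',
                            edgeRows$from[i], edgeRows$to[i], edgeRows[[ordCol]][i]))
    c(out, "  ]")
  }
  lines <- c(lines,
    emit("left", nd[nd$inLeft & !isCtx, , drop = FALSE], "leftLabel", "leftCharge",
         ed[!is.na(ed$leftOrder) & !ctxE, , drop = FALSE], "leftOrder"),
    emit("context", nd[isCtx, , drop = FALSE], "leftLabel", "leftCharge",
         ed[ctxE, , drop = FALSE], "leftOrder"),
    emit("right", nd[nd$inRight & !isCtx, , drop = FALSE], "rightLabel", "rightCharge",
         ed[!is.na(ed$rightOrder) & !ctxE, , drop = FALSE], "rightOrder"),
    "]")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(con)) { writeLines(txt, con); return(invisible(txt)) }
  txt
}

.ctxEdge <- function(ed) {
  !is.na(ed$leftOrder) & !is.na(ed$rightOrder) & ed$leftOrder == ed$rightOrder
}
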