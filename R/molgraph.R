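#' Construct a molecular graph
#'
#' @param atoms data.frame with columns \code{id}, \code{label} and
#'   optionally \code{charge} (default 0).
#' @param bonds data.frame with columns \code{from}, \code{to},
#'   \code{order}; may be empty for single-atom molecules.
#' @param name optional display name.
#' @return a validated [MolGraph-class].
#' @examples
#' water <- MolGraph(
#'   atoms = data.frame(id = 1:3, label = c("O", "H", "H")),
#'   bonds = data.frame(from = c(1, 1), to = c(2, 3), order = "-"),
#'   name = "water")
#' countCarbons(water)
#' @export
MolGraph <- function(atoms, bonds = NULL, name = NA_character_) {
  if (is.null(atoms$charge)) atoms$charge <- rep(0L, nrow(atoms))
  atoms <- data.frame(id = as.integer(atoms$id), label = as.character(atoms$label),
                      charge = as.integer(atoms$charge), stringsAsFactors = FALSE)
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(from = integer(), to = integer(), order = character(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(from = as.integer(bonds$from), to = as.integer(bonds$to),
                        order = as.character(bonds$order), stringsAsFactors = FALSE)
  }
  new("MolGraph", atoms = atoms, bonds = bonds, name = name)
}

#' @describeIn MolGraph number of atoms.
#' @param x,object a MolGraph.
#' @export
atomCount <- function(x) nrow(x@atoms)

#' @describeIn MolGraph number of bonds.
#' @export
bondCount <- function(x) nrow(x@bonds)

#' @describeIn MolGraph display name (possibly NA).
#' @export
molName <- function(x) x@name

setMethod("show", "MolGraph", function(object) {
  comp <- table(object@atoms$label)
  cat(sprintf("MolGraph %s: %d atoms (%s), %d bonds\n",
              if (is.na(object@name)) "<unnamed>" else sQuote(object@name),
              nrow(object@atoms),
              paste(sprintf("%s%d", names(comp), comp), collapse = " "),
              nrow(object@bonds)))
})

#' Count carbon atoms of a molecule
#'
#' Vertices labeled \code{"C"}; the CoA pseudo-atom contributes zero even
#' though Coenzyme A contains carbons, mirroring the expansion restriction
#' that exempts the covalently bound cofactor from the 6-carbon limit.
#'
#' @param mol a [MolGraph-class].
#' @return nonnegative integer.
#' @export
countCarbons <- function(mol) sum(mol@atoms$label == "C")

#' Count CoA pseudo-atoms of a molecule
#'
#' @param mol a [MolGraph-class].
#' @return nonnegative integer; the expansion filter rejects molecules where
#'   this exceeds the CRN's \code{coaMax} (default 1).
#' @export
countCoA <- function(mol) sum(mol@atoms$label == "CoA")

# igraph view of a molecule; bond orders become edge attribute "order"
molToIgraph <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol@atoms), directed = FALSE)
  igraph::V(g)$label <- mol@atoms$label
  igraph::V(g)$charge <- mol@atoms$charge
  if (nrow(mol@bonds) > 0L) {
    idx <- match(c(rbind(mol@bonds$from, mol@bonds$to)), mol@atoms$id)
    g <- igraph::add_edges(g, idx)
    igraph::E(g)$order <- mol@bonds$order
  }
  g
}

#' Canonical key of a molecule
#'
#' An opaque string equal for two molecules if and only if they are
#' isomorphic respecting atom labels, formal charges and bond orders. Bond
#' orders are encoded by subdividing every bond with an auxiliary vertex
#' colored by the order, and a canonical vertex ordering of the resulting
#' vertex-colored graph is computed with igraph's BLISS backend; the key is
#' the serialization of the canonically ordered graph together with the
#' label legend.
#'
#' @param mol a [MolGraph-class].
#' @return character scalar key.
#' @examples
#' w1 <- MolGraph(data.frame(id = 1:3, label = c("O", "H", "H")),
#'                data.frame(from = c(1, 1), to = c(2, 3), order = "-"))
#' w2 <- MolGraph(data.frame(id = 1:3, label = c("H", "O", "H")),
#'                data.frame(from = c(2, 2), to = c(1, 3), order = "-"))
#' identical(canonicalKey(w1), canonicalKey(w2))
#' @export
canonicalKey <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  n <- nrow(a); m <- nrow(b)
  vlab <- paste0(a$label, "#", a$charge)
  vLegend <- sort(unique(vlab))
  if (m == 0L) {
    # single atom (n == 1 for valid molecules)
    return(paste0("K1|", vlab[1]))
  }
  oLegend <- sort(unique(b$order))
  colors <- c(match(vlab, vLegend) - 1L,
              length(vLegend) + match(b$order, oLegend) - 1L)
  g <- igraph::make_empty_graph(n = n + m, directed = FALSE)
  bi <- match(b$from, a$id); bj <- match(b$to, a$id)
  ev <- integer(0)
  for (k in seq_len(m)) ev <- c(ev, n + k, bi[k], n + k, bj[k])
  g <- igraph::add_edges(g, ev)
  cp <- igraph::canonical_permutation(g, colors = colors)$labeling
  # position of original vertices in canonical order
  atomRank <- cp[seq_len(n)]
  ord <- order(atomRank)
  canonLab <- vlab[ord]
  pos <- integer(n); pos[ord] <- seq_len(n)
  ef <- pos[bi]; et <- pos[bj]
  edges <- sprintf("%d-%d:%s", pmin(ef, et), pmax(ef, et), b$order)
  edges <- sort(edges)
  paste0("K", n, "|", paste(canonLab, collapse = ","), "|",
         paste(edges, collapse = ";"))
}

#' Test label/charge/bond-preserving isomorphism of two molecules
#'
#' Convenience wrapper comparing canonical keys.
#' @param a,b [MolGraph-class] objects.
#' @return logical.
#' @export
isIsomorphic <- function(a, b) identical(canonicalKey(a), canonicalKey(b))
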