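# Synthetic fixtures: a toy chemistry with a planted autocatalytic cycle,
# and random hypernetworks for stress-testing the flow solver.

#' Build the synthetic toy chemistry
#'
#' A small abstract chemistry over the real atom alphabet (C, O, H, N, S plus
#' the CoA pseudo-atom) that emulates the structure of a carbon-fixation
#' space: an autocatalytic seed molecule (the "replicator", one carbon with
#' thiol-type and amine-type handles), a one-carbon fixable species (CO2),
#' cofactor-like helper pairs (a dithiol/disulfide redox couple, a thiyl
#' donor playing the energy-carrier role), and nine directed transformation
#' rules. Four of the rules form the planted autocatalytic cycle
#'
#' \preformatted{ carboxylation:       replicator + CO2            -> carboxy-replicator
#'  carboxyl_reduction:  carboxy-replicator + dithiol -> formyl-replicator + water + disulfide
#'  amination:           formyl-replicator + ammonia  -> amino-replicator + water
#'  thiolytic_cleavage:  amino-replicator + thiyl     -> 2 replicator }
#'
#' whose net reaction fixes one carbon unit and nets one replicator; the
#' remaining rules are decoys (a reverse decarboxylation, a promiscuous
#' wildcard hydrogenation, an amine alkylation whose context varies with
#' \code{seed}, CoA thioesterification, and a charge-changing carboxyl
#' deprotonation). All rules conserve atoms. The pathway intermediates are
#' part of the input pool, mirroring how carbon-fixation spaces are seeded
#' with known pathway intermediates plus helpers.
#'
#' @param seed integer; fixes the decoy-rule context variant and the vertex
#'   numbering of the input molecules. The planted cycle is identical for
#'   every seed.
#' @return object of class \code{ToyChemistry}: list with \code{molecules}
#'   (named list of [MolGraph-class]), \code{rules} (list of
#'   [ReactionRule-class]), \code{knownOptimum} (planted shortest support:
#'   rule names, step count), \code{config} (autocatalyst, sources, sinks,
#'   cofactor classification), and \code{energyTable} (toy formation
#'   energies, kJ/mol).
#' @export
makeToyChemistry <- function(seed = 0L) {
  seed <- as.integer(seed)
  molGml <- c(
    replicator = '
      graph [ name "replicator"
        node [ id 1 label "C" ] node [ id 2 label "S" ] node [ id 3 label "N" ]
        node [ id 4 label "H" ] node [ id 5 label "H" ]
        edge [ source 1 target 2 label "-" ] edge [ source 1 target 3 label "-" ]
        edge [ source 1 target 4 label "-" ] edge [ source 3 target 5 label "-" ] ]',
    `carboxy-replicator` = '
      graph [ name "carboxy-replicator"
        node [ id 1 label "C" ] node [ id 2 label "S" ] node [ id 3 label "N" ]
        node [ id 4 label "H" ] node [ id 5 label "C" ] node [ id 6 label "O" ]
        node [ id 7 label "O" ] node [ id 8 label "H" ]
        edge [ source 1 target 2 label "-" ] edge [ source 1 target 3 label "-" ]
        edge [ source 3 target 4 label "-" ] edge [ source 1 target 5 label "-" ]
        edge [ source 5 target 6 label "=" ] edge [ source 5 target 7 label "-" ]
        edge [ source 7 target 8 label "-" ] ]',
    `formyl-replicator` = '
      graph [ name "formyl-replicator"
        node [ id 1 label "C" ] node [ id 2 label "S" ] node [ id 3 label "N" ]
        node [ id 4 label "H" ] node [ id 5 label "C" ] node [ id 6 label "O" ]
        node [ id 7 label "H" ]
        edge [ source 1 target 2 label "-" ] edge [ source 1 target 3 label "-" ]
        edge [ source 3 target 4 label "-" ] edge [ source 1 target 5 label "-" ]
        edge [ source 5 target 6 label "=" ] edge [ source 5 target 7 label "-" ] ]',
    `amino-replicator` = '
      graph [ name "amino-replicator"
        node [ id 1 label "C" ] node [ id 2 label "S" ] node [ id 3 label "N" ]
        node [ id 4 label "H" ] node [ id 5 label "C" ] node [ id 6 label "H" ]
        node [ id 7 label "N" ] node [ id 8 label "H" ]
        edge [ source 1 target 2 label "-" ] edge [ source 1 target 3 label "-" ]
        edge [ source 3 target 4 label "-" ] edge [ source 1 target 5 label "-" ]
        edge [ source 5 target 6 label "-" ] edge [ source 5 target 7 label "-" ]
        edge [ source 7 target 8 label "-" ] ]',
    CO2 = '
      graph [ name "CO2"
        node [ id 1 label "C" ] node [ id 2 label "O" ] node [ id 3 label "O" ]
        edge [ source 1 target 2 label "=" ] edge [ source 1 target 3 label "=" ] ]',
    dithiol = '
      graph [ name "dithiol"
        node [ id 1 label "H" ] node [ id 2 label "S" ] node [ id 3 label "S" ]
        node [ id 4 label "H" ]
        edge [ source 1 target 2 label "-" ] edge [ source 2 target 3 label "-" ]
        edge [ source 3 target 4 label "-" ] ]',
    disulfide = '
      graph [ name "disulfide"
        node [ id 1 label "S" ] node [ id 2 label "S" ]
        edge [ source 1 target 2 label "=" ] ]',
    ammonia = '
      graph [ name "ammonia"
        node [ id 1 label "N" ] node [ id 2 label "H" ] node [ id 3 label "H" ]
        node [ id 4 label "H" ]
        edge [ source 1 target 2 label "-" ] edge [ source 1 target 3 label "-" ]
        edge [ source 1 target 4 label "-" ] ]',
    thiyl = '
      graph [ name "thiyl"
        node [ id 1 label "S" ] node [ id 2 label "H" ]
        edge [ source 1 target 2 label "-" ] ]',
    water = '
      graph [ name "water"
        node [ id 1 label "O" ] node [ id 2 label "H" ] node [ id 3 label "H" ]
        edge [ source 1 target 2 label "-" ] edge [ source 1 target 3 label "-" ] ]',
    proton = '
      graph [ name "proton" node [ id 1 label "H+" ] ]',
    `coa-thiol` = '
      graph [ name "coa-thiol"
        node [ id 1 label "CoA" ] node [ id 2 label "S" ] node [ id 3 label "H" ]
        edge [ source 1 target 2 label "-" ] edge [ source 2 target 3 label "-" ] ]')

  variant <- c("S", "N", "O")[(seed %% 3L) + 1L]
  ruleGml <- c(
    carboxylation = '
      rule [ ruleID "carboxylation"
        left [
          edge [ source 1 target 2 label "-" ]
          edge [ source 3 target 4 label "=" ] ]
        context [
          node [ id 1 label "C" ] node [ id 2 label "H" ] node [ id 3 label "C" ]
          node [ id 4 label "O" ] node [ id 5 label "O" ] node [ id 6 label "S" ]
          node [ id 7 label "N" ]
          edge [ source 3 target 5 label "=" ]
          edge [ source 1 target 6 label "-" ]
          edge [ source 1 target 7 label "-" ] ]
        right [
          edge [ source 1 target 3 label "-" ]
          edge [ source 3 target 4 label "-" ]
          edge [ source 4 target 2 label "-" ] ] ]',
    carboxyl_reduction = '
      rule [ ruleID "carboxyl_reduction"
        left [
          edge [ source 1 target 2 label "-" ]
          edge [ source 5 target 6 label "-" ]
          edge [ source 7 target 8 label "-" ]
          edge [ source 5 target 7 label "-" ] ]
        context [
          node [ id 1 label "C" ] node [ id 2 label "O" ] node [ id 3 label "H" ]
          node [ id 4 label "O" ] node [ id 5 label "S" ] node [ id 6 label "H" ]
          node [ id 7 label "S" ] node [ id 8 label "H" ]
          edge [ source 2 target 3 label "-" ]
          edge [ source 1 target 4 label "=" ] ]
        right [
          edge [ source 1 target 6 label "-" ]
          edge [ source 2 target 8 label "-" ]
          edge [ source 5 target 7 label "=" ] ] ]',
    amination = '
      rule [ ruleID "amination"
        left [
          edge [ source 1 target 2 label "=" ]
          edge [ source 3 target 4 label "-" ]
          edge [ source 3 target 5 label "-" ] ]
        context [
          node [ id 1 label "C" ] node [ id 2 label "O" ] node [ id 3 label "N" ]
          node [ id 4 label "H" ] node [ id 5 label "H" ] node [ id 6 label "H" ]
          node [ id 7 label "H" ]
          edge [ source 3 target 6 label "-" ]
          edge [ source 1 target 7 label "-" ] ]
        right [
          edge [ source 1 target 3 label "-" ]
          edge [ source 2 target 4 label "-" ]
          edge [ source 2 target 5 label "-" ] ] ]',
    thiolytic_cleavage = '
      rule [ ruleID "thiolytic_cleavage"
        left [
          edge [ source 1 target 2 label "-" ]
          edge [ source 3 target 4 label "-" ] ]
        context [
          node [ id 1 label "C" ] node [ id 2 label "C" ] node [ id 3 label "S" ]
          node [ id 4 label "H" ] node [ id 5 label "S" ] node [ id 6 label "N" ]
          node [ id 7 label "N" ]
          edge [ source 1 target 5 label "-" ]
          edge [ source 1 target 6 label "-" ]
          edge [ source 2 target 7 label "-" ] ]
        right [
          edge [ source 1 target 4 label "-" ]
          edge [ source 2 target 3 label "-" ] ] ]',
    decarboxylation = '
      rule [ ruleID "decarboxylation"
        left [
          edge [ source 1 target 3 label "-" ]
          edge [ source 3 target 4 label "-" ]
          edge [ source 4 target 2 label "-" ] ]
        context [
          node [ id 1 label "C" ] node [ id 2 label "H" ] node [ id 3 label "C" ]
          node [ id 4 label "O" ] node [ id 5 label "O" ]
          edge [ source 3 target 5 label "=" ] ]
        right [
          edge [ source 1 target 2 label "-" ]
          edge [ source 3 target 4 label "=" ] ] ]',
    hydrogenation = '
      rule [ ruleID "hydrogenation"
        labelclass [ label "X" member "C" member "O" ]
        left [
          edge [ source 1 target 2 label "=" ]
          edge [ source 3 target 4 label "-" ]
          edge [ source 5 target 6 label "-" ]
          edge [ source 3 target 5 label "-" ] ]
        context [
          node [ id 1 label "C" ] node [ id 2 label "X" ] node [ id 3 label "S" ]
          node [ id 4 label "H" ] node [ id 5 label "S" ] node [ id 6 label "H" ]
          node [ id 7 label "H" ]
          edge [ source 1 target 7 label "-" ] ]
        right [
          edge [ source 1 target 2 label "-" ]
          edge [ source 1 target 4 label "-" ]
          edge [ source 2 target 6 label "-" ]
          edge [ source 3 target 5 label "=" ] ] ]',
    amine_alkylation = sprintf('
      rule [ ruleID "amine_alkylation"
        left [
          edge [ source 1 target 2 label "-" ]
          edge [ source 3 target 4 label "-" ] ]
        context [
          node [ id 1 label "N" ] node [ id 2 label "H" ] node [ id 3 label "C" ]
          node [ id 4 label "H" ] node [ id 5 label "%s" ] node [ id 6 label "H" ]
          edge [ source 1 target 6 label "-" ]
          edge [ source 3 target 5 label "-" ] ]
        right [
          edge [ source 1 target 3 label "-" ]
          edge [ source 2 target 4 label "-" ] ] ]', variant),
    coa_thioesterification = '
      rule [ ruleID "coa_thioesterification"
        left [
          edge [ source 1 target 2 label "-" ]
          edge [ source 3 target 4 label "-" ] ]
        context [
          node [ id 1 label "S" ] node [ id 2 label "H" ] node [ id 3 label "C" ]
          node [ id 4 label "H" ] node [ id 5 label "CoA" ] node [ id 6 label "N" ]
          edge [ source 1 target 5 label "-" ]
          edge [ source 3 target 6 label "-" ] ]
        right [
          edge [ source 1 target 3 label "-" ]
          edge [ source 2 target 4 label "-" ] ] ]',
    carboxyl_deprotonation = '
      rule [ ruleID "carboxyl_deprotonation"
        left [
          node [ id 1 label "O" ] node [ id 2 label "H" ]
          edge [ source 1 target 2 label "-" ] ]
        context [
          node [ id 3 label "C" ] node [ id 4 label "O" ]
          edge [ source 1 target 3 label "-" ]
          edge [ source 3 target 4 label "=" ] ]
        right [
          node [ id 1 label "O-" ] node [ id 2 label "H+" ] ] ]')

  molecules <- lapply(molGml, readMoleculeGML)
  # seed-dependent relabeling of vertex ids: canonical keys must not care
  set.seed(seed)
  molecules <- lapply(molecules, function(m) {
    perm <- sample(m@atoms$id)
    remap <- stats::setNames(perm, m@atoms$id)
    a <- m@atoms; a$id <- unname(remap[as.character(a$id)])
    b <- m@bonds
    if (nrow(b)) {
      b$from <- unname(remap[as.character(b$from)])
      b$to <- unname(remap[as.character(b$to)])
    }
    MolGraph(a, b, name = m@name)
  })
  rules <- lapply(ruleGml, readRuleGML)

  config <- list(
    autocatalyst = "replicator",
    sources = c("replicator", "CO2", "dithiol", "ammonia", "thiyl", "coa-thiol"),
    sinks = c("replicator", "water", "disulfide", "proton", "coa-thiol"),
    atp_species = "thiyl",
    redox_reduced_species = "dithiol",
    carbon_species = "CO2")

  energyTable <- data.frame(
    compound = c("replicator", "CO2", "dithiol", "disulfide", "ammonia",
                 "thiyl", "water", "proton", "coa-thiol",
                 "carboxy-replicator", "formyl-replicator", "amino-replicator"),
    dfG_prime_kJ_per_mol = c(-30, -394, 100, -10, -16,
                             50, -237, 0, -50,
                             -420, -150, -90),
    source = "toy",
    stringsAsFactors = FALSE)

  structure(list(
    molecules = molecules,
    rules = rules,
    knownOptimum = list(
      steps = 4L,
      supportRules = c("carboxylation", "carboxyl_reduction", "amination",
                       "thiolytic_cleavage")),
    config = config,
    energyTable = energyTable,
    seed = seed), class = "ToyChemistry")
}

#' @export
print.ToyChemistry <- function(x, ...) {
  cat(sprintf("ToyChemistry (seed %d): %d molecules, %d rules; planted cycle of %d steps\n",
              x$seed, length(x$molecules), length(x$rules), x$knownOptimum$steps))
  invisible(x)
}

#' Write the toy chemistry to disk as GML/TSV/JSON files
#'
#' Produces \code{molecules/*.gml}, \code{rules/*.gml},
#' \code{toy_energy.tsv}, \code{cofactors.json} and an
#' \code{expected_optimum.json} manifest, mirroring the on-disk layout the
#' loaders in this package consume.
#'
#' @param toy result of [makeToyChemistry()].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeToyChemistry <- function(toy, dir) {
  mdir <- file.path(dir, "molecules"); rdir <- file.path(dir, "rules")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  for (m in toy$molecules)
    writeMoleculeGML(m, file.path(mdir, paste0(gsub("[^A-Za-z0-9_-]", "_", m@name), ".gml")))
  for (r in toy$rules)
    writeRuleGML(r, file.path(rdir, paste0(r@name, ".gml")))
  utils::write.table(toy$energyTable, file.path(dir, "toy_energy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(toy$config, file.path(dir, "cofactors.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(toy$knownOptimum, file.path(dir, "expected_optimum.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Generate a random hypernetwork CRN with an optional planted cycle
#'
#' Vertices are opaque marker molecules (hydrogen stars around a nitrogen
#' core, so they carry no carbon and are trivially distinct isomorphism
#' classes); reactions are random educt/product multisets. With
#' \code{planted = TRUE} an autocatalytic route
#' \code{A + F -> I1 -> ... -> 2 A} of \code{cycleLength} reactions is
#' embedded, guaranteeing feasibility of the standard autocatalysis query
#' (autocatalyst \code{A}, source \code{F}).
#'
#' @param nMolecules number of molecule vertices (>= cycleLength + 2).
#' @param nReactions total number of reactions including planted ones.
#' @param seed RNG seed; fixed seed gives an identical CRN.
#' @param planted embed the feasible autocatalytic route.
#' @param cycleLength length of the planted route (default 4).
#' @return list with \code{crn}, \code{autocatalyst}, \code{source} and
#'   \code{plantedIds} (reaction ids of the planted route, when any).
#' @export
makeRandomHypernetwork <- function(nMolecules, nReactions, seed = 1L,
                                   planted = TRUE, cycleLength = 4L) {
  stopifnot(nMolecules >= cycleLength + 2L)
  set.seed(seed)
  mols <- lapply(seq_len(nMolecules), function(i) {
    atoms <- data.frame(id = seq_len(i + 1L), label = c("N", rep("H", i)))
    bonds <- data.frame(from = 1L, to = seq_len(i) + 1L, order = "-")
    MolGraph(atoms, bonds, name = sprintf("v%02d", i))
  })
  crn <- initCRN(mols)
  keys <- names(crn@molecules)
  nm <- crn@molNames
  keyOf <- function(name) names(nm)[nm == name]
  A <- keyOf("v01"); F1 <- keyOf("v02")
  inter <- vapply(sprintf("v%02d", 2L + seq_len(cycleLength - 1L)), keyOf, character(1))
  rxns <- list()
  if (planted) {
    chain <- c(list(list(rule = "plant_init", educts = c(A, F1),
                         products = inter[1]))
               , if (cycleLength > 2L) lapply(seq_len(cycleLength - 2L), function(j)
                   list(rule = sprintf("plant_mid%d", j),
                        educts = inter[j], products = inter[j + 1L])))
    chain[[length(chain) + 1L]] <- list(rule = "plant_close",
                                        educts = inter[cycleLength - 1L],
                                        products = c(A, A))
    rxns <- chain
  }
  nDecoy <- nReactions - length(rxns)
  tries <- 0L
  while (nDecoy > 0L && tries < 50L * nReactions) {
    tries <- tries + 1L
    ne <- sample(1:2, 1L); np <- sample(1:2, 1L)
    ed <- sample(keys, ne, replace = TRUE)
    pr <- sample(keys, np, replace = TRUE)
    if (identical(sort(ed), sort(pr))) next
    before <- nrow(crn@reactions)
    crn <- addReactionsRaw(crn, list(list(rule = sprintf("decoy%03d", tries),
                                          educts = ed, products = pr)))
    if (nrow(crn@reactions) > before) nDecoy <- nDecoy - 1L
  }
  if (length(rxns)) crn <- addReactionsRaw(crn, rxns)
  plantedIds <- if (planted) {
    sig <- crn@reactions$rule
    crn@reactions$id[grepl("^plant_", sig)]
  } else character(0)
  list(crn = crn, autocatalyst = A, source = F1, plantedIds = plantedIds)
}

#' Load a transcribed study space from GML files
#'
#' Reads a directory of rule GML files and a directory of molecule GML
#' files, as transcribed from a published supplementary rule set (this
#' package ships only the synthetic toy chemistry; a real carbon-fixation
#' space must be transcribed into this layout by the user).
#'
#' @param rulesDir directory of \code{*.gml} rule files.
#' @param moleculesDir directory of \code{*.gml} molecule files.
#' @param strict stop on the first malformed file (default); otherwise skip
#'   malformed files with a warning naming each one.
#' @return \code{list(rules =, molecules =)} with parse counts reported via
#'   message.
#' @export
loadStudySpace <- function(rulesDir, moleculesDir, strict = TRUE) {
  readDir <- function(dir, reader, what) {
    if (!dir.exists(dir))
      stop(sprintf("%s directory '%s' does not exist", what, dir), call. = FALSE)
    files <- sort(list.files(dir, pattern = "\\.gml$", full.names = TRUE))
    if (!length(files))
      stop(sprintf("no .gml files in %s directory '%s'", what, dir), call. = FALSE)
    out <- list()
    for (f in files) {
      res <- tryCatch(reader(f, file = TRUE), error = function(e) e)
      if (inherits(res, "error")) {
        msg <- sprintf("failed to parse %s file '%s': %s", what, basename(f),
                       conditionMessage(res))
        if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      } else {
        if (is.list(res) && !isS4(res)) out <- c(out, res)
        else out[[length(out) + 1L]] <- res
      }
    }
    out
  }
  mols <- readDir(moleculesDir, readMoleculeGML, "molecule")
  rules <- readDir(rulesDir, readRuleGML, "rule")
  message(sprintf("loaded %d molecules and %d rules", length(mols), length(rules)))
  list(rules = rules, molecules = mols)
}
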