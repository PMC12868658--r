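# Post-annotation of flow solutions: net reaction, standard transformed
# Gibbs reaction energy, cofactor accounting and carbon-fixation metrics.

#' Read a formation-energy table
#'
#' Tab-separated with header
#' \code{compound  dfG_prime_kJ_per_mol  source}; energies are standard
#' transformed Gibbs energies of formation at the stated condition
#' (pH 7, ionic strength 0.1 M unless overridden).
#'
#' @param path TSV file path.
#' @param pH,ionicStrength condition metadata stored with the table.
#' @return data.frame with attributes \code{pH}, \code{ionicStrength}.
#' @export
readEnergyTable <- function(path, pH = 7, ionicStrength = 0.1) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("compound", "dfG_prime_kJ_per_mol")
  if (!all(needed %in% names(tab)))
    stop("energy table must have columns 'compound' and 'dfG_prime_kJ_per_mol'",
         call. = FALSE)
  if (any(!is.finite(tab$dfG_prime_kJ_per_mol)))
    stop("energy table contains non-finite formation energies", call. = FALSE)
  attr(tab, "pH") <- pH
  attr(tab, "ionicStrength") <- ionicStrength
  tab
}

#' Read a cofactor configuration
#'
#' JSON or YAML with fields \code{atp_species} (energy carriers whose
#' inflow is counted as ATP units), \code{redox_reduced_species} (reduced
#' redox carriers whose inflow is counted as redox units) and
#' \code{carbon_species} (the inorganic carbon sources, e.g. CO2 and
#' bicarbonate). Species are molecule display names.
#'
#' @param path file path (.json, .yml or .yaml).
#' @return named list.
#' @export
readCofactorConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("atp_species", "redox_reduced_species", "carbon_species"))
    if (is.null(cfg[[f]])) cfg[[f]] <- character()
  cfg
}

#' Net reaction of a flow solution
#'
#' The stoichiometric educt and product multisets of the pathway as a whole:
#' its inflow and outflow (zero entries dropped). All internal molecules
#' balance to zero by flow conservation.
#'
#' @param sol a [FlowSolution-class].
#' @return \code{list(educts =, products =)}, named numeric vectors keyed by
#'   molecule display name.
#' @export
netReaction <- function(sol) {
  list(educts = sol@inflow[sol@inflow != 0L],
       products = sol@outflow[sol@outflow != 0L])
}

#' Standard transformed Gibbs energy of a net reaction
#'
#' \eqn{\Delta_r G'^\circ = \sum \Delta_f G'^\circ(\mathrm{products})
#' - \sum \Delta_f G'^\circ(\mathrm{reactants})}, stoichiometry-weighted.
#' Every species of the net reaction must have a table entry; missing
#' entries raise an error listing the absent compounds rather than
#' defaulting to zero.
#'
#' @param net \code{list(educts =, products =)} named numeric vectors, as
#'   from [netReaction()].
#' @param table energy table from [readEnergyTable()] (or any data.frame
#'   with \code{compound} and \code{dfG_prime_kJ_per_mol}).
#' @return numeric, kJ/mol.
#' @export
reactionEnergy <- function(net, table) {
  species <- c(names(net$educts), names(net$products))
  missing <- setdiff(unique(species), table$compound)
  if (length(missing))
    stop(sprintf("no formation energy for compound(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  g <- stats::setNames(table$dfG_prime_kJ_per_mol, table$compound)
  sum(net$products * g[names(net$products)]) -
    sum(net$educts * g[names(net$educts)])
}

#' Count cofactor usage of a flow solution
#'
#' ATP units are the inflow of the configured energy-carrier species
#' (counted on consumption, regardless of the discharged form returned);
#' redox units are the total inflow of the configured reduced redox
#' carriers.
#'
#' @param sol a [FlowSolution-class].
#' @param config cofactor configuration (see [readCofactorConfig()]).
#' @return \code{list(atpUnits =, redoxUnits =, total =)} (integers).
#' @export
countCofactors <- function(sol, config) {
  inf <- sol@inflow
  atp <- sum(inf[names(inf) %in% config$atp_species])
  redox <- sum(inf[names(inf) %in% config$redox_reduced_species])
  list(atpUnits = as.integer(atp), redoxUnits = as.integer(redox),
       total = as.integer(atp + redox))
}

#' Carbon units fixed by a flow solution
#'
#' Total inflow of the configured inorganic carbon species (CO2 and
#' bicarbonate in the carbon-fixation setting) per completed cycle.
#'
#' @inheritParams countCofactors
#' @return integer.
#' @export
carbonUnitsFixed <- function(sol, config) {
  as.integer(sum(sol@inflow[names(sol@inflow) %in% config$carbon_species]))
}

#' Annotate a flow solution
#'
#' Combines the net reaction, the reaction energy (when a table is given),
#' cofactor counts, carbon units fixed and the per-carbon / per-step
#' normalizations used to compare carbon-fixation pathways.
#'
#' @param sol a [FlowSolution-class].
#' @param config cofactor configuration (see [readCofactorConfig()]).
#' @param energyTable optional energy table; without it \code{deltaG} is NA.
#' @return an [Annotation-class].
#' @export
annotateSolution <- function(sol, config, energyTable = NULL) {
  net <- netReaction(sol)
  cf <- countCofactors(sol, config)
  cu <- carbonUnitsFixed(sol, config)
  dg <- if (is.null(energyTable)) NA_real_ else reactionEnergy(net, energyTable)
  ratio <- function(x) if (cu > 0L) x / cu else NA_real_
  new("Annotation",
      netEducts = net$educts, netProducts = net$products, deltaG = dg,
      atpUnits = cf$atpUnits, redoxUnits = cf$redoxUnits,
      cofactorsTotal = cf$total, carbonUnits = cu, steps = sol@steps,
      atpPerCarbon = ratio(cf$atpUnits),
      cofactorsPerCarbon = ratio(cf$total),
      cofactorsPerStep = cf$total / sol@steps)
}

setMethod("show", "Annotation", function(object) {
  fmt <- function(v) paste(sprintf("%s:%g", names(v), v), collapse = " + ")
  cat("Annotation\n")
  cat("  net: ", fmt(object@netEducts), " -> ", fmt(object@netProducts), "\n", sep = "")
  cat(sprintf("  steps %d | ATP %d | redox %d | cofactors %d | carbons %d\n",
              object@steps, object@atpUnits, object@redoxUnits,
              object@cofactorsTotal, object@carbonUnits))
  cat(sprintf("  ATP/C %.3g | cofactors/C %.3g | cofactors/step %.3g | drG' %.5g kJ/mol\n",
              object@atpPerCarbon, object@cofactorsPerCarbon,
              object@cofactorsPerStep, object@deltaG))
})

#' Summary statistics over a pool of flow solutions
#'
#' Mean pathway length, mean cofactor usage, the cofactor-per-step ratio
#' (mean cofactors divided by mean steps) and mean reaction energy across
#' all supplied solutions, together with the per-solution annotation table.
#'
#' @param solutions list of [FlowSolution-class].
#' @param config cofactor configuration.
#' @param energyTable optional energy table.
#' @return \code{list(summary =, perSolution =)}: a one-row data.frame of
#'   the means and the per-solution data.frame.
#' @export
summarizeSolutions <- function(solutions, config, energyTable = NULL) {
  stopifnot(length(solutions) >= 1L)
  anns <- lapply(solutions, annotateSolution, config = config,
                 energyTable = energyTable)
  per <- data.frame(
    solution = seq_along(anns),
    steps = vapply(anns, function(a) a@steps, integer(1)),
    atpUnits = vapply(anns, function(a) a@atpUnits, integer(1)),
    redoxUnits = vapply(anns, function(a) a@redoxUnits, integer(1)),
    cofactors = vapply(anns, function(a) a@cofactorsTotal, integer(1)),
    carbonUnits = vapply(anns, function(a) a@carbonUnits, integer(1)),
    deltaG = vapply(anns, function(a) a@deltaG, numeric(1)))
  summary <- data.frame(
    nSolutions = length(anns),
    meanSteps = mean(per$steps),
    meanCofactors = mean(per$cofactors),
    cofactorsPerStep = mean(per$cofactors) / mean(per$steps),
    meanDeltaG = mean(per$deltaG))
  list(summary = summary, perSolution = per)
}
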