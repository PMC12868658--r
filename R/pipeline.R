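# End-to-end pipeline: expand -> query -> annotate -> summarize, with
# serialized outputs and a run manifest.

#' Write flow solutions to JSON
#'
#' @param solutions list of [FlowSolution-class].
#' @param path output path.
#' @param meta optional named list stored under \code{query} (autocatalyst,
#'   parameters, ...).
#' @return \code{path}, invisibly.
#' @export
writeSolutions <- function(solutions, path, meta = list()) {
  doc <- list(
    format = "crnflow-solutions", version = 1L, query = meta,
    exhausted = isTRUE(attr(solutions, "exhausted")),
    solutions = lapply(solutions, function(s) list(
      flows = as.list(s@flows[s@flows > 0L]),
      inflow = as.list(s@inflow), outflow = as.list(s@outflow),
      objective = s@objective, steps = s@steps, status = s@status)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read flow solutions written by [writeSolutions()]
#' @param path JSON path.
#' @return list of [FlowSolution-class] (with the stored query metadata as
#'   attribute \code{query}).
#' @export
readSolutions <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "crnflow-solutions"))
    stop("not a crnflow solutions document", call. = FALSE)
  out <- lapply(doc$solutions, function(s) {
    fl <- vapply(s$flows, as.integer, integer(1))
    new("FlowSolution",
        flows = fl,
        inflow = vapply(s$inflow, as.integer, integer(1)),
        outflow = vapply(s$outflow, as.integer, integer(1)),
        objective = as.numeric(s$objective), steps = as.integer(s$steps),
        status = as.character(s$status))
  })
  attr(out, "query") <- doc$query
  attr(out, "exhausted") <- isTRUE(doc$exhausted)
  out
}

#' Run the full pathway-design pipeline
#'
#' Executes the four stages expand, query, annotate and summarize from one
#' configuration and writes \code{crn.json}, \code{solutions.json},
#' \code{annotations.tsv}, \code{summary.tsv} and \code{manifest.json} into
#' the output directory. Later stages fail without discarding the outputs
#' of earlier ones; the manifest records each stage's status. Reruns on
#' identical inputs are deterministic.
#'
#' @param config named list or path to a YAML file with fields:
#'   \describe{
#'     \item{toySeed}{use the built-in toy chemistry with this seed
#'       (alternative to rulesDir/moleculesDir)}
#'     \item{rulesDir, moleculesDir}{GML directories (see
#'       [loadStudySpace()])}
#'     \item{steps, cMax, coaMax}{expansion parameters (defaults 2, 6, 1)}
#'     \item{autocatalyst, sources, sinks}{query species (display names)}
#'     \item{numSolutions, w, flowCap}{query parameters (defaults 1, 1000, 10)}
#'     \item{energyTable}{path to a formation-energy TSV (optional)}
#'     \item{cofactorConfig}{path to a cofactor JSON/YAML (optional; the toy
#'       chemistry supplies its own defaults)}
#'     \item{outDir}{output directory}
#'   }
#' @return invisible list with the in-memory results and the manifest.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outDir <- config$outDir
  if (is.null(outDir)) stop("config$outDir is required", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "crnflow",
                   version = as.character(utils::packageVersion("crnflow")),
                   config = config, stages = list())
  t00 <- Sys.time()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    entry <- list(stage = name,
                  status = if (inherits(res, "error")) "failed" else "completed",
                  seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    if (inherits(res, "error")) entry$error <- conditionMessage(res)
    manifest$stages[[name]] <<- entry
    res
  }
  finish <- function(results) {
    manifest$totalSeconds <- round(as.numeric(Sys.time() - t00, units = "secs"), 3)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(results, list(manifest = manifest)))
  }

  toy <- NULL
  crn <- stage("expand", function() {
    if (!is.null(config$toySeed)) {
      toy <<- makeToyChemistry(config$toySeed)
      mols <- toy$molecules; rules <- toy$rules
    } else {
      sp <- loadStudySpace(config$rulesDir, config$moleculesDir)
      mols <- sp$molecules; rules <- sp$rules
    }
    crn <- initCRN(mols, cMax = config$cMax %||% 6L, coaMax = config$coaMax %||% 1L)
    crn <- expandCRN(crn, rules, steps = config$steps %||% 2L, quiet = FALSE)
    writeCRN(crn, file.path(outDir, "crn.json"))
    crn
  })
  if (inherits(crn, "error")) return(finish(list()))

  cfg <- if (!is.null(config$cofactorConfig)) readCofactorConfig(config$cofactorConfig)
         else if (!is.null(toy)) toy$config
         else list(atp_species = character(), redox_reduced_species = character(),
                   carbon_species = character())
  autocat <- config$autocatalyst %||% cfg$autocatalyst
  sources <- config$sources %||% cfg$sources %||% character()
  sinks <- config$sinks %||% cfg$sinks %||% character()

  solutions <- stage("query", function() {
    q <- FlowQuery(crn, autocat, sources = sources, sinks = sinks,
                   w = config$w %||% 1000L, flowCap = config$flowCap %||% 10L,
                   numSolutions = config$numSolutions %||% 1L)
    sols <- enumerateDistinct(q)
    if (!length(sols)) stop("flow query infeasible: no pathway exists", call. = FALSE)
    writeSolutions(sols, file.path(outDir, "solutions.json"),
                   meta = list(autocatalyst = autocat,
                               numSolutions = q@numSolutions,
                               w = q@w, flowCap = q@flowCap))
    sols
  })
  if (inherits(solutions, "error")) return(finish(list(crn = crn)))

  energy <- NULL
  anns <- stage("annotate", function() {
    energy <<- if (!is.null(config$energyTable)) readEnergyTable(config$energyTable)
               else if (!is.null(toy))
                 structure(toy$energyTable, pH = 7, ionicStrength = 0.1)
    anns <- lapply(solutions, annotateSolution, config = cfg, energyTable = energy)
    tab <- annotationTable(anns)
    utils::write.table(tab, file.path(outDir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    anns
  })
  if (inherits(anns, "error")) return(finish(list(crn = crn, solutions = solutions)))

  summ <- stage("summarize", function() {
    sm <- summarizeSolutions(solutions, cfg, energy)
    utils::write.table(sm$summary, file.path(outDir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sm
  })
  if (inherits(summ, "error"))
    return(finish(list(crn = crn, solutions = solutions, annotations = anns)))
  finish(list(crn = crn, solutions = solutions, annotations = anns,
              summary = summ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flat table of annotations
annotationTable <- function(anns) {
  fmt <- function(v) paste(sprintf("%s:%g", names(v), v), collapse = "+")
  data.frame(
    solution = seq_along(anns),
    steps = vapply(anns, function(a) a@steps, integer(1)),
    atpUnits = vapply(anns, function(a) a@atpUnits, integer(1)),
    redoxUnits = vapply(anns, function(a) a@redoxUnits, integer(1)),
    cofactors = vapply(anns, function(a) a@cofactorsTotal, integer(1)),
    carbonUnits = vapply(anns, function(a) a@carbonUnits, integer(1)),
    atpPerCarbon = vapply(anns, function(a) a@atpPerCarbon, numeric(1)),
    cofactorsPerCarbon = vapply(anns, function(a) a@cofactorsPerCarbon, numeric(1)),
    cofactorsPerStep = vapply(anns, function(a) a@cofactorsPerStep, numeric(1)),
    deltaG = vapply(anns, function(a) a@deltaG, numeric(1)),
    netEducts = vapply(anns, function(a) fmt(a@netEducts), character(1)),
    netProducts = vapply(anns, function(a) fmt(a@netProducts), character(1)))
}

#' Compare annotated solutions against literature benchmark pathways
#'
#' Reads a benchmark TSV with columns \code{pathway}, \code{status},
#' \code{steps}, \code{atp}, \code{cofactors}, \code{carbons} (one row per
#' literature pathway), computes the per-carbon normalizations for both the
#' benchmarks and the supplied annotations, and returns the merged
#' comparison table. Zero-carbon rows get NA normalizations rather than a
#' division error.
#'
#' @param annotations list of [Annotation-class] (labelled "this work"), may
#'   be empty.
#' @param benchmarksFile path to the benchmark TSV; the package ships one
#'   with well-known natural and synthetic carbon-fixation cycles under
#'   \code{system.file("extdata", "benchmark_pathways.tsv", package = "crnflow")}.
#' @param labels optional names for the annotation rows.
#' @return data.frame with one row per pathway and derived columns
#'   \code{atpPerCarbon}, \code{cofactorsPerCarbon}.
#' @export
comparePathways <- function(annotations, benchmarksFile, labels = NULL) {
  bm <- utils::read.delim(benchmarksFile, stringsAsFactors = FALSE)
  needed <- c("pathway", "status", "steps", "atp", "cofactors", "carbons")
  if (!all(needed %in% names(bm)))
    stop(sprintf("benchmark file must have columns: %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  norm <- function(x, c) ifelse(c > 0, x / c, NA_real_)
  rows <- bm[, needed]
  if (length(annotations)) {
    lab <- labels %||% sprintf("this work, solution %d", seq_along(annotations))
    ours <- data.frame(
      pathway = lab, status = "theoretical",
      steps = vapply(annotations, function(a) a@steps, integer(1)),
      atp = vapply(annotations, function(a) a@atpUnits, integer(1)),
      cofactors = vapply(annotations, function(a) a@cofactorsTotal, integer(1)),
      carbons = vapply(annotations, function(a) a@carbonUnits, integer(1)))
    rows <- rbind(ours, rows)
  }
  rows$atpPerCarbon <- norm(rows$atp, rows$carbons)
  rows$cofactorsPerCarbon <- norm(rows$cofactors, rows$carbons)
  rows
}
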