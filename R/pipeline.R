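#' @include AllClasses.R AllGenerics.R structure-io.R synthetic.R ccs.R
#' @include sampler.R collapse.R imms.R
NULL

#' Default workflow configuration
#'
#' A single nested list with one section per stage; every default is echoed
#' into the report provenance so no setting is hidden. The input is either a
#' fixture recipe (`fixture` section with [syntheticAntibodyParams()]
#' arguments) or a prepared structure (`input` section: `pdb`, `topology`
#' JSON path, optional `radii` CSV).
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged one level deep).
#' @return configuration list for [runWorkflow()]
#' @export
workflowConfig <- function(...) {
  cfg <- list(
    fixture = list(beadsPerDomain = 40L, flexibleResiduesPerArm = 5L,
                   seed = 1L),
    input = NULL,
    ccs = list(nOrientations = 300L, nPoints = 40000L, seed = 1L),
    sampler = list(nSamples = 1000L, stepSize = 15, clashFactor = 0.7,
                   seed = 1L),
    select = list(k = 3L, diversityRmsd = 5),
    collapse = list(netCharge = 21L, nSteps = 200000L, seeds = c(11L, 12L, 13L),
                    rule = "surface_spread"),
    experiment = NULL,  # list(mean =, sd =) or NULL
    band = 0.06)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(dots[[nm]])) cfg[[nm]][[k]] <- dots[[nm]][[k]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Run the integrative gas-phase modelling workflow
#'
#' Executes the four-stage pipeline: initial model CCS -> Fab-arm RRT
#' sampling -> compact-conformer selection -> charged vacuum collapse (one
#' replicate per selected conformer) -> comparison against an experimental
#' CCS when supplied. Fully reproducible from the configuration seeds.
#'
#' @param config list from [workflowConfig()], or a path to a YAML file with
#'   the same structure
#' @param outDir optional directory; when given, intermediates are written
#'   (initial/selected PDBs, ensemble CSV, stage-report JSON)
#' @return a [StageReport]; the ensemble, selection and trajectories are
#'   attached as the attribute `"artifacts"`.
#' @export
runWorkflow <- function(config = workflowConfig(), outDir = NULL) {
  if (is.character(config)) config <- .configFromYAML(config)
  stage <- "input"
  report <- tryCatch({
    if (!is.null(config$input)) {
      structure <- readPDB(config$input$pdb)
      topology <- readTopologyJSON(config$input$topology)
      radii <- if (!is.null(config$input$radii)) readRadii(config$input$radii)
        else defaultRadii()
    } else {
      fx <- do.call(syntheticAntibodyParams, config$fixture)
      fx <- makeSyntheticAntibody(fx)
      structure <- fx$structure
      topology <- fx$topology
      radii <- fx$radii
    }

    stage <- "initial CCS"
    cc <- config$ccs
    initial <- projectionArea(structure, radii,
                              nOrientations = cc$nOrientations,
                              nPoints = cc$nPoints, seed = cc$seed)

    stage <- "Fab-arm sampling"
    sp <- config$sampler
    ens <- sampleEnsemble(structure, topology,
                          rrtParams(nSamples = sp$nSamples,
                                    stepSize = sp$stepSize,
                                    clashFactor = sp$clashFactor,
                                    seed = sp$seed),
                          radii)
    summ <- summariseEnsemble(ens)

    stage <- "selection"
    k <- min(config$select$k, nConformers(ens))
    sel <- selectCompact(ens, k, config$select$diversityRmsd)
    # re-score the selected conformers at full CCS settings
    selCcs <- vapply(sel$structures, function(s)
      ccs(projectionArea(s, radii, nOrientations = cc$nOrientations,
                         nPoints = cc$nPoints, seed = cc$seed)), numeric(1))

    stage <- "collapse"
    cl <- config$collapse
    ffArgs <- cl[setdiff(names(cl), c("netCharge", "seeds", "rule"))]
    reps <- replicateCollapse(
      sel$structures, topology, cl$netCharge,
      do.call(forceFieldParams, ffArgs), radii,
      seeds = rep_len(cl$seeds, length(sel$structures)),
      rule = if (is.null(cl$rule)) "surface_spread" else cl$rule)

    stage <- "report"
    makeReport(
      initialCcs = ccs(initial), initialSE = initial@mcStandardError,
      sampledMinCcs = min(selCcs), sampledSE = initial@mcStandardError,
      collapsedCcs = vapply(reps$trajectories, function(t) t@finalCcs,
                            numeric(1)),
      collapsedRange = vapply(reps$trajectories,
                              function(t) t@finalWindowRange, numeric(1)),
      experiment = config$experiment, band = config$band,
      provenance = list(config = config, ensembleSummary = summ[
        c("n", "ccsMin", "ccsMax", "deltaCcs", "overlapFraction")],
        selectedIndices = sel$indices, collapseSpreadPct = reps$spreadPct,
        samplerTruncated = ens@truncated),
      artifacts = list(structure = structure, topology = topology,
                       radii = radii, ensemble = ens, selection = sel,
                       trajectories = reps$trajectories))
  }, error = function(e) {
    stop("workflow failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(outDir)) .writeArtifacts(report, outDir)
  report
}

#' Assemble a stage report
#'
#' Builds the stage summary from CCS values (computed by the pipeline, or
#' injected directly for a report on external numbers): percent reductions
#' between consecutive stages, each relative to the preceding stage, and
#' model-vs-experiment verdicts. Missing stages produce a partial report
#' with explicit gaps.
#'
#' @param initialCcs,sampledMinCcs CCS of the initial model and of the
#'   lowest-CCS sampled conformer, Angstrom^2 (NA allowed)
#' @param collapsedCcs vector of final collapse CCS values (one per
#'   replicate; NA allowed)
#' @param initialSE,sampledSE Monte-Carlo uncertainties for the model stages
#' @param collapsedRange final-window CCS range per replicate
#' @param experiment `list(mean =, sd =)` or NULL
#' @param band comparison band, see [compareToExperiment()]
#' @param provenance,artifacts free-form lists carried on the report
#' @return a [StageReport]
#' @examples
#' makeReport(initialCcs = 9532, sampledMinCcs = 8756, collapsedCcs = 7226,
#'            experiment = list(mean = 6827, sd = 81))
#' @export
makeReport <- function(initialCcs = NA_real_, sampledMinCcs = NA_real_,
                       collapsedCcs = NA_real_, initialSE = NA_real_,
                       sampledSE = NA_real_, collapsedRange = NA_real_,
                       experiment = NULL, band = 0.06,
                       provenance = list(), artifacts = NULL) {
  collapsedFinal <- if (all(is.na(collapsedCcs))) NA_real_ else
    mean(collapsedCcs, na.rm = TRUE)
  stages <- c(initial = initialCcs, sampledMin = sampledMinCcs,
              collapsedFinal = collapsedFinal)
  uncertainties <- c(initial = initialSE, sampledMin = sampledSE,
                     collapsedFinal = if (all(is.na(collapsedRange))) NA_real_
                     else mean(collapsedRange, na.rm = TRUE))
  reductions <- c(
    sampling = 100 * (initialCcs - sampledMinCcs) / initialCcs,
    collapse = 100 * (sampledMinCcs - collapsedFinal) / sampledMinCcs)

  comparison <- data.frame()
  if (!is.null(experiment) && is.finite(experiment$mean)) {
    rows <- list()
    for (s in names(stages)) {
      if (is.na(stages[[s]])) next
      v <- compareToExperiment(stages[[s]], experiment$mean,
                               if (is.null(experiment$sd)) NA else experiment$sd,
                               band)
      v$stage <- s
      rows[[s]] <- v
    }
    if (length(collapsedCcs) > 1 && !all(is.na(collapsedCcs))) {
      for (r in seq_along(collapsedCcs)) {
        v <- compareToExperiment(collapsedCcs[r], experiment$mean,
                                 if (is.null(experiment$sd)) NA else experiment$sd,
                                 band)
        v$stage <- paste0("collapsedReplicate", r)
        rows[[v$stage]] <- v
      }
    }
    comparison <- do.call(rbind, rows)
    rownames(comparison) <- NULL
  }

  replicates <- data.frame(
    replicate = seq_along(collapsedCcs), finalCcs = collapsedCcs,
    finalWindowRange = rep_len(collapsedRange, length(collapsedCcs)))

  rep <- new("StageReport", stages = stages, uncertainties = uncertainties,
             reductions = reductions, comparison = comparison,
             replicates = replicates, provenance = provenance)
  if (!is.null(artifacts)) attr(rep, "artifacts") <- artifacts
  rep
}

#' Serialise a stage report to JSON
#' @param report a [StageReport]
#' @param path output path
#' @return invisibly, the path
#' @export
reportToJSON <- function(report, path) {
  obj <- list(stages = as.list(report@stages),
              uncertainties = as.list(report@uncertainties),
              reductions = as.list(report@reductions),
              comparison = report@comparison,
              replicates = report@replicates,
              provenance = report@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

.configFromYAML <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(workflowConfig, cfg)
}

.writeArtifacts <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  art <- attr(report, "artifacts")
  if (!is.null(art)) {
    writePDB(art$structure, file.path(outDir, "initial.pdb"))
    topologyToJSON(art$topology, file.path(outDir, "topology.json"))
    ens <- art$ensemble
    utils::write.csv(
      data.frame(conformer = seq_len(nConformers(ens)), ccs = ccs(ens),
                 ens@dihedrals),
      file.path(outDir, "ensemble.csv"), row.names = FALSE)
    for (i in seq_along(art$selection$structures))
      writePDB(art$selection$structures[[i]],
               file.path(outDir, sprintf("selected_%d.pdb", i)))
    for (r in seq_along(art$trajectories)) {
      tr <- art$trajectories[[r]]
      utils::write.csv(
        data.frame(step = tr@stepIndex, ccs = tr@ccsSeries),
        file.path(outDir, sprintf("collapse_ccs_%d.csv", r)), row.names = FALSE)
    }
  }
  reportToJSON(report, file.path(outDir, "stage_report.json"))
  invisible(outDir)
}
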